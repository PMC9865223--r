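test_that("noiseless scenes reproduce the class means exactly", {
  sim <- simulate_scene(default_profiles(),
                        scene_config(plots_per_class = 3, seed = 2,
                                     noise_multiplier = 0))
  profs <- default_profiles()
  tab <- extract_samples(sim$stack, sim$plots)
  for (cl in veg_classes()) {
    sub <- tab[tab$class == cl & tab$phase == "JUN", ]
    for (b in c("RED", "RE2", "NIR", "RE4")) {
      want <- profs[[cl]]$mean["JUN", b]
      expect_true(all(sub$reflectance[sub$band == b] == want))
    }
  }
  # labels agree with plot classes everywhere
  expect_identical(sim$labels[cbind(sim$plots$row, sim$plots$col)],
                   sim$plots$class)
})

test_that("scenes are reproducible under a seed and vary across seeds", {
  cfg <- scene_config(plots_per_class = 3, seed = 5)
  s1 <- simulate_scene(default_profiles(), cfg)
  s2 <- simulate_scene(default_profiles(), cfg)
  expect_identical(s1$stack$reflectance, s2$stack$reflectance)
  expect_identical(s1$plots, s2$plots)
  s3 <- simulate_scene(default_profiles(),
                       scene_config(plots_per_class = 3, seed = 6))
  expect_false(identical(s1$stack$reflectance, s3$stack$reflectance))
})

test_that("the study preset mirrors the 270-plot field campaign", {
  cfg <- scene_config(preset = "study", seed = 1)
  expect_identical(sum(cfg$plots_per_class), 270L)
  sim <- simulate_scene(default_profiles(), cfg)
  expect_identical(length(unique(sim$plots$plot_id)), 270L)
  expect_identical(nrow(sim$plots), 2430L)  # 270 x 9 labelled pixels
  counts <- table(sim$plots$class) / 9
  expect_identical(as.integer(counts[veg_classes()]),
                   unname(cfg$plots_per_class))
})

test_that("sampled noise matches the configured dispersion", {
  tab <- simulate_sample_table(n_per_class = 4000, seed = 3)
  v <- tab$reflectance[tab$class == "pinus_tabuliformis" &
                         tab$phase == "JUN" & tab$band == "NIR"]
  expect_lt(abs(sd(v) - 0.008), 0.001)
  mu <- default_profiles()$pinus_tabuliformis$mean["JUN", "NIR"]
  expect_lt(abs(mean(v) - mu), 0.001)
  flat <- simulate_sample_table(n_per_class = 100, seed = 3,
                                noise_multiplier = 0)
  st <- class_spectral_stats(flat)
  expect_true(all(st$sd == 0))
  # distinct seeds give distinct draws
  expect_false(identical(simulate_sample_table(n_per_class = 5, seed = 1),
                         simulate_sample_table(n_per_class = 5, seed = 2)))
})

test_that("zero-noise sample tables equal the profile means cell by cell", {
  tab <- simulate_sample_table(n_per_class = 2, seed = 9,
                               noise_multiplier = 0)
  profs <- default_profiles()
  agg <- class_spectral_stats(tab)
  for (i in seq_len(nrow(agg)))
    expect_identical(agg$mean[i],
                     unname(profs[[agg$class[i]]]$mean[agg$phase[i],
                                                       agg$band[i]]))
})

test_that("default profiles encode the documented phenological contrasts", {
  p <- default_profiles(noise_sd = 0)
  m <- function(cl) p[[cl]]$mean
  pool <- c("quercus_wutaishanica", "scrub_grass", "larix_principis", "shaw")

  # pine-oak: February RE4 equals SWIR1; the to-identify pool sits well below
  expect_equal(m("pine_oak_mixed")["FEB", "RE4"],
               m("pine_oak_mixed")["FEB", "SWIR1"], ignore_attr = TRUE)
  for (cl in pool)
    expect_lt(m(cl)["FEB", "RE4"], m(cl)["FEB", "SWIR1"])

  # Quercus: June and October NIR/RE4 highest in its pool; bounded sums
  for (cl in setdiff(pool, "quercus_wutaishanica")) {
    for (b in c("NIR", "RE4")) {
      expect_gt(m("quercus_wutaishanica")["JUN", b], m(cl)["JUN", b])
      expect_gt(m("quercus_wutaishanica")["OCT", b], m(cl)["OCT", b])
    }
  }
  for (cl in pool) {
    expect_lt(m(cl)["JUN", "RE4"], 0.54)
    expect_lt(m(cl)["OCT", "RE4"], 0.34)
    expect_lt(m(cl)["JUN", "RE4"] + m(cl)["OCT", "RE4"], 1)
  }

  # scrub grass rises June -> August in the red-edge/NIR bands, others fall
  for (b in c("RE2", "RE3", "NIR", "RE4")) {
    expect_gt(m("scrub_grass")["AUG", b], m("scrub_grass")["JUN", b])
    for (cl in c("larix_principis", "shaw"))
      expect_lt(m(cl)["AUG", b], m(cl)["JUN", b])
  }

  # shaw exceeds Larix in June, falls below it in October
  for (b in c("RE2", "RE3", "NIR", "RE4")) {
    expect_gt(m("shaw")["JUN", b], m("larix_principis")["JUN", b])
    expect_lt(m("shaw")["OCT", b], m("larix_principis")["OCT", b])
  }

  # NDVI contrasts for the two typical-index rules
  nd <- function(cl, ph) ndvi(m(cl)[ph, "RED"], m(cl)[ph, "NIR"])
  others <- setdiff(veg_classes(), "pinus_tabuliformis")
  expect_true(all(nd("pinus_tabuliformis", "DEC") >
                    sapply(others, nd, ph = "DEC") + 0.15))
  rest <- setdiff(veg_classes(), "crops")
  expect_true(all(nd("crops", "APR") < sapply(rest, nd, ph = "APR") - 0.15))

  # means stay within the physical reflectance range
  for (cl in veg_classes())
    expect_true(all(m(cl) >= 0 & m(cl) <= 1))
})

test_that("noiseless scenes are perfectly separable end to end", {
  sim <- simulate_scene(default_profiles(),
                        scene_config(plots_per_class = 5, seed = 4,
                                     noise_multiplier = 0))
  fs <- optimal_feature_set(sim$stack)
  ft <- feature_table(fs, sim$plots)
  sp <- split_train_verify(sim$plots, 0.6, seed = 4)
  tr <- ft[ft$plot_id %in% sp$plot_id[sp$role == "train"], ]
  ve <- ft[ft$plot_id %in% sp$plot_id[sp$role == "verify"], ]
  tree <- build_knowledge_tree(tr)
  pred <- classify_tree(tree, ve)
  expect_equal(overall_accuracy(confusion_matrix(pred, ve$class,
                                                 veg_classes())), 1)
})

test_that("scene configs validate their inputs", {
  expect_error(scene_config(plots_per_class = 0), ">= 1")
  expect_error(scene_config(plots_per_class = c(1, 2)), "length")
  expect_error(scene_config(plot_size = 0), "plot_size")
  expect_error(simulate_sample_table(n_per_class = 1), ">= 2")
})
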