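# independent oracle: try every midpoint of adjacent distinct pooled values
# under the direction pointing at the target mean, count errors
bf_threshold <- function(target, rest) {
  pooled <- sort(unique(c(target, rest)))
  cuts <- (pooled[-length(pooled)] + pooled[-1]) / 2
  dir <- if (mean(target) >= mean(rest)) "GE" else "LE"
  errs <- sapply(cuts, function(t) {
    if (dir == "GE") sum(target < t) + sum(rest >= t)
    else sum(target > t) + sum(rest <= t)
  })
  list(threshold = cuts[which.min(errs)], direction = dir,
       errors = min(errs))
}

test_that("threshold calibration separates cleanly separable classes", {
  cal <- calibrate_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_identical(cal$direction, "GE")
  expect_gt(cal$threshold, 0.2)
  expect_lt(cal$threshold, 0.8)
  expect_identical(cal$errors, 0L)
  cal2 <- calibrate_threshold(c(0.1, 0.2), c(0.8, 0.9))
  expect_identical(cal2$direction, "LE")
  expect_identical(cal2$errors, 0L)
})

test_that("overlapping classes get the minimal-error split", {
  cal <- calibrate_threshold(c(0.1, 0.3), c(0.2, 0.4))
  expect_identical(cal$errors, 1L)
  expect_identical(cal$direction, "LE")
  bf <- bf_threshold(c(0.1, 0.3), c(0.2, 0.4))
  expect_equal(cal$threshold, bf$threshold)
})

test_that("calibration equals exhaustive split search on random samples", {
  set.seed(77)
  for (i in 1:40) {
    n1 <- sample(2:100, 1); n2 <- sample(2:100, 1)
    target <- round(rnorm(n1, mean = runif(1, -1, 1)), 2)
    rest <- round(rnorm(n2, mean = runif(1, -1, 1)), 2)
    if (length(unique(c(target, rest))) < 2) next
    cal <- calibrate_threshold(target, rest)
    bf <- bf_threshold(target, rest)
    expect_identical(cal$direction, bf$direction)
    expect_equal(cal$threshold, bf$threshold)
    expect_identical(cal$errors, as.integer(bf$errors))
  }
})

test_that("calibration rejects inseparable constant vectors", {
  expect_error(calibrate_threshold(c(0.5, 0.5), c(0.5, 0.5)), "constant")
  expect_error(calibrate_threshold(numeric(0), 1), "empty")
})

test_that("the knowledge tree is perfectly calibrated on noiseless data", {
  ft <- simulate_feature_table(n_per_class = 9, seed = 5,
                               noise_multiplier = 0)
  tree <- build_knowledge_tree(ft)
  expect_identical(tree$fallback, "larix_principis")
  expect_identical(vapply(tree$rules, function(r) r$class, character(1)),
                   default_hierarchy()$class)
  pred <- classify_tree(tree, ft)
  expect_identical(pred, ft$class)  # 100% training accuracy
  # determinism: same data, same tree
  tree2 <- build_knowledge_tree(ft)
  expect_identical(vapply(tree$rules, function(r) r$threshold, numeric(1)),
                   vapply(tree2$rules, function(r) r$threshold, numeric(1)))
})

test_that("tree building requires every class in training data", {
  ft <- simulate_feature_table(n_per_class = 5, seed = 6)
  expect_error(build_knowledge_tree(ft[ft$class != "shaw", ]), "shaw")
})

test_that("rule directions point at the expected side of each contrast", {
  ft <- simulate_feature_table(n_per_class = 20, seed = 7)
  tree <- build_knowledge_tree(ft)
  dirs <- setNames(vapply(tree$rules, function(r) r$direction, character(1)),
                   vapply(tree$rules, function(r) r$feature, character(1)))
  expect_identical(dirs[["NDVI@DEC"]], "GE")   # evergreen pine high
  expect_identical(dirs[["NDVI@APR"]], "LE")   # bare crops low
  expect_identical(dirs[["MTM-NDQI"]], "LE")   # Quercus has largest RE4 sum
  expect_identical(dirs[["MTM-DSI"]], "LE")    # scrub rises June->August
  expect_identical(dirs[["MTM-RSI"]], "GE")    # shaw on the high side
})

test_that("classification is sequential masking with a fallback", {
  tree <- knowledge_tree(list(
    decision_rule("f1", 0.5, "GE", "A"),
    decision_rule("f2", 0.5, "GE", "B")), fallback = "C")
  df <- data.frame(f1 = c(0.9, 0.1, 0.1, 0.9),
                   f2 = c(0.9, 0.9, 0.1, 0.1))
  # first rule wins even when later rules would also fire
  expect_identical(classify_tree(tree, df), c("A", "B", "C", "A"))
  # masked value at a needed rule -> nodata; earlier assignment unaffected
  df2 <- data.frame(f1 = c(0.9, NA, 0.1), f2 = c(NA, 0.9, NA))
  expect_identical(classify_tree(tree, df2), c("A", NA, NA))
})

test_that("dropping a later rule never changes earlier assignments", {
  ft <- simulate_feature_table(n_per_class = 30, seed = 8)
  tree <- build_knowledge_tree(ft)
  full <- classify_tree(tree, ft)
  for (k in 1:5) {
    partial <- classify_tree(tree, ft, n_rules = k)
    assigned <- vapply(tree$rules[seq_len(k)], function(r) r$class,
                       character(1))
    done <- partial %in% assigned
    expect_identical(full[done], partial[done])
  }
  # totality: every row gets exactly one of the seven labels
  expect_false(anyNA(full))
  expect_identical(length(full), nrow(ft))
  expect_true(all(full %in% veg_classes()))
})

test_that("tree classification works identically on rasters and tables", {
  sim <- simulate_scene(default_profiles(),
                        scene_config(plots_per_class = 4, seed = 9))
  fs <- optimal_feature_set(sim$stack)
  ft <- feature_table(fs, sim$plots)
  tree <- build_knowledge_tree(ft)
  lbl_raster <- classify_tree(tree, fs)
  expect_identical(dim(lbl_raster), dim(sim$labels))
  at_plots <- lbl_raster[cbind(sim$plots$row, sim$plots$col)]
  expect_identical(at_plots, classify_tree(tree, ft))
})

test_that("trees survive JSON round-trips", {
  ft <- simulate_feature_table(n_per_class = 10, seed = 10)
  tree <- build_knowledge_tree(ft)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tree, path)
  back <- read_tree_json(path)
  expect_identical(classify_tree(back, ft), classify_tree(tree, ft))
  expect_identical(back$fallback, tree$fallback)
})

test_that("expert threshold overrides replace calibration", {
  ft <- simulate_feature_table(n_per_class = 10, seed = 11)
  tree <- build_knowledge_tree(
    ft, overrides = list(`NDVI@DEC` = list(threshold = 0.55,
                                           direction = "GE")))
  expect_identical(tree$rules[[1]]$threshold, 0.55)
})

test_that("the ensemble comparator follows its contract", {
  ft <- simulate_feature_table(n_per_class = 20, seed = 12)
  feats <- ft[, setdiff(names(ft), c("class", "pixel"))]
  expect_identical(ncol(feats), 6L)
  m <- train_ensemble(feats, ft$class, ensemble_config(seed = 4))
  expect_identical(m$mtry, 2L)                 # floor(sqrt(6))
  expect_identical(m$fit$ntree, 250L)
  # determinism under the seed
  m2 <- train_ensemble(feats, ft$class, ensemble_config(seed = 4))
  expect_identical(as.character(classify_ensemble(m, feats)),
                   as.character(classify_ensemble(m2, feats)))
  # separable training data is reproduced exactly
  ft0 <- simulate_feature_table(n_per_class = 20, seed = 13,
                                noise_multiplier = 0)
  feats0 <- ft0[, setdiff(names(ft0), c("class", "pixel"))]
  m0 <- train_ensemble(feats0, ft0$class, ensemble_config(seed = 1))
  expect_identical(as.character(classify_ensemble(m0, feats0)), ft0$class)
  # empty prediction input and column mismatch
  expect_length(classify_ensemble(m, feats[0, ]), 0)
  expect_error(classify_ensemble(m, feats[, 1:3]), "missing feature")
  expect_error(train_ensemble(feats, rep("crops", nrow(feats))),
               "single class")
})
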