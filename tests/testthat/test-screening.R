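test_that("class spectral statistics use the sample (n-1) deviation", {
  tab <- rbind(make_sample_rows("crops", "RED", "FEB", c(0.2, 0.4)),
               make_sample_rows("shaw", "RED", "FEB", c(0.3, 0.3, 0.3)))
  st <- class_spectral_stats(tab)
  crops <- st[st$class == "crops", ]
  expect_equal(crops$mean, 0.3)
  expect_equal(crops$sd, sd(c(0.2, 0.4)))   # 0.1414214
  expect_equal(st[st$class == "shaw", "sd"], 0)
  expect_error(class_spectral_stats(tab[0, ]), "empty")
  expect_error(
    class_spectral_stats(make_sample_rows("crops", "RED", "FEB", 0.1)),
    ">= 2")
})

test_that("a full synthetic sample set yields 7 x 6 x 10 statistic rows", {
  tab <- simulate_sample_table(n_per_class = 5, seed = 2)
  st <- class_spectral_stats(tab)
  expect_identical(nrow(st), 7L * 6L * 10L)
  expect_true(all(st$n == 5L))
})

test_that("the SD-sum score adds both operands over the class scope", {
  # sd(c(0.29, 0.30, 0.31)) is exactly 0.01
  v01 <- c(0.29, 0.30, 0.31)
  mk <- function(cls, sdv) rbind(
    make_sample_rows(cls, "RE4", "FEB", 0.3 + sdv / 0.01 * (v01 - 0.3)),
    make_sample_rows(cls, "SWIR1", "FEB", 0.3 + sdv / 0.01 * (v01 - 0.3)))
  cmb <- band_combination("RE4", "FEB", "SWIR1", "FEB",
                          target_class = "crops",
                          classes_to_identify = c("crops", "scrub_grass",
                                                  "shaw", "larix_principis"))
  one <- mk("crops", 0.01)
  expect_equal(sd_sum_score(cmb, one, scope = "target_only"), 200)
  four <- rbind(mk("crops", 0.005), mk("scrub_grass", 0.005),
                mk("shaw", 0.005), mk("larix_principis", 0.005))
  expect_equal(sd_sum_score(cmb, four, scope = "to_identify"), 400)
  # zero-noise samples score zero
  flat <- rbind(make_sample_rows("crops", "RE4", "FEB", rep(0.3, 4)),
                make_sample_rows("crops", "SWIR1", "FEB", rep(0.2, 4)))
  expect_equal(sd_sum_score(cmb, flat, scope = "target_only"), 0)
})

test_that("SD-sum scores scale linearly with reflectance", {
  tab <- simulate_sample_table(n_per_class = 30, seed = 5)
  cmb <- band_combination("RE2", "JUN", "RE2", "AUG",
                          target_class = "scrub_grass")
  s1 <- sd_sum_score(cmb, tab, scope = "target_only")
  tab2 <- tab; tab2$reflectance <- tab2$reflectance * 0.5
  s2 <- sd_sum_score(cmb, tab2, scope = "target_only")
  expect_equal(s2, 0.5 * s1)
})

test_that("screening selects the minimal SD sum, first on ties", {
  rep1 <- screening_report(c("a", "b"), c(391.40, 456.15))
  expect_identical(selected_combination(rep1)$combination, "a")
  rep2 <- screening_report(c("a", "b"), c(720.60, 719.15))
  expect_identical(selected_combination(rep2)$combination, "b")
  tie <- screening_report(c("x", "y"), c(5, 5))
  expect_identical(selected_combination(tie)$combination, "x")
  single <- screening_report("only", 999)
  expect_true(single$selected)
  expect_error(screening_report(character(0), numeric(0)))
})

test_that("candidate permutation never changes the winning score", {
  tab <- simulate_sample_table(n_per_class = 20, seed = 8)
  cands <- list(
    band_combination("RE2", "JUN", "RE2", "AUG", target_class = "scrub_grass"),
    band_combination("RE3", "JUN", "RE3", "AUG", target_class = "scrub_grass"),
    band_combination("NIR", "JUN", "NIR", "AUG", target_class = "scrub_grass"),
    band_combination("RE4", "JUN", "RE4", "AUG", target_class = "scrub_grass"))
  base <- select_combination(cands, tab, scope = "target_only")
  best <- selected_combination(base)$sd_sum
  set.seed(3)
  for (i in 1:5) {
    perm <- sample(cands)
    r <- select_combination(perm, tab, scope = "target_only")
    expect_equal(selected_combination(r)$sd_sum, best)
  }
})

test_that("zero-noise samples give all-zero scores and select the first", {
  tab <- simulate_sample_table(n_per_class = 10, seed = 1,
                               noise_multiplier = 0)
  cands <- list(
    band_combination("NIR", "JUN", "NIR", "OCT",
                     target_class = "quercus_wutaishanica"),
    band_combination("RE4", "JUN", "RE4", "OCT",
                     target_class = "quercus_wutaishanica"))
  r <- select_combination(cands, tab, scope = "target_only")
  expect_true(all(r$sd_sum == 0))
  expect_identical(which(r$selected), 1L)
})

test_that("instantiated definitions reproduce the four indices bit-for-bit", {
  defs <- list(
    list(cmb = band_combination("RE4", "FEB", "SWIR1", "FEB"),
         tmpl = "DIFFERENCE", name = "UTM-DMI", fun = utm_dmi),
    list(cmb = band_combination("RE4", "JUN", "RE4", "OCT"),
         tmpl = "NORMALIZED_COMPLEMENT", name = "MTM-NDQI", fun = mtm_ndqi),
    list(cmb = band_combination("RE2", "JUN", "RE2", "AUG"),
         tmpl = "DIFFERENCE", name = "MTM-DSI", fun = mtm_dsi),
    list(cmb = band_combination("RE2", "JUN", "RE2", "OCT"),
         tmpl = "RELATIVE_CHANGE", name = "MTM-RSI", fun = mtm_rsi))
  for (seed in 1:3) {
    stk <- make_test_stack(seed = 100 + seed)
    for (d in defs) {
      def <- instantiate_index(d$cmb, d$tmpl, d$name)
      got <- evaluate_index(def, stk)$values
      want <- d$fun(stack_band(stk, d$cmb$band_a, d$cmb$phase_a),
                    stack_band(stk, d$cmb$band_b, d$cmb$phase_b))
      expect_identical(got, want)  # bit-exact, not just approximately equal
    }
  }
})

test_that("index definitions survive JSON serialization", {
  cmb <- band_combination("RE2", "JUN", "RE2", "OCT",
                          target_class = "shaw",
                          classes_to_identify = c("shaw", "larix_principis"))
  def <- instantiate_index(cmb, "RELATIVE_CHANGE", "MTM-RSI")
  path <- withr::local_tempfile(fileext = ".json")
  write_index_definitions(list(def), path)
  back <- read_index_definitions(path)[[1]]
  stk <- make_test_stack(seed = 21)
  expect_identical(evaluate_index(back, stk)$values,
                   evaluate_index(def, stk)$values)
  expect_identical(back$combination$classes_to_identify,
                   c("shaw", "larix_principis"))
})

test_that("overlap fraction counts pooled samples in the range intersection", {
  expect_equal(overlap_fraction(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(overlap_fraction(c(1, 2), c(5, 6)), 0)
  expect_equal(overlap_fraction(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)
  expect_error(overlap_fraction(numeric(0), 1), "empty")
  # IQR variant is never wider than the range variant
  set.seed(4)
  a <- rnorm(100); b <- rnorm(100, 1)
  expect_lte(overlap_fraction(a, b, "iqr"), overlap_fraction(a, b, "range"))
})

test_that("exhaustive enumeration produces distinct, optionally cross-phase pairs", {
  cands <- enumerate_combinations(c("RE2", "RE4"), c("JUN", "OCT"))
  expect_length(cands, 6)  # C(4,2)
  cross <- enumerate_combinations(c("RE2", "RE4"), c("JUN", "OCT"),
                                  cross_phase_only = TRUE)
  expect_length(cross, 4)
  expect_true(all(vapply(cross, function(c) c$phase_a != c$phase_b,
                         logical(1))))
})
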