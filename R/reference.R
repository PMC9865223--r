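#' Reference tables from the Lingkong Mountain field study
#'
#' Published summary tables from the Lingkong Mountain Nature Reserve
#' vegetation survey on which this toolkit's method was developed,
#' shipped as plain CSVs under `inst/extdata/`. The survey imagery and
#' plots themselves are not publicly deposited, so these printed
#' aggregates are the only real-data ground truth available for checking
#' the package's arithmetic:
#'
#' * `"confusion"` -- the 7 x 7 verification confusion matrix of the
#'   knowledge-decision-tree classification (630 pixels; rows =
#'   classified, columns = ground truth), returned as a
#'   [confusion_matrix()].
#' * `"screening"` -- the candidate feature-band-combination
#'   standard-deviation sums (x 10^4 scale) screened for each of the
#'   four modified indices; data frame (target_class, combination,
#'   sd_sum).
#' * `"feature_set_oa"` -- overall accuracy (percent) and Kappa of the
#'   random-forest comparison across the optimal feature set and the
#'   three time-series typical-index sets; data frame (feature_set,
#'   oa_pct, kappa).
#'
#' @param which which table to load.
#' @return see above.
#' @export
lmnr_reference <- function(which = c("confusion", "screening",
                                     "feature_set_oa")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      switch(which,
                             confusion = "lmnr_tree_confusion.csv",
                             screening = "lmnr_screening_scores.csv",
                             feature_set_oa = "lmnr_feature_set_oa.csv"),
                      package = "vegindex", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (which == "confusion") {
    m <- as.matrix(df[, -1])
    rownames(m) <- df$classified
    return(as_confusion_matrix(m, classes = df$classified))
  }
  df
}
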