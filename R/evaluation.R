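#' Confusion matrix
#'
#' k x k contingency table of classification results with rows =
#' classified labels and columns = ground truth -- the orientation under
#' which producer accuracy divides the diagonal by column totals and
#' user accuracy by row totals.
#'
#' @param predicted vector of predicted labels.
#' @param truth vector of ground-truth labels, same length.
#' @param classes ordered class labels; both label vectors must be
#'   subsets of it. Defaults to the union of observed labels.
#' @return integer matrix of class `confusion_matrix` with dimnames
#'   (classified, truth).
#' @export
confusion_matrix <- function(predicted, truth, classes = NULL) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (is.null(classes)) classes <- sort(unique(c(predicted, truth)))
  bad <- setdiff(c(predicted, truth), classes)
  if (length(bad))
    stop("label(s) not in class order: ", paste(unique(bad), collapse = ", "))
  cm <- table(factor(predicted, levels = classes),
              factor(truth, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(classified = classes, truth = classes))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Wrap an existing count matrix as a confusion matrix
#'
#' For published or externally computed k x k count tables (rows =
#' classified, columns = ground truth).
#'
#' @param counts square numeric matrix of nonnegative counts.
#' @param classes optional class labels (defaults to existing dimnames
#'   or `V1..Vk`).
#' @return a `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, classes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (is.null(classes))
    classes <- if (!is.null(rownames(counts))) rownames(counts)
               else paste0("V", seq_len(nrow(counts)))
  cm <- matrix(as.integer(round(counts)), nrow = nrow(counts),
               dimnames = list(classified = classes, truth = classes))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

.cm_check <- function(cm) {
  if (!inherits(cm, "confusion_matrix"))
    stop("not a confusion_matrix; see confusion_matrix() / as_confusion_matrix()")
  cm
}

#' Accuracy statistics from a confusion matrix
#'
#' `overall_accuracy()` is trace/N. `producer_accuracy()` divides each
#' diagonal count by its ground-truth (column) total: the omission-error
#' complement. `user_accuracy()` divides by the classified (row) total:
#' the commission-error complement. `kappa()` is the chance-corrected
#' agreement `(N * trace - S) / (N^2 - S)` with
#' `S = sum(row totals * column totals)`.
#'
#' @param cm a [confusion_matrix()].
#' @param class optional single class (name or index) for the per-class
#'   measures; default returns the full named vector.
#' @return proportions (not percentages).
#' @name accuracy_stats
NULL

#' @rdname accuracy_stats
#' @export
overall_accuracy <- function(cm) {
  cm <- .cm_check(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(cm)) / n
}

#' @rdname accuracy_stats
#' @export
producer_accuracy <- function(cm, class = NULL) {
  cm <- .cm_check(cm)
  tot <- colSums(cm)
  pa <- diag(cm) / tot
  pa[tot == 0] <- NA_real_
  if (is.null(class)) pa else {
    if (is.na(pa[class]) && tot[class] == 0)
      stop("class '", class, "' has no ground-truth samples")
    unname(pa[class])
  }
}

#' @rdname accuracy_stats
#' @export
user_accuracy <- function(cm, class = NULL) {
  cm <- .cm_check(cm)
  tot <- rowSums(cm)
  ua <- diag(cm) / tot
  ua[tot == 0] <- NA_real_
  if (is.null(class)) ua else {
    if (is.na(ua[class]) && tot[class] == 0)
      stop("class '", class, "' was never predicted")
    unname(ua[class])
  }
}

#' @rdname accuracy_stats
#' @export
kappa <- function(cm) {
  cm <- .cm_check(cm)
  n <- sum(cm)
  s <- sum(rowSums(cm) * colSums(cm))
  den <- n^2 - s
  if (den == 0)
    stop("degenerate matrix (all mass in one row/column pair); ",
         "kappa undefined")
  (n * sum(diag(cm)) - s) / den
}

#' Full accuracy report
#'
#' Bundles overall accuracy, Kappa and the per-class producer/user
#' accuracies; printing renders the standard report layout (counts with
#' ground truth in columns, per-class PA column, UA row, OA/Kappa
#' footer) with percentages rounded to two decimals. Full precision is
#' retained in the object.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `accuracy_report`: list with `cm`, `oa`,
#'   `kappa`, `pa`, `ua`, `n`.
#' @export
accuracy_report <- function(cm) {
  cm <- .cm_check(cm)
  structure(list(cm = cm, oa = overall_accuracy(cm), kappa = kappa(cm),
                 pa = producer_accuracy(cm), ua = user_accuracy(cm),
                 n = sum(cm)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cm <- x$cm
  k <- nrow(cm)
  # two-decimal rounding, trailing zeros trimmed ("100", "86.4", "92.59")
  pct <- function(v) ifelse(is.na(v), "-",
                            sub("\\.?0+$", "", sprintf("%.2f", 100 * v)))
  body <- cbind(matrix(as.character(cm), k), Total = rowSums(cm),
                `PA%` = pct(x$pa))
  totals <- c(colSums(cm), sum(cm), "-")
  ua <- c(pct(x$ua), "-", "-")
  tab <- rbind(body, Total = totals, `UA%` = ua)
  rownames(tab) <- c(rownames(cm), "Total", "UA%")
  colnames(tab) <- c(colnames(cm), "Total", "PA%")
  cat("Confusion matrix (rows = classified, columns = ground truth)\n")
  print(tab, quote = FALSE, right = TRUE)
  cat(sprintf("OA: %.2f%%  Kappa: %.2f  (N = %d)\n",
              100 * x$oa, x$kappa, x$n))
  invisible(x)
}

#' @export
format.accuracy_report <- function(x, ...) {
  paste(utils::capture.output(print(x)), collapse = "\n")
}

#' Write an accuracy report as CSV
#'
#' Two sections: the count matrix (with totals) and a statistics block
#' (OA, Kappa, per-class PA/UA as percentages at full precision).
#'
#' @param report an [accuracy_report()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  cm <- report$cm
  counts <- data.frame(section = "counts", classified = rownames(cm),
                       as.data.frame.matrix(unclass(cm)),
                       check.names = FALSE)
  stats_df <- data.frame(
    section = "stats",
    metric = c("OA_pct", "Kappa", paste0("PA_pct_", rownames(cm)),
               paste0("UA_pct_", rownames(cm))),
    value = c(100 * report$oa, report$kappa, 100 * report$pa,
              100 * report$ua))
  utils::write.csv(counts, path, row.names = FALSE)
  suppressWarnings(utils::write.table(stats_df, path, append = TRUE,
                                      sep = ",", row.names = FALSE,
                                      col.names = TRUE))
  invisible(path)
}

#' Difference between two printed overall accuracies
#'
#' Published OA percentages are typically rounded to two decimals while
#' the underlying quantity is a count out of `n` verification pixels.
#' Differencing the printed values can therefore be off by one unit in
#' the last digit. `oa_gain()` snaps each percentage to the nearest
#' achievable count over `n` before differencing, recovering the
#' count-level difference.
#'
#' @param oa_a,oa_b overall accuracies in percent.
#' @param n number of verification samples both percentages refer to.
#' @return `oa_a - oa_b` in percentage points, computed at count level.
#' @export
oa_gain <- function(oa_a, oa_b, n) {
  ca <- round(oa_a / 100 * n)
  cb <- round(oa_b / 100 * n)
  (ca - cb) / n * 100
}
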