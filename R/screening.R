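#' Feature band combinations
#'
#' A candidate pair of (band, phase) operands from which a modified
#' index may be built. Cross-phase pairs are the multi-temporal case.
#'
#' @param band_a,phase_a,band_b,phase_b operand bands and phases.
#' @param target_class class the index is being developed for.
#' @param classes_to_identify classes still in the pool at this stage of
#'   the hierarchy (including the target); the default screening scope.
#' @return an object of class `band_combination`.
#' @export
band_combination <- function(band_a, phase_a, band_b, phase_b,
                             target_class = NULL,
                             classes_to_identify = NULL) {
  .check_band(band_a); .check_band(band_b)
  .check_phase(phase_a); .check_phase(phase_b)
  if (band_a == band_b && phase_a == phase_b)
    stop("the two operands must be distinct")
  structure(list(band_a = band_a, phase_a = phase_a,
                 band_b = band_b, phase_b = phase_b,
                 target_class = target_class,
                 classes_to_identify = classes_to_identify),
            class = "band_combination")
}

#' @export
format.band_combination <- function(x, ...) {
  paste0(x$band_a, "@", x$phase_a, " & ", x$band_b, "@", x$phase_b)
}

#' @export
print.band_combination <- function(x, ...) {
  cat("<band_combination>", format(x), "\n")
  invisible(x)
}

#' Per-class spectral statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of
#' reflectance for every (class, phase, band) cell of a long sample
#' table -- the statistical summary underlying both the spectral-curve
#' analysis and the standard-deviation-sum screening.
#'
#' @param samples long sample table with columns class, phase, band,
#'   reflectance (as from [extract_samples()] or
#'   [simulate_sample_table()]).
#' @return data frame (class, phase, band, n, mean, sd).
#' @export
class_spectral_stats <- function(samples) {
  need <- c("class", "phase", "band", "reflectance")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) == 0L) stop("empty sample table")
  key <- interaction(samples$class, samples$phase, samples$band, drop = TRUE)
  n <- tapply(samples$reflectance, key, length)
  if (any(n < 2))
    stop("every (class, phase, band) cell needs >= 2 pixels")
  mu <- tapply(samples$reflectance, key, mean)
  sd_ <- tapply(samples$reflectance, key, stats::sd)
  parts <- do.call(rbind, strsplit(names(mu), ".", fixed = TRUE))
  out <- data.frame(class = parts[, 1], phase = parts[, 2], band = parts[, 3],
                    n = as.integer(n), mean = as.numeric(mu),
                    sd = as.numeric(sd_), stringsAsFactors = FALSE)
  out[order(out$class, match(out$phase, .VEG_PHASES),
            match(out$band, .VEG_BANDS)), , drop = FALSE]
}

.sd_of <- function(samples, band, phase, cls) {
  v <- samples$reflectance[samples$band == band & samples$phase == phase &
                             samples$class == cls]
  if (length(v) < 2)
    stop("no (or singleton) samples for ", band, "@", phase,
         " in class ", cls)
  stats::sd(v)
}

#' Standard-deviation-sum score of a band combination
#'
#' The screening statistic: over the configured class scope, the sum of
#' each class's sample standard deviation in both operand bands. Lower
#' means more stable intra-class spectra, hence a more reliable index.
#' Reported on a configurable scale; the x 10^4 default (digital-number
#' convention) makes magnitudes comparable across studies reporting
#' reflectance as scaled integers.
#'
#' @param combination a [band_combination()].
#' @param samples long sample table (class, phase, band, reflectance).
#' @param scope `"to_identify"` (default) sums over
#'   `combination$classes_to_identify`; `"target_only"` over the target
#'   class alone.
#' @param scale multiplier applied to the reflectance-scale sum
#'   (default 1e4).
#' @return single numeric score.
#' @export
sd_sum_score <- function(combination, samples,
                         scope = c("to_identify", "target_only"),
                         scale = 1e4) {
  stopifnot(inherits(combination, "band_combination"))
  scope <- match.arg(scope)
  classes <- switch(scope,
    to_identify = combination$classes_to_identify,
    target_only = combination$target_class)
  if (is.null(classes)) {
    if (scope == "to_identify")
      stop("combination has no classes_to_identify; set them or use ",
           "scope = 'target_only'")
    stop("combination has no target_class")
  }
  total <- sum(vapply(classes, function(cl)
    .sd_of(samples, combination$band_a, combination$phase_a, cl) +
      .sd_of(samples, combination$band_b, combination$phase_b, cl),
    numeric(1)))
  total * scale
}

#' Screen candidate band combinations
#'
#' Selects the candidate with the smallest standard-deviation sum; ties
#' are broken by candidate order (first wins). `screening_report()` is
#' the score-level core, usable directly on precomputed or published
#' score tables; `select_combination()` computes the scores from a
#' sample table first.
#'
#' @param candidates list of [band_combination()] objects.
#' @param samples long sample table.
#' @inheritParams sd_sum_score
#' @return data frame (combination, sd_sum, selected) of class
#'   `screening_report`, one row per candidate, exactly one selected.
#' @export
select_combination <- function(candidates, samples,
                               scope = c("to_identify", "target_only"),
                               scale = 1e4) {
  if (!length(candidates)) stop("empty candidate list")
  scope <- match.arg(scope)
  scores <- vapply(candidates, sd_sum_score, numeric(1),
                   samples = samples, scope = scope, scale = scale)
  labels <- vapply(candidates, format, character(1))
  screening_report(labels, scores)
}

#' @rdname select_combination
#' @param labels character vector naming each candidate.
#' @param sd_sums numeric score per candidate.
#' @export
screening_report <- function(labels, sd_sums) {
  stopifnot(length(labels) == length(sd_sums), length(labels) >= 1L)
  sel <- which.min(sd_sums)  # which.min takes the first minimum: first wins
  out <- data.frame(combination = labels, sd_sum = sd_sums,
                    selected = seq_along(labels) == sel,
                    stringsAsFactors = FALSE)
  class(out) <- c("screening_report", "data.frame")
  out
}

#' @export
print.screening_report <- function(x, ...) {
  y <- x
  y$sd_sum <- formatC(y$sd_sum, format = "f", digits = 2)
  y$selected <- ifelse(y$selected, "*", "")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Selected row of a screening report
#'
#' @param report a `screening_report`.
#' @return one-row data frame: the selected combination.
#' @export
selected_combination <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  report[report$selected, , drop = FALSE]
}

.TEMPLATE_KINDS <- c("DIFFERENCE", "NORMALIZED_COMPLEMENT", "RELATIVE_CHANGE")

#' Index formula templates
#'
#' The three formula shapes from which the modified indices are built,
#' mirroring the construction principles of DVI, NDVI and RVI:
#' `DIFFERENCE` is `a - b`; `NORMALIZED_COMPLEMENT` is
#' `(1 - a - b) / (a + b)` (defined when the operand sum is positive and
#' informative when it stays below 1); `RELATIVE_CHANGE` is
#' `(a - b) / b`.
#'
#' @param kind one of `"DIFFERENCE"`, `"NORMALIZED_COMPLEMENT"`,
#'   `"RELATIVE_CHANGE"`.
#' @return an object of class `formula_template`.
#' @export
formula_template <- function(kind = .TEMPLATE_KINDS) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "formula_template")
}

.template_fun <- function(kind) {
  switch(kind,
    DIFFERENCE = function(a, b) a - b,
    NORMALIZED_COMPLEMENT = function(a, b) {
      den <- a + b
      out <- (1 - a - b) / den
      out[!is.na(den) & den == 0] <- NA_real_
      out
    },
    RELATIVE_CHANGE = function(a, b) {
      out <- (a - b) / b
      out[!is.na(b) & b == 0] <- NA_real_
      out
    },
    stop("unknown template kind: ", kind))
}

#' Instantiate an index definition from a screened combination
#'
#' Binds a winning band combination to a formula template, producing an
#' evaluatable index definition. The four shipped modified indices are
#' exactly such instantiations:
#' (RE4@FEB, SWIR1@FEB) + DIFFERENCE = UTM-DMI;
#' (RE4@JUN, RE4@OCT) + NORMALIZED_COMPLEMENT = MTM-NDQI;
#' (RE2@JUN, RE2@AUG) + DIFFERENCE = MTM-DSI;
#' (RE2@JUN, RE2@OCT) + RELATIVE_CHANGE = MTM-RSI.
#'
#' @param combination a [band_combination()].
#' @param template a [formula_template()] (or its kind as a string).
#' @param name feature name for the resulting index.
#' @return an object of class `index_definition`.
#' @export
instantiate_index <- function(combination, template, name) {
  stopifnot(inherits(combination, "band_combination"))
  if (is.character(template)) template <- formula_template(template)
  stopifnot(inherits(template, "formula_template"))
  structure(list(name = name, template = template$kind,
                 combination = combination),
            class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cat("<index_definition> ", x$name, ": ", x$template, " on ",
      format(x$combination), "\n", sep = "")
  invisible(x)
}

#' Evaluate an index definition on a stack
#'
#' @param definition an [instantiate_index()] result.
#' @param stack an `mt_stack`.
#' @return an [index_layer()] named after the definition.
#' @export
evaluate_index <- function(definition, stack) {
  stopifnot(inherits(definition, "index_definition"),
            inherits(stack, "mt_stack"))
  cmb <- definition$combination
  a <- stack_band(stack, cmb$band_a, cmb$phase_a)
  b <- stack_band(stack, cmb$band_b, cmb$phase_b)
  vals <- .template_fun(definition$template)(a, b)
  index_layer(vals, definition$name,
              list(c(cmb$band_a, cmb$phase_a), c(cmb$band_b, cmb$phase_b)))
}

#' Serialize index definitions to and from JSON
#'
#' @param definitions list of `index_definition` objects.
#' @param path JSON file path.
#' @return `path` invisibly; `read_index_definitions()` returns the
#'   list.
#' @export
write_index_definitions <- function(definitions, path) {
  if (inherits(definitions, "index_definition"))
    definitions <- list(definitions)
  payload <- lapply(definitions, function(d) list(
    name = d$name, template = d$template,
    band_a = d$combination$band_a, phase_a = d$combination$phase_a,
    band_b = d$combination$band_b, phase_b = d$combination$phase_b,
    target_class = d$combination$target_class,
    classes_to_identify = d$combination$classes_to_identify))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_index_definitions
#' @export
read_index_definitions <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    cmb <- band_combination(p$band_a, p$phase_a, p$band_b, p$phase_b,
                            target_class = p$target_class,
                            classes_to_identify =
                              if (is.null(p$classes_to_identify)) NULL
                              else unlist(p$classes_to_identify))
    instantiate_index(cmb, p$template, p$name)
  })
}

#' Distribution overlap between two classes on one feature
#'
#' Fraction of the pooled samples lying inside the intersection of the
#' two classes' value ranges -- the box-plot-style separability check
#' used to admit features into the optimal set (a feature is considered
#' weak for a pair when the overlap exceeds 0.25). `method = "iqr"`
#' replaces each class's full range by its interquartile range.
#'
#' @param a,b numeric sample vectors for the two classes.
#' @param method `"range"` (default) or `"iqr"`.
#' @return proportion in [0, 1].
#' @export
overlap_fraction <- function(a, b, method = c("range", "iqr")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty sample vector")
  bounds <- function(v) switch(method,
    range = range(v),
    iqr = stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7))
  ba <- bounds(a); bb <- bounds(b)
  lo <- max(ba[1], bb[1]); hi <- min(ba[2], bb[2])
  if (lo > hi) return(0)
  pooled <- c(a, b)
  mean(pooled >= lo & pooled <= hi)
}

#' Exhaustive candidate enumeration (beyond the published procedure)
#'
#' Candidate feature band combinations are normally supplied explicitly
#' (they come from visual spectral-curve analysis, which this package
#' does not automate). As a convenience extension, this helper
#' enumerates all distinct pairs over a stated band and phase subset --
#' an exhaustive search mode that goes beyond the manual screening
#' procedure and should be read as exploratory.
#'
#' @param bands,phases character vectors to enumerate over.
#' @param target_class,classes_to_identify as in [band_combination()].
#' @param cross_phase_only if `TRUE`, keep only pairs whose operands
#'   differ in phase (the multi-temporal case).
#' @return list of [band_combination()] objects.
#' @export
enumerate_combinations <- function(bands, phases, target_class = NULL,
                                   classes_to_identify = NULL,
                                   cross_phase_only = FALSE) {
  ops <- expand.grid(band = bands, phase = phases,
                     stringsAsFactors = FALSE)
  n <- nrow(ops)
  out <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (cross_phase_only && ops$phase[i] == ops$phase[j]) next
    out[[length(out) + 1L]] <- band_combination(
      ops$band[i], ops$phase[i], ops$band[j], ops$phase[j],
      target_class = target_class,
      classes_to_identify = classes_to_identify)
  }
  out
}
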