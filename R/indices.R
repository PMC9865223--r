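#' Typical vegetation indices
#'
#' The three classical red/NIR indices, computed per acquisition date.
#' All index functions are vectorised and pixel-wise: they accept
#' scalars, vectors or matrices and return the same shape. Degenerate
#' pixels (zero denominator) and pixels with any masked operand yield
#' `NA` rather than an error, so whole-raster computation never aborts
#' on isolated bad pixels.
#'
#' `rvi()` follows the source convention RED/NIR by default;
#' `orientation = "conventional"` gives the classical NIR/RED ratio.
#'
#' @param red,nir surface reflectance in [0, 1].
#' @param orientation `"as_published"` (RED/NIR, default) or
#'   `"conventional"` (NIR/RED).
#' @return numeric of the same shape as the inputs.
#' @name typical_indices
NULL

#' @rdname typical_indices
#' @export
rvi <- function(red, nir, orientation = c("as_published", "conventional")) {
  orientation <- match.arg(orientation)
  if (orientation == "as_published") {
    out <- red / nir
    out[!is.na(nir) & nir == 0] <- NA_real_
  } else {
    out <- nir / red
    out[!is.na(red) & red == 0] <- NA_real_
  }
  out
}

#' @rdname typical_indices
#' @export
dvi <- function(red, nir) nir - red

#' @rdname typical_indices
#' @export
ndvi <- function(red, nir) {
  out <- (nir - red) / (nir + red)
  den <- nir + red
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Uni- and multi-temporal modified vegetation indices
#'
#' Four indices built from red-edge and shortwave-infrared feature band
#' combinations selected by standard-deviation-sum screening, each
#' designed to peel one class out of the remaining pool:
#'
#' * `utm_dmi(re4_feb, swir1_feb)` = RE4 - SWIR1 in February. Near zero
#'   for pine-oak mixed forests (their February RE4 and SWIR1 are nearly
#'   equal), clearly negative for the other deciduous classes whose
#'   dormant-season spectra show a shortwave-infrared reflection peak.
#' * `mtm_ndqi(re4_june, re4_oct)` = (1 - a - b)/(a + b) on June and
#'   October RE4. Quercus wutaishanica has the largest June + October
#'   RE4 sum (always below 1), hence the smallest index value.
#' * `mtm_dsi(re2_june, re2_aug)` = June - August RE2. Negative for
#'   scrub grass, whose red-edge reflectance rises into late summer
#'   while the tree classes decline.
#' * `mtm_rsi(re2_june, re2_oct)` = (June - October)/October RE2.
#'   Larger for shaw, which greens stronger in June and senesces harder
#'   by October than Larix principis-rupprechtii.
#'
#' @param re4_feb,swir1_feb,re4_june,re4_oct,re2_june,re2_aug,re2_oct
#'   surface reflectance in [0, 1] from the named band and month.
#' @return numeric of the same shape as the inputs; `NA` where an
#'   operand is masked or a denominator is zero.
#' @name modified_indices
NULL

#' @rdname modified_indices
#' @export
utm_dmi <- function(re4_feb, swir1_feb) re4_feb - swir1_feb

#' @rdname modified_indices
#' @export
mtm_ndqi <- function(re4_june, re4_oct) {
  den <- re4_june + re4_oct
  out <- (1 - re4_june - re4_oct) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' @rdname modified_indices
#' @export
mtm_dsi <- function(re2_june, re2_aug) re2_june - re2_aug

#' @rdname modified_indices
#' @export
mtm_rsi <- function(re2_june, re2_oct) {
  out <- (re2_june - re2_oct) / re2_oct
  out[!is.na(re2_oct) & re2_oct == 0] <- NA_real_
  out
}

#' Index layers and feature sets
#'
#' An `index_layer` is one computed index raster (matrix of values, `NA`
#' masked) plus its feature name and (band, phase) operand provenance.
#' A `feature_set` is an ordered, uniquely named list of co-registered
#' layers.
#'
#' @param values numeric matrix.
#' @param name feature name, e.g. `"NDVI@DEC"` or `"MTM-NDQI"`.
#' @param operands list of `c(band, phase)` character pairs.
#' @return `index_layer()` an object of class `index_layer`;
#'   `feature_set()` an object of class `feature_set`.
#' @export
index_layer <- function(values, name, operands = list()) {
  stopifnot(is.matrix(values), is.character(name), length(name) == 1L)
  structure(list(values = values, name = name, operands = operands),
            class = "index_layer")
}

#' @rdname index_layer
#' @param layers list of `index_layer` objects with unique names and
#'   identical dimensions.
#' @export
feature_set <- function(layers, name = "feature_set") {
  stopifnot(is.list(layers), length(layers) >= 1L)
  ok <- vapply(layers, inherits, logical(1), "index_layer")
  if (!all(ok)) stop("all elements must be index_layer objects")
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate feature names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  dims <- vapply(layers, function(l) dim(l$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("layers are not co-registered (differing dimensions)")
  names(layers) <- nm
  structure(list(layers = layers, name = name), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> '", x$name, "': ", length(x$layers), " layers (",
      paste(names(x$layers), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
names.feature_set <- function(x) names(x$layers)

.layer_from <- function(stack, fun, name, operands) {
  args <- lapply(operands, function(op) stack_band(stack, op[1], op[2]))
  index_layer(do.call(fun, args), name, operands)
}

#' The optimal feature set
#'
#' The six-layer feature set found to give the best class separability:
#' December NDVI (evergreen Pinus), April NDVI (bare pre-sowing crops),
#' then UTM-DMI, MTM-NDQI, MTM-DSI and MTM-RSI, in that order.
#'
#' @param stack an `mt_stack` containing all six phases and the RED,
#'   NIR, RE2, RE4 and SWIR1 bands.
#' @inheritParams typical_indices
#' @return a six-layer [feature_set()].
#' @export
optimal_feature_set <- function(stack) {
  stopifnot(inherits(stack, "mt_stack"))
  need_ph <- c("FEB", "APR", "JUN", "AUG", "OCT", "DEC")
  miss <- setdiff(need_ph, stack$phases)
  if (length(miss)) stop("stack is missing phase(s): ",
                         paste(miss, collapse = ", "))
  need_bd <- c("RED", "NIR", "RE2", "RE4", "SWIR1")
  miss <- setdiff(need_bd, stack$bands)
  if (length(miss)) stop("stack is missing band(s): ",
                         paste(miss, collapse = ", "))
  feature_set(list(
    .layer_from(stack, ndvi, "NDVI@DEC",
                list(c("RED", "DEC"), c("NIR", "DEC"))),
    .layer_from(stack, ndvi, "NDVI@APR",
                list(c("RED", "APR"), c("NIR", "APR"))),
    .layer_from(stack, utm_dmi, "UTM-DMI",
                list(c("RE4", "FEB"), c("SWIR1", "FEB"))),
    .layer_from(stack, mtm_ndqi, "MTM-NDQI",
                list(c("RE4", "JUN"), c("RE4", "OCT"))),
    .layer_from(stack, mtm_dsi, "MTM-DSI",
                list(c("RE2", "JUN"), c("RE2", "AUG"))),
    .layer_from(stack, mtm_rsi, "MTM-RSI",
                list(c("RE2", "JUN"), c("RE2", "OCT")))
  ), name = "optimal")
}

#' Time-series feature set of one typical index
#'
#' One layer per phase of the chosen typical index, named
#' `"INDEX@PHASE"` -- the comparator feature sets used to benchmark the
#' optimal set.
#'
#' @inheritParams optimal_feature_set
#' @param index which typical index to compute.
#' @inheritParams typical_indices
#' @return a [feature_set()] with one layer per phase of the stack.
#' @export
time_series_feature_set <- function(stack, index = c("NDVI", "RVI", "DVI"),
                                    orientation = c("as_published",
                                                    "conventional")) {
  stopifnot(inherits(stack, "mt_stack"))
  index <- match.arg(index)
  orientation <- match.arg(orientation)
  miss <- setdiff(c("RED", "NIR"), stack$bands)
  if (length(miss)) stop("stack is missing band(s): ",
                         paste(miss, collapse = ", "))
  fun <- switch(index, NDVI = ndvi, DVI = dvi,
                RVI = function(red, nir) rvi(red, nir, orientation))
  layers <- lapply(stack$phases, function(ph)
    .layer_from(stack, fun, paste0(index, "@", ph),
                list(c("RED", ph), c("NIR", ph))))
  feature_set(layers, name = paste0("time_series_", index))
}

#' Sample feature values at pixel locations
#'
#' Builds the wide per-pixel table (one column per feature) used to
#' calibrate the knowledge tree and train the ensemble comparator.
#'
#' @param fs a [feature_set()].
#' @param plots plot table ([sample_plots()]); its (row, col) pixels are
#'   sampled.
#' @return data frame with plot_id, class, row, col and one numeric
#'   column per feature.
#' @export
feature_table <- function(fs, plots) {
  stopifnot(inherits(fs, "feature_set"))
  plots <- sample_plots(plots)
  d <- dim(fs$layers[[1]]$values)
  oob <- plots$row < 1 | plots$row > d[1] | plots$col < 1 | plots$col > d[2]
  if (any(oob))
    stop("plot(s) with out-of-bounds pixels: ",
         paste(unique(plots$plot_id[oob]), collapse = ", "))
  out <- plots[, c("plot_id", "class", "row", "col")]
  idx <- cbind(plots$row, plots$col)
  for (nm in names(fs$layers)) out[[nm]] <- fs$layers[[nm]]$values[idx]
  out
}

#' Write and read feature sets
#'
#' `write_feature_set()` writes either a long CSV (feature, row, col,
#' value) or a multi-page 32-bit float TIFF with one page per layer in
#' feature order. TIFF float storage is only defined on [0, 1], so each
#' layer is packed affinely into [0.5, 1] (`packed = 0.5 + 0.5 * (v -
#' lo) / (hi - lo)`) with 0 marking nodata; the per-layer names and
#' (lo, hi) ranges go to a JSON sidecar `<path>.json`, from which
#' `read_feature_set()` restores the original values (to float
#' precision).
#'
#' @param fs a [feature_set()].
#' @param path output file; `.csv` selects the CSV form.
#' @return `path`, invisibly; `read_feature_set()` returns a
#'   [feature_set()].
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    long <- do.call(rbind, lapply(fs$layers, function(l) {
      d <- dim(l$values)
      data.frame(feature = l$name,
                 row = rep(seq_len(d[1]), times = d[2]),
                 col = rep(seq_len(d[2]), each = d[1]),
                 value = as.vector(l$values))
    }))
    utils::write.csv(long, path, row.names = FALSE)
    return(invisible(path))
  }
  meta <- list(name = fs$name, layers = list())
  pages <- vector("list", length(fs$layers))
  for (i in seq_along(fs$layers)) {
    l <- fs$layers[[i]]
    fin <- l$values[is.finite(l$values)]
    lo <- if (length(fin)) min(fin) else 0
    hi <- if (length(fin)) max(fin) else 1
    span <- if (hi > lo) hi - lo else 1
    m <- 0.5 + 0.5 * (l$values - lo) / span
    m[!is.finite(l$values)] <- 0
    pages[[i]] <- m
    meta$layers[[i]] <- list(name = l$name, lo = lo, hi = lo + span,
                             operands = l$operands)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  layers <- lapply(seq_along(pages), function(i) {
    mi <- meta$layers[[i]]
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    v <- mi$lo + (m - 0.5) / 0.5 * (mi$hi - mi$lo)
    v[m == 0] <- NA_real_
    ops <- lapply(mi$operands, function(op) unlist(op))
    index_layer(v, mi$name, ops)
  })
  feature_set(layers, name = meta$name)
}
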