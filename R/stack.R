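#' Multi-temporal reflectance stacks
#'
#' A `mt_stack` holds co-registered surface reflectance for every
#' (phase, band) pair on a common pixel grid: a four-dimensional array
#' indexed (phase, band, row, col), values on the unit reflectance scale
#' in [0, 1], with `NA` marking nodata pixels. All phases share one grid;
#' inputs at a coarser resolution are brought onto the finest grid by
#' nearest-neighbour (block-replication) resampling at read time.
#'
#' @param reflectance numeric array of dimension
#'   (n phases, n bands, rows, cols).
#' @param phases character vector of phase labels (subset of
#'   [veg_phases()], in that order).
#' @param bands character vector of band names (subset of [veg_bands()]).
#' @param pixel_size pixel edge length in metres.
#' @param origin numeric length-2, map coordinates of the top-left pixel
#'   centre (informational; no reprojection is performed).
#' @return an object of class `mt_stack`.
#' @export
multi_temporal_stack <- function(reflectance, phases = veg_phases(),
                                 bands = veg_bands(), pixel_size = 10,
                                 origin = c(0, 0)) {
  stopifnot(is.array(reflectance), length(dim(reflectance)) == 4L)
  d <- dim(reflectance)
  if (d[1] != length(phases))
    stop("reflectance has ", d[1], " phases but ", length(phases),
         " phase labels were given")
  if (d[2] != length(bands))
    stop("reflectance has ", d[2], " bands but ", length(bands),
         " band names were given")
  vapply(phases, .check_phase, character(1))
  vapply(bands, .check_band, character(1))
  rng <- range(reflectance, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("reflectance values outside [0, 1]; apply the scale factor on read")
  dimnames(reflectance) <- list(phases, bands, NULL, NULL)
  structure(list(reflectance = reflectance, phases = phases, bands = bands,
                 pixel_size = pixel_size, origin = origin),
            class = "mt_stack")
}

#' @export
print.mt_stack <- function(x, ...) {
  d <- dim(x$reflectance)
  cat("<mt_stack> ", d[1], " phases x ", d[2], " bands x ",
      d[3], " x ", d[4], " pixels (", x$pixel_size, " m)\n", sep = "")
  cat("  phases:", paste(x$phases, collapse = " "), "\n")
  cat("  nodata:", sum(is.na(x$reflectance)), "cells\n")
  invisible(x)
}

#' @export
dim.mt_stack <- function(x) dim(x$reflectance)

#' Extract one (band, phase) layer from a stack
#'
#' @param stack an [multi_temporal_stack()] object.
#' @param band band name, one of [veg_bands()].
#' @param phase phase label, one of [veg_phases()].
#' @return numeric matrix (rows x cols), `NA` where masked.
#' @export
stack_band <- function(stack, band, phase) {
  stopifnot(inherits(stack, "mt_stack"))
  .check_band(band)
  .check_phase(phase)
  if (!phase %in% stack$phases)
    stop("stack has no phase '", phase, "'")
  if (!band %in% stack$bands)
    stop("stack has no band '", band, "'")
  m <- stack$reflectance[match(phase, stack$phases),
                         match(band, stack$bands), , , drop = TRUE]
  matrix(m, dim(stack$reflectance)[3], dim(stack$reflectance)[4])
}

#' Nearest-neighbour upsampling by an integer factor
#'
#' Block replication: each input pixel becomes a `factor` x `factor`
#' block, which is exactly nearest-neighbour interpolation for integer
#' upsampling. Used to bring 20 m bands onto the 10 m grid.
#'
#' @param raster numeric matrix.
#' @param factor integer upsampling factor, >= 1.
#' @return numeric matrix with dimensions `dim(raster) * factor`.
#' @export
resample_nearest <- function(raster, factor) {
  stopifnot(is.matrix(raster))
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be a single integer >= 1")
  f <- as.integer(factor)
  if (f == 1L) return(raster)
  raster[rep(seq_len(nrow(raster)), each = f),
         rep(seq_len(ncol(raster)), each = f), drop = FALSE]
}

#' Read a multi-temporal stack from per-phase multi-page TIFF files
#'
#' Each phase is one TIFF file holding one band per page. `band_map`
#' names the page index of each of the ten bands. Reflectance stored as
#' scaled integers (the common 0--10000 convention) is brought onto the
#' unit scale by `scale_factor`. Phases stored at a coarser resolution
#' than the finest one are upsampled by [resample_nearest()]; the
#' coarse/fine dimension ratio must be an integer (inputs must share a
#' CRS and alignment -- reprojection is out of scope).
#'
#' @param paths_by_phase named character vector or list, phase label ->
#'   file path.
#' @param band_map named integer vector or list, band name -> page index
#'   in the TIFF; must cover all ten bands.
#' @param scale_factor divide raw values by this to reach [0, 1]
#'   (default 1, i.e. already unit-scale).
#' @param pixel_size pixel size in metres of the finest grid.
#' @param mask_page optional page index of a validity mask (nonzero =
#'   valid); pixels with a zero mask become `NA` in every band of that
#'   phase. [write_stack()] writes such a mask as the page after the
#'   last band.
#' @return an `mt_stack`.
#' @export
read_stack <- function(paths_by_phase, band_map, scale_factor = 1,
                       pixel_size = 10, mask_page = NULL) {
  phases <- names(paths_by_phase)
  if (is.null(phases) || any(!nzchar(phases)))
    stop("paths_by_phase must be named by phase label")
  vapply(phases, .check_phase, character(1))
  phases <- .VEG_PHASES[.VEG_PHASES %in% phases]  # calendar order
  missing_bands <- setdiff(.VEG_BANDS, names(band_map))
  if (length(missing_bands))
    stop("band_map is missing band(s): ", paste(missing_bands, collapse = ", "))

  pages <- lapply(phases, function(ph) {
    path <- paths_by_phase[[ph]]
    if (!file.exists(path)) stop("file not found for phase ", ph, ": ", path)
    pg <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    pg
  })
  names(pages) <- phases

  dims <- vapply(pages, function(pg) dim(pg[[1]])[1:2], integer(2))
  target <- c(max(dims[1, ]), max(dims[2, ]))

  n <- length(phases)
  refl <- array(NA_real_, dim = c(n, length(.VEG_BANDS), target[1], target[2]))
  for (i in seq_len(n)) {
    pg <- pages[[i]]
    fr <- target[1] / dims[1, i]
    fc <- target[2] / dims[2, i]
    if (fr != round(fr) || fc != round(fc) || fr != fc)
      stop("phase ", phases[i], " grid (", dims[1, i], "x", dims[2, i],
           ") is not an integer subdivision of the finest grid (",
           target[1], "x", target[2], "); reprojection is not supported")
    msk <- NULL
    if (!is.null(mask_page)) {
      if (mask_page > length(pg))
        stop("phase ", phases[i], ": mask_page ", mask_page,
             " but file has ", length(pg), " pages")
      msk <- pg[[mask_page]]
      if (length(dim(msk)) == 3L) msk <- msk[, , 1]
      if (fr > 1) msk <- resample_nearest(msk, fr)
    }
    for (b in seq_along(.VEG_BANDS)) {
      k <- band_map[[.VEG_BANDS[b]]]
      if (k > length(pg))
        stop("phase ", phases[i], ": band ", .VEG_BANDS[b],
             " mapped to page ", k, " but file has ", length(pg), " pages")
      m <- pg[[k]]
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m <- m / scale_factor
      if (fr > 1) m <- resample_nearest(m, fr)
      if (!is.null(msk)) m[msk == 0] <- NA_real_
      refl[i, b, , ] <- m
    }
  }
  refl[!is.na(refl) & (refl < 0 | refl > 1)] <- NA_real_
  multi_temporal_stack(refl, phases = phases, bands = .VEG_BANDS,
                       pixel_size = pixel_size)
}

#' Write a stack as per-phase multi-page TIFF files
#'
#' Inverse of [read_stack()] on the unit scale: one file per phase, one
#' 32-bit-float page per band in [veg_bands()] order, plus a trailing
#' validity-mask page (1 = valid, 0 = nodata); `NA` cells are written as
#' 0 in the band pages and flagged in the mask. Read back with
#' `read_stack(..., mask_page = length(bands) + 1)`.
#'
#' @param stack an `mt_stack`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of written paths, invisibly; the
#'   band-page mapping is `seq_along(veg_bands())` and the mask page is
#'   the last one.
#' @export
write_stack <- function(stack, dir, prefix = "phase") {
  stopifnot(inherits(stack, "mt_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ph in stack$phases) {
    pages <- lapply(stack$bands, function(b) {
      m <- stack_band(stack, b, ph)
      m[is.na(m)] <- 0
      m
    })
    valid <- Reduce(`&`, lapply(stack$bands, function(b)
      !is.na(stack_band(stack, b, ph))))
    pages <- c(pages, list(valid * 1))
    path <- file.path(dir, paste0(prefix, "_", ph, ".tif"))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    paths[ph] <- path
  }
  invisible(paths)
}

#' Validate a table of labelled sample plots
#'
#' A plot table has one row per pixel with columns `plot_id`, `class`,
#' `row`, `col` (1-based pixel indices). All pixels of one plot must
#' share one class label; the conventional plot is a contiguous 3 x 3
#' pixel square (30 x 30 m at 10 m resolution), but any shape is
#' accepted.
#'
#' @param plots data frame with columns plot_id, class, row, col.
#' @return the validated data frame, class column as character.
#' @export
sample_plots <- function(plots) {
  need <- c("plot_id", "class", "row", "col")
  miss <- setdiff(need, names(plots))
  if (length(miss))
    stop("plot table is missing column(s): ", paste(miss, collapse = ", "))
  plots$class <- as.character(plots$class)
  bad <- tapply(plots$class, plots$plot_id, function(z) length(unique(z)) > 1)
  if (any(bad))
    stop("plot(s) with mixed class labels: ",
         paste(names(bad)[bad], collapse = ", "))
  plots
}

#' Extract per-pixel spectra at sample plots
#'
#' Returns the long sample table used throughout screening and
#' calibration: one row per (pixel, phase, band).
#'
#' @param stack an `mt_stack`.
#' @param plots a plot table as validated by [sample_plots()].
#' @return data frame with columns plot_id, class, row, col, phase, band,
#'   reflectance.
#' @export
extract_samples <- function(stack, plots) {
  stopifnot(inherits(stack, "mt_stack"))
  plots <- sample_plots(plots)
  if (nrow(plots) == 0L)
    return(data.frame(plot_id = character(0), class = character(0),
                      row = integer(0), col = integer(0),
                      phase = character(0), band = character(0),
                      reflectance = numeric(0)))
  d <- dim(stack$reflectance)
  oob <- plots$row < 1 | plots$row > d[3] | plots$col < 1 | plots$col > d[4]
  if (any(oob))
    stop("plot(s) with out-of-bounds pixels: ",
         paste(unique(plots$plot_id[oob]), collapse = ", "))

  np <- nrow(plots); nph <- d[1]; nb <- d[2]
  # expand (pixel) x (phase, band); array index order is (phase, band, row, col)
  pix <- rep(seq_len(np), each = nph * nb)
  ph <- rep(rep(seq_len(nph), times = nb), times = np)
  bd <- rep(rep(seq_len(nb), each = nph), times = np)
  idx <- cbind(ph, bd, plots$row[pix], plots$col[pix])
  out <- data.frame(plot_id = plots$plot_id[pix],
                    class = plots$class[pix],
                    row = plots$row[pix], col = plots$col[pix],
                    phase = stack$phases[ph], band = stack$bands[bd],
                    reflectance = stack$reflectance[idx],
                    stringsAsFactors = FALSE)
  if (anyNA(out$reflectance)) {
    badp <- unique(out$plot_id[is.na(out$reflectance)])
    stop("plot(s) covering masked pixels: ", paste(badp, collapse = ", "))
  }
  out
}

#' Stratified plot-level train/verify split
#'
#' Splits whole plots (never single pixels, to avoid spatial leakage
#' within a 3 x 3 plot) into training and verification sets, stratified
#' by class: per class, `round(train_fraction * n)` plots go to
#' training. Deterministic under a fixed seed.
#'
#' @param plots a plot table ([sample_plots()]).
#' @param train_fraction proportion of plots per class used for
#'   training (default 0.6, the conventional 6:4 split).
#' @param seed integer RNG seed.
#' @return data frame (plot_id, class, role) with role in
#'   {"train", "verify"}.
#' @export
split_train_verify <- function(plots, train_fraction = 0.6, seed = 1) {
  plots <- sample_plots(plots)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  u <- unique(plots[, c("plot_id", "class")])
  counts <- table(u$class)
  if (any(counts < 2))
    stop("class(es) with fewer than 2 plots cannot be stratified: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  u <- u[order(u$class, u$plot_id), ]
  roles <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(u)), u$class), function(i) {
      k <- round(train_fraction * length(i))
      k <- max(1L, min(length(i) - 1L, k))
      r <- rep("verify", length(i))
      r[sample(length(i), k)] <- "train"
      r
    }))
  })
  ord <- unlist(split(seq_len(nrow(u)), u$class))
  out <- data.frame(plot_id = u$plot_id[ord], class = u$class[ord],
                    role = roles, stringsAsFactors = FALSE)
  out[order(match(out$plot_id, u$plot_id)), , drop = FALSE]
}

#' Select the plot rows belonging to one role of a split
#'
#' @param plots plot table; @param split output of
#'   [split_train_verify()]; @param role "train" or "verify".
#' @return the subset of `plots` whose plot_id has that role.
#' @export
plots_in_role <- function(plots, split, role = c("train", "verify")) {
  role <- match.arg(role)
  keep <- split$plot_id[split$role == role]
  plots[plots$plot_id %in% keep, , drop = FALSE]
}
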