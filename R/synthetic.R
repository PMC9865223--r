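# Base endmember spectra (unit reflectance) over the ten bands. Class
# means are linear soil/green-vegetation mixtures driven by a seasonal
# greenness schedule, plus band-level overrides encoding the documented
# phenological contrasts between the seven classes.
.SOIL <- c(BLUE = 0.08, GREEN = 0.10, RED = 0.13, RE1 = 0.16, RE2 = 0.19,
           RE3 = 0.21, NIR = 0.23, RE4 = 0.25, SWIR1 = 0.30, SWIR2 = 0.28)
.GREEN <- c(BLUE = 0.03, GREEN = 0.06, RED = 0.04, RE1 = 0.10, RE2 = 0.25,
            RE3 = 0.32, NIR = 0.36, RE4 = 0.38, SWIR1 = 0.18, SWIR2 = 0.10)

# greenness (vegetation fraction) per class and phase
.GREENNESS <- rbind(
  crops                = c(0.00, 0.02, 0.05, 0.80, 0.40, 0.00),
  scrub_grass          = c(0.05, 0.40, 0.80, 0.65, 0.35, 0.05),
  pinus_tabuliformis   = c(0.70, 0.75, 0.80, 0.80, 0.75, 0.72),
  quercus_wutaishanica = c(0.05, 0.40, 0.80, 0.65, 0.35, 0.05),
  pine_oak_mixed       = c(0.30, 0.50, 0.80, 0.70, 0.40, 0.30),
  larix_principis      = c(0.05, 0.40, 0.80, 0.65, 0.35, 0.05),
  shaw                 = c(0.05, 0.40, 0.80, 0.65, 0.35, 0.05))
colnames(.GREENNESS) <- .VEG_PHASES

#' Class-conditional spectral profiles
#'
#' A `class_profile` carries, for one vegetation class, the mean surface
#' reflectance and the within-class noise standard deviation for every
#' (phase, band) cell. [default_profiles()] returns the seven built-in
#' profiles. Their means are soil/green-vegetation mixtures under a
#' per-class seasonal greenness schedule, with band-level adjustments
#' encoding the contrasts the classifier exploits:
#'
#' * Pinus tabuliformis is evergreen: high NDVI all winter.
#' * Crops are bare until early summer: lowest April NDVI.
#' * Pine-oak mixed forests: February RE4 equals SWIR1, while the other
#'   deciduous classes show a dormant-season shortwave-infrared
#'   reflection peak (RE4 well below SWIR1).
#' * Quercus wutaishanica: highest June and October NIR/RE4 among the
#'   remaining pool; June RE4 < 0.54, October RE4 < 0.34, sum < 1.
#' * Scrub grass: red-edge/NIR reflectance rises June to August while
#'   the tree classes decline.
#' * Shaw exceeds Larix principis-rupprechtii in those bands in June
#'   and falls below it in October.
#'
#' The default within-class noise sd (0.008 reflectance, every cell) is
#' a single dispersion scale chosen so that x 10^4-scaled screening sums
#' over three to five classes land in the few-hundreds range typical of
#' field studies.
#'
#' @param noise_sd within-class Gaussian standard deviation applied to
#'   every (phase, band) cell (default 0.008).
#' @return list of seven `class_profile` objects named by class.
#' @export
default_profiles <- function(noise_sd = 0.008) {
  profs <- lapply(.VEG_CLASSES, function(cl) {
    g <- .GREENNESS[cl, ]
    mu <- outer(g, .GREEN) + outer(1 - g, .SOIL)
    dimnames(mu) <- list(.VEG_PHASES, .VEG_BANDS)
    # dormant-season SWIR peak of the four deciduous to-identify classes
    if (cl %in% c("quercus_wutaishanica", "scrub_grass",
                  "larix_principis", "shaw")) {
      mu["FEB", "RE4"] <- 0.24
      mu["FEB", "SWIR1"] <- 0.31
    }
    if (cl == "pine_oak_mixed") {            # RE4 ~ SWIR1 in February
      mu["FEB", "RE4"] <- 0.28
      mu["FEB", "SWIR1"] <- 0.28
    }
    if (cl == "quercus_wutaishanica") {      # dense canopy: NIR/RE4 boost
      mu["JUN", c("NIR", "RE4")] <- mu["JUN", c("NIR", "RE4")] + 0.07
      mu["OCT", "NIR"] <- mu["OCT", "NIR"] + 0.05
      mu["OCT", "RE4"] <- mu["OCT", "RE4"] + 0.035
    }
    if (cl == "scrub_grass") {               # late-summer flush
      b <- c("RE2", "RE3", "NIR", "RE4")
      mu["AUG", b] <- mu["AUG", b] + 0.06
    }
    if (cl == "shaw") {                      # early green-up, early senescence
      b <- c("RE2", "RE3", "NIR", "RE4")
      mu["JUN", b] <- mu["JUN", b] + 0.03
      mu["OCT", b] <- mu["OCT", b] - 0.03
    }
    sd_ <- matrix(noise_sd, length(.VEG_PHASES), length(.VEG_BANDS),
                  dimnames = list(.VEG_PHASES, .VEG_BANDS))
    structure(list(class = cl, mean = mu, sd = sd_),
              class = "class_profile")
  })
  names(profs) <- .VEG_CLASSES
  profs
}

#' Scene configuration
#'
#' Layout and sampling parameters of a simulated scene. The scene is a
#' grid of square cells, one vegetation class per cell; each of the
#' first `sum(plots_per_class)` cells carries one sample plot of
#' `plot_size` x `plot_size` pixels placed at a seed-jittered offset
#' inside the cell, with a `guard` margin keeping plots apart.
#'
#' @param plots_per_class integer: one value recycled over the seven
#'   classes, or a named/ordered vector per class. The `"study"` preset
#'   uses 270 plots split proportionally to a typical field campaign
#'   (27, 31, 50, 54, 50, 31, 27 in [veg_classes()] order), giving
#'   2430 labelled pixels at the default plot size.
#' @param plot_size plot edge in pixels (default 3, i.e. 3 x 3 pixels =
#'   30 x 30 m at 10 m resolution).
#' @param guard margin in pixels between a plot and its cell edge.
#' @param noise_multiplier scales every profile's noise sd (0 = exact
#'   class means).
#' @param seed integer RNG seed; scenes are reproducible under it.
#' @param preset `"uniform"` (use `plots_per_class` as given) or
#'   `"study"` (override with the 270-plot campaign layout).
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(plots_per_class = 12, plot_size = 3, guard = 2,
                         noise_multiplier = 1, seed = 1,
                         preset = c("uniform", "study")) {
  preset <- match.arg(preset)
  k <- length(.VEG_CLASSES)
  if (preset == "study") {
    plots_per_class <- c(27, 31, 50, 54, 50, 31, 27)
  }
  if (length(plots_per_class) == 1L)
    plots_per_class <- rep(plots_per_class, k)
  if (length(plots_per_class) != k)
    stop("plots_per_class must have length 1 or ", k)
  if (any(plots_per_class < 1)) stop("plots_per_class must be >= 1")
  if (plot_size < 1 || guard < 0) stop("invalid plot_size/guard")
  plots_per_class <- stats::setNames(as.integer(plots_per_class),
                                     .VEG_CLASSES)
  structure(list(plots_per_class = plots_per_class,
                 plot_size = as.integer(plot_size),
                 guard = as.integer(guard),
                 noise_multiplier = noise_multiplier,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Simulate a multi-temporal scene with labelled sample plots
#'
#' Draws reflectance as class mean + independent Gaussian noise per
#' (pixel, phase, band), clipped to [0, 1], on a cell grid whose cells
#' each hold one class; sample plots are jittered inside their cells.
#' Deterministic under `config$seed`.
#'
#' @param profiles list of `class_profile` objects
#'   ([default_profiles()]).
#' @param config a [scene_config()].
#' @return list with `stack` (an `mt_stack`), `labels` (character
#'   matrix of true classes, full scene), and `plots` (plot table as in
#'   [sample_plots()]).
#' @export
simulate_scene <- function(profiles = default_profiles(),
                           config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  classes <- names(profiles)
  cell <- config$plot_size + 2L * config$guard
  n_plots <- sum(config$plots_per_class)
  ncc <- ceiling(sqrt(n_plots))
  ncr <- ceiling(n_plots / ncc)
  n_cells <- ncr * ncc
  rows <- ncr * cell
  cols <- ncc * cell

  with_seed(config$seed, {
    cell_class <- c(rep(classes, times = config$plots_per_class),
                    sample(classes, n_cells - n_plots, replace = TRUE))
    cell_class <- sample(cell_class)  # shuffle over the grid
    # assign plots to cells by class so per-class plot counts are exact
    plot_cells <- integer(0)
    for (cl in classes) {
      cand <- which(cell_class == cl)
      need <- config$plots_per_class[[cl]]
      plot_cells <- c(plot_cells, cand[seq_len(need)])
    }

    labels <- matrix(NA_character_, rows, cols)
    nph <- length(.VEG_PHASES); nb <- length(.VEG_BANDS)
    refl <- array(NA_real_, dim = c(nph, nb, rows, cols))
    for (ci in seq_len(n_cells)) {
      cr <- (ci - 1L) %/% ncc
      cc <- (ci - 1L) %% ncc
      rr <- (cr * cell + 1L):(cr * cell + cell)
      cc2 <- (cc * cell + 1L):(cc * cell + cell)
      cl <- cell_class[ci]
      labels[rr, cc2] <- cl
      p <- profiles[[cl]]
      npx <- cell * cell
      mu <- array(rep(as.vector(p$mean), npx), dim = c(nph, nb, npx))
      sdv <- array(rep(as.vector(p$sd), npx), dim = c(nph, nb, npx))
      z <- array(stats::rnorm(nph * nb * npx), dim = c(nph, nb, npx))
      block <- pmin(pmax(mu + sdv * config$noise_multiplier * z, 0), 1)
      refl[, , rr, cc2] <- array(block, dim = c(nph, nb, cell, cell))
    }

    plots <- do.call(rbind, lapply(seq_along(plot_cells), function(i) {
      ci <- plot_cells[i]
      cr <- (ci - 1L) %/% ncc
      cc <- (ci - 1L) %% ncc
      jr <- sample.int(2L * config$guard + 1L, 1L) - 1L
      jc <- sample.int(2L * config$guard + 1L, 1L) - 1L
      r0 <- cr * cell + jr
      c0 <- cc * cell + jc
      px <- expand.grid(row = r0 + seq_len(config$plot_size),
                        col = c0 + seq_len(config$plot_size))
      data.frame(plot_id = sprintf("P%03d", i), class = cell_class[ci],
                 row = px$row, col = px$col, stringsAsFactors = FALSE)
    }))

    stack <- multi_temporal_stack(refl)
    list(stack = stack, labels = labels, plots = sample_plots(plots))
  })
}

#' Simulate a plot-free sample table
#'
#' Draws `n_per_class` independent pixels per class straight from the
#' profiles, bypassing scene layout -- the quick input for screening and
#' calibration unit work.
#'
#' @inheritParams simulate_scene
#' @param n_per_class pixels per class (>= 2).
#' @param seed integer RNG seed.
#' @param noise_multiplier scales every profile's noise sd.
#' @return long data frame (class, pixel, phase, band, reflectance)
#'   compatible with [class_spectral_stats()].
#' @export
simulate_sample_table <- function(profiles = default_profiles(),
                                  n_per_class = 50, seed = 1,
                                  noise_multiplier = 1) {
  if (n_per_class < 2) stop("n_per_class must be >= 2")
  nph <- length(.VEG_PHASES); nb <- length(.VEG_BANDS)
  with_seed(seed, {
    out <- lapply(names(profiles), function(cl) {
      p <- profiles[[cl]]
      mu <- as.vector(p$mean)   # phase-major within band columns
      sdv <- as.vector(p$sd)
      z <- matrix(stats::rnorm(n_per_class * nph * nb), n_per_class,
                  byrow = TRUE, ncol = nph * nb)
      vals <- sweep(z, 2, sdv * noise_multiplier, `*`)
      vals <- sweep(vals, 2, mu, `+`)
      vals <- pmin(pmax(vals, 0), 1)
      data.frame(class = cl,
                 pixel = rep(sprintf("%s_%04d", cl, seq_len(n_per_class)),
                             times = nph * nb),
                 phase = rep(rep(.VEG_PHASES, times = nb),
                             each = n_per_class),
                 band = rep(.VEG_BANDS, each = n_per_class * nph),
                 reflectance = as.vector(vals),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Wide per-pixel feature table straight from profiles
#'
#' Convenience wrapper: simulates a sample table, reshapes it into one
#' row per pixel with (phase, band) reflectance columns, and computes
#' the optimal-set features -- used for classifier work without building
#' a full scene.
#'
#' @inheritParams simulate_sample_table
#' @return data frame with `class`, `pixel` and the six optimal-set
#'   feature columns.
#' @export
simulate_feature_table <- function(profiles = default_profiles(),
                                   n_per_class = 50, seed = 1,
                                   noise_multiplier = 1) {
  long <- simulate_sample_table(profiles, n_per_class, seed,
                                noise_multiplier)
  g <- function(band, phase) {
    v <- long$reflectance[long$band == band & long$phase == phase]
    # long format is ordered identically for every (band, phase): by
    # class then pixel
    v
  }
  key <- long$band == "RED" & long$phase == "FEB"
  out <- data.frame(class = long$class[key], pixel = long$pixel[key],
                    stringsAsFactors = FALSE)
  out[["NDVI@DEC"]] <- ndvi(g("RED", "DEC"), g("NIR", "DEC"))
  out[["NDVI@APR"]] <- ndvi(g("RED", "APR"), g("NIR", "APR"))
  out[["UTM-DMI"]] <- utm_dmi(g("RE4", "FEB"), g("SWIR1", "FEB"))
  out[["MTM-NDQI"]] <- mtm_ndqi(g("RE4", "JUN"), g("RE4", "OCT"))
  out[["MTM-DSI"]] <- mtm_dsi(g("RE2", "JUN"), g("RE2", "AUG"))
  out[["MTM-RSI"]] <- mtm_rsi(g("RE2", "JUN"), g("RE2", "OCT"))
  out
}
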