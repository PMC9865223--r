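#' Band and phase vocabularies
#'
#' The toolkit works on ten Sentinel-2-style surface-reflectance bands
#' (the three 60 m bands -- coastal aerosol, water vapour and cirrus --
#' are excluded) observed on six acquisition dates spread over one
#' phenological year. Band and phase identifiers are plain character
#' constants; every function that takes a band or phase validates against
#' these vocabularies.
#'
#' @format `veg_bands()` returns a character vector of the ten band names
#'   in wavelength order; `veg_phases()` the six phase labels in calendar
#'   order; `veg_classes()` the seven vegetation class labels in the
#'   conventional reporting order (crops, scrub grass, Pinus tabuliformis,
#'   Quercus wutaishanica, pine-oak mixed forests, Larix
#'   principis-rupprechtii, shaw).
#' @name vocabularies
NULL

.VEG_BANDS <- c("BLUE", "GREEN", "RED", "RE1", "RE2", "RE3", "NIR", "RE4",
                "SWIR1", "SWIR2")

# native ground sampling distance in metres
.BAND_RESOLUTION <- c(BLUE = 10, GREEN = 10, RED = 10, RE1 = 20, RE2 = 20,
                      RE3 = 20, NIR = 10, RE4 = 20, SWIR1 = 20, SWIR2 = 20)

.VEG_PHASES <- c("FEB", "APR", "JUN", "AUG", "OCT", "DEC")

.VEG_CLASSES <- c("crops", "scrub_grass", "pinus_tabuliformis",
                  "quercus_wutaishanica", "pine_oak_mixed",
                  "larix_principis", "shaw")

#' @rdname vocabularies
#' @export
veg_bands <- function() .VEG_BANDS

#' @rdname vocabularies
#' @export
veg_phases <- function() .VEG_PHASES

#' @rdname vocabularies
#' @export
veg_classes <- function() .VEG_CLASSES

#' @rdname vocabularies
#' @export
band_resolution <- function() .BAND_RESOLUTION

.check_band <- function(band) {
  if (!band %in% .VEG_BANDS)
    stop("unknown band '", band, "'; expected one of: ",
         paste(.VEG_BANDS, collapse = ", "), call. = FALSE)
  band
}

.check_phase <- function(phase) {
  if (!phase %in% .VEG_PHASES)
    stop("unknown phase '", phase, "'; expected one of: ",
         paste(.VEG_PHASES, collapse = ", "), call. = FALSE)
  phase
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
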