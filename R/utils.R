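# Shared grids, seed substream derivation and input checks.

.datatable.aware <- TRUE

# Wavelength grids (nm). The two simulated spectrometer grids are deliberately
# non-uniform relative to the 1 nm analysis grid so that stitching always
# exercises resampling.
VIS_GRID <- seq(200, 1160, by = 2)
NIR_GRID <- seq(900, 1750, by = 3)
STITCH_GRID <- seq(200, 1750, by = 1)
ANALYSIS_GRID <- seq(400, 1599, by = 1) # 1200 samples, half-open [400, 1600)
OVERLAP_LO <- 900
OVERLAP_HI <- 1160

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single cohort or run seed.
#' Independent stages (composition sampling, replicate noise, CV partitions,
#' RUS resampling, ...) draw their own seeds through this function so that
#' changing one stage's consumption of random numbers cannot perturb another.
#'
#' @param seed Integer master seed.
#' @param key Character tag naming the substream.
#' @return An integer in `[1, 2^31 - 2]`, deterministic in `(seed, key)`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer((h * 48271) %% (m - 1)) + 1L
}

# with_seed: evaluate expr under a local RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

abort_input <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort_input("'%s' must lie in [0, 1]", name)
  }
  invisible(x)
}
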