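# Synthetic NIR spectra: a low-rank factor model over the 950-1650 nm
# grid (5-nm steps, 141 wavelengths) plus isotropic noise, with optional
# inflated-variance outliers whose indices are recorded as ground truth.

#' The NIR wavelength grid (950-1650 nm at 5-nm steps)
#'
#' @return Numeric vector of length 141.
#' @export
nir_wavelengths <- function() seq(950, 1650, by = 5)

# Smooth spectral basis: Gaussian absorbance bumps spread over the grid,
# unit-normalized, so factor scores produce realistic correlated spectra.
spectral_loadings <- function(rank, wl = nir_wavelengths()) {
  if (rank == 0) return(matrix(0, length(wl), 0))
  centers <- seq(min(wl), max(wl), length.out = rank + 2)[-c(1, rank + 2)]
  width <- diff(range(wl)) / (rank + 1)
  L <- sapply(seq_len(rank), function(k) {
    v <- exp(-((wl - centers[k]) / width)^2)
    v / sqrt(sum(v^2))
  })
  matrix(L, nrow = length(wl))
}

#' Generate synthetic experimental and calibration NIR spectra
#'
#' Both sets are drawn from the same low-rank-plus-noise model
#' (`x = mean + L s + e`, scores `s ~ N(0, score_sd^2)`, noise
#' `e ~ N(0, noise_sd^2)`); a fraction of experimental rows are replaced
#' by inflated-variance outliers (score and noise standard deviations
#' multiplied by `outlier_inflation`), and their indices are returned as
#' ground truth.  With `rank = 0` and `noise_sd = 1` the rows are
#' standard multivariate normal with identity covariance.
#'
#' @param n_experimental,n_calibration Row counts (nonnegative integers).
#' @param outlier_fraction Fraction of experimental rows made outliers,
#'   in `[0, 1)`.
#' @param rank Rank of the factor model (default 5).
#' @param score_sd,noise_sd Standard deviations of factor scores and
#'   isotropic noise.
#' @param outlier_inflation Variance-inflation multiplier for outliers.
#' @param baseline Mean absorbance level added to every spectrum.
#' @param rng_seed Integer seed.
#' @return List with `experimental` and `calibration` matrices (141
#'   columns, wavelength column names) and `outlier_idx` (integer indices
#'   into the experimental rows).
#' @examples
#' sp <- generate_spectra(20, 50, outlier_fraction = 0.1, rng_seed = 1)
#' dim(sp$experimental)
#' @export
generate_spectra <- function(n_experimental, n_calibration,
                             outlier_fraction = 0, rank = 5,
                             score_sd = 0.5, noise_sd = 0.02,
                             outlier_inflation = 6, baseline = 0.4,
                             rng_seed = 42L) {
  if (n_experimental < 0 || n_calibration < 0)
    stop("spectra counts must be nonnegative")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  wl <- nir_wavelengths()
  p <- length(wl)
  L <- spectral_loadings(rank, wl)
  set.seed(substream_seed(rng_seed, 0L))

  draw <- function(n, inflate = 1) {
    scores <- matrix(rnorm(n * rank, sd = score_sd * inflate),
                     nrow = n, ncol = rank)
    noise <- matrix(rnorm(n * p, sd = noise_sd * inflate), nrow = n)
    sweep(scores %*% t(L) + noise, 2, rep(baseline, p), "+")
  }

  calibration <- draw(n_calibration)
  experimental <- draw(n_experimental)
  n_out <- floor(outlier_fraction * n_experimental)
  outlier_idx <- integer(0)
  if (n_out > 0) {
    outlier_idx <- sort(sample.int(n_experimental, n_out))
    experimental[outlier_idx, ] <- draw(n_out, inflate = outlier_inflation)
  }
  colnames(experimental) <- colnames(calibration) <- as.character(wl)
  list(experimental = experimental, calibration = calibration,
       outlier_idx = outlier_idx)
}
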