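# NIR spectral quality control: calibration-range exclusion, Mahalanobis
# distance vs chi-square outlier exclusion, and dry-matter adjustment of
# predicted constituents.

#' Calibration-range filter for a predicted constituent
#'
#' Keep iff `lo <= value <= hi` (boundaries inclusive).
#'
#' @param value Predicted constituent value(s), g/100 g.
#' @param range Length-2 numeric `c(lo, hi)`.
#' @return Logical vector, TRUE = keep.
#' @examples
#' range_filter(c(15, 21, 8), c(8, 20))
#' @export
range_filter <- function(value, range) {
  if (length(range) != 2 || is.na(range[1]) || is.na(range[2]))
    stop("calibration range must be c(lo, hi)")
  if (range[1] > range[2]) stop("calibration range has lo > hi")
  value >= range[1] & value <= range[2]
}

#' Mahalanobis-distance outlier filter against a calibration set
#'
#' The centroid is the column mean of the calibration spectra only; the
#' covariance is the sample covariance (denominator n-1) of the pooled
#' experimental + calibration rows.  Squared distances
#' `d2 = (x - mu)' Sigma^-1 (x - mu)` are compared with the chi-square
#' quantile at `1 - alpha` with degrees of freedom equal to the number of
#' wavelengths; rows above the quantile are excluded.  A near-singular
#' covariance (condition number above `cond_tol`) is ridge-regularized by
#' adding `ridge * trace(Sigma) / p` to the diagonal.
#'
#' @param experimental,calibration Numeric matrices with identical column
#'   counts (wavelengths).
#' @param alpha Exclusion level (default 0.001).
#' @param ridge Ridge coefficient (default 1e-8).
#' @param cond_tol Condition-number threshold triggering regularization.
#' @param center,cov_matrix Optional known centroid and covariance,
#'   overriding the estimates (useful when the instrument supplies its
#'   calibration statistics directly).
#' @param statistic Report the squared distance (`"squared"`, default) or
#'   the distance itself (`"distance"`); the exclusion decision is
#'   identical either way (the threshold is square-rooted along with the
#'   statistic).
#' @return List: `keep` (logical per experimental row), `d2` (squared
#'   distances, or distances under `statistic = "distance"`),
#'   `threshold`, `df`, `regularized` (logical).
#' @examples
#' sp <- generate_spectra(50, 100, rng_seed = 1)
#' mf <- mahalanobis_filter(sp$experimental, sp$calibration)
#' sum(!mf$keep)
#' @export
mahalanobis_filter <- function(experimental, calibration, alpha = 0.001,
                               ridge = 1e-8, cond_tol = 1e12,
                               center = NULL, cov_matrix = NULL,
                               statistic = c("squared", "distance")) {
  statistic <- match.arg(statistic)
  experimental <- as.matrix(experimental)
  calibration <- as.matrix(calibration)
  if (ncol(experimental) != ncol(calibration))
    stop("experimental and calibration column counts differ (",
         ncol(experimental), " vs ", ncol(calibration), ")")
  if (nrow(calibration) < 1) stop("calibration set is empty")
  pooled <- rbind(experimental, calibration)
  if (is.null(cov_matrix) && nrow(pooled) < 2)
    stop("need at least 2 pooled rows to estimate a covariance")
  p <- ncol(pooled)
  mu <- if (is.null(center)) colMeans(calibration) else center
  sigma <- if (is.null(cov_matrix)) cov(pooled) else cov_matrix
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  regularized <- FALSE
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) >
        cond_tol) {
    sigma <- sigma + diag(ridge * sum(diag(sigma)) / p, p)
    regularized <- TRUE
  }
  d2 <- mahalanobis(experimental, mu, sigma)
  threshold <- qchisq(1 - alpha, df = p)
  keep <- d2 <= threshold
  if (statistic == "distance") {
    d2 <- sqrt(d2)
    threshold <- sqrt(threshold)
  }
  list(keep = keep, d2 = d2, threshold = threshold, df = p,
       regularized = regularized)
}

#' Dry-matter adjustment of an as-is constituent value
#'
#' `value * 100 / (100 - moisture)`: converts g/100 g on an as-is basis
#' to a dry-matter basis.
#'
#' @param value Constituent value, g/100 g as-is.
#' @param moisture Moisture content, g/100 g, in `[0, 100)`.
#' @return Value on dry basis, g/100 g.
#' @examples
#' dry_matter_adjust(15, 8) # 16.304
#' @export
dry_matter_adjust <- function(value, moisture) {
  if (any(moisture < 0 | moisture >= 100))
    stop("moisture must be in [0, 100)")
  value * 100 / (100 - moisture)
}

#' Full NIR QC pass: range filter, Mahalanobis filter, adjustment
#'
#' Applies the two exclusion steps in order — calibration-range check on
#' each predicted constituent, then the Mahalanobis/chi-square spectral
#' filter — and dry-matter-adjusts the predicted constituents of the
#' surviving samples.
#'
#' @param spectra Experimental spectra matrix (rows = samples).
#' @param calibration Calibration spectra matrix.
#' @param predicted Data frame of predicted constituents per sample (must
#'   include a `moisture` column for the adjustment).
#' @param ranges Named list of `c(lo, hi)` calibration ranges, one per
#'   constituent column to check.
#' @param alpha Mahalanobis exclusion level (default 0.001).
#' @return Data frame: sample index, qc_status (`kept`,
#'   `excluded_range`, `excluded_mahalanobis`), `mahalanobis_d2`, and
#'   dry-basis adjusted constituent columns (`NA` for excluded rows).
#' @export
nir_qc <- function(spectra, calibration, predicted, ranges,
                   alpha = 0.001) {
  spectra <- as.matrix(spectra)
  stopifnot(is.data.frame(predicted), nrow(predicted) == nrow(spectra))
  if (!"moisture" %in% names(predicted))
    stop("predicted must contain a moisture column")
  missing_rng <- setdiff(names(ranges), names(predicted))
  if (length(missing_rng))
    stop("ranges name constituents absent from predicted: ",
         paste(missing_rng, collapse = ", "))
  n <- nrow(spectra)
  status <- rep("kept", n)
  for (cn in names(ranges)) {
    bad <- !range_filter(predicted[[cn]], ranges[[cn]])
    status[bad & status == "kept"] <- "excluded_range"
  }
  in_range <- status == "kept"
  d2 <- rep(NA_real_, n)
  if (any(in_range)) {
    mf <- mahalanobis_filter(spectra[in_range, , drop = FALSE],
                             calibration, alpha)
    d2[in_range] <- mf$d2
    status[in_range][!mf$keep] <- "excluded_mahalanobis"
  }
  out <- data.frame(sample = seq_len(n), qc_status = status,
                    mahalanobis_d2 = d2, stringsAsFactors = FALSE)
  kept <- status == "kept"
  for (cn in setdiff(names(predicted), "moisture")) {
    adj <- rep(NA_real_, n)
    adj[kept] <- dry_matter_adjust(predicted[[cn]][kept],
                                   predicted$moisture[kept])
    out[[paste0(cn, "_dry")]] <- adj
  }
  out
}
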