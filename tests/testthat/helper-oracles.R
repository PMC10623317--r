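# Independent oracle implementations used across test files.  These are
# written from first principles (sums of squares, studentized-range
# probabilities, correspondence-analysis algebra, dense grid search) and
# share no code path with the package functions they check.

# One-way ANOVA + Tukey HSD from scratch: textbook sums of squares and
# ptukey on the studentized range statistic.
oracle_anova_tukey <- function(groups) {
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(unlist(groups))
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- k - 1
  df_w <- sum(ns) - k
  mse <- ss_within / df_w
  f <- (ss_between / df_b) / mse
  p_f <- pf(f, df_b, df_w, lower.tail = FALSE)
  cmb <- utils::combn(k, 2)
  p_pairs <- apply(cmb, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    ptukey(q, k, df_w, lower.tail = FALSE)
  })
  names(p_pairs) <- apply(cmb, 2, function(ij)
    paste(names(groups)[ij], collapse = "-"))
  list(f = f, p_f = p_f, p_pairs = p_pairs, means = means)
}

# Multiple correspondence analysis as plain CA of the stacked indicator
# matrix, built from the CA standardized-residual algebra; returns row
# principal coordinates rescaled by sqrt(Q) to sit on the same scale as
# the package's FAMD row coordinates (U d of the encoded matrix), plus
# the CA eigenvalue spectrum for degeneracy checks.
oracle_mca_rowcoords <- function(factors, n_dims) {
  Zs <- lapply(factors, function(f) stats::model.matrix(~ f - 1))
  Z <- do.call(cbind, Zs)
  Q <- length(factors)
  P <- Z / sum(Z)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  coords <- diag(1 / sqrt(r)) %*% sv$u %*% diag(sv$d) * sqrt(Q)
  list(coords = coords[, seq_len(n_dims), drop = FALSE],
       sv = sv$d)
}

# Dense grid maximum of the proportional-odds log-likelihood for one
# predictor and J = 3 (theta1, gap, beta).
oracle_grid_loglik <- function(X, y, theta1_grid, gap_grid, beta_grid) {
  best <- -Inf
  for (t1 in theta1_grid) for (gp in gap_grid) for (b in beta_grid) {
    eta <- X[, 1] * b
    th <- c(t1, t1 + gp)
    up <- c(th, Inf)[y] - eta
    lo <- c(-Inf, th)[y] - eta
    ll <- sum(log(plogis(up) - plogis(lo)))
    if (is.finite(ll) && ll > best) best <- ll
  }
  best
}

# Small assay builder: replicate germinated counts out of 10.
make_assay <- function(germ, variety = "v1", treatment = "NT",
                       sown = 10L) {
  germination_assay(variety, treatment, rep(sown, length(germ)), germ)
}
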