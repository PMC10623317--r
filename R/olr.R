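# Proportional-odds ordinal logistic regression by maximum likelihood.
#
# Model: logit P(Y <= j) = theta_j - x'beta, j = 1..J-1, with common
# slopes beta across cut-points and strictly increasing theta.  Fit by
# Newton-Raphson with step-halving on the unconstrained reparameterization
# (beta, theta_1, log successive gaps); standard errors from the inverse
# observed information in the original parameterization; p-values from
# the two-sided normal approximation 2 * (1 - Phi(|t|)).

# log-likelihood, analytic gradient in the ORIGINAL (beta, theta) space
olr_loglik <- function(beta, theta, X, y, J) {
  eta <- drop(X %*% beta)
  upper <- c(theta, Inf)[y] - eta
  lower <- c(-Inf, theta)[y] - eta
  pi_i <- plogis(upper) - plogis(lower)
  if (any(pi_i <= 0)) return(-Inf)
  sum(log(pi_i))
}

olr_gradient <- function(beta, theta, X, y, J) {
  n <- length(y)
  eta <- drop(X %*% beta)
  upper <- c(theta, Inf)[y] - eta
  lower <- c(-Inf, theta)[y] - eta
  pi_i <- plogis(upper) - plogis(lower)
  fA <- ifelse(is.finite(upper), dlogis(upper), 0)
  fB <- ifelse(is.finite(lower), dlogis(lower), 0)
  g_eta <- -(fA - fB) / pi_i
  g_beta <- drop(crossprod(X, g_eta))
  g_theta <- numeric(J - 1)
  for (k in seq_len(J - 1)) {
    g_theta[k] <- sum(fA[y == k] / pi_i[y == k]) -
      sum(fB[y == k + 1] / pi_i[y == k + 1])
  }
  c(g_beta, g_theta)
}

# psi = (beta, theta_1, log(theta_2 - theta_1), ...)
psi_to_theta <- function(psi, p, J) {
  th <- psi[p + 1]
  if (J > 2) th <- c(th, th + cumsum(exp(psi[(p + 2):(p + J - 1)])))
  th
}

theta_to_psi <- function(beta, theta) {
  c(beta, theta[1], if (length(theta) > 1) log(diff(theta)))
}

# Jacobian d(beta, theta) / d(psi)
psi_jacobian <- function(psi, p, J) {
  K <- J - 1
  Jm <- diag(p + K)
  if (K > 1) {
    for (k in 2:K) {
      Jm[p + k, p + 1] <- 1 # every theta_k shifts with theta_1
      for (m in 2:k) {
        Jm[p + k, p + m] <- exp(psi[p + m])
      }
    }
  }
  Jm
}

olr_grad_psi <- function(psi, X, y, J) {
  p <- ncol(X)
  beta <- psi[seq_len(p)]
  theta <- psi_to_theta(psi, p, J)
  g <- olr_gradient(beta, theta, X, y, J)
  drop(crossprod(psi_jacobian(psi, p, J), g))
}

olr_ll_psi <- function(psi, X, y, J) {
  p <- ncol(X)
  olr_loglik(psi[seq_len(p)], psi_to_theta(psi, p, J), X, y, J)
}

# central-difference Hessian of an analytic gradient function
fd_hessian <- function(grad_fn, x, h_rel = 1e-5) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- h_rel * (1 + abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    H[, j] <- (grad_fn(xp) - grad_fn(xm)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a proportional-odds ordinal logistic regression
#'
#' Maximizes the proportional-odds likelihood by Newton-Raphson with
#' step-halving, starting from marginal cumulative-proportion logits for
#' the cut-points and zero slopes.  Predictors are used on their raw
#' scale (no standardization).
#'
#' @param x Numeric predictor matrix (may have zero columns for the null
#'   model); see [olr_design_matrix()].
#' @param y Ordinal response: ordered factor or integers `1..J`.  Every
#'   category must be observed.
#' @param tol Convergence tolerance on the gradient max-norm (default
#'   1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return Object of class `olr`: `coefficients` (slopes), `zeta`
#'   (cut-points, named `"1|2"`, ...), `se`, `t_values`, `p_values`
#'   (normal approximation), `log_lik`, `vcov`, `iterations`,
#'   `grad_norm`, `converged`, `n`, `J`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "x"))
#' y <- cut(drop(x) + rlogis(200), c(-Inf, -1, 1, Inf), labels = FALSE)
#' olr(x, y)
#' @export
olr <- function(x, y, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(x)
  if (is.ordered(y) || is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  J <- max(y)
  if (J < 2) stop("response needs at least 2 categories")
  obs <- tabulate(y, J)
  if (any(obs == 0))
    stop("unobserved response category: ",
         paste(which(obs == 0), collapse = ", "))
  p <- ncol(X)
  n <- length(y)
  if (n <= p + J - 1) stop("more parameters than observations")
  if (is.null(colnames(X)) && p > 0) colnames(X) <- paste0("x", seq_len(p))

  # scale of each predictor, for the (scale-free) separation diagnostic
  x_scale <- if (p > 0) pmax(apply(X, 2, sd), 1e-12) else numeric(0)

  # init: cut-points at marginal cumulative logits, slopes at zero
  theta0 <- qlogis(cumsum(obs)[-J] / n)
  psi <- theta_to_psi(rep(0, p), theta0)

  ll <- olr_ll_psi(psi, X, y, J)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    g <- olr_grad_psi(psi, X, y, J)
    if (max(abs(g)) <= tol) { converged <- TRUE; break }
    H <- fd_hessian(function(z) olr_grad_psi(z, X, y, J), psi)
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      step <- g / max(1, max(abs(g))) # gradient ascent fallback
    }
    # step-halving: never decrease the log-likelihood (beyond rounding,
    # so terminal Newton steps smaller than the double-precision
    # resolution of the log-likelihood are still taken)
    lam <- 1
    repeat {
      cand <- psi + lam * step
      ll_new <- olr_ll_psi(cand, X, y, J)
      if (is.finite(ll_new) &&
          ll_new >= ll - 1e-10 * max(1, abs(ll))) break
      lam <- lam / 2
      if (lam < 1e-12) { cand <- psi; ll_new <- ll; break }
    }
    psi <- cand
    ll <- ll_new
    if (p > 0 && max(abs(psi[seq_len(p)] * x_scale)) > 30)
      stop("slope estimates diverging: possible complete separation ",
           "(a monotone predictor direction perfectly orders the response)")
  }
  g <- olr_grad_psi(psi, X, y, J)
  if (!converged && max(abs(g)) <= tol) converged <- TRUE
  if (!converged)
    warning("Newton-Raphson did not reach gradient tolerance (max |g| = ",
            format(max(abs(g)), digits = 3), ")")

  beta <- psi[seq_len(p)]
  theta <- psi_to_theta(psi, p, J)
  est <- c(beta, theta)
  labels <- c(colnames(X), paste(seq_len(J - 1), 2:J, sep = "|"))
  names(est) <- labels

  H_orig <- fd_hessian(function(z) {
    olr_gradient(z[seq_len(p)], z[(p + 1):(p + J - 1)], X, y, J)
  }, est)
  vc <- tryCatch(solve(-H_orig), error = function(e)
    matrix(NA_real_, length(est), length(est)))
  dimnames(vc) <- list(labels, labels)
  se <- sqrt(diag(vc))
  tv <- est / se
  pv <- 2 * pnorm(-abs(tv))

  structure(list(
    coefficients = if (p > 0) est[seq_len(p)] else numeric(0),
    zeta = est[(p + 1):(p + J - 1)],
    estimates = est, se = se, t_values = tv, p_values = pv,
    log_lik = olr_loglik(beta, theta, X, y, J),
    vcov = vc, iterations = iter,
    grad_norm = max(abs(olr_gradient(beta, theta, X, y, J))),
    converged = converged, n = n, J = J
  ), class = "olr")
}

#' @export
print.olr <- function(x, ...) {
  cat("Proportional-odds ordinal logistic regression (J =", x$J,
      "categories, n =", x$n, ")\n")
  print(olr_coef_table(x), digits = 8, ...)
  cat("log-likelihood:", format(x$log_lik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Coefficient table for an `olr` fit
#'
#' Mirrors the reporting layout of an ordinal-regression table:
#' Variables, Estimate, Standard Error, t-value, p-value, with slope rows
#' followed by cut-point rows labeled `"1|2"`, `"2|3"`, ...
#'
#' @param x An [olr()] fit.
#' @return Data frame with one row per parameter.
#' @export
olr_coef_table <- function(x) {
  data.frame(
    Variables = names(x$estimates),
    Estimate = unname(x$estimates),
    `Standard Error` = unname(x$se),
    `t value` = unname(x$t_values),
    `p value` = unname(x$p_values),
    check.names = FALSE
  )
}

#' @export
coef.olr <- function(object, ...) object$estimates

#' @export
logLik.olr <- function(object, ...) {
  structure(object$log_lik, df = length(object$estimates),
            class = "logLik")
}

#' @export
vcov.olr <- function(object, ...) object$vcov

#' Predictor matrix for ordinal regression of dormancy on traits
#'
#' Continuous predictors pass through unscaled, in the order given;
#' categorical predictors are dummy-coded with the baseline level
#' omitted and the remaining level columns in alphabetical order.
#'
#' @param table Data frame of predictor columns only (numeric and
#'   factor/character).
#' @param baselines Named list/vector mapping a categorical column to its
#'   baseline level (e.g. `c(coat_color = "beige")`, the most prevalent
#'   coat color).  Categorical columns without an entry use their most
#'   frequent level.  A named baseline absent from the data is an error.
#' @return Numeric matrix (continuous columns first, then dummies).
#' @examples
#' olr_design_matrix(data.frame(th = c(1, 2, 3),
#'                              col = c("beige", "black", "beige")),
#'                   baselines = c(col = "beige"))
#' @export
olr_design_matrix <- function(table, baselines = c(coat_color = "beige")) {
  stopifnot(is.data.frame(table))
  is_num <- vapply(table, is.numeric, logical(1))
  cols <- list()
  for (v in names(table)[is_num]) cols[[v]] <- table[[v]]
  for (v in names(table)[!is_num]) {
    f <- droplevels(factor(table[[v]]))
    base <- if (v %in% names(baselines)) {
      as.character(baselines[[v]])
    } else {
      names(sort(table(f), decreasing = TRUE))[1]
    }
    if (!base %in% levels(f))
      stop("baseline level '", base, "' absent from column ", v)
    for (l in sort(setdiff(levels(f), base))) {
      cols[[paste(v, l, sep = "")]] <- as.numeric(f == l)
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = nrow(table), ncol = 0))
  }
  do.call(cbind, cols)
}

#' Simulate from the proportional-odds model and refit
#'
#' Draws responses through the latent-logistic representation
#' (`y = 1 + sum(x'beta + e > theta_j)`, `e` standard logistic) at a
#' fixed standard-normal design, refits with [olr()], and reports slope
#' bias, 95\% Wald coverage and the rejection rate of the zero-slope
#' hypothesis at the 5\% level.
#'
#' @param beta_true Slope vector.
#' @param theta_true Increasing cut-points.
#' @param n Observations per replicate.
#' @param n_reps Simulation replicates.
#' @param rng_seed Integer seed.
#' @return List: `bias`, `coverage`, `rejection_rate` (per slope),
#'   `n_ok` (replicates that converged), `estimates` (matrix of slope
#'   estimates).
#' @export
olr_simulate_recover <- function(beta_true, theta_true, n = 500,
                                 n_reps = 200, rng_seed = 42L) {
  if (is.unsorted(theta_true, strictly = TRUE))
    stop("theta_true must be strictly increasing")
  p <- length(beta_true)
  J <- length(theta_true) + 1
  set.seed(substream_seed(rng_seed, 3L))
  est <- se <- matrix(NA_real_, n_reps, p)
  for (r in seq_len(n_reps)) {
    X <- matrix(rnorm(n * p), n, p)
    lat <- drop(X %*% beta_true) + stats::rlogis(n)
    y <- 1L + rowSums(outer(lat, theta_true, ">"))
    if (length(unique(y)) < J) next
    fit <- tryCatch(olr(X, y), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    est[r, ] <- fit$coefficients
    se[r, ] <- fit$se[seq_len(p)]
  }
  ok <- stats::complete.cases(est)
  z <- qnorm(0.975)
  cover <- (est - z * se <= rep(beta_true, each = n_reps)) &
    (est + z * se >= rep(beta_true, each = n_reps))
  list(
    bias = colMeans(est[ok, , drop = FALSE]) - beta_true,
    coverage = colMeans(cover[ok, , drop = FALSE]),
    rejection_rate = colMeans(abs(est[ok, , drop = FALSE] /
                                    se[ok, , drop = FALSE]) > z),
    n_ok = sum(ok),
    estimates = est[ok, , drop = FALSE]
  )
}
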