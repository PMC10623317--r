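sim_ordinal <- function(n, beta, theta, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n)
  lat <- drop(X %*% beta) + rlogis(n)
  list(X = X, y = 1L + rowSums(outer(lat, theta, ">")))
}

test_that("design matrix: continuous first, baseline-omitted dummies in
          alphabetical order", {
  X <- olr_design_matrix(data.frame(col = c("beige", "black", "beige")),
                         baselines = c(col = "beige"))
  expect_equal(dim(X), c(3L, 1L))
  expect_equal(unname(X[, "colblack"]), c(0, 1, 0))

  cols7 <- c("beige", "black", "brown", "cream", "grey", "red", "yellow")
  X7 <- olr_design_matrix(data.frame(col = rep(cols7, 2)),
                          baselines = c(col = "beige"))
  expect_equal(ncol(X7), 6L)
  expect_equal(colnames(X7), paste0("col", cols7[-1]))

  Xc <- olr_design_matrix(data.frame(a = 1:3, b = c(0.1, 0.2, 0.3)))
  expect_equal(colnames(Xc), c("a", "b"))

  expect_error(olr_design_matrix(data.frame(col = c("black", "brown")),
                                 baselines = c(col = "beige")),
               "baseline level")
})

test_that("null model cut-points equal marginal cumulative-proportion
          logits", {
  fit <- olr(matrix(numeric(0), nrow = 6, ncol = 0), c(1, 1, 2, 3, 3, 4))
  expect_equal(unname(fit$zeta), qlogis(c(2, 3, 5) / 6), tolerance = 1e-8)
  expect_equal(names(fit$zeta), c("1|2", "2|3", "3|4"))
})

test_that("with two categories the fit matches binary logistic
          regression (IRLS oracle) to 1e-6", {
  set.seed(41)
  X <- matrix(rnorm(160), ncol = 2,
              dimnames = list(NULL, c("u", "v")))
  y <- 1L + rbinom(80, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 2]))
  fit <- olr(X, y)
  g <- glm(I(y == 2) ~ X, family = binomial)
  expect_lt(max(abs(fit$coefficients - coef(g)[2:3])), 1e-6)
  expect_lt(abs(unname(fit$zeta) - (-coef(g)[1])), 1e-6)
  expect_lt(max(abs(fit$se[1:2] -
                      summary(g)$coefficients[2:3, 2])), 1e-6)
})

test_that("the returned maximum beats a dense grid search on a small
          three-category problem", {
  d <- sim_ordinal(30, 0.8, c(-0.5, 0.8), seed = 42)
  fit <- olr(d$X, d$y)
  best_grid <- oracle_grid_loglik(
    d$X, d$y,
    theta1_grid = seq(-2, 1, by = 0.05),
    gap_grid = seq(0.05, 3, by = 0.05),
    beta_grid = seq(-1, 2.5, by = 0.05))
  expect_gte(fit$log_lik, best_grid - 1e-6)
  expect_true(fit$converged)
  expect_lte(fit$grad_norm, 1e-8)
})

test_that("estimates, cut-points and standard errors agree with an
          independent proportional-odds implementation", {
  d <- sim_ordinal(400, c(1, -0.7), c(-1, 0.5, 1.5), seed = 43)
  fit <- olr(d$X, d$y)
  m <- MASS::polr(factor(d$y, ordered = TRUE) ~ d$X,
                  method = "logistic", Hess = TRUE)
  expect_lt(max(abs(fit$coefficients - coef(m))), 1e-4)
  expect_lt(max(abs(fit$zeta - m$zeta)), 1e-4)
  expect_lt(max(abs(fit$se - sqrt(diag(vcov(m))))), 1e-4)
  expect_equal(fit$log_lik, as.numeric(logLik(m)), tolerance = 1e-8)
})

test_that("shifting a predictor by a constant moves the cut-points by
          beta * constant and changes nothing else", {
  d <- sim_ordinal(200, 0.9, c(-0.8, 0.6), seed = 44)
  f1 <- olr(d$X, d$y)
  f2 <- olr(d$X + 5, d$y)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-7)
  expect_equal(unname(f2$zeta - f1$zeta),
               rep(unname(5 * f1$coefficients), 2), tolerance = 1e-6)
  expect_equal(f1$log_lik, f2$log_lik, tolerance = 1e-8)
})

test_that("degenerate inputs raise diagnostic errors: separation,
          unobserved categories, over-parameterization", {
  X <- matrix(1:20, ncol = 1)
  y_sep <- rep(1:2, each = 10) # perfectly ordered by x
  expect_error(olr(X, y_sep), "separation")
  expect_error(olr(X, rep(c(1, 3), 10)), "unobserved")
  expect_error(olr(matrix(rnorm(8), 4), 1:4), "more parameters")
})

test_that("simulation recovery: slope bias vanishes at large n", {
  r <- olr_simulate_recover(1, c(-1, 0.5, 1.5), n = 2000, n_reps = 25,
                            rng_seed = 45)
  expect_gte(r$n_ok, 20)
  expect_lt(abs(r$bias), 0.1)
})

test_that("the coefficient table mirrors the reporting layout", {
  d <- sim_ordinal(100, 0.5, c(-1, 0, 1), seed = 46)
  colnames(d$X) <- "thickness"
  tab <- olr_coef_table(olr(d$X, d$y))
  expect_equal(names(tab), c("Variables", "Estimate", "Standard Error",
                             "t value", "p value"))
  expect_equal(tab$Variables, c("thickness", "1|2", "2|3", "3|4"))
  expect_equal(tab$`t value`, tab$Estimate / tab$`Standard Error`)
})
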