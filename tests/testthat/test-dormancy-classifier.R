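init_means <- function(nt, a01, a1, a10) {
  c(NT = nt, ABA0.1 = a01, ABA1 = a1, ABA10 = a10)
}

test_that("initial rules fire on their textbook patterns", {
  expect_equal(as.character(
    classify_initial(init_means(0.10, 0.08, 0.05, 0.00), FALSE)$category),
    "SD")
  expect_equal(as.character(
    classify_initial(init_means(0.96, 0.92, 0.88, 0.80), FALSE)$category),
    "ND")
  expect_equal(as.character(
    classify_initial(init_means(0.40, 0.35, 0.25, 0.10), TRUE)$category),
    "MD")
  expect_equal(as.character(
    classify_initial(init_means(0.70, 0.65, 0.50, 0.30), TRUE)$category),
    "WD")
  expect_error(classify_initial(c(NT = 0.5), FALSE), "missing treatment")
})

test_that("initial thresholds sit on the documented side at 0.25, 0.50
          and 0.75", {
  # SD boundary: strictly below 0.25 everywhere
  expect_equal(as.character(
    classify_initial(init_means(0.24999, 0.2, 0.1, 0), FALSE)$category),
    "SD")
  just_at <- classify_initial(init_means(0.25, 0.2, 0.1, 0), TRUE)
  expect_false(identical(just_at$rule_fired, "initial_SD_all<25"))
  # ND boundary: strictly above 0.75 everywhere
  nd_at <- classify_initial(init_means(0.9, 0.85, 0.8, 0.75), FALSE)
  expect_false(identical(nd_at$rule_fired, "initial_ND_all>75"))
  expect_equal(as.character(
    classify_initial(init_means(0.9, 0.85, 0.8, 0.75001),
                     FALSE)$category), "ND")
  # MD needs NT strictly below 0.50; WD strictly above
  expect_equal(as.character(
    classify_initial(init_means(0.49999, 0.4, 0.3, 0.1), TRUE)$category),
    "MD")
  expect_equal(as.character(
    classify_initial(init_means(0.50001, 0.4, 0.3, 0.1), TRUE)$category),
    "WD")
  at_half <- classify_initial(init_means(0.50, 0.4, 0.3, 0.1), TRUE)
  expect_true(at_half$ambiguous) # 0.50 satisfies neither MD nor WD
})

test_that("refined rules fire on their textbook patterns and respect
          the 0.25/0.30/0.50 boundaries", {
  rm3 <- function(nt, aba, ga) c(NT = nt, ABA10 = aba, GA10 = ga)
  expect_equal(as.character(
    classify_refined(rm3(0.10, 0.00, 0.20), FALSE)$category), "SD")
  expect_equal(as.character(
    classify_refined(rm3(0.35, 0.10, 0.80), TRUE)$category), "MD")
  expect_equal(as.character(
    classify_refined(rm3(0.60, 0.25, 0.90), TRUE)$category), "WD")
  # GA boundary 0.30 exclusive for SD
  expect_equal(as.character(
    classify_refined(rm3(0.10, 0.00, 0.29999), FALSE)$category), "SD")
  expect_false(identical(
    classify_refined(rm3(0.10, 0.00, 0.30), FALSE)$rule_fired,
    "refined_SD"))
  # MD: GA inclusive at 0.50, NT exclusive below 0.50
  expect_equal(as.character(
    classify_refined(rm3(0.49999, 0.1, 0.50), TRUE)$category), "MD")
  at_bounds <- classify_refined(rm3(0.50, 0.1, 0.49999), TRUE)
  expect_true(at_bounds$ambiguous) # 0.50 NT satisfies no refined rule
  expect_error(classify_refined(c(NT = 0.5, ABA10 = 0.1), TRUE),
               "missing treatment")
})

test_that("classification is deterministic and monotone: raising every
          mean never moves the category toward SD", {
  set.seed(31)
  for (rep in 1:200) {
    m <- sort(runif(4)) # NT >= ABA0.1 >= ... not enforced; random order
    m <- init_means(m[4], m[3], m[2], m[1])
    resp <- sample(c(TRUE, FALSE), 1)
    c1 <- classify_initial(m, resp)
    c1b <- classify_initial(m, resp)
    expect_identical(c1, c1b)
    delta <- runif(1, 0, 0.3)
    m2 <- pmin(m + delta, 1)
    c2 <- classify_initial(m2, resp)
    expect_lte(c2$category_code, c1$category_code)
  }
})

test_that("viability tree: AR release, scarification rescue and
          long-after-ripening mirror the screening cascade", {
  ref <- list(NT = rep(0.1, 9))
  base <- list(variety_id = "v", category = "SD", refined = ref)

  t1 <- c(base, list(AR1 = list(NT = c(0.9, 0.85, 0.95), ABA10 = rep(0.2, 3),
                                GA10 = rep(0.9, 3))))
  d1 <- viability_decision(t1)
  expect_equal(d1$rule_fired, "AR_release")
  expect_equal(d1$mechanism, "embryo")
  expect_equal(d1$viable, "yes")

  t2 <- c(base, list(
    AR1 = list(NT = rep(0.12, 9), ABA10 = rep(0, 9), GA10 = rep(0.15, 9)),
    SCR = c(0.8, 0.9, 0.85)))
  d2 <- viability_decision(t2)
  expect_equal(d2$rule_fired, "scarification_rescue")
  expect_equal(d2$mechanism, "seedcoat")

  t3 <- c(base, list(
    AR1 = list(NT = rep(0.12, 9), ABA10 = rep(0, 9), GA10 = rep(0.15, 9)),
    SCR = rep(0.15, 9),
    LAR3 = list(NT = c(0.8, 0.85, 0.75), ABA10 = rep(0.2, 3),
                GA10 = rep(0.8, 3), SCR = rep(0.9, 3))))
  d3 <- viability_decision(t3)
  expect_equal(d3$rule_fired, "LAR_release")
  expect_equal(d3$mechanism, "embryo")

  # nothing rescues: viability concern
  t4 <- c(base, list(
    AR1 = list(NT = rep(0.1, 9), ABA10 = rep(0, 9), GA10 = rep(0.1, 9)),
    SCR = rep(0.1, 9),
    LAR3 = list(NT = rep(0.1, 9), ABA10 = rep(0, 9), GA10 = rep(0.1, 9),
                SCR = rep(0.12, 9))))
  d4 <- viability_decision(t4)
  expect_equal(d4$viable, "concern")
  expect_equal(d4$mechanism, "undetermined")

  expect_error(viability_decision(base), "without AR1 data")
})

test_that("a slow after-ripener (significant partial AR release below
          50%) is called embryo-imposed and viable", {
  t5 <- list(variety_id = "v", category = "SD",
             refined = list(NT = rep(0.05, 9)),
             AR1 = list(NT = c(0.3, 0.4, 0.35, 0.3, 0.4, 0.3, 0.35, 0.4,
                               0.3),
                        ABA10 = rep(0, 9), GA10 = rep(0.4, 9)))
  d5 <- viability_decision(t5)
  expect_equal(d5$rule_fired, "AR_partial_release")
  expect_equal(d5$mechanism, "embryo")
  expect_equal(d5$viable, "yes")
})

test_that("panel summary counts categories and cross-tabulates colors;
          duplicates are rejected; empty input gives zero counts", {
  calls <- rbind(
    classify_initial(init_means(0.1, 0.1, 0.05, 0), FALSE, "v1"),
    classify_initial(init_means(0.96, 0.95, 0.9, 0.85), FALSE, "v2"),
    classify_initial(init_means(0.8, 0.7, 0.5, 0.1), TRUE, "v3")
  )
  s <- summarize_panel(calls, coat_color = c("beige", "beige", "black"))
  expect_identical(s$counts, c(ND = 1L, WD = 1L, MD = 0L, SD = 1L))
  expect_equal(sum(s$color_by_category), 3)

  s0 <- summarize_panel(calls[0, ])
  expect_identical(s0$counts, c(ND = 0L, WD = 0L, MD = 0L, SD = 0L))

  expect_error(summarize_panel(rbind(calls, calls[1, ])), "duplicate")
})

test_that("strict ND variant requires 95% germination without hormone", {
  m <- init_means(0.90, 0.88, 0.85, 0.80)
  expect_equal(as.character(
    classify_initial(m, FALSE, nd_rule = "methods")$category), "ND")
  strict <- classify_initial(m, FALSE, nd_rule = "strict")
  expect_false(identical(strict$rule_fired, "initial_ND_all>75"))
  expect_equal(as.character(
    classify_initial(init_means(0.96, 0.9, 0.85, 0.8), FALSE,
                     nd_rule = "strict")$category), "ND")
})
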