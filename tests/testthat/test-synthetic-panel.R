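test_that("default panel reproduces the 141/27/9/12 composition and is
          seed-deterministic", {
  cfg <- panel_config(rng_seed = 42)
  panel <- generate_panel(cfg)
  expect_identical(as.vector(table(panel$truth$true_class)),
                   c(141L, 27L, 9L, 12L))
  panel2 <- generate_panel(panel_config(rng_seed = 42))
  expect_identical(panel, panel2)
  # different seed, different draws (but same class counts)
  panel3 <- generate_panel(panel_config(rng_seed = 43))
  expect_false(identical(panel$truth$g0, panel3$truth$g0))
  expect_identical(table(panel3$truth$true_class),
                   table(panel$truth$true_class))
})

test_that("degenerate proportions give an all-ND panel; invalid
          proportions error", {
  cfg <- panel_config(n_varieties = 4,
                      class_proportions = c(ND = 1, WD = 0, MD = 0,
                                            SD = 0))
  panel <- generate_panel(cfg)
  expect_identical(as.character(panel$truth$true_class), rep("ND", 4))
  expect_error(panel_config(class_proportions = c(ND = 0.6, WD = 0.2,
                                                  MD = 0.1, SD = 0.2)),
               "sum to 1")
})

test_that("ground-truth dose-response respects the class invariants", {
  panel <- generate_panel(panel_config(rng_seed = 7))
  truth <- panel$truth
  in_assay <- list(
    list(hormone = "none", conc = 0),
    list(hormone = "ABA", conc = 0.1), list(hormone = "ABA", conc = 1),
    list(hormone = "ABA", conc = 10), list(hormone = "GA", conc = 10)
  )
  for (i in seq_len(nrow(truth))) {
    p <- vapply(in_assay, function(tr)
      germination_prob(truth[i, ], hormone = tr$hormone,
                       conc_uM = tr$conc), numeric(1))
    if (truth$true_class[i] == "SD") expect_lt(max(p), 0.25)
    if (truth$true_class[i] == "ND") expect_gt(min(p), 0.75)
  }
})

test_that("seed-coat-imposed SD is rescued by scarification but not by
          one month of after-ripening (closed-form expectations)", {
  panel <- generate_panel(panel_config(rng_seed = 42))
  sc <- panel$truth[panel$truth$true_mechanism == "seedcoat", ]
  expect_gt(nrow(sc), 0)
  for (i in seq_len(nrow(sc))) {
    p_scr <- germination_prob(sc[i, ], months = 1, scarified = TRUE)
    p_ar <- germination_prob(sc[i, ], months = 1)
    expect_gte(p_scr, 0.5)
    expect_lt(p_ar, 0.25)
  }
})

test_that("simulated counts are binomial: Monte-Carlo mean within 3
          standard errors of the closed-form expectation", {
  cfg <- panel_config(rng_seed = 1)
  truth <- data.frame(variety_id = "t", g0 = 0.5, aba_ic50 = 1e6,
                      hill = 1, ga_boost = 0, ar_release = 0,
                      scar_release = 0)
  set.seed(99)
  draws <- rbinom(10000, 10, germination_prob(truth)) / 10
  se <- sqrt(0.5 * 0.5 / 10) / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)

  # generator path: replicate proportions for an ND truth all have high
  # expectation
  panel <- generate_panel(panel_config(rng_seed = 3))
  nd <- panel$truth[panel$truth$true_class == "ND", ][1, ]
  trts <- data.frame(round = "initial",
                     treatment = c("NT", "ABA0.1", "ABA1", "ABA10"))
  sim <- simulate_germination(nd, trts, cfg, variety_index = 1)
  expect_true(all(sim$germinated >= 0 & sim$germinated <= sim$sown))
  for (tr in trts$treatment) {
    sp <- treatment_spec(tr)
    expect_gt(germination_prob(nd, hormone = sp$hormone,
                               conc_uM = sp$conc_uM), 0.75)
  }
})

test_that("unknown treatment codes are rejected", {
  expect_error(treatment_spec("ABA100"), "unknown treatment")
  expect_error(treatment_spec("NT", "AR9"), "unknown assay round")
})

test_that("class-conditional trait construction: SD seeds have thicker
          coats and a narrower, lower eccentricity range than ND", {
  panel <- generate_panel(panel_config(rng_seed = 42))
  tr <- panel$traits
  sd_rows <- tr$dormancy == "SD"
  nd_rows <- tr$dormancy == "ND"
  expect_gt(mean(tr$thickness[sd_rows]), mean(tr$thickness[nd_rows]))
  expect_lt(diff(range(tr$eccentricity[sd_rows])),
            diff(range(tr$eccentricity[nd_rows])))
  expect_lt(max(tr$eccentricity[sd_rows]), 0.5)
  # derived shape fields are internally consistent
  expect_equal(tr$minor_axis,
               tr$major_axis * sqrt(1 - tr$eccentricity^2))
})
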