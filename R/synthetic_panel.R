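# Synthetic variety panels with known dormancy ground truth.
#
# The generator emulates the structure of a 189-variety quinoa dormancy
# screen: per-variety dose-response parameters drive binomial germination
# counts under hormone / after-ripening / scarification treatments, and
# class-conditional trait distributions reproduce the qualitative
# morphology-dormancy associations (thicker seed coats and a narrow, low
# eccentricity range among strongly dormant varieties).

DORMANCY_LEVELS <- c("ND", "WD", "MD", "SD")

COAT_COLORS <- c(
  "beige", "black", "brown", "cream", "grey", "red", "warm cream", "yellow"
)

# Class-conditional coat-color weights (multinomial), most-prevalent-first
# composition per dormancy category of a typical diversity panel.
COLOR_WEIGHTS <- list(
  ND = c(79, 7, 20, 24, 4, 0, 5, 1),
  WD = c(13, 3, 7, 2, 0, 1, 0, 0),
  MD = c(5, 0, 1, 1, 2, 0, 0, 0),
  SD = c(6, 1, 1, 2, 1, 0, 1, 0)
)

#' Configuration for a synthetic variety panel
#'
#' Defaults reproduce the composition of the screened quinoa panel:
#' 189 varieties of which 141 are non-dormant (ND), 27 weakly (WD), 9
#' moderately (MD) and 12 strongly dormant (SD); 10 seeds per technical
#' replicate, 3 technical replicates in the initial dose-response round and
#' 3 biological x 3 technical replicates in later rounds.
#'
#' @param n_varieties Number of varieties in the panel.
#' @param class_proportions Named fractions for ND/WD/MD/SD, summing to 1.
#'   Counts are apportioned by largest-remainder rounding, so the default
#'   gives exactly 141/27/9/12.
#' @param sd_mechanism_split Fraction of SD varieties whose dormancy is
#'   seed-coat-imposed (the rest are embryo-imposed); default 1/6, i.e. 2
#'   of 12 SD varieties.
#' @param n_bio_reps,n_tech_reps Biological and technical replicates for
#'   the refined and after-ripening rounds.
#' @param seeds_per_rep Seeds sown per technical replicate.
#' @param rng_seed Integer master seed; every draw is a pure function of
#'   the configuration and this seed.
#' @return A list of class `panel_config`.
#' @examples
#' cfg <- panel_config()
#' cfg$class_proportions
#' @export
panel_config <- function(n_varieties = 189L,
                         class_proportions = c(ND = 141, WD = 27, MD = 9,
                                               SD = 12) / 189,
                         sd_mechanism_split = 1 / 6,
                         n_bio_reps = 3L,
                         n_tech_reps = 3L,
                         seeds_per_rep = 10L,
                         rng_seed = 42L) {
  if (n_varieties < 1) stop("n_varieties must be a positive integer")
  if (!all(DORMANCY_LEVELS %in% names(class_proportions)))
    stop("class_proportions must be named with ND, WD, MD, SD")
  class_proportions <- class_proportions[DORMANCY_LEVELS]
  if (any(class_proportions < 0))
    stop("class_proportions must be nonnegative")
  if (abs(sum(class_proportions) - 1) > 1e-12)
    stop("class_proportions must sum to 1")
  if (sd_mechanism_split < 0 || sd_mechanism_split > 1)
    stop("sd_mechanism_split must be in [0, 1]")
  if (seeds_per_rep < 1) stop("seeds_per_rep must be >= 1")
  structure(list(
    n_varieties = as.integer(n_varieties),
    class_proportions = class_proportions,
    sd_mechanism_split = sd_mechanism_split,
    n_bio_reps = as.integer(n_bio_reps),
    n_tech_reps = as.integer(n_tech_reps),
    seeds_per_rep = as.integer(seeds_per_rep),
    rng_seed = as.integer(rng_seed)
  ), class = "panel_config")
}

# Dose-response parameter ranges per dormancy class.  Baseline
# germinability g0 is inhibited by ABA through a Hill term
# 1 / (1 + (c / ic50)^h); GA promotes germination multiplicatively on the
# non-germinating fraction; after-ripening releases a per-month fraction of
# the remaining dormancy (compounded over months); scarification releases a
# further fraction of whatever dormancy remains.
class_param_ranges <- function(class) {
  switch(class,
    ND = list(g0 = c(0.92, 0.99), ic50 = c(500, 2000), hill = c(0.8, 1.2),
              ga = c(0.30, 0.60), ar = c(0.30, 0.70), scar = c(0, 0.10)),
    WD = list(g0 = c(0.70, 0.88), ic50 = c(0.5, 2), hill = c(1.1, 1.6),
              ga = c(0.40, 0.70), ar = c(0.30, 0.70), scar = c(0, 0.10)),
    MD = list(g0 = c(0.28, 0.40), ic50 = c(0.3, 1), hill = c(1.0, 1.5),
              ga = c(0.55, 0.80), ar = c(0.30, 0.60), scar = c(0, 0.20)),
    SD = list(g0 = c(0.02, 0.10), ic50 = c(0.2, 0.8), hill = c(1.0, 1.5),
              ga = c(0.02, 0.12), ar = NULL, scar = NULL),
    stop("unknown dormancy class: ", class)
  )
}

# After-ripening / scarification release ranges for SD varieties by true
# mechanism.  Embryo-imposed dormancy responds to dry after-ripening
# (a fast-releasing majority and a slow-releasing minority); seed-coat
# imposed dormancy responds only to scarification.
sd_release_ranges <- function(mechanism, fast) {
  if (mechanism == "seedcoat") {
    list(ar = c(0, 0.02), scar = c(0.70, 0.92))
  } else if (fast) {
    list(ar = c(0.85, 0.97), scar = c(0, 0.20))
  } else {
    list(ar = c(0.20, 0.32), scar = c(0, 0.20))
  }
}

# Class-conditional trait distributions: mean, sd, lower, upper of a
# truncated normal.  Strong dormancy is constructed with thicker seed
# coats and a narrow, low eccentricity range.
TRAIT_PARAMS <- list(
  thickness = list(ND = c(0.040, 0.012, 0.02, 0.08),
                   WD = c(0.050, 0.006, 0.040, 0.065),
                   MD = c(0.055, 0.015, 0.03, 0.10),
                   SD = c(0.065, 0.020, 0.03, 0.12)),
  eccentricity = list(ND = c(0.42, 0.12, 0.34, 0.85),
                      WD = c(0.44, 0.12, 0.34, 0.85),
                      MD = c(0.40, 0.08, 0.34, 0.68),
                      SD = c(0.40, 0.035, 0.36, 0.49)),
  major_axis = list(ND = c(1.81, 0.18, 1.18, 2.16),
                    WD = c(1.71, 0.18, 1.22, 2.11),
                    MD = c(1.68, 0.10, 1.37, 1.80),
                    SD = c(1.80, 0.11, 1.60, 2.04)),
  protein = list(ND = c(15.6, 1.8, 8.3, 20.1),
                 WD = c(15.7, 1.2, 12.7, 18.0),
                 MD = c(15.6, 1.0, 13.2, 17.2),
                 SD = c(15.7, 1.1, 13.4, 18.0)),
  moisture = list(ND = c(8.14, 0.18, 7.67, 8.41),
                  WD = c(8.28, 0.30, 7.81, 9.09),
                  MD = c(7.89, 0.25, 7.37, 8.35),
                  SD = c(8.10, 0.18, 7.69, 8.39))
)

draw_trait <- function(trait, classes) {
  pars <- TRAIT_PARAMS[[trait]]
  out <- numeric(length(classes))
  for (cl in DORMANCY_LEVELS) {
    idx <- classes == cl
    if (any(idx)) {
      p <- pars[[cl]]
      out[idx] <- rtruncnorm(sum(idx), p[1], p[2], p[3], p[4])
    }
  }
  out
}

#' Generate a ground-truthed synthetic variety panel
#'
#' Draws one dormancy class per variety (exact class counts by
#' largest-remainder rounding of `class_proportions`), dose-response
#' parameters from class-conditional ranges, a dormancy mechanism for SD
#' varieties (seed-coat vs embryo-imposed per `sd_mechanism_split`), and a
#' per-variety trait table (seed coat thickness, shape descriptors, crude
#' protein, moisture, multinomial coat color).  Identical configuration
#' and seed give identical output.
#'
#' @param config A [panel_config()].
#' @return List with components `truth` (data frame: variety_id,
#'   true_class, true_mechanism, dose-response parameters) and `traits`
#'   (data frame: variety_id, quantitative traits, coat_color, dormancy —
#'   the true class as an ordered factor).
#' @examples
#' panel <- generate_panel(panel_config(n_varieties = 20, rng_seed = 1))
#' table(panel$truth$true_class)
#' @export
generate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  counts <- largest_remainder(config$n_varieties, config$class_proportions)
  classes <- rep(names(counts), counts)
  n <- config$n_varieties
  variety_id <- sprintf("SYN-%04d", seq_len(n))

  set.seed(substream_seed(config$rng_seed, 0L))

  g0 <- ic50 <- hill <- ga <- ar <- scar <- numeric(n)
  mechanism <- rep("none", n)
  for (cl in DORMANCY_LEVELS) {
    idx <- which(classes == cl)
    if (!length(idx)) next
    pr <- class_param_ranges(cl)
    g0[idx]   <- runif(length(idx), pr$g0[1], pr$g0[2])
    ic50[idx] <- rloguniform(length(idx), pr$ic50[1], pr$ic50[2])
    hill[idx] <- runif(length(idx), pr$hill[1], pr$hill[2])
    ga[idx]   <- runif(length(idx), pr$ga[1], pr$ga[2])
    if (cl == "SD") {
      n_sd <- length(idx)
      n_coat <- largest_remainder(n_sd, c(config$sd_mechanism_split,
                                          1 - config$sd_mechanism_split))[1]
      mech <- rep("embryo", n_sd)
      if (n_coat > 0) mech[seq_len(n_coat)] <- "seedcoat"
      n_embryo <- n_sd - n_coat
      fast <- rep(TRUE, n_sd)
      if (n_embryo > 0) {
        n_fast <- largest_remainder(n_embryo, c(0.7, 0.3))[1]
        fast[which(mech == "embryo")] <-
          seq_len(n_embryo) <= n_fast
      }
      for (k in seq_along(idx)) {
        rr <- sd_release_ranges(mech[k], fast[k])
        ar[idx[k]]   <- runif(1, rr$ar[1], rr$ar[2])
        scar[idx[k]] <- runif(1, rr$scar[1], rr$scar[2])
      }
      mechanism[idx] <- mech
    } else {
      ar[idx]   <- runif(length(idx), pr$ar[1], pr$ar[2])
      scar[idx] <- runif(length(idx), pr$scar[1], pr$scar[2])
      if (cl == "MD") mechanism[idx] <- "embryo"
    }
  }

  thickness <- draw_trait("thickness", classes)
  ecc <- draw_trait("eccentricity", classes)
  major <- draw_trait("major_axis", classes)
  minor <- major * sqrt(1 - ecc^2)
  area <- pi / 4 * major * minor * runif(n, 0.95, 1.05)
  perimeter <- ramanujan_perimeter(major / 2, minor / 2) *
    runif(n, 1.05, 1.15)
  solidity <- rtruncnorm(n, 0.98, 0.008, 0.95, 1)
  protein <- draw_trait("protein", classes)
  moisture <- draw_trait("moisture", classes)

  coat_color <- character(n)
  for (cl in DORMANCY_LEVELS) {
    idx <- which(classes == cl)
    if (!length(idx)) next
    w <- COLOR_WEIGHTS[[cl]]
    coat_color[idx] <- sample(COAT_COLORS, length(idx), replace = TRUE,
                              prob = w / sum(w))
  }

  true_class <- factor(classes, levels = DORMANCY_LEVELS, ordered = TRUE)
  truth <- data.frame(
    variety_id = variety_id, true_class = true_class,
    true_mechanism = mechanism, g0 = g0, aba_ic50 = ic50, hill = hill,
    ga_boost = ga, ar_release = ar, scar_release = scar,
    stringsAsFactors = FALSE
  )
  traits <- data.frame(
    variety_id = variety_id, area = area, thickness = thickness,
    protein = protein, moisture = moisture, eccentricity = ecc,
    major_axis = major, minor_axis = minor, perimeter = perimeter,
    solidity = solidity,
    coat_color = factor(coat_color, levels = COAT_COLORS),
    dormancy = true_class,
    stringsAsFactors = FALSE
  )
  list(truth = truth, traits = traits, config = config)
}

#' Closed-form expected germination under a treatment
#'
#' The generator's dose-response model.  Baseline germinability is first
#' released by after-ripening (`g_m = g0 + (1 - (1 - r)^months) (1 - g0)`),
#' then by scarification (`g_s = g_m + s (1 - g_m)`); ABA at concentration
#' `c` microM inhibits through a Hill term `g / (1 + (c/ic50)^h)`; GA
#' promotes on the non-germinating fraction (`g + b (1 - g)`).
#'
#' @param truth One row of the panel `truth` data frame (or a list with the
#'   same fields).
#' @param months After-ripening duration in months (0, 1 or 3).
#' @param scarified Logical; was the seed coat nicked?
#' @param hormone One of "none", "ABA", "GA".
#' @param conc_uM Hormone concentration in microM (0 for "none").
#' @return Expected germination fraction in `[0, 1]`.
#' @export
germination_prob <- function(truth, months = 0, scarified = FALSE,
                             hormone = "none", conc_uM = 0) {
  g <- truth$g0
  if (months > 0) g <- g + (1 - (1 - truth$ar_release)^months) * (1 - g)
  if (scarified) g <- g + truth$scar_release * (1 - g)
  p <- switch(hormone,
    none = g,
    ABA = g / (1 + (conc_uM / truth$aba_ic50)^truth$hill),
    GA = g + truth$ga_boost * (1 - g),
    stop("unknown hormone: ", hormone)
  )
  pmin(pmax(p, 0), 1)
}

# Assay rounds and their after-ripening state.
ROUND_MONTHS <- c(initial = 0, refined = 0, AR1 = 1, SCR = 1, LAR3 = 3)

#' Decode a treatment code into hormone, concentration and scarification
#'
#' Valid codes are `NT` (no treatment), `ABA0.1`, `ABA1`, `ABA10`, `GA10`
#' and `SCR` (scarified, no hormone).  The assay round supplies the
#' after-ripening duration: 0 months for `initial`/`refined`, 1 for
#' `AR1`/`SCR`, 3 for `LAR3`.
#'
#' @param treatment Treatment code string.
#' @param round Assay round: "initial", "refined", "AR1", "SCR" or "LAR3".
#' @return List with `hormone`, `conc_uM`, `months`, `scarified`.
#' @export
treatment_spec <- function(treatment, round = "initial") {
  if (!round %in% names(ROUND_MONTHS))
    stop("unknown assay round: ", round)
  months <- ROUND_MONTHS[[round]]
  spec <- switch(treatment,
    NT = list(hormone = "none", conc_uM = 0, scarified = FALSE),
    ABA0.1 = list(hormone = "ABA", conc_uM = 0.1, scarified = FALSE),
    ABA1 = list(hormone = "ABA", conc_uM = 1, scarified = FALSE),
    ABA10 = list(hormone = "ABA", conc_uM = 10, scarified = FALSE),
    GA10 = list(hormone = "GA", conc_uM = 10, scarified = FALSE),
    SCR = list(hormone = "none", conc_uM = 0, scarified = TRUE),
    stop("unknown treatment code: ", treatment)
  )
  spec$months <- months
  spec
}

#' Simulate one variety's germination counts
#'
#' Per replicate, the germinated count is Binomial(`seeds_per_rep`,
#' p) with p from [germination_prob()].
#'
#' @param truth One row of the panel truth table.
#' @param treatments Data frame with columns `round` and `treatment`
#'   (see [treatment_spec()] for valid codes).
#' @param config A [panel_config()] (replicate structure and seed).
#' @param variety_index Integer offset used to derive this variety's RNG
#'   substream from the master seed.
#' @return Long-format data frame: variety_id, round, treatment, bio_rep,
#'   tech_rep, sown, germinated.
#' @export
simulate_germination <- function(truth, treatments, config = panel_config(),
                                 variety_index = 1L) {
  stopifnot(is.data.frame(treatments),
            all(c("round", "treatment") %in% names(treatments)))
  set.seed(substream_seed(config$rng_seed, as.integer(variety_index)))
  out <- vector("list", nrow(treatments))
  for (i in seq_len(nrow(treatments))) {
    rd <- treatments$round[i]
    tr <- treatments$treatment[i]
    sp <- treatment_spec(tr, rd)
    p <- germination_prob(truth, months = sp$months,
                          scarified = sp$scarified, hormone = sp$hormone,
                          conc_uM = sp$conc_uM)
    if (rd == "initial") {
      bio <- 1L
      tech <- seq_len(config$n_tech_reps)
    } else {
      bio <- seq_len(config$n_bio_reps)
      tech <- seq_len(config$n_tech_reps)
    }
    grid <- expand.grid(bio_rep = bio, tech_rep = tech)
    out[[i]] <- data.frame(
      variety_id = truth$variety_id, round = rd, treatment = tr,
      bio_rep = grid$bio_rep, tech_rep = grid$tech_rep,
      sown = config$seeds_per_rep,
      germinated = rbinom(nrow(grid), config$seeds_per_rep, p),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate the full assay table for a panel
#'
#' All varieties receive the initial ABA dose-response round (NT, 0.1, 1,
#' 10 microM ABA) and the refined hormone round (NT, ABA10, GA10).
#' Varieties whose true class is SD or MD additionally receive the
#' one-month after-ripening round (AR1: NT, ABA10, GA10), the scarification
#' viability test (SCR) and the three-month long-after-ripening round
#' (LAR3: NT, ABA10, GA10, SCR), mirroring the screening cascade.
#'
#' @param panel Output of [generate_panel()].
#' @return Long-format assay data frame (see [simulate_germination()]).
#' @export
simulate_panel_assays <- function(panel) {
  config <- panel$config
  initial <- data.frame(round = "initial",
                        treatment = c("NT", "ABA0.1", "ABA1", "ABA10"))
  refined <- data.frame(round = "refined",
                        treatment = c("NT", "ABA10", "GA10"))
  viability <- rbind(
    data.frame(round = "AR1", treatment = c("NT", "ABA10", "GA10")),
    data.frame(round = "SCR", treatment = "SCR"),
    data.frame(round = "LAR3", treatment = c("NT", "ABA10", "GA10", "SCR"))
  )
  out <- vector("list", nrow(panel$truth))
  for (i in seq_len(nrow(panel$truth))) {
    truth <- panel$truth[i, ]
    trt <- rbind(initial, refined)
    if (truth$true_class %in% c("SD", "MD")) trt <- rbind(trt, viability)
    out[[i]] <- simulate_germination(truth, trt, config, variety_index = i)
  }
  do.call(rbind, out)
}
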