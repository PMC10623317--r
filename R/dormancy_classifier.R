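# Rule-based dormancy classification.
#
# Two staged rule sets assign a dormancy-strength category (ND < WD < MD <
# SD) from mean germination fractions: an initial ABA dose-response stage
# and a refined ABA+GA stage.  Varieties that remain dormant then pass
# through an after-ripening / scarification / long-after-ripening decision
# tree that assigns the dormancy mechanism (embryo- vs seed-coat-imposed)
# and a viability verdict.  Rules are evaluated in a fixed order (most
# restrictive first); inputs that satisfy no rule receive the category of
# the nearest rule (smallest threshold violation in percentage points)
# with an ambiguity flag.

CATEGORY_CODES <- c(ND = 1L, WD = 2L, MD = 3L, SD = 4L)

dormancy_call <- function(variety_id, category, stage, rule_fired,
                          mechanism = "undetermined", viable = "unknown",
                          ambiguous = FALSE) {
  data.frame(
    variety_id = variety_id,
    category_code = CATEGORY_CODES[[category]],
    category = factor(category, levels = names(CATEGORY_CODES),
                      ordered = TRUE),
    stage = stage, mechanism = mechanism, viable = viable,
    rule_fired = rule_fired, ambiguous = ambiguous,
    stringsAsFactors = FALSE
  )
}

# Shared two-group comparison: is `hi` significantly above `lo`?
# Pooled-variance t test on arcsine-transformed fractions; when the
# replicates carry no residual variance the rule falls back to a raw mean
# difference of at least 20 percentage points.
two_group_greater <- function(hi, lo, alpha = 0.05) {
  d <- mean(hi) - mean(lo)
  if (d <= 0) return(FALSE)
  x <- arcsine_transform(hi)
  y <- arcsine_transform(lo)
  pooled_ss <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  if (pooled_ss < 1e-12) return(d >= 0.20)
  n1 <- length(x); n2 <- length(y)
  s2 <- pooled_ss / (n1 + n2 - 2)
  tval <- (mean(x) - mean(y)) / sqrt(s2 * (1 / n1 + 1 / n2))
  pval <- 2 * pt(abs(tval), df = n1 + n2 - 2, lower.tail = FALSE)
  pval < alpha
}

# Percentage-point penalty for a mismatched responsiveness requirement,
# used only by the nearest-rule fallback: a rule that needs
# responsiveness but lacks it is short by (20 - drop) points (20 points
# being the operational zero-variance responsiveness drop); a rule that
# requires non-responsiveness is violated by the observed drop itself.
resp_penalty <- function(required, responsive, drop_pp) {
  if (required && !responsive) return(max(0, 20 - drop_pp))
  if (!required && responsive) return(drop_pp)
  0
}

#' Initial dormancy category from the ABA dose-response assay
#'
#' Rules, evaluated in order on day-7 mean germination fractions:
#' \enumerate{
#'   \item SD if all four means are below 0.25 (the 0-24\% rule);
#'   \item ND if all four means are above 0.75 and the variety is not
#'     ABA-responsive (option `nd_rule = "strict"` instead requires NT
#'     above 0.95 and 10 microM ABA above 0.75);
#'   \item MD if the NT mean is below 0.50 and the means are
#'     non-increasing in ABA concentration with a total drop of at least
#'     5 percentage points;
#'   \item WD if the NT mean is above 0.50 and the variety is
#'     ABA-responsive;
#'   \item otherwise the nearest rule's category, flagged `ambiguous`.
#' }
#'
#' @param means Named fractions `c(NT=, ABA0.1=, ABA1=, ABA10=)`.
#' @param responsive Logical from [is_aba_responsive()].
#' @param variety_id Identifier carried into the call.
#' @param nd_rule `"methods"` (above 75\% regardless of ABA) or
#'   `"strict"` (NT above 95\%, ABA10 above 75\%).
#' @return One-row data frame (a dormancy call).
#' @examples
#' classify_initial(c(NT = 0.1, ABA0.1 = 0.08, ABA1 = 0.05, ABA10 = 0),
#'                  responsive = FALSE)
#' @export
classify_initial <- function(means, responsive, variety_id = "",
                             nd_rule = c("methods", "strict")) {
  nd_rule <- match.arg(nd_rule)
  need <- c("NT", "ABA0.1", "ABA1", "ABA10")
  if (!all(need %in% names(means)))
    stop("missing treatment mean(s): ",
         paste(setdiff(need, names(means)), collapse = ", "))
  m <- as.numeric(means[need])
  if (any(m < 0 | m > 1)) stop("means must be in [0, 1]")
  names(m) <- need
  drop_pp <- (m["NT"] - m["ABA10"]) * 100

  if (max(m) < 0.25)
    return(dormancy_call(variety_id, "SD", "initial", "initial_SD_all<25"))
  nd_ok <- if (nd_rule == "methods") {
    min(m) > 0.75 && !responsive
  } else {
    m["NT"] > 0.95 && m["ABA10"] > 0.75 && !responsive
  }
  if (nd_ok)
    return(dormancy_call(variety_id, "ND", "initial", "initial_ND_all>75",
                         mechanism = "none", viable = "yes"))
  steps <- diff(m) # along increasing ABA concentration
  if (m["NT"] < 0.50 && all(steps <= 1e-12) && drop_pp >= 5)
    return(dormancy_call(variety_id, "MD", "initial",
                         "initial_MD_decreasing"))
  if (m["NT"] > 0.50 && responsive)
    return(dormancy_call(variety_id, "WD", "initial",
                         "initial_WD_responsive"))

  viol <- c(
    SD = sum(pmax(0, m - 0.25)) * 100,
    ND = if (nd_rule == "methods") {
      max(0, 0.75 - min(m)) * 100 + resp_penalty(FALSE, responsive, drop_pp)
    } else {
      (max(0, 0.95 - m["NT"]) + max(0, 0.75 - m["ABA10"])) * 100 +
        resp_penalty(FALSE, responsive, drop_pp)
    },
    MD = max(0, m["NT"] - 0.50) * 100 + sum(pmax(0, steps)) * 100 +
      max(0, 5 - drop_pp),
    WD = max(0, 0.50 - m["NT"]) * 100 +
      resp_penalty(TRUE, responsive, drop_pp)
  )
  nearest <- names(viol)[which.min(viol[c("SD", "ND", "MD", "WD")])]
  dormancy_call(variety_id, nearest, "initial",
                paste0("initial_nearest_", nearest), ambiguous = TRUE)
}

#' Refined dormancy category from the ABA + GA hormone assay
#'
#' Applied to varieties not initially classified ND.  Rules in order on
#' mean germination fractions:
#' \enumerate{
#'   \item SD if NT and 10 microM ABA are below 0.25 and 10 microM GA is
#'     below 0.30;
#'   \item MD if GA reaches at least 0.50 while NT stays below 0.50 and
#'     the variety is ABA-responsive;
#'   \item WD if NT or GA exceeds 0.50 and the variety is ABA-responsive;
#'   \item otherwise nearest rule, flagged `ambiguous`.
#' }
#'
#' @param means Named fractions `c(NT=, ABA10=, GA10=)`.
#' @param responsive Logical from [is_aba_responsive()] on the refined
#'   round.
#' @param variety_id Identifier carried into the call.
#' @return One-row data frame (a dormancy call).
#' @examples
#' classify_refined(c(NT = 0.35, ABA10 = 0.1, GA10 = 0.8),
#'                  responsive = TRUE)
#' @export
classify_refined <- function(means, responsive, variety_id = "") {
  need <- c("NT", "ABA10", "GA10")
  if (!all(need %in% names(means)))
    stop("missing treatment mean(s): ",
         paste(setdiff(need, names(means)), collapse = ", "))
  m <- as.numeric(means[need])
  if (any(m < 0 | m > 1)) stop("means must be in [0, 1]")
  names(m) <- need
  drop_pp <- (m["NT"] - m["ABA10"]) * 100

  if (m["NT"] < 0.25 && m["ABA10"] < 0.25 && m["GA10"] < 0.30)
    return(dormancy_call(variety_id, "SD", "refined", "refined_SD"))
  if (m["GA10"] >= 0.50 && m["NT"] < 0.50 && responsive)
    return(dormancy_call(variety_id, "MD", "refined", "refined_MD_GA"))
  if ((m["NT"] > 0.50 || m["GA10"] > 0.50) && responsive)
    return(dormancy_call(variety_id, "WD", "refined",
                         "refined_WD_responsive"))

  viol <- c(
    SD = (max(0, m["NT"] - 0.25) + max(0, m["ABA10"] - 0.25) +
            max(0, m["GA10"] - 0.30)) * 100,
    MD = (max(0, 0.50 - m["GA10"]) + max(0, m["NT"] - 0.50)) * 100 +
      resp_penalty(TRUE, responsive, drop_pp),
    WD = min(max(0, 0.50 - m["NT"]), max(0, 0.50 - m["GA10"])) * 100 +
      resp_penalty(TRUE, responsive, drop_pp)
  )
  nearest <- names(viol)[which.min(viol[c("SD", "MD", "WD")])]
  dormancy_call(variety_id, nearest, "refined",
                paste0("refined_nearest_", nearest), ambiguous = TRUE)
}

#' Viability and dormancy-mechanism decision tree
#'
#' For varieties classified SD or MD at the refined stage, decides in
#' fixed order from the after-ripening (AR, 1 month), scarification (SCR)
#' and long-after-ripening (LAR, 3 months) screens:
#' \enumerate{
#'   \item AR NT or GA mean at or above 0.75: dormancy released by
#'     after-ripening; embryo-imposed, viable;
#'   \item AR NT significantly above the refined NT but still below 0.50:
#'     a slow after-ripener; embryo-imposed, viable;
#'   \item scarified germination at or above 0.50 and significantly above
#'     the refined NT: seed-coat-imposed, viable;
#'   \item LAR NT or GA at or above 0.75: embryo-imposed (long
#'     after-ripening requirement), viable;
#'   \item only LAR scarification rescues (at or above 0.50 and
#'     significant): seed-coat-imposed, viable;
#'   \item otherwise a viability concern, mechanism undetermined.
#' }
#'
#' @param timeline List with elements `variety_id`, `category` (refined
#'   category label), `refined` (list of per-replicate germination
#'   fractions: `NT`, `ABA10`, `GA10`), `AR1` (same shape; required),
#'   and optionally `SCR` (fraction vector) and `LAR3` (list `NT`,
#'   `ABA10`, `GA10`, `SCR`).
#' @param alpha Significance level for the increase tests.
#' @return One-row data frame (a dormancy call with mechanism and
#'   viability fields set).
#' @export
viability_decision <- function(timeline, alpha = 0.05) {
  if (is.null(timeline$AR1))
    stop("viability tree consulted without AR1 data for ",
         timeline$variety_id)
  if (!timeline$category %in% c("SD", "MD"))
    stop("viability tree is only entered by SD or MD varieties")
  vid <- timeline$variety_id
  cat_lab <- timeline$category
  ref_nt <- timeline$refined$NT
  ar_nt <- timeline$AR1$NT
  ar_ga <- timeline$AR1$GA10

  if (mean(ar_nt) >= 0.75 || mean(ar_ga) >= 0.75)
    return(dormancy_call(vid, cat_lab, "post_AR", "AR_release",
                         mechanism = "embryo", viable = "yes"))
  if (mean(ar_nt) < 0.50 && two_group_greater(ar_nt, ref_nt, alpha))
    return(dormancy_call(vid, cat_lab, "post_AR", "AR_partial_release",
                         mechanism = "embryo", viable = "yes"))
  if (!is.null(timeline$SCR) && mean(timeline$SCR) >= 0.50 &&
      two_group_greater(timeline$SCR, ref_nt, alpha))
    return(dormancy_call(vid, cat_lab, "post_AR", "scarification_rescue",
                         mechanism = "seedcoat", viable = "yes"))
  if (!is.null(timeline$LAR3)) {
    if (mean(timeline$LAR3$NT) >= 0.75 || mean(timeline$LAR3$GA10) >= 0.75)
      return(dormancy_call(vid, cat_lab, "post_LAR", "LAR_release",
                           mechanism = "embryo", viable = "yes"))
    if (!is.null(timeline$LAR3$SCR) && mean(timeline$LAR3$SCR) >= 0.50 &&
        two_group_greater(timeline$LAR3$SCR, ref_nt, alpha))
      return(dormancy_call(vid, cat_lab, "post_LAR",
                           "LAR_scarification_rescue",
                           mechanism = "seedcoat", viable = "yes"))
  }
  stage <- if (is.null(timeline$LAR3)) "post_AR" else "post_LAR"
  dormancy_call(vid, cat_lab, stage, "viability_concern",
                mechanism = "undetermined", viable = "concern")
}

# Replicate germination fractions for one variety/round/treatment.
assay_fractions <- function(assays, vid, rd, tr) {
  sub <- assays[assays$variety_id == vid & assays$round == rd &
                  assays$treatment == tr, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  sub$germinated / sub$sown
}

assay_obj <- function(assays, vid, rd, tr) {
  sub <- assays[assays$variety_id == vid & assays$round == rd &
                  assays$treatment == tr, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  germination_assay(vid, tr, sub$sown, sub$germinated)
}

#' Classify every variety in a long-format assay table
#'
#' Runs the full staged cascade per variety: initial ABA dose-response
#' classification; varieties not called ND are re-classified from the
#' refined ABA+GA round; refined SD and MD varieties then pass through the
#' viability/mechanism tree when after-ripening data are present (a
#' missing AR round yields mechanism `undetermined` and viability
#' `unknown` rather than an error, so partially assayed panels still
#' classify).
#'
#' @param assays Data frame with columns variety_id, round, treatment,
#'   sown, germinated (see [simulate_panel_assays()]).
#' @param alpha Significance level for responsiveness and increase tests.
#' @param nd_rule Passed to [classify_initial()].
#' @return Data frame of dormancy calls, one row per variety.
#' @export
classify_panel <- function(assays, alpha = 0.05, nd_rule = "methods") {
  need <- c("variety_id", "round", "treatment", "sown", "germinated")
  if (!all(need %in% names(assays)))
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  vids <- unique(assays$variety_id)
  calls <- vector("list", length(vids))
  for (i in seq_along(vids)) {
    vid <- vids[i]
    init_means <- vapply(c("NT", "ABA0.1", "ABA1", "ABA10"), function(tr) {
      fr <- assay_fractions(assays, vid, "initial", tr)
      if (is.null(fr)) stop("variety ", vid, ": missing initial ", tr)
      mean(fr)
    }, numeric(1))
    init_resp <- is_aba_responsive(
      assay_obj(assays, vid, "initial", "NT"),
      assay_obj(assays, vid, "initial", "ABA10"), alpha
    )
    call <- classify_initial(init_means, init_resp, vid, nd_rule)
    if (call$category != "ND") {
      ref_means <- vapply(c("NT", "ABA10", "GA10"), function(tr) {
        fr <- assay_fractions(assays, vid, "refined", tr)
        if (is.null(fr)) stop("variety ", vid, ": missing refined ", tr)
        mean(fr)
      }, numeric(1))
      ref_resp <- is_aba_responsive(
        assay_obj(assays, vid, "refined", "NT"),
        assay_obj(assays, vid, "refined", "ABA10"), alpha
      )
      call <- classify_refined(ref_means, ref_resp, vid)
      if (call$category %in% c("SD", "MD")) {
        ar_nt <- assay_fractions(assays, vid, "AR1", "NT")
        if (is.null(ar_nt)) {
          call$mechanism <- "undetermined"
          call$viable <- "unknown"
          call$rule_fired <- paste0(call$rule_fired, ";no_AR_data")
        } else {
          lar_nt <- assay_fractions(assays, vid, "LAR3", "NT")
          timeline <- list(
            variety_id = vid, category = as.character(call$category),
            refined = list(NT = assay_fractions(assays, vid, "refined",
                                                "NT")),
            AR1 = list(NT = ar_nt,
                       ABA10 = assay_fractions(assays, vid, "AR1",
                                               "ABA10"),
                       GA10 = assay_fractions(assays, vid, "AR1", "GA10")),
            SCR = assay_fractions(assays, vid, "SCR", "SCR"),
            LAR3 = if (is.null(lar_nt)) NULL else list(
              NT = lar_nt,
              ABA10 = assay_fractions(assays, vid, "LAR3", "ABA10"),
              GA10 = assay_fractions(assays, vid, "LAR3", "GA10"),
              SCR = assay_fractions(assays, vid, "LAR3", "SCR")
            )
          )
          tree <- viability_decision(timeline, alpha)
          tree$ambiguous <- call$ambiguous
          call <- tree
        }
      }
    }
    calls[[i]] <- call
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Category counts (and optional color cross-tabulation) for a panel
#'
#' @param calls Data frame of dormancy calls ([classify_panel()] output).
#' @param coat_color Optional factor/character vector of seed coat colors
#'   aligned with `calls` rows; when given, a color x category
#'   contingency table is included.
#' @return List with `counts` (named integer vector over ND, WD, MD, SD),
#'   `n` (denominator) and optionally `color_by_category`.
#' @export
summarize_panel <- function(calls, coat_color = NULL) {
  if (anyDuplicated(calls$variety_id))
    stop("duplicate variety ids in calls")
  counts <- setNames(integer(4), names(CATEGORY_CODES))
  if (nrow(calls)) {
    tab <- table(factor(calls$category, levels = names(CATEGORY_CODES)))
    counts[names(tab)] <- as.integer(tab)
  }
  out <- list(counts = counts, n = nrow(calls))
  if (!is.null(coat_color)) {
    stopifnot(length(coat_color) == nrow(calls))
    out$color_by_category <- table(
      color = coat_color,
      category = factor(calls$category, levels = names(CATEGORY_CODES))
    )
  }
  out
}
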