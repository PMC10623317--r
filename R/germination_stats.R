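# Germination statistics: percent germination, the arcsine square-root
# transform, one-way ANOVA with Tukey all-pairwise comparisons and compact
# letter display, and the operational ABA-responsiveness test consumed by
# the dormancy classifier.

#' Construct a germination assay record
#'
#' @param variety_id Variety identifier.
#' @param treatment Treatment code (see [treatment_spec()]).
#' @param sown,germinated Integer vectors, one entry per replicate;
#'   `0 <= germinated <= sown`, `sown >= 1`.
#' @param scoring_day Day of scoring (default 7).
#' @return Object of class `germination_assay`.
#' @export
germination_assay <- function(variety_id, treatment, sown, germinated,
                              scoring_day = 7L) {
  if (length(sown) != length(germinated))
    stop("sown and germinated must have the same length")
  if (length(sown) == 0) stop("assay needs at least one replicate")
  if (any(sown < 1)) stop("sown must be >= 1")
  if (any(germinated < 0 | germinated > sown))
    stop("germinated must be in [0, sown]")
  if (scoring_day < 1) stop("scoring_day must be >= 1")
  structure(list(variety_id = variety_id, treatment = treatment,
                 sown = as.integer(sown),
                 germinated = as.integer(germinated),
                 scoring_day = as.integer(scoring_day)),
            class = "germination_assay")
}

#' Per-replicate and mean germination fractions
#'
#' @param assay A [germination_assay()], or a data frame with `sown` and
#'   `germinated` columns.
#' @return List with `fractions` (per replicate) and `mean` (unweighted
#'   mean over replicates).
#' @examples
#' percent_germination(germination_assay("v", "NT", c(10, 10), c(7, 9)))
#' @export
percent_germination <- function(assay) {
  if (is.data.frame(assay)) {
    assay <- germination_assay(assay$variety_id[1], assay$treatment[1],
                               assay$sown, assay$germinated)
  }
  stopifnot(inherits(assay, "germination_assay"))
  fr <- assay$germinated / assay$sown
  list(fractions = fr, mean = mean(fr))
}

#' Arcsine square-root transform of a germination fraction
#'
#' `asin(sqrt(p))`, mapping `[0, 1]` onto `[0, pi/2]`; the standard
#' variance-stabilizing transform for binomial proportions used before
#' ANOVA on germination percentages.
#'
#' @param p Fractions in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @examples
#' arcsine_transform(c(0, 0.5, 1))
#' @export
arcsine_transform <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  asin(sqrt(p))
}

# Compact letter display by insert-and-absorb (Piepho-style): start with
# one letter covering all groups; for each significantly different pair,
# split every letter set containing both, then absorb subsets.  `groups`
# must already be in display order (descending mean, ties by name).
cld_letters <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    g1 <- sig_pairs$g1[k]; g2 <- sig_pairs$g2[k]
    nxt <- list()
    for (s in sets) {
      if (all(c(g1, g2) %in% s)) {
        nxt <- c(nxt, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else {
        nxt <- c(nxt, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(nxt))
    for (i in seq_along(nxt)) {
      for (j in seq_along(nxt)) {
        if (i != j && keep[j] &&
            all(nxt[[i]] %in% nxt[[j]]) &&
            (length(nxt[[i]]) < length(nxt[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- nxt[keep]
  }
  # order letter sets by first member's display position
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a fixed-effects one-way ANOVA on the supplied (typically
#' arcsine-transformed) values, runs Tukey's all-pairwise honest
#' significant difference test at the residual degrees of freedom, and
#' assigns compact letters by the insert-and-absorb procedure over groups
#' sorted by descending mean (ties by group name).  With zero residual
#' variance, identical groups share one letter; unequal means are reported
#' as all-pairs significant with `zero_variance = TRUE`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Object of class `tukey_result`: `means`, `pairs` (data frame
#'   g1, g2, diff, p_adj), `letters`, `f_statistic`, `df`, `alpha`,
#'   `zero_variance`.
#' @examples
#' anova_tukey(list(NT = c(1.2, 1.4, 1.3), ABA = c(0.1, 0.2, 0.15)))
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  df_resid <- length(values) - nlevels(g)
  if (df_resid < 1) stop("residual degrees of freedom must be >= 1")

  means <- vapply(groups, mean, numeric(1))
  ord <- order(-means, names(means))
  display <- names(means)[ord]

  cmb <- utils::combn(names(groups), 2)
  pairs <- data.frame(g1 = cmb[1, ], g2 = cmb[2, ],
                      diff = means[cmb[2, ]] - means[cmb[1, ]],
                      stringsAsFactors = FALSE)

  ss_resid <- sum((values - ave(values, g))^2)
  zero_var <- ss_resid < 1e-12 * max(1, sum(values^2))
  if (zero_var) {
    equal <- abs(pairs$diff) < 1e-12
    pairs$p_adj <- ifelse(equal, 1, 0)
    if (any(!equal))
      warning("zero residual variance with unequal group means; ",
              "all differing pairs reported significant")
    fstat <- if (any(!equal)) Inf else NaN
  } else {
    fit <- aov(values ~ g)
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
    key <- paste(pairs$g2, pairs$g1, sep = "-") # TukeyHSD order
    key2 <- paste(pairs$g1, pairs$g2, sep = "-")
    rn <- rownames(tk)
    p <- ifelse(key %in% rn, tk[match(key, rn), "p adj"],
                tk[match(key2, rn), "p adj"])
    pairs$p_adj <- p
    fstat <- summary(fit)[[1]]$`F value`[1]
  }

  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  lett <- cld_letters(display, sig)

  structure(list(
    means = means, pairs = pairs, letters = lett[names(means)],
    f_statistic = fstat, df = c(between = nlevels(g) - 1,
                                within = df_resid),
    alpha = alpha, zero_variance = zero_var
  ), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("One-way ANOVA + Tukey HSD (alpha =", x$alpha, ")\n")
  cat("F =", format(x$f_statistic, digits = 4), "on", x$df[1], "and",
      x$df[2], "df\n")
  tab <- data.frame(mean = x$means, letter = x$letters)
  print(tab, ...)
  invisible(x)
}

#' Is a variety operationally responsive to ABA?
#'
#' TRUE when the 10 microM ABA germination mean is below the no-treatment
#' mean and the difference is supported: either a pooled-variance t test
#' on the arcsine scale rejects at `alpha` (equivalent to Tukey HSD with
#' two groups), or — when the replicates carry no residual variance — the
#' raw mean drop is at least 20 percentage points.
#'
#' @param nt,aba10 [germination_assay()] objects for the no-treatment and
#'   10 microM ABA arms of the same variety.
#' @param alpha Significance level (default 0.05).
#' @return Logical.
#' @export
is_aba_responsive <- function(nt, aba10, alpha = 0.05) {
  stopifnot(inherits(nt, "germination_assay"),
            inherits(aba10, "germination_assay"))
  if (!identical(nt$variety_id, aba10$variety_id))
    stop("assays come from different varieties: ", nt$variety_id, " vs ",
         aba10$variety_id)
  two_group_greater(percent_germination(nt)$fractions,
                    percent_germination(aba10)$fractions, alpha)
}
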