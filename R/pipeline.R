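# End-to-end pipeline: simulate (or load) a panel, classify dormancy,
# run morphometrics on rendered scan images, NIR QC, the four FAMD
# analyses and the three ordinal-regression analyses, and assemble a
# report bundle (category counts, trait-by-category means and ranges,
# color-by-category table, FAMD and OLR summaries).

# The four FAMD variable sets: all traits; seed coat color + thickness;
# shape descriptors; quality traits.  Dormancy category is appended to
# each as the categorical variable of interest.
FAMD_SETS <- list(
  all_traits = c("area", "thickness", "protein", "moisture",
                 "eccentricity", "major_axis", "minor_axis", "perimeter",
                 "solidity", "coat_color"),
  coat = c("thickness", "coat_color"),
  shape = c("area", "eccentricity", "major_axis", "minor_axis",
            "perimeter", "solidity"),
  quality = c("protein", "moisture")
)

# The three OLR predictor sets: coat color + thickness; protein +
# moisture; combined shape descriptors.
OLR_MODELS <- list(
  coat = c("thickness", "coat_color"),
  quality = c("protein", "moisture"),
  shape = c("area", "solidity", "perimeter", "eccentricity",
            "major_axis", "minor_axis")
)

#' Pipeline run configuration
#'
#' Bundles every stage's tunables with full defaulting so
#' `run_pipeline(run_config())` works with zero arguments.  A YAML file
#' with any subset of these fields can be loaded with
#' `run_config(yaml = path)`.
#'
#' @param panel A [panel_config()].
#' @param alpha Significance level for responsiveness/viability tests.
#' @param nd_rule Initial ND rule variant (see [classify_initial()]).
#' @param classify Run the dormancy classifier (when FALSE, downstream
#'   stages use the ground-truth dormancy labels and the report omits
#'   category counts).
#' @param dpi Scanner resolution for rendered images.
#' @param n_image_samples,seeds_per_image Rendered scan images per run
#'   and seeds per image.
#' @param nir_alpha Mahalanobis exclusion level.
#' @param nir_ranges Named list of calibration ranges per constituent.
#' @param n_calibration_spectra,spectra_outlier_fraction NIR simulation
#'   settings.
#' @param famd_dims Dimensions retained per FAMD analysis.
#' @param out_dir Optional output directory for CSV/PNG artifacts.
#' @param yaml Optional path to a YAML file overriding defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(panel = panel_config(), alpha = 0.05,
                       nd_rule = "methods", classify = TRUE, dpi = 1200,
                       n_image_samples = 2L, seeds_per_image = 12L,
                       nir_alpha = 0.001,
                       nir_ranges = list(protein = c(8, 21),
                                         moisture = c(7, 10)),
                       n_calibration_spectra = 150L,
                       spectra_outlier_fraction = 0.03,
                       famd_dims = 2L, out_dir = NULL, yaml = NULL) {
  cfg <- list(panel = panel, alpha = alpha, nd_rule = nd_rule,
              classify = classify, dpi = dpi,
              n_image_samples = as.integer(n_image_samples),
              seeds_per_image = as.integer(seeds_per_image),
              nir_alpha = nir_alpha, nir_ranges = nir_ranges,
              n_calibration_spectra = as.integer(n_calibration_spectra),
              spectra_outlier_fraction = spectra_outlier_fraction,
              famd_dims = as.integer(famd_dims), out_dir = out_dir)
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    pn <- intersect(names(ov$panel), names(formals(panel_config)))
    if (length(pn)) cfg$panel <- do.call(panel_config, ov$panel[pn])
    for (nm in intersect(names(ov), setdiff(names(cfg), "panel"))) {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  stopifnot(alpha > 0, alpha < 1, nir_alpha > 0, nir_alpha < 1)
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(verbose, stage, n_in, n_out) {
  if (verbose)
    message(sprintf("[%s] rows in: %d, rows out: %d", stage, n_in, n_out))
}

#' Run the full phenotyping pipeline on a synthetic panel
#'
#' Chains simulate -> germination stats -> classify -> morphometrics ->
#' NIR QC -> trait-table assembly -> FAMD (four analyses) -> ordinal
#' regression (three analyses) -> report.  Deterministic given the
#' configuration (which carries the master seed).
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage row counts (default FALSE).
#' @return List with `panel`, `assays`, `calls` (NULL when
#'   classification is disabled), `morphometrics`, `nir`, `trait_table`,
#'   `famd`, `olr` and `report`; written to `config$out_dir` as CSV when
#'   set.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$panel$rng_seed

  panel <- generate_panel(config$panel)
  assays <- simulate_panel_assays(panel)
  stage_log(verbose, "simulate", nrow(panel$truth), nrow(assays))

  calls <- NULL
  if (isTRUE(config$classify)) {
    calls <- classify_panel(assays, config$alpha, config$nd_rule)
    stage_log(verbose, "classify", length(unique(assays$variety_id)),
              nrow(calls))
    if (nrow(calls) != nrow(panel$truth))
      stop("classifier dropped varieties: ", nrow(panel$truth), " in, ",
           nrow(calls), " out")
  }

  morph <- list()
  if (config$n_image_samples > 0) {
    for (i in seq_len(config$n_image_samples)) {
      layout <- random_seed_layout(config$seeds_per_image,
                                   rng_seed = substream_seed(seed, 1000 + i))
      rend <- render_seed_image(layout, dpi = config$dpi,
                                rng_seed = substream_seed(seed, 2000 + i))
      morph[[i]] <- analyze_seed_image(rend$image, dpi = config$dpi)
      morph[[i]]$truth <- rend$truth
    }
    stage_log(verbose, "morphometrics", config$n_image_samples,
              sum(vapply(morph, function(m) m$summary$n_seeds, 1L)))
  }

  spectra <- generate_spectra(
    n_experimental = nrow(panel$truth),
    n_calibration = config$n_calibration_spectra,
    outlier_fraction = config$spectra_outlier_fraction,
    rng_seed = substream_seed(seed, 3000)
  )
  predicted <- panel$traits[, c("protein", "moisture")]
  nir <- nir_qc(spectra$experimental, spectra$calibration, predicted,
                config$nir_ranges, config$nir_alpha)
  stage_log(verbose, "nir_qc", nrow(nir), sum(nir$qc_status == "kept"))

  trait_table <- panel$traits
  if (!is.null(calls)) {
    trait_table$dormancy <- calls$category[
      match(trait_table$variety_id, calls$variety_id)]
  }

  famd_fits <- lapply(FAMD_SETS, function(vars) {
    tab <- trait_table[, c(vars, "dormancy")]
    fit <- famd(tab, n_dims = config$famd_dims)
    list(fit = fit, support = support_check(fit))
  })

  y <- as.integer(trait_table$dormancy)
  olr_fits <- lapply(OLR_MODELS, function(vars) {
    X <- olr_design_matrix(trait_table[, vars, drop = FALSE],
                           baselines = c(coat_color = "beige"))
    tryCatch(olr(X, y), error = function(e) {
      warning("ordinal regression failed: ", conditionMessage(e))
      NULL
    })
  })

  report <- make_report(calls, trait_table, famd_fits, olr_fits, nir)
  out <- list(panel = panel, assays = assays, calls = calls,
              morphometrics = morph, nir = nir,
              trait_table = trait_table, famd = famd_fits,
              olr = olr_fits, report = report, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out)
  out
}

TRAIT_COLUMNS <- c("area", "thickness", "protein", "moisture",
                   "eccentricity", "major_axis", "minor_axis",
                   "perimeter", "solidity")

#' Assemble the summary report bundle
#'
#' @param calls Dormancy calls ([classify_panel()]) or NULL.
#' @param trait_table Per-variety trait table with a `dormancy` column.
#' @param famd_fits,olr_fits Lists of FAMD fits (with support checks) and
#'   `olr` fits, as built by [run_pipeline()] (may be NULL).
#' @param nir NIR QC table or NULL.
#' @return List: `category_counts` (when calls given),
#'   `trait_by_category` (means and ranges per dormancy category, with
#'   denominators), `color_by_category`, `famd_summary`, `olr_tables`,
#'   `nir_exclusions`.
#' @export
make_report <- function(calls, trait_table, famd_fits = NULL,
                        olr_fits = NULL, nir = NULL) {
  report <- list()
  if (!is.null(calls)) {
    s <- summarize_panel(calls, trait_table$coat_color[
      match(calls$variety_id, trait_table$variety_id)])
    report$category_counts <- s$counts
    report$n_classified <- s$n
    report$color_by_category <- s$color_by_category
  }

  cats <- levels(trait_table$dormancy)
  rows <- list()
  for (tr in intersect(TRAIT_COLUMNS, names(trait_table))) {
    for (cl in cats) {
      v <- trait_table[[tr]][trait_table$dormancy == cl]
      rows[[paste(tr, cl)]] <- data.frame(
        trait = tr, category = cl, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_
      )
    }
  }
  report$trait_by_category <- do.call(rbind, c(rows,
                                               make.row.names = FALSE))

  if (!is.null(famd_fits)) {
    report$famd_summary <- do.call(rbind, lapply(names(famd_fits),
      function(nm) {
        f <- famd_fits[[nm]]$fit
        sup <- famd_fits[[nm]]$support
        data.frame(analysis = nm, n_rows = f$n_rows, n_dims = f$n_dims,
                   dim1_pct = f$percent_inertia[1],
                   dim2_pct = if (length(f$percent_inertia) > 1)
                     f$percent_inertia[2] else NA_real_,
                   cumulative_pct = sup$cumulative_percent,
                   supported = sup$supported)
      }))
  }
  if (!is.null(olr_fits)) {
    report$olr_tables <- lapply(olr_fits, function(f)
      if (is.null(f)) NULL else olr_coef_table(f))
  }
  if (!is.null(nir)) {
    report$nir_exclusions <- table(nir$qc_status)
  }
  report
}

# 6-significant-digit CSV floats, except ordinal-regression estimates at
# 8 decimals.
fmt_num <- function(df, digits = 6, olr_style = FALSE) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- if (olr_style) sprintf("%.8f", df[[nm]])
        else signif(df[[nm]], digits)
    }
  }
  df
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name, olr_style = FALSE) {
    write.csv(fmt_num(df, olr_style = olr_style),
              file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  wr(result$panel$truth, "panel_truth")
  wr(result$trait_table, "trait_table")
  wr(result$assays, "assays")
  if (!is.null(result$calls)) {
    wr(result$calls, "dormancy_calls")
    wr(data.frame(category = names(result$report$category_counts),
                  count = as.integer(result$report$category_counts)),
       "category_counts")
  }
  wr(result$report$trait_by_category, "trait_by_category")
  if (!is.null(result$report$famd_summary))
    wr(result$report$famd_summary, "famd_summary")
  for (nm in names(result$olr)) {
    if (!is.null(result$olr[[nm]]))
      wr(olr_coef_table(result$olr[[nm]]), paste0("olr_", nm),
         olr_style = TRUE)
  }
  wr(result$nir, "nir_qc")
  invisible(dir)
}
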