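# Factorial analysis of mixed data (FAMD): a joint PCA/MCA through one
# singular value decomposition of a weighted, centered encoding of
# quantitative and categorical columns.
#
# Quantitative columns are standardized with the population (1/n) standard
# deviation, so each contributes inertia 1; each categorical level's
# indicator column is divided by the square root of its frequency
# proportion and centered, so a variable with L levels contributes
# inertia L - 1.  Total inertia is therefore K_quant + sum(levels - 1).

#' Weighted centered encoding of a mixed trait table
#'
#' @param table Data frame of quantitative (numeric) and categorical
#'   (factor/character) columns.  Rows with missing cells are dropped
#'   (count reported in the `dropped` attribute).
#' @param population_sd Standardize quantitative columns with the
#'   population (1/n) standard deviation (default TRUE; FALSE uses the
#'   sample sd).
#' @return Numeric matrix with attributes `quant` (column names),
#'   `cat` (variable names), `levels` (level count per categorical
#'   variable), `col_var` (source variable per encoded column), and
#'   `dropped` (rows removed for missingness).
#' @examples
#' encode_mixed(data.frame(x = c(1, 2, 3)))
#' @export
encode_mixed <- function(table, population_sd = TRUE) {
  stopifnot(is.data.frame(table))
  cc <- complete.cases(table)
  dropped <- sum(!cc)
  table <- table[cc, , drop = FALSE]
  n <- nrow(table)
  if (n < 2) stop("need at least 2 complete rows")
  is_num <- vapply(table, is.numeric, logical(1))
  quant <- names(table)[is_num]
  cats <- names(table)[!is_num]

  cols <- list()
  col_var <- character(0)
  for (v in quant) {
    x <- table[[v]]
    s <- if (population_sd) sqrt(mean((x - mean(x))^2)) else sd(x)
    if (s < 1e-12)
      stop("quantitative column has zero variance: ", v)
    cols[[v]] <- (x - mean(x)) / s
    col_var <- c(col_var, v)
  }
  n_levels <- integer(0)
  for (v in cats) {
    f <- factor(table[[v]])
    f <- droplevels(f)
    if (nlevels(f) < 2)
      stop("categorical column has fewer than 2 observed levels: ", v)
    n_levels[v] <- nlevels(f)
    for (l in levels(f)) {
      p_l <- mean(f == l)
      z <- (as.numeric(f == l) - p_l) / sqrt(p_l)
      cols[[paste(v, l, sep = ".")]] <- z
      col_var <- c(col_var, v)
    }
  }
  M <- do.call(cbind, cols)
  rownames(M) <- rownames(table)
  structure(M, quant = quant, cat = cats, levels = n_levels,
            col_var = col_var, dropped = dropped)
}

#' Fit FAMD by singular value decomposition
#'
#' With uniform row masses 1/n, the eigenvalues are the squared singular
#' values of the encoded matrix divided by n; row principal coordinates
#' are left singular vectors times singular values; column loadings are
#' the right singular vectors.  Signs are fixed by making the
#' largest-magnitude element of each loading vector positive.
#'
#' @param table Mixed trait data frame (see [encode_mixed()]), or an
#'   already-encoded matrix from [encode_mixed()].
#' @param n_dims Number of dimensions to retain (default
#'   `min(5, n - 1, p)`).
#' @param population_sd Passed to [encode_mixed()].
#' @return Object of class `famd`: `eigenvalues`, `percent_inertia`,
#'   `cumulative_inertia`, `row_coords`, `loadings`, `contributions`
#'   (percent contribution of each encoded column per dimension),
#'   `total_inertia`, `n_dims`, `n_rows`, `dropped`.
#' @examples
#' f <- famd(data.frame(x = rnorm(10), y = rnorm(10)), n_dims = 2)
#' f$percent_inertia
#' @export
famd <- function(table, n_dims = NULL, population_sd = TRUE) {
  M <- if (is.matrix(table)) table else
    encode_mixed(table, population_sd = population_sd)
  n <- nrow(M)
  p <- ncol(M)
  max_dims <- min(n - 1, p)
  if (is.null(n_dims)) n_dims <- min(5, max_dims)
  if (n_dims > max_dims)
    stop("n_dims must be <= min(n_rows - 1, n_cols) = ", max_dims)
  sv <- svd(M)
  eig <- sv$d^2 / n
  keep <- seq_len(max_dims)
  eig <- eig[keep]
  # deterministic sign: largest |loading| element positive per dimension
  for (k in keep) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  total <- sum(eig)
  pct <- 100 * eig / total
  dims <- seq_len(n_dims)
  row_coords <- sv$u[, dims, drop = FALSE] %*%
    diag(sv$d[dims], n_dims, n_dims)
  loadings <- sv$v[, dims, drop = FALSE]
  contrib <- 100 * sweep(loadings^2, 2, colSums(loadings^2), "/")
  dn <- paste0("Dim", dims)
  dimnames(row_coords) <- list(rownames(M), dn)
  dimnames(loadings) <- list(colnames(M), dn)
  dimnames(contrib) <- list(colnames(M), dn)
  structure(list(
    eigenvalues = eig, percent_inertia = pct,
    cumulative_inertia = cumsum(pct), row_coords = row_coords,
    loadings = loadings, contributions = contrib,
    total_inertia = total, n_dims = n_dims, n_rows = n,
    quant = attr(M, "quant"), cat = attr(M, "cat"),
    levels = attr(M, "levels"),
    dropped = if (is.null(attr(M, "dropped"))) 0L else attr(M, "dropped")
  ), class = "famd")
}

#' @export
print.famd <- function(x, ...) {
  cat("FAMD:", x$n_rows, "rows,", length(x$quant), "quantitative and",
      length(x$cat), "categorical variable(s)")
  if (x$dropped > 0) cat(" (", x$dropped, " incomplete rows dropped)",
                         sep = "")
  cat("\nTotal inertia:", format(x$total_inertia, digits = 6), "\n")
  tab <- data.frame(
    eigenvalue = x$eigenvalues[seq_len(x$n_dims)],
    percent = x$percent_inertia[seq_len(x$n_dims)],
    cumulative = x$cumulative_inertia[seq_len(x$n_dims)]
  )
  rownames(tab) <- paste0("Dim", seq_len(x$n_dims))
  print(tab, digits = 4, ...)
  invisible(x)
}

#' Cumulative-inertia support rule for a FAMD
#'
#' The retained dimensions support an interpretation when their combined
#' inertia reaches the threshold (50\% by default).
#'
#' @param result A [famd()] fit.
#' @param n_dims Number of leading dimensions to pool (default: the
#'   retained count).
#' @param threshold Required cumulative fraction (default 0.5).
#' @return List with `supported` (logical), `cumulative_percent`, and a
#'   human-readable `report` line.
#' @examples
#' f <- famd(data.frame(x = rnorm(20), y = rnorm(20)), n_dims = 2)
#' support_check(f)$supported
#' @export
support_check <- function(result, n_dims = result$n_dims,
                          threshold = 0.5) {
  stopifnot(inherits(result, "famd"), n_dims >= 1)
  n_dims <- min(n_dims, length(result$cumulative_inertia))
  cum <- result$cumulative_inertia[n_dims]
  ok <- cum >= 100 * threshold
  list(
    supported = ok, cumulative_percent = cum,
    report = sprintf(
      "first %d dimension(s) explain %.1f%% of inertia: %s the %.0f%% support threshold",
      n_dims, cum, if (ok) "meets" else "below", 100 * threshold
    )
  )
}

#' Scatter plot of the first two FAMD dimensions
#'
#' @param x A [famd()] fit.
#' @param color Optional factor (e.g. dormancy category) coloring points.
#' @param ... Unused.
#' @return A ggplot object if ggplot2 is installed, otherwise a base plot
#'   is drawn and `invisible(NULL)` returned.
#' @export
plot.famd <- function(x, color = NULL, ...) {
  d <- data.frame(Dim1 = x$row_coords[, 1], Dim2 = x$row_coords[, 2])
  labs <- sprintf("Dim%d (%.1f%%)", 1:2, x$percent_inertia[1:2])
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    if (!is.null(color)) d$group <- color
    g <- ggplot2::ggplot(d, ggplot2::aes(.data$Dim1, .data$Dim2)) +
      (if (is.null(color)) ggplot2::geom_point() else
        ggplot2::geom_point(ggplot2::aes(color = .data$group))) +
      ggplot2::labs(x = labs[1], y = labs[2]) +
      ggplot2::theme_minimal()
    return(g)
  }
  plot(d$Dim1, d$Dim2, xlab = labs[1], ylab = labs[2],
       col = if (is.null(color)) 1 else as.integer(factor(color)),
       pch = 19)
  invisible(NULL)
}
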