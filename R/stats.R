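# Inferential stages: three-way factorial ANOVA (tissue x pathology x
# MW) on per-nucleus metrics, Welch t-tests for stain intensities, and
# Pearson correlation. P-values are reported uncorrected.

#' Three-way factorial ANOVA
#'
#' Full-factorial linear-model decomposition of a per-nucleus metric over
#' tissue, pathology and molecular-weight category, with Type II sums of
#' squares (robust to the unbalanced cell counts typical of imaging
#' experiments; equal to the classical decomposition on balanced data).
#'
#' @param records Data frame with factor columns `tissue`, `pathology`,
#'   `mw` and a numeric `value` column (finite, non-missing).
#' @param value Name of the response column.
#' @return An `anova_table` data frame: `term`, `sumsq`, `df`,
#'   `statistic`, `p.value` (residual row included; p-values
#'   uncorrected).
#' @export
three_way_anova <- function(records, value = "value") {
  need <- c("tissue", "pathology", "mw", value)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  records <- records[is.finite(records[[value]]), , drop = FALSE]
  for (f in c("tissue", "pathology", "mw")) {
    records[[f]] <- factor(records[[f]])
    if (nlevels(records[[f]]) < 2) {
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  cells <- table(records$tissue, records$pathology, records$mw)
  if (any(cells == 0)) {
    warning("empty design cells; only estimable terms are reported")
  }
  fml <- stats::as.formula(paste0("`", value, "` ~ tissue * pathology * mw"))
  fit <- stats::lm(fml, data = records)
  a <- car::Anova(fit, type = 2, singular.ok = TRUE)
  out <- data.frame(
    term = rownames(a),
    sumsq = a[["Sum Sq"]],
    df = a[["Df"]],
    statistic = a[["F value"]],
    p.value = a[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  attr(out, "n") <- nrow(records)
  attr(out, "p_adjustment") <- "none"
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Independent two-sample t-test (Welch)
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return List: `t`, `df`, `p`, `mean_difference`, per-sample means and
#'   sds.
#' @export
ttest_independent <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = mean(a) - mean(b),
       mean_a = mean(a), mean_b = mean(b),
       sd_a = stats::sd(a), sd_b = stats::sd(b))
}

#' Pearson correlation and R-squared
#'
#' @param x,y Equal-length numeric samples, n >= 3, nonzero variance.
#' @return List: `r`, `r_squared`, `n`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length samples with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a sample", call. = FALSE)
  }
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2, n = length(x))
}

#' Simulate balanced factorial metric records
#'
#' Draws i.i.d. normal per-nucleus values on a balanced tissue (2) x
#' pathology (2) x molecular-weight (3) design, with optional additive
#' main effects, for null calibration and power studies of
#' [three_way_anova()].
#'
#' @param n_per_cell Observations per design cell.
#' @param mw_effect Additive shift (in sd units) between successive MW
#'   levels.
#' @param tissue_effect,pathology_effect Additive shifts for the second
#'   level of each factor.
#' @param sd Residual standard deviation.
#' @param seed RNG seed.
#' @return Data frame with `tissue`, `pathology`, `mw`, `value`.
#' @export
simulate_factorial_records <- function(n_per_cell, mw_effect = 0,
                                       tissue_effect = 0,
                                       pathology_effect = 0,
                                       sd = 1, seed = 1L) {
  grid <- expand.grid(
    tissue = c("breast", "prostate"),
    pathology = c("healthy", "cancerous"),
    mw = c("free_dye", "3kDa", "10kDa"),
    rep = seq_len(n_per_cell),
    stringsAsFactors = FALSE
  )
  withr::with_seed(as.integer(seed), {
    mu <- mw_effect * sd * (match(grid$mw, c("free_dye", "3kDa", "10kDa")) - 1) +
      tissue_effect * sd * (grid$tissue == "prostate") +
      pathology_effect * sd * (grid$pathology == "cancerous")
    grid$value <- stats::rnorm(nrow(grid), mean = mu, sd = sd)
  })
  grid$rep <- NULL
  grid
}
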