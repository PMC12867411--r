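# Cell-line-normalized cross-MW ratiometrics. Any cell-line-specific
# multiplicative characteristic N (e.g. nuclear pore count) cancels in
# metric ratios across molecular weights within a line:
#   (UD_high * N) / (UD_low * N) = UD_high / UD_low
# so the log10 ratio table is comparable between cell lines. Entries
# whose direction contradicts size-dependent (Fickian) diffusion - or
# sits within a tolerance band of equality - are classified non-Fickian.

metric_kinds <- c("t_half", "y_half_normalized", "max_rate")

metric_column <- c(t_half = "t_half_s",
                   y_half_normalized = "y_half_normalized",
                   max_rate = "max_rate_per_s")

#' Population medians per (cell line, cargo, metric)
#'
#' Flagged nuclei (no uptake, censored, failed normalization) are
#' excluded; groups left empty after exclusion are omitted with a
#' warning.
#'
#' @param metrics Data frame of per-nucleus metrics with columns `line`,
#'   `cargo`, `molecular_weight`, the metric columns of
#'   [run_experiment()], and `flags`.
#' @return Data frame: `line`, `cargo`, `molecular_weight`, `metric`,
#'   `median`, `mad`, `sd`, `n_cells`.
#' @export
population_medians <- function(metrics) {
  need <- c("line", "cargo", "molecular_weight", "flags",
            unname(metric_column))
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("metrics table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  # an empty flags field may round-trip through CSV as NA
  fl <- metrics$flags
  fl[is.na(fl)] <- ""
  clean <- metrics[fl == "", , drop = FALSE]
  groups <- unique(metrics[c("line", "cargo", "molecular_weight")])
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- clean$line == groups$line[g] & clean$cargo == groups$cargo[g]
    sub <- clean[sel, , drop = FALSE]
    if (!nrow(sub)) {
      warning("group ", groups$line[g], " / ", groups$cargo[g],
              " has no unflagged nuclei; row omitted")
      next
    }
    for (mk in metric_kinds) {
      v <- sub[[metric_column[[mk]]]]
      v <- v[is.finite(v)]
      if (!length(v)) next
      rows[[length(rows) + 1]] <- data.frame(
        line = groups$line[g], cargo = groups$cargo[g],
        molecular_weight = groups$molecular_weight[g], metric = mk,
        median = stats::median(v), mad = stats::mad(v), sd = stats::sd(v),
        n_cells = length(v), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Log10 cross-MW ratio table
#'
#' For every cell line, metric and ordered molecular-weight pair (high >
#' low) with both medians present, computes `log10(median_high /
#' median_low)`. Positive entries (heavier cargo larger) colour red,
#' negative blue. Zero or negative medians make the entry missing with a
#' warning.
#'
#' @param mt Median table from [population_medians()].
#' @param tolerance Log10 equality band handed to [classify_fickian()].
#' @return Data frame: `line`, `metric`, `pair`, `mw_high`, `mw_low`,
#'   `log10_ratio`, `sign_color`, `fickian_class`.
#' @export
ratio_heatmap <- function(mt, tolerance = 0.02) {
  rows <- list()
  for (line in unique(mt$line)) {
    for (mk in unique(mt$metric)) {
      sub <- mt[mt$line == line & mt$metric == mk, , drop = FALSE]
      sub <- sub[order(sub$molecular_weight), , drop = FALSE]
      if (nrow(sub) < 2) next
      for (hi in 2:nrow(sub)) {
        for (lo in 1:(hi - 1)) {
          num <- sub$median[hi]; den <- sub$median[lo]
          if (!is.finite(num) || !is.finite(den) || num <= 0 || den <= 0) {
            warning("non-positive median for ", line, " / ", mk,
                    "; ratio entry omitted")
            next
          }
          lr <- log10(num / den)
          rows[[length(rows) + 1]] <- data.frame(
            line = line, metric = mk,
            pair = paste0(sub$cargo[hi], "/", sub$cargo[lo]),
            mw_high = sub$molecular_weight[hi],
            mw_low = sub$molecular_weight[lo],
            log10_ratio = lr,
            sign_color = if (lr > 0) "red" else "blue",
            fickian_class = classify_fickian(mk, lr, tolerance),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Classify a ratio entry as Fickian or non-Fickian
#'
#' Under size-dependent (Fickian) diffusion a heavier cargo diffuses more
#' slowly, so the expected direction is: half-time ratio positive (heavier
#' = slower), max-rate ratio negative, and normalized-Y1/2 ratio negative
#' (under the assumption that packing density falls with molecule size;
#' configurable via `y_half_expect`). An entry violating the expected
#' direction, or lying within `tolerance` of zero ("equal or faster"),
#' is non-Fickian.
#'
#' @param metric One of `"t_half"`, `"y_half_normalized"`, `"max_rate"`.
#' @param log10_ratio Log10 of the high/low-MW metric ratio.
#' @param tolerance Half-width of the equality band in log10 units.
#' @param y_half_expect Expected Fickian sign of the normalized-Y1/2
#'   ratio: `"negative"` (default) or `"positive"`.
#' @return `"fickian"` or `"non_fickian"`.
#' @export
classify_fickian <- function(metric, log10_ratio, tolerance = 0.02,
                             y_half_expect = c("negative", "positive")) {
  y_half_expect <- match.arg(y_half_expect)
  if (!metric %in% metric_kinds) {
    stop("unknown metric kind: ", metric, call. = FALSE)
  }
  expected_positive <- switch(metric,
    t_half = TRUE,
    max_rate = FALSE,
    y_half_normalized = y_half_expect == "positive"
  )
  ok <- if (expected_positive) log10_ratio > tolerance
        else log10_ratio < -tolerance
  if (ok) "fickian" else "non_fickian"
}

#' Fold change of a condition relative to a control
#'
#' `ratio = mean(condition) / mean(control)` with propagated standard
#' error `|ratio| * sqrt((se_c/mean_c)^2 + (se_0/mean_0)^2)`, where
#' `se = sd / sqrt(n)`.
#'
#' @param condition,control Numeric metric samples (nonempty; control
#'   mean must be nonzero).
#' @return A `fold_change` list: `ratio`, `se`, per-sample means, ses
#'   and ns.
#' @export
fold_change_to_control <- function(condition, control) {
  condition <- condition[is.finite(condition)]
  control <- control[is.finite(control)]
  if (!length(condition) || !length(control)) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  m_c <- mean(condition); m_0 <- mean(control)
  if (m_0 == 0) stop("control mean is zero", call. = FALSE)
  se_c <- if (length(condition) > 1) stats::sd(condition) / sqrt(length(condition)) else 0
  se_0 <- if (length(control) > 1) stats::sd(control) / sqrt(length(control)) else 0
  ratio <- m_c / m_0
  se <- abs(ratio) * sqrt((se_c / m_c)^2 + (se_0 / m_0)^2)
  structure(
    list(ratio = ratio, se = se, mean_condition = m_c, mean_control = m_0,
         se_condition = se_c, se_control = se_0,
         n_condition = length(condition), n_control = length(control)),
    class = "fold_change"
  )
}

#' Render the log10 ratio heatmap
#'
#' Red tiles: heavier molecular weight larger; blue: smaller. Stars mark
#' non-Fickian entries (heavier cargo with an equal-or-faster diffusion
#' metric).
#'
#' @param rt Ratio table from [ratio_heatmap()].
#' @return A ggplot object.
#' @export
plot_ratio_heatmap <- function(rt) {
  rt$star <- ifelse(rt$fickian_class == "non_fickian", "★", "")
  lim <- max(abs(rt$log10_ratio))
  ggplot2::ggplot(rt, ggplot2::aes(x = .data$pair, y = .data$line,
                                   fill = .data$log10_ratio)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), size = 5) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim),
                                  name = "log10 ratio") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "MW pair (high/low)", y = "cell line") +
    ggplot2::theme_minimal()
}
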