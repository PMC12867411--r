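#' Quantify a factorial grid of simulated fields
#'
#' Runs [quantify_stack()] over every entry of a [make_condition_grid()]
#' result and row-binds the per-nucleus metric tables, annotated with the
#' design factors. QC uses the true cell count of each field.
#'
#' @param grid Output of [make_condition_grid()].
#' @param config [kinetics_config()] parameters.
#' @param ... Passed to [quantify_stack()].
#' @return Data frame: design columns (`line`, `cargo`,
#'   `molecular_weight`, `tissue`, `pathology`, `field`) plus the
#'   [run_experiment()] metric columns.
#' @export
grid_metrics <- function(grid, config = kinetics_config(), ...) {
  rows <- lapply(grid, function(entry) {
    q <- quantify_stack(entry$stack, cell_mask = entry$truth$cell_mask,
                        total_cells = entry$truth$n_cells, config = config,
                        override_qc = TRUE, ...)
    m <- q$metrics
    if (!nrow(m)) return(NULL)
    cbind(
      data.frame(line = entry$line, cargo = entry$cargo,
                 molecular_weight = entry$molecular_weight,
                 tissue = entry$tissue, pathology = entry$pathology,
                 field = entry$field, stringsAsFactors = FALSE),
      m
    )
  })
  do.call(rbind, rows)
}

#' Match detected nuclei to ground truth by centroid
#'
#' Greedy nearest-centroid matching within a radius, for
#' precision/recall scoring of the segmentation against the generator
#' truth.
#'
#' @param ns A `nucleus_set`.
#' @param truth A `field_truth`.
#' @param max_dist Maximum centroid distance in px for a match.
#' @return Data frame, one row per detected nucleus: `label`,
#'   `population`, `truth_id` (`NA` if unmatched), `dist`,
#'   `truth_population`, `k_per_s`, `t_half_s`.
#' @export
match_to_truth <- function(ns, truth, max_dist = 5) {
  f <- ns$features
  td <- truth$nuclei
  out <- data.frame(label = f$label, population = f$population,
                    truth_id = NA_integer_, dist = NA_real_,
                    truth_population = NA_character_,
                    k_per_s = NA_real_, t_half_s = NA_real_,
                    stringsAsFactors = FALSE)
  if (!nrow(f) || !nrow(td)) return(out)
  taken <- logical(nrow(td))
  d <- outer(f$centroid_y, td$cy, `-`)^2 + outer(f$centroid_x, td$cx, `-`)^2
  d <- sqrt(d)
  ord <- order(apply(d, 1, min))
  for (i in ord) {
    j <- which.min(ifelse(taken, Inf, d[i, ]))
    if (!is.finite(d[i, j]) || d[i, j] > max_dist || taken[j]) next
    taken[j] <- TRUE
    out$truth_id[i] <- td$nucleus_id[j]
    out$dist[i] <- d[i, j]
    out$truth_population[i] <- td$population[j]
    out$k_per_s[i] <- td$k_per_s[j]
    out$t_half_s[i] <- td$t_half_s[j]
  }
  out
}
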