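# Per-nucleus uptake traces and model-free kinetic metrics from
# polynomial fits: half-time of uptake (T1/2), peri-normalized
# half-uptake level (normalized Y1/2), and maximum uptake rate (max of
# the analytic derivative of the fitted polynomial).

#' Extract per-nucleus uptake traces
#'
#' For every nucleus with a nonempty peri-nuclear ring, computes per
#' frame the mean cargo intensity over the (optionally eroded) nucleus
#' mask and over the ring, each rescaled to \[0, 1\] by `2^bit_depth - 1`
#' (a saturated 16-bit pixel maps to exactly 1.0).
#'
#' @param stack A `timelapse_stack`.
#' @param ns A `nucleus_set` whose labels match the stack frame shape.
#' @param rings The matching `ring_set`.
#' @param erode_px Erosion of the nucleus mask before sampling (px);
#'   guards against partial-volume mixing of cytosolic signal at the mask
#'   edge. 0 uses the mask as-is. Nuclei whose eroded mask would be empty
#'   fall back to the un-eroded mask.
#' @return List of `uptake_trace` objects: `nucleus_id`, `population`,
#'   `times`, `nuclear_fi`, `peri_fi`. Nuclei with an empty ring are
#'   skipped with a warning.
#' @export
extract_traces <- function(stack, ns, rings, erode_px = 1) {
  stopifnot(inherits(stack, "timelapse_stack"), inherits(ns, "nucleus_set"),
            inherits(rings, "ring_set"))
  dm <- dim(stack$cargo)
  if (dm[2] != nrow(ns$labels) || dm[3] != ncol(ns$labels)) {
    stop("mask shape does not match stack frame shape", call. = FALSE)
  }
  denom <- 2^stack$acquisition$bit_depth - 1
  nt <- dm[1]
  flat <- matrix(stack$cargo, nrow = nt)   # frames x pixels (column-major yx)
  out <- list()
  for (i in seq_len(nrow(ns$features))) {
    id <- ns$features$label[i]
    mask <- ns$labels == id
    if (erode_px > 0) {
      er <- as.matrix(EBImage::erode(mask, disc_brush(erode_px))) > 0
      if (any(er)) mask <- er
    }
    nuc_idx <- which(mask)
    ring_idx <- which(rings$ring_labels == id)
    if (!length(ring_idx)) {
      warning("nucleus ", id, " has an empty peri-nuclear ring; trace skipped")
      next
    }
    tr <- structure(
      list(
        nucleus_id = id,
        population = ns$features$population[i],
        times = stack$times,
        nuclear_fi = rowMeans(flat[, nuc_idx, drop = FALSE]) / denom,
        peri_fi = rowMeans(flat[, ring_idx, drop = FALSE]) / denom
      ),
      class = "uptake_trace"
    )
    out[[length(out) + 1]] <- tr
  }
  out
}

#' Least-squares polynomial fit of a trace
#'
#' @param values Trace values (one per frame).
#' @param times Frame times (strictly increasing, same length).
#' @param degree Polynomial degree; needs at least `degree + 2` frames.
#'   A rank-deficient design triggers a degree reduction with a warning.
#' @return A `fitted_curve`: `degree`, `coefficients` (increasing
#'   powers), `fitted` (clipped to the observed value range to suppress
#'   end oscillation), `residual_sd`, `times`.
#' @export
fit_trace <- function(values, times, degree = 5) {
  if (length(values) != length(times)) {
    stop("values and times must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (length(values) < degree + 2) {
    stop("need at least degree + 2 frames (", degree + 2, ") for a degree-",
         degree, " fit", call. = FALSE)
  }
  # centre/scale time for conditioning; coefficients mapped back below
  ts <- (times - times[1]) / diff(range(times))
  repeat {
    X <- outer(ts, 0:degree, `^`)
    fit <- stats::lm.fit(X, values)
    if (fit$rank == ncol(X)) break
    degree <- degree - 1
    warning("rank-deficient polynomial design; reduced degree to ", degree)
    if (degree < 1) stop("cannot fit a polynomial of degree < 1", call. = FALSE)
  }
  beta_s <- fit$coefficients
  # back-transform to coefficients in t - times[1]
  span <- diff(range(times))
  beta <- beta_s / span^(0:degree)
  fitted_raw <- drop(X %*% beta_s)
  resid_sd <- stats::sd(values - fitted_raw)
  structure(
    list(
      degree = degree,
      coefficients = unname(beta),   # powers of (t - times[1])
      t0 = times[1],
      fitted = pmin(pmax(fitted_raw, min(values)), max(values)),
      residual_sd = resid_sd,
      times = times
    ),
    class = "fitted_curve"
  )
}

#' Evaluate a fitted polynomial (unclipped) at arbitrary times
#' @param fit A `fitted_curve`.
#' @param t Times in s.
#' @return Polynomial values.
#' @export
eval_poly <- function(fit, t) {
  drop(outer(t - fit$t0, seq_along(fit$coefficients) - 1, `^`) %*%
         fit$coefficients)
}

#' Evaluate the analytic derivative of a fitted polynomial
#' @param fit A `fitted_curve`.
#' @param t Times in s.
#' @return Derivative values (per s).
#' @export
eval_poly_deriv <- function(fit, t) {
  p <- seq_along(fit$coefficients) - 1
  dcoef <- (fit$coefficients * p)[-1]
  if (!length(dcoef)) return(rep(0, length(t)))
  drop(outer(t - fit$t0, seq_along(dcoef) - 1, `^`) %*% dcoef)
}

first_crossing <- function(times, values, level) {
  above <- values >= level
  if (above[1]) return(times[1])
  idx <- which(!above[-length(above)] & above[-1])
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  # linear interpolation between frames
  frac <- (level - values[i]) / (values[i + 1] - values[i])
  times[i] + frac * (times[i + 1] - times[i])
}

#' Kinetic metrics from fitted nuclear and peri-nuclear curves
#'
#' Definitions: plateau = fitted nuclear value at the final frame ("total
#' uptake"); Y1/2 = plateau / 2; T1/2 = first time the fitted nuclear
#' curve crosses Y1/2 (linear interpolation between frames); max rate =
#' maximum of the analytic derivative of the fitted polynomial over a
#' 10x-oversampled grid within the observed span; normalized Y1/2 =
#' nuclear fit at T1/2 divided by peri fit at T1/2 (time-consistent
#' reading of the peri normalization, which cancels per-cell
#' permeabilization extent).
#'
#' Flags: `no_uptake` when plateau - initial < 3 x residual sd of the
#' nuclear fit; `censored` when the curve has not plateaued (derivative
#' at the final frame > 10% of the max rate); `peri_nonpositive` when the
#' peri fit is <= 0 at T1/2 (normalized Y1/2 reported missing).
#'
#' @param nuclear_fit,peri_fit `fitted_curve` objects on the same grid.
#' @param times Acquisition time grid (defaults to the nuclear fit grid).
#' @param oversample Derivative grid refinement factor.
#' @return A `kinetic_metrics` list: `t_half`, `y_half_nuclear`,
#'   `y_half_peri`, `y_half_normalized`, `max_rate`, `plateau`, `flags`
#'   (character vector, possibly empty).
#' @export
compute_metrics <- function(nuclear_fit, peri_fit, times = nuclear_fit$times,
                            oversample = 10) {
  stopifnot(inherits(nuclear_fit, "fitted_curve"),
            inherits(peri_fit, "fitted_curve"))
  if (!isTRUE(all.equal(nuclear_fit$times, peri_fit$times))) {
    stop("nuclear and peri fits must share the acquisition grid", call. = FALSE)
  }
  flags <- character(0)
  fitted_n <- nuclear_fit$fitted
  plateau <- fitted_n[length(fitted_n)]
  y_half <- plateau / 2

  grid <- seq(min(times), max(times), length.out = oversample * length(times))
  deriv <- eval_poly_deriv(nuclear_fit, grid)
  max_rate <- max(deriv)
  if (deriv[length(deriv)] > 0.10 * max_rate) flags <- c(flags, "censored")

  initial <- fitted_n[1]
  if ((plateau - initial) < 3 * nuclear_fit$residual_sd + 1e-9) {
    flags <- c(flags, "no_uptake")
  }

  t_half <- if ("no_uptake" %in% flags) NA_real_
            else first_crossing(times, fitted_n, y_half)
  if (is.na(t_half)) flags <- unique(c(flags, if (!"no_uptake" %in% flags) "censored"))

  y_half_norm <- NA_real_
  y_half_peri <- NA_real_
  if (!is.na(t_half)) {
    nuc_at <- eval_poly(nuclear_fit, t_half)
    peri_at <- eval_poly(peri_fit, t_half)
    y_half_peri <- peri_at
    if (peri_at <= 0) {
      flags <- c(flags, "peri_nonpositive")
    } else {
      y_half_norm <- nuc_at / peri_at
    }
  }
  structure(
    list(t_half = t_half, y_half_nuclear = y_half, y_half_peri = y_half_peri,
         y_half_normalized = y_half_norm, max_rate = max_rate,
         plateau = plateau, flags = flags),
    class = "kinetic_metrics"
  )
}

#' Default kinetics configuration
#'
#' @param degree Polynomial degree of the trace fits.
#' @param erode_px Nucleus-mask erosion before trace extraction.
#' @param ring_width Peri-nuclear ring width in px.
#' @param oversample Derivative grid refinement.
#' @return Named list of parameters.
#' @export
kinetics_config <- function(degree = 5, erode_px = 1, ring_width = 3,
                            oversample = 10) {
  list(degree = degree, erode_px = erode_px, ring_width = ring_width,
       oversample = oversample)
}

#' Run the trace-fit-metrics stage for one stack
#'
#' Glue over [extract_traces()], [fit_trace()] and [compute_metrics()]
#' with QC gating: a failing permeabilization QC refuses the run unless
#' overridden.
#'
#' @param stack A `timelapse_stack`.
#' @param ns A `nucleus_set`.
#' @param rings The matching `ring_set`.
#' @param config See [kinetics_config()].
#' @param qc Optional `qc_report`; when failing and `override_qc` is
#'   `FALSE` the run stops.
#' @param override_qc Proceed despite a failing QC.
#' @return Data frame, one row per traced nucleus: `nucleus_id`,
#'   `population`, `t_half_s`, `y_half_nuclear`, `y_half_peri`,
#'   `y_half_normalized`, `max_rate_per_s`, `plateau`, `flags`
#'   (comma-collapsed, `""` when clean).
#' @export
run_experiment <- function(stack, ns, rings, config = kinetics_config(),
                           qc = NULL, override_qc = FALSE) {
  if (!is.null(qc) && !qc$pass && !override_qc) {
    stop("permeabilization QC failed (permeabilized ",
         round(100 * qc$permeabilized_fraction), "%, well-defined ",
         round(100 * qc$well_defined_fraction),
         "%); pass override_qc = TRUE to force", call. = FALSE)
  }
  traces <- extract_traces(stack, ns, rings, erode_px = config$erode_px)
  rows <- lapply(traces, function(tr) {
    nf <- fit_trace(tr$nuclear_fi, tr$times, degree = config$degree)
    pf <- fit_trace(tr$peri_fi, tr$times, degree = config$degree)
    m <- compute_metrics(nf, pf, oversample = config$oversample)
    data.frame(
      nucleus_id = tr$nucleus_id,
      population = tr$population,
      t_half_s = m$t_half,
      y_half_nuclear = m$y_half_nuclear,
      y_half_peri = m$y_half_peri,
      y_half_normalized = m$y_half_normalized,
      max_rate_per_s = m$max_rate,
      plateau = m$plateau,
      flags = paste(m$flags, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(nucleus_id = integer(0), population = character(0),
                      t_half_s = numeric(0), y_half_nuclear = numeric(0),
                      y_half_peri = numeric(0), y_half_normalized = numeric(0),
                      max_rate_per_s = numeric(0), plateau = numeric(0),
                      flags = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Segment, ring and quantify one simulated or real stack
#'
#' Convenience pipeline: preprocess the nuclear-stain frame, two-pass
#' detection, peri-nuclear rings, QC, then [run_experiment()].
#'
#' @param stack A `timelapse_stack`.
#' @param cell_mask Optional cell label matrix bounding the rings.
#' @param total_cells Total cell count for QC (defaults to the detected
#'   count, making QC trivially pass on permeabilization; supply the
#'   truth value for synthetic data).
#' @param config [kinetics_config()] parameters.
#' @param bg_radius,sigma [preprocess()] parameters.
#' @param override_qc Proceed despite failing QC.
#' @param ... Passed to [detect_nuclei_two_pass()].
#' @return List: `metrics` data frame (as [run_experiment()]), `nuclei`
#'   (`nucleus_set`), `rings`, `qc`.
#' @export
quantify_stack <- function(stack, cell_mask = NULL, total_cells = NULL,
                           config = kinetics_config(), bg_radius = 50,
                           sigma = 2, override_qc = FALSE, ...) {
  pre <- preprocess(stack$rd2, bg_radius = bg_radius, sigma = sigma)
  ns <- detect_nuclei_two_pass(pre, ...)
  rings <- make_perinuclear_ring(ns, cell_mask = cell_mask,
                                 width = config$ring_width)
  if (is.null(total_cells)) total_cells <- max(n_nuclei(ns), 1L)
  qc <- qc_permeabilization(ns, total_cells)
  metrics <- run_experiment(stack, ns, rings, config = config, qc = qc,
                            override_qc = override_qc)
  list(metrics = metrics, nuclei = ns, rings = rings, qc = qc)
}
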