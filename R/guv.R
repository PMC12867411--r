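# Giant-unilamellar-vesicle control: dye influx into a chemically
# permeabilized vesicle is protein-free membrane transport, so its
# half-time must increase monotonically with cargo size under Stokes
# scaling - the resolving-power control of the cellular assay.

#' Simulate a GUV dye-influx stack
#'
#' Single spherical vesicle imaged at a fast frame rate (25 ms default).
#' Inside intensity follows `bath * (1 - exp(-k t))` when permeabilized
#' and stays at a residual dark level otherwise; outside sits at the
#' bath level. Shot/read noise and quantization as in the cell
#' simulator.
#'
#' @param k Influx rate constant in 1/s.
#' @param acq An [acquisition_spec()] (e.g. `frame_interval = 0.025`).
#' @param radius_px Vesicle radius.
#' @param bath Outside dye level in counts.
#' @param permeabilized Logical; unpermeabilized vesicles admit no dye.
#' @param dark_level Inside level before any influx.
#' @return List: `stack` (`timelapse_stack`, single channel: `cargo`
#'   frames only), `inner_mask`, `outer_mask` (logical matrices), `k`.
#' @export
simulate_guv <- function(k, acq, radius_px = 18, bath = 12000,
                         permeabilized = TRUE, dark_level = 100) {
  stopifnot(inherits(acq, "acquisition_spec"))
  withr::with_seed(acq$seed, {
    h <- acq$image_shape[1]; w <- acq$image_shape[2]
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
    inner <- d2 <= (radius_px - 3)^2
    outer_mask <- d2 >= (radius_px + 3)^2 & d2 <= (radius_px + 9)^2
    membrane <- !inner & d2 <= radius_px^2
    times <- frame_times(acq)
    frames <- array(0, dim = c(length(times), h, w))
    for (t_i in seq_along(times)) {
      bl <- exp(-acq$bleach_rate * times[t_i])
      inside <- if (permeabilized) {
        dark_level + (bath - dark_level) * (1 - exp(-k * times[t_i]))
      } else dark_level
      fr <- matrix(bath * bl, h, w)
      fr[d2 <= radius_px^2] <- inside * bl
      fr[membrane] <- bath * 1.2 * bl   # lipid-dye rim
      frames[t_i, , ] <- add_noise(fr, acq$shot_scale, acq$read_sd,
                                   acq$bit_depth)
    }
    stack <- structure(
      list(rd2 = NULL, cargo = frames, times = times, acquisition = acq,
           metadata = list(kind = "guv", k = k, permeabilized = permeabilized,
                           seed = acq$seed)),
      class = "timelapse_stack"
    )
    list(stack = stack, inner_mask = inner, outer_mask = outer_mask, k = k)
  })
}

#' Inside/outside dye ratio trace of a GUV
#'
#' Per frame, the mean dye intensity inside the vesicle divided by the
#' mean intensity outside it; the ratio trace is then normalized to its
#' own maximum (so the normalized trace lies in \[0, 1\] with max 1).
#' Frames with a nonpositive outside mean are flagged and excluded from
#' the normalization. The literal per-frame normalization (every frame
#' divided by its own value) is available for completeness but destroys
#' the kinetics and is non-default.
#'
#' @param stack A `timelapse_stack` (cargo frames).
#' @param inner_mask,outer_mask Disjoint nonempty logical masks.
#' @param normalization `"trace_max"` (default) or `"per_frame"`.
#' @return A `guv_trace`: `times`, `inside`, `outside`, `ratio`,
#'   `normalized_ratio`, `ok` (per-frame validity).
#' @export
guv_ratio_trace <- function(stack, inner_mask, outer_mask,
                            normalization = c("trace_max", "per_frame")) {
  normalization <- match.arg(normalization)
  if (any(inner_mask & outer_mask)) stop("masks must be disjoint", call. = FALSE)
  if (!any(inner_mask) || !any(outer_mask)) {
    stop("masks must both be nonempty", call. = FALSE)
  }
  nt <- dim(stack$cargo)[1]
  flat <- matrix(stack$cargo, nrow = nt)
  inside <- rowMeans(flat[, which(inner_mask), drop = FALSE])
  outside <- rowMeans(flat[, which(outer_mask), drop = FALSE])
  ok <- outside > 0
  if (any(!ok)) warning(sum(!ok), " frame(s) with nonpositive outside mean excluded")
  ratio <- ifelse(ok, inside / outside, NA_real_)
  norm <- if (normalization == "per_frame") {
    ifelse(ok, 1, NA_real_)
  } else {
    ratio / max(ratio[ok])
  }
  structure(
    list(times = stack$times, inside = inside, outside = outside,
         ratio = ratio, normalized_ratio = norm, ok = ok),
    class = "guv_trace"
  )
}

#' Half-time of GUV dye influx
#'
#' Plateau is the median normalized ratio over the last 5% of frames;
#' the half-time is the first crossing of half-plateau, linearly
#' interpolated between frames (the convention of the cellular kinetics
#' stage). Traces whose raw inside/outside ratio never reaches
#' `min_uptake` are censored (no detectable dye entrance, as for
#' unpermeabilized vesicles).
#'
#' @param trace A `guv_trace`.
#' @param min_uptake Minimum raw plateau ratio counted as uptake.
#' @return List: `t_half` (s, `NA` when censored), `censored`, `plateau`.
#' @export
guv_t_half <- function(trace, min_uptake = 0.1) {
  stopifnot(inherits(trace, "guv_trace"))
  ok <- trace$ok
  n_tail <- max(3, ceiling(0.05 * sum(ok)))
  tail_idx <- utils::tail(which(ok), n_tail)
  plateau_raw <- stats::median(trace$ratio[tail_idx])
  if (!is.finite(plateau_raw) || plateau_raw < min_uptake) {
    return(list(t_half = NA_real_, censored = TRUE, plateau = plateau_raw))
  }
  plateau <- stats::median(trace$normalized_ratio[tail_idx])
  th <- first_crossing(trace$times[ok], trace$normalized_ratio[ok],
                       plateau / 2)
  list(t_half = th, censored = is.na(th), plateau = plateau_raw)
}
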