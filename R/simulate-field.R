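# Synthetic two-channel uptake time-lapse generator.
#
# The cargo influx model is a first-order exchange across the nuclear
# envelope, dFn/dt = k (Fperi - Fn / partition), with the peri-nuclear
# bath stepping instantaneously to the bath level at cargo addition
# (permeabilized cells are cytosol-free so dextrans equilibrate within
# seconds). Closed-form per frame:
#   Fn(t) = partition * bath * (1 - exp(-(k / partition) t))
# so the nuclear half-time is ln(2) * partition / k and the long-time
# nuclear:peri ratio is the partition coefficient.

max_count <- function(bit_depth) 2^bit_depth - 1

# Pixel indices (into an H x W matrix) of an ellipse with semi-axes a, b
# and orientation theta centred at (cy, cx). 0-based geometry on a
# (row, col) grid.
ellipse_pixels <- function(cy, cx, a, b, theta, shape) {
  h <- shape[1]; w <- shape[2]
  r0 <- max(1, floor(cy - a)); r1 <- min(h, ceiling(cy + a))
  c0 <- max(1, floor(cx - a)); c1 <- min(w, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  # outer(rows, cols) grids of rotated coordinates
  u <- outer(dy * ct, dx * st, `+`)    # dy*ct + dx*st
  v <- outer(-dy * st, dx * ct, `+`)   # -dy*st + dx*ct
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  (c0 - 1 + idx[, 2] - 1) * h + (r0 - 1 + idx[, 1])
}

# Jittered-grid placement: nuclei occupy a randomly chosen subset of
# grid slots whose pitch guarantees that cells (nucleus + cytosolic
# apron) never overlap; radii are truncated log-normal so the guarantee
# holds for every draw. Mimics a sub-confluent epithelial field.
place_nuclei <- function(n, shape, radius_mean, radius_sdlog, margin,
                         axis_ratio_max = 1.3) {
  h <- shape[1]; w <- shape[2]
  rmax <- radius_mean * exp(2.2 * radius_sdlog)
  a_max <- rmax * sqrt(axis_ratio_max)
  pitch <- 2 * (a_max + margin) + 2
  ny <- floor((h - 2) / pitch)
  nx <- floor((w - 2) / pitch)
  if (ny * nx < n) {
    stop("could not place ", n, " non-overlapping nuclei in a ",
         h, "x", w, " field (capacity ", ny * nx,
         "); reduce n_nuclei or enlarge image_shape", call. = FALSE)
  }
  oy <- (h - ny * pitch) / 2
  ox <- (w - nx * pitch) / 2
  slots <- expand.grid(iy = seq_len(ny), ix = seq_len(nx))
  pick <- slots[sample.int(nrow(slots), n), , drop = FALSE]
  jit <- max(0, pitch / 2 - a_max - margin / 2 - 1)
  r <- pmin(radius_mean * stats::rlnorm(n, 0, radius_sdlog), rmax)
  data.frame(
    cy = oy + (pick$iy - 0.5) * pitch + stats::runif(n, -jit, jit),
    cx = ox + (pick$ix - 0.5) * pitch + stats::runif(n, -jit, jit),
    r = r
  )
}

add_noise <- function(img, shot_scale, read_sd, bit_depth) {
  x <- img
  if (shot_scale > 0) {
    x <- stats::rpois(length(x), lambda = pmax(x, 0) / shot_scale) * shot_scale
  }
  if (read_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, read_sd)
  }
  x <- round(pmin(pmax(x, 0), max_count(bit_depth)))
  matrix(x, nrow = nrow(img))
}

#' Simulate a two-channel uptake field with ground truth
#'
#' Generates a field of elliptical nuclei. Permeabilized nuclei are
#' stained (bright or dim population) in the nuclear-stain channel at
#' t = 0 and take up cargo with rate `k = unit_diffusion[cargo] *
#' pore_count`; non-permeabilized cells are unstained and stay dark in
#' the cargo channel. The cytosol of permeabilized cells and the
#' extracellular space sit at the bath level from frame 0. All cargo
#' signal decays as `exp(-bleach_rate * t)`; scaled-Poisson shot noise
#' and Gaussian read noise are applied before quantization to the bit
#' depth. Deterministic for a fixed `acq$seed`.
#'
#' @param line A [cell_line_spec()].
#' @param cargo A [cargo_spec()].
#' @param acq An [acquisition_spec()].
#' @param n_nuclei Number of nuclei to place (rejection sampling;
#'   placement failure raises an error).
#' @param cell_margin Width in px of the cytosolic apron around each
#'   nucleus that forms its cell mask.
#' @param background Nuclear-stain channel background level in counts.
#' @param dark_level Cargo-channel level inside non-permeabilized cells.
#' @param axis_ratio_max Maximum ellipse major:minor axis ratio.
#' @return A list with elements `stack` (class `timelapse_stack`: `rd2`
#'   matrix, `cargo` array `[t, y, x]`, `times`, `acquisition`,
#'   `metadata`) and `truth` (class `field_truth`: per-nucleus data frame
#'   plus `cell_mask` label matrix and `n_cells`).
#' @export
simulate_field <- function(line, cargo, acq, n_nuclei = 12,
                           cell_margin = 5, background = 300,
                           dark_level = 150, axis_ratio_max = 1.3) {
  stopifnot(inherits(line, "cell_line_spec"),
            inherits(cargo, "cargo_spec"),
            inherits(acq, "acquisition_spec"))
  if (n_nuclei < 1) stop("n_nuclei must be >= 1", call. = FALSE)
  withr::with_seed(acq$seed, {
    shape <- acq$image_shape
    h <- shape[1]; w <- shape[2]
    pl <- place_nuclei(n_nuclei, shape, line$nucleus_radius_px,
                       line$nucleus_radius_sdlog, margin = cell_margin,
                       axis_ratio_max = axis_ratio_max)

    k <- influx_rate(line, cargo)
    P <- line$partition
    bath <- cargo$concentration_scale
    times <- frame_times(acq)

    nuc_px <- vector("list", n_nuclei)
    cell_mask <- matrix(0L, h, w)
    perm <- stats::runif(n_nuclei) < line$permeabilized_fraction
    bright <- stats::runif(n_nuclei) < line$well_defined_fraction
    pop <- ifelse(perm, ifelse(bright, "bright", "dim"), "none")
    stain <- numeric(n_nuclei)

    for (i in seq_len(n_nuclei)) {
      ar <- stats::runif(1, 1, axis_ratio_max)
      a <- pl$r[i] * sqrt(ar)
      b <- pl$r[i] / sqrt(ar)
      theta <- stats::runif(1, 0, pi)
      nuc_px[[i]] <- ellipse_pixels(pl$cy[i], pl$cx[i], a, b, theta, shape)
      cell_i <- ellipse_pixels(pl$cy[i], pl$cx[i], a + cell_margin,
                               b + cell_margin, theta, shape)
      cell_mask[cell_i] <- i
      lvl <- if (pop[i] == "bright") line$brightness_levels[["bright"]]
             else if (pop[i] == "dim") line$brightness_levels[["dim"]] else 0
      stain[i] <- lvl * stats::rlnorm(1, 0, 0.08)
    }

    # nuclear-stain frame at t = 0 (cargo not yet added)
    rd2 <- matrix(background, h, w)
    for (i in seq_len(n_nuclei)) {
      if (perm[i]) rd2[nuc_px[[i]]] <- stain[i]
    }
    rd2 <- add_noise(rd2, acq$shot_scale, acq$read_sd, acq$bit_depth)

    # cargo channel over time
    dark_px <- unlist(lapply(which(!perm), function(i) {
      c(which(cell_mask == i), nuc_px[[i]])
    }))
    nt <- length(times)
    cargo_frames <- array(0, dim = c(nt, h, w))
    keff <- if (P > 0) k / P else 0
    for (t_i in seq_len(nt)) {
      tt <- times[t_i]
      bl <- exp(-acq$bleach_rate * tt)
      fr <- matrix(bath * bl, h, w)
      if (length(dark_px)) fr[dark_px] <- dark_level * bl
      for (i in seq_len(n_nuclei)) {
        fn <- if (perm[i]) P * bath * (1 - exp(-keff * tt)) else dark_level
        fr[nuc_px[[i]]] <- fn * bl
      }
      cargo_frames[t_i, , ] <- add_noise(fr, acq$shot_scale, acq$read_sd,
                                         acq$bit_depth)
    }

    truth_df <- data.frame(
      nucleus_id = seq_len(n_nuclei),
      cy = pl$cy - 1, cx = pl$cx - 1,       # 0-based coordinates
      radius_px = pl$r,
      permeabilized = perm,
      population = pop,
      k_per_s = ifelse(perm, k, 0),
      t_half_s = ifelse(perm & k > 0, log(2) * P / k, NA_real_),
      plateau = ifelse(perm, P * bath, NA_real_),
      stringsAsFactors = FALSE
    )

    stack <- structure(
      list(
        rd2 = rd2,
        cargo = cargo_frames,
        times = times,
        acquisition = acq,
        metadata = list(line = line$name, cargo = cargo$name,
                        tissue = line$tissue, pathology = line$pathology,
                        molecular_weight = cargo$molecular_weight,
                        seed = acq$seed)
      ),
      class = "timelapse_stack"
    )
    truth <- structure(
      list(nuclei = truth_df, cell_mask = cell_mask, n_cells = n_nuclei),
      class = "field_truth"
    )
    list(stack = stack, truth = truth)
  })
}

#' Simulate a factorial grid of fields
#'
#' One seeded stack per (cell line, cargo, field); per-stack seeds are
#' drawn reproducibly from the master seed, so the same master seed
#' yields bit-identical stacks.
#'
#' @param lines List of [cell_line_spec()] objects (>= 1).
#' @param cargoes List of [cargo_spec()] objects (>= 1).
#' @param acq An [acquisition_spec()] template, or a function
#'   `(line, cargo) -> acquisition_spec` for cargo-dependent frame rates
#'   (the acquisition protocol of the assay images each cargo at its own
#'   interval).
#' @param n_fields Fields per (line, cargo) combination; >= 1.
#' @param master_seed Master RNG seed.
#' @param ... Passed on to [simulate_field()].
#' @return List of entries `list(line, cargo, field, stack, truth)`.
#' @export
make_condition_grid <- function(lines, cargoes, acq, n_fields,
                                master_seed = 1L, ...) {
  if (length(lines) < 1 || length(cargoes) < 1) {
    stop("need at least one cell line and one cargo", call. = FALSE)
  }
  if (n_fields < 1) stop("n_fields must be >= 1", call. = FALSE)
  n <- length(lines) * length(cargoes) * n_fields
  seeds <- withr::with_seed(as.integer(master_seed),
                            sample.int(.Machine$integer.max - 1L, n))
  out <- vector("list", n)
  idx <- 0
  for (line in lines) {
    for (cargo in cargoes) {
      a <- if (is.function(acq)) acq(line, cargo) else acq
      for (f in seq_len(n_fields)) {
        idx <- idx + 1
        a$seed <- seeds[idx]
        sim <- simulate_field(line, cargo, a, ...)
        out[[idx]] <- list(line = line$name, cargo = cargo$name, field = f,
                           molecular_weight = cargo$molecular_weight,
                           tissue = line$tissue, pathology = line$pathology,
                           stack = sim$stack, truth = sim$truth)
      }
    }
  }
  out
}

#' Acquisition matched to the expected kinetics of a condition
#'
#' Chooses a duration of `span_half_times` nuclear half-times and ~
#' `n_frames` frames, so that both fast and slow lines are resolved (the
#' imaging protocol of the assay likewise adapts the frame interval per
#' cargo).
#'
#' @param span_half_times Duration in units of the true nuclear half-time.
#' @param n_frames Approximate number of frames.
#' @param ... Overrides forwarded to [acquisition_spec()].
#' @return A function `(line, cargo) -> acquisition_spec` for use with
#'   [make_condition_grid()].
#' @export
adaptive_acquisition <- function(span_half_times = 8, n_frames = 76, ...) {
  force(span_half_times); force(n_frames)
  extra <- list(...)
  function(line, cargo) {
    k <- influx_rate(line, cargo)
    if (k <= 0) stop("adaptive acquisition needs a positive influx rate",
                     call. = FALSE)
    t_half <- log(2) * line$partition / k
    duration <- span_half_times * t_half
    args <- utils::modifyList(
      list(frame_interval = duration / (n_frames - 1), duration = duration),
      extra
    )
    do.call(acquisition_spec, args)
  }
}
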