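#' Cargo specification
#'
#' Describes a fluorescent cargo molecule used in an uptake experiment.
#' The hydrodynamic radius is derived from the molecular weight by a
#' configurable scaling law: random-coil polymers (dextrans) scale as
#' `MW^0.5`, compact globular molecules as `MW^(1/3)` (Stokes-like).
#'
#' @param name Cargo name (e.g. `"alexa488"`, `"dextran3k"`).
#' @param molecular_weight Molecular weight in Da; must be positive.
#' @param shape `"coil"` (dextran-like) or `"globular"` (free dye,
#'   peptide-like); selects the radius scaling exponent.
#' @param concentration_scale Bath fluorescence level in detector counts
#'   once the cargo is added (arbitrary fluorescence units).
#' @param radius_prefactor_nm Prefactor of the radius scaling law in nm.
#'   Defaults give realistic radii: ~0.6 nm for a ~700 Da dye,
#'   ~1.4 / ~2.6 nm for 3 / 10 kDa dextrans.
#' @return An object of class `cargo_spec`.
#' @export
cargo_spec <- function(name, molecular_weight,
                       shape = c("coil", "globular"),
                       concentration_scale = 12000,
                       radius_prefactor_nm = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(molecular_weight) || length(molecular_weight) != 1 ||
      !is.finite(molecular_weight) || molecular_weight <= 0) {
    stop("molecular_weight must be a single positive number", call. = FALSE)
  }
  if (concentration_scale <= 0) {
    stop("concentration_scale must be positive", call. = FALSE)
  }
  exponent <- if (shape == "coil") 0.5 else 1 / 3
  if (is.null(radius_prefactor_nm)) {
    radius_prefactor_nm <- if (shape == "coil") 0.0257 else 0.0664
  }
  r_h <- radius_prefactor_nm * molecular_weight^exponent
  structure(
    list(
      name = as.character(name),
      molecular_weight = molecular_weight,
      shape = shape,
      hydrodynamic_radius = r_h,
      concentration_scale = concentration_scale
    ),
    class = "cargo_spec"
  )
}

#' Default cargo set
#'
#' The three inert probes of the uptake assay: a ~700 Da free dye and
#' Alexa-labelled dextrans of 3 and 10 kDa.
#'
#' @return Named list of [cargo_spec()] objects ordered by molecular weight.
#' @export
default_cargoes <- function() {
  cs <- list(
    cargo_spec("alexa488", 700, shape = "globular"),
    cargo_spec("dextran3k", 3000, shape = "coil"),
    cargo_spec("dextran10k", 10000, shape = "coil")
  )
  names(cs) <- vapply(cs, `[[`, "", "name")
  cs
}

#' Per-pore unit-diffusion map for a cargo set
#'
#' Unit diffusion (rate contribution of a single nuclear pore, 1/s per
#' pore) follows Stokes-like scaling `UD = ud_scale / r_h`, so it strictly
#' decreases with molecular weight under the default radius law. Per-cargo
#' overrides allow injecting non-Fickian behaviour (e.g. a 10 kDa unit
#' diffusion at least as large as the 3 kDa one) for classifier testing.
#'
#' @param cargoes List of [cargo_spec()] objects.
#' @param ud_scale Scale of the law in nm/s per pore.
#' @param overrides Named numeric vector of unit-diffusion values that
#'   replace the scaling law for the named cargoes.
#' @return Named numeric vector, one rate per cargo name.
#' @export
make_ud_map <- function(cargoes, ud_scale = 2.4e-4, overrides = NULL) {
  ud <- vapply(cargoes, function(cg) ud_scale / cg$hydrodynamic_radius, 0)
  names(ud) <- vapply(cargoes, `[[`, "", "name")
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(ud))
    if (length(bad)) stop("override for unknown cargo: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    ud[names(overrides)] <- overrides
  }
  if (any(ud < 0)) stop("unit diffusion values must be >= 0", call. = FALSE)
  ud
}

#' Cell line specification
#'
#' Ground-truth generative parameters of a cell line: how many nuclear
#' pores its nuclei carry, the per-pore unit diffusion of each cargo, the
#' nuclear:cytosolic partition coefficient at equilibrium (>= 1, the
#' "molecular sink" behaviour), and permeabilization statistics.
#'
#' The influx rate constant of cargo `c` is `k = unit_diffusion[c] *
#' pore_count`.
#'
#' @param name Cell line name.
#' @param tissue `"breast"` or `"prostate"`.
#' @param pathology `"healthy"`, `"cancerous"` or `"transformed"`.
#' @param pore_count Nuclear pore count N (>= 0).
#' @param unit_diffusion Named numeric vector, cargo name -> rate per pore
#'   (1/s per pore); see [make_ud_map()].
#' @param partition Nuclear:cytosolic equilibrium ratio, >= 1.
#' @param permeabilized_fraction Fraction of cells permeabilized, in \[0,1\].
#' @param well_defined_fraction Fraction of permeabilized cells with a
#'   bright, well-defined nuclear stain, in \[0,1\].
#' @param nucleus_radius_px Mean nucleus radius in px.
#' @param nucleus_radius_sdlog Log-normal sdlog of the radius distribution.
#' @param brightness_levels Length-2 numeric `(bright, dim)` nuclear-stain
#'   intensities in counts.
#' @return An object of class `cell_line_spec`.
#' @export
cell_line_spec <- function(name,
                           tissue = c("breast", "prostate"),
                           pathology = c("healthy", "cancerous", "transformed"),
                           pore_count,
                           unit_diffusion,
                           partition = 2,
                           permeabilized_fraction = 0.75,
                           well_defined_fraction = 0.55,
                           nucleus_radius_px = 8,
                           nucleus_radius_sdlog = 0.12,
                           brightness_levels = c(bright = 28000, dim = 7000)) {
  tissue <- match.arg(tissue)
  pathology <- match.arg(pathology)
  if (pore_count < 0) stop("pore_count must be >= 0", call. = FALSE)
  if (any(unit_diffusion < 0)) stop("unit_diffusion values must be >= 0", call. = FALSE)
  if (is.null(names(unit_diffusion)) || any(!nzchar(names(unit_diffusion)))) {
    stop("unit_diffusion must be a named vector (cargo name -> rate)", call. = FALSE)
  }
  if (permeabilized_fraction < 0 || permeabilized_fraction > 1) {
    stop("permeabilized_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (well_defined_fraction < 0 || well_defined_fraction > 1) {
    stop("well_defined_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (partition < 1) stop("partition must be >= 1", call. = FALSE)
  structure(
    list(
      name = as.character(name),
      tissue = tissue,
      pathology = pathology,
      pore_count = pore_count,
      unit_diffusion = unit_diffusion,
      partition = partition,
      permeabilized_fraction = permeabilized_fraction,
      well_defined_fraction = well_defined_fraction,
      nucleus_radius_px = nucleus_radius_px,
      nucleus_radius_sdlog = nucleus_radius_sdlog,
      brightness_levels = brightness_levels
    ),
    class = "cell_line_spec"
  )
}

#' Default four-line study design
#'
#' Two tissues x two pathologies with line-specific pore counts, mirroring
#' the factorial layout of the uptake study. All lines share the default
#' Fickian unit-diffusion map, so cross-line ratiometrics are comparable.
#'
#' @param cargoes Cargo set the unit-diffusion maps are built for.
#' @return Named list of [cell_line_spec()] objects.
#' @export
default_cell_lines <- function(cargoes = default_cargoes()) {
  ud <- make_ud_map(cargoes)
  ls <- list(
    cell_line_spec("MCF10A", "breast", "healthy", pore_count = 1000,
                   unit_diffusion = ud),
    cell_line_spec("MDAMB231", "breast", "cancerous", pore_count = 1600,
                   unit_diffusion = ud),
    cell_line_spec("WPE1NA22", "prostate", "healthy", pore_count = 1300,
                   unit_diffusion = ud),
    cell_line_spec("PC3", "prostate", "cancerous", pore_count = 800,
                   unit_diffusion = ud)
  )
  names(ls) <- vapply(ls, `[[`, "", "name")
  ls
}

#' Acquisition specification
#'
#' @param frame_interval Seconds between cargo frames; > 0.
#' @param duration Total acquisition time in s; >= frame_interval. The
#'   stack holds `floor(duration / frame_interval) + 1` frames (frame 0 at
#'   cargo addition).
#' @param image_shape Length-2 integer `(height, width)` in px.
#' @param bit_depth 8, 12 or 16.
#' @param bleach_rate Photobleaching rate (1/s) applied to all cargo
#'   signal; default 0 (acquisition filters are assumed chosen to avoid
#'   measurable bleaching).
#' @param shot_scale Gain of the scaled-Poisson shot-noise model; the
#'   variance of a pixel of mean `m` counts is `shot_scale * m`. 0 disables.
#' @param read_sd Gaussian read-noise sd in counts; 0 disables.
#' @param seed Integer RNG seed for the stack.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(frame_interval, duration,
                             image_shape = c(160, 160),
                             bit_depth = 16,
                             bleach_rate = 0,
                             shot_scale = 4,
                             read_sd = 25,
                             seed = 1L) {
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (duration < frame_interval) stop("duration must be >= frame_interval", call. = FALSE)
  if (!bit_depth %in% c(8, 12, 16)) stop("bit_depth must be 8, 12 or 16", call. = FALSE)
  if (length(image_shape) != 2 || any(image_shape < 16)) {
    stop("image_shape must be two dimensions of at least 16 px", call. = FALSE)
  }
  structure(
    list(
      frame_interval = frame_interval,
      duration = duration,
      image_shape = as.integer(image_shape),
      bit_depth = as.integer(bit_depth),
      bleach_rate = bleach_rate,
      shot_scale = shot_scale,
      read_sd = read_sd,
      seed = as.integer(seed)
    ),
    class = "acquisition_spec"
  )
}

#' Acquisition presets per cargo
#'
#' Frame intervals follow the imaging protocol of the assay: free dye
#' 0.56 s over 45 s; dextrans 1.08 s over 130.26 s; the intercalating drug
#' 6.43 s over 20 min.
#'
#' @param cargo_name One of `"alexa488"`, `"dextran3k"`, `"dextran10k"`,
#'   `"dox"`.
#' @param ... Overrides passed on to [acquisition_spec()].
#' @return An [acquisition_spec()].
#' @export
default_acquisition <- function(cargo_name, ...) {
  preset <- switch(cargo_name,
    alexa488 = list(frame_interval = 0.56, duration = 45),
    dextran3k = ,
    dextran10k = list(frame_interval = 1.08, duration = 130.26),
    dox = list(frame_interval = 6.43, duration = 1200),
    stop("no acquisition preset for cargo ", cargo_name, call. = FALSE)
  )
  args <- utils::modifyList(preset, list(...))
  do.call(acquisition_spec, args)
}

#' Frame times of an acquisition
#' @param acq An [acquisition_spec()].
#' @return Numeric vector of frame times in s, starting at 0.
#' @export
frame_times <- function(acq) {
  n <- floor(acq$duration / acq$frame_interval) + 1
  (seq_len(n) - 1) * acq$frame_interval
}

#' Influx rate constant of a cargo in a cell line
#'
#' The pore-level rate is `k = unit_diffusion[cargo] * pore_count`; the
#' observable nuclear trace relaxes with effective rate `k / partition`
#' toward a plateau of `partition * bath`.
#'
#' @param line A [cell_line_spec()].
#' @param cargo A [cargo_spec()] or cargo name.
#' @return Pore-level rate constant in 1/s.
#' @export
influx_rate <- function(line, cargo) {
  nm <- if (inherits(cargo, "cargo_spec")) cargo$name else as.character(cargo)
  if (!nm %in% names(line$unit_diffusion)) {
    stop("cell line ", line$name, " has no unit diffusion for cargo ", nm,
         call. = FALSE)
  }
  unname(line$unit_diffusion[[nm]] * line$pore_count)
}
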