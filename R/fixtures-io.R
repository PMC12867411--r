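# On-disk fixtures: multi-page 16-bit TIFF per channel + CSV ground truth
# + YAML metadata sidecar. Pixel values round-trip exactly.

counts_to_unit <- function(m) m / 65535

unit_to_counts <- function(m) {
  storage.mode(m) <- "double"
  round(m * 65535)
}

#' Write a simulated field to disk
#'
#' Writes `<base>_rd2.tif` (nuclear-stain frame), `<base>_cargo.tif`
#' (multi-page cargo time series), `<base>_cellmask.tif` (cell label
#' image), `<base>_truth.csv` (per-nucleus ground truth) and
#' `<base>_meta.yaml` (acquisition parameters, axes order TCYX, seed).
#' All images are stored as 16-bit TIFF; reading the fixture back
#' reproduces the pixel values exactly.
#'
#' @param stack A `timelapse_stack` from [simulate_field()].
#' @param truth The matching `field_truth`.
#' @param base Path prefix (directory must exist and be writable).
#' @return Invisibly, the named character vector of files written.
#' @export
write_fixture <- function(stack, truth, base) {
  dir <- dirname(base)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  files <- c(
    rd2 = paste0(base, "_rd2.tif"),
    cargo = paste0(base, "_cargo.tif"),
    cellmask = paste0(base, "_cellmask.tif"),
    truth = paste0(base, "_truth.csv"),
    meta = paste0(base, "_meta.yaml")
  )
  tiff::writeTIFF(counts_to_unit(stack$rd2), files[["rd2"]],
                  bits.per.sample = 16)
  pages <- lapply(seq_len(dim(stack$cargo)[1]),
                  function(i) counts_to_unit(stack$cargo[i, , ]))
  tiff::writeTIFF(pages, files[["cargo"]], bits.per.sample = 16)
  tiff::writeTIFF(counts_to_unit(truth$cell_mask), files[["cellmask"]],
                  bits.per.sample = 16)
  utils::write.csv(truth$nuclei, files[["truth"]], row.names = FALSE)
  acq <- stack$acquisition
  yaml::write_yaml(list(
    axes = "TCYX",
    frame_interval = acq$frame_interval,
    duration = acq$duration,
    image_shape = as.integer(acq$image_shape),
    bit_depth = acq$bit_depth,
    bleach_rate = acq$bleach_rate,
    shot_scale = acq$shot_scale,
    read_sd = acq$read_sd,
    seed = acq$seed,
    n_cells = truth$n_cells,
    metadata = stack$metadata
  ), files[["meta"]])
  invisible(files)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param base Path prefix used when writing.
#' @return A list with `stack` and `truth`, equivalent to the
#'   [simulate_field()] output (pixel-exact).
#' @export
read_fixture <- function(base) {
  meta <- yaml::read_yaml(paste0(base, "_meta.yaml"))
  rd2 <- unit_to_counts(tiff::readTIFF(paste0(base, "_rd2.tif")))
  pages <- tiff::readTIFF(paste0(base, "_cargo.tif"), all = TRUE)
  cargo <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) cargo[i, , ] <- unit_to_counts(pages[[i]])
  cell_mask <- unit_to_counts(tiff::readTIFF(paste0(base, "_cellmask.tif")))
  storage.mode(cell_mask) <- "integer"
  truth_df <- utils::read.csv(paste0(base, "_truth.csv"),
                              stringsAsFactors = FALSE)
  acq <- acquisition_spec(
    frame_interval = meta$frame_interval, duration = meta$duration,
    image_shape = meta$image_shape, bit_depth = meta$bit_depth,
    bleach_rate = meta$bleach_rate, shot_scale = meta$shot_scale,
    read_sd = meta$read_sd, seed = meta$seed
  )
  stack <- structure(
    list(rd2 = rd2, cargo = cargo, times = frame_times(acq),
         acquisition = acq, metadata = meta$metadata),
    class = "timelapse_stack"
  )
  truth <- structure(
    list(nuclei = truth_df, cell_mask = cell_mask, n_cells = meta$n_cells),
    class = "field_truth"
  )
  list(stack = stack, truth = truth)
}
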