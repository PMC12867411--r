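# Nucleus segmentation from the t = 0 nuclear-stain frame: two-pass Otsu
# population capture, size/circularity constraints, peri-nuclear rings,
# permeabilization QC. Masks are label matrices, 0 = background,
# (row, col) pixel order, 0-based centroid coordinates.

disc_brush <- function(width) EBImage::makeBrush(2 * width + 1, shape = "disc")

#' Otsu threshold of a 2-D image
#'
#' Between-class-variance maximization over `levels` histogram bins
#' spanning the image range (vectorized over all candidate cuts).
#'
#' @param img 2-D numeric matrix.
#' @param levels Number of histogram bins.
#' @return Threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, levels = 256) {
  rng <- range(img)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop("degenerate image: no intensity spread", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(as.vector(img), breaks, all.inside = TRUE), 1L),
         levels),
    nbins = levels
  )
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  w1 <- 1 - w0
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  i <- which.max(bcv[-levels])
  breaks[i + 1]
}

# Crofton perimeter from directed boundary-crossing counts,
# P = (pi / 4) (n_h + n_v). A digital disk of radius 10 yields
# circularity 4*pi*A/P^2 ~ 0.92.
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  nh <- sum(abs(m[, -1] - m[, -ncol(m)]))
  nv <- sum(abs(m[-1, ] - m[-nrow(m), ]))
  (pi / 4) * (nh + nv)
}

label_features <- function(labels, population) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  if (!length(ids)) {
    return(data.frame(label = integer(0), population = character(0),
                      area_px2 = numeric(0), circularity = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0),
                      stringsAsFactors = FALSE))
  }
  feats <- lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    area <- nrow(idx)
    per <- crofton_perimeter(labels == id)
    data.frame(
      label = id,
      population = population[[as.character(id)]],
      area_px2 = area,
      circularity = 4 * pi * area / per^2,
      centroid_y = mean(idx[, 1]) - 1,
      centroid_x = mean(idx[, 2]) - 1,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, feats)
}

new_nucleus_set <- function(labels, population) {
  structure(
    list(labels = labels, population = population,
         features = label_features(labels, population)),
    class = "nucleus_set"
  )
}

#' Number of nuclei in a nucleus set
#' @param ns A `nucleus_set`.
#' @return Integer count.
#' @export
n_nuclei <- function(ns) nrow(ns$features)

#' Preprocess a nuclear-stain frame for thresholding
#'
#' Rolling-ball background subtraction (grayscale opening with a disc
#' structuring element of the given radius) followed by a Gaussian blur.
#' Output is non-negative on the input intensity scale.
#'
#' @param frame 2-D numeric image.
#' @param bg_radius Rolling-ball radius in px; 0 disables subtraction.
#' @param sigma Gaussian blur sigma in px; 0 disables blurring.
#' @return 2-D double matrix.
#' @export
preprocess <- function(frame, bg_radius = 50, sigma = 2) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("frame must be a 2-D numeric image", call. = FALSE)
  }
  x <- frame
  storage.mode(x) <- "double"
  if (bg_radius > 0) {
    # replicate-pad before the opening so border pixels are not treated
    # as a dark frame by the structuring element
    r <- bg_radius
    ri <- c(rep(1, r), seq_len(nrow(x)), rep(nrow(x), r))
    ci <- c(rep(1, r), seq_len(ncol(x)), rep(ncol(x), r))
    pad <- x[ri, ci]
    sc <- max(pad, 1)   # EBImage grayscale morphology clips to [0, 1]
    bg <- as.matrix(EBImage::opening(pad / sc, disc_brush(bg_radius))) * sc
    bg <- bg[r + seq_len(nrow(x)), r + seq_len(ncol(x))]
    x <- pmax(x - bg, 0)
  }
  if (sigma > 0) {
    x <- as.matrix(EBImage::gblur(x, sigma = sigma))
    x <- pmax(x, 0)
  }
  x
}

size_circ_filter <- function(mask, min_area, max_area, min_circularity) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(as.matrix(lab)), nrow(mask))
  ids <- setdiff(unique(as.vector(lab)), 0L)
  keep <- integer(0)
  for (id in ids) {
    obj <- lab == id
    area <- sum(obj)
    if (area < min_area || area > max_area) next
    circ <- 4 * pi * area / crofton_perimeter(obj)^2
    if (circ < min_circularity) next
    keep <- c(keep, id)
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (j in seq_along(keep)) out[lab == keep[j]] <- j
  out
}

#' Two-pass Otsu nucleus detection
#'
#' Pass 1 applies an Otsu threshold to the preprocessed frame and keeps
#' the bright, well-defined nuclei. Their (slightly dilated) footprint is
#' then set to background and Otsu is re-applied to the remainder,
#' capturing the dim nucleus population. Both passes are size- and
#' circularity-filtered; no third pass is taken (it would capture
#' background and cytosol). Dim objects must additionally clear a
#' contrast floor over the residual background so that a field with only
#' bright nuclei yields an empty second pass rather than noise blobs.
#'
#' @param img Preprocessed 2-D image (see [preprocess()]).
#' @param min_area,max_area Object area bounds in px^2.
#' @param min_circularity Minimum `4*pi*A/P^2` (Crofton perimeter).
#' @param halo_margin Dilation in px of pass-1 objects before exclusion,
#'   suppressing their blurred halos in pass 2.
#' @param min_dim_contrast Minimum (object mean - background median) /
#'   background MAD for pass-2 objects.
#' @return A `nucleus_set`: `labels` (bright objects first, then dim),
#'   `population` (label -> `"bright"`/`"dim"`), `features` data frame
#'   (label, population, area_px2, circularity, centroid_y, centroid_x).
#'   A degenerate image (<= 1 distinct value) yields zero objects with a
#'   warning, not an error.
#' @export
detect_nuclei_two_pass <- function(img, min_area = 50, max_area = 5000,
                                   min_circularity = 0.6, halo_margin = 4,
                                   min_dim_contrast = 8) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("img must be a 2-D numeric image", call. = FALSE)
  }
  empty <- function() new_nucleus_set(matrix(0L, nrow(img), ncol(img)),
                                      structure(list(), names = character(0)))
  if (length(unique(as.vector(img))) <= 1) {
    warning("degenerate image (single intensity value): no objects detected")
    return(empty())
  }

  th1 <- otsu_threshold(img)
  lab1 <- size_circ_filter(img > th1, min_area, max_area, min_circularity)
  n1 <- max(lab1)

  # second pass on the remainder, bright footprints blanked
  excl <- as.matrix(EBImage::dilate(img > th1, disc_brush(halo_margin))) > 0
  img2 <- img
  img2[excl] <- 0
  lab2 <- matrix(0L, nrow(img), ncol(img))
  if (length(unique(as.vector(img2))) > 1) {
    th2 <- otsu_threshold(img2)
    mask2 <- img2 > th2 & !excl
    lab2 <- size_circ_filter(mask2, min_area, max_area, min_circularity)
    if (max(lab2) > 0) {
      bgv <- img2[!excl & img2 <= th2]
      bg_med <- stats::median(bgv)
      bg_mad <- max(stats::mad(bgv), 1e-9)
      keep <- integer(0)
      for (id in seq_len(max(lab2))) {
        contrast <- (mean(img2[lab2 == id]) - bg_med) / bg_mad
        if (contrast >= min_dim_contrast) keep <- c(keep, id)
      }
      relab <- matrix(0L, nrow(img), ncol(img))
      for (j in seq_along(keep)) relab[lab2 == keep[j]] <- j
      lab2 <- relab
    }
  }
  n2 <- max(lab2)

  labels <- lab1
  labels[lab2 > 0] <- lab2[lab2 > 0] + n1
  pop <- c(rep("bright", n1), rep("dim", n2))
  names(pop) <- as.character(seq_len(n1 + n2))
  new_nucleus_set(labels, as.list(pop))
}

#' Filter a nucleus set on area and circularity
#'
#' Objects outside `[min_area, max_area]` or below `min_circularity` are
#' removed and the surviving labels re-compacted (population tags kept).
#'
#' @param ns A `nucleus_set`.
#' @param min_area,max_area Area bounds in px^2.
#' @param min_circularity Minimum circularity.
#' @return The filtered `nucleus_set`. The number removed is reported via
#'   `message()`.
#' @export
filter_objects <- function(ns, min_area = 50, max_area = 5000,
                           min_circularity = 0.6) {
  stopifnot(inherits(ns, "nucleus_set"))
  if (min_area > max_area) stop("min_area > max_area", call. = FALSE)
  f <- ns$features
  keep <- f$label[f$area_px2 >= min_area & f$area_px2 <= max_area &
                    f$circularity >= min_circularity]
  dropped <- nrow(f) - length(keep)
  if (dropped > 0) message("filter_objects: removed ", dropped, " of ",
                           nrow(f), " objects")
  labels <- matrix(0L, nrow(ns$labels), ncol(ns$labels))
  pop <- list()
  for (j in seq_along(keep)) {
    labels[ns$labels == keep[j]] <- j
    pop[[as.character(j)]] <- ns$population[[as.character(keep[j])]]
  }
  new_nucleus_set(labels, pop)
}

#' Peri-nuclear ring masks
#'
#' Ring i is the dilation of nucleus i by `width` px minus all nucleus
#' pixels; pixels contested by two rings are assigned to neither (keeps
#' the per-nucleus normalization unbiased); when a cell label mask is
#' given, ring i is further restricted to cell i ("just beyond the
#' nuclear boundary but still within the cell boundary"). Rings are
#' clipped at the image border.
#'
#' @param ns A `nucleus_set`.
#' @param cell_mask Optional cell label matrix (`NULL` on real data
#'   without a cell channel; the restriction is then dilation-minus-nuclei
#'   only). Each nucleus is assigned the cell label its mask
#'   majority-overlaps; nuclei outside any cell get no cell restriction.
#' @param width Ring width in px; >= 1.
#' @return A `ring_set`: `ring_labels` matrix (label i = ring of nucleus
#'   i) and `width`.
#' @export
make_perinuclear_ring <- function(ns, cell_mask = NULL, width = 3) {
  stopifnot(inherits(ns, "nucleus_set"))
  if (width < 1) stop("ring width must be >= 1", call. = FALSE)
  labels <- ns$labels
  any_nuc <- labels > 0
  ids <- ns$features$label
  claims <- matrix(0L, nrow(labels), ncol(labels))
  cand <- vector("list", length(ids))
  br <- disc_brush(width)
  for (j in seq_along(ids)) {
    id <- ids[j]
    dil <- as.matrix(EBImage::dilate(labels == id, br)) > 0
    ring <- dil & !any_nuc
    if (!is.null(cell_mask)) {
      under <- cell_mask[labels == id]
      under <- under[under > 0]
      if (length(under)) {
        cell_id <- as.integer(names(which.max(table(under))))
        ring <- ring & cell_mask == cell_id
      }
    }
    cand[[j]] <- ring
    claims <- claims + ring
  }
  ring_labels <- matrix(0L, nrow(labels), ncol(labels))
  for (j in seq_along(ids)) {
    ring_labels[cand[[j]] & claims == 1L] <- ids[j]
  }
  structure(list(ring_labels = ring_labels, width = width),
            class = "ring_set")
}

#' Permeabilization quality control
#'
#' An experiment passes QC when at least 60% of the cells are
#' permeabilized (detected, stained nuclei) and at least 30% of the
#' cells show a distinct, well-defined (bright-population) nuclear stain.
#'
#' @param ns A `nucleus_set` (all detected nuclei are stained, hence
#'   permeabilized).
#' @param total_cells Total cell count in the field (e.g. from a
#'   transmitted-light channel or simulation truth); must be >= the
#'   detected count and > 0.
#' @param min_permeabilized,min_well_defined QC thresholds.
#' @return A `qc_report` list: `pass`, `permeabilized_fraction`,
#'   `well_defined_fraction`, counts.
#' @export
qc_permeabilization <- function(ns, total_cells,
                                min_permeabilized = 0.60,
                                min_well_defined = 0.30) {
  stopifnot(inherits(ns, "nucleus_set"))
  if (length(total_cells) != 1 || total_cells <= 0) {
    stop("total_cells must be a positive count", call. = FALSE)
  }
  n_det <- n_nuclei(ns)
  if (total_cells < n_det) {
    stop("total_cells (", total_cells, ") < detected nuclei (", n_det, ")",
         call. = FALSE)
  }
  n_bright <- sum(ns$features$population == "bright")
  pf <- n_det / total_cells
  wf <- n_bright / total_cells
  structure(
    list(pass = pf >= min_permeabilized && wf >= min_well_defined,
         permeabilized_fraction = pf, well_defined_fraction = wf,
         n_detected = n_det, n_bright = n_bright,
         total_cells = as.integer(total_cells)),
    class = "qc_report"
  )
}
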