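test_that("preprocess flattens backgrounds and conserves mean when blur-only", {
  expect_error(preprocess(1:10), "2-D")
  flat <- matrix(500, 64, 64)
  expect_true(all(preprocess(flat, bg_radius = 20, sigma = 0) == 0))

  # bright disk on flat background: subtraction matches an opening oracle
  img <- matrix(100, 96, 96)
  img[disk_mask(96, 96, 48, 48, 9)] <- 5000
  out <- preprocess(img, bg_radius = 25, sigma = 0)
  # oracle: replicate-padded grayscale opening, computed directly
  ri <- c(rep(1, 25), 1:96, rep(96, 25))
  bg <- as.matrix(EBImage::opening(img[ri, ri] / 65535,
                                   EBImage::makeBrush(51, "disc"))) * 65535
  oracle <- img - bg[25 + 1:96, 25 + 1:96]
  expect_equal(out, pmax(oracle, 0))
  expect_lt(max(out[!disk_mask(96, 96, 48, 48, 12)]), 1)
  expect_gt(mean(out[disk_mask(96, 96, 48, 48, 5)]), 4000)

  # blur only conserves the mean
  set.seed(1)
  noisy <- matrix(runif(64 * 64, 100, 200), 64, 64)
  blurred <- preprocess(noisy, bg_radius = 0, sigma = 2)
  expect_equal(mean(blurred), mean(noisy), tolerance = 1e-6)
})

test_that("otsu threshold equals exhaustive between-class-variance search", {
  set.seed(42)
  img <- matrix(c(rnorm(3000, 100, 10), rnorm(1000, 500, 30)), 80, 50)
  th <- otsu_threshold(img)
  oracle <- otsu_oracle(img)
  binw <- diff(range(img)) / 256
  expect_lt(abs(th - oracle), binw + 1e-9)
  expect_gt(th, max(img[img < 200]) * 0.5); expect_lt(th, 450)
  expect_error(otsu_threshold(matrix(1, 5, 5)), "degenerate")
})

test_that("two-pass detection recovers bright and dim populations", {
  ln <- test_line(permeabilized_fraction = 1, well_defined_fraction = 0.5)
  acq <- acquisition_spec(1, 5, seed = 31)
  sim <- simulate_field(ln, test_cargoes()$alexa488, acq, n_nuclei = 10)
  ns <- detect_nuclei_two_pass(preprocess(sim$stack$rd2))
  m <- match_to_truth(ns, sim$truth)
  truth <- sim$truth$nuclei
  expect_equal(n_nuclei(ns), nrow(truth))
  expect_true(all(!is.na(m$truth_id)))
  expect_true(all(m$dist < 2))
  expect_equal(m$population, m$truth_population)
})

test_that("degenerate and single-population images are handled gracefully", {
  expect_warning(ns <- detect_nuclei_two_pass(matrix(0, 64, 64)), "degenerate")
  expect_equal(n_nuclei(ns), 0)

  # bright-only field: second pass yields no dim objects, no error
  img <- matrix(0, 128, 128)
  img[disk_mask(128, 128, 40, 40, 9)] <- 1
  img[disk_mask(128, 128, 90, 90, 9)] <- 1
  img <- preprocess(img * 20000 + matrix(rnorm(128^2, 300, 20), 128),
                    bg_radius = 0, sigma = 2)
  ns <- detect_nuclei_two_pass(img)
  expect_equal(n_nuclei(ns), 2)
  expect_true(all(ns$features$population == "bright"))
})

test_that("object filtering removes small and irregular objects", {
  img <- matrix(0, 128, 128)
  img[disk_mask(128, 128, 30, 30, 10)] <- 1      # area ~317
  img[disk_mask(128, 128, 90, 90, 3)] <- 1       # area ~29
  img[60:61, 10:120] <- 1                        # elongated bar
  lab <- matrix(0L, 128, 128)
  lab[disk_mask(128, 128, 30, 30, 10)] <- 1L
  lab[disk_mask(128, 128, 90, 90, 3)] <- 2L
  lab[60:61, 10:120] <- 3L
  ns <- nucflux:::new_nucleus_set(lab, list(`1` = "bright", `2` = "bright",
                                            `3` = "dim"))
  expect_error(filter_objects(ns, min_area = 100, max_area = 50), "min_area")
  suppressMessages(out <- filter_objects(ns, min_area = 50, max_area = 5000,
                                         min_circularity = 0.7))
  expect_equal(n_nuclei(out), 1)
  expect_equal(out$features$area_px2, sum(disk_mask(128, 128, 30, 30, 10)))

  # digital disk circularity near 1 under the Crofton perimeter
  disk_feat <- ns$features[ns$features$label == 1, ]
  nh_nv <- local({
    m <- disk_mask(128, 128, 30, 30, 10) * 1L
    pad <- matrix(0L, 130, 130); pad[2:129, 2:129] <- m
    sum(abs(pad[, -1] - pad[, -130])) + sum(abs(pad[-1, ] - pad[-130, ]))
  })
  oracle_circ <- 4 * pi * sum(disk_mask(128, 128, 30, 30, 10)) /
    ((pi / 4) * nh_nv)^2
  expect_equal(disk_feat$circularity, oracle_circ)
  expect_gt(disk_feat$circularity, 0.9)
  expect_lt(disk_feat$circularity, 1.1)

  # empty in, empty out
  empty <- nucflux:::new_nucleus_set(matrix(0L, 8, 8),
                                     structure(list(), names = character(0)))
  expect_equal(n_nuclei(filter_objects(empty)), 0)
})

test_that("peri-nuclear rings match a pixel-enumeration oracle and stay disjoint", {
  lab <- matrix(0L, 64, 64)
  lab[disk_mask(64, 64, 32, 32, 10)] <- 1L
  ns <- nucflux:::new_nucleus_set(lab, list(`1` = "bright"))
  expect_error(make_perinuclear_ring(ns, width = 0), "width")
  rs <- make_perinuclear_ring(ns, width = 3)
  dil <- as.matrix(EBImage::dilate(lab == 1, EBImage::makeBrush(7, "disc"))) > 0
  expect_equal(sum(rs$ring_labels == 1), sum(dil) - sum(lab == 1))
  expect_true(all(rs$ring_labels[lab > 0] == 0))

  # two close nuclei: rings never overlap nuclei; contested pixels dropped
  lab2 <- matrix(0L, 64, 64)
  lab2[disk_mask(64, 64, 32, 20, 8)] <- 1L
  lab2[disk_mask(64, 64, 32, 38, 8)] <- 2L
  ns2 <- nucflux:::new_nucleus_set(lab2, list(`1` = "bright", `2` = "bright"))
  rs2 <- make_perinuclear_ring(ns2, width = 3)
  expect_true(all(rs2$ring_labels[lab2 > 0] == 0))
  d1 <- as.matrix(EBImage::dilate(lab2 == 1, EBImage::makeBrush(7, "disc"))) > 0
  d2 <- as.matrix(EBImage::dilate(lab2 == 2, EBImage::makeBrush(7, "disc"))) > 0
  contested <- d1 & d2 & lab2 == 0
  expect_true(any(contested))
  expect_true(all(rs2$ring_labels[contested] == 0))

  # nucleus at the image border: ring clipped in-bounds
  lab3 <- matrix(0L, 32, 32)
  lab3[disk_mask(32, 32, 3, 16, 5)] <- 1L
  ns3 <- nucflux:::new_nucleus_set(lab3, list(`1` = "dim"))
  rs3 <- make_perinuclear_ring(ns3, width = 3)
  expect_gt(sum(rs3$ring_labels == 1), 0)
  expect_equal(dim(rs3$ring_labels), c(32L, 32L))
})

test_that("ring/nucleus disjointness holds across random fields", {
  ln <- test_line()
  for (seed in 1:12) {
    acq <- acquisition_spec(1, 4, seed = seed, image_shape = c(128, 128))
    sim <- simulate_field(ln, test_cargoes()$alexa488, acq, n_nuclei = 6)
    ns <- detect_nuclei_two_pass(preprocess(sim$stack$rd2))
    rs <- make_perinuclear_ring(ns, cell_mask = sim$truth$cell_mask)
    expect_true(all(rs$ring_labels[ns$labels > 0] == 0))
    # each ring confined to one nucleus id
    expect_true(all(rs$ring_labels %in% c(0L, ns$features$label)))
  }
})

test_that("permeabilization QC applies the 60%/30% rule", {
  lab <- matrix(0L, 64, 64)
  pop <- list()
  centers <- expand.grid(y = c(10, 30, 50), x = c(10, 30, 50))
  for (i in 1:7) {
    lab[disk_mask(64, 64, centers$y[i], centers$x[i], 4)] <- i
    pop[[as.character(i)]] <- if (i <= 4) "bright" else "dim"
  }
  ns <- nucflux:::new_nucleus_set(lab, pop)
  qc <- qc_permeabilization(ns, total_cells = 10)    # 70% perm, 40% bright
  expect_true(qc$pass)
  expect_equal(qc$permeabilized_fraction, 0.7)
  expect_equal(qc$well_defined_fraction, 0.4)
  qc2 <- qc_permeabilization(ns, total_cells = 14)   # 50% perm
  expect_false(qc2$pass)
  expect_error(qc_permeabilization(ns, total_cells = 0), "positive")
  expect_error(qc_permeabilization(ns, total_cells = 3), "<")
})
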