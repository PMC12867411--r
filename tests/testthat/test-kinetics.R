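test_that("traces rescale by the bit-depth maximum", {
  # 16-bit: a saturated pixel maps to exactly 1.0; uniform 13107 to 0.2
  ln <- test_line()
  acq <- noiseless_acq(1, 6, seed = 2, image_shape = c(96, 96))
  sim <- simulate_field(ln, test_cargoes()$alexa488, acq, n_nuclei = 3)
  nt <- dim(sim$stack$cargo)[1]
  sim$stack$cargo <- array(13107, dim = dim(sim$stack$cargo))
  ns <- detect_nuclei_two_pass(preprocess(sim$stack$rd2))
  rs <- make_perinuclear_ring(ns)
  traces <- extract_traces(sim$stack, ns, rs)
  expect_gt(length(traces), 0)
  for (tr in traces) {
    expect_equal(tr$nuclear_fi, rep(0.2, nt))
    expect_equal(tr$peri_fi, rep(0.2, nt))
  }
  sim$stack$cargo <- array(65535, dim = dim(sim$stack$cargo))
  tr <- extract_traces(sim$stack, ns, rs)[[1]]
  expect_identical(unique(tr$nuclear_fi), 1)
  sim$stack$cargo <- array(0, dim = dim(sim$stack$cargo))
  tr <- extract_traces(sim$stack, ns, rs)[[1]]
  expect_true(all(tr$nuclear_fi == 0))
})

test_that("trace extraction validates shapes and skips ringless nuclei", {
  ln <- test_line()
  acq <- acquisition_spec(1, 5, seed = 2, image_shape = c(96, 96))
  sim <- simulate_field(ln, test_cargoes()$alexa488, acq, n_nuclei = 3)
  ns <- detect_nuclei_two_pass(preprocess(sim$stack$rd2))
  rs <- make_perinuclear_ring(ns)
  bad <- sim$stack
  bad$cargo <- bad$cargo[, 1:50, , drop = FALSE]
  expect_error(extract_traces(bad, ns, rs), "shape")
  rs_empty <- rs
  rs_empty$ring_labels[] <- 0L
  expect_warning(tr <- extract_traces(sim$stack, ns, rs_empty), "empty")
  expect_length(tr, 0)
})

test_that("polynomial fits interpolate low-degree data and match an lm oracle", {
  t <- seq(0, 10, by = 0.5)
  y <- 2 + 0.3 * t - 0.01 * t^2
  fit <- fit_trace(y, t, degree = 5)
  expect_equal(fit$fitted, y, tolerance = 1e-9)

  yc <- rep(3, length(t))
  fitc <- fit_trace(yc, t, degree = 3)
  expect_equal(fitc$fitted, yc, tolerance = 1e-9)
  expect_equal(fitc$residual_sd, 0, tolerance = 1e-9)

  # noiseless saturating curve, protocol sampling: close fit, oracle agreement
  t2 <- seq(0, 45, by = 0.56)
  y2 <- 1 - exp(-0.1 * t2)
  fit2 <- fit_trace(y2, t2, degree = 5)
  expect_lt(max(abs(fit2$fitted - y2)), 0.01)
  or <- stats::lm(y2 ~ stats::poly(t2, 5, raw = TRUE))
  expect_equal(fit2$fitted, pmin(pmax(unname(stats::fitted(or)), min(y2)), max(y2)),
               tolerance = 1e-6)

  expect_error(fit_trace(y2[1:4], t2[1:4], degree = 5), "degree \\+ 2")
  expect_error(fit_trace(c(1, 2), c(1, 1)), "increasing")
})

test_that("metrics recover closed-form half-time and max rate", {
  t <- seq(0, 45, by = 0.56)
  y <- 1 - exp(-0.1 * t)
  nf <- fit_trace(y, t, degree = 5)
  pf <- fit_trace(rep(1, length(t)), t, degree = 5)
  m <- compute_metrics(nf, pf)
  expect_equal(m$t_half, log(2) / 0.1, tolerance = 0.05)
  expect_equal(m$max_rate, 0.1 * m$plateau, tolerance = 0.05)
  expect_false("no_uptake" %in% m$flags)

  # identical nuclear and peri traces: normalized Y1/2 is exactly 1
  m2 <- compute_metrics(nf, nf)
  expect_equal(m2$y_half_normalized, 1, tolerance = 1e-9)

  # flat trace flags no_uptake with a missing half-time
  nf0 <- fit_trace(rep(0.01, length(t)), t, degree = 5)
  m3 <- compute_metrics(nf0, pf)
  expect_true("no_uptake" %in% m3$flags)
  expect_true(is.na(m3$t_half))

  # curve still rising at the end is censored
  yr <- t / 45
  m4 <- compute_metrics(fit_trace(yr, t, degree = 5), pf)
  expect_true("censored" %in% m4$flags)
})

test_that("steady-state nuclear:peri ratio recovers the partition coefficient", {
  ln <- test_line(k_alexa = 0.5, partition = 2, permeabilized_fraction = 1)
  acq <- noiseless_acq(0.5, 40, seed = 8)
  sim <- simulate_field(ln, test_cargoes()$alexa488, acq, n_nuclei = 4)
  q <- quantify_stack(sim$stack, cell_mask = sim$truth$cell_mask,
                      total_cells = sim$truth$n_cells, override_qc = TRUE)
  # long-time fitted nuclear plateau over the (flat) peri level = partition
  expect_equal(mean(q$metrics$plateau / q$metrics$y_half_peri), 2,
               tolerance = 0.05)
})

test_that("pipeline recovers half-times within 10% and flags dark fields", {
  ln <- test_line(k_alexa = 0.25, partition = 1, permeabilized_fraction = 1)
  acqf <- adaptive_acquisition(seed = 17)
  acq <- acqf(ln, test_cargoes()$alexa488)
  acq$seed <- 17L
  sim <- simulate_field(ln, test_cargoes()$alexa488, acq, n_nuclei = 10)
  q <- quantify_stack(sim$stack, cell_mask = sim$truth$cell_mask,
                      total_cells = sim$truth$n_cells)
  expect_equal(nrow(q$metrics), sum(sim$truth$nuclei$permeabilized))
  rel <- q$metrics$t_half_s / (log(2) / 0.25) - 1
  expect_lt(stats::median(abs(rel)), 0.10)

  # unpermeabilized field, QC overridden: every row flagged no_uptake
  ln0 <- test_line(permeabilized_fraction = 0)
  sim0 <- simulate_field(ln0, test_cargoes()$alexa488,
                         acquisition_spec(0.56, 20, seed = 4), n_nuclei = 6)
  pre <- preprocess(sim0$stack$rd2)
  ns0 <- detect_nuclei_two_pass(pre)   # nothing stained: no nuclei detected
  expect_equal(n_nuclei(ns0), 0)
})

test_that("QC gating refuses failing runs unless overridden", {
  ln <- test_line(permeabilized_fraction = 1, well_defined_fraction = 1)
  acq <- acquisition_spec(0.56, 30, seed = 6)
  sim <- simulate_field(ln, test_cargoes()$alexa488, acq, n_nuclei = 6)
  pre <- preprocess(sim$stack$rd2)
  ns <- detect_nuclei_two_pass(pre)
  rs <- make_perinuclear_ring(ns)
  qc_bad <- qc_permeabilization(ns, total_cells = n_nuclei(ns) * 3)
  expect_false(qc_bad$pass)
  expect_error(run_experiment(sim$stack, ns, rs, qc = qc_bad), "QC failed")
  tab <- run_experiment(sim$stack, ns, rs, qc = qc_bad, override_qc = TRUE)
  expect_equal(nrow(tab), n_nuclei(ns))
})

test_that("doubling the pore count halves T1/2 and doubles the max rate", {
  cg <- test_cargoes()$alexa488
  acqf <- adaptive_acquisition()
  med <- function(pores, seed) {
    ln <- test_line(k_alexa = 0.1 * pores / 1000, pore_count = pores,
                    partition = 1, permeabilized_fraction = 1)
    a <- acqf(ln, cg); a$seed <- seed
    sim <- simulate_field(ln, cg, a, n_nuclei = 10)
    q <- quantify_stack(sim$stack, cell_mask = sim$truth$cell_mask,
                        total_cells = sim$truth$n_cells, override_qc = TRUE)
    c(t_half = stats::median(q$metrics$t_half_s),
      rate = stats::median(q$metrics$max_rate_per_s))
  }
  m1 <- med(1000, 101); m2 <- med(2000, 102)
  expect_equal(m1[["t_half"]] / m2[["t_half"]], 2, tolerance = 0.10)
  expect_equal(m2[["rate"]] / m1[["rate"]], 2, tolerance = 0.10)
})

test_that("peri normalization cancels the extent of permeabilization", {
  # scaling bath and nuclear signal by a common per-cell factor leaves
  # normalized Y1/2 unchanged
  ln <- test_line(k_alexa = 0.3, partition = 2, permeabilized_fraction = 1)
  cg <- test_cargoes()$alexa488
  acq <- acquisition_spec(0.56, 45, seed = 55)
  run_scaled <- function(scale) {
    cgs <- cargo_spec(cg$name, cg$molecular_weight, shape = cg$shape,
                      concentration_scale = cg$concentration_scale * scale)
    sim <- simulate_field(ln, cgs, acq, n_nuclei = 10)
    q <- quantify_stack(sim$stack, cell_mask = sim$truth$cell_mask,
                        total_cells = sim$truth$n_cells, override_qc = TRUE)
    stats::median(q$metrics$y_half_normalized, na.rm = TRUE)
  }
  y1 <- run_scaled(1)
  y2 <- run_scaled(0.55)
  expect_lt(abs(y2 / y1 - 1), 0.02)
})

test_that("half-times rise and max rates fall with MW under Fickian defaults", {
  ln <- test_line(k_alexa = 0.4, partition = 1, permeabilized_fraction = 1)
  acqf <- adaptive_acquisition()
  meds <- lapply(test_cargoes(), function(cg) {
    a <- acqf(ln, cg); a$seed <- 7L + round(cg$molecular_weight)
    sim <- simulate_field(ln, cg, a, n_nuclei = 10)
    q <- quantify_stack(sim$stack, cell_mask = sim$truth$cell_mask,
                        total_cells = sim$truth$n_cells, override_qc = TRUE)
    c(t = stats::median(q$metrics$t_half_s),
      r = stats::median(q$metrics$max_rate_per_s))
  })
  t_half <- vapply(meds, `[[`, 0, "t")
  rate <- vapply(meds, `[[`, 0, "r")
  expect_true(all(diff(t_half) > 0))
  expect_true(all(diff(rate) < 0))
})
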