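# Shared fixtures: small, fast synthetic conditions used across tests.

test_cargoes <- function() default_cargoes()

# single-line spec with controllable kinetics and populations
test_line <- function(k_alexa = 0.4, pore_count = 1000, partition = 2,
                      permeabilized_fraction = 0.8,
                      well_defined_fraction = 0.6, ...) {
  cargoes <- test_cargoes()
  ud_scale <- k_alexa * cargoes$alexa488$hydrodynamic_radius / pore_count
  cell_line_spec("testline", "breast", "healthy", pore_count = pore_count,
                 unit_diffusion = make_ud_map(cargoes, ud_scale = ud_scale),
                 partition = partition,
                 permeabilized_fraction = permeabilized_fraction,
                 well_defined_fraction = well_defined_fraction, ...)
}

noiseless_acq <- function(frame_interval, duration, seed = 1L, ...) {
  acquisition_spec(frame_interval, duration, shot_scale = 0, read_sd = 0,
                   seed = seed, ...)
}

# analytic nuclear trace of the exchange model, rescaled units
model_trace <- function(t, k, partition = 1, bath = 12000, bleach = 0) {
  partition * bath * (1 - exp(-(k / partition) * t)) * exp(-bleach * t) / 65535
}

# exhaustive between-class-variance Otsu oracle over binned levels
otsu_oracle <- function(img, levels = 256) {
  rng <- range(img)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- hist(as.vector(img), breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; best_t <- NA
  for (i in 1:(levels - 1)) {
    w0 <- sum(p[1:i]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:i] * mids[1:i]) / w0
    mu1 <- sum(p[(i + 1):levels] * mids[(i + 1):levels]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- breaks[i + 1] }
  }
  best_t
}

# digital disk mask
disk_mask <- function(h, w, cy, cx, r) {
  outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`) <= r^2
}
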