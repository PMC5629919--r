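# shared in-code fixtures: small montages, protocols and sessions

full_montage <- function(sources, detectors, distance_cm = 3.0) {
  montage(as.matrix(expand.grid(detector = detectors, source = sources))[, 2:1],
          distance_cm = distance_cm)
}

two_block_protocol <- function(fs = 7.8125, total = 120) {
  protocol(fs, list(
    a = rbind(c(10, 20), c(60, 70)),
    b = rbind(c(35, 45), c(85, 95))
  ), total)
}

# a small noisy multi-channel regression problem with known coefficients
sim_glm_problem <- function(n_channels = 5, fs = 7.8125, total = 120,
                            noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  p <- two_block_protocol(fs, total)
  X <- build_design(p)
  B <- matrix(stats::rnorm(ncol(X) * n_channels), ncol(X), n_channels)
  Y <- X %*% B + matrix(stats::rnorm(nrow(X) * n_channels, sd = noise_sd),
                        nrow(X), n_channels)
  list(protocol = p, X = X, B = B, Y = Y)
}

# concentration runs for classifier tests: convert a simulated session's
# raw intensities back through the MBLL stage
session_runs <- function(sess) {
  lapply(sess$runs, function(r) {
    conv <- stream_convert(r$raw, montage = sess$montage)
    list(hbo = conv$hbo, hb = conv$hb, protocol = r$protocol)
  })
}
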