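# Shared fixtures: everything is generated in code at test time.

hs_wl33 <- seq(400, 720, 10)

# small scene for fast unit tests
tiny_scene <- function(seed = 42, dim = c(64, 96), ...) {
  synthetic_scene(seed = seed, dim = dim, ...)
}

# a noiseless, spatially uniform scene (symmetric by construction)
symmetric_scene <- function(seed = 7, dim = c(96, 128)) {
  synthetic_scene(seed = seed, dim = dim, het_amplitude = 0,
                  gain_amplitude = 0, read_sigma = 0, shot_scale = 0)
}

random_spectrum <- function(n = 31, wl = seq(400, 700, 10), kind = "reflectance") {
  spectrum(wl[seq_len(n)], runif(n, 0.05, 0.9), kind)
}

random_lab_cloud <- function(n, spread = 10) {
  tibble::tibble(L = runif(n, 20, 90),
                 a = rnorm(n, 10, spread),
                 b = rnorm(n, 15, spread))
}

# independent piecewise-linear interpolation oracle
interp_oracle <- function(wl, v, t) {
  vapply(t, function(x) {
    i <- max(which(wl <= x + 1e-12))
    if (i == length(wl)) return(v[i])
    v[i] + (x - wl[i]) / (wl[i + 1] - wl[i]) * (v[i + 1] - v[i])
  }, numeric(1))
}
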