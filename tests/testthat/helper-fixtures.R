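# Shared fixtures: small geometries, fast parameter variants, and a
# memoised full-scale fidelity sweep reused by several test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Frozen-gating RyR parameters: channels never change state, so the forced
# channel stays open and field dynamics are deterministic.
frozen_ryr_params <- function() {
  p <- default_params()
  p$ryr$kplus_max <- 0
  p$ryr$kminus <- 0
  p
}

# Buffer-free transport configuration for pure-diffusion checks.
no_buffer_params <- function() {
  p <- default_params()
  for (nm in names(p$buffers)) p$buffers[[nm]]$b_total <- 0
  p
}

# Reduced-scale fidelity sweep at saturating IP3 (the trend experiment):
# 50-RyR checkerboard, 50 trials per condition, full 200-ms trials.
trend_sweep <- function() {
  memo("trend_sweep", {
    run_fidelity_sweep(n_ip3r = c(0, 2, 5, 10), ip3 = 10, n_trials = 50,
                       n_ryr = 50, duration = 200, base_seed = 20)
  })
}

# Random small geometry for cluster-statistics oracles.
random_geometry <- function(n, nx = 20, ny = 20, seed = 1) {
  set.seed(seed)
  cells <- sample.int(nx * ny, n)
  ix <- (cells - 1L) %% nx + 1L
  iy <- (cells - 1L) %/% nx + 1L
  g <- make_checkerboard(0)
  g$nx <- as.integer(nx); g$ny <- as.integer(ny)
  g$sites <- data.frame(kind = "RYR", ix = ix, iy = iy)
  g
}
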