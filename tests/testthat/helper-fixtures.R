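# shared fixture builders; everything is generated in code at test time

# von Mises sampler (Best & Fisher rejection scheme) for circular power tests
rvonmises <- function(n, mu = 0, kappa = 1) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1
      out[i] <- sign(u[3] - 0.5) * acos(f) + mu
    }
  }
  wrap_phase(out)
}

# tiny two-electrode session with a single planted directed edge
coupled_pair_config <- function(seed, gain = 1.5, n_trials = 10,
                                n_scenes = 10, ...) {
  synth_config(n_rows = 1, n_cols = 2, spacing_mm = 1, phase_noise_sd = 0.3,
               coupling_edges = data.frame(sender = 1, receiver = 2,
                                           gain = gain, lag_ms = 10),
               n_trials = n_trials, n_scenes = n_scenes, seed = seed, ...)
}

# brute-force conditional MI oracle: direct evaluation of
# sum p(x,y,z) log2[ p(x,y|z) / (p(x|z) p(y|z)) ] over all cells
cmi_oracle <- function(xs, ys, zs) {
  n <- length(xs)
  lev <- function(v) sort(unique(v))
  total <- 0
  for (z in lev(zs)) {
    iz <- zs == z
    pz <- sum(iz) / n
    for (x in lev(xs)) {
      for (y in lev(ys)) {
        pxyz <- sum(iz & xs == x & ys == y) / n
        if (pxyz == 0) next
        px_z <- sum(iz & xs == x) / sum(iz)
        py_z <- sum(iz & ys == y) / sum(iz)
        pxy_z <- pxyz / pz
        total <- total + pxyz * log2(pxy_z / (px_z * py_z))
      }
    }
  }
  total
}
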