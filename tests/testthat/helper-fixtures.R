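# Shared fixtures. Heavy relaxed-network states are built once per test run
# and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

# Desk-scale relaxed network: 300 neurons, 600 s of relaxation.
relaxed_state <- function(M = 3) {
  key <- paste0("relaxed_M", M)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- prepare_relaxed_network(
      N = 300, M = M, relax_s = 600, seed = 1, quiet = TRUE)
  }
  .fixture_cache[[key]]
}

# Tiny all-to-all network for mechanistic simulator tests.
tiny_network <- function(N = 2, p_conn = 1, kappa = 8, f_noise = 0,
                         kappa_noise = 0, M = 1, seed = 7,
                         np = neuron_parameters()) {
  build_network(np, network_config(N = N, p_conn = p_conn, kappa = kappa,
                                   f_noise = f_noise,
                                   kappa_noise = kappa_noise, M = M), seed)
}

# Random sub-normalised conditional ISI chain on a coarse grid. lam1 is
# normalised (every cycle has at least one spike), matching the
# stimulation-controlled regime the theory's cycle-boundary term assumes.
random_isi_chain <- function(f = 50, bin = 0.2, max_order = 3, seed = 1) {
  set.seed(seed)
  nb <- round(1000 / f / bin)
  lam1 <- stats::runif(nb)^3
  lam1 <- lam1 / sum(lam1)
  lam <- vector("list", max_order)
  for (l in 2:max_order) {
    m <- matrix(0, nb, nb)
    for (x in seq_len(nb)) {
      if (x + 5 > nb) next
      v <- stats::runif(nb)^4
      v[seq_len(5)] <- 0                 # refractory gap of 1 ms
      v[(nb - x + 1):nb] <- 0            # keep the next spike inside the cycle
      s <- sum(v)
      if (s > 0) m[, x] <- v / s * stats::runif(1, 0.2, 0.9)
    }
    lam[[l]] <- m
  }
  isi_densities(f, bin, lam1, lam)
}

# Point-mass densities: every cycle has exactly one spike in bin `b`.
point_mass_isi <- function(f = 10, bin = 0.2, b = 51) {
  nb <- round(1000 / f / bin)
  lam1 <- numeric(nb)
  lam1[b] <- 1
  isi_densities(f, bin, lam1)
}
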