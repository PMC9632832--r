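test_that("degenerate deterministic responses give point-mass densities", {
  # every neuron fires exactly once, 2 ms after each onset
  f <- 5; T_ms <- 200
  onsets <- seq(0, 4800, by = T_ms)
  spikes <- data.frame(
    neuron = rep(1:4, each = length(onsets)),
    time = rep(onsets + 2, times = 4))
  isi <- estimate_isi_densities(spikes, onsets, f)
  b2 <- floor(2 / 0.2)  # 0-based bin 10
  expect_equal(sum(isi$lam1), 1)
  expect_equal(isi$lam1[b2 + 1], 1)
  expect_equal(isi$max_spikes, 1L)
  expect_equal(isi$mean_spikes_per_cycle, 1)
  std <- spike_time_densities(isi)
  expect_equal(std$P_k, 1)
  expect_equal(std$P_0, 0)
  expect_equal(std$Lambda_last, isi$lam1)

  # two-spike deterministic response at 2 and 6 ms
  spikes2 <- rbind(spikes,
                   data.frame(neuron = rep(1:4, each = length(onsets)),
                              time = rep(onsets + 6, times = 4)))
  isi2 <- estimate_isi_densities(spikes2, onsets, f)
  std2 <- spike_time_densities(isi2)
  expect_equal(isi2$max_spikes, 2L)
  b6 <- floor(6 / 0.2)
  expect_equal(std2$Lambda[b6 + 1, 2], 1)     # second spike at 6 ms
  expect_equal(std2$P_k, c(0, 1))
  expect_equal(std2$Lambda_last[b6 + 1], 1)
  # F_k monotone with total mass P(>=k)
  expect_true(all(diff(std2$F_k[, 1]) >= 0))
  expect_equal(std2$F_k[isi2$nb, 2], 1)
})

test_that("no spikes at all yield the empty response", {
  isi <- estimate_isi_densities(data.frame(neuron = integer(0),
                                           time = numeric(0)),
                                onsets = c(0, 200), f = 5, neurons = 1:3)
  expect_equal(sum(isi$lam1), 0)
  expect_equal(isi$mean_spikes_per_cycle, 0)
  std <- spike_time_densities(isi)
  expect_equal(std$P_0, 1)
})

test_that("generator and estimator are inverse on the discrete grid", {
  isi <- random_isi_chain(f = 50, max_order = 3, seed = 4)
  trains <- generate_locked_trains(isi, n_neurons = 40, n_cycles = 400,
                                   seed = 11)
  onsets <- seq(0, by = 20, length.out = 400)
  est <- estimate_isi_densities(trains, onsets, f = 50)
  # first-spike mass recovered in total variation
  tv1 <- 0.5 * sum(abs(est$lam1 - isi$lam1))
  expect_lt(tv1, 0.05)
  # conditional second-order masses recovered where the conditioning bin
  # was visited often
  cnt <- est$counts[[2]]
  busy <- which(cnt > 200)
  expect_gt(length(busy), 0)
  for (x in busy) {
    tv <- 0.5 * sum(abs(est$lam[[2]][, x] - isi$lam[[2]][, x]))
    expect_lt(tv, 0.15)
  }
})

test_that("sub-normalised continuation mass controls the multi-spike
           fraction", {
  f <- 50; nb <- 100
  lam1 <- numeric(nb); lam1[11] <- 1
  lam2 <- matrix(0, nb, nb)
  lam2[20, 11] <- 0.3                  # 30% of cycles get a second spike
  isi <- isi_densities(f, 0.2, lam1, list(NULL, lam2))
  std <- spike_time_densities(isi)
  expect_equal(std$P_k, c(0.7, 0.3))
  trains <- generate_locked_trains(isi, 1, 4000, seed = 3)
  frac2 <- mean(table(trains$cycle) == 2)
  expect_lt(abs(frac2 - 0.3), 4 * sqrt(0.3 * 0.7 / 4000))
  # point-mass chain: every cycle identical pattern
  lam2b <- matrix(0, nb, nb); lam2b[20, 11] <- 1
  isib <- isi_densities(f, 0.2, lam1, list(NULL, lam2b))
  tr <- generate_locked_trains(isib, 1, 50, seed = 5)
  expect_true(all(table(tr$cycle) == 2))
  expect_equal(unique(round(tr$time %% 20, 3)), c(2.1, 6.1))
})

test_that("probability is conserved and last-spike law matches Monte Carlo", {
  isi <- random_isi_chain(f = 50, max_order = 4, seed = 8)
  std <- spike_time_densities(isi)
  expect_equal(sum(std$P_k) + std$P_0, 1, tolerance = 1e-9)
  # Lambda_k integrates to P(>= k)
  for (k in seq_along(std$P_k)) {
    expect_equal(sum(std$Lambda[, k]), sum(std$P_k[k:length(std$P_k)]),
                 tolerance = 1e-9)
  }
  expect_equal(sum(std$Lambda_last), 1 - std$P_0, tolerance = 1e-9)

  # Monte-Carlo check of P(k) and the last-spike histogram
  n_mc <- 20000
  tr <- generate_locked_trains(isi, 1, n_mc, seed = 21)
  cnt <- table(factor(tabulate(tr$cycle, nbins = n_mc),
                      levels = 0:length(std$P_k)))
  p_mc <- as.numeric(cnt) / n_mc
  for (k in seq_along(std$P_k)) {
    p <- std$P_k[k]
    expect_lt(abs(p_mc[k + 1] - p), 4 * sqrt(p * (1 - p) / n_mc) + 1e-12)
  }
  last <- tapply(tr$time %% 20, tr$cycle, max)
  last_bin <- floor(last / 0.2)
  h_mc <- tabulate(last_bin + 1L, nbins = isi$nb) / n_mc
  # total variation between empirical and analytic last-spike laws
  expect_lt(0.5 * sum(abs(h_mc - std$Lambda_last)), 0.05)
})

test_that("mean spikes per ISI counts within-cycle spikes only", {
  onsets <- c(0, 200, 400)
  spikes <- data.frame(neuron = c(1, 1, 2, 2, 2),
                       time = c(10, 210, 50, 250, 450))
  expect_equal(mean_spikes_per_isi(spikes, onsets, neurons = 1:2), 5 / 6)
  expect_error(mean_spikes_per_isi(spikes, numeric(0)), "onset")
})
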