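test_that("point-mass densities reproduce the two-pairing closed form", {
  stdp <- stdp_parameters()
  f <- 10; T_ms <- 100
  isi <- point_mass_isi(f = f, b = 51)
  for (phi in c(0.03, 0.2, 0.5, 0.77)) {
    for (xi in c(3, 0, -2)) {
      r <- mean_rate_of_weight_change(phi, f, xi, isi, stdp)
      # one pre and one post spike per cycle: the post pairs with the
      # nearest earlier pre arrival (lag dt+) and the pre with the nearest
      # earlier post arrival (lag dt+ - T)
      dtp <- (phi * T_ms - xi) %% T_ms
      if (dtp == 0) dtp <- T_ms
      J_closed <- f * (stdp_function(dtp, stdp) +
                       stdp_function(dtp - T_ms, stdp))
      expect_equal(r$J, J_closed, tolerance = 1e-12)
      expect_equal(r$J, f * (r$W_plus + r$W_minus))
    }
  }
})

test_that("null STDP and empty densities give zero rate", {
  f <- 10
  isi <- point_mass_isi(f = f)
  r <- mean_rate_of_weight_change(0.3, f, 3, isi, stdp_parameters(eta = 0))
  expect_equal(r$J, 0)
  expect_equal(per_cycle_update_positive(1, 0.3, f, 3, isi,
                                         stdp_parameters(eta = 0)), 0)
  empty <- isi_densities(f, 0.2, numeric(500))
  expect_equal(mean_rate_of_weight_change(0.3, f, 3, empty,
                                          stdp_parameters())$J, 0)
})

test_that("rate is linear in eta and periodic in the phase lag", {
  isi <- random_isi_chain(f = 50, seed = 2)
  J1 <- mean_rate_of_weight_change(0.37, 50, 3, isi, stdp_parameters())$J
  J2 <- mean_rate_of_weight_change(0.37, 50, 3, isi,
                                   stdp_parameters(eta = 0.04))$J
  expect_equal(J2, 2 * J1, tolerance = 1e-12)
  Jp <- mean_rate_of_weight_change(1.37, 50, 3, isi, stdp_parameters())$J
  expect_equal(Jp, J1, tolerance = 1e-9)
})

test_that("swapping phi -> 1 - phi and xi -> -xi negates the pairing lags
           for point masses", {
  stdp <- stdp_parameters()
  f <- 10; T_ms <- 100
  isi <- point_mass_isi(f = f, b = 51)
  for (phi in c(0.13, 0.4)) {
    for (xi in c(2, -1)) {
      a <- mean_rate_of_weight_change(phi, f, xi, isi, stdp)
      b <- mean_rate_of_weight_change((1 - phi) %% 1, f, -xi, isi, stdp)
      dtp_a <- (phi * T_ms - xi) %% T_ms        # a's positive pairing lag
      # b's lag set is the negation of a's: {T - dtp_a, -dtp_a}
      expect_equal(b$W_plus, stdp_function(T_ms - dtp_a, stdp),
                   tolerance = 1e-12)
      expect_equal(b$W_minus, stdp_function(-dtp_a, stdp),
                   tolerance = 1e-12)
      expect_equal(a$W_plus, stdp_function(dtp_a, stdp), tolerance = 1e-12)
    }
  }
})

test_that("theory matches the Monte-Carlo pairing oracle on random density
           chains", {
  stdp <- stdp_parameters()
  worst_z <- 0
  for (q in 1:20) {
    isi <- random_isi_chain(f = 50, max_order = 3, seed = 100 + q)
    set.seed(q)
    phi <- runif(1)
    xi <- sample(c(0, 3, -1), 1)
    J_th <- mean_rate_of_weight_change(phi, 50, xi, isi, stdp)$J
    Js <- vapply(1:6, function(b) {
      bruteforce_rate_oracle(isi, phi, 50, xi, stdp, n_cycles = 2500,
                             seed = 1000 * q + b)$J
    }, numeric(1))
    sem <- stats::sd(Js) / sqrt(length(Js))
    z <- abs(J_th - mean(Js)) / sem
    worst_z <- max(worst_z, z)
    expect_lt(abs(J_th - mean(Js)), 3 * sem + 1e-6)
  }
})

test_that("oracle reproduces the closed form exactly for point masses", {
  stdp <- stdp_parameters()
  isi <- point_mass_isi(f = 10, b = 51)
  for (phi in c(0.2, 0.8)) {
    orc <- bruteforce_rate_oracle(isi, phi, 10, 3, stdp, n_cycles = 500,
                                  seed = 2)
    J_th <- mean_rate_of_weight_change(phi, 10, 3, isi, stdp)$J
    # edge cycles contribute O(1/n) error
    expect_equal(orc$J, J_th, tolerance = 2 / 500)
  }
  orc0 <- bruteforce_rate_oracle(isi, 0.2, 10, 3, stdp_parameters(eta = 0),
                                 n_cycles = 100, seed = 2)
  expect_equal(orc0$J, 0)
})

test_that("linear growth is gated by the hard bounds", {
  expect_equal(linear_growth(-0.5, 0), 0)
  expect_equal(linear_growth(0.5, 1), 0)
  expect_equal(linear_growth(-0.01, 0.38), -0.0038)
  expect_equal(linear_growth(0.02, 0.25), 0.015)
  expect_error(linear_growth(0.1, 1.2), "\\[0, 1\\]")
})

test_that("block forecasts clip, saturate and average correctly", {
  isi <- point_mass_isi(f = 10, b = 51)
  # t = t0 returns w0; monotone decay reaches 0 in finite time w0/|S|
  fc <- forecast_blocks(c(0.5, 0.5), 10, 3, isi, w0 = 0.4, t = 0)
  expect_equal(fc$block_weights[[1]], matrix(0.4, 3, 3))
  J <- fc$J_matrix
  expect_equal(J[1, 1], J[2, 2])
  expect_equal(J[1, 1], J[3, 3])          # diagonal blocks share phi = 0
  # pick a horizon long enough to saturate every block
  S <- matrix(linear_growth(as.vector(J), 0.4), 3, 3)
  t_sat <- 2 * max(ifelse(J < 0, 0.4 / abs(S), (1 - 0.4) / abs(S)))
  fc2 <- forecast_blocks(c(0.5, 0.5), 10, 3, isi, w0 = 0.4,
                         t = c(t_sat / 4, t_sat))
  blocks <- fc2$block_weights[[2]]
  expect_true(all(blocks %in% c(0, 1)))
  expect_equal(blocks, fc2$block_weights_inf)
  expect_equal(fc2$mean_weight[2], mean(blocks))
  # monotone towards the limit
  mid <- fc2$block_weights[[1]]
  expect_true(all((blocks - mid) * sign(J) >= -1e-12))
  # this pattern down-regulates every block: complete decoupling at t -> Inf
  expect_true(all(J < 0))
  expect_equal(fc2$block_weights_inf, matrix(0, 3, 3))
  expect_equal(fc2$mean_weight_inf, 0)
})
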