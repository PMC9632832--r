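test_that("rate estimation normalises the fitted slope by the movable
           fraction", {
  t_ms <- seq(0, 20000, by = 50)
  down <- data.frame(time = t_ms, value = 0.38 - 0.005 * t_ms / 1000)
  r <- estimate_J(down, w0 = 0.38)
  expect_equal(r$J_dagger, -0.005, tolerance = 1e-9)
  expect_equal(r$J_est, -0.005 / 0.38, tolerance = 1e-9)

  up <- data.frame(time = t_ms, value = 0.38 + 0.005 * t_ms / 1000)
  r <- estimate_J(up, w0 = 0.38)
  expect_equal(r$J_est, 0.005 / 0.62, tolerance = 1e-9)

  flat <- data.frame(time = t_ms, value = rep(0.4, length(t_ms)))
  expect_equal(estimate_J(flat, 0.4)$J_est, 0)

  # only the initial in-band monotone run is fitted
  v <- c(0.95, 0.8, 0.6, 0.4, 0.2, 0.05, 0.05, 0.05)
  tr <- data.frame(time = seq_along(v) * 1000, value = v)
  r <- estimate_J(tr, w0 = 0.8)
  expect_equal(r$n_points, 4)            # 0.8, 0.6, 0.4, 0.2
  expect_equal(r$J_dagger, -0.2, tolerance = 1e-9)

  expect_error(estimate_J(data.frame(time = 0, value = 0.5), 0.5),
               "fewer than 2")
  expect_error(estimate_J(data.frame(time = c(0, 50), value = c(0.95, 0.99)),
                          0.5), "retention band")
})

test_that("rate estimation is sign-preserving and scale-equivariant", {
  t_ms <- seq(0, 10000, by = 50)
  base <- 0.5 + 0.004 * t_ms / 1000
  for (c_scale in c(0.5, 2)) {
    tr <- data.frame(time = t_ms, value = 0.5 + c_scale * (base - 0.5))
    r <- estimate_J(tr, w0 = 0.5)
    expect_equal(r$J_dagger, c_scale * 0.004, tolerance = 1e-9)
    expect_gt(r$J_est, 0)
  }
})

test_that("block means match a per-pair loop oracle", {
  st <- tiny_network(N = 12, p_conn = 0.6, M = 3, seed = 5)
  set.seed(1)
  st$w <- runif(length(st$w))
  bm <- block_means(st)
  sub <- integer(12)
  for (s in 1:3) sub[st$partition[[s]]] <- s
  for (x in 1:3) for (y in 1:3) {
    sel <- sub[st$edge_pre] == x & sub[st$edge_post] == y
    expect_equal(bm[x, y],
                 if (any(sel)) mean(st$w[sel]) else NA_real_)
  }
  # uniform weights give uniform blocks; refinement consistency with the
  # overall mean
  st$w[] <- 0.37
  expect_equal(block_means(st), matrix(0.37, 3, 3))
  expect_equal(mean_weight(st), 0.37)
})

test_that("matrix input with NA for missing synapses is supported", {
  W <- matrix(NA_real_, 4, 4)
  W[1, 2] <- 1; W[2, 1] <- 0; W[3, 4] <- 0.5; W[4, 3] <- 0.5
  part <- list(1:2, 3:4)
  bm <- block_means(W, part)
  expect_equal(bm, matrix(c(0.5, NA, NA, 0.5), 2, 2))
  expect_error(block_means(W), "partition")
})

test_that("mean weight averages existing synapses only", {
  expect_equal(mean_weight(c(1, 1, 1)), 1)
  expect_equal(mean_weight(c(0, 1)), 0.5)
  expect_error(mean_weight(numeric(0)), "no synapses")
})

test_that("collective-event detector separates synchronous bursts from
           matched-rate asynchronous spiking", {
  N <- 200
  # synchronous: the whole population fires within 2 ms, 3.5 bursts/s
  burst_times <- seq(100, 20000 - 100, by = 1000 / 3.5)
  sync <- data.frame(
    neuron = rep(seq_len(N), times = length(burst_times)),
    time = rep(burst_times, each = N) + runif(N * length(burst_times), 0, 2))
  ev <- detect_collective_events(sync, N, t_start = 0, t_end = 20000)
  expect_equal(ev$rate, 3.5, tolerance = 0.15)
  # event times sit at the bursts
  expect_true(all(vapply(ev$times, function(t) {
    min(abs(t - burst_times)) < 10
  }, logical(1))))

  # asynchronous Poisson spiking at the same mean rate: no events
  set.seed(3)
  n_sp <- nrow(sync)
  async <- data.frame(neuron = sample.int(N, n_sp, replace = TRUE),
                      time = runif(n_sp, 0, 20000))
  ev0 <- detect_collective_events(async, N, t_start = 0, t_end = 20000)
  expect_equal(ev0$rate, 0, tolerance = 0.05)

  # empty record
  ev_empty <- detect_collective_events(data.frame(neuron = integer(0),
                                                  time = numeric(0)), N)
  expect_equal(ev_empty$n_events, 0L)
})

test_that("records persist as a container plus tabular text", {
  net <- tiny_network(N = 5, p_conn = 1, seed = 2)
  rec <- simulate_network(net, NULL, simulation_config(duration_s = 0.5,
                                                       seed = 1))
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  save_record(rec, dir)
  expect_true(all(file.exists(file.path(
    dir, c("record.rds", "spikes.tsv", "mean_weight_trace.tsv",
           "block_trace.tsv", "config.yaml", "MANIFEST")))))
  back <- readRDS(file.path(dir, "record.rds"))
  expect_identical(back$state$w, rec$state$w)
  sp <- read.delim(file.path(dir, "spikes.tsv"))
  expect_equal(nrow(sp), nrow(rec$spikes))
})
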