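#' Estimate the mean rate of weight change from a recorded weight trace
#'
#' Fits a straight line to the trace of a synapse group's mean weight
#' during stimulation and normalises the slope by the fraction of synapses
#' that can still move: data points are restricted to the band
#' `(w_lo, w_hi)` — specifically the longest contiguous in-band run
#' starting at stimulation onset, so that only the initial monotone
#' increase or decay is fitted — and the raw slope `J_dagger` (per second)
#' becomes `J_est = J_dagger / (1 - w0)` if positive (growth fills the
#' `1 - w0` weak synapses) or `J_dagger / w0` if non-positive (decay
#' empties the `w0` strong ones).
#'
#' @param trace Data.frame with columns `time` (ms) and a weight column
#'   (the second column, or named `value`/`mean_w`).
#' @param w0 Pre-stimulation mean weight of the group.
#' @param w_lo,w_hi Retention band for the fit.
#' @return List with `J_est`, `J_dagger` (ordinary least-squares slope per
#'   second) and `n_points`. Fewer than 2 usable points is an error.
#' @export
estimate_J <- function(trace, w0, w_lo = 0.1, w_hi = 0.9) {
  if (w0 < 0 || w0 > 1) stop("'w0' must lie in [0, 1]")
  vcol <- intersect(c("value", "mean_w"), names(trace))
  v <- if (length(vcol)) trace[[vcol[1]]] else trace[[2]]
  t_s <- trace$time / 1000
  inband <- v > w_lo & v < w_hi
  if (!any(inband)) stop("no trace points inside the retention band")
  i0 <- which(inband)[1]
  run_end <- i0
  while (run_end < length(v) && inband[run_end + 1L]) run_end <- run_end + 1L
  idx <- i0:run_end
  if (length(idx) < 2L) {
    stop("fewer than 2 in-band points: rate of weight change is undefined")
  }
  fit <- stats::lm.fit(cbind(1, t_s[idx]), v[idx])
  J_dagger <- unname(fit$coefficients[2])
  J_est <- if (J_dagger > 0) J_dagger / (1 - w0) else J_dagger / w0
  list(J_est = J_est, J_dagger = J_dagger, n_points = length(idx))
}

#' Block means of the synaptic weight matrix
#'
#' Averages the weights of existing synapses between each ordered pair of
#' subpopulations: entry `(x, y)` is the mean weight of synapses with
#' presynaptic neuron in subpopulation `x` and postsynaptic neuron in
#' subpopulation `y`. Blocks containing no synapse are `NA`.
#'
#' @param x A `network_state`, a `simulation_record`, or a square weight
#'   matrix with `NA` marking absent synapses.
#' @param partition List of per-subpopulation neuron index vectors;
#'   defaults to the state's own partition.
#' @return An `M x M` numeric matrix.
#' @export
block_means <- function(x, partition = NULL) {
  if (inherits(x, "simulation_record")) x <- x$state
  if (inherits(x, "network_state")) {
    if (is.null(partition)) partition <- x$partition
    pre <- x$edge_pre; post <- x$edge_post; w <- x$w
  } else if (is.matrix(x)) {
    if (is.null(partition)) stop("'partition' is required for matrix input")
    keep <- which(!is.na(x))
    pre <- ((keep - 1L) %% nrow(x)) + 1L
    post <- ((keep - 1L) %/% nrow(x)) + 1L
    w <- x[keep]
  } else {
    stop("unsupported input")
  }
  if (!length(partition)) stop("empty partition")
  M <- length(partition)
  sub <- integer(max(unlist(partition)))
  for (s in seq_len(M)) sub[partition[[s]]] <- s
  bx <- sub[pre]; by <- sub[post]
  out <- matrix(NA_real_, M, M)
  for (xx in seq_len(M)) {
    for (yy in seq_len(M)) {
      sel <- bx == xx & by == yy
      if (any(sel)) out[xx, yy] <- mean(w[sel])
    }
  }
  out
}

#' Mean synaptic weight over existing synapses
#'
#' @param x A `network_state`, `simulation_record`, or numeric weight
#'   vector.
#' @return The mean weight.
#' @export
mean_weight <- function(x) {
  if (inherits(x, "simulation_record")) x <- x$state
  w <- if (inherits(x, "network_state")) x$w else x
  if (!length(w)) stop("no synapses")
  mean(w)
}

#' Detect collective spiking events
#'
#' Counts population spikes in a sliding window and declares an event for
#' every maximal run of windows in which the count exceeds
#' `frac_threshold * N`; the event is timestamped at the run's peak. In the
#' synchronised state these events are the near-simultaneous population
#' bursts; asynchronous spiking at the same mean rate produces none.
#'
#' @param spikes Data.frame with columns `neuron`, `time` (ms).
#' @param N Network size (the threshold is a fraction of `N`).
#' @param window_ms Sliding window width (ms).
#' @param frac_threshold Event threshold as a fraction of `N`.
#' @param t_start,t_end Observation window (ms); defaults to the span of
#'   the spike record.
#' @return List with `times` (event peak times, ms), `n_events`, `rate`
#'   (events per second) and `duration_s`.
#' @export
detect_collective_events <- function(spikes, N, window_ms = 10,
                                     frac_threshold = 0.5,
                                     t_start = NULL, t_end = NULL) {
  if (is.null(t_start)) t_start <- if (nrow(spikes)) min(spikes$time) else 0
  if (is.null(t_end)) t_end <- if (nrow(spikes)) max(spikes$time) else t_start
  dur_s <- (t_end - t_start) / 1000
  if (dur_s <= 0 || nrow(spikes) == 0L) {
    return(list(times = numeric(0), n_events = 0L, rate = 0,
                duration_s = max(dur_s, 0)))
  }
  tt <- spikes$time[spikes$time >= t_start & spikes$time <= t_end]
  # spike counts on a 1 ms grid, then a rolling sum over the window
  grid <- 1
  nbins <- max(1L, ceiling((t_end - t_start) / grid))
  cnt <- tabulate(pmin(nbins, floor((tt - t_start) / grid) + 1L), nbins)
  k <- max(1L, round(window_ms / grid))
  roll <- cumsum(cnt)
  roll <- c(roll[k:length(roll)] - c(0, roll[seq_len(length(roll) - k)]))
  above <- roll > frac_threshold * N
  if (!any(above)) {
    return(list(times = numeric(0), n_events = 0L, rate = 0,
                duration_s = dur_s))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev_times <- numeric(0)
  for (q in which(r$values)) {
    seg <- starts[q]:ends[q]
    peak <- seg[which.max(roll[seg])]
    # window [peak, peak + k) on the grid; timestamp at the window centre
    ev_times <- c(ev_times, t_start + (peak - 1) * grid + k * grid / 2)
  }
  list(times = ev_times, n_events = length(ev_times),
       rate = length(ev_times) / dur_s, duration_s = dur_s)
}

#' Persist a simulation record
#'
#' Writes a run container (`record.rds`) together with plain-text exports:
#' the spike table, the mean-weight and block-mean traces, the resolved
#' configuration as YAML, and a manifest listing all artifacts.
#'
#' @param record A `simulation_record`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
save_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(record, file.path(dir, "record.rds"))
  utils::write.table(record$spikes, file.path(dir, "spikes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(record$mean_weight_trace,
                     file.path(dir, "mean_weight_trace.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(record$block_trace, file.path(dir, "block_trace.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  st <- record$state
  write_config(file.path(dir, "config.yaml"), st$neuron_params,
               st$net_config, record$stdp,
               extra = list(h = record$config$h,
                            duration_s = record$config$duration_s,
                            seed = record$config$seed))
  writeLines(c("record.rds", "spikes.tsv", "mean_weight_trace.tsv",
               "block_trace.tsv", "config.yaml"),
             file.path(dir, "MANIFEST"))
  invisible(dir)
}
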