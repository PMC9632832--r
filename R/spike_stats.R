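#' Estimate conditional interspike-interval densities from stimulus-locked
#' spikes
#'
#' Characterises the spiking response of a periodically stimulated
#' population by the conditional probability densities
#' `lambda_l(eps | x)`: the density of the lth within-cycle interspike
#' interval `eps`, given that the (l-1)th spike occurred at time `x` after
#' stimulus onset. `lambda_1(eps)` is the density of the first spike time
#' after onset. Only intervals between spikes falling before the next
#' stimulus onset are considered, so the individual densities are
#' sub-normalised: the missing mass at a given `(l, x)` is the probability
#' that the spike at `x` was the cycle's last. Densities are pooled over all
#' stimulated neurons and cycles (homogeneity assumption) and binned on a
#' common grid of width `bin` ms covering one cycle `[0, 1/f)`. Empty
#' conditioning bins yield zero densities; no smoothing is applied.
#'
#' @param spikes A data.frame with columns `neuron` and `time` (ms), e.g.
#'   the `spikes` element of a [simulate_network()] record.
#' @param onsets Numeric vector of stimulus onset times (ms) of the
#'   stimulated population, one per cycle, sorted.
#' @param f Stimulation frequency (Hz); the cycle length is `1000/f` ms.
#' @param bin Bin width (ms); must divide the cycle length to within
#'   rounding.
#' @param neurons Integer vector of stimulated neuron ids; spikes of other
#'   neurons are ignored. Defaults to all neurons present in `spikes`.
#' @return An object of class `isi_densities` with elements `f`, `bin`,
#'   `nb` (bins per cycle), `lam1` (first-spike probability mass per bin),
#'   `lam` (list; element `l` for `l >= 2` is the conditional ISI mass
#'   matrix, row = ISI in bins, column = previous-spike bin), `counts`
#'   (cycles observed per conditioning bin and order, for diagnostics),
#'   `max_spikes`, `n_cycles` (neuron-cycles observed) and
#'   `mean_spikes_per_cycle`. Masses convert to the densities of the
#'   continuous description via division by `bin`.
#' @export
estimate_isi_densities <- function(spikes, onsets, f, bin = 0.2,
                                   neurons = NULL) {
  T_ms <- 1000 / f
  nb <- round(T_ms / bin)
  if (abs(nb * bin - T_ms) > 1e-6) {
    stop("'bin' must divide the cycle length 1/f")
  }
  if (is.null(neurons)) neurons <- sort(unique(spikes$neuron))
  n_onsets <- length(onsets)
  if (n_onsets < 1) stop("need at least one stimulus onset")
  sp <- spikes[spikes$neuron %in% neurons, , drop = FALSE]

  n_cycles <- length(neurons) * n_onsets
  empty <- structure(list(
    f = f, bin = bin, nb = nb, lam1 = numeric(nb), lam = list(),
    counts = NULL, max_spikes = 0L, n_cycles = n_cycles,
    mean_spikes_per_cycle = 0), class = "isi_densities")
  if (nrow(sp) == 0L) return(empty)

  cyc <- findInterval(sp$time, onsets)
  x <- sp$time - onsets[pmax(cyc, 1L)]
  keep <- cyc >= 1L & x >= 0 & x < T_ms
  sp <- sp[keep, , drop = FALSE]
  cyc <- cyc[keep]; x <- x[keep]
  if (nrow(sp) == 0L) return(empty)

  b <- pmin(floor(x / bin), nb - 1L)                 # spike bin in [0, nb)
  ord <- order(sp$neuron, cyc, x)
  nrn <- sp$neuron[ord]; cyc <- cyc[ord]; b <- b[ord]
  new_grp <- c(TRUE, nrn[-1L] != nrn[-length(nrn)] | cyc[-1L] != cyc[-length(cyc)])
  l <- stats::ave(rep(1L, length(b)), cumsum(new_grp), FUN = seq_along)
  max_spikes <- max(l)

  # first-spike mass
  lam1 <- tabulate(b[l == 1L] + 1L, nbins = nb) / n_cycles

  lam <- vector("list", max_spikes)
  counts <- vector("list", max_spikes)
  if (max_spikes >= 2L) {
    prev_b <- c(NA_integer_, b[-length(b)])
    for (k in 2L:max_spikes) {
      sel <- l == k & !new_grp
      denom <- tabulate(b[l == (k - 1L)] + 1L, nbins = nb)  # cycles whose
      # (k-1)th spike sits in each bin, whether or not a kth spike follows
      m <- matrix(0, nrow = nb, ncol = nb)
      if (any(sel)) {
        e <- b[sel] - prev_b[sel]
        xb <- prev_b[sel]
        if (any(e < 1L)) stop("non-increasing spike bins within a cycle")
        tab <- table(factor(e, levels = 1:nb), factor(xb, levels = 0:(nb - 1L)))
        m <- matrix(as.numeric(tab), nrow = nb)
        nzd <- denom > 0
        m[, nzd] <- sweep(m[, nzd, drop = FALSE], 2L, denom[nzd], "/")
      }
      lam[[k]] <- m
      counts[[k]] <- denom
    }
  }

  structure(list(f = f, bin = bin, nb = nb, lam1 = lam1, lam = lam,
                 counts = counts, max_spikes = as.integer(max_spikes),
                 n_cycles = n_cycles,
                 mean_spikes_per_cycle = length(b) / n_cycles),
            class = "isi_densities")
}

#' Construct conditional ISI densities directly from masses
#'
#' Mostly used to build synthetic response statistics in tests and examples:
#' point masses, hand-made grids, or random sub-normalised chains.
#'
#' @param f Stimulation frequency (Hz).
#' @param bin Bin width (ms).
#' @param lam1 First-spike probability mass per bin (length `nb = 1000 /
#'   (f * bin)`); must sum to at most 1.
#' @param lam List of conditional ISI mass matrices: element `l` (for
#'   `l >= 2`) has rows = ISI in bins, columns = previous-spike bin, and
#'   each column sums to at most 1. Elements 1 (and missing trailing
#'   orders) may be `NULL`.
#' @return An `isi_densities` object.
#' @export
isi_densities <- function(f, bin, lam1, lam = list()) {
  T_ms <- 1000 / f
  nb <- round(T_ms / bin)
  if (abs(nb * bin - T_ms) > 1e-6) stop("'bin' must divide the cycle length")
  if (length(lam1) != nb) stop("'lam1' must have one mass per bin")
  if (any(lam1 < 0) || sum(lam1) > 1 + 1e-9) {
    stop("'lam1' must be a sub-normalised mass vector")
  }
  max_order <- 1L
  for (l in seq_along(lam)) {
    if (is.null(lam[[l]])) next
    if (l < 2L) stop("conditional ISI matrices start at order 2")
    m <- lam[[l]]
    if (!is.matrix(m) || ncol(m) != nb) stop("ISI matrix has wrong shape")
    if (any(m < 0) || any(colSums(m) > 1 + 1e-9)) {
      stop("ISI matrices must have sub-normalised columns")
    }
    max_order <- max(max_order, l)
  }
  structure(list(f = f, bin = bin, nb = nb, lam1 = lam1, lam = lam,
                 counts = NULL, max_spikes = as.integer(max_order),
                 n_cycles = NA_integer_,
                 mean_spikes_per_cycle = NA_real_),
            class = "isi_densities")
}

#' Spike-time distributions of a conditional ISI chain
#'
#' Propagates the conditional ISI densities into the distributions
#' `Lambda_k(x)` of the kth spike time per cycle (a chained convolution on
#' the discrete grid), the last-spike distribution `Lambda_last(x)`, the
#' spike-count distribution `P(k)`, and the cumulative distributions
#' `F_k(t)`. `Lambda_1 = lambda_1`; `Lambda_{k+1}` moves the mass of
#' `Lambda_k` through `lambda_{k+1}(eps | x)`; a cycle's sequence ends at
#' order `k` with the sub-normalisation deficit of `lambda_{k+1}`.
#' Probability is conserved: `P(0) + sum_k P(k) = 1`.
#'
#' @param isi An `isi_densities` object.
#' @return An object of class `spike_time_densities` with `Lambda` (matrix,
#'   `nb` rows, one column per spike order; per-bin masses), `Lambda_last`,
#'   `P_k`, `P_0`, `F_k` (cumulative masses, same shape as `Lambda`), and
#'   the grid fields `f`, `bin`, `nb`.
#' @export
spike_time_densities <- function(isi) {
  stopifnot(inherits(isi, "isi_densities"))
  nb <- isi$nb
  kmax <- max(isi$max_spikes, 1L)
  Lambda <- matrix(0, nrow = nb, ncol = kmax)
  Lambda[, 1L] <- isi$lam1
  if (kmax >= 2L) {
    for (k in 2L:kmax) {
      lamk <- if (k <= length(isi$lam)) isi$lam[[k]] else NULL
      if (is.null(lamk)) break
      prev <- Lambda[, k - 1L]
      nxt <- numeric(nb)
      for (x in which(prev > 0)) {          # x: 1-based bin of (k-1)th spike
        col <- lamk[, x]
        nz <- which(col > 0)
        if (!length(nz)) next
        tgt <- (x - 1L) + nz                # ISI of nz bins -> bin x-1+nz
        ok <- tgt <= nb - 1L
        if (any(ok)) {
          nxt[tgt[ok] + 1L] <- nxt[tgt[ok] + 1L] + prev[x] * col[nz[ok]]
        }
      }
      Lambda[, k] <- nxt
    }
  }
  # continuation mass out of order k at bin x
  cont <- matrix(0, nrow = nb, ncol = kmax)
  for (k in seq_len(kmax)) {
    lamk1 <- if (k + 1L <= length(isi$lam)) isi$lam[[k + 1L]] else NULL
    if (!is.null(lamk1)) cont[, k] <- colSums(lamk1)
  }
  stopmass <- (1 - cont) * Lambda
  Lambda_last <- rowSums(stopmass)
  P_k <- colSums(stopmass)
  structure(list(f = isi$f, bin = isi$bin, nb = nb,
                 Lambda = Lambda, Lambda_last = Lambda_last,
                 P_k = P_k, P_0 = 1 - sum(isi$lam1),
                 F_k = apply(Lambda, 2L, cumsum)),
            class = "spike_time_densities")
}

#' Sample stimulus-locked spike trains from conditional ISI densities
#'
#' Generates, per neuron and cycle, a within-cycle spike sequence by drawing
#' the first spike bin from `lambda_1` and each subsequent ISI from
#' `lambda_{l+1}(. | x)`; a draw landing in the sub-normalisation deficit
#' terminates the sequence. Spikes are placed at bin centres relative to
#' cycle onsets at `0, 1000/f, 2000/f, ...` ms, so that re-estimating
#' densities from the generated record recovers the generator's densities.
#'
#' @param isi An `isi_densities` object.
#' @param n_neurons,n_cycles Numbers of independent neurons and cycles.
#' @param seed Integer seed.
#' @param t_offset Optional shift (ms) added to all spike times (and
#'   implicitly to the onsets).
#' @return A data.frame with columns `neuron`, `time` (ms) and `cycle`.
#' @export
generate_locked_trains <- function(isi, n_neurons, n_cycles, seed,
                                   t_offset = 0) {
  stopifnot(inherits(isi, "isi_densities"))
  set.seed(as.integer(seed))
  nb <- isi$nb
  T_ms <- 1000 / isi$f
  p1 <- isi$lam1
  stop1 <- 1 - sum(p1)
  # per-order cumulative samplers
  neuron_v <- integer(0); time_v <- numeric(0); cycle_v <- integer(0)
  res_n <- list(); res_t <- list(); res_c <- list(); ri <- 0L
  for (nr in seq_len(n_neurons)) {
    for (cc in seq_len(n_cycles)) {
      # first spike
      u <- stats::runif(1)
      if (u >= 1 - stop1) next
      bcur <- findInterval(u, cumsum(p1), left.open = TRUE) + 1L  # 1-based
      bins <- bcur
      l <- 1L
      repeat {
        lamk <- if (l + 1L <= length(isi$lam)) isi$lam[[l + 1L]] else NULL
        if (is.null(lamk)) break
        col <- lamk[, bcur]
        tot <- sum(col)
        if (tot <= 0) break
        u <- stats::runif(1)
        if (u >= tot) break
        e <- findInterval(u, cumsum(col), left.open = TRUE) + 1L
        bcur <- bcur + e
        if (bcur > nb) break                     # safety; estimated chains
        bins <- c(bins, bcur)                    # cannot leave the cycle
        l <- l + 1L
      }
      ri <- ri + 1L
      res_n[[ri]] <- rep.int(nr, length(bins))
      res_t[[ri]] <- (cc - 1L) * T_ms + (bins - 0.5) * isi$bin + t_offset
      res_c[[ri]] <- rep.int(cc, length(bins))
    }
  }
  if (ri == 0L) {
    return(data.frame(neuron = integer(0), time = numeric(0),
                      cycle = integer(0)))
  }
  data.frame(neuron = unlist(res_n), time = unlist(res_t),
             cycle = unlist(res_c))
}

#' Mean number of spikes per inter-stimulus interval and neuron
#'
#' @param spikes Data.frame with columns `neuron`, `time` (ms).
#' @param onsets Stimulus onset times (ms), one per cycle.
#' @param neurons Stimulated neuron ids (defaults to those present).
#' @return Total within-cycle spike count divided by neurons x cycles.
#' @export
mean_spikes_per_isi <- function(spikes, onsets, neurons = NULL) {
  if (length(onsets) < 1) stop("need at least one stimulus onset")
  if (is.null(neurons)) neurons <- sort(unique(spikes$neuron))
  if (!length(neurons)) stop("no neurons to average over")
  T_ms <- diff(onsets)[1]
  if (is.na(T_ms)) T_ms <- Inf
  sp <- spikes[spikes$neuron %in% neurons, , drop = FALSE]
  cyc <- findInterval(sp$time, onsets)
  x <- sp$time - onsets[pmax(cyc, 1L)]
  n_in <- sum(cyc >= 1L & x >= 0 & x < T_ms)
  n_in / (length(neurons) * length(onsets))
}
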