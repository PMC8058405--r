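# Distance correlation between binned population firing and running speed.
#
# The sample distance correlation (double-centered pairwise Euclidean
# distance matrices; biased / classical estimator) captures linear and
# non-linear dependence, is zero only under independence, and accepts
# variables of different dimension -- here an n_units x n_bins rate matrix
# against a univariate speed vector.

#' Bin population spiking into a rate matrix
#'
#' @param units List of [unit()] objects (or numeric spike-time vectors).
#' @param duration_s Recording duration, seconds.
#' @param bin_s Bin width, seconds. A trailing partial bin is dropped.
#' @return `n_units x n_bins` matrix of firing rates (Hz).
#' @export
bin_population <- function(units, duration_s, bin_s) {
  stopifnot(bin_s > 0)
  n_bins <- floor(duration_s / bin_s)
  if (n_bins < 1) stop("duration shorter than one bin")
  edges <- (0:n_bins) * bin_s
  sts <- lapply(units, function(u) if (is.list(u)) u$spike_times else u)
  X <- t(vapply(sts, function(st) {
    findInterval(edges[-1], st, left.open = TRUE) -
      findInterval(edges[-(n_bins + 1)], st, left.open = TRUE)
  }, numeric(n_bins)))
  X / bin_s
}

#' Bin a behavioral trace by averaging within bins
#'
#' @param trace A [behavior_trace()].
#' @param duration_s Duration covered, seconds.
#' @param bin_s Bin width, seconds.
#' @return Numeric vector of per-bin means (NA-free bins only are expected
#'   when the trace covers the duration).
#' @export
bin_trace <- function(trace, duration_s, bin_s) {
  n_bins <- floor(duration_s / bin_s)
  idx <- floor(trace$t / bin_s) + 1L
  keep <- idx >= 1 & idx <= n_bins & trace$t < duration_s
  sums <- tabulate_weighted(idx[keep], trace$v[keep], n_bins)
  cnts <- tabulate(idx[keep], nbins = n_bins)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

tabulate_weighted <- function(idx, w, nbins) {
  as.numeric(rowsum(w, factor(idx, levels = seq_len(nbins)), reorder = FALSE))
}

center_dist <- function(D) {
  rm <- rowMeans(D)
  sweep(sweep(D, 1L, rm), 2L, rm) + mean(D)
}

#' Sample distance correlation
#'
#' Classical (biased) estimator: pairwise Euclidean distance matrices of the
#' samples of `X` (columns) and of `y` are double-centered; dCov^2 is the
#' mean elementwise product, and dCor = dCov / sqrt(dVarX * dVarY). Returns
#' 0 when either variable is constant (no dependence measurable).
#'
#' @param X `n_vars x n_bins` matrix (or numeric vector), samples in columns.
#' @param y Numeric vector of length `n_bins` (or a second matrix).
#' @return Distance correlation in \[0, 1\].
#' @export
distance_correlation <- function(X, y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  stopifnot(ncol(X) == ncol(y), ncol(X) >= 4)
  A <- center_dist(as.matrix(stats::dist(t(X))))
  B <- center_dist(as.matrix(stats::dist(t(y))))
  dcor_from_centered(A, B)
}

dcor_from_centered <- function(A, B) {
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  dcov2 <- mean(A * B)
  sqrt(max(dcov2, 0)) / (dvx * dvy)^0.25
}

#' Geometric ladder of time-bin sizes
#'
#' Doubles from `from` (default 50 ms) up to at most `ceiling_s`.
#'
#' @param from Smallest bin, seconds.
#' @param ceiling_s Largest allowed bin, seconds (default 40 s).
#' @return Numeric vector of bin sizes.
#' @export
bin_ladder <- function(from = 0.05, ceiling_s = 40) {
  k <- floor(log2(ceiling_s / from) + 1e-9)
  from * 2^(0:k)
}

#' Shuffle-corrected distance-correlation sweep across time-bin sizes
#'
#' For each bin size in the ladder: bins population firing and running speed,
#' computes the raw distance correlation, the mean distance correlation over
#' `n_shuffles` random permutations of the binned speed vector (shuffle
#' control), the corrected value (raw minus shuffle mean), and a permutation
#' p-value = (number of shuffles with dcor >= raw) / n_shuffles. Ladder
#' steps with fewer than 4 bins are returned as `NA`.
#'
#' @param units List of [unit()] objects or spike-time vectors.
#' @param speed Running-speed [behavior_trace()].
#' @param duration_s Duration analyzed; default the speed-trace extent.
#' @param ladder Bin sizes, seconds (default [bin_ladder()]).
#' @param n_shuffles Number of speed permutations (default 50).
#' @param seed RNG seed for the shuffles.
#' @param shuffle `"permute"` (default; full random permutation, as in the
#'   shuffle control) or `"circular"` (random circular shift, conservative
#'   under autocorrelation).
#' @return A `data.frame` of class `dcor_sweep`: `bin_s`, `n_bins`,
#'   `dcor_raw`, `shuffle_mean`, `dcor_corrected`, `p_value`.
#' @export
dcor_sweep <- function(units, speed, duration_s = NULL, ladder = bin_ladder(),
                       n_shuffles = 50, seed = 1,
                       shuffle = c("permute", "circular")) {
  shuffle <- match.arg(shuffle)
  if (is.null(duration_s)) duration_s <- max(speed$t)
  out <- data.frame(bin_s = ladder, n_bins = NA_integer_, dcor_raw = NA_real_,
                    shuffle_mean = NA_real_, dcor_corrected = NA_real_,
                    p_value = NA_real_)
  local_seed(seed, {
    for (i in seq_along(ladder)) {
      bs <- ladder[i]
      n_bins <- floor(duration_s / bs)
      out$n_bins[i] <- n_bins
      if (n_bins < 4) next
      X <- bin_population(units, duration_s, bs)
      y <- bin_trace(speed, duration_s, bs)
      ok <- !is.na(y)
      X <- X[, ok, drop = FALSE]; y <- y[ok]
      n <- length(y)
      if (n < 4) next
      A <- center_dist(as.matrix(stats::dist(t(X))))
      B <- center_dist(as.matrix(stats::dist(y)))
      raw <- dcor_from_centered(A, B)
      # double centering commutes with sample permutation, so the centered
      # distance matrix of the shuffled speed is just B[p, p]
      dvx <- mean(A * A); dvy <- mean(B * B)
      sh <- numeric(n_shuffles)
      for (k in seq_len(n_shuffles)) {
        p <- if (shuffle == "permute") sample.int(n) else
          ((seq_len(n) + sample.int(n, 1) - 2L) %% n) + 1L
        sh[k] <- if (dvx <= 0 || dvy <= 0) 0 else
          sqrt(max(mean(A * B[p, p]), 0)) / (dvx * dvy)^0.25
      }
      out$dcor_raw[i] <- raw
      out$shuffle_mean[i] <- mean(sh)
      out$dcor_corrected[i] <- raw - mean(sh)
      out$p_value[i] <- sum(sh >= raw) / n_shuffles
    }
  })
  class(out) <- c("dcor_sweep", "data.frame")
  out
}
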