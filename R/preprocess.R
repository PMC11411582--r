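# Preprocessing chain: continuous filtering, ICA-based ocular artifact
# removal, epoching with baseline correction, sliding-window peak-to-peak
# rejection, Morlet wavelet spectral decomposition with mirrored buffers, and
# per-feature z-scoring.

# ---- filtering ---------------------------------------------------------------

#' Band-pass and notch filter a continuous recording
#'
#' Removes low-frequency drift (high-pass), high-frequency noise (low-pass,
#' clipped below Nyquist with a warning when necessary), and line noise at the
#' notch frequency and its harmonics. Butterworth filters applied forward and
#' backward (zero phase).
#'
#' @param x a `simulated_session` or a channels x samples matrix.
#' @param low high-pass cutoff in Hz (default 0.5; 0 disables).
#' @param high low-pass cutoff in Hz (default 200).
#' @param notch line frequency in Hz (default 60; 0 disables).
#' @param harmonics also notch harmonics of `notch` below the low-pass cutoff
#'   (default TRUE).
#' @param fs sampling rate (taken from the session when `x` is one).
#' @return same type as `x`, filtered.
#' @export
filter_continuous <- function(x, low = 0.5, high = 200, notch = 60,
                              harmonics = TRUE, fs = NULL) {
  session <- inherits(x, "simulated_session")
  dat <- if (session) x$data else x
  if (session) fs <- x$sampling_rate
  if (is.null(fs)) stop("fs required when filtering a plain matrix")
  nyq <- fs / 2
  if (high >= nyq) {
    high_eff <- 0.95 * nyq
    warning("low-pass cutoff ", high, " Hz at or above Nyquist (", nyq,
            " Hz); clipped to ", round(high_eff, 1), " Hz")
    high <- high_eff
  }
  hp <- if (low > 0) signal::butter(2, low / nyq, type = "high") else NULL
  lp <- signal::butter(4, high / nyq, type = "low")
  notches <- list()
  if (notch > 0 && notch <= high - 5) {
    for (h in seq(notch, high - 5, by = notch)) {
      notches[[length(notches) + 1L]] <-
        signal::butter(2, c(h - 2, h + 2) / nyq, type = "stop")
    }
  }
  for (c in seq_len(nrow(dat))) {
    v <- dat[c, ]
    if (!is.null(hp)) v <- signal::filtfilt(hp, v)
    v <- signal::filtfilt(lp, v)
    for (nf in notches) v <- signal::filtfilt(nf, v)
    dat[c, ] <- v
  }
  if (session) {
    x$data <- dat
    x
  } else {
    dat
  }
}

# ---- ICA / ocular artifact removal ------------------------------------------

# deflationary FastICA with tanh contrast on whitened data; returns unmixing
# in the whitened space plus the whitening/dewhitening matrices. Components
# are extracted one at a time: strongly non-Gaussian sources (blinks, spikes)
# converge to stable directions, while directions within a Gaussian-noise
# subspace are rotation-indeterminate and simply fill the remaining basis.
fastica_decompose <- function(X, n_comp = nrow(X), maxit = 100, tol = 1e-6,
                              seed = NULL) {
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  d <- pmax(eg$values[keep], .Machine$double.eps)
  K <- diag(1 / sqrt(d)) %*% t(eg$vectors[, keep, drop = FALSE])   # whitening
  Kinv <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(d))       # dewhitening
  Z <- K %*% Xc
  n <- ncol(Z)
  W <- matrix(0, n_comp, n_comp)
  with_seed(seed, {
    for (i in seq_len(n_comp)) {
      w <- stats::rnorm(n_comp)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(maxit)) {
        u <- drop(crossprod(w, Z))
        g <- tanh(u)
        w1 <- drop(Z %*% g) / n - mean(1 - g^2) * w
        if (i > 1) {  # orthogonalize against extracted components
          Wp <- W[seq_len(i - 1L), , drop = FALSE]
          w1 <- w1 - drop(crossprod(Wp, Wp %*% w1))
        }
        nrm <- sqrt(sum(w1^2))
        if (nrm < .Machine$double.eps) break
        w1 <- w1 / nrm
        conv <- abs(abs(sum(w1 * w)) - 1)
        w <- w1
        if (conv < tol) break
      }
      W[i, ] <- w
    }
  })
  list(sources = W %*% Z, mixing = Kinv %*% t(W), mean = mu, W = W, K = K)
}

#' Remove EOG-correlated independent components
#'
#' Decomposes the scalp channels into independent components, correlates each
#' component timecourse with each EOG channel, z-scores the correlations per
#' EOG channel across components, zeroes out every component whose absolute
#' z exceeds `z_threshold`, and reconstructs the scalp data.
#'
#' @param x a `simulated_session` or channels x samples matrix with rownames.
#' @param eog_channels names of the EOG rows (default the montage EOG set).
#' @param z_threshold removal threshold on the z-scored correlation
#'   (default 3).
#' @param n_comp number of components (default all scalp channels).
#' @param seed seed for the ICA initialisation.
#' @return same type as `x`, with scalp channels reconstructed; the removed
#'   component indices are attached as attribute `"removed_components"`.
#' @export
remove_ocular_components <- function(x, eog_channels = NULL, z_threshold = 3,
                                     n_comp = NULL, seed = 1L) {
  session <- inherits(x, "simulated_session")
  dat <- if (session) x$data else x
  if (is.null(rownames(dat))) stop("channel rownames required")
  if (is.null(eog_channels)) {
    eog_channels <- grep("^EOG", rownames(dat), value = TRUE)
  }
  if (length(eog_channels) < 2) stop("need at least 2 EOG channels")
  scalp <- setdiff(rownames(dat), eog_channels)
  if (is.null(n_comp)) n_comp <- length(scalp)
  dec <- fastica_decompose(dat[scalp, , drop = FALSE], n_comp = n_comp,
                           seed = seed)
  if (any(!is.finite(dec$sources))) {
    stop("ICA decomposition failed: non-finite sources (n_comp = ", n_comp,
         ", channels = ", length(scalp), ")")
  }
  eog <- dat[eog_channels, , drop = FALSE]
  r <- stats::cor(t(dec$sources), t(eog))           # n_comp x n_eog
  z <- scale(r)                                      # per EOG channel
  bad <- which(apply(abs(z) > z_threshold, 1, any))
  clean <- dec$sources
  if (length(bad)) clean[bad, ] <- 0
  rec <- dec$mixing %*% clean + dec$mean
  dat[scalp, ] <- rec
  out <- if (session) {
    x$data <- dat
    x
  } else dat
  attr(out, "removed_components") <- bad
  out
}

# ---- epoching ----------------------------------------------------------------

#' Extract epochs and baseline-correct them
#'
#' Epochs span `window` (default -100..1000 ms, endpoints inclusive) around
#' each onset; the mean of the baseline period (left-closed, right-open) is
#' subtracted from the whole epoch, per channel. Onsets whose window falls
#' outside the recording are dropped with a message.
#'
#' @param x a `simulated_session` or channels x samples matrix.
#' @param onsets onset sample indices (default: the session's onsets).
#' @param fs sampling rate (from the session when omitted).
#' @param window epoch span in seconds relative to onset.
#' @param baseline baseline span in seconds (default -0.1..0).
#' @param metadata optional per-onset data frame carried along (default the
#'   session's trial table).
#' @return object of class `epoch_array`: list with `voltage` (trials x
#'   channels x samples), `times_ms`, `sampling_rate`, `channels`, `metadata`,
#'   `rejected` (all `FALSE` initially), `dropped` (indices of onsets that did
#'   not fit).
#' @export
epoch_and_baseline <- function(x, onsets = NULL, fs = NULL,
                               window = c(-0.1, 1.0), baseline = c(-0.1, 0),
                               metadata = NULL) {
  if (inherits(x, "simulated_session")) {
    if (is.null(onsets)) onsets <- x$onsets
    if (is.null(fs)) fs <- x$sampling_rate
    if (is.null(metadata)) metadata <- x$trials
    dat <- x$data
  } else {
    dat <- x
    if (is.null(onsets) || is.null(fs)) stop("onsets and fs required")
  }
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  n_s <- length(rel)
  fits <- onsets + rel[1] >= 1 & onsets + rel[n_s] <= ncol(dat)
  dropped <- which(!fits)
  if (length(dropped)) {
    message(length(dropped), " onset(s) too close to the recording edge; dropped")
  }
  use <- which(fits)
  n_tr <- length(use)
  n_ch <- nrow(dat)
  v <- array(NA_real_, c(n_tr, n_ch, n_s))
  for (i in seq_len(n_tr)) {
    v[i, , ] <- dat[, onsets[use[i]] + rel]
  }
  times_ms <- rel / fs * 1000
  bidx <- which(times_ms >= baseline[1] * 1000 & times_ms < baseline[2] * 1000)
  bl <- apply(v[, , bidx, drop = FALSE], c(1, 2), mean)
  v <- v - array(bl, c(n_tr, n_ch, n_s))
  md <- if (!is.null(metadata)) metadata[use, , drop = FALSE] else NULL
  structure(list(voltage = v, times_ms = times_ms, sampling_rate = fs,
                 channels = rownames(dat), metadata = md,
                 rejected = rep(FALSE, n_tr), dropped = dropped),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$voltage)
  cat("epoch_array: ", d[1], " epochs x ", d[2], " channels x ", d[3],
      " samples (", round(min(x$times_ms)), "..", round(max(x$times_ms)),
      " ms @ ", x$sampling_rate, " Hz), ", sum(x$rejected), " rejected\n",
      sep = "")
  invisible(x)
}

#' Flag epochs with excessive peak-to-peak amplitude
#'
#' An epoch is rejected iff any channel's max-minus-min within any sliding
#' window exceeds the threshold. The final partial window is evaluated when at
#' least half the window length remains.
#'
#' @param epochs an `epoch_array`.
#' @param threshold peak-to-peak limit in microvolts (default 250).
#' @param win_ms window length (default 200 ms); `step_ms` step (default 50).
#' @param step_ms see `win_ms`.
#' @param channels channels to screen (default all scalp, i.e. non-EOG).
#' @return logical rejection mask, one per epoch.
#' @export
reject_artifacts <- function(epochs, threshold = 250, win_ms = 200,
                             step_ms = 50, channels = NULL) {
  fs <- epochs$sampling_rate
  wlen <- as.integer(round(win_ms / 1000 * fs))
  step <- as.integer(round(step_ms / 1000 * fs))
  if (wlen > dim(epochs$voltage)[3]) stop("window longer than epoch")
  ch_idx <- seq_along(epochs$channels)
  if (is.null(channels)) {
    ch_idx <- which(!grepl("^EOG", epochs$channels))
  } else {
    ch_idx <- match(channels, epochs$channels)
  }
  n_s <- dim(epochs$voltage)[3]
  starts <- seq(1L, n_s, by = step)
  rejected <- rep(FALSE, dim(epochs$voltage)[1])
  for (s in starts) {
    e <- min(s + wlen - 1L, n_s)
    if (e - s + 1L < ceiling(wlen / 2)) next
    sl <- lapply(s:e, function(k) epochs$voltage[, ch_idx, k, drop = FALSE])
    mx <- Reduce(pmax, sl)
    mn <- Reduce(pmin, sl)
    pp <- mx - mn
    rejected <- rejected | apply(pp > threshold, 1, any)
  }
  rejected
}

# ---- spectral decomposition --------------------------------------------------

#' Logarithmically spaced analysis frequencies
#' @param from,to endpoints in Hz; `n` number of frequencies.
#' @return numeric vector of length `n`.
#' @export
log_freqs <- function(from = 4, to = 100, n = 30) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Morlet wavelet spectral power of an epoch array
#'
#' Each epoch is temporally reflected to form mirrored pre- and post-buffers,
#' convolved with complex Morlet wavelets (fixed number of cycles per
#' frequency), the buffers discarded, and base-10 log power returned. Output
#' is either time-averaged per epoch (`"average"`), averaged within sliding
#' windows of the epoch (`"windowed"`), or the full time-resolved array
#' (`"resolved"`; memory-heavy, intended for small inputs).
#'
#' @param epochs an `epoch_array`.
#' @param freqs analysis frequencies in Hz (default 30 log-spaced, 4-100 Hz);
#'   all must lie below Nyquist.
#' @param n_cycles wavelet cycles per frequency (default 4).
#' @param time_bandwidth retained for wavelet parameterisations that use it;
#'   the implementation is governed by `n_cycles`.
#' @param output `"average"`, `"windowed"`, or `"resolved"`.
#' @param win_ms,step_ms window length/step for `"windowed"` (default 100/50
#'   ms over the presentation period starting at 0 ms).
#' @param window_ms for `"average"` output, restrict the time average to this
#'   `c(lo, hi)` ms span (left-closed, right-open; default the whole epoch).
#' @param channels subset of channel names (default all non-EOG channels).
#' @return object of class `spectral_power`: list with `power` (log10 power;
#'   trials x channels x freqs [x windows or samples]), `freqs`, `channels`,
#'   `output`, `window_start_ms` (windowed output), `times_ms` (resolved),
#'   `metadata`, `rejected`.
#' @export
spectral_power <- function(epochs, freqs = log_freqs(), n_cycles = 4,
                           time_bandwidth = 4,
                           output = c("average", "windowed", "resolved"),
                           win_ms = 100, step_ms = 50, window_ms = NULL,
                           channels = NULL) {
  output <- match.arg(output)
  fs <- epochs$sampling_rate
  if (max(freqs) > fs / 2) {
    stop("max analysis frequency ", round(max(freqs), 1),
         " Hz exceeds Nyquist (", fs / 2, " Hz)")
  }
  if (is.null(channels)) channels <- epochs$channels[!grepl("^EOG", epochs$channels)]
  ch_idx <- match(channels, epochs$channels)
  n_tr <- dim(epochs$voltage)[1]
  n_s <- dim(epochs$voltage)[3]
  n_f <- length(freqs)
  N <- 3L * n_s
  fax <- (seq_len(N) - 1L) * fs / N
  # analytic Morlet kernels in the frequency domain (one per column)
  kern <- sapply(freqs, function(f) {
    sd_f <- f / n_cycles
    h <- exp(-(fax - f)^2 / (2 * sd_f^2))
    h[fax > fs / 2] <- 0  # one-sided (analytic) response
    h
  })
  win_idx <- NULL
  if (output == "windowed") {
    starts <- seq(0, max(epochs$times_ms) - win_ms + 1e-9, by = step_ms)
    win_idx <- lapply(starts, function(s) {
      which(epochs$times_ms >= s & epochs$times_ms < s + win_ms)
    })
    out <- array(NA_real_, c(n_tr, length(ch_idx), n_f, length(starts)))
  } else if (output == "resolved") {
    out <- array(NA_real_, c(n_tr, length(ch_idx), n_f, n_s))
  } else {
    out <- array(NA_real_, c(n_tr, length(ch_idx), n_f))
  }
  mid <- (n_s + 1L):(2L * n_s)
  avg_idx <- seq_len(n_s)
  if (output == "average" && !is.null(window_ms)) {
    avg_idx <- which(epochs$times_ms >= window_ms[1] &
                       epochs$times_ms < window_ms[2])
    if (length(avg_idx) == 0) stop("window_ms outside the epoch span")
  }
  for (i in seq_len(n_tr)) {
    for (jc in seq_along(ch_idx)) {
      xv <- epochs$voltage[i, ch_idx[jc], ]
      y <- c(rev(xv), xv, rev(xv))
      Y <- stats::fft(y)
      conv <- stats::mvfft(Y * kern, inverse = TRUE) / N
      pw <- log10(pmax(Mod(conv[mid, , drop = FALSE])^2,
                       .Machine$double.xmin))
      if (output == "average") {
        out[i, jc, ] <- colMeans(pw[avg_idx, , drop = FALSE])
      } else if (output == "windowed") {
        for (w in seq_along(win_idx)) {
          out[i, jc, , w] <- colMeans(pw[win_idx[[w]], , drop = FALSE])
        }
      } else {
        out[i, jc, , ] <- t(pw)
      }
    }
  }
  structure(list(power = out, freqs = freqs, channels = channels,
                 output = output,
                 window_start_ms = if (output == "windowed")
                   seq(0, by = step_ms, length.out = dim(out)[4]) else NULL,
                 times_ms = if (output == "resolved") epochs$times_ms else NULL,
                 metadata = epochs$metadata, rejected = epochs$rejected),
            class = "spectral_power")
}

#' z-score spectral features across epochs
#'
#' Computes the across-epoch mean and SD of the time-averaged log power
#' separately for every channel x frequency feature (rejected epochs
#' excluded), and standardises. For windowed/resolved input the same
#' epoch-level statistics are applied to every time point, so evoked dynamics
#' within the epoch are preserved.
#'
#' @param sp a `spectral_power` object.
#' @param keep logical vector of epochs to use for the statistics (default
#'   `!sp$rejected`).
#' @return object of class `spectral_features`: list with `z` (kept trials x
#'   features matrix for averaged input; kept trials x features x windows for
#'   windowed), `feature_index` (data frame `channel`, `freq`), `mean`, `sd`,
#'   `kept` (row indices into the original epochs), `metadata`.
#' @export
zscore_features <- function(sp, keep = NULL) {
  if (is.null(keep)) keep <- !sp$rejected
  if (sum(keep) < 2) stop("need at least 2 retained epochs to z-score")
  pw <- sp$power
  d <- dim(pw)
  n_feat <- d[2] * d[3]
  feature_index <- data.frame(
    channel = rep(sp$channels, times = d[3]),
    freq = rep(sp$freqs, each = d[2]), stringsAsFactors = FALSE)
  # epoch-level (time-averaged) feature values
  epoch_avg <- if (length(d) == 3) pw else apply(pw, c(1, 2, 3), mean)
  m <- matrix(epoch_avg[keep, , ], nrow = sum(keep), ncol = n_feat)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero)) {
    stop("zero variance in feature(s): ",
         paste(utils::head(paste0(feature_index$channel[zero], "@",
                                  round(feature_index$freq[zero], 1), "Hz"), 3),
               collapse = ", "))
  }
  if (length(d) == 3) {
    z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  } else {
    z <- array(NA_real_, c(sum(keep), n_feat, d[4]))
    for (w in seq_len(d[4])) {
      mw <- matrix(pw[keep, , , w], nrow = sum(keep), ncol = n_feat)
      z[, , w] <- sweep(sweep(mw, 2, mu), 2, sdv, "/")
    }
  }
  structure(list(z = z, feature_index = feature_index, mean = mu, sd = sdv,
                 kept = which(keep),
                 window_start_ms = sp$window_start_ms,
                 metadata = if (!is.null(sp$metadata))
                   sp$metadata[keep, , drop = FALSE] else NULL),
            class = "spectral_features")
}
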