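test_that("continuous filtering attenuates line noise and keeps the passband", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  x60 <- sin(2 * pi * 60 * t)
  x10 <- sin(2 * pi * 10 * t)
  dc <- rep(7, length(t))
  dat <- rbind(x60, x10, dc)
  rownames(dat) <- c("A", "B", "C")
  out <- filter_continuous(dat, fs = fs)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(out[1, ]) / rms(x60), 0.10)          # notch >= 20 dB
  expect_lt(abs(rms(out[2, ]) / rms(x10) - 1), 0.05) # passband preserved
  expect_lt(abs(mean(out[3, ])), 0.1)                # drift removed
  # cutoff above Nyquist is clipped with a warning
  expect_warning(filter_continuous(dat, high = 300, fs = fs), "Nyquist")
})

test_that("EOG-correlated components are identified and removed", {
  set.seed(42)
  n <- 8000
  n_ch <- 16
  # constructed mixing: 16 independent sources into 16 channels; source 1 is
  # a sparse blink train (high kurtosis, as real blinks are -- a single
  # near-Gaussian source among Gaussians is not identifiable by ICA). The
  # z > 3 removal rule also needs a reasonable number of components: the
  # largest attainable z among k correlations is (k - 1) / sqrt(k).
  blink <- rep(0, n)
  starts <- sort(sample(seq(1, n - 120, by = 40), 20))
  shape <- (1 - cos(2 * pi * (1:100) / 101)) / 2
  for (s in starts) blink[s:(s + 99)] <- blink[s:(s + 99)] + shape * 50
  S <- rbind(blink, matrix(rnorm((n_ch - 1) * n), n_ch - 1))
  A <- matrix(rnorm(n_ch^2), n_ch)
  X <- A %*% S
  eog <- rbind(EOG1 = S[1, ] * 3 + rnorm(n, sd = 0.2),
               EOG2 = S[1, ] * 2.5 + rnorm(n, sd = 0.2))
  dat <- rbind(X, eog)
  rownames(dat) <- c(paste0("CH", 1:n_ch), "EOG1", "EOG2")
  out <- remove_ocular_components(dat, eog_channels = c("EOG1", "EOG2"),
                                  seed = 1)
  expect_length(attr(out, "removed_components"), 1)
  r_after <- max(abs(stats::cor(t(out[1:n_ch, ]), t(dat[n_ch + 1:2, ]))))
  expect_lt(r_after, 0.1)
  # with no coupled component, reconstruction approximates the input
  dat2 <- rbind(matrix(rnorm(n_ch * n), n_ch), matrix(rnorm(2 * n), 2))
  rownames(dat2) <- rownames(dat)
  out2 <- remove_ocular_components(dat2, eog_channels = c("EOG1", "EOG2"),
                                   seed = 1)
  if (length(attr(out2, "removed_components")) == 0) {
    expect_lt(max(abs(out2[1:n_ch, ] - dat2[1:n_ch, ])), 1e-6)
  }
  expect_error(remove_ocular_components(dat, eog_channels = "EOG1"),
               "at least 2")
})

test_that("epoching subtracts the baseline and respects window arithmetic", {
  fs <- 250
  n <- 5000
  dat <- rbind(const = rep(7, n), step = rep(0, n))
  onsets <- c(500, 1500, 2500)
  dat["step", ] <- 0
  for (o in onsets) dat["step", o:(o + 300)] <- 10  # +10 uV from t = 0
  ep <- epoch_and_baseline(dat, onsets = onsets, fs = fs)
  expect_equal(dim(ep$voltage), c(3, 2, 276))
  expect_true(all(abs(ep$voltage[, 1, ]) < 1e-12))   # constant channel -> 0
  post <- which(ep$times_ms >= 0 & ep$times_ms < 1000)
  pre <- which(ep$times_ms < 0)
  expect_equal(unique(round(ep$voltage[1, 2, post[1:100]], 6)), 10)
  expect_true(all(abs(ep$voltage[, 2, pre]) < 1e-12))
  # onsets at the edge are dropped with a message
  expect_message(ep2 <- epoch_and_baseline(dat, onsets = c(5, 1500), fs = fs),
                 "dropped")
  expect_equal(dim(ep2$voltage)[1], 1)
  # shift equivariance: delaying recording and onsets gives identical epochs
  k <- 37
  shifted <- cbind(matrix(0, 2, k), dat)
  rownames(shifted) <- rownames(dat)
  ep3 <- epoch_and_baseline(shifted, onsets = onsets + k, fs = fs)
  expect_equal(ep3$voltage, ep$voltage)
})

test_that("artifact rejection equals the brute-force sliding-window oracle", {
  set.seed(7)
  fs <- 250
  n_s <- 276
  v <- array(rnorm(200 * 3 * n_s, sd = 60), c(200, 3, n_s))
  ep <- structure(list(voltage = v, times_ms = seq(-100, 1000, by = 4),
                       sampling_rate = fs, channels = c("A", "B", "C"),
                       metadata = NULL, rejected = rep(FALSE, 200)),
                  class = "epoch_array")
  mask <- reject_artifacts(ep)
  # oracle: every window, every channel, max - min
  wlen <- 50L; step <- 13L  # 200 ms / 50 ms at 250 Hz (rounded step 12.5 -> 13? )
  step <- as.integer(round(50 / 1000 * fs))
  oracle <- rep(FALSE, 200)
  for (i in 1:200) for (c in 1:3) {
    s <- 1L
    while (s <= n_s) {
      e <- min(s + wlen - 1L, n_s)
      if (e - s + 1L >= ceiling(wlen / 2)) {
        if (diff(range(v[i, c, s:e])) > 250) oracle[i] <- TRUE
      }
      s <- s + step
    }
  }
  expect_identical(mask, oracle)
  # flat epochs are never rejected; a single large spike is
  flat <- ep
  flat$voltage <- array(0, c(4, 3, n_s))
  flat$rejected <- rep(FALSE, 4)
  expect_false(any(reject_artifacts(flat)))
  flat$voltage[2, 1, 100] <- 300
  expect_identical(which(reject_artifacts(flat)), 2L)
})

test_that("wavelet power has the documented frequency axis and identities", {
  fx <- log_freqs()
  expect_length(fx, 30)
  expect_equal(fx[1], 4)
  expect_equal(fx[30], 100)
  expect_true(all(diff(log(fx)) - diff(log(fx))[1] < 1e-12))
  # pure tone peaks at the nearest axis frequency
  fs <- 250
  n_s <- 276
  tt <- seq_len(n_s) / fs
  tone <- sin(2 * pi * 10 * tt)
  v <- array(rep(tone, each = 2), c(1, 2, n_s))
  ep <- structure(list(voltage = v, times_ms = seq(-100, 1000, by = 4),
                       sampling_rate = fs, channels = c("A", "B"),
                       metadata = NULL, rejected = FALSE),
                  class = "epoch_array")
  freqs <- log_freqs(4, 50, 15)
  sp <- spectral_power(ep, freqs = freqs)
  peak <- freqs[which.max(sp$power[1, 1, ])]
  expect_equal(peak, freqs[which.min(abs(freqs - 10))])
  # doubling the amplitude raises log10 power by log10(4) everywhere
  ep2 <- ep
  ep2$voltage <- ep$voltage * 2
  sp2 <- spectral_power(ep2, freqs = freqs)
  expect_equal(sp2$power - sp$power,
               array(log10(4), dim(sp$power)), tolerance = 1e-9)
  expect_error(spectral_power(ep, freqs = c(10, 200)), "Nyquist")
})

test_that("mirrored buffers approximate true surrounding data at the centre", {
  set.seed(11)
  fs <- 250
  n_s <- 276
  # narrowband 6 Hz signal embedded in a long recording
  long <- stats::filter(rnorm(5 * n_s), rep(1, 8), sides = 2)
  long[is.na(long)] <- 0
  start <- 2 * n_s + 1
  seg <- as.numeric(long[start:(start + n_s - 1)])
  v <- array(seg, c(1, 1, n_s))
  ep <- structure(list(voltage = v, times_ms = seq(-100, 1000, by = 4),
                       sampling_rate = fs, channels = "A",
                       metadata = NULL, rejected = FALSE),
                  class = "epoch_array")
  freqs <- c(4, 8, 16)
  sp <- spectral_power(ep, freqs = freqs, output = "resolved")
  # oracle: same Morlet convolution with the *true* pre/post data as buffers
  y <- as.numeric(long[(start - n_s):(start + 2 * n_s - 1)])
  N <- 3 * n_s
  fax <- (seq_len(N) - 1L) * fs / N
  mid <- (n_s + 1):(2 * n_s)
  centre <- 80:200  # interior samples
  for (k in seq_along(freqs)) {
    sd_f <- freqs[k] / 4
    h <- exp(-(fax - freqs[k])^2 / (2 * sd_f^2))
    h[fax > fs / 2] <- 0
    conv <- stats::fft(stats::fft(y) * h, inverse = TRUE) / N
    oracle <- log10(Mod(conv[mid])^2)
    rel <- abs(10^sp$power[1, 1, k, centre] - 10^oracle[centre]) /
      10^oracle[centre]
    expect_lt(stats::median(rel), 0.01)
  }
})

test_that("z-scored features satisfy their moment invariants exactly", {
  set.seed(13)
  pw <- array(rnorm(40 * 3 * 5, mean = -10), c(40, 3, 5))
  sp <- structure(list(power = pw, freqs = 1:5, channels = c("A", "B", "C"),
                       output = "average", window_start_ms = NULL,
                       metadata = NULL, rejected = rep(FALSE, 40)),
                  class = "spectral_power")
  zf <- zscore_features(sp)
  expect_lt(max(abs(colMeans(zf$z))), 1e-10)
  expect_lt(max(abs(apply(zf$z, 2, sd) - 1)), 1e-10)
  expect_equal(dim(zf$z), c(40, 15))
  # invariants hold after rejecting a subset
  sp$rejected[c(3, 9, 31)] <- TRUE
  zf2 <- zscore_features(sp)
  expect_equal(nrow(zf2$z), 37)
  expect_lt(max(abs(colMeans(zf2$z))), 1e-10)
  expect_lt(max(abs(apply(zf2$z, 2, sd) - 1)), 1e-10)
  # permuting epochs permutes rows identically (no cross-feature leakage)
  perm <- sample(40)
  sp3 <- sp
  sp3$power <- pw[perm, , ]
  sp3$rejected <- rep(FALSE, 40)
  sp$rejected <- rep(FALSE, 40)
  expect_equal(zscore_features(sp3)$z, zscore_features(sp)$z[perm, ])
  # hand-computed 3-epoch toy
  toy <- array(c(1, 2, 3), c(3, 1, 1))
  spt <- structure(list(power = toy, freqs = 1, channels = "A",
                        output = "average", window_start_ms = NULL,
                        metadata = NULL, rejected = rep(FALSE, 3)),
                   class = "spectral_power")
  expect_equal(as.numeric(zscore_features(spt)$z), c(-1, 0, 1))
  # zero-variance feature errors with its name
  spz <- spt
  spz$power <- array(5, c(3, 1, 1))
  expect_error(zscore_features(spz), "zero variance")
})

test_that("time-resolved z-scoring reuses the epoch-level statistics", {
  set.seed(17)
  pw <- array(rnorm(10 * 2 * 3 * 6), c(10, 2, 3, 6))
  sp <- structure(list(power = pw, freqs = 1:3, channels = c("A", "B"),
                       output = "windowed", window_start_ms = seq(0, 250, 50),
                       metadata = NULL, rejected = rep(FALSE, 10)),
                  class = "spectral_power")
  zf <- zscore_features(sp)
  # averaging the windowed z over windows must equal z of the window-averaged
  # power computed with the same statistics
  avg <- apply(pw, c(1, 2, 3), mean)
  m <- matrix(avg, nrow = 10)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  zavg <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  expect_equal(apply(zf$z, c(1, 2), mean), zavg, tolerance = 1e-12)
})
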