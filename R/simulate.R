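# Synthetic EEG + behaviour generator. Every condition effect that the
# analysis chain is meant to detect is planted here with known parameters, so
# downstream stages can be tested by parameter recovery without any recorded
# data.

#' Construct a generative specification for the simulator
#'
#' Collects every planted-effect parameter of the synthetic session: the
#' P300-like parietal deflection with condition-dependent amplitude, the three
#' community-specific channel templates carried by narrowband theta activity at
#' posterior channels, predictive mixing of the adjacent community's template
#' into boundary-node epochs (scaled by the preceding within-community run
#' length), 1/f background noise, 60 Hz line noise, blink artifacts coupled to
#' the EOG channels, rare high-amplitude spikes, and the behavioural response
#' model. Neural effect sizes are chosen for testability (the reference
#' experiment reports none); behavioural parameters default to the reported
#' group means.
#'
#' @param sampling_rate Hz (default 250; configurable up to 1000).
#' @param n_channels scalp channel count (default 64, plus 4 EOG channels).
#' @param p300_amp named amplitudes in microvolts for
#'   `novel`/`learned`/`nonboundary` trials at the parietal peak.
#' @param p300_latency_s,p300_width_s Gaussian bump peak and SD in seconds.
#' @param template_gain microvolt amplitude of the community theta templates.
#' @param template_freq length-2 Hz range of the community templates' main
#'   (strongest) band.
#' @param template_broadband relative amplitude of a secondary broadband
#'   (15-40 Hz) component of the community templates (default 0.5, i.e. 20%
#'   of template power), mirroring the multiband spectral structure seen in
#'   empirical component loadings; 0 for a purely narrowband template.
#' @param predictive_mix `c(alpha0, alpha1)`: mixing proportion of the adjacent
#'   community's template at boundary-node epochs is
#'   `min(1, alpha0 + alpha1 * run_length)`.
#' @param mix_onset_s time after stimulus onset at which the predictive
#'   mixture becomes active (default 0.25 s, emulating a retrieval-like
#'   latency; 0 for mixing throughout the epoch).
#' @param noise_beta 1/f^beta exponent of the background noise.
#' @param noise_scale background noise RMS in microvolts.
#' @param line_amp 60 Hz line-noise amplitude in microvolts.
#' @param blink_rate blinks per second; `blink_amp` microvolt EOG amplitude.
#' @param blink_amp see `blink_rate`.
#' @param spike_rate per-epoch probability of a high-amplitude spike;
#'   `spike_amp` its microvolt amplitude (exceeds the +-250 uV rejection
#'   criterion).
#' @param spike_amp see `spike_rate`.
#' @param parse_prob named parse probabilities per transition condition.
#' @param parse_rt_mean,parse_rt_sd named RT parameters (ms) per condition for
#'   the truncated-normal response-time model.
#' @param rotation_hit,rotation_fa rotation-task hit and false-alarm rates.
#' @param rotation_rt_mean named RT means (ms) for `learned_boundary` and
#'   `nonboundary` rotation-task trials; `rotation_rt_sd` their SD.
#' @param rotation_rt_sd see `rotation_rt_mean`.
#' @param posttest_acc probability of a correct posttest answer.
#' @param template_seed seed fixing the community template patterns.
#' @return object of class `generative_spec` (a validated list).
#' @export
generative_spec <- function(sampling_rate = 250,
                            n_channels = 64,
                            p300_amp = c(novel = 3, learned = 5,
                                         nonboundary = 2),
                            p300_latency_s = 0.35,
                            p300_width_s = 0.05,
                            template_gain = 4,
                            template_freq = c(5, 7),
                            template_broadband = 0.5,
                            predictive_mix = c(alpha0 = 0, alpha1 = 0.08),
                            mix_onset_s = 0.25,
                            noise_beta = 1,
                            noise_scale = 10,
                            line_amp = 2,
                            blink_rate = 0.1,
                            blink_amp = 150,
                            spike_rate = 0.02,
                            spike_amp = 400,
                            parse_prob = c(novel = 0.183, learned = 0.190,
                                           nonboundary = 0.140),
                            parse_rt_mean = c(novel = 690, learned = 648,
                                              nonboundary = 631),
                            parse_rt_sd = c(novel = 150, learned = 150,
                                            nonboundary = 150),
                            rotation_hit = 0.85,
                            rotation_fa = 0.15,
                            rotation_rt_mean = c(learned_boundary = 676,
                                                 nonboundary = 665),
                            rotation_rt_sd = 120,
                            posttest_acc = 0.656,
                            template_seed = 1L) {
  montage <- build_montage(n_channels)
  spec <- structure(list(
    sampling_rate = sampling_rate, n_channels = n_channels, montage = montage,
    p300_amp = p300_amp, p300_latency_s = p300_latency_s,
    p300_width_s = p300_width_s,
    template_gain = template_gain, template_freq = template_freq,
    template_broadband = template_broadband,
    predictive_mix = predictive_mix, mix_onset_s = mix_onset_s,
    noise_beta = noise_beta, noise_scale = noise_scale, line_amp = line_amp,
    blink_rate = blink_rate, blink_amp = blink_amp,
    spike_rate = spike_rate, spike_amp = spike_amp,
    parse_prob = parse_prob, parse_rt_mean = parse_rt_mean,
    parse_rt_sd = parse_rt_sd,
    rotation_hit = rotation_hit, rotation_fa = rotation_fa,
    rotation_rt_mean = rotation_rt_mean, rotation_rt_sd = rotation_rt_sd,
    posttest_acc = posttest_acc, template_seed = template_seed),
    class = "generative_spec")
  spec$community_templates <- make_community_templates(spec)
  errs <- validate_generative_spec(spec)
  if (length(errs)) stop("invalid generative spec: ",
                         paste(errs, collapse = "; "))
  spec
}

# one posterior-weighted random channel pattern per community
make_community_templates <- function(spec) {
  scalp <- spec$montage[!spec$montage$eog, , drop = FALSE]
  posterior <- exp(-pmax(scalp$y + 2, 0)^2 / 4)  # strongest behind Cz
  with_seed(spec$template_seed, {
    tmpl <- sapply(1:3, function(cm) {
      w <- stats::rnorm(nrow(scalp)) * posterior
      w / sqrt(mean(w^2))
    })
    rownames(tmpl) <- scalp$name
    colnames(tmpl) <- paste0("community", 1:3)
    tmpl
  })
}

#' Validate a generative specification
#'
#' @param spec a `generative_spec` (or plain list with its fields).
#' @return character vector of violation messages (empty when valid).
#' @export
validate_generative_spec <- function(spec) {
  errs <- character(0)
  chk_rate <- function(v, nm) {
    if (any(v < 0 | v > 1)) errs[[length(errs) + 1L]] <<-
        paste0(nm, " must lie in [0, 1]")
  }
  chk_rate(spec$parse_prob, "parse_prob")
  chk_rate(c(spec$rotation_hit, spec$rotation_fa), "rotation rates")
  chk_rate(spec$posttest_acc, "posttest_acc")
  chk_rate(spec$spike_rate, "spike_rate")
  for (nm in c("p300_amp", "template_gain", "noise_scale", "line_amp",
               "blink_amp", "spike_amp", "blink_rate")) {
    if (any(spec[[nm]] < 0)) errs[[length(errs) + 1L]] <-
        paste0(nm, " must be non-negative")
  }
  if (spec$predictive_mix[1] < 0 || spec$predictive_mix[1] > 1) {
    errs[[length(errs) + 1L]] <- "predictive_mix alpha0 must lie in [0, 1]"
  }
  if (spec$sampling_rate < 2 * max(spec$template_freq)) {
    errs[[length(errs) + 1L]] <- "sampling_rate below template Nyquist"
  }
  if (!all(c("novel", "learned", "nonboundary") %in% names(spec$p300_amp))) {
    errs[[length(errs) + 1L]] <- "p300_amp must name novel/learned/nonboundary"
  }
  errs
}

# ---- signal building blocks --------------------------------------------------

# 1/f^beta noise with RMS `scale`, via spectral shaping of white noise
one_over_f_noise <- function(n, beta = 1, scale = 1) {
  nf <- n %/% 2L + 1L
  f <- c(1, seq_len(nf - 1L))  # avoid division by zero at DC
  mag <- f^(-beta / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- mag * exp(1i * phase)
  spec[1] <- 0
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1L)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x - mean(x)
  x / stats::sd(x) * scale
}

# narrowband noise restricted to [f_lo, f_hi] Hz with unit RMS
narrowband_noise <- function(n, fs, f_lo, f_hi) {
  spec <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  spec[f < f_lo | f > f_hi] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s
}

# one realisation of the community-template carrier: main narrowband
# component plus an optional secondary broadband component, unit RMS
template_carrier <- function(ev_len, fs, spec) {
  s <- narrowband_noise(ev_len, fs, spec$template_freq[1],
                        spec$template_freq[2])
  bb <- spec$template_broadband %||% 0
  if (bb > 0) {
    hi <- min(40, fs / 2 - 2)
    s <- (s + bb * narrowband_noise(ev_len, fs, 15, hi)) / sqrt(1 + bb^2)
  }
  s
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) && guard < 100L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
  }
  pmin(pmax(out, lower), upper)
}

# run length: number of consecutive same-community trials immediately
# preceding each trial (0 for the first trial of a community visit)
community_run_lengths <- function(graph, nodes) {
  cm <- graph$community[nodes]
  n <- length(cm)
  run <- integer(n)
  for (i in seq_len(n)) {
    run[i] <- if (i > 1 && cm[i] == cm[i - 1]) run[i - 1] + 1L else 0L
  }
  run
}

# ---- session simulation ------------------------------------------------------

#' Simulate a continuous EEG session with planted effects
#'
#' Builds a continuous multi-channel recording (scalp + EOG, microvolts) for a
#' trial sequence: 1/f background and 60 Hz line noise on every channel, a
#' condition-dependent P300-like parietal bump per trial, the trial community's
#' theta-band channel template, predictive mixing of the adjacent community's
#' template at boundary-node trials, blinks coupled into the EOG channels, and
#' rare high-amplitude spikes. All injected structure is logged as ground
#' truth for recovery tests.
#'
#' @param trials a `sequence_trials` data frame (from the sequence builders).
#' @param spec a `generative_spec`.
#' @param graph the `community_graph` the trials were generated on.
#' @param seed optional integer seed.
#' @return object of class `simulated_session`: list with `data` (channels x
#'   samples matrix, rownames = channel names), `sampling_rate`, `onsets`
#'   (sample index of each stimulus onset), `trials`, `spec`, and
#'   `ground_truth` (per-trial condition, P300 amplitude, mixing proportion,
#'   run length, spike trial indices, blink onset times).
#' @export
simulate_session <- function(trials, spec, graph, seed = NULL) {
  errs <- validate_generative_spec(spec)
  if (length(errs)) stop("invalid generative spec: ",
                         paste(errs, collapse = "; "))
  with_seed(seed, {
    fs <- spec$sampling_rate
    soa <- if ("duration_s" %in% names(trials)) trials$duration_s[1] else 1.25
    n_tr <- nrow(trials)
    pad <- as.integer(round(fs))
    n_samp <- as.integer(2L * pad + round(n_tr * soa * fs))
    montage <- spec$montage
    ch_names <- montage$name
    scalp_idx <- which(!montage$eog)
    eog_idx <- which(montage$eog)
    n_ch <- nrow(montage)

    data <- matrix(0, n_ch, n_samp, dimnames = list(ch_names, NULL))
    if (spec$noise_scale > 0) {
      for (c in seq_len(n_ch)) {
        sc <- if (montage$eog[c]) spec$noise_scale * 0.5 else spec$noise_scale
        data[c, ] <- one_over_f_noise(n_samp, spec$noise_beta, sc)
      }
    }
    if (spec$line_amp > 0) {
      tt <- (seq_len(n_samp) - 1L) / fs
      for (c in seq_len(n_ch)) {
        data[c, ] <- data[c, ] +
          spec$line_amp * sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi))
      }
    }

    onsets <- pad + as.integer(round((seq_len(n_tr) - 1L) * soa * fs)) + 1L
    ev_len <- as.integer(round(soa * fs))  # stimulus presentation span
    t_ev <- (seq_len(ev_len) - 1L) / fs

    # P300 bump and community templates, per trial
    p300_topo <- spatial_profile(montage, "Pz")
    bump <- exp(-(t_ev - spec$p300_latency_s)^2 / (2 * spec$p300_width_s^2))
    cond <- transition_condition(trials$transition_label)
    run_len <- community_run_lengths(graph, trials$node)
    alpha <- numeric(n_tr)
    tmpl <- spec$community_templates
    envelope <- sin(pi * seq_len(ev_len) / (ev_len + 1))^2
    for (i in seq_len(n_tr)) {
      sl <- onsets[i]:(onsets[i] + ev_len - 1L)
      amp <- spec$p300_amp[[cond[i]]]
      if (amp > 0) {
        data[scalp_idx, sl] <- data[scalp_idx, sl] +
          amp * outer(unname(p300_topo), bump)
      }
      if (spec$template_gain > 0) {
        cm <- graph$community[[trials$node[i]]]
        sig <- template_carrier(ev_len, fs, spec) * envelope
        data[scalp_idx, sl] <- data[scalp_idx, sl] +
          spec$template_gain * outer(tmpl[, cm], sig)
        if (graph$role[[trials$node[i]]] == "boundary") {
          a <- min(1, spec$predictive_mix[[1]] +
                     spec$predictive_mix[[2]] * run_len[i])
          alpha[i] <- a
          if (a > 0) {
            adj <- graph$community[[graph$boundary_partner[[trials$node[i]]]]]
            # sustained plateau from the mixing onset: 50 ms cosine rise,
            # 100 ms cosine fall at the end of the presentation
            mix_env <- pmin(1, pmax(0, (t_ev - spec$mix_onset_s) / 0.05)) *
              pmin(1, pmax(0, (max(t_ev) - t_ev) / 0.1))
            sig2 <- template_carrier(ev_len, fs, spec) * mix_env
            data[scalp_idx, sl] <- data[scalp_idx, sl] +
              a * spec$template_gain * outer(tmpl[, adj], sig2)
          }
        }
      }
    }

    # blinks: raised-cosine deflections, strong on EOG, frontal on scalp
    blink_times <- numeric(0)
    if (spec$blink_rate > 0 && spec$blink_amp > 0) {
      n_blink <- stats::rpois(1, spec$blink_rate * n_samp / fs)
      blen <- as.integer(round(0.4 * fs))
      bshape <- (1 - cos(2 * pi * seq_len(blen) / (blen + 1))) / 2
      frontal <- exp(-pmax(2.5 - montage$y[scalp_idx], 0)^2 / 3)
      if (n_blink > 0) {
        starts <- sort(sample.int(n_samp - blen, n_blink))
        blink_times <- (starts - 1L) / fs
        for (s in starts) {
          sl <- s:(s + blen - 1L)
          for (e in eog_idx) {
            data[e, sl] <- data[e, sl] + spec$blink_amp * bshape
          }
          data[scalp_idx, sl] <- data[scalp_idx, sl] +
            0.4 * spec$blink_amp * outer(frontal, bshape)
        }
      }
    }

    # rare high-amplitude spikes (ground truth for artifact rejection)
    spike_trials <- integer(0)
    if (spec$spike_rate > 0 && spec$spike_amp > 0) {
      hit <- which(stats::runif(n_tr) < spec$spike_rate)
      spike_trials <- hit
      slen <- max(3L, as.integer(round(0.03 * fs)))
      sshape <- sin(pi * seq_len(slen) / (slen + 1))
      span <- min(ev_len, as.integer(round(0.9 * fs)))  # inside the epoch window
      for (i in hit) {
        ch <- scalp_idx[sample.int(length(scalp_idx), 1)]
        at <- onsets[i] + sample.int(span - slen, 1)
        data[ch, at:(at + slen - 1L)] <- data[ch, at:(at + slen - 1L)] +
          spec$spike_amp * sshape * sample(c(-1, 1), 1)
      }
    }

    structure(list(
      data = data, sampling_rate = fs, onsets = onsets, trials = trials,
      spec = spec,
      ground_truth = list(condition = cond, p300_amp = spec$p300_amp[cond],
                          alpha = alpha, run_length = run_len,
                          spike_trials = spike_trials,
                          blink_times = blink_times)),
      class = "simulated_session")
  })
}

#' @export
print.simulated_session <- function(x, ...) {
  cat("simulated_session: ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sampling_rate, " Hz, ", length(x$onsets),
      " trials\n", sep = "")
  invisible(x)
}

# map transition labels to the three analysis conditions
transition_condition <- function(labels) {
  out <- rep("nonboundary", length(labels))
  out[!is.na(labels) & labels == "novel_boundary"] <- "novel"
  out[!is.na(labels) & labels == "learned_boundary"] <- "learned"
  out
}

# ---- behaviour ---------------------------------------------------------------

#' Simulate behavioural responses for a trial sequence
#'
#' Parsing-phase trials receive a Bernoulli parse decision with
#' condition-dependent probability and a truncated-normal response time;
#' exposure-phase trials receive rotation-task responses generated from hit /
#' false-alarm rates with condition-dependent response times. Both response
#' modes of the paradigm are supported: `"every_trial"` records a keypress
#' (and RT) on every trial, `"parse_only"` records responses only on parsed
#' trials.
#'
#' @param trials a `sequence_trials` data frame.
#' @param spec a `generative_spec`.
#' @param mode `"every_trial"` or `"parse_only"` (parsing phase only).
#' @param seed optional integer seed.
#' @return data frame aligned with `trials`: `index`, `condition`, and either
#'   `parse`/`rt_ms` (parsing) or `rotated`/`response_rotated`/`correct`/
#'   `rt_ms` (exposure).
#' @export
simulate_behavior <- function(trials, spec,
                              mode = c("every_trial", "parse_only"),
                              seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    n <- nrow(trials)
    cond <- transition_condition(trials$transition_label)
    if (trials$phase[1] == "exposure") {
      rotated <- trials$rotated
      p_yes <- ifelse(rotated, spec$rotation_hit, spec$rotation_fa)
      resp <- stats::runif(n) < p_yes
      lab <- ifelse(!is.na(trials$transition_label) &
                      trials$transition_label == "learned_boundary",
                    "learned_boundary", "nonboundary")
      rt <- rtruncnorm(n, spec$rotation_rt_mean[lab], spec$rotation_rt_sd,
                       150, 1250)
      data.frame(index = trials$index, condition = lab, rotated = rotated,
                 response_rotated = resp, correct = resp == rotated,
                 rt_ms = rt, stringsAsFactors = FALSE)
    } else {
      parse <- stats::runif(n) < spec$parse_prob[cond]
      rt <- rep(NA_real_, n)
      if (mode == "every_trial") {
        rt <- rtruncnorm(n, spec$parse_rt_mean[cond], spec$parse_rt_sd[cond],
                         150, 1250)
      } else {
        idx <- which(parse)
        rt[idx] <- rtruncnorm(length(idx), spec$parse_rt_mean[cond[idx]],
                              spec$parse_rt_sd[cond[idx]], 150, 1250)
      }
      data.frame(index = trials$index, condition = cond, parse = parse,
                 rt_ms = rt, mode = mode, stringsAsFactors = FALSE)
    }
  })
}

#' Simulate posttest answers
#'
#' @param posttest data frame from [build_posttest()].
#' @param spec a `generative_spec` (uses `posttest_acc`).
#' @param seed optional integer seed.
#' @return `posttest` with a logical `correct` column.
#' @export
simulate_posttest_answers <- function(posttest, spec, seed = NULL) {
  with_seed(seed, {
    posttest$correct <- stats::runif(nrow(posttest)) < spec$posttest_acc
    posttest
  })
}
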