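# Behavioural statistics: signal-detection sensitivity for the rotation task,
# parsing rates and response times, posttest scoring, and across-participant
# correlations.

#' Signal-detection sensitivity (d-prime)
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)` with the log-linear
#' correction (0.5 added to every cell) applied uniformly, so perfect
#' performance stays finite and estimates vary continuously.
#'
#' @param hits,misses,fas,crs non-negative counts (hits/misses on rotated
#'   trials, false alarms/correct rejections on non-rotated trials).
#' @return list with `dprime`, `hit_rate`, `fa_rate` (corrected rates).
#' @export
dprime <- function(hits, misses, fas, crs) {
  if (any(c(hits, misses, fas, crs) < 0)) stop("counts must be non-negative")
  n_sig <- hits + misses
  n_noise <- fas + crs
  if (n_sig == 0 || n_noise == 0) {
    stop("zero trials in the signal or noise class")
  }
  hr <- (hits + 0.5) / (n_sig + 1)
  fr <- (fas + 0.5) / (n_noise + 1)
  list(dprime = stats::qnorm(hr) - stats::qnorm(fr), hit_rate = hr,
       fa_rate = fr)
}

#' Rotation-task summary for one participant
#'
#' d-prime overall and per transition condition, with response times.
#'
#' @param behavior exposure-phase table from [simulate_behavior()].
#' @return data frame with one row per condition (plus `overall`): `dprime`,
#'   `rt_mean`, `n`.
#' @export
rotation_summary <- function(behavior) {
  summarise <- function(df, label) {
    counts <- c(hits = sum(df$rotated & df$response_rotated),
                misses = sum(df$rotated & !df$response_rotated),
                fas = sum(!df$rotated & df$response_rotated),
                crs = sum(!df$rotated & !df$response_rotated))
    dp <- dprime(counts[1], counts[2], counts[3], counts[4])
    data.frame(condition = label, dprime = dp$dprime,
               rt_mean = mean(df$rt_ms, na.rm = TRUE), n = nrow(df),
               stringsAsFactors = FALSE)
  }
  out <- summarise(behavior, "overall")
  for (cond in c("learned_boundary", "nonboundary")) {
    df <- behavior[behavior$condition == cond, , drop = FALSE]
    if (nrow(df)) out <- rbind(out, summarise(df, cond))
  }
  out
}

#' Parsing summary across participants with condition statistics
#'
#' Per participant and condition: percentage of trials parsed and mean RT of
#' parsed trials; across participants: repeated-measures ANOVA and pairwise
#' paired t tests on both measures.
#'
#' @param behavior_list list of parsing-phase behaviour tables (one per
#'   participant) from [simulate_behavior()].
#' @return list with `summary` (participant x condition parse % / RT),
#'   `parse_stats`, `rt_stats` (each a `stats_result_set`).
#' @export
parsing_summary <- function(behavior_list) {
  per <- do.call(rbind, lapply(seq_along(behavior_list), function(p) {
    beh <- behavior_list[[p]]
    do.call(rbind, lapply(c("novel", "learned", "nonboundary"), function(cond) {
      df <- beh[beh$condition == cond, , drop = FALSE]
      rts <- df$rt_ms[df$parse %in% TRUE]
      if (nrow(df) && !length(rts)) {
        message("participant ", p, ": no parses in condition ", cond,
                "; RT recorded as missing")
      }
      data.frame(participant = p, condition = cond,
                 parse_pct = 100 * mean(df$parse %in% TRUE),
                 rt_mean = if (length(rts)) mean(rts, na.rm = TRUE)
                           else NA_real_,
                 n = nrow(df), stringsAsFactors = FALSE)
    }))
  }))
  parse_means <- data.frame(participant = per$participant,
                            condition = per$condition, value = per$parse_pct)
  rt_means <- data.frame(participant = per$participant,
                         condition = per$condition, value = per$rt_mean)
  run_stats <- length(behavior_list) >= 2
  list(summary = per,
       parse_stats = if (run_stats) condition_contrasts(parse_means),
       rt_stats = if (run_stats)
         condition_contrasts(rt_means[!is.na(rt_means$value), ]))
}

#' Score posttest answers and test the group against chance
#'
#' @param answers_list list of answered posttest tables (logical `correct`
#'   column), one per participant; missing answers are dropped with a
#'   message.
#' @param chance chance level in percent (default 50).
#' @return list with `percent_correct` (per participant), `mean`, and
#'   `wilcoxon` (V statistic and p of the signed-rank test vs chance).
#' @export
posttest_score <- function(answers_list, chance = 50) {
  if (is.data.frame(answers_list)) answers_list <- list(answers_list)
  pc <- vapply(seq_along(answers_list), function(p) {
    a <- answers_list[[p]]$correct
    if (length(a) == 0) stop("participant ", p, ": no posttest answers")
    if (anyNA(a)) {
      message("participant ", p, ": ", sum(is.na(a)), " missing answer(s)")
      a <- a[!is.na(a)]
    }
    100 * mean(a)
  }, numeric(1))
  wt <- if (length(pc) >= 2 && stats::sd(pc) > 0) {
    suppressWarnings(stats::wilcox.test(pc, mu = chance))
  } else NULL
  list(percent_correct = pc, mean = mean(pc),
       wilcoxon = if (!is.null(wt)) data.frame(V = unname(wt$statistic),
                                               p = wt$p.value) else NULL)
}

#' Across-participant Pearson correlation
#'
#' @param x,y equal-length participant vectors (length >= 3).
#' @return data frame: `r`, `df` (N - 2), `p`, `r_sq`.
#' @export
across_participant_correlation <- function(x, y) {
  brain_behavior_correlation(x, y)
}
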