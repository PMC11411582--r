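# P300 / windowed-amplitude analyses: per-condition window means, repeated-
# measures condition contrasts, brain-behaviour correlations, and the
# permutation contrast between condition-specific correlations.

#' Mean voltage in an analysis window at one electrode
#'
#' Averages the baseline-corrected voltage within a poststimulus window
#' (left-closed, right-open in milliseconds) at a single electrode, per epoch,
#' and optionally aggregates per condition.
#'
#' @param epochs an `epoch_array`.
#' @param electrode channel name (default `"Pz"`).
#' @param window `c(lo, hi)` in ms (default the 250-450 ms P300 window; use
#'   `c(50, 250)` for the early-peak control).
#' @param by_condition when TRUE (default) also return per-condition means
#'   using the metadata's transition labels; rejected epochs are excluded.
#' @return list with `per_epoch` (numeric, NA for rejected epochs) and, when
#'   requested, `per_condition` (named mean amplitude for
#'   novel/learned/nonboundary).
#' @export
window_amplitude <- function(epochs, electrode = "Pz", window = c(250, 450),
                             by_condition = TRUE) {
  ci <- match(electrode, epochs$channels)
  if (is.na(ci)) {
    stop("electrode '", electrode, "' not found; available: ",
         paste(epochs$channels, collapse = ", "))
  }
  sidx <- which(epochs$times_ms >= window[1] & epochs$times_ms < window[2])
  amp <- apply(epochs$voltage[, ci, sidx, drop = FALSE], 1, mean)
  amp[epochs$rejected] <- NA_real_
  out <- list(per_epoch = amp)
  if (by_condition && !is.null(epochs$metadata)) {
    cond <- transition_condition(epochs$metadata$transition_label)
    out$per_condition <- tapply(amp, factor(cond, levels = c("novel",
      "learned", "nonboundary")), mean, na.rm = TRUE)
  }
  out
}

# paired-samples Cohen's d
cohens_d_paired <- function(x, y) {
  d <- x - y
  mean(d) / stats::sd(d)
}

#' Repeated-measures contrast of per-condition participant means
#'
#' One-way repeated-measures ANOVA over the three transition conditions plus
#' pairwise paired t tests, with eta-squared and Cohen's d effect sizes.
#' Participants missing any condition are dropped (reported in the result).
#'
#' @param means data frame with columns `participant`, `condition`
#'   (novel/learned/nonboundary), `value`.
#' @return object of class `stats_result_set`: list with `anova` (data frame:
#'   statistic, df1, df2, p, eta_sq), `pairwise` (data frame of paired t
#'   tests with Cohen's d), `n`, `dropped`.
#' @export
condition_contrasts <- function(means) {
  wide <- stats::reshape(means[, c("participant", "condition", "value")],
                         idvar = "participant", timevar = "condition",
                         direction = "wide")
  conds <- intersect(c("novel", "learned", "nonboundary"),
                     unique(means$condition))
  cols <- paste0("value.", conds)
  complete <- stats::complete.cases(wide[, cols])
  dropped <- wide$participant[!complete]
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)
  if (n < 2) stop("need at least 2 complete participants")
  long <- data.frame(
    participant = factor(rep(wide$participant, length(conds))),
    condition = factor(rep(conds, each = n)),
    value = unlist(wide[, cols], use.names = FALSE))
  fit <- stats::aov(value ~ condition + Error(participant / condition),
                    data = long)
  tab <- summary(fit)[["Error: participant:condition"]][[1]]
  ss_cond <- tab["condition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  an <- data.frame(statistic = tab["condition", "F value"],
                   df1 = tab["condition", "Df"],
                   df2 = tab["Residuals", "Df"],
                   p = tab["condition", "Pr(>F)"],
                   eta_sq = ss_cond / (ss_cond + ss_err))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    x <- wide[[paste0("value.", pr[1])]]
    y <- wide[[paste0("value.", pr[2])]]
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(a = pr[1], b = pr[2], statistic = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               cohens_d = cohens_d_paired(x, y))
  }))
  structure(list(anova = an, pairwise = pw, n = n, dropped = dropped,
                 means = colMeans(wide[, cols])),
            class = "stats_result_set")
}

#' @export
print.stats_result_set <- function(x, ...) {
  a <- x$anova
  cat(sprintf("repeated-measures ANOVA: F(%d,%d) = %.2f, p = %.4g, eta^2 = %.3f (n = %d)\n",
              a$df1, a$df2, a$statistic, a$p, a$eta_sq, x$n))
  for (i in seq_len(nrow(x$pairwise))) {
    p <- x$pairwise[i, ]
    cat(sprintf("  %s vs %s: t(%d) = %.2f, p = %.4g, d = %.2f\n",
                p$a, p$b, p$df, p$statistic, p$p, p$cohens_d))
  }
  invisible(x)
}

#' Correlate a neural difference with a behavioural difference
#'
#' Pearson correlation across participants (e.g., novel-minus-nonboundary P300
#' amplitude against novel-minus-nonboundary parse probability).
#'
#' @param delta_neural,delta_behavior equal-length participant vectors.
#' @return data frame: `r`, `df`, `p`, `r_sq`.
#' @export
brain_behavior_correlation <- function(delta_neural, delta_behavior) {
  stopifnot(length(delta_neural) == length(delta_behavior),
            length(delta_neural) >= 3)
  if (stats::sd(delta_neural) == 0 || stats::sd(delta_behavior) == 0) {
    stop("correlation undefined: zero variance input")
  }
  ct <- stats::cor.test(delta_neural, delta_behavior)
  data.frame(r = unname(ct$estimate), df = unname(ct$parameter),
             p = ct$p.value, r_sq = unname(ct$estimate)^2)
}

#' Permutation test for a difference between two condition correlations
#'
#' The observed statistic is `cor(novel pairs) - cor(learned pairs)` over
#' participants. The null is built by independently swapping, per participant,
#' which condition's (neural difference, behavioural difference) pair carries
#' the novel label; the two-tailed p is `(1 + #{|null| >= |obs|}) /
#' (1 + n_perm)`.
#'
#' @param novel_pairs,learned_pairs two-column matrices (neural, behaviour),
#'   one row per participant, aligned.
#' @param n_perm permutations (default 10000; < 100 warns).
#' @param seed optional integer seed.
#' @return list: `observed` (r difference), `r_novel`, `r_learned`, `p`,
#'   `null` (the permutation distribution).
#' @export
correlation_difference_permutation <- function(novel_pairs, learned_pairs,
                                               n_perm = 10000, seed = NULL) {
  novel_pairs <- as.matrix(novel_pairs)
  learned_pairs <- as.matrix(learned_pairs)
  stopifnot(nrow(novel_pairs) == nrow(learned_pairs), ncol(novel_pairs) == 2)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  n <- nrow(novel_pairs)
  stat <- function(np, lp) {
    stats::cor(np[, 1], np[, 2]) - stats::cor(lp[, 1], lp[, 2])
  }
  obs <- stat(novel_pairs, learned_pairs)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(k) {
      swap <- stats::runif(n) < 0.5
      np <- novel_pairs
      lp <- learned_pairs
      np[swap, ] <- learned_pairs[swap, ]
      lp[swap, ] <- novel_pairs[swap, ]
      stat(np, lp)
    }, numeric(1))
    p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
    list(observed = obs,
         r_novel = stats::cor(novel_pairs[, 1], novel_pairs[, 2]),
         r_learned = stats::cor(learned_pairs[, 1], learned_pairs[, 2]),
         p = p, null = null)
  })
}
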