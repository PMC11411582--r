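# Lag-matched representational pattern similarity across novel / learned /
# nonboundary spans within Hamiltonian blocks, and the boundary-position
# item-level similarity contrast.

#' Find lag-matched inner-node epoch pairs within Hamiltonian blocks
#'
#' Identifies pairs of trials (i, i+lag) that both lie inside the same
#' Hamiltonian block, are both inner-node epochs (and not swap-involved), and
#' for which no trial in the span carries a parse response. The pair's
#' condition is assigned from the intervening transition labels: a span
#' containing the manipulated between-community transition is `novel`, one
#' containing an unmanipulated between-community transition is `learned`, and
#' spans with only within-community transitions are `nonboundary`.
#'
#' @param trials a `sequence_trials` data frame for the parsing phase.
#' @param behavior behavioural table from [simulate_behavior()] (needs
#'   `parse`), aligned by `index`; `NULL` skips the parse filter.
#' @param graph the `community_graph`.
#' @param lag interitem lag (default 3).
#' @param parse_filter `"span"` (default: no parse anywhere in the closed span
#'   `[i, i+lag]`) or `"endpoints"` (endpoints only).
#' @return data frame with `i`, `j` (trial indices, 0-based as in `trials`),
#'   `condition`, `block`.
#' @export
find_pairs <- function(trials, behavior = NULL, graph, lag = 3,
                       parse_filter = c("span", "endpoints")) {
  parse_filter <- match.arg(parse_filter)
  n <- nrow(trials)
  parse <- rep(FALSE, n)
  if (!is.null(behavior)) {
    parse[match(behavior$index, trials$index)] <- behavior$parse %in% TRUE
  }
  ham <- trials$block_kind == "hamiltonian"
  block_id <- cumsum(c(TRUE, trials$block_kind[-1] != trials$block_kind[-n]))
  role <- graph$role[trials$node]
  swapped <- if (is.null(trials$swapped)) rep(FALSE, n) else trials$swapped
  rows <- list()
  for (a in seq_len(n - lag)) {
    b <- a + lag
    if (!ham[a] || !ham[b] || block_id[a] != block_id[b]) next
    if (role[a] != "inner" || role[b] != "inner") next
    if (swapped[a] || swapped[b]) next
    span <- a:b
    if (parse_filter == "span") {
      if (any(parse[span])) next
    } else {
      if (parse[a] || parse[b]) next
    }
    labs <- trials$transition_label[(a + 1):b]
    condition <- if (any(labs == "novel_boundary", na.rm = TRUE)) "novel"
      else if (any(labs == "learned_boundary", na.rm = TRUE)) "learned"
      else "nonboundary"
    rows[[length(rows) + 1L]] <- data.frame(
      i = trials$index[a], j = trials$index[b], condition = condition,
      block = block_id[a], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      condition = character(0), block = integer(0)))
  }
  do.call(rbind, rows)
}

# Fisher r-to-z with the degenerate |r| = 1 guard
fisher_z <- function(r, clip = 1 - 1e-10) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Pattern similarity of epoch pairs over retained PC scores
#'
#' Computes the Pearson correlation between the two trials of each pair over
#' the retained principal component scores, applies the Fisher r-to-z
#' transform (values at |r| = 1 are clipped before `atanh`), and averages
#' within condition.
#'
#' @param pc a `pc_space` whose `scores` rows correspond to `trial_index`.
#' @param pairs data frame from [find_pairs()].
#' @param trial_index trial indices (0-based) labelling the score rows
#'   (default `0:(n-1)`).
#' @return list with `pair_z` (per-pair data frame adding `r` and `z`) and
#'   `condition_means` (named mean z per condition).
#' @export
pair_similarity <- function(pc, pairs, trial_index = NULL) {
  scores <- pc$scores
  if (is.null(trial_index)) trial_index <- seq_len(nrow(scores)) - 1L
  ri <- match(pairs$i, trial_index)
  rj <- match(pairs$j, trial_index)
  ok <- !is.na(ri) & !is.na(rj)
  pairs <- pairs[ok, , drop = FALSE]
  ri <- ri[ok]
  rj <- rj[ok]
  r <- vapply(seq_along(ri), function(k) {
    stats::cor(scores[ri[k], ], scores[rj[k], ])
  }, numeric(1))
  z <- fisher_z(r)
  pair_z <- cbind(pairs, r = r, z = z)
  condition_means <- tapply(z, factor(pair_z$condition,
                                      levels = c("novel", "learned",
                                                 "nonboundary")), mean)
  list(pair_z = pair_z, condition_means = condition_means)
}

#' Group-level similarity contrast across participants
#'
#' Takes per-participant condition mean z values and runs the one-way
#' repeated-measures ANOVA plus pairwise paired t tests. Participants missing
#' any condition are dropped.
#'
#' @param means data frame with `participant`, `condition`, `value` (mean z).
#' @return a `stats_result_set` (see [condition_contrasts()]).
#' @export
similarity_contrasts <- function(means) {
  condition_contrasts(means)
}

#' Item-level similarity at boundary positions
#'
#' Contrasts the similarity of epochs from the two true boundary nodes of a
#' manipulated transition (learned-learned) against the similarity of a true
#' boundary node's epochs with the swapped-in inner node occupying the other
#' boundary position (learned-novel). Epochs are compared through their
#' retained PC scores and similarities are Fisher-z averaged per pair type.
#'
#' @param pc a `pc_space`.
#' @param trials the parsing-phase `sequence_trials` (with `swapped`).
#' @param graph the `community_graph`.
#' @param schedule the `manipulation_schedule` used (default from `trials`).
#' @param trial_index trial indices labelling the score rows.
#' @param min_epochs minimum epochs per node set (default 2).
#' @return list with `z_learned_learned`, `z_learned_novel`, and `detail`
#'   (per manipulated transition), or `NULL` when no block provides enough
#'   epochs (a message is emitted).
#' @export
boundary_item_similarity <- function(pc, trials, graph, schedule = NULL,
                                     trial_index = NULL, min_epochs = 2) {
  if (is.null(schedule)) schedule <- attr(trials, "schedule")
  stopifnot(!is.null(schedule))
  scores <- pc$scores
  if (is.null(trial_index)) trial_index <- seq_len(nrow(scores)) - 1L
  rows <- list()
  for (b in seq_len(nrow(schedule))) {
    sw <- schedule_swap(schedule, b)
    if (length(sw) == 0) next
    bl <- schedule_block(schedule, trials$index + 1L) == b
    u <- schedule$edge_u[b]
    v <- schedule$edge_v[b]
    # epochs displaying each item's own stimulus (boundary-node visits during
    # the manipulated block are excluded since they display the partner), and
    # epochs of the swapped-in item occupying the boundary position (visits
    # to the boundary node during the block, displaying the inner partner's
    # stimulus)
    own <- function(nd) {
      idx <- trials$index[trials$node == nd & !(trials$swapped %in% TRUE)]
      match(idx, trial_index)
    }
    occupying <- function(bnode) {
      idx <- trials$index[bl & trials$node == bnode &
                            (trials$swapped %in% TRUE)]
      match(idx, trial_index)
    }
    drop_na <- function(ix) ix[!is.na(ix)]
    eu <- drop_na(own(u)); ev <- drop_na(own(v))
    ou <- drop_na(occupying(u)); ov <- drop_na(occupying(v))
    if (length(eu) < min_epochs || length(ev) < min_epochs) next
    mean_sim <- function(ix1, ix2) {
      if (length(ix1) == 0 || length(ix2) == 0) return(NA_real_)
      rs <- as.vector(stats::cor(t(scores[ix1, , drop = FALSE]),
                                 t(scores[ix2, , drop = FALSE])))
      mean(fisher_z(rs))
    }
    ll <- mean_sim(eu, ev)
    ln <- mean(c(mean_sim(eu, ov), mean_sim(ev, ou)), na.rm = TRUE)
    if (is.na(ll) || is.na(ln)) next
    rows[[length(rows) + 1L]] <- data.frame(block = b, edge = paste0(u, v),
                                            z_ll = ll, z_ln = ln)
  }
  if (length(rows) == 0) {
    message("no manipulated block with enough epochs; participant dropped")
    return(NULL)
  }
  detail <- do.call(rbind, rows)
  list(z_learned_learned = mean(detail$z_ll),
       z_learned_novel = mean(detail$z_ln), detail = detail)
}
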