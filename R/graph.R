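#' @keywords internal
"_PACKAGE"

# ---- seeding helpers ---------------------------------------------------------

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous RNG
#' state afterwards. With `seed = NULL` the code runs under the current RNG.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a parent seed
#'
#' Deterministic splitting so that independent stages of a pipeline can be
#' seeded from one named seed. Kept below 2^31.
#'
#' @param seed parent integer seed (or `NULL`, returning `NULL`).
#' @param k non-negative integer stream index.
#' @return integer seed or `NULL`.
#' @export
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 69069 + 48271 * as.double(k) + 1) %% 2147483647)
}

# ---- community graph ---------------------------------------------------------

#' Build the 15-node temporal community graph
#'
#' Constructs the standard three-community, degree-4 regular graph used in
#' temporal community structure experiments: communities `{a-e}`, `{f-j}`,
#' `{k-o}`, each with three inner nodes fully connected to their four community
#' members and two boundary nodes each carrying the single edge to the adjacent
#' community. The three between-community edges (`e-f`, `j-k`, `o-a`) join the
#' communities into a ring. Every node has degree 4 and community membership is
#' invisible to local degree.
#'
#' @param seed optional integer; when given, stimulus ids are drawn uniformly
#'   without replacement from a pool of `n_stimulus_pool` ids and assigned to
#'   nodes. Without a seed the assignment is the identity `1:15`.
#' @param n_stimulus_pool size of the stimulus pool to draw from (default 74).
#' @return an object of class `community_graph`: list with `nodes`, `adjacency`
#'   (symmetric logical matrix), `community` (named integer), `role` (named
#'   character, `"inner"`/`"boundary"`), `stimulus` (named integer map),
#'   `between_edges` (3 x 2 character matrix), and `boundary_partner` (named
#'   character: cross-community neighbour of each boundary node).
#' @export
build_graph <- function(seed = NULL, n_stimulus_pool = 74) {
  nodes <- letters[1:15]
  community <- rep(1:3, each = 5)
  names(community) <- nodes
  # boundary nodes: first and last of each community block
  role <- rep("inner", 15)
  names(role) <- nodes
  role[c("a", "e", "f", "j", "k", "o")] <- "boundary"

  adj <- matrix(FALSE, 15, 15, dimnames = list(nodes, nodes))
  for (cm in 1:3) {
    members <- nodes[community == cm]
    inner <- members[role[members] == "inner"]
    bound <- members[role[members] == "boundary"]
    # inner nodes fully connected among themselves and to both boundary nodes
    for (i in seq_along(inner)) for (j in seq_along(inner)) {
      if (i < j) adj[inner[i], inner[j]] <- adj[inner[j], inner[i]] <- TRUE
    }
    for (b in bound) for (i in inner) adj[b, i] <- adj[i, b] <- TRUE
  }
  between <- rbind(c("e", "f"), c("j", "k"), c("o", "a"))
  for (r in seq_len(nrow(between))) {
    adj[between[r, 1], between[r, 2]] <- TRUE
    adj[between[r, 2], between[r, 1]] <- TRUE
  }

  boundary_partner <- c(a = "o", e = "f", f = "e", j = "k", k = "j", o = "a")

  stimulus <- if (is.null(seed)) {
    stats::setNames(1:15, nodes)
  } else {
    with_seed(seed, stats::setNames(sample.int(n_stimulus_pool, 15), nodes))
  }

  structure(
    list(nodes = nodes, adjacency = adj, community = community, role = role,
         stimulus = stimulus, between_edges = between,
         boundary_partner = boundary_partner),
    class = "community_graph")
}

#' @export
print.community_graph <- function(x, ...) {
  cat("community_graph: ", length(x$nodes), " nodes, ",
      sum(x$adjacency) / 2, " edges, ",
      length(unique(x$community)), " communities\n", sep = "")
  cat("boundary nodes:", paste(names(x$role)[x$role == "boundary"],
                               collapse = " "), "\n")
  invisible(x)
}

graph_neighbors <- function(graph, node) {
  graph$nodes[graph$adjacency[node, ]]
}

is_edge <- function(graph, u, v) graph$adjacency[u, v]

inner_nodes <- function(graph, cm) {
  graph$nodes[graph$community == cm & graph$role == "inner"]
}

boundary_nodes <- function(graph, cm) {
  graph$nodes[graph$community == cm & graph$role == "boundary"]
}

# ---- walks -------------------------------------------------------------------

#' Uniform random walk on the community graph
#'
#' @param graph a `community_graph`.
#' @param length number of nodes in the walk (>= 1).
#' @param start starting node (defaults to a uniformly chosen node).
#' @param seed optional integer seed.
#' @return character vector of visited nodes, first element `start`.
#' @export
random_walk <- function(graph, length, start = NULL, seed = NULL) {
  if (length < 1) stop("walk length must be >= 1")
  with_seed(seed, {
    if (is.null(start)) start <- sample(graph$nodes, 1)
    stopifnot(start %in% graph$nodes)
    out <- character(length)
    out[1] <- start
    for (i in seq_len(length - 1L)) {
      nb <- graph_neighbors(graph, out[i])
      out[i + 1L] <- nb[sample.int(length(nb), 1)]
    }
    out
  })
}

#' Pseudorandom walk with forced community exits
#'
#' Like [random_walk()], except that once `force_after` consecutive
#' same-community stimuli have occurred, the next visit to a boundary node must
#' take its between-community edge. The counter resets on every community
#' change, forced or spontaneous. Forcing increases the number of community
#' transitions relative to a plain random walk.
#'
#' @inheritParams random_walk
#' @param force_after consecutive same-community stimuli that trigger a forced
#'   exit at the next boundary-node visit (default 9; `Inf` disables forcing).
#' @return character vector of visited nodes.
#' @export
pseudorandom_walk <- function(graph, length, start = NULL, force_after = 9,
                              seed = NULL) {
  if (length < 1) stop("walk length must be >= 1")
  with_seed(seed, {
    if (is.null(start)) start <- sample(graph$nodes, 1)
    stopifnot(start %in% graph$nodes)
    out <- character(length)
    out[1] <- start
    run <- 1L  # consecutive stimuli in the current community, incl. current
    for (i in seq_len(length - 1L)) {
      u <- out[i]
      forced <- is.finite(force_after) && run >= force_after &&
        graph$role[u] == "boundary"
      if (forced) {
        nxt <- graph$boundary_partner[[u]]
      } else {
        nb <- graph_neighbors(graph, u)
        nxt <- nb[sample.int(length(nb), 1)]
      }
      if (graph$community[[nxt]] != graph$community[[u]]) run <- 1L
      else run <- run + 1L
      out[i + 1L] <- nxt
    }
    out
  })
}

# ---- Hamiltonian paths -------------------------------------------------------

#' Enumerate all Hamiltonian paths from a start node
#'
#' Exhaustive depth-first enumeration; on the standard 15-node graph this is
#' fast. Used as the independent oracle for path properties (every path on the
#' standard graph crosses between communities exactly twice).
#'
#' @param graph a `community_graph`.
#' @param start start node.
#' @param limit stop after this many paths (default all).
#' @return list of character vectors, each a Hamiltonian path.
#' @export
enumerate_hamiltonian <- function(graph, start, limit = Inf) {
  n <- length(graph$nodes)
  found <- list()
  path <- character(n)
  visited <- stats::setNames(rep(FALSE, n), graph$nodes)
  recurse <- function(u, depth) {
    if (length(found) >= limit) return(invisible(NULL))
    path[depth] <<- u
    visited[u] <<- TRUE
    if (depth == n) {
      found[[length(found) + 1L]] <<- path
    } else {
      for (v in graph_neighbors(graph, u)) {
        if (!visited[v]) recurse(v, depth + 1L)
      }
    }
    visited[u] <<- FALSE
    invisible(NULL)
  }
  recurse(start, 1L)
  found
}

community_crossings <- function(graph, path) {
  n <- length(path)
  sum(graph$community[path[-1]] != graph$community[path[-n]])
}

# randomized depth-first search for a single Hamiltonian path
random_hamiltonian <- function(graph, start) {
  n <- length(graph$nodes)
  path <- character(n)
  visited <- stats::setNames(rep(FALSE, n), graph$nodes)
  ok <- FALSE
  recurse <- function(u, depth) {
    if (ok) return(invisible(NULL))
    path[depth] <<- u
    visited[u] <<- TRUE
    if (depth == n) {
      ok <<- TRUE
      return(invisible(NULL))
    }
    nb <- graph_neighbors(graph, u)
    for (v in sample(nb, length(nb))) {
      if (!visited[v]) {
        recurse(v, depth + 1L)
        if (ok) return(invisible(NULL))
      }
    }
    visited[u] <<- FALSE
    invisible(NULL)
  }
  recurse(start, 1L)
  if (!ok) stop("no Hamiltonian path from node '", start, "'")
  path
}

# randomized Hamiltonian path from `start` with the minimum (2) community
# crossings; such a path exists from every node of the standard graph
contiguous_hamiltonian <- function(graph, start, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    p <- random_hamiltonian(graph, start)
    if (community_crossings(graph, p) == 2L) return(p)
  }
  random_hamiltonian(graph, start)
}

#' Pre-generate a pool of Hamiltonian paths
#'
#' By default the pool is restricted to paths that traverse each community as
#' one contiguous stretch, so every pooled path contributes exactly two
#' between-community transitions (the enumerated minimum on the standard
#' graph). This keeps the design statistic of the parsing phase -- manipulated
#' transitions as a fixed share of all transitions -- at its intended value.
#'
#' @param graph a `community_graph`.
#' @param size number of distinct paths (default 15).
#' @param contiguous restrict to minimum-crossing paths (default TRUE).
#' @param seed optional integer seed.
#' @return list of character vectors.
#' @export
hamiltonian_pool <- function(graph, size = 15, contiguous = TRUE, seed = NULL) {
  with_seed(seed, {
    pool <- list()
    keys <- character(0)
    guard <- 0L
    while (length(pool) < size && guard < 5000L) {
      guard <- guard + 1L
      p <- random_hamiltonian(graph, sample(graph$nodes, 1))
      if (contiguous && community_crossings(graph, p) > 2L) next
      k <- paste(p, collapse = "")
      if (!k %in% keys) {
        pool[[length(pool) + 1L]] <- p
        keys <- c(keys, k)
      }
    }
    pool
  })
}

#' Draw a Hamiltonian path starting at a given node
#'
#' Selects pseudorandomly from a pre-generated pool of paths, restricted to
#' paths beginning at `start`. When the pool contains no such path, a fresh
#' randomized path from `start` is generated (the standard graph admits
#' Hamiltonian paths from every node).
#'
#' @param graph a `community_graph`.
#' @param start required first node.
#' @param pool optional list of paths from [hamiltonian_pool()].
#' @param pool_size pool size when `pool` is not supplied.
#' @param seed optional integer seed.
#' @return character vector of 15 nodes, each visited exactly once.
#' @export
hamiltonian_path <- function(graph, start, pool = NULL, pool_size = 15,
                             seed = NULL) {
  stopifnot(start %in% graph$nodes)
  with_seed(seed, {
    if (is.null(pool)) pool <- hamiltonian_pool(graph, pool_size)
    cand <- Filter(function(p) p[1] == start, pool)
    if (length(cand) > 0) return(cand[[sample.int(length(cand), 1)]])
    contiguous_hamiltonian(graph, start)
  })
}

# ---- manipulation schedule ---------------------------------------------------

#' Build the boundary-manipulation schedule for the parsing phase
#'
#' One of the three community transitions is manipulated per 200-stimulus
#' block, cycling so that each transition is manipulated equally often (twice
#' over the six blocks of a 1,200-trial phase). Within a block, each boundary
#' node of the manipulated transition is swapped with a randomly chosen inner
#' node of its own community; swap partners stay constant within the block.
#'
#' @param graph a `community_graph`.
#' @param n_trials parsing-phase length (default 1200).
#' @param block_len manipulation block length in trials (default 200).
#' @param seed optional integer seed.
#' @return object of class `manipulation_schedule`: data frame with one row per
#'   block (`block`, `edge_u`, `edge_v`) and a `swap` attribute (list of named
#'   character vectors mapping node -> swap partner, bidirectional).
#' @export
manipulation_schedule <- function(graph, n_trials = 1200, block_len = 200,
                                  seed = NULL) {
  n_blocks <- ceiling(n_trials / block_len)
  with_seed(seed, {
    reps <- ceiling(n_blocks / 3)
    order <- unlist(lapply(seq_len(reps), function(i) sample.int(3)))[seq_len(n_blocks)]
    swaps <- vector("list", n_blocks)
    df <- data.frame(block = seq_len(n_blocks),
                     edge_u = graph$between_edges[order, 1],
                     edge_v = graph$between_edges[order, 2],
                     stringsAsFactors = FALSE)
    for (b in seq_len(n_blocks)) {
      sw <- character(0)
      for (node in c(df$edge_u[b], df$edge_v[b])) {
        inn <- inner_nodes(graph, graph$community[[node]])
        partner <- inn[sample.int(length(inn), 1)]
        sw[node] <- partner
        sw[partner] <- node
      }
      swaps[[b]] <- sw
    }
    attr(df, "swap") <- swaps
    attr(df, "block_len") <- block_len
    class(df) <- c("manipulation_schedule", "data.frame")
    df
  })
}

#' An empty manipulation schedule (no swapped transitions)
#' @param n_trials,block_len as in [manipulation_schedule()].
#' @return a `manipulation_schedule` with zero manipulated blocks.
#' @export
empty_schedule <- function(n_trials = 1200, block_len = 200) {
  df <- data.frame(block = integer(0), edge_u = character(0),
                   edge_v = character(0), stringsAsFactors = FALSE)
  attr(df, "swap") <- list()
  attr(df, "block_len") <- block_len
  class(df) <- c("manipulation_schedule", "data.frame")
  df
}

schedule_block <- function(schedule, trial_index) {
  ((trial_index - 1L) %/% attr(schedule, "block_len")) + 1L
}

manipulated_edge <- function(schedule, block) {
  if (block > nrow(schedule)) return(NULL)
  c(schedule$edge_u[block], schedule$edge_v[block])
}

schedule_swap <- function(schedule, block) {
  sw <- attr(schedule, "swap")
  if (block > length(sw)) return(character(0))
  sw[[block]]
}

# ---- sequence assembly -------------------------------------------------------

new_sequence_trials <- function(df) {
  class(df) <- c("sequence_trials", "data.frame")
  df
}

#' Label transitions into each trial
#'
#' The transition into trial *i* is labelled by the node pair
#' (`node[i-1]`, `node[i]`): within-community steps are `nonboundary`;
#' between-community steps crossing the transition manipulated in trial *i*'s
#' 200-trial block are `novel_boundary`; other between-community steps are
#' `learned_boundary`. Non-adjacent junctions (only possible under the
#' `same_node` Hamiltonian origination) are `seam`. The first trial is `NA`.
#'
#' @param trials a `sequence_trials` data frame with a `node` column.
#' @param graph a `community_graph`.
#' @param schedule a `manipulation_schedule` (use [empty_schedule()] for none).
#' @return character vector of labels, one per trial.
#' @export
label_transitions <- function(trials, graph, schedule) {
  n <- nrow(trials)
  lab <- rep(NA_character_, n)
  if (n < 2) return(lab)
  u <- trials$node[-n]
  v <- trials$node[-1]
  for (i in seq_len(n - 1L)) {
    if (u[i] == v[i] || !is_edge(graph, u[i], v[i])) {
      lab[i + 1L] <- "seam"
    } else if (graph$community[[u[i]]] == graph$community[[v[i]]]) {
      lab[i + 1L] <- "nonboundary"
    } else {
      blk <- schedule_block(schedule, i + 1L)
      me <- manipulated_edge(schedule, blk)
      if (!is.null(me) && all(sort(c(u[i], v[i])) == sort(me))) {
        lab[i + 1L] <- "novel_boundary"
      } else {
        lab[i + 1L] <- "learned_boundary"
      }
    }
  }
  lab
}

#' Apply the boundary-stimulus swap to a trial sequence
#'
#' Within a manipulated 200-trial block, each boundary node of the manipulated
#' transition displays its swap partner's stimulus and the partner inner node
#' displays the boundary node's stimulus (a bidirectional swap). Outside
#' manipulated blocks the mapping is the identity.
#'
#' @param trials a `sequence_trials` data frame with `node` column.
#' @param schedule a `manipulation_schedule`.
#' @param graph a `community_graph` providing the node -> stimulus map.
#' @return `trials` with a `stimulus` column (and `swapped` logical).
#' @export
apply_boundary_swap <- function(trials, schedule, graph) {
  stim <- graph$stimulus[trials$node]
  swapped <- rep(FALSE, nrow(trials))
  if (nrow(schedule) > 0) {
    for (b in seq_len(nrow(schedule))) {
      sw <- schedule_swap(schedule, b)
      if (length(sw) == 0) next
      for (node in names(sw)) {
        partner <- sw[[node]]
        if (graph$community[[node]] != graph$community[[partner]]) {
          stop("swap partner must belong to the same community as its node")
        }
      }
      idx <- which(schedule_block(schedule, trials$index + 1L) == b &
                     trials$node %in% names(sw))
      if (length(idx)) {
        stim[idx] <- graph$stimulus[unname(sw[trials$node[idx]])]
        swapped[idx] <- TRUE
      }
    }
  }
  trials$stimulus <- unname(stim)
  trials$swapped <- swapped
  trials
}

#' Generate the exposure-phase sequence
#'
#' A 1,400-trial uniform random walk with independent per-trial rotation flags
#' (default probability 0.25) and transition labels
#' (`learned_boundary`/`nonboundary`).
#'
#' @param graph a `community_graph`.
#' @param n number of trials (default 1400).
#' @param rotate_prob probability a trial's stimulus is displayed rotated.
#' @param soa_s stimulus onset asynchrony in seconds (default 1.25).
#' @param seed optional integer seed.
#' @return a `sequence_trials` data frame.
#' @export
build_exposure_sequence <- function(graph, n = 1400, rotate_prob = 0.25,
                                    soa_s = 1.25, seed = NULL) {
  with_seed(seed, {
    nodes <- random_walk(graph, n)
    trials <- new_sequence_trials(data.frame(
      index = seq_len(n) - 1L,
      onset_s = (seq_len(n) - 1L) * soa_s,
      duration_s = soa_s,
      node = nodes,
      phase = "exposure",
      block_kind = "walk",
      block_200 = ((seq_len(n) - 1L) %/% 200L) + 1L,
      rotated = stats::runif(n) < rotate_prob,
      stringsAsFactors = FALSE))
    sched <- empty_schedule(n)
    trials <- apply_boundary_swap(trials, sched, graph)
    trials$transition_label <- label_transitions(trials, graph, sched)
    trials$manipulated <- FALSE
    trials
  })
}

#' Generate the parsing-phase sequence
#'
#' Alternates 15-trial pseudorandom-walk blocks (forced community exit after
#' nine within-community stimuli) with 15-trial Hamiltonian-path blocks. Each
#' Hamiltonian path originates from the final node of the preceding walk: the
#' walk takes one further pseudorandom step and the landing node becomes the
#' path's first trial, so every junction is an ordinary graph step and the
#' phase has exactly `n` trials. `origin = "same_node"` instead re-displays the
#' walk's final node as the path's first trial (that junction is labelled
#' `seam`). The boundary-swap manipulation and transition labels are applied
#' per the schedule.
#'
#' @param graph a `community_graph`.
#' @param n total trials, divisible by `2 * block` (default 1200).
#' @param block trials per walk/Hamiltonian block (default 15).
#' @param schedule a `manipulation_schedule`; default builds one from `seed`.
#' @param force_after forced-exit counter for walk blocks (default 9).
#' @param origin Hamiltonian origination rule, `"step"` (default) or
#'   `"same_node"`.
#' @param soa_s stimulus onset asynchrony in seconds (default 1.25).
#' @param seed optional integer seed.
#' @return a `sequence_trials` data frame.
#' @export
build_parsing_sequence <- function(graph, n = 1200, block = 15,
                                   schedule = NULL, force_after = 9,
                                   origin = c("step", "same_node"),
                                   soa_s = 1.25, seed = NULL) {
  origin <- match.arg(origin)
  if (n %% (2L * block) != 0L) {
    stop("n must be divisible by 2 * block (pairs of walk/Hamiltonian blocks)")
  }
  with_seed(seed, {
    if (is.null(schedule)) schedule <- manipulation_schedule(graph, n)
    if (nrow(schedule) > 0 &&
        attr(schedule, "block_len") * nrow(schedule) < n) {
      stop("manipulation schedule does not cover ", n, " trials")
    }
    n_pairs <- n %/% (2L * block)
    pool <- hamiltonian_pool(graph, 15)
    nodes <- character(0)
    kind <- character(0)
    prev <- NULL
    for (p in seq_len(n_pairs)) {
      if (is.null(prev)) {
        w <- pseudorandom_walk(graph, block, force_after = force_after)
      } else {
        w <- pseudorandom_walk(graph, block + 1L, start = prev,
                               force_after = force_after)[-1L]
      }
      nodes <- c(nodes, w)
      kind <- c(kind, rep("walk", block))
      last <- w[block]
      if (origin == "step") {
        nbs <- graph_neighbors(graph, last)
        cand <- Filter(function(pp) pp[1] %in% nbs, pool)
        h <- if (length(cand)) cand[[sample.int(length(cand), 1)]]
             else contiguous_hamiltonian(graph, nbs[sample.int(length(nbs), 1)])
      } else {
        h <- hamiltonian_path(graph, last, pool = pool)
      }
      nodes <- c(nodes, h)
      kind <- c(kind, rep("hamiltonian", block))
      prev <- h[block]
    }
    trials <- new_sequence_trials(data.frame(
      index = seq_len(n) - 1L,
      onset_s = (seq_len(n) - 1L) * soa_s,
      duration_s = soa_s,
      node = nodes,
      phase = "parsing",
      block_kind = kind,
      block_200 = ((seq_len(n) - 1L) %/% attr(schedule, "block_len")) + 1L,
      rotated = FALSE,
      stringsAsFactors = FALSE))
    trials <- apply_boundary_swap(trials, schedule, graph)
    trials$transition_label <- label_transitions(trials, graph, schedule)
    trials$manipulated <- !is.na(trials$transition_label) &
      trials$transition_label == "novel_boundary"
    attr(trials, "schedule") <- schedule
    trials
  })
}

#' Summarise transition-label composition of a sequence
#'
#' @param trials a `sequence_trials` data frame.
#' @return named list: counts per label, `pct_novel` (percent of all
#'   transitions that are novel boundaries), and `novel_of_boundary` (novel as
#'   a fraction of all between-community transitions).
#' @export
transition_stats <- function(trials) {
  lab <- trials$transition_label[!is.na(trials$transition_label)]
  n_trans <- nrow(trials) - 1L
  counts <- table(factor(lab, levels = c("novel_boundary", "learned_boundary",
                                         "nonboundary", "seam")))
  novel <- as.integer(counts[["novel_boundary"]])
  boundary <- novel + as.integer(counts[["learned_boundary"]])
  list(counts = counts,
       n_transitions = n_trans,
       pct_novel = 100 * novel / n_trans,
       novel_of_boundary = if (boundary > 0) novel / boundary else NA_real_)
}

# ---- posttest ----------------------------------------------------------------

#' Build the forced-choice association posttest
#'
#' Each of the 15 stimuli appears as the cue once with each of its four
#' same-community members as the target (60 trials); the lure is drawn from a
#' different community. Trial order is randomized.
#'
#' @param graph a `community_graph`.
#' @param seed optional integer seed.
#' @return data frame with columns `cue`, `target`, `lure` (node labels) and
#'   `cue_stim`, `target_stim`, `lure_stim` (stimulus ids).
#' @export
build_posttest <- function(graph, seed = NULL) {
  with_seed(seed, {
    rows <- list()
    for (cue in graph$nodes) {
      cm <- graph$community[[cue]]
      targets <- setdiff(graph$nodes[graph$community == cm], cue)
      others <- graph$nodes[graph$community != cm]
      for (tg in targets) {
        lure <- others[sample.int(length(others), 1)]
        rows[[length(rows) + 1L]] <- data.frame(
          cue = cue, target = tg, lure = lure, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    df$cue_stim <- unname(graph$stimulus[df$cue])
    df$target_stim <- unname(graph$stimulus[df$target])
    df$lure_stim <- unname(graph$stimulus[df$lure])
    df
  })
}

# ---- session timing ----------------------------------------------------------

#' Self-paced break schedule
#'
#' Exposure-phase breaks occur every 350 stimuli; parsing-phase breaks after
#' the first 405 stimuli and then after another 390. With a 1.25 s stimulus
#' onset asynchrony these segments last about 7.3, 8.4, and 8.1 minutes.
#'
#' @param phase `"exposure"` or `"parsing"`.
#' @param n_trials phase length (defaults 1400 / 1200).
#' @param soa_s stimulus onset asynchrony in seconds (default 1.25).
#' @return data frame with `after_stimuli` (cumulative trial counts at each
#'   break), `segment_stimuli`, and `segment_minutes`.
#' @export
break_schedule <- function(phase = c("exposure", "parsing"), n_trials = NULL,
                           soa_s = 1.25) {
  phase <- match.arg(phase)
  if (phase == "exposure") {
    if (is.null(n_trials)) n_trials <- 1400
    seg <- rep(350, floor(n_trials / 350))
  } else {
    if (is.null(n_trials)) n_trials <- 1200
    seg <- c(405, 390)
  }
  cum <- cumsum(seg)
  cum <- cum[cum < n_trials]
  seg <- seg[seq_along(cum)]
  data.frame(after_stimuli = cum, segment_stimuli = seg,
             segment_minutes = seg * soa_s / 60)
}

# ---- I/O ---------------------------------------------------------------------

#' Write a trial sequence as a BIDS-events-like TSV
#'
#' @param trials a `sequence_trials` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(trials, path) {
  cols <- c("onset_s", "duration_s", "index", "node", "stimulus", "phase",
            "block_kind", "block_200", "rotated", "transition_label",
            "manipulated")
  cols <- intersect(cols, names(trials))
  out <- trials[, cols, drop = FALSE]
  names(out)[names(out) == "index"] <- "trial_index"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' Export the graph as an annotated edge list
#'
#' Writes a text file with a commented header block giving each node's
#' community and role, followed by one `u v` edge per line.
#'
#' @param graph a `community_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nd in graph$nodes) {
    writeLines(sprintf("# node %s community %d role %s stimulus %d", nd,
                       graph$community[[nd]], graph$role[[nd]],
                       graph$stimulus[[nd]]), con)
  }
  idx <- which(graph$adjacency & upper.tri(graph$adjacency), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    writeLines(paste(graph$nodes[idx[r, 1]], graph$nodes[idx[r, 2]]), con)
  }
  invisible(path)
}
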