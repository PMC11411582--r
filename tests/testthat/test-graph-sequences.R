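test_that("the community graph satisfies its structural invariants", {
  g <- std_graph()
  expect_length(g$nodes, 15)
  expect_equal(unname(table(g$community)), rep(5L, 3), ignore_attr = TRUE)
  # two boundary nodes per community, the rest inner
  for (cm in 1:3) {
    expect_length(boundary_nodes(g, cm), 2)
    expect_length(inner_nodes(g, cm), 3)
  }
  # degree-4 regular, 30 edges, symmetric, no self loops
  expect_true(isSymmetric(g$adjacency))
  expect_false(any(diag(g$adjacency)))
  expect_equal(unname(rowSums(g$adjacency)), rep(4, 15))
  expect_equal(sum(g$adjacency) / 2, 30)
  # all between-community edges join boundary nodes of adjacent communities
  idx <- which(g$adjacency & upper.tri(g$adjacency), arr.ind = TRUE)
  between <- idx[g$community[idx[, 1]] != g$community[idx[, 2]], , drop = FALSE]
  expect_equal(nrow(between), 3)
  for (r in seq_len(nrow(between))) {
    expect_true(all(g$role[between[r, ]] == "boundary"))
  }
  # connected: reachability via repeated adjacency application
  reach <- diag(15) > 0
  for (k in 1:15) reach <- reach | (reach %*% g$adjacency) > 0
  expect_true(all(reach))
  # same-community membership of neighbouring labels
  expect_equal(g$community[["a"]], g$community[["b"]])
  # stimulus assignment is a draw without replacement from the pool
  g2 <- build_graph(seed = 7)
  expect_length(unique(g2$stimulus), 15)
  expect_true(all(g2$stimulus >= 1 & g2$stimulus <= 74))
})

test_that("random walks stay on edges and cover the graph uniformly", {
  g <- std_graph()
  expect_equal(random_walk(g, 1, start = "c", seed = 1), "c")
  expect_error(random_walk(g, 0, start = "a"), "length")
  w <- random_walk(g, 10000, seed = 2)
  adj_ok <- vapply(seq_len(9999), function(i) {
    g$adjacency[w[i], w[i + 1]]
  }, logical(1))
  expect_true(all(adj_ok))
  # regular graph: stationary occupancy is uniform
  w2 <- random_walk(g, 1e5, seed = 3)
  occ <- table(factor(w2, levels = g$nodes)) / length(w2)
  expect_true(all(abs(occ - 1 / 15) < 0.01))
})

test_that("pseudorandom walk forces a community exit after nine stimuli", {
  g <- std_graph()
  w <- pseudorandom_walk(g, 2e4, seed = 4)
  cm <- g$community[w]
  run <- 1L
  for (i in seq_len(length(w) - 1L)) {
    if (run >= 9 && g$role[[w[i]]] == "boundary") {
      expect_false(cm[i + 1] == cm[i])
    }
    run <- if (cm[i + 1] == cm[i]) run + 1L else 1L
  }
  # with the counter disabled the walk is the plain random walk
  expect_identical(pseudorandom_walk(g, 500, start = "a", force_after = Inf,
                                     seed = 5),
                   random_walk(g, 500, start = "a", seed = 5))
  # forcing increases community transitions
  wf <- pseudorandom_walk(g, 2e4, seed = 6)
  wr <- random_walk(g, 2e4, seed = 6)
  expect_gt(crossings_oracle(g, wf), crossings_oracle(g, wr))
})

test_that("Hamiltonian paths visit every node once with minimal crossings", {
  g <- std_graph()
  pool <- hamiltonian_pool(g, size = 15, seed = 8)
  expect_length(pool, 15)
  for (p in pool) {
    expect_setequal(p, g$nodes)
    adj_ok <- vapply(seq_len(14), function(i) g$adjacency[p[i], p[i + 1]],
                     logical(1))
    expect_true(all(adj_ok))
    expect_equal(crossings_oracle(g, p), 2)
  }
  h <- hamiltonian_path(g, start = "c", pool = pool, seed = 9)
  expect_equal(h[1], "c")
  expect_setequal(h, g$nodes)
  # degenerate two-node graph has the unique path
  g2 <- path_graph_2()
  expect_equal(enumerate_hamiltonian(g2, "a"), list(c("a", "b")))
})

test_that("manipulation schedule cycles all three transitions equally", {
  g <- std_graph()
  sch <- manipulation_schedule(g, n_trials = 1200, seed = 10)
  expect_equal(nrow(sch), 6)
  edges <- paste(sch$edge_u, sch$edge_v)
  expect_equal(unname(table(edges)), rep(2L, 3), ignore_attr = TRUE)
  for (b in 1:6) {
    sw <- attr(sch, "swap")[[b]]
    expect_length(sw, 4)  # two boundary nodes + their two partners
    for (nd in names(sw)) {
      expect_equal(g$community[[nd]], g$community[[sw[[nd]]]])
      expect_equal(sw[[sw[[nd]]]], nd)  # bidirectional
    }
  }
})

test_that("boundary swap rewrites displayed stimuli and inverts exactly", {
  g <- std_graph()
  sch <- manipulation_schedule(g, n_trials = 1200, seed = 11)
  tr <- build_parsing_sequence(g, n = 1200, schedule = sch, seed = 12)
  # within a manipulated block, boundary nodes display the partner's stimulus
  sw1 <- attr(sch, "swap")[[1]]
  blk1 <- tr$index < 200
  for (nd in names(sw1)) {
    rows <- which(blk1 & tr$node == nd)
    if (length(rows)) {
      expect_true(all(tr$stimulus[rows] == g$stimulus[[sw1[[nd]]]]))
      expect_true(all(tr$swapped[rows]))
    }
  }
  # inverting the swap recovers the unmanipulated display sequence
  inverted <- tr$stimulus
  for (b in seq_len(nrow(sch))) {
    sw <- attr(sch, "swap")[[b]]
    rows <- which((tr$index %/% 200 + 1) == b & tr$node %in% names(sw))
    inverted[rows] <- g$stimulus[tr$node[rows]]
  }
  expect_equal(inverted, unname(g$stimulus[tr$node]))
  # empty schedule is the identity mapping
  tr0 <- build_parsing_sequence(g, n = 120, schedule = empty_schedule(120),
                                seed = 13)
  expect_equal(tr0$stimulus, unname(g$stimulus[tr0$node]))
  expect_false(any(tr0$swapped))
})

test_that("transition labels follow the node-pair and schedule rules", {
  g <- std_graph()
  sch <- manipulation_schedule(g, n_trials = 1200, seed = 14)
  tr <- build_parsing_sequence(g, n = 1200, schedule = sch, seed = 15)
  lab <- tr$transition_label
  expect_true(is.na(lab[1]))
  cm <- g$community[tr$node]
  for (i in 2:200) {  # spot-check the first manipulated block
    same <- cm[i] == cm[i - 1]
    if (same) {
      expect_equal(lab[i], "nonboundary")
    } else {
      me <- sort(c(sch$edge_u[1], sch$edge_v[1]))
      is_manip <- all(sort(c(tr$node[i - 1], tr$node[i])) == me)
      expect_equal(lab[i],
                   if (is_manip) "novel_boundary" else "learned_boundary")
    }
  }
  # novel labels only while their transition is the manipulated one
  nv <- which(lab == "novel_boundary")
  for (i in nv) {
    b <- tr$block_200[i]
    expect_equal(sort(c(tr$node[i - 1], tr$node[i])),
                 sort(c(sch$edge_u[b], sch$edge_v[b])))
  }
  # no schedule, no novel labels
  tr0 <- build_parsing_sequence(g, n = 120, schedule = empty_schedule(120),
                                seed = 16)
  expect_false(any(tr0$transition_label == "novel_boundary", na.rm = TRUE))
  # novel labels are about a third of all boundary labels
  st <- transition_stats(tr)
  expect_gt(st$novel_of_boundary, 0.2)
  expect_lt(st$novel_of_boundary, 0.5)
})

test_that("parsing sequences alternate walk and Hamiltonian blocks", {
  g <- std_graph()
  tr <- build_parsing_sequence(g, n = 1200, seed = 17)
  expect_equal(nrow(tr), 1200)
  kinds <- tr$block_kind[seq(1, 1200, by = 15)]
  expect_equal(kinds, rep(c("walk", "hamiltonian"), 40))
  # every consecutive node pair is a graph edge under the default origination
  adj_ok <- vapply(2:1200, function(i) {
    g$adjacency[tr$node[i - 1], tr$node[i]]
  }, logical(1))
  expect_true(all(adj_ok))
  # each Hamiltonian block is a full path
  for (b in seq(16, 1200, by = 30)[1:5]) {
    expect_setequal(tr$node[b:(b + 14)], g$nodes)
  }
  expect_error(build_parsing_sequence(g, n = 100), "divisible")
  # same_node origination re-displays the junction node and labels a seam
  trs <- build_parsing_sequence(g, n = 120, origin = "same_node", seed = 18)
  seams <- which(trs$transition_label == "seam")
  expect_true(length(seams) > 0)
  expect_true(all(trs$node[seams] == trs$node[seams - 1]))
})

test_that("exposure sequences flag rotations at the requested rate", {
  g <- std_graph()
  tr <- build_exposure_sequence(g, seed = 19)
  expect_equal(nrow(tr), 1400)
  expect_true(all(tr$phase == "exposure"))
  expect_false(any(tr$transition_label == "novel_boundary", na.rm = TRUE))
  tr0 <- build_exposure_sequence(g, n = 200, rotate_prob = 0, seed = 20)
  expect_false(any(tr0$rotated))
  frac <- mean(replicate(20, mean(
    build_exposure_sequence(g, n = 700, seed = sample.int(1e6, 1))$rotated)))
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / (20 * 700)))
})

test_that("the posttest is balanced over all same-community cue-target pairs", {
  g <- std_graph()
  pt <- build_posttest(g, seed = 21)
  expect_equal(nrow(pt), 60)
  for (i in seq_len(60)) {
    expect_true(pt$cue[i] != pt$target[i])
    expect_equal(g$community[[pt$cue[i]]], g$community[[pt$target[i]]])
    expect_false(g$community[[pt$cue[i]]] == g$community[[pt$lure[i]]])
  }
  key <- paste(pt$cue, pt$target)
  expect_equal(max(table(key)), 1)
  expect_equal(length(unique(key)), 60)
})

test_that("break schedule matches the session timing arithmetic", {
  ex <- break_schedule("exposure")
  expect_equal(ex$after_stimuli, c(350, 700, 1050))
  expect_equal(ex$segment_minutes, rep(350 * 1.25 / 60, 3))
  pa <- break_schedule("parsing")
  expect_equal(pa$after_stimuli, c(405, 795))
  expect_equal(pa$segment_minutes, c(405, 390) * 1.25 / 60)
})

test_that("events TSV and graph edge list round-trip through disk", {
  g <- std_graph()
  tr <- build_parsing_sequence(g, n = 60, seed = 22)
  f <- tempfile(fileext = ".tsv")
  write_events_tsv(tr, f)
  back <- read.delim(f, na.strings = "n/a")
  expect_equal(nrow(back), 60)
  expect_equal(back$node, tr$node)
  expect_equal(back$onset_s, tr$onset_s)
  expect_equal(back$transition_label[-1], tr$transition_label[-1])
  f2 <- tempfile(fileext = ".txt")
  write_graph_edgelist(g, f2)
  lines <- readLines(f2)
  expect_equal(sum(!startsWith(lines, "#")), 30)
  expect_equal(sum(startsWith(lines, "#")), 15)
})
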