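# shared fixtures, built once per test run

std_graph <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- build_graph()
    g
  }
})

# a small, fast generative spec for EEG tests (artifacts off unless a test
# turns them on)
quiet_spec <- function(...) {
  args <- utils::modifyList(
    list(sampling_rate = 125, n_channels = 8, spike_rate = 0,
         blink_rate = 0, line_amp = 0), list(...))
  do.call(generative_spec, args)
}

# one small preprocessed participant, memoised: 120-trial parsing session
small_session <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- build_graph(seed = 101)
    tr <- build_parsing_sequence(g, n = 120, seed = 102)
    spec <- quiet_spec()
    ses <- simulate_session(tr, spec, g, seed = 103)
    ep <- epoch_and_baseline(ses)
    cache <<- list(graph = g, trials = tr, spec = spec, session = ses,
                   epochs = ep)
    cache
  }
})

# hand-built two-node path graph for degenerate-path tests
path_graph_2 <- function() {
  nodes <- c("a", "b")
  adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2,
                dimnames = list(nodes, nodes))
  structure(list(nodes = nodes, adjacency = adj,
                 community = c(a = 1L, b = 1L),
                 role = c(a = "inner", b = "inner"),
                 stimulus = c(a = 1L, b = 2L),
                 between_edges = NULL, boundary_partner = NULL),
            class = "community_graph")
}

# independent oracle: count community crossings in a node sequence
crossings_oracle <- function(graph, nodes) {
  sum(graph$community[nodes[-1]] != graph$community[nodes[-length(nodes)]])
}
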