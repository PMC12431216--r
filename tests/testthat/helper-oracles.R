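# Independent oracles used to cross-check the package's two computation
# routes. They deliberately share no code with the implementation: the
# landscape oracle iterates each trajectory state by state, and the cycle
# oracle reads the attractors off the strongly connected components of the
# functional graph via igraph.

# Landscape by naive per-state trajectory iteration: follow w until a state
# repeats, extract the terminal cycle, and pair w with every orbit state.
oracle_landscape_pairs <- function(m) {
  N <- 2^m$n
  pairs <- NULL
  for (w in 0:(N - 1L)) {
    seen <- integer(0)
    cur <- w
    while (!cur %in% seen) {
      seen <- c(seen, cur)
      cur <- m$image[cur + 1L]
    }
    orbit <- seen[which(seen == cur):length(seen)]
    pairs <- rbind(pairs, cbind(w, sort(orbit)))
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("initial", "attractor"))
  pairs
}

# Attractor orbits via igraph strongly connected components: a component of
# size > 1, or a single state with a self-loop, is an attractor cycle.
oracle_cycle_orbits <- function(m) {
  g <- igraph::graph_from_edgelist(
    cbind(0:(2^m$n - 1L), m$image) + 1L, directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  orbits <- list()
  for (k in seq_len(comp$no)) {
    states <- which(comp$membership == k) - 1L
    if (length(states) > 1L || m$image[states + 1L] == states) {
      # order the orbit by following the map from its minimal state
      orbit <- integer(0)
      cur <- min(states)
      repeat {
        orbit <- c(orbit, cur)
        cur <- m$image[cur + 1L]
        if (cur == min(states)) break
      }
      orbits[[length(orbits) + 1L]] <- orbit
    }
  }
  orbits[order(vapply(orbits, min, 0L))]
}

# t-fold self-composition by plain repetition (no squaring).
map_power_t <- function(m, t) {
  acc <- m
  for (k in seq_len(t - 1L)) acc <- compose_maps(m, acc)
  acc
}

# Deterministic pool of small random networks for the property suites.
random_instances <- function(n_instances, sizes = 2:6, seed_base = 1000L) {
  lapply(seq_len(n_instances), function(k) {
    n <- sizes[1L + (k - 1L) %% length(sizes)]
    random_network(n, max_inputs = min(3L, n), seed = seed_base + k)
  })
}
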