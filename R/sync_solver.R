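# Synchronous attractor landscapes ----------------------------------------
#
# The synchronous scheme is S(t, u0) = (M_F)^t u0 over the Boolean semiring,
# a deterministic special case of the Chapman-Kolmogorov iteration. For
# fixed-point-only systems the powers converge to a stationary matrix S*;
# when cycles are present the powers become periodic and the landscape is
# the entrywise logical OR of the powers over one full period after the
# transient has died out.

new_landscape <- function(n, pairs) {
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("initial", "attractor"))
  structure(list(n = as.integer(n), pairs = pairs),
            class = "attractor_landscape")
}

#' @export
print.attractor_landscape <- function(x, ...) {
  cat("Attractor landscape on", 2^x$n, "states;",
      nrow(x$pairs), "relation pair(s)\n")
  invisible(x)
}

#' Least transient and period of the powers of a functional matrix
#'
#' Finds the least `T0` and least `p >= 1` with `M^(T0+p) = M^(T0)`. For a
#' functional matrix these are the longest transient of the underlying map
#' and the least common multiple of its cycle lengths; both are computed
#' exactly from the functional graph rather than by probing a large `t`.
#'
#' @param M a functional `transition_matrix` (or an `integer_map`).
#' @return list with `transient` (`T0`) and `period` (`p`).
#' @export
power_orbit <- function(M) {
  m <- if (inherits(M, "integer_map")) M else matrix_to_map(M)
  fg <- functional_graph_analysis(m)
  list(transient = max(fg$depth),
       period = as.integer(Reduce(lcm2, fg$periods, accumulate = FALSE)))
}

#' Stationary or periodic landscape of a functional matrix
#'
#' For period 1 the landscape is the stationary power `M^T0`; otherwise it is
#' the entrywise logical OR of `M^t` for `t` in a full period window at the
#' transient, which pairs every initial state with every state of the orbit
#' it reaches.
#'
#' @param M a functional `transition_matrix` (or an `integer_map`).
#' @return an `attractor_landscape` with 0-based `(initial, attractor)`
#'   pairs; see [as_matrix_landscape()] for the matrix view.
#' @export
stationary_landscape <- function(M) {
  m <- if (inherits(M, "integer_map")) M else matrix_to_map(M)
  po <- power_orbit(m)
  w <- 0:(2^m$n - 1L)
  cur <- map_power(m, po$transient)$image
  pairs <- cbind(w, cur)
  if (po$period > 1L) {
    for (t in seq_len(po$period - 1L)) {
      cur <- m$image[cur + 1L]
      pairs <- rbind(pairs, cbind(w, cur))
    }
  }
  new_landscape(m$n, pairs)
}

#' Landscape as a sorted relation
#' @param L an `attractor_landscape`.
#' @return two-column integer matrix of `(initial, attractor)` pairs sorted
#'   by initial state then attractor state; a function (one row per initial
#'   state) exactly when the system has only fixed-point attractors.
#' @export
landscape_relation <- function(L) L$pairs

#' Matrix view of a landscape
#' @param L an `attractor_landscape`.
#' @return 0/1 matrix with entry `(i, j) = 1` iff initial state `j` reaches
#'   attractor state `i`.
#' @export
as_matrix_landscape <- function(L) {
  N <- 2^L$n
  M <- matrix(0L, N, N)
  M[cbind(L$pairs[, 2L] + 1L, L$pairs[, 1L] + 1L)] <- 1L
  structure(M, class = c("transition_matrix", "matrix"), n = L$n)
}

#' Landscape assembled from attractors and basins
#'
#' Independent, matrix-free route to the same relation: each basin is paired
#' with the full orbit of its attractor.
#'
#' @param m an `integer_map`.
#' @return an `attractor_landscape`.
#' @export
landscape_from_attractors <- function(m) {
  bm <- compute_basins(m)
  pairs <- do.call(rbind, lapply(seq_along(bm$attractors), function(i) {
    orbit_relation(bm$attractors[[i]], bm$basins[[i]])
  }))
  new_landscape(m$n, pairs)
}

#' Export a landscape as two-column CSV
#' @param L an `attractor_landscape`.
#' @param path output file.
#' @export
write_landscape_csv <- function(L, path) {
  utils::write.csv(as.data.frame(L$pairs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
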