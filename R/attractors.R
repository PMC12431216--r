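# Attractors and basins from the functional graph -------------------------
#
# A tabulated map m on 2^n states is a functional graph: every weakly
# connected component contains exactly one cycle (a fixed point being a
# 1-cycle), and every state flows into one of those cycles. Everything here
# is computed exactly and fully vectorized: the cycle states are read off a
# high power of the map (any exponent at least the longest transient), and
# transient depths come from a reverse breadth-first search over the
# predecessor lists.

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a / gcd2(a, b) * b

# Full structural analysis of a functional map; internal workhorse shared by
# the attractor, basin, landscape and compaction code.
#
# Returns: attractors (list of attractor objects, sorted by minimal orbit
# element), attractor_of (1-based attractor index per state, index = w + 1),
# depth (steps for each state to enter its cycle), periods (cycle lengths).
functional_graph_analysis <- function(m) {
  n <- m$n
  N <- 2^n
  # image of m^t for any t >= the longest transient is exactly the cycle set
  fK <- map_power(m, N)
  on_cycle_img <- fK$image
  cycle_states <- sort(unique(on_cycle_img))

  # enumerate cycles; ascending start gives the canonical minimal rotation
  visited <- logical(N)
  attractors <- list()
  cycle_id <- integer(N) # by state + 1, 0 = not a cycle state
  for (cs in cycle_states) {
    if (visited[cs + 1L]) next
    orbit <- integer(0)
    w <- cs
    repeat {
      orbit <- c(orbit, w)
      visited[w + 1L] <- TRUE
      w <- m$image[w + 1L]
      if (w == cs) break
    }
    attractors[[length(attractors) + 1L]] <- structure(
      list(kind = if (length(orbit) == 1L) "fixed" else "cyclic",
           orbit = orbit, period = length(orbit)),
      class = "bn_attractor")
    cycle_id[orbit + 1L] <- length(attractors)
  }

  attractor_of <- cycle_id[on_cycle_img + 1L]

  # reverse BFS from the cycles over predecessor lists
  ord <- order(m$image)
  cnt <- tabulate(m$image + 1L, N)
  start <- c(0L, cumsum(cnt))
  depth <- rep(NA_integer_, N)
  depth[cycle_states + 1L] <- 0L
  frontier <- cycle_states
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    has <- frontier[cnt[frontier + 1L] > 0L]
    if (length(has) == 0L) break
    idx <- sequence(cnt[has + 1L], from = start[has + 1L] + 1L)
    preds <- ord[idx] - 1L
    new <- preds[is.na(depth[preds + 1L])]
    depth[new + 1L] <- d
    frontier <- new
  }

  list(attractors = attractors,
       attractor_of = attractor_of,
       depth = depth,
       periods = vapply(attractors, `[[`, 0L, "period"))
}

#' Fixed points of an integer map
#'
#' The fixed-point attractors of a synchronously updated network are exactly
#' the reflexive elements of its integer transition map.
#'
#' @param m an `integer_map`.
#' @return sorted integer vector of states `w` with `m(w) = w`.
#' @export
find_fixed_points <- function(m) {
  w <- 0:(2^m$n - 1L)
  w[m$image == w]
}

#' All attractors (cycles of the functional graph) of an integer map
#'
#' @param m an `integer_map`.
#' @return list of attractor objects, each with fields `kind` (`"fixed"` or
#'   `"cyclic"`), `orbit` (states in successor order, rotated to start at the
#'   minimal element) and `period`; the list is sorted by minimal orbit
#'   element. Fixed points are reported as period-1 attractors.
#' @export
find_cycles <- function(m) {
  functional_graph_analysis(m)$attractors
}

#' @export
print.bn_attractor <- function(x, ...) {
  cat(if (x$kind == "fixed") "Fixed-point attractor" else
        paste0("Cyclic attractor (period ", x$period, ")"),
      ": ", paste(x$orbit, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Basins of attraction
#'
#' Assigns every state to the unique attractor its synchronous trajectory
#' enters; the basins partition the state space.
#'
#' @param m an `integer_map`.
#' @param attractors optional attractor list as returned by [find_cycles()];
#'   when supplied it is checked for consistency with `m`.
#' @return a `basin_map`: list with `assignment` (1-based attractor index for
#'   each state `w`, position `w + 1`), `basins` (list of state vectors, one
#'   per attractor) and `attractors`.
#' @export
compute_basins <- function(m, attractors = NULL) {
  fg <- functional_graph_analysis(m)
  if (!is.null(attractors)) {
    key <- function(as) lapply(as, function(a) a$orbit)
    if (!identical(key(attractors), key(fg$attractors))) {
      stop("supplied attractor list is inconsistent with the map")
    }
  }
  basins <- split(0:(2^m$n - 1L), fg$attractor_of)
  basins <- lapply(seq_along(fg$attractors), function(i) {
    unname(basins[[as.character(i)]])
  })
  structure(list(assignment = fg$attractor_of, basins = basins,
                 attractors = fg$attractors, n = m$n),
            class = "basin_map")
}

#' Relation between a basin and a cyclic orbit
#'
#' In the long run every basin element visits every orbit state, so the
#' landscape restricted to one attractor is the complete bipartite relation
#' basin x orbit.
#'
#' @param a an attractor.
#' @param basin integer vector of basin states.
#' @return two-column integer matrix of (initial, attractor-state) pairs,
#'   sorted.
#' @export
orbit_relation <- function(a, basin) {
  pairs <- cbind(initial = rep(sort(basin), each = a$period),
                 attractor = rep(sort(a$orbit), times = length(basin)))
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' Check the union-of-compositions decomposition of a cyclic orbit
#'
#' A cyclic orbit of period L, viewed as a relation, equals the union of the
#' successor function with its compositions up to order L (which covers all
#' rotations and ends in the diagonal).
#'
#' @param a an attractor.
#' @return `TRUE` iff the union of `f, f^2, ..., f^L` on the orbit equals
#'   orbit x orbit, where `f` is the orbit successor function.
#' @export
verify_union_decomposition <- function(a) {
  L <- a$period
  orbit <- a$orbit
  succ <- c(orbit[-1L], orbit[1L]) # f on the orbit
  names(succ) <- as.character(orbit)
  pairs <- character(0)
  cur <- stats::setNames(orbit, as.character(orbit)) # f^0
  for (k in seq_len(L)) {
    cur <- succ[as.character(cur)]
    pairs <- union(pairs, paste(orbit, unname(cur)))
  }
  full <- paste(rep(orbit, each = L), rep(orbit, times = L))
  setequal(pairs, full)
}
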