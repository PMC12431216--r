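# Modular solving of large networks ----------------------------------------
#
# A large network is partitioned into modules whose inter-module dependency
# graph is acyclic. Processing modules in topological order, each module is
# solved in isolation with its external inputs frozen at the values they
# take in upstream semi-attractors; the module's fixed states under those
# frozen inputs are its semi-attractors. Joining one semi-attractor per
# module gives the candidate global attractors, which are then validated on
# the full network (F(s) = s). Basin sizes follow from the support of each
# module's compacted map: if the joint dynamics is driven by a set D of
# driver variables, each true attractor collects the 2^(n - |D|) states
# sharing its driver assignment.

#' Validate a module partition
#'
#' @param net a `boolean_network`.
#' @param assignment either a list of disjoint node-index vectors covering
#'   all nodes, or an integer vector of length `n` giving each node's module
#'   id.
#' @return a `module_partition`: list with `modules` (list of sorted node
#'   indices), `deps` (upstream module indices per module) and `order`
#'   (a topological order of the modules). Errors if the modules do not
#'   partition the nodes or depend on each other cyclically.
#' @export
validate_partition <- function(net, assignment) {
  if (!is.list(assignment)) {
    if (length(assignment) != net$n) {
      stop("assignment vector must have one module id per node")
    }
    assignment <- split(seq_len(net$n), assignment)
    names(assignment) <- NULL
  }
  modules <- lapply(assignment, function(s) sort(as.integer(s)))
  flat <- unlist(modules)
  if (length(flat) != net$n || !setequal(flat, seq_len(net$n)) ||
      anyDuplicated(flat)) {
    stop("modules must partition the node set 1..", net$n)
  }
  module_of <- integer(net$n)
  for (k in seq_along(modules)) module_of[modules[[k]]] <- k

  deps <- lapply(seq_along(modules), function(k) {
    vars <- unlist(lapply(modules[[k]], function(i) expr_vars(net$rules[[i]])))
    sort(unique(module_of[setdiff(vars, modules[[k]])]))
  })

  # Kahn's algorithm for a topological order of the module DAG
  indeg <- lengths(deps)
  order <- integer(0)
  ready <- which(indeg == 0L)
  remaining_deps <- deps
  while (length(ready) > 0L) {
    k <- ready[1L]
    ready <- ready[-1L]
    order <- c(order, k)
    for (j in seq_along(modules)) {
      if (k %in% remaining_deps[[j]]) {
        remaining_deps[[j]] <- setdiff(remaining_deps[[j]], k)
        if (length(remaining_deps[[j]]) == 0L) ready <- c(ready, j)
      }
    }
  }
  if (length(order) != length(modules)) {
    stop("modules depend on each other cyclically; feedback between modules ",
         "is not supported")
  }
  structure(list(modules = modules, deps = deps, order = order,
                 module_of = module_of, n = net$n),
            class = "module_partition")
}

#' Partition a network into consecutive blocks
#' @param net a `boolean_network`.
#' @param block_size nodes per module (`n` must be divisible by it).
#' @return a `module_partition`.
#' @export
consecutive_partition <- function(net, block_size) {
  if (net$n %% block_size != 0L) {
    stop("n = ", net$n, " is not divisible by block size ", block_size)
  }
  validate_partition(net, rep(seq_len(net$n %/% block_size), each = block_size))
}

# Integer map of one module with external inputs frozen to constants.
# `inputs` is a named integer vector keyed by global node index.
frozen_module_map <- function(net, nodes, inputs, cap = default_state_cap()) {
  nm <- length(nodes)
  check_cap(nm, cap)
  wm <- 0:(2^nm - 1L)
  local_pos <- integer(net$n)
  local_pos[nodes] <- seq_len(nm)
  getvar <- function(i) {
    if (local_pos[i] > 0L) {
      bitwAnd(bitwShiftR(wm, nm - local_pos[i]), 1L)
    } else {
      v <- inputs[as.character(i)]
      if (is.na(v)) stop("module rule references unfrozen external node ", i)
      as.integer(v)
    }
  }
  img <- 0
  for (j in seq_len(nm)) {
    img <- img + eval_expr(net$rules[[nodes[j]]], getvar) * 2^(nm - j)
  }
  new_integer_map(nm, as.integer(rep_len(img, 2^nm)))
}

# Distinct frozen-input assignments for module k, drawn from the cross
# product of the upstream modules' semi-attractors restricted to the needed
# input nodes. Returns a matrix (possibly 0-column) with one row per
# assignment, columns named by global node index.
module_input_patterns <- function(net, part, k, semi) {
  nodes <- part$modules[[k]]
  vars <- sort(unique(unlist(lapply(nodes, function(i) expr_vars(net$rules[[i]])))))
  ext <- setdiff(vars, nodes)
  if (length(ext) == 0L) {
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  }
  ups <- sort(unique(part$module_of[ext]))
  per_up <- lapply(ups, function(u) {
    cols <- match(intersect(ext, part$modules[[u]]), part$modules[[u]])
    pat <- semi[[u]][, cols, drop = FALSE]
    colnames(pat) <- as.character(intersect(ext, part$modules[[u]]))
    unique(pat)
  })
  combo <- Reduce(function(A, B) {
    ia <- rep(seq_len(nrow(A)), times = nrow(B))
    ib <- rep(seq_len(nrow(B)), each = nrow(A))
    cbind(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
  }, per_up)
  unique(combo[, as.character(ext), drop = FALSE])
}

#' Semi-attractors of every module
#'
#' Modules are processed in topological order; for every combination of
#' upstream semi-attractor values restricted to a module's external inputs,
#' the inputs are frozen and the module's fixed states are collected. A
#' module's semi-attractor set is the union over its input combinations.
#'
#' @param net a `boolean_network`.
#' @param part a `module_partition`.
#' @param cap per-module state-space cap.
#' @return a `semi_attractor_set`: list with `partition` and `semi`, a list
#'   holding for each module a 0/1 matrix (one row per semi-attractor,
#'   columns = the module's nodes in order, rows sorted by encoded value).
#' @export
module_semi_attractors <- function(net, part, cap = default_state_cap()) {
  semi <- vector("list", length(part$modules))
  for (k in part$order) {
    nodes <- part$modules[[k]]
    nm <- length(nodes)
    inputs <- module_input_patterns(net, part, k, semi)
    pats <- NULL
    for (r in seq_len(nrow(inputs))) {
      assign <- stats::setNames(as.integer(inputs[r, ]), colnames(inputs))
      mm <- frozen_module_map(net, nodes, assign, cap = cap)
      fixed <- find_fixed_points(mm)
      if (length(fixed) > 0L) {
        bits <- vapply(fixed, decode_state, integer(nm), n = nm)
        pats <- rbind(pats, matrix(bits, ncol = nm, byrow = TRUE))
      }
    }
    if (is.null(pats)) {
      stop("module ", k, " has no fixed semi-attractor under any frozen ",
           "input; cyclic semi-attractors are not supported")
    }
    pats <- unique(pats)
    enc <- apply(pats, 1L, encode_state)
    semi[[k]] <- pats[order(enc), , drop = FALSE]
  }
  structure(list(partition = part, semi = semi), class = "semi_attractor_set")
}

#' Join per-module semi-attractors into global candidates
#'
#' @param s a `semi_attractor_set`.
#' @return 0/1 matrix of candidate global attractor states, one row per
#'   candidate (cross product of the per-module sets), columns in node
#'   order; the row count is the product of the per-module counts.
#' @export
join_candidates <- function(s) {
  part <- s$partition
  counts <- vapply(s$semi, nrow, 0L)
  if (any(counts == 0L)) stop("some module has no semi-attractor")
  grid <- expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE)
  cand <- matrix(0L, nrow(grid), part$n)
  for (k in seq_along(s$semi)) {
    cand[, part$modules[[k]]] <- s$semi[[k]][grid[[k]], , drop = FALSE]
  }
  colnames(cand) <- NULL
  cand
}

# One synchronous step applied to rows of a 0/1 state matrix.
step_state_matrix <- function(net, states) {
  getvar <- function(i) states[, i]
  img <- matrix(0L, nrow(states), net$n)
  for (i in seq_len(net$n)) {
    img[, i] <- eval_expr(net$rules[[i]], getvar)
  }
  img
}

#' Validate candidates on the full network
#'
#' Keeps exactly the candidates `s` with `F(s) = s`, evaluating every rule
#' on the full network (no state-space enumeration, so this scales to
#' hundreds of nodes).
#'
#' @param net a `boolean_network`.
#' @param candidates 0/1 candidate matrix from [join_candidates()].
#' @return 0/1 matrix of the true global fixed-point attractors (rows sorted
#'   by bit pattern).
#' @export
validate_candidates <- function(net, candidates) {
  img <- step_state_matrix(net, candidates)
  keep <- rowSums(img != candidates) == 0L
  out <- candidates[keep, , drop = FALSE]
  out[order(apply(out, 1L, paste, collapse = "")), , drop = FALSE]
}

#' Basin sizes from canonical-form support variables
#'
#' Computes, for every module and frozen-input combination, the support of
#' the module's compacted map (the variables its canonical form actually
#' depends on) and pools them into the driver set D. When the true
#' attractors are in bijection with the 2^|D| driver assignments, every
#' attractor's basin holds exactly `2^(n - |D|)` states -- all
#' configurations sharing its driver values -- and the driver assignment is
#' the attractor's reachability condition.
#'
#' @param net a `boolean_network`.
#' @param part a `module_partition`.
#' @param cap per-module state-space cap.
#' @return list with `drivers` (global node indices), `attractors` (0/1
#'   matrix), `basin_size` (one count per attractor), and `conditions`
#'   (per-attractor named driver assignment). Errors when the attractors are
#'   not determined by the drivers alone ("not computable by support
#'   counting").
#' @export
basin_size_by_support <- function(net, part, cap = default_state_cap()) {
  s <- module_semi_attractors(net, part, cap = cap)
  drivers <- integer(0)
  for (k in part$order) {
    nodes <- part$modules[[k]]
    inputs <- module_input_patterns(net, part, k, s$semi)
    for (r in seq_len(nrow(inputs))) {
      assign <- stats::setNames(as.integer(inputs[r, ]), colnames(inputs))
      cm <- compact_map(frozen_module_map(net, nodes, assign, cap = cap))
      drivers <- union(drivers, nodes[map_support(cm)])
    }
  }
  drivers <- sort(drivers)
  atts <- validate_candidates(net, join_candidates(s))
  dpat <- atts[, drivers, drop = FALSE]
  keys <- apply(dpat, 1L, paste, collapse = "")
  if (nrow(atts) != 2^length(drivers) || anyDuplicated(keys)) {
    stop("basins are not computable by support counting: the true attractors ",
         "are not in bijection with the driver assignments")
  }
  conditions <- lapply(seq_len(nrow(atts)), function(r) {
    stats::setNames(as.integer(dpat[r, ]), net$nodes[drivers])
  })
  list(drivers = drivers,
       attractors = atts,
       basin_size = rep(2^(net$n - length(drivers)), nrow(atts)),
       conditions = conditions)
}

# Variables an integer map actually depends on: local index j is in the
# support iff flipping bit j changes some image.
map_support <- function(m) {
  n <- m$n
  w <- 0:(2^n - 1L)
  which(vapply(seq_len(n), function(j) {
    flipped <- bitwXor(w, bitwShiftL(1L, n - j))
    any(m$image != m$image[flipped + 1L])
  }, TRUE))
}

#' Read a module assignment file
#'
#' Accepts JSON (an object or array mapping nodes to module ids) or TSV with
#' columns `node` and `module`.
#'
#' @param path file path.
#' @param net a `boolean_network` used to resolve node names.
#' @return integer vector of module ids in node order, suitable for
#'   [validate_partition()].
#' @export
read_module_assignment <- function(path, net) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    ids <- if (is.list(x) || !is.null(names(x))) unlist(x) else x
    if (!is.null(names(ids))) ids <- ids[net$nodes]
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    ids <- stats::setNames(tab$module, tab$node)[net$nodes]
  }
  if (any(is.na(ids)) || length(ids) != net$n) {
    stop("assignment does not cover every node of the network")
  }
  as.integer(ids)
}
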