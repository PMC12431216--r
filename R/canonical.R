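# Canonical forms: basin compaction + exact two-level minimization --------
#
# The canonical form of a synchronously updated network is obtained by
# (1) compacting the transition map so every state lands directly in its
# attractor orbit while each cycle survives at full length, (2) reading off
# the minterms of each node from the compacted map, and (3) exact two-level
# minimization (Quine-McCluskey prime implicants + minimum cover). The
# result is a minimal network whose landscape -- attractors and basins -- is
# identical to the original's.

#' Compact a map onto its attractors
#'
#' Returns `m` composed with itself `t*` times, where `t*` is the least
#' `t >= max transient` with `gcd(t, L) = 1` for every cycle length `L`.
#' Raising to such a power sends every state into its attractor orbit in one
#' step while restricting to a full-length cycle on each orbit (a power
#' coprime to the period is again a single cycle), which is exactly the
#' compaction a canonical form requires.
#'
#' @param m an `integer_map`.
#' @return the compacted `integer_map`.
#' @export
compact_map <- function(m) {
  fg <- functional_graph_analysis(m)
  t_star <- max(fg$depth)
  while (any(vapply(fg$periods, function(L) gcd2(t_star, L), 0) != 1)) {
    t_star <- t_star + 1L
  }
  map_power(m, t_star)
}

#' Minterm table of an integer map
#'
#' Node `i`'s minterm set is the set of input states whose image has bit `i`
#' set (with `x1` the most significant bit) -- the sum-of-minterms reading of
#' the map's truth table.
#'
#' @param m an `integer_map`.
#' @return list of length `n`; element `i` the sorted integer minterms of
#'   node `i`.
#' @export
minterms_from_map <- function(m) {
  n <- m$n
  w <- 0:(2^n - 1L)
  lapply(seq_len(n), function(i) {
    w[bitwAnd(bitwShiftR(m$image, n - i), 1L) == 1L]
  })
}

# Quine-McCluskey ----------------------------------------------------------
#
# Implicants are (bits, mask) pairs on n variables: mask bits are don't-
# cares, the remaining bits fix literals. An implicant covers minterm w iff
# (w AND NOT mask) == bits.

qm_prime_implicants <- function(minterms, n) {
  cur <- unique(cbind(bits = as.integer(minterms), mask = 0L))
  primes <- NULL
  while (nrow(cur) > 0L) {
    combined <- logical(nrow(cur))
    nxt <- NULL
    ones <- vapply(seq_len(nrow(cur)), function(k) {
      sum(decode_state(cur[k, "bits"], max(n, 1L)))
    }, 0L)
    ord <- order(ones)
    cur <- cur[ord, , drop = FALSE]
    ones <- ones[ord]
    for (a in seq_len(nrow(cur))) {
      for (b in seq_len(nrow(cur))) {
        if (ones[b] != ones[a] + 1L) next
        if (cur[a, "mask"] != cur[b, "mask"]) next
        d <- bitwXor(cur[a, "bits"], cur[b, "bits"])
        if (bitwAnd(d, d - 1L) != 0L) next # not a single-bit difference
        combined[a] <- combined[b] <- TRUE
        nxt <- rbind(nxt, c(bits = bitwAnd(cur[a, "bits"], cur[b, "bits"]),
                            mask = bitwOr(cur[a, "mask"], d)))
      }
    }
    primes <- rbind(primes, cur[!combined, , drop = FALSE])
    cur <- if (is.null(nxt)) matrix(integer(0), 0, 2,
                                    dimnames = list(NULL, c("bits", "mask")))
           else unique(nxt)
  }
  unique(primes)
}

# Exact minimum cover with a deterministic tie-break: fewest terms, then
# fewest literals, then lexicographically smallest (bits, mask) sequence.
qm_min_cover <- function(primes, minterms, n) {
  nlit <- n - vapply(seq_len(nrow(primes)), function(k) {
    sum(decode_state(primes[k, "mask"], max(n, 1L)))
  }, 0L)
  ord <- order(nlit, primes[, "bits"], primes[, "mask"])
  primes <- primes[ord, , drop = FALSE]
  nlit <- nlit[ord]

  covers <- lapply(seq_len(nrow(primes)), function(k) {
    minterms[bitwAnd(minterms, bitwNot(primes[k, "mask"])) == primes[k, "bits"]]
  })
  covered_by <- lapply(minterms, function(w) {
    which(vapply(covers, function(cv) w %in% cv, TRUE))
  })

  # essential primes first
  chosen <- sort(unique(vapply(covered_by[lengths(covered_by) == 1L],
                               `[[`, 0L, 1L)))
  covered <- unique(unlist(covers[chosen]))
  remaining <- setdiff(minterms, covered)

  best <- NULL
  best_key <- NULL
  sel_key <- function(sel) {
    c(length(sel), sum(nlit[sel]), as.vector(t(primes[sel, , drop = FALSE])))
  }
  key_less <- function(a, b) {
    la <- max(length(a), length(b))
    a <- c(a, rep(Inf, la - length(a)))
    b <- c(b, rep(Inf, la - length(b)))
    d <- a - b
    i <- which(d != 0)
    length(i) > 0 && d[i[1]] < 0
  }
  search <- function(sel, remaining) {
    if (length(remaining) == 0L) {
      k <- sel_key(sort(sel))
      if (is.null(best_key) || key_less(k, best_key)) {
        best <<- sort(sel)
        best_key <<- k
      }
      return(invisible())
    }
    if (!is.null(best_key) && length(sel) + 1L > best_key[1]) return(invisible())
    # branch on the hardest minterm (fewest covering primes)
    cand <- covered_by[match(remaining, minterms)]
    hard <- remaining[which.min(lengths(cand))]
    for (k in covered_by[[match(hard, minterms)]]) {
      search(c(sel, k), setdiff(remaining, covers[[k]]))
    }
  }
  search(chosen, remaining)
  primes[best, , drop = FALSE]
}

new_dnf <- function(n, terms = NULL, constant = NULL) {
  structure(list(n = as.integer(n), terms = terms, constant = constant),
            class = "bn_dnf")
}

#' Exact two-level minimization of a minterm set
#'
#' Quine-McCluskey prime implicant generation followed by an exact minimum
#' cover (essential primes, then branch-and-bound with a deterministic
#' tie-break: fewer terms, then fewer literals, then lexicographic order).
#' The minimized form evaluates identically to minterm membership on every
#' state; empty and full minterm sets give the constants 0 and 1.
#'
#' @param minterms integer vector of minterms (0-based states).
#' @param n number of variables.
#' @return a `bn_dnf`: either `constant` 0/1 or a `terms` matrix with
#'   columns `bits`/`mask` (mask bits are absent literals).
#' @export
minimize_dnf <- function(minterms, n) {
  minterms <- sort(unique(as.integer(minterms)))
  if (length(minterms) == 0L) return(new_dnf(n, constant = 0L))
  if (length(minterms) == 2^n) return(new_dnf(n, constant = 1L))
  primes <- qm_prime_implicants(minterms, n)
  cover <- qm_min_cover(primes, minterms, n)
  new_dnf(n, terms = cover)
}

#' Evaluate a minimized DNF on every state
#' @param d a `bn_dnf`.
#' @return integer 0/1 vector over states `0:(2^n - 1)`.
#' @export
eval_dnf <- function(d) {
  w <- 0:(2^d$n - 1L)
  if (!is.null(d$constant)) return(rep(d$constant, length(w)))
  out <- rep(0L, length(w))
  for (k in seq_len(nrow(d$terms))) {
    out <- bitwOr(out, as.integer(
      bitwAnd(w, bitwNot(d$terms[k, "mask"])) == d$terms[k, "bits"]))
  }
  out
}

# DNF -> expression tree (x1 = most significant bit).
dnf_to_expr <- function(d) {
  if (!is.null(d$constant)) return(bx_const(d$constant))
  n <- d$n
  terms <- lapply(seq_len(nrow(d$terms)), function(k) {
    bits <- decode_state(d$terms[k, "bits"], n)
    mask <- decode_state(d$terms[k, "mask"], n)
    lits <- lapply(which(mask == 0L), function(i) {
      if (bits[i] == 1L) bx_var(i) else bx_not(bx_var(i))
    })
    if (length(lits) == 0L) bx_const(1L) else bx_and(lits)
  })
  bx_or(terms)
}

#' Canonical form of a synchronously updated network
#'
#' Pipeline: integer map -> basin compaction -> per-node minterms -> exact
#' minimization -> network. The output has one minimized two-level rule per
#' node and is dynamically equivalent to the input (identical attractors and
#' basins); this is verified before returning.
#'
#' @param net a `boolean_network`.
#' @param cap state-space cap (see [build_integer_map()]).
#' @return a `boolean_network` with the same node names.
#' @export
canonical_network <- function(net, cap = default_state_cap()) {
  m <- build_integer_map(net, cap = cap)
  cm <- compact_map(m)
  mt <- minterms_from_map(cm)
  rules <- lapply(mt, function(ms) dnf_to_expr(minimize_dnf(ms, net$n)))
  out <- new_boolean_network(net$nodes, rules)
  if (!check_equivalence(net, out, cap = cap)) {
    stop("internal error: canonical network is not landscape-equivalent")
  }
  out
}

#' Dynamical equivalence of two networks
#'
#' Two networks are dynamically equivalent when their attractor landscapes
#' are identical: same attractor orbits and the same basin assignment for
#' every initial state. Their one-step maps may differ.
#'
#' @param a,b `boolean_network`s with the same node count.
#' @param cap state-space cap.
#' @return `TRUE` or `FALSE`.
#' @export
check_equivalence <- function(a, b, cap = default_state_cap()) {
  if (a$n != b$n) stop("networks have different node counts")
  la <- landscape_from_attractors(build_integer_map(a, cap = cap))
  lb <- landscape_from_attractors(build_integer_map(b, cap = cap))
  identical(la$pairs, lb$pairs)
}
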