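# Deterministic periodic asynchronous updating -----------------------------
#
# A schedule assigns each node an update period tau_i (node i fires at the
# steps divisible by tau_i), or gives an explicit cyclic list of update
# subsets. Each step is a subset-update map (update the scheduled nodes,
# copy the rest); composing one full hyperperiod of steps yields a single
# map G whose attractors define the asynchronous landscape. Synchronous
# fixed points are fixed under every subset-update map, so they survive any
# schedule; cycles and basins generally do not.

#' Construct an update schedule
#'
#' @param periods named or positional integer vector of per-node periods
#'   `tau_i >= 1`; node `i` is updated at steps `t` with `t mod tau_i = 0`
#'   (steps are 1-based), so all-`tau = 1` is the synchronous scheme.
#' @param sequence alternatively, an explicit list of node-index subsets
#'   applied at steps `1, 2, ...` and repeated cyclically (the empty integer
#'   vector is a no-op step).
#' @return an `update_schedule` with the hyperperiod in `$hyperperiod`
#'   (`lcm` of the periods, or the sequence length).
#' @export
update_schedule <- function(periods = NULL, sequence = NULL) {
  if (is.null(periods) == is.null(sequence)) {
    stop("give exactly one of `periods` or `sequence`")
  }
  if (!is.null(periods)) {
    periods <- as.integer(periods)
    if (length(periods) == 0L || any(periods < 1L)) {
      stop("periods must be positive integers")
    }
    P <- as.integer(Reduce(lcm2, periods))
    structure(list(form = "periods", periods = periods, hyperperiod = P),
              class = "update_schedule")
  } else {
    if (length(sequence) == 0L) stop("sequence must be non-empty")
    sequence <- lapply(sequence, function(s) sort(unique(as.integer(s))))
    structure(list(form = "sequence", sequence = sequence,
                   hyperperiod = length(sequence)),
              class = "update_schedule")
  }
}

#' Subset-update map
#'
#' One asynchronous micro-step: the nodes in `subset` are updated by their
#' rules evaluated on the current state, all other bits are copied.
#'
#' @param net a `boolean_network`.
#' @param subset integer vector of node indices (possibly empty, giving the
#'   identity map).
#' @param cap state-space cap.
#' @return an `integer_map`.
#' @export
subset_update_map <- function(net, subset, cap = default_state_cap()) {
  check_cap(net$n, cap)
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) > 0L && (min(subset) < 1L || max(subset) > net$n)) {
    stop("subset contains node indices outside 1..", net$n)
  }
  n <- net$n
  w <- 0:(2^n - 1L)
  getvar <- state_var_accessor(w, n)
  img <- 0
  for (i in seq_len(n)) {
    bit <- if (i %in% subset) eval_expr(net$rules[[i]], getvar) else getvar(i)
    img <- img + bit * 2^(n - i)
  }
  new_integer_map(n, as.integer(rep_len(img, 2^n)))
}

#' Update subsets of one hyperperiod
#'
#' @param sched an `update_schedule`.
#' @param net a `boolean_network` (for the node count).
#' @return list of length `hyperperiod`; element `t` the node subset updated
#'   at step `t` (for the periods form, `{i : t mod tau_i = 0}`).
#' @export
schedule_subsets <- function(sched, net) {
  if (sched$form == "periods") {
    if (length(sched$periods) != net$n) {
      stop("schedule has ", length(sched$periods), " periods but the network has ",
           net$n, " nodes")
    }
    lapply(seq_len(sched$hyperperiod), function(t) {
      which(t %% sched$periods == 0L)
    })
  } else {
    if (length(unlist(sched$sequence)) > 0L &&
        max(unlist(sched$sequence)) > net$n) {
      stop("sequence refers to node indices outside 1..", net$n)
    }
    sched$sequence
  }
}

#' Step maps of one hyperperiod
#' @param sched an `update_schedule`.
#' @param net a `boolean_network`.
#' @param cap state-space cap.
#' @return list of `integer_map`s, one per step, in step order.
#' @export
schedule_steps <- function(sched, net, cap = default_state_cap()) {
  lapply(schedule_subsets(sched, net), function(s) {
    subset_update_map(net, s, cap = cap)
  })
}

# Hyperperiod map: apply the step maps in time order.
hyperperiod_map <- function(net, sched, cap = default_state_cap()) {
  steps <- schedule_steps(sched, net, cap = cap)
  acc <- new_integer_map(net$n, 0:(2^net$n - 1L))
  for (st in steps) acc <- compose_maps(st, acc)
  acc
}

#' Asynchronous attractor landscape of a schedule
#'
#' Builds the hyperperiod map `G` (composition of the step maps in step
#' order) and reports its attractors, basins and landscape, together with
#' which synchronous attractors are preserved or lost under the schedule.
#'
#' @param net a `boolean_network`.
#' @param sched an `update_schedule`.
#' @param cap state-space cap.
#' @return list with `map` (`G`), `attractors`, `basins` (a `basin_map`),
#'   `landscape`, and `sync_comparison` (orbits of the synchronous scheme
#'   marked preserved/lost).
#' @export
async_landscape <- function(net, sched, cap = default_state_cap()) {
  G <- hyperperiod_map(net, sched, cap = cap)
  bm <- compute_basins(G)
  L <- landscape_from_attractors(G)
  sync_atts <- find_cycles(build_integer_map(net, cap = cap))
  async_orbits <- lapply(bm$attractors, `[[`, "orbit")
  comparison <- lapply(sync_atts, function(a) {
    list(orbit = a$orbit, kind = a$kind,
         preserved = any(vapply(async_orbits, identical, TRUE, y = a$orbit)))
  })
  list(map = G, attractors = bm$attractors, basins = bm,
       landscape = L, sync_comparison = comparison)
}

#' Compare the landscapes of two schedules
#'
#' @param net a `boolean_network`.
#' @param s1,s2 `update_schedule`s.
#' @param cap state-space cap.
#' @return list with per-schedule attractor orbits, the orbits common to
#'   both, orbits exclusive to each, per-schedule basin sizes keyed by the
#'   orbit, and `identical_landscape`.
#' @export
compare_schedules <- function(net, s1, s2, cap = default_state_cap()) {
  a1 <- async_landscape(net, s1, cap = cap)
  a2 <- async_landscape(net, s2, cap = cap)
  key <- function(orbit) paste(orbit, collapse = ",")
  o1 <- vapply(a1$attractors, function(a) key(a$orbit), "")
  o2 <- vapply(a2$attractors, function(a) key(a$orbit), "")
  b1 <- stats::setNames(lengths(a1$basins$basins), o1)
  b2 <- stats::setNames(lengths(a2$basins$basins), o2)
  list(orbits_1 = o1, orbits_2 = o2,
       common = intersect(o1, o2),
       only_1 = setdiff(o1, o2), only_2 = setdiff(o2, o1),
       basin_sizes_1 = as.list(b1), basin_sizes_2 = as.list(b2),
       identical_landscape = identical(a1$landscape$pairs, a2$landscape$pairs))
}
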