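test_that("basin compaction reproduces the printed compacted maps", {
  expect_equal(compact_map(build_integer_map(fixture("E13")))$image,
               c(3L, 2L, 3L, 2L, 7L, 7L, 7L, 7L))
  expect_equal(compact_map(build_integer_map(fixture("E11")))$image,
               c(3L, 2L, 3L, 2L))
  # fixed-point-only system: two squarings send everything home
  expect_equal(compact_map(build_integer_map(fixture("E1")))$image,
               c(0L, 7L, 0L, 7L, 0L, 7L, 0L, 7L))
  # already-compact maps are preserved up to a coprime orbit rotation
  for (net in random_instances(15, sizes = 2:6, seed_base = 800L)) {
    m <- build_integer_map(net)
    cm <- compact_map(m)
    bm <- compute_basins(m)
    orbit_states <- unlist(lapply(bm$attractors, `[[`, "orbit"))
    # every state lands in its own attractor's orbit in one step
    for (w in 0:(2^m$n - 1L)) {
      expect_true(cm$image[w + 1L] %in%
                    bm$attractors[[bm$assignment[w + 1L]]]$orbit)
    }
    # each orbit is still a single full-length cycle of the compacted map
    for (a in find_cycles(cm)) expect_true(verify_union_decomposition(a))
    expect_equal(sort(unlist(lapply(find_cycles(cm), `[[`, "orbit"))),
                 sort(orbit_states))
  }
})

test_that("minterm extraction reads bits off the compacted map", {
  mt1 <- minterms_from_map(compact_map(build_integer_map(fixture("E1"))))
  expect_equal(mt1, rep(list(c(1L, 3L, 5L, 7L)), 3))
  mt13 <- minterms_from_map(compact_map(build_integer_map(fixture("E13"))))
  expect_equal(mt13[[2]], 0:7)  # x2 is set in every image
  zero <- structure(list(n = 2L, image = rep(0L, 4)), class = "integer_map")
  expect_equal(minterms_from_map(zero), list(integer(0), integer(0)))
})

test_that("exact two-level minimization matches hand simplifications and the truth table", {
  # {1,3,5,7} over 3 variables collapses to the single literal x3
  d <- minimize_dnf(c(1L, 3L, 5L, 7L), 3L)
  expect_equal(nrow(d$terms), 1L)
  expect_equal(eval_dnf(d), as.integer(0:7 %% 2 == 1))
  # constants
  expect_equal(minimize_dnf(integer(0), 2L)$constant, 0L)
  expect_equal(minimize_dnf(0:3, 2L)$constant, 1L)
  # a single minterm stays one full product term
  d1 <- minimize_dnf(5L, 3L)
  expect_equal(nrow(d1$terms), 1L)
  expect_equal(which(eval_dnf(d1) == 1L) - 1L, 5L)
  # exactness on random minterm sets (oracle: direct membership)
  set.seed(42)
  for (k in 1:40) {
    n <- sample(2:5, 1)
    ms <- sort(sample(0:(2^n - 1L), sample(0:(2^n), 1)))
    d <- minimize_dnf(ms, n)
    expect_equal(which(eval_dnf(d) == 1L) - 1L, as.integer(ms))
  }
})

test_that("canonical networks reproduce the printed simplified systems", {
  truth <- function(net) build_integer_map(net)$image
  # all three rules collapse to the x3 copy
  expect_equal(truth(canonical_network(fixture("E1"))), truth(fixture("E2")))
  expect_equal(truth(canonical_network(fixture("E11"))), truth(fixture("E12")))
  expect_equal(truth(canonical_network(fixture("E13"))), truth(fixture("E14")))
  # per-node truth-table equality, not just map equality
  cn <- canonical_network(fixture("E13"))
  e14 <- fixture("E14")
  w <- 0:7
  for (i in 1:3) {
    got <- vapply(w, function(s) evaluate_rule(cn, i, s), 0L)
    want <- vapply(w, function(s) evaluate_rule(e14, i, s), 0L)
    expect_equal(got, want, info = paste("node", i))
  }
})

test_that("dynamical equivalence compares landscapes, not one-step maps", {
  expect_true(check_equivalence(fixture("E1"), fixture("E2")))
  expect_true(check_equivalence(fixture("E13"), fixture("E14")))
  expect_true(check_equivalence(fixture("E11"), fixture("E12")))
  # E.8 has a 2-cycle; the 2-node identity network has 4 fixed points
  expect_false(check_equivalence(fixture("E8"), parse_network("x1, x1\nx2, x2")))
  expect_error(check_equivalence(fixture("E8"), fixture("E13")),
               "different node counts")
  # E.1 and E.2 have different one-step maps yet equal landscapes
  expect_false(identical(build_integer_map(fixture("E1"))$image,
                         build_integer_map(fixture("E2"))$image))
})

test_that("canonical networks are landscape-equivalent to their source", {
  for (net in random_instances(30, sizes = 2:6, seed_base = 900L)) {
    expect_true(check_equivalence(net, canonical_network(net)))
  }
})
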