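test_that("subset-update maps match the printed step functions", {
  net <- fixture("E8")
  expect_equal(subset_update_map(net, integer(0))$image, 0:3)        # f0
  expect_equal(subset_update_map(net, 1L)$image, c(0L, 3L, 0L, 3L))  # f1
  expect_equal(subset_update_map(net, 2L)$image, c(0L, 0L, 3L, 3L))  # f2
  expect_equal(subset_update_map(net, 1:2)$image, c(0L, 2L, 1L, 3L)) # f3
  expect_error(subset_update_map(net, 5L), "node indices")
})

test_that("period schedules fire node i at multiples of tau_i", {
  net <- fixture("E8")
  sch <- update_schedule(periods = c(2L, 3L))
  expect_equal(sch$hyperperiod, 6L)
  expect_equal(schedule_subsets(sch, net),
               list(integer(0), 1L, 2L, 1L, integer(0), c(1L, 2L)))
  # explicit sequences pass through unchanged
  ex <- update_schedule(sequence = list(1L, 2L))
  steps <- schedule_steps(ex, net)
  expect_equal(steps[[1]]$image, c(0L, 3L, 0L, 3L))
  expect_equal(steps[[2]]$image, c(0L, 0L, 3L, 3L))
  # all-tau = 1 is the synchronous scheme
  sync <- update_schedule(periods = c(1L, 1L))
  expect_equal(schedule_subsets(sync, net), list(c(1L, 2L)))
  expect_error(update_schedule(periods = c(0L, 2L)), "positive")
  expect_error(update_schedule(), "exactly one")
  expect_error(update_schedule(periods = 2L) |> schedule_subsets(net),
               "2 nodes")
})

test_that("the (2,3) schedule keeps the fixed points and loses the cycle", {
  net <- fixture("E8")
  res <- async_landscape(net, update_schedule(periods = c(2L, 3L)))
  orbits <- lapply(res$attractors, `[[`, "orbit")
  expect_equal(orbits, list(0L, 3L))   # no cyclic attractor survives
  preserved <- vapply(res$sync_comparison, `[[`, TRUE, "preserved")
  kinds <- vapply(res$sync_comparison, `[[`, "", "kind")
  expect_true(all(preserved[kinds == "fixed"]))
  expect_false(any(preserved[kinds == "cyclic"]))
})

test_that("all-tau = 1 reproduces the synchronous landscape exactly", {
  for (net in c(list(fixture("E8"), fixture("E13")),
                random_instances(10, sizes = 2:5, seed_base = 1100L))) {
    res <- async_landscape(net, update_schedule(periods = rep(1L, net$n)))
    expect_equal(res$map$image, build_integer_map(net)$image)
    expect_equal(res$landscape$pairs,
                 landscape_from_attractors(build_integer_map(net))$pairs)
  }
})

test_that("hyperperiod composition equals stepping every trajectory", {
  for (net in random_instances(10, sizes = 2:5, seed_base = 1200L)) {
    set.seed(net$n * 17L)
    sched <- update_schedule(periods = sample(1:3, net$n, replace = TRUE))
    steps <- schedule_steps(sched, net)
    G <- async_landscape(net, sched)$map
    for (w in 0:(2^net$n - 1L)) {
      cur <- w
      for (st in steps) cur <- st$image[cur + 1L]
      expect_equal(G$image[w + 1L], cur)
    }
  }
})

test_that("synchronous fixed points are invariant under every subset update", {
  for (net in random_instances(20, sizes = 2:6, seed_base = 1300L)) {
    fps <- find_fixed_points(build_integer_map(net))
    subsets <- lapply(0:(2^net$n - 1L), function(b) which(decode_state(b, net$n) == 1L))
    for (s in subsets) {
      msub <- subset_update_map(net, s)
      expect_equal(msub$image[fps + 1L], fps)
    }
    # hence any schedule's hyperperiod map fixes them too
    sched <- update_schedule(periods = rep_len(c(2L, 3L), net$n))
    G <- async_landscape(net, sched)$map
    expect_equal(G$image[fps + 1L], fps)
  }
})

test_that("schedule comparison reports preserved orbits and basin differences", {
  net <- fixture("E8")
  fwd <- update_schedule(periods = c(2L, 3L))
  rev_seq <- update_schedule(sequence = rev(schedule_subsets(fwd, net)))
  cmp <- compare_schedules(net, fwd, rev_seq)
  expect_setequal(cmp$common, c("0", "3"))     # fixed points in both
  expect_length(cmp$only_1, 0L)
  expect_false(cmp$identical_landscape)        # basin membership differs
  same <- compare_schedules(net, fwd, fwd)
  expect_true(same$identical_landscape)
  expect_length(same$only_1, 0L)
  expect_length(same$only_2, 0L)
  # sync vs (2,3): the cycle {1,2} exists only under the synchronous scheme
  sync <- update_schedule(periods = c(1L, 1L))
  cmp2 <- compare_schedules(net, sync, fwd)
  expect_true("1,2" %in% cmp2$only_1)
})
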