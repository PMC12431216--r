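# boolscape

Exact analysis of Boolean network dynamics on integer-encoded state
spaces: attractor landscapes, canonical forms, synchronous and
deterministic asynchronous update schemes, and a modular solver for large
networks. It is aimed at systems biologists who model gene regulatory
logic as Boolean networks and want exact, reproducible answers to "what
are the attractors, who reaches them, and what is the minimal network with
the same dynamics?".

## What it computes

A Boolean network `F : B^n -> B^n` (one logic rule per node,
`x_i(t+1) = f_i(x(t))`) is re-encoded on the integer state space
`Ω = {0, ..., 2^n - 1}` with `x1` as the most significant bit. The package
then provides:

* **Transition maps and matrices** — the tabulated one-step map `f**` and
  the `2^n × 2^n` 0/1 transition matrix `M_F` over the Boolean semiring,
  whose powers implement the synchronous scheme
  `S(t, u0) = (M_F)^t u0` (the deterministic special case of the
  Chapman–Kolmogorov iteration).
* **Landscapes** — the stationary matrix `S* = lim S(t)` for
  fixed-point-only systems, and the periodic logical sum of powers when
  cycles are present; equivalently (and independently) the attractors,
  basins and basin×orbit relation read off the functional graph.
* **Canonical forms** — basin compaction (the least map power at or above
  the longest transient and coprime to every cycle length), per-node
  minterm extraction, and exact Quine–McCluskey minimization, yielding a
  minimal network with an identical landscape; equivalence is verified.
* **Asynchronous schedules** — per-node update periods or explicit subset
  sequences; the hyperperiod composition of subset-update maps, its
  attractors, and comparisons against the synchronous solution (fixed
  points always survive; cycles and basins generally do not).
* **Modular solving** — per-module fixed states under frozen upstream
  inputs (semi-attractors), candidate joining, full-network validation
  `F(s) = s`, and basin sizes from driver-variable support, scaling to
  hundreds of nodes.

## Worked example

The 3-node network with rules `x1+ = x1`, `x2+ = x2 + x3`,
`x3+ = (x1 + !x3)(x2 + !x3)` (product = AND, `+` = OR, `!` = NOT):

```r
library(boolscape)
net <- parse_network("x1+ = x1\nx2+ = x2 + x3\nx3+ = (x1 + !x3)(x2 + !x3)",
                     dialect = "paper")
m <- build_integer_map(net)
m$image
#> [1] 1 2 3 2 5 6 7 7
find_cycles(m)
#> [[1]] Cyclic attractor (period 2): 2 -> 3
#> [[2]] Fixed-point attractor: 7
compute_basins(m)$basins
#> [[1]] 0 1 2 3
#> [[2]] 4 5 6 7
canonical_network(net)
#> Boolean network with 3 node(s)
#>   x1 <- x1
#>   x2 <- 1
#>   x3 <- !x3 | x1
```

The image table says state 0 steps to 1, 1 to 2, and so on. The functional
graph of that table has one 2-cycle `{2, 3}` and one fixed point `7`; the
four states `0–3` flow into the cycle and `4–7` into the fixed point. The
canonical form is the smallest network with exactly that landscape: `x2`
collapses to the constant 1 and `x3` to `x1 | !x3`, while `x1` keeps its
self-copy — the three rules that actually drive the dynamics.

The same machinery scales via the modular route:

```r
e19 <- fixture("E19")                      # 9-node two-chain network
b <- basin_size_by_support(e19, consecutive_partition(e19, 3))
b$drivers        # 1 4    -> x1 and x4 drive everything
b$basin_size     # 128 128 128 128
```

A command-line wrapper lives at `inst/cli/boolscape`
(`attractors`, `landscape`, `canonical`, `async`, `modular`, `matrix`
subcommands); see `?run_cli`.

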