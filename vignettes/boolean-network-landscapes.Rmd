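---
title: "Attractor landscapes, canonical forms and update schemes for Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor landscapes, canonical forms and update schemes for Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolscape)
```

## The model

A Boolean network on $n$ nodes is a map $F:\mathbb{B}^n \to \mathbb{B}^n$,
$\mathbb{B} = \{0, 1\}$, given by one logic rule per node,
$x_i(t+1) = f_i(x_1(t), \dots, x_n(t))$. Under the synchronous update scheme
every rule fires at once, so the dynamics is deterministic and every
trajectory eventually enters an attractor: a fixed point $F(p) = p$ or a
cycle of states visited periodically. The set of attractors together with
the map from each initial state to the attractor it reaches — the
*attractor landscape* — is the object this package computes, exactly.

The central device is integer re-encoding. A state is read as a binary
number with $x_1$ the most significant bit, so the state space becomes
$\Omega = \{0, \dots, 2^n - 1\}$ and $F$ becomes a tabulated function
$f^{**}:\Omega \to \Omega$ (`build_integer_map()`). The bit order is not a
free choice here: it is fixed by the worked transition tables the package
reproduces (the 2-node cross-coupling network must send state 1 to state 2
and vice versa), and every other convention fails those tables.

Three equivalent views of the dynamics are maintained:

* the **integer map** (the canonical representation; a length-$2^n$ table);
* the **transition matrix** $M_F$, a $2^n \times 2^n$ 0/1 matrix over the
  Boolean semiring with entry $(i, j) = 1$ iff $j \to i$. $t$-step dynamics
  is the matrix power $S(t) = M_F^t u_0$ — the discrete, deterministic
  special case of the Chapman–Kolmogorov iteration, which is why a
  stationary solution $S^* = \lim_{t\to\infty} S(t)$ exists for
  fixed-point-only systems and the powers become periodic when cycles are
  present;
* the **functional graph** of the map, whose cycles are the attractors and
  whose weakly connected components are the basins.

A note on matrix orientation: with $u_0$ a one-hot *column* and powers
applied on the left, columns must index source states. The package follows
this convention throughout because it is the only one consistent with the
worked $4\times4$ matrices it reproduces in its tests.

## Solving the synchronous scheme

`power_orbit()` returns the least $T_0$ and least period $p$ with
$M^{T_0+p} = M^{T_0}$. Rather than probing a large exponent, both are read
exactly off the functional graph: $T_0$ is the longest transient and $p$
the least common multiple of the cycle lengths. `stationary_landscape()`
then returns $M^{T_0}$ when $p = 1$, and otherwise the entrywise logical OR
of $M^t$ over the window $t \in \{T_0, \dots, T_0 + p - 1\}$. Any full
window at or after $T_0$ gives the same union — the choice of window start
is therefore immaterial, and the result pairs every initial state with
*every* state of the orbit it reaches (a function for fixed-point-only
systems, a relation otherwise).

`find_cycles()` and `compute_basins()` compute the same landscape without
matrices. The implementation is fully vectorized rather than a per-state
coloring walk: the set of cycle states is read off a high power of the map
(computed by composition-by-squaring; any exponent at least the longest
transient works, and $2^n$ always is), cycles are then walked within that
set, and transient depths come from a reverse breadth-first search over the
predecessor lists. This was a deliberate design choice: in R an interpreted
per-state loop over $2^n$ states is orders of magnitude slower than the
handful of whole-table operations used here, and the two formulations are
exactly equivalent. The matrix route and the graph route are kept as two
independent code paths and cross-checked against each other (and against a
naive per-trajectory oracle) in the test suite.

```{r}
net <- fixture("E13")
net
m <- build_integer_map(net)
find_cycles(m)
lengths(compute_basins(m)$basins)
```

## Canonical forms

The canonical form of a synchronously updated network is the minimal
network — one minimized two-level rule per node — with the *same landscape*
(same attractors and same basins). It is computed in three steps
(`canonical_network()`):

1. **Compaction** (`compact_map()`): replace the map by the power
   $f^{t^*}$, where $t^*$ is the least $t$ at or above the longest
   transient with $\gcd(t, L) = 1$ for every cycle length $L$. Such a $t$
   always exists, every state then lands in its attractor orbit in one
   step, and each orbit remains a single full-length cycle (a power coprime
   to the period is again a cyclic permutation of full order). The
   coprimality condition is the package's own definitional choice for how
   transient states map onto cyclic orbits after compaction; it is the
   unique simple power rule that preserves cycles and it reproduces both
   worked compacted maps in the test suite exactly.
2. **Minterms** (`minterms_from_map()`): node $i$'s on-set is the set of
   input states whose image has bit $i$ set.
3. **Exact minimization** (`minimize_dnf()`): Quine–McCluskey prime
   implicants followed by an exact minimum cover (essential primes, then
   branch-and-bound). Ties are broken deterministically — fewer terms, then
   fewer literals, then lexicographic order — so outputs are byte-stable.
   Hand-simplified reference systems are matched up to logical equivalence
   (truth-table equality per node), never by string comparison.

`check_equivalence()` defines dynamical equivalence as identity of
landscapes (attractors *and* basin assignment); the one-step maps of a
network and its canonical form usually differ.

```{r}
canonical_network(fixture("E13"))
```

## Asynchronous schedules

The package implements deterministic periodic asynchrony: a schedule
assigns node $i$ a period $\tau_i$ (node $i$ fires at steps $t$ with
$t \bmod \tau_i = 0$, steps 1-based), or lists update subsets explicitly.
Each step is a subset-update map (scheduled nodes updated, others copied),
and the composition of one hyperperiod ($\mathrm{lcm}$ of the $\tau_i$) of
steps is a single map $G$ whose attractors define the asynchronous
landscape. Explicit subset sequences exist because a bare period vector
does not pin down the phase of the printed step orderings in the worked
asynchronous example; when an exact ordering matters, it can be given
verbatim. Stochastic random-order asynchrony is out of scope.

Two structural facts follow immediately from this formulation and are
enforced as tested invariants: a synchronous fixed point is fixed by
*every* subset-update map, hence by $G$ under every schedule; and because
function composition is not commutative, different schedules yield
different $G$'s — cyclic attractors are generally destroyed and basins
redistributed, which is also why no unique canonical form exists for
asynchronously updated systems. The module therefore only reports
landscapes and differences (`compare_schedules()`), never an asynchronous
canonical form.

```{r}
res <- async_landscape(fixture("E8"), update_schedule(periods = c(2, 3)))
res$map$image           # the hyperperiod map
str(res$sync_comparison)
```

## Modular solving of large networks

For networks beyond exhaustive reach, `module_semi_attractors()` solves a
partition of the nodes whose module-level dependency graph is acyclic
(feedback between modules is rejected; only the partition's DAG condition
is checked, automatic SCC partitioning is not attempted). Modules are
processed in topological order; for each combination of upstream
semi-attractor values restricted to a module's external inputs, those
inputs are frozen to constants and the module's fixed states are collected.
`join_candidates()` takes the cross product, `validate_candidates()` keeps
exactly the full states with $F(s) = s$ — evaluated rule-wise, so a
200-node network needs only 2048 candidate evaluations rather than
$2^{200}$ states. Only fixed semi-attractors are joined; a frozen module
with no fixed state is reported as unsupported rather than silently
dropped.

`basin_size_by_support()` adds basin counting: the support of each frozen
module's compacted map (computed by an exact bit-flip test, which equals
the variable support of the minimized canonical form) is pooled into a
driver set $D$. When the validated attractors are in bijection with the
$2^{|D|}$ driver assignments, each basin holds exactly $2^{n-|D|}$ states —
all configurations sharing that attractor's driver values — and the driver
assignment is reported as the attractor's reachability condition. When the
bijection fails the function refuses with an explicit error instead of
returning a wrong count. On the 9-node worked chain this yields drivers
$\{x_1, x_4\}$ and four basins of $2^7 = 128$ states, confirmed by brute
force over all 512 states in the tests; on the 200-node extension the same
logic gives $2^{198}$ states per basin.

```{r}
e19 <- fixture("E19")
b <- basin_size_by_support(e19, consecutive_partition(e19, 3))
b$drivers
b$basin_size
b$conditions[[2]]
```

## Random networks, tolerances and limits

* `random_network(n, max_inputs, seed)` draws, per node, a uniform truth
  table over at most `max_inputs` uniformly chosen regulators. This
  emulates the unbiased random ensembles standard in Boolean-network
  studies; it does not emulate the degree distributions, canalization or
  bias of curated biological rule sets, so property-suite results certify
  algebraic correctness of the machinery, not biological realism. The
  property suites run 200 seeded instances with $n \in \{2, \dots, 6\}$,
  sizes at which every check has an independent brute-force oracle while
  the whole suite stays fast.
* Everything is integer-exact; there are no numerical tolerances anywhere.
  All comparisons in the tests are equality comparisons.
* Exhaustive operations refuse networks above the state-space cap
  (default $n = 24$, configurable) with an explicit error rather than
  attempting a $2^n$ table. Exact minimization is practical to roughly a
  dozen variables per rule; the modular route exists precisely so that
  large networks never need a global table. In the shipped analyses the
  largest exhaustive objects are the $2^{20}$-state module maps of the
  200-node chain.
* Degenerate inputs are handled explicitly: constant rules are legal,
  empty update subsets are identity steps, empty/full minterm sets minimize
  to the constants 0/1, and a map that is already compact is preserved (up
  to the coprime orbit rotation) by compaction.

## Known limitations

Only fixed-point semi-attractors participate in the modular join; cyclic
semi-attractors and partitions with inter-module feedback are rejected.
The asynchronous module covers deterministic periodic schedules only.
Multi-valued logic and SBML-qual/GINsim interchange are out of scope;
rule I/O is BoolNet-style `.bnet` text plus the product/sum notation in
which such systems are usually printed.
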