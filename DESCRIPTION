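Package: boolscape
Title: Attractor Landscapes and Canonical Forms of Synchronous and
    Asynchronous Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the exact analysis of Boolean network dynamics on
    integer-encoded state spaces. Converts logic rules to integer transition
    maps and 0/1 transition matrices over the Boolean semiring, solves the
    synchronous scheme by matrix iteration (a deterministic special case of
    the Chapman-Kolmogorov equation), detects fixed-point and cyclic
    attractors with their basins of attraction from the functional graph,
    extracts minimal dynamically equivalent networks (canonical forms) by
    basin compaction and exact two-level logic minimization, analyses
    deterministic periodic asynchronous update schedules as compositions of
    subset-update maps, and solves large modular networks by joining
    per-module semi-attractors with frozen upstream inputs. Reads and writes
    BoolNet-style .bnet rule files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
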