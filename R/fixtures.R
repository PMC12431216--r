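# Built-in example networks and seeded random networks ---------------------
#
# The worked-example networks used throughout the documentation and tests,
# written in the product/sum dialect in which they are usually printed
# (juxtaposition = AND, + = OR, ! = NOT). "E19" is a 9-node pair of
# switch-driven chains with four fixed points; "E20" extends it to 200
# nodes by continuing the second chain.

fixture_texts <- function() {
  list(
    # three nodes all slaved to x3
    E1 = "x1+ = x2 x3\nx2+ = x3\nx3+ = x3",
    E2 = "x1+ = x3\nx2+ = x3\nx3+ = x3",
    # two-node OR / XNOR pair: two fixed points at 2 and 3
    E4 = "x1+ = x1 + x2\nx2+ = !x1 !x2 + x1 x2",
    # cross-coupling swap: fixed points 0 and 3, cycle {1, 2}
    E8 = "x1+ = x2\nx2+ = x1",
    # pure 2-cycle system
    E11 = "x1+ = x1 + x2\nx2+ = !x2",
    E12 = "x1+ = 1\nx2+ = !x2",
    # mixed system: cycle {2, 3} and fixed point 7
    E13 = "x1+ = x1\nx2+ = x2 + x3\nx3+ = (x1 + !x3)(x2 + !x3)",
    E14 = "x1+ = x1\nx2+ = 1\nx3+ = x1 + !x3"
  )
}

e19_network <- function() {
  parse_network(paste(
    c("x1, x1", "x2, x1", "x3, x2",
      "x4, x4", "x5, x4", "x6, x5",
      "x7, x6", "x8, x7", "x9, x8"),
    collapse = "\n"))
}

e20_network <- function() {
  lines <- c("x1, x1", "x2, x1", "x3, x2",
             "x4, x4", "x5, x4", "x6, x5",
             paste0("x", 7:200, ", x", 6:199))
  parse_network(paste(lines, collapse = "\n"))
}

#' Built-in example networks
#'
#' @param name one of `"E1"`, `"E2"`, `"E4"`, `"E8"`, `"E11"`, `"E12"`,
#'   `"E13"`, `"E14"`, `"E19"`, `"E20"`.
#' @return a `boolean_network`.
#' @examples
#' fixture("E8")
#' @export
fixture <- function(name) {
  if (name == "E19") return(e19_network())
  if (name == "E20") return(e20_network())
  texts <- fixture_texts()
  if (!name %in% names(texts)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(c(names(texts), "E19", "E20"), collapse = ", "))
  }
  parse_network(texts[[name]], dialect = "paper")
}

#' Seeded random Boolean network
#'
#' Each node receives a uniformly drawn truth table over at most
#' `max_inputs` randomly chosen regulators. The generator is fully
#' reproducible from `seed` and restores the caller's RNG state.
#'
#' @param n number of nodes.
#' @param max_inputs maximum regulators per node (`<= n`).
#' @param seed integer seed.
#' @return a `boolean_network` with nodes `x1..xn`.
#' @export
random_network <- function(n, max_inputs, seed) {
  if (n < 1L || max_inputs < 1L || max_inputs > n) {
    stop("need n >= 1 and 1 <= max_inputs <= n")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  rules <- lapply(seq_len(n), function(i) {
    k <- sample.int(max_inputs, 1L)
    regs <- sort(sample.int(n, k))
    tt <- sample(0:1, 2^k, replace = TRUE)
    minterms <- which(tt == 1L) - 1L
    if (length(minterms) == 0L) return(bx_const(0L))
    if (length(minterms) == 2^k) return(bx_const(1L))
    bx_or(lapply(minterms, function(mt) {
      bits <- decode_state(mt, k)
      bx_and(lapply(seq_len(k), function(j) {
        if (bits[j] == 1L) bx_var(regs[j]) else bx_not(bx_var(regs[j]))
      }))
    }))
  })
  new_boolean_network(paste0("x", seq_len(n)), rules)
}

#' Render a state as a bit string
#' @param w integer state or 0/1 bit vector.
#' @param n node count (required when `w` is an integer).
#' @return character such as `"000111111"` (`x1` first).
#' @export
state_bits <- function(w, n = NULL) {
  bits <- if (length(w) > 1L) as.integer(w) else decode_state(w, n)
  paste(bits, collapse = "")
}

#' JSON attractor report
#'
#' @param m an `integer_map`.
#' @param path optional output file.
#' @param include_basins include the basin state lists (capped at
#'   `basin_cap` states each).
#' @param basin_cap cap for listed basin states.
#' @return the report list, invisibly when written to a file.
#' @export
attractor_report <- function(m, path = NULL, include_basins = FALSE,
                             basin_cap = 1024L) {
  bm <- compute_basins(m)
  rep_list <- lapply(seq_along(bm$attractors), function(i) {
    a <- bm$attractors[[i]]
    out <- list(kind = a$kind,
                period = a$period,
                orbit = a$orbit,
                orbit_bits = vapply(a$orbit, state_bits, "", n = m$n),
                basin_size = length(bm$basins[[i]]))
    if (include_basins) {
      out$basin <- utils::head(bm$basins[[i]], basin_cap)
    }
    out
  })
  report <- list(n = m$n, n_attractors = length(rep_list),
                 attractors = rep_list)
  if (is.null(path)) return(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
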