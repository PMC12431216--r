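# Boolean networks and the state <-> integer encoding ---------------------

#' @keywords internal
new_boolean_network <- function(nodes, rules) {
  stopifnot(length(nodes) == length(rules), length(nodes) >= 1L)
  structure(list(nodes = nodes, rules = rules, n = length(nodes)),
            class = "boolean_network")
}

#' Default cap on exhaustive state-space operations
#'
#' Exhaustive operations enumerate all `2^n` states; beyond `n = 24` the
#' tables no longer fit comfortably in memory, so they are refused with an
#' explicit error rather than attempted.
#' @keywords internal
default_state_cap <- function() 24L

check_cap <- function(n, cap = default_state_cap()) {
  if (n > cap) {
    stop("exhaustive operation refused: network has ", n,
         " nodes but the state-space cap is ", cap,
         " (2^n states would be enumerated); raise `cap` explicitly if intended")
  }
  invisible(n)
}

#' Parse a Boolean network from rule text
#'
#' Accepts BoolNet-style `.bnet` content (`targets, factors` header, one
#' `target, expression` line per node, `#` comments, operators `&`, `|`, `!`)
#' or a product/sum dialect in which juxtaposition denotes AND, `+` denotes
#' OR and `!` denotes negation; targets there may be written `x1+ = ...`.
#' Node order follows declaration order and every referenced variable must be
#' a declared target.
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines with the rule declarations.
#' @param dialect `"bnet"` (default) or `"paper"`.
#' @return an object of class `boolean_network` with fields `nodes`
#'   (character), `rules` (list of expression trees) and `n`.
#' @examples
#' net <- parse_network("x1, x1\nx2, x2 | x3\nx3, (x1 | !x3) & (x2 | !x3)")
#' net$nodes
#' @export
parse_network <- function(text, dialect = c("bnet", "paper")) {
  dialect <- match.arg(dialect)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  raw <- text
  keep <- !grepl("^[[:space:]]*(#|$)", raw)
  lines <- trimws(raw[keep])
  lineno <- which(keep)
  is_header <- grepl("^targets[[:space:]]*,[[:space:]]*factors$", lines,
                     ignore.case = TRUE)
  lines <- lines[!is_header]
  lineno <- lineno[!is_header]
  if (length(lines) == 0L) stop("no rule declarations found")

  split_line <- function(s, ln) {
    if (grepl(",", s, fixed = TRUE)) {
      i <- regexpr(",", s, fixed = TRUE)
      c(substr(s, 1L, i - 1L), substr(s, i + 1L, nchar(s)))
    } else if (dialect == "paper" && grepl("=", s, fixed = TRUE)) {
      i <- regexpr("=", s, fixed = TRUE)
      c(substr(s, 1L, i - 1L), substr(s, i + 1L, nchar(s)))
    } else {
      stop("line ", ln, ": expected 'target, expression'", call. = FALSE)
    }
  }
  parts <- mapply(split_line, lines, lineno, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  targets <- vapply(parts, function(p) sub("\\+$", "", trimws(p[1])), "",
                    USE.NAMES = FALSE)
  exprs_text <- vapply(parts, function(p) trimws(p[2]), "", USE.NAMES = FALSE)

  bad <- !grepl("^[A-Za-z_][A-Za-z0-9_.]*$", targets)
  if (any(bad)) {
    stop("line ", lineno[which(bad)[1]], ": invalid target name '",
         targets[which(bad)[1]], "'")
  }
  dup <- duplicated(targets)
  if (any(dup)) {
    stop("line ", lineno[which(dup)[1]], ": duplicate target '",
         targets[which(dup)[1]], "'")
  }

  idx <- seq_along(targets)
  names(idx) <- targets
  rules <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    lookup <- local({
      ln <- lineno[k]
      function(name) {
        if (is.na(idx[name])) {
          stop("line ", ln, ": undeclared variable '", name, "'", call. = FALSE)
        }
        unname(idx[name])
      }
    })
    rules[[k]] <- tryCatch(
      parse_rule_expr(exprs_text[k], dialect, lookup),
      error = function(e) {
        msg <- conditionMessage(e)
        if (grepl("^line ", msg)) stop(e)
        stop("line ", lineno[k], ": ", msg, call. = FALSE)
      }
    )
  }
  new_boolean_network(targets, rules)
}

#' Read a Boolean network from a .bnet file
#' @param path file path.
#' @param dialect expression dialect, see [parse_network()].
#' @return a `boolean_network`.
#' @export
read_bnet <- function(path, dialect = "bnet") {
  parse_network(readLines(path, warn = FALSE), dialect = dialect)
}

#' Serialize a network to BoolNet .bnet text
#' @param net a `boolean_network`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return character vector of lines, invisibly when writing to a file.
#' @export
write_bnet <- function(net, path = NULL) {
  lines <- c("targets, factors",
             vapply(seq_len(net$n), function(i) {
               paste0(net$nodes[i], ", ", format_expr(net$rules[[i]], net$nodes))
             }, ""))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", x$n, "node(s)\n")
  for (i in seq_len(x$n)) {
    cat("  ", x$nodes[i], " <- ", format_expr(x$rules[[i]], x$nodes), "\n", sep = "")
  }
  invisible(x)
}

#' Encode a bit vector as a state integer
#'
#' States are labelled by the integer `sum(bits[i] * 2^(n-i))`: node `x1`
#' carries the most significant bit, so e.g. with `n = 2` the state
#' `(x1=1, x2=0)` is `2`.
#'
#' @param bits integer 0/1 vector, `bits[i]` the state of node i.
#' @return integer in `0:(2^n - 1)`.
#' @export
encode_state <- function(bits) {
  n <- length(bits)
  if (n < 1L || n > 30L) stop("bit vector length must be in 1..30")
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0 or 1")
  as.integer(sum(as.integer(bits) * 2^(n - seq_len(n))))
}

#' Decode a state integer to its bit vector
#' @param w integer state in `0:(2^n - 1)`.
#' @param n number of nodes.
#' @return integer 0/1 vector of length `n` (`x1` first).
#' @export
decode_state <- function(w, n) {
  if (n < 1L || n > 30L) stop("n must be in 1..30")
  if (w < 0 || w >= 2^n) stop("state ", w, " out of range for n = ", n)
  bitwAnd(bitwShiftR(as.integer(w), n - seq_len(n)), 1L)
}

#' Evaluate one node's rule at a state
#' @param net a `boolean_network`.
#' @param node_index 1-based node index.
#' @param state either an integer state label or a 0/1 bit vector of length n.
#' @return 0 or 1.
#' @export
evaluate_rule <- function(net, node_index, state) {
  if (node_index < 1L || node_index > net$n) {
    stop("node index ", node_index, " out of range 1..", net$n)
  }
  bits <- if (length(state) == net$n && all(state %in% c(0L, 1L))) {
    as.integer(state)
  } else if (length(state) == 1L) {
    decode_state(state, net$n)
  } else {
    stop("state must be an integer label or a length-n bit vector")
  }
  eval_expr(net$rules[[node_index]], function(i) bits[i])
}
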