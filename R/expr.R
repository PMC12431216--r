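# Boolean expression trees -----------------------------------------------
#
# Rules are stored as small ASTs over node indices. Two textual dialects
# compile to the same AST:
#   * "bnet"  : BoolNet operators  &  |  !  ( )  and constants 0/1
#   * "paper" : product/sum notation where juxtaposition is AND, "+" is OR
#               and "!" is negation (the overbar of the printed rules)

bx_var <- function(i) structure(list(kind = "var", index = as.integer(i)), class = "bool_expr")
bx_const <- function(v) structure(list(kind = "const", value = as.integer(v)), class = "bool_expr")
bx_not <- function(e) structure(list(kind = "not", arg = e), class = "bool_expr")
bx_and <- function(args) {
  if (length(args) == 1L) return(args[[1L]])
  structure(list(kind = "and", args = args), class = "bool_expr")
}
bx_or <- function(args) {
  if (length(args) == 1L) return(args[[1L]])
  structure(list(kind = "or", args = args), class = "bool_expr")
}

#' Evaluate a Boolean expression
#'
#' Evaluates an expression tree against an arbitrary variable accessor, so the
#' same AST serves integer-encoded state vectors, candidate bit matrices and
#' modules with frozen external inputs.
#'
#' @param e expression tree.
#' @param getvar function taking a 1-based node index and returning an
#'   integer 0/1 vector (all calls must return vectors of one common length).
#' @return integer 0/1 vector.
#' @keywords internal
eval_expr <- function(e, getvar) {
  switch(e$kind,
    var = getvar(e$index),
    const = e$value,
    not = 1L - eval_expr(e$arg, getvar),
    and = Reduce(bitwAnd, lapply(e$args, eval_expr, getvar = getvar)),
    or = Reduce(bitwOr, lapply(e$args, eval_expr, getvar = getvar)),
    stop("unknown expression kind: ", e$kind)
  )
}

# Accessor for integer-encoded states: x1 is the most significant bit.
state_var_accessor <- function(w, n) {
  force(w); force(n)
  function(i) bitwAnd(bitwShiftR(w, n - i), 1L)
}

# Variable indices appearing in an expression.
expr_vars <- function(e) {
  switch(e$kind,
    var = e$index,
    const = integer(0),
    not = expr_vars(e$arg),
    sort(unique(unlist(lapply(e$args, expr_vars))))
  )
}

# Deparse to the bnet dialect (OR lowest precedence, then AND, then NOT).
format_expr <- function(e, nodes) {
  fmt <- function(x, parent) {
    s <- switch(x$kind,
      var = nodes[x$index],
      const = as.character(x$value),
      not = paste0("!", fmt(x$arg, "not")),
      and = paste(vapply(x$args, fmt, "", parent = "and"), collapse = " & "),
      or = paste(vapply(x$args, fmt, "", parent = "or"), collapse = " | ")
    )
    needs_paren <- (x$kind == "or" && parent %in% c("and", "not")) ||
      (x$kind == "and" && parent == "not")
    if (needs_paren) paste0("(", s, ")") else s
  }
  fmt(e, "top")
}

# Tokenizers ---------------------------------------------------------------

tokenize_bnet <- function(s) {
  pat <- "[A-Za-z_][A-Za-z0-9_.]*|[01]|[&|!()]"
  toks <- regmatches(s, gregexpr(pat, s))[[1]]
  resid <- gsub(pat, "", s)
  resid <- gsub("[[:space:]]", "", resid)
  if (nzchar(resid)) stop("unexpected character(s) '", resid, "'")
  toks
}

# In the paper dialect names are a letter block followed by digits, so a
# product like "x1x2" splits into two variables.
tokenize_paper <- function(s) {
  pat <- "[A-Za-z_]+[0-9]*|[01]|[+*!()]"
  toks <- regmatches(s, gregexpr(pat, s))[[1]]
  resid <- gsub(pat, "", s)
  resid <- gsub("[[:space:]]", "", resid)
  if (nzchar(resid)) stop("unexpected character(s) '", resid, "'")
  toks
}

# Recursive-descent parser shared by both dialects. `lookup` maps a name to
# a node index (or signals an undeclared-variable error).
parse_expr_tokens <- function(toks, dialect, lookup) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  is_atom_start <- function(t) {
    !is.na(t) && (t == "!" || t == "(" || t %in% c("0", "1") ||
      grepl("^[A-Za-z_]", t))
  }

  parse_or <- function() {
    or_op <- if (dialect == "bnet") "|" else "+"
    terms <- list(parse_and())
    while (!is.na(peek()) && peek() == or_op) {
      advance()
      terms <- c(terms, list(parse_and()))
    }
    bx_or(terms)
  }
  parse_and <- function() {
    factors <- list(parse_factor())
    repeat {
      t <- peek()
      if (dialect == "bnet") {
        if (!is.na(t) && t == "&") {
          advance()
          factors <- c(factors, list(parse_factor()))
        } else break
      } else {
        # "*" or plain juxtaposition both mean AND
        if (!is.na(t) && t == "*") {
          advance()
          factors <- c(factors, list(parse_factor()))
        } else if (is_atom_start(t)) {
          factors <- c(factors, list(parse_factor()))
        } else break
      }
    }
    bx_and(factors)
  }
  parse_factor <- function() {
    t <- advance()
    if (is.na(t)) stop("unexpected end of expression")
    if (t == "!") return(bx_not(parse_factor()))
    if (t == "(") {
      e <- parse_or()
      if (is.na(peek()) || advance() != ")") stop("missing closing parenthesis")
      return(e)
    }
    if (t %in% c("0", "1")) return(bx_const(as.integer(t)))
    if (grepl("^[A-Za-z_]", t)) return(bx_var(lookup(t)))
    stop("unexpected token '", t, "'")
  }

  e <- parse_or()
  if (!is.na(peek())) stop("unexpected token '", peek(), "' after expression")
  e
}

parse_rule_expr <- function(text, dialect, lookup) {
  toks <- if (dialect == "bnet") tokenize_bnet(text) else tokenize_paper(text)
  if (length(toks) == 0L) stop("empty expression")
  parse_expr_tokens(toks, dialect, lookup)
}
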