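# Integer transition maps and Boolean-semiring transition matrices --------
#
# The canonical representation of the synchronous dynamics is the integer
# map w -> F(w) tabulated over all 2^n states; the 2^n x 2^n 0/1 matrix is a
# derived view with entry (i, j) = 1 iff state j transitions to state i, so
# that t-step dynamics is the Boolean-semiring matrix power applied to a
# one-hot initial column.

new_integer_map <- function(n, image) {
  stopifnot(length(image) == 2^n, all(image >= 0L), all(image < 2^n))
  structure(list(n = as.integer(n), image = as.integer(image)),
            class = "integer_map")
}

#' @export
print.integer_map <- function(x, ...) {
  cat("Integer transition map on {0..", 2^x$n - 1L, "} (n = ", x$n, ")\n", sep = "")
  if (2^x$n <= 32) {
    cat(paste0("(", 0:(2^x$n - 1L), ",", x$image, ")", collapse = " "), "\n")
  }
  invisible(x)
}

#' Build the integer transition map of a network
#'
#' Tabulates one full synchronous step for every state: `image[w]` is the
#' integer label of `F(decode(w))`, with `x1` as the most significant bit.
#' All node rules are evaluated vectorized over the whole state space.
#'
#' @param net a `boolean_network`.
#' @param cap state-space cap; networks with more than `cap` nodes are
#'   refused (the table has `2^n` entries).
#' @return an `integer_map` with fields `n` and `image` (0-based states).
#' @examples
#' net <- parse_network("x1, x2\nx2, x1")
#' build_integer_map(net)$image  # c(0, 2, 1, 3): the two middle states swap
#' @export
build_integer_map <- function(net, cap = default_state_cap()) {
  check_cap(net$n, cap)
  n <- net$n
  w <- 0:(2^n - 1L)
  getvar <- state_var_accessor(w, n)
  img <- 0
  for (i in seq_len(n)) {
    img <- img + eval_expr(net$rules[[i]], getvar) * 2^(n - i)
  }
  new_integer_map(n, as.integer(rep_len(img, 2^n)))
}

#' Convert an integer map to its transition matrix
#'
#' @param m an `integer_map`.
#' @return a `transition_matrix`: a `2^n x 2^n` 0/1 matrix with entry
#'   `(i, j) = 1` iff `m` sends state `j` to state `i` (columns index
#'   sources); every column of a functional matrix holds exactly one 1.
#' @export
map_to_matrix <- function(m) {
  N <- 2^m$n
  M <- matrix(0L, N, N)
  M[cbind(m$image + 1L, seq_len(N))] <- 1L
  structure(M, class = c("transition_matrix", "matrix"), n = m$n)
}

#' Recover the integer map from a functional transition matrix
#' @param M a functional `transition_matrix` (one 1 per column).
#' @return an `integer_map`.
#' @export
matrix_to_map <- function(M) {
  n <- attr(M, "n")
  if (is.null(n)) n <- as.integer(round(log2(nrow(M))))
  if (!all(colSums(M != 0) == 1L)) {
    stop("matrix is not functional: some column does not have exactly one 1")
  }
  new_integer_map(n, apply(M != 0, 2, which) - 1L)
}

#' Compose two integer maps
#'
#' Returns `g` after `f`: the map `w -> g(f(w))`, the tabulated equivalent of
#' the Boolean matrix product `M_g x M_f`.
#'
#' @param g,f `integer_map`s on the same state space.
#' @return an `integer_map`.
#' @export
compose_maps <- function(g, f) {
  if (g$n != f$n) stop("cannot compose maps with different node counts")
  new_integer_map(g$n, g$image[f$image + 1L])
}

# t-fold self-composition by exponentiation-by-squaring; t = 0 gives the
# identity map.
map_power <- function(m, t) {
  stopifnot(t >= 0)
  acc <- new_integer_map(m$n, 0:(2^m$n - 1L))
  base <- m
  t <- as.double(t)
  while (t > 0) {
    if (t %% 2 == 1) acc <- compose_maps(base, acc)
    base <- compose_maps(base, base)
    t <- t %/% 2
  }
  acc
}

# Boolean-semiring product of two 0/1 matrices (OR of ANDs).
bool_matmult <- function(A, B) {
  M <- (A %*% B) > 0
  storage.mode(M) <- "integer"
  structure(M, class = c("transition_matrix", "matrix"), n = attr(A, "n"))
}

#' Boolean-semiring matrix power
#'
#' `M^0` is the identity. Functional matrices are raised via their integer
#' map (composition by squaring); general 0/1 matrices fall back to repeated
#' Boolean products.
#'
#' @param M a `transition_matrix`.
#' @param t non-negative integer exponent.
#' @return a `transition_matrix`.
#' @export
matrix_power <- function(M, t) {
  if (t < 0) stop("exponent must be non-negative")
  n <- attr(M, "n")
  if (is.null(n)) n <- as.integer(round(log2(nrow(M))))
  if (all(colSums(M != 0) == 1L)) {
    return(map_to_matrix(map_power(matrix_to_map(M), t)))
  }
  acc <- structure(diag(nrow(M)), class = c("transition_matrix", "matrix"), n = n)
  storage.mode(acc) <- "integer"
  base <- M
  while (t > 0) {
    if (t %% 2 == 1) acc <- bool_matmult(base, acc)
    base <- bool_matmult(base, base)
    t <- t %/% 2
  }
  acc
}

#' Synchronous trajectory of a state
#' @param m an `integer_map`.
#' @param u0 initial state (0-based integer).
#' @param t_max number of steps.
#' @return integer vector `c(u0, m(u0), ..., m^t_max(u0))` of length
#'   `t_max + 1`.
#' @export
trajectory <- function(m, u0, t_max) {
  if (u0 < 0 || u0 >= 2^m$n) stop("initial state ", u0, " out of range")
  out <- integer(t_max + 1L)
  out[1L] <- u0
  for (t in seq_len(t_max)) out[t + 1L] <- m$image[out[t] + 1L]
  out
}

#' Flatten a transition matrix to the bracketed row-major digit string
#' @param M a `transition_matrix`.
#' @return character scalar such as `"[0000100001100001]"`.
#' @export
format_matrix_string <- function(M) {
  paste0("[", paste(t(unclass(M)), collapse = ""), "]")
}

#' Write a transition matrix as CSV (0/1 entries, row-major)
#' @param M a `transition_matrix`.
#' @param path output file.
#' @export
write_matrix_csv <- function(M, path) {
  utils::write.table(unclass(M), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
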