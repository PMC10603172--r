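#' Construct a context matrix
#'
#' The context matrix \eqn{C} encodes the task constraints acting on a dyad.
#' Its four entries are ternary: 1 (active constraint), 0 (inactive) or -1
#' (inhibitory). The matrix is laid out as
#' \deqn{C = \begin{pmatrix} s_1 & o_1 \\ o_2 & s_2 \end{pmatrix}}
#' acting on the column vector \eqn{(b_1, b_2)}: row 1 produces Person 1's
#' next behavior, row 2 Person 2's. The diagonal entries are self-influence
#' (behavioral autocorrelation), the off-diagonal entries cross-agent
#' influence: \code{o1} is how much Person 2 influences Person 1, \code{o2}
#' how much Person 1 influences Person 2.
#'
#' @param s1 Self-influence of Person 1 (Person 1 on Person 1).
#' @param o1 Influence of Person 2 on Person 1.
#' @param o2 Influence of Person 1 on Person 2.
#' @param s2 Self-influence of Person 2 (Person 2 on Person 2).
#' @param relaxed If \code{TRUE}, entries may be arbitrary finite reals
#'   (for model extensions); by default entries must be in \{-1, 0, 1\}.
#' @return An object of class \code{"context_matrix"}.
#' @examples
#' context_matrix(1, 0, 1, -1)  # lecture with an inhibited listener
#' @export
context_matrix <- function(s1, o1, o2, s2, relaxed = FALSE) {
  vals <- c(s1 = s1, o1 = o1, o2 = o2, s2 = s2)
  if (length(vals) != 4L || !is.numeric(vals) || anyNA(vals) || any(!is.finite(vals)))
    stop("context entries must be four finite numbers", call. = FALSE)
  if (!relaxed && !all(vals %in% c(-1, 0, 1)))
    stop("context entries must be ternary (-1, 0 or 1); use relaxed = TRUE for real-valued entries",
         call. = FALSE)
  structure(as.list(vals), relaxed = relaxed, class = "context_matrix")
}

#' Coerce to a context matrix
#'
#' Accepts a \code{context_matrix}, a numeric vector of length 4 in
#' \code{(s1, o1, o2, s2)} order, or a list / one-row data frame with
#' components \code{s1, o1, o2, s2}.
#'
#' @param x Object to coerce.
#' @param relaxed Allow non-ternary entries.
#' @return A \code{context_matrix}.
#' @export
as_context_matrix <- function(x, relaxed = FALSE) {
  if (inherits(x, "context_matrix")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single row", call. = FALSE)
    x <- as.list(x)
  }
  if (is.list(x)) {
    if (!all(c("s1", "o1", "o2", "s2") %in% names(x)))
      stop("need components s1, o1, o2, s2", call. = FALSE)
    return(context_matrix(x$s1, x$o1, x$o2, x$s2, relaxed = relaxed))
  }
  if (is.numeric(x) && length(x) == 4L)
    return(context_matrix(x[1], x[2], x[3], x[4], relaxed = relaxed))
  stop("cannot interpret input as a context matrix", call. = FALSE)
}

#' @export
as.matrix.context_matrix <- function(x, ...) {
  matrix(c(x$s1, x$o1, x$o2, x$s2), nrow = 2, byrow = TRUE,
         dimnames = list(c("b1", "b2"), c("b1", "b2")))
}

#' @export
print.context_matrix <- function(x, ...) {
  cat(sprintf("context matrix C = (%g, %g; %g, %g)\n", x$s1, x$o1, x$o2, x$s2))
  invisible(x)
}

#' Enumerate all ternary context matrices
#'
#' Returns the 81 possible ternary context matrices (entries in \{-1,0,1\}),
#' one per row, in lexicographic order of \code{(s1, o1, o2, s2)} over
#' \code{(-1, 0, 1)}. The fixed ordering makes sweep tables diffable across
#' runs.
#'
#' @return A data frame with columns \code{s1, o1, o2, s2} and 81 rows.
#' @examples
#' head(enumerate_contexts())
#' @export
enumerate_contexts <- function() {
  g <- expand.grid(s2 = -1:1, o2 = -1:1, o1 = -1:1, s1 = -1:1,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("s1", "o1", "o2", "s2")]
  rownames(g) <- NULL
  g
}

#' Does a context contain an inhibitory constraint?
#'
#' @param x A \code{context_matrix} (or anything \code{\link{as_context_matrix}}
#'   accepts).
#' @return \code{TRUE} iff any of the four entries equals -1.
#' @export
has_negative_param <- function(x) {
  x <- as_context_matrix(x, relaxed = TRUE)
  any(c(x$s1, x$o1, x$o2, x$s2) == -1)
}

.dummy_names <- c("s_1p", "s_1n", "o_1p", "o_1n", "o_2p", "o_2n", "s_2p", "s_2n")

#' Dummy-code a ternary context matrix
#'
#' Each of the four ternary parameters is expanded into a positive and a
#' negative indicator with value 0 as the reference level: value 1 sets the
#' "p" indicator, value -1 the "n" indicator, value 0 neither.
#'
#' @param x A ternary \code{context_matrix}.
#' @return A named integer vector of the 8 indicators
#'   \code{s_1p, s_1n, o_1p, o_1n, o_2p, o_2n, s_2p, s_2n}.
#' @seealso [decode_dummy()] for the inverse.
#' @export
dummy_code <- function(x) {
  x <- as_context_matrix(x)
  v <- c(x$s1, x$o1, x$o2, x$s2)
  out <- as.integer(rbind(v == 1, v == -1))
  names(out) <- .dummy_names
  out
}

#' Recover a context matrix from its dummy coding
#'
#' @param d A named vector or list of the 8 indicators produced by
#'   [dummy_code()].
#' @return A \code{context_matrix}.
#' @export
decode_dummy <- function(d) {
  d <- unlist(d)[.dummy_names]
  if (anyNA(d)) stop("need all 8 dummy indicators", call. = FALSE)
  val <- function(p, n) {
    if (p == 1 && n == 1) stop("indicators p and n cannot both be set", call. = FALSE)
    if (p == 1) 1L else if (n == 1) -1L else 0L
  }
  context_matrix(val(d["s_1p"], d["s_1n"]), val(d["o_1p"], d["o_1n"]),
                 val(d["o_2p"], d["o_2n"]), val(d["s_2p"], d["s_2n"]))
}
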