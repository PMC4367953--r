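# Maximum-weight balanced assignment (Hungarian / Kuhn-Munkres family).

#' Solve the maximum-weight assignment problem
#'
#' Finds a perfect matching of rows to columns of a square weight matrix
#' maximising the total weight, via an O(n^3) shortest-augmenting-path solver
#' with dual potentials (the minimising core is reused by negating weights).
#' Among equally optimal assignments an arbitrary optimum is returned.
#'
#' @param weights square numeric matrix of finite weights.
#' @return object of class `assignment`: list with `pairs` (two-column matrix
#'   of matched (row, col) indices, one per row) and `total_weight`.
#' @examples
#' solve_max_assignment(rbind(c(2, 1), c(1, 2)))$pairs
#' @export
solve_max_assignment <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weight matrix must be square")
  if (nrow(weights) == 0) stop("empty weight matrix")
  if (!all(is.finite(weights))) stop("weights must be finite")
  cost <- max(weights) - weights
  row_of_col <- .lsap_min_cpp(cost)
  pairs <- cbind(row = row_of_col, col = seq_len(ncol(weights)))
  pairs <- pairs[order(pairs[, "row"]), , drop = FALSE]
  structure(list(pairs = pairs,
                 total_weight = sum(weights[pairs])),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("assignment: %d pairs, total weight %.6g\n",
              nrow(x$pairs), x$total_weight))
  invisible(x)
}

#' Pad a rectangular weight matrix with zero-weight sinks
#'
#' Balances a case-by-control weight matrix for the assignment solver by
#' appending `|nrow - ncol|` all-zero rows or columns ("sinks"). Individuals
#' matched to a sink are discarded after solving.
#'
#' @param weights nonnegative rectangular weight matrix (e.g. IBS scores,
#'   cases in rows and controls in columns).
#' @return list with `weights` (square matrix), `sink_rows`, `sink_cols`
#'   (index vectors of the padded rows/columns, possibly empty).
#' @export
pad_with_sinks <- function(weights) {
  weights <- as.matrix(weights)
  nr <- nrow(weights); nc <- ncol(weights)
  if (nr == 0 || nc == 0) stop("both sides of the bipartite problem must be non-empty")
  if (any(weights < 0)) stop("sink padding assumes nonnegative weights")
  m <- max(nr, nc)
  out <- matrix(0, m, m)
  out[seq_len(nr), seq_len(nc)] <- weights
  list(weights = out,
       sink_rows = if (m > nr) (nr + 1L):m else integer(0),
       sink_cols = if (m > nc) (nc + 1L):m else integer(0))
}
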