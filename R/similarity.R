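# Genetic similarity scores: averaged identity by state (IBS).
#
# For individuals i, j the score is
#   s_ij = 1 - (1/2N) * sum_k |g_ik - g_jk|
# over the N loci successfully genotyped in both, g in {0,1,2}. The matrix
# form runs on the packed bitplanes with a popcount kernel; optional locus
# weights generalise both the sum and 2N to their weighted forms.

#' IBS similarity of two genotype vectors
#'
#' @param g_i,g_j integer genotype vectors (dosages 0/1/2, `NA` missing) of
#'   equal length.
#' @param weights optional nonnegative per-locus weights (e.g. derived from
#'   Hardy-Weinberg deviation or minor allele frequency); default unweighted.
#' @return similarity score in `[0, 1]`.
#' @examples
#' ibs_pair(c(0, 1, 2, 2), c(0, 2, 0, 2))  # 1 - 3/8
#' @export
ibs_pair <- function(g_i, g_j, weights = NULL) {
  stopifnot(length(g_i) == length(g_j))
  shared <- !is.na(g_i) & !is.na(g_j)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(g_i), all(weights >= 0, na.rm = TRUE))
    w <- weights[shared]
  } else {
    w <- rep(1, sum(shared))
  }
  if (sum(shared) == 0L || sum(w) == 0) {
    stop("undefined similarity: no (positively weighted) locus genotyped in both individuals")
  }
  1 - sum(w * abs(g_i[shared] - g_j[shared])) / (2 * sum(w))
}

#' Pairwise IBS similarity matrix
#'
#' @param x a `packed_genotypes` object or integer genotype matrix
#'   (individuals x SNPs).
#' @param locus_subset optional SNP indices (or ids) restricting the score to
#'   a local window.
#' @param weights optional per-locus weights (on the subset scale if
#'   `locus_subset` is given); the weighted path is computed densely.
#' @param on_empty what to do for pairs with no shared genotyped locus:
#'   `"error"` (default) or `"zero"` (score 0 with a warning).
#' @return object of class `similarity_matrix`: list with `scores` (symmetric
#'   numeric matrix, unit diagonal), `n_shared` (loci genotyped in both) and
#'   `ids`.
#' @export
ibs_matrix <- function(x, locus_subset = NULL, weights = NULL,
                       on_empty = c("error", "zero")) {
  on_empty <- match.arg(on_empty)
  pg <- if (inherits(x, "packed_genotypes")) x else pack_genotypes(x)
  if (!is.null(locus_subset)) {
    codes <- unpack_genotypes(pg)
    if (is.character(locus_subset)) locus_subset <- match(locus_subset, pg$snp_ids)
    codes <- codes[, locus_subset, drop = FALSE]
    pg <- pack_genotypes(codes, snp_ids = pg$snp_ids[locus_subset],
                         individual_ids = pg$individual_ids)
  }
  n <- pg$n_individuals
  if (n < 2) stop("need at least 2 individuals")

  if (is.null(weights)) {
    res <- .ibs_packed_cpp(pg$p1, pg$p2, pg$mm, n, pg$bytes_per_ind)
    nsh <- res$n_shared
    sc <- 1 - res$mismatch / (2 * pmax(nsh, 1L))
  } else {
    codes <- unpack_genotypes(pg)
    stopifnot(length(weights) == ncol(codes), all(weights >= 0))
    sc <- matrix(1, n, n)
    nsh <- matrix(0L, n, n)
    for (i in seq_len(n)) {
      gi <- codes[i, ]
      for (j in i:n) {
        shared <- !is.na(gi) & !is.na(codes[j, ])
        nsh[i, j] <- nsh[j, i] <- sum(shared)
        wsum <- sum(weights[shared])
        sc[i, j] <- sc[j, i] <- if (wsum > 0) {
          1 - sum(weights[shared] * abs(gi[shared] - codes[j, shared])) / (2 * wsum)
        } else NA_real_
      }
    }
  }

  empty <- nsh == 0L | is.na(sc)
  if (any(empty)) {
    if (on_empty == "error") {
      stop("pair(s) with no shared genotyped locus; use on_empty = \"zero\" to score them 0")
    }
    warning(sum(empty[upper.tri(empty, diag = TRUE)]),
            " pair(s) with no shared genotyped locus scored 0")
    sc[empty] <- 0
  }
  dimnames(sc) <- list(pg$individual_ids, pg$individual_ids)
  structure(list(scores = sc, n_shared = nsh, ids = pg$individual_ids),
            class = "similarity_matrix")
}

.sim_scores <- function(sim) {
  if (inherits(sim, "similarity_matrix")) sim$scores else as.matrix(sim)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$scores[upper.tri(x$scores)]
  cat(sprintf("similarity_matrix: %d individuals; off-diagonal IBS in [%.4f, %.4f], mean %.4f\n",
              length(x$ids), min(off), max(off), mean(off)))
  invisible(x)
}

#' Write / read a similarity matrix as TSV
#'
#' Square layout with a header row and a leading column of individual ids.
#'
#' @param sim a `similarity_matrix` (or plain matrix) to write.
#' @param path file path.
#' @return `read_similarity_tsv()` returns a `similarity_matrix`.
#' @export
write_similarity_tsv <- function(sim, path) {
  sc <- .sim_scores(sim)
  df <- data.frame(id = rownames(sc), sc, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  sc <- as.matrix(df[, -1, drop = FALSE])
  dimnames(sc) <- list(ids, ids)
  structure(list(scores = sc, n_shared = NULL, ids = ids),
            class = "similarity_matrix")
}
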