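# Benchmark arm: multidimensional-scaling structure covariates and logistic
# regression with likelihood-ratio testing.

#' MDS structure covariates from a similarity matrix
#'
#' Classical (Torgerson) metric scaling of the genetic distance
#' `d_ij = 1 - s_ij`: double-centered Gram eigendecomposition, coordinates =
#' eigenvectors scaled by the square root of their (nonnegative) eigenvalues.
#' Leading coordinates serve as ancestry covariates in regression models.
#'
#' @param sim a `similarity_matrix` (or plain score matrix).
#' @param k number of components (0 < k < n).
#' @return object of class `structure_covariates`: list with `coordinates`
#'   (n x k, column-centered), `eigenvalues` (nonincreasing) and `k`.
#' @export
mds_components <- function(sim, k) {
  sc <- .sim_scores(sim)
  n <- nrow(sc)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of individuals")
  d <- 1 - sc
  # degenerate geometries (fewer positive eigenvalues than k) are padded below
  fit <- suppressWarnings(cmdscale(as.dist(d), k = k, eig = TRUE))
  coords <- fit$points
  if (ncol(coords) < k) {  # degenerate geometry: pad zero coordinates
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  colnames(coords) <- sprintf("C%d", seq_len(k))
  rownames(coords) <- rownames(sc)
  structure(list(coordinates = coords,
                 eigenvalues = fit$eig[seq_len(k)],
                 k = k, ids = rownames(sc)),
            class = "structure_covariates")
}

#' @export
print.structure_covariates <- function(x, ...) {
  cat(sprintf("structure_covariates: %d components over %d individuals; leading eigenvalues %s\n",
              x$k, nrow(x$coordinates),
              paste(signif(x$eigenvalues[seq_len(min(3, x$k))], 3), collapse = ", ")))
  invisible(x)
}

.covar_matrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (inherits(covariates, "structure_covariates")) covariates$coordinates
  else as.matrix(covariates)
}

#' Logistic-regression likelihood-ratio test for one SNP
#'
#' Fits case-control status on intercept + covariates (null) and additionally
#' the additive genotype dosage (full) by IRLS (`glm.fit`, binomial,
#' tolerance 1e-8, up to 50 iterations); the LRT statistic
#' `2 (l_full - l_null)` is referred to the upper chi-squared 1-df tail.
#' Individuals with missing genotype or phenotype are excluded for the SNP.
#' Non-convergence or separation (|beta_genotype| > 20) yields `NA`.
#'
#' @param g genotype dosage vector (0/1/2, `NA` missing).
#' @param phen a [phenotype()] object.
#' @param covariates `structure_covariates`, a numeric matrix, or `NULL`.
#' @return P-value (1 for a constant genotype), or `NA` when flagged.
#' @export
logistic_lrt <- function(g, phen, covariates = NULL) {
  X <- .covar_matrix(covariates)
  y <- phen$status
  keep <- !is.na(g) & !is.na(y)
  if (!is.null(X)) keep <- keep & complete.cases(X)
  g <- g[keep]; y <- y[keep]
  X0 <- cbind(`(Intercept)` = rep(1, length(y)),
              if (!is.null(X)) X[keep, , drop = FALSE])
  if (length(y) == 0 || length(unique(y)) < 2) return(NA_real_)
  ctrl <- list(epsilon = 1e-8, maxit = 50, trace = FALSE)
  null_fit <- suppressWarnings(tryCatch(
    glm.fit(X0, y, family = binomial(), control = ctrl),
    error = function(e) NULL))
  full_fit <- suppressWarnings(tryCatch(
    glm.fit(cbind(X0, genotype = g), y, family = binomial(), control = ctrl),
    error = function(e) NULL))
  if (is.null(null_fit)) return(NA_real_)
  if (is.null(full_fit) || !full_fit$converged || !null_fit$converged) return(NA_real_)
  beta_g <- full_fit$coefficients["genotype"]
  if (is.na(beta_g)) return(1)   # constant / collinear genotype: LRT = 0
  if (abs(beta_g) > 20) return(NA_real_)  # separation
  lrt <- null_fit$deviance - full_fit$deviance
  pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
}

#' Logistic-regression scan with MDS covariates
#'
#' Applies [logistic_lrt()] to every SNP, with `k` MDS components (computed
#' from `sim` if not supplied directly).
#'
#' @param geno `packed_genotypes` or genotype matrix.
#' @param phen phenotype.
#' @param covariates precomputed covariates, or `NULL` to derive them.
#' @param sim similarity matrix (needed when `covariates` is `NULL`).
#' @param k number of MDS components when deriving covariates.
#' @return numeric vector of P-values (one per SNP).
#' @export
lr_mds_scan <- function(geno, phen, covariates = NULL, sim = NULL, k = NULL) {
  if (is.null(covariates)) {
    if (is.null(sim) || is.null(k)) stop("supply covariates, or sim and k")
    covariates <- mds_components(sim, k)
  }
  g <- .geno_matrix(geno)
  vapply(seq_len(ncol(g)), function(s) logistic_lrt(g[, s], phen, covariates),
         numeric(1))
}

#' Write structure covariates as TSV
#'
#' Columns `individual_id`, `C1` ... `Ck`.
#'
#' @param covariates a `structure_covariates` object.
#' @param path file path.
#' @export
write_covariates_tsv <- function(covariates, path) {
  co <- covariates$coordinates
  ids <- covariates$ids
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(co)))
  write.table(data.frame(individual_id = ids, co, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
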