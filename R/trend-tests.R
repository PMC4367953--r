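# Cochran-Armitage trend statistics and their matched extensions.
#
# Per 2x3 genotype table (rows controls/cases, columns reference-homozygote,
# heterozygote, risk-homozygote; co-dominant scores t = (0,1,2)):
#
#   X_T2 = (N / (n_co n_ca)) * U^2 / D            (squared CAT, ~ chi^2_1)
#   X_U  = sqrt((N-1) / (n_co n_ca)) * U / sqrt(D)  (linear CAT, Var = 1)
#   U    = n_co (n22 + 2 n23) - n_ca (n12 + 2 n13)
#   D    = N (n*2 + 4 n*3) - (n*2 + 2 n*3)^2
#
# The finite-population factor sqrt((N-1)/N) makes Var(X_U) = 1 exactly under
# the within-table permutation (multivariate hypergeometric) null, so summing
# X_U over M matched units gives Y_U ~ N(0, M) (MCAT1), while the
# sign-weighted sum of X_T2 gives the permutation-calibrated MCAT2 statistic
#   Y_T2 = | sum_i sgn(f_ca - f_co) X_T2^(i) | .

#' Genotype contingency table of one SNP within one unit
#'
#' Tallies unit members with a non-missing genotype at the SNP into the 2x3
#' control/case by dosage table.
#'
#' @param geno `packed_genotypes` or integer genotype matrix.
#' @param phen [phenotype()] object.
#' @param unit a unit (list with `cases`, `controls` index vectors) or a
#'   plain index vector (roles then taken from `phen`).
#' @param snp SNP index or id.
#' @return object of class `contingency_table`: 2x3 integer matrix (rows
#'   `control`, `case`) with margin attributes.
#' @export
contingency_table <- function(geno, phen, unit, snp) {
  g <- .geno_matrix(geno)
  if (is.character(snp)) snp <- match(snp, colnames(g))
  if (is.list(unit)) {
    A <- unit$cases; O <- unit$controls
  } else {
    A <- intersect(unit, cases(phen)); O <- intersect(unit, controls(phen))
  }
  tab <- matrix(0L, 2, 3, dimnames = list(c("control", "case"), c("g0", "g1", "g2")))
  for (g0 in 0:2) {
    tab["control", g0 + 1L] <- sum(g[O, snp] == g0, na.rm = TRUE)
    tab["case", g0 + 1L] <- sum(g[A, snp] == g0, na.rm = TRUE)
  }
  as_contingency_table(tab)
}

#' @rdname contingency_table
#' @param x 2x3 matrix of counts (rows controls, cases) or a vector
#'   `c(n11, n12, n13, n21, n22, n23)`.
#' @export
as_contingency_table <- function(x) {
  if (!is.matrix(x)) x <- matrix(as.integer(x), 2, 3, byrow = TRUE)
  stopifnot(all(dim(x) == c(2, 3)), all(x >= 0))
  storage.mode(x) <- "integer"
  dimnames(x) <- list(c("control", "case"), c("g0", "g1", "g2"))
  structure(x, class = c("contingency_table", "matrix"),
            n_co = sum(x[1, ]), n_ca = sum(x[2, ]), N = sum(x))
}

.ct_parts <- function(t) {
  t <- unclass(t)
  n_co <- sum(t[1, ]); n_ca <- sum(t[2, ]); N <- n_co + n_ca
  cstar <- colSums(t)
  U <- n_co * (t[2, 2] + 2 * t[2, 3]) - n_ca * (t[1, 2] + 2 * t[1, 3])
  D <- N * (cstar[2] + 4 * cstar[3]) - (cstar[2] + 2 * cstar[3])^2
  list(n_co = n_co, n_ca = n_ca, N = N, U = U, D = unname(D))
}

.ct_usable <- function(p) p$n_co > 0 && p$n_ca > 0 && p$D > 0

#' Cochran-Armitage trend statistic (squared form)
#'
#' @param t a [contingency_table()] (or 2x3 count matrix).
#' @return nonnegative statistic, asymptotically chi-squared with 1 df under
#'   the null; `NA` when the table is monomorphic or one-sided.
#' @examples
#' cat_statistic(as_contingency_table(c(5, 3, 2, 2, 4, 4)))  # ~1.9305
#' @export
cat_statistic <- function(t) {
  p <- .ct_parts(as_contingency_table(t))
  if (!.ct_usable(p)) return(NA_real_)
  (p$N / (p$n_co * p$n_ca)) * p$U^2 / p$D
}

#' Cochran-Armitage trend statistic (linear, finite-population corrected)
#'
#' Signed statistic with exact unit variance under the within-table
#' permutation null; `cat_linear(t)^2 == (N-1)/N * cat_statistic(t)`.
#'
#' @inheritParams cat_statistic
#' @return signed statistic (positive when cases carry more risk alleles);
#'   `NA` when unusable.
#' @export
cat_linear <- function(t) {
  p <- .ct_parts(as_contingency_table(t))
  if (!.ct_usable(p)) return(NA_real_)
  sqrt((p$N - 1) / (p$n_co * p$n_ca)) * p$U / sqrt(p$D)
}

#' Reference-allele frequencies of a unit table
#'
#' `f_co = (2 n11 + n12) / (2 n_co)` and `f_ca = (2 n21 + n22) / (2 n_ca)`,
#' i.e. the frequency of the allele in the first (reference-homozygote)
#' column; only the sign of `f_ca - f_co` enters the MCAT2 statistic.
#'
#' @inheritParams cat_statistic
#' @return named vector `c(f_co = , f_ca = )` in `[0, 1]`.
#' @export
unit_allele_freqs <- function(t) {
  t <- as_contingency_table(t)
  n_co <- sum(t[1, ]); n_ca <- sum(t[2, ])
  if (n_co == 0 || n_ca == 0) stop("unit has an empty case or control side at this SNP")
  c(f_co = (2 * t[1, 1] + t[1, 2]) / (2 * n_co),
    f_ca = (2 * t[2, 1] + t[2, 2]) / (2 * n_ca))
}

.unit_contribs <- function(tables) {
  lapply(tables, function(t) {
    t <- as_contingency_table(t)
    p <- .ct_parts(t)
    if (!.ct_usable(p)) return(NULL)
    f <- unit_allele_freqs(t)
    list(x_t2 = (p$N / (p$n_co * p$n_ca)) * p$U^2 / p$D,
         x_u = sqrt((p$N - 1) / (p$n_co * p$n_ca)) * p$U / sqrt(p$D),
         sgn = sign(f["f_ca"] - f["f_co"]))
  })
}

#' Squared matching trend statistic MCAT2
#'
#' Sign-weighted sum of per-unit squared CAT statistics,
#' `Y_T2 = |sum_i sgn(f_ca - f_co) X_T2^(i)|`. Units with a monomorphic or
#' one-sided table are skipped (they do not count towards `M`); a unit with
#' equal case and control allele frequencies contributes 0 via `sgn(0) = 0`
#' but still counts. Not chi-squared distributed: use within-unit permutation
#' for P-values.
#'
#' @param tables list of per-unit contingency tables for one SNP.
#' @return list with `statistic` (`NA` if no unit is usable, i.e. the SNP is
#'   untestable) and `M` (number of usable units).
#' @export
mcat2 <- function(tables) {
  contribs <- Filter(Negate(is.null), .unit_contribs(tables))
  if (length(contribs) == 0) return(list(statistic = NA_real_, M = 0L))
  list(statistic = abs(sum(vapply(contribs, function(c) unname(c$sgn * c$x_t2), numeric(1)))),
       M = length(contribs))
}

#' Linear matching trend statistic MCAT1
#'
#' `Y_U = sum_i X_U^(i)` over usable units; asymptotically `N(0, M)` under
#' the null, so `Y_U / sqrt(M)` is the standardised statistic.
#'
#' @inheritParams mcat2
#' @return list with `statistic` (`Y_U`), `M` and `z` (`Y_U / sqrt(M)`).
#' @export
mcat1 <- function(tables) {
  contribs <- Filter(Negate(is.null), .unit_contribs(tables))
  if (length(contribs) == 0) return(list(statistic = NA_real_, M = 0L, z = NA_real_))
  y <- sum(vapply(contribs, function(c) c$x_u, numeric(1)))
  list(statistic = y, M = length(contribs), z = y / sqrt(length(contribs)))
}

#' Genome scan of a matched trend test with within-unit permutation
#'
#' Computes the chosen statistic for every SNP and, for `B > 0`, its
#' within-unit permutation distribution: the case/control labels are permuted
#' inside every unit once per cycle (so all SNPs share each cycle's
#' relabeling, as the minP adjustment requires) and exceedances of the
#' observed magnitude are counted.
#'
#' @param geno `packed_genotypes` or genotype matrix.
#' @param phen phenotype.
#' @param units a `unit_structure`; for a naive (unstructured) CAT scan pass
#'   a single unit holding the whole sample.
#' @param method `"cat"` (pooled trend statistic over all unit members),
#'   `"mcat1"` or `"mcat2"`.
#' @param B number of permutation cycles (0 = observed statistics only).
#' @param return_null keep the full B x SNP matrix of permuted statistic
#'   magnitudes (needed for [minp_adjust()]).
#' @param p_mode permutation P-value estimator: `"add_one"` ((b+1)/(B+1),
#'   never zero) or `"fraction"` (b/B, the plain exceedance fraction).
#' @return data-frame-like list of class `mcat_scan` with per-SNP `snp_id`,
#'   `statistic`, `M`, and for `B > 0` `p_perm`; plus `null` when requested.
#' @export
mcat_scan <- function(geno, phen, units, method = c("cat", "mcat1", "mcat2"),
                      B = 0, return_null = FALSE,
                      p_mode = c("add_one", "fraction")) {
  method <- match.arg(method)
  p_mode <- match.arg(p_mode)
  g <- .geno_matrix(geno)
  stopifnot(inherits(units, "unit_structure"), nrow(g) == units$n_ind)
  uidx <- unit_index(units)
  res <- .mcat_scan_cpp(g, ifelse(is.na(uidx), -1L, uidx - 1L),
                        ifelse(is.na(phen$status), 0L, phen$status),
                        length(units$units),
                        match(method, c("cat", "mcat1", "mcat2")) - 1L,
                        as.integer(B), isTRUE(return_null))
  out <- list(snp_id = colnames(g), statistic = res$stat, M = res$M,
              method = method, B = B)
  if (B > 0) {
    out$exceed <- res$exceed
    p <- if (p_mode == "add_one") (res$exceed + 1) / (B + 1) else res$exceed / B
    p[is.na(res$stat)] <- NA_real_
    out$p_perm <- p
    if (return_null) out$null <- res$null
  }
  class(out) <- "mcat_scan"
  out
}

#' @export
print.mcat_scan <- function(x, ...) {
  cat(sprintf("mcat_scan (%s): %d SNPs, %s\n", x$method, length(x$statistic),
              if (x$B > 0) sprintf("%d permutation cycles", x$B) else "no permutations"))
  invisible(x)
}

#' Whole-sample unit
#'
#' Convenience structure holding the full phenotyped sample in one unit, for
#' naive (unstructured) scans and for sample-wide resampling.
#'
#' @param phen a [phenotype()] object.
#' @return a `unit_structure` with a single unit.
#' @export
whole_sample_unit <- function(phen) {
  unit_structure(list(list(cases = cases(phen), controls = controls(phen))),
                 kind = "cluster", removed = integer(0),
                 n_ind = length(phen$status), ids = phen$ids)
}

#' Per-SNP results table
#'
#' Assembles the exchange-format results table (snp_id, method, statistic,
#' M, p_value and optionally the genomic-control corrected p).
#'
#' @param scan an `mcat_scan`.
#' @param p p-values to report (default the scan's permutation p).
#' @param lambda optional inflation factor; adds a `p_gc` column via
#'   [gc_correct()].
#' @return data frame.
#' @export
scan_results <- function(scan, p = scan$p_perm, lambda = NULL) {
  df <- data.frame(snp_id = if (is.null(scan$snp_id)) sprintf("snp%d", seq_along(scan$statistic)) else scan$snp_id,
                   method = scan$method,
                   statistic = scan$statistic,
                   M = scan$M,
                   p_value = if (is.null(p)) NA_real_ else p,
                   stringsAsFactors = FALSE)
  if (!is.null(lambda)) df$p_gc <- gc_correct(df$p_value, lambda)
  df
}
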