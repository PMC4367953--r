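# Inference: within-unit permutation, minP multiplicity adjustment,
# asymptotic reference distributions, and genomic control.

# median of a chi^2_1 variate; 0.456 to printed precision
.CHI2_MEDIAN <- qchisq(0.5, df = 1)

#' Permute case-control labels within units
#'
#' Shuffles the affection states independently inside every unit, preserving
#' each unit's case/control counts; individuals outside all units keep their
#' labels.
#'
#' @param phen a [phenotype()] object.
#' @param structure a `unit_structure`.
#' @return a permuted `phenotype`.
#' @export
permute_within_units <- function(phen, structure) {
  status <- phen$status
  for (u in structure$units) {
    members <- c(u$cases, u$controls)
    status[members] <- status[sample(members)]
  }
  phenotype(status, ids = phen$ids)
}

# all distinct case-position choices per unit, combined across units
.enumerate_relabelings <- function(phen, structure, limit = 2e5) {
  per_unit <- lapply(structure$units, function(u) {
    members <- c(u$cases, u$controls)
    utils::combn(members, length(u$cases), simplify = FALSE)
  })
  total <- prod(vapply(per_unit, length, numeric(1)))
  if (total > limit) stop("exhaustive enumeration too large (", total, " relabelings)")
  grid <- expand.grid(lapply(per_unit, seq_along))
  lapply(seq_len(nrow(grid)), function(r) {
    status <- phen$status
    for (k in seq_along(per_unit)) {
      u <- structure$units[[k]]
      members <- c(u$cases, u$controls)
      status[members] <- 0L
      status[per_unit[[k]][[grid[r, k]]]] <- 1L
    }
    phenotype(status, ids = phen$ids)
  })
}

#' Permutation P-value of a statistic under within-unit resampling
#'
#' The default estimator is `(1 + #\{stat_b >= stat_obs\}) / (B + 1)`
#' (add-one, never zero); `mode = "fraction"` gives the plain fraction of
#' resamples at least as extreme. Extremeness is one-sided on the statistic
#' as supplied, so pass a magnitude (e.g. `|Y_U|`) for signed statistics.
#' With `exhaustive = TRUE` all distinct within-unit relabelings are
#' enumerated instead of sampled and `B` is ignored.
#'
#' @param stat_fn function `phenotype -> scalar statistic`.
#' @param phen observed phenotype.
#' @param structure a `unit_structure`.
#' @param B number of resampling cycles.
#' @param mode `"add_one"` or `"fraction"`.
#' @param exhaustive enumerate all relabelings (small problems only).
#' @return the P-value, with attribute `B` (cycles or enumeration size);
#'   `NA` if the observed statistic is not finite (untestable SNP).
#' @export
permutation_pvalue <- function(stat_fn, phen, structure, B = 999,
                               mode = c("add_one", "fraction"),
                               exhaustive = FALSE) {
  mode <- match.arg(mode)
  obs <- stat_fn(phen)
  if (!is.finite(obs)) return(NA_real_)
  if (exhaustive) {
    stats <- vapply(.enumerate_relabelings(phen, structure), stat_fn, numeric(1))
    b <- sum(stats >= obs, na.rm = TRUE)
    n <- sum(!is.na(stats))
  } else {
    stopifnot(B >= 1)
    stats <- vapply(seq_len(B), function(i) stat_fn(permute_within_units(phen, structure)),
                    numeric(1))
    b <- sum(stats >= obs, na.rm = TRUE)
    n <- B
  }
  p <- if (mode == "add_one" && !exhaustive) (b + 1) / (n + 1) else b / n
  attr(p, "B") <- n
  p
}

#' minP multiplicity adjustment from a shared permutation null
#'
#' Westfall-Young style single-step adjustment. In the default `"add_one"`
#' mode the observed statistics are pooled with the permuted ones as a
#' (B+1)-th resample; every row of the pool is converted rank-wise to a
#' P-value against its own SNP's pooled null, and the adjusted P-value of a
#' SNP is the fraction of rows whose minimum P-value across SNPs is at most
#' the SNP's raw P-value. Exchangeability of the pooled rows under the null
#' gives familywise error control. `"fraction"` mode reports the plain
#' exceedance-fraction estimators instead (the resampling definition without
#' self-inclusion); its adjusted values are slightly anticonservative at
#' small B. Requires the same permutations for all SNPs (as produced by
#' [mcat_scan()] with `return_null = TRUE`); avoids nested resampling.
#'
#' @param null B x S matrix of permuted statistic magnitudes.
#' @param observed length-S vector of observed magnitudes.
#' @param mode `"add_one"` (pooled, recommended) or `"fraction"`.
#' @return list with `raw` and `adjusted` P-vectors (`adjusted >= raw`).
#' @export
minp_adjust <- function(null, observed, mode = c("add_one", "fraction")) {
  mode <- match.arg(mode)
  null <- as.matrix(null)
  B <- nrow(null); S <- ncol(null)
  stopifnot(length(observed) == S)
  if (B < 100) warning("few permutations (B = ", B, "): minP resolution is coarse")
  usable <- !is.na(observed) & colSums(is.na(null)) == 0
  raw <- adj <- rep(NA_real_, S)
  if (!any(usable)) return(list(raw = raw, adjusted = adj))
  nu <- null[, usable, drop = FALSE]
  ob <- observed[usable]
  if (mode == "add_one") {
    pool <- rbind(nu, ob)                    # observed as the (B+1)-th row
    pmat <- apply(pool, 2, function(q) {
      (B + 1 - rank(q, ties.method = "min") + 1) / (B + 1)
    })
    minp <- apply(pmat, 1, min)
    raw_u <- pmat[B + 1, ]
    adj_u <- vapply(raw_u, function(p) mean(minp <= p), numeric(1))
  } else {
    cnt <- colSums(sweep(nu, 2, ob, ">=") * 1)
    raw_u <- cnt / B
    pmat <- apply(nu, 2, function(q) (B - rank(q, ties.method = "min") + 1) / B)
    minp <- apply(pmat, 1, min)
    adj_u <- vapply(raw_u, function(p) mean(minp <= p), numeric(1))
  }
  raw[usable] <- raw_u
  adj[usable] <- pmax(adj_u, raw_u)
  list(raw = raw, adjusted = adj)
}

#' Asymptotic P-values for the trend statistics
#'
#' CAT and MCAT2-free statistics: upper-tail chi-squared with 1 df. MCAT1:
#' two-sided normal with variance `M` (the number of contributing units).
#'
#' @param statistic statistic vector (`X_T2`, or `Y_U` for the normal law).
#' @param law `"chi2_1"` or `"normal"`.
#' @param M unit counts (required for `law = "normal"`); entries with
#'   `M = 0` give `NA`.
#' @return P-value vector.
#' @examples
#' asymptotic_pvalues(3.841, "chi2_1")              # ~0.05
#' asymptotic_pvalues(1.96 * sqrt(8), "normal", 8)  # ~0.05
#' @export
asymptotic_pvalues <- function(statistic, law = c("chi2_1", "normal"), M = NULL) {
  law <- match.arg(law)
  if (law == "chi2_1") {
    pchisq(statistic, df = 1, lower.tail = FALSE)
  } else {
    if (is.null(M)) stop("the normal law needs the unit count M")
    p <- 2 * pnorm(-abs(statistic) / sqrt(M))
    p[!is.na(M) & M == 0] <- NA_real_
    p
  }
}

#' Genomic-control inflation factor
#'
#' `lambda = median(statistic) / median(chi^2_1)` with the exact constant
#' `qchisq(0.5, 1) = 0.4549364` (0.456 to display precision). P-value input
#' is first converted to chi-squared statistics through the upper-tail
#' quantile function; for MCAT1 pass the squared standardised statistic
#' `Y_U^2 / M`.
#'
#' @param x statistics (default) or P-values.
#' @param input `"statistic"` or `"pvalue"`.
#' @return the inflation factor lambda.
#' @export
inflation_factor <- function(x, input = c("statistic", "pvalue")) {
  input <- match.arg(input)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite statistics to estimate lambda from")
  if (input == "pvalue") {
    if (any(x < 0 | x > 1)) stop("p-values must lie in [0, 1]")
    x <- qchisq(x, df = 1, lower.tail = FALSE)
  }
  median(x) / .CHI2_MEDIAN
}

#' Genomic-control correction of P-values
#'
#' Converts P-values to chi-squared statistics by the inverse upper-tail
#' distribution, rescales them by `1 / lambda`, and converts back.
#'
#' @param pvalues vector in `(0, 1]` (`NA` passed through).
#' @param lambda inflation factor (> 0).
#' @return corrected P-values (identity for `lambda = 1`; for `lambda > 1`
#'   corrected values are never smaller than the input).
#' @export
gc_correct <- function(pvalues, lambda) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] <= 0 | pvalues[ok] > 1)) stop("p-values must lie in (0, 1]")
  out <- pvalues
  out[ok] <- pchisq(qchisq(pvalues[ok], df = 1, lower.tail = FALSE) / lambda,
                    df = 1, lower.tail = FALSE)
  out
}
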