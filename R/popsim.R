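# Synthetic stratified-population generator.
#
# Stratum allele frequencies follow the Balding-Nichols model around an
# ancestral frequency p: Beta(p(1-F)/F, (1-p)(1-F)/F), so E = p and
# Var = F p (1-p). Haplotypes are drawn from a first-order Markov chain over
# loci whose transitions realise a target adjacent-locus allele correlation
# (pairwise LD), and genotypes are haplotype sums (HWE within stratum).
# SNPs monomorphic in any stratum are removed before analysis.

#' Simulation design for a stratified case-control study
#'
#' @param n_controls,n_cases integer vectors of per-stratum control and case
#'   counts (equal length = number of strata).
#' @param S number of SNPs simulated (before monomorphic filtering).
#' @param fst Balding-Nichols divergence F in `[0, 1)` (scalar or
#'   per-stratum).
#' @param ld adjacent-locus haplotype allele correlation in `[0, 1)`.
#' @param rr relative disease risk per risk allele under the multiplicative
#'   model (power mode).
#' @param prevalence stratum disease prevalence used to anchor the baseline
#'   penetrance in power mode.
#' @param maf_range range of the ancestral allele frequency draw.
#' @param strata_ids optional stratum names.
#' @return object of class `sim_design`.
#' @export
sim_design <- function(n_controls, n_cases, S = 2000, fst = 0.05, ld = 0.2,
                       rr = 1.5, prevalence = 0.1, maf_range = c(0.05, 0.5),
                       strata_ids = NULL) {
  stopifnot(length(n_controls) == length(n_cases),
            all(n_controls >= 0), all(n_cases >= 0),
            all(fst >= 0), all(fst < 1), ld >= 0, ld < 1, rr > 0,
            prevalence > 0, prevalence < 1, S >= 1)
  K <- length(n_controls)
  fst <- rep_len(fst, K)
  if (is.null(strata_ids)) strata_ids <- sprintf("S%d", seq_len(K))
  structure(list(K = K, n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases), S = as.integer(S),
                 fst = fst, ld = ld, rr = rr, prevalence = prevalence,
                 maf_range = maf_range, strata_ids = strata_ids),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("sim_design: %d strata, %d controls + %d cases, %d SNPs, F = %s, LD = %.2f, RR = %.2f\n",
              x$K, sum(x$n_controls), sum(x$n_cases), x$S,
              paste(unique(signif(x$fst, 3)), collapse = "/"), x$ld, x$rr))
  invisible(x)
}

#' The scaled-down five-stratum study design
#'
#' Default design used throughout the package's calibration experiments:
#' 5 strata, 400 individuals (200 controls + 200 cases) whose per-stratum
#' case/control imbalance mirrors the 14-stratum benchmark's over- and
#' under-sampling profile, 2,000 SNPs, F = 0.05, mild adjacent-locus LD.
#'
#' @param ... overrides passed to [sim_design()].
#' @return a `sim_design`.
#' @export
default_design <- function(...) {
  args <- list(n_controls = c(70L, 20L, 55L, 25L, 30L),
               n_cases = c(35L, 40L, 25L, 50L, 50L))
  do.call(sim_design, utils::modifyList(args, list(...)))
}

#' The 14-stratum benchmark design
#'
#' Per-stratum distribution of 1,845 individuals (967 controls, 878 cases)
#' across 14 ancestries from four continents, with strongly asymmetric
#' case/control sampling.
#'
#' @param ... overrides passed to [sim_design()].
#' @return a `sim_design`.
#' @export
table2_design <- function(...) {
  args <- list(
    n_controls = c(85L, 96L, 66L, 30L, 88L, 36L, 130L, 66L, 45L, 31L, 92L, 120L, 9L, 73L),
    n_cases = c(42L, 48L, 66L, 60L, 44L, 73L, 65L, 133L, 88L, 61L, 46L, 60L, 18L, 74L),
    strata_ids = c("ASW", "LWK", "YRI", "CLM", "MXL", "PUR", "CHB",
                   "CHS", "JPT", "CEU", "FIN", "GBR", "IBS", "TSI"))
  do.call(sim_design, utils::modifyList(args, list(...)))
}

#' Balding-Nichols per-stratum allele frequencies
#'
#' @param p ancestral allele frequency vector (one entry per SNP), in (0,1).
#' @param fst divergence F in `[0, 1)`, scalar or per-stratum.
#' @param K number of strata.
#' @return K x S matrix of stratum frequencies (`fst = 0` rows equal `p`).
#' @export
balding_nichols_freqs <- function(p, fst, K) {
  stopifnot(all(p > 0), all(p < 1), all(fst >= 0), all(fst < 1), K >= 1)
  fst <- rep_len(fst, K)
  S <- length(p)
  out <- matrix(NA_real_, K, S)
  for (k in seq_len(K)) {
    if (fst[k] == 0) {
      out[k, ] <- p
    } else {
      a <- p * (1 - fst[k]) / fst[k]
      b <- (1 - p) * (1 - fst[k]) / fst[k]
      out[k, ] <- rbeta(S, a, b)
    }
  }
  out
}

# haplotype matrix (n_hap x S) from a first-order Markov chain with marginal
# allele frequencies q and adjacent-locus correlation r; infeasible
# transitions are clipped (flagged via attribute)
.sim_haplotypes <- function(q, r, n_hap) {
  S <- length(q)
  H <- matrix(0L, n_hap, S)
  H[, 1] <- rbinom(n_hap, 1, q[1])
  clipped <- FALSE
  if (S > 1) for (k in 2:S) {
    qp <- q[k - 1]; qk <- q[k]
    if (r == 0) {
      H[, k] <- rbinom(n_hap, 1, qk)
      next
    }
    cov <- r * sqrt(qp * (1 - qp) * qk * (1 - qk))
    p1 <- qk + cov / qp         # P(1 | previous = 1)
    p0 <- qk - cov / (1 - qp)   # P(1 | previous = 0)
    if (p1 > 1 || p1 < 0 || p0 > 1 || p0 < 0) clipped <- TRUE
    p1 <- min(max(p1, 0), 1); p0 <- min(max(p0, 0), 1)
    pr <- ifelse(H[, k - 1] == 1L, p1, p0)
    H[, k] <- rbinom(n_hap, 1, pr)
  }
  attr(H, "clipped") <- clipped
  H
}

#' Simulate genotypes for one stratum
#'
#' Two haplotypes per individual from the Markov chain, summed to genotypes;
#' Hardy-Weinberg equilibrium holds within the stratum by construction.
#'
#' @param freqs per-SNP allele frequencies of the stratum.
#' @param ld adjacent-locus haplotype correlation; correlations infeasible
#'   for a frequency pair are clipped, with one warning.
#' @param n number of individuals.
#' @return n x S integer genotype matrix.
#' @export
simulate_stratum <- function(freqs, ld, n) {
  stopifnot(n >= 1)
  h1 <- .sim_haplotypes(freqs, ld, n)
  h2 <- .sim_haplotypes(freqs, ld, n)
  if (isTRUE(attr(h1, "clipped")) || isTRUE(attr(h2, "clipped"))) {
    warning("LD parameter infeasible for some adjacent frequency pairs; clipped")
  }
  g <- h1 + h2
  storage.mode(g) <- "integer"
  g
}

#' Filter SNPs monomorphic in any stratum
#'
#' A SNP is retained only if it is polymorphic (both alleles observed) in
#' every stratum.
#'
#' @param geno genotype matrix (individuals x SNPs).
#' @param strata per-individual stratum labels.
#' @return integer vector of retained SNP indices.
#' @export
filter_monomorphic <- function(geno, strata) {
  g <- .geno_matrix(geno)
  keep <- rep(TRUE, ncol(g))
  for (st in unique(strata)) {
    rows <- which(strata == st)
    sub <- g[rows, , drop = FALSE]
    rng <- apply(sub, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) 0 else max(x) - min(x)
    })
    keep <- keep & rng > 0
  }
  which(keep)
}

.new_study <- function(codes, status, strata, design, causal_index = NULL,
                       causal_freqs = NULL) {
  n <- nrow(codes)
  ids <- sprintf("%s_i%04d", strata, seq_len(n))
  snp_ids <- colnames(codes)
  pg <- pack_genotypes(codes, snp_ids = snp_ids, individual_ids = ids)
  structure(list(genotypes = pg,
                 phenotype = phenotype(status, ids = ids),
                 strata = strata,
                 causal_index = causal_index,
                 causal_freqs = causal_freqs,
                 design = design),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d individuals (%d controls, %d cases), %d SNPs, %d strata%s\n",
              x$genotypes$n_individuals, length(controls(x$phenotype)),
              length(cases(x$phenotype)), x$genotypes$n_snps,
              length(unique(x$strata)),
              if (is.null(x$causal_index)) "" else sprintf(", causal SNP #%d", x$causal_index)))
  invisible(x)
}

# simulate the merged panel for all strata (no phenotype-genotype link)
.sim_panel <- function(design, filter = TRUE) {
  p <- runif(design$S, design$maf_range[1], design$maf_range[2])
  freqs <- balding_nichols_freqs(p, design$fst, design$K)
  n_k <- design$n_controls + design$n_cases
  codes <- NULL
  strata <- character(0)
  for (k in seq_len(design$K)) {
    if (n_k[k] == 0) next
    codes <- rbind(codes, suppressWarnings(simulate_stratum(freqs[k, ], design$ld, n_k[k])))
    strata <- c(strata, rep(design$strata_ids[k], n_k[k]))
  }
  colnames(codes) <- sprintf("snp%05d", seq_len(ncol(codes)))
  if (filter) {
    keep <- filter_monomorphic(codes, strata)
    if (length(keep) == 0) stop("all SNPs monomorphic in some stratum; enlarge the design")
    codes <- codes[, keep, drop = FALSE]
  }
  list(codes = codes, strata = strata, freqs = freqs, ancestral = p)
}

#' Simulate a stratified study under the null hypothesis
#'
#' Within each stratum, case and control labels are assigned independently of
#' genotype (no association anywhere); merging the strata with the design's
#' asymmetric per-stratum counts produces population stratification. Stratum
#' labels are retained for evaluation only.
#'
#' @param design a [sim_design()].
#' @param seed optional RNG seed.
#' @return object of class `sim_study`.
#' @export
sample_h0_study <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- .sim_panel(design)
  status <- integer(0)
  for (k in seq_len(design$K)) {
    status <- c(status, rep(0L, design$n_controls[k]), rep(1L, design$n_cases[k]))
  }
  .new_study(panel$codes, status, panel$strata, design)
}

#' Simulate a stratified study with one causal SNP
#'
#' Affection follows the multiplicative penetrance model at the causal SNP
#' within each stratum: `f_g = f_0 * rr^g`, with the baseline `f_0` anchored
#' so the stratum prevalence equals the design's `prevalence` given the
#' stratum risk-allele frequency `q` (`f_0 = prev / (1 + q (rr - 1))^2`).
#' Case and control genotypes at the causal SNP are drawn from the exact
#' conditional distributions `P(g | case) ~ HWE(q) rr^g` and
#' `P(g | control) ~ HWE(q) (1 - f_0 rr^g)`. The matching panel is simulated
#' independently of the causal SNP, which realises the design rule that
#' matching SNPs keep a wide gap from the analysed SNP (no LD between them).
#'
#' @param design a [sim_design()] (with `rr`; `rr = 1` reduces to the null).
#' @param causal_freqs optional per-stratum risk-allele frequency of the
#'   causal SNP; drawn from the Balding-Nichols model when `NULL`.
#' @param seed optional RNG seed.
#' @return a `sim_study`; the causal SNP is the last genotype column (id
#'   `"causal"`, index in `causal_index`), the preceding columns form the
#'   matching panel.
#' @export
sample_power_study <- function(design, causal_freqs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(causal_freqs)) {
    p0 <- runif(1, design$maf_range[1], design$maf_range[2])
    causal_freqs <- as.vector(balding_nichols_freqs(p0, design$fst, design$K))
  }
  stopifnot(length(causal_freqs) == design$K,
            all(causal_freqs > 0), all(causal_freqs < 1))
  rr <- design$rr
  panel <- .sim_panel(design)
  n_k <- design$n_controls + design$n_cases
  status <- integer(0)
  causal <- integer(0)
  offset <- 0L
  for (k in seq_len(design$K)) {
    if (n_k[k] == 0) next
    q <- causal_freqs[k]
    f0 <- design$prevalence / (1 + q * (rr - 1))^2
    if (f0 * rr^2 > 1) {
      stop("penetrance sampling infeasible: baseline x rr^2 exceeds 1 for stratum ", k)
    }
    hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    pen <- f0 * rr^(0:2)
    p_case <- hwe * pen / sum(hwe * pen)
    p_ctrl <- hwe * (1 - pen) / sum(hwe * (1 - pen))
    g_ctrl <- sample(0:2, design$n_controls[k], replace = TRUE, prob = p_ctrl)
    g_case <- sample(0:2, design$n_cases[k], replace = TRUE, prob = p_case)
    status <- c(status, rep(0L, design$n_controls[k]), rep(1L, design$n_cases[k]))
    causal <- c(causal, g_ctrl, g_case)
    offset <- offset + n_k[k]
  }
  codes <- cbind(panel$codes, causal = causal)
  .new_study(codes, status, panel$strata, design,
             causal_index = ncol(codes), causal_freqs = causal_freqs)
}
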