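test_that("Balding-Nichols frequencies have the model moments", {
  expect_equal(as.vector(balding_nichols_freqs(c(0.2, 0.4), fst = 0, K = 3)),
               rep(c(0.2, 0.4), each = 3))
  set.seed(90)
  draws <- balding_nichols_freqs(rep(0.3, 1e5), fst = 0.1, K = 1)
  expect_equal(mean(draws), 0.3, tolerance = 0.01)
  # Var = F p (1 - p) = 0.021, within 3%
  expect_lt(abs(var(as.vector(draws)) - 0.021) / 0.021, 0.03)
  # high divergence concentrates mass near fixation
  extreme <- balding_nichols_freqs(rep(0.3, 1e4), fst = 0.95, K = 1)
  expect_gt(mean(extreme < 0.05 | extreme > 0.95), 0.8)
  expect_error(balding_nichols_freqs(0, 0.1, 2))
})

test_that("single-locus genotypes follow Hardy-Weinberg proportions", {
  set.seed(91)
  q <- 0.35
  g <- simulate_stratum(rep(q, 1), ld = 0, n = 1e5)
  props <- tabulate(g + 1, 3) / 1e5
  expect_equal(props, c((1 - q)^2, 2 * q * (1 - q), q^2), tolerance = 0.02)
})

test_that("the LD parameter controls adjacent-haplotype correlation", {
  set.seed(92)
  freqs <- runif(40, 0.2, 0.8)
  g0 <- simulate_stratum(freqs, ld = 0, n = 4000)
  r0 <- mean(abs(vapply(1:39, function(k) cor(g0[, k], g0[, k + 1]), numeric(1))))
  expect_lt(r0, 0.05)
  freqs2 <- runif(40, 0.35, 0.65)  # range where r = 0.3 is feasible everywhere
  g5 <- simulate_stratum(freqs2, ld = 0.3, n = 4000)
  # genotype correlation equals the haplotype allele correlation here
  r5 <- vapply(1:39, function(k) cor(g5[, k], g5[, k + 1]), numeric(1))
  expect_equal(mean(r5), 0.3, tolerance = 0.05)
  # infeasible correlation for extreme frequency contrast warns
  expect_warning(simulate_stratum(c(0.02, 0.98), ld = 0.9, n = 100), "clipped")
})

test_that("monomorphic filtering requires polymorphism in every stratum", {
  g <- rbind(c(0L, 1L, 0L), c(0L, 2L, 1L),   # stratum a: SNP1 fixed
             c(1L, 2L, 2L), c(2L, 2L, 0L))   # stratum b: SNP2 fixed
  strata <- c("a", "a", "b", "b")
  expect_identical(filter_monomorphic(g, strata), 3L)
  g2 <- matrix(1L, 4, 2)
  expect_length(filter_monomorphic(g2, strata), 0)
})

test_that("the 14-stratum benchmark design reproduces the published totals", {
  d <- table2_design()
  expect_equal(sum(d$n_controls), 967)
  expect_equal(sum(d$n_cases), 878)
  expect_equal(sum(d$n_controls) + sum(d$n_cases), 1845)
  expect_equal(d$K, 14)
})

test_that("null studies match the design counts with no within-stratum association", {
  set.seed(93)
  d <- sim_design(n_controls = c(30, 10), n_cases = c(10, 30),
                  S = 400, fst = 0.1, ld = 0)
  st <- sample_h0_study(d)
  expect_equal(length(controls(st$phenotype)), 40)
  expect_equal(length(cases(st$phenotype)), 40)
  for (k in unique(st$strata)) {
    rows <- st$strata == k
    expect_equal(sum(st$phenotype$status[rows] == 0),
                 d$n_controls[match(k, d$strata_ids)])
  }
  # within-stratum case/control allele-frequency difference centred at zero
  g <- unpack_genotypes(st$genotypes)
  diffs <- unlist(lapply(unique(st$strata), function(k) {
    rows <- which(st$strata == k)
    co <- intersect(rows, controls(st$phenotype))
    ca <- intersect(rows, cases(st$phenotype))
    colMeans(g[ca, , drop = FALSE]) - colMeans(g[co, , drop = FALSE])
  }))
  expect_lt(abs(mean(diffs)), 0.01)
})

test_that("identical design and seed reproduce the identical study", {
  d <- default_design(S = 200)
  s1 <- sample_h0_study(d, seed = 99)
  s2 <- sample_h0_study(d, seed = 99)
  expect_identical(unpack_genotypes(s1$genotypes), unpack_genotypes(s2$genotypes))
  expect_identical(s1$phenotype$status, s2$phenotype$status)
})

test_that("realized divergence recovers the design F", {
  set.seed(94)
  d <- sim_design(n_controls = rep(50, 4), n_cases = rep(50, 4),
                  S = 5000, fst = 0.1, ld = 0)
  st <- sample_h0_study(d)
  g <- unpack_genotypes(st$genotypes)
  # Weir-Cockerham theta averaged over SNPs
  strata <- as.factor(st$strata)
  r <- nlevels(strata); nk <- as.vector(table(strata))
  pk <- do.call(rbind, lapply(levels(strata), function(k)
    colMeans(g[strata == k, , drop = FALSE]) / 2))
  nbar <- mean(nk)
  pbar <- colSums(pk * nk) / sum(nk)
  s2 <- colSums(nk * sweep(pk, 2, pbar)^2) / ((r - 1) * nbar)
  hk <- do.call(rbind, lapply(levels(strata), function(k)
    colMeans(g[strata == k, , drop = FALSE] == 1)))
  hbar <- colSums(hk * nk) / sum(nk)
  nc <- (sum(nk) - sum(nk^2) / sum(nk)) / (r - 1)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) * s2 / r - (2 * nbar - 1) * hbar / (4 * nbar))
  cc <- hbar / 2
  theta <- sum(a) / sum(a + b + cc)
  expect_lt(abs(theta - 0.1) / 0.1, 0.1)
})

test_that("power-mode sampling follows the multiplicative penetrance model", {
  d <- sim_design(n_controls = 2000, n_cases = 2000, S = 50, fst = 0,
                  ld = 0, rr = 1.5, prevalence = 0.1)
  # penetrance ratios are rr and rr^2 by construction
  q <- 0.3
  f0 <- d$prevalence / (1 + q * (d$rr - 1))^2
  expect_equal((f0 * d$rr) / f0, 1.5)
  expect_equal((f0 * d$rr^2) / (f0 * d$rr), 1.5)
  set.seed(95)
  st <- sample_power_study(d, causal_freqs = q)
  g <- unpack_genotypes(st$genotypes)[, st$causal_index]
  f_ca <- mean(g[cases(st$phenotype)]) / 2
  f_co <- mean(g[controls(st$phenotype)]) / 2
  # expected case risk-allele frequency under P(g|case) ~ HWE * rr^g
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  pc <- hwe * d$rr^(0:2) / sum(hwe * d$rr^(0:2))
  expect_lt(abs(f_ca - sum(pc * 0:2) / 2), 0.025)
  expect_gt(f_ca, f_co)
})

test_that("rr = 1 power sampling reduces to the null", {
  d <- sim_design(n_controls = c(3000, 3000), n_cases = c(3000, 3000),
                  S = 50, fst = 0.05, ld = 0, rr = 1)
  set.seed(96)
  st <- sample_power_study(d, causal_freqs = c(0.3, 0.4))
  g <- unpack_genotypes(st$genotypes)[, st$causal_index]
  for (k in unique(st$strata)) {
    rows <- which(st$strata == k)
    f_ca <- mean(g[intersect(rows, cases(st$phenotype))])
    f_co <- mean(g[intersect(rows, controls(st$phenotype))])
    expect_lt(abs(f_ca - f_co), 0.05)
  }
  # infeasible penetrance errors out
  d2 <- sim_design(n_controls = 10, n_cases = 10, S = 20, fst = 0,
                   ld = 0, rr = 6, prevalence = 0.5)
  expect_error(suppressWarnings(sample_power_study(d2, causal_freqs = 0.05)),
               "infeasible")
})

test_that("within-stratum genotypes are independent of the H0 phenotype", {
  set.seed(97)
  d <- sim_design(n_controls = c(60, 60), n_cases = c(60, 60),
                  S = 500, fst = 0.1, ld = 0)
  st <- sample_h0_study(d)
  g <- unpack_genotypes(st$genotypes)
  # chi-square calibration of the naive trend test within a single stratum
  rows <- which(st$strata == "S1")
  sub_phen <- phenotype(st$phenotype$status[rows])
  scan <- mcat_scan(g[rows, ], sub_phen, whole_sample_unit(sub_phen), "cat", B = 0)
  lam <- inflation_factor(scan$statistic)
  expect_lt(abs(lam - 1), 0.2)
  fp <- mean(asymptotic_pvalues(scan$statistic, "chi2_1") < 0.05, na.rm = TRUE)
  expect_lt(abs(fp - 0.05), 0.03)
})
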