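test_that("within-unit permutation preserves per-unit label counts", {
  set.seed(70)
  phen <- phenotype(c(1, 0, 1, 1, 0, 0, 1, 0, NA))
  st <- unit_structure(list(list(cases = 1L, controls = 2L),
                            list(cases = c(3L, 4L), controls = 5L),
                            list(cases = 7L, controls = c(6L, 8L))),
                       kind = "group", n_ind = 9)
  for (i in 1:25) {
    p2 <- permute_within_units(phen, st)
    for (u in st$units) {
      members <- c(u$cases, u$controls)
      expect_equal(sum(p2$status[members]), sum(phen$status[members]))
    }
    expect_identical(p2$status[9], NA_integer_)        # outside units untouched
    expect_equal(sum(p2$status, na.rm = TRUE), sum(phen$status, na.rm = TRUE))
  }
  # a pair is either kept or swapped
  p3 <- permute_within_units(phen, st)
  expect_true(all(p3$status[1:2] %in% 0:1))
})

test_that("enumerated relabelings cover all distinct arrangements", {
  phen <- phenotype(c(1, 1, 0))
  st <- unit_structure(list(list(cases = c(1L, 2L), controls = 3L)),
                       kind = "group", n_ind = 3)
  arr <- stratmatch:::.enumerate_relabelings(phen, st)
  expect_length(arr, 3)   # choose(3, 2)
  mats <- unique(vapply(arr, function(p) paste(p$status, collapse = ""), ""))
  expect_length(mats, 3)
})

test_that("exhaustive permutation p-value matches the hand count", {
  # two pairs; statistic = number of case-coded members among {1, 3};
  # observed labeling is strictly maximal in 1 of 4 relabelings
  phen <- phenotype(c(1, 0, 1, 0))
  st <- unit_structure(list(list(cases = 1L, controls = 2L),
                            list(cases = 3L, controls = 4L)),
                       kind = "pair", n_ind = 4)
  stat_fn <- function(p) sum(p$status[c(1, 3)])
  p <- permutation_pvalue(stat_fn, phen, st, exhaustive = TRUE, mode = "fraction")
  expect_equal(as.numeric(p), 1 / 4)
  expect_equal(attr(p, "B"), 4)
  # a constant statistic gives p = 1
  pconst <- permutation_pvalue(function(p) 1, phen, st, exhaustive = TRUE)
  expect_equal(as.numeric(pconst), 1)
})

test_that("add-one estimator is bounded below by 1/(B+1)", {
  set.seed(71)
  phen <- phenotype(rep(c(1, 0), 6))
  st <- unit_structure(lapply(seq(1, 12, 2), function(i)
    list(cases = i, controls = i + 1L)), kind = "pair", n_ind = 12)
  x <- rnorm(12)
  stat_fn <- function(p) sum(x[cases(p)])
  p <- permutation_pvalue(stat_fn, phen, st, B = 49, mode = "add_one")
  expect_gte(as.numeric(p), 1 / 50)
  expect_lte(as.numeric(p), 1)
})

test_that("permutation streams are reproducible under a fixed seed", {
  g <- rand_geno(16, 25, miss = 0, seed = 72)
  phen <- phenotype(rep(c(0, 1), 8))
  st <- unit_structure(lapply(seq(1, 16, 2), function(i)
    list(cases = i + 1L, controls = i)), kind = "pair", n_ind = 16)
  set.seed(123); s1 <- mcat_scan(g, phen, st, "mcat2", B = 200)
  set.seed(123); s2 <- mcat_scan(g, phen, st, "mcat2", B = 200)
  expect_identical(s1$exceed, s2$exceed)
  set.seed(124); s3 <- mcat_scan(g, phen, st, "mcat2", B = 200)
  expect_false(identical(s1$exceed, s3$exceed))
})

test_that("permutation p-values are super-uniform under an exchangeable null", {
  set.seed(73)
  n <- 40; S <- 400
  g <- rand_geno(n, S, miss = 0)
  phen <- phenotype(rep(c(0, 1), n / 2))
  st <- unit_structure(lapply(seq(1, n, 4), function(i)
    list(cases = c(i + 1L, i + 3L), controls = c(i, i + 2L))),
    kind = "group", n_ind = n)
  scan <- mcat_scan(g, phen, st, "mcat2", B = 199, p_mode = "add_one")
  for (a in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(scan$p_perm <= a, na.rm = TRUE),
               a + 3 * sqrt(a * (1 - a) / S))
  }
})

test_that("minP adjustment: single SNP, Sidak agreement, duplicate columns", {
  set.seed(74)
  B <- 2000
  # S = 1: adjusted equals raw
  null1 <- matrix(rnorm(B), B, 1)
  adj1 <- minp_adjust(null1, observed = 1.5, mode = "fraction")
  expect_equal(adj1$adjusted, adj1$raw)
  # independent SNPs: adjusted ~ Sidak 1 - (1 - p)^S
  S <- 10
  nullS <- matrix(rnorm(B * S), B, S)
  obs <- rep(1.8, S)
  adjS <- minp_adjust(nullS, obs, mode = "fraction")
  praw <- adjS$raw[1]
  sidak <- 1 - (1 - adjS$raw)^S
  expect_equal(adjS$adjusted, sidak, tolerance = 0.06)
  expect_true(all(adjS$adjusted >= adjS$raw - 1e-12))
  # duplicated SNP columns add no extra penalty
  nulld <- cbind(nullS[, 1], nullS[, 1])
  adjd <- minp_adjust(nulld, c(1.8, 1.8), mode = "fraction")
  adj_single <- minp_adjust(nullS[, 1, drop = FALSE], 1.8, mode = "fraction")
  expect_equal(adjd$adjusted[1], adj_single$adjusted[1], tolerance = 1e-12)
})

test_that("minP controls the familywise error under a multi-SNP null", {
  set.seed(75)
  B <- 999; S <- 10; reps <- 150
  hits <- 0
  for (r in seq_len(reps)) {
    null <- matrix(rnorm(B * S), B, S)
    obs <- rnorm(S)
    adj <- minp_adjust(null, obs)
    expect_true(all(adj$adjusted >= adj$raw))
    if (any(adj$adjusted <= 0.05)) hits <- hits + 1
  }
  expect_lte(hits / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(hits, 0)   # the bound is attained, not vacuous
})

test_that("asymptotic p-values use the stated reference laws", {
  expect_equal(asymptotic_pvalues(3.841, "chi2_1"), 0.05, tolerance = 1e-3)
  expect_equal(asymptotic_pvalues(0, "normal", M = 5), 1)
  expect_equal(asymptotic_pvalues(1.96 * sqrt(7), "normal", M = 7), 0.05,
               tolerance = 1e-3)
  expect_true(is.na(asymptotic_pvalues(1.2, "normal", M = 0)))
  expect_error(asymptotic_pvalues(1, "normal"), "unit count")
})

test_that("the inflation factor is anchored at the chi-squared median", {
  expect_equal(inflation_factor(rep(qchisq(0.5, 1), 5)), 1)
  expect_equal(qchisq(0.5, 1), 0.4549364, tolerance = 1e-7)
  set.seed(76)
  x <- 2 * rchisq(1e5, 1)
  expect_equal(inflation_factor(x), 2, tolerance = 0.02 * 2)
  p <- runif(1e5)
  expect_equal(inflation_factor(p, input = "pvalue"), 1, tolerance = 0.02)
  expect_error(inflation_factor(numeric(0)), "no finite")
})

test_that("genomic control rescales through the inverse chi-squared", {
  p <- c(0.9, 0.5, 0.05, 0.0001)
  expect_equal(gc_correct(p, 1), p)
  expect_equal(gc_correct(pchisq(1, 1, lower.tail = FALSE), 2),
               pchisq(0.5, 1, lower.tail = FALSE))
  expect_equal(gc_correct(0.3173, 2), 0.4795, tolerance = 1e-3)
  expect_true(all(gc_correct(p, 1.7) >= p))
  expect_true(all(gc_correct(p, 0.8) <= p))
  expect_error(gc_correct(c(0.5, 0), 1.2), "p-values")
  expect_error(gc_correct(0.5, -1), "positive")
  expect_identical(gc_correct(c(0.5, NA), 2)[2], NA_real_)
})

test_that("the standardised MCAT1 statistic is near-normal over group units", {
  set.seed(77)
  M <- 200; reps <- 10000
  # 4 cases + 4 controls per unit, binomial genotypes at varying frequency;
  # X_U computed vectorised over units straight from the count formulas
  q <- runif(M, 0.2, 0.8)
  z <- replicate(reps, {
    gco <- matrix(rbinom(4 * M, 2, rep(q, each = 4)), 4)
    gca <- matrix(rbinom(4 * M, 2, rep(q, each = 4)), 4)
    co1 <- colSums(gco == 1); co2 <- colSums(gco == 2)
    ca1 <- colSums(gca == 1); ca2 <- colSums(gca == 2)
    c2 <- co1 + ca1; c3 <- co2 + ca2
    D <- 8 * (c2 + 4 * c3) - (c2 + 2 * c3)^2
    U <- 4 * (ca1 + 2 * ca2) - 4 * (co1 + 2 * co2)
    ok <- D > 0
    xu <- sqrt(7 / 16) * U[ok] / sqrt(D[ok])
    sum(xu) / sqrt(sum(ok))
  })
  ks <- suppressWarnings(ks.test(z, pnorm))
  expect_lt(unname(ks$statistic), 0.02)
})
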