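# Shared fixture builders (all data generated in code).

# random genotype matrix with optional missingness
rand_geno <- function(n, s, miss = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(c(0:2, NA), n * s, replace = TRUE,
                prob = c((1 - miss) / 3, (1 - miss) / 3, (1 - miss) / 3, miss)),
         nrow = n)
}

# block similarity matrix: two strata with given within/between scores
two_block_sim <- function(n1 = 10, n2 = 10, within = 0.9, between = 0.1) {
  n <- n1 + n2
  sc <- matrix(between, n, n)
  sc[seq_len(n1), seq_len(n1)] <- within
  sc[(n1 + 1):n, (n1 + 1):n] <- within
  diag(sc) <- 1
  sc
}

# brute-force maximum assignment weight over all permutations (n <= 8)
brute_force_assignment <- function(w) {
  n <- nrow(w)
  best <- -Inf
  perm <- function(v, acc) {
    if (length(v) == 0) {
      best <<- max(best, acc)
      return()
    }
    r <- n - length(v) + 1
    for (i in seq_along(v)) perm(v[-i], acc + w[r, v[i]])
  }
  perm(seq_len(n), 0)
  best
}

# naive IBS similarity matrix via the per-pair formula
naive_ibs <- function(g) {
  n <- nrow(g)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <- ibs_pair(g[i, ], g[j, ])
  }
  out
}

# adjusted Rand index between two label vectors
adj_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  ex <- si * sj / choose(n, 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

# per-unit contingency tables for one SNP (R-side reference path)
unit_tables <- function(g, phen, units, snp) {
  lapply(units$units, function(u) contingency_table(g, phen, u, snp))
}

# a small study with k strata as packed genotypes + phenotype + labels
tiny_study <- function(seed = 1, K = 2, per = 10, S = 300, fst = 0.2) {
  set.seed(seed)
  d <- sim_design(n_controls = rep(per, K), n_cases = rep(per, K),
                  S = S, fst = fst, ld = 0)
  sample_h0_study(d)
}
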