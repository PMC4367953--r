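test_that("match_pairs maximises total IBS (brute force on 2x2)", {
  # cases 1,2; controls 3,4; unique optimum pairs (1,4), (2,3)
  sc <- diag(1, 4)
  sc[1, 3] <- sc[3, 1] <- 0.2; sc[1, 4] <- sc[4, 1] <- 0.9
  sc[2, 3] <- sc[3, 2] <- 0.8; sc[2, 4] <- sc[4, 2] <- 0.3
  phen <- phenotype(c(1, 1, 0, 0))
  ms <- match_pairs(sc, phen)
  got <- lapply(ms$units, function(u) c(u$cases, u$controls))
  expect_setequal(vapply(got, paste, "", collapse = "-"), c("1-4", "2-3"))
  expect_length(ms$removed, 0)
})

test_that("unequal sides are reduced to min(|O|, |A|) pairs via sinks", {
  sc <- matrix(0.5, 4, 4); diag(sc) <- 1
  sc[1, 2] <- sc[2, 1] <- 0.9
  phen <- phenotype(c(1, 0, 0, 0))  # 1 case, 3 controls
  ms <- match_pairs(sc, phen)
  expect_length(ms$units, 1)
  expect_identical(ms$units[[1]]$controls, 2L)
  expect_length(ms$removed, 2)
  expect_error(match_pairs(sc, phenotype(c(1, 1, 1, 1))), "at least one")
})

test_that("vicinity threshold is the log of the set-size product", {
  expect_equal(vicinity_threshold(10, 10), log(100))
  expect_equal(vicinity_threshold(1, 1), 0)
  expect_equal(vicinity_threshold(967, 878), log(849026))
  expect_equal(vicinity_threshold(967, 878), 13.652, tolerance = 1e-3)
  expect_error(vicinity_threshold(0, 5), "non-empty")
})

test_that("vicinity check counts strictly better mates over the full sets", {
  # 5 cases (1-5), 5 controls (6-10); hand-set weights around pair (1, 6)
  sc <- matrix(0.1, 10, 10); diag(sc) <- 1
  sc[1, 6] <- sc[6, 1] <- 0.5
  sc[1, 7] <- sc[7, 1] <- 0.6
  sc[1, 8] <- sc[8, 1] <- 0.7
  sc[1, 9] <- sc[9, 1] <- 0.8   # three better controls for case 1
  sc[2, 6] <- sc[6, 2] <- 0.55  # one better case for control 6
  phen <- phenotype(c(rep(1, 5), rep(0, 5)))
  t_cc <- vicinity_threshold(5, 5)   # log(25) ~ 3.22

  v <- vicinity_check(1, 6, sc, phen)
  expect_identical(attr(v, "t_x"), 3L)
  expect_identical(attr(v, "t_y"), 1L)
  expect_true(as.logical(v))         # 3 < T and 1 < T

  sc[1, 10] <- sc[10, 1] <- 0.9      # now 4 >= T better controls
  v2 <- vicinity_check(1, 6, sc, phen)
  expect_identical(attr(v2, "t_x"), 4L)
  expect_false(as.logical(v2))

  # third clause: t_y = 0 validates regardless of t_x
  sc[2, 6] <- sc[6, 2] <- 0.2
  v3 <- vicinity_check(1, 6, sc, phen)
  expect_identical(attr(v3, "t_y"), 0L)
  expect_true(as.logical(v3))

  # equal weights do not count as better mates (strict inequality)
  sc2 <- matrix(0.5, 10, 10); diag(sc2) <- 1
  v4 <- vicinity_check(1, 6, sc2, phen)
  expect_identical(attr(v4, "t_x"), 0L)
  expect_true(as.logical(v4))
})

test_that("vicinity validation rejects cross-stratum pairs in asymmetric strata", {
  # block 1: 14 cases + 8 controls; block 2: 8 cases + 14 controls
  sc <- two_block_sim(22, 22)
  status <- c(rep(1, 14), rep(0, 8), rep(1, 8), rep(0, 14))
  phen <- phenotype(status)
  ms <- match_pairs(sc, phen)
  val <- validate_units(ms, sc, phen, strategy = "vicinity")
  cross <- vapply(val$structure$units, function(u) {
    (u$cases <= 22) != (u$controls <= 22)
  }, logical(1))
  expect_false(any(cross))
  expect_gt(length(val$rejected), 0)

  # everything intra-cluster passes cluster validation untouched
  clusters <- rep(1:2, each = 22)
  mc <- match_within_clusters(sc, phen, clusters)
  vc <- validate_units(mc, sc, phen, strategy = "cluster", clusters = clusters)
  expect_length(vc$rejected, 0)
  expect_identical(length(vc$structure$units), length(mc$units))
})

test_that("validate_units handles empty structures and missing clusters", {
  sc <- two_block_sim(2, 2)
  phen <- phenotype(c(1, 0, 1, 0))
  empty <- unit_structure(list(), kind = "pair", n_ind = 4)
  out <- validate_units(empty, sc, phen, strategy = "vicinity")
  expect_length(out$structure$units, 0)
  expect_error(validate_units(empty, sc, phen, strategy = "cluster"),
               "cluster assignment")
})

test_that("match_within_clusters keeps pairs inside clusters", {
  sc <- two_block_sim(4, 4, within = 0.8, between = 0.2)
  phen <- phenotype(c(1, 1, 0, 0, 1, 1, 0, 0))
  clusters <- rep(1:2, each = 4)
  ms <- match_within_clusters(sc, phen, clusters)
  expect_length(ms$units, 4)
  for (u in ms$units) {
    expect_identical(clusters[u$cases], clusters[u$controls])
  }
  # a caseless cluster contributes only removals
  phen2 <- phenotype(c(1, 1, 0, 0, 0, 0, 0, 0))
  ms2 <- match_within_clusters(sc, phen2, clusters)
  expect_length(ms2$units, 2)
  expect_true(all(5:8 %in% ms2$removed))
  # single cluster reduces to match_pairs
  ms3 <- match_within_clusters(sc, phen, rep(1, 8))
  mp <- match_pairs(sc, phen)
  expect_equal(length(ms3$units), length(mp$units))
})

test_that("groupwise matching absorbs the control surplus into one group", {
  sc <- matrix(0.7, 4, 4); diag(sc) <- 1
  sc[1, 2] <- sc[2, 1] <- 0.9
  phen <- phenotype(c(1, 0, 0, 0))
  g <- match_groups(sc, phen, validation = "vicinity")
  expect_length(g$units, 1)
  expect_setequal(g$units[[1]]$controls, 2:4)
  expect_length(g$removed, 0)
})

test_that("a balanced first round makes groups identical to validated pairs", {
  sc <- two_block_sim(4, 4, within = 0.8, between = 0.2)
  phen <- phenotype(rep(c(1, 0), 4))
  clusters <- rep(1:2, each = 4)
  g <- match_groups(sc, phen, "cluster", clusters = clusters)
  p <- match_within_clusters(sc, phen, clusters)
  expect_equal(length(g$units), length(p$units))
  expect_true(all(vapply(g$units, function(u)
    length(u$cases) == 1 && length(u$controls) == 1, logical(1))))
})

test_that("groupwise matching with stratum excesses keeps units intra-stratum", {
  # stratum 1 has a case excess, stratum 2 a control excess
  sc <- two_block_sim(22, 22)
  status <- c(rep(1, 14), rep(0, 8), rep(1, 8), rep(0, 14))
  phen <- phenotype(status)
  g <- match_groups(sc, phen, validation = "vicinity")
  cross <- vapply(g$units, function(u) {
    length(unique(c(u$cases, u$controls) <= 22)) > 1
  }, logical(1))
  expect_false(any(cross))
  # groupwise output covers a superset of the validated pairwise output
  pv <- validate_units(match_pairs(sc, phen), sc, phen, "vicinity")$structure
  matched_g <- setdiff(seq_len(44), g$removed)
  matched_p <- setdiff(seq_len(44), pv$removed)
  expect_true(all(matched_p %in% matched_g))
})

test_that("unit structures enforce their invariants", {
  expect_error(unit_structure(list(list(cases = 1L, controls = integer(0))),
                              kind = "pair", n_ind = 2), "at least one")
  expect_error(unit_structure(list(list(cases = 1:2, controls = 3L)),
                              kind = "pair", n_ind = 3), "exactly one")
  expect_error(unit_structure(list(list(cases = 1L, controls = 2L),
                                   list(cases = 1L, controls = 3L)),
                              kind = "pair", n_ind = 3), "disjoint")
  st <- unit_structure(list(list(cases = 1L, controls = 2L)), "pair", n_ind = 3)
  expect_identical(unit_index(st), c(1L, 1L, NA_integer_))
})

test_that("unit structure TSV round-trips", {
  ids <- sprintf("i%d", 1:6)
  st <- unit_structure(list(list(cases = 1L, controls = c(2L, 3L)),
                            list(cases = c(4L, 5L), controls = 6L)),
                       kind = "group", n_ind = 6, ids = ids)
  f <- tempfile(fileext = ".tsv")
  write_units_tsv(st, f)
  back <- read_units_tsv(f, ids)
  expect_equal(length(back$units), 2)
  expect_setequal(unit_index(back), unit_index(st))
})
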