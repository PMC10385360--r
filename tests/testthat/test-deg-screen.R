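test_that("RBH pairing keeps exactly the mutually-best pairs", {
  m <- matrix(c(9, 1, 1, 9), 2, 2,
              dimnames = list(c("A1", "A2"), c("B1", "B2")))
  p <- rbh_pairs(m)
  expect_equal(p$gene_a, c("A1", "A2"))
  expect_equal(p$gene_b, c("B1", "B2"))

  # A2's best hit B1 is already taken by A1: single pair survives
  m2 <- matrix(c(9, 7, 8, 1), 2, 2,
               dimnames = list(c("A1", "A2"), c("B1", "B2")))
  p2 <- rbh_pairs(m2)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$gene_a, "A1")
  expect_equal(p2$gene_b, "B1")

  # ties break toward the lexicographically smallest partner, logged
  m3 <- matrix(c(5, 0, 5, 0, 0, 4), 2, 3,
               dimnames = list(c("A1", "A2"), c("B1", "B2", "B3")))
  expect_message(p3 <- rbh_pairs(m3), "tie for best hit")
  expect_equal(p3$gene_b[p3$gene_a == "A1"], "B1")

  expect_equal(nrow(rbh_pairs(matrix(numeric(0), 0, 0))), 0L)
})

test_that("RBH output is invariant under matrix transposition", {
  withr::local_seed(3)
  for (rep in 1:5) {
    m <- matrix(runif(30 * 25, 0, 100), 30, 25,
                dimnames = list(sprintf("A%02d", 1:30),
                                sprintf("B%02d", 1:25)))
    p <- rbh_pairs(m)
    pt <- rbh_pairs(t(m))
    expect_setequal(paste(p$gene_a, p$gene_b),
                    paste(pt$gene_b, pt$gene_a))
  }
})

test_that("fold change and significance behave on degenerate inputs", {
  vals <- matrix(c(5, 5, 5, 5,
                   4, 4, 8, 8), 2, 4, byrow = TRUE,
                 dimnames = list(c("flat", "dbl"), NULL))
  tbl <- expression_table("HG", vals, c("early", "early", "late", "late"),
                          c(1, 2, 1, 2))
  fc_flat <- fold_change(tbl, "flat")
  expect_equal(unname(fc_flat["fc"]), 1)
  expect_equal(unname(fc_flat["p"]), 1)
  # exact doubling, zero within-group variance: fc -> 2 as pseudo -> 0
  fc_dbl <- fold_change(tbl, "dbl", pseudo = 1e-12)
  expect_equal(unname(fc_dbl["fc"]), 2, tolerance = 1e-9)
  expect_equal(unname(fc_dbl["p"]), 0)
  expect_error(fold_change(tbl, "nope"), "not found")
  # vectorised version agrees
  fcs <- fold_changes(tbl)
  expect_equal(fcs$fc[fcs$gene == "flat"], 1)
})

test_that("estimated fold changes centre on the planted effect", {
  # 500 genes with log2FC = 3 under NB noise, dispersion 0.1, n = 2:
  # the median estimate stays within [6, 10]
  withr::local_seed(11)
  n <- 500
  mu_e <- 500
  vals <- cbind(matrix(rnbinom(2 * n, mu = mu_e, size = 10), n, 2),
                matrix(rnbinom(2 * n, mu = mu_e * 8, size = 10), n, 2))
  rownames(vals) <- sprintf("g%03d", 1:n)
  tbl <- expression_table("sim", vals, c("early", "early", "late", "late"),
                          c(1, 2, 1, 2))
  fcs <- fold_changes(tbl)
  expect_gt(median(fcs$fc), 6)
  expect_lt(median(fcs$fc), 10)
})

test_that("ratio of ratios matches the candidate-table arithmetic", {
  expect_equal(round(ratio_of_ratios(3.03, 8.20), 2), 2.71)
  expect_equal(round(ratio_of_ratios(2.62, 32.56), 2), 12.43)
  expect_equal(ratio_of_ratios(5.5, 5.5), 1)
  expect_equal(ratio_of_ratios(0, 8.62), Inf)
  expect_equal(format_ratio(c(2.706, Inf)), c("2.71", "~"))
  expect_error(ratio_of_ratios(-1, 2), "non-negative")
  # reciprocal identity for positive arguments
  withr::local_seed(5)
  a <- runif(20, 0.01, 50)
  b <- runif(20, 0.01, 50)
  expect_equal(ratio_of_ratios(a, b) * ratio_of_ratios(b, a),
               rep(1, 20), tolerance = 1e-12)
})

test_that("group classification is a total significance-gated partition", {
  expect_equal(classify_group(3.03, 0.01, 8.20, 0.01), "I")
  expect_equal(classify_group(0.15, 0.01, 0.33, 0.01), "II")
  expect_equal(classify_group(0.31, 0.01, 19.86, 0.01), "III")
  # fc 2.45 but not significant in M43: constant, hence group IV
  expect_equal(classify_group(0.37, 0.01, 2.45, 0.30), "IV")
  expect_equal(classify_group(1.05, 0.50, 3.00, 0.01), "V")
  expect_equal(classify_group(3.00, 0.01, 0.30, 0.01), "other")
  expect_equal(classify_group(1.00, 0.90, 1.00, 0.90), "other")
  # totality: every (status, status) combination yields exactly one label
  fcs <- c(3, 0.2, 1)       # up / down / constant when significant
  ps <- c(0.01, 0.5)
  grid <- expand.grid(f1 = fcs, p1 = ps, f2 = fcs, p2 = ps)
  labs <- classify_group(grid$f1, grid$p1, grid$f2, grid$p2)
  expect_true(all(labs %in% c("I", "II", "III", "IV", "V", "other")))
  expect_length(labs, nrow(grid))
})

test_that("the screen applies cutoff, pathway filter and constancy rule", {
  rec <- data.frame(
    gene_hg = c("h1", "h2", "h3", "h4", "h5"),
    gene_m43 = c("m1", "m2", "m3", "m4", "m5"),
    ko = c("ko00561", "ko00561", "ko03010", "ko00561", "ko00592"),
    fc_hg = c(3, 3, 0.2, 1.0, 0),
    p_hg = c(0.01, 0.01, 0.01, 0.5, 0.01),
    fc_m43 = c(9, 4.4, 9, 1.1, 8.6),
    p_m43 = c(0.01, 0.01, 0.01, 0.6, 0.01),
    stringsAsFactors = FALSE)
  out <- screen_candidates(rec)
  # h2: ratio 1.47 below cutoff; h3: off-pathway; h4: constant in both;
  # h5: sentinel ratio retained
  expect_setequal(out$gene_hg, c("h1", "h5"))
  expect_equal(out$group[out$gene_hg == "h1"], "I")
  expect_true(is.infinite(out$ratio[out$gene_hg == "h5"]))
  expect_error(screen_candidates(rec, lipid_kos = character(0)),
               "non-empty")
})

test_that("ddCt fold differences follow the exponent arithmetic", {
  expect_equal(ddct_fold(20, 18, 20, 18), 1)
  expect_equal(ddct_fold(20, 18, 19, 18), 2)   # one cycle earlier
  expect_equal(ddct_fold(20, 18, 23.32, 18), 2^-3.32, tolerance = 1e-12)
  expect_equal(2^-3.32, 0.1, tolerance = 0.01)
})

test_that("expression tables round-trip through TSV", {
  withr::local_seed(2)
  vals <- matrix(runif(12, 0, 100), 3, 4,
                 dimnames = list(c("g1", "g2", "g3"), NULL))
  tbl <- expression_table("HG", vals, c("early", "early", "late", "late"),
                          c(1, 2, 1, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(tbl, path)
  back <- read_expression(path)
  expect_equal(unname(back$values[rownames(tbl$values), ]),
               unname(tbl$values), tolerance = 1e-12)
  expect_equal(back$timepoint, tbl$timepoint)

  m <- matrix(runif(6, 0, 10), 2, 3,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  write_scores(m, path)
  expect_equal(read_scores(path), m, tolerance = 1e-12)
})
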