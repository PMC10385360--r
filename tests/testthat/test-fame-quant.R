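test_that("internal-standard quantification converts areas to contents", {
  # area equal to the IS area with rf 1 carries the IS mass: 75 ug in
  # 10 mg kernel = 0.75 % dry mass
  pt <- peak_table("s1", kernel_mass_mg = 10, is_area = 1e5,
                   peaks = c("18:1d9" = 1e5))
  pr <- quantify(pt)
  expect_equal(unname(pr$content["18:1d9"]), 0.75)
  expect_equal(pr$total_oil, 0.75)
  expect_equal(unname(pr$mol_pct["18:1d9"]), 100)

  # response factors scale species masses
  pt2 <- peak_table("s2", kernel_mass_mg = 10, is_area = 1e5,
                    peaks = c("18:1d9" = 1e5, "16:0" = 5e4))
  pr2 <- quantify(pt2, response_factors = c("16:0" = 2))
  expect_equal(unname(pr2$content["16:0"]),
               unname(pr2$content["18:1d9"]))
})

test_that("empty peak maps yield zero oil and a warning", {
  pt <- peak_table("s0", kernel_mass_mg = 5, is_area = 1e4,
                   peaks = numeric(0))
  expect_warning(pr <- quantify(pt), "empty")
  expect_equal(pr$total_oil, 0)
  expect_length(pr$mol_pct, 0)
})

test_that("mole percent follows inverse molecular weights", {
  # equal masses of two species have mole ratio mw2 : mw1
  pt <- peak_table("s3", kernel_mass_mg = 10, is_area = 1e5,
                   peaks = c("16:0" = 2e5, "18:0" = 2e5))
  pr <- quantify(pt)
  reg <- fa_registry()
  mw16 <- reg$mw[reg$name == "16:0"]
  mw18 <- reg$mw[reg$name == "18:0"]
  # independent arithmetic: mol_i = m / mw_i, normalised to 100
  expect_equal(unname(pr$mol_pct["16:0"] / pr$mol_pct["18:0"]),
               mw18 / mw16, tolerance = 1e-12)
  expect_equal(sum(pr$mol_pct), 100, tolerance = 1e-9)
})

test_that("quantification is linear in peak areas", {
  areas <- c("16:0" = 4e4, "18:1d9" = 3e5, "18:2" = 5e4, "18:3" = 3e3)
  p1 <- quantify(peak_table("a", 10, 1e5, areas))
  pk <- quantify(peak_table("b", 10, 1e5, areas * 3.7))
  expect_equal(pk$total_oil, 3.7 * p1$total_oil, tolerance = 1e-12)
  expect_equal(pk$mol_pct, p1$mol_pct, tolerance = 1e-12)
  # total equals the sum of per-species quantifications
  singles <- vapply(names(areas), function(s) {
    quantify(peak_table("c", 10, 1e5, areas[s]))$total_oil
  }, numeric(1))
  expect_equal(p1$total_oil, sum(singles), tolerance = 1e-12)
})

test_that("peak-table validation rejects degenerate inputs", {
  expect_error(peak_table("x", 0, 1e5, c("16:0" = 1)), "kernel_mass")
  expect_error(peak_table("x", 10, 0, c("16:0" = 1)), "internal-standard")
  expect_error(peak_table("x", 10, 1e5, c("16:0" = -1)), ">= 0")
  expect_error(peak_table("x", 10, 1e5, c("16:0" = 1, "16:0" = 2)),
               "duplicate")
})

test_that("composition ratios behave on symmetric and degenerate profiles", {
  reg <- fa_registry()
  mw_o <- reg$mw[reg$name == "18:1d9"]
  mw_s <- reg$mw[reg$name == "18:0"]
  # equal moles of one MUFA and one SFA -> USFA/SFA = 1
  pr <- fa_profile("sym", c("18:1d9" = 1 * mw_o, "18:0" = 1 * mw_s))
  r <- suppressWarnings(composition_ratios(pr))
  expect_equal(unname(r["usfa_sfa"]), 1, tolerance = 1e-12)
  # only 16:0 -> no 18C at all
  r16 <- suppressWarnings(composition_ratios(fa_profile("p", c("16:0" = 2))))
  expect_equal(unname(r16["c18_c16"]), 0)
  expect_warning(composition_ratios(fa_profile("p", c("16:0" = 2))),
                 "denominator")
})

test_that("a Camellia-like composition gives an ~8-fold 18C/16C ratio", {
  # dominant oleic profile: ~70 mol% 18:1d9, 8% 16:0, 9% 18:2 and minors
  reg <- fa_registry()
  mol <- c("18:1d9" = 70, "16:0" = 8, "18:2" = 9, "18:0" = 4,
           "18:3" = 1, "16:1d9" = 0.5, "16:1d11" = 0.5, "18:1d11" = 4,
           "20:0" = 2, "20:1d13" = 1)
  mw <- reg$mw[match(names(mol), reg$name)]
  pr <- fa_profile("cam", mol * mw / 100)
  r <- composition_ratios(pr)
  c18 <- sum(mol[c("18:0", "18:1d9", "18:1d11", "18:2", "18:3")])
  c16 <- sum(mol[c("16:0", "16:1d9", "16:1d11")])
  expect_equal(unname(r["c18_c16"]), c18 / c16, tolerance = 1e-12)
  expect_gt(r["c18_c16"], 7)
  expect_lt(r["c18_c16"], 11)
})

test_that("time courses round-trip through TSV and reject bad keys", {
  tc <- make_random_tc()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse(tc, path)
  back <- read_timecourse(path)
  expect_s3_class(back, "fa_timecourse")
  expect_equal(back$data, tc$data, tolerance = 1e-12)

  # a well-formed three-row file: one week, one replicate, 3 species
  writeLines(c("cultivar\tweek\treplicate\tspecies\tcontent_pct",
               "QG\t46\t1\t16:0\t3.5",
               "QG\t46\t1\t18:1d9\t30.1",
               "QG\t46\t1\t18:2\t4.2"), path)
  one <- read_timecourse(path)
  expect_equal(tc_weeks(one), 46L)
  expect_equal(sort(unique(one$data$species)),
               c("16:0", "18:1d9", "18:2"))

  # duplicate (week, replicate, species) key is a format error
  writeLines(c("cultivar\tweek\treplicate\tspecies\tcontent_pct",
               "QG\t46\t1\t16:0\t3.5",
               "QG\t46\t1\t16:0\t3.6"), path)
  expect_error(read_timecourse(path), "duplicate")

  # missing column is a format error
  writeLines(c("cultivar\tweek\tspecies\tcontent_pct",
               "QG\t46\t16:0\t3.5"), path)
  expect_error(read_timecourse(path), "missing columns")
})

test_that("replicate aggregation reports mean and n-1 SD", {
  m <- matrix(c(10, 20), 1, 2, dimnames = list("18:1d9", c(46, 47)))
  tc <- make_tc(m, replicates = 3,
                jitter = function(v) v + rep(c(-1, 0, 1), length.out = length(v)))
  ag <- aggregate_replicates(tc)
  expect_equal(ag$mean, c(10, 20))
  expect_equal(ag$sd, c(1, 1))   # sd of {v-1, v, v+1} with n-1 denominator
  expect_equal(ag$n, c(3L, 3L))
})
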