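test_that("scenario generation is deterministic given the seed", {
  spec <- scenario_spec(seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(spec, d1)
  write_scenario(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed changes the draws
  g1 <- gen_timecourse(scenario_spec(seed = 1))
  g2 <- gen_timecourse(scenario_spec(seed = 2))
  expect_false(identical(g1$timecourses$QG$data$content_pct,
                         g2$timecourses$QG$data$content_pct))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(3)
  set.seed(123)
  invisible(gen_timecourse(scenario_spec(seed = 5)))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("generated tables parse back through the pipeline readers", {
  d <- withr::local_tempdir()
  paths <- write_scenario(scenario_spec(seed = 3), d)
  expect_no_warning({
    tcs <- read_timecourse(paths[["timecourse"]])
    exprs <- read_expression(paths[["expression"]])
    scores <- read_scores(paths[["scores"]])
    ann <- read_annotation(paths[["annotation"]])
  })
  expect_named(tcs, c("HG", "M43", "QG"), ignore.order = TRUE)
  expect_named(exprs, c("HG", "M43"), ignore.order = TRUE)
  expect_true(all(c("gene", "ko") %in% names(ann)))
  expect_true(nrow(scores) > 0)
})

test_that("noiseless QG-like trajectory loses exactly the configured fraction", {
  g <- gen_timecourse(scenario_spec(seed = 1, noise_cv = 0))
  m <- content_matrix(g$timecourses$QG)
  expect_equal(sum(m["54", ]) / sum(m["53", ]), 0.75, tolerance = 1e-12)
  # M43 loses its configured fraction of the week-52 total by week 54
  m43 <- content_matrix(g$timecourses$M43)
  expect_equal(sum(m43["54", ]) / sum(m43["52", ]), 0.70,
               tolerance = 1e-12)
  # HG never loses oil
  hg <- content_matrix(g$timecourses$HG)
  expect_gt(sum(hg["54", ]), sum(hg["52", ]))
})

test_that("mole percent sums to 100 on every generated profile", {
  g <- gen_timecourse(scenario_spec(seed = 8))
  for (tc in g$timecourses) {
    for (w in tc_weeks(tc)) {
      pr <- tc_profile(tc, w, 1)
      expect_equal(sum(pr$mol_pct), 100, tolerance = 1e-9)
    }
  }
})

test_that("proxy sign patterns are recovered from generated data", {
  spec <- scenario_spec(seed = 1)
  g <- gen_timecourse(spec)
  # noiseless run recovers every stored sign exactly
  g0 <- gen_timecourse(scenario_spec(seed = 1, noise_cv = 0))
  for (cv in names(g0$timecourses)) {
    tr <- g0$truth[[cv]]
    for (e in enzymes()) {
      ps <- suppressWarnings(proxy_series(g0$timecourses[[cv]], e))
      expect_equal(sign(ps$delta), unname(tr$proxy_sign[e, ]),
                   info = paste(cv, e))
    }
  }
  # the M43-like KASII pattern is biphasic: peaks at weeks 49 and 52
  expect_equal(unname(g$truth$M43$proxy_sign["KASII", ]),
               c(1, 1, 1, -1, 1, 1, -1, -1))
  # noisy run recovers the signs on noise-reliable intervals
  for (cv in names(g$timecourses)) {
    tr <- g$truth[[cv]]
    for (e in enzymes()) {
      ps <- suppressWarnings(proxy_series(g$timecourses[[cv]], e))
      rel <- tr$sign_reliable[e, ]
      expect_equal(sign(ps$delta)[rel], unname(tr$proxy_sign[e, rel]),
                   info = paste(cv, e))
    }
  }
})

test_that("planted HG-like FAD2 discordance appears after week 50", {
  g <- gen_timecourse(scenario_spec(seed = 1))
  pr <- lapply(c("FAD2", "KASII"), function(e) {
    suppressWarnings(proxy_series(g$timecourses$HG, e))
  })
  pre <- synchrony(pr, window = c(47, 50))
  post <- synchrony(pr, window = c(51, 54))
  expect_lt(post$r["FAD2", "KASII"], pre$r["FAD2", "KASII"])
})

test_that("the 20:1 total-oil correlation separates the cultivars", {
  g <- gen_timecourse(scenario_spec(seed = 1))
  nets <- lapply(g$timecourses, correlate)
  edge_klass <- function(net) {
    e <- net$edges
    e$klass[e$node_a == "total_oil" & e$node_b == "20:1d13"]
  }
  expect_equal(edge_klass(nets$QG), "positive")
  expect_equal(edge_klass(nets$HG), "positive")
  expect_equal(edge_klass(nets$M43), "ns")
  d <- compare_networks(nets$M43, nets$QG)
  expect_true(any(d$node_a == "total_oil" & d$node_b == "20:1d13"))
})

test_that("expression generator plants recoverable candidate structure", {
  ex <- gen_expression(scenario_spec(seed = 4))
  pairs <- rbh_pairs(ex$scores)
  # decoy orphans are never paired
  expect_false(any(grepl("orph", pairs$gene_a)))
  expect_false(any(grepl("orph", pairs$gene_b)))
  expect_equal(nrow(pairs), nrow(ex$truth))
  # zero-dispersion limit realises the planted fold-change signatures
  ex0 <- gen_expression(scenario_spec(seed = 4, nb_dispersion = 0))
  fcs <- fold_changes(ex0$expr_m43)
  tr <- ex0$truth
  up <- tr$gene_m43[tr$group == "V"]
  expect_true(all(fcs$fc[match(up, fcs$gene)] > 2))
  flat <- tr$gene_m43[tr$group == "IV"]
  expect_equal(fcs$fc[match(flat, fcs$gene)],
               rep(1, length(flat)), tolerance = 1e-9)
})
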