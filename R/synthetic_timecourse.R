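# Run expr with a private RNG stream seeded at `seed`, restoring any
# pre-existing global RNG state afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation scenario specification
#'
#' Bundles every tunable of the synthetic-data generators: the replicate
#' noise for fatty-acid contents, the negative-binomial dispersion and
#' planted effect sizes for expression, the terminal oil-loss fractions,
#' and the RNG seed. The same spec object drives [gen_timecourse()] and
#' [gen_expression()]; a fixed seed gives byte-identical output.
#'
#' @param seed Integer RNG seed.
#' @param noise_cv Replicate coefficient of variation of fatty-acid
#'   contents (multiplicative lognormal; default 0.05).
#' @param nb_dispersion Negative-binomial dispersion of expression counts
#'   (variance `mu + mu^2 * dispersion`; default 0.1). Zero gives the
#'   deterministic noise-free limit (`counts = mu`).
#' @param replicates Fatty-acid replicates per week (default 3).
#' @param expr_replicates Expression replicates per timepoint (default 2).
#' @param loss Named terminal oil-loss fractions in `[0, 1)` for the
#'   cultivars that lose oil late in desiccation (default QG 0.25,
#'   M43 0.30).
#' @param n_lipid_pairs Homolog pairs annotated to lipid pathways
#'   (default 400), of which the planted candidates are a subset.
#' @param n_offpath_pairs Homolog pairs with off-pathway annotations
#'   (default 100).
#' @param n_orphans Unpaired decoy genes per cultivar whose similarity
#'   scores are deliberately non-reciprocal (default 20).
#' @param planted_groups Named integer vector of planted candidate counts
#'   per group (default `c(I = 6, II = 5, III = 6, IV = 15, V = 26)`,
#'   the group sizes of the M43/HG candidate table).
#' @param group_lfc Named list of planted `c(log2FC_HG, log2FC_M43)`
#'   pairs per group; DE arms use |log2FC| of 5 to 7 so that the
#'   two-replicate t-test retains power at dispersion 0.1 (see the
#'   methods vignette).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1,
                          noise_cv = 0.05,
                          nb_dispersion = 0.1,
                          replicates = 3,
                          expr_replicates = 2,
                          loss = c(QG = 0.25, M43 = 0.30),
                          n_lipid_pairs = 400,
                          n_offpath_pairs = 100,
                          n_orphans = 20,
                          planted_groups = c(I = 6, II = 5, III = 6,
                                             IV = 15, V = 26),
                          group_lfc = list(I = c(5, 7), II = c(-7, -5),
                                           III = c(-5, 6), IV = c(-6, 0),
                                           V = c(0, 6))) {
  stopifnot(noise_cv >= 0, nb_dispersion >= 0,
            replicates >= 1, expr_replicates >= 2,
            all(loss >= 0 & loss < 1),
            all(c("QG", "M43") %in% names(loss)),
            all(names(planted_groups) %in% c("I", "II", "III", "IV", "V")),
            sum(planted_groups) <= n_lipid_pairs)
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 nb_dispersion = nb_dispersion,
                 replicates = as.integer(replicates),
                 expr_replicates = as.integer(expr_replicates),
                 loss = loss,
                 n_lipid_pairs = as.integer(n_lipid_pairs),
                 n_offpath_pairs = as.integer(n_offpath_pairs),
                 n_orphans = as.integer(n_orphans),
                 planted_groups = planted_groups,
                 group_lfc = group_lfc),
            class = "scenario_spec")
}

# Noiseless trajectory templates, % dry mass, weeks 46-54 after anthesis.
# Knot values are piecewise-linear weekly levels chosen to emulate the
# study design: QG rises near-linearly then loses `loss["QG"]` of total
# oil in the final week; M43 is biphasic (peaks at weeks 49 and 52) then
# loses `loss["M43"]` over the last two weeks (trace species 20:1d13 and
# 16:1d11 are spared so their series stay flat through the loss); HG
# rises fast to week 47 then climbs gently with no loss, with 18:2 moving
# with the pathway up to week 50 and against it afterwards.
.traj_templates <- function(loss = c(QG = 0.25, M43 = 0.30)) {
  sp <- c("16:0", "16:1d9", "16:1d11", "18:0", "18:1d9",
          "18:1d11", "18:2", "18:3", "20:0", "20:1d13")
  wk <- 46:54
  mk <- function(...) {
    m <- rbind(...)
    dimnames(m) <- list(sp, wk)
    m
  }
  qg <- mk(
    c(3.30, 3.40, 3.50, 3.58, 3.66, 3.74, 3.82, 3.90, NA),
    c(0.030, 0.030, 0.030, 0.030, 0.030, 0.030, 0.030, 0.030, NA),
    c(0.050, 0.052, 0.049, 0.051, 0.050, 0.049, 0.051, 0.050, NA),
    c(0.50, 0.56, 0.63, 0.70, 0.78, 0.88, 1.00, 1.10, NA),
    c(15.0, 20.0, 25.0, 30.0, 35.0, 40.0, 45.0, 50.0, NA),
    c(0.55, 0.55, 0.54, 0.53, 0.50, 0.46, 0.42, 0.38, NA),
    c(4.10, 4.12, 4.08, 4.11, 4.09, 4.10, 4.12, 4.10, NA),
    c(0.18, 0.20, 0.21, 0.23, 0.24, 0.26, 0.28, 0.30, NA),
    c(0.200, 0.210, 0.200, 0.205, 0.200, 0.210, 0.200, 0.205, NA),
    c(0.050, 0.056, 0.061, 0.067, 0.072, 0.080, 0.088, 0.095, NA))
  qg[, 9] <- qg[, 8] * (1 - loss[["QG"]])
  m43 <- mk(
    c(3.50, 3.60, 3.70, 3.78, 3.72, 3.82, 3.95, NA, NA),
    c(0.030, 0.030, 0.030, 0.030, 0.030, 0.030, 0.030, NA, NA),
    c(0.050, 0.052, 0.049, 0.051, 0.050, 0.049, 0.051, 0.050, 0.051),
    c(0.50, 0.56, 0.63, 0.72, 0.74, 0.88, 1.00, NA, NA),
    c(17.0, 22.0, 27.0, 32.0, 27.0, 32.0, 37.0, NA, NA),
    c(0.55, 0.55, 0.54, 0.52, 0.50, 0.45, 0.41, NA, NA),
    c(4.20, 4.22, 4.18, 4.21, 4.19, 4.20, 4.23, NA, NA),
    c(0.18, 0.20, 0.22, 0.24, 0.23, 0.26, 0.29, NA, NA),
    c(0.200, 0.210, 0.200, 0.205, 0.210, 0.200, 0.210, NA, NA),
    c(0.080, 0.082, 0.079, 0.081, 0.080, 0.082, 0.080, 0.081, 0.080))
  spared <- c("20:1d13", "16:1d11")
  scaled <- setdiff(sp, spared)
  t52 <- sum(m43[, 7])
  for (k in 8:9) {
    frac <- 1 - loss[["M43"]] * (k - 7) / 2   # 0.85 then 0.70 of week 52
    target <- frac * t52
    m43[scaled, k] <- m43[scaled, 7] *
      (target - sum(m43[spared, k])) / sum(m43[scaled, 7])
  }
  hg <- mk(
    c(3.60, 3.70, 3.55, 3.65, 3.55, 3.62, 3.50, 3.58, 3.48),
    c(0.030, 0.030, 0.030, 0.030, 0.030, 0.030, 0.030, 0.030, 0.030),
    c(0.050, 0.052, 0.049, 0.051, 0.050, 0.049, 0.051, 0.050, 0.049),
    c(0.50, 0.50, 0.50, 0.50, 0.55, 0.65, 0.77, 0.89, 1.01),
    c(20.0, 28.0, 28.8, 29.6, 27.5, 29.5, 31.9, 34.7, 37.9),
    c(0.55, 0.55, 0.54, 0.53, 0.50, 0.46, 0.42, 0.39, 0.36),
    c(4.10, 5.00, 5.07, 5.12, 5.02, 4.77, 4.37, 3.82, 3.12),
    c(0.200, 0.240, 0.250, 0.260, 0.255, 0.265, 0.275, 0.287, 0.300),
    c(0.200, 0.205, 0.200, 0.210, 0.200, 0.205, 0.200, 0.210, 0.200),
    c(0.050, 0.056, 0.061, 0.067, 0.072, 0.078, 0.084, 0.090, 0.095))
  list(QG = qg, HG = hg, M43 = m43)
}

# Proxy sign pattern and its noise reliability for one noiseless matrix.
# An interval's sign counts as reliable when the noiseless pool change
# exceeds 2.5 standard deviations of the replicate-mean difference noise
# (lognormal CV / sqrt(replicates) per weekly mean).
.proxy_truth <- function(traj, noise_cv, replicates) {
  enz <- enzymes()
  nint <- ncol(traj) - 1L
  signs <- matrix(0L, length(enz), nint,
                  dimnames = list(enz, colnames(traj)[-1]))
  reliable <- signs == 1L
  for (e in enz) {
    pool <- colSums(traj[get_pool(e), , drop = FALSE])
    d <- diff(pool)
    signs[e, ] <- sign(d)
    sd_d <- (noise_cv / sqrt(replicates)) *
      sqrt(pool[-1]^2 + pool[-length(pool)]^2)
    reliable[e, ] <- ifelse(sd_d == 0, TRUE, abs(d) >= 2.5 * sd_d)
  }
  list(sign = signs, reliable = reliable)
}

#' Generate fatty-acid time courses for the three cultivars
#'
#' Simulates the weekly sampling design (weeks 46-54 after anthesis,
#' `replicates` kernels per week, ten fatty-acid species) from the
#' noiseless cultivar templates, with multiplicative lognormal replicate
#' noise of the configured CV. The QG-like template loses exactly
#' `loss["QG"]` of its total oil in the final week; the M43-like template
#' is biphasic with peaks at weeks 49 and 52, then loses `loss["M43"]` of
#' its week-52 total over the last two weeks; the HG-like template never
#' loses oil and carries the planted post-week-50 FAD2 discordance.
#'
#' @param spec A [scenario_spec()].
#' @return List with elements
#'   \describe{
#'     \item{timecourses}{named list of [fa_timecourse()] (QG, HG, M43).}
#'     \item{truth}{per-cultivar ground truth: the noiseless
#'       species-by-week matrix (`trajectory`), the proxy sign pattern per
#'       enzyme (`proxy_sign`) with its per-interval noise-reliability
#'       flags (`sign_reliable`), and the configured loss fraction.}
#'   }
#' @export
gen_timecourse <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  templates <- .traj_templates(spec$loss)
  .with_seed(spec$seed, {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    out <- list()
    truth <- list()
    for (cv in names(templates)) {
      traj <- templates[[cv]]
      rows <- expand.grid(replicate = seq_len(spec$replicates),
                          species = rownames(traj),
                          week = as.integer(colnames(traj)),
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      base <- traj[cbind(rows$species, as.character(rows$week))]
      noise <- if (spec$noise_cv == 0) {
        rep(1, nrow(rows))
      } else {
        stats::rlnorm(nrow(rows), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      rows$content_pct <- base * noise
      out[[cv]] <- fa_timecourse(cv, rows)
      pt <- .proxy_truth(traj, spec$noise_cv, spec$replicates)
      truth[[cv]] <- list(trajectory = traj,
                          proxy_sign = pt$sign,
                          sign_reliable = pt$reliable,
                          loss = if (cv %in% names(spec$loss)) {
                            spec$loss[[cv]]
                          } else {
                            0
                          })
    }
    list(timecourses = out, truth = truth)
  })
}
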