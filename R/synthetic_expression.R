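# NB count draw on the FPKM-precursor (count) scale; dispersion 0 is the
# deterministic noise-free limit.
.nb_draw <- function(n, mu, dispersion) {
  if (dispersion == 0) return(mu)
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate paired expression data with planted candidate structure
#'
#' Simulates the two-cultivar, two-timepoint, two-replicate expression
#' design together with its cross-cultivar scaffolding: negative-binomial
#' counts converted to FPKM, a similarity-score matrix with planted
#' reciprocal best hits (plus deliberately non-reciprocal decoy genes),
#' and a gene-to-KEGG annotation table. A configurable number of homolog
#' pairs is annotated to lipid pathways; within those, the planted
#' candidates realise their group's fold-change signature (e.g. group V:
#' flat in HG, strongly up in M43) so the downstream screen can be scored
#' against stored truth. The remaining lipid pairs are non-DE; off-pathway
#' pairs include both DE and non-DE genes to exercise the pathway filter.
#'
#' @param spec A [scenario_spec()].
#' @return List with elements
#'   \describe{
#'     \item{expr_hg, expr_m43}{[expression_table()]s.}
#'     \item{scores}{similarity matrix, rows = HG genes, cols = M43
#'       genes, with planted reciprocal maxima for true pairs.}
#'     \item{annotation}{data frame `gene`, `ko`, `description` covering
#'       both cultivars' genes.}
#'     \item{truth}{data frame, one row per true homolog pair: `pair_id`,
#'       `gene_hg`, `gene_m43`, `lipid`, `group` (`"I"`..`"V"` or
#'       `"none"`), `log2fc_hg`, `log2fc_m43`.}
#'   }
#' @export
gen_expression <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  .with_seed(spec$seed + 1L, {
    n_planted <- sum(spec$planted_groups)
    n_pairs <- spec$n_lipid_pairs + spec$n_offpath_pairs
    pair_id <- sprintf("P%04d", seq_len(n_pairs))
    gene_hg <- sprintf("HG_%04d", seq_len(n_pairs))
    gene_m43 <- sprintf("M43_%04d", seq_len(n_pairs))
    group <- rep("none", n_pairs)
    group[seq_len(n_planted)] <- rep(names(spec$planted_groups),
                                     times = spec$planted_groups)
    lipid <- c(rep(TRUE, spec$n_lipid_pairs),
               rep(FALSE, spec$n_offpath_pairs))
    lfc_hg <- numeric(n_pairs)
    lfc_m43 <- numeric(n_pairs)
    for (g in names(spec$group_lfc)) {
      idx <- group == g
      lfc_hg[idx] <- spec$group_lfc[[g]][1]
      lfc_m43[idx] <- spec$group_lfc[[g]][2]
    }
    # half of the off-pathway pairs are strongly DE in M43: they must be
    # caught by the pathway filter, not the ratio cutoff
    off <- which(!lipid)
    de_off <- off[seq_len(floor(length(off) / 2))]
    lfc_m43[de_off] <- 6
    truth <- data.frame(pair_id = pair_id, gene_hg = gene_hg,
                        gene_m43 = gene_m43, lipid = lipid,
                        group = group, log2fc_hg = lfc_hg,
                        log2fc_m43 = lfc_m43, stringsAsFactors = FALSE)

    base_mu <- stats::runif(n_pairs, 300, 3000)
    len_kb <- stats::runif(n_pairs, 0.5, 3)
    reps <- spec$expr_replicates
    tp <- rep(c("early", "late"), each = reps)
    make_tbl <- function(cultivar, genes, lfc) {
      mu <- cbind(matrix(base_mu, n_pairs, reps),
                  matrix(base_mu * 2^lfc, n_pairs, reps))
      counts <- matrix(.nb_draw(length(mu), as.vector(mu),
                                spec$nb_dispersion),
                       n_pairs, 2 * reps)
      rownames(counts) <- genes
      # libraries are simulated at equal sequencing depth (1e6 mapped
      # reads), so the per-million factor is a constant
      fpkm <- counts / len_kb
      expression_table(cultivar, fpkm, tp, rep(seq_len(reps), 2))
    }
    expr_hg <- make_tbl("HG", gene_hg, lfc_hg)
    expr_m43 <- make_tbl("M43", gene_m43, lfc_m43)

    # similarity scores: low background, strong reciprocal diagonal,
    # plus orphan decoys whose best hits are not reciprocated
    orange <- spec$n_orphans
    hg_all <- c(gene_hg, sprintf("HGorph_%03d", seq_len(orange)))
    m43_all <- c(gene_m43, sprintf("M43orph_%03d", seq_len(orange)))
    scores <- matrix(stats::runif(length(hg_all) * length(m43_all), 0, 50),
                     length(hg_all), length(m43_all),
                     dimnames = list(hg_all, m43_all))
    scores[cbind(seq_len(n_pairs), seq_len(n_pairs))] <-
      stats::runif(n_pairs, 200, 500)
    # each orphan's best hit is a paired gene, below that gene's true
    # partner score (>= 200), so it can never be reciprocal
    scores[cbind(n_pairs + seq_len(orange), seq_len(orange))] <- 150
    scores[cbind(seq_len(orange), n_pairs + seq_len(orange))] <- 150

    lipid_kos <- c("ko00061", "ko00062", "ko00071", "ko00073", "ko00100",
                   "ko00561", "ko00564", "ko00565", "ko00590", "ko00591",
                   "ko00592", "ko00600", "ko01040")
    other_kos <- c("ko00195", "ko00710", "ko03010", "ko04626", "ko00940")
    pair_ko <- ifelse(lipid,
                      sample(lipid_kos, n_pairs, replace = TRUE),
                      sample(other_kos, n_pairs, replace = TRUE))
    annotation <- data.frame(
      gene = c(gene_hg, gene_m43),
      ko = c(pair_ko, pair_ko),
      description = rep("synthetic annotation", 2L * n_pairs),
      stringsAsFactors = FALSE)

    list(expr_hg = expr_hg, expr_m43 = expr_m43, scores = scores,
         annotation = annotation, truth = truth)
  })
}

#' Write every synthetic input of a scenario to TSV files
#'
#' Emits the five pipeline inputs (time-course table, two expression
#' tables merged in one file, score matrix, annotation) plus a truth
#' summary, all as plain TSV under `outdir`.
#'
#' @param spec A [scenario_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_scenario <- function(spec = scenario_spec(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tc <- gen_timecourse(spec)
  ex <- gen_expression(spec)
  paths <- c(timecourse = file.path(outdir, "fa_timecourse.tsv"),
             expression = file.path(outdir, "expression.tsv"),
             scores = file.path(outdir, "scores.tsv"),
             annotation = file.path(outdir, "annotation.tsv"),
             truth = file.path(outdir, "truth_pairs.tsv"))
  write_timecourse(tc$timecourses, paths[["timecourse"]])
  write_expression(list(ex$expr_hg, ex$expr_m43), paths[["expression"]])
  write_scores(ex$scores, paths[["scores"]])
  utils::write.table(ex$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ex$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
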