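#' Replicate expression table for one cultivar
#'
#' Gene x sample matrix of non-negative expression values (FPKM scale)
#' with an early and a late desiccation timepoint, at least two replicates
#' each.
#'
#' @param cultivar Cultivar label.
#' @param values Numeric matrix, rows = genes (rownames required), cols =
#'   samples.
#' @param timepoint Character vector per sample, `"early"` or `"late"`.
#' @param replicate Integer vector per sample.
#' @return Object of class `expression_table`.
#' @export
expression_table <- function(cultivar, values, timepoint, replicate) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            length(timepoint) == ncol(values),
            length(replicate) == ncol(values))
  if (!all(timepoint %in% c("early", "late"))) {
    stop("timepoint must be 'early' or 'late'", call. = FALSE)
  }
  if (any(values < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (any(table(timepoint) < 2L) || length(unique(timepoint)) != 2L) {
    stop("need >= 2 replicates at both timepoints", call. = FALSE)
  }
  structure(list(cultivar = as.character(cultivar),
                 values = values,
                 timepoint = timepoint,
                 replicate = as.integer(replicate)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table>", x$cultivar, "|", nrow(x$values), "genes,",
      sum(x$timepoint == "early"), "early +",
      sum(x$timepoint == "late"), "late replicates\n")
  invisible(x)
}

#' Reciprocal-best-hit homolog pairing
#'
#' Given a similarity-score matrix between two cultivars' gene sets (rows
#' = cultivar A, columns = cultivar B; higher scores more similar), returns
#' the pairs (a, b) such that b is a's best-scoring hit and a is b's best
#' hit. Genes with no positive score have no hit. Ties for the best hit are
#' broken toward the lexicographically smallest partner id and logged via
#' `message()`; a tied pair is emitted only if that tie-break choice is
#' reciprocal.
#'
#' @param scores Non-negative numeric matrix with row and column names.
#' @return Data frame with columns `gene_a`, `gene_b`, `score`, ordered by
#'   `gene_a`. Each gene appears in at most one pair. Running the function
#'   on `t(scores)` yields the same pair set with roles swapped.
#' @examples
#' m <- matrix(c(9, 1, 1, 9), 2, 2,
#'             dimnames = list(c("A1", "A2"), c("B1", "B2")))
#' rbh_pairs(m)
#' @export
rbh_pairs <- function(scores) {
  stopifnot(is.matrix(scores))
  if (length(scores) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("score matrix needs row and column names", call. = FALSE)
  }
  if (any(scores < 0)) stop("scores must be non-negative", call. = FALSE)
  best_hit <- function(v, ids) {
    mx <- max(v)
    if (mx <= 0) return(NA_character_)
    hits <- ids[v == mx]
    if (length(hits) > 1L) {
      hits <- sort(hits)
      message("tie for best hit broken toward ", hits[1])
    }
    hits[1]
  }
  best_b <- vapply(seq_len(nrow(scores)), function(i) {
    best_hit(scores[i, ], colnames(scores))
  }, character(1))
  best_a <- vapply(seq_len(ncol(scores)), function(j) {
    best_hit(scores[, j], rownames(scores))
  }, character(1))
  names(best_b) <- rownames(scores)
  names(best_a) <- colnames(scores)
  keep <- !is.na(best_b) & best_a[best_b] == names(best_b)
  keep[is.na(keep)] <- FALSE
  a <- names(best_b)[keep]
  b <- unname(best_b[keep])
  out <- data.frame(gene_a = a, gene_b = b,
                    score = scores[cbind(a, b)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), ]
  rownames(out) <- NULL
  out
}

# up / down / constant status of one gene in one cultivar
.de_status <- function(fc, p, alpha = 0.05, fc_up = 2, fc_down = 0.5) {
  ifelse(fc > fc_up & p < alpha, "up",
         ifelse(fc < fc_down & p < alpha, "down", "constant"))
}

#' Within-cultivar fold change and significance for one gene
#'
#' Late/early fold change on pseudo-count-stabilised means,
#' `fc = (mean late + pseudo) / (mean early + pseudo)`, with a two-sided
#' pooled-variance t-test on `log2(FPKM + pseudo)` supplying the
#' significance value (with two replicates per timepoint the pooled test
#' keeps its 2 degrees of freedom, where the unequal-variance correction
#' would collapse toward 1 and lose essentially all power).
#' When both timepoints have zero within-group variance the t statistic is
#' undefined; the p-value is then 0 if the group means differ and 1 if
#' they are equal, which makes the noise-free limit exact.
#'
#' @param tbl An [expression_table()].
#' @param gene Gene id (rowname of `tbl$values`).
#' @param pseudo Pseudo-count in FPKM units (default 0.1).
#' @return Named numeric vector `c(fc, p)`; `fc` is always finite and > 0.
#' @export
fold_change <- function(tbl, gene, pseudo = 0.1) {
  stopifnot(inherits(tbl, "expression_table"))
  if (!gene %in% rownames(tbl$values)) {
    stop("gene not found: ", gene, call. = FALSE)
  }
  v <- tbl$values[gene, ]
  early <- v[tbl$timepoint == "early"]
  late <- v[tbl$timepoint == "late"]
  fc <- (mean(late) + pseudo) / (mean(early) + pseudo)
  le <- log2(early + pseudo)
  ll <- log2(late + pseudo)
  if (stats::sd(le) == 0 && stats::sd(ll) == 0) {
    p <- if (isTRUE(all.equal(mean(le), mean(ll)))) 1 else 0
  } else {
    p <- stats::t.test(ll, le, var.equal = TRUE)$p.value
  }
  c(fc = unname(fc), p = unname(p))
}

#' Fold changes for every gene of an expression table
#'
#' Vectorised wrapper around the [fold_change()] computation.
#'
#' @inheritParams fold_change
#' @return Data frame with columns `gene`, `fc`, `p`.
#' @export
fold_changes <- function(tbl, pseudo = 0.1) {
  stopifnot(inherits(tbl, "expression_table"))
  early <- tbl$values[, tbl$timepoint == "early", drop = FALSE]
  late <- tbl$values[, tbl$timepoint == "late", drop = FALSE]
  fc <- (rowMeans(late) + pseudo) / (rowMeans(early) + pseudo)
  le <- log2(early + pseudo)
  ll <- log2(late + pseudo)
  p <- vapply(seq_len(nrow(tbl$values)), function(i) {
    if (stats::sd(le[i, ]) == 0 && stats::sd(ll[i, ]) == 0) {
      if (isTRUE(all.equal(mean(le[i, ]), mean(ll[i, ])))) 1 else 0
    } else {
      stats::t.test(ll[i, ], le[i, ], var.equal = TRUE)$p.value
    }
  }, numeric(1))
  data.frame(gene = rownames(tbl$values), fc = unname(fc), p = p,
             stringsAsFactors = FALSE)
}

#' Cross-cultivar ratio of within-cultivar fold changes
#'
#' The screen statistic: the M43 late/early fold change divided by the HG
#' late/early fold change of the homologous gene. When the HG fold change
#' is (machine) zero, or the M43 fold change is itself undefined/infinite
#' (gene undetected early), the ratio is the undefined sentinel,
#' represented as `Inf` and printed as `"~"` by [format_ratio()].
#'
#' @param fc_hg,fc_m43 Non-negative fold changes (vectorised).
#' @return Numeric vector; `Inf` marks the sentinel.
#' @examples
#' ratio_of_ratios(3.03, 8.20)   # 2.71 at 2 d.p.
#' ratio_of_ratios(0, 8.62)      # Inf (printed "~")
#' @export
ratio_of_ratios <- function(fc_hg, fc_m43) {
  if (any(fc_hg < 0, na.rm = TRUE) || any(fc_m43 < 0, na.rm = TRUE)) {
    stop("fold changes must be non-negative", call. = FALSE)
  }
  ifelse(!is.finite(fc_m43) | fc_hg < .Machine$double.eps,
         Inf, fc_m43 / fc_hg)
}

#' @rdname ratio_of_ratios
#' @param ratio Numeric vector from `ratio_of_ratios()`.
#' @export
format_ratio <- function(ratio) {
  ifelse(is.finite(ratio), sprintf("%.2f", ratio), "~")
}

#' Five-group classification of a homolog pair
#'
#' Per-cultivar status is `up` when fc > 2 with p < alpha, `down` when
#' fc < 0.5 with p < alpha, and `constant` otherwise -- note that a fold
#' change beyond the bounds still counts as constant when it is not
#' significant. The (HG, M43) status pair maps to: I = up/up, II =
#' down/down, III = down/up, IV = down/constant, V = constant/up; every
#' other combination is `"other"`.
#'
#' @param fc_hg,p_hg Fold change and significance value in HG.
#' @param fc_m43,p_m43 Fold change and significance value in M43.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of group labels (vectorised over inputs).
#' @examples
#' classify_group(3.03, 0.01, 8.20, 0.01)   # "I"
#' classify_group(0.37, 0.01, 2.45, 0.30)   # "IV": M43 not significant
#' @export
classify_group <- function(fc_hg, p_hg, fc_m43, p_m43, alpha = 0.05) {
  s_hg <- .de_status(fc_hg, p_hg, alpha)
  s_m43 <- .de_status(fc_m43, p_m43, alpha)
  key <- paste(s_hg, s_m43, sep = "/")
  map <- c("up/up" = "I", "down/down" = "II", "down/up" = "III",
           "down/constant" = "IV", "constant/up" = "V")
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  out
}

#' Assemble homolog-pair DEG records
#'
#' Joins fold changes from the two cultivars over an RBH pair list and a
#' gene -> KEGG ko annotation, computing the ratio-of-ratios statistic and
#' the five-group label for every pair.
#'
#' @param expr_hg,expr_m43 [expression_table()]s for HG and M43.
#' @param pairs Data frame of homolog pairs with columns `gene_hg`,
#'   `gene_m43` (e.g. [rbh_pairs()] output with columns renamed to the
#'   cultivars).
#' @param annotation Data frame with columns `gene`, `ko` (slash-separated
#'   ko ids allowed) and optionally `description`; consulted for both
#'   genes of a pair.
#' @param pseudo Pseudo-count for [fold_changes()].
#' @param alpha Significance level for the group classifier.
#' @return Data frame with one row per pair: `gene_hg`, `gene_m43`, `ko`,
#'   `description`, `fc_hg`, `p_hg`, `fc_m43`, `p_m43`, `ratio`, `group`.
#' @export
deg_records <- function(expr_hg, expr_m43, pairs, annotation,
                        pseudo = 0.1, alpha = 0.05) {
  stopifnot(all(c("gene_hg", "gene_m43") %in% names(pairs)),
            all(c("gene", "ko") %in% names(annotation)))
  fch <- fold_changes(expr_hg, pseudo)
  fcm <- fold_changes(expr_m43, pseudo)
  ih <- match(pairs$gene_hg, fch$gene)
  im <- match(pairs$gene_m43, fcm$gene)
  if (anyNA(ih) || anyNA(im)) {
    stop("pairs reference genes absent from the expression tables",
         call. = FALSE)
  }
  ann_of <- function(g) {
    kos <- annotation$ko[annotation$gene == g]
    paste(unique(unlist(strsplit(kos, "/", fixed = TRUE))), collapse = "/")
  }
  desc_of <- function(g) {
    if (!"description" %in% names(annotation)) return("")
    d <- annotation$description[annotation$gene == g]
    if (length(d)) d[1] else ""
  }
  ko <- vapply(seq_len(nrow(pairs)), function(i) {
    k <- c(ann_of(pairs$gene_hg[i]), ann_of(pairs$gene_m43[i]))
    paste(unique(unlist(strsplit(k[nzchar(k)], "/", fixed = TRUE))),
          collapse = "/")
  }, character(1))
  desc <- vapply(seq_len(nrow(pairs)), function(i) {
    d <- c(desc_of(pairs$gene_m43[i]), desc_of(pairs$gene_hg[i]))
    d <- d[nzchar(d)]
    if (length(d)) d[1] else ""
  }, character(1))
  data.frame(gene_hg = pairs$gene_hg,
             gene_m43 = pairs$gene_m43,
             ko = ko,
             description = desc,
             fc_hg = fch$fc[ih], p_hg = fch$p[ih],
             fc_m43 = fcm$fc[im], p_m43 = fcm$p[im],
             ratio = ratio_of_ratios(fch$fc[ih], fcm$fc[im]),
             group = classify_group(fch$fc[ih], fch$p[ih],
                                    fcm$fc[im], fcm$p[im], alpha),
             stringsAsFactors = FALSE)
}

#' KEGG lipid-metabolism pathway identifiers
#'
#' The ko pathway ids counted as "lipid pathway" by the candidate screen:
#' the KEGG lipid-metabolism class (fatty acid biosynthesis, elongation
#' and degradation; cutin/wax; steroid; glycerolipid, glycerophospholipid
#' and ether lipid; sphingolipid; arachidonic, linoleic and
#' alpha-linolenic acid metabolism; biosynthesis of unsaturated fatty
#' acids).
#'
#' @return Character vector of ko ids.
#' @export
lipid_pathway_kos <- function() {
  c("ko00061", "ko00062", "ko00071", "ko00072", "ko00073", "ko00100",
    "ko00120", "ko00121", "ko00140", "ko00561", "ko00564", "ko00565",
    "ko00590", "ko00591", "ko00592", "ko00600", "ko01040", "ko01004")
}

#' Cross-cultivar candidate screen
#'
#' Retains homolog-pair records whose ratio-of-ratios exceeds the cutoff
#' (the undefined-ratio sentinel is retained), that carry at least one
#' lipid-pathway annotation, and that are not expression-constant in both
#' cultivars. Sentinel ratios sort after all finite ones.
#'
#' @param records Data frame from [deg_records()] (or any table with
#'   columns `fc_hg`, `p_hg`, `fc_m43`, `p_m43`, `ko`; `ratio` and `group`
#'   are recomputed if absent).
#' @param lipid_kos Character vector of pathway ids counting as lipid
#'   pathway (default [lipid_pathway_kos()]); must be non-empty.
#' @param cutoff Ratio cutoff (default 2).
#' @param alpha Significance level for the status classification.
#' @return The retained records, with `ratio` and `group` columns, ordered
#'   by decreasing ratio (sentinels last).
#' @export
screen_candidates <- function(records, lipid_kos = lipid_pathway_kos(),
                              cutoff = 2, alpha = 0.05) {
  if (length(lipid_kos) == 0L) {
    stop("lipid pathway ko set must be non-empty", call. = FALSE)
  }
  need <- c("fc_hg", "p_hg", "fc_m43", "p_m43", "ko")
  if (!all(need %in% names(records))) {
    stop("records missing columns: ",
         paste(setdiff(need, names(records)), collapse = ", "),
         call. = FALSE)
  }
  records$ratio <- ratio_of_ratios(records$fc_hg, records$fc_m43)
  records$group <- classify_group(records$fc_hg, records$p_hg,
                                  records$fc_m43, records$p_m43, alpha)
  has_lipid <- vapply(strsplit(records$ko, "[/|]"), function(k) {
    any(k %in% lipid_kos)
  }, logical(1))
  s_hg <- .de_status(records$fc_hg, records$p_hg, alpha)
  s_m43 <- .de_status(records$fc_m43, records$p_m43, alpha)
  keep <- (records$ratio > cutoff | !is.finite(records$ratio)) &
    has_lipid & !(s_hg == "constant" & s_m43 == "constant")
  out <- records[keep, ]
  out <- out[order(is.infinite(out$ratio), -ifelse(is.finite(out$ratio),
                                                   out$ratio, 0)), ]
  rownames(out) <- NULL
  out
}

#' qRT-PCR relative quantification (2^-ddCt)
#'
#' Fold difference of a target transcript in a test sample relative to a
#' reference sample, each normalised to a housekeeping gene:
#' `2^-((Ct_target,test - Ct_hk,test) - (Ct_target,ref - Ct_hk,ref))`.
#'
#' @param ct_target_ref,ct_housekeeping_ref Ct values in the reference
#'   sample.
#' @param ct_target_test,ct_housekeeping_test Ct values in the test
#'   sample.
#' @return Fold difference (vectorised).
#' @examples
#' ddct_fold(20, 15, 19, 15)  # one cycle earlier -> 2-fold up
#' @export
ddct_fold <- function(ct_target_ref, ct_housekeeping_ref,
                      ct_target_test, ct_housekeeping_test) {
  stopifnot(all(ct_target_ref > 0), all(ct_housekeeping_ref > 0),
            all(ct_target_test > 0), all(ct_housekeeping_test > 0))
  ddct <- (ct_target_test - ct_housekeeping_test) -
    (ct_target_ref - ct_housekeeping_ref)
  2^(-ddct)
}
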