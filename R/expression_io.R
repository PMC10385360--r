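#' Read / write replicate expression tables as TSV
#'
#' Long format with header `cultivar, gene, timepoint, replicate, fpkm`.
#' A file holding a single cultivar reads back as one
#' [expression_table()], otherwise a named list.
#'
#' @param path File path.
#' @param tbl An `expression_table` or list of them.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "gene", "timepoint", "replicate", "fpkm")
  if (!all(need %in% names(df))) {
    stop("expression file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$cultivar), function(d) {
    samp <- unique(d[c("timepoint", "replicate")])
    samp <- samp[order(samp$timepoint, samp$replicate), ]
    genes <- unique(d$gene)
    m <- matrix(NA_real_, length(genes), nrow(samp),
                dimnames = list(genes, paste0(samp$timepoint, "_",
                                              samp$replicate)))
    idx <- cbind(match(d$gene, genes),
                 match(paste0(d$timepoint, "_", d$replicate),
                       colnames(m)))
    m[idx] <- d$fpkm
    if (anyNA(m)) {
      stop("expression file has missing (gene, sample) cells",
           call. = FALSE)
    }
    expression_table(d$cultivar[1], m, samp$timepoint, samp$replicate)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname read_expression
#' @export
write_expression <- function(tbl, path) {
  if (inherits(tbl, "expression_table")) tbl <- list(tbl)
  rows <- do.call(rbind, lapply(tbl, function(x) {
    data.frame(cultivar = x$cultivar,
               gene = rep(rownames(x$values), times = ncol(x$values)),
               timepoint = rep(x$timepoint, each = nrow(x$values)),
               replicate = rep(x$replicate, each = nrow(x$values)),
               fpkm = as.vector(x$values),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a similarity-score matrix as TSV
#'
#' Row names in the first column (`gene`), one column per partner-cultivar
#' gene.
#'
#' @param path File path.
#' @param scores Numeric matrix with dimnames.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_scores
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(gene = rownames(scores), scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene -> pathway annotation TSV
#'
#' Columns `gene`, `ko` (slash-separated ko ids allowed) and optional
#' `description`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "ko") %in% names(df))) {
    stop("annotation file needs columns gene, ko", call. = FALSE)
  }
  df
}

#' The 58-record candidate gene table from the M43 / HG comparison
#'
#' The curated table of lipid-pathway homolog pairs retained by the
#' cross-cultivar screen in the Camellia desiccation study: per-cultivar
#' late-vs-early fold changes, the reported M43-relative-to-HG ratio, the
#' KEGG annotation and the reported five-group label. Fold changes printed
#' as `"~"` (gene undetected at the early timepoint) are parsed as `Inf`.
#'
#' Because the table reports fold changes and group labels but not the
#' underlying p-values, the loader derives per-cultivar significance
#' flags from the reported group patterns (groups I-III: significant in
#' both cultivars; IV: significant in HG only; V: significant in M43
#' only), exposed as `sig_hg` / `sig_m43` and as nominal `p_hg` / `p_m43`
#' columns (0.01 when flagged significant, 0.5 otherwise) so the table can
#' be replayed through [classify_group()] and [screen_candidates()].
#'
#' @return Data frame with columns `gene_hg`, `gene_m43`, `ko`,
#'   `description`, `fc_hg`, `fc_m43`, `ratio_reported`,
#'   `group_reported`, `sig_hg`, `sig_m43`, `p_hg`, `p_m43`.
#' @export
candidate_table <- function() {
  path <- system.file("extdata", "candidate_degs.tsv",
                      package = "camelliaoil", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  parse_fc <- function(x) {
    out <- suppressWarnings(as.numeric(x))
    out[x == "~"] <- Inf
    out
  }
  df$fc_hg <- parse_fc(df$fc_hg)
  df$fc_m43 <- parse_fc(df$fc_m43)
  df$ratio_reported <- parse_fc(df$ratio)
  df$ratio <- NULL
  names(df)[names(df) == "group"] <- "group_reported"
  df$sig_hg <- df$group_reported %in% c("I", "II", "III", "IV")
  df$sig_m43 <- df$group_reported %in% c("I", "II", "III", "V")
  df$p_hg <- ifelse(df$sig_hg, 0.01, 0.5)
  df$p_m43 <- ifelse(df$sig_m43, 0.01, 0.5)
  df
}
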