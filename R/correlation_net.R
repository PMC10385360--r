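#' Pearson correlation edges among node series
#'
#' Workhorse behind [correlate()]: for every unordered pair of columns,
#' computes the Pearson coefficient and its two-tailed p-value from the
#' t distribution with n - 2 degrees of freedom (via [stats::cor.test()]),
#' and classifies the edge as `positive` (p < alpha, r > 0), `negative`
#' (p < alpha, r < 0) or `ns`. A constant column yields `NA` correlations
#' and `ns` edges rather than propagating NaN.
#'
#' @param mat Numeric matrix, rows = observations (weeks), named columns =
#'   nodes; needs >= 3 rows.
#' @param alpha Two-tailed significance level (default 0.05).
#' @return Data frame with columns `node_a`, `node_b`, `r`, `p`, `klass`.
#' @export
cor_edges <- function(mat, alpha = 0.05) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  if (nrow(mat) < 3L) {
    stop("correlation needs at least three observations", call. = FALSE)
  }
  nodes <- colnames(mat)
  k <- length(nodes)
  pairs <- utils::combn(k, 2)
  out <- data.frame(node_a = nodes[pairs[1, ]],
                    node_b = nodes[pairs[2, ]],
                    r = NA_real_, p = NA_real_,
                    klass = "ns",
                    stringsAsFactors = FALSE)
  for (e in seq_len(ncol(pairs))) {
    x <- mat[, pairs[1, e]]
    y <- mat[, pairs[2, e]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    out$r[e] <- unname(ct$estimate)
    out$p[e] <- ct$p.value
    if (ct$p.value < alpha) {
      out$klass[e] <- if (ct$estimate > 0) "positive" else "negative"
    }
  }
  out
}

#' Correlation network of total oil and individual fatty acids
#'
#' Builds the network among total seed-oil content and every individual
#' fatty-acid content across sampling weeks. Node series are replicate
#' means per week; `total_oil` is the per-week sum over species. Edges are
#' classified by two-tailed Pearson tests at level `alpha`; no
#' multiple-testing correction is applied by default (each edge is tested
#' marginally), matching common practice for these small descriptive
#' networks -- set `adjust = "BH"` for Benjamini-Hochberg control instead.
#'
#' @param tc An [fa_timecourse()] with >= 3 sampled weeks.
#' @param alpha Significance level (default 0.05).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Object of class `fa_cornet`: list with `cultivar`, `nodes`,
#'   `edges` (data frame as in [cor_edges()]), `alpha`, `n` (number of
#'   weeks).
#' @export
correlate <- function(tc, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(tc, "fa_timecourse"))
  m <- content_matrix(tc)
  if (nrow(m) < 3L) {
    stop("correlation network needs at least three sampled weeks",
         call. = FALSE)
  }
  mat <- cbind(total_oil = rowSums(m), m)
  edges <- cor_edges(mat, alpha = alpha)
  if (adjust != "none") {
    message("adjusting edge p-values with method '", adjust, "'")
    edges$p <- stats::p.adjust(edges$p, method = adjust)
    edges$klass <- ifelse(is.na(edges$r) | edges$p >= alpha, "ns",
                          ifelse(edges$r > 0, "positive", "negative"))
  }
  structure(list(cultivar = tc$cultivar,
                 nodes = colnames(mat),
                 edges = edges,
                 alpha = alpha,
                 n = nrow(mat)),
            class = "fa_cornet")
}

#' @export
print.fa_cornet <- function(x, ...) {
  tab <- table(factor(x$edges$klass,
                      levels = c("positive", "negative", "ns")))
  cat("<fa_cornet>", x$cultivar, "|", length(x$nodes), "nodes,",
      nrow(x$edges), "edges over", x$n, "weeks (alpha =", x$alpha, ")\n")
  cat("  positive:", tab[["positive"]],
      " negative:", tab[["negative"]],
      " ns:", tab[["ns"]], "\n")
  invisible(x)
}

#' @export
plot.fa_cornet <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting the network requires the igraph package", call. = FALSE)
  }
  sig <- x$edges[x$edges$klass != "ns", ]
  g <- igraph::graph_from_data_frame(
    sig[c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = x$nodes))
  igraph::E(g)$color <- ifelse(sig$klass == "positive", "red3", "black")
  igraph::plot.igraph(g, vertex.color = "grey90", vertex.size = 28,
                      vertex.label.cex = 0.8, main = x$cultivar, ...)
  invisible(x)
}

#' Edge-class differences between two correlation networks
#'
#' Lists edges whose significance class differs between two cultivars'
#' networks, e.g. a 20:1 / total-oil correlation present in one germplasm
#' but absent in another.
#'
#' @param netA,netB `fa_cornet` objects over the same node set.
#' @return Data frame with columns `node_a`, `node_b`, `klass_a`,
#'   `klass_b`; zero rows when the networks agree.
#' @export
compare_networks <- function(netA, netB) {
  stopifnot(inherits(netA, "fa_cornet"), inherits(netB, "fa_cornet"))
  if (!setequal(netA$nodes, netB$nodes)) {
    stop("networks have different node sets", call. = FALSE)
  }
  key <- function(e) paste(pmin(e$node_a, e$node_b),
                           pmax(e$node_a, e$node_b))
  ea <- netA$edges
  eb <- netB$edges
  idx <- match(key(ea), key(eb))
  out <- data.frame(node_a = ea$node_a,
                    node_b = ea$node_b,
                    klass_a = ea$klass,
                    klass_b = eb$klass[idx],
                    stringsAsFactors = FALSE)
  out <- out[out$klass_a != out$klass_b, ]
  rownames(out) <- NULL
  out
}

#' Write a correlation network edge list as TSV
#'
#' @param net An `fa_cornet`.
#' @param path File path.
#' @export
write_cornet <- function(net, path) {
  stopifnot(inherits(net, "fa_cornet"))
  utils::write.table(cbind(cultivar = net$cultivar, net$edges), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
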