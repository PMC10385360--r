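#' Pathway-pool content at one sampling week
#'
#' Sums the replicate-mean contents of an enzyme's downstream product pool
#' (see [get_pool()]) at a given week. Species absent from the time course
#' are treated as zero content, with a warning.
#'
#' @param tc An [fa_timecourse()].
#' @param enzyme Enzyme name, see [enzymes()].
#' @param week Sampled week after anthesis.
#' @return Pool content, % of kernel dry mass.
#' @examples
#' # FAD3's pool is {18:3}, so its pool content is the mean 18:3 content
#' @export
pool_content <- function(tc, enzyme, week) {
  stopifnot(inherits(tc, "fa_timecourse"))
  pool <- get_pool(enzyme)
  if (!week %in% tc$data$week) {
    stop("week ", week, " not sampled in this time course", call. = FALSE)
  }
  present <- intersect(pool, unique(tc$data$species))
  missing <- setdiff(pool, present)
  if (length(missing)) {
    warning("pool species missing from time course, treated as zero: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!length(present)) return(0)
  d <- tc$data[tc$data$week == week & tc$data$species %in% present, ]
  # mean over replicates of the per-replicate pool sum
  sums <- tapply(d$content_pct, d$replicate, sum)
  mean(sums)
}

#' Weekly enzyme-activity proxy series
#'
#' The relative in-planta activity proxy for a pathway enzyme: the change
#' of its downstream product-pool content between consecutive sampled
#' weeks, in % dry mass per week. When sampling gaps exceed one week the
#' raw difference is divided by the gap so a missed week does not inflate
#' apparent activity.
#'
#' @param tc An [fa_timecourse()] with at least two sampled weeks.
#' @param enzyme Enzyme name.
#' @return Object of class `enzyme_proxy`: list with `cultivar`, `enzyme`,
#'   `weeks` (interval end labels: the entry for week t is the change from
#'   the previous sample to t), `delta` (% dry mass per week), `gap`
#'   (weeks spanned) and `raw_delta` (`delta * gap`). The raw deltas
#'   telescope: their sum equals pool content at the last week minus pool
#'   content at the first.
#' @export
proxy_series <- function(tc, enzyme) {
  stopifnot(inherits(tc, "fa_timecourse"))
  wk <- tc_weeks(tc)
  if (length(wk) < 2L) {
    stop("proxy series needs at least two sampled weeks", call. = FALSE)
  }
  pc <- vapply(wk, function(w) {
    suppressWarnings(pool_content(tc, enzyme, w))
  }, numeric(1))
  missing <- setdiff(get_pool(enzyme), unique(tc$data$species))
  if (length(missing)) {
    warning("pool species missing from time course, treated as zero: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- diff(pc)
  gap <- diff(wk)
  structure(list(cultivar = tc$cultivar,
                 enzyme = enzyme,
                 weeks = wk[-1],
                 delta = raw / gap,
                 gap = gap,
                 raw_delta = raw),
            class = "enzyme_proxy")
}

#' @export
print.enzyme_proxy <- function(x, ...) {
  cat("<enzyme_proxy>", x$cultivar, x$enzyme, "\n")
  print(data.frame(week = x$weeks,
                   delta_pct_per_week = round(x$delta, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Synchrony of enzyme-activity fluctuations
#'
#' Pairwise Pearson correlations among proxy delta series, summarising how
#' concerted the weekly activity fluctuations of the pathway enzymes are.
#' A series with zero variance over the chosen window (typically FAD3 when
#' 18:3 is flat) has undefined correlations; its pairs are recorded as
#' missing and excluded from the mean.
#'
#' @param series List of [proxy_series()] objects over the same weeks.
#' @param window Optional length-2 numeric `c(from, to)`: restrict to
#'   intervals whose end week lies in `[from, to]`.
#' @return Object of class `synchrony_report`: list with `cultivar`, `r`
#'   (symmetric matrix, unit diagonal, `NA` for undefined pairs),
#'   `mean_r` (mean of defined off-diagonal upper-triangle entries) and
#'   `window`.
#' @export
synchrony <- function(series, window = NULL) {
  if (length(series) < 2L) {
    stop("synchrony needs at least two proxy series", call. = FALSE)
  }
  stopifnot(all(vapply(series, inherits, logical(1), "enzyme_proxy")))
  wk <- series[[1]]$weeks
  for (s in series) {
    if (!identical(s$weeks, wk)) {
      stop("proxy series cover different weeks", call. = FALSE)
    }
  }
  keep <- rep(TRUE, length(wk))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- wk >= window[1] & wk <= window[2]
    if (sum(keep) < 2L) {
      stop("window leaves fewer than two intervals", call. = FALSE)
    }
  }
  nm <- vapply(series, function(s) s$enzyme, character(1))
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  d <- vapply(series, function(s) s$delta[keep], numeric(sum(keep)))
  colnames(d) <- nm
  k <- ncol(d)
  r <- diag(1, k)
  dimnames(r) <- list(nm, nm)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (stats::sd(d[, i]) == 0 || stats::sd(d[, j]) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
      } else {
        r[i, j] <- r[j, i] <- stats::cor(d[, i], d[, j])
      }
    }
  }
  ut <- r[upper.tri(r)]
  structure(list(cultivar = series[[1]]$cultivar,
                 r = r,
                 mean_r = mean(ut[!is.na(ut)]),
                 window = window),
            class = "synchrony_report")
}

#' @export
print.synchrony_report <- function(x, ...) {
  cat("<synchrony_report>", x$cultivar)
  if (!is.null(x$window)) cat(" | weeks", x$window[1], "-", x$window[2])
  cat(sprintf(" | mean pairwise r = %.3f\n", x$mean_r))
  print(round(x$r, 3))
  invisible(x)
}
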