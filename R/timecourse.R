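#' Fatty-acid content time course for one cultivar
#'
#' Long-format container: one row per (week, replicate, species) with the
#' content in % of kernel dry mass. Weeks are weeks after anthesis and must
#' be strictly increasing across the sampling design; every (week,
#' replicate) cell carries the same species set.
#'
#' @param cultivar Cultivar label (e.g. "QG", "HG", "M43").
#' @param data Data frame with columns `week` (integer), `replicate`
#'   (integer), `species`, `content_pct`.
#' @return Object of class `fa_timecourse`.
#' @export
fa_timecourse <- function(cultivar, data) {
  need <- c("week", "replicate", "species", "content_pct")
  if (!all(need %in% names(data))) {
    stop("time-course data must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  data <- data[need]
  data$week <- as.integer(data$week)
  data$replicate <- as.integer(data$replicate)
  data$species <- normalize_fa_name(as.character(data$species))
  data$content_pct <- as.numeric(data$content_pct)
  key <- paste(data$week, data$replicate, data$species)
  if (anyDuplicated(key)) {
    stop("duplicate (week, replicate, species) keys in time course",
         call. = FALSE)
  }
  sp_sets <- tapply(data$species, paste(data$week, data$replicate),
                    function(s) paste(sort(s), collapse = "|"))
  if (length(unique(sp_sets)) != 1L) {
    stop("every (week, replicate) cell must cover the same species set",
         call. = FALSE)
  }
  data <- data[order(data$week, data$replicate, data$species), ]
  rownames(data) <- NULL
  structure(list(cultivar = as.character(cultivar), data = data),
            class = "fa_timecourse")
}

#' @export
print.fa_timecourse <- function(x, ...) {
  wk <- sort(unique(x$data$week))
  cat("<fa_timecourse>", x$cultivar, "|", length(wk), "weeks (",
      min(wk), "-", max(wk), "),",
      length(unique(x$data$replicate)), "replicates,",
      length(unique(x$data$species)), "species\n")
  invisible(x)
}

#' @export
as.data.frame.fa_timecourse <- function(x, ...) x$data

#' Sampled weeks of a time course
#' @param tc An `fa_timecourse`.
#' @return Increasing integer vector of weeks after anthesis.
#' @export
tc_weeks <- function(tc) sort(unique(tc$data$week))

#' Replicate-mean content matrix
#'
#' Averages replicates to one value per (week, species).
#'
#' @param tc An `fa_timecourse`.
#' @return Numeric matrix, rows = weeks (rownames), cols = species.
#' @export
content_matrix <- function(tc) {
  stopifnot(inherits(tc, "fa_timecourse"))
  agg <- stats::aggregate(content_pct ~ week + species, data = tc$data,
                          FUN = mean)
  wk <- sort(unique(agg$week))
  sp <- sort(unique(agg$species))
  m <- matrix(NA_real_, length(wk), length(sp),
              dimnames = list(wk, sp))
  m[cbind(match(agg$week, wk), match(agg$species, sp))] <- agg$content_pct
  m
}

#' Replicate mean and standard deviation per week and species
#'
#' Summarises the n = 3 replicate design as mean +/- SD (n - 1
#' denominator).
#'
#' @param tc An `fa_timecourse`.
#' @return Data frame with columns `week`, `species`, `mean`, `sd`, `n`.
#' @export
aggregate_replicates <- function(tc) {
  stopifnot(inherits(tc, "fa_timecourse"))
  sp <- split(tc$data, list(tc$data$week, tc$data$species), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(week = d$week[1], species = d$species[1],
               mean = mean(d$content_pct),
               sd = stats::sd(d$content_pct),
               n = nrow(d))
  }))
  out <- out[order(out$week, out$species), ]
  rownames(out) <- NULL
  out
}

#' Profile of one (week, replicate) cell
#'
#' @param tc An `fa_timecourse`.
#' @param week Week after anthesis.
#' @param replicate Replicate index.
#' @return An [fa_profile()].
#' @export
tc_profile <- function(tc, week, replicate) {
  d <- tc$data[tc$data$week == week & tc$data$replicate == replicate, ]
  if (nrow(d) == 0L) {
    stop("no sample for week ", week, " replicate ", replicate,
         call. = FALSE)
  }
  fa_profile(paste0(tc$cultivar, "_w", week, "_r", replicate),
             stats::setNames(d$content_pct, d$species))
}

#' Read / write fatty-acid time courses as TSV
#'
#' Long-format TSV with header `cultivar, week, replicate, species,
#' content_pct` (tab-separated, UTF-8). `read_timecourse()` returns a
#' single `fa_timecourse` when the file holds one cultivar, otherwise a
#' named list of them. Writing then reading reproduces the object up to
#' numeric formatting.
#'
#' @param path File path.
#' @param tc An `fa_timecourse` or list of them.
#' @return See Details.
#' @export
read_timecourse <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "week", "replicate", "species", "content_pct")
  if (!all(need %in% names(df))) {
    stop("time-course file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$cultivar), function(d) {
    fa_timecourse(d$cultivar[1], d[c("week", "replicate", "species",
                                     "content_pct")])
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(tc, path) {
  if (inherits(tc, "fa_timecourse")) tc <- list(tc)
  rows <- do.call(rbind, lapply(tc, function(x) {
    cbind(cultivar = x$cultivar, x$data)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a single fatty-acid profile as TSV
#'
#' Columns: `sample_id, species, content_pct, mol_pct` plus a `total_oil`
#' attribute row is not used -- total oil is recoverable as the content
#' sum.
#'
#' @param profile An `fa_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fa_profile"))
  df <- data.frame(sample_id = profile$sample_id,
                   species = names(profile$content),
                   content_pct = unname(profile$content),
                   mol_pct = unname(profile$mol_pct))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
plot.fa_timecourse <- function(x, species = NULL, ...) {
  m <- content_matrix(x)
  if (!is.null(species)) m <- m[, normalize_fa_name(species), drop = FALSE]
  wk <- as.integer(rownames(m))
  graphics::matplot(wk, m, type = "b", pch = 16, lty = 1,
                    xlab = "week after anthesis",
                    ylab = "content (% dry mass)",
                    main = x$cultivar, ...)
  graphics::legend("topleft", legend = colnames(m), col = seq_len(ncol(m)),
                   lty = 1, pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
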