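#' Build a GC-FID peak table
#'
#' Container for one sample's FID peak areas together with the quantities
#' needed for internal-standard quantification: the dry kernel mass, the
#' mass of the margaric-acid (17:0) internal standard spiked in before
#' methylation, and the internal standard's own peak area.
#'
#' @param sample_id Sample label.
#' @param kernel_mass_mg Dry kernel powder mass, mg (> 0).
#' @param is_area FID peak area of the internal-standard FAME (> 0).
#' @param peaks Named numeric vector, species label -> FID peak area
#'   (areas >= 0; names go through [normalize_fa_name()]).
#' @param is_mass_ug Internal-standard mass, micrograms (default 75).
#' @return An object of class `peak_table`.
#' @examples
#' pt <- peak_table("wk46_r1", kernel_mass_mg = 10, is_area = 1e5,
#'                  peaks = c("18:1d9" = 3e5, "16:0" = 4e4))
#' @export
peak_table <- function(sample_id, kernel_mass_mg, is_area, peaks,
                       is_mass_ug = 75) {
  stopifnot(is.numeric(kernel_mass_mg), length(kernel_mass_mg) == 1L,
            is.numeric(is_area), length(is_area) == 1L,
            is.numeric(is_mass_ug), length(is_mass_ug) == 1L)
  if (kernel_mass_mg <= 0) stop("kernel_mass_mg must be > 0", call. = FALSE)
  if (is_area <= 0) stop("internal-standard area must be > 0", call. = FALSE)
  if (length(peaks)) {
    if (is.null(names(peaks)) || any(!nzchar(names(peaks)))) {
      stop("peaks must be a named vector of species areas", call. = FALSE)
    }
    names(peaks) <- normalize_fa_name(names(peaks))
    if (anyDuplicated(names(peaks))) {
      stop("duplicate species in peak table", call. = FALSE)
    }
    if (any(peaks < 0)) stop("peak areas must be >= 0", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 kernel_mass_mg = kernel_mass_mg,
                 is_mass_ug = is_mass_ug,
                 is_area = is_area,
                 peaks = peaks),
            class = "peak_table")
}

#' Internal-standard quantification of a GC-FID peak table
#'
#' Converts FID peak areas into per-species fatty-acid contents by
#' normalising each area to the internal-standard area:
#' `mass_i = is_mass_ug * (area_i / is_area) * rf_i`, then expressing the
#' mass as a percentage of kernel dry mass. Total oil content is the sum
#' over species, and the content vector is additionally converted to mole
#' percent using the registry molecular weights.
#'
#' @param peaks A [peak_table()].
#' @param response_factors Optional named numeric vector of per-species FID
#'   response factors (default 1 for every species: areas are normalised to
#'   the internal standard directly).
#' @param fame_to_fa Mass correction factor applied uniformly (default 1;
#'   contents are reported on the measured FAME-equivalent mass basis).
#' @param mw Optional named numeric vector of molecular weights (g/mol)
#'   overriding the registry free-fatty-acid weights for the mole-percent
#'   conversion.
#' @return An object of class `fa_profile`: list with `sample_id`,
#'   `content` (named, % dry mass), `total_oil` (% dry mass) and `mol_pct`
#'   (named, sums to 100).
#' @examples
#' pt <- peak_table("s1", kernel_mass_mg = 10, is_area = 1e5,
#'                  peaks = c("18:1d9" = 1e5))
#' quantify(pt)$content  # 75 ug in 10 mg kernel = 0.75 % dry mass
#' @export
quantify <- function(peaks, response_factors = NULL, fame_to_fa = 1,
                     mw = NULL) {
  stopifnot(inherits(peaks, "peak_table"))
  pk <- peaks$peaks
  if (length(pk) == 0L) {
    warning("empty peak table: total oil 0, mole percent undefined",
            call. = FALSE)
    return(structure(list(sample_id = peaks$sample_id,
                          content = numeric(0),
                          total_oil = 0,
                          mol_pct = numeric(0)),
                     class = "fa_profile"))
  }
  sp <- names(pk)
  rf <- rep(1, length(sp))
  names(rf) <- sp
  if (!is.null(response_factors)) {
    names(response_factors) <- normalize_fa_name(names(response_factors))
    if (any(response_factors <= 0)) {
      stop("response factors must be positive", call. = FALSE)
    }
    rf[intersect(sp, names(response_factors))] <-
      response_factors[intersect(sp, names(response_factors))]
  }
  mass_ug <- peaks$is_mass_ug * (pk / peaks$is_area) * rf * fame_to_fa
  content <- mass_ug / (peaks$kernel_mass_mg * 1000) * 100
  mws <- .fa_registry_df$mw[match(sp, .fa_registry_df$name)]
  if (!is.null(mw)) {
    names(mw) <- normalize_fa_name(names(mw))
    idx <- match(sp, names(mw))
    mws[!is.na(idx)] <- mw[idx[!is.na(idx)]]
  }
  mol <- content / mws
  mol_pct <- if (sum(mol) > 0) mol / sum(mol) * 100 else mol * 0
  structure(list(sample_id = peaks$sample_id,
                 content = content,
                 total_oil = sum(content),
                 mol_pct = mol_pct),
            class = "fa_profile")
}

#' Construct an fa_profile directly from contents
#'
#' Convenience constructor used when contents (% dry mass) are already
#' known, e.g. from a time-course table; computes total oil and mole
#' percent the same way as [quantify()].
#'
#' @param sample_id Sample label.
#' @param content Named numeric vector of contents, % dry mass.
#' @return An `fa_profile`.
#' @export
fa_profile <- function(sample_id, content) {
  sp <- normalize_fa_name(names(content))
  names(content) <- sp
  if (any(content < 0)) stop("contents must be >= 0", call. = FALSE)
  mws <- .fa_registry_df$mw[match(sp, .fa_registry_df$name)]
  mol <- content / mws
  mol_pct <- if (sum(mol) > 0) mol / sum(mol) * 100 else mol * 0
  structure(list(sample_id = as.character(sample_id),
                 content = content,
                 total_oil = sum(content),
                 mol_pct = mol_pct),
            class = "fa_profile")
}

#' @export
print.fa_profile <- function(x, ...) {
  cat("<fa_profile> sample", x$sample_id,
      sprintf("| total oil %.3f %% dry mass\n", x$total_oil))
  if (length(x$content)) {
    df <- data.frame(species = names(x$content),
                     content_pct = round(unname(x$content), 4),
                     mol_pct = round(unname(x$mol_pct), 3))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Composition ratios of a fatty-acid profile
#'
#' The three descriptors of seed-oil composition, computed on the
#' mole-percent basis: unsaturated-to-saturated (USFA/SFA),
#' mono-to-polyunsaturated (MUFA/PUFA), and 18-carbon to 16-carbon
#' (18C/16C; 20C species belong to neither class).
#'
#' @param profile An `fa_profile`.
#' @return Named numeric vector `c(usfa_sfa, mufa_pufa, c18_c16)`. A zero
#'   denominator class yields `Inf` with a warning.
#' @export
composition_ratios <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  mp <- profile$mol_pct
  reg <- .fa_registry_df[match(names(mp), .fa_registry_df$name), ]
  cls_sum <- function(keep) sum(mp[keep])
  sfa  <- cls_sum(reg$sat_class == "SFA")
  usfa <- cls_sum(reg$sat_class != "SFA")
  mufa <- cls_sum(reg$sat_class == "MUFA")
  pufa <- cls_sum(reg$sat_class == "PUFA")
  c16  <- cls_sum(reg$carbons == 16L)
  c18  <- cls_sum(reg$carbons == 18L)
  rat <- function(num, den, lab) {
    if (den == 0) {
      warning("zero ", lab, " denominator: ratio reported as Inf",
              call. = FALSE)
      return(Inf)
    }
    num / den
  }
  c(usfa_sfa = rat(usfa, sfa, "SFA"),
    mufa_pufa = rat(mufa, pufa, "PUFA"),
    c18_c16 = rat(c18, c16, "16C"))
}
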