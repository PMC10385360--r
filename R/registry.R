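#' @title Fatty-acid species registry
#' @description The ten fatty-acid species detected in Camellia seed oil,
#'   with chemical metadata used throughout the pipeline: chain length,
#'   double-bond count and positions, free fatty-acid molecular weight,
#'   saturation class and biosynthetic route.
#'
#' @details Saturation classes follow the usual convention: SFA for zero
#'   double bonds, MUFA for one, PUFA for two or more. The `route` column
#'   records where a species enters triacylglycerol synthesis: plastidial
#'   KASII-derived acyl chains (`KASII_POOL`), the ER elongase branch
#'   (`FAE_POOL`, the omega-7 series plus its 16C precursors), or direct
#'   FatB thioesterase export (`FATB_PRODUCT`, 16:0). Molecular weights are
#'   those of the free fatty acids (mole-percent composition is computed on
#'   that basis by default; pass custom weights to [quantify()] to use a
#'   FAME basis instead).
#'
#' @return A data frame with one row per species and columns `name`,
#'   `carbons`, `double_bonds`, `db_positions` (comma-separated string),
#'   `mw`, `sat_class`, `route`.
#' @examples
#' fa_registry()
#' @export
fa_registry <- function() {
  .fa_registry_df
}

.fa_registry_df <- data.frame(
  name         = c("16:0", "16:1d9", "16:1d11", "18:0", "18:1d9",
                   "18:1d11", "18:2", "18:3", "20:0", "20:1d13"),
  carbons      = c(16L, 16L, 16L, 18L, 18L, 18L, 18L, 18L, 20L, 20L),
  double_bonds = c(0L, 1L, 1L, 0L, 1L, 1L, 2L, 3L, 0L, 1L),
  db_positions = c("", "9", "11", "", "9", "11", "9,12", "9,12,15", "", "13"),
  mw           = c(256.43, 254.41, 254.41, 284.48, 282.47,
                   282.47, 280.45, 278.44, 312.54, 310.52),
  sat_class    = c("SFA", "MUFA", "MUFA", "SFA", "MUFA",
                   "MUFA", "PUFA", "PUFA", "SFA", "MUFA"),
  route        = c("FATB_PRODUCT", "FAE_POOL", "FAE_POOL", "KASII_POOL",
                   "KASII_POOL", "FAE_POOL", "KASII_POOL", "KASII_POOL",
                   "KASII_POOL", "FAE_POOL"),
  stringsAsFactors = FALSE
)

# Enzyme -> downstream product pool. Each pool is the set of species whose
# summed content change week-over-week proxies that enzyme's activity.
# All 18C/20C species except the FAE products run through KASII; the
# desaturation chain gives the strict nesting FAD3 < FAD2 < SAD < KASII.
.enzyme_pools <- list(
  KASII = c("18:0", "18:1d9", "18:2", "18:3", "20:0"),
  FatB  = c("16:0"),
  SAD   = c("18:1d9", "18:2", "18:3"),
  FAD2  = c("18:2", "18:3"),
  FAD3  = c("18:3"),
  FAE   = c("18:1d11", "20:1d13")
)

#' Registered enzyme names
#'
#' @return Character vector of the six enzymes with a defined product pool:
#'   KASII, FatB, SAD, FAD2, FAD3, FAE.
#' @export
enzymes <- function() names(.enzyme_pools)

#' Product pool of a pathway enzyme
#'
#' Returns the set of fatty-acid species whose summed content is taken as
#' the downstream product pool of `enzyme`; the week-over-week change of
#' this pool is the relative activity proxy used by [proxy_series()].
#'
#' @param enzyme One of `"KASII"`, `"FatB"`, `"SAD"`, `"FAD2"`, `"FAD3"`,
#'   `"FAE"`.
#' @return Character vector of canonical species names.
#' @examples
#' get_pool("KASII")
#' get_pool("FAD3")
#' @export
get_pool <- function(enzyme) {
  if (length(enzyme) != 1L || !enzyme %in% names(.enzyme_pools)) {
    stop("unknown enzyme: ", paste(enzyme, collapse = ", "),
         " (expected one of ", paste(names(.enzyme_pools), collapse = ", "),
         ")", call. = FALSE)
  }
  .enzyme_pools[[enzyme]]
}

# Synonym map: common labelling variants -> canonical registry names.
# Covers superscript-delta forms, 'C'-prefixed forms, omega (n-) notation
# and the unqualified 16:1 / 18:1 / 20:1 shorthand used in figure axes.
.fa_synonyms <- c(
  "16:1"        = "16:1d9",
  "18:1"        = "18:1d9",
  "20:1"        = "20:1d13",
  "16:1n-7"     = "16:1d9",
  "18:1n-9"     = "18:1d9",
  "18:1n-7"     = "18:1d11",
  "20:1n-7"     = "20:1d13",
  "18:2n-6"     = "18:2",
  "18:3n-3"     = "18:3",
  "18:2d9,12"   = "18:2",
  "18:3d9,12,15" = "18:3"
)

#' Normalize a fatty-acid label to its canonical registry name
#'
#' Accepts the canonical `"18:1d9"` style plus common variants: a leading
#' `"C"` (`"C18:1n-9"`), unicode delta (`"18:1Δ9"`), caret-delta
#' (`"18:1^d9"`), omega notation (`"18:1n-9"`), and the unqualified
#' `"16:1"`/`"18:1"`/`"20:1"` shorthand (mapped to the dominant isomer:
#' d9, d9 and d13 respectively).
#'
#' @param x Character vector of labels.
#' @return Character vector of canonical names.
#' @examples
#' normalize_fa_name(c("C18:1n-9", "18:1Δ9", "20:1"))
#' @export
normalize_fa_name <- function(x) {
  stopifnot(is.character(x))
  y <- trimws(x)
  y <- sub("^[Cc](?=[0-9])", "", y, perl = TRUE)
  y <- gsub("Δ", "d", y)           # unicode capital delta
  y <- gsub("δ", "d", y)           # lowercase delta
  y <- gsub("\\^", "", y)               # markup carets around delta
  y <- gsub("[Dd](?=[0-9])", "d", y, perl = TRUE)
  out <- ifelse(y %in% .fa_registry_df$name, y,
                unname(.fa_synonyms[y]))
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown fatty-acid species: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Classify a fatty-acid species by saturation and chain length
#'
#' @param name Species label (any form accepted by [normalize_fa_name()]).
#' @return Named character vector with elements `sat_class` (SFA, MUFA or
#'   PUFA) and `chain_class` (C16, C18 or C20).
#' @examples
#' classify_species("16:0")   # SFA, C16
#' classify_species("18:2")   # PUFA, C18
#' @export
classify_species <- function(name) {
  nm <- normalize_fa_name(name)
  row <- .fa_registry_df[match(nm, .fa_registry_df$name), ]
  c(sat_class = row$sat_class,
    chain_class = paste0("C", row$carbons))
}

#' Read / write a species-registry TSV
#'
#' The registry serialises to a plain TSV with columns `name`, `carbons`,
#' `double_bonds`, `db_positions`, `mw`, `sat_class`, `route`. Reading
#' validates the saturation-class/double-bond consistency rule.
#'
#' @param path File path.
#' @param registry Data frame in the layout of [fa_registry()].
#' @return `read_registry()` returns the registry data frame;
#'   `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(db_positions = "character"))
  need <- c("name", "carbons", "double_bonds", "db_positions",
            "mw", "sat_class", "route")
  if (!all(need %in% names(reg))) {
    stop("registry file missing columns: ",
         paste(setdiff(need, names(reg)), collapse = ", "), call. = FALSE)
  }
  expect_class <- ifelse(reg$double_bonds == 0L, "SFA",
                         ifelse(reg$double_bonds == 1L, "MUFA", "PUFA"))
  if (!all(reg$sat_class == expect_class)) {
    stop("registry saturation classes inconsistent with double-bond counts",
         call. = FALSE)
  }
  reg[need]
}

#' @rdname read_registry
#' @export
write_registry <- function(registry = fa_registry(), path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
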