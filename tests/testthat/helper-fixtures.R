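# Shared builders and independent oracles for the test suite.

# brute-force Pearson r via the explicit sum formula
bf_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# brute-force two-tailed p from the t distribution with n - 2 df
bf_pearson_p <- function(x, y) {
  n <- length(x)
  r <- bf_pearson(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# minimal single-cultivar time course from a species x week matrix of
# replicate-mean contents; each replicate gets the same values unless a
# jitter function is supplied
make_tc <- function(mat, cultivar = "TC", replicates = 1,
                    jitter = function(v) v) {
  rows <- expand.grid(replicate = seq_len(replicates),
                      species = rownames(mat),
                      week = as.integer(colnames(mat)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$content_pct <- jitter(mat[cbind(rows$species,
                                       as.character(rows$week))])
  fa_timecourse(cultivar, rows)
}

# random valid time course over all ten registered species
make_random_tc <- function(weeks = 46:51, replicates = 2) {
  sp <- fa_registry()$name
  m <- matrix(stats::runif(length(sp) * length(weeks), 0.1, 30),
              length(sp), length(weeks), dimnames = list(sp, weeks))
  make_tc(m, replicates = replicates,
          jitter = function(v) v * stats::rlnorm(length(v), 0, 0.02))
}
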