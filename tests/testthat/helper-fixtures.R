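# Shared fixture builders: everything is generated in code at test time.

# tiny genotype matrix from a call matrix (samples x sites)
make_gm <- function(calls, chrom = "chr1", pos = NULL, samples = NULL) {
  calls <- as.matrix(calls)
  p <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(p) * 1000L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(calls)))
  genotype_matrix(calls,
                  data.frame(chrom = rep_len(chrom, p), pos = pos,
                             ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  samples)
}

# random genotype matrix with HWE sites and optional missingness
random_gm <- function(n, p, seed, miss_rate = 0, af = NULL) {
  set.seed(seed)
  if (is.null(af)) af <- stats::runif(p, 0.05, 0.95)
  calls <- matrix(stats::rbinom(n * p, 2L, rep(af, each = n)), n, p)
  if (miss_rate > 0)
    calls[stats::runif(n * p) < miss_rate] <- NA_integer_
  make_gm(calls)
}

# 1-based inclusive interval Jaccard
interval_jaccard <- function(a, b) {
  i <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  i / ((a[2] - a[1] + 1) + (b[2] - b[1] + 1) - i)
}

# minimal sample-table row builder
sample_row <- function(id, sire = "0", dam = "0", breed = "ACS",
                       cohort = "model_pedigree", sry = "negative",
                       phenotype = "unknown", gonad = "none_recorded") {
  data.frame(sample_id = id, sire = sire, dam = dam, breed = breed,
             cohort = cohort, sry = sry, phenotype = phenotype,
             gonad = gonad, stringsAsFactors = FALSE)
}
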