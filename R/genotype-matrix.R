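#' Genotype matrix of biallelic calls
#'
#' The central container of the package: an integer matrix of genotype calls
#' (rows = samples, columns = sites) coded as allele dosage of the alternate
#' allele -- `0` hom-ref, `1` het, `2` hom-alt, `NA` missing -- together with
#' a site table and a sample id vector. All genomic coordinates are 1-based
#' inclusive, matching VCF and the intervals printed in genome browsers.
#'
#' @param calls integer matrix, samples x sites, values in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `vtype` (`"snp"`/`"indel"`, inferred from allele
#'   lengths when absent).
#' @param samples character vector of sample ids, one per row of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.character(samples)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(
    nrow(calls) == length(samples),
    ncol(calls) == nrow(sites),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites))
  )
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (any(sites$pos < 1L)) stop("site positions are 1-based; pos must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  if (is.null(sites$vtype)) {
    sites$vtype <- ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L,
                          "snp", "indel")
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  rownames(calls) <- samples
  colnames(calls) <- if (nrow(sites)) paste0(sites$chrom, ":", sites$pos)
  structure(list(calls = calls, sites = sites, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%d chromosome%s)\n",
              n_samples(x), n_sites(x),
              length(unique(x$sites$chrom)),
              if (length(unique(x$sites$chrom)) == 1L) "" else "s"))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname genotype_matrix
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a genotype matrix by site and/or sample
#'
#' @param x a `genotype_matrix`.
#' @param sites integer or logical index into the site table.
#' @param samples character ids, or integer/logical index into the samples.
#' @return A `genotype_matrix` restricted to the selection; site order is
#'   preserved.
#' @export
subset_genotypes <- function(x, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(x)) else sites
  if (is.null(samples)) {
    sj <- seq_len(n_samples(x))
  } else if (is.character(samples)) {
    sj <- match(samples, x$samples)
    if (anyNA(sj)) stop("unknown sample id(s): ",
                        paste(samples[is.na(sj)], collapse = ", "))
  } else sj <- samples
  genotype_matrix(x$calls[sj, si, drop = FALSE],
                  x$sites[si, , drop = FALSE],
                  x$samples[sj])
}

#' Per-site call rate
#'
#' Fraction of non-missing calls at each site.
#'
#' @param x a `genotype_matrix`.
#' @return Numeric vector in `[0, 1]`, one entry per site.
#' @export
call_rate <- function(x) colMeans(!is.na(x$calls))

#' Drop low call-rate sites
#'
#' Retains sites whose call rate is at least `min_rate`, preserving site
#' order (the array-QC step: probes with call rate below 70% were discarded
#' before association testing).
#'
#' @param x a `genotype_matrix`.
#' @param min_rate minimum fraction of non-missing calls, in `[0, 1]`.
#' @return List with `matrix` (the filtered `genotype_matrix`) and `dropped`
#'   (the site table rows that were removed).
#' @export
call_rate_filter <- function(x, min_rate) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  keep <- call_rate(x) >= min_rate
  list(matrix = subset_genotypes(x, sites = which(keep)),
       dropped = x$sites[!keep, , drop = FALSE])
}

#' Alternate-allele frequency from genotype-class tallies
#'
#' Computes AF = (2 n_hom_alt + n_het) / (2 (n_hom_ref + n_het + n_hom_alt)).
#' Counts and fractions are interchangeable: fractions are tallies divided by
#' a common n, which cancels. Missing genotypes never enter either side.
#' Genotypes carrying a third (non-insertion) allele are handled by
#' `third_allele_policy`: `"exclude"` leaves them out of numerator and
#' denominator; `"as_noncarrier"` folds them into the non-carrier
#' (hom-ref) class, i.e. they contribute two non-alternate alleles to the
#' denominator. The latter reproduces the published cohort AFs at the
#' insertion locus, where CT-SNP dogs were counted among the genotyped.
#'
#' @param hom_ref,het,hom_alt nonnegative tallies (counts or fractions) of
#'   the three biallelic genotype classes.
#' @param other tally of genotypes carrying a third allele (default 0).
#' @param third_allele_policy `"exclude"` or `"as_noncarrier"`.
#' @return Alternate-allele frequency in `[0, 1]`.
#' @export
allele_frequency <- function(hom_ref, het, hom_alt, other = 0,
                             third_allele_policy = c("exclude", "as_noncarrier")) {
  third_allele_policy <- match.arg(third_allele_policy)
  stopifnot(hom_ref >= 0, het >= 0, hom_alt >= 0, other >= 0)
  if (third_allele_policy == "as_noncarrier") hom_ref <- hom_ref + other
  denom <- 2 * (hom_ref + het + hom_alt)
  if (denom == 0) stop("allele frequency undefined: zero genotyped samples")
  (2 * hom_alt + het) / denom
}

#' Per-site minor allele frequency
#'
#' @param x a `genotype_matrix`.
#' @return Numeric vector of `min(af, 1 - af)` per site; `NaN` where no
#'   sample is genotyped.
#' @export
site_maf <- function(x) {
  af <- colMeans(x$calls, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}
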