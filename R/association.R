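# Candidate-locus cohort association: genotype count tables, chi-squared
# tests under genetic models, multiple-testing control, the cohort
# allele-frequency-gradient check, and the GWAS SNP prefilter.

#' Genotype count table per cohort at one site
#'
#' Tallies `{hom_alt, het, hom_ref}` per cohort at a site; missing calls
#' are excluded from `n`; genotypes carrying a third allele can be passed
#' through `other_counts` (array genotypes flagged as a different alternate
#' allele) and are tallied separately. Cohorts with zero genotyped samples
#' are flagged, not fatal.
#'
#' @param x a [genotype_matrix()].
#' @param site_index column index of the site.
#' @param cohorts character vector assigning each sample to a cohort.
#' @param other_counts optional named vector of third-allele genotype
#'   counts per cohort.
#' @return data.frame `cohort n_homalt n_het n_homref n_other n flagged`.
#' @export
genotype_count_table <- function(x, site_index, cohorts,
                                 other_counts = NULL) {
  stopifnot(site_index >= 1L, site_index <= n_sites(x),
            length(cohorts) == n_samples(x))
  g <- x$calls[, site_index]
  out <- do.call(rbind, lapply(unique(cohorts), function(co) {
    gi <- g[cohorts == co]
    oth <- if (!is.null(other_counts) && co %in% names(other_counts))
      other_counts[[co]] else 0L
    data.frame(cohort = co,
               n_homalt = sum(gi == 2L, na.rm = TRUE),
               n_het = sum(gi == 1L, na.rm = TRUE),
               n_homref = sum(gi == 0L, na.rm = TRUE),
               n_other = oth,
               stringsAsFactors = FALSE)
  }))
  out$n <- out$n_homalt + out$n_het + out$n_homref + out$n_other
  out$flagged <- out$n == 0L
  out
}

#' Contingency-table chi-squared test
#'
#' Pearson chi-squared test of independence on a 2x2 or 2x3 table of
#' nonnegative integer counts, expected counts from the margins. The Yates
#' continuity correction (subtracting 0.5 from each |O - E|) applies only
#' when `df = 1` and `yates = TRUE`. p-values come from the continuous
#' chi-squared upper tail.
#'
#' @param tab integer matrix of counts.
#' @param yates apply the continuity correction on 2x2 tables.
#' @return List of class `association_result`: `statistic`, `df`, `p`,
#'   `yates`, `model` (NA here; filled by the model-collapse caller).
#' @export
contingency_chisq <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0))
    stop("degenerate margin: row ", which(rs == 0)[1], " sums to zero")
  if (any(cs == 0))
    stop("degenerate margin: column ", which(cs == 0)[1], " sums to zero")
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p = max(unname(res$p.value), .Machine$double.xmin),
                 yates = yates && unname(res$parameter) == 1,
                 model = NA_character_),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("chi-squared = %.4f, df = %d, p = %.3g%s%s\n",
              x$statistic, x$df, x$p,
              if (isTRUE(x$yates)) " (Yates-corrected)" else "",
              if (!is.na(x$model)) paste0(" [", x$model, " model]") else ""))
  invisible(x)
}

#' Collapse cohort genotype counts under a genetic model
#'
#' Builds the contingency table for a pair of cohorts: `dominant` compares
#' carriers (hom-alt + het) against non-carriers; `recessive` hom-alt
#' against the rest; `allelic` counts alleles (2 per homozygote, 1 per
#' het); `genotypic` keeps the full 2x3 genotype table. Third-allele
#' genotypes are excluded under the default policy, or folded into the
#' non-carrier class with `third_allele_policy = "as_noncarrier"`.
#'
#' @param counts data.frame of two rows from [genotype_count_table()] (or
#'   with columns `n_homalt n_het n_homref`, optionally `n_other`).
#' @param model `"dominant"`, `"recessive"`, `"allelic"` or `"genotypic"`.
#' @param third_allele_policy `"exclude"` or `"as_noncarrier"`.
#' @return Integer matrix (2x2, or 2x3 for genotypic) with cohort rows.
#' @export
genetic_model_collapse <- function(counts,
                                   model = c("dominant", "recessive",
                                             "allelic", "genotypic"),
                                   third_allele_policy = c("exclude",
                                                           "as_noncarrier")) {
  model <- match.arg(model)
  third_allele_policy <- match.arg(third_allele_policy)
  stopifnot(nrow(counts) == 2L)
  hr <- counts$n_homref
  if (third_allele_policy == "as_noncarrier" && !is.null(counts$n_other))
    hr <- hr + counts$n_other
  ha <- counts$n_homalt; he <- counts$n_het
  tab <- switch(model,
    dominant = cbind(carrier = ha + he, non_carrier = hr),
    recessive = cbind(hom_alt = ha, rest = he + hr),
    allelic = cbind(alt = 2L * ha + he, ref = 2L * hr + he),
    genotypic = cbind(hom_alt = ha, het = he, hom_ref = hr))
  rownames(tab) <- if (!is.null(counts$cohort)) counts$cohort else NULL
  tab
}

#' Association test at a locus under a genetic model
#'
#' Convenience wrapper: collapse then test.
#'
#' @inheritParams genetic_model_collapse
#' @inheritParams contingency_chisq
#' @return An `association_result` with `model` filled in.
#' @export
model_association_test <- function(counts, model = "dominant",
                                   yates = FALSE,
                                   third_allele_policy = "exclude") {
  tab <- genetic_model_collapse(counts, model, third_allele_policy)
  res <- contingency_chisq(tab, yates = yates)
  res$model <- model
  res
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment (`adj_(i) = min_{j >= i} m p_(j) / j`, capped at
#' 1), returned in the input order.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Allele-frequency gradient check across the three pet cohorts
#'
#' Computes the insertion allele frequency per cohort, checks the strict
#' ordering AF(affected) > AF(control 1) > AF(control 2) predicted for a
#' variant inherited from the ancestral dog population, and attaches the
#' pairwise allelic chi-squared tests.
#'
#' @param affected,control1,control2 single rows with columns `n_homalt
#'   n_het n_homref` (optionally `n_other`), as produced by
#'   [genotype_count_table()] or [simulate_cohorts()].
#' @param third_allele_policy passed to [allele_frequency()].
#' @return List with `af` (named numeric, cohort order as given),
#'   `gradient` (logical), and `pairwise` (data.frame of allelic
#'   chi-squared results for the three cohort pairs).
#' @export
af_gradient_check <- function(affected, control1, control2,
                              third_allele_policy = "exclude") {
  rows <- list(affected = affected, control1 = control1,
               control2 = control2)
  for (nm in names(rows))
    if (!nrow(rows[[nm]]) || sum(rows[[nm]]$n_homalt + rows[[nm]]$n_het +
                                 rows[[nm]]$n_homref) == 0)
      stop("cohort '", nm, "' has no genotyped samples")
  af <- vapply(rows, function(r)
    allele_frequency(r$n_homref, r$n_het, r$n_homalt,
                     other = if (is.null(r$n_other)) 0 else r$n_other,
                     third_allele_policy = third_allele_policy), 0)
  pairs <- utils::combn(names(rows), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- rows[[pairs[1L, i]]]; b <- rows[[pairs[2L, i]]]
    res <- model_association_test(rbind(a[, c("n_homalt", "n_het", "n_homref")],
                                        b[, c("n_homalt", "n_het", "n_homref")]),
                                  model = "allelic")
    data.frame(cohort_a = pairs[1L, i], cohort_b = pairs[2L, i],
               statistic = res$statistic, df = res$df, p = res$p,
               stringsAsFactors = FALSE)
  }))
  list(af = af,
       gradient = af[1L] > af[2L] && af[2L] > af[3L],
       pairwise = pw)
}

#' GWAS SNP prefilter: missingness, MAF, thinning
#'
#' Applied in order: (1) drop sites with any missing call; (2) drop sites
#' with minor allele frequency below `maf_min` (the boundary itself is
#' kept: "MAF < maf_min" removed); (3) thin the survivors, by default
#' *keeping* every `thin_every`-th site starting from the first
#' (`thin = "keep"`); `thin = "drop"` instead removes every
#' `thin_every`-th site, the other reading of "thinning every 10th SNP".
#'
#' @param x a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.3).
#' @param thin_every thinning stride (default 10; 1 disables).
#' @param thin `"keep"` or `"drop"`.
#' @return The filtered `genotype_matrix`.
#' @export
gwas_snp_prefilter <- function(x, maf_min = 0.3, thin_every = 10L,
                               thin = c("keep", "drop")) {
  thin <- match.arg(thin)
  stopifnot(thin_every >= 1L)
  keep <- which(colSums(is.na(x$calls)) == 0L)
  x <- subset_genotypes(x, sites = keep)
  keep <- which(site_maf(x) >= maf_min)
  x <- subset_genotypes(x, sites = keep)
  idx <- seq_len(n_sites(x))
  sel <- if (thin == "keep") idx[(idx - 1L) %% thin_every == 0L]
         else idx[idx %% thin_every != 0L]
  subset_genotypes(x, sites = sel)
}

#' Per-locus association report
#'
#' One TSV-ready row per requested model at a site: cohort counts, AFs,
#' statistic, df, p and Bonferroni flag.
#'
#' @param counts two-cohort counts (see [genetic_model_collapse()]).
#' @param models character vector of genetic models to test.
#' @param alpha,m_tests Bonferroni family parameters.
#' @param yates continuity correction for df=1 tables.
#' @return data.frame, one row per model.
#' @export
association_report <- function(counts, models = c("dominant", "recessive",
                                                  "allelic", "genotypic"),
                               alpha = 0.05, m_tests = 1L, yates = FALSE) {
  thr <- bonferroni_threshold(alpha, m_tests)
  do.call(rbind, lapply(models, function(m) {
    res <- model_association_test(counts, model = m, yates = yates)
    data.frame(model = m, statistic = res$statistic, df = res$df,
               p = res$p, bonferroni_threshold = thr,
               significant = res$p < thr, stringsAsFactors = FALSE)
  }))
}
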