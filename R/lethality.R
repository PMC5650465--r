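# Mendelian expected counts per cross and segregation-distortion testing:
# the statistics used to show that insertion homozygotes on a susceptible
# breed background are never born.

#' Mendelian expected offspring counts for one cross
#'
#' Class probabilities from the two-allele Punnett rules for the parental
#' genotypes, times the number of offspring. Only Mendelian-possible
#' classes (probability > 0) are returned; probabilities always sum to 1.
#' A het x het cross with 17 offspring yields (4.25, 8.5, 4.25) over
#' (hom-ref, het, hom-alt); het x hom-alt with 22 yields (11, 11) over
#' (het, hom-alt).
#'
#' @param sire_gt,dam_gt parental calls: `"hom_ref"`, `"het"`, `"hom_alt"`.
#' @param n number of offspring (>= 0).
#' @return Named numeric vector of expected counts over the possible
#'   classes, in (hom_ref, het, hom_alt) order.
#' @export
mendelian_expected <- function(sire_gt, dam_gt, n) {
  stopifnot(n >= 0)
  alt_prob <- function(g) switch(g, hom_ref = 0, het = 0.5, hom_alt = 1,
                                 stop("missing or unknown parent genotype: ",
                                      g))
  ps <- alt_prob(sire_gt); pd <- alt_prob(dam_gt)
  prob <- c(hom_ref = (1 - ps) * (1 - pd),
            het = ps * (1 - pd) + (1 - ps) * pd,
            hom_alt = ps * pd)
  n * prob[prob > 0]
}

#' Goodness-of-fit chi-squared with optional Yates correction
#'
#' `sum((O - E)^2 / E)` over identical class sets; with `yates_if_df1 =
#' TRUE` and a single degree of freedom the statistic becomes
#' `sum((|O - E| - 0.5)^2 / E)` (continuity correction). df = classes - 1;
#' p from the chi-squared upper tail.
#'
#' @param observed,expected numeric vectors over the same classes;
#'   `expected` strictly positive.
#' @param yates_if_df1 apply the continuity correction when df = 1.
#' @return List: `statistic`, `df`, `p`, `yates`.
#' @export
gof_chisq <- function(observed, expected, yates_if_df1 = FALSE) {
  if (length(observed) != length(expected))
    stop("observed and expected must cover identical class sets")
  if (any(expected <= 0))
    stop("zero expected count in class ", which(expected <= 0)[1],
         "; merge classes before testing")
  df <- length(observed) - 1L
  if (df < 1L) stop("need at least two classes")
  dev <- abs(observed - expected)
  yates <- yates_if_df1 && df == 1L
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       yates = yates)
}

#' Screen pooled crosses for genotype classes lost to embryonic lethality
#'
#' For every Mendelian-possible offspring class, observed and expected
#' counts are pooled class-wise across the crosses and a pooled
#' goodness-of-fit chi-squared is computed (Yates-corrected when df = 1).
#' A class is flagged as consistent with embryonic lethality when it was
#' never observed, its pooled expectation is at least `min_expected`
#' (chi-squared small-sample validity guard), and the pooled test is
#' significant at `alpha`. Per-cross tests are reported alongside.
#'
#' @param crosses cross-outcome data.frame (`sire_gt dam_gt n_homref n_het
#'   n_homalt`).
#' @param alpha significance level for the pooled test (default 0.01).
#' @param yates apply the continuity correction to df = 1 tests.
#' @param min_expected minimum pooled expected count for flagging
#'   (default 5).
#' @return List with `flagged` (character vector of genotype classes),
#'   `pooled` (data.frame class/observed/expected), `pooled_test` (the
#'   pooled GOF result over classes possible in any cross) and `per_cross`
#'   (data.frame of per-cross statistics).
#' @export
lethality_screen <- function(crosses, alpha = 0.01, yates = TRUE,
                             min_expected = 5) {
  stopifnot(nrow(crosses) >= 1L)
  obs_cols <- c(hom_ref = "n_homref", het = "n_het", hom_alt = "n_homalt")
  pooled_obs <- stats::setNames(numeric(3L), GT_LEVELS)
  pooled_exp <- stats::setNames(numeric(3L), GT_LEVELS)
  per_cross <- list()
  for (i in seq_len(nrow(crosses))) {
    exp_i <- mendelian_expected(crosses$sire_gt[i], crosses$dam_gt[i],
                                sum(unlist(crosses[i, obs_cols])))
    obs_i <- vapply(names(exp_i), function(cl)
      as.numeric(crosses[i, obs_cols[[cl]]]), 0)
    imposs <- setdiff(GT_LEVELS, names(exp_i))
    bad <- imposs[vapply(imposs, function(cl)
      crosses[i, obs_cols[[cl]]] > 0, TRUE)]
    if (length(bad))
      stop(sprintf("cross %d has offspring in Mendelian-impossible class %s",
                   i, paste(bad, collapse = ", ")))
    pooled_obs[names(exp_i)] <- pooled_obs[names(exp_i)] + obs_i
    pooled_exp[names(exp_i)] <- pooled_exp[names(exp_i)] + exp_i
    gof <- if (length(exp_i) >= 2L)
      gof_chisq(obs_i, exp_i, yates_if_df1 = yates)
    else list(statistic = NA_real_, df = NA_integer_, p = NA_real_)
    per_cross[[i]] <- data.frame(
      cross = i, sire_gt = crosses$sire_gt[i], dam_gt = crosses$dam_gt[i],
      statistic = gof$statistic, df = gof$df, p = gof$p,
      stringsAsFactors = FALSE)
  }
  possible <- names(pooled_exp)[pooled_exp > 0]
  pooled_test <- gof_chisq(pooled_obs[possible], pooled_exp[possible],
                           yates_if_df1 = yates)
  flagged <- possible[pooled_obs[possible] == 0 &
                        pooled_exp[possible] >= min_expected &
                        pooled_test$p < alpha]
  list(flagged = flagged,
       pooled = data.frame(class = possible,
                           observed = unname(pooled_obs[possible]),
                           expected = unname(pooled_exp[possible]),
                           stringsAsFactors = FALSE),
       pooled_test = pooled_test,
       per_cross = do.call(rbind, per_cross))
}
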