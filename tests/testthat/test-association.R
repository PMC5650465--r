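# cohort association: count tables, chi-squared models, multiple testing,
# allele-frequency gradient, GWAS prefilter

test_that("genotype count tables exclude missing and flag empty cohorts", {
  gm <- make_gm(matrix(c(1L, 1L, 2L, NA), 4, 1))
  cohorts <- c("a", "a", "a", "a")
  tab <- genotype_count_table(gm, 1L, cohorts)
  expect_equal(unname(unlist(tab[, c("n_homalt", "n_het", "n_homref")])),
               c(1L, 2L, 0L))
  expect_equal(tab$n, 3L)
  tab2 <- genotype_count_table(gm, 1L, c("a", "a", "a", "b"))
  expect_true(tab2$flagged[tab2$cohort == "b"])
  # matches a brute-force recount on simulated cohorts
  gm2 <- random_gm(60, 5, seed = 71, miss_rate = 0.1)
  coh <- sample(c("x", "y", "z"), 60, replace = TRUE)
  tab3 <- genotype_count_table(gm2, 3L, coh)
  for (co in c("x", "y", "z")) {
    g <- gm2$calls[coh == co, 3L]
    expect_equal(tab3$n_het[tab3$cohort == co], sum(g == 1L, na.rm = TRUE))
    expect_equal(tab3$n[tab3$cohort == co], sum(!is.na(g)))
  }
})

test_that("contingency chi-squared matches the textbook formula and CDF", {
  expect_equal(contingency_chisq(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(contingency_chisq(rbind(c(10, 10), c(10, 10)))$p, 1)
  set.seed(72)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 30) + 1L, 2, 2)
    # direct formula oracle
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    res <- contingency_chisq(tab, yates = FALSE)
    expect_equal(res$statistic, stat, tolerance = 1e-10)
    expect_equal(res$p, pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    staty <- sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
    expect_equal(contingency_chisq(tab, yates = TRUE)$statistic, staty,
                 tolerance = 1e-8)
    # Yates never increases the statistic at df = 1
    expect_lte(contingency_chisq(tab, yates = TRUE)$statistic,
               res$statistic + 1e-12)
  }
  # 2x3 tables: df = 2, no correction applied
  tab3 <- rbind(c(5, 20, 30), c(12, 18, 25))
  E <- outer(rowSums(tab3), colSums(tab3)) / sum(tab3)
  expect_equal(contingency_chisq(tab3, yates = TRUE)$statistic,
               sum((tab3 - E)^2 / E), tolerance = 1e-10)
  expect_equal(contingency_chisq(tab3)$df, 2L)
  expect_error(contingency_chisq(rbind(c(0, 0), c(1, 2))), "margin")
  # p for the 0.05 critical value
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
})

test_that("genetic model collapse reproduces the published genotype split", {
  counts <- data.frame(cohort = c("affected", "controls"),
                       n_homalt = c(3L, 14L), n_het = c(75L, 67L),
                       n_homref = c(21L, 113L))
  dom <- genetic_model_collapse(counts, "dominant")
  expect_equal(unname(dom[1, ]), c(78L, 21L))
  rec <- genetic_model_collapse(counts, "recessive")
  expect_equal(unname(rec[1, ]), c(3L, 96L))
  gen <- genetic_model_collapse(counts, "genotypic")
  expect_equal(dim(gen), c(2L, 3L))
  # dominant/recessive/genotypic conserve the genotyped total
  for (m in c("dominant", "recessive", "genotypic"))
    expect_equal(sum(genetic_model_collapse(counts, m)),
                 sum(counts$n_homalt + counts$n_het + counts$n_homref))
  # allelic equals brute-force allele enumeration
  alle <- genetic_model_collapse(counts, "allelic")
  enum <- function(r) c(alt = 2 * r$n_homalt + r$n_het,
                        ref = 2 * r$n_homref + r$n_het)
  expect_equal(unname(alle[1, ]), unname(enum(counts[1, ])))
  expect_equal(unname(alle[2, ]), unname(enum(counts[2, ])))
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 76), 0.05 / 76)
  expect_equal(signif(bonferroni_threshold(0.05, 76), 2), 6.6e-4)
  expect_equal(bonferroni_threshold(0.1, 1), 0.1)
  expect_equal(bonferroni_threshold(0.05, 2000), 2.5e-5)
})

test_that("BH adjustment equals the quadratic step-up oracle", {
  bh_slow <- function(p) {
    m <- length(p); o <- order(p); adj <- numeric(m)
    for (i in seq_len(m)) {
      r <- which(o == i)   # rank of p[i]
      adj[i] <- min(1, min(m * p[o][r:m] / (r:m)))
    }
    adj
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(73)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_slow(p), tolerance = 1e-12)
  }
  # monotone in sorted order and permutation-invariant
  p <- runif(25)
  adj <- bh_adjust(p)
  expect_true(!is.unsorted(adj[order(p)]))
  perm <- sample(25)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("AF gradient check reproduces the published cohort ordering", {
  aff <- data.frame(n_homalt = 3, n_het = 75, n_homref = 22)   # of 100
  c1 <- data.frame(n_homalt = 9, n_het = 42, n_homref = 49)
  c2 <- data.frame(n_homalt = 5, n_het = 25, n_homref = 70)
  res <- af_gradient_check(aff, c1, c2)
  expect_equal(unname(res$af), c(0.405, 0.30, 0.175))
  expect_true(res$gradient)
  expect_equal(nrow(res$pairwise), 3L)
  # equal cohorts: strict gradient fails
  res0 <- af_gradient_check(aff, aff, aff)
  expect_false(res0$gradient)
  expect_error(af_gradient_check(aff, c1, data.frame(n_homalt = 0,
                                                     n_het = 0,
                                                     n_homref = 0)),
               "no genotyped")
})

test_that("a planted AF gradient is detected in most simulated cohorts", {
  hits <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, cohort_n = c(affected_pets = 60L,
                                             control_pets_1 = 60L,
                                             control_pets_2 = 60L))
    co <- simulate_cohorts(cfg)
    af_gradient_check(co[1, ], co[2, ], co[3, ])$gradient
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("dominant-model type-I error is nominal on null cohorts", {
  set.seed(74)
  rej <- vapply(1:2000, function(i) {
    g1 <- rbinom(60, 2, 0.3); g2 <- rbinom(60, 2, 0.3)
    counts <- data.frame(n_homalt = c(sum(g1 == 2), sum(g2 == 2)),
                         n_het = c(sum(g1 == 1), sum(g2 == 1)),
                         n_homref = c(sum(g1 == 0), sum(g2 == 0)))
    model_association_test(counts, "dominant")$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("GWAS prefilter applies missing, MAF and thinning in order", {
  calls <- cbind(c(0L, 1L, NA, 0L),          # missing -> dropped
                 matrix(rep(c(0L, 1L, 1L, 2L), 12), 4))  # MAF 0.5
  gm <- make_gm(calls)
  out <- gwas_snp_prefilter(gm, maf_min = 0.3, thin_every = 1L)
  expect_equal(n_sites(out), 12L)
  # boundary: MAF 0.29 dropped, 0.30 kept ("<0.3 removed")
  n <- 50
  g_030 <- c(rep(2L, 15), rep(0L, 35))       # af 0.30
  g_029 <- c(rep(2L, 14), rep(1L, 1), rep(0L, 35))  # af 0.29
  gm2 <- make_gm(cbind(g_030, g_029))
  out2 <- gwas_snp_prefilter(gm2, maf_min = 0.3, thin_every = 1L)
  expect_equal(n_sites(out2), 1L)
  expect_equal(out2$sites$pos, 1000L)
  # thinning keeps the 1st, (1+k)th, ... surviving site
  gm3 <- random_gm(30, 100, seed = 75, af = rep(0.5, 100))
  out3 <- gwas_snp_prefilter(gm3, maf_min = 0, thin_every = 10L)
  expect_equal(out3$sites$pos, gm3$sites$pos[seq(1, 100, by = 10)])
  # drop-mode removes every k-th instead
  out3d <- gwas_snp_prefilter(gm3, maf_min = 0, thin_every = 10L,
                              thin = "drop")
  expect_equal(n_sites(out3d), 90L)
  # survivor count equals brute-force sequential application
  gm4 <- random_gm(40, 1000, seed = 76, miss_rate = 0.02)
  out4 <- gwas_snp_prefilter(gm4)
  keep <- apply(gm4$calls, 2, function(g) !anyNA(g))
  maf <- vapply(seq_len(1000), function(j) {
    g <- gm4$calls[, j]
    if (anyNA(g)) return(NA_real_)
    af <- mean(g) / 2; min(af, 1 - af)
  }, 0)
  surv <- which(keep & maf >= 0.3)
  expect_equal(n_sites(out4), length(surv[seq(1, length(surv), by = 10)]))
})
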