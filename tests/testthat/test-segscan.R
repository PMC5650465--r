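# segregation-pattern filtering, enrichment scanning, homozygosity blocks,
# breed sharing

test_that("pattern filter keeps exactly the sites matching every required call", {
  gm <- make_gm(rbind(c(2, 2, 2), c(2, 2, 2), c(1, 0, 1), c(0, 0, 0)),
                samples = c("aff1", "aff2", "carrier", "control"))
  pat <- segregation_pattern(c(aff1 = "hom_alt", aff2 = "hom_alt",
                               carrier = "het", control = "hom_ref"))
  ret <- segregation_pattern_filter(gm, pat)
  expect_equal(ret$pos, c(1000L, 3000L))   # site 2: carrier is 0 -> rejected
  expect_error(
    segregation_pattern_filter(gm, segregation_pattern(c(ghost = "het"))),
    "ghost")
})

test_that("missing calls fail the match under the default policy and are
           skipped under ignore_sample", {
  gm <- make_gm(rbind(c(2, 2), c(NA, 2), c(1, 1), c(0, 0)),
                samples = c("a1", "a2", "ca", "co"))
  req <- c(a1 = "hom_alt", a2 = "hom_alt", ca = "het", co = "hom_ref")
  strict <- segregation_pattern(req, "fail_match")
  lax <- segregation_pattern(req, "ignore_sample")
  expect_equal(segregation_pattern_filter(gm, strict)$pos, 2000L)
  expect_equal(segregation_pattern_filter(gm, lax)$pos, c(1000L, 2000L))
})

test_that("pattern filter equals the brute-force per-site oracle on
           simulated data and is monotone in the pattern", {
  st <- simulate_study(sim_config(
    seed = 61, n_background_variants = 3000L, n_linked_variants = 60L,
    expression_params = list(n_genes = 50L, n_planted = 5L)))
  gm <- st$genotypes
  pat <- default_pattern_from_study(st)
  ret <- segregation_pattern_filter(gm, pat)
  want <- match(pat$required, c("hom_ref", "het", "hom_alt")) - 1L
  rows <- match(names(pat$required), gm$samples)
  oracle <- vapply(seq_len(n_sites(gm)), function(j) {
    calls <- gm$calls[rows, j]
    !anyNA(calls) && all(calls == want)
  }, TRUE)
  expect_setequal(ret$site_index, which(oracle))
  # monotonicity: adding a required sample never grows the retained set
  extra_id <- setdiff(gm$samples, names(pat$required))[1]
  pat2 <- segregation_pattern(c(pat$required,
                                stats::setNames("hom_ref", extra_id)))
  ret2 <- segregation_pattern_filter(gm, pat2)
  expect_true(all(ret2$site_index %in% ret$site_index))
})

test_that("fold enrichment reproduces the published arithmetic and is
           scale-invariant", {
  f <- fold_enrichment(244, 1.9e6, 18600, 2.392e9)
  expect_gt(f, 16)
  expect_equal(f, (244 / 1.9e6) / (18600 / 2.392e9))
  expect_equal(fold_enrichment(50, 1e6, 1000, 2e7),
               fold_enrichment(50, 7e6, 1000, 1.4e8))
  expect_equal(fold_enrichment(10, 1e6, 100, 1e7), 1)  # uniform density
  expect_equal(fold_enrichment(100, 5e6, 100, 5e6), 1) # k=K, w=G
  expect_error(fold_enrichment(1, 1e6, 0, 1e9), "zero genome-wide")
})

test_that("enrichment scan ranks the loaded window first and breaks ties
           deterministically", {
  ret <- data.frame(chrom = "chr1",
                    pos = c(seq(1e6, 1.5e6, by = 1e4), 5e7),
                    stringsAsFactors = FALSE)
  sc <- enrichment_scan(ret, G_bp = 1e8)
  expect_equal(sc$windows$start[1] <= 1e6, TRUE)
  expect_gte(sc$top_segment$k, 51L)
  # two equal clusters: tie broken by (chrom, start)
  ret2 <- data.frame(
    chrom = rep(c("chr2", "chr1"), each = 5),
    pos = rep(seq(2e6, 2.04e6, by = 1e4), 2))
  sc2 <- enrichment_scan(ret2, G_bp = 1e8, fold_threshold = 1)
  expect_equal(sc2$top_segment$chrom, "chr1")
})

test_that("the top merged segment localizes the planted causal interval", {
  st <- simulate_study(sim_config(
    seed = 62, expression_params = list(n_genes = 50L, n_planted = 5L)))
  ret <- segregation_pattern_filter(st$genotypes,
                                    default_pattern_from_study(st))
  cfg <- st$config
  sc <- enrichment_scan(ret,
                        G_bp = cfg$n_chromosomes * cfg$chrom_length_bp)
  ts <- sc$top_segment
  expect_equal(ts$chrom, st$truth$causal_chrom)
  expect_gte(interval_jaccard(c(ts$start, ts$end),
                              st$truth$causal_interval), 0.8)
  expect_gte(ts$fold, 10)
  # the causal site itself lies inside the reported segment
  cau_pos <- st$genotypes$sites$pos[st$truth$causal_index]
  expect_true(ts$start <= cau_pos && cau_pos <= ts$end)
})

test_that("maximum window fold on uniform backgrounds stays modest", {
  # sanity calibration: scattered sites should not fake a strong cluster
  # at study-scale density (~10 matching variants per Mb window)
  maxfold <- vapply(1:60, function(s) {
    set.seed(700 + s)
    ret <- data.frame(chrom = sample(sprintf("chr%d", 1:5), 3000,
                                     replace = TRUE),
                      pos = sample.int(6e7, 3000, replace = TRUE))
    sc <- enrichment_scan(ret, G_bp = 3e8, fold_threshold = Inf)
    max(sc$windows$fold)
  }, 0)
  expect_lt(stats::median(maxfold), 3)
})

test_that("homozygosity blocks match a quadratic brute-force finder", {
  find_blocks_slow <- function(gm, cases, controls, min_sites) {
    qual <- vapply(seq_len(n_sites(gm)), function(j) {
      ca <- gm$calls[match(cases, gm$samples), j]
      co <- gm$calls[match(controls, gm$samples), j]
      !anyNA(ca) && !anyNA(co) && all(ca == 2L) && all(co == 0L)
    }, TRUE)
    out <- list()
    for (i in seq_len(n_sites(gm))) for (j in i:n_sites(gm)) {
      if (j - i + 1L < min_sites) next
      if (gm$sites$chrom[i] != gm$sites$chrom[j]) next
      if (all(qual[i:j]) &&
          (i == 1L || !qual[i - 1L] ||
             gm$sites$chrom[i - 1L] != gm$sites$chrom[i]) &&
          (j == n_sites(gm) || !qual[j + 1L] ||
             gm$sites$chrom[j + 1L] != gm$sites$chrom[j]))
        out[[length(out) + 1L]] <- c(i, j)
    }
    out
  }
  set.seed(63)
  gm <- random_gm(8, 80, seed = 63, miss_rate = 0.05)
  cases <- gm$samples[1:2]; controls <- gm$samples[3:6]
  # plant two qualifying runs separated by a non-qualifying site
  gm$calls[, 10:14] <- rep(c(2L, 2L, 0L, 0L, 0L, 0L, 1L, 1L), 5)
  gm$calls[, 15] <- 1L
  gm$calls[, 16:18] <- rep(c(2L, 2L, 0L, 0L, 0L, 0L, 2L, 0L), 3)
  for (ms in c(2L, 3L, 6L)) {
    got <- homozygosity_blocks(gm, cases, controls, min_sites = ms)
    want <- find_blocks_slow(gm, cases, controls, ms)
    expect_equal(nrow(got), length(want))
    if (length(want))
      expect_equal(unname(as.matrix(got[, c("first_index", "last_index")])),
                   do.call(rbind, want), ignore_attr = TRUE)
  }
  expect_error(homozygosity_blocks(gm, character(), controls), "at least one")
  expect_error(homozygosity_blocks(gm, cases, c(cases[1], controls)),
               "disjoint")
})

test_that("a qualifying run broken by one bad site yields two blocks", {
  calls <- matrix(0L, 6, 7)
  calls[1:2, ] <- 2L            # cases hom-alt everywhere
  calls[1, 4] <- 1L             # break at site 4
  gm <- make_gm(calls)
  blocks <- homozygosity_blocks(gm, gm$samples[1:2], gm$samples[3:6],
                                min_sites = 3L)
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$n_sites, c(3L, 3L))
})

test_that("breed sharing counts affected homozygotes per breed", {
  calls <- matrix(2L, 5, 4)
  calls[4, 2] <- 1L   # breaks hom-alt for sample 4
  gm <- make_gm(calls)
  samples <- rbind(
    sample_row("s01", breed = "ACS", phenotype = "xx_dsd"),
    sample_row("s02", breed = "ECS", phenotype = "xx_dsd"),
    sample_row("s03", breed = "ECS", phenotype = "unaffected"),
    sample_row("s04", breed = "PUG", phenotype = "xx_dsd"),
    sample_row("s05", breed = "LAB", phenotype = "unaffected"))
  block <- data.frame(first_index = 1L, last_index = 4L)
  res <- breed_sharing_table(gm, block, samples)
  expect_equal(res$n_segregating_breeds, 2L)   # ACS + ECS; PUG broken
  expect_equal(res$table$segregates[res$table$breed == "PUG"], FALSE)
  # no affected homozygotes anywhere -> 0
  samples0 <- samples; samples0$phenotype <- "unaffected"
  expect_equal(breed_sharing_table(gm, block, samples0)$n_segregating_breeds,
               0L)
})

test_that("simulated multi-breed cohort reports the planted sharing count", {
  set.seed(64)
  n_breeds <- 21
  calls <- matrix(0L, n_breeds, 6)
  sharing <- c(rep(TRUE, 20), FALSE)
  calls[sharing, ] <- 2L
  gm <- make_gm(calls)
  samples <- do.call(rbind, lapply(seq_len(n_breeds), function(i)
    sample_row(sprintf("s%02d", i), breed = sprintf("breed%02d", i),
               phenotype = "xx_dsd")))
  block <- data.frame(first_index = 1L, last_index = 6L)
  expect_equal(breed_sharing_table(gm, block, samples)$n_segregating_breeds,
               20L)
})
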