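# stringent DE filter, fold categories, genomic binning, pathway summaries

fake_record <- function(gene_id = "g1", chrom = "chr1", start = 1e6,
                        age_group = "d42_44", fa = 5, fc = 2.2,
                        l2fc = NULL, q = 0.04) {
  data.frame(gene_id = gene_id, chrom = chrom, start = start,
             age_group = age_group, fpkm_affected = fa, fpkm_control = fc,
             log2fc = if (is.null(l2fc)) log2(fa / fc) else l2fc,
             q_value = q, stringsAsFactors = FALSE)
}

test_that("the three stringent gates act literally and independently", {
  r <- fake_record(fa = 2.2, fc = 5, l2fc = -1.2, q = 0.04)
  out <- stringent_de_filter(r)
  expect_equal(nrow(out), 1L)
  expect_equal(out$direction, "down")
  # |log2FC| below 1 -> rejected
  expect_equal(nrow(stringent_de_filter(fake_record(l2fc = -0.9))), 0L)
  # q above cutoff -> rejected
  expect_equal(nrow(stringent_de_filter(fake_record(l2fc = -1.2, q = 0.06))),
               0L)
  # neither group reaching FPKM 4 -> rejected
  expect_equal(nrow(stringent_de_filter(
    fake_record(fa = 1.1, fc = 3.9, l2fc = -1.8))), 0L)
  # one group at the boundary passes (>= 4)
  expect_equal(nrow(stringent_de_filter(
    fake_record(fa = 1.5, fc = 4, l2fc = -1.4))), 1L)
})

test_that("the filter equals the brute-force triple-gate oracle and is
           antitone in every threshold", {
  res <- simulate_expression(sim_config(seed = 101, expression_params =
    list(n_genes = 4000L, n_planted = 150L)))
  rec <- res$records
  de <- stringent_de_filter(rec)
  oracle <- rec[rec$q_value <= 0.05 & abs(rec$log2fc) >= 1 &
                  pmax(rec$fpkm_affected, rec$fpkm_control) >= 4, ]
  expect_equal(nrow(de), nrow(oracle))
  expect_setequal(paste(de$gene_id, de$age_group),
                  paste(oracle$gene_id, oracle$age_group))
  # tightening any one gate never adds genes
  for (args in list(list(q_max = 0.01), list(min_abs_log2fc = 1.5),
                    list(min_group_fpkm = 8))) {
    tighter <- do.call(stringent_de_filter, c(list(rec), args))
    expect_true(all(paste(tighter$gene_id, tighter$age_group) %in%
                      paste(de$gene_id, de$age_group)))
  }
})

test_that("planted >=2-fold genes are recovered at the default noise", {
  res <- simulate_expression(sim_config(seed = 102))
  de <- stringent_de_filter(res$records)
  hit <- res$truth$planted_genes %in% de$gene_id
  expect_gte(mean(hit), 0.9)
  # essentially all recovered genes are called down
  planted_rows <- de[de$gene_id %in% res$truth$planted_genes, ]
  expect_true(all(planted_rows$direction == "down"))
})

test_that("null expression tables yield few stringent-DE calls", {
  res <- simulate_expression(sim_config(seed = 103, expression_params =
    list(n_planted = 0L, age_groups = "d42_44")))
  de <- stringent_de_filter(res$records)
  expect_lte(nrow(de), 0.05 * nrow(res$records) * 1.5)
})

test_that("fold categories use the documented closed boundaries", {
  expect_equal(fold_category(-1.3), ">2-fold")
  expect_equal(fold_category(1.0), ">2-fold")     # closed at 1
  expect_equal(fold_category(-0.95), "~2-fold")
  expect_equal(fold_category(0.6), "<2-fold")
  expect_equal(fold_category(0), "<<2-fold")
  expect_equal(fold_category(c(2, -0.9, 0.4, 0.39)),
               c(">2-fold", "~2-fold", "<2-fold", "<<2-fold"))
  expect_error(fold_category(Inf), "finite")
})

test_that("genomic binning respects bin boundaries and finds the argmax", {
  de <- rbind(fake_record("a", start = 1, l2fc = -2),
              fake_record("b", start = 9999999, l2fc = -2),
              fake_record("c", start = 10000001, l2fc = -2),
              fake_record("d", chrom = "chr2", start = 5, l2fc = 2))
  de <- stringent_de_filter(de)
  bins <- genomic_binning(de)
  expect_equal(nrow(bins$bins), 3L)
  b1 <- bins$bins[bins$bins$chrom == "chr1" & bins$bins$bin == 0, ]
  expect_equal(b1$n_down, 2L)                     # 1 and 9,999,999 share a bin
  expect_equal(bins$top_down$bin, 0)
  expect_equal(bins$top_up$chrom, "chr2")
  # empty input -> all-zero bins
  empty <- genomic_binning(de[0, ])
  expect_equal(nrow(empty$bins), 0L)
  expect_null(empty$top_down)
  # unknown chromosome errors when lengths are declared
  expect_error(genomic_binning(de, chrom_lengths = c(chr1 = 6e7)),
               "unknown chromosome")
})

test_that("a planted cluster is the argmax bin", {
  res <- simulate_expression(sim_config(seed = 104, expression_params =
    list(n_genes = 3000L, n_planted = 0L)))
  rec <- res$records
  # plant a dense down-regulated cluster in chr5:20-30M
  idx <- sample(which(rec$age_group == "d42_44"), 40)
  rec$chrom[idx] <- "chr5"
  rec$start[idx] <- sample(seq(2e7 + 1, 3e7), 40)
  rec$log2fc[idx] <- -2
  rec$q_value[idx] <- 1e-4
  rec$fpkm_affected[idx] <- 3; rec$fpkm_control[idx] <- 12
  de <- stringent_de_filter(rec)
  bins <- genomic_binning(de)
  expect_equal(bins$top_down$chrom, "chr5")
  expect_equal(bins$top_down$bin, 2)
})

test_that("pathway summaries classify significance across age groups", {
  rec <- rbind(
    fake_record("rspo1", age_group = "d37_39", l2fc = -0.8, q = 0.004),
    fake_record("rspo1", age_group = "d42_44", l2fc = -1.2, q = 5e-5),
    fake_record("wnt4", age_group = "d37_39", l2fc = -0.95, q = 5e-5),
    fake_record("wnt4", age_group = "d42_44", l2fc = -0.9, q = 5e-5),
    fake_record("lef1", age_group = "d37_39", l2fc = 0.1, q = 0.4),
    fake_record("lef1", age_group = "d42_44", l2fc = 0.05, q = 0.6),
    fake_record("fgf9", age_group = "d37_39", l2fc = 0.5, q = 0.2),
    fake_record("fgf9", age_group = "d42_44", l2fc = 0.6, q = 0.001))
  pw <- data.frame(gene_id = c("rspo1", "wnt4", "lef1", "fgf9", "foxl2"),
                   pathway = c("ovary", "ovary", "ovary", "testis", "ovary"),
                   stringsAsFactors = FALSE)
  res <- pathway_summary(rec, pw)
  g <- res$genes
  expect_equal(g$significance[g$gene_id == "rspo1"], "both ages")
  expect_equal(g$fold_category[g$gene_id == "rspo1"], ">2-fold")
  expect_equal(g$direction[g$gene_id == "rspo1"], "down")
  expect_equal(g$significance[g$gene_id == "fgf9"], "one age")
  expect_equal(g$significance[g$gene_id == "lef1"], "neither")
  expect_equal(g$significance[g$gene_id == "foxl2"], "not measured")
  # empty pathway set -> empty report
  expect_equal(nrow(pathway_summary(rec, pw[0, ])$genes), 0L)
})

test_that("planted ovary-set downregulation yields a LOWER majority", {
  res <- simulate_expression(sim_config(seed = 105))
  pw <- data.frame(gene_id = res$truth$planted_genes[1:50],
                   pathway = "ovary", stringsAsFactors = FALSE)
  summ <- pathway_summary(res$records, pw)
  g <- summ$genes
  expect_gt(mean(g$direction == "down"), 0.9)
  expect_gt(mean(g$significance == "both ages"), 0.8)
})
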