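# End-to-end orchestration: simulate (or load) inputs, then run the
# segregation scan, cohort association, mixed-model GWAS, lethality screen
# and expression filter from one configuration, with a hashed output
# manifest so identical config + seed reproduce identical runs.

#' Build the default segregation pattern from a simulated study
#'
#' Selects the four reference animals of the recessive mapping design from
#' the realized pedigree: two affected dogs (required homozygous for the
#' insertion), one obligate carrier (required heterozygous), and one
#' unaffected non-carrier control (required homozygous reference), using
#' the study's ground-truth carrier dosages.
#'
#' @param study a `simulated_study`.
#' @return A [segregation_pattern()].
#' @export
default_pattern_from_study <- function(study) {
  s <- study$samples
  dos <- study$truth$carrier_dosage[s$sample_id]
  aff <- s$sample_id[s$phenotype == "xx_dsd" & dos == 2L]
  car <- s$sample_id[s$phenotype != "xx_dsd" & dos == 1L]
  ctl <- s$sample_id[s$phenotype != "xx_dsd" & dos == 0L]
  if (length(aff) < 2L || length(car) < 1L || length(ctl) < 1L)
    stop("study lacks the reference animals for the recessive pattern ",
         "(need 2 affected homozygotes, 1 carrier, 1 non-carrier control)")
  segregation_pattern(c(
    stats::setNames(rep("hom_alt", 2L), aff[1:2]),
    stats::setNames("het", car[1L]),
    stats::setNames("hom_ref", ctl[1L])))
}

#' Run configuration for the full pipeline
#'
#' @param seed top-level seed (drives the simulator and any stage
#'   randomness).
#' @param stages character vector of stages to run, in dependency order;
#'   subset of `c("segscan", "assoc", "glmm", "lethality", "expression")`.
#' @param simulate generate inputs with [simulate_study()] (`TRUE`,
#'   default) or load them from `inputs` paths.
#' @param inputs named list of paths (`vcf`, `samples`, `crosses`,
#'   `expression`, `pattern`) used when `simulate = FALSE`.
#' @param sim named list of [sim_config()] overrides.
#' @param params named list of per-stage parameter blocks (`segscan`,
#'   `assoc`, `glmm`, `lethality`, `expression`), merged over defaults.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = c("segscan", "assoc", "glmm", "lethality",
                                  "expression"),
                       simulate = TRUE, inputs = list(), sim = list(),
                       params = list()) {
  known <- c("segscan", "assoc", "glmm", "lethality", "expression")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  defaults <- list(
    segscan = list(window_bp = 1e6, step_bp = 1e5, fold_threshold = 5,
                   min_block_sites = 3L),
    assoc = list(model = "dominant", yates = FALSE, alpha = 0.05),
    glmm = list(maf_min = 0.3, thin_every = 10L, pca_maf_min = 0.01,
                pca_thin_every = 100L, n_pcs = 5L, bh_max = 0.1),
    lethality = list(alpha = 0.01, yates = TRUE),
    expression = list(q_max = 0.05, min_abs_log2fc = 1, min_group_fpkm = 4,
                      bin_bp = 1e7))
  for (nm in names(params)) defaults[[nm]][names(params[[nm]])] <- params[[nm]]
  structure(list(seed = as.integer(seed), stages = stages,
                 simulate = isTRUE(simulate), inputs = inputs,
                 sim = sim, params = defaults),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
                                  c("seed", "stages", "simulate", "inputs",
                                    "sim", "params"))])
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order against simulated or
#' loaded inputs, writes every stage artifact as TSV under `out_dir`,
#' records an md5 manifest of all outputs (`manifest.json`, which also
#' echoes the seed and all thresholds so every reported number is
#' auditable), and returns a consolidated report. With `resume = TRUE`, a
#' stage whose outputs already exist under an identical configuration
#' hash is skipped.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param resume skip stages whose outputs are already present from an
#'   identical configuration.
#' @return Report list with one entry per executed stage plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!config$simulate) {
    need <- c("vcf", "samples", "crosses", "expression")
    for (nm in need) {
      if (is.null(config$inputs[[nm]]))
        stop("simulate = FALSE but no '", nm, "' input path given")
      if (!file.exists(config$inputs[[nm]]))
        stop("input file missing before any stage ran: ",
             config$inputs[[nm]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  cfg_hash <- {
    tf <- tempfile(); writeLines(cfg_json, tf)
    h <- unname(tools::md5sum(tf)); unlink(tf); h
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  if (resume && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    prev_files <- file.path(out_dir, names(prev$files))
    if (identical(prev$config_hash, unname(cfg_hash)) &&
        all(file.exists(prev_files)) &&
        identical(as.list(stats::setNames(unname(tools::md5sum(prev_files)),
                                          basename(prev_files))),
                  lapply(prev$files, identity))) {
      message("[resume] configuration and outputs unchanged; skipping all stages")
      return(invisible(list(manifest = prev, resumed = TRUE)))
    }
  }
  report <- list()
  t_all <- list()
  log_stage <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  # -- inputs ----------------------------------------------------------
  if (config$simulate) {
    sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    study <- simulate_study(sc)
    gm <- study$genotypes
    samples <- study$samples
    crosses <- study$crosses
    expr <- study$expression
    cohorts <- study$cohorts
    pattern <- default_pattern_from_study(study)
    G_bp <- sc$n_chromosomes * sc$chrom_length_bp
  } else {
    study <- NULL
    gm <- read_vcf(config$inputs$vcf)
    samples <- read_sample_table(config$inputs$samples)
    crosses <- read_cross_table(config$inputs$crosses)
    expr <- read_expression_table(config$inputs$expression)
    cohorts <- NULL
    pattern <- if (!is.null(config$inputs$pattern))
      read_pattern_tsv(config$inputs$pattern) else NULL
    G_bp <- config$inputs$genome_bp %||%
      sum(tapply(gm$sites$pos, gm$sites$chrom, max))
  }

  outputs <- character()

  if ("segscan" %in% config$stages) {
    pr <- config$params$segscan
    t0 <- Sys.time()
    if (is.null(pattern)) stop("segscan requires a segregation pattern")
    retained <- segregation_pattern_filter(gm, pattern)
    scan <- enrichment_scan(retained, G_bp = G_bp,
                            window_bp = pr$window_bp, step_bp = pr$step_bp,
                            fold_threshold = pr$fold_threshold)
    f1 <- file.path(out_dir, "segscan_retained.tsv")
    f2 <- file.path(out_dir, "segscan_segments.tsv")
    write_interval_tsv(retained, f1)
    if (!is.null(scan$segments)) write_interval_tsv(scan$segments, f2)
    outputs <- c(outputs, f1, if (!is.null(scan$segments)) f2)
    report$segscan <- list(
      n_retained = nrow(retained),
      top_segment = scan$top_segment,
      params = pr)
    log_stage("segscan", sprintf(
      "%d retained variants; top segment %s:%s-%s (fold %.1f) [%.1fs]",
      nrow(retained),
      scan$top_segment$chrom, scan$top_segment$start, scan$top_segment$end,
      scan$top_segment$fold, as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("assoc" %in% config$stages) {
    pr <- config$params$assoc
    t0 <- Sys.time()
    if (is.null(cohorts)) stop("assoc stage requires cohort counts ",
                               "(simulated studies provide them)")
    aff <- cohorts[cohorts$cohort == "affected_pets", ]
    c1 <- cohorts[cohorts$cohort == "control_pets_1", ]
    c2 <- cohorts[cohorts$cohort == "control_pets_2", ]
    pooled_controls <- c1
    pooled_controls[, c("n_homalt", "n_het", "n_homref", "n_other", "n")] <-
      c1[, c("n_homalt", "n_het", "n_homref", "n_other", "n")] +
      c2[, c("n_homalt", "n_het", "n_homref", "n_other", "n")]
    rep_tab <- association_report(rbind(aff, pooled_controls),
                                  models = pr$model, alpha = pr$alpha,
                                  m_tests = 1L, yates = pr$yates)
    grad <- af_gradient_check(aff, c1, c2)
    f1 <- file.path(out_dir, "assoc_report.tsv")
    utils::write.table(rep_tab, f1, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    outputs <- c(outputs, f1)
    report$assoc <- list(tests = rep_tab, af = grad$af,
                         gradient = grad$gradient,
                         pairwise = grad$pairwise, params = pr)
    log_stage("assoc", sprintf(
      "%s-model p = %.3g; AF gradient %s [%.1fs]", pr$model, rep_tab$p[1],
      if (grad$gradient) "holds" else "violated",
      as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("glmm" %in% config$stages) {
    pr <- config$params$glmm
    t0 <- Sys.time()
    y <- as.integer(samples$phenotype == "xx_dsd")
    K <- centered_grm(gm)
    pcs <- tryCatch(
      suppressWarnings(genotype_pca(gm, maf_min = pr$pca_maf_min,
                                    thin_every = pr$pca_thin_every,
                                    k = pr$n_pcs)),
      error = function(e) NULL)
    X <- cbind(intercept = 1,
               if (!is.null(pcs)) pcs[samples$sample_id, , drop = FALSE])
    while (ncol(X) > 1L && qr(X)$rank < ncol(X))
      X <- X[, -ncol(X), drop = FALSE]
    fit <- fit_null_glmm(y, X, K)
    scan_gm <- gwas_snp_prefilter(gm, maf_min = pr$maf_min,
                                  thin_every = pr$thin_every)
    scan <- score_test_scan(fit, scan_gm)
    scan$p_bh <- bh_adjust(scan$p)
    f1 <- file.path(out_dir, "glmm_scan.tsv")
    utils::write.table(scan, f1, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    outputs <- c(outputs, f1)
    top <- scan[which.min(scan$p), ]
    report$glmm <- list(tau = fit$tau, converged = fit$converged,
                        n_sites_tested = nrow(scan), top = top,
                        n_bh_hits = sum(scan$p_bh < pr$bh_max),
                        params = pr)
    log_stage("glmm", sprintf(
      "tau = %.3f; %d sites tested; top %s:%d p = %.2g (BH %.3g) [%.1fs]",
      fit$tau, nrow(scan), top$chrom, top$pos, top$p, top$p_bh,
      as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("lethality" %in% config$stages) {
    pr <- config$params$lethality
    t0 <- Sys.time()
    screen <- lethality_screen(crosses, alpha = pr$alpha, yates = pr$yates)
    f1 <- file.path(out_dir, "lethality_report.tsv")
    utils::write.table(
      cbind(screen$pooled,
            flagged = screen$pooled$class %in% screen$flagged),
      f1, quote = FALSE, sep = "\t", row.names = FALSE)
    outputs <- c(outputs, f1)
    report$lethality <- list(flagged = screen$flagged,
                             pooled_test = screen$pooled_test,
                             params = pr)
    log_stage("lethality", sprintf(
      "flagged class(es): %s (pooled chi2 = %.2f, p = %.2g) [%.1fs]",
      if (length(screen$flagged)) paste(screen$flagged, collapse = ", ")
      else "none",
      screen$pooled_test$statistic, screen$pooled_test$p,
      as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("expression" %in% config$stages) {
    pr <- config$params$expression
    t0 <- Sys.time()
    de <- stringent_de_filter(expr, q_max = pr$q_max,
                              min_abs_log2fc = pr$min_abs_log2fc,
                              min_group_fpkm = pr$min_group_fpkm)
    bins <- genomic_binning(de, bin_bp = pr$bin_bp)
    f1 <- file.path(out_dir, "expression_de.tsv")
    f2 <- file.path(out_dir, "expression_bins.tsv")
    utils::write.table(de, f1, quote = FALSE, sep = "\t", row.names = FALSE)
    utils::write.table(bins$bins, f2, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    outputs <- c(outputs, f1, f2)
    report$expression <- list(n_de = nrow(de),
                              n_down = sum(de$direction == "down"),
                              top_down_bin = bins$top_down, params = pr)
    log_stage("expression", sprintf(
      "%d stringent-DE rows (%d down) [%.1fs]", nrow(de),
      sum(de$direction == "down"),
      as.numeric(Sys.time() - t0, units = "secs")))
  }

  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   params = config$params,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(outputs)), basename(outputs))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             manifest_path)
  report$manifest <- manifest
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
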