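# Forward simulator for the study design the pipeline analyzes: a
# two-founder-breed pedigree segregating a recessive insertion inside a
# non-recombining linked variant block, genotype-by-background penetrance,
# genotype-by-background embryonic lethality in breeding crosses, three pet
# cohorts with an allele-frequency gradient, and FPKM expression tables with
# planted fold changes. Every stochastic step draws from a named substream
# of the single top-level seed, so whole studies reproduce bit-for-bit.

#' Derive a named substream seed from a top-level seed
#'
#' Deterministic 32-bit-safe hash mixing the top-level seed with a stream
#' name, so independent simulator stages never share a random stream.
#'
#' @param seed integer top-level seed.
#' @param name character stream name.
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
substream <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulation configuration
#'
#' Assembles and validates the full set of generator parameters; any field
#' can be overridden by name. Defaults emulate the study conditions: a
#' cocker-spaniel-by-beagle (ACS x BGL) model pedigree with backcrosses and
#' intercrosses segregating a recessive insertion carried by the ACS
#' founder sires; a ~20,000-variant genome with a 250-site linked block in
#' a 2 Mb interval of one chromosome; penetrance rising with ACS background
#' in insertion homozygotes; homozygote lethality on >= 50% German
#' shorthaired pointer (GSHP) background; three pet cohorts whose insertion
#' allele frequencies follow the published gradient (0.405, 0.292, 0.175);
#' and expression tables with designated ovary-pathway genes planted >=
#' 2-fold down in affected samples.
#'
#' @param seed top-level integer seed.
#' @param ... named overrides of any default field.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chromosomes = 10L,
    chrom_length_bp = 6e7,
    n_background_variants = 19750L,
    causal_chrom = "chr9",
    causal_interval = c(5e6, 7e6),
    causal_pos = 6048201L,
    n_linked_variants = 249L,
    recombination_rate = 0,
    background_af_range = c(0.05, 0.95),
    # breeds & pedigree
    causal_breed = "ACS",
    other_breed = "BGL",
    n_founder_sires = 2L,
    n_founder_dams = 6L,
    n_generations = 3L,
    n_matings_per_generation = 6L,
    offspring_per_mating = 4L,
    backcross_prob = 0.3,
    # phenotype model
    penetrance_params = list(pi_hom_max = 0.9, pi_het = 0.1,
                             background_coefficient = 0.5),
    # embryonic lethality rule
    lethality_rule = list(genotype = "hom_alt", breed = "GSHP",
                          min_fraction = 0.5, survive = 0),
    # pet cohorts (published genotyped sizes and allele frequencies)
    cohort_n = c(affected_pets = 63L, control_pets_1 = 65L,
                 control_pets_2 = 60L),
    cohort_af = c(affected_pets = 0.405, control_pets_1 = 0.292,
                  control_pets_2 = 0.175),
    # expression tables
    expression_params = list(
      n_genes = 10000L, n_affected = 6L, n_control = 6L,
      sigma = 0.25, baseline_meanlog = log(2), baseline_sdlog = 1.5,
      n_planted = 300L, planted_log2fc = -2, planted_min_mean_fpkm = 10,
      age_groups = c("d37_39", "d42_44"))
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  pp <- cfg$penetrance_params
  probs <- c(pp$pi_hom_max, pp$pi_het, cfg$lethality_rule$survive,
             cfg$backcross_prob, cfg$cohort_af)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_founder_sires < 1L || cfg$n_founder_dams < 1L)
    stop("impossible design: pedigree needs founders of both breeds")
  ci <- cfg$causal_interval
  if (ci[1] < 1 || ci[2] > cfg$chrom_length_bp || ci[1] > ci[2])
    stop("causal_interval outside the simulated genome")
  if (cfg$causal_pos < ci[1] || cfg$causal_pos > ci[2])
    stop("causal_pos outside causal_interval")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the model pedigree
#'
#' Founder sires of the causal breed and founder dams of the other breed,
#' followed by `n_generations` of matings that are founder backcrosses with
#' probability `backcross_prob` and within-generation intercrosses
#' otherwise. Sexes are drawn 1:1; SRY status follows sex (males positive,
#' females negative) and males are phenotyped `xy_male`. Female phenotypes
#' are `unknown` until [apply_penetrance()].
#'
#' @param config a [sim_config()].
#' @return List with `pedigree` (a [pedigree_graph()]) and `samples` (the
#'   sample table).
#' @export
simulate_pedigree <- function(config) {
  set.seed(substream(config$seed, "pedigree"))
  rows <- list()
  add <- function(id, sire, dam, breed, sex, gen) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = id, sire = sire, dam = dam, breed = breed,
      cohort = "model_pedigree",
      sry = if (sex == "M") "positive" else "negative",
      phenotype = if (sex == "M") "xy_male" else "unknown",
      gonad = "none_recorded", sex = sex, generation = gen,
      stringsAsFactors = FALSE)
  }
  sires <- sprintf("%s%d", config$causal_breed, seq_len(config$n_founder_sires))
  dams <- sprintf("%s%d", config$other_breed, seq_len(config$n_founder_dams))
  for (s in sires) add(s, "0", "0", config$causal_breed, "M", 0L)
  for (d in dams) add(d, "0", "0", config$other_breed, "F", 0L)
  cross_label <- paste0(config$causal_breed, "/", config$other_breed)
  counter <- 0L
  prev_m <- character(); prev_f <- character()
  cur_m <- sires; cur_f <- dams
  for (g in seq_len(config$n_generations)) {
    new_m <- character(); new_f <- character()
    n_mat <- if (g == 1L) length(dams) else config$n_matings_per_generation
    for (m in seq_len(n_mat)) {
      if (g == 1L) {
        sire <- sample(sires, 1L); dam <- dams[m]
      } else if (stats::runif(1) < config$backcross_prob || !length(cur_m)) {
        sire <- sample(sires, 1L); dam <- sample(cur_f, 1L)
      } else {
        sire <- sample(cur_m, 1L); dam <- sample(cur_f, 1L)
      }
      for (k in seq_len(config$offspring_per_mating)) {
        counter <- counter + 1L
        id <- sprintf("C%04d", counter)
        sex <- sample(c("M", "F"), 1L)
        add(id, sire, dam, cross_label, sex, g)
        if (sex == "M") new_m <- c(new_m, id) else new_f <- c(new_f, id)
      }
    }
    cur_m <- new_m; cur_f <- new_f
    if (!length(cur_f)) cur_f <- dams
  }
  samples <- do.call(rbind, rows)
  list(pedigree = pedigree_graph(samples), samples = samples)
}

#' Simulate genotypes through a pedigree
#'
#' Founder background haplotypes are drawn from per-breed allele-frequency
#' profiles and transmitted with exact Mendelian segregation, each
#' background site independently. The causal insertion and its
#' `n_linked_variants` neighbours form a single block transmitted as one
#' unit: founders of the causal breed carry the insertion haplotype on both
#' chromosomes, all other founders carry the reference haplotype. With
#' `recombination_rate > 0`, each transmitted linked-block state may swap
#' to the other parental haplotype at the block edge with that probability
#' per meiosis; the default 0 keeps linked sites perfectly correlated with
#' the causal site.
#'
#' @param ped result of [simulate_pedigree()] (or a list with `pedigree`
#'   and `samples`).
#' @param config a [sim_config()].
#' @return List with `matrix` (a [genotype_matrix()], sites sorted by
#'   chromosome and position) and `truth` (causal site index, block site
#'   indices, per-sample carrier dosage).
#' @export
simulate_genotypes <- function(ped, config) {
  set.seed(substream(config$seed, "genotypes"))
  samples <- ped$samples
  n <- nrow(samples)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  if (!config$causal_chrom %in% chroms)
    chroms[length(chroms)] <- config$causal_chrom
  # -- site table -----------------------------------------------------
  nb <- config$n_background_variants
  bg <- data.frame(
    chrom = sample(chroms, nb, replace = TRUE),
    pos = sample.int(config$chrom_length_bp, nb, replace = TRUE),
    stringsAsFactors = FALSE)
  nl <- config$n_linked_variants
  ci <- config$causal_interval
  linked_pos <- sort(sample(seq(ci[1], ci[2]), nl))
  block <- data.frame(
    chrom = config$causal_chrom,
    pos = as.integer(c(linked_pos, config$causal_pos)),
    stringsAsFactors = FALSE)
  is_causal <- c(rep(FALSE, nl), TRUE)
  is_block <- c(rep(FALSE, nb), rep(TRUE, nl + 1L))
  sites <- rbind(bg, block)
  sites$ref <- "A"
  sites$alt <- "G"
  sites$alt[nb + nl + 1L] <- "GG"   # the causal guanine insertion
  is_causal <- c(rep(FALSE, nb), is_causal)
  ord <- order(match(sites$chrom, chroms), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  is_block <- is_block[ord]
  is_causal <- is_causal[ord]
  rownames(sites) <- NULL
  bg_idx <- which(!is_block)
  # -- breed allele-frequency profiles for background sites ------------
  breeds <- unique(samples$breed[samples$sire == "0" & samples$dam == "0"])
  afr <- config$background_af_range
  af <- matrix(stats::runif(length(breeds) * length(bg_idx), afr[1], afr[2]),
               nrow = length(breeds), dimnames = list(breeds, NULL))
  # -- founder haplotypes & Mendelian transmission ---------------------
  H1 <- matrix(NA_integer_, n, length(bg_idx))
  H2 <- matrix(NA_integer_, n, length(bg_idx))
  blk1 <- integer(n); blk2 <- integer(n)      # carrier-haplotype indicator
  lnk1 <- integer(n); lnk2 <- integer(n)      # linked-site state per haplotype
  idx <- stats::setNames(seq_len(n), samples$sample_id)
  for (id in ped$pedigree$order) {
    i <- idx[[id]]
    if (samples$sire[i] == "0" && samples$dam[i] == "0") {
      p <- af[samples$breed[i], ]
      H1[i, ] <- stats::rbinom(length(p), 1L, p)
      H2[i, ] <- stats::rbinom(length(p), 1L, p)
      carr <- as.integer(samples$breed[i] == config$causal_breed)
      blk1[i] <- carr; blk2[i] <- carr
      lnk1[i] <- carr; lnk2[i] <- carr
    } else {
      for (side in 1:2) {
        pid <- if (side == 1L) samples$sire[i] else samples$dam[i]
        j <- idx[[pid]]
        pick <- stats::rbinom(length(bg_idx), 1L, 0.5) == 1L
        hap <- ifelse(pick, H1[j, ], H2[j, ])
        bpick <- stats::runif(1) < 0.5
        bcar <- if (bpick) blk1[j] else blk2[j]
        blnk <- if (bpick) lnk1[j] else lnk2[j]
        if (config$recombination_rate > 0 &&
            stats::runif(1) < config$recombination_rate)
          blnk <- if (bpick) lnk2[j] else lnk1[j]
        if (side == 1L) {
          H1[i, ] <- hap; blk1[i] <- bcar; lnk1[i] <- blnk
        } else {
          H2[i, ] <- hap; blk2[i] <- bcar; lnk2[i] <- blnk
        }
      }
    }
  }
  calls <- matrix(NA_integer_, n, nrow(sites))
  calls[, bg_idx] <- H1 + H2
  calls[, which(is_block & !is_causal)] <- lnk1 + lnk2
  calls[, which(is_causal)] <- blk1 + blk2
  gm <- genotype_matrix(calls, sites, samples$sample_id)
  list(matrix = gm,
       truth = list(causal_index = which(is_causal),
                    block_indices = which(is_block),
                    causal_interval = ci,
                    causal_chrom = config$causal_chrom,
                    carrier_dosage = stats::setNames(blk1 + blk2,
                                                     samples$sample_id)))
}

#' Apply genotype-by-background penetrance
#'
#' Only SRY-negative individuals are eligible for the affected (`xx_dsd`)
#' phenotype. With `b` the expected causal-founder-breed background
#' fraction and parameters `(pi_hom_max, pi_het, background_coefficient)`:
#' insertion homozygotes are affected with probability
#' `clamp(pi_hom_max - background_coefficient * (1 - b), 0, 1)`,
#' heterozygotes with probability `pi_het * b`, and non-carriers never.
#' Affected individuals receive a gonad-histology class whose testis
#' content increases with `b` (ovary, ovotestis below/above half testis,
#' testis); everyone else keeps `none_recorded`.
#'
#' @param samples sample table.
#' @param causal_genotype integer dosage (0/1/2) at the causal site, one
#'   per sample row.
#' @param background numeric causal-breed background fraction per sample.
#' @param config a [sim_config()].
#' @return The sample table with `phenotype` and `gonad` realized.
#' @export
apply_penetrance <- function(samples, causal_genotype, background, config) {
  set.seed(substream(config$seed, "penetrance"))
  pp <- config$penetrance_params
  p_aff <- numeric(nrow(samples))
  hom <- causal_genotype == 2L
  het <- causal_genotype == 1L
  p_aff[hom] <- pmin(pmax(
    pp$pi_hom_max - pp$background_coefficient * (1 - background[hom]), 0), 1)
  p_aff[het] <- pp$pi_het * background[het]
  eligible <- samples$sry == "negative"
  p_aff[!eligible] <- 0
  aff <- stats::runif(nrow(samples)) < p_aff
  samples$phenotype[eligible] <- ifelse(aff[eligible], "xx_dsd", "unaffected")
  sev <- c("ov", "ovt_lt_half_t", "ovt_gt_half_t", "t")
  samples$gonad[aff] <- sev[pmin(4L, 1L + floor(background[aff] * 4))]
  samples
}

#' Apply an embryonic-lethality rule to conceptuses
#'
#' Conceptuses whose genotype class matches the rule and whose breed
#' background fraction is at least the rule threshold survive with
#' probability `rule$survive` (default 0: none born). Non-matching
#' conceptuses always survive.
#'
#' @param conceptuses data.frame with columns `genotype`
#'   (`hom_ref`/`het`/`hom_alt`) and `breed_fraction` (fraction of the
#'   rule's breed).
#' @param config a [sim_config()].
#' @return List with `survivors` (subset of the input) and `truth`
#'   (`n_conceived`, `n_removed`, `removed_by_class`).
#' @export
apply_lethality <- function(conceptuses, config) {
  set.seed(substream(config$seed, "lethality"))
  rule <- config$lethality_rule
  match_rule <- conceptuses$genotype == rule$genotype &
    conceptuses$breed_fraction >= rule$min_fraction
  die <- match_rule & stats::runif(nrow(conceptuses)) >= rule$survive
  list(survivors = conceptuses[!die, , drop = FALSE],
       truth = list(n_conceived = nrow(conceptuses),
                    n_removed = sum(die),
                    removed_by_class = table(conceptuses$genotype[die])))
}

#' Simulate breeding-cross outcomes under the lethality rule
#'
#' For each requested cross, conceptus genotypes at the focal site are
#' drawn by exact Mendelian segregation from the parental genotypes, the
#' lethality rule is applied at the stated offspring breed fraction, and
#' surviving offspring are tallied per genotype class.
#'
#' @param crosses data.frame with columns `sire_gt`, `dam_gt`
#'   (`hom_ref`/`het`/`hom_alt`), `n_conceptuses`, `breed_fraction`
#'   (offspring fraction of the lethality-rule breed). Default: two crosses
#'   patterned on the published breeding experiments (het x het with 17
#'   conceptuses expected born, het dam x hom-alt sire with 22, both on
#'   full at-risk background) -- conceptus numbers are inflated so that the
#'   expected number *born* matches when the rule removes homozygotes.
#' @param config a [sim_config()].
#' @return List with `outcomes` (a cross-outcome data.frame with columns
#'   `sire_gt dam_gt n_homref n_het n_homalt`) and `truth` (lethal
#'   conceptus count per cross).
#' @export
simulate_crosses <- function(config, crosses = NULL) {
  set.seed(substream(config$seed, "crosses"))
  if (is.null(crosses)) {
    crosses <- data.frame(
      sire_gt = c("het", "hom_alt"),
      dam_gt = c("het", "het"),
      n_conceptuses = c(23L, 44L),
      breed_fraction = c(1, 0.5),
      stringsAsFactors = FALSE)
  }
  rule <- config$lethality_rule
  gt_prob <- function(g) switch(g, hom_ref = c(1, 0), het = c(0.5, 0.5),
                                hom_alt = c(0, 1))
  out <- list(); truth <- integer(nrow(crosses))
  for (i in seq_len(nrow(crosses))) {
    ps <- gt_prob(crosses$sire_gt[i]); pd <- gt_prob(crosses$dam_gt[i])
    n <- crosses$n_conceptuses[i]
    a1 <- sample(0:1, n, replace = TRUE, prob = ps)
    a2 <- sample(0:1, n, replace = TRUE, prob = pd)
    gt <- GT_LEVELS[a1 + a2 + 1L]
    conceptuses <- data.frame(genotype = gt,
                              breed_fraction = crosses$breed_fraction[i],
                              stringsAsFactors = FALSE)
    match_rule <- conceptuses$genotype == rule$genotype &
      conceptuses$breed_fraction >= rule$min_fraction
    die <- match_rule & stats::runif(n) >= rule$survive
    born <- conceptuses$genotype[!die]
    truth[i] <- sum(die)
    out[[i]] <- data.frame(
      sire_gt = crosses$sire_gt[i], dam_gt = crosses$dam_gt[i],
      n_homref = sum(born == "hom_ref"), n_het = sum(born == "het"),
      n_homalt = sum(born == "hom_alt"), stringsAsFactors = FALSE)
  }
  list(outcomes = do.call(rbind, out),
       truth = list(lethal_per_cross = truth))
}

#' Simulate pet-cohort genotype counts at the focal locus
#'
#' Draws each cohort's genotypes at the insertion site under
#' Hardy-Weinberg proportions at that cohort's configured allele
#' frequency, reproducing the study's allele-frequency gradient across
#' affected pets and the two control groups.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per cohort: `cohort n_homalt n_het
#'   n_homref n_other n`.
#' @export
simulate_cohorts <- function(config) {
  set.seed(substream(config$seed, "cohorts"))
  out <- lapply(names(config$cohort_n), function(co) {
    n <- config$cohort_n[[co]]; q <- config$cohort_af[[co]]
    g <- stats::rbinom(n, 2L, q)
    data.frame(cohort = co, n_homalt = sum(g == 2L), n_het = sum(g == 1L),
               n_homref = sum(g == 0L), n_other = 0L, n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate an FPKM expression table with planted fold changes
#'
#' Per-gene per-sample FPKM is lognormal around a gene-specific baseline;
#' `n_planted` designated genes (the stand-ins for ovary-pathway targets)
#' have their affected-group mean multiplied by `2^planted_log2fc` in every
#' age group, and their baselines are floored at `planted_min_mean_fpkm`
#' so the expression gate is reachable. q-values come from a Welch t-test
#' on log2(FPKM + 0.1) followed by Benjamini-Hochberg within each age
#' group -- a documented stand-in for the cuffdiff statistic, used only to
#' make the downstream filter exercisable. Gene starts are scattered
#' uniformly over the simulated chromosomes.
#'
#' @param config a [sim_config()].
#' @return List with `records` (long data.frame, one row per gene x age
#'   group: `gene_id chrom start age_group fpkm_affected fpkm_control
#'   log2fc q_value`) and `truth` (planted gene ids and their log2 fold
#'   change).
#' @export
simulate_expression <- function(config) {
  set.seed(substream(config$seed, "expression"))
  ep <- config$expression_params
  ng <- ep$n_genes
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  genes <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(ng)),
    chrom = sample(chroms, ng, replace = TRUE),
    start = sample.int(config$chrom_length_bp, ng, replace = TRUE),
    stringsAsFactors = FALSE)
  meanlog <- stats::rnorm(ng, ep$baseline_meanlog, ep$baseline_sdlog)
  planted <- sample.int(ng, ep$n_planted)
  meanlog[planted] <- pmax(meanlog[planted], log(ep$planted_min_mean_fpkm))
  shift <- numeric(ng)
  shift[planted] <- ep$planted_log2fc * log(2)
  na <- ep$n_affected; nc <- ep$n_control
  rec <- list()
  for (ag in ep$age_groups) {
    A <- matrix(stats::rlnorm(ng * na, meanlog + shift, ep$sigma), ng, na)
    C <- matrix(stats::rlnorm(ng * nc, meanlog, ep$sigma), ng, nc)
    la <- log2(A + 0.1); lc <- log2(C + 0.1)
    ma <- rowMeans(la); mc <- rowMeans(lc)
    va <- apply(la, 1L, stats::var); vc <- apply(lc, 1L, stats::var)
    se2 <- va / na + vc / nc
    tstat <- (ma - mc) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vc / nc)^2 / (nc - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    mean_a <- rowMeans(A); mean_c <- rowMeans(C)
    l2fc <- log2(ifelse(mean_a > 0, mean_a, 0.1) /
                 ifelse(mean_c > 0, mean_c, 0.1))
    rec[[ag]] <- data.frame(genes, age_group = ag, fpkm_affected = mean_a,
                            fpkm_control = mean_c, log2fc = l2fc,
                            q_value = pmax(q, .Machine$double.xmin),
                            stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, c(rec, make.row.names = FALSE)),
       truth = list(planted_genes = genes$gene_id[planted],
                    planted_log2fc = ep$planted_log2fc))
}

#' Simulate a complete study
#'
#' Runs the pedigree, genotype, penetrance, cross, cohort and expression
#' generators from one configuration and assembles the results with a
#' ground-truth record (causal site, per-sample carrier dosage, lethal
#' conceptus counts, planted expression genes).
#'
#' @param config a [sim_config()].
#' @return Object of class `simulated_study`.
#' @export
simulate_study <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  gen <- simulate_genotypes(ped, config)
  b <- breed_fraction(ped$pedigree, config$causal_breed)
  dosage <- gen$truth$carrier_dosage[ped$samples$sample_id]
  samples <- apply_penetrance(ped$samples, dosage, b, config)
  crosses <- simulate_crosses(config)
  cohorts <- simulate_cohorts(config)
  expr <- simulate_expression(config)
  structure(list(
    config = config,
    pedigree = ped$pedigree,
    samples = samples,
    genotypes = gen$matrix,
    crosses = crosses$outcomes,
    cohorts = cohorts,
    expression = expr$records,
    truth = list(causal_index = gen$truth$causal_index,
                 block_indices = gen$truth$block_indices,
                 causal_chrom = gen$truth$causal_chrom,
                 causal_interval = gen$truth$causal_interval,
                 carrier_dosage = gen$truth$carrier_dosage,
                 background_fraction = b,
                 lethal_per_cross = crosses$truth$lethal_per_cross,
                 planted_genes = expr$truth$planted_genes)),
    class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(paste0("simulated_study: %d pedigree samples, %d sites ",
                     "(causal %s:%d), %d crosses, %d cohort rows, ",
                     "%d expression rows\n"),
              nrow(x$samples), n_sites(x$genotypes), x$truth$causal_chrom,
              x$genotypes$sites$pos[x$truth$causal_index],
              nrow(x$crosses), nrow(x$cohorts), nrow(x$expression)))
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Emits the genotypes as VCF, the sample table, cross outcomes and
#' expression records as TSV, into `dir`.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             samples = file.path(dir, "samples.tsv"),
             crosses = file.path(dir, "crosses.tsv"),
             expression = file.path(dir, "expression.tsv"))
  write_vcf(study$genotypes, paths[["vcf"]])
  write_sample_table(study$samples, paths[["samples"]])
  write_cross_table(study$crosses, paths[["crosses"]])
  write_expression_table(study$expression, paths[["expression"]])
  paths
}
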