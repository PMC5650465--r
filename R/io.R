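# Readers/writers for the plain-text formats the pipeline consumes:
# VCF (GT fields only), PLINK text PED/MAP, and the TSV dialects for sample
# metadata, cross outcomes, expression tables and segregation patterns.
# All writers emit files that re-read bit-stably given fixed input ordering.

GT_LEVELS <- c("hom_ref", "het", "hom_alt")

COHORT_LEVELS <- c("model_pedigree", "affected_pets", "control_pets_1",
                   "control_pets_2", "external_control")
SRY_LEVELS <- c("positive", "negative", "untested")
PHENOTYPE_LEVELS <- c("unaffected", "xx_dsd", "xy_male", "unknown")
GONAD_LEVELS <- c("ov", "ovt_lt_half_t", "ovt_gt_half_t", "t", "none_recorded")

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses the GT field of a VCF v4.x file (via \pkg{vcfR}). Biallelic
#' records map directly; multiallelic records are split into one biallelic
#' site per alternate allele (with a warning), where a genotype counts the
#' dosage of that alternate allele and genotypes containing any *other*
#' alternate allele at the record are set missing for the split site.
#' Half-calls and `./.` are missing. Phased separators are accepted.
#'
#' @param path VCF file (plain text or bgzip).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)    # single-record VCF -> bare vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field")
  samples <- colnames(gt_raw)
  # allele-index pairs; NA for missing/half calls
  parse_gt <- function(g) {
    g[g %in% c(".", "./.", ".|.")] <- NA
    sp <- strsplit(g, "[/|]")
    a1 <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(sp, function(z)
      if (length(z) >= 2L) z[2L] else NA_character_, "")))
    cbind(a1, a2)
  }
  out_calls <- list(); out_sites <- list()
  multi <- FALSE
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    al <- parse_gt(gt_raw[i, ])
    if (length(alts) > 1L) multi <- TRUE
    for (k in seq_along(alts)) {
      dos <- rowSums(al == k)              # NA if any allele missing
      other <- rowSums(al != 0L & al != k) # carries a different alt
      dos[!is.na(other) & other > 0L] <- NA_integer_
      out_calls[[length(out_calls) + 1L]] <- dos
      out_sites[[length(out_sites) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], stringsAsFactors = FALSE)
    }
  }
  if (multi) warning("multiallelic record(s) split into biallelic sites")
  genotype_matrix(do.call(cbind, out_calls),
                  do.call(rbind, out_sites), samples)
}

#' Write a genotype matrix as a minimal VCF v4.2
#'
#' Emits one biallelic record per site with GT-only FORMAT; missing calls
#' become `./.`. Coordinates are written 1-based as stored.
#'
#' @param x a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_sites(x)), function(j) {
    calls <- x$calls[, j]
    g <- ifelse(is.na(calls), "./.", gt_str[calls + 1L])
    paste(c(x$sites$chrom[j], x$sites$pos[j], ".", x$sites$ref[j],
            x$sites$alt[j], ".", "PASS", ".", "GT", g), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read PLINK text PED/MAP genotypes
#'
#' Whitespace-delimited PED with the 6 leading columns (family, individual,
#' father, mother, sex, phenotype) followed by two allele columns per site;
#' MAP with chrom, id, cM, pos. The missing allele code is `"0"`. PLINK text
#' files carry no reference-allele designation, so the first non-missing
#' allele seen at a site (scanning samples in file order) defines the
#' reference unless `ref_alleles` supplies one per site. The PED phenotype
#' column is returned but the sample metadata table remains authoritative.
#'
#' @param ped_path,map_path PED and MAP files.
#' @param ref_alleles optional character vector, one reference allele per
#'   MAP site.
#' @return List with `matrix` (a [genotype_matrix()]) and `fam` (the six
#'   leading PED columns as a data.frame).
#' @export
read_plink_text <- function(ped_path, map_path, ref_alleles = NULL) {
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  p <- nrow(map)
  if (ncol(ped) != 6L + 2L * p)
    stop(sprintf("PED has %d columns but MAP implies %d (6 + 2 x %d sites)",
                 ncol(ped), 6L + 2L * p, p))
  fam <- ped[, 1:6]
  names(fam) <- c("family", "sample_id", "father", "mother", "sex",
                  "phenotype")
  calls <- matrix(NA_integer_, nrow(ped), p)
  refs <- character(p); alts <- character(p)
  for (j in seq_len(p)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    miss <- a1 == "0" | a2 == "0"
    seen <- c(a1[!miss], a2[!miss])
    ref <- if (!is.null(ref_alleles)) ref_alleles[j]
           else if (length(seen)) seen[1L] else "N"
    alt <- setdiff(unique(seen), ref)
    if (length(alt) > 1L)
      stop(sprintf("site %s is not biallelic (alleles %s)", map$id[j],
                   paste(unique(seen), collapse = ",")))
    if (length(alt) == 0L) alt <- "N"
    calls[, j] <- (a1 == alt) + (a2 == alt)
    calls[miss, j] <- NA_integer_
    refs[j] <- ref; alts[j] <- alt
  }
  sites <- data.frame(chrom = map$chrom, pos = map$pos, ref = refs,
                      alt = alts, stringsAsFactors = FALSE)
  list(matrix = genotype_matrix(calls, sites, fam$sample_id), fam = fam)
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_plink_text()]; missing calls become `0 0`.
#'
#' @param x a `genotype_matrix`.
#' @param ped_path,map_path output files.
#' @param fam optional data.frame of the six leading PED columns; defaults
#'   to family = sample id, unknown parents, sex/phenotype 0.
#' @return `ped_path`, invisibly.
#' @export
write_plink_text <- function(x, ped_path, map_path, fam = NULL) {
  if (is.null(fam)) {
    fam <- data.frame(family = x$samples, sample_id = x$samples,
                      father = "0", mother = "0", sex = "0",
                      phenotype = "0", stringsAsFactors = FALSE)
  }
  map <- data.frame(x$sites$chrom,
                    paste0(x$sites$chrom, "_", x$sites$pos),
                    0, x$sites$pos)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  alle <- matrix("0", n_samples(x), 2L * n_sites(x))
  for (j in seq_len(n_sites(x))) {
    g <- x$calls[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g == 2L, x$sites$alt[j], x$sites$ref[j]))
    a2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, x$sites$alt[j], x$sites$ref[j]))
    alle[, 2L * j - 1L] <- a1
    alle[, 2L * j] <- a2
  }
  utils::write.table(cbind(fam, alle), ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(ped_path)
}

#' Read the sample/pedigree metadata table
#'
#' TSV with header `sample_id sire dam breed cohort sry phenotype gonad`.
#' Founder parents use the sentinel `"0"`. Validates the two diagnostic
#' invariants: an `xx_dsd` phenotype requires SRY-negative status and
#' `xy_male` requires SRY-positive.
#'
#' @param path TSV file.
#' @return data.frame of sample records.
#' @export
read_sample_table <- function(path) {
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  validate_sample_table(s)
}

#' @rdname read_sample_table
#' @param samples data.frame to validate (same columns as the TSV).
#' @export
validate_sample_table <- function(samples) {
  need <- c("sample_id", "sire", "dam", "breed", "cohort", "sry",
            "phenotype", "gonad")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(samples$cohort), COHORT_LEVELS)
  if (length(bad)) stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$sry), SRY_LEVELS)
  if (length(bad)) stop("unknown sry status: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$phenotype), PHENOTYPE_LEVELS)
  if (length(bad)) stop("unknown phenotype code: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$gonad), GONAD_LEVELS)
  if (length(bad)) stop("unknown gonad class: ", paste(bad, collapse = ", "))
  viol <- samples$phenotype == "xx_dsd" & samples$sry != "negative"
  if (any(viol)) stop("xx_dsd sample(s) not SRY-negative: ",
                      paste(samples$sample_id[viol], collapse = ", "))
  viol <- samples$phenotype == "xy_male" & samples$sry != "positive"
  if (any(viol)) stop("xy_male sample(s) not SRY-positive: ",
                      paste(samples$sample_id[viol], collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  samples
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(
    samples[, c("sample_id", "sire", "dam", "breed", "cohort", "sry",
                "phenotype", "gonad")],
    path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read/write cross-outcome tables
#'
#' TSV with header `sire_gt dam_gt n_homref n_het n_homalt`, one row per
#' (possibly pooled) cross; genotype labels are `hom_ref`/`het`/`hom_alt`.
#'
#' @param path TSV file.
#' @return data.frame of cross outcomes.
#' @export
read_cross_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sire_gt", "dam_gt", "n_homref", "n_het", "n_homalt")
                %in% names(x)))
  if (any(x$n_homref < 0 | x$n_het < 0 | x$n_homalt < 0))
    stop("negative offspring counts")
  x
}

#' @rdname read_cross_table
#' @param crosses data.frame of cross outcomes.
#' @export
write_cross_table <- function(crosses, path) {
  utils::write.table(crosses, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Read/write per-gene expression tables
#'
#' Long-format TSV, one row per gene x age group, with header `gene_id chrom
#' start age_group fpkm_affected fpkm_control log2fc q_value`. `log2fc` is
#' affected vs control (positive = higher in affected).
#'
#' @param path TSV file.
#' @return data.frame of expression records.
#' @export
read_expression_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "chrom", "start", "age_group", "fpkm_affected",
                  "fpkm_control", "log2fc", "q_value") %in% names(x)))
  if (any(x$fpkm_affected < 0 | x$fpkm_control < 0)) stop("negative FPKM")
  x
}

#' @rdname read_expression_table
#' @param records data.frame of expression records.
#' @export
write_expression_table <- function(records, path) {
  utils::write.table(records, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Read a segregation pattern from TSV
#'
#' Two columns, `sample_id` and `required_genotype` in
#' `hom_ref`/`het`/`hom_alt`.
#'
#' @param path TSV file.
#' @param missing_policy passed to [segregation_pattern()].
#' @return A `segregation_pattern`.
#' @export
read_pattern_tsv <- function(path, missing_policy = "fail_match") {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  stopifnot(all(c("sample_id", "required_genotype") %in% names(x)))
  segregation_pattern(stats::setNames(x$required_genotype, x$sample_id),
                      missing_policy = missing_policy)
}
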