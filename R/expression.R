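# Stringent differential-expression filtering of FPKM tables, verbal
# fold-change categorization, 10-Mb genomic binning of DE genes, and
# curated-pathway summaries.

FOLD_CATEGORY_LEVELS <- c(">2-fold", "~2-fold", "<2-fold", "<<2-fold")

#' Stringent differential-expression filter
#'
#' Retains a record iff all three gates pass: `q_value <= q_max`,
#' `|log2fc| >= min_abs_log2fc` (a minimum 2-fold change at the default
#' 1), and the larger group-mean FPKM is at least `min_group_fpkm` (at
#' least one comparison arm averaging FPKM >= 4 by default). Direction
#' follows the sign of `log2fc` (positive = up in affected).
#'
#' @param records expression data.frame (see [read_expression_table()]).
#' @param q_max,min_abs_log2fc,min_group_fpkm the three gate thresholds.
#' @return The retained records with `direction` (`"up"`/`"down"`) and
#'   `fold_category` columns appended.
#' @export
stringent_de_filter <- function(records, q_max = 0.05, min_abs_log2fc = 1,
                                min_group_fpkm = 4) {
  keep <- records$q_value <= q_max &
    abs(records$log2fc) >= min_abs_log2fc &
    pmax(records$fpkm_affected, records$fpkm_control) >= min_group_fpkm
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  out$fold_category <- fold_category(out$log2fc)
  rownames(out) <- NULL
  out
}

#' Verbal fold-change category
#'
#' Maps |log2FC| onto the verbal categories used in pathway reports:
#' `">2-fold"` at |log2FC| >= 1 (closed boundary: a 2-fold change
#' qualifies), `"~2-fold"` in [0.9, 1), `"<2-fold"` in [0.4, 0.9), and
#' `"<<2-fold"` below 0.4. The cut points are configurable; the defaults
#' are the package's reporting convention and are echoed in report
#' headers.
#'
#' @param log2fc finite log2 fold change(s).
#' @param cuts named numeric: `strong` (default 1), `near` (0.9), `weak`
#'   (0.4).
#' @return Character vector of category labels.
#' @export
fold_category <- function(log2fc, cuts = c(strong = 1, near = 0.9,
                                           weak = 0.4)) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  a <- abs(log2fc)
  ifelse(a >= cuts[["strong"]], ">2-fold",
         ifelse(a >= cuts[["near"]], "~2-fold",
                ifelse(a >= cuts[["weak"]], "<2-fold", "<<2-fold")))
}

#' Bin DE genes into fixed genomic intervals
#'
#' Assigns each gene to bin `floor((start - 1) / bin_bp)` on its
#' chromosome (genes spanning a boundary count by start coordinate only)
#' and tallies up- and down-regulated genes per bin. The argmax bin is
#' reported per direction, ties broken lexicographically by (chrom, bin).
#'
#' @param de_genes output of [stringent_de_filter()] (needs `chrom`,
#'   `start`, `direction`).
#' @param bin_bp bin width (default 1e7, i.e. 10 Mb).
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   genes on unknown chromosomes or beyond the declared length raise an
#'   error.
#' @return List with `bins` (data.frame `chrom bin start end n_up n_down`)
#'   and `top_down`/`top_up` (single rows, or NULL when empty).
#' @export
genomic_binning <- function(de_genes, bin_bp = 1e7, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    unk <- setdiff(unique(de_genes$chrom), names(chrom_lengths))
    if (length(unk)) stop("unknown chromosome(s): ",
                          paste(unk, collapse = ", "))
    over <- de_genes$start > chrom_lengths[de_genes$chrom]
    if (any(over)) stop("gene start beyond declared chromosome length: ",
                        paste(de_genes$gene_id[over], collapse = ", "))
  }
  if (!nrow(de_genes))
    return(list(bins = data.frame(chrom = character(), bin = integer(),
                                  start = numeric(), end = numeric(),
                                  n_up = integer(), n_down = integer()),
                top_down = NULL, top_up = NULL))
  bin <- floor((de_genes$start - 1) / bin_bp)
  key <- paste(de_genes$chrom, bin)
  agg <- do.call(rbind, lapply(unique(key), function(k) {
    sel <- key == k
    data.frame(chrom = de_genes$chrom[sel][1], bin = bin[sel][1],
               n_up = sum(de_genes$direction[sel] == "up"),
               n_down = sum(de_genes$direction[sel] == "down"),
               stringsAsFactors = FALSE)
  }))
  agg$start <- agg$bin * bin_bp + 1
  agg$end <- (agg$bin + 1) * bin_bp
  agg <- agg[order(agg$chrom, agg$bin), c("chrom", "bin", "start", "end",
                                          "n_up", "n_down")]
  rownames(agg) <- NULL
  pick <- function(col) {
    if (all(agg[[col]] == 0L)) return(NULL)
    agg[which(agg[[col]] == max(agg[[col]]))[1L], , drop = FALSE]
  }
  list(bins = agg, top_down = pick("n_down"), top_up = pick("n_up"))
}

#' Curated-pathway expression summary
#'
#' One row per pathway gene (ovary, testis, bipotential or any supplied
#' sets): direction and verbal fold category from the age group with the
#' largest |log2FC|, and a significance class over age groups
#' (`both ages` / `one age` / `neither`, at `q_max`). Pathway genes absent
#' from the records are reported as `not measured`. Summary counts per
#' pathway and direction are attached.
#'
#' @param records full expression table (long format with `age_group`).
#' @param pathways data.frame with columns `gene_id`, `pathway`.
#' @param q_max significance cutoff per age group (default 0.05).
#' @return List with `genes` (per-gene report) and `summary` (counts per
#'   pathway x direction, significant genes only).
#' @export
pathway_summary <- function(records, pathways, q_max = 0.05) {
  stopifnot(all(c("gene_id", "pathway") %in% names(pathways)))
  n_ages <- length(unique(records$age_group))
  rows <- lapply(seq_len(nrow(pathways)), function(i) {
    gid <- pathways$gene_id[i]
    rec <- records[records$gene_id == gid, , drop = FALSE]
    if (!nrow(rec))
      return(data.frame(gene_id = gid, pathway = pathways$pathway[i],
                        direction = "not measured",
                        fold_category = NA_character_,
                        significance = "not measured",
                        stringsAsFactors = FALSE))
    n_sig <- sum(rec$q_value <= q_max)
    best <- rec[which.max(abs(rec$log2fc)), ]
    data.frame(
      gene_id = gid, pathway = pathways$pathway[i],
      direction = if (best$log2fc >= 0) "up" else "down",
      fold_category = fold_category(best$log2fc),
      significance = if (n_sig == 0) "neither"
                     else if (n_sig >= n_ages) "both ages" else "one age",
      stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(list(genes = data.frame(gene_id = character(),
                                   pathway = character(),
                                   direction = character(),
                                   fold_category = character(),
                                   significance = character()),
                summary = data.frame(pathway = character(),
                                     direction = character(),
                                     n_genes = integer())))
  genes <- do.call(rbind, rows)
  sig <- genes[genes$significance %in% c("both ages", "one age"), ,
               drop = FALSE]
  summary <- as.data.frame(table(pathway = sig$pathway,
                                 direction = sig$direction),
                           stringsAsFactors = FALSE)
  names(summary)[3] <- "n_genes"
  list(genes = genes, summary = summary)
}
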