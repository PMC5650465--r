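# WGS fine-mapping core: filter variants by a predicted pedigree
# segregation pattern, scan for density-enriched windows, and map
# homozygosity/haplotype blocks with breed-sharing summaries.

#' Predicted segregation pattern
#'
#' The genotype call each selected pedigree member must show for a variant
#' to be consistent with the hypothesized inheritance model. For the
#' default recessive model that means: affected dogs homozygous for the
#' alternate allele, the obligate carrier heterozygous, and the unrelated
#' control homozygous reference. `missing_policy` controls missing calls:
#' `"fail_match"` (default) -- a missing call cannot confirm the pattern,
#' the site is rejected; `"ignore_sample"` -- that sample is dropped from
#' the comparison at that site.
#'
#' @param required named character vector, `sample_id -> required call`
#'   (`"hom_ref"`, `"het"`, `"hom_alt"`).
#' @param missing_policy `"fail_match"` or `"ignore_sample"`.
#' @return Object of class `segregation_pattern`.
#' @export
segregation_pattern <- function(required,
                                missing_policy = c("fail_match",
                                                   "ignore_sample")) {
  missing_policy <- match.arg(missing_policy)
  bad <- setdiff(unique(required), GT_LEVELS)
  if (length(bad)) stop("unknown genotype class: ", paste(bad, collapse = ", "))
  if (is.null(names(required)) || any(!nzchar(names(required))))
    stop("pattern must be a named vector of sample_id -> required call")
  structure(list(required = required, missing_policy = missing_policy),
            class = "segregation_pattern")
}

#' Filter variants by a segregation pattern
#'
#' Retains exactly those sites where every patterned sample's call equals
#' its required call. Output is the site table of retained variants,
#' sorted by (chrom, pos), with a `site_index` column back into the input
#' matrix.
#'
#' @param x a [genotype_matrix()].
#' @param pattern a [segregation_pattern()].
#' @return data.frame of retained sites.
#' @export
segregation_pattern_filter <- function(x, pattern) {
  ids <- names(pattern$required)
  missing_ids <- setdiff(ids, x$samples)
  if (length(missing_ids))
    stop("pattern sample(s) absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  want <- match(pattern$required, GT_LEVELS) - 1L
  sub <- x$calls[match(ids, x$samples), , drop = FALSE]
  ok <- sub == want          # NA where call is missing
  keep <- if (pattern$missing_policy == "fail_match") {
    colSums(ok, na.rm = TRUE) == length(ids) & colSums(is.na(ok)) == 0L
  } else {
    colSums(!ok, na.rm = TRUE) == 0L
  }
  out <- x$sites[keep, , drop = FALSE]
  out$site_index <- which(keep)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Fold enrichment of local variant density
#'
#' Ratio of the variant density inside an interval to the genome-wide
#' density: `(k / w_bp) / (K / G_bp)`.
#'
#' @param k matching variants inside the interval.
#' @param w_bp interval length in bp.
#' @param K genome-wide matching variants.
#' @param G_bp effective genome length in bp.
#' @return Fold enrichment (dimensionless).
#' @export
fold_enrichment <- function(k, w_bp, K, G_bp) {
  if (K <= 0) stop("enrichment undefined: zero genome-wide variants")
  stopifnot(w_bp > 0, G_bp >= w_bp, k >= 0, k <= K)
  (k / w_bp) / (K / G_bp)
}

#' Sliding-window variant-density enrichment scan
#'
#' Slides fixed-width windows along each chromosome over the retained
#' (pattern-matching) sites, computes each window's fold enrichment
#' against the genome-wide density, merges overlapping windows at or above
#' `fold_threshold` into maximal segments, and reports the top segment
#' spanning the first to last retained variant inside it. Windows are
#' ranked by (fold descending, chrom, start); ties therefore break to the
#' lexicographically first location.
#'
#' @param retained data.frame of retained sites (from
#'   [segregation_pattern_filter()]); needs `chrom` and `pos`.
#' @param G_bp effective genome length.
#' @param window_bp,step_bp window width and slide step (defaults 1 Mb /
#'   100 kb).
#' @param fold_threshold minimum fold for a window to enter a merged
#'   segment (default 5).
#' @param trim_gap_bp boundary refinement: within a merged segment the
#'   retained variants are split into runs at inter-variant gaps larger
#'   than this value and the reported interval spans the run with the
#'   most variants (default `step_bp`), so the segment covers the dense
#'   cluster rather than isolated stragglers caught by a flanking
#'   window. Set 0 to disable.
#' @return List with `windows` (ranked data.frame `chrom start end k
#'   fold`), `segments` (merged data.frame with the spanned-variant
#'   interval and its fold), and `top_segment` (first row of `segments`,
#'   or NULL when no window passes the threshold).
#' @export
enrichment_scan <- function(retained, G_bp, window_bp = 1e6, step_bp = 1e5,
                            fold_threshold = 5, trim_gap_bp = step_bp) {
  if (nrow(retained) < 1L) stop("no retained sites to scan")
  K <- nrow(retained)
  wins <- list()
  for (ch in sort(unique(retained$chrom))) {
    pos <- sort(retained$pos[retained$chrom == ch])
    starts <- seq(1, max(pos), by = step_bp)
    ends <- starts + window_bp - 1
    k <- vapply(seq_along(starts), function(i)
      sum(pos >= starts[i] & pos <= ends[i]), 0L)
    nz <- k > 0L
    if (!any(nz)) next
    wins[[ch]] <- data.frame(chrom = ch, start = starts[nz], end = ends[nz],
                             k = k[nz],
                             fold = (k[nz] / window_bp) / (K / G_bp),
                             stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, c(wins, make.row.names = FALSE))
  windows <- windows[order(-windows$fold, windows$chrom, windows$start), ,
                     drop = FALSE]
  rownames(windows) <- NULL
  hot <- windows[windows$fold >= fold_threshold, , drop = FALSE]
  segments <- NULL
  if (nrow(hot)) {
    segs <- list()
    for (ch in sort(unique(hot$chrom))) {
      h <- hot[hot$chrom == ch, , drop = FALSE]
      h <- h[order(h$start), , drop = FALSE]
      cur_s <- h$start[1]; cur_e <- h$end[1]
      flush <- function(s, e) {
        pos <- sort(retained$pos[retained$chrom == ch & retained$pos >= s &
                                   retained$pos <= e])
        if (trim_gap_bp > 0 && length(pos) > 1L) {
          run <- cumsum(c(0L, diff(pos) > trim_gap_bp))
          best <- which.max(tabulate(run + 1L)) - 1L
          pos <- pos[run == best]
        }
        data.frame(chrom = ch, start = min(pos), end = max(pos),
                   k = length(pos),
                   fold = (length(pos) / (max(pos) - min(pos) + 1)) /
                     (K / G_bp),
                   stringsAsFactors = FALSE)
      }
      if (nrow(h) > 1L) for (i in 2:nrow(h)) {
        if (h$start[i] <= cur_e + 1) cur_e <- max(cur_e, h$end[i])
        else { segs[[length(segs) + 1L]] <- flush(cur_s, cur_e)
               cur_s <- h$start[i]; cur_e <- h$end[i] }
      }
      segs[[length(segs) + 1L]] <- flush(cur_s, cur_e)
    }
    segments <- do.call(rbind, c(segs, make.row.names = FALSE))
    # the top segment is the one holding the most matching variants;
    # fold breaks ties (guards against degenerate one-variant spans
    # whose per-bp density is huge)
    segments <- segments[order(-segments$k, -segments$fold, segments$chrom,
                               segments$start), , drop = FALSE]
    rownames(segments) <- NULL
  }
  list(windows = windows, segments = segments,
       top_segment = if (!is.null(segments)) segments[1L, , drop = FALSE])
}

#' Homozygosity/haplotype blocks shared by cases against controls
#'
#' Maximal runs of consecutive sites (in site order) where every case is
#' homozygous for the alternate allele and every control homozygous
#' reference; runs shorter than `min_sites` are dropped. Missing calls
#' disqualify a site (`max_violations` per-site tolerance defaults to 0
#' disqualifying sites allowed inside a run).
#'
#' @param x a [genotype_matrix()] (sites assumed position-ordered within
#'   chromosome).
#' @param case_ids,control_ids disjoint sample id sets.
#' @param min_sites minimum run length (default 2).
#' @param max_violations number of non-qualifying sites tolerated inside a
#'   run (default 0, strict).
#' @return data.frame of blocks: `chrom start end n_sites first_index
#'   last_index`.
#' @export
homozygosity_blocks <- function(x, case_ids, control_ids, min_sites = 2L,
                                max_violations = 0L) {
  if (!length(case_ids) || !length(control_ids))
    stop("need at least one case and one control")
  if (length(intersect(case_ids, control_ids)))
    stop("cases and controls must be disjoint")
  ca <- x$calls[match(case_ids, x$samples), , drop = FALSE]
  co <- x$calls[match(control_ids, x$samples), , drop = FALSE]
  if (anyNA(match(c(case_ids, control_ids), x$samples)))
    stop("unknown sample id in case/control sets")
  qual <- colSums(ca == 2L, na.rm = TRUE) == length(case_ids) &
    colSums(is.na(ca)) == 0L &
    colSums(co == 0L, na.rm = TRUE) == length(control_ids) &
    colSums(is.na(co)) == 0L
  blocks <- list()
  for (ch in unique(x$sites$chrom)) {
    idx <- which(x$sites$chrom == ch)
    q <- qual[idx]
    if (max_violations > 0L) {
      # absorb isolated violations up to the allowance within a run
      r <- rle(q)
      for (i in seq_along(r$values)) {
        if (!r$values[i] && r$lengths[i] <= max_violations &&
            i > 1L && i < length(r$values)) r$values[i] <- TRUE
      }
      q <- inverse.rle(r)
    }
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] && r$lengths[i] >= min_sites) {
        si <- idx[starts[i]]; ei <- idx[ends[i]]
        blocks[[length(blocks) + 1L]] <- data.frame(
          chrom = ch, start = x$sites$pos[si], end = x$sites$pos[ei],
          n_sites = r$lengths[i], first_index = si, last_index = ei,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(blocks))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      first_index = integer(), last_index = integer()))
  do.call(rbind, c(blocks, make.row.names = FALSE))
}

#' Breed-sharing summary across a haplotype block
#'
#' Tallies, per breed, affected individuals homozygous for the alternate
#' allele at every site of the block; a breed "segregates" when it has at
#' least one such individual. Reports the per-breed table and the count of
#' segregating breeds.
#'
#' @param x a [genotype_matrix()].
#' @param block one row of [homozygosity_blocks()] output (needs
#'   `first_index`/`last_index`).
#' @param samples sample table with `sample_id`, `breed`, `phenotype`.
#' @return List with `table` (data.frame `breed n_affected
#'   n_affected_hom_alt segregates`) and `n_segregating_breeds`.
#' @export
breed_sharing_table <- function(x, block, samples) {
  idx <- seq(block$first_index, block$last_index)
  sub <- x$calls[match(samples$sample_id, x$samples), idx, drop = FALSE]
  hom_all <- rowSums(sub == 2L, na.rm = TRUE) == length(idx) &
    rowSums(is.na(sub)) == 0L
  aff <- samples$phenotype == "xx_dsd"
  tab <- do.call(rbind, lapply(sort(unique(samples$breed)), function(b) {
    in_b <- samples$breed == b
    data.frame(breed = b, n_affected = sum(aff & in_b),
               n_affected_hom_alt = sum(aff & in_b & hom_all),
               stringsAsFactors = FALSE)
  }))
  tab$segregates <- tab$n_affected_hom_alt >= 1L
  list(table = tab, n_segregating_breeds = sum(tab$segregates))
}

#' Write windows/segments as a BED-like TSV
#'
#' Default dialect uses 1-based inclusive ends, matching the intervals as
#' printed in genome browsers and in this package's reports; `bed_strict =
#' TRUE` emits true BED (0-based half-open).
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and any extra
#'   columns (e.g. `k`, `fold`).
#' @param path output file.
#' @param bed_strict emit 0-based half-open coordinates.
#' @return `path`, invisibly.
#' @export
write_interval_tsv <- function(intervals, path, bed_strict = FALSE) {
  out <- intervals
  if (bed_strict) out$start <- out$start - 1L
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = !bed_strict)
  invisible(path)
}
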