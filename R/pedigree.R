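#' Pedigree graph over a sample table
#'
#' Wraps a validated sample table as a directed acyclic graph of
#' offspring -> sire and offspring -> dam edges. Founders are rows whose
#' sire and dam are both the sentinel `"0"`; their `breed` label seeds
#' expected-background-fraction computation. Every non-founder must name a
#' sire and a dam that are either present in the table or `"0"` (unknown).
#'
#' @param samples sample-table data.frame (see [read_sample_table()]).
#' @return Object of class `pedigree_graph`.
#' @export
pedigree_graph <- function(samples) {
  samples <- validate_sample_table(samples)
  ids <- samples$sample_id
  for (col in c("sire", "dam")) {
    unk <- setdiff(samples[[col]], c("0", ids))
    if (length(unk)) stop(col, " id(s) absent from table: ",
                          paste(unk, collapse = ", "))
  }
  # topological order by generation depth; also proves acyclicity
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  pending <- ids
  guard <- 0L
  while (length(pending)) {
    guard <- guard + 1L
    if (guard > length(ids) + 1L) stop("pedigree contains a cycle")
    progressed <- FALSE
    for (id in pending) {
      i <- match(id, ids)
      pd <- c(samples$sire[i], samples$dam[i])
      pd <- pd[pd != "0"]
      if (!length(pd)) { depth[id] <- 0L; progressed <- TRUE }
      else if (!anyNA(depth[pd])) {
        depth[id] <- max(depth[pd]) + 1L; progressed <- TRUE
      }
    }
    pending <- names(depth)[is.na(depth)]
    if (!progressed && length(pending)) stop("pedigree contains a cycle")
  }
  structure(list(samples = samples,
                 order = ids[order(depth[ids])],
                 depth = depth),
            class = "pedigree_graph")
}

#' @export
print.pedigree_graph <- function(x, ...) {
  nf <- sum(x$depth == 0L)
  cat(sprintf("pedigree_graph: %d individuals (%d founders, max depth %d)\n",
              nrow(x$samples), nf, max(x$depth)))
  invisible(x)
}

#' Founder ids of a pedigree
#' @param ped a `pedigree_graph`.
#' @export
founders <- function(ped) names(ped$depth)[ped$depth == 0L]

#' Expected breed-background fraction per individual
#'
#' The expected fraction of an individual's genome descending from founders
#' of the given breed: 1 for founders of that breed, 0 for other founders,
#' and the mean of the parental fractions otherwise (an unknown parent,
#' sentinel `"0"`, contributes `unknown_value`, default 0). Fractions always
#' lie in `[0, 1]`; an F1 between pure founder breeds scores exactly 0.5 and
#' an F1 x founder backcross 0.75/0.25.
#'
#' @param ped a `pedigree_graph`.
#' @param breed breed label to trace.
#' @param unknown_value fraction attributed to an unknown parent.
#' @return Named numeric vector over all individuals, in pedigree order.
#' @export
breed_fraction <- function(ped, breed, unknown_value = 0) {
  s <- ped$samples
  frac <- stats::setNames(rep(NA_real_, nrow(s)), s$sample_id)
  for (id in ped$order) {
    i <- match(id, s$sample_id)
    if (ped$depth[id] == 0L) {
      frac[id] <- as.numeric(s$breed[i] == breed)
    } else {
      pf <- vapply(c(s$sire[i], s$dam[i]), function(p)
        if (p == "0") unknown_value else frac[[p]], 0)
      frac[id] <- mean(pf)
    }
  }
  frac[s$sample_id]
}
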