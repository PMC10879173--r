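# Descriptor-driven motif scanning.
#
# scan_sequence() enumerates every placement of a descriptor on a subject
# sequence: an assignment of a length (within its range) to every element,
# laid out contiguously left to right, such that all identity constraints
# match IUPAC-compatibly, helix strands are reverse-complementary position
# by position (G.T wobble accepted where enabled), and the fraction of
# ambiguous subject nucleotides in the match does not exceed the
# descriptor's nratio. Distinct length assignments giving the same
# (start, end, strand) are collapsed to one hit; overlapping distinct
# matches are all reported. The heavy lifting is a backtracking matcher in
# compiled code; an independent pure-R enumeration oracle lives in the test
# suite.

#' @useDynLib thetascan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' @keywords internal
.compile_descriptor <- function(d) {
  el <- d$elements
  kind <- match(el$kind, c("single_strand", "helix_5p", "helix_3p")) - 1L
  cons <- lapply(seq_len(nrow(el)), function(j) {
    if (!nzchar(el$constraint[j])) NULL
    else .seq_to_masks(el$constraint[j],
                       what = sprintf("constraint of %s", el$id[j]))
  })
  partner <- ifelse(el$kind == "helix_3p",
                    match(el$partner, el$id) - 1L, -1L)
  # wobble acceptance is decided per helix; the 3' strand's flag is used
  list(kind = kind, min_len = el$min_len, max_len = el$max_len,
       constraints = cons, partner = as.integer(partner),
       wobble = as.integer(el$wobble))
}

.empty_hits <- function() {
  h <- data.frame(contig = character(), start = integer(), end = integer(),
                  strand = character(), variant = character(),
                  sequence = character(), cleavage_site = integer(),
                  stringsAsFactors = FALSE)
  h$element_lens <- list()
  class(h) <- c("drz_hits", "data.frame")
  h
}

#' Scan a DNA sequence for descriptor matches
#'
#' @param d A `drz_descriptor`.
#' @param seq Character scalar, the subject DNA (IUPAC codes allowed).
#' @param contig Contig id recorded in the hits.
#' @param both_strands Scan the reverse strand too (default `TRUE`);
#'   reverse-strand hits are reported in forward coordinates with strand
#'   `"-"`.
#' @return A `drz_hits` data frame with 0-based half-open `start`/`end`
#'   forward-strand coordinates, the matched sequence 5'->3' on the hit
#'   strand, the strand-aware coordinate of the cleavage-site nucleotide G1,
#'   and a list column `element_lens` holding the element-length assignment
#'   of the first (shortest-lengths) placement for each hit.
#' @export
scan_sequence <- function(d, seq, contig = "contig", both_strands = TRUE) {
  stopifnot(inherits(d, "drz_descriptor"), is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(.empty_hits())
  seq <- toupper(chartr("u", "t", seq))
  comp <- .compile_descriptor(d)
  L <- nchar(seq)

  run <- function(s) {
    masks <- .seq_to_masks(s)
    .scan_engine(masks, comp$kind, comp$min_len, comp$max_len,
                 comp$constraints, comp$partner, comp$wobble,
                 d$max_ambiguous_fraction)
  }

  nE <- nrow(d$elements)
  collect <- function(mat, strand, subject) {
    if (nrow(mat) == 0L) return(NULL)
    lens <- mat[, -1L, drop = FALSE]
    s0 <- mat[, 1L]
    tot <- rowSums(lens)
    e0 <- s0 + tot
    # collapse identical (start, end); keep the first (shortest-first) row
    keep <- !duplicated(cbind(s0, e0))
    mat <- mat[keep, , drop = FALSE]; s0 <- s0[keep]; e0 <- e0[keep]
    lens <- lens[keep, , drop = FALSE]
    # coordinates of the cleavage element's first nucleotide on the scanned
    # strand, then mapped to forward coordinates
    ci <- if (is.null(d$cleavage)) NA_integer_
          else match(d$cleavage, d$elements$id)
    n <- nrow(mat)
    if (is.na(ci)) {
      cs_local <- s0
    } else {
      before <- if (ci == 1L) rep(0L, n)
                else rowSums(lens[, seq_len(ci - 1L), drop = FALSE])
      cs_local <- s0 + before
    }
    seqs <- substring(subject, s0 + 1L, e0)
    if (strand == "+") {
      start <- s0; end <- e0; cs <- cs_local
    } else {
      start <- L - e0; end <- L - s0; cs <- L - 1L - cs_local
    }
    h <- data.frame(contig = contig, start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    variant = d$variant, sequence = seqs,
                    cleavage_site = as.integer(cs), stringsAsFactors = FALSE)
    h$element_lens <- lapply(seq_len(n), function(r) {
      stats::setNames(as.integer(lens[r, ]), d$elements$id)
    })
    h
  }

  out <- list(collect(run(seq), "+", seq))
  if (both_strands) {
    rc <- revcomp(seq)
    out <- c(out, list(collect(run(rc), "-", rc)))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.empty_hits())
  h <- do.call(rbind, out)
  h <- h[order(h$start, h$end, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("drz_hits", "data.frame")
  h
}

#' Scan a set of contigs (optionally with all four motif variants)
#'
#' @param d Active `drz_descriptor`.
#' @param seqs Named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param variants If `TRUE`, also scan the three derived false-positive
#'   motifs (CdA, CdG, CdU) and return the combined hit set.
#' @param both_strands Passed to [scan_sequence()].
#' @return A `drz_hits` data frame.
#' @export
scan_contigs <- function(d, seqs, variants = FALSE, both_strands = TRUE) {
  seqs <- .as_seq_vector(seqs)
  ds <- list(d)
  if (variants) ds <- c(ds, derive_fp_variants(d))
  out <- list()
  for (dd in ds) {
    for (nm in names(seqs)) {
      h <- scan_sequence(dd, seqs[[nm]], contig = nm,
                         both_strands = both_strands)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(.empty_hits())
  h <- do.call(rbind, out)
  rownames(h) <- NULL
  class(h) <- c("drz_hits", "data.frame")
  h
}

#' Label hit loci as true or false positives
#'
#' Hits from the active and the three false-positive motif scans of the
#' same sequences are grouped into loci (overlapping intervals on one
#' contig and strand). A locus matched by the active motif is a true
#' positive regardless of any false-positive motif matching it too (the
#' dual-fit tie-break); remaining loci are labeled by their false-positive
#' variant.
#'
#' @param active_hits,fp_hits `drz_hits` from the active scan and the
#'   combined false-positive scans. Alternatively pass a single combined
#'   frame as `active_hits` with `fp_hits = NULL`.
#' @return The combined hits with added columns `locus` (id) and `label`
#'   (`"true_positive"` or `"false_positive"`).
#' @export
classify_hits <- function(active_hits, fp_hits = NULL) {
  h <- if (is.null(fp_hits)) active_hits else rbind(active_hits, fp_hits)
  if (nrow(h) == 0L) {
    h$locus <- integer(0); h$label <- character(0)
    return(h)
  }
  h$locus <- NA_integer_
  nextid <- 1L
  for (key in unique(paste(h$contig, h$strand))) {
    sel <- which(paste(h$contig, h$strand) == key)
    ir <- IRanges::IRanges(start = h$start[sel] + 1L, end = h$end[sel])
    red <- IRanges::reduce(ir)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    h$locus[sel] <- nextid + grp - 1L
    nextid <- nextid + length(red)
  }
  tp_loci <- unique(h$locus[h$variant == "active"])
  h$label <- ifelse(h$locus %in% tp_loci, "true_positive", "false_positive")
  class(h) <- c("drz_hits", "data.frame")
  h
}

#' False-positive rate over unique hit sequences
#'
#' The fraction of unique matched sequences that are only explained by a
#' false-positive (catalytic-position-substituted) motif. A sequence
#' matched by the active motif anywhere is counted as a true positive.
#'
#' @param labeled_hits Output of [classify_hits()].
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when there are
#'   no hits.
#' @export
fp_rate <- function(labeled_hits) {
  if (!"label" %in% names(labeled_hits))
    stop("fp_rate: hits carry no labels; run classify_hits() first",
         call. = FALSE)
  tp <- unique(labeled_hits$sequence[labeled_hits$label == "true_positive"])
  fp <- setdiff(unique(labeled_hits$sequence[labeled_hits$label == "false_positive"]),
                tp)
  n <- length(tp) + length(fp)
  if (n == 0L) {
    warning("fp_rate undefined: no hits")
    return(NA_real_)
  }
  length(fp) / n
}

#' Dereplicate true-positive hits into unique ribozyme records
#'
#' One record per distinct matched nucleotide sequence, with its occurrence
#' count and a rank name of the form `Θ0001` assigned by descending
#' occurrence (ties broken lexicographically by sequence).
#'
#' @param hits A `drz_hits` frame; if it carries labels only the
#'   true-positive hits are used.
#' @param prefix Name prefix, default the Greek letter theta.
#' @return A `theta_records` data frame (`sequence`, `occurrences`, `rank`,
#'   `name`, list column `hit_rows` of row indices into `hits`).
#' @export
dereplicate_hits <- function(hits, prefix = "Θ") {
  rows <- seq_len(nrow(hits))
  if ("label" %in% names(hits)) rows <- rows[hits$label == "true_positive"]
  seqs <- hits$sequence[rows]
  if (!length(seqs)) {
    r <- data.frame(sequence = character(), occurrences = integer(),
                    rank = integer(), name = character(),
                    stringsAsFactors = FALSE)
    r$hit_rows <- list()
    class(r) <- c("theta_records", "data.frame")
    return(r)
  }
  tab <- table(seqs)
  sq <- names(tab)
  occ <- as.integer(tab)
  o <- order(-occ, sq)
  r <- data.frame(sequence = sq[o], occurrences = occ[o],
                  rank = seq_along(o), stringsAsFactors = FALSE)
  r$name <- sprintf("%s%04d", prefix, r$rank)
  r$hit_rows <- lapply(r$sequence, function(s) rows[seqs == s])
  class(r) <- c("theta_records", "data.frame")
  r
}

#' Element-anchored consensus profile with conservation tiers
#'
#' Each record's sequence is re-matched to the descriptor so positions
#' align by element and offset; variable-length elements are aligned
#' left-anchored with gap padding to the element's maximum length. For
#' every aligned position the nucleotide frequencies (over the unique
#' records, gaps counted in the denominator) and the conservation tier of
#' the modal nucleotide are reported, using the 0.97 / 0.90 / 0.75 tiers
#' conventionally used for consensus drawings.
#'
#' @param records A `theta_records` frame (or any frame with `sequence`
#'   and `name` columns).
#' @param d The `drz_descriptor` the records were found with.
#' @return Data frame: `element`, `offset`, counts and frequencies of
#'   A/C/G/T and gap, `modal`, `modal_freq`, `tier`.
#' @export
element_consensus <- function(records, d) {
  stopifnot(nrow(records) >= 1L)
  el <- d$elements
  width <- sum(el$max_len)
  aln <- matrix("-", nrow = nrow(records), ncol = width)
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    h <- scan_sequence(d, s, both_strands = FALSE)
    h <- h[h$start == 0L & h$end == nchar(s), , drop = FALSE]
    if (nrow(h) == 0L)
      stop(sprintf("record %s does not match descriptor %s",
                   records$name[i] %||% i, d$name), call. = FALSE)
    lens <- h$element_lens[[1L]]
    pos <- 0L; col <- 0L
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(el))) {
      l <- lens[[el$id[j]]]
      if (l > 0L) aln[i, col + seq_len(l)] <- chars[pos + seq_len(l)]
      pos <- pos + l
      col <- col + el$max_len[j]
    }
  }
  element <- rep(el$id, el$max_len)
  offset <- unlist(lapply(el$max_len, function(m) seq_len(m) - 1L),
                   use.names = FALSE)
  n <- nrow(records)
  cnt <- function(b) colSums(aln == b)
  counts <- sapply(c("A", "C", "G", "T", "-"), cnt)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, c("A", "C", "G", "T", "-")))
  modal_i <- max.col(counts[, 1:4, drop = FALSE], ties.method = "first")
  modal <- c("A", "C", "G", "T")[modal_i]
  modal_freq <- counts[cbind(seq_len(nrow(counts)), modal_i)] / n
  tier <- ifelse(modal_freq >= 0.97, ">=0.97",
                 ifelse(modal_freq >= 0.90, ">=0.90",
                        ifelse(modal_freq >= 0.75, ">=0.75", "none")))
  out <- data.frame(element = element, offset = offset,
                    A = counts[, "A"] / n, C = counts[, "C"] / n,
                    G = counts[, "G"] / n, T = counts[, "T"] / n,
                    gap = counts[, "-"] / n,
                    modal = modal, modal_freq = modal_freq, tier = tier,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
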