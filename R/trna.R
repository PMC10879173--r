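# tRNA association and genomic-context classification.
#
# A ribozyme hit is tRNA-associated when a tRNA 3'-end lies within a
# +/- 5 nt window of its cleavage site (G1). The signed distance is
# measured from the tRNA's last nucleotide to G1 along the coding strand,
# positive when the ribozyme starts downstream; a directly adjacent
# cassette (no spacer) therefore has distance +1. Association requires
# co-orientation (the ribozyme processes the tRNA 3'-trailer in cis).

#' Pair ribozyme hits with nearby tRNA 3'-ends
#'
#' @param hits `drz_hits` frame (must carry `cleavage_site`).
#' @param trnas `trna_annotations` frame.
#' @param window Association window in nucleotides (default 5).
#' @param allow_antisense Also consider tRNAs on the opposite strand
#'   (default `FALSE`; sensitivity analysis only).
#' @return Data frame of association records: the hit row index
#'   (`hit_row`), tRNA row index (`trna_row`), `contig`, `strand`,
#'   signed `distance`, and `adjacency` (`"direct"` when `|d| <= 1`,
#'   else `"near"`). Each hit pairs with at most one tRNA (smallest
#'   `|distance|`; ties go to the upstream tRNA).
#' @export
associate_trnas <- function(hits, trnas, window = 5L,
                            allow_antisense = FALSE) {
  out <- list()
  for (i in seq_len(nrow(hits))) {
    cand <- which(trnas$contig == hits$contig[i] &
                    (allow_antisense | trnas$strand == hits$strand[i]))
    if (!length(cand)) next
    d <- if (hits$strand[i] == "+")
      hits$cleavage_site[i] - trnas$three_prime_end[cand]
    else
      trnas$three_prime_end[cand] - hits$cleavage_site[i]
    ok <- abs(d) <= window
    if (!any(ok)) next
    cand <- cand[ok]; d <- d[ok]
    # nearest |distance|; tie -> the upstream tRNA (5' of the hit on the
    # coding strand, i.e. the more negative distance... upstream tRNA ends
    # earlier, giving the larger d)
    o <- order(abs(d), -d)
    j <- o[1L]
    out[[length(out) + 1L]] <- data.frame(
      hit_row = i, trna_row = cand[j], contig = hits$contig[i],
      strand = hits$strand[i], distance = d[j],
      adjacency = if (abs(d[j]) <= 1L) "direct" else "near",
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(hit_row = integer(), trna_row = integer(),
                      contig = character(), strand = character(),
                      distance = integer(), adjacency = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the genomic context of a ribozyme hit
#'
#' A hit overlapping an ORF by at least one nucleotide is `intragenic`;
#' otherwise it is `distal` when the nearest ORF edge is more than
#' `distance` nucleotides away, else `noncoding_sense` /
#' `noncoding_antisense` by strand agreement with the nearest ORF
#' (distance ties go to the downstream ORF). Contigs without ORFs give
#' `distal`.
#'
#' @param hit One row of a `drz_hits` frame (or a list with `start`,
#'   `end`, `strand`).
#' @param orfs Frame of ORF intervals (`start`, `end` 0-based half-open,
#'   `strand`) on the hit's contig.
#' @param distance Distal threshold in nt (default 200).
#' @return One of `"intragenic"`, `"noncoding_sense"`,
#'   `"noncoding_antisense"`, `"distal"`.
#' @export
classify_context <- function(hit, orfs, distance = 200L) {
  if (is.null(orfs) || nrow(orfs) == 0L) return("distal")
  ov <- orfs$start < hit$end & orfs$end > hit$start
  if (any(ov)) return("intragenic")
  # gap between hit and each ORF
  gap <- ifelse(orfs$start >= hit$end, orfs$start - hit$end,
                hit$start - orfs$end)
  downstream <- orfs$start >= hit$end
  o <- order(gap, !downstream)
  j <- o[1L]
  if (gap[j] > distance) return("distal")
  if (orfs$strand[j] == hit$strand) "noncoding_sense" else "noncoding_antisense"
}

#' Which stop codon does an anticodon read?
#'
#' A tRNA is a suppressor when its anticodon is the reverse complement of
#' a stop codon: CTA reads UAG (amber), TCA reads UGA (opal), TTA reads
#' UAA (ochre).
#'
#' @param anticodon 3-mer over A/C/G/T (as annotated, DNA alphabet).
#' @return `"UAG"`, `"UGA"`, `"UAA"`, or `NA` for a non-suppressor.
#' @export
is_suppressor <- function(anticodon) {
  vapply(anticodon, function(a) {
    a <- toupper(a)
    if (is.na(a) || !grepl("^[ACGT]{3}$", a))
      stop(sprintf("malformed anticodon '%s'", a), call. = FALSE)
    switch(a, CTA = "UAG", TCA = "UGA", TTA = "UAA", NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

#' Does a genomically encoded tRNA end in CCA?
#'
#' @param seq tRNA nucleotide sequence(s).
#' @return Logical vector.
#' @export
has_cca_tail <- function(seq) {
  stopifnot(all(nzchar(seq) | is.na(seq)))
  !is.na(seq) & grepl("CCA$", toupper(seq))
}

#' Compose tRNA/ribozyme pair names
#'
#' Names follow the occurrence-rank convention
#' `tRNA<Isotype><tRNA rank>_Θ<ribozyme rank>`, e.g. the 25th-most
#' prevalent tRNA (a Val) paired with the 46th-most prevalent ribozyme is
#' `tRNAVal0025_Θ0046`.
#'
#' @param isotype,trna_rank,rz_rank Vectors of equal length: the tRNA
#'   isotype labels and the 1-based occurrence ranks of the tRNA and the
#'   ribozyme.
#' @return Character vector of pair names.
#' @export
name_pairs <- function(isotype, trna_rank, rz_rank) {
  if (anyNA(trna_rank) || anyNA(rz_rank) ||
      any(trna_rank < 1L) || any(rz_rank < 1L))
    stop("name_pairs: unranked input (ranks must be positive integers)",
         call. = FALSE)
  sprintf("tRNA%s%04d_Θ%04d", isotype, as.integer(trna_rank),
          as.integer(rz_rank))
}

#' Fold enrichment of a feature in a subset over a background
#'
#' @param p_subset Fraction in the subset, in `[0, 1]`.
#' @param p_background Fraction in the background, in `(0, 1]`.
#' @return `p_subset / p_background`.
#' @export
fold_enrichment <- function(p_subset, p_background) {
  if (any(p_background <= 0))
    stop("fold_enrichment: zero background fraction", call. = FALSE)
  stopifnot(all(p_subset >= 0 & p_subset <= 1), all(p_background <= 1))
  p_subset / p_background
}
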