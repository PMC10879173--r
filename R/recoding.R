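# Alternative genetic-code (recoding) detection by coding-density
# comparison.
#
# Recoded phage genomes reassign a stop codon to a sense codon: code 15
# reads UAG as Gln (stop set TAA/TGA), code 4 reads UGA as Trp (stop set
# TAA/TAG); code 11 is the standard bacterial code. Genes of a recoded
# genome fragment when predicted in standard code, so the genome's coding
# density is markedly higher under its true code. A contig is called
# recoded when the alternative-code density exceeds the standard-code
# density by 10 percentage points (contigs under 100 kbp) or 5 points
# (100 kbp and above).
#
# ORF calling is a deterministic maximal-ORF surrogate (not a gene
# finder): in each of the six frames, an ORF runs from the first start
# codon (ATG/GTG/TTG) after the previous in-frame stop (or the frame
# edge) to the next in-frame stop (included), or to the frame edge when
# no stop follows. Codons containing ambiguity codes are neither starts
# nor stops.

.STOP_SETS <- list(`11` = c("TAA", "TAG", "TGA"),
                   `15` = c("TAA", "TGA"),
                   `4`  = c("TAA", "TAG"))
.START_CODONS <- c("ATG", "GTG", "TTG")

#' Find maximal open reading frames under a genetic code
#'
#' @param seq DNA sequence (character scalar).
#' @param code Genetic code: 11 (standard bacterial), 15 (TAG
#'   reassigned), or 4 (TGA reassigned).
#' @param min_len Minimum ORF length in nucleotides, stop codon included
#'   (default 90).
#' @return Data frame of 0-based half-open forward-strand intervals with
#'   `strand` and `frame` (0..2 on the scanned strand).
#' @export
find_orfs <- function(seq, code = 11, min_len = 90L) {
  stops <- .STOP_SETS[[as.character(code)]]
  if (is.null(stops)) stop(sprintf("invalid genetic code '%s'", code),
                           call. = FALSE)
  seq <- toupper(seq)
  L <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      if (L - f < 3L) next
      cs <- seq.int(f + 1L, L - 2L, by = 3L)
      cod <- substring(s, cs, cs + 2L)
      is_stop <- cod %in% stops
      is_start <- cod %in% .START_CODONS
      n <- length(cod)
      stop_i <- which(is_stop)
      start_i <- which(is_start)
      if (!length(start_i)) next
      # segments delimited by stops: (prev_stop, this_stop]; a trailing
      # stop-less segment reaches the frame edge
      seg_lo <- c(0L, stop_i)            # exclusive lower codon bound
      seg_hi <- c(stop_i, n)             # inclusive upper codon bound
      keep <- seg_hi > seg_lo           # drops an empty trailing segment
      seg_lo <- seg_lo[keep]; seg_hi <- seg_hi[keep]
      # first start codon strictly after seg_lo and at most seg_hi
      k <- findInterval(seg_lo, start_i) + 1L
      has <- k <= length(start_i)
      first_start <- rep(NA_integer_, length(seg_lo))
      first_start[has] <- start_i[k[has]]
      ok <- !is.na(first_start) & first_start <= seg_hi
      if (!any(ok)) next
      a <- first_start[ok]; b <- seg_hi[ok]
      # codon indices a..b -> nt coords on the scanned strand (1-based)
      p1 <- cs[a]; p2 <- cs[b] + 2L
      len <- p2 - p1 + 1L
      keep2 <- len >= min_len
      if (!any(keep2)) next
      p1 <- p1[keep2]; p2 <- p2[keep2]
      if (strand == "+") {
        st <- p1 - 1L; en <- p2
      } else {
        st <- L - p2; en <- L - p1 + 1L
      }
      res[[length(res) + 1L]] <- data.frame(
        start = st, end = en, strand = strand, frame = f,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coding density of a set of ORF intervals
#'
#' Both strands are projected onto genome coordinates and the length of
#' the interval union is divided by the genome length.
#'
#' @param orfs Frame with `start`, `end` (0-based half-open).
#' @param genome_length Contig length in nt.
#' @return Fraction in `[0, 1]`.
#' @export
coding_density <- function(orfs, genome_length) {
  if (nrow(orfs) == 0L) return(0)
  stopifnot(all(orfs$start >= 0L), all(orfs$end <= genome_length))
  ir <- IRanges::reduce(IRanges::IRanges(orfs$start + 1L, orfs$end))
  sum(IRanges::width(ir)) / genome_length
}

#' Assign the genetic code of a contig by coding-density comparison
#'
#' Densities under codes 11, 15 and 4 are computed; the alternative code
#' with the largest density excess over code 11 is assigned when that
#' excess reaches the size-dependent threshold (0.10 below 100 kbp, 0.05
#' at or above), otherwise code 11. An exact tie between codes 15 and 4
#' is unresolvable and falls back to code 11.
#'
#' @param seq DNA sequence.
#' @param contig Contig id carried into the result.
#' @param min_len Minimum ORF length (see [find_orfs()]).
#' @return A `coding_density_result`: one-row data frame with `contig`,
#'   `length`, `density11`, `density15`, `density4`, `assigned_code`,
#'   `margin` (density of the assigned code minus density under 11).
#' @export
assign_code <- function(seq, contig = "contig", min_len = 90L) {
  L <- nchar(seq)
  stopifnot(L > 0L)
  dens <- vapply(c(11, 15, 4), function(code)
    coding_density(find_orfs(seq, code, min_len = min_len), L), numeric(1))
  names(dens) <- c("11", "15", "4")
  thr <- if (L < 1e5) 0.10 else 0.05
  ex15 <- dens[["15"]] - dens[["11"]]
  ex4 <- dens[["4"]] - dens[["11"]]
  assigned <- 11L
  if (max(ex15, ex4) >= thr) {
    if (ex15 > ex4) assigned <- 15L
    else if (ex4 > ex15) assigned <- 4L
    # exact tie: unresolvable, keep 11
  }
  margin <- dens[[as.character(assigned)]] - dens[["11"]]
  out <- data.frame(contig = contig, length = L,
                    density11 = dens[["11"]], density15 = dens[["15"]],
                    density4 = dens[["4"]], assigned_code = assigned,
                    margin = margin, stringsAsFactors = FALSE)
  class(out) <- c("coding_density_result", "data.frame")
  out
}

#' Stratified recoding summary
#'
#' Fractions of contigs assigned to codes 11/15/4 in four strata: (i) all
#' contigs, (ii) contigs carrying a true-positive ribozyme hit, (iii)
#' contigs carrying a tRNA-associated ribozyme, (iv) contigs whose
#' associated tRNA is a suppressor.
#'
#' @param results Row-bound [assign_code()] results.
#' @param theta_contigs Character vector of contigs with ribozyme hits.
#' @param assoc_contigs Contigs with tRNA-associated hits.
#' @param sup_contigs Contigs with suppressor-tRNA-associated hits.
#' @return Data frame with one row per stratum: `n` and the code
#'   fractions (`NA` for an empty stratum).
#' @export
recoding_summary <- function(results, theta_contigs = character(),
                             assoc_contigs = character(),
                             sup_contigs = character()) {
  strata <- list(all = results$contig,
                 theta = intersect(results$contig, theta_contigs),
                 trna_associated = intersect(results$contig, assoc_contigs),
                 sup_associated = intersect(results$contig, sup_contigs))
  rows <- lapply(names(strata), function(nm) {
    ct <- strata[[nm]]
    sub <- results[results$contig %in% ct, , drop = FALSE]
    n <- nrow(sub)
    frac <- function(code) if (n == 0L) NA_real_ else
      mean(sub$assigned_code == code)
    data.frame(stratum = nm, n = n, frac_code11 = frac(11L),
               frac_code15 = frac(15L), frac_code4 = frac(4L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
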