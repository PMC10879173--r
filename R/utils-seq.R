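# Internal nucleotide utilities shared by the motif engine and the
# synthetic-data generator. Sequences are plain upper-case character
# scalars over the IUPAC DNA alphabet; U is accepted on input as T.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.MASK_BASES <- list(`1` = "A", `2` = "C", `4` = "G", `8` = "T")

#' @keywords internal
.seq_to_masks <- function(seq, what = "sequence") {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  m <- unname(.IUPAC_MASK[ch])
  if (anyNA(m)) {
    bad <- unique(ch[is.na(m)])
    stop(sprintf("invalid character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m
}

.mask_to_bases <- function(mask) {
  b <- c("A", "C", "G", "T")
  b[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented code-wise (e.g. R -> Y).
#'
#' @param seq character scalar over the IUPAC DNA alphabet.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  from <- "ACGTUNRYSWKMBDHVacgtunryswkmbdhv"
  to   <- "TGCAANYRSWMKVHDBtgcaanyrswmkvhdb"
  paste(rev(strsplit(chartr(from, to, seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' @keywords internal
.random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Watson-Crick complement of a concrete base; wobble partner or NA.
.WC <- c(A = "T", C = "G", G = "C", T = "A")
.WOBBLE <- c(G = "T", T = "G", A = NA_character_, C = NA_character_)

#' @keywords internal
.is_dna_concrete <- function(seq) {
  grepl("^[ACGT]*$", toupper(seq))
}
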