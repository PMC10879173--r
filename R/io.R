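# Format plumbing: FASTA via Biostrings, GFF3 and TSV writers with a
# provenance header, and readers for tRNA annotation tables (a
# tRNAscan-SE-like TSV dialect or GFF3).

#' @keywords internal
.as_seq_vector <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- Biostrings::readDNAStringSet(seqs)
  if (methods::is(seqs, "DNAStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (!is.character(seqs))
    stop("expected a named character vector, DNAStringSet, or FASTA path",
         call. = FALSE)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("contig", seq_along(seqs))
  # FASTA headers: keep the first word as the contig id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @keywords internal
.provenance_header <- function(extra = character()) {
  v <- as.character(utils::packageVersion("thetascan"))
  c(sprintf("## thetascan %s", v), extra)
}

#' @keywords internal
.string_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' Write a data frame as TSV with a provenance header
#' @param df Data frame (list columns are dropped).
#' @param path Output path.
#' @param header Extra comment lines (without the leading `##`).
#' @export
write_tsv_report <- function(df, path, header = character()) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(sprintf("## %s", header)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_report()]
#' @param path Input path.
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write ribozyme hits as GFF3
#'
#' Coordinates are converted from the internal 0-based half-open
#' convention to GFF3's 1-based inclusive one. Feature type is
#' `"ribozyme"`; attributes carry the variant, the (optional) record
#' name, and the cleavage-site coordinate.
#'
#' @param hits `drz_hits` frame; an optional `name` column is emitted.
#' @param path Output path.
#' @param source GFF3 source field.
#' @export
write_hits_gff3 <- function(hits, path, source = "thetascan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(.provenance_header(), con)
  if (nrow(hits)) {
    attr_str <- sprintf("ID=hit%d;variant=%s;cleavage_site=%d",
                        seq_len(nrow(hits)), hits$variant,
                        hits$cleavage_site + 1L)
    if (!is.null(hits$name))
      attr_str <- paste0(attr_str, ";Name=", hits$name)
    lines <- sprintf("%s\t%s\tribozyme\t%d\t%d\t.\t%s\t.\t%s",
                     hits$contig, source, hits$start + 1L, hits$end,
                     hits$strand, attr_str)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write ORF intervals as GFF3
#' @param orfs Frame with `contig` (optional), `start`, `end` (0-based
#'   half-open), `strand`.
#' @param path Output path.
#' @param type Feature type, default `"CDS"`.
#' @export
write_orfs_gff3 <- function(orfs, path, type = "CDS") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(.provenance_header(), con)
  if (nrow(orfs)) {
    contig <- orfs$contig %||% "contig"
    writeLines(sprintf("%s\tthetascan\t%s\t%d\t%d\t.\t%s\t0\tID=orf%d",
                       contig, type, orfs$start + 1L, orfs$end,
                       orfs$strand, seq_len(nrow(orfs))), con)
  }
  invisible(path)
}

#' Read tRNA annotations
#'
#' Two dialects are accepted. TSV: columns `contig`, `strand`, `begin`,
#' `end` (0-based half-open), `anticodon`, `isotype`, optional `sequence`.
#' GFF3: features of type `tRNA` with `anticodon` and `isotype`
#' attributes (1-based inclusive coordinates, converted on read). The
#' strand-aware 3'-end coordinate (`three_prime_end`, the last tRNA
#' nucleotide) is derived from the interval.
#'
#' @param path Input path; format chosen by extension (`.gff3`/`.gff` vs
#'   anything else).
#' @return A `trna_annotations` data frame.
#' @export
read_trna_annotations <- function(path) {
  if (grepl("\\.gff3?$", path)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(lines)) return(.empty_trnas())
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    keep <- f[, 3] == "tRNA"
    f <- f[keep, , drop = FALSE]
    if (!nrow(f)) return(.empty_trnas())
    getattr <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
      vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
             character(1))
    }
    df <- data.frame(contig = f[, 1], strand = f[, 7],
                     begin = as.integer(f[, 4]) - 1L,
                     end = as.integer(f[, 5]),
                     anticodon = toupper(getattr(f[, 9], "anticodon")),
                     isotype = getattr(f[, 9], "isotype"),
                     sequence = getattr(f[, 9], "sequence"),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("contig", "strand", "begin", "end", "anticodon", "isotype")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(sprintf("tRNA table %s lacks column(s): %s", path,
                   paste(miss, collapse = ", ")), call. = FALSE)
    if (is.null(df$sequence)) df$sequence <- NA_character_
  }
  as_trna_annotations(df)
}

.empty_trnas <- function() {
  as_trna_annotations(data.frame(
    contig = character(), strand = character(), begin = integer(),
    end = integer(), anticodon = character(), isotype = character(),
    sequence = character(), stringsAsFactors = FALSE))
}

#' Validate and complete a tRNA annotation frame
#'
#' @param df Frame with `contig`, `strand`, `begin`, `end` (0-based
#'   half-open), `anticodon`, `isotype`, optional `sequence` and
#'   `three_prime_end`.
#' @return A `trna_annotations` data frame with `three_prime_end` filled
#'   in (coordinate of the last tRNA nucleotide on the coding strand).
#' @export
as_trna_annotations <- function(df) {
  if (is.null(df$sequence)) df$sequence <- NA_character_
  if (nrow(df)) {
    stopifnot(all(df$begin < df$end), all(df$strand %in% c("+", "-")),
              all(nchar(df$anticodon) == 3L | is.na(df$anticodon)))
    if (is.null(df$three_prime_end))
      df$three_prime_end <- ifelse(df$strand == "+", df$end - 1L, df$begin)
    stopifnot(all(df$three_prime_end >= df$begin &
                    df$three_prime_end < df$end))
  } else if (is.null(df$three_prime_end)) {
    df$three_prime_end <- integer(0)
  }
  class(df) <- c("trna_annotations", "data.frame")
  df
}

#' Write tRNA annotations as TSV
#' @param trnas `trna_annotations` frame.
#' @param path Output path.
#' @export
write_trna_tsv <- function(trnas, path) {
  write_tsv_report(as.data.frame(trnas), path, "tRNA annotations")
}
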