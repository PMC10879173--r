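# Synthetic phage-like contigs with a ground-truth manifest.
#
# The generator emulates the genomic structures the pipeline is designed
# to detect: tRNA genes with annotated 3'-ends/anticodons/CCA status,
# ribozyme motif instances (active and catalytic-position-substituted
# variants) directly downstream of tRNAs or isolated, protein-coding
# genes written in genetic code 11 or 15 (with a controlled in-frame TAG
# rate), and stop-codon-rich intergenic DNA. The intergenic background
# carries a stop codon in every reading frame at least every 30 nt on
# both strands, so it contributes no ORFs of >= 90 nt and the designed
# coding density is recoverable to within small ORF-end effects.
# Placeholder tRNAs are length-realistic annotated blocks, not foldable
# cloverleafs: tRNA detection is out of scope and annotations are the
# pipeline input.

#' Sample a nucleotide string satisfying a descriptor
#'
#' Element lengths are drawn uniformly within their ranges and
#' nucleotides uniformly within their IUPAC constraints; helix 3' strands
#' are generated reverse-complementary to their partners, substituting a
#' G.T wobble pair with probability `wobble_prob` where the helix allows
#' it and the strand constraint still holds. The returned string is
#' guaranteed to be matched by [scan_sequence()] with the same
#' descriptor.
#'
#' @param d A `drz_descriptor`.
#' @param seed Optional RNG seed.
#' @param wobble_prob Per-position wobble substitution probability.
#' @return A DNA string.
#' @export
sample_motif_instance <- function(d, seed = NULL, wobble_prob = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  el <- d$elements
  for (attempt in 1:200) {
    lens <- integer(nrow(el))
    for (j in seq_len(nrow(el))) {
      lens[j] <- if (el$kind[j] == "helix_3p")
        lens[match(el$partner[j], el$id)]
      else if (el$min_len[j] == el$max_len[j]) el$min_len[j]
      else sample(el$min_len[j]:el$max_len[j], 1L)
    }
    parts <- vector("list", nrow(el))
    ok <- TRUE
    for (j in seq_len(nrow(el))) {
      l <- lens[j]
      cons <- el$constraint[j]
      cmask <- if (nzchar(cons)) .seq_to_masks(cons) else rep(15L, max(l, 1L))
      if (el$kind[j] != "helix_3p") {
        chars <- vapply(seq_len(l), function(i) {
          b <- .mask_to_bases(cmask[i])
          if (!length(b)) return(NA_character_)
          if (length(b) == 1L) b else sample(b, 1L)
        }, character(1))
        if (anyNA(chars)) { ok <- FALSE; break }
        parts[[j]] <- chars
      } else {
        p5 <- parts[[match(el$partner[j], el$id)]]
        chars <- character(l)
        for (i in seq_len(l)) {
          x <- p5[l - i + 1L]               # paired 5' strand position
          cand <- .WC[[x]]
          wb <- .WOBBLE[[x]]
          allowed <- .mask_to_bases(cmask[i])
          cand_ok <- intersect(c(cand, wb[!is.na(wb)]), allowed)
          if (!length(cand_ok)) { chars <- NULL; break }
          pick <- cand_ok[1L]
          if (length(cand_ok) > 1L && el$wobble[j] &&
              stats::runif(1) < wobble_prob)
            pick <- setdiff(cand_ok, cand)[1L]
          chars[i] <- pick
        }
        if (is.null(chars)) { ok <- FALSE; break }
        parts[[j]] <- chars
      }
    }
    if (ok)
      return(paste(unlist(parts), collapse = ""))
  }
  stop(sprintf("descriptor %s: constraints unsatisfiable", d$name),
       call. = FALSE)
}

#' Build a tRNA/ribozyme cassette
#'
#' A placeholder tRNA block (70-90 nt, anticodon embedded around position
#' 34, optional genomically encoded CCA tail), an optional spacer, and a
#' ribozyme motif instance. `spacing` is the number of spacer nucleotides
#' between the tRNA's physical 3'-end and the ribozyme's G1, so the
#' resulting 3'-end-to-cleavage-site distance is `spacing + 1`. Negative
#' spacings keep the blocks adjacent but shift the *annotated* 3'-end
#' into the ribozyme, emulating tRNA end-prediction error.
#'
#' @param isotype,anticodon tRNA annotation fields.
#' @param spacing Integer in `[-5, 10]`.
#' @param cca Append a genomically encoded CCA tail.
#' @param d Descriptor used to sample the ribozyme instance.
#' @param seed Optional RNG seed.
#' @return List: `cassette` (string), `trna` (relative annotation:
#'   `begin`, `end`, `three_prime_end`, `anticodon`, `isotype`,
#'   `sequence`, `cca`), `rz` (`sequence`, `offset`, `cleavage_offset`),
#'   `spacing`, `distance`.
#' @export
generate_trna_cassette <- function(isotype, anticodon, spacing = 0L,
                                   cca = FALSE, d = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(spacing >= -5L, spacing <= 10L, grepl("^[ACGT]{3}$", anticodon))
  if (is.null(d)) d <- read_descriptor(descriptor_file("theta"))
  trna_len <- sample(70:90, 1L)
  trna <- strsplit(.random_dna(trna_len), "", fixed = TRUE)[[1]]
  trna[34:36] <- strsplit(anticodon, "", fixed = TRUE)[[1]]
  if (cca) {
    trna[(trna_len - 2L):trna_len] <- c("C", "C", "A")
  } else if (identical(trna[(trna_len - 2L):trna_len], c("C", "C", "A"))) {
    # keep cca_fraction exact: a non-CCA tRNA must not end in CCA by chance
    trna[trna_len] <- sample(c("C", "G", "T"), 1L)
  }
  trna <- paste(trna, collapse = "")
  rz <- sample_motif_instance(d)
  spacer <- .random_dna(max(spacing, 0L))
  cassette <- paste0(trna, spacer, rz)
  rz_off <- trna_len + max(spacing, 0L)
  cleav <- rz_off                       # G1 is the first motif nucleotide
  annot_3p <- cleav - spacing - 1L
  list(cassette = cassette,
       trna = list(begin = 0L, end = max(trna_len, annot_3p + 1L),
                   three_prime_end = annot_3p, anticodon = anticodon,
                   isotype = isotype, sequence = trna, cca = cca),
       rz = list(sequence = rz, offset = rz_off, cleavage_offset = cleav),
       spacing = as.integer(spacing),
       distance = as.integer(spacing) + 1L)
}

#' Specification of one synthetic contig
#'
#' Defaults describe a realistic gut-phage-like contig: dense coding
#' (target 0.72), mostly direct tRNA/ribozyme cassettes, a ~20%
#' suppressor-tRNA fraction among cassettes, a 4.5% genomically encoded
#' CCA rate, and (for code-15 contigs) an in-frame TAG rate of 0.04 per
#' codon.
#'
#' @param length Contig length (nt).
#' @param n_trna_cassettes Number of tRNA/ribozyme cassettes.
#' @param n_active,n_cda,n_cdg,n_cdu Isolated ribozyme instances per
#'   motif variant.
#' @param spacings Pool the cassette spacings are drawn from (nt, in
#'   `[-5, 10]`).
#' @param sup_fraction Probability a cassette tRNA is a suppressor
#'   (anticodon CTA).
#' @param cca_fraction Probability a tRNA encodes a CCA tail.
#' @param isotypes Isotype pool for non-suppressor tRNAs.
#' @param genetic_code 11 or 15.
#' @param orf_density_target Designed fraction of the contig covered by
#'   genes.
#' @param tag_rate In-frame TAG rate per codon for code-15 genes.
#' @param designed_excess Optional designed coding-density excess of code
#'   15 over code 11 (`NA` = let `tag_rate` act on all genes).
#' @param gene_len Range of gene lengths in codons.
#' @param rev_fraction Probability a feature is placed on the minus
#'   strand.
#' @param descriptor Active motif used for ribozyme instances (default:
#'   the shipped theta motif).
#' @param seed RNG seed for [build_genome()].
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length = 30000L, n_trna_cassettes = 4L,
                        n_active = 3L, n_cda = 0L, n_cdg = 0L, n_cdu = 0L,
                        spacings = c(-1L, 0L, 0L, 0L, 1L, 2L, 4L),
                        sup_fraction = 0.2, cca_fraction = 0.045,
                        isotypes = c("Met", "Leu", "Val", "Gly", "Ser",
                                     "Thr", "Gln"),
                        genetic_code = 11L, orf_density_target = 0.72,
                        tag_rate = 0.04, designed_excess = NA_real_,
                        gene_len = c(100L, 400L), rev_fraction = 0.3,
                        descriptor = NULL, seed = NULL) {
  stopifnot(length > 1000L, genetic_code %in% c(11L, 15L),
            orf_density_target >= 0, orf_density_target < 0.95,
            all(spacings >= -5L & spacings <= 10L),
            sup_fraction >= 0, sup_fraction <= 1,
            cca_fraction >= 0, cca_fraction <= 1)
  structure(as.list(environment()), class = "genome_spec")
}

# sense codons of the standard code (no TAA/TAG/TGA)
.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# "hidden-stop" block: four codons that are sense (in frame) under codes
# 11, 15 and 4 but whose 12-mer contains stop triplets in both non-coding
# forward frames and in all three reverse frames. Interleaving it into
# gene bodies emulates the frequent off-frame stops of real coding
# sequence, so the maximal-ORF surrogate does not call long spurious ORFs
# in shifted or reverse frames inside genes.
.HIDDEN_STOP_BLOCK <- c("CTA", "ACT", "AAC", "TAC")

# gene: ATG + body + TAA (TAA is a stop in codes 11, 15 and 4, keeping
# standard-code genes code-neutral); body codons are standard sense
# codons with a hidden-stop block every hs_every codons, plus in-frame
# TAGs at tag_rate for code-15 genes
#' @keywords internal
.make_gene <- function(n_codons, tag_rate = 0, hs_every = 6L) {
  n_body <- n_codons - 2L
  body <- character(0)
  while (length(body) < n_body) {
    k <- min(hs_every, n_body - length(body))
    rnd <- sample(.SENSE_CODONS, k, replace = TRUE)
    if (tag_rate > 0) {
      sub <- stats::runif(k) < tag_rate
      rnd[sub] <- "TAG"
    }
    body <- c(body, rnd)
    if (length(body) + length(.HIDDEN_STOP_BLOCK) <= n_body)
      body <- c(body, .HIDDEN_STOP_BLOCK)
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# intergenic DNA with a stop in every frame on both strands every 30 nt
#' @keywords internal
.stop_rich_spacer <- function(n) {
  if (n <= 0L) return("")
  units <- ceiling(n / 10)
  s <- paste(vapply(seq_len(units),
                    function(i) paste0(.random_dna(4L), "TAATTA"),
                    character(1)),
             collapse = "")
  substr(s, 1L, n)
}

#' Assemble a synthetic contig from a specification
#'
#' Features (cassettes, isolated ribozymes, genes) are built, shuffled,
#' optionally reverse-complemented, and concatenated with stop-rich
#' intergenic spacers; a complete ground-truth manifest records every
#' feature with its coordinates, strand, variant/isotype/anticodon,
#' designed spacing and expected association status.
#'
#' @param spec A `genome_spec`.
#' @param contig Contig id.
#' @return A `synthetic_genome` list: `contig`, `sequence`, `manifest`
#'   (data frame), `spec`.
#' @export
build_genome <- function(spec, contig = "contig1") {
  stopifnot(inherits(spec, "genome_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  d <- spec$descriptor
  if (is.null(d)) d <- read_descriptor(descriptor_file("theta"))
  fps <- derive_fp_variants(d)

  feats <- list()
  add <- function(f) feats[[length(feats) + 1L]] <<- f

  for (i in seq_len(spec$n_trna_cassettes)) {
    sup <- stats::runif(1) < spec$sup_fraction
    isotype <- if (sup) "Sup" else sample(spec$isotypes, 1L)
    anticodon <- if (sup) "CTA" else {
      repeat {
        a <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                   collapse = "")
        if (!a %in% c("CTA", "TCA", "TTA")) break
      }
      a
    }
    cas <- generate_trna_cassette(isotype, anticodon,
                                  spacing = sample(spec$spacings, 1L),
                                  cca = stats::runif(1) < spec$cca_fraction,
                                  d = d)
    add(list(type = "cassette", seq = cas$cassette, cas = cas))
  }
  for (v in c("active", "CdA", "CdG", "CdU")) {
    nv <- spec[[switch(v, active = "n_active", CdA = "n_cda",
                       CdG = "n_cdg", CdU = "n_cdu")]]
    dv <- if (v == "active") d else fps[[v]]
    for (i in seq_len(nv))
      add(list(type = "ribozyme", seq = sample_motif_instance(dv),
               variant = v))
  }

  # genes to reach the designed coding density
  gene_target <- spec$orf_density_target * spec$length
  heavy_target <- if (!is.na(spec$designed_excess) &&
                      spec$genetic_code == 15L)
    spec$designed_excess * spec$length else NA_real_
  tot <- 0
  heavy <- 0
  while (tot < gene_target) {
    nc <- sample(spec$gene_len[1]:spec$gene_len[2], 1L)
    # trim the last gene of a budget so designed totals are met closely
    nc <- min(nc, max(30L, ceiling((gene_target - tot) / 3)))
    if (!is.na(heavy_target)) {
      make_heavy <- heavy < heavy_target
      if (make_heavy)
        nc <- min(nc, max(30L, ceiling((heavy_target - heavy) / 3)))
      rate <- if (make_heavy) max(spec$tag_rate, 0.3) else 0
      if (make_heavy) heavy <- heavy + nc * 3L
    } else {
      rate <- if (spec$genetic_code == 15L) spec$tag_rate else 0
    }
    g <- .make_gene(nc, tag_rate = rate)
    add(list(type = "gene", seq = g,
             tagged = rate > 0))
    tot <- tot + nchar(g)
  }

  lens <- vapply(feats, function(f) nchar(f$seq), integer(1))
  min_gap <- 30L
  nfeat <- length(feats)
  slack <- spec$length - sum(lens) - (nfeat + 1L) * min_gap
  if (slack < 0)
    stop(sprintf(paste("infeasible packing: features (%d nt) + spacers",
                       "exceed length %d; reduce orf_density_target,",
                       "n_trna_cassettes or ribozyme counts"),
                 sum(lens), spec$length), call. = FALSE)
  ord <- sample.int(nfeat)
  # distribute slack over the nfeat+1 gaps
  cuts <- sort(sample.int(slack + nfeat, nfeat))
  gaps <- diff(c(0L, cuts, slack + nfeat + 1L)) - 1L + min_gap

  pieces <- character(0)
  man <- list()
  pos <- 0L
  emit <- function(row) man[[length(man) + 1L]] <<- row
  blank <- data.frame(type = NA_character_, contig = contig,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, variant = NA_character_,
                      isotype = NA_character_, anticodon = NA_character_,
                      cca = NA, spacing = NA_integer_,
                      distance = NA_integer_, expected_associated = NA,
                      cleavage_site = NA_integer_,
                      three_prime_end = NA_integer_,
                      tagged = NA, sequence = NA_character_,
                      stringsAsFactors = FALSE)

  for (k in seq_len(nfeat)) {
    sp <- .stop_rich_spacer(gaps[k])
    pieces <- c(pieces, sp)
    pos <- pos + nchar(sp)
    f <- feats[[ord[k]]]
    n <- nchar(f$seq)
    minus <- stats::runif(1) < spec$rev_fraction
    block <- if (minus) revcomp(f$seq) else f$seq
    strand <- if (minus) "-" else "+"
    # map a block-relative interval [a, b) to contig coordinates
    iv <- function(a, b) if (minus) c(pos + n - b, pos + n - a)
                         else c(pos + a, pos + b)
    pt <- function(a) if (minus) pos + n - 1L - a else pos + a
    if (f$type == "gene") {
      r <- blank; r$type <- "gene"; r$strand <- strand
      r[c("start", "end")] <- as.list(iv(0L, n))
      r$tagged <- f$tagged
      emit(r)
    } else if (f$type == "ribozyme") {
      r <- blank; r$type <- "ribozyme"; r$strand <- strand
      r[c("start", "end")] <- as.list(iv(0L, n))
      r$variant <- f$variant
      r$cleavage_site <- pt(0L)
      r$expected_associated <- FALSE
      r$sequence <- f$seq
      emit(r)
    } else {
      cas <- f$cas
      rt <- blank; rt$type <- "trna"; rt$strand <- strand
      rt[c("start", "end")] <- as.list(iv(cas$trna$begin, cas$trna$end))
      rt$isotype <- cas$trna$isotype
      rt$anticodon <- cas$trna$anticodon
      rt$cca <- cas$trna$cca
      rt$three_prime_end <- pt(cas$trna$three_prime_end)
      rt$sequence <- cas$trna$sequence
      emit(rt)
      rz <- blank; rz$type <- "ribozyme"; rz$strand <- strand
      rz[c("start", "end")] <- as.list(iv(cas$rz$offset,
                                          cas$rz$offset + nchar(cas$rz$sequence)))
      rz$variant <- "active"
      rz$spacing <- cas$spacing
      rz$distance <- cas$distance
      rz$expected_associated <- abs(cas$distance) <= 5L
      rz$cleavage_site <- pt(cas$rz$cleavage_offset)
      rz$sequence <- cas$rz$sequence
      emit(rz)
    }
    pieces <- c(pieces, block)
    pos <- pos + n
  }
  tail_gap <- spec$length - pos
  pieces <- c(pieces, .stop_rich_spacer(tail_gap))
  seq <- paste(pieces, collapse = "")
  manifest <- if (length(man)) do.call(rbind, man) else blank[0, ]
  rownames(manifest) <- NULL
  structure(list(contig = contig, sequence = seq, manifest = manifest,
                 spec = spec),
            class = "synthetic_genome")
}

#' Manifest tRNA annotations of one or more synthetic genomes
#'
#' @param genomes A `synthetic_genome` or list of them.
#' @return A `trna_annotations` frame built from the manifests.
#' @export
manifest_trnas <- function(genomes) {
  if (inherits(genomes, "synthetic_genome")) genomes <- list(genomes)
  man <- do.call(rbind, lapply(genomes, `[[`, "manifest"))
  tr <- man[man$type == "trna", , drop = FALSE]
  as_trna_annotations(data.frame(
    contig = tr$contig, strand = tr$strand, begin = tr$start,
    end = tr$end, anticodon = tr$anticodon, isotype = tr$isotype,
    sequence = tr$sequence, three_prime_end = tr$three_prime_end,
    stringsAsFactors = FALSE))
}

#' Sample shotgun-style reads from a genome
#'
#' Uniform start positions on both strands, constant quality; the short
#' read length (default 150 nt) emulates metagenomic raw-read data in
#' which a tRNA and a ribozyme rarely co-occur on one read.
#'
#' @param seq Genome sequence (character scalar).
#' @param n_reads Number of reads.
#' @param read_length Read length (<= genome length).
#' @param seed Optional RNG seed.
#' @return Data frame: `read_id`, `start` (0-based), `strand`,
#'   `sequence`.
#' @export
sample_reads <- function(seq, n_reads, read_length = 150L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(seq)
  stopifnot(read_length <= L, n_reads >= 0L)
  if (n_reads == 0L)
    return(data.frame(read_id = character(), start = integer(),
                      strand = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  start <- sample.int(L - read_length + 1L, n_reads, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  fwd <- substring(seq, start + 1L, start + read_length)
  sq <- ifelse(strand == "+", fwd, vapply(fwd, revcomp, character(1),
                                          USE.NAMES = FALSE))
  data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
             start = start, strand = strand, sequence = sq,
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#' @param reads Output of [sample_reads()].
#' @param path Output path.
#' @param quality Constant quality character.
#' @export
write_reads_fastq <- function(reads, path, quality = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    q <- strrep(quality, nchar(reads$sequence))
    writeLines(rbind(paste0("@", reads$read_id), reads$sequence,
                     "+", q), con)
  }
  invisible(path)
}
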