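test_that("drz-Mtgn-1 validates against the shipped minimal motif", {
  d <- read_descriptor(descriptor_file("minimal_drz"))
  h <- scan_sequence(d, drz_mtgn1)
  expect_gte(nrow(h), 1L)
  # an active hit starts at the 5' G and the cleavage site is G1
  expect_true(any(h$start == 0L & h$strand == "+"))
  expect_equal(h$cleavage_site[h$start == 0L & h$strand == "+"][1], 0L)
  # match count agrees with exhaustive enumeration
  oracle <- oracle_scan(d, drz_mtgn1)
  fwd <- h[h$strand == "+", ]
  expect_equal(fwd$start, oracle$start)
  expect_equal(fwd$end, oracle$end)
})

test_that("an embedded motif instance is found exactly at its offset", {
  d <- read_descriptor(descriptor_file("theta"))
  set.seed(7)
  inst <- sample_motif_instance(d)
  genome <- paste0(random_dna(100), inst, random_dna(100))
  h <- scan_sequence(d, genome, both_strands = FALSE)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 100L)
  expect_equal(h$end, 100L + nchar(inst))
})

test_that("a dinucleotide-shuffled drz-Mtgn-1 matches the oracle count (zero)", {
  d <- read_descriptor(descriptor_file("minimal_drz"))
  set.seed(11)
  shuf <- dinucleotide_shuffle(drz_mtgn1)
  h <- scan_sequence(d, shuf, both_strands = FALSE)
  oracle <- oracle_scan(d, shuf)
  expect_equal(nrow(h), nrow(oracle))
  expect_equal(nrow(h), 0L)
})

test_that("scan equals exhaustive enumeration on random descriptor/sequence cases", {
  set.seed(101)
  for (i in 1:60) {
    d <- random_descriptor()
    s <- random_dna(sample(20:60, 1), n_prob = if (i %% 4 == 0) 0.05 else 0)
    h <- scan_sequence(d, s, both_strands = FALSE)
    o <- oracle_scan(d, s)
    expect_equal(h$start, o$start,
                 info = paste("case", i, paste(d$elements$id, collapse = " "), s))
    expect_equal(h$end, o$end, info = paste("case", i))
  }
})

test_that("scanning is strand-symmetric", {
  d <- read_descriptor(descriptor_file("theta"))
  set.seed(21)
  inst <- sample_motif_instance(d)
  genome <- paste0(random_dna(60), inst, random_dna(60))
  L <- nchar(genome)
  a <- scan_sequence(d, genome)
  b <- scan_sequence(d, revcomp(genome))
  # reverse-complementing the subject mirrors coordinates and flips strands
  expect_gte(nrow(a), 1L)
  expect_equal(nrow(a), nrow(b))
  flip <- c(`+` = "-", `-` = "+")
  expect_setequal(paste(L - b$end, L - b$start, flip[b$strand]),
                  paste(a$start, a$end, a$strand))
  # cleavage sites mirror too
  expect_setequal(L - 1L - b$cleavage_site, a$cleavage_site)
})

test_that("empty input and invalid characters behave per contract", {
  d <- toy_descriptor()
  expect_equal(nrow(scan_sequence(d, "")), 0L)
  expect_error(scan_sequence(d, "ACGTX"), "invalid character")
})

test_that("variant scans partition unambiguous catalytic loci", {
  d <- read_descriptor(descriptor_file("theta"))
  variants <- c(list(active = d), derive_fp_variants(d))
  set.seed(31)
  for (v in names(variants)) {
    inst <- sample_motif_instance(variants[[v]])
    matched <- vapply(variants, function(dv)
      nrow(scan_sequence(dv, inst, both_strands = FALSE)) > 0, logical(1))
    expect_equal(unname(matched), names(variants) == v, info = v)
  }
})

test_that("classify_hits applies the dual-fit true-positive rule", {
  hit <- function(contig, start, end, strand, variant, seq)
    data.frame(contig = contig, start = start, end = end, strand = strand,
               variant = variant, sequence = seq, cleavage_site = start,
               stringsAsFactors = FALSE)
  # locus matched by both active and CdU -> true positive
  a <- hit("c1", 100, 150, "+", "active", "AAA")
  f <- rbind(hit("c1", 100, 150, "+", "CdU", "AAT"),
             hit("c1", 400, 450, "+", "CdG", "GGG"),  # FP-only locus
             hit("c2", 100, 150, "+", "CdA", "CCC"))  # disjoint contig
  lab <- classify_hits(a, f)
  expect_equal(lab$label[lab$variant == "active"], "true_positive")
  expect_equal(lab$label[lab$variant == "CdU"], "true_positive")
  expect_equal(lab$label[lab$variant == "CdG"], "false_positive")
  expect_equal(lab$label[lab$variant == "CdA"], "false_positive")
  # disjoint active and FP loci on one contig give one record each
  expect_equal(length(unique(lab$locus)), 3L)
})

test_that("fp_rate counts unique sequences", {
  mk <- function(n, variant, label, prefix)
    data.frame(contig = "c", start = seq_len(n), end = seq_len(n) + 10,
               strand = "+", variant = variant,
               sequence = paste0(prefix, seq_len(n)), cleavage_site = 0,
               label = label, stringsAsFactors = FALSE)
  h <- rbind(mk(10, "active", "true_positive", "a"),
             mk(10, "CdU", "false_positive", "f"))
  expect_equal(fp_rate(h), 0.5)
  expect_equal(fp_rate(mk(5, "active", "true_positive", "a")), 0)
  expect_warning(r <- fp_rate(h[0, ]), "undefined")
  expect_true(is.na(r))
})

test_that("a genome seeded with 8 active and 2 CdU instances gives fp_rate 0.2", {
  sp <- genome_spec(length = 25000L, n_trna_cassettes = 0L, n_active = 8L,
                    n_cdu = 2L, orf_density_target = 0.3, seed = 77)
  g <- build_genome(sp)
  d <- read_descriptor(descriptor_file("theta"))
  hits <- scan_contigs(d, setNames(g$sequence, g$contig), variants = TRUE)
  lab <- classify_hits(hits)
  expect_equal(fp_rate(lab), 0.2)
})

test_that("dereplication ranks by occurrence with lexicographic ties", {
  h <- data.frame(sequence = c("TTT", "TTT", "AAA", "CCC", "CCC"),
                  stringsAsFactors = FALSE)
  r <- dereplicate_hits(h)
  expect_equal(r$sequence, c("CCC", "TTT", "AAA"))
  expect_equal(r$occurrences, c(2L, 2L, 1L))
  expect_equal(r$name, c("Θ0001", "Θ0002", "Θ0003"))
  # occurrences are conserved
  expect_equal(sum(r$occurrences), nrow(h))
  # deterministic across reruns
  expect_identical(r, dereplicate_hits(h))
})

test_that("element consensus computes tiers from aligned frequencies", {
  # fixed-length descriptor so the alignment is gap-free
  d <- parse_descriptor(c("order: s1", "s1 10:10 -", "cleavage: s1"))
  base <- "ACGTACGTAC"
  recs <- data.frame(sequence = rep(base, 100), name = sprintf("r%03d", 1:100),
                     stringsAsFactors = FALSE)
  cons <- element_consensus(recs, d)
  expect_true(all(cons$tier == ">=0.97"))
  expect_equal(cons$modal, strsplit(base, "")[[1]])

  # 96/100 modal -> >=0.90 but not >=0.97
  recs2 <- recs
  recs2$sequence[1:4] <- "CCGTACGTAC"
  cons2 <- element_consensus(recs2, d)
  expect_equal(cons2$tier[1], ">=0.90")
  expect_equal(cons2$modal_freq[1], 0.96)

  # mutated set: tiers match direct frequency counts
  set.seed(5)
  seqs <- vapply(1:50, function(i) {
    ch <- strsplit(base, "")[[1]]
    mut <- runif(10) < 0.05
    ch[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  recs3 <- data.frame(sequence = seqs, name = sprintf("m%02d", 1:50),
                      stringsAsFactors = FALSE)
  cons3 <- element_consensus(recs3, d)
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (p in 1:10) {
    tab <- table(factor(mat[, p], levels = c("A", "C", "G", "T")))
    expect_equal(cons3$modal_freq[p], max(tab) / 50)
  }
  # a record that does not match the descriptor is reported by name
  bad <- data.frame(sequence = "ACGT", name = "bad1", stringsAsFactors = FALSE)
  expect_error(element_consensus(bad, d), "bad1")
})
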