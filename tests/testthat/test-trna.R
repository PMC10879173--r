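mk_hit <- function(contig = "c1", start = 1000L, end = 1050L, strand = "+",
                   cleavage = start)
  data.frame(contig = contig, start = start, end = end, strand = strand,
             variant = "active", sequence = "X", cleavage_site = cleavage,
             stringsAsFactors = FALSE)

mk_trna <- function(contig = "c1", strand = "+", begin = 900L, end = 1000L,
                    anticodon = "CAT", isotype = "Met", three_prime = NULL) {
  df <- data.frame(contig = contig, strand = strand, begin = begin,
                   end = end, anticodon = anticodon, isotype = isotype,
                   sequence = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(three_prime)) df$three_prime_end <- three_prime
  as_trna_annotations(df)
}

test_that("association distance and adjacency follow the +/-5 window", {
  # tRNA 3'-end at 999, cleavage site at 1000 -> distance +1, direct
  a <- associate_trnas(mk_hit(cleavage = 1000L), mk_trna(end = 1000L))
  expect_equal(a$distance, 1L)
  expect_equal(a$adjacency, "direct")
  # distance -5 -> near
  a <- associate_trnas(mk_hit(cleavage = 994L), mk_trna(end = 1000L))
  expect_equal(a$distance, -5L)
  expect_equal(a$adjacency, "near")
  # distance 6 -> no record
  a <- associate_trnas(mk_hit(cleavage = 1005L), mk_trna(end = 1000L))
  expect_equal(nrow(a), 0L)
  # strand mismatch -> no record unless allow_antisense
  a <- associate_trnas(mk_hit(), mk_trna(strand = "-", three_prime = 900L))
  expect_equal(nrow(a), 0L)
})

test_that("each hit pairs with its nearest tRNA, ties to the upstream one", {
  trnas <- rbind(mk_trna(end = 999L),                 # d = +2
                 mk_trna(end = 1004L, isotype = "Leu")) # d = -3
  a <- associate_trnas(mk_hit(cleavage = 1000L), trnas)
  expect_equal(nrow(a), 1L)
  expect_equal(a$trna_row, 1L)
  # exact tie in |d|: upstream (more positive distance) wins
  trnas2 <- rbind(mk_trna(end = 998L),                  # d = +3
                  mk_trna(end = 1004L, isotype = "Leu")) # d = -3
  a2 <- associate_trnas(mk_hit(cleavage = 1000L), trnas2)
  expect_equal(a2$trna_row, 1L)
  expect_equal(a2$distance, 3L)
})

test_that("association works on minus-strand cassettes", {
  # minus strand: tRNA downstream in forward coordinates
  h <- mk_hit(start = 500L, end = 550L, strand = "-", cleavage = 549L)
  tr <- mk_trna(strand = "-", begin = 550L, end = 630L, three_prime = 550L)
  a <- associate_trnas(h, tr)
  expect_equal(a$distance, 1L)
  expect_equal(a$adjacency, "direct")
})

test_that("genomic context classification follows overlap/distance/strand rules", {
  hit <- list(start = 1000L, end = 1050L, strand = "+")
  orf <- function(s, e, strand = "+")
    data.frame(start = s, end = e, strand = strand, stringsAsFactors = FALSE)
  expect_equal(classify_context(hit, orf(900, 2000)), "intragenic")
  expect_equal(classify_context(hit, orf(1049, 1200)), "intragenic") # 1 nt
  expect_equal(classify_context(hit, orf(1351, 1500)), "distal")    # 301 nt
  expect_equal(classify_context(hit, orf(1150, 1300)), "noncoding_sense")
  expect_equal(classify_context(hit, orf(1150, 1300, "-")),
               "noncoding_antisense")
  # hit 50 nt downstream of a minus-strand ORF, hit on +
  expect_equal(classify_context(hit, orf(800, 950, "-")),
               "noncoding_antisense")
  # tie in distance: downstream ORF wins
  both <- rbind(orf(850, 950, "-"), orf(1100, 1200, "+"))
  expect_equal(classify_context(hit, both), "noncoding_sense")
  expect_equal(classify_context(hit, NULL), "distal")
})

test_that("exactly three anticodons are suppressors", {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  reads <- is_suppressor(all64)
  expect_equal(sum(!is.na(reads)), 3L)
  expect_equal(is_suppressor("CTA"), "UAG")
  expect_equal(is_suppressor("TCA"), "UGA")
  expect_equal(is_suppressor("TTA"), "UAA")
  expect_true(is.na(is_suppressor("TAC")))
  expect_error(is_suppressor("CU"), "malformed")
})

test_that("CCA-tail detection and generator CCA fraction", {
  expect_true(has_cca_tail("GGTCCA"))
  expect_false(has_cca_tail("GGTCC"))
  # generator tRNAs at cca_fraction 0.045: observed fraction within the
  # binomial 99% CI around 0.045 for n = 1000
  set.seed(13)
  d <- toy_descriptor()
  flags <- runif(1000) < 0.045
  seqs <- vapply(flags, function(cca)
    generate_trna_cassette("Met", "CAT", 0L, cca = cca, d = d)$trna$sequence,
    character(1))
  obs <- mean(has_cca_tail(seqs))
  ci <- qbinom(c(0.005, 0.995), 1000, 0.045) / 1000
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
})

test_that("pair names combine isotype and occurrence ranks", {
  expect_equal(name_pairs("Val", 25, 46), "tRNAVal0025_Θ0046")
  expect_equal(name_pairs("Met", 1, 1), "tRNAMet0001_Θ0001")
  expect_error(name_pairs("Met", NA, 1), "unranked")
  # unique and stable across reruns
  set.seed(3)
  iso <- sample(c("Met", "Leu", "Sup"), 12, replace = TRUE)
  n1 <- name_pairs(iso, 1:12, 12:1)
  n2 <- name_pairs(iso, 1:12, 12:1)
  expect_identical(n1, n2)
  expect_equal(anyDuplicated(n1), 0L)
})

test_that("fold enrichment is a simple ratio with a guarded background", {
  expect_equal(fold_enrichment(0.5, 0.25), 2)
  expect_equal(fold_enrichment(0.3, 0.3), 1)
  # the tRNA adenylyltransferase arithmetic: 20.6% vs 0.08% ~ 250-fold
  expect_equal(fold_enrichment(0.206, 0.0008), 257.5)
  expect_error(fold_enrichment(0.5, 0), "zero background")
})

test_that("association on synthetic cassettes is manifest-exact", {
  sp <- genome_spec(length = 25000L, n_trna_cassettes = 6L, n_active = 3L,
                    spacings = c(-2L, 0L, 1L, 3L, 8L),
                    orf_density_target = 0.3, seed = 99)
  g <- build_genome(sp)
  d <- read_descriptor(descriptor_file("theta"))
  hits <- scan_contigs(d, setNames(g$sequence, g$contig))
  trnas <- manifest_trnas(g)
  a <- associate_trnas(hits, trnas)
  man <- g$manifest[g$manifest$type == "ribozyme", ]
  expected <- man[which(man$expected_associated), ]
  # recall and precision 1.0: associated cleavage sites match the manifest
  expect_setequal(hits$cleavage_site[a$hit_row], expected$cleavage_site)
  # distances equal the designed spacing + 1
  key <- match(hits$cleavage_site[a$hit_row], expected$cleavage_site)
  expect_equal(a$distance, expected$distance[key])
  expect_true(all(abs(a$distance) <= 5))
  # direct/near partition the associations
  expect_setequal(unique(a$adjacency[abs(a$distance) <= 1]), "direct")
  expect_true(all(a$adjacency[abs(a$distance) > 1] == "near"))
})

test_that("association is invariant under coordinate mirroring", {
  h <- mk_hit(start = 100L, end = 150L, strand = "+", cleavage = 100L)
  tr <- mk_trna(begin = 20L, end = 97L)   # 3' end 96, d = +4
  a <- associate_trnas(h, tr)
  L <- 1000L
  # mirror: reverse-complement the contig
  h2 <- h; h2$start <- L - h$end; h2$end <- L - h$start; h2$strand <- "-"
  h2$cleavage_site <- L - 1L - h$cleavage_site
  tr2 <- mk_trna(strand = "-", begin = L - tr$end, end = L - tr$begin,
                 three_prime = L - 1L - tr$three_prime_end)
  a2 <- associate_trnas(h2, tr2)
  expect_equal(a2$distance, a$distance)
  expect_equal(a2$adjacency, a$adjacency)
})
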