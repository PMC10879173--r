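# Fixture builders: toy descriptors and random descriptor/sequence cases
# for the oracle-equivalence property tests.

toy_descriptor <- function() {
  parse_descriptor(c(
    "order: s1 h1 s2 h1'",
    "s1 2:2 NN",
    "h1 3:3 NNN",
    "s2 2:4 -",
    "h1' 3:3 NNN",
    "cleavage: s1"))
}

# single-strand-only descriptor with a catalytic C at offset 0 of j42
toy_catalytic_descriptor <- function() {
  parse_descriptor(c(
    "order: s1 j42 s2",
    "s1 3:3 GGG",
    "j42 3:3 CNN",
    "s2 3:3 TTT",
    "catalytic: j42 0",
    "cleavage: s1"))
}

random_dna <- function(n, n_prob = 0) {
  pool <- c("A", "C", "G", "T")
  s <- sample(pool, n, replace = TRUE)
  if (n_prob > 0) {
    amb <- runif(n) < n_prob
    s[amb] <- "N"
  }
  paste(s, collapse = "")
}

# a small random descriptor (<= 5 elements, <= 1 helix) in dialect text
random_descriptor <- function() {
  iupac <- c("A", "C", "G", "T", "R", "Y", "N", "W", "S")
  rand_cons <- function(len) paste(sample(iupac, len, replace = TRUE),
                                   collapse = "")
  tmpl <- sample(list(
    c("s1"),
    c("s1", "h1", "s2", "h1'"),
    c("h1", "s1", "h1'"),
    c("h1", "s1", "h1'", "s2"),
    c("s1", "h1", "s2", "h1'", "s3")), 1)[[1]]
  lines <- paste("order:", paste(tmpl, collapse = " "))
  hlen_min <- sample(2:3, 1)
  hlen_max <- hlen_min + sample(0:1, 1)
  hw <- sample(c("wobble=0", "wobble=1"), 1)
  for (id in tmpl) {
    if (grepl("^h", id)) {
      cons <- if (!grepl("'", id) && runif(1) < 0.3) rand_cons(hlen_max) else "-"
      lines <- c(lines, paste(id, paste0(hlen_min, ":", hlen_max), cons, hw))
    } else {
      mn <- sample(0:2, 1); mx <- mn + sample(0:2, 1)
      cons <- if (mx > 0 && runif(1) < 0.4) rand_cons(mx) else "-"
      lines <- c(lines, paste(id, paste0(mn, ":", mx), cons))
    }
  }
  parse_descriptor(lines)
}

drz_mtgn1 <- "GGTAGCACACCTATGCGTTCCCGTCGCGCTACTGATTTAGACTAAATAGGT"

# non-overlapping dinucleotide shuffle (deterministic under the caller's
# RNG state)
dinucleotide_shuffle <- function(seq) {
  n <- nchar(seq)
  pairs <- substring(seq, seq(1, n - 1, by = 2), seq(2, n, by = 2))
  tail <- if (n %% 2 == 1) substr(seq, n, n) else ""
  paste0(paste(sample(pairs), collapse = ""), tail)
}
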