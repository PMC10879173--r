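# Independent oracles, implemented from scratch (no shared code with the
# package's matcher): an exhaustive enumeration scanner for small
# descriptors/sequences and a codon-by-codon six-frame ORF scanner.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# all placements (start, end), 0-based half-open, on the given strand only
oracle_scan <- function(d, seq) {
  el <- d$elements
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(chars)
  amb <- !(chars %in% c("A", "C", "G", "T"))
  if (L == 0L) return(data.frame(start = integer(), end = integer()))
  grid <- do.call(expand.grid,
                  lapply(seq_len(nrow(el)),
                         function(j) el$min_len[j]:el$max_len[j]))
  ok <- rep(TRUE, nrow(grid))
  for (j in which(el$kind == "helix_3p")) {
    pj <- match(el$partner[j], el$id)
    ok <- ok & grid[[j]] == grid[[pj]]
  }
  grid <- grid[ok, , drop = FALSE]
  pair_ok <- function(x, y, wob) {
    (x == "A" && y == "T") || (x == "T" && y == "A") ||
      (x == "C" && y == "G") || (x == "G" && y == "C") ||
      (wob && ((x == "G" && y == "T") || (x == "T" && y == "G")))
  }
  hits <- list()
  for (start in 0:(L - 1L)) {
    for (r in seq_len(nrow(grid))) {
      lens <- as.integer(grid[r, ])
      total <- sum(lens)
      if (total == 0L || start + total > L) next
      offs <- cumsum(c(0L, lens))[seq_len(length(lens))]
      good <- TRUE
      for (j in seq_len(nrow(el))) {
        l <- lens[j]
        if (l == 0L) next
        p0 <- start + offs[j]
        idx <- (p0 + 1L):(p0 + l)
        if (nzchar(el$constraint[j])) {
          cch <- strsplit(el$constraint[j], "", fixed = TRUE)[[1]]
          for (i in seq_len(l)) {
            if (amb[idx[i]]) next
            if (!(chars[idx[i]] %in% ORACLE_IUPAC[[cch[i]]])) {
              good <- FALSE; break
            }
          }
        }
        if (good && el$kind[j] == "helix_3p") {
          pj <- match(el$partner[j], el$id)
          p5 <- start + offs[pj]
          for (i in seq_len(l)) {
            i5 <- p5 + i
            i3 <- p0 + l - i + 1L
            if (amb[i5] || amb[i3]) next
            if (!pair_ok(chars[i5], chars[i3], el$wobble[j])) {
              good <- FALSE; break
            }
          }
        }
        if (!good) break
      }
      if (good &&
          sum(amb[(start + 1L):(start + total)]) <=
            d$max_ambiguous_fraction * total)
        hits[[length(hits) + 1L]] <- c(start, start + total)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  m <- unique(do.call(rbind, hits))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

# plain loop six-frame maximal-ORF scanner (start after stop/edge to next
# stop or edge), forward 0-based half-open coordinates
oracle_orfs <- function(seq, code, min_len = 90L) {
  stops <- list(`11` = c("TAA", "TAG", "TGA"), `15` = c("TAA", "TGA"),
                `4` = c("TAA", "TAG"))[[as.character(code)]]
  starts <- c("ATG", "GTG", "TTG")
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "",
                                       fixed = TRUE)[[1]]), collapse = "")
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- toupper(if (strand == "+") seq else rc(toupper(seq)))
    for (f in 0:2) {
      i <- f + 1L
      orf_start <- NA_integer_
      while (i + 2L <= L) {
        cod <- substr(s, i, i + 2L)
        if (is.na(orf_start) && cod %in% starts) orf_start <- i
        if (cod %in% stops) {
          if (!is.na(orf_start)) {
            a <- orf_start; b <- i + 2L
            if (b - a + 1L >= min_len)
              out[[length(out) + 1L]] <-
                if (strand == "+") c(a - 1L, b, f) else c(L - b, L - a + 1L, f)
          }
          orf_start <- NA_integer_
        }
        i <- i + 3L
      }
      if (!is.na(orf_start)) {        # edge ORF: runs to last full codon
        b <- i - 1L
        a <- orf_start
        if (b - a + 1L >= min_len)
          out[[length(out) + 1L]] <-
            if (strand == "+") c(a - 1L, b, f) else c(L - b, L - a + 1L, f)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}
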