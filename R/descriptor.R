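# Structural-motif descriptors.
#
# A descriptor is an ordered list of structural elements (single strands and
# the 5'/3' strands of helices) with length ranges and optional IUPAC
# identity constraints, plus the location of the catalytic cytosine and of
# the cleavage site (the first nucleotide, G1, of one element). Helix
# strands may interleave arbitrarily in element order, so pseudoknots are
# expressible.
#
# Descriptor file dialect (line based, "#" comments, UTF-8):
#
#   name: <text>                       (optional)
#   order: p1 j12 p2 p3 l3 p3' p1' ... (required, one line)
#   <id> <min>:<max> <IUPAC|-> [wobble=0|1]
#   catalytic: <id> <offset>           (0-based offset within the element)
#   cleavage: <id>
#   nratio: <float>                    (default 0.1)
#   variant: active|CdA|CdG|CdU        (optional, default active)
#
# An id ending in a prime/apostrophe (e.g. "p1'") is the 3' strand of the
# helix named by the unprimed id, which must also appear in the order line.
# Identity constraints are strings of length max_len; when an element
# matches at a length below max_len the constraint applies left-anchored.

#' Parse a structural-motif descriptor
#'
#' @param text Character: the descriptor file content (single string or a
#'   vector of lines).
#' @return An object of class `drz_descriptor`.
#' @seealso [read_descriptor()], [derive_fp_variants()], [scan_sequence()]
#' @export
parse_descriptor <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  name <- "descriptor"
  order <- NULL
  catalytic <- NULL
  cleavage <- NULL
  nratio <- 0.1
  variant <- "active"
  defs <- list()

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^name:", ln)) {
      name <- trimws(sub("^name:", "", ln))
    } else if (grepl("^order:", ln)) {
      order <- strsplit(trimws(sub("^order:", "", ln)), "[[:space:]]+")[[1]]
    } else if (grepl("^catalytic:", ln)) {
      f <- strsplit(trimws(sub("^catalytic:", "", ln)), "[[:space:]]+")[[1]]
      if (length(f) != 2L || is.na(suppressWarnings(as.integer(f[2]))))
        stop(sprintf("descriptor line %d: malformed catalytic directive", i),
             call. = FALSE)
      catalytic <- list(element = f[1], offset = as.integer(f[2]))
    } else if (grepl("^cleavage:", ln)) {
      cleavage <- trimws(sub("^cleavage:", "", ln))
    } else if (grepl("^nratio:", ln)) {
      nratio <- as.numeric(trimws(sub("^nratio:", "", ln)))
    } else if (grepl("^variant:", ln)) {
      variant <- trimws(sub("^variant:", "", ln))
    } else {
      f <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(f) < 2L || !grepl("^[0-9]+:[0-9]+$", f[2]))
        stop(sprintf("descriptor line %d ('%s'): expected '<id> <min>:<max> [constraint]'",
                     i, ln), call. = FALSE)
      rng <- as.integer(strsplit(f[2], ":", fixed = TRUE)[[1]])
      constraint <- if (length(f) >= 3L && f[3] != "-") toupper(f[3]) else ""
      wob <- TRUE
      wf <- grep("^wobble=", f, value = TRUE)
      if (length(wf)) wob <- sub("^wobble=", "", wf[1]) == "1"
      if (rng[1] > rng[2] || rng[1] < 0L)
        stop(sprintf("descriptor element '%s': invalid length range %d:%d",
                     f[1], rng[1], rng[2]), call. = FALSE)
      if (nzchar(constraint)) {
        if (nchar(constraint) != rng[2])
          stop(sprintf("descriptor element '%s': constraint length %d != max_len %d",
                       f[1], nchar(constraint), rng[2]), call. = FALSE)
        ch <- strsplit(constraint, "", fixed = TRUE)[[1]]
        bad <- setdiff(ch, names(.IUPAC_MASK))
        if (length(bad))
          stop(sprintf("descriptor element '%s': non-IUPAC character(s) %s",
                       f[1], paste(unique(bad), collapse = ", ")), call. = FALSE)
      }
      defs[[f[1]]] <- list(min_len = rng[1], max_len = rng[2],
                           constraint = constraint, wobble = wob)
    }
  }

  if (is.null(order)) stop("descriptor has no 'order:' line", call. = FALSE)
  if (anyDuplicated(order))
    stop("duplicate element id in order line", call. = FALSE)

  missing_def <- setdiff(order, names(defs))
  if (length(missing_def))
    stop(sprintf("element(s) in order line without definition: %s",
                 paste(missing_def, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(defs), order)
  if (length(unknown))
    stop(sprintf("unknown element id not in order line: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)

  # an id ending in "'" is a helix 3' strand; an unprimed id is a helix
  # 5' strand iff "<id>'" also occurs in the order line
  is_3p <- grepl("'$", order)
  base <- sub("'$", "", order)
  kind <- ifelse(is_3p, "helix_3p",
                 ifelse(paste0(order, "'") %in% order,
                        "helix_5p", "single_strand"))
  partner <- rep(NA_character_, length(order))
  partner[is_3p] <- base[is_3p]
  partner[kind == "helix_5p"] <- paste0(order[kind == "helix_5p"], "'")

  for (id in order[is_3p]) {
    b <- sub("'$", "", id)
    if (!(b %in% order))
      stop(sprintf("unpaired helix strand %s", id), call. = FALSE)
    if (match(b, order) > match(id, order))
      stop(sprintf("helix %s: 5' strand must precede its 3' strand", b),
           call. = FALSE)
  }

  el <- data.frame(
    id = order,
    kind = kind,
    min_len = vapply(order, function(id) defs[[id]]$min_len, integer(1)),
    max_len = vapply(order, function(id) defs[[id]]$max_len, integer(1)),
    constraint = vapply(order, function(id) defs[[id]]$constraint, character(1)),
    partner = partner,
    wobble = vapply(order, function(id) defs[[id]]$wobble, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  # helix invariants: both strands present, equal length ranges
  for (j in which(el$kind == "helix_5p")) {
    k <- match(el$partner[j], el$id)
    if (is.na(k)) stop(sprintf("unpaired helix strand %s", el$id[j]), call. = FALSE)
    if (el$min_len[j] != el$min_len[k] || el$max_len[j] != el$max_len[k])
      stop(sprintf("helix %s: strand length ranges differ", el$id[j]),
           call. = FALSE)
  }
  # wobble flag must agree between strands (3' strand value wins at scan time)
  if (!is.null(catalytic)) {
    j <- match(catalytic$element, el$id)
    if (is.na(j))
      stop(sprintf("catalytic element '%s' not in order", catalytic$element),
           call. = FALSE)
    if (catalytic$offset < 0L || catalytic$offset >= el$min_len[j])
      stop(sprintf("catalytic offset %d outside the fixed part of element '%s'",
                   catalytic$offset, catalytic$element), call. = FALSE)
    cc <- substr(el$constraint[j], catalytic$offset + 1L, catalytic$offset + 1L)
    expected <- switch(variant, active = "C", CdA = "A", CdG = "G", CdU = "T",
                       stop(sprintf("unknown variant '%s'", variant), call. = FALSE))
    if (!identical(cc, expected))
      stop(sprintf("catalytic position constraint is '%s' but variant '%s' requires '%s'",
                   cc, variant, expected), call. = FALSE)
  }
  if (!is.null(cleavage) && !(cleavage %in% el$id))
    stop(sprintf("cleavage element '%s' not in order", cleavage), call. = FALSE)
  if (!is.finite(nratio) || nratio < 0 || nratio > 1)
    stop("nratio must be in [0, 1]", call. = FALSE)

  structure(
    list(name = name, elements = el, catalytic = catalytic,
         cleavage = cleavage, max_ambiguous_fraction = nratio,
         variant = variant),
    class = "drz_descriptor"
  )
}

#' Read a descriptor file
#'
#' @param path Path to a descriptor file in the dialect described in
#'   [parse_descriptor()].
#' @return A `drz_descriptor`.
#' @export
read_descriptor <- function(path) {
  d <- parse_descriptor(readLines(path, warn = FALSE))
  if (identical(d$name, "descriptor"))
    d$name <- sub("\\.[^.]*$", "", basename(path))
  d
}

#' Path to a descriptor shipped with the package
#'
#' Two motifs are shipped: `"minimal_drz"`, a loose minimal HDV-like
#' ribozyme motif against which the reference sequence drz-Mtgn-1
#' validates, and `"theta"`, the refined high-specificity motif with
#' identity constraints and a degenerate last J4/2 position.
#'
#' @param which `"minimal_drz"` or `"theta"`.
#' @return File path.
#' @export
descriptor_file <- function(which = c("minimal_drz", "theta")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, ".desc"), package = "thetascan",
              mustWork = TRUE)
}

#' Derive the three catalytic-position false-positive motifs
#'
#' Given an active motif, produce the three descriptors identical to it
#' except that the catalytic-cytosine constraint is replaced by A, G or
#' T (denoted CdA, CdG, CdU). Hits to these inactive motifs estimate the
#' structural search's background rate.
#'
#' @param d A `drz_descriptor` with `variant == "active"`.
#' @return Named list of three descriptors (`CdA`, `CdG`, `CdU`).
#' @export
derive_fp_variants <- function(d) {
  stopifnot(inherits(d, "drz_descriptor"))
  if (!identical(d$variant, "active"))
    stop("derive_fp_variants: input descriptor is not the active variant",
         call. = FALSE)
  if (is.null(d$catalytic))
    stop("derive_fp_variants: descriptor has no catalytic position",
         call. = FALSE)
  j <- match(d$catalytic$element, d$elements$id)
  off <- d$catalytic$offset + 1L
  out <- list()
  for (v in c(CdA = "A", CdG = "G", CdU = "T")) {
    dv <- d
    substr(dv$elements$constraint[j], off, off) <- v
    dv$variant <- names(which(c(CdA = "A", CdG = "G", CdU = "T") == v))
    dv$name <- paste0(d$name, "_", dv$variant)
    out[[dv$variant]] <- dv
  }
  out
}

#' @export
print.drz_descriptor <- function(x, ...) {
  cat(sprintf("<drz_descriptor> %s (variant %s, nratio %.3g)\n",
              x$name, x$variant, x$max_ambiguous_fraction))
  cat(sprintf("  elements: %s\n", paste(x$elements$id, collapse = " ")))
  if (!is.null(x$catalytic))
    cat(sprintf("  catalytic: %s +%d\n", x$catalytic$element, x$catalytic$offset))
  if (!is.null(x$cleavage))
    cat(sprintf("  cleavage (G1): first nt of %s\n", x$cleavage))
  invisible(x)
}

# total length range of a descriptor
#' @keywords internal
.descriptor_span <- function(d) {
  c(sum(d$elements$min_len), sum(d$elements$max_len))
}
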