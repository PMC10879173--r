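---
title: "thetascan: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thetascan: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetascan)
```

# Scope

`thetascan` is a desk-scale re-implementation of the computational
workflow around tRNA-associated, HDV-like *theta* ribozymes: a
structural motif search with built-in false-positive controls, tRNA
association and genomic-context classification, genetic-code
(recoding) detection by coding-density comparison, and self-scission
kinetics fitting. The original study ran against hundreds of thousands
of phage contigs and metagenomic read sets; those databases are out of
scope here, so the package ships a synthetic-genome generator whose
manifest provides exact ground truth for every pipeline stage. This
vignette records the models, parameter choices and conventions, and —
importantly — what a passing test does and does not establish.

# The motif model

A descriptor is an ordered list of *elements*: single strands and the
5′/3′ strands of helices, each with a length range `min:max` and an
optional IUPAC identity constraint. Helix strands may interleave with
other helices in the element order, so the nested double pseudoknot of
HDV-like folds is expressible. A match assigns a length to every
element, laid out contiguously, such that constraints match, helix
strands are reverse-complementary position by position, and the
fraction of ambiguous subject nucleotides stays within `nratio`
(default 0.1, mirroring common practice for motif scanners on
assemblies with Ns).

Decisions where the problem statement left room:

* **Dialect.** The original descriptor grammar is not reproducible from
  the source, so the package defines a minimal line-based dialect
  (`order:` line, one definition line per element, `catalytic:` /
  `cleavage:` / `nratio:` directives). Figure-legend conventions for
  variable content — "any or no nucleotide", "between zero and X
  nucleotides" — map onto length ranges `0:1` and `0:X` with no
  constraint.
* **Pairing.** Watson–Crick plus G·U (G·T in DNA space) wobble, because
  HDV-like helices contain wobble pairs — including the conserved
  G1·U pair closing P1 at the cleavage site. Wobble acceptance is
  switchable per helix (`wobble=0`).
* **Ambiguity.** An ambiguous subject nucleotide (anything other than
  A/C/G/T) is compatible with any constraint and any pairing but counts
  toward the `nratio` budget of the whole match.
* **Constraints on variable-length elements** apply left-anchored: when
  an element matches below its maximum length, the first `len`
  constraint positions are enforced.
* **Overlap policy.** All satisfying placements are reported; length
  assignments producing the same `(start, end, strand)` collapse to one
  hit (the shortest-lengths assignment is kept for element spans). This
  completeness is what makes the matcher checkable against exhaustive
  enumeration.
* **Strands and coordinates.** Both strands are scanned by default;
  coordinates are 0-based half-open on the forward strand internally
  and 1-based inclusive in GFF3 output. The cleavage site is reported
  as the strand-aware coordinate of G1, the first nucleotide of the
  designated cleavage element.

The matcher itself is a depth-first backtracking search over element
lengths with early pruning (compiled code under `src/`); an independent
pure-R enumeration oracle in the test suite checks exact placement
equality on hundreds of randomized descriptor/sequence cases.

## The shipped motifs

Two descriptors are shipped as data, transcribed by the package authors
onto the reference sequence drz-Mtgn-1 (51 nt), whose published
secondary structure anchors the element layout: P1 (6 bp, with the
characteristic G·U wobble at the cleavage-site-proximal pair), J1/2,
the pseudoknotted P2 (5 bp, closed by the 3′-terminal strand), P3
(3 bp) with its loop, a short P4-like hairpin, and the J4/2 junction
whose first position is the catalytic cytosine.

* `minimal_drz.desc` — a loose starting motif: generous length ranges,
  no identity constraints beyond the catalytic C. drz-Mtgn-1 must (and
  does) validate against it as an active hit beginning at its 5′ G;
  its CΔU point mutant is matched only by the CΔU variant. This
  consistency check is part of the acceptance suite.
* `theta.desc` — the refined motif: tightened ranges, identity
  constraints at strongly conserved positions (the P3 stem, the loop
  CCC, the P1 3′ half), and one additional degree of freedom — a
  degenerate `R` — at the last J4/2 position. Because the exact
  constraint set of the original refined motif is not recoverable from
  the source text, the shipped transcription is calibrated to the same
  design goals: near-zero false-positive rate and high specificity on
  motif-bearing sequence.

False-positive motifs are derived, not hand-written:
`derive_fp_variants()` substitutes the catalytic-position constraint
with A/G/T and leaves everything else untouched, so active and control
motifs can never drift apart. The classification rule follows the
dual-fit convention: a locus matched by both an active and a
false-positive motif is a true positive. Uniqueness (for rates,
dereplication and ranks) is by the exact matched nucleotide string;
rank ties break lexicographically so names like `Θ0001` are
deterministic.

The consensus profile (`element_consensus()`) is an unweighted,
element-anchored alignment: variable-length elements are left-anchored
and gap-padded to their maximum length, and the modal-nucleotide
conservation tiers (0.97 / 0.90 / 0.75) follow the thresholds
conventionally used for consensus drawings. Tree-weighted (GSC)
consensus is intentionally not reproduced.

# tRNA association

A ribozyme is tRNA-associated when a tRNA 3′-end lies within ±5 nt of
its cleavage site. Conventions:

* **Distance sign.** Measured from the tRNA's last nucleotide to G1
  along the coding strand, positive when the ribozyme starts
  downstream; a cassette with no spacer has distance +1. Only |d| is
  biologically interpreted; the sign is kept for diagnostics.
* **Same strand required.** The biological model is processing of the
  tRNA 3′-trailer in *cis*, which requires co-orientation. An
  `allow_antisense` flag exists for sensitivity analysis and defaults
  off.
* **Tie-breaks.** Each hit pairs with the nearest tRNA by |d|; exact
  ties go to the upstream tRNA. For genomic context, distance ties
  between ORFs go to the downstream ORF. Both choices are arbitrary but
  deterministic and documented.
* **2–5 nt gaps** are attributed upstream to tRNA end-prediction
  inaccuracy; no correction is applied.

Adjacency is `direct` at |d| ≤ 1 and `near` at 2–5; suppressor
anticodons are exactly the reverse complements of the three stop
codons; CCA detection is a literal genomic suffix test. Pair names
combine the isotype and the occurrence ranks of both partners
(`tRNAVal0025_Θ0046`).

# Recoding detection

Genes of a phage genome that reassigns a stop codon fragment when
predicted under the standard code, so its coding density is markedly
higher under the true code. The detector compares densities under codes
11 (stops TAA/TAG/TGA), 15 (TAG reassigned; stops TAA/TGA) and 4 (TGA
reassigned; stops TAA/TAG).

* **ORF surrogate.** Prodigal's GC-frame and RBS scoring is not
  reproduced. Instead a deterministic maximal-ORF scanner is used: in
  each of the six frames, from the first start codon (ATG/GTG/TTG)
  after the previous in-frame stop (or the frame edge) to the next
  in-frame stop (included), or to the frame edge when none follows;
  minimum length 90 nt; codons containing ambiguity codes are neither
  starts nor stops. This is oracle-checkable and sufficient for the
  density-difference statistic on synthetic data, but it is *not* a
  gene finder; it deliberately overcounts ORFs relative to Prodigal.
* **Density** is the union coverage of ORF intervals from both strands
  projected to genome coordinates, divided by the genome length
  (union semantics; a nucleotide covered by several ORFs counts once).
* **Threshold.** The alternative code with the largest density excess
  over code 11 is assigned when the excess reaches 0.10 (contigs under
  100 kbp) or 0.05 (at or above; the boundary case uses the laxer
  value). The 5–10% rule is interpreted as an absolute difference of
  density fractions. An exact tie between codes 15 and 4 is
  unresolvable and falls back to 11.

Stop-set monotonicity — removing a stop codon can only lengthen or
preserve ORFs, hence density(15) ≥ density(11) and density(4) ≥
density(11) — holds structurally for this surrogate and is asserted on
a thousand random sequences.

# Kinetics

Band intensities of body-labeled RNA scale with cytosine content, so
cleaved fractions divide each band by its cytosine count before
normalizing. Time courses are fit to the inverted mono- or
biexponential decay; the printed monoexponential formula omits the time
variable in the exponent in the source and is read as `e^(−k₁·t)` by
analogy with the biexponential. The reported `k_obs` is `k₁` for mono
fits and the faster rate for bi fits.

Decisions where the source is silent:

* **Model selection** (`model = "auto"`): the biexponential is accepted
  only when an extra-sum-of-squares F-test at α = 0.01 favors it *and*
  the two rates differ at least 3-fold. This guards against overfitting
  triplicate gel data; on noiseless mono-generated data the bi fit
  cannot reduce the SSR beyond the threshold and mono is kept.
* **Weighting:** unweighted least squares over pooled replicates (all
  individual measurements enter the fit).
* **Numerics:** bounded least squares via PORT (`nlminb`), relative
  tolerance 1e-14, rate bounds (1e-6, 1e3) min⁻¹, a small deterministic
  multi-start (no RNG use inside fitting), standard errors from the
  numerical Hessian of the SSR surface. Exponential rates are
  initialized from a log-linear regression on the rising phase;
  noiseless synthetic data are recovered to ~1e-6.
* **Two-pKa constraint:** the profile is parametrized as
  (k_max, pKa2, ΔpKa ≥ 0) with pKa1 = pKa2 + ΔpKa, enforcing
  pKa1 > pKa2 (basic limb above acidic limb); the fitted bell then
  peaks at (pKa1+pKa2)/2, which the tests verify numerically. Monotone
  (one-limb) profiles trigger a warning since the constants are then
  poorly constrained.
* **Simulation windows** scale with 1/k (about five half-lives), so
  both the slow (~0.002 min⁻¹) and fast (>10 min⁻¹) regimes are
  identifiable; trace noise is additive and clipped to [0, 1], rate
  (k_obs) noise is relative, matching how rate errors scale.

# The synthetic world

The generator's defaults describe one fixed, realistic "stated world"
rather than tunable knobs:

* contig length 30 kb, coding-density target 0.72 (dense, phage-like,
  while leaving room for the non-coding features);
* cassette spacings drawn from {−1, 0, 0, 0, 1, 2, 4} nt — mostly
  directly adjacent, as observed for real tRNA/ribozyme pairs;
  *negative* spacing keeps the blocks physically adjacent but shifts
  the annotated tRNA 3′-end into the ribozyme, emulating tRNA
  end-prediction error (the stated explanation for non-direct pairs);
* suppressor fraction 0.2 among cassette tRNAs (every fifth associated
  tRNA a suppressor, anticodon CTA), genomically encoded CCA fraction
  0.045, and an in-frame TAG rate of 0.04 per codon for code-15 genes;
* features are placed on the minus strand with probability 0.3, and
  reads are 150 nt, the typical metagenomic raw-read length.

Two construction details matter for closure:

* **Stop-rich spacers.** Intergenic DNA is built from 10-nt units
  containing `TAATTA`, which guarantees a stop codon in every reading
  frame on both strands at least every 30 nt. Random DNA would contain
  abundant spurious ≥90-nt ORFs, destroying the designed coding
  density; stop-rich background keeps the measured density within
  ~0.02 of the target (ORF-end effects only).
* **Hidden-stop codon blocks.** Uniform-random sense codons leave long
  stop-free runs in the five non-coding frames of a gene, which the
  maximal-ORF surrogate would call as ORFs — in particular covering
  TAG-recoded genes under code 11 and erasing the designed density
  margin. Gene bodies therefore interleave the block
  `CTA ACT AAC TAC` (sense in frame under codes 11, 15 and 4, but
  containing stops in both shifted forward frames and all three reverse
  frames) every six codons. Real coding sequences are similarly
  enriched for off-frame "hidden" stops, so this is a realism fix, not
  a trick. With it, a designed code-15 density excess is reproduced to
  within ~0.02, and the thresholds separate cleanly (a designed excess
  of 0.07 on 50 kb is assigned code 11, 0.12 is assigned code 15).

What the generator does **not** emulate: placeholder tRNAs are
length-realistic annotated blocks with an embedded anticodon, not
foldable cloverleafs (tRNA detection is upstream of this package and
annotations are its input); gene content has no codon-usage or amino
acid realism; the background is i.i.d. uniform ACGT between features.
A green pipeline-closure test therefore establishes that the
*implemented* operations are mutually consistent and exact on their
stated contracts — not that the motif would achieve the published
sensitivity or specificity on real phage databases, which cannot be
assessed at desk scale.

# Known limitations

* The shipped motifs are transcriptions anchored on one published
  reference sequence and figure-level descriptions; they are data, and
  the engine is motif-agnostic.
* The ORF surrogate differs from Prodigal; absolute densities are not
  comparable with the published ones, only density *differences* are
  used, and the size-dependent threshold is applied to those.
* `fp_rate()` estimates the structural search background from the
  catalytic-position controls only, as in the original design; it says
  nothing about biological activity.
* Alternative parses of one locus (same placement window, slightly
  different element boundaries, possibly under a false-positive motif)
  are expected behavior of a complete matcher; locus-level
  classification with the dual-fit rule is the intended consumer.
* Standard errors from the SSR Hessian are asymptotic and unweighted;
  no bootstrap or Bayesian uncertainty is provided.
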