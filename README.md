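# thetascan

Discovery and validation toolkit for **tRNA-associated, HDV-like
"theta" ribozymes** in (gut) bacteriophage genomes.

Minimal HDV-like delta ribozymes (drzs) are small self-cleaving RNAs
with a nested double-pseudoknotted fold (helices P1, P1.1, P2, P3, and
for non-minimal variants P4) that cut the phosphodiester bond 5′ of
their first nucleotide, G1. A subgroup of them sits directly downstream
of phage tRNA genes, with the cleavage site at the tRNA 3′-end —
suggesting a role in viral tRNA 3′-trailer maturation — and is strongly
linked to *recoded* phages that reassign the amber stop codon (genetic
code 15, UAG→Gln) and carry suppressor tRNAs. `thetascan` implements the
complete desk-scale computational workflow around this biology:

1. **Motif engine** — parse secondary-structure descriptor files
   (ordered elements with length ranges, IUPAC identity constraints,
   pseudoknot-capable helix pairing with G·U wobble, an ambiguity budget
   `nratio`), scan both strands of DNA sequences for every satisfying
   placement, and control specificity with three *false-positive
   motifs*, identical to the active motif except that the catalytic
   cytosine (first position of the J4/2 junction) is replaced by A, G or
   U (CΔA/CΔG/CΔU). A locus matched by both an active and a
   false-positive motif counts as a true positive. Hits are
   dereplicated into unique ribozymes named by occurrence rank (Θ0001,
   Θ0002, …), and element-anchored consensus profiles report 0.97 /
   0.90 / 0.75 conservation tiers.
2. **tRNA association** — a ribozyme is tRNA-associated when a tRNA
   3′-end lies within ±5 nt of its cleavage site (co-oriented);
   direct (±1 nt) vs near adjacency, suppressor anticodons
   (CTA→UAG amber, TCA→UGA, TTA→UAA), genomically encoded CCA tails,
   genomic-context classes for isolated hits (intragenic /
   sense / antisense / >200 nt distal), pair names such as
   `tRNAVal0025_Θ0046`, and fold-enrichment arithmetic.
3. **Recoding detection** — maximal-ORF calling under genetic codes 11,
   15 and 4; coding density as the union coverage of ORFs; a contig is
   called recoded when the alternative-code density exceeds the code-11
   density by ≥10 percentage points (<100 kbp) or ≥5 points (≥100 kbp).
4. **Kinetics** — cytosine-corrected cleaved fractions
   `f = (I_t/nC_t)/(I_t/nC_t + I_s/nC_s)`, inverted mono/biexponential
   self-scission fits (`f(t) = 1 − (A·e^(−k₁t) [+ B·e^(−k₂t)] + C)`,
   k_obs = k₁ or the faster rate), Hill-type Mg²⁺ dependence
   `k_obs = k_max / (1 + (K_d/[Mg²⁺])^n)`, and the two-pKa pH-rate
   profile
   `k_obs = k_max / (1 + 10^(pH−pKa1) + 10^(pKa2−pH) + 10^(pKa2−pKa1))`.
5. **Synthetic data** — phage-like contigs with a ground-truth manifest:
   tRNA/ribozyme cassettes at controlled spacings, isolated
   active/false-positive motif instances, code-11/15 genes with a
   controlled in-frame TAG rate, stop-rich intergenic DNA, and
   short-read sampling. Every pipeline stage is testable without any
   external database.
6. **CLI** — `thetascan scan|associate|recode|fit|simulate` over plain
   key=value configs, reading/writing FASTA, GFF3, TSV and JSON.

## Worked example

```r
library(thetascan)

d  <- read_descriptor(descriptor_file("theta"))
sp <- genome_spec(length = 30000, n_trna_cassettes = 4, n_active = 2,
                  n_cdu = 1, genetic_code = 15, tag_rate = 0.04, seed = 101)
g  <- build_genome(sp, contig = "phage01")

hits <- scan_contigs(d, setNames(g$sequence, g$contig), variants = TRUE)
lab  <- classify_hits(hits)
nrow(lab); fp_rate(lab)
#> [1] 7
#> [1] 0.1428571
```

Seven motif placements are found: the six planted active ribozymes (4
in tRNA cassettes + 2 isolated) and the one planted CΔU control, giving
a false-positive rate of 1/7 over unique sequences.

```r
assoc <- associate_trnas(lab[lab$label == "true_positive" &
                             lab$variant == "active", ], manifest_trnas(g))
assoc[, c("distance", "adjacency")]
#>   distance adjacency
#> 1        1    direct
#> 2        0    direct
#> 3        5      near
#> 4        1    direct
```

The four cassette ribozymes associate with their tRNAs (three directly
adjacent, one within the ±5 nt window); the isolated ones do not.

```r
assign_code(g$sequence, contig = g$contig)
#>    contig length density11 density15  density4 assigned_code margin
#> 1 phage01  30000 0.4295667 0.7580667 0.4307333            15 0.3285
```

The TAG-recoded genome fragments under the standard code (coding
density 0.43 vs 0.76), so it is correctly assigned code 15.

```r
ph   <- seq(5, 9, length.out = 9)
prof <- simulate_trace("ph", list(k_max = 1, pKa1 = 9, pKa2 = 6), ph,
                       noise_sd = 0.05, seed = 1)
fit_ph(prof$ph, prof$k_obs)
#> <ph_fit> k_max 1.006 min^-1, pKa1 9.031, pKa2 5.989 (SSR 0.00608)
```

A noisy pH-rate profile generated with pKa values of 9.0 (hydrated
Mg²⁺ ion) and 6.0 (catalytic cytosine) is recovered within a few
hundredths of a pH unit.

The reference sequence drz-Mtgn-1
(`GGTAGCACACCTATGCGTTCCCGTCGCGCTACTGATTTAGACTAAATAGGT`) validates
against the shipped `minimal_drz` motif as an active hit starting at its
5′ G, is matched by no false-positive motif, and its CΔU point mutant is
matched only by the CΔU descriptor (see `tests/testthat/test-acceptance.R`).

## Layout

- `R/`, `src/` — implementation (descriptor parsing, compiled
  backtracking matcher, association, recoding, kinetics, generator, CLI)
- `inst/extdata/` — shipped descriptors (`minimal_drz.desc`, `theta.desc`)
- `inst/exec/thetascan` — command-line wrapper
- `vignettes/thetascan-methods.Rmd` — models, assumptions, numerical
  choices, and what the synthetic tests do and do not establish
- `tests/testthat/` — unit, property (including an independent pure-R
  enumeration oracle for the matcher) and acceptance tests
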