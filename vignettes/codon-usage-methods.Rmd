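---
title: "Methods: codon usage bias diagnostics for mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias diagnostics for mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocub)
```

## Scope and model

`mitocub` quantifies synonymous codon usage bias in mitochondrial
protein-coding genes and attributes it to mutation pressure versus natural
selection using four classical diagnostics: RSCU, the ENC plot, the
PR2-bias plot and the neutrality plot. The package assumes its input is a
set of correctly annotated, in-frame CDS; it does not assemble, annotate or
align anything.

The genetic code is a first-class parameter. Every statistic derives its
synonymous-family structure from the active NCBI translation table rather
than hard-coding the standard code's degeneracy. This matters for
mitochondria: under table 5 (invertebrate mitochondrial) AGA/AGG encode
Ser, ATA encodes Met and TGA encodes Trp, giving 62 sense codons organised
as twelve 2-fold, six 4-fold, one 6-fold (Leu) and one 8-fold (Ser) family
— no 1-fold families at all, unlike the standard code's Met and Trp.

## Sequence extraction

`read_genbank()` parses GenBank flat files directly (LOCUS, FEATURES with
`complement()`/`join()` locations, ORIGIN). Coordinates stay 1-based and
inclusive, the GenBank and IRanges convention; keeping a single convention
end to end avoids the off-by-one risk that motivates half-open systems in
0-based ecosystems.

`extract_cds()` reverse-complements light-strand features to sense
orientation and then applies a deliberately conservative incomplete-stop
rule: a frame remainder is padded with A only when the trailing fragment is
`T` or `TA` — a prefix of TAA, the stop completed in vivo by mRNA
polyadenylation. Any other remainder, and any internal stop after
extraction, is a hard error rather than a silent repair, because both
indicate a broken annotation whose downstream statistics would be
meaningless.

Counting conventions, each exposed as a flag with the stated default:

* the initiation codon is counted as the sense codon it encodes (TTG as
  Leu, ATT as Ile; `include_start = TRUE`), mirroring how codon-usage
  tools conventionally tabulate alternative starts;
* the terminal stop codon never enters counts, RSCU, ENC or
  third-position composition;
* codons containing ambiguous bases are dropped from counts and from all
  positional denominators (`exclude_ambiguous = TRUE`), so no fractional
  attribution is ever needed.

## Composition statistics

GC1/GC2/GC3 are computed over the respective positions of all counted
sense codons, GCall over all three positions, and GC12 = (GC1 + GC2)/2.
Because all statistics share one codon set, GCall ≡ mean(GC1, GC2, GC3)
holds as an exact identity and is asserted in the tests.

GC3s restricts the third-position denominator to codons whose amino acid
has at least two synonymous codons under the active code. Under table 5
this excludes nothing; under table 1 it drops Met and Trp. The
third-position proportions A3/T3/G3/C3 are computed over **all** sense
codons by default, following the plain reading of "nucleotide proportions
at the third codon position in each gene"; `synonymous_only = TRUE`
reproduces the alternative (CodonW's A3s/T3s/G3s/C3s) convention. Both are
available and neither is asserted to be what any particular published
table used.

AT skew is (A − T)/(A + T) and GC skew (G − C)/(G + C). Genome-level
composition is computed on the deposited (heavy-strand) sequence.
Proportions and skews are conventionally reported at 3 decimal places.

## ENC and its expected curve

Wright's estimator is generalised to the active code. For each family with
total count n ≥ 2, the codon homozygosity is F = (n Σp²ᵢ − 1)/(n − 1);
families in a degeneracy class are averaged arithmetically and
ENC = Σₖ Nₖ/F̄ₖ, with 1-fold classes contributing their family count
directly. Numerical edge cases, in order of application:

* families with n < 2 are skipped (F is undefined at n = 1);
* a class left without a usable family, or with a non-positive mean, has
  its F̄ imputed as the mean of the nearest available classes — the
  generalisation of Wright's F̄₃ ≈ (F̄₂ + F̄₄)/2 fallback — and the class is
  recorded in `imputed_classes`;
* the estimate is reported unclamped; short genes can legitimately exceed
  the code's sense-codon count through sampling noise, and such values are
  flagged (`exceeds_maximum`) rather than truncated, so means over genes
  are not biased downward.

`codonw_compat = TRUE` forces table-1 classes regardless of the supplied
code, for comparison against CodonW output whose code setting is unknown.

The expected curve ENC = 2 + GC3s + 29/[GC3s² + (1 − GC3s)²] is the
no-selection null: a gene whose usage is driven purely by third-position
composition falls on it (60.5 at GC3s = 0.5; 31 and 32 at the endpoints).
`enc_deviation` = ENC − expected(GC3s) is attached to every gene profile;
systematically negative values indicate selection.

## Neutrality regression and correlations

The regression is fixed as GC12 ~ GC3 (GC3 on the x axis), the universal
neutrality-plot orientation. Slope and intercept come from ordinary least
squares, the slope p-value from the t distribution with n − 2 df, and the
adjusted R² from the Wherry formula with one predictor,
1 − (1 − R²)(n − 1)/(n − 2); negative adjusted values are reported as-is.
Zero variance in GC3 is an error (the plot is undefined), and fewer than 3
genes is an error.

Pearson correlations among GC1, GC2, GC3, GCall and ENC use two-sided
t-tests with n − 2 df and per-test significance stars (* p < 0.05,
** p < 0.01, *** p < 0.001) with **no** multiple-testing correction —
matching how such matrices are conventionally starred. A zero-variance
variable yields NA for its pairs rather than a spurious r. High-frequency
codons use the strict rule RSCU > 1; unobserved families get NA, never 0.

Genes with an undefined PR2 denominator (no G+C or no A+T at third
positions) are dropped from that plot with a warning, never imputed.

## The synthetic-data generator

The generator exists so that the mutation-versus-selection logic of the
diagnostics can be tested against known truth. Codons are drawn i.i.d.
with mutational weight g^nGC · (1 − g)^nAT over sense codons, where g is
the probability that a mutationally free base is G or C; selection
multiplies the weight of one preferred codon per family by (1 + s). A
start codon from the code's initiation set is placed first and a TAA stop
appended, truncated to `TA`/`T` for designated genes.

Defaults are sized to the real system the package targets: 13 genes named
cox1…atp8, 50–600 codons per gene (the atp8-to-nad5 length spread), table
5, four light-strand genes, three truncated-stop genes, g = 0.35 (the
AT-rich composition typical of these mitogenomes, ~65% A+T) and s = 0. The
preferred-codon set defaults to the T-ending (else A-ending) codon of each
family, mirroring the U/A-ending high-frequency codons these genomes
show. All randomness flows from a single seed through a per-gene counter,
so individual genes are reproducible in isolation and draw order is
irrelevant; `emit_fixture_genome()` output is byte-stable for a fixed
seed.

Because sampling is i.i.d., closed-form expectations exist by enumerating
the 62 sense codons (`expected_positional_gc()`), and these serve as
independent oracles in the parameter-recovery tests: with s = 0 and g
spread 0.2–0.8 across genes the fitted neutrality slope matches the
oracle-predicted slope (≈ 0.97) within a bootstrap 95% interval; with
fixed g and s = 10 the slope collapses toward 0 and mean ENC drops from
≈ 55 to ≈ 26, well below the expected curve — the textbook signatures of
mutation- and selection-dominated regimes respectively.

What the generator deliberately does **not** emulate: site dependence,
realistic amino-acid profiles, strand-asymmetric mutational spectra, and
phylogenetic correlation between genomes. Passing the recovery tests
therefore shows the diagnostics respond correctly to marginal codon
frequencies, not that they are robust to those real-data complications.

## Problem sizes and runtime choices

Test and acceptance runs use 13 genes of 300–400 codons and 20 replicate
genomes per regime, with 1000 bootstrap resamples for the slope interval —
sizes chosen to keep Monte-Carlo error well inside the asserted margins
(slope SD across replicate genomes ≈ 0.03) while the whole suite runs in
seconds. Large-sample checks (uniform-usage ENC → 62/61, strong-selection
RSCU → family size) use 10⁴–2×10⁵ codons, where the finite-n correction is
negligible at the asserted tolerances.

## Known limitations

* The GenBank parser covers the feature types and location forms found in
  mitogenome records (`complement`, `join`, origin-spanning joins,
  partial markers); it is not a general GenBank implementation.
* ENC requires at least one family with n ≥ 2 in some class; very short
  or degenerate inputs error rather than guess.
* Accession-backed replication of published per-species values depends on
  the (unstated) counting conventions of the original tools; the flags
  above expose the candidate conventions but the package does not assert
  which one any publication used.
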