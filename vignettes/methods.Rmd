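---
title: "Methods: differential small-RNA, methylation and expression analysis in smrnapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential small-RNA, methylation and expression analysis in smrnapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`smrnapipe` compares a mutant and its sibling wild type across three
regulatory layers in a plant genome: small-RNA (smRNA) abundance in
genomic windows, mature miRNA expression (known catalogue entries and
novel stem-loop candidates), and cytosine methylation at selected loci
assayed by clone-based bisulfite sequencing, with a microarray-style
expression comparison alongside.  The biological setting is the
RNA-directed DNA methylation (RdDM) pathway: RNA-dependent RNA
polymerases convert single-stranded transcripts into double-stranded
precursors of siRNAs, and siRNA abundance changes at a locus are expected
to co-occur with CHH-context methylation changes there.  The pipeline
therefore ends with a cross-layer association step that flags
sign-concordant smRNA and CHH methylation differences.

# smRNA cluster analysis

Clean (adapter-trimmed) reads are collapsed to unique sequences with
counts, exact-matched to the genome on both strands, and counted in
100 bp windows: a hit is assigned to the single window containing its
5'-most genomic base, both strands pooled.  Window counts are normalized
to RPM (reads per million) on each library's **total clean reads**, not
the mapped subtotal, so libraries of different depth are comparable.
Per window, `X` and `Y` are the medians of RPM across the mutant and
wild-type libraries (the median of one library is itself), and the fold
value is

$$\log_2\frac{X + c}{Y + c}$$

with pseudocount $c = 0.5$ RPM.  A window is a differential cluster iff
$|\log_2((X+c)/(Y+c))| \ge \log_2 4$ — the 4-fold cut-off, inclusive.
A parallel analysis restricted to 20–24 nt reads (the size range that
parsimoniously contains the siRNAs) uses the same machinery.

Decisions worth stating explicitly:

* **Windows tile; they do not slide by 1 bp.**  The window unit is a
  disjoint 100 bp cluster; a 1 bp slide would count every read about 100
  times and make per-window fold values meaningless.  The step is an
  argument (`count_windows(step = )`) for sensitivity analysis.
* **Pseudocount.**  Zero-count windows are common at desk-scale depth;
  $c = 0.5$ RPM keeps the log ratio defined while leaving genuinely
  4-fold windows essentially untouched.  All-zero windows ($X = Y = 0$)
  are never called.  With $c = 0$ on nonzero windows the formula reduces
  exactly to $\log_2 X - \log_2 Y$, and fold values are invariant under
  common rescaling of both libraries.
* **Multi-mapping.**  A read contributes its full collapsed count at
  every exact hit; no fractional splitting.  This is the simplest
  auditable rule and is recorded in output metadata.  Palindromic reads
  (equal to their reverse complement) are canonicalized to the + strand
  so a site is counted once.
* **Exact matching only.**  Zero-mismatch placement keeps the
  brute-force string-scan oracle exact, which is how the mapper is
  tested.

# miRNA analysis

**Known catalogue quantification.**  A read counts toward a mature
sequence iff it matches exactly at the 5' end and differs only by a 3'
trim or extension of at most 2 nt — the dominant isomiR mode; 5'
variation changes the seed and is deliberately not tolerated.  Counts
are RPM-normalized on clean totals.  Entries are classified `up` (ratio
$\ge 2$ and significant), `down` (ratio $\le 0.5$ and significant), else
`unchanged`.  With a single library per genotype a t-test is not
estimable, so significance comes from a two-sided binomial "count test"
of the mutant count against its expectation under equal abundance given
the two library totals; when two or more libraries per genotype are
supplied, a Welch t-test on per-library RPM activates automatically.
Families are parsed from the `miR<number>` stem of catalogue names, and
families with at least one `up` and one `down` member are reported as
divergent.

**Novel miRNA discovery.**  Seeds are read stacks — reads sharing a 5'
genomic position and strand with summed count ≥ 5 and length 20–24 nt —
that overlap nothing annotated except genes or unannotated sequence.
Around each stack, nine 160 nt windows at staggered offsets are folded on
the stack's strand with a weighted base-pair–maximization dynamic program
(GC 3, AU 2, GU 1 model units, maximized; minimum hairpin loop 3; the
reported `fold_score` is the negated optimum, so lower is more stable —
it is a model-unit score labelled "mfe" in reports, not a thermodynamic
free energy).  A candidate is accepted iff the fold score is at most −15
model units, at most 4 mature bases are unpaired, and every paired
mature base pairs to the opposite arm (this simultaneously places the
mature on one arm and outside the loop).  The star is the arm segment
pairing the mature, with the canonical 2 nt 3' offset; the guide arm is
the arm with the larger 20–24 nt read support.  Candidates with an
identical mature sequence at different loci are grouped into one family.
Stacks within 200 bp of a stronger stack are suppressed before folding so
one hairpin yields one candidate.

The folding engine is intentionally a pair-counting model rather than a
nearest-neighbour thermodynamic one: it is self-contained, deterministic
(traceback prefers a pairing decomposition over leaving the terminal base
unpaired, smallest partner index on ties), and exactly testable against
exhaustive enumeration of all legal structures for short sequences.
Candidate ranking, not absolute stability, is what the pipeline needs.

# Bisulfite methylation calling

Only the top (converted) strand of each amplicon is analyzed; clones are
globally aligned to their locus reference under a bisulfite-aware cost
(reference C : clone T is free — a conversion; other matches free;
substitutions 1; gap bases 2), trying both orientations and keeping the
better identity.  Alignment identity, computed excluding C→T positions,
must reach 0.9 or the clone is rejected.  At each reference cytosine,
clone C calls methylated, clone T unmethylated, anything else uncovered.
Context comes from the reference trinucleotide: CG if the next base is G,
else CHG if the base after that is G, else CHH; cytosines whose context
would run off the locus end are excluded.  Per locus and genotype the
package reports per-context percent methylation with Wilson 95%
intervals, and genotype differences as absolute percentage-point deltas
(mutant − wild type) with a two-proportion z-test on the pooled site
calls.  The delta is deliberately absolute: statements like "a 30%
decrease" are ambiguous between absolute and relative readings, and
percentage points are the unambiguous choice.  Incomplete conversion is
not corrected for — the conversion rate can be estimated from designated
control positions for QC, but reported percentages are raw.

# Expression analysis

The expression layer starts from a genes × samples log2 intensity matrix
with at least two replicates per genotype ("expressed" means present in
the matrix after whatever detection filter produced it).  The default
per-gene test is the moderated t (limma `lmFit`/`eBayes`): with three
replicates, per-gene variance estimates are so noisy that an unmoderated
t-test loses most of its power after multiple-testing adjustment, and
empirical-Bayes variance shrinkage across genes is the field-standard
remedy; `method = "welch"` selects a plain Welch t-test for comparison.
Benjamini–Hochberg adjustment is applied over all tested genes, and a
gene is called `up`/`down` iff its q-value is at most α = 0.05 **and**
its observed $|\log_2$ fold change$|$ reaches `min_lfc` = 1.  Note the
consequence of the hard fold filter: a gene whose true effect is exactly
2-fold has an observed fold change below the filter about half the time
(the SD of the fold-change estimate at σ = 0.25, n = 3 is ≈ 0.20), so
classification power at exactly 2-fold is capped near 0.5 for any test,
while rejection-based detection power (q ≤ α with the correct sign)
exceeds 0.95.  Both α, `min_lfc` and the test are arguments.

Chromosomal non-randomness of the called DEGs is tested with a
goodness-of-fit chi-square whose expected counts are weighted by the
per-chromosome density of tested genes (a length-weighted mode is
available); the p-value comes from the chi-square survival function with
df = chromosomes − 1.  GO-category proportions are descriptive — DE genes
in a category divided by expressed genes mapped to it, categories ordered
by abundance; no enrichment p-values are computed, because inventing an
enrichment test the study design never specified would suggest precision
that is not there.

# Cross-layer association

A passing differential cluster associates with a bisulfite locus or DEG
iff their intervals overlap or lie within 1000 bp (`max_gap`); the
distance rule is a package decision — the association is inherently
regional and qualitative.  For loci with both layers present, the
concordance flag records whether the smRNA fold value and the CHH delta
share a sign, the RdDM-style positive correlation.  miRNA–target pairs
are classified into four relationship types by the two direction calls
(I: miRNA down & target up; II: up & down; III: both up; IV: both down;
`none` when either side is unchanged).

# The synthetic study

The generator produces the full study at desk scale, with every planted
quantity recorded as ground truth:

* **Genome**: 4 chromosomes × 200 kb of i.i.d. uniform ACGT (standing in
  for 12 rice chromosomes).  Annotated genes (55 per chromosome, with GO
  labels from a 12-term pool), one LTR-retrotransposon-like and one DNA
  transposon-like TE copy family, structural RNA loci, and 40 known
  miRNA hairpins embedded in the sequence (mature + 8–15 nt loop + star
  = reverse complement with 1–2 mismatches — at least one, so a mature
  read never exact-maps onto its own star arm).  Five novel hairpins are
  embedded but deliberately left unannotated: a three-locus family
  sharing one mature sequence, a two-arm case with 5p-dominant reads,
  and a singleton.
* **Libraries**: exactly 200,000 reads per genotype (scaled down from
  the ~10^7 clean reads of a real sequencing run; every detection rule
  is ratio/RPM-based, hence scale-invariant), drawn as exact genomic
  substrings with a length distribution bimodal at 21 and 24 nt — the
  canonical plant miRNA/siRNA size classes.  Twenty planted clusters
  receive Poisson(480) reads in the biased genotype and Poisson(60) in
  the other (8-fold), window-aligned; three of them are co-located with
  the CHH-changing bisulfite loci with matching sign.  Planted miRNA
  ratios echo the magnitudes such studies report: a 9.0:1 top up-ratio,
  a 1:6.1 lowest ratio, and an opposite-direction family pair at 4.2:1
  and 1:5.6.  Planted reads are drawn from, not added to, the library
  total.  Ratios within a factor ~1.5 of the 4-fold cut-off (4.2:1,
  1:5.6) are flagged `clear = FALSE` in the truth table: Poisson noise
  legitimately leaves them on either side of the threshold, so recovery
  statistics score sensitivity on clear plantings only while precision
  accepts borderline ones.
* **Expression**: per-gene baselines ~ Normal(8, 1.5), replicate noise
  σ = 0.25 (a configurable stand-in — the generator does not model
  probe-level microarray noise), 36 up / 12 down planted effects of
  |log2| 1.2–2.5 (the 3:1 asymmetry of the motivating design), biased
  toward the first two chromosomes so the chromosomal chi-square has
  signal, with the miRNA-target relationship genes forced to their
  relationship directions.
* **Bisulfite**: 10 loci of 300 bp (four retrotransposon regions, three
  DNA-transposon regions, three gene 5' regions), 30 clones per locus
  per genotype, conversion rate 0.995.  Planted per-context levels give
  one locus a −30-point CG/CHG drop, one a −20 CG / +30 CHG / +50 CHH
  pattern, one a +30 CHH body change, one gene a +50 CG gain, the rest
  unchanged — the canonical locus-specific RdDM signatures.

What the generator does **not** emulate: sequencing error, adapter
artefacts, non-uniform genomic composition (repeats, GC structure),
probe-level array effects, PCR duplicates in clone sequencing.  Passing
tests therefore demonstrate correctness of the computations and
calibration under the stated noise models, not robustness to real-data
artefacts.

# Numerical choices and degenerate inputs

* Window grids always tile to the chromosome end; the final short window
  is kept.
* `call_differential` refuses mismatched window grids; all-zero windows
  are emitted with `passes = FALSE`.
* The folding DP accepts sequences up to 400 nt and is exact; traceback
  tie-breaks are fixed (pairing preferred, smallest partner index).
* Chi-square expectations of zero drop that chromosome and reduce df,
  with the exclusion recorded.
* Methylation contexts undefined at locus ends are excluded rather than
  guessed; contexts with no covered sites yield missing percents and
  missing deltas.
* All generators derive their RNG streams from the config seed with
  fixed offsets, so every output (including written tables) is
  byte-reproducible for a given config.

# Problem sizes used in the shipped checks

The reference simulation used by the test-suite and the acceptance
script runs 2 × 200,000 reads on an 800 kb genome, 40 known + 5 novel
hairpins, 220 genes × 6 arrays, and 10 × 2 × 30 bisulfite clones; oracle
comparisons use 20 random 10–50 kb genomes (mapping/windowing), 200
random sequences ≤ 14 nt (folding), 1000 random references (context
calling), and 100-seed calibrations for methylation and DEG error rates.
These sizes were chosen so the whole suite exercises every claim at
desk scale.

# Known limitations

* One smRNA library per genotype (as in the motivating design) means the
  per-window medians degenerate to single values and no within-genotype
  variance is available; the miRNA count-test is the principled fallback
  and is labelled as such in outputs.
* The fold-score model ranks hairpins; it does not estimate free
  energies.
* Cluster calling has no count-model p-values by design — the 4-fold
  rule is the published decision rule being reproduced; adjacent-window
  merging is likewise out of scope.
* Bisulfite deltas are descriptive; the attached two-proportion test
  treats pooled site-calls as independent, which understates variance if
  clones are clonal duplicates.
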