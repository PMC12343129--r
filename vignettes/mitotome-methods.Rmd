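---
title: "mitotome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitotome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotome)
```

## The problem

Standard RNA-seq references for non-model species omit most
mitochondrially encoded transcripts beyond the 13 oxidative-phosphorylation
mRNAs: the mitochondrial-derived peptides (MDPs, microproteins encoded by
small ORFs on either strand of mtDNA) and the mitochondrial lncRNAs are
simply not in the annotation, so their reads are discarded. mitotome
builds an *extended* mitochondrial transcriptome for a circular
mitochondrial genome — classical mRNAs and rRNAs, homology-predicted MDP
ORFs, a positionally defined nested antisense ORF (Rudel), and
template-placed lncRNAs — and then profiles expression across hibernation
states from transcript-quantification output.

## Reference construction

### Coordinates and circularity

All internal coordinates are 0-based half-open and interpreted modulo the
genome length; GFF3 output is 1-based inclusive. Features whose interval
crosses the replication origin (typically the control region) are
represented by a `wraps_origin` flag with `end < start` rather than by
splitting, because arithmetic on a single modular interval is less
error-prone than segment bookkeeping; only the serializers split at the
junction. Every sequence operation satisfies two invariants that the test
suite checks by property: minus-strand extraction is the reverse
complement of plus-strand extraction for every interval, and rotating the
genome while shifting all features leaves every extracted transcript
byte-identical.

### GenBank parsing

No installed R package parses GenBank feature tables, so a minimal
single-record flat-file parser is included. Gene names key on the `/gene`
qualifier with `/product` as fallback (the qualifier actually populated
varies across RefSeq records); unknown feature keys are kept as
`kind = "other"` with a warning rather than dropped, and origin-spanning
`join(a..L,1..b)` locations map onto the `wraps_origin` representation.

### ORF scanning under translation table 2

`scan_orfs()` enumerates, per strand, every maximal ORF from an allowed
start codon to the first in-frame stop, reading across the origin (an ORF
whose footprint would exceed one full turn is discarded). The vertebrate
mitochondrial code is hard-wired: `TGA` = Trp, `ATA` = Met, and
`AGA`/`AGG` act as stops alongside `TAA`/`TAG`. Choices the literature
leaves open, exposed as parameters:

* **Start codons** default to `ATG, ATA, ATT, ATC, GTG` — the initiation
  codons observed in vertebrate mitochondrial genes. Tightening to `ATG`
  only is a one-argument change.
* **Minimum ORF length** defaults to 24 nt so that the shortest panel
  member's ORF (MOTS-c, nominally 36 nt) is detectable with margin.
* **Nested starts**: only the longest ORF per (strand, stop) is reported
  by default (`all_starts = TRUE` reports every start), matching
  conventional ORF-caller behaviour. On a circle the longest ORF for a
  stop near the origin can be the *wrapping* candidate; the scanner
  selects by coding length, not by linearized position, and is tested for
  exact equality against a brute-force six-frame oracle on random
  genomes.
* **Incomplete stops** (a trailing `T`/`TA` completed by
  polyadenylation) are only honoured where the ORF 3' end coincides
  exactly with an annotated transcript boundary, because poly(A)
  completion happens at processing sites; accepting them anywhere floods
  the caller with pseudo-ORFs.

### MDP homology calls

Candidate ORF peptides are aligned to a bundled peptide panel by
Smith–Waterman local alignment (affine gaps, BLOSUM62, gap open 11,
extend 1 — a gap of length $k$ costs $11 + k$). Defaults of 50% identity
over aligned columns and 70% coverage of the reference peptide were
chosen to accept diverged rodent homologs while rejecting random ORFs
(random-peptide alignments at these lengths score far below both bars;
the synthetic-null behaviour is exercised in the tests). Matching is
restricted to each panel entry's anchor locus (±100 nt) and strand,
because MDP ORFs are positionally conserved within their host genes; at
most one hit — the best-scoring — is reported per entry, and absence is a
recorded result, not an error.

Two panel design points deserve emphasis. First, **Rudel is positional,
not homological**: it is defined as the longest antisense ORF across the
adjacent mt-Atp8/mt-Atp6 genes ("Russian doll" nesting), since no
reference peptide exists for it. Second, the bundled panel file is
honest about provenance: MOTS-c and Humanin carry the canonical human
peptides, while the other ten homology entries are *seeded synthetic
surrogate sequences* (the filename and metadata say so). The surrogates
make the bundled panel exactly right for the bundled synthetic reference
and for pipeline testing; analyses of real genomes should supply a real
panel FASTA/TSV via the `mdp_panel()` arguments or the command-line
flags.

### lncRNA template

No printed coordinates exist for the ten catalogued mitochondrial
lncRNAs in this species, so `default_lncrna_template()` is a documented
reconstruction expressed relative to anchor genes: full antisense spans
of the name gene for lncND5/lncND6/lncCYB; the control-region span for
MDL1/MDL1AS (sense/antisense); the 16S span for SncmtRNA/ASncmtRNA1 with
a 3'-anchored 800-nt segment for ASncmtRNA2 (rodent-reported lengths run
shorter than human); a 215-nt light-strand control-region segment for
7SRNA; and a two-segment chimera of the mt-Co2 and mt-Cyb 3' ends for
LIPCAR. Every rule is a row in a plain-text table and user-overridable.
Species differences in these lengths are a known limitation — it is
expected that some template transcripts fail detection in real data.

### Manifest arithmetic

tRNAs lack poly(A) tails and are excluded from a poly-A-selected
transcriptome up front, with the reason recorded. The default build on
the bundled reference therefore yields

```{r manifest, eval = FALSE}
ref <- synthetic_reference(seed = 1)
man <- build_transcriptome(ref$genome, ref$features)
manifest_counts(man)
#>     mRNA     rRNA      MDP   lncRNA    total excluded
#>       13        2       13       10       38       22
```

## Expression profiling

### Detection

The detection filter keeps a transcript in a tissue only when
`log2(count / size factor + 1) >= 7` in **all** samples of that tissue
(boundary inclusive; a normalized count of 127 sits exactly at 7). The
transform is a deliberate surrogate for shrinkage-based regularized-log
transforms: it preserves the threshold semantics while remaining a
closed-form monotone function, so pass/fail sets near the boundary may
differ slightly from a shrinkage implementation's. Size factors are
median-of-ratios with an optional positive-count pseudo-reference
fallback for sparse matrices, normalized to geometric mean one.

### The NB likelihood-ratio test

Per gene, nested negative-binomial GLMs with log link and
`log(size factor)` offset are compared: `~ state + sex` against `~ sex`,
so the test asks whether *any* hibernation state shifts expression once
sex is accounted for. The reference state is the summer-active animal.
Two numerical choices matter:

* **Dispersion** is a gene-wise Pearson-moment estimate at residual
  degrees of freedom (`MASS::theta.md` on Poisson full-model fits, so
  design effects never inflate it), shrunk toward the across-gene
  *mean* with prior weight $2n$ ($n$ = samples). Gene-wise estimates at
  a dozen samples are noisy and right-skewed; their mean is the natural
  pooling target for a homogeneous panel of a few dozen mitochondrial
  transcripts, and the heavy shrink keeps single-gene noise out of the
  test statistic. A raw cross-sample moment estimator (ignoring the
  design) is badly anti-conservative here and was rejected.
* **Reference distribution**: because the dispersion is estimated, not
  known, the LRT statistic divided by its numerator df (#states − 1) is
  referred to $F(\mathrm{df}, (n-p) + 5n)$ rather than the chi-square
  limit, and per-state Wald statistics to the matching $t$. This is the
  same reasoning as quasi-likelihood F-tests; the denominator-df
  constant was fixed once by null-simulation calibration of this design
  (2000 genes, 4–6 states, 3 replicates) so that the nominal 5% level
  is held (observed type-I 0.036–0.057 across seeds) and a global null
  yields no Benjamini–Hochberg discoveries in ≥95% of runs. Both
  properties are asserted by the test suite, which is the package's
  standing evidence that the calibration is not stale.

Multiplicity is handled by Benjamini–Hochberg over the converged genes;
non-converging fits are flagged, get `NA`, and are excluded from
adjustment. A per-state cell in the direction report is coloured
up/down only when the gene's global LRT `padj <= 0.05` **and** its
per-state coefficient is itself significant — a single global p-value
says nothing about which state moved, so both gates are required; this
composite rule is a package choice where the upstream convention is
unstated. DE is computed per tissue independently, and an optional
grouping map can aggregate loci (e.g. mt-Atp8 + mt-Atp6 → "mt-Atp6/8")
before testing.

### Mitochondrial read fraction

Per sample: summed estimated counts over manifest transcripts divided by
the run summary's total processed reads, in percent. Published analyses
disagree on the denominator (total vs aligned reads) — one reported
adrenal-gland discrepancy plausibly reduces to exactly this choice — so
both are supported via `denominator = "total"|"aligned"`.

## The synthetic-data generator

The generator exists so every claim above is testable offline, with
truth known by construction.

**Genomes.** `make_genome()` plants ORFs through a nucleotide-level
constraint solver: each planted element (CDS with a random peptide,
free-peptide nested ORF, identity-mutated homolog) contributes codon
constraints — synonymous-codon sets, "any non-stop codon", start-codon
and stop-codon sets — on genome positions; overlapping constraint sets
(a host reading frame and an antisense ORF inside it) are merged and
solved jointly by seeded depth-first search, so nested planting never
corrupts the host frame. Every planted ORF gets an adjacent upstream
in-frame stop so the scanner must recover its exact coordinates.
Homolog identity is realized by substituting the target fraction of
residues and verified post hoc; `clean_background` iteratively knocks
out incidental start codons (directly in background, via added
anti-start constraints inside planted regions) until scanning returns
exactly the planted truth — used for oracle fixtures, not for the
realistic reference. Generation is byte-identical per seed.

`synthetic_reference()` assembles a complete ~16.6 kb squirrel-like
molecule: 13 CDS, 2 rRNA and 22 tRNA features in standard mammalian
gene order, a 1 kb control region spanning the origin, a planted free
663-nt antisense ORF across the adjacent mt-Atp8/mt-Atp6 genes (matching
the documented Rudel structure), and one planted homolog of every
homology-mode panel entry at its anchor locus at 85% identity. It is a
clearly labelled synthetic stand-in: the *structure* follows the real
annotation, the *sequence* is generated. What passing tests on it show
is that the pipeline recovers planted structure exactly; they cannot
show anything about the real NC_027278.1 sequence, real homology
divergence, or real read data.

**Counts.** `simulate_counts()` draws
$K_{gj} \sim \mathrm{NB}(s_j\,\mu_g\,2^{\text{state}+\text{sex}},\,\alpha_g)$
with sex alternating within state (never confounded). Defaults emulate
the hibernation design: six states × 3 replicates, log-normal baselines
around 200 counts, dispersion 0.05, log-normal size factors (sd 0.15).
It does not emulate library-size heterogeneity beyond size factors,
transcript-length bias, or multimapping — so detection and DE results on
real quantifier output can differ in ways these simulations cannot
reveal. Simulation sizes used by the tests (2000-gene null and recovery
runs, 20 seeded null repetitions, 50 oracle genomes up to 5 kb, 200
alignment pairs) were chosen to give stable Monte-Carlo estimates on a
single CPU in a few minutes.

## Known limitations

* The bundled panel's ten surrogate peptides and the lncRNA template are
  reconstructions; real-data work should replace the panel and may need
  template coordinates adjusted per species.
* The moderated-log detection filter is not a shrinkage rlog; borderline
  transcripts (normalized counts near 127) can flip relative to a
  shrinkage implementation.
* The F-referenced LRT's denominator df is a calibrated constant, not a
  per-gene estimate; designs far from the calibrated regime (very many
  replicates, extreme dispersions) deserve a fresh null check.
* Quantification itself (pseudoalignment) is out of scope: the package
  consumes abundance tables and trusts their estimated counts.
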