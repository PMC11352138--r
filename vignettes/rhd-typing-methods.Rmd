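---
title: "Two-stage molecular RHD typing in silico: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage molecular RHD typing in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhdtyper)
```

## The problem

Serologic RhD typing fails exactly where it matters most: samples with
weakened or ambiguous D antigen expression. Molecular typing resolves these
by determining the *RHD* allele and predicting the phenotype from it, which
drives transfusion strategy (weak D types 1–3 can safely be treated as
D-positive; partial D and DEL carriers cannot). Because a handful of variant
alleles dominate any given region, an efficient scheme is two-staged:

1. **Allele-specific real-time PCR (PCR-SSP)** for the regionally
   predominant variants — here weak D types 1, 2, 3 (`RHD*01W.1`,
   `RHD*01W.2`, `RHD*01W.3`) and DVII (`RHD*07.01`) — read out by
   **melting-curve genotyping**. A β-globin fragment is co-amplified in
   every reaction as an internal control against false negatives.
2. For target-negative samples, **amplification of RHD exons 1–10** with
   intron-flanking primers, **triage** on the amplification pattern, and
   **Sanger sequence-based typing (SBT)** of the coding sequence, ending in
   ISBT allele assignment.

`rhdtyper` implements this scheme end to end in silico, together with a
synthetic-data module that makes every stage testable without any external
data: a 10-exon gene model carrying the assays' primer binding sites, diploid
samples constructed from allele names, and simulated single-direction
sequencing traces with Phred quality values. The packaged 24-sample panel
mirrors a six-year external quality assessment (EQA) series with published
expected results, which serves as the end-to-end oracle.

## The SSP model

PCR-SSP rests on one mechanism: a primer whose 3′-terminal base pairs with
the variant base primes synthesis; a 3′-terminal mismatch does not.
`find_amplicon()` models this **binarily** — both primers must find
convergently oriented sites whose 3′-terminal base matches exactly; up to a
configurable number of mismatches (`max_mismatch`, default 0) are tolerated
elsewhere in the primer. No partial-efficiency or late-amplification
behavior is modeled, because the priming principle is categorical at the
decision level the pipeline needs. Where several products are possible the
shortest below `max_len` (default 1500 nt) is taken, reflecting the kinetic
advantage of short products; the packaged fixtures guarantee uniqueness
anyway. M13 sequencing tails are excluded from template matching and
restored on the product.

A reaction's readout is a synthetic −dF/dT melting curve
(`synthesize_melt_curve()`): each product contributes a Gaussian peak at its
*assigned* melting temperature over the 70–95 °C protocol window (grid
0.1 °C, σ = 0.8 °C, target amplitude 1.0, control 0.6 — display constants;
only peak positions carry information). `classify_melt()` matches called
peaks to predefined genotyping standards within a tolerance.

Two design choices deserve emphasis:

* **Assigned, not computed, melt standards.** Classification uses the
  assays' empirically defined reference temperatures (83.0/80.7 °C for the
  weak D type 1 assay, 74.4/86.0, 86.4/80.7, 85.8/80.7 for the others;
  per-exon standards 88.4, 89.0, 86.5, 85.8, 88.7, 88.3, 87.1, 87.2, 78.4,
  85.6 °C for exons 1–10). Thermodynamic prediction cannot reproduce an
  instrument's empirical values without buffer and dye parameters that are
  not available, so the nearest-neighbor estimator `estimate_tm()`
  (SantaLucia's unified duplex parameters, entropic salt correction
  0.368 (N−1) ln[Na⁺]) is provided **as a diagnostic only** and is never
  authoritative for classification.
* **Tolerance 1.0 °C.** The instrument software's numeric matching window is
  not published; 1.0 °C is this package's documented choice. It must — and
  does — resolve the tightest configured pair (83.0 °C target vs 80.7 °C
  control, Δ = 2.3 °C); `validate_melt_standards()` rejects any
  configuration with standards closer than twice the tolerance before a
  single sample is classified.

Call semantics: `POSITIVE` iff a target peak is present; `NEGATIVE` iff only
the control peak appears (the control rules out a false negative);
`INVALID` iff no peak at all — which a sample with intact genomic DNA can
never produce, and which is the *expected* appearance of the no-template
control. A clean NTC validates the run; any NTC peak invalidates it.

## Triage and its arithmetic

A negative SSP result says nothing about the presence of the *RHD* gene
itself, so target-negative samples proceed to the exon 1–10 screen:

* amplification of **no exon at all** → suspected whole-gene deletion
  (`RHD*01N.01`);
* a contiguous absent set exactly matching an exon-dropout allele in the
  database → suspected hybrid (packaged: exons 6–9 → `RHD*04.03`, a DIV
  type 3 hybrid in which the dropped exons — including their primer binding
  sites — are replaced by non-RHD sequence);
* an absent pattern matching no allele → sequencing with an
  `unexplained_dropout` flag;
* all exons present → sequencing.

Both structural suspicions are provisional: confirmation requires
exon-specific PCR with primers located inside exonic regions, which is not
part of the assay set and is not simulated; the routes therefore always
carry a `confirmation_required` flag.

The pipeline runs in two modes. In **routine** mode an SSP-positive sample
is reported directly and never sequenced. In **study** mode — the
evaluation design used for the packaged panel — every amplifiable sample is
sequenced regardless of SSP outcome, so SSP and SBT can be checked for
concordance. On the packaged panel that yields 18 sequencing-routed samples
(5 deletions and 1 hybrid are excluded) and therefore 180 simulated
chromatograms at ten reads each. The hybrid sample is *not* sequenced even
in study mode, although six of its exons would amplify; this keeps the
sequencing arithmetic consistent with the panel's published evaluation.

## Sequence-based typing

Traces are simulated per amplicon in the direction of the M13-tailed primer
(single direction; exons 2 and 8 read in reverse). A trace covers the
template between the two primer sites; heterozygous positions yield the
two-base IUPAC code; per-base Phred QVs come from a configurable profile.
`filter_read()` implements the validation rule: pure base calls with
**QV ≥ 20** (error probability ≤ 10^(−20/10) = 0.01) are accepted
automatically; pure calls below threshold are flagged `low_quality`; mixed
calls are flagged `mixed_base` whatever their QV and are never silently
dropped. The threshold is inclusive at 20.

"Alignment" is **anchored placement**: amplicon coordinates are known by
construction and the simulated traces are indel-free, so each read is placed
at its exon's window and compared base-by-base; a general pairwise aligner
is deliberately out of scope, and an indel in a trace raises an explicit
unsupported-event error. Accepted positions differing from the reference
become homozygous-or-hemizygous calls. The manual review step of real
chromatogram editing is replaced by a deterministic, conservative rule:
a mixed call whose two bases are reference + one alternate is auto-resolved
to a heterozygous call; any other flagged position is left as a coverage gap
and qualifies the summary as incomplete.

`match_variants()` assigns alleles by exact defining-set comparison. An
empty variant set is the reference allele `RHD*01` (partner `unresolved`,
since sequencing cannot distinguish homozygous from hemizygous). A single
heterozygous variant defining allele A yields (A, `RHD*01`) — the variant in
trans to an unaltered reference haplotype, the only phasing case a
single-direction read supports. Multiple heterozygous variants are not
phased; they are reported as a `novel_candidate` with the variant set
verbatim, never an exception. Homozygous sets matching no allele likewise.
Note the DEL allele `RHD*01EL.01` is defined by the synonymous change
c.1227G>A (K409K); its phenotype is annotation from the database — no
protein-level reasoning is implemented anywhere.

Discordance between a positive SSP assay and the sequencing calls (either
direction) sets a `discordant` flag on the report rather than raising an
error: a diagnostic pipeline must not crash on real-world contradiction.

## The synthetic data, and what it does not show

The gene model is fully synthetic: 10 exons with the true RHD coding exon
lengths (148, 187, 151, 148, 167, 138, 134, 80, 74, 27 nt — summing to the
1254-nt CDS), 300-nt introns, 250-nt flanks, random background sequence,
and every assay primer site embedded verbatim at a registered location,
with lowercase (intronic) primer characters landing in introns and
uppercase in exons. The reference carries the wild-type base at every
allele-defining position; the allele-specific primers' 3′ bases therefore
match only variant haplotypes. A post-build scan guarantees each binding
site occurs exactly once (and each discriminating primer zero times) in
reference plus control locus. True RHD intron sizes are not modeled and no
claim of biological sequence fidelity is made — the model preserves exactly
the properties the pipeline logic depends on: coordinates, primer
complementarity, and variant placement.

Fixture zygosity is a documented choice: the DNB sample is heterozygous
(`RHD*25` in trans to `RHD*01`, the single heterozygous substitution
c.1063G>A); all other panel samples are homozygous, since published EQA
results do not state zygosity and sequencing cannot distinguish homozygous
from hemizygous anyway. The trace QV model has two modes: `clean` (QV floor
25 — the whole panel passes the QV 20 filter, matching the evaluation in
which all base calls were above QV 20) and `degraded` (floor 5, miscall
rate 0.3 *only* at sub-threshold positions, so the QV filter alone
guarantees accepted-call correctness). Every stochastic operation takes an
explicit seed; the packaged panel uses 20240806.

Passing tests on this panel demonstrate the *logic* of the scheme —
discrimination, control validity, triage, calling, assignment — under ideal
amplification and base-calling. They do not demonstrate robustness to
polymerase errors, allele dropout, primer-site polymorphisms, indels,
chromatogram artifacts, or real melting-curve variability, none of which
the generator emulates.

## Numerical choices and degenerate inputs

* Melt grid 0.1 °C over 70–95 °C; peak = local maximum above 0.1 signal
  units; a called peak's position is therefore within one grid step of its
  assigned Tm.
* Amplicon search: mismatch budget 0 by default; the 3′-terminal base is
  always exact-match; shortest-then-leftmost product selection.
* Problem sizes: the full test suite runs the 24-sample panel end to end
  (both modes), 100 randomized brute-force PCR oracle comparisons, and 50
  randomized injected-variant round trips; everything completes in about a
  minute on one CPU.
* Degenerate inputs: absent haplotypes amplify nothing and a deletion
  homozygote cannot be traced (explicit error); an empty observed variant
  set is a valid input meaning "reference"; unknown variant combinations
  are reported, not raised; malformed allele tables, plate orders and
  truncated trace files fail loudly with the offending record named.

## Reproducing the panel analysis

The numbered drivers under `analysis/` run the workflow over the packaged
panel: `01_simulate_panel.R` (fixtures to disk), `02_ssp_screen.R` (stage
one), `03_exon_triage.R` (triage), `04_type_panel.R` (end-to-end typing and
concordance). `scripts/acceptance.R` recomputes the headline quantities
from scratch with a caller-supplied seed. The allele database ships as an
editable flat table (`inst/extdata/rhd_alleles.tsv`) because the scheme is
meant to be extended or modified to a region's predominant alleles; the
twelve packaged alleles are those observed on the EQA panel.

## Known limitations

* Substitutions only — no indels, no structural breakpoint mapping, no
  Rhesus-box or RHD/RHCE architecture modeling beyond the exon-dropout
  abstraction.
* No amplification-efficiency, Cq or fluorescence modeling; melt peaks are
  positional abstractions.
* Phasing is limited to the single-heterozygote-in-trans case; RHCE is out
  of scope entirely.
* Structural calls (deletion, hybrid) remain suspicions pending a
  confirmatory exon-specific assay the package does not provide.
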