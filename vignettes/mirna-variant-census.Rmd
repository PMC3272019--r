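---
title: "Methods: the miRNA variant census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the miRNA variant census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircensus)
```

This vignette is the package's own account of its models and the decisions
behind them: what each stage computes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## Inputs and coordinates

The reference is a set of precursor hairpins: sequence (FASTA), secondary
structure (dot-bracket, one two-line record per hairpin) and mature/star or
-5p/-3p annotations (miRBase-style GFF3 with `type=miRNA`, or a five-column
TSV). All coordinates are 1-based and inclusive on the hairpin's 5′→3′ axis;
offsets are signed integers on the same axis. Sequences are stored uppercase
in the DNA alphabet (U and T are equivalent on input); the RNA alphabet is
used in composition reports. Records with sequence/structure length
disagreements or unbalanced brackets are rejected with a reason rather than
silently dropped; multi-loop structures are tolerated with a warning because
deposited folds occasionally contain them, and the longest enclosed unpaired
span then serves as the terminal loop.

## Tag placement and the MMR policy

Reads (15–35 nt, adapter-trimmed) are collapsed to unique *tags* with
counts. Tags are aligned to both strands of every hairpin, and leftover tags
to a genome if one is supplied, allowing up to one substitution
(`max_mismatches`, default 1). Alignment is substitution-only by design:
with a single tolerated mismatch, multi-base events are unresolvable anyway,
and a trailing base that cannot place is reported as a non-templated
addition via the mismatch channel instead.

The mismatch-and-multimapping resolver is deterministic: if a tag has any
perfect placement, all its mismatched placements are dropped; the survivors
share the tag's count with equal weights `1/k`; placements tied across
sequence-identical hairpins are flagged `identical-locus` so per-family
reports (two-locus families like miR-133a-1/-2) can aggregate them. The
policy conserves counts exactly, is idempotent, and is echoed in output
headers, since other resolvers are conceivable. A 3′-terminal mismatch is a
non-templated addition (NTA) subtyped by the added base; internal
substitutions are subtyped 12 ways (an A-to-I editing event appears as
A-to-G).

## The variant taxonomy

Generic membership is decided by 5′ start proximity alone: a tag anchors on
the annotation minimizing `|Δ5|` with `|Δ5| ≤ generic_window` (default 3
nt); ties prefer the smaller offset, then mature over star over -5p/-3p.
Deciding by start position rather than containment matters at the Dicer
side: a generic tag with a +3 extension may dip into the terminal loop and
must not be reclassified. Offsets for both ends are measured against the
anchor annotation even when `Δ5 ≠ 0`, so 3′ histograms share one scale.
Non-generic tags become e-miR candidates (arm already annotated), novel-miR*
candidates (arm unannotated) or remain unassigned (loop-spanning;
AGO2-processing candidates of the miR-451 type).

"Well-phased" is operationalized as: the modal 5′ start ±1 nt holds at
least half the set's weighted count, with at least 10 weighted tags — a
testable stand-in for the visual inspection such calls otherwise rely on;
both constants are configurable. e-miR calls additionally require ≥ 20% of
the hairpin's weighted tags and a modal length of 18–26 nt, on hairpins at
the stringent expression threshold (150 weighted tags; 25 is the permissive
comparative setting; both boundaries inclusive). A novel miR* is upgraded to
*generic* when the duplex it forms with the known miRNA has both overhangs
within `star_geom_tol` (1 nt) of the canonical 2-nt 3′ overhang.

The 3′-variability statistic is reported twice — weighted over all generic
tags and as the per-miRNA mean — because the two aggregations differ and
either could be meant by a single quoted percentage; columns are labelled
explicitly.

## Arm bias and differential expression

Arm fractions use generic tags only, so bias reflects competition between
annotated species rather than e-miR contamination. Categories follow the
80%/20% thresholds with the boundary assigned to the inner (symmetrical)
class, because the defining inequality is strict (> 80%). Hairpins below
150 weighted tags are `not_assessed`; single-annotation hairpins are
concordant-by-default and flagged.

The two-condition screen normalizes to counts per million mapped tags (the
simplest defensible choice; recorded in the output's `normalization`
attribute), requires the fold change to reach 2 in the same direction in
*every* replicate, and gates on > 1000 normalized tags in every library.
M/A values are computed on replicate-averaged normalized counts.

## Cleavage-site composition and duplex geometry

For each miRNA above threshold, frequency vectors over A/C/G/U are built at
four positions — first and last tag positions (the tag's own bases, so NTAs
count as observed) and one position outside each terminus (hairpin bases) —
weighted by isomiR tag counts and renormalized per miRNA. The background is
the unweighted mean over all available position vectors; when a hairpin
expresses one arm only, whatever positions exist are included and counted.
Composition calls use a two-sided Welch *t*-test of per-miRNA frequencies
against the per-miRNA background frequencies at `alpha = 0.01`; groups with
fewer than three miRNAs are reported `ns` with a flag rather than tested.
Major/minor/symmetric grouping reuses the 80%/20% thresholds rather than
introducing new constants.

Duplexes take the dominant isomiR interval per arm. The Drosha-end overhang
is `end3p − partner(start5p)`, the Dicer-end overhang
`end5p − partner(start3p)`; positive values are 3′ overhangs. When an anchor
is unpaired, the nearest paired position inward is used and the gap added
back — a diagonal extrapolation — and the duplex carries an
`anchored_unpaired` flag so strict tallies can exclude it. One geometric
subtlety is worth recording: reverse-complementing a hairpin description
swaps the duplex ends and converts 3′ overhangs into 5′ overhangs, so only
overhang *magnitudes* are conserved under that transformation (the test
suite asserts exactly this).

Structural distortions are classified from the pairing pattern of the four
nucleotides straddling each cleavage boundary on both strands
(`distortion_window = 4`): all paired → `fully_paired`; equal unpaired
counts on both strands → symmetric internal loop of 2, 4 or more; unpaired
on one strand only → `bulge`; otherwise `other`. The Dicer boundary is
first checked for terminal-loop adjacency (0 or 1 nt), which takes
precedence because distortions adjoining the loop merge with it. These are
deterministic codifications of calls that would otherwise be made by eye;
the window is configurable.

## Discovery and the folding backend

Genome-mapped tags (size-selected to 18–26 nt) are clustered per chromosome
and strand: greedy assignment of tags within 30 nt of the current modal 5′
start (the genomic *end* anchors antisense placements), keeping clusters
with ≥ 50 weighted tags — a declared default, not a derived one — and phase
fraction ≥ 0.5. Windows of 100 and 160 nt (bracketing typical pri-miRNA
hairpins) are folded with the cluster placed on either arm and the
best-scoring fold kept.

The folding contract is sequence in, dot-bracket plus score out. The bundled
backend is a deterministic base-pair-maximization dynamic program (Rcpp)
admitting Watson–Crick and G·U pairs with a minimum loop of 3 nt; ViennaRNA's
`RNAfold` can be selected when present. Under base-pair maximization a
random window pairs promiscuously, so the raw pair count does not separate
hairpins from background; the stem criterion is therefore the longest
*contiguous* stacked helix spanning a hairpin loop (≥ 16 bp), evaluated
against whichever loop carries the strongest such helix — planted stems
score near their full length while shuffled controls stay below ten. The
remaining mandatory criteria: candidate entirely on one arm, ≥ 60% of
candidate bases paired, terminal loop 3–30 nt, modal length 20–24 nt. A
second cluster at the canonical 2-nt-overhang duplex position records miR*
support as a confidence bonus, never a requirement, and such a pair is
linked into a single locus (clusters within 120 nt on one strand). Accepted
loci are named miR-N1, miR-N2, … by coordinate sort, stable across runs.

Antisense candidates fold the reverse complement of the hairpin locus,
evaluate it with the same criteria, and additionally require at least one
tag on the opposing arm. The screen is gated on the stringent expression
threshold (150 weighted tags): with single-mismatch tolerance, a rare
sequencing error can resolve a tag antisense-perfect, and an abundance gate
is the natural defence — credible antisense species express well above it.

## Seeds and target scanning

The seed is positions 2–8 of the variant's own sequence, so a +1 5′ isomiR
shifts it by one. UTR scanning is an explicit simplification: an exact
reverse-complement 7-mer match, labelled "not TargetScan" in its outputs,
because the downstream set logic (shared versus variant-specific targets)
needs membership only. Venn reports compute per-term hypergeometric
enrichment within each subset against the UTR universe,
Benjamini–Hochberg-corrected within subset, significant at p < 0.01.

## What the generator emulates — and what it does not

`sim_spec()` defaults are the study conditions, chosen once: 20 stem-loop
hairpins (30-bp stem, 10-nt loop), log-normal abundances (meanlog
log 1000, sdlog 1), 22-nt mature species at hairpin position 8 with exact
2-nt 3′-overhang annotation geometry, mature arm on the 5′ arm with
probability 0.55, biased hairpins at mature-arm fractions 0.75–0.95 and
-5p/-3p hairpins at 0.35–0.65. The 5′ offset distribution puts 95% of mass
at 0 over −3..+3 and the 3′ distribution 48% at 0 over −4..+4, so about 5%
of tags are 5′ isomiRs, half vary at the 3′ end, and the modal tag length
stays 22 nt with 5′-arm tags at 22–23 nt. NTAs occur at 5% (A- and
U-biased), internal substitution errors at 0.5%. One e-miR (25% of its
hairpin), one antisense locus (2% of reads) and two novel genomic loci (2%
each, 20% star) are planted by default in a 1-Mb random genome, and two
hairpins are annotated on one arm only to exercise novel-miR* detection.

Each synthetic stem carries one G·U wobble pair mid-stem. A perfectly paired
stem makes the arms exact reverse complements, so every arm tag would also
align antisense to the opposite arm — an artefact of idealized geometry that
real hairpins, with their bulges and wobbles, do not show. The single wobble
is positioned so that every simulated tag window covers it (the spurious
cross-placement then carries a mismatch and loses to the perfect sense
placement), while the reverse-complemented hairpin still retains a ≥ 16-bp
contiguous helix for the antisense screen.

The generator does not emulate: ligation or amplification biases, quality
score structure, multi-base 3′ tails, genuine A-to-I editing hotspots,
repeat-derived multimapping beyond identical hairpin copies, or expression
correlation between loci. Passing round-trip tests therefore demonstrates
correctness of the census logic under the declared statistical model, not
robustness to every artefact of real libraries. Planted structural
distortions cover symmetric internal loops at the Drosha site; one-sided
bulges cannot be produced by unpairing positions of a balanced dot-bracket
and are exercised with hand-built structures in the unit tests instead, and
Dicer-site distortions planted on these short canonical stems would merge
with the terminal loop, which is why Dicer classes are tested through
interval placement rather than generator switches.

Determinism: the reference is generated under `seed`, the library under
`seed + 1`, so either can be regenerated independently; identical
specifications yield byte-identical FASTQ output.

## Numerical choices and problem sizes

Weights are exact rationals `1/k` stored as doubles; count-conservation
checks use a 1e-9 tolerance. Ties are broken deterministically throughout
(smaller offset, higher annotation class, smaller coordinate, larger
weighted count). Frequency vectors renormalize per miRNA and their sums are
asserted to 1e-9; the Welch test and BH correction are validated against
first-principles implementations at 1e-9 and 1e-12.

The shipped tests run the full pipeline on libraries of 4,000–50,000 reads
over 2–20 hairpins, 100 seeded replicates for the arm-bias category
recovery, six replicates pooled across miRNAs for isomiR-proportion
recovery (each proportion within three binomial standard errors), 100
shuffled-genome control windows for the discovery false-positive check, and
1,000 random structures for the pair-table oracle — sizes chosen so the
suite completes in well under a minute on one CPU while every planted
parameter remains identifiable.

## Known limitations

Single-substitution alignment cannot see multi-base tails or indel isomiRs;
NTA calling is single-base by construction. The MMR policy is one defensible
choice among several and is therefore declared in every output. Base-pair
maximization is a crude energy model: it recovers planted and canonical
stems but should not be trusted to rank marginal folds, which is why the
discovery criteria lean on helix contiguity and why `RNAfold` is available
as a drop-in backend. The composition background averages the available
positions of single-arm hairpins, which slightly tilts it toward expressed
arms in small cohorts. Cross-species conservation, miRtron models and
context-aware target scoring are out of scope.
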