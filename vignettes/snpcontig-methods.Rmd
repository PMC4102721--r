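---
title: "Methods: intergenomic SNP screening of multidimensional BAC pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intergenomic SNP screening of multidimensional BAC pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcontig)
```

## The problem

An allopolyploid genome such as oilseed rape (AACC) carries two highly
similar copies of every chromosome region, one inherited from each
progenitor species. Building a BAC (bacterial artificial chromosome)
contig for one specific region therefore needs markers that do two jobs
at once: find the clones that carry the region, and say *which* of the
two homoeologous copies each clone carries. Intergenomic SNPs - sites
where the A and C subgenomes differ - do both, and because the extant
diploid progenitors are sequenced, such SNPs can be predicted from
progenitor-genome alignments without touching the polyploid itself.

The package implements the complete screening pipeline around this idea
and, equally importantly, a synthetic-data generator that reproduces the
study conditions with full ground truth, so every stage can be checked
against the truth rather than against itself.

## Assay design from progenitor alignments

`filter_hsps()` keeps local alignment blocks (HSPs) of at least 500 bp
and >= 95% identity whose subject span lies in the target region and
whose query has no additional hit of >= 150 bp and >= 90% identity
elsewhere - the off-target exclusion that protects downstream decoding
from homologous loci. `assemble_gss_contigs()` merges single-pass
genome-survey reads retaining only bases on which all covering reads
agree; disagreement columns are masked and thereby barred from assay
sites and flanks, which suppresses both accession polymorphisms between
the sequenced lines and single-pass errors.

`find_assay_sites()` emits a candidate at every aligned substitution
whose neighbourhood supports allele-specific oligonucleotide extension:
no indel and at most one mismatch within 25 bases per side, any
mismatch more than 15 bases from the site, at least 20 perfectly
identical flanking bases per side, and a full 60-base window extractable
on each side. The two published flank rules (20-25 identical bases;
single mismatches tolerated beyond 15 bases) are applied jointly, so in
practice a tolerated mismatch can only sit 21-25 bases out. Vendor
designability scoring is proprietary; the package substitutes a
transparent surrogate - one minus the fraction of window bases inside a
homopolymer run of length >= 6 or a centred 21-bp subwindow with GC
outside [0.25, 0.75] - thresholded at the published cut-off of 0.6. The
hook is deliberately replaceable; only the threshold semantics matter to
the pipeline.

Alignment computation itself is injected, not reimplemented: real data
enters as 12-column tabular hits (`read_blast_hits()`), synthetic data
uses the generator's recorded alignment truth.

## The synthetic study

`sim_config()` defaults encode the study conditions: two ~1 Mbp
homoeologous regions whose realised alignment identity averages about
96.3% (substitution rate 0.037 plus sparse geometric indels), an
amphidiploid whose subgenomes differ from their progenitors at
accession-SNP rates drawn uniformly from [0.82%, 1.98%], a
216-plate x 16 x 24 library (82,944 coordinates) of Normal(142.5 kbp,
15 kbp) inserts truncated at 20 kbp giving tenfold genome coverage, and
a 50-assay panel mixed over the five assay categories in the proportions
observed experimentally (0.46/0.26/0.12/0.08/0.08). Values the source
study does not state - the indel rate and length, the insert-length
standard deviation, the substitution model (uniform over the three
alternative bases) - were chosen once as field-typical and are exposed
as parameters, not revisited. Empty wells and cross-contamination are
not modelled (no rates are published for them); one clone per
coordinate.

The generator keeps every truth table: the progenitor alignment, the
per-site amphidiploid changes (including which intergenomic sites became
monomorphic - the category-5 substrate - and which acquired footprint
interference - the category-4 substrate), each clone's genomic interval
and subgenome, each pool's ideal call, and each assay's true category
and detectable subgenomes. All randomness flows from one master seed
through per-operation substreams (`substream()`), so any stage replays
in isolation.

Signal generation mirrors a two-channel genotyping screen: pools holding
only nucleotide-1 clones sit at theta ~ 0, only nucleotide-2 at ~ 1,
mixed pools in between, empty pools emit residual fluorescence below the
0.2 threshold. Noise enters as explicit, interpretable events - a
dropout probability (positive pool emits only residual signal) and a
flip probability (pool ascribed to the wrong nucleotide) - rather than
through distribution tails, because those are exactly the two failure
modes the downstream refinement step is designed to absorb. Positive
intensities are truncated at 0.25 so the noiseless screen is exactly
clean; this is a modelling decision, stated here once.

## Calling and deconvolution

`classify_pools()` applies the published thresholds verbatim and
inclusively: pools with normalised R < 0.2 are negative; theta <= 0.05
and >= 0.95 call the two alternative nucleotides; everything between is
"both". The vendor normalisation itself is accepted as input; a
reference normalisation (`normalize_channels()`) exists for the
simulator.

A clone coordinate is reported for nucleotide k iff **all seven** of its
pools are positive for k, where "both" pools count as positive for
either nucleotide (a pool holding clones of both subgenomes genuinely
fluoresces in both channels; any stricter rule would drop true
coordinates). Coordinates satisfying all seven dimensions for both
nucleotides are emitted once with class "both" and treated downstream as
unassignable, mirroring the handful of ambiguous clones seen in
practice. The optimised decoder intersects per-dimension positive-pool
sets on the design's membership matrix; `decode_bruteforce()` retains
the defining per-coordinate scan, recomputing each coordinate's pools
from the design parameters, as a genuinely independent oracle - the
test suite holds the two equal up to full library size.

### The pooling design

The published screen used 276 six-dimensional pools plus 216 single
plate pools; the composition of the six-dimensional pools is described
in prior work and not reproduced here. The package's default is a
shifted-transversal-style construction preserving both the
seven-dimension contract and the published pool-count scale: writing the
coordinate index in base q (q the smallest prime with q^3 >= library
size; 47 at full scale, hence 6 x 47 = 282 six-dimensional pools), layer
j pools coordinate (d0, d1, d2) into (d0 + j d1 + j^2 d2) mod q. Two
distinct coordinates then share a pool in at most two of the six layers
- the polynomial-agreement bound - which keeps the expected number of
shadow coordinates (false positives whose seven pools are all covered by
the union of true positives) small at tenfold coverage. A plate-digit
family ("digits": plate-index digits, row, column, a diagonal pool, and
the plate) is also provided and fully supported; it was not made the
default because its very large pools in the low-cardinality dimensions
make shadows, not true positives, the dominant output at full scale.
Decoding logic depends only on the partition property, which every
family (and any user-supplied dimension set) is validated against.

Shadows are not a defect to be hidden: the real screen produced 8100
putative clones of which 197 were eventually confirmed. The pipeline's
contract is therefore *no false negatives at zero noise* at the decoding
stage, and *truth recovery after the validation stage*; the noiseless
acceptance check asserts exactly that, and the property suite
additionally asserts raw-decode equality at scales where the shadow
expectation is negligible.

## Subgenome assignment and assay categories

Reference-panel evidence follows the published table layout: two
accessions plus a WGS call per progenitor (plus a GSS call on the C
side), the amphidiploid call, and amplicon reads. `classify_assay()`
distils it with one calibrated notion: a progenitor side is *concordant*
iff it has at least two non-missing, non-heterozygous sources that all
name the same base. Two concordant sides naming different nucleotides of
the amphidiploid pair give category 1; exactly one concordant side gives
category 2 (the concordant side anchors the map, the other nucleotide
goes to the other subgenome); anything else with a two-nucleotide
amphidiploid call is left pending and resolved to category 3 by clone
inference. A single-nucleotide amphidiploid call is category 5 when the
subgenome amplicons show the site monomorphic, otherwise pending
category 4. When the amphidiploid genotyping call is missing, the
amplicon's IUPAC code substitutes for the call shape; assays with usable
pool data but unusable evidence can optionally take their map from the
WGS columns alone while remaining category-unassigned.

Clone inference (`infer_pending()`) lets clones already labelled through
category-1/2 assays vote on each pending nucleotide; the majority
subgenome is accepted at a quorum of 0.8 over at least 3 labelled
clones. The quorum is not a published constant - the source describes
the inference qualitatively - so it is exposed as a parameter; the
defaults were chosen once as a conventional supermajority. The operation
is idempotent and never touches categories 1, 2 or 5.

Two documented limitations: an assay at a monomorphic site whose one
subgenome additionally carries footprint interference classifies as
category 5 from evidence alone (the published analogue was resolved only
by sequence inspection of the oligo footprint), and a single-base
amplicon on an otherwise category-2 pattern follows the single-nucleotide
path. The synthetic evidence generator avoids both ambiguities by
construction, so category recovery on synthetic panels is well-defined.

## Selection, validation, refinement, bridging

Selection applies the three published criteria in order: (A) scored by
>= 4 assays, not counting assays with more than 3000 putative clones;
(B) for clones failing A, two scoring markers separated by at least two
intervening markers in the reference order; (C) at least two directly
adjacent scored markers among the first or last `end_marker_count`
markers of the region. The published phrase "two or three markers" at
the region ends is resolved by making the count a parameter with default
3. A clone records every criterion it meets; the primary label follows
A > B > C.

Validation checks every score of every selected clone against an
amplicon oracle (in simulation, ground truth with optional
subgenome-specific masking, emulating amplicons that interrogate only
one homoeolog - masked claims are excluded from the false-positive
denominator). Contigs connect clones sharing a *confirmed* marker -
marker content is the only overlap evidence available here;
fingerprint-style overlap detection is out of scope by design. Member
order is leftmost confirmed marker, then rightmost, then clone id.
Marker-order violations (a clone skipping interior markers) are
reported, never auto-corrected.

Refinement iterates to a fixed point: for each member, untested markers
interior to its confirmed interval and the markers directly adjacent to
its ends are oracle-tested; presences are integrated as recovered false
negatives. Interior testing precedes end-extension within each pass -
an implementation decision recorded here, as the source does not state
an iteration order. Because each pass strictly grows the confirmed
interval or stops, termination is guaranteed. Bridging then validates
putative clones scored near the facing ends of adjacent contigs across
the gap interval; a confirmed clone reaching into both contigs merges
them, and unbridged gaps are reported with a diagnosis (no candidates /
candidates mapping elsewhere / no spanning clone), mirroring the
published gap analyses.

## Numerical and coordinate conventions

Coordinates are 0-based half-open internally; 1-based only in rendered
clone names ("27D10" = plate 27, row D, column 10) and reports. Printed
percentages use round-half-up at the printed precision
(`render_percent()`), which reproduces every published rendering
(9.11 -> 9.1, 6.896 -> 6.9, 72.03 -> 72, 99.972 -> 99.97); raw ratios
are retained alongside. One published figure deserves a note: the 2.5%
false-positive rate is reproducible only with confirmed scores
(1055 - 37 = 1018) as denominator; the fixture check states that
derivation explicitly. Ties in clone ordering break lexicographically.
TSV exports render doubles with 17 significant digits so round-trips
are lossless.

## What the tests do and do not show

The test suite runs the generator at reduced sizes chosen for the
property under test, as the package's own experimental design: 6-plate
libraries for exhaustive pooling checks, 24-48 plates for noise
parameter recovery (10 seeds at 2% dropout; 10 seeds at 0.5% flips
against a Monte-Carlo propagation estimate that re-simulates signals
from the frozen truth), twofold coverage where raw-decode equality with
truth is asserted (shadow expectation ~ 0 there), and the full 82,944
coordinate, ~1 Mbp, 50-assay default for the noiseless end-to-end and
decoding-oracle checks.

Passing these tests shows the pipeline is internally correct under the
generator's assumptions. It does not show robustness to what the
generator deliberately omits: the triplicated paleopolyploid structure
of real crucifer genomes (off-target loci are modelled as independent
background sites, not structured paralogy), empty or misplaced wells,
cross-contamination, vendor normalisation artefacts, or real
designability scoring. The fixture checks, conversely, verify the
arithmetic of the published tables exactly but involve no simulation.

## Session info

```{r}
sessionInfo()
```
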