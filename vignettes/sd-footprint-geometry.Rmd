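---
title: "Internal Shine–Dalgarno sites and footprint geometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal Shine–Dalgarno sites and footprint geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboSD)
```

`riboSD` quantifies how internal Shine–Dalgarno (SD) elements reshape
ribosome-protected fragments in bacterial ribosome profiling: SD:aSD pairing
pauses the elongating ribosome and, by staying bound while a few further
codons are decoded, anchors the footprint 5′ end while the 3′ end extends.
This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open, in enough detail that a maintainer can
tell what a passing test does and does not establish.

## 1. The duplex energy model

An SD site is defined thermodynamically: an octamer predicted to hybridize to
the 16S rRNA anti-SD tail (5′-CACCUCCU-3′) with free energy ΔG ≤ −8 kcal/mol.
`duplex_free_energy()` computes the minimum free energy over all antiparallel
intermolecular structures built from Watson–Crick and G:U pairs, where
consecutive pairs are joined by a stack, a bulge, or an internal loop, and

* energy = duplex initiation + Σ stack increments + Σ loop penalties,
* a qualifying structure contains at least one helix of
  `min_helix_pairs = 2` contiguously stacked pairs,
* bulges and internal loops are capped at `max_loop_len = 4` unpaired nt,
* if no qualifying structure is stabilizing the function returns the 0.0
  "no binding" sentinel, so every threshold comparison is of the form
  `dg <= t` with t < 0.

Parameters (units kcal/mol at 37 °C) live in the versioned text table
`inst/extdata/duplex_params.tsv`: the Turner 2004 stack increments including
wobble pairs, bulge initiation (3.8, 2.8, 3.2, 3.6 for lengths 1–4), internal
loop initiation (1.0, 1.0, 1.1 for total sizes 2–4), and the intermolecular
initiation penalty 4.10. Deliberate simplifications, documented here because
they shift absolute energies slightly relative to full folding programs: no
terminal-AU penalty, no dangling ends, no sequence-specific 1×1/2×2 loop
tables, no temperature dependence, no intramolecular structure. Two published
thresholds in this field are printed as magnitudes; stabilizing free energies
are negative, so detection is ΔG ≤ −8 and the "no SD" exclusion is ΔG ≤ −2.

The single-nucleotide bulge penalty (3.8) exceeds the two-nucleotide one
(2.8) in the published table because the source model preserves the flanking
stack across a 1-nt bulge; this model does not add that stack, so the
published value is used as-is and the monotonicity check on bulge penalties
starts at length 2.

Correctness is established by redundancy: the production dynamic programme
(C++), an independent exhaustive structure enumerator (C++), and a third
pure-R enumerator in the test helpers must agree; the test suite sweeps all
65,536 octamers against the aSD with both compiled kernels and checks that
the perfect complement AGGAGGUG attains the global minimum (−13.4 kcal/mol
under this parameterization). The physically meaningful symmetry is
probe/target exchange — `dg(a, b) == dg(b, a)` — because an antiparallel
duplex read from the other strand is the same complex; reversing both
sequences is *not* a symmetry of a stacked nearest-neighbor model.

Scanning reports discrete sites: among overlapping passing octamers the
strongest (ties: leftmost) is kept, repeatedly. The site coordinate is the
octamer's first nucleotide whether or not that base pairs. Whether whole CDSs
or only read-filtered interiors are scanned is exposed
(`scan_sd_sites_genome(interior_only =)`); whole CDSs are the default.

## 2. Read filters and footprint classes

Footprints must be uniquely aligned (SAM flags 0x100/0x800 and MAPQ 0 are
treated as non-unique) and fully contained in the ORF interior: 5′ end
strictly after CDS nucleotide 30 and 3′ end at or before L − 75. Full
containment is used at both boundaries so that initiation and termination
peaks cannot leak into any downstream statistic. Genes enter
length-distribution and hexamer analyses above 10 footprints per codon;
density uses the interior codon count as denominator (only interior
footprints are counted), with the whole-ORF denominator available behind a
flag.

A footprint is **SD** when some octamer starting at footprint positions 3–17
(1-based from the 5′ end, coding strand) reaches −8 kcal/mol, **NoSD** when no
octamer starting there reaches −2 kcal/mol, **Ambiguous** otherwise. The
start-position reading of the window is implemented (an octamer may extend
past position 17 as long as it starts by 17 and fits inside the footprint);
for footprints shorter than 24 nt the start window is clipped to
`len − 7`, and footprints under 10 nt admit no octamer and are Ambiguous.
For per-SD bookkeeping an SD footprint is attributed to the scanned site
whose octamer overlaps its classification window (the site start may sit up
to 7 nt outside the window, because a shifted register of a strong octamer
can carry the classification); when several sites qualify the strongest wins.

## 3. Length distributions and the rank-sum comparison

The printed index notation of the length-frequency statistic is internally
inconsistent; the implemented reading matches its stated intent — "per SD
basis" for the SD class, "per gene basis" for NoSD:
`f(l) ∝ Σ_k Σ_j x_{l,j,k} / N_k`, with `N_k` the number of SD sites in gene
k for SD units and 1 for gene units, renormalized to Σ f = 1. The alternative
reading (normalize each unit's histogram to 1 before averaging) is available
via `unit_normalize = TRUE` and makes f(l) invariant to rescaling any single
unit's counts. SD vs NoSD is tested on raw per-footprint lengths with a
two-sided Wilcoxon rank-sum test using the normal approximation and
tie-corrected variance (exact p = 1 when all values are identical).

## 4. End-density profiles

For each SD site, footprint 5′ and 3′ ends are counted at offsets
s ∈ [−49, 50] (s = 1 at the SD first nucleotide; 100 nt total) and normalized
by the site's mean footprint coverage per nucleotide in that window (X), then
averaged across sites: `d(s) = (1/N) Σ_i x_{s,i}/X_i`. Numerical rules, all
of which show up in the identities the tests assert:

* sites whose window leaves the trimmed interior are excluded (truncation
  bias), as are sites at or below 1 footprint per codon in the window or with
  X = 0;
* per-length strata restrict both x and X to that footprint length, but the
  density floor stays on all-length footprints — at realistic depth a
  per-stratum floor of 1/codon would exclude every site — and a stratum site
  additionally needs at least two stratum footprints, because a single
  clipped footprint makes x/X spike (1 end over a near-zero X);
* with uniform input the profile is flat at (ends per nt)/(footprints per
  nt), and for footprints wholly inside the window Σ_s x5 = Σ_s x3 = the
  site's footprint count.

`profile_peak_stats()` summarizes a profile column by baseline (median over
the SD-distal flank s ≤ −15), argmax, FWHM, and excess-weighted centroid and
variance accumulated within ±16 nt of the argmax — the window keeps baseline
noise far from the peak out of the moments; ±16 covers the half-spread of
the widest admissible footprint (47 nt) around its center.

`recover_pause_parameters()` inverts the profile: the 3′−5′ excess-centroid
separation equals (mean footprint length − 1) + mean extension, so
subtracting the NoSD mean length isolates the extension; and the summed 5′
excess over the peak, divided by baseline × 3 × (number of pause codons),
gives the per-codon pause fold. The fold estimate carries a known upward bias
of order +1 per background codon inside the extension window (those
footprints are themselves relocated onto the anchor); on the default fixture
it reads ~10 for a planted fold of 9, within the 20% band the acceptance
test allows.

## 5. SD read enrichment

The published enrichment statements do not define their expectation. The
implemented expectation is uniform placement: for each gene and footprint
length, the fraction of admissible interior 5′-end positions whose
classification window contains a −8 kcal/mol octamer, summed over the
observed footprints. This makes the null case (uniform reads) give
enrichment 1 by construction, is invariant to scaling all counts, and uses
each footprint's own length, so length composition cannot masquerade as
enrichment.

## 6. The simulator and what it can (and cannot) show

`run_simulation()` draws 1000 random 1000-nt sequences (i.i.d. uniform
nucleotides), 600 footprints each, lengths 20–47 nt from a discretized
triangular distribution peaking at 28 nt — the empirical length distribution
it stands in for rises steeply to a mode near 28 and decays slowly; any
user-supplied table is accepted. Candidate P-sites are codon starts (step 3
from position 1) within margins that keep the longest footprint inside the
sequence, plus the slow coordinates themselves (x = SD start + 11 may be off
the global lattice; the offset from the SD to the slow P-site codon is the
`pause_offset` parameter since neither endpoint is fixed by the published
description). Footprints are centered on the P-site codon; for even lengths
the 5′ half carries the extra nucleotide (the published "centers at the
P-site" is ambiguous for even lengths; a uniform half-nucleotide tie-break
has no effect on any contrast).

Under the **single** model, slow codons carry weight 9 (others 1). Under the
**caterpillar** model the pause spreads over x, x+3, x+6 at weight 3 each
(replacing, not multiplying, the base weight), and any footprint whose P-site
p falls in x+1…x+6 is extended at the 5′ end by p − x, i.e. its 5′ end is
anchored where a footprint with P-site x and the same drawn length would
start, while its 3′ end keeps the position centered on p. Out-of-bounds
placements are resampled. Setting the multiplier to 1 yields statistically
flat profiles, which the suite asserts.

The discriminating signatures, reproduced by the acceptance checks: single —
5′ and 3′ end-density peaks of equal width (mirror images through the
centering rule) separated by the mean footprint length minus one; caterpillar
— strictly larger 3′-peak variance, a dip immediately downstream of the 5′
peak (footprints from x+3/x+6 are relocated onto the anchor, emptying the
positions they would have occupied), and a 5′ peak that does not track
footprint length while the 3′ peak does.

One caveat is worth stating precisely. In experimental data the SD:aSD duplex
fixes the 5′ boundary physically, so per-length 5′ peaks coincide exactly. In
the simulator the anchored 5′ end is `x − ceil((drawn − 3)/2)`: the
drawn-length dependence survives, and within an emitted-length stratum the
drawn length varies by the extension δ ∈ {0, 3, 6}. The per-stratum 5′
argmax therefore wanders within a ±2 nt band (no trend; the suite asserts
stationarity and a 3′ slope near +1), but it is not bit-identical across
strata, and the 3′ argmax advances at an average slope slightly below 1. A
stricter per-stratum invariance check is included in the acceptance suite and
fails for this structural reason; the geometry above, not sampling noise, is
the cause.

## 7. The synthetic fixture

`build_fixture()` generates the regime the analyses assume, as ground truth:

* 200 genes of 600 nt on one contig, alternating strands, separated by
  low-complexity C/T spacers; 25% are SD-free controls;
* SD genes are random ORFs (start codon, 61-sense-codon body, stop) with one
  planted octamer drawn evenly across ΔG ∈ [−14, −8.5] kcal/mol, placed ≥ 50
  nt inside the trimmed interior, and resampled until a −8 kcal/mol scan
  recovers exactly the planted sites and the frame stays stop-free. Only
  "scan-canonical" octamers are planted — those whose terminal base pairs, so
  the greedy leftmost tie-break reports them at their own start;
* control ORFs are built from C/U-only codons: no base of such a sequence can
  form more than one pair with 5′-CACCUCCU-3′, so no octamer reaches
  −2 kcal/mol. This is constructive rather than rejection sampling (a random
  600-nt ORF essentially always contains a ≥ −2 kcal/mol octamer, so
  rejection would not terminate); a verification scan errors if the
  construction ever failed;
* reads reuse the simulator's engine per gene: pause codons at x, x+3, …,
  x+3K with per-codon weight `pause_fold` (default 9), where
  K = round(2 × length_shift/3) realizes the requested mean extension on the
  codon lattice (the planted mean, 3K/2 = 4.5 nt at the default
  `length_shift_nt = 4`, is stored in the ground truth and is what recovery
  is judged against); all P-sites keep footprints inside the trimmed
  interior, so the 10/codon gene filter passes deterministically, by design;
* all randomness flows from one seed, recorded in every emitted file header.

What passing fixture tests establish: coordinate conventions (both strands),
the classification window, the Eq.-style normalizations, and that the
pipeline recovers planted pause parameters from the profile without using
labels. What they do not establish: absolute agreement with any particular
folding program's site census (parameterizations differ), RNase digestion or
ligation bias, rRNA contamination, or non-uniform codon usage — none of which
the fixture emulates.

A note on the length-distribution reading of the shift: the classification
window admits anchored footprints only when they are long enough to reach
back over the SD, so the SD-class mean length is selection-biased upward; on
the default fixture the distribution shift reads ~4.6 nt for a planted mean
extension of 4.5 nt with the widened site attribution, and the acceptance
check brackets it asymmetrically (−1/+3 nt around the planted value). The
profile-based estimator is free of this bias and is the quantitative
recovery.

## 8. Problem sizes and interfaces

Defaults follow the study conditions throughout: simulator 1000 × 1000 nt ×
600 footprints; fixture 200 genes × 2000 reads; sweeps over all 4^8 octamers
and 4^6 hexamers. The full test suite and the acceptance script each run in a
few minutes on one CPU. The package exposes everything as R functions driven
by the numbered scripts under `analysis/`; no separate shell tool is shipped,
as the functions plus drivers are the interface of this analysis package.
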