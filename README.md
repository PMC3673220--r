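# riboSD

Internal Shine–Dalgarno sites and the geometry of ribosome footprints in
bacterial ribosome profiling data.

## The problem

In bacteria, purine-rich Shine–Dalgarno (SD) motifs inside coding sequences
base-pair with the anti-SD (aSD) tail of 16S rRNA (here 5′-CACCUCCU-3′) and
stall elongating ribosomes. Beyond the pause itself, the SD:aSD contact
tethers the mRNA: while the ribosome decodes the next few codons the duplex
stays attached, so the protected fragment keeps its 5′ boundary and grows at
the 3′ end — a caterpillar-like movement that makes SD-containing footprints
longer and asymmetric. That matters to anyone who reads ribo-seq coverage as
translation kinetics: the A-site offset of a bacterial footprint is
sequence-dependent.

`riboSD` implements the full analysis chain needed to detect and quantify
this effect, plus the simulator that discriminates single-codon pausing from
multi-codon SD-tethered pausing:

* **SD detection** — nearest-neighbor RNA:RNA duplex minimum free energy of
  any short probe against the aSD (Turner 2004 stacks incl. G:U wobble,
  bulges/internal loops to 4 nt, duplex initiation 4.10 kcal/mol), computed
  by a dynamic programme in C++ with an independent exhaustive enumerator as
  oracle. An SD site is an octamer with ΔG ≤ −8 kcal/mol; overlapping
  octamers are resolved greedily (strongest, then leftmost).
* **Footprint ingestion** — FASTA genomes, GFF3/BED12 gene models, BED6/SAM/
  BAM alignments; unique-mappers only; footprints restricted to ORF
  interiors (downstream of the first 30 nt, upstream of the last 75 nt).
* **Footprint classes** — *SD* if an octamer starting at footprint positions
  3–17 (from the 5′ end) reaches −8 kcal/mol, *NoSD* if none reaches
  −2 kcal/mol, *Ambiguous* otherwise.
* **Length statistics** — the normalized length frequency
  `f(l) ∝ Σ_k Σ_j x_{l,j,k} / N_k` (per SD site for the SD class, per gene
  for NoSD; genes above 10 footprints/codon), and a Wilcoxon rank-sum
  comparison of the two classes.
* **Metagene end densities** — `d(s) = (1/N) Σ_i x_{s,i}/X_i` for footprint
  5′ and 3′ ends at offsets s ∈ [−49, 50] around the SD first nucleotide
  (s = 1), optionally per footprint length; plus estimators that read the
  pause fold and the mean 3′ extension back off the profile.
* **Hexamer correlations** — per-hexamer mean footprint length and
  normalized density for footprints starting 8–2 nt upstream, against the
  hexamer:aSD duplex strength.
* **Simulator** — 1000 random 1000-nt sequences × 600 footprints (lengths
  20–47 nt, centered on the P-site codon), with either a single 9-fold slow
  codon 11 nt downstream of each SD, or the caterpillar model: 3-fold weights
  at x, x+3, x+6 and 5′-anchored extension for P-sites at x+1…x+6.
* **Synthetic fixture** — ORFs with planted SD octamers of known ΔG, SD-free
  control ORFs, and reads with known pause fold and extension, so the whole
  pipeline is testable without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
fixture; each writes tables under `results/`:

```sh
Rscript analysis/01_build_fixture.R
Rscript analysis/02_scan_sd_sites.R
Rscript analysis/03_footprint_classes_and_lengths.R
Rscript analysis/04_end_density_profiles.R
Rscript analysis/05_hexamer_correlation.R
Rscript analysis/06_model_comparison.R
```

On the default fixture (200 genes × 2000 reads, seed 7) this prints, among
other things:

```
150 SD sites in 150 of 200 genes -> results/sd_sites.tsv
planted-site recovery: 150/150
mean length SD 36.30 vs NoSD 31.66 nt (distribution shift 4.63 nt)
Wilcoxon rank-sum p = 0
SD-classified reads: 64343 observed vs 11388 expected (5.6-fold)
recovered pause fold 10.09 (planted 9); mean extension 4.65 nt (planted 4.5)
```

The scan recovers exactly the planted SD sites; SD-classified footprints are
~4.6 nt longer than SD-free ones (the planted caterpillar extension averages
4.5 nt) and ~5.6-fold enriched over uniform placement; reading the end-density
profile back gives the planted pause parameters. The model comparison prints
the two signatures that discriminate the hypotheses: under single-codon
pausing the 5′ and 3′ end peaks are mirror images (FWHM 8 vs 8) separated by
the mean footprint length, while the caterpillar model widens the 3′ peak
(variance 18.9 vs 11.0), keeps the 5′ peak put across length strata, and digs
a dip just downstream of it (0.48 of baseline).

The same functions run on real data: give `02_scan_sd_sites.R` a genome FASTA
and GFF3, and point `read_footprints()` at an aligned BAM/SAM/BED of
ribosome-protected fragments.

## Layout

```
R/                  package code (energy model, IO, metrics, simulator, fixture)
src/                C++ duplex-energy kernels (DP + exhaustive enumerator)
inst/extdata/       versioned nearest-neighbor parameter table (TSV)
analysis/           numbered workflow drivers (write results/)
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, assumptions, design choices)
```
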