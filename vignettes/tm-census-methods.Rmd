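---
title: "Methods: a transmembrane-protein census for prokaryotic viruses and their hosts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a transmembrane-protein census for prokaryotic viruses and their hosts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmcensus)
```

## The problem

Double-stranded DNA viruses of bacteria and archaea encode far fewer
membrane proteins than their hosts, and almost no proteins with complicated
polytopic topologies — with the striking exception of viruses whose virions
carry lipid (an envelope, an internal lipid core, or an inner membrane
vesicle). Quantifying that contrast requires the same machinery across tens
to hundreds of proteomes: predict which proteins carry α-helical
transmembrane (TM) segments, aggregate per-genome statistics, control for
redundancy among closely related genomes, measure how virus-specific each
gene family is, and test the group contrasts. `tmcensus` implements that
pipeline end to end, together with a fully seeded synthetic-proteome
generator so every stage can be exercised and validated without downloads.

## TM topology prediction

The built-in predictor is a hydropathy sliding-window segment caller in the
classic Kyte–Doolittle tradition, not a reimplementation of an HMM
predictor. For a sanitized sequence:

1. every window of `window` residues (default 19, the canonical span of a
   membrane-crossing helix) whose mean hydropathy reaches `threshold`
   (default 1.6 scale units) marks its residues as candidate membrane
   residues;
2. maximal candidate runs separated by fewer than `merge_gap` (3) residues
   are merged;
3. each run is trimmed inward past terminal residues with hydropathy below
   `trim_cutoff` (0), so the call tracks the hydrophobic core rather than
   the full extent of every qualifying window — without this step every
   call would overhang its helix by up to window − minimum-overlap
   residues on both sides, and segment-length statistics would be inflated
   by ~10 aa;
4. runs longer than `max_len` (35) are split at their least hydrophobic
   interior residue; runs shorter than `min_len` (15) are discarded.

Ties and boundary cases: a window sum landing exactly on the threshold is
accepted (an epsilon guards against accumulation-order effects); a sequence
shorter than one window yields an empty prediction, not an error.

**Orientation** follows the positive-inside rule: Lys/Arg are counted in
the membrane-proximal part of each inter-segment loop (within `flank = 15`
residues of an adjacent segment) under both candidate orientations, and the
orientation placing more K/R on the cytoplasmic ('in') side wins. The
restriction to membrane-proximal residues matters: positive-inside
enrichment is a local property of loop ends, and counting whole loops lets
a long C-terminal soluble tail outvote a short, genuinely biased
cytoplasmic loop. Exact ties resolve to N-in, the topology class dominant
in nearly all organisms.

**Signal peptides** are recognized by a tripartite heuristic (a K/R in the
first five residues, a hydrophobic h-region of 7–15 residues starting
within the first ten, then a small-residue cleavage region, all within the
N-terminal 30 aa). A detected signal removes any TM segment lying wholly
within the signal region: its hydrophobic core is an export signal, not a
membrane anchor. A protein with at least one remaining segment counts as a
TM protein whether or not it also has a signal.

When externally produced predictions are available (Phobius short format,
parsed by `parse_phobius()`), they carry a `source` tag and can be fed to
the census in place of the built-in predictor — the census is agnostic
about where its topology set came from.

## Census statistics

`genome_census()` aggregates, per genome: protein count, TM-protein count
and fraction, a TM-segment-count histogram (capped at 15 with an overflow
bucket; raw counts retained), and a 2×2 TM-by-conserved cross-tabulation
against an orthogroup membership table. `stratify_by_length()` bins
proteins into half-open length intervals and splits each bin by TM class
(0, 1, 2, 3, 4+), the standard control for the possibility that viruses
lack polytopic proteins merely because their proteins are short.

Redundancy reduction mirrors common practice: virus genomes sharing at
least 90 % of their genes (shared orthogroups over the assigned gene count
of the smaller genome; Jaccard available as an option) are linked, and one
random, seed-recorded representative is kept per single-linkage component.
Single linkage is used because it is deterministic and order-independent;
a genome with no orthogroup-assigned genes cannot be compared and is kept
with a warning. Cellular genomes keep the largest genome per genus, ties
broken toward the lexicographically smallest id so the choice is
reproducible.

## The Viral Quotient

For a gene family, let `f_v` be the fraction of virus genomes in the
universe containing at least one member, `f_c` the fraction of cellular
genomes containing one anywhere, and `f_p` the fraction of cellular
genomes whose matches include a protein inside an annotated prophage
region. The Viral Quotient is

$$VQ = \frac{f_v + f_p}{f_v + f_p + f_c}.$$

Frequencies are per-genome (a genome either contains the family or not),
which makes VQ invariant under proportional scaling of the universe. The
prophage term credits integrated viruses to the viral side: a family found
only in lytic viruses scores 1.0, only in non-prophage cellular chromosome
0.0, and only inside prophage regions exactly 0.5. Classification places
the 0.5 boundary with the predominantly-viral class, because the
prophage-only case that lands exactly there is phage-derived by
construction. An alternative algebra that also adds `f_p` to the
denominator a second time is available as
`compute_vq(prophage_mode = "both_sides")` (it scores a prophage-only
family 1/3); it is not the default because it breaks the 0.5 anchor.

## Group comparisons

- `tm_correlate()`: Pearson product–moment correlation of per-genome TM
  fraction against virion lipid association (binary; tentative lipid
  assignments inherit their tentative class), host domain (Archaea = 1, so
  archaeal TM enrichment appears as a positive coefficient) or genome size.
  Zero variance in either variable is an error, not an NA.
- `mww_test()`: two-sided Mann–Whitney–Wilcoxon. Untied samples with
  n·m ≤ 400 use the exact U distribution; tied small samples use full
  enumeration of all group labelings of the midranks; everything else uses
  the normal approximation with tie-corrected variance and continuity
  correction. The two-sided convention is the probability of a U at least
  as far from nm/2 as observed (the null distribution is symmetric, so
  this coincides with doubling the smaller tail for untied data).
- `chisq_hist_test()`: Pearson chi-squared homogeneity test between two
  count histograms, with adjacent low-expected bins (< 5) merged rightward
  (the rightmost bin folds leftward) before the statistic is computed; no
  continuity correction. No multiple-testing correction is applied across
  the report.
- `orthogroup_consistency()`: for every orthogroup with ≥ 2 predicted
  members, uniformity is exact TM-count equality and discordance magnitude
  is max − min; aggregates report the uniform fraction and the split of
  discordant groups by 1, 2, or > 2 segments.

## The synthetic generator

`generate_synthetic()` emulates the statistical structure the census
assumes, with all randomness flowing from one seed through per-genome
substreams (virus and cellular genomes occupy disjoint substream ranges,
so enlarging one class never reseeds the other; identical spec + seed give
byte-identical output).

Defaults, and why:

- **TM fractions.** Virus-like genomes target 8 % TM proteins and
  cell-like genomes 22 %, the centers of the regimes observed in real
  proteomes. Virus genomes from lipid-associated virion families target
  30 % instead (the lipid effect). Per-genome targets are beta-distributed
  around these means with concentration 25 (virus), 400 (cellular) and 80
  (lipid): viral TM fractions are empirically far more variable than the
  nearly constant cellular 20–25 % band, and a fixed target cannot
  reproduce that contrast.
- **TM-count distributions.** Virus-like proteins carry 1–3 segments
  (0.70/0.20/0.10); cell-like proteins have a heavy polytopic tail with
  planted secondary modes at 6 and 12 segments.
- **Helices and loops.** Helix lengths are truncated-normal, mean 21, sd
  1.5 on [19, 25]; loops are ≥ 10 aa (10 + Poisson), built from an
  all-hydropathy-negative hydrophilic composition so that hydrophobic-core
  trimming recovers planted boundaries. Each 'in'-side loop receives a
  planted excess of 3 K/R residues placed membrane-proximally. TM
  residues are drawn from a strongly hydrophobic-enriched composition
  (window means ≈ 3 scale units, ~5 sd above threshold, so planted helices
  are essentially never missed).
- **Soluble proteins** use a mildly hydrophilic average composition (mean
  Kyte–Doolittle ≈ −1.0). This yields ~1.5 % false-positive TM calls on
  soluble proteins — deliberately nonzero, since real hydropathy
  predictors also occasionally call hydrophobic patches of soluble
  proteins.
- **Plumbing.** ~3 % of proteins get a signal-peptide prefix; ~60 % of
  proteins are assigned to class-specific orthogroup pools; half of the
  cellular genomes carry one 15-protein prophage region whose proteins are
  virus-like (10 % TM) and draw from the viral orthogroup pool.

What the generator does **not** emulate: sequence homology within
orthogroups (pool labels are sharing structure, not related sequences —
use `perturb_orthogroup()` to build genuinely homologous families from one
ancestor when testing prediction consistency), nucleotide genomes, gene
order, phylogenetic correlation between genomes, and compositional
idiosyncrasies of real proteomes. Passing tests therefore demonstrate
correctness of the statistical machinery on data with the assumed
structure, not predictor accuracy on real proteins.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
~1000 proteins per class for predictor-recovery checks, tens of genomes
for distributional contrasts, exhaustive enumeration only where the
combinatorics are tiny (MWW with n + m ≤ 8, VQ universes with ≤ 6 genomes
per side, brute-force window scoring on sequences ≤ 60 aa). Dataset-wide
quantities from real censuses (e.g. a lipid correlation of ~0.78 over
hundreds of genomes) require the full external data and are validated here
only through the oracle equivalences above.

Known limitations: the segment caller is a single-scale windowing method
and will not resolve marginal helices the way a trained HMM does; the
signal-peptide heuristic is deliberately conservative; `mww_test` switches
to a normal approximation for large tied samples (exact-with-ties is
enumeration-bounded); and the generator's orthogroup labels are not
sequence-based (see above).
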