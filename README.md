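# tmcensus

A comparative census of α-helical transmembrane (TM) proteins in
double-stranded DNA viruses of bacteria and archaea versus their cellular
hosts. Bacteriophages and archaeal viruses typically devote far less of
their proteome to membrane proteins than cells do (< 10 % versus a nearly
constant 20–25 %), almost never encode polytopic proteins with many TM
segments, and break this rule chiefly when their virion carries lipid — an
envelope, an internal lipid core, or an inner membrane vesicle. `tmcensus`
provides the machinery to quantify those contrasts for anyone working with
per-genome protein FASTA files, orthologous gene-family tables (POGs), and
genome metadata:

- a **TM topology predictor**: Kyte–Doolittle sliding-window segment
  calling (window 19, threshold 1.6) with hydrophobic-core trimming,
  positive-inside orientation of the N terminus, and a signal-peptide
  guard — plus a parser for Phobius short-format output so externally
  produced predictions can drive the same census;
- a **per-genome census**: TM counts and fractions, TM-segment-count
  histograms, conservation cross-tabulations, protein-length
  stratification, and redundancy reduction (one representative per group
  of virus genomes sharing ≥ 90 % of genes; largest cellular genome per
  genus);
- the **Viral Quotient** for each gene family,
  `VQ = (f_v + f_p) / (f_v + f_p + f_c)`, where `f_v`, `f_c`, `f_p` are the
  per-genome frequencies of family members among virus genomes, cellular
  genomes, and prophage regions of cellular genomes — 1.0 means seen only
  in lytic viruses, values above 0.5 predominantly viral, below 0.5
  predominantly cellular;
- **group statistics**: point-biserial/Pearson correlation of TM fraction
  with virion lipid association, host domain, or genome size;
  Mann–Whitney–Wilcoxon tests with exact small-sample paths; chi-squared
  comparison of TM-count histograms; orthogroup prediction-consistency
  reports;
- a **seeded synthetic-proteome generator** that plants helices, loop
  charge bias, signal peptides, orthogroup sharing and prophage regions
  with known ground truth, so the entire pipeline runs and is testable
  with no external data.

## Worked example

Simulate 20 virus-like and 6 cell-like genomes, predict topology, and run
the census and the headline comparisons:

```r
library(tmcensus)

spec <- synthetic_spec(seed = 42, n_virus_genomes = 20,
                       n_cellular_genomes = 6)
d    <- generate_synthetic(spec)
pred <- predict_proteome(d$proteins)
pred
#> TM topology set: 2932 proteins, 534 with >=1 TM segment
#> sources: builtin

cen <- genome_census(d$proteins, pred, d$orthogroups)
cen
#> Genome census: 26 genome(s)
#>   total proteins 2932, TM proteins 534 (mean per-genome fraction 0.168)

segment_length_stats(pred)$mean       # characteristic helix length, aa
#> [1] 21.3
```

Virus genomes sit mostly below 10 % TM proteins (median 0.088, range
0.012–0.382 here) while the cellular genomes stay in the narrow 0.21–0.29
band. The genomes that break the viral rule are the lipid-associated ones:

```r
md  <- d$metadata[d$metadata$entity_class == "virus", ]
vc  <- cen[cen$genome_id %in% md$genome_id, ]
lip <- md$genome_id[md$lipid_class %in% c("lipid_associated",
                                          "tentative_lipid")]

tm_correlate(vc, md, "lipid_binary")
#> [1] 0.838
mww_test(vc$tm_fraction[vc$genome_id %in% lip],
         vc$tm_fraction[!vc$genome_id %in% lip])
#> Mann-Whitney-Wilcoxon test (exact): U = 75 (n = 5, m = 15),
#>   two-sided p = 0.000129
```

The virus and host TM-count distributions differ sharply (cells carry the
polytopic tail with its 6- and 12-segment modes):

```r
cc <- cen[!cen$genome_id %in% md$genome_id, ]
chisq_hist_test(aggregate_histogram(vc), aggregate_histogram(cc))
#> Chi-squared homogeneity test: X^2 = 170.2, df = 6 (7 bins), p = 4.108e-34
```

And the Viral Quotient separates gene families by virus specificity:

```r
vq <- vq_table(d$orthogroups, d$proteins, d$metadata, d$prophages)
table(vq$vq_class)
#> predominantly_cellular    predominantly_viral             viral_only
#>                    522                     22                    269
```

`run_pipeline(out_dir, spec)` wires all stages together and writes every
table (census, pooled histograms, VQ, predictions, report) with provenance
headers; reruns with the same seed are byte-identical. See the methods
vignette (`vignettes/tm-census-methods.Rmd`) for the model, parameter
defaults, and design rationale.

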