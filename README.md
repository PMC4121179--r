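# uniparent

Analysis of **uniparental genetic markers** — mitochondrial DNA HVS-I
haplotypes and Y-chromosomal SNP/STR profiles — for human population
genetics. The package implements, as tested reusable code, the full
analysis chain of a classical population survey: who carries which
haplogroup, how diverse each population is, whether its frequency
spectrum signals expansion, how old its clades are, and how populations
relate to each other.

It is written for population geneticists and genetic anthropologists who
have per-sample marker tables (motif strings relative to the rCRS,
hierarchically typed Y-SNP panels, 17-locus Y-filer STR profiles) and
want the standard downstream numbers without stitching together
NETWORK, Arlequin, DnaSP and BATWING.

## What it computes

* **Haplogroup classification** against user-supplied (or bundled)
  haplogroup trees: hierarchical Y-SNP descent with paragroup (`*`)
  calls and conflict detection; mtDNA scoring of HVS-I motifs plus
  coding-region SNPs with ties reported, not broken.
* **Diversity indices**: gene diversity
  H = n/(n−1)·(1 − Σ pᵢ²) with Nei's variance; mean pairwise differences
  π̂ with Tajima's total variance; nucleotide diversity π̂/L;
  polymorphic-site and haplotype counts.
* **Neutrality tests**: Tajima's D; Fu & Li's D, F (outgroup), D*, F*;
  Fu's Fs = ln(S′/(1−S′)) with S′ = Pr(K ≥ k | θ̂, n) under the Ewens
  sampling distribution, computed in log space; coalescent simulation
  p-values conditioned on S.
* **ρ dating**: ρ = mean mutational distance to the clade founder in
  16090–16365, σ_ρ by Saillard's formula, age = ρ × 18,845 years per
  mutation.
* **Median-joining networks** (Bandelt 1999) over binary or STR
  characters, with quasi-medians, ε relaxation, and GML export.
* **Population structure**: haplogroup-frequency PCA; pairwise R_ST
  (Arlequin sum-of-squared-size-differences convention) or haplotype
  F_ST; neighbour-joining trees (via `ape`), newick export.
* **Y-STR coalescent machinery**: genealogy simulation under
  exponential-growth-from-constant demography N(t) = N_anc·e^{α(t_onset−t)},
  single-step STR mutation, the ASD moment estimator, and a
  BATWING-style Bayesian sampler whose TMRCA is the tree height × 25
  years/generation, with EMR/OMRB/OMRS/lmMR mutation-rate calibrations.
* **Synthetic data**: a generator emulating a four-population western
  Sichuan corridor study design (18/16/46/47 males, 46/40/119/192 mtDNA
  samples) so the whole pipeline runs and is tested with no downloads.

## Worked example

```r
library(uniparent)

# synthetic four-population study (stand-in for a deposited dataset)
yd  <- generate_y_dataset(study_design("y"), seed = 7)
cls <- classify_y(yd$profiles, y_panel_tree())
ft  <- frequency_table(cls, populations = c("DB", "DF", "XL", "YJ"))
haplogroup_percent(ft, "D1", "DB")
#> [1] 44.44444

md <- generate_mt_dataset(study_design("mt"), seed = 7)
diversity_table(md$seqs)[, c("population", "N", "h", "S",
                             "haplotype_diversity", "MNPD")]
#>   population   N   h   S haplotype_diversity  MNPD
#> 1         DB  46  37  58              0.9884 5.643
#> 2         DF  40  33  65              0.9897 6.063
#> 3         XL 119  81 108              0.9895 5.712
#> 4         YJ 192 105 128              0.9864 6.181
#> 5     pooled 397 223 231              0.9930 6.012

neutrality_summary(md$seqs, reps = 1000, seed = 7)
#> n=397 S=231 eta=237 pi=6.012 k=223
#> Tajima's D=-2.511  Fs=-433.728  D*=-6.850  F*=-5.386  D=NA  F=NA

founders <- read_founders()
g2a <- md$seqs[md$truth$haplogroup == "G2a"]
rho_date(g2a, founders[["G2a"]], haplogroup = "G2a")
#> G2a: n=18 rho=0.8889 (se 0.2222)  16751 +/- 4188 years BP
```

Reading the output: haplotype diversities near 0.99 with strongly
negative Tajima's D and Fu's Fs are the signature of expanded
populations; each G2a haplotype sits on average 0.89 mutations from the
G2a founder motif, which at 18,845 years/mutation dates the clade's
coalescence to roughly 17 kya ± 4 kya. (The pooled D* / F* here are far
more negative than any per-population value in real surveys — pooling
distinct populations inflates singleton excess; per-population rows are
the meaningful ones.)

A command-line interface covers the same stages
(`classify-y`, `classify-mt`, `diversity`, `neutrality`, `rho-date`,
`network`, `distances`, `pca`, `simulate`), emitting TSV/GML/newick:

```sh
Rscript -e 'uniparent::uniparent_cli()' classify-mt --input motifs.tsv --out calls.tsv
```

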