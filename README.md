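# nimher

Heritability partitioning and fine-mapping of Neanderthal-introgressed
variants (NIMs), with a calibrated synthetic genotype generator for
validating every step against known truth.

## The scientific problem

Variants inherited from Neanderthal introgression segregate at low minor
allele frequency yet sit in unusually strong linkage disequilibrium — each
introgressed haplotype entered the population as one long block. Two
questions about them require methods that respect this structure:

1. **How much trait variance do NIMs explain, and is a NIM worth less than
   a comparable modern-human (MH) SNP?** `nimher` partitions phenotypic
   variance with a multi-component method-of-moments model over
   ancestry × MAF × LD annotation bins,

   *y'K*<sub>k</sub>*y* = Σ<sub>l</sub> σ²<sub>l</sub> tr(*K*<sub>k</sub>*K*<sub>l</sub>) + σ²<sub>e</sub> tr(*K*<sub>k</sub>),  *K*<sub>k</sub> = *W*<sub>k</sub>*W*<sub>k</sub>ᵀ/*M*<sub>k</sub>,

   aggregates ĥ²‍_NIM = Σ<sub>NIM bins</sub> ĥ²<sub>k</sub>, forms the
   MAF/LD-matched background ĥ²_MH = Σ (*M*<sub>NIM,i</sub>/*M*<sub>MH,i</sub>) ĥ²<sub>MH,i</sub>,
   and tests Δh² = ĥ²_NIM − ĥ²_MH (negative = depletion) with
   delete-one-block jackknife standard errors (100 contiguous SNP blocks,
   covariances between annotation aggregates propagated).

2. **Which regions harbour introgressed alleles that actually modulate the
   trait?** A significant NIM may merely tag a causal MH variant. The
   credible-NIM pipeline LD-prunes significant NIMs, fine-maps each 200 kb
   window with a sum-of-single-effects regression (L = 10, coverage 0.95),
   unions credible sets, drops majority-MH unions, merges overlapping
   windows, and reports credible NIM regions with a false-discovery-
   proportion evaluation against simulation truth.

Supporting modules: a block-introgression genotype simulator calibrated to
the observed NIM/MH MAF and LD-score contrasts, the additive phenotype
model with MAF/LD-coupled architectures, QC + HWE exact test + windowed LD
scores + NIM set expansion, DerSimonian–Laird random-effects meta-analysis,
NIM principal components, greedy tag-SNP array design, and PLINK1
bed/bim/fam I/O.

## Worked example

```r
library(nimher)
panel <- preparePanel(panelConfig(seed = 42))   # simulate + QC + LD scores
panel
#> NimPanel: 19561 variants x 2000 individuals
#>   NIM: 4761  MH: 14800  QC-pass: 19431
#>   mean LD score (NIM / MH): 170.7 / 62.4
#>   haplotypes: absent
```

The generated classes reproduce the introgression contrasts (mean NIM MAF
0.040 vs target 0.039; mean NIM LD score 170.7 vs 170.6). Simulate a
phenotype under the RARE architecture and estimate the components:

```r
prt <- buildPartition(panel, c(maf = 5, ld = 5), dropUnmatched = TRUE)
causal <- selectCausalVariants(panel, architectureSpec("RARE", 25, 0.5), seed = 1)
truth <- simulatePhenotype(panel, causal, h2 = 0.5, seed = 2)
truth
#> PhenotypeTruth: n = 2000, 25 causal variants, true h2 = 0.5, true h2_NIM = 0.165

estimateComponents(truth@y, panel, prt, mode = "exact")
#> ComponentEstimates (31 bins)
#>   h2 total      0.3877 (se 0.1131)
#>   h2 NIM        0.0667 (se 0.0493)  Z(=0) 1.35
#>   h2 MH matched 0.5124 (se 1.0398)
#>   delta h2      -0.4456 (se 1.0404)  Z(=0) -0.43, p 0.668
```

One draw of 25 causal variants is noisy at n = 2,000 — the 60-simulation
suite (`runCalibrationStudy()`) is what shows the estimator calibrated.
Association plus fine-mapping on the same phenotype:

```r
assoc <- clumpAssociations(gwasLinear(truth@y, panel), panel)
assoc
#> AssocResult: 4643 variants tested, 601 significant at p < 1.08e-05
#>   3 clumps
fm <- fineMapRegions(truth@y, panel, assoc)
evaluateFdp(fm$regions, truth, panel)[c("fdp", "tp", "fp")]
#> $fdp [1] 0   $tp [1] 3   $fp [1] 0
```

All three credible NIM regions contain a truly causal NIM: the pipeline
localized every signal to its introgressed block.

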