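# mirdep

Quantifying how much of an activation-induced gene-expression signature
depends on a microRNA, by contrasting wild-type (WT) and knockout (KO)
genotypes — and discovering candidate microRNA targets via repression,
re-induction and inverse-correlation screens.

## The scientific problem

Inflammatory (M1) macrophage activation induces a large transcriptional
signature, and microRNAs such as miR-155 are among its strongest-induced
regulators. Given log2 expression matrices for a genotype × condition
design (WT/KO × M0/M1, a few replicates per group), `mirdep` answers:

1. **Which genes respond to activation?** Per-probe linear fold change
   `FC = 2^(Δ log2 mean)`, pooled-variance two-tailed t-tests, and
   Benjamini–Hochberg adjustment define an up (`FC ≥ 2, p < 0.05`) and a
   down (`FC ≤ 0.5`) signature.
2. **How much of that signature needs the microRNA?** Each WT signature
   gene is labelled by its KO behaviour: *dependent* (KO fold change
   strictly inside the 2-fold band — response lost), *attenuated*
   (still beyond the band but blunted, `FC_KO/FC_WT < 1` for up genes),
   or *independent*. Percentages are reported per direction and pooled.
   A power-law trend `FC_KO = a · FC_WT^b` fitted on the log–log scale
   summarizes the genome-wide dampening (`b = 1` means responses are
   preserved; `b < 1` means graded attenuation).
3. **Which repressed genes look like direct targets?** A canonical
   seed-site 3'UTR scanner (8mer / 7mer-m8 / 7mer-A1 / 6mer against miRNA
   nucleotides 2–8) or a user list defines the universe; genes repressed
   in WT activation, re-induced in KO-M1 vs WT-M1 (top set: `FC ≥ 2`),
   and inversely Pearson-correlated with microRNA expression across all
   samples form the ranked target report.

Hierarchical clustering of samples on a dependent-gene/target panel
(correlation distance, average linkage), ΔΔCt and standard-curve qPCR
quantification, and a synthetic-data generator with exact planted truth
complete the pipeline. Everything is driven by explicit thresholds and
seeds; the orchestrated run writes a reproducibility manifest.

## Worked example

A full synthetic study at the package defaults (10,000 probes, 3/3/3/2
samples, half the planted signature microRNA-dependent, attenuation
exponent 0.6):

```r
library(mirdep)

gen   <- generate_expression(generator_params(seed = 1))
fc_wt <- contrast(gen$matrix, "WT_M1", "WT_M0")
fc_ko <- contrast(gen$matrix, "KO_M1", "KO_M0")

sig <- call_signature(fc_wt)
#> signature from WT_M1_vs_WT_M0: 500 up (FC >= 2), 529 down (FC <= 0.5), adjusted p < 0.05

part <- classify_dependency(sig, fc_wt, fc_ko)
#> dependency partition: 500 up + 529 down signature genes
#>   dependent 537 | attenuated 492 | independent 0
#>   % dependent: up 50.2, down 54.1, overall 52.2

responding <- part$label != "dependent"
fit_fcfc_trend(part$fc_wt[responding], part$fc_ko[responding])
#> power-law trend: y = 1.008 * x^0.6033 (R^2 = 0.987, n = 492)
```

Reading the numbers: 500 up and 529 down probes are called into the WT M1
signature; 50.2% of the up signature falls inside the 2-fold band in the
knockout (the planted truth is 50%), the down percentage is a little
higher because the 30 planted direct targets behave as fully dependent
repression; and the genes that still respond do so with an attenuation
exponent of 0.60 (planted: 0.6) — a gene induced 100-fold in WT is
induced only about `100^0.6 ≈ 16`-fold in the KO.

The bundled published target-screen table is re-analysed in one call:

```r
build_target_report(published_target_screen())
#> target report: 18 genes, 16 significantly correlated at p < 0.05
#>    gene     r    p_r fc_wt   p_wt fc_cross p_cross fc_ko  p_ko significant
#> 1  Bat5 -0.96 0.0001  0.51 0.0027     2.07  0.0015  1.10 0.261        TRUE
#> 2  Mafb -0.95 0.0001  0.37 0.0001     2.37  0.0385  0.91 0.599        TRUE
#> ...
```

The whole pipeline (contrasts → signature → dependency → target screen →
clustering → report bundle + manifest) runs from one config:

```r
run_pipeline(list(seed = 7), out_dir = "results/run1")
```

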