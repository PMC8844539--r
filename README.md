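# proxiglyco

Identification of lectin counter-receptors from proximity-labelling
quantitative proteomics, with companion glycomics mass annotation.

## What it is for

Proximity labelling couples a lectin bait (e.g. Siglec-1/CD169) to
horseradish peroxidase so that biotin radicals tag the membrane
glycoproteins in the bait's immediate vicinity; label-free quantification
(LFQ) against a non-binding mutant control then turns "which glycoproteins
does the lectin engage?" into a fold-change filtering problem. This package
is for proteomics analysts who have such bait/control LFQ tables (the shape
of a MaxQuant `proteinGroups` export) and want a reproducible,
fully-audited version of the standard four-stage filtration, plus the
downstream characterization and the permethylated-glycan MALDI-TOF
annotation that accompany this kind of study.

## The method

For each labelling dataset *d* (one bait sample, one control sample) and
protein *i*:

```
log2FC_id = log2(bait_id / control_id)        (missing side imputed at the
                                               sample's 1st-percentile noise floor)
```

1. **Tail assessment** — a dataset is retained iff its membrane proteins
   are hypergeometrically over-represented above the 0.99 quantile of the
   *non-membrane* log2FC distribution (≥ 20 membrane proteins above, p <
   0.01): the "proximity labelling tail".
2. **Paired-t volcano** — per protein, `t = mean(x)/(sd(x)/√n)` over the
   retained datasets, two-sided p on n−1 df, BH q values; selection at
   p < 0.05 and mean log2FC > 1, enrichment side only.
3. **Annotation filter** — keep plasma-membrane proteins with ≥ 1 predicted
   N-glycosylation sequon (N-X-S/T, X ≠ P).
4. **Back-mapping** — remove any candidate falling below the tail cutoff in
   any retained dataset where it was observed.

Glycan masses are monoisotopic [M+Na]+ values of permethylated glycans,
built from elemental residue formulas (Hex C9H16O5, HexNAc C11H19NO5, dHex
C8H14O4, NeuAc C16H27NO8, NeuGc C17H29NO9) plus the permethylated reducing
end (C2H6O) and the sodium cation. Copy numbers per cell use the histone
ruler: `copies = (I / ΣI_histone) × m_DNA × N_A / MW`.

## Worked example

```r
library(proxiglyco)

# a synthetic experiment with known ground truth: 2000 proteins,
# 50 spiked counter-receptors, 3 replicates x 2 multimer formats
ex <- generate_experiment(sim_config(seed = 42))
report <- run_pipeline(ex$quant, ex$design, ex$annotation)
print(report)
#> counter_receptor_report
#>   datasets retained: 6 of 6
#>   proteins tested:   1948
#>   significant:       52
#>   annotation-passed: 49
#>   final set:         7
length(intersect(report$final_set, ex$truth$spiked_ids))
#> [1] 7
```

All six datasets show a proximity labelling tail (e.g. dataset 1: cutoff
1.92, 45 membrane proteins above it, enrichment p = 1.6e-13); the volcano
stage selects 52 proteins of which 48 are spiked truth; the final set after
strict back-mapping contains 7 proteins, all true spikes — the all-datasets
back-mapping rule trades sensitivity for an essentially zero false-discovery
proportion (see the methods vignette for measured operating
characteristics). The audit trail in `report$audit` records exactly one
removal reason per excluded protein.

Glycan annotation:

```r
nominal_mz("Hex3HexNAc1NeuAc1")      # NeuAc-capped GM1b glycan
#> [1] 1288
nominal_mz("Hex3HexNAc1NeuGc1")      # its NeuGc counterpart, +CH2O
#> [1] 1318
counter_receptor_fraction(sprintf("M%03d", 1:49), sprintf("M%03d", 1:943))
#> [1] 5.2
```

A thin command-line wrapper ships at
`inst/scripts/proxiglyco.R` with subcommands `simulate`, `filter`,
`characterize`, `glyco-annotate` and `mz`.

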