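# hmucall

Single-base resolution calling of 5-hydroxymethyluracil (5hmU) from
chemical-conversion sequencing data.

5hmU is an oxidised thymine base found in a range of genomes, notably in
trypanosomatid parasites. It can be located at single-base resolution by
oxidising 5hmU to 5-formyluracil (5fU): ionised 5fU base-pairs with G
during polymerase extension, so molecules carrying 5hmU read out as **C
instead of T** after PCR and sequencing. A matched **no-oxidation
control** library separates true 5hmU signal from pre-existing mutations
and damage.

`hmucall` is the analysis toolkit for this assay, aimed at people
developing or benchmarking conversion-based base-modification callers:

* **Simulation** — generative model of converted reads/counts with
  empirically characterised rates (treated conversion ≈ 39% / 30% C at
  fully modified sites, 1.4% background, ≈ 2.2–2.7% in the control), the
  three synthetic oligonucleotide designs (fully modified ODN1, 0–26%
  titration ODN2, all 16 N1-5hmU-N2 contexts ODN3), FASTQ emission with
  ground-truth BED (`make_odn()`, `simulate_counts()`, `emit_fastq()`).
* **Pileup & signal** — positional amplicon pileup and the per-site
  statistics %T, %C, %other and %C/(C+T) with replicate aggregation
  (`count_bases()`, `site_signal()`, `aggregate_replicates()`).
* **Calling** — per-site one-sided Fisher's exact test of the treated
  arm against the control on pooled counts,

  ```
  p = P(X >= n_C^treated),  X ~ Hypergeom over [[n_C^tr, n_T^tr], [n_C^ctl, n_T^ctl]]
  ```

  with Benjamini–Hochberg FDR control (significant at q < 0.1 by
  default), pseudocounted fold change, and an exact Wilcoxon rank-sum
  test (midrank ties, full enumeration for small groups) for
  replicate-level amplicon comparisons (`call_sites()`, `site_test()`,
  `replicate_rank_test()`).
* **Detection limits & context** — incorporation-level titrations at
  fixed coverage with a fold-change + FDR detection rule, and the
  16-context sequence-bias analysis (`titrate()`,
  `detection_limit_scan()`, `context_signal()`).
* **Overlap testing** — permutation significance of overlap between
  called single-base sites and region sets, with the null drawn from
  candidate T positions (`permutation_pvalue()`).

See `vignettes/hmucall-methods.Rmd` for the model, assumptions, and the
reasoning behind the statistical choices.

## Worked example

Simulate the fully modified two-site amplicon in triplicate at 5000x,
in both arms, and call sites against the control:

```r
library(hmucall)

odn    <- make_odn("ODN1", seed = 1)
models <- list(conversion_preset("ODN1_site1"), conversion_preset("ODN1_site2"))
treated <- simulate_counts(odn$reference, odn$profile, models,
                           depth = 5000, replicates = 3,
                           condition = "treated", seed = 1)
control <- simulate_counts(odn$reference, odn$profile, models,
                           depth = 5000, replicates = 3,
                           condition = "control", seed = 1)

agg <- aggregate_replicates(site_signal(treated))
subset(agg, pos0 %in% odn$profile$pos0,
       c(pos0, mean_pct_T, mean_pct_C, mean_pct_other, sd_pct_C))
#>   pos0 mean_pct_T mean_pct_C mean_pct_other sd_pct_C
#> 3   23      0.511      0.391         0.0984  0.00780
#> 7   55      0.657      0.299         0.0439  0.00779
```

The two modified sites read out ≈ 39% and 30% C (triplicate mean ± SD),
against a 1.4% background at the seven unmodified Ts. Calling against
the no-oxidation control flags exactly the two planted sites:

```r
subset(call_sites(treated, control, fdr = 0.1, min_depth = 100), significant)
#>             ref pos0 refbase strand n_C_treated n_T_treated n_C_control
#> 3 ODN1_amplicon   23       T      +        5860        7664         353
#> 7 ODN1_amplicon   55       T      +        4491        9851         403
#>   ... p_value q_value fold_change significant
#> 3 ...       0       0        18.3        TRUE
#> 7 ...       0       0        11.5        TRUE
```

At replicate level, the modified site's %C separates completely from the
proximal unmodified Ts:

```r
sig <- site_signal(treated)
replicate_rank_test(subset(sig, pos0 == 23)$pct_C,
                    subset(sig, !pos0 %in% odn$profile$pos0)$pct_C,
                    alternative = "greater")$p_value
#> [1] 0.003328009
```

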