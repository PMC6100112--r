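---
title: "Calling 5-hydroxymethyluracil at single-base resolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling 5-hydroxymethyluracil at single-base resolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmucall)
```

## The assay and its generative model

5-hydroxymethyluracil (5hmU) is an oxidised form of thymine found in a
range of genomes, most prominently in trypanosomatid parasites. It can be
sequenced at single-base resolution by chemistry: oxidation (KRuO4)
converts 5hmU to 5-formyluracil (5fU), whose ionised form base-pairs with
G during a polymerase extension step, so that molecules carrying 5hmU read
out as **C instead of T** after PCR and Illumina sequencing. Because
T-to-C changes can also arise from pre-existing mutations or unrelated
damage, every treated library is paired with a **no-oxidation control**
prepared identically except for the conversion step; real 5hmU gives a C
signal only in the treated arm.

`hmucall` implements the computational side of this assay. Its simulator
reduces the chemistry to per-site readout rates, collected in a
`conversion_model`:

| rate | meaning | default |
|------|---------|---------|
| `p_conv` | P(read shows C) at a fully modified site, treated | 0.394 (site 1) / 0.303 (site 2) |
| `p_other_mod` | P(non-T, non-C event) at a modified site, treated | 0.099 / 0.046 |
| `p_bg_c` | background C rate at unmodified T, any arm | 0.014 |
| `p_bg_other` | background other-event rate at unmodified T | 0.004 |
| `p_ctrl_c` | C rate at a modified site in the control | 0.022 / 0.027 |
| `p_ctrl_other` | other-event rate at a modified site, control | 0.005 / 0.013 |

The two presets (`conversion_preset("ODN1_site1")`, `"ODN1_site2"`) carry
the empirical triplicate readout rates of the two 5hmU sites of the fully
modified synthetic amplicon at >1000x depth. Two of the "other"-event
rates are only bounded (< 1%) in the characterisation data rather than
printed; we fixed `p_bg_other = 0.004` and the site-1 control other rate
at 0.005, i.e. mid-range values consistent with those bounds, and we use
one background C rate (1.4%) for both arms. These choices only affect the
simulated "other" channel and background, neither of which enters the
C-versus-T test statistic directly.

A site with **incorporation level** $L \in [0,1]$ (the fraction of
molecules modified, as in a spike-in titration) converts at the mixed rate

$$p_C(L) = L\,p_\mathrm{conv} + (1-L)\,p_\mathrm{bg}$$

and analogously for the other-event channel. Per-read outcomes are
independent across reads and positions, so each site x replicate is one
trinomial draw of size `depth` (`simulate_counts()`); coverage is fixed by
default, with a Poisson mode for more realistic depth variation. This
reproduces the marginal per-site statistics of converted sequencing data.
What it deliberately does **not** model: PCR duplicate structure,
sequencing-quality and alignment error, strand-specific artefacts, and
context-dependent chemistry (unless injected explicitly, see below). Tests
passing on these simulations therefore validate the statistical machinery
at the characterised rates, not robustness to alignment or library
artefacts in real data.

## Synthetic oligonucleotide designs

`make_odn()` generates the three amplicon designs used to characterise
such an assay, with documented seeds. The literal laboratory
oligonucleotide sequences are not part of the package; the generated
references are structural analogues that preserve everything the analysis
consumes — site counts, context coverage and level ranges:

* **ODN1** — 80 nt, two fully modified 5hmU sites, exactly seven
  unmodified Ts (non-T positions are drawn from A/C/G so the T census is
  by construction);
* **ODN2** — the same backbone with two sites at sub-stoichiometric levels
  (defaults 0.26 and 0.13, spanning the 0–26% titration range);
* **ODN3** — sixteen 41-nt variants realising every N1-5hmU-N2
  trinucleotide context exactly once around a central modified T.

Reverse-strand sites are represented as A positions whose converted
readout is G in forward-read coordinates, by complementarity.
`emit_fastq()` materialises a count table as full-length reads (constant
placeholder qualities), assigning exactly `n_C` reads the converted base
at each site, so simulator counts and a pileup of the emitted FASTQ agree
*exactly* — an identity the test suite exploits as a round-trip check.
"Other" events are written as G (C at reverse-strand sites): the analysis
only ever uses the three-way T/C/other split, so the specific base is
immaterial.

## From reads to signal

`count_bases()` performs a positional amplicon pileup (every read
full-length, no indel handling; mismatched-length reads are dropped and
counted). `site_signal()` converts counts to the per-site statistics
%T, %C, %other — proportions over all retained reads — and the
conversion signal

$$\%C/(C{+}T) = \frac{n_C}{n_C + n_T},$$

which ignores the other-event channel and is the quantity tracked in
titrations. Zero-depth sites are flagged missing rather than erroring;
`aggregate_replicates()` reports mean and sample SD (n−1) across
technical replicates. Genome-scale data enter as pre-computed per-site
count TSVs: read alignment is a solved problem and out of scope here.
Downstream analysis applies a minimum-depth screen (default 100; the
amplicon characterisation used >1000x, and the default is deliberately
permissive for genome-mode data — it is exposed everywhere as
`min_depth`).

## Calling sites against the no-oxidation control

For each T site, replicates are pooled by summing counts and the treated
arm is compared to the control with a **one-sided Fisher's exact test**
on

$$\begin{pmatrix} n_C^{treat} & n_T^{treat} \\ n_C^{ctrl} & n_T^{ctrl} \end{pmatrix},$$

alternative: C excess in the treated arm (`site_test()`, computed as the
exact hypergeometric tail). The per-site test behind published FDR-based
5hmU site lists is not specified in the primary text we base the design
on; Fisher's exact test is our choice, made for exactness at low depth,
one-sided because the chemistry predicts the direction, and it is kept
behind a small pluggable surface. P-values are adjusted by
Benjamini–Hochberg (`bh_fdr()`, delegating to `stats::p.adjust`) and
sites are flagged at `q < 0.1` by default, matching the FDR < 0.1
convention for genome-mode site lists. An effect-size companion,
`fold_change()`, compares the pseudocounted conversion signals
($\psi = 0.5$ guards division by zero at clean control sites).

Two test granularities coexist deliberately: genome-mode calling pools
replicates (maximising per-site power), while the amplicon-style analysis
keeps replicates separate and uses `replicate_rank_test()` — a Wilcoxon
rank-sum test of the modified site's per-replicate %C against the
proximal unmodified Ts. For both groups up to 12 values the p-value is
**exact including ties**: midranks are doubled to integers and the
rank-sum distribution is enumerated by dynamic programming over subset
sums (base R's `wilcox.test` has no exact-with-ties mode); larger samples
fall back to the tie-corrected normal approximation. The two-sided
p-value doubles the smaller tail, capped at 1 — e.g. complete separation
of 3 versus 7 values gives exactly $1/\binom{10}{3} = 1/120$ one-sided.

Degenerate inputs are resolved by convention: an all-zero 2x2 table gives
p = 1; identical constant groups give p = 1; BH of an empty vector is
empty.

## Titration, detection limit, context

`titrate()` simulates a single site over a level series (default 0–0.26
in steps of 0.01) at fixed coverage (default 100x) with triplicates in
both arms, and applies a two-part **detection rule**: pseudocounted fold
change over the control > 2 *and* BH-adjusted exact-test q < 0.1
(adjustment across the series). The supplementary fold-change rule behind
the published 15% detection-limit figure is not reproduced verbatim in
the text we work from; both thresholds are therefore parameters, with the
stated defaults. The detection limit — the smallest detected level — is a
stochastic quantity at 100x, so `detection_limit_scan()` reports its
distribution over independent runs and summarises it by the mode
(smallest level among modal ties). One consequence worth knowing: because
the BH adjustment is shared across the series, a null (level-0) point can
occasionally ride on the many true positives and be flagged; the suite
bounds the rate of such events rather than pretending they cannot occur.
Expected signal is affine in level up to a mild denominator effect from
the other-event channel, so the least-squares fit reported by `titrate()`
attains $r^2 > 0.99$ at high depth.

`simulate_context()` / `context_signal()` run the 16-context experiment:
per-context conversion signal in both arms and the same detection rule
(BH across 16 contexts). Context bias is injected, when wanted, as a
multiplier on `p_conv` per context; because the signal denominator
$1 - p_\mathrm{other}$ does not involve `p_conv`, an injected multiplier
is recovered as the same multiple of the context's signal, which the
tests verify to within sampling error.

## Overlap of called sites with enrichment regions

`permutation_pvalue()` asks whether single-base calls fall inside a
region set (e.g. peaks from chemical-enrichment mapping) more often than
chance. The null redraws the same number of sites uniformly **from the
candidate T positions** of the reference — calls can only occur at Ts, so
shuffling over all bases would overstate significance; alternative nulls
were considered and rejected as the default for that reason. Regions are
merged first (no double counting), the alternative is one-sided
enrichment, and the estimator uses the add-one correction
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$,
so $p \ge 1/(1+n_\mathrm{perm})$ and reported significance is never an
artefact of too few permutations. Under uniform sampling the null overlap
count is hypergeometric, which provides a closed-form oracle the test
suite compares against at small candidate counts.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally and in all BED output;
  TSV interchange keeps the same convention in a `pos0` column.
* **Randomness**: every user-facing function takes a `seed`; child seeds
  for stages and iterations are derived deterministically, so a pipeline
  run is reproducible bit-for-bit from one integer. Global RNG state is
  left untouched (`withr::with_seed`).
* **Trinomial sampling** is vectorised as two sequential binomials
  (exactly the conditional decomposition of the multinomial), keeping
  genome-scale simulation fast in plain R.
* **Depth screens**: `min_depth` applies to pooled per-arm depth in
  `call_sites()`.
* **Problem sizes in the suite**: the test and acceptance simulations use
  triplicates at 5000x for amplicon rate recovery, 200 runs of the 100x
  titration, 100 simulated ~40 kb chromosomes (~10,000 Ts, 10 planted
  sites) for false-discovery calibration, and 1e5 permutations against a
  200-candidate hypergeometric oracle — sizes chosen so Monte-Carlo error
  is small relative to the tolerances being asserted while the whole
  suite runs in about a minute.

## Limitations

* Rates are collapsed per site; polymerase identity, dNTP balance and
  oxidation kinetics enter only through their effect on the preset rates.
* The simulator's independence assumptions mean FDR calibration results
  transfer to real data only to the extent that per-read conversion noise is
  independent; clustered errors (PCR duplicates) would require the
  Poisson-depth mode plus external duplicate handling.
* Absolute 5hmU stoichiometry is not estimated: %C/(C+T) is a signal, not
  a level, because conversion is incomplete (~39% at full modification).
* Real-genome reproduction (alignment, published site lists and their
  overlap p-values) requires the original sequencing data and reference
  genome and is outside the package's scope; the package validates the
  machinery on synthetic data with known truth instead.
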