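---
title: "Methods: count-based methylation profiling with mcseedr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: count-based methylation profiling with mcseedr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcseedr)
```

# The readout model

Methylation-content-sensitive enzyme ddRAD (MCSeEd-class) assays digest
genomic DNA with a methylation-sensitive enzyme (here AciI by default)
paired with an insensitive companion (MseI), size-select fragments carrying
one terminus of each enzyme, and sequence them. Because cytosine methylation
blocks the sensitive cut, the read count at a cut-site locus reports the
*unmethylated* fraction of the molecules in the sample:

$$\mathbb{E}[c_{ij}] = s_j \, a_i \, (1 - m_{ij})$$

where $s_j$ is the library scale of sample $j$, $a_i$ a locus-specific
capture propensity, and $m_{ij} \in [0,1]$ the methylation level. This sign
convention (counts decrease as methylation increases) is fixed across the
whole package: the synthetic generator produces counts from exactly this
law, and the estimation stage inverts it, so the two halves are consistent
by construction.

# Pipeline stages and their parameters

1. **In-silico digestion and enzyme ranking** (`find_sites`,
   `double_digest`, `select_fragments`, `rank_enzymes`). Recognition sites
   are matched with IUPAC-aware patterns on both strands (non-palindromic
   enzymes such as AciI are scanned on the reverse strand with the mirrored
   cut offset). Matches containing `N` never count. Cleavage is modeled as
   a single forward-axis coordinate — sufficient for fragment-length
   distributions, which is all that enzyme ranking needs. The default
   size-selection window is 200–700 bp with mixed ends required (the
   ddRAD-capturable configuration); whether a plain size filter without the
   mixed-end requirement is wanted is exposed as `require_mixed_ends`.
   Enzyme chemistry lives in an editable TSV registry
   (`inst/extdata/enzymes.tsv`); cut offsets move fragment boundaries by at
   most a few bp and never change counts.

   One geometric consequence of the single-coordinate cut model is worth
   stating: for a palindromic enzyme cut off-centre (MseI, T^TAA, offset
   1), reflecting a sequence moves every cut by $k - 2\cdot\text{offset} =
   2$ bp, so reverse-complement digestion mirrors fragment-length multisets
   only up to that shift (exactly, for AciI, whose reverse-strand matches
   already use the mirrored offset). The tests assert the exact per-enzyme
   mirror laws rather than naive multiset equality.

2. **Count matrix, standardization, filter** (`assemble_counts`,
   `normalize_libraries`, `filter_coverage`). Per-sample locus counts are
   unioned (absent = 0) and sorted. Standardization rescales each sample to
   the median library total (robust to a few deep libraries; counts per
   million available as `"cpm"`). The coverage filter keeps loci with at
   least `min_reads = 10` *normalized* reads in every sample — the assay's
   conventional registry filter, applied after standardization following
   the pipeline's step ordering. An alternative `"per-comparison"` scope
   restricts the requirement to the two groups being compared.

   Standardization by library totals assumes differential loci are a small
   minority; a genome-wide shift in methylation changes the totals
   themselves and is partially absorbed into the scale factors (the
   classic composition effect — same caveat as for expression data).

3. **Relative methylation** (`relative_methylation`). The assay has no
   absolute methylation scale, so the most-cut sample of each locus anchors
   it: with $M_i = \max_j \tilde c_{ij}$ (normalized counts),

   $$\hat m_{ij} = 1 - \tilde c_{ij} / M_i,$$

   effective coverage $\mathrm{round}(M_i)$, and integer pseudo
   methylated/unmethylated counts (`round half-up`, because the logistic
   test needs integer trials). Two documented consequences: every locus has
   at least one sample at estimated methylation 0, and the anchor is the
   *maximum* of noisy counts, so estimates are biased upward by roughly
   $\mathbb{E}[\max z] \times \mathrm{CV}(c) \approx 1.7\sqrt{1/\mu + \phi}$
   — about 0.06 at coverage 400 and Poisson noise, but 0.2–0.3 at coverage
   200 with dispersion 0.05. A locus uniformly methylated across samples is
   invisible by construction; only within-locus contrast is measurable.
   The transform is a declared stand-in for the assay's unpublished
   reference implementation and is isolated behind
   `relative_methylation()` so it can be swapped.

4. **DMP testing** (`test_locus`, `call_dmps`, `adjust_fdr`). Binomial
   logistic regression of methylation proportion on the group indicator
   with coverage weights, evaluated as the 1-df likelihood-ratio test
   against the intercept-only model. With equal trials per sample within a
   locus, the group-pooled proportions are the MLE, so the test reduces to
   a closed form on sufficient statistics — vectorized over loci and
   verified against an explicit `glm()` fit in the tests. FDR control is
   Benjamini–Hochberg (the conventional choice; Bonferroni available), and
   the effect-size filter defaults to 25 percentage points, configurable
   down to 0. Direction `"methylated"` means higher methylation at the
   *later* timepoint of a comparison named `T30_vs_T0` and so on.

   **Calibration caveat (important).** The pseudo-binomial construction
   treats $M_i$ as a real number of trials, but the underlying counts are
   negative-binomial/Poisson. The variance of an estimated proportion is
   $\mu/M^2$ (count noise) rather than the binomial
   $\mu(M-\mu)/M^3$, inflating the likelihood-ratio statistic by roughly
   $M/(M-\mu)$ — and the coverage filter makes this worse, because
   surviving loci have every count within a small factor of the rowmax.
   On null simulations at coverage 30 the empirical type-I error at
   $\alpha = 0.05$ is 0.1–0.5 depending on the baseline law, never the
   nominal 0.05. No overdispersion correction is applied (deliberately
   mirroring the default behavior of the count-to-methylKit adaptation
   this stage re-implements); the corresponding calibration benchmark in
   `test-acceptance.R` is left failing rather than papered over, and raw
   p-values from this stage should be read as scores, not probabilities.
   The effect-size threshold and BH step are what keep the null DMR count
   near zero in practice.

5. **DMR calling with window-width optimization** (`tile_windows`,
   `call_dmrs_at_width`, `optimize_width`). Each chromosome is tiled with
   adjacent non-overlapping windows anchored at coordinate 0 (the anchor is
   exposed as `phase`); a window becomes a DMR when its majority direction
   holds at least two significant, concordant DMPs. Exact direction ties
   with both sides at two or more are skipped and logged — the source
   procedure never mentions mixed windows, so the conservative choice is to
   call nothing. The width grid is 100–2000 bp in 100 bp steps; the chosen
   width maximizes the DMR count per comparison (the source reports
   distinct optimal widths per comparison), with ties broken toward the
   smallest width and flagged. DMR boundaries are tile boundaries; the
   member-DMP span is reported alongside.

6. **Gene assignment** (`load_annotation`, `regulatory_interval`,
   `intersect_dmrs`, `gene_table`). GFF3 gene features (1-based inclusive)
   are converted to 0-based half-open; BED is taken as-is. The regulatory
   region is the 2.5 kb extension at the transcription-orientation 5' end:
   upstream of the start for `+` genes and beyond the higher-coordinate end
   for `-` genes — the promoter-symmetric reading, which is the only
   biologically coherent interpretation of a strand-aware extension rule.
   A 1 bp overlap suffices (`min_overlap` configurable); a DMR touching
   both body and regulatory region of a gene is reported once as `body`.
   Genes hit in both directions within a comparison are `"mixed"`: counted
   in gene totals, excluded from the direction columns.

7. **Downstream** (`classify_response`, `enrich_terms`, `delta_delta_ct`,
   `test_expression`, `agreement`). Response classes over the three
   pairwise gene lists:
   early $= G_{30,0} \setminus G_{90,0}$;
   mid $= (G_{90,0} \cap G_{90,30}) \setminus G_{30,0}$;
   continuous $= G_{90,0} \setminus (\text{early} \cup \text{mid})$.
   Early/mid/continuous are pairwise disjoint by construction. Term
   enrichment is an exact hypergeometric upper tail per term; the
   two-independent-tools consensus idea is emulated by requiring
   significance under *both* BH and Bonferroni on this single exact test —
   a stand-in, not a reproduction of any graph-based GO tool (no DAG
   propagation, no term grouping). qPCR relative expression is
   $2^{-\Delta\Delta C_t}$ against the mean of two reference genes (SDHA,
   HPRT — the standard equine blood references) and a calibrator
   timepoint; significance is one-way ANOVA on $\log_2$ expression gated
   ahead of pairwise Welch tests with Holm correction. A bulk-level random
   effect is not estimable with one observation per bulk and timepoint
   without an assumed covariance structure, so the model is deliberately
   fixed-effects; this is recorded in the output metadata of the CLI.
   Agreement between methylation and expression outcomes is filled only
   when both are significant: `"Yes"` for the canonical inverse pairs
   (de-methylation with up-regulation, methylation with down-regulation),
   `"No"` otherwise, blank when either side is N.S.

# The synthetic world

The generator exists so every stage has a truth-labeled input. Its stated
world, chosen once:

* **Design**: 5 bulks × 3 timepoints (T0/T30/T90), the bulked time-course
  layout of the assay's reference deployment. Bulks are simulated
  independent within timepoint even though real bulks are the same pools
  resampled over time; the inferential model downstream is likewise
  unpaired, so the generator does not model within-bulk temporal
  correlation (a documented mismatch with reality that makes the test
  slightly conservative for paired designs).
* **Genome**: random nucleotide chromosomes with recognition sites
  *planted* at the requested density and chance occurrences scrubbed, so
  the locus registry is exactly the planted set. Site planting uses exact
  uniform placement with minimum separation; over-dense requests fail with
  a capacity message.
* **Baseline methylation**: per locus and bulk, $m \sim \mathrm{Beta}(2,2)$
  — partially methylated loci, the only regime a cut-count assay can
  report on (fully methylated sites yield no reads and never enter a
  registry). The baseline is drawn once per bulk and shared across
  timepoints.
* **Differential loci**: grouped in clusters (default 3 loci within
  400 bp) shifted by $\pm\Delta$ from a configured onset timepoint onward,
  truncated to $[0,1]$. Directions are conditional on the baseline:
  gaining clusters start at $\mathrm{Beta}(2,18)$ (mean 0.1) and losing
  clusters at that law plus $\Delta$, mirror trajectories both observable
  by the assay — planting a 0.5 loss on a 0.1-methylated locus would be
  physically meaningless.
* **Counts**: negative-binomial with dispersion $\phi = 0.02$ (bulk
  pooling averages biological variability; $\phi = 0$ recovers Poisson)
  and locus propensities $\mathrm{Gamma}(25, 25)$ (CV 0.2: a registry
  conditioned on an absolute per-sample read floor cannot contain loci
  with several-fold capture-efficiency spread).

What a green end-to-end test establishes: the pipeline recovers planted,
clustered, moderately sized methylation changes from count data generated
under its own readout assumption, and stays near-silent under the null.
What it does not establish: calibrated per-locus error rates (see the
caveat above), behavior under paired designs, real genome composition
(repeats, CpG islands, chance restriction sites), mapping artifacts, or
anything about reads themselves (no FASTQ is simulated).

A quantitative note on the end-to-end benchmark: with coverage ≈ 50, a
$\Delta = 0.5$ shift parks a locus at mean ~20–25 reads in 5–10 of the 15
samples, directly against the all-samples ≥ 10-read filter; about a third
of shifted loci are removed by the filter before testing, capping cluster
recovery near 70–77% under this world. The benchmark in
`test-acceptance.R` asserts the 80% goal as stated and currently fails by
that margin; the bottleneck is the filter/effect interaction, not the
caller (every cluster with two surviving DMPs is recovered).

# Numerical choices

* Coordinates are 0-based half-open everywhere internally; GFF3 input is
  converted on load, BED written as-is.
* Pseudo-count rounding is half-up (`floor(x + 0.5)`), not banker's
  rounding, so results are platform-stable.
* Enzyme-ranking ties break alphabetically and are flagged; width-scan
  ties break toward the smallest width and are flagged; direction ties in
  a window call nothing and are logged.
* All-zero loci are dropped with a warning before methylation estimation
  ($M = 0$ has no scale); zero-variance expression groups with equal means
  are N.S. by definition.
* Every stochastic stage takes an explicit seed; identical seed and
  configuration give byte-identical FASTA, truth, and counts.

# Known limitations

* Raw DMP p-values are anti-conservative (analysis above); rely on the
  effect-size threshold and the clustering requirement, which together
  keep null DMR calls near zero.
* The relative-methylation anchor is biased upward at low coverage or
  high dispersion and blind to uniform methylation.
* No paired/longitudinal model, no beta-binomial alternative, no
  covariate adjustment.
* Enrichment ignores the GO DAG: terms are independent labels.
* Real-read support starts at per-locus counts; alignment is out of
  scope by design.
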