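---
title: "Methods: permutation-based differential ligand-receptor crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-based differential ligand-receptor crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Single-cell experiments that profile the same tissue in young and old
donors let us ask whether a signaling axis between two cell populations
strengthens with age. `agecrosstalk` scores a candidate axis as an ordered
ligand-receptor gene pair $(l, r)$ between a sender subset $i$ and a
receiver subset $j$, within one age group:

$$S \;=\; \bar e_{i,l} \times \bar e_{j,r},$$

where $\bar e_{i,l}$ is the mean expression of the ligand over the sender
cells of that age group and $\bar e_{j,r}$ the mean receptor expression
over the receiver cells. The product is a standard communication proxy: it
is large only when both sides of the axis are expressed, and it is zero
whenever either mean is zero.

Raw scores are not comparable across pairs, so significance comes from a
label-permutation null. The age-group labels are shuffled *within each
cell subset* — subset identity is biology we condition on; age is the
exposure under test — and the score is recomputed, $N$ times (default
1000). With $n$ the number of permuted scores at least as large as the
observed one (ties count),

$$p = \frac{n}{N},$$

and an interaction is called significantly up-regulated in its age group
when $p \le 0.01$. The test is one-sided for up-regulation within the
scored age group; down-regulation with age is read off the symmetric
record of the other age group.

Assumptions worth stating explicitly:

* **Exchangeability within subsets.** Under the null, age labels carry no
  information about expression inside a subset. Confounders that
  correlate with age within a subset (batch, donor) are not modeled here
  and must be handled upstream.
* **Means on a linear scale.** A product of means is distorted if the
  means are taken over log-transformed values, so the default expression
  layer for scoring is counts-per-10,000 (cp10k), linear. The layer is
  configurable (`normalization` in `analysis_config()`) and recorded in
  the output headers; which scale the score should use is a genuine
  modeling choice, not a settled fact.
* **Single-gene pairs.** Multi-subunit receptor complexes are out of
  scope; a pair table row is one ligand gene and one receptor gene, and
  A→B is distinct from B→A.

# Permutation design

Three design choices shape the null:

* **One joint shuffle per iteration.** Each iteration draws one
  within-subset permutation of the age labels of *every* subset and
  reuses it for all pairs, all (sender, receiver) combinations and both
  age groups. This gives a consistent joint null across records and costs
  $O(N)$ shuffles instead of $O(N \cdot \text{pairs})$. When sender and
  receiver are the same subset, the single shuffle serves both roles.
* **Sampling with replacement, identity included.** Arrangements are
  drawn uniformly over the within-subset label arrangements; the identity
  arrangement can recur. On tiny instances the sampled p-value therefore
  converges to the exhaustive-enumeration value, which
  `exact_crosstalk_pvalues()` computes directly and which the test suite
  uses as the ground truth.
* **No shift, no correction by default.** $p = n/N$ is reported exactly
  as defined, so $p = 0$ is attainable and the flagging probability of a
  truly null interaction at level $\alpha$ is
  $(\lfloor\alpha N\rfloor + 1)/(N + 1)$ — about 0.011 at $\alpha = 0.01$,
  $N = 1000$ — the familiar small anti-conservative bias of the unshifted
  permutation p-value. The bias-corrected $(n+1)/(N+1)$ is available via
  `report_pseudo_p = TRUE`; no multiple-testing correction is applied to
  crosstalk p-values by default because the flagging rule is a raw
  threshold.

# Upstream steps and their thresholds

Quality control keeps a cell when it has at least 200 detected genes
*and* at most 10% mitochondrial counts; both inequalities are strict on
the removal side, so boundary cells (exactly 200 genes, exactly 10%) are
kept. The removal rule joins the two criteria with OR by default
(`qc_rule = "union"`, the common practice); the stricter AND reading is
available as `"intersection"`. Gene filtering runs second, on the
surviving cells only: genes expressed in fewer than 3 of them are
removed. One pass, no iteration — re-running QC on its own output changes
nothing, which the suite checks. The mitochondrial share is computed over
total counts, with genes identified by a configurable regular expression
(default `^MT-`, the human convention).

Marker detection is the group-versus-rest Wilcoxon rank-sum test per
gene, Bonferroni-corrected within the tested group; a marker needs a
corrected p below 0.01 *and* a fold change above 1.5. The fold change is
a ratio of linear-scale means with a pseudocount of $10^{-9}$ (log-scale
values are de-logged first); a `log2_diff` mode exists because the 1.5
threshold is sometimes quoted on either scale. Aging-associated genes use
the old-versus-young Wilcoxon test within one subset; flagging uses the
raw p below 0.05 while Benjamini-Hochberg values are always reported, and
a switch (`aging_use_adjusted`) moves the flag to the corrected value —
which quantity the threshold properly applies to is ambiguous in common
usage, so both are carried.

The Wilcoxon p-value is exact (full enumeration) when both groups have at
most 8 observations and no ties occur, and otherwise uses the normal
approximation with midrank tie handling and continuity correction — the
behavior of `stats::wilcox.test`, which backs `wilcoxon_test()`.

# What the generator emulates — and what it does not

`sim_config()` + `generate_dataset()` produce the statistical structure
the crosstalk test assumes, with ground truth attached:

* **Counts.** Negative binomial (gamma-Poisson) with mean
  `baseline_mean` (default 2 counts/gene/cell) and size `dispersion`
  (default 2), the standard overdispersion model for UMI counts. The
  defaults give cells that comfortably clear the 200-detected-genes
  threshold at the default 500-gene panel.
* **Library size.** A per-cell log-normal factor (`libsize_sdlog`,
  default 0.25, mean fixed at 1) multiplies every gene's mean, so
  normalization choices are consequential and testable.
* **Mitochondrial block.** The first `n_mito_genes` genes (default 13,
  the human mtDNA protein-coding count) carry the `MT-` prefix and a
  2-fold elevated mean, putting healthy cells near a 5% mitochondrial
  share.
* **Planted effects.** A `planted_effect()` multiplies the ligand mean in
  the (sender, age) block and the receptor mean in the (receiver, age)
  block by `fold`; at fold $f$ on both sides the old/young score ratio
  is close to $f^2$. The pair table mixes planted pairs with decoy pairs
  drawn from effect-free filler genes.
* **Low-quality cells.** Planted cells are corrupted before sampling, so
  QC outcomes hold by construction: detected-gene downsampling leaves
  only a `lowquality_gene_fraction` (default 0.2) of the non-mitochondrial
  panel expressed (mitochondrial means are scaled along, keeping the
  share at baseline), mitochondrial boosting rescales the mito block to
  an expected share of `lowquality_mito_share` (default 0.3), and a
  third class gets both.
* **Determinism.** Everything is drawn under the config seed with pinned
  RNG kinds; the same config yields byte-identical files across fresh
  sessions.

Real data differ in ways the generator deliberately ignores: there is no
per-gene mean heterogeneity beyond the mitochondrial factor, no cluster
substructure or marker programs inside subsets, no batch or donor
effects, no doublets, no ambient RNA. Passing the planted-recovery and
calibration checks therefore demonstrates that the statistics do what
they claim under their own assumptions — not that those assumptions hold
in any particular tissue.

# Numerical choices

* **p representation.** `p` is stored as the double `n/N`; the integer
  columns `n` and `N` are authoritative. At the default $N = 1000$ the
  identity $p \cdot N = n$ is exact in IEEE doubles for every $n$; at
  awkward $N$ the product can differ from $n$ by one ulp, which is why
  the integers are carried in every record.
* **Tie counting.** "At least as large" is evaluated as `>=` on doubles
  with no tolerance. In the fully degenerate case (constant expression)
  all group means are exactly equal in floating point, every permuted
  score ties the observed one, and $p = 1$ — asserted in the suite.
* **Zero-total cells** are left all-zero by cp10k normalization, with a
  warning, rather than dividing by zero; all-zero groups produce score 0.
* **Subsets missing an age group** cannot be permuted meaningfully; they
  are dropped from a crosstalk run with a warning (and left unshuffled,
  with a warning, by `permute_age_labels()`).
* **Validation sizes.** The packaged checks run at sizes chosen to make
  their guarantees sharp but cheap: exhaustive enumeration on 2 subsets
  with 2 cells per subset per age (36 arrangements) against $N = 10^4$
  Monte-Carlo draws; type-I calibration over ~2000 null interactions from
  two independent datasets at $N = 1000$; power over 20 replicate
  datasets with a 4-fold effect and 200 cells per (subset, age).

# Limitations

The permutation preserves per-subset age composition but nothing else;
strong compositional signals (a subset nearly absent in one age group)
shrink the effective arrangement space and coarsen the p-value support.
All records of one run share the same $N$ draws, so their p-values are
correlated — convenient for joint interpretation, but a reason to treat
"number of significant interactions" as descriptive rather than as
independent discoveries. Finally, the score uses means, so a pair driven
by a rare but intense sender subpopulation can be diluted; subset
definitions are the user's lever there.
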