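---
title: "Tag-based digital gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based digital gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The assay and its model

Restriction-tag digital gene expression (DGE, the Illumina descendant of
SAGE) measures a transcriptome by counting short sequence tags rather than
full reads. Double-stranded cDNA captured on oligo(dT) beads is digested
with NlaIII, which cuts at every CATG; the 3'-most fragment stays on the
bead, an adapter is ligated to it, and MmeI — which cuts a fixed distance
from its recognition site at the adapter junction — releases a 21-bp tag:
the CATG anchor plus the following 17 nucleotides. Each transcript therefore
contributes one *canonical tag*, and a gene's expression level is the copy
number of that tag in the sequenced library.

This design fixes the whole analysis chain implemented here:

1. **Reference digestion** (`canonical_tag()`, `build_tag_index()`): every
   reference transcript is digested in silico to the 21-mer at its 3'-most
   qualifying CATG. Because the bead captures 3' fragments, sites upstream
   of the last one never produce tags. A site only qualifies if 17 valid
   (non-N) bases follow it; windows containing N fall back to the next site
   upstream. The index maps tag → gene set; tags claimed by several genes
   are kept but flagged ambiguous, because they cannot identify a
   transcript. By default both strands are digested (`strand_mode = "both"`),
   which matches reference tag databases of roughly 1.8 distinct tags per
   gene; sense-only digestion is available for strand-resolved references.

2. **Tag QC** (`filter_tags()`): raw tags are partitioned into four
   exhaustive categories — N-containing or structurally malformed tags,
   exact matches to a configured adaptor sequence (adapter-only inserts),
   tags seen only once in the library (probable sequencing errors), and the
   clean remainder. Precedence is fixed: N/low-quality first, then adaptor,
   then singletons. An adaptor match is its own category even though it
   lacks CATG structure; all other malformed tags count with the
   N/low-quality class. The four counts sum *exactly* to the raw total —
   this conservation is asserted on every simulated run. Copy-number
   filtering is per library: a tag with one copy here and many elsewhere is
   still removed here.

3. **Mapping** (`map_tags()`): clean distinct tags are assigned to genes
   with at most one mismatch. Exact hits come first and are final — an
   exact hit shared by several genes is ambiguous and is *not* rescued by
   error-tolerant matching, since a perfect observation should not be
   overridden. Tags with no exact hit have their 51 single-substitution
   neighbors (17 variable positions × 3 alternative bases) looked up; the
   CATG anchor is held fixed because anchor-corrupted tags were already
   removed at QC. The union of neighbor hits decides the status: one gene →
   `mismatch_unique`, several → `ambiguous`, none → `unknown`. A tag
   hitting the sense and antisense tags of the *same* gene is unique to it.
   Only unambiguous tags are quantified; ambiguous ones are discarded, not
   apportioned.

4. **Quantification** (`count_genes()`, `tag_tpm()`): a gene's raw count is
   the summed copy number of its unique tags, normalized to TPM — tag
   copies per million *clean* tags. The clean-total denominator (rather
   than mapped-total) means TPM values across genes sum to at most 1e6,
   with equality only if every clean tag maps unambiguously.

## The exact test

Differential expression between two libraries uses the Audic–Claverie exact
test. Under Poisson sampling, the count $y$ of a tag in a library of depth
$N_2$, conditioned on observing $x$ in a library of depth $N_1$, follows

$$p(y \mid x) \;=\; \frac{r^{y}\,(x+y)!}{x!\,y!\,(1+r)^{x+y+1}},
\qquad r = N_2/N_1,$$

which is a negative-binomial distribution with size $x+1$ and success
probability $1/(1+r)$. The two-sided p-value doubles the smaller inclusive
tail, capped at 1.

Two numerical points matter:

* **Orientation.** The doubled-tail construction is not invariant under
  swapping the libraries: for $x=5, y=0$ at equal depths, conditioning on 5
  gives $2\cdot(1/2)^{6} = 0.03125$ while conditioning on 0 gives 0.0625.
  `ac_test()` therefore canonically conditions on the library with the
  larger normalized count (ties: larger raw count, then smaller depth),
  which makes the p-value exactly symmetric under library swap and
  reproduces the closed form above. The test oracle (the negative-binomial
  CDF) applies the same orientation.
* **Stability.** Tails are accumulated in log space via `lgamma`. The upper
  tail is taken as $1 - P(K \le y-1)$ only while the lower tail is below
  0.9; beyond that the upper tail is summed directly upward from $y$ in
  blocks, avoiding catastrophic cancellation for extreme counts. The
  implementation agrees with the independent CDF route to better than 1e-9
  over the count grid 0–200 at depths $10^5$–$5\times10^6$ (the acceptance
  suite recomputes this).

Multiplicity is handled by Benjamini–Hochberg step-up adjustment
(`bh_fdr()`, delegating to `stats::p.adjust`); the FDR procedure for tag
DGE pipelines of this family is conventionally BH. A gene is called
differentially expressed when FDR ≤ 0.001 *and* |log2 ratio| passes the
effect threshold. The literature around this assay states the effect rule
both as "log2 fold change ≥ 2" and as "absolute log2Ratio ≥ 1"; both
readings are exposed through `min_abs_log2`, with 1.0 (two-fold) as the
default because the accompanying differential-expression tables use it.
Ratios use TPM with 0.001 substituted for zeros — the substitution affects
only the ratio, never the test counts.

## Expression categories and stage patterns

Per-library TPM values are binned into the standard abundance classes:
rare [0,5), low [5,50), moderate [50,100), high [100,∞). The interval
notation in report prose ("TPM > 5–50") is boundary-ambiguous; left-closed
bins are used so every value has exactly one class.

Five-stage profiles are classified into four trend groups by ordered rules
on the profile floored at TPM 0.001, with amplitude $a = \max/\min$ and
Spearman rank correlation $\rho$ against the stage index:

1. **Constitutive** if $a < 4$ — *unless* the profile trends strongly
   ($|\rho| \ge 0.6$ with $a \ge 2$). The escape exists because a steadily
   monotone two- to four-fold profile is a trending gene, not a flat one;
   without it, smoothly increasing housekeeping-adjacent genes would be
   absorbed into the flat class.
2. **Low-high-low** if stage 3 is the unique maximum and at least 1.3× both
   endpoints.
3. **Up** if $\rho \ge 0.6$, or the last stage is the maximum at ≥ 2× the
   first.
4. **Down** mirrored.
5. Otherwise **unclassified**.

Rank-correlation thresholds are compared with a 1e-9 tolerance: five-point
profiles often land *exactly* on $\rho = \pm 0.6$, and a bit-level
comparison would misroute them. The thresholds (4, 0.6, 1.3, 2, and the
escape amplitude 2) were calibrated once against the 39 published reference
profiles bundled as `ripening_profiles()` and then frozen. On those
profiles the classifier reproduces 38 of 39 printed group memberships; the
one disagreement is a plasma-membrane ATPase profile with a 14-fold spike
at stage 4 that is printed as constitutive — no amplitude-based rule can
honor that label, and the classifier reports it as unclassified rather
than special-casing it.

## Pathway enrichment

Over-representation of a DEG set in a pathway uses the hypergeometric upper
tail: with $N$ annotated genes, $n$ DEGs among them, $M$ pathway members
and $m$ DEG members, $P = P(X \ge m)$ via `stats::phyper`. Significance is
flagged on the raw $P \le 0.05$ (the convention of this assay's reports); a
BH-adjusted column is provided but does not drive the default flag. Genes
in several pathways count in each; DEGs without any annotation are dropped
with a message. The tests verify the tail against exact combinatorial
enumeration (to 1e-12 for all instances with $N \le 30$, and against the
fully enumerated $\binom{20}{5}$ draw space for a worked instance).

## Saturation

`saturation_curve()` measures detected genes (≥ 1 unambiguously mapped tag)
as a function of depth by *nested* subsampling: one permutation of the
per-copy tag stream per replicate, evaluated at all grid depths as prefix
statistics. Nesting makes within-replicate monotonicity structural rather
than statistical. For the uniform toy case (G genes × t copies), the mean
curve is checked against the closed form
$G\,(1 - \binom{T-t}{d}/\binom{T}{d})$; the comparison uses a 99%
confidence band plus a rule-of-three floor ($3/R$ for $R$ replicates) for
depths where no replicate misses any gene and the sample variance
degenerates to zero.

## The simulator

`sim_config()` + `sim_transcriptome()` + `sim_ground_truth()` +
`sim_tag_library()` generate a complete experiment with known truth:

* **Transcripts**: i.i.d. bases at the configured GC (default 0.45, typical
  of plant transcriptomes), uniform lengths 150–900 bp (bracketing the
  ~500 bp mean of short-read unigene assemblies). By default every
  transcript is rejection-sampled to contain a qualifying CATG site;
  `siteless_fraction` relaxes this. Note the conditioning matters: with
  rejection active, the mean number of CATG sites per transcript exceeds
  the unconditioned i.i.d. expectation $(L-3)/4^4$, so the closed-form
  check in the tests uses `siteless_fraction = 1`.
* **Expression**: log-normal baseline abundances (sdlog 2, spanning the
  4–5 decades typical of transcriptomes), normalized per stage. For each
  adjacent stage pair an exact-size random subset (`de_fraction`) is
  multiplied by $2^{\pm u}$, $u \sim U[\text{log2fc}_{\min},
  \text{log2fc}_{\max}]$, and recorded as truth. Exact subset sampling (not
  per-gene Bernoulli) keeps planted counts reproducible. Renormalization
  shifts all genes by a common small constant, so observed ratios are
  compared to truth with that in mind.
* **Tags**: each stream position is real, N-artifact, or adaptor-artifact;
  artifacts *replace* positions so the stream length equals the configured
  depth exactly (report percentages partition a fixed raw total). Real tags
  carry i.i.d. per-base substitutions over all 21 positions — including the
  anchor, which deliberately exercises the QC and unknown-tag paths.
  Defaults: substitution 0.002/base (so ≈ 4.1% of tags carry ≥ 1 error),
  N-artifacts 0.005, adaptor 0.002 — consistent with libraries that retain
  ≈ 97% of raw tags after QC.

What the simulator does **not** model: read-level qualities, PCR
duplication, ligation chemistry, isoforms, overdispersion beyond the
planted fold changes (sampling is multinomial, i.e. Poisson-like). Tests
passing on these simulations therefore demonstrate correctness of the
pipeline's logic and calibration of its statistics under the stated
sampling model — not robustness to biological overdispersion, which the
exact test by construction does not address.

All randomness flows from `config$seed` through fixed offsets per stage;
`with_seed()` restores the caller's RNG state, and re-running a pipeline
from its manifest reproduces every artifact byte for byte.

## Problem sizes used by the test suite

The bundled checks run at desk scale by choice: 2,000 genes with libraries
of 1–2 million tags for the error-control and power studies (three seeds
for the null study), 300-gene indexes with 1,000 queries for the mapping
oracle, 200-replicate subsampling for the saturation law, and full count
grids 0–200 for the exact-test oracle. At these sizes a full suite run
completes in about a minute; the same code operates unchanged at sequencing
scale (~6 million tags per library, ~90k reference genes).

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 500, depth_per_stage = 1e5, seed = 1)
res <- run_dge_pipeline(cfg, out_dir = "dge_run")
res$summaries$qc          # report-style QC table, one column per stage
res$de$FS1_vs_FS2         # ranked exact-test table with calls
res$patterns              # five-stage trend groups
```

## Known limitations

* The exact test assumes Poisson sampling; biological replicates and
  overdispersion are out of scope (no negative-binomial GLM).
* Ambiguous tags are discarded entirely; genes whose canonical tags
  collide are invisible to quantification.
* No indel tolerance in mapping, and at most one substitution.
* The pattern classifier is a fixed-rule device calibrated on 39 reference
  profiles; it is not a clustering of the transcriptome.
* Saturation reports observed detection only — no richness extrapolation.
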