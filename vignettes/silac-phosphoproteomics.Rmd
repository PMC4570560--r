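---
title: "Anchored triple-SILAC phosphoproteomics: ratios, outlier significance, and kinase-target enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored triple-SILAC phosphoproteomics: ratios, outlier significance, and kinase-target enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacsites)
```

# The analysis

`silacsites` implements the downstream quantitative analysis of a two-set
triple-SILAC phosphoproteomic experiment: the kind of design in which two
cell states (here called *proficient* and *deficient*, e.g. cells with and
without a restored tumor-suppressor gene) are profiled under two growth
conditions (high serum and serum starvation), with one shared reference —
the proficient, high-serum, light-labeled culture — measured in both
mixes. The package takes the search engine's phosphosite quantification
table as its input and carries the analysis through five stages:

1. **Ratios.** Per-site log2 abundance ratios for named condition
   comparisons, either within one SILAC mix or chained across mixes through
   the shared anchor channel.
2. **Differential sites.** Outlier p-values for each ratio using the
   asymmetric, intensity-binned statistics Significance A and Significance
   B, thresholded at `alpha`, plus the cross-condition overlap (Venn)
   of significant sites.
3. **Serum-withdrawal classes.** A partition of each site's pair of
   serum-response ratios into *correlated*, *persistent-in-deficient*
   ("blue"), *lost-in-deficient* ("gray"), or *unclassified*.
4. **Kinase-target enrichment.** Residue-level kinase target sets scored
   against the pre-ranked site list with the classic (unweighted,
   Kolmogorov–Smirnov) running-sum enrichment score, permutation-normalized
   NES, permutation p-values and permutation FDR, with leading-edge
   extraction.
5. **Functional context.** Hypergeometric annotation over-representation
   with Benjamini–Hochberg correction, and high-confidence
   interaction-network neighborhoods over a local scored edge list.

A fully deterministic synthetic-data generator with planted ground truth
drives calibration and power checks; `run_pipeline()` orchestrates all
stages from a single configuration.

# The experiment design model

A `silac_design()` maps each `(set, channel)` pair to a biological
condition, names the anchor condition, and declares the comparisons of
interest. The default design is:

```{r}
default_design()
```

The anchor (proficient cells, high serum, light label) appears in both
sets. Which of the remaining channels carries which condition is not fixed
by the design idea itself, so the assignment is fully configurable; the
default above was chosen so that three comparisons are direct and one — the
deficient-cell serum response — must be chained through the anchor,
exercising the cross-set composition:

$$\log_2\frac{\mathrm{def~high}}{\mathrm{def~low}}
  = \log_2\frac{\mathrm{def~high}}{\mathrm{anchor}_{(1)}}
  - \log_2\frac{\mathrm{def~low}}{\mathrm{anchor}_{(2)}}.$$

With an error-free anchor the two reference terms cancel; with a noisy
anchor the chained ratio carries the noise of four channels, which is why
its summed intensity is taken as the *minimum* of the two legs' summed
intensities (the noisier leg limits the information), and why the two
serum-response axes share anchor noise (see *Limitations*).

Ratios are median-centered per comparison before significance scoring. The
upstream normalization state of a site table is unknown in general and the
asymmetric outlier model below measures deviations from the ratio
population's center, so a zero median is the natural gauge; the subtracted
offset is retained as an attribute for truth-recovery work.

# Significance A and B

For a vector of log ratios with median $r_0$, the side-specific scales are
taken from the $\pm 1\sigma$ percentiles of the empirical distribution
(15.87th and 84.13th, linearly interpolated between order statistics):
$s^+ = P_{84.13} - r_0$, $s^- = r_0 - P_{15.87}$. Each ratio $r$ gets

$$z = \begin{cases}(r - r_0)/s^+ & r > r_0\\ (r_0 - r)/s^- & r \le r_0\end{cases},
\qquad p = \tfrac12\,\mathrm{erfc}\!\left(z/\sqrt2\right) = 1 - \Phi(z).$$

This is a one-sided tail probability against the ratio's own side: $p =
0.5$ at the median and $p \approx 0.1587$ one scale unit out. Thresholding
this one-sided score at $\alpha$ — the convention used when the statistic
is applied directly — exceeds the threshold at rate $2\alpha$ under a
symmetric null. `two_sided = TRUE` doubles the tail probability (capped at
1), which is the standard transformation under which the statistic is
calibrated: a Gaussian null then yields a flag rate of $\alpha$. The
package defaults to the classical one-sided form; the calibration tests use
the doubled form, and both behaviors are asserted in the test suite.

**Significance B** applies the same statistic within contiguous
equal-occupancy bins of sites ordered by summed intensity (ties broken by
site id for a deterministic binning). Ratio spread in SILAC data shrinks as
intensity grows, so a global scale under-calls precise high-intensity sites
and over-calls noisy low-intensity ones; binning judges each site against
comparably measured peers. The minimum bin occupancy defaults to 300 —
large enough for stable percentile estimates, small enough to resolve the
intensity trend in tables of a few thousand sites — and is configurable.
With fewer sites than `min_bin`, a single bin is used and B reduces to A
exactly. Degenerate scales ($s^+$ or $s^-$ equal to zero, e.g. constant
input) raise a statistic error advising jitter or a larger input rather
than returning misleading p-values.

BH q-values are available (`bh_adjust()`, a wrapper over
`stats::p.adjust`), but the significance flag defaults to the raw p-value
at `alpha = 0.05`, matching the statistic's usual thresholding convention;
adjustment is opt-in via configuration.

# Serum-withdrawal classification

Each site quantified in both serum comparisons contributes a point $(x,
y)$: its log2(high serum / starvation) ratio in proficient ($x$) and
deficient ($y$) cells. The partition rule, with thresholds
$\tau_{\mathrm{change}} > \tau_{\mathrm{null}} \ge 0$:

* **correlated** — same sign, $\min(|x|,|y|) \ge \tau_{\mathrm{null}}$, and
  $|x - y| < \tau_{\mathrm{change}}$ (coordinated response in both
  genotypes; excluded from the network stage);
* **persistent-in-deficient** (blue) — $x \ge \tau_{\mathrm{change}}$ and
  $y \le \tau_{\mathrm{null}}$: the site loses its phosphorylation on
  starvation only in proficient cells;
* **lost-in-deficient** (gray) — the axis-swapped mirror;
* **unclassified** otherwise. Where the correlated band touches an
  anti-correlated corner, exclusion wins.

The defaults $\tau_{\mathrm{change}} = 1$ and $\tau_{\mathrm{null}} = 0.5$
log2 units (a clear response is at least a two-fold change; a null response
is within $\sqrt2$-fold) are package choices: the partition they formalize
is qualitative in origin, so both thresholds are exposed as configuration
parameters and downstream conclusions should be checked for stability
under them. Sites missing either ratio are skipped, not "unclassified" —
absence of evidence is not an anti-correlated response.

# Kinase-target enrichment

Residue-level target sets (one per kinase, members keyed by `(gene,
residue)`) are intersected with the ranked universe; sets below `min_size =
3` members are dropped — small sets cannot produce a stable running-sum
extremum, and 3 matches the smallest set size that is still scored in
practice. The ranked list orders sites by their log2(proficient/deficient)
ratio with the deficient-enriched (most negative) end first by default, so
a kinase hyperactive in deficient cells scores positively.

The enrichment score walks the list accumulating $+1/k$ at members and
$-1/(N-k)$ at non-members; ES is the signed maximum deviation. With these
unweighted increments, $|ES|$ is exactly the two-sample Kolmogorov–Smirnov
statistic between member positions and the uniform rank distribution (the
suite verifies this against `stats::ks.test` and `fgsea`'s unweighted
statistic, and against brute-force enumeration of every small subset). The
running sum is accumulated in exact integer units of $1/(k(N-k))$ — hit
step $N-k$, miss step $-k$ — so exactly symmetric deviations are tied out
deterministically (toward the positive side) instead of depending on
floating-point accumulation order.

The null is gene-set permutation: for each of `n_perm` (default 1000)
permutations, a random member set of equal effective size is drawn from the
universe. A single pre-ranked list offers no sample labels to permute, so
set permutation is the appropriate null; it tests membership, not
inter-site correlation. Then, per set,

$$\mathrm{NES} = \frac{ES}{\operatorname{mean}\left(|ES_{\mathrm{null}}|
\;:\; \operatorname{sign}(ES_{\mathrm{null}}) = \operatorname{sign}(ES)\right)},
\qquad
p_{\mathrm{perm}} = \frac{1 + \#\{|ES_{\mathrm{null}}| \ge |ES|,\ \mathrm{same\ sign}\}}
{1 + \#\{\mathrm{same\ sign\ nulls}\}},$$

with the add-one guard keeping $p > 0$ and a flag raised if no
matching-sign null exists. The FDR of an observed NES is the matching-sign
null tail fraction (over the pooled, identically normalized null NES)
divided by the observed tail fraction, clipped to $[0,1]$, then
monotone-adjusted in the conservative direction: each set's FDR is raised
to the worst among sets at least as extreme, so FDR is non-increasing in
$|NES|$. A permutation seed is mandatory and recorded in the result;
identical seeds give bit-identical NES, p and FDR.

# Functional context

Annotation over-representation is the plain one-tailed hypergeometric
upper tail $P(X \ge k)$ with population $M$ (background), $K$ annotated, $n$
drawn — chosen over service-specific variants for exactness and
testability — with BH correction across all tested terms (a single
annotation namespace, a single correction). Terms without a hit are
omitted; querying proteins outside the background is an error rather than a
silent renormalization.

The interaction stage keeps edges with combined confidence **strictly**
above the threshold (default 0.9, i.e. "high confidence") whose endpoints
both belong to the query set, and reports induced connected components in
decreasing size order (ties by lexicographically smallest member).
Proteins with no retained edge are absent: a neighborhood is by definition
connected. Component node sets can then be re-queried for annotation
enrichment, after intersection with the annotation background.

# The synthetic-data generator

`synthetic_config()` fixes the study conditions for all simulation-based
checks. Per site, a base log2 intensity is drawn from
$\mathcal N(\mu_I, \sigma_I)$ (defaults 25 and 2, typical of log2 MS
intensities); channel intensities are $2^{B + e_c + \varepsilon}$ with
condition effect $e_c$ and channel noise
$\varepsilon \sim \mathcal N(0, \sigma(B))$,

$$\sigma(B) = a + b\,e^{-c\,(B - B_{\min})},$$

defaults $a = 0.15$, $b = 0.6$, $c = 0.4$ per log2 unit,
$B_{\min} = \mu_I - 2\sigma_I$. Noise is additive on the log2 scale per
channel, so a ratio's noise is the difference of two channel noises:
multiplicative intensity error with an intensity-dependent spread, exactly
the premise of the binned outlier statistic. Setting $b = 0$ gives a
homoscedastic null for calibration.

Planted structure: a fraction `pi_diff` (default 5%) of sites receives a
genotype effect of magnitude $|\mathcal N(2, 0.5)|$ log2 units with random
sign; serum classes (defaults 15% correlated, 4% blue, 4% gray) receive
$(x,y)$ responses of $(2,2)$, $(2,0)$, $(0,2)$; one planted kinase set of
30 members is shifted by $-2$ log2 units against 20 unshifted decoy sets;
3% of channel entries go missing; and 3 network modules of 8 proteins are
term-coherent and densely connected above score 0.9 against a sparse
sub-0.9 background. The anchored design has only three free condition
effects relative to the anchor, so the four comparison effects satisfy
$d_{\mathrm{low}} = d_{\mathrm{high}} + y - x$ by construction; the truth
table records the realized values per comparison. A single master seed
drives independent substreams for the site, kinase and network tables, so
regenerating one table never perturbs another, and identical
configurations are byte-identical.

What the generator does **not** emulate: peptide-level rollup and shared
peptides, label-incorporation efficiency, intensity-dependent missingness
(missingness is uniform), ratio compression, multi-site phosphopeptides,
and correlated biological replicates. Passing tests therefore demonstrate
the statistical machinery on data with the assumed noise structure, not
robustness to every artifact of real MS data.

# Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run on
one CPU in well under their time budgets while keeping estimates stable:
calibration uses ~10,000 null sites (binomial standard error ~0.2% on a 5%
rate); power and recovery checks use 2,000–4,000 sites; permutation
analyses use 1,000 permutations for 21 sets over a ~2,800-site universe;
exhaustive enrichment-score enumeration covers every subset of size ≤ 5 at
$N \in \{5, 12, 20\}$ (23,314 subsets). Percentile estimation uses R's
default linear interpolation (type 7); intensity ties in binning and metric
ties in ranking break by site key; all RNG flows through explicit seeds.

# Known limitations

* **Anchor-induced correlation of the serum axes.** The $x$ and $y$
  serum-response ratios share the anchor channel(s), so their measurement
  errors are positively correlated (about $\rho = 0.35$ at equal channel
  noise in the default design). Under noise this inflates the same-sign,
  near-diagonal *correlated* region with true-null sites: at a flat channel
  noise of 0.2 log2 units, roughly 2% of all pairs leak from null into
  *correlated*. Class proportions at moderate noise should be read with
  that bias in mind; the noiseless partition is exact.
* **One-sided outlier convention.** The classical Significance A/B score
  thresholded at $\alpha$ admits $2\alpha$ of a symmetric null. Use
  `two_sided = TRUE` when a calibrated type-I rate is required.
* **Set permutation null.** The permutation NES/FDR treats sites as
  exchangeable; correlated target sites (e.g. multiple residues of one
  substrate) make the null slightly liberal.
* **No protein-level rollup, no imputation, no moderated-variance
  alternatives** — these are out of scope by design.
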