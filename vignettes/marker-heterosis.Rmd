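---
title: "Predicting heterosis from microsatellite distance in a half diallel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting heterosis from microsatellite distance in a half diallel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterodist)
library(dplyr)
```

## The problem

Developing a hybrid rice variety means crossing candidate parents, growing
the F1s in replicated trials, and measuring how far each hybrid exceeds its
parents — its *heterosis*. Field evaluation of every possible cross is the
expensive step: $n$ parents imply $n(n-1)/2$ hybrids even without
reciprocals. If the genetic distance between two parents, measured cheaply
from molecular markers, predicted the heterosis of their cross, breeders
could rank candidate combinations before ever making them.

`heterodist` implements the complete analysis chain for testing that idea in
a half-diallel design (Griffing method 2: all unordered parent pairs, no
selfs, no reciprocals) of homozygous inbred lines genotyped at multi-allelic
microsatellite (SSR) loci and phenotyped in a randomized complete block
design (RCBD):

1. per-locus marker informativeness (allele counts, gene diversity, PIC);
2. pairwise Nei DA genetic distances among parents, UPGMA clustering,
   Newick export;
3. entry means, RCBD ANOVA, mid-parent and better-parent heterosis with
   LSD significance;
4. Pearson correlation of parental marker distance with heterosis, per
   trait;
5. a simulator that generates half-diallel datasets with *known* additive
   and dominance architecture, so every stage can be checked against ground
   truth.

## Marker informativeness

For allele frequencies $p_1,\dots,p_k$ at a locus, the package reports both
Nei gene diversity (expected heterozygosity)

$$H = 1 - \sum_i p_i^2,$$

and Botstein's polymorphic information content

$$PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2\,p_i^2 p_j^2 .$$

The two are often conflated in the applied literature; $PIC \le H \le
1-1/k$ always holds, so reporting both makes the distinction visible.
Markers with $PIC > 0.5$ are conventionally called highly informative.
Frequencies are computed complete-case per locus (missing calls leave the
denominator), and a heterozygous call written `"a/b"` contributes half a
count to each allele — inbred panels should not contain such calls, but the
dialect is parsed for generality.

```{r}
g <- read_genotypes(system.file("extdata", "synthetic_genotypes.csv",
                                package = "heterodist"))
summarize_panel(g)
```

The package also bundles a published reference summary of an 11-locus rice
SSR panel (`rice_ssr_panel()`); its diversity column is reproduced as
printed and treated purely as an input to the panel aggregates. Two of its
printed diversity values exceed the theoretical maximum $1 - 1/k$ for their
stated allele counts, so no frequency vector can regenerate them; the
package deliberately aggregates rather than recomputes that column.
Relatedly, the bundled marker-metadata table (`rice_ssr_markers()`)
disagrees with the summary table on two marker names; the two tables mirror
their respective sources and are not merged.

## Genetic distance and clustering

Between two lines, with within-line allele frequencies $x_a$ and $y_a$,

$$D_A = 1 - \frac{1}{L} \sum_{l=1}^{L} \sum_a \sqrt{x_a y_a}.$$

For fully homozygous inbreds each locus term is 1 when the alleles match
and 0 otherwise, so $D_A$ reduces to the proportion of compared loci at
which the lines differ — the documented default behaviour, and the oracle
the tests exploit. Loci with a missing call in either line are excluded
pairwise, so $L$ is a per-pair denominator. One numerical consequence worth
knowing: on complete tables $D_A$ is a pseudo-metric (symmetric,
triangle inequality), but pairwise deletion can break the triangle
inequality because different pairs are compared over different locus sets.
`nei_da_distance(..., method = "nei_standard")` provides Nei's 1972
standard distance $-\log\!\big(J_{xy}/\sqrt{J_xJ_y}\big)$ as an
alternative; it is unbounded above and diverges for pairs sharing no
allele, which is why the bounded $D_A$ is the default.

UPGMA clustering is implemented with the size-weighted
arithmetic-mean update; ties in the closest-pair search are broken by the
lowest (row, column) position so trees are deterministic. Each internal
node sits at half its merge distance, giving an ultrametric tree whose
cophenetic distances reproduce the merge distances; `to_newick()` writes it
with branch lengths.

```{r, fig.width = 6, fig.height = 4}
d <- pairwise_distances(g)
plot_dendrogram(upgma(d))
```

## Heterosis and its significance

With entry means $F_1$, $P_1$, $P_2$ over blocks, $MP = (P_1+P_2)/2$ and
$BP$ the larger parent mean,

$$HMP = 100\,\frac{F_1 - MP}{MP}, \qquad HBP = 100\,\frac{F_1 - BP}{BP}.$$

Taking $BP$ as the larger-mean parent for *every* trait — including plant
height and sterility, where a breeder wants lower values — keeps $HBP \le
HMP$ for positive parent means, matching how diallel heterosis tables are
conventionally printed. Trait desirability (`rice_traits()`) is carried as
metadata only and never alters a formula.

Significance uses the LSD thresholds built from the RCBD error mean square
$MSE$ (Wynne's formulas): the contrast $F_1 - MP$ has variance
$3\sigma^2/2r$ and $F_1 - BP$ has $2\sigma^2/r$, giving

$$LSD_{MP} = t_{\alpha/2,\,df}\sqrt{\tfrac{3\,MSE}{2r}}, \qquad
  LSD_{BP} = t_{\alpha/2,\,df}\sqrt{\tfrac{2\,MSE}{r}},$$

and the fixed ratio $LSD_{BP}/LSD_{MP} = 2/\sqrt{3}$. The comparison is made
on the trait-unit difference scale by default (`sig_scale = "unit"`):
published tables print LSD rows under percentage columns without stating
units, and comparing $|F_1 - MP|$ with the LSD in trait units is the
interpretation consistent with the formulas above. `sig_scale = "percent"`
rescales the LSD by the reference mean for users who want the comparison on
the percentage scale. The ANOVA takes all entries — parents and F1s — as
one genotype factor in a single RCBD, so one $MSE$ per trait is shared by
all crosses; unbalanced data are accepted by `entry_means()` (with a
warning) but rejected by `rcbd_anova()`, because the LSD formulas assume
balance. The two-sided $t$ quantile uses the ANOVA's error degrees of
freedom $(g-1)(b-1)$.

## Distance–heterosis correlation

`correlate_gd_heterosis()` pairs each cross's parental distance with its
heterosis and reports the Pearson $r$, with a two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, separately per trait and basis
(MP/BP). No multiple-testing correction is applied across traits by
default, matching the reporting convention of diallel marker studies; both
levels 0.05 and 0.01 are annotated. The default correlates *distance* with
heterosis; `similarity = TRUE` correlates $1 - D_A$ instead, which only
flips signs. Crosses with undefined heterosis (zero reference mean) are
dropped and counted, and constant distance is an explicit error rather than
a silent `NaN`.

## What the simulator emulates

`simulation_config()` encodes the study conditions of an eight-parent rice
diallel: 8 homozygous parents, 11 multi-allelic marker loci, 28 crosses,
three complete blocks. The genetic model is additive + dominance:

* a parent's genotypic value is $\mu + \sum_l a_l(\text{allele}_l)$;
* an F1's genotypic value is the mid-parent value plus $\sum_l d_l$ over
  trait loci at which its parents differ;
* a plot observation adds a block effect and $N(0,\sigma^2)$ noise.

So the true dominance deviation of a cross is $D = \sum_{l\,\text{het}}
d_l$, true mid-parent heterosis is $100\,D/MP$, and — when the trait loci
*are* the marker loci (`markers_are_trait_loci = TRUE`, the default) — the
heterozygosity fraction driving $D$ equals the marker mismatch proportion,
i.e. exactly the Nei DA distance. With flat additive effects this makes
$HMP = 100\,d\,L\,GD/\mu$ a closed-form function of distance: the
configuration under which marker distance predicts heterosis perfectly, and
the positive control for the whole pipeline. Setting $d \equiv 0$ gives the
null: distance and heterosis independent, for type-I calibration.

Defaults the design fixes: `n_parents = 8`, `n_marker_loci = 11`,
`r_blocks = 3`. Defaults chosen once as realistic for plot-mean agronomic
traits, on a scale where the baseline is ~100 units (think plant height in
cm or filled grains per panicle): `alleles_per_locus = 4` (the upper end of
the 2–4 alleles such small panels segregate, matching a mean near 3.5),
`baseline_mu = 100`, `additive_effects = 2` and `dominance_effects = 3`
trait units per locus (per-cross dominance deviations of a few percent of
the mean), `block_effects = c(-1, 0, 1)` and `residual_sigma = 1` (block
and plot noise of ~1% of the mean, typical for plot means of ten plants).
Allele sampling is uniform by default; `allele_skew` tilts the weights for
diversity-statistic stress tests. Drought or any other stress enters only
as a label (`stress_multiplier` rescales the baseline mean) — the stress
protocol itself is agronomy, not statistics. One quantitative trait is
simulated per run; a multi-trait study is eight configured runs sharing the
same genotypes.

What the simulator does *not* emulate: linkage and recombination (loci are
independent), epistasis, genotype-by-environment interaction, genotyping
error, segregation within lines. Passing tests therefore demonstrate that
the estimators recover the additive + dominance model they assume — not
that real drought-trial heterosis is predictable from marker distance; in
real panels dominance loci need not coincide with markers, which is
precisely why empirical correlations are weak for most traits.

## Validation choices and problem sizes

The test suite validates each stage against an independent route: PIC
against an explicit double-loop evaluation; Nei DA against brute-force
mismatch counting on ~1,000 random tables; UPGMA against both a naive
$O(n^3)$ re-agglomeration (all sizes up to 6 taxa) and
`stats::hclust(method = "average")`; the ANOVA partition against the total
sum of squares on random complete tables; Pearson against `cor.test()`.
End-to-end recovery runs 40 simulated diallels under the default
conditions: per-cross estimated HMP is required to land within 3 residual
SDs of truth ($SD = \sigma\sqrt{3/(2r)}\,/\,MP \times 100$, per-cross) for
at least 95% of crosses — the observed rate is ~99.6%, with ~94% inside 2
SDs (slightly under the Gaussian 95.4% because crosses sharing a parent
have correlated mean errors). The null calibration uses 500 simulated
diallels with $d \equiv 0$ and checks the GD–HMP rejection rate at
$\alpha = 0.05$ against its binomial band. These sizes keep the whole
suite to roughly two minutes on one core while leaving the stochastic
checks well-powered.

## Known limitations

* The LSD machinery assumes a balanced RCBD; there is no mixed-model path
  for unbalanced trials.
* Combining-ability decomposition (GCA/SCA) is out of scope: the mating
  design is used for heterosis only.
* Allele calls are taken as pre-binned labels; no fragment-size binning or
  error modelling is attempted.
* Bootstrap support for dendrograms and neighbor-joining are not provided.
* The Pearson test treats the 28 cross-level points as independent;
  crosses sharing a parent are not, and the simulation-based calibration
  above is the honest account of how much that matters at this scale.
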