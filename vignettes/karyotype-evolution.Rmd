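---
title: "Modelling karyotype evolution in free-living human cell lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling karyotype evolution in free-living human cell lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoevolve)
```

## The scientific problem

Cultured human cell lines live as quasi-unicellular populations. Freed from
the constraints of a multicellular body, their karyotypes evolve: lines
derived from male tissue frequently lose the Y, lines derived from female
tissue lose the inactive X (Xi), and in both sexes the remaining active X
(Xa) is often duplicated while autosomes are added roughly one haploid
complement at a time. Writing a karyotype as C(Xa:A) — the number of active
X chromosomes against the autosome ploidy in multiples of 22 — the normal
somatic state is C(1:2), yet large cell-line panels are dominated by C(1:2)
*and* C(2:3), with C(2:2) rare. `karyoevolve` implements the full analysis
chain needed to establish and interpret that pattern, plus a synthetic-data
generator so every stage is testable without any external download.

## Chromosome-level calling

Input is probe-level output of an allele-specific copy-number caller for
SNP arrays: per probe a genotype (AA/AB/BB/NC) and total and minor copy
numbers. The calling rules are deliberately simple and operate per whole
chromosome:

* **LOH** — called when at least 95% of genotyped probes are homozygous
  (inclusive boundary). No-call probes are excluded from numerator and
  denominator: they carry no zygosity information. Loss of heterozygosity
  is irreversible, so it records that one homolog was lost even if copy
  number was later restored.
* **Copy number** — assigned k when at least 95% of probes agree on a
  constant k in 0–4; anything else is undetermined. A consequence worth
  knowing: a chromosome genuinely present in five or more copies (e.g. the
  X of a C(4:4) line that still carries an Xi) is *undetermined*, never
  miscalled.
* **Y loss** — called when strictly more than 60% of Y probes report zero
  copies. The lenient, strict-inequality rule reflects that a sizeable
  minority of Y-array probes cross-hybridize with X-homologous sequence and
  report non-zero copy even when no Y is present.
* **Assessability** — each call needs at least `min_probes` (default 50)
  informative probes; below that the result is `NA`, which downstream code
  treats as "not assessable", never as `FALSE`.

`summarize_panel_loh()` aggregates calls into per-chromosome LOH
percentages by sex, their male/female correlation, and an ordinary
least-squares regression of autosomal LOH on chromosome length. The
regression's prediction for a chromosome the size of the X is the yardstick
against which the X's actual loss rate (~37% in female lines) stands out.

## Counting active X chromosomes

Active X's can only be counted where every X present can be assumed
active. XIST — the lncRNA expressed from, and silencing, the inactive X —
is the marker: a line with silent XIST (log2 array intensity below 5) and k
X copies has k active X's. Male lines qualify whenever XIST is silent
(genotypes Xa[Y] and XaXa[Y]); female lines qualify only after whole-X LOH
(XaO, or XaXa isodisomy), because XaXb females retain an XIST-expressing Xi
that makes the count ambiguous — they are classified but excluded from
karyotype tallies. XIST does not spontaneously activate in culture, so
silence is informative. Autosome ploidy n_A is the copy number shared by a
supermajority (default 70%) of the 13 largest autosomes, the set that
evolves cohesively; smaller autosomes are too erratic to vote.

Karyotype labels are tallied into four clusters centred on the dominant
genotypes — x1 ~ C(1:2), x2 ~ C(2:2), x3 ~ C(2:3), x4 ~ C(2:4) — with
adjacent minor genotypes folded in and C(1:3), adjacent to two clusters,
split half-and-half. The mapping ships as a YAML file
(`system.file("extdata", "cluster_map.yaml", package = "karyoevolve")`)
and labels outside it count toward an explicit residual rather than being
guessed into a cluster.

## The X:autosome expression ratio

`compute_exa()` defines E_X/A as the ratio of the median expression of
expressed X-linked genes to that of expressed autosomal genes, per line.
Two numerical choices matter:

* The ratio is taken on the **linear** scale (array log2 intensities are
  un-logged first). A ratio of medians of logs is not a dosage ratio, and
  dosage is the quantity of interest.
* The expressed gene set is chosen once, by median signal across reference
  lines (inclusive cutoffs: log2 ≥ 5 for arrays, RPKM ≥ 1 for RNA-seq),
  and reused unchanged for other lines. Selecting the set on normal lines
  guards against inflation by X-enriched genes that are silent in normal
  tissue but awaken in tumours. Raising the cutoff can only shrink the
  set (monotone filtering). XIST is excluded from the X set — it reports
  Xi presence, not dosage.

The per-line ratio is reported (a group-level E_X/A could also be defined
as a pooled ratio; per-line is the default because it gives a
distribution, and the two agree closely on synthetic panels).
`x_dosage_de()` contrasts X-linked expression between Xa[Y] and XaXa[Y]
lines gene by gene with two-sided Welch t-tests, reporting both raw-p
flags at 0.05 (the per-gene annotation convention) and
Benjamini–Hochberg-adjusted flags.

## Cohesion of the autosome set

If each of the 13 largest autosomes gained copies independently, the
number gaining x extra copies in a clonal subline would be
Poisson(lambda). Cohesive evolution — gains added one chromosome at a
time, with the pairwise difference Delta_ij tolerated at 1 but not 2 —
instead packs the gains into at most two adjacent values, producing an
excess at x = 1 whenever lambda < 1. `poisson_chisq()` compares the
observed {0, 1, >=2} histogram to its Poisson expectation:

* Bins are {0, 1, >=2}; merging the tail keeps expected counts usable at
  n = 13 chromosomes.
* The Poisson mean per subline is its maximum-likelihood estimate, the
  sample mean of the gains.
* Pooled tests sum per-subline expectations (a mixture of Poissons, one
  lambda-hat each) and are restricted to sublines with lambda-hat < 1,
  where the two hypotheses differ most.
* Degrees of freedom: with k occupied bins and m means estimated from the
  same data, df = k − 1 − min(m, k − 2), never below 1. With three bins
  this gives df = 1 for both single and pooled tests. The exact chi-square
  variant behind any particular published p-value is rarely stated, so the
  package treats calibration as the testable property: under
  independent-gain simulation the pooled test's type-I error at alpha =
  0.05 sits near nominal (checked at 2,000 replicates in the test suite),
  and under cohesive simulation it rejects in essentially all panels of
  five sublines.
* Fractional (depth-based) copy estimates are rounded to the nearest
  integer before gains are formed; copies below 2 raise an error because
  losses are outside the model.

## The karyotype-cluster Markov chain

Genotypes are grouped into clusters and transitions allowed between
neighbours: the X count changes at rate u per unit time, the autosome set
at the slower rate v (default u = 10v; results are insensitive to the
ratio). Back-multipliers a, b, c > 1 encode that gain/loss probability
grows with chromosome number. The neutral 3-state chain has transition
matrix

$$M = \begin{pmatrix} 1-u & u & 0 \\ au & 1-au-v & v \\ 0 & bv & 1-bv \end{pmatrix}$$

and closed-form equilibrium [ab, b, 1]/z with z = ab + b + 1 — independent
of u and v. Two consequences drive the neutrality test: with a, b > 1 the
equilibrium ordering is x1 > x2 > x3, and x3 < 1/3 at equilibrium *and*
along the whole trajectory from X(0) = [1, 0, 0] (verified numerically on
a parameter grid; the trajectory of x3 rises monotonically toward its
equilibrium). An observed x3 of 0.482 therefore cannot be reached by any
neutral history, at any time, for any admissible a, b — this is the
rejection of neutrality, and `neutrality_test()` reports the supremum it
actually searched.

### Selection

The 4-state model adds C(2:4) (reached from C(2:3) at rate v, left at
c·v; c defaults to b by the same more-chromosomes-change-more principle)
and fitnesses W = [1, 1+s, 1+t, 1]. Selection enters through an expanded
transition matrix followed by a normalization step: each neutral
transition probability M_ij is weighted by the destination fitness W_j and
rows are renormalized. The resulting chain is tridiagonal and reversible;
to first order in the rates its stationary vector is proportional to

$$\left[1,\; \frac{1+s}{a},\; \frac{1+t}{ab},\; \frac{1}{abc}\right],$$

which collapses to the neutral [ab, b, 1]/z when s = t = 0. This
formulation was chosen over the textbook per-generation
mutation-then-selection vector iteration (kept available as
`update = "population"`) for a substantive reason: with |s|, |t| of order
0.5 and rates of order 0.01, the vector iteration drives essentially all
equilibrium mass onto the fittest cluster, which is not the regime the
observed frequencies live in, whereas the transition-weighted chain
reproduces both the neutral closed form and the observed equilibrium
structure (x1 > x3 > x4 > x2 at s = −0.5, t = 0.5).

Equilibria are computed by fixed-point iteration (tolerance 1e-12, capped
at 1e6 iterations) and cross-checked against the dominant left eigenvector
of the chain; the eigen route is exact for this small matrix and is used
as the fast path inside grid fitting. With convergence governed by the
spectral gap (order v), iterate/eigen agreement is asserted at 1e-8.

### Fitting s and t

No fitting procedure accompanies the original model-to-data comparison,
so the package supplies one as its own extension: squared-error loss
between the model state (equilibrium by default, or X(T) for a finite
horizon) and the observed 4-cluster frequencies, scanned on an (s, t)
grid over [−0.9, 2] (step 0.05) and refined with Nelder–Mead inside the
bounds. Because the scientific question is directional, the fit also
reports the best loss attainable under the constraints s ≥ 0 and t ≤ 0.
For the observed cluster vector both constrained losses are several-fold
worse than the unconstrained fit — the numerical form of "s < 0 and t > 0
are necessary". A caution on single-ratio shortcuts: as rates shrink, the
stationary ratios approach b((1+s)/(1+t))², so x2 < x3 alone does not
force s < 0; only the joint fit of all four frequencies does.

## What the synthetic generator emulates — and what it does not

`generate_panel()` plants a C(Xa:A) karyotype per line (default
frequencies chosen so the cluster tally reproduces the observed
[0.374, 0.087, 0.292, 0.128] with 0.119 of marginal genotypes; only
cluster sums are observable, so the within-cluster split is a modelling
choice), then synthesizes probe tables and expression consistent with it:

* 620 lines (279 female, 341 male), 500 probes per chromosome, autosomal
  LOH at base rate 0.13 declining with chromosome length (slope −3e-4 per
  Mb), whole-X LOH in 37% of female lines, Y loss in 40% of male lines.
* Probe genotypes AA/AB/BB with per-probe heterozygosity 0.3 on non-LOH
  chromosomes; probes are exchangeable within a chromosome (no spatial
  structure is modelled).
* Expression: per-gene log2 intensities ~ Normal(8, 1), autosomal genes
  shifted by log2(copy/2), X-linked genes by log2(Xa count) plus a
  constant offset of log2(0.84) — the dosage-compensation level of
  karyotypically normal lines, so a pure C(1:2) panel centres near
  E_X/A = 0.84 and dosage ratios between karyotype groups are linear in
  Xa/(n_A/2). XIST sits at 9 when an Xi is present and 2 otherwise,
  placing it far from the log2 = 5 cutoff.
* A single seed drives one generator per panel; the draw order (sexes,
  karyotypes, LOH flags, X-LOH, Y-loss, then per-line probes and finally
  expression) is fixed, so outputs are reproducible across versions.

Deliberately not emulated: sub-chromosomal segments, within-line cell
heterogeneity, sequencing reads, and chromosome-specific LOH biology
beyond length. The last point matters for interpretation: in real panels
the male/female correlation of per-chromosome LOH percentages is very
high because both sexes share strong chromosome-specific propensities;
in synthetic panels the only chromosome effect is length, so that
correlation is attenuated by binomial noise. Passing tests therefore
certify the calling and modelling machinery, not the realism of
chromosome-specific LOH variation.

Subline profiles (`generate_sublines()`) emulate depth-based per-
chromosome copy counts of clonally expanded sublines in two modes:
independent Poisson gains (truncated at +2 so copies stay in 2–4) and
cohesive assignment of a gain total one chromosome at a time, always to a
currently-minimal chromosome, so Delta_ij never reaches 2. Chromosomes
14–22 and the X stay at baseline — the cohesion constraint is loosened
for small autosomes, and the model does not use them.

## Problem sizes and reproducibility

The test suite and the acceptance script regenerate everything from
seeds: the full 620-line default panel for cluster frequencies; 60–200
line panels for recovery, dosage and differential-expression checks;
2,000 independent-mode replicates for test calibration and 200
cohesive-mode replicates for power; 200 multinomial resamples of 444
lines for selection-sign recovery. These sizes were chosen to keep Monte
Carlo error well below the effect sizes being checked. `run_pipeline()`
writes a manifest (config hash, seed, package version) next to its
outputs, and identical seeds give byte-identical outputs.

The user-facing interface of the pipeline is the exported functions plus
`run_pipeline()`; there is no shell executable because users of an
analysis package of this kind drive it from R scripts.

## Known limitations

* The cluster composition of published tallies cannot be re-derived from
  printed cluster sums alone; the generator's within-cluster split is a
  choice, documented above.
* The neutrality argument is a numerical supremum over a parameter grid
  and a log-spaced time scan, not a symbolic proof; the grid and scan are
  exposed as arguments.
* The selection model compares karyotype clusters, not individual
  chromosomes, and makes no attempt to estimate the absolute strength of
  selection — the time-in-culture vT of any given line is unknown, so
  only the direction of s and t is identified.
* Copy-number calling is whole-chromosome by design; segmental
  aneuploidy is out of scope.
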