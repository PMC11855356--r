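---
title: "Separating incomplete lineage sorting from introgression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating incomplete lineage sorting from introgression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a plastid (or mitochondrial) phylogeny places a lineage somewhere the
nuclear gene trees do not, two very different histories can be responsible:

* **Incomplete lineage sorting (ILS)** — ancestral polymorphism persisting
  across short internodes, so that individual gene genealogies disagree
  with the species tree even without any gene flow; and
* **Introgression** — hybridization followed by backcrossing, which moves a
  fraction of one lineage's genome into another.

`phydisc` implements the inference machinery used to separate the two in a
cyto-nuclear discordance setting such as the placement of *Xanthoceras*
within Sapindaceae: multispecies-coalescent (MSC) simulation of gene trees
on species trees and on networks with inheritance probabilities,
concordance and tree-distance statistics with a rank test, site-pattern
invariants detection of hybridization with a moment estimator of the
inheritance probability $\gamma$, and a triplet branch-length mixture model
that attributes gene-tree conflicts to ILS or to introgression.

The package operates on trees and alignments (newick, FASTA, relaxed
PHYLIP); it deliberately does not infer trees, date them, or search for
networks — those are upstream or downstream tools' jobs.

## Gene-tree simulation under the MSC

`simulate_gene_trees()` runs the standard coalescent-within-species-tree
model. Time is measured from the tips (0) toward the root in coalescent
units (one unit = 2N generations), so within any species-tree interval
containing $k$ gene lineages the waiting time to the next coalescence is
exponential with rate $k(k-1)/2$. Lineages that fail to coalesce by the top
of an interval are handed to the parent edge; above the root, coalescence
continues until a single lineage remains. The classic check — and a test
the suite runs — is the rooted-triplet concordance probability
$1 - \tfrac{2}{3}e^{-\tau}$ for an internal branch of $\tau$ coalescent
units.

Species networks add *pulse* introgression: at a fixed event time, every
lineage present on the recipient edge independently routes to the donor
edge with probability $\gamma$ (the donor's inheritance probability); the
two parental probabilities are $\gamma$ and $1-\gamma$ by construction.
A pulse, not continuous migration, is the appropriate model for a single
ancient hybridization event. One lineage is sampled per species by default
(a species-level analysis); per-species counts are configurable.

Sequences evolve along the simulated gene trees under Jukes–Cantor via
`simulate_alignment()` (delegated to `phangorn::simSeq()`): the root
sequence is uniform over the four nucleotides and along an edge of length
$t$ each site changes with total probability
$\tfrac{3}{4}\bigl(1 - e^{-4\mu t/3}\bigr)$, $\mu$ being the substitution
rate per site per coalescent unit.

### The hybrid-quartet scenario

`xanthoceras_scenario()` builds the rooted quartet $(((P1,H),P2),O)$ used
throughout the package's synthetic experiments: $P1$ and $P2$ diverge at
depth 2.0 coalescent units, the outgroup $O$ at 3.0, and the putative
hybrid $H$ attaches at time 1.0 to the $P1$ edge with probability
$1-\gamma$ and to the $P2$ edge with probability $\gamma$. The depths are
deliberately **symmetric**: whichever parent $H$ follows, the quartet
internal branch spans the same interval $[1, 2]$, so the two parental gene-
tree classes share their site-pattern probabilities with the roles of $P1$
and $P2$ exchanged. That symmetry is what makes the moment estimator of
$\gamma$ (below) exact in expectation, and it is why these depths — rather
than any empirical divergence times, which are not in coalescent units —
define the scenario.

Defaults are 2000 loci of 500 bp at $\mu = 0.02$ substitutions/site per
coalescent unit. At these settings roughly 2.5% of sites are classifiable
polarized patterns — enough for a decisive Z-score — while per-branch
expected substitutions stay low ($\le 0.06$), keeping homoplasy and
polarization error second-order.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses assume: free
recombination between loci, none within a locus; a single pulse of gene
flow; equal base frequencies; no rate variation among sites, branches, or
loci; no missing data or alignment error. Passing the recovery tests
therefore demonstrates correctness of the estimators under their own
model, not robustness to the many ways real transcriptome data violate it
(orthology errors, alignment noise, heterotachy, gene flow elsewhere in
the tree).

## Discordance statistics

`rf_distance()` computes the Robinson–Foulds distance as the symmetric
difference of **unrooted** non-trivial bipartition sets; root placement
never changes it, and a `rooted = TRUE` flag exposes the clade-based
alternative for users who want rooted semantics. Multifurcating inputs
simply contribute fewer bipartitions; nothing is randomly resolved.
`distance_distribution()` maps a set of gene trees to one RF value each
(restricting to the species-tree leaf set and skipping, with a warning,
trees that lack required taxa), and `mann_whitney_u()` compares an
empirical with a simulated distribution: the p-value is exact by full
enumeration when both samples have at most 8 tie-free observations, and
otherwise uses the normal approximation with midrank ties, tie-corrected
variance, and continuity correction. The decision rule is the usual one:
$p \ge 0.05$ fails to reject the ILS-only null.

`concordance_fraction()` reports how often gene trees agree with a
reference topology in two modes, both first-class: **full** (the
restricted topology matches exactly) and **split** (the gene tree contains
one focal bipartition). When the scientific question is where a single
lineage attaches — as with a plastid placement — the split mode is the
faithful reading, and the full mode is the stricter alternative; reports
label which was used. `node_concordance()` classifies every gene tree at
every species-tree split as concordant, conflicting (two splits conflict
iff all four pairwise intersections are non-empty — the usual PhyParts
semantics), or uninformative (missing taxa or unresolved restriction), and
the three counts sum to the number of gene trees at every node.

## Site-pattern invariants and the $\gamma$ estimator

`count_site_patterns()` polarizes each site of a quartet alignment by the
outgroup allele and counts sites where the ingroup trio is biallelic with
exactly two taxa sharing the derived state: BBAA ($P1,H$), ABBA ($H,P2$),
BABA ($P1,P2$). Sites with a gap or N in any of the four taxa are skipped.
Under a two-topology mixture with equal internal branches — pattern
probabilities $f_{\mathrm{BBAA}} = (1-\gamma)C + \gamma d$,
$f_{\mathrm{ABBA}} = (1-\gamma)d + \gamma C$, $f_{\mathrm{BABA}} = d$ —
the moment estimator

$$\hat\gamma = \frac{f_{\mathrm{ABBA}} - f_{\mathrm{BABA}}}
                    {f_{\mathrm{BBAA}} + f_{\mathrm{ABBA}}
                     - 2 f_{\mathrm{BABA}}}$$

returns $\gamma$ exactly, for any concordant-class excess $C > d$; under
the no-introgression null $f_{\mathrm{ABBA}} = f_{\mathrm{BABA}}$ and
$\hat\gamma = 0$. Swapping the parental roles estimates $1-\gamma$, the
complementary contribution of the other parent. This is the package's own
Patterson's-D-style estimator; reproducing any particular tool's invariant
algebra is out of scope, and symmetric extra classes (homoplasy noise)
cancel from both the numerator and the denominator.

The standard error comes from a multinomial bootstrap of the classified
site counts (default $B = 200$; deterministic given a seed), $Z =
\hat\gamma/\mathrm{SE}$, and the p-value is the one-sided upper tail of the
standard normal — the question being whether $\gamma$ deviates upward from
zero. `triple_scan()` tries every ingroup taxon as the hybrid for every
unordered triple ($3\binom{k}{3}$ tests), canonicalizing the parental order
so $\hat\gamma \ge 0$ (the swap is recorded), and the significance filter
retains results with $0 < \hat\gamma < 1$, $p < 0.05$, $Z > 3$. A zero
denominator yields an NA sentinel that the filter removes; a zero SE
yields $Z$ = NA with $p = 1$ and a warning.

## The triplet branch-length mixture

For a triplet $\{A,B,C\}$, `extract_triplet_branches()` roots each gene
tree with the outgroup, restricts to the triplet, classifies it by its
sister pair, and records the internal branch length (zero-length branches
are dropped with a count; polytomies are tallied as unresolved). Under
ILS, discordant-class internal branches are exponential; a speciation or
introgression event adds a fixed waiting time. `fit_mixture_em()` fits

$$f(x) = \pi_1 \frac{1}{\theta} e^{-x/\theta}
       + \pi_2 \frac{1}{\theta} e^{-(x-\delta)/\theta}\,
         \mathbf{1}[x \ge \delta],$$

with $\pi_1 + \pi_2 = 1$. Both components share one scale $\theta$: the
minimal model in which the shift $\delta$, not a second free scale,
carries the signal. Model choice is by BIC against the one-component
exponential ($k = 1$ vs $k = 3$ parameters, $n$ = class size), and
`call_introgression()` keeps discordant-topology classes with
$\Delta\mathrm{BIC} < -30$; a shift on the *concordant* class is read as
speciation, never introgression. The mean $\pi_2$ across discordant
classes summarizes the introgression contribution to gene-tree conflict.

EM details, which matter for this model: initialization is fixed and
deterministic ($\pi_2 = 0.5$, $\delta$ = median, $\theta$ = mean/2);
$\pi_2$ and $\theta$ have closed-form M-steps. The shift is the delicate
parameter: maximizing the *expected complete-data* log-likelihood over
$\delta$ is degenerate, because its gradient is a positive constant and
points below $\delta$ carry zero responsibility, so that update can only
push $\delta$ upward — a too-high start could never recover. The package
therefore updates $\delta$ by a damped line search over a 101-point
quantile grid of the *observed* log-likelihood (damping factor
`gradascentscalar`, default 0.5), accepting a move only if the observed
log-likelihood does not decrease. This keeps the EM sequence monotone,
allows $\delta$ to move in both directions, and, because the
one-component model is nested at $\delta = 0$, the final fit is never
worse than the exponential fit (a degenerate fallback guarantees it).
Iteration stops after `numsteps` (default 50) or when the improvement
falls below `likelihoodthresh` (default 0.01). On the reference fixture —
60% Exp(1) plus 40% shifted by $\delta = 1$, $n = 5000$ — the fit agrees
with a $50^3$ grid-search ML oracle to within 0.05 in $\pi_2$, and pure
exponential data of $n = 2000$ essentially never reach
$\Delta\mathrm{BIC} < -30$.

## Tunable parameters

| parameter | default | units / domain | why |
|---|---|---|---|
| stripping threshold | 0.2 | gap fraction per column | columns with more than 20% gaps are removed (exactly 20% is kept: the threshold reads as a tolerance); N counts as missing |
| bootstrap $B$ | 200 | replicates | SE stable to ~5% while keeping all-triples scans cheap |
| significance filter | $0<\hat\gamma<1$, $p<0.05$, $Z>3$ | — | the standard hybridization-detection filter |
| $\Delta$BIC threshold | $-30$ | — | decisive-evidence cutoff for the two-component model |
| EM `numsteps` / `likelihoodthresh` / `gradascentscalar` | 50 / 0.01 / 0.5 | — | standard defaults of the triplet-mixture analysis |
| scenario $\mu$ | 0.02 | subst./site per coalescent unit | informative-site yield vs saturation trade-off (see above) |

Every stage takes an explicit seed; one top-level seed fans out to
per-stage seeds by a fixed affine map, so stages can be rerun
independently and identical configs give byte-identical outputs.

## Numerical choices and degenerate inputs

Missing branch lengths parse as absent, never as zero. The newick dialect
is plain: unquoted labels, lengths after `:`, no NHX or quoted-whitespace
labels. Round trips preserve lengths to 10 significant digits. Bipartition
keys canonicalize each split by the side not containing the
lexicographically smallest leaf, so a split equals its complement.
`estimate_gamma()` returns NA on a zero denominator rather than guessing;
`z_test()` reports $p = 1$ with a warning when the bootstrap SE is zero;
mixture classes with fewer than 5 usable branches are skipped with a note.
Hybrid event times are validated against both edges' time spans, and
routing at an edge's top boundary happens before the speciation merge at
the same instant.

## Scale of the shipped experiments

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which the statistical claims
are sharp: 100,000 replicates for closed-form coalescent checks, 2000
loci × 500 bp for the $\gamma = 0.16$ recovery (estimator spread ~0.013),
20 replicates of 500 loci for the null calibration, and $n = 5000$ for the
mixture-recovery fixture. Empirical quantities that depend on the original
transcriptome and plastome data (per-node concordance percentages,
divergence dates, locus counts) are outside what synthetic data can
certify and are exercised only as pipeline-shape tests.

## Known limitations

* JC69 only; no rate heterogeneity, indels, or base-composition bias.
* Pulse introgression only; continuous migration and repeated pulses on
  one edge are not modeled.
* The invariants estimator assumes the symmetric two-topology mixture; on
  asymmetric histories it remains a consistent *detector* (the null
  $f_{\mathrm{ABBA}} = f_{\mathrm{BABA}}$ still holds) but $\hat\gamma$
  is then a biased point estimate.
* The mixture model shares one scale between components; data whose
  discordant classes have genuinely different scales will load the
  difference onto $\delta$ and $\pi_2$.
* Branch-length units of input gene trees are taken as given; no
  conversion between substitutions/site and coalescent units is
  attempted.
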