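---
title: "Full factorial consortium assembly and landscape analytics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full factorial consortium assembly and landscape analytics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consortia)
```

This vignette is the package's account of its own methods: the model behind
the assembly protocol, the conventions and tunable parameters of the
analytics, the design choices made where more than one reasonable option
existed, and the limits of what the synthetic-data tests demonstrate.

## The assembly model

Every consortium from an $m$-strain library is a binary number
$c = x_m x_{m-1}\cdots x_1$, $x_k \in \{0,1\}$ marking the presence of
strain $k$. Two properties carry the whole design:

* **Disjoint merges are additions.** If two consortia share no strain,
  the code of their union is the sum of their codes. Adding one strain to a
  whole block of consortia is therefore a single (multichannel) addition,
  which is what collapses the naive $m\,2^{m-1}$ pipetting events into a
  few hundred.
* **Row/column bit split.** Plates with $2^r$ rows ($r = 3$ for 96-well,
  $r = 4$ for 384-well) let the low $r$ bits of $c$ index the row and the
  high bits the global column: $c = (j-1)\,2^r + (i-1)$. Consequently
  strain $k \le r$ occupies alternating sets of $2^{k-1}$ rows and strain
  $k > r$ alternating sets of $2^{k-r-1}$ global columns, and the Hamming
  weight (richness) splits positionally,
  $H(c) = H(B(i-1)) + H(B(j-1))$ — the identity that lets buffer be
  dispensed column-wise and row-wise rather than well by well.

Global columns beyond the physical plate width continue on further plates
(`plates_required()`); for $m < r$ the whole design lives in the top
$2^m$ wells of column 1. Row letters map A (top) to $i = 1$; wells are named
letter plus zero-padded column number ("C02") — the padding is a
convention, chosen for lexicographic sorting.

### Density homogenization

Pipetting a fixed volume $v_0$ of every member's monoculture leaves the
per-strain density varying as $1/H(c)$ across consortia. Homogenization
tops each well up with buffer volume $v_B(c) = v_0\,(m - H(c))$, bringing
every well to $m\,v_0$ total so that each member sits at $1/m$ of its
monoculture density everywhere. Using the positional split, the buffer is
applied as a column term $v_0\,[m - r - H(B(j-1))]$ and a row term
$v_0\,[r - H(B(i-1))]$; the row term can be folded into the starting mixes
(below), which removes the row-wise pipetting pass entirely. The buffer
identity (water, PBS, medium) is a label only — no chemistry is modeled.

### Two planning strategies

`plan_assembly()` supports two ways to realize the layout, both verified by
the transfer simulator:

* **`direct_dispense`** (default). The $2^r$ combinations of the row
  strains are prepared once in tubes, each sized for all
  $n_\mathrm{cols} = 2^{m-r}$ columns, with the row-term buffer included in
  the tube under full homogenization. The mixes are dispensed
  multichannel-wise into every column ($r\,v_0$ per well), the column
  strains $k > r$ are added column-wise per the placement rule, and the
  column-term buffer closes each column. Per-well volumes never exceed
  $m\,v_0$, and the resource list (for $m = 8$: three 96-well plates and
  eight tubes) matches what one would stage at the bench.
* **`block_duplication`.** The literal column-doubling scheme: assemble the
  row-strain combinations in column 1, then for each further strain
  transfer half of every existing column into a fresh column, add the
  strain to the copies, and re-buffer the originals. To end at $v_0$ per
  member, column 1 must start at $2^{m-r}$-fold scale, so first-column
  volumes grow as $2^{m-r}\,v_0$: the scheme is faithful to the doubling
  narrative and correct for small $m$, but exceeds any realistic well
  capacity for large $m$. The planner does not hide this — it raises a
  capacity error naming the failing step.

The invariant behind the halving schedule: before the round that introduces
strain $k$, every existing well holds $2^{m-k+1} v_0$ per member and
$2^{m-k+1} v_0 (k\!-\!1\!-\!H)$ of buffer. Halving and adding strain $k$ at
$2^{m-k} v_0$ preserves it for the copies with no extra buffer; the
originals need exactly $2^{m-k} v_0$ of buffer — the same volume the copies
received as strain.

`homogenize = "column_only"` (column-term buffer only) is supported for
`direct_dispense`; combined with `block_duplication` the per-row totals
diverge and no halving schedule reproduces the endpoint, so the
configuration is rejected rather than approximated.

### The transfer simulator as oracle

`simulate_transfers()` executes the elementary transfers in order, tracking
per-well monoculture-equivalent volumes per strain plus buffer, moving
composition proportionally for mixed-content (tube/well) sources, and
enforcing source sufficiency and well capacity. Every plan the package
emits must simulate to the exact layout composition — that check runs
inside `plan_assembly()` itself. All planned volumes are $v_0$ times powers
of two and all transfer fractions are powers of two, so the arithmetic is
exact in double precision; verification tolerances (1e-6 µL) are therefore
formalities. Default `well_capacity` is 300 µL, a standard 96-well working
volume; it is a parameter, not a constant.

Tip-count estimates are one tip set per multichannel event and one tip per
single-channel event — an estimate, since re-use policies differ between
labs. Tube working volumes are unconstrained: only the well endpoint is
authoritative.

## Spectral deviations

`additive_expectation()` sums constituent monoculture spectra on a shared
wavelength grid (no interpolation: plate readers measure all samples on one
grid, so a mismatch indicates a data problem, not something to smooth
over). `spectral_deviations()` computes the relative deviation
$\delta(c,\lambda) = |A - A^{(\mathrm{add})}| / A$ with the *empirical*
spectrum in the denominator, masked to `NA` where $A \le 0.1$ A.U. (the
ratio is unstable near zero); absolute deviations are kept everywhere.
Replicates are averaged per (sample, wavelength) before the comparison —
the deviation is defined on one spectrum per mixture. Headline summaries
pool all unmasked (mixture, wavelength) points of mixtures with $\ge 2$
constituents with equal weight; per-mixture-first weighting was the
alternative, and the pooled choice is exposed by the `group_by = "sample"`
summary for anyone who prefers to reweight.

## Landscape conventions

`function_landscape()` stores replicate-level values and works on replicate
means. Conventions, each of which had a genuine alternative:

* **Empty consortium.** If the blank row is measured it is used; otherwise
  $F(\varnothing) = 0$ with a warning. Background-referenced formulas stay
  defined either way, and the warning keeps the substitution visible.
* **Ranking ties** break by code integer, ascending — the ranking is
  illustrative, so any deterministic rule suffices; determinism is the
  requirement.
* **Incompleteness** is an error that names the missing codes, not a silent
  `NA`: every interaction formula is a signed sum over a sub-lattice, and a
  missing corner invalidates it.

Effects and interactions are plain finite differences on the hypercube:
$\Delta F_k(b)$, $\varepsilon_{ij}(b)$ (four corners), and the third-order
term as the alternating inclusion–exclusion sum over the $2^3$ sub-lattice.
"Interaction" is statistical, not mechanistic: the additive baseline is a
minimal-assumptions null, nothing more. Orders above three are handled only
through the variance decomposition, where they are well defined without
choosing a generalization of the background-referenced formulas.

## Variance by interaction order

The decomposition uses the orthogonal Walsh–Hadamard basis
$\phi_S(c) = (-1)^{|S \cap c|}$ on the complete $\{0,1\}^m$ cube:
coefficients $a_S = 2^{-m}\sum_c F(c)\,\phi_S(c)$ via a fast transform, the
fraction at order $r$ being $\sum_{|S|=r} a_S^2$ normalized over all
$|S| \ge 1$. This is the standard variance partition for complete
landscapes; the main alternative — background-averaged Taylor coefficients —
differs only in basis normalization and is deliberately isolated behind
`walsh_coefficients()` so the basis could be swapped without touching the
fractions' plumbing. Fractions are computed on replicate means, so
measurement noise contributes variance (mostly at high orders, since noise
is incoherent across the basis); decomposing means rather than modeling the
noise explicitly is a documented choice, visible in the tests as a
stochastic trend check. A landscape with (numerically) zero variance gets
`NA` fractions and a warning rather than a 0/0.

## Global epistasis

`global_epistasis_fit()` regresses $\Delta F_k(b)$ on $F(b)$ by ordinary
least squares over all $2^{m-1}$ backgrounds. Conventions: $R^2 = 0$ when
the response is constant (a purely additive landscape is "perfectly
predictable", but not by the background function, and reporting $R^2 = 1$
there would be misleading); a constant predictor yields an `NA` slope with
$R^2 = 0$.

The null model (`epistasis_null()`) permutes the replicate-mean values
across consortia: it preserves the value distribution exactly while
destroying all composition–function structure. The statistic is the mean
$R^2$ across strains. Note the null mean $R^2$ is well above zero even for
random landscapes — $\Delta F_k(b)$ and $F(b)$ share the term $F(b)$, which
induces correlation by construction — which is precisely why a null
comparison, not an absolute $R^2$ threshold, is the honest test. `B`
defaults to 1000 and the seed is mandatory; the exact randomization choice
(permutation) is recorded in the result object.

## Synthetic data: what it does and does not show

`generate_spectra()` emulates a colorant-style validation: smooth
single-peak Gaussian "colorant" spectra on a 380–780 nm grid, mixtures
formed as $\sum_k (1+\eta_k)\,A_k(\lambda)$ with independent multiplicative
aliquot noise $\eta_k \sim N(0, \mathrm{cv})$. The default
$\mathrm{cv} = 0.0075$ sits mid-range of typical 0.5–1 % micropipette
error. `generate_landscape()` plants subset coefficients in the presence
basis — $F(c) = \sum_{S \subseteq c} \beta_S$ plus replicate noise — chosen
over the $\pm 1$ basis because the package's $\varepsilon$ definitions are
background-referenced differences: a planted pair coefficient is then
*exactly* the recovered $\varepsilon$ in every background at zero noise,
which makes recovery tests sharp rather than approximate.
`generate_epistatic_landscape()` builds
$F(c) = (f_0+\alpha)\prod_{k \in c}(1+s_k) - \alpha$, on which every
strain's effect is exactly linear in the background function ($R^2 = 1$) —
a positive control for the null comparison.

What the generators do **not** emulate: growth dynamics (no
Lotka–Volterra or consumer–resource structure), instrument nonlinearity at
high absorbance (the absorbance–biomass relation is only linear at low
values), plate-position effects, or correlated pipetting errors within a
multichannel stroke. Passing tests therefore certify the *calculus* —
encodings, plans, deviations, interaction recovery, decomposition,
regressions — on data with the statistical structure the analyses assume,
not the biology of any particular system.

## Problem sizes and numerical choices

The shipped tests run exhaustive layout checks for $m \le 10$, full planner
simulations at $m = 8$ (256 wells), interaction recovery at $m \le 6$, and
the permutation null at $m = 5$ with $B = 200$ — sizes chosen to keep the
whole suite under a minute of compute while still covering every multi-plate
and capacity-boundary branch. Tolerances: exact-recovery assertions at
1e-10–1e-12 (the arithmetic is exact; the tolerance absorbs accumulated
rounding), variance-fraction unit-sum at 1e-9, Monte-Carlo comparisons at
10 %. Volumes are reported to 0.1 µL in exports while kept exact
internally.

## Known limitations

* Plans target generic CSV worklists, not vendor robot dialects; no
  dead-volume or evaporation modeling, no scheduling optimization.
* Partial (non-full-factorial) landscapes are accepted as containers but
  most analytics require completeness by design.
* Interaction formulas above order three are intentionally not provided
  outside the variance decomposition.
* The 384-well generalization follows the same bit-split with four row
  bits; it is tested combinatorially, not validated at the bench.
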