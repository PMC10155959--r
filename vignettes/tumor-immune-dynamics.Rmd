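---
title: "Coupled tumor immunopeptidome and CTL repertoire dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled tumor immunopeptidome and CTL repertoire dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoprey)
```

## The model

`immunoprey` simulates a tumor and the adaptive immune response against it
as a predator-prey-like system. The prey side is a set of cancer cell
lineages; the predator side is a set of antigen-specific cytotoxic
T-lymphocyte (CTL) clones plus one pooled, tumor-ignorant CTL population.
The two sides are coupled through the tumor *immunopeptidome*: the set of
neoantigens a lineage actually presents, which is the product of a
per-neoantigen expression flag `E` and the intactness of the presenting MHC
allele.

**Tumor.** Each lineage $i$ grows logistically with a lineage-specific death
rate:
$$\frac{dN_i}{dt} = k_g N_i \left(1 - \frac{N}{K}\right) (1 - k_{d,i}),$$
where $N = \sum_i N_i$. The death rate combines natural turnover with
saturable CTL killing driven by the fraction $\phi_i$ of CTLs reactive
against the lineage's immunopeptidome:
$$k_{d,i} = f_{die} + (k_{mag} + 1 - f_{die})
  \frac{\phi_i k_{kill}}{1 + (\phi_i k_{kill})^2},\qquad
\phi_i = \frac{\sum_{k \in \text{pept}(i)} CTL_k}
              {NSCTL + \sum_{k \in \text{pept}(i)} CTL_k}.$$
With the default constants ($f_{die} = 0.3$, $k_{mag} = 1$,
$k_{kill} = 0.7$) the death rate exceeds 1 — net shrinkage — only when
$\phi_i > 0.751$, i.e. when tumor-reactive CTLs outnumber tumor-ignorant
CTLs roughly three to one.

**CTLs and the shared stimulus.** Each registered neoantigen $k$ has one
cognate clone, created at $2^n$ cells with $n \sim \text{Poisson}(\mu)$:
$$\frac{dCTL_k}{dt} = CTL_k\,T_d\,(C - 1) + \text{ICB}\; S_k\, T_a\, C,$$
where $S_k = R_k \sum_i N_i E_{k,i} MHC_{k,i}$ is the
immunogenicity-weighted number of cells presenting $k$. The antigen term is
per-capita in the clone (the stimulus available to each CTL falls as the
clone grows), which makes antigen-driven influx additive rather than
exponential. The tumor-ignorant pool follows
$dNSCTL/dt = NSCTL\,T_d\,(C-1)$, and the shared nonspecific stimulus $C$
(cytokines, co-stimulation) turns over as
$$\frac{dC}{dt} = k_{in} - k_{in} f_{out} - k_{in}(1 - f_{out})
  \frac{NSCTL + \sum_k CTL_k}{\text{ICB} \cdot CTL_{ss}},\qquad C \ge 0.$$
Interclonal competition acts entirely through $C$: every clone consumes it,
so expansion of one clone suppresses all others (immunodominance).
Checkpoint blockade is a constant multiplier applied for the treatment year
to both the antigen-sensitivity term and the CTL carrying capacity.

**Neoantigens.** Feature vectors are sampled from distributions fitted to
NSCLC-derived TESLA peptides: a Gaussian copula couples log binding
affinity, log binding stability and log agretopicity (correlations
$-0.3495$, $-0.930$, $0.2041$); transcript abundance is exponential (rate
6.6625); foreignness is a zero- and one-inflated beta (masses 0.7603 at 0
and 0.0685 above 0.99, interior Beta(0.0597, 1.4404)). A neoantigen is
putatively immunogenic when it passes all four TESLA thresholds (affinity
< 34 nM, stability > 1.4 h, agretopicity > 0.1, foreignness < 1e-16, all
strict); passers draw an intrinsic immunogenicity $R$ from the exponential
density $\propto e^{-6x}$ truncated to $[0,1]$ (inverse-CDF sampling),
failers get $R = 0$.

**Stochastic immunopeptidome evolution (human presets).** Human tumors
start from one founder cell with a Gamma(1.14, scale 56.24)-distributed
clonal neoantigen burden and a 14% chance of one clonally lost MHC allele.
During growth, three event types branch lineages: neoantigen gain,
neoantigen loss and MHC allele loss. An event deducts one cell from the
parent and creates a one-cell child differing by exactly that modification;
expression and MHC flags only ever flip from 1 to 0. Gains register a new
neoantigen (fresh feature draw) and spawn its cognate CTL clone. Per-tumor
gain rates are log-normal around `nG` (one decade log-sd), with additional
day-to-day log-normal jitter.

## Numerical scheme

The simulator advances in hybrid daily steps: a deterministic flow of the
coupled ODE system over one day (adaptive multistep integration, relative
tolerance $10^{-6}$, populations floored at zero and $C$ clamped at zero; a
stiff-capable solver retries at halved step on failure), followed by the
stochastic events at the day boundary. The daily cadence matches the
parameter table, whose event rates are per day and whose gain-rate jitter
is explicitly day-to-day.

Two implementation choices matter for scale:

* **Event coalescence.** For each living lineage, each day, each event type
  fires at most once, with probability $1 - e^{-\text{rate} \cdot N_i}$ —
  the exact probability that a per-cell Poisson process of that rate fires
  at least once in the lineage that day; same-day same-type firings
  coalesce into a single branching. Uncapped per-cell event counts would
  produce tens of thousands of one-cell lineages per late-stage tumor
  (rate $\times \int N\,dt \sim 10^4$), two orders of magnitude beyond the
  few hundred unique neoantigens the model is meant to produce at 5 cm, and
  the branching would be computationally intractable at cohort scale.
* **Exact reduction of neutral clones.** Clones with $R_k = 0$ receive no
  antigen stimulus, so they satisfy $dX/dt = X\,T_d\,(C-1)$ exactly — as
  does $NSCTL$. All such clones are therefore propagated through one shared
  log-factor $\Lambda(t) = \int T_d (C-1)\,dt$ instead of individual ODE
  states. This is algebraically exact, and shrinks the ODE dimension from
  (lineages + all clones) to (lineages + immunogenic clones + 3).

The daily stepper agrees with a single fine-tolerance solve of the full
naive system (every clone explicit) to within 0.1% over 100 days; the test
suite checks this, together with the closed-form logistic solution
$N(t) = K / (1 + \frac{K - N_0}{N_0} e^{-k_g(1 - f_{die})t})$ in
immunodeficient mode.

## Parameters and presets

All published parameters are exposed under their table symbols through
`preset(name, overrides = list(...))` and YAML configs (`kg`, `f_die`,
`cellVol`, `K`, `nG`, `nGS`, `nGSt`, `g_1`, `g_2`, `nL`, `hlaL`, `hlaL0`,
`k_in`, `f_out`, `T_ss`, `TCR_other`, `T_d`, `mu`, `T_a`, `k_kill`,
`k_max`, `rho`, `lambda`, `phat_1`, `phat_2`, `alpha`, `beta`, `epsilon`).
Mouse presets (`mouse_nsg`, `mouse_c57bl6`, and MC38 variants with +50%
growth rate) hold immunopeptidomes fixed and start from a single lineage of
$4.77 \times 10^7$ cells (a 200 mm$^3$ tumor); immunodeficient presets
disable CTL dynamics entirely ($k_d \equiv f_{die}$). Human presets start
from one cell; `rcc_like` halves the growth rate and cuts the three event
rates by 90%, `msi_like` doubles the growth rate and triples the founder
clonal-burden scale (the founder distribution is the only mechanism that
sets clonal burden).

Two printed values required interpretation. The gain rate is stored as
$2.5 \times 10^{-9}$ per cell per day (the printed positive exponent is
inconsistent with the loss rate it is calibrated against). The exponential
transcript-abundance parameter is treated as a rate (mean $1/6.6625$);
both conventions are configurable.

### Choices made where the source was open

* **Copula marginals.** The log-scale marginals for affinity, stability and
  agretopicity were fitted to 146 peptides that were never published as
  parameters. The defaults are log-normal with medians 40 nM, 1 h and 1 —
  values typical of bioinformatically shortlisted candidate neoantigens,
  which are enriched for strong predicted binders. Jointly with the copula
  and foreignness model this gives an ~18% TESLA pass fraction, so a median
  founder carries a handful of bona fide immunogenic clonal neoantigens. We
  calibrated the two spread parameters once, against the reported response
  scale of the 10-fold-treatment virtual cohort (about a third of tumors
  responding), by Monte Carlo on founder panels alone; under the model's
  additive antigen-driven expansion, response requires the *summed*
  immunogenicity of clonal neoantigens to exceed roughly 2, so the response
  rate is the one output sharply controlled by this otherwise free choice.
* **Foreignness direction.** The criterion is implemented as printed
  (pass when foreignness < 1e-16, which the zero-inflated mass satisfies).
  The TESLA literature treats *high* foreignness as immunogenic, and the
  source's own cross-validation correction (an 80.6% reduction) is
  consistent with the opposite direction; `foreignness_direction = "above"`
  switches the convention.
* **Shrinkage basis.** Maximal tumor shrinkage defaults to the volume
  (cell-count) scale. The killing function caps $k_d$ at about 1.1, so
  diameter can shrink at most ~20% in a treatment year and a 30% diameter
  threshold would be unattainable; on the volume scale the same dynamics
  allow up to ~50%/year and the 30% partial-response threshold separates
  tumors as reported. `basis = "diameter"` gives the strict RECIST 1.1
  measurement.
* **Clonality counting.** `clonal_subclonal_burden()` defaults to literal
  lineage membership (clonal = present in every living lineage). Because a
  single surviving one-cell branch demotes an antigen under that reading,
  cohort analytics use the cell-weighted form (clonal = presented by at
  least 95% of living cells), which mirrors how clonality is called from
  sequencing data with a detection limit.
* **Gain-rate convention.** The log-normal per-tumor base rate is
  median-preserving (`exp(log nG + N(0, nGS))`); a mean-preserving option
  exists.
* **Tie-breaks and degenerate cases.** The rank-1 neoantigen is the highest
  R, ties broken by higher clonality then lower id; constant ELISpot panels
  scale to all-zero immunogenicity; $\phi$ is defined as 0 when no CTLs
  exist; lineages below 0.5 cells leave the dynamics (configurable).
* **Biomarker threshold.** Sensitivity/specificity for single biomarkers
  use the Youden-optimal threshold over observed values, trying both
  classification directions.

## What the generator emulates — and what it does not

The synthetic cohorts emulate the *joint feature distribution* of candidate
neoantigens, the founder clonal-burden distribution, stochastic
immunopeptidome diversification, and treatment as a constant multiplier on
CTL antigen sensitivity and carrying capacity. They do not emulate spatial
structure or metastases, T-cell exhaustion states, intratumoral versus
peripheral CTL compartments, TCR cross-reactivity, pharmacokinetics of
checkpoint inhibitors, or neoantigen re-expression and MHC recovery. Tests
passing on these cohorts show that the implementation reproduces the
*model's* behavior under its stated conditions — not that the model
captures any particular patient population.

## Problem sizes used in the test suite

The packaged tests exercise distribution recovery at $10^5$ draws,
35-day mouse runs against the analytic logistic, 100-day stepper-vs-oracle
comparisons, and cohort-level sign checks on 50 NSCLC-like tumors grown to
5 cm and treated for one year at 10-fold strength (subsets of 10 tumors for
the 2- and 6-fold arms) plus 10 RCC-like tumors — sizes chosen to keep the
full suite in the tens of minutes on a single core while leaving the
stochastic sign tests well clear of boundary cases. Cohort growth runs use
a 2200-day horizon (4200 for the slower RCC-like tumors) with the
projected-arrival stop, so tumors that cannot reach treatment size within
the horizon are pruned as immune-controlled without simulating the full
window. `simulate_cohort()` runs full 100-tumor cohorts at any strength
when more than sign-level resolution is wanted.

## Worked example

```{r example, eval = FALSE}
pan <- generate_fixture("bbn963", seed = 1)
nsg <- run_mouse(preset("mouse_nsg"), pan, seed = 1)
b6  <- run_mouse(preset("mouse_c57bl6"), pan, seed = 1)
tail(trajectory(nsg), 1)  # ~6.35e8 cells: the closed-form logistic value
tail(trajectory(b6), 1)   # smaller: CTL-mediated suppression

sim <- run_to_diameter(preset("human_nsclc"), 5, seed = 7)
tr <- run_icb(sim, strength = 10, duration = 365, seed = 8)
tr$summary$max_shrinkage
```

## Known limitations

Late-stage tumors near carrying capacity are frozen by the logistic factor
regardless of killing pressure (a property of the growth law; simulated
sizes stay well below $K$). Immune-controlled tumors are redrawn when
building treatment cohorts, so treated cohorts are conditioned on reaching
treatment size — exactly as the corresponding clinical cohorts are — and
pre-treatment immunoediting biases them toward less immunogenic tumors.
The per-lineage-per-day event coalescence slightly undercounts branchings
in the largest lineages on days when the per-cell expectation exceeds one.
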