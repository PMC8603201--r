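---
title: "Models and methods in repairflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in repairflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

Ionizing radiation produces DNA double-strand breaks, visible as discrete
γH2A.X foci in stained nuclei, and simultaneously perturbs cellular
energetics: mitochondrial respiration collapses within about an hour of
irradiation ("mitochondrial shutdown") and recovers slowly and incompletely
over 24 h, while glycolytic capacity dips and rebounds quickly. repairflux
implements the statistical machinery to quantify both processes from their
raw readouts and to couple them: stress-test parameter extraction from
extracellular-flux traces, multilevel Bayesian models of log-metabolic
parameters, a hierarchical binomial–beta model of focus-count kinetics,
distance-based comparison of repair time courses, and per-cell-line linear
models relating repair to metabolism. A seeded synthetic-data generator
reproduces the assumed data structure so that every stage can be validated
end to end against known truth.

# Extracellular-flux parameters

A Mito Stress Test trace is a per-well OCR time course over four injection
phases (basal → oligomycin → FCCP → rotenone/antimycin A), each with
(by default) three measurement cycles; a Glycolysis Stress Test is the ECAR
analogue over baseline → glucose → oligomycin → 2-deoxy-glucose. The kit
conventions implemented in `flux_params()` are:

* non-mitochondrial OCR = minimum over rotenone/antimycin A cycles;
* basal respiration = last basal cycle − non-mitochondrial;
* ATP production = last basal cycle − minimum oligomycin cycle;
* proton leak = minimum oligomycin cycle − non-mitochondrial;
* maximal respiration = maximum FCCP cycle − non-mitochondrial;
* spare capacity = maximal − basal;

and for the glycolytic arm: non-glycolytic acidification = last pre-glucose
cycle; glycolysis = max glucose − non-glycolytic; glycolytic capacity = max
oligomycin − non-glycolytic; reserve = capacity − glycolysis. Whether a
last, min, max or per-phase-mean cycle is used is a kit convention rather
than a scientific necessity, so `cycle_stat = "mean"` switches every
selection to per-phase means. Parameters are divided by the well's Hoechst
fluorescence (RFU) to correct for cell number; the operation is linear, so
the additive identities above survive normalisation. Negative derived
parameters can arise in noisy wells; they are kept and flagged rather than
clipped, because clipping would bias group means.

Fold changes against unirradiated controls are ratios of group means on the
log2 scale, `log2(mean(treated)/mean(control))`, matching the presentation
of well-group means (n = 8–16 wells per condition); a fold change against a
non-positive control mean is an error, not a silent `NaN`.

# The multilevel model of log-metabolic parameters

Log-transformed per-well parameters are modelled with normal distributions
at every level: an overall mean, cell-line deflections, and replicate
(experiment) deflections nested within cell line,

$$y_{n} \sim \mathcal N(\mu + a_{c[n]} + b_{r[n]},\ \sigma^2),\qquad
a_c \sim \mathcal N(0, \tau_a^2),\quad b_r \sim \mathcal N(0, \tau_b^2),$$

with weakly informative priors: $\mu \sim \mathcal N(\bar y, (10\,s_y)^2)$
and half-normal$(0, 2.5\,s_y)$ on each scale, where $s_y$ is the sample
standard deviation of the response. The time-course variant adds additive
time deflections $g_t \sim \mathcal N(0, \tau_g^2)$ and reports the combined
cell-line × time deflection.

Sampling is by exact conjugate Gibbs draws for all location parameters and
slice sampling for the scales. The sampler works in the *centred*
parameterisation (replicate means around cell-line means around the grand
mean): with well-measured groups the non-centred deflection
parameterisation leaves a flat translation direction between the grand mean
and the deflections, and its random-walk exploration is slow; centring
removes it. Deflections are reported relative to the grand mean with the
sum-to-zero constraint applied per draw at summary time, which makes the
summaries invariant to how the mean is absorbed during sampling.

Summaries per cell line are the posterior median, the 50% and 95%
highest-density intervals, and $P_-$, the posterior probability that the
deflection is negative. HDIs use the sliding-window estimator on sorted
draws (the narrowest window containing ⌈mass·n⌉ draws, ties toward the
lower start), valid for the unimodal posteriors arising here. Convergence
is monitored by rank-normalised split-chain $\widehat R$ and a bulk
effective sample size; $\widehat R > 1.05$ flags the fit and propagates a
warning rather than failing silently.

With a single replicate per cell line the nested variance is unidentified;
the model then drops the replicate level with a logged notice instead of
returning an arbitrary prior-driven $\tau_b$.

# The hierarchical model of focus-count kinetics

Counts are binomial at the nucleus level with the nuclear area as the
number of trials, measured in unit areas of 0.1·Pixel² — a unit small
enough that the per-unit-area focus probability is safely inside (0, 1):

$$k_i \sim \text{Binomial}(A_i,\ p_{r(i),t(i)}),$$

replicate-level probabilities are beta-distributed around a
replicate-overarching, time-dependent probability $p_t$ with variance
$v_t$, and $v_t$ is modelled through a scaled χ² distribution:

$$p_{r,t} \sim \text{Beta}(\text{mean}=p_t, \text{var}=v_t), \qquad
v_t = \sigma^2 X_t / k_t,\ X_t \sim \chi^2(k_t)\ \text{truncated},$$

with $p_t \sim U(0,1)$, and χ²(2) priors on the positive hyperparameters
$k_t \ge 1$ (time-specific by default; `k_shared = TRUE` shares one value)
and $\sigma^2$.

**The unimodality constraint.** The beta level is constrained so that both
shape parameters are at least 1, i.e.
$v_t < p_t(1-p_t)\cdot q/(1+q)$ with $q = \min(p_t, 1-p_t)$. This is a
deliberate design choice with a sharp reason. With only three replicates
the likelihood carries three effective observations per time point about
$(p_t, v_t)$; without the constraint, the posterior under a flat location
prior is dominated *by volume* by U-shaped beta states — distributions with
a shape parameter far below 1 whose mean can sit anywhere while their
density still covers the observed replicate probabilities. In pilot runs
the posterior median of $p_t$ then drifted an order of magnitude above
every observed focus density, and independent brute-force grid integration
confirmed that this is a property of the unconstrained posterior rather
than a sampler artefact. Scientifically, a U-shaped between-replicate law
is absurd: biological replicates of one condition cluster around a typical
value. Restricting the beta to unimodal shapes encodes exactly that and
removes the degenerate region. The cost is that truths with extreme
overdispersion (shape parameters below 1, e.g. a between-replicate
concentration below $1/p$) fall outside the model family; simulation-based
calibration and the parameter-recovery tests show the constrained model is
self-consistent and covers truth at the intended rate in its domain.

**Sampling.** For hyperparameter updates the replicate level is collapsed:
given the per-(replicate, time) sums of foci $S_{rt}$ and unit areas
$N_{rt}$, the marginal of $S_{rt}$ is exactly beta-binomial
$(N_{rt}, \alpha_t, \beta_t)$, which decouples the hyperparameters from the
tightly-pinned replicate probabilities. $p_t$ and the variance fraction
$w_t = v_t / v_{\max}(p_t)$ are updated by adaptive random-walk Metropolis
on logit scales, mixed (probability 0.3) with independence proposals — a
beta centred at the pooled empirical focus density for $p_t$ and a broad
beta for $w_t$ — which lets chains hop between posterior modes with exact
Metropolis correction instead of being trapped by one. $k_t$ and $\sigma^2$
are updated on log scales; replicate probabilities are recovered by exact
conjugate Gibbs draws afterwards. $p_t$ is initialised at the per-time
pooled empirical focus density (clipped to $[10^{-6}, 1-10^{-6}]$), the
variance fraction at its empirical between-replicate estimate, jittered per
chain. An exact zero focus probability in the *generator* bypasses the beta
level (a point mass at zero); the model itself keeps $p_t$ interior.

The per-nucleus log-likelihood matrix (nucleus × draw) is retained for
model comparison. Two simpler models share the interface: a
replicate-pooled beta-binomial (same χ² variance hierarchy, no replicate
level) and a fully pooled binomial whose conjugate posterior is sampled
exactly. PSIS-LOO (`psis_loo()`, `loo_compare_foci()`) compares them by
expected log predictive density, with the generalised-Pareto tail fit of
the importance ratios implemented from the profile-posterior method and the
tail-shape diagnostic $\hat k$ reported per observation; a preference is
declared only when the elpd difference exceeds twice its standard error.
With fewer than five tail samples the raw normalised weights are used
unchanged.

Posterior predictive checks replicate count tables from the fitted model
and compare per-time mean counts, per-time variance/mean ratios, and the
maximum count; simulation-based calibration (truth drawn from the model's
own prior, rank of truth among thinned posterior draws) is part of the test
suite and validates the sampler itself.

# Repair vectors, distances, clustering, residual damage

For each cell line the five posterior medians of $p_t$ at
t = 0, 0.5, 2, 6, 24 h form its repair vector; cell lines are compared by
the Euclidean distances of these vectors, computed once per pair so the
matrix is exactly symmetric. Point summaries (medians) feed the distance
because the heatmap is a single-matrix display; propagating posterior
uncertainty into a distance distribution is possible but out of scope of
the default display. The linkage criterion for the heatmap ordering is not
dictated by the analysis; average linkage is the default, with single,
complete and Ward-on-distances available (Ward heights are then not
cophenetic distances). Agglomeration and tie handling follow
`stats::hclust`, which is deterministic for a fixed input; input-order
invariance therefore holds up to `hclust`'s own conventions rather than a
lowest-label rule. Residual damage is the percent of mean focus density
(foci per unit area) remaining at 24 h relative to 0.5 h, per cell line and
replicate.

# Coupling repair to metabolism

Flux assays run at 0, 1, 6, 24 h but foci are scored at 0, 0.5, 2, 6, 24 h,
so the 1 h focus probability is interpolated between 0.5 h and 2 h. Linear
interpolation in time (weight 1/3) is the default as the minimal
assumption; log-time interpolation is available since repair kinetics are
closer to exponential. The regression direction is fixed: focus probability
per unit area (response) on the natural-log metabolic parameter
(predictor). With only four points the Bayesian fit uses wide priors
(normal(0, 10 × empirical scale) on slope and intercept, half-normal on the
residual scale; the coefficient block is conjugate given the scale), and
the slope-sign report classifies a relation as negative or positive only
when the 95% HDI excludes zero — point estimates alone would overstate what
four points can support. The ordinary least-squares line is computed
alongside as the plotted representation.

# The synthetic-data generator

The generator is a stated world, not a tuning knob. Focus tables: two
default cell lines (a fast and a slow repairer) with focus probabilities
per unit area peaking at 0.5 h after irradiation (0.030) over a baseline of
0.002, three replicates of 80 nuclei per time (the study design scored at
least 50 nuclei, N = 3), nuclear areas from a discretised log-normal with
median ≈ 400 unit areas (area summaries are not reported anywhere, so this
is an explicit placeholder, configurable), and a between-replicate beta
concentration of 1500 — about 16% coefficient of variation at p = 0.02,
typical of well-controlled triplicate foci assays and consistent with the
unimodal replicate-level beta across the default probability range. Flux
plates: per-well traces are baseline × phase multiplier × irradiation
factor × mean-one log-normal noise (CV 8% by default, 12 wells per
condition), with the irradiation factor equal to 1 at time 0, the shutdown
fraction at 1 h (0.4 mitochondrial, 0.5 glycolytic) and staged recoveries
(mitochondrial 0.6 at 6 h and 0.8 at 24 h — incomplete; glycolytic 0.95 at
6 h and 1.05 at 24 h — fast and slightly overshooting), linearly
interpolated in between. Randomness is split into one deterministic
substream per (cell line, replicate/well, time) group, so enlarging a
design never perturbs draws of existing groups.

The coupled study drives both sides from one latent trajectory $L(t)$ (the
log mitochondrial irradiation factor), piecewise linear on the
focus-scoring grid, with $p(t) = p_0 + s\,L(t)$: the true linear relation
between focus probability and any log Mito Stress Test parameter then has
exactly the configured slope $s$, and because $L$ is linear between 0.5 h
and 2 h, interpolation to 1 h is exact. The realised 1 h flux factor
consequently differs slightly from the configured shutdown fraction — the
price of exact collinearity, recorded in the truth metadata.

What the generator does **not** emulate: cell-cycle structure, apoptosis,
spatial focus clustering within nuclei, instrument drift within a plate,
injection-volume artefacts, or dose–response beyond a single
treatment-versus-control contrast. A green test establishes that the
pipeline recovers the parameters of *this* world at the study's design
scale, not that the biological model is true.

# Numerical choices and edge cases

* Reals are serialised with 17 significant digits; write → read round-trips
  are exact, and the full pipeline is byte-identical across runs at a fixed
  seed.
* The beta-binomial pmf is computed via `lchoose` and `lbeta`, and is the
  exact replicate-integrated likelihood (verified against quadrature to
  1e-6 relative over a design grid).
* HDI ties between equally narrow windows break toward the lower start;
  `mass = 1` spans the sample range. The sample HDI endpoint at n = 1e5 has
  Monte-Carlo sd ≈ 0.02, which the calibration tests account for by using
  a deterministic equal-mass grid plus a median over replicates.
* Foci fits refuse single-replicate hierarchical fits with guidance to the
  pooled model; non-convergent fits carry `converged = FALSE`, which
  `repair_vector()` propagates as an attribute.
* In `cluster_order()` NA distances are an error, and
  `write_distance_matrix()` refuses non-symmetric input.

# Known limitations

* With only three replicates, between-replicate variance information is
  weak by design; the unimodality constraint is what makes the location
  estimable, and datasets whose true between-replicate law is U-shaped are
  outside the model family.
* The χ²-variance hierarchy is one operationalisation of "variance modelled
  through a χ² distribution"; the description underdetermines the scaling,
  and alternatives (a direct truncated χ² on the variance) behave
  equivalently in the regimes we tested.
* Four-point coupling regressions are intentionally weak inference; the
  sign report, not the point estimate, is the supported conclusion.
* The multilevel GLM assumes a shared residual scale across cell lines;
  strongly heteroscedastic panels would need a per-cell-line scale.
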