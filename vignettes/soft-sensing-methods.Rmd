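---
title: "Inverse-system soft sensing for fed-batch Pichia pastoris fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse-system soft sensing for fed-batch Pichia pastoris fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In high-density *Pichia pastoris* cultivations producing recombinant
inulinase, the quantities a plant operator most needs — cell concentration
$X$, residual methanol $S$, and enzyme concentration $E$ — cannot be
measured online. They come from offline assays (wet weight, HPLC) every few
hours, with delay and contamination risk. What *is* measured continuously
is dissolved oxygen $C_L$, pH (equivalently hydrogen-ion concentration
$[\mathrm{H}^+]$), broth volume $V$, the four feed rates (methanol, ammonia
water, phosphate, antifoam), and the environment (temperature, agitation,
airflow).

A soft sensor closes this gap: an inferential model that reconstructs
$(X, S, E)$ in real time from the measurable signals. `fermsens`
implements the inverse-system approach to this problem end to end: a
grey-box process model, a diagnostic establishing that inversion is
possible, and a learned inverse model.

## The grey-box process model

The six states $x = (X, S, E, C_L, [\mathrm{H}^+], V)$ follow balance
equations of the form *accumulation = inflow − outflow + formation*. With
feeds $u = (u_1, \dots, u_4)$ in L/h and $\dot V = \sum_i u_i$,

$$
\begin{aligned}
\dot x_1 &= \mu x_1 - \tfrac{x_1}{x_6}\textstyle\sum_i a_{1i} u_i, &
\dot x_2 &= -\nu x_1 + \tfrac{S_C u_1}{x_6} - \tfrac{x_2}{x_6}\textstyle\sum_i a_{2i} u_i,\\
\dot x_3 &= \rho x_1 - K_P x_3 + \tfrac{K_M u_3 + K_A u_4}{x_6} - \tfrac{x_3}{x_6}\textstyle\sum_i a_{3i} u_i, &
\dot x_4 &= -\eta x_1 + K_{La}(C_L^* - x_4) - \tfrac{x_4}{x_6}\textstyle\sum_i a_{4i} u_i,\\
\dot x_5 &= \gamma x_1 + \tfrac{S_f u_1 - S_m u_3 - S_n u_2 - S_a u_4}{x_6} - \tfrac{x_5}{x_6}\textstyle\sum_i a_{5i} u_i, &
\dot x_6 &= \textstyle\sum_i u_i.
\end{aligned}
$$

The five specific rates $\mu, \nu, \rho, \eta, \gamma$ (growth, substrate
uptake, enzyme production, oxygen uptake, proton release, each per unit
biomass) are the "grey" part: mechanistic structure, empirical content.
They are pluggable (`rate_laws()`); the defaults (`default_rate_laws()`)
are

$$
\mu = \mu_{max}\,
\frac{S}{K_S + S + S^2/K_i}\,
\frac{C_L}{K_O + C_L}\,
\Bigl(1 - \frac{X}{X_{max}}\Bigr)\,
\frac{1}{1 + E/K_E},
$$

with yield-plus-maintenance couplings $\nu = \mu/Y_{XS} + m_S$,
$\eta = \mu/Y_{XO} + m_O$, the Luedeking–Piret product law
$\rho = \alpha\mu + \beta$, and proton release with its own substrate
saturation, $\gamma = \gamma_{max}\, S/(K_H + S)$.

Two default choices deserve justification, because they are what makes the
inverse problem well posed:

* **Product burden on growth** ($1/(1+E/K_E)$). Without any rate
  depending on $E$, the enzyme state influences *nothing* measurable: the
  third column of the invertibility Jacobian (below) is identically zero
  and no inverse model — learned or analytic — could recover $E$ from the
  outputs. The burden factor encodes the metabolic cost of recombinant
  protein expression, a well-documented effect in *P. pastoris*, and
  reduces to the plain logistic–Monod form at $K_E = \infty$.
* **Proton release tied to methanol oxidation** rather than strictly to
  growth ($\gamma \propto S/(K_H+S)$ instead of $\gamma \propto \mu$). If
  $\gamma$ were an affine function of $\mu$, the gradients of $\eta$ and
  $\gamma$ with respect to $(S, E)$ would be parallel and the pH channel
  would duplicate the oxygen channel up to scale; invertibility would then
  hinge entirely on finite-difference residuals of the second output
  derivative. Giving acidification its own substrate affinity
  ($K_H \neq K_S$) makes the two measured channels genuinely independent
  witnesses of the hidden states.

Two conventions in this model family are fixed on mass-balance grounds:
the substrate inflow is implemented as $S_C u_1 / x_6$ (a feed of
concentration $S_C$ at rate $u_1$ diluted into volume $x_6$; a config
switch restores literal alternatives seen in the literature for
comparison), and the phosphate/antifoam terms in the enzyme balance carry
signed coefficients $K_M, K_A$ (additive by default; negative values
treat them as the inhibition effects their name suggests, one config
entry away).

Integration uses a fixed-step classical Runge–Kutta scheme (default step
0.01 h, 0.02 h for campaign simulation), chosen over an adaptive solver
because it is bit-reproducible and because the nonnegativity policy —
states floored at zero after each step, with a clip counter — needs access
to the step loop. Tests verify fourth-order step-halving convergence and
agreement with `deSolve::ode` at tight tolerances.

## Invertibility: when can the outputs reveal the states?

Let $z = (z_1, z_2, z_3) = (x_4, x_5, x_6)$ be the measurable outputs.
Differentiating them along the model flow until the hidden states appear,
the derivative vector $(\ddot z_1, \dot z_1, \dot z_2)$ is (locally) an
invertible function of $(x_1, x_2, x_3)$ exactly when the Jacobian

$$ J = \frac{\partial(\ddot z_1, \dot z_1, \dot z_2)}{\partial(x_1, x_2, x_3)} $$

has rank 3. `jacobian_outputs()` builds $J$ numerically: $\dot z_1,
\dot z_2$ come directly from the balance equations, $\ddot z_1$ from a
central difference of $\dot x_4$ along a short simulated arc (half-width
$10^{-3}$ h, feeds frozen), and the state derivatives from central
differences with step $10^{-4}$ in scaled units. The chain-rule
expansion of $\ddot z_1$ is deliberately not carried out in closed form —
it is long, error-prone and specific to one choice of rate laws — and the
numerical rank test is the operative criterion in any case.

Numerical rank needs care here because the outputs live on wildly
different scales ($[\mathrm{H}^+] \sim 10^{-6}$ mol/L versus $C_L$ in tens
of percent): the raw-unit Jacobian has a third singular value around
$10^{-12}$ of the first purely for unit reasons. `numerical_rank()`
therefore works on the scaled Jacobian — columns multiplied by the state
scales $\max(|x_i|, 1)$, rows divided by their largest entry — which
changes no rank in exact arithmetic and makes the threshold
($10^{-8} \times \sigma_{max}$) meaningful. On the default fixture the
scaled singular values at mid-induction are roughly $(1, 5\times 10^{-2},
2\times 10^{-4})$: rank 3 with orders of magnitude to spare, at every
operating point of the induction phase (`invertibility_scan()`).

The reported `det_diagnostic` is explicitly a heuristic: the determinant
of the scaled Jacobian multiplied by a normalised coupling factor
$|\partial\eta/\partial x_1|\,x_1 / (|\partial\eta/\partial x_1|\,x_1 +
|\eta|)$, so it vanishes both when $J$ is singular and when oxygen uptake
does not respond to biomass — the two failure modes the theory isolates.
It supports no quantitative claim beyond "zero means trouble".

## The inverse extended model and its identification

Rather than inverting the map analytically, the inverse is *identified*:
three independent fully connected networks (one per hidden state) learn

$$ \hat x_k = \phi_k\bigl(x_4, x_5, x_6, \dot x_4, \ddot x_4, \dot x_5,
u_1, \dots, u_4, T_w, S_a, F_a\bigr), \qquad k = 1, 2, 3, $$

a 13-dimensional feature vector: the measurable states, the output
derivatives that the invertibility analysis shows are needed, the feeds
(whose own derivatives are dropped — feeds are near-constant, so their
derivatives add complexity without information), and three auxiliary
environment variables that extend the inverse model with process context
the balance equations do not carry. An optional 14th feature
($\dot x_6$) is available but off by default, matching the feature list
above.

The pipeline in `build_features()` is: digital filter, then five-point
differentiation, then (at fitting time) normalisation.

* **Filter.** A moving average over the last $m$ samples (default 5) with
  an outlier rule: when a sample's innovation relative to the previous
  filtered value exceeds a threshold $D$, the sample is replaced by the
  previous filtered value plus a step of exactly $D$ in the innovation's
  direction, and the window mean is recomputed with the replacement. The
  replacement is a deliberate interpretation choice: clamping the
  *innovation* preserves the signal level, whereas substituting the raw
  innovation itself (a difference, not a level) would discard it. By
  default only the measured channels $x_4, x_5, x_6$ are filtered, and
  $D$ defaults to 6 MAD of the channel's increments so that genuine
  dynamics pass untouched.
* **Differentiation.** Five-point central stencils, fourth-order, exact
  through quartic polynomials; the two points at each boundary use
  one-sided five-point stencils of matching order. Derivatives are taken
  on the dense (0.5 h) measured grid, not the 4 h assay grid.
* **Normalisation.** Min–max to $[0,1]$ per channel (z-score available).
  Statistics are computed on training rows only and frozen — applied
  unchanged to test and online data — which is the leakage guard the
  tests assert. Targets are normalised the same way, so reported MSEs are
  in comparable normalised units.
* **Assay alignment.** When offline assay times do not lie on the feature
  grid, targets are aligned by sliding-window local least squares
  (window 5, degree 2) — the same scheme used to interpolate prediction
  curves onto a 30-minute display grid. No extrapolation, ever.

Each network (default 13–32–16–1, ReLU hidden, linear output — regression
targets) is trained full batch by iterative minimisation of the MSE with
the Adam optimizer: decayed gradient moments
$m_t = \beta_1 m_{t-1} + (1-\beta_1) g_t$,
$v_t = \beta_2 v_{t-1} + (1-\beta_2) g_t^2$, bias corrections
$\hat m_t = m_t/(1-\beta_1^t)$, $\hat v_t = v_t/(1-\beta_2^t)$, update
$\theta \leftarrow \theta - \lambda\, \hat m_t / (\sqrt{\hat v_t} +
\varepsilon)$. Defaults $\lambda = 10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\varepsilon = 10^{-8}$ (the standard values).
Training is deterministic given the seed (He-scaled initialisation,
full-batch updates, no dropout or regularisation). The squared-error
objective is minimised iteratively rather than by a closed-form
least-squares solve — the networks are nonlinear in their parameters.

Useful identities the tests pin down: the first Adam step moves every
coordinate by exactly $\lambda$ as $\varepsilon \to 0$ (bias correction
cancels the gradient scale); with $\beta_1 = \beta_2 = 0$ it reduces to
sign-gradient descent, and with huge $\varepsilon$ to gradient descent at
rate $\lambda/\varepsilon$; backpropagated gradients match central finite
differences to $10^{-6}$ relative.

**Online correction.** When a new offline assay arrives,
`online_correct()` continues training all three networks for a few epochs
(default 50) on a sliding window of the most recent labelled samples
(default 20), with normalisation statistics kept frozen. All three
networks are retrained rather than trying to attribute drift to one
target; with three small networks this costs milliseconds. The regime-shift
fixture shows the intended effect: after a mid-campaign step in the growth
kinetics, a correction on the first post-shift assays roughly halves the
error on the following ones.

## The synthetic campaign: what it emulates, what it does not

No plant data accompany the method, so the package ships a seeded campaign
generator (`generate_campaign()`) that reproduces the *structure* of the
study's data: a 240 h methanol-induction phase (the batch and glycerol
phases are summarised by the initial state, since their role is biomass
accumulation), near-constant feed profiles with seeded ramps within ±5%,
dense 0.5 h logging, offline assays every 4 h — hence exactly 60
feature/target pairs per batch — and Gaussian noise at the printed
instrument accuracies: DO 0.5% of reading, pH 0.02 (applied in pH space,
mapped to $[\mathrm{H}^+]$), flows 2% of setpoint, plus 2% relative assay
noise with the enzyme assay floored at its 0.01 detection limit.

The methanol feed level is *sized by simulation*: a pilot run estimates
the campaign-average substrate demand $\nu X V / (S_C - S_{set})$, and the
feed is set to cover it (with head-room for the ramp), which holds
substrate within ±50% of its 8 g/L setpoint ("about 1%" methanol) because
growth-dominated uptake responds stabilisingly to substrate excursions.
Kinetic parameters are fixture values chosen for realistic trajectory
shapes — slow growth ($\mu < 0.01\,h^{-1}$), DO declining from ~40% to
~20%, enzyme accumulating to tens of U/mL, volume growing ~50 to ~68 L —
not estimates of any real plant. Optional batch-to-batch jitter (±10% on
$\mu_{max}$, $Y_{XS}$) exercises generalisation across batches.

What passing tests on this generator shows: the pipeline is internally
consistent — the cascade of simulator and identified inverse approximates
the identity map on the states (median relative error well under 5%
noise-free, a few percent at instrument noise), and Adam dominates
fixed-rate gradient descent at matched budgets. What it does not show:
performance on real plant data, where unmodelled dynamics (pH control
actions, foam events, sensor drift, assay bias) and a plant/model mismatch
between the grey-box simulator and reality would all degrade accuracy.
The generator has none of these failure modes by construction.

## Evaluation conventions

* MSE is reported per target on the train and test splits in normalised
  units; the default split is chronological 70/30 within batch
  (time-series hygiene — random splits would leak the future into
  training), with batch-wise hold-out the natural choice for multi-batch
  campaigns. Note that chronological test rows are a genuine
  extrapolation for a process whose volume grows monotonically; test
  errors are accordingly much larger than training errors.
* Relative error series are guarded: points with $|y| < 10^{-6}$
  (physical units) are flagged and excluded from medians.
* The "Table-2-style" optimizer comparison uses the aggregate MSE per
  dataset (mean over the three targets), one number for training and one
  for testing per model, mirroring how such comparisons are usually
  tabulated.
* The cascade identity check compares reconstructions against the
  simulator's true states at the assay times — the operational meaning of
  the composite pseudo-linear system being "approximately the identity".

## Numerical choices and degenerate inputs

* ReLU subgradient at exactly 0 is taken as 0.
* Degenerate (constant) channels normalise with scale 1 and a warning;
  constant targets are fitted anyway (and predicted exactly).
* Rank tolerance $10^{-8}\sigma_{max}$; finite-difference steps $10^{-4}$
  (state), $10^{-3}$ h (flow arc); both configurable.
* Negative states are clipped to zero after each integrator step with a
  warning counter; the default campaign never clips.
* Integration problem sizes used in the tests (2–240 h horizons, steps
  0.01–0.05 h, 60-sample training sets, 800–4000 epochs) were chosen so
  the whole suite exercises every claim at desk scale.

## Known limitations

* The grey-box model has no temperature or agitation dependence in
  $K_{La}$, no CO₂ balance, and only ion bookkeeping for pH — the
  environment features help the *learned* inverse precisely because the
  mechanistic model ignores them.
* The true kinetic laws of any particular strain/plant are unknown; all
  quantitative test thresholds are statements about the synthetic study
  conditions.
* The learned inverse is static (no recurrence); temporal context enters
  only through the derivative features.
* Uncertainty quantification and closed-loop feed control are out of
  scope.
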