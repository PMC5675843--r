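---
title: "An active-vision simulator: joint learning of binocular perception, vergence and saccades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active-vision simulator: joint learning of binocular perception, vergence and saccades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aecvision` simulates an active binocular vision system built on the
*active efficient coding* idea: a sensory code and the behaviour that feeds
it are optimized together, sharing one objective — the fidelity of the
sensory representation. Three learners run simultaneously on synthetic
stereo scenes:

* a **perceptual representation**: a bank of two-dimensional subspaces over
  binocular image patches, learned online by an adaptive-subspace
  self-organizing map with sparsity and temporal slowness;
* a **vergence controller**: a linear-softmax policy over 11 discrete
  horizontal shifts, trained by a natural actor-critic whose reward is the
  negative reconstruction error of the representation;
* a **saccade generator**: fixation targets sampled from a binocular
  saliency map — the summed Shannon self-information of the learned
  feature responses — combined with inhibition of return.

This vignette documents the model, its parameters, the synthetic-data
generator, the numerical choices, and what the desk-scale experiments can
and cannot show.

## The environment: window-shift stereo

Eye movements are modelled entirely in 2-D. A scene is a set of textured
fronto-parallel planes, each at an integer disparity $D$ (px), over a
full-frame background plane; the right eye's view shows each plane's
texture shifted left by its disparity, occlusions resolved near-over-far
(larger disparity = nearer). A *fixation state* is a left-image point
$(x, y)$ plus a horizontal shift $d$ standing in for the vergence angle:
the right-eye analysis windows are centred at $(x - d, y)$. The **retinal
disparity** is $d - D(x, y)$; zero means the two foveal windows show the
same scene point.

The vergence input is three binocular 55×55-px window pairs (at full
scale): a 220-px window down-sampled ×4 (coarse), 110-px ×2 (medium) and
the raw 55-px window (fine). The saccade input is the largest aligned
sub-window pair (cropped by $|d|$ columns) down-sampled ×4. All
down-sampling is separable cubic-convolution interpolation (Keys kernel,
$a = -0.5$) with reflected boundaries and no anti-alias prefilter; the 1/f
textures carry little energy near the Nyquist frequency, so plain
interpolation suffices.

Fixations last 10 frames; the scene is replaced every 30 fixations. The
shift is carried across saccades unchanged, clamped to ±40 px, and reset
to 0 when the scene is replaced — with an untrained policy the shift
otherwise random-walks to the clamp within a scene and parks there, which
at the time scales simulated here starves both learners of
near-correspondence input. Fixation points are restricted to a margin such
that the coarse window plus the maximal shift stays inside the frame; the
saccade-target distribution is zero outside this margin.

### The synthetic generator, and what it leaves out

`generate_scene()` draws `n_planes` (default 5) planes with sides 20–45 %
of the frame, uniform integer disparities in ±20 px, and textures from a
family: broadband noise with a 1/f amplitude spectrum (default),
sinusoidal gratings, or dead-leaves discs. The background defaults to
`"mixed"`: the same 1/f texture with several near-constant rectangles
stamped in — the indoor-scene-like blend of textured surfaces and
low-texture regions (walls, shadows) that makes fixation targets
genuinely unequal in information content, which is the property the
saliency-versus-random comparisons turn on. `"onef"` textures everything;
`"flat"` (a uniform level plus σ = 0.01 sensor-like noise) is entirely
near-constant and is what the entropy protocol uses for maximal contrast
with textured objects. The faint noise on "flat" regions matters: an
*exactly* constant region normalizes to a zero patch vector with zero
reconstruction error, creating a "look at nothing" optimum that
photographic scenes do not have.

The generator reproduces the mechanics that drive the model — textured
surfaces at distinct depths, occlusion, ground-truth disparity — but not
the statistics of natural scenes: no perspective, no vertical disparity,
no photometric asymmetries between the eyes, no depth gradients within a
surface. Results obtained here show that the *mechanisms* behave as
described; they do not calibrate absolute performance on photographic
stereo imagery.

## The perceptual representation

Each window pair is cut into 10×10 patches (stride 5 for vergence
pooling, stride 1 for saliency). Left and right patches are separately
normalized to zero mean and unit variance and concatenated into a 200-d
vector $x$; monocular halves with standard deviation below $10^{-6}$ are
flagged low-contrast, normalized with a clamped denominator, excluded
from learning but included in error averages.

A bank holds $N$ feature extractors (324 at full scale, 64 in the desk
profile), each a 2-column orthonormal basis $\Phi_n \in \mathbb{R}^{200
\times 2}$. The response is the squared projection length $r_n(x) =
\lVert \Phi_n^\top x \rVert^2$ — the subspace analogue of a binocular
complex cell's energy. The best-fitting subspace is the response argmax
(ties to the lowest index) and the reconstruction error is
$e(x) = \lVert x \rVert^2 - \max_n r_n(x)$.

Learning rotates subspaces toward the patches they are responsible for:

$$\Delta\Phi_n = \sum_j h_{n,j}\,
  \tilde{x}_{j,n}\,\frac{x_j^\top \Phi_n}{\lVert \hat{x}_{j,n}\rVert\,
  \lVert x_j \rVert},
  \qquad \Phi_n \leftarrow \mathrm{orth}(\Phi_n + \lambda \Delta\Phi_n),$$

with $\hat{x} = \Phi_n \Phi_n^\top x$ the projection and $\tilde{x} = x -
\hat{x}$ the residual. Re-orthonormalization (two-column Gram–Schmidt)
runs after every update because the energy interpretation of $r_n$
requires orthonormal columns. Responsibilities combine sparsity and
slowness:

$$h_n \propto \exp\!\big(r_n / 2\sigma_e^2\big) \cdot
  \begin{cases} \omega & n = \text{previous winner} \\
  (1-\omega)/(N-1) & \text{otherwise,} \end{cases}$$

normalized per patch; defaults $\sigma_e = 0.2$, $\omega = 0.5$, with a
hard winner-take-all mode for ablation. The slowness context is cleared
at saccades and scene changes, where the input stream genuinely breaks.
Responsibilities below $10^{-12}$ are skipped in the update — at the
default $\sigma_e$ the softmax is extremely peaked and the skipped terms
are below double-precision noise of the summed update. The learning rate
defaults to $\lambda = 0.02$ (desk scale) and anneals linearly to a 10 %
floor over the first 30 % of a training run (`lambda_floor_frac`): the
representation does most of its moving early, and the vergence policy —
whose actor-critic has no mechanism for tracking a drifting feature
space — then learns on quasi-stationary features. Without this
separation of time scales, desk-scale joint runs leave the actor chasing
the representation and no usable policy emerges; the full-scale system
achieves the same separation simply by being slow.

## Vergence control

Responses at each scale are mean-pooled over patches and concatenated
(coarse, medium, fine) into a $3N$-d vector (972-d at full scale). The
policy is $\pi = \mathrm{softmax}(\theta^\top r / \beta)$ over the action
set $\{-16,-8,-4,-2,-1,0,1,2,4,8,16\}$ px, $\beta = 1$. The reward is the
negative three-scale average reconstruction error.

The cited actor-critic family leaves the instantiation open; ours is:
TD(0) on a linear value function $V(r) = v^\top r + b$; compatible
features $\psi(a, r) = (\mathbf{1}_a - \pi) \otimes r$; natural-gradient
weights $w$ kept as an exponential running average of $\delta \psi$
(rate $\alpha_w$); actor step $\theta \leftarrow \theta + \alpha_a w$.
Updates occur only within fixations — 9 transitions per 10-frame
fixation — never across saccades.

Three conditioning choices matter and are defaults (all flag-controlled):

* **Reward scaling.** $-E_{avg}$ is divided by 200, the energy of a
  normalized 200-d patch vector, so rewards live in $[-1, 0]$ and the
  learning rates are scale-free.
* **Feature centring.** Pooled energies share a large common mean across
  stimuli. Uncentred, the actor's gradient is dominated by that common
  direction: the policy collapses to a state-independent action
  preference and the saturated softmax stops exploring. Features are
  therefore centred by a running mean and scaled by a running mean of the
  centred norm (EMA rate 0.01, norm capped at 10 during warm-up). The
  actor deliberately has no intercept pathway; the critic keeps its bias.
* **Learning rates.** $\gamma = 0.3$, $\alpha_c = 0.1$, $\alpha_a = 1.0$,
  $\alpha_w = 0.3$, selected by sweeping on a frozen-representation
  vergence decision process (state = disparity, features = the trained
  bank's pooled responses) before any end-to-end evaluation. At the
  thousands-of-steps scale simulated here, rates an order of magnitude
  smaller show no policy emergence at all.

## Binocular saliency and saccades

Saliency is computed at the coarse scale from 10×10 patches at stride 1.
Each feature's response map is min–max normalized to $[0,1]$ (a constant
map becomes all zeros), binned into $K$ equal-width bins ($K$ = the
number of patches in the estimation context, the model's stated binning
rule; a value of exactly 1.0 falls in the top bin), and the per-patch saliency is
$-\ln(\alpha + (1-\alpha) h(\text{bin}))$ with floor $\alpha = 10^{-6}$,
summed over a random subset of 25 feature extractors redrawn per map.
The **global** variant estimates histograms over all patches; the
**local** variant over a 31×31 patch neighbourhood of the current
fixation (clipped at borders), which makes salience fixation-dependent:
patches whose responses differ from those around the fixation — in
texture or in depth — are surprising, hence salient. A monocular
degeneracy (right half zeroed, left rescaled by $\sqrt{2}$) provides the
texture-only baseline.

The coarse map is zero-padded back to the coarse image size, upsampled ×4
(bicubic, undershoot clamped at 0), placed into frame coordinates at the
crop offset, multiplied by the inhibition-of-return mask
$\prod_k \big(1 - e^{-\lVert p - p_k \rVert^2 / 2\sigma_k^2}\big)$ over
the last two fixations ($\sigma_1 = 20$, $\sigma_2 = 10$ px, full-image
coordinates) and by the valid margin, normalized, and sampled. A blank
product falls back to uniform-over-margin and is logged.

## Evaluation protocols

All protocols draw evaluation scenes from seed streams disjoint from
training. `policy_rmse()` runs the policy 10 steps on single-plane inputs
at initial disparities −20…20 and reports the root mean squared final
retinal disparity. `reconstruction_error_curve()` + `fit_vcurve()`
measure disparity tuning; the V-model $f(d) = c - a\,e^{-|d-\mu|/b}$ is
fitted by Levenberg–Marquardt (initialized $\mu$ = argmin, $c$ = max,
$a = c - \min$, $b = 5$; a Nelder–Mead sweep over $\mu$ is the fallback),
and the sharpness is $a/b$. `window_entropy()` uses 256 equal-width
intensity bins on $[0,1]$. `expected_disparity_difference()` computes the
exact expectation of $|D_i - D_j|$ under the IOR-free target law, with
the shift held at 0 so only the local context depends on the current
fixation. `fixation_error_decrease()` reports
$(E_{start}-E_{end})/E_{start}$ per fixation with a running mean.

## Scales, run times, defaults

The full-scale architecture (640×480 frames, 55-px windows, $N = 324$,
100 patches/scale, 972-d pooled vector) is exposed as
`run_config("full")` and structurally verified by the tests. Experiments
run at the desk profile: 320×240 frames, 35-px fine window (so the
coarse 140-px window fits with margin), $N = 64$, 36 patches/scale. The
spec sheet for this profile — joint runs of 700–2000 fixations, three
replicate seeds, RMSE with a handful of textured inputs per disparity,
disparity-controlled bank training of 1500 window presentations — was
chosen so each experiment completes in minutes on one CPU. Replicate
master seeds share the scene stream and bank initialization across
saccade variants, so variants differ only where the model says they
should.

Desk scale compresses development by two orders of magnitude relative to
the tens of thousands of fixations of a full run, by raising learning
rates. Two consequences are honest and worth stating. First, the
representation's own within-fixation adaptation contributes a reward
drift comparable to the action-driven reward differences, so the
vergence policies that emerge here are coarser than full-scale ones.
Second, the across-seed variability of the final policy RMSE at desk
scale is comparable to the difference between saccade-policy variants:
robust desk-scale conclusions are the large improvement over the
untrained policy and the anti-diagonal sign structure of the learned
action map, while resolving the ordering *between* saccade variants —
which at full scale emerges from a slow positive feedback between
representation and behaviour — demands replicate counts or run lengths
beyond the desk profile. The comparison machinery reports whatever the
runs produce; it does not presuppose the ordering.

## Numerical choices and degenerate inputs

* Ties in winner selection and greedy actions break to the lowest index.
* Zero-norm patches contribute nothing to updates; constant windows
  produce zero patch vectors (flagged), zero responses and zero entropy.
* A constant response map yields a single occupied histogram bin and zero
  self-information everywhere — harmless by construction.
* The softmax subtracts the max activation; non-finite activations raise
  an error naming the offending actions.
* Histograms close the top bin so a normalized response of exactly 1.0 is
  counted.
* The saccade crop mirrors the corner formula for negative shifts and
  errors when $|d|$ reaches the image width.
* `fit_vcurve()` bounds $b > 0$, $a \ge 0$ and carries residuals in the
  returned object; non-convergence of both optimizers is an error.

## Checkpoints and interfaces

Checkpoints are plain R objects (`saveRDS`) holding the three banks, the
policy and the configuration; scenes and frames export to 8-bit grayscale
PNG with disparity as integer CSV. User-supplied rectified stereo pairs
can be ingested (`read_stereo_pair()`); without ground-truth disparity
the disparity-dependent metrics are unavailable. A thin command-line
wrapper lives at `inst/cli/aecvision.R`.

## Known limitations

* 2-D window-shift vergence only: no angular (degree-valued) control, no
  vertical disparity, no 3-D rendering.
* The saliency-to-saccade pathway is hard-coded (as in the model);
  only the feature extractors underneath it are learned.
* $K$ = number-of-context-patches histogram bins is implemented as
  specified but yields near-singleton bins; `subset_cc_curve()` is the
  tool to probe sensitivity, and a square-root-rule option exists.
* Desk-scale absolute numbers depend on the compressed time scale;
  see above.
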