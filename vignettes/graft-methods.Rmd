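---
title: "Graph-filtered temporal dictionary learning: model and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-filtered temporal dictionary learning: model and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Functional fluorescence videos (two-photon calcium imaging of somata,
dendrites or axons; widefield vascular recordings) are arranged as a
pixels-by-time matrix $Y \in \mathbb{R}^{N \times T}$. The package factorizes

$$ Y = A \Phi^\top + E, $$

where the columns of $\Phi \in \mathbb{R}^{T \times M}$ are time traces of $M$
fluorescing components, the columns of $A \in \mathbb{R}^{N \times M}$ are the
corresponding sparse, nonnegative spatial profiles, and $E$ is Gaussian sensor
noise. Two assumptions replace the spatial shape priors of ROI-based methods:
each pixel expresses only a few traces (row-sparsity of $A$), and pixels with
similar activity should have similar representations. The latter is encoded by
a k-nearest-neighbour graph over pixel traces, not by spatial proximity, so a
component may be spatially scattered (an axonal arbour, both branches of an
arteriole tree) and still be a single component.

### Graph construction

Affinities use a Gaussian kernel with self-tuning bandwidths,
$W_{ij} = \exp(-\lVert y_i - y_j\rVert^2 / \sigma_i\sigma_j)$, where
$\sigma_i$ is the distance from trace $i$ to its `k_sigma`-th nearest
neighbour (Zelnik-Manor/Perona rule). Edges come from a kNN search
(`k_neighbors`, default 12) symmetrized by union, which cannot isolate nodes;
mutual symmetrization is available. Rows of $W$ are normalized to the
diffusion operator $K = D^{-1}W$, whose application averages a pixel-indexed
quantity over graph neighbours. The graph is built once, before learning
(`updateEmbed false` in the reference parameter set). Defaults
`k_neighbors = 12`, `k_sigma = 7` are conventional for self-tuning affinity
graphs at these pixel counts; duplicate traces are handled by flooring
bandwidths at $10^{-8}\times$ the median pairwise distance.

### Spatial step: re-weighted $\ell_1$ graph filtering

Given $\Phi$, each pixel solves a weighted nonnegative LASSO

$$ \hat a_i = \arg\min_{a \ge 0} \tfrac{1}{2\sigma_y^2}
   \lVert y_i - \Phi a \rVert_2^2 + \lambda_0 \textstyle\sum_k \lambda_{ik} a_k, $$

followed by the graph-filtered weight update
$\lambda_{ik} = \xi / (\beta + a_{ik} + [K a_k]_i)$ (with nonnegative $A$ the
modulus of the graph term is inert). Three such rounds run per outer
iteration, with weights initialized to 1. Rounds are **synchronous**: all
pixels solve, then all weights update. The reference pseudo-code nests the
loops ambiguously; synchronous rounds make the result independent of pixel
order, which we consider a requirement for reproducibility.

The data-term weight $\sigma_y^2$ defaults to **1**, so `lambda0` (default
0.7) acts directly against the unscaled residual — the scale at which the
reference parameter set is meaningful, and the form the QP treatment below
uses. Setting $\sigma_y^2$ to a noise-variance estimate
(`estimate_noise_var()`, pooled MAD of first differences) rescales the
trade-off to likelihood units; with SNR-5 data this weakens the effective
penalty by roughly two orders of magnitude and the sparse-coding step
degenerates toward nonnegative least squares, so it is deliberately not the
default.

$\xi$ is fixed at 1: only the product $\lambda_0\lambda_{ik}$ matters, so a
separate $\xi$ scale would be redundant with `lambda0`. $\beta = 0.09$ bounds
the weights at $\xi/\beta \approx 11$.

### QP solvers for the LASSO

The $\ell_1$ term is linearized by auxiliary variables $u \ge |a|$, making the
LASSO a smooth QP with linear constraints ($x = (a, u)$,
$H = \mathrm{blockdiag}(\Phi^\top\Phi, 0)$, rows $a - u \le 0$,
$-a - u \le 0$, $-u \le 0$). Under nonnegativity $|a| = a$, so the reduced
$p$-variable form $H = \Phi^\top\Phi$, $f = -\Phi^\top y + \lambda$, $a \ge 0$
is used in the pipeline; the general $2p$ construction is retained for the
non-nonnegative case and for cross-checks.

Two solvers are provided:

* **Interior point**: damped Newton on the log-barrier objective with
  geometric barrier decay (`mu0 = 1`, `mu_decay = 0.1`, stop at
  $m\mu < \mathrm{tol}$) and backtracking line search. The Newton stage stops
  when the decrement falls below $\mathrm{tol}^2$, which makes the final
  iterate accurate to the order of `tol`.
* **Active set**: a primal working-set iteration (add the blocking
  constraint, drop the most negative multiplier), with a Bland-style
  lowest-index rule engaged if cycling is suspected. Nonnegativity-only
  problems are routed to a compiled Lawson–Hanson-type kernel on the Gram
  system — the same active-set algorithm specialized to bound constraints —
  which warm-starts from the previous solution's support. This is what makes
  the three re-weighting rounds cheap: supports change little between rounds.

`select_solver()` prefers the active set for repeated (warm-startable)
solves or below 64 coefficients (strictly; 128 variables in the general
form), the interior point above. The reduced Hessian is ridge-regularized by
$10^{-10}$ on Cholesky failure, which occurs when dictionary traces are
strongly correlated.

### Dictionary step

$$ \Phi^{l} = \arg\min_{\Phi \ge 0}\;
   \lVert Y - A\Phi^\top\rVert_F^2 + \gamma_1\lVert\Phi\rVert_F^2
   + \gamma_2 \sum_{i \ne k} \Phi_i^\top \Phi_k
   + \gamma_3 \lVert \Phi - \Phi^{l-1}\rVert_F^2 . $$

The four terms are data fidelity, magnitude control, decorrelation of
redundant traces (the sum of off-diagonal Gram entries), and iterate
smoothness. Defaults $\gamma_1 = 0.2$, $\gamma_2 = 0.1$, $\gamma_3 = 0.1$
follow the reference parameter set; the mapping of its names
(λForb → $\gamma_1$, λCorr → $\gamma_2$, λCont → $\gamma_3$) is an inference
from "Frobenius/correlation/continuity" and is configurable.

The default solver is cyclic column block-coordinate descent: for one column
the subproblem has a diagonal Hessian
($\lVert a_m\rVert^2 + \gamma_1 + \gamma_3$), so the exact nonnegative column
minimizer is a clamped closed form and **every sweep decreases the
objective** — the property the pipeline's monotonicity contract relies on. A
projected-gradient mode with the reference step schedule (`step s`,
`step decay`, `GD iters`) is provided for fidelity, guarded by a
fallback-to-previous-iterate rule. Columns with all-zero spatial
coefficients are anchored to $\gamma_3/(\gamma_1+\gamma_3)\,\Phi^{l-1}$;
optional re-seeding from the worst-reconstructed pixel's residual is off by
default because per-iteration pruning removes dead components first.

### Outer loop

Each outer iteration runs the spatial step (3 inner rounds), prunes
components whose spatial column norm falls below $10^{-3}\times$ the largest
(a component expressed at a thousandth of the strongest is scientifically
dead even if numerically nonzero), rescales surviving spatial columns to unit
norm with inverse scaling of the traces (`normalizeSpatial`; leaves
$A\Phi^\top$ unchanged and fixes the scale at which $\beta$ operates), and
updates the dictionary. Convergence is declared when
$\lVert \Phi_t - \Phi_{t-1}\rVert_F / \lVert\Phi_{t-1}\rVert_F <$ `learn_eps`
(default $5\times10^{-4}$); the outer cap is 50 iterations (the reference
table's "maxiter 0.01" cannot be an iteration count and is not interpreted).
$M$ is fixed at `max_components` (50) with pruning shrinking the effective
count. One master seed fans out to named substreams (dictionary
initialization, sketch, synthetic data), so runs are bit-reproducible
single-threaded.

## Temporal compression

Because pixel traces are sparse in the dictionary, their geometry survives a
random projection $\Psi \in \mathbb{R}^{\tilde T \times T}$ (restricted
isometry). The pipeline sketches $\tilde Y = Y\Psi^\top$ **once** before the
loop, runs both steps in the compressed space
($\tilde\Phi = \Psi\Phi$), and solves the dictionary problem once at full
length at the end using the final $A$ and the uncompressed $Y$ (with
$\gamma_3 = 0$: there is no previous full-length iterate to anchor to).

Choices worth stating:

* $\Psi$ is i.i.d. Gaussian with variance $1/\tilde T$, the canonical RIP
  ensemble, giving scaling $\alpha \approx 1$. "Normalized" mode rescales
  rows to unit $\ell_2$ norm, which shrinks sketched energy by
  $\approx \tilde T/T$ and hence strengthens the effective sparsity penalty —
  the reason reference runs pair normalized sketching with a smaller
  $\lambda$ (0.1 instead of 0.7). `ratio = 1` returns an exact identity
  passthrough, the regression anchor for compressed-vs-uncompressed
  equivalence.
* Nonnegativity of $\tilde\Phi$ is **not** enforced in the compressed loop
  (sketched traces are sign-indefinite) and is re-imposed at recovery.
* The kNN graph is built from the **raw** traces by default
  (`distance_on = "raw"`): the raw matrix is available by construction, the
  graph is built once so the saving from sketching it is marginal, and at
  high compression (e.g. 512×, $\tilde T = 8$) sketched distances are too
  distorted to define a meaningful neighbourhood structure.
  `distance_on = "compressed"` extends the compression saving to graph
  construction when moderate ratios are used.
* The data-term weight estimated (if requested) on raw data is reused in
  compressed runs; `rip_distortion()` reports empirical $(\hat\alpha,
  \hat\delta)$ for an operator against a sparse basis.

## Synthetic study data

`generate_video()` emulates the statistical structure the model assumes:
isotropic Gaussian blobs (sd 2–4 px, somata) and curvilinear random-walk
paths (width 1–2 px, processes); Poisson spike trains (default 0.1 Hz at
30 Hz sampling) convolved with a double-exponential kernel
$(1 - e^{-t/\tau_r})e^{-t/\tau_d}$ ($\tau_r = 0.1$ s, $\tau_d = 1$ s); a 5%
constant baseline; additive Gaussian noise calibrated so the mean temporal
standard deviation of the clean signal over core (half-maximum) pixels is 5
times the noise sd. Components whose half-maximum cores overlap earlier
components by more than `overlap_fraction` (default 0.25) are re-drawn. The
default field of view is 40×40 px with T = 4096 frames and 20 components —
small enough to analyse in about a minute, large enough that compression
ratios up to 512× leave a nontrivial sketch ($\tilde T = 8$).

What the generator does **not** simulate: optics (PSF, scanning, laser
power), slow drift, neuropil contamination, motion. Passing tests on this
data shows the optimization recovers the model's own structure under
calibrated noise; it does not certify performance on data violating the
factorization (preprocessing for motion and denoising is out of scope).

## Evaluation conventions

`match_traces()` tags every estimated trace with its highest Pearson
correlation against a reference set (many-to-one allowed; zero-variance
traces get $\rho = 0$ and a flag). Raw traces are correlated — Pearson is
already location/scale invariant — with z-scoring exposed as an option.
`agreement_matrix()` supports two conventions: `"reference"` (fraction of
reference-run traces matched above threshold; bounded by 100) and
`"comparison"` (comparison-run traces tagged above threshold relative to the
reference count; may exceed 100 when the comparison run finds more traces).
Histograms default to bin width 0.05.

## Problem sizes and verification

The shipped tests verify: exact agreement of both QP solvers with an
exhaustive support-enumeration oracle and an ADMM oracle (50 seeded
instances); per-update monotonicity of the dictionary objective over a
30-iteration run; row-stochasticity of $K$ to $10^{-10}$ and the kernel
against a dense oracle; identity-sketch equivalence to $10^{-8}$ relative;
empirical RIP distortion below 0.5 at 4× compression of $K$-sparse signals;
and, at the default study scale (40×40 × 4096), recovery of ≥90% of
ground-truth traces at $\rho \ge 0.8$ across three seeds plus
cross-compression self-agreement at ratios up to 512×. The same
cross-compression quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* Dense $N \times N$ distance matrices bound the practical pixel count to a
  few tens of thousands per run; the reference implementations patch larger
  fields of view, which is out of scope here.
* $M$ does not grow during learning; choose `max_components` generously and
  let pruning shrink it.
* The alternation is monotone in the dictionary objective but not, in
  general, in the reconstruction error during the first iterations
  (regularizers and the sparse-coding step trade fit for structure).
* HDF5 containers are not read or written; use multipage TIFF or in-memory
  matrices.
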