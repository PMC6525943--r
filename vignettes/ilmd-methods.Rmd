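---
title: "Methods: dual-tree wavelet ERD/ERS features and incremental landmark MVU"
author: "ilmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-tree wavelet ERD/ERS features and incremental landmark MVU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and the numerical decisions behind the
package: what is computed, under which assumptions, which parameters
matter, and where a design was genuinely open and had to be settled.

## 1. The pipeline

A two-class motor-imagery trial enters as a channels × samples record
(C3, Cz, C4 at sampling rate `fs`). The pipeline is

1. dual-tree complex wavelet decomposition of C3 and C4 into J+1
   reconstructed subband signals;
2. selection of an *optimal time block* and, per subject, of the most
   discriminative wave(s);
3. a 2-D normalised band-energy feature `F1 = (AE_alpha, AE_beta)`;
4. a high-dimensional channel-difference vector per trial, embedded into
   d dimensions by landmark maximum variance unfolding (L-MVU) at
   training time and by its incremental extension (IL-MVU) at test time;
5. fusion `F = [100 F1 ; F2]`, two-class LDA, stratified k-fold
   cross-validation, Cohen's kappa, pooled two-sample t-tests.

The central modelling assumptions are those of the ERD/ERS literature:
class information is carried by lateralised band-power changes of the mu
and beta rhythms at C3/C4 during the imagery interval, and the trial-wise
structure of the band-limited difference signal lies near a
low-dimensional manifold.

## 2. Dual-tree complex wavelet transform

Two parallel real DWT trees form the real and imaginary parts of the
transform. The first level uses an odd-length biorthogonal pair; levels
two and up use an even-length orthonormal Q-shift pair whose tree-B
low-pass is the time reverse of tree A's. Tree B's first-level filters
are delayed one sample, so the cumulative inter-tree delay is half a
sample at every level's rate — the property that makes subband energies
nearly shift invariant (verified in the tests: a one-sample shift moves
subband energies of in-band tones by well under 5%, versus tens of
percent for a single critically sampled tree).

**Filter catalogue.** First level: Antonini 9/7 (default), LeGall 5/3,
and near-symmetric 5/7- and 13/19-tap pairs; later levels: Q-shift banks
of 10 (6 nonzero), 10, 14, 16 (default) and 18 taps. Antonini and LeGall
are derived exactly from the maximally flat halfband factorisation (the
classical coefficients). The 14-tap and the sparse 10-tap Q-shift banks
are the published coefficient tables, refitted onto the paraunitary
lattice so that orthonormality holds to machine precision rather than to
the published eight decimals. The remaining banks are designed in-package:
the biorthogonal pairs by halfband-root assignment at the catalogue tap
counts (choosing the split that best matches analysis and synthesis
magnitudes), and the Q-shift banks on the paraunitary lattice with an
exact vanishing moment (lattice angles summing to −π/4) and a
quarter-sample group-delay + stopband objective. Every bank is validated
for perfect reconstruction (≤ 1e−10), half-sample delay (cross-correlation
peak offset within 0.3–0.7 samples) and band localisation.

**Boundary handling and exactness.** The input is extended by reflection
to a period-2n sequence and the transform is run as a *periodic* DWT per
tree (FFT-based circular filtering). The perfect-reconstruction
identities are polynomial identities, hence exact modulo every even
period: inversion and single-subband reconstruction are exact to
round-off for every bank, a constant input yields exactly vanishing
detail bands, and the J+1 subband signals sum to the input by linearity.
A `"periodic"` boundary option treats the input as one period as-is; it
is the right mode for measuring shift behaviour with whole-period tones,
because reflection is not shift-equivariant (re-mirroring a shifted
signal changes the extension, which any symmetric-extension transform
inherits).

**Subband geometry.** With J levels the subbands tile `[0, fs/2]`
dyadically; at fs = 128 Hz, J = 4 the bands are 0–4, 4–8, 8–16, 16–32,
32–64 Hz, tagged delta, theta, alpha, beta, gamma by greatest frequency
overlap (ties to the lower wave).

## 3. Time block, energies, wave selection

**Average power spectrum.** `P(j)` is the mean over a class's trials of
the squared j-th sample of a channel. For time-block *selection* the
spectra are smoothed by a moving average of width fs/4 samples; features
never see the smoothing.

**Optimal time block.** In practice this block is often chosen by
visual inspection of the average power spectra; a package needs a
deterministic rule. The automatic
rule scores every window of the configured length (default 4 s) inside
the post-cue interval by the integrated class contrast
`sum_j |(P_L^C3 − P_L^C4) − (P_R^C3 − P_R^C4)|(j)` and takes the
maximiser, earliest start on ties. An explicit override always wins and
accepts seconds or 1-based inclusive sample indices; seconds are
authoritative (at 128 Hz the block 3.5–7.5 s maps to samples 449–960,
length 512). All sample blocks are 1-based inclusive `[min, max]` of
length `max − min + 1`, matching the field's convention.

**Sliding energies.** A window of 2·fs samples slides one sample at a
time (`max − min − 2 fs + 2` windows per block); per window the energies
of the J+1 subbands are normalised to sum to one. `AE_wv` is the mean
normalised energy on C3 minus that on C4; `F1 = (AE_alpha, AE_beta)`.
Normalised energies are invariant to rescaling the raw signal; raw
energies scale quadratically. A window where every subband is exactly
zero is given an equal split rather than NaN.

**Wave selection.** Per-subject wave choice is automated: each candidate
subband is scored by the Fisher ratio of its single-subband AE feature
between classes on training data, and bands scoring at least a configured
fraction (default 0.5) of the best are kept; an explicit override exists
because individual subjects are known to express discriminative activity
outside mu/beta, including delta and gamma. When no
band separates the classes (best score below 1e−3) the selection is
flagged non-discriminative and deterministically returns the single best
band. When several waves are selected, the per-wave channel-difference
vectors are concatenated, which preserves each wave's information without presuming
a reweighting.

## 4. Landmark MVU and its incremental extension

Given training vectors `x_i ∈ R^D` (columns of X):

1. *Reconstruction weights.* Each `x_i` is reconstructed from its r
   nearest neighbours by weights minimising `|x_i − Σ_j W_ij x_j|²`
   subject to `Σ_j W_ij = 1`. The constraint is eliminated
   (`w = e_1 + N v` over the sum-zero subspace) and the reduced system is
   solved by SVD least squares; singular values below 1e−10 of the
   largest are truncated, which handles affinely dependent
   neighbourhoods (r above the local rank) with the deterministic
   minimum-norm solution. Neighbours coinciding with the target get the
   weight split equally among them — the exact minimiser and the
   tie-break that makes re-presenting a training point reproduce its own
   embedding exactly.
2. *Landmark transform.* With `Λ = (I − W)ᵀ(I − W)` partitioned by the
   first m samples (the landmarks), the map is `Q = [I_m ; −Λ₄⁻¹Λ₃]`
   — the minimiser of the quadratic form given the landmark coordinates.
   (The transform is sometimes printed with the inverse on the wrong
   block, which is dimensionally impossible; the minimiser is used.)
3. *The SDP.* Maximise `trace(QLQᵀ)` over PSD `L` subject to the
   neighbour-pair inequalities
   `(QLQᵀ)_ii − 2(QLQᵀ)_ij + (QLQᵀ)_jj ≤ |x_i − x_j|²` on the union
   k-NN graph and the centering `Σ_ij (QLQᵀ)_ij = 0`.
4. *Embedding.* Rows of the landmark embedding are `sqrt(λ_k) V_k` for
   the d largest eigenpairs of L — the square root, so that `YᵀY`
   reproduces the kernel (without it the Gram identity fails); signs are
   fixed by making each eigenvector's largest-magnitude entry positive.
   All samples embed as `Y = Y_lm Qᵀ`.
5. *Incremental map.* A new `x` is embedded by finding its w nearest
   training vectors, solving the same sum-to-one least squares, and
   applying the weights to the training embedding. No SDP is touched at
   test time; the work is O(nD) for the neighbour search.

**The solver.** No semidefinite-programming backend is available to this
package, so the SDP is solved by a primal log-barrier interior-point
method written here. The centering equality is eliminated analytically:
a PSD matrix with a vanishing quadratic form on `u = Qᵀ1` must annihilate
`u`, so `L = V M Vᵀ` with `V` an orthonormal basis of `u⊥` and `M ≻ 0` of
order m−1. What remains is a linear objective with rank-one inequality
constraints, handled with a log-det barrier on `M` and log barriers on
the slacks; Newton systems are assembled in the symmetric-matrix basis
(the log-det Hessian `tr(P E_v P E_w)` in closed form) and the path is
followed with μ = 10 until the gap bound `(p + q)/t` falls below 1e−9
relative. Two practical points matter:

- *Warm start.* The least-squares landmark kernel of the input Gram
  matrix, `L₀ = (QᵀQ)⁻¹ Qᵀ K Q (QᵀQ)⁻¹` with K the centred Gram of X,
  scaled into the strict interior, starts the path near the optimal face
  for locally isometric data; the barrier parameter then starts
  objective-dominant. Without this the first centering must traverse a
  long, nearly flat valley and can appear (falsely) converged — the
  solver therefore also requires a genuine Newton decrement below
  tolerance before any barrier-parameter increase, and falls back to a
  cold start from εI if the warm attempt fails to centre.
- *Diagnostics.* A disconnected constraint graph makes the variance
  objective unbounded; connectivity is checked up front and the solve
  refuses with an explicit message. Solutions report the duality-gap
  bound, the maximum constraint violation (zero up to interior-point
  slack, as constraint I is an inequality) and the centering residual.

Degenerate inputs: if every constrained pair coincides, `L = 0` is
returned directly; duplicate columns are legal everywhere.

**Parameter defaults** are r = 52, m = 14, d = 5, k = 24, w = 4 — a
well-performing operating point for 128 Hz two-channel recordings —
clamped to
the data (r, k ≤ n−1; m ≤ n; d < m). The tests confirm the expected
robustness: varying w across 2–12 moves the cross-validated accuracy by
well under 5 percentage points.

## 5. Classification and evaluation

`F1` is multiplied by 100 before fusion so its order of magnitude matches
the embedding coordinates. LDA uses the pooled within-class covariance
with equal priors; if the covariance condition number exceeds 1e8 it is
shrunk towards the scaled identity with an escalating weight until well
conditioned (needed when a feature degenerates). Cross-validation is
stratified (plain randomisation into k packages risks degenerate folds
at small n) and leakage-free by
default: time block, waves and the manifold are fitted per fold on
training trials only, and held-out trials are embedded incrementally —
never by refitting. A `selectionScope = "all"` switch exists to quantify
the effect of selection leakage. Kappa is Cohen's. The two-sample t-test uses the pooled variance with a one-sided upper
tail by default, rejecting at p ≤ 0.05; a two-sided option is provided.

## 6. The synthetic generator

Each channel is 1/f^α Gaussian background (α = 1, RMS 2 µV) plus
band-limited Gaussian rhythm noise in 8–13 Hz (RMS 2 µV at C3/C4) and
13–30 Hz (RMS 1 µV), synthesized in the frequency domain. Rhythms are
noise, not tones, so subband energies are non-degenerate. During the cue
interval (default 3–8 s of a 9 s, 128 Hz trial) the contralateral
channel's rhythm power is multiplied by `erdFactor` (default 0.3) and the
ipsilateral by `ersFactor` (default 1.3), with 0.5 s raised-cosine ramps
to avoid spectral edge artifacts. Generation is bit-reproducible given
the seed, and the class assignment only changes the gain envelopes, never
the random stream.

The generator emulates what the feature extractors consume: lateralised,
cue-locked band-power changes over a coloured background. It does not
emulate EOG/EMG artifacts, volume conduction, inter-trial
non-stationarity, electrode drift or more than three channels. Passing
the pipeline's recovery tests on this data therefore demonstrates that
the machinery extracts planted ERD/ERS correctly — not that any given
real recording will reach the same accuracy.

## 7. Problem sizes and known limitations

The test and acceptance runs use 200 trials (100 per class) at 128 Hz,
9 s trials, 10-fold cross-validation, and desk-scale manifold toys
(arcs of 30–79 points, m ≤ 14 landmarks) — sizes chosen so the whole
suite re-runs in a few minutes on one core while exercising every stage
at the reference operating point. Known limitations: the method is
two-channel (Cz is carried but unused) and two-class by construction;
the SDP solver targets desk-scale m (tens of landmarks), not thousands;
landmark quality depends on the first-m-samples rule, so pathological
input orderings (all landmarks clustered at one end of the manifold) can
distort the embedding — the toys place landmarks across the data, and
real use at the default m = 14 over shuffled trials behaves the same way.
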