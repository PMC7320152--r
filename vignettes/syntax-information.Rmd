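---
title: "Scoring vocal syntax: suffix-tree Markov models, the SIS, and centroid refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring vocal syntax: suffix-tree Markov models, the SIS, and centroid refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvsis)
```

## The problem

Mouse ultrasonic vocalizations (USVs) come as discrete syllables organized
into sequences, and several published algorithms assign each syllable a
discrete label from its spectral shape. There is no ground truth for the
"right" labeling, so the algorithms cannot be compared by classification
accuracy. `usvsis` implements an information-theoretic alternative: a good
labeling should expose the temporal regularities (the *syntax*) that are
present in the data. If knowing the labels of the recent past reduces
uncertainty about the next label, the labeling has captured structure that
is really there; a labeling that scrambles natural classes destroys that
predictability.

## The model

Labeled sequences are modeled as a stationary, irreducible Markov chain of
order $D$ over an alphabet of $N_c$ labels, represented as a full suffix
tree of depth $D$: one leaf per possible suffix (the $D$ labels preceding a
syllable), holding the count $N(\text{suffix})$ and the conditional counts
$N(x \mid \text{suffix})$. All probabilities are plug-in (maximum
likelihood) ratios; there is no smoothing or bias correction. Counting
windows never cross a sequence boundary: the paperwork of deciding what
"precedes" the first syllable of a sequence is avoided entirely, at the
cost of discarding the $D$ boundary windows of each sequence. Sequences are
delimited by inter-syllable intervals (ISI) above 160 ms, with the
convention that an ISI *strictly* greater than the threshold breaks the
sequence.

Two scores are computed from a fitted tree, both in bits/symbol and both in
log base 2 with $0 \log 0 := 0$:

* **Entropy rate** $H_D = -\sum_{i,j} \mu_i P_{ij} \log_2 P_{ij}$, where
  $\mu_i$ is the suffix-visit probability and $P_{ij}$ the conditional
  probability of label $j$ after suffix $i$. It measures residual
  uncertainty about the next label and is bounded by $\log_2 N_c$. It is
  *not* comparable across labelings: assigning every syllable the same
  label gives perfect "predictability" while conveying nothing.
* **Syntax Information Score (SIS)** — the mutual information
  $I(X; Y) = \sum p(x,y)\log_2 \frac{p(x,y)}{p(x)\,p(y)}$ between the next
  label $X$ and its suffix $Y$, equivalently $H(X) - H(X \mid Y)$. A
  degenerate labeling scores 0, a random labeling scores 0, and data with
  no temporal structure scores 0 under every labeling — the properties that
  make the SIS a usable comparison criterion. Dividing by $\log_2 N_c$
  (normalized SIS) compares labelings across alphabet sizes.

By default `sis()` takes $p(x)$ and $p(y)$ as the marginals of the
empirical $(D{+}1)$-tuple distribution. This "one ensemble" convention
guarantees $I \ge 0$ and the exact identity $I = H(p_x) - H_D$ on the same
ensemble. The alternative reading — $p(x)$ as the label frequencies over
*all* syllables, which differs only through sequence-boundary effects — is
available as `x_marginal = "corpus"`; we default to the marginal-consistent
mode because a mutual information that can go negative through a bookkeeping
mismatch is harder to interpret.

A tree estimate is only trusted when fewer than 10% of the $N_c^{D+1}$
potential $(D{+}1)$-tuples are unobserved (`validity_check()`); the
denominator is all potential tuples, tying zero conditional probabilities to
unobserved tuples. Uncertainty is quantified by refitting on 25 random
subsets of 60% of the sequences and reporting mean ± 2 SD
(`resampled_scores()`).

## Analytic ground truth

`markov_model()` defines a synthetic chain by its conditional probabilities.
Any order-$D$ chain is a first-order chain over $N_c^D$ suffix states, so
the stationary distribution is the eigenvalue-1 eigenvector of the
suffix-state transition matrix ($\mu = e / \sum_i e_i$), irreducibility
being checked first via strong connectivity of the positive-transition
graph. Entropy rate and SIS then have closed forms, and `generate_sequences()`
draws realizations whose initial $D$ labels come from the stationary suffix
distribution — the generated ensemble is stationary from the first symbol,
matching the analysis assumption. `estimation_error()` measures the gap
between plug-in estimates on generated data and the analytic values; it
shrinks as $n^{-1/2}$ and is below 0.01 bits at $10^5$ syllables for the
4-label first-order models used in the tests.

Worked two-label example (pitch-jump J vs no-jump N): a 0.43/0.57 label
split gives a 0th-order entropy of
`r round(analytic_entropy_rate(markov_model(matrix(c(.43,.57),1), alphabet=c("J","N"), depth=0)), 4)`
bits/symbol; with first-order dependence $p(J|J) = 0.64$, $p(N|N) = 0.67$
the entropy rate drops to 0.93 and the SIS is ≈ 0.070 bits/symbol.

## Labelers

Two reference labeling families are provided as front-ends:

* **Pitch-jump labeler**: `jump_label()` maps jump features to
  Simple / Up / Down / Multiple; `fit_duration_split()` then splits each
  class at its median duration into `-short`/`-long` (ties to `-short`;
  the choice is arbitrary and documented) for 8 labels. Externally fitted
  medians (e.g. 27.6 / 48.1 / 50.7 / 96.3 ms with a 35.3 ms global median)
  can be supplied via `jump_scheme()` for compatibility runs; syllables
  without jump features fall back to Simple / Multiple by the global median
  (`assign_unclassified()`). The scoring loop some pipelines use to shrink
  their "unclassified" class depends on internals not reproduced here and
  is out of scope.
* **Centroid labeler**: `preprocess_spectral()` converts a syllable
  spectrogram to a 16-channel × 126-frame energy vector (length 2016,
  time-normalized by linear interpolation, per-syllable energy normalized
  to 1). The filterbank is a log-spaced triangular bank over 25–125 kHz
  with unit-area filters — a smooth stand-in for a gammatone bank, chosen
  because the exact gammatone implementation used elsewhere is not
  reproduced here; the bank is configurable. `train_centroids()` runs
  k-means under cosine distance (spherical k-means with restarts; empty
  clusters reseeded from the worst-fit point) on up to 5000 syllables, and
  `assign_by_centroid()` labels by minimal cosine distance, ties to the
  lowest index. Cosine assignment makes the pipeline invariant to recording
  level; unit normalization before clustering is forced by the metric.

## The SIM optimizer

Syntax Information Maximization starts from a centroid set (typically a
spectral clustering), splits sequences 50/50 into train and test halves,
and iterates: draw one random vector $V$ with entries uniform in
$[0.9, 1.1]$; perturb each centroid *in turn* with the same $V$ by the
elementwise product; re-assign all training syllables and evaluate the SIS
of each candidate labeling; apply the best candidate if it beats the
current SIS, otherwise count a failure, and at 5 consecutive failures apply
the best candidate regardless (an escape from local maxima); any
application resets the counter. After training converges, the recorded
perturbation chain is replayed on the test half to verify that the gain
generalizes.

Two design points deserve comment. First, the perturbation "product between
the centroid and $V$" is implemented as the Hadamard (elementwise) product:
a true inner product would collapse the centroid to a scalar, so the
elementwise reading is the only one that yields a perturbed centroid.
Second, convergence is not prescribed anywhere, so we declare it when the
best-so-far training SIS has improved by at most `tol` (default $10^{-4}$
bits) over the last 20 applied perturbations, capped at `max_iters`; forced
applications are flagged in the log so history plots can distinguish them.
With the seed fixed, the entire run — including the replay — is
bit-reproducible.

## What the synthetic generators emulate

`make_label_corpus()` produces corpora whose *defaults encode the
statistics reported for large USV databases*:

* syllable durations: a shifted exponential whose binned density is
  $a e^{b x}$ with $(a, b) = (0.51, -0.41)$ in 4-ms bin units (the implied
  support shift is ≈ 2.1 ms, the shortest credible syllable). The bin unit
  matters: printed density parameters of this form are binning-dependent,
  so the package treats them as generator defaults rather than universal
  constants, and `fit_pdf_with_ks()` reports its own bin width.
* sequence lengths: a discrete power law $a x^b$, $(a, b) = (0.6, -1.88)$,
  truncated to 1–50 syllables (a is fixed by normalization; the fitted
  value ≈ 0.58 reflects that).
* lag-1 correlation 0.44 between adjacent durations, induced by a latent
  AR(1) Gaussian copula ($d = x_0 + F^{-1}_{\exp}(\Phi(z))$). The copula
  preserves the exponential marginal *exactly* while hitting the target
  correlation exactly — the AR coefficient is solved from the Hermite
  expansion of the correlation transfer function. A shared per-sequence
  scale factor would have been simpler but distorts the marginal the
  generator must reproduce.
* ISIs: a two-Gaussian mixture with modes at 20 and 70 ms truncated to
  (1 ms, 160 ms] — the bimodal shape seen in real ISI histograms, bounded
  by the segmentation threshold so generated sequences are internally
  consistent.

`make_feature_corpus()` attaches cluster-structured feature vectors:
centroid × elementwise uniform noise (±10% by default), with hidden labels
following the Markov model. A key geometric fact shaped its design:
multiplicative ±20% corruption of a centroid projects onto any *fixed*
between-cluster direction with magnitude of order one coordinate's scale,
independent of dimension, so well-separated random centroids are immune to
corruption and provide nothing for an optimizer to recover. Real syllable
feature clouds overlap heavily. The generator therefore places centroids
around a shared base vector with a `separation` parameter;
`sim_recovery_fixture()` freezes the recovery conditions at $k = 8$
clusters, dimension 16, separation 0.16, feature noise ±10%, corruption
±20% and a self-transition probability of 0.5 — under which the true
centroids classify at ≈ 0.999 accuracy, the corrupted ones at ≈ 0.7, and
SIM recovers most of the lost SIS and accuracy. What passing these tests
shows is that the optimizer recovers *recoverable* structure; it does not
show that 2016-dimensional real features behave identically, only that the
overlap regime they live in is the one exercised.

`make_audio_fixture()` renders a timed corpus as linear FM chirps
(40–70 kHz onsets, instantaneous ≥ 25 kHz carrier steps for pitch jumps so
detection is unambiguous) over white Gaussian noise at a configurable SNR,
at 250 kHz sampling. It is a parser test bed, not an acoustic mouse model:
no harmonics, no amplitude modulation, no reverberation.

## Parser

`parse_wav()` is a deliberately simple spectrogram thresholder: 256-point
FFT, half-window hop, per-bin noise floor = median frame power over the
file (robust when vocal activity is sparse), detection at 10 dB above the
in-band floor, events closer than 10 ms merged, events shorter than 5 ms
dropped. All thresholds are package choices exposed in `parser_config()`,
not reproductions of any published parser. Boundaries are reported at hop
resolution with a one-hop onset correction (windows trigger on partial
overlap, so the first triggered frame starts about one hop before the
tone); at 20 dB SNR this lands boundaries within half a hop (~0.26 ms) of
ground truth. The detection spectrogram is zero-padded by one FFT length so
an event ending at end-of-file closes cleanly. Parser fixtures use
`parser_fixture_corpus()`, which floors durations near 10 ms and ISIs above
the merge gap: audio rendered from it certifies boundary accuracy, not the
detectability of ultra-short syllables (a 2 ms syllable is below the
default `min_duration` by design).

## Numerical choices and degenerate inputs

* Suffixes are stored oldest→newest (oldest = most significant digit in
  the leaf index) and printed newest-first by `format_suffix()`, matching
  the right-to-left reading convention.
* Tree sizes are capped (`max_cells`, default $2^{20}$ cells) with an
  actionable error, since $N_c^{D+1}$ grows exponentially.
* `analytic_stationary()` rejects reducible chains, fixes the eigenvector
  sign, clips `-1e-12`-scale negatives, and verifies $\mu P = \mu$ to
  $10^{-9}$.
* Empty suffix trees, unlabeled syllables, zero-norm features, unsorted or
  overlapping syllable tables, and unattainable correlation targets are all
  rejected with messages naming the offending element.
* Problem sizes in the test suite are chosen to keep the full run in a few
  minutes: estimator validation uses $10^3$–$10^5$ syllables, the SIM
  recovery check 10 seeded runs of ≤ 150 iterations on ~2500-syllable
  corpora, the parser fixture ~100–400 syllables.

## Known limitations

* Plug-in entropies are biased low in small samples; the package follows
  the 10% zero-cell validity rule instead of bias-correcting, so scores
  from barely-valid trees should be compared only at equal corpus size.
* The SIS compares labelings of the *same* syllable inventory; it says
  nothing about parsers that segment differently.
* SIM is a random search; it is computationally suboptimal by construction
  and makes no claim of reaching a global optimum — the test-set replay is
  the guard against mistaking overfitting for recovered structure.
* Hierarchical-clustering labelers and their similarity measures are not
  implemented, and the audio front-end is a simplified stand-in.
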