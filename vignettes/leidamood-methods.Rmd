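---
title: "Methods: brain-state dynamics, emotion dynamics, and mediation in leidamood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-state dynamics, emotion dynamics, and mediation in leidamood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`leidamood` analyses naturalistic music-listening fMRI cohorts in which each
subject contributes (i) an ROI-level BOLD matrix (volumes x regions), (ii) a
continuous valence rating trace on a -6 (very sad) to +6 (very happy) scale,
and (iii) questionnaire metadata including an anhedonic-depression score
(MASQ-AD, 14 items, totals 14-70). The scientific question it packages: do
people with more severe anhedonic symptoms recruit attention-related brain
states more, and is their emotional responding flatter, with anhedonia
mediating the link between the two?

## The stimulus programme and condition labelling

The experiment plays 13 classical pieces (3 happy, 3 sad, 7 neutral) in a
fixed order with 2 s of silence between pieces; every sad and happy piece is
followed by a neutral one. The programme ships as a plain-text fixture
(`stimulus_schedule.tsv`) and is validated on parse: monotone, non-overlapping
events, a constant inter-piece gap, and only the three labels.

Volumes are mapped to conditions by their temporal midpoint against half-open
event windows `[start, end)`. With a 2-s TR against integer-second piece
boundaries this rule is unambiguous: a volume midpoint can never sit exactly
on a boundary. Clock zero is the start of the analysed series (dummy scans
already discarded); `dummy_offset_s` shifts the grid for other conventions.
Neutral pieces inherit a derived category (`neutral_following_sad`,
`neutral_following_happy`) over **all** their volumes, because per-song-type
analyses average each metric across all songs of a type rather than
privileging early volumes.

Rating traces are assumed uniformly sampled; each volume takes the trace
value nearest its midpoint, ties resolved toward the earlier sample. Traces
with gaps are rejected rather than imputed — the synthetic generator never
produces gaps, and real button-box dropouts deserve explicit upstream
handling, not silent interpolation.

## Emotion dynamics

Two within-subject statistics summarise a rating trace \(x_1,\dots,x_n\):

\[
\mathrm{STD} = \sqrt{\frac{\sum_i (x_i-\mu)^2}{n}}, \qquad
\mathrm{RMSSD} = \sqrt{\frac{\sum_{i=1}^{n-1}(x_{i+1}-x_i)^2}{n-1}}.
\]

STD is deliberately the population form (denominator \(n\), no Bessel
correction) — the affect-dynamics literature defines it this way and the
package reproduces that definition exactly. Low STD is read as emotional
blunting; RMSSD captures moment-to-moment lability and is order-sensitive
where STD is not. Both are computed over the entire task including silences
by default; `exclude_silence` restricts them to music volumes. Both are
computed on the TR-resampled trace by default (the raw-trace alternative is
just a matter of what you pass in), since the rating sampling convention of
the original design is not fixed by the data formats.

## LEiDA: leading-eigenvector dynamics

Each ROI series is demeaned and Hilbert-transformed (FFT construction of the
analytic signal; no band-pass by default, since none is assumed by the
pipeline — an optional FFT band-pass is config-gated for users replicating
filtered variants). No edge tapering is applied; accuracy tests exclude the
outer 10% of volumes where analytic-signal phase estimates are least
reliable.

At each volume \(t\) the phase-locking matrix
\(\mathrm{dPL}_{ij}(t)=\cos(\theta_i(t)-\theta_j(t))\) is formed. This matrix
is the real part of a complex rank-one outer product, hence positive
semidefinite with rank at most 2; its top eigenvalue divided by \(N\) lies in
\((0,1]\) and reaches 1 only at full synchrony. The leading eigenvector
\(V_1(t)\) is computed by shifted power iteration with Rayleigh-quotient
polishing (warm-started across volumes), and sign-normalised so that the
majority of elements are negative; ties flip so the element sum is \(\le 0\),
and an exactly zero sum forces the first element negative. Under this
convention a globally coherent volume is all-negative, and the ROIs whose
phases detach from the global mode are exactly the positive entries. A
deflated second iteration flags (near-)degenerate top eigenvalues; dPL
matrices of real phase data are essentially never degenerate, but the flag
matters for arbitrary symmetric inputs.

Eigenvectors from all subjects and volumes are pooled and clustered with
k-means (Euclidean distance — monotone in cosine distance on unit vectors —
50 random restarts by default, best within-cluster sum of squares kept) for
each candidate \(k\) in 5–10. The point-based Dunn index (minimum
inter-cluster point distance over maximum intra-cluster diameter) scores each
candidate; the \(k\) with the highest Dunn score is selected. The Dunn
variant is the point-based one because the centroid-based variants hide
boundary structure that this model-selection step exists to penalise. Cluster
numbering is deterministic (decreasing cluster size), and a fixed seed is
mandatory: the whole pipeline is bit-reproducible.

Per subject and state the package reports: occurrence (fraction of volumes),
lifetime (mean maximal run length, in TRs with a seconds column alongside),
and the switching matrix (transition counts between consecutive volumes,
row-normalised over all outgoing transitions including self-transitions, so
occurring rows are stochastic; the off-diagonal entries are the switching
probabilities of interest). Condition-restricted metrics are computed per
song first — runs truncate at song boundaries — then averaged without
weighting across songs of the type.

States are labelled by correlating each signed centroid with binary
membership vectors of the seven canonical resting-state networks (Pearson,
two-sided), significant at \(p < 0.01/k\). A state with no significant
network is a global-coherence candidate. Correlating the full signed centroid
is the default (binarised positive projections are config-gated, off),
because the signed vector carries the anti-phase structure that defines the
state. The shipped network table is a **synthetic** block assignment over the
generator's ROI names — it exists so examples and tests are self-contained;
analyses of real data must supply their own ROI-to-network mapping.

## Statistics

Correlation screens are covariate-controlled Pearson correlations: both
variables are residualised on age, gender (one binary column) and music
background, and the residual correlation is tested against a t reference
with \(n-2-q\) degrees of freedom, two-sided throughout. Each screen family
is corrected with Benjamini–Hochberg FDR; rejection uses the step-up rule,
equivalently adjusted \(p \le q\).

The mediation model is the standardized single-mediator chain: `a` is the
slope of the mediator on the IV, `b` and the direct effect `c'` come from the
joint regression of the DV on mediator and IV, the total effect `c` from the
DV on the IV alone, and the identity \(c = c' + ab\) holds exactly. The
indirect effect \(ab\) receives a percentile bootstrap CI (case resampling,
5000 resamples by default, fixed seed); percentile rather than
bias-corrected, which is the plainest defensible reading of a
"state-of-the-art bootstrap" without further specification. Covariates are
not inside the mediation by default; a flag residualises all three variables
on the covariates first. Full mediation is declared when the CI excludes
zero, the total effect is significant and the direct effect is not. In the
pipeline the IV is the occupancy of the focal state (largest \(|r|\) against
the anhedonia score, mirroring how such a state is singled out in practice),
the mediator is the anhedonia score, and the DV is the rating STD.

The median split assigns `high` to scores at or above the sample median,
matching the convention that the median score itself belongs to the
high-anhedonia group.

## The synthetic cohort generator

The generator plants exactly the structure the analysis assumes, so every
stage has a recoverable ground truth:

* **Brain states.** A Markov chain over `planted_k` states (geometric dwell,
  mean `dwell_mean_trs = 10` TRs) drives a common carrier oscillation at
  `carrier_hz = 0.1` Hz with slow phase jitter. ROIs in the active state's
  community (disjoint equal blocks; leftover ROIs never detach) run in
  anti-phase (\(\pi\) shift); independent phase noise (sd 0.3 rad) is added;
  the BOLD value is the cosine of the phase. The anti-phase construction
  makes the planted community exactly the positive-projection set of the
  leading eigenvector in the noiseless limit, which is what makes the oracle
  analytic. The carrier sits at the top of the BOLD band deliberately: the
  analytic signal tracks a phase-modulated oscillation only when the
  modulation is slow relative to the carrier, so the mean dwell (20 s) must
  span multiple carrier periods (10 s). A slower carrier violates that
  narrowband requirement and smears the \(\pi\)-flips across whole state
  visits, breaking the construction's own guarantee — this is a property of
  the signal model, not a tuning knob.
* **Behaviour.** One designated attention-like state has its entry odds
  tilted by a subject loading; the standardized anhedonia latent is
  `a_true * z(occupancy) + sqrt(1-a_true^2) * noise` (so `a_true = 0.54` is
  the planted standardized path), mapped to the questionnaire scale with
  mean 34.26 and SD 8.84 and clipped to 14–70. The rating amplitude
  multiplier is `1 + amp_spread * (b_true * z(score) + sqrt(1-b_true^2) * eps)`
  with a subject-level disturbance `eps`: without that disturbance the STD
  would be a nearly deterministic function of the score and the planted
  "path" would be a correlation of \(\approx -1\) instead of `b_true = -0.62`.
  Ratings follow the 13-piece programme on the TR grid (`+amp` happy, `-amp`
  sad, 0 otherwise, base amplitude 3 with spread 0.4, per-volume noise sd
  0.8 — consistent with per-song means around \(\pm 2.5\)–3.9 and SDs around
  1.4–2.8 on this scale) and are clipped to \([-6, 6]\).

What the generator does **not** emulate: hemodynamic convolution, scanner
noise spectra, motion, physiological confounds, button-press dynamics, or an
empirical ROI-to-network atlas. Passing recovery tests therefore demonstrates
that the pipeline's machinery is correct and well-calibrated on data
satisfying its assumptions — not that those assumptions hold in any given
scanner dataset.

## Numerical choices and problem sizes

* Default cohort: 31 subjects, 105 ROIs, 250 volumes at TR 2 s — the scale of
  the design it mirrors while staying desk-sized.
* Recovery suites run 20 cohorts of 20 subjects x 200 volumes at 0.3 rad
  phase noise with `planted_k = 6`, and the test-time k-means uses 10
  restarts (the planted optima are found reliably; the package default stays
  at 50 for real analyses).
* The Dunn index reuses one pooled distance matrix across all candidate k;
  memory grows quadratically in pooled volumes (about 240 MB at 7750 pooled
  eigenvectors), which bounds practical pool sizes long before runtime does.
* Power iteration stops on direction change below 1e-14 and polishes with up
  to 8 Rayleigh-quotient steps to a residual of 1e-12; degeneracy is flagged
  when the top gap falls below 1e-8 relative.
* Bootstrap CIs use `quantile()` type 7 on the resampled `ab` draws;
  degenerate resamples are redrawn (more than 10% redraws aborts).
* All randomness derives from one master seed through a fixed per-stage rule
  (`derive_seed`), so reruns are bit-identical and stages are independently
  reproducible.

## Known limitations

* The eigenvector sign convention resolves exact ties deterministically, but
  volumes whose leading eigenvector is genuinely ambiguous (near-degenerate
  dPL) are still assigned to a single state — there is no soft assignment.
* Model selection maximises one cluster-validity index; on real data
  neighbouring k values with near-equal Dunn scores deserve inspection
  (`plot_dunn()`), not blind trust in the argmax.
* Volumes spanning a state transition are intrinsically mixtures; with short
  dwell times the per-volume hard assignment near boundaries is noisy, which
  slightly biases lifetimes downward.
* The mediation model is a single-mediator OLS chain on standardized
  variables: no multiple mediators, no moderated mediation, no Sobel test,
  and causal language is the user's responsibility, not the estimator's.
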