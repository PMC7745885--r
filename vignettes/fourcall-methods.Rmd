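---
title: "Viewpoint-anchored 4C-seq interaction calling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viewpoint-anchored 4C-seq interaction calling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and the model

Circularized chromosome conformation capture sequencing (4C-seq) measures
how often one chosen locus — the *viewpoint*, in practice the inverse-PCR
primer region — is in physical contact with every other restriction
fragment of the genome. The assay digests crosslinked chromatin with a
primary 4-bp cutter (classically DpnII, site `GATC`), ligates the
crosslinked ends into circles, trims them with a secondary 4-bp cutter
(Csp6I, `GTAC`), and sequences outward from the viewpoint. After mapping,
the data reduce to a read count per restriction fragment.

`fourcall` models the normalized per-fragment signal
$S(x)$ at genomic position $x$ as three independent contributions:

$$
S(x) \;=\; B \;+\; I_v\, e^{-|x - x_v|/\lambda}
\;+\; \sum_{i=1}^{N} P_i\, e^{-(x - x_i)^2 / (2\sigma^2)}
$$

* $B$ — a constant background: random ligation contacts, in normalized
  signal units;
* $I_v\, e^{-|x-x_v|/\lambda}$ — the monotonic distance decay of contact
  frequency away from the viewpoint centre $x_v$, with amplitude $I_v$ at
  the viewpoint and decay length $\lambda$ in bp (tens of kb in practice);
* $N$ Gaussian interaction peaks with centres $x_i$, amplitudes $P_i > 0$
  and a shared width $\sigma$ (default 20 kb), representing specific
  chromatin loops.

The package implements the full path from a genome sequence to tested
interaction peaks: in-silico double digestion, read-to-fragment assignment,
the standard fragment filters, windowed normalization, background fitting on
the left–right folded profile, peak detection with a calibrated
significance test, and multi-sample consensus regions.

# Stages and their parameters

## Digestion and fragment classes

`digest_genome()` cuts every chromosome at each occurrence of the two
motifs (cut placed at the motif start by default; the offset is a
configurable `fourc_enzyme` field and nothing downstream depends on it —
only on the boundaries). Fragments are classified by their flanking sites:
`valid` (one primary, one secondary), `blind_primary` / `blind_secondary`
(two sites of the same enzyme — such fragments cannot arise from a proper
primary-ligation/secondary-trim circle and are uninformative), and
`terminal` (chromosome ends). Motifs never match across `N` bases.
Coordinates are 0-based half-open everywhere; BED output stays 0-based.
Only linear chromosomes are supported.

## Counting

Each mapped read is credited to the fragment containing its 5′ position
(`start` for `+` reads, `end − 1` for `−` reads): 4C reads begin at
restriction sites, so the 5′ end identifies the ligated fragment. Duplicate
reads are counted as-is — the protocol includes no UMIs, so deduplication
would be guesswork. Counting is per fragment (not per fragment end); the
two conventions differ only for reads on opposite ends of long fragments
and the per-fragment form matches the single-count-per-fragment model used
downstream.

## Filters and normalization

Three filters are applied in a fixed attribution order (class → length →
viewpoint proximity), so the removal report is deterministic:

| filter            | default | meaning                                           |
|-------------------|---------|---------------------------------------------------|
| fragment class    | —       | remove blind and terminal fragments               |
| minimum length    | 40 bp   | tiny fragments map and ligate unreliably          |
| exclusion radius  | 10 kb   | self-ligation/over-digestion zone around $x_v$    |

The 10-kb window "around" the viewpoint is read as a symmetric radius (a
20-kb excluded span); both radii are configurable. The retained profile is
scaled so that the summed signal within the normalization radius
(default ±2 Mb) equals `target_total` (default $10^6$, i.e. "signal per
million in-window reads"), with the plain sum as the total weight — no
inverse-distance weighting. Profiles are then comparable across libraries,
and the whole analysis is invariant to rescaling raw counts.

## Background fitting on the folded profile

Contact decay is assumed symmetric around the viewpoint, so both arms are
folded onto a common distance axis $d = |x - x_v|$, averaged in 5-kb bins,
and $a(d) = B + I_v e^{-d/\lambda}$ is fitted by bounded
Levenberg–Marquardt ($\lambda \in [1\,\mathrm{kb}, 10\,\mathrm{Mb}]$,
$B, I_v \ge 0$). Peaks sit *above* the decay, so the fit must resist them;
robustness is layered:

1. **Theil–Sen backbone.** For each $\lambda$ on a 25-point log grid the
   linear pair $(B, I_v)$ is fitted against $t = e^{-d/\lambda}$ by
   repeated-median slopes over a deterministic systematic pair sample, and
   the $\lambda$ with the smallest median absolute residual wins. This
   50%-breakdown start cannot be steered by contamination the way least
   squares can (a fixed-fraction trim of a badly started least-squares fit
   can lock onto a spurious short-$\lambda$ "spike" solution).
2. **Threshold trimming.** Bins whose standardized positive residual
   exceeds 3 are treated as putative peaks and dropped, at most 10% of bins
   per cycle, for two cycles. The threshold matters: trimming a fixed
   fraction unconditionally clips the upper noise tail of a peakless
   profile and biases the whole fit low.
3. **Fragment-resolution GLS pass.** Once a noise model is available (next
   section), the decay is refitted at fragment resolution on the folded
   distance axis — binning is only a smoothing device and costs about a
   factor 2.5 in $\hat\lambda$ precision — using inverse-variance weights,
   with weights updated over two IRLS rounds. Only fragments from distance
   bins that survived the binned pass are used, because one-sided trimming
   of skewed per-fragment counts would bias the mean. Decay-length
   precision matters directly: a few percent of $\hat\lambda$ error leaves
   coherent residuals near the viewpoint that masquerade as peaks.

A perfectly flat profile degenerates gracefully
($B = \bar a$, $I_v = 0$, $\lambda$ at its lower bound, flagged not
converged); non-convergence returns the best iterate with
`converged = FALSE`.

## Noise model

Fragment counts are overdispersed. When the profile carries raw counts the
noise is modelled as negative binomial on the count scale,
$\mathrm{var}(c) = \mu + \mu^2/\phi$, with $\phi$ estimated by a trimmed
moment pilot (the statistic $((c-\mu)^2 - \mu)/\mu^2$ has expectation
$1/\phi$ at any $\mu$) followed by maximum likelihood on fragments within
5 pilot standard deviations (clipping removes peak-inflated fragments). On
the normalized scale this gives the closed form
$\sigma(m) = \sqrt{\mathrm{nc}\, m + m^2/\phi}$ with $\mathrm{nc}$ the
normalization constant and $m$ the expected signal. Without counts
(e.g. a profile re-read from bedGraph) a power law $\sigma(m) = A m^b$ is
fitted to distance-binned MADs, and a constant global MAD
($1.4826 \times$ median absolute deviation) is the last fallback. The
global MAD is also reported as `residual_scale` on every fit.

A single global scale is *not* adequate: near the viewpoint the expected
count — and hence the noise — is orders of magnitude larger than far-cis,
and a homoscedastic test floods the decay zone with false positives.

## Peak detection and significance

Candidates are local maxima of the noise-standardized residual series after
a centred running mean over `smooth_k = 5` retained fragments (shrunk at
the edges). Each candidate is scored by the weighted least-squares
amplitude of a fixed-width Gaussian kernel at its position,

$$
\hat P = \frac{\sum_j g_j r_j / \sigma_j^2}{\sum_j g_j^2 / \sigma_j^2},
\qquad
z = \hat P \Big/ \mathrm{sd}(\hat P),
$$

where $g_j$ is the kernel, $r_j$ the residual and $\sigma_j$ the local
noise scale; for constant noise this reduces to
$z = \hat P \sqrt{k_\mathrm{eff}} / \mathrm{scale}$ with
$k_\mathrm{eff} = \sum_j g_j^2$ the effective number of fragments under the
kernel. $\mathrm{sd}(\hat P)$ additionally includes the delta-method
variance of the subtracted background prediction (from the decay-fit
parameter covariance), which would otherwise inflate $z$ where the decay
curve is least certain. The p-value is the one-sided upper-tail normal
probability, and a peak is significant when $p < \alpha$ with
$\alpha = 5 \times 10^{-4}$ by default.

Significant peaks are called greedily: the best candidate is accepted, its
centre and width refined by least squares (centre within $\pm 2\sigma$ and
never inside the exclusion window; width within a factor 2 of $\sigma$),
its fitted Gaussian subtracted — raising the local noise model by its mean,
since called signal carries count noise too — and the series rescanned.
This prevents one physical interaction from being called repeatedly through
its shoulders. Candidates closer than $\sigma$ to the exclusion window are
not eligible: their kernel is half-truncated and indistinguishable from
decay misfit. After the greedy pass all called peaks are refitted *jointly*
(amplitudes profiled out by weighted linear least squares, centres and
log-widths by bounded quasi-Newton in units of $\sigma$), each call is
re-tested against the full model of the others, and calls closer than
$2\sigma$ are merged keeping the smaller p-value.

The $\alpha$ threshold is applied per candidate; no FDR layer is added.
Because candidates are selected as local maxima, moderate p-value quantiles
are mildly inflated relative to uniform (roughly twofold at $p \approx
0.01$ in our null simulations) while the decision-relevant far tail at the
default $\alpha$ is at or slightly below nominal; the package's null
simulations quantify exactly this.

## Consensus across samples

Significant peaks become intervals $[x_i - 2\sigma, x_i + 2\sigma]$;
bases covered by at least `min_support` samples (base-level coverage via
run-length encodings, robust to width differences between samples) form
consensus regions, merged across gaps of at most `merge_gap` bp (default
0). Each region records its supporting samples and their best p-values.
Note that two true interactions closer than about $4\sigma$ produce
abutting intervals and can fuse into a single region or leave slivers at
the junction — consensus resolution is set by $\sigma$, not by fragment
size.

# The synthetic-data generator

`simulate_genome()`, `simulate_counts()` and `make_fixture()` provide a
generative twin of the signal model so every stage can be validated against
known truth without downloads. Defaults, chosen once as the package's study
conditions:

* genome: i.i.d. bases at GC 0.41 (human-like; what matters is the implied
  ~270 bp GATC spacing), 5 Mb, viewpoint at the centre;
* background $B = 0.5$, $I_v = 20$, $\lambda = 50$ kb (signal units are
  arbitrary — only ratios matter after normalization);
* two peaks mirroring a promoter-like strong interaction ~350 kb from the
  viewpoint (amplitude 15, $\sigma$ 20 kb) and a broader enhancer-like one
  at ~430 kb (amplitude 8, $\sigma$ 30 kb) — geometry only, no real
  coordinates claimed;
* expected in-window depth $2 \times 10^5$ reads; negative-binomial
  inverse-dispersion $\phi = 5$ (strong overdispersion, a stress case for
  the noise estimator; $\phi \to \infty$ recovers Poisson);
* blind and short fragments draw background-rate counts so the filters have
  real work; valid fragments inside the exclusion zone keep the full
  viewpoint-inflated mean.

Every draw flows from one integer seed (`withr::with_seed`, no global-state
leakage), so fixtures are byte-reproducible.

What the generator does *not* emulate: mappability and GC biases along the
genome, PCR duplicates, ligation-junction chemistry, trans contacts, and
fragment-length-dependent capture efficiency. Passing the synthetic
validation therefore demonstrates correctness of the statistical machinery
under the stated model, not robustness to every artefact of real
libraries.

# Numerical choices and test design

* Problem sizes in the test-suite simulation studies: one shared 4.6 Mb
  digested genome (~33,000 fragments, ~11,000 retained in ±2 Mb), 100
  replicates for peak recovery, 200 null profiles for calibration, 20 for
  decay-length recovery. The acceptance script uses 25/25/10 replicates.
* Centre accuracy is information-limited: with dispersion 5, the
  Cramér–Rao bound for a Gaussian-peak centre on a ~270 bp fragment grid at
  the default amplitudes is ~0.4–0.5 kb — several fragment lengths. Peak
  centres are accurate to about one fragment only in the near-Poisson
  regime; under strong overdispersion no estimator can do better, which the
  validation suite makes visible rather than hiding.
* Ties at the significance floor: p-values below ~$10^{-308}$ underflow to
  0, so greedy selection ranks candidates by $z$, not $p$.
* Optimizer scaling: peak centres are parametrized in units of $\sigma$ so
  bounded quasi-Newton sees $O(1)$ parameters; raw-coordinate parameters
  (~$10^6$ bp) defeat finite-difference gradients.
* All stages are deterministic given inputs and configuration; randomness
  exists only in the generator, which takes explicit seeds. Pipeline
  outputs carry no timestamps, so reruns are byte-identical and the run
  manifest records md5 checksums.

# Known limitations

* The significance procedure is a calibrated stand-in: the analysis this
  package reproduces states the threshold ($p < 0.0005$) but not the test.
  The kernel z-test is simple, fast, and its null behaviour is quantified
  by simulation; a permutation-based variant could be swapped in behind
  `detect_peaks()` without touching the rest of the pipeline.
* The model is cis-only within the normalization window (±2 Mb);
  genome-wide trans interactions are out of scope.
* A single shared $\sigma$ is assumed at detection time (per-peak widths
  are refined afterwards within a bounded range); interactions much broader
  than $3\sigma$ will be fragmented, much narrower ones diluted.
* Two-sided biological asymmetry (different decay left and right of the
  viewpoint) is averaged away by folding, as in the published analysis.
* Methylation-sensitive digestion, enzyme-database lookup and circular
  chromosomes are unsupported.
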