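---
title: "Methods: shrinkage mutual information for single-cell differential expression, and the synthetic benchmark behind it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shrinkage mutual information for single-cell differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `scbench`: the
generative model of the synthetic single-cell experiment, the
mutual-information differential-expression statistic and its shrinkage
estimator, the fluctuation analysis, and the numerical conventions used
throughout. It states no empirical results; those live in the test suite and
in `scripts/acceptance.R`, which compute them from scratch on every run.

## 1. Why mutual information, and why shrinkage

A differential-expression statistic for single cells has to cope with
distributions that are zero-inflated by dropout, right-skewed, occasionally
bimodal (cell-cycle or mixed subpopulations), and estimated from a dozen or
two cells per type. Location tests (t, Wilcoxon) see only a shift;
mutual information between the *discretized expression level* $B$ and the
*cell-type label* $T$,

$$I(B;T) = H(B) + H(T) - H(B,T),
\qquad H(p) = -\sum_i p_i \log_2 p_i,$$

captures any change in the conditional distribution — shift, spread, or
modality — and is expressed in interpretable units (bits). The design
decision to measure dependence between expression *bins* and *state labels*
(rather than, say, between pairs of genes) keeps the contingency table small
($K \times L$ with $L$ the number of cell types), which matters because the
number of cells $n$ is the scarce resource.

The maximum-likelihood (plug-in) MI estimator is badly biased upward for
small $n$: with $n \approx 24$ cells and $K L \approx 10$–$30$ cells in the
table, empty and singleton cells dominate. We therefore estimate cell
frequencies with a James–Stein-type convex shrinkage toward the uniform
distribution $t_{kl} = 1/(KL)$:

$$\hat p^{\lambda}_{kl} = \lambda^\* t_{kl} + (1-\lambda^\*)\hat\theta_{kl},
\qquad \hat\theta_{kl} = c_{kl}/n,$$

with the closed-form data-driven intensity

$$\lambda^\* =
\frac{1-\sum_{kl}\hat\theta_{kl}^2}{(n-1)\sum_{kl}(t_{kl}-\hat\theta_{kl})^2},$$

clipped to $[0,1]$, and $\lambda^\* = 1$ when the denominator vanishes (the
observed table already sits on the target, so full shrinkage is a no-op).
The estimator trades a small bias toward independence for a large variance
reduction; its mean-squared error beats maximum likelihood precisely in the
small-$n$ regime (the test suite verifies this by simulation). Entropies and
MI are then computed from the *shrunk joint*, with marginals obtained by
summing the joint — this guarantees $I \ge 0$, symmetry in the two margins,
and $I \le \min(H(B), H(T))$ by construction. A table with a single row or
column is degenerate and reported as $I = 0$ with a flag.

Because shrinkage mixes the joint toward uniform, an independent (rank-1)
table does not generally stay at $I = 0$ after shrinkage; only the plug-in
estimate is exactly zero there. This is the usual bias/variance trade and is
documented rather than "fixed".

MI is an effect size, not a calibrated test statistic, so `de_scan()` pairs
it with a Wilcoxon rank-sum p-value per gene (exact when group sizes permit
and ties are absent, normal approximation with continuity correction
otherwise) and Benjamini–Hochberg adjustment across tested genes. Genes with
identical values in every cell carry no information and are excluded from
testing.

## 2. Discretization: Freedman–Diaconis with explicit degenerate rules

Expression values for one gene (all cells pooled across types, so the bin
grid is label-blind) are binned with the Freedman–Diaconis rule: width
$h = 2\,\mathrm{IQR}\, n^{-1/3}$ using type-7 quantiles (R's default), and
$K = \lceil \mathrm{range}/h \rceil$ capped to $[1, 16]$. The cap keeps the
contingency table estimable at single-cell sample sizes. Degenerate inputs
are handled deterministically:

- zero range (all values equal): $K = 1$;
- zero IQR but nonzero range (more than half the values tied, typical under
  dropout): $K = \lceil \log_2 n \rceil + 1$ equal-width bins, the
  Sturges-like fallback.

Bins are half-open $[e_k, e_{k+1})$ with the last bin closed, so the maximum
falls in bin $K$; values outside the grid are an error rather than silently
clamped.

## 3. The generative model of the synthetic experiment

The benchmark's philosophy: every analysis must be scored against a known
answer, so the generator retains all latent quantities (`make_truth()`), and
the generator defaults *are* the study conditions — they are chosen up
front, on generative grounds, not adjusted to make recovery easy.

For gene $g$ in cell $c$ of type $\tau$ and phase $\phi$, the measured
expression is

$$x_{gc} = 10^{\,\mu_g + \delta_g \log_{10}(2)\,[\tau = \mathrm{PrE}]
 + \gamma_{g\phi} + \varepsilon^{bio}_{gc}}
 \times 10^{\,\varepsilon^{tech}_{gc}} \times d_{gc},$$

with

- baseline $\mu_g \sim \mathcal N(1.2,\,0.6^2)$ on the $\log_{10}$ scale
  (median $\sim 16$ expression units, spanning roughly 0.1–1000 across
  genes);
- DE effect $\delta_g$: for `n_de` genes, $|\delta_g| \sim U(1,4)$ in
  $\log_2$ units with alternating sign (balanced up/down in the second
  type), 0 otherwise;
- cell-cycle offsets $\gamma_{g\phi}$ for a `cycle_fraction = 0.1` subset of
  genes, $\mathcal N(0, 0.3^2)$ per non-G1 phase;
- biological fluctuation
  $\varepsilon^{bio}_{gc} \sim \mathcal N(0, \sigma^{bio\,2}_g)$ with
  $\sigma^{bio}_g \sim U(0.1, 0.5)$ — per-gene lognormal cell-to-cell
  variability;
- technical noise $\varepsilon^{tech}_{gc} \sim \mathcal N(0, 0.15^2)$,
  applied to *every* sample class;
- dropout $d_{gc} \in \{0,1\}$, a Bernoulli with logistic probability
  $\mathrm{logit}^{-1}(\beta_0 - \beta_e \log_{10} x - \beta_\ell \log_{10}
  \ell_g + \beta_{gc}\, \mathrm{GC}_g)$, defaults
  $\beta_0 = -2, \beta_e = 2, \beta_\ell = 0.5, \beta_{gc} = 1$: low-
  expression, short, GC-rich transcripts drop out more — the qualitative
  bias pattern the QC module is designed to detect.

Transcript lengths are lognormal (median 1.8 kb, floor 200 bp), GC fractions
Beta(24, 26) (centered slightly below 0.5 with realistic spread).

Three sample classes share this machinery:

- **single_cell**: the full model above;
- **pooled_equivalent**: a single-cell-sized aliquot of a many-cell lysate.
  Averaging the lognormal biological term over many cells replaces
  $10^{\mu_g + \varepsilon^{bio}}$ by its population mean
  $10^{\mu_g} \exp\!\big(\tfrac12 (\sigma^{bio}_g \ln 10)^2\big)$; the
  sample then carries technical noise only, and no dropout. This class is
  the measurement-error null for the fluctuation analysis;
- **bulk_reference**: same construction, used as technical replicates for
  reproducibility scoring.

Exogenous spike-in transcripts enter at fixed copy numbers per
cell-equivalent (1000, 100, 20, 5 for the four controls), receive technical
noise but neither biological fluctuation nor dropout, and sit outside the
endogenous gene count.

Read-level data are generated separately: `simulate_reads()` plants the
26-base amplification-adaptor sequence in exactly
`round(n_reads * adaptor_rate)` reads (default rate 0.05), on either strand
at a uniform position including partial overhangs, then applies uniform
per-base sequencing errors. The scanner (`adaptor_scan()`) slides the
adaptor over each read at every offset with at least 16 overlapping bases
and calls a hit at $\ge 80\%$ ungapped identity, on both strands, treating
`N` as a mismatch. The identity threshold makes recovery robust to the
planted per-base error rate without inflating hits on random sequence
(a 16-mer match at 80% identity is vanishingly unlikely by chance).

What the generator deliberately does **not** emulate: amplification-length
bias along transcripts, UMI/duplication structure, batch effects beyond the
declared batch labels, correlated gene modules (genes are independent given
type and phase), empirical count noise (expression is continuous, FPKM-like),
and doublets. These are out of scope for the analyses benchmarked here; all
claims the package makes are about recovering what the model plants.

## 4. Reproducibility, depth and fluctuation conventions

- **Detected/reproducible rule** (`count_reproducible()`): a transcript is
  detected when strictly above `min_expr` in both profiles (unit presets:
  FPKM/tpm $> 1$, RMA $\log_2 > 7$), and reproducible when additionally the
  larger/smaller ratio on the *linear* scale is strictly below the 2-fold
  window; $\log_2$ units are exponentiated first. Strict inequalities make
  boundary behaviour unambiguous.
- **Correlations** are Pearson on $\log_{10}(x + 1)$; the pseudo-count keeps
  zeros finite and is reported with each result.
- **Depth curves** (`downsample_detection()`): multinomial subsampling (a
  reads-are-exchangeable approximation, used by default for speed) or exact
  multivariate hypergeometric sampling without replacement, which reproduces
  the observed counts at full depth. When transcript lengths are supplied,
  FPKM is recomputed at each depth as
  $\mathrm{count} / (\mathrm{length}_{kb}\cdot\mathrm{depth}_{M})$.
- **Fluctuation** (`fluctuation_reproducibility()`,
  `fluctuation_vs_error()`): per-gene variance ratio of $\log_{10}$
  expression against the $F(n_a-1, n_b-1)$ distribution. Two-sided
  $p = 2\min\{P(F \le f), P(F \ge f)\}$ between two independent single-cell
  sets; a gene is *reproducibly fluctuating* when its BH-adjusted $p$
  exceeds 0.6 — failure to reject variance equality at a deliberately
  conservative threshold. Against pooled-equivalent samples the test is
  one-sided (upper tail), since only excess single-cell variance indicates
  biology. Zero variance in both sets is degenerate-reproducible with
  $p$ undefined; in exactly one set, non-reproducible with $p = 0$.
- **Structure**: PCA on genes-centered $\log_{10}(x+1)$ via the singular
  value decomposition (`prcomp`), with a deterministic sign convention
  (largest-magnitude loading positive); Ward clustering (`ward.D2`) on
  Euclidean distances of the same transform, with input columns sorted by
  sample id so the serialized Newick tree is order-invariant; hypergeometric
  over-representation $P(X \ge k)$ for gene-set enrichment.

## 5. Numerical choices

- Entropy terms $0 \log 0$ are defined as 0; MI is clamped at 0 to absorb
  $-10^{-16}$-scale rounding from summing the three entropies.
- Two-sided F p-values compute both tails with `pf(..., lower.tail =)`
  directly rather than `1 - pf(...)`, avoiding catastrophic cancellation for
  extreme statistics, and are capped at 1.
- All randomness flows through one master seed. Each sample, stage and
  utility derives an independent stream via a multiplicative hash of
  `(master, label)` kept strictly inside double-precision integer range, so
  adding a sample or toggling a pipeline stage never perturbs other draws,
  and a rerun reproduces `report.json` byte for byte (the config hash
  excludes the output directory, which is location not content).
- TSV round-trips serialize at full precision (`%.17g`); JSON output uses
  `digits = NA` for the same reason.

## 6. Problem sizes

Default sizes are the package's own choice, set for a laptop-scale
demonstration that still has statistical teeth: the default generator makes
2,000 genes with 200 DE; the default pipeline runs 1,000 genes / 100 DE with
12 cells per type (two batches of 12 for the ES type), 8 pooled-equivalent
samples, 2 bulk technical replicates and 2,000 simulated 50-bp reads. Twelve
cells per type is a realistic lower bound for single-cell studies and is
exactly the regime where the shrinkage estimator earns its keep; the
per-gene analyses are linear in gene count, so scaling up is routine.

## 7. Limitations

- MI after shrinkage is biased toward (but not onto) independence; rankings
  are trustworthy, absolute bit values at small $n$ are not.
- The FD bin count interacts with dropout: heavy zero-inflation triggers the
  zero-IQR fallback, which coarsens resolution among expressed cells.
- The Wilcoxon p-value attached to each gene tests location, while MI also
  responds to spread/modality changes — a gene can have high MI and a
  non-significant location test. The pairing is a pragmatic compromise, not
  a calibrated test of $I = 0$ (that would require permutation).
- Pooled-equivalent samples model technical error only if pooling truly
  averages biology; real pools of few cells retain residual biological
  variance, so the one-sided F-test is anti-conservative there.
- The generator's independence across genes means gene-gene covariance
  structure (and its effect on PCA beyond the planted type axis) is not
  benchmarked.
- The adaptor scanner is ungapped; indel-containing contaminant copies
  degrade identity quickly and can be missed near the 80% threshold.
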