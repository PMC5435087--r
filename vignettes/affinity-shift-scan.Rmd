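---
title: "Scanning a phylogeny for shifts in ligand affinity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning a phylogeny for shifts in ligand affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affshift)
```

# Overview

`affshift` turns per-node affinity estimates on a protein-family phylogeny
into statements about *where* affinity changed. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
what the synthetic-data generators do and do not emulate, and the design
decisions taken where the methodology was genuinely open.

# Ancestral reconstruction

## Model

Sequences evolve under a continuous-time reversible Markov model built from
empirical exchangeabilities $s_{ij}$ (LG by default; WAG/JTT available) and
equilibrium frequencies $\pi$: $q_{ij} = s_{ij}\pi_j$, diagonal set so rows
sum to zero, and the matrix normalized so that one unit of branch length is
one expected substitution per site. Among-site rate variation uses the
discrete-gamma approximation with `k = 4` equal-weight categories and shape
$\alpha$ (default 1; `fit_gamma_shape()` maximizes the likelihood over
$\log\alpha$ by one-dimensional search, tolerance $10^{-4}$). Transition
probabilities come from a symmetric eigendecomposition of
$\Pi^{1/2} Q\, \Pi^{-1/2}$, which is numerically stable out to branch
lengths of tens of substitutions/site; tiny negative entries from round-off
are clamped to zero and rows renormalized.

## The gap state

Ancestral insertions and deletions can matter as much as substitutions —
a two-residue insertion next to an RNA-contacting histidine is exactly the
kind of event a reconstruction should expose. The default model therefore
treats the gap `-` as a 21st character state with uniform exchangeability
(1.0, the scale of a typical LG entry) to every amino acid and an
equilibrium frequency estimated from the alignment
(`estimate_gap_freq()`). This makes indel states reconstructable and
sampled like residues, at the cost of modelling each gap column as a single
substitution-like process. `gap_state = FALSE` recovers the classical
treatment (gaps as missing data, 20 states). `X` always means "unknown
residue": any amino acid, but not a gap.

## Marginal reconstruction and sampling

`marginal_asr()` computes, per internal node and site, the posterior state
distribution by combining the partial likelihoods below the node (pruning
pass) with those above it (outside pass), re-weighted by the root prior
$\pi$; with several rate categories the posterior is the mixture over
categories weighted by per-site category likelihoods. ML sequences take the
per-site argmax with ties broken alphabetically by state symbol, for
reproducibility. `sample_ancestral()` draws sequences site-independently
from those posteriors (20 per node by default), the input to the robustness
test below. Branch lengths are taken as given and never re-optimized; trees
must be rooted (marginal reconstruction is root-dependent), and
`midpoint_root()` is provided but never applied silently.

Correctness is established against exhaustive enumeration: on instances
with up to 5 leaves and 3 sites, posteriors match the brute-force sum over
all joint internal states to $10^{-9}$, with transition matrices computed by
an independent route (`Matrix::expm`) in the oracle; the likelihood is
invariant under re-rooting to $10^{-8}$, as time-reversibility requires.

# The branch scan

Each node carries replicate pKd values (default 5, matching replicate
structural models per sequence). For every branch, `welch_t()` compares
child and parent replicates (unequal-variance, Satterthwaite df,
two-tailed); `bh_fdr()` applies Benjamini–Hochberg step-up correction
jointly across all branches; branches with $q < 0.05$ are flagged. Edge
conventions: two zero-variance samples with equal means give $p = 1$, with
different means $p = 0$. BH was chosen over BY as the field default; the
procedure is exposed so BY can be substituted upstream if dependence is a
concern.

A shift call is *robust* when the ML sequence's replicate affinities are
not significantly different (Welch, $\alpha = 0.05$) from the affinities of
sequences sampled from the ancestral posterior, pooled across draws —
pooling matches the idea of testing against the *distribution* over
plausible ancestors rather than each draw separately. Reconstruction-quality
diagnostics include Pearson/Spearman correlations between per-node mean
posterior probability and pKd (`ambiguity_correlation()`) and a
Gaussian-KDE mode of the pKd distribution (`kde_mode()`; Silverman
bandwidth, 512-point grid over the range ± 3 bandwidths, ties to the lower
value).

The scan tests each branch marginally, so it cannot attribute slow trends
spread over many consecutive branches — by design; that regime belongs to
the rate model below.

# Brownian-motion rate shifts

Affinity is modelled as a trait evolving by Brownian motion whose variance
accrues proportionally to branch length in substitutions/site; the
coefficient of proportionality $\sigma^2$ is free, and discrete *rate
shifts* place multipliers $m > 0$ at nodes. A shift at node $n$ applies to
the branch above $n$ and is inherited by the whole subtree until overridden
by a nested shift. Per-observation standard errors enter the likelihood as
independent Gaussian noise; observations may sit at leaves only or at
leaves plus internal nodes (`use_ancestral_values`), and both modes run on
the same inputs. The likelihood is computed by pruning (Gaussian message
passing), never by dense covariance inversion, and matches the dense
multivariate-normal density to $10^{-8}$ on small trees; a tip with
infinite standard error drops out of the likelihood exactly.

`rjmcmc_run()` samples shift configurations by reversible jump:

* **Priors** — number of shifts $\sim$ Poisson($\lambda = 1$) with uniform
  locations among non-root nodes; $\log m \sim N(0, \tau^2)$, $\tau = 1$;
  $\log\sigma^2$ uniform on $[-20, 20]$; root value diffuse Gaussian. The
  cited break-point model's exact priors are unpublished, so these are
  documented, configurable substitutes.
* **Proposals** — 25% birth (location uniform among free nodes, multiplier
  drawn from its prior, which cancels in the acceptance ratio and requires
  no extra Jacobian), 25% death, 25% move (relocate a shift), 25% scale
  (random-walk on $\log\sigma^2$, the root value, or one $\log m$).
  Invalid proposals (death with no shifts) are rejected in place, which
  preserves detailed balance.
* **Defaults** — 100,000 generations, thinned every 100, first 25% of
  samples discarded, 4 independent chains whose post-burn-in samples are
  pooled; chain $i$ uses `seed + i - 1`.
* **Diagnostics** — `asdsf()` reports the mean across-run standard
  deviation of per-node shift posteriors with the conventional < 0.01
  convergence gate. Shifts are classified as increases or decreases by
  comparing the sampled multiplier with the parent's effective rate.

Sampler correctness is checked the standard way: with the likelihood
disabled, the chain must recover the Poisson prior on the shift count
within Monte Carlo error (it does), and with a planted 20× subtree
multiplier the true node must attain the top posterior shift probability in
≥ 90% of seeded runs (it does, 19/20 at 10,000 generations). One practical
note from those experiments: when the shifted subtree is very small (a few
tips), single trait realizations can be genuinely ambiguous about the exact
shift node — neighbouring placements explain the data equally well — which
is a property of the data, not the sampler; the validation experiment
plants the shift on a 10-tip subtree, the clade scale the model targets.

# Binding kinetics

`steady_state_fit()` fits the one-site isotherm
$R = R_{max} C / (K_d + C)$ to plateau responses by `nls` (port algorithm)
with multi-start — $K_d$ initialized at the geometric mean of the
concentration series and at the concentration nearest half-max — keeping
the best residual sum of squares. `association_rates()` fits
$R(t) = R_{eq}(1 - e^{-k_{obs} t})$ per concentration (log-linear start for
$k_{obs}$, three-point multi-start), and `km_fit()` fits a hyperbola to
(concentration, rate) pairs; interpolation at half-maximal rate is exposed
as an alternative.

One subtlety deserves emphasis. The *instantaneous* initial rate of an
ideal 1:1 system is $R_{eq} k_{obs} = R_{max} k_{on} C$ — linear in
concentration, with no finite half-max. What saturates in practice is the
mean rate over a finite observation window,
$R_{eq}(1 - e^{-k_{obs}T})/T$, which for $k_{obs}T \gg 1$ is proportional
to the plateau and therefore half-maximal at exactly $K_d$. Both readouts
are implemented (`rate_type = "initial"` / `"windowed"`); the windowed
readout is what makes an empirical $K_m$ comparable to $K_d$, and is used
for that consistency check. Replicate constants are compared and
summarized on the pKd scale, where replicate error is closer to Gaussian.

The sensorgram generator emits association (6 min) and dissociation
(4 min) phases with $k_{off} = k_{on} K_d$, Gaussian noise, and
noise-only control probes; the default sampling interval is 0.5 s rather
than an instrument-grade 3 ms purely to keep test data small (the `dt`
argument restores any grid). Association-phase times are measured from the
phase start, which the fits assume.

# Clustering and consensus

`build_graph()` converts pairwise E-values ($\le 0.1$) to weights
$\min(-\log_{10} E, 200)$ and caps node degrees at 280 by keeping an edge
only when it ranks within the top 280 at *both* endpoints. The
either-endpoint union alternative was considered and rejected: it can
never remove a leaf node's only edge, so a hub's cap would not actually be
enforced — the mutual rule both enforces the cap and preserves symmetry.
`mcl()` is a from-scratch Markov clustering: self-loops at each node's
maximum incident weight, one-off pre-inflation (power 3) for contrast, then
expansion/inflation to a $10^{-6}$ fixed point (column stochasticity is
tracked every iteration and holds to $10^{-12}$); clusters are the
connected components of the converged support.
`select_clustering()` scores an inflation sweep by the mean number of
annotated members per annotated-containing cluster (max-count and purity
scorings are exposed as options, since "maximizing annotated members per
cluster" admits several readings), with ties going to the lowest inflation.

`mrp_matrix()` codes every non-trivial clade of every input tree as a
0/1/? column (missing taxa get `?`), exported as TSV or relaxed PHYLIP for
external supertree inference — the tree search itself is out of scope.
`majority_consensus()` counts clades, keeps those above the frequency
threshold (default 0.5; such sets are mutually compatible by construction),
assembles the tree by nesting, and records frequencies as node supports;
`collapse_low_support()` then contracts any edge whose child support falls
below a threshold (0.8 is the conventional cut for SH-like aLRT), with the
contracted edge's length discarded and children keeping their own lengths.

# Synthetic data: what a green test establishes

The generators produce data exactly under the models the inference assumes:
sequences i.i.d. across sites under the reconstruction model, affinities as
a deterministic 2-site motif score (a +0.7 "contact histidine" and a +0.3
"basic patch") plus Gaussian replicate noise, traits exactly Brownian,
sensorgrams exactly 1:1 Langmuir. Default scale: 32-leaf pure-birth trees
with branch lengths U(0.05, 0.5) substitutions/site — the shape and depth
of a deep domain phylogeny, small enough for desk-fast tests.

Green tests therefore establish *correctness of the machinery* — estimators
recover planted truth at nominal error rates when the model is right. They
do not establish robustness to what real data add: alignment error,
among-site dependence, model misspecification, predictor bias shared across
adjacent nodes (which would correlate parent and child replicates), or
non-1:1 binding artifacts. Conclusions about any real protein family still
rest on the user's alignment, tree and affinity estimates.

# Numerical conventions

Partial likelihoods are rescaled per site by their maximum (log-scale
accumulators) to prevent underflow; category mixing uses log-sum-exp.
Argmax ties in ML sequences break alphabetically. Kd is molar everywhere
internally; micromolar appears only in I/O and reporting. All stochastic
functions take an explicit seed, restore the caller's RNG state, and are
bit-reproducible; multi-chain runs derive per-chain seeds by increment.
Fits that fail from every start raise errors naming the constant being
fitted; saturation-only designs are flagged unidentifiable rather than
returning an arbitrary Km.

# Known limitations

* Site-independent gap evolution is a crude indel model; a two-residue
  insertion is treated as two independent events.
* The branch scan assumes replicate noise independent across nodes; shared
  predictor bias would inflate both false positives and false negatives in
  ways the synthetic world does not probe.
* The rjMCMC explores shift placements one node at a time; for very large
  trees, mixing over distant multi-shift configurations may need longer
  chains than the defaults.
* `mcl()` materializes a dense matrix — appropriate for domain-family
  graphs of up to a few thousand nodes, not for full-database graphs.
* Joint (as opposed to marginal) reconstruction, codon models,
  branch-length optimization, OU/Lévy trait models and global kinetic fits
  are out of scope.
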