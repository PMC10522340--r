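---
title: "Differential RBMs for immune repertoire sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential RBMs for immune repertoire sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffrbm)
```

## The problem

Two recurring questions in T-cell immunology have the same statistical
shape. First: among the peptides that an HLA class I molecule presents on
the cell surface, which ones actually elicit a T-cell response
(immunogenicity)? Second: among the T-cell receptors a person carries,
which ones recognize a given epitope (specificity)? In both cases the
interesting sequences are a small *selected* subset of a much larger
*background* ensemble — immunogenic peptides within all presented
peptides, epitope-specific CDR3β chains within the bulk recombination
repertoire — and the background itself has strong sequence constraints
(HLA anchor preferences, V(D)J generation statistics) that have nothing to
do with selection.

A model trained directly on the small selected set conflates the two
signals. The approach implemented here separates them by construction.

## The model

Sequences are fixed-length categorical vectors $\sigma$: 9 residue sites
for peptides (21 states per site, 20 amino acids plus gap), 20 residue
sites for CDR3β, optionally followed by a V site (48 states) and a J site
(13 states). The probability model is a Boltzmann distribution
$P(\sigma) \propto e^{-H(\sigma)}$ whose energy splits into a background
and a differential part, $H = H^b + H^d$, each parametrized as a
Restricted Boltzmann Machine marginal:

$$H^b(\sigma) = -\Big(\sum_i g^b_i(\sigma_i)
  + \sum_{\mu=1}^{M_b} \Gamma^b_\mu\big(I^b_\mu(\sigma)\big)\Big),
  \qquad I^b_\mu(\sigma) = \sum_i w^b_{i\mu}(\sigma_i),$$

with single-site fields $g$, weights $w$ coupling sites to hidden units,
and $\Gamma_\mu(I) = \log \int dh\, e^{-U_\mu(h) + hI}$ the cumulant of
the hidden-unit potential $U_\mu$. $H^d$ has the same form with its own
fields $g^d$, weights $w^d$ and $M_d$ hidden units.

Training is two-step transfer learning:

1. **Background fit** (`trainBackground`): maximize the (optionally
   similarity-reweighted) mean log-likelihood of the large background
   dataset over the background parameters.
2. **Differential fit** (`trainDifferential`): with the background frozen
   (bitwise untouched, and verified so in the tests), maximize the mean
   log-likelihood of the selected dataset under the *combined* model over
   the differential parameters only.

Because energies add, the log-probability score decomposes exactly:
$L = L^b + L^d$ with $L^b = -H^b$ and $L^d = -H^d$ (all up to additive
constants, so only differences and rankings are meaningful). $L^d$, the
*differential-units score*, isolates what distinguishes selected
sequences from the background and is the package's discrimination score.
When positive- and negative-selected models share one background, the
difference $L^d - L^{d,neg}$ equals $L - L^{neg}$ exactly
(`differenceScore` enforces the shared background).

### Hidden-unit potentials

Three families are implemented with closed-form cumulants, conditional
means and parameter gradients (`hiddenCGF`, `hiddenMean`): quadratic
(gaussian), binary (bernoulli) and the double rectified linear unit
(dReLU), whose independent curvatures $\gamma_\pm$ and tilts
$\theta_\pm$ on the two half-lines can express sparse, asymmetric
activations. dReLU is the training default, in line with the RBM lineage
this architecture belongs to; the gaussian family is used for planted
models in the synthetic module because it keeps them analytically
convenient. All closed forms are verified against numerical quadrature of
the defining integrals at tolerance $10^{-8}$ in the test suite.

### Training procedure and numerics

The likelihood gradient is data expectation minus model expectation of the
sufficient statistics. The model expectation uses persistent contrastive
divergence: persistent parallel Gibbs chains (block updates of all hidden
units, then all sites), 10 sweeps per parameter update, with
Rao-Blackwellized hidden means. For fields-only models ($M = 0$ on both
parts) the model expectation is instead computed exactly from the
independent-site closed form — same estimator, no Monte-Carlo noise.
Updates use ADAM (default rate $5\times10^{-3}$) with a geometric decay to
one tenth of the rate by the last epoch, so the optimizer settles near the
optimum instead of hovering at the minibatch noise floor; the tests check
convergence to the closed-form maximum-likelihood solution where one
exists. dReLU curvatures are clipped at $0.05$ to keep the cumulant
finite. One master seed drives initialization, minibatching and chains;
training is bit-reproducible.

The weight penalty is the squared-L1 form
$\frac{\lambda_{2,1}}{2q}\sum_\mu\big(\sum_{i,a}|w_{i\mu}(a)|\big)^2$
($q$ = residue cardinality), which presses whole hidden units toward
sparse, localized weights; the default $\lambda_{2,1} = 0.001$ and
$M_b = 10$ hidden units follow the peptide-model setting (the TCR
background uses $M_b = 100$). After training a zero-sum gauge over states
is applied at each site to fields and weights (weight shifts compensated
exactly by translating the potentials), making single-site parameters
comparable across positions without changing the distribution.

## Interpretation: single-site factors and contacts

The *single-site factor* of position $i$ in sequence $\sigma$ is

$$T_i(\sigma_i) = g_i(\sigma_i)
  + \sum_{\mu} w_{i\mu}(\sigma_i)\,\langle h_\mu \mid \sigma\rangle,$$

computed from differential parameters (`singleSiteFactors(..., "diff")`)
or background parameters (`"background"`). With differential parameters
it approximates, to first order in the weights, the log odds-ratio
between the full and background probabilities of residue $\sigma_i$
conditional on the rest of the sequence — the residue's predicted
contribution to selection. Ranking positions by $|T_i|$
(`rankPositions`, gaps excluded, ties to the smaller index) predicts
contact positions: differential factors flag peptide positions contacting
the TCR, background factors flag the HLA anchor positions.

Predictions are assessed against crystallographic contacts with the
positive predictive value $PPV_p$ = (true contacts among the top $p$
positions) / $\min(p, \#\text{contacts})$, which reaches 1 at $p$ equal
to the sequence length. Because structure availability is heavily skewed
toward a few epitopes, entries are reweighted: $n_\sigma$ counts entries
whose sequence is within one substitution, each entry contributes with
weight $1/n_\sigma$, and $R_{\text{eff}} = \sum_r 1/n_{\sigma_r}$ is the
effective entry count. The random-prediction baseline is computed
analytically from the hypergeometric expectation, and a one-sided
binomial tail tests whether top-rank successes exceed the mean
contact fraction $s$; the observed count is included in the tail
($P(X \ge k)$), and the trial count is the raw entry count $R$ rather
than $R_{\text{eff}}$ — a binomial needs integer trials; both counts are
reported.

Contacts come from PDB/mmCIF structures (`parseStructure`,
`computeContacts`): a position is a contact if any of its heavy atoms
(element not H/D; highest-occupancy conformer) lies within the cutoff of
any partner heavy atom, boundary-inclusive. Default cutoffs are 4.0 Å for
peptide–TCR and CDR3β–peptide contacts and the slightly stricter 3.5 Å
for peptide–HLA contacts; both are configurable upward for robustness
checks. Positions are 1-based ranks along the chain (CDR3β positions
along the C...F span), not author numbering.

## Mutation costs

For a point mutation $\sigma_i \to \sigma_i'$ the predicted cost is
$T_i(\sigma_i) - T_i(\sigma_i')$, evaluated with only site $i$ changed —
exactly antisymmetric under swapping wild type and mutant. Differential
factors are used for lethal-mutation analyses (loss of immunogenicity),
background factors for non-lethal ones (presentation effects). The
experimental counterpart is $\log(EC50^{MT}/EC50^{WT})$; natural log by
default, a documented and configurable choice since the base only
rescales and the Spearman analyses are base-invariant. Lethal mutations
(formally infinite $EC50^{MT}$) are kept out of correlations and summarized
by their sign statistics. The control distribution scores all
$9 \times 19 = 171$ substitutions on randomly drawn presented peptides
and compares observed costs by a one-sided Mann-Whitney U test.

## Discrimination benchmarks

`evaluateDiscrimination` repeats the experiment over random 80/20
train/test partitions (default 50 repeats; train size
$\lfloor 0.8 n \rfloor$, remainder to test), retrains the differential
part per repeat, and reports AUC (tie-aware Mann-Whitney form, exactly
the ROC area) and average precision (tie-grouped) with mean and standard
deviation. For receptor tasks test negatives are drawn per repeat from a
background pool with the positive test-set size, using an RNG stream
separate from the split stream so negative draws never perturb the
splits. `leaveOneOrganismOut` builds the organism-held-out folds
(organisms with at least 15 records in both classes). The background
model is trained once and held fixed across repeats.

## The synthetic study and what it shows

Real studies need IEDB, VDJdb and PDB downloads; the synthetic module
replays their logic end-to-end without any. `makeScenario` plants a
seeded background RBM plus a differential perturbation confined to
designated focus positions (default 4–8, the central peptide positions
typically contacted by the TCR) and scaled by a strength parameter;
strength 0 makes the selected distribution exactly the background.
`sampleScenario` draws background and selected datasets by Gibbs sampling
with burn-in, with the characteristic size asymmetry (defaults 4000
background, 1600 selected, matching the largest peptide study arm).
`makeContactFixtures` writes minimal PDB files — residues as Cα-like
pseudo-atoms 8 Å apart, partner atoms 3 Å from each contact position — so
the 4 Å contact extraction recovers the planted contacts exactly; sampled
gap states are replaced by residues, since structures contain real
residues only. `makeAssayTable` emulates the 171-mutant scanning design
with planted costs and optional noise.

On these scenarios the package reproduces the method's qualitative
claims, and the test suite asserts them: the planted differential fields
are recovered (Pearson $r \ge 0.9$ at 2000 selected sequences, strength
1); the mean AUC over 50 repeats orders as differential $\ge$ full $\ge$
background on planted tasks and sits in $[0.45, 0.55]$ at zero strength;
the contact pipeline reaches $PPV_1 = 1$ on unjittered fixtures, beats
the analytic random baseline, and rejects the binomial null at
$p < 0.01$. What synthetic data cannot show: real immunogenicity signal
strength, alignment noise from real length variation, phylogenetic and
database-curation biases, or the adequacy of the contact cutoffs to real
van der Waals geometry — conclusions about real repertoires still require
the real datasets.

## Numerical and design choices

- **Alignment rule.** Profiles of length 9 (peptides) or 20 (CDR3β) are
  learnt from the background set only (exact-length sequences seed the
  profile; one refinement round follows). 8-mers receive one gap at the
  placement maximizing profile likelihood (all placements enumerated,
  ties leftmost); 10/11-mers lose the 1–2 internal positions whose
  removal maximizes profile likelihood. CDR3β uses a deterministic
  anchored rule — first $\lceil L/2\rceil$ residues left, the rest right,
  gaps in the middle — reflecting the conserved loop ends; loops longer
  than 20 lose their most central residues. This anchored rule is a
  documented substitute for a full HMM-profile aligner, which the package
  deliberately does not re-implement.
- **Similarity reweighting** uses identity over residue sites only (gene
  sites excluded) with threshold 0.8, and counts gap–gap positions as
  matches; a sequence's weight is 1 over the number of sequences
  (itself included) above the threshold.
- **Degenerate inputs.** Empty sequence lists, empty contact sets,
  constant vectors in correlations, and cardinality mismatches are
  errors; a model without differential parameters scores $L^d = 0$ and
  yields zero factors (not an error); mutant-equals-wild-type costs are 0
  with a warning.
- **Ties.** Position rankings break ties by ascending index; AUC counts
  ties as 1/2; average precision groups tied scores; Spearman uses
  average ranks, exact permutation p-values up to $n = 9$ and the
  t-approximation beyond.
- **Problem sizes.** The shipped tests and the acceptance script run the
  synthetic study at 9 sites × 21 states with up to 4000 background /
  2000 selected sequences, 50 split repeats, and 12 structure fixtures —
  sizes chosen so the full study replays in minutes on one core while
  keeping every statistical check comfortably powered.

## Known limitations

Training is plain R (vectorized over sparse one-hot encodings); it is
comfortable at repertoire-study sizes but not meant for millions of
sequences. Absolute log-likelihoods are not computed (no annealed
importance sampling) — scores are comparative only. The anchored CDR3β
alignment is cruder than a learned profile HMM for unusual loop shapes.
Joint training of background and differential parts, needed when baseline
and selection features are entangled, is out of scope by design.
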