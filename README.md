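# diffrbm

Transfer-learning Restricted Boltzmann Machines for immune-repertoire
sequence analysis.

## What it is for

In T-cell immunology the sequences of interest are usually a small
*selected* subset of a much larger, strongly structured *background*:
immunogenic peptides within all HLA-presented peptides, or
epitope-specific CDR3β chains within the bulk recombination repertoire.
A model trained on the small selected set alone mixes the selection
signal with the background constraints (HLA anchors, V(D)J statistics).

`diffrbm` separates the two by construction. A background RBM with
energy

&nbsp;&nbsp;&nbsp;&nbsp;*H<sup>b</sup>(σ) = −( Σ<sub>i</sub> g<sup>b</sup><sub>i</sub>(σ<sub>i</sub>) + Σ<sub>μ</sub> Γ<sup>b</sup><sub>μ</sub>(I<sup>b</sup><sub>μ</sub>(σ)) ),&nbsp;&nbsp; I<sup>b</sup><sub>μ</sub>(σ) = Σ<sub>i</sub> w<sup>b</sup><sub>iμ</sub>(σ<sub>i</sub>)*

is trained on the background data and frozen; differential fields,
weights and hidden units (*H<sup>d</sup>*, same form) are then trained on
the selected data under the combined model *H = H<sup>b</sup> +
H<sup>d</sup>*. The package provides:

- the three scores *L = L<sup>b</sup> + L<sup>d</sup>* (exact
  decomposition), with the differential-units score *L<sup>d</sup>* as
  the selection-specific discriminator, plus the positive-minus-negative
  difference score;
- single-site factors
  *T<sub>i</sub>(σ<sub>i</sub>) = g<sub>i</sub>(σ<sub>i</sub>) +
  Σ<sub>μ</sub> w<sub>iμ</sub>(σ<sub>i</sub>)⟨h<sub>μ</sub>|σ⟩* —
  approximate conditional log odds-ratios used to rank antigen–TCR
  contact positions and to predict mutation costs
  *T<sub>i</sub>(σ<sub>i</sub>) − T<sub>i</sub>(σ′<sub>i</sub>)*;
- contact extraction from PDB/mmCIF structures (heavy atoms, 4 Å
  peptide–TCR / 3.5 Å peptide–HLA cutoffs), redundancy-aware PPV curves
  with 1/n<sub>σ</sub> reweighting and effective counts
  R<sub>eff</sub> = Σ 1/n<sub>σ</sub>, analytic random baselines and a
  binomial significance test;
- dataset curation (IEDB-style immunogenicity filtering, VDJdb-style
  tables), fixed-length profile alignment (9 for peptides, 20 for CDR3β,
  optional 48/13-state V/J sites), 80%-similarity reweighting;
- a repeated-split discrimination harness (AUC / average precision over
  50 partitions, organism-held-out folds);
- a synthetic-data module (planted models, toy structures, mutational
  assay tables) so the whole pipeline runs and is tested without any
  downloads.

## Worked example

A planted study: background peptides vs peptides selected at the central
positions 4–8, the positions a TCR typically contacts.

```r
library(diffrbm)

scenario <- makeScenario(nSites = 9, cardinality = 21, Mb = 0, Md = 0,
                         strength = 2, focusPositions = 4:8, seed = 42)
data <- sampleScenario(scenario, nBackground = 2000, nSelected = 500,
                       seed = 43, burnin = 30)

bg    <- trainBackground(data$background,
                         config = trainingConfig(nHidden = 0, epochs = 150, seed = 44))
model <- trainDifferential(bg, data$selected,
                           trainingConfig(nHidden = 0, epochs = 150, seed = 45))
model
#> DiffRBM: 9 sites, background M = 0, differential M = 0

fresh  <- sampleScenario(scenario, nBackground = 300, nSelected = 300,
                         seed = 46, burnin = 30)
scores <- scoreSequences(model, fresh$selected)
round(head(scores, 3), 3)
#>    full background  diff
#> 1 9.533      3.365 6.168
#> 2 4.757      1.366 3.390
#> 3 6.886      2.310 4.576
aucScore(scores$diff, scoreSequences(model, fresh$background)$diff)
#> 0.991
```

Scores are log-probabilities up to constants — only differences and
rankings mean anything. `full` minus `background` equals `diff` exactly;
the differential score alone separates selected from background
sequences (AUC 0.99 here because the planted signal is strong).

Contact prediction on synthetic structures whose true contacts are the
planted positions:

```r
fx  <- makeContactFixtures(scenario, 12, seed = 47)
ent <- data.frame(sequence = fx$sequence); ent$contacts <- fx$contacts
ent <- contactMultiplicities(deduplicateEntries(ent))
st  <- encodeSequences(ent$sequence)
Tf  <- singleSiteFactors(model, st, "diff")
curves <- t(sapply(seq_len(nrow(ent)), function(k)
  ppvCurve(rankPositions(Tf[k, ], st[k, ]), ent$contacts[[k]], 9)))
averagePPV(curves, ent$n_sigma)$ppv[1:4]
#> 1.000 1.000 1.000 0.979
randomPPVBaseline(sapply(ent$contacts, length), 9, ent$n_sigma)[1:4]
#> 0.556 0.556 0.556 0.556
```

The factor-ranked positions recover the planted contacts (PPV 1 at the
top ranks) far above the 5/9 random expectation.

The methods vignette (`vignettes/differential-rbm-methods.Rmd`) explains
the model, the training numerics, the alignment and reweighting rules,
and what the synthetic study does and does not demonstrate.

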