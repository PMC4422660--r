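# mldppi

Sequence-based prediction of protein–protein interactions (PPIs) with
multi-scale local descriptors (MLD) and a random forest.

Experimental PPI detection (yeast two-hybrid, TAP-MS) is expensive and
covers a small, noisy fraction of real interactomes, so classifiers that
predict interaction from primary sequence alone are a standard complement.
`mldppi` is for computational biologists who want a complete, reproducible
sequence-only PPI pipeline: FASTA + labelled pair list in, cross-validated
performance report out, with a seedable synthetic benchmark so the whole
pipeline can be exercised and tested without any external dataset.

## The method

**Featurization (MLD).** Each protein sequence is first reduced to a
7-letter alphabet that groups the 20 amino acids by side-chain dipole and
volume ({A,G,V}=1, {C}=2, {M,S,T,Y}=3, {F,I,L,P}=4, {H,N,Q,W}=5, {K,R}=6,
{D,E}=7). The sequence is cut into S equal-length segments (default S = 4)
and every *contiguous* run of segments — written as a binary mask, e.g.
`0011` = the final half — defines a local region; excluding the full-length
mask this gives 9 overlapping regions at S = 4, capturing local structure at
multiple scales. On each region three classical CTD statistics are computed
over the group codes:

- **C**omposition (7 values): `C_g = 100 · n_g / L`, the percentage of each
  group;
- **T**ransition (21 values): for each unordered group pair (g, h), the
  percentage of adjacent positions alternating between g and h, out of
  L − 1 adjacencies;
- **D**istribution (35 values): for each group, the normalized sequence
  positions of its first, 25%, 50%, 75% and 100% occurrences.

That is 63 descriptors per region, 9 × 63 = **567 per protein**, and a pair
(A, B) is the concatenation of both vectors: **1134 features**.

**Classification.** A random forest of N unpruned CART trees (default
N = 60), each grown on a bootstrap resample with M features considered per
Gini split (default M = 10), majority vote, out-of-bag accuracy reported.
Evaluation uses stratified k-fold cross-validation with the seven standard
confusion-matrix measures: ACC, SN, Spec, PPV, NPV, F-score and MCC.

## Worked example

The encoder's arithmetic on a 22-residue demonstration sequence, printed by
`worked_example()` (or `exec/mld worked-example` from a shell):

```
sequence     GGYCCCYYGYYYGCCGGYYGCG
group codes  1132223313331221133121

composition (%):
   C1    C2    C3    C4    C5    C6    C7
36.36 27.27 36.36  0.00  0.00  0.00  0.00

transition (%):
 T1.2  T1.3  T2.3
19.05 28.57  9.52

distribution (%), milestones first/25/50/75/100:
  group 1: 4.55  9.09  59.09  77.27  100.00
  group 2: 18.18  18.18  27.27  63.64  95.45
  group 3: 13.64  31.82  45.45  54.55  86.36

all values match the published reference: TRUE
```

Reading: the sequence contains 8 group-1, 6 group-2 and 8 group-3 residues,
so e.g. `C1 = 8/22 × 100 = 36.36%`; there are 4 adjacencies alternating
between groups 1 and 2 among the 21 adjacent pairs (`T1.2 = 19.05%`); the
4th of the 8 group-1 residues (the 50% milestone) sits at position 13, so
`D1.50 = 13/22 × 100 = 59.09%`.

A full pipeline run on synthetic data:

```r
library(mldppi)
sim   <- simulate_ppi_data(n_positive = 200, n_negative = 200, seed = 1)
feats <- pair_features(sim$pairs, mld_featurize(sim$proteins))
cv    <- mld_cross_validate(feats, k = 5, n_trees = 60, mtry = 10, seed = 1)
cv
#> <mld_cv> 5-fold CV, forest (N = 60, M = 10), 400 pairs
#>   acc      95.00% +/- 1.25
#>   sn       95.50% +/- 3.26
#>   spec     94.50% +/- 4.81
#>   ppv      94.81% +/- 4.26
#>   npv      95.64% +/- 3.08
#>   f_score  95.04% +/- 1.14
#>   mcc      90.22% +/- 2.41
autoplot(cv)
```

The 400 pairs carry a planted motif signal (see
`vignette("mldppi-methods")`); the forest recovers it at 95% accuracy, while
the same data with shuffled labels scores ~50% — the pipeline does not
manufacture signal.

## Command line

```
exec/mld simulate  --out data --n-positive 200 --n-negative 200 --seed 1
exec/mld featurize --fasta data/proteins.fasta --out features.tsv
exec/mld cv        --fasta data/proteins.fasta --pairs data/pairs.tsv --out report
exec/mld sweep     --fasta data/proteins.fasta --pairs data/pairs.tsv \
                   --out sweep --m-values 5,10,15,20,25,30
exec/mld worked-example
```

Every run writes a provenance JSON (configuration, hash, layout version,
seeds) next to its outputs.

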