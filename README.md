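# isfcdecode

Decoding task states from large-scale functional connectivity with
inter-subject functional correlation (ISFC).

## The problem

When two groups of brain regions cooperate during a task, their BOLD time
series correlate — but within a single subject that correlation is dominated
by intrinsic fluctuations and physiological artefacts that have nothing to do
with the task. Ordinary functional connectivity (FC), the Pearson correlation
between region *i* and region *j* of the *same* subject, therefore looks
nearly identical across task states, and classifiers built on FC patterns
transfer poorly across subjects.

ISFC sidesteps this by correlating region *i* of one subject with region *j*
averaged over the *other* subjects performing the same time-locked task.
Intrinsic fluctuations are not shared across brains, so they cancel in the
cross-subject average, and what survives is the stimulus- and task-locked
covariance. For subject *k* with normalised node-by-time matrix `X_k`
(P nodes, N time points, each row zero-mean unit-variance):

    C_k = (1/N) * X_k %*% t( mean of X_q over q != k )

Each element (i, j) is the correlation between node *i* of subject *k* and
the mean series of node *j* of everyone else. Coefficients are Fisher
r-to-z transformed, symmetrised as `(C_k + t(C_k))/2`, and averaged across
subjects into a group matrix. Task decoding is correlation template
matching: per leave-one-subject-out fold, one group ISFC template per task
is built from the training subjects, and each held-out run is assigned the
task whose template its own ISFC pattern matches best. The package also
implements the surrounding analyses: group-split similarity, edge-wise
discriminative mapping with max-statistic permutation correction,
subnetwork-restricted classification, scan-length curves, and the
signal-level cleaning chain (detrending, nuisance + derivative regression,
DCT high-pass, canonical-HRF task-evoked removal, framewise displacement).

Because the method is defined by multi-subject structure, the package ships
a synthetic generator (`generate_dataset()`) that emulates a 12-subject,
two-task, 5-runs-per-task study with known ground truth: shared
stimulus-locked signals, subject-idiosyncratic intrinsic networks, and
unstructured noise.

## Worked example

```r
library(isfcdecode)

ds <- generate_dataset(generator_config(seed = 1))
ds
#> Study dataset: 12 subjects, 120 runs (beh: 60, tax: 60), 60 nodes x 196 time points

fit <- losocv(ds, mode = "isfc")
fit
#> LOSOCV template matching (isfc): accuracy 95.00% over 120 runs (12 folds)
losocv(ds, mode = "fc")
#> LOSOCV template matching (fc): accuracy 58.33% over 120 runs (12 folds)
```

ISFC recovers the task of 95% of held-out runs while within-subject FC —
same template-matching procedure, same data — stays near chance, because
each subject's FC is dominated by their own intrinsic network structure.
The similarity analysis shows the same dissociation at the group level:

```r
sim <- similarity_analysis(ds)
sim
#> Similarity analysis: 462 group splits
#>   mean within-task:  0.2520
#>   mean between-task: 0.0205
similarity_permutation_test(sim$within, sim$between, seed = 2)
#> Permutation test of mean(within) - mean(between)
#>   observed 0.2315, p = 0.001 (1000 permutations)
```

Group ISFC patterns computed from disjoint halves of the subjects agree far
more when the halves perform the same task (0.25) than different tasks
(0.02); over 1000 permutations no null resplit comes close, so the p-value
sits at its floor of 1/1000. Edge-wise mapping then localises the effect:

```r
phi <- losocv(ds, mode = "isfc", discriminative = TRUE)$phi
nullmax <- label_permutation_test(ds,
  function(d, lab) max(discriminative_map(d, labels = lab)$phi),
  n_perm = 100, seed = 3)
edges <- select_edges(phi, nullmax$null$samples, alpha = 0.05)
length(edges)   # edges surviving max-statistic FWE correction
```

Selected edges can be exported for surface rendering with
`export_brainnet()`.

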