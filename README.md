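# periofuse

Multimodal fusion of periocular eye-tracking signals for demographic
classification.

## What it is for

Signals measured around the eye by a remote eye tracker carry weak
demographic information: resting pupil diameter declines with age,
spontaneous blink rate differs slightly between women and men (about 15.2
vs 13.3 blinks per minute), and fixation behaviour varies across groups.
Individually these *soft biometrics* classify poorly; combined, they can
do markedly better. `periofuse` is a tested, fully seeded R pipeline that
takes raw Tobii-style gaze logs (timestamp, per-eye validity code 0–4,
per-eye pupil diameter, gaze position) to binary gender (male/female) and
age-group (under 30 / over 30) classification, for researchers studying
score-level fusion, eye-movement biometrics, or pupillometry-based
profiling.

The pipeline:

1. **Preprocessing** — keep only records with validity pair (0,0) or
   (4,4); segment blinks from the "(4,4) run returning to (0,0)"
   signature, counting single-sample runs as *fast* blinks with undefined
   duration; detect fixations with the dispersion-threshold (I-DT)
   algorithm.
2. **Features** — per (subject, stimulus): 7 pupil-diameter descriptors
   (mean, median, population sd, min, max, quartiles), 6 blink descriptors
   (counts and duration statistics), 5 fixation descriptors; seeded
   down-sampling of the majority class to exact parity.
3. **Feature-level fusion** — concatenation of modality blocks with
   max-absolute scaling fitted on the training rows (zeros stay zero).
4. **Classification** — an 80:20 stratified split, then an in-package
   classifier zoo (decision tree, random forest, bagging, AdaBoost,
   gradient boosting, kNN, linear SVM, SGD logistic regression) tuned by
   exhaustive grid search crossed with k-fold cross-validation, k ∈ [2,10].
5. **Score-level fusion** — for member confidences `s_i` and weights
   `w_i ∈ {0.1, …, 1.0}` searched by brute force over all member subsets:
   weighted sum `S = Σ w_i s_i`, weighted product `S = Π s_i^{w_i}`, the
   pairwise Bayes rule `S = t_a t_b / ((1−t_a)(1−t_b) + t_a t_b)`, and
   classifier-based fusion of the two best members' concatenated
   confidences on a 70:30 re-split.

The reference corpus for this kind of study is not publicly available, so
the package includes a first-class synthetic cohort generator emulating
its structure (112 subjects, 73 M / 39 F, 18 stimuli, 50 Hz, validity-code
blink signatures, age-dependent pupil baseline, gender-dependent blink
rate) with every effect size configurable. See the methods vignette
(`vignettes/periocular-fusion.Rmd`) for the model, parameter meanings and
design decisions.

## Worked example

```r
library(periofuse)

cfg <- experiment_config(
  task = "age", with_concatenation = TRUE,
  cohort = cohort_config(n_subjects = 24, n_stimuli = 6, session_duration_s = 10,
                         pupil_age_slope = 0.4, pupil_subject_sd = 0.6, seed = 42),
  families = c("decision_tree", "random_forest", "knn", "svm"),
  k_range = 2:3,
  grids = list(decision_tree = list(max_depth = 4L), random_forest = list(n_trees = 25L),
               knn = list(k_neighbors = 5L), svm = list(lambda = 0.01)),
  select_threshold = 0.5, sizes = 2L, seed = 42)
report <- run_experiment(cfg)
```

Printed summary of that run (exact output, fixed seed):

```
pupil     best: random_forest k=3  accuracy 0.9231
blink     best: random_forest k=2  accuracy 0.6154
fixation  best: svm           k=2  accuracy 0.6154
candidates: random_forest, decision_tree, knn, svm
sum      size 2: random_forest+decision_tree  weights 0.4/0.1  accuracy 0.9231
product  size 2: random_forest+decision_tree  weights 0.4/0.1  accuracy 0.9231
bayes    size 2: random_forest+decision_tree  weights 0.3  accuracy 0.9615
best accuracy overall: 1.0000
```

Reading it: with a planted strong pupil-age effect, the pupil modality
alone classifies age at 0.92 on the held-out 20% while blink and fixation
sit near chance on this small cohort (0.62); fusing the two best concat
classifiers' scores with the Bayes rule lifts accuracy to 0.96, and the
best entry in the full report (here a classifier-based fusion) reaches
1.00 on the 26-sample test set. Accuracies on such small held-out sets are
coarse — the test suite runs the scaled-up version.

The same pipeline is scriptable from the command line (see `exec/periofuse`):

```sh
periofuse simulate   --config cfg.yaml --out-dir data --seed 1
periofuse preprocess --in data --out events
periofuse features   --in data --metadata data/subjects.csv --task age --out features.csv --seed 1
periofuse train      --features features.csv --task age --config cfg.yaml --seed 1 --out scores.json
periofuse fuse       --scores scores.json --rule all --sizes 2,3 --out fusion.json
periofuse run        --config cfg.yaml --seed 1 --out results/
```

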