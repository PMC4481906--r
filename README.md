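# piradl

Recognition of activities of daily living (ADL) in single-resident smart
homes from ambient sensors: passive infrared (PIR) motion, temperature,
luminescence, bathroom humidity and fridge-door acceleration, sampled at
0.2 Hz by wireless boxes placed one or two per room. The package is aimed
at researchers in ambient assisted living who need a complete, testable
pipeline — from raw event logs to per-activity performance tables — without
access to a deployed sensor network: a synthetic-home simulator with known
ground truth stands in for real deployments.

## What it does

The stream is resampled onto a 5-s grid (one column per room × channel,
plus weekday) and segmented into occupancy episodes in one of three ways:

- **Token segmentation** — the joint PIR state of all rooms is encoded as
  an integer token (room *r* of *R* contributes 2^(R−r)); a change point is
  set whenever the token switches to a different *active* constellation,
  transitions into the all-quiet state being neglected. Periods between
  change points are compressed to single rows (mean, population variance,
  min, max, first/last per feature) with the previous/next tokens as
  context.
- **Room-based segmentation** — per-room PIR is filtered with short (15 s)
  and long (300 s) centred moving averages, weighted per room (bathroom
  short-term movement up-weighted), thresholded into activity/no-activity
  periods with raw-PIR edge refinement, split at changes of the dominant
  room, and post-filtered by a strict 20-s short-activity exclusion. Each
  segment carries its estimated room and activity degree.
- **Fixed 60-s slots** — the conventional baseline.

Episodes are classified into eight ADLs (Cooking, Eating, Get ready for
bed, Grooming, Seated activity, Sleeping, Toileting, Watching TV) by a
random forest, SVM or Gaussian naive Bayes; absence ("AWAY") is detected
from the PIR stream by rule, not learned; a parallel, independent random
forest flags visitor episodes. Evaluation is one-vs-rest over 5-s time
slices under leave-one-home-out cross-validation, reporting sensitivity,
specificity, precision and F-measure per activity with pooled confusion
counts and an unweighted macro mean.

## Worked example

Simulate a ten-home study (three days per home, visitor episodes included),
and cross-validate a random forest on room-based segments:

```r
library(piradl)

homes <- lapply(1:10, function(h)
  simulate_home(n_days = 3, seed = derive_seed(1, 1000 + h),
                home_id = sprintf("home%02d", h), visitor_rate = 1))
grids <- lapply(homes, preprocess_home)
res <- leave_one_home_out(grids, classifier_spec("rf", seed = 1), "room",
                          visitor = TRUE,
                          visitor_rooms = c("BATHROOM", "TV_ROOM", "LIVING"))
format_report(res$report)[, -1]
```

```
           activity sensitivity specificity precision f_measure
1           Cooking       99.30       99.90     98.00     98.64
2            Eating       72.89       99.70     92.55     81.55
3 Get ready for bed       70.01       99.94     78.13     73.85
4          Grooming       99.24       99.73     87.67     93.10
5   Seated activity       99.07       97.70     93.41     96.16
6          Sleeping       99.65       99.95     99.91     99.78
7         Toileting       85.08       98.58     58.57     69.38
8       Watching TV       99.85       99.33     91.84     95.68
9              Mean       90.64       99.35     87.51     88.52
```

Values are percentages over ~518,000 evaluated 5-s slices. The pattern is
informative: activities with a room of their own (Sleeping, Watching TV,
Cooking) are near-perfect; Eating suffers because an episode of eating at
the dining table followed by sitting on the sofa happens in one room and
cannot be split by room-level segmentation; Toileting is short and pays a
precision penalty at episode boundaries. The visitor classifier
(`res$visitor$metrics`) lands in the conservative regime — specificity
0.991, sensitivity 0.30 — expected when a visitor is only detectable while
the two occupants occupy different rooms.

## Command line

```sh
exec/pir-adl simulate   --homes 10 --days 3 --seed 1 --out data/
exec/pir-adl preprocess --in data/home01 --out grid01.csv
exec/pir-adl segment    --in data/home01 --method room --out segs01.csv
exec/pir-adl evaluate   --in data/ --algo rf --segmentation room \
                        --out report.csv
```

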