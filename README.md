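# parentese

Computational analysis of early caregiver–infant interaction, built around
three linked questions from developmental research on autism: *how* parents
speak to their infants (parentese — infant-directed emotional prosody with
higher pitch, slower tempo and exaggerated intonation contours — versus other
speech), *what* infants do in the seconds that follow, and *how* the
probability of an infant response depends on time, group, speaker and speech
type.

The package is aimed at researchers in social signal processing and
computational behavioural phenotyping who work with coded observational data
(time-stamped behaviour logs from video annotation) and the accompanying
audio. Because such corpora are rarely shareable, the package ships a
synthetic-data generator that emulates both the prosodic contrast and the
statistical structure of a two-group home-movie study, so every stage of the
pipeline is testable end to end with known ground truth.

## What is inside

**Acoustic parentese detector.** Utterances are represented by two feature
streams: frame-level Mel-frequency cepstral coefficients (25 ms frames,
10 ms hop, 13 coefficients + log energy — the *segmental* stream) and an
utterance-level vector of prosodic statistics (F0 mean/SD/min/max/range/
slope from an autocorrelation pitch tracker, energy statistics, duration,
voiced fraction — the *supra-segmental* stream). Each stream gets one
diagonal-covariance Gaussian mixture model per class (M = 12 segmental,
M = 15 supra-segmental), fitted by seeded EM. Scores are fused at the
posterior level,

P(c | x) = lambda * P_seg(c | x) + (1 - lambda) * P_supra(c | x), lambda = 0.4,

and evaluation reports accuracy, PPV and NPV with two-sided exact
(Clopper–Pearson) 95% binomial intervals.

**Interaction database.** Behaviour logs use the ICBS coding frame
(caregiver solicitation items, infant engagement items; point events plus
regulation-up/down states), grouped into 5 caregiver and 6 infant
meta-behaviours. A response bi-gram is a caregiver event followed by an
infant event within a 3-second window (lag in [0, 3] s, same-second
responses included; all qualifying pairs are kept). Bi-grams aggregate into
per-semester count tables with "toward object" / "toward people" margins and
into per-vocalisation binary response records.

**Response models.** Binomial GLMMs (logit link, child-level random
intercept, fitted with lme4) of response probability on semester
(successive-difference contrasts: S2 vs S1, S3 vs S2), group (AD vs TD),
speaker (mother vs father) and speech type (parentese vs other speech), with
post-hoc stratified suites and a parentese-use trend model. Fits have
`tidy()`/`glance()` methods and coefficient plots.

## Worked example

```r
library(parentese)

# 1. a labelled audio corpus and the two-stream detector
train <- synth_corpus(100, seed = 11)
test  <- synth_corpus(50,  seed = 99)
det   <- train_parentese_detector(train, fusion_config(0.4, 12, 15), seed = 1)
pred  <- predict(det, test)
evaluate_classifier(ifelse(test$style == "parentese", "parentese", "other_speech"),
                    pred$.pred_class)
#> <eval_report> n=100  (TP=50 FN=0 FP=0 TN=50; positive=parentese)
#>   accuracy  100.00%  (95% CI 96.38-100.00%)
#>   ppv       100.00%  (95% CI 92.89-100.00%)
#>   npv       100.00%  (95% CI 92.89-100.00%)

# 2. a synthetic two-group interaction study, bi-grams and proportions
study <- synth_interaction_study(study_design(random_seed = 5))
bg    <- extract_bigrams(study$events)            # 3-second response window
count_responses(bg, study$events)                 # Table-style counts + margins
parentese_proportions(study$events)               # by group/semester/speaker

# 3. response model: does parentese raise the response probability?
rec <- build_response_dataset(study$events, bg)
fit <- fit_response_glmm(rec, response = "any")
tidy(fit)
#> # A tibble: 6 x 5
#>   term                      estimate std_error      z       p_value
#>   <chr>                        <dbl>     <dbl>  <dbl>         <dbl>
#> 1 (Intercept)                 0.973     0.162   6.01  0.00000000182
#> 2 S2 vs S1                    0.229     0.0762  3.00  0.00270
#> 3 S3 vs S2                    0.235     0.0781  3.00  0.00267
#> 4 AD vs TD                   -0.598     0.218  -2.74  0.00612
#> 5 mother vs father           -0.0572    0.0703 -0.813 0.416
#> 6 parentese vs other_speech   0.124     0.0684  1.81  0.0708
```

Here the AD-group deficit (`AD vs TD` negative) and the semester rise are
generated by the design's reference response rates; the parentese effect is
attenuated toward zero because, at the default 1-second vocalisation
spacing, neighbouring response windows overlap and responses cannot be
attributed uniquely — see the methods vignette for why estimator-calibration
simulations use non-overlapping windows.

On clean synthetic corpora the detector separates the two styles essentially
perfectly (the prosodic contrast is generated with a large margin); the
interesting guarantees are the exact arithmetic ones — the fusion rule, the
window semantics, the count-table margins and the Clopper–Pearson intervals —
and the statistical ones — parameter recovery of the mixed model on studies
with known effects.

## Package layout

- `R/synth_audio.R`, `R/synth_study.R` — synthetic utterances, corpora and
  interaction studies with ground truth
- `R/acoustics.R` — MFCC and prosodic feature extraction, F0 tracking
- `R/gmm.R`, `R/classifier.R` — EM for diagonal GMMs, two-stream detector,
  fusion, evaluation with exact intervals
- `R/event_log.R` — event-log dialect and I/O, semester binning,
  meta-behaviour map, Cohen's kappa
- `R/interaction.R` — bi-gram extraction, count tables, proportions
- `R/glmm.R` — response records, binomial GLMMs, post-hoc suites, trend model
- `vignettes/parentese-methods.Rmd` — models, assumptions, parameter choices
  and limitations
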