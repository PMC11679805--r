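# distillecg

Knowledge distillation for single-lead ECG arrhythmia classification in R.

Wearable ECG monitors record one lead (lead II) and run on microcontrollers
with kilobytes of memory, while the accurate rhythm classifiers are deep
networks trained on 12-lead recordings. `distillecg` implements the
teacher-student remedy end to end:

1. a **teacher** — a 1-D convolutional recurrent network (stem convolution,
   four residual squeeze-and-excitation blocks, two LSTM layers, softmax
   head) — is trained on 12-lead records with cross-entropy;
2. a **student** — two convolutions, one fully connected layer, softmax —
   is trained on the paired lead II view against the combined objective

   L_total = α · L_CE + (1 − α) · KL(q^T ‖ p^T),

   where q^T and p^T are the teacher's and student's temperature-softened
   class distributions, q_i = exp(z_i/T) / Σ_j exp(z_j/T).

The task is four-class rhythm classification — AFIB (atrial
fibrillation/flutter), GSVT (merged supraventricular tachycardias), SB
(sinus bradycardia), SR (sinus rhythm) — over 10 s, 500 Hz Chapman-style
CSV records, resampled to 250 Hz and z-scored per lead. The package also
provides the data plumbing (usability filter, 11→4 label merge, stratified
70/20/10 splits), a synthetic 12-lead ECG generator so everything runs
without downloads, one-vs-rest metrics with the macro "Overall" row used in
the published tables, and parameter/MAC complexity profiling. The neural
network layers and their backward passes are implemented natively on R's
BLAS; correctness is pinned by finite-difference gradient checks in the
test suite.

## Worked example

The headline experiment — simulate 250 records per class, train the
teacher on 12 leads, then train five paired students with and without
distillation (T = 4, α = 0.5 vs α = 1) and compare median test accuracy:

```r
library(distillecg)
ex <- run_kd_experiment(n_per_class = 250, seeds = 5, epochs = 12, seed = 1)
ex
#> <kd_experiment>
#>   teacher test accuracy: 100.00%
#>   student median test accuracy: KD 94.00% vs no-KD 88.00% (delta +6.00)
ex$runs
#> # A tibble: 10 × 4
#>     seed arm   test_accuracy best_val_acc
#>    <int> <chr>         <dbl>        <dbl>
#>  1     1 kd             94           92.5
#>  2     1 no_kd          95           93.5
#>  3     2 kd             90           85.5
#>  4     2 no_kd          85           80.5
#>  5     3 kd             88           88.5
#>  6     3 no_kd          84           85.5
#>  7     4 kd             94           90
#>  8     4 no_kd          94           90
#>  9     5 kd             94           92.5
#> 10     5 no_kd          88           89
```

The teacher saturates the synthetic task (its classes are separable by
rate and RR regularity by construction); the distilled student beats or
ties the plain student in four of five seeds, a +6-point median gain from
the soft labels alone — the desk-scale analogue of the published
improvement. Runtime is about 8 minutes on one CPU.

Individual stages compose with the pipe:

```r
rec <- simulate_ecg("AFIB", seed = 7)        # 12 x 5000 @ 500 Hz
rec |> preprocess_records() |> extract_lead_ii()
#> <ecg_record> SYN_AFIB_7: 1 lead(s) x 2500 samples @ 250 Hz, rhythm AFIB (class AFIB)

soften(c(2, 0, 0, 0), temperature = 2)
#> [1] 0.4753669 0.1748777 0.1748777 0.1748777

teacher <- build_teacher(seed = 1)           # full-width default spec
student <- build_student(seed = 1)
compression_ratio(teacher, student)
#> [1] 124.0273
count_macs(student, 2500)
#> [1] 87416
```

Fitted models have `tidy()` (per-epoch training log), `glance()` (one-row
summary) and `autoplot()` (training curves) methods; `metrics_report()`
lays out sensitivity / precision / specificity / F1 / accuracy per class
plus the macro Overall row, and `autoplot()` on a confusion matrix draws
the usual tile plot.

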