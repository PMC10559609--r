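# laryngoscreen

Segmentation-based screening of laryngopharyngeal cancer (LPC) in
endoscopy images and videos.

Laryngopharyngeal cancer — carcinoma of the larynx and hypopharynx — is
diagnosed by flexible laryngoscopy under white-light (WLI) and narrow-band
(NBI) imaging, an examination whose accuracy depends heavily on the
endoscopist's experience. `laryngoscreen` implements, as reusable and tested
R components, the full computer-aided pipeline such screening systems use:

1. **Semantic segmentation** — a U-Net (4 encoder blocks of two 3×3
   conv + ReLU with 2×2 stride-2 max-pooling, 4 decoder blocks with skip
   concatenation, 1×1 output convolution) produces a per-pixel cancer
   probability map. The network, backprop and Adam optimizer are implemented
   natively (im2col + BLAS, C++ kernels via Rcpp), fully seeded.
2. **Frame decision** — the binarized mask is cleaned by morphological
   closing then opening; the frame is called cancer iff the largest
   connected component's area **strictly exceeds** an area threshold
   (default 32×32 = 1024 px at the 512×512 working resolution, selected
   from the grid 8², 16², …, 256²).
3. **Video diagnosis** — a video is called cancer iff the longest run of
   **consecutive** cancer frames exceeds a duration threshold (default 2 s,
   selected from 0.5–3 s), with duration = run length / fps.
4. **Evaluation statistics** — accuracy, sensitivity, specificity, PPV, NPV
   with Clopper–Pearson or Wald 95 % intervals, ROC/AUC (pairwise
   concordance = trapezoidal), segmentation IoU, Cohen's kappa, and the
   two-sided McNemar test (exact and continuity-corrected χ²).

Because clinical laryngoscopy datasets are private, the package ships a
seed-controlled **synthetic endoscopy generator** (modality-dependent
palettes, irregular star-convex lesions with exact labelme polygon
annotations, sub-threshold distractor blobs, videos with lesion
persistence) so that every stage of the pipeline is testable end to end.
Dataset manifests enforce the construction rules of a properly designed
diagnostic study: patient-disjoint splits, at most 10 frames per patient,
and annotated cancer training frames.

## Worked example

Evaluate a diagnostic confusion table — here 200 videos, 120 cancer and 80
non-cancer, with 6 misses and 6 false alarms:

```r
library(laryngoscreen)
rep <- report_from_counts(confusion_counts(TP = 114, FP = 6, FN = 6, TN = 74),
                          ci_method = "wald")
print(rep)
#> Diagnostic evaluation report
#>   TP 114  FP 6  FN 6  TN 74
#>   accuracy     0.940 (0.907-0.973)
#>   sensitivity  0.950 (0.911-0.989)
#>   specificity  0.925 (0.867-0.983)
#>   ppv          0.950 (0.911-0.989)
#>   npv          0.925 (0.867-0.983)
```

Accuracy is the proportion of correctly classified videos; sensitivity and
specificity condition on true cancer and true non-cancer; PPV/NPV condition
on the predicted class. The parenthesized ranges are 95 % binomial
confidence intervals.

The two decision rules, on their own:

```r
m <- matrix(0L, 512, 512); m[100:140, 100:140] <- 1L   # a 41x41 component
classify_frame(m, area_threshold = 1024)
#> is_cancer TRUE  largest_component_area 1681  component_count 1  score 1681

diagnose_video(c(rep(FALSE, 20), rep(TRUE, 60), rep(FALSE, 10)), fps = 25)
#> is_cancer TRUE  longest_run_frames 60  longest_run_seconds 2.4
```

The 1681-px component exceeds 1024, so the frame is cancer; the 60-frame
run lasts 2.4 s > 2 s, so the video is cancer (a 50-frame run — exactly
2.0 s — would not be, since the rule is strict).

End-to-end on synthetic data:

```r
cfg <- synth_config(seed = 1)                       # 128x128 frames
manifest <- generate_dataset(cfg, n_patients = 30,
                             frames_per_patient = 10, dir = "synth")
model <- build_model(unet_spec(input_size = c(128, 128), base_channels = 4))
model <- train(model, manifest,
               train_config(epochs = 16, learning_rate = 2e-3))
video <- generate_video(cfg, cancer = TRUE, id = 1)
stream_diagnose(video, model)$is_cancer
#> TRUE
```

A command-line interface wraps the same functions
(`inst/cli/laryngoscreen`): subcommands `simulate`, `train`, `predict`,
`decide-frame`, `diagnose-video`, `evaluate`, each writing a JSON run
manifest with its options, seed and package version.

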