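# clemsim

Automated registration for correlative light and electron microscopy
(CLEM), for microscopists who need fluorescence channels overlaid on
electron micrographs of the same section without placing fiducials or
dragging images by hand.

Correlation-based alignment fails across modalities because EM and
fluorescence contrast are unrelated. The one structure visible in both is
chromatin: heterochromatin puncta are electron-dense (dark) in EM and
Hoechst-bright in fluorescence. `clemsim` exploits this by

1. predicting a **virtual chromatin image** from the EM image with a
   compact U-Net trained on 30–40 manually aligned pairs
   (*in-silico labeling*),
2. registering the **measured** chromatin channel to that prediction with
   a robustly estimated 2D **similarity transform**
   `p' = s·R(θ)·p + t` (LoG blob detection of puncta, rotation-invariant
   descriptors, ratio-test matching, RANSAC, exhaustive
   correlation-search fallback, sub-pixel landmark refit), and
3. applying the recovered transform to the channels of interest to
   produce the CLEM overlay, a transform XML, and a JSON report.

The package also ships a synthetic correlative-scene simulator with exact
ground truth (nuclei, puncta, true misalignment) and a
known-perturbation benchmark that reports per-axis registration error in
nanometres — so the entire workflow is trainable and testable with no
external data.

## Worked example

Simulate one correlative scene, register the (misaligned, noisy) measured
chromatin to the chromatin image in the EM frame, and compare with the
known ground truth:

```r
library(clemsim)

params <- scene_params(seed = 11)      # 256x256 px @ 25 nm/px, 2 nuclei
scene  <- sample_scene(params)
#> <synthetic_scene> 256 x 256 px, 2 nuclei, 6 puncta, seed 11
#> <similarity_transform> theta = -6.693801 deg, scale = 0.984142, t = (-23.9488, -4.6037) px

em        <- render_em(scene)                                   # EM frame
chromatin <- render_fluorescence(scene, apply_misalignment = TRUE)  # microscope frame

# stand-in for the network: the ground-truth chromatin as a perfect prediction
virtual   <- oracle_model(render_fluorescence(scene, FALSE, noise = FALSE))
predicted <- predict_chromatin(virtual, em)

reg <- register_planes(percentile_normalize(chromatin),
                       percentile_normalize(predicted))
reg
#> <registration_result> status OK (features), 5 inliers, NCC -0.0059 -> 0.9321
#> <similarity_transform> theta = 6.660558 deg, scale = 1.016546, t = (23.5275, 7.4966) px

invert_transform(scene$true_transform)   # what a perfect registration would return
#> <similarity_transform> theta = 6.693801 deg, scale = 1.016113, t = (23.6235, 7.4825) px

residual_error_nm(reg$transform, invert_transform(scene$true_transform),
                  as.matrix(scene$puncta[, c("x_px", "y_px")]),
                  params$pixel_size_nm)
#> err_x_nm err_y_nm
#>     0.78     0.59
```

The registration recovered the unknown misalignment (rotation 6.69°,
scale 1.016, ~24 px shift) to well under a nanometre at the puncta, and
the correlation between the images rose from −0.006 to 0.93.

For the full workflow, train a model and run it on image files:

```r
pairs <- make_training_set(30, scene_params(), seed = 101)
model <- train_model(pairs, model_config(),                       # depth-3 U-Net
                     train_config(epochs = 20, patches_per_pair = 2, seed = 5))
save_model(model, "my_model")

run_pipeline("em.tif", "chromatin.tif", channel_paths = "synapses.tif",
             model_path = "my_model", out_dir = "correlated")
```

which writes `chromatin_predicted.tif`, the registered channels,
`overlay.png`, `transform.xml`, and `report.json`. The same steps are
available from a shell via `inst/scripts/clemsim.R`
(`simulate`, `train`, `predict`, `register`, `evaluate`, `run`
subcommands, each with `--seed` and `--config`).

`run_benchmark()` quantifies accuracy the way the registration should be
validated: perturb a ground-truth-aligned pair by a known transform
(aligned, 3125 nm shift in X, 90°, 180°), run the whole workflow, and
measure the residual per-axis error in nm at the puncta
(success threshold 250 nm). `tidy()`, `glance()` and `autoplot()` give
the records, a one-row summary, and an error plot.

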