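# wormmri

Motion-predictive MR-imaging simulation for freely moving *C. elegans*.

MRI acquires its data line by line in k-space: one phase-encoded echo per
repetition time `TR`, 64 repetitions for a 64-line image. An organism that
moves between repetitions scatters those lines across different anatomical
configurations and the Fourier reconstruction smears. A crawling worm moves
on exactly the same timescale as a microscopy-grade MR sequence
(`TR` = 83 ms at a 12 Hz camera), so conventional imaging of an unrestrained
worm is hopeless — but the worm's motion is *predictable*: body segments
largely follow their predecessors along the center line. If an optical
camera watches the worm, the scanner's gradient center can be steered to the
predicted position of the target slice before every repetition.

`wormmri` implements and evaluates that idea end to end in simulation:

1. **Synthetic videos** (`worm_kinematics()`, `generate_dataset()`) — an
   undulating 1.2 mm worm crawling at ~0.13 mm/s, rendered at 12 Hz for
   10 s with exact ground-truth center-line poses, plus a library of 50
   synthetic cross-section phantoms (64 x 64, ~1.6 um in-plane) standing in
   for an electron-microscopy slice stack.
2. **Detection** (`track_video()`) — grayscale 9x downsampling, temporal
   background estimation, difference-image segmentation, thinning to an
   ordered one-pixel center line with the normalized coordinate
   `s` (head = 0, tail = 1), difference-image head detection, smoothed
   center of gravity, and a speed estimate `v` in s-units per frame.
3. **Prediction** (`predict_poi()`, `predict_cog()`) — a point of interest
   now at coordinate `s` is predicted, `dk` frames ahead, at
   `s_c = s - v * dk` on the current center line (clamped at the head);
   the COG is extrapolated linearly from its last five positions.
4. **Acquisition** (`run_gre()`, `reconstruct()`) — a gradient-echo
   Cartesian sequence encodes one k-space line per frame from the
   instantaneous field of view around the gradient center `G_C`, which
   either follows the predictor, stays fixed (no prediction), follows the
   ground truth (oracle), or images a frozen worm (static). Off-center
   errors shift the cross-section (zero-filled) and substitute
   neighbouring-slice content, exactly the two artifact mechanisms of a
   mis-steered gradient.
5. **Evaluation** (`ssim()`, `simulation_body_position()`,
   `simulation_resolution()`, `simulation_horizon()`,
   `classify_imageability()`) — reconstructions are scored against the true
   slice with the structural similarity measure `s_xy` in [0, 1], across
   body positions, MR:optical resolution ratios and prediction horizons
   1–10, and the motion / prediction / repetition timescales are classified
   into the three imageability regimes.

## Worked example

```r
library(wormmri)

ds <- generate_dataset(worm_kinematics(seed = 3))  # 120 frames, 50 phantoms
tr <- track_video(ds)

# how well is the mid-body slice s = 0.52 imaged at a one-frame horizon?
tru  <- true_slice_image(ds, 0.52)
kp   <- run_gre(ds, sequence_params(mode = "prediction",    horizon = 1), 0.52, track = tr)
kn   <- run_gre(ds, sequence_params(mode = "no_prediction", horizon = 1), 0.52)
ssim(tru, reconstruct(kp))$s_xy   # 0.563
ssim(tru, reconstruct(kn))$s_xy   # 0.069

# is this setup imageable at all?
classify_imageability(t_motion = 500, t_pred = 76, TR = 83)
# "imageable_unrestricted"
```

With the gradient center following the predictor the reconstruction keeps
most of the slice structure (`s_xy` = 0.56); with a fixed gradient center
the worm slides out of the field of view within a few repetitions and the
reconstruction is essentially unrelated to the true slice (`s_xy` = 0.07).
Averaged over eight videos, four slice positions and horizons 1–10, the
test suite measures a prediction/no-prediction similarity ratio of about
2.8, and a prediction-mode decline from ~0.49 (83 ms horizon) to ~0.24
(830 ms horizon) at `s` = 0.52.

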