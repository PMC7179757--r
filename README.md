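# biocyloop

Closed-loop ("biocybernetic") difficulty adaptation for simulated
shooting-range training, with the psychophysiological feature pipelines
needed to drive and evaluate it.

Firearms trainers describe an optimal arousal band for marksmanship — a
heart rate of roughly 100–115 BPM, enough sympathetic drive for fast
cognitive responses without degrading fine motor control. A
biocybernetic training simulator measures the trainee's physiology in
real time and modulates scenario difficulty (target count, size, speed,
weather, light) to steer the trainee into that band. This package
implements the full measurement-to-adaptation chain for researchers in
physiological computing and adaptive training:

* **Synthetic trainee physiology** — an integral pulse frequency
  modulation (IPFM) generator for RR-interval series with prescribed
  LF/HF spectral structure, a band-structured frontal EEG generator
  (TP9/Fp1/Fp2/TP10), a first-order "plant" model of the trainee's HR
  response to difficulty, and a repeated-measures cohort generator.
* **HRV pipeline** — RR intervals in device units of 1/1024 s; mean HR,
  SDNN, RMSSD; Welch–Hann spectral band powers with trapezoidal
  area-under-the-curve integration over VLF (0.0033–0.04 Hz),
  LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz), in ms².
* **EEG pipeline** — Welch PSD with 256-sample Hamming windows at 90%
  overlap on a 0–110 Hz grid; absolute log₁₀ bandpowers for δ (1–4),
  θ (4–8), α (8–12), β (12–30) and γ (30–100 Hz); engagement index
  β/(α+θ), frontal alpha asymmetry α(Fp2) − α(Fp1), and the θ/β ratio.
* **Statistical battery** — Lilliefors-type normality screen, Friedman
  omnibus (χ², df = k − 1), Wilcoxon signed-rank post-hocs
  (Z = (T − μ_T)/σ_T, normal approximation without continuity
  correction) with Bonferroni adjustment (0.05/4 = 0.0125).
* **SSQ scoring** — the 16-item Simulator Sickness Questionnaire scored
  into nausea (×9.54), oculomotor (×7.58), disorientation (×13.92) and
  total severity (×3.74) with cut-off flags at 9.5 / 15.2 / 0 / 15.
* **Adaptation engine** — the buffered zone controller: average the
  incoming metrics, compare against the 100–115 BPM target zone (with a
  frontal-theta concentration gate on the increase branch), step the
  difficulty configuration, clamp to hard variable ranges, and log the
  whole trajectory.

## Worked example

Generate one 3-min "easy" block of physiology and extract both feature
sets:

```r
library(biocyloop)

prof <- state_profile("easy", hr_mean = 88)
rri <- generate_rri(prof, duration = 180, seed = 7)
hrv_summary(rri)
#>   mean_hr  sdnn rmssd    vlf    lf   hf
#> 1      88 44.16  39.7 0.9975 586.9 1363

eeg <- generate_eeg(prof, duration = 180, seed = 8)
eeg_feature_summary(eeg)
#>   frontal_delta frontal_theta frontal_alpha frontal_beta frontal_gamma
#> 1          2.29          1.74           1.6         1.13         0.446
#>   engagement asymmetry theta_beta
#> 1      0.143  -0.00113       4.06
```

The HRV row says the simulated trainee averaged 88 BPM with moderate
beat-to-beat variability (SDNN 44 ms, RMSSD 40 ms) and
respiratory-dominated spectral power (HF 1363 ms² against LF 587 ms² —
the profile's 0.25 Hz modulation is deeper than its 0.1 Hz one). The
EEG row gives frontal log bandpowers in Bels and the three indexes: a
low engagement index and a high θ/β ratio, as expected when θ power
dominates β.

Close the loop for a 10-min session and check where the controller
settles:

```r
traj <- run_closed_loop(duration = 600, seed = 1)
mean(traj$hr[traj$time > 540])
#> [1] 112.2
table(traj$decision)
#>     hold increase
#>      525       75
```

Starting from the easy preset (resting plant at ~80 BPM), the rule
issues 75 increase steps and then holds: the final-minute mean heart
rate, 112.2 BPM, sits inside the trainer's 100–115 BPM target zone.

A complete synthetic study — cohort, features, statistics, SSQ, all
written as headed CSV tables — is one call:

```r
bundle <- run_full_study(seed = 1, out_dir = "study-out")
bundle$report$omnibus
```

A thin command-line wrapper with subcommands `synthesize`, `features`,
`stats`, `ssq`, `loop` and `full-study` ships in
`inst/cli/biocyloop.R`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantities
from scratch — the forced Wilcoxon Z statistic from a
cohort-with-large-HR-effect run through the feature pipeline, and the
final-minute mean heart rate of a 600-s closed-loop session judged
against both bounds of the target zone — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

The synthetic plant and cohort are stated models, not fitted ones: they
reproduce the qualitative structure (HR rising and frontal theta
falling with difficulty, IPFM-constructible HRV bands) that the
adaptation rule needs, and nothing else. See the methods vignette
(`vignettes/biocybernetic-adaptation.Rmd`) for the model equations,
parameter choices, and what a green test does and does not establish.
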