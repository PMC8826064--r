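# pairspace

Tools for analysing how humpback whale (*Megaptera novaeangliae*) adult
female–calf pairs balance acoustic contact with vocal crypsis during
migration. From animal-borne tag data (depth time series, position fixes,
call events, ambient-noise samples), the package:

1. computes six per-bin **movement metrics** over 10-min bins — swim speed,
   southerly speed, course deviation, energetic surface behaviours (ESB),
   proportion of time at the surface, and the number of deep dives
   (> 10 m and > 75 s) initiated per bin;
2. classifies bins into **behavioral states** — resting/milling versus
   travelling — via k-means on the standardized metrics, with the cluster
   count chosen by a four-index internal-validity vote (silhouette,
   Calinski–Harabasz, Davies–Bouldin, gap statistic);
3. relates states to **vocal behavior**: per-state call rates by age class
   with a negative-binomial mixed model (log link, log time offset, random
   intercept per tag; Var = μ + μ²/θ), and adult-female received call levels
   with a REML linear mixed model — pairwise state contrasts use
   least-squares means with multivariate-t adjustment;
4. estimates the **acoustic active space** of every call: broadband ambient
   noise is the power sum of the 40 Hz–2.5 kHz third-octave bands,
   SNR = RL − N, and the detection distance is the closed-form inversion of
   a per-octave-band piecewise transmission-loss model

   TL(x) = a + b·log₁₀(x),

   with slope `b_near` out to a crossover distance and `b_far` beyond it
   (continuous at the crossover), solved for the range where SNR = 0 —
   compared between states with a gamma log-link mixed model.

A seeded synthetic tag-data generator (`simulate_pair_dataset()`) emulates
the statistical structure of such field datasets — a two-state Markov bin
process, state-specific kinematics and dive regimes, state-dependent call
rates (≈ 4.6 calls/h resting vs ≈ 1.6–1.9 travelling), received levels in
124–173 dB re 1 µPa, wind noise in 94–104 dB re 1 µPa — so the whole
pipeline is testable end to end without field recordings.

The bundled transmission-loss coefficient table
(`inst/extdata/tl_bands_synthetic.csv`) is **synthetic**: it mimics the
shape of site-specific measured coefficients and is intended for simulation
and testing. For analysis of real recordings, supply the measured table via
`load_tl_bands("path/to/tl_bands.csv")`.

## Worked example

```r
library(pairspace)

sim <- simulate_pair_dataset(sim_config(), seed = 1)       # 15 follows
res <- run_pair_analysis(sim$datasets, config = run_config(seed = 1))

res$selection$k
#> [1] 2
res$rates[, c("age_class", "state", "rate_per_h")]
#>      age_class           state rate_per_h
#> 1 adult_female resting_milling   6.190476
#> 2         calf resting_milling   4.666667
#> 3 adult_female      travelling   1.456311
#> 4         calf      travelling   1.514563
res$rate_models$adult_female$contrast[, c("contrast", "log_estimate", "p")]
#>                       contrast log_estimate            p
#> 1 travelling / resting_milling    -1.447106 7.796439e-10
median(res$detections$distance_m, na.rm = TRUE)
#> [1] 466.616
mean(res$detections$distance_m <= 2000, na.rm = TRUE)
#> [1] 0.9450549
```

Reading: the index vote selects two behavioral states; adult females call
about four times more often when resting/milling (when prolonged maternal
dives separate the pair) than when travelling (log rate ratio ≈ −1.45,
Wald z p ≈ 8e-10 on this realization); and the median call is audible to
about 470 m, with ~95% of calls inaudible beyond 2 km — a restricted active
space consistent with cryptic contact calling.

`res$dive_models` ranks binomial mixed models of state against the adult
female's dive duration, mean depth, and maximum depth by AIC;
`res$level_model` and `res$distance_model` hold the received-level and
detection-distance state comparisons; `res$surface` is a gridded
median-distance summary over (received level × noise) for plotting.

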