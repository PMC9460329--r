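# bandevents

Event-based heart-rate (HR) and respiratory-rate (RR) estimation from a
single chest-worn resistive-fabric band signal.

## The problem

A conductive-fabric band across the chest, polarized under constant
current, yields one voltage channel carrying both respiration (a large
oscillation, ~3120 mV peak-to-peak) and the cardiac pulse (~84 mV
peak-to-peak, a 37:1 ratio). For overnight monitoring the interesting
output is two rate curves, yet storing raw samples at 200 Hz with
timestamps costs ~38 MB per 8-hour night. `bandevents` implements an
edge-processing alternative: the waveform is reduced on the fly to
sparse 16-byte **events**, and HR/RR are estimated from the events
alone, cutting data volume by 40–140× while retaining enough information
to reconstruct the waveform.

It is intended for researchers working on wearable cardiorespiratory
monitoring and event-driven biosignal processing who need a complete,
testable reference implementation of the chain.

## The method

1. **Delayed comparator.** With delay `p = 10` samples (50 ms at 200 Hz),
   `V(n) = 1` iff `Y(n+p) < Y(n)`. A cumulative count over each run of
   `V = 1` gives the event period `H`; each closed run becomes an event
   `(T, H, V1, V2)` — timestamp, run length, edge amplitudes — 16 bytes.
2. **Repair and classify.** Long events (`H > 20`) are breaths, short
   ones heartbeats. Breaths split by a pulse (two long events separated
   by `P·N < 20` samples, `P = T2 − H2/N − T1`) are merged back, and the
   interruption is recovered as a cardiac blip. Detections violating
   physiological ceilings (60 breaths/min, 180 bpm) are rejected,
   keeping the larger-`H` event.
3. **Missed-beat compensation.** ~30% of beats leave no pulse on the
   band. An overlong cardiac period near `k`× the prevailing period is
   `k−1` missed beats; three algorithms fold such periods back:
   median-harmonics (divide by the best `k ∈ 1..5` of the running
   30-period median), a 14-bucket nonuniform histogram of the last 30
   periods with single/dual/triple majority rules, and windowed k-means
   with seeds at the median and its multiples.
4. **Rates.** Breath-to-breath RR = `60/Δt` over consecutive breath
   peaks; HR per event as the mean of the last 30 instantaneous rates,
   smoothed by a six-sample moving average.
5. **Reconstruction and budgets.** Piecewise-linear interpolation through
   all event anchors rebuilds the waveform; storage/bus arithmetic
   quantifies the data reduction.

A synthetic band-signal generator with exact ground truth (breath peaks,
all beat times, dropped-beat flags) makes the whole chain testable
end-to-end; see the vignette (`vignettes/event-based-hr-rr.Rmd`) for the
model, its assumptions, and its limits.

## Worked example

```r
library(bandevents)

cfg <- pipeline_config(synthetic = synthetic_config(duration_s = 600,
                                                    seed = 42))
res <- run_pipeline(cfg)
#> simulate: 120001 samples @ 200 Hz, 174 breaths, 849 beats
#> generate-events: 903 events
#> process-events: 174 respiratory, 580 cardiac after FP reduction
#> estimate: 520 HR values (median), 173 RR values
#> evaluate: resp sens 100.0% prec 100.0%; HR MAE 0.47 bpm; RR MAE 0.14

hr <- res$hr
mean(hr$rate[!is.na(hr$rate) & hr$time_s > 60])   # 84.80 bpm (truth 84.94)
mean(res$rr$rate)                                  # 17.39 breaths/min

stream_sizes(length(res$series), nrow(res$events))$reduction_factor
#> 66.4
```

Ten minutes of synthetic band signal at 200 Hz (true HR ≈ 85 bpm, RR ≈
17.4 breaths/min, 30% of pulses dropped from the waveform) are reduced to
903 events; every breath is recovered (sensitivity and precision 100%),
the median-harmonics HR tracks truth to ~0.5 bpm despite the missed
beats, breath-to-breath RR is accurate to ~0.14 breaths/min, and the
event stream is ~66× smaller than the raw one.

The same stages are available as a command-line tool:

```sh
CLI=$(Rscript -e 'cat(system.file("exec/bandevents", package = "bandevents"))')
Rscript $CLI simulate --duration 60 --seed 4 --output sim.csv
Rscript $CLI generate-events --input sim.csv --output ev.evt
Rscript $CLI estimate-hr --input ev.evt --method bucket --output hr.csv
Rscript $CLI run-all --duration 600 --seed 42 --out-dir out/
```

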