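#!/usr/bin/env Rscript
# Wall-thickness sensitivity of the degradation effect: the compliant
# straight-tube surrogate (0.41 cm diameter) under the cyclic 8.7-20 kPa
# load, run damaged and undamaged at three wall thicknesses. The quantity of
# interest is the relative change in final-cycle peak radial strain between
# the twins, and how much it varies across thickness.

suppressPackageStartupMessages(library(aneuflow))
dir.create("results", showWarnings = FALSE)

wf <- make_waveform(period = 0.8)
spec <- tube_spec(D0 = 0.41, h = 0.04,
                  material = aneurysm_params("aneurysm_gamma18"),
                  pressure_program = pressure_program_from_waveform(wf, 8.7, 20),
                  period = 0.8, n_cycles = 5)

ex <- run_tube_experiment(spec, n_steps = 64)
cat(sprintf(
  "h = 0.04 cm: peak strain %.4f (undamaged) vs %.4f (damaged), D -> %.3f\n",
  ex$eps_nd_peak, ex$eps_d_peak, max(ex$degraded$D_family1)))
utils::write.csv(ex$degraded, "results/tube_trace_degraded.csv",
                 row.names = FALSE)
utils::write.csv(ex$non_degraded, "results/tube_trace_non_degraded.csv",
                 row.names = FALSE)

sw <- thickness_sweep(spec, thicknesses = c(0.02, 0.04, 0.06), n_steps = 64)
utils::write.csv(sw$table, "results/tube_thickness_sweep.csv",
                 row.names = FALSE)
print(sw$table)
cat(sprintf(
  "Spread of the degradation effect across h = 0.02-0.06 cm: %.2f%%\n",
  sw$spread_pct))
cat(if (sw$spread_pct < 15)
  "The effect is insensitive to wall thickness (< 15% variation),\nsupporting a spatially homogeneous thickness assumption.\n"
  else "WARNING: thickness sensitivity exceeds 15%.\n")
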