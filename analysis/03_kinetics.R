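#!/usr/bin/env Rscript
# Adsorption-kinetics analysis at the optimized batch conditions
# (1.5 g/L dose: 75 mg biomass in 50 mL, 10 mg/L initial Pb(II)).
#
# No raw uptake trace ships with the package, so the trace is generated from
# the pseudo-second-order closed form at the reference parameters
# (qe = 3.782 mg/g, k2 = 0.1148 g/mg/min) and both linearized models are
# fitted back.
#
# Findings: the second-order fit recovers its generating parameters to 4
# significant figures with R^2 = 1, and beats the first-order linearization
# on the same data — the model-selection outcome expected for Pb(II) uptake
# on algal biomass. The script also surfaces the mass-balance consistency
# check: qe = 3.727 mg/g at these batch constants corresponds to ~55.9%
# removal of a 10 mg/L solution, not the ~97% seen at optimum, so capacity
# and removal figures must come from different batch conditions.

library(sorbRSM)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

c0 <- 10; volume <- 0.05; mass <- 0.075
times <- seq(0, 120, by = 5)

tr <- simulate_kinetic_trace("second", qe = 3.782, k = 0.1148,
                             c0 = c0, volume = volume, mass = mass,
                             times = times, sigma = 0)
qt <- qt_series(tr)
write.csv(data.frame(time_min = tr$times, conc_mg_l = tr$conc,
                     qt_mg_g = qt),
          file.path(out_dir, "kinetic_trace.csv"), row.names = FALSE)

pso <- fit_pseudo_second_order(tr$times, qt)
pfo <- fit_pseudo_first_order(tr$times, qt, qe_exp = max(qt))
print(pso)
print(pfo)
cat(sprintf("second-order R^2 (%.6f) > first-order R^2 (%.6f): %s\n",
            pso$r_squared, pfo$r_squared, pso$r_squared > pfo$r_squared))

write_kv(list(qe_exp = max(qt),
              pfo_qe_calc = pfo$qe_calc, pfo_k1 = pfo$k1,
              pfo_r_squared = pfo$r_squared,
              pso_qe_calc = pso$qe_calc, pso_k2 = pso$k2,
              pso_r_squared = pso$r_squared),
         file.path(out_dir, "kinetic_fits.txt"))

# consistency between capacity and removal-efficiency views of the batch
qe_ref <- 3.727
removal_at_qe <- 100 * mass * qe_ref / (volume * c0)
cat(sprintf("\nmass-balance check: qe = %.3f mg/g at %g g in %g L of %g mg/L\n",
            qe_ref, mass, volume, c0))
cat(sprintf("  implies removal of %.1f%% (compare ~97%% at the optimum)\n",
            removal_at_qe))

cat("\nmixed-metal removal ordering predicted by electronegativity:\n")
print(rank_by_electronegativity(heavy_metals()), row.names = FALSE)
cat("wrote kinetic_trace.csv, kinetic_fits.txt to", out_dir, "\n")
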