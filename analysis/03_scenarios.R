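#!/usr/bin/env Rscript
# Operating-strategy comparison on the coupled column-bioreactor loop.
#
# Scenario 1 (baseline): 48 h growth, recirculation at 5 mL/min, one 80%
# medium replacement after 48 h of leaching, 96 h second phase.
# Scenario 2 (refined): recirculation starts at the bacterial metabolic
# peak (threshold 0.005 g Fe2+/(L min)) at half flow; flow halved again
# 15 h later; 65% replacement; flow doubled back at the Fe2+/Fe3+ crossing.
#
# Finding under the shipped calibrated parameters: both schedules exceed
# 95% Cu leaching efficiency, and the refined schedule gets there about a
# day earlier — the energy comparison below scales accordingly.

library(pcbbioleach)
dir.create("results", showWarnings = FALSE)

run1 <- run_coupled(schedule_sim1())
run2 <- run_coupled(schedule_sim2())
t1 <- time_to_efficiency(run1, 0.95)
t2 <- time_to_efficiency(run2, 0.95)

cat(sprintf("scenario 1: 95%% at %.1f h (%.2f d); final efficiency %.1f%%\n",
            t1, t1 / 24, 100 * tail(run1$trajectory$efficiency, 1)))
cat(sprintf("scenario 2: 95%% at %.1f h (%.2f d); final efficiency %.1f%%\n",
            t2, t2 / 24, 100 * tail(run2$trajectory$efficiency, 1)))
cat(sprintf("refined schedule is faster by %.1f h\n", t1 - t2))

cat("\nevent log, scenario 2:\n")
print(run2$events)
cat("\nper-phase extraction, scenario 2:\n")
print(run2$phase_metrics)

aud <- mass_audit(run1)
cat(sprintf("\nloop mass audit (scenario 1): Fe %.4f -> %.4f g, Cu %.4f -> %.4f g\n",
            aud$fe_initial_g, aud$fe_final_g,
            aud$cu_initial_g, aud$cu_final_g))

# energy demand of the two reactor concepts. A stirred tank draws 500 W/m3
# (scales with volume); the pump loop draws a flat 5 W regardless of volume,
# so the comparison basis matters: at bench scale (3.6 L) the pump actually
# dominates, and the specific-power advantage only materializes at scale.
# Both quantities are therefore reported under explicit bases.
e_stirred_bench <- stirred_energy(3.6, 500, t1 / 24)
e_pump <- pump_energy(5, t2 / 24)
cat(sprintf("\nenergy to 95%% at bench scale: stirred 3.6 L tank %.3f kWh vs 5 W pump loop %.3f kWh\n",
            e_stirred_bench, e_pump))
e_stirred_m3 <- stirred_energy(1000, 500, t1 / 24)
cat(sprintf("energy to 95%% at 1 m3 scale: stirred %.0f kWh vs 5 W pump loop %.2f kWh (%.1f%% lower)\n",
            e_stirred_m3, e_pump, 100 * (1 - e_pump / e_stirred_m3)))
cat(sprintf("shorter treatment alone (%.2f d -> %.2f d) saves %.0f%% of stirring energy at any scale\n",
            t1 / 24, t2 / 24, 100 * (1 - t2 / t1)))

write.csv(run1$trajectory, "results/scenario1_trajectory.csv",
          row.names = FALSE)
write.csv(run2$trajectory, "results/scenario2_trajectory.csv",
          row.names = FALSE)
generate_scenario_fixture("sim1", "results/scenario1_schedule.yml")
generate_scenario_fixture("sim2", "results/scenario2_schedule.yml")
cat("wrote results/scenario{1,2}_trajectory.csv and schedule fixtures\n")
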