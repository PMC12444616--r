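#!/usr/bin/env Rscript
# Chemical leaching of Cu from PCB powder in the packed column: the two
# flow regimes and the recirculation (refeed) pass.
#
# Findings with the shipped calibrated kinetics:
#   - 25 mL/min: ferric breakthrough — outflow Fe3+ rises through the whole
#     first 2 h because the 5-min contact time cannot complete the reaction.
#   - 5 mL/min: near-complete conversion — Cu outflow holds a ~4 g/L plateau
#     and ~43 g (≈85% of the inventory) is extracted in 38 h at ~1.1 g/h.
#   - refeeding the collected outflow extracts further Cu from the residual
#     ferric iron in the mixed solution.

library(pcbbioleach)
dir.create("results", showWarnings = FALSE)

geom <- column_geometry()
kin <- chem_kinetics()
feed <- inflow_program("constant", fe3 = 10 / AW_FE)

low <- simulate_column(geom, kin, feed, 5, 38 * 60)
m <- extraction_metrics(low, geom)
cat(sprintf("low flow (5 mL/min, 38 h): %.1f g Cu extracted, efficiency %.1f%%, rate %.2f g/h\n",
            m$extracted_g, 100 * m$efficiency_fraction, m$rate_g_per_h))
w <- low$times >= 8 * 60 & low$times <= 33 * 60
cat(sprintf("  Cu outflow plateau (8-33 h): %.2f g/L\n",
            mean(low$cu2[w]) * AW_CU))

high <- simulate_column(geom, kin, feed, 25, 2 * 60)
cat(sprintf("high flow (25 mL/min): outflow Fe3+ %.2f g/L at 5 min -> %.2f g/L at 2 h (monotone rise: %s)\n",
            high$fe3[high$times == 5] * AW_FE,
            tail(high$fe3, 1) * AW_FE,
            all(diff(high$fe3) > -1e-12)))

second <- refeed_run(high, geom, kin, 25)
cat(sprintf("refeed pass: inflow Fe3+ %.2f g/L (mixed first-pass outflow), extra Cu %.1f g\n",
            second$inflow$fe3 * AW_FE,
            tail(second$cumulative_cu_extracted_g, 1)))

keep <- function(run) {
  i <- seq(1, length(run$times), by = 10)   # thin to 1-min cadence
  data.frame(time_min = run$times[i], cu_out_mol_l = run$cu2[i],
             fe3_out_mol_l = run$fe3[i], fe2_out_mol_l = run$fe2[i],
             cu_out_g_l = run$cu2[i] * AW_CU,
             fe3_out_g_l = run$fe3[i] * AW_FE,
             fe2_out_g_l = run$fe2[i] * AW_FE)
}
write.csv(keep(low), "results/column_low_flow.csv", row.names = FALSE)
write.csv(keep(high), "results/column_high_flow.csv", row.names = FALSE)
write.csv(keep(second), "results/column_refeed.csv", row.names = FALSE)
cat("wrote results/column_{low_flow,high_flow,refeed}.csv\n")
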