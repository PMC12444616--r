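test_that("stirred-tank and pump energies are linear power-time products", {
  expect_equal(stirred_energy(1, 500, 11), 0.132)
  expect_equal(stirred_energy(0, 500, 11), 0)
  expect_equal(stirred_energy(3.6, 500, 11), 3.6 * 0.132)
  expect_equal(round(stirred_energy(3.6, 500, 11), 3), 0.475)
  expect_equal(pump_energy(5, 6.5), 0.78)
  expect_equal(pump_energy(5, 0), 0)
  expect_equal(pump_energy(2.5, 6.5), 0.39)
  expect_error(stirred_energy(-1, 500, 11), "non-negative")
})

test_that("recovery reagent demand follows the cementation stoichiometry", {
  expect_equal(reagent_demand(0, 0)$zn_cement_g, 0)
  # 1.1 x 0.1 mol x 65.38 g/mol
  expect_equal(reagent_demand(0.1, 0)$zn_cement_g, 7.1918)
  # oxalic acid on total zinc 0.05 mol: 1.3 x 0.05 x 90.03
  expect_equal(reagent_demand(0, 0.05)$oa_g, 5.85195)
  expect_equal(round(reagent_demand(0, 0.05)$oa_g, 2), 5.85)
  # cementation zinc re-enters solution and feeds the oxalate demand
  both <- reagent_demand(0.1, 0.05)
  expect_equal(both$oa_g, 1.3 * (0.05 + 0.11) * MW_OA)
  expect_error(reagent_demand(-1, 0), "non-negative")
})

test_that("footprint aggregation is linear with correctly signed credits", {
  inv <- build_inventory(pcb_g_l = 100, cu_fraction = 0.2,
                         zn_fraction = 0.02)
  cf <- placeholder_cf_table()
  fp <- carbon_footprint(inv, cf)
  expect_equal(fp$net, fp$leaching + fp$recovery - fp$credit)
  expect_gt(fp$leaching, 0)
  expect_gt(fp$credit, 0)
  # linearity: doubling every factor doubles every component
  cf2 <- cf; cf2$cf <- cf$cf * 2
  fp2 <- carbon_footprint(inv, cf2)
  expect_equal(fp2$net, 2 * fp$net)
  expect_equal(fp2$credit, 2 * fp$credit)
  # all-zero factors give a zero footprint
  cf0 <- cf; cf0$cf <- 0 * cf$cf
  expect_equal(carbon_footprint(inv, cf0)$net, 0)
  # credits exceeding burdens turn the net negative
  cfneg <- cf; cfneg$cf[cfneg$item == "cu_credit_g"] <- 1e3
  expect_lt(carbon_footprint(inv, cfneg)$net, 0)
  # a missing factor is reported by item name
  expect_error(carbon_footprint(inv, cf[cf$item != "oa_g", ]), "oa_g")
})

test_that("net footprint is monotone decreasing in the credit masses", {
  cf <- placeholder_cf_table()
  inv <- build_inventory(100, 0.2, 0.02)
  nets <- sapply(seq(0, 50, by = 5), function(extra) {
    inv$cu_credit_g <- inv$cu_credit_g + extra
    carbon_footprint(inv, cf)$net
  })
  expect_true(all(diff(nets) < 0))
})

test_that("Monte Carlo draws are reproducible with exact accounting", {
  a <- monte_carlo(n = 180, seed = 11)
  b <- monte_carlo(n = 180, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, monte_carlo(n = 180, seed = 12)))
  expect_equal(nrow(a$draws), 180)
  expect_equal(a$n, 180)
  # shares computed on absolute magnitudes sum to 100 in every draw
  sums <- a$draws$share_leaching + a$draws$share_recovery +
    a$draws$share_credit
  expect_true(all(abs(sums - 100) < 1e-9))
  # and therefore in every grid cell of the summary
  cell_sums <- a$shares$leaching + a$shares$recovery + a$shares$credit
  expect_true(all(abs(cell_sums - 100) < 0.5))
  # sampled concentrations respect their truncation at zero
  expect_true(all(a$draws$pcb_pct > 0 & a$draws$cu_pct > 0))
  expect_error(monte_carlo(n = 0), "positive")
})

test_that("degenerate sampling collapses every draw to the same point", {
  cells <- data.frame(pcb_mean = 10, cu_mean = 20, pcb_sd = 0, cu_sd = 0)
  cf <- placeholder_cf_table(rel_uncertainty = 0)
  mc <- monte_carlo(n = 25, cf = cf, seed = 5, cells = cells, zn_sd = 0)
  expect_equal(sd(mc$draws$net), 0)
  expect_equal(sd(mc$draws$pcb_pct), 0)
})

test_that("share structure shifts with composition as expected", {
  mc <- monte_carlo(n = 900, seed = 2)
  sh <- mc$shares[order(mc$shares$cell), ]
  # at fixed Cu content, richer PCB loading dilutes the fixed leaching inputs
  lo_cu <- sh[sh$cu_mean == 10, ]
  expect_true(all(diff(lo_cu$leaching[order(lo_cu$pcb_mean)]) < 0))
  # at fixed loading, more copper increases the credit share
  lo_pcb <- sh[sh$pcb_mean == 5, ]
  expect_true(all(diff(lo_pcb$credit[order(lo_pcb$cu_mean)]) > 0))
})
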