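test_that("column_rhs evaluates the balance terms correctly", {
  geom <- default_geom()
  v <- pore_volume(geom)
  kin <- chem_kinetics(1)
  # hand-evaluated rate term: k (Cu0 - Cu2+) Fe3+ = 1 * 0.4 * 0.05 = 0.02
  st <- column_solution(cu2 = 0.1, fe3 = 0.05, fe2 = 0, cu_solid = 0.5)
  d <- column_rhs(st, list(cu2 = 0, fe3 = 0, fe2 = 0), 0, kin, v)
  expect_equal(unname(d["cu2"]), 0.02)
  expect_equal(unname(d["fe3"]), -0.04)
  expect_equal(unname(d["fe2"]), 0.04)
  expect_equal(unname(d["cu_solid"]), -0.02)

  # no reaction, inflow equal to state: everything cancels
  st2 <- column_solution(cu2 = 0.01, fe3 = 0.05, fe2 = 0.02, cu_solid = 1)
  d2 <- column_rhs(st2, st2, 5, chem_kinetics(0), v)
  expect_equal(max(abs(d2)), 0)

  # no oxidant: pure CSTR mixing at rate Q/V
  st3 <- column_solution(cu2 = 0.05, fe3 = 0, fe2 = 0.02, cu_solid = 1)
  infl <- list(cu2 = 0.01, fe3 = 0, fe2 = 0)
  d3 <- column_rhs(st3, infl, 5, chem_kinetics(1), v)
  expect_equal(unname(d3["cu2"]), 0.005 * (0.01 - 0.05) / v)
  expect_equal(unname(d3["fe2"]), 0.005 * (0 - 0.02) / v)
  expect_equal(unname(d3["cu_solid"]), 0)

  # the driving force floors at zero when dissolved Cu exceeds the solid
  st4 <- column_solution(cu2 = 0.6, fe3 = 0.05, fe2 = 0, cu_solid = 0.5)
  d4 <- column_rhs(st4, list(cu2 = 0, fe3 = 0, fe2 = 0), 0, kin, v)
  expect_equal(max(abs(d4)), 0)
})

test_that("zero-duration and invalid configurations are handled", {
  geom <- default_geom()
  run <- simulate_column(geom, chem_kinetics(), ferric_feed(), 5, 0)
  expect_length(run$times, 1)
  expect_equal(run$cu_solid[1], initial_cu_solid(geom))
  expect_error(simulate_column(geom, chem_kinetics(), ferric_feed(), 5,
                               duration_min = 1, dt_min = 2), "dt")
})

test_that("with no reaction the column follows the CSTR washout closed form", {
  geom <- default_geom()
  v <- pore_volume(geom)
  init <- column_solution(cu2 = 0.05, fe3 = 0.1, fe2 = 0.02, cu_solid = 1)
  feed <- inflow_program("constant", cu2 = 0.01, fe3 = 0.179, fe2 = 0.001)
  run <- simulate_column(geom, chem_kinetics(0), feed, 5, 240, init = init)
  tt <- run$times
  washout <- function(c0, cin) cin + (c0 - cin) * exp(-0.005 * tt / v)
  expect_lt(max(abs(run$fe3 - washout(0.1, 0.179)) / washout(0.1, 0.179)),
            0.01)
  expect_lt(max(abs(run$cu2 - washout(0.05, 0.01)) / washout(0.05, 0.01)),
            0.01)
  expect_lt(max(abs(run$fe2 - washout(0.02, 0.001)) / washout(0.02, 0.001)),
            0.01)
})

test_that("closed column conserves copper and iron over 1e5 steps", {
  geom <- default_geom()
  init <- column_solution(cu2 = 0.01, fe3 = 0.15, fe2 = 0.02,
                          cu_solid = 2)
  run <- simulate_column(geom, chem_kinetics(), ferric_feed(), 0,
                         duration_min = 1e4, dt_min = 0.1, init = init)
  cu_tot <- run$cu2 + run$cu_solid
  fe_tot <- run$fe2 + run$fe3
  expect_lt(max(abs(cu_tot - cu_tot[1])) / cu_tot[1], 1e-4)
  expect_lt(max(abs(fe_tot - fe_tot[1])) / fe_tot[1], 1e-4)
})

test_that("cumulative Fe2+ production is m times cumulative Cu dissolution", {
  geom <- default_geom()
  v <- pore_volume(geom)
  run <- simulate_column(geom, chem_kinetics(), ferric_feed(), 5,
                         duration_min = 600)
  tt <- run$times
  trap <- function(x) sum(diff(tt) * (x[-1] + x[-length(x)]) / 2)
  # dissolved from the solid phase (mol, per free volume basis times V)
  dissolved <- (run$cu_solid[1] - run$cu_solid[length(tt)]) * v
  # Fe2+ produced = accumulation + export (feed carries no Fe2+)
  produced <- (run$fe2[length(tt)] - run$fe2[1]) * v + 0.005 * trap(run$fe2)
  expect_equal(produced / dissolved, 2, tolerance = 1e-3)
})

test_that("halving the step changes the final state by less than 0.5%", {
  geom <- default_geom()
  a <- simulate_column(geom, chem_kinetics(), ferric_feed(), 5, 600,
                       dt_min = 0.1)
  b <- simulate_column(geom, chem_kinetics(), ferric_feed(), 5, 600,
                       dt_min = 0.05)
  fa <- a$final_state; fb <- b$final_state
  for (f in c("cu2", "fe3", "fe2", "cu_solid"))
    expect_lt(abs(fa[[f]] - fb[[f]]) / max(fb[[f]], 1e-9), 0.005)
})

test_that("the Q = 0 limit matches independent batch integrations", {
  geom <- default_geom()
  init <- column_solution(cu2 = 0, fe3 = 0.179, fe2 = 0, cu_solid = 3)
  run <- simulate_column(geom, chem_kinetics(), ferric_feed(), 0,
                         duration_min = 300, dt_min = 0.1, init = init)
  # hand-coded batch Euler over the same rate law
  oracle <- batch_oracle(init, k = 0.015, m = 2, duration_min = 300,
                         dt_min = 0.1)
  expect_equal(run$final_state$cu2, oracle$cu2, tolerance = 1e-10)
  expect_equal(run$final_state$fe3, oracle$fe3, tolerance = 1e-10)
  # continuous-time solution via deSolve as a second, scheme-independent check
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) {
    r <- p$k * max(y[4] - y[1], 0) * y[2]
    list(c(r, -p$m * r, p$m * r, -r))
  }
  sol <- deSolve::ode(c(0, 0.179, 0, 3), c(0, 300), rhs,
                      list(k = 0.015, m = 2), rtol = 1e-9, atol = 1e-12)
  expect_equal(run$final_state$cu2, unname(sol[2, 2]), tolerance = 5e-3)
  expect_equal(run$final_state$fe3, unname(sol[2, 3]), tolerance = 5e-3)
})

test_that("outflow shapes reproduce the documented flow-rate contrast", {
  geom <- default_geom()
  kin <- chem_kinetics()
  # high flow: ferric breakthrough, outflow Fe3+ rising through the first 2 h
  high <- simulate_column(geom, kin, ferric_feed(), 25, 120)
  expect_true(all(diff(high$fe3) > -1e-12))
  expect_gt(tail(high$fe3, 1), high$fe3[2])
  # low flow: Cu outflow plateaus near 4 g/L over the 8-33 h window
  low <- simulate_column(geom, kin, ferric_feed(), 5, 38 * 60)
  w <- low$times >= 8 * 60 & low$times <= 33 * 60
  plateau <- mean(low$cu2[w]) * AW_CU
  expect_gt(plateau, 3)
  expect_lt(plateau, 5)
  # and its extraction metrics sit near the reference milestones
  m <- extraction_metrics(low, geom)
  expect_gt(m$efficiency_fraction, 0.8)
  expect_lt(m$efficiency_fraction, 0.9)
  expect_equal(m$rate_g_per_h, 1.15, tolerance = 0.05)
})

test_that("refeed uses the mixed first-pass outflow and conserves copper", {
  geom <- default_geom()
  kin <- chem_kinetics()
  first <- simulate_column(geom, kin, ferric_feed(), 25, 120)
  second <- refeed_run(first, geom, kin, 25)
  # refeed composition is the flow-weighted mean of the collected outflow
  comp <- collected_mean_composition(first)
  expect_equal(second$inflow$fe3, comp$fe3)
  expect_gt(comp$fe3, 0)
  # residual Fe3+ keeps extracting from the carried-over solid
  extracted2 <- second$cumulative_cu_extracted_g[length(second$times)]
  expect_gt(extracted2, 0)
  total <- first$cumulative_cu_extracted_g[length(first$times)] + extracted2
  expect_lt(total, geom$pcb_mass_g * geom$cu_mass_fraction)
  expect_error(refeed_run(structure(list(times = numeric(0)),
                                    class = "column_run"), geom, kin, 25))
})

test_that("extraction metrics integrate the outflow correctly", {
  geom <- default_geom()
  # constant 4 g/L Cu outflow at 5 mL/min: 0.3 L/h x 4 g/L = 1.2 g/h
  run <- structure(list(times = seq(0, 2160, by = 1),
                        cu2 = rep(4 / AW_CU, 2161), q_ml_min = 5),
                   class = "column_run")
  m <- extraction_metrics(run, geom, window = c(0, 600))
  expect_equal(m$rate_g_per_h, 1.2, tolerance = 1e-9)
  expect_equal(m$extracted_g, 12, tolerance = 1e-9)
  # 43 g out of the 50.6 g inventory is 85% efficiency
  t43 <- 43 / 1.2 * 60
  m43 <- extraction_metrics(run, geom, window = c(0, t43))
  expect_equal(m43$efficiency_fraction, 0.85, tolerance = 1e-3)
  expect_error(extraction_metrics(run, geom, window = c(2200, 2400)),
               "outside")
  expect_error(extraction_metrics(run, geom, window = c(100, 100)),
               "interval")
})
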