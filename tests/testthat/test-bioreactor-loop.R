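test_that("Monod growth rate has the textbook anchor points", {
  bio <- bio_kinetics()
  expect_identical(monod_mu(0, bio), 0)
  expect_equal(monod_mu(bio$k_s, bio), bio$mu_max / 2)
  expect_equal(monod_mu(100 * bio$k_s, bio), bio$mu_max * 100 / 101)
  expect_error(monod_mu(-1, bio), "non-negative")
})

test_that("bacterial growth balances growth against quadratic toxicity", {
  # no toxicity, saturating substrate: essentially exponential at mu_max
  bio <- bio_kinetics(mu_d = 0, mu_tox = 0)
  st <- bioreactor_state(n_bacteria = 1e9, fe2_g = 1000 * bio$k_s)
  expect_equal(bacteria_rhs(st, bio), bio$mu_max * 1e9, tolerance = 1e-2)
  # N = 0 is absorbing
  expect_identical(bacteria_rhs(bioreactor_state(0, 5, 0, 0), bio), 0)
  # balance point: mu = 0.001 against mu_tox Cu^2 = 1e-5 * 100
  bal <- bio_kinetics(mu_max_per_min = 0.001, k_s_g_l = 0,
                      mu_d = 0, mu_tox = 1e-5)
  st2 <- bioreactor_state(n_bacteria = 1e6, fe2_g = 5, cu2_g = 10)
  expect_equal(bacteria_rhs(st2, bal), 0)
})

test_that("metabolic rate is (mu/Y) N in g Fe2+ per litre-minute", {
  # arithmetic matching the scheduling threshold 0.005 g/(L min)
  bio <- bio_kinetics(mu_max_per_min = 0.002, k_s_g_l = 0,
                      y_ns_cells_g = 1e9)
  st <- bioreactor_state(n_bacteria = 2.5e9, fe2_g = 3)
  expect_equal(metabolic_rate(st, bio), 0.005)
  expect_identical(metabolic_rate(bioreactor_state(0, 3, 0, 0), bio), 0)
  expect_identical(metabolic_rate(bioreactor_state(1e9, 0, 0, 0), bio), 0)
})

test_that("bioreactor step applies the V_rim dilution balance", {
  bio <- bio_kinetics()
  cfg <- loop_config(q_ml_min = 5, dt_min = 0.1)
  # V_rim = 3.6 - 0.005 * 0.1 = 3.5995 L; dilution-only step on 8 g/L
  st <- bioreactor_state(n_bacteria = 0, fe2_g = 0, fe3_g = 0, cu2_g = 8)
  out <- list(cu2 = 0, fe3 = 0, fe2 = 0)
  expect_equal(bioreactor_step(st, out, cfg, bio)$cu2_g, 8 * 3.5995 / 3.6)
  expect_equal(round(bioreactor_step(st, out, cfg, bio)$cu2_g, 4), 7.9989)
  # Q = 0 and N = 0: state unchanged
  cfg0 <- loop_config(q_ml_min = 0)
  st2 <- bioreactor_state(n_bacteria = 0, fe2_g = 3, fe3_g = 2, cu2_g = 1)
  expect_equal(unclass(bioreactor_step(st2, out, cfg0, bio)), unclass(st2))
  # biological conversion moves iron from Fe2+ to Fe3+, conserving total Fe
  st3 <- bioreactor_state(n_bacteria = 2e9, fe2_g = 5, fe3_g = 1)
  nxt <- bioreactor_step(st3, out, cfg0, bio)
  expect_lt(nxt$fe2_g, 5)
  expect_equal(nxt$fe2_g + nxt$fe3_g, 6)
})

test_that("medium replacement mixes retained solution with fresh medium", {
  st <- bioreactor_state(n_bacteria = 1e9, fe2_g = 1, fe3_g = 2.6,
                         cu2_g = 10)
  # 80% replacement knocks 2.6 g/L Fe3+ down to 0.52 (~0.5)
  post <- replace_medium(st, 0.8, fresh_fe2_g = 9.4)
  expect_equal(post$fe3_g, 0.52)
  expect_equal(round(post$fe3_g, 1), 0.5)
  expect_equal(post$fe2_g, 0.2 * 1 + 0.8 * 9.4)
  expect_equal(post$n_bacteria, 2e8)
  # 65% replacement retains 35% of the copper
  expect_equal(replace_medium(st, 0.65, 9.4)$cu2_g, 3.5)
  # vanishing fraction approaches identity
  tiny <- replace_medium(st, 1e-9, 9.4)
  expect_equal(tiny$cu2_g, st$cu2_g, tolerance = 1e-6)
  expect_error(replace_medium(st, 0, 9.4), "fraction")
  expect_error(replace_medium(st, 1, 9.4), "fraction")
})

test_that("schedule constructors validate events and triggers", {
  expect_error(sched_event("set_flow", at_h = 1, after_h = 2, q_ml_min = 5),
               "exactly one")
  expect_error(sched_event("set_flow", at_h = 1), "q_ml_min")
  expect_error(sched_event("replace_medium", at_h = 1, fraction = 0.8),
               "fresh_fe2_g")
  expect_error(sched_event("stop", when = list(type = "nope")), "unknown")
  expect_error(sched_event("stop", when = list(type = "cu_ge")),
               "threshold")
  expect_error(process_schedule(list(1)), "sched_event")
})

test_that("without recirculation the column is untouched and bacteria grow", {
  sched <- process_schedule(list(sched_event("stop", at_h = 24)),
                            max_duration_h = 30)
  run <- run_coupled(sched)
  tr <- run$trajectory
  expect_equal(max(tr$q_ml_min), 0)
  expect_equal(max(tr$efficiency), 0)
  expect_equal(sd(tr$cu_solid_mol_l), 0)
  # growth: abundance increases, Fe2+ is oxidized to Fe3+
  expect_gt(tail(tr$n_cells_per_l, 1), tr$n_cells_per_l[1])
  expect_gt(tail(tr$fe3_g_l, 1), 5)
  expect_lt(tail(tr$fe2_g_l, 1), 5)
})

test_that("the coupled loop conserves iron and copper through replacements", {
  run <- run_coupled(schedule_sim1())
  audit <- mass_audit(run)
  expect_lt(abs(audit$fe_final_g - audit$fe_initial_g) / audit$fe_initial_g,
            1e-3)
  expect_lt(abs(audit$cu_final_g - audit$cu_initial_g) / audit$cu_initial_g,
            1e-3)
  tr <- run$trajectory
  # positivity and monotone efficiency at every record
  expect_true(all(tr$fe2_g_l >= 0 & tr$fe3_g_l >= 0 & tr$cu_g_l >= 0 &
                    tr$n_cells_per_l >= 0 & tr$cu_solid_mol_l >= 0))
  expect_true(all(diff(tr$efficiency) >= -1e-12))
})

test_that("triggers fire deterministically and in sequence", {
  a <- run_coupled(schedule_sim2())
  b <- run_coupled(schedule_sim2())
  expect_identical(a$events, b$events)
  expect_identical(a$trajectory, b$trajectory)
  ev <- a$events
  expect_equal(ev$action[1], "start_recirculation")
  expect_true(all(diff(ev$time_h) > 0))
  # the metabolic-rate trigger fired at its threshold, not before
  t1 <- ev$time_h[1] * 60
  tr <- a$trajectory
  before <- tr[tr$time_min < t1 - 1, ]
  bio <- bio_kinetics()
  rates <- bio$mu_max * before$fe2_g_l / (bio$k_s + before$fe2_g_l) *
    before$n_cells_per_l / bio$y_ns
  expect_lt(max(rates), 0.005)
})

test_that("a schedule whose trigger never fires warns and runs out the clock", {
  sched <- process_schedule(list(
    sched_event("start_recirculation",
                when = list(type = "cu_ge", threshold = 50),
                q_ml_min = 5),
    sched_event("stop", after_h = 1)), max_duration_h = 2)
  expect_warning(run <- run_coupled(sched), "never fired")
  expect_equal(tail(run$trajectory$time_min, 1), 120)
})

test_that("halving the loop step changes final efficiency by <0.5%", {
  sched <- process_schedule(list(
    sched_event("start_recirculation", at_h = 24, q_ml_min = 5),
    sched_event("stop", after_h = 24)), max_duration_h = 48)
  a <- run_coupled(sched, cfg = loop_config(dt_min = 0.1))
  b <- run_coupled(sched, cfg = loop_config(dt_min = 0.05))
  ea <- tail(a$trajectory$efficiency, 1)
  eb <- tail(b$trajectory$efficiency, 1)
  expect_gt(ea, 0.1)
  expect_lt(abs(ea - eb) / eb, 0.005)
})
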