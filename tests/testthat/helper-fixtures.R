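# shared fixtures: the bench column and the ~10 g/L ferric feed
default_geom <- function() column_geometry()

ferric_feed <- function(fe3_g_l = 10)
  inflow_program("constant", fe3 = fe3_g_l / AW_FE)

# hand-coded closed-batch integrator over the same rate law, used as an
# independent oracle for the Q = 0 limit of the column model
batch_oracle <- function(init, k, m, duration_min, dt_min) {
  cu2 <- init$cu2; fe3 <- init$fe3; fe2 <- init$fe2; cus <- init$cu_solid
  for (i in seq_len(round(duration_min / dt_min))) {
    r <- k * max(cus - cu2, 0) * fe3
    cu2 <- cu2 + dt_min * r
    fe3 <- fe3 - dt_min * m * r
    fe2 <- fe2 + dt_min * m * r
    cus <- cus - dt_min * r
  }
  list(cu2 = cu2, fe3 = fe3, fe2 = fe2, cu_solid = cus)
}
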