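#' Energy demand of a mechanically stirred reactor
#'
#' power density x volume x duration, in kWh. A 1 L tank stirred at the
#' typical 500 W/m3 for 11 days draws 0.132 kWh.
#'
#' @param volume_l reactor volume, L.
#' @param power_density_w_m3 specific power input, W/m3.
#' @param duration_days run length, days.
#' @return energy in kWh.
#' @export
stirred_energy <- function(volume_l, power_density_w_m3, duration_days) {
  vals <- c(volume_l, power_density_w_m3, duration_days)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all inputs must be non-negative")
  power_density_w_m3 * (volume_l / 1000) / 1000 * duration_days * 24
}

#' Energy demand of a peristaltic pump
#'
#' @param power_w pump power draw, W.
#' @param duration_days run length, days.
#' @return energy in kWh.
#' @export
pump_energy <- function(power_w, duration_days) {
  vals <- c(power_w, duration_days)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all inputs must be non-negative")
  power_w / 1000 * duration_days * 24
}

#' Reagent demand of the metal-recovery stage
#'
#' Cementation zinc at a Zn/Cu molar ratio of 1.1:1, oxalic acid at an
#' OA/Zn molar ratio of 1.3:1 (on the total dissolved zinc: PCB-derived
#' plus the cementation zinc, which re-enters solution), and the fixed NaOH
#' demand for iron precipitation.
#'
#' @param cu_leached_mol moles of leached copper to recover.
#' @param zn_in_solution_mol moles of PCB-derived zinc in solution.
#' @param naoh_kg fixed NaOH demand, kg (default the inventory entry 0.035).
#' @return list with `zn_cement_g`, `oa_g`, `naoh_kg`.
#' @export
reagent_demand <- function(cu_leached_mol, zn_in_solution_mol,
                           naoh_kg = 0.035) {
  if (any(!is.finite(c(cu_leached_mol, zn_in_solution_mol))) ||
      cu_leached_mol < 0 || zn_in_solution_mol < 0)
    stop("moles must be non-negative")
  zn_cement_mol <- 1.1 * cu_leached_mol
  zn_total_mol <- zn_in_solution_mol + zn_cement_mol
  list(zn_cement_g = zn_cement_mol * MW_ZN,
       oa_g = 1.3 * zn_total_mol * MW_OA,
       naoh_kg = naoh_kg)
}

#' Life-cycle inventory per functional unit (1 L of bioreactor)
#'
#' Fixed leaching inputs (electricity, ferrous sulfate, water, sulfuric
#' acid, NaOH, micronutrients) and recovery inputs (NaOH, recovery energy),
#' plus the variable items computed from a sampled PCB load and
#' composition: cementation zinc, oxalic acid, and the Cu/Zn credits.
#'
#' @param pcb_g_l PCB concentration in the leach, g per L of bioreactor.
#' @param cu_fraction copper mass fraction of the PCB powder (w/w).
#' @param zn_fraction zinc mass fraction of the PCB powder (w/w).
#' @param leach_efficiency fraction of the metal dissolved (default 0.95,
#'   the documented process performance).
#' @return an object of class `inventory_table`: named list of item
#'   quantities in the units of [placeholder_cf_table()].
#' @export
build_inventory <- function(pcb_g_l, cu_fraction, zn_fraction,
                            leach_efficiency = 0.95) {
  vals <- c(pcb_g_l, cu_fraction, zn_fraction, leach_efficiency)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("inventory inputs must be non-negative")
  cu_g <- pcb_g_l * cu_fraction * leach_efficiency
  zn_g <- pcb_g_l * zn_fraction * leach_efficiency
  rg <- reagent_demand(cu_g / AW_CU, zn_g / MW_ZN)
  structure(list(
    electricity_kwh = 0.132,
    feso4_g = 2.5,
    water_kg = 0.17,
    h2so4_kg = 0.015,
    naoh_leaching_kg = 0.01,
    micronutrients_g = 0.4,
    naoh_recovery_kg = 0.035,
    recovery_energy_kwh = 4.7e-4,
    zn_cement_g = rg$zn_cement_g,
    oa_g = rg$oa_g,
    cu_credit_g = cu_g,
    zn_credit_g = zn_g), class = "inventory_table")
}

.leaching_items <- c("electricity_kwh", "feso4_g", "water_kg", "h2so4_kg",
                     "naoh_leaching_kg", "micronutrients_g")
.recovery_items <- c("naoh_recovery_kg", "recovery_energy_kwh",
                     "zn_cement_g", "oa_g")
.credit_items <- c("cu_credit_g", "zn_credit_g")

#' Placeholder characterization-factor table
#'
#' SYNTHETIC STAND-IN: the characterization factors used in the original
#' assessment come from a proprietary database and are not published, so
#' this table carries order-of-magnitude literature values for the
#' global-warming category (kg CO2-equiv per item unit) purely so the
#' aggregation machinery can run. Absolute footprints computed from it are
#' NOT comparable to any published figure; structural properties (shares,
#' signs, monotonicity, linearity) are.
#'
#' @param rel_uncertainty relative (1-sigma) uncertainty applied to each
#'   factor in Monte Carlo draws; default 0.10.
#' @return an object of class `cf_table`: data.frame with `item`, `cf`
#'   (kg CO2-equiv per unit), `rel_uncertainty`, `provenance`.
#' @export
placeholder_cf_table <- function(rel_uncertainty = 0.10) {
  items <- c(electricity_kwh = 0.4,       # kg CO2e per kWh grid power
             feso4_g = 2e-4,              # per g iron(II) sulfate
             water_kg = 3e-4,             # per kg process water
             h2so4_kg = 0.13,             # per kg sulfuric acid
             naoh_leaching_kg = 1.1,      # per kg NaOH
             micronutrients_g = 1e-3,     # per g nutrient salts
             naoh_recovery_kg = 1.1,
             recovery_energy_kwh = 0.4,
             zn_cement_g = 3e-3,          # per g zinc metal input
             oa_g = 2e-3,                 # per g oxalic acid
             cu_credit_g = 4e-3,          # avoided primary Cu, per g
             zn_credit_g = 3e-3)          # avoided primary Zn, per g
  structure(data.frame(item = names(items), cf = unname(items),
                       rel_uncertainty = rel_uncertainty,
                       provenance = "synthetic placeholder, not from any published dataset",
                       stringsAsFactors = FALSE),
            class = c("cf_table", "data.frame"))
}

#' Carbon footprint of one inventory
#'
#' Burdens are summed as quantity x factor over the leaching and recovery
#' item groups; the credit (avoided primary Cu/Zn production) is summed
#' with a positive sign and subtracted at aggregation:
#' net = leaching + recovery - credit.
#'
#' @param inv an [build_inventory()] result (or named list of quantities).
#' @param cf a `cf_table` (see [placeholder_cf_table()]); factor values can
#'   be pre-perturbed for uncertainty propagation.
#' @return list with `net`, `leaching`, `recovery`, `credit` in kg
#'   CO2-equiv.
#' @export
carbon_footprint <- function(inv, cf) {
  lookup <- stats::setNames(cf$cf, cf$item)
  get_cf <- function(item) {
    if (!item %in% names(lookup))
      stop("no characterization factor for inventory item: ", item)
    lookup[[item]]
  }
  comp <- function(items)
    sum(vapply(items, function(it) inv[[it]] * get_cf(it), numeric(1)))
  leaching <- comp(.leaching_items)
  recovery <- comp(.recovery_items)
  credit <- comp(.credit_items)
  list(net = leaching + recovery - credit,
       leaching = leaching, recovery = recovery, credit = credit)
}

#' Monte Carlo carbon-footprint assessment
#'
#' For each cell of a PCB-load x Cu-content grid, draws PCB concentration
#' (% w/v) and Cu content (% w/w) from truncated normal distributions at
#' the cell's mean +/- SD, the Zn content from the powder assay
#' (2.0 +/- 0.5% w/w), perturbs every characterization factor by an
#' independent multiplicative normal with its stated relative uncertainty
#' (truncated at zero), and propagates through [build_inventory()] and
#' [carbon_footprint()]. Shares are computed on absolute component
#' magnitudes, |leaching| + |recovery| + |credit| = 100% per draw.
#'
#' @param n total number of draws (default 8000, split evenly over cells).
#' @param cf a `cf_table`.
#' @param seed integer seed; the full draw table is bit-reproducible.
#' @param cells data.frame defining the grid (columns `pcb_mean`, `pcb_sd`
#'   in % w/v and `cu_mean`, `cu_sd` in % w/w); default the 3 x 3 reference
#'   grid (PCB 5/10/15 +/- 2, Cu 10/20/50 +/- 5).
#' @param zn_mean,zn_sd Zn content of the powder, % w/w.
#' @return an object of class `mc_result`: `draws` (one row per draw with
#'   sampled inputs and footprint components) and `shares` (per-cell mean
#'   and SD of the percentage repartition).
#' @export
monte_carlo <- function(n = 8000, cf = placeholder_cf_table(), seed = 1,
                        cells = NULL, zn_mean = 2.0, zn_sd = 0.5) {
  if (!is.finite(n) || n <= 0) stop("n must be a positive draw count")
  if (is.null(cells))
    cells <- expand.grid(pcb_mean = c(5, 10, 15), cu_mean = c(10, 20, 50))
  if (is.null(cells$pcb_sd)) cells$pcb_sd <- 2
  if (is.null(cells$cu_sd)) cells$cu_sd <- 5
  n <- as.integer(n)
  n_cells <- nrow(cells)
  # exact draw count: spread the remainder over the first cells
  alloc <- rep(n %/% n_cells, n_cells) +
    as.integer(seq_len(n_cells) <= n %% n_cells)
  set.seed(as.integer(seed))

  rtrunc_norm <- function(m, s, lo = 0) {
    x <- stats::rnorm(1, m, s)
    while (x <= lo) x <- stats::rnorm(1, m, s)
    x
  }
  rows <- vector("list", n)
  idx <- 1L
  for (ci in seq_len(nrow(cells))) {
    for (d in seq_len(alloc[ci])) {
      pcb_pct <- rtrunc_norm(cells$pcb_mean[ci], cells$pcb_sd[ci])
      cu_pct <- rtrunc_norm(cells$cu_mean[ci], cells$cu_sd[ci])
      zn_pct <- rtrunc_norm(zn_mean, zn_sd)
      inv <- build_inventory(pcb_g_l = pcb_pct * 10,
                             cu_fraction = cu_pct / 100,
                             zn_fraction = zn_pct / 100)
      pert <- cf
      mult <- stats::rnorm(nrow(cf), 1, cf$rel_uncertainty)
      mult[mult < 0] <- 0
      pert$cf <- cf$cf * mult
      fp <- carbon_footprint(inv, pert)
      tot <- abs(fp$leaching) + abs(fp$recovery) + abs(fp$credit)
      rows[[idx]] <- c(cell = ci, pcb_mean = cells$pcb_mean[ci],
                       cu_mean = cells$cu_mean[ci], pcb_pct = pcb_pct,
                       cu_pct = cu_pct, zn_pct = zn_pct,
                       net = fp$net, leaching = fp$leaching,
                       recovery = fp$recovery, credit = fp$credit,
                       share_leaching = 100 * abs(fp$leaching) / tot,
                       share_recovery = 100 * abs(fp$recovery) / tot,
                       share_credit = 100 * abs(fp$credit) / tot)
      idx <- idx + 1L
    }
  }
  draws <- as.data.frame(do.call(rbind, rows))
  agg <- function(fun) do.call(rbind, lapply(split(draws, draws$cell),
    function(d) data.frame(cell = d$cell[1], pcb_mean = d$pcb_mean[1],
                           cu_mean = d$cu_mean[1],
                           leaching = fun(d$share_leaching),
                           recovery = fun(d$share_recovery),
                           credit = fun(d$share_credit))))
  shares <- agg(mean)
  shares_sd <- agg(stats::sd)
  structure(list(draws = draws, shares = shares, shares_sd = shares_sd,
                 n = nrow(draws), seed = seed),
            class = "mc_result")
}
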