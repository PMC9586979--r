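# One full sweep over the 0-80 psu gradient is shared by several blocks.
sweep <- salinity_sweep(seq(0, 80, by = 10))
cfg0 <- bettina_config(salinity = 0)

test_that("configuration and tree state validate their invariants", {
  expect_error(bettina_config(salinity = 95), class = "mangroflux_invalid_input")
  expect_error(bettina_config(psi_leaf = 1e6), class = "mangroflux_invalid_input")
  expect_error(bettina_config(timestep = 0), class = "mangroflux_invalid_input")
  expect_error(bettina_tree(r_stem = 0), class = "mangroflux_invalid_state")
  expect_error(bettina_tree(h_stem = -1), class = "mangroflux_invalid_state")
  expect_equal(bettina_tree(r_stem = 0.15)$r_stem * 200, 30) # dbh in cm
})

test_that("water uptake follows the potential gradient and resistance network", {
  cfg <- bettina_config(salinity = 35)
  tree <- bettina_tree(r_stem = 0.1, h_stem = 10, r_crown = 3, r_root = 2)

  # hand evaluation of the resistance formula
  psi_soil <- -cfg$osmotic_coeff * 35
  gradient <- psi_soil - cfg$psi_leaf - 9810 * 10
  r_ag <- cfg$ag_resistivity * (10 + 3 + 2) / 0.1^2 + cfg$leaf_resistance
  r_bg <- cfg$bg_resistivity / 2^2
  expect_equal(water_uptake(tree, cfg),
    gradient / (r_ag + r_bg) * 1000 * 86400)

  # doubling stem radius cuts the geometric above-ground term 4-fold
  tree2 <- tree; tree2$r_stem <- 0.2
  r_ag2 <- cfg$ag_resistivity * (10 + 3 + 2) / 0.2^2 + cfg$leaf_resistance
  expect_equal(r_ag2 - cfg$leaf_resistance, (r_ag - cfg$leaf_resistance) / 4)
  expect_equal(water_uptake(tree2, cfg),
    gradient / (r_ag2 + r_bg) * 1000 * 86400)

  # salinity monotonicity at fixed geometry, and the zero-gradient cutoff
  expect_lt(water_uptake(tree, cfg, salinity = 35),
    water_uptake(tree, cfg, salinity = 0))
  cutoff <- (-cfg$psi_leaf - 9810 * 10) / cfg$osmotic_coeff
  expect_equal(water_uptake(tree, cfg, salinity = cutoff + 1), 0)

  expect_error(water_uptake(bettina_tree(), "not a config"))
})

test_that("potential transpiration is uptake at zero salinity", {
  cfg <- bettina_config(salinity = 25)
  tree <- bettina_tree(r_stem = 0.1, h_stem = 8, r_crown = 2, r_root = 2)
  expect_equal(potential_transpiration(tree, cfg),
    water_uptake(tree, cfg, salinity = 0))
  expect_gt(potential_transpiration(tree, cfg), water_uptake(tree, cfg))
  cfg0_ <- bettina_config(salinity = 0)
  expect_equal(potential_transpiration(tree, cfg0_), water_uptake(tree, cfg0_))
})

test_that("one growth step matches a hand recomputation of the allocation", {
  cfg <- bettina_config(salinity = 20, timestep = 0.5)
  tree <- bettina_tree(r_stem = 0.05, h_stem = 5, r_crown = 1.5, r_root = 1)

  uptake_m3_yr <- water_uptake(tree, cfg) / (1000 * 86400) * 31557600
  e_w <- cfg$water_efficiency * uptake_m3_yr
  e_l <- cfg$light_efficiency * pi * 1.5^2
  gain <- min(e_w, e_l)
  maint <- cfg$maintenance_coeff * tree_biomass(tree, cfg)
  allocated <- max(gain - maint, 0) * 0.5
  frac_w <- e_w / (e_w + e_l)
  w <- c(h = frac_w / 2, crown = frac_w / 2, stem = (1 - frac_w) / 2,
    root = (1 - frac_w) / 2)
  h_max <- cfg$height_headroom * (-cfg$osmotic_coeff * 20 - cfg$psi_leaf) / 9810
  taper <- max(0, 1 - (5 / h_max)^4)
  w[["stem"]] <- w[["stem"]] + w[["h"]] * (1 - taper)
  w[["h"]] <- w[["h"]] * taper
  dv <- allocated / cfg$wood_density
  h_new <- 5 + w[["h"]] * dv / (pi * 0.05^2)
  r_stem_new <- sqrt((pi * 0.05^2 * h_new + w[["stem"]] * dv) / (pi * h_new))
  r_crown_new <- sqrt((cfg$crown_thickness * pi * 1.5^2 + w[["crown"]] * dv) /
    (cfg$crown_thickness * pi))
  r_root_new <- ((cfg$root_packing * (2 / 3) * pi * 1^3 + w[["root"]] * dv) /
    (cfg$root_packing * (2 / 3) * pi))^(1 / 3)

  stepped <- grow_step(tree, cfg)
  expect_equal(stepped$h_stem, h_new, tolerance = 1e-12)
  expect_equal(stepped$r_stem, r_stem_new, tolerance = 1e-12)
  expect_equal(stepped$r_crown, r_crown_new, tolerance = 1e-12)
  expect_equal(stepped$r_root, r_root_new, tolerance = 1e-12)
  expect_equal(stepped$age, tree$age + 0.5)
})

test_that("a zero increment leaves the geometry unchanged", {
  # heavy maintenance guarantees gain < cost
  cfg <- bettina_config(salinity = 80, maintenance_coeff = 50)
  tree <- bettina_tree(r_stem = 0.1, h_stem = 5, r_crown = 1, r_root = 1)
  stepped <- grow_step(tree, cfg)
  expect_equal(stepped$r_stem, tree$r_stem)
  expect_equal(stepped$h_stem, tree$h_stem)
  expect_equal(stepped$r_crown, tree$r_crown)
  expect_equal(stepped$r_root, tree$r_root)
})

test_that("water-limited trees weight roots and girth over height and crown", {
  cfg <- bettina_config(salinity = 75)
  tree <- bettina_tree(r_stem = 0.05, h_stem = 3, r_crown = 2, r_root = 0.5)
  before <- tree_biomass(tree, cfg)
  stepped <- grow_step(tree, cfg)
  # relative investment: root and stem girth grew, crown barely
  d_root <- stepped$r_root - tree$r_root
  d_crown <- stepped$r_crown - tree$r_crown
  expect_gt(d_root, d_crown)
  expect_gt(tree_biomass(stepped, cfg), before)
})

test_that("simulations are deterministic and year-0 returns the initial state", {
  cfg <- bettina_config(salinity = 30, years = 5)
  t1 <- bettina_simulate(cfg)
  t2 <- bettina_simulate(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  t0 <- bettina_simulate(bettina_config(salinity = 30, years = 0))
  expect_equal(nrow(t0), 1)
  expect_equal(t0$age, 0)
})

test_that("trajectories are monotone in age and geometry with exact mass balance", {
  traj <- bettina_simulate(bettina_config(salinity = 40, years = 50))
  expect_true(all(diff(traj$age) > 0))
  for (colm in c("r_stem", "h_stem", "r_crown", "r_root", "biomass_kg")) {
    expect_true(all(diff(traj[[colm]]) >= -1e-12), label = colm)
  }
  # cumulative allocated biomass equals the biomass the tree actually added
  expect_equal(sum(traj$allocated_kg),
    traj$biomass_kg[nrow(traj)] - traj$biomass_kg[1],
    tolerance = 1e-6)
  # and allocation equals gain minus maintenance whenever growth is positive
  pos <- traj$allocated_kg > 0
  expect_equal(traj$allocated_kg[pos],
    (traj$gain_kg - traj$maintenance_kg)[pos], tolerance = 1e-9)
})

test_that("final water use decreases strictly with salinity over 0-80 psu", {
  expect_true(all(diff(sweep$uptake_l_day) < 0))
  # soft calibration band around the reported one-fifth at double seawater
  ratio_70 <- sweep$uptake_l_day[sweep$salinity_psu == 70] /
    sweep$uptake_l_day[sweep$salinity_psu == 0]
  expect_gt(ratio_70, 0.10)
  expect_lt(ratio_70, 0.40)
})

test_that("trees become shorter but proportionally thicker as salinity rises", {
  expect_true(all(diff(sweep$h_stem) < 0))
  slenderness <- (sweep$dbh_cm / 200) / sweep$h_stem
  expect_true(all(diff(slenderness) > 0))
})

test_that("the actual-to-potential transpiration ratio is 1 at zero salinity and declines", {
  expect_equal(sweep$uptake_ratio[sweep$salinity_psu == 0], 1)
  expect_true(all(sweep$uptake_ratio > 0 & sweep$uptake_ratio <= 1))
  expect_true(all(diff(sweep$uptake_ratio) <= 0))
})

test_that("growth is near-asymptotic by year 200", {
  for (s in c(0, 40, 80)) {
    cfg <- bettina_config(salinity = s)
    traj <- bettina_simulate(cfg)
    last_decade <- traj[traj$age >= 190, ]
    rel_growth <- (last_decade$biomass_kg[nrow(last_decade)] -
      last_decade$biomass_kg[1]) / last_decade$biomass_kg[1]
    expect_lt(rel_growth, 0.01)
  }
})

test_that("halving the timestep changes 200-yr outputs by less than 1%", {
  f1 <- final_tree(bettina_simulate(bettina_config(salinity = 40, timestep = 0.5)))
  f2 <- final_tree(bettina_simulate(bettina_config(salinity = 40, timestep = 0.25)))
  cfg <- bettina_config(salinity = 40)
  expect_lt(abs(water_uptake(f1, cfg) - water_uptake(f2, cfg)) /
    water_uptake(f2, cfg), 0.01)
  expect_lt(abs(f1$h_stem - f2$h_stem) / f2$h_stem, 0.01)
})

test_that("adapted allometry beats the frozen 40-psu allometry only below 40 psu", {
  fixed <- fixed_allometry_uptake(40, sweep$salinity_psu)
  cmp <- dplyr::left_join(as_tibble(sweep), fixed, by = "salinity_psu")
  below <- cmp$salinity_psu < 40
  above <- cmp$salinity_psu > 40
  at <- cmp$salinity_psu == 40
  expect_true(all(cmp$uptake_l_day[below] >= cmp$uptake_fixed_l_day[below]))
  expect_true(all(cmp$uptake_l_day[above] <= cmp$uptake_fixed_l_day[above]))
  # at the reference the two coincide by construction
  expect_equal(cmp$uptake_l_day[at], cmp$uptake_fixed_l_day[at],
    tolerance = 1e-9)
})

test_that("trajectory and sweep plots render", {
  traj <- bettina_simulate(bettina_config(salinity = 40, years = 10))
  expect_s3_class(autoplot(traj), "ggplot")
  expect_s3_class(autoplot(sweep), "ggplot")
})
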