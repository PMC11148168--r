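test_that("diffusion ceiling and depth limit match the analytic flux law", {
  # 2.43 mm column at 181 uM delivers ~200 fmol/mm^2/s
  expect_equal(max_ocr(medium_column(2.43)), 200, tolerance = 0.01)
  # a 5 mm column caps OCR near 97 fmol/mm^2/s
  expect_equal(max_ocr(medium_column(5)), 2.69e-3 * 181 * 1000 / 5)
  # no gradient, no flux
  expect_lt(max_ocr(medium_column(2.43, c_interface = 1e-9)), 1e-3)
  # inverse relation
  expect_equal(max_depth(200), 2.43, tolerance = 0.005)
  expect_equal(max_depth(100), 2 * max_depth(200))
  expect_error(max_depth(0), "zero demand")
  expect_error(medium_column(0), "positive")
})

test_that("max_ocr and max_depth are exact inverses", {
  for (J in c(13, 100, 200, 400)) {
    col <- medium_column(max_depth(J))
    expect_equal(max_ocr(col), J, tolerance = 1e-9)
  }
  # strict monotonicity in depth
  depths <- seq(0.5, 6, by = 0.5)
  fluxes <- vapply(depths, function(x) max_ocr(medium_column(x)), numeric(1))
  expect_true(all(diff(fluxes) < 0))
})

test_that("pericellular oxygen solution covers all regimes", {
  # demand exactly at capacity with no critical cutoff: pericellular ~ 0
  col <- medium_column(2.43)
  sol <- solve_pericellular(col, monolayer_demand(max_ocr(col), critical_o2 = 0))
  expect_equal(sol$c_pericellular, 0, tolerance = 1e-9)
  expect_false(sol$limited)

  # shallow column: demand met with oxygen to spare
  sol2 <- solve_pericellular(medium_column(1.03), monolayer_demand(200, 4))
  expect_equal(sol2$realised_ocr, 200)
  expect_equal(sol2$c_pericellular, 181 - 200 * 1.03 / 2.69, tolerance = 1e-9)
  expect_false(sol2$limited)

  # no consumption: flat profile at the interface concentration
  sol3 <- solve_pericellular(col, monolayer_demand(0))
  expect_equal(sol3$c_pericellular, col$c_interface)

  # limited regime: respiration pinned at capacity, monolayer at critical O2
  sol4 <- solve_pericellular(medium_column(5), monolayer_demand(200, 4))
  expect_true(sol4$limited)
  expect_equal(sol4$c_pericellular, 4)
  expect_equal(sol4$realised_ocr, 2.69e-3 * (181 - 4) * 1000 / 5)
  expect_lt(sol4$realised_ocr, 200)

  # interface below the respiration threshold: nothing respires, no error
  sol5 <- solve_pericellular(medium_column(2, c_interface = 3),
                             monolayer_demand(200, 4))
  expect_equal(sol5$realised_ocr, 0)
  expect_true(sol5$limited)
})

test_that("solution invariants hold across random parameter sets", {
  set.seed(42)
  for (i in 1:50) {
    col <- medium_column(runif(1, 0.3, 8), runif(1, 1e-3, 4e-3),
                         runif(1, 20, 250))
    dem <- monolayer_demand(runif(1, 0, 500), runif(1, 0, 10))
    sol <- solve_pericellular(col, dem)
    expect_lte(sol$realised_ocr, dem$ocr_demand + 1e-12)
    expect_gte(sol$c_pericellular, 0)
    expect_lte(sol$c_pericellular, col$c_interface + 1e-12)
    expect_identical(sol$limited, sol$realised_ocr < dem$ocr_demand - 1e-12)
  }
})

test_that("concentration profile is affine with slope OCR/D", {
  col <- medium_column(3.125)
  sol <- solve_pericellular(col, monolayer_demand(120, 4))
  h <- seq(0, col$depth_x, length.out = 7)
  prof <- profile_at_height(sol, col, h)
  slopes <- diff(prof) / diff(h)
  expect_equal(slopes, rep(sol$realised_ocr / (col$diffusion_D * 1000),
                           length(slopes)))
  # boundary identities
  expect_equal(prof[1], sol$c_pericellular)
  expect_equal(prof[length(prof)], col$c_interface)  # unlimited: full span
  expect_error(profile_at_height(sol, col, 5), "within")
})

test_that("limited-regime sensor-window prediction matches plug-in arithmetic", {
  # 100 uL flat fill in a 96-well: 3.125 mm column, demand 200, critical 4
  col <- medium_column(3.125)
  sol <- solve_pericellular(col, monolayer_demand(200, 4))
  expect_true(sol$limited)
  capacity <- 2.69e-3 * (181 - 4) * 1000 / 3.125
  expect_equal(profile_at_height(sol, col, 0.55),
               4 + capacity * 0.55 / 2.69, tolerance = 1e-9)
  expect_equal(profile_at_height(sol, col, 0.55), 35.2, tolerance = 0.002)
})

test_that("finite-difference steady-state solver reproduces the analytic model", {
  set.seed(7)
  for (i in 1:10) {
    depth <- runif(1, 0.5, 6)
    D <- runif(1, 1.5e-3, 3.5e-3)
    cint <- runif(1, 50, 220)
    demand <- runif(1, 10, 400)
    crit <- runif(1, 0, 8)
    col <- medium_column(depth, D, cint)
    sol <- solve_pericellular(col, monolayer_demand(demand, crit))
    ora <- fd_oxygen_oracle(depth, D, cint, demand, crit)
    expect_equal(sol$realised_ocr, ora$realised_ocr,
                 tolerance = 1e-3)
    expect_equal(sol$c_pericellular, ora$profile[1],
                 tolerance = 1e-3 * max(1, ora$profile[1]))
    mid <- profile_at_height(sol, col, ora$z[201])
    expect_equal(mid, ora$profile[201], tolerance = 1e-3 * max(1, mid))
  }
})

test_that("Henry conversions reproduce the calibrated pressure pairs", {
  expect_equal(mmhg_to_um(140), 181)
  expect_equal(round_mmhg(um_to_mmhg(38)), 29)
  expect_equal(round_mmhg(um_to_mmhg(73)), 56)
  expect_equal(mmhg_to_um(0), 0)
  expect_equal(um_to_mmhg(mmhg_to_um(57)), 57)
  expect_error(mmhg_to_um(-1), ">= 0")
  expect_error(um_to_mmhg(-1), ">= 0")
  # half-away-from-zero integer reporting
  expect_equal(round_mmhg(c(10.5, 11.4, -10.5)), c(11, 11, -11))
})

test_that("oxygen report wires plate geometry into the column model", {
  rep <- oxygen_report(medium_spec(1000, "12-well"), ocr_demand = 200)
  # minimum-depth capacity just above demand net of critical O2 handling,
  # nominal-depth capacity below demand -> limited at nominal depth
  expect_equal(rep$minimum$depth_mm, 2.40, tolerance = 0.005)
  expect_equal(rep$nominal$depth_mm, 1000 / 380)
  expect_equal(rep$nominal$capacity_fmol_mm2_s,
               2.69e-3 * 181 * 1000 / (1000 / 380))
  expect_true(rep$nominal$limited)
  expect_true(all(rep$minimum$profile$o2_um >= 0))
})
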