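test_that("solute activities follow the Norrish form and its limits", {
  # pure water: exponent term is 10^0
  expect_equal(solute_activity("glucose", 1), 1)
  expect_equal(solute_activity("sucrose", 0), 0)
  # frozen: 0.5 * 10^(-0.858 * 0.25), independent calculator
  expect_equal(solute_activity("glucose", 0.5), 0.30511952832233163,
               tolerance = 1e-12)
  expect_error(solute_activity("maltose", 0.5))
  expect_error(solute_activity("glucose", 1.2), "mole fraction")
})

test_that("water mole fraction is the hyperbolic dilution formula", {
  expect_equal(water_mole_fraction(0, 0.5, 0.08326), 0)
  # frozen: 0.1 / (0.1 + 0.08326)
  expect_equal(water_mole_fraction(0.1, 1, 0.08326), 0.5456728145803776,
               tolerance = 1e-12)
  expect_gt(water_mole_fraction(1e6, 1, 0.08326), 1 - 1e-6)  # dilution limit
  xs <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), water_mole_fraction,
               numeric(1), w_solute = 0.4, mole_coeff = 0.08764)
  expect_true(all(diff(xs) > 0))
  expect_error(water_mole_fraction(0, 0, 0.08326), "degenerate")
})

test_that("vacuole activity is the Ross product with absent-solute convention", {
  comp <- composition(sugar = 0.3, ash = 0.1, starch = 0.6)
  expect_equal(vacuole_aw(0, comp), 0)   # every mole fraction is 0
  # only ash present: product reduces to the ash activity alone
  ash_only <- suppressWarnings(composition(ash = 0.2, starch = 0.8))
  x_v <- 0.25
  x <- water_mole_fraction(x_v, 1, 0.16981)
  expect_equal(vacuole_aw(x_v, ash_only), solute_activity("ash", x))
  # Ross product cannot exceed any single factor
  w <- c(glucose = 0.5 * 0.3, sucrose = 0.5 * 0.3, ash = 0.1) / 0.4
  singles <- c(
    solute_activity("glucose", water_mole_fraction(x_v, w[["glucose"]], 0.08326)),
    solute_activity("sucrose", water_mole_fraction(x_v, w[["sucrose"]], 0.08764)),
    solute_activity("ash", water_mole_fraction(x_v, w[["ash"]], 0.16981)))
  expect_lte(vacuole_aw(x_v, comp), min(singles))
  # strictly increasing towards 1
  aw <- vapply(c(0.05, 0.1, 0.3, 0.6, 1, 3, 10), vacuole_aw, numeric(1),
               comp = comp)
  expect_true(all(diff(aw) > 0))
  expect_gt(vacuole_aw(100, comp), 0.99)
  no_vac <- suppressWarnings(composition(starch = 0.9, protein = 0.1))
  expect_error(vacuole_aw(0.2, no_vac), "degenerate")
  expect_error(vacuole_moisture(0.5, no_vac), "degenerate")
})

test_that("vacuole inversion round-trips and is monotone", {
  comp <- composition(sugar = 0.4923, ash = 0.077, fiber = 0.13384,
                      starch = 0.07692, protein = 0.1892, oil = 0.0311)
  set.seed(31)
  for (a in runif(20, 0.05, 0.95)) {
    x_v <- vacuole_moisture(a, comp)
    expect_equal(vacuole_aw(x_v, comp), a, tolerance = 1e-8)
  }
  expect_lt(vacuole_moisture(0.3, comp), vacuole_moisture(0.6, comp))
  # zero-water limit: x_v ~ a_w^(1/3) near zero (three-factor Ross product)
  expect_lt(vacuole_moisture(1e-6, comp), vacuole_moisture(1e-3, comp))
  expect_lt(vacuole_moisture(1e-6, comp), 5e-3)
  expect_error(vacuole_moisture(1, comp), "\\(0, 1\\)")
  expect_error(vacuole_moisture(0, comp), "\\(0, 1\\)")
})

test_that("fiber equation matches its frozen values under both sign readings", {
  # frozen: y(0.05) and a_w at x_f = 0.05, independent calculator
  expect_equal(fiber_aw(0.05, "pos"), 0.11775252548853947, tolerance = 1e-10)
  expect_equal(fiber_aw(0.05, "neg"), 0.06068259436512226, tolerance = 1e-10)
  # asymptote: saturated fiber approaches a_w = 1
  expect_gt(fiber_aw(10, "pos"), 0.95)
  expect_gt(fiber_aw(10, "neg"), 0.95)
  expect_error(fiber_aw(0), "> 0")
  expect_error(fiber_aw(-0.1), "> 0")
})

test_that("fiber forward map is monotone and invertible on (0, 1)", {
  xs <- seq(0.01, 1, by = 0.01)
  aw_pos <- fiber_aw(xs, "pos")
  pre_clamp <- aw_pos < 1
  expect_true(all(diff(aw_pos[pre_clamp]) > 0))  # strict before saturation
  expect_true(all(diff(aw_pos) >= 0))
  aw_neg <- fiber_aw(xs, "neg")
  expect_true(all(diff(aw_neg) > 0))
  set.seed(32)
  for (a in runif(20, 0.05, 0.95)) {
    expect_equal(fiber_aw(fiber_moisture(a, "pos"), "pos"), a,
                 tolerance = 1e-8)
    expect_equal(fiber_aw(fiber_moisture(a, "neg"), "neg"), a,
                 tolerance = 1e-8)
  }
  expect_lt(fiber_moisture(0.01), 0.01)  # near-zero limit
  expect_lt(fiber_moisture(0.4), fiber_moisture(0.7))
})

test_that("starch and protein sub-isotherms match their printed constants", {
  expect_equal(starch_moisture(0), 0)
  expect_equal(starch_moisture(1 - exp(-1)), 18.19182)  # bracket term = 1
  # frozen: 18.19182 * 0.693147^0.41181, independent calculator
  expect_equal(starch_moisture(0.5), 15.64323189504876, tolerance = 1e-10)
  expect_error(starch_moisture(1))
  expect_equal(protein_moisture(exp(-1)), 0.090614)     # (-ln a_w) = 1
  # frozen: near-zero limit value, independent calculator
  expect_equal(protein_moisture(1e-6), 0.017789666224385887,
               tolerance = 1e-10)
  expect_error(protein_moisture(0))
  expect_error(protein_moisture(1))
  g <- seq(0.02, 0.98, by = 0.02)
  expect_true(all(diff(starch_moisture(g)) > 0))
  expect_true(all(diff(protein_moisture(g)) > 0))
})

test_that("predicted isotherm is the normalized weight combination", {
  # a pure-starch material reduces to the starch sub-isotherm
  pure_starch <- composition(starch = 1)
  cv <- predict_isotherm(pure_starch, c(0.3, 1 - exp(-1), 0.8))
  expect_equal(cv$h_total[2], 18.19182)
  expect_equal(cv$h_total, cv$h_starch)
  expect_true(all(cv$h_vacuole == 0) && all(cv$h_fiber == 0) &&
                all(cv$h_protein == 0))
  # every sub-isotherm and the total are strictly increasing in a_w
  comp <- mixed_composition()
  curve <- predict_isotherm(comp, seq(0.02, 0.95, length.out = 50))
  for (col in c("h_vacuole", "h_fiber", "h_starch", "h_protein", "h_total"))
    expect_true(all(diff(curve[[col]]) > 0), label = paste(col, "monotone"))
  # zero-water limit: total vanishes with a_w (power-law tails are slow,
  # so the corner is probed at very small a_w)
  low <- predict_isotherm(comp, c(1e-6, 1e-4, 1e-2))
  expect_true(all(diff(low$h_total) > 0))
  expect_lt(low$h_total[1], 0.05 * predict_isotherm(comp, 0.5)$h_total)
})

test_that("oil is inert: changing w_oil leaves the prediction unchanged", {
  grid <- seq(0.1, 0.9, by = 0.1)
  c0 <- mixed_composition(oil = 0)
  c1 <- mixed_composition(oil = 0.05)
  expect_equal(predict_isotherm(c1, grid)$h_total,
               predict_isotherm(c0, grid)$h_total, tolerance = 1e-12)
})

test_that("composition and grid preconditions are enforced", {
  expect_error(composition(sugar = -0.1), "\\[0, 1\\]")
  expect_error(composition(sugar = 0.8, starch = 0.8), "sum")
  expect_error(composition(sugar = 0.5, glucose_share = 1.5),
               "glucose_share")
  expect_warning(composition(sugar = 0.1, ash = 0.02, fiber = 0.2),
                 "renormalizes")
  oil_only <- suppressWarnings(composition(oil = 0.9))
  expect_error(predict_isotherm(oil_only, 0.5), "degenerate")
  comp <- mixed_composition()
  expect_error(predict_isotherm(comp, c(0.5, 0.3)), "increasing")
  expect_error(predict_isotherm(comp, c(0.2, 1)), "\\(0, 1\\)")
})
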