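test_that("area per molecule converts trough area and spread amount", {
  # hand evaluation: 500 cm^2 = 5e18 A^2 over 6.02214076e15 molecules
  expect_equal(area_per_molecule(500, 1e-8), 5e18 / (1e-8 * N_AV),
               tolerance = 1e-12)
  expect_equal(area_per_molecule(500, 1e-8), 830.27, tolerance = 1e-4) # frozen
  # doubling the spread amount halves the area exactly
  expect_equal(area_per_molecule(500, 2e-8), area_per_molecule(500, 1e-8) / 2)
  # round trip through the inverse
  amt <- 300 * 1e16 / (100 * N_AV)
  expect_equal(area_per_molecule(300, amt), 100, tolerance = 1e-12)
  expect_error(area_per_molecule(0, 1e-8), class = "memmech_invalid_input")
})

test_that("isotherm construction normalizes compression order", {
  iso <- compression_isotherm(seq(60, 200, length.out = 20),
                              seq(40, 0, length.out = 20))
  expect_true(all(diff(iso$area) < 0))
  expect_error(compression_isotherm(1:20, rep(-1, 20)),
               class = "memmech_invalid_input")
  expect_error(compression_isotherm(1:5, rep(1, 5)),
               class = "memmech_invalid_input")
})

test_that("compressibility matches closed forms on analytic isotherms", {
  areas <- seq(300, 60, length.out = 200)
  # ideal-gas-like isotherm pi = c/A has C^-1 = pi exactly
  iso <- compression_isotherm(areas, 400 / areas)
  prof <- compressibility_profile(iso, 11)
  inner <- 7:193
  expect_lt(max(abs(prof$modulus[inner] - prof$pressure[inner]) /
                  prof$pressure[inner]), 0.02)
  # linear segment pi = a - b A has C^-1 = b A (quadratic window is exact)
  iso2 <- compression_isotherm(areas, 62 - 0.2 * areas)
  prof2 <- compressibility_profile(iso2, 11)
  expect_lt(max(abs(prof2$modulus - 0.2 * prof2$area) / (0.2 * prof2$area)),
            0.01)
})

test_that("window validation rejects even or out-of-range windows", {
  iso <- compression_isotherm(seq(200, 60, length.out = 40),
                              seq(0, 40, length.out = 40))
  expect_error(compressibility_profile(iso, 8), class = "memmech_invalid_input")
  expect_error(compressibility_profile(iso, 3), class = "memmech_invalid_input")
  expect_error(compressibility_profile(iso, 21), class = "memmech_invalid_input")
})

test_that("numerical modulus tracks the symbolic oracle of the generator", {
  sim <- gen_isotherm() # OMM-like, noiseless
  prof <- compressibility_profile(sim$data, 11)
  truth <- sim$cinv_fun(prof$area)
  n <- nrow(prof)
  sel <- truth > 0.05 * max(truth)
  sel[c(1:5, (n - 4):n)] <- FALSE # half-window edges
  expect_lt(max(abs(prof$modulus[sel] - truth[sel]) / truth[sel]), 0.02)
  # with pressure noise at the tensiometer precision the agreement is
  # looser; the derivative window is widened to ~5% of the samples, since
  # the variance of a local-polynomial derivative grows as the spacing
  # shrinks at fixed window length
  simn <- gen_isotherm(noise_sd = 0.2, seed = 4)
  profn <- compressibility_profile(simn$data, 41)
  truthn <- sim$cinv_fun(profn$area)
  seln <- truthn > 0.25 * max(truthn)
  seln[c(1:5, (n - 4):n)] <- FALSE
  expect_lt(stats::median(abs(profn$modulus[seln] - truthn[seln]) /
                            truthn[seln]), 0.10)
})

test_that("modulus profiles are invariant to a uniform pressure offset", {
  sim <- gen_isotherm()
  shifted <- compression_isotherm(sim$data$area, sim$data$pressure + 5)
  p1 <- compressibility_profile(sim$data, 11)
  p2 <- compressibility_profile(shifted, 11)
  expect_equal(p1$modulus, p2$modulus, tolerance = 1e-12)
})

test_that("windows 7 and 11 agree on noiseless analytic curves", {
  sim <- gen_isotherm()
  p7 <- compressibility_profile(sim$data, 7)
  p11 <- compressibility_profile(sim$data, 11)
  n <- nrow(p11)
  sel <- p11$modulus > 0.1 * max(p11$modulus)
  sel[c(1:6, (n - 5):n)] <- FALSE
  expect_lt(max(abs(p7$modulus[sel] - p11$modulus[sel]) /
                  abs(p11$modulus[sel])), 0.03)
})

test_that("the modulus maximum is recovered with its pressure", {
  sim <- gen_isotherm(lift_off = 140, cinv_max = 80, pi_at_max = 32,
                      pi_c = 40) # IMM-like
  prof <- compressibility_profile(sim$data, 11)
  mx <- max_compressibility(prof, c(0, 45))
  expect_equal(mx$cinv_max, 80, tolerance = 0.05)
  expect_lt(abs(mx$pi_at_max - 32), 2)
  expect_false(mx$boundary)
  # a monotone profile flags its endpoint maximum as a boundary
  areas <- seq(200, 100, length.out = 30)
  mono <- compressibility_profile(
    compression_isotherm(areas, 50 - 0.2 * areas), 11)
  expect_true(max_compressibility(mono)$boundary)
  expect_error(max_compressibility(prof, c(100, 200)),
               class = "memmech_invalid_input")
})

test_that("lift-off area is interpolated at the threshold crossing", {
  sim <- gen_isotherm(lift_off = 140, cinv_max = 80, pi_at_max = 32,
                      pi_c = 40)
  expect_lt(abs(lift_off_area(sim$data) - 140), 2)
  expect_gte(lift_off_area(sim$data), min(sim$data$area))
  # threshold 0 with all-positive pressures: never below, hence not found
  areas <- seq(200, 100, length.out = 20)
  iso <- compression_isotherm(areas, seq(1, 30, length.out = 20))
  expect_error(lift_off_area(iso, threshold = 0), class = "memmech_not_found")
  # an exact-sample crossing returns that sample's area
  iso2 <- compression_isotherm(seq(200, 105, by = -5),
                               c(0, 0, 0, 0.5, 1:16))
  expect_equal(lift_off_area(iso2), 185)
})

test_that("collapse onset is located on the pressure plateau", {
  sim <- gen_isotherm(lift_off = 140, cinv_max = 80, pi_at_max = 32,
                      pi_c = 40)
  cp <- collapse_point(sim$data)
  expect_lt(abs(cp$pi_c - 40), 1)
  expect_lte(cp$pi_c, max(sim$data$pressure))
  # an isotherm truncated before collapse reports not-found
  keep <- sim$data$pressure < 30
  early <- compression_isotherm(sim$data$area[keep], sim$data$pressure[keep])
  expect_error(collapse_point(early), class = "memmech_not_found")
})
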