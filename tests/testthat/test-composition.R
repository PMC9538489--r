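omm_intensities <- c(PC = 35.0, PE = 41.0, CL = 1.0, SM = 6.3, Chol = 16.7)
imm_intensities <- c(PC = 27.4, PE = 34.4, CL = 21.0, SM = 1.6, PI = 2.2,
                     PS = 2.4, Chol = 10.3, LPC = 0.7)

test_that("percentages are intensities over their sum", {
  tab <- densitometry_table(names(omm_intensities), omm_intensities)
  comp <- percent_composition(tab)
  # intensities already proportional to percentages
  expect_equal(comp$percent, unname(omm_intensities), tolerance = 1e-12)
  expect_equal(sum(comp$percent), 100, tolerance = 1e-6)
  # scale invariance
  comp2 <- percent_composition(
    densitometry_table(names(omm_intensities), omm_intensities * 37.2))
  expect_equal(comp2$percent, comp$percent, tolerance = 1e-12)
  # single entry is 100%
  expect_equal(percent_composition(densitometry_table("PC", 3))$percent, 100)
  expect_error(densitometry_table(c("a", "b"), c(0, 0)),
               class = "memmech_invalid_input")
})

test_that("excluding cholesterol reproduces the phospholipid basis", {
  omm <- percent_composition(
    densitometry_table(names(omm_intensities), omm_intensities))
  ex <- renormalize_excluding(omm, "Chol")
  pct <- setNames(ex$percent, ex$lipid)
  expect_equal(round(pct[["PC"]], 1), 42.0)
  expect_equal(round(pct[["PE"]], 1), 49.2)
  expect_equal(round(pct[["CL"]], 1), 1.2)
  expect_equal(round(pct[["SM"]], 1), 7.6)
  imm <- percent_composition(
    densitometry_table(names(imm_intensities), imm_intensities))
  exi <- renormalize_excluding(imm, "Chol")
  pcti <- setNames(exi$percent, exi$lipid)
  expect_equal(round(pcti[["PC"]], 1), 30.5)
  expect_equal(round(pcti[["CL"]], 1), 23.4)
  expect_equal(sum(exi$percent), 100, tolerance = 1e-6)
  expect_identical(attr(exi, "excluded"), "Chol")
})

test_that("exclusion equals deletion before normalization", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    labels <- paste0("L", 1:k)
    intens <- runif(k, 0.1, 50)
    full <- percent_composition(densitometry_table(labels, intens))
    drop_lab <- sample(labels, 1)
    ex <- renormalize_excluding(full, drop_lab)
    direct <- percent_composition(
      densitometry_table(labels[labels != drop_lab],
                         intens[labels != drop_lab]))
    expect_equal(ex$percent, direct$percent, tolerance = 1e-12)
  }
  # excluding a zero-intensity component changes nothing
  full <- percent_composition(densitometry_table(c("a", "b", "c"),
                                                 c(30, 70, 0)))
  ex <- renormalize_excluding(full, "c")
  expect_equal(ex$percent, full$percent[1:2], tolerance = 1e-12)
  only <- percent_composition(densitometry_table("a", 5))
  expect_error(renormalize_excluding(only, "a"),
               class = "memmech_invalid_input")
})

test_that("replicate lanes summarize to mean and SEM", {
  lanes <- lapply(1:3, function(i) {
    sim <- gen_densitometry(noise_frac = 0.05, seed = 40 + i)
    percent_composition(sim$data)
  })
  sm <- summarize_lanes(lanes)
  expect_equal(sum(sm$mean_percent), 100, tolerance = 1e-9)
  expect_true(all(sm$sem >= 0))
  expect_error(summarize_lanes(lanes[1]), class = "memmech_invalid_input")
})

test_that("phosphorus standards calibrate a linear quantification", {
  amounts <- seq(0, 0.228, length.out = 6)
  cal <- suppressWarnings(fit_phosphorus_curve(amounts, 0.1 + 2 * amounts))
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(quantify_phosphorus(0.556, cal), 0.228, tolerance = 1e-12)
  expect_equal(quantify_phosphorus(0.1, cal), 0) # absorbance == intercept
  # round trip at every standard
  for (a in amounts) {
    expect_equal(quantify_phosphorus(0.1 + 2 * a, cal), a, tolerance = 1e-9)
  }
  # dilution factor is multiplicative
  expect_equal(quantify_phosphorus(0.3, cal, dilution_factor = 10),
               10 * quantify_phosphorus(0.3, cal))
  expect_error(quantify_phosphorus(2.0, cal), class = "memmech_out_of_range")
  expect_error(fit_phosphorus_curve(c(0, 0.1), c(0.1, 0.3)),
               class = "memmech_invalid_input")
})

test_that("GUV populations reduce z-stacks to per-vesicle maxima", {
  meas <- data.frame(vesicle_id = rep(1:12, each = 3),
                     diameter = as.vector(vapply(1:12, function(i) {
                       sort(runif(3, 5, 30))
                     }, numeric(3))))
  pop <- guv_population(meas)
  brute <- vapply(split(meas$diameter, meas$vesicle_id), max, numeric(1))
  expect_equal(sort(pop$diameters), sort(unname(brute)))
  sd_ <- size_distribution(pop, bin_width = 5)
  expect_equal(sum(sd_$counts), 12)
})

test_that("size summaries match the generating distribution", {
  sim <- gen_guv(n = 300, seed = 21)
  sd_ <- size_distribution(sim$data, bin_width = 5)
  expect_lt(abs(sd_$median - sim$truth$median) / sim$truth$median, 0.05)
  # degenerate: all identical diameters occupy a single bin
  pop <- guv_population(rep(20, 15))
  one <- size_distribution(pop, bin_width = 5)
  expect_equal(sum(one$counts > 0), 1)
  expect_equal(one$median, 20)
})

test_that("phase-separated fraction carries a Wilson interval", {
  pop <- guv_population(rep(10, 100), c(rep(TRUE, 90), rep(FALSE, 10)))
  ps <- phase_separated_fraction(pop)
  expect_equal(ps$fraction, 0.90)
  expect_true(ps$conf_int[["lower"]] < 0.9 && ps$conf_int[["upper"]] > 0.9)
  # all / none flagged
  expect_equal(phase_separated_fraction(
    guv_population(rep(10, 20), rep(TRUE, 20)))$fraction, 1.0)
  none <- phase_separated_fraction(
    guv_population(rep(10, 20), rep(FALSE, 20)))
  expect_equal(none$fraction, 0)
  expect_equal(none$conf_int[["lower"]], 0)
  expect_error(phase_separated_fraction(guv_population(rep(10, 20))),
               class = "memmech_invalid_input")
})
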