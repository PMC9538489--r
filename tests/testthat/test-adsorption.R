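test_that("the equation of state evaluates to hand-computed values", {
  # c = 0 leaves the bare interface untouched
  expect_identical(eval_gibbs_langmuir(72, 3e-6, 0.42, 0, 295.15), 72)
  # hand evaluation at c = 50 nM (1 + Kc = 22)
  expect_equal(eval_gibbs_langmuir(72, 3e-6, 0.42, 50, 295.15),
               gl_oracle(72, 3e-6, 0.42, 50, 295.15), tolerance = 1e-12)
  expect_equal(eval_gibbs_langmuir(72, 3e-6, 0.42, 50, 295.15), 49.24, # frozen
               tolerance = 1e-4)
  expect_error(eval_gibbs_langmuir(72, 3e-6, 0.42, -1),
               class = "memmech_invalid_input")
  expect_error(eval_gibbs_langmuir(72, -3e-6, 0.42, 1),
               class = "memmech_invalid_input")
})

test_that("surface tension is non-increasing in concentration", {
  set.seed(7)
  for (i in 1:25) {
    g0 <- runif(1, 40, 75)
    ginf <- 10^runif(1, -7, -5)
    k <- 10^runif(1, -2, 1)
    gam <- eval_gibbs_langmuir(g0, ginf, k, sort(runif(50, 0, 500)))
    expect_true(all(diff(gam) <= 1e-12))
  }
})

test_that("mean molecular area inverts the surface concentration", {
  expect_equal(round(mean_molecular_area(3.0e-6)), 55)
  expect_equal(round(mean_molecular_area(2.4e-6)), 69)
  # inverse identity: Gamma_inf = 1/(A N_A) recovers A
  expect_equal(mean_molecular_area(1e20 / (100 * N_AV)), 100, tolerance = 1e-9)
  # strictly decreasing in Gamma_inf
  g <- sort(10^runif(20, -7, -5))
  expect_true(all(diff(mean_molecular_area(g)) < 0))
  expect_error(mean_molecular_area(0), class = "memmech_invalid_input")
})

test_that("adsorption_data validates and sorts its inputs", {
  d <- adsorption_data(c(5, 1, 20, 80), c(62, 70, 52, 47))
  expect_true(all(diff(d$concentration) > 0))
  expect_error(adsorption_data(c(1, 2, 3), c(70, 60, 50)),
               class = "memmech_invalid_input") # too short
  expect_error(adsorption_data(c(1, 1, 3, 4), c(70, 60, 50, 40)),
               class = "memmech_invalid_input") # duplicate concentration
  expect_error(adsorption_data(c(1, 2, 3, 4), c(70, 60, 50, 120)),
               class = "memmech_invalid_input") # tension out of range
  expect_error(adsorption_data(c(1, 2, 3, 4), c(70, 60, 50, 40),
                               temperature = 200),
               class = "memmech_invalid_input")
})

test_that("noiseless data give back the generating parameters", {
  sim <- gen_adsorption(noise_sd = 0)
  fit <- fit_gibbs_langmuir(sim$data)
  expect_equal(fit$gamma0, sim$truth$gamma0, tolerance = 1e-3)
  expect_equal(fit$gamma_inf_conc, sim$truth$gamma_inf_conc, tolerance = 1e-3)
  expect_equal(fit$k_ads, sim$truth$k_ads, tolerance = 1e-3)
  # fitted curve reproduces the generator pointwise
  curve <- eval_gibbs_langmuir(fit$gamma0, fit$gamma_inf_conc, fit$k_ads,
                               sim$data$concentration)
  expect_lt(max(abs(curve - sim$data$tension)), 1e-8)
  # fixing gamma0 at its true value changes nothing material
  fit2 <- fit_gibbs_langmuir(sim$data, fix_gamma0 = 72)
  expect_equal(fit2$gamma_inf_conc, sim$truth$gamma_inf_conc, tolerance = 1e-3)
})

test_that("fit is robust to noise at the instrument precision", {
  # 50 replicates at the tensiometer sd; median recovery of Gamma_inf
  errs <- vapply(1:50, function(i) {
    sim <- gen_adsorption(noise_sd = 0.2, seed = 100 + i)
    fit <- fit_gibbs_langmuir(sim$data)
    abs(fit$gamma_inf_conc - sim$truth$gamma_inf_conc) /
      sim$truth$gamma_inf_conc
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("one-sigma intervals have sane coverage at doubled width", {
  hits <- vapply(1:100, function(i) {
    sim <- gen_adsorption(noise_sd = 0.2, seed = 5000 + i)
    fit <- fit_gibbs_langmuir(sim$data)
    abs(fit$gamma_inf_conc - sim$truth$gamma_inf_conc) <=
      2 * fit$param_uncertainties[["gamma_inf_conc"]]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 1.0)
})

test_that("plateau points are excluded from the equation-of-state fit", {
  # truncated (micellizing) data: fitting without exclusion would bias
  # Gamma_inf; with the built-in trailing-plateau drop the branch fit is
  # still exact
  sim <- gen_adsorption(cmc = 23, noise_sd = 0)
  fit <- fit_gibbs_langmuir(sim$data)
  expect_equal(fit$gamma_inf_conc, 3.0e-6, tolerance = 1e-3)
  expect_equal(fit$k_ads, 0.42, tolerance = 1e-3)
})

test_that("two-segment CMC lands on the generating breakpoint", {
  for (true_cmc in c(23, 50)) {
    sim <- gen_adsorption(cmc = true_cmc, noise_sd = 0)
    est <- estimate_cmc(sim$data, method = "two-segment")
    conc <- sim$data$concentration
    step <- max(diff(conc[abs(conc - true_cmc) < true_cmc]))
    expect_lt(abs(est - true_cmc), step + 1e-9)
  }
})

test_that("plateau-intersection CMC is exact on noiseless truncated data", {
  sim <- gen_adsorption(cmc = 23, noise_sd = 0)
  expect_equal(estimate_cmc(sim$data, method = "plateau-intersection"), 23,
               tolerance = 1e-4)
})

test_that("monotone data with no plateau yield an undefined-CMC error", {
  sim <- gen_adsorption(noise_sd = 0) # no truncation: tension keeps falling
  expect_error(estimate_cmc(sim$data), class = "memmech_undefined_cmc")
  # and the full fit reports CMC as NA rather than failing
  expect_true(is.na(fit_gibbs_langmuir(sim$data)$cmc))
})

test_that("mean area and CMC are propagated into the fit object", {
  sim <- gen_adsorption(cmc = 50, gamma_inf_conc = 2.4e-6, k_ads = 0.15,
                        noise_sd = 0)
  fit <- fit_gibbs_langmuir(sim$data)
  expect_equal(fit$mean_area, mean_molecular_area(fit$gamma_inf_conc))
  expect_false(is.na(fit$cmc))
  expect_output(print(fit), "Gibbs-Langmuir")
})
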