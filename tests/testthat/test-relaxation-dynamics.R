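test_that("hNOE is the plain intensity ratio, sign included", {
  expect_equal(hnoe(80, 80), 1.0)
  expect_equal(hnoe(-0.1 * 50, 50), -0.1)
  expect_error(hnoe(10, 0), "non-zero")
})

test_that("R2eff matches the closed form to machine precision on random inputs", {
  set.seed(123)
  i0 <- runif(1000, 50, 200)
  r2 <- runif(1000, 1, 60)
  tcp <- 0.05
  inten <- i0 * exp(-r2 * tcp)
  expect_equal(r2eff(inten, i0, tcp), r2, tolerance = 1e-12)
  # the constant-time identity: I = I0/e at T_CP = 50 ms gives exactly 20
  expect_identical(r2eff(exp(-1) * 100, 100, 0.05), 20)
  expect_equal(r2eff(100, 100, 0.05), 0)
  expect_true(is.na(r2eff(-1, 100, 0.05)))
})

test_that("duplicate CPMG frequencies are averaged before conversion", {
  s <- data.frame(nu = c(80, 120, 120, 960),
                  intensity = c(60, 50, 70, 80))
  dp <- dispersion_profile(s, i0 = 100)
  expect_equal(nrow(dp$r2eff), 3)
  expect_equal(dp$r2eff$r2eff[dp$r2eff$nu == 120],
               -log(60 / 100) / 0.05)
})

test_that("exchange-free series are flat with flag none; missing anchors flag unobserved", {
  sim <- simulate_cpmg(NULL, r20 = 15, noise_sigma = 0, seed = 1)
  dp <- dispersion_profile(sim$series, sim$i0)
  expect_equal(dp$delta_r2, 0, tolerance = 1e-9)
  expect_equal(dp$exchange_flag, "none")
  part <- sim$series[sim$series$nu != 960, ]
  dp2 <- dispersion_profile(part, sim$i0)
  expect_true(is.na(dp2$delta_r2))
  expect_equal(dp2$exchange_flag, "unobserved")
})

test_that("fast-exchange dispersion is flagged by the analytic tier of its delta_r2", {
  ex <- list(p_minor = 0.05, delta_omega = 1200, k_ex = 2000)
  truth_delta <- luz_meiboom(80, 15, ex$p_minor, ex$delta_omega, ex$k_ex) -
    luz_meiboom(960, 15, ex$p_minor, ex$delta_omega, ex$k_ex)
  expect_gt(truth_delta, 6)
  sim <- simulate_cpmg(ex, r20 = 15, noise_sigma = 0.005, seed = 2)
  dp <- dispersion_profile(sim$series, sim$i0)
  expect_equal(dp$exchange_flag, "strong")
  expect_equal(dp$delta_r2, truth_delta, tolerance = 0.25)
  # a weaker exchange process lands in the moderate tier
  ex2 <- list(p_minor = 0.02, delta_omega = 900, k_ex = 3000)
  d2 <- luz_meiboom(80, 15, ex2$p_minor, ex2$delta_omega, ex2$k_ex) -
    luz_meiboom(960, 15, ex2$p_minor, ex2$delta_omega, ex2$k_ex)
  expect_true(d2 > 2 && d2 < 6)
  sim2 <- simulate_cpmg(ex2, r20 = 15, noise_sigma = 0.005, seed = 3)
  expect_equal(dispersion_profile(sim2$series, sim2$i0)$exchange_flag,
               "moderate")
})

test_that("false moderate flags on exchange-free series stay below 5%", {
  flags <- vapply(1:200, function(s) {
    sim <- simulate_cpmg(NULL, r20 = 15, noise_sigma = 0.01, seed = s)
    dispersion_profile(sim$series, sim$i0)$exchange_flag
  }, "")
  expect_lt(mean(flags != "none"), 0.05)
})

test_that("accessibility classification applies gadolinium precedence and partitions", {
  g <- c(`1` = 0.2, `2` = 0.3, `3` = 0.9, `4` = 0.8)
  m <- c(`1` = 0.2, `2` = 0.9, `3` = 0.3, `4` = 0.9)
  acc <- classify_accessibility(g, m, cutoff = 0.5, residues = 1:5)
  expect_equal(acc$class, c("water_exposed", "water_exposed", "headgroup",
                            "buried_or_bonded", "unobserved"))
  expect_equal(nrow(acc), 5)
  expect_true(all(table(acc$residue) == 1))
})

test_that("noise-free titration simulation is classified back to the exact truth", {
  tr <- paper_truth()
  sim <- simulate_hnoe_and_titration(tr, noise = 0, seed = 4)
  acc <- classify_accessibility(sim$gado_ratios, sim$mn_ratios)
  map <- c(water_exposed = "water_exposed", headgroup = "headgroup",
           buried = "buried_or_bonded")
  expect_equal(acc$class, unname(map[tr$depth]))
})

test_that("class fractions on noisy titrations match the truth within 10%", {
  tr <- paper_truth()
  sim <- simulate_hnoe_and_titration(tr, noise = 0.05, seed = 6)
  acc <- classify_accessibility(sim$gado_ratios, sim$mn_ratios)
  truth_frac <- table(tr$depth) / tr$n_res
  got <- c(buried = mean(acc$class == "buried_or_bonded"),
           headgroup = mean(acc$class == "headgroup"),
           water_exposed = mean(acc$class == "water_exposed"))
  expect_true(all(abs(got[names(truth_frac)] - truth_frac) < 0.10))
})

test_that("dynamics table joins the three measurements on residue", {
  h <- data.frame(residue = 1:3, hnoe = c(0.9, 0.6, 0.2))
  d <- data.frame(residue = 2:3, delta_r2 = c(1, 8),
                  exchange_flag = c("none", "strong"))
  a <- data.frame(residue = c(1, 3), class = c("water_exposed", "headgroup"))
  tab <- dynamics_table(h, d, a)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$accessibility[2], NA_character_)
  expect_equal(tab$exchange_flag[3], "strong")
})
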