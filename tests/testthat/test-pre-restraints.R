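test_that("intensity ratios and first-order error propagation are exact", {
  expect_equal(intensity_ratio(100, 100)$ratio, 1.0)
  expect_equal(intensity_ratio(0, 100)$ratio, 0.0)
  r <- intensity_ratio(50, 100, sigma = 5)
  expect_equal(r$ratio, 0.5)
  # analytic propagation: sqrt((5/100)^2 + (50*5/100^2)^2)
  expect_equal(r$ratio_sd, sqrt(0.05^2 + 0.025^2), tolerance = 1e-12)
  expect_warning(rc <- intensity_ratio(-3, 100), "clamped")
  expect_equal(rc$ratio, 0)
  expect_error(intensity_ratio(10, 0), "i_dia")
})

test_that("ratio -> R2sp inversion matches an independent bisection oracle", {
  bisect <- function(rt, r2_dia, t_inept) {
    f <- function(r) r2_dia * exp(-r * t_inept) / (r2_dia + r) - rt
    lo <- 0; hi <- 1
    while (f(hi) > 0) hi <- hi * 2
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-10 * max(1, hi)) break
    }
    (lo + hi) / 2
  }
  for (rt in c(0.1, 0.25, 0.5, 0.7, 0.84)) {
    expect_equal(ratio_to_r2sp(rt, 20, 0.010), bisect(rt, 20, 0.010),
                 tolerance = 1e-7)
  }
  expect_error(ratio_to_r2sp(1.0), "unaffected")
  expect_error(ratio_to_r2sp(0), "vanished")
})

test_that("the attenuation model has the correct analytic limits", {
  # r2sp -> 0+ gives ratio -> 1-, so inverting a ratio near 1 gives ~0
  expect_lt(ratio_to_r2sp(0.9999), 0.01)
  expect_gt(r2sp_to_ratio(1e-9), 0.999999)
})

test_that("forward/inverse round trip holds to 1e-6 relative over [1, 200] s^-1", {
  grid <- seq(1, 200, length.out = 80)
  back <- ratio_to_r2sp(r2sp_to_ratio(grid))
  expect_lt(max(abs(back - grid) / grid), 1e-6)
})

test_that("PRE-rate-to-distance conversion matches direct evaluation and scaling laws", {
  tau <- 15e-9; om <- 2 * pi * 800e6; K <- 1.23e16
  direct <- (K / 20 * (4 * tau + 3 * tau / (1 + om^2 * tau^2)))^(1 / 6)
  expect_equal(r2sp_to_distance(20), direct, tolerance = 1e-12)
  # strictly decreasing in r2sp
  d <- r2sp_to_distance(c(1, 5, 20, 100))
  expect_true(all(diff(d) < 0))
  # doubling k_const multiplies d by 2^(1/6)
  expect_equal(r2sp_to_distance(20, k_const = 2 * K),
               r2sp_to_distance(20, k_const = K) * 2^(1 / 6),
               tolerance = 1e-12)
  # distance_to_r2sp is the exact inverse
  expect_equal(distance_to_r2sp(r2sp_to_distance(37.5)), 37.5,
               tolerance = 1e-9)
})

test_that("the 0.85 rule and vanished-peak rule classify exactly", {
  meas <- data.frame(residue = 1:4,
                     i_para = c(90, 50, 0, 10), i_dia = rep(100, 4))
  r <- build_restraints(meas, site = 50)
  expect_equal(r$class, c("unrestrained", "bounded", "upper_only",
                          "upper_only"))
  expect_true(is.na(r$d[1]))
  expect_true(all(r$lower[r$class == "bounded"] <= r$d[r$class == "bounded"]))
  # vanished upper bound equals d(vanish_cutoff)
  p <- pre_params()
  d_vanish <- r2sp_to_distance(ratio_to_r2sp(p$vanish_cutoff))
  expect_equal(r$upper[3], d_vanish, tolerance = 1e-9)
})

test_that("label-site residues are excluded and counting partitions the input", {
  meas <- data.frame(residue = 1:10, i_para = seq(5, 95, by = 10),
                     i_dia = rep(100, 10))
  expect_message(r <- build_restraints(meas, site = 4), "excluding 1")
  expect_equal(attr(r, "excluded"), 4L)
  expect_equal(nrow(r) + length(attr(r, "excluded")), nrow(meas))
  counts <- table(factor(r$class, levels = c("unrestrained", "bounded",
                                             "upper_only", "vanished")))
  expect_equal(sum(counts) + length(attr(r, "excluded")), nrow(meas))
})

test_that("bounded intervals always contain the distance implied by their own ratio", {
  tr <- small_truth()
  pm <- simulate_pre(tr, 6, noise_sigma = 0.05, seed = 9)
  r <- suppressMessages(build_restraints(pm, 6))
  b <- r[r$class == "bounded", ]
  d_self <- r2sp_to_distance(ratio_to_r2sp(b$ratio))
  expect_true(all(b$lower <= d_self & d_self <= b$upper))
})

test_that("noise-free closed loop recovers true distances within the bound width", {
  tr <- paper_truth()
  for (s in c(6, 89)) {
    pm <- simulate_pre(tr, s, noise_sigma = 0, seed = 1)
    r <- suppressMessages(build_restraints(pm, s))
    td <- attr(pm, "true_distance")[match(r$residue, pm$residue)]
    b <- r$class == "bounded"
    expect_gt(sum(b), 10)
    expect_true(all(abs(r$d[b] - td[b]) <= pre_params()$bound_width))
    # the 0.85 rule excludes exactly the residues whose forward ratio > 0.85
    fwd <- r2sp_to_ratio(distance_to_r2sp(td))
    expect_equal(r$class == "unrestrained", unname(fwd > 0.85))
  }
})

test_that("recovered distances preserve the monotone ordering of true distances", {
  tr <- paper_truth()
  pm <- simulate_pre(tr, 102, noise_sigma = 0, seed = 2)
  r <- suppressMessages(build_restraints(pm, 102))
  b <- r[r$class == "bounded", ]
  td <- attr(pm, "true_distance")[match(b$residue, pm$residue)]
  expect_equal(order(b$d), order(td))
})

test_that("per-site QC counts sum to the table size", {
  tr <- small_truth()
  r <- do.call(rbind, lapply(tr$label_sites, function(s)
    suppressMessages(build_restraints(
      simulate_pre(tr, s, noise_sigma = 0.02, seed = 5), s))))
  qc <- restraint_qc(r)
  expect_equal(sum(qc$total), nrow(r))
})
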