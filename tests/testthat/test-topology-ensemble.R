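test_that("superposition is exact for identity and rigid transforms", {
  set.seed(1)
  x <- matrix(rnorm(30, sd = 5), ncol = 3)
  self <- superpose(x, x)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  y <- sweep(x %*% t(R), 2, c(3, -2, 7), `+`)
  fit <- superpose(x, y)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)
  expect_error(superpose(x[1:2, ], x[1:2, ]), "3 atoms")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("superposition agrees with the bio3d reference implementation", {
  set.seed(2)
  x <- matrix(rnorm(45, sd = 4), ncol = 3)
  y <- x + matrix(rnorm(45, sd = 0.8), ncol = 3)
  ours <- superpose(x, y)$rmsd
  ref <- bio3d::rmsd(as.vector(t(y)), as.vector(t(x)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("post-fit RMSD to a noisy copy follows the degrees-of-freedom trend", {
  set.seed(3)
  n <- 20; sig <- 0.3
  x <- matrix(rnorm(3 * n, sd = 6), ncol = 3)
  sims <- replicate(300, superpose(x, x + matrix(rnorm(3 * n, 0, sig),
                                                 ncol = 3))$rmsd)
  # expected RMSD ~ sigma * sqrt((3n - 6)/n): 6 dof absorbed by the fit
  expect_equal(mean(sims), sig * sqrt((3 * n - 6) / n), tolerance = 0.05)
})

test_that("ensemble RMSD is zero for identical or rigidly transformed models", {
  tr <- small_truth()
  ens <- simulate_ensemble(tr, n_models = 3, backbone_sigma = 0,
                           sidechain_sigma = 0, hydrogen_sigma = 0, seed = 1)
  sel <- helix_residues(tr$helices)
  expect_equal(ensemble_rmsd(ens, sel, "all"), 0, tolerance = 1e-8)
  # rotate model 2 rigidly: still zero
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  m2 <- ens$models[[2]]
  xyz <- as.matrix(m2[, c("x", "y", "z")]) %*% t(R)
  ens$models[[2]][, c("x", "y", "z")] <- sweep(xyz, 2, c(5, 5, -2), `+`)
  expect_equal(ensemble_rmsd(ens, sel, "all"), 0, tolerance = 1e-8)
  expect_error(ensemble_rmsd(list(models = ens$models[1]), sel), "2 models")
})

test_that("ensemble spread ordering all >= heavy >= backbone holds by construction", {
  tr <- small_truth()
  ens <- simulate_ensemble(tr, n_models = 8, seed = 7)
  sel <- helix_residues(tr$helices)
  for (method in c("mean", "pairwise")) {
    bb <- ensemble_rmsd(ens, sel, "backbone", method = method)
    hv <- ensemble_rmsd(ens, sel, "heavy", method = method)
    al <- ensemble_rmsd(ens, sel, "all", method = method)
    expect_gte(al, hv)
    expect_gte(hv, bb)
    expect_gt(bb, 0)
  }
})

test_that("restraints derived from a model score zero violations on it", {
  tr <- small_truth()
  r <- restraints_from_truth(tr, tr$label_sites)
  v <- restraint_violations(tr$coords, r, linker_pad = 0)
  expect_equal(v$n_violated, 0)
  expect_equal(v$sum_violation, 0)
  # an upper_only restraint satisfied by the model contributes nothing
  up <- data.frame(site = 1L, residue = 10L, d = NA, lower = 0,
                   upper = 100, class = "upper_only")
  expect_equal(restraint_violations(tr$coords, up)$n_violated, 0)
  # unscorable residues are listed, not fatal
  miss <- data.frame(site = 1L, residue = 999L, d = 10, lower = 5,
                     upper = 15, class = "bounded")
  expect_equal(restraint_violations(tr$coords, miss)$unscorable, 999L)
})

test_that("a displaced-helix decoy concentrates violations on that helix", {
  tr <- small_truth()
  r <- restraints_from_truth(tr, tr$label_sites)
  decoy <- tr$coords
  h2 <- seq(tr$helices$start[2], tr$helices$end[2])
  decoy[h2, 1] <- decoy[h2, 1] + 10
  v <- restraint_violations(decoy, r, linker_pad = 0)
  expect_gt(v$n_violated, 0)
  pr <- v$per_restraint
  on_h2 <- pr$residue %in% h2 | pr$site %in% h2
  expect_gt(sum(pr$violation[on_h2]), 0.95 * sum(pr$violation))
})

test_that("a single helix is reconstructed from its own ideal-geometry restraints", {
  tr <- make_bundle(n_helices = 1, lengths = 10L, loop_lengths = c(0L, 0L),
                    seed = 5)
  r <- restraints_from_truth(tr, sites = c(1L, 10L))
  mod <- reconstruct_topology(r, tr$helices, tr$n_res, n_restarts = 4,
                              steps = 20000, seed = 2, linker_pad = 0)
  rmsd <- ca_rmsd_to(mod$models[[1]], tr$coords)
  expect_lt(rmsd, 1.0)
})

test_that("reconstruction is exactly reproducible for a fixed seed", {
  tr <- small_truth()
  r <- restraints_from_truth(tr, tr$label_sites)
  m1 <- reconstruct_topology(r, tr$helices, tr$n_res, n_restarts = 2,
                             steps = 5000, seed = 7)
  m2 <- reconstruct_topology(r, tr$helices, tr$n_res, n_restarts = 2,
                             steps = 5000, seed = 7)
  expect_identical(m1$models, m2$models)
  expect_identical(m1$energies, m2$energies)
})

test_that("the best-so-far annealing trace is non-increasing", {
  tr <- small_truth()
  r <- restraints_from_truth(tr, tr$label_sites)
  mod <- reconstruct_topology(r, tr$helices, tr$n_res, n_restarts = 2,
                              steps = 10000, seed = 3)
  for (trace in mod$traces)
    expect_true(all(diff(trace) <= 1e-9))
})

test_that("zero restraints still run but are flagged low-confidence", {
  tr <- small_truth()
  expect_warning(
    mod <- reconstruct_topology(NULL, tr$helices, tr$n_res, n_restarts = 2,
                                steps = 5000, seed = 1),
    "low-confidence")
  expect_true(mod$low_confidence)
  expect_true(all(is.finite(mod$energies)))
})

test_that("mirror correction matters for distance-only reconstructions", {
  tr <- small_truth()
  m <- tr$coords
  expect_equal(ca_rmsd_to(mirror_model(m), m, mirror_correct = TRUE), 0,
               tolerance = 1e-8)
  expect_gt(ca_rmsd_to(mirror_model(m), m, mirror_correct = FALSE), 0.5)
})

test_that("Calpha PDB writer round trips through the ensemble reader", {
  tr <- small_truth()
  f <- tempfile(fileext = ".pdb")
  write_ca_pdb(list(tr$coords, tr$coords + 1), f, aa = tr$sequence)
  ens <- read_ensemble(f)
  expect_equal(n_models(ens), 2)
  got <- as.matrix(ens$models[[1]][, c("x", "y", "z")])
  expect_equal(unname(got), unname(tr$coords), tolerance = 1e-3)
})
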