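# Forward models generating every pipeline input from a known ground truth:
# a helical-bundle Calpha structure with per-residue rigidity and burial
# classes, plus simulators for chemical shifts, spin-label PRE intensity
# pairs, CPMG dispersion series, hNOE pairs and paramagnetic titrations.
# Every simulator is deterministic given its seed, and its noise-free limit
# is the exact inverse of the corresponding analysis operation.

# ideal alpha-helix Calpha geometry: rise 1.5 A, 100 deg/residue; the radius
# making consecutive Calpha distances exactly 3.8 A
.HELIX_RISE <- 1.5
.HELIX_TURN <- 100 * pi / 180
.HELIX_RADIUS <- sqrt(3.8^2 - 1.5^2) / (2 * sin(.HELIX_TURN / 2))

.ideal_helix <- function(len) {
  i <- seq_len(len) - 1
  cbind(.HELIX_RADIUS * cos(i * .HELIX_TURN),
        .HELIX_RADIUS * sin(i * .HELIX_TURN),
        .HELIX_RISE * i)
}

# SHAKE-style bond equilibration of a chain with fixed endpoints
.shake_bridge <- function(pts, target = 3.8, fixed_ends = TRUE,
                          tol = 0.005, iters = 2000) {
  n <- nrow(pts)
  for (it in seq_len(iters)) {
    worst <- 0
    for (i in seq_len(n - 1)) {
      v <- pts[i + 1, ] - pts[i, ]
      d <- sqrt(sum(v^2))
      err <- d - target
      worst <- max(worst, abs(err))
      if (abs(err) < tol) next
      corr <- err / max(d, 1e-9) * v
      f1 <- fixed_ends && i == 1
      f2 <- fixed_ends && i == n - 1
      if (f1 && f2) next
      if (f1) pts[i + 1, ] <- pts[i + 1, ] - corr
      else if (f2) pts[i, ] <- pts[i, ] + corr
      else {
        pts[i, ] <- pts[i, ] + corr / 2
        pts[i + 1, ] <- pts[i + 1, ] - corr / 2
      }
    }
    if (worst < tol) break
  }
  pts
}

.bridge_loop <- function(a, b, n_loop, step = 3.8, max_try = 25) {
  gap <- sqrt(sum((b - a)^2))
  if (gap > 0.95 * step * (n_loop + 1))
    stop("loop of ", n_loop, " residues cannot bridge a ", round(gap, 1),
         " A gap")
  for (tr in seq_len(max_try)) {
    tt <- seq_len(n_loop) / (n_loop + 1)
    base <- outer(1 - tt, a) + outer(tt, b)
    # transverse wobble so the equilibrated chain has enough contour length
    amp <- 0.35 * step * sqrt(n_loop) * (1 + 0.2 * tr)
    noise <- matrix(rnorm(3 * n_loop, 0, amp / sqrt(n_loop)), ncol = 3)
    pts <- rbind(a, base + noise, b)
    pts <- .shake_bridge(pts, step)
    bonds <- sqrt(rowSums(diff(pts)^2))
    if (all(abs(bonds - step) < 0.01)) return(pts[-c(1, nrow(pts)), , drop = FALSE])
  }
  pts[-c(1, nrow(pts)), , drop = FALSE]
}

.free_walk <- function(from, n, step = 3.8, away = c(0, 0, 0)) {
  out <- matrix(0, n, 3)
  cur <- from
  for (i in seq_len(n)) {
    v <- rnorm(3) + 0.5 * away
    cur <- cur + step * v / sqrt(sum(v^2))
    out[i, ] <- cur
  }
  out
}

#' Construct a ground-truth helical bundle
#'
#' Builds an idealized membrane-embedded bundle: `n_helices` ideal
#' alpha-helices (rise 1.5 A, 100 degrees/residue, consecutive Calpha
#' distance 3.8 A) arranged antiparallel on a circle, joined by
#' bond-equilibrated random-coil loops.  Per-residue rigidity (`rigid` in
#' helices, `flexible` in loops) and burial-depth classes
#' (`water_exposed` / `headgroup` / `buried`, assigned from the depth
#' coordinate with the study fractions 17:30:78 out of 125) complete the
#' truth object.
#'
#' The default shape mirrors the study system: five helices of lengths
#' 5, 9, 5, 10, 10 at residues 3-7, 22-30, 90-94, 98-107 and 116-125 of a
#' 125-residue chain carrying the P56S MSP-domain sequence.
#'
#' @param n_helices number of helices.
#' @param lengths helix lengths (residues).
#' @param loop_lengths coil lengths: leading coil, `n_helices - 1`
#'   connecting loops, trailing coil (length `n_helices + 1`).
#' @param seed RNG seed.
#' @param sequence one-letter sequence of the full chain (defaults to the
#'   P56S MSP domain for the paper-shaped bundle, otherwise poly-Ala with
#'   glycine loops' first residues left as Ala).
#' @param bundle_radius circle radius for helix axes, Angstrom.
#' @return object of class `ground_truth`: list with `coords` (N x 3,
#'   residue rownames), `sequence`, `helices`, `label_sites`, `rigidity`,
#'   `depth`, `n_res`.
#' @export
make_bundle <- function(n_helices = 5L,
                        lengths = c(5L, 9L, 5L, 10L, 10L),
                        loop_lengths = c(2L, 14L, 59L, 3L, 8L, 0L),
                        seed = 1L,
                        sequence = NULL,
                        bundle_radius = 8.5) {
  stopifnot(n_helices == length(lengths),
            length(loop_lengths) == n_helices + 1)
  n_res <- sum(lengths) + sum(loop_lengths)
  starts <- cumsum(c(1 + loop_lengths[1],
                     utils::head(lengths, -1) +
                       loop_lengths[seq(2, n_helices)]))
  ends <- starts + lengths - 1
  if (any(diff(starts) <= 0) || any(ends >= c(starts[-1], n_res + 1)))
    stop("overlapping or out-of-order segments")
  helices <- segments_df(starts, ends)
  if (is.null(sequence)) {
    sequence <- if (n_res == 125 && identical(as.integer(starts),
                                              c(3L, 22L, 90L, 98L, 116L)))
      study_sequence("msp_p56s") else paste(rep("A", n_res), collapse = "")
  }
  stopifnot(nchar(sequence) == n_res)

  set.seed(seed)
  coords <- matrix(NA_real_, n_res, 3)
  for (h in seq_len(n_helices)) {
    loc <- .ideal_helix(lengths[h])
    loc[, 3] <- loc[, 3] - mean(loc[, 3])
    if (h %% 2 == 0) {            # antiparallel: flip axis
      loc[, 3] <- -loc[, 3]
      loc[, 1] <- -loc[, 1]
    }
    ang <- 2 * pi * (h - 1) / n_helices
    centre <- c(bundle_radius * cos(ang), bundle_radius * sin(ang), 0)
    coords[starts[h]:ends[h], ] <- sweep(loc, 2, centre, `+`)
  }
  for (h in seq_len(n_helices - 1)) {
    nl <- loop_lengths[h + 1]
    if (nl == 0) next
    a <- coords[ends[h], ]; b <- coords[starts[h + 1], ]
    coords[(ends[h] + 1):(starts[h + 1] - 1), ] <- .bridge_loop(a, b, nl)
  }
  if (loop_lengths[1] > 0)
    coords[loop_lengths[1]:1, ] <- .free_walk(coords[starts[1], ],
                                              loop_lengths[1])
  nl <- loop_lengths[n_helices + 1]
  if (nl > 0)
    coords[(ends[n_helices] + 1):n_res, ] <- .free_walk(coords[ends[n_helices], ], nl)
  rownames(coords) <- seq_len(n_res)

  rigidity <- rep("flexible", n_res)
  for (h in seq_len(n_helices)) rigidity[starts[h]:ends[h]] <- "rigid"

  # burial depth from the z coordinate: micelle normal along z, fractions
  # fixed at the study design's 17 exposed : 30 headgroup : remainder buried
  z <- coords[, 3]
  q_exp <- quantile(z, 1 - 17 / 125)
  q_head <- quantile(z, 1 - (17 + 30) / 125)
  depth <- ifelse(z >= q_exp, "water_exposed",
           ifelse(z >= q_head, "headgroup", "buried"))

  sites <- default_label_sites()
  sites <- sites[sites <= n_res]
  structure(list(coords = coords, sequence = sequence, helices = helices,
                 label_sites = sites, rigidity = rigidity, depth = depth,
                 n_res = n_res),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth: ", x$n_res, " residues, ", nrow(x$helices),
      " helices, ", length(x$label_sites), " label sites\n", sep = "")
  invisible(x)
}

#' Simulate Calpha/Cbeta chemical shifts from a ground truth
#'
#' Observed shift = random-coil reference + helical offset + Gaussian
#' noise.  Inside helices the (dCa - dCb) index is displaced by
#' `helix_offset` ppm, split 2/3 onto Calpha and -1/3 onto Cbeta; glycine
#' (no Cbeta) carries the full offset on Calpha.  Coil residues have zero
#' offset.
#'
#' @param truth a `ground_truth`.
#' @param helix_offset injected secondary-shift amplitude, ppm (default 3).
#' @param noise_sigma per-shift Gaussian noise, ppm.
#' @param seed RNG seed.
#' @param refs random-coil table (default [random_coil_shifts()]).
#' @param condition condition label for the table.
#' @return a `shift_table`.
#' @export
simulate_shifts <- function(truth, helix_offset = 3.0, noise_sigma = 0.2,
                            seed = 1L, refs = random_coil_shifts(),
                            condition = "synthetic") {
  stopifnot(helix_offset >= 0)
  set.seed(seed)
  aa <- strsplit(truth$sequence, "")[[1]]
  m <- match(aa, refs$aa)
  helical <- truth$rigidity == "rigid"
  ca <- refs$ca[m] + ifelse(helical,
                            ifelse(aa == "G", helix_offset, helix_offset * 2 / 3), 0) +
    rnorm(truth$n_res, 0, noise_sigma)
  cb <- refs$cb[m] + ifelse(helical & aa != "G", -helix_offset / 3, 0) +
    rnorm(truth$n_res, 0, noise_sigma)
  cb[aa == "G"] <- NA
  new_shift_table(seq_len(truth$n_res), aa, ca, cb, condition = condition)
}

#' Simulate paired paramagnetic/diamagnetic peak intensities for one site
#'
#' Forward model of a spin-label PRE experiment: the truth Calpha-Calpha
#' distance from the label site to each residue is converted to R2sp by
#' the Solomon-Bloembergen relation and then to an intensity ratio by the
#' attenuation model (the exact inverses of the analysis chain).
#' Diamagnetic intensities are drawn log-normal to mimic realistic peak
#' heterogeneity; both intensities carry multiplicative Gaussian noise.
#' The label-site residue itself vanishes (ratio 0).
#'
#' @param truth a `ground_truth`.
#' @param site label-site residue index (must be in
#'   `truth$label_sites` bounds).
#' @param params [pre_params()] conversion parameters.
#' @param noise_sigma multiplicative intensity noise (default 0.02).
#' @param seed RNG seed.
#' @param i_dia_meanlog,i_dia_sdlog log-normal parameters of the
#'   diamagnetic intensities.
#' @return data frame `residue`, `i_para`, `i_dia`, `sigma`, plus
#'   attribute `true_distance` (Angstrom, `NA` at the site).
#' @export
simulate_pre <- function(truth, site, params = pre_params(),
                         noise_sigma = 0.02, seed = 1L,
                         i_dia_meanlog = log(100), i_dia_sdlog = 0.3) {
  stopifnot(site >= 1, site <= truth$n_res)
  set.seed(seed + site)  # distinct but reproducible stream per site
  d <- sqrt(rowSums(sweep(truth$coords, 2, truth$coords[site, ])^2))
  ratio <- numeric(truth$n_res)
  ok <- d > 1e-6
  ratio[ok] <- r2sp_to_ratio(
    distance_to_r2sp(d[ok], params$tau_c, params$omega_h, params$k_const),
    params$r2_dia, params$t_inept)
  i_dia <- exp(rnorm(truth$n_res, i_dia_meanlog, i_dia_sdlog))
  if (noise_sigma > 0) {
    i_para <- i_dia * ratio * (1 + rnorm(truth$n_res, 0, noise_sigma))
    i_dia <- i_dia * (1 + rnorm(truth$n_res, 0, noise_sigma))
  } else {
    i_para <- i_dia * ratio
  }
  out <- data.frame(residue = seq_len(truth$n_res), i_para = i_para,
                    i_dia = i_dia, sigma = noise_sigma * exp(i_dia_meanlog))
  attr(out, "true_distance") <- ifelse(ok, d, NA)
  out
}

#' Luz-Meiboom fast-exchange CPMG dispersion
#'
#' Closed-form effective rate for two-site fast exchange:
#' \deqn{R_{2eff}(\nu) = R_2^0 + \frac{p_a p_b \Delta\omega^2}{k_{ex}}
#'   \left(1 - \frac{4\nu}{k_{ex}} \tanh\frac{k_{ex}}{4\nu}\right).}
#'
#' @param nu CPMG frequency(ies), Hz.
#' @param r20 exchange-free rate, s^-1.
#' @param p_minor minor-state population (`p_b`).
#' @param delta_omega chemical-shift difference, rad/s.
#' @param k_ex exchange rate, s^-1.
#' @return R2eff value(s), s^-1.
#' @export
luz_meiboom <- function(nu, r20, p_minor, delta_omega, k_ex) {
  stopifnot(all(nu > 0), p_minor >= 0, p_minor <= 1)
  if (p_minor == 0 || delta_omega == 0) return(rep(r20, length(nu)))
  pa <- 1 - p_minor
  r20 + (pa * p_minor * delta_omega^2 / k_ex) *
    (1 - (4 * nu / k_ex) * tanh(k_ex / (4 * nu)))
}

#' Simulate a constant-time CPMG intensity series
#'
#' Back-computes intensities from the Luz-Meiboom dispersion through the
#' constant-time relation `I = I0 exp(-R2eff T_CP)`, with multiplicative
#' Gaussian noise.  The fast-exchange closed form doubles as the oracle
#' for dispersion-flagging tests.
#'
#' @param exchange list with `p_minor`, `delta_omega` (rad/s), `k_ex`
#'   (s^-1), or `NULL` for an exchange-free residue.
#' @param r20 exchange-free rate, s^-1.
#' @param t_cp constant-time delay, s.
#' @param nus CPMG frequencies, Hz (default [default_cpmg_nus()];
#'   duplicated entries are independent repeat measurements).
#' @param i0 reference-plane intensity.
#' @param noise_sigma multiplicative intensity noise.
#' @param seed RNG seed.
#' @return list: `series` (data frame `nu`, `intensity`), `i0`, `t_cp`,
#'   `r2eff_true` (noise-free rates at `nus`).
#' @export
simulate_cpmg <- function(exchange = NULL, r20 = 15, t_cp = 0.050,
                          nus = default_cpmg_nus(), i0 = 100,
                          noise_sigma = 0.01, seed = 1L) {
  set.seed(seed)
  r2 <- if (is.null(exchange)) rep(r20, length(nus))
        else luz_meiboom(nus, r20, exchange$p_minor, exchange$delta_omega,
                         exchange$k_ex)
  inten <- i0 * exp(-r2 * t_cp)
  if (noise_sigma > 0)
    inten <- inten * (1 + rnorm(length(nus), 0, noise_sigma))
  list(series = data.frame(nu = nus, intensity = inten), i0 = i0,
       t_cp = t_cp, r2eff_true = r2)
}

#' hNOE and titration preset parameter sets
#'
#' `"micelle"`: rigid mean 0.95, flexible mean 0.60 — with the study's
#' 39 helix + 86 loop residues this gives an overall average of 0.71.
#' `"water"`: both classes at mean 0.08 with larger spread, so several
#' N-terminal values fall below zero.
#'
#' @param which `"micelle"` or `"water"`.
#' @return list `rigid_mean`, `flexible_mean`, `noise`.
#' @export
hnoe_preset <- function(which = c("micelle", "water")) {
  which <- match.arg(which)
  switch(which,
         micelle = list(rigid_mean = 0.95, flexible_mean = 0.60, noise = 0.05),
         water = list(rigid_mean = 0.08, flexible_mean = 0.08, noise = 0.15))
}

#' Simulate hNOE intensity pairs and paramagnetic titration ratios
#'
#' hNOE values are drawn per rigidity class
#' (`rigid_mean`/`flexible_mean` + Gaussian noise) and converted to
#' saturated/reference intensity pairs.  Titration endpoint ratios are
#' drawn per burial-depth class: water-exposed residues are attenuated by
#' both gadodiamide and Mn2+, head-group residues by Mn2+ only, buried
#' residues by neither.  Attenuated ratios centre on 0.25 and
#' unattenuated on 0.80, with spread `3 * noise`; at `noise = 0` the
#' classes are exactly recoverable by [classify_accessibility()].
#'
#' @param truth a `ground_truth`.
#' @param rigid_mean,flexible_mean hNOE class means (in `[-0.5, 1]`).
#' @param noise Gaussian noise level.
#' @param seed RNG seed.
#' @return list: `hnoe` (data frame `residue`, `i_sat`, `i_ref`, `hnoe`),
#'   `gado_ratios`, `mn_ratios` (named vectors).
#' @export
simulate_hnoe_and_titration <- function(truth, rigid_mean = 0.95,
                                        flexible_mean = 0.60, noise = 0.05,
                                        seed = 1L) {
  stopifnot(rigid_mean >= -0.5, rigid_mean <= 1,
            flexible_mean >= -0.5, flexible_mean <= 1)
  set.seed(seed)
  n <- truth$n_res
  mu <- ifelse(truth$rigidity == "rigid", rigid_mean, flexible_mean)
  hn <- mu + rnorm(n, 0, noise)
  i_ref <- exp(rnorm(n, log(100), 0.2))
  hnoe_df <- data.frame(residue = seq_len(n), i_sat = hn * i_ref,
                        i_ref = i_ref, hnoe = hn)
  spread <- 3 * noise
  draw <- function(centre) pmin(0.99, pmax(0.01,
    centre + runif(n, -1, 1) * spread))
  gado <- ifelse(truth$depth == "water_exposed", draw(0.25), draw(0.80))
  mn <- ifelse(truth$depth %in% c("water_exposed", "headgroup"),
               draw(0.25), draw(0.80))
  names(gado) <- names(mn) <- seq_len(n)
  list(hnoe = hnoe_df, gado_ratios = gado, mn_ratios = mn)
}

# Deterministic pseudo-backbone expansion of a Calpha trace: N and C along
# the chain direction, O off C, CB/CG side-chain stubs along the local
# normal, HA/HB hydrogens. Geometry is schematic; it exists so atom-class
# selections (backbone/heavy/all) have something to select.
.expand_backbone <- function(ca) {
  n <- nrow(ca)
  dirs <- rbind(ca[2, ] - ca[1, ], ca[seq(3, n + 1 - 1), ] - ca[seq_len(n - 2), ],
                ca[n, ] - ca[n - 1, ])
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ref <- matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
  side <- cbind(dirs[, 2] * ref[, 3] - dirs[, 3] * ref[, 2],
                dirs[, 3] * ref[, 1] - dirs[, 1] * ref[, 3],
                dirs[, 1] * ref[, 2] - dirs[, 2] * ref[, 1])
  nz <- sqrt(rowSums(side^2)); nz[nz < 1e-6] <- 1
  side <- side / nz
  up <- cbind(dirs[, 2] * side[, 3] - dirs[, 3] * side[, 2],
              dirs[, 3] * side[, 1] - dirs[, 1] * side[, 3],
              dirs[, 1] * side[, 2] - dirs[, 2] * side[, 1])
  atoms <- list(N = -1.46 * dirs, CA = 0 * dirs, C = 1.52 * dirs,
                O = 1.52 * dirs + 1.23 * up,
                CB = 1.53 * side, CG = 2.9 * side + 0.5 * up,
                HA = 1.0 * up, HB = 1.53 * side + 1.0 * up)
  do.call(rbind, lapply(names(atoms), function(a)
    data.frame(resno = seq_len(n), elety = a,
               x = ca[, 1] + atoms[[a]][, 1],
               y = ca[, 2] + atoms[[a]][, 2],
               z = ca[, 3] + atoms[[a]][, 3], stringsAsFactors = FALSE)))
}

#' Simulate a structural ensemble around a ground truth
#'
#' Expands the truth Calpha trace to a schematic all-atom representation
#' (backbone N/CA/C/O, side-chain stubs CB/CG, hydrogens HA/HB) and draws
#' `n_models` copies with Gaussian coordinate noise whose amplitude
#' increases from backbone to side-chain heavy atoms to hydrogens, and is
#' inflated in flexible (loop) residues.  By construction the ensemble
#' spread ordering is all >= heavy >= backbone.
#'
#' @param truth a `ground_truth`.
#' @param n_models number of models (default 10).
#' @param backbone_sigma,sidechain_sigma,hydrogen_sigma per-class noise,
#'   Angstrom.
#' @param loop_factor noise multiplier for flexible residues (default 3).
#' @param seed RNG seed.
#' @return a `structure_ensemble`.
#' @export
simulate_ensemble <- function(truth, n_models = 10L, backbone_sigma = 0.5,
                              sidechain_sigma = 1.2, hydrogen_sigma = 1.8,
                              loop_factor = 3, seed = 1L) {
  set.seed(seed)
  base <- .expand_backbone(truth$coords)
  base$aa <- strsplit(truth$sequence, "")[[1]][base$resno]
  sig <- ifelse(base$elety %in% c("N", "CA", "C", "O"), backbone_sigma,
         ifelse(grepl("^H", base$elety), hydrogen_sigma, sidechain_sigma))
  sig <- sig * ifelse(truth$rigidity[base$resno] == "flexible", loop_factor, 1)
  models <- lapply(seq_len(n_models), function(m) {
    out <- base
    out$x <- base$x + rnorm(nrow(base), 0, sig)
    out$y <- base$y + rnorm(nrow(base), 0, sig)
    out$z <- base$z + rnorm(nrow(base), 0, sig)
    out[order(out$resno), c("resno", "aa", "elety", "x", "y", "z")]
  })
  structure(list(models = models, source_id = "synthetic_ensemble"),
            class = "structure_ensemble")
}
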