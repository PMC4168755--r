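# Geometry engine: Kabsch superposition, ensemble RMSD, restraint-violation
# scoring and the coarse-grained Calpha topology reconstruction.

.atom_class_mask <- function(elety, atom_class) {
  switch(atom_class,
    backbone = elety %in% c("N", "CA", "C", "O"),
    ca_only = elety == "CA",
    heavy = !grepl("^[0-9]*H", elety),
    all = rep(TRUE, length(elety)),
    stop("unknown atom class: ", atom_class))
}

.model_xyz <- function(model) as.matrix(model[, c("x", "y", "z")])

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` (determinant +1) and translation `t`
#' minimizing the RMSD between `R %*% mobile + t` and `target` over paired
#' atoms, via the SVD of the covariance matrix.
#'
#' @param mobile,target N x 3 coordinate matrices with matched rows
#'   (N >= 3, not collinear).
#' @return list with `R` (3 x 3), `t` (length 3) and `rmsd` (post-fit, in
#'   the coordinate units).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, ncol(target) == 3,
            nrow(mobile) == nrow(target))
  if (nrow(mobile) < 3) stop("need at least 3 atoms to superpose")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  s <- svd(crossprod(A, B))
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("selection is (near-)collinear; superposition is degenerate")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tvec <- ct - as.vector(R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, tvec, `+`)
  list(R = R, t = tvec, rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

#' Apply a superposition transform to coordinates
#' @param xyz N x 3 matrix.
#' @param fit result of [superpose()].
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(xyz, fit)
  sweep(as.matrix(xyz) %*% t(fit$R), 2, fit$t, `+`)

#' Average ensemble RMSD under a residue/atom selection
#'
#' Superposes all models over `selection` residues (atoms of class
#' `selection_atoms`), then reports the spread over atoms of class
#' `report_atoms` within the full residue roster.  Two conventions:
#' \describe{
#'   \item{`"mean"`}{iterative superposition onto the evolving mean
#'     structure (to mean-shift < 1e-6 Angstrom), then the average over
#'     models of the RMSD to the mean;}
#'   \item{`"pairwise"`}{average RMSD over all model pairs, each pair
#'     superposed on the selection.}
#' }
#'
#' @param ens a `structure_ensemble`.
#' @param selection integer vector of residue indices used for the fit
#'   (e.g. `parse_selection("3-7,22-30,90-94,98-107,116-125")`).
#' @param report_atoms `"backbone"`, `"heavy"` or `"all"`.
#' @param selection_atoms atom class used for the fit (default
#'   `"backbone"`).
#' @param method `"mean"` or `"pairwise"`.
#' @return average RMSD in Angstrom.
#' @export
ensemble_rmsd <- function(ens, selection, report_atoms = c("backbone", "heavy", "all"),
                          selection_atoms = "backbone",
                          method = c("mean", "pairwise")) {
  report_atoms <- match.arg(report_atoms)
  method <- match.arg(method)
  if (length(ens$models) < 2) stop("need at least 2 models")
  ref <- ens$models[[1]]
  fit_mask <- ref$resno %in% selection &
    .atom_class_mask(ref$elety, selection_atoms)
  if (sum(fit_mask) < 3) stop("selection matches fewer than 3 atoms")
  rep_mask <- .atom_class_mask(ref$elety, report_atoms)
  xyz <- lapply(ens$models, .model_xyz)

  if (method == "pairwise") {
    nm <- length(xyz)
    tot <- 0; np <- 0
    for (i in seq_len(nm - 1)) for (j in (i + 1):nm) {
      fit <- superpose(xyz[[j]][fit_mask, ], xyz[[i]][fit_mask, ])
      moved <- apply_transform(xyz[[j]], fit)
      tot <- tot + sqrt(mean(rowSums((moved[rep_mask, ] - xyz[[i]][rep_mask, ])^2)))
      np <- np + 1
    }
    return(tot / np)
  }

  # iterative superposition to the evolving mean over the fit selection
  cur <- xyz
  mean_sel <- cur[[1]][fit_mask, ]
  for (it in 1:100) {
    cur <- lapply(cur, function(m) {
      fit <- superpose(m[fit_mask, ], mean_sel)
      apply_transform(m, fit)
    })
    new_mean <- Reduce(`+`, lapply(cur, function(m) m[fit_mask, ])) / length(cur)
    shift <- sqrt(mean(rowSums((new_mean - mean_sel)^2)))
    mean_sel <- new_mean
    if (shift < 1e-6) break
  }
  mean_all <- Reduce(`+`, cur) / length(cur)
  mean(vapply(cur, function(m)
    sqrt(mean(rowSums((m[rep_mask, ] - mean_all[rep_mask, ])^2))), 0))
}

.ca_coords <- function(model) {
  if (is.data.frame(model) && "elety" %in% names(model))
    model <- model[model$elety == "CA", , drop = FALSE]
  if (is.data.frame(model)) {
    xyz <- as.matrix(model[, c("x", "y", "z")])
    rownames(xyz) <- model$resno
  } else {
    xyz <- as.matrix(model)
    if (is.null(rownames(xyz))) rownames(xyz) <- seq_len(nrow(xyz))
  }
  xyz
}

#' Score PRE restraint violations against a model
#'
#' Uses the Calpha-Calpha distance between the label-site residue and the
#' restrained residue as a proxy for the label-amide distance; to absorb
#' the nitroxide linker, bounds are widened by `linker_pad` on both sides.
#' Violation per restraint: `max(0, d - upper - pad) +
#' max(0, lower - pad - d)`; `upper_only` entries contribute only the
#' first term.  Restraints on residues absent from the model are listed
#' as unscorable rather than fatal.
#'
#' @param model Calpha model: data frame (`resno`, `x`, `y`, `z`, or full
#'   atom table with `elety`) or an N x 3 matrix with residue rownames.
#' @param restraints restraint data frame (classes `unrestrained` and
#'   `vanished` are ignored).
#' @param linker_pad bound widening in Angstrom (default 3).
#' @return list: `n_scored`, `n_violated`, `sum_violation` (Angstrom),
#'   `per_restraint` data frame, `unscorable` (residue indices).
#' @export
restraint_violations <- function(model, restraints, linker_pad = 3) {
  xyz <- .ca_coords(model)
  act <- restraints[restraints$class %in% c("bounded", "upper_only"), ,
                    drop = FALSE]
  have <- rownames(xyz)
  ok <- as.character(act$site) %in% have & as.character(act$residue) %in% have
  unscorable <- act$residue[!ok]
  act <- act[ok, , drop = FALSE]
  if (nrow(act) == 0)
    return(list(n_scored = 0L, n_violated = 0L, sum_violation = 0,
                per_restraint = data.frame(), unscorable = unscorable))
  d <- sqrt(rowSums((xyz[as.character(act$site), , drop = FALSE] -
                     xyz[as.character(act$residue), , drop = FALSE])^2))
  up <- act$upper + linker_pad
  lo <- ifelse(act$class == "bounded", pmax(act$lower - linker_pad, 0), 0)
  viol <- pmax(0, d - up) + pmax(0, lo - d)
  list(n_scored = nrow(act), n_violated = sum(viol > 0),
       sum_violation = sum(viol),
       per_restraint = data.frame(site = act$site, residue = act$residue,
                                  d_model = d, violation = viol),
       unscorable = unscorable)
}

# Build the energy-term lists consumed by the C++ core.  Bounded restraints
# contribute a flat-bottom well plus a weak harmonic pull toward the
# converted distance d (the mid-well point estimate): the well dominates,
# while the pull selects the most probable point among the many
# zero-violation structures the wide wells admit.
.build_terms <- function(n_res, restraints, helices,
                         k_chain = 10, k_helix = 5, k_restraint = 1,
                         linker_pad = 3, center_weight = 0.2) {
  pi <- pj <- integer(0); d0 <- lo <- hi <- w <- numeric(0); type <- integer(0)
  add <- function(i, j, tgt, l, h, wt, ty) {
    pi <<- c(pi, i - 1L); pj <<- c(pj, j - 1L)
    d0 <<- c(d0, tgt); lo <<- c(lo, l); hi <<- c(hi, h)
    w <<- c(w, wt); type <<- c(type, ty)
  }
  i <- seq_len(n_res - 1)
  for (k in i) add(k, k + 1L, 3.8, 0, 0, k_chain, 0L)
  if (!is.null(helices) && nrow(helices) > 0) {
    for (s in seq_len(nrow(helices))) {
      a <- helices$start[s]; b <- helices$end[s]
      if (b - a >= 3)
        for (k in a:(b - 3)) add(k, k + 3L, 5.1, 0, 0, k_helix, 0L)
      if (b - a >= 4)
        for (k in a:(b - 4)) add(k, k + 4L, 6.2, 0, 0, k_helix, 0L)
    }
  }
  if (!is.null(restraints) && nrow(restraints) > 0) {
    act <- restraints[restraints$class %in% c("bounded", "upper_only"), ,
                      drop = FALSE]
    for (k in seq_len(nrow(act))) {
      l <- if (act$class[k] == "bounded") max(act$lower[k] - linker_pad, 0) else 0
      add(act$site[k], act$residue[k], 0,
          l, act$upper[k] + linker_pad, k_restraint, 1L)
      if (act$class[k] == "bounded" && center_weight > 0)
        add(act$site[k], act$residue[k], act$d[k], 0, 0,
            k_restraint * center_weight, 0L)
    }
  }
  list(pi = pi, pj = pj, d0 = d0, lo = lo, hi = hi, w = w, type = type)
}

.random_coil_start <- function(n_res, step = 3.8) {
  x <- matrix(0, n_res, 3)
  for (i in 2:n_res) {
    v <- rnorm(3)
    x[i, ] <- x[i - 1, ] + step * v / sqrt(sum(v^2))
  }
  x
}

#' Reconstruct a Calpha topology from PRE restraints and helix segments
#'
#' Coarse-grained stand-in for an all-atom simulated-annealing structure
#' calculation.  Minimizes
#' `E = sum(flat-bottom restraint terms) + sum(chain terms, target 3.8 A) +
#' sum(helix i,i+3 / i,i+4 terms, targets 5.1 / 6.2 A)` by simulated
#' annealing from random-coil starts (geometric cooling, single-bead
#' Gaussian moves), followed by an L-BFGS-B polish on the same energy.
#' Undeclared regions (e.g. a long unstructured loop) carry chain terms
#' only.  Runs are exactly reproducible for a fixed `seed`.
#'
#' Distance-only information cannot fix chirality: any solution and its
#' mirror image fit the restraints equally well, so recovery against a
#' reference should always be assessed mirror-corrected (see
#' [ca_rmsd_to()]).
#'
#' @param restraints restraint data frame from [build_restraints()].
#' @param helices segment data frame (`start`, `end`).
#' @param n_res number of residues.
#' @param n_restarts independent annealing runs (default 10).
#' @param n_keep number of lowest-energy models returned (default 5).
#' @param steps annealing steps per restart (default 50000).
#' @param t0,t_end initial/final temperature (default 50 / 0.01).
#' @param step_size move amplitude at `t0`, Angstrom (default 2).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param linker_pad restraint-bound widening, Angstrom (default 3; set to
#'   0 when restraints were simulated with the label at the Calpha, i.e.
#'   with no linker to absorb).
#' @param center_weight relative weight of the harmonic pull toward each
#'   bounded restraint's distance estimate (default 0.2; 0 disables).
#' @return list of class `topology_models`: `models` (list of N x 3
#'   Calpha matrices, energy-ranked), `energies`, `traces` (best-so-far
#'   energy traces), `low_confidence` flag (no long-range restraints).
#' @export
reconstruct_topology <- function(restraints, helices, n_res,
                                 n_restarts = 10L, n_keep = 5L,
                                 steps = 50000L, t0 = 50, t_end = 0.01,
                                 step_size = 2, seed = 1L, linker_pad = 3,
                                 center_weight = 0.2) {
  stopifnot(n_res >= 5)
  if (!is.null(helices) && nrow(helices) > 0 &&
      (min(helices$start) < 1 || max(helices$end) > n_res))
    stop("helices outside sequence bounds")
  act <- if (is.null(restraints)) data.frame() else
    restraints[restraints$class %in% c("bounded", "upper_only"), , drop = FALSE]
  long_range <- nrow(act) > 0 && any(abs(act$site - act$residue) > 4)
  low_conf <- !long_range
  if (low_conf)
    warning("no long-range restraints: reconstruction is low-confidence")
  if (nrow(act) > 0 && length(unique(act$site)) < 2)
    warning("fewer than 2 spin-label sites represented")

  tm <- .build_terms(n_res, restraints, helices, linker_pad = linker_pad,
                     center_weight = center_weight)
  set.seed(seed)
  runs <- lapply(seq_len(n_restarts), function(r) {
    start <- .random_coil_start(n_res)
    out <- .anneal_cpp(start, tm$pi, tm$pj, tm$d0, tm$lo, tm$hi, tm$w,
                       tm$type, as.integer(steps), t0, t_end, step_size)
    # deterministic quasi-Newton polish on the same energy surface
    efun <- function(v) .energy_cpp(matrix(v, ncol = 3), tm$pi, tm$pj,
                                    tm$d0, tm$lo, tm$hi, tm$w, tm$type)
    gfun <- function(v) as.vector(.gradient_cpp(matrix(v, ncol = 3), tm$pi,
                                                tm$pj, tm$d0, tm$lo, tm$hi,
                                                tm$w, tm$type))
    pol <- optim(as.vector(out$coords), efun, gfun, method = "L-BFGS-B",
                 control = list(maxit = 500))
    coords <- matrix(pol$par, ncol = 3)
    rownames(coords) <- seq_len(n_res)
    list(coords = coords, energy = pol$value, trace = out$trace)
  })
  ord <- order(vapply(runs, `[[`, 0, "energy"))
  keep <- ord[seq_len(min(n_keep, length(runs)))]
  structure(list(models = lapply(runs[keep], `[[`, "coords"),
                 energies = vapply(runs[keep], `[[`, 0, "energy"),
                 traces = lapply(runs[keep], `[[`, "trace"),
                 low_confidence = low_conf),
            class = "topology_models")
}

#' @export
print.topology_models <- function(x, ...) {
  cat("topology_models: ", length(x$models), " model(s), energies ",
      paste(signif(x$energies, 4), collapse = ", "),
      if (x$low_confidence) " [LOW CONFIDENCE]", "\n", sep = "")
  invisible(x)
}

#' Mirror a Calpha model (invert chirality)
#' @param xyz N x 3 matrix.
#' @return mirrored matrix.
#' @export
mirror_model <- function(xyz) {
  out <- as.matrix(xyz)
  out[, 1] <- -out[, 1]
  out
}

#' Superposed Calpha RMSD of a model to a reference
#'
#' Superposes over `residues` and reports the RMSD there.  With
#' `mirror_correct = TRUE` (default) the minimum over the model and its
#' mirror image is returned, which is the appropriate metric for
#' distance-restraint-only reconstructions.
#'
#' @param model,ref N x 3 Calpha matrices with residue rownames (or plain
#'   matrices with implicit 1..N numbering).
#' @param residues residue indices to fit/report over (default: all
#'   shared).
#' @param mirror_correct take the minimum over the mirror image.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd_to <- function(model, ref, residues = NULL, mirror_correct = TRUE) {
  m <- .ca_coords(model); r <- .ca_coords(ref)
  if (is.null(residues)) residues <- intersect(rownames(m), rownames(r))
  residues <- as.character(residues)
  one <- function(mm) superpose(mm[residues, ], r[residues, ])$rmsd
  if (mirror_correct) min(one(m), one(mirror_model(m))) else one(m)
}

#' Write ranked Calpha models as a multi-model PDB file
#'
#' @param models `topology_models` or a list of N x 3 matrices.
#' @param path output path.
#' @param aa optional one-letter sequence for residue names.
#' @export
write_ca_pdb <- function(models, path, aa = NULL) {
  if (inherits(models, "topology_models")) models <- models$models
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- models[[m]]
    resn <- if (is.null(aa)) rep("ALA", nrow(xyz)) else AA3[strsplit(aa, "")[[1]]]
    for (i in seq_len(nrow(xyz)))
      writeLines(sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                         i, resn[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
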