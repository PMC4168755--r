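# Pipeline orchestration: a single YAML-serializable config drives the
# stages shift -> PRE -> dynamics -> amphiphilicity -> reconstruction ->
# ensemble analysis over a study directory of TSV/FASTA/PDB inputs, and a
# synthetic-study generator writes exactly the files the pipeline reads.

#' Default pipeline configuration
#'
#' Every stage parameter with its default; the config round-trips through
#' YAML.  `stages` toggles individual stages; paths are interpreted
#' relative to the study directory.
#'
#' @param ... named overrides for top-level entries (nested lists are
#'   replaced wholesale).
#' @return nested list of class `nmrtopo_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    stages = list(shifts = TRUE, pre = TRUE, dynamics = TRUE,
                  amphi = TRUE, reconstruct = TRUE, ensemble = FALSE),
    shifts = list(file = "shifts_micelle.tsv", threshold = 1.4,
                  min_len = 4L, max_gap = 1L),
    pre = c(list(file_pattern = "pre_site%d.tsv", sites = default_label_sites()),
            pre_params()),
    dynamics = list(hnoe_file = "hnoe_micelle.tsv", cpmg_file = "cpmg.tsv",
                    cpmg_ref_file = "cpmg_ref.tsv",
                    titration_file = "titration.tsv",
                    t_cp = 0.050, flag_moderate = 2, flag_strong = 6,
                    access_cutoff = 0.5),
    amphi = list(fasta = "sequence.fasta", tm_window = 19L,
                 tm_threshold = 1.0, moment_window = 11L, delta = 100,
                 mu_threshold = 0.35),
    reconstruct = list(n_restarts = 10L, n_keep = 5L, steps = 50000L,
                       t0 = 50, t_end = 0.01, step_size = 2),
    ensemble = list(file = "ensemble.pdb",
                    selection = "3-7,22-30,90-94,98-107,116-125"))
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- c("nmrtopo_config", "list")
  cfg
}

#' Read / write a pipeline config as YAML
#' @param path YAML file.
#' @return config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]]))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  base
}

#' @rdname read_config
#' @param cfg config list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Generate a complete synthetic study directory
#'
#' Writes every input the pipeline reads, simulated from a paper-shaped
#' ground-truth bundle: micelle and water shift tables, one PRE intensity
#' table per spin-label site, hNOE tables for both conditions, a CPMG
#' series with reference plane (two exchange-free control residues and
#' two fast-exchange residues), titration ratios, the sequence FASTA, a
#' truth Calpha PDB, the truth helix table and the config itself.
#'
#' @param dir output directory (created).
#' @param seed master seed; each simulator derives its own stream.
#' @param truth optional `ground_truth` (default: paper-shaped
#'   [make_bundle()]).
#' @param noise list of noise levels: `shift`, `pre`, `cpmg`, `hnoe`.
#' @return the ground truth, invisibly.
#' @export
generate_study <- function(dir, seed = 1L, truth = NULL,
                           noise = list(shift = 0.2, pre = 0.02,
                                        cpmg = 0.01, hnoe = 0.05)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(truth)) truth <- make_bundle(seed = seed)
  p <- function(f) file.path(dir, f)

  write_shift_table(simulate_shifts(truth, noise_sigma = noise$shift,
                                    seed = seed + 10, condition = "DPC"),
                    p("shifts_micelle.tsv"))
  water <- simulate_shifts(truth, helix_offset = 0, noise_sigma = noise$shift,
                           seed = seed + 11, condition = "water")
  write_shift_table(water, p("shifts_water.tsv"))

  for (s in truth$label_sites) {
    pm <- simulate_pre(truth, s, noise_sigma = noise$pre, seed = seed + 20)
    write.table(format(pm, digits = 10), p(sprintf("pre_site%d.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  mic <- hnoe_preset("micelle")
  ht <- simulate_hnoe_and_titration(truth, mic$rigid_mean, mic$flexible_mean,
                                    noise = noise$hnoe, seed = seed + 30)
  write.table(format(ht$hnoe[, c("residue", "i_sat", "i_ref")], digits = 10),
              p("hnoe_micelle.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  wat <- hnoe_preset("water")
  hw <- simulate_hnoe_and_titration(truth, wat$rigid_mean, wat$flexible_mean,
                                    noise = wat$noise, seed = seed + 31)
  write.table(format(hw$hnoe[, c("residue", "i_sat", "i_ref")], digits = 10),
              p("hnoe_water.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tit <- data.frame(residue = rep(seq_len(truth$n_res), 2),
                    probe = rep(c("gadodiamide", "mn"), each = truth$n_res),
                    ratio = c(ht$gado_ratios, ht$mn_ratios))
  write.table(format(tit, digits = 10), p("titration.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # CPMG: exchange-free controls plus two dispersive residues mimicking the
  # mid-loop exchange cluster
  cp_res <- list(`20` = NULL, `50` = NULL,
                 `70` = list(p_minor = 0.05, delta_omega = 1200, k_ex = 2000),
                 `76` = list(p_minor = 0.03, delta_omega = 1100, k_ex = 2500))
  rows <- list(); refs <- list()
  for (rn in names(cp_res)) {
    sim <- simulate_cpmg(cp_res[[rn]], noise_sigma = noise$cpmg,
                         seed = seed + 40 + as.integer(rn))
    rows[[rn]] <- cbind(residue = as.integer(rn), sim$series)
    refs[[rn]] <- data.frame(residue = as.integer(rn), i0 = sim$i0,
                             t_cp = sim$t_cp)
  }
  write.table(format(do.call(rbind, rows), digits = 10), p("cpmg.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(format(do.call(rbind, refs), digits = 10), p("cpmg_ref.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  write_fasta_seqs(c(synthetic_study = truth$sequence), p("sequence.fasta"))
  write_ca_pdb(list(truth$coords), p("truth_ca.pdb"), aa = truth$sequence)
  write.table(truth$helices, p("truth_helices.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_config(default_config(seed = seed), p("config.yaml"))
  invisible(truth)
}

.read_tsv <- function(path) read.table(path, sep = "\t", header = TRUE,
                                       stringsAsFactors = FALSE)

#' Run the analysis pipeline over a study directory
#'
#' Executes the enabled stages in order (shifts, PRE, dynamics,
#' amphiphilicity, reconstruction, ensemble analysis), writes per-stage
#' TSV outputs and a flat key-value summary into `out_dir`, and returns
#' the run report.  Identical config + inputs give an identical report.
#' A failing stage aborts with an error naming the completed stages.
#'
#' @param config config list (see [default_config()]) or path to a YAML
#'   config.
#' @param dir study directory holding the input files.
#' @param out_dir output directory (default `file.path(dir, "out")`).
#' @return run report: nested list of stage summaries plus provenance
#'   (config hash, seed).
#' @export
run_pipeline <- function(config = default_config(), dir,
                         out_dir = file.path(dir, "out")) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  done <- character(0)
  report <- list(provenance = list(config_hash = .config_hash(config),
                                   seed = config$seed))
  fail <- function(stage, e)
    stop("stage '", stage, "' failed after [",
         paste(done, collapse = ", "), "]: ", conditionMessage(e),
         call. = FALSE)

  # stages consume each other's outputs through these locals
  segments <- NULL; restraints <- NULL

  if (isTRUE(config$stages$shifts)) {
    tryCatch({
      sc <- config$shifts
      if (!file.exists(p(sc$file))) stop("missing input file: ", sc$file)
      shifts <- read_shift_table(p(sc$file))
      prof <- secondary_shifts(shifts)
      segments <- call_helices(prof, sc$threshold, sc$min_len, sc$max_gap)
      write.table(shift_report(prof, segments), file.path(out_dir, "shifts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(segments, file.path(out_dir, "helix_segments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$shifts <- list(n_helices = nrow(segments), segments = segments)
    }, error = function(e) fail("shifts", e))
    done <- c(done, "shifts")
  }

  if (isTRUE(config$stages$pre)) {
    tryCatch({
      pc <- config$pre
      params <- do.call(pre_params, pc[names(pre_params())])
      pieces <- lapply(pc$sites, function(s) {
        f <- p(sprintf(pc$file_pattern, s))
        if (!file.exists(f)) stop("missing input file: ", basename(f))
        suppressMessages(build_restraints(.read_tsv(f), s, params))
      })
      restraints <- do.call(rbind, pieces)
      write_restraints(restraints, file.path(out_dir, "restraints.tsv"), "tsv")
      qc <- restraint_qc(restraints)
      write.table(qc, file.path(out_dir, "restraint_qc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$pre <- list(n_sites = length(pc$sites), qc = qc,
                         n_restrained = sum(restraints$class %in%
                                              c("bounded", "upper_only")))
    }, error = function(e) fail("pre", e))
    done <- c(done, "pre")
  }

  if (isTRUE(config$stages$dynamics)) {
    tryCatch({
      dc <- config$dynamics
      for (f in c(dc$hnoe_file, dc$cpmg_file, dc$cpmg_ref_file,
                  dc$titration_file))
        if (!file.exists(p(f))) stop("missing input file: ", f)
      hn <- .read_tsv(p(dc$hnoe_file))
      hn_df <- data.frame(residue = hn$residue,
                          hnoe = hnoe(hn$i_sat, hn$i_ref))
      cp <- .read_tsv(p(dc$cpmg_file))
      cpr <- .read_tsv(p(dc$cpmg_ref_file))
      disp <- do.call(rbind, lapply(unique(cp$residue), function(rn) {
        ref <- cpr[cpr$residue == rn, ]
        dd <- dispersion_profile(cp[cp$residue == rn, ], i0 = ref$i0[1],
                                 t_cp = dc$t_cp, dc$flag_moderate,
                                 dc$flag_strong)
        data.frame(residue = rn, delta_r2 = dd$delta_r2,
                   exchange_flag = dd$exchange_flag)
      }))
      tit <- .read_tsv(p(dc$titration_file))
      g <- tit[tit$probe == "gadodiamide", ]
      m <- tit[tit$probe == "mn", ]
      acc <- classify_accessibility(setNames(g$ratio, g$residue),
                                    setNames(m$ratio, m$residue),
                                    dc$access_cutoff)
      dyn <- dynamics_table(hn_df, disp, acc)
      write.table(dyn, file.path(out_dir, "dynamics.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$dynamics <- list(
        mean_hnoe = mean(hn_df$hnoe),
        n_exchange = sum(disp$exchange_flag %in% c("moderate", "strong")),
        accessibility_counts = as.list(table(acc$class)))
    }, error = function(e) fail("dynamics", e))
    done <- c(done, "dynamics")
  }

  if (isTRUE(config$stages$amphi)) {
    tryCatch({
      ac <- config$amphi
      if (!file.exists(p(ac$fasta))) stop("missing input file: ", ac$fasta)
      seq <- read_fasta_seq(p(ac$fasta))
      tm <- tm_screen(seq, ac$tm_window, ac$tm_threshold)
      mp <- moment_profile(seq, window = ac$moment_window, delta = ac$delta)
      segs <- detect_amphiphilic_segments(mp, ac$mu_threshold)
      prof <- merge(tm$profile, mp, by = "position", all = TRUE)
      write.table(prof, file.path(out_dir, "amphiphilicity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(segs, file.path(out_dir, "amphiphilic_segments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$amphi <- list(tm_peak = tm$peak_position,
                           n_tm_segments = nrow(tm$segments),
                           amphiphilic_segments = segs)
    }, error = function(e) fail("amphi", e))
    done <- c(done, "amphi")
  }

  if (isTRUE(config$stages$reconstruct)) {
    tryCatch({
      if (is.null(restraints)) stop("reconstruction requires the pre stage")
      rc <- config$reconstruct
      n_res <- max(restraints$residue, restraints$site,
                   if (!is.null(segments)) segments$end else 0)
      models <- reconstruct_topology(
        restraints, segments, n_res, n_restarts = rc$n_restarts,
        n_keep = rc$n_keep, steps = rc$steps, t0 = rc$t0, t_end = rc$t_end,
        step_size = rc$step_size, seed = config$seed)
      write_ca_pdb(models, file.path(out_dir, "reconstructed.pdb"))
      viol <- restraint_violations(models$models[[1]], restraints)
      report$reconstruct <- list(energies = models$energies,
                                 low_confidence = models$low_confidence,
                                 n_violated = viol$n_violated)
    }, error = function(e) fail("reconstruct", e))
    done <- c(done, "reconstruct")
  }

  if (isTRUE(config$stages$ensemble)) {
    tryCatch({
      ec <- config$ensemble
      if (!file.exists(p(ec$file))) stop("missing input file: ", ec$file)
      ens <- read_ensemble(p(ec$file))
      sel <- parse_selection(ec$selection)
      report$ensemble <- list(
        n_models = n_models(ens),
        rmsd_backbone = ensemble_rmsd(ens, sel, "backbone"),
        rmsd_heavy = ensemble_rmsd(ens, sel, "heavy"),
        rmsd_all = ensemble_rmsd(ens, sel, "all"))
    }, error = function(e) fail("ensemble", e))
    done <- c(done, "ensemble")
  }

  report$stages_run <- done
  .write_summary(report, file.path(out_dir, "summary.txt"))
  report
}

# flatten the report to stable key=value lines
.write_summary <- function(report, path) {
  out <- character(0)
  emit <- function(prefix, x) {
    if (is.data.frame(x)) {
      out <<- c(out, paste0(prefix, ".n=", nrow(x)))
    } else if (is.list(x)) {
      for (nm in names(x)) emit(paste0(prefix, ".", nm), x[[nm]])
    } else {
      out <<- c(out, paste0(prefix, "=",
                            paste(format(x, digits = 10), collapse = ",")))
    }
  }
  for (nm in names(report)) emit(nm, report[[nm]])
  writeLines(out, path)
  invisible(path)
}
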