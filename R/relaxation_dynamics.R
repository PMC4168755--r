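# Backbone dynamics: heteronuclear NOE, CPMG relaxation dispersion and
# paramagnetic-probe accessibility classification.

#' Heteronuclear steady-state NOE
#'
#' `hnoe = i_sat / i_ref` from the saturated and reference spectra.  No
#' clamping: negative values are meaningful and indicate large-amplitude
#' sub-nanosecond motions.
#'
#' @param i_sat,i_ref peak intensities with and without proton
#'   presaturation (`i_ref != 0`).
#' @return dimensionless hNOE value(s).
#' @export
hnoe <- function(i_sat, i_ref) {
  if (any(i_ref == 0)) stop("i_ref must be non-zero")
  i_sat / i_ref
}

#' Effective transverse relaxation rate from a constant-time CPMG point
#'
#' `R2eff = -ln(I(nu_cpmg) / I0) / T_CP` with a reference plane acquired
#' without the CPMG block.
#'
#' @param intensity peak intensity at a CPMG frequency (> 0 to be
#'   quantifiable).
#' @param i0 reference-plane intensity (> 0).
#' @param t_cp constant-time relaxation delay in seconds (default 0.050).
#' @return rate(s) in s^-1; `NA` where the peak has vanished
#'   (`intensity <= 0`), which is reported rather than thrown at pipeline
#'   level.
#' @export
r2eff <- function(intensity, i0, t_cp = 0.050) {
  stopifnot(t_cp > 0)
  if (any(i0 <= 0)) stop("reference intensity i0 must be > 0")
  out <- rep(NA_real_, length(intensity))
  ok <- intensity > 0
  out[ok] <- -log(intensity[ok] / i0) / t_cp
  out
}

#' CPMG frequency schedule of the study design
#'
#' 40-960 Hz with the 120 Hz point acquired in duplicate.
#'
#' @return numeric vector of nu_CPMG values (Hz).
#' @export
default_cpmg_nus <- function()
  c(40, 80, 120, 120, 160, 200, 240, 320, 400, 480, 560, 640, 720, 800, 960)

#' Per-residue dispersion profile and exchange flag
#'
#' Converts a constant-time CPMG intensity series to `R2eff(nu)`
#' (duplicated frequencies are averaged on the intensity scale before
#' conversion), computes the dispersion amplitude
#' `delta_r2 = R2eff(low) - R2eff(high)` between the 80 and 960 Hz points,
#' and assigns a two-tier exchange flag:
#' `none` (`delta_r2 <= flag_moderate`), `moderate`
#' (`flag_moderate < delta_r2 <= flag_strong`) or `strong`
#' (`delta_r2 > flag_strong`); defaults 2 and 6 s^-1.
#'
#' @param series data frame with columns `nu` (Hz) and `intensity` for one
#'   residue.
#' @param i0 reference-plane intensity.
#' @param t_cp constant-time delay (s).
#' @param flag_moderate,flag_strong flag thresholds in s^-1.
#' @param nu_low,nu_high frequencies used for `delta_r2` (80 and 960 Hz).
#' @return list with `r2eff` (data frame `nu`, `r2eff`), `delta_r2` (s^-1
#'   or `NA`) and `exchange_flag` (`"none"`, `"moderate"`, `"strong"` or
#'   `"unobserved"` when either anchor frequency is missing or
#'   unquantifiable).
#' @export
dispersion_profile <- function(series, i0, t_cp = 0.050,
                               flag_moderate = 2, flag_strong = 6,
                               nu_low = 80, nu_high = 960) {
  stopifnot(all(c("nu", "intensity") %in% names(series)),
            all(series$nu > 0), flag_strong >= flag_moderate)
  nus <- sort(unique(series$nu))
  mean_int <- vapply(nus, function(v) mean(series$intensity[series$nu == v]), 0)
  rr <- r2eff(mean_int, i0, t_cp)
  prof <- data.frame(nu = nus, r2eff = rr)
  lo <- prof$r2eff[match(nu_low, prof$nu)]
  hi <- prof$r2eff[match(nu_high, prof$nu)]
  if (length(lo) == 0 || length(hi) == 0 || is.na(lo) || is.na(hi)) {
    delta <- NA_real_; flag <- "unobserved"
  } else {
    delta <- lo - hi
    flag <- if (delta > flag_strong) "strong"
            else if (delta > flag_moderate) "moderate" else "none"
  }
  list(r2eff = prof, delta_r2 = delta, exchange_flag = flag)
}

#' Classify residue accessibility from paramagnetic titrations
#'
#' Endpoint attenuation ratios from two probes: gadodiamide (confined to
#' bulk water) and Mn2+ (also reaches the micelle head-group layer).
#' A residue attenuated by gadodiamide (`ratio < cutoff`) is
#' `water_exposed` (gadodiamide takes precedence); otherwise attenuation by
#' Mn2+ places it in the `headgroup` layer; a residue attenuated by
#' neither is `buried_or_bonded` (hydrocarbon phase or hydrogen-bond
#' protected).  Residues absent from both maps are `unobserved`.
#'
#' @param gado_ratios,mn_ratios named numeric vectors (names = residue
#'   indices) of endpoint/reference intensity ratios.
#' @param cutoff attenuation cutoff in (0, 1), default 0.5.
#' @param residues optional full residue roster; defaults to the union of
#'   the two maps.
#' @return data frame `residue`, `class`.
#' @export
classify_accessibility <- function(gado_ratios, mn_ratios, cutoff = 0.5,
                                   residues = NULL) {
  stopifnot(cutoff > 0, cutoff < 1)
  gn <- as.integer(names(gado_ratios)); mn <- as.integer(names(mn_ratios))
  if (is.null(residues)) residues <- sort(union(gn, mn))
  g <- unname(gado_ratios)[match(residues, gn)]
  m <- unname(mn_ratios)[match(residues, mn)]
  cls <- ifelse(is.na(g) & is.na(m), "unobserved",
         ifelse(!is.na(g) & g < cutoff, "water_exposed",
         ifelse(!is.na(m) & m < cutoff, "headgroup", "buried_or_bonded")))
  data.frame(residue = as.integer(residues), class = cls,
             stringsAsFactors = FALSE)
}

#' Combined per-residue dynamics table
#'
#' Convenience assembler joining hNOE values, dispersion flags and
#' accessibility classes on the residue index.
#'
#' @param hnoe_df data frame `residue`, `hnoe` (or `NULL`).
#' @param disp_df data frame `residue`, `delta_r2`, `exchange_flag` (or
#'   `NULL`).
#' @param acc_df data frame `residue`, `class` (or `NULL`).
#' @return merged data frame keyed by `residue`.
#' @export
dynamics_table <- function(hnoe_df = NULL, disp_df = NULL, acc_df = NULL) {
  pieces <- Filter(Negate(is.null), list(hnoe_df, disp_df, acc_df))
  if (length(pieces) == 0) return(data.frame(residue = integer()))
  out <- Reduce(function(a, b) merge(a, b, by = "residue", all = TRUE), pieces)
  if ("class" %in% names(out))
    names(out)[names(out) == "class"] <- "accessibility"
  out[order(out$residue), , drop = FALSE]
}
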