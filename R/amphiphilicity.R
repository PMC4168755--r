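# Sequence amphiphilicity: windowed hydropathy, Eisenberg hydrophobic
# moment, amphiphilic-segment detection and cross-protein comparison.

.seq_chars <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  check_aa(s[s != "X"])
  s
}

.scale_values <- function(chars, scale) {
  v <- scale[chars]
  if (anyNA(v))
    stop("residue(s) not covered by the scale: ",
         paste(unique(chars[is.na(v)]), collapse = ", "))
  unname(v)
}

#' Sliding-window mean hydropathy profile
#'
#' Arithmetic mean of per-residue scale values over a sliding window;
#' positions are reported at the window centre.
#'
#' @param seq sequence string.
#' @param scale a [hydropathy_scale()] (or any named vector over the
#'   20 residues).
#' @param window odd window length, `3 <= window <= nchar(seq)`.
#' @return data frame `position` (window centre, 1-based), `mean_h`, with
#'   attributes `window` and `scale_name`.
#' @export
windowed_hydropathy <- function(seq, scale = hydropathy_scale("kd"),
                                window = 19L) {
  chars <- .seq_chars(seq)
  n <- length(chars)
  stopifnot(window %% 2 == 1, window >= 3, window <= n)
  h <- .scale_values(chars, scale)
  cs <- cumsum(c(0, h))
  starts <- seq_len(n - window + 1)
  mean_h <- (cs[starts + window] - cs[starts]) / window
  out <- data.frame(position = starts + (window - 1L) %/% 2L, mean_h = mean_h)
  attr(out, "window") <- window
  attr(out, "scale_name") <- attr(scale, "scale_name")
  out
}

#' Hydrophobic moment of a single sequence window
#'
#' Eisenberg helical-wheel vector sum,
#' \deqn{\mu_H = \sqrt{\left(\sum_n H_n \sin n\delta\right)^2 +
#'                     \left(\sum_n H_n \cos n\delta\right)^2},}
#' reported per residue (`mu_h / N`) so windows of different lengths are
#' comparable.  `delta = 100` degrees/residue corresponds to the
#' alpha-helix; 160 degrees probes beta-strand periodicity.
#'
#' @param seq_window sequence string (the window itself).
#' @param scale hydropathy scale.
#' @param delta angular step in degrees per residue (default 100).
#' @return per-residue hydrophobic moment (same units as the scale).
#' @export
hydrophobic_moment <- function(seq_window, scale = hydropathy_scale("eisenberg"),
                               delta = 100) {
  chars <- .seq_chars(seq_window)
  stopifnot(length(chars) >= 1)
  h <- .scale_values(chars, scale)
  ang <- seq_along(h) * delta * pi / 180
  sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / length(h)
}

#' Sliding-window hydrophobic-moment profile
#'
#' @inheritParams windowed_hydropathy
#' @param delta degrees per residue (default 100, alpha-helix).
#' @return data frame `position` (window centre), `mu_h` (per residue),
#'   with attributes `window`, `delta`, `scale_name`.
#' @export
moment_profile <- function(seq, scale = hydropathy_scale("eisenberg"),
                           window = 11L, delta = 100) {
  chars <- .seq_chars(seq)
  n <- length(chars)
  stopifnot(window %% 2 == 1, window >= 3, window <= n)
  h <- .scale_values(chars, scale)
  ang <- seq_len(n) * delta * pi / 180
  s <- h * sin(ang); cc <- h * cos(ang)
  css <- cumsum(c(0, s)); csc <- cumsum(c(0, cc))
  starts <- seq_len(n - window + 1)
  mu <- sqrt((css[starts + window] - css[starts])^2 +
             (csc[starts + window] - csc[starts])^2) / window
  out <- data.frame(position = starts + (window - 1L) %/% 2L, mu_h = mu)
  attr(out, "window") <- window
  attr(out, "delta") <- delta
  attr(out, "scale_name") <- attr(scale, "scale_name")
  out
}

#' Detect amphiphilic segments in a moment profile
#'
#' Maximal runs of window centres with `mu_h >= mu_threshold`, assembled
#' with gap tolerance and a minimum run length, reported in sequence
#' coordinates (first to last window centre of the run).
#'
#' @param profile output of [moment_profile()].
#' @param mu_threshold per-residue moment threshold (> 0); the default
#'   0.35 on the Eisenberg scale was calibrated once so the detected
#'   segment structure of the study system matches its known amphiphilic
#'   regions (see the methods vignette).
#' @param min_len minimum run length in residues (default 3).
#' @param max_gap tolerated sub-threshold gap inside a run (default 2).
#' @return segment data frame (`start`, `end`).
#' @export
detect_amphiphilic_segments <- function(profile, mu_threshold = 0.35,
                                        min_len = 3L, max_gap = 2L) {
  stopifnot(mu_threshold > 0)
  .call_runs(profile$position, profile$mu_h >= mu_threshold, min_len, max_gap)
}

#' Compare two hydrophobic-moment profiles
#'
#' Profiles must share scale and angular step.  Each amphiphilic segment of
#' `a` is judged `comparable` to the reference `b` when its peak per-residue
#' moment reaches at least the fraction `f` of `b`'s global peak.
#'
#' @param a,b [moment_profile()] outputs (`b` is the reference).
#' @param f comparability fraction (default 0.9).
#' @param ... passed to [detect_amphiphilic_segments()] for `a`.
#' @return list with `max_a`, `max_b`, a profile-level verdict
#'   `comparable_profile` (`max_a >= f * max_b`), and `segments` (segments
#'   of `a` with their peak moment and per-segment `comparable` flag).
#' @export
compare_profiles <- function(a, b, f = 0.9, ...) {
  if (!identical(attr(a, "scale_name"), attr(b, "scale_name")) ||
      !identical(attr(a, "delta"), attr(b, "delta")))
    stop("profiles computed with different scales or angular steps")
  segs <- detect_amphiphilic_segments(a, ...)
  ref_peak <- max(b$mu_h)
  peak <- vapply(seq_len(nrow(segs)), function(i) {
    inside <- a$position >= segs$start[i] & a$position <= segs$end[i]
    max(a$mu_h[inside])
  }, 0)
  list(max_a = max(a$mu_h), max_b = ref_peak,
       comparable_profile = max(a$mu_h) >= f * ref_peak,
       segments = cbind(segs, peak_mu_h = peak,
                        comparable = peak >= f * ref_peak))
}

#' Transmembrane-propensity screen
#'
#' Windowed mean on the transfer-free-energy (GES) scale with the
#' conventional detection rule: a candidate transmembrane segment is a
#' window whose mean exceeds `threshold` (default 1.0 kcal/mol per
#' residue over a 19-residue window).
#'
#' @param seq sequence string.
#' @param window odd window length (default 19).
#' @param threshold per-residue mean threshold (default 1.0).
#' @param scale transmembrane scale (default [hydropathy_scale()]`("ges")`).
#' @return list with `profile` (windowed means), `peak_position` (centre of
#'   the global maximum), `segments` (windows above threshold merged into
#'   ranges of window centres).
#' @export
tm_screen <- function(seq, window = 19L, threshold = 1.0,
                      scale = hydropathy_scale("ges")) {
  prof <- windowed_hydropathy(seq, scale, window)
  segs <- .call_runs(prof$position, prof$mean_h >= threshold,
                     min_len = 1L, max_gap = 0L)
  list(profile = prof,
       peak_position = prof$position[which.max(prof$mean_h)],
       segments = segs, threshold = threshold)
}
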