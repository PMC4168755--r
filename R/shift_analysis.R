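#' Residue-specific secondary chemical shifts (delta-Ca minus delta-Cb)
#'
#' For each residue computes
#' \deqn{(C\alpha_{obs} - C\alpha_{rc}) - (C\beta_{obs} - C\beta_{rc})}
#' against a random-coil reference table.  Runs of large positive values
#' indicate alpha-helix; large negative runs indicate beta-strand.  For
#' glycine (no Cbeta) the index reduces to the Calpha secondary shift
#' alone.  Residues missing the observed shift needed for a term get `NA`.
#'
#' @param shifts a `shift_table` (see [read_shift_table()]).
#' @param refs random-coil reference table with columns `aa`, `ca`, `cb`;
#'   must cover all residue types present.  Default [random_coil_shifts()].
#' @return data frame `residue`, `aa`, `dca_dcb` with attribute
#'   `reference_set`.
#' @export
secondary_shifts <- function(shifts, refs = random_coil_shifts()) {
  validate_shift_table(shifts)
  m <- match(shifts$aa, refs$aa)
  if (anyNA(m)) {
    missing <- unique(shifts$aa[is.na(m)])
    stop("residue type(s) absent from the reference set: ",
         paste(missing, collapse = ", "))
  }
  dca <- shifts$ca - refs$ca[m]
  dcb <- shifts$cb - refs$cb[m]
  val <- ifelse(shifts$aa == "G", dca, dca - dcb)
  # non-Gly residues need both terms
  val[shifts$aa != "G" & (is.na(dca) | is.na(dcb))] <- NA_real_
  out <- data.frame(residue = shifts$residue, aa = shifts$aa, dca_dcb = val,
                    stringsAsFactors = FALSE)
  attr(out, "reference_set") <-
    if (!is.null(attr(refs, "set"))) attr(refs, "set") else "user"
  out
}

# Shared run-calling engine: maximal runs of positions whose value passes
# `test`, tolerating up to max_gap consecutive failing/absent positions
# inside a run; runs shorter than min_len are dropped.
.call_runs <- function(residue, pass, min_len, max_gap) {
  pass[is.na(pass)] <- FALSE
  hits <- residue[pass]
  if (length(hits) == 0) return(segments_df(integer(), integer()))
  # merge consecutive hit residues whose index gap (in sequence coordinates)
  # leaves at most max_gap non-passing residues between them
  brk <- which(diff(hits) > max_gap + 1)
  starts <- hits[c(1, brk + 1)]
  ends <- hits[c(brk, length(hits))]
  keep <- (ends - starts + 1) >= min_len
  segments_df(starts[keep], ends[keep])
}

#' Call helical segments from a secondary-shift profile
#'
#' Helices are maximal runs of residues with `dca_dcb >= threshold`,
#' tolerating up to `max_gap` consecutive sub-threshold or unobserved
#' residues inside a run; runs shorter than `min_len` are dropped.  With
#' `sense = "strand"` the symmetric rule `dca_dcb <= -threshold` calls
#' extended structure instead (off by default in the pipeline).
#'
#' @param profile output of [secondary_shifts()] (columns `residue`,
#'   `dca_dcb`).
#' @param threshold ppm threshold (> 0); default 1.4.
#' @param min_len minimum segment length; default 4 (>= 3 required).
#' @param max_gap tolerated in-run gap; default 1.
#' @param sense `"helix"` or `"strand"`.
#' @return data frame of segments (`start`, `end`), ascending and
#'   non-overlapping; empty for an empty profile.
#' @export
call_helices <- function(profile, threshold = 1.4, min_len = 4L,
                         max_gap = 1L, sense = c("helix", "strand")) {
  sense <- match.arg(sense)
  stopifnot(threshold > 0, min_len >= 3)
  if (nrow(profile) == 0) return(segments_df(integer(), integer()))
  pass <- if (sense == "helix") profile$dca_dcb >= threshold
          else profile$dca_dcb <= -threshold
  .call_runs(profile$residue, pass, min_len, max_gap)
}

#' Geometric helix caller for a Calpha trace
#'
#' DSSP-free criterion on Calpha geometry alone: a five-residue window is
#' helical when its i,i+2 / i,i+3 / i,i+4 Calpha distances all match ideal
#' alpha-helix geometry (about 5.4, 5.1 and 6.2 Angstrom) within `tol`.
#' Segments are then assembled with the same run logic as
#' [call_helices()].
#'
#' @param ca matrix-like Calpha coordinates: data frame with `resno`, `x`,
#'   `y`, `z` or an N x 3 matrix (residues assumed consecutive).
#' @param tol distance tolerance in Angstrom (default 0.5).
#' @param min_len,max_gap run assembly parameters as in [call_helices()].
#' @return segment data frame (`start`, `end`).
#' @export
call_helices_geometric <- function(ca, tol = 0.5, min_len = 4L,
                                   max_gap = 1L) {
  if (is.data.frame(ca)) {
    resno <- ca$resno
    xyz <- as.matrix(ca[, c("x", "y", "z")])
  } else {
    xyz <- as.matrix(ca)
    resno <- seq_len(nrow(xyz))
  }
  n <- nrow(xyz)
  if (n < 5) return(segments_df(integer(), integer()))
  d <- function(i, j) sqrt(rowSums((xyz[i, , drop = FALSE] -
                                    xyz[j, , drop = FALSE])^2))
  i <- seq_len(n - 4)
  # contiguity in residue numbering required for the window to be meaningful
  contig <- (resno[i + 4] - resno[i]) == 4
  ok <- contig &
    abs(d(i, i + 2) - 5.4) <= tol &
    abs(d(i, i + 3) - 5.1) <= tol &
    abs(d(i, i + 4) - 6.2) <= tol
  # window (i..i+4) helical -> mark all five residues
  helical <- rep(FALSE, n)
  for (k in which(ok)) helical[k:(k + 4)] <- TRUE
  .call_runs(resno, helical, min_len, max_gap)
}

#' Fraction of segment a covered by segment b
#' @keywords internal
segment_overlap_frac <- function(a_start, a_end, b_start, b_end) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
  ov / (a_end - a_start + 1)
}

#' Tabulate a secondary-shift profile with helix flags
#'
#' @param profile output of [secondary_shifts()].
#' @param segments output of [call_helices()].
#' @return data frame `residue`, `aa`, `dca_dcb`, `helix_flag`.
#' @export
shift_report <- function(profile, segments) {
  flag <- vapply(profile$residue, function(r)
    any(segments$start <= r & r <= segments$end), TRUE)
  cbind(profile, helix_flag = flag)
}
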