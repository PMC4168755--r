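#' @useDynLib nmrtopo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef complete.cases lm median optim quantile rnorm
#'   runif sd setNames uniroot weighted.mean
#' @importFrom utils read.table write.table head tail download.file
NULL

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Validate a vector of one-letter amino-acid codes
#'
#' Accepts the 20 standard residues plus `"X"` for unknown.
#'
#' @param aa character vector of one-letter codes.
#' @return `aa`, invisibly, after validation.
#' @keywords internal
check_aa <- function(aa) {
  bad <- !(aa %in% c(AA1, "X"))
  if (any(bad))
    stop("unknown amino-acid code(s): ", paste(unique(aa[bad]), collapse = ", "))
  invisible(aa)
}

new_shift_table <- function(residue, aa, ca, cb, condition = "") {
  stopifnot(length(residue) == length(aa))
  df <- data.frame(residue = as.integer(residue), aa = as.character(aa),
                   ca = as.numeric(ca), cb = as.numeric(cb),
                   stringsAsFactors = FALSE)
  validate_shift_table(df)
  attr(df, "condition") <- condition
  class(df) <- c("shift_table", "data.frame")
  df
}

validate_shift_table <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$residue < 1)) stop("residue indices must be >= 1")
  if (anyDuplicated(df$residue))
    stop("duplicate residue index: ",
         paste(df$residue[duplicated(df$residue)], collapse = ", "))
  if (is.unsorted(df$residue, strictly = TRUE))
    stop("residue indices must be strictly increasing")
  check_aa(df$aa)
  gly_cb <- df$aa == "G" & !is.na(df$cb)
  if (any(gly_cb))
    stop("glycine cannot carry a Cbeta shift (residue ",
         paste(df$residue[gly_cb], collapse = ", "), ")")
  invisible(df)
}

#' Read a per-residue chemical-shift table
#'
#' Reads observed Calpha/Cbeta shifts in either the package's native
#' four-column TSV dialect (`residue`, `aa`, `ca`, `cb`; missing shifts as
#' `NA` or `.`) or a minimal NMR-STAR-like loop carrying the standard
#' `_Atom_chem_shift` tags (`Seq_ID`, `Comp_ID`, `Atom_ID`, `Val`).
#'
#' Rows in which both the Calpha and the Cbeta shift are missing carry no
#' information for the secondary-shift index and are dropped with a warning.
#'
#' @param path path to the table.
#' @param dialect `"tsv"` (native) or `"nmrstar"` (NMR-STAR-lite loop).
#' @param condition free-text condition label (e.g. `"water"`, `"DPC"`)
#'   stored on the returned object.
#' @return a `shift_table` data frame with columns `residue`, `aa`, `ca`,
#'   `cb` and attribute `condition`.
#' @export
read_shift_table <- function(path, dialect = c("tsv", "nmrstar"),
                             condition = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (dialect == "tsv") .read_shift_tsv(path) else .read_shift_star(path)
  empty <- is.na(df$ca) & is.na(df$cb)
  if (any(empty)) {
    warning(sum(empty), " row(s) with neither Calpha nor Cbeta shift dropped")
    df <- df[!empty, , drop = FALSE]
  }
  new_shift_table(df$residue, df$aa, df$ca, df$cb, condition = condition)
}

.read_shift_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0)
    return(data.frame(residue = integer(), aa = character(),
                      ca = numeric(), cb = numeric()))
  # skip an optional header line
  if (grepl("^residue\\b", lines[1], ignore.case = TRUE)) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("malformed shift-table row at line ", which(nf < 3)[1], ": '",
         lines[which(nf < 3)[1]], "'")
  num <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c(".", "", "NA"), NA, x)))
  res <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
  if (anyNA(res))
    stop("malformed residue index at line ", which(is.na(res))[1])
  data.frame(residue = res,
             aa = toupper(vapply(parts, `[`, "", 2)),
             ca = num(vapply(parts, `[`, "", 3)),
             cb = num(vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, "")),
             stringsAsFactors = FALSE)
}

# Minimal NMR-STAR chemical-shift loop reader: finds the loop_ whose tags
# include Seq_ID/Comp_ID/Atom_ID/Val (with or without the
# _Atom_chem_shift. prefix) and collects CA/CB rows.
.read_shift_star <- function(path) {
  lines <- trimws(readLines(path))
  tag_idx <- grep("^_", lines)
  tags <- sub("^_([A-Za-z_0-9]+\\.)?", "", lines[tag_idx])
  need <- c("Seq_ID", "Comp_ID", "Atom_ID", "Val")
  if (!all(need %in% tags)) stop("NMR-STAR loop tags not found in ", path)
  col <- match(need, tags)
  body <- lines[seq(max(tag_idx) + 1, length(lines))]
  body <- body[!grepl("^\\s*$", body)]
  stop_at <- grep("^(stop_|loop_|save_)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1)]
  fields <- strsplit(body, "\\s+")
  ok <- lengths(fields) >= length(tags)
  if (any(!ok)) stop("malformed NMR-STAR row at data line ", which(!ok)[1])
  seq_id <- as.integer(vapply(fields, `[`, "", col[1]))
  comp <- toupper(vapply(fields, `[`, "", col[2]))
  atom <- toupper(vapply(fields, `[`, "", col[3]))
  val <- as.numeric(vapply(fields, `[`, "", col[4]))
  aa1 <- names(AA3)[match(comp, AA3)]
  aa1[is.na(aa1)] <- "X"
  keep <- atom %in% c("CA", "CB")
  seq_id <- seq_id[keep]; aa1 <- aa1[keep]; atom <- atom[keep]; val <- val[keep]
  res <- sort(unique(seq_id))
  ca <- cb <- rep(NA_real_, length(res))
  aa <- vapply(res, function(r) aa1[seq_id == r][1], "")
  for (i in seq_along(res)) {
    v <- val[seq_id == res[i] & atom == "CA"]
    if (length(v)) ca[i] <- v[1]
    v <- val[seq_id == res[i] & atom == "CB"]
    if (length(v)) cb[i] <- v[1]
  }
  data.frame(residue = res, aa = aa, ca = ca, cb = cb, stringsAsFactors = FALSE)
}

#' Write a shift table in the native TSV dialect
#'
#' @param x a `shift_table`.
#' @param path output path.
#' @export
write_shift_table <- function(x, path) {
  validate_shift_table(x)
  out <- data.frame(residue = x$residue, aa = x$aa,
                    ca = ifelse(is.na(x$ca), ".", format(x$ca, digits = 15)),
                    cb = ifelse(is.na(x$cb), ".", format(x$cb, digits = 15)))
  writeLines(c("residue\taa\tca\tcb",
               do.call(paste, c(out, sep = "\t"))), path)
  invisible(path)
}

#' Read a multi-model PDB file into a structure ensemble
#'
#' One model per `MODEL` record; a file with `ATOM` records but no `MODEL`
#' records is read as a single-model ensemble.  `HETATM` records, waters and
#' alternate locations other than `'A'`/blank are excluded.  All models must
#' share an identical residue/atom roster.
#'
#' Parsing of the PDB fixed-column format is delegated to
#' \code{\link[bio3d]{read.pdb}}.
#'
#' @param path path to a PDB file.
#' @param source_id identifier stored on the ensemble (defaults to the
#'   file name).
#' @return an object of class `structure_ensemble`: a list with `models`
#'   (each a data frame `resno`, `aa`, `elety`, `x`, `y`, `z`) and
#'   `source_id`.
#' @export
read_ensemble <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path)
  nmodel <- sum(grepl("^MODEL", txt))
  # roster pre-check so a mismatch yields a named validation error rather
  # than an opaque failure inside the parser
  if (nmodel > 1) {
    starts <- grep("^MODEL", txt)
    ends <- grep("^ENDMDL", txt)
    if (length(ends) >= length(starts)) {
      counts <- vapply(seq_along(starts), function(i)
        sum(grepl("^ATOM", txt[starts[i]:ends[i]])), 0L)
      if (length(unique(counts)) > 1)
        stop("models have differing atom rosters (ATOM counts: ",
             paste(counts, collapse = ", "), ")")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")) &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  idx <- which(keep)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nm <- max(1L, nmodel)
  if (nrow(xyz) != nm)
    nm <- nrow(xyz)
  aa1 <- names(AA3)[match(at$resid[idx], AA3)]
  aa1[is.na(aa1)] <- "X"
  models <- lapply(seq_len(nm), function(m) {
    v <- xyz[m, ]
    data.frame(resno = at$resno[idx], aa = aa1, elety = at$elety[idx],
               x = v[3 * (idx - 1) + 1], y = v[3 * (idx - 1) + 2],
               z = v[3 * (idx - 1) + 3], stringsAsFactors = FALSE)
  })
  for (m in models)
    if (any(!is.finite(c(m$x, m$y, m$z))))
      stop("non-finite coordinates in ", path)
  structure(list(models = models, source_id = source_id),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("structure_ensemble '", x$source_id, "': ", length(x$models),
      " model(s), ", length(unique(x$models[[1]]$resno)), " residues, ",
      nrow(x$models[[1]]), " atoms/model\n", sep = "")
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens a `structure_ensemble`.
#' @return integer model count.
#' @export
n_models <- function(ens) length(ens$models)

#' Fetch a PDB entry from the RCSB archive
#'
#' Thin wrapper around [utils::download.file()]; requires network access.
#'
#' @param id 4-character PDB accession, e.g. `"2MDK"`.
#' @param dest destination file (default: a tempfile).
#' @return the path to the downloaded file.
#' @export
fetch_pdb <- function(id, dest = tempfile(fileext = ".pdb")) {
  url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
  status <- try(suppressWarnings(
    download.file(url, dest, quiet = TRUE, mode = "wb")), silent = TRUE)
  if (inherits(status, "try-error") || !identical(status, 0L) ||
      !file.exists(dest) || file.size(dest) == 0)
    stop("could not fetch PDB entry ", id, " (no network access?)")
  dest
}

restraint_classes <- c("unrestrained", "bounded", "upper_only", "vanished")

validate_restraints <- function(r) {
  stopifnot(is.data.frame(r),
            all(c("site", "residue", "d", "lower", "upper", "class") %in% names(r)))
  if (!all(r$class %in% restraint_classes))
    stop("unknown restraint class: ",
         paste(setdiff(r$class, restraint_classes), collapse = ", "))
  act <- r$class %in% c("bounded", "upper_only")
  if (any(act & !is.finite(r$upper)))
    stop("active restraints must carry a finite upper bound")
  b <- r$class == "bounded"
  if (any(b & !(r$lower <= r$d & r$d <= r$upper)))
    stop("bounded restraint violates lower <= d <= upper")
  invisible(r)
}

#' Write PRE distance restraints
#'
#' The `tsv` dialect is the package's native round-trippable format
#' (columns `site`, `residue`, `d`, `lower`, `upper`, `class`).  The
#' `xplor` dialect emits one `assign` statement per restraint with the
#' conventional `d dminus dplus` triplet, suitable as input for
#' simulated-annealing structure-calculation engines.  Entries of class
#' `unrestrained` carry no distance and are skipped with a message.
#'
#' @param restraints restraint data frame (see [build_restraints()]).
#' @param path output path.
#' @param format `"tsv"` or `"xplor"`.
#' @export
write_restraints <- function(restraints, path, format = c("tsv", "xplor")) {
  format <- match.arg(format)
  if (nrow(restraints) == 0) stop("empty restraint list")
  validate_restraints(restraints)
  skip <- restraints$class %in% c("unrestrained", "vanished")
  if (any(skip) && format == "xplor") {
    message("skipping ", sum(skip), " unrestrained entr(ies)")
    restraints <- restraints[!skip, , drop = FALSE]
  }
  restraints <- restraints[order(restraints$site, restraints$residue), , drop = FALSE]
  if (format == "tsv") {
    out <- restraints[, c("site", "residue", "d", "lower", "upper", "class")]
    for (cl in c("d", "lower", "upper"))
      out[[cl]] <- ifelse(is.na(out[[cl]]), "NA", format(out[[cl]], digits = 17))
    writeLines(c("site\tresidue\td\tlower\tupper\tclass",
                 do.call(paste, c(out, sep = "\t"))), path)
  } else {
    fmt_line <- function(site, res, d, dminus, dplus)
      sprintf("assign (resid %d and name CA) (resid %d and name HN) %.1f %.1f %.1f",
              site, res, d, dminus, dplus)
    ln <- character(nrow(restraints))
    for (i in seq_len(nrow(restraints))) {
      r <- restraints[i, ]
      if (r$class == "bounded")
        ln[i] <- fmt_line(r$site, r$residue, r$d, r$d - r$lower, r$upper - r$d)
      else # upper_only: bottom open down to van der Waals contact
        ln[i] <- fmt_line(r$site, r$residue, r$upper, r$upper - 1.8, 0)
    }
    writeLines(ln, path)
  }
  invisible(path)
}

#' Read PRE distance restraints from the native TSV dialect
#'
#' Inverse of [write_restraints()] with `format = "tsv"`: the write/read
#' round trip reproduces the restraint list exactly.
#'
#' @param path path to a restraint TSV.
#' @return restraint data frame.
#' @export
read_restraints <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  df$site <- as.integer(df$site); df$residue <- as.integer(df$residue)
  validate_restraints(df)
  df
}

#' Read a single protein sequence from a FASTA file
#'
#' @param path FASTA file (first record is used).
#' @return a single upper-case sequence string.
#' @export
read_fasta_seq <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(fa) == 0) stop("no sequences in ", path)
  toupper(as.character(fa[[1]]))
}

#' Write a named set of sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta_seqs <- function(seqs, path) {
  seqinr::write.fasta(lapply(seqs, function(s) strsplit(s, "")[[1]]),
                      names = names(seqs), file.out = path)
  invisible(path)
}

#' Parse a residue-range selection string
#'
#' Understands the range syntax used throughout structure papers, e.g.
#' `"3-7,22-30,90-94,98-107,116-125"`.
#'
#' @param txt selection string: comma-separated `start-end` ranges or
#'   single indices.
#' @return sorted integer vector of residue indices.
#' @export
parse_selection <- function(txt) {
  parts <- strsplit(gsub("\\s", "", txt), ",")[[1]]
  idx <- unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      if (length(ab) != 2 || anyNA(ab) || ab[2] < ab[1])
        stop("bad range: '", p, "'")
      seq(ab[1], ab[2])
    } else {
      v <- as.integer(p)
      if (is.na(v)) stop("bad index: '", p, "'")
      v
    }
  }))
  sort(unique(idx))
}

#' Convert helix segments to a data frame of ranges
#' @keywords internal
segments_df <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  data.frame(start = as.integer(start), end = as.integer(end))
}
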