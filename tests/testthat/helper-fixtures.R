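# Shared fixtures, built in code at test time.

# memoized paper-shaped bundle (125 residues, 5 helices, 7 label sites)
.fixture_env <- new.env()
paper_truth <- function() {
  if (is.null(.fixture_env$truth)) .fixture_env$truth <- make_bundle(seed = 1)
  .fixture_env$truth
}

helix_residues <- function(segments)
  unlist(mapply(seq, segments$start, segments$end, SIMPLIFY = FALSE))

# small two-helix truth for cheap tests
small_truth <- function(seed = 42)
  make_bundle(n_helices = 2, lengths = c(8L, 8L),
              loop_lengths = c(1L, 6L, 2L), seed = seed)

# minimal two-model PDB text (5 residues, backbone + CB)
write_tiny_pdb <- function(path, n_models = 2, drop_last_atom_in = NULL,
                           with_model_records = TRUE) {
  atoms <- c("N", "CA", "C", "O", "CB")
  lines <- character(0)
  serial <- 0
  for (m in seq_len(n_models)) {
    if (with_model_records) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (r in 1:5) for (a in atoms) {
      if (isTRUE(drop_last_atom_in == m) && r == 5 && a == "CB") next
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, a, r, r * 3.8 + 0.1 * m, m * 1.0, serial * 0.01,
        substr(a, 1, 1)))
    }
    if (with_model_records) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# build a bounded-restraint table straight from true coordinates
restraints_from_truth <- function(truth, sites, width = 0.5) {
  do.call(rbind, lapply(sites, function(s) {
    d <- sqrt(rowSums(sweep(truth$coords, 2, truth$coords[s, ])^2))
    keep <- seq_len(truth$n_res) != s
    data.frame(site = s, residue = which(keep), d = d[keep],
               lower = pmax(d[keep] - width, 0), upper = d[keep] + width,
               class = "bounded", stringsAsFactors = FALSE)
  }))
}
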