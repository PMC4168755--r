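# Packaged reference assets: random-coil shift table, hydropathy scales and
# the study sequences. Kept as code (not binary data) so every value is
# auditable in the source.

#' Random-coil Calpha/Cbeta chemical shifts
#'
#' The Wishart and co-workers random-coil reference values (ppm) commonly
#' used for secondary-shift indexing.  Glycine has no Cbeta.  Users may
#' supply their own table to [secondary_shifts()]; the set used is recorded
#' in the profile's `reference_set` attribute.
#'
#' @param set name of the packaged set; currently `"wishart1995"`.
#' @return data frame with columns `aa`, `ca`, `cb`.
#' @export
random_coil_shifts <- function(set = "wishart1995") {
  set <- match.arg(set)
  df <- data.frame(
    aa = c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V"),
    ca = c(52.5, 56.0, 53.1, 54.2, 58.2, 55.7, 56.6, 45.1, 55.0, 61.1,
           55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 57.5, 57.9, 62.2),
    cb = c(19.1, 30.9, 38.9, 41.1, 28.0, 29.4, 29.9,   NA, 29.0, 38.8,
           42.4, 33.1, 32.9, 39.6, 32.1, 63.8, 69.8, 29.6, 38.8, 32.9),
    stringsAsFactors = FALSE)
  attr(df, "set") <- set
  df
}

#' Packaged hydropathy scales
#'
#' Three classic per-residue scales:
#' \describe{
#'   \item{`"kd"`}{Kyte-Doolittle hydropathy (dimensionless).}
#'   \item{`"ges"`}{Goldman-Engelman-Steitz transfer free energies
#'     (kcal/mol; positive = favours the membrane interior), the
#'     conventional choice for transmembrane-segment detection.}
#'   \item{`"eisenberg"`}{Eisenberg consensus hydrophobicity, the scale the
#'     hydrophobic-moment formalism was defined on.}
#' }
#'
#' @param name one of `"kd"`, `"ges"`, `"eisenberg"`.
#' @return named numeric vector over the 20 one-letter codes, with
#'   attribute `scale_name`.
#' @export
hydropathy_scale <- function(name = c("kd", "ges", "eisenberg")) {
  name <- match.arg(name)
  v <- switch(name,
    kd = c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5,
           E = -3.5, G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9,
           M =  1.9, F =  2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
           Y = -1.3, V =  4.2),
    ges = c(A =  1.6, R = -12.3, N = -4.8, D = -9.2, C =  2.0, Q = -4.1,
            E = -8.2, G =  1.0, H = -3.0, I =  3.1, L =  2.8, K = -8.8,
            M =  3.4, F =  3.7, P = -0.2, S =  0.6, T =  1.2, W =  1.9,
            Y = -0.7, V =  2.6),
    eisenberg = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                  Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                  L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                  S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08))
  attr(v, "scale_name") <- name
  v
}

# VAPB MSP domain, residues 1-125 (human VAPB / UniProt O95292 numbering).
.MSP_WT <-
  "MAKVEQVLSLEPQHELKFRGPFTDVVTTNLKLGNPTDRNVCFKVKTTAPRRYCVRPNSGIIDAGASINVSVMLQPFDYDPNEKSKHKFMVQSMFAPTDTSDMEAVWKEAKPEDLMDSKLRCVFEL"

#' Study sequences
#'
#' Amino-acid sequences used by the amphiphilicity module and the
#' paper-shaped synthetic preset:
#' \describe{
#'   \item{`"msp_wt"`}{the 125-residue wild-type major sperm protein (MSP)
#'     domain of human VAPB.}
#'   \item{`"msp_p56s"`}{the ALS-linked P56S mutant of the same domain.}
#'   \item{`"vapb_p56s_synthetic_fl"`}{a synthetic full-length VAPB-like
#'     construct: the real P56S MSP domain (1-125) followed by a generic
#'     polar linker and an idealized 21-residue transmembrane anchor at the
#'     C-terminus, standing in for the 243-residue full-length protein for
#'     qualitative transmembrane-profile comparisons.  The region beyond
#'     residue 125 is synthetic, not the natural sequence.}
#'   \item{`"melittin"`}{the 26-residue honeybee membrane-active toxin, the
#'     classic amphipathic reference peptide.}
#'   \item{`"asyn"`}{human alpha-synuclein (140 residues).}
#' }
#'
#' @param which sequence name.
#' @return a single sequence string.
#' @export
study_sequence <- function(which = c("msp_p56s", "msp_wt",
                                     "vapb_p56s_synthetic_fl",
                                     "melittin", "asyn")) {
  which <- match.arg(which)
  p56s <- paste0(substr(.MSP_WT, 1, 55), "S", substr(.MSP_WT, 57, 125))
  linker <- paste(rep("SGTEKSPSQTESNKP", 7), collapse = "") # polar filler
  tm <- "LLVIAGVLLVILAFILWLVFF" # idealized 21-residue TM anchor
  switch(which,
    msp_wt = .MSP_WT,
    msp_p56s = p56s,
    vapb_p56s_synthetic_fl = paste0(p56s, substr(linker, 1, 97), tm),
    melittin = "GIGAVLKVLTTGLPALISWIKRKRQQ",
    asyn = paste0("MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHG",
                  "VATVAEKTKEQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGK",
                  "NEEGAPQEGILEDMPVDPDNEAYEMPSEEGYQDYEPEA"))
}

#' Spin-label sites of the seven-site PRE study design
#'
#' Residue positions of the single-cysteine mutants used for nitroxide
#' spin labelling (Q6C, D24C, A53C, N68C, M89C, M102C, A121C).
#'
#' @return integer vector of residue indices.
#' @export
default_label_sites <- function() c(6L, 24L, 53L, 68L, 89L, 102L, 121L)

#' Helix segments of the micelle-bound P56S MSP topology
#'
#' The five helices of the deposited micelle-bound structure
#' (3-7, 22-30, 90-94, 98-107, 116-125).
#'
#' @return data frame with columns `start`, `end`.
#' @export
default_helices <- function()
  segments_df(c(3L, 22L, 90L, 98L, 116L), c(7L, 30L, 94L, 107L, 125L))
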