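# Residue-level constants for the 20 standard amino acids.
#
# Average residue masses follow the ExPASy/ProtParam table (IUPAC 1997 atomic
# weights); monoisotopic masses are the usual values to 5 decimals. Hydropathy
# is the Kyte-Doolittle index. All masses are residue (dehydrated) masses; a
# peptide adds one water.

.AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AVG_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.MONO_RESIDUE_MASS <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  Q = 128.05858, E = 129.04259, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)

.WATER_AVG <- 18.01524
.WATER_MONO <- 18.010565

# -OH -> -NH2 on the C-terminal carboxylate (alpha-amidation)
.AMIDE_SHIFT_AVG <- -0.98476
.AMIDE_SHIFT_MONO <- -0.98402

# proton mass used for ESI+ [M + zH]^z+ arithmetic
.PROTON_MASS <- 1.00728

.KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Kyte-Doolittle hydropathy scale
#'
#' Returns the per-residue Kyte-Doolittle hydropathy indices used for GRAVY
#' and for the built-in signal-peptide heuristic.
#'
#' @return A named numeric vector over the 20 standard amino acids.
#' @export
#' @examples
#' kyte_doolittle()[c("I", "R")]
kyte_doolittle <- function() {
  .KYTE_DOOLITTLE
}

# split a peptide into residues, validating the alphabet
.residues <- function(seq, what = "peptide") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort(sprintf("`%s` must be a single non-empty string.", what))
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), .AA_ORDER)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-standard residue%s '%s' in %s \"%s\".",
      if (length(bad) > 1) "s" else "", paste(bad, collapse = "', '"),
      what, seq
    ))
  }
  chars
}
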