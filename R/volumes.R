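#' Amino-acid residue volumes
#'
#' Zamyatnin residue volumes for the 20 canonical amino acids, in cubic
#' angstroms. These are the volumes entering the size score
#' (`w5 / volume`): smaller residues at the heme-contacting position score
#' higher because they leave room for the propionate to approach the
#' backbone.
#'
#' @return Named numeric vector of volumes (Å³), names are 3-letter
#'   residue codes in upper case.
#' @examples
#' aa_volumes()[["ALA"]]  # 88.6
#' @export
aa_volumes <- function() {
  v <- c(
    GLY = 60.1,  ALA = 88.6,  SER = 89.0,  CYS = 108.5, ASP = 111.1,
    PRO = 112.7, ASN = 114.1, THR = 116.1, GLU = 138.4, VAL = 140.0,
    GLN = 143.8, HIS = 153.2, MET = 162.9, ILE = 166.7, LEU = 166.7,
    LYS = 168.6, ARG = 173.4, PHE = 189.9, TYR = 193.6, TRP = 227.8
  )
  stopifnot(
    all(v > 50), all(v < 250),
    which.min(v) == match("GLY", names(v)),
    which.max(v) == match("TRP", names(v)),
    v[["GLY"]] < v[["ALA"]], v[["ALA"]] < v[["VAL"]], v[["VAL"]] < v[["TRP"]]
  )
  v
}

# Accepts "ALA", "Ala" or one-letter "A"; returns canonical 3-letter code.
canonical_aa <- function(code) {
  one <- c(
    G = "GLY", A = "ALA", S = "SER", C = "CYS", D = "ASP", P = "PRO",
    N = "ASN", T = "THR", E = "GLU", V = "VAL", Q = "GLN", H = "HIS",
    M = "MET", I = "ILE", L = "LEU", K = "LYS", R = "ARG", F = "PHE",
    Y = "TYR", W = "TRP"
  )
  code <- toupper(code)
  out <- ifelse(nchar(code) == 1L, unname(one[code]), code)
  bad <- is.na(out) | !(out %in% names(aa_volumes()))
  if (any(bad)) {
    stop("unknown amino-acid code(s): ", paste(code[bad], collapse = ", "))
  }
  out
}
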