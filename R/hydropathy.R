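# Residue chemistry: H/P/C partition of the 20 standard amino acids,
# hydrophobicity scale handling and the parabolic hydropathy score.

STANDARD_RESIDUES <- c(
  "GLY", "ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TYR", "TRP",
  "SER", "PRO", "THR", "CYS", "ASN", "GLN",
  "HIS", "LYS", "ARG", "ASP", "GLU"
)

RESIDUE_CLASS_MAP <- c(
  GLY = "H", ALA = "H", VAL = "H", LEU = "H", ILE = "H", MET = "H",
  PHE = "H", TYR = "H", TRP = "H",
  SER = "P", PRO = "P", THR = "P", CYS = "P", ASN = "P", GLN = "P",
  HIS = "C", LYS = "C", ARG = "C", ASP = "C", GLU = "C"
)

#' Chemical class of residues
#'
#' Maps three-letter residue names to the hydrophobic (H), polar (P) or
#' charged (C) class used throughout the interface analyses.
#'
#' @param resname Character vector of three-letter residue names.
#' @return Character vector with values `"H"`, `"P"`, `"C"`, or `NA` for
#'   nonstandard residues.
#' @examples
#' residue_class(c("LEU", "SER", "ARG"))
#' @export
residue_class <- function(resname) {
  unname(RESIDUE_CLASS_MAP[toupper(resname)])
}

#' Unordered chemical class of a residue pair
#'
#' The six unordered pairings of the H/P/C partition: HH, HP, HC, PP, PC, CC.
#' Order-insensitive, so `pair_class("SER","LEU")` equals
#' `pair_class("LEU","SER")`.
#'
#' @param resname_a,resname_b Three-letter residue names (vectorised).
#' @return Character vector of pair classes.
#' @export
pair_class <- function(resname_a, resname_b) {
  ca <- residue_class(resname_a)
  cb <- residue_class(resname_b)
  # canonical order H < P < C
  lv <- c("H", "P", "C")
  ia <- match(ca, lv)
  ib <- match(cb, lv)
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  out <- paste0(lv[lo], lv[hi])
  out[is.na(ca) | is.na(cb)] <- NA_character_
  out
}

PAIR_CLASSES <- c("HH", "HP", "HC", "PP", "PC", "CC")

#' Load a hydrophobicity scale
#'
#' Reads a two-column CSV (`resname`, `H`) mapping every standard residue to
#' a non-negative hydrophobicity index. Indices close to zero mark
#' hydrophobic residues; larger values mark hydrophilic ones. The default is
#' a synthetic surrogate scale shipped with the package (the published
#' MD-derived indices are not redistributable here): it is class-consistent
#' (H low, P intermediate, C high) and its maximum product of indices is
#' 11.0, the upper root of the hydropathy parabola.
#'
#' @param path Path to a scale CSV; `NULL` loads the shipped surrogate.
#' @param a,b Coefficients of the hydropathy parabola (defaults 0.033 and
#'   0.363).
#' @return A tibble with columns `resname`, `H` and attributes `a`, `b`.
#' @export
load_hydrophobicity_scale <- function(path = NULL, a = 0.033, b = 0.363) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_hydrophobicity_scale.csv",
      package = "surfcomp"
    )
  }
  if (!file.exists(path)) {
    abort(paste0("hydrophobicity scale file not found: ", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("resname", "H") %in% names(df))) {
    abort("hydrophobicity scale must have columns 'resname' and 'H'")
  }
  df$resname <- toupper(df$resname)
  missing <- setdiff(STANDARD_RESIDUES, df$resname)
  if (length(missing) > 0) {
    abort(paste0(
      "hydrophobicity scale is missing residues: ",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(df$H < 0)) abort("hydrophobicity indices must be >= 0")
  out <- tibble::as_tibble(df[df$resname %in% STANDARD_RESIDUES, c("resname", "H")])
  attr(out, "a") <- a
  attr(out, "b") <- b
  class(out) <- c("hydrophobicity_scale", class(out))
  out
}

scale_lookup <- function(scale, resname) {
  idx <- match(toupper(resname), scale$resname)
  if (anyNA(idx)) {
    abort(paste0(
      "residue(s) not in hydrophobicity scale: ",
      paste(unique(resname[is.na(idx)]), collapse = ", ")
    ))
  }
  scale$H[idx]
}

#' Hydropathy complementarity between two residues
#'
#' Parabolic score of the product of two hydrophobicity indices,
#' `H_r = -a (H_A H_B)^2 + b (H_A H_B)`. With the default coefficients
#' a = 0.033 and b = 0.363 the parabola has roots at products 0 and 11.0 and
#' its vertex is `b^2 / (4 a) = 0.99825`, i.e. approximately one. Values
#' close to zero correspond to higher hydropathy complementarity (two
#' hydrophobic residues, or the extreme hydrophobic/hydrophilic pairing at
#' the upper root).
#'
#' @param h_a,h_b Non-negative hydrophobicity indices (vectorised).
#' @param a,b Parabola coefficients.
#' @return Numeric vector of hydropathy complementarity values.
#' @examples
#' hydropathy_complementarity(0, 0) # 0: perfect complementarity
#' hydropathy_complementarity(sqrt(5.5), sqrt(5.5)) # vertex, ~1
#' @export
hydropathy_complementarity <- function(h_a, h_b, a = 0.033, b = 0.363) {
  if (any(h_a < 0) || any(h_b < 0)) {
    abort("hydrophobicity indices must be >= 0")
  }
  x <- h_a * h_b
  -a * x^2 + b * x
}

#' Hydropathy complementarity for named residues
#'
#' Convenience wrapper looking indices up in a scale before applying
#' [hydropathy_complementarity()].
#'
#' @param resname_a,resname_b Three-letter residue names (vectorised).
#' @param scale A scale from [load_hydrophobicity_scale()].
#' @return Numeric vector.
#' @export
residue_hydropathy <- function(resname_a, resname_b, scale) {
  a <- attr(scale, "a") %||% 0.033
  b <- attr(scale, "b") %||% 0.363
  hydropathy_complementarity(
    scale_lookup(scale, resname_a),
    scale_lookup(scale, resname_b),
    a = a, b = b
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
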