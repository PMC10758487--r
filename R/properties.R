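# Dinucleotide physicochemical property table backing the covariance and
# pseudo-composition encoders.

DINUCLEOTIDES <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                                 function(a, b) paste0(a, b)))
# outer() fills column-major: AA CA GA UA AC ... ; we want row-major lexicographic
DINUCLEOTIDES <- sort(DINUCLEOTIDES)

#' Standardize a property table over the 16 dinucleotides
#'
#' Each property row is centered and scaled to mean 0, standard deviation 1
#' across the 16 dinucleotides, the conventional normalization before
#' covariance-style encodings so properties on different physical scales
#' contribute comparably.
#'
#' @param props Numeric matrix, properties x 16 dinucleotides (columns named
#'   AA, AC, ..., UU).
#' @return Matrix of the same shape with standardized rows and attribute
#'   \code{standardized = TRUE}.
#' @export
standardize_properties <- function(props) {
  stopifnot(is.matrix(props), ncol(props) == 16L)
  props <- props[, DINUCLEOTIDES, drop = FALSE]
  out <- t(apply(props, 1L, function(r) {
    s <- stats::sd(r)
    if (s == 0) stop("constant property row cannot be standardized")
    (r - mean(r)) / s
  }))
  dimnames(out) <- dimnames(props)
  attr(out, "standardized") <- TRUE
  out
}

#' Load the dinucleotide physicochemical property table
#'
#' The bundled default table carries six properties per dinucleotide:
#' nearest-neighbour stacking free energy (kcal/mol, Watson-Crick stack of
#' the dinucleotide on its complement), GC content, purine content, keto
#' content, mean electron-ion interaction pseudopotential of the two bases,
#' and the 5'->3' EIIP asymmetry. The last two derive from the per-base EIIP
#' scalars; the first is order-sensitive, so the table distinguishes e.g. AU
#' from UA. Users may supply their own table (same TSV layout: one
#' \code{property} column then the 16 dinucleotide columns) to use other
#' property sets such as helical step parameters.
#'
#' @param path Optional TSV path; default is the bundled table.
#' @param standardize Standardize rows over the 16 dinucleotides (default
#'   TRUE; the encoders expect standardized input).
#' @return Numeric matrix, properties x 16 dinucleotides.
#' @export
dhu_properties <- function(path = NULL, standardize = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "rna_dinucleotide_properties.tsv",
                        package = "dhupred", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "property" || !all(DINUCLEOTIDES %in% names(df)))
    stop("property table must have a 'property' column and all 16 dinucleotide columns")
  m <- as.matrix(df[, DINUCLEOTIDES])
  rownames(m) <- df$property
  if (standardize) m <- standardize_properties(m)
  m
}
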