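## Amino-acid alphabets shared across the package.

# 20 standard residues, alphabetical one-letter codes
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Nonstandard codes tolerated in input sequences (selenocysteine and
# ambiguity codes); they score the neutral weight 0 in the psi model.
.AA_NONSTANDARD <- c("U", "X", "B", "Z")

# Encoding slot for any residue outside the standard 20
.AA_UNKNOWN <- 21L

#' Default hydrophobic residue set
#'
#' The hydrophobic set \eqn{\Phi} used to classify C-terminal ligand motifs
#' (class 1 `X-S/T-X-`\eqn{\Phi}, class 2 `X-`\eqn{\Phi}`-X-`\eqn{\Phi},
#' class 3 `X-D/E-X-`\eqn{\Phi}). The PDZ literature writes \eqn{\Phi} for
#' "any hydrophobic residue" without enumerating it; this standard set is
#' the package default and every classifier accepts an alternative.
#'
#' @return Character vector of one-letter residue codes.
#' @export
#' @examples
#' phi_residues()
phi_residues <- function() {
  c("A", "V", "L", "I", "M", "F", "W", "Y", "C")
}

# Map residue letters to integer codes 1..20, unknown -> 21
.aa_encode <- function(chars) {
  idx <- match(chars, .AA20)
  idx[is.na(idx)] <- .AA_UNKNOWN
  idx
}

# Split fixed-width residue strings into an integer code matrix (n x width)
.encode_strings <- function(strings, width) {
  if (any(nchar(strings) != width)) {
    stop("all sequences must have exactly ", width, " residues", call. = FALSE)
  }
  m <- matrix(.aa_encode(unlist(strsplit(strings, "", fixed = TRUE))),
              ncol = width, byrow = TRUE)
  rownames(m) <- names(strings)
  m
}

.check_residues <- function(chars, where = "sequence") {
  bad <- setdiff(unique(chars), c(.AA20, .AA_NONSTANDARD))
  if (length(bad) > 0) {
    stop("invalid residue code(s) in ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
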