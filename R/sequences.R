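## C-terminus extraction and ligand motif classification.

#' Extract the 5-residue C-terminal ligand of a protein
#'
#' Returns the last five residues of each protein sequence, uppercased,
#' after stripping one optional trailing stop symbol `*`. Position 0 is
#' the C-terminal residue, positions run 0, -1, ..., -4 towards the
#' N-terminus.
#'
#' @param seqs Character vector of amino-acid sequences (or anything
#'   coercible with `as.character`, e.g. a `Biostrings::AAStringSet`).
#' @return Character vector of 5-mers, named like the input.
#' @export
#' @examples
#' extract_cterminus(c(p1 = "MKAVLETSV", p2 = "LETSV*"))
extract_cterminus <- function(seqs) {
  s <- toupper(as.character(seqs))
  s <- sub("\\*$", "", s)
  if (any(grepl("*", s, fixed = TRUE))) {
    stop("internal stop symbol '*' in sequence", call. = FALSE)
  }
  .check_residues(unlist(strsplit(s, "", fixed = TRUE)))
  short <- nchar(s) < 5
  if (any(short)) {
    stop("sequence(s) shorter than 5 residues: ",
         paste(utils::head(which(short), 5), collapse = ", "), call. = FALSE)
  }
  out <- substr(s, nchar(s) - 4L, nchar(s))
  names(out) <- names(seqs)
  out
}

#' Classify a C-terminal ligand into PDZ binding classes
#'
#' Class 1 motifs are `X-S/T-X-`\eqn{\Phi}`-COOH`, class 2
#' `X-`\eqn{\Phi}`-X-`\eqn{\Phi}, class 3 `X-D/E-X-`\eqn{\Phi}, where
#' position 0 is the C-terminus and \eqn{\Phi} a hydrophobic residue.
#' S/T and D/E are not hydrophobic, so only class 2 can overlap the other
#' definitions; precedence 1 > 3 > 2 keeps the classes exclusive.
#'
#' @param peptides Character vector of 5-residue C-terminal peptides.
#' @param phi Hydrophobic residue set; defaults to [phi_residues()].
#' @return Character vector with values `"class1"`, `"class2"`, `"class3"`
#'   or `"unclassified"`.
#' @export
#' @examples
#' classify_ligand(c("NGTSV", "NGEYV", "NGVFV", "NGTSR"))
classify_ligand <- function(peptides, phi = phi_residues()) {
  p <- toupper(as.character(peptides))
  if (any(nchar(p) != 5)) {
    stop("ligand peptides must have exactly 5 residues", call. = FALSE)
  }
  pos0 <- substr(p, 5, 5)
  posm2 <- substr(p, 3, 3)
  out <- rep("unclassified", length(p))
  hyd0 <- pos0 %in% phi
  out[hyd0 & posm2 %in% phi] <- "class2"
  out[hyd0 & posm2 %in% c("D", "E")] <- "class3"
  out[hyd0 & posm2 %in% c("S", "T")] <- "class1"
  names(out) <- names(peptides)
  out
}

#' Keep the longest protein per gene
#'
#' Non-redundant proteome helper: for FASTA headers carrying a
#' `gene:<id>` tag, keeps only the longest sequence of each gene
#' (first wins on ties). Sequences without a tag are kept as-is.
#'
#' @param proteins A `Biostrings::AAStringSet`.
#' @return Filtered `AAStringSet`.
#' @export
keep_longest_per_gene <- function(proteins) {
  nm <- names(proteins)
  gene <- ifelse(grepl("gene:", nm), sub(".*gene:([^ ]+).*", "\\1", nm), NA)
  keep <- rep(TRUE, length(proteins))
  widths <- Biostrings::width(proteins)
  tagged <- which(!is.na(gene))
  if (length(tagged) > 0) {
    best <- tapply(seq_along(proteins)[tagged],
                   gene[tagged],
                   function(i) i[which.max(widths[i])])
    keep[tagged] <- tagged %in% unlist(best)
  }
  proteins[keep]
}

#' Read / write C-termini tables
#'
#' Two-column tab-separated dialect of the supplementary C-termini file:
#' `protein_id<TAB>cterm5`, no header.
#'
#' @param path File path.
#' @return `read_ctermini`: data frame with columns `protein_id`, `cterm`.
#' @export
read_ctermini <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein_id", "cterm"),
                          stringsAsFactors = FALSE, quote = "")
  if (any(nchar(df$cterm) != 5)) {
    stop("malformed C-termini table: entries must be 5-mers", call. = FALSE)
  }
  df
}

#' @rdname read_ctermini
#' @param ctermini Data frame with columns `protein_id`, `cterm` (or a
#'   named character vector of 5-mers).
#' @export
write_ctermini <- function(ctermini, path) {
  if (is.character(ctermini)) {
    ctermini <- data.frame(protein_id = names(ctermini), cterm = ctermini)
  }
  utils::write.table(ctermini[, c("protein_id", "cterm")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
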