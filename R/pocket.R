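## Binding-pocket extraction from PDZ domain sequences, and pocket mutation.
##
## The binding pocket is represented as an 18-residue string: the 16 key
## ligand-contacting residues from the betaB/betaC strands and alphaB helix
## plus the two flanking residues. Within the 18-mer, position 14 is alphaB1
## and position 16 is alphaB5 -- the two residues that control class-1
## promiscuity.

#' alphaB1 / alphaB5 positions within the 18-residue pocket
#' @return Integer position (1-based within the pocket string).
#' @export
alphaB1_index <- function() 14L

#' @rdname alphaB1_index
#' @export
alphaB5_index <- function() 16L

#' Reference profile for pocket extraction
#'
#' A reference PDZ sequence whose 18 pocket columns are known (e.g. from
#' structural modeling), together with pairwise-alignment parameters.
#' Query domains are aligned to this reference and the residues falling
#' on the annotated columns form their pocket.
#'
#' @param sequence Reference amino-acid sequence (length >= 50).
#' @param pocket_columns Strictly increasing integer vector of length 18:
#'   positions of the pocket residues within `sequence`.
#' @param key_positions Which of the 18 pocket positions are the key
#'   binding residues (default: all but the two flanks, i.e. 2..17).
#' @param substitution_matrix Name of the substitution matrix
#'   (a matrix bundled with Biostrings, default `"BLOSUM62"`).
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @return A `pdz_profile` object.
#' @export
reference_profile <- function(sequence, pocket_columns,
                              key_positions = 2:17,
                              substitution_matrix = "BLOSUM62",
                              gap_opening = 11, gap_extension = 1) {
  sequence <- toupper(as.character(sequence))
  pocket_columns <- as.integer(pocket_columns)
  if (length(pocket_columns) != 18) {
    stop("exactly 18 pocket columns are required", call. = FALSE)
  }
  if (any(diff(pocket_columns) <= 0)) {
    stop("pocket columns must be strictly increasing", call. = FALSE)
  }
  if (max(pocket_columns) > nchar(sequence) || min(pocket_columns) < 1) {
    stop("pocket columns outside the reference sequence", call. = FALSE)
  }
  structure(
    list(sequence = sequence,
         pocket_columns = pocket_columns,
         key_positions = as.integer(key_positions),
         substitution_matrix = substitution_matrix,
         gap_opening = gap_opening,
         gap_extension = gap_extension),
    class = "pdz_profile")
}

#' Extract the 18-residue binding pocket from a PDZ domain sequence
#'
#' Globally aligns the query domain to the profile reference
#' (Needleman-Wunsch with affine gaps via [Biostrings::pairwiseAlignment()])
#' and reads off the query residues aligned to the 18 annotated reference
#' columns. A pocket column aligned to a gap in the query makes the pocket
#' incomplete: an error by default, or a `-` placeholder with
#' `allow_incomplete = TRUE`.
#'
#' @param domain_seq Query PDZ domain sequence (length >= 50).
#' @param profile A [reference_profile()].
#' @param domain_id Optional identifier stored on the result.
#' @param allow_incomplete Accept pockets with gapped positions.
#' @return A `binding_pocket`: list with `domain_id`, `residues` (18-mer
#'   string), `key_positions`, and `gap_free` (logical per position).
#' @export
extract_pocket <- function(domain_seq, profile, domain_id = NULL,
                           allow_incomplete = FALSE) {
  stopifnot(inherits(profile, "pdz_profile"))
  domain_seq <- toupper(as.character(domain_seq))
  if (nchar(domain_seq) < 50) {
    stop("domain sequence too short (< 50 residues)", call. = FALSE)
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(profile$sequence),
    subject = Biostrings::AAString(domain_seq),
    type = "global",
    substitutionMatrix = profile$substitution_matrix,
    gapOpening = profile$gap_opening,
    gapExtension = profile$gap_extension)
  ref_gapped <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  qry_gapped <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ref_pos <- cumsum(ref_gapped != "-")
  # alignment column of each reference position (gap columns carry no ref pos)
  col_of_ref <- match(profile$pocket_columns, ref_pos)
  residues <- qry_gapped[col_of_ref]
  gap_free <- !is.na(residues) & residues != "-"
  if (!all(gap_free)) {
    if (!allow_incomplete) {
      stop("incomplete pocket: ", sum(!gap_free),
           " annotated column(s) aligned to a gap", call. = FALSE)
    }
    residues[!gap_free | is.na(residues)] <- "-"
  }
  structure(
    list(domain_id = domain_id,
         residues = paste(residues, collapse = ""),
         key_positions = profile$key_positions,
         gap_free = gap_free),
    class = "binding_pocket")
}

#' @export
print.binding_pocket <- function(x, ...) {
  cat("PDZ binding pocket", if (!is.null(x$domain_id)) x$domain_id else "",
      "\n  ", x$residues, "\n  alphaB1 (pos 14): ",
      substr(x$residues, 14, 14), "  alphaB5 (pos 16): ",
      substr(x$residues, 16, 16), "\n", sep = "")
  invisible(x)
}

.pocket_string <- function(pocket) {
  s <- if (inherits(pocket, "binding_pocket")) pocket$residues else
    toupper(as.character(pocket))
  if (any(nchar(s) != 18)) {
    stop("binding pockets must have exactly 18 residues", call. = FALSE)
  }
  s
}

#' Substitute residues in a binding pocket
#'
#' Pure function: returns a new pocket differing from the input only at
#' the given positions. The canonical promiscuity-conferring substitution
#' is `c("14" = "H", "16" = "V")` (histidine at alphaB1, valine at
#' alphaB5); the reverse substitutions model loss of promiscuity.
#'
#' @param pocket An 18-residue pocket string or a `binding_pocket`.
#' @param substitutions Named character vector: names are pocket positions
#'   (1..18), values single residue codes. Empty map returns the input
#'   pocket unchanged.
#' @return Pocket of the same type as the input.
#' @export
#' @examples
#' mutate_pocket("GLGFSIAGGRDNPHSEQG", c("14" = "H", "16" = "V"))
mutate_pocket <- function(pocket, substitutions) {
  s <- .pocket_string(pocket)
  if (length(substitutions) > 0) {
    pos <- as.integer(names(substitutions))
    res <- toupper(as.character(substitutions))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > 18L)) {
      stop("substitution positions must be in 1..18", call. = FALSE)
    }
    if (any(!res %in% .AA20)) {
      stop("substitution residues must be standard amino acids", call. = FALSE)
    }
    chars <- strsplit(s, "")[[1]]
    chars[pos] <- res
    s <- paste(chars, collapse = "")
  }
  if (inherits(pocket, "binding_pocket")) {
    pocket$residues <- s
    pocket
  } else {
    s
  }
}

#' Read / write binding-pocket tables
#'
#' Two-column tab-separated dialect of the supplementary pocket file:
#' `domain_id<TAB>pocket18`, no header. An optional third column carries
#' group labels (used by the synthetic generator's truth output).
#'
#' @param path File path.
#' @return `read_pockets`: data frame with columns `domain_id`, `pocket`
#'   (and `group` if present in the file).
#' @export
read_pockets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  names(df) <- c("domain_id", "pocket", "group")[seq_len(ncol(df))]
  if (any(nchar(df$pocket) != 18)) {
    stop("malformed pocket table: entries must be 18-mers", call. = FALSE)
  }
  df
}

#' @rdname read_pockets
#' @param pockets Data frame with columns `domain_id`, `pocket` (optionally
#'   `group`).
#' @export
write_pockets <- function(pockets, path) {
  cols <- intersect(c("domain_id", "pocket", "group"), names(pockets))
  utils::write.table(pockets[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
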