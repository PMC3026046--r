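## The additive pairwise lookup table behind the psi score.
##
## psi(pocket, ligand) = intercept +
##   sum over contact pairs (i, j) of  weights[(i,j)][pocket[i], ligand[j]]
##
## i is a pocket position (1..18), j a ligand position (0, -1, ..., -4 with
## 0 the C-terminus). Residues outside the standard 20 contribute the
## neutral weight 0, as do (residue, residue) entries absent from a sparse
## table. All model structure lives in the parameter file: the engine makes
## no assumption about which contact pairs exist.

.LIGAND_POSITIONS <- 0:-4

# 21st row/column holds the neutral weight for unknown residues
.empty_weight_matrix <- function() {
  matrix(0, 21, 21, dimnames = list(c(.AA20, "X"), c(.AA20, "X")))
}

#' Construct a psi lookup table
#'
#' @param weights Long-format data frame with columns `pocket_pos` (1..18),
#'   `ligand_pos` (0..-4), `pocket_aa`, `ligand_aa`, `weight`. Entries not
#'   listed default to 0 (sparse tables are legal). Alternatively a named
#'   list as stored in a `pdz_lookup` (internal fast path).
#' @param intercept Additive constant of the model.
#' @param threshold Binder-call threshold theta; scores at or above it are
#'   called binders. The published calibration is theta = 0.798,
#'   corresponding to predicted Kd < 100 uM at a stated false positive
#'   rate of 6.27%.
#' @param fpr Stated false positive rate (percent) of the threshold, kept
#'   as metadata.
#' @param provenance Free-text origin of the parameters.
#' @return A `pdz_lookup` object.
#' @export
lookup_table <- function(weights, intercept = 0, threshold = 0.798,
                         fpr = 6.27, provenance = "") {
  if (is.data.frame(weights)) {
    req <- c("pocket_pos", "ligand_pos", "pocket_aa", "ligand_aa", "weight")
    if (!all(req %in% names(weights))) {
      stop("weights data frame needs columns: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    key <- paste(weights$pocket_pos, weights$ligand_pos,
                 weights$pocket_aa, weights$ligand_aa)
    if (anyDuplicated(key)) {
      stop("duplicate weight entry for contact pair/residue combination",
           call. = FALSE)
    }
    pairs <- unique(weights[, c("pocket_pos", "ligand_pos")])
    W <- vector("list", nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      m <- .empty_weight_matrix()
      rows <- weights$pocket_pos == pairs$pocket_pos[p] &
        weights$ligand_pos == pairs$ligand_pos[p]
      m[cbind(.aa_encode(weights$pocket_aa[rows]),
              .aa_encode(weights$ligand_aa[rows]))] <- weights$weight[rows]
      W[[p]] <- m
    }
  } else {
    pairs <- attr(weights, "pairs")
    W <- weights
  }
  .validate_lookup(pairs, W, intercept, threshold)
  structure(
    list(pairs = as.data.frame(pairs), W = W, intercept = intercept,
         threshold = threshold, fpr = fpr, provenance = provenance),
    class = "pdz_lookup")
}

.validate_lookup <- function(pairs, W, intercept, threshold) {
  if (anyDuplicated(paste(pairs$pocket_pos, pairs$ligand_pos))) {
    stop("duplicate contact pair in lookup table", call. = FALSE)
  }
  if (!all(pairs$pocket_pos %in% 1:18)) {
    stop("pocket positions must be in 1..18", call. = FALSE)
  }
  if (!all(pairs$ligand_pos %in% .LIGAND_POSITIONS)) {
    stop("ligand positions must be in 0..-4", call. = FALSE)
  }
  finite <- vapply(W, function(m) all(is.finite(m)), logical(1))
  if (!all(finite) || !is.finite(intercept) || !is.finite(threshold)) {
    stop("all weights, intercept and threshold must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.pdz_lookup <- function(x, ...) {
  nw <- sum(vapply(x$W, function(m) sum(m != 0), integer(1)))
  cat(sprintf(paste0("psi lookup table: %d contact pairs, %d non-zero weights\n",
                     "  intercept %.4f, threshold %.3f, stated FPR %.2f%%\n"),
              nrow(x$pairs), nw, x$intercept, x$threshold, x$fpr))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a psi lookup table
#'
#' Canonical text format: `#`-prefixed header lines `#intercept <float>`,
#' `#threshold <float>`, `#fpr <float>`, followed by tab-separated data
#' rows `pocket_pos<TAB>ligand_pos<TAB>pocket_aa<TAB>ligand_aa<TAB>weight`.
#' Unlisted (residue, residue) entries are 0. The `dialect` argument is
#' the adapter seam for externally distributed table layouts; only
#' `"canonical"` is built in.
#'
#' @param path File path.
#' @param dialect Table layout name.
#' @return A `pdz_lookup`.
#' @export
read_lookup_table <- function(path, dialect = "canonical") {
  if (!identical(dialect, "canonical")) {
    stop("unknown lookup-table dialect: '", dialect, "'", call. = FALSE)
  }
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  meta <- list(intercept = 0, threshold = 0.798, fpr = NA_real_)
  for (h in lines[is_header]) {
    parts <- strsplit(sub("^#", "", h), "[ \t]+")[[1]]
    if (parts[1] %in% names(meta)) meta[[parts[1]]] <- as.numeric(parts[2])
  }
  data_idx <- which(!is_header & nzchar(lines))
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5)) {
    stop("malformed lookup-table row at line ",
         data_idx[which(nf != 5)[1]], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  df <- data.frame(pocket_pos = as.integer(m[, 1]),
                   ligand_pos = as.integer(m[, 2]),
                   pocket_aa = m[, 3], ligand_aa = m[, 4],
                   weight = as.numeric(m[, 5]))
  if (any(is.na(df$pocket_pos)) || any(is.na(df$weight))) {
    bad <- which(is.na(df$pocket_pos) | is.na(df$weight))[1]
    stop("malformed lookup-table row at line ", data_idx[bad], call. = FALSE)
  }
  key <- paste(df$pocket_pos, df$ligand_pos, df$pocket_aa, df$ligand_aa)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop("duplicate lookup-table entry at line ", data_idx[bad], call. = FALSE)
  }
  lookup_table(df, intercept = meta$intercept, threshold = meta$threshold,
               fpr = meta$fpr, provenance = path)
}

#' Write a psi lookup table (canonical format)
#'
#' Only non-zero weights are written; [read_lookup_table()] restores the
#' rest as zeros.
#'
#' @param table A `pdz_lookup`.
#' @param path Output file path.
#' @export
write_lookup_table <- function(table, path) {
  stopifnot(inherits(table, "pdz_lookup"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#intercept %.17g", table$intercept),
               sprintf("#threshold %.17g", table$threshold),
               sprintf("#fpr %.17g", table$fpr)), con)
  aa <- c(.AA20, "X")
  for (p in seq_len(nrow(table$pairs))) {
    nz <- which(table$W[[p]] != 0, arr.ind = TRUE)
    if (nrow(nz) == 0) {
      next
    }
    writeLines(sprintf("%d\t%d\t%s\t%s\t%.17g",
                       table$pairs$pocket_pos[p], table$pairs$ligand_pos[p],
                       aa[nz[, 1]], aa[nz[, 2]],
                       table$W[[p]][nz]), con)
  }
  invisible(path)
}
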