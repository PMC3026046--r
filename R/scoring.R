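## The psi-scoring engine: score pockets against C-terminal ligands,
## call binders at the threshold, estimate the false positive rate.

# Shared core: pockets/ligands as integer code matrices, one contribution
# per contact pair. `cross = TRUE` returns the full pockets x ligands
# matrix; otherwise pockets and ligands are paired element-wise.
.psi_core <- function(pk_codes, lg_codes, table, cross) {
  pairs <- table$pairs
  if (cross) {
    S <- matrix(table$intercept, nrow(pk_codes), nrow(lg_codes))
    for (p in seq_len(nrow(pairs))) {
      S <- S + table$W[[p]][pk_codes[, pairs$pocket_pos[p]],
                            lg_codes[, 5L + pairs$ligand_pos[p]]]
    }
  } else {
    S <- rep(table$intercept, nrow(pk_codes))
    for (p in seq_len(nrow(pairs))) {
      S <- S + table$W[[p]][cbind(pk_codes[, pairs$pocket_pos[p]],
                                  lg_codes[, 5L + pairs$ligand_pos[p]])]
    }
  }
  S
}

#' psi binding score of pocket/ligand pairs
#'
#' The additive lookup-table score:
#' \deqn{\psi = intercept + \sum_{(i,j)} w_{ij}(pocket_i, ligand_j)}
#' over the table's contact pairs. Vectorised and paired element-wise;
#' length-1 arguments are recycled.
#'
#' @param pockets Character vector of 18-residue pocket strings (or
#'   `binding_pocket` objects via [mutate_pocket()] conventions).
#' @param ligands Character vector of 5-residue C-terminal peptides.
#' @param table A `pdz_lookup`.
#' @return Numeric vector of psi scores.
#' @export
psi_score <- function(pockets, ligands, table) {
  stopifnot(inherits(table, "pdz_lookup"))
  pockets <- .pocket_string(pockets)
  ligands <- toupper(as.character(ligands))
  n <- max(length(pockets), length(ligands))
  if (length(pockets) == 1L) pockets <- rep(pockets, n)
  if (length(ligands) == 1L) ligands <- rep(ligands, n)
  if (length(pockets) != length(ligands)) {
    stop("pockets and ligands must have equal length (or length 1)",
         call. = FALSE)
  }
  .psi_core(.encode_strings(pockets, 18L), .encode_strings(ligands, 5L),
            table, cross = FALSE)
}

#' Genome-wide psi score matrix
#'
#' Scores every pocket against every ligand: entry (d, l) equals
#' `psi_score(pocket_d, ligand_l, table)`. Residues are encoded once, so
#' a full PDZome x proteome run (hundreds of pockets against tens of
#' thousands of C-termini) takes seconds.
#'
#' @inheritParams psi_score
#' @param pockets Named character vector of pocket 18-mers (names become
#'   row names), or a data frame with columns `domain_id`, `pocket`.
#' @param ligands Named character vector of ligand 5-mers, or a data frame
#'   with columns `protein_id`, `cterm`.
#' @return Numeric matrix, pockets in rows, ligands in columns.
#' @export
score_matrix <- function(pockets, ligands, table) {
  stopifnot(inherits(table, "pdz_lookup"))
  if (is.data.frame(pockets)) {
    pockets <- stats::setNames(pockets$pocket, pockets$domain_id)
  }
  if (is.data.frame(ligands)) {
    ligands <- stats::setNames(ligands$cterm, ligands$protein_id)
  }
  if (length(pockets) == 0 || length(ligands) == 0) {
    stop("pockets and ligands must be non-empty", call. = FALSE)
  }
  S <- .psi_core(.encode_strings(toupper(pockets), 18L),
                 .encode_strings(toupper(ligands), 5L),
                 table, cross = TRUE)
  dimnames(S) <- list(names(pockets), names(ligands))
  S
}

#' Call predicted interactions above the binder threshold
#'
#' Thresholds a psi score matrix into an interaction set. Ties at the
#' threshold are called binders (comparison is `>=`); pass
#' `strict = TRUE` for a strict `>`.
#'
#' @param matrix psi score matrix from [score_matrix()].
#' @param threshold Binder threshold theta (default 0.798).
#' @param strict Use strict `>` instead of `>=`.
#' @return Data frame with columns `domain_id`, `ligand_id`, `psi`
#'   (class `interaction_set`, threshold kept as attribute), ordered by
#'   domain then ligand.
#' @export
predict_interactions <- function(matrix, threshold = 0.798, strict = FALSE) {
  hit <- if (strict) matrix > threshold else matrix >= threshold
  idx <- which(hit, arr.ind = TRUE)
  rn <- rownames(matrix)
  cn <- colnames(matrix)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(matrix)))
  if (is.null(cn)) cn <- as.character(seq_len(ncol(matrix)))
  out <- data.frame(domain_id = rn[idx[, 1]],
                    ligand_id = cn[idx[, 2]],
                    psi = matrix[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$domain_id, out$ligand_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Estimate the false positive rate on null peptides
#'
#' Fraction of (pocket, null ligand) pairs scoring at or above the
#' threshold, with an exact binomial confidence interval. The null
#' ligands should come from a stated null model (uniform-random or
#' shuffled 5-mers). With `pairing = "paired"`, pocket i is scored only
#' against ligand i, so pairs are independent and the binomial interval
#' is exact; `"cross"` scores all combinations (pairs sharing a pocket
#' are then dependent and the interval is approximate).
#'
#' @inheritParams psi_score
#' @param null_ligands Character vector of null 5-mers (>= 100).
#' @param threshold Binder threshold; defaults to the table's.
#' @param pairing `"paired"` or `"cross"`.
#' @param conf_level Confidence level of the interval.
#' @return List with `fpr`, `conf_int`, `n_pairs`, `n_hits`.
#' @export
estimate_fpr <- function(table, pockets, null_ligands,
                         threshold = table$threshold,
                         pairing = c("paired", "cross"),
                         conf_level = 0.95) {
  pairing <- match.arg(pairing)
  if (length(null_ligands) == 0) {
    stop("null ligand set is empty", call. = FALSE)
  }
  if (length(null_ligands) < 100) {
    warning("fewer than 100 null ligands; the FPR estimate will be coarse")
  }
  if (pairing == "paired") {
    psi <- psi_score(pockets, null_ligands, table)
  } else {
    psi <- as.vector(score_matrix(pockets, null_ligands, table))
  }
  hits <- sum(psi >= threshold)
  n <- length(psi)
  ci <- stats::binom.test(hits, n, conf.level = conf_level)$conf.int
  list(fpr = hits / n, conf_int = as.numeric(ci), n_pairs = n, n_hits = hits)
}

#' Read / write interaction sets
#'
#' Tab-separated `domain_id<TAB>ligand_id<TAB>psi` with a header line.
#'
#' @param path File path.
#' @export
read_interactions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c("interaction_set", "data.frame")
  df
}

#' @rdname read_interactions
#' @param calls An `interaction_set` data frame.
#' @export
write_interactions <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
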