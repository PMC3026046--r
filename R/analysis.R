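## Downstream analyses of the psi score matrix: cross-reactivity,
## two-group clustering, PWMs, pocket enrichment, mutation scans, assay
## summaries, and the two-sample comparisons used throughout.

#' Cross-reactivity statistics of a predicted interaction set
#'
#' A domain "shares" ligands when its called ligand set intersects at
#' least one other domain's set (literal non-empty pairwise
#' intersection). Reports how many domains share, how many distinct
#' ligands are called by two or more domains, and the mean +/- s.e.m.
#' ligand count over the sharing domains.
#'
#' @param calls An `interaction_set` (data frame with `domain_id`,
#'   `ligand_id`).
#' @return List with `ligand_counts` (per domain), `n_sharing_domains`,
#'   `n_shared_ligands`, `mean_ligands`, `sem_ligands` (over sharing
#'   domains). Empty input returns zeros.
#' @export
overlap_stats <- function(calls) {
  if (nrow(calls) == 0) {
    return(list(ligand_counts = integer(0), n_sharing_domains = 0L,
                n_shared_ligands = 0L, mean_ligands = NA_real_,
                sem_ligands = NA_real_))
  }
  sets <- split(calls$ligand_id, calls$domain_id)
  counts <- lengths(sets)
  multiplicity <- table(unique(calls[, c("domain_id", "ligand_id")])$ligand_id)
  shared_ligands <- names(multiplicity)[multiplicity >= 2]
  sharing <- vapply(sets, function(s) any(s %in% shared_ligands), logical(1))
  share_counts <- counts[sharing]
  list(ligand_counts = counts,
       n_sharing_domains = sum(sharing),
       n_shared_ligands = length(shared_ligands),
       mean_ligands = if (length(share_counts)) mean(share_counts) else NA_real_,
       sem_ligands = if (length(share_counts) > 1)
         stats::sd(share_counts) / sqrt(length(share_counts)) else NA_real_)
}

#' Predicted ligand count per domain
#'
#' @inheritParams overlap_stats
#' @param domain_ids Optional domain universe; domains without calls get
#'   count 0.
#' @return List with `counts` (named), `mean`, `sem`.
#' @export
ligand_counts_per_domain <- function(calls, domain_ids = NULL) {
  counts <- table(factor(calls$domain_id,
                         levels = if (is.null(domain_ids))
                           sort(unique(calls$domain_id)) else domain_ids))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       mean = if (length(counts)) mean(counts) else NA_real_,
       sem = if (length(counts) > 1)
         stats::sd(counts) / sqrt(length(counts)) else NA_real_)
}

# Row-row distance matrices. "uncentered" is the correlation without mean
# centering (cosine similarity), the classic expression-clustering default;
# "pearson" centers each row first. Zero-variance/zero-norm rows get
# similarity 1 with identical rows and 0 otherwise, so degenerate inputs
# stay clusterable.
.row_distance <- function(mat, distance) {
  if (distance == "euclidean") {
    return(stats::dist(mat))
  }
  if (distance == "uncentered") {
    nrm <- sqrt(rowSums(mat^2))
    X <- mat / ifelse(nrm > 0, nrm, 1)
    sim <- tcrossprod(X)
  } else {
    sim <- suppressWarnings(stats::cor(t(mat)))
  }
  if (anyNA(sim)) {
    bad <- which(is.na(sim), arr.ind = TRUE)
    same <- rowSums(abs(mat[bad[, 1], , drop = FALSE] -
                        mat[bad[, 2], , drop = FALSE])) == 0
    sim[bad] <- ifelse(same, 1, 0)
  }
  stats::as.dist(1 - sim)
}

#' Hierarchical clustering of binding-score profiles
#'
#' Agglomerative clustering of the score matrix rows (domains), cut into
#' `k` groups. Clustering operates on the raw psi values, positive and
#' negative; binder calls enter only through the per-group mean ligand
#' counts. Defaults mirror the classic expression-clustering setup:
#' distance one minus the uncentered correlation, average linkage, k = 2
#' (the specific-versus-promiscuous split).
#'
#' @param matrix psi score matrix (domains in rows).
#' @param k Number of groups to cut the tree into.
#' @param distance `"uncentered"`, `"pearson"` or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param threshold Binder threshold used for the group ligand-count
#'   summaries.
#' @return A `pdz_clusters` list: `labels` (named group per domain),
#'   `sizes`, `group_mean_ligands`, `ligand_counts`, `hclust`, `params`.
#'   Group 1 is the group with the lower mean ligand count (the
#'   ligand-specific group) when k = 2.
#' @export
cluster_scores <- function(matrix, k = 2,
                           distance = c("uncentered", "pearson", "euclidean"),
                           linkage = "average", threshold = 0.798) {
  distance <- match.arg(distance)
  if (k > nrow(matrix)) {
    stop("k exceeds the number of domains", call. = FALSE)
  }
  hc <- stats::hclust(.row_distance(matrix, distance), method = linkage)
  labels <- stats::cutree(hc, k = k)
  counts <- rowSums(matrix >= threshold)
  means <- tapply(counts, labels, mean)
  # relabel so groups are ordered by increasing promiscuity
  ord <- order(means)
  relab <- match(labels, ord)
  names(relab) <- rownames(matrix)
  structure(
    list(labels = relab,
         sizes = as.integer(table(relab)),
         group_mean_ligands = as.numeric(means[ord]),
         ligand_counts = counts,
         hclust = hc,
         params = list(k = k, distance = distance, linkage = linkage,
                       threshold = threshold)),
    class = "pdz_clusters")
}

#' @export
print.pdz_clusters <- function(x, ...) {
  cat(sprintf("PDZ score clustering (%s distance, %s linkage, k = %d)\n",
              x$params$distance, x$params$linkage, x$params$k))
  for (g in seq_along(x$sizes)) {
    cat(sprintf("  group %d: %d domains, mean %.1f ligands at theta = %.3f\n",
                g, x$sizes[g], x$group_mean_ligands[g], x$params$threshold))
  }
  invisible(x)
}

#' Position weight matrix of a ligand set
#'
#' Unweighted residue frequencies of the called ligands at positions
#' -4..0. No pseudocounts by default.
#'
#' @param ligands Character vector of 5-mer ligand peptides (e.g. the
#'   called ligands of one domain).
#' @param pseudocount Added to every count before normalising.
#' @return 20 x 5 matrix (`pdz_pwm`), residues in rows, positions
#'   `-4,...,0` in columns; columns sum to 1. Attribute `n` carries the
#'   support.
#' @export
build_pwm <- function(ligands, pseudocount = 0) {
  ligands <- toupper(as.character(ligands))
  if (length(ligands) == 0) {
    stop("cannot build a PWM from zero ligands", call. = FALSE)
  }
  if (any(nchar(ligands) != 5)) {
    stop("ligands must be 5-mers", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(ligands, "", fixed = TRUE)),
                  ncol = 5, byrow = TRUE)
  pwm <- vapply(1:5, function(j) {
    cnt <- table(factor(chars[, j], levels = .AA20)) + pseudocount
    as.numeric(cnt) / sum(cnt)
  }, numeric(20))
  dimnames(pwm) <- list(.AA20, as.character(-4:0))
  attr(pwm, "n") <- length(ligands)
  class(pwm) <- c("pdz_pwm", class(pwm))
  pwm
}

#' Similarity between two position weight matrices
#'
#' Mean over positions of the Pearson correlation between the 20-residue
#' frequency vectors. A position where either column has zero variance
#' (e.g. a uniform column) contributes 0, so the similarity stays
#' defined.
#'
#' @param a,b PWMs of identical shape.
#' @return Similarity in \[-1, 1\]; 1 for identical PWMs.
#' @export
compare_pwms <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    stop("PWMs must have identical dimensions", call. = FALSE)
  }
  per_pos <- vapply(seq_len(ncol(a)), function(j) {
    if (stats::sd(a[, j]) == 0 || stats::sd(b[, j]) == 0) {
      return(0)
    }
    stats::cor(a[, j], b[, j])
  }, numeric(1))
  mean(per_pos)
}

#' Residue enrichment of binding pockets by group
#'
#' Per-group, per-position residue frequencies of the 18-mer pockets,
#' e.g. the fraction of promiscuous pockets with histidine at alphaB1
#' (position 14) or valine at alphaB5 (position 16). Positions whose
#' modal-residue frequency differs between two groups by more than
#' `margin` are flagged.
#'
#' @param pockets Character vector of 18-mer pocket strings.
#' @param groups Group label per pocket (same length).
#' @param margin Flagging margin on the modal-residue frequency
#'   difference.
#' @return A `pocket_enrichment` list: `fractions` (one 20 x 18 matrix
#'   per group; columns sum to 1), `sizes`, `flagged_positions`.
#' @export
pocket_enrichment <- function(pockets, groups, margin = 0.25) {
  if (length(pockets) == 0) {
    stop("every group must contain at least one pocket", call. = FALSE)
  }
  pockets <- .pocket_string(pockets)
  if (length(pockets) != length(groups)) {
    stop("pockets and groups must have equal length", call. = FALSE)
  }
  split_pockets <- split(pockets, groups)
  if (any(lengths(split_pockets) == 0)) {
    stop("every group must contain at least one pocket", call. = FALSE)
  }
  fractions <- lapply(split_pockets, function(pk) {
    chars <- matrix(unlist(strsplit(pk, "", fixed = TRUE)),
                    ncol = 18, byrow = TRUE)
    f <- vapply(1:18, function(i) {
      cnt <- table(factor(chars[, i], levels = .AA20))
      as.numeric(cnt) / length(pk)
    }, numeric(20))
    dimnames(f) <- list(.AA20, as.character(1:18))
    f
  })
  flagged <- integer(0)
  if (length(fractions) >= 2) {
    g1 <- fractions[[1]]
    g2 <- fractions[[2]]
    modal_diff <- vapply(1:18, function(i) {
      max(abs(g1[, i] - g2[, i]))
    }, numeric(1))
    flagged <- which(modal_diff > margin)
  }
  structure(list(fractions = fractions,
                 sizes = lengths(split_pockets),
                 flagged_positions = flagged,
                 margin = margin),
            class = "pocket_enrichment")
}

#' In-silico mutation scan of a binding pocket
#'
#' Scores a pocket against a ligand panel before and after each
#' substitution set and records binder-call changes at the threshold: a
#' `gain` crosses theta upward, a `loss` downward. The canonical forward
#' scan installs H at alphaB1 and V at alphaB5 of a non-promiscuous
#' pocket; the reverse scan removes them from a promiscuous one.
#'
#' @param pocket 18-mer pocket string (or `binding_pocket`).
#' @param substitutions A named character vector (single set) or a list of
#'   them; list names label the sets.
#' @param ligands Named character vector of panel 5-mers.
#' @param table A `pdz_lookup`.
#' @param threshold Binder threshold.
#' @return Data frame with columns `set`, `ligand_id`, `psi_before`,
#'   `psi_after`, `delta`, `call_change` (`gain`/`loss`/`none`).
#' @export
mutation_scan <- function(pocket, substitutions, ligands, table,
                          threshold = table$threshold) {
  if (!is.list(substitutions)) {
    substitutions <- list(substitutions)
  }
  if (is.null(names(substitutions))) {
    names(substitutions) <- paste0("set", seq_along(substitutions))
  }
  lig_ids <- if (is.null(names(ligands)))
    as.character(seq_along(ligands)) else names(ligands)
  before <- psi_score(.pocket_string(pocket), ligands, table)
  out <- lapply(names(substitutions), function(nm) {
    mut <- mutate_pocket(.pocket_string(pocket), substitutions[[nm]])
    after <- psi_score(mut, ligands, table)
    change <- rep("none", length(ligands))
    change[before < threshold & after >= threshold] <- "gain"
    change[before >= threshold & after < threshold] <- "loss"
    data.frame(set = nm, ligand_id = lig_ids, psi_before = before,
               psi_after = after, delta = after - before,
               call_change = change, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  res
}

#' Summarise replicate binding-assay readings
#'
#' Per (construct, peptide): mean, standard deviation (n - 1 denominator)
#' and replicate count of the absorbance readings (ELISA-style assays
#' read at 450 nm typically use n = 6 replicates).
#'
#' @param plate Data frame with columns `construct`, `peptide`,
#'   `absorbance` (a `replicate` column is allowed and ignored).
#' @return Data frame with columns `construct`, `peptide`, `mean`, `sd`,
#'   `n`.
#' @export
summarize_assay <- function(plate) {
  req <- c("construct", "peptide", "absorbance")
  if (!all(req %in% names(plate))) {
    stop("plate needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  key <- interaction(plate$construct, plate$peptide, drop = TRUE)
  n <- tapply(plate$absorbance, key, length)
  if (any(n < 2)) {
    stop("every (construct, peptide) pair needs >= 2 replicates",
         call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(plate, key), function(d) {
    data.frame(construct = d$construct[1], peptide = d$peptide[1],
               mean = mean(d$absorbance), sd = stats::sd(d$absorbance),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$construct, agg$peptide), , drop = FALSE]
}

#' Two-sample comparison of group measurements
#'
#' Two-sided two-sample Student t-test (equal variances pooled), the
#' comparison used for cross-species ligand counts and network group
#' distributions. Welch's unequal-variance form is available via
#' `welch = TRUE`.
#'
#' @param sample_a,sample_b Numeric vectors, each with n >= 2.
#' @param welch Use Welch's t-test instead of Student's.
#' @return List with `t`, `p_value`, `df`.
#' @export
compare_groups <- function(sample_a, sample_b, welch = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(sample_a) + stats::var(sample_b) == 0) {
    stop("zero pooled variance: the t statistic is undefined", call. = FALSE)
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = !welch)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
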