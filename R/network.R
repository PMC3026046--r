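## Interactome context: multi-database edge consensus, degree statistics,
## power-law fits, GO compartment distributions, and the four-step
## contextual filter that reduces inherent PDZ binding overlap.

#' GO compartment code labels
#'
#' Subcellular localisation encoding used on interactome nodes:
#' 0 unknown, 1 nucleus, 2 cytoplasm, 3 plasma membrane, 4 mitochondria,
#' 5 multiple compartments but non-nuclear, 6 all compartments,
#' 7 extracellular.
#'
#' @return Named character vector (names are the codes `0`..`7`).
#' @export
go_compartment_codes <- function() {
  c("0" = "unknown", "1" = "nucleus", "2" = "cytoplasm",
    "3" = "plasma membrane", "4" = "mitochondria",
    "5" = "multiple non-nuclear", "6" = "all compartments",
    "7" = "extracellular")
}

.normalize_ids <- function(ids, synonyms) {
  if (is.null(synonyms)) {
    return(ids)
  }
  hit <- match(ids, synonyms$alias)
  ifelse(is.na(hit), ids, synonyms$canonical[hit])
}

#' Merge interaction edge lists into a consensus graph
#'
#' Union of edge lists from several source databases, as an undirected
#' simple graph with per-edge source counts. "Consensus" is reachable by
#' raising `min_sources` (e.g. 2 keeps only edges reported by two or
#' more databases). Identifiers are normalised through an optional
#' synonym map before merging; rows with missing identifiers are skipped
#' and counted.
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`,
#'   `source`, or a named list of two-column data frames (names used as
#'   source tags).
#' @param min_sources Minimum number of distinct source databases per
#'   edge.
#' @param synonyms Optional data frame with columns `alias`, `canonical`.
#' @return An [igraph::graph] with edge attributes `n_sources` and
#'   `sources`, and attribute `n_skipped` counting dropped rows.
#' @export
merge_databases <- function(edges, min_sources = 1, synonyms = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) {
    tags <- names(edges)
    if (is.null(tags)) tags <- paste0("db", seq_along(edges))
    edges <- do.call(rbind, lapply(seq_along(edges), function(i) {
      e <- edges[[i]]
      data.frame(protein_a = e[[1]], protein_b = e[[2]], source = tags[i],
                 stringsAsFactors = FALSE)
    }))
  }
  a <- .normalize_ids(as.character(edges$protein_a), synonyms)
  b <- .normalize_ids(as.character(edges$protein_b), synonyms)
  src <- as.character(edges$source)
  bad <- is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b)
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    message(n_skipped, " edge row(s) with unresolvable identifiers skipped")
    a <- a[!bad]; b <- b[!bad]; src <- src[!bad]
  }
  # undirected canonical form; drop self-loops
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- lo != hi
  key <- paste(lo[keep], hi[keep], sep = "\r")
  src_by_edge <- lapply(split(src[keep], key), unique)
  n_src <- lengths(src_by_edge)
  sel <- n_src >= min_sources
  parts <- strsplit(names(src_by_edge)[sel], "\r", fixed = TRUE)
  el <- data.frame(from = vapply(parts, `[`, "", 1),
                   to = vapply(parts, `[`, "", 2),
                   n_sources = n_src[sel],
                   sources = vapply(src_by_edge[sel], paste,
                                    "", collapse = ","),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  g <- igraph::set_graph_attr(g, "n_skipped", n_skipped)
  g
}

#' Degree distribution and CCDF of a node set
#'
#' Degree histogram plus the complementary cumulative distribution
#' P(degree >= k) over the observed degrees, the form used for
#' power-law fitting.
#'
#' @param graph An igraph graph.
#' @param nodes Optional vertex names restricting the node set.
#' @return Data frame with columns `k`, `count`, `ccdf` (non-increasing).
#' @export
degree_distribution <- function(graph, nodes = NULL) {
  deg <- if (is.null(nodes)) igraph::degree(graph) else
    igraph::degree(graph, v = nodes)
  if (length(deg) == 0) {
    stop("empty node set", call. = FALSE)
  }
  ks <- sort(unique(deg))
  data.frame(k = ks,
             count = as.integer(table(factor(deg, levels = ks))),
             ccdf = vapply(ks, function(k) mean(deg >= k), numeric(1)))
}

#' Power-law fit of a degree distribution
#'
#' Ordinary least squares of log CCDF on log k over k >= k_min. Because
#' the CCDF of a degree density `p(k) ~ k^-gamma` falls as
#' `k^-(gamma - 1)`, the reported exponent is `1 - slope`, i.e. the
#' density exponent gamma (about 3 for a preferential-attachment
#' network). CCDF regression is robust to histogram binning noise;
#' maximum-likelihood fitting is a known alternative not used here.
#'
#' @param dist Data frame from [degree_distribution()] (or an igraph
#'   graph, converted internally).
#' @param k_min Lower fitting bound on the degree.
#' @return A `powerlaw_fit` list: `exponent`, `intercept`, `r_squared`,
#'   `k_min`, `n_points`.
#' @export
fit_degree_powerlaw <- function(dist, k_min = 1) {
  if (inherits(dist, "igraph")) {
    dist <- degree_distribution(dist)
  }
  pts <- dist[dist$k >= k_min & dist$k > 0 & dist$ccdf > 0, , drop = FALSE]
  if (length(unique(pts$k)) < 3) {
    stop("need at least 3 distinct degrees >= k_min to fit", call. = FALSE)
  }
  fit <- stats::lm(log(ccdf) ~ log(k), data = pts)
  structure(
    list(exponent = unname(1 - stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit))$r.squared,
         k_min = k_min,
         n_points = nrow(pts)),
    class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Degree power law: exponent %.2f (CCDF OLS, k >= %g, R^2 %.3f)\n",
              x$exponent, x$k_min, x$r_squared))
  invisible(x)
}

.node_compartment <- function(graph, nodes) {
  comp <- igraph::vertex_attr(graph, "compartment", index = nodes)
  if (is.null(comp)) comp <- rep(NA_integer_, length(nodes))
  comp[is.na(comp)] <- 0L
  as.integer(comp)
}

#' GO compartment distribution of a node group
#'
#' Counts and fractions of nodes over compartment codes 0..7; nodes
#' without annotation count as code 0 (unknown).
#'
#' @param graph An igraph graph with a `compartment` vertex attribute.
#' @param nodes Optional vertex names (default: all nodes).
#' @return Data frame with columns `code`, `label`, `count`, `fraction`.
#' @export
go_distribution <- function(graph, nodes = NULL) {
  if (is.null(nodes)) nodes <- igraph::V(graph)$name
  comp <- .node_compartment(graph, nodes)
  cnt <- table(factor(comp, levels = 0:7))
  data.frame(code = 0:7,
             label = unname(go_compartment_codes()),
             count = as.integer(cnt),
             fraction = as.integer(cnt) / max(length(nodes), 1L))
}

#' Compare two node groups by degree or compartment profile
#'
#' Student t-test between the groups' per-node degrees
#' (`axis = "degree"`) or between their 8-element compartment fraction
#' vectors (`axis = "compartment"`), mirroring the published even-
#' distribution checks (P > 0.30 over compartments, P > 0.90 over
#' degrees for the two promiscuity groups).
#'
#' @param graph An igraph graph.
#' @param group_a,group_b Vertex name vectors.
#' @param axis `"degree"` or `"compartment"`.
#' @return List with `t`, `p_value`, `df` (from [compare_groups()]).
#' @export
compare_group_distributions <- function(graph, group_a, group_b,
                                        axis = c("degree", "compartment")) {
  axis <- match.arg(axis)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (axis == "degree") {
    a <- as.numeric(igraph::degree(graph, v = group_a))
    b <- as.numeric(igraph::degree(graph, v = group_b))
  } else {
    a <- go_distribution(graph, group_a)$fraction
    b <- go_distribution(graph, group_b)$fraction
  }
  c(compare_groups(a, b), list(axis = axis))
}

# Compartment compatibility: code 0 (unknown) matches everything, 6 (all
# compartments) matches everything, 5 (multiple non-nuclear) matches the
# non-nuclear codes it spans.
.compartment_compatible <- function(a, b) {
  non_nuclear <- c(2L, 3L, 4L, 5L, 7L)
  a == b | a == 0L | b == 0L | a == 6L | b == 6L |
    (a == 5L & b %in% non_nuclear) | (b == 5L & a %in% non_nuclear)
}

#' Contextual filtering of predicted PDZ interactions
#'
#' The four-step mechanism that reduces inherent PDZ binding overlap in
#' the cell: (1) keep calls with psi at or above the threshold; (2) keep
#' pairs whose proteins share a GO compartment (codes 5 and 6 span
#' compartments, code 0 is compatible with everything); (3) optionally
#' keep pairs whose node degrees are within a relative band of each
#' other; (4) annotate calls whose PDZ protein carries another domain
#' calling the same ligand (binding-affinity redundancy within one
#' protein). Step 4 is annotation only: the surviving set is the
#' intersection of filters 1-3 and is invariant to their order.
#'
#' @param calls An `interaction_set` data frame.
#' @param graph Interactome with `compartment` vertex attributes.
#' @param pdz_protein_map Data frame with columns `domain_id`,
#'   `protein_id` mapping each PDZ domain to its carrier protein.
#' @param threshold psi threshold for step 1.
#' @param degree_band Relative degree band for step 3: pairs pass when
#'   `min(deg)/max(deg) >= 1 - degree_band`. `NULL` disables the step.
#' @return List with `calls` (survivors, plus columns `protein_id` and
#'   `sibling_overlap`), `dropped` (per-step counts) and `n_unresolved`
#'   (calls whose proteins are absent from the graph, skipped).
#' @export
contextual_filter <- function(calls, graph, pdz_protein_map,
                              threshold = 0.798, degree_band = NULL) {
  df <- as.data.frame(calls)
  df$protein_id <- pdz_protein_map$protein_id[
    match(df$domain_id, pdz_protein_map$domain_id)]
  vn <- igraph::V(graph)$name
  resolved <- !is.na(df$protein_id) & df$protein_id %in% vn &
    df$ligand_id %in% vn
  n_unresolved <- sum(!resolved)
  if (n_unresolved > 0) {
    message(n_unresolved, " call(s) with proteins absent from the graph skipped")
  }
  df <- df[resolved, , drop = FALSE]
  dropped <- c(below_threshold = 0L, compartment_mismatch = 0L,
               degree_mismatch = 0L)

  pass1 <- df$psi >= threshold
  dropped["below_threshold"] <- sum(!pass1)
  step1 <- df[pass1, , drop = FALSE]

  comp_p <- .node_compartment(graph, step1$protein_id)
  comp_l <- .node_compartment(graph, step1$ligand_id)
  pass2 <- .compartment_compatible(comp_p, comp_l)
  dropped["compartment_mismatch"] <- sum(!pass2)
  step2 <- step1[pass2, , drop = FALSE]

  if (!is.null(degree_band)) {
    deg <- igraph::degree(graph)
    d_p <- deg[step2$protein_id]
    d_l <- deg[step2$ligand_id]
    ratio <- ifelse(pmax(d_p, d_l) == 0, 1, pmin(d_p, d_l) / pmax(d_p, d_l))
    pass3 <- ratio >= 1 - degree_band
    dropped["degree_mismatch"] <- sum(!pass3)
    step2 <- step2[pass3, , drop = FALSE]
  }

  # step 4: flag same-protein sibling domains calling the same ligand
  all_called <- df[pass1, c("domain_id", "ligand_id"), drop = FALSE]
  all_called$protein_id <- pdz_protein_map$protein_id[
    match(all_called$domain_id, pdz_protein_map$domain_id)]
  sib_key <- paste(all_called$protein_id, all_called$ligand_id)
  sib_domains <- split(all_called$domain_id, sib_key)
  this_key <- paste(step2$protein_id, step2$ligand_id)
  step2$sibling_overlap <- vapply(seq_len(nrow(step2)), function(i) {
    doms <- sib_domains[[this_key[i]]]
    length(setdiff(doms, step2$domain_id[i])) > 0
  }, logical(1))
  rownames(step2) <- NULL
  list(calls = step2, dropped = dropped, n_unresolved = n_unresolved)
}
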