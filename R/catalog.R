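## PDZome catalog: multi-species gene records and their summary statistics.

.SPECIES_CODES <- c("Hs", "Mm", "Gg", "Xt", "Tn", "Tr", "Ci", "Dm", "Ce",
                    "Hv", "Sp", "Mb", "At", "Ec", "Pa")

# Metazoan species over which the mean PDZ-per-gene ratio is reported
.METAZOAN_CODES <- c("Hs", "Mm", "Gg", "Xt", "Tn", "Tr", "Ci", "Dm", "Ce",
                     "Hv", "Sp")

#' Construct a PDZome catalog
#'
#' A catalog is one row per PDZ-encoding gene with the number of PDZ domains
#' it encodes, its species, its essentiality status where known, and the
#' species' protein-coding genome size (used by [fit_size_scaling()]).
#'
#' @param records Data frame with columns `gene_id`, `species`,
#'   `n_pdz_domains`, `essential` (1 = essential, 0 = non-essential,
#'   `NA` = unknown) and `genome_size` (protein-coding gene count of the
#'   species; constant within species).
#' @param extra_species Character vector of species codes to accept beyond
#'   the 15 built-in codes.
#' @return A `pdz_catalog` object (validated data frame).
#' @export
pdz_catalog <- function(records, extra_species = character()) {
  required <- c("gene_id", "species", "n_pdz_domains", "essential", "genome_size")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$n_pdz_domains <- as.integer(records$n_pdz_domains)
  if (any(is.na(records$n_pdz_domains)) || any(records$n_pdz_domains < 1L)) {
    stop("every gene record must have n_pdz_domains >= 1", call. = FALSE)
  }
  allowed <- c(.SPECIES_CODES, extra_species)
  bad <- setdiff(unique(records$species), allowed)
  if (length(bad) > 0) {
    stop("unknown species code(s): ", paste(bad, collapse = ", "),
         "; register them via extra_species", call. = FALSE)
  }
  if (!all(records$essential %in% c(0, 1, NA))) {
    stop("essential must be 1, 0 or NA", call. = FALSE)
  }
  class(records) <- c("pdz_catalog", "data.frame")
  records
}

#' Read a PDZome catalog from CSV
#'
#' Flat CSV dialect of the PDZome supplementary workbook: columns
#' `gene_id,species,n_pdz_domains,essential,genome_size` with
#' `essential` in `{1, 0, NA}`.
#'
#' @param path Path to the CSV file.
#' @inheritParams pdz_catalog
#' @return A `pdz_catalog`.
#' @export
read_catalog <- function(path, extra_species = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pdz_catalog(df, extra_species = extra_species)
}

#' Write a PDZome catalog to CSV
#' @param catalog A `pdz_catalog`.
#' @param path Output file path.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.catalog_species <- function(catalog, species) {
  rows <- catalog[catalog$species == species, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("species '", species, "' not present in catalog", call. = FALSE)
  }
  rows
}

#' PDZ domains per gene
#'
#' The pooled ratio (total PDZ domains) / (number of PDZ-encoding genes)
#' for one species. The human PDZome, with 267 domains over 152 genes,
#' has ratio 1.76 (reported as 1.8:1).
#'
#' @param catalog A `pdz_catalog`.
#' @param species Single species code.
#' @return Ratio >= 1.
#' @seealso [mean_pdz_per_gene_ratio()] for the across-species mean.
#' @export
pdz_per_gene_ratio <- function(catalog, species) {
  rows <- .catalog_species(catalog, species)
  sum(rows$n_pdz_domains) / nrow(rows)
}

#' Mean PDZ-per-gene ratio over a species set
#'
#' Unweighted mean of the per-species pooled ratios. The default species
#' set is the metazoan codes (Hs through Sp), over which the ratio is
#' roughly constant at ~1.7.
#'
#' @inheritParams pdz_per_gene_ratio
#' @param species Character vector of species codes; species absent from
#'   the catalog are dropped (at least one must be present).
#' @export
mean_pdz_per_gene_ratio <- function(catalog, species = .METAZOAN_CODES) {
  present <- intersect(species, unique(catalog$species))
  if (length(present) == 0) {
    stop("none of the requested species are present in the catalog", call. = FALSE)
  }
  mean(vapply(present, function(s) pdz_per_gene_ratio(catalog, s), numeric(1)))
}

#' Fraction of essential PDZ-encoding genes
#'
#' Percentage of essential genes among genes with known essentiality
#' status; genes with unknown status are excluded from the denominator.
#'
#' @inheritParams pdz_per_gene_ratio
#' @return Percentage in \[0, 100\].
#' @export
essential_fraction <- function(catalog, species) {
  rows <- .catalog_species(catalog, species)
  known <- rows$essential[!is.na(rows$essential)]
  if (length(known) == 0) {
    stop("no gene with known essentiality status for species '", species, "'",
         call. = FALSE)
  }
  100 * sum(known == 1) / length(known)
}

#' Power-law fit of domain-family size against genome size
#'
#' Ordinary least squares of log(count) on log(genome size) across
#' species: `count = c * size^exponent`. Models the observation that
#' domain-family expansion over genomes is approximately a power law.
#'
#' @param catalog A `pdz_catalog`, or `NULL` if `genome_sizes` and
#'   `family_counts` are given directly.
#' @param family_counts Optional named numeric vector of per-species domain
#'   counts; defaults to the catalog's per-species PDZ domain totals.
#' @param genome_sizes Optional named numeric vector of per-species genome
#'   sizes; defaults to the catalog's `genome_size` column.
#' @return List with `exponent`, `intercept` (on the log scale),
#'   `r_squared` and `n_species`, class `scaling_fit`.
#' @export
fit_size_scaling <- function(catalog = NULL, family_counts = NULL,
                             genome_sizes = NULL) {
  if (is.null(family_counts)) {
    stopifnot(!is.null(catalog))
    family_counts <- tapply(catalog$n_pdz_domains, catalog$species, sum)
  }
  if (is.null(genome_sizes)) {
    stopifnot(!is.null(catalog))
    genome_sizes <- tapply(catalog$genome_size, catalog$species,
                           function(x) x[1])
  }
  if (!is.null(names(family_counts)) && !is.null(names(genome_sizes))) {
    common <- intersect(names(family_counts), names(genome_sizes))
    family_counts <- family_counts[common]
    genome_sizes <- genome_sizes[common]
  }
  ok <- is.finite(genome_sizes) & is.finite(family_counts) &
    genome_sizes > 0 & family_counts > 0
  if (sum(ok) < 3) {
    stop("need at least 3 species with positive genome size and count",
         call. = FALSE)
  }
  x <- log(as.numeric(genome_sizes[ok]))
  y <- log(as.numeric(family_counts[ok]))
  fit <- stats::lm(y ~ x)
  structure(
    list(exponent = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit))$r.squared,
         n_species = sum(ok)),
    class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Power-law size scaling over %d species: exponent %.3f (R^2 %.3f)\n",
              x$n_species, x$exponent, x$r_squared))
  invisible(x)
}

#' Distribution of PDZ domains per gene
#'
#' Percentage of a species' PDZ-encoding genes carrying 1, 2, ... PDZ
#' domains. Percentages sum to 100.
#'
#' @inheritParams pdz_per_gene_ratio
#' @return Named numeric vector: names are domain counts, values percentages.
#' @export
domains_per_gene_distribution <- function(catalog, species) {
  rows <- .catalog_species(catalog, species)
  tab <- table(rows$n_pdz_domains)
  out <- 100 * as.numeric(tab) / nrow(rows)
  names(out) <- names(tab)
  out
}
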