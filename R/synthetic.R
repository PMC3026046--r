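## Seedable generators emulating every input the pipeline consumes, with
## planted structure for parameter-recovery benchmarks: lookup table,
## pocket set, proteome, interactome, PDZome catalog and assay plates.
##
## All generators are pure functions of the configuration: the same seed
## gives byte-identical output. Each generator perturbs the configured
## seed with its own offset so the individual inputs are mutually
## independent draws.

.SEED_OFFSETS <- c(table = 101L, pockets = 202L, proteome = 303L,
                   interactome = 404L, catalog = 505L, assay = 606L,
                   ligands = 707L)

.gen_seed <- function(config, what) {
  (config$seed + .SEED_OFFSETS[[what]]) %% .Machine$integer.max
}

# Default per-species catalog conditions. Human: 267 domains over 152
# genes (ratio 1.76); Monosiga brevicollis ratio 2.5; C. elegans 89/96
# genes essential (92.7%); E. coli 1/6 (16.7%). Genome sizes are
# protein-coding gene counts of the usual assemblies, order of magnitude.
.default_catalog_species <- function() {
  data.frame(
    species = c("Hs", "Mm", "Gg", "Xt", "Tn", "Tr", "Ci", "Dm",
                "Ce", "Hv", "Sp", "Mb", "At", "Ec", "Pa"),
    n_genes = c(152L, 155L, 110L, 112L, 120L, 118L, 60L, 70L,
                96L, 25L, 100L, 30L, 18L, 6L, 8L),
    n_domains = c(267L, 270L, 190L, 195L, 210L, 205L, 102L, 120L,
                  160L, 42L, 170L, 75L, 20L, 7L, 9L),
    n_known = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                96L, 0L, 0L, 0L, 0L, 6L, 0L),
    n_essential = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                    89L, 0L, 0L, 0L, 0L, 1L, 0L),
    genome_size = c(21000L, 22000L, 17000L, 18500L, 20000L, 18000L,
                    14000L, 14000L, 20000L, 20000L, 23000L, 9200L,
                    27000L, 4300L, 5600L),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic study conditions. The defaults
#' mirror the published analysis in shape: 254 pockets of which 107
#' (42%) are promiscuous, histidine at alphaB1 in 80% and valine at
#' alphaB5 in 70% of the promiscuous pockets, binder threshold 0.798,
#' and a 6.27% null false positive rate.
#'
#' @param seed Integer master seed; every generator derives its stream
#'   from it.
#' @param n_pockets Number of binding pockets.
#' @param promiscuous_fraction Fraction of pockets in the promiscuous
#'   group.
#' @param p_his,p_val Marginal probabilities of H at position 14 and V at
#'   position 16 in promiscuous pockets. The two draws are coupled so
#'   every promiscuous pocket carries at least one of the two
#'   determinants while the marginals stay at `p_his` / `p_val`.
#' @param n_proteins Number of proteome sequences.
#' @param class_mix Named fractions of class-1/2/3/unclassified
#'   C-termini; must sum to 1. Generated counts follow the mix exactly.
#' @param class1_bonus Planted weight bonus beta on the class-1 contacts:
#'   (14, -2) for H against S/T and (16, 0) for V against hydrophobic
#'   residues.
#' @param background_sd Standard deviation sigma of the background
#'   contact weights.
#' @param ligand_effect_sd Standard deviation of the per-(ligand
#'   position, residue) main effects shared by all pockets. These make
#'   ligand columns differ in overall stickiness, as additive
#'   domain-peptide models fitted to real data do; without them the
#'   non-promiscuous pockets would be mutually uncorrelated noise and no
#'   clustering could group them.
#' @param intercept Intercept used when `target_null_fpr` is `NA`.
#' @param threshold Binder threshold theta.
#' @param target_null_fpr Null exceedance probability the intercept is
#'   calibrated to (Monte-Carlo over `calibration_n` null pairs); `NA`
#'   keeps `intercept` as given.
#' @param calibration_n Monte-Carlo size of the intercept calibration.
#' @param protein_length Length range of generated protein sequences.
#' @param network List: `n_nodes`, `m` (preferential-attachment edges per
#'   node), `pdz_fraction` (nodes flagged as PDZ proteins),
#'   `compartment_probs` (categorical over codes 0..7).
#' @param catalog List: `species` (per-species condition table; see
#'   defaults), `scaling_noise_sd` (lognormal noise on planted power-law
#'   counts, 0 = exact).
#' @param assay List: `mu_binder`, `mu_background`, `sd`, `n_replicates`
#'   (absorbance units at 450 nm).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_pockets = 254L,
                         promiscuous_fraction = 107 / 254,
                         p_his = 0.80,
                         p_val = 0.70,
                         n_proteins = 2000L,
                         class_mix = c(class1 = 0.45, class2 = 0.05,
                                       class3 = 0.03, unclassified = 0.47),
                         class1_bonus = 1.0,
                         background_sd = 0.05,
                         ligand_effect_sd = 0.3,
                         intercept = 0,
                         threshold = 0.798,
                         target_null_fpr = 0.0627,
                         calibration_n = 100000L,
                         protein_length = c(50L, 400L),
                         network = list(),
                         catalog = list(),
                         assay = list()) {
  network <- utils::modifyList(
    list(n_nodes = 5000L, m = 2L, pdz_fraction = 0.1,
         compartment_probs = c(0.15, 0.12, 0.18, 0.15, 0.05,
                               0.15, 0.12, 0.08)),
    network)
  catalog <- utils::modifyList(
    list(species = .default_catalog_species(), scaling_noise_sd = 0),
    catalog)
  assay <- utils::modifyList(
    list(mu_binder = 1.2, mu_background = 0.1, sd = 0.05,
         n_replicates = 6L),
    assay)
  cfg <- list(seed = as.integer(seed), n_pockets = as.integer(n_pockets),
              promiscuous_fraction = promiscuous_fraction,
              p_his = p_his, p_val = p_val,
              n_proteins = as.integer(n_proteins), class_mix = class_mix,
              class1_bonus = class1_bonus, background_sd = background_sd,
              ligand_effect_sd = ligand_effect_sd, intercept = intercept,
              threshold = threshold, target_null_fpr = target_null_fpr,
              calibration_n = as.integer(calibration_n),
              protein_length = as.integer(protein_length),
              network = network, catalog = catalog, assay = assay)
  stopifnot(cfg$n_pockets >= 1, cfg$n_proteins >= 1,
            cfg$promiscuous_fraction >= 0, cfg$promiscuous_fraction <= 1,
            cfg$p_his >= 0, cfg$p_his <= 1, cfg$p_val >= 0, cfg$p_val <= 1,
            cfg$background_sd >= 0, cfg$ligand_effect_sd >= 0,
            all(cfg$class_mix >= 0))
  if (abs(sum(cfg$class_mix) - 1) > 1e-8) {
    stop("class_mix fractions must sum to 1", call. = FALSE)
  }
  if (length(cfg$network$compartment_probs) != 8) {
    stop("compartment_probs must have 8 entries (codes 0..7)", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

# sample pocket position codes with H@14 / V@16 excluded for the null
.sample_null_pocket_codes <- function(n) {
  vapply(1:18, function(i) {
    pool <- switch(as.character(i),
                   "14" = which(.AA20 != "H"),
                   "16" = which(.AA20 != "V"),
                   seq_along(.AA20))
    sample(pool, n, replace = TRUE)
  }, integer(n))
}

#' Generate a synthetic psi lookup table with planted class-1 structure
#'
#' Background weights are drawn Normal(0, sigma) on all 90 contact pairs.
#' On top sit (a) the planted class-1 bonuses: `+beta` on pair (14, -2)
#' for (H, S) and (H, T) and on pair (16, 0) for (V, x) with x
#' hydrophobic; and (b) per-(ligand position, residue) main effects
#' shared by all pockets, folded into the contact pairs of pocket
#' position 1 so the model remains a pure additive lookup table. The
#' intercept is calibrated by Monte-Carlo so a (non-H/V pocket, uniform
#' random ligand) pair exceeds the threshold with probability
#' `target_null_fpr`.
#'
#' @param config A [synth_config()].
#' @return A `pdz_lookup` with attribute `planted` (bonus pairs and
#'   calibration details).
#' @export
gen_lookup_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(.gen_seed(config, "table"), {
    pairs <- expand.grid(pocket_pos = 1:18, ligand_pos = 0:-4)
    W <- lapply(seq_len(nrow(pairs)), function(p) {
      m <- .empty_weight_matrix()
      m[1:20, 1:20] <- stats::rnorm(400, 0, config$background_sd)
      m
    })
    # ligand main effects, one block per ligand position
    for (j in 0:-4) {
      p1 <- which(pairs$pocket_pos == 1 & pairs$ligand_pos == j)
      eff <- stats::rnorm(20, 0, config$ligand_effect_sd)
      W[[p1]][1:20, 1:20] <- W[[p1]][1:20, 1:20] +
        matrix(eff, 20, 20, byrow = TRUE)
    }
    beta <- config$class1_bonus
    p14 <- which(pairs$pocket_pos == 14 & pairs$ligand_pos == -2)
    p16 <- which(pairs$pocket_pos == 16 & pairs$ligand_pos == 0)
    W[[p14]]["H", c("S", "T")] <- W[[p14]]["H", c("S", "T")] + beta
    W[[p16]]["V", phi_residues()] <- W[[p16]]["V", phi_residues()] + beta

    if (is.na(config$target_null_fpr)) {
      intercept <- config$intercept
      achieved <- NA_real_
    } else {
      n <- config$calibration_n
      pk0 <- .sample_null_pocket_codes(n)
      lg0 <- matrix(sample.int(20, n * 5, replace = TRUE), n, 5)
      psi0 <- rep(0, n)
      for (p in seq_len(nrow(pairs))) {
        psi0 <- psi0 + W[[p]][cbind(pk0[, pairs$pocket_pos[p]],
                                    lg0[, 5L + pairs$ligand_pos[p]])]
      }
      if (stats::sd(psi0) == 0) {
        stop("calibration unattainable: null scores are constant ",
             "(background_sd = 0); set target_null_fpr = NA and supply ",
             "an intercept", call. = FALSE)
      }
      intercept <- config$threshold -
        stats::quantile(psi0, 1 - config$target_null_fpr, names = FALSE)
      achieved <- mean(psi0 + intercept >= config$threshold)
    }
    if (intercept + 2 * beta < config$threshold) {
      stop("calibration unattainable: class1_bonus too small for planted ",
           "binders to reach the threshold", call. = FALSE)
    }
    attr(W, "pairs") <- pairs
    tab <- lookup_table(W, intercept = intercept,
                        threshold = config$threshold,
                        fpr = if (is.na(config$target_null_fpr)) NA_real_
                          else 100 * config$target_null_fpr,
                        provenance = sprintf("synthetic (seed %d)",
                                             config$seed))
    attr(tab, "planted") <- list(
      bonus = beta,
      bonus_pairs = list(c(14L, -2L), c(16L, 0L)),
      calibration_fpr = achieved)
    tab
  })
}

#' Generate synthetic binding pockets with planted promiscuity groups
#'
#' A fraction `promiscuous_fraction` of pockets form group `b`
#' (promiscuous): H at alphaB1 with marginal probability `p_his` and V at
#' alphaB5 with marginal `p_val`, coupled so each carries at least one of
#' the two. Group `a` (ligand-specific) pockets draw positions 14/16
#' from non-H / non-V residues. All other positions are uniform over the
#' 20 standard residues.
#'
#' @param config A [synth_config()].
#' @return Data frame with columns `domain_id`, `pocket`, `group`.
#' @export
gen_pockets <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(.gen_seed(config, "pockets"), {
    n <- config$n_pockets
    nb <- round(n * config$promiscuous_fraction)
    codes <- matrix(sample.int(20, n * 18, replace = TRUE), n, 18)
    if (nb > 0) {
      hasH <- stats::runif(nb) < config$p_his
      # coupled draw: marginal P(V) = p_val, and no pocket lacks both
      p_v_given_h <- if (config$p_his > 0)
        max(0, (config$p_val - (1 - config$p_his)) / config$p_his) else 0
      hasV <- ifelse(hasH, stats::runif(nb) < p_v_given_h, TRUE)
      iH <- which(.AA20 == "H")
      iV <- which(.AA20 == "V")
      codes[1:nb, 14] <- ifelse(hasH, iH,
                                sample(which(.AA20 != "H"), nb, replace = TRUE))
      codes[1:nb, 16] <- ifelse(hasV, iV,
                                sample(which(.AA20 != "V"), nb, replace = TRUE))
    }
    if (nb < n) {
      sp <- (nb + 1):n
      codes[sp, 14] <- sample(which(.AA20 != "H"), n - nb, replace = TRUE)
      codes[sp, 16] <- sample(which(.AA20 != "V"), n - nb, replace = TRUE)
    }
    data.frame(
      domain_id = sprintf("PDZ%03d", seq_len(n)),
      pocket = apply(codes, 1, function(i) paste(.AA20[i], collapse = "")),
      group = c(rep("b", nb), rep("a", n - nb)),
      stringsAsFactors = FALSE)
  })
}

# class counts that follow the mix exactly and sum to n
.exact_mix_counts <- function(mix, n) {
  counts <- diff(c(0, round(cumsum(mix) * n)))
  names(counts) <- names(mix)
  counts
}

#' Generate a synthetic proteome with a controlled C-terminal class mix
#'
#' Random-length sequences whose final 5-mers follow `class_mix` exactly
#' (counts are constructed, not sampled). Class membership agrees with
#' [classify_ligand()]: class-1 C-termini carry S/T at -2 and a
#' hydrophobic residue at 0, class 2 hydrophobic at both, class 3 D/E at
#' -2; unclassified C-termini carry a non-hydrophobic residue at 0 and
#' none of the class motifs at -2.
#'
#' @param config A [synth_config()].
#' @return List with `proteins` (a `Biostrings::AAStringSet`, headers
#'   carrying `gene:` tags) and `truth` (data frame `protein_id`,
#'   `cterm`, `class`).
#' @export
gen_proteome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(.gen_seed(config, "proteome"), {
    n <- config$n_proteins
    counts <- .exact_mix_counts(config$class_mix, n)
    classes <- rep(names(counts), counts)
    phi <- phi_residues()
    non_phi <- setdiff(.AA20, phi)
    neutral_m2 <- setdiff(.AA20, c("S", "T", "D", "E", phi))
    lens <- sample(config$protein_length[1]:config$protein_length[2],
                   n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(.AA20, L, replace = TRUE), collapse = "")
    }, character(1))
    tails <- matrix(sample(.AA20, n * 5, replace = TRUE), n, 5)
    i1 <- classes == "class1"
    i2 <- classes == "class2"
    i3 <- classes == "class3"
    i0 <- classes == "unclassified"
    tails[i1, 3] <- sample(c("S", "T"), sum(i1), replace = TRUE)
    tails[i1, 5] <- sample(phi, sum(i1), replace = TRUE)
    tails[i2, 3] <- sample(phi, sum(i2), replace = TRUE)
    tails[i2, 5] <- sample(phi, sum(i2), replace = TRUE)
    tails[i3, 3] <- sample(c("D", "E"), sum(i3), replace = TRUE)
    tails[i3, 5] <- sample(phi, sum(i3), replace = TRUE)
    tails[i0, 3] <- sample(neutral_m2, sum(i0), replace = TRUE)
    tails[i0, 5] <- sample(non_phi, sum(i0), replace = TRUE)
    cterm <- apply(tails, 1, paste, collapse = "")
    seqs <- paste0(substr(seqs, 1, lens - 5L), cterm)
    ids <- sprintf("P%05d", seq_len(n))
    proteins <- Biostrings::AAStringSet(seqs)
    names(proteins) <- sprintf("%s gene:G%05d", ids, seq_len(n))
    list(proteins = proteins,
         truth = data.frame(protein_id = ids, cterm = cterm,
                            class = classes, stringsAsFactors = FALSE))
  })
}

#' Generate uniform-random null ligand peptides
#'
#' The stated null model for false-positive-rate estimation: 5-mers
#' uniform over the 20 standard residues.
#'
#' @param config A [synth_config()].
#' @param n Number of null peptides.
#' @return Character vector of 5-mers.
#' @export
gen_null_ligands <- function(config, n) {
  withr::with_seed(.gen_seed(config, "ligands"), {
    m <- matrix(sample(.AA20, n * 5, replace = TRUE), n, 5)
    apply(m, 1, paste, collapse = "")
  })
}

#' Generate null (non-H/V) pockets
#'
#' Pockets drawn uniformly except that position 14 is never H and
#' position 16 never V — the null population the lookup-table intercept
#' is calibrated against.
#'
#' @inheritParams gen_null_ligands
#' @return Character vector of 18-mers.
#' @export
gen_null_pockets <- function(config, n) {
  withr::with_seed(.gen_seed(config, "pockets") + 1L, {
    codes <- .sample_null_pocket_codes(n)
    apply(codes, 1, function(i) paste(.AA20[i], collapse = ""))
  })
}

#' Generate a synthetic scale-free interactome
#'
#' Preferential-attachment graph with i.i.d. GO compartment codes and
#' promiscuity group labels assigned independently of degree and
#' compartment (the even-distribution null).
#'
#' @param config A [synth_config()].
#' @return An igraph graph with vertex attributes `name`, `compartment`,
#'   `is_pdz` and `group` (`a`/`b`/`none`).
#' @export
gen_interactome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  net <- config$network
  withr::with_seed(.gen_seed(config, "interactome"), {
    g <- igraph::sample_pa(net$n_nodes, m = net$m, directed = FALSE)
    igraph::V(g)$name <- sprintf("N%05d", seq_len(net$n_nodes))
    igraph::V(g)$compartment <- sample(0:7, net$n_nodes, replace = TRUE,
                                       prob = net$compartment_probs)
    is_pdz <- stats::runif(net$n_nodes) < net$pdz_fraction
    igraph::V(g)$is_pdz <- is_pdz
    grp <- rep("none", net$n_nodes)
    grp[is_pdz] <- ifelse(
      stats::runif(sum(is_pdz)) < config$promiscuous_fraction, "b", "a")
    igraph::V(g)$group <- grp
    g
  })
}

#' Generate a synthetic PDZome catalog
#'
#' Per-species gene records reproducing the configured species table:
#' exact gene/domain totals (extra domains beyond one per gene
#' distributed at random), exact essential/non-essential counts, and the
#' configured genome sizes. With `scaling_noise_sd > 0`, domain totals
#' are replaced by a planted power law `count = c * size^gamma` with
#' lognormal noise (fields `scaling_gamma`, `scaling_c` of
#' `config$catalog`; defaults 0.9 and exp(-4)).
#'
#' @param config A [synth_config()].
#' @return A `pdz_catalog`.
#' @export
gen_catalog <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  spp <- config$catalog$species
  withr::with_seed(.gen_seed(config, "catalog"), {
    rows <- lapply(seq_len(nrow(spp)), function(i) {
      s <- spp[i, ]
      n_domains <- s$n_domains
      if (config$catalog$scaling_noise_sd > 0) {
        gamma <- if (is.null(config$catalog$scaling_gamma)) 0.9
          else config$catalog$scaling_gamma
        cc <- if (is.null(config$catalog$scaling_c)) exp(-4)
          else config$catalog$scaling_c
        n_domains <- max(s$n_genes, round(
          cc * s$genome_size^gamma *
            exp(stats::rnorm(1, 0, config$catalog$scaling_noise_sd))))
      }
      extra <- n_domains - s$n_genes
      per_gene <- rep(1L, s$n_genes)
      if (extra > 0) {
        # concentrate extra domains on a few multi-PDZ genes
        add <- table(sample.int(s$n_genes, extra, replace = TRUE,
                                prob = stats::rexp(s$n_genes)^2))
        per_gene[as.integer(names(add))] <-
          per_gene[as.integer(names(add))] + as.integer(add)
      }
      essential <- rep(NA, s$n_genes)
      if (s$n_known > 0) {
        essential[seq_len(s$n_known)] <-
          c(rep(1, s$n_essential), rep(0, s$n_known - s$n_essential))
      }
      data.frame(gene_id = sprintf("%s_G%04d", s$species, seq_len(s$n_genes)),
                 species = s$species,
                 n_pdz_domains = per_gene,
                 essential = essential,
                 genome_size = s$genome_size,
                 stringsAsFactors = FALSE)
    })
    pdz_catalog(do.call(rbind, rows))
  })
}

#' Generate a replicate binding-assay plate
#'
#' Replicate absorbance readings (450 nm) for construct/peptide pairs.
#' Binder pairs draw from Normal(`mu_binder`, sd), non-binders from
#' Normal(`mu_background`, sd), n replicates each. The design comes from
#' a [mutation_scan()] result — wild-type binder status from
#' `psi_before`, mutant status from `psi_after`, so gain/loss patterns
#' mirror the scan — or from an explicit design data frame.
#'
#' @param config A [synth_config()].
#' @param scan Optional `mutation_scan()` result.
#' @param design Optional data frame with columns `construct`, `peptide`,
#'   `is_binder` (used when `scan` is `NULL`).
#' @param construct Base name for constructs derived from `scan`.
#' @return Data frame with columns `construct`, `peptide`, `replicate`,
#'   `absorbance`; attribute `design` carries the truth.
#' @export
gen_assay_plate <- function(config, scan = NULL, design = NULL,
                            construct = "PDZ") {
  stopifnot(inherits(config, "synth_config"))
  asy <- config$assay
  if (!is.null(scan)) {
    thr <- attr(scan, "threshold")
    design <- rbind(
      data.frame(construct = paste0(construct, "_WT"),
                 peptide = scan$ligand_id,
                 is_binder = scan$psi_before >= thr,
                 stringsAsFactors = FALSE),
      data.frame(construct = paste0(construct, "_", scan$set),
                 peptide = scan$ligand_id,
                 is_binder = scan$psi_after >= thr,
                 stringsAsFactors = FALSE))
    design <- unique(design)
  }
  if (is.null(design)) {
    stop("either a mutation scan or an explicit design is required",
         call. = FALSE)
  }
  withr::with_seed(.gen_seed(config, "assay"), {
    nrep <- asy$n_replicates
    out <- design[rep(seq_len(nrow(design)), each = nrep), , drop = FALSE]
    out$replicate <- rep(seq_len(nrep), nrow(design))
    mu <- ifelse(out$is_binder, asy$mu_binder, asy$mu_background)
    out$absorbance <- stats::rnorm(nrow(out), mu, asy$sd)
    out$is_binder <- NULL
    rownames(out) <- NULL
    attr(out, "design") <- design
    out
  })
}

#' Write the full synthetic input bundle to a directory
#'
#' Emits every pipeline input generated from one configuration:
#' `proteome.fasta`, `pockets.tsv` (with group labels), `ctermini.tsv`,
#' `lookup_table.tsv`, `edges.tsv`, `go.tsv`, `catalog.csv` and
#' `truth.json` (planted parameters; requires jsonlite).
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  tab <- gen_lookup_table(config)
  write_lookup_table(tab, path("lookup_table.tsv"))
  pockets <- gen_pockets(config)
  write_pockets(pockets, path("pockets.tsv"))
  prot <- gen_proteome(config)
  Biostrings::writeXStringSet(prot$proteins, path("proteome.fasta"))
  write_ctermini(prot$truth, path("ctermini.tsv"))
  g <- gen_interactome(config)
  el <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(
    data.frame(protein_a = el$from, protein_b = el$to, source = "synthetic"),
    path("edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(
    data.frame(protein_id = igraph::V(g)$name,
               compartment = igraph::V(g)$compartment),
    path("go.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_catalog(gen_catalog(config), path("catalog.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- list(seed = config$seed,
                  promiscuous_fraction = config$promiscuous_fraction,
                  p_his = config$p_his, p_val = config$p_val,
                  class_mix = as.list(config$class_mix),
                  class1_bonus = config$class1_bonus,
                  threshold = config$threshold,
                  target_null_fpr = config$target_null_fpr,
                  intercept = tab$intercept)
    jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  files <- c("lookup_table.tsv", "pockets.tsv", "proteome.fasta",
             "ctermini.tsv", "edges.tsv", "go.tsv", "catalog.csv")
  invisible(stats::setNames(file.path(dir, files), files))
}
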