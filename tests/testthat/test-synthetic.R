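# The synthetic-data generators: determinism, planted structure, exact
# mixes, and file round-trips.

fast_cfg <- function(seed = 1, ...) {
  synth_config(seed = seed, n_pockets = 40, n_proteins = 100,
               calibration_n = 20000, ...)
}

test_that("generators are pure functions of the configuration", {
  cfg <- fast_cfg(seed = 9)
  t1 <- gen_lookup_table(cfg)
  t2 <- gen_lookup_table(cfg)
  expect_identical(t1$W, t2$W)
  expect_identical(t1$intercept, t2$intercept)
  expect_identical(gen_pockets(cfg), gen_pockets(cfg))
  p1 <- gen_proteome(cfg)
  p2 <- gen_proteome(cfg)
  expect_identical(as.character(p1$proteins), as.character(p2$proteins))
  expect_identical(gen_catalog(cfg), gen_catalog(cfg))

  # different seeds give different weights but the same planted positions
  t3 <- gen_lookup_table(fast_cfg(seed = 10))
  expect_false(identical(t1$W, t3$W))
  expect_identical(attr(t1, "planted")$bonus_pairs,
                   attr(t3, "planted")$bonus_pairs)
})

test_that("noise-free tables separate planted binders exactly", {
  cfg <- synth_config(seed = 2, n_pockets = 10, n_proteins = 20,
                      background_sd = 0, ligand_effect_sd = 0,
                      target_null_fpr = NA, intercept = 0)
  tab <- gen_lookup_table(cfg)
  hv <- mutate_pocket(paste(rep("A", 18), collapse = ""),
                      c("14" = "H", "16" = "V"))
  class1 <- "AATAV"  # T at -2, V (hydrophobic) at 0
  other <- "AAKAR"
  non_hv <- paste(rep("A", 18), collapse = "")
  expect_gte(psi_score(hv, class1, tab), cfg$threshold)  # both bonuses: 2*beta
  expect_lt(psi_score(hv, other, tab), cfg$threshold)
  expect_lt(psi_score(non_hv, class1, tab), cfg$threshold)
})

test_that("calibration refuses impossible configurations", {
  expect_error(gen_lookup_table(synth_config(seed = 1, background_sd = 0,
                                             ligand_effect_sd = 0,
                                             calibration_n = 1000)),
               "calibration unattainable")
  expect_error(gen_lookup_table(fast_cfg(seed = 1, class1_bonus = 0.01)),
               "class1_bonus too small")
})

test_that("gen_pockets plants the configured H/V structure", {
  all_hv <- gen_pockets(synth_config(seed = 3, n_pockets = 30,
                                     promiscuous_fraction = 1,
                                     p_his = 1, p_val = 1))
  expect_true(all(substr(all_hv$pocket, 14, 14) == "H"))
  expect_true(all(substr(all_hv$pocket, 16, 16) == "V"))

  pk <- gen_pockets(synth_config(seed = 7, n_pockets = 1000))
  b <- pk[pk$group == "b", ]
  a <- pk[pk$group == "a", ]
  expect_lt(abs(mean(substr(b$pocket, 14, 14) == "H") - 0.80), 0.04)
  expect_lt(abs(mean(substr(b$pocket, 16, 16) == "V") - 0.70), 0.04)
  # every promiscuous pocket carries at least one determinant
  expect_true(all(substr(b$pocket, 14, 14) == "H" |
                    substr(b$pocket, 16, 16) == "V"))
  # specific pockets never do
  expect_true(all(substr(a$pocket, 14, 14) != "H"))
  expect_true(all(substr(a$pocket, 16, 16) != "V"))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_pockets(pk, path)
  expect_equal(read_pockets(path), pk)
})

test_that("gen_proteome follows the class mix exactly", {
  cfg <- fast_cfg(seed = 4)
  prot <- gen_proteome(cfg)
  got_mix <- table(prot$truth$class) / nrow(prot$truth)
  want <- cfg$class_mix[order(names(cfg$class_mix))]
  expect_equal(as.numeric(got_mix[order(names(got_mix))]),
               as.numeric(round(want * cfg$n_proteins) / cfg$n_proteins),
               tolerance = 1e-9)
  # stored class agrees with the classifier
  expect_equal(unname(classify_ligand(prot$truth$cterm)), prot$truth$class)
  # C-terminus extraction of the FASTA reproduces the stored 5-mers
  expect_equal(unname(extract_cterminus(prot$proteins)), prot$truth$cterm)

  pure <- gen_proteome(fast_cfg(seed = 5, class_mix = c(
    class1 = 1, class2 = 0, class3 = 0, unclassified = 0)))
  expect_true(all(classify_ligand(extract_cterminus(pure$proteins)) == "class1"))
})

test_that("gen_interactome builds the configured scale-free graph", {
  tree <- gen_interactome(synth_config(seed = 6,
                                       network = list(n_nodes = 200, m = 1)))
  expect_equal(igraph::gsize(tree), 199)
  g <- gen_interactome(synth_config(seed = 6,
                                    network = list(n_nodes = 500, m = 2)))
  expect_true(all(igraph::V(g)$compartment %in% 0:7))
  expect_true(all(igraph::V(g)$group %in% c("a", "b", "none")))
  expect_true(all(igraph::V(g)$group[!igraph::V(g)$is_pdz] == "none"))
})

test_that("gen_catalog reproduces the planted species conditions", {
  cfg <- synth_config(seed = 8)
  catalog <- gen_catalog(cfg)
  expect_equal(round(essential_fraction(catalog, "Ce"), 1), 92.7)
  expect_equal(round(essential_fraction(catalog, "Ec"), 1), 16.7)
  expect_equal(pdz_per_gene_ratio(catalog, "Mb"), 2.5)
  expect_equal(pdz_per_gene_ratio(catalog, "Hs"), 267 / 152)
  spp <- cfg$catalog$species
  totals <- tapply(catalog$n_pdz_domains, catalog$species, sum)
  expect_equal(as.numeric(totals[spp$species]), spp$n_domains)
  ratio_mean <- mean_pdz_per_gene_ratio(catalog)
  expect_lt(abs(ratio_mean - 1.7), 0.2)
})

test_that("planted power-law catalogs are recovered by the scaling fit", {
  gamma <- 0.9
  cfg <- synth_config(seed = 12, catalog = list(scaling_noise_sd = 0.1,
                                                scaling_gamma = gamma))
  fit <- fit_size_scaling(gen_catalog(cfg))
  expect_lt(abs(fit$exponent - gamma), 0.25)
})

test_that("gen_assay_plate reflects a mutation scan's gain/loss pattern", {
  cfg <- fast_cfg(seed = 13)
  tab <- gen_lookup_table(cfg)
  pk <- gen_pockets(cfg)
  specific <- pk$pocket[pk$group == "a"][1]
  prot <- gen_proteome(cfg)
  panel <- stats::setNames(prot$truth$cterm[prot$truth$class == "class1"][1:5],
                           paste0("pep", 1:5))
  scan <- mutation_scan(specific, list(HV = c("14" = "H", "16" = "V")),
                        panel, tab)
  plate <- gen_assay_plate(cfg, scan = scan)
  s <- summarize_assay(plate)
  expect_true(all(s$n == 6))
  design <- attr(plate, "design")
  key <- paste(s$construct, s$peptide)
  dkey <- paste(design$construct, design$peptide)
  mu <- ifelse(design$is_binder[match(key, dkey)],
               cfg$assay$mu_binder, cfg$assay$mu_background)
  expect_true(all(abs(s$mean - mu) < 3 * cfg$assay$sd / sqrt(6) + 0.05))

  flat_cfg <- fast_cfg(seed = 13, assay = list(sd = 0))
  flat <- gen_assay_plate(flat_cfg, scan = scan)
  expect_true(all(summarize_assay(flat)$sd == 0))
})

test_that("simulate_bundle writes a readable, consistent input bundle", {
  dir <- withr::local_tempdir()
  cfg <- fast_cfg(seed = 14)
  files <- simulate_bundle(cfg, dir)
  expect_true(all(file.exists(files)))
  tab <- read_lookup_table(files[["lookup_table.tsv"]])
  pk <- read_pockets(files[["pockets.tsv"]])
  ct <- read_ctermini(files[["ctermini.tsv"]])
  fasta <- Biostrings::readAAStringSet(files[["proteome.fasta"]])
  expect_equal(unname(extract_cterminus(fasta)), ct$cterm)
  # scores computed from the round-tripped files match the in-memory run
  S_file <- score_matrix(pk, ct, tab)
  S_mem <- score_matrix(gen_pockets(cfg), gen_proteome(cfg)$truth,
                        gen_lookup_table(cfg))
  expect_equal(S_file, S_mem, tolerance = 1e-12)
  catalog <- read_catalog(files[["catalog.csv"]])
  expect_equal(round(essential_fraction(catalog, "Ce"), 1), 92.7)
})
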