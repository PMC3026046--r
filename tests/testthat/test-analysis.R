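# Downstream analyses: cross-reactivity, clustering, PWMs, enrichment,
# mutation scans, assay summaries, group comparisons.

test_that("overlap_stats counts sharing domains and shared ligands", {
  calls <- make_calls(list(A = c("x", "y"), B = c("y", "z"), C = "w"))
  os <- overlap_stats(calls)
  expect_equal(os$n_sharing_domains, 2L)   # A and B share y
  expect_equal(os$n_shared_ligands, 1L)    # y
  expect_equal(os$mean_ligands, 2.0)       # over the sharing domains A, B
  expect_equal(os$sem_ligands, 0)

  disjoint <- make_calls(list(A = c("x", "y"), B = c("z"), C = "w"))
  expect_equal(overlap_stats(disjoint)$n_sharing_domains, 0L)

  empty <- make_calls(list(A = character(0)))
  os0 <- overlap_stats(data.frame(domain_id = character(0),
                                  ligand_id = character(0)))
  expect_equal(os0$n_sharing_domains, 0L)
  expect_equal(os0$n_shared_ligands, 0L)
})

test_that("overlap_stats is invariant to call order", {
  set.seed(31)
  calls <- make_calls(list(A = c("x", "y", "q"), B = c("y", "z"),
                           C = c("w", "x"), D = "v"))
  os1 <- overlap_stats(calls)
  os2 <- overlap_stats(calls[sample(nrow(calls)), ])
  expect_equal(os1[c("n_sharing_domains", "n_shared_ligands",
                     "mean_ligands", "sem_ligands")],
               os2[c("n_sharing_domains", "n_shared_ligands",
                     "mean_ligands", "sem_ligands")])
})

test_that("ligand_counts_per_domain counts calls with optional zero domains", {
  calls <- make_calls(list(A = c("x", "y", "z"), B = "x"))
  lc <- ligand_counts_per_domain(calls, domain_ids = c("A", "B", "C"))
  expect_equal(lc$counts, c(A = 3L, B = 1L, C = 0L))
  expect_equal(lc$mean, 4 / 3)
  expect_equal(lc$sem, sd(c(3, 1, 0)) / sqrt(3))
})

test_that("cluster_scores recovers a planted two-block structure", {
  set.seed(32)
  n_hi <- 12
  n_lo <- 18
  m <- 200
  class1_cols <- 1:80
  S <- matrix(rnorm(30 * m, 0, 0.1), 30, m)
  S <- S + 0.5  # shared baseline
  S[1:n_hi, class1_cols] <- S[1:n_hi, class1_cols] + 3
  rownames(S) <- paste0("D", 1:30)
  cl <- cluster_scores(S, k = 2)
  planted <- rep(c(2, 1), c(n_hi, n_lo))
  expect_equal(mclust::adjustedRandIndex(cl$labels, planted), 1.0)
  expect_equal(sort(cl$sizes), c(n_hi, n_lo))
  # group 2 is the promiscuous (higher mean ligand count) group
  expect_gt(cl$group_mean_ligands[2], cl$group_mean_ligands[1])
})

test_that("cluster_scores handles degenerate identical rows", {
  S <- matrix(1, 10, 20)
  cl <- cluster_scores(S, k = 2)
  expect_equal(sort(cl$sizes), c(1L, 9L))
  expect_error(cluster_scores(S, k = 11), "exceeds")
})

test_that("cluster assignments are invariant to row order", {
  set.seed(33)
  S <- matrix(rnorm(20 * 50), 20, 50) + 0.4
  S[1:8, 1:25] <- S[1:8, 1:25] + 2
  rownames(S) <- paste0("D", 1:20)
  perm <- sample(20)
  cl1 <- cluster_scores(S, k = 2)
  cl2 <- cluster_scores(S[perm, ], k = 2)
  expect_equal(mclust::adjustedRandIndex(cl1$labels[rownames(S)[perm]],
                                         cl2$labels), 1.0)
})

test_that("build_pwm computes per-position residue frequencies", {
  one <- build_pwm("LETSV")
  expect_equal(dim(one), c(20, 5))
  expect_equal(colnames(one), as.character(-4:0))
  expect_equal(unname(one["L", "-4"]), 1)
  expect_equal(unname(one["V", "0"]), 1)
  expect_equal(unname(colSums(one)), rep(1, 5))

  two <- build_pwm(c("AAAAA", "CCCCC"))
  expect_equal(unname(two["A", ]), rep(0.5, 5))
  expect_equal(unname(two["C", ]), rep(0.5, 5))

  expect_error(build_pwm(character(0)), "zero ligands")
})

test_that("build_pwm equals a direct counting oracle on random ligands", {
  set.seed(34)
  lig <- random_ligand(50)
  pwm <- build_pwm(lig)
  for (j in 1:5) {
    counts <- table(factor(substr(lig, j, j), levels = AA20))
    expect_equal(unname(pwm[, j]), as.numeric(counts) / 50)
  }
  expect_equal(unname(colSums(pwm)), rep(1, 5), tolerance = 1e-9)
})

test_that("compare_pwms is a mean per-position correlation", {
  set.seed(35)
  a <- build_pwm(random_ligand(30))
  b <- build_pwm(random_ligand(30))
  expect_equal(compare_pwms(a, a), 1.0)
  expect_equal(compare_pwms(a, b), compare_pwms(b, a))
  want <- mean(vapply(1:5, function(j) cor(a[, j], b[, j]), numeric(1)))
  expect_equal(compare_pwms(a, b), want)
  # uniform PWM has zero variance: defined as similarity 0
  u <- matrix(1 / 20, 20, 5, dimnames = dimnames(a))
  expect_equal(compare_pwms(a, u), 0)
  expect_error(compare_pwms(a, a[, 1:4]), "identical dimensions")
})

test_that("pocket_enrichment reports per-group residue fractions", {
  all_h <- vapply(1:6, function(i)
    mutate_pocket(random_pocket(), c("14" = "H")), character(1))
  enr <- pocket_enrichment(all_h, rep("b", 6))
  expect_equal(unname(enr$fractions$b["H", "14"]), 1.0)
  expect_equal(unname(colSums(enr$fractions$b)), rep(1, 18))
  expect_error(pocket_enrichment(all_h, c(rep("b", 6), "a")[1:6][c(1:6)],
                                 margin = 0.2), NA)
  expect_error(pocket_enrichment(character(0), character(0)),
               "at least one pocket")
})

test_that("pocket_enrichment equals direct counting and flags divergent positions", {
  set.seed(36)
  pk <- random_pocket(40)
  grp <- rep(c("a", "b"), 20)
  enr <- pocket_enrichment(pk, grp)
  chars_a <- do.call(rbind, strsplit(pk[grp == "a"], ""))
  for (i in c(1, 14, 18)) {
    counts <- table(factor(chars_a[, i], levels = AA20))
    expect_equal(unname(enr$fractions$a[, as.character(i)]),
                 as.numeric(counts) / 20)
  }
  # planted divergence at position 14 gets flagged
  pk2 <- c(vapply(1:20, function(i) mutate_pocket(random_pocket(),
                                                  c("14" = "H")), character(1)),
           vapply(1:20, function(i) mutate_pocket(random_pocket(),
                                                  c("14" = "G")), character(1)))
  enr2 <- pocket_enrichment(pk2, rep(c("b", "a"), each = 20), margin = 0.5)
  expect_true(14 %in% enr2$flagged_positions)
})

test_that("mutation_scan reports deltas and call changes at theta", {
  set.seed(37)
  tab <- lookup_table(random_weights_df(8, 60), intercept = 0,
                      threshold = 0.5)
  pk <- random_pocket()
  lig <- stats::setNames(random_ligand(10), paste0("L", 1:10))

  none <- mutation_scan(pk, character(0), lig, tab)
  expect_equal(none$delta, rep(0, 10))
  expect_true(all(none$call_change == "none"))

  fwd <- mutation_scan(pk, list(HV = c("14" = "H", "16" = "V")), lig, tab)
  expect_equal(fwd$delta, fwd$psi_after - fwd$psi_before)
  gains <- fwd$call_change == "gain"
  expect_equal(gains, fwd$psi_before < 0.5 & fwd$psi_after >= 0.5)

  # reversing the substitution negates every delta (additivity)
  mut <- mutate_pocket(pk, c("14" = "H", "16" = "V"))
  back <- c("14" = substr(pk, 14, 14), "16" = substr(pk, 16, 16))
  rev <- mutation_scan(mut, back, lig, tab)
  expect_equal(rev$delta, -fwd$delta, tolerance = 1e-12)
})

test_that("summarize_assay gives replicate mean, sd and n", {
  plate <- data.frame(construct = "C1", peptide = "P1",
                      replicate = 1:6, absorbance = c(1, 2, 3, 4, 5, 6))
  s <- summarize_assay(plate)
  expect_equal(s$mean, 3.5)
  expect_equal(s$sd, sd(1:6))        # 1.8708...
  expect_equal(s$sd, 1.8708287, tolerance = 1e-6)
  expect_equal(s$n, 6L)

  flat <- data.frame(construct = "C1", peptide = "P1",
                     replicate = 1:6, absorbance = rep(0.8, 6))
  expect_equal(summarize_assay(flat)$sd, 0)

  short <- data.frame(construct = "C1", peptide = "P1",
                      replicate = 1, absorbance = 0.5)
  expect_error(summarize_assay(short), ">= 2 replicates")
})

test_that("compare_groups is the two-sided Student t-test", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  r <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  # textbook pooled-variance closed form
  sp2 <- (2 * var(c(1, 2, 3)) + 2 * var(c(2, 3, 4))) / 4
  t_want <- (2 - 3) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$t, t_want, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(t_want, df = 4), tolerance = 1e-12)
  expect_equal(r$df, 4)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  expect_error(compare_groups(c(1, 1), c(1, 1)), "zero pooled variance")
  w <- compare_groups(c(1, 2, 3), c(2, 3, 4, 10, 20), welch = TRUE)
  expect_lt(w$df, 6)  # Welch degrees of freedom are fractional
})
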