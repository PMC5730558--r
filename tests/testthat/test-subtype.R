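test_that("signed KS statistics match a hand ECDF computation", {
  # 8 genes; signature genes sit at the four lowest ranks {1,2,3,4}
  expr <- matrix(c(1:8), 8, 1,
                 dimnames = list(sprintf("g%d", 1:8), "s1"))
  expr <- cbind(expr, ctrl = expr[, 1])
  colnames(expr) <- c("s1", "n1")
  study <- expression_study(expr, c(s1 = "tumor", n1 = "control"))
  sig <- signature_set(list(LOW = c("g1", "g2", "g3", "g4"),
                            HIGH = c("g5", "g6", "g7", "g8")))
  ass <- assign_subtypes(study, sig)
  # normalized ranks {1/9, 2/9, 3/9, 4/9}: hand ECDF gives
  # downward D = 1 - 4/9 = 5/9 and upward D = 1/9
  expect_equal(unname(ass$D["s1", "LOW"]), 5 / 9, tolerance = 1e-12)
  expect_equal(unname(ass$D_up["s1", "LOW"]), 1 / 9, tolerance = 1e-12)
  # the top-ranked signature mirrors it
  expect_equal(unname(ass$D_up["s1", "HIGH"]), 5 / 9, tolerance = 1e-12)
  expect_identical(ass$assignments$subtype, "HIGH")
  expect_false(ass$assignments$low_confidence)
})

test_that("a sample whose signature genes occupy the top ranks is assigned to it", {
  set.seed(61)
  genes <- sprintf("g%03d", 1:100)
  expr <- matrix(rnorm(200, 8, 1), 100, 2,
                 dimnames = list(genes, c("t1", "n1")))
  sigA <- genes[1:10]
  expr[sigA, "t1"] <- max(expr[, "t1"]) + seq_len(10)  # top 10 ranks
  study <- expression_study(expr, c(t1 = "tumor", n1 = "control"))
  sig <- signature_set(list(A = sigA, B = genes[11:20], C = genes[21:30]))
  ass <- assign_subtypes(study, sig)
  expect_identical(ass$assignments$subtype, "A")
  expect_true(ass$D_up["t1", "A"] > max(ass$D_up["t1", c("B", "C")]))
})

test_that("subtype assignment recovers planted cohort labels", {
  sim <- generate_human_cohort(cohort_sim_config(samples_per_subtype = 10L,
                                                 n_normals = 5L, seed = 62L))
  ass <- assign_subtypes(sim$human, sim$signature)
  acc <- mean(ass$assignments$subtype ==
                sim$truth$subtype_of[ass$assignments$sample])
  expect_gte(acc, 0.95)
})

test_that("ortholog mapping is one-to-one with full accounting", {
  map <- ortholog_map(data.frame(
    rat = c("r1", "r2", "r3", "r3", "r4", "r5"),
    human = c("H1", "H2", "H3a", "H3b", "H4", "H4")))
  out <- map_orthologs(c("r1", "r2", "r3", "r4", "r5", "r9"), map)
  # r3 maps to two humans; r4/r5 share a human: all dropped
  expect_identical(out$pairs$rat, c("r1", "r2"))
  expect_identical(out$n_dropped_multi, 4L)
  expect_identical(out$n_unmapped, 1L)

  ident <- ortholog_map(data.frame(rat = c("a", "b"), human = c("A", "B")))
  expect_identical(nrow(map_orthologs(c("a", "b"), ident)$pairs), 2L)
  expect_error(map_orthologs(c("zz"), ident),
               class = "gliomaTME_validation_error")
})

test_that("fold-change vectors are log2 differences against the normal mean", {
  expr <- matrix(c(6, 6, 8, 7), 1, 4,
                 dimnames = list("g1", c("n1", "n2", "t1", "t2")))
  study <- expression_study(expr, c(n1 = "control", n2 = "control",
                                    t1 = "tumor", t2 = "tumor"))
  per <- fold_change_vector(study, per_sample = TRUE)
  expect_equal(unname(per["g1", ]), c(2, 1))
  grp <- fold_change_vector(study, per_sample = FALSE)
  expect_equal(unname(grp["g1"]), 1.5)
  # per-sample vectors average to the group-mean vector
  expect_equal(rowMeans(per), grp, tolerance = 1e-12)
  # a tumor equal to the normal mean gives the zero vector
  expr0 <- matrix(c(3, 5, 4), 1, 3,
                  dimnames = list("g1", c("n1", "n2", "t1")))
  s0 <- expression_study(expr0, c(n1 = "control", n2 = "control",
                                  t1 = "tumor"))
  expect_identical(unname(fold_change_vector(s0)["g1", "t1"]), 0)
})

test_that("Spearman correlations agree with rank-then-Pearson, ties included", {
  set.seed(63)
  for (i in 1:12) {
    x <- sample(1:6, 15, replace = TRUE)   # ties guaranteed
    y <- x + rnorm(15)
    expect_equal(cor(x, y, method = "spearman"), spearman_by_hand(x, y),
                 tolerance = 1e-12)
  }
})

test_that("similarity ranking finds the matching subtype and is order-invariant", {
  sim <- generate_human_cohort(cohort_sim_config(samples_per_subtype = 8L,
                                                 n_normals = 4L, seed = 64L))
  ass <- assign_subtypes(sim$human, sim$signature)
  mapped <- map_orthologs(rownames(sim$rat$expr), sim$orthologs)
  rat_fcs <- fold_change_vector(sim$rat)
  human_fcs <- fold_change_vector(sim$human)
  res <- similarity_ranking(rat_fcs, human_fcs, ass, mapped)
  expect_identical(res$winner, sim$truth$target)
  expect_identical(res$ranking[1],
                   res$summary$subtype[which.max(res$summary$mean_rho)])
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  expect_true(res$small_sample_warning)

  # permuting gene order in the inputs leaves the winner unchanged
  perm <- sample(nrow(rat_fcs))
  res2 <- similarity_ranking(rat_fcs[perm, , drop = FALSE],
                             human_fcs[sample(nrow(human_fcs)), , drop = FALSE],
                             ass, mapped)
  expect_identical(res2$winner, res$winner)
  expect_equal(res2$summary$mean_rho, res$summary$mean_rho,
               tolerance = 1e-12)

  # a rat vector equal to a subtype reference correlates perfectly
  ref_genes <- mapped$pairs
  mes_samples <- ass$assignments$sample[ass$assignments$subtype ==
                                          "Mesenchymal"]
  ref <- rowMeans(human_fcs[ref_genes$human, mes_samples, drop = FALSE])
  fake_rat <- matrix(ref, ncol = 1,
                     dimnames = list(ref_genes$rat, "fake"))
  res3 <- similarity_ranking(fake_rat, human_fcs, ass, mapped)
  expect_equal(unname(res3$rho["Mesenchymal", 1]), 1, tolerance = 1e-12)
  # ... and so does any strictly increasing transform of it
  res4 <- similarity_ranking(exp(fake_rat / 2), human_fcs, ass, mapped)
  expect_equal(unname(res4$rho["Mesenchymal", 1]), 1, tolerance = 1e-12)
})

test_that("per-human-sample correlation mode agrees on the winner", {
  sim <- generate_human_cohort(cohort_sim_config(samples_per_subtype = 6L,
                                                 n_normals = 4L, seed = 66L))
  ass <- assign_subtypes(sim$human, sim$signature)
  mapped <- map_orthologs(rownames(sim$rat$expr), sim$orthologs)
  rat_fcs <- fold_change_vector(sim$rat)
  human_fcs <- fold_change_vector(sim$human)
  res_h <- similarity_ranking(rat_fcs, human_fcs, ass, mapped,
                              replicate_mode = "human")
  expect_identical(res_h$winner, sim$truth$target)
  # n per subtype equals the number of samples assigned to it
  counts <- table(ass$assignments$subtype)
  expect_identical(res_h$summary$n,
                   as.integer(counts[res_h$summary$subtype]))
})

test_that("subtypes without assigned samples are excluded but flagged", {
  set.seed(65)
  genes <- sprintf("g%03d", 1:60)
  expr <- matrix(rnorm(60 * 5, 8, 1), 60, 5,
                 dimnames = list(genes, c("t1", "t2", "t3", "n1", "n2")))
  sigA <- genes[1:6]
  expr[sigA, 1:3] <- expr[sigA, 1:3] + 6
  study <- expression_study(
    expr, c(t1 = "tumor", t2 = "tumor", t3 = "tumor",
            n1 = "control", n2 = "control"))
  sig <- signature_set(list(A = sigA, B = genes[7:12]))
  ass <- assign_subtypes(study, sig)
  mapped <- list(pairs = data.frame(rat = genes, human = genes))
  rat <- matrix(rnorm(60), 60, 1, dimnames = list(genes, "r1"))
  res <- similarity_ranking(rat, fold_change_vector(study), ass, mapped)
  expect_identical(res$excluded_subtypes, "B")
  expect_identical(res$winner, "A")
})
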