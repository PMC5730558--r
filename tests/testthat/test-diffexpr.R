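test_that("probe aggregation keeps uniquely-mapping probes and averages them", {
  m <- matrix(c(2, 4, 1, 7, 9, 3), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  groups <- c(s1 = "control", s2 = "tumor")

  # one probe per gene: identity
  ann1 <- list(p1 = "A", p2 = "B", p3 = "C")
  out1 <- aggregate_probes(m, ann1, groups)
  expect_equal(unname(out1$study$expr[c("A", "B", "C"), "s1"]),
               c(2, 4, 1))

  # two probes on one gene are averaged; multi-mapping probe dropped
  ann2 <- list(p1 = "G", p2 = "G", p3 = c("G", "H"))
  out2 <- aggregate_probes(m, ann2, groups)
  expect_equal(unname(out2$study$expr["G", ]), c((2 + 4) / 2, (7 + 9) / 2))
  expect_identical(out2$report$n_multi, 1L)
  expect_identical(out2$report$n_unique, 2L)

  # unmapped probes are counted; nothing uniquely mapped is an error
  ann3 <- list(p1 = character(), p2 = c("X", "Y"), p3 = character())
  expect_error(aggregate_probes(m, ann3, groups),
               class = "gliomaTME_validation_error")
})

test_that("Welch statistics match the textbook formula and t.test", {
  set.seed(41)
  for (i in 1:15) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), 1)
    study <- make_study(matrix(a, 1), matrix(b, 1))
    r <- welch_de(study, alpha = 0.05)$table
    hand <- welch_by_hand(a, b)
    ref <- t.test(b, a)
    expect_equal(r$t, hand$t, tolerance = 1e-10)
    expect_equal(r$df, hand$df, tolerance = 1e-10)
    expect_equal(r$p, hand$p, tolerance = 1e-10)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$df, unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("degenerate genes follow the documented conventions", {
  # tumor identical to control: t = 0, no discoveries
  study <- make_study(matrix(c(1, 2, 3), 1), matrix(c(1, 2, 3), 1))
  r <- welch_de(study, alpha = 0.05)
  expect_identical(r$table$t, 0)
  expect_identical(r$k, 0L)
  expect_true(is.na(r$fdr_hat))

  # zero variance in both groups, equal means: t = 0, p = 1
  flat <- make_study(matrix(5, 1, 4), matrix(5, 1, 3))
  rf <- welch_de(flat, alpha = 0.05)$table
  expect_identical(rf$t, 0)
  expect_identical(rf$p, 1)

  # near-degenerate separation: tiny jitter, huge t
  set.seed(42)
  sep <- make_study(matrix(rnorm(4, 0, 1e-6), 1),
                    matrix(rnorm(3, 2, 1e-6), 1))
  rs <- welch_de(sep, alpha = 0.05)$table
  expect_lt(rs$p, 1e-6)
  expect_identical(rs$direction, "up")
})

test_that("discovery bookkeeping and the plug-in FDR identity hold", {
  set.seed(43)
  de <- data.frame(gene = sprintf("g%05d", 1:60),
                   effect = rep(c(-3, 3), 30))
  sim <- generate_expression_study(
    expr_sim_config(800L, de_genes = de, seed = 44L))
  r <- welch_de(sim$study, alpha = 0.01)
  expect_identical(r$up + r$down, r$k)
  expect_equal(r$fdr_hat * r$k, r$m * r$alpha, tolerance = 1e-12)

  # the printed FDR bounds are consistent with the plug-in formula
  expect_equal(estimate_fdr(6800, 1620, 0.01), 0.0419753086, tolerance = 1e-8)
  expect_lt(estimate_fdr(6800, 1620, 0.01), 0.042)
  # the largest m consistent with the printed microglia bound is 10527
  expect_equal(estimate_fdr(10527, 1698, 0.01), 105.27 / 1698,
               tolerance = 1e-12)
  expect_lt(estimate_fdr(10527, 1698, 0.01), 0.062)
  # boundary: k = m * alpha gives exactly 1
  expect_identical(estimate_fdr(1000, 10, 0.01), 1)
  expect_warning(out <- estimate_fdr(10, 0, 0.01), "undefined")
  expect_true(is.na(out))
  expect_error(estimate_fdr(5, 6, 0.01),
               class = "gliomaTME_validation_error")
})

test_that("an |fc| window composes with the alpha criterion", {
  de <- data.frame(gene = c("g00001", "g00002"), effect = c(0.8, 4))
  sim <- generate_expression_study(
    expr_sim_config(200L, de_genes = de, noise_sd = 0.1, seed = 45L))
  loose <- welch_de(sim$study, alpha = 0.01)
  strict <- welch_de(sim$study, alpha = 0.01, min_abs_fc = 2)
  expect_true(loose$table$significant[loose$table$gene == "g00001"])
  expect_false(strict$table$significant[strict$table$gene == "g00001"])
  expect_true(strict$table$significant[strict$table$gene == "g00002"])
  expect_lte(strict$k, loose$k)
})

test_that("control-centring zeroes control means, is idempotent, keeps contrasts", {
  study <- make_study(matrix(c(1, 3), 1), matrix(5, 1))
  c1 <- center_on_control(study)
  expect_equal(unname(c1[1, ]), c(-1, 1, 3))

  set.seed(46)
  study2 <- make_study(matrix(rnorm(40), 10), matrix(rnorm(30), 10))
  c2 <- center_on_control(study2)
  expect_true(all(abs(rowMeans(c2[, 1:4])) < 1e-12))
  study2c <- expression_study(c2, study2$groups)
  expect_equal(center_on_control(study2c), c2, tolerance = 1e-12)
  d_orig <- rowMeans(study2$expr[, 5:7]) - rowMeans(study2$expr[, 1:4])
  d_cent <- rowMeans(c2[, 5:7]) - rowMeans(c2[, 1:4])
  expect_equal(d_cent, d_orig, tolerance = 1e-12)
})

test_that("top_regulated ranks by |fc| with deterministic tie-breaks", {
  tab <- data.frame(
    gene = c("b", "a", "c", "d"),
    log2fc = c(3, -4, 1, 4), t = 1, df = 1,
    p = c(0.001, 0.002, 0.003, 0.002), q = 0.01,
    significant = c(TRUE, TRUE, TRUE, FALSE),
    direction = c("up", "down", "up", "up"))
  res <- structure(list(table = tab, alpha = 0.01, m = 4L, k = 3L,
                        up = 2L, down = 1L, fdr_hat = 0.013),
                   class = "de_result")
  top2 <- top_regulated(res, 2)
  expect_identical(top2$gene, c("a", "b"))     # |-4| then |+3|
  expect_identical(nrow(top_regulated(res, 50)), 3L)

  # exact ties: smaller p, then lexicographic gene id
  tab2 <- tab
  tab2$log2fc <- c(2, -2, 2, 1); tab2$p <- c(0.002, 0.002, 0.002, 0.002)
  res2 <- res; res2$table <- tab2
  expect_identical(top_regulated(res2, 3)$gene, c("a", "b", "c"))
})

test_that("marker-panel reports use the signed linear fold-change convention", {
  study <- make_study(matrix(rep(1, 4), 1), matrix(rep(2, 3), 1) +
                        matrix(rnorm(3, 0, 1e-9), 1), genes = "Arg1")
  r <- welch_de(study, alpha = 0.05)
  rep1 <- marker_panel_report(r, marker_panel("mini", c("Arg1", "Nos2")))
  expect_equal(rep1$fold_change[1], 2, tolerance = 1e-6)   # log2fc 1 -> 2.0
  expect_true(rep1$missing[2])
  expect_true(is.na(rep1$p[2]))

  # planted upregulated panel: all present genes up and significant
  set.seed(47)
  panel_genes <- sprintf("g%05d", 1:8)
  de <- data.frame(gene = panel_genes, effect = 3)
  sim <- generate_expression_study(
    expr_sim_config(100L, de_genes = de, noise_sd = 0.2, seed = 48L))
  rr <- welch_de(sim$study, alpha = 0.01)
  rep2 <- marker_panel_report(rr, marker_panel("up", panel_genes))
  expect_true(all(rep2$direction == "up"))
  expect_true(all(rep2$significant))

  # negative log2fc reports a negative linear fold (halved = -2)
  simdn <- generate_expression_study(expr_sim_config(
    50L, de_genes = data.frame(gene = "g00001", effect = -1),
    noise_sd = 0, seed = 49L))
  rdn <- welch_de(simdn$study, alpha = 0.5)
  repdn <- marker_panel_report(rdn, marker_panel("dn", "g00001"))
  expect_equal(repdn$fold_change[1], -2, tolerance = 1e-12)
})

test_that("planted effects are recovered with controlled observed FDR", {
  set.seed(50)
  n_seeds <- 10
  sens <- fdr_ratio_ok <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    genes <- sprintf("g%05d", 1:1000)
    de <- data.frame(gene = sample(genes, 80),
                     effect = sample(c(-1, 1), 80, TRUE) *
                       runif(80, 2, 5))
    sim <- generate_expression_study(
      expr_sim_config(1000L, de_genes = de, noise_sd = 0.5,
                      seed = 500L + s))
    r <- welch_de(sim$study, alpha = 0.01)
    hits <- r$table$gene[r$table$significant]
    sens[s] <- mean(de$gene %in% hits) >= 0.75
    obs_fdr <- mean(!(hits %in% de$gene))
    fdr_ratio_ok[s] <- obs_fdr <= 2 * r$fdr_hat
  }
  expect_true(all(sens))
  expect_true(all(fdr_ratio_ok))
})
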