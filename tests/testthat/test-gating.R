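test_that("positivity cutoff reproduces the isotype quantile", {
  iso <- make_events(data.frame(CD4 = rep(5, 200)), stain = "isotype")
  st <- make_events(data.frame(CD4 = runif(50, 1, 10)))
  th <- derive_thresholds(st, iso, split_channel = NULL)
  expect_identical(unname(th$theta_pos[["CD4"]]), 5)

  # log-normal isotype: the 0.99 cutoff matches the analytic quantile
  set.seed(31)
  n <- 100000
  iso2 <- make_events(data.frame(CD4 = rlnorm(n, 1, 0.5)), stain = "isotype")
  th2 <- derive_thresholds(st, iso2, split_channel = NULL)
  analytic <- exp(1 + qnorm(0.99) * 0.5)
  expect_lt(abs(th2$theta_pos[["CD4"]] / analytic - 1), 0.02)
})

test_that("the CD45 low/high split separates well-separated components", {
  set.seed(32)
  n <- 20000
  lo <- rlnorm(n * 0.6, 4, 0.3)
  hi <- rlnorm(n * 0.4, 8, 0.3)
  st <- make_events(data.frame(CD11b = rlnorm(n, 6, 0.3),
                               CD45 = c(lo, hi)))
  iso <- make_events(data.frame(CD11b = rlnorm(1000, 1, 0.5),
                                CD45 = rlnorm(1000, 1, 0.5)),
                     stain = "isotype")
  th <- derive_thresholds(st, iso)
  expect_gt(th$theta_split, exp(4))
  expect_lt(th$theta_split, exp(8))
  expect_gt(mean(lo <= th$theta_split), 0.99)
  expect_gt(mean(hi > th$theta_split), 0.99)

  # unimodal positives: flagged error asking for a manual split
  st_uni <- make_events(data.frame(CD11b = rlnorm(n, 6, 0.3),
                                   CD45 = rlnorm(n, 6, 0.3)))
  expect_error(derive_thresholds(st_uni, iso),
               class = "gliomaTME_split_error")
  th_manual <- derive_thresholds(st_uni, iso, manual_split = exp(5))
  expect_identical(th_manual$theta_split, exp(5))
})

test_that("myeloid quadrant classification counts noise-free patterns exactly", {
  th <- make_thresholds(c(CD11b = 10, CD45 = 10), theta_split = 100)
  block <- function(n, cd11b, cd45)
    data.frame(CD11b = rep(cd11b, n), CD45 = rep(cd45, n))
  ev <- make_events(rbind(block(280, 50, 50),    # CD11b+ CD45low
                          block(40, 50, 500),    # CD11b+ CD45high
                          block(200, 5, 500),    # CD11b- CD45high
                          block(480, 5, 5)))     # negative
  fr <- classify_myeloid(ev, th)
  expect_equal(unname(fr$fractions[c("microglia", "macrophage",
                                     "leukocyte")]),
               c(0.28, 0.04, 0.20))
  # partition property
  expect_identical(sum(fr$counts), fr$n_total)

  # all below all thresholds: everything unclassified
  fr0 <- classify_myeloid(make_events(block(100, 1, 1)), th)
  expect_true(all(fr0$fractions[c("microglia", "macrophage",
                                  "leukocyte")] == 0))
  expect_identical(unname(fr0$counts[["unclassified"]]), 100L)

  # boundary events (exactly at a threshold) are negative
  frb <- classify_myeloid(make_events(block(10, 10, 500)), th)
  expect_identical(unname(frb$counts[["leukocyte"]]), 10L)
  expect_identical(unname(frb$counts[["macrophage"]]), 0L)

  expect_error(classify_myeloid(make_events(data.frame(CD11b = 1:3 * 1.0)),
                                th),
               class = "gliomaTME_schema_error")
})

test_that("single-marker gating is monotone in the threshold", {
  set.seed(33)
  ev <- make_events(data.frame(FOXP3 = rlnorm(5000, 2, 1)))
  fracs <- vapply(c(1, 5, 20, 100), function(cut) {
    classify_tcell_panel(ev, make_thresholds(c(FOXP3 = cut)),
                         "FOXP3")$fractions[[1]]
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))

  none <- classify_tcell_panel(ev, make_thresholds(c(FOXP3 = 1e9)), "FOXP3")
  expect_identical(unname(none$fractions[["FOXP3_pos"]]), 0)
  expect_error(classify_tcell_panel(ev, make_thresholds(c(FOXP3 = 1)), "CD3"),
               class = "gliomaTME_validation_error")
})

test_that("MDSC double-positive and conditional fractions count correctly", {
  th <- make_thresholds(c(CD11b = 10, Gr1 = 10))
  ev <- make_events(data.frame(
    CD11b = c(rep(50, 50), rep(1, 50)),
    Gr1 = c(rep(50, 10), rep(1, 40), rep(1, 50))))
  cl <- classify_mdsc(ev, th)
  expect_equal(unname(cl$fractions[["mdsc"]]), 0.10)
  expect_equal(cl$conditional_fraction, 0.20)

  allneg <- classify_mdsc(make_events(data.frame(CD11b = rep(1, 20),
                                                 Gr1 = rep(1, 20))), th)
  expect_identical(unname(allneg$fractions[["mdsc"]]), 0)
  expect_false(allneg$conditional_defined)
  expect_true(is.na(allneg$conditional_fraction))
})

test_that("kinetics ratios divide fractions and flag undefined shams", {
  gl <- classify_myeloid(
    make_events(data.frame(CD11b = c(rep(50, 28), rep(1, 72)),
                           CD45 = c(rep(50, 28), rep(1, 72)))),
    make_thresholds(c(CD11b = 10, CD45 = 10), 100))
  sh <- classify_myeloid(
    make_events(data.frame(CD11b = c(rep(50, 13), rep(1, 87)),
                           CD45 = c(rep(50, 13), rep(1, 87)))),
    make_thresholds(c(CD11b = 10, CD45 = 10), 100))
  kr <- kinetics_ratio(gl, sh)
  expect_equal(kr$ratio[kr$population == "microglia"], 28 / 13,
               tolerance = 1e-12)
  # sham macrophage fraction is zero: flagged undefined, no error
  mac <- kr[kr$population == "macrophage", ]
  expect_true(is.na(mac$ratio))
  expect_false(mac$defined)

  same <- kinetics_ratio(gl, gl)
  expect_true(all(same$ratio[same$defined] == 1))
})

test_that("group comparison pairs the Welch and Mann-Whitney tests", {
  same <- compare_groups(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_identical(same$t, 0)
  expect_identical(same$t_p, 1)
  expect_false(same$significant)

  sep <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$mw_p, 0.1, tolerance = 1e-12)
  expect_identical(sep$U, 0)

  const <- compare_groups(c(2, 2), c(2, 2))
  expect_false(const$significant)
  expect_identical(const$t, 0)

  expect_error(compare_groups(numeric(0), 1:3),
               class = "gliomaTME_validation_error")
})

test_that("exact Mann-Whitney p equals brute-force enumeration, with ties", {
  set.seed(34)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:5, n1, replace = TRUE)  # ties likely
    y <- sample(1:5, n2, replace = TRUE)
    got <- mann_whitney(x, y)
    expect_equal(got$p, brute_mw_p(x, y), tolerance = 1e-10)
    expect_true(got$U >= 0 && got$U <= n1 * n2)
  }
  # tie-free cases also agree with the standard exact implementation
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mann_whitney(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("gating recovers planted fractions on well-separated myeloid panels", {
  # CD45 low/high components at log-means 4 and 8: misgating is negligible
  # and the only error left is binomial sampling noise
  n <- 100000L
  ch <- c("CD11b", "CD45")
  pops <- list(
    list(name = "microglia", fraction = 0.28,
         meanlog = c(CD11b = 6, CD45 = 4), sdlog = c(CD11b = 0.35, CD45 = 0.35)),
    list(name = "macrophage", fraction = 0.04,
         meanlog = c(CD11b = 6, CD45 = 8), sdlog = c(CD11b = 0.35, CD45 = 0.35)),
    list(name = "leukocyte", fraction = 0.20,
         meanlog = c(CD11b = 0.5, CD45 = 8), sdlog = c(CD11b = 0.5, CD45 = 0.35)),
    list(name = "negative", fraction = 0.48,
         meanlog = c(CD11b = 0.5, CD45 = 0.5), sdlog = c(CD11b = 0.5, CD45 = 0.5)))
  ok <- vapply(1:20, function(s) {
    cfg <- panel_sim_config("myeloid", ch, pops, n,
                            isotype_meanlog = c(CD11b = 1, CD45 = 1),
                            isotype_sdlog = c(CD11b = 0.5, CD45 = 0.5),
                            condition = "glioma", day = 21L, seed = 100L + s)
    sim <- generate_event_panel(cfg)
    th <- derive_thresholds(sim$stained, sim$isotype)
    fr <- classify_myeloid(sim$stained, th)
    truth <- unlist(sim$truth$fractions[c("microglia", "macrophage",
                                          "leukocyte")])
    est <- fr$fractions[c("microglia", "macrophage", "leukocyte")]
    all(abs(est - truth) <= 3 * sqrt(truth * (1 - truth) / n))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
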