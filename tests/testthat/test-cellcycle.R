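test_that("the width gate keeps singlets, removes doublets, and is idempotent", {
  clean <- generateCytometryEvents(histogramParams(doublet_rate = 0,
                                                   n_events = 20000L,
                                                   seed = 2))
  g0 <- gateSinglets(clean, gateLoose)
  expect_gte(attr(g0, "retained_fraction"), 0.99)
  dirty <- generateCytometryEvents(histogramParams(doublet_rate = 0.10,
                                                   n_events = 20000L,
                                                   seed = 3))
  g1 <- gateSinglets(dirty, gateLoose)
  expect_lt(abs(attr(g1, "retained_fraction") - 0.90), 0.02)
  kept <- table(g1$true_class)
  removedDoublets <- sum(dirty$true_class == "doublet") -
                     sum(g1$true_class == "doublet")
  expect_gte(removedDoublets / sum(dirty$true_class == "doublet"), 0.95)
  # fixed-point construction makes re-gating a no-op
  g2 <- gateSinglets(g1, gateLoose)
  expect_equal(nrow(g2), nrow(g1))
  expect_warning(gateSinglets(clean[1:100, ], gateParams()), "retained")
  expect_error(gateSinglets(data.frame(x = 1)), "columns")
})

test_that("a pure-G1 histogram fits as a single component", {
  ev <- generateCytometryEvents(histogramParams(f_g1 = 1, f_s = 0, f_g2m = 0,
                                                doublet_rate = 0,
                                                debris_rate = 0,
                                                n_events = 20000L, seed = 5))
  fit <- suppressWarnings(fitDeanJettFox(ev))
  expect_gte(cellCycleFractions(fit)[["f_g1"]], 0.98)
  expect_lt(abs(fit@muG1 - 100), 1)
})

test_that("phase fractions are recovered and scale-invariant", {
  truth <- c(0.7, 0.2, 0.1)
  for (s in 1:5) {
    ev <- generateCytometryEvents(histogramParams(f_g1 = truth[1],
                                                  f_s = truth[2],
                                                  f_g2m = truth[3],
                                                  n_events = 20000L,
                                                  seed = 20 + s))
    fit <- fitDeanJettFox(gateSinglets(ev, gateLoose))
    expect_lt(max(abs(cellCycleFractions(fit) - truth)), 0.02)
    expect_true(abs(sum(cellCycleFractions(fit)) - 1) < 1e-6)
    expect_true(fit@muG2 / fit@muG1 > 1.7 && fit@muG2 / fit@muG1 < 2.3)
  }
  ev <- generateCytometryEvents(histogramParams(n_events = 20000L, seed = 77))
  gt <- gateSinglets(ev, gateLoose)
  f1 <- cellCycleFractions(fitDeanJettFox(gt))
  gt2 <- gt; gt2$pe_a <- gt2$pe_a * 37.5
  f2 <- cellCycleFractions(fitDeanJettFox(gt2))
  expect_equal(f1, f2, tolerance = 1e-6)
  # quadratic S variant agrees closely on data generated with uniform S
  f3 <- cellCycleFractions(fitDeanJettFox(gt, sModel = "quadratic"))
  expect_lt(max(abs(f1 - f3)), 0.05)
})

test_that("species are separated by G1 peak position", {
  evA <- generateCytometryEvents(histogramParams(g1_mean = 130,
                                                 n_events = 20000L, seed = 1))
  evB <- generateCytometryEvents(histogramParams(g1_mean = 100,
                                                 n_events = 20000L, seed = 2))
  fA <- fitDeanJettFox(gateSinglets(evA, gateLoose))
  fB <- fitDeanJettFox(gateSinglets(evB, gateLoose))
  r <- classifySpecies(fA, fB)
  expect_equal(r$label, "a_larger")
  expect_lt(abs(r$ratio - 1.3), 0.05)
  expect_equal(classifySpecies(fA, fA)$label, "indistinguishable")
  ok <- 0
  for (s in 1:30) {
    a <- fitDeanJettFox(gateSinglets(generateCytometryEvents(
      histogramParams(g1_mean = 125, n_events = 20000L, seed = 100 + s)),
      gateLoose))
    b <- fitDeanJettFox(gateSinglets(generateCytometryEvents(
      histogramParams(g1_mean = 100, n_events = 20000L, seed = 900 + s)),
      gateLoose))
    if (classifySpecies(a, b)$label == "a_larger") ok <- ok + 1
  }
  expect_equal(ok, 30)
})

test_that("arcsine transform hits its endpoints and rejects bad input", {
  expect_equal(arcsineTransform(0), 0)
  expect_equal(arcsineTransform(1), pi / 2)
  expect_equal(arcsineTransform(0.5), asin(sqrt(0.5)))
  expect_error(arcsineTransform(1.2), "\\[0, 1\\]")
})

test_that("group comparison detects a 10-point S-phase shift at n = 3", {
  hits <- 0
  for (rep in 1:30) {
    fa <- vapply(1:3, function(i) cellCycleFractions(fitDeanJettFox(
      gateSinglets(generateCytometryEvents(histogramParams(
        f_g1 = 0.8, f_s = 0.1, f_g2m = 0.1, n_events = 20000L,
        seed = rep * 31 + i)), gateLoose)))[["f_s"]], 0)
    fb <- vapply(1:3, function(i) cellCycleFractions(fitDeanJettFox(
      gateSinglets(generateCytometryEvents(histogramParams(
        f_g1 = 0.7, f_s = 0.2, f_g2m = 0.1, n_events = 20000L,
        seed = 70000 + rep * 31 + i)), gateLoose)))[["f_s"]], 0)
    p <- t.test(arcsineTransform(fa), arcsineTransform(fb))$p.value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.8)
})

test_that("two-way ANOVA machinery runs and calibrates under permutation", {
  set.seed(10)
  # twelve fitted samples from one population, arbitrary factor labels
  fs <- vapply(1:12, function(i) cellCycleFractions(fitDeanJettFox(
    gateSinglets(generateCytometryEvents(histogramParams(
      n_events = 10000L, seed = 4000 + i)), gateLoose)))[["f_s"]], 0)
  df <- data.frame(f_g1 = 1 - fs - 0.05, f_s = fs, f_g2m = 0.05,
                   nutrition = rep(c("replete", "limited"), each = 6),
                   source = rep(c("culture", "host"), 6))
  gc <- groupCompare(df)
  expect_named(gc, c("f_g1", "f_s", "f_g2m"))
  expect_true(all(c("f_value", "p_value") %in% names(gc$f_s$anova)))
  expect_s3_class(gc$f_s$pairwise_welch, "data.frame")
  # permuting labels on exchangeable data: p-values approximately uniform
  pv <- replicate(400, {
    d2 <- df
    d2$nutrition <- sample(d2$nutrition)
    d2$source <- sample(d2$source)
    y <- arcsineTransform(d2$f_s)
    a <- summary(aov(y ~ nutrition * source, data = d2))[[1]]
    a[1, "Pr(>F)"]  # nutrition main effect
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.001)
  expect_gt(mean(pv), 0.35)
  expect_lt(mean(pv), 0.65)
  # unbalanced design with an empty cell drops the interaction
  df2 <- df[df$nutrition == "replete" | df$source == "culture", ]
  expect_warning(groupCompare(df2), "empty design cells")
})

test_that("degenerate fits are rejected and ratio bounds are enforced", {
  expect_error(fitDeanJettFox(runif(50, 1, 2)), "too few")
  # data simulated below the allowed G2/G1 range: the fit stays in bounds
  ev <- generateCytometryEvents(histogramParams(g2_ratio = 1.6,
                                                n_events = 20000L, seed = 3))
  fit <- withCallingHandlers(
    fitDeanJettFox(gateSinglets(ev, gateLoose)),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_gte(fit@muG2 / fit@muG1, 1.7 - 1e-9)
  expect_lte(fit@muG2 / fit@muG1, 2.3 + 1e-9)
})
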