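test_that("kNN distances match a brute-force sort and stay ordered", {
  set.seed(5)
  for (rep in 1:30) {
    src <- matrix(runif(3 * sample(20:120, 1), 0, 50), ncol = 3)
    tgt <- matrix(runif(3 * sample(60:200, 1), 0, 50), ncol = 3)
    k <- min(12, nrow(tgt))
    nn <- knnDistances(src, tgt, kMax = k)
    # independent oracle: full distance matrix, full sort per row
    for (i in seq_len(nrow(src))) {
      d <- sort(sqrt(colSums((t(tgt) - src[i, ])^2)))
      expect_equal(unname(nn$distances[i, ]), d[1:k], tolerance = 1e-12)
    }
    expect_true(all(nn$distances[, -1] - nn$distances[, -k] >= -1e-12))
  }
})

test_that("kNN edge cases follow the self-exclusion contract", {
  tgt <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(5, 5, 5))
  src <- rbind(c(3, 0, 0), c(10, 10, 10))
  nn <- knnDistances(src, tgt, kMax = 2)
  expect_equal(unname(nn$distances[1, 1]), 0)  # coincident but distinct sets
  same <- knnDistances(tgt, tgt, kMax = 3)
  expect_true(all(same$distances[, 1] > 0))  # self excluded
  expect_error(knnDistances(src, tgt, kMax = 5), "available target")
  expect_error(knnDistances(tgt, tgt, kMax = 4), "available target")
  empty <- knnDistances(matrix(numeric(0), 0, 3), tgt, kMax = 2)
  expect_equal(nrow(empty$distances), 0)
})

test_that("distribution comparison reproduces small-sample statistics", {
  a <- c(1.5, 2.5, 3.5)
  r <- compareDistributions(a, a)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$mean_a, r$mean_b)
  ex <- compareDistributions(c(1, 2), c(3, 4))
  expect_equal(unname(ex$u_statistic), 0)
  expect_equal(ex$u_p, 1 / 3, tolerance = 1e-12)
  expect_equal(ex$mad_a, mad(c(1, 2)))
  # shifting one sample never decreases the median gap
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40)
  base <- compareDistributions(x, y)
  shifted <- compareDistributions(x, y + 2)
  expect_gte(shifted$median_b - shifted$median_a,
             base$median_b - base$median_a)
  expect_error(compareDistributions(1, c(1, 2)), "at least 2")
})

test_that("inside/outside counts follow the closed-box convention", {
  pts <- rbind(c(0.5, 0.5, 0.5), c(1, 0.5, 0.5), c(2, 2, 2))
  box <- data.frame(xmin = 0, xmax = 1, ymin = 0, ymax = 1, zmin = 0, zmax = 1)
  io <- insideOutsideCounts(pts, box)
  expect_equal(unname(io), c(2L, 1L))   # the face point counts inside
  none <- insideOutsideCounts(pts, matrix(numeric(0), 0, 6))
  expect_equal(unname(none), c(0L, 3L))
  set.seed(8)
  rp <- matrix(runif(3000, 0, 10), ncol = 3)
  lo <- matrix(runif(90, 0, 9), ncol = 3)
  boxes <- cbind(lo[, 1], lo[, 1] + runif(30, 0.3, 2),
                 lo[, 2], lo[, 2] + runif(30, 0.3, 2),
                 lo[, 3], lo[, 3] + runif(30, 0.3, 2))
  # brute-force per-point per-box oracle
  oracle <- apply(rp, 1, function(p)
    any(p[1] >= boxes[, 1] & p[1] <= boxes[, 2] &
        p[2] >= boxes[, 3] & p[2] <= boxes[, 4] &
        p[3] >= boxes[, 5] & p[3] <= boxes[, 6]))
  io2 <- insideOutsideCounts(rp, boxes)
  expect_equal(io2[["n_in"]], sum(oracle))
  expect_equal(sum(io2), nrow(rp))
})

test_that("neutral-dispersal test reproduces hand-computed fixtures", {
  r0 <- neutralDispersalTest(data.frame(n_in = 50, n_out = 50,
                                        v_sym = 0.5, v_total = 1))
  expect_equal(r0@chiSquare, 0)
  expect_equal(perTentacle(r0)$expected_in, 50)
  r1 <- neutralDispersalTest(data.frame(n_in = 30, n_out = 10,
                                        v_sym = 0.2, v_total = 1))
  expect_equal(r1@chiSquare, 75.625, tolerance = 1e-12)
  expect_equal(r1@df, 1)
  expect_equal(perTentacle(r1)$expected_in, 8)
  expect_equal(perTentacle(r1)$diff, 22)
  # aggregation is order-invariant
  tb <- data.frame(n_in = c(30, 12, 4), n_out = c(10, 40, 60),
                   v_sym = c(0.2, 0.3, 0.1), v_total = c(1, 1, 1))
  expect_equal(neutralDispersalTest(tb)@chiSquare,
               neutralDispersalTest(tb[3:1, ])@chiSquare)
  # degenerate volume fractions
  expect_error(neutralDispersalTest(
    data.frame(n_in = 3, n_out = 5, v_sym = 0, v_total = 1)), "zero-volume")
  expect_warning(
    rz <- neutralDispersalTest(data.frame(n_in = c(0, 30), n_out = c(5, 10),
                                          v_sym = c(0, 0.2),
                                          v_total = c(1, 1))),
    "excluded")
  expect_equal(rz@df, 1)
  expect_error(neutralDispersalTest(
    data.frame(n_in = 1, n_out = 1, v_sym = 2, v_total = 1)), "exceed")
})

test_that("tentacle summaries convert densities and diameters correctly", {
  s <- tentacleSummary(nHost = 100, nEdu = 10, nSymbiont = 5,
                       volumeUm3 = 1e5, symbiontVolumeUm3 = 2e4)
  expect_equal(s$percent_edu, 10)
  expect_equal(s$host_density_per_mm3, 100 / 1e5 * 1e9)
  expect_equal(s$symbiont_volume_fraction, 0.2)
  expect_equal(s$est_cell_diameter_um, (6 * (1e5 / 100) / pi)^(1 / 3))
  expect_error(tentacleSummary(10, 20, 0, 1e5), "nEdu")
  # printed-density worked examples
  expect_equal(round(equivalentSphereDiameter(3.8e6), 2), 7.95)
  expect_lt(abs(equivalentSphereDiameter(4.1e6) - 7.80), 0.1)
})

test_that("z profiles measure the depth shift of proliferating nuclei", {
  expect_equal(zProfile(1:10, 1:10)$normalized_z, 0)
  zp <- zProfile(1:10, 6:10)
  expect_equal(zp$normalized_z, 2.5)
  zp2 <- zProfile(1:10, 6:10, zSym = c(20, 25, 30))
  expect_equal(zp2$boundary_z, unname(quantile(c(20, 25, 30), 0.05)))
  nos <- zProfile(1:10, 6:10, zSym = NULL)
  expect_true(is.na(nos$boundary_z) && is.na(nos$frac_edu_gastrodermis))
  expect_error(zProfile(numeric(0), 1:3), "empty")
  # simulator sign check: coupling pulls EdU+ deeper; null stays centred
  nzC <- nzN <- numeric(15)
  for (s in 1:15) {
    trC <- generateTentacleScene(miniSceneParams(seed = 600 + s,
                                                 coupling_lambda = 5),
                                 render = FALSE)$truth
    trN <- generateNullScene(miniSceneParams(seed = 600 + s),
                             render = FALSE)$truth
    nzC[s] <- zProfile(hostNuclei(trC)[, 3],
                       hostNuclei(trC)[eduFlags(trC), 3],
                       symbiontCenters(trC)[, 3])$normalized_z
    nzN[s] <- zProfile(hostNuclei(trN)[, 3],
                       hostNuclei(trN)[eduFlags(trN), 3],
                       symbiontCenters(trN)[, 3])$normalized_z
  }
  expect_gt(mean(nzC), 0)
  expect_gt(mean(nzC), mean(nzN) + 1)
  expect_lt(abs(mean(nzN)), 1)
})

test_that("regression summaries match hand-computed least squares", {
  # an exact linear relation triggers lm's perfect-fit note; that is the point
  ex <- suppressWarnings(regressTentacles(1:10, 2 * (1:10)))
  expect_equal(ex$slope, 2)
  expect_equal(ex$r_squared, 1)
  h <- regressTentacles(c(1, 2, 3), c(1, 3, 2))
  expect_equal(h$slope, 0.5)
  expect_equal(h$r_squared, 0.25, tolerance = 1e-12)
  expect_equal(h$f_statistic, 1 / 3, tolerance = 1e-12)
  # jointly permuting pairs changes nothing
  set.seed(2)
  x <- runif(12); y <- 3 * x + rnorm(12)
  o <- sample(12)
  a <- regressTentacles(x, y); b <- regressTentacles(x[o], y[o])
  expect_equal(a$slope, b$slope)
  expect_equal(a$r_squared, b$r_squared)
  expect_equal(a$p_value, b$p_value)
  expect_error(regressTentacles(rep(1, 5), 1:5), "zero variance")
  expect_error(regressTentacles(1:2, 1:2), "at least 3")
})

test_that("truth-driven object sets and batches wire the pipeline together", {
  tr <- generateTentacleScene(miniSceneParams(seed = 12), render = FALSE)$truth
  sym <- truthObjectSet(tr, "symbionts")
  expect_equal(nObjects(sym), nrow(symbiontCenters(tr)))
  bb <- boundingBoxes(sym)
  expect_equal(bb$xmax - bb$xmin, rep(10, nObjects(sym)))
  eb <- enrichmentBatch(miniSceneParams(), nTentacles = 4, seed = 3)
  expect_s4_class(eb, "EnrichmentResult")
  expect_equal(nrow(perTentacle(eb)), 4)
  expect_identical(perTentacle(enrichmentBatch(miniSceneParams(),
                                               nTentacles = 4, seed = 3)),
                   perTentacle(eb))
})
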