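test_that("empty and degenerate channels are handled per contract", {
  z <- array(0, c(20, 20, 10))
  st <- stackFromArray(z)
  empty <- detectObjects(st, "hoechst",
                         detectParams(thresholdMethod = "fixed",
                                      thresholdValue = 0.5,
                                      backgroundRadiusUm = 0),
                         "host_nuclei")
  expect_equal(nObjects(empty), 0)
  expect_error(detectObjects(stackFromArray(array(1, c(10, 10, 5))),
                             "hoechst",
                             detectParams(backgroundRadiusUm = 0),
                             "host_nuclei"),
               "no threshold separable")
})

test_that("a single bright voxel lands at the voxel-centre convention", {
  z <- array(0, c(20, 20, 10))
  z[5, 7, 3] <- 1   # 0-based voxel (4, 6, 2)
  st <- stackFromArray(z, voxelUm = c(0.5, 0.5, 1))
  os <- detectObjects(st, "hoechst",
                      detectParams(thresholdMethod = "fixed",
                                   thresholdValue = 0.5,
                                   backgroundRadiusUm = 0,
                                   minSizeVoxels = 1),
                      "host_nuclei")
  expect_equal(nObjects(os), 1)
  expect_equal(unname(coords(os)[1, ]), c(4.5 * 0.5, 6.5 * 0.5, 2.5 * 1))
  # a one-voxel object is all surface, distance zero
  cs <- centerToSurfaceDistances(os, 1L)
  expect_equal(cs$mean, 0)
  # its bounding box spans exactly one voxel
  bb <- boundingBoxes(os)
  expect_equal(unname(unlist(bb[1, -1])),
               c(4 * 0.5, 5 * 0.5, 6 * 0.5, 7 * 0.5, 2, 3))
})

test_that("well-separated simulated nuclei are recovered exactly", {
  # ~50 nuclei at low density: no contact, detection must be exact
  p <- sceneParams(extent_um = c(100, 100, 40),
                   epidermis_z_um = c(center = 10, width = 20),
                   gastrodermis_z_um = c(center = 30, width = 20),
                   nucleus_density_per_mm3 = 1.25e5, symbiont_count = 0,
                   coupling_lambda = 0, noise_sd = 0, seed = 31,
                   nucleus_min_sep_um = 12)
  sc <- generateTentacleScene(p)
  tr <- sc$truth
  os <- detectObjects(sc$stack, "hoechst", detectParams(), "host_nuclei")
  expect_equal(nObjects(os), nrow(hostNuclei(tr)))
  d <- SymbioCycle:::cpp_min_dist(coords(os), hostNuclei(tr))
  # half a voxel diagonal for nuclei whose sphere is fully in frame;
  # nuclei clipped by a scene face have their centre of mass pulled inward
  nuc <- hostNuclei(tr)
  margin <- pmin(nuc[, 1], p$extent_um[1] - nuc[, 1],
                 nuc[, 2], p$extent_um[2] - nuc[, 2],
                 nuc[, 3], p$extent_um[3] - nuc[, 3])
  interior <- margin > p$nucleus_radius_um + 0.5
  dDet <- SymbioCycle:::cpp_min_dist(nuc, coords(os))
  expect_lt(max(dDet[interior]), sqrt(sum((p$voxel_um / 2)^2)))
  expect_lt(max(dDet), 1.5)
})

test_that("two-round watershed resolves touching sphere fixtures", {
  ext <- c(44, 24, 24)
  # one isolated sphere: nothing to split, com unchanged
  one <- sphereStack(rbind(c(12, 12, 12)), 5, ext)
  s1 <- detectObjects(one, "hoechst",
                      detectParams(thresholdMethod = "fixed",
                                   thresholdValue = 0.5,
                                   backgroundRadiusUm = 0), "host_nuclei")
  s1s <- splitClusters(s1)
  expect_equal(nObjects(s1s), 1)
  expect_lt(max(abs(coords(s1s)[1, ] - c(12, 12, 12))),
            sqrt(sum((c(0.5, 0.5, 1) / 2)^2)))
  # overlapping pair, centres 8 um apart
  two <- sphereStack(rbind(c(12, 12, 12), c(20, 12, 12)), 5, ext)
  s2 <- detectObjects(two, "hoechst",
                      detectParams(thresholdMethod = "fixed",
                                   thresholdValue = 0.5,
                                   backgroundRadiusUm = 0), "host_nuclei")
  expect_equal(nObjects(s2), 1)
  s2s <- splitClusters(s2)
  expect_equal(nObjects(s2s), 2)
  d <- SymbioCycle:::cpp_min_dist(rbind(c(12, 12, 12), c(20, 12, 12)),
                                  coords(s2s))
  expect_lt(max(d), 1)
  # linear chain of three touching spheres
  chain <- sphereStack(rbind(c(10, 12, 12), c(20, 12, 12), c(30, 12, 12)),
                       5, ext)
  s3s <- splitClusters(detectObjects(chain, "hoechst",
                                     detectParams(thresholdMethod = "fixed",
                                                  thresholdValue = 0.5,
                                                  backgroundRadiusUm = 0),
                                     "host_nuclei"))
  expect_equal(nObjects(s3s), 3)
})

test_that("splitting conserves voxels and never merges", {
  two <- sphereStack(rbind(c(12, 12, 12), c(20, 12, 12)), 5, c(44, 24, 24))
  s2 <- detectObjects(two, "hoechst",
                      detectParams(thresholdMethod = "fixed",
                                   thresholdValue = 0.5,
                                   backgroundRadiusUm = 0), "host_nuclei")
  s2s <- splitClusters(s2)
  expect_gte(nObjects(s2s), nObjects(s2))
  expect_equal(sum(s2s@objects$voxel_count), sum(s2@objects$voxel_count))
  expect_equal(sum(s2s@mask > 0), sum(s2@mask > 0))
  # rounds = 0 is a no-op; negative rounds are rejected
  expect_equal(nObjects(splitClusters(s2, detectParams(watershedRounds = 0))),
               nObjects(s2))
  expect_error(detectParams(watershedRounds = -1), "watershedRounds")
})

test_that("bounding boxes have physical extent and contain their object", {
  st <- sphereStack(rbind(c(12, 12, 12)), 5, c(24, 24, 24))
  os <- detectObjects(st, "hoechst",
                      detectParams(thresholdMethod = "fixed",
                                   thresholdValue = 0.5,
                                   backgroundRadiusUm = 0), "host_nuclei")
  bb <- boundingBoxes(os)
  side <- c(bb$xmax - bb$xmin, bb$ymax - bb$ymin, bb$zmax - bb$zmin)
  expect_true(all(abs(side - 10) <= 1 + 1e-9))
  com <- coords(os)[1, ]
  expect_true(com[1] >= bb$xmin && com[1] <= bb$xmax &&
              com[2] >= bb$ymin && com[2] <= bb$ymax &&
              com[3] >= bb$zmin && com[3] <= bb$zmax)
})

test_that("union volume is exact on constructed and random boxes", {
  expect_equal(unionVolume(rbind(c(0, 1, 0, 1, 0, 1), c(2, 3, 0, 1, 0, 1))), 2)
  expect_equal(unionVolume(rbind(c(0, 1, 0, 1, 0, 1), c(0, 1, 0, 1, 0, 1))), 1)
  expect_equal(unionVolume(matrix(numeric(0), 0, 6)), 0)
  set.seed(14)
  lo <- matrix(runif(20 * 3, 0, 8), 20)
  boxes <- cbind(lo[, 1], lo[, 1] + runif(20, 0.5, 3),
                 lo[, 2], lo[, 2] + runif(20, 0.5, 3),
                 lo[, 3], lo[, 3] + runif(20, 0.5, 3))
  # snap to the oracle grid so fine voxelization is itself exact
  boxes <- round(boxes / 0.05) * 0.05
  # brute-force fine-voxelization oracle
  g <- seq(0.025, 11, by = 0.05)
  pts <- as.matrix(expand.grid(g, g, g))
  inb <- SymbioCycle:::cpp_in_any_box(pts, boxes)
  oracle <- sum(inb) * 0.05^3
  expect_lt(abs(unionVolume(boxes) - oracle) / oracle, 0.01)
  # subadditivity with equality iff disjoint
  vols <- (boxes[, 2] - boxes[, 1]) * (boxes[, 4] - boxes[, 3]) *
          (boxes[, 6] - boxes[, 5])
  expect_lte(unionVolume(boxes), sum(vols))
  disj <- rbind(c(0, 1, 0, 1, 0, 1), c(5, 6, 5, 6, 5, 6))
  expect_equal(unionVolume(disj), 2)
})

test_that("tentacle hull volume matches exact geometry and scene truth", {
  corners <- as.matrix(expand.grid(c(0, 100), c(0, 100), c(0, 100)))
  tv <- tentacleVolume(corners, dilationUm = 0)
  expect_equal(tv$volume_um3, 1e6, tolerance = 1e-9)
  # interior points never change the hull
  tv2 <- tentacleVolume(rbind(corners, c(50, 50, 50), c(10, 90, 40)),
                        dilationUm = 0)
  expect_equal(tv2$volume_um3, 1e6, tolerance = 1e-9)
  expect_error(tentacleVolume(corners[1:3, ]), "4 non-coplanar")
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(tentacleVolume(flat, dilationUm = 0), "coplanar")
  # simulated scene: tissue fills the frame, so the undilated hull applies
  tr <- generateTentacleScene(sceneParams(seed = 9), render = FALSE)$truth
  tvs <- tentacleVolume(hostNuclei(tr), dilationUm = 0)
  expect_lt(abs(tvs$volume_um3 - trueVolume(tr)) / trueVolume(tr), 0.15)
})

test_that("centre-to-surface distances recover sphere and ellipsoid radii", {
  st <- sphereStack(rbind(c(12, 12, 12)), 5, c(24, 24, 24),
                    voxelUm = c(0.5, 0.5, 0.5))
  os <- detectObjects(st, "hoechst",
                      detectParams(thresholdMethod = "fixed",
                                   thresholdValue = 0.5,
                                   backgroundRadiusUm = 0), "host_nuclei")
  cs <- centerToSurfaceDistances(os, 1L)
  expect_lt(abs(cs$mean - 5), 0.3)
  expect_lt(abs(cs$median - 5), 0.3)
  # ellipsoid with semi-axes 2, 2, 4 um (4 x 4 x 8 um)
  vox <- c(0.25, 0.25, 0.25)
  dims <- c(48L, 48L, 64L)
  cc <- c(6, 6, 8)
  ii <- (seq_len(dims[1]) - 0.5) * vox[1]
  jj <- (seq_len(dims[2]) - 0.5) * vox[2]
  kk <- (seq_len(dims[3]) - 0.5) * vox[3]
  a <- array(0, dims)
  for (k in seq_len(dims[3])) {
    m <- outer((ii - cc[1])^2 / 4, (jj - cc[2])^2 / 4, `+`) +
         (kk[k] - cc[3])^2 / 16
    a[, , k] <- (m <= 1) * 1
  }
  ose <- detectObjects(stackFromArray(a, voxelUm = vox), "hoechst",
                       detectParams(thresholdMethod = "fixed",
                                    thresholdValue = 0.5,
                                    backgroundRadiusUm = 0), "host_nuclei")
  cse <- centerToSurfaceDistances(ose, 1L)
  expect_lt(abs(min(cse$distances) - 2), 0.25)
  expect_lt(abs(max(cse$distances) - 4), 0.25)
  expect_error(centerToSurfaceDistances(ose, 99L), "empty")
})
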