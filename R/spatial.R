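#' k-nearest-neighbour cross distances between cell populations
#'
#' Euclidean distances in physical micrometres from every source centre to
#' its k nearest target centres, k = 1..`kMax`, sorted ascending per
#' source point. A source point coincident with a target point is not
#' excluded unless source and target are the same set, in which case the
#' self-distance is excluded. Either direction (symbiont-to-host or
#' host-to-symbiont) can be computed; the direction is recorded in the
#' result.
#'
#' @param source,target [ObjectSet-class] or n x 3 coordinate matrices.
#' @param kMax largest neighbour order (12 by convention).
#' @param tentacleId identifier recorded in the result.
#' @return list of class `"NNResult"`: `distances` (n_source x kMax
#'   matrix), `sourceGroup`, `targetGroup`, `direction`, `kMax`,
#'   `tentacleId`.
#' @export
knnDistances <- function(source, target, kMax = 12L, tentacleId = "t1") {
  src <- asCoords(source)
  tgt <- asCoords(target)
  kMax <- as.integer(kMax)
  if (kMax < 1) stop("kMax must be >= 1")
  selfQuery <- identical(unname(src), unname(tgt))
  avail <- nrow(tgt) - as.integer(selfQuery)
  if (nrow(src) > 0 && kMax > avail)
    stop("kMax = ", kMax, " exceeds the ", avail,
         " available target points", if (selfQuery) " (self-query excludes each point itself)")
  d <- if (nrow(src) == 0) matrix(numeric(0), 0, kMax)
       else cpp_knn(src, tgt, kMax, selfQuery)
  colnames(d) <- paste0("k", seq_len(kMax))
  sg <- if (is(source, "ObjectSet")) source@group else "points"
  tg <- if (is(target, "ObjectSet")) target@group else "points"
  structure(list(distances = d, sourceGroup = sg, targetGroup = tg,
                 direction = paste(sg, "to", tg), kMax = kMax,
                 tentacleId = tentacleId),
            class = "NNResult")
}

#' Two-sample comparison of distance distributions
#'
#' Welch's unequal-variance t-test and a two-sided Mann-Whitney U test
#' (exact by enumeration when the pooled sample size is at most 12 and no
#' ties are present, otherwise the normal approximation with continuity
#' and tie correction), plus descriptive statistics including the median
#' absolute deviation (scaled by 1.4826).
#'
#' @param a,b numeric vectors of distances, each of length >= 2.
#' @return list of class `"TestResult"` with means, SDs, medians, MADs,
#'   `t_statistic`, `t_p`, `u_statistic`, `u_p`, `n_a`, `n_b`.
#' @examples
#' compareDistributions(c(1, 2), c(3, 4))$u_p  # exact 1/3
#' @export
compareDistributions <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  tt <- t.test(a, b, var.equal = FALSE)
  exact <- (length(a) + length(b) <= 12) && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sd_a = sd(a), sd_b = sd(b),
                 median_a = median(a), median_b = median(b),
                 mad_a = mad(a), mad_b = mad(b),
                 t_statistic = unname(tt$statistic), t_p = tt$p.value,
                 u_statistic = unname(wt$statistic), u_p = wt$p.value,
                 n_a = length(a), n_b = length(b)),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("TestResult (n = %d vs %d)\n", x$n_a, x$n_b))
  cat(sprintf("  means %.3f vs %.3f (Welch t = %.3f, p = %.3g)\n",
              x$mean_a, x$mean_b, x$t_statistic, x$t_p))
  cat(sprintf("  medians %.3f vs %.3f (Mann-Whitney U = %g, p = %.3g)\n",
              x$median_a, x$median_b, x$u_statistic, x$u_p))
  invisible(x)
}

#' Count points inside and outside a set of boxes
#'
#' A point is inside if it lies within at least one box; intervals are
#' closed on both ends, so a point exactly on a face counts as inside.
#'
#' @param points [ObjectSet-class] or n x 3 matrix.
#' @param boxes data.frame or 6-column matrix of boxes.
#' @return named integer vector `c(n_in, n_out)`.
#' @export
insideOutsideCounts <- function(points, boxes) {
  pts <- asCoords(points)
  m <- asBoxMatrix(boxes)
  if (nrow(pts) == 0) return(c(n_in = 0L, n_out = 0L))
  if (nrow(m) == 0) return(c(n_in = 0L, n_out = nrow(pts)))
  inb <- cpp_in_any_box(pts, m)
  c(n_in = sum(inb), n_out = sum(!inb))
}

#' Neutral-dispersal enrichment test
#'
#' Tests whether proliferating nuclei fall inside symbiont-containing
#' regions more often than their volume share predicts. For each tentacle
#' with observed counts inside/outside and volumes, the expected inside
#' count under neutral dispersal is `f * (n_in + n_out)` with
#' `f = v_sym / v_total`; the per-tentacle 2-cell chi-square terms are
#' pooled (one df per tentacle), and a paired t-test compares observed and
#' expected inside counts across tentacles.
#'
#' @param tentacles data.frame with columns `n_in`, `n_out`, `v_sym`,
#'   `v_total` and optionally `tentacle_id`.
#' @return an [EnrichmentResult-class].
#' @examples
#' neutralDispersalTest(data.frame(n_in = 30, n_out = 10,
#'   v_sym = 0.2, v_total = 1))  # chi-square 75.625
#' @export
neutralDispersalTest <- function(tentacles) {
  need <- c("n_in", "n_out", "v_sym", "v_total")
  if (!all(need %in% names(tentacles)))
    stop("tentacles needs columns ", paste(need, collapse = ", "))
  if (any(tentacles$v_sym > tentacles$v_total + 1e-9))
    stop("v_sym cannot exceed v_total")
  tot <- tentacles$n_in + tentacles$n_out
  if (any(tot < 1)) stop("each tentacle needs n_in + n_out >= 1")
  f <- tentacles$v_sym / tentacles$v_total
  if (any(f == 0 & tentacles$n_in > 0))
    stop("inconsistent tentacle: observed nuclei inside a zero-volume region")
  eIn <- f * tot
  eOut <- (1 - f) * tot
  chiTerm <- rep(NA_real_, nrow(tentacles))
  usable <- f > 0 & f < 1
  if (any(!usable))
    warning(sum(!usable), " tentacle(s) with volume fraction 0 or 1 excluded from the chi-square")
  chiTerm[usable] <- (tentacles$n_in[usable] - eIn[usable])^2 / eIn[usable] +
                     (tentacles$n_out[usable] - eOut[usable])^2 / eOut[usable]
  chi <- sum(chiTerm[usable])
  df <- sum(usable)
  chiP <- if (df > 0) pchisq(chi, df, lower.tail = FALSE) else NA_real_
  if (nrow(tentacles) >= 2 && var(tentacles$n_in - eIn) > 0) {
    pt <- t.test(tentacles$n_in, eIn, paired = TRUE)
    pairedT <- unname(pt$statistic); pairedP <- pt$p.value
  } else {
    pairedT <- NA_real_; pairedP <- NA_real_
  }
  ids <- if ("tentacle_id" %in% names(tentacles))
    as.character(tentacles$tentacle_id) else as.character(seq_len(nrow(tentacles)))
  per <- data.frame(tentacle_id = ids,
                    n_in = tentacles$n_in, n_out = tentacles$n_out,
                    volume_fraction = f, expected_in = eIn,
                    diff = tentacles$n_in - eIn, chi_term = chiTerm)
  new("EnrichmentResult", perTentacle = per, chiSquare = chi, chiP = chiP,
      df = df, pairedT = pairedT, pairedP = pairedP)
}

#' Equivalent-sphere cell diameter from a density
#'
#' Converts a cell density (cells per cubic millimetre) to the diameter of
#' the sphere with the per-cell volume: `d = (6 V_cell / pi)^(1/3)` with
#' `V_cell = 1e9 / density` cubic micrometres.
#'
#' @param densityPerMm3 cells per mm^3.
#' @return diameter in micrometres.
#' @examples
#' equivalentSphereDiameter(3.8e6)  # ~7.95 um
#' @export
equivalentSphereDiameter <- function(densityPerMm3) {
  checkPositive(densityPerMm3, "densityPerMm3")
  (6 * (1e9 / densityPerMm3) / pi)^(1 / 3)
}

#' @rdname equivalentSphereDiameter
#' @param volumeUm3 tissue volume in cubic micrometres.
#' @param n number of cells in that volume.
#' @export
perCellDiameter <- function(volumeUm3, n) {
  checkPositive(volumeUm3, "volumeUm3")
  checkPositive(n, "n")
  (6 * (volumeUm3 / n) / pi)^(1 / 3)
}

#' Per-tentacle summary statistics
#'
#' Densities (cells per mm^3, converted from um^3 by the factor 1e9),
#' percent proliferating, the equivalent-sphere cell diameter, and the
#' symbiont volume fraction.
#'
#' @param nHost,nEdu,nSymbiont object counts.
#' @param volumeUm3 tentacle volume (um^3).
#' @param symbiontVolumeUm3 overlap-subtracted symbiont-region volume
#'   (um^3), optional.
#' @param tentacleId identifier.
#' @return one-row data.frame.
#' @export
tentacleSummary <- function(nHost, nEdu, nSymbiont, volumeUm3,
                            symbiontVolumeUm3 = NA_real_,
                            tentacleId = "t1") {
  checkPositive(volumeUm3, "volumeUm3")
  if (nEdu > nHost) stop("nEdu cannot exceed nHost")
  data.frame(
    tentacle_id = tentacleId,
    n_host = nHost, n_edu = nEdu, n_symbiont = nSymbiont,
    tentacle_volume_um3 = volumeUm3,
    host_density_per_mm3 = nHost / volumeUm3 * 1e9,
    edu_density_per_mm3 = nEdu / volumeUm3 * 1e9,
    symbiont_density_per_mm3 = nSymbiont / volumeUm3 * 1e9,
    percent_edu = if (nHost > 0) 100 * nEdu / nHost else NA_real_,
    est_cell_diameter_um = if (nHost > 0) perCellDiameter(volumeUm3, nHost)
                           else NA_real_,
    symbiont_volume_fraction = symbiontVolumeUm3 / volumeUm3)
}

#' Depth profile of cell populations along the z axis
#'
#' Per-tentacle z medians of each population, the normalized location of
#' proliferating nuclei (`median z of EdU+ minus median z of all host
#' nuclei`; positive = shifted toward the deeper gastrodermis), and a
#' tissue-layer partition: the epidermal-gastrodermal boundary is placed
#' at the shallow edge of the symbiont z distribution (by default its 5th
#' percentile), and the fractions of EdU+ and of all nuclei at or deeper
#' than the boundary are reported.
#'
#' @param zHost,zEdu,zSym z coordinates (micrometres) of host nuclei,
#'   EdU+ nuclei and symbionts; `zSym` may be NULL (no layer partition).
#' @param boundaryQuantile quantile of the symbiont z distribution used as
#'   the layer boundary.
#' @return list with `median_host`, `median_edu`, `median_symbiont`,
#'   `normalized_z`, `boundary_z`, `frac_edu_gastrodermis`,
#'   `frac_host_gastrodermis`.
#' @export
zProfile <- function(zHost, zEdu, zSym = NULL, boundaryQuantile = 0.05) {
  if (length(zHost) == 0) stop("host population is empty")
  mh <- median(zHost)
  me <- if (length(zEdu)) median(zEdu) else NA_real_
  ms <- if (length(zSym)) median(zSym) else NA_real_
  if (length(zSym)) {
    bz <- unname(quantile(zSym, boundaryQuantile))
    fe <- if (length(zEdu)) mean(zEdu >= bz) else NA_real_
    fh <- mean(zHost >= bz)
  } else {
    bz <- NA_real_; fe <- NA_real_; fh <- NA_real_
  }
  list(median_host = mh, median_edu = me, median_symbiont = ms,
       normalized_z = me - mh, boundary_z = bz,
       frac_edu_gastrodermis = fe, frac_host_gastrodermis = fh)
}

#' Ordinary least-squares regression across tentacles
#'
#' Simple linear regression with intercept; reports the coefficient of
#' determination, the F statistic on (1, n - 2) degrees of freedom and its
#' p-value.
#'
#' @param x,y per-tentacle predictor and response (n >= 3).
#' @return list of class `"RegressionResult"`: `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `p_value`, `n`.
#' @export
regressTentacles <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("regression needs at least 3 tentacles")
  if (var(x) == 0) stop("predictor has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fs <- if (is.null(sm$fstatistic)) c(value = NA_real_, numdf = 1, dendf = length(x) - 2)
        else sm$fstatistic
  pv <- stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]], lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 f_statistic = unname(fs[["value"]]),
                 p_value = unname(pv), n = length(x)),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("OLS over %d tentacles: slope %.4g, intercept %.4g\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f, F(1, %d) = %.3f, p = %.3g\n",
              x$r_squared, x$n - 2, x$f_statistic, x$p_value))
  invisible(x)
}

#' End-to-end enrichment analysis of simulated tentacles
#'
#' Convenience pipeline used for calibration and power studies: for each
#' seed, generate one batch of tentacles from ground truth (no imaging),
#' count EdU+ nuclei inside the union of symbiont bounding boxes, and run
#' [neutralDispersalTest()] on the batch.
#'
#' @param params a [sceneParams()] list; its `seed` is replaced per
#'   tentacle.
#' @param nTentacles tentacles per batch.
#' @param seed batch seed; per-tentacle seeds are drawn from it with
#'   `sample.int` so that tentacle RNG streams are well separated.
#' @return an [EnrichmentResult-class] for the batch.
#' @export
enrichmentBatch <- function(params = sceneParams(), nTentacles = 8L,
                            seed = 1L) {
  tentSeeds <- withSeed(seed, sample.int(2147483646L, nTentacles))
  rows <- vector("list", nTentacles)
  for (i in seq_len(nTentacles)) {
    params$seed <- tentSeeds[i]
    tr <- generateTentacleScene(params, render = FALSE)$truth
    boxes <- boundingBoxes(truthObjectSet(tr, "symbionts"))
    eduPts <- tr@nucleiUm[tr@eduFlags, , drop = FALSE]
    io <- insideOutsideCounts(eduPts, boxes)
    rows[[i]] <- data.frame(tentacle_id = paste0("t", i),
                            n_in = io[["n_in"]], n_out = io[["n_out"]],
                            v_sym = unionVolume(boxes),
                            v_total = tr@tentacleVolumeUm3)
  }
  neutralDispersalTest(do.call(rbind, rows))
}
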