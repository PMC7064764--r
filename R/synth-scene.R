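#' Parameters for a synthetic tentacle scene
#'
#' Defines the study conditions the simulator emulates: a two-layer
#' tentacle (shallow epidermis, deep gastrodermis) populated with host
#' nuclei at a target density, clustered symbiont cells confined to the
#' gastrodermal band, and an optional proximity coupling that raises the
#' probability that a nucleus is proliferating (EdU+) near symbionts.
#'
#' Defaults correspond to partially recolonized tentacles: host nuclei at
#' 3.8e6 cells/mm^3, symbionts at 5e5 cells/mm^3 (288 cells in the default
#' 120 x 120 x 40 um scene), symbiont radius 5 um, and a baseline EdU rate
#' of 0.045 boosted multiplicatively by
#' `1 + coupling_lambda * exp(-d / coupling_scale_um)` at distance `d`
#' from the nearest symbiont centre (clipped to probability 1). The two
#' depth bands tile the axial extent with equal nuclear density so that,
#' with `coupling_lambda = 0`, EdU+ nuclei fall inside any subregion in
#' proportion to its volume.
#'
#' @param extent_um physical scene size (x, y, z) in micrometres.
#' @param voxel_um voxel pitch (dx, dy, dz) in micrometres.
#' @param epidermis_z_um,gastrodermis_z_um numeric(2) `c(center, width)`
#'   depth bands for the two nuclear layers.
#' @param nucleus_density_per_mm3 target host-nucleus density.
#' @param edu_base_rate baseline probability that a nucleus is EdU+.
#' @param symbiont_count number of symbiont cells.
#' @param symbiont_radius_um symbiont sphere radius.
#' @param cluster_parents,cluster_sigma_um parent count and offspring
#'   dispersion of the Thomas-type clustered symbiont placement.
#' @param coupling_lambda strength (>= 0) of EdU enrichment near symbionts.
#' @param coupling_scale_um exponential decay length of the enrichment.
#' @param psf_sigma_um isotropic rendering blur.
#' @param noise_sd additive Gaussian noise on rendered intensities.
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical scenes.
#' @param nucleus_radius_um rendered nucleus sphere radius.
#' @param nucleus_min_sep_um,symbiont_min_sep_um hard-core minimum
#'   centre-to-centre separations (cells cannot interpenetrate).
#'
#' @return a validated parameter list of class `"SceneParams"`.
#' @seealso [generateTentacleScene()], [generateNullScene()]
#' @export
sceneParams <- function(extent_um = c(120, 120, 40),
                        voxel_um = c(0.5, 0.5, 1),
                        epidermis_z_um = c(center = 8, width = 16),
                        gastrodermis_z_um = c(center = 28, width = 24),
                        nucleus_density_per_mm3 = 3.8e6,
                        edu_base_rate = 0.045,
                        symbiont_count = 288,
                        symbiont_radius_um = 5,
                        cluster_parents = 30,
                        cluster_sigma_um = 12,
                        coupling_lambda = 3,
                        coupling_scale_um = 10,
                        psf_sigma_um = 0.4,
                        noise_sd = 0.02,
                        seed = 1L,
                        nucleus_radius_um = 2.5,
                        nucleus_min_sep_um = 5.2,
                        symbiont_min_sep_um = 7.5) {
  p <- list(extent_um = as.numeric(extent_um), voxel_um = as.numeric(voxel_um),
            epidermis_z_um = as.numeric(epidermis_z_um),
            gastrodermis_z_um = as.numeric(gastrodermis_z_um),
            nucleus_density_per_mm3 = nucleus_density_per_mm3,
            edu_base_rate = edu_base_rate,
            symbiont_count = as.integer(symbiont_count),
            symbiont_radius_um = symbiont_radius_um,
            cluster_parents = as.integer(cluster_parents),
            cluster_sigma_um = cluster_sigma_um,
            coupling_lambda = coupling_lambda,
            coupling_scale_um = coupling_scale_um,
            psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
            seed = as.integer(seed),
            nucleus_radius_um = nucleus_radius_um,
            nucleus_min_sep_um = nucleus_min_sep_um,
            symbiont_min_sep_um = symbiont_min_sep_um)
  validateSceneParams(p)
  class(p) <- "SceneParams"
  p
}

validateSceneParams <- function(p) {
  checkPositive(p$extent_um, "extent_um")
  checkPositive(p$voxel_um, "voxel_um")
  checkPositive(p$nucleus_density_per_mm3, "nucleus_density_per_mm3")
  checkPositive(p$symbiont_radius_um, "symbiont_radius_um")
  checkPositive(p$cluster_sigma_um, "cluster_sigma_um")
  checkPositive(p$coupling_scale_um, "coupling_scale_um")
  if (p$edu_base_rate < 0 || p$edu_base_rate >= 1)
    stop("edu_base_rate must lie in [0, 1)")
  if (p$coupling_lambda < 0) stop("coupling_lambda must be >= 0")
  if (p$symbiont_count < 0) stop("symbiont_count must be >= 0")
  if (p$cluster_parents < 1) stop("cluster_parents must be >= 1")
  if (p$psf_sigma_um < 0 || p$noise_sd < 0)
    stop("psf_sigma_um and noise_sd must be >= 0")
  if (any(floor(p$extent_um / p$voxel_um) < 1))
    stop("voxel_um too coarse: fewer than one voxel on an axis")
  for (band in c("epidermis_z_um", "gastrodermis_z_um")) {
    b <- p[[band]]
    if (length(b) != 2 || b[2] <= 0) stop(band, " must be c(center, width) with width > 0")
    if (b[1] - b[2] / 2 < -1e-9 || b[1] + b[2] / 2 > p$extent_um[3] + 1e-9)
      stop(band, " extends beyond the z extent")
  }
  invisible(p)
}

bandRange <- function(b) c(b[1] - b[2] / 2, b[1] + b[2] / 2)

#' Generate a synthetic tentacle scene with ground truth
#'
#' Places host nuclei in the two depth bands by hard-core dart throwing at
#' the requested density, places symbiont cells by a Thomas-type
#' parent-offspring clustered process confined to the gastrodermal band
#' (centres kept at least one radius from every scene face), flags each
#' nucleus EdU+ with probability
#' `edu_base_rate * (1 + coupling_lambda * exp(-d / coupling_scale_um))`
#' (d = distance to the nearest symbiont centre, probability clipped to
#' \[0, 1\]), and optionally renders three channels as Gaussian-blurred
#' solid spheres: Hoechst (all nuclei), EdU (EdU+ nuclei) and chlorophyll
#' (symbiont spheres), each convolved with the PSF, plus additive
#' Gaussian noise.
#'
#' @param params a [sceneParams()] list.
#' @param render if FALSE, skip voxel rendering and return only the truth
#'   (fast path for point-pattern simulations).
#' @return list with elements `stack` ([VoxelStack-class] or NULL) and
#'   `truth` ([SceneTruth-class]).
#' @examples
#' sc <- generateTentacleScene(sceneParams(extent_um = c(40, 40, 20),
#'   symbiont_count = 10, seed = 7), render = FALSE)
#' sc$truth
#' @export
generateTentacleScene <- function(params = sceneParams(), render = TRUE) {
  validateSceneParams(params)
  withSeed(params$seed, {
    ex <- params$extent_um
    eb <- bandRange(params$epidermis_z_um)
    gb <- bandRange(params$gastrodermis_z_um)
    volE <- ex[1] * ex[2] * (eb[2] - eb[1])
    volG <- ex[1] * ex[2] * (gb[2] - gb[1])
    tissueVol <- volE + volG
    nTotal <- max(0L, as.integer(round(params$nucleus_density_per_mm3 * 1e-9 * tissueVol)))

    contiguous <- abs(eb[2] - gb[1]) < 1e-9 || abs(gb[2] - eb[1]) < 1e-9
    if (contiguous) {
      zlo <- min(eb[1], gb[1]); zhi <- max(eb[2], gb[2])
      nuclei <- cpp_hardcore_uniform(nTotal, c(0, 0, zlo), c(ex[1], ex[2], zhi),
                                     params$nucleus_min_sep_um, 200000L,
                                     "host nuclei (nucleus_density_per_mm3)")
    } else {
      nE <- as.integer(round(nTotal * volE / tissueVol))
      nG <- nTotal - nE
      nuclei <- rbind(
        cpp_hardcore_uniform(nE, c(0, 0, eb[1]), c(ex[1], ex[2], eb[2]),
                             params$nucleus_min_sep_um, 200000L,
                             "epidermal nuclei (nucleus_density_per_mm3)"),
        cpp_hardcore_uniform(nG, c(0, 0, gb[1]), c(ex[1], ex[2], gb[2]),
                             params$nucleus_min_sep_um, 200000L,
                             "gastrodermal nuclei (nucleus_density_per_mm3)"))
    }

    r <- params$symbiont_radius_um
    slo <- c(r, r, gb[1] + r)
    shi <- c(ex[1] - r, ex[2] - r, gb[2] - r)
    if (any(shi <= slo) && params$symbiont_count > 0)
      stop("gastrodermis too thin for symbiont_radius_um")
    if (params$symbiont_count > 0) {
      # an unlucky (strongly clumped) parent draw can jam the hard core;
      # resample the parent set a bounded number of times before giving up
      sym <- NULL
      lastErr <- NULL
      for (attempt in 1:20) {
        parents <- cbind(runif(params$cluster_parents, slo[1], shi[1]),
                         runif(params$cluster_parents, slo[2], shi[2]),
                         runif(params$cluster_parents, slo[3], shi[3]))
        sym <- tryCatch(
          cpp_thomas_hardcore(params$symbiont_count, parents,
                              params$cluster_sigma_um, slo, shi,
                              params$symbiont_min_sep_um, 50000L,
                              "symbionts (symbiont_count)"),
          error = function(e) { lastErr <<- e; NULL })
        if (!is.null(sym)) break
      }
      if (is.null(sym)) stop(lastErr)
    } else {
      sym <- matrix(numeric(0), 0, 3)
    }

    if (nTotal > 0) {
      if (params$coupling_lambda > 0 && nrow(sym) > 0) {
        d <- cpp_min_dist(nuclei, sym)
        pEdU <- params$edu_base_rate *
          (1 + params$coupling_lambda * exp(-d / params$coupling_scale_um))
      } else {
        pEdU <- rep(params$edu_base_rate, nTotal)
      }
      pEdU <- pmin(1, pmax(0, pEdU))
      flags <- runif(nTotal) < pEdU
    } else flags <- logical(0)

    truth <- new("SceneTruth", nucleiUm = nuclei, eduFlags = flags,
                 symbiontCentersUm = sym,
                 symbiontRadiusUm = rep(r, nrow(sym)),
                 tentacleVolumeUm3 = tissueVol, params = unclass(params))

    stack <- NULL
    if (render) {
      dims <- as.integer(round(ex / params$voxel_um))
      sp <- params$voxel_um
      rn <- params$nucleus_radius_um
      hoechst <- cpp_render_spheres(dims, sp, nuclei, rn)
      edu <- cpp_render_spheres(dims, sp, nuclei[flags, , drop = FALSE], rn)
      chl <- cpp_render_spheres(dims, sp, sym, r)
      if (params$psf_sigma_um > 0) {
        psf <- params$psf_sigma_um / sp
        hoechst <- cpp_gauss3d(hoechst, dims, psf)
        edu <- cpp_gauss3d(edu, dims, psf)
        chl <- cpp_gauss3d(chl, dims, psf)
      }
      nvox <- prod(dims)
      if (params$noise_sd > 0) {
        hoechst <- hoechst + rnorm(nvox, 0, params$noise_sd)
        edu <- edu + rnorm(nvox, 0, params$noise_sd)
        chl <- chl + rnorm(nvox, 0, params$noise_sd)
      }
      stack <- new("VoxelStack",
                   data = list(hoechst = array(hoechst, dims),
                               edu = array(edu, dims),
                               chlorophyll = array(chl, dims)),
                   channelNames = c("hoechst", "edu", "chlorophyll"),
                   voxelUm = sp)
    }
    list(stack = stack, truth = truth)
  })
}

#' Generate a neutral (uncoupled) scene
#'
#' Identical to [generateTentacleScene()] with `coupling_lambda` forced to
#' zero: EdU+ status is independent of symbiont proximity, the null under
#' which proliferating nuclei fall inside symbiont-containing regions in
#' proportion to those regions' volume. Used for type-I-error calibration
#' of the enrichment test.
#'
#' @inheritParams generateTentacleScene
#' @return as [generateTentacleScene()].
#' @export
generateNullScene <- function(params = sceneParams(), render = TRUE) {
  params$coupling_lambda <- 0
  generateTentacleScene(params, render = render)
}

#' Convert simulated ground truth to an ObjectSet
#'
#' Builds the per-class object tables directly from ground-truth points,
#' bypassing rendering and segmentation. Bounding boxes for symbionts are
#' the cubes circumscribing each sphere; nuclei get point boxes.
#'
#' @param truth a [SceneTruth-class].
#' @param group `"host_nuclei"`, `"edu_nuclei"` or `"symbionts"`.
#' @param tentacleId identifier.
#' @return an [ObjectSet-class] without voxel mask.
#' @export
truthObjectSet <- function(truth,
                           group = c("host_nuclei", "edu_nuclei", "symbionts"),
                           tentacleId = "truth") {
  group <- match.arg(group)
  if (group == "symbionts") {
    pts <- truth@symbiontCentersUm
    r <- if (length(truth@symbiontRadiusUm)) truth@symbiontRadiusUm else numeric(0)
    vol <- 4 / 3 * pi * r^3
  } else {
    pts <- truth@nucleiUm
    if (group == "edu_nuclei") pts <- pts[truth@eduFlags, , drop = FALSE]
    r <- rep(0, nrow(pts))
    vol <- rep(NA_real_, nrow(pts))
  }
  df <- data.frame(label = seq_len(nrow(pts)),
                   x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                   voxel_count = rep(NA_integer_, nrow(pts)),
                   volume_um3 = vol,
                   xmin = pts[, 1] - r, xmax = pts[, 1] + r,
                   ymin = pts[, 2] - r, ymax = pts[, 2] + r,
                   zmin = pts[, 3] - r, zmax = pts[, 3] + r)
  new("ObjectSet", group = group, objects = df, tentacleId = tentacleId,
      voxelUm = c(NA_real_, NA_real_, NA_real_),
      mask = array(integer(0), c(0, 0, 0)),
      intensity = array(numeric(0), c(0, 0, 0)))
}
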