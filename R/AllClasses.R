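#' Calibrated multichannel 3D image stack
#'
#' A lightweight container for a confocal z-stack: one 3D intensity array
#' per channel plus the physical voxel pitch. Voxel (i, j, k) (0-based) has
#' its centre at ((i + 1/2) dx, (j + 1/2) dy, (k + 1/2) dz) micrometres.
#'
#' @slot data named list of 3D numeric arrays, one per channel, all sharing
#'   the same dimensions.
#' @slot channelNames ordered channel labels, conventionally
#'   `c("hoechst", "edu", "chlorophyll")`.
#' @slot voxelUm numeric(3), voxel pitch (dx, dy, dz) in micrometres.
#'
#' @seealso [generateTentacleScene()], [readVoxelStack()], [detectObjects()]
#' @export
setClass("VoxelStack",
  representation(data = "list", channelNames = "character",
                 voxelUm = "numeric"))

setValidity("VoxelStack", function(object) {
  msg <- character()
  if (length(object@data) != length(object@channelNames))
    msg <- c(msg, "one array per channel name required")
  if (length(object@voxelUm) != 3 || any(!is.finite(object@voxelUm)) ||
      any(object@voxelUm <= 0))
    msg <- c(msg, "voxelUm must be three positive values")
  dims <- lapply(object@data, dim)
  if (length(dims) > 1 && !all(vapply(dims, identical, logical(1), dims[[1]])))
    msg <- c(msg, "all channels must share the same dimensions")
  if (length(dims) >= 1 && length(dims[[1]]) != 3)
    msg <- c(msg, "channel arrays must be 3D")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated tentacle scene
#'
#' Emitted by [generateTentacleScene()] alongside the rendered stack so that
#' segmentation and spatial statistics can be scored against known answers.
#'
#' @slot nucleiUm matrix (n x 3) of host-nucleus centres in micrometres.
#' @slot eduFlags logical per nucleus; TRUE = proliferating (EdU+).
#' @slot symbiontCentersUm matrix (m x 3) of symbiont centres.
#' @slot symbiontRadiusUm numeric, per-symbiont sphere radius.
#' @slot tentacleVolumeUm3 true tissue volume in cubic micrometres.
#' @slot params the generating parameter list (see [sceneParams()]).
#' @export
setClass("SceneTruth",
  representation(nucleiUm = "matrix", eduFlags = "logical",
                 symbiontCentersUm = "matrix", symbiontRadiusUm = "numeric",
                 tentacleVolumeUm3 = "numeric", params = "list"))

setValidity("SceneTruth", function(object) {
  msg <- character()
  if (nrow(object@nucleiUm) != length(object@eduFlags))
    msg <- c(msg, "one EdU flag per nucleus required")
  if (ncol(object@nucleiUm) != 3 || ncol(object@symbiontCentersUm) != 3)
    msg <- c(msg, "coordinates must have three columns")
  nr <- length(object@symbiontRadiusUm)
  if (nr != 1 && nr != nrow(object@symbiontCentersUm))
    msg <- c(msg, "symbiontRadiusUm must be scalar or per-symbiont")
  if (object@tentacleVolumeUm3 <= 0)
    msg <- c(msg, "tentacleVolumeUm3 must be positive")
  if (length(msg)) msg else TRUE
})

#' Segmented objects of one cell class
#'
#' One row per individuated 3D object with intensity-weighted centre of
#' mass (micrometres), voxel count, physical volume, and the axis-aligned
#' minimum bounding box in micrometres (outer voxel faces). Segmented sets
#' retain the labelled voxel mask so that watershed splitting and
#' centre-to-surface distances can operate on them; ground-truth-derived
#' sets (see [truthObjectSet()]) carry coordinates and boxes only.
#'
#' @slot group one of `"host_nuclei"`, `"edu_nuclei"`, `"symbionts"`.
#' @slot objects data.frame with columns label, x_um, y_um, z_um,
#'   voxel_count, volume_um3, xmin, xmax, ymin, ymax, zmin, zmax.
#' @slot tentacleId identifier used when aggregating across tentacles.
#' @slot voxelUm voxel pitch of the source stack (NA for truth-derived sets).
#' @slot mask labelled integer array (or empty) matching `objects$label`.
#' @slot intensity processed intensity array used for weighted centres
#'   (or empty).
#' @export
setClass("ObjectSet",
  representation(group = "character", objects = "data.frame",
                 tentacleId = "character", voxelUm = "numeric",
                 mask = "array", intensity = "array"))

setValidity("ObjectSet", function(object) {
  msg <- character()
  if (!object@group %in% c("host_nuclei", "edu_nuclei", "symbionts"))
    msg <- c(msg, "group must be host_nuclei, edu_nuclei or symbionts")
  need <- c("label", "x_um", "y_um", "z_um", "voxel_count", "volume_um3",
            "xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  if (!all(need %in% names(object@objects)))
    msg <- c(msg, paste("objects must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@objects$label))
    msg <- c(msg, "labels must be unique within a set")
  if (length(msg)) msg else TRUE
})

#' Dean-Jett-Fox cell-cycle fit
#'
#' Result of deconvolving a DNA-content histogram into G1, S and G2/M
#' components: Gaussian G1 and G2 peaks plus a broadened S compartment.
#'
#' @slot fractions named numeric(3): f_g1, f_s, f_g2m, summing to 1.
#' @slot muG1,muG2 fitted peak means (relative fluorescence units).
#' @slot cvG1,cvG2 fitted peak coefficients of variation.
#' @slot rmsResidual root-mean-square residual of the binned fit, as a
#'   fraction of the total event count.
#' @slot nEventsUsed events entering the histogram after the debris cut.
#' @slot binEdges histogram bin edges used.
#' @slot converged logical.
#' @slot notes character; flags such as a G2/G1 ratio at its bound.
#' @export
setClass("CellCycleFit",
  representation(fractions = "numeric", muG1 = "numeric", muG2 = "numeric",
                 cvG1 = "numeric", cvG2 = "numeric", rmsResidual = "numeric",
                 nEventsUsed = "numeric", binEdges = "numeric",
                 converged = "logical", notes = "character"))

setValidity("CellCycleFit", function(object) {
  msg <- character()
  f <- object@fractions
  if (length(f) != 3 || any(f < -1e-9) ||
      abs(sum(f) - 1) > 1e-6)
    msg <- c(msg, "fractions must be three non-negative values summing to 1")
  if (object@cvG1 <= 0 || object@cvG2 <= 0)
    msg <- c(msg, "CVs must be positive")
  if (length(msg)) msg else TRUE
})

#' Enrichment of proliferating nuclei inside symbiont-containing regions
#'
#' Per-tentacle observed vs expected EdU+ counts inside the union of
#' symbiont bounding boxes under the neutral-dispersal null (expected
#' proportional to the region's share of tentacle volume), with a pooled
#' chi-square over tentacles (one 2-cell table each) and a paired t-test of
#' observed against expected inside-counts.
#'
#' @slot perTentacle data.frame with columns tentacle_id, n_in, n_out,
#'   volume_fraction, expected_in, diff (= n_in - expected_in), chi_term.
#' @slot chiSquare,chiP,df pooled chi-square statistic, p-value and df
#'   (number of tentacles contributing a term).
#' @slot pairedT,pairedP paired t-test across tentacles.
#' @export
setClass("EnrichmentResult",
  representation(perTentacle = "data.frame", chiSquare = "numeric",
                 chiP = "numeric", df = "numeric", pairedT = "numeric",
                 pairedP = "numeric"))

# ---- show methods ---------------------------------------------------------

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@data[[1]])
  cat("VoxelStack:", paste(d, collapse = " x "), "voxels,",
      length(object@channelNames), "channel(s)\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  cat("  voxel pitch (um):", paste(object@voxelUm, collapse = " x "), "\n")
})

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth:", nrow(object@nucleiUm), "nuclei (",
      sum(object@eduFlags), "EdU+ ),",
      nrow(object@symbiontCentersUm), "symbionts\n")
  cat("  tissue volume:", format(object@tentacleVolumeUm3, big.mark = ","),
      "um^3\n")
})

setMethod("show", "ObjectSet", function(object) {
  cat("ObjectSet <", object@group, ">:", nrow(object@objects),
      "objects, tentacle", object@tentacleId, "\n")
})

setMethod("show", "CellCycleFit", function(object) {
  f <- object@fractions
  cat("CellCycleFit: G1", sprintf("%.1f%%", 100 * f[["f_g1"]]),
      " S", sprintf("%.1f%%", 100 * f[["f_s"]]),
      " G2/M", sprintf("%.1f%%", 100 * f[["f_g2m"]]), "\n")
  cat(sprintf("  G1 peak %.3g (CV %.3f), G2 peak %.3g (CV %.3f), G2/G1 %.3f\n",
              object@muG1, object@cvG1, object@muG2, object@cvG2,
              object@muG2 / object@muG1))
  cat(sprintf("  events used %d, rms residual %.4f%s\n",
              as.integer(object@nEventsUsed), object@rmsResidual,
              if (length(object@notes)) paste0("; ", paste(object@notes, collapse = "; ")) else ""))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult over", nrow(object@perTentacle), "tentacle(s)\n")
  cat(sprintf("  pooled chi-square = %.3f (df = %d, p = %.3g)\n",
              object@chiSquare, as.integer(object@df), object@chiP))
  cat(sprintf("  paired t = %.3f (p = %.3g)\n", object@pairedT, object@pairedP))
})

# ---- accessors ------------------------------------------------------------

#' Object centre-of-mass coordinates
#'
#' @param x an [ObjectSet-class].
#' @return matrix (n x 3) of centres in micrometres.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "ObjectSet", function(x) {
  as.matrix(x@objects[, c("x_um", "y_um", "z_um"), drop = FALSE])
})

#' @rdname coords
#' @export
setMethod("coords", "SceneTruth", function(x) x@nucleiUm)

#' Number of objects in a set
#' @param x an [ObjectSet-class].
#' @export
nObjects <- function(x) {
  stopifnot(is(x, "ObjectSet"))
  nrow(x@objects)
}

#' Accessors for simulated ground truth
#'
#' @param x a [SceneTruth-class].
#' @return `hostNuclei()` and `symbiontCenters()` return coordinate
#'   matrices; `eduFlags()` a logical vector; `trueVolume()` the tissue
#'   volume in cubic micrometres.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
hostNuclei <- function(x) { stopifnot(is(x, "SceneTruth")); x@nucleiUm }

#' @rdname truth-accessors
#' @export
eduFlags <- function(x) { stopifnot(is(x, "SceneTruth")); x@eduFlags }

#' @rdname truth-accessors
#' @export
symbiontCenters <- function(x) { stopifnot(is(x, "SceneTruth")); x@symbiontCentersUm }

#' @rdname truth-accessors
#' @export
trueVolume <- function(x) { stopifnot(is(x, "SceneTruth")); x@tentacleVolumeUm3 }

#' Phase fractions of a cell-cycle fit
#' @param x a [CellCycleFit-class].
#' @return named numeric(3): f_g1, f_s, f_g2m.
#' @export
cellCycleFractions <- function(x) {
  stopifnot(is(x, "CellCycleFit"))
  x@fractions
}

#' Channel array of a voxel stack
#' @param x a [VoxelStack-class].
#' @param channel channel name or index.
#' @return 3D numeric array.
#' @export
channelData <- function(x, channel) {
  stopifnot(is(x, "VoxelStack"))
  if (is.character(channel)) {
    i <- match(channel, x@channelNames)
    if (is.na(i)) stop("no channel named '", channel, "'")
  } else i <- channel
  x@data[[i]]
}

#' @rdname channelData
#' @export
channelNames <- function(x) {
  stopifnot(is(x, "VoxelStack"))
  x@channelNames
}

#' @rdname channelData
#' @export
voxelSize <- function(x) {
  stopifnot(is(x, "VoxelStack"))
  x@voxelUm
}

#' Per-tentacle enrichment table
#' @param x an [EnrichmentResult-class].
#' @export
perTentacle <- function(x) {
  stopifnot(is(x, "EnrichmentResult"))
  x@perTentacle
}
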