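#' Detection parameters for 3D object segmentation
#'
#' Controls the detection pipeline: optional Gaussian smoothing, rolling
#' background subtraction (separable grayscale box opening of the stated
#' half-width), thresholding, 26-connected component labelling, a minimum
#' object size, and the distance-transform watershed used by
#' [splitClusters()].
#'
#' @param gaussianSigmaUm smoothing sigma in micrometres (0 = none).
#' @param backgroundRadiusUm background-opening half-width in micrometres
#'   (0 = none; default 10).
#' @param thresholdMethod `"otsu"` (default, reproducible) or `"fixed"`.
#' @param thresholdValue threshold for `"fixed"`.
#' @param minSizeVoxels discard components smaller than this; default is
#'   the voxel volume of a 2-um-radius sphere, computed per stack.
#' @param watershedRounds number of sequential watershed passes (default 2).
#' @param watershedHUm h-maxima suppression depth of the Euclidean distance
#'   transform, in micrometres.
#' @return list of class `"DetectParams"`.
#' @export
detectParams <- function(gaussianSigmaUm = 0, backgroundRadiusUm = 10,
                         thresholdMethod = c("otsu", "fixed"),
                         thresholdValue = NULL, minSizeVoxels = NULL,
                         watershedRounds = 2L, watershedHUm = 1) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (gaussianSigmaUm < 0 || backgroundRadiusUm < 0)
    stop("sigma and background radius must be >= 0")
  if (thresholdMethod == "fixed" && is.null(thresholdValue))
    stop("fixed thresholding needs thresholdValue")
  if (!is.null(minSizeVoxels) && minSizeVoxels < 1)
    stop("minSizeVoxels must be >= 1")
  if (watershedRounds < 0) stop("watershedRounds must be >= 0")
  if (watershedHUm <= 0) stop("watershedHUm must be > 0")
  structure(list(gaussianSigmaUm = gaussianSigmaUm,
                 backgroundRadiusUm = backgroundRadiusUm,
                 thresholdMethod = thresholdMethod,
                 thresholdValue = thresholdValue,
                 minSizeVoxels = minSizeVoxels,
                 watershedRounds = as.integer(watershedRounds),
                 watershedHUm = watershedHUm),
            class = "DetectParams")
}

defaultMinSize <- function(voxelUm) {
  max(1L, as.integer(round(4 / 3 * pi * 2^3 / prod(voxelUm))))
}

# shared: label a processed channel and assemble the object table
buildObjectSet <- function(labels, intensity, dims, voxelUm, group,
                           tentacleId, minSize) {
  nlab <- max(labels, 0L)
  keepMask <- labels
  if (nlab > 0) {
    st <- cpp_com_stats(labels, intensity, dims, voxelUm, nlab)
    keep <- which(st[, 1] >= minSize)
    remap <- integer(nlab)
    remap[keep] <- seq_along(keep)
    keepMask <- integer(length(labels))
    pos <- labels > 0L
    keepMask[pos] <- remap[labels[pos]]
    st <- st[keep, , drop = FALSE]
  } else {
    st <- matrix(numeric(0), 0, 11)
    keep <- integer(0)
  }
  vv <- prod(voxelUm)
  w <- pmax(st[, 2], .Machine$double.eps)
  df <- data.frame(
    label = seq_along(keep),
    x_um = st[, 3] / w, y_um = st[, 4] / w, z_um = st[, 5] / w,
    voxel_count = as.integer(st[, 1]),
    volume_um3 = st[, 1] * vv,
    xmin = (st[, 6] - 1) * voxelUm[1], xmax = st[, 7] * voxelUm[1],
    ymin = (st[, 8] - 1) * voxelUm[2], ymax = st[, 9] * voxelUm[2],
    zmin = (st[, 10] - 1) * voxelUm[3], zmax = st[, 11] * voxelUm[3])
  new("ObjectSet", group = group, objects = df, tentacleId = tentacleId,
      voxelUm = voxelUm,
      mask = array(as.integer(keepMask), dims),
      intensity = array(intensity, dims))
}

#' Detect objects in one channel of a 3D stack
#'
#' Pipeline: optional Gaussian smoothing, background subtraction,
#' thresholding, 3D connected components (26-connectivity), size filter,
#' and per-object intensity-weighted centres of mass in physical
#' micrometres. An empty result is returned as an empty set, not an error;
#' Otsu thresholding of a constant channel is an error.
#'
#' @param stack a [VoxelStack-class].
#' @param channel channel name or index.
#' @param params a [detectParams()] list.
#' @param group object class label for the resulting set.
#' @param tentacleId identifier carried through downstream tables.
#' @return an [ObjectSet-class] (with labelled mask retained).
#' @seealso [splitClusters()] to separate touching cells.
#' @export
detectObjects <- function(stack, channel, params = detectParams(),
                          group = c("host_nuclei", "edu_nuclei", "symbionts"),
                          tentacleId = "t1") {
  group <- match.arg(group)
  img <- channelData(stack, channel)
  dims <- dim(img)
  sp <- stack@voxelUm
  proc <- as.numeric(img)
  if (params$gaussianSigmaUm > 0)
    proc <- cpp_gauss3d(proc, dims, params$gaussianSigmaUm / sp)
  if (params$backgroundRadiusUm > 0) {
    bg <- cpp_boxopen(proc, dims, as.integer(round(params$backgroundRadiusUm / sp)))
    proc <- pmax(proc - bg, 0)
  }
  thr <- if (params$thresholdMethod == "otsu") otsuThreshold(proc)
         else params$thresholdValue
  mask <- proc > thr
  if (!any(mask)) {
    return(buildObjectSet(integer(length(proc)), proc, dims, sp, group,
                          tentacleId, 1L))
  }
  labels <- cpp_label3d(mask, dims)
  minSize <- if (is.null(params$minSizeVoxels)) defaultMinSize(sp)
             else params$minSizeVoxels
  buildObjectSet(labels, proc, dims, sp, group, tentacleId, minSize)
}

#' Split touching cells with a distance-transform watershed
#'
#' Applies a marker-based 3D watershed to the labelled mask of a segmented
#' [ObjectSet-class]: seeds are h-suppressed local maxima of the Euclidean
#' distance transform (computed in physical micrometres on the anisotropic
#' grid), flooding is confined within each original object so that
#' splitting can never merge objects, and the pass is repeated
#' `watershedRounds` times. Objects without an interior maximum are kept
#' intact. Centres of mass are recomputed after relabelling.
#'
#' @param x a segmented [ObjectSet-class] (must carry its mask).
#' @param params a [detectParams()] list; `watershedRounds` and
#'   `watershedHUm` are used.
#' @return a relabelled [ObjectSet-class]; object count never decreases.
#' @export
splitClusters <- function(x, params = detectParams()) {
  stopifnot(is(x, "ObjectSet"))
  if (length(x@mask) == 0)
    stop("ObjectSet has no voxel mask; splitClusters needs a segmented set")
  if (params$watershedRounds < 0) stop("watershedRounds must be >= 0")
  dims <- dim(x@mask)
  sp <- x@voxelUm
  labels <- as.integer(x@mask)
  if (params$watershedRounds > 0 && max(labels) > 0) {
    mask <- labels > 0L
    edt <- cpp_edt3d(mask, dims, sp)
    for (round in seq_len(params$watershedRounds)) {
      marker <- pmax(edt - params$watershedHUm, 0)
      marker[!mask] <- 0
      rec <- cpp_grayrec(marker, edt, dims)
      seeds <- cpp_regmax_markers(rec, mask, dims)
      seeds <- cpp_ensure_markers(seeds, labels, edt)
      labels <- cpp_watershed(edt, seeds, labels, dims)
      # relabel sequentially
      u <- sort(unique(labels[labels > 0L]))
      remap <- integer(max(u))
      remap[u] <- seq_along(u)
      newlab <- integer(length(labels))
      pos <- labels > 0L
      newlab[pos] <- remap[labels[pos]]
      labels <- newlab
    }
  }
  buildObjectSet(labels, as.numeric(x@intensity), dims, sp, x@group,
                 x@tentacleId, 1L)
}

#' Distances from an object's centre of mass to its surface
#'
#' Surface voxels are foreground voxels of the object with at least one
#' background 6-neighbour (or lying on the stack border). Distances are
#' measured in micrometres from the object's intensity-weighted centre of
#' mass to each surface voxel centre.
#'
#' @param x a segmented [ObjectSet-class].
#' @param label object label; default 1.
#' @return list with `mean`, `median`, `quantiles` (5, 25, 75, 95 percent)
#'   and the full `distances` vector.
#' @export
centerToSurfaceDistances <- function(x, label = 1L) {
  stopifnot(is(x, "ObjectSet"))
  if (length(x@mask) == 0) stop("ObjectSet has no voxel mask")
  sel <- x@mask == label
  if (!any(sel)) stop("object ", label, " is empty")
  dims <- dim(x@mask)
  idx <- which(sel, arr.ind = TRUE)
  inObj <- function(i, j, k) {
    ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] & k >= 1 & k <= dims[3]
    out <- logical(length(i))
    out[ok] <- x@mask[cbind(i[ok], j[ok], k[ok])] == label
    out
  }
  surf <- !(inObj(idx[, 1] - 1, idx[, 2], idx[, 3]) &
            inObj(idx[, 1] + 1, idx[, 2], idx[, 3]) &
            inObj(idx[, 1], idx[, 2] - 1, idx[, 3]) &
            inObj(idx[, 1], idx[, 2] + 1, idx[, 3]) &
            inObj(idx[, 1], idx[, 2], idx[, 3] - 1) &
            inObj(idx[, 1], idx[, 2], idx[, 3] + 1))
  sv <- idx[surf, , drop = FALSE]
  sp <- x@voxelUm
  row <- x@objects[x@objects$label == label, ]
  com <- c(row$x_um, row$y_um, row$z_um)
  pts <- sweep(sv - 0.5, 2, sp, `*`)
  d <- sqrt(rowSums(sweep(pts, 2, com)^2))
  list(mean = mean(d), median = median(d),
       quantiles = quantile(d, c(0.05, 0.25, 0.75, 0.95)),
       distances = d)
}

#' Match detected objects against ground-truth points
#'
#' Greedy one-to-one matching by ascending distance within a matching
#' radius; reports recall (matched truth / truth) and precision
#' (matched detections / detections).
#'
#' @param detected coordinates ([ObjectSet-class] or matrix).
#' @param truth coordinates ([ObjectSet-class] or matrix).
#' @param radiusUm maximum centre-to-centre matching distance
#'   (conventionally one cell radius).
#' @return list with `recall`, `precision`, `nMatched`, `nDetected`,
#'   `nTruth`.
#' @export
matchObjects <- function(detected, truth, radiusUm) {
  det <- asCoords(detected)
  tru <- asCoords(truth)
  if (nrow(det) == 0 || nrow(tru) == 0)
    return(list(recall = 0, precision = 0, nMatched = 0L,
                nDetected = nrow(det), nTruth = nrow(tru)))
  d2 <- outer(rowSums(det^2), rep(1, nrow(tru))) +
        outer(rep(1, nrow(det)), rowSums(tru^2)) - 2 * det %*% t(tru)
  d2[d2 < 0] <- 0
  cand <- which(d2 <= radiusUm^2, arr.ind = TRUE)
  ord <- order(d2[cand])
  usedD <- logical(nrow(det)); usedT <- logical(nrow(tru))
  nm <- 0L
  for (i in ord) {
    a <- cand[i, 1]; b <- cand[i, 2]
    if (!usedD[a] && !usedT[b]) { usedD[a] <- TRUE; usedT[b] <- TRUE; nm <- nm + 1L }
  }
  list(recall = nm / nrow(tru), precision = nm / nrow(det),
       nMatched = nm, nDetected = nrow(det), nTruth = nrow(tru))
}
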