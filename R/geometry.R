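#' Axis-aligned minimum bounding boxes of segmented objects
#'
#' For segmented sets the box spans the outer voxel faces of each object;
#' for truth-derived sets it is the cube circumscribing each sphere.
#' Membership downstream treats intervals as closed, so a point exactly on
#' a face counts as inside.
#'
#' @param x an [ObjectSet-class].
#' @return data.frame with columns label, xmin, xmax, ymin, ymax, zmin,
#'   zmax (micrometres).
#' @export
boundingBoxes <- function(x) {
  stopifnot(is(x, "ObjectSet"))
  x@objects[, c("label", "xmin", "xmax", "ymin", "ymax", "zmin", "zmax")]
}

#' Volume of a union of axis-aligned boxes
#'
#' Exact union volume by a coordinate-compressed sweep (x slabs, then y
#' slabs, then 1D interval union along z); overlapping regions are counted
#' once, matching the overlap-subtracted symbiont-region volume used for
#' density estimates.
#'
#' @param boxes data.frame or 6-column matrix (xmin, xmax, ymin, ymax,
#'   zmin, zmax).
#' @return the union volume; 0 for an empty set.
#' @examples
#' unionVolume(rbind(c(0, 1, 0, 1, 0, 1), c(2, 3, 0, 1, 0, 1)))  # 2
#' @export
unionVolume <- function(boxes) {
  m <- asBoxMatrix(boxes)
  cpp_union_volume(m)
}

#' Tentacle tissue volume
#'
#' Default (`"hull"`) mode: volume of the 3D convex hull of host-nucleus
#' centres, dilated outward by one mean cell radius via the Steiner
#' formula for convex bodies
#' `V(r) = V + A r + (sum of edge_length x exterior_angle) r^2 / 2 +
#' 4/3 pi r^3`. When `dilationUm` is NULL the dilation radius is half the
#' equivalent-sphere cell diameter estimated from the undilated hull.
#' `"mask"` mode: thresholded-tissue volume of the Hoechst channel.
#'
#' @param nuclei host-nucleus coordinates ([ObjectSet-class] or matrix);
#'   at least 4 non-coplanar points required in hull mode.
#' @param mode `"hull"` or `"mask"`.
#' @param dilationUm outward dilation radius (micrometres); NULL =
#'   estimate from cell density, 0 = bare hull.
#' @param stack [VoxelStack-class]; required for `"mask"` mode.
#' @param channel channel used by `"mask"` mode.
#' @return list with `volume_um3`, `mode`, `dilation_um`.
#' @examples
#' corners <- as.matrix(expand.grid(c(0, 100), c(0, 100), c(0, 100)))
#' tentacleVolume(corners, dilationUm = 0)$volume_um3  # 1e6
#' @export
tentacleVolume <- function(nuclei, mode = c("hull", "mask"),
                           dilationUm = NULL, stack = NULL,
                           channel = "hoechst") {
  mode <- match.arg(mode)
  if (mode == "mask") {
    if (is.null(stack)) stop("mask mode needs the voxel stack")
    img <- channelData(stack, channel)
    thr <- otsuThreshold(as.numeric(img))
    return(list(volume_um3 = sum(img > thr) * prod(stack@voxelUm),
                mode = "mask", dilation_um = 0))
  }
  pts <- asCoords(nuclei)
  if (nrow(pts) < 4)
    stop("hull mode needs at least 4 non-coplanar nuclei")
  h <- cpp_convhull3(pts)
  if (is.null(dilationUm)) {
    d <- perCellDiameter(h$volume, nrow(pts))
    dilationUm <- d / 2
  }
  r <- dilationUm
  vol <- h$volume + h$area * r + h$edge_term * r^2 / 2 + 4 / 3 * pi * r^3
  list(volume_um3 = vol, mode = "hull", dilation_um = r)
}
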