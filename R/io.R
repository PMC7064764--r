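#' Write / read a voxel stack as multi-page TIFF with a JSON sidecar
#'
#' Channels are written as consecutive 32-bit float pages (all z slices of
#' channel 1, then channel 2, ...). Voxel size and channel order are
#' recorded in a `<path>.json` sidecar, which `readVoxelStack()` uses to
#' reassemble the stack; both can be overridden on read.
#'
#' @param stack a [VoxelStack-class].
#' @param path output TIFF path.
#' @return `writeVoxelStack()` returns the path invisibly;
#'   `readVoxelStack()` returns a [VoxelStack-class].
#' @export
writeVoxelStack <- function(stack, path) {
  stopifnot(is(stack, "VoxelStack"))
  pages <- list()
  for (ch in stack@channelNames) {
    a <- channelData(stack, ch)
    rng <- range(a)
    # float TIFF expects [0, 1]; store an affine normalisation in the sidecar
    scale <- if (diff(rng) > 0) diff(rng) else 1
    for (k in seq_len(dim(a)[3]))
      pages[[length(pages) + 1L]] <- (a[, , k] - rng[1]) / scale
  }
  meta <- list(channel_names = stack@channelNames,
               dims = dim(stack@data[[1]]), voxel_um = stack@voxelUm,
               ranges = lapply(stack@data, range))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVoxelStack
#' @param path TIFF path (sidecar `<path>.json` expected alongside unless
#'   overridden).
#' @param voxelUm optional voxel-size override `c(dx, dy, dz)`.
#' @param channelNames optional channel-name override.
#' @export
readVoxelStack <- function(path, voxelUm = NULL, channelNames = NULL) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else NULL
  if (is.null(meta) && (is.null(voxelUm) || is.null(channelNames)))
    stop("no sidecar metadata found; supply voxelUm and channelNames")
  pages <- tiff::readTIFF(path, all = TRUE)
  cn <- if (!is.null(channelNames)) channelNames else meta$channel_names
  vx <- if (!is.null(voxelUm)) as.numeric(voxelUm) else as.numeric(meta$voxel_um)
  nz <- length(pages) / length(cn)
  if (nz != round(nz)) stop("page count is not a multiple of channel count")
  dims <- c(dim(pages[[1]]), nz)
  data <- list()
  for (i in seq_along(cn)) {
    a <- array(0, dims)
    for (k in seq_len(nz)) a[, , k] <- pages[[(i - 1) * nz + k]]
    if (!is.null(meta$ranges)) {
      rng <- as.numeric(meta$ranges[[i]])
      scale <- if (diff(rng) > 0) diff(rng) else 1
      a <- a * scale + rng[1]
    }
    data[[cn[i]]] <- a
  }
  new("VoxelStack", data = data, channelNames = cn, voxelUm = vx)
}

#' Write / read scene ground truth as CSV
#'
#' One row per object (`class` in host_nucleus / symbiont; EdU status as a
#' flag), coordinates in micrometres, plus a JSON sidecar holding the
#' generating parameters and the true tissue volume.
#'
#' @param truth a [SceneTruth-class].
#' @param path output CSV path.
#' @export
writeSceneTruth <- function(truth, path) {
  stopifnot(is(truth, "SceneTruth"))
  n <- nrow(truth@nucleiUm)
  m <- nrow(truth@symbiontCentersUm)
  df <- data.frame(
    class = c(rep("host_nucleus", n), rep("symbiont", m)),
    x_um = c(truth@nucleiUm[, 1], truth@symbiontCentersUm[, 1]),
    y_um = c(truth@nucleiUm[, 2], truth@symbiontCentersUm[, 2]),
    z_um = c(truth@nucleiUm[, 3], truth@symbiontCentersUm[, 3]),
    edu_flag = c(truth@eduFlags, rep(NA, m)),
    radius_um = c(rep(NA_real_, n), truth@symbiontRadiusUm))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(params = truth@params, tentacle_volume_um3 = truth@tentacleVolumeUm3),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSceneTruth
#' @export
readSceneTruth <- function(path) {
  df <- read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(params = list(), tentacle_volume_um3 = NA_real_)
  nuc <- df[df$class == "host_nucleus", ]
  sym <- df[df$class == "symbiont", ]
  new("SceneTruth",
      nucleiUm = as.matrix(nuc[, c("x_um", "y_um", "z_um")]),
      eduFlags = as.logical(nuc$edu_flag),
      symbiontCentersUm = as.matrix(sym[, c("x_um", "y_um", "z_um")]),
      symbiontRadiusUm = as.numeric(sym$radius_um),
      tentacleVolumeUm3 = as.numeric(meta$tentacle_volume_um3),
      params = as.list(meta$params))
}

#' Write / read flow-cytometry event tables as CSV
#'
#' Uses the conventional cytometry headers `FSC-H`, `FSC-W`, `PE-A`
#' (mapped to the package's `fsc_h`, `fsc_w`, `pe_a`); extra columns such
#' as simulator truth labels are carried through.
#'
#' @param events event data.frame.
#' @param path CSV path.
#' @export
writeEventTable <- function(events, path) {
  out <- events
  names(out)[match(c("fsc_h", "fsc_w", "pe_a"), names(out))] <-
    c("FSC-H", "FSC-W", "PE-A")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("FSC-H", "FSC-W", "PE-A")
  if (!all(need %in% names(df)))
    stop("event CSV needs columns ", paste(need, collapse = ", "))
  names(df)[match(need, names(df))] <- c("fsc_h", "fsc_w", "pe_a")
  df
}

#' Write an object table as CSV
#'
#' Long-format table (tentacle_id, group, label, coordinates, volume and
#' bounding box) matching the per-object output of [detectObjects()].
#'
#' @param x an [ObjectSet-class] or list of them.
#' @param path CSV path.
#' @export
writeObjectTable <- function(x, path) {
  sets <- if (is(x, "ObjectSet")) list(x) else x
  rows <- lapply(sets, function(s)
    cbind(tentacle_id = s@tentacleId, group = s@group, s@objects))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
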