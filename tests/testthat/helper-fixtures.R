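# shared fixtures: small scenes and hand-built stacks

# a reduced tentacle scene for fast unit tests (same densities as default)
miniSceneParams <- function(seed = 1L, noise_sd = 0, ...) {
  sceneParams(extent_um = c(60, 60, 30), voxel_um = c(0.5, 0.5, 1),
              epidermis_z_um = c(center = 6, width = 12),
              gastrodermis_z_um = c(center = 21, width = 18),
              symbiont_count = 50, cluster_parents = 8,
              noise_sd = noise_sd, seed = seed, ...)
}

# wrap a plain array as a single-channel VoxelStack
stackFromArray <- function(a, voxelUm = c(0.5, 0.5, 1), name = "hoechst") {
  methods::new("VoxelStack", data = stats::setNames(list(a), name),
               channelNames = name, voxelUm = voxelUm)
}

# render spheres on a grid (via the package kernel) and wrap as a stack
sphereStack <- function(centers, radius, extent, voxelUm = c(0.5, 0.5, 1)) {
  dims <- as.integer(round(extent / voxelUm))
  img <- SymbioCycle:::cpp_render_spheres(dims, voxelUm,
                                          as.matrix(centers), radius)
  stackFromArray(array(img, dims), voxelUm)
}

# detect-and-split convenience used throughout recovery tests
segmentChannel <- function(stack, channel, group, params = detectParams()) {
  splitClusters(detectObjects(stack, channel, params, group), params)
}

gateLoose <- gateParams(minEventsAfterGate = 1000L)
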