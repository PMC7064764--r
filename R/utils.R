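# internal helpers

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Otsu threshold on a numeric vector/array; 256-bin between-class variance
otsuThreshold <- function(x, nbins = 256L) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    stop("no threshold separable: channel is constant")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                        all.inside = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  bc <- w1 * w2 * (m1 - m2)^2
  bc[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(bc)]
}

# coerce ObjectSet / SceneTruth / matrix / data.frame to an n x 3 matrix
asCoords <- function(x) {
  if (is(x, "ObjectSet")) return(coords(x))
  if (is(x, "SceneTruth")) return(x@nucleiUm)
  if (is.data.frame(x)) {
    cn <- intersect(c("x_um", "y_um", "z_um"), names(x))
    if (length(cn) == 3) return(as.matrix(x[, cn]))
    x <- as.matrix(x)
  }
  if (is.matrix(x) && ncol(x) == 3) {
    storage.mode(x) <- "double"
    return(x)
  }
  stop("cannot interpret input as 3D coordinates")
}

# coerce a box specification to the 6-column matrix used internally
asBoxMatrix <- function(boxes) {
  cols <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  if (is.data.frame(boxes)) {
    if (!all(cols %in% names(boxes)))
      stop("boxes need columns ", paste(cols, collapse = ", "))
    boxes <- as.matrix(boxes[, cols])
  }
  if (!is.matrix(boxes) || ncol(boxes) != 6)
    stop("boxes must be a 6-column matrix or data.frame")
  storage.mode(boxes) <- "double"
  if (nrow(boxes) && any(boxes[, c(1, 3, 5)] > boxes[, c(2, 4, 6)]))
    stop("box min must not exceed box max on any axis")
  boxes
}

checkPositive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(name, " must be positive and finite", call. = FALSE)
  invisible(x)
}
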