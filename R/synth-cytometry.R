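#' Parameters for a synthetic DNA-content histogram
#'
#' Forward model for propidium-iodide flow cytometry of a haploid algal
#' population: a Gaussian G1 peak, a Gaussian G2/M peak at `g2_ratio`
#' times the G1 mean (2x DNA content), an S phase uniform in DNA content
#' between the two peaks convolved with the G1 measurement spread, plus
#' optional G1-G1 doublets (at twice the G1 fluorescence, with enlarged
#' forward-scatter width) and sub-G1 debris.
#'
#' @param f_g1,f_s,f_g2m phase fractions of the singlet population; must
#'   sum to 1.
#' @param g1_mean G1 peak position (relative fluorescence units; the scale
#'   is arbitrary).
#' @param g1_cv coefficient of variation of the G1 peak, in (0, 0.5).
#' @param g2_ratio G2/G1 mean ratio (2.0 for full DNA duplication).
#' @param n_events number of events.
#' @param doublet_rate fraction of events that are G1-G1 doublets.
#' @param debris_rate fraction of events that are sub-G1 debris.
#' @param seed integer RNG seed.
#' @return a validated parameter list of class `"HistogramParams"`.
#' @seealso [generateCytometryEvents()], [fitDeanJettFox()]
#' @export
histogramParams <- function(f_g1 = 0.85, f_s = 0.10, f_g2m = 0.05,
                            g1_mean = 100, g1_cv = 0.05, g2_ratio = 2.0,
                            n_events = 20000L, doublet_rate = 0.02,
                            debris_rate = 0.02, seed = 1L) {
  p <- list(f_g1 = f_g1, f_s = f_s, f_g2m = f_g2m, g1_mean = g1_mean,
            g1_cv = g1_cv, g2_ratio = g2_ratio,
            n_events = as.integer(n_events), doublet_rate = doublet_rate,
            debris_rate = debris_rate, seed = as.integer(seed))
  validateHistogramParams(p)
  class(p) <- "HistogramParams"
  p
}

validateHistogramParams <- function(p) {
  f <- c(p$f_g1, p$f_s, p$f_g2m)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("phase fractions must be >= 0 and sum to 1")
  checkPositive(p$g1_mean, "g1_mean")
  if (p$g1_cv <= 0 || p$g1_cv >= 0.5) stop("g1_cv must lie in (0, 0.5)")
  if (p$g2_ratio < 1.5 || p$g2_ratio > 2.5)
    stop("g2_ratio must be near 2 (DNA duplication)")
  if (p$n_events <= 0) stop("n_events must be positive")
  if (p$doublet_rate < 0 || p$doublet_rate >= 1 ||
      p$debris_rate < 0 || p$debris_rate >= 1 ||
      p$doublet_rate + p$debris_rate >= 1)
    stop("doublet_rate and debris_rate must be fractions summing below 1")
  invisible(p)
}

#' Generate a synthetic flow-cytometry event table
#'
#' Draws `n_events` events from the forward model in [histogramParams()].
#' Singlets form one forward-scatter cluster (FSC-W near 1); doublets form
#' a high-width cluster so that a width gate can discriminate them.
#'
#' @param params a [histogramParams()] list.
#' @return data.frame with columns `fsc_h`, `fsc_w`, `pe_a` and the
#'   ground-truth column `true_class` (one of g1, s, g2m, doublet, debris).
#' @examples
#' ev <- generateCytometryEvents(histogramParams(n_events = 1000, seed = 3))
#' table(ev$true_class)
#' @export
generateCytometryEvents <- function(params = histogramParams()) {
  validateHistogramParams(params)
  withSeed(params$seed, {
    n <- params$n_events
    singlet <- 1 - params$doublet_rate - params$debris_rate
    probs <- c(g1 = params$f_g1 * singlet, s = params$f_s * singlet,
               g2m = params$f_g2m * singlet,
               doublet = params$doublet_rate, debris = params$debris_rate)
    cls <- sample(names(probs), n, replace = TRUE, prob = probs)
    mu <- params$g1_mean
    sdv <- params$g1_cv * mu
    mu2 <- params$g2_ratio * mu
    pe <- numeric(n)
    i <- cls == "g1"
    pe[i] <- rnorm(sum(i), mu, sdv)
    i <- cls == "s"
    pe[i] <- runif(sum(i), mu, mu2) + rnorm(sum(i), 0, sdv)
    i <- cls == "g2m"
    pe[i] <- rnorm(sum(i), mu2, params$g1_cv * mu2)
    i <- cls == "doublet"
    pe[i] <- rnorm(sum(i), mu, sdv) + rnorm(sum(i), mu, sdv)
    i <- cls == "debris"
    pe[i] <- mu * runif(sum(i), 0.05, 0.45)
    pe <- pmax(pe, 0)
    fsc_h <- rnorm(n, 1, 0.08)
    fsc_w <- ifelse(cls == "doublet", rnorm(n, 1.8, 0.10), rnorm(n, 1, 0.05))
    data.frame(fsc_h = fsc_h, fsc_w = fsc_w, pe_a = pe,
               true_class = cls, stringsAsFactors = FALSE)
  })
}
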