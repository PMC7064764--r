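#' Doublet-gate parameters
#'
#' The default gate is a linear boundary on forward-scatter width: events
#' with `fsc_w` above `q50 + k (q75 - q50)` are classified doublets. The
#' threshold is iterated to a fixed point (recomputed on the retained
#' events until the retained set stops changing), which makes the gate
#' idempotent.
#'
#' @param method gating method; `"width-threshold"` is implemented.
#' @param quantileK multiplier k on the upper quartile spread.
#' @param minEventsAfterGate warn (not error) if fewer events survive.
#' @param maxIter fixed-point iteration cap.
#' @return list of class `"GateParams"`.
#' @export
gateParams <- function(method = "width-threshold", quantileK = 6,
                       minEventsAfterGate = 20000L, maxIter = 20L) {
  method <- match.arg(method)
  if (quantileK <= 0) stop("quantileK must be positive")
  structure(list(method = method, quantileK = quantileK,
                 minEventsAfterGate = as.integer(minEventsAfterGate),
                 maxIter = as.integer(maxIter)),
            class = "GateParams")
}

#' Gate out doublets on forward-scatter width
#'
#' Removes events whose FSC width exceeds the iterated quantile threshold
#' (see [gateParams()]), the screening step that prevents G1-G1 doublets
#' (which carry 2x DNA) from inflating the apparent G2/M population.
#'
#' @param events data.frame with columns `fsc_h`, `fsc_w`, `pe_a`.
#' @param params a [gateParams()] list.
#' @return the retained events, with attributes `retained_fraction`,
#'   `threshold` and `gate` (the gate geometry description).
#' @export
gateSinglets <- function(events, params = gateParams()) {
  need <- c("fsc_h", "fsc_w", "pe_a")
  if (!all(need %in% names(events)))
    stop("events needs columns ", paste(need, collapse = ", "))
  w <- events$fsc_w
  keep <- rep(TRUE, length(w))
  thr <- Inf
  for (it in seq_len(params$maxIter)) {
    q <- quantile(w[keep], c(0.5, 0.75), names = FALSE)
    thrNew <- q[1] + params$quantileK * (q[2] - q[1])
    keepNew <- w <= thrNew
    if (identical(keepNew, keep)) { thr <- thrNew; break }
    keep <- keepNew
    thr <- thrNew
  }
  out <- events[keep, , drop = FALSE]
  if (nrow(out) < params$minEventsAfterGate)
    warning("only ", nrow(out), " events retained after gating (< ",
            params$minEventsAfterGate, ")")
  attr(out, "retained_fraction") <- nrow(out) / nrow(events)
  attr(out, "threshold") <- thr
  attr(out, "gate") <- sprintf("fsc_w <= %.4g (width-threshold, k = %g)",
                               thr, params$quantileK)
  out
}

# model bin probabilities: Gaussian G1 + Gaussian G2 + S phase uniform in
# DNA content between the peaks, convolved with the G1 measurement spread
djfModelCounts <- function(par, mids, bw, sGrid = NULL) {
  a1 <- par[1]; aS <- par[2]; a2 <- par[3]
  mu1 <- par[4]; ratio <- par[5]; cv1 <- par[6]; cv2 <- par[7]
  mu2 <- ratio * mu1
  s1 <- cv1 * mu1
  s2 <- cv2 * mu2
  g1 <- dnorm(mids, mu1, s1)
  g2 <- dnorm(mids, mu2, s2)
  if (is.null(sGrid)) {
    sComp <- (pnorm((mids - mu1) / s1) - pnorm((mids - mu2) / s1)) / (mu2 - mu1)
  } else {
    # quadratic synthesis-rate variant: density 1 + b1 t + b2 t^2 over t in [0,1]
    b1 <- par[8]; b2 <- par[9]
    tg <- sGrid
    q <- pmax(1 + b1 * (tg - 0.5) + b2 * (tg - 0.5)^2, 0)
    q <- q / sum(q)
    us <- mu1 + tg * (mu2 - mu1)
    sComp <- as.numeric(vapply(seq_along(tg), function(i)
      q[i] * dnorm(mids, us[i], s1), numeric(length(mids))) %*% rep(1, length(tg)))
  }
  bw * (a1 * g1 + aS * sComp + a2 * g2)
}

#' Dean-Jett-Fox deconvolution of a DNA-content histogram
#'
#' Fits a three-component mixture to the binned `pe_a` histogram: Gaussian
#' G1 and G2 peaks and an S-phase compartment that is uniform in DNA
#' content between the two peak means, convolved with the G1 measurement
#' Gaussian (a quadratic synthesis-rate variant is available). Parameters
#' (component areas, G1 mean, G2/G1 ratio, both CVs) are estimated by
#' bounded nonlinear least squares on the binned counts
#' (Levenberg-Marquardt). The G1 mean is initialised at the histogram
#' mode, the G2/G1 ratio at 2 and bounded to \[1.7, 2.3\]; bins below
#' `debrisCut` times the initial G1 mean are excluded as debris. The fit
#' is invariant to uniform rescaling of the fluorescence axis.
#'
#' @param events data.frame with a `pe_a` column, or a numeric vector of
#'   fluorescence values.
#' @param bins number of histogram bins (default 256).
#' @param debrisCut lower cutoff as a fraction of the initial G1 peak.
#' @param sModel `"uniform"` (default) or `"quadratic"` S compartment.
#' @return a [CellCycleFit-class]. Non-convergence raises an error of
#'   class `"djfConvergenceError"` carrying the best-so-far fit in its
#'   `fit` field; a fitted G2/G1 ratio at the \[1.7, 2.3\] bounds is
#'   flagged in `notes`.
#' @examples
#' ev <- generateCytometryEvents(histogramParams(n_events = 5000, seed = 2))
#' fitDeanJettFox(gateSinglets(ev, gateParams(minEventsAfterGate = 1000)))
#' @export
fitDeanJettFox <- function(events, bins = 256L, debrisCut = 0.5,
                           sModel = c("uniform", "quadratic")) {
  sModel <- match.arg(sModel)
  pe <- if (is.data.frame(events)) events$pe_a else as.numeric(events)
  pe <- pe[is.finite(pe) & pe > 0]
  if (length(pe) < 100) stop("too few positive events to fit (need >= 100)")
  # initial G1 position: mode of a coarse histogram
  coarse <- seq(0, quantile(pe, 0.995), length.out = 129L)
  hc <- tabulate(findInterval(pe, coarse, all.inside = TRUE), 128L)
  mu0 <- (coarse[which.max(hc)] + coarse[which.max(hc) + 1]) / 2
  hi <- 1.2 * 2.3 * mu0
  edges <- seq(0, hi, length.out = bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bw <- edges[2] - edges[1]
  use <- pe >= debrisCut * mu0 & pe <= hi
  counts <- tabulate(findInterval(pe[use], edges, all.inside = TRUE), bins)
  sel <- mids >= debrisCut * mu0
  n <- sum(counts[sel])
  sGrid <- if (sModel == "quadratic") seq(0.025, 0.975, length.out = 32) else NULL
  par0 <- c(a1 = 0.8 * n, aS = 0.1 * n, a2 = 0.1 * n,
            mu1 = mu0, ratio = 2, cv1 = 0.07, cv2 = 0.07)
  lower <- c(0, 0, 0, 0.6 * mu0, 1.7, 0.005, 0.005)
  upper <- c(Inf, Inf, Inf, 1.5 * mu0, 2.3, 0.49, 0.49)
  if (sModel == "quadratic") {
    par0 <- c(par0, b1 = 0, b2 = 0)
    lower <- c(lower, -2, -2)
    upper <- c(upper, 2, 2)
  }
  resid <- function(p) counts[sel] - djfModelCounts(p, mids[sel], bw, sGrid)
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  areas <- pmax(p[1:3], 0)
  fr <- areas / sum(areas)
  notes <- character()
  if (p[5] <= 1.7 + 1e-6 || p[5] >= 2.3 - 1e-6) {
    notes <- c(notes, sprintf("G2/G1 ratio at bound (%.3f)", p[5]))
    warning("fitted G2/G1 ratio sits at its [1.7, 2.3] bound")
  }
  result <- new("CellCycleFit",
                fractions = c(f_g1 = unname(fr[1]), f_s = unname(fr[2]),
                              f_g2m = unname(fr[3])),
                muG1 = unname(p[4]), muG2 = unname(p[4] * p[5]),
                cvG1 = unname(p[6]), cvG2 = unname(p[7]),
                rmsResidual = sqrt(mean(fit$fvec^2)) / max(n, 1),
                nEventsUsed = n, binEdges = edges,
                converged = fit$info %in% 1:4, notes = notes)
  if (!fit$info %in% 1:4) {
    cond <- structure(
      class = c("djfConvergenceError", "error", "condition"),
      list(message = paste0("Dean-Jett-Fox fit did not converge (",
                            fit$message, "); best-so-far fit attached"),
           call = sys.call(-1), fit = result))
    stop(cond)
  }
  result
}

#' Compare two populations by G1-peak DNA content
#'
#' The G1 peak position is proportional to genome size, so two samples
#' can be assigned to species by comparing fitted G1 means (optionally
#' corrected by an instrument normalization factor). Ratios within the
#' indifference band are reported as indistinguishable.
#'
#' @param fitA,fitB [CellCycleFit-class] objects (must have converged).
#' @param normalization factor multiplying `fitB`'s G1 mean before
#'   comparison (instrument cross-calibration).
#' @param indifference half-width of the relative indifference band
#'   (default 0.05, i.e. 5 percent).
#' @return list with `label` (`"a_larger"`, `"b_larger"` or
#'   `"indistinguishable"`) and `ratio` (muG1_a / muG1_b after
#'   normalization).
#' @export
classifySpecies <- function(fitA, fitB, normalization = 1,
                            indifference = 0.05) {
  stopifnot(is(fitA, "CellCycleFit"), is(fitB, "CellCycleFit"))
  if (!fitA@converged || !fitB@converged)
    stop("both fits must have converged")
  ratio <- fitA@muG1 / (fitB@muG1 * normalization)
  label <- if (abs(ratio - 1) <= indifference) "indistinguishable"
           else if (ratio > 1) "a_larger" else "b_larger"
  list(label = label, ratio = ratio)
}

#' Arcsine square-root transform for proportions
#'
#' Variance-stabilizing transform `asin(sqrt(p))` applied to phase
#' fractions before analysis of variance.
#'
#' @param p proportions in \[0, 1\].
#' @return transformed values in \[0, pi/2\].
#' @export
arcsineTransform <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Compare cell-cycle fractions across condition groups
#'
#' For each phase fraction, applies the arcsine square-root transform and
#' fits a two-way ANOVA over the two condition factors (with interaction
#' when every cell of the design is occupied, otherwise additive with a
#' warning), followed by Tukey HSD post hoc comparisons and plain Welch
#' t-tests between all pairs of factor-combination groups.
#'
#' @param fits data.frame with phase-fraction columns (default `f_g1`,
#'   `f_s`, `f_g2m`) and two factor columns.
#' @param factors names of the two factor columns (e.g. nutrition and
#'   source).
#' @param phases phase-fraction column names.
#' @return list of class `"CellCycleComparison"`, one element per phase
#'   with `anova` (data.frame), `tukey` and `pairwise_welch`.
#' @export
groupCompare <- function(fits, factors = c("nutrition", "source"),
                         phases = c("f_g1", "f_s", "f_g2m")) {
  if (!all(factors %in% names(fits)))
    stop("missing factor columns: ", paste(setdiff(factors, names(fits)), collapse = ", "))
  if (!all(phases %in% names(fits)))
    stop("missing phase columns: ", paste(setdiff(phases, names(fits)), collapse = ", "))
  A <- factor(fits[[factors[1]]])
  B <- factor(fits[[factors[2]]])
  fullDesign <- all(table(A, B) > 0)
  if (!fullDesign)
    warning("empty design cells: interaction term dropped")
  out <- lapply(phases, function(ph) {
    y <- arcsineTransform(fits[[ph]])
    d <- data.frame(y = y, A = A, B = B)
    form <- if (fullDesign) y ~ A * B else y ~ A + B
    fit <- aov(form, data = d)
    tuk <- TukeyHSD(fit)
    grp <- interaction(A, B, drop = TRUE)
    lv <- levels(grp)
    pw <- if (length(lv) >= 2) {
      combs <- utils::combn(lv, 2)
      do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
        ya <- y[grp == combs[1, i]]; yb <- y[grp == combs[2, i]]
        if (length(ya) < 2 || length(yb) < 2)
          return(data.frame(group1 = combs[1, i], group2 = combs[2, i],
                            t = NA_real_, p = NA_real_))
        tt <- tryCatch(t.test(ya, yb, var.equal = FALSE),
                       error = function(e) NULL)  # constant data
        if (is.null(tt))
          return(data.frame(group1 = combs[1, i], group2 = combs[2, i],
                            t = NA_real_, p = NA_real_))
        data.frame(group1 = combs[1, i], group2 = combs[2, i],
                   t = unname(tt$statistic), p = tt$p.value)
      }))
    } else NULL
    an <- as.data.frame(summary(fit)[[1]])
    names(an) <- c("df", "sum_sq", "mean_sq", "f_value", "p_value")
    list(anova = an, tukey = tuk, pairwise_welch = pw)
  })
  names(out) <- phases
  structure(out, class = "CellCycleComparison",
            factors = factors, interaction = fullDesign)
}
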