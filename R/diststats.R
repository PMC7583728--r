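# Cohort-level statistics: Gaussian decomposition of conductance
# histograms, substate AUC ratios, exponential fits to transition-kinetics
# distributions.

.histCounts <- function(v, binWidth, from = NULL) {
  lo <- if (is.null(from)) floor(min(v) / binWidth) * binWidth else from
  hi <- ceiling(max(v) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(mids = h$mids, counts = h$counts)
}

# deterministic initial means for a k-component fit: the k highest
# well-separated local maxima of the lightly smoothed histogram
.peakInits <- function(mids, counts, k, minSepBins = 3L) {
  cs <- as.numeric(stats::runmed(counts, 3L))
  ord <- order(-cs)
  picks <- integer(0)
  for (i in ord) {
    if (all(abs(i - picks) >= minSepBins)) picks <- c(picks, i)
    if (length(picks) == k) break
  }
  if (length(picks) < k)
    picks <- unique(c(picks, round(quantile(seq_along(mids),
                                            probs = seq(0.25, 0.75,
                                                        length.out = k)))))
  sort(mids[picks[seq_len(k)]])
}

#' Gaussian decomposition of a conductance histogram
#'
#' Fits one or two Gaussian components to the binned, max-normalized
#' conductance histogram by least squares (the approach used for unitary
#' conductance distributions in this field); `method = "mle"` instead fits
#' a Gaussian (mixture) to the raw conductances by maximum likelihood
#' (deterministic EM), which is statistically preferable and is
#' cross-checked against the histogram route in the test suite.
#'
#' @param conductances event conductances (pS); at least 30 values for one
#'   component, 60 for two.
#' @param nComponents 1 or 2.
#' @param binWidth histogram bin width (pS), default 10.
#' @param method `"histogram"` or `"mle"`.  Default (`NULL`): histogram
#'   least squares for a single component (stable for a dominant peak) and
#'   maximum likelihood for two components -- at a few hundred events the
#'   binned least-squares objective is nearly flat along a
#'   narrow-substate/wide-main ridge and routinely collapses the minor
#'   component, while the mixture MLE stays well-behaved.
#' @param truncateBelow optional left-truncation bound (pS) for the MLE:
#'   event sets from automated detection exclude conductances below the
#'   detection threshold, so fitting an untruncated model to them biases
#'   the low component upward.  When set, the likelihood is that of the
#'   mixture truncated to `(truncateBelow, Inf)`.  Ignored by the
#'   histogram method (whose shape fit is unaffected by truncation as long
#'   as the component peak lies above the bound).
#' @return data.frame with one row per component (sorted by mean):
#'   `label`, `mean`, `sd` (pS), `amplitude` (normalized peak height),
#'   `auc` (component area, normalized units).  Attributes: `fallback`
#'   (TRUE when a two-component fit failed and one component was fitted),
#'   `degenerate` (TRUE when the SD had to be floored at the bin width).
#' @examples
#' set.seed(1)
#' fitConductanceHistogram(rnorm(500, 217, 66))
#' @export
fitConductanceHistogram <- function(conductances, nComponents = 1,
                                    binWidth = 10, method = NULL,
                                    truncateBelow = NA_real_) {
  if (is.null(method))
    method <- if (nComponents >= 2) "mle" else "histogram"
  method <- match.arg(method, c("histogram", "mle"))
  g <- conductances[is.finite(conductances)]
  need <- if (nComponents >= 2) 60L else 30L
  if (length(g) < need)
    stop("need at least ", need, " events for a ", nComponents,
         "-component fit (", length(g), " given)")
  if (sd(g) == 0) {
    warning("all conductances identical; SD floored at the bin width")
    out <- data.frame(label = "c1", mean = g[1L], sd = binWidth,
                      amplitude = 1, auc = binWidth * sqrt(2 * pi))
    attr(out, "degenerate") <- TRUE
    attr(out, "fallback") <- FALSE
    return(out)
  }
  if (method == "mle")
    return(.gaussMixMLE(g, nComponents, binWidth, truncateBelow))
  h <- .histCounts(g, binWidth)
  ymax <- max(h$counts)
  y <- h$counts / ymax
  x <- h$mids
  m0 <- .peakInits(x, y, nComponents)
  a0 <- vapply(m0, function(m) max(y[which.min(abs(x - m))], 0.1), numeric(1))
  s0 <- rep(max(2.5 * binWidth, diff(range(g)) / (6 * nComponents)),
            nComponents)
  fit <- tryCatch({
    if (nComponents == 1) {
      minpack.lm::nlsLM(y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)),
        start = list(a1 = a0[1], m1 = m0[1], s1 = s0[1]),
        lower = c(0, min(x), binWidth / 4),
        upper = c(Inf, max(x), diff(range(x)) + binWidth),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
            a2 * exp(-(x - m2)^2 / (2 * s2^2)),
        start = list(a1 = a0[1], m1 = m0[1], s1 = s0[1],
                     a2 = a0[2], m2 = m0[2], s2 = s0[2]),
        lower = c(0, min(x), binWidth / 4, 0, min(x), binWidth / 4),
        upper = rep(c(Inf, max(x), diff(range(x)) + binWidth), 2),
        control = minpack.lm::nls.lm.control(maxiter = 400))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    if (nComponents > 1) {
      warning("two-component fit failed to converge; single-component fallback")
      out <- fitConductanceHistogram(g, 1, binWidth)
      attr(out, "fallback") <- TRUE
      return(out)
    }
    stop("Gaussian histogram fit failed to converge")
  }
  cf <- coef(fit)
  k <- nComponents
  out <- data.frame(
    label = paste0("c", seq_len(k)),
    mean = cf[paste0("m", seq_len(k))],
    sd = abs(cf[paste0("s", seq_len(k))]),
    amplitude = cf[paste0("a", seq_len(k))])
  out$auc <- out$amplitude * out$sd * sqrt(2 * pi)
  out <- out[order(out$mean), , drop = FALSE]
  out$label <- paste0("c", seq_len(k))
  rownames(out) <- NULL
  attr(out, "fallback") <- FALSE
  attr(out, "degenerate") <- FALSE
  attr(out, "normalization") <- ymax
  out
}

# deterministic EM for a 1- or 2-component Gaussian mixture on raw values;
# with a truncation bound the (truncated-model) likelihood is maximized
# directly, started from the EM solution
.gaussMixMLE <- function(g, k, binWidth, truncateBelow = NA_real_) {
  if (k == 1) {
    out <- data.frame(label = "c1", mean = mean(g), sd = sd(g),
                      amplitude = 1, auc = 1)
    if (is.finite(truncateBelow)) {
      nll <- function(p) {
        mu <- p[1]; s <- exp(p[2])
        -sum(dnorm(g, mu, s, log = TRUE)) +
          length(g) * pnorm(truncateBelow, mu, s, lower.tail = FALSE,
                            log.p = TRUE)
      }
      o <- stats::optim(c(mean(g), log(sd(g))), nll, method = "BFGS")
      out$mean <- o$par[1]; out$sd <- exp(o$par[2])
    }
    attr(out, "fallback") <- FALSE
    attr(out, "degenerate") <- FALSE
    return(out)
  } else {
    m <- .peakInits(.histCounts(g, binWidth)$mids,
                    .histCounts(g, binWidth)$counts, 2)
    s <- rep(sd(g) / 2, 2); w <- c(0.5, 0.5)
    for (it in 1:500) {
      d1 <- w[1] * dnorm(g, m[1], s[1]); d2 <- w[2] * dnorm(g, m[2], s[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      r <- d1 / tot
      w1 <- mean(r)
      m.new <- c(sum(r * g) / sum(r), sum((1 - r) * g) / sum(1 - r))
      s.new <- c(sqrt(sum(r * (g - m.new[1])^2) / sum(r)),
                 sqrt(sum((1 - r) * (g - m.new[2])^2) / sum(1 - r)))
      s.new <- pmax(s.new, binWidth / 4)
      done <- max(abs(c(m.new - m, s.new - s))) < 1e-8
      m <- m.new; s <- s.new; w <- c(w1, 1 - w1)
      if (done) break
    }
    if (is.finite(truncateBelow)) {
      rng <- diff(range(g))
      nll <- function(p) {
        w1 <- stats::plogis(p[1])
        m1 <- p[2]; s1 <- exp(p[3]); m2 <- p[4]; s2 <- exp(p[5])
        if (s1 > rng || s2 > rng) return(1e10)
        z <- w1 * pnorm(truncateBelow, m1, s1, lower.tail = FALSE) +
          (1 - w1) * pnorm(truncateBelow, m2, s2, lower.tail = FALSE)
        dens <- w1 * dnorm(g, m1, s1) + (1 - w1) * dnorm(g, m2, s2)
        -sum(log(pmax(dens, 1e-300))) + length(g) * log(max(z, 1e-300))
      }
      par0 <- function(w1, m1, s1, m2, s2)
        c(stats::qlogis(min(max(w1, 1e-3), 1 - 1e-3)), m1, log(s1), m2,
          log(s2))
      # starts: the untruncated EM solution and valley-split moments
      h <- .histCounts(g, binWidth)
      pk <- .peakInits(h$mids, h$counts, 2)
      iv <- which(h$mids > pk[1] & h$mids < pk[2])
      split <- if (length(iv)) h$mids[iv[which.min(h$counts[iv])]]
        else mean(pk)
      gl <- g[g < split]; gh <- g[g >= split]
      starts <- list(par0(w[1], m[1], s[1], m[2], s[2]))
      if (length(gl) >= 5 && length(gh) >= 5)
        starts <- c(starts, list(par0(length(gl) / length(g),
                                      mean(gl), max(sd(gl), binWidth / 2),
                                      mean(gh), max(sd(gh), binWidth / 2))))
      fits <- list()
      for (p0 in starts) for (meth in c("BFGS", "Nelder-Mead")) {
        o <- tryCatch(stats::optim(p0, nll, method = meth,
                                   control = list(maxit = 1000)),
                      error = function(e) NULL)
        if (!is.null(o)) fits[[length(fits) + 1L]] <- o
      }
      if (length(fits)) {
        o <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
        w <- c(stats::plogis(o$par[1]), 1 - stats::plogis(o$par[1]))
        m <- o$par[c(2, 4)]; s <- exp(o$par[c(3, 5)])
      }
    }
    out <- data.frame(label = c("c1", "c2"), mean = m, sd = s,
                      amplitude = w / (s * sqrt(2 * pi)), auc = w)
    out <- out[order(out$mean), , drop = FALSE]
    out$label <- paste0("c", 1:2)
    rownames(out) <- NULL
  }
  attr(out, "fallback") <- FALSE
  attr(out, "degenerate") <- FALSE
  out
}

#' Rescale a substate Gaussian template to another condition's histogram
#'
#' Amplitude-only least-squares rescaling of a fixed-shape (mean and SD
#' frozen) substate Gaussian to a reference condition's event histogram
#' within the one-SD conductance range of the template.  Used to estimate
#' the substate area in a condition whose own fit shows no separate
#' substate peak.
#'
#' @param template one-row data.frame (`mean`, `sd`) of the substate
#'   component.
#' @param conductances reference-condition conductances (pS).
#' @param binWidth bin width (pS).
#' @return One-row component data.frame with the rescaled `amplitude` and
#'   `auc` in the reference histogram's max-normalized units.
#' @export
scaleSubstateTemplate <- function(template, conductances, binWidth = 10) {
  h <- .histCounts(conductances, binWidth)
  y <- h$counts / max(h$counts)
  keep <- h$mids >= template$mean - template$sd &
    h$mids <= template$mean + template$sd
  if (!any(keep)) keep <- which.min(abs(h$mids - template$mean))
  shape <- exp(-(h$mids[keep] - template$mean)^2 / (2 * template$sd^2))
  amp <- max(0, sum(shape * y[keep]) / sum(shape^2))
  data.frame(label = "substate_template", mean = template$mean,
             sd = template$sd, amplitude = amp,
             auc = amp * template$sd * sqrt(2 * pi))
}

#' Substate share of gating and its fold-change between conditions
#'
#' The substate ratio of a condition is `AUC_sub / (AUC_full + AUC_sub)`,
#' the area of the subconductance component relative to all transitions.
#' Inputs may be component tables from [fitConductanceHistogram()] (the
#' component with the smallest mean is the substate, the largest the full
#' open state) or plain precomputed ratios.
#'
#' @param test component data.frame or a single numeric ratio for the test
#'   condition.
#' @param reference component data.frame or single numeric ratio for the
#'   reference; when a component table lacks a substate component, supply
#'   `referenceSub` (e.g. from [scaleSubstateTemplate()]); the result is
#'   then flagged.
#' @param referenceSub optional one-row component data.frame giving the
#'   scaled-template substate estimate of the reference condition.
#' @return list: `auc_sub`, `auc_full`, `ratio` (test condition),
#'   `ratio_reference`, `fold_vs_reference`, `flagged` (template-based or
#'   overflow).
#' @examples
#' substateRatio(0.347, 0.053)   # fold ~ 6.5
#' @export
substateRatio <- function(test, reference = NULL, referenceSub = NULL) {
  asRatio <- function(obj, subExtra = NULL) {
    if (is.numeric(obj) && length(obj) == 1L)
      return(list(ratio = obj, sub = NA_real_, full = NA_real_,
                  flagged = FALSE))
    stopifnot(is.data.frame(obj))
    flag <- FALSE
    if (nrow(obj) >= 2L) {
      sub <- obj$auc[which.min(obj$mean)]
      full <- obj$auc[which.max(obj$mean)]
    } else if (!is.null(subExtra)) {
      sub <- subExtra$auc
      full <- obj$auc[which.max(obj$mean)]
      flag <- TRUE
    } else stop("no substate component identified; supply referenceSub")
    list(ratio = sub / (sub + full), sub = sub, full = full, flagged = flag)
  }
  tt <- asRatio(test)
  out <- list(auc_sub = tt$sub, auc_full = tt$full, ratio = tt$ratio,
              ratio_reference = NA_real_, fold_vs_reference = NA_real_,
              flagged = tt$flagged)
  if (!is.null(reference)) {
    rr <- asRatio(reference, referenceSub)
    out$ratio_reference <- rr$ratio
    out$flagged <- out$flagged || rr$flagged
    if (rr$ratio <= 0) {
      warning("reference substate area is zero; fold overflows")
      out$fold_vs_reference <- Inf
      out$flagged <- TRUE
    } else out$fold_vs_reference <- tt$ratio / rr$ratio
  }
  out
}

#' Mono-/biexponential decomposition of transition time constants
#'
#' Fits both a monoexponential and a biexponential decay to the tc_trans
#' distribution and reports the model preferred by AIC (both candidates
#' are retained).  The default fits the raw values by maximum likelihood
#' (multi-start deterministic EM for the mixture); `method = "histogram"`
#' instead fits `A exp(-t/tau)` curves to the binned histogram by least
#' squares, matching how such distributions are usually displayed --
#' retained for presentation, but at a few hundred events its sparse-bin
#' objective is unstable (spurious biexponential wins, biased slow tau),
#' so it is not the default estimator.
#'
#' @param tc transition time constants (ms); at least 50 values.
#' @param binWidth histogram bin width (ms), default 2 (histogram method).
#' @param method `"mle"` (default) or `"histogram"`.
#' @return An object of class `ExponentialFit`: list with `n_components`
#'   (1 or 2), `taus` (ms, ascending), `weights` (mixture fractions by
#'   area, summing to 1), `mono_tau` (the monoexponential candidate's tau
#'   regardless of which model won), `model_score` (AIC of the winner),
#'   `fits` (both candidate fits), `flagged` (TRUE when a tau hit its
#'   bound), `method`.
#' @examples
#' set.seed(1)
#' fitTcDistribution(rexp(500, 1 / 5.2))
#' @export
fitTcDistribution <- function(tc, binWidth = 2, method = c("mle",
                                                           "histogram")) {
  method <- match.arg(method)
  v <- tc[is.finite(tc)]
  if (length(v) < 50) stop("need at least 50 tc values (", length(v), " given)")
  if (sd(v) == 0) stop("degenerate tc distribution: all values equal")
  if (method == "mle") return(.expMixMLE(v))
  h <- .histCounts(v, binWidth, from = 0)
  x <- h$mids; y <- h$counts
  nb <- length(y)
  mu <- mean(v)
  tauMax <- 20 * mu
  mono <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-x / tau),
      start = list(A = max(y), tau = mu),
      lower = c(0, binWidth / 20), upper = c(Inf, tauMax),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  bi <- tryCatch(
    minpack.lm::nlsLM(y ~ A1 * exp(-x / tau1) + A2 * exp(-x / tau2),
      start = list(A1 = max(y) * 0.7, tau1 = mu / 3,
                   A2 = max(y) * 0.3, tau2 = mu * 2),
      lower = c(0, binWidth / 20, 0, binWidth / 20),
      upper = c(Inf, tauMax, Inf, tauMax),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  aic <- function(f, k) if (is.null(f)) Inf else
    nb * log(stats::deviance(f) / nb) + 2 * (k + 1)
  aics <- c(mono = aic(mono, 2), bi = aic(bi, 4))
  if (all(!is.finite(aics))) stop("no exponential model converged")
  pick <- names(which.min(aics))
  flagged <- FALSE
  if (pick == "mono") {
    cf <- coef(mono)
    taus <- cf[["tau"]]; weights <- 1
    flagged <- taus >= 0.99 * tauMax || taus <= binWidth / 19
  } else {
    cf <- coef(bi)
    taus <- c(cf[["tau1"]], cf[["tau2"]])
    w <- c(cf[["A1"]], cf[["A2"]]) * taus
    ord <- order(taus)
    taus <- taus[ord]; w <- w[ord]
    weights <- w / sum(w)
    flagged <- any(taus >= 0.99 * tauMax) || any(taus <= binWidth / 19)
  }
  if (flagged) warning("an exponential time constant hit its fit bound")
  structure(list(n_components = if (pick == "mono") 1L else 2L,
                 taus = unname(taus), weights = unname(weights),
                 mono_tau = if (is.null(mono)) NA_real_ else
                   coef(mono)[["tau"]],
                 model_score = unname(aics[pick]),
                 all_scores = aics,
                 fits = list(mono = mono, bi = bi), flagged = flagged,
                 method = method), class = "ExponentialFit")
}

# maximum-likelihood exponential (mixture) fit: deterministic multi-start
# EM, best log-likelihood kept
.expMixEM <- function(v, t1, t2, w = 0.5) {
  for (it in 1:2000) {
    d1 <- w * stats::dexp(v, 1 / t1); d2 <- (1 - w) * stats::dexp(v, 1 / t2)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    w.new <- mean(r)
    t1.new <- sum(r * v) / sum(r); t2.new <- sum((1 - r) * v) / sum(1 - r)
    done <- max(abs(c(t1.new - t1, t2.new - t2, w.new - w))) < 1e-10
    t1 <- t1.new; t2 <- t2.new; w <- w.new
    if (done) break
  }
  list(t1 = t1, t2 = t2, w = w,
       ll = sum(log(w * stats::dexp(v, 1 / t1) +
                      (1 - w) * stats::dexp(v, 1 / t2))))
}

.expMixMLE <- function(v) {
  n <- length(v)
  ll1 <- sum(stats::dexp(v, 1 / mean(v), log = TRUE))
  m <- mean(v)
  starts <- list(c(m / 3, 2 * m), c(m / 5, m), c(m / 2, 4 * m))
  fits <- lapply(starts, function(s) .expMixEM(v, s[1], s[2]))
  fb <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  t1 <- fb$t1; t2 <- fb$t2; w <- fb$w
  aics <- c(mono = -2 * ll1 + 2, bi = -2 * fb$ll + 6)
  if (aics[["mono"]] <= aics[["bi"]]) {
    structure(list(n_components = 1L, taus = mean(v), weights = 1,
                   mono_tau = mean(v),
                   model_score = aics[["mono"]], all_scores = aics,
                   fits = list(), flagged = FALSE, method = "mle"),
              class = "ExponentialFit")
  } else {
    taus <- c(t1, t2); wts <- c(w, 1 - w)
    ord <- order(taus)
    structure(list(n_components = 2L, taus = unname(taus[ord]),
                   weights = unname(wts[ord]), mono_tau = mean(v),
                   model_score = aics[["bi"]],
                   all_scores = aics, fits = list(), flagged = FALSE,
                   method = "mle"), class = "ExponentialFit")
  }
}

# (the histogram route above is retained for figure-style fits; see the
# method argument documentation for why MLE is the default)

#' @export
print.ExponentialFit <- function(x, ...) {
  cat(sprintf("ExponentialFit (%s): %d component(s)\n", x$method,
              x$n_components))
  for (k in seq_along(x$taus))
    cat(sprintf("  tau%d = %.3f ms (weight %.3f)\n", k, x$taus[k],
                x$weights[k]))
  cat(sprintf("  AIC = %.2f%s\n", x$model_score,
              if (x$flagged) " [flagged: tau at bound]" else ""))
  invisible(x)
}

#' Compare transition kinetics between two conditions, per state class
#'
#' Summarizes tc_trans per conductance state class for two event cohorts
#' and tests each class with a two-sample Wilcoxon (Mann-Whitney) rank
#' test; classes with fewer than five events in either cohort get a
#' summary only.
#'
#' @param eventsA,eventsB event data.frames with `tc_trans_ms` and either
#'   a `state_class` or a `conductance_pS` column.
#' @param components classification components (used when `state_class` is
#'   absent).
#' @return data.frame, one row per state class: event counts, mean and
#'   median tc per cohort, `tc_ratio` (B/A, by mean), `p_value`.
#' @export
compareTcByState <- function(eventsA, eventsB,
                             components = defaultComponents()) {
  prep <- function(ev) {
    sc <- if ("state_class" %in% names(ev)) ev$state_class
      else classifyState(ev$conductance_pS, components)
    data.frame(tc = ev$tc_trans_ms, class = sc)[is.finite(ev$tc_trans_ms), ]
  }
  a <- prep(eventsA); b <- prep(eventsB)
  classes <- union(unique(a$class), unique(b$class))
  rows <- lapply(classes, function(cl) {
    ta <- a$tc[a$class == cl]; tb <- b$tc[b$class == cl]
    p <- if (length(ta) >= 5 && length(tb) >= 5)
      suppressWarnings(wilcox.test(ta, tb, exact = FALSE)$p.value)
      else NA_real_
    data.frame(state_class = cl, n_a = length(ta), n_b = length(tb),
               mean_tc_a = mean(ta), mean_tc_b = mean(tb),
               median_tc_a = median(ta), median_tc_b = median(tb),
               tc_ratio = mean(tb) / mean(ta), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
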