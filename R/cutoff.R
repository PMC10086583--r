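#' Two-component Gaussian mixture fit for bimodal scores
#'
#' Fits a two-component Gaussian mixture by expectation-maximisation.
#' Initialisation is deterministic (component means at the 25th and 75th
#' percentiles, common starting standard deviation, equal weights);
#' iteration stops when the log-likelihood improves by less than `tol`
#' or after `max_iter` iterations. Components are ordered by mean. A
#' component collapse (standard deviation below 1e-6) is reported as a
#' non-converged fit.
#'
#' @param values numeric vector (at least 10 finite values with nonzero
#'   variance).
#' @param seed integer; kept for interface stability (the fit itself is
#'   deterministic) and recorded in the result.
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance.
#' @return object of class `MixtureFit` with `means`, `sds`, `weights`,
#'   `loglik`, `converged`, `cutoff` (weighted-density crossing between
#'   the means) and `cutoff_fallback` flag.
#' @export
fit_two_component_mixture <- function(values, seed = 1L, max_iter = 500L,
                                      tol = 1e-8) {
  x <- values[is.finite(values)]
  if (length(x) < 10L) stop("need at least 10 finite values")
  if (stats::var(x) == 0) stop("degenerate fit: values have zero variance")
  mu <- as.numeric(stats::quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5) * stats::sd(x)
  sg <- rep(max(stats::sd(x) / 2, 1e-3), 2L)
  w <- c(0.5, 0.5)
  loglik <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    w <- c(mean(r), 1 - mean(r))
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sg <- sqrt(c(sum(r * (x - mu[1])^2) / sum(r),
                 sum((1 - r) * (x - mu[2])^2) / sum(1 - r)))
    if (any(!is.finite(sg)) || any(sg < 1e-6) ||
        any(!is.finite(mu)) || any(w < 1e-9)) {
      degenerate <- TRUE
      break
    }
    if (is.finite(loglik) && ll - loglik < tol) { converged <- TRUE; loglik <- ll; break }
    loglik <- ll
  }
  ord <- order(mu)
  fit <- structure(
    list(means = mu[ord], sds = sg[ord], weights = w[ord],
         loglik = loglik, converged = converged && !degenerate,
         n = length(x), seed = seed,
         cutoff = NA_real_, cutoff_fallback = FALSE,
         ci_low = NA_real_, ci_high = NA_real_),
    class = "MixtureFit")
  if (fit$converged) {
    co <- mixture_cutoff(fit)
    fit$cutoff <- as.numeric(co)
    fit$cutoff_fallback <- isTRUE(attr(co, "fallback"))
  }
  fit
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf(paste0("Two-component Gaussian mixture (n=%d, %s)\n",
                     "  means   %.3f / %.3f\n  sds     %.3f / %.3f\n",
                     "  weights %.3f / %.3f\n  cutoff  %.4f%s\n"),
              x$n, if (x$converged) "converged" else "NOT converged",
              x$means[1], x$means[2], x$sds[1], x$sds[2],
              x$weights[1], x$weights[2], x$cutoff,
              if (x$cutoff_fallback) " (midpoint fallback)" else ""))
  invisible(x)
}

#' Cut-off separating the two mixture peaks
#'
#' The cut-off is the point between the two component means where the
#' weighted component densities cross, i.e. where the posterior
#' probability of either component is 0.5. Found by bisection to 1e-6
#' absolute tolerance; if the weighted densities do not cross between
#' the means (extreme weight imbalance) the midpoint of the means is
#' returned with the `fallback` attribute set.
#'
#' @param fit a converged [fit_two_component_mixture()] result.
#' @return numeric cut-off (attribute `fallback` flags the midpoint
#'   fallback).
#' @export
mixture_cutoff <- function(fit) {
  if (!fit$converged) stop("mixture fit did not converge")
  m <- fit$means; s <- fit$sds; w <- fit$weights
  f <- function(x) log(w[1]) + stats::dnorm(x, m[1], s[1], log = TRUE) -
    log(w[2]) - stats::dnorm(x, m[2], s[2], log = TRUE)
  lo <- m[1]; hi <- m[2]
  if (!(f(lo) > 0 && f(hi) < 0)) {
    out <- (m[1] + m[2]) / 2
    attr(out, "fallback") <- TRUE
    return(out)
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "fallback") <- FALSE
  out
}

#' Monte-Carlo confidence interval for the mixture cut-off
#'
#' Parametric bootstrap: `n_boot` samples of the original size are drawn
#' from the fitted mixture, each is refitted, and the 2.5/97.5
#' percentiles of the resulting cut-offs form the interval.
#' Deterministic given `seed`. If more than 20% of replicates yield a
#' degenerate fit a warning is raised.
#'
#' @param values the original numeric sample.
#' @param n_boot number of bootstrap replicates (> 0).
#' @param seed integer seed.
#' @return named vector `c(low, high)`.
#' @export
bootstrap_cutoff_ci <- function(values, n_boot = 1000L, seed = 1L) {
  if (n_boot <= 0) stop("n_boot must be positive")
  base <- fit_two_component_mixture(values, seed = seed)
  if (!base$converged) stop("base mixture fit did not converge")
  n <- base$n
  set.seed(seed)
  cuts <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    comp <- sample.int(2L, n, replace = TRUE, prob = base$weights)
    xb <- stats::rnorm(n, base$means[comp], base$sds[comp])
    fb <- tryCatch(fit_two_component_mixture(xb, seed = seed),
                   error = function(e) NULL)
    if (!is.null(fb) && fb$converged) cuts[b] <- fb$cutoff
  }
  fail_rate <- mean(is.na(cuts))
  if (fail_rate > 0.2)
    warning(sprintf("degenerate-fit rate %.0f%% in bootstrap", 100 * fail_rate))
  ci <- stats::quantile(cuts, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(low = ci[1], high = ci[2])
}

#' Classify values against a cut-off
#'
#' Boundary inclusive: a value equal to the cut-off is "high"
#' (the HRD-score convention "higher or equal to").
#'
#' @param values numeric vector.
#' @param cutoff finite cut-off.
#' @return character vector of "high"/"low".
#' @export
classify_by_cutoff <- function(values, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  ifelse(values >= cutoff, "high", "low")
}

#' ROC curve and Youden-index optimal cut-point
#'
#' Candidate thresholds are the midpoints between adjacent distinct
#' sorted scores plus -Inf and +Inf; a sample is called positive when
#' its score is at or above the threshold. The optimal cut-point
#' maximises the Youden index J = sensitivity + specificity - 1, with
#' ties broken by higher sensitivity and then by the lower threshold.
#' AUC is the trapezoid integral of the ROC curve.
#'
#' @param labels binary labels (logical, 0/1, or two-level factor /
#'   character with the positive class being the higher level, e.g.
#'   "high" vs "low" sorts so that "low" < "high" is FALSE; pass
#'   logical/0-1 to be explicit).
#' @param scores numeric biomarker values.
#' @return object of class `ROCResult` with `thresholds`, `sensitivity`,
#'   `specificity`, `youden`, `optimal_cutpoint`, `optimal_j`, `auc`.
#' @export
roc_youden <- function(labels, scores) {
  if (is.character(labels)) labels <- labels == "high"
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores))
  ok <- !is.na(labels) & is.finite(scores)
  labels <- labels[ok]; scores <- scores[ok]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[sens[best] == max(sens[best])]
  if (length(best) > 1L) best <- best[which.min(thr[best])]
  # trapezoid AUC over (FPR, TPR), thresholds descending trace the curve
  fpr <- 1 - spec; tpr <- sens
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(o)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 youden = j, optimal_cutpoint = thr[best],
                 optimal_j = j[best], auc = auc),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f; Youden-optimal cutpoint %.4g (J = %.4f)\n",
              x$auc, x$optimal_cutpoint, x$optimal_j))
  invisible(x)
}
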