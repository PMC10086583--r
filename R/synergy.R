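#' Normalise viability readings to untreated controls
#'
#' Each reading is divided by the mean of the untreated control wells,
#' so the control mean maps to 1.
#'
#' @param raw numeric readings (e.g. luminescence).
#' @param untreated_controls control-well readings (at least one).
#' @return normalised viability.
#' @export
normalize_viability <- function(raw, untreated_controls) {
  if (!length(untreated_controls)) stop("need at least one control well")
  m <- mean(untreated_controls)
  if (!is.finite(m) || m <= 0) stop("non-positive control mean")
  raw / m
}

predict_4pl_pars <- function(x, bottom, top, ic50, hill) {
  r <- (x / ic50)^hill
  r[x == 0] <- if (hill > 0) 0 else Inf
  bottom + (top - bottom) / (1 + r)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`; with
#' `hill > 0` the curve decreases with dose (viability), with
#' `hill < 0` it increases (inhibition). The least-squares fit uses a
#' fixed multi-start grid (hill in {+-0.5, +-1, +-2}; ic50 at the dose
#' range extremes and geometric centre) with bounds
#' `bottom in [-0.2, 1]`, `top in [0.5, 1.5]`, so the fit is
#' deterministic given the data. If no start converges, or the
#' responses show no dose effect, the curve is flagged non-converged
#' and a monotone interpolating spline over log10 dose is kept as a
#' fallback for synergy use.
#'
#' @param doses strictly positive dose vector (at least 4 distinct).
#' @param responses normalised responses.
#' @param drug optional drug label.
#' @return object of class `DoseResponseCurve` (`bottom`, `top`,
#'   `ic50`, `hill`, `residual`, `converged`).
#' @export
fit_4pl <- function(doses, responses, drug = NA_character_) {
  stopifnot(length(doses) == length(responses))
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (length(unique(doses)) < 4L) stop("need at least 4 distinct doses")
  curve <- structure(list(drug = drug, doses = doses, responses = responses,
                          bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
                          hill = NA_real_, residual = NA_real_,
                          converged = FALSE, fallback = NULL),
                     class = "DoseResponseCurve")
  flat <- diff(range(responses)) < 1e-6
  best <- NULL
  if (!flat) {
    lo <- c(bottom = -0.2, top = 0.5, ic50 = min(doses) / 100, hill = -10)
    hi <- c(bottom = 1.0, top = 1.5, ic50 = max(doses) * 100, hill = 10)
    ic50_starts <- c(min(doses), exp(mean(log(range(doses)))), max(doses))
    for (h0 in c(-2, -1, -0.5, 0.5, 1, 2)) {
      for (c0 in ic50_starts) {
        fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
          responses ~ bottom + (top - bottom) / (1 + (doses / ic50)^hill),
          start = list(bottom = max(min(responses), -0.2),
                       top = min(max(max(responses), 0.5), 1.5),
                       ic50 = c0, hill = h0),
          lower = lo, upper = hi,
          control = minpack.lm::nls.lm.control(maxiter = 200))),
          error = function(e) NULL)
        if (is.null(fit)) next
        sse <- sum(stats::resid(fit)^2)
        if (is.null(best) || sse < best$sse)
          best <- list(pars = stats::coef(fit), sse = sse)
      }
    }
  }
  if (!is.null(best)) {
    p <- best$pars
    curve$bottom <- unname(p["bottom"]); curve$top <- unname(p["top"])
    curve$ic50 <- unname(p["ic50"]); curve$hill <- unname(p["hill"])
    curve$residual <- best$sse
    curve$converged <- TRUE
  } else {
    o <- order(doses)
    curve$fallback <- stats::splinefun(log10(doses[o]), responses[o],
                                       method = "monoH.FC")
  }
  curve
}

#' @rdname fit_4pl
#' @param curve a fitted `DoseResponseCurve`.
#' @param x doses at which to predict.
#' @export
predict_4pl <- function(curve, x) {
  if (curve$converged)
    predict_4pl_pars(x, curve$bottom, curve$top, curve$ic50, curve$hill)
  else {
    lo <- min(curve$doses); hi <- max(curve$doses)
    curve$fallback(log10(pmin(pmax(x, lo), hi)))
  }
}

#' @export
print.DoseResponseCurve <- function(x, ...) {
  if (x$converged)
    cat(sprintf("4PL fit%s: bottom %.3f, top %.3f, IC50 %.3g, hill %.3f (SSE %.2g)\n",
                if (is.na(x$drug)) "" else paste0(" [", x$drug, "]"),
                x$bottom, x$top, x$ic50, x$hill, x$residual))
  else cat("4PL fit: non-converged (monotone-spline fallback)\n")
  invisible(x)
}

#' Area under the dose-response curve
#'
#' Trapezoid integral of normalised viability over log10(dose), divided
#' by the log10 dose span: a dimensionless mean viability (1 for a flat
#' curve at full viability).
#'
#' @param doses strictly positive doses (at least 2), or a
#'   `DoseResponseCurve` (its fitted values at its doses are used).
#' @param viability responses matching `doses` (ignored when a curve is
#'   given).
#' @return numeric area.
#' @export
auc_dose_response <- function(doses, viability = NULL) {
  if (inherits(doses, "DoseResponseCurve")) {
    curve <- doses
    doses <- sort(unique(curve$doses))
    viability <- predict_4pl(curve, doses)
  }
  if (length(unique(doses)) < 2L) stop("need at least 2 distinct doses")
  o <- order(doses)
  lx <- log10(doses[o]); y <- viability[o]
  sum(diff(lx) * (y[-1] + y[-length(y)]) / 2) / (max(lx) - min(lx))
}

#' Construct a two-drug dose matrix
#'
#' `viability[i, j]` is the normalised viability at
#' `(d1[i], d2[j])`; both dose vectors must include 0, whose row and
#' column hold the monotherapy responses. The inhibition grid is
#' `1 - viability` clipped to [0, 1].
#'
#' @param d1,d2 dose vectors including 0, strictly increasing.
#' @param viability matrix of dim `length(d1) x length(d2)`.
#' @param drugs optional character pair of drug names.
#' @return object of class `DoseMatrix`.
#' @export
dose_matrix <- function(d1, d2, viability, drugs = c("drug1", "drug2")) {
  stopifnot(is.matrix(viability), nrow(viability) == length(d1),
            ncol(viability) == length(d2))
  if (d1[1] != 0 || d2[1] != 0) stop("dose vectors must start at 0 (monotherapy axes)")
  if (any(diff(d1) <= 0) || any(diff(d2) <= 0)) stop("doses must be strictly increasing")
  structure(list(d1 = d1, d2 = d2, viability = viability,
                 inhibition = pmin(pmax(1 - viability, 0), 1),
                 drugs = drugs),
            class = "DoseMatrix")
}

#' Read a long-format combination viability table
#'
#' Columns `drug1_dose drug2_dose viability` (an optional `replicate`
#' column is averaged over).
#'
#' @param path TSV path.
#' @return a [dose_matrix()].
#' @export
read_dose_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug1_dose", "drug2_dose", "viability")
  if (!all(need %in% names(tab)))
    stop("dose table must have columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(viability ~ drug1_dose + drug2_dose, data = tab, FUN = mean)
  d1 <- sort(unique(agg$drug1_dose)); d2 <- sort(unique(agg$drug2_dose))
  m <- matrix(NA_real_, length(d1), length(d2))
  m[cbind(match(agg$drug1_dose, d1), match(agg$drug2_dose, d2))] <- agg$viability
  if (anyNA(m)) stop("incomplete dose grid")
  dose_matrix(d1, d2, m)
}

mono_curves <- function(matrix) {
  d1 <- matrix$d1[-1]; d2 <- matrix$d2[-1]
  y1 <- matrix$inhibition[-1, 1]   # drug1 alone (d2 = 0)
  y2 <- matrix$inhibition[1, -1]   # drug2 alone (d1 = 0)
  list(f1 = fit_4pl(d1, y1, drug = matrix$drugs[1]),
       f2 = fit_4pl(d2, y2, drug = matrix$drugs[2]),
       y1 = y1, y2 = y2)
}

# analytic inverse of an inhibition 4PL: dose achieving effect y
invert_4pl <- function(curve, y) {
  b <- curve$bottom; t <- curve$top; h <- curve$hill
  lo <- min(b, t); hi <- max(b, t)
  out <- rep(NA_real_, length(y))
  ok <- y > lo + 1e-12 & y < hi - 1e-12
  out[ok] <- curve$ic50 * ((t - y[ok]) / (y[ok] - b))^(1 / h)
  out
}

loewe_cell <- function(d1, d2, f1, f2) {
  lo <- max(min(f1$bottom, f1$top), min(f2$bottom, f2$top))
  hi <- min(max(f1$bottom, f1$top), max(f2$bottom, f2$top))
  if (!(hi > lo)) return(NA_real_)
  g <- function(E) d1 / invert_4pl(f1, E) + d2 / invert_4pl(f2, E) - 1
  eps <- (hi - lo) * 1e-9
  glo <- g(lo + eps); ghi <- g(hi - eps)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) return(NA_real_)
  a <- lo + eps; b2 <- hi - eps
  while (b2 - a > 1e-8 * (hi - lo)) {
    mid <- (a + b2) / 2
    if (g(mid) > 0) a <- mid else b2 <- mid
  }
  (a + b2) / 2
}

# ZIP potency-shift fit along one direction: 2-parameter logistic with
# baseline fixed at the other drug's fitted monotherapy effect and top 1
zip_directional <- function(doses, obs, baseline, start_m, start_h) {
  if (baseline >= 0.999) return(rep(baseline, length(doses)))
  fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
    obs ~ baseline + (1 - baseline) / (1 + (doses / m)^h),
    start = list(m = start_m, h = if (start_h < 0) start_h else -1),
    lower = c(m = min(doses[doses > 0]) / 100, h = -10),
    upper = c(m = max(doses) * 100, h = -1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  baseline + (1 - baseline) / (1 + (doses / p[["m"]])^p[["h"]])
}

#' Expected inhibition under a synergy reference model
#'
#' Computes the expected-inhibition grid at all combination cells
#' (both doses positive) under one of the reference models, on
#' inhibition fractions `y = 1 - viability` clipped to [0, 1]:
#' \describe{
#'   \item{bliss}{independence: `E = y1 + y2 - y1*y2` from the observed
#'     monotherapies.}
#'   \item{hsa}{highest single agent: `E = max(y1, y2)`.}
#'   \item{loewe}{dose additivity: `E` solves
#'     `d1/D1(E) + d2/D2(E) = 1` with `D` the inverse of the fitted
#'     monotherapy 4PL (bisection; cells where a monotherapy curve is
#'     not invertible are NA and excluded from scoring).}
#'   \item{zip}{the zero-interaction-potency null: Bliss independence
#'     evaluated on the fitted monotherapy 4PL curves.}
#' }
#'
#' @param matrix a [dose_matrix()].
#' @param model one of "bliss", "hsa", "loewe", "zip".
#' @return matrix of expected inhibition, NA outside combination cells.
#' @export
expected_inhibition <- function(matrix, model = c("bliss", "hsa", "loewe", "zip")) {
  model <- match.arg(model)
  n1 <- length(matrix$d1); n2 <- length(matrix$d2)
  E <- matrix(NA_real_, n1, n2)
  y1 <- matrix$inhibition[, 1]  # observed drug1 monotherapy over d1
  y2 <- matrix$inhibition[1, ]  # observed drug2 monotherapy over d2
  if (model == "bliss") {
    E <- outer(y1, y2, function(a, b) a + b - a * b)
  } else if (model == "hsa") {
    E <- outer(y1, y2, pmax)
  } else {
    mono <- mono_curves(matrix)
    if (model == "loewe") {
      if (!mono$f1$converged || !mono$f2$converged)
        stop("loewe requires invertible 4PL fits of both monotherapies")
      for (i in 2:n1) for (j in 2:n2)
        E[i, j] <- loewe_cell(matrix$d1[i], matrix$d2[j], mono$f1, mono$f2)
    } else {
      f1v <- predict_4pl(mono$f1, matrix$d1)
      f2v <- predict_4pl(mono$f2, matrix$d2)
      E <- outer(f1v, f2v, function(a, b) a + b - a * b)
    }
  }
  E[1, ] <- NA_real_
  E[, 1] <- NA_real_
  E
}

# average of the two directional potency-shift fits at combination cells
zip_fitted_grid <- function(matrix) {
  mono <- mono_curves(matrix)
  n1 <- length(matrix$d1); n2 <- length(matrix$d2)
  f1v <- predict_4pl(mono$f1, matrix$d1)
  f2v <- predict_4pl(mono$f2, matrix$d2)
  bliss_fit <- outer(f1v, f2v, function(a, b) a + b - a * b)
  along_d1 <- matrix(NA_real_, n1, n2)
  for (j in 2:n2) {
    fitj <- zip_directional(matrix$d1, matrix$inhibition[, j], f2v[j],
                            if (mono$f1$converged) mono$f1$ic50 else stats::median(matrix$d1[-1]),
                            if (mono$f1$converged) -abs(mono$f1$hill) else -1)
    along_d1[, j] <- if (is.null(fitj)) bliss_fit[, j] else fitj
  }
  along_d2 <- matrix(NA_real_, n1, n2)
  for (i in 2:n1) {
    fiti <- zip_directional(matrix$d2, matrix$inhibition[i, ], f1v[i],
                            if (mono$f2$converged) mono$f2$ic50 else stats::median(matrix$d2[-1]),
                            if (mono$f2$converged) -abs(mono$f2$hill) else -1)
    along_d2[i, ] <- if (is.null(fiti)) bliss_fit[i, ] else fiti
  }
  (along_d1 + along_d2) / 2
}

#' Synergy score under a reference model
#'
#' 100 times the mean excess of observed over expected inhibition over
#' all defined combination cells; positive values indicate synergy.
#' For the ZIP model the "observed" surface is the average of the two
#' directional potency-shift fits (the published ZIP formulation) and
#' the expectation is the ZIP null.
#'
#' @param matrix a [dose_matrix()].
#' @param model one of "bliss", "hsa", "loewe", "zip".
#' @return numeric score (percentage points of inhibition).
#' @export
synergy_score <- function(matrix, model = c("bliss", "hsa", "loewe", "zip")) {
  model <- match.arg(model)
  E <- expected_inhibition(matrix, model)
  obs <- if (model == "zip") zip_fitted_grid(matrix) else matrix$inhibition
  combo <- which(!is.na(E))
  if (!length(combo)) stop("no defined combination cells for model ", model)
  100 * mean(obs[combo] - E[combo])
}

#' @rdname synergy_score
#' @param models character vector of models.
#' @return `synergy_report`: named numeric vector of scores.
#' @export
synergy_report <- function(matrix, models = c("zip", "loewe", "bliss", "hsa")) {
  vapply(models, function(m) synergy_score(matrix, m), numeric(1))
}
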