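# Screen evaluation (ROC/AUC, relative enrichment factors) and
# competition-binding assay analysis (percent-of-control, Hill Kd fit).

#' Labelled ranking
#'
#' Binds scores and binary activity labels into an ordered ranking (strictly
#' by descending score; ties keep input order and are recorded).
#'
#' @param names Ligand identifiers.
#' @param scores Numeric scores, higher = better.
#' @param labels Logical or 0/1 active labels.
#' @return `labeled_ranking` data.frame ordered by descending score.
#' @export
labeled_ranking <- function(names, scores, labels) {
  stopifnot(length(names) == length(scores),
            length(scores) == length(labels))
  lab <- as.logical(labels)
  if (any(is.na(lab))) stop("labels must be binary")
  o <- order(-scores, seq_along(scores))
  out <- data.frame(name = names[o], score = scores[o], active = lab[o],
                    stringsAsFactors = FALSE)
  attr(out, "ties") <- anyDuplicated(scores) > 0
  class(out) <- c("labeled_ranking", class(out))
  out
}

#' Rank-based ROC AUC
#'
#' Probability that a random active outscores a random decoy; tied scores
#' contribute 1/2 (Mann-Whitney formulation).
#'
#' @param ranking `labeled_ranking`, or anything with `score` and `active`
#'   columns.
#' @return AUC in [0,1].
#' @export
roc_auc <- function(ranking) {
  act <- ranking$active
  if (!any(act) || all(act))
    stop("AUC needs at least one active and one decoy")
  r <- rank(ranking$score)  # ties averaged -> 1/2 contribution
  n1 <- sum(act); n0 <- sum(!act)
  (sum(r[act]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Relative enrichment factor
#'
#' Fraction of the maximum attainable number of actives recovered in the top
#' x% of the ranking, times 100: `EF_rel = n_a / min(N_x, n) * 100`, where
#' the top set size `N_x = floor(N * x/100)` (minimum 1) and `n` is the
#' total number of actives. Bounded above by 100.
#'
#' @param ranking `labeled_ranking`.
#' @param x_percent Cutoff percentage in (0, 100].
#' @return EF_rel in [0, 100].
#' @export
relative_ef <- function(ranking, x_percent) {
  if (x_percent <= 0 || x_percent > 100) stop("x_percent must be in (0,100]")
  N <- nrow(ranking)
  if (N == 0) stop("empty ranking")
  n <- sum(ranking$active)
  topn <- max(1L, floor(N * x_percent / 100))
  na <- sum(ranking$active[seq_len(topn)])
  na / min(topn, n) * 100
}

#' Percent of control
#'
#' Linear rescaling of an assay signal between the positive control (0%)
#' and the negative/vehicle control (100%): lower values indicate stronger
#' competition (stronger binding).
#'
#' @param signal Test compound signal.
#' @param positive_control Signal at complete competition.
#' @param negative_control Vehicle (no-compound) signal.
#' @return Percent of control.
#' @export
percent_control <- function(signal, positive_control, negative_control) {
  if (negative_control == positive_control)
    stop("controls are equal; percent of control undefined")
  (signal - positive_control) / (negative_control - positive_control) * 100
}

#' Hill dose-response fit for the dissociation constant
#'
#' Least-squares fit of
#' `Response = Background + (Signal_max - Background) / (1 + (kd/Dose)^slope)`
#' with the Hill slope fixed (default -1, the standard competition-binding
#' form where signal decreases with dose). The fit is on log(kd) for
#' positivity, initialized at the geometric mean of the doses; background
#' and maximal signal are co-fitted unless supplied.
#'
#' @param doses Doses (nM), strictly positive and increasing.
#' @param responses Signal at each dose.
#' @param hill_slope Fixed Hill slope.
#' @param background,signal_max Optional fixed asymptotes.
#' @return Object of class `hill_fit` with `kd` (nM), fitted parameters,
#'   and diagnostics; supports `coef`, `predict`, `residuals`, `print`.
#' @export
hill_fit <- function(doses, responses, hill_slope = -1,
                     background = NULL, signal_max = NULL) {
  if (length(doses) != length(responses)) stop("length mismatch")
  if (any(doses <= 0)) stop("doses must be positive")
  if (is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly increasing")
  if (length(doses) < 4)
    warning("fewer than 4 dose points; kd poorly constrained")
  span <- diff(range(responses))
  if (span < 1e-9 * max(abs(responses), 1))
    stop("responses are constant; no finite kd can be fitted")
  model <- function(p, d) {
    b <- if (is.null(background)) p[["b"]] else background
    s <- if (is.null(signal_max)) p[["s"]] else signal_max
    kd <- exp(p[["logkd"]])
    b + (s - b) / (1 + (kd / d)^hill_slope)
  }
  start <- c(logkd = log(exp(mean(log(doses)))))
  if (is.null(background)) start <- c(start, b = min(responses))
  if (is.null(signal_max)) start <- c(start, s = max(responses))
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) responses - model(p, doses),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5, 9))
    stop("Hill fit did not converge: ", fit$message)
  kd <- exp(fit$par[["logkd"]])
  if (!is.finite(kd) || kd <= 0) stop("non-positive kd estimate")
  structure(list(kd = kd, par = fit$par, hill_slope = hill_slope,
                 background = if (is.null(background)) fit$par[["b"]]
                              else background,
                 signal_max = if (is.null(signal_max)) fit$par[["s"]]
                              else signal_max,
                 doses = doses, responses = responses,
                 fitted = model(fit$par, doses),
                 deviance = fit$deviance, info = fit$info),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit (slope %g): kd = %.4g nM, background %.4g, max %.4g, RSS %.4g\n",
    x$hill_slope, x$kd, x$background, x$signal_max, x$deviance))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(kd = object$kd, background = object$background,
    signal_max = object$signal_max)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$doses else newdata
  object$background + (object$signal_max - object$background) /
    (1 + (object$kd / d)^object$hill_slope)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$responses - object$fitted
}

#' Simulate a competition-binding dose-response series
#'
#' Serial-dilution doses and Hill-model responses with optional Gaussian
#' noise; the generator used in fit-recovery checks.
#'
#' @param kd True dissociation constant (nM).
#' @param top Highest dose (nM).
#' @param n_points Number of dilution points.
#' @param fold Dilution factor between consecutive points.
#' @param background,signal_max Model asymptotes.
#' @param hill_slope Hill slope.
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @return data.frame with `dose` and `response`.
#' @export
simulate_dose_response <- function(kd = 100, top = 30000, n_points = 11,
                                   fold = 3, background = 50,
                                   signal_max = 5000, hill_slope = -1,
                                   noise_sd = 0) {
  doses <- sort(top / fold^(seq_len(n_points) - 1))
  resp <- background + (signal_max - background) /
    (1 + (kd / doses)^hill_slope)
  if (noise_sd > 0) resp <- resp + rnorm(n_points, 0, noise_sd)
  data.frame(dose = doses, response = resp)
}
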