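#' Monotonic repair of a quantile vector
#'
#' Inference-time guard against residual quantile crossing: returns the
#' non-decreasing rearrangement (sort) of the vector, which preserves the
#' multiset of predicted values and equals the input whenever the input is
#' already non-decreasing.
#'
#' @param yhat_vec numeric quantile vector in grid order.
#' @return sorted vector.
#' @export
repair_monotonic <- function(yhat_vec) sort(yhat_vec)

#' Predicted cumulative distribution from a quantile vector
#'
#' Piecewise-linear interpolation of the (value, tau) knots of a repaired
#' (non-decreasing) quantile vector, evaluated at `x`. Outside the outer
#' knots the CDF ramps linearly to exactly 0 and 1 over a tail width equal
#' to the adjacent inter-quantile gap (a local-scale extrapolation; the
#' model does not carry the 0th/100th percentiles, which would correspond
#' to the extremes of the training data). `tails = "clamp"` instead
#' freezes the CDF at the outer grid levels. At a repeated knot value the
#' upper tau is taken (right-continuity). A fully degenerate vector (all
#' values equal) yields a step CDF at that value.
#'
#' @param yhat_vec repaired quantile vector.
#' @param taus quantile grid (same length).
#' @param x numeric evaluation point(s), ppm.
#' @param tails `"ramp"` (default) or `"clamp"`.
#' @return cumulative probabilities in `[0, 1]`, non-decreasing in `x`,
#'   with `cdf(q_tau) = tau` at every strictly increasing knot.
#' @export
quantile_cdf <- function(yhat_vec, taus = quantile_grid(), x,
                         tails = c("ramp", "clamp")) {
  tails <- match.arg(tails)
  taus <- as.numeric(taus)
  stopifnot(length(yhat_vec) == length(taus))
  if (is.unsorted(yhat_vec)) stop("quantile vector must be repaired (non-decreasing)")
  q <- length(yhat_vec)
  # collapse repeated values, keeping the upper tau (right-continuous CDF)
  keep <- c(yhat_vec[-q] != yhat_vec[-1], TRUE)
  v <- yhat_vec[keep]; tt <- taus[keep]
  if (length(v) == 1) {           # degenerate: step CDF
    lo <- ifelse(x < v, 0, 1)
    return(lo)
  }
  if (tails == "ramp") {
    wlo <- v[2] - v[1]
    whi <- v[length(v)] - v[length(v) - 1]
    v <- c(v[1] - wlo, v, v[length(v)] + whi)
    tt <- c(0, tt, 1)
  }
  stats::approx(v, tt, xout = x, rule = 2, ties = "ordered")$y
}

#' Error score of one atom (probability mass within the observed error)
#'
#' The predicted probability that the shift lies within +/- the observed
#' absolute error of the predicted median:
#' `P = F(yhat + |yhat - y|) - F(yhat - |yhat - y|)` where `F` is the
#' predicted CDF and `yhat` the predicted median. `P` is 0 when the
#' observation hits the median exactly, grows monotonically with the
#' error, and approaches 1 when the observation lies far outside the
#' predicted distribution. The atomic confidence score is `1 - P`.
#'
#' @param yhat_vec quantile vector (repaired internally).
#' @param taus quantile grid.
#' @param y observed shift (ppm).
#' @param tails tail handling passed to [quantile_cdf()].
#' @return list with `P`, `dp5q = 1 - P`, `median`, `error`.
#' @export
error_score <- function(yhat_vec, taus = quantile_grid(), y,
                        tails = "ramp") {
  taus <- as.numeric(taus)
  v <- repair_monotonic(yhat_vec)
  med <- .median_of(v, taus)
  e <- abs(med - y)
  P <- quantile_cdf(v, taus, med + e, tails) -
       quantile_cdf(v, taus, med - e, tails)
  P <- min(max(P, 0), 1)
  list(P = P, dp5q = 1 - P, median = med, error = e)
}

#' Molecular DP5q score (geometric average of atomic scores)
#'
#' Computed in log space; exactly zero if any atomic score is zero. The
#' result is bounded by the smallest and largest atomic scores.
#'
#' @param dp5q numeric vector of atomic scores in `[0, 1]` (n >= 1).
#' @return scalar geometric mean.
#' @export
molecule_dp5q <- function(dp5q) {
  if (!length(dp5q)) stop("no atomic scores supplied")
  stopifnot(all(dp5q >= 0), all(dp5q <= 1))
  if (any(dp5q == 0)) return(0)
  exp(mean(log(dp5q)))
}

#' Mean absolute error of median predictions against an assigned spectrum
#'
#' @param class_medians predicted median shift per carbon class (the mean
#'   of the member atoms' medians).
#' @param spectrum a [shift_spectrum()].
#' @param assignment integer vector mapping each peak to a class; taken
#'   from the spectrum when omitted.
#' @return MAE in ppm over the assigned peaks.
#' @export
molecule_mae <- function(class_medians, spectrum, assignment = NULL) {
  if (is.null(assignment)) assignment <- spectrum$assignment
  if (is.null(assignment) || any(is.na(assignment)))
    stop("every peak must be assigned to a carbon class")
  stopifnot(length(assignment) == length(spectrum$shifts))
  mean(abs(class_medians[assignment] - spectrum$shifts))
}

#' Score one structure-spectrum pair
#'
#' The full confidence pipeline: predict quantiles (over one conformer or
#' the whole ensemble), average them within each carbon equivalence class,
#' repair monotonicity, assign peaks to classes (by optimal matching when
#' no assignment is given), and convert each matched peak's error into an
#' error score `P` and atomic confidence `1 - P`. The molecular score is
#' the geometric mean over scored classes; MAE compares class medians to
#' the assigned peaks.
#'
#' @param model a trained `dp5q_model`.
#' @param mol a `mol_record` with at least one conformer.
#' @param spectrum a [shift_spectrum()].
#' @param conformers conformer indices for [predict_ensemble()] (default
#'   all).
#' @param weights optional conformer weights.
#' @param assignment optional peak-to-class map; defaults to the
#'   spectrum's own assignment, or optimal matching when absent.
#' @param per_atom when `TRUE`, every atom of a matched class contributes
#'   one score (so larger classes weigh more in the geometric mean);
#'   default `FALSE` scores once per class -- one experimental peak, one
#'   score.
#' @param tails tail handling for the CDF.
#' @return object of class `dp5q_result`: list with `atom_scores` (data
#'   frame: class, peak, median, observed, error, P, dp5q), `dp5q`
#'   (molecular), `mae` (ppm), `n` (classes scored), `assignment`,
#'   `unmatched_classes`.
#' @export
dp5q_score <- function(model, mol, spectrum, conformers = NULL,
                       weights = NULL, assignment = NULL, per_atom = FALSE,
                       tails = "ramp") {
  pred <- predict_ensemble(model, mol, conformers, weights)
  taus <- attr(pred, "taus"); atom_of <- attr(pred, "atoms")
  class_vecs <- lapply(mol$carbon_classes, function(cl) {
    repair_monotonic(colMeans(unclass(pred)[match(cl, atom_of), , drop = FALSE]))
  })
  med <- vapply(class_vecs, .median_of, numeric(1), taus = taus)
  if (is.null(assignment)) assignment <- spectrum$assignment
  if (is.null(assignment)) {
    assignment <- assign_peaks(med, spectrum$shifts)$assignment
  }
  stopifnot(length(assignment) == length(spectrum$shifts))
  scored <- !is.na(assignment)
  rows <- lapply(which(scored), function(p) {
    ci <- assignment[p]
    es <- error_score(class_vecs[[ci]], taus, spectrum$shifts[p], tails)
    reps <- if (per_atom) length(mol$carbon_classes[[ci]]) else 1L
    data.frame(class = ci, peak = p, median = es$median,
               observed = spectrum$shifts[p], error = es$error,
               P = es$P, dp5q = es$dp5q)[rep(1, reps), ]
  })
  scores <- do.call(rbind, rows)
  structure(list(atom_scores = scores,
                 dp5q = molecule_dp5q(scores$dp5q),
                 mae = mean(scores$error),
                 n = nrow(scores),
                 assignment = assignment,
                 unmatched_classes = setdiff(seq_along(class_vecs),
                                             assignment[scored])),
            class = "dp5q_result")
}

#' @export
print.dp5q_result <- function(x, ...) {
  cat(sprintf("<dp5q_result> molecular DP5q %.3f | MAE %.2f ppm | %d classes scored\n",
              x$dp5q, x$mae, x$n))
  invisible(x)
}
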