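#' Score a labelled benchmark of structure-spectrum pairs
#'
#' For every pair the spectrum is assigned to the candidate structure by
#' optimal matching (the pair's own assignment is deliberately ignored:
#' cross pairs have none) and scored with [dp5q_score()]. Pairs that fail
#' to score are excluded with a warning and counted in the `excluded`
#' attribute.
#'
#' @param bench benchmark table from [make_benchmark()] (with its
#'   `spectra` attribute and the pool in `pool`), or any data frame with
#'   `structure`, `spectrum`, `label` plus explicit `pool` and `spectra`.
#' @param model a trained `dp5q_model`.
#' @param pool list of `mol_record` with conformers (defaults to the
#'   benchmark's pool attribute).
#' @param spectra list of [shift_spectrum()] per pool molecule (defaults
#'   to the spectra simulated by [make_benchmark()]).
#' @return data frame with one row per scored pair: `structure`,
#'   `spectrum`, `label`, `dp5q`, `mae`; attribute `excluded` counts
#'   unscorable pairs.
#' @export
score_benchmark <- function(bench, model, pool = attr(bench, "pool"),
                            spectra = NULL) {
  if (is.null(spectra)) {
    sims <- attr(bench, "spectra")
    if (is.null(sims)) stop("no spectra supplied or attached to the benchmark")
    spectra <- lapply(sims, `[[`, "spectrum")
  }
  if (is.null(pool)) stop("no molecule pool supplied or attached")
  excluded <- 0L
  rows <- lapply(seq_len(nrow(bench)), function(k) {
    i <- bench$structure[k]; j <- bench$spectrum[k]
    sp <- shift_spectrum(spectra[[j]]$shifts)   # strip assignment
    res <- tryCatch(dp5q_score(model, pool[[i]], sp),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("pair ", i, "/", j, " excluded: ", conditionMessage(res))
      excluded <<- excluded + 1L
      return(NULL)
    }
    data.frame(structure = i, spectrum = j, label = bench$label[k],
               dp5q = res$dp5q, mae = res$mae)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  attr(out, "excluded") <- excluded
  out
}

#' Binned correct-ratio surface over (MAE, DP5q)
#'
#' Groups scored pairs into 2D bins and reports, per bin, the ratio of
#' correct interpretations to the total -- an empirical estimate of the
#' probability that an interpretation with that (MAE, DP5q) combination is
#' correct. Bins are half-open `[lo, hi)` except the last (closed); empty
#' bins are `NA`, not 0.
#'
#' @param table output of [score_benchmark()].
#' @param mae_edges increasing bin edges for MAE (default 0-10 ppm in 0.5
#'   ppm steps).
#' @param dp5q_edges increasing bin edges for DP5q (default 0-1 in 0.05
#'   steps).
#' @return object of class `ratio_surface`: list with `ratio`, `n`,
#'   `n_correct` matrices (MAE bins x DP5q bins) and the edges.
#' @export
ratio_surface <- function(table, mae_edges = seq(0, 10, by = 0.5),
                          dp5q_edges = seq(0, 1, by = 0.05)) {
  if (!nrow(table)) stop("empty score table")
  if (any(diff(mae_edges) <= 0) || any(diff(dp5q_edges) <= 0))
    stop("bin edges must be strictly increasing")
  bin_of <- function(x, edges) {
    b <- findInterval(x, edges, rightmost.closed = TRUE)
    b[x < edges[1] | x > edges[length(edges)]] <- NA
    b
  }
  bi <- bin_of(table$mae, mae_edges)
  bj <- bin_of(table$dp5q, dp5q_edges)
  ni <- length(mae_edges) - 1; nj <- length(dp5q_edges) - 1
  n <- matrix(0L, ni, nj); nc <- matrix(0L, ni, nj)
  ok <- !is.na(bi) & !is.na(bj)
  for (k in which(ok)) {
    n[bi[k], bj[k]] <- n[bi[k], bj[k]] + 1L
    if (table$label[k] == "correct") nc[bi[k], bj[k]] <- nc[bi[k], bj[k]] + 1L
  }
  ratio <- ifelse(n > 0, nc / n, NA_real_)
  structure(list(ratio = ratio, n = n, n_correct = nc,
                 mae_edges = mae_edges, dp5q_edges = dp5q_edges),
            class = "ratio_surface")
}

#' Rank candidate structures against one spectrum
#'
#' Scores every candidate with [dp5q_score()] over its conformer ensemble
#' and reports both the DP5q ranking and the MAE ranking. For display in
#' stereochemistry workflows the scores divided by the candidate count are
#' included (`dp5q_norm`), indicating relative magnitude and absolute
#' probability at once. Ties on the maximal score are flagged, not
#' silently broken.
#'
#' @param candidates list of `mol_record` with conformers (>= 2).
#' @param spectrum a [shift_spectrum()].
#' @param model a trained `dp5q_model`.
#' @param weights optional per-candidate list of conformer weights.
#' @return object of class `ranking_report`: data frame with `candidate`,
#'   `dp5q`, `mae`, `dp5q_norm` plus attributes `winner` (index of maximal
#'   dp5q), `winner_mae` (index of minimal MAE) and `tie`.
#' @export
rank_candidates <- function(candidates, spectrum, model, weights = NULL) {
  stopifnot(length(candidates) >= 2)
  res <- lapply(seq_along(candidates), function(k)
    dp5q_score(model, candidates[[k]], spectrum,
               weights = if (!is.null(weights)) weights[[k]]))
  out <- data.frame(candidate = seq_along(candidates),
                    dp5q = vapply(res, `[[`, 0, "dp5q"),
                    mae = vapply(res, `[[`, 0, "mae"))
  out$dp5q_norm <- out$dp5q / length(candidates)
  top <- max(out$dp5q)
  tie <- sum(abs(out$dp5q - top) < 1e-12) > 1
  structure(out, winner = which.max(out$dp5q),
            winner_mae = which.min(out$mae), tie = tie,
            class = c("ranking_report", "data.frame"))
}

#' Classify benchmark pairs by a DP5q threshold
#'
#' Pairs with DP5q below the threshold are discarded as incorrect
#' proposals. With the recommended threshold of 0.2 this reliably rejects
#' wrong structures while keeping correct ones. Positives are correct
#' pairs: TP = correct kept, FN = correct discarded, TN = incorrect
#' discarded, FP = incorrect kept.
#'
#' @param table output of [score_benchmark()].
#' @param threshold DP5q cutoff (default 0.2).
#' @return named integer vector `c(TP, FP, TN, FN)` summing to
#'   `nrow(table)`.
#' @export
threshold_classify <- function(table, threshold = 0.2) {
  keep <- table$dp5q >= threshold
  correct <- table$label == "correct"
  c(TP = sum(correct & keep), FP = sum(!correct & keep),
    TN = sum(!correct & !keep), FN = sum(correct & !keep))
}

#' Area under the ROC curve of DP5q as a correctness classifier
#'
#' Rank-based (Mann-Whitney) AUC of the molecular DP5q score separating
#' correct from incorrect pairs.
#'
#' @param table output of [score_benchmark()].
#' @return AUC in `[0, 1]`.
#' @export
benchmark_auc <- function(table) {
  x <- table$dp5q[table$label == "correct"]
  y <- table$dp5q[table$label == "incorrect"]
  if (!length(x) || !length(y)) stop("need both correct and incorrect pairs")
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}
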