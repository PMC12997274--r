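#' Assign experimental peaks to predicted carbon environments
#'
#' Minimum-cost bipartite matching between observed peaks and predicted
#' class median shifts under the absolute-deviation cost `|median - shift|`
#' (Hungarian algorithm). The smaller side is always fully matched; with
#' more classes than peaks the surplus classes are left unmatched (and
#' excluded from scoring), with more peaks than classes the surplus peaks
#' stay unassigned. Deterministic; equal-cost alternatives resolve to the
#' lowest (peak index, class index) pair.
#'
#' @param class_medians numeric vector of predicted median shifts (ppm),
#'   one per carbon class.
#' @param shifts numeric vector of observed peaks (ppm).
#' @return list with `assignment` (integer per peak: matched class index
#'   or `NA`), `unmatched_classes`, and `cost` (total absolute deviation
#'   over matched pairs, ppm).
#' @export
assign_peaks <- function(class_medians, shifts) {
  if (!length(class_medians) || !length(shifts))
    stop("need at least one class and one peak")
  np <- length(shifts); nc <- length(class_medians)
  cost <- abs(outer(shifts, class_medians, "-"))   # peaks x classes
  if (np <= nc) {
    match_col <- .hungarian(cost)
    assignment <- match_col
  } else {
    match_row <- .hungarian(t(cost))               # classes x peaks
    assignment <- rep(NA_integer_, np)
    assignment[match_row] <- seq_len(nc)
  }
  matched <- !is.na(assignment)
  list(assignment = assignment,
       unmatched_classes = setdiff(seq_len(nc), assignment[matched]),
       cost = sum(cost[cbind(which(matched), assignment[matched])]))
}

# Hungarian algorithm (Jonker-style with potentials), n rows <= m columns;
# returns for each row its assigned column. O(n^2 m).
.hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- Inf
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)       # p[j+1]: row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(INF, m + 1); used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- -1
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  out <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) out[p[j + 1]] <- j
  out
}

#' Enumerate labelled correct/incorrect candidate pairs from a corpus
#'
#' Every (structure, spectrum) cross pair with matching molecular formula:
#' a molecule with its own spectrum is a correct pair, with another
#' molecule's spectrum an incorrect pair. The labels partition the emitted
#' set.
#'
#' @param corpus list of records `list(mol, spectrum)` (N >= 2).
#' @return data frame with columns `structure`, `spectrum` (record
#'   indices) and `label`.
#' @export
enumerate_pairs <- function(corpus) {
  stopifnot(length(corpus) >= 2)
  formulas <- vapply(corpus, function(r) r$mol$formula, "")
  rows <- list()
  for (i in seq_along(corpus)) {
    for (j in seq_along(corpus)) {
      if (i == j) {
        rows[[length(rows) + 1L]] <- data.frame(structure = i, spectrum = i,
                                                label = "correct")
      } else if (formulas[i] == formulas[j]) {
        rows[[length(rows) + 1L]] <- data.frame(structure = i, spectrum = j,
                                                label = "incorrect")
      }
    }
  }
  do.call(rbind, rows)
}
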