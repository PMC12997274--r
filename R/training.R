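#' Training configuration
#'
#' Optimisation schedule for the quantile net: Adam with an initial
#' learning rate of 5e-4, decayed by 4 percent every 100 000 optimiser
#' steps, for at most 1200 epochs, with early stopping once the validation
#' loss has not improved (any strict decrease counts) for `patience`
#' consecutive epochs.
#'
#' @param max_epochs upper bound on epochs (default 1200).
#' @param lr initial learning rate (default 5e-4).
#' @param decay fractional learning-rate reduction per decay interval
#'   (default 0.04).
#' @param decay_interval optimiser steps per decay (default 1e5).
#' @param optimiser only `"adam"` is implemented.
#' @param patience early-stopping patience in epochs (default 10).
#' @param val_fraction fraction of molecules held out for validation
#'   (default 0.1; the split is by molecule).
#' @param batch_size molecules per optimiser step (default 32).
#' @param ema decay of the exponential moving average kept over the
#'   weights (default 0.995; 0 disables). The averaged weights are
#'   validated alongside the raw ones each epoch and the returned
#'   checkpoint is whichever achieved the best validation loss --
#'   averaging smooths the minibatch noise near convergence.
#' @param recalibrate when `TRUE` (default) the selected checkpoint's
#'   per-quantile output biases are adjusted so that each predicted
#'   quantile attains its nominal empirical coverage on a dedicated
#'   calibration split (split quantile recalibration). A finite model
#'   partially fits the noise in its training targets and therefore tends
#'   to predict slightly narrow distributions; the calibration molecules
#'   -- excluded from both the gradient steps and the early-stopping
#'   checkpoint choice, so their residuals are unbiased -- measure and
#'   remove that global bias. The offsets are projected to be
#'   non-decreasing across the grid (isotonic regression) so the
#'   adjustment cannot introduce quantile crossing.
#' @param cal_fraction fraction of molecules reserved for the calibration
#'   split (default 0.1; only used when `recalibrate` is `TRUE`).
#' @param seed integer seed for the split and batch order.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 1200, lr = 5e-4, decay = 0.04,
                         decay_interval = 1e5, optimiser = "adam",
                         patience = 10, val_fraction = 0.1, batch_size = 32,
                         ema = 0.995, recalibrate = TRUE, cal_fraction = 0.1,
                         seed = 1) {
  stopifnot(lr > 0, decay >= 0, decay < 1, patience >= 1,
            val_fraction > 0, val_fraction < 1, batch_size >= 1,
            max_epochs >= 1, ema >= 0, ema < 1,
            cal_fraction > 0, cal_fraction < 1)
  optimiser <- match.arg(optimiser, "adam")
  structure(list(max_epochs = max_epochs, lr = lr, decay = decay,
                 decay_interval = decay_interval, optimiser = optimiser,
                 patience = patience, val_fraction = val_fraction,
                 batch_size = batch_size, ema = ema,
                 recalibrate = isTRUE(recalibrate),
                 cal_fraction = cal_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate after a given number of optimiser steps
#'
#' `lr * (1 - decay)^k` where `k` is the number of completed decay
#' intervals, i.e. step-wise (not epoch-wise) decay.
#'
#' @param step optimiser step count (0-based).
#' @param config a [train_config()].
#' @return learning rate.
#' @export
lr_at_step <- function(step, config = train_config()) {
  config$lr * (1 - config$decay)^(step %/% config$decay_interval)
}

#' Split a corpus into training and validation sets by molecule
#'
#' Disjoint, exhaustive and reproducible under the seed; all atoms of a
#' molecule land on the same side.
#'
#' @param corpus list of records (any list; commonly the output of
#'   [build_corpus()]).
#' @param fraction fraction assigned to the training side, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `validation` index vectors.
#' @export
split_corpus <- function(corpus, fraction = 0.9, seed = 1) {
  n <- length(corpus)
  stopifnot(n >= 2)
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  .with_seed(seed, {
    perm <- sample.int(n)
    ntr <- max(1L, min(n - 1L, round(fraction * n)))
    list(train = sort(perm[seq_len(ntr)]),
         validation = sort(perm[(ntr + 1L):n]))
  })
}

#' Pair molecules with assigned spectra into a training corpus
#'
#' @param mols list of `mol_record` with conformers.
#' @param spectra list of [shift_spectrum()] with class assignments, one
#'   per molecule.
#' @return list of records `list(mol, spectrum)`, the corpus format the
#'   curation filters and [train()] operate on.
#' @export
build_corpus <- function(mols, spectra) {
  stopifnot(length(mols) == length(spectra))
  Map(function(m, s) list(mol = m, spectrum = s), mols, spectra)
}

# per-carbon target vector for a record: each carbon inherits the observed
# shift of its equivalence class
.carbon_targets <- function(rec) {
  mol <- rec$mol; sp <- rec$spectrum
  if (is.null(sp$assignment))
    stop("training requires class-assigned spectra (molecule '",
         mol$name, "')")
  carbons <- unlist(mol$carbon_classes)
  class_of <- rep(seq_along(mol$carbon_classes),
                  lengths(mol$carbon_classes))
  y_class <- rep(NA_real_, length(mol$carbon_classes))
  y_class[sp$assignment] <- sp$shifts
  ord <- order(carbons)
  y <- y_class[class_of][ord]
  if (any(is.na(y)))
    stop("unassigned carbon class in molecule '", mol$name, "'")
  y
}

.adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      out <- lapply(keys, function(k) walk(p[[k]], g[[k]], m[[k]], v[[k]]))
      names(out) <- names(p)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t); vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(t = state$t, m = out$m, v = out$v))
}

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like) else p * 0
}

# elementwise a + w * (b - a) over nested parameter lists
.lerp_params <- function(a, b, w) {
  if (is.list(a)) {
    keys <- if (is.null(names(a))) seq_along(a) else names(a)
    out <- lapply(keys, function(k) .lerp_params(a[[k]], b[[k]], w))
    names(out) <- names(a)
    out
  } else a + w * (b - a)
}

#' Train the quantile model
#'
#' Runs mini-batch Adam on the composite loss (tau-weighted multi-quantile
#' Huber plus crossing penalty), with a molecule-level validation split,
#' step-wise learning-rate decay and early stopping. The checkpoint with
#' the best validation loss is returned. Target normalisation and the
#' output-bias initialisation (the marginal quantiles of the training
#' shifts) are set from the training split before the first step.
#'
#' @param corpus list of records from [build_corpus()]; every molecule
#'   needs at least one conformer and a class-assigned spectrum.
#' @param config a [model_config()].
#' @param tconfig a [train_config()].
#' @param lconfig a [loss_config()].
#' @param cal_corpus optional separate corpus used for quantile
#'   recalibration instead of a split carved from `corpus`. Supply this
#'   when the deployment population differs from the training corpus --
#'   e.g. fresh molecules when the corpus contains duplicate structures,
#'   which make corpus-internal residuals unrepresentatively small.
#' @param verbose print per-epoch progress.
#' @return a trained `dp5q_model` with attribute `"log"`: a data frame of
#'   epoch, train loss, validation loss and learning rate.
#' @export
train <- function(corpus, config = model_config(),
                  tconfig = train_config(), lconfig = loss_config(),
                  cal_corpus = NULL, verbose = FALSE) {
  stopifnot(length(corpus) >= 2)
  if (length(config$grid) != length(lconfig$grid) ||
      any(as.numeric(config$grid) != as.numeric(lconfig$grid)))
    stop("model and loss quantile grids differ")
  sp <- split_corpus(corpus, 1 - tconfig$val_fraction, tconfig$seed)
  cal_idx <- integer(0)
  if (tconfig$recalibrate && is.null(cal_corpus)) {
    cal_idx <- .with_seed(tconfig$seed + 7L, {
      ncal <- max(1L, round(tconfig$cal_fraction * length(sp$train)))
      sort(sample(sp$train, ncal))
    })
    sp$train <- setdiff(sp$train, cal_idx)
  }
  feats <- lapply(corpus, function(r) featurize(r$mol, 1, config))
  ys <- lapply(corpus, .carbon_targets)

  model <- build_model(config)
  y_train <- unlist(ys[sp$train])
  model$norm_mu <- mean(y_train)
  model$norm_sc <- max(stats::sd(y_train), 1)
  taus <- as.numeric(config$grid)
  model$params$b_r2 <- as.numeric(
    (stats::quantile(y_train, probs = taus, names = FALSE) - model$norm_mu) /
      model$norm_sc)

  batches <- .with_seed(tconfig$seed + 1L, {
    perm <- sample(sp$train)
    split(perm, ceiling(seq_along(perm) / tconfig$batch_size))
  })
  bdata <- lapply(batches, function(idx)
    list(fb = .batch_features(feats[idx]), y = unlist(ys[idx])))
  vdata <- list(fb = .batch_features(feats[sp$validation]),
                y = unlist(ys[sp$validation]))

  state <- list(t = 0, m = .zeros_like(model$params),
                v = .zeros_like(model$params))
  step <- 0L
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  bad <- 0L
  ema_w <- if (tconfig$ema > 0) model$params
  log <- vector("list", tconfig$max_epochs)
  for (epoch in seq_len(tconfig$max_epochs)) {
    tr_loss <- 0
    for (b in bdata) {
      fwd <- .forward(model, b$fb, keep = TRUE)
      lg <- total_loss_grad(b$y, fwd$Y, lconfig)
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", epoch, ", step ", step)
      grads <- .backward(model, b$fb, fwd$cache, lg$grad)
      lr <- lr_at_step(step, tconfig)
      state$t <- state$t + 1
      upd <- .adam_update(model$params, grads, state, lr)
      model$params <- upd$params; state <- upd$state
      if (!is.null(ema_w))
        ema_w <- .lerp_params(ema_w, model$params, 1 - tconfig$ema)
      step <- step + 1L
      tr_loss <- tr_loss + lg$loss * length(b$y)
    }
    tr_loss <- tr_loss / length(unlist(ys[sp$train]))
    vl <- total_loss_grad(vdata$y, .forward(model, vdata$fb)$Y, lconfig)$loss
    cand <- list(list(loss = vl, params = model$params))
    if (!is.null(ema_w)) {
      me <- model; me$params <- ema_w
      vle <- total_loss_grad(vdata$y, .forward(me, vdata$fb)$Y, lconfig)$loss
      cand[[2]] <- list(loss = vle, params = ema_w)
      vl <- min(vl, vle)
    }
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                               val_loss = vl, lr = lr_at_step(step, tconfig))
    if (verbose && (epoch %% 20 == 0 || epoch == 1))
      message(sprintf("epoch %4d  train %.4f  val %.4f", epoch, tr_loss, vl))
    improved <- FALSE
    for (cd in cand) {
      if (cd$loss < best$loss) {
        best <- list(loss = cd$loss, params = cd$params, epoch = epoch)
        improved <- TRUE
      }
    }
    if (improved) bad <- 0L else {
      bad <- bad + 1L
      if (bad >= tconfig$patience) break
    }
  }
  model$params <- best$params
  if (isTRUE(tconfig$recalibrate)) {
    # split quantile recalibration on molecules unseen by both the
    # gradient steps and the checkpoint choice; isotonic projection keeps
    # the adjustment from introducing quantile crossing
    cdata <- if (is.null(cal_corpus)) {
      list(fb = .batch_features(feats[cal_idx]), y = unlist(ys[cal_idx]))
    } else {
      list(fb = .batch_features(lapply(cal_corpus, function(r)
             featurize(r$mol, 1, config))),
           y = unlist(lapply(cal_corpus, .carbon_targets)))
    }
    Yc <- .forward(model, cdata$fb)$Y
    off <- vapply(seq_along(taus), function(k)
      stats::quantile(cdata$y - Yc[, k], probs = taus[k], names = FALSE),
      numeric(1))
    # median-smooth the noisy per-level estimates, then the minimal
    # monotone projection; running isoreg on raw offsets would pool
    # noise-driven violations across wide tau ranges and distort the
    # central levels
    if (length(off) >= 7) off <- stats::runmed(off, 7, endrule = "median")
    off <- stats::isoreg(seq_along(off), off)$yf
    model$params$b_r2 <- model$params$b_r2 + off / model$norm_sc
    attr(model, "recalibration_offsets") <- off
  }
  attr(model, "log") <- do.call(rbind, log[!vapply(log, is.null, TRUE)])
  attr(model, "best_epoch") <- best$epoch
  model
}
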