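#' Desk-scale training protocol on the synthetic corpus
#'
#' One self-contained reproduction of the study conditions at a scale a
#' single CPU handles in minutes: generate a synthetic corpus from the
#' surrogate shift model, embed one conformer per molecule, train the
#' quantile net, and return the model together with a held-out fixture
#' set for calibration checks.
#'
#' The desk scale is 3200 corpus molecules (duplicate structures appear
#' and are kept as independent entries, as a real corpus would), a
#' 48-wide net with 3 message-passing steps, Adam at 2.5e-3 decayed 4%
#' every 150 steps, batches of 48 molecules, at most 350 epochs with
#' patience 60. These sizes are the package's calibration-study design;
#' the full-scale defaults of [train_config()] remain available for
#' larger corpora.
#'
#' @param seed integer master seed; every stream (corpus, surrogate
#'   noise, weight init, batching, held-out fixtures) derives from it.
#' @param mono_weight crossing-penalty weight for the run (default 1).
#' @param n_molecules corpus size (default 3200).
#' @param n_heldout held-out fixture molecules (default 120).
#' @param corpus optional pre-built corpus from [desk_corpus()] with the
#'   same seed, so paired runs (e.g. with and without the crossing
#'   penalty) train on identical data.
#' @param verbose print training progress.
#' @return list with `model`, `surrogate`, `corpus`, `heldout` (molecules
#'   with conformers), and the three configs used.
#' @export
desk_train <- function(seed = 1, mono_weight = 1, n_molecules = 3200,
                       n_heldout = 120, corpus = NULL, verbose = FALSE) {
  seed <- as.integer(seed) %% 100000L
  sm <- surrogate_model(seed = seed + 3L)
  if (is.null(corpus)) corpus <- desk_corpus(seed, n_molecules)
  mcfg <- model_config(hidden = 48, readout_hidden = 48, seed = seed + 1L)
  tcfg <- train_config(max_epochs = 350, lr = 2.5e-3, decay = 0.04,
                       decay_interval = 150, batch_size = 48,
                       patience = 60, seed = seed + 2L)
  lcfg <- loss_config(mono_weight = mono_weight)
  # fresh molecules for quantile recalibration: exchangeable with future
  # prediction targets, unlike corpus members (which recur as duplicates
  # inside the training set and so have unrepresentatively small residuals)
  cal_mols <- generate_conformers(
    fixture_molecules(300, seed = seed + 2000L, prefix = "cal"),
    n_conf = 1, seed = 42)
  cal_corpus <- build_corpus(cal_mols,
                             lapply(lapply(cal_mols, simulate_spectrum,
                                           model = sm), `[[`, "spectrum"))
  model <- train(corpus, mcfg, tcfg, lcfg, cal_corpus = cal_corpus,
                 verbose = verbose)
  heldout <- generate_conformers(
    fixture_molecules(n_heldout, seed = seed + 1000L, prefix = "heldout"),
    n_conf = 1, seed = 42)
  list(model = model, surrogate = sm, corpus = corpus, heldout = heldout,
       model_config = mcfg, train_config = tcfg, loss_config = lcfg)
}

#' Build the desk-scale synthetic corpus
#'
#' Fixture molecules with one embedded conformer each, paired with their
#' simulated (class-assigned) surrogate spectra.
#'
#' @param seed master seed, as in [desk_train()].
#' @param n_molecules corpus size.
#' @return corpus list as from [build_corpus()].
#' @export
desk_corpus <- function(seed = 1, n_molecules = 3200) {
  seed <- as.integer(seed) %% 100000L
  sm <- surrogate_model(seed = seed + 3L)
  mols <- generate_conformers(fixture_molecules(n_molecules, seed = seed),
                              n_conf = 1, seed = 42)
  sims <- lapply(mols, simulate_spectrum, model = sm)
  build_corpus(mols, lapply(sims, `[[`, "spectrum"))
}

#' Calibration of a trained model against the surrogate ground truth
#'
#' On held-out molecules, compares predicted quantiles with the known true
#' quantiles `mean + sigma * qnorm(tau)` of the surrogate model and
#' reports: the mean absolute quantile deviation over tau in [0.1, 0.9]
#' expressed in units of the local sigma (`mad_sigma_ratio`), the
#' empirical coverage of the predicted interquartile interval for fresh
#' draws (`iq_coverage`), and the adjacent-quantile crossing rate of the
#' raw predictions (`crossing_rate`).
#'
#' @param model a trained `dp5q_model`.
#' @param heldout list of `mol_record` with conformers.
#' @param surrogate the [surrogate_model()] that generated the corpus.
#' @return list with `mad_sigma_ratio`, `mad_ppm`, `iq_coverage`,
#'   `crossing_rate`, `n_atoms`.
#' @export
calibration_report <- function(model, heldout, surrogate) {
  taus <- as.numeric(model$config$grid)
  sel <- taus >= 0.1 & taus <= 0.9
  i25 <- which.min(abs(taus - 0.25)); i75 <- which.min(abs(taus - 0.75))
  ratios <- c(); devs <- c(); cover <- c(); crossings <- 0; npairs <- 0
  for (mol in heldout) {
    tr <- surrogate_truth(mol, surrogate)
    pred <- predict_quantiles(model, mol)
    crossings <- crossings + sum(apply(unclass(pred), 1,
                                       function(v) sum(diff(v) < 0)))
    npairs <- npairs + nrow(pred) * (length(taus) - 1)
    sim <- simulate_spectrum(mol, surrogate)
    for (r in seq_len(nrow(tr))) {
      i <- match(tr$atom[r], attr(pred, "atoms"))
      true_q <- tr$mean[r] + tr$sigma[r] * qnorm(taus)
      dev <- mean(abs(pred[i, sel] - true_q[sel]))
      devs <- c(devs, dev); ratios <- c(ratios, dev / tr$sigma[r])
    }
    for (ci in seq_along(mol$carbon_classes)) {
      a <- mol$carbon_classes[[ci]][1]; i <- match(a, attr(pred, "atoms"))
      y <- sim$spectrum$shifts[ci]
      cover <- c(cover, y >= pred[i, i25] && y <= pred[i, i75])
    }
  }
  list(mad_sigma_ratio = mean(ratios), mad_ppm = mean(devs),
       iq_coverage = mean(cover), crossing_rate = crossings / npairs,
       n_atoms = length(devs))
}
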