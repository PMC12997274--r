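#' @importFrom Matrix sparseMatrix crossprod
NULL

#' Model configuration
#'
#' Architecture of the quantile-regression graph net: an edge-conditioned
#' message-passing network over heavy atoms whose geometry enters only
#' through interatomic distances (hence predictions are invariant to
#' translation and rotation of the conformer), with a per-atom readout MLP
#' whose final layer has one output per quantile of the grid.
#'
#' @param hidden hidden width of the node embeddings (default 64).
#' @param steps number of message-passing steps (default 3; the shift
#'   model's gamma-neighbour effects need three bonds of context).
#' @param readout_hidden width of the readout MLP hidden layer.
#' @param n_rbf number of radial basis functions expanding each edge
#'   distance (default 32).
#' @param cutoff distance cutoff in angstrom for edges (default 5).
#' @param grid a [quantile_grid()].
#' @param seed integer; fixes the weight initialisation, so identical
#'   config + seed gives bitwise-identical models.
#' @return object of class `model_config`.
#' @export
model_config <- function(hidden = 64, steps = 3, readout_hidden = 64,
                         n_rbf = 32, cutoff = 5, grid = quantile_grid(),
                         seed = 1) {
  stopifnot(hidden >= 1, steps >= 1, readout_hidden >= 1, n_rbf >= 1,
            cutoff > 0)
  structure(list(hidden = hidden, steps = steps,
                 readout_hidden = readout_hidden, n_rbf = n_rbf,
                 cutoff = cutoff, grid = grid, seed = as.integer(seed)),
            class = "model_config")
}

.feature_elements <- c("B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
.n_node_features <- length(.feature_elements) + 5L

#' Featurise one conformer of a molecule for the graph net
#'
#' Node features: element one-hot over the allowed heavy-atom set plus
#' scaled attached-hydrogen count, heavy-atom degree, total bond order,
#' ring and aromatic flags (all derived from the 2D graph, hence
#' geometry-independent). Edges connect every atom pair within the distance
#' cutoff, in both directions; the edge feature is the interatomic distance
#' expanded in Gaussian radial basis functions, concatenated with a
#' bond-order one-hot (none/single/aromatic/double/triple). Deterministic.
#'
#' @param mol a `mol_record`.
#' @param conformer index of the conformer to use.
#' @param config a [model_config()] (controls cutoff and basis count).
#' @return list with `x` (nodes x features), `src`, `dst` (edge endpoint
#'   indices), `rbf` (edges x n_rbf), `carbon_idx`, `n_atoms`.
#' @export
featurize <- function(mol, conformer = 1, config = model_config()) {
  if (conformer > length(mol$conformers) || conformer < 1)
    stop("molecule '", mol$name, "' has no conformer ", conformer,
         "; generate conformers first (see generate_conformers)")
  xyz <- mol$conformers[[conformer]]
  n <- nrow(mol$atoms)
  el <- mol$atoms$element
  rings <- perceive_rings(mol)
  x <- matrix(0, n, .n_node_features)
  x[cbind(seq_len(n), match(el, .feature_elements))] <- 1
  deg <- numeric(n); bord <- numeric(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      o <- if (mol$bonds$order[k] == 4) 1.5 else mol$bonds$order[k]
      deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1
      bord[i] <- bord[i] + o; bord[j] <- bord[j] + o
    }
  }
  x[, length(.feature_elements) + 1L] <- mol$atoms$nH / 4
  x[, length(.feature_elements) + 2L] <- deg / 4
  x[, length(.feature_elements) + 3L] <- bord / 4
  x[, length(.feature_elements) + 4L] <- as.numeric(rings$ring_atom)
  x[, length(.feature_elements) + 5L] <- as.numeric(rings$aromatic_atom)
  d2 <- as.matrix(stats::dist(xyz))
  hit <- which(d2 <= config$cutoff & upper.tri(d2), arr.ind = TRUE)
  src <- c(hit[, 1], hit[, 2]); dst <- c(hit[, 2], hit[, 1])
  dvals <- c(d2[hit], d2[hit])
  centers <- seq(0, config$cutoff, length.out = config$n_rbf)
  width <- if (config$n_rbf > 1) centers[2] - centers[1] else config$cutoff
  rbf <- exp(-outer(dvals, centers, function(d, m) (d - m)^2) / (2 * width^2))
  # bond-order one-hot appended to the distance expansion: none / single /
  # aromatic / double / triple, symmetric in the edge direction
  bmat <- matrix(0, n, n)
  if (nrow(mol$bonds)) {
    ords <- ifelse(rings$aromatic_bond, 1.5, mol$bonds$order)
    bmat[cbind(mol$bonds$i, mol$bonds$j)] <- ords
    bmat[cbind(mol$bonds$j, mol$bonds$i)] <- ords
  }
  bvals <- c(bmat[hit], bmat[hit])
  bf <- matrix(0, length(bvals), 5)
  bf[cbind(seq_along(bvals), match(bvals, c(0, 1, 1.5, 2, 3)))] <- 1
  list(x = x, src = src, dst = dst, rbf = cbind(rbf, bf),
       carbon_idx = which(el == "C"), n_atoms = n)
}

# combine per-molecule featurisations into one batch with index offsets and
# the sparse scatter matrices used by forward/backward passes
.batch_features <- function(feats) {
  offs <- cumsum(c(0, vapply(feats, `[[`, 0, "n_atoms")))
  n <- offs[length(offs)]
  x <- do.call(rbind, lapply(feats, `[[`, "x"))
  src <- unlist(lapply(seq_along(feats), function(k) feats[[k]]$src + offs[k]))
  dst <- unlist(lapply(seq_along(feats), function(k) feats[[k]]$dst + offs[k]))
  rbf <- do.call(rbind, lapply(feats, `[[`, "rbf"))
  carbon_idx <- unlist(lapply(seq_along(feats), function(k)
    feats[[k]]$carbon_idx + offs[k]))
  ne <- length(src)
  s_dst <- Matrix::sparseMatrix(i = dst, j = seq_len(ne), x = 1, dims = c(n, ne))
  s_src <- Matrix::sparseMatrix(i = src, j = seq_len(ne), x = 1, dims = c(n, ne))
  list(x = x, src = src, rbf = rbf, carbon_idx = carbon_idx,
       n = n, s_dst = s_dst, s_src = s_src,
       mol_of_carbon = unlist(lapply(seq_along(feats), function(k)
         rep(k, length(feats[[k]]$carbon_idx)))))
}

.glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

#' Build an untrained quantile model
#'
#' Weights are initialised reproducibly from the config seed. The output
#' head's final weight matrix starts at zero, so an untrained model
#' predicts the (de-normalised) output bias for every atom and quantile.
#' Target normalisation (`norm_mu`, `norm_sc`, ppm) maps shifts to an
#' order-one internal scale and is refitted from the corpus by [train()].
#'
#' @param config a [model_config()].
#' @return object of class `dp5q_model`.
#' @export
build_model <- function(config = model_config()) {
  d <- config$hidden; h <- config$readout_hidden
  q <- length(config$grid); k <- config$n_rbf + 5L  # distance RBF + bond one-hot
  params <- .with_seed(config$seed, {
    p <- list(W_in = .glorot(.n_node_features, d), b_in = numeric(d),
              steps = lapply(seq_len(config$steps), function(t)
                list(W_e = .glorot(k, d), W_s = .glorot(d, d),
                     W_u = .glorot(d, d), b = numeric(d))),
              W_r1 = .glorot(d, h), b_r1 = numeric(h),
              W_r2 = matrix(0, h, q), b_r2 = numeric(q))
    p
  })
  structure(list(config = config, params = params,
                 norm_mu = 100, norm_sc = 60),
            class = "dp5q_model")
}

# forward pass over a feature batch; keep = TRUE retains intermediates for
# the backward pass
.forward <- function(model, fb, keep = FALSE) {
  p <- model$params
  pre0 <- sweep(fb$x %*% p$W_in, 2, p$b_in, "+")
  H <- tanh(pre0)
  cache <- if (keep) list(H0 = H, steps = vector("list", length(p$steps)))
  for (t in seq_along(p$steps)) {
    st <- p$steps[[t]]
    G <- fb$rbf %*% st$W_e
    HJ <- H[fb$src, , drop = FALSE]
    Magg <- as.matrix(fb$s_dst %*% (G * HJ))
    A <- sweep(H %*% st$W_s + Magg %*% st$W_u, 2, st$b, "+")
    TA <- tanh(A)
    if (keep) cache$steps[[t]] <- list(H_in = H, G = G, HJ = HJ,
                                       Magg = Magg, TA = TA)
    H <- H + TA
  }
  Hc <- H[fb$carbon_idx, , drop = FALSE]
  preR <- sweep(Hc %*% p$W_r1, 2, p$b_r1, "+")
  Rr <- tanh(preR)
  Z <- sweep(Rr %*% p$W_r2, 2, p$b_r2, "+")
  Y <- model$norm_mu + model$norm_sc * Z
  if (keep) { cache$Hc <- Hc; cache$Rr <- Rr }
  list(Y = Y, cache = cache)
}

# backward pass: gradient of a scalar loss wrt all parameters, given dY
.backward <- function(model, fb, cache, dY) {
  p <- model$params
  dZ <- dY * model$norm_sc
  g <- list()
  g$W_r2 <- crossprod(cache$Rr, dZ)
  g$b_r2 <- colSums(dZ)
  dRr <- dZ %*% t(p$W_r2)
  dPreR <- dRr * (1 - cache$Rr^2)
  g$W_r1 <- crossprod(cache$Hc, dPreR)
  g$b_r1 <- colSums(dPreR)
  dH <- matrix(0, fb$n, ncol(cache$H0))
  dH[fb$carbon_idx, ] <- dPreR %*% t(p$W_r1)
  g$steps <- vector("list", length(p$steps))
  for (t in rev(seq_along(p$steps))) {
    st <- p$steps[[t]]; cc <- cache$steps[[t]]
    dA <- dH * (1 - cc$TA^2)
    gs <- list(W_s = crossprod(cc$H_in, dA),
               W_u = crossprod(cc$Magg, dA),
               b = colSums(dA))
    dMagg <- dA %*% t(st$W_u)
    dMmsg <- as.matrix(Matrix::crossprod(fb$s_dst, dMagg))
    gs$W_e <- crossprod(fb$rbf, dMmsg * cc$HJ)
    dHJ <- dMmsg * cc$G
    dH <- dH + dA %*% t(st$W_s) + as.matrix(fb$s_src %*% dHJ)
    g$steps[[t]] <- gs
  }
  dPre0 <- dH * (1 - cache$H0^2)
  g$W_in <- crossprod(fb$x, dPre0)
  g$b_in <- colSums(dPre0)
  g
}

#' Predict shift quantiles for every carbon atom
#'
#' Runs the graph net on one conformer and returns, for each carbon, the
#' predicted inverse CDF of its chemical shift evaluated on the quantile
#' grid. Deterministic; non-carbon atoms are excluded.
#'
#' @param model a trained (or freshly built) `dp5q_model`.
#' @param mol a `mol_record` with at least the indexed conformer.
#' @param conformer conformer index (default 1).
#' @return a `quantile_prediction`: numeric matrix (carbons x quantiles)
#'   with attributes `taus` (the grid) and `atoms` (carbon atom indices).
#' @export
predict_quantiles <- function(model, mol, conformer = 1) {
  fb <- .batch_features(list(featurize(mol, conformer, model$config)))
  Y <- .forward(model, fb)$Y
  structure(Y, taus = as.numeric(model$config$grid),
            atoms = fb$carbon_idx, class = "quantile_prediction")
}

#' Predict over a conformer ensemble
#'
#' The per-atom quantile vector is the weighted arithmetic mean of the
#' single-conformer predictions (the quantile-function average, which
#' preserves ordering). Default weights are uniform; supply
#' [boltzmann_weights()] of conformer energies for thermal weighting.
#'
#' @param model a `dp5q_model`.
#' @param mol a `mol_record` with conformers.
#' @param conformers indices of conformers to include (default: all).
#' @param weights optional non-negative weights summing to 1, one per
#'   included conformer.
#' @return a `quantile_prediction` as in [predict_quantiles()].
#' @export
predict_ensemble <- function(model, mol, conformers = NULL, weights = NULL) {
  if (is.null(conformers)) conformers <- seq_along(mol$conformers)
  stopifnot(length(conformers) >= 1)
  if (is.null(weights)) weights <- rep(1 / length(conformers), length(conformers))
  if (length(weights) != length(conformers))
    stop("weights length (", length(weights),
         ") does not match conformer count (", length(conformers), ")")
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-8)
  preds <- lapply(conformers, function(ci) predict_quantiles(model, mol, ci))
  out <- Reduce(`+`, Map(function(p, w) unclass(p) * w, preds, weights))
  structure(out, taus = attr(preds[[1]], "taus"),
            atoms = attr(preds[[1]], "atoms"), class = "quantile_prediction")
}

#' Predicted class medians from a quantile prediction
#'
#' The median of each carbon equivalence class: the tau = 0.5 entry (or the
#' interpolated median if 0.5 is absent from the grid), averaged over the
#' atoms of the class.
#'
#' @param pred a `quantile_prediction`.
#' @param mol the corresponding `mol_record`.
#' @return numeric vector, one median shift (ppm) per carbon class.
#' @export
class_medians <- function(pred, mol) {
  taus <- attr(pred, "taus")
  med <- apply(unclass(pred), 1, function(v) .median_of(v, taus))
  atom_of <- attr(pred, "atoms")
  vapply(mol$carbon_classes, function(cl)
    mean(med[match(cl, atom_of)]), numeric(1))
}

.median_of <- function(v, taus) {
  i <- which(taus == 0.5)
  if (length(i)) return(v[i])
  stats::approx(taus, v, xout = 0.5, rule = 2)$y
}

#' Save / load a model
#'
#' Checkpoints are JSON with the config embedded, so a reloaded model
#' reproduces predictions exactly.
#'
#' @param model a `dp5q_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  obj <- list(config = list(hidden = model$config$hidden,
                            steps = model$config$steps,
                            readout_hidden = model$config$readout_hidden,
                            n_rbf = model$config$n_rbf,
                            cutoff = model$config$cutoff,
                            taus = as.numeric(model$config$grid),
                            seed = model$config$seed),
              norm_mu = model$norm_mu, norm_sc = model$norm_sc,
              params = model$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  cfg <- model_config(hidden = obj$config$hidden, steps = obj$config$steps,
                      readout_hidden = obj$config$readout_hidden,
                      n_rbf = obj$config$n_rbf, cutoff = obj$config$cutoff,
                      grid = quantile_grid(obj$config$taus),
                      seed = obj$config$seed)
  model <- build_model(cfg)
  model$norm_mu <- obj$norm_mu; model$norm_sc <- obj$norm_sc
  p <- obj$params
  model$params$W_in <- as.matrix(p$W_in); model$params$b_in <- as.numeric(p$b_in)
  model$params$W_r1 <- as.matrix(p$W_r1); model$params$b_r1 <- as.numeric(p$b_r1)
  model$params$W_r2 <- as.matrix(p$W_r2); model$params$b_r2 <- as.numeric(p$b_r2)
  for (t in seq_along(model$params$steps)) {
    st <- p$steps[[t]]
    model$params$steps[[t]] <- list(W_e = as.matrix(st$W_e),
                                    W_s = as.matrix(st$W_s),
                                    W_u = as.matrix(st$W_u),
                                    b = as.numeric(st$b))
  }
  model
}
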