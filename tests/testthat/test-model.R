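# shared small fixtures for model tests
local_mols <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_conformers(
        list(parse_smiles("CC(C)CO"), parse_smiles("Cc1ccccc1"),
             parse_smiles("CC(=O)OCC")), n_conf = 2, seed = 42)
    cache
  }
})

test_that("featurisation respects the cutoff and geometry invariances", {
  cfg <- model_config(cutoff = 5, n_rbf = 16)
  two <- mol_record(c("C", "C"), data.frame(i = 1, j = 2, order = 1),
                    conformers = list(rbind(c(0, 0, 0), c(1.5, 0, 0))))
  f <- featurize(two, 1, cfg)
  expect_equal(length(f$src), 2)   # one pair, both directions
  centers <- seq(0, 5, length.out = 16)
  expect_equal(centers[which.max(f$rbf[1, 1:16])], centers[which.min(abs(centers - 1.5))])

  far <- mol_record(c("C", "C"), data.frame(i = 1, j = 2, order = 1),
                    conformers = list(rbind(c(0, 0, 0), c(6, 0, 0))))
  expect_length(featurize(far, 1, cfg)$src, 0)

  expect_error(featurize(parse_smiles("CC"), 1, cfg), "conformer")
})

test_that("predictions are invariant to rotation and translation", {
  mol <- local_mols()[[1]]
  model <- build_model(model_config(seed = 4))
  model$params$W_r2[] <- 0.01
  p1 <- predict_quantiles(model, mol)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mol2 <- mol
  mol2$conformers[[1]] <- sweep(mol$conformers[[1]] %*% rot, 2, c(3, -2, 7), "+")
  p2 <- predict_quantiles(model, mol2)
  expect_lt(max(abs(p1 - p2)), 1e-5)
})

test_that("predictions are equivariant under atom permutation", {
  mol <- local_mols()[[3]]
  cfg <- model_config(seed = 6, grid = quantile_grid(c(0.25, 0.5, 0.75)))
  model <- build_model(cfg)
  model$params$W_r2[] <- 0.02
  p1 <- predict_quantiles(model, mol)
  n <- nrow(mol$atoms)
  set.seed(11); perm <- sample(n)    # position k gets old atom perm[k]
  inv <- order(perm)
  mol2 <- mol_record(mol$atoms$element[perm],
                     data.frame(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                                order = mol$bonds$order),
                     nH = mol$atoms$nH[perm],
                     conformers = list(mol$conformers[[1]][perm, ]))
  p2 <- predict_quantiles(model, mol2)
  a1 <- attr(p1, "atoms"); a2 <- attr(p2, "atoms")
  for (k in seq_along(a1)) {
    new_pos <- inv[a1[k]]
    expect_equal(unclass(p2)[match(new_pos, a2), ], unclass(p1)[k, ],
                 tolerance = 1e-10)
  }
})

test_that("untrained zero-head model predicts the output bias everywhere", {
  cfg <- model_config(seed = 2, grid = quantile_grid(c(0.1, 0.5, 0.9)))
  model <- build_model(cfg)
  model$params$b_r2 <- c(-0.5, 0, 0.5)
  p <- predict_quantiles(model, local_mols()[[2]])
  expect_equal(ncol(p), 3)
  expected <- model$norm_mu + model$norm_sc * model$params$b_r2
  for (k in seq_len(nrow(p)))
    expect_equal(unclass(p)[k, ], expected)
})

test_that("identical config and seed give bitwise-identical predictions", {
  cfg <- model_config(seed = 31)
  m1 <- build_model(cfg); m2 <- build_model(cfg)
  mol <- local_mols()[[1]]
  expect_identical(predict_quantiles(m1, mol), predict_quantiles(m2, mol))
})

test_that("ensemble prediction averages conformer quantile vectors", {
  mol <- local_mols()[[2]]
  model <- build_model(model_config(seed = 9))
  model$params$W_r2[] <- 0.015
  p1 <- predict_quantiles(model, mol, 1)
  p2 <- predict_quantiles(model, mol, 2)
  expect_equal(unclass(predict_ensemble(model, mol, 1)), unclass(p1))
  pe <- predict_ensemble(model, mol, c(1, 2), weights = c(1, 0))
  expect_equal(unclass(pe), unclass(p1))
  pu <- predict_ensemble(model, mol, c(1, 2))
  expect_equal(unclass(pu), (unclass(p1) + unclass(p2)) / 2)
  # invariant to conformer ordering
  expect_equal(unclass(predict_ensemble(model, mol, c(2, 1))), unclass(pu))
  expect_error(predict_ensemble(model, mol, c(1, 2), weights = 1),
               "conformer count")
})

test_that("model save/load round-trips predictions exactly", {
  model <- build_model(model_config(seed = 13, hidden = 16,
                                    readout_hidden = 12, n_rbf = 8))
  model$params$W_r2[] <- 0.03
  mol <- local_mols()[[1]]
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(unclass(predict_quantiles(back, mol)),
               unclass(predict_quantiles(model, mol)), tolerance = 1e-12)
})
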