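test_that("fixture generation is reproducible and curation-clean", {
  a <- fixture_molecules(8, seed = 1)
  b <- fixture_molecules(8, seed = 1)
  expect_identical(lapply(a, function(m) m[c("atoms", "bonds", "formula")]),
                   lapply(b, function(m) m[c("atoms", "bonds", "formula")]))
  for (m in a) {
    expect_equal(n_fragments(m), 1L)
    expect_true(all(m$atoms$element %in%
                      setdiff(dp5q:::ALLOWED_ELEMENTS, "H")))
    expect_gte(sum(m$atoms$element == "C"), 1)
  }
  expect_false(identical(lapply(a, `[[`, "bonds"),
                         lapply(fixture_molecules(8, seed = 2), `[[`, "bonds")))
})

test_that("zero-noise surrogate spectra equal the table means exactly", {
  sm0 <- surrogate_model(seed = 5, sigma_scale = 0)
  mol <- parse_smiles("CCO")
  sim <- simulate_spectrum(mol, sm0)
  expect_equal(sort(sim$spectrum$shifts), sort(sim$class_mean))
})

test_that("simulated draws follow the stated normal model", {
  mol <- parse_smiles("CC")   # one class
  sm <- surrogate_model(seed = 1)
  tr <- surrogate_truth(mol, sm)
  draws <- vapply(seq_len(4000), function(k) {
    m2 <- mol; m2$name <- paste0("rep", k)   # independent entries
    simulate_spectrum(m2, sm)$spectrum$shifts[1]
  }, numeric(1))
  se <- tr$sigma[1] / sqrt(length(draws))
  expect_lt(abs(mean(draws) - tr$mean[1]), 3 * se)
  ks <- suppressWarnings(stats::ks.test(draws, "pnorm", tr$mean[1], tr$sigma[1]))
  expect_gt(ks$p.value, 0.01)
  # different seeds give different shifts
  expect_false(isTRUE(all.equal(
    simulate_spectrum(mol, surrogate_model(seed = 1))$spectrum$shifts,
    simulate_spectrum(mol, surrogate_model(seed = 2))$spectrum$shifts)))
  # numeric sanity: draws within 6 sigma
  expect_true(all(abs(draws - tr$mean[1]) < 6 * tr$sigma[1]))
})

test_that("true quantile function matches mean + sigma * qnorm(tau)", {
  mol <- parse_smiles("CCCO")
  sim <- simulate_spectrum(mol, surrogate_model(seed = 3))
  for (ci in seq_along(mol$carbon_classes)) {
    expect_equal(sim$true_quantile(ci, c(0.1, 0.5, 0.9)),
                 sim$class_mean[ci] + sim$class_sigma[ci] * qnorm(c(0.1, 0.5, 0.9)))
  }
})

test_that("surrogate means span a realistic carbon shift range", {
  tr <- do.call(rbind, lapply(fixture_molecules(40, seed = 6),
                              surrogate_truth))
  expect_gt(min(tr$mean), -20)
  expect_lt(max(tr$mean), 230)
  expect_gt(diff(range(tr$mean)), 150)   # spans sp3 through carbonyl
  expect_true(all(tr$sigma > 0))
})

test_that("benchmark pair counts follow the formula-restricted N^2 - N rule", {
  # all-distinct formulae: no incorrect pairs
  pool <- list(parse_smiles("CCO"), parse_smiles("CCC"), parse_smiles("CCN"))
  b <- make_benchmark(pool, surrogate_model())
  expect_equal(sum(b$label == "correct"), 3)
  expect_equal(sum(b$label == "incorrect"), 0)
  # two constitutional isomers: 2 correct + 2 incorrect
  iso2 <- list(parse_smiles("CCCO"), parse_smiles("CC(C)O"))
  b2 <- make_benchmark(iso2, surrogate_model())
  expect_equal(as.vector(table(b2$label)), c(2, 2))
  # full isomer family: equality with N^2 - N
  fam <- fixture_isomers(6, seed = 2)
  expect_length(unique(vapply(fam, `[[`, "", "formula")), 1)
  b3 <- make_benchmark(fam, surrogate_model())
  expect_equal(sum(b3$label == "incorrect"), 6^2 - 6)
  # no pair is both correct and incorrect
  expect_false(any(duplicated(b3[c("structure", "spectrum")])))
})

test_that("isomer generator yields distinct constitutions, same formula", {
  fam <- fixture_isomers(15, n_carbon = 8, seed = 9)
  expect_length(fam, 15)
  expect_length(unique(vapply(fam, `[[`, "", "formula")), 1)
  keys <- vapply(fam, function(m) {
    paste(sort(paste(pmin(m$bonds$i, m$bonds$j), pmax(m$bonds$i, m$bonds$j),
                     m$atoms$element[m$bonds$i], m$atoms$element[m$bonds$j])),
          collapse = ";")
  }, "")
  expect_false(any(duplicated(keys)))   # weaker than canonical, still useful
  expect_identical(
    lapply(fixture_isomers(5, seed = 4), `[[`, "bonds"),
    lapply(fixture_isomers(5, seed = 4), `[[`, "bonds"))
})
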