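# small raw corpus with known defects, built in code
make_raw <- function() {
  good1 <- parse_smiles("CCO")
  good2 <- parse_smiles("CCC")
  salt <- mol_record(c("C", "C", "O", "O", "Na"),
                     data.frame(i = c(1, 2, 2), j = c(2, 3, 4),
                                order = c(1, 2, 1)), nH = c(3, 0, 0, 0, 0))
  silane <- mol_record(c("C", "Si"), data.frame(i = 1, j = 2, order = 1),
                       nH = c(3, 3))
  sp <- function(m) simulate_spectrum(m, surrogate_model(seed = 1))$spectrum
  raw_corpus(list(good1, good2, salt, silane, good1),
             list(sp(good1), NULL, sp(good1), sp(silane), sp(good1)))
}

test_that("spectrum-presence filter drops missing and empty spectra", {
  recs <- make_raw()
  kept <- filter_has_carbon_spectrum(recs)
  expect_length(kept, 4)
  recs[[1]]$spectrum <- shift_spectrum(numeric(0))
  expect_length(filter_has_carbon_spectrum(recs), 3)
})

test_that("fragment filter matches a flood-fill component count", {
  flood_components <- function(mol) {
    n <- nrow(mol$atoms)
    adj <- lapply(seq_len(n), function(i)
      c(mol$bonds$j[mol$bonds$i == i], mol$bonds$i[mol$bonds$j == i]))
    seen <- logical(n); ncomp <- 0
    for (s in seq_len(n)) {
      if (seen[s]) next
      ncomp <- ncomp + 1
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (seen[v]) next
        seen[v] <- TRUE
        queue <- c(queue, adj[[v]][!seen[adj[[v]]]])
      }
    }
    ncomp
  }
  for (mol in fixture_molecules(50, seed = 12))
    expect_equal(n_fragments(mol), flood_components(mol))
  salt <- make_raw()[[3]]$mol
  expect_equal(n_fragments(salt), 2L)
  expect_equal(flood_components(salt), 2)
})

test_that("element filter enforces the 11-element allowed set", {
  recs <- make_raw()
  kept <- filter_elements(recs)
  expect_false(any(vapply(kept, function(r)
    "Si" %in% r$mol$atoms$element, logical(1))))
  bromo <- list(mol = parse_smiles("Brc1ccccc1"), spectrum = NULL)
  ferrocene_ish <- list(mol = mol_record(c("C", "Fe"),
                                         data.frame(i = 1, j = 2, order = 1),
                                         nH = c(3, 0)), spectrum = NULL)
  expect_length(filter_elements(list(bromo, ferrocene_ish)), 1)
})

test_that("the 50 ppm outlier rule uses a strict per-peak boundary", {
  mol <- parse_smiles("CCO")
  obs <- shift_spectrum(c(60, 18))
  rec <- function(devs) list(mol = mol, spectrum = obs,
                             ref_shifts = obs$shifts + devs)
  expect_length(filter_shift_outliers(list(rec(c(49.9, 0)))), 1)  # kept
  expect_length(filter_shift_outliers(list(rec(c(50, 0)))), 1)    # boundary kept
  expect_length(filter_shift_outliers(list(rec(c(51, 0)))), 0)    # removed
  expect_length(filter_shift_outliers(list(rec(c(0, -51)))), 0)
  expect_length(filter_shift_outliers(list(rec(c(500, 0))),
                                      threshold = Inf), 1)
  expect_error(filter_shift_outliers(
    list(list(mol = mol, spectrum = obs, ref_shifts = 1))), "reference")
})

test_that("the chain conserves counts, retains duplicates, is idempotent", {
  recs <- make_raw()
  out <- curate(recs)
  rep <- attr(out, "report")
  expect_equal(rep$records_in, 5)
  expect_equal(rep$records_out,
               rep$records_in - rep$removed_no_carbon_spectrum -
                 rep$removed_multi_fragment - rep$removed_disallowed_element -
                 rep$removed_shift_outlier)
  # the two byte-identical ethanol records both survive
  expect_equal(sum(vapply(out, function(r) r$mol$formula == "C2H6O",
                          logical(1))), 2)
  again <- curate(out)
  expect_equal(length(again), length(out))
  expect_equal(attr(again, "report")$records_out,
               attr(again, "report")$records_in)
})
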