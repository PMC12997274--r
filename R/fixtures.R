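#' @importFrom stats rnorm qnorm runif
NULL

# ---------------------------------------------------------------------------
# Surrogate carbon-13 shift model
#
# Emulates an experimentally assigned corpus: every carbon gets a
# deterministic "true" mean shift from its local environment plus additive
# neighbour-count increments, and observed peaks are drawn from
# Normal(mean, sigma(class)) with a class-dependent sigma. Closed-form true
# quantiles mean + sigma * qnorm(tau) make calibration exactly checkable.
# ---------------------------------------------------------------------------

.surrogate_base <- c(sp3 = -5, alkene = 118, aromatic = 110,
                     carbonyl = 205, sp = 70)

.surrogate_sigma <- c(sp3 = 1.6, alkene = 2.2, aromatic = 1.9,
                      carbonyl = 2.4, sp = 2.1)

# additive increments (ppm per neighbour), by environment group
.surrogate_inc <- list(
  sp3 = c(C_a = 9.1, C_b = 9.4, C_g = -2.5, O_a = 43, O_b = 8,
          N_a = 26, N_b = 5, S_a = 11, P_a = 8, B_a = 4,
          F_a = 68, Cl_a = 31, Br_a = 19, I_a = -7, X_b = 8, ring = 2),
  alkene = c(C_a = 7, C_b = 2, C_g = -1, O_a = 25, O_b = 1,
             N_a = 18, N_b = 1, S_a = 9, P_a = 5, B_a = 3,
             F_a = 33, Cl_a = 5, Br_a = -4, I_a = -32, X_b = 1, ring = 0),
  aromatic = c(C_a = 6.5, C_b = 1.5, C_g = -0.8, O_a = 22, O_b = 1,
               N_a = 16, N_b = 1, S_a = 8, P_a = 4, B_a = 3,
               F_a = 28, Cl_a = 4, Br_a = -5, I_a = -28, X_b = 1, ring = 0),
  carbonyl = c(C_a = 8, C_b = 1.5, C_g = 0, O_a = -35, O_b = 0,
               N_a = -25, N_b = 0, S_a = -10, P_a = 0, B_a = 0,
               F_a = -20, Cl_a = -15, Br_a = -15, I_a = -15, X_b = 0, ring = -3),
  sp = c(C_a = 8, C_b = 2, C_g = 0, O_a = 18, O_b = 0,
         N_a = 48, N_b = 0, S_a = 10, P_a = 0, B_a = 0,
         F_a = 0, Cl_a = 0, Br_a = 0, I_a = 0, X_b = 0, ring = 0))

#' Surrogate shift model for synthetic corpora
#'
#' A deterministic ground-truth model standing in for an experimentally
#' assigned shift table. Each carbon's mean shift is a base value for its
#' environment class (sp3, alkene, aromatic, carbonyl, sp) plus additive
#' increments per alpha/beta/gamma neighbour, in the style of empirical
#' additivity rules; the observation noise is Gaussian with a
#' class-dependent standard deviation. True quantiles are
#' `mean + sigma * qnorm(tau)`.
#'
#' @param seed integer; fixes all simulated draws.
#' @param sigma_scale multiplier on the class sigmas (0 gives noise-free
#'   spectra equal to the table means).
#' @return object of class `surrogate_model`.
#' @export
surrogate_model <- function(seed = 1, sigma_scale = 1) {
  stopifnot(sigma_scale >= 0)
  structure(list(base = .surrogate_base,
                 sigma = .surrogate_sigma * sigma_scale,
                 inc = .surrogate_inc, seed = as.integer(seed)),
            class = "surrogate_model")
}

# Per-atom environment description used by the surrogate model: class label
# plus alpha/beta/gamma neighbour counts on the heavy-atom graph.
atom_environments <- function(mol) {
  n <- nrow(mol$atoms); el <- mol$atoms$element
  rings <- perceive_rings(mol)
  maxord <- rep(1, n)
  dbl_o <- logical(n)   # carbon double-bonded to O (carbonyl)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
      maxord[i] <- max(maxord[i], o); maxord[j] <- max(maxord[j], o)
      if (o == 2) {
        if (el[i] == "C" && el[j] == "O") dbl_o[i] <- TRUE
        if (el[j] == "C" && el[i] == "O") dbl_o[j] <- TRUE
      }
    }
  }
  cls <- ifelse(maxord >= 3, "sp",
         ifelse(dbl_o, "carbonyl",
         ifelse(rings$aromatic_atom, "aromatic",
         ifelse(maxord == 2 | maxord == 4, "alkene", "sp3"))))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(mol$bonds)) g <- igraph::add_edges(g, t(cbind(mol$bonds$i, mol$bonds$j)))
  D <- igraph::distances(g)
  halogens <- c("F", "Cl", "Br", "I")
  env <- vector("list", n)
  for (a in seq_len(n)) {
    a1 <- which(D[a, ] == 1); a2 <- which(D[a, ] == 2); a3 <- which(D[a, ] == 3)
    counts <- c(C_a = sum(el[a1] == "C"), C_b = sum(el[a2] == "C"),
                C_g = sum(el[a3] == "C"),
                O_a = sum(el[a1] == "O"), O_b = sum(el[a2] == "O"),
                N_a = sum(el[a1] == "N"), N_b = sum(el[a2] == "N"),
                S_a = sum(el[a1] == "S"), P_a = sum(el[a1] == "P"),
                B_a = sum(el[a1] == "B"),
                F_a = sum(el[a1] == "F"), Cl_a = sum(el[a1] == "Cl"),
                Br_a = sum(el[a1] == "Br"), I_a = sum(el[a1] == "I"),
                X_b = sum(el[a2] %in% halogens),
                ring = as.integer(rings$ring_atom[a] && !rings$aromatic_atom[a]))
    env[[a]] <- list(class = cls[a], counts = counts)
  }
  env
}

#' True per-carbon mean shifts and sigmas under a surrogate model
#'
#' @param mol a `mol_record` with at least one carbon.
#' @param model a [surrogate_model()].
#' @return data frame with one row per carbon atom: `atom`, `class`,
#'   `mean` (ppm) and `sigma` (ppm).
#' @export
surrogate_truth <- function(mol, model = surrogate_model()) {
  carbons <- which(mol$atoms$element == "C")
  if (!length(carbons)) stop("molecule has no carbon")
  env <- atom_environments(mol)
  res <- lapply(carbons, function(a) {
    e <- env[[a]]
    if (!e$class %in% names(model$base))
      stop("environment key missing from base table: ", e$class)
    inc <- model$inc[[e$class]]
    # carbonyl oxygens counted as substituent effects only when single-bonded
    cnt <- e$counts
    if (e$class == "carbonyl") cnt["O_a"] <- cnt["O_a"] - 1
    data.frame(atom = a, class = e$class,
               mean = unname(model$base[e$class] + sum(inc[names(cnt)] * cnt)),
               sigma = unname(model$sigma[e$class]))
  })
  do.call(rbind, res)
}

# deterministic small string hash (djb2, kept below 2^28)
.str_hash <- function(s) {
  h <- 5381
  for (c in utf8ToInt(s)) h <- (h * 33 + c) %% 268435456
  as.integer(h %% 2147483)
}

# run expr with a local, seeded RNG stream, restoring global state after
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an assigned carbon spectrum for a molecule
#'
#' Draws one observed shift per carbon equivalence class from
#' `Normal(mean(class), sigma(class))` under the surrogate model. The draw
#' is deterministic given (molecule, model seed). Alongside the spectrum, a
#' true quantile function for each class is returned as the calibration
#' ground truth.
#'
#' @param mol a `mol_record` with at least one carbon.
#' @param model a [surrogate_model()].
#' @return list with `spectrum` (a [shift_spectrum()] with one peak per
#'   class, assigned to its class), `truth` (per-atom data frame from
#'   [surrogate_truth()]), `class_mean`, `class_sigma` (per class) and
#'   `true_quantile(class_index, tau)`.
#' @export
simulate_spectrum <- function(mol, model = surrogate_model()) {
  tr <- surrogate_truth(mol, model)
  ncls <- length(mol$carbon_classes)
  cm <- vapply(mol$carbon_classes, function(cl) mean(tr$mean[match(cl, tr$atom)]), numeric(1))
  cs <- vapply(mol$carbon_classes, function(cl) mean(tr$sigma[match(cl, tr$atom)]), numeric(1))
  # record identity (name) is part of the key: duplicate structures are
  # independent entries with their own measurement noise
  key <- paste(mol$name, mol$formula, nrow(mol$bonds),
               paste(mol$bonds$i, mol$bonds$j, collapse = ","))
  shifts <- .with_seed(model$seed + .str_hash(key),
                       rnorm(ncls, mean = cm, sd = cs))
  list(spectrum = shift_spectrum(shifts, assignment = seq_len(ncls)),
       truth = tr, class_mean = cm, class_sigma = cs,
       true_quantile = function(class_index, tau)
         cm[class_index] + cs[class_index] * qnorm(tau))
}

# ---------------------------------------------------------------------------
# Fixture molecules
# ---------------------------------------------------------------------------

# ~50 small organics spanning the allowed element set
.fixture_smiles <- c(
  "CC", "CCC", "CCCC", "CC(C)C", "CCCCC", "CC(C)CC", "CCCCCC", "CC(C)(C)C",
  "CCO", "CCCO", "CC(C)O", "CC(C)(C)O", "OCCO", "CCOC", "CCOCC", "C1CCOC1",
  "CC=O", "CCC=O", "CC(C)=O", "CCC(C)=O", "CC(=O)O", "CCC(=O)O",
  "CC(=O)OC", "CCC(=O)OCC", "CC(=O)N", "CC(=O)NC",
  "CCN", "CCCN", "CC(C)N", "CCNCC", "C1CCNC1", "CC#N", "CCC#N",
  "C=C", "CC=C", "CC=CC", "C1CCCCC1", "C1CCCC1", "CC1CCCCC1",
  "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Cc1ccccc1C", "Cc1ccc(C)cc1",
  "Oc1ccccc1", "COc1ccccc1", "Nc1ccccc1", "Cc1ccncc1", "c1ccncc1",
  "c1ccoc1", "c1ccsc1", "CCS", "CCSC", "CSC",
  "CCCl", "CC(C)Cl", "CCBr", "CCCBr", "CCI", "CCF", "FC(F)CC",
  "Clc1ccccc1", "Brc1ccccc1", "Fc1ccccc1", "CCCP", "CP(C)C", "OB(O)C",
  "OB(O)c1ccccc1")

# substituents usable in valence-legal decoration (replace one implicit H)
.decorations <- c("C", "O", "N", "F", "Cl", "Br")

# attach a single new atom to heavy atom `at`, consuming one implicit H
.attach_atom <- function(rec, at, element) {
  elements <- c(rec$atoms$element, element)
  nH <- c(rec$atoms$nH, .default_valence[[element]] - 1L)
  nH[at] <- nH[at] - 1L
  bonds <- rbind(rec$bonds,
                 data.frame(i = at, j = length(elements), order = 1))
  mol_record(elements, bonds, nH = nH, name = rec$name, stereo = rec$stereo)
}

#' Generate reproducible fixture molecules
#'
#' Draws from an embedded list of small organic structures spanning the
#' allowed element set (H, B, C, N, O, F, P, S, Cl, Br, I), optionally
#' decorated with 0-2 extra substituents attached by valence-legal edits
#' (each replaces one implicit hydrogen on a carbon). All outputs are
#' single-fragment and survive the curation filters by construction.
#' Records carry no conformers; see [generate_conformers()].
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed; the same (n, seed) yields identical output.
#' @param decorate maximum number of decorations per molecule (default 2).
#' @param prefix record-name prefix; records with different names are
#'   independent corpus entries (own noise draws) even when their
#'   structures coincide.
#' @return list of `n` [mol_record()] objects.
#' @export
fixture_molecules <- function(n, seed = 1, decorate = 2, prefix = "mol") {
  stopifnot(n >= 1)
  base <- lapply(seq_along(.fixture_smiles), function(k)
    parse_smiles(.fixture_smiles[k], name = paste0("fix", k)))
  .with_seed(seed, {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      rec <- base[[sample.int(length(base), 1)]]
      ndec <- if (decorate > 0) sample.int(decorate + 1, 1) - 1 else 0
      for (d in seq_len(ndec)) {
        cand <- which(rec$atoms$element == "C" & rec$atoms$nH >= 1)
        if (!length(cand)) break
        at <- cand[sample.int(length(cand), 1)]
        rec <- .attach_atom(rec, at, sample(.decorations, 1))
      }
      rec$name <- paste0(prefix, k)
      out[[k]] <- rec
    }
    out
  })
}

#' Generate same-formula constitutional isomers
#'
#' Random acyclic saturated skeletons with `n_carbon` carbons and
#' `n_oxygen` ether/alcohol oxygens: every such tree has the same molecular
#' formula (CnH(2n+2)O...), so the set forms an isomer family for the
#' combinatorial correct/incorrect benchmark. Duplicate constitutions are
#' removed via canonical graph hashing.
#'
#' @param n number of distinct isomers requested.
#' @param n_carbon carbons per molecule (default 9).
#' @param n_oxygen oxygens per molecule (default 1).
#' @param seed integer seed.
#' @return list of up to `n` distinct [mol_record()] objects (an error is
#'   raised if the family cannot supply `n` distinct members).
#' @export
fixture_isomers <- function(n, n_carbon = 9, n_oxygen = 1, seed = 1) {
  stopifnot(n >= 1, n_carbon >= 3)
  nat <- n_carbon + n_oxygen
  elements <- c(rep("C", n_carbon), rep("O", n_oxygen))
  maxdeg <- c(rep(4L, n_carbon), rep(2L, n_oxygen))
  .with_seed(seed, {
    seen <- character(0); out <- list(); tries <- 0
    while (length(out) < n && tries < 4000 * n) {
      tries <- tries + 1
      # random labelled tree via Pruefer sequence
      prf <- sample.int(nat, nat - 2, replace = TRUE)
      deg <- rep(1L, nat)
      for (p in prf) deg[p] <- deg[p] + 1L
      if (any(deg > maxdeg)) next
      edges <- matrix(0L, nat - 1, 2); dleft <- deg; ptr <- 1
      leaves <- which(dleft == 1L)
      prf2 <- c(prf, 0L)
      for (k in seq_len(nat - 1)) {
        if (k < nat - 1) {
          leaf <- min(leaves)
          p <- prf2[ptr]; ptr <- ptr + 1
          edges[k, ] <- c(leaf, p)
          leaves <- leaves[leaves != leaf]
          dleft[p] <- dleft[p] - 1L
          if (dleft[p] == 1L) leaves <- c(leaves, p)
        } else {
          edges[k, ] <- sort(leaves)[1:2]
        }
      }
      # forbid O-O bonds (peroxides would leave the intended family)
      if (any(elements[edges[, 1]] == "O" & elements[edges[, 2]] == "O")) next
      g <- igraph::make_empty_graph(nat, directed = FALSE)
      g <- igraph::add_edges(g, t(edges))
      cp <- igraph::canonical_permutation(g, colors = as.integer(factor(elements)))
      gc <- igraph::permute(g, cp$labeling)
      key <- paste(apply(igraph::as_edgelist(gc), 1, paste, collapse = "-"),
                   collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      bonds <- data.frame(i = edges[, 1], j = edges[, 2], order = 1)
      out[[length(out) + 1L]] <-
        mol_record(elements, bonds, name = paste0("iso", length(out) + 1L))
    }
    if (length(out) < n)
      stop("could not generate ", n, " distinct isomers for C", n_carbon,
           " O", n_oxygen)
    out
  })
}

#' Build a labelled correct/incorrect benchmark from a molecule pool
#'
#' Every molecule paired with its own simulated spectrum gives a correct
#' pair; pairing it with another molecule's spectrum gives an incorrect
#' pair, emitted only when the two molecules share a molecular formula (an
#' incorrect proposal with a different formula would be trivially
#' rejected). A pool of size N yields N correct pairs and at most N^2 - N
#' incorrect pairs, with equality when all formulae agree.
#'
#' @param pool list of `mol_record` (N >= 2).
#' @param model a [surrogate_model()] used to simulate each spectrum.
#' @return data frame with columns `structure` (index into pool),
#'   `spectrum` (index of the molecule whose spectrum is used) and `label`
#'   (`"correct"`/`"incorrect"`), plus attribute `"spectra"`: the list of
#'   simulated [simulate_spectrum()] results per pool molecule.
#' @export
make_benchmark <- function(pool, model = surrogate_model()) {
  stopifnot(length(pool) >= 2)
  sims <- lapply(pool, simulate_spectrum, model = model)
  formulas <- vapply(pool, function(m) m$formula, "")
  rows <- list()
  for (i in seq_along(pool)) {
    rows[[length(rows) + 1L]] <- data.frame(structure = i, spectrum = i,
                                            label = "correct")
    for (j in seq_along(pool)) {
      if (i != j && formulas[i] == formulas[j])
        rows[[length(rows) + 1L]] <- data.frame(structure = i, spectrum = j,
                                                label = "incorrect")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spectra") <- sims
  attr(out, "pool") <- pool
  out
}
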