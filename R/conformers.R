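#' Generate conformer ensembles
#'
#' Populates the `conformers` field of one or more molecule records.
#' Backend `"etkdg"` delegates distance-geometry embedding (ETKDGv3, fixed
#' random seed, hence reproducible coordinates) and MMFF94s force-field
#' relaxation to RDKit, driven through a bundled Python helper; backend
#' `"passthrough"` returns existing conformers unchanged and is the hook
#' for externally supplied ensembles (e.g. DFT-optimised geometries with
#' their energies). All conformers share the record's atom ordering.
#'
#' Records whose embedding fails raise an error naming the molecule; zero
#' conformers are never returned silently.
#'
#' @param mols a `mol_record` or list of them.
#' @param n_conf conformers requested per molecule (>= 1; default 20 for
#'   ensemble work, but single-conformer prediction is common).
#' @param seed integer seed for the embedding.
#' @param backend `"etkdg"` or `"passthrough"`.
#' @param python path of the Python interpreter with RDKit available.
#' @return the input records with `conformers` populated and an
#'   `energies` field (kcal/mol per conformer, MMFF94s) attached; a single
#'   input record returns a single record.
#' @export
generate_conformers <- function(mols, n_conf = 1, seed = 42,
                                backend = c("etkdg", "passthrough"),
                                python = Sys.which("python")) {
  backend <- match.arg(backend)
  single <- inherits(mols, "mol_record")
  if (single) mols <- list(mols)
  stopifnot(n_conf >= 1)
  if (backend == "passthrough") {
    for (k in seq_along(mols)) {
      if (!length(mols[[k]]$conformers))
        stop("passthrough backend but molecule '", mols[[k]]$name,
             "' has no conformers")
    }
    return(if (single) mols[[1]] else mols)
  }
  if (!nzchar(python)) stop("no python interpreter found for the etkdg backend")
  helper <- system.file("python", "etkdg_embed.py", package = "dp5q")
  if (!nzchar(helper)) helper <- file.path("inst", "python", "etkdg_embed.py")
  inp <- tempfile(fileext = ".sdf"); out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(inp, out)))
  write_structures(mols, inp)
  status <- system2(python, c(helper, inp, out, n_conf, seed),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(out))
    stop("conformer generation failed (python exit status ", status, ")")
  entries <- .read_conformer_sdf(out)
  for (k in seq_along(mols)) {
    hits <- entries[vapply(entries, function(e) e$mol_index == k, logical(1))]
    if (!length(hits))
      stop("embedding failed for molecule '", mols[[k]]$name, "' (index ", k, ")")
    nat <- nrow(mols[[k]]$atoms)
    for (h in hits) {
      if (nrow(h$xyz) != nat)
        stop("conformer atom count mismatch for molecule '", mols[[k]]$name, "'")
    }
    mols[[k]]$conformers <- lapply(hits, function(h) h$xyz)
    mols[[k]]$energies <- vapply(hits, function(h) h$energy, numeric(1))
  }
  if (single) mols[[1]] else mols
}

# minimal reader for the helper's output: per entry, coordinates plus the
# mol_index/conf_index/energy_kcal properties
.read_conformer_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  breaks <- c(0, which(lines == "$$$$"))
  entries <- list()
  for (b in seq_len(length(breaks) - 1)) {
    blk <- lines[(breaks[b] + 1):(breaks[b + 1] - 1)]
    if (!length(blk)) next
    counts <- blk[4]
    nat <- as.integer(substr(counts, 1, 3))
    atoms <- blk[5:(4 + nat)]
    xyz <- t(vapply(atoms, function(l) {
      c(as.numeric(substr(l, 1, 10)), as.numeric(substr(l, 11, 20)),
        as.numeric(substr(l, 21, 30)))
    }, numeric(3)))
    dimnames(xyz) <- NULL
    prop <- function(name) {
      i <- grep(paste0("^>\\s*<", name, ">"), blk)
      if (length(i)) blk[i[1] + 1] else NA_character_
    }
    entries[[length(entries) + 1L]] <-
      list(mol_index = as.integer(prop("mol_index")),
           conf_index = as.integer(prop("conf_index")),
           energy = as.numeric(prop("energy_kcal")),
           xyz = xyz)
  }
  entries
}

#' Boltzmann weights from conformer energies
#'
#' `w_i` proportional to `exp(-E_i / RT)`, normalised to sum to one.
#' Energies are shifted by their minimum before exponentiation for
#' numerical stability, which leaves the weights unchanged.
#'
#' @param energies numeric vector, kcal/mol.
#' @param temperature kelvin (> 0), default 298.15.
#' @return numeric weights summing to 1.
#' @export
boltzmann_weights <- function(energies, temperature = 298.15) {
  stopifnot(length(energies) >= 1, temperature > 0, all(is.finite(energies)))
  R <- 1.98720425864083e-3   # kcal / (mol K)
  x <- exp(-(energies - min(energies)) / (R * temperature))
  x / sum(x)
}
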