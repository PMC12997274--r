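#' @import ChemmineR
#' @importFrom stats setNames
NULL

# Elements allowed in the curated corpus (heavy atoms; H tracked implicitly).
ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# Default valences used to infer implicit hydrogen counts from an SDF/SMILES
# bond table when hydrogens are not explicit.
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                      Cl = 1, Br = 1, I = 1)

#' Molecular structure record
#'
#' The container used throughout the package for one candidate structure:
#' heavy atoms (element symbol plus attached-hydrogen count), bonds with
#' integer orders, zero or more 3D conformers (heavy-atom coordinates, in
#' angstrom), the canonical molecular formula, and the partition of carbon
#' atoms into symmetry-equivalence classes (the distinct 13C environments).
#'
#' Atom indices are 1-based and contiguous, and stable across conformers.
#' Stereochemistry is carried as an annotation (`stereo`, typically the
#' source SMILES) so diastereomers can be distinguished by their 3D
#' conformers; it does not enter the equivalence-class computation, which is
#' purely 2D (element, attached H, bond orders).
#'
#' @param elements character vector of heavy-atom element symbols.
#' @param bonds data frame or matrix with columns `i`, `j`, `order`
#'   (1-based atom indices, integer bond order; 4 denotes aromatic).
#' @param nH integer vector of attached hydrogens per heavy atom; if `NULL`
#'   it is inferred from default valences and the bond table.
#' @param conformers list of numeric matrices (n_atoms x 3), possibly empty.
#' @param name molecule identifier.
#' @param stereo optional stereochemistry annotation (e.g. isomeric SMILES).
#' @return An object of class `mol_record` with fields `atoms` (data frame
#'   `element`, `nH`), `bonds`, `conformers`, `formula`, `carbon_classes`,
#'   `name`, `stereo`.
#' @export
mol_record <- function(elements, bonds, nH = NULL, conformers = list(),
                       name = "", stereo = NA_character_) {
  elements <- as.character(elements)
  n <- length(elements)
  stopifnot(n >= 1)
  if (is.null(dim(bonds))) bonds <- matrix(bonds, ncol = 3, byrow = TRUE)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    names(bonds) <- c("i", "j", "order")
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.numeric(bonds$order)
    if (any(bonds$i == bonds$j) || any(bonds$i < 1) || any(bonds$j < 1) ||
        any(bonds$i > n) || any(bonds$j > n))
      stop("every bond must reference two distinct existing atoms")
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  if (is.null(nH)) nH <- .implicit_h(elements, bonds)
  nH <- as.integer(nH)
  stopifnot(length(nH) == n, all(nH >= 0))
  conformers <- lapply(conformers, function(xyz) {
    xyz <- as.matrix(xyz)
    stopifnot(nrow(xyz) == n, ncol(xyz) == 3, all(is.finite(xyz)))
    dimnames(xyz) <- NULL
    xyz
  })
  rec <- structure(
    list(atoms = data.frame(element = elements, nH = nH,
                            stringsAsFactors = FALSE),
         bonds = bonds, conformers = conformers,
         formula = NA_character_, carbon_classes = list(),
         name = name, stereo = stereo),
    class = "mol_record")
  rec$formula <- molecular_formula(rec)
  if (any(elements == "C")) rec$carbon_classes <- carbon_equivalence(rec)
  rec
}

# implicit hydrogens from default valence minus total bond order
# (aromatic order 4 counts 1.5, as in kekulised alternatives)
.implicit_h <- function(elements, bonds) {
  val <- .default_valence[elements]
  val[is.na(val)] <- 0
  used <- numeric(length(elements))
  if (nrow(bonds)) {
    ord <- ifelse(bonds$order == 4, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      used[bonds$i[k]] <- used[bonds$i[k]] + ord[k]
      used[bonds$j[k]] <- used[bonds$j[k]] + ord[k]
    }
  }
  as.integer(pmax(0, round(val - used)))
}

#' Canonical molecular formula (Hill order)
#'
#' Counts include implicit hydrogens. Invariant under atom reordering.
#'
#' @param mol a `mol_record`.
#' @return formula string, e.g. `"C2H6O"`.
#' @export
molecular_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  counts <- setNames(as.integer(counts), names(counts))
  h <- sum(mol$atoms$nH)
  if (h > 0) counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h
  els <- names(counts)
  ord <- if ("C" %in% els) {
    c("C", "H", sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  ord <- ord[ord %in% els]
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, ""), collapse = "")
}

#' Ring and aromaticity perception
#'
#' Derives, from the heavy-atom bond graph alone, which atoms lie in rings
#' and which bonds belong to aromatic rings. A ring is taken as aromatic
#' when it has 5-7 members and every ring atom carries a double (or
#' declared-aromatic, order 4) bond to another ring member -- this merges
#' the two kekule forms of benzenoid rings so symmetry and environment keys
#' do not depend on which alternation the input happened to use.
#'
#' @param mol a `mol_record`.
#' @return list with logical vectors `ring_atom` (per atom),
#'   `aromatic_atom` (per atom) and `aromatic_bond` (per bond row).
#' @export
perceive_rings <- function(mol) {
  n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  ring_atom <- logical(n); aromatic_bond <- logical(nb)
  if (nb) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(cbind(mol$bonds$i, mol$bonds$j)))
    br <- igraph::bridges(g)
    cyc_edges <- setdiff(seq_len(nb), as.integer(br))
    for (e in cyc_edges) {
      i <- mol$bonds$i[e]; j <- mol$bonds$j[e]
      ring_atom[c(i, j)] <- TRUE
      g2 <- igraph::delete_edges(g, e)
      sp <- suppressWarnings(igraph::shortest_paths(g2, i, j)$vpath[[1]])
      ring <- as.integer(sp)
      if (length(ring) < 5 || length(ring) > 7) next
      in_ring <- logical(n); in_ring[ring] <- TRUE
      has_pi <- vapply(ring, function(v) {
        rows <- which((mol$bonds$i == v & in_ring[mol$bonds$j]) |
                      (mol$bonds$j == v & in_ring[mol$bonds$i]))
        any(mol$bonds$order[rows] %in% c(2, 4))
      }, logical(1))
      if (all(has_pi)) {
        pairs <- cbind(ring, c(ring[-1], ring[1]))
        for (k in seq_len(nrow(pairs))) {
          row <- which((mol$bonds$i == pairs[k, 1] & mol$bonds$j == pairs[k, 2]) |
                       (mol$bonds$j == pairs[k, 1] & mol$bonds$i == pairs[k, 2]))
          aromatic_bond[row] <- TRUE
        }
      }
    }
    aromatic_bond <- aromatic_bond | mol$bonds$order == 4
  }
  aromatic_atom <- logical(n)
  if (nb && any(aromatic_bond))
    aromatic_atom[unique(c(mol$bonds$i[aromatic_bond], mol$bonds$j[aromatic_bond]))] <- TRUE
  list(ring_atom = ring_atom, aromatic_atom = aromatic_atom,
       aromatic_bond = aromatic_bond)
}

#' Carbon symmetry-equivalence classes
#'
#' Partitions the carbon atoms into classes related by a graph automorphism
#' of the 2D molecular graph (element + attached-H count as vertex colours,
#' bond order encoded on subdivided edges). Carbons in one class are
#' magnetically equivalent at this level of theory and contribute a single
#' 13C peak; the number of classes is the expected peak count.
#'
#' Stereochemistry and 3D geometry are deliberately ignored: peak counts in
#' tabulated carbon spectra are derived from the constitution, and the
#' partition must not depend on which conformer is present.
#'
#' @param mol a `mol_record` with at least one carbon.
#' @return list of integer vectors, a partition of the carbon atom indices,
#'   ordered by smallest member; deterministic for a fixed input.
#' @export
carbon_equivalence <- function(mol) {
  el <- mol$atoms$element
  carbons <- which(el == "C")
  if (!length(carbons)) stop("molecule has no carbon")
  n <- length(el)
  # vertex colours: atom identity = (element, nH); bond order as an extra
  # coloured vertex subdividing each edge (BLISS supports vertex colours only)
  atom_key <- paste(el, mol$atoms$nH)
  colors <- as.integer(factor(atom_key))
  nb <- nrow(mol$bonds)
  if (nb) {
    # aromatic bonds share one colour so kekule alternation does not split
    # symmetric positions (ortho/meta pairs of a monosubstituted ring)
    ord_label <- ifelse(perceive_rings(mol)$aromatic_bond, 4, mol$bonds$order)
    dummy_col <- max(colors) + as.integer(factor(ord_label))
    edges <- rbind(cbind(mol$bonds$i, n + seq_len(nb)),
                   cbind(mol$bonds$j, n + seq_len(nb)))
    g <- igraph::make_empty_graph(n + nb, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    vcol <- c(colors, dummy_col)
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    vcol <- colors
  }
  gens <- igraph::automorphism_group(g, colors = vcol)
  # orbits of the original vertices under the generated group (union-find)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (p in gens) {
    p <- as.integer(p)[seq_len(n)]
    for (v in seq_len(n)) {
      a <- find(v); b <- find(p[v])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(carbons, find, integer(1))
  cls <- split(carbons, roots)
  cls <- cls[order(vapply(cls, min, integer(1)))]
  names(cls) <- NULL
  lapply(cls, as.integer)
}

#' Read molecular structures
#'
#' Reads an SDF (V2000) file or a SMILES file (one SMILES per line, optional
#' whitespace-separated name). Explicit hydrogens are folded into per-atom
#' counts; SDF 3D coordinate blocks become a single conformer, while SMILES
#' inputs yield zero conformers (generate them with [generate_conformers()]).
#'
#' Entries that fail to parse are skipped with a warning naming their index,
#' never silently dropped.
#'
#' @param path input file.
#' @param format `"sdf"` or `"smiles"`.
#' @return list of [mol_record()] objects.
#' @export
read_structures <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "sdf") .read_sdf(path) else .read_smiles_file(path)
}

.read_sdf <- function(path) {
  if (length(readLines(path, n = 1, warn = FALSE)) == 0) {
    warning("empty structure file: ", path)
    return(list())
  }
  sdfset <- ChemmineR::read.SDFset(path)
  valid <- ChemmineR::validSDF(sdfset)
  if (any(!valid))
    warning("skipped unparseable SDF record(s) at index: ",
            paste(which(!valid), collapse = ", "))
  out <- list()
  for (k in which(valid)) {
    sdf <- sdfset[[k]]
    rec <- tryCatch(.sdf_to_record(sdf), error = function(e) e)
    if (inherits(rec, "error")) {
      warning("skipped SDF record ", k, ": ", conditionMessage(rec))
    } else out[[length(out) + 1L]] <- rec
  }
  out
}

.sdf_to_record <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  xyz <- ab[, 1:3, drop = FALSE]
  bonds <- if (length(bb)) data.frame(i = as.integer(bb[, 1]),
                                      j = as.integer(bb[, 2]),
                                      order = as.numeric(bb[, 3]))
           else data.frame(i = integer(), j = integer(), order = numeric())
  heavy <- which(el != "H")
  expl_h <- integer(length(heavy))
  if (any(el == "H") && nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      if (el[i] == "H" && el[j] != "H") expl_h[match(j, heavy)] <- expl_h[match(j, heavy)] + 1L
      if (el[j] == "H" && el[i] != "H") expl_h[match(i, heavy)] <- expl_h[match(i, heavy)] + 1L
    }
  }
  remap <- match(seq_along(el), heavy)
  keep <- el[bonds$i] != "H" & el[bonds$j] != "H"
  bonds <- bonds[keep, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  nH <- expl_h + .implicit_h(el[heavy], bonds)
  conf <- if (all(xyz[heavy, ] == 0)) list() else list(unname(as.matrix(xyz[heavy, , drop = FALSE])))
  hdr <- ChemmineR::header(sdf)
  mol_record(el[heavy], bonds, nH = nH, conformers = conf,
             name = if (length(hdr)) unname(hdr[1]) else "")
}

.read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  idx <- which(nzchar(lines))
  if (!length(idx)) {
    warning("empty structure file: ", path)
    return(list())
  }
  out <- list()
  for (k in idx) {
    parts <- strsplit(lines[k], "[[:space:]]+")[[1]]
    rec <- tryCatch(parse_smiles(parts[1], name = if (length(parts) > 1) parts[2] else ""),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      warning("skipped SMILES record at line ", k, ": ", conditionMessage(rec))
    } else out[[length(out) + 1L]] <- rec
  }
  out
}

#' Parse a single SMILES string into a molecule record
#'
#' Conversion (including kekulisation and implicit-hydrogen perception) is
#' delegated to OpenBabel through ChemmineR/ChemmineOB. The result carries
#' no conformers; the isomeric SMILES is retained as the stereochemistry
#' annotation.
#'
#' @param smiles SMILES string.
#' @param name molecule identifier.
#' @return a [mol_record()].
#' @export
parse_smiles <- function(smiles, name = "") {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  rec <- .sdf_to_record(sdf)
  rec$conformers <- list()   # SMILES carries no geometry
  rec$name <- name
  rec$stereo <- smiles
  rec
}

#' Write molecule records to an SDF (V2000) file
#'
#' Implicit hydrogens are not expanded; the first conformer (or a zero
#' block when absent) supplies coordinates. With `conformers = "all"` a
#' record is written as one SDF entry per conformer (a multi-conformer
#' SDF). Round-tripping through [read_structures()] preserves atom count,
#' bonds, formula and carbon classes.
#'
#' @param mols list of `mol_record` objects (or a single record).
#' @param path output file.
#' @param conformers `"first"` (default) or `"all"`.
#' @export
write_structures <- function(mols, path, conformers = c("first", "all")) {
  conformers <- match.arg(conformers)
  if (inherits(mols, "mol_record")) mols <- list(mols)
  entries <- list()
  for (m in mols) {
    if (conformers == "all" && length(m$conformers) > 1) {
      for (ci in seq_along(m$conformers)) {
        e <- m; e$conformers <- m$conformers[ci]
        e$name <- paste0(m$name, "_conf", ci)
        entries[[length(entries) + 1L]] <- e
      }
    } else entries[[length(entries) + 1L]] <- m
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (m in entries) {
    n <- nrow(m$atoms); nb <- nrow(m$bonds)
    xyz <- if (length(m$conformers)) m$conformers[[1]] else matrix(0, n, 3)
    lines <- c(m$name, "  dp5q", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    for (a in seq_len(n))
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                xyz[a, 1], xyz[a, 2], xyz[a, 3], m$atoms$element[a]))
    for (b in seq_len(nb))
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                m$bonds$i[b], m$bonds$j[b], as.integer(m$bonds$order[b])))
    lines <- c(lines, "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Experimental carbon-13 peak list
#'
#' @param shifts numeric vector of chemical shifts (ppm), order preserved.
#' @param assignment optional integer vector mapping peak index to carbon
#'   equivalence class (same length as `shifts`), or `NULL` when the
#'   spectrum is unassigned.
#' @return object of class `shift_spectrum`.
#' @export
shift_spectrum <- function(shifts, assignment = NULL) {
  shifts <- as.numeric(shifts)
  if (length(shifts) && any(!is.finite(shifts)))
    stop("shifts must be finite numbers")
  if (!is.null(assignment)) {
    assignment <- as.integer(assignment)
    stopifnot(length(assignment) == length(shifts))
  }
  structure(list(shifts = shifts, assignment = assignment),
            class = "shift_spectrum")
}

#' Read a peak list from CSV or JSON
#'
#' CSV: headerless, one shift (ppm) per line, optional second column with a
#' carbon-class index. JSON: object with a `shifts` array and an optional
#' `assignment` map from 1-based peak index to class index.
#'
#' @param path input file; format chosen by `.json` extension.
#' @return a [shift_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    assignment <- NULL
    if (!is.null(obj$assignment) && length(obj$assignment)) {
      assignment <- rep(NA_integer_, length(obj$shifts))
      assignment[as.integer(names(obj$assignment))] <- as.integer(unlist(obj$assignment))
    }
    return(shift_spectrum(obj$shifts, assignment))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  shifts <- numeric(length(lines)); cls <- rep(NA_integer_, length(lines))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], ",")[[1]]
    v <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(v)) stop("non-numeric shift at row ", k, ": '", parts[1], "'")
    shifts[k] <- v
    if (length(parts) > 1 && nzchar(trimws(parts[2])))
      cls[k] <- as.integer(parts[2])
  }
  shift_spectrum(shifts, if (all(is.na(cls))) NULL else cls)
}

#' Write a peak list as headerless CSV
#' @param spectrum a [shift_spectrum()].
#' @param path output file.
#' @export
write_spectrum <- function(spectrum, path) {
  lines <- if (is.null(spectrum$assignment)) {
    format(spectrum$shifts, trim = TRUE)
  } else {
    paste(format(spectrum$shifts, trim = TRUE), spectrum$assignment, sep = ",")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.mol_record <- function(x, ...) {
  cat("<mol_record>", x$formula,
      sprintf("| %d heavy atoms, %d bonds, %d conformer(s), %d carbon class(es)",
              nrow(x$atoms), nrow(x$bonds), length(x$conformers),
              length(x$carbon_classes)),
      if (nzchar(x$name)) paste("|", x$name) else "", "\n")
  invisible(x)
}

#' @export
print.shift_spectrum <- function(x, ...) {
  cat("<shift_spectrum>", length(x$shifts), "peak(s):",
      paste(round(x$shifts, 1), collapse = ", "), "\n")
  invisible(x)
}
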