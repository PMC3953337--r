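#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter group_by ungroup summarise arrange bind_rows
NULL

# Standard atomic masses (u), IUPAC 2021 abridged values.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38
)

# run a block under a temporary RNG state so fixture generation honours its
# own seed without clobbering the caller's random stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct an atomic structure table
#'
#' A structure is a tibble of atoms, one row per atom, whose row order defines
#' the atom index `i` used by every matrix in the package (contact topology,
#' Hessians, eigenvectors). Required columns: `elety` (atom name), `elem`
#' (element symbol, may be `NA` and inferred later), `chain`, `resno`
#' (author residue number), `x`, `y`, `z` (angstroms), `b` (B-factor,
#' angstrom^2). A 0-based `res_index` (ordinal position of the residue within
#' its chain, in file order) is computed; sequence separation is defined on
#' this ordinal, not on the author numbering, so insertion codes and numbering
#' gaps cannot break it.
#'
#' @param atoms data frame with the columns above (`mass`, `is_hetero`,
#'   `altloc` optional and filled with defaults).
#' @param source_id free-text identifier carried in the `source_id` attribute.
#' @return A `cnd_structure` tibble with masses assigned.
#' @export
as_structure <- function(atoms, source_id = "structure") {
  req <- c("elety", "elem", "chain", "resno", "x", "y", "z", "b")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    abort(paste0("missing structure columns: ", paste(missing_cols, collapse = ", ")))
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) abort("empty structure: no atoms after selection")
  if (!("is_hetero" %in% names(atoms))) atoms$is_hetero <- FALSE
  if (!("altloc" %in% names(atoms))) atoms$altloc <- ""
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    abort("non-finite coordinates in structure")
  atoms$b[is.na(atoms$b)] <- 0
  if (any(atoms$b < 0)) abort("negative B-factor in structure")
  # 0-based residue ordinal within each chain, in file order
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  atoms$res_index <- stats::ave(seq_len(nrow(atoms)), atoms$chain,
    FUN = function(idx) {
      k <- key[idx]
      cumsum(c(FALSE, k[-1] != k[-length(k)]))
    })
  atoms$atom <- seq_len(nrow(atoms))
  atoms <- atoms[, unique(c("atom", "elety", "elem", "chain", "resno",
                            "res_index", "x", "y", "z", "b", "is_hetero",
                            "altloc", setdiff(names(atoms), "atom")))]
  out <- assign_masses(atoms)
  class(out) <- c("cnd_structure", class(tibble()))
  attr(out, "source_id") <- source_id
  out
}

#' Read a protein structure from a PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper applies the
#' selection policy and returns the atom table. The default policy keeps heavy
#' protein atoms of the requested chains: waters, other HETATM records and
#' hydrogens are dropped, and of alternate-location duplicates only the
#' first-listed conformer is retained.
#'
#' @param path PDB file.
#' @param chains character vector of chain identifiers, or `NULL` for all.
#' @param keep_hetero keep non-water HETATM records (e.g. ligands).
#' @param keep_hydrogens keep hydrogen atoms.
#' @param keep_waters keep water molecules.
#' @return A [as_structure()] tibble.
#' @export
read_structure <- function(path, chains = NULL, keep_hetero = FALSE,
                           keep_hydrogens = FALSE, keep_waters = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) abort(paste0("cannot parse PDB file '", path, "': ",
                                                   conditionMessage(e))))
  at <- as_tibble(pdb$atom)
  if (!is.null(chains)) {
    unknown <- setdiff(chains, unique(at$chain))
    if (length(unknown) > 0)
      abort(paste0("chain(s) not present in file: ", paste(unknown, collapse = ", ")))
    at <- at[at$chain %in% chains, ]
  }
  if (!keep_waters) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD", "H2O")), ]
  if (!keep_hetero) at <- at[at$type == "ATOM", ]
  elem <- infer_elements(at$elety, at$elesy)
  if (!keep_hydrogens) {
    keep <- !(elem %in% c("H", "D"))
    at <- at[keep, ]
    elem <- elem[keep]
  }
  # altloc policy: keep the first-listed conformer of each (chain, resno, name)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  dupkey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- !duplicated(dupkey)
  at <- at[keep, ]
  elem <- elem[keep]
  alt <- alt[keep]
  if (nrow(at) == 0) abort("empty structure: no atoms after selection")
  as_structure(
    tibble(elety = at$elety, elem = elem, chain = at$chain, resno = at$resno,
           x = at$x, y = at$y, z = at$z,
           b = ifelse(is.na(at$b), 0, at$b),
           is_hetero = at$type == "HETATM", altloc = alt),
    source_id = basename(path)
  )
}

#' Write a structure as a PDB file
#'
#' @param structure a [as_structure()] tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  n <- nrow(structure)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords(structure))),
    type = ifelse(structure$is_hetero, "HETATM", "ATOM"),
    resno = structure$resno,
    resid = rep("GLY", n),
    eleno = structure$atom,
    elety = structure$elety,
    chain = structure$chain,
    o = rep(1, n),
    b = structure$b,
    elesy = structure$elem
  )
  invisible(path)
}

infer_elements <- function(elety, elesy = NULL) {
  elem <- if (is.null(elesy)) rep(NA_character_, length(elety)) else toupper(trimws(elesy))
  elem[elem %in% c("", "NA")] <- NA_character_
  blank <- is.na(elem)
  if (any(blank)) {
    # atom-name heuristic: strip digits/primes, take the leading letter;
    # "CA" in an ATOM record is an alpha carbon, not calcium
    nm <- gsub("[0-9']", "", toupper(trimws(elety[blank])))
    elem[blank] <- substr(nm, 1, 1)
  }
  elem
}

#' Standard atomic mass lookup
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in unified atomic mass units.
#' @export
element_mass <- function(elements) {
  key <- toupper(elements)
  key[key == "NA"] <- "NA."
  m <- .atomic_masses[key]
  if (any(is.na(m))) {
    bad <- unique(elements[is.na(m)])
    abort(paste0("cannot resolve atomic mass for element(s): ",
                 paste(bad, collapse = ", ")))
  }
  unname(m)
}

#' Assign per-atom masses
#'
#' Fills the `mass` column from the element symbol, inferring the element from
#' the atom name where the element column is blank (an atom named `CA` with a
#' blank element column is taken as an alpha carbon).
#'
#' @param structure structure table (element column may contain `NA`).
#' @return the structure with a strictly positive `mass` column.
#' @export
assign_masses <- function(structure) {
  elem <- infer_elements(structure$elety, structure$elem)
  bad <- is.na(elem) | !(ifelse(elem == "NA", "NA.", elem) %in% names(.atomic_masses))
  if (any(bad))
    abort(paste0("cannot resolve element for atom(s): ",
                 paste(utils::head(structure$elety[bad], 5), collapse = ", ")))
  structure$elem <- elem
  structure$mass <- element_mass(elem)
  structure
}

#' Atom coordinates as an N x 3 matrix
#' @param structure structure table.
#' @return numeric matrix with one row per atom (angstroms).
#' @export
coords <- function(structure) {
  cbind(x = structure$x, y = structure$y, z = structure$z)
}

#' Replace atom coordinates
#' @param structure structure table.
#' @param xyz N x 3 matrix or length-3N vector.
#' @return the structure with new coordinates.
#' @export
set_coords <- function(structure, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  stopifnot(nrow(xyz) == nrow(structure))
  structure$x <- xyz[, 1]; structure$y <- xyz[, 2]; structure$z <- xyz[, 3]
  structure
}

#' Sequence separation between atoms
#'
#' Residue-ordinal distance along the chain: `|res_index_i - res_index_j|`
#' for atoms in the same chain, `Inf` across chains (cross-chain pairs are
#' always non-local, so a two-chain complex can be analysed without
#' redefining the local topology).
#'
#' @param structure structure table.
#' @param i,j atom indices (vectors recycle).
#' @return numeric vector of separations (0 within a residue).
#' @export
sequence_separation <- function(structure, i, j) {
  stopifnot(all(i >= 1 & i <= nrow(structure)), all(j >= 1 & j <= nrow(structure)))
  sep <- abs(structure$res_index[i] - structure$res_index[j])
  sep[structure$chain[i] != structure$chain[j]] <- Inf
  sep
}

# idealised alpha-helix geometry: radius 2.3 A, rise 1.5 A and 100 degrees
# of twist per residue; per-residue pseudo-atoms are placed by fixed offsets
# in the local (radial, tangent, axial) frame
.helix_offsets <- function(atoms_per_residue) {
  base <- list(
    c(-0.6, -1.1, -0.5),  # N  : back toward the previous residue
    c(0, 0, 0),           # CA : on the helix
    c(0.4, 1.2, 0.6),     # C  : forward
    c(1.5, 1.4, 0.4),     # O  : forward and outward
    c(1.5, 0.0, 0.0),     # CB : radially out
    c(2.9, 0.3, 0.2),     # CG
    c(4.1, -0.3, 0.1),    # CD
    c(5.2, 0.2, -0.2)     # CE
  )
  elems <- c("N", "C", "C", "O", "C", "C", "C", "S")
  names_ <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE")
  k <- seq_len(atoms_per_residue)
  if (atoms_per_residue > length(base))
    abort("at most 8 atoms per residue are supported by the fixture generator")
  list(off = base[k], elem = elems[k], name = names_[k])
}

#' Generate a synthetic helical test structure
#'
#' Builds a deterministic idealised alpha-helix of pseudo-residues (radius
#' 2.3 A, rise 1.5 A, 100 degrees per residue) with `atoms_per_residue`
#' heavy pseudo-atoms per residue, standard masses, and synthetic B-factors
#' given by a smooth function of burial: `b = 5 + 25 * (r/r_max)^2`, where
#' `r` is the atom's distance from the helix axis (exposed atoms get larger
#' B). Gaussian coordinate noise of standard deviation `noise` is added under
#' the given seed; the generator restores the caller's RNG state.
#'
#' @param n_residues number of residues (>= 3).
#' @param atoms_per_residue heavy atoms per residue (1-8).
#' @param noise coordinate jitter standard deviation in angstroms.
#' @param seed integer seed controlling the jitter.
#' @param chain chain identifier.
#' @return A [as_structure()] tibble with `n_residues * atoms_per_residue` rows.
#' @export
make_helix_fixture <- function(n_residues, atoms_per_residue = 4, noise = 0,
                               seed = 1, chain = "A") {
  stopifnot(n_residues >= 3, atoms_per_residue >= 1)
  spec <- .helix_offsets(atoms_per_residue)
  phi <- (seq_len(n_residues) - 1) * 100 * pi / 180
  zax <- (seq_len(n_residues) - 1) * 1.5
  ur <- cbind(cos(phi), sin(phi), 0)
  ut <- cbind(-sin(phi), cos(phi), 0)
  uz <- matrix(rep(c(0, 0, 1), each = n_residues), ncol = 3)
  ca <- 2.3 * ur + cbind(0, 0, zax)
  rows <- lapply(seq_len(n_residues), function(r) {
    xyz <- t(vapply(spec$off, function(o) {
      ca[r, ] + o[1] * ur[r, ] + o[2] * ut[r, ] + o[3] * uz[r, ]
    }, numeric(3)))
    tibble(elety = spec$name, elem = spec$elem, chain = chain, resno = r,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = 0)
  })
  at <- bind_rows(rows)
  if (noise > 0) {
    jit <- with_local_seed(seed, matrix(stats::rnorm(3 * nrow(at), sd = noise), ncol = 3))
    at$x <- at$x + jit[, 1]; at$y <- at$y + jit[, 2]; at$z <- at$z + jit[, 3]
  }
  rad <- sqrt(at$x^2 + at$y^2)
  at$b <- 5 + 25 * (rad / max(rad))^2
  as_structure(at, source_id = sprintf("helix-%d-%d-seed%d", n_residues,
                                       atoms_per_residue, seed))
}

# Rodrigues rotation of points about a unit axis through the origin
.rotate_about_axis <- function(xyz, axis, angle_deg) {
  a <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  xyz %*% t(R)
}

#' Generate a synthetic apo-holo pair related by a hinge rotation
#'
#' The apo structure is a [make_helix_fixture()]; the holo structure is the
#' same set of atoms with every residue beyond `hinge_residue` rotated
#' rigidly by `angle` degrees about the axis through the hinge residue's CA
#' directed along its radial (outward) direction. Atom counts and ordering
#' are identical between the two structures, mimicking matched apo-holo
#' crystal pairs.
#'
#' @param n_residues,atoms_per_residue,noise,seed passed to
#'   [make_helix_fixture()].
#' @param hinge_residue residue index (1-based, interior to the chain).
#' @param angle hinge rotation in degrees.
#' @return list with elements `apo` and `holo`.
#' @export
make_hinge_pair <- function(n_residues, atoms_per_residue = 4,
                            hinge_residue = ceiling(n_residues / 2),
                            angle = 30, noise = 0, seed = 1) {
  stopifnot(hinge_residue > 1, hinge_residue < n_residues)
  apo <- make_helix_fixture(n_residues, atoms_per_residue, noise, seed)
  holo <- apo
  ca_row <- which(apo$resno == hinge_residue & apo$elety == "CA")
  if (length(ca_row) == 0) ca_row <- which(apo$resno == hinge_residue)[1]
  pivot <- unlist(apo[ca_row, c("x", "y", "z")], use.names = FALSE)
  axis <- c(pivot[1], pivot[2], 0)
  if (sum(axis^2) < 1e-12) axis <- c(1, 0, 0)
  moving <- apo$resno > hinge_residue
  xyz <- coords(apo)[moving, , drop = FALSE]
  xyz <- sweep(xyz, 2, pivot)
  xyz <- .rotate_about_axis(xyz, axis, angle)
  xyz <- sweep(xyz, 2, pivot, `+`)
  holo$x[moving] <- xyz[, 1]; holo$y[moving] <- xyz[, 2]; holo$z[moving] <- xyz[, 3]
  attr(holo, "source_id") <- paste0(attr(apo, "source_id"), "-hinge", angle)
  list(apo = apo, holo = holo)
}

#' Construct a trajectory from coordinate frames
#'
#' @param structure reference structure (defines atoms and masses).
#' @param frames list of N x 3 coordinate matrices, or a `n_frames x 3N`
#'   matrix in x1,y1,z1,... order.
#' @return A `cnd_trajectory` object.
#' @export
as_trajectory <- function(structure, frames) {
  if (is.list(frames)) {
    frames <- t(vapply(frames, function(f) {
      if (is.null(dim(f))) f <- matrix(f, ncol = 3, byrow = TRUE)
      if (nrow(f) != nrow(structure)) abort("frame atom count mismatch")
      as.vector(t(f))
    }, numeric(3 * nrow(structure))))
  }
  if (ncol(frames) != 3 * nrow(structure)) abort("frame atom count mismatch")
  out <- list(xyz = unname(as.matrix(frames)), structure = structure)
  class(out) <- "cnd_trajectory"
  out
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path multi-model PDB (MODEL/ENDMDL records).
#' @inheritParams read_structure
#' @return A `cnd_trajectory`; the reference structure is model 1.
#' @export
read_trajectory <- function(path, chains = NULL, keep_hetero = FALSE,
                            keep_hydrogens = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) abort(paste0("cannot parse PDB file '", path, "': ",
                                                   conditionMessage(e))))
  ref <- read_structure(path, chains = chains, keep_hetero = keep_hetero,
                        keep_hydrogens = keep_hydrogens)
  at <- as_tibble(pdb$atom)
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD", "H2O"))
  if (!keep_hetero) keep <- keep & at$type == "ATOM"
  elem <- infer_elements(at$elety, at$elesy)
  if (!keep_hydrogens) keep <- keep & !(elem %in% c("H", "D"))
  keep <- keep & !duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|"))
  cidx <- as.vector(t(cbind(3 * which(keep) - 2, 3 * which(keep) - 1, 3 * which(keep))))
  xyz <- pdb$xyz[, cidx, drop = FALSE]
  as_trajectory(ref, unname(as.matrix(xyz)))
}

#' @export
print.cnd_trajectory <- function(x, ...) {
  cat(sprintf("<cnd_trajectory> %d frames x %d atoms\n",
              nrow(x$xyz), nrow(x$structure)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cnd_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)
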