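#' A P450-steroid complex structure
#'
#' Wraps a single-model atom table, splitting protein and ligand by residue
#' name.  Waters are excluded from the protein set; the heme (and other
#' non-ligand heteroresidues) is retained for context but never enters the
#' C-alpha RMSD, which uses CA atoms only.
#'
#' @param atoms Tibble with the roster columns plus `x`, `y`, `z`
#'   (e.g. `as_tibble()` of a one-frame [trajectory()]).
#' @param id Identifier string (e.g. a PDB ID).
#' @param ligand_resnames Character vector of ligand residue names.
#' @param water_resnames Residue names treated as water
#'   (default HOH/WAT/SOL).
#' @return A `complex_structure` with elements `protein`, `ligand`,
#'   `context`, `id`.
#' @export
complex_structure <- function(atoms, id, ligand_resnames = character(),
                              water_resnames = c("HOH", "WAT", "SOL")) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("serial", "name", "element", "resname", "resnum", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atoms table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  is_lig <- atoms$resname %in% ligand_resnames
  is_wat <- atoms$resname %in% water_resnames
  protein <- atoms[!is_lig & !is_wat, ]
  if (sum(protein$name == "CA") < 3) {
    stop("complex needs >= 3 C-alpha atoms", call. = FALSE)
  }
  structure(list(protein = protein, ligand = atoms[is_lig, ],
                 context = atoms[is_wat, ], id = id),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure> %s: %d protein atoms (%d CA), %d ligand atoms\n",
              x$id, nrow(x$protein), sum(x$protein$name == "CA"),
              nrow(x$ligand)))
  invisible(x)
}

#' Read a complex structure from a PDB file
#'
#' Convenience wrapper: parses the first model of a PDB file and builds a
#' [complex_structure()].
#'
#' @param path PDB file path.
#' @param id Identifier (default: file name without extension).
#' @inheritParams complex_structure
#' @return A `complex_structure`.
#' @export
read_complex_pdb <- function(path, id = NULL, ligand_resnames = character(),
                             water_resnames = c("HOH", "WAT", "SOL")) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  traj <- read_multimodel_pdb(path)
  atoms <- as_tibble.trajectory(traj)
  atoms <- atoms[atoms$frame == 1, setdiff(names(atoms), c("frame", "time_ps"))]
  complex_structure(atoms, id, ligand_resnames, water_resnames)
}

#' Map C-alpha atoms between two complexes
#'
#' Pairs CA atoms by the intersection of `(chain, resnum)` identity --
#' appropriate when comparing crystal forms of the same protein.  Input
#' order is irrelevant; pairs are returned sorted.
#'
#' @param a,b `complex_structure` objects.
#' @return Tibble with `chain`, `resnum`, `idx_a`, `idx_b` (row indices into
#'   each protein table) plus attributes `unmatched_a` / `unmatched_b`
#'   (counts of residues only present on one side).
#' @export
map_calpha <- function(a, b) {
  stopifnot(inherits(a, "complex_structure"), inherits(b, "complex_structure"))
  ca <- function(s) {
    d <- s$protein[s$protein$name == "CA", ]
    d$row <- which(s$protein$name == "CA")
    # one CA per residue: keep the first occurrence
    d[!duplicated(paste(d$chain, d$resnum)), ]
  }
  ca_a <- ca(a); ca_b <- ca(b)
  key_a <- paste(ca_a$chain, ca_a$resnum)
  key_b <- paste(ca_b$chain, ca_b$resnum)
  shared <- intersect(key_a, key_b)
  if (length(shared) < 3) {
    stop("insufficient overlap: fewer than 3 shared residues", call. = FALSE)
  }
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  out <- tibble::tibble(chain = ca_a$chain[ia], resnum = ca_a$resnum[ia],
                        idx_a = ca_a$row[ia], idx_b = ca_b$row[ib])
  out <- dplyr::arrange(out, .data$chain, .data$resnum)
  attr(out, "unmatched_a") <- length(key_a) - length(shared)
  attr(out, "unmatched_b") <- length(key_b) - length(shared)
  out
}

#' C-alpha RMSD between two complexes
#'
#' Superposes the mapped CA atoms of `b` onto `a` by [kabsch()] and returns
#' the minimized RMSD with the mapping and transform attached.
#'
#' @param a,b `complex_structure` objects.
#' @return A `structure_comparison`: list with `rmsd` (Angstrom),
#'   `n_mapped`, `superposition`, `mapping`, `id_a`, `id_b`.
#' @export
calpha_rmsd <- function(a, b) {
  mp <- map_calpha(a, b)
  pa <- as.matrix(a$protein[mp$idx_a, c("x", "y", "z")])
  pb <- as.matrix(b$protein[mp$idx_b, c("x", "y", "z")])
  sp <- kabsch(pb, pa)
  structure(list(rmsd = sp$rmsd, n_mapped = nrow(mp), superposition = sp,
                 mapping = mp, id_a = a$id, id_b = b$id),
            class = "structure_comparison")
}

#' @export
print.structure_comparison <- function(x, ...) {
  cat(sprintf("<structure_comparison> %s vs %s: %d CA mapped, rmsd %.3f A\n",
              x$id_a, x$id_b, x$n_mapped, x$rmsd))
  invisible(x)
}

#' @method glance structure_comparison
#' @export
glance.structure_comparison <- function(x, ...) {
  tibble::tibble(pair = paste(x$id_a, x$id_b, sep = "-"),
                 n_mapped = x$n_mapped, rmsd = x$rmsd)
}

#' Compare one reference complex against several others
#'
#' @param ref A `complex_structure`.
#' @param others List of `complex_structure` objects.
#' @return Tibble with one row per pair: `pair`, `n_mapped`, `rmsd`.
#' @export
compare_structures <- function(ref, others) {
  purrr::map_dfr(others, function(b) glance(calpha_rmsd(ref, b)))
}

#' Ligand-atom correspondence distance
#'
#' Distance between a named ligand atom of `a` and a named ligand atom of
#' `b`, measured after superposing `b`'s protein onto `a`'s over mapped CA
#' atoms.  Used to ask whether, e.g., C15 of one steroid occupies the
#' position of C16 of another.
#'
#' @param a,b `complex_structure` objects with ligands.
#' @param atom_a,atom_b Ligand atom names (e.g. `"C15"`, `"C16"`).
#' @return Distance in Angstrom.
#' @export
ligand_atom_correspondence <- function(a, b, atom_a, atom_b) {
  pos <- function(s, nm) {
    hit <- which(s$ligand$name == nm)
    if (length(hit) == 0) {
      stop(sprintf("ligand atom '%s' not found in %s; available: %s",
                   nm, s$id, paste(unique(s$ligand$name), collapse = ", ")),
           call. = FALSE)
    }
    as.numeric(s$ligand[hit[1], c("x", "y", "z")])
  }
  cmp <- calpha_rmsd(a, b)
  pb <- apply_superposition(cmp$superposition, pos(b, atom_b))
  vec_distance(pos(a, atom_a), pb)
}
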