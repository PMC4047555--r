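# Atom-centred 2D topological circular fingerprints.
#
# The descriptor of an atomic site is a layered count vector: for each bond
# distance k = 0..d and each SYBYL type t in a fixed ordered alphabet, the
# number of atoms at topological distance exactly k from the centre that carry
# type t. Length L = (d + 1) * |alphabet|, layer-major. Distance-0 is the
# centre atom itself, so its layer always sums to 1. Atoms in other connected
# components (counter-ions in salt entries) are unreachable and contribute
# nothing.

#' Topological distances from a centre atom
#'
#' Minimum bond counts (breadth-first shortest paths) from `centre_atom` to
#' every atom in the same connected component.
#'
#' @param mol A [som_molecule()].
#' @param centre_atom 1-based atom index.
#' @return Named integer vector: names are atom indices (as characters),
#'   values are distances; unreachable atoms are absent.
#' @export
topological_distances <- function(mol, centre_atom) {
  if (!centre_atom %in% mol$atoms$index) {
    abort(sprintf("atom %d is not in molecule %s", centre_atom, mol$mol_id))
  }
  g <- mol_graph(mol)
  dm <- igraph::distances(g, v = as.character(centre_atom), mode = "all")
  d <- setNames(dm[1, ], colnames(dm))
  d <- d[is.finite(d)]
  setNames(as.integer(d), names(d))
}

#' Build the sorted SYBYL type alphabet of a corpus
#'
#' @param molecules List of [som_molecule()] objects.
#' @return Character vector of distinct SYBYL types, lexicographically sorted
#'   (C locale); this ordering is fixed and persisted with any dataset.
#' @export
type_alphabet <- function(molecules) {
  types <- unique(unlist(map(molecules, ~ .x$atoms$sybyl_type)))
  withr::with_locale(c(LC_COLLATE = "C"), sort(types))
}

#' Circular fingerprint of one atomic site
#'
#' @param mol A [som_molecule()].
#' @param centre_atom 1-based atom index of the site.
#' @param depth Bond depth d (>= 0). Layers beyond the molecular diameter are
#'   all-zero.
#' @param alphabet Ordered type alphabet; every atom type in the molecule must
#'   be present in it.
#' @return Integer vector of length `(depth + 1) * length(alphabet)`,
#'   layer-major.
#' @export
#' @examples
#' m <- som_molecule("ethane",
#'   atoms = tibble::tibble(index = 1:2, sybyl_type = c("C.3", "C.3")),
#'   bonds = tibble::tibble(from = 1, to = 2))
#' circular_fingerprint(m, 1, depth = 1, alphabet = "C.3")
circular_fingerprint <- function(mol, centre_atom, depth, alphabet) {
  stopifnot(depth >= 0)
  check_alphabet(mol, alphabet)
  d <- topological_distances(mol, centre_atom)
  fingerprint_from_distances(mol, d, depth, alphabet)
}

check_alphabet <- function(mol, alphabet) {
  unseen <- setdiff(mol$atoms$sybyl_type, alphabet)
  if (length(unseen) > 0L) {
    abort(sprintf(
      "molecule %s carries SYBYL type(s) outside the alphabet: %s (alphabet built from a different corpus?)",
      mol$mol_id, paste(unseen, collapse = ", ")),
      class = "somkit_alphabet_error")
  }
  invisible(TRUE)
}

fingerprint_from_distances <- function(mol, dists, depth, alphabet) {
  A <- length(alphabet)
  fp <- integer((depth + 1L) * A)
  keep <- dists <= depth
  if (any(keep)) {
    idx <- as.integer(names(dists)[keep])
    t_i <- match(mol$atoms$sybyl_type[match(idx, mol$atoms$index)], alphabet)
    pos <- dists[keep] * A + t_i
    tab <- table(pos)
    fp[as.integer(names(tab))] <- as.integer(tab)
  }
  fp
}

# all-atom distance matrix (atom index x atom index, Inf across components)
all_distances <- function(mol) {
  g <- mol_graph(mol)
  d <- igraph::distances(g, mode = "all")
  dimnames(d) <- list(as.character(mol$atoms$index), as.character(mol$atoms$index))
  d
}

# fingerprints for several centres at once; rows in `centres` order
fingerprint_rows <- function(mol, centres, depth, alphabet) {
  check_alphabet(mol, alphabet)
  dm <- all_distances(mol)
  t(vapply(centres, function(a) {
    d <- dm[as.character(a), ]
    d <- d[is.finite(d)]
    fingerprint_from_distances(mol, setNames(as.integer(d), names(d)), depth, alphabet)
  }, integer((depth + 1L) * length(alphabet))))
}

#' Topologically equivalent atomic sites
#'
#' Groups candidate atoms whose whole-molecule circular fingerprints are
#' identical. Fingerprints are computed at depth equal to the molecular graph
#' diameter, the smallest depth guaranteed to span the entire ligand, so e.g.
#' the six carbons of benzene fall in one class. Such sites are topologically
#' interchangeable and are collapsed to a single prediction when ranking.
#'
#' @param mol A [som_molecule()].
#' @param candidate_atoms Atom indices to partition (default: heavy atoms).
#' @return A list of integer vectors (sorted atom indices); disjoint groups
#'   covering all candidate atoms, ordered by smallest member.
#' @export
equivalence_classes <- function(mol, candidate_atoms = NULL) {
  if (is.null(candidate_atoms)) candidate_atoms <- mol$atoms$index[mol$atoms$is_heavy]
  if (!all(candidate_atoms %in% mol$atoms$index)) {
    abort("candidate_atoms must be a subset of the molecule's atoms")
  }
  if (length(candidate_atoms) == 0L) return(list())
  dm <- all_distances(mol)
  diam <- max(0L, as.integer(dm[is.finite(dm)]))
  alpha <- type_alphabet(list(mol))
  fps <- fingerprint_rows(mol, candidate_atoms, diam, alpha)
  key <- apply(fps, 1L, paste, collapse = ",")
  groups <- split(as.integer(candidate_atoms), key)
  groups <- map(groups, sort)
  groups[order(map_int(groups, 1L))] |> unname()
}

#' Build a labelled site dataset from molecules and annotations
#'
#' One record per candidate atomic site per molecule; the label is `SOM`
#' (class omega0) iff the atom is annotated as an experimentally observed site
#' of metabolism, `NONSOM` (omega1) otherwise. The type alphabet is the sorted
#' union of SYBYL types over the corpus unless supplied.
#'
#' @param molecules List of [som_molecule()] objects.
#' @param annotations Annotation tibble from [read_som_annotations()];
#'   molecules without a row get all-`NONSOM` sites.
#' @param depth Bond depth d (0-8).
#' @param include_h_sites Should hydrogens be candidate (rankable/labelled)
#'   sites? Default `FALSE`: SoMs in curated CYP sets are heavy atoms (hydrogen
#'   abstraction is attributed to the attached heavy atom), but hydrogens
#'   always contribute counts inside fingerprints.
#' @param alphabet Optional fixed alphabet (e.g. a training alphabet).
#' @return A `som_sites` tibble, rows ordered by molecule (input order) then
#'   atom index — deterministic for a given corpus.
#' @export
build_site_dataset <- function(molecules, annotations, depth,
                               include_h_sites = FALSE, alphabet = NULL) {
  stopifnot(depth >= 0, depth <= 8)
  validate_annotations(molecules, annotations)
  if (is.null(alphabet)) alphabet <- type_alphabet(molecules)
  rows <- map(molecules, function(m) {
    cand <- if (include_h_sites) m$atoms$index else m$atoms$index[m$atoms$is_heavy]
    cand <- sort(cand)
    if (length(cand) == 0L) return(NULL)
    som <- annotations$som_atoms[match(m$mol_id, annotations$mol_id)]
    som <- if (length(som) == 1L && !is.null(som[[1]])) som[[1]] else integer()
    fps <- fingerprint_rows(m, cand, depth, alphabet)
    colnames(fps) <- paste0("f_", seq_len(ncol(fps)))
    dplyr::bind_cols(
      tibble(mol_id = m$mol_id, atom_index = cand,
             label = ifelse(cand %in% som, "SOM", "NONSOM")),
      as_tibble(fps))
  })
  as_som_sites(bind_rows(rows), depth = depth, alphabet = alphabet)
}
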