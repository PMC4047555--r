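# Applicability-domain split by whole-molecule similarity.
#
# A random test set TS1 (20% of the corpus by default) is split off, and its
# most dissimilar half, TS2, is identified by each TS1 molecule's maximum
# path-based Tanimoto similarity to any training molecule. Comparing
# performance on TS1 vs TS2 probes how far the classifiers extrapolate beyond
# the training chemistry.

#' Path-based whole-molecule fingerprint
#'
#' The set of canonical SYBYL-type strings of all simple (non-revisiting)
#' linear paths of up to `max_len` bonds in the molecule. Each path is read as
#' the sequence of atom types along it; forward and reverse readings are
#' collapsed to the lexicographically smaller one.
#'
#' @param mol A [som_molecule()].
#' @param max_len Maximum path length in bonds (default 4).
#' @return Character vector (a set) of canonical path strings.
#' @export
path_fingerprint <- function(mol, max_len = 4L) {
  idx <- mol$atoms$index
  type_of <- setNames(mol$atoms$sybyl_type, as.character(idx))
  nbrs <- map(setNames(idx, as.character(idx)), function(a) {
    c(mol$bonds$to[mol$bonds$from == a], mol$bonds$from[mol$bonds$to == a])
  })
  paths <- character(0)
  walk_from <- function(path) {
    types <- unname(type_of[as.character(path)])
    fwd <- paste(types, collapse = "-")
    rev_ <- paste(rev(types), collapse = "-")
    paths[[length(paths) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    if (length(path) > max_len) return(invisible())
    for (nb in nbrs[[as.character(path[length(path)])]]) {
      if (!nb %in% path) walk_from(c(path, nb))
    }
  }
  for (a in idx) walk_from(a)
  unique(paths)
}

#' Tanimoto similarity between two fingerprint sets
#'
#' @param a,b Character vectors treated as sets.
#' @return `|intersection| / |union|` in `[0, 1]` (1 for two empty sets).
#' @export
tanimoto_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Random test split with a dissimilar subset
#'
#' Selects a seeded random test set TS1 of `fraction` of the molecules (the
#' rest form the training set), scores each TS1 molecule by its maximum
#' path-fingerprint Tanimoto similarity to any training molecule, and marks
#' the least-similar half of TS1 as TS2.
#'
#' @param molecules List of [som_molecule()] objects (>= 10).
#' @param fraction Test fraction in (0, 1), default 0.2.
#' @param seed Integer RNG seed.
#' @param max_len Path length for [path_fingerprint()].
#' @return A tibble with one row per molecule: `mol_id`, `set` (`"train"` or
#'   `"TS1"`), `max_similarity` (NA for training molecules) and `ts2`
#'   (logical; TS2 is a subset of TS1).
#' @export
similarity_split <- function(molecules, fraction = 0.2, seed = 1, max_len = 4L) {
  if (fraction <= 0 || fraction >= 1) {
    abort("fraction must lie in (0, 1)", class = "somkit_parameter_error")
  }
  n <- length(molecules)
  if (n < 10L) abort("similarity split needs >= 10 molecules",
                     class = "somkit_parameter_error")
  ids <- map_chr(molecules, "mol_id")
  n_test <- max(1L, round(fraction * n))
  test_idx <- withr::with_seed(as.integer(seed), sort(sample.int(n, n_test)))
  fps <- map(molecules, path_fingerprint, max_len = max_len)
  train_fps <- fps[-test_idx]
  max_sim <- map_dbl(test_idx, function(i) {
    max(map_dbl(train_fps, tanimoto_similarity, b = fps[[i]]))
  })
  n_ts2 <- floor(n_test / 2)
  # least similar half of TS1; deterministic tie-break by mol_id
  ord <- order(max_sim, ids[test_idx])
  ts2_ids <- ids[test_idx][ord][seq_len(n_ts2)]
  tibble(
    mol_id = ids,
    set = ifelse(seq_len(n) %in% test_idx, "TS1", "train"),
    max_similarity = ifelse(seq_len(n) %in% test_idx,
                            max_sim[match(seq_len(n), test_idx)], NA_real_),
    ts2 = ids %in% ts2_ids
  )
}
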