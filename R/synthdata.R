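# Synthetic corpora with a plantable local-motif SoM signal.
#
# Molecules are random connected graphs (uniform-attachment spanning tree plus
# a few chords, degree-capped at 4) with SYBYL-like atom types sampled from a
# small alphabet. One instance of a local motif — required neighbour types at
# given bond distances around a centre — is planted per molecule, and atoms
# are labelled SoM with a high probability when they match the motif and a low
# background probability otherwise. Because the default motif leaves the
# centre's own type free (any type may be a centre), the distance-0 layer of a
# fingerprint carries no label signal: depth-0 models perform at chance while
# models at or beyond the motif depth can recover the signal. No chemical
# realism is claimed; the corpus exercises the topological machinery only.

#' Configuration for the synthetic corpus generator
#'
#' @param n_molecules Number of molecules (>= 1).
#' @param atom_range Length-2 integer range of atoms per molecule (min >= 3 so
#'   a distance-2 shell always exists).
#' @param alphabet SYBYL-like types to sample atoms from.
#' @param motif List with `centre` (a type, or `NA` for any — the
#'   "type-balanced centres" condition) and `shells`, a list mapping bond
#'   distance (names, `"1"`, `"2"`, ...) to the multiset (character vector) of
#'   types required at exactly that distance.
#' @param motif_p Probability that a motif-matching atom is labelled SoM
#'   (default 0.95).
#' @param background_p Probability that any other atom is labelled SoM
#'   (default 0.01).
#' @param extra_edge_p Expected chords per atom beyond the spanning tree
#'   (default 0.15).
#' @param seed Integer RNG seed; corpora are byte-identical for equal seeds.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_molecules = 100, atom_range = c(8L, 16L),
                         alphabet = c("C.3", "C.ar", "N.3", "O.3", "S.3"),
                         motif = list(centre = NA_character_,
                                      shells = list("1" = "N.3", "2" = "O.3")),
                         motif_p = 0.95, background_p = 0.01,
                         extra_edge_p = 0.15, seed = 1) {
  if (motif_p < 0 || motif_p > 1 || background_p < 0 || background_p > 1) {
    abort("motif_p and background_p must lie in [0, 1]", class = "somkit_config_error")
  }
  need <- unique(c(if (!is.na(motif$centre)) motif$centre, unlist(motif$shells)))
  if (!all(need %in% alphabet)) {
    abort(sprintf("motif type(s) absent from the alphabet: %s",
                  paste(setdiff(need, alphabet), collapse = ", ")),
          class = "somkit_config_error")
  }
  if (length(atom_range) != 2L || atom_range[1] < 3L || atom_range[2] < atom_range[1]) {
    abort("atom_range must be c(min, max) with min >= 3", class = "somkit_config_error")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 atom_range = as.integer(atom_range), alphabet = alphabet,
                 motif = motif, motif_p = motif_p, background_p = background_p,
                 extra_edge_p = extra_edge_p, seed = as.integer(seed)),
            class = "synth_config")
}

#' Motif depth of a configuration
#' @param config A [synth_config()].
#' @return The largest shell distance the motif constrains.
#' @export
motif_depth <- function(config) {
  if (length(config$motif$shells) == 0L) return(0L)
  max(as.integer(names(config$motif$shells)))
}

#' Atoms of a molecule matching a motif
#'
#' An atom matches when its own type equals the motif centre (or the centre is
#' `NA`) and, for every constrained distance k, the multiset of types found at
#' exactly distance k contains the required multiset.
#'
#' @param mol A [som_molecule()].
#' @param motif A motif list (see [synth_config()]).
#' @return Integer vector of matching atom indices.
#' @export
motif_atoms <- function(mol, motif) {
  keep(mol$atoms$index, function(a) {
    if (!is.na(motif$centre) &&
        mol$atoms$sybyl_type[match(a, mol$atoms$index)] != motif$centre) {
      return(FALSE)
    }
    d <- topological_distances(mol, a)
    for (k in names(motif$shells)) {
      at_k <- as.integer(names(d)[d == as.integer(k)])
      types_k <- mol$atoms$sybyl_type[match(at_k, mol$atoms$index)]
      req <- table(motif$shells[[k]])
      have <- table(factor(types_k, levels = names(req)))
      if (any(have < req)) return(FALSE)
    }
    TRUE
  }) |> as.integer()
}

# one random connected typed graph with the motif planted; pure given the RNG
random_molecule <- function(mol_id, config) {
  n <- sample(seq(config$atom_range[1], config$atom_range[2]), 1L)
  deg <- integer(n)
  from <- integer(0); to <- integer(0)
  for (k in seq(2L, n)) {          # uniform attachment, degree cap 4
    open <- which(deg[seq_len(k - 1L)] < 4L)
    parent <- open[sample.int(length(open), 1L)]
    from <- c(from, parent); to <- c(to, k)
    deg[parent] <- deg[parent] + 1L; deg[k] <- deg[k] + 1L
  }
  for (try in seq_len(rbinom(1L, n, min(1, config$extra_edge_p)))) {
    ab <- sample.int(n, 2L)
    a <- min(ab); b <- max(ab)
    dup <- any(from == a & to == b)
    if (!dup && deg[a] < 4L && deg[b] < 4L) {
      from <- c(from, a); to <- c(to, b)
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    }
  }
  types <- sample(config$alphabet, n, replace = TRUE)
  mol <- som_molecule(mol_id, tibble(index = seq_len(n), sybyl_type = types),
                      tibble(from = from, to = to))
  plant_motif(mol, config)
}

# retype atoms around a feasible centre so one motif instance exists
plant_motif <- function(mol, config) {
  motif <- config$motif
  if (length(motif$shells) == 0L) return(mol)
  dists <- map(mol$atoms$index, ~ topological_distances(mol, .x))
  feasible <- keep(seq_along(dists), function(i) {
    all(map_lgl(names(motif$shells), function(k) {
      sum(dists[[i]] == as.integer(k)) >= length(motif$shells[[k]])
    }))
  })
  if (length(feasible) == 0L) return(mol)   # tiny pathological graph; caller resamples
  ci <- feasible[sample.int(length(feasible), 1L)]
  types <- mol$atoms$sybyl_type
  if (!is.na(motif$centre)) types[ci] <- motif$centre
  d <- dists[[ci]]
  for (k in names(motif$shells)) {
    shell <- as.integer(names(d)[d == as.integer(k)])
    pick <- sample(shell, length(motif$shells[[k]]))
    types[match(pick, mol$atoms$index)] <- motif$shells[[k]]
  }
  som_molecule(mol$mol_id, tibble(index = mol$atoms$index, sybyl_type = types),
               mol$bonds)
}

#' Generate a synthetic corpus
#'
#' @param config A [synth_config()].
#' @return A list with `molecules` (list of [som_molecule()]) and
#'   `annotations` (tibble `mol_id`, `som_atoms`; SoM sets may be empty for
#'   unlucky molecules and are then excluded by [evaluate_som()]).
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  if (config$n_molecules < 1L) {
    abort("n_molecules must be >= 1", class = "somkit_generation_error")
  }
  withr::with_seed(config$seed, {
    molecules <- map(seq_len(config$n_molecules), function(i) {
      random_molecule(sprintf("synth_%03d", i), config)
    })
    annotations <- bind_rows(map(molecules, function(m) {
      matches <- motif_atoms(m, config$motif)
      p <- ifelse(m$atoms$index %in% matches, config$motif_p, config$background_p)
      tibble(mol_id = m$mol_id,
             som_atoms = list(m$atoms$index[runif(nrow(m$atoms)) < p]))
    }))
    list(molecules = molecules, annotations = annotations)
  })
}

#' Generate a labelled fingerprint site dataset
#'
#' Generates a corpus and fingerprints it at the requested depth. If one of
#' the two classes comes out empty (possible for tiny corpora), the corpus is
#' regenerated with an incremented sub-seed, up to 100 attempts.
#'
#' @param config A [synth_config()].
#' @param depth Fingerprint bond depth; a depth below [motif_depth()] cannot
#'   encode the planted signal (by design — the signal-erasure control).
#' @return A list with `sites` (`som_sites` tibble), `molecules`,
#'   `annotations`.
#' @export
generate_site_dataset <- function(config, depth) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  for (attempt in seq_len(100L)) {
    cfg <- config
    cfg$seed <- config$seed + (attempt - 1L)
    corpus <- generate_corpus(cfg)
    sites <- build_site_dataset(corpus$molecules, corpus$annotations, depth)
    if (all(.SOM_LABELS %in% sites$label)) {
      if (attempt > 1L) {
        inform(sprintf("regenerated corpus %d time(s) to obtain both classes",
                       attempt - 1L))
      }
      return(list(sites = sites, molecules = corpus$molecules,
                  annotations = corpus$annotations))
    }
  }
  abort("could not generate a corpus with both classes in 100 attempts",
        class = "somkit_generation_error")
}
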