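# Shared fixtures and independent oracles, all built in code.

mk_mol <- function(id, types, bonds) {
  som_molecule(id,
               atoms = tibble::tibble(index = seq_along(types), sybyl_type = types),
               bonds = tibble::tibble(from = bonds[, 1], to = bonds[, 2]))
}

methane_mol <- function() {
  mk_mol("methane", c("C.3", "H", "H", "H", "H"),
         cbind(1L, 2:5))
}

# ethanol with explicit hydrogens: C1(H3) - C2(H2) - O3(H)
ethanol_mol <- function() {
  mk_mol("ethanol",
         c("C.3", "C.3", "O.3", "H", "H", "H", "H", "H", "H"),
         rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5), c(1, 6),
               c(2, 7), c(2, 8), c(3, 9)))
}

benzene_mol <- function() {
  mk_mol("benzene", rep("C.ar", 6),
         rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1)))
}

# para-xylene heavy skeleton: ring C1..C6 (C.ar), methyls C7 on C1, C8 on C4
para_xylene_mol <- function() {
  mk_mol("para_xylene", c(rep("C.ar", 6), "C.3", "C.3"),
         rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1),
               c(1, 7), c(4, 8)))
}

# connected random typed graph, independent of the package's generator
random_test_mol <- function(n, types = c("C.3", "N.3", "O.3"), extra = 2L,
                            id = "rnd") {
  stopifnot(n >= 2)
  bonds <- cbind(vapply(2:n, function(k) sample.int(k - 1L, 1L), 1L), 2:n)
  for (i in seq_len(extra)) {
    ab <- sort(sample.int(n, 2L))
    if (!any(bonds[, 1] == ab[1] & bonds[, 2] == ab[2])) bonds <- rbind(bonds, ab)
  }
  mk_mol(id, sample(types, n, replace = TRUE), bonds)
}

# Floyd-Warshall all-pairs shortest paths; independent of igraph BFS
fw_distances <- function(mol) {
  n <- nrow(mol$atoms)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[r]; j <- mol$bonds$to[r]
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# shell-count oracle: type counts per exact distance, from fw_distances
shell_fp_oracle <- function(mol, centre, depth, alphabet) {
  d <- fw_distances(mol)[match(centre, mol$atoms$index), ]
  fp <- integer((depth + 1L) * length(alphabet))
  for (k in 0:depth) {
    at_k <- which(d == k)
    for (a in at_k) {
      t_i <- match(mol$atoms$sybyl_type[a], alphabet)
      fp[k * length(alphabet) + t_i] <- fp[k * length(alphabet) + t_i] + 1L
    }
  }
  fp
}

# graph-automorphism orbit oracle by exhaustive permutation (n <= 8)
automorphism_orbits <- function(mol, candidates) {
  n <- nrow(mol$atoms)
  stopifnot(n <= 8)
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(mol$bonds))) {
    adj[mol$bonds$from[r], mol$bonds$to[r]] <- TRUE
    adj[mol$bonds$to[r], mol$bonds$from[r]] <- TRUE
  }
  types <- mol$atoms$sybyl_type
  perms <- gtools_permutations(n)
  orbit_id <- seq_len(n)
  for (p in perms) {
    if (!all(types[p] == types)) next
    if (!identical(adj[p, p], adj)) next
    for (v in seq_len(n)) {           # union the orbits v ~ p[v]
      a <- min(orbit_id[v], orbit_id[p[v]])
      orbit_id[orbit_id %in% c(orbit_id[v], orbit_id[p[v]])] <- a
    }
  }
  unname(split(candidates, orbit_id[candidates]))
}

gtools_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- gtools_permutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# tiny labelled site tibble from raw matrices, for classifier/ensemble tests
sites_from_matrices <- function(X0, X1, depth = 0L) {
  L <- ncol(X0)
  alphabet <- paste0("T", seq_len(L))  # depth 0, |alphabet| = L
  df <- tibble::tibble(
    mol_id = c(sprintf("m0_%d", seq_len(nrow(X0))), sprintf("m1_%d", seq_len(nrow(X1)))),
    atom_index = 1L,
    label = c(rep("SOM", nrow(X0)), rep("NONSOM", nrow(X1)))
  )
  feats <- rbind(X0, X1)
  colnames(feats) <- paste0("f_", seq_len(L))
  as_som_sites(dplyr::bind_cols(df, tibble::as_tibble(feats)),
               depth = depth, alphabet = alphabet)
}

rand_count_matrix <- function(n, L, max_val = 3L) {
  matrix(sample(0:max_val, n * L, replace = TRUE), nrow = n)
}
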