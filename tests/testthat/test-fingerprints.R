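# Circular fingerprints, distances and equivalent-site detection.

test_that("topological distances match definitions on chains and the centre", {
  chain <- mk_mol("chain", c("C.3", "C.3", "O.3"), rbind(c(1, 2), c(2, 3)))
  d <- topological_distances(chain, 1L)
  expect_equal(d[["1"]], 0L)
  expect_equal(d[["2"]], 1L)
  expect_equal(d[["3"]], 2L)
})

test_that("BFS distances agree with a Floyd-Warshall oracle on random graphs", {
  set.seed(101)
  for (rep in 1:10) {
    m <- random_test_mol(12L, extra = 3L)
    fw <- fw_distances(m)
    for (a in c(1L, 5L, 12L)) {
      d <- topological_distances(m, a)
      expect_equal(unname(d[as.character(seq_len(12))]), as.integer(fw[a, ]))
    }
  }
})

test_that("fingerprints handle isolated atoms and forced small cases", {
  lone <- mk_mol("lone", "C.3", matrix(integer(), ncol = 2))
  fp <- circular_fingerprint(lone, 1L, depth = 3, alphabet = c("C.3", "H"))
  expect_equal(fp, c(1L, rep(0L, 7)))

  fp_me <- circular_fingerprint(methane_mol(), 1L, depth = 1,
                                alphabet = c("C.3", "H"))
  expect_equal(fp_me, c(1L, 0L, 0L, 4L))
})

test_that("fingerprints equal an independent shell-enumeration oracle (ethanol, all atoms)", {
  m <- ethanol_mol()
  alpha <- type_alphabet(list(m))
  for (a in m$atoms$index) {
    expect_equal(circular_fingerprint(m, a, 4, alpha),
                 shell_fp_oracle(m, a, 4, alpha))
  }
})

test_that("fingerprint length is (depth+1) x |alphabet|, e.g. 175 at depth 6 with 25 types", {
  alpha25 <- sprintf("T%02d", 1:25)
  m <- mk_mol("x", c("T01", "T02"), rbind(c(1, 2)))
  expect_length(circular_fingerprint(m, 1L, 6, alpha25), 175L)
})

test_that("types outside the alphabet raise an alphabet error", {
  m <- ethanol_mol()
  expect_error(circular_fingerprint(m, 1L, 2, c("C.3", "H")),
               class = "somkit_alphabet_error")
})

test_that("layer counts conserve BFS shell sizes and sum of layer 0 is 1", {
  set.seed(7)
  for (rep in 1:8) {
    m <- random_test_mol(10L)
    alpha <- type_alphabet(list(m))
    A <- length(alpha)
    depth <- 4L
    d <- fw_distances(m)
    for (a in c(1L, 10L)) {
      fp <- circular_fingerprint(m, a, depth, alpha)
      for (k in 0:depth) {
        layer <- fp[(k * A + 1):((k + 1) * A)]
        expect_equal(sum(layer), sum(d[a, ] == k))
      }
      expect_equal(sum(fp[1:A]), 1L)
    }
  }
})

test_that("fingerprints are graph-intrinsic: permuting atom input order changes nothing", {
  set.seed(21)
  m <- random_test_mol(9L)
  perm <- sample(9L)
  # relabel atoms: atom i becomes perm[i]
  m2 <- som_molecule("perm",
                     tibble::tibble(index = perm, sybyl_type = m$atoms$sybyl_type)[order(perm), ],
                     tibble::tibble(from = perm[m$atoms$index[m$bonds$from]],
                                    to = perm[m$atoms$index[m$bonds$to]]))
  alpha <- type_alphabet(list(m))
  for (a in m$atoms$index) {
    expect_equal(circular_fingerprint(m, a, 3, alpha),
                 circular_fingerprint(m2, perm[a], 3, alpha))
  }
})

test_that("increasing depth preserves existing layers (prefix property)", {
  set.seed(31)
  m <- random_test_mol(10L)
  alpha <- type_alphabet(list(m))
  A <- length(alpha)
  for (a in c(2L, 6L)) {
    fp3 <- circular_fingerprint(m, a, 3, alpha)
    fp6 <- circular_fingerprint(m, a, 6, alpha)
    expect_equal(fp6[seq_len(4 * A)], fp3)
  }
})

test_that("equivalence classes capture full symmetry and its absence", {
  expect_equal(equivalence_classes(benzene_mol()), list(1:6))
  eth_heavy <- equivalence_classes(ethanol_mol())
  expect_equal(eth_heavy, list(1L, 2L, 3L))
})

test_that("equivalence classes match a brute-force automorphism-orbit oracle", {
  m <- para_xylene_mol()
  got <- equivalence_classes(m)
  want <- automorphism_orbits(m, m$atoms$index[m$atoms$is_heavy])
  normalise <- function(cls) unname(cls[order(purrr::map_int(cls, 1L))])
  expect_equal(normalise(got), normalise(purrr::map(want, sort)))
  # ring carbons split 2+4 (adjacent to methyl vs not), methyls together
  expect_equal(sort(lengths(got)), c(2L, 2L, 4L))
})

test_that("equivalence is an equivalence relation: disjoint groups covering all candidates", {
  set.seed(41)
  for (rep in 1:5) {
    m <- random_test_mol(8L)
    cls <- equivalence_classes(m)
    all_atoms <- sort(unlist(cls))
    expect_equal(all_atoms, m$atoms$index[m$atoms$is_heavy])
    expect_equal(anyDuplicated(unlist(cls)), 0L)
  }
})

test_that("build_site_dataset labels, counts and alphabet behave as specified", {
  m <- ethanol_mol()
  ann <- tibble::tibble(mol_id = "ethanol", som_atoms = list(2L))
  sites <- build_site_dataset(list(m), ann, depth = 2)
  expect_equal(nrow(sites), 3L)                      # heavy atoms only
  expect_equal(sites$label, c("NONSOM", "SOM", "NONSOM"))
  expect_equal(attr(sites, "alphabet"), c("C.3", "H", "O.3"))
  expect_equal(sum(grepl("^f_", names(sites))), 3L * 3L)

  with_h <- build_site_dataset(list(m), ann, depth = 2, include_h_sites = TRUE)
  expect_equal(nrow(with_h), 9L)

  # corpora differing in one atom type: L differs by (d+1)
  m2 <- mk_mol("m2", c("C.3", "S.3"), rbind(c(1, 2)))
  ann2 <- tibble::tibble(mol_id = "m2", som_atoms = list(1L))
  s_a <- build_site_dataset(list(m), ann, depth = 2)
  s_b <- build_site_dataset(list(m, m2), dplyr::bind_rows(ann, ann2), depth = 2)
  expect_equal(sum(grepl("^f_", names(s_b))) - sum(grepl("^f_", names(s_a))), 3L)
})

test_that("class sizes equal an independent recount of annotation entries", {
  cfg <- synth_config(n_molecules = 20, seed = 5)
  corp <- generate_corpus(cfg)
  sites <- build_site_dataset(corp$molecules, corp$annotations, depth = 2)
  n0_expected <- sum(purrr::map_int(corp$molecules, function(m) {
    som <- corp$annotations$som_atoms[match(m$mol_id, corp$annotations$mol_id)][[1]]
    length(intersect(som, m$atoms$index[m$atoms$is_heavy]))
  }))
  expect_equal(sum(sites$label == "SOM"), n0_expected)
  expect_equal(nrow(sites), sum(purrr::map_int(corp$molecules,
                                               ~ sum(.x$atoms$is_heavy))))
})

test_that("annotations referencing a missing molecule raise a consistency error", {
  ann <- tibble::tibble(mol_id = "ghost", som_atoms = list(1L))
  expect_error(build_site_dataset(list(ethanol_mol()), ann, depth = 1),
               class = "somkit_consistency_error")
})

test_that("site datasets built twice from the same inputs are byte-identical", {
  cfg <- synth_config(n_molecules = 6, seed = 9)
  corp <- generate_corpus(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_site_dataset(build_site_dataset(corp$molecules, corp$annotations, 3), p1)
  write_site_dataset(build_site_dataset(corp$molecules, corp$annotations, 3), p2)
  expect_identical(readLines(p1), readLines(p2))
})
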