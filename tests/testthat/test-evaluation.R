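# LOO folds, ranking, metrics and the similarity split.

small_corpus <- function(n = 10, seed = 3) {
  generate_corpus(synth_config(n_molecules = n, atom_range = c(6L, 10L), seed = seed))
}

test_that("LOO folds partition the corpus at molecule level with no leakage", {
  cfg <- synth_config(n_molecules = 10, seed = 2)
  ds <- generate_site_dataset(cfg, depth = 2)
  folds <- loo_folds(ds$sites)
  expect_length(folds, 10L)
  test_ids <- purrr::map_chr(folds, "mol_id")
  expect_setequal(test_ids, unique(ds$sites$mol_id))
  expect_equal(anyDuplicated(test_ids), 0L)
  for (f in folds) {
    expect_equal(sum(f$train$mol_id == f$mol_id), 0L)
    expect_equal(nrow(f$train) + nrow(f$test), nrow(ds$sites))
  }
  one_mol <- ds$sites[ds$sites$mol_id == test_ids[1], ]
  expect_error(loo_folds(one_mol), class = "somkit_fold_error")
})

test_that("rank_sites collapses equivalent atoms, sorts, and breaks ties by atom index", {
  m <- para_xylene_mol()  # classes {1,4}? no: ring-adjacent {2,3,5,6}, ipso {1,4}, methyl {7,8}
  cls <- equivalence_classes(m)
  probs <- c(0.9, 0.4, 0.4, 0.9, 0.4, 0.4, 0.1, 0.1)
  preds <- tibble::tibble(mol_id = "para_xylene", atom_index = 1:8,
                          prob_som = probs)
  ranked <- rank_sites(preds, list(m))
  expect_equal(nrow(ranked), length(cls))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_true(all(diff(ranked$prob_som) <= 0))
  expect_equal(ranked$atom_index[1], 1L)          # p=0.9 class, rep = min index

  # all equal probabilities: ranks follow representative atom-index order
  preds_eq <- tibble::tibble(mol_id = "para_xylene", atom_index = 1:8, prob_som = 0.5)
  ranked_eq <- rank_sites(preds_eq, list(m))
  expect_equal(ranked_eq$atom_index, sort(ranked_eq$atom_index))

  # random probabilities agree with a sort oracle on (-p, atom_index)
  set.seed(20)
  m2 <- random_test_mol(7L, id = "rnd7")
  cls2 <- equivalence_classes(m2)
  p2 <- runif(7)
  # equivalent atoms must share a probability for the contract to hold
  for (g in cls2) p2[g] <- p2[g[1]]
  preds2 <- tibble::tibble(mol_id = "rnd7", atom_index = 1:7, prob_som = p2)
  ranked2 <- rank_sites(preds2, list(m2))
  reps <- purrr::map_int(cls2, 1L)
  oracle_order <- reps[order(-p2[reps], reps)]
  expect_equal(ranked2$atom_index, oracle_order)

  expect_error(rank_sites(preds2[-1, ], list(m2)), class = "somkit_coverage_error")
})

test_that("top-k percentages count molecules with a SoM in the top k classes", {
  # single molecule, SoM at rank 1
  m <- ethanol_mol()
  preds <- tibble::tibble(mol_id = "ethanol", atom_index = 1:3,
                          prob_som = c(0.9, 0.2, 0.1))
  ranked <- rank_sites(preds, list(m))
  ann <- tibble::tibble(mol_id = "ethanol", som_atoms = list(1L))
  expect_equal(top_k_percent(ranked, ann, 2), 100)
  expect_error(top_k_percent(ranked, ann, 0), class = "somkit_parameter_error")

  # 4 molecules with best-SoM ranks {1,2,3,5}: top-2 = 50, top-3 = 75
  ranked4 <- dplyr::bind_rows(purrr::map2(
    c("a", "b", "c", "d"), c(1L, 2L, 3L, 5L),
    function(id, r) tibble::tibble(mol_id = id, atom_index = 1:5,
                                   members = as.list(1:5),
                                   prob_som = seq(0.9, 0.1, length.out = 5),
                                   rank = 1:5)[r, ] |>
      dplyr::mutate(rank = r)))
  # mark the true SoM as the atom at the molecule's best rank
  ranked_full <- dplyr::bind_rows(purrr::map(c("a", "b", "c", "d"), function(id) {
    tibble::tibble(mol_id = id, atom_index = 1:5, members = as.list(1:5),
                   prob_som = seq(0.9, 0.1, length.out = 5), rank = 1:5)
  }))
  ann4 <- tibble::tibble(mol_id = c("a", "b", "c", "d"),
                         som_atoms = list(1L, 2L, 3L, 5L))
  expect_equal(top_k_percent(ranked_full, ann4, 2), 50)
  expect_equal(top_k_percent(ranked_full, ann4, 3), 75)
  br <- best_som_ranks(ranked_full, ann4)
  expect_equal(br$best_som_rank, c(1L, 2L, 3L, 5L))
})

test_that("MCC matches its closed form and the zero-denominator convention", {
  expect_equal(mcc_score(tp = 5, fp = 0, tn = 7, fn = 0), 1)
  expect_equal(mcc_score(tp = 0, fp = 0, tn = 12, fn = 3), 0)  # all one class
  got <- mcc_score(tp = 3, fp = 1, tn = 5, fn = 1)
  want <- (3 * 5 - 1 * 1) / sqrt((3 + 1) * (3 + 1) * (5 + 1) * (5 + 1))
  expect_equal(got, want)
  expect_equal(round(got, 4), 0.5833)
})

test_that("confusion counts use the majority-vote operating point with ties to nonSoM", {
  preds <- tibble::tibble(label = c("SOM", "SOM", "NONSOM", "NONSOM"),
                          prob_som = c(0.6, 0.5, 0.4, 0.51))
  cc <- confusion_counts(preds)
  expect_equal(cc$tp, 1L)   # 0.5 exactly -> nonSoM call
  expect_equal(cc$fn, 1L)
  expect_equal(cc$fp, 1L)
  expect_equal(cc$tn, 1L)
  expect_equal(sum(unlist(cc)), 4L)
})

test_that("ROC/AUC: separation gives 1, null data ~0.5, ties match the U statistic", {
  sep <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c("SOM", "SOM", "NONSOM", "NONSOM"))
  expect_equal(sep$auc, 1)
  expect_error(roc_auc(c(0.2, 0.3), c("SOM", "SOM")),
               class = "somkit_undefined_auc_error")

  set.seed(30)
  n <- 4000
  probs <- round(runif(n), 2)
  labels <- sample(c("SOM", "NONSOM"), n, replace = TRUE)
  auc_null <- roc_auc(probs, labels)$auc
  n0 <- sum(labels == "SOM"); n1 <- n - n0
  sd_null <- sqrt((n0 + n1 + 1) / (12 * n0 * n1))
  expect_lt(abs(auc_null - 0.5), 3 * sd_null)

  # exhaustive pair counting with half credit for ties (Mann-Whitney U)
  for (rep in 1:20) {
    probs <- sample(seq(0, 1, by = 0.25), 30, replace = TRUE)
    labels <- sample(c("SOM", "NONSOM"), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    p0 <- probs[labels == "SOM"]; p1 <- probs[labels != "SOM"]
    u <- 0
    for (a in p0) for (b in p1) u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(probs, labels)$auc, u / (length(p0) * length(p1)),
                 tolerance = 1e-12)
  }
})

test_that("the ROC threshold grid runs the curve from (0,0) to (1,1)", {
  set.seed(31)
  probs <- sample(seq(0, 1, by = 1 / 22), 40, replace = TRUE)
  labels <- sample(c("SOM", "NONSOM"), 40, replace = TRUE)
  curve <- roc_curve(probs, labels, j = 11)
  expect_equal(curve$tpr[1], 0); expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1); expect_equal(curve$fpr[nrow(curve)], 1)
  expect_true(all(diff(curve$tpr) >= 0) && all(diff(curve$fpr) >= 0))
})

test_that("evaluate_som produces a coherent report and top-k is monotone in k", {
  corp <- small_corpus(10)
  ev <- evaluate_som(corp$molecules, corp$annotations, depth = 2,
                     base = "rascal", q = 5, j = 11, seed = 1)
  m <- glance(ev)
  expect_true(m$mcc >= -1 && m$mcc <= 1)
  expect_true(m$auc >= 0 && m$auc <= 1)
  expect_lte(m$top1, m$top2); expect_lte(m$top2, m$top3)
  expect_true(all(c("mol_id", "rank", "prob_som") %in% names(tidy(ev))))
})

test_that("identical seed, config and data give bit-identical reports", {
  corp <- small_corpus(8, seed = 17)
  run <- function() evaluate_som(corp$molecules, corp$annotations, depth = 2,
                                 base = "prw", q = 5, j = 11, seed = 9)
  e1 <- run(); e2 <- run()
  expect_identical(glance(e1), glance(e2))
  expect_identical(e1$predictions$prob_som, e2$predictions$prob_som)
})

test_that("scan_q returns one metrics row per grid point", {
  corp <- small_corpus(8, seed = 23)
  sc <- scan_q(corp$molecules, corp$annotations, depth = 1,
               base = "nb", q_grid = c(3L, 6L), j = 11, seed = 1)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$q, c(3L, 6L))
})

test_that("similarity split sizes, identity similarity and the path oracle agree", {
  mols <- purrr::map(1:20, function(i) {
    set.seed(100 + i)
    random_test_mol(8L, id = sprintf("m%02d", i))
  })
  # make one test molecule identical to a training molecule
  sp <- similarity_split(mols, fraction = 0.2, seed = 7)
  expect_equal(sum(sp$set == "TS1"), 4L)
  expect_equal(sum(sp$ts2), 2L)
  expect_true(all(sp$ts2 <= (sp$set == "TS1")))

  ts1_ids <- sp$mol_id[sp$set == "TS1"]
  train_ids <- sp$mol_id[sp$set == "train"]
  dup <- mols[[match(train_ids[1], purrr::map_chr(mols, "mol_id"))]]
  dup$mol_id <- ts1_ids[1]
  mols2 <- mols
  mols2[[match(ts1_ids[1], purrr::map_chr(mols, "mol_id"))]] <- dup
  sp2 <- similarity_split(mols2, fraction = 0.2, seed = 7)
  expect_equal(sp2$max_similarity[sp2$mol_id == ts1_ids[1]], 1)
  if (any(sp2$max_similarity[sp2$set == "TS1"] < 1)) {
    expect_false(sp2$ts2[sp2$mol_id == ts1_ids[1]])
  }

  # path-set Tanimoto against igraph all_simple_paths enumeration
  canonical_paths <- function(m, len) {
    g <- igraph::graph_from_data_frame(m$bonds, directed = FALSE,
                                       vertices = data.frame(name = m$atoms$index))
    out <- character(0)
    for (v in m$atoms$index) {
      out <- c(out, m$atoms$sybyl_type[match(v, m$atoms$index)])
      ps <- igraph::all_simple_paths(g, from = as.character(v), cutoff = len)
      for (p in ps) {
        ids <- as.integer(names(p))
        ty <- m$atoms$sybyl_type[match(ids, m$atoms$index)]
        fwd <- paste(ty, collapse = "-"); rv <- paste(rev(ty), collapse = "-")
        out <- c(out, min(fwd, rv))
      }
    }
    unique(out)
  }
  for (i in 1:5) {
    a <- mols[[i]]; b <- mols[[i + 5]]
    want <- length(intersect(canonical_paths(a, 4), canonical_paths(b, 4))) /
      length(union(canonical_paths(a, 4), canonical_paths(b, 4)))
    expect_equal(tanimoto_similarity(path_fingerprint(a), path_fingerprint(b)),
                 want, info = i)
    expect_setequal(path_fingerprint(a), canonical_paths(a, 4))
  }

  expect_error(similarity_split(mols, fraction = 1.2, seed = 1),
               class = "somkit_parameter_error")
  expect_error(similarity_split(mols[1:5], fraction = 0.2, seed = 1),
               class = "somkit_parameter_error")
})
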