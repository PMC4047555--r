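# Molecule-level leave-one-out evaluation and the reporting metrics.
#
# Each molecule in turn is held out entirely (all its atomic sites removed
# from training) and its sites are scored by an ensemble trained on the rest.
# Per molecule, symmetry-equivalent sites (identical whole-molecule
# fingerprints) are collapsed to one ranked prediction. Reported metrics:
# MCC at the majority-vote operating point, pooled ROC/AUC over all sites,
# and top-k — the percentage of molecules with a true SoM among the k
# highest-ranked site classes.

#' Molecule-level leave-one-out folds
#'
#' @param sites A `som_sites` tibble covering at least two molecules.
#' @return A list of folds, one per molecule (in first-appearance order), each
#'   a list with `mol_id`, `train` (all sites of the other molecules) and
#'   `test` (the held-out molecule's sites).
#' @export
loo_folds <- function(sites) {
  ids <- unique(sites$mol_id)
  if (length(ids) < 2L) {
    abort("leave-one-out needs at least 2 molecules", class = "somkit_fold_error")
  }
  map(ids, function(id) {
    list(mol_id = id,
         train = sites[sites$mol_id != id, ],
         test = sites[sites$mol_id == id, ])
  })
}

#' Leave-one-out site predictions
#'
#' Runs the full molecule-level LOO loop: for each fold an ensemble is trained
#' on all other molecules' sites (fold seed = `seed` + fold index, so folds
#' are reproducible yet draw distinct subsamples) and the held-out sites are
#' scored.
#'
#' @inheritParams train_ensemble
#' @param sites A `som_sites` tibble with >= 2 molecules and both classes.
#' @return A tibble with one row per site: `mol_id`, `atom_index`, `label`,
#'   `votes_som`, `votes_nonsom`, `prob_som`; the number of subclassifiers is
#'   attached as attribute `j`.
#' @export
loo_predict <- function(sites, base = c("rascal", "prw", "nb"), q = 5, j = 201,
                        seed = 1, h = 0.1, tie = c("nonsom", "som")) {
  base <- match.arg(base)
  tie <- match.arg(tie)
  folds <- loo_folds(sites)
  j_used <- NULL
  out <- map(seq_along(folds), function(i) {
    f <- folds[[i]]
    model <- train_ensemble(f$train, base = base, q = q, j = j,
                            seed = seed + i, h = h, tie = tie)
    stopifnot(!any(f$test$mol_id %in% f$train$mol_id))  # no leakage
    j_used <<- model$j
    predict(model, f$test)
  })
  structure(bind_rows(out), j = j_used)
}

#' Rank a molecule's sites with equivalent-atom collapsing
#'
#' Sites with identical whole-molecule circular fingerprints are included only
#' once: each equivalence class becomes one entry, represented by its lowest
#' atom index. Class members share fingerprints and hence probabilities at the
#' modelled depth (asserted). Entries are sorted by descending SoM
#' probability, ties broken by ascending representative atom index.
#'
#' @param predictions Per-site prediction tibble (e.g. from [loo_predict()])
#'   with `mol_id`, `atom_index`, `prob_som`.
#' @param molecules List of [som_molecule()] objects covering the predictions.
#' @param include_h_sites Candidate-atom convention used when predicting.
#' @return A tibble with one row per (molecule, equivalence class): `mol_id`,
#'   `atom_index` (representative), `members` (list), `prob_som`, `rank`
#'   (1 = most likely SoM, gapless within molecule).
#' @export
rank_sites <- function(predictions, molecules, include_h_sites = FALSE) {
  mol_ids <- map_chr(molecules, "mol_id")
  out <- map(unique(predictions$mol_id), function(id) {
    m <- molecules[[match(id, mol_ids)]]
    if (is.na(match(id, mol_ids))) {
      abort(sprintf("no molecule '%s' supplied for ranking", id))
    }
    p <- predictions[predictions$mol_id == id, ]
    cand <- if (include_h_sites) m$atoms$index else m$atoms$index[m$atoms$is_heavy]
    if (!all(cand %in% p$atom_index)) {
      abort(sprintf("molecule %s: missing probability for atom(s) %s", id,
                    paste(setdiff(cand, p$atom_index), collapse = ", ")),
            class = "somkit_coverage_error")
    }
    classes <- equivalence_classes(m, cand)
    probs <- map_dbl(classes, function(cls) {
      pr <- p$prob_som[match(cls, p$atom_index)]
      if (diff(range(pr)) > 1e-9) {
        abort(sprintf("molecule %s: equivalent sites %s carry unequal probabilities",
                      id, paste(cls, collapse = ",")))
      }
      pr[1]
    })
    reps <- map_int(classes, 1L)
    ord <- order(-probs, reps)
    tibble(mol_id = id, atom_index = reps[ord],
           members = classes[ord], prob_som = probs[ord],
           rank = seq_along(ord))
  })
  bind_rows(out)
}

#' Top-k percentage over a ranked prediction set
#'
#' The percentage of molecules for which at least one experimentally observed
#' SoM appears among the `k` highest-ranked site classes (a class counts if
#' any member atom is a true SoM).
#'
#' @param ranked Output of [rank_sites()].
#' @param annotations Annotation tibble; every ranked molecule must have at
#'   least one annotated SoM.
#' @param k Number of top predictions considered (>= 1).
#' @return A percentage in `[0, 100]`.
#' @export
top_k_percent <- function(ranked, annotations, k) {
  if (k < 1L) abort("k must be >= 1", class = "somkit_parameter_error")
  ids <- unique(ranked$mol_id)
  hit <- map_lgl(ids, function(id) {
    som <- annotations$som_atoms[match(id, annotations$mol_id)]
    som <- if (length(som) == 1L && !is.null(som[[1]])) som[[1]] else integer()
    if (length(som) == 0L) {
      abort(sprintf("molecule %s has no annotated SoM", id))
    }
    r <- ranked[ranked$mol_id == id & ranked$rank <= k, ]
    any(map_lgl(r$members, ~ length(intersect(.x, som)) > 0L))
  })
  100 * mean(hit)
}

#' Per-molecule rank of the best-ranked true SoM
#'
#' @inheritParams top_k_percent
#' @return Tibble with `mol_id` and `best_som_rank` (the smallest rank whose
#'   equivalence class contains a true SoM).
#' @export
best_som_ranks <- function(ranked, annotations) {
  ids <- unique(ranked$mol_id)
  best <- map_int(ids, function(id) {
    som <- annotations$som_atoms[match(id, annotations$mol_id)][[1]]
    r <- ranked[ranked$mol_id == id, ]
    is_som <- map_lgl(r$members, ~ length(intersect(.x, som)) > 0L)
    if (!any(is_som)) return(NA_integer_)
    min(r$rank[is_som])
  })
  tibble(mol_id = ids, best_som_rank = best)
}

#' Confusion counts at the majority-vote operating point
#'
#' A site is called SoM when more than half of the subclassifier votes are for
#' omega0 (`prob_som > 0.5`); an exact half split is called nonSoM.
#'
#' @param predictions Per-site prediction tibble with `label` and `prob_som`.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn` (SoM = positive class).
#' @export
confusion_counts <- function(predictions) {
  pred_som <- predictions$prob_som > 0.5
  is_som <- predictions$label == "SOM"
  tibble(tp = sum(pred_som & is_som), fp = sum(pred_som & !is_som),
         tn = sum(!pred_som & !is_som), fn = sum(!pred_som & is_som))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; when any factor of
#' the denominator is zero (e.g. all sites predicted into one class) the score
#' is 0 by convention.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; `tp` may also be a
#'   one-row tibble as returned by [confusion_counts()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc_score <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.data.frame(tp)) { fp <- tp$fp; tn <- tp$tn; fn <- tp$fn; tp <- tp$tp }
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' ROC curve and AUC over pooled site predictions
#'
#' Thresholds sweep the achievable probability grid — multiples of `1/(2j)`
#' when `j` is supplied, otherwise the observed unique probabilities — plus
#' endpoints; a site is called positive when `prob_som >= threshold`. Ties in
#' probability are handled by the sweep itself (all tied sites flip together),
#' and the trapezoidal AUC consequently gives half credit to ties, matching
#' the Mann-Whitney U statistic.
#'
#' @param probs Numeric vector of SoM probabilities.
#' @param labels `"SOM"`/`"NONSOM"` character vector (or logical, `TRUE` =
#'   SoM); both classes must be present.
#' @param j Number of subclassifiers defining the probability grid (optional).
#' @return `roc_curve()`: tibble `threshold`, `tpr`, `fpr` (threshold
#'   descending so the curve runs (0,0) to (1,1)); `roc_auc()`: list with
#'   `auc` and `curve`.
#' @export
roc_curve <- function(probs, labels, j = NULL) {
  pos <- if (is.logical(labels)) labels else labels == "SOM"
  if (!any(pos) || all(pos)) {
    abort("ROC needs both classes present", class = "somkit_undefined_auc_error")
  }
  grid <- if (is.null(j)) sort(unique(probs)) else seq(0, 1, by = 1 / (2 * j))
  thr <- c(Inf, sort(unique(c(grid, 0, 1)), decreasing = TRUE))
  tibble(
    threshold = thr,
    tpr = map_dbl(thr, ~ mean(probs[pos] >= .x)),
    fpr = map_dbl(thr, ~ mean(probs[!pos] >= .x))
  )
}

#' @rdname roc_curve
#' @export
roc_auc <- function(probs, labels, j = NULL) {
  curve <- roc_curve(probs, labels, j)
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  list(auc = auc, curve = curve)
}

#' Full site-of-metabolism evaluation of a corpus
#'
#' The package's main driver: builds the fingerprint dataset, runs
#' molecule-level leave-one-out predictions, ranks sites with
#' equivalent-atom collapsing, and computes the metrics report. Molecules
#' without any annotated SoM are excluded from evaluation (with a message), as
#' top-k is undefined for them.
#'
#' @inheritParams loo_predict
#' @param molecules List of [som_molecule()] objects.
#' @param annotations Annotation tibble ([read_som_annotations()]).
#' @param depth Fingerprint bond depth (0-8).
#' @param include_h_sites Rank hydrogens as candidate sites? Default `FALSE`.
#' @return An object of class `som_eval`: list with `predictions` (per-site
#'   tibble), `ranked` ([rank_sites()] output), `metrics` (one-row tibble:
#'   `mcc`, `auc`, `top1`, `top2`, `top3` plus the configuration echo),
#'   `roc` (curve tibble) and `best_ranks`.
#' @export
#' @examples
#' cfg <- synth_config(n_molecules = 12, seed = 7)
#' corpus <- generate_corpus(cfg)
#' ev <- evaluate_som(corpus$molecules, corpus$annotations, depth = 2,
#'                    base = "rascal", q = 5, j = 11, seed = 1)
#' glance(ev)
evaluate_som <- function(molecules, annotations, depth,
                         base = c("rascal", "prw", "nb"), q = 5, j = 201,
                         seed = 1, h = 0.1, tie = c("nonsom", "som"),
                         include_h_sites = FALSE) {
  base <- match.arg(base)
  tie <- match.arg(tie)
  with_som <- annotations$mol_id[lengths(annotations$som_atoms) > 0L]
  keep <- map_lgl(molecules, ~ .x$mol_id %in% with_som)
  if (any(!keep)) {
    inform(sprintf("excluding %d molecule(s) without annotated SoMs from evaluation",
                   sum(!keep)))
    molecules <- molecules[keep]
    annotations <- annotations[annotations$mol_id %in% map_chr(molecules, "mol_id"), ]
  }
  sites <- build_site_dataset(molecules, annotations, depth,
                              include_h_sites = include_h_sites)
  preds <- loo_predict(sites, base = base, q = q, j = j, seed = seed, h = h, tie = tie)
  ranked <- rank_sites(preds, molecules, include_h_sites = include_h_sites)
  roc <- roc_auc(preds$prob_som, preds$label, j = attr(preds, "j"))
  metrics <- tibble(
    mcc = mcc_score(confusion_counts(preds)),
    auc = roc$auc,
    top1 = top_k_percent(ranked, annotations, 1L),
    top2 = top_k_percent(ranked, annotations, 2L),
    top3 = top_k_percent(ranked, annotations, 3L),
    base = base, depth = as.integer(depth),
    q = if (identical(q, "full")) n_features(sites) else as.integer(q),
    j = attr(preds, "j"), seed = as.integer(seed), h = h,
    n_molecules = length(molecules), n_sites = nrow(preds)
  )
  structure(list(predictions = preds, ranked = ranked, metrics = metrics,
                 roc = roc$curve, best_ranks = best_som_ranks(ranked, annotations)),
            class = "som_eval")
}

#' @export
print.som_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<som_eval> %s depth=%d q=%d j=%d | %d molecules, %d sites\n  MCC %.3f  AUC %.3f  top-1 %.0f%%  top-2 %.0f%%  top-3 %.0f%%\n",
    m$base, m$depth, m$q, m$j, m$n_molecules, m$n_sites,
    m$mcc, m$auc, m$top1, m$top2, m$top3))
  invisible(x)
}

#' @export
glance.som_eval <- function(x, ...) x$metrics

#' @export
tidy.som_eval <- function(x, ...) x$ranked

#' Scan the subsample length q
#'
#' Repeats the full LOO evaluation for each value of a q grid (conventionally
#' 5 to L in steps of 5). RASCAL is expected to collapse towards MCC 0 as q
#' approaches L (exact matching of long subvectors fails), while PRW and NB
#' stay comparatively stable; the scan reports, it does not enforce.
#'
#' @inheritParams evaluate_som
#' @param q_grid Integer vector of subsample lengths within `[1, L]`.
#' @return A tibble of metric rows (class `som_scan`), one per grid point.
#' @export
scan_q <- function(molecules, annotations, depth, base = c("rascal", "prw", "nb"),
                   q_grid = NULL, j = 201, seed = 1, h = 0.1,
                   include_h_sites = FALSE) {
  base <- match.arg(base)
  if (is.null(q_grid)) {
    L <- (depth + 1L) * length(type_alphabet(molecules))
    q_grid <- unique(c(seq(5L, L, by = 5L), L))
  }
  out <- map(q_grid, function(qi) {
    glance(evaluate_som(molecules, annotations, depth, base = base, q = qi,
                        j = j, seed = seed, h = h,
                        include_h_sites = include_h_sites))
  })
  structure(bind_rows(out), class = c("som_scan", class(tibble())))
}
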