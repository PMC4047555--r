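# Random feature-subspace voting ensembles.
#
# j subclassifiers each see a random draw of q distinct feature indices out of
# the L fingerprint positions; each casts one vote (SoM / nonSoM, or a
# half-vote to each class when its Dirac conditionals are both zero), and the
# site's SoM probability is votes(SoM) / j. One subsample set is drawn per
# trained ensemble and shared across all test sites.

#' Draw the feature-index subsamples of an ensemble
#'
#' @param L Full fingerprint length.
#' @param q Subsample length, `1 <= q <= L` (the conventional scan grid is 5
#'   to L in steps of 5).
#' @param j Number of subclassifiers; odd values reduce exact vote ties.
#' @param seed Integer RNG seed; identical `(L, q, j, seed)` give identical
#'   draws. Draws are without replacement within a subclassifier but
#'   independent across subclassifiers (duplicates across rows allowed).
#' @return Integer matrix, `j` rows by `q` columns of 1-based feature indices.
#' @export
draw_subsamples <- function(L, q, j, seed) {
  if (q > L) abort("q cannot exceed L", class = "somkit_parameter_error")
  if (q < 1L || j < 1L) abort("q and j must be >= 1", class = "somkit_parameter_error")
  withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(j), function(i) sort(sample.int(L, q)), integer(q)))
  })
}

#' Train a subspace-voting ensemble on a site dataset
#'
#' Splits the dataset into its two classes, draws the subsample set, and
#' freezes everything needed for prediction. The model is immutable:
#' predictions for any query are deterministic given (model, query).
#'
#' @param sites A `som_sites` tibble with both classes represented.
#' @param base Base classifier: `"rascal"` (Dirac kernel), `"prw"`
#'   (Gaussian kernel) or `"nb"` (Naive Bayes).
#' @param q Subsample length, or `"full"` for a single subclassifier on all L
#'   features (no subsampling, the natural mode for PRW and NB).
#' @param j Number of subclassifiers (default 201; forced to 1 when
#'   `q = "full"`).
#' @param seed Integer seed for the subsample draw.
#' @param h Gaussian bandwidth for `base = "prw"` (default 0.1 on raw counts).
#' @param tie Exact-tie vote policy, `"nonsom"` (default, conservative) or
#'   `"som"`.
#' @return An object of class `som_ensemble`.
#' @export
train_ensemble <- function(sites, base = c("rascal", "prw", "nb"), q = 5, j = 201,
                           seed = 1, h = 0.1, tie = c("nonsom", "som")) {
  base <- match.arg(base)
  tie <- match.arg(tie)
  L <- n_features(sites)
  if (identical(q, "full")) { q <- L; j <- 1L }
  q <- as.integer(q); j <- as.integer(j)
  X <- feature_matrix(sites)
  i0 <- sites$label == "SOM"
  if (sum(i0) == 0L || sum(!i0) == 0L) {
    abort("training data must contain both SoM and nonSoM sites",
          class = "somkit_empty_class_error")
  }
  structure(list(
    X0 = X[i0, , drop = FALSE], X1 = X[!i0, , drop = FALSE],
    subsamples = draw_subsamples(L, q, j, seed),
    base = base, q = q, j = j, seed = as.integer(seed), h = h, tie = tie,
    L = L, depth = site_depth(sites), alphabet = site_alphabet(sites)
  ), class = "som_ensemble")
}

#' @export
print.som_ensemble <- function(x, ...) {
  cat(sprintf("<som_ensemble> base=%s q=%d j=%d seed=%d | N0=%d N1=%d L=%d depth=%d\n",
              x$base, x$q, x$j, x$seed, nrow(x$X0), nrow(x$X1), x$L, x$depth))
  invisible(x)
}

#' Predict SoM probabilities for new sites
#'
#' Each subclassifier restricts the query and training vectors to its feature
#' subsample and votes; the SoM probability is the omega0 vote fraction, so it
#' lives on the grid `{0, 0.5, 1, ...} / j`.
#'
#' @param object A `som_ensemble`.
#' @param newdata A `som_sites` tibble or an integer matrix with `L` columns.
#' @param ... Unused.
#' @return A tibble with columns `votes_som`, `votes_nonsom`, `prob_som` (and
#'   `mol_id`, `atom_index`, `label` when `newdata` is a site tibble).
#' @export
predict.som_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "som_sites") || is.data.frame(newdata)) {
    Tm <- feature_matrix(newdata)
    meta <- newdata[, intersect(c("mol_id", "atom_index", "label"), names(newdata))]
  } else {
    Tm <- newdata
    storage.mode(Tm) <- "integer"
    meta <- NULL
  }
  if (ncol(Tm) != object$L) {
    abort(sprintf("query has %d features but the model expects L = %d",
                  ncol(Tm), object$L), class = "somkit_dimension_error")
  }
  v0 <- ensemble_votes_cpp(object$X0, object$X1, Tm, object$subsamples,
                           object$base, object$h,
                           as.integer(object$tie == "som"))
  out <- tibble(votes_som = v0, votes_nonsom = object$j - v0,
                prob_som = v0 / object$j)
  if (!is.null(meta)) out <- dplyr::bind_cols(tibble::as_tibble(meta), out)
  out
}

#' Ensemble probability for a single site (reference path)
#'
#' Convenience wrapper running one full-length query through a trained
#' ensemble; equivalent to `predict()` on a one-row matrix.
#'
#' @param model A `som_ensemble`.
#' @param x Integer vector of length `L`.
#' @return List with `prob_som`, `votes_som`, `votes_nonsom`, `j`.
#' @export
ensemble_probability <- function(model, x) {
  p <- predict(model, matrix(as.integer(x), nrow = 1L))
  list(prob_som = p$prob_som, votes_som = p$votes_som,
       votes_nonsom = p$votes_nonsom, j = model$j)
}

#' @export
glance.som_ensemble <- function(x, ...) {
  tibble(base = x$base, q = x$q, j = x$j, seed = x$seed, h = x$h,
         n_som = nrow(x$X0), n_nonsom = nrow(x$X1), L = x$L, depth = x$depth)
}

#' @export
tidy.som_ensemble <- function(x, ...) {
  tibble(subclassifier = rep(seq_len(x$j), each = x$q),
         feature = as.integer(t(x$subsamples)))
}
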