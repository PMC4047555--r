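# The three base probabilistic classifiers.
#
# All three estimate the class-conditional density p(x | omega_alpha) of a
# (sub)vector of integer fingerprint counts and combine the two conditionals
# with equal class priors p(omega0) = p(omega1) into a posterior:
#
#   * Naive Bayes: per-feature value-match frequencies with a +1/+2
#     pseudo-count correction, multiplied under independence;
#   * Parzen-Rosenblatt window: mean Gaussian kernel density over the class's
#     training vectors, bandwidth h (default 0.1 on raw counts);
#   * RASCAL: mean Dirac (exact-match) kernel, i.e. the fraction of training
#     vectors identical to the query subvector.
#
# Products over up to ~175 features underflow double precision, so
# conditionals are represented in the log domain and exponentiated on demand.

#' Naive Bayes per-feature probability
#'
#' Frequency of a feature value in a class with a +1/+2 pseudo-count
#' correction: `(C_l + 1) / (N_alpha + 2)`, never exactly 0 or 1.
#'
#' @param C_l Number of training vectors in the class whose feature l equals
#'   the query's value.
#' @param N_alpha Class size.
#' @return Probability in (0, 1).
#' @export
nb_feature_prob <- function(C_l, N_alpha) {
  if (any(C_l > N_alpha)) abort("C_l cannot exceed N_alpha", class = "somkit_logic_error")
  if (any(C_l < 0) || any(N_alpha < 0)) abort("counts must be non-negative",
                                              class = "somkit_logic_error")
  (C_l + 1) / (N_alpha + 2)
}

#' Naive Bayes class-conditional (log domain)
#'
#' @param x_q Integer query (sub)vector.
#' @param class_vectors Matrix of training vectors (rows) for one class, same
#'   number of columns as `length(x_q)`.
#' @return Object of class `som_conditional`: list with `log_value` and
#'   `value` (exponentiated, may underflow to 0 for reporting only).
#' @export
nb_class_conditional <- function(x_q, class_vectors) {
  class_vectors <- as_class_matrix(class_vectors)
  if (ncol(class_vectors) != length(x_q)) {
    abort("query length does not match training vector length",
          class = "somkit_dimension_error")
  }
  N <- nrow(class_vectors)
  C_l <- colSums(class_vectors == rep(x_q, each = N))
  lp <- sum(log(C_l + 1) - log(N + 2))
  conditional(lp)
}

#' Dirac (exact-match) kernel
#'
#' @param a,b Equal-length integer vectors.
#' @return 1 if all components are equal, else 0.
#' @export
dirac_kernel <- function(a, b) {
  if (length(a) != length(b)) abort("vectors differ in length",
                                    class = "somkit_dimension_error")
  as.numeric(all(a == b))
}

#' Gaussian (Parzen-Rosenblatt) kernel
#'
#' `(1 / (h * sqrt(2*pi)))^q * exp(-||a - b||^2 / (2 h^2))` with q the vector
#' length. The normalisation constant cancels between the two classes in the
#' posterior but is included for fidelity to the density estimate.
#'
#' @param a,b Equal-length numeric vectors.
#' @param h Smoothing bandwidth, > 0 (default 0.1 on raw integer counts).
#' @return Strictly positive density value (may underflow for very distant
#'   vectors; see [kernel_class_conditional()] for the log-domain path).
#' @export
gaussian_kernel <- function(a, b, h = 0.1) {
  if (length(a) != length(b)) abort("vectors differ in length",
                                    class = "somkit_dimension_error")
  if (h <= 0) abort("bandwidth h must be > 0", class = "somkit_parameter_error")
  q <- length(a)
  exp(-q * log(h * sqrt(2 * pi)) - sum((a - b)^2) / (2 * h^2))
}

#' Kernel class-conditional (mean kernel over a training class)
#'
#' The average similarity of the query to all training vectors of one class,
#' Parzen-Rosenblatt style; with a Dirac kernel this is the exact-match
#' fraction (RASCAL), with a Gaussian kernel the PRW density estimate.
#'
#' @param x_q Query (sub)vector.
#' @param class_vectors Matrix of training vectors (rows) for one class.
#' @param kernel `"dirac"` or `"gaussian"`.
#' @param h Gaussian bandwidth.
#' @return A `som_conditional` (log-domain; `log_value = -Inf` when the mean is
#'   exactly 0, possible only for the Dirac kernel).
#' @export
kernel_class_conditional <- function(x_q, class_vectors, kernel = c("dirac", "gaussian"),
                                     h = 0.1) {
  kernel <- match.arg(kernel)
  class_vectors <- as_class_matrix(class_vectors)
  N <- nrow(class_vectors)
  if (N < 1L) abort("empty training class", class = "somkit_empty_class_error")
  if (ncol(class_vectors) != length(x_q)) {
    abort("query length does not match training vector length",
          class = "somkit_dimension_error")
  }
  if (kernel == "dirac") {
    matches <- sum(rowSums(class_vectors != rep(x_q, each = N)) == 0L)
    conditional(log(matches) - log(N))  # -Inf when no match
  } else {
    if (h <= 0) abort("bandwidth h must be > 0", class = "somkit_parameter_error")
    q <- length(x_q)
    d2 <- rowSums((class_vectors - rep(x_q, each = N))^2)
    expo <- -d2 / (2 * h^2)
    m <- max(expo)
    lse <- m + log(sum(exp(expo - m)))
    conditional(-q * log(h * sqrt(2 * pi)) + lse - log(N))
  }
}

conditional <- function(log_value) {
  structure(list(log_value = log_value, value = exp(log_value)),
            class = "som_conditional")
}

as_class_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, x))
  matrix(x, nrow = 1L)
}

#' Posterior class probabilities under equal priors
#'
#' Normalises the two class-conditionals into `p(omega0 | x)` and
#' `p(omega1 | x)`. When both conditionals are exactly zero (possible only for
#' the Dirac kernel: no training vector of either class matches the query
#' subvector) the posterior is undetermined and both classes are set to 0.5 —
#' in the ensemble this becomes a half-vote to each class, preserving vote
#' normalisation without biasing either class.
#'
#' @param cond_som,cond_nonsom `som_conditional` objects (or non-negative
#'   numbers) for class omega0 (SoM) and omega1 (nonSoM).
#' @return List with `p_som`, `p_nonsom`, `undetermined` (logical).
#' @export
posterior <- function(cond_som, cond_nonsom) {
  lv <- function(x) {
    if (inherits(x, "som_conditional")) return(x$log_value)
    if (!is.finite(x) || x < 0) abort("conditionals must be finite and >= 0",
                                      class = "somkit_logic_error")
    log(x)
  }
  l0 <- lv(cond_som); l1 <- lv(cond_nonsom)
  if (l0 == -Inf && l1 == -Inf) {
    return(list(p_som = 0.5, p_nonsom = 0.5, undetermined = TRUE))
  }
  m <- max(l0, l1)
  z <- exp(l0 - m) + exp(l1 - m)
  list(p_som = exp(l0 - m) / z, p_nonsom = exp(l1 - m) / z, undetermined = FALSE)
}

#' Hard classification from a posterior
#'
#' Argmax over the two classes. An exact tie between positive posteriors is
#' broken by a deterministic policy, by default `"nonsom"` (conservative for
#' SoM calls); an undetermined posterior has no argmax and contributes a
#' half-vote to each class in the ensemble instead.
#'
#' @param post A posterior from [posterior()].
#' @param tie Tie-break policy, `"nonsom"` or `"som"`.
#' @return `"SOM"`, `"NONSOM"`, or `NA_character_` for an undetermined
#'   posterior.
#' @export
classify <- function(post, tie = c("nonsom", "som")) {
  tie <- match.arg(tie)
  if (isTRUE(post$undetermined)) return(NA_character_)
  if (post$p_som > post$p_nonsom) "SOM"
  else if (post$p_som < post$p_nonsom) "NONSOM"
  else if (tie == "nonsom") "NONSOM" else "SOM"
}
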