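#' Hidden Markov model parameters
#'
#' Bundles a row-stochastic transition matrix, per-state normal emission
#' parameters for the daily GAB-distance increment `d_t`, and an initial
#' state distribution. In the constrained three-state migration model the
#' states are resident (1), outward (2) and inward (3), and direct switches
#' between the two migratory states are forbidden: the transition entries
#' (outward -> inward) and (inward -> outward) are structural zeros, so a
#' fish can change migration direction only via the resident state.
#'
#' @param transition K x K row-stochastic matrix.
#' @param means,sds Numeric vectors of length K: per-state emission mean and
#'   standard deviation of `d_t` in km/day. Inward movement has a negative
#'   mean (the observable is signed).
#' @param initial Initial state distribution; defaults to the stationary
#'   distribution of `transition`.
#' @param state_labels Character labels; defaults to
#'   `c("resident", "outward", "inward")` for K = 3 and
#'   `c("resident", "migratory")` for K = 2.
#' @param constrained If `TRUE`, require the structural zeros of the
#'   three-state migration model to be exactly zero.
#' @return An object of class `hmm_params`.
#' @examples
#' P <- constrained_transition(0.9, 0.05, 0.9, 0.9)
#' hmm_params(P, means = c(0, 39, -31), sds = c(14, 22, 23), constrained = TRUE)
#' @export
hmm_params <- function(transition, means, sds, initial = NULL,
                       state_labels = NULL, constrained = FALSE) {
  transition <- as.matrix(transition)
  K <- nrow(transition)
  stopifnot(ncol(transition) == K, length(means) == K, length(sds) == K)
  if (any(transition < 0 | transition > 1)) {
    abort("transition probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(transition) - 1) > 1e-8)) {
    abort("transition matrix rows must sum to 1")
  }
  if (constrained) {
    if (K != 3) abort("the constrained migration model has 3 states")
    if (transition[2, 3] != 0 || transition[3, 2] != 0) {
      abort("structural zeros violated: outward<->inward transitions must be exactly 0")
    }
  }
  if (any(sds <= 0)) abort("emission standard deviations must be positive")
  if (is.null(state_labels)) {
    state_labels <- switch(as.character(K),
      "3" = c("resident", "outward", "inward"),
      "2" = c("resident", "migratory"),
      paste0("state", seq_len(K)))
  }
  if (is.null(initial)) {
    initial <- stationary_distribution(transition)
  }
  if (length(initial) != K || abs(sum(initial) - 1) > 1e-8 || any(initial < 0)) {
    abort("initial distribution must be a length-K probability vector")
  }
  dimnames(transition) <- list(state_labels, state_labels)
  structure(
    list(transition = transition,
         means = setNames(as.numeric(means), state_labels),
         sds = setNames(as.numeric(sds), state_labels),
         initial = setNames(as.numeric(initial) / sum(initial), state_labels),
         state_labels = state_labels,
         constrained = constrained),
    class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(length(x$state_labels), "state hidden Markov model",
      if (x$constrained) "(constrained: outward<->inward forbidden)" else "", "\n")
  cat("Transition matrix:\n")
  print(round(x$transition, 4))
  cat("Emissions (km/day):\n")
  print(tibble::tibble(state = x$state_labels,
                       mean = unname(x$means), sd = unname(x$sds)))
  invisible(x)
}

#' Build the constrained three-state transition matrix
#'
#' Parameterised by its four free probabilities: the resident self-transition
#' `p11`, the resident-to-outward probability `p12` (resident-to-inward is the
#' remainder), and the two migratory self-transitions `p22`, `p33`. The
#' forbidden outward<->inward entries are exactly zero.
#'
#' @param p11,p12,p22,p33 Probabilities as described above.
#' @return 3 x 3 transition matrix.
#' @export
constrained_transition <- function(p11, p12, p22, p33) {
  p13 <- 1 - p11 - p12
  if (p13 < -1e-12) abort("p11 + p12 must not exceed 1")
  p13 <- max(p13, 0)
  matrix(c(p11, p12, p13,
           1 - p22, p22, 0,
           1 - p33, 0, p33),
         nrow = 3, byrow = TRUE)
}

#' Stationary distribution of a transition matrix
#'
#' Solves pi = pi P for the left eigenvector of eigenvalue one, normalised to
#' a probability vector. Errors when the chain is reducible on its
#' non-forbidden transition graph (no unique stationary law).
#'
#' @param P Row-stochastic matrix.
#' @return Numeric probability vector of length `nrow(P)`.
#' @export
stationary_distribution <- function(P) {
  P <- as.matrix(P)
  K <- nrow(P)
  if (any(abs(rowSums(P) - 1) > 1e-8)) abort("rows of P must sum to 1")
  if (!is_irreducible(P)) {
    abort("transition matrix is reducible; stationary distribution is not unique")
  }
  A <- t(diag(K) - P)
  A[K, ] <- 1
  b <- c(rep(0, K - 1), 1)
  pi <- solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi / sum(pi)
}

is_irreducible <- function(P) {
  K <- nrow(P)
  adj <- (P > 0) * 1
  reach <- diag(K)
  for (i in seq_len(K)) reach <- (reach + reach %*% adj) > 0
  all(reach > 0)
}

#' Serialise fitted model parameters to YAML
#'
#' Writes a flat YAML representation with keys `transition`,
#' `emission_means`, `emission_sds`, `initial` and `state_labels`;
#' [read_hmm_params()] restores it losslessly.
#'
#' @param params An [hmm_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hmm_params <- function(params, path) {
  stopifnot(inherits(params, "hmm_params"))
  obj <- list(
    state_labels = params$state_labels,
    transition = lapply(seq_len(nrow(params$transition)),
                        function(i) unname(params$transition[i, ])),
    emission_means = unname(params$means),
    emission_sds = unname(params$sds),
    initial = unname(params$initial),
    constrained = params$constrained
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_hmm_params
#' @export
read_hmm_params <- function(path) {
  obj <- yaml::read_yaml(path)
  P <- do.call(rbind, lapply(obj$transition, as.numeric))
  hmm_params(P, means = obj$emission_means, sds = obj$emission_sds,
             initial = obj$initial, state_labels = obj$state_labels,
             constrained = isTRUE(obj$constrained))
}
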