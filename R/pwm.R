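#' Construct a position weight matrix
#'
#' A PWM is a 4 x l column-stochastic matrix of nucleotide probabilities,
#' rows ordered A, C, G, T. `pseudocount` is the probability floor applied
#' before any logarithm is taken (see [pwm_to_weights()]); it is stored with
#' the object so downstream conversions use a consistent floor.
#'
#' @param probs 4 x l numeric matrix; columns must sum to 1 (within 1e-9).
#' @param pseudocount Probability floor in `[0, 0.25)` used when converting to
#'   log-space weights. A floor of 0 is allowed for purely probabilistic uses
#'   (e.g. sampling sites), but such a PWM cannot be log-converted while it
#'   contains zeros.
#' @return A `wsmd_pwm` object (the matrix with row names A,C,G,T).
#' @export
pwm <- function(probs, pseudocount = 1e-3) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("a PWM must have 4 rows (A, C, G, T)")
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(colSums(probs) - 1) > 1e-9)) stop("every PWM column must sum to 1")
  if (pseudocount < 0 || pseudocount >= 0.25) stop("pseudocount must be in [0, 0.25)")
  rownames(probs) <- DNA_BASES
  structure(probs, pseudocount = pseudocount, class = c("wsmd_pwm", "matrix"))
}

#' @export
print.wsmd_pwm <- function(x, ...) {
  cat("PWM, width", ncol(x), "-", format(information_content(x), digits = 4),
      "bits\n")
  print(unclass(x)[, , drop = FALSE], digits = 3)
  invisible(x)
}

motif_width <- function(x) ncol(x)

#' Convert a PWM to a linear motif model
#'
#' Concatenates the column-wise natural-log probabilities into a weight
#' vector `w` of length `4*l`, so that the inner product of `w` with a
#' one-hot encoded site equals the site's log-probability binding energy.
#' The PWM's pseudocount floor is applied (entries are floored and the column
#' renormalized) before the logarithm so that `w` is finite.
#'
#' @param P A [pwm()] object.
#' @param b Threshold/intercept of the resulting model (default 0, i.e. unset).
#' @return A `wsmd_model` object: list with `w` (length `4*l`), `b`, `l`.
#' @export
pwm_to_weights <- function(P, b = 0) {
  stopifnot(inherits(P, "wsmd_pwm"))
  pc <- attr(P, "pseudocount")
  probs <- unclass(P)
  if (pc > 0) {
    probs <- pmax(probs, pc)
    probs <- sweep(probs, 2L, colSums(probs), "/")
  } else if (any(probs == 0)) {
    stop("PWM contains zero entries and has no pseudocount; log weights would be infinite")
  }
  linear_model(as.vector(log(probs)), b = b, l = ncol(probs))
}

#' Construct a linear motif model
#'
#' The linear (latent-SVM) form of a motif: a weight vector `w` of length
#' `4*l` scoring one-hot encoded windows, plus a detection threshold `b`.
#'
#' @param w Numeric vector of length `4*l`, finite.
#' @param b Scalar threshold.
#' @param l Motif length.
#' @return A `wsmd_model` object.
#' @export
linear_model <- function(w, b = 0, l = length(w) / 4L) {
  w <- as.numeric(w)
  if (length(w) != 4L * l) stop("weight vector must have length 4*l")
  if (!all(is.finite(w)) || !is.finite(b)) stop("model weights must be finite")
  structure(list(w = w, b = as.numeric(b), l = as.integer(l)), class = "wsmd_model")
}

#' @export
print.wsmd_model <- function(x, ...) {
  cat("linear motif model, width", x$l, "- b =", format(x$b, digits = 4), "\n")
  invisible(x)
}

# internal: w as a 4 x l matrix (column j = weights of motif position j)
model_weight_matrix <- function(m) matrix(m$w, nrow = 4L, ncol = m$l)

#' Recover a PWM from a linear motif model
#'
#' Each column of the reported PWM is the unit-scale softmax of the
#' corresponding 4-block of `w`. Softmax inverts log-probabilities exactly
#' (up to the per-column additive constant, which shifts all windows equally
#' and is absorbed by the threshold), so a model built by [pwm_to_weights()]
#' round-trips to its PWM.
#'
#' @param m A `wsmd_model`.
#' @param pseudocount Pseudocount recorded on the resulting PWM.
#' @return A [pwm()] object of the model's width.
#' @export
weights_to_pwm <- function(m, pseudocount = 1e-3) {
  W <- model_weight_matrix(m)
  W <- sweep(W, 2L, apply(W, 2L, max), "-")  # shift-invariant, avoids overflow
  E <- exp(W)
  pwm(sweep(E, 2L, colSums(E), "/"), pseudocount = pseudocount)
}

#' Sequence-level binding energy
#'
#' The binding energy of a sequence is the maximal window score
#' `w' x` over all windows of the sequence and its reverse complement.
#' Ties are broken deterministically: forward strand first, then smallest
#' offset.
#'
#' @param m A `wsmd_model`.
#' @param bag A `wsmd_bag` whose window length matches `m$l`.
#' @return List with `energy` (the maximum), and `window`: a list with
#'   `index`, `offset` (0-based forward-strand start), `strand`.
#' @export
sequence_energy <- function(m, bag) {
  stopifnot(inherits(m, "wsmd_model"), inherits(bag, "wsmd_bag"))
  if (bag$l != m$l) stop("bag window length ", bag$l, " does not match model width ", m$l)
  if (nrow(bag$sites) == 0L)
    stop("sequence '", bag$id, "' has an empty window bag (all windows masked or N)")
  e <- cpp_window_energies(bag$sites, model_weight_matrix(m))
  i <- which.max(e)  # bag order is forward-first, ascending offset
  list(energy = e[i],
       window = list(index = i, offset = bag$offset[i], strand = bag$strand[i]))
}

# internal: vector of max energies over a list of bags
bag_max_energies <- function(m, bags) {
  W <- model_weight_matrix(m)
  vapply(bags, function(b) {
    if (nrow(b$sites) == 0L)
      stop("sequence '", b$id, "' has an empty window bag (all windows masked or N)")
    max(cpp_window_energies(b$sites, W))
  }, numeric(1))
}

# internal: all window energies of a list of bags, concatenated
all_window_energies <- function(m, bags) {
  W <- model_weight_matrix(m)
  unlist(lapply(bags, function(b) cpp_window_energies(b$sites, W)), use.names = FALSE)
}

#' Information content of a PWM, in bits
#'
#' `IC = sum over columns of (2 + sum_base p * log2 p)`, with `0*log(0) = 0`.
#' A uniform column contributes 0 bits, a deterministic column 2 bits.
#'
#' @param P A [pwm()] object.
#' @return Total information content in bits.
#' @export
information_content <- function(P) {
  p <- unclass(P)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + colSums(plogp))
}
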