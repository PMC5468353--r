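#' Synthetic benchmark configuration
#'
#' Defaults reproduce the refinement benchmark conditions: 2000 sequences of
#' 500 bp per set, drawn uniformly over ACGT, a width-8 signal motif
#' implanted in the foreground only and a width-8, 10-bit decoy motif
#' implanted in both sets.
#'
#' @param n_seq Sequences per set (foreground and background each).
#' @param seq_len Sequence length in bp.
#' @param signal_width,signal_ic Width and total information content (bits)
#'   of the signal PWM.
#' @param decoy_width,decoy_ic Width and total information content of the
#'   decoy PWM.
#' @param rng_seed Integer seed; the dataset is fully determined by it.
#' @return A `wsmd_synth_config` list.
#' @export
synthetic_config <- function(n_seq = 2000L, seq_len = 500L,
                             signal_width = 8L, signal_ic = 14,
                             decoy_width = 8L, decoy_ic = 10,
                             rng_seed = 1L) {
  if (signal_ic < 0 || signal_ic > 2 * signal_width)
    stop("signal_ic must lie in [0, 2*signal_width]")
  if (decoy_ic < 0 || decoy_ic > 2 * decoy_width)
    stop("decoy_ic must lie in [0, 2*decoy_width]")
  if (seq_len < signal_width + decoy_width)
    stop("seq_len too small to implant both a signal and a decoy site")
  structure(list(n_seq = as.integer(n_seq), seq_len = as.integer(seq_len),
                 signal_width = as.integer(signal_width), signal_ic = signal_ic,
                 decoy_width = as.integer(decoy_width), decoy_ic = decoy_ic,
                 rng_seed = as.integer(rng_seed)),
            class = "wsmd_synth_config")
}

# per-column IC (bits) of the single-dominant-base column family
column_ic <- function(p) {
  q <- (1 - p) / 3
  plogp <- function(v) ifelse(v > 0, v * log2(v), 0)
  2 + plogp(p) + 3 * plogp(q)
}

#' Generate a PWM with a prescribed information content
#'
#' Each column has one dominant base (chosen uniformly at random) with
#' probability `p` and `(1-p)/3` on the other three; `p` is solved by
#' bisection so that each column carries `total_ic / width` bits (within
#' 1e-9). The single-dominant-base family is one-parameter, spans the full
#' `[0, 2]` bits/column range and is strictly monotone in `p`, so the target
#' is always attainable.
#'
#' @param width Number of columns.
#' @param total_ic Total information content in bits, in `[0, 2*width]`.
#' @return A [pwm()] object whose measured [information_content()] matches
#'   `total_ic` within 1e-6 bits.
#' @export
generate_pwm_with_ic <- function(width, total_ic) {
  if (total_ic < 0 || total_ic > 2 * width)
    stop("total_ic must lie in [0, 2*width]")
  target <- total_ic / width
  lo <- 0.25; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (column_ic(mid) < target) lo <- mid else hi <- mid
  }
  p <- (lo + hi) / 2
  dominant <- sample.int(4L, width, replace = TRUE)
  P <- matrix((1 - p) / 3, nrow = 4L, ncol = width)
  P[cbind(dominant, seq_len(width))] <- p
  pwm(P, pseudocount = 0)
}

#' Sample a uniform background sequence
#'
#' i.i.d. uniform over `{A, C, G, T}`.
#'
#' @param len Sequence length (>= 1).
#' @return A DNA string of length `len`.
#' @export
sample_background_sequence <- function(len) {
  if (len < 1L) stop("len must be >= 1")
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

#' Implant a motif instance into a sequence
#'
#' Samples a site column-wise from the PWM and overwrites it at a uniformly
#' random forward-strand position that does not overlap any previously
#' implanted interval; the sequence length is preserved.
#'
#' @param seq DNA string.
#' @param P A [pwm()] object.
#' @param avoid Optional two-column matrix of 0-based half-open intervals to
#'   keep clear.
#' @return List with `seq` (modified string) and `interval`
#'   (`c(start, end)`, 0-based half-open).
#' @export
implant <- function(seq, P, avoid = NULL) {
  w <- ncol(P)
  n <- nchar(seq)
  if (n < w) stop("sequence is shorter than the motif width")
  starts <- 0:(n - w)
  if (!is.null(avoid) && nrow(avoid) > 0L) {
    ok <- rep(TRUE, length(starts))
    for (r in seq_len(nrow(avoid)))
      ok <- ok & (starts + w <= avoid[r, 1L] | starts >= avoid[r, 2L])
    starts <- starts[ok]
  }
  if (length(starts) == 0L)
    stop("no non-overlapping implant position available")
  s <- starts[sample.int(length(starts), 1L)]
  site <- vapply(seq_len(w), function(j)
    sample(DNA_BASES, 1L, prob = P[, j]), character(1))
  chars <- strsplit(seq, "")[[1L]]
  chars[(s + 1L):(s + w)] <- site
  list(seq = paste(chars, collapse = ""), interval = c(s, s + w))
}

#' Generate a synthetic signal/decoy benchmark dataset
#'
#' Foreground and background sets each contain `n_seq` uniform-background
#' sequences of `seq_len` bp. One decoy instance is implanted in every
#' sequence of both sets; one signal instance is additionally implanted in
#' every foreground sequence, non-overlapping with the decoy. Ground-truth
#' intervals of both kinds are recorded. Fully determined by
#' `cfg$rng_seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A `wsmd_synthetic` list: `F`, `B` (sequence tables), `truth`
#'   (`data.frame` with `id`, `start`, `end`, `strand`, `kind`, `set`),
#'   `signal_pwm`, `decoy_pwm`, `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  with_local_seed(cfg$rng_seed, {
    signal_pwm <- generate_pwm_with_ic(cfg$signal_width, cfg$signal_ic)
    decoy_pwm <- generate_pwm_with_ic(cfg$decoy_width, cfg$decoy_ic)
    truth <- list()
    gen_set <- function(set_name, with_signal) {
      ids <- sprintf("%s_%04d", set_name, seq_len(cfg$n_seq))
      seqs <- character(cfg$n_seq)
      for (i in seq_len(cfg$n_seq)) {
        s <- sample_background_sequence(cfg$seq_len)
        iv <- NULL
        if (with_signal) {
          im <- implant(s, signal_pwm)
          s <- im$seq
          iv <- matrix(im$interval, 1L)
          truth[[length(truth) + 1L]] <<- data.frame(
            id = ids[i], start = im$interval[1L], end = im$interval[2L],
            strand = "+", kind = "signal", set = set_name,
            stringsAsFactors = FALSE)
        }
        im <- implant(s, decoy_pwm, avoid = iv)
        seqs[i] <- im$seq
        truth[[length(truth) + 1L]] <<- data.frame(
          id = ids[i], start = im$interval[1L], end = im$interval[2L],
          strand = "+", kind = "decoy", set = set_name,
          stringsAsFactors = FALSE)
      }
      labeled_sequences(ids, seqs, if (with_signal) 1L else -1L)
    }
    Fg <- gen_set("fg", TRUE)
    Bg <- gen_set("bg", FALSE)
    structure(list(F = Fg, B = Bg, truth = do.call(rbind, truth),
                   signal_pwm = signal_pwm, decoy_pwm = decoy_pwm,
                   config = cfg),
              class = "wsmd_synthetic")
  })
}

#' Benchmark parameter grids
#'
#' The two simulation grids of the refinement and extension benchmarks: the
#' refinement grid varies the signal IC of a width-8 signal against a
#' width-8, 10-bit decoy (8 IC values x 10 replicate datasets = 80
#' experiments); the extension grid varies the signal IC of a width-18
#' signal against a width-18, 20-bit decoy (11 IC values x 10 replicates =
#' 110 experiments).
#'
#' @param stage `"refinement"` or `"extension"`.
#' @param n_replicates Replicate datasets per parameter setting (default 10).
#' @return A `data.frame` with one row per experiment: `signal_width`,
#'   `signal_ic`, `decoy_width`, `decoy_ic`, `replicate`.
#' @export
benchmark_grid <- function(stage = c("refinement", "extension"),
                           n_replicates = 10L) {
  stage <- match.arg(stage)
  if (stage == "refinement") {
    g <- expand.grid(replicate = seq_len(n_replicates),
                     signal_ic = seq(2, 16, by = 2))
    g$signal_width <- 8L; g$decoy_width <- 8L; g$decoy_ic <- 10
  } else {
    g <- expand.grid(replicate = seq_len(n_replicates),
                     signal_ic = seq(6, 26, by = 2))
    g$signal_width <- 18L; g$decoy_width <- 18L; g$decoy_ic <- 20
  }
  g[, c("signal_width", "signal_ic", "decoy_width", "decoy_ic", "replicate")]
}
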