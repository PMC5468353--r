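# internal: forward and reverse-complement code vectors of a sequence
codes_pair <- function(seq, id = "<sequence>") {
  f <- seq_to_codes(seq, id)
  list(fwd = f, rc = rev(5L - f))
}

#' Substring minimal distance (SMD)
#'
#' The minimal Hamming distance between a k-mer word and all k-length
#' substrings of a sequence and of its reverse complement. Substrings
#' containing `N` are skipped.
#'
#' @param word DNA string of length k (no `N`).
#' @param seq DNA string of length >= k.
#' @return Integer distance in `[0, k]`.
#' @export
smd <- function(word, seq) {
  wc <- seq_to_codes(word, "<word>")
  if (anyNA(wc)) stop("seed word may not contain N")
  cp <- codes_pair(seq)
  if (length(cp$fwd) < length(wc))
    stop("sequence is shorter than the word length ", length(wc))
  d <- cpp_smd_word(wc, cp$fwd, cp$rc)
  if (is.na(d)) stop("sequence has no N-free window of length ", length(wc))
  as.integer(d)
}

# internal: (k+1) x 4^k histogram of SMD values over a set of sequences.
# Row d+1 counts sequences at distance d; column index = lexicographic word.
smd_histograms <- function(seqs, k) {
  M <- 4L^k
  h <- matrix(0, nrow = k + 1L, ncol = M)
  for (i in seq_len(nrow(seqs))) {
    cp <- codes_pair(seqs$seq[i], seqs$id[i])
    if (length(cp$fwd) < k)
      stop("sequence '", seqs$id[i], "' is shorter than the seed length ", k)
    d <- cpp_smd_all_words(cp$fwd, cp$rc, k)
    if (anyNA(d))
      stop("sequence '", seqs$id[i], "' has no N-free window of length ", k)
    h[cbind(d + 1L, seq_len(M))] <- h[cbind(d + 1L, seq_len(M))] + 1
  }
  h
}

# internal: P(SMD in F < SMD in B) + 0.5 P(equal), per word, from histograms
score_from_histograms <- function(hF, hB) {
  k1 <- nrow(hF)
  nF <- sum(hF[, 1L]); nB <- sum(hB[, 1L])
  # tailB[a, ] = number of background sequences with SMD > a-1
  tailB <- apply(hB[k1:1L, , drop = FALSE], 2L, cumsum)[k1:1L, , drop = FALSE]
  tailB <- rbind(tailB[-1L, , drop = FALSE], 0)  # strictly greater
  colSums(hF * (tailB + 0.5 * hB)) / (nF * nB)
}

#' Discrimination score of a seed word
#'
#' The probability, over all foreground/background sequence pairs, that the
#' word has a strictly smaller SMD in the foreground sequence than in the
#' background sequence; ties count 1/2. The score is computed exactly over
#' all `|F| * |B|` pairs (it factorizes over the per-set SMD histograms), is
#' symmetric (`score(F,B) + score(B,F) = 1`) and equals 0.5 for
#' uninformative words.
#'
#' @param word DNA k-mer.
#' @param F,B Foreground / background sequence tables ([labeled_sequences()]).
#' @return Score in `[0, 1]`.
#' @export
discrimination_score <- function(word, F, B) {
  if (nrow(F) == 0L || nrow(B) == 0L) stop("foreground and background must be non-empty")
  wc <- seq_to_codes(word, "<word>")
  if (anyNA(wc)) stop("seed word may not contain N")
  k <- length(wc)
  dist_one <- function(seqs) vapply(seq_len(nrow(seqs)), function(i) {
    cp <- codes_pair(seqs$seq[i], seqs$id[i])
    if (length(cp$fwd) < k)
      stop("sequence '", seqs$id[i], "' is shorter than the word length ", k)
    d <- cpp_smd_word(wc, cp$fwd, cp$rc)
    if (is.na(d)) stop("sequence '", seqs$id[i], "' has no N-free window of length ", k)
    as.integer(d)
  }, integer(1))
  dF <- dist_one(F); dB <- dist_one(B)
  hF <- matrix(tabulate(dF + 1L, k + 1L), ncol = 1L)
  hB <- matrix(tabulate(dB + 1L, k + 1L), ncol = 1L)
  as.numeric(score_from_histograms(hF, hB))
}

# internal: word index (0-based, lexicographic) -> reverse complement index
revcomp_index <- function(idx, k) {
  out <- integer(length(idx))
  rem <- idx
  for (j in seq_len(k)) {           # j-th position from the left, weight 4^(k-j)
    d <- rem %/% 4L^(k - j)
    rem <- rem %% 4L^(k - j)
    out <- out + (3L - d) * 4L^(j - 1L)
  }
  out
}

index_to_word <- function(idx, k) {
  m <- vapply(seq_len(k), function(j) (idx %/% 4L^(k - j)) %% 4L, numeric(length(idx)))
  m <- matrix(m, ncol = k)
  apply(m, 1L, function(d) paste(DNA_BASES[d + 1L], collapse = ""))
}

#' Select top discriminative seed words
#'
#' Enumerates all `4^k` exact k-mers, scores each by its exact discrimination
#' score, collapses each word with its reverse complement to the
#' lexicographically smaller canonical representative (double-strand scanning
#' makes the pair equivalent), and returns the highest-scoring seeds, ties
#' broken lexicographically.
#'
#' @param F,B Foreground / background sequence tables.
#' @param k Seed length (default 6); must satisfy `3 <= k <= 10`.
#' @param n_seeds Number of seeds to return (default 5).
#' @return A `data.frame` with columns `word` and `score`, best first.
#' @export
select_seeds <- function(F, B, k = 6L, n_seeds = 5L) {
  if (k < 3L || k > 10L)
    stop("seed length k must be in [3, 10]; exact enumeration of 4^k words is ",
         "infeasible beyond that")
  if (nrow(F) == 0L || nrow(B) == 0L) stop("foreground and background must be non-empty")
  hF <- smd_histograms(F, k)
  hB <- smd_histograms(B, k)
  score <- score_from_histograms(hF, hB)
  idx <- 0:(4L^k - 1L)
  rc <- revcomp_index(idx, k)
  canonical <- idx <= rc
  idx <- idx[canonical]; score <- score[canonical]
  ord <- order(-score, idx)
  top <- head(ord, n_seeds)
  data.frame(word = index_to_word(idx[top], k), score = score[top],
             stringsAsFactors = FALSE)
}

#' Initial linear model from a seed word
#'
#' Builds a PWM with probability `match_prob` on the seed base of each column
#' and `(1 - match_prob)/3` on the other bases, then converts it to log-space
#' weights. The threshold is left at 0 (it does not affect the first latent
#' update).
#'
#' @param word DNA seed word.
#' @param match_prob Probability mass on the seed base, in `(0.25, 1)`.
#' @param pseudocount Probability floor recorded on the PWM.
#' @return A `wsmd_model` of width `nchar(word)`.
#' @export
seed_to_initial_model <- function(word, match_prob = 0.85, pseudocount = 1e-3) {
  if (match_prob <= 0.25 || match_prob >= 1)
    stop("match_prob must be in (0.25, 1)")
  codes <- seq_to_codes(word, "<word>")
  if (anyNA(codes)) stop("seed word may not contain N")
  P <- matrix((1 - match_prob) / 3, nrow = 4L, ncol = length(codes))
  P[cbind(codes, seq_along(codes))] <- match_prob
  pwm_to_weights(pwm(P, pseudocount = pseudocount))
}
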