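# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_seq_table <- function(n_seq, len, label = NA_integer_, prefix = "s") {
  labeled_sequences(paste0(prefix, seq_len(n_seq)),
                    vapply(seq_len(n_seq), function(i) random_dna(len),
                           character(1)),
                    label)
}

# a sequence set with `word` planted at a random position in a fraction of
# the sequences
planted_seq_table <- function(n_seq, len, word, fraction = 1, prefix = "s",
                              label = NA_integer_) {
  k <- nchar(word)
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- random_dna(len)
    if (i <= round(fraction * n_seq)) {
      p <- sample.int(len - k + 1L, 1L)
      substr(s, p, p + k - 1L) <- word
    }
    s
  }, character(1))
  labeled_sequences(paste0(prefix, seq_len(n_seq)), seqs, label)
}

random_pwm <- function(l) {
  P <- matrix(stats::runif(4 * l, 0.05, 1), 4, l)
  pwm(sweep(P, 2, colSums(P), "/"))
}

# brute-force oracle: best window energy by direct enumeration of substrings
# of the sequence and its reverse complement, scored by the log-sum (not the
# inner-product path used by the implementation)
oracle_best_energy <- function(P, seq) {
  l <- ncol(P)
  scan <- function(s) {
    n <- nchar(s)
    vapply(1:(n - l + 1), function(p) {
      site <- strsplit(substr(s, p, p + l - 1), "")[[1]]
      sum(log(P[cbind(match(site, c("A", "C", "G", "T")), 1:l)]))
    }, numeric(1))
  }
  max(c(scan(seq), scan(reverse_complement(seq))))
}

# brute-force oracle for SMD: direct min over all offsets of both strands
oracle_smd <- function(word, seq) {
  k <- nchar(word)
  wchars <- strsplit(word, "")[[1]]
  dists <- function(s) {
    n <- nchar(s)
    vapply(1:(n - k + 1), function(p)
      sum(strsplit(substr(s, p, p + k - 1), "")[[1]] != wchars), integer(1))
  }
  min(c(dists(seq), dists(reverse_complement(seq))))
}

# brute-force AUC: mean over all fg x bg pairs of win/half/lose
oracle_auc <- function(fg, bg) {
  tot <- 0
  for (a in fg) for (b in bg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(fg) * length(bg))
}

# exact hypergeometric upper tail P(X >= q) by direct summation of choose()
# terms (log-space), for small N
oracle_hyper_tail <- function(q, K, N, n) {
  lo <- max(q, 0, n - (N - K)); hi <- min(K, n)
  if (lo > hi) return(0)
  terms <- vapply(lo:hi, function(x)
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)), numeric(1))
  sum(terms)
}

oracle_fisher_log10 <- function(tp, fn, fp, tn) {
  log10(oracle_hyper_tail(tp, tp + fn, tp + fn + fp + tn, tp + fp))
}

oracle_mhg_log10 <- function(fg, bg) {
  nf <- length(fg); nb <- length(bg); N <- nf + nb
  is_fg <- c(rep(TRUE, nf), rep(FALSE, nb))
  s <- c(fg, bg)
  ord <- order(-s, is_fg)
  k <- cumsum(is_fg[ord])
  p <- vapply(1:(N - 1), function(n) oracle_hyper_tail(k[n], nf, N, n),
              numeric(1))
  log10(min(p))
}

# 200+200 sequence planted-motif training set used by several refinement tests
small_planted_set <- function(n = 40, len = 60, word = "ACGTTGCA", seed = 42) {
  set.seed(seed)
  F <- planted_seq_table(n, len, word, fraction = 1, prefix = "f", label = 1L)
  B <- random_seq_table(n, len, label = -1L, prefix = "b")
  list(F = F, B = B, word = word)
}
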