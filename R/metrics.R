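#' Site-level detection threshold
#'
#' The `1 - q` quantile (linear interpolation) of the site-level binding
#' energies of every window of every background sequence; with the default
#' `q = 0.001` this is the top 0.1% background site threshold used for the
#' contingency table, for Fisher's score and for masking.
#'
#' @param m A `wsmd_model`.
#' @param bg_bags Background window bags.
#' @param q Upper tail mass, in `(0, 1)`.
#' @return The threshold energy.
#' @export
detection_threshold <- function(m, bg_bags, q = 0.001) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  e <- all_window_energies(m, bg_bags)
  if (length(e) == 0L) stop("background bags contain no windows")
  unname(stats::quantile(e, probs = 1 - q, type = 7))
}

#' Sequence-level contingency table
#'
#' Classifies every sequence by whether its maximal binding energy exceeds
#' the threshold: `FN` counts foreground sequences with `E - b < 0`, `FP`
#' background sequences with `E - b > 0`; `TP` and `TN` are the complements
#' within each class (a background sequence exactly at the threshold is not
#' detected).
#'
#' @param m A `wsmd_model`.
#' @param fg_bags,bg_bags Window bags of the two classes.
#' @param b Detection threshold (see [detection_threshold()]).
#' @return A `wsmd_contingency` list with `tp`, `fn`, `fp`, `tn`.
#' @export
contingency <- function(m, fg_bags, bg_bags, b) {
  stopifnot(is.finite(b))
  ef <- bag_max_energies(m, fg_bags)
  eb <- bag_max_energies(m, bg_bags)
  fn <- sum(ef - b < 0)
  fp <- sum(eb - b > 0)
  contingency_table(tp = length(ef) - fn, fn = fn, fp = fp,
                    tn = length(eb) - fp)
}

#' @rdname contingency
#' @param tp,fn,fp,tn Non-negative sequence counts.
#' @export
contingency_table <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "wsmd_contingency")
}

#' Classification accuracy from a contingency table
#'
#' @param t A [contingency_table()].
#' @return `(tp + tn) / (tp + fn + fp + tn)`.
#' @export
classification_accuracy <- function(t) {
  n <- t$tp + t$fn + t$fp + t$tn
  if (n == 0) stop("empty contingency table")
  (t$tp + t$tn) / n
}

#' Area under the ROC curve
#'
#' Probability that a random foreground score exceeds a random background
#' score, ties counting 1/2 (the rank-sum formulation). Scores are typically
#' sequence-level binding energies.
#'
#' @param fg_scores,bg_scores Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(fg_scores, bg_scores) {
  nf <- length(fg_scores); nb <- length(bg_scores)
  if (nf == 0L || nb == 0L) stop("both score sets must be non-empty")
  r <- rank(c(fg_scores, bg_scores))
  (sum(r[seq_len(nf)]) - nf * (nf + 1) / 2) / (nf * nb)
}

#' Fisher's exact test score
#'
#' log10 of the one-sided (foreground-enrichment) Fisher exact p-value of
#' the sequence-level present/absent contingency table: the hypergeometric
#' tail probability of observing at least `tp` foreground sequences among
#' the `tp + fp` motif-containing ones. Computed in log space.
#'
#' @param t A [contingency_table()].
#' @return `log10(p)`, non-positive.
#' @export
fisher_score <- function(t) {
  stats::phyper(t$tp - 1, t$tp + t$fn, t$fp + t$tn, t$tp + t$fp,
                lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Minimal hypergeometric (MHG) enrichment score
#'
#' Ranks all sequences by score, best first (ties: background first, the
#' conservative order); for every prefix length `n` computes the
#' hypergeometric tail probability of seeing at least the observed number of
#' foreground sequences in the prefix, and returns log10 of the minimum over
#' `n = 1 .. N-1`. No multiple-testing correction is applied. As a rank
#' statistic it is invariant to strictly monotone transforms of the scores.
#'
#' @param fg_scores,bg_scores Numeric score vectors.
#' @return `log10(min_n p_n)`, non-positive.
#' @export
mhg_score <- function(fg_scores, bg_scores) {
  nf <- length(fg_scores); nb <- length(bg_scores)
  if (nf == 0L || nb == 0L) stop("both score sets must be non-empty")
  is_fg <- c(rep(TRUE, nf), rep(FALSE, nb))
  s <- c(fg_scores, bg_scores)
  ord <- order(-s, is_fg)             # ties: background first
  k <- cumsum(is_fg[ord])
  n <- seq_len(nf + nb)
  logp <- stats::phyper(k - 1, nf, nb, n, lower.tail = FALSE, log.p = TRUE)
  min(logp[-(nf + nb)]) / log(10)
}

#' Nucleotide-level correlation coefficient (nCC)
#'
#' Matthews-style correlation over all nucleotide positions of the
#' foreground sequences: a position is predicted-positive if covered by any
#' predicted site and truly positive if covered by any true site (strand
#' ignored). Returns 0 when any marginal is zero.
#'
#' @param predicted,truth `data.frame`s of site intervals with columns `id`,
#'   `start`, `end` (0-based half-open, forward-strand coordinates).
#' @param seqs Foreground sequence table (ids and lengths define the
#'   universe of scored positions).
#' @return nCC in `[-1, 1]`.
#' @export
ncc <- function(predicted, truth, seqs) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(seqs))) {
    n <- nchar(seqs$seq[i])
    pred <- cover_mask(predicted, seqs$id[i], n)
    tru <- cover_mask(truth, seqs$id[i], n)
    tp <- tp + sum(pred & tru);  fp <- fp + sum(pred & !tru)
    fn <- fn + sum(!pred & tru); tn <- tn + sum(!pred & !tru)
  }
  den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fn * fp) / den
}

cover_mask <- function(sites, id, n) {
  mask <- logical(n)
  if (is.null(sites) || nrow(sites) == 0L) return(mask)
  rows <- which(sites$id == id)
  for (r in rows) {
    a <- max(0L, sites$start[r]); b <- min(n, sites$end[r])
    if (b > a) mask[(a + 1L):b] <- TRUE
  }
  mask
}

#' Average site-level performance (sASP)
#'
#' A predicted site is correct when it overlaps a true site by at least a
#' quarter of the site length (`ceiling(l/4)` nucleotides, strand ignored).
#' sASP is the mean of site-level sensitivity (fraction of true sites
#' recovered) and site-level precision (fraction of predictions that are
#' correct); it is 0 when there are no predictions.
#'
#' @param predicted,truth Site interval `data.frame`s (`id`, `start`, `end`).
#' @return sASP in `[0, 1]`.
#' @export
sasp <- function(predicted, truth) {
  if (is.null(truth) || nrow(truth) == 0L) stop("truth annotation is empty")
  if (is.null(predicted) || nrow(predicted) == 0L) return(0)
  hit <- function(a, b) {  # does site a overlap site b enough?
    ov <- min(a$end, b$end) - max(a$start, b$start)
    ov >= ceiling((b$end - b$start) / 4)
  }
  true_hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(vapply(which(predicted$id == truth$id[i]), function(j)
      hit(predicted[j, ], truth[i, ]), logical(1)))
  }, logical(1))
  pred_hit <- vapply(seq_len(nrow(predicted)), function(j) {
    any(vapply(which(truth$id == predicted$id[j]), function(i)
      hit(predicted[j, ], truth[i, ]), logical(1)))
  }, logical(1))
  (mean(true_hit) + mean(pred_hit)) / 2
}

#' Evaluate motifs on labeled sequence sets
#'
#' Computes the reference-free metrics (AUC, Fisher's score at the top
#' 0.1%-quantile background site threshold, MHG score) for each motif, and
#' the ground-truth metrics (nCC, sASP) when a site annotation is supplied.
#'
#' @param motifs A list of `wsmd_motif` results (see [discover()]) or
#'   `wsmd_model`s.
#' @param F,B Foreground / background sequence tables.
#' @param truth Optional site annotation `data.frame` (`id`, `start`, `end`).
#' @param q Background quantile for the detection threshold.
#' @return A `data.frame` with one row per motif.
#' @export
evaluate_motifs <- function(motifs, F, B, truth = NULL, q = 0.001) {
  if (inherits(motifs, "wsmd_motif") || inherits(motifs, "wsmd_model"))
    motifs <- list(motifs)
  rows <- lapply(seq_along(motifs), function(i) {
    mo <- motifs[[i]]
    m <- if (inherits(mo, "wsmd_motif")) mo$model else mo
    fg_bags <- make_window_bags(F, m$l)
    bg_bags <- make_window_bags(B, m$l)
    ef <- bag_max_energies(m, fg_bags)
    eb <- bag_max_energies(m, bg_bags)
    thr <- detection_threshold(m, bg_bags, q)
    tab <- contingency(m, fg_bags, bg_bags, thr)
    out <- data.frame(motif = i,
                      auc = auc_score(ef, eb),
                      fisher = fisher_score(tab),
                      mhg = mhg_score(ef, eb),
                      accuracy = classification_accuracy(tab))
    if (!is.null(truth)) {
      calls <- call_sites(m, fg_bags, thr)
      out$ncc <- ncc(calls, truth, F)
      out$sasp <- sasp(calls, truth)
    }
    out
  })
  do.call(rbind, rows)
}

# internal: best-window site calls on foreground bags above a threshold
call_sites <- function(m, fg_bags, threshold) {
  rows <- lapply(fg_bags, function(b) {
    se <- sequence_energy(m, b)
    if (se$energy > threshold)
      data.frame(id = b$id, start = se$window$offset,
                 end = se$window$offset + b$l, strand = se$window$strand,
                 energy = se$energy, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(id = character(), start = integer(), end = integer(),
                      strand = character(), energy = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Stratified cross-validation of motif discovery
#'
#' Splits each class into `n_folds` folds of near-equal size (sizes differ
#' by at most one), runs [discover()] on the training folds and evaluates
#' AUC, Fisher's score and MHG score of the best discovered motif on both
#' the training and the held-out fold. Deterministic given
#' `cfg$refinement$rng_seed`.
#'
#' @param F,B Foreground / background sequence tables.
#' @param cfg A [discovery_config()].
#' @param n_folds Number of folds (default 3).
#' @return List with `folds` (per-fold metric `data.frame`) and `mean`
#'   (column means of the metrics).
#' @export
cross_validate <- function(F, B, cfg = discovery_config(), n_folds = 3L) {
  ff <- stratified_folds(nrow(F), n_folds, cfg$refinement$rng_seed)
  fb <- stratified_folds(nrow(B), n_folds, cfg$refinement$rng_seed + 1L)
  rows <- lapply(seq_len(n_folds), function(f) {
    res <- discover(F[ff != f, , drop = FALSE], B[fb != f, , drop = FALSE], cfg)
    train <- evaluate_motifs(res[1L], F[ff != f, , drop = FALSE],
                             B[fb != f, , drop = FALSE])
    test <- evaluate_motifs(res[1L], F[ff == f, , drop = FALSE],
                            B[fb == f, , drop = FALSE])
    data.frame(fold = f,
               train_auc = train$auc, train_fisher = train$fisher,
               train_mhg = train$mhg,
               test_auc = test$auc, test_fisher = test$fisher,
               test_mhg = test$mhg)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds, mean = colMeans(folds[, -1L]))
}
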