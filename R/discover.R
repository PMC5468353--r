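#' Discovery configuration
#'
#' @param motif_length Target motif width `l`.
#' @param seed_length Seed width `k` (`k <= l`); default 6.
#' @param n_seeds Number of seeds carried into refinement; default 5.
#' @param n_motifs Number of motifs to report (masking between rounds).
#' @param refinement A [refinement_config()].
#' @param extension_mode `"unified"` (all `l - k + 1` placements re-refined,
#'   the default) or `"greedy"` (column-by-column growth, the comparison
#'   baseline).
#' @param extend_all_seeds If `TRUE` every refined seed is extended and the
#'   best final objective wins; by default only the best refined seed is
#'   extended, which bounds the runtime.
#' @param threshold_quantile Background site quantile `q` for the detection
#'   threshold used in site calling and masking.
#' @return A `wsmd_config` list.
#' @export
discovery_config <- function(motif_length = 8L, seed_length = 6L, n_seeds = 5L,
                             n_motifs = 1L, refinement = refinement_config(),
                             extension_mode = c("unified", "greedy"),
                             extend_all_seeds = FALSE,
                             threshold_quantile = 0.001) {
  extension_mode <- match.arg(extension_mode)
  if (seed_length > motif_length) stop("seed_length must not exceed motif_length")
  if (n_motifs < 1L) stop("n_motifs must be >= 1")
  structure(list(motif_length = as.integer(motif_length),
                 seed_length = as.integer(seed_length),
                 n_seeds = as.integer(n_seeds), n_motifs = as.integer(n_motifs),
                 refinement = refinement, extension_mode = extension_mode,
                 extend_all_seeds = extend_all_seeds,
                 threshold_quantile = threshold_quantile),
            class = "wsmd_config")
}

#' Unified motif extension
#'
#' Extends a refined motif of width `k` to width `l` by evaluating every
#' placement: for each `x` in `0 .. l-k`, an initial width-`l` model is
#' built with `x` uniform columns upstream and `l-k-x` downstream of the
#' refined motif and re-refined; the candidate with the minimal objective
#' wins, ties going to the smallest `x`. In weight space a uniform (0.25
#' each) column is the zero 4-block (its additive constant is immaterial to
#' window ranking and zero keeps the L2 norm unchanged), so the padded
#' model scores windows exactly as the refined core does; in particular at
#' `k == l` the single candidate starts from the refined model itself and
#' the returned objective can never exceed it.
#'
#' @param refined A `wsmd_trained` of width `k`.
#' @param fg_bags,bg_bags Window bags re-windowed at the target width.
#' @param cfg A [refinement_config()].
#' @return A `wsmd_trained` of the target width with fields
#'   `extension_offset` (the winning `x`) and `candidates` (per-`x`
#'   objectives).
#' @export
extend_motif <- function(refined, fg_bags, bg_bags, cfg = refinement_config()) {
  k <- refined$model$l
  l <- fg_bags[[1L]]$l
  if (k > l) stop("refined width exceeds target width")
  cands <- lapply(0:(l - k), function(x) {
    w0 <- c(rep(0, 4 * x), refined$model$w, rep(0, 4 * (l - k - x)))
    init <- linear_model(w0, b = refined$model$b, l = l)
    tr <- suppressWarnings(refine(init, fg_bags, bg_bags, cfg))
    tr$extension_offset <- x
    tr
  })
  objs <- vapply(cands, `[[`, numeric(1), "objective")
  best <- cands[[which.min(objs)]]   # which.min takes the smallest x on ties
  best$candidates <- data.frame(x = 0:(l - k), objective = objs)
  best
}

#' Greedy motif extension (baseline)
#'
#' Grows the refined motif one uniform column at a time: at each step both
#' the left- and the right-extended candidate are re-refined and the lower
#' objective is kept, until the target width is reached. Provided as the
#' greedy comparison baseline for [extend_motif()].
#'
#' @param refined A `wsmd_trained` of width `k`.
#' @param F,B Sequence tables (bags are rebuilt at every intermediate width).
#' @param target_length Final motif width `l`.
#' @param cfg A [refinement_config()].
#' @param exclude Optional per-sequence masked-interval lists for `F`.
#' @return A `wsmd_trained` of width `l` (identity when `k == l`).
#' @export
extend_motif_greedy <- function(refined, F, B, target_length,
                                cfg = refinement_config(), exclude = NULL) {
  current <- refined
  while (current$model$l < target_length) {
    w <- current$model$l + 1L
    fg_bags <- make_window_bags(F, w, exclude = exclude)
    bg_bags <- make_window_bags(B, w)
    wl <- linear_model(c(rep(0, 4), current$model$w), b = current$model$b, l = w)
    wr <- linear_model(c(current$model$w, rep(0, 4)), b = current$model$b, l = w)
    left <- suppressWarnings(refine(wl, fg_bags, bg_bags, cfg))
    right <- suppressWarnings(refine(wr, fg_bags, bg_bags, cfg))
    current <- if (left$objective <= right$objective) left else right
  }
  current
}

#' Mask the binding sites of a reported motif
#'
#' For every foreground sequence whose best binding energy exceeds the
#' motif's detection threshold, removes the best window and every window
#' overlapping it by at least one nucleotide (either strand) from the
#' sequence's bag; background bags are untouched. Subsequent discovery
#' rounds therefore cannot rediscover the same support.
#'
#' @param fg_bags Foreground window bags.
#' @param motif A `wsmd_motif` (see [discover()]) whose `sites` were called
#'   on these sequences, or a list with `model` and `threshold`.
#' @return List of modified copies of the bags.
#' @export
mask_sites <- function(fg_bags, motif) {
  thr <- motif$threshold
  m <- motif$model
  lapply(fg_bags, function(b) {
    se <- sequence_energy(m, b)
    if (se$energy <= thr) return(b)
    p <- se$window$offset
    keep <- (b$offset + b$l <= p) | (b$offset >= p + m$l)
    b$offset <- b$offset[keep]
    b$strand <- b$strand[keep]
    b$sites <- b$sites[keep, , drop = FALSE]
    b
  })
}

#' Discover discriminative motifs
#'
#' The full pipeline: seed words are selected by discrimination score at
#' width `k`, refined by the latent-SVM alternation, extended to the target
#' width `l` (unified or greedy), reported with site calls, and their
#' binding regions masked before the next round, until `n_motifs` motifs
#' are found. Fully deterministic given the configuration and input order.
#'
#' @param F,B Foreground / background sequence tables ([read_fasta()]).
#' @param cfg A [discovery_config()].
#' @return A list of `wsmd_motif` objects ordered by objective, each with
#'   `pwm`, `model`, `objective`, `threshold`, `sites` (0-based half-open
#'   forward-strand calls), `seed` (word and score), `extension_offset`,
#'   `trace`.
#' @export
discover <- function(F, B, cfg = discovery_config()) {
  if (nrow(F) < 2L || nrow(B) < 2L)
    stop("need at least 2 foreground and 2 background sequences")
  k <- cfg$seed_length; l <- cfg$motif_length
  rcfg <- cfg$refinement
  masks <- replicate(nrow(F), NULL, simplify = FALSE)
  bg_bags_l <- make_window_bags(B, l)
  results <- list()
  Fmasked <- F
  for (round in seq_len(cfg$n_motifs)) {
    seeds <- select_seeds(Fmasked, B, k = k, n_seeds = cfg$n_seeds)
    fg_bags_k <- make_window_bags(F, k, exclude = masks)
    bg_bags_k <- if (k == l) bg_bags_l else make_window_bags(B, k)
    refined <- lapply(seeds$word, function(wd) {
      suppressWarnings(refine(seed_to_initial_model(wd), fg_bags_k, bg_bags_k, rcfg))
    })
    objs <- vapply(refined, `[[`, numeric(1), "objective")
    chosen <- if (cfg$extend_all_seeds) seq_along(refined) else which.min(objs)
    final <- NULL
    for (ci in chosen) {
      tr <- refined[[ci]]
      if (l > k) {
        tr <- if (cfg$extension_mode == "unified") {
          fg_bags_l <- make_window_bags(F, l, exclude = masks)
          extend_motif(tr, fg_bags_l, bg_bags_l, rcfg)
        } else {
          extend_motif_greedy(tr, F, B, l, rcfg, exclude = masks)
        }
      }
      tr$seed <- seeds[ci, ]
      if (is.null(final) || tr$objective < final$objective) final <- tr
    }
    fg_bags_l <- make_window_bags(F, l, exclude = masks)
    thr <- detection_threshold(final$model, bg_bags_l, cfg$threshold_quantile)
    sites <- call_sites(final$model, fg_bags_l, thr)
    motif <- structure(list(pwm = weights_to_pwm(final$model),
                            model = final$model, objective = final$objective,
                            threshold = thr, sites = sites,
                            seed = final$seed,
                            extension_offset = final$extension_offset,
                            trace = final$trace, converged = final$converged),
                       class = "wsmd_motif")
    results[[round]] <- motif
    if (round < cfg$n_motifs) {
      # record masked intervals; masked regions are N-ed out for re-seeding and
      # excluded from every re-windowing, which removes exactly the windows
      # overlapping the called site
      for (r in seq_len(nrow(sites))) {
        i <- match(sites$id[r], F$id)
        iv <- matrix(c(sites$start[r], sites$end[r]), 1L)
        masks[[i]] <- rbind(masks[[i]], iv)
        s <- strsplit(Fmasked$seq[i], "")[[1L]]
        s[(sites$start[r] + 1L):sites$end[r]] <- "N"
        Fmasked$seq[i] <- paste(s, collapse = "")
      }
      # drop foreground sequences whose bags would become empty
      ok <- vapply(make_window_bags(F, k, exclude = masks), function(b)
        nrow(b$sites) > 0L, logical(1))
      if (!all(ok)) {
        F <- F[ok, , drop = FALSE]
        Fmasked <- Fmasked[ok, , drop = FALSE]
        masks <- masks[ok]
      }
      if (nrow(F) < 2L) break
    }
  }
  results[order(vapply(results, `[[`, numeric(1), "objective"))]
}

#' @export
print.wsmd_motif <- function(x, ...) {
  cat("motif (seed ", x$seed$word, "), width ", x$model$l,
      ", objective ", format(x$objective, digits = 6),
      ", ", nrow(x$sites), " site calls\n", sep = "")
  print(x$pwm)
  invisible(x)
}

#' Write motifs in MEME minimal format
#'
#' @param motifs List of `wsmd_motif` or [pwm()] objects.
#' @param path Output file.
#' @param names Optional motif names (default `motif_1`, ...).
#' @export
write_meme <- function(motifs, path, names = NULL) {
  if (inherits(motifs, "wsmd_motif") || inherits(motifs, "wsmd_pwm"))
    motifs <- list(motifs)
  if (is.null(names)) names <- paste0("motif_", seq_along(motifs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", ""), con)
  for (i in seq_along(motifs)) {
    P <- motifs[[i]]
    if (inherits(P, "wsmd_motif")) P <- P$pwm
    writeLines(sprintf("MOTIF %s", names[i]), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(P)), con)
    for (j in seq_len(ncol(P)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", P[1, j], P[2, j], P[3, j], P[4, j]),
                 con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal file
#'
#' @param path A MEME minimal format file.
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  if (length(starts) == 0L) stop("no MOTIF records in ", path)
  out <- list()
  for (s in starts) {
    name <- sub("^MOTIF +", "", lines[s])
    name <- strsplit(name, "[ \t]")[[1L]][1L]
    h <- s + grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1L]
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    P <- vapply(strsplit(trimws(rows), " +"),
                function(v) as.numeric(v), numeric(4))   # 4 x w
    P <- sweep(P, 2L, colSums(P), "/")  # normalize away rounding
    out[[name]] <- pwm(P)
  }
  out
}

#' Write site calls as BED6
#'
#' Columns: sequence id, 0-based half-open start/end, motif name, site
#' energy, strand.
#'
#' @param sites Site `data.frame` (`id`, `start`, `end`, `strand`, `energy`).
#' @param path Output file.
#' @param name Motif name placed in the BED name column.
#' @export
write_sites_bed <- function(sites, path, name = "motif_1") {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.6f\t%s", sites$id, sites$start,
                   sites$end, rep_len(name, nrow(sites)), sites$energy,
                   sites$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 site annotation
#'
#' @param path BED file (at least 3 columns; name/score/strand optional).
#' @return Site `data.frame` with `id`, `start`, `end`, `name`, `strand`.
#' @export
read_sites_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE, fill = TRUE)
  names(d) <- c("id", "start", "end", "name", "score", "strand")[seq_len(ncol(d))]
  if (is.null(d$name)) d$name <- "."
  if (is.null(d$strand)) d$strand <- "+"
  d
}
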