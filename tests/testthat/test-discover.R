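# A single small planted-motif dataset shared by the discovery tests.
disc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(synthetic_config(n_seq = 40, seq_len = 60,
                                                  signal_width = 8,
                                                  signal_ic = 15,
                                                  decoy_width = 8,
                                                  decoy_ic = 10,
                                                  rng_seed = 99))
    }
    cache
  }
})

test_that("unified extension evaluates l-k+1 placements and keeps the best", {
  ds <- disc_fixture()
  fg6 <- make_window_bags(ds$F, 6); bg6 <- make_window_bags(ds$B, 6)
  cfg <- refinement_config(max_iters = 5)
  seed <- select_seeds(ds$F, ds$B, 6, 1)$word[1]
  tr6 <- suppressWarnings(refine(seed_to_initial_model(seed), fg6, bg6, cfg))
  fg10 <- make_window_bags(ds$F, 10); bg10 <- make_window_bags(ds$B, 10)
  ext <- suppressWarnings(extend_motif(tr6, fg10, bg10, cfg))
  expect_equal(nrow(ext$candidates), 10 - 6 + 1)
  expect_equal(ext$model$l, 10L)
  expect_equal(ext$objective, min(ext$candidates$objective))
  expect_equal(ext$extension_offset,
               ext$candidates$x[which.min(ext$candidates$objective)])
  # k = l: a single candidate, objective no worse than the input's
  ext_same <- suppressWarnings(extend_motif(tr6, fg6, bg6, cfg))
  expect_equal(nrow(ext_same$candidates), 1L)
  expect_lte(ext_same$objective, tr6$objective + 1e-9)
})

test_that("greedy extension grows one column at a time and is identity at k = l", {
  ds <- disc_fixture()
  fg6 <- make_window_bags(ds$F, 6); bg6 <- make_window_bags(ds$B, 6)
  cfg <- refinement_config(max_iters = 3)
  seed <- select_seeds(ds$F, ds$B, 6, 1)$word[1]
  tr6 <- suppressWarnings(refine(seed_to_initial_model(seed), fg6, bg6, cfg))
  same <- extend_motif_greedy(tr6, ds$F, ds$B, 6, cfg)
  expect_identical(same$model$w, tr6$model$w)
  grown <- suppressWarnings(extend_motif_greedy(tr6, ds$F, ds$B, 9, cfg))
  expect_equal(grown$model$l, 9L)
})

test_that("masking removes exactly the windows overlapping the called site", {
  ds <- disc_fixture()
  res <- discover(ds$F, ds$B, discovery_config(motif_length = 8,
                                               seed_length = 8, n_seeds = 2))
  motif <- res[[1]]
  fg <- make_window_bags(ds$F, 8)
  masked <- mask_sites(fg, motif)
  called <- motif$sites
  for (i in seq_along(fg)) {
    r <- which(called$id == fg[[i]]$id)
    if (length(r) == 0) {
      expect_identical(masked[[i]]$sites, fg[[i]]$sites)  # below threshold
    } else {
      p <- called$start[r]
      drop <- sum(fg[[i]]$offset + 8 > p & fg[[i]]$offset < p + 8)
      expect_equal(nrow(fg[[i]]$sites) - nrow(masked[[i]]$sites), drop)
      expect_lte(drop, 2 * (2 * 8 - 1))
      # interior sites remove the full 2(2l-1) window set
      if (p >= 7 && p + 8 <= fg[[i]]$n - 7) expect_equal(drop, 30L)
      # masking again is a no-op once the residual best drops below threshold
      if (nrow(masked[[i]]$sites) > 0 &&
          sequence_energy(motif$model, masked[[i]])$energy <= motif$threshold) {
        again <- mask_sites(masked[i], motif)
        expect_identical(again[[1]]$sites, masked[[i]]$sites)
      }
    }
  }
})

test_that("masking strictly worsens the masked motif's objective", {
  ds <- disc_fixture()
  res <- discover(ds$F, ds$B, discovery_config(motif_length = 8,
                                               seed_length = 8, n_seeds = 2))
  motif <- res[[1]]
  fg <- make_window_bags(ds$F, 8)
  bg <- make_window_bags(ds$B, 8)
  masked <- mask_sites(fg, motif)
  keep <- vapply(masked, function(b) nrow(b$sites) > 0, logical(1))
  expect_gt(objective_value(motif$model, masked[keep], bg),
            objective_value(motif$model, fg[keep], bg))
})

test_that("degenerate inputs are rejected with descriptive errors", {
  ds <- disc_fixture()
  expect_error(discover(ds$F[1, , drop = FALSE], ds$B, discovery_config()),
               "at least 2")
  expect_error(discovery_config(motif_length = 6, seed_length = 8),
               "seed_length")
})

test_that("discovery recovers the planted signal and masking yields distinct motifs", {
  ds <- disc_fixture()
  res <- discover(ds$F, ds$B, discovery_config(motif_length = 8,
                                               seed_length = 8, n_seeds = 3))
  tru <- ds$truth[ds$truth$kind == "signal", ]
  expect_gt(ncc(res[[1]]$sites, tru, ds$F), 0.5)
  # plant a second, distinct motif and ask for two
  set.seed(100)
  F2 <- ds$F
  for (i in seq_len(nrow(F2))) {
    s <- F2$seq[i]
    # overwrite a fixed window far from the signal when possible
    tr_i <- tru[tru$id == F2$id[i], ]
    pos <- if (tr_i$start >= 20) 1 else 45
    substr(s, pos, pos + 7) <- "ACGTACGT"
    F2$seq[i] <- s
  }
  res2 <- discover(F2, ds$B, discovery_config(motif_length = 8,
                                              seed_length = 8, n_seeds = 3,
                                              n_motifs = 2))
  expect_length(res2, 2L)
  cons <- vapply(res2, function(r)
    paste(c("A", "C", "G", "T")[apply(unclass(r$pwm), 2, which.max)],
          collapse = ""), character(1))
  expect_false(cons[1] == cons[2])
  # the two motifs explain different implants: compare site overlap
  planted2 <- do.call(rbind, lapply(seq_len(nrow(F2)), function(i) {
    tr_i <- tru[tru$id == F2$id[i], ]
    pos <- if (tr_i$start >= 20) 1 else 45
    data.frame(id = F2$id[i], start = pos - 1, end = pos + 7)
  }))
  overlaps <- vapply(res2, function(r)
    c(sasp(r$sites, tru), sasp(r$sites, planted2)), numeric(2))
  expect_false(which.max(overlaps[1, ]) == which.max(overlaps[2, ]))
})

test_that("rerunning the pipeline with the same config is byte-identical", {
  ds <- disc_fixture()
  cfg <- discovery_config(motif_length = 8, seed_length = 8, n_seeds = 2)
  r1 <- discover(ds$F, ds$B, cfg)
  r2 <- discover(ds$F, ds$B, cfg)
  expect_identical(r1[[1]]$model$w, r2[[1]]$model$w)
  expect_identical(r1[[1]]$sites, r2[[1]]$sites)
})
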