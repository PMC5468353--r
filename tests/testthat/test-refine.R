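test_that("zero model has objective 1 and trained models beat it", {
  set.seed(15)
  d <- small_planted_set(n = 15, len = 40)
  fg <- make_window_bags(d$F, 8); bg <- make_window_bags(d$B, 8)
  zero <- linear_model(rep(0, 32), l = 8)
  expect_identical(objective_value(zero, fg, bg, c = 1), 1)
  # brute-force evaluation of the objective on a random model
  for (i in 1:5) {
    m <- linear_model(rnorm(32), b = rnorm(1), l = 8)
    N <- length(fg) + length(bg)
    ener <- function(bags) vapply(bags, function(b)
      max(apply(b$sites, 1, function(r) sum(m$w[4 * (0:7) + r]))), numeric(1))
    brute <- sum(m$w^2) + (1 / N) *
      sum(pmax(1 - c(ener(fg) - m$b, m$b - ener(bg)), 0))
    expect_equal(objective_value(m, fg, bg, c = 1), brute, tolerance = 1e-9)
  }
})

test_that("latent update returns the argmax window with the deterministic tie rule", {
  bag1 <- make_window_bag("one", "ACGTT", 5)
  m <- linear_model(rnorm(20), l = 5)
  e2 <- wsmd:::cpp_window_energies(bag1$sites, matrix(m$w, 4))
  expect_equal(latent_update(m, list(bag1))$index, which.max(e2))
  # with the reverse strand masked away the single remaining window is chosen
  bag_one <- bag1; bag_one$sites <- bag1$sites[1, , drop = FALSE]
  bag_one$offset <- bag1$offset[1]; bag_one$strand <- bag1$strand[1]
  expect_equal(latent_update(m, list(bag_one))$index, 1L)
  # all-equal weights: every window ties; forward strand, offset 0 wins
  flat <- linear_model(rep(0.3, 20), l = 5)
  a <- latent_update(flat, list(make_window_bag("s", "ACGTTACG", 5)))
  expect_equal(a$offset, 0L)
  expect_equal(a$strand, "+")
  # random model matches an exhaustive scan
  set.seed(16)
  for (i in 1:10) {
    s <- random_dna(30)
    m <- linear_model(rnorm(24), l = 6)
    bag <- make_window_bag("s", s, 6)
    e <- apply(bag$sites, 1, function(r) sum(m$w[4 * (0:5) + r]))
    a <- latent_update(m, list(bag))
    expect_equal(a$energy, max(e), tolerance = 1e-12)
  }
})

test_that("qp_step solves the analytic max-margin toys exactly", {
  X1 <- rbind(c(1, 0, 0, 0), c(-1, 0, 0, 0))
  m1 <- qp_step(X1, c(1, -1), c = 1e6, n_total = 2)
  expect_equal(m1$w, c(1, 0, 0, 0), tolerance = 1e-8)
  expect_equal(m1$b, 0, tolerance = 1e-8)
  expect_equal(c(1, -1) * (as.vector(X1 %*% m1$w) - m1$b), c(1, 1),
               tolerance = 1e-8)  # functional margins exactly 1
  X2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  m2 <- qp_step(X2, c(1, -1), c = 1e6, n_total = 2)
  expect_equal(m2$w, c(1, -1, 0, 0), tolerance = 1e-8)
  expect_equal(m2$b, 0, tolerance = 1e-8)
  expect_equal(sum(m2$w^2), 2, tolerance = 1e-8)
  expect_error(qp_step(X1, c(1, 1), c = 1), "positive and one negative")
})

test_that("qp_step carries a primal-dual certificate of optimality", {
  set.seed(17)
  for (i in 1:10) {
    n <- 16
    X <- matrix(rnorm(n * 6), n, 6)
    y <- rep(c(1, -1), each = n / 2)
    cc <- sample(c(0.5, 5, 50), 1)
    m <- qp_step(X, y, cc, n_total = n)
    alpha <- attr(m, "alpha")
    primal <- sum(m$w^2) + (cc / n) * sum(pmax(1 - y * (X %*% m$w - m$b), 0))
    dual <- sum(alpha) - sum(m$w^2)
    expect_lte(primal - dual, 1e-6)
    expect_gte(primal - dual, -1e-9)   # weak duality
  }
})

test_that("refinement decreases the surrogate at every QP step and returns the best iterate", {
  set.seed(18)
  d <- small_planted_set(n = 25, len = 50)
  fg <- make_window_bags(d$F, 8); bg <- make_window_bags(d$B, 8)
  tr <- suppressWarnings(refine(seed_to_initial_model(d$word), fg, bg,
                                refinement_config(c = 4)))
  expect_true(all(tr$trace$surrogate_after <= tr$trace$surrogate_before + 1e-9))
  expect_equal(tr$objective, min(c(tr$trace$objective,
                                   objective_value(seed_to_initial_model(d$word),
                                                   fg, bg, 4))))
  expect_equal(objective_value(tr$model, fg, bg, 4), tr$objective,
               tolerance = 1e-12)
})

test_that("a separating seed with unit margins is a fixed point region", {
  # two tiny sequences separated by construction
  F <- labeled_sequences("f", "AAAAAA", 1L)
  B <- labeled_sequences("b", "CCCCCC", -1L)
  fg <- make_window_bags(F, 4); bg <- make_window_bags(B, 4)
  seed <- seed_to_initial_model("AAAA")
  tr <- refine(seed, fg, bg, refinement_config(c = 100))
  expect_lte(tr$objective, objective_value(seed, fg, bg, 100))
  expect_true(tr$converged)
})

test_that("refinement is deterministic given data order and config", {
  set.seed(19)
  d <- small_planted_set(n = 20, len = 40, seed = 77)
  fg <- make_window_bags(d$F, 8); bg <- make_window_bags(d$B, 8)
  t1 <- suppressWarnings(refine(seed_to_initial_model(d$word), fg, bg))
  t2 <- suppressWarnings(refine(seed_to_initial_model(d$word), fg, bg))
  expect_identical(t1$model$w, t2$model$w)
  expect_identical(t1$trace, t2$trace)
})

test_that("exact-negative mode terminates with no violated background window", {
  set.seed(20)
  d <- small_planted_set(n = 15, len = 40, seed = 5)
  fg <- make_window_bags(d$F, 8); bg <- make_window_bags(d$B, 8)
  cfg <- refinement_config(c = 10, solver_mode = "exact_negative")
  tr <- suppressWarnings(refine(seed_to_initial_model(d$word), fg, bg, cfg))
  m <- tr$model
  for (b in bg) {
    e <- max(apply(b$sites, 1, function(r) sum(m$w[4 * (0:7) + r])))
    xi <- max(0, 1 + e - m$b)
    # constraint -(w'x - b) >= 1 - xi for the worst window, up to 1e-4
    expect_lte(e - m$b + 1, xi + 1e-4 + 1e-9)
  }
})

test_that("choose_c respects membership, determinism, and the smallest-c tie rule", {
  expect_equal(choose_c(NULL, NULL, NULL, grid = 3.5), 3.5)
  set.seed(21)
  d <- small_planted_set(n = 12, len = 40, seed = 9)
  fg <- make_window_bags(d$F, 8); bg <- make_window_bags(d$B, 8)
  seed_m <- seed_to_initial_model(d$word)
  c1 <- choose_c(fg, bg, seed_m, grid = c(0.1, 1), cfg = refinement_config(max_iters = 5))
  c2 <- choose_c(fg, bg, seed_m, grid = c(0.1, 1), cfg = refinement_config(max_iters = 5))
  expect_identical(c1, c2)
  expect_true(c1 %in% c(0.1, 1))
})
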