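#' Refinement configuration
#'
#' @param c Positive tradeoff between the L2 penalty and the hinge loss.
#' @param max_iters Cap on alternating iterations.
#' @param tol Relative decrease of the true objective below which the
#'   alternation stops.
#' @param solver_mode `"paper_alternating"` (argmax latent windows on both
#'   classes, the default) or `"exact_negative"` (hard-negative mining makes
#'   the background side of the objective exact).
#' @param rng_seed Integer seed for the few operations that randomize
#'   (cross-validated fold assignment in [choose_c()]); the refinement itself
#'   is deterministic.
#' @return A `wsmd_refine_config` list.
#' @export
refinement_config <- function(c = 1, max_iters = 50L, tol = 1e-4,
                              solver_mode = c("paper_alternating", "exact_negative"),
                              rng_seed = 1L) {
  solver_mode <- match.arg(solver_mode)
  if (c <= 0) stop("c must be positive")
  if (max_iters < 1L) stop("max_iters must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  structure(list(c = c, max_iters = as.integer(max_iters), tol = tol,
                 solver_mode = solver_mode, rng_seed = as.integer(rng_seed)),
            class = "wsmd_refine_config")
}

#' True latent-SVM objective value
#'
#' `||w||^2 + (c/N) * sum_s hinge(y_s * (E(s) - b))` where `E(s)` is the
#' maximal window score of sequence `s` (exact full scan) and
#' `N = |F| + |B|`.
#'
#' @param m A `wsmd_model`.
#' @param fg_bags,bg_bags Lists of `wsmd_bag` for the two classes.
#' @param c Tradeoff constant.
#' @return The objective value.
#' @export
objective_value <- function(m, fg_bags, bg_bags, c = 1) {
  ef <- bag_max_energies(m, fg_bags)
  eb <- bag_max_energies(m, bg_bags)
  N <- length(fg_bags) + length(bg_bags)
  margins <- c(ef - m$b, -(eb - m$b))
  sum(m$w^2) + c * sum(pmax(1 - margins, 0)) / N
}

#' Latent window update
#'
#' For every sequence (both classes) selects the best-scoring window under
#' the current weights; ties go to the forward strand, then to the smallest
#' offset.
#'
#' @param m A `wsmd_model`.
#' @param bags List of `wsmd_bag`.
#' @return A `data.frame` with one row per bag: `bag`, `index`, `offset`,
#'   `strand`, `energy`.
#' @export
latent_update <- function(m, bags) {
  W <- model_weight_matrix(m)
  n <- length(bags)
  index <- integer(n); offset <- integer(n)
  strand <- character(n); energy <- numeric(n)
  for (i in seq_len(n)) {
    b <- bags[[i]]
    if (nrow(b$sites) == 0L)
      stop("sequence '", b$id, "' has an empty window bag")
    e <- cpp_window_energies(b$sites, W)
    j <- which.max(e)
    index[i] <- j; offset[i] <- b$offset[j]
    strand[i] <- b$strand[j]; energy[i] <- e[j]
  }
  data.frame(bag = seq_len(n), index = index, offset = offset,
             strand = strand, energy = energy, stringsAsFactors = FALSE)
}

# internal: fixed-latent surrogate objective on chosen encodings
surrogate_value <- function(w, b, X, y, c, N) {
  sum(w^2) + c * sum(pmax(1 - y * (as.vector(X %*% w) - b), 0)) / N
}

# internal: exact piecewise-linear minimization of the hinge sum over b at
# fixed w. e = per-sequence effective energy, y = labels. The minimum of a
# convex piecewise-linear function is attained at a breakpoint; on a flat
# optimal segment the midpoint of the tied breakpoints is returned.
optimal_intercept <- function(e, y) {
  bp <- sort(unique(e - y))
  loss <- vapply(bp, function(b) sum(pmax(1 - y * (e - b), 0)), numeric(1))
  ties <- bp[loss <= min(loss) + 1e-12]
  mean(range(ties))
}

#' Soft-margin QP step
#'
#' Exactly minimizes `||w||^2 + (c/N) * sum_g xi_g` subject to
#' `y_g (w'x_i - b) >= 1 - xi_g` for every window `i` of group (sequence)
#' `g`, with unregularized intercept `b`. With the default one-window-per-
#' sequence grouping this is the standard soft-margin linear SVM on the
#' chosen windows. The dual is solved to high precision by a compiled SMO
#' solver; `b` is then recovered by exact 1-D minimization of the hinge sum
#' at the optimal `w`.
#'
#' @param X Numeric matrix (rows = one-hot window encodings).
#' @param y Label vector in `{+1, -1}`, one per row of `X`.
#' @param c Tradeoff constant.
#' @param n_total The `N` in the `c/N` scaling, i.e. the number of sequences
#'   in the training data (defaults to `length(unique(groups))`).
#' @param groups Integer vector assigning rows to sequences; rows of one
#'   group share the label and a single slack (defaults to one group per row).
#' @param tol SMO duality-gap tolerance.
#' @param max_iter SMO iteration cap.
#' @return A `wsmd_model` with attributes `alpha`, `solver_iterations`,
#'   `solver_converged`.
#' @export
qp_step <- function(X, y, c, n_total = NULL, groups = NULL,
                    tol = 1e-10, max_iter = 500000L) {
  X <- as.matrix(X)
  if (is.null(groups)) groups <- seq_len(nrow(X))
  groups <- match(groups, unique(groups))      # densify to 1..ngroup
  if (is.null(n_total)) n_total <- length(unique(groups))
  gy <- tapply(y, groups, function(v) {
    if (length(unique(v)) != 1L) stop("all windows of one group must share a label")
    v[1L]
  })
  if (length(unique(as.vector(gy))) < 2L)
    stop("QP step needs at least one positive and one negative example")
  Cbox <- c / n_total
  fit <- cpp_smo(X, as.numeric(y), Cbox, as.integer(groups) - 1L,
                 length(unique(groups)), tol, as.integer(max_iter))
  alpha <- fit$alpha
  w <- as.vector(crossprod(X, alpha * y)) / 2
  # per-group effective energy: max over that group's windows
  ener <- as.vector(X %*% w)
  ge <- tapply(ener, groups, max)
  b <- optimal_intercept(as.vector(ge), as.vector(gy))
  m <- linear_model(w, b = b, l = ncol(X) / 4L)
  attr(m, "alpha") <- alpha
  attr(m, "solver_iterations") <- fit$iterations
  attr(m, "solver_converged") <- fit$converged
  m
}

# internal: one-hot encodings of the chosen windows of an assignment
assignment_encodings <- function(bags, assignment) {
  l <- bags[[1L]]$l
  sites <- matrix(0L, nrow(assignment), l)
  for (r in seq_len(nrow(assignment)))
    sites[r, ] <- bags[[assignment$bag[r]]]$sites[assignment$index[r], ]
  encode_site_rows(sites)
}

#' Refine a motif model by alternating latent updates and QP steps
#'
#' Starting from a seed model, alternates (i) re-selecting each sequence's
#' best-scoring window under the current weights and (ii) exactly re-solving
#' the convex soft-margin QP on the selected windows, until the true
#' objective's relative decrease falls below `cfg$tol` or `cfg$max_iters` is
#' reached. Because the argmax update on background sequences can increase
#' the true objective, the best-by-true-objective iterate (which may be an
#' intermediate one) is returned. In `exact_negative` mode, violated
#' background windows are accumulated as shared-slack constraints
#' (hard-negative mining) until no background window violates by more than
#' 1e-4, which makes the background side of the objective exact.
#'
#' @param seed_model Initial `wsmd_model` (e.g. from
#'   [seed_to_initial_model()]); width must match the bags' window length.
#' @param fg_bags,bg_bags Window bags of the two classes.
#' @param cfg A [refinement_config()].
#' @return A `wsmd_trained` list: `model`, `objective`, `iterations`,
#'   `trace` (per-iteration objective and surrogate values), `assignment`
#'   (latent windows under the returned model), `converged`.
#' @export
refine <- function(seed_model, fg_bags, bg_bags, cfg = refinement_config()) {
  stopifnot(inherits(seed_model, "wsmd_model"))
  if (length(fg_bags) == 0L || length(bg_bags) == 0L)
    stop("refinement needs non-empty foreground and background sets")
  if (fg_bags[[1L]]$l != seed_model$l)
    stop("seed model width ", seed_model$l, " does not match window length ",
         fg_bags[[1L]]$l)
  if (cfg$solver_mode == "exact_negative")
    return(refine_exact_negative(seed_model, fg_bags, bg_bags, cfg))

  bags <- c(fg_bags, bg_bags)
  y <- c(rep(1, length(fg_bags)), rep(-1, length(bg_bags)))
  N <- length(bags)
  # objective from an assignment's argmax energies (equals the full-scan value)
  obj_from <- function(m, assignment)
    sum(m$w^2) + cfg$c * sum(pmax(1 - y * (assignment$energy - m$b), 0)) / N
  model <- seed_model
  assignment <- latent_update(model, bags)
  best_model <- model
  best_obj <- obj_from(model, assignment)
  best_assignment <- assignment
  objs <- numeric(0)
  trace <- vector("list", cfg$max_iters)
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iters) {
    iter <- iter + 1L
    X <- assignment_encodings(bags, assignment)
    sur_before <- surrogate_value(model$w, model$b, X, y, cfg$c, N)
    model <- qp_step(X, y, cfg$c, n_total = N)
    sur_after <- surrogate_value(model$w, model$b, X, y, cfg$c, N)
    assignment <- latent_update(model, bags)
    obj <- obj_from(model, assignment)
    trace[[iter]] <- data.frame(iter = iter, objective = obj,
                                surrogate_before = sur_before,
                                surrogate_after = sur_after)
    if (obj < best_obj) {
      best_obj <- obj; best_model <- model; best_assignment <- assignment
    }
    # converged when the objective revisits (within tol) any of the last few
    # iterates: a plateau, or the short cycle the argmax update on background
    # sequences settles into
    recent <- utils::tail(objs, 4L)
    if (length(recent) &&
        any(abs(recent - obj) < cfg$tol * max(1, abs(obj)))) {
      converged <- TRUE
      break
    }
    objs <- c(objs, obj)
  }
  if (!converged)
    warning("refinement did not converge within ", cfg$max_iters,
            " iterations; returning the best iterate", call. = FALSE)
  structure(list(model = best_model, objective = best_obj, iterations = iter,
                 trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
                 assignment = best_assignment,
                 converged = converged),
            class = "wsmd_trained")
}

# hard-negative mining: the foreground keeps its argmax latent window, the
# background accumulates every violating window (shared slack per sequence)
# so that at termination the negative side of the objective is exact.
refine_exact_negative <- function(seed_model, fg_bags, bg_bags, cfg,
                                  violation_tol = 1e-4) {
  nf <- length(fg_bags); nb <- length(bg_bags)
  N <- nf + nb
  model <- seed_model
  # active negative windows per background bag, start with current argmax
  neg_active <- lapply(latent_update(model, bg_bags)$index, identity)
  best_model <- model                   # fallback if no clean iterate emerges
  best_obj <- Inf
  seed_obj <- objective_value(model, fg_bags, bg_bags, cfg$c)
  objs <- numeric(0)
  trace <- vector("list", cfg$max_iters)
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iters) {
    iter <- iter + 1L
    pos <- latent_update(model, fg_bags)
    Xp <- assignment_encodings(fg_bags, pos)
    Xn <- do.call(rbind, lapply(seq_len(nb), function(i) {
      encode_site_rows(bg_bags[[i]]$sites[neg_active[[i]], , drop = FALSE])
    }))
    X <- rbind(Xp, Xn)
    y <- c(rep(1, nf), rep(-1, sum(lengths(neg_active))))
    groups <- c(seq_len(nf), nf + rep(seq_len(nb), lengths(neg_active)))
    model <- qp_step(X, y, cfg$c, n_total = N, groups = groups)
    obj <- objective_value(model, fg_bags, bg_bags, cfg$c)
    trace[[iter]] <- data.frame(iter = iter, objective = obj,
                                surrogate_before = NA_real_,
                                surrogate_after = NA_real_)
    # mine violated background windows: E > b - 1 + xi + tol
    W <- model_weight_matrix(model)
    added <- FALSE
    for (i in seq_len(nb)) {
      e <- cpp_window_energies(bg_bags[[i]]$sites, W)
      xi <- max(0, 1 + max(e[neg_active[[i]]]) - model$b)
      worst <- which.max(e)
      if (e[worst] - model$b + 1 > xi + violation_tol &&
          !(worst %in% neg_active[[i]])) {
        neg_active[[i]] <- c(neg_active[[i]], worst)
        added <- TRUE
      }
    }
    # only violation-free iterates are candidates for the returned model, so
    # the exactness guarantee holds for the output, not just the last iterate
    if (!added && obj < best_obj) { best_obj <- obj; best_model <- model }
    recent <- utils::tail(objs, 4L)
    if (!added && length(recent) &&
        any(abs(recent - obj) < cfg$tol * max(1, abs(obj)))) {
      converged <- TRUE
      break
    }
    objs <- c(objs, obj)
  }
  if (!converged)
    warning("exact-negative refinement did not converge within ", cfg$max_iters,
            " iterations; returning the best iterate", call. = FALSE)
  if (!is.finite(best_obj)) best_obj <- seed_obj
  structure(list(model = best_model, objective = best_obj, iterations = iter,
                 trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
                 assignment = latent_update(best_model, c(fg_bags, bg_bags)),
                 converged = converged),
            class = "wsmd_trained")
}

#' @export
print.wsmd_trained <- function(x, ...) {
  cat("refined motif, width", x$model$l, "- objective",
      format(x$objective, digits = 6), "after", x$iterations, "iterations",
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' Select the hinge/regularization tradeoff by cross-validation
#'
#' Picks the `c` in a grid that maximizes mean held-out AUC under internal
#' stratified 3-fold cross-validation of [refine()] started from
#' `seed_model`. Ties (within 1e-12) go to the smallest `c`. Deterministic
#' given `cfg$rng_seed`.
#'
#' @param fg_bags,bg_bags Window bags of the training data.
#' @param seed_model Initial model used for every fold.
#' @param grid Candidate `c` values.
#' @param cfg A [refinement_config()]; its `c` is ignored.
#' @param n_folds Number of folds.
#' @return The selected `c`.
#' @export
choose_c <- function(fg_bags, bg_bags, seed_model,
                     grid = c(0.01, 0.1, 1, 10),
                     cfg = refinement_config(), n_folds = 3L) {
  if (length(grid) == 0L) stop("grid must be non-empty")
  grid <- sort(grid)
  if (length(grid) == 1L) return(grid)
  folds_f <- stratified_folds(length(fg_bags), n_folds, cfg$rng_seed)
  folds_b <- stratified_folds(length(bg_bags), n_folds, cfg$rng_seed + 1L)
  aucs <- vapply(grid, function(cc) {
    cfg_c <- cfg; cfg_c$c <- cc
    mean(vapply(seq_len(n_folds), function(f) {
      tr <- suppressWarnings(
        refine(seed_model, fg_bags[folds_f != f], bg_bags[folds_b != f], cfg_c))
      auc_score(bag_max_energies(tr$model, fg_bags[folds_f == f]),
                bag_max_energies(tr$model, bg_bags[folds_b == f]))
    }, numeric(1)))
  }, numeric(1))
  grid[which(aucs >= max(aucs) - 1e-12)[1L]]
}

# internal: deterministic stratified fold ids (sizes differ by <= 1)
stratified_folds <- function(n, n_folds, seed) {
  if (n < n_folds) stop("too few sequences (", n, ") for ", n_folds, " folds")
  perm <- with_local_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(n_folds), n)
  folds
}

# internal: run expr under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
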