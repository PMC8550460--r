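# Nested swarm searches for G- and prediction-D-optimal designs.

# encode a candidate design as a CSO particle: support coordinates
# (column-major by factor) followed by raw weights on [0,1]; raw weights
# are normalized to the simplex (an all-zero raw vector means uniform)
particle_bounds <- function(space, k, fixed_support = NULL) {
  if (is.null(fixed_support)) {
    lower <- c(rep(space$lower, each = k), rep(0, k))
    upper <- c(rep(space$upper, each = k), rep(1, k))
  } else {
    lower <- rep(0, k)
    upper <- rep(1, k)
  }
  list(lower = lower, upper = upper)
}

particle_to_design <- function(par, space, k, fixed_support = NULL) {
  if (is.null(fixed_support)) {
    X <- matrix(par[seq_len(k * space$dim)], k, space$dim)
    r <- par[k * space$dim + seq_len(k)]
  } else {
    X <- as_points_matrix(fixed_support, space$dim)
    r <- par
  }
  w <- if (sum(r) <= 0) rep(1 / k, k) else r / sum(r)
  list(points = X, weights = w)
}

# phi-maximum objective with a regularized information matrix; the
# workhorse of the outer G search.  The inner maximization refines all
# grid local maxima (see maximize_over_space), so the outer minimizer
# cannot hide sharp phi peaks between grid nodes.
g_objective_factory <- function(model, space, k, fixed_support, grid_n,
                                reg = 1e-7) {
  n <- model$n
  Delta <- model$Delta
  p <- model$p
  function(par) {
    cand <- particle_to_design(par, space, k, fixed_support)
    if (any(cand$weights < 0) || !space_contains(space, cand$points, 1e-9)) {
      return(Inf)                        # polish steps may wander off the box
    }
    Fm <- tryCatch(basis_matrix(model$basis, cand$points),
                   error = function(e) NULL)
    if (is.null(Fm)) return(Inf)
    M <- sym(crossprod(Fm, cand$weights * Fm)) + reg * diag(p)
    Minv <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
    if (is.null(Minv)) return(Inf)
    N <- Delta - Delta %*% tryCatch(solve(Minv + Delta, Delta),
                                    error = function(e) return(matrix(NA, p, p)))
    if (anyNA(N)) return(Inf)
    fn <- function(X) {
      Fx <- basis_matrix(model$basis, X)
      rowSums((Fx %*% Minv) * Fx) + (n - 1) * rowSums((Fx %*% N) * Fx)
    }
    maximize_over_space(fn, space, grid_n = grid_n, polish = FALSE)$value
  }
}

#' Find a G-optimal approximate design
#'
#' Two-layer min-max search: an outer competitive swarm over support
#' coordinates and weights minimizes the G-criterion, whose every
#' evaluation maximizes the prediction variance \eqn{\phi} over the
#' design space (dense grid for one or two factors, inner swarm
#' otherwise).  The best design over `restarts` independent swarm runs
#' is cleaned with [normalize_design()], re-evaluated without
#' regularization, and certified with [verify_g_optimality()].
#'
#' @param model An [hlm_model()].
#' @param k Number of support-point slots (default `p + 1`; surplus
#'   points are pruned).  Ignored when `fixed_support` is given.
#' @param fixed_support Optional matrix/tibble of fixed support points;
#'   only the weights are then optimized.
#' @param outer [cso_config()] for the outer search (default 128
#'   particles, 200 iterations, \eqn{\gamma = 0}).
#' @param search_grid_n Grid resolution of the inner maximization during
#'   the search (the final criterion uses [g_criterion()]'s finer grid).
#' @param restarts Independent swarm runs; the best result is kept.
#' @param seed Integer seed governing the whole search.
#' @param verify Run the equivalence-theorem certificate.
#' @param tol Certification tolerance, see [verify_g_optimality()].
#' @return A `design_fit`: the design tibble, criterion value, the
#'   certificate (`report`), and search history.
#' @export
find_g_optimal <- function(model, k = NULL, fixed_support = NULL,
                           outer = cso_config(swarm = 128L, max_iter = 200L),
                           search_grid_n = 201, restarts = 5L, seed = 1L,
                           verify = TRUE, tol = 0.02) {
  sp <- model$space
  if (is.null(fixed_support)) {
    k <- as.integer(k %||% (model$p + 1L))
    if (k < model$p) stop("`k` must be at least p = ", model$p, ".")
  } else {
    fixed_support <- as_points_matrix(fixed_support, sp$dim)
    k <- nrow(fixed_support)
  }
  obj <- g_objective_factory(model, sp, k, fixed_support, search_grid_n)
  bnd <- particle_bounds(sp, k, fixed_support)
  set.seed(seed)
  runs <- lapply(seq_len(restarts), function(r) {
    cfg <- outer
    cfg$seed <- NULL                      # run off the seeded stream
    cso_minimize(obj, bnd$lower, bnd$upper, cfg)
  })
  best <- runs[[which.min(vapply(runs, `[[`, 0, "value"))]]
  # deterministic local polish of the min-max objective on a finer grid,
  # sharpening the swarm output enough for the answering set to resolve;
  # repeated after pruning surplus support points, whose presence blunts
  # the Nelder-Mead steps
  polish_once <- function(par, kk, fs) {
    # unregularized: a ridge would bias the criterion downward near
    # singular configurations and the polish would chase that bias
    obj <- g_objective_factory(model, sp, kk, fs, max(search_grid_n, 1001),
                               reg = 0)
    val <- obj(par)
    for (round in 1:3) {                # restarted simplexes escape stalls
      pol <- tryCatch(
        stats::optim(par, obj, method = "Nelder-Mead",
                     control = list(maxit = 400 * length(par),
                                    reltol = 1e-13)),
        error = function(e) NULL)
      if (is.null(pol) || pol$value > val - 1e-10) break
      par <- pol$par
      val <- pol$value
    }
    par
  }
  clip_pts <- function(pts) {
    kk <- nrow(pts)
    pmin(pmax(pts, matrix(sp$lower, kk, sp$dim, byrow = TRUE)),
         matrix(sp$upper, kk, sp$dim, byrow = TRUE))
  }
  par <- polish_once(best$par, k, fixed_support)
  cand <- particle_to_design(par, sp, k, fixed_support)
  cand$points <- clip_pts(cand$points)
  des <- normalize_design(design(cand$points, cand$weights), space = sp)
  repolish <- function(d0) {
    k2 <- nrow(d0)
    par2 <- polish_once(c(as.vector(design_points(d0)), d0$weight), k2, NULL)
    cand2 <- particle_to_design(par2, sp, k2, NULL)
    cand2$points <- clip_pts(cand2$points)
    normalize_design(design(cand2$points, cand2$weights), space = sp)
  }
  if (is.null(fixed_support)) {
    cands <- list(des)
    if (nrow(des) < k) cands <- c(cands, list(repolish(des)))
    if (any(des$weight < 0.01) && sum(des$weight >= 0.01) >= model$p) {
      slim <- design(design_points(des)[des$weight >= 0.01, , drop = FALSE],
                     des$weight[des$weight >= 0.01])
      cands <- c(cands, list(repolish(slim)))
    }
    vals <- vapply(cands, function(d0) g_criterion(d0, model)$value, 0)
    ks <- vapply(cands, nrow, 0L)
    # at (numerically) equal criterion prefer the smaller support
    v0 <- min(vals)
    near <- vals <= v0 + 1e-5 * max(1, abs(v0))
    best_i <- which(near)[order(ks[near], vals[near])][1]
    des <- cands[[best_i]]
  }
  val <- g_criterion(des, model)
  report <- if (verify) verify_g_optimality(des, model, tol = tol) else NULL
  structure(
    list(design = des, value = val$value, criterion = "G_pred",
         argmax = val$argmax, report = report, model = model,
         history = best$history, restarts = restarts, seed = seed),
    class = "design_fit"
  )
}

#' Find a prediction D-optimal design
#'
#' Single-layer competitive swarm search minimizing the prediction
#' D-criterion [d_pred_criterion()] over support points and weights.
#'
#' @inheritParams find_g_optimal
#' @param config [cso_config()] for the search.
#' @return A `design_fit` with `criterion = "D_pred"` (no certificate).
#' @export
find_d_optimal_pred <- function(model, k = NULL,
                                config = cso_config(swarm = 128L,
                                                    max_iter = 200L),
                                restarts = 5L, seed = 1L) {
  sp <- model$space
  k <- as.integer(k %||% (model$p + 1L))
  if (k < model$p) stop("`k` must be at least p = ", model$p, ".")
  obj <- function(par) {
    cand <- particle_to_design(par, sp, k, NULL)
    des <- tryCatch(design(cand$points, cand$weights),
                    error = function(e) NULL)
    if (is.null(des)) return(Inf)
    v <- tryCatch(d_pred_criterion(des, model, reg = 1e-7)$value,
                  error = function(e) Inf)
    v
  }
  bnd <- particle_bounds(sp, k, NULL)
  set.seed(seed)
  runs <- lapply(seq_len(restarts), function(r) {
    cfg <- config
    cfg$seed <- NULL
    cso_minimize(obj, bnd$lower, bnd$upper, cfg)
  })
  best <- runs[[which.min(vapply(runs, `[[`, 0, "value"))]]
  cand <- particle_to_design(best$par, sp, k, NULL)
  des <- normalize_design(design(cand$points, cand$weights), space = sp)
  val <- d_pred_criterion(des, model)
  structure(
    list(design = des, value = val$value, criterion = "D_pred",
         argmax = NULL, report = NULL, model = model,
         history = best$history, restarts = restarts, seed = seed),
    class = "design_fit"
  )
}

#' @export
print.design_fit <- function(x, ...) {
  cat("<design_fit> ", x$criterion, " = ", format(x$value), "  (",
      nrow(x$design), " support points)\n", sep = "")
  print(x$design)
  if (!is.null(x$report)) {
    cat("certificate: ", if (x$report$pass) "PASS" else "FAIL",
        "  max sensitivity ", format(x$report$max_sensitivity), "\n",
        sep = "")
  }
  invisible(x)
}
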