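# Joint learning of simplex-constrained kernel weights and a soft-margin
# SVM on the composite kernel, by alternating optimization:
#   (a) fix lambda, solve the SVM dual on K(lambda) = sum_l lambda_l K_l;
#   (b) update lambda by a reduced-gradient step on the dual-optimal
#       objective J(lambda) over the probability simplex, with an Armijo
#       backtracking line search (each trial point re-solves the SVM).
# J(lambda) is convex in lambda (a pointwise maximum of linear functions),
# and by Danskin's theorem its gradient at the dual optimum alpha* is
#   dJ/dlambda_l = -1/2 (alpha* o y)' K_l (alpha* o y),
# so accepted steps strictly decrease J and the outer objective trace is
# monotone non-increasing.

# Refine an approximate dual solution to machine-precision KKT by
# active-set iteration seeded from the interior-point iterate. States
# per coordinate: at 0, at C, free. Each round solves the stationarity
# equations exactly on the free set,
#   sum_{j in F} y_j a_j K(i,j) + b = y_i - C sum_{j at C} y_j K(i,j)
#   sum_{j in F} y_j a_j           =   - C sum_{j at C} y_j
# (SVD pseudo-inverse: with a rank-deficient kernel any least-squares
# solution yields identical decision values, since null-space
# directions of K_FF are orthogonal to every kernel row), then moves
# the single worst offender between states: a free coefficient outside
# the box goes to the violated bound; a bound coefficient whose KKT
# multiplier has the wrong sign becomes free. Returns the best KKT
# point found; falls back to the input if no progress is possible.
polish_active_set <- function(K, y, C, alpha, eps = 1e-4, max_moves = 50) {
  n <- length(y)
  state <- integer(n)                      # 0 = at 0, 1 = free, 2 = at C
  state[alpha > eps * C] <- 1L
  state[alpha > C * (1 - eps)] <- 2L
  tol <- 1e-9 * max(1, C)
  best <- alpha
  best_viol <- Inf
  for (it in seq_len(max_moves)) {
    free <- state == 1L
    atC <- state == 2L
    if (!any(free)) break
    nf <- sum(free)
    rhs_c <- if (any(atC))
      C * as.vector(K[free, atC, drop = FALSE] %*% y[atC]) else numeric(nf)
    A <- rbind(cbind(sweep(K[free, free, drop = FALSE], 2, y[free], "*"), 1),
               c(y[free], 0))
    b_vec <- c(y[free] - rhs_c, -C * sum(y[atC]))
    sv <- svd(A)
    keep <- sv$d > max(sv$d) * 1e-12
    sol <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], b_vec) / sv$d[keep])
    if (any(!is.finite(sol)) ||
        max(abs(A %*% sol - b_vec)) > 1e-6 * max(1, C)) break
    a_free <- sol[seq_len(nf)]
    # free coefficient outside the box: pin the worst to its bound
    out_lo <- -a_free
    out_hi <- a_free - C
    worst_box <- max(out_lo, out_hi)
    if (worst_box > tol) {
      fi <- which(free)
      if (max(out_lo) >= max(out_hi)) {
        state[fi[which.max(out_lo)]] <- 0L
      } else {
        state[fi[which.max(out_hi)]] <- 2L
      }
      next
    }
    cand <- ifelse(atC, C, 0)
    cand[free] <- pmin(pmax(a_free, 0), C)
    b <- sol[nf + 1]
    # KKT multipliers at the bounds: at 0 requires y f >= 1, at C <= 1
    marg <- y * (as.vector(K %*% (cand * y)) + b)
    viol <- pmax(ifelse(state == 0L, 1 - marg,
                        ifelse(state == 2L, marg - 1, abs(marg - 1))), 0)
    worst <- max(viol)
    if (worst < best_viol) { best <- cand; best_viol <- worst }
    if (worst <= tol) break
    state[which.max(viol)] <- 1L         # free the worst bound violator
  }
  # only adopt the refinement when it reached a near-exact KKT point;
  # otherwise keep the interior-point iterate untouched
  if (best_viol <= 1e-5 * max(1, C)) best else alpha
}

# Soft-margin SVM dual on a precomputed kernel:
#   max_alpha 1'alpha - 1/2 alpha' (yy' o K) alpha
#   s.t. 0 <= alpha_i <= C, sum_i alpha_i y_i = 0
# solved as a box-constrained QP with one equality via kernlab::ipop.
svm_dual_solve <- function(K, y, C, sigf = 8, maxiter = 120) {
  n <- length(y)
  H <- K * tcrossprod(y)
  # rank-deficient kernels or over-tight precision can defeat the
  # interior-point solve; retry at lower precision, then with a small
  # ridge (which changes the objective by only O(ridge * C^2 n))
  attempts <- list(c(sigf, 0), c(sigf - 1, 0), c(sigf - 2, 1e-10),
                   c(sigf - 2, 1e-8), c(sigf - 3, 1e-6))
  sol <- NULL
  for (at in attempts) {
    sol <- tryCatch(
      kernlab::ipop(c = matrix(-1, n, 1),
                    H = H + diag(at[2], n),
                    A = matrix(y, 1, n), b = 0,
                    l = matrix(0, n, 1), u = matrix(C, n, 1), r = 0,
                    sigf = at[1], maxiter = maxiter),
      error = function(e) NULL)
    if (!is.null(sol) && all(is.finite(kernlab::primal(sol)))) break
    sol <- NULL
  }
  if (is.null(sol)) stop_("SVM dual solve failed (singular kernel system)")
  alpha <- pmin(pmax(as.vector(kernlab::primal(sol)), 0), C)
  alpha <- polish_active_set(K, y, C, alpha)
  ay <- alpha * y
  f <- as.vector(K %*% ay)           # decision values without bias
  eps <- 1e-6 * C
  free <- alpha > eps & alpha < C - eps
  if (any(free)) {
    bias <- mean(y[free] - f[free])
  } else {
    # no free support vectors: the KKT conditions only bracket the bias
    #   alpha_i = 0: y_i (f_i + b) >= 1;  alpha_i = C: y_i (f_i + b) <= 1
    # take the midpoint of the feasible interval (libsvm's convention)
    at0 <- alpha <= eps
    atC <- alpha >= C - eps
    up <- c(y[y == 1 & atC] - f[y == 1 & atC],
            y[y == -1 & at0] - f[y == -1 & at0])
    lo <- c(y[y == 1 & at0] - f[y == 1 & at0],
            y[y == -1 & atC] - f[y == -1 & atC])
    bias <- mean(c(min(up, Inf), max(lo, -Inf)))
    if (!is.finite(bias)) bias <- 0
  }
  list(alpha = alpha, dual_coef = ay, bias = bias,
       objective = sum(alpha) - 0.5 * sum(ay * f))
}

#' Train a multiple-kernel-learning SVM
#'
#' Learns simplex-constrained kernel weights \eqn{\lambda} (nonnegative,
#' summing to 1) jointly with a soft-margin SVM on the composite kernel
#' \eqn{K = \sum_\ell \lambda_\ell K_\ell}, so that the weights reflect
#' the relative informativeness of the feature groups. Optimization
#' alternates an exact SVM dual solve at fixed weights with a
#' reduced-gradient descent step on the weights over the simplex,
#' starting from uniform weights.
#'
#' @param kernels a `kernel_set` from [compute_base_kernels()] (training
#'   kernels, aligned to `labels`).
#' @param labels vector in `{-1, +1}`, both classes present.
#' @param C soft-margin regularization constant (default 1); see
#'   [tune_C()] for data-driven selection.
#' @param tol stop when the relative objective change falls below this
#'   (default `1e-5`) or the weight vector moves less than `1e-4` in
#'   max-norm.
#' @param max_iter maximum outer iterations (default 100).
#' @return an `mkl_model` with fields `weights` (named \eqn{\lambda}),
#'   `dual_coef` (\eqn{\alpha_i y_i}), `bias`, `support_index`, `C`,
#'   `kernels` (the fitted `kernel_set`, retained to kernelize new
#'   variants), `objective` (per-iteration trace, non-increasing),
#'   `converged`, `n_iter`.
#' @export
train_mkl <- function(kernels, labels, C = 1, tol = 1e-5, max_iter = 100) {
  stopifnot(inherits(kernels, "kernel_set"))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1)))
    stop_("labels must be coded -1/+1")
  if (length(unique(labels)) < 2L)
    stop_("training labels contain a single class")
  n <- length(labels)
  if (nrow(kernels$matrices[[1]]) != n)
    stop_("kernels and labels are misaligned")
  p <- length(kernels$names)
  lam <- rep(1 / p, p)
  fit <- svm_dual_solve(compose_kernel(kernels, lam), labels, C)
  obj_trace <- fit$objective
  converged <- (p == 1L)
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    ay <- fit$dual_coef
    grad <- -0.5 * vapply(kernels$matrices,
                          function(Kl) sum(ay * (Kl %*% ay)), numeric(1))
    # reduced gradient wrt the largest-weight component
    mu <- which.max(lam)
    gred <- grad - grad[mu]
    dirn <- numeric(p)
    act <- lam > 1e-12 | gred < 0
    dirn[act] <- -gred[act]
    dirn[mu] <- 0
    dirn[mu] <- -sum(dirn)
    if (max(abs(dirn)) < 1e-12) { converged <- TRUE; break }
    # largest feasible step keeping lambda >= 0
    shrink <- dirn < 0 & lam > 0
    t_max <- if (any(shrink)) min(-lam[shrink] / dirn[shrink]) else 1
    t_max <- min(t_max, 1 / max(abs(dirn)))
    slope <- sum(grad * dirn)        # <= 0 by construction
    t_step <- t_max
    accepted <- FALSE
    for (ls in 1:15) {
      lam_new <- pmax(lam + t_step * dirn, 0)
      lam_new <- lam_new / sum(lam_new)
      fit_new <- svm_dual_solve(compose_kernel(kernels, lam_new), labels, C)
      if (fit_new$objective <= fit$objective + 1e-4 * t_step * slope) {
        accepted <- TRUE
        break
      }
      t_step <- t_step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    d_obj <- fit$objective - fit_new$objective
    d_lam <- max(abs(lam_new - lam))
    lam <- lam_new
    fit <- fit_new
    obj_trace <- c(obj_trace, fit$objective)
    if (d_obj / (abs(fit$objective) + 1e-12) < tol || d_lam < 1e-4)
      converged <- TRUE
  }
  structure(list(weights = stats::setNames(lam, kernels$names),
                 dual_coef = fit$dual_coef, bias = fit$bias,
                 support_index = which(abs(fit$dual_coef) > 1e-8 * C),
                 C = C, kernels = kernels, labels = labels,
                 objective = obj_trace, converged = converged,
                 n_iter = it),
            class = "mkl_model")
}

#' @export
print.mkl_model <- function(x, ...) {
  cat("mkl_model:", length(x$labels), "training variants,",
      length(x$weights), "kernels, C =", x$C, "\n")
  cat("  kernel weights:\n")
  for (g in names(x$weights))
    cat(sprintf("    %s: %.4f\n", g, x$weights[[g]]))
  cat("  support vectors:", length(x$support_index),
      "| outer iterations:", x$n_iter,
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Decision values for new variants
#'
#' Computes \eqn{\phi = \sum_\ell \lambda'_\ell \sum_i \alpha_i y_i
#' K_\ell(x, x_i) + b} per test variant, where the effective weights
#' \eqn{\lambda'} come from [rescale_weights()] applied to that variant's
#' feature-group availability mask: groups the variant lacks contribute
#' nothing and the remaining weights are renormalized to sum to 1.
#' Variants with no available group yield `NA` ("no prediction").
#'
#' @param model an `mkl_model`.
#' @param test_kernels per-group cross-kernel blocks (`m x n_train`), as
#'   produced by [cross_kernels()]; a `cross_kernels()` result may be
#'   passed directly.
#' @param available `m x p` logical availability mask (default: taken from
#'   `test_kernels` if it is a `cross_kernels()` result, else all `TRUE`).
#' @return numeric vector of decision values, `NA` where no prediction is
#'   possible.
#' @export
decision_function <- function(model, test_kernels, available = NULL) {
  stopifnot(inherits(model, "mkl_model"))
  if (is.list(test_kernels) && !is.null(test_kernels$blocks)) {
    if (is.null(available)) available <- test_kernels$available
    test_kernels <- test_kernels$blocks
  }
  p <- length(model$weights)
  if (length(test_kernels) != p)
    stop_("expected ", p, " cross-kernel blocks, got ", length(test_kernels))
  n <- length(model$dual_coef)
  m <- nrow(test_kernels[[1]])
  if (is.null(available)) available <- matrix(TRUE, m, p)
  available <- matrix(as.logical(available), m, p)
  # per-group margin contributions, weight-rescaled per availability row
  contrib <- vapply(test_kernels, function(B) {
    if (ncol(B) != n) stop_("cross-kernel block has wrong training dimension")
    as.vector(B %*% model$dual_coef)
  }, numeric(m))
  contrib <- matrix(contrib, nrow = m, ncol = p)
  w_avail <- available %*% diag(model$weights, p)   # row-masked weights
  denom <- rowSums(w_avail)
  phi <- ifelse(denom > 0,
                rowSums(w_avail * contrib) / ifelse(denom > 0, denom, 1) +
                  model$bias,
                NA_real_)
  as.vector(phi)
}

#' Predicted class labels
#'
#' `sign(phi)` with the documented tie-break: \eqn{\phi = 0} predicts
#' positive (the at-or-above convention). `NA` decision values propagate
#' as `NA` ("no prediction").
#'
#' @inheritParams decision_function
#' @return integer vector in `{+1, -1, NA}`.
#' @export
predict_labels <- function(model, test_kernels, available = NULL) {
  phi <- decision_function(model, test_kernels, available)
  ifelse(is.na(phi), NA_integer_, ifelse(phi >= 0, 1L, -1L))
}

#' @export
#' @rdname predict_labels
#' @param object an `mkl_model`.
#' @param features a [feature_group_set()] of new variants.
#' @param type `"decision"` for \eqn{\phi}, `"label"` for classes.
#' @param ... unused.
predict.mkl_model <- function(object, features,
                              type = c("decision", "label"), ...) {
  type <- match.arg(type)
  ck <- cross_kernels(object$kernels, features)
  if (type == "decision") decision_function(object, ck)
  else predict_labels(object, ck)
}

#' Select the SVM regularization constant by inner cross-validation
#'
#' Grid-searches `C` with stratified k-fold cross-validation on the
#' training kernels, selecting by mean AUC of the decision values
#' (largest `C` on ties is *not* used — ties go to the smallest, favoring
#' stronger regularization).
#'
#' @param kernels training `kernel_set`.
#' @param labels -1/+1 vector.
#' @param grid candidate values, default `c(0.01, 0.1, 1, 10, 100)`.
#' @param k inner folds (default 3).
#' @param seed fold-shuffle seed.
#' @return list with `C` (the selected value) and `auc` (mean AUC per
#'   grid point).
#' @export
tune_C <- function(kernels, labels, grid = c(0.01, 0.1, 1, 10, 100),
                   k = 3, seed = NULL) {
  folds <- kfold_cv(labels, k = k, stratified = TRUE, seed = seed)
  aucs <- vapply(grid, function(C) {
    mean(vapply(folds, function(f) {
      sub <- kernel_set_subset(kernels, f$train)
      m <- train_mkl(sub, labels[f$train], C = C)
      blocks <- lapply(kernels$matrices,
                       function(K) K[f$test, f$train, drop = FALSE])
      roc_auc(decision_function(m, blocks), labels[f$test])
    }, numeric(1)))
  }, numeric(1))
  list(C = grid[which.max(aucs)], auc = stats::setNames(aucs, grid))
}

# restrict a fitted kernel_set to a subset of its training rows
kernel_set_subset <- function(kernels, idx) {
  out <- kernels
  out$matrices <- lapply(kernels$matrices,
                         function(K) K[idx, idx, drop = FALSE])
  out$train_features <- lapply(kernels$train_features,
                               function(x) x[idx, , drop = FALSE])
  out$self_sim <- lapply(kernels$self_sim, function(d) d[idx])
  out
}
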