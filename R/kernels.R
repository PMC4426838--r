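# Base-kernel construction from feature groups, composite-kernel algebra
# and the missing-group kernel-weight rescaling rule.

#' Compute base kernels from feature-group matrices
#'
#' Per group: each feature column is standardized to zero mean and unit
#' variance on the supplied (training) rows, constant columns mapping to
#' zero; value-missing cells are imputed as 0 after standardization (i.e.
#' at the feature mean); the kernel is then built (`linear`: inner
#' products; `rbf`: \eqn{\exp(-\gamma \|x-y\|^2)} with \eqn{\gamma} from
#' the median heuristic unless supplied) and unit-diagonal normalized,
#' \eqn{K(i,j) \leftarrow K(i,j)/\sqrt{K(i,i)K(j,j)}} with 0/0 mapped to
#' 0, so that groups of very different dimensionality contribute on
#' comparable scales before weighting.
#'
#' @param features a [feature_group_set()]; no row may be group-missing in
#'   any retained group (the training path requires complete groups —
#'   see [assemble_training_set()]).
#' @param kind kernel form per group: `"linear"` (default) or `"rbf"`,
#'   recycled across groups.
#' @param gamma optional per-group RBF bandwidth(s); default median
#'   heuristic (`1 / median squared pairwise distance`).
#' @return a `kernel_set`: fields `names`, `matrices` (n x n, symmetric,
#'   positive semidefinite, unit diagonal), `kind`, `scalers` (per-group
#'   centers/scales), `train_features` (standardized, imputed training
#'   rows needed to kernelize new variants), `self_sim` (pre-normalization
#'   diagonal), `gamma`.
#' @export
compute_base_kernels <- function(features, kind = "linear", gamma = NULL) {
  stopifnot(inherits(features, "feature_group_set"))
  p <- length(features$group_names)
  kind <- rep_len(match.arg(kind, c("linear", "rbf"), several.ok = TRUE), p)
  if (!is.null(gamma)) gamma <- rep_len(gamma, p)
  if (any(features$group_missing))
    stop_("group-level missingness among training rows; filter with ",
          "assemble_training_set() first")
  out <- list(names = features$group_names, matrices = list(), kind = kind,
              scalers = list(), train_features = list(),
              self_sim = list(), gamma = numeric(p))
  for (g in seq_len(p)) {
    nm <- features$group_names[g]
    m <- features$matrices[[nm]]
    if (ncol(m) == 0L) stop_("feature group '", nm, "' has zero features")
    sc <- fit_scaler(m)
    x <- apply_scaler(m, sc)     # all-constant group -> all-zero kernel
    if (kind[g] == "linear") {
      K <- tcrossprod(x)
      out$gamma[g] <- NA_real_
    } else {
      d2 <- sq_dists(x, x)
      gm <- if (is.null(gamma)) median_heuristic(d2) else gamma[g]
      K <- exp(-gm * d2)
      out$gamma[g] <- gm
    }
    d <- diag(K)
    out$matrices[[nm]] <- normalize_unit_diag(K, d, d)
    out$scalers[[nm]] <- sc
    out$train_features[[nm]] <- x
    out$self_sim[[nm]] <- d
  }
  structure(out, class = "kernel_set")
}

fit_scaler <- function(m) {
  center <- colMeans(m, na.rm = TRUE)
  center[is.nan(center)] <- 0        # all-missing column
  s <- apply(m, 2, stats::sd, na.rm = TRUE)
  s[is.na(s) | s == 0] <- Inf        # constant column -> standardized to 0
  list(center = center, scale = s)
}

apply_scaler <- function(m, sc) {
  x <- sweep(sweep(m, 2, sc$center, "-"), 2, sc$scale, "/")
  x[is.na(x)] <- 0                   # mean-impute after standardization
  x
}

sq_dists <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

median_heuristic <- function(d2) {
  off <- d2[lower.tri(d2)]
  med <- stats::median(off[off > 0])
  if (!is.finite(med) || med == 0) 1 else 1 / med
}

normalize_unit_diag <- function(K, d_row, d_col) {
  denom <- sqrt(outer(d_row, d_col))
  out <- ifelse(denom > 0, K / ifelse(denom > 0, denom, 1), 0)
  if (length(d_row) == length(d_col) && isTRUE(all.equal(d_row, d_col)))
    out <- (out + t(out)) / 2        # keep exact symmetry
  out
}

#' @export
print.kernel_set <- function(x, ...) {
  cat("kernel_set:", length(x$names), "base kernels over",
      nrow(x$matrices[[1]]), "variants\n")
  for (g in seq_along(x$names))
    cat(sprintf("  %s: %s%s\n", x$names[g], x$kind[g],
                if (x$kind[g] == "rbf") sprintf(" (gamma=%.4g)", x$gamma[g])
                else ""))
  invisible(x)
}

#' Compose base kernels with simplex weights
#'
#' Returns the composite kernel \eqn{K = \sum_\ell \lambda_\ell K_\ell}.
#' With PSD base kernels and nonnegative weights the result is PSD.
#'
#' @param kernels a `kernel_set` (or plain list of equal-size square
#'   matrices).
#' @param weights numeric vector of kernel weights, one per base kernel.
#' @return the composite kernel matrix.
#' @export
compose_kernel <- function(kernels, weights) {
  mats <- if (inherits(kernels, "kernel_set")) kernels$matrices else kernels
  if (length(mats) != length(weights))
    stop_("got ", length(weights), " weights for ", length(mats), " kernels")
  K <- weights[1] * mats[[1]]
  for (g in seq_along(mats)[-1]) K <- K + weights[g] * mats[[g]]
  K
}

#' Validate simplex kernel weights
#'
#' @param lambda numeric vector; must be nonnegative and sum to 1 within
#'   `tol`.
#' @param tol tolerance on the simplex sum (default `1e-9`).
#' @return `lambda`, invisibly.
#' @export
check_kernel_weights <- function(lambda, tol = 1e-9) {
  if (any(lambda < 0))
    stop_("kernel weights must be nonnegative")
  if (abs(sum(lambda) - 1) > tol)
    stop_("kernel weights must sum to 1 (got ", format(sum(lambda)), ")")
  invisible(lambda)
}

#' Rescale kernel weights for missing feature groups
#'
#' At prediction time a variant may lack entire feature groups. Its
#' missing groups get weight 0 and the remaining weights are renormalized,
#' \eqn{\lambda'_\ell = \lambda_\ell / \sum_{\ell \in avail} \lambda_\ell},
#' so the effective weights again sum to 1. Idempotent.
#'
#' @param weights simplex weight vector (see [check_kernel_weights()]).
#' @param available logical mask, `TRUE` where the group has data.
#' @return rescaled weight vector of the same length.
#'   When no available group carries positive weight, no prediction is
#'   possible and an error of class `mklvariant_no_prediction` is signaled.
#' @examples
#' rescale_weights(c(0.71, 0.26, 0.004, 0.03), c(TRUE, TRUE, TRUE, FALSE))
#' @export
rescale_weights <- function(weights, available) {
  # published weight vectors are printed rounded, so tolerate a simplex
  # defect up to typical rounding error before renormalizing
  check_kernel_weights(weights, tol = 0.05)
  stopifnot(length(available) == length(weights))
  w <- ifelse(available, weights, 0)
  s <- sum(w)
  if (s <= 0)
    stop_("no prediction possible: no available feature group with ",
          "positive kernel weight", class = "mklvariant_no_prediction")
  w / s
}

#' Cross kernels between new variants and a fitted kernel set
#'
#' Standardizes the new variants' features with the scalers captured at
#' training, imputes value-missing cells as 0, and computes the
#' `new x train` kernel block for every group under the same functional
#' form and unit-diagonal normalization as training. Rows that are
#' group-missing yield zero rows in that group's block; their availability
#' is reported in the mask.
#'
#' @param kernels a fitted `kernel_set`.
#' @param features a [feature_group_set()] for the new variants, with the
#'   same group names.
#' @return list with `blocks` (per-group `m x n` matrices) and `available`
#'   (`m x p` logical mask).
#' @export
cross_kernels <- function(kernels, features) {
  stopifnot(inherits(kernels, "kernel_set"),
            inherits(features, "feature_group_set"))
  miss <- setdiff(kernels$names, features$group_names)
  if (length(miss))
    stop_("feature groups absent from new data: ", paste(miss, collapse = ", "))
  blocks <- list()
  for (g in seq_along(kernels$names)) {
    nm <- kernels$names[g]
    x <- apply_scaler(features$matrices[[nm]], kernels$scalers[[nm]])
    if (kernels$kind[g] == "linear") {
      K <- tcrossprod(x, kernels$train_features[[nm]])
      K <- normalize_unit_diag(K, rowSums(x^2), kernels$self_sim[[nm]])
    } else {
      K <- exp(-kernels$gamma[g] * sq_dists(x, kernels$train_features[[nm]]))
    }
    K[features$group_missing[, nm], ] <- 0
    blocks[[nm]] <- K
  }
  list(blocks = blocks,
       available = !features$group_missing[, kernels$names, drop = FALSE])
}
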