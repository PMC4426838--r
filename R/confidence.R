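# Platt sigmoid calibration of SVM decision values into posterior
# probabilities, and cautious classification (reject option) at
# confidence cutoffs.

#' Fit a Platt sigmoid to decision values
#'
#' Maps decision values \eqn{\phi} to posterior probabilities
#' \eqn{P(y=1|\phi) = 1/(1+\exp(a\phi+b))} by minimizing the
#' cross-entropy against Platt's smoothed targets
#' \eqn{t_+ = (N_+ + 1)/(N_+ + 2)} and \eqn{t_- = 1/(N_- + 2)}
#' (the +1/+2 smoothing acts as a uniform prior and regularizes the fit).
#' Optimization is a damped Newton iteration with backtracking on the
#' (strictly convex) objective; the result is deterministic for fixed
#' input. When positives have larger \eqn{\phi} than negatives on
#' average, the fitted slope `a` is negative, so `P` increases with
#' \eqn{\phi}.
#'
#' Calibrate on out-of-fold decision values (see [mkl_cv()]), never on
#' the \eqn{\phi} of the very examples the SVM was trained on, to avoid
#' overconfident posteriors.
#'
#' @param phi numeric decision values.
#' @param labels -1/+1 vector, both classes present.
#' @param max_iter Newton iteration cap (default 200).
#' @param tol gradient max-norm convergence tolerance (default `1e-6`);
#'   a line search stalled at machine precision also counts as
#'   converged, since the convex objective cannot be improved further
#'   in double precision.
#' @return a `platt_calibrator` with fields `a`, `b`, `n_iter`,
#'   `converged`. Non-convergence signals an error of class
#'   `mklvariant_platt_error` carrying the last iterate in its `data`.
#' @export
fit_platt <- function(phi, labels, max_iter = 200, tol = 1e-6) {
  stopifnot(length(phi) == length(labels), all(labels %in% c(-1, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L)
    stop_("both classes must be present to fit the sigmoid")
  t_i <- ifelse(labels == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  # objective F(a,b) = -sum t_i log p_i + (1-t_i) log(1-p_i),
  # p_i = 1/(1+exp(a phi_i + b)); numerically safe via log1p
  nll <- function(a, b) {
    z <- a * phi + b
    sum(ifelse(z >= 0, t_i * z + log1p(exp(-z)), (t_i - 1) * z + log1p(exp(z))))
  }
  a <- 0
  b <- log((n_neg + 1) / (n_pos + 1))
  fval <- nll(a, b)
  converged <- FALSE
  it <- 0L
  sigma <- 1e-12
  while (it < max_iter) {
    it <- it + 1L
    p <- stats::plogis(-(a * phi + b))
    d1 <- t_i - p                    # dF/dz per point
    g <- c(sum(d1 * phi), sum(d1))
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- p * (1 - p)
    H <- matrix(c(sum(w * phi^2) + sigma, sum(w * phi),
                  sum(w * phi), sum(w) + sigma), 2, 2)
    step <- -solve(H, g)
    # backtracking line search on the convex objective
    t_step <- 1
    stalled <- FALSE
    repeat {
      a_new <- a + t_step * step[1]
      b_new <- b + t_step * step[2]
      f_new <- nll(a_new, b_new)
      if (f_new < fval + 1e-4 * t_step * sum(g * step)) break
      t_step <- t_step / 2
      if (t_step < 1e-12) { stalled <- TRUE; break }
    }
    if (stalled) { converged <- TRUE; break }
    a <- a_new; b <- b_new; fval <- f_new
  }
  cal <- structure(list(a = a, b = b, n_iter = it, converged = converged),
                   class = "platt_calibrator")
  if (!converged)
    stop(structure(class = c("mklvariant_platt_error", "mklvariant_error",
                             "error", "condition"),
                   list(message = paste0("Platt fit did not converge in ",
                                         max_iter, " iterations"),
                        call = sys.call(), data = cal)))
  cal
}

#' @export
print.platt_calibrator <- function(x, ...) {
  cat(sprintf("platt_calibrator: P(y=1|phi) = 1/(1+exp(%.4g*phi + %.4g))\n",
              x$a, x$b))
  invisible(x)
}

#' Posterior probability of a pathogenic outcome
#'
#' Evaluates \eqn{P(y=1|\phi) = 1/(1+\exp(a\phi+b))} overflow-safely.
#'
#' @param cal a `platt_calibrator`.
#' @param phi decision value(s); `NA` propagates.
#' @return probabilities in (0, 1).
#' @export
posterior <- function(cal, phi) {
  stopifnot(inherits(cal, "platt_calibrator"))
  stats::plogis(-(cal$a * phi + cal$b))
}

#' Assemble per-variant prediction records
#'
#' @param keys variant keys (see [variant_keys()]).
#' @param phi decision values (`NA` = no prediction).
#' @param cal a `platt_calibrator`.
#' @param groups_used optional logical availability matrix (variants x
#'   groups).
#' @return data.frame with columns `key`, `phi`, `posterior`,
#'   `predicted` (+1/-1/NA, tie at `phi = 0` predicting positive),
#'   `confidence` (`max(P, 1-P)`, in `[0.5, 1]`) and `groups_used`
#'   (comma-separated group names).
#' @export
prediction_records <- function(keys, phi, cal, groups_used = NULL) {
  post <- posterior(cal, phi)
  gu <- if (is.null(groups_used)) NA_character_
        else apply(groups_used, 1, function(a)
          paste(colnames(groups_used)[a], collapse = ","))
  data.frame(key = keys, phi = phi, posterior = post,
             predicted = ifelse(is.na(phi), NA_integer_,
                                ifelse(phi >= 0, 1L, -1L)),
             confidence = pmax(post, 1 - post),
             groups_used = gu, stringsAsFactors = FALSE)
}

#' Cautious classification: restrict predictions to confident records
#'
#' Splits prediction records at a confidence cutoff: records with
#' `confidence >= cutoff` (inclusive) are kept, the rest abstain.
#' Restricting to high-confidence predictions trades coverage (the kept
#' fraction) for accuracy.
#'
#' @param records data.frame from [prediction_records()] (needs a
#'   `confidence` column; `NA` confidence always abstains).
#' @param cutoff confidence threshold in `[0.5, 1]`.
#' @return list with `kept`, `abstained` (row subsets) and `coverage`
#'   (= kept / total).
#' @export
cautious_subset <- function(records, cutoff) {
  stopifnot(cutoff >= 0.5, cutoff <= 1)
  keep <- !is.na(records$confidence) & records$confidence >= cutoff
  list(kept = records[keep, , drop = FALSE],
       abstained = records[!keep, , drop = FALSE],
       coverage = if (nrow(records)) sum(keep) / nrow(records) else NA_real_)
}
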