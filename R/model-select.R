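# multivariate normal helpers (chol-based; avoids an extra dependency)
.dmvnorm_log <- function(X, mean, cholS) {
  d <- length(mean)
  Y <- forwardsolve(t(cholS), t(X) - mean)
  -0.5 * colSums(Y^2) - sum(log(diag(cholS))) - d / 2 * log(2 * pi)
}
.rmvnorm <- function(n, mean, cholS) {
  d <- length(mean)
  t(mean + t(cholS) %*% matrix(stats::rnorm(n * d), d, n))
}

#' Bridge-sampling estimate of the log marginal likelihood
#'
#' Implements the Meng-Wong optimal-bridge fixed-point recursion from
#' scratch: posterior draws on the unconstrained scale are split in half,
#' the first half fits a moment-matched multivariate-normal proposal, and
#' the second half plus fresh proposal draws drive the iteration for the
#' evidence.  The supplied `log_post` must be the *normalized-prior*
#' unnormalized posterior (log prior + log likelihood + transform
#' Jacobians), as produced by [fit_group()], so that its integral is the
#' marginal likelihood.
#'
#' @param fit a converged `posterior_fit`, or any list with elements
#'   `draws_z` (matrix of unconstrained draws) and `log_post` (function of
#'   one unconstrained parameter vector).
#' @param n_boot bootstrap resamples used for the Monte-Carlo SE.
#' @param tol relative convergence tolerance of the fixed-point iteration.
#' @param max_iter iteration cap.
#' @param seed optional seed for the proposal draws.
#' @param label model label carried into the result.
#' @return A `model_evidence` list: `logml`, `se`, `label`, `n_iter`.
#' @export
log_marginal_likelihood <- function(fit, n_boot = 20, tol = 1e-10,
                                    max_iter = 1000, seed = NULL,
                                    label = NULL) {
  if (inherits(fit, "posterior_fit") && !fit$converged)
    stop("refusing model selection on a non-converged fit")
  Z <- fit$draws_z
  stopifnot(is.matrix(Z), nrow(Z) >= 20)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(label))
    label <- if (!is.null(fit$model)) paste0("model", fit$model) else "model"

  n <- nrow(Z)
  first <- seq_len(floor(n / 2))
  Zfit <- Z[first, , drop = FALSE]
  Zest <- Z[-first, , drop = FALSE]
  m <- colMeans(Zfit)
  S <- stats::cov(Zfit)
  cholS <- chol(S + diag(1e-10, ncol(Z)))

  n2 <- nrow(Zest)
  Zprop <- .rmvnorm(n2, m, cholS)
  lpost_vec <- function(M) apply(M, 1, fit$log_post)
  l1 <- lpost_vec(Zest) - .dmvnorm_log(Zest, m, cholS)   # posterior side
  l2 <- lpost_vec(Zprop) - .dmvnorm_log(Zprop, m, cholS) # proposal side
  if (all(!is.finite(l2)))
    stop("bridge sampling failed: proposal and posterior do not overlap")
  l2[!is.finite(l2)] <- -Inf

  run_bridge <- function(l1, l2) {
    n1 <- length(l1); n2 <- length(l2)
    s1 <- n1 / (n1 + n2); s2 <- n2 / (n1 + n2)
    lstar <- stats::median(l1)
    e2 <- exp(l2 - lstar)
    f1 <- exp(l1 - lstar)
    r <- 1
    for (it in seq_len(max_iter)) {
      num <- mean(e2 / (s1 * e2 + s2 * r))
      den <- mean(1 / (s1 * f1 + s2 * r))
      r_new <- num / den
      if (!is.finite(r_new) || r_new <= 0)
        stop("bridge iteration degenerated (all weights collapsed)")
      if (abs(r_new - r) / r < tol) {
        return(list(logml = lstar + log(r_new), n_iter = it))
      }
      r <- r_new
    }
    warning("bridge iteration hit max_iter without meeting tol")
    list(logml = lstar + log(r), n_iter = max_iter)
  }

  est <- run_bridge(l1, l2)
  boots <- vapply(seq_len(n_boot), function(i) {
    run_bridge(sample(l1, replace = TRUE), sample(l2, replace = TRUE))$logml
  }, numeric(1))
  structure(list(logml = est$logml, se = stats::sd(boots),
                 label = label, n_iter = est$n_iter),
            class = "model_evidence")
}

#' @export
print.model_evidence <- function(x, ...) {
  cat(sprintf("log marginal likelihood [%s] = %.4f (MC SE %.4f)\n",
              x$label, x$logml, x$se))
  invisible(x)
}

#' Bayes factor comparing two model evidences
#'
#' `BF = exp(logml2 - logml1)` for the state-transition model (numerator)
#' against the recovery-only model (denominator); `BF > 3` is read as
#' positive evidence for a state transition (Kass & Raftery).
#'
#' @param ev2,ev1 `model_evidence` objects (or lists with `logml`).
#' @return A `bf_result` list: `bf`, `log_bf`, `label`.
#' @export
bayes_factor <- function(ev2, ev1) {
  stopifnot(is.finite(ev2$logml), is.finite(ev1$logml))
  log_bf <- ev2$logml - ev1$logml
  structure(list(bf = exp(log_bf), log_bf = log_bf,
                 label = if (exp(log_bf) > 3) "positive evidence"
                         else "no positive evidence"),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF (state transition vs recovery-only) = %.3g [%s]\n",
              x$bf, x$label))
  invisible(x)
}
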