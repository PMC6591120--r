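#' Generalized Lotka-Volterra system
#'
#' `dx_i/dt = x_i (r_i + sum_j a_ij x_j)` with self-limitation
#' (`a_ii < 0`).
#'
#' @param r numeric vector of intrinsic growth rates.
#' @param A square interaction matrix; diagonal entries must be negative.
#' @return A `glv_system` list.
#' @export
glv_system <- function(r, A) {
  A <- as.matrix(A)
  stopifnot(length(r) >= 1, nrow(A) == length(r), ncol(A) == length(r),
            all(is.finite(r)), all(is.finite(A)))
  if (any(diag(A) >= 0)) stop("self-limitation required: all a_ii < 0")
  structure(list(r = as.numeric(r), A = A, n = length(r)),
            class = "glv_system")
}

.glv_deriv <- function(sys, x) x * (sys$r + drop(sys$A %*% x))

# fixed-step RK4 with blow-up guard; returns final state or NULL if the
# trajectory diverges (unbounded system)
.glv_integrate <- function(sys, x0, t_max = 500, h = 0.02, blow_up = 1e6) {
  x <- pmax(x0, 0)
  steps <- ceiling(t_max / h)
  check_every <- 50L
  for (i in seq_len(steps)) {
    k1 <- .glv_deriv(sys, x)
    k2 <- .glv_deriv(sys, pmax(x + h / 2 * k1, 0))
    k3 <- .glv_deriv(sys, pmax(x + h / 2 * k2, 0))
    k4 <- .glv_deriv(sys, pmax(x + h * k3, 0))
    x_new <- pmax(x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    if (any(!is.finite(x_new)) || any(x_new > blow_up)) return(NULL)
    if (i %% check_every == 0 && max(abs(x_new - x)) < 1e-12 * h) {
      return(x_new)
    }
    x <- x_new
  }
  x
}

#' Shannon diversity of a community state
#'
#' `H = -sum p_i log p_i` over relative abundances of the species present
#' (abundance > tol); extinct species contribute nothing.  The all-extinct
#' state has H = 0.
#'
#' @param x abundance vector.
#' @param tol presence threshold.
#' @return Shannon index (nats).
#' @export
shannon_diversity <- function(x, tol = 1e-9) {
  x <- x[x > tol]
  if (length(x) == 0) return(0)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' All non-negative fixed points of a small GLV system
#'
#' Enumerates every support subset (2^n, n <= 4), solves the linear
#' subsystem `A[S,S] x_S = -r[S]`, keeps solutions with strictly positive
#' support abundances, and classifies stability from the Jacobian
#' `J_ij = delta_ij (r_i + (Ax)_i) + x_i a_ij`: strictly negative maximum
#' real eigenvalue (< -1e-8) is `stable`, > 1e-8 `unstable`, otherwise
#' `marginal` (excluded from the stable count downstream).
#'
#' @param sys a [glv_system()].
#' @param tol duplicate-merging tolerance.
#' @return data.frame: one row per equilibrium with columns `x1..xn`,
#'   `stability`, `max_re_eig`, `diversity` (Shannon), `n_present`.
#' @export
find_fixed_points <- function(sys, tol = 1e-9) {
  stopifnot(inherits(sys, "glv_system"))
  if (sys$n > 4) stop("exhaustive support enumeration limited to n <= 4")
  n <- sys$n
  pts <- list(rep(0, n))
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    AS <- sys$A[S, S, drop = FALSE]
    xs <- tryCatch(solve(AS, -sys$r[S]), error = function(e) NULL)
    if (is.null(xs) || any(!is.finite(xs)) || any(xs <= tol)) next
    x <- rep(0, n)
    x[S] <- xs
    pts[[length(pts) + 1]] <- x
  }
  # merge duplicates (numerically identical equilibria from different masks)
  keep <- list()
  for (x in pts) {
    dup <- any(vapply(keep, function(y) max(abs(x - y)) < tol, logical(1)))
    if (!dup) keep[[length(keep) + 1]] <- x
  }
  res <- lapply(keep, function(x) {
    growth <- sys$r + drop(sys$A %*% x)
    J <- diag(growth, n) + x * sys$A
    ev <- max(Re(eigen(J, only.values = TRUE)$values))
    stability <- if (ev < -1e-8) "stable" else if (ev > 1e-8) "unstable"
                 else "marginal"
    c(x, ev = ev, div = shannon_diversity(x), np = sum(x > tol),
      stab = match(stability, c("stable", "unstable", "marginal")))
  })
  res <- do.call(rbind, res)
  out <- as.data.frame(res[, seq_len(n), drop = FALSE])
  names(out) <- paste0("x", seq_len(n))
  out$stability <- c("stable", "unstable", "marginal")[res[, "stab"]]
  out$max_re_eig <- res[, "ev"]
  out$diversity <- res[, "div"]
  out$n_present <- as.integer(res[, "np"])
  out
}

#' Does a system exhibit the two-state behaviour of the landscape model?
#'
#' TRUE iff (i) at least two distinct stable non-negative equilibria
#' exist, (ii) two of them differ in Shannon diversity by more than
#' `div_tol`, and (iii) an abundance-reducing instantaneous perturbation
#' applied to the highest-diversity stable state can carry the system into
#' the basin of a different stable state (verified by numerical
#' integration from a small library of knockdown/scaling perturbations).
#' Systems with diverging trajectories are flagged unbounded and return
#' FALSE.
#'
#' @param sys a [glv_system()].
#' @param fp optional precomputed [find_fixed_points()] result.
#' @param div_tol minimum diversity difference between the two states.
#' @param t_max integration horizon for the basin test.
#' @return logical with attribute `unbounded` (TRUE if a trajectory
#'   diverged).
#' @export
classify_two_state <- function(sys, fp = NULL, div_tol = 1e-6, t_max = 300) {
  if (is.null(fp)) fp <- find_fixed_points(sys)
  n <- sys$n
  stable <- fp[fp$stability == "stable", , drop = FALSE]
  ans <- function(v, unbounded = FALSE) structure(v, unbounded = unbounded)
  if (nrow(stable) < 2) return(ans(FALSE))
  if (diff(range(stable$diversity)) <= div_tol) return(ans(FALSE))
  stable <- stable[order(-stable$diversity), , drop = FALSE]
  x_hi <- as.numeric(stable[1, seq_len(n)])
  others <- as.matrix(stable[-1, seq_len(n), drop = FALSE])
  div_hi <- stable$diversity[1]

  # perturbation library: uniform scalings and species knockdowns, all
  # abundance-reducing
  perts <- list()
  for (f in c(0.5, 0.1, 0.01)) perts[[length(perts) + 1]] <- x_hi * f
  for (mask in seq_len(2^n - 1)) {
    S <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    x0 <- x_hi
    x0[S] <- x0[S] * 0.01
    perts[[length(perts) + 1]] <- x0
  }
  saw_unbounded <- FALSE
  for (x0 in perts) {
    xf <- .glv_integrate(sys, x0, t_max = t_max)
    if (is.null(xf)) { saw_unbounded <- TRUE; next }
    reached <- apply(others, 1, function(y) max(abs(xf - y)) < 1e-4)
    if (any(reached) &&
        abs(shannon_diversity(xf) - div_hi) > div_tol)
      return(ans(TRUE, saw_unbounded))
  }
  ans(FALSE, saw_unbounded)
}

#' Grid specification for the GLV sweep
#'
#' Free parameters are the `n` growth rates and the `n(n-1)` off-diagonal
#' interactions (9 for n = 3, matching a 5^9 full grid); `a_ii` is fixed
#' at -1.
#'
#' @param values candidate values each free parameter ranges over: either
#'   one numeric vector shared by all free parameters, or a list of
#'   `n + n(n-1)` vectors (growth rates first, then off-diagonal
#'   interactions in column-minor order).
#' @param n number of species.
#' @return A `glv_grid` list with the number of cells.
#' @export
glv_grid <- function(values = c(-1, -0.5, 0, 0.5, 1), n = 3) {
  k <- n + n * (n - 1)
  if (!is.list(values)) values <- rep(list(values), k)
  stopifnot(n >= 1, length(values) == k,
            all(vapply(values, length, integer(1)) >= 1))
  structure(list(values = values, n = n, n_free = k,
                 n_cells = prod(vapply(values, length, integer(1)))),
            class = "glv_grid")
}

# decode a 0-based cell index into a glv_system
.grid_system <- function(grid, cell) {
  k <- grid$n_free
  par <- numeric(k)
  for (j in seq_len(k)) {
    nv <- length(grid$values[[j]])
    par[j] <- grid$values[[j]][cell %% nv + 1L]
    cell <- cell %/% nv
  }
  n <- grid$n
  r <- par[seq_len(n)]
  A <- diag(-1, n)
  A[row(A) != col(A)] <- par[(n + 1):k]
  glv_system(r, A)
}

#' Sweep a GLV parameter grid for two-state systems
#'
#' Classifies each (sub)sampled grid cell with [classify_two_state()] and
#' reports the fraction exhibiting two-state behaviour.  The full default
#' grid has 5^9 = 1,953,125 cells; `n_sample` draws a uniform random
#' subsample for desk-scale runs.
#'
#' @param grid a [glv_grid()].
#' @param n_sample number of cells to sample (`NULL` = full grid; avoid
#'   for the default grid size).
#' @param seed integer seed for the subsample.
#' @param keep_records return the per-cell records (set FALSE to save
#'   memory on big sweeps).
#' @return list: `fraction` of two-state systems, `n_evaluated`,
#'   `n_two_state`, `n_unbounded`, and (optionally) `records` data.frame
#'   with `cell`, `n_stable`, `two_state`, `unbounded`.
#' @export
sweep_glv <- function(grid = glv_grid(), n_sample = 10000, seed = 1L,
                      keep_records = TRUE) {
  stopifnot(inherits(grid, "glv_grid"))
  if (is.null(n_sample) || n_sample >= grid$n_cells) {
    cells <- seq_len(grid$n_cells) - 1
  } else {
    set.seed(seed)
    cells <- sample(grid$n_cells, n_sample) - 1
  }
  two <- logical(length(cells))
  unb <- logical(length(cells))
  nst <- integer(length(cells))
  for (i in seq_along(cells)) {
    sys <- .grid_system(grid, cells[i])
    fp <- find_fixed_points(sys)
    nst[i] <- sum(fp$stability == "stable")
    cls <- classify_two_state(sys, fp)
    two[i] <- as.logical(cls)
    unb[i] <- isTRUE(attr(cls, "unbounded"))
  }
  out <- list(fraction = mean(two), n_evaluated = length(cells),
              n_two_state = sum(two), n_unbounded = sum(unb))
  if (keep_records)
    out$records <- data.frame(cell = cells, n_stable = nst,
                              two_state = two, unbounded = unb)
  out
}
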