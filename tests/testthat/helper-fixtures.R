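# shared fixtures: built in code at test time, no stored data

toy_tree <- function() ape::read.tree(text = "((A:1,B:2):1,C:3):0;")

# single-group archetype designs
one_group_design <- function(group = "clindamycin", site = "gut", n = 9,
                             D = 8.45, A = 0.84, phi1 = 0, phi2 = 0.56,
                             sigma = 0.4, seed = 1L, ...) {
  study_design(groups = data.frame(group = group, site = site, n = n,
                                   D = D, A = A, phi1 = phi1, phi2 = phi2,
                                   stringsAsFactors = FALSE),
               sigma = sigma, seed = seed, ...)
}

# cheap MCMC protocol for tests that do not assert the convergence
# contract (determinism, shapes, error paths)
fast_mcmc <- function(seed = 1L) {
  mcmc_config(chains = 2, burnin = 200, iter = 800, seed = seed,
              substeps = 2)
}

# draws uniformly from the prior box of (D, phi1, phi2)
draw_prior_box <- function(n, priors = prior_spec()) {
  data.frame(D = runif(n, priors$D[1], priors$D[2]),
             phi1 = runif(n, priors$phi1[1], priors$phi1[2]),
             phi2 = runif(n, priors$phi2[1], priors$phi2[2]))
}

# conjugate toy for the evidence oracle: y_i ~ N(mu, 1), mu ~ N(0, 1)
normal_normal_logml <- function(y) {
  n <- length(y)
  -n / 2 * log(2 * pi) - 0.5 * log(n + 1) -
    0.5 * (sum(y^2) - sum(y)^2 / (n + 1))
}

# iid draws from the exact conjugate posterior stand in for MCMC output
normal_normal_fit <- function(y, n_draws = 4000, seed = 1) {
  set.seed(seed)
  n <- length(y)
  list(draws_z = matrix(rnorm(n_draws, sum(y) / (n + 1), sqrt(1 / (n + 1))),
                        ncol = 1),
       log_post = function(z)
         dnorm(z[1], 0, 1, log = TRUE) + sum(dnorm(y, z[1], 1, log = TRUE)))
}

# a 3-species system with nested-support bistability (stable interior
# coexistence state, diversity 0.77, plus a stable single-species state),
# found by random search over competitive parameters; frozen here as the
# canonical two-state example
TWO_STATE_R <- c(0.8747, 0.4199, 0.8565)
TWO_STATE_A <- rbind(c(-1.0000, -1.5586, -1.1747),
                     c(-0.3071, -1.0000, -1.4919),
                     c(-1.2242, -1.0120, -1.0000))
two_state_system <- function() glv_system(TWO_STATE_R, TWO_STATE_A)
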