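test_that("logistic one-species system has the textbook equilibria", {
  fp <- find_fixed_points(glv_system(1, matrix(-1, 1, 1)))
  fp <- fp[order(fp$x1), ]
  expect_equal(fp$x1, c(0, 1))
  expect_identical(fp$stability, c("unstable", "stable"))
  expect_equal(fp$max_re_eig, c(1, -1))
})

test_that("symmetric 2-species competition is founder-controlled", {
  sys <- glv_system(c(1, 1), matrix(c(-1, -1.5, -1.5, -1), 2, 2))
  fp <- find_fixed_points(sys)
  st <- fp[fp$stability == "stable", ]
  expect_equal(nrow(st), 2)
  expect_equal(sort(st$x1 + st$x2), c(1, 1))  # the two single-species states
  # analytic Jacobian eigenvalues: boundary (-1, -0.5), coexistence max 0.2
  expect_equal(sort(st$max_re_eig), c(-0.5, -0.5))
  co <- fp[fp$n_present == 2, ]
  expect_equal(unlist(co[, c("x1", "x2")]), c(x1 = 0.4, x2 = 0.4))
  expect_identical(co$stability, "unstable")
  expect_equal(co$max_re_eig, 0.2)
  # perfectly symmetric pair: equal diversity, so not two-state
  expect_false(as.logical(classify_two_state(sys)))
})

test_that("equilibrium residuals vanish and labels match eigenvalues", {
  set.seed(33)
  for (i in 1:10) {
    sys <- glv_system(runif(3, -1, 1),
                      {A <- matrix(runif(9, -1.5, 0.5), 3, 3)
                       diag(A) <- -runif(3, 0.5, 1.5); A})
    fp <- find_fixed_points(sys)
    for (j in seq_len(nrow(fp))) {
      x <- as.numeric(fp[j, 1:3])
      resid <- x * (sys$r + drop(sys$A %*% x))
      expect_lt(max(abs(resid)), 1e-8)
      expect_identical(fp$stability[j],
                       if (fp$max_re_eig[j] < -1e-8) "stable"
                       else if (fp$max_re_eig[j] > 1e-8) "unstable"
                       else "marginal")
    }
  }
})

test_that("stable states attract under 1% multiplicative noise", {
  set.seed(44)
  checked <- 0
  while (checked < 10) {
    sys <- glv_system(runif(3, 0.2, 1),
                      {A <- -matrix(runif(9, 0, 1.2), 3, 3)
                       diag(A) <- -1; A})
    fp <- find_fixed_points(sys)
    st <- fp[fp$stability == "stable" & fp$n_present > 0, ]
    if (nrow(st) == 0) next
    x0 <- as.numeric(st[1, 1:3])
    xp <- x0 * (1 + rnorm(3, 0, 0.01) * (x0 > 0))
    xf <- mbimpulse:::.glv_integrate(sys, xp, t_max = 300)
    expect_lt(max(abs(xf - x0)), 1e-4)
    checked <- checked + 1
  }
})

test_that("two-state classification on the frozen bistable system", {
  sys <- two_state_system()
  fp <- find_fixed_points(sys)
  st <- fp[fp$stability == "stable", ]
  expect_equal(nrow(st), 2)
  expect_true(any(st$n_present == 3))     # stable coexistence
  expect_true(any(st$n_present == 1))     # stable single-species state
  expect_gt(diff(range(st$diversity)), 0.5)
  expect_true(as.logical(classify_two_state(sys, fp)))
  # invariant under species relabelling
  perm <- c(2, 3, 1)
  sys_p <- glv_system(TWO_STATE_R[perm], TWO_STATE_A[perm, perm])
  expect_true(as.logical(classify_two_state(sys_p)))
  # single stable point is never two-state
  expect_false(as.logical(classify_two_state(glv_system(1, matrix(-1, 1, 1)))))
})

test_that("mutualistic blow-up is caught by the integration guard", {
  sys <- glv_system(c(1, 1), matrix(c(-0.1, 1, 1, -0.1), 2, 2))
  expect_null(mbimpulse:::.glv_integrate(sys, c(5, 5), t_max = 100))
})

test_that("degenerate singular supports are skipped", {
  # species 2 is a neutral clone of species 1's dynamics on the shared
  # support: the 2-species subsystem is singular and yields no isolated
  # equilibrium
  sys <- glv_system(c(1, 1), matrix(c(-1, -1, -1, -1), 2, 2))
  fp <- find_fixed_points(sys)
  expect_false(any(fp$n_present == 2))
})

test_that("sweep handles degenerate one-cell grids", {
  vals <- as.list(c(TWO_STATE_R, TWO_STATE_A[row(TWO_STATE_A) !=
                                             col(TWO_STATE_A)]))
  g1 <- glv_grid(values = vals, n = 3)
  expect_equal(g1$n_cells, 1)
  expect_equal(sweep_glv(g1, n_sample = NULL)$fraction, 1)
  g0 <- glv_grid(values = as.list(c(1, 1, 1, rep(0, 6))), n = 3)
  res0 <- sweep_glv(g0, n_sample = NULL)
  expect_equal(res0$fraction, 0)
  expect_equal(res0$records$n_stable, 1)  # logistic-like: one stable point
})

test_that("default grid has 5^9 cells and decodes correctly", {
  g <- glv_grid()
  expect_equal(g$n_cells, 5^9)
  sys0 <- mbimpulse:::.grid_system(g, 0)
  expect_equal(sys0$r, rep(-1, 3))
  expect_equal(diag(sys0$A), rep(-1, 3))
  expect_equal(sys0$A[row(sys0$A) != col(sys0$A)], rep(-1, 6))
  sys_last <- mbimpulse:::.grid_system(g, 5^9 - 1)
  expect_equal(sys_last$r, rep(1, 3))
  expect_equal(sys_last$A[row(sys_last$A) != col(sys_last$A)], rep(1, 6))
})
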