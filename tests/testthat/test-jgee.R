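test_that("gaussian identity fit with independence equals least squares", {
  set.seed(10)
  d <- unrelated_fds(200, K = 1, kind = "continuous")
  fit <- jgee_null(d, "independence", "independence")
  ols <- lm.fit(d$X, d$Y[, 1])$coefficients
  expect_equal(unname(fit$alpha[, 1]), unname(ols), tolerance = 1e-8)
  expect_true(fit$converged)

  # K = 2 with independence structures: trait-wise least squares
  d2 <- quick_trio_study(50, "continuous")
  fit2 <- jgee_null(d2, "independence", "independence")
  for (k in 1:2)
    expect_equal(unname(fit2$alpha[, k]),
                 unname(lm.fit(d2$X, d2$Y[, k])$coefficients),
                 tolerance = 1e-8)
})

test_that("intercept-only logit fit recovers the log-odds of prevalence", {
  set.seed(11)
  n <- 300
  Y <- matrix(rbinom(n, 1, 0.27), n, 1)
  d <- famkat:::fds_stacked(Y, matrix(1, n, 1), NULL, rep(1L, n), "binary")
  fit <- jgee_null(d, "independence", "independence")
  pbar <- mean(Y)
  expect_equal(fit$alpha[1, 1], log(pbar / (1 - pbar)), tolerance = 1e-6)
  expect_equal(fit$phi, 1)
})

test_that("working covariance matches the hand-expanded Kronecker product", {
  set.seed(12)
  d <- quick_trio_study(30, "continuous")
  fit <- jgee_null(d, "exchangeable", "exchangeable")
  rho <- fit$R_n[1, 2]; gam <- fit$R_K[1, 2]; phi <- fit$phi
  V <- working_covariance(fit, 5)
  n <- 3
  # gaussian: A = 1, layout trait-major, entries {1, rho, gam, gam*rho}*phi
  for (j in 1:n) for (j2 in 1:n) for (k in 1:2) for (k2 in 1:2) {
    expected <- phi * (if (k == k2) 1 else gam) * (if (j == j2) 1 else rho) *
      (if (k == k2 && j == j2) 1 else 1)
    expect_equal(V[(k - 1) * n + j, (k2 - 1) * n + j2], expected,
                 tolerance = 1e-12)
  }

  # binary at mu ~ 0.5 with independence: V ~ mu(1-mu) * I
  Yb <- matrix(rbinom(40, 1, 0.5), 20, 2)
  db <- famkat:::fds_stacked(Yb, matrix(1, 20, 1), NULL, rep(2L, 10),
                             rep("binary", 2))
  fb <- jgee_null(db, "independence", "independence")
  Vb <- working_covariance(fb, 1)
  mu <- fb$mu[1, ]
  expect_equal(diag(Vb), rep(mu * (1 - mu), each = 2), tolerance = 1e-10)
  expect_equal(Vb[1, 2], 0)
})

test_that("standardized residuals solve V S = y - mu", {
  set.seed(13)
  d <- quick_trio_study(40, "continuous")
  fit <- jgee_null(d, "exchangeable", "unstructured")
  for (i in c(1, 17, 40)) {
    V <- working_covariance(fit, i)
    rows <- fit$fam_index == i
    r <- as.vector(d$Y[rows, ] - fit$mu[rows, ])
    S <- as.vector(fit$S[rows, ])
    expect_lt(max(abs(V %*% S - r)), 1e-10)
  }
  blocks <- standardized_residuals(fit)
  expect_length(blocks, 40)
  expect_equal(blocks[[17]], fit$S[fit$fam_index == 17, , drop = FALSE])
})

test_that("the GEE estimating equation is solved at convergence", {
  set.seed(14)
  for (kind in c("continuous", "binary")) {
    d <- quick_trio_study(80, kind)
    fit <- jgee_null(d, "exchangeable", "exchangeable", tol = 1e-8)
    expect_true(fit$converged)
    # estimating function in alpha units: one further Fisher-scoring step
    # must move alpha by less than 10x the convergence tolerance
    U <- fit$A * fit$S
    score <- as.vector(vapply(seq_len(d$K), function(k)
      crossprod(d$X, U[, k]), numeric(d$q + 1)))
    expect_lt(max(abs(score)) / nrow(d$Y), 1e-5)
  }
})

test_that("moment estimators recover generating correlations without covariates", {
  set.seed(15)
  nf <- 8000
  X <- matrix(1, 3 * nf, 1)
  Y <- simulate_continuous(X, NULL, matrix(0, 1, 2), NULL)
  d <- famkat:::fds_stacked(Y, X, NULL, rep(3L, nf), rep("continuous", 2))
  fit <- jgee_null(d, "exchangeable", "exchangeable")
  se3 <- 3 / sqrt(nf)
  expect_lt(abs(fit$R_n[1, 2] - 0.2), se3)
  expect_lt(abs(fit$R_K[1, 2] - 0.3), se3)
  expect_lt(abs(fit$phi - 1), se3)
  # unstructured estimates agree with the exchangeable truth positionwise
  fit_u <- jgee_null(d, "unstructured", "unstructured")
  expect_lt(max(abs(fit_u$R_n[upper.tri(fit_u$R_n)] - 0.2)), 2 * se3)
  expect_lt(abs(fit_u$R_K[1, 2] - 0.3), 2 * se3)
})

test_that("fit is invariant to family relabeling", {
  set.seed(16)
  d <- quick_trio_study(40, "continuous")
  fit <- jgee_null(d)
  perm <- sample(40)
  rows <- unlist(lapply(perm, function(i) which(rep(seq_len(40), d$n_vec) == i)))
  d2 <- famkat:::fds_stacked(d$Y[rows, ], d$X[rows, ], d$G[rows, ],
                             d$n_vec[perm], d$trait_kinds,
                             founder = d$founder[rows])
  fit2 <- jgee_null(d2)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 1e-10)
  expect_equal(fit2$R_n, fit$R_n, tolerance = 1e-10)
  expect_equal(fit2$phi, fit$phi, tolerance = 1e-10)
})

test_that("equal-cluster fast path agrees with the general per-family path", {
  set.seed(17)
  d <- quick_trio_study(30, "binary")
  fit_fast <- jgee_null(d, "exchangeable", "exchangeable")
  # force the general path by making one family a different size (drop a
  # member of the last family), then compare on an equal-size subset fit
  upd <- famkat:::gee_step_general(d$X, fit_fast$A, d$Y - fit_fast$mu,
                                   fit_fast$fam_index, d$n_vec,
                                   fit_fast$R_n, fit_fast$R_K,
                                   d$q + 1L, d$K)
  C <- famkat:::make_pd(fit_fast$R_K %x% fit_fast$R_n)
  upd_fast <- famkat:::gee_step_equal_n(d$X, fit_fast$A, d$Y - fit_fast$mu,
                                        fit_fast$fam_index, 30L, 3L, d$K,
                                        d$q + 1L, C, fit_fast$phi)
  expect_lt(max(abs(upd$delta - upd_fast$delta)),
            1e-10 * (1 + max(abs(upd$delta))))
})

test_that("contract violations error clearly", {
  set.seed(18)
  d <- quick_trio_study(10, "continuous")
  mixed <- d; mixed$trait_kinds <- c("continuous", "binary")
  expect_error(jgee_null(mixed), "not supported")
  # unstructured within-cluster needs constant cluster size
  d2 <- famkat:::fds_stacked(rbind(d$Y, d$Y[1:2, ]), rbind(d$X, d$X[1:2, ]),
                             rbind(d$G, d$G[1:2, ]), c(d$n_vec, 2L),
                             d$trait_kinds)
  expect_error(jgee_null(d2, "unstructured", "exchangeable"),
               "constant cluster size")
  expect_error(family_data_set(list(list(y = matrix(1, 2, 1),
                                         x = matrix(c(2, 2), 2, 1),
                                         g = NULL)), "continuous"),
               "first covariate")
})
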