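test_that("genotype summaries fold MAF, weight by beta density, and filter", {
  G <- rbind(c(0, 2, 1, 0), c(1, 2, 0, 0), c(0, 2, 1, 0), c(1, 2, 2, 0))
  # variant 2 monomorphic (all 2), variant 4 monomorphic (all 0): dropped
  gs <- genotype_summary(G)
  expect_equal(gs$keep, c(1L, 3L))
  expect_equal(gs$m, c(0.25, 0.5))
  expect_equal(gs$w, c(1, 1))                       # Beta(1,1) density = 1
  gs2 <- genotype_summary(G, weights = c(1, 25))
  expect_equal(gs2$w[2], 25 * 0.5^24, tolerance = 1e-12)
  expect_equal(gs2$w, dbeta(gs$m, 1, 25))
  expect_equal(reweight(gs, c(1, 25))$w, gs2$w)

  # duplicated variant column: genotype correlation exactly 1
  G3 <- cbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 0, 1, 1))
  gs3 <- genotype_summary(G3)
  expect_equal(gs3$H[1, 2], 1)

  # founder-restricted MAF differs from the all-sample frequency
  Gf <- rbind(c(1, 0), c(1, 2), c(0, 1), c(0, 1))
  gsf <- genotype_summary(Gf, founder = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(gsf$m), c(0.5, 0.5))
  expect_equal(unname(genotype_summary(Gf)$m), c(0.25, 0.5))

  expect_error(genotype_summary(matrix(2, 4, 2)), "monomorphic")
  expect_error(genotype_summary(matrix(c(0, 1), 1, 2)), "single individual")
})

test_that("score components satisfy the homogeneous/heterogeneous identity", {
  set.seed(30)
  d <- quick_trio_study(50, "continuous")
  fit <- jgee_null(d)
  Om <- trio_omega(50)
  sc <- score_components(fit, Om, d$G)
  expect_equal(sc$C_Ho, sum(sc$C_He), tolerance = 1e-10)
  expect_true(sc$C_Ho > 0)
  expect_true(all(diag(sc$C_He) > 0))
  expect_equal(sc$C_He, t(sc$C_He))

  # batched same-Omega path agrees with the generic per-family loop
  Om_copies <- lapply(Om, function(o) o + 0)        # breaks identical()
  sc2 <- score_components(fit, Om_copies, d$G)
  expect_equal(sc2$Z, sc$Z)
  expect_equal(sc2$C_Ho, sc$C_Ho, tolerance = 1e-12)
  expect_equal(sc2$C_He, sc$C_He, tolerance = 1e-12)
})

test_that("with identity relatedness and one trait, C_Ho is a plain quadratic", {
  set.seed(31)
  d <- unrelated_fds(80, K = 1, kind = "continuous")
  fit <- jgee_null(d, "independence", "independence")
  Om <- rep(list(matrix(1, 1, 1)), 80)
  sc <- score_components(fit, Om, d$G)
  expect_equal(sc$C_Ho, sc$C_He[1, 1])              # K = 1 identity
  # brute-force loop oracle: sum_i S_i' A_i^2 S_i (A = 1 here)
  oracle <- sum((fit$A * fit$S)^2 / fit$A)
  expect_equal(sc$C_Ho, oracle, tolerance = 1e-10)
  # conceptual perfect fit: zero residuals give zero scores
  fit0 <- fit; fit0$S <- fit$S * 0
  sc0 <- score_components(fit0, Om, d$G)
  expect_equal(unname(sc0$Z), matrix(0, ncol(d$G), 1))
  expect_equal(sc0$C_Ho, 0)
})

test_that("single-variant kernel and burden tests coincide", {
  set.seed(32)
  d <- quick_trio_study(60, "continuous", p = 25)
  fit <- jgee_null(d)
  Om <- trio_omega(60)
  gs_all <- genotype_summary(d$G, founder = d$founder, weights = c(1, 25))
  l <- gs_all$keep[5]
  gs1 <- genotype_summary(d$G[, l, drop = FALSE], founder = d$founder,
                          weights = c(1, 25))
  sc1 <- score_components(fit, Om, d$G[, l, drop = FALSE])
  expect_equal(hok_test(sc1, gs1)$p, burden_test(sc1, gs1)$p,
               tolerance = 1e-10)
})

test_that("with one trait the heterogeneous kernel equals the homogeneous", {
  set.seed(33)
  d <- unrelated_fds(120, K = 1, kind = "continuous", p = 8,
                     maf = runif(8, 0.05, 0.4))
  fit <- jgee_null(d, "independence", "independence")
  Om <- rep(list(matrix(1, 1, 1)), 120)
  gs <- genotype_summary(d$G, weights = c(1, 25))
  sc <- score_components(fit, Om, d$G[, gs$keep, drop = FALSE])
  hok <- hok_test(sc, gs)
  hek <- hek_test(sc, gs)
  expect_equal(hek$statistic, hok$statistic, tolerance = 1e-12)
  expect_equal(hek$p, hok$p, tolerance = 1e-12)
})

test_that("heterogeneous null covariance decomposes for independent traits", {
  # with diagonal C_He and unit weights the (pK) x (pK) covariance's
  # spectrum is the concatenation of the per-trait spectra
  set.seed(34)
  p <- 6
  H <- cov2cor(crossprod(matrix(rnorm(p * p * 3), p * 3, p)))
  m <- runif(p, 0.05, 0.45)
  C_He <- diag(c(2.3, 0.7))
  B <- H * tcrossprod(sqrt(m * (1 - m)))
  M <- 2 * (B %x% C_He)
  lam_joint <- eigen_weights(M)
  lam_parts <- sort(c(eigen_weights(2 * B * C_He[1, 1]),
                      eigen_weights(2 * B * C_He[2, 2])), decreasing = TRUE)
  expect_equal(lam_joint, lam_parts, tolerance = 1e-10)
})

test_that("burden numerator equals the weighted column-sum of scores", {
  set.seed(35)
  d <- quick_trio_study(40, "continuous")
  fit <- jgee_null(d)
  Om <- trio_omega(40)
  gs <- genotype_summary(d$G, founder = d$founder, weights = c(1, 25))
  sc <- score_components(fit, Om, d$G[, gs$keep, drop = FALSE])
  bt <- burden_test(sc, gs)
  num <- sum(gs$w * rowSums(sc$Z))^2
  sw <- gs$w * sqrt(gs$m * (1 - gs$m))
  den <- 2 * drop(crossprod(sw, gs$H %*% sw)) * sc$C_Ho
  expect_equal(bt$statistic, num / den, tolerance = 1e-12)
  expect_equal(bt$p, pchisq(bt$statistic, 1, lower.tail = FALSE))
})

test_that("Cauchy combination has its fixed points and symmetry", {
  expect_equal(cauchy_omnibus(0.5, 0.5)$p, 0.5)
  expect_equal(cauchy_omnibus(0.5, 0.5)$statistic, 0)
  for (p in c(1e-6, 0.01, 0.3, 0.77, 0.999))
    expect_equal(cauchy_omnibus(p, p)$p, p, tolerance = 1e-9)
  expect_equal(cauchy_omnibus(0.01, 0.99)$p, 0.5, tolerance = 1e-9)
  expect_error(cauchy_omnibus(0, 0.5), "must lie in")
  expect_error(cauchy_omnibus(0.5, 1.2), "must lie in")
  # extreme inputs survive the tangent clipping
  expect_lt(cauchy_omnibus(1e-300, 0.5)$p, 1e-14)
})

test_that("kernel p-value agrees with a genotype-permutation oracle", {
  set.seed(36)
  n <- 150
  d <- unrelated_fds(n, K = 1, kind = "continuous", p = 8,
                     maf = runif(8, 0.1, 0.4))
  fit <- jgee_null(d, "independence", "independence")
  Om <- rep(list(matrix(1, 1, 1)), n)
  gs <- genotype_summary(d$G)
  sc <- score_components(fit, Om, d$G[, gs$keep, drop = FALSE])
  hok <- hok_test(sc, gs)
  u <- (fit$A * fit$S)[, 1]
  B <- 2e4
  Gk <- d$G[, gs$keep, drop = FALSE]
  kappa_perm <- vapply(seq_len(B), function(b) {
    sum(gs$w * crossprod(Gk[sample.int(n), , drop = FALSE], u)^2)
  }, numeric(1))
  p_perm <- mean(kappa_perm >= hok$statistic)
  expect_lt(abs(hok$p - p_perm), 0.03)
})

test_that("the full battery is consistent with individual calls and deterministic", {
  set.seed(37)
  d <- quick_trio_study(40, "continuous")
  fit <- jgee_null(d)
  Om <- trio_omega(40)
  res <- run_all_tests(fit, Om, weights = c(1, 25))
  gs <- genotype_summary(d$G, founder = d$founder, weights = c(1, 25))
  sc <- score_components(fit, Om, d$G[, gs$keep, drop = FALSE])
  expect_equal(res$HoK$p, hok_test(sc, gs)$p)
  expect_equal(res$HeK$p, hek_test(sc, gs)$p)
  expect_equal(res$BT$p, burden_test(sc, gs)$p)
  expect_equal(res$HoO$p, cauchy_omnibus(res$HoK$p, res$BT$p)$p)
  expect_equal(res$HeO$p, cauchy_omnibus(res$HeK$p, res$BT$p)$p)
  res2 <- run_all_tests(fit, Om, weights = c(1, 25))
  expect_identical(as.data.frame(res), as.data.frame(res2))
  # precomputed summaries give identical answers
  res3 <- run_all_tests(fit, Om, weights = c(1, 25), gs = gs, sc = sc)
  expect_equal(as.data.frame(res3), as.data.frame(res))
})

test_that("null p-values are roughly uniform for unrelated gaussian data", {
  set.seed(38)
  B <- 400
  pv <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    d <- unrelated_fds(120, K = 1, kind = "continuous", p = 8,
                       maf = runif(8, 0.1, 0.4))
    fit <- jgee_null(d, "independence", "independence")
    Om <- rep(list(matrix(1, 1, 1)), 120)
    res <- run_all_tests(fit, Om)
    pv[b, ] <- c(res$HoK$p, res$BT$p)
  }
  expect_gt(ks.test(pv[, 1], "punif")$p.value, 0.001)
  expect_gt(ks.test(pv[, 2], "punif")$p.value, 0.001)
})
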