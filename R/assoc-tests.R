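#' Genotype summaries for region-based tests
#'
#' Computes the per-variant quantities entering the null variance of the
#' retrospective score statistics: folded minor allele frequencies
#' (estimated from designated individuals, founders by default, to avoid
#' double-counting transmitted alleles), the genotype-score correlation
#' matrix `H` over all individuals, and beta-density variant weights
#' `w_l = dbeta(m_l; shape1, shape2)`.  Monomorphic variants (and,
#' optionally, variants below a MAF threshold) are filtered here, once,
#' for all downstream tests.
#'
#' @param G stacked genotype dosage matrix (all subjects x variants,
#'   entries in `[0, 2]`).
#' @param founder logical vector (length `nrow(G)`) marking the
#'   individuals used for allele-frequency estimation; `NULL` uses all.
#' @param weights length-2 numeric `c(shape1, shape2)` of the
#'   beta-density weighting scheme; `c(1, 1)` gives the unweighted test.
#'   Ignored when `w` is supplied.
#' @param w optional explicit per-variant weights (length `ncol(G)`,
#'   non-negative), overriding the beta scheme.
#' @param maf_min drop variants with folded MAF below this value.
#' @return an object of class `genotype_summary`: list with `m`, `H`,
#'   `w`, and `keep` (indices of retained variants in the input order).
#' @export
genotype_summary <- function(G, founder = NULL, weights = c(1, 1), w = NULL,
                             maf_min = 0) {
  G <- as.matrix(G)
  if (nrow(G) < 2L) stop("genotype correlation undefined for a single individual")
  if (is.null(founder)) founder <- rep(TRUE, nrow(G))
  if (sum(founder) < 1L) stop("no individuals designated for MAF estimation")
  af <- colMeans(G[founder, , drop = FALSE]) / 2
  m <- pmin(af, 1 - af)
  # a variant must vary among all genotyped individuals for H to exist
  varies <- matrixStats_colVars(G) > 0
  keep <- which(m > 0 & m >= maf_min & varies)
  if (!length(keep)) stop("all variants monomorphic (or below the MAF threshold)")
  m <- m[keep]
  H <- stats::cor(G[, keep, drop = FALSE])
  if (is.null(w)) {
    if (length(weights) != 2L || any(weights <= 0))
      stop("'weights' must be positive beta shape parameters c(a, b)")
    w <- stats::dbeta(m, weights[1], weights[2])
  } else {
    if (length(w) != ncol(G)) stop("'w' must have one weight per input variant")
    w <- w[keep]
  }
  if (any(w < 0)) stop("negative variant weight")
  structure(list(m = m, H = H, w = w, keep = keep), class = "genotype_summary")
}

#' Score components of the multivariate-trait region tests
#'
#' Computes the per-variant, per-trait score matrix
#' `Z[l, k] = sum_i g_il' Delta_ik A_ik S_ik` from a fitted null model,
#' together with the residual-kinship quadratic forms that scale the null
#' variance of every statistic: the scalar
#' `C_Ho = sum_i u_i' Omega_i u_i` with `u_i = sum_k Delta_ik A_ik S_ik`,
#' and the `K x K` matrix
#' `C_He[k, k'] = sum_i u_ik' Omega_i u_ik'` with `u_ik` the per-trait
#' summand.  By construction `C_Ho` equals the sum of all entries of
#' `C_He`; this identity is asserted.
#'
#' @param fit a [jgee_null()] fit.
#' @param Omega list of per-family genetic-correlation matrices, aligned
#'   with the fit's families (see [genetic_correlation_from_pedigree()]).
#' @param G stacked genotype matrix (all subjects x variants), typically
#'   the retained columns of the data's genotypes.
#' @return an object of class `score_components`: list with `Z` (p x K),
#'   `C_Ho`, `C_He`.
#' @export
score_components <- function(fit, Omega, G) {
  stopifnot(inherits(fit, "jgee_fit"))
  G <- as.matrix(G)
  if (nrow(G) != nrow(fit$S)) stop("genotype rows do not match fitted subjects")
  N <- length(fit$n_vec)
  if (length(Omega) != N) stop("Omega must have one matrix per family")
  U <- fit$A * fit$S                    # Delta = 1 for both supported links
  Z <- crossprod(G, U)                  # p x K
  K <- fit$K
  C_He <- matrix(0, K, K)
  C_Ho <- 0
  n0 <- fit$n_vec[1]
  same_omega <- length(unique(fit$n_vec)) == 1L &&
    all(vapply(Omega, identical, logical(1), y = Omega[[1]]))
  if (same_omega) {
    # all families share one Omega (e.g. simulated trios): batch over
    # families with N x n_i reshapes instead of a per-family loop
    Om <- as.matrix(Omega[[1]])
    if (nrow(Om) != n0) stop("Omega does not match family size")
    Uk <- lapply(seq_len(K), function(k) matrix(U[, k], N, n0, byrow = TRUE))
    UkO <- lapply(Uk, function(u) u %*% Om)
    for (k in seq_len(K)) for (k2 in k:K) {
      v <- sum(UkO[[k]] * Uk[[k2]])
      C_He[k, k2] <- v
      C_He[k2, k] <- v
    }
    Ur <- Reduce(`+`, Uk)
    C_Ho <- sum((Ur %*% Om) * Ur)
  } else {
    ends <- cumsum(fit$n_vec)
    starts <- ends - fit$n_vec + 1L
    for (i in seq_len(N)) {
      rows <- starts[i]:ends[i]
      Om <- Omega[[i]]
      if (nrow(Om) != length(rows))
        stop("Omega[[", i, "]] does not match family size")
      ui <- U[rows, , drop = FALSE]
      C_He <- C_He + crossprod(ui, Om %*% ui)
      ri <- rowSums(ui)
      C_Ho <- C_Ho + as.numeric(crossprod(ri, Om %*% ri))
    }
  }
  C_He <- (C_He + t(C_He)) / 2
  if (abs(C_Ho - sum(C_He)) > 1e-6 * max(abs(C_Ho), 1))
    stop("internal error: C_Ho != sum(C_He)")
  structure(list(Z = Z, C_Ho = C_Ho, C_He = C_He), class = "score_components")
}

matrixStats_colVars <- function(G) {
  n <- nrow(G)
  (colSums(G^2) - colSums(G)^2 / n) / (n - 1)
}

#' Re-derive beta-density weights of an existing genotype summary
#'
#' @param gs a [genotype_summary()] object.
#' @param weights beta shape pair `c(shape1, shape2)`.
#' @return the summary with `w` recomputed; MAFs and `H` are unchanged.
#' @export
reweight <- function(gs, weights) {
  stopifnot(inherits(gs, "genotype_summary"), length(weights) == 2L)
  gs$w <- stats::dbeta(gs$m, weights[1], weights[2])
  gs
}

new_test_result <- function(method, statistic, p, n_eigen = NA_integer_,
                            flags = character(0)) {
  structure(list(method = method, statistic = statistic, p = p,
                 n_eigen = n_eigen, flags = flags),
            class = "famkat_test")
}

#' @export
print.famkat_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g", x$method, x$statistic, x$p))
  if (!is.na(x$n_eigen)) cat(sprintf("  (%d eigenvalue(s))", x$n_eigen))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Homogeneous kernel association test
#'
#' Quadratic statistic for a shared (homogeneous) variant effect across
#' traits: `kappa_Ho = sum_l w_l (sum_k Z_lk)^2`.  Under the null the
#' statistic is a mixture of 1-df chi-squares whose weights are the
#' eigenvalues of the retrospective null covariance of the weighted
#' scores, `M[l, l'] = 2 C_Ho sqrt(w_l w_l') H_ll'
#' sqrt(m_l (1 - m_l)) sqrt(m_l' (1 - m_l'))`; the p-value comes from the
#' saddlepoint approximation.
#'
#' @param sc a [score_components()] object.
#' @param gs a [genotype_summary()] object (variants aligned with the
#'   rows of `sc$Z`).
#' @return a `famkat_test` result.
#' @export
hok_test <- function(sc, gs) {
  if (sc$C_Ho <= 0) stop("C_Ho must be positive")
  Zl <- rowSums(sc$Z)
  kappa <- sum(gs$w * Zl^2)
  v <- gs$m * (1 - gs$m)
  d <- sqrt(gs$w * v)
  M <- 2 * sc$C_Ho * gs$H * tcrossprod(d)
  lambda <- eigen_weights(M)
  pr <- mixture_chisq_sf(kappa, lambda)
  new_test_result("HoK", kappa, pr$p, length(lambda),
                  if (pr$fallback) "fallback" else character(0))
}

#' Heterogeneous kernel association test
#'
#' Quadratic statistic allowing trait-specific variant effects:
#' `kappa_He = sum_l sum_k w_lk Z_lk^2`, with null covariance over index
#' pairs `(l, k)` given by `2 sqrt(w_lk w_l'k') H_ll'
#' sqrt(m_l (1 - m_l) m_l' (1 - m_l')) C_He[k, k']`.  With `K = 1` it
#' reduces exactly to [hok_test()].
#'
#' @inheritParams hok_test
#' @param w_trait optional `p x K` matrix of trait-specific weights;
#'   default replicates the homogeneous weights `gs$w` across traits.
#' @return a `famkat_test` result.
#' @export
hek_test <- function(sc, gs, w_trait = NULL) {
  K <- ncol(sc$Z); p <- nrow(sc$Z)
  if (is.null(w_trait)) w_trait <- matrix(gs$w, p, K)
  if (!all(dim(w_trait) == c(p, K))) stop("'w_trait' must be p x K")
  kappa <- sum(w_trait * sc$Z^2)
  v <- gs$m * (1 - gs$m)
  B <- gs$H * tcrossprod(sqrt(v))
  M <- 2 * (B %x% sc$C_He)                      # index (l-1)*K + k
  dw <- sqrt(as.vector(t(w_trait)))             # same index order
  M <- M * tcrossprod(dw)
  lambda <- eigen_weights(M)
  pr <- mixture_chisq_sf(kappa, lambda)
  new_test_result("HeK", kappa, pr$p, length(lambda),
                  if (pr$fallback) "fallback" else character(0))
}

#' Weighted burden association test
#'
#' Collapses the region into the weighted dosage sum
#' `g_tilde_i = sum_l w_l g_il` and tests its pooled score across traits:
#' the squared score `(sum_l w_l sum_k Z_lk)^2` divided by its
#' retrospective null variance
#' `2 (sum_l sum_l' w_l w_l' H_ll' sqrt(m_l(1-m_l) m_l'(1-m_l'))) C_Ho`
#' is compared to a 1-df chi-square.
#'
#' @inheritParams hok_test
#' @return a `famkat_test` result.
#' @export
burden_test <- function(sc, gs) {
  if (sc$C_Ho <= 0) stop("C_Ho must be positive")
  num <- sum(gs$w * rowSums(sc$Z))^2
  sw <- gs$w * sqrt(gs$m * (1 - gs$m))
  den <- 2 * as.numeric(crossprod(sw, gs$H %*% sw)) * sc$C_Ho
  if (den <= 0) stop("burden null variance is zero (all weights zero?)")
  stat <- num / den
  new_test_result("BT", stat, stats::pchisq(stat, df = 1, lower.tail = FALSE), 1L)
}

#' Cauchy-combination omnibus p-value
#'
#' Combines two p-values through the standard Cauchy quantile transform:
#' `O = -(tan(pi * (p_a - 1/2)) + tan(pi * (p_b - 1/2))) / 2`, which is
#' approximately standard Cauchy under the null whatever the dependence
#' between the two tests; the omnibus p-value is
#' `1/2 - atan(O) / pi`.  Inputs are clipped to `[1e-15, 1 - 1e-15]` to
#' guard the tangent.
#'
#' @param p_a,p_b component p-values in `(0, 1]`.
#' @param method label for the result (default `"CauchyO"`).
#' @return a `famkat_test` result whose statistic is `O`.
#' @export
cauchy_omnibus <- function(p_a, p_b, method = "CauchyO") {
  for (p in c(p_a, p_b))
    if (!is.finite(p) || p <= 0 || p > 1) stop("p-values must lie in (0, 1]")
  pa <- min(max(p_a, 1e-15), 1 - 1e-15)
  pb <- min(max(p_b, 1e-15), 1 - 1e-15)
  O <- -0.5 * (tan(pi * (pa - 0.5)) + tan(pi * (pb - 0.5)))
  p <- 0.5 - atan(O) / pi
  new_test_result(method, O, max(min(p, 1), 1e-300))
}

#' Run the full battery of region tests
#'
#' Computes the homogeneous kernel (HoK), heterogeneous kernel (HeK) and
#' burden (BT) statistics from shared score components, then the two
#' omnibus combinations: HoO = Cauchy(HoK, BT) and HeO = Cauchy(HeK, BT).
#'
#' @param fit a [jgee_null()] fit.
#' @param Omega list of per-family genetic-correlation matrices.
#' @param weights beta-density shape pair, passed to [genotype_summary()].
#' @param maf_min MAF filter threshold.
#' @param gs,sc optional precomputed [genotype_summary()] /
#'   [score_components()] objects (reused across weight schemes; `gs` is
#'   reweighted to `weights`).
#' @return object of class `famkat_results`: named list of `famkat_test`
#'   results (`HoK`, `HeK`, `BT`, `HoO`, `HeO`) plus the `genotype_summary`.
#' @export
run_all_tests <- function(fit, Omega, weights = c(1, 1), maf_min = 0,
                          gs = NULL, sc = NULL) {
  data <- fit$data
  if (data$p < 1L) stop("no genotypes in the data")
  G <- data$G
  if (is.null(gs)) {
    gs <- genotype_summary(G, founder = data$founder, weights = weights,
                           maf_min = maf_min)
  } else {
    gs <- reweight(gs, weights)
  }
  if (is.null(sc))
    sc <- score_components(fit, Omega, G[, gs$keep, drop = FALSE])
  hok <- hok_test(sc, gs)
  hek <- hek_test(sc, gs)
  bt <- burden_test(sc, gs)
  hoo <- cauchy_omnibus(hok$p, bt$p, "HoO")
  heo <- cauchy_omnibus(hek$p, bt$p, "HeO")
  structure(list(HoK = hok, HeK = hek, BT = bt, HoO = hoo, HeO = heo,
                 summary = gs),
            class = "famkat_results")
}

#' @export
print.famkat_results <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.famkat_results <- function(x, ...) {
  meth <- c("HoK", "HeK", "BT", "HoO", "HeO")
  data.frame(method = meth,
             statistic = vapply(x[meth], function(t) t$statistic, numeric(1)),
             p = vapply(x[meth], function(t) t$p, numeric(1)),
             n_eigen = vapply(x[meth], function(t) as.integer(t$n_eigen), integer(1)),
             flags = vapply(x[meth], function(t)
               paste(t$flags, collapse = ";"), character(1)),
             row.names = NULL)
}
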