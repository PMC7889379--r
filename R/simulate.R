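#' Two-subpopulation haplotype pools
#'
#' Generates a pair of haplotype pools emulating a short sequenced region
#' segregating in two diverged subpopulations (a European-like and an
#' admixed African-American-like stand-in).  Per-site minor allele
#' frequencies are drawn from a two-component spectrum (a rare component
#' below a MAF threshold and a common component above it); the two pools
#' share sites but perturb the base frequency by a Balding--Nichols beta
#' draw with differentiation parameter `fst`.  Haplotype alleles are
#' i.i.d. Bernoulli per site (no linkage disequilibrium); sites
#' monomorphic in the combined pool are redrawn so that every variant is
#' polymorphic.
#'
#' @param p number of variant sites (>= 10).
#' @param n_hap haplotypes per pool.
#' @param spectrum list with `rare_frac` (fraction of sites from the rare
#'   component), `rare_range` and `common_range` (MAF ranges; the rare
#'   component is log-uniform), and `fst` (between-pool differentiation).
#' @return list of two objects of class `haplotype_pool` (`$EUR`, `$AA`),
#'   each with the 0/1 haplotype matrix `H` (`n_hap x p`), the realized
#'   frequency vector `maf`, and the pool `label`.
#' @export
make_pools <- function(p = 30L, n_hap = 10000L,
                       spectrum = list(rare_frac = 0.6,
                                       rare_range = c(0.002, 0.03),
                                       common_range = c(0.03, 0.5),
                                       fst = 0.05)) {
  if (p < 10L) stop("need at least 10 variant sites")
  if (spectrum$rare_frac < 0 || spectrum$rare_frac > 1 ||
      any(unlist(spectrum[c("rare_range", "common_range")]) <= 0) ||
      any(unlist(spectrum[c("rare_range", "common_range")]) >= 1))
    stop("degenerate MAF spectrum")
  n_rare <- round(p * spectrum$rare_frac)
  base <- numeric(p)
  rare_idx <- seq_len(n_rare)
  common_idx <- setdiff(seq_len(p), rare_idx)
  lr <- log10(spectrum$rare_range)
  base[rare_idx] <- 10^stats::runif(n_rare, lr[1], lr[2])
  base[common_idx] <- stats::runif(length(common_idx),
                                   spectrum$common_range[1],
                                   spectrum$common_range[2])
  draw_pool_freq <- function(m0) {
    fst <- spectrum$fst
    if (fst <= 0) return(m0)
    a <- m0 * (1 - fst) / fst
    b <- (1 - m0) * (1 - fst) / fst
    stats::rbeta(length(m0), a, b)
  }
  freq1 <- draw_pool_freq(base)
  freq2 <- draw_pool_freq(base)
  H1 <- matrix(stats::rbinom(n_hap * p, 1L, rep(freq1, each = n_hap)), n_hap, p)
  H2 <- matrix(stats::rbinom(n_hap * p, 1L, rep(freq2, each = n_hap)), n_hap, p)
  # guarantee polymorphism in the combined pool
  for (tries in 1:100) {
    tot <- colSums(H1) + colSums(H2)
    mono <- which(tot == 0L | tot == 2L * n_hap)
    if (!length(mono)) break
    f1 <- draw_pool_freq(base[mono]); f2 <- draw_pool_freq(base[mono])
    H1[, mono] <- stats::rbinom(n_hap * length(mono), 1L, rep(f1, each = n_hap))
    H2[, mono] <- stats::rbinom(n_hap * length(mono), 1L, rep(f2, each = n_hap))
  }
  tot <- colSums(H1) + colSums(H2)
  if (any(tot == 0L | tot == 2L * n_hap))
    stop("degenerate spectrum: could not realize polymorphic sites")
  pool <- function(H, label) {
    structure(list(H = H, maf = colMeans(H), label = label,
                   n_hap = nrow(H), p = ncol(H)),
              class = "haplotype_pool")
  }
  list(EUR = pool(H1, "EUR"), AA = pool(H2, "AA"))
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("haplotype_pool '", x$label, "': ", x$n_hap, " haplotypes x ", x$p,
      " sites; MAF range ", paste(signif(range(x$maf), 3), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' Gene-drop a nuclear trio from a haplotype pool
#'
#' Draws four founder haplotypes (two per parent, without replacement)
#' and transmits one uniformly chosen haplotype from each parent to the
#' child — Mendelian inheritance without recombination across the short
#' region.  Dosage is the haplotype sum.
#'
#' @param pool a `haplotype_pool`.
#' @return `3 x p` dosage matrix with rows `father`, `mother`, `child`.
#' @export
draw_trio <- function(pool) {
  draw_trios(pool, 1L)[[1L]]
}

#' Gene-drop many nuclear trios at once
#'
#' Vectorized version of [draw_trio()].
#'
#' @param pool a `haplotype_pool`.
#' @param n_fam number of trios.
#' @return list of `3 x p` dosage matrices.
#' @export
draw_trios <- function(pool, n_fam) {
  G <- draw_trios_stacked(pool, n_fam)
  lapply(seq_len(n_fam), function(i) {
    g <- G[(i - 1L) * 3L + 1:3, , drop = FALSE]
    rownames(g) <- c("father", "mother", "child")
    g
  })
}

# stacked form (father, mother, child per family) without per-family lists
draw_trios_stacked <- function(pool, n_fam) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (pool$n_hap < 4L) stop("pool must contain at least 4 haplotypes")
  idx <- vapply(seq_len(n_fam), function(i) sample.int(pool$n_hap, 4L),
                integer(4))                    # 4 x n_fam
  H <- pool$H
  f1 <- H[idx[1L, ], , drop = FALSE]; f2 <- H[idx[2L, ], , drop = FALSE]
  m1 <- H[idx[3L, ], , drop = FALSE]; m2 <- H[idx[4L, ], , drop = FALSE]
  tf <- stats::runif(n_fam) < 0.5
  tm <- stats::runif(n_fam) < 0.5
  child <- ifelse(matrix(tf, n_fam, pool$p), f1, f2) +
    ifelse(matrix(tm, n_fam, pool$p), m1, m2)
  G <- matrix(0L, 3L * n_fam, pool$p)
  rows <- seq_len(n_fam) * 3L
  G[rows - 2L, ] <- f1 + f2
  G[rows - 1L, ] <- m1 + m2
  G[rows, ] <- child
  G
}

#' Check Mendelian consistency of a trio dosage matrix
#'
#' At every site the child's dosage must lie within the bounds implied by
#' the parents' dosages: at least one copy must be transmitted by a
#' homozygous-alternate parent and none can come from a
#' homozygous-reference parent.
#'
#' @param trio `3 x p` matrix with rows father, mother, child.
#' @return logical scalar.
#' @export
mendelian_consistent <- function(trio) {
  f <- trio[1L, ]; m <- trio[2L, ]; c <- trio[3L, ]
  lo <- (f == 2) + (m == 2)
  hi <- (f > 0) + (m > 0)
  all(c >= lo & c <= hi)
}

#' Simulate the nongenetic covariates of a cluster
#'
#' Column 1 is the intercept; column 2 is i.i.d. Bernoulli(0.5) per
#' subject; column 3 is multivariate normal across the cluster's subjects
#' with mean 0.5, unit variances, and pairwise covariance 0.1.
#'
#' @param n_fam number of families.
#' @param n_i subjects per family.
#' @return stacked covariate matrix (`n_fam * n_i` rows, 3 columns),
#'   family-blocked.
#' @export
draw_covariates <- function(n_fam, n_i = 3L) {
  M <- n_fam * n_i
  x1 <- stats::rbinom(M, 1L, 0.5)
  Sig <- matrix(0.1, n_i, n_i); diag(Sig) <- 1
  Z <- matrix(stats::rnorm(n_fam * n_i), n_fam, n_i) %*% chol(Sig)
  x2 <- as.vector(t(Z)) + 0.5
  cbind(1, x1, x2)
}

#' Variant effect sizes for the alternative model
#'
#' A random `causal_frac` of the variants with MAF strictly below
#' `maf_threshold` receive nonzero effects, of magnitude
#' `c_scale * |log10(m_l)|`; a variant is risk (positive sign) with
#' probability `pos_frac` and protective (`c_scale * log10(m_l)`,
#' negative) otherwise.  Under the homogeneous model all traits share the
#' effect vector; under the heterogeneous model only trait 1 carries it.
#'
#' @param m MAF vector.
#' @param K number of traits.
#' @param scenario `"null"` (all zero), `"hom"` or `"het"`.
#' @param causal_frac fraction of sub-threshold variants made causal.
#' @param maf_threshold MAF cut-off (strict inequality).
#' @param pos_frac probability a causal variant is risk (positive).
#' @param c_scale effect-size scale.
#' @return `p x K` matrix of regression coefficients.
#' @export
effect_sizes <- function(m, K = 2L, scenario = c("null", "hom", "het"),
                         causal_frac = 0.35, maf_threshold = 0.03,
                         pos_frac = 1, c_scale = 0.095) {
  scenario <- match.arg(scenario)
  p <- length(m)
  beta1 <- numeric(p)
  if (scenario != "null") {
    low <- which(m < maf_threshold)
    n_causal <- round(causal_frac * length(low))
    causal <- if (n_causal > 0) sample(low, n_causal) else integer(0)
    pos <- stats::runif(length(causal)) < pos_frac
    beta1[causal] <- ifelse(pos, c_scale * abs(log10(m[causal])),
                            c_scale * log10(m[causal]))
  }
  B <- matrix(0, p, K)
  if (scenario == "hom") B[] <- beta1
  if (scenario == "het") B[, 1] <- beta1
  if (scenario == "null") B[] <- 0
  B
}

# Error / latent correlation matrix over the trait-major layout of one
# cluster: same subject & trait = 1, same trait across subjects = rho_n,
# same subject across traits = rho_K, different subject & trait = rho_x.
phenotype_correlation <- function(n_i, K, rho_n = 0.2, rho_K = 0.3, rho_x = 0.1) {
  Rdiag <- matrix(rho_n, n_i, n_i); diag(Rdiag) <- 1
  Roff <- matrix(rho_x, n_i, n_i); diag(Roff) <- rho_K
  S <- diag(K) %x% (Rdiag - Roff) + matrix(1, K, K) %x% Roff
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("phenotype correlation matrix is not positive definite")
  S
}

#' Simulate correlated continuous phenotypes
#'
#' Adds to the linear predictor `X alpha + G beta` a zero-mean Gaussian
#' error whose cluster-level correlation has unit variances, within-trait
#' cross-subject correlation `rho_n`, same-subject cross-trait
#' correlation `rho_K`, and cross-subject cross-trait correlation
#' `rho_x`.
#'
#' @param X stacked covariate matrix (family-blocked, `n_i` rows each).
#' @param G stacked genotype matrix (or `NULL` for no genetic term).
#' @param alpha `(q+1) x K` covariate coefficients.
#' @param beta `p x K` genetic coefficients.
#' @param n_i cluster size.
#' @param rho_n,rho_K,rho_x error correlation parameters.
#' @return stacked `M x K` phenotype matrix.
#' @export
simulate_continuous <- function(X, G, alpha, beta, n_i = 3L,
                                rho_n = 0.2, rho_K = 0.3, rho_x = 0.1) {
  M <- nrow(X)
  if (M %% n_i != 0L) stop("rows are not a multiple of the cluster size")
  n_fam <- M %/% n_i
  K <- ncol(alpha)
  mu <- X %*% alpha
  if (!is.null(G) && !is.null(beta)) mu <- mu + G %*% beta
  S <- phenotype_correlation(n_i, K, rho_n, rho_K, rho_x)
  E <- matrix(stats::rnorm(n_fam * n_i * K), n_fam) %*% chol(S)
  eps <- matrix(0, M, K)
  for (k in seq_len(K))
    eps[, k] <- as.vector(t(E[, (k - 1L) * n_i + seq_len(n_i), drop = FALSE]))
  mu + eps
}

# ---- dichotomized-normal machinery for binary phenotypes ----------------

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho,
# via Phi2(a,b,rho) = Phi(a)Phi(b) + int_0^rho phi2(a,b,r) dr.
binorm_sf <- function(a, b, rho) {
  base <- stats::pnorm(a, lower.tail = FALSE) * stats::pnorm(b, lower.tail = FALSE)
  if (abs(rho) < 1e-12) return(base)
  f <- function(r) exp(-(a^2 - 2 * r * a * b + b^2) / (2 * (1 - r^2))) /
    (2 * pi * sqrt(1 - r^2))
  corr <- stats::integrate(Vectorize(f), 0, rho, rel.tol = 1e-10)$value
  base + corr
}

# correlation of 1{Z1 > a}, 1{Z2 > b} induced by latent correlation rho
binary_corr_from_latent <- function(a, b, rho) {
  p1 <- stats::pnorm(a, lower.tail = FALSE)
  p2 <- stats::pnorm(b, lower.tail = FALSE)
  (binorm_sf(a, b, rho) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# solve for the latent correlation matching a target binary correlation;
# NA when the target lies outside the Frechet bounds at these prevalences
solve_latent_rho <- function(p1, p2, target) {
  a <- stats::qnorm(1 - p1); b <- stats::qnorm(1 - p2)
  f <- function(r) binary_corr_from_latent(a, b, r) - target
  lo <- -0.999; hi <- 0.999
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

# Cached grid of latent correlations over a prevalence lattice, one per
# target; bilinear interpolation makes per-replicate assembly cheap.
.latent_cache <- new.env(parent = emptyenv())

latent_grid <- function(target, pg = seq(0.01, 0.8, length.out = 24L)) {
  key <- paste0("t", format(target, digits = 12))
  if (!is.null(.latent_cache[[key]])) return(.latent_cache[[key]])
  n <- length(pg)
  Gd <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    Gd[i, j] <- Gd[j, i] <- solve_latent_rho(pg[i], pg[j], target)
  }
  out <- list(pg = pg, grid = Gd)
  .latent_cache[[key]] <- out
  out
}

# vectorized bilinear interpolation of the latent correlation
latent_rho_interp <- function(p1, p2, target) {
  lg <- latent_grid(target)
  pg <- lg$pg
  cl <- function(p) pmin(pmax(p, pg[1]), pg[length(pg)])
  p1 <- cl(p1); p2 <- cl(p2)
  i <- pmin(findInterval(p1, pg), length(pg) - 1L)
  j <- pmin(findInterval(p2, pg), length(pg) - 1L)
  u <- (p1 - pg[i]) / (pg[i + 1L] - pg[i])
  v <- (p2 - pg[j]) / (pg[j + 1L] - pg[j])
  g <- lg$grid
  out <- (1 - u) * (1 - v) * g[cbind(i, j)] + u * (1 - v) * g[cbind(i + 1L, j)] +
    (1 - u) * v * g[cbind(i, j + 1L)] + u * v * g[cbind(i + 1L, j + 1L)]
  if (anyNA(out))
    stop("target binary correlation ", target, " infeasible (outside the ",
         "Frechet bounds) at some prevalence pair near (",
         signif(p1[which(is.na(out))[1]], 3), ", ",
         signif(p2[which(is.na(out))[1]], 3), ")")
  out
}

#' Simulate correlated binary phenotypes
#'
#' Subject-level marginal probabilities follow the logistic model
#' `logit P(y = 1) = X alpha + G beta`; the joint distribution within a
#' cluster is a dichotomized multivariate normal whose latent
#' correlations are solved numerically (via the bivariate-normal orthant
#' equation) so that the *binary-scale* correlations match the targets
#' `rho_n` (within trait), `rho_K` (same subject, across traits) and
#' `rho_x` (across subjects and traits) at each pair's marginal
#' prevalences.
#'
#' @inheritParams simulate_continuous
#' @return stacked `M x K` 0/1 phenotype matrix.
#' @export
simulate_binary <- function(X, G, alpha, beta, n_i = 3L,
                            rho_n = 0.2, rho_K = 0.3, rho_x = 0.1) {
  M <- nrow(X)
  if (M %% n_i != 0L) stop("rows are not a multiple of the cluster size")
  n_fam <- M %/% n_i
  K <- ncol(alpha)
  eta <- X %*% alpha
  if (!is.null(G) && !is.null(beta)) eta <- eta + G %*% beta
  pr <- stats::plogis(eta)                       # M x K prevalences
  if (any(pr < 1e-6 | pr > 1 - 1e-6))
    stop("extreme linear predictor: prevalence numerically 0 or 1")
  d <- n_i * K
  # prevalence of element (k-1)*n_i + j of each cluster
  Pc <- matrix(0, n_fam, d)
  for (k in seq_len(K))
    Pc[, (k - 1L) * n_i + seq_len(n_i)] <- matrix(pr[, k], n_fam, n_i, byrow = TRUE)
  # latent correlations for every element pair, all clusters at once
  targets <- phenotype_correlation(n_i, K, rho_n, rho_K, rho_x)
  pairs <- which(upper.tri(targets), arr.ind = TRUE)
  Lat <- array(0, c(n_fam, d, d))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    Lat[, a, b] <- Lat[, b, a] <-
      latent_rho_interp(Pc[, a], Pc[, b], targets[a, b])
  }
  Th <- stats::qnorm(1 - Pc)
  Yc <- matrix(0L, n_fam, d)
  Zr <- matrix(stats::rnorm(n_fam * d), n_fam, d)
  Sig <- diag(d)
  for (i in seq_len(n_fam)) {
    Sig[] <- Lat[i, , ]
    diag(Sig) <- 1
    L <- tryCatch(chol(Sig), error = function(e) chol(make_pd(Sig)))
    Yc[i, ] <- as.integer(Zr[i, ] %*% L > Th[i, ])
  }
  Y <- matrix(0L, M, K)
  for (k in seq_len(K))
    Y[, k] <- as.vector(t(Yc[, (k - 1L) * n_i + seq_len(n_i), drop = FALSE]))
  Y
}

#' Simulate a complete two-population family study
#'
#' Draws nuclear trios from two haplotype pools (preserving a configurable
#' family ratio), simulates covariates, builds effect sizes for the
#' requested scenario, and generates continuous or binary phenotypes with
#' the standard correlation targets.  Defaults mirror the package's
#' simulation-study conditions: two traits, covariate effects
#' `(0.01, 0.1, 0.1)` per trait for continuous phenotypes and
#' `(-1.4, 0.1, 0.1)` for binary ones.
#'
#' @param pools a pair of pools from [make_pools()].
#' @param n_fam integer vector `c(nEUR, nAA)` of families per pool.
#' @param trait_kind `"continuous"` or `"binary"`.
#' @param scenario `"null"`, `"hom"` or `"het"` (see [effect_sizes()]).
#' @param K number of traits.
#' @param alpha optional `(q+1) x K` covariate coefficient matrix.
#' @param pos_frac,c_scale passed to [effect_sizes()].
#' @param rho_n,rho_K,rho_x phenotype correlation targets.
#' @return a [family_data_set()] with founder flags set (parents are
#'   founders) and attribute `"maf_pool"` carrying the combined-pool
#'   allele frequencies used for effect-size assignment.
#' @export
simulate_study <- function(pools, n_fam = c(170L, 130L),
                           trait_kind = c("continuous", "binary"),
                           scenario = c("null", "hom", "het"), K = 2L,
                           alpha = NULL, pos_frac = 1, c_scale = 0.095,
                           rho_n = 0.2, rho_K = 0.3, rho_x = 0.1) {
  trait_kind <- match.arg(trait_kind)
  scenario <- match.arg(scenario)
  if (is.null(alpha)) {
    a0 <- if (trait_kind == "continuous") c(0.01, 0.1, 0.1) else c(-1.4, 0.1, 0.1)
    alpha <- matrix(a0, 3, K)
  }
  N <- sum(n_fam)
  G <- rbind(draw_trios_stacked(pools[[1]], n_fam[1]),
             draw_trios_stacked(pools[[2]], n_fam[2]))
  X <- draw_covariates(N, 3L)
  maf_pool <- (pools[[1]]$maf * pools[[1]]$n_hap + pools[[2]]$maf * pools[[2]]$n_hap) /
    (pools[[1]]$n_hap + pools[[2]]$n_hap)
  maf_pool <- pmin(maf_pool, 1 - maf_pool)
  beta <- effect_sizes(maf_pool, K, scenario, pos_frac = pos_frac,
                       c_scale = c_scale)
  Y <- if (trait_kind == "continuous") {
    simulate_continuous(X, G, alpha, beta, 3L, rho_n, rho_K, rho_x)
  } else {
    simulate_binary(X, G, alpha, beta, 3L, rho_n, rho_K, rho_x)
  }
  founder <- rep(c(TRUE, TRUE, FALSE), N)
  out <- fds_stacked(Y, X, G, rep(3L, N), rep(trait_kind, K),
                     fid = sprintf("F%04d", seq_len(N)), founder = founder)
  attr(out, "maf_pool") <- maf_pool
  attr(out, "beta") <- beta
  out
}

#' Genetic-correlation matrices for simulated trios
#'
#' @param n_fam number of trios.
#' @return list of `n_fam` copies of the father/mother/child
#'   genetic-correlation matrix.
#' @export
trio_omega <- function(n_fam) {
  om <- matrix(c(1, 0, 0.5, 0, 1, 0.5, 0.5, 0.5, 1), 3, 3)
  rep(list(om), n_fam)
}
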