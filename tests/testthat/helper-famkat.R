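# Shared fixtures and small independent oracles, built in code.

# families of unrelated singletons (population data): n families of size 1
unrelated_fds <- function(n, K = 1L, kind = "continuous", p = 5L,
                          maf = rep(0.3, p)) {
  X <- cbind(1, stats::rnorm(n), stats::rbinom(n, 1, 0.5))
  G <- sapply(maf, function(m) stats::rbinom(n, 2, m))
  eta <- X %*% matrix(c(0.2, 0.1, -0.1), 3, K)
  Y <- if (kind == "continuous") {
    eta + matrix(stats::rnorm(n * K), n, K)
  } else {
    matrix(stats::rbinom(n * K, 1, stats::plogis(eta)), n, K)
  }
  famkat:::fds_stacked(Y, X, G, rep(1L, n), rep(kind, K),
                       founder = rep(TRUE, n))
}

# small trio study in one call
quick_trio_study <- function(n_fam = 60L, kind = "continuous",
                             scenario = "null", p = 20L, n_hap = 400L) {
  pools <- make_pools(p, n_hap)
  n1 <- ceiling(n_fam * 4 / 7); n2 <- n_fam - n1
  simulate_study(pools, c(n1, n2), kind, scenario)
}

# gene-drop oracle: empirical dosage correlation between two pedigree
# members, dropping a freq-0.5 biallelic variant through founders B times
gene_drop_cor <- function(ped_drop, member_a, member_b, B = 1e5) {
  # ped_drop: list of members, each NULL (founder) or c(father, mother)
  n <- length(ped_drop)
  hap1 <- matrix(NA_integer_, B, n)
  hap2 <- matrix(NA_integer_, B, n)
  for (j in seq_len(n)) {
    pa <- ped_drop[[j]]
    if (is.null(pa)) {
      hap1[, j] <- stats::rbinom(B, 1, 0.5)
      hap2[, j] <- stats::rbinom(B, 1, 0.5)
    } else {
      pick <- stats::runif(B) < 0.5
      hap1[, j] <- ifelse(pick, hap1[, pa[1]], hap2[, pa[1]])
      pick <- stats::runif(B) < 0.5
      hap2[, j] <- ifelse(pick, hap1[, pa[2]], hap2[, pa[2]])
    }
  }
  stats::cor(hap1[, member_a] + hap2[, member_a],
             hap1[, member_b] + hap2[, member_b])
}

# Imhof numerical inversion: accurate tail of sum lambda_l chi2_1;
# independent of the saddlepoint implementation under test
imhof_sf <- function(q, lambda) {
  th <- function(u) 0.5 * sapply(u, function(uu) sum(atan(lambda * uu))) - q * u / 2
  rho <- function(u) sapply(u, function(uu) prod((1 + lambda^2 * uu^2)^0.25))
  f <- function(u) sin(th(u)) / (u * rho(u))
  0.5 + stats::integrate(f, 0, 500, rel.tol = 1e-10,
                         subdivisions = 20000L)$value / pi
}

# cache for expensive shared simulations (filled lazily by acceptance tests)
.famkat_test_cache <- new.env(parent = emptyenv())

acc_null_study <- function(kind) {
  key <- paste0("null_", kind)
  if (is.null(.famkat_test_cache[[key]])) {
    cfg <- experiment_config(
      scenario = "null", trait_kind = kind,
      n_fam = c(170L, 130L), n_rep = 2000L,
      levels = c(0.05, 0.01), seed = if (kind == "continuous") 1234L else 5678L)
    .famkat_test_cache[[key]] <- replicate_pvalues(cfg)
  }
  .famkat_test_cache[[key]]
}
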