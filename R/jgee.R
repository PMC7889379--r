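#' Assemble per-family phenotype/covariate/genotype data
#'
#' Bundles the per-family blocks consumed by the null-model fit and the
#' association tests.  Within each family the `n_i x K` phenotype matrix,
#' the `n_i x (q+1)` covariate matrix (first column all ones), and the
#' `n_i x p` genotype dosage matrix share row order (one row per subject).
#' The stacked response used internally is trait-major: trait 1 for all
#' subjects, then trait 2, matching the Kronecker working covariance
#' `R_K %x% R_n`.
#'
#' @param families list; each element a list with components `y`
#'   (`n_i x K` numeric matrix), `x` (`n_i x (q+1)`, first column ones),
#'   `g` (`n_i x p` dosages in `[0, 2]`), and optionally `fid` and
#'   `founder` (logical, marks founders for allele-frequency estimation).
#' @param trait_kinds character vector of length K, each `"continuous"`
#'   or `"binary"`.  Binary traits must be coded 0/1.
#' @return an object of class `family_data_set`.
#' @export
family_data_set <- function(families, trait_kinds) {
  if (length(families) < 1L) stop("need at least one family")
  K <- ncol(as.matrix(families[[1]]$y))
  q1 <- ncol(as.matrix(families[[1]]$x))
  p <- if (is.null(families[[1]]$g)) 0L else ncol(as.matrix(families[[1]]$g))
  trait_kinds <- match.arg(trait_kinds, c("continuous", "binary"),
                           several.ok = TRUE)
  trait_kinds <- rep_len(trait_kinds, K)
  for (i in seq_along(families)) {
    f <- families[[i]]
    f$y <- as.matrix(f$y); f$x <- as.matrix(f$x)
    if (!is.null(f$g)) f$g <- as.matrix(f$g)
    ni <- nrow(f$y)
    if (ncol(f$y) != K || ncol(f$x) != q1 || nrow(f$x) != ni)
      stop("family ", i, ": inconsistent dimensions")
    if (!is.null(f$g) && (nrow(f$g) != ni || ncol(f$g) != p))
      stop("family ", i, ": genotype block dimensions differ")
    if (anyNA(f$y) || anyNA(f$x) || (!is.null(f$g) && anyNA(f$g)))
      stop("family ", i, ": missing values (complete cases required)")
    if (any(f$x[, 1] != 1)) stop("family ", i, ": first covariate column must be 1")
    for (k in which(trait_kinds == "binary"))
      if (!all(f$y[, k] %in% c(0, 1)))
        stop("family ", i, ": binary trait ", k, " not coded 0/1")
    families[[i]] <- f
  }
  Y <- do.call(rbind, lapply(families, function(f) f$y))
  X <- do.call(rbind, lapply(families, function(f) f$x))
  G <- if (p > 0L) do.call(rbind, lapply(families, function(f) f$g)) else NULL
  n_vec <- vapply(families, function(f) nrow(f$y), integer(1))
  fid <- vapply(seq_along(families), function(i) {
    if (is.null(families[[i]]$fid)) as.character(i) else as.character(families[[i]]$fid)
  }, character(1))
  has_founder <- all(vapply(families, function(f) !is.null(f$founder), logical(1)))
  founder <- if (has_founder)
    unlist(lapply(families, function(f) as.logical(f$founder)), use.names = FALSE)
  else NULL
  fds_stacked(Y, X, G, n_vec, trait_kinds, fid = fid, founder = founder)
}

# Internal constructor on pre-stacked matrices (rows grouped by family in
# order); used by the simulators, which build valid data by construction.
fds_stacked <- function(Y, X, G, n_vec, trait_kinds, fid = NULL, founder = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  M <- nrow(Y)
  if (sum(n_vec) != M || nrow(X) != M) stop("stacked dimensions inconsistent")
  if (!is.null(G) && nrow(G) != M) stop("stacked genotype rows inconsistent")
  if (!is.null(founder) && length(founder) != M) stop("founder flag length mismatch")
  if (is.null(fid)) fid <- as.character(seq_along(n_vec))
  structure(list(Y = Y, X = X, G = G,
                 n_vec = as.integer(n_vec), fid = fid, founder = founder,
                 trait_kinds = trait_kinds, K = ncol(Y), q = ncol(X) - 1L,
                 p = if (is.null(G)) 0L else ncol(G)),
            class = "family_data_set")
}

#' Extract the data blocks of one family
#'
#' @param data a `family_data_set`.
#' @param i family index.
#' @return list with `y`, `x`, `g` (or `NULL`), `fid`, `founder`.
#' @export
family_blocks <- function(data, i) {
  stopifnot(inherits(data, "family_data_set"))
  rows <- rep(seq_along(data$n_vec), data$n_vec) == i
  list(y = data$Y[rows, , drop = FALSE],
       x = data$X[rows, , drop = FALSE],
       g = if (is.null(data$G)) NULL else data$G[rows, , drop = FALSE],
       fid = data$fid[i],
       founder = if (is.null(data$founder)) NULL else data$founder[rows])
}

#' @export
print.family_data_set <- function(x, ...) {
  cat("family_data_set:", length(x$n_vec), "families,", sum(x$n_vec),
      "subjects, K =", x$K, paste0("(", paste(x$trait_kinds, collapse = ", "), ")"),
      ", covariates q =", x$q, ", variants p =", x$p, "\n")
  invisible(x)
}

link_funs <- function(kind) {
  if (kind == "continuous") {
    list(mu = function(eta) eta, avar = function(mu) rep(1, length(mu)))
  } else {
    list(mu = function(eta) 1 / (1 + exp(-eta)),
         avar = function(mu) mu * (1 - mu))
  }
}

#' Fit the joint-GEE null model for K correlated traits
#'
#' Estimates the covariate coefficients `alpha`, the scale `phi`, and the
#' working correlation structures of the joint (multivariate-response)
#' GEE model under the null hypothesis of no genetic effect.  The working
#' covariance of a family's stacked response is
#' `V_i = A_i^{1/2} (R_K %x% R_ni) A_i^{1/2} phi`, where `R_ni` captures
#' correlation between subjects of a cluster and `R_K` correlation
#' between traits of a subject.  Correlation parameters come from moment
#' estimators on Pearson residuals; `alpha` is updated by Fisher scoring
#' of the GEE estimating equation; the two are alternated to convergence.
#'
#' The scale `phi` is estimated from Pearson residuals when all traits
#' are continuous and fixed at 1 when all are binary (standard GEE
#' practice).  Mixing continuous and binary traits in one model is not
#' supported.
#'
#' @param data a [family_data_set()].
#' @param corstr_n working within-cluster correlation structure:
#'   `"independence"`, `"exchangeable"`, or `"unstructured"`
#'   (unstructured requires a constant cluster size).
#' @param corstr_K working multivariate-response structure (same choices).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   max-norm of the `alpha` update.
#' @return an object of class `jgee_fit` with elements `alpha`
#'   (`(q+1) x K`), `phi`, `R_n`, `R_K`, stacked per-subject matrices
#'   `mu`, `A`, `S` (the standardized residuals `V^{-1}(y - mu)` arranged
#'   subjects x traits), the family index `fam_index`, convergence
#'   diagnostics, and the data.
#' @export
jgee_null <- function(data, corstr_n = "exchangeable", corstr_K = "exchangeable",
                      max_iter = 50L, tol = 1e-6) {
  stopifnot(inherits(data, "family_data_set"))
  corstr_n <- match.arg(corstr_n, c("independence", "exchangeable", "unstructured"))
  corstr_K <- match.arg(corstr_K, c("independence", "exchangeable", "unstructured"))
  if (length(data$n_vec) < 2L) stop("need at least two families")
  kinds <- data$trait_kinds
  if (length(unique(kinds)) > 1L)
    stop("mixing continuous and binary traits in one model is not supported")
  kind <- kinds[1]
  K <- data$K; q1 <- data$q + 1L
  n_vec <- data$n_vec
  if (corstr_n == "unstructured" && length(unique(n_vec)) > 1L)
    stop("unstructured within-cluster correlation requires a constant cluster size")
  N <- length(n_vec); M <- sum(n_vec)
  fam_index <- rep(seq_len(N), n_vec)
  Y <- data$Y
  X <- data$X
  lk <- link_funs(kind)
  fixed_phi <- (kind == "binary")

  # warm start: trait-wise GLM under independence
  alpha <- matrix(0, q1, K)
  for (k in seq_len(K)) {
    alpha[, k] <- if (kind == "continuous") {
      stats::lm.fit(X, Y[, k])$coefficients
    } else {
      suppressWarnings(stats::glm.fit(X, Y[, k],
        family = stats::binomial())$coefficients)
    }
  }

  equal_n <- length(unique(n_vec)) == 1L
  n0 <- n_vec[1]
  iter <- 0L; delta_norm <- Inf; converged <- FALSE
  phi <- 1; R_n <- diag(n0); R_K <- diag(K)
  flags <- character(0)

  repeat {
    iter <- iter + 1L
    eta <- X %*% alpha
    mu <- lk$mu(eta)
    A <- matrix(lk$avar(as.vector(mu)), M, K)
    if (kind == "binary" && any(A < 1e-10)) {
      flags <- unique(c(flags, "separation"))
      A <- pmax(A, 1e-10)
    }
    resid <- Y - mu
    rstd <- resid / sqrt(A)
    phi <- if (fixed_phi) 1 else
      sum(rstd^2) / max(M * K - q1 * K, 1)
    R_n <- estimate_Rn(rstd, fam_index, n_vec, corstr_n, phi)
    R_K <- estimate_RK(rstd, corstr_K, phi)
    C <- make_pd(R_K %x% R_n_for(R_n, n0))  # used on the equal-n fast path

    if (equal_n) {
      upd <- gee_step_equal_n(X, A, resid, fam_index, N, n0, K, q1, C, phi)
    } else {
      upd <- gee_step_general(X, A, resid, fam_index, n_vec, R_n, R_K, q1, K)
    }
    delta <- upd$delta
    alpha <- alpha + matrix(delta, q1, K)
    delta_norm <- max(abs(delta))
    if (delta_norm < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) flags <- unique(c(flags, "non-convergence"))

  # final quantities at the converged alpha
  eta <- X %*% alpha
  mu <- lk$mu(eta)
  A <- matrix(lk$avar(as.vector(mu)), M, K)
  if (kind == "binary") A <- pmax(A, 1e-10)
  resid <- Y - mu
  rstd <- resid / sqrt(A)
  phi <- if (fixed_phi) 1 else sum(rstd^2) / max(M * K - q1 * K, 1)
  R_n <- estimate_Rn(rstd, fam_index, n_vec, corstr_n, phi)
  R_K <- estimate_RK(rstd, corstr_K, phi)

  # standardized residuals S_i = V_i^{-1} (y_i - mu_i), subject x trait layout
  S <- matrix(0, M, K)
  if (equal_n) {
    C <- make_pd(R_K %x% R_n_for(R_n, n0))
    Cinv <- solve(C)
    # per family: S = A^{-1/2} Cinv (A^{-1/2} r) / phi, vectorized over families
    RS <- matrix(0, N, n0 * K)
    for (k in seq_len(K))
      RS[, (k - 1L) * n0 + seq_len(n0)] <- matrix(rstd[, k], N, n0, byrow = TRUE)
    TS <- RS %*% Cinv
    for (k in seq_len(K))
      S[, k] <- as.vector(t(TS[, (k - 1L) * n0 + seq_len(n0), drop = FALSE]))
    S <- S / sqrt(A) / phi
  } else {
    for (i in seq_len(N)) {
      rows <- which(fam_index == i)
      ni <- length(rows)
      C <- make_pd(R_K %x% R_n_for(R_n, ni))
      ai <- as.vector(A[rows, ])          # trait-major
      ri <- as.vector(resid[rows, ])
      Vi <- sqrt(ai) * t(sqrt(ai) * t(C)) * phi
      S[rows, ] <- matrix(solve(Vi, ri), ni, K)
    }
  }

  structure(list(alpha = alpha, phi = phi, R_n = R_n, R_K = R_K,
                 corstr_n = corstr_n, corstr_K = corstr_K,
                 mu = mu, A = A, S = S, resid = resid,
                 fam_index = fam_index, n_vec = n_vec,
                 trait_kind = kind, K = K, q = data$q,
                 iterations = iter, delta_norm = delta_norm,
                 converged = converged, flags = flags,
                 data = data),
            class = "jgee_fit")
}

# R_n may be stored for the common cluster size; rebuild exchangeable /
# independence structures for another size when clusters are unequal.
R_n_for <- function(R_n, ni) {
  if (nrow(R_n) == ni) return(R_n)
  if (all(R_n == diag(nrow(R_n)))) return(diag(ni))
  rho <- R_n[1, 2]
  m <- matrix(rho, ni, ni); diag(m) <- 1
  m
}

estimate_Rn <- function(rstd, fam_index, n_vec, corstr, phi) {
  n0 <- n_vec[1]; K <- ncol(rstd); N <- length(n_vec)
  if (corstr == "independence") return(diag(n0))
  if (corstr == "exchangeable") {
    ssq <- rowsum(rstd^2, fam_index)
    s <- rowsum(rstd, fam_index)
    num <- sum(s^2 - ssq)
    den <- phi * K * sum(n_vec * (n_vec - 1))
    rho <- if (den > 0) num / den else 0
    rho <- max(min(rho, 0.99), -0.99 / max(n_vec - 1, 1))
    R <- matrix(rho, n0, n0); diag(R) <- 1
    return(make_pd(R))
  }
  # unstructured (constant cluster size enforced by the caller)
  R <- matrix(0, n0, n0)
  for (k in seq_len(K)) {
    Rk <- matrix(rstd[, k], N, n0, byrow = TRUE)
    R <- R + crossprod(Rk)
  }
  R <- R / (phi * N * K)
  D <- sqrt(pmax(diag(R), 1e-12))
  R <- R / tcrossprod(D)
  diag(R) <- 1
  make_pd(R)
}

estimate_RK <- function(rstd, corstr, phi) {
  K <- ncol(rstd); M <- nrow(rstd)
  if (corstr == "independence" || K == 1L) return(diag(K))
  if (corstr == "exchangeable") {
    t_sub <- rowSums(rstd)
    num <- sum(t_sub^2 - rowSums(rstd^2))
    den <- phi * M * K * (K - 1)
    gam <- if (den > 0) num / den else 0
    gam <- max(min(gam, 0.99), -0.99 / (K - 1))
    R <- matrix(gam, K, K); diag(R) <- 1
    return(make_pd(R))
  }
  R <- crossprod(rstd) / (phi * M)
  D <- sqrt(pmax(diag(R), 1e-12))
  R <- R / tcrossprod(D)
  diag(R) <- 1
  make_pd(R)
}

# Nudge a symmetric matrix to positive definiteness by shrinking toward I.
# Cheap path first: if Cholesky succeeds the matrix is already PD.
make_pd <- function(R, eps = 1e-6) {
  R <- (R + t(R)) / 2
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (ok) return(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > eps) return(R)
  s <- (eps - min(ev)) / (1 - min(ev))
  R2 <- R * (1 - s) + diag(nrow(R)) * s
  (R2 + t(R2)) / 2
}

# One Fisher-scoring step with all clusters the same size: all per-family
# quantities live in N x n matrices, and the Kronecker inverse is shared.
gee_step_equal_n <- function(X, A, resid, fam_index, N, n0, K, q1, C, phi) {
  Cinv <- solve(C)
  # T[[k]][[m]] = N x n matrix of sqrt(A[., k]) * x[., m]
  sqA <- sqrt(A)
  Tm <- vector("list", K)
  for (k in seq_len(K)) {
    Tm[[k]] <- lapply(seq_len(q1), function(m)
      matrix(sqA[, k] * X[, m], N, n0, byrow = TRUE))
  }
  Rk <- lapply(seq_len(K), function(k)
    matrix(resid[, k] / sqA[, k], N, n0, byrow = TRUE))
  np <- q1 * K
  LHS <- matrix(0, np, np)
  RHS <- numeric(np)
  for (k in seq_len(K)) for (k2 in seq_len(K)) {
    Cn <- Cinv[(k - 1L) * n0 + seq_len(n0), (k2 - 1L) * n0 + seq_len(n0)]
    for (m in seq_len(q1)) {
      TmC <- Tm[[k]][[m]] %*% Cn
      r_idx <- (k - 1L) * q1 + m
      RHS[r_idx] <- RHS[r_idx] + sum(TmC * Rk[[k2]])
      for (m2 in seq_len(q1)) {
        c_idx <- (k2 - 1L) * q1 + m2
        LHS[r_idx, c_idx] <- LHS[r_idx, c_idx] + sum(TmC * Tm[[k2]][[m2]])
      }
    }
  }
  delta <- tryCatch(solve(LHS, RHS), error = function(e)
    solve(LHS + diag(1e-8, np), RHS))
  list(delta = delta)
}

gee_step_general <- function(X, A, resid, fam_index, n_vec, R_n, R_K, q1, K) {
  np <- q1 * K
  LHS <- matrix(0, np, np)
  RHS <- numeric(np)
  for (i in seq_along(n_vec)) {
    rows <- which(fam_index == i)
    ni <- length(rows)
    C <- make_pd(R_K %x% R_n_for(R_n, ni))
    ai <- as.vector(A[rows, , drop = FALSE])
    ri <- as.vector(resid[rows, , drop = FALSE])
    xi <- X[rows, , drop = FALSE]
    Wi <- matrix(0, ni * K, np)    # A^{1/2} (I_K kron x_i)
    for (k in seq_len(K)) {
      rws <- (k - 1L) * ni + seq_len(ni)
      cls <- (k - 1L) * q1 + seq_len(q1)
      Wi[rws, cls] <- sqrt(ai[rws]) * xi
    }
    tmp <- solve(C, cbind(Wi, ri / sqrt(ai)))
    LHS <- LHS + crossprod(Wi, tmp[, seq_len(np), drop = FALSE])
    RHS <- RHS + crossprod(Wi, tmp[, np + 1L])
  }
  delta <- tryCatch(solve(LHS, RHS), error = function(e)
    solve(LHS + diag(1e-8, np), RHS))
  list(delta = as.vector(delta))
}

#' Working covariance matrix of one family
#'
#' Reconstructs `V_i = A_i^{1/2} (R_K %x% R_ni) A_i^{1/2} phi` for family
#' `i` of a fitted null model, in the trait-major layout of the stacked
#' response.
#'
#' @param fit a `jgee_fit`.
#' @param i family index.
#' @return the `(n_i K) x (n_i K)` working covariance matrix.
#' @export
working_covariance <- function(fit, i) {
  rows <- which(fit$fam_index == i)
  ni <- length(rows)
  C <- make_pd(fit$R_K %x% R_n_for(fit$R_n, ni))
  ai <- as.vector(fit$A[rows, , drop = FALSE])
  if (any(ai <= 0)) stop("non-positive variance-function value")
  sqrt(ai) * t(sqrt(ai) * t(C)) * fit$phi
}

#' Standardized residual blocks of a fitted null model
#'
#' Returns the per-family standardized residuals
#' `S_i = V_i^{-1}(y_i - mu_i)`, partitioned into per-trait blocks
#' `S_ik`; these are the inputs of every association statistic.
#'
#' @param fit a `jgee_fit`.
#' @return list over families; each element an `n_i x K` matrix.
#' @export
standardized_residuals <- function(fit) {
  lapply(seq_along(fit$n_vec), function(i)
    fit$S[fit$fam_index == i, , drop = FALSE])
}

#' @export
print.jgee_fit <- function(x, ...) {
  cat("Joint-GEE null model (", x$trait_kind, " traits, K = ", x$K, ")\n", sep = "")
  cat("  families:", length(x$n_vec), " subjects:", length(x$fam_index), "\n")
  cat("  working structures:", x$corstr_n, "(cluster) x", x$corstr_K, "(trait)\n")
  cat("  phi =", format(x$phi, digits = 4),
      " iterations =", x$iterations,
      " converged =", x$converged, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  cat("alpha:\n")
  print(round(x$alpha, 4))
  invisible(x)
}
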