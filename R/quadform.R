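#' Tail probability of a positive mixture of 1-df chi-squares
#'
#' Computes `P(sum_l lambda_l * chisq_1 > q)` for non-negative weights
#' `lambda`, the null distribution of kernel (quadratic-form) association
#' statistics.  The primary route is the Kuonen saddlepoint approximation
#' (Lugannani--Rice form) on the cumulant generating function
#' `K(t) = -1/2 sum log(1 - 2 lambda_l t)`; if the saddlepoint equation
#' cannot be solved, a Satterthwaite moment-matching approximation
#' (scaled chi-square with the first two moments matched) is used and the
#' result is flagged.
#'
#' @param q observed value of the quadratic form (scalar, `>= 0` for a
#'   meaningful tail; `q <= 0` returns 1).
#' @param lambda numeric vector of mixture weights (eigenvalues); must
#'   contain at least one positive entry.  Near-zero components (below
#'   `1e-10 * max(lambda)`) are dropped.
#' @return a list with elements `p` (the survival probability, floored at
#'   `1e-300`) and `fallback` (`TRUE` if the moment-matching route was
#'   taken).
#' @seealso [eigen_weights()]
#' @examples
#' mixture_chisq_sf(qchisq(0.95, df = 1), 1)$p   # 0.05
#' mixture_chisq_sf(10, c(2, 1, 0.5))$p
#' @export
mixture_chisq_sf <- function(q, lambda) {
  if (!is.numeric(lambda) || length(lambda) == 0L || any(!is.finite(lambda)))
    stop("'lambda' must be a finite numeric vector")
  if (any(lambda < 0)) stop("'lambda' must be non-negative")
  lmax <- max(lambda)
  if (lmax <= 0) stop("all mixture weights are zero")
  lambda <- lambda[lambda > 1e-10 * lmax]
  if (!is.finite(q)) stop("'q' must be finite")
  if (q <= 0) return(list(p = 1, fallback = FALSE))

  # equal weights: the mixture is exactly a scaled chi-square
  if (diff(range(lambda)) <= 1e-12 * lmax) {
    p <- stats::pchisq(q / lambda[1], df = length(lambda), lower.tail = FALSE)
    return(list(p = max(min(p, 1), 1e-300), fallback = FALSE))
  }

  p <- saddlepoint_sf(q, lambda)
  fallback <- FALSE
  if (is.na(p)) {
    p <- satterthwaite_sf(q, lambda)
    fallback <- TRUE
  }
  list(p = max(min(p, 1), 1e-300), fallback = fallback)
}

# Saddlepoint survival probability (Lugannani-Rice form); NA signals
# failure so the caller can fall back to moment matching.
saddlepoint_sf <- function(q, lambda) {
  mu <- sum(lambda)
  # At the mean the saddlepoint is zeta = 0 and the formula is singular
  # (w and v both vanish); interpolate across a small window there.
  if (abs(q - mu) < 1e-3 * mu) {
    p1 <- saddlepoint_sf(mu * (1 - 2e-3), lambda)
    p2 <- saddlepoint_sf(mu * (1 + 2e-3), lambda)
    if (is.na(p1) || is.na(p2)) return(NA_real_)
    h <- (q - mu * (1 - 2e-3)) / (4e-3 * mu)
    return((1 - h) * p1 + h * p2)
  }

  Kfun <- function(t) -0.5 * sum(log1p(-2 * lambda * t))
  K1 <- function(t) sum(lambda / (1 - 2 * lambda * t))
  K2 <- function(t) 2 * sum(lambda^2 / (1 - 2 * lambda * t)^2)

  tmax <- 1 / (2 * max(lambda))
  # K' is increasing on (-Inf, tmax): bracket the root of K'(t) = q.
  if (q > mu) {
    lo <- 0
    hi <- tmax * (1 - 1e-12)
    # ensure K1(hi) > q; K1 -> Inf as t -> tmax so shrink the gap if needed
    for (i in 1:60) {
      if (K1(hi) > q) break
      hi <- tmax - (tmax - hi) / 10
    }
    if (K1(hi) <= q) return(NA_real_)
  } else {
    hi <- 0
    lo <- -1
    for (i in 1:60) {
      if (K1(lo) < q) break
      lo <- lo * 2
    }
    if (K1(lo) >= q) return(NA_real_)
  }
  zeta <- tryCatch(
    stats::uniroot(function(t) K1(t) - q, c(lo, hi), tol = 1e-14)$root,
    error = function(e) NA_real_
  )
  if (is.na(zeta)) return(NA_real_)

  w <- sign(zeta) * sqrt(max(2 * (zeta * q - Kfun(zeta)), 0))
  v <- zeta * sqrt(K2(zeta))
  if (!is.finite(w) || !is.finite(v) || abs(w) < 1e-6 || abs(v) < 1e-300)
    return(NA_real_)
  p <- stats::pnorm(w, lower.tail = FALSE) + stats::dnorm(w) * (1 / v - 1 / w)
  if (!is.finite(p) || p < 0) return(NA_real_)
  p
}

# Scaled chi-square with the first two moments matched: Q ~ a * chisq_d,
# a = sum(lambda^2)/sum(lambda), d = sum(lambda)^2/sum(lambda^2).
satterthwaite_sf <- function(q, lambda) {
  a <- sum(lambda^2) / sum(lambda)
  d <- sum(lambda)^2 / sum(lambda^2)
  stats::pchisq(q / a, df = d, lower.tail = FALSE)
}

#' Eigenvalue weights of a null covariance matrix
#'
#' Extracts the mixture weights for the chi-square mixture null
#' distribution: the eigenvalues of a symmetric positive semidefinite
#' matrix, sorted descending, with numerically-zero components dropped.
#' Tiny negative eigenvalues (rounding noise, above `-1e-8 * max`) are
#' clipped to zero; anything more negative is treated as evidence of an
#' upstream construction error.
#'
#' @param M symmetric PSD matrix (symmetrized internally as `(M + t(M))/2`).
#' @return numeric vector of positive eigenvalues, decreasing.
#' @export
eigen_weights <- function(M) {
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop("covariance matrix has non-finite entries")
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  top <- max(ev, 0)
  if (top == 0) return(numeric(0))
  if (any(ev < -1e-8 * top))
    stop("matrix has a substantially negative eigenvalue; not PSD")
  ev <- pmax(ev, 0)
  ev <- ev[ev >= 1e-10 * top]
  sort(ev, decreasing = TRUE)
}
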