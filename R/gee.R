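#' Poisson GEE with exchangeable working correlation
#'
#' Marginal Poisson log-link regression for clustered counts, estimated by
#' generalized estimating equations with an exchangeable working
#' correlation and robust (sandwich) standard errors. Written against the
#' standard Liang-Zeger moment estimators; no GEE package is assumed.
#'
#' @param formula model formula (counts on the left).
#' @param data data.frame.
#' @param id cluster identifier (unquoted column name as string).
#' @param offset optional offset column name (log scale).
#' @param maxit,tol Fisher-scoring controls.
#' @return object of class `pois_gee`: coefficients, robust vcov,
#'   naive vcov, working correlation `alpha`, dispersion `phi`,
#'   n_clusters, convergence flag. Robust SEs are flagged unreliable with
#'   fewer than 3 clusters per the small-sample caveat.
#' @export
pois_gee <- function(formula, data, id, offset = NULL,
                     maxit = 50L, tol = 1e-8) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  keep <- as.integer(rownames(mf))
  cl <- factor(data[[id]][keep])
  off <- if (is.null(offset)) rep(0, length(y)) else data[[offset]][keep]
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (all(y == 0))
    stop("all counts are zero: rate ratios are inestimable", call. = FALSE)
  p <- ncol(X)
  beta <- stats::coef(stats::glm.fit(X, y, offset = off,
                                     family = stats::poisson()))
  groups <- split(seq_along(y), cl)
  alpha <- 0; phi <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    r <- (y - mu) / sqrt(mu)                     # Pearson residuals
    phi <- sum(r^2) / (length(y) - p)
    num <- 0; den <- 0
    for (g in groups) {
      ni <- length(g)
      if (ni > 1L) {
        num <- num + (sum(r[g])^2 - sum(r[g]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    alpha <- if (den > p) num / (phi * (den - p)) else 0
    alpha <- max(min(alpha, 0.99), -0.99)
    U <- matrix(0, p, 1); H <- matrix(0, p, p)
    for (g in groups) {
      ni <- length(g)
      Ai <- sqrt(mu[g])
      R <- matrix(alpha, ni, ni); diag(R) <- 1
      Di <- X[g, , drop = FALSE] * mu[g]
      Vinv <- solve(R * tcrossprod(Ai)) / phi
      U <- U + crossprod(Di, Vinv %*% (y[g] - mu[g]))
      H <- H + crossprod(Di, Vinv %*% Di)
    }
    step <- tryCatch(solve(H, U), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break   # singular/degenerate
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta) + off
  mu <- exp(eta)
  M <- matrix(0, p, p); H <- matrix(0, p, p)
  for (g in groups) {
    ni <- length(g)
    Ai <- sqrt(mu[g])
    R <- matrix(alpha, ni, ni); diag(R) <- 1
    Di <- X[g, , drop = FALSE] * mu[g]
    Vinv <- solve(R * tcrossprod(Ai)) / phi
    si <- crossprod(Di, Vinv %*% (y[g] - mu[g]))
    M <- M + tcrossprod(si)
    H <- H + crossprod(Di, Vinv %*% Di)
  }
  Hinv <- tryCatch(solve(H), error = function(e) {
    warning("singular GEE information matrix; using pseudo-inverse",
            call. = FALSE)
    sv <- svd(H)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = Hinv %*% M %*% Hinv,
                 naive_vcov = Hinv,
                 alpha = alpha, phi = phi,
                 n_clusters = length(groups),
                 robust_se_reliable = length(groups) >= 3L,
                 converged = converged),
            class = "pois_gee")
}

#' @export
coef.pois_gee <- function(object, ...) object$coefficients

#' @export
vcov.pois_gee <- function(object, ...) object$vcov

#' @export
print.pois_gee <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  cat("Poisson GEE (exchangeable), ", x$n_clusters, " clusters, alpha = ",
      round(x$alpha, 3), "\n", sep = "")
  print(cbind(estimate = x$coefficients, robust_se = se,
              z = x$coefficients / se))
  if (!x$robust_se_reliable)
    cat("warning: < 3 clusters; robust SEs unreliable\n")
  invisible(x)
}
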