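# Restricted maximum likelihood for variance-component mixed models.
#
# Model: y = X beta + sum_i u_i + e with Var(u_i) = K_i sigma_i^2 and
# Var(e) = I sigma_e^2. The REML log-likelihood (constant omitted) is
#   l(theta) = -1/2 [ log|V| + log|X' V^-1 X| + y' P y ],
#   V = sum_i sigma_i^2 K_i + sigma_e^2 I,
#   P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1.
# Estimation follows the GREML recipe: one EM-REML step from the starting
# values, then average-information (AI) updates with step halving whenever
# the likelihood would decrease, and components falling below the floor
# (1e-6 x phenotypic variance) constrained there. Standard errors come from
# the inverse AI matrix at the optimum. All linear algebra is dense with a
# single Cholesky factorization of V per iteration.

#' Specify a variance-component mixed model
#'
#' @param y Numeric phenotype vector (for case-control data, 0/1 status on
#'   the observed scale).
#' @param X Fixed-effects design matrix including the intercept (typically
#'   intercept, sex, array, PC1..PC10). Must have full column rank.
#' @param K Named list of n x n covariance structures (e.g. `list(G = ...)`
#'   for the null genome-wide model, `list(G = ..., Q = ...)` with a
#'   regional GRM for the alternative). The residual identity structure is
#'   implicit and always last.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(y, X, K) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  .assert(nrow(X) == n, "X rows must match length(y)", "rhmap_dim")
  .assert(qr(X)$rank == ncol(X), "X must have full column rank",
          "rhmap_rank")
  if (is.null(names(K)) || any(!nzchar(names(K))))
    names(K) <- paste0("K", seq_along(K))
  for (nm in names(K)) {
    Ki <- K[[nm]]
    if (inherits(Ki, "grm")) K[[nm]] <- Ki <- Ki$mat
    .assert(is.matrix(Ki) && all(dim(Ki) == n),
            paste0("structure ", nm, " must be n x n"), "rhmap_dim")
  }
  # Error-contrast (projected) formulation: with A an orthonormal basis of
  # the orthogonal complement of col(X), the restricted likelihood is
  #   -1/2 [ log|A'VA| + log|X'X| + y* ' (A'VA)^-1 y* ],  y* = A'y,
  # identical to -1/2 [ log|V| + log|X'V^-1X| + y'Py ] but immune to the
  # structural singularity of V at the residual boundary (a GRM built from
  # in-sample frequencies annihilates the ones vector, which lies in
  # col(X) via the intercept and cancels analytically, not numerically).
  qx <- qr(X)
  A <- qr.Q(qx, complete = TRUE)[, -seq_len(ncol(X)), drop = FALSE]
  Ks <- lapply(K, function(Ki) crossprod(A, Ki %*% A))
  structure(list(y = y, X = X, K = K,
                 ys = as.vector(crossprod(A, y)), Ks = Ks,
                 logdet_xtx = sum(log(abs(diag(qr.R(qx))) ^ 2))),
            class = "model_spec")
}

# Evaluate the projected V* = A'VA, its inverse M, M y* and the
# log-likelihood at theta (length(K) genetic components then the residual).
.reml_eval <- function(spec, theta) {
  m <- length(spec$Ks)
  Vs <- diag(theta[m + 1], length(spec$ys))
  for (i in seq_len(m)) Vs <- Vs + theta[i] * spec$Ks[[i]]
  R <- tryCatch(chol(Vs), error = function(e)
    .stop_rhmap(paste0("V is not positive definite at theta = ",
                       paste(signif(theta, 4), collapse = ", ")),
                "rhmap_numeric"))
  M <- chol2inv(R)
  My <- as.vector(M %*% spec$ys)
  ll <- -0.5 * (2 * sum(log(diag(R))) + spec$logdet_xtx +
                  sum(spec$ys * My))
  list(ll = ll, M = M, My = My)
}

#' REML log-likelihood
#'
#' Evaluates the restricted log-likelihood (additive constant omitted) at
#' the given variance components.
#'
#' @param spec A [model_spec].
#' @param components Numeric vector: one variance per structure in
#'   `spec$K`, then the residual variance. All non-negative, not all zero,
#'   and V must be positive definite.
#' @return The log-likelihood value.
#' @export
reml_loglik <- function(spec, components) {
  .assert(length(components) == length(spec$K) + 1,
          "need one component per structure plus the residual", "rhmap_dim")
  .assert(all(components >= 0) && any(components > 0),
          "components must be non-negative and not all zero", "rhmap_value")
  .reml_eval(spec, components)$ll
}

# Score and AI matrix at the current evaluation, in the projected space
# where P = A M A' (structures: K_1..K_m, then the identity residual).
.score_ai <- function(spec, ev) {
  m <- length(spec$Ks)
  M <- ev$M
  My <- ev$My
  # v_i = K*_i M y* (residual: M y*); tr(P K_i) = sum(M * K*_i)
  v <- vector("list", m + 1)
  trPK <- numeric(m + 1)
  for (i in seq_len(m)) {
    v[[i]] <- as.vector(spec$Ks[[i]] %*% My)
    trPK[i] <- sum(M * spec$Ks[[i]])
  }
  v[[m + 1]] <- My
  trPK[m + 1] <- sum(diag(M))
  yPKPy <- vapply(v, function(vi) sum(My * vi), 0)
  score <- -0.5 * (trPK - yPKPy)
  AI <- matrix(0, m + 1, m + 1)
  Mv <- lapply(v, function(vi) as.vector(M %*% vi))
  for (i in seq_len(m + 1))
    for (j in i:(m + 1))
      AI[i, j] <- AI[j, i] <- 0.5 * sum(v[[i]] * Mv[[j]])
  list(score = score, AI = AI, yPKPy = yPKPy, trPK = trPK)
}

#' Fit variance components by AI-REML
#'
#' One EM-REML step from the starting values, then average-information
#' updates until the log-likelihood changes by less than `tol` (default
#' `1e-4`) or `max_iter` iterations. Proposed steps that would decrease the
#' likelihood are halved (up to 30 times, so that near-singular
#' average-information steps along flat ridges still collapse to an
#' accepted micro-step); components falling below the
#' floor (`1e-6` times the phenotypic variance) are constrained there and
#' flagged. Non-convergence is reported via the `converged` flag, never an
#' exception.
#'
#' @param spec A [model_spec].
#' @param start Optional numeric vector of starting values (genetic
#'   components then residual); default: phenotypic variance split equally.
#' @param max_iter,tol Iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `variance_estimate`: `components` (named),
#'   `se` (from the inverse AI matrix), `loglik`, `converged`,
#'   `constrained` (logical per component), `trace` (per-iteration
#'   log-likelihood), `n`, `floor`.
#' @export
fit_reml <- function(spec, start = NULL, max_iter = 100L, tol = 1e-4) {
  m <- length(spec$K)
  nc <- m + 1L
  n <- length(spec$y)
  varP <- var(spec$y)
  floor_v <- 1e-6 * varP
  theta <- if (is.null(start)) rep(varP / nc, nc) else as.numeric(start)
  .assert(length(theta) == nc, "start has wrong length", "rhmap_dim")
  theta <- pmax(theta, floor_v)
  nms <- c(paste0("sigma2_", names(spec$K)), "sigma2_e")

  ev <- .reml_eval(spec, theta)
  sa <- .score_ai(spec, ev)
  # EM-REML first step: theta_i += theta_i^2 (y'PK_iPy - tr(PK_i)) / n
  theta_new <- pmax(theta + theta^2 * (sa$yPKPy - sa$trPK) / n, floor_v)
  ev_new <- tryCatch(.reml_eval(spec, theta_new), error = function(e) NULL)
  if (!is.null(ev_new) && ev_new$ll >= ev$ll - 1e-10) {
    theta <- theta_new
    ev <- ev_new
  }
  trace <- ev$ll
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(max_iter)) {
    sa <- .score_ai(spec, ev)
    AI <- sa$AI
    # active set: components held at the floor whose score pushes further
    # down stay constrained; the AI system is solved for the free ones
    free <- !(theta <= floor_v & sa$score < 0)
    if (!any(free)) {
      converged <- TRUE
      break
    }
    delta <- rep(0, nc)
    sub <- tryCatch(solve(sa$AI[free, free, drop = FALSE], sa$score[free]),
                    error = function(e) NULL)
    if (is.null(sub))
      sub <- (theta^2 * (sa$yPKPy - sa$trPK) / n)[free]
    delta[free] <- sub
    step <- 1
    ok <- FALSE
    for (h in 0:30) {
      cand <- pmax(theta + step * delta, floor_v)
      ev_c <- tryCatch(.reml_eval(spec, cand), error = function(e) NULL)
      if (!is.null(ev_c) && ev_c$ll >= ev$ll - 1e-10) {
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok) {                            # AI failed: try one EM step
      cand <- pmax(theta + theta^2 * (sa$yPKPy - sa$trPK) / n, floor_v)
      ev_c <- tryCatch(.reml_eval(spec, cand), error = function(e) NULL)
      ok <- !is.null(ev_c) && ev_c$ll >= ev$ll - 1e-10
    }
    if (!ok) break                        # cannot improve: stop here
    dll <- ev_c$ll - ev$ll
    theta <- cand
    ev <- ev_c
    trace <- c(trace, ev$ll)
    if (abs(dll) < tol) {
      converged <- TRUE
      break
    }
  }
  sa <- .score_ai(spec, ev)
  se <- tryCatch(sqrt(pmax(diag(solve(sa$AI)), 0)),
                 error = function(e) rep(NA_real_, nc))
  structure(list(components = setNames(theta, nms),
                 se = setNames(se, nms),
                 loglik = ev$ll,
                 converged = converged,
                 constrained = setNames(theta <= floor_v, nms),
                 ai = sa$AI,
                 trace = trace,
                 n = n,
                 floor = floor_v),
            class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat("AI-REML fit", if (!x$converged) "(NOT converged)", "\n")
  est <- data.frame(component = names(x$components),
                    estimate = unname(x$components),
                    se = unname(x$se),
                    constrained = unname(x$constrained))
  print(est, row.names = FALSE)
  cat(sprintf("logL = %.6f after %d iterations\n", x$loglik,
              length(x$trace)))
  invisible(x)
}

#' Heritability (variance ratio) from a fit
#'
#' Ratio of one component to the total phenotypic variance, with a
#' delta-method standard error from the inverse AI matrix.
#'
#' @param fit A `variance_estimate`.
#' @param component Name or index of the numerator component.
#' @return List `ratio`, `se`.
#' @export
variance_ratio <- function(fit, component = 1L) {
  th <- fit$components
  total <- sum(th)
  i <- if (is.character(component)) match(component, names(th))
  else as.integer(component)
  r <- th[i] / total
  grad <- rep(-th[i] / total^2, length(th))
  grad[i] <- (total - th[i]) / total^2
  cov <- tryCatch(solve(fit$ai), error = function(e) NULL)
  se <- if (is.null(cov)) NA_real_
  else sqrt(max(0, as.numeric(t(grad) %*% cov %*% grad)))
  list(ratio = unname(r), se = se)
}

#' Likelihood-ratio test for a regional variance component
#'
#' LRT = -2 ln(L0/L1) = 2 (l1 - l0), floored at zero. Because the regional
#' variance is tested on the boundary of its parameter space, the null
#' distribution is a 50-50 mixture of chi-square with 0 and 1 degrees of
#' freedom: p = 0.5 * P(chi2_1 > LRT), and p = 0.5 when LRT = 0.
#'
#' @param null_fit,alt_fit `variance_estimate`s of the null (genome-wide
#'   only) and alternative (plus regional) models on the same data.
#' @return An object of class `lrt_result`: `l0`, `l1`, `lrt`, `p`,
#'   `optimizer_failure` (TRUE when l1 fell below l0 by more than numeric
#'   tolerance and the statistic was floored).
#' @export
lrt_regional <- function(null_fit, alt_fit) {
  l0 <- null_fit$loglik
  l1 <- alt_fit$loglik
  raw <- 2 * (l1 - l0)
  failure <- raw < -1e-6
  lrt <- max(0, raw)
  p <- if (lrt <= 0) 0.5 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(l0 = l0, l1 = l1, lrt = lrt, p = p,
                 optimizer_failure = failure),
            class = "lrt_result")
}
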