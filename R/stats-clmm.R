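# Cumulative-link mixed model (proportional odds, logit link) with a
# participant random intercept, fitted by maximising the marginal likelihood
# with adaptive Gauss-Hermite quadrature. For subject i with observations j:
#
#   P(y_ij <= k | u_i) = logistic(zeta_k - x_ij' beta - sigma u_i),  u_i ~ N(0,1)
#
# The per-subject integral over u is centred and scaled at the conditional
# mode (found by Newton's method; the integrand is log-concave), then
# evaluated on Gauss-Hermite nodes. sigma = 0 reduces exactly to the
# fixed-effects cumulative-link model.

clmm_nll_factory <- function(X, y, subj, K, n_quad) {
  gh <- statmod::gauss.quad(n_quad, kind = "hermite")
  lw <- log(gh$weights) + gh$nodes^2
  G <- max(subj)
  p <- ncol(X)
  nld <- K - 2L  # log-differences between successive thresholds
  iu <- y + 1L   # index of the upper threshold in c(-Inf, zeta, Inf)
  il <- y        # index of the lower threshold
  state <- new.env(parent = emptyenv())
  state$u <- numeric(G)  # warm start for the conditional modes

  lgs <- function(x) 1 / (1 + exp(-x))                 # logistic cdf
  dls <- function(x) { e <- exp(-abs(x)); e / (1 + e)^2 }  # logistic pdf

  obs_logp <- function(zeta, eta, shift) {
    zf <- c(-Inf, zeta, Inf)
    A <- zf[iu] - eta - shift
    B <- zf[il] - eta - shift
    P <- lgs(A) - lgs(B)
    list(A = A, B = B, P = pmax(P, 1e-300))
  }

  # curvature of sum log P wrt u, times sigma^2 (per observation)
  d2logp <- function(o) {
    fA <- dls(o$A); fB <- dls(o$B)
    (fA * (1 - 2 * lgs(o$A)) - fB * (1 - 2 * lgs(o$B))) / o$P -
      ((fA - fB) / o$P)^2
  }

  function(par) {
    zeta <- par[1L]
    if (nld > 0L) zeta <- cumsum(c(par[1L], exp(par[2:(nld + 1L)])))
    beta <- if (p > 0L) par[(nld + 2L):(nld + 1L + p)] else numeric()
    sigma <- par[length(par)]
    eta <- if (p > 0L) drop(X %*% beta) else numeric(length(y))

    if (sigma < 1e-8) {
      o <- obs_logp(zeta, eta, 0)
      return(-sum(log(o$P)))
    }
    # conditional modes: Newton on g(u) = sum_j log P_j(u) - u^2/2, warm
    # started from the previous evaluation (the mode moves little between
    # optimiser steps); the integrand is log-concave so Newton is safe
    u <- state$u
    for (it in 1:25) {
      o <- obs_logp(zeta, eta, sigma * u[subj])
      fA <- dls(o$A); fB <- dls(o$B)
      g1o <- -sigma * (fA - fB) / o$P
      grad <- rowsum(g1o, subj)[, 1] - u
      hess <- sigma^2 * rowsum(d2logp(o), subj)[, 1] - 1
      step <- grad / hess
      u <- u - step
      if (max(abs(step)) < 1e-9) break
    }
    state$u <- u
    o <- obs_logp(zeta, eta, sigma * u[subj])
    h <- 1 - sigma^2 * rowsum(d2logp(o), subj)[, 1]
    s_hat <- 1 / sqrt(h)

    logint <- matrix(0, G, n_quad)
    for (k in seq_len(n_quad)) {
      uk <- u + sqrt(2) * s_hat * gh$nodes[k]
      ok <- obs_logp(zeta, eta, sigma * uk[subj])
      logint[, k] <- lw[k] + rowsum(log(ok$P), subj)[, 1] +
        stats::dnorm(uk, log = TRUE)
    }
    m <- apply(logint, 1, max)
    ll <- sum(log(sqrt(2) * s_hat) + m + log(rowSums(exp(logint - m))))
    -ll
  }
}

#' Cumulative-link mixed model for ordinal ratings
#'
#' Proportional-odds (logit) regression of a 7-point (or shorter) ordinal
#' response on the fixed terms, with a participant random intercept, fitted
#' natively by adaptive Gauss-Hermite quadrature (21 nodes by default).
#' Thresholds are parameterised by log-differences and are therefore strictly
#' increasing in the fit. Each fixed term is tested by a likelihood-ratio
#' comparison against the model with the term removed. With the subject
#' variance at zero the model reduces exactly to the fixed-effects
#' cumulative-link model (which also provides the starting values, via
#' [MASS::polr()]).
#'
#' @param data Data frame of ratings (e.g. [rating_records()] joined with
#'   design covariates).
#' @param dv Ordinal response column (integer or ordered factor; at least two
#'   observed categories).
#' @param fixed Character vector of fixed-effect term labels.
#' @param random Subject column name.
#' @param n_quad Number of Gauss-Hermite quadrature nodes.
#' @param lrt Compute per-term likelihood-ratio tests (default `TRUE`).
#' @param se Compute standard errors from the numerical Hessian (default
#'   `TRUE`; skip for speed in large simulation studies).
#' @param sigma_fixed `NULL` (estimate the random-intercept SD, the default)
#'   or a fixed non-negative value; `sigma_fixed = 0` fits the fixed-effects
#'   cumulative-link model through the same likelihood code path, the exact
#'   sigma -> 0 limit used for validation.
#' @return An object of class `prehensr_clmm`: tidy `table` of fixed terms
#'   (`term`, `estimate`, `std.error`, `chisq`, `df`, `p.value`),
#'   `thresholds`, `sigma` (random-intercept SD), `logLik`, `n_obs`,
#'   `n_groups`, and `convergence` (optimiser status and gradient norm).
#' @export
clmm_fit <- function(data, dv, fixed = c("content", "surface"),
                     random = "participant", n_quad = 21L, lrt = TRUE,
                     se = TRUE, sigma_fixed = NULL) {
  data <- as.data.frame(data)
  yf <- droplevels(factor(data[[dv]], ordered = TRUE))
  K <- nlevels(yf)
  if (K < 2) stop("ordinal response needs at least 2 observed categories",
                  call. = FALSE)
  y <- as.integer(yf)
  subj <- as.integer(factor(data[[random]]))
  rhs <- paste(fixed, collapse = " + ")
  fixed_fml <- stats::as.formula(paste0("~ ", rhs))
  X <- stats::model.matrix(fixed_fml, data = data)
  asg <- attr(X, "assign")[-1]
  X <- X[, -1, drop = FALSE]
  labels <- attr(stats::terms(fixed_fml), "term.labels")

  fit1 <- clmm_optim(X, y, subj, K, n_quad, sigma_fixed)
  p <- ncol(X)
  nld <- K - 2L
  beta_idx <- (nld + 2L):(nld + 1L + p)

  # standard errors from the numerical Hessian of the negative log-likelihood
  se_vec <- rep(NA_real_, p)
  if (se) {
    vc <- tryCatch({
      H <- numDeriv::hessian(fit1$nll, fit1$par)
      solve(H)
    }, error = function(e) NULL)
    if (!is.null(vc)) {
      dv_ <- diag(vc)[beta_idx]
      se_vec <- ifelse(dv_ > 0, sqrt(dv_), NA_real_)
    }
  }

  rows <- purrr::map(seq_along(labels), function(k) {
    idx <- which(asg == k)
    tibble::tibble(
      term = labels[k],
      estimate = if (length(idx) == 1) unname(fit1$beta[idx]) else NA_real_,
      std.error = if (length(idx) == 1) se_vec[idx] else NA_real_,
      chisq = NA_real_, df = length(idx), p.value = NA_real_
    )
  })
  table <- dplyr::bind_rows(rows)

  if (lrt && p > 0) {
    for (k in seq_along(labels)) {
      keep <- asg != k
      red <- clmm_optim(X[, keep, drop = FALSE], y, subj, K, n_quad,
                        sigma_fixed)
      chisq <- max(0, 2 * (fit1$logLik - red$logLik))
      df <- sum(!keep)
      table$chisq[k] <- chisq
      table$df[k] <- df
      table$p.value[k] <- stats::pchisq(chisq, df, lower.tail = FALSE)
    }
  }
  structure(list(
    table = table, thresholds = fit1$zeta, sigma = fit1$sigma,
    logLik = fit1$logLik, n_obs = length(y), n_groups = max(subj),
    n_quad = n_quad, dv = dv,
    convergence = fit1$convergence,
    .internal = list(X = X, y = y, subj = subj, K = K, par = fit1$par)),
    class = "prehensr_clmm")
}

# Optimise the marginal likelihood for one design matrix; polr provides
# starting values for thresholds and slopes. With sigma_fixed the
# random-intercept SD is held at that value instead of being estimated.
clmm_optim <- function(X, y, subj, K, n_quad, sigma_fixed = NULL) {
  p <- ncol(X)
  nld <- K - 2L
  start <- tryCatch({
    suppressWarnings({  # polr warns on near-separated starting fits
      if (p > 0) {
        pf <- MASS::polr(factor(y, ordered = TRUE) ~ X, method = "logistic")
        list(zeta = pf$zeta, beta = unname(pf$coefficients))
      } else {
        pf <- MASS::polr(factor(y, ordered = TRUE) ~ 1, method = "logistic")
        list(zeta = pf$zeta, beta = numeric())
      }
    })
  }, error = function(e) {
    props <- cumsum(tabulate(y, K) / length(y))[-K]
    list(zeta = stats::qlogis(pmin(pmax(props, 1e-3), 1 - 1e-3)),
         beta = rep(0, p))
  })
  zeta0 <- sort(start$zeta)
  zeta0 <- zeta0 + seq(0, 1e-6, length.out = length(zeta0))  # break exact ties
  nll_full <- clmm_nll_factory(X, y, subj, K, n_quad)
  if (is.null(sigma_fixed)) {
    par0 <- c(zeta0[1],
              if (nld > 0) log(pmax(diff(zeta0), 1e-6)),
              start$beta, 0.7)
    nll <- nll_full
    lower <- c(rep(-Inf, length(par0) - 1L), 0)
  } else {
    par0 <- c(zeta0[1],
              if (nld > 0) log(pmax(diff(zeta0), 1e-6)),
              start$beta)
    nll <- function(par) nll_full(c(par, sigma_fixed))
    lower <- rep(-Inf, length(par0))
  }
  opt <- stats::nlminb(par0, nll, lower = lower,
                       control = list(iter.max = 500, eval.max = 1000,
                                      rel.tol = 1e-12))
  par_full <- if (is.null(sigma_fixed)) opt$par else c(opt$par, sigma_fixed)
  gnorm <- tryCatch(max(abs(numDeriv::grad(nll, opt$par))),
                    error = function(e) NA_real_)
  zeta <- par_full[1L]
  if (nld > 0L) zeta <- cumsum(c(par_full[1L], exp(par_full[2:(nld + 1L)])))
  beta <- if (p > 0) par_full[(nld + 2L):(nld + 1L + p)] else numeric()
  list(par = par_full, zeta = zeta, beta = beta,
       sigma = par_full[length(par_full)],
       logLik = -opt$objective, nll = nll_full,
       convergence = list(code = opt$convergence, message = opt$message,
                          gradient_norm = gnorm))
}

#' Marginal log-likelihood of a fitted CLMM at a given quadrature precision
#'
#' Re-evaluates the marginal log-likelihood of a [clmm_fit()] object at its
#' fitted parameters with a different number of Gauss-Hermite nodes. Useful
#' for checking that the quadrature has reached its numerical plateau.
#'
#' @param object A `prehensr_clmm` fit.
#' @param n_quad Number of nodes.
#' @return The marginal log-likelihood (numeric scalar).
#' @export
clmm_logLik <- function(object, n_quad = object$n_quad) {
  stopifnot(inherits(object, "prehensr_clmm"))
  it <- object$.internal
  nll <- clmm_nll_factory(it$X, it$y, it$subj, it$K, n_quad)
  -nll(it$par)
}

#' @export
print.prehensr_clmm <- function(x, ...) {
  cat(sprintf(
    "Cumulative-link mixed model on %s (%d obs, %d subjects, %d GH nodes)\n",
    x$dv, x$n_obs, x$n_groups, x$n_quad))
  cat(sprintf("  random-intercept SD = %.3f, logLik = %.2f (grad %.2e)\n",
              x$sigma, x$logLik, x$convergence$gradient_norm))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    if (is.na(r$chisq)) {
      cat(sprintf("  %-24s b = %.2f, SE = %.2f\n", r$term, r$estimate,
                  r$std.error))
    } else {
      cat(sprintf("  %-24s b = %.2f, SE = %.2f, chi2(%d) = %.2f, p = %.4g\n",
                  r$term, r$estimate, r$std.error, r$df, r$chisq, r$p.value))
    }
  }
  invisible(x)
}
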