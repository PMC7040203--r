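#' Random-intercept linear mixed model with likelihood-ratio term tests
#'
#' Fits `dv ~ fixed terms + (1 | subject)` with \pkg{lme4}. Coefficients and
#' standard errors are reported from the REML fit; each fixed term is tested
#' by a likelihood-ratio comparison of nested models fitted by maximum
#' likelihood (the full model against the model with that term removed),
#' giving the chi-squared statistics used in block-wise reporting. A singular
#' random-effects fit (subject variance estimated at zero) is reported with a
#' warning, not an error: the fixed-effect estimates then coincide with
#' ordinary least squares.
#'
#' @param data Feature data frame.
#' @param dv Dependent variable column name.
#' @param fixed Character vector of fixed-effect term labels (may include
#'   interactions, e.g. `"glossiness:hardness"`).
#' @param random Subject column for the random intercept.
#' @param lrt Compute per-term likelihood-ratio tests (default `TRUE`; skip
#'   for speed in large simulation studies).
#' @return An object of class `prehensr_lmm`: a tidy `table` (`term`,
#'   `estimate`, `std.error`, `chisq`, `df`, `p.value`), the underlying
#'   `merMod` fit, log-likelihood, group counts and a `singular` flag.
#' @export
lmm_fit <- function(data, dv, fixed = c("surface", "content", "feedback"),
                    random = "participant", lrt = TRUE) {
  data <- as.data.frame(data)
  if (length(unique(data[[random]])) < 2) {
    stop("need at least 2 subjects for a random intercept", call. = FALSE)
  }
  rhs <- paste(fixed, collapse = " + ")
  fml <- stats::as.formula(paste0(dv, " ~ ", rhs, " + (1 | ", random, ")"))
  fit <- suppressMessages(lme4::lmer(fml, data = data, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular random-effects fit: subject variance estimated at zero",
            call. = FALSE)
  }
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixed_fml <- stats::as.formula(paste0("~ ", rhs))
  asg <- attr(stats::model.matrix(fixed_fml, data = data), "assign")
  labels <- attr(stats::terms(fixed_fml), "term.labels")

  rows <- purrr::map(seq_along(labels), function(k) {
    idx <- which(asg == k)
    tibble::tibble(
      term = labels[k],
      estimate = if (length(idx) == 1) unname(co[idx]) else NA_real_,
      std.error = if (length(idx) == 1) unname(se[idx]) else NA_real_,
      chisq = NA_real_, df = length(idx), p.value = NA_real_
    )
  })
  table <- dplyr::bind_rows(rows)

  if (lrt) {
    full_ml <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = data, REML = FALSE)))
    ll_full <- as.numeric(stats::logLik(full_ml))
    for (k in seq_along(labels)) {
      red_rhs <- paste0(rhs, " - ", labels[k])
      red_fml <- stats::as.formula(paste0(dv, " ~ ", red_rhs,
                                          " + (1 | ", random, ")"))
      red <- suppressMessages(suppressWarnings(
        lme4::lmer(red_fml, data = data, REML = FALSE)))
      chisq <- max(0, 2 * (ll_full - as.numeric(stats::logLik(red))))
      df <- attr(stats::logLik(full_ml), "df") - attr(stats::logLik(red), "df")
      table$chisq[k] <- chisq
      table$df[k] <- df
      table$p.value[k] <- stats::pchisq(chisq, df, lower.tail = FALSE)
    }
  }
  structure(list(table = table, model = fit,
                 logLik = as.numeric(stats::logLik(fit)),
                 n_obs = stats::nobs(fit),
                 n_groups = lme4::ngrps(fit)[[1]],
                 singular = singular, dv = dv),
            class = "prehensr_lmm")
}

#' @export
print.prehensr_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model on %s (%d obs, %d subjects%s)\n",
              x$dv, x$n_obs, x$n_groups,
              if (x$singular) ", singular" else ""))
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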