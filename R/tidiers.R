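#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.prehensr_anova <- function(x, ...) x$table

#' @export
glance.prehensr_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, degenerate = x$degenerate)
}

#' @export
tidy.prehensr_lmm <- function(x, ...) x$table

#' @export
glance.prehensr_lmm <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, n_obs = x$n_obs, n_groups = x$n_groups,
                 singular = x$singular)
}

#' @export
tidy.prehensr_clmm <- function(x, ...) x$table

#' @export
glance.prehensr_clmm <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, logLik = x$logLik, n_obs = x$n_obs,
                 n_groups = x$n_groups, n_quad = x$n_quad,
                 gradient_norm = x$convergence$gradient_norm)
}

#' @export
tidy.prehensr_kw <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 degenerate = x$degenerate)
}

#' @export
glance.prehensr_kw <- function(x, ...) tidy(x)
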