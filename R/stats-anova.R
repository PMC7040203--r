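#' Repeated-measures ANOVA with generalized eta squared
#'
#' Fits a fully within-subject ANOVA on per-cell means: the data are first
#' aggregated to one mean per subject x factor cell, then analysed with
#' univariate error strata (`Error(subject/(A*B*C))`). No sphericity
#' correction is applied by default, matching the reporting convention of the
#' block-wise analyses this accompanies. Generalized eta squared is computed
#' for every effect as
#' \deqn{\eta^2_G = SS_{effect} / (SS_{effect} + \sum SS_{error})}
#' where the sum runs over the residual sums of squares of *all* error strata
#' (including the between-subject stratum), the form appropriate for fully
#' within designs with subjects as the only measured factor.
#'
#' @param data Feature data frame (one row per trial is fine; replicates
#'   within a cell are averaged).
#' @param dv Name of the dependent variable column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject identifier column.
#' @return An object of class `prehensr_anova` with a tidy `table` of terms
#'   (`term`, `df`, `df_error`, `statistic`, `p.value`, `ges`).
#' @export
rm_anova <- function(data, dv, within = c("surface", "content", "feedback"),
                     subject = "participant") {
  data <- as.data.frame(data)
  miss <- setdiff(c(dv, within, subject), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  cells <- stats::aggregate(data[[dv]],
                            by = c(lapply(data[within], factor),
                                   list(.subject = factor(data[[subject]]))),
                            FUN = mean)
  names(cells) <- c(within, ".subject", ".dv")
  n_cells_expected <- prod(vapply(cells[within], nlevels, 1L))
  counts <- table(cells$.subject)
  if (any(counts != n_cells_expected)) {
    stop("aggregation error: missing cells for subject(s) ",
         paste(names(counts)[counts != n_cells_expected], collapse = ", "),
         "; every subject needs every factor combination", call. = FALSE)
  }
  if (stats::sd(cells$.dv) < 1e-12) {
    res <- structure(list(
      table = tibble::tibble(term = character(), df = numeric(),
                             df_error = numeric(), statistic = numeric(),
                             p.value = numeric(), ges = numeric()),
      dv = dv, n_subjects = nlevels(cells$.subject), degenerate = TRUE),
      class = "prehensr_anova")
    return(res)
  }
  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(paste0(".dv ~ ", rhs,
                                  " + Error(.subject/(", rhs, "))"))
  fit <- stats::aov(fml, data = cells)
  sm <- summary(fit)

  term_rows <- list()
  error_ss <- 0
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    resid_i <- which(rn == "Residuals")
    if (length(resid_i)) error_ss <- error_ss + tab[resid_i, "Sum Sq"]
    for (i in setdiff(seq_along(rn), resid_i)) {
      term_rows[[rn[i]]] <- tibble::tibble(
        term = rn[i], df = tab[i, "Df"],
        df_error = if (length(resid_i)) tab[resid_i, "Df"] else NA_real_,
        sumsq = tab[i, "Sum Sq"],
        statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"]
      )
    }
  }
  table <- dplyr::bind_rows(term_rows)
  table$ges <- table$sumsq / (table$sumsq + error_ss)
  table$sumsq <- NULL
  structure(list(table = table, dv = dv,
                 n_subjects = nlevels(cells$.subject), degenerate = FALSE),
            class = "prehensr_anova")
}

#' @export
print.prehensr_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA on", x$dv, "(", x$n_subjects, "subjects )\n")
  if (x$degenerate) {
    cat("  degenerate: dependent variable is constant; F undefined\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-28s F(%d,%d) = %.2f, p = %.4g, ges = %.3f\n",
                r$term, r$df, r$df_error, r$statistic, r$p.value, r$ges))
  }
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction), used to test whether a feature's distribution differs across
#' the experiment blocks. All-tied data are flagged degenerate rather than
#' tested.
#'
#' @param data Feature data frame.
#' @param dv Dependent variable column name.
#' @param group Grouping column name (default `"block"`).
#' @return An object of class `prehensr_kw` with `statistic` (H), `df`,
#'   `p.value` and a `degenerate` flag.
#' @export
kruskal_wallis <- function(data, dv, group = "block") {
  data <- as.data.frame(data)
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  y <- data[[dv]]
  if (length(unique(y[!is.na(y)])) < 2) {
    return(structure(list(statistic = NA_real_, df = nlevels(g) - 1L,
                          p.value = NA_real_, dv = dv, group = group,
                          degenerate = TRUE), class = "prehensr_kw"))
  }
  kt <- stats::kruskal.test(y, g)
  structure(list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p.value = kt$p.value, dv = dv, group = group,
                 degenerate = FALSE), class = "prehensr_kw")
}

#' @export
print.prehensr_kw <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Kruskal-Wallis on %s by %s: degenerate (all values tied)\n",
                x$dv, x$group))
  } else {
    cat(sprintf("Kruskal-Wallis on %s by %s: chi-squared(%d) = %.2f, p = %.4g\n",
                x$dv, x$group, x$df, x$statistic, x$p.value))
  }
  invisible(x)
}
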