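#' @export
tidy.two_sample_t <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, statistic = x$statistic, df = x$df,
                 p.value = x$p.value, method = x$method)
}

#' @export
glance.two_sample_t <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n1 = x$group1$n, n2 = x$group2$n, method = x$method)
}

#' @export
print.two_sample_t <- function(x, ...) {
  cat(sprintf("Two-sample t (%s): t = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
tidy.factorial_anova <- function(x, ...) x$table

#' @export
glance.factorial_anova <- function(x, ...) {
  tibble::tibble(type = x$type, balanced = x$balanced,
                 replicated = x$replicated)
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type %s sums of squares)\n", x$type))
  print(x$table)
  invisible(x)
}

#' @export
tidy.mwu_test <- function(x, ...) {
  tibble::tibble(u = x$u, u1 = x$u1, u2 = x$u2, p.value = x$p.value,
                 method = x$method)
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.4g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$u, x$n1, x$n2, x$p.value, x$method))
  invisible(x)
}

#' @export
tidy.correlation_result <- function(x, ...) x$per_cell

#' @export
glance.correlation_result <- function(x, ...) {
  tibble::tibble(correlated_firing_ratio = x$correlated_firing_ratio,
                 n_active = x$n_active,
                 n_correlated = sum(x$per_cell$correlated),
                 undefined = x$undefined)
}
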