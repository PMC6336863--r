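#' Group summary statistics (mean, SEM, n)
#'
#' Container for a group described only by its published summary statistics,
#' as printed in figure captions ("mean +/- SEM, n"). [pooled_t()] accepts
#' these in place of raw values, recovering the group SD as `sem * sqrt(n)`.
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (>= 0).
#' @param n Group size (>= 2).
#' @param label Optional group label.
#' @return A list of class `group_summary`.
#' @export
#' @examples
#' wt <- group_summary(257.7, 16.2, 39, "wt")
#' het <- group_summary(216.2, 11.19, 33, "het")
#' tidy(pooled_t(wt, het))
group_summary <- function(mean, sem, n, label = "") {
  check_scalar(mean, "mean")
  check_scalar(sem, "sem", min = 0)
  check_scalar(n, "n", min = 2, integer = TRUE)
  structure(list(mean = mean, sem = sem, n = as.integer(n),
                 label = as.character(label)),
            class = "group_summary")
}

as_group_summary <- function(x, label = "") {
  if (inherits(x, "group_summary")) return(x)
  x <- as.numeric(x)
  if (length(x) < 2 || any(!is.finite(x))) {
    abort("each group needs >= 2 finite values (or a group_summary).")
  }
  group_summary(mean(x), sd(x) / sqrt(length(x)), length(x), label)
}

#' Two-sample t test from raw values or summary statistics
#'
#' Pooled-variance two-sample t by default (`df = n1 + n2 - 2`), the variant
#' that reproduces published t statistics computed from printed mean/SEM/n;
#' Welch's unequal-variance form by flag. Groups may be numeric vectors or
#' [group_summary()] objects (mixing is fine) and both routes give identical
#' results on the same data.
#'
#' @param group1,group2 Numeric vectors or `group_summary` objects.
#' @param welch Use the Welch unequal-variance statistic.
#' @return A list of class `two_sample_t` (statistic, df, p.value, group
#'   summaries); see [tidy()]/[glance()].
#' @export
pooled_t <- function(group1, group2, welch = FALSE) {
  g1 <- as_group_summary(group1, "group1")
  g2 <- as_group_summary(group2, "group2")
  if (g1$n + g2$n < 4) abort("need n1 + n2 >= 4 observations.")
  s1 <- g1$sem * sqrt(g1$n)
  s2 <- g2$sem * sqrt(g2$n)
  diff <- g1$mean - g2$mean
  if (welch) {
    v1 <- s1^2 / g1$n; v2 <- s2^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  } else {
    sp2 <- ((g1$n - 1) * s1^2 + (g2$n - 1) * s2^2) / (g1$n + g2$n - 2)
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
    df <- g1$n + g2$n - 2
  }
  if (se == 0) {
    if (diff == 0) {
      tval <- 0
    } else {
      abort("zero pooled variance with unequal means: t is undefined.")
    }
  } else {
    tval <- diff / se
  }
  p <- 2 * pt(-abs(tval), df)
  structure(list(statistic = tval, df = df, p.value = p,
                 method = if (welch) "welch" else "pooled",
                 estimate = diff, group1 = g1, group2 = g2),
            class = "two_sample_t")
}

#' Two-way fixed-effects ANOVA
#'
#' Crossed two-factor ANOVA with interaction when the design is replicated
#' (any cell with more than one observation), additive otherwise. Balanced
#' designs use the sequential (Type I) decomposition, where the sums of
#' squares partition the total exactly; unbalanced designs fall back to
#' Type II sums of squares with a warning.
#'
#' @param data Data frame of observations.
#' @param response,factor_a,factor_b Column names (strings).
#' @return A list of class `factorial_anova`; `tidy()` gives one row per term
#'   (`term`, `df`, `sumsq`, `meansq`, `statistic`, `p.value`).
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  data <- as.data.frame(data)
  for (v in c(response, factor_a, factor_b)) {
    if (!v %in% names(data)) abort(sprintf("column `%s` not found.", v))
  }
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  if (nlevels(a) < 2 || nlevels(b) < 2) abort("need >= 2 levels per factor.")
  cells <- table(a, b)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    abort(paste0("empty design cells: ",
                 paste(sprintf("(%s, %s)", rownames(cells)[bad[, 1]],
                               colnames(cells)[bad[, 2]]), collapse = ", ")))
  }
  replicated <- any(cells > 1)
  balanced <- length(unique(as.vector(cells))) == 1
  d <- data.frame(y = data[[response]], A = a, B = b)
  form <- if (replicated) y ~ A * B else y ~ A + B
  fit <- lm(form, data = d)
  if (balanced) {
    tab <- withCallingHandlers(
      stats::anova(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    type <- "I"
  } else {
    rlang::check_installed("car")
    warn("unbalanced design: using Type II sums of squares.")
    tab <- car::Anova(fit, type = 2)
    # put residuals row last, matching anova() layout
    type <- "II"
  }
  tt <- tibble::tibble(
    term = sub("^A$", factor_a,
               sub("^B$", factor_b,
                   sub("^A:B$", paste0(factor_a, ":", factor_b),
                       rownames(tab)))),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Sum Sq` / tab$Df,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`)
  # degenerate (numerically zero residual) designs: a zero-SS term has F = 0,
  # a real effect has F = Inf, rather than the unstable 0/0 ratios of anova()
  tot <- sum(tt$sumsq)
  mse <- tt$sumsq[tt$term == "Residuals"] / tt$df[tt$term == "Residuals"]
  if (!is.finite(mse) || (tot > 0 && mse < 1e-10 * tot / sum(tt$df)) ||
      tot == 0) {
    eff <- tt$term != "Residuals"
    zero <- eff & (tt$sumsq <= 1e-9 * max(tot, .Machine$double.eps))
    tt$statistic[zero] <- 0
    tt$p.value[zero] <- 1
    tt$statistic[eff & !zero] <- Inf
    tt$p.value[eff & !zero] <- 0
    tt$statistic[tt$term == "Residuals"] <- NA_real_
    tt$p.value[tt$term == "Residuals"] <- NA_real_
  }
  structure(list(table = tt, type = type, balanced = balanced,
                 replicated = replicated, fit = fit),
            class = "factorial_anova")
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midrank handling of ties. For small samples
#' (`n1 + n2 <= exact_below`) the two-sided p value is computed exactly by
#' enumerating all assignments of the pooled ranks to the two groups (valid
#' under ties, unlike the classical no-tie exact distribution); larger samples
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param group1,group2 Numeric vectors.
#' @param exact_below Enumerate exactly when `n1 + n2` is at most this
#'   (default 20).
#' @return A list of class `mwu_test` with `u` (min of the two group U
#'   statistics), `u1`, `u2`, `p.value`, `method`.
#' @export
mann_whitney_u <- function(group1, group2, exact_below = 20) {
  x <- as.numeric(group1); y <- as.numeric(group2)
  if (!length(x) || !length(y)) abort("both groups must be nonempty.")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  # enumeration is capped at 20 pooled observations (choose(20, 10) splits)
  if (n1 + n2 <= min(exact_below, 20)) {
    # exact by enumeration of all rank splits (ties kept as midranks)
    splits <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    us_min <- pmin(us, n1 * n2 - us)
    p <- mean(us_min <= u + 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-z)
    method <- "normal approximation"
  }
  structure(list(u = u, u1 = u1, u2 = u2, p.value = min(1, p),
                 n1 = n1, n2 = n2, method = method),
            class = "mwu_test")
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`: with sorted p values `p_(1) <= ... <=
#' p_(m)`, find the largest `k` with `p_(k) <= k q / m` and flag all p values
#' at or below `p_(k)`. Adjusted values are the standard monotone BH
#' transform (as in `p.adjust`), so a flag is equivalent to
#' `adjusted <= q`.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return A tibble of class `fdr_result`: `p.value`, `adjusted`,
#'   `significant`, with attribute `q`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p values must be finite and in [0, 1].")
  }
  check_scalar(q, "q", min = 1e-12, max = 1)
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  sig <- logical(m)
  if (length(ok)) sig[p <= p[o][max(ok)]] <- TRUE
  out <- tibble::tibble(p.value = p, adjusted = p.adjust(p, method = "BH"),
                        significant = sig)
  structure(out, q = q, class = c("fdr_result", class(out)))
}
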