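#' Descriptive group statistics with coefficient of variation
#'
#' Per-group sample size, mean, sample (n-1) standard deviation and
#' coefficient of variation `CV = 100 SD / mean` (%).
#'
#' @param value numeric observations.
#' @param group grouping factor (coerced).
#' @return Data frame with `group`, `n`, `mean`, `sd`, `cv`. Groups with a
#'   single observation get `NA` for `sd` and `cv`.
#' @examples
#' descriptive_stats(c(1, 2, 3, 10, 12, 14), rep(c("a", "b"), each = 3))
#' @export
descriptive_stats <- function(value, group) {
  group <- as.factor(group)
  stopifnot(length(value) == length(group))
  out <- do.call(rbind, lapply(split(value, group), function(v) {
    m <- mean(v)
    s <- if (length(v) > 1) sd(v) else NA_real_
    data.frame(n = length(v), mean = m, sd = s,
               cv = if (is.na(s)) NA_real_ else 100 * s / m)
  }))
  out <- cbind(group = levels(group), out)
  rownames(out) <- NULL
  out
}

# Duncan least-significant-range multiplier for a span of p means:
# studentized range quantile at Duncan's protection level (1-alpha)^(p-1).
duncan_q <- function(p, df, alpha) {
  qtukey((1 - alpha)^(p - 1), nmeans = p, df = df)
}

# Letters for the underlining pattern given a symmetric "not significantly
# different" matrix over means sorted ascending: maximal TRUE intervals.
letters_from_nonsig <- function(nonsig) {
  k <- nrow(nonsig)
  # maximal intervals [i, j] with all pairs inside declared non-significant;
  # nonsig is already transitive over ranges by construction
  ivals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    ivals[[i]] <- c(i, j)
  }
  # drop intervals nested in an earlier one
  keep <- list()
  for (iv in ivals) {
    nested <- any(vapply(keep, function(p) p[1] <= iv[1] && iv[2] <= p[2],
                         logical(1)))
    if (!nested) keep[[length(keep) + 1]] <- iv
  }
  lab <- character(k)
  for (m in seq_along(keep)) {
    iv <- keep[[m]]
    lab[iv[1]:iv[2]] <- paste0(lab[iv[1]:iv[2]], letters[m])
  }
  lab
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Fits a one-way ANOVA and groups the treatment means with Duncan's multiple
#' range test at level `alpha`. Means sorted ascending are compared with the
#' least significant range for their span `p`,
#' `R_p = q_{(1-alpha)^(p-1), p, df} * sqrt(MSE / n_h)` (studentized-range
#' quantile at Duncan's protection level; `n_h` the harmonic mean group
#' size), with the usual multiple-range rule that a range inside a
#' non-significant span is itself declared non-significant. Groups sharing a
#' letter do not differ at level `alpha`. The range test is Fisher-protected:
#' when the ANOVA F test is not significant at `alpha`, all groups share one
#' letter.
#'
#' @param value numeric observations.
#' @param group grouping factor (>= 2 levels, each with >= 2 observations).
#' @param alpha significance level (default 0.05).
#' @return Object of class `duncan_test`: list with `F`, `p_value`, `df`,
#'   `MSE`, and `groups` (data frame of group, n, mean, letters, sorted by
#'   mean ascending).
#' @examples
#' set.seed(1)
#' v <- c(rnorm(10), rnorm(10), rnorm(10, 4))
#' g <- rep(c("x", "y", "z"), each = 10)
#' anova_duncan(v, g)
#' @export
anova_duncan <- function(value, group, alpha = 0.05) {
  group <- droplevels(as.factor(group))
  stopifnot(length(value) == length(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  ns <- tabulate(group)
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  fit <- aov(value ~ group)
  an <- anova(fit)
  MSE <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  if (MSE <= 1e-12 * max(var(value), .Machine$double.eps))
    stop("zero within-group variance: range test degenerate")

  means <- tapply(value, group, mean)
  o <- order(means)
  means_s <- means[o]
  ns_s <- ns[o]
  k <- length(means_s)
  nh <- k / sum(1 / ns)  # harmonic mean group size
  se <- sqrt(MSE / nh)

  nonsig <- matrix(FALSE, k, k)
  diag(nonsig) <- TRUE
  if (pv > alpha) {
    nonsig[] <- TRUE
  } else {
    # multiple-range sweep: widest spans first; a non-significant span
    # protects all its sub-ranges
    for (span in k:2) {
      Rp <- duncan_q(span, df_err, alpha) * se
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        if (nonsig[i, j]) next
        if (means_s[j] - means_s[i] <= Rp) {
          nonsig[i:j, i:j] <- TRUE
        }
      }
    }
  }
  lab <- letters_from_nonsig(nonsig)
  structure(list(
    F = Fv, p_value = pv, df = c(k - 1, df_err), MSE = MSE, alpha = alpha,
    groups = data.frame(group = names(means_s), n = ns_s,
                        mean = as.numeric(means_s), letters = lab)
  ), class = "duncan_test")
}

#' @export
print.duncan_test <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_value))
  cat(sprintf("Duncan's multiple range test at alpha = %g\n", x$alpha))
  print(x$groups, row.names = FALSE)
  cat("(groups sharing a letter are not significantly different)\n")
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric alternative to the one-way ANOVA for non-normal data:
#' tie-corrected rank statistic H with a chi-square p-value (wraps
#' [stats::kruskal.test()]).
#'
#' @param value numeric observations.
#' @param group grouping factor.
#' @return List with `H`, `df` and `p_value`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(value, group) {
  kt <- kruskal.test(value, as.factor(group))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pearson correlation with significance flag
#'
#' Pearson's r with the two-sided t-test p-value on pairwise-complete
#' observations, and a significance flag at `alpha`.
#'
#' @param x,y numeric vectors of equal length.
#' @param alpha significance level for the flag (default 0.05).
#' @return Object of class `pearson_cor`: list with `r`, `p_value`, `n`,
#'   `significant`.
#' @examples
#' pearson_cor(1:10, (1:10)^2)
#' @export
pearson_cor <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
                 significant = ct$p.value <= alpha, alpha = alpha),
            class = "pearson_cor")
}

#' @export
print.pearson_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.4g)%s\n", x$r, x$n, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Group comparison with a normality gate
#'
#' Applies the standard decision rule of grain-quality studies: Shapiro-Wilk
#' normality per group at `alpha`; when every group is compatible with
#' normality, one-way ANOVA with Duncan's test, otherwise the Kruskal-Wallis
#' rank test.
#'
#' @inheritParams anova_duncan
#' @return A `duncan_test` or the [kruskal_wallis()] result, with attribute
#'   `test` naming the route taken (`"anova_duncan"` or `"kruskal_wallis"`).
#' @export
compare_groups <- function(value, group, alpha = 0.05) {
  group <- droplevels(as.factor(group))
  normal <- vapply(split(value, group), function(v) {
    if (length(v) < 3 || sd(v) == 0) return(TRUE)
    shapiro.test(v)$p.value > alpha
  }, logical(1))
  if (all(normal)) {
    out <- anova_duncan(value, group, alpha)
    attr(out, "test") <- "anova_duncan"
  } else {
    out <- kruskal_wallis(value, group)
    attr(out, "test") <- "kruskal_wallis"
  }
  out
}
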