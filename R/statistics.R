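#' Paired t-test between pre- and post-treatment values
#'
#' Two-sided paired t-test on `post - pre` with `df = n - 1`. The
#' all-differences-zero degenerate case is reported as `t = 0, p = 1` by
#' convention (no evidence of change), rather than erroring.
#'
#' @param pre,post paired numeric vectors of equal length `n >= 2`.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
#' @examples
#' paired_test(c(1, 2, 3), c(1, 3, 5))  # t = sqrt(3), df = 2
paired_test <- function(pre, post) {
  if (length(pre) != length(post))
    stop("'pre' and 'post' must have equal length", call. = FALSE)
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    ## constant non-zero differences: infinite evidence
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d)))
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Post/pre percentage ratios for one subject
#'
#' @param pre,post named numeric vectors of per-measure values (e.g.
#'   thickness and E1/E2/E3); names must match.
#' @return named vector of `100 * post / pre`; `NA` (with a message) where
#'   `pre <= 0`.
#' @export
ratio_percent <- function(pre, post) {
  if (!identical(names(pre), names(post)))
    stop("'pre' and 'post' must carry identical measure names", call. = FALSE)
  bad <- pre <= 0
  if (any(bad)) {
    message("ratio undefined for measures with pre <= 0: ",
            paste(names(pre)[bad], collapse = ", "))
  }
  ifelse(bad, NA_real_, 100 * post / pre)
}

#' One-way between-subjects ANOVA with Fisher LSD post hoc
#'
#' Omnibus F test across treatment arms followed by uncorrected pairwise
#' Fisher least-significant-difference comparisons: t statistics on the
#' group-mean differences using the pooled ANOVA mean squared error with its
#' residual degrees of freedom, two-sided, no multiplicity correction (as
#' LSD prescribes).
#'
#' @param groups named list of numeric vectors, one per arm, each `n >= 2`.
#' @return list with `F`, `df`, `p`, `mse`, and a data frame `lsd` of
#'   pairwise comparisons (`group1`, `group2`, `diff`, `t`, `p`).
#' @export
oneway_anova_lsd <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs n >= 2", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  if (stats::var(y) == 0)
    stop("zero total variance: F undefined", call. = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups),
                  vapply(groups, length, 0L)),
              levels = names(groups) %||% seq_along(groups))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  df <- c(s[["Df"]][1], s[["Df"]][2])
  mse <- s[["Mean Sq"]][2]

  means <- vapply(groups, mean, 0)
  ns <- vapply(groups, length, 0L)
  cmb <- utils::combn(seq_along(groups), 2)
  lsd <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tv <- (means[i] - means[j]) / se
    data.frame(group1 = levels(g)[i], group2 = levels(g)[j],
               diff = means[i] - means[j], t = tv,
               p = 2 * stats::pt(-abs(tv), df[2]))
  }))
  list(F = Fv, df = df, p = p, mse = mse, lsd = lsd)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Two-sided p-values via the t transform (`cor.test`). Cells involving a
#' zero-variance measure are flagged `NA`.
#'
#' @param measures data frame or matrix, one column per measure, rows are
#'   subjects (`n >= 3`).
#' @return list of matrices `r` and `p`; `r` is symmetric with unit
#'   diagonal.
#' @export
pearson_matrix <- function(measures) {
  measures <- as.data.frame(measures)
  m <- ncol(measures)
  if (nrow(measures) < 3) stop("need n >= 3 subjects", call. = FALSE)
  r <- diag(1, m); p <- matrix(NA_real_, m, m)
  dimnames(r) <- dimnames(p) <- list(names(measures), names(measures))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    x <- measures[[i]]; y <- measures[[j]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}

## significance stars matching the report notation: * p < 0.05, ** p < 0.01
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
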