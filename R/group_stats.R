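#' ROUT-style robust outlier removal for a univariate sample
#'
#' Robust center and scale are the median and the robust standard deviation
#' from the 68.27th percentile of the absolute residuals (with an n/(n-1)
#' small-sample correction). Candidates are tested outside-in with a t-type
#' test under false-discovery-rate control at rate `Q`: the i-th most extreme
#' residual is declared an outlier when its two-sided p-value falls below
#' `Q * (n - i + 1) / n`, stopping at the first failure. With fewer than 4
#' values, or a zero robust scale, nothing is removed.
#'
#' @param values Numeric vector.
#' @param Q False-discovery rate (default 0.05).
#' @return A list with `kept` and `removed` (values, order-independent
#'   partition) and `outlier` (logical mask aligned with `values`).
#' @export
rout_outliers <- function(values, Q = 0.05) {
  n <- length(values)
  keep_all <- list(kept = values, removed = values[0],
                   outlier = rep(FALSE, n))
  if (n < 4) {
    warning("fewer than 4 values: ROUT removes nothing")
    return(keep_all)
  }
  res <- values - median(values)
  ares <- abs(res)
  rsdr <- unname(quantile(ares, 0.6827, type = 7)) * n / (n - 1)
  if (rsdr <= 0) return(keep_all)
  ord <- order(ares, decreasing = TRUE)
  pvals <- 2 * pt(-ares[ord] / rsdr, df = n - 1)
  out_mask <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (pvals[i] < Q * (n - i + 1) / n) out_mask[ord[i]] <- TRUE else break
  }
  list(kept = values[!out_mask], removed = values[out_mask],
       outlier = out_mask)
}

#' Kruskal-Wallis omnibus test with Dunn post-hoc comparisons
#'
#' The omnibus H statistic (tie-corrected) comes from
#' [stats::kruskal.test()]; pairwise Dunn z statistics are computed from the
#' pooled-rank mean differences with tie-corrected pooled variance, and the
#' two-sided pairwise p-values are adjusted across all pairs (Holm by
#' default; Bonferroni and Sidak available).
#'
#' @param groups Named list of numeric vectors, at least 3 groups with at
#'   least 3 values each.
#' @param adjust `"holm"`, `"bonferroni"` or `"sidak"`.
#' @return A list with `H`, `df`, `p_value` and a `pairwise` tibble
#'   (`comparison`, `z`, `p`, `adjusted_p`).
#' @export
kruskal_dunn <- function(groups, adjust = c("holm", "bonferroni", "sidak")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 3) stop("kruskal_dunn requires at least 3 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 3)) stop("each group needs at least 3 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  n <- length(x)

  if (length(unique(x)) == 1L) {
    pairs <- utils::combn(names(groups), 2)
    pw <- tibble::tibble(
      comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
      z = 0, p = 1, adjusted_p = 1
    )
    return(list(H = 0, df = length(groups) - 1L, p_value = 1, pairwise = pw))
  }

  kw <- kruskal.test(x, g)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pooled_var <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(pooled_var * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  adj <- switch(adjust,
    holm = p.adjust(p, "holm"),
    bonferroni = p.adjust(p, "bonferroni"),
    sidak = pmin(1, 1 - (1 - p)^length(p))
  )
  list(
    H = unname(kw$statistic), df = unname(kw$parameter),
    p_value = kw$p.value,
    pairwise = tibble::tibble(
      comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
      z = z, p = p, adjusted_p = adj
    )
  )
}

#' Mann-Whitney U test for two groups
#'
#' Exact two-sided p for small samples (both n <= 8, no ties), otherwise the
#' normal approximation with tie correction and continuity correction, via
#' [stats::wilcox.test()].
#'
#' @param a,b Numeric vectors with at least 3 values each.
#' @return A list with `U` and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) {
    stop("mann_whitney requires at least 3 values per group")
  }
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

# Greenhouse-Geisser epsilon from a pooled within-group covariance of the
# subjects x levels matrix: epsilon = tr(S_centered)^2 /
# ((k - 1) * sum(S_centered^2)), bounded to [1/(k-1), 1].
gg_epsilon <- function(wide, group) {
  k <- ncol(wide)
  groups <- split(seq_len(nrow(wide)), group)
  s <- matrix(0, k, k)
  dof <- 0
  for (idx in groups) {
    if (length(idx) < 2) next
    m <- wide[idx, , drop = FALSE]
    s <- s + crossprod(scale(m, center = TRUE, scale = FALSE))
    dof <- dof + length(idx) - 1
  }
  s <- s / dof
  rm_ <- rowMeans(s); gm <- mean(s)
  sc <- s - outer(rm_, rep(1, k)) - outer(rep(1, k), rm_) + gm
  eps <- sum(diag(sc))^2 / ((k - 1) * sum(sc^2))
  min(1, max(1 / (k - 1), eps))
}

#' Mixed-design repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Two-way ANOVA with one between-subject factor (group) and one
#' within-subject factor, using an `Error(subject)` stratum for the sums of
#' squares. The Greenhouse-Geisser epsilon is estimated from the pooled
#' within-group covariance of the subject-by-level matrix and multiplies the
#' degrees of freedom of the within-subject and interaction effects.
#' Subjects with an incomplete level set are excluded listwise with a
#' warning. Post-hoc Tukey comparisons of the group marginal means (subject
#' averages) are available via [tukey_groups()].
#'
#' @param data Data frame in long format.
#' @param value,subject,within,between Column names (strings).
#' @return A list with `effects` (tibble: effect, df1, df2, statistic,
#'   p_uncorrected, df1_gg, df2_gg, p_gg) and `epsilon`.
#' @export
rm_anova_gg <- function(data, value = "value", subject = "subject",
                        within = "within", between = "between") {
  d <- data.frame(
    value = data[[value]],
    subject = factor(data[[subject]]),
    within = factor(data[[within]]),
    between = factor(data[[between]])
  )
  k <- nlevels(d$within)
  if (k < 2) stop("at least 2 within-subject levels are required")
  counts <- table(d$subject)
  complete <- names(counts)[counts == k]
  if (length(complete) < length(counts)) {
    warning(length(counts) - length(complete),
            " subject(s) with incomplete level sets excluded listwise")
    d <- d[d$subject %in% complete, , drop = FALSE]
    d$subject <- droplevels(d$subject)
  }
  if (nlevels(d$between) < 2) stop("at least 2 groups are required")

  fit <- aov(value ~ between * within + Error(subject), data = d)
  sm <- summary(fit)
  btab <- sm[["Error: subject"]][[1]]
  wtab <- sm[["Error: Within"]][[1]]
  rn_b <- trimws(rownames(btab))
  rn_w <- trimws(rownames(wtab))
  df_bsub <- btab[rn_b == "Residuals", "Df"]
  ms_bsub <- btab[rn_b == "Residuals", "Mean Sq"]
  df_werr <- wtab[rn_w == "Residuals", "Df"]
  ms_werr <- wtab[rn_w == "Residuals", "Mean Sq"]

  wide <- tapply(d$value, list(d$subject, d$within), mean)
  grp <- vapply(rownames(wide), function(s) {
    as.character(d$between[d$subject == s][1])
  }, character(1))
  eps <- gg_epsilon(wide, grp)

  eff <- function(name, tab, rn, df_err, ms_err, corrected) {
    dfe <- tab[rn == name, "Df"]
    f <- tab[rn == name, "Mean Sq"] / ms_err
    p0 <- pf(f, dfe, df_err, lower.tail = FALSE)
    if (corrected) {
      tibble::tibble(
        effect = name, df1 = dfe, df2 = df_err, statistic = f,
        p_uncorrected = p0, df1_gg = eps * dfe, df2_gg = eps * df_err,
        p_gg = pf(f, eps * dfe, eps * df_err, lower.tail = FALSE)
      )
    } else {
      tibble::tibble(
        effect = name, df1 = dfe, df2 = df_err, statistic = f,
        p_uncorrected = p0, df1_gg = dfe, df2_gg = df_err, p_gg = p0
      )
    }
  }
  effects <- rbind(
    eff("between", btab, rn_b, df_bsub, ms_bsub, corrected = FALSE),
    eff("within", wtab, rn_w, df_werr, ms_werr, corrected = TRUE),
    eff("between:within", wtab, rn_w, df_werr, ms_werr, corrected = TRUE)
  )
  list(effects = effects, epsilon = eps)
}

#' Tukey HSD comparisons of group marginal means
#'
#' Averages the within-subject levels per subject and applies Tukey's
#' honestly-significant-difference test across groups.
#'
#' @inheritParams rm_anova_gg
#' @return A tibble: `comparison`, `diff`, `lwr`, `upr`, `adjusted_p`.
#' @export
tukey_groups <- function(data, value = "value", subject = "subject",
                         between = "between") {
  d <- data.frame(
    value = data[[value]],
    subject = factor(data[[subject]]),
    between = factor(data[[between]])
  )
  means <- aggregate(value ~ subject + between, data = d, FUN = mean)
  tk <- TukeyHSD(aov(value ~ between, data = means))$between
  tibble::tibble(
    comparison = rownames(tk), diff = tk[, "diff"],
    lwr = tk[, "lwr"], upr = tk[, "upr"], adjusted_p = tk[, "p adj"]
  )
}

fit_one_phase <- function(x, y) {
  x_pos <- x[x > 0]
  k0 <- if (length(x_pos)) 1 / median(x_pos) else 1
  p0 <- max(y)
  if (p0 <= 0) p0 <- max(abs(y), 1e-6)
  fit <- minpack.lm::nlsLM(
    y ~ plateau * (1 - exp(-k * x)),
    start = list(plateau = p0, k = k0),
    lower = c(plateau = -Inf, k = 1e-8),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500)
  )
  list(coef = coef(fit), rss = sum(resid(fit)^2))
}

#' Extra-sum-of-squares F-test on origin-constrained one-phase curves
#'
#' Fits `Y = Plateau * (1 - exp(-K * x))` (through the origin) to each
#' group's points and to the pooled points, and compares "one shared curve"
#' against "separate curves per group" with the extra-sum-of-squares F-test.
#'
#' @param x Non-negative predictor (e.g. current step, pA).
#' @param y Response (e.g. proportion of sweeps with one or more spikes).
#' @param group Group labels, same length as `x`.
#' @return A list with `shared` (coefficients), `per_group` (list of
#'   coefficients), `F`, `df1`, `df2`, `p_value`.
#' @export
one_phase_f_test <- function(x, y, group) {
  if (any(x < 0)) stop("x must be non-negative")
  group <- factor(group)
  if (any(table(group) < 4)) stop("each group needs at least 4 points")
  shared <- fit_one_phase(x, y)
  sep <- lapply(levels(group), function(g) {
    fit_one_phase(x[group == g], y[group == g])
  })
  names(sep) <- levels(group)
  rss_sep <- sum(vapply(sep, function(f) f$rss, numeric(1)))
  n <- length(x)
  df_shared <- n - 2
  df_sep <- n - 2 * nlevels(group)
  f_stat <- ((shared$rss - rss_sep) / (df_shared - df_sep)) /
    (rss_sep / df_sep)
  list(
    shared = shared$coef, per_group = lapply(sep, function(f) f$coef),
    F = f_stat, df1 = df_shared - df_sep, df2 = df_sep,
    p_value = pf(f_stat, df_shared - df_sep, df_sep, lower.tail = FALSE)
  )
}

#' Extra-sum-of-squares F-test on lines through the origin
#'
#' The straight-line analog of [one_phase_f_test()], for endpoints fitted by
#' `Y = slope * x` through the origin.
#'
#' @inheritParams one_phase_f_test
#' @return A list with `shared_slope`, `per_group_slopes`, `F`, `df1`,
#'   `df2`, `p_value`.
#' @export
line_f_test <- function(x, y, group) {
  group <- factor(group)
  shared <- lm(y ~ x + 0)
  sep <- lm(y ~ x:group + 0)
  rss_sh <- sum(resid(shared)^2)
  rss_sep <- sum(resid(sep)^2)
  n <- length(x)
  df_sh <- n - 1
  df_sep <- n - nlevels(group)
  f_stat <- ((rss_sh - rss_sep) / (df_sh - df_sep)) / (rss_sep / df_sep)
  list(
    shared_slope = unname(coef(shared)),
    per_group_slopes = coef(sep),
    F = f_stat, df1 = df_sh - df_sep, df2 = df_sep,
    p_value = pf(f_stat, df_sh - df_sep, df_sep, lower.tail = FALSE)
  )
}
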