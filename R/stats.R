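#' One-way between-subjects ANOVA with eta-squared
#'
#' Classical between-subjects decomposition; `eta_sq = SS_between /
#' SS_total`.
#'
#' @param values numeric vector, or a list of numeric group samples.
#' @param groups grouping factor (ignored when `values` is a list).
#' @return An `anova_result`: list with the effect `table` (`ss`, `df`,
#'   `statistic`, `p`, `eta_sq`), and `n`.
#' @export
oneway_anova <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 values")
  fit <- lm(values ~ g)
  tab <- anova(fit)
  ss_b <- tab$`Sum Sq`[1]
  ss_e <- tab$`Sum Sq`[2]
  structure(list(
    table = data.frame(effect = c("group", "error"),
                       ss = c(ss_b, ss_e),
                       df = tab$Df,
                       statistic = c(tab$`F value`[1], NA),
                       p = c(tab$`Pr(>F)`[1], NA)),
    eta_sq = ss_b / (ss_b + ss_e),
    n = length(values)
  ), class = "anova_result")
}

#' Mixed repeated-measures ANOVA with partial and generalized eta-squared
#'
#' Univariate mixed-design decomposition for one between-subjects factor
#' and one to three within-subjects factors, with Type III sums of squares
#' under sum-to-zero contrasts (so unbalanced group sizes are handled), a
#' subjects-within-groups error term for between effects, and
#' factor-by-subjects error strata for the within effects. For each effect,
#' partial eta-squared is `SS_e / (SS_e + SS_err(e))` and generalized
#' eta-squared is `SS_e / (SS_e + sum of all error SS in the design)`.
#'
#' @param data long-format data frame.
#' @param dv name of the numeric response column.
#' @param subject name of the subject-id column.
#' @param within character vector (length 0..3) of within-factor columns;
#'   empty/`NULL` gives a purely between-subjects Type III analysis (one
#'   error term, so partial and generalized eta-squared coincide).
#' @param between optional name of the between-groups column.
#' @return An `anova_result` with columns `effect`, `ss`, `df`, `error_ss`,
#'   `error_df`, `statistic` (F), `p`, `pes` (partial eta-sq), `ges`
#'   (generalized eta-sq).
#' @export
mixed_rm_anova <- function(data, dv, subject, within = NULL,
                           between = NULL) {
  if (length(within) == 0) {
    if (is.null(between)) stop("need a between or within factor")
    data[[between]] <- factor(data[[between]])
    fit <- lm(stats::reformulate(between, response = dv), data = data,
              contrasts = setNames(list("contr.sum"), between))
    av <- car::Anova(fit, type = 3)
    ss <- av$`Sum Sq`[2]
    ss_e <- av$`Sum Sq`[nrow(av)]
    tab <- data.frame(effect = between, ss = ss, df = av$Df[2],
                      error_ss = ss_e, error_df = av$Df[nrow(av)],
                      statistic = av$`F value`[2], p = av$`Pr(>F)`[2],
                      pes = ss / (ss + ss_e), ges = ss / (ss + ss_e),
                      row.names = NULL)
    return(structure(list(table = tab, error_strata = "between",
                          total_error_ss = ss_e, n = nrow(data)),
                     class = "anova_result"))
  }
  stopifnot(length(within) >= 1, length(within) <= 3)
  for (col in c(dv, subject, within, between))
    if (!col %in% names(data)) stop("column not found: ", col)
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])

  # wide response: one row per subject, one column per within cell
  cells <- do.call(expand.grid, c(lapply(rev(within), function(w)
    levels(data[[w]])), list(stringsAsFactors = TRUE)))
  names(cells) <- rev(within)
  cells <- cells[, within, drop = FALSE]
  cell_key <- function(df) do.call(paste, c(df[, within, drop = FALSE],
                                            list(sep = ".")))
  data$`..cell` <- cell_key(data)
  wanted <- cell_key(cells)
  subjects <- levels(data[[subject]])
  Y <- matrix(NA_real_, length(subjects), nrow(cells),
              dimnames = list(subjects, wanted))
  for (i in seq_len(nrow(data))) {
    Y[as.character(data[[subject]][i]), data$`..cell`[i]] <-
      data[[dv]][i]
  }
  if (anyNA(Y)) {
    bad <- which(is.na(Y), arr.ind = TRUE)[1, ]
    stop(sprintf("missing within-subject cell: subject %s, cell %s",
                 subjects[bad[1]], wanted[bad[2]]))
  }

  if (!is.null(between)) {
    grp <- data[[between]][!duplicated(data[[subject]])]
    grp <- grp[match(subjects, unique(as.character(data[[subject]])))]
    bdf <- data.frame(..grp = factor(grp))
    if (nlevels(bdf$..grp) < 2) stop("between factor needs >= 2 levels")
    mod <- lm(Y ~ ..grp, data = bdf,
              contrasts = list(..grp = "contr.sum"))
  } else {
    mod <- lm(Y ~ 1)
  }
  idesign <- stats::as.formula(paste("~", paste(within, collapse = " * ")))
  av <- car::Anova(mod, idata = cells, idesign = idesign, type = 3)
  ut <- suppressWarnings(summary(av, multivariate = FALSE))$univariate.tests

  eff <- rownames(ut)
  ss <- ut[, "Sum Sq"]
  df <- ut[, "num Df"]
  err_ss <- ut[, "Error SS"]
  err_df <- ut[, "den Df"]

  # stratum of each effect = its within-factor part
  stratum <- vapply(eff, function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1]]
    paste(intersect(within, parts), collapse = ":")
  }, character(1))
  uniq <- !duplicated(stratum)
  total_error_ss <- sum(err_ss[uniq])

  keep <- eff != "(Intercept)"
  out_eff <- sub("^\\.\\.grp", between %||% "group", eff[keep])
  out_eff <- gsub(":\\.\\.grp", paste0(":", between %||% "group"), out_eff)
  tab <- data.frame(effect = out_eff, ss = ss[keep], df = df[keep],
                    error_ss = err_ss[keep], error_df = err_df[keep],
                    statistic = ut[keep, "F value"],
                    p = ut[keep, "Pr(>F)"],
                    pes = ss[keep] / (ss[keep] + err_ss[keep]),
                    ges = ss[keep] / (ss[keep] + total_error_ss),
                    row.names = NULL)
  structure(list(table = tab, error_strata = unique(stratum),
                 total_error_ss = total_error_ss, n = length(subjects)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' t tests with the report's standardized effect sizes
#'
#' Two-sample: independent pooled-variance t test with Glass' delta
#' `(mean(a) - mean(b)) / sd(b)` (the second sample is the reference
#' group). One-sample (when `b` is `NULL`): t test against `mu` with
#' Hedges' g1, the small-sample bias-corrected standardized mean
#' difference `J * (mean(a) - mu) / sd(a)`, `J = 1 - 3/(4 df - 1)`.
#'
#' @param a numeric sample.
#' @param b reference sample, or `NULL` for a one-sample test.
#' @param mu null value for the one-sample test.
#' @return A `test_result` list: `statistic`, `df`, `p`, `effect_size`,
#'   `effect_size_name`, `n`, and `effect_size_undefined` when the
#'   reference SD is zero.
#' @export
t_test_report <- function(a, b = NULL, mu = 0) {
  if (is.null(b)) {
    ht <- t.test(a, mu = mu)
    df <- unname(ht$parameter)
    J <- 1 - 3 / (4 * df - 1)
    sda <- sd(a)
    es <- if (sda > 0) J * (mean(a) - mu) / sda else NA_real_
    structure(list(statistic = unname(ht$statistic), df = df,
                   p = ht$p.value, effect_size = es,
                   effect_size_name = "hedges_g1",
                   effect_size_undefined = !(sda > 0),
                   n = length(a), tails = 2),
              class = "test_result")
  } else {
    ht <- t.test(a, b, var.equal = TRUE)
    sdb <- sd(b)
    es <- if (sdb > 0) (mean(a) - mean(b)) / sdb else NA_real_
    structure(list(statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p = ht$p.value,
                   effect_size = es, effect_size_name = "glass_delta",
                   effect_size_undefined = !(sdb > 0),
                   n = c(length(a), length(b)), tails = 2),
              class = "test_result")
  }
}

#' Kruskal-Wallis test
#'
#' Rank-based k-group comparison with tie correction (via
#' [stats::kruskal.test()]).
#'
#' @param values numeric vector or list of group samples.
#' @param groups grouping factor (ignored for a list).
#' @return A `test_result` with `statistic` (H), `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  g <- factor(groups)
  if (any(table(g) < 2)) stop("every group needs at least 2 values")
  ht <- kruskal.test(values, g)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 n = length(values)), class = "test_result")
}

#' Mann-Whitney U test with Cohen's U3
#'
#' U is counted over pairs as `sum(a_i > b_j) + 0.5 * ties` and reported
#' with the convention `max(U, n1*n2 - U)`. The p value is exact when
#' `n1*n2 <= 400` and there are no ties, otherwise a normal approximation
#' with tie and continuity correction is used. Cohen's U3 is the
#' proportion of the second sample's values strictly below the median of
#' the first sample, ties counted half.
#'
#' @param a first sample (reference for U3's median).
#' @param b second sample.
#' @return A `test_result` with `statistic` (reported U), `u_a` (the raw
#'   first-sample U), `u3`, `p`, `n`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("empty group")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && n1 * n2 <= 400
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  med_a <- median(a)
  u3 <- (sum(b < med_a) + 0.5 * sum(b == med_a)) / n2
  structure(list(statistic = max(u_a, n1 * n2 - u_a), u_a = u_a,
                 u3 = u3, p = ht$p.value, n = c(n1 = n1, n2 = n2)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic %.4g, p %.4g\n", x$statistic, x$p))
  invisible(x)
}

#' Pearson and Spearman correlations
#'
#' Thin wrapper over [stats::cor.test()] returning the fields used in the
#' report. Spearman p values use the t approximation when ties are present.
#'
#' @param x,y numeric vectors (pairwise complete observations are used).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `test_result` with `statistic` (r or rho), `p`, `n`.
#' @export
cor_report <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          n = length(x), undefined = TRUE,
                          method = method), class = "test_result"))
  ht <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  structure(list(statistic = unname(ht$estimate), p = ht$p.value,
                 n = length(x), undefined = FALSE, method = method),
            class = "test_result")
}

#' Partial Spearman correlation controlling for one covariate
#'
#' Spearman correlation of `x` and `y` with `z` partialled out: the
#' first-order recursion on the pairwise Spearman correlations,
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, equivalent to
#' correlating the residuals of rank regressions. The p value uses the t
#' distribution with `n - 3` degrees of freedom.
#'
#' @param x,y variables of interest.
#' @param z controlled covariate.
#' @return A `test_result` with `statistic` (partial rho), `p`, `n`.
#' @export
partial_spearman <- function(x, y, z) {
  ok <- complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete triples")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (sd(rx) == 0 || sd(ry) == 0 || sd(rz) == 0)
    return(structure(list(statistic = NA_real_, p = NA_real_, n = n,
                          undefined = TRUE), class = "test_result"))
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den < 1e-12)
    return(structure(list(statistic = NA_real_, p = NA_real_, n = n,
                          undefined = TRUE), class = "test_result"))
  rp <- (rxy - rxz * ryz) / den
  rp <- clamp(rp, -1, 1)
  p <- if (abs(rp) >= 1) 0 else {
    tt <- rp * sqrt((n - 3) / (1 - rp^2))
    2 * pt(-abs(tt), df = n - 3)
  }
  structure(list(statistic = rp, p = p, n = n, undefined = FALSE),
            class = "test_result")
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for a family of `m` comparisons; e.g. three behavioral
#' readouts against 54 subjective scales give `0.05 / (3 * 54) = 0.00031`
#' (5 dp).
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons (>= 1).
#' @return corrected per-comparison threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is_scalar_number(m) || m < 1) stop("m must be >= 1")
  alpha / m
}
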