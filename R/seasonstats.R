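# Seasonal comparisons and sigma-restricted general linear models.
#
# The GLM table mirrors what mainstream ANCOVA software prints per term:
# standardized beta with its CI, the Type-III (partial) F and p, partial
# eta-squared = SS_term / (SS_term + SS_residual), and observed power at
# alpha = 0.05 computed from the noncentral F at ncp = F_obs * df1.

#' Seasonal one-way comparison with post hoc tests
#'
#' One-way ANOVA of a cohort response across groups (default seasons), with
#' Tukey HSD adjusted pairwise comparisons, per-group Shapiro-Wilk normality
#' annotations and a Kruskal-Wallis H test alongside for when normality is
#' doubtful.
#'
#' @param cohort data frame (e.g. a `cohort_table`).
#' @param response name of the numeric response column.
#' @param group name of the grouping column (default `"season"`).
#' @return list of class `comparison_result`: `F`, `df`, `p`, `posthoc`
#'   (pair, difference, adjusted p), `shapiro`, `kruskal`, `n`.
#' @export
seasonal_anova <- function(cohort, response, group = "season") {
  df <- as.data.frame(cohort)
  stopifnot(response %in% names(df), group %in% names(df))
  ok <- is.finite(df[[response]]) & !is.na(df[[group]])
  y <- df[[response]][ok]
  g <- factor(df[[group]][ok],
              levels = intersect(c(SEASONS, unique(df[[group]])),
                                 unique(df[[group]][ok])))
  cnt <- table(g)
  if (length(cnt) < 2 || sum(cnt >= 2) < 2)
    stop("need at least 2 groups with at least 2 observations")

  shapiro <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- y[g == lv]
    if (length(v) >= 3 && length(v) <= 5000 && stats::sd(v) > 0) {
      sw <- stats::shapiro.test(v)
      data.frame(group = lv, n = length(v), W = unname(sw$statistic),
                 p = sw$p.value)
    } else data.frame(group = lv, n = length(v), W = NA_real_, p = NA_real_)
  }))

  pairs <- utils::combn(levels(g), 2)
  if (stats::var(y) == 0) {
    posthoc <- data.frame(
      pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
      difference = 0, p_adj = 1)
    out <- list(test = "one-way ANOVA", F = 0,
                df = c(length(levels(g)) - 1L, length(y) - length(levels(g))),
                p = 1, posthoc = posthoc, shapiro = shapiro,
                kruskal = NULL, n = length(y))
    class(out) <- "comparison_result"
    return(out)
  }

  fit <- stats::aov(y ~ g)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  posthoc <- data.frame(pair = rownames(tk), difference = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL)
  kw <- stats::kruskal.test(y, g)
  out <- list(test = "one-way ANOVA",
              F = sm[["F value"]][1],
              df = c(sm[["Df"]][1], sm[["Df"]][2]),
              p = sm[["Pr(>F)"]][1],
              posthoc = posthoc, shapiro = shapiro,
              kruskal = list(H = unname(kw$statistic), df = unname(kw$parameter),
                             p = kw$p.value),
              n = length(y))
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: F(%d, %d) = %.4g, p = %.4g (n = %d)\n",
              x$test, x$df[1], x$df[2], x$F, x$p, x$n))
  if (!is.null(x$kruskal))
    cat(sprintf("  Kruskal-Wallis: H(%d) = %.4g, p = %.4g\n",
                x$kruskal$df, x$kruskal$H, x$kruskal$p))
  if (!is.null(x$posthoc)) {
    cat("  Tukey HSD:\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %-18s diff = %8.4g  p = %.4g\n", x$posthoc$pair[i],
                  x$posthoc$difference[i], x$posthoc$p_adj[i]))
  }
  invisible(x)
}

#' Observed power of an F test at the sample-estimated noncentrality
#'
#' The convention used by mainstream ANCOVA software: the power of the
#' term's F test computed at noncentrality `ncp = F * df1` and level `alpha`.
#'
#' @param f observed F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @param alpha test level.
#' @return power in \code{[0, 1]}.
#' @export
observed_power <- function(f, df1, df2, alpha = 0.05) {
  fcrit <- stats::qf(1 - alpha, df1, df2)
  ifelse(is.finite(f),
         stats::pf(fcrit, df1, df2, ncp = f * df1, lower.tail = FALSE),
         1)
}

#' Partial eta-squared from an F statistic
#'
#' `partial eta^2 = F*df1 / (F*df1 + df2)`, identical to
#' `SS_term / (SS_term + SS_residual)`.
#'
#' @inheritParams observed_power
#' @return partial eta-squared in \code{[0, 1]}.
#' @export
partial_eta_squared <- function(f, df1, df2)
  ifelse(is.finite(f), f * df1 / (f * df1 + df2), 1)

# Build the standardized sigma-restricted design block for one term.
# Continuous variables are z-scored; two-level factors are effect-coded
# -1/+1 (first sorted level +1) and then z-scored so their coefficient is a
# standardized beta; `season` is either a z-scored ordered numeric score
# (winter < spring < summer < autumn; single df) or sum-coded columns.
term_block <- function(name, col, season_coding) {
  if (name == "season" && (is.character(col) || is.factor(col))) {
    lev <- intersect(SEASONS, unique(as.character(col)))
    if (season_coding == "linear") {
      sc <- match(as.character(col), lev)
      m <- matrix(z_score(sc), ncol = 1,
                  dimnames = list(NULL, "season"))
      return(m)
    }
    f <- factor(as.character(col), levels = lev)
    m <- stats::model.matrix(~ f, contrasts.arg = list(f = "contr.sum"))[, -1,
                                                                         drop = FALSE]
    colnames(m) <- paste0("season", seq_len(ncol(m)))
    return(apply(m, 2, z_score))
  }
  if (is.character(col) || is.factor(col) || is.logical(col)) {
    lev <- sort(unique(as.character(col)))
    if (length(lev) != 2)
      stop("factor term '", name, "' must have exactly 2 levels (got ",
           length(lev), ")")
    code <- ifelse(as.character(col) == lev[1], 1, -1)
    m <- matrix(z_score(code), ncol = 1, dimnames = list(NULL, name))
    return(m)
  }
  if (stats::sd(col) == 0)
    stop("continuous term '", name, "' has zero variance")
  matrix(z_score(col), ncol = 1, dimnames = list(NULL, name))
}

#' Sigma-restricted general linear model table
#'
#' Fits an ordinary least-squares model of a (standardized) response on
#' standardized predictors with sigma-restricted (sum-to-zero) coding of
#' categorical terms, and reports, per term: the standardized coefficient
#' and its CI, the Type-III partial F and p, partial eta-squared and
#' observed power at `alpha = 0.05`.
#'
#' The `season` term (when present) is by default a single-df ordered
#' numeric score winter < spring < summer (< autumn); set
#' `season_coding = "categorical"` for sum-coded multi-df seasons.
#'
#' @param cohort data frame of one row per observation.
#' @param formula model formula, e.g.
#'   `log2_re ~ light_mesor + light_phase + population + age + bmi + sex`.
#' @param seasons optional season subset applied before fitting (e.g.
#'   `c("winter", "spring", "summer")` to omit autumn).
#' @param season_coding `"linear"` (single df) or `"categorical"`.
#' @param standardize_response z-score the response (`TRUE`, the standardized
#'   beta convention) or leave it on its own scale (`FALSE`, so coefficients
#'   are per-SD-of-predictor effects useful for recovery against generating
#'   values). F, p, partial eta-squared and power are unaffected.
#' @param alpha level for observed power.
#' @return data frame of class `glm_table` with one row per term: `term`,
#'   `beta`, `ci_lo`, `ci_hi`, `F`, `p`, `partial_eta2`, `observed_power`,
#'   `df1`, `df2`; attributes `n`, `response`, `coding`.
#' @export
fit_glm <- function(cohort, formula, seasons = NULL,
                    season_coding = c("linear", "categorical"),
                    standardize_response = TRUE, alpha = 0.05) {
  season_coding <- match.arg(season_coding)
  df <- as.data.frame(cohort)
  if (!is.null(seasons)) {
    stopifnot("season" %in% names(df))
    df <- df[df$season %in% seasons, , drop = FALSE]
  }
  tf <- stats::terms(formula)
  vars <- all.vars(formula)
  response <- vars[1]
  labels <- attr(tf, "term.labels")
  if (length(labels) == 0) stop("formula has no predictors")
  miss <- setdiff(c(response, labels), names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  use <- df[, c(response, labels), drop = FALSE]
  cc <- stats::complete.cases(use) & is.finite(use[[response]])
  if (sum(!cc) > 0)
    message(sum(!cc), " incomplete row(s) dropped")
  use <- use[cc, , drop = FALSE]
  n <- nrow(use)
  if (n < length(labels) + 2)
    stop("too few complete rows (", n, ") for ", length(labels), " terms")

  blocks <- lapply(labels, function(lb)
    term_block(lb, use[[lb]], season_coding))
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  block_cols <- split(seq_len(ncol(X))[-1],
                      rep(seq_along(blocks), vapply(blocks, ncol, 0L)))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  y <- use[[response]]
  if (standardize_response) y <- z_score(y)
  coef <- qr.coef(qrX, y)
  rss_full <- sum((y - drop(X %*% coef))^2)
  df2 <- n - ncol(X)
  sigma2 <- rss_full / df2
  V <- sigma2 * chol2inv(qr.R(qrX))
  tcrit <- stats::qt(1 - alpha / 2, df2)

  rows <- lapply(seq_along(labels), function(j) {
    cols <- block_cols[[j]]
    Xr <- X[, -cols, drop = FALSE]
    cr <- qr.coef(qr(Xr), y)
    ss <- sum((y - drop(Xr %*% cr))^2) - rss_full
    df1 <- length(cols)
    f <- (ss / df1) / (rss_full / df2)
    beta <- if (df1 == 1) unname(coef[cols]) else NA_real_
    se <- if (df1 == 1) sqrt(V[cols, cols]) else NA_real_
    data.frame(term = labels[j], beta = beta,
               ci_lo = beta - tcrit * se, ci_hi = beta + tcrit * se,
               F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
               partial_eta2 = ss / (ss + rss_full),
               observed_power = observed_power(f, df1, df2, alpha),
               df1 = df1, df2 = df2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$F), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "response") <- response
  attr(out, "coding") <- "sigma-restricted"
  attr(out, "season_coding") <- season_coding
  class(out) <- c("glm_table", "data.frame")
  out
}

#' @export
print.glm_table <- function(x, digits = 3, ...) {
  cat(sprintf("<glm_table> response %s, n = %d, sigma-restricted coding\n",
              attr(x, "response"), attr(x, "n")))
  cat(sprintf("  %-22s %7s %17s %8s %8s %7s %7s\n", "term", "beta",
              "beta 95% CI", "F", "p", "eta2p", "power"))
  for (i in seq_len(nrow(x))) {
    ci <- if (is.na(x$beta[i])) "" else
      sprintf("(%6.3f; %6.3f)", x$ci_lo[i], x$ci_hi[i])
    cat(sprintf("  %-22s %7.3f %17s %8.3f %8.4f %7.3f %7.3f\n",
                x$term[i], x$beta[i], ci, x$F[i], x$p[i],
                x$partial_eta2[i], x$observed_power[i]))
  }
  invisible(x)
}
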