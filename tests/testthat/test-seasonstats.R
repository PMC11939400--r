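make_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    season = sample(SEASONS, n, replace = TRUE),
    y = rnorm(n, 10, 2),
    x1 = rnorm(n),
    x2 = runif(n, 5, 9),
    population = sample(c("native", "nonnative"), n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = runif(n, 18, 52),
    bmi = runif(n, 18, 35)
  )
}

test_that("identical observations give F = 0 and unit post hoc p-values", {
  df <- data.frame(season = rep(SEASONS, each = 5), y = 3)
  res <- seasonal_anova(df, "y")
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$posthoc$p_adj == 1))
  expect_equal(nrow(res$posthoc), 6L)      # all season pairs
})

test_that("two-group ANOVA F equals the pooled-variance t squared", {
  set.seed(51)
  df <- data.frame(season = rep(c("winter", "summer"), c(12, 15)),
                   y = c(rnorm(12, 5), rnorm(15, 6)))
  res <- seasonal_anova(df, "y")
  tt <- t.test(y ~ season, data = df, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("the seasonal ANOVA reports Tukey, Shapiro and Kruskal companions", {
  ch <- simulate_cohort(generator_config(), seed = 14)
  re <- delta_delta_cq(ch$expression)
  tab <- assemble_cohort(re, ch$meta)
  tab$log2_re <- log2(tab$relative_expression)
  res <- seasonal_anova(tab, "log2_re")
  expect_equal(res$df[1], 3)
  expect_equal(res$n, 97)
  expect_equal(nrow(res$posthoc), 6L)
  expect_equal(nrow(res$shapiro), 4L)
  expect_true(res$kruskal$H > 0)
  # summer is generated highest, winter lowest
  sw <- res$posthoc[res$posthoc$pair == "summer-winter", ]
  expect_gt(sw$difference, 0)
  expect_lt(sw$p_adj, 0.05)
})

test_that("a response equal to its predictor gives beta = 1, eta2 = 1, power = 1", {
  df <- make_cohort(30, seed = 52)
  df$y <- df$x1
  tab <- fit_glm(df, y ~ x1)
  expect_equal(tab$beta, 1, tolerance = 1e-12)
  expect_equal(tab$partial_eta2, 1)
  expect_equal(tab$observed_power, 1)
})

test_that("partial eta2 identity F*df1/(F*df1+df2) holds on every row", {
  df <- make_cohort(60, seed = 53)
  df$y <- df$y + 0.5 * df$x1
  tab <- fit_glm(df, y ~ x1 + x2 + season + population + age + bmi + sex,
                 season_coding = "categorical")
  expect_equal(tab$partial_eta2,
               tab$F * tab$df1 / (tab$F * tab$df1 + tab$df2),
               tolerance = 1e-12)
  expect_true(all(tab$observed_power >= 0 & tab$observed_power <= 1))
})

test_that("observed power is monotone in F at fixed df", {
  f <- seq(0.1, 40, length.out = 60)
  pw <- observed_power(f, 1, 65)
  expect_true(all(diff(pw) > 0))
  pw2 <- observed_power(f, 3, 20)
  expect_true(all(diff(pw2) > 0))
})

test_that("affine rescaling of a continuous predictor changes nothing", {
  df <- make_cohort(50, seed = 54)
  df$y <- df$y + 0.8 * df$x1
  a <- fit_glm(df, y ~ x1 + x2 + sex)
  df$x1 <- 100 * df$x1 - 7
  b <- fit_glm(df, y ~ x1 + x2 + sex)
  expect_equal(a$beta, b$beta, tolerance = 1e-9)
  expect_equal(a$F, b$F, tolerance = 1e-9)
  expect_equal(a$partial_eta2, b$partial_eta2, tolerance = 1e-9)
  expect_equal(a$observed_power, b$observed_power, tolerance = 1e-9)
})

test_that("per-term F agrees with an independent Type-III oracle (car::Anova)", {
  for (seed in c(55, 56, 57)) {
    df <- make_cohort(28, seed = seed)
    df$y <- df$y + 0.6 * df$x1 - 0.3 * df$x2 +
      0.5 * (df$population == "native")
    tab <- fit_glm(df, y ~ x1 + x2 + population + sex + season,
                   season_coding = "categorical")
    dd <- data.frame(y = scale(df$y),
                     x1 = scale(df$x1), x2 = scale(df$x2),
                     population = factor(df$population),
                     sex = factor(df$sex),
                     season = factor(df$season, levels = SEASONS))
    fit <- lm(y ~ x1 + x2 + population + sex + season, data = dd,
              contrasts = list(population = "contr.sum", sex = "contr.sum",
                               season = "contr.sum"))
    aa <- car::Anova(fit, type = 3)
    for (trm in c("x1", "x2", "population", "sex", "season")) {
      expect_equal(tab$F[tab$term == trm], aa[trm, "F value"],
                   tolerance = 1e-8, label = paste("F for", trm))
    }
  }
})

test_that("standardized betas match a scaled lm fit for 1-df terms", {
  df <- make_cohort(45, seed = 58)
  df$y <- df$y + 0.7 * df$x1
  tab <- fit_glm(df, y ~ x1 + x2 + age)
  fit <- lm(scale(y) ~ scale(x1) + scale(x2) + scale(age), data = df)
  sm <- coef(summary(fit))
  for (trm in c("x1", "x2", "age")) {
    expect_equal(tab$beta[tab$term == trm],
                 unname(sm[paste0("scale(", trm, ")"), "Estimate"]),
                 tolerance = 1e-9)
  }
  ci <- confint(fit)
  expect_equal(tab$ci_lo[tab$term == "x1"],
               unname(ci["scale(x1)", 1]), tolerance = 1e-9)
})

test_that("season can enter as a single-df ordered score, omitting autumn", {
  df <- make_cohort(80, seed = 59)
  df$y <- df$y + match(df$season, SEASONS)
  tab <- fit_glm(df, y ~ season + x1, seasons = c("winter", "spring", "summer"))
  expect_equal(tab$df1[tab$term == "season"], 1L)
  expect_false(is.na(tab$beta[tab$term == "season"]))
  expect_gt(tab$beta[tab$term == "season"], 0)
  expect_equal(attr(tab, "n"), sum(df$season != "autumn"))
  tab2 <- fit_glm(df, y ~ season + x1,
                  seasons = c("winter", "spring", "summer"),
                  season_coding = "categorical")
  expect_equal(tab2$df1[tab2$term == "season"], 2L)
})

test_that("rank deficiency is a hard error naming the collinear term", {
  df <- make_cohort(30, seed = 60)
  df$x2 <- 2 * df$x1 + 1
  expect_error(fit_glm(df, y ~ x1 + x2), "collinear")
  df$x3 <- 5
  expect_error(fit_glm(df, y ~ x1 + x3), "zero variance")
})

test_that("incomplete rows are dropped listwise with a message", {
  df <- make_cohort(30, seed = 61)
  df$x1[c(3, 9)] <- NA
  expect_message(tab <- fit_glm(df, y ~ x1 + x2), "2 incomplete")
  expect_equal(attr(tab, "n"), 28L)
})
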