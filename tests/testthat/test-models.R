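cell_data <- function(a, b, c, d) {
  # exposed: a cases, d non-cases... laid out so the cross-product (a*b')/(..)
  # equals the odds ratio of outcome vs exposure
  data.frame(
    x = factor(rep(c("exposed", "unexposed"), times = c(a + b, c + d)),
               levels = c("unexposed", "exposed")),
    y = factor(rep(c("case", "control", "case", "control"),
                   times = c(a, b, c, d)), levels = c("control", "case")))
}

test_that("chi-square screen matches the closed form and brute force", {
  d0 <- cell_data(10, 10, 10, 10)
  s0 <- chisq_screen(d0, "x", "y")
  expect_equal(s0$statistic, 0)
  expect_equal(s0$p_value, 1)
  expect_false(s0$pass)

  d1 <- cell_data(30, 10, 10, 30)
  s1 <- chisq_screen(d1, "x", "y")
  expect_equal(s1$statistic, 20)   # every expected count is 20
  expect_equal(s1$df, 1)
  expect_true(s1$pass)

  # 3x2 against a brute-force expected-count computation
  set.seed(31)
  d2 <- data.frame(x = sample(c("a", "b", "c"), 300, replace = TRUE),
                   y = sample(c("s", "t"), 300, replace = TRUE,
                              prob = c(0.3, 0.7)))
  tab <- table(d2$x, d2$y)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chisq_screen(d2, "x", "y")$statistic,
               sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(chisq_screen(d2, "x", "y")$df, 2)

  expect_error(chisq_screen(data.frame(x = rep("a", 10),
                                       y = rep(c("s", "t"), 5)), "x", "y"),
               "degenerate")
})

test_that("single-covariate logistic OR equals the contingency cross-product", {
  # odds(exposed) / odds(unexposed) = (10/5) / (20/40) = 4
  d <- data.frame(
    x = factor(rep(c("unexposed", "exposed"), times = c(60, 15)),
               levels = c("unexposed", "exposed")),
    y = factor(rep(c("case", "control", "case", "control"),
                   times = c(20, 40, 10, 5)), levels = c("control", "case")))
  des <- build_design(d, "x")
  fit <- fit_multinomial(des, d$y, ref_outcome = "control")
  expect_true(fit$converged)
  expect_equal(exp(fit$coefficients["xexposed", "case"]), 4,
               tolerance = 1e-8)

  # null case: balanced independent covariate gives OR 1
  d0 <- cell_data(25, 25, 25, 25)
  f0 <- fit_multinomial(build_design(d0, "x"), d0$y, "control")
  expect_equal(exp(f0$coefficients["xexposed", "case"]), 1, tolerance = 1e-6)
})

test_that("two-level fit equals an independent IRLS binary logistic fit", {
  set.seed(37)
  n <- 800
  d <- data.frame(x1 = factor(sample(c("a", "b"), n, TRUE)),
                  x2 = factor(sample(c("u", "v", "w"), n, TRUE)))
  eta <- -0.4 + 0.8 * (d$x1 == "b") + 0.5 * (d$x2 == "v")
  d$y <- factor(ifelse(runif(n) < plogis(eta), "case", "control"),
                levels = c("control", "case"))
  des <- build_design(d, c("x1", "x2"))
  fit <- fit_multinomial(des, d$y, "control")
  ref <- glm(y ~ x1 + x2, data = d, family = binomial())
  expect_equal(unname(fit$coefficients[, "case"]), unname(coef(ref)),
               tolerance = 1e-8)
  se_ref <- sqrt(diag(vcov(ref)))
  expect_equal(unname(fit$se[, "case"]), unname(se_ref), tolerance = 1e-6)
})

test_that("three-level fit agrees with an independent multinomial fitter", {
  skip_if_not_installed("nnet")
  set.seed(41)
  n <- 2000
  d <- data.frame(x = factor(sample(c("lo", "hi"), n, TRUE)))
  p_hi <- c(0.5, 0.25, 0.25)
  p_lo <- c(0.6, 0.3, 0.1)
  lvl <- c("A", "B", "C")
  draw <- function(p) sample(lvl, 1, prob = p)
  d$y <- factor(vapply(seq_len(n), function(i) {
    if (d$x[i] == "hi") draw(p_hi) else draw(p_lo)
  }, character(1)), levels = lvl)
  des <- build_design(d, "x")
  fit <- fit_multinomial(des, d$y, "A")
  nn <- nnet::multinom(y ~ x, data = d, trace = FALSE, reltol = 1e-14)
  expect_equal(unname(t(fit$coefficients)), unname(coef(nn)),
               tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("log-likelihood never decreases across Newton iterations", {
  # monitored indirectly: a deliberately hard, near-separated problem still
  # ends at a likelihood no worse than the start and converges or flags
  set.seed(43)
  n <- 60
  d <- data.frame(x = factor(c(rep("a", 30), rep("b", 30))))
  d$y <- factor(c(rep("case", 28), rep("control", 2),
                  rep("case", 3), rep("control", 27)),
                levels = c("control", "case"))
  fit <- fit_multinomial(build_design(d, "x"), d$y, "control")
  ll0 <- {
    p0 <- mean(d$y == "case")
    sum(log(ifelse(d$y == "case", p0, 1 - p0)))
  }
  expect_gte(fit$loglik, ll0)
  expect_true(fit$converged)
})

test_that("complete separation is flagged and handled by ridge fallback", {
  d <- data.frame(x = factor(rep(c("a", "b"), each = 20)),
                  y = factor(rep(c("case", "control"), each = 20),
                             levels = c("control", "case")))
  expect_warning(fit <- fit_multinomial(build_design(d, "x"), d$y, "control"),
                 "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("backward elimination drops a planted null and keeps a strong covariate", {
  set.seed(47)
  n <- 4000
  d <- data.frame(strong = factor(sample(c("no", "yes"), n, TRUE)),
                  null = factor(sample(c("p", "q"), n, TRUE)))
  eta <- -1 + log(2.5) * (d$strong == "yes")
  d$y <- factor(ifelse(runif(n) < plogis(eta), "case", "control"),
                levels = c("control", "case"))
  fit <- backward_eliminate(d, "y", c("strong", "null"), "control")
  expect_equal(fit$retained, "strong")
  expect_equal(fit$eliminated$covariate, "null")
  expect_gt(fit$eliminated$p_value, 0.05)

  # all-strong spec is unchanged
  d$strong2 <- factor(ifelse(runif(n) < plogis(-0.5 + 1 * (d$y == "case")),
                             "hi", "lo"))
  fit2 <- backward_eliminate(d, "y", c("strong", "strong2"), "control")
  expect_setequal(fit2$retained, c("strong", "strong2"))

  # empty covariate list falls back to intercept-only
  expect_warning(fit3 <- backward_eliminate(d, "y", character(0), "control"),
                 "intercept-only")
  expect_equal(nrow(fit3$coefficients), 1L)
})

test_that("VIF: orthogonality, aliasing, planted R-squared, scale invariance", {
  set.seed(53)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  X <- cbind("(Intercept)" = 1, a = x1, b = x2, c = x3)
  v <- vif_diagnostics(X)
  expect_true(all(abs(v$vif - 1) < 0.06))
  expect_false(any(v$aliased))

  Xd <- cbind(X, dup = x1)
  vd <- vif_diagnostics(Xd)
  expect_true(vd$aliased[vd$column == "dup"])
  expect_true(is.infinite(vd$vif[vd$column == "a"]))

  # x2 = x1 + noise tuned so R^2 = 0.75 -> VIF = 4
  noise <- rnorm(n, sd = sd(x1) / sqrt(3))
  Xr <- cbind("(Intercept)" = 1, a = x1, b = x1 + noise)
  vr <- vif_diagnostics(Xr)
  expect_lt(abs(vr$vif[1] - 4), 0.45)

  # invariant to column scaling
  Xs <- Xr; Xs[, "b"] <- Xs[, "b"] * 1000
  expect_equal(vif_diagnostics(Xs)$vif, vr$vif, tolerance = 1e-9)

  expect_error(vif_diagnostics(X[, 1:2]), "at least 2")
})

test_that("OR table renders reference rows, CIs and stars", {
  set.seed(59)
  n <- 3000
  d <- data.frame(x = factor(sample(c("ref_lvl", "exp"), n, TRUE),
                             levels = c("ref_lvl", "exp")))
  eta <- -0.8 + log(2) * (d$x == "exp")
  d$y <- factor(ifelse(runif(n) < plogis(eta), "case", "control"),
                levels = c("control", "case"))
  fit <- backward_eliminate(d, "y", "x", "control")
  tab <- or_table(list(main = fit))
  ref_row <- tab[tab$reference, ]
  expect_equal(ref_row$or, 1)
  expect_true(is.na(ref_row$ci_low))
  expect_equal(ref_row$level, "ref_lvl")
  exp_row <- tab[!tab$reference, ]
  expect_true(exp_row$ci_low <= exp_row$or & exp_row$or <= exp_row$ci_high)
  expect_true(exp_row$significant)
  expect_true(exp_row$ci_low < 2 & 2 < exp_row$ci_high)
})

test_that("Wald CI coverage of a planted coefficient is near nominal", {
  set.seed(61)
  beta <- log(1.8)
  hits <- 0L
  n_rep <- 300L
  for (r in seq_len(n_rep)) {
    n <- 1500
    x <- rbinom(n, 1, 0.5)
    y <- runif(n) < plogis(-0.7 + beta * x)
    d <- data.frame(x = factor(x), y = factor(y, levels = c(FALSE, TRUE)))
    fit <- fit_multinomial(build_design(d, "x"), d$y, "FALSE")
    b <- fit$coefficients["x1", "TRUE"]
    s <- fit$se["x1", "TRUE"]
    if (b - 1.96 * s <= beta && beta <= b + 1.96 * s) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.92)
  expect_lt(hits / n_rep, 0.98)
})
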