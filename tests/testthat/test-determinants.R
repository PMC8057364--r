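test_that("intercept-only logit recovers the log odds of the base rate", {
  dm <- data.frame(che = rep(c(1L, 0L), c(60, 40)))
  attr(dm, "threshold") <- 0.30
  class(dm) <- c("che_design", "data.frame")
  fit <- fit_logit(dm)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(0.6 / 0.4),
               tolerance = 1e-6)
  expect_equal(fit$lr_df, 0)
})

test_that("logit recovers known coefficients within 3 SE at n = 5000", {
  set.seed(2024)
  b <- c(x1 = 0.4, x2 = -0.6, x3 = 0.25)
  dm <- logistic_design(5000, b, intercept = -0.5)
  fit <- fit_logit(dm)
  expect_true(fit$converged)
  for (v in names(b)) {
    expect_lt(abs(fit$coefficients[v] - b[v]), 3 * fit$std_errors[v])
  }
  ## CI brackets the estimate, pseudo-R2 in [0, 1], gradient ~ 0
  expect_true(all(fit$ci95[, "lo"] < fit$coefficients &
                    fit$coefficients < fit$ci95[, "hi"]))
  expect_gte(fit$pseudo_r2, 0)
  expect_lte(fit$pseudo_r2, 1)
  X <- model.matrix(fit$glm)
  score <- drop(crossprod(X, dm$che - fitted(fit$glm)))
  expect_lt(max(abs(score)), 1e-6)
})

test_that("null-covariate slope CIs cover zero at about the 95% rate", {
  set.seed(314)
  hits <- vapply(1:300, function(i) {
    dm <- logistic_design(200, numeric(0), n_null = 1, intercept = 0)
    fit <- suppressWarnings(fit_logit(dm))
    fit$ci95["x1", "lo"] < 0 && 0 < fit$ci95["x1", "hi"]
  }, logical(1))
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})

test_that("pseudo-R2 is invariant to affine rescaling of covariates", {
  set.seed(8)
  dm <- logistic_design(2000, c(x1 = 0.5, x2 = -0.3))
  f1 <- fit_logit(dm)
  dm$x1 <- 100 * dm$x1 + 7
  dm$x2 <- -2 * dm$x2
  f2 <- fit_logit(dm)
  expect_equal(f1$pseudo_r2, f2$pseudo_r2, tolerance = 1e-8)
})

test_that("singular designs raise a rank error naming the column", {
  set.seed(9)
  dm <- logistic_design(200, c(x1 = 0.5))
  dm$x2 <- 2 * dm$x1
  expect_error(fit_logit(dm), "x2")
  expect_error(fit_lpm(dm), "x2")
})

test_that("AMEs match central finite differences of mean probability", {
  set.seed(21)
  dm <- logistic_design(1500, c(x1 = 0.6, x2 = -0.4))
  dm$bin <- rbinom(1500, 1, 0.5)  # binary covariate
  fit <- fit_logit(dm)
  ame <- marginal_effects(fit)
  X <- model.matrix(fit$glm)
  h <- 1e-5
  for (v in c("x1", "x2")) {
    Xp <- X; Xp[, v] <- Xp[, v] + h
    Xm <- X; Xm[, v] <- Xm[, v] - h
    fd <- (mean(plogis(Xp %*% fit$coefficients)) -
             mean(plogis(Xm %*% fit$coefficients))) / (2 * h)
    expect_equal(unname(ame[v]), fd, tolerance = 1e-6)
  }
  ## binary AME is the counterfactual-mean contrast by definition
  X1 <- X; X1[, "bin"] <- 1
  X0 <- X; X0[, "bin"] <- 0
  expect_equal(unname(ame["bin"]),
               mean(plogis(X1 %*% fit$coefficients)) -
                 mean(plogis(X0 %*% fit$coefficients)))
  ## continuous AMEs are proportional to their coefficients
  expect_equal(unname(ame["x1"] / fit$coefficients["x1"]),
               unname(ame["x2"] / fit$coefficients["x2"]))
})

test_that("LPM matches the closed-form normal equations on a toy design", {
  X <- cbind(1, c(0, 1, 2, 3, 4))
  y <- c(0, 0, 1, 1, 1)
  dm <- data.frame(che = y, x1 = X[, 2])
  attr(dm, "threshold") <- 0.30
  class(dm) <- c("che_design", "data.frame")
  fit <- fit_lpm(dm)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), drop(beta_hat),
               tolerance = 1e-12)
})

test_that("LPM is exact when the response equals a column", {
  dm <- data.frame(che = c(0, 1, 0, 1, 1, 0), x1 = c(0, 1, 0, 1, 1, 0))
  attr(dm, "threshold") <- 0.30
  class(dm) <- c("che_design", "data.frame")
  fit <- suppressWarnings(fit_lpm(dm))  # summary warns on a perfect fit
  expect_equal(unname(fit$coefficients["x1"]), 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_lt(max(abs(residuals(fit$lm))), 1e-12)
})

test_that("OLS residuals are orthogonal to every design column", {
  set.seed(12)
  dm <- logistic_design(800, c(x1 = 0.5, x2 = -0.2, x3 = 0.1))
  fit <- fit_lpm(dm)
  X <- model.matrix(fit$lm)
  r <- residuals(fit$lm)
  rel <- abs(crossprod(X, r)) / (sqrt(colSums(X^2)) * sqrt(sum(r^2)))
  expect_lt(max(rel), 1e-8)
})

test_that("stepwise keeps a single significant covariate", {
  set.seed(33)
  dm <- logistic_design(2000, c(x1 = 0.8))
  st <- stepwise_select(dm, "logit")
  expect_equal(st$selected, "x1")
  expect_equal(st$log$action[1], "enter")
  expect_s3_class(st$fit, "che_fit")
})

test_that("stepwise degenerates to the full and empty models", {
  set.seed(34)
  dm <- logistic_design(800, c(x1 = 0.5, x2 = -0.4), n_null = 2)
  full <- stepwise_select(dm, "logit", p_enter = 1, p_remove = 1)
  expect_setequal(full$selected, paste0("x", 1:4))
  empty <- stepwise_select(dm, "logit", p_enter = 1e-20,
                           p_remove = 1e-20)
  expect_equal(empty$selected, character(0))
  expect_error(stepwise_select(dm, "logit", p_enter = 0.1,
                               p_remove = 0.05), "p_enter")
})

test_that("stepwise works identically through the OLS route", {
  set.seed(35)
  dm <- logistic_design(2000, c(x1 = 0.6, x2 = -0.5), n_null = 3)
  st <- stepwise_select(dm, "ols")
  expect_true(all(c("x1", "x2") %in% st$selected))
  expect_equal(st$fit$model, "ols")
})

test_that("model comparison aligns AMEs with OLS slopes", {
  set.seed(44)
  dm <- logistic_design(3000, c(x1 = 0.5, x2 = -0.5))
  fl <- fit_logit(dm)
  fl$marginal_effects <- marginal_effects(fl)
  lp <- fit_lpm(dm)
  cmp <- compare_models(fl, lp)
  expect_true(all(cmp$sign_agree))
  expect_true(all(cmp$abs_diff < 0.05))
  ## identical effect vectors give zero differences
  fl2 <- fl
  fl2$marginal_effects <- lp$marginal_effects
  cmp2 <- compare_models(fl2, lp)
  expect_equal(cmp2$abs_diff, rep(0, 2))
  ## name mismatch is an alignment error
  lp2 <- lp
  names(lp2$marginal_effects) <- c("x1", "zz")
  expect_error(compare_models(fl, lp2), "align")
})

test_that("contingency chi-square matches the textbook formula", {
  ## 2x2 table [[30,10],[10,30]]: chi2 = n (ad-bc)^2 / (r1 r2 c1 c2) = 20
  flags <- rep(c(0L, 1L, 0L, 1L), c(30, 10, 10, 30))
  group <- rep(c("a", "b"), c(40, 40))
  res <- contingency_chi2(flags, group)
  expect_equal(res$chi2, 80 * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40))
  expect_equal(res$df, 1)
  ## perfectly balanced tables carry no association
  f2 <- rep(c(0L, 1L), 20)
  g2 <- rep(c("a", "b"), each = 20)
  expect_equal(contingency_chi2(f2, g2)$chi2, 0)
  g3 <- rep(c("a", "b", "c"), length.out = 60)
  f3 <- rep(c(0L, 1L), 30)
  res3 <- contingency_chi2(f3, g3)
  expect_equal(res3$df, 2)
  expect_equal(res3$chi2, 0)
})

test_that("empty groups are dropped with a warning", {
  flags <- rep(c(0L, 1L), 10)
  group <- factor(rep(c("a", "b"), 10), levels = c("a", "b", "c"))
  expect_warning(res <- contingency_chi2(flags, group), "empty")
  expect_equal(res$df, 1)
  expect_error(contingency_chi2(flags, rep("a", 20)), "two non-empty")
})

test_that("significance stars follow both table conventions", {
  p <- c(0.005, 0.03, 0.07, 0.5)
  expect_equal(significance_stars(p, "regression"),
               c("***", "**", "*", ""))
  expect_equal(significance_stars(c(0.0005, 0.005, 0.03, 0.07),
                                  "descriptive"),
               c("***", "**", "*", ""))
})
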