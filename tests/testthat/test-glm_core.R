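# Model fitting: design matrices, closed-form checks, oracle equivalence,
# information-matrix consistency and coding invariance.

test_that("design matrices are coded and rank-checked as specified", {
  df <- data.frame(e = c("glo", "glo", "sp1", "sp1"), y = 1:4,
                   stringsAsFactors = FALSE)
  b <- build_design_matrix(df, design_spec("e"))
  expect_equal(unname(b$X[, "e1"]), c(1, 1, -1, -1))  # sum-to-zero, 2 levels
  # shadehouse germination structure: intercept + 6 effect columns
  mf <- model_frame(simulate_rte(sim_config(seed = 1)),
                    "shadehouse_germination")
  b2 <- build_design_matrix(mf, design_spec(
    default_terms("shadehouse_germination")))
  expect_equal(ncol(b2$X), 7L)
  # a full five-factor interaction is not estimable on this design
  sf <- model_frame(simulate_rte(sim_config(seed = 1)), "survival")
  expect_error(
    build_design_matrix(sf, design_spec(c("e", "h", "o", "r", "s",
                                          "e:h:o:r:s"))),
    class = "rte_data_error")
})

test_that("binomial logit matches closed forms and the MLE oracle", {
  X <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_binomial_logit(rep(c(0, 1), 5), X)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  f2 <- fit_binomial_logit(c(rep(1, 7), rep(0, 3)), X)
  expect_equal(unname(f2$coefficients), log(7 / 3), tolerance = 1e-8)
  # small-n oracle: Nelder-Mead maximization of the same likelihood
  set.seed(3)
  for (rep in 1:5) {
    n <- 40
    x <- rnorm(n)
    X3 <- cbind("(Intercept)" = 1, x = x)
    y <- rbinom(n, 1, plogis(0.3 - 0.7 * x))
    fit <- fit_binomial_logit(y, X3)
    orc <- oracle_mle(function(b) rtadapt:::binomial_loglik(b, y, X3), 2)
    expect_lt(max(abs(fit$coefficients - orc)), 1e-5)
  }
})

test_that("binomial logit recovers simulated coefficients within 3 SE", {
  set.seed(4)
  n <- 5000
  e <- sample(c(-1, 1), n, replace = TRUE)
  t <- runif(n, 0, 10)
  beta_true <- c(-0.5, 0.6, 0.15)
  X <- cbind("(Intercept)" = 1, e = e, t = t)
  y <- rbinom(n, 1, plogis(X %*% beta_true))
  fit <- fit_binomial_logit(y, X)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - beta_true) < 3 * se))
})

test_that("separation is detected and handled by a penalized refit", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x  # perfectly separated
  X <- cbind("(Intercept)" = 1, x = x)
  expect_warning(fit <- fit_binomial_logit(y, X), "separation")
  expect_true("separation" %in% fit$flags)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("geometric fit matches the closed-form MLE and the oracle", {
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_geometric(c(0, 1, 2), rep(FALSE, 3), X)
  expect_equal(plogis(unname(f$coefficients)), 0.5, tolerance = 1e-8)
  # everyone dies in the first year: continuation probability 0
  f0 <- fit_geometric(rep(0, 20), rep(FALSE, 20),
                      matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)")))
  expect_lt(plogis(unname(f0$coefficients)), 1e-3)
  # censoring enters as q^k: closed form from the likelihood
  k <- c(2, 3, 1, 5, 5)
  cens <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  Xk <- matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)"))
  fc <- fit_geometric(k, cens, Xk)
  expect_equal(plogis(unname(fc$coefficients)),
               sum(k) / (sum(k) + sum(!cens)), tolerance = 1e-8)
  # oracle equivalence with a covariate
  set.seed(5)
  n <- 50
  x <- sample(c(-1, 1), n, replace = TRUE)
  q <- plogis(0.8 + 0.4 * x)
  kk <- rgeom(n, 1 - q)
  cc <- kk > 5
  kk <- pmin(kk, 5)
  Xx <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_geometric(kk, cc, Xx)
  orc <- oracle_mle(function(b) rtadapt:::geometric_loglik(b, kk, cc, Xx), 2)
  expect_lt(max(abs(fit$coefficients - orc)), 1e-5)
  expect_error(fit_geometric(c(1, 2), c(TRUE, TRUE),
                             matrix(1, 2, 1)), class = "rte_data_error")
})

test_that("geometric recovery: censored simulation at realistic survival", {
  # ~37% of 510 alive after the full experiment is roughly q^5 = 0.6 for
  # the germinated cohort; recovery checked within 3 SE at n = 2000
  set.seed(6)
  n <- 2000
  x1 <- sample(c(-1, 1), n, replace = TRUE)
  x2 <- sample(c(-1, 1), n, replace = TRUE)
  beta_true <- c(2.0, 0.4, -0.3)
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  q <- plogis(drop(X %*% beta_true))
  k <- rgeom(n, 1 - q)
  cens <- k >= 5
  k <- pmin(k, 5)
  fit <- fit_geometric(k, cens, X)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - beta_true) < 3 * se))
})

test_that("gaussian LM matches closed forms and recovers simulations", {
  X1 <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_gaussian_lm(c(1, 2, 3), X1)
  expect_equal(unname(f$coefficients), 2)
  expect_equal(f$sigma2, 1)
  # exact interpolation: coefficients to machine precision, sigma2 = 0
  set.seed(7)
  X <- cbind("(Intercept)" = 1, x = rnorm(20), z = rnorm(20))
  beta_true <- c(1, -2, 0.5)
  f2 <- fit_gaussian_lm(drop(X %*% beta_true), X)
  expect_equal(unname(f2$coefficients), beta_true, tolerance = 1e-12)
  expect_lt(f2$sigma2, 1e-20)
  # stochastic recovery within 3 SE at n = 2000
  Xs <- cbind("(Intercept)" = 1, x = rnorm(2000), z = rnorm(2000))
  ys <- drop(Xs %*% beta_true) + rnorm(2000, 0, 0.7)
  f3 <- fit_gaussian_lm(ys, Xs)
  expect_true(all(abs(f3$coefficients - beta_true) <
                    3 * sqrt(diag(f3$vcov))))
  expect_error(fit_gaussian_lm(1:2, cbind(1, c(0, 1), c(1, 0))),
               class = "rte_data_error")
})

test_that("observed information matches a finite-difference Hessian", {
  set.seed(8)
  n <- 200
  x <- rnorm(n)
  X <- cbind("(Intercept)" = 1, x = x)
  y <- rbinom(n, 1, plogis(0.2 + 0.5 * x))
  fit <- fit_binomial_logit(y, X)
  H <- fd_hessian(function(b) rtadapt:::binomial_loglik(b, y, X),
                  unname(fit$coefficients))
  info_fd <- -H
  info_fit <- solve(fit$vcov)
  expect_lt(max(abs(info_fd - info_fit)) / max(abs(info_fit)), 1e-4)

  q <- plogis(0.5 + 0.3 * x)
  k <- pmin(rgeom(n, 1 - q), 5)
  cens <- k == 5
  fitg <- fit_geometric(k, cens, X)
  Hg <- fd_hessian(function(b) rtadapt:::geometric_loglik(b, k, cens, X),
                   unname(fitg$coefficients))
  info_fd <- -Hg
  info_fit <- solve(fitg$vcov)
  expect_lt(max(abs(info_fd - info_fit)) / max(abs(info_fit)), 1e-4)
})

test_that("predictions are invariant to factor coding", {
  rec <- simulate_rte(sim_config(seed = 9))
  mf <- model_frame(rec, "growth", trait = "height_cm")
  terms <- default_terms("growth")
  f_sum <- rte_glm(mf, "y", terms, "gaussian", coding = "sum_to_zero")
  f_trt <- rte_glm(mf, "y", terms, "gaussian", coding = "treatment")
  nd <- expand.grid(e = rte_levels$ecotype, h = rte_levels$habitat,
                    o = rte_levels$provenance, r = rte_levels$plantation,
                    s = rte_levels$status, a = c(0, 1, 2, 4, 5),
                    stringsAsFactors = FALSE)
  expect_lt(max(abs(predict_linear(f_sum, nd)$eta -
                      predict_linear(f_trt, nd)$eta)), 1e-10)
})

test_that("wald_test covers degenerate, null and powered cases", {
  set.seed(10)
  X <- cbind("(Intercept)" = 1, x = rnorm(100))
  y <- drop(X %*% c(1, 0.5)) + rnorm(100)
  fit <- fit_gaussian_lm(y, X)
  z <- wald_test(fit, c(0, 0))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  # null p-values are uniform (scaled-down simulation, 400 reps)
  pvals <- replicate(400, {
    yy <- rnorm(60)
    ff <- fit_gaussian_lm(yy, cbind("(Intercept)" = 1, x = rnorm(60)))
    wald_test(ff, c(0, 1))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
  # a 4-SE effect: power at the 5% level is ~98% analytically
  hits <- replicate(200, {
    xx <- rnorm(200)
    se_b <- 1 / sqrt(sum((xx - mean(xx))^2))
    yy <- 4 * se_b * xx + rnorm(200)
    ff <- fit_gaussian_lm(yy, cbind("(Intercept)" = 1, x = xx))
    wald_test(ff, c(0, 1))$p_value < 0.05
  })
  expect_gt(mean(hits), 0.93)
})
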