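# Adjusted means and the home/away contrast: oracle equivalence, planted
# effect recovery, symmetry and back-transformed timing comparisons.

make_saturated_logit_fit <- function(cell_logits) {
  # construct a 2x2 logit fit whose cell predictions are exactly
  # cell_logits[e, o], by fitting weighted data at the exact probabilities
  grid <- expand.grid(e = c("glo", "sp1"), o = c("E", "W"),
                      stringsAsFactors = FALSE)
  reps <- 2000L
  rows <- do.call(rbind, lapply(seq_len(4), function(i) {
    p <- plogis(cell_logits[i])
    n1 <- round(reps * p)
    data.frame(e = grid$e[i], o = grid$o[i],
               y = rep(c(1, 0), c(n1, reps - n1)),
               stringsAsFactors = FALSE)
  }))
  rte_glm(rows, "y", c("e", "o", "e:o"), "binomial_logit")
}

test_that("lsmean averages cell predictions exactly", {
  # saturated 2x2 fit with approximate cell logits (0, 1, 2, 3):
  # the glo LS mean over provenance equals mean(cell(glo,E), cell(glo,W))
  fit <- make_saturated_logit_fit(c(0, 1, 2, 3))
  m <- lsmean(fit, focal = list(e = "glo"), nuisance = "o")
  cells <- predict_linear(fit, data.frame(e = "glo", o = c("E", "W")))$eta
  expect_equal(m$estimate, mean(cells), tolerance = 1e-10)
  expect_equal(m$estimate, brute_force_lsmean(fit, list(e = "glo"), "o"),
               tolerance = 1e-10)
  # weight vector reproduces the estimate exactly
  expect_equal(drop(m$weights %*% fit$coefficients), m$estimate)
  # asking for an uncovered model variable is a configuration error
  expect_error(lsmean(fit, focal = list(e = "glo")),
               class = "rte_config_error")
})

test_that("lsmean equals the brute-force cell average on small fits", {
  # acceptance-style oracle equivalence at n <= 50, both codings
  for (seed in 1:6) {
    set.seed(seed)
    n <- 50
    df <- data.frame(
      e = sample(c("glo", "sp1"), n, replace = TRUE),
      h = sample(c("SF", "HT"), n, replace = TRUE),
      o = sample(c("E", "W"), n, replace = TRUE),
      a = sample(0:5, n, replace = TRUE),
      stringsAsFactors = FALSE)
    df$y <- rnorm(n, 1 + 0.3 * df$a + (df$e == "glo") * 0.5)
    for (coding in c("sum_to_zero", "treatment")) {
      fit <- rte_glm(df, "y", c("e", "h", "e:h", "o", "a", "a:e"),
                     "gaussian", coding = coding)
      m <- lsmean(fit, focal = list(e = "glo", h = "SF"),
                  nuisance = "o", at = list(a = 3))
      expect_equal(m$estimate,
                   brute_force_lsmean(fit, list(e = "glo", h = "SF"),
                                      "o", at = list(a = 3)),
                   tolerance = 1e-10)
    }
  }
})

test_that("under sum-to-zero coding the LS mean is the closed-form weight", {
  # survival-style model: mu + alpha_eh + mean over the 8 (o,r,s) cells
  rec <- simulate_rte(sim_config(seed = 21))
  sf <- model_frame(rec, "survival")
  fit <- rte_glm(sf, "k", default_terms("survival"), "geometric")
  m <- lsmean(fit, focal = list(e = "glo", h = "SF"),
              nuisance = c("o", "r", "s"))
  cells <- expand.grid(o = c("E", "W"), r = c("E", "W"),
                       s = c("seed", "seedling"), stringsAsFactors = FALSE)
  cells$e <- "glo"
  cells$h <- "SF"
  expect_equal(m$estimate, mean(predict_linear(fit, cells)$eta),
               tolerance = 1e-10)
  expect_equal(m$n_cells, 8L)
})

test_that("home/away contrast recovers a planted effect of 4d", {
  # alpha_11 = alpha_22 = +d, alpha_12 = alpha_21 = -d in the growth
  # generator implies C_a -> 4d for every age
  d <- 0.15
  g <- sim_config()$growth$height_cm
  g$alpha_eh <- matrix(c(d, -d, -d, d), 2, 2)  # [e, h] home-diagonal
  g$gamma_eh[] <- 0
  est <- vapply(1:8, function(s) {
    cfg <- sim_config(seed = 100 + s, traits = "height_cm",
                      growth = list(height_cm = g))
    rec <- simulate_rte(cfg)
    mf <- model_frame(rec, "growth", trait = "height_cm")
    fit <- rte_glm(mf, "y", default_terms("growth"), "gaussian")
    home_away_contrast(fit, c("e", "h"), nuisance = c("o", "r", "s"),
                       at_values = list(a = 2))$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 4 * d), 3 * sd(est) / sqrt(length(est)) + 0.02)
})

test_that("the contrast is antisymmetric in the habitat labels", {
  rec <- simulate_rte(sim_config(seed = 23))
  mf <- model_frame(rec, "growth", trait = "height_cm")
  fit <- rte_glm(mf, "y", default_terms("growth"), "gaussian")
  ca <- home_away_contrast(fit, c("e", "h"), nuisance = c("o", "r", "s"),
                           at_values = list(a = c(1, 5)))
  # swapping which cells count as "home" flips the sign, not the size
  ca_swap <- home_away_contrast(fit, c("e", "h"),
                                nuisance = c("o", "r", "s"),
                                at_values = list(a = c(1, 5)),
                                home = list(c("glo", "HT"), c("sp1", "SF")))
  expect_equal(ca$estimate, -ca_swap$estimate, tolerance = 1e-10)
  expect_equal(abs(ca$statistic), abs(ca_swap$statistic), tolerance = 1e-10)
  expect_s3_class(ca, "contrast_result")
  expect_true(all(ca$stars %in% c("NS", "*", "**", "***")))
})

test_that("a symmetric model yields a null contrast", {
  # all four (e,h) cells identical by construction: fit on data simulated
  # with no (e,h) structure at all and sigma = 0
  g <- sim_config()$growth$height_cm
  g$alpha_eh[] <- 0
  g$gamma_eh[] <- 0
  g$sigma <- 1e-8
  g$delta_ors[] <- 0
  g$theta_ors[] <- 0
  cfg <- sim_config(seed = 24, traits = "height_cm",
                    growth = list(height_cm = g))
  rec <- simulate_rte(cfg)
  mf <- model_frame(rec, "growth", trait = "height_cm")
  fit <- rte_glm(mf, "y", default_terms("growth"), "gaussian")
  ca <- home_away_contrast(fit, c("e", "h"), nuisance = c("o", "r", "s"),
                           at_values = list(a = 3))
  expect_lt(abs(ca$estimate), 1e-6)
})

test_that("overall-germination LS means separate a planted cell", {
  germ <- sim_config()$germination
  germ$mu <- 0.0
  germ$beta_t <- 0
  germ$alpha_e[] <- 0
  germ$delta_o[] <- 0
  germ$eta_o[] <- 0
  germ$eps_eo[] <- 0
  germ$eps_eo["glo", "E"] <- 2  # one cell planted +2 logit
  germ$field_hazard[] <- 0.05
  cfg <- sim_config(seed = 25, germination = germ)
  rec <- simulate_rte(cfg)
  mf <- model_frame(rec, "overall_germination")
  fit <- rte_glm(mf, "y", default_terms("overall_germination"),
                 "binomial_logit")
  res <- germination_overall_lsmeans(fit, c("e", "o"))
  planted <- res$lsmeans$estimate[res$lsmeans$e == "glo" &
                                    res$lsmeans$o == "E"]
  expect_true(all(planted > res$lsmeans$estimate[!(res$lsmeans$e == "glo" &
                                                     res$lsmeans$o == "E")]))
  cmp <- res$comparisons
  involving <- grepl("glo:E", cmp$cell_1) | grepl("glo:E", cmp$cell_2)
  expect_lt(min(cmp$p_adjusted[involving]), 0.001)
  # single-group margin: one LS mean, no comparisons
  res1 <- germination_overall_lsmeans(fit, character(0))
  expect_null(res1$comparisons)
})

test_that("expected germination time back-transforms correctly", {
  # intercept-only geometric fit on delays with mean 3 -> LS mean time 3
  df <- data.frame(k = c(2, 3, 4, 1, 5), censored = FALSE, g = "all",
                   stringsAsFactors = FALSE)
  fit <- rte_glm(df, "k", "g", "geometric", link = "log_on_mean")
  res <- germination_time_comparison(fit, by = "g")
  expect_equal(res$lsmeans$expected_time, mean(df$k), tolerance = 1e-6)
  # degenerate: identical delays reproduce that time exactly
  dfc <- data.frame(k = rep(3, 30), censored = FALSE, g = "all",
                    stringsAsFactors = FALSE)
  fitc <- rte_glm(dfc, "k", "g", "geometric", link = "log_on_mean")
  resc <- germination_time_comparison(fitc, by = "g")
  expect_equal(resc$lsmeans$expected_time, 3, tolerance = 1e-6)
  # east-fast / west-slow world: ordering recovered, contrast significant
  germ <- sim_config()$germination
  germ$mu <- -8          # nobody germinates in the shadehouse
  germ$beta_t <- 0
  germ$field_hazard[] <- rep(c(0.5, 0.12), times = 4)  # E fast, W slow
  cfg <- sim_config(seed = 26, germination = germ)
  rec <- simulate_rte(cfg)
  tf <- model_frame(rec, "germination_timing")
  fit2 <- rte_glm(tf, "k", default_terms("germination_timing"),
                  "geometric", link = "log_on_mean")
  res2 <- germination_time_comparison(fit2, by = "o")
  tE <- res2$lsmeans$expected_time[res2$lsmeans$o == "E"]
  tW <- res2$lsmeans$expected_time[res2$lsmeans$o == "W"]
  expect_lt(tE, tW)
  expect_lt(res2$comparisons$p_value, 0.05)
})
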