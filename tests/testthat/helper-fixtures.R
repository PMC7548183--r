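# Shared fixtures and independent oracles for the test suite.

# a tiny hand-built individuals table (4 individuals, 2 gardens)
tiny_individuals <- function() {
  data.frame(
    individual_id = c("i1", "i2", "i3", "i4"),
    mother_id = c("m1", "m1", "m2", "m2"),
    garden_id = c("g1", "g1", "g2", "g2"),
    ecotype = c("glo", "glo", "sp1", "sp1"),
    habitat = c("SF", "SF", "HT", "HT"),
    provenance = c("E", "E", "W", "W"),
    plantation = c("E", "E", "W", "W"),
    status = c("seedling", "seed", "seed", "seed"),
    shadehouse_days = c(100L, 100L, 40L, 40L),
    germ_timing = c("at_transplant", "year2", "never", "year1"),
    fate_y1 = c("alive", "pre_germination", "pre_germination", "alive"),
    fate_y2 = c("alive", "alive", "pre_germination", "alive"),
    fate_y3 = c("alive", "alive", "pre_germination", "dead"),
    fate_y4 = c("alive", "dead", "pre_germination", "dead"),
    fate_y5 = c("alive", "dead", "pre_germination", "dead"),
    stringsAsFactors = FALSE
  )
}

tiny_measurements <- function() {
  data.frame(
    individual_id = c("i1", "i1", "i1", "i4"),
    age = c(0L, 1L, 2L, 1L),
    trait = c("height_cm", "height_cm", "height_cm", "height_cm"),
    value = c(10, 20, 40, 12),
    stringsAsFactors = FALSE
  )
}

# independent maximum-likelihood oracle: direct numerical maximization of
# the log-likelihood with Nelder-Mead (never touches the package fitters'
# internals)
oracle_mle <- function(loglik, p, start = rep(0, p)) {
  opt <- stats::optim(start, function(b) -loglik(b), method = "Nelder-Mead",
                      control = list(maxit = 50000, reltol = 1e-14))
  opt$par
}

# brute-force LS mean: average of per-cell linear predictors enumerated
# over the nuisance grid (independent of lsmean()'s weight algebra)
brute_force_lsmean <- function(fit, focal, nuisance, at = list()) {
  grid <- expand.grid(fit$spec$xlevels[nuisance], stringsAsFactors = FALSE)
  if (!nrow(grid)) grid <- data.frame(row.names = 1L)
  preds <- vapply(seq_len(max(1L, nrow(grid))), function(i) {
    nd <- grid[i, , drop = FALSE]
    for (nm in names(focal)) nd[[nm]] <- focal[[nm]]
    for (nm in names(at)) nd[[nm]] <- at[[nm]]
    predict_linear(fit, nd)$eta
  }, numeric(1))
  mean(preds)
}

# finite-difference Hessian of a scalar function
fd_hessian <- function(f, x, eps = 1e-5) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ei <- ej <- rep(0, p)
    ei[i] <- eps
    ej[j] <- eps
    H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                  f(x - ei + ej) + f(x - ei - ej)) / (4 * eps^2)
  }
  (H + t(H)) / 2
}
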