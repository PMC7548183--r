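# From-scratch model fitting: binomial-logit regression by iteratively
# reweighted least squares, censored geometric time-to-event regression by
# Newton's method with analytic derivatives, and Gaussian linear models by
# QR decomposition. All fitters expose coefficients plus their covariance,
# which is what the least-squares-means layer consumes.

#' Specify a design matrix
#'
#' @param terms Character vector of term labels built from column names of
#'   the model frame, with `:` for interactions (e.g.
#'   `c("e", "o", "e:o", "t", "e:t", "o:t")`). An intercept is always
#'   included.
#' @param coding Factor coding: `"sum_to_zero"` (default; effects sum to
#'   zero over levels, so cell effects match the symmetric-parametrization
#'   formulas) or `"treatment"` (first level as reference).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(terms, coding = c("sum_to_zero", "treatment")) {
  coding <- match.arg(coding)
  structure(list(terms = terms, coding = coding), class = "design_spec")
}

#' Build a numeric design matrix from a model frame
#'
#' Character columns are treated as factors (level order: canonical
#' [rte_levels] order where the column matches a design factor, sorted
#' otherwise) and coded per the spec. Columns are ordered
#' deterministically by the term order given. Rank deficiency — e.g. a
#' requested interaction whose level combinations were not all observed —
#' is an estimability error naming the offending columns, never a silent
#' drop.
#'
#' @param data Model frame (data frame).
#' @param spec A [design_spec()].
#' @param xlevels Optional named list of factor levels (used to rebuild
#'   the matrix for new data with the training levels).
#' @param check_rank Whether to error on rank deficiency.
#' @return List with `X` (matrix), `xlevels`, `contrasts` and `formula`.
#' @export
build_design_matrix <- function(data, spec, xlevels = NULL,
                                check_rank = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  vars <- unique(unlist(strsplit(spec$terms, ":", fixed = TRUE)))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop_config("model frame is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  canonical <- c(e = "ecotype", h = "habitat", o = "provenance",
                 r = "plantation", s = "status")
  df <- data[vars]
  lev <- list()
  for (v in vars) {
    x <- df[[v]]
    if (is.character(x) || is.factor(x)) {
      levels_v <- if (!is.null(xlevels[[v]])) {
        xlevels[[v]]
      } else if (v %in% names(canonical)) {
        rte_levels[[canonical[[v]]]]
      } else if (v %in% names(rte_levels)) {
        rte_levels[[v]]
      } else {
        sort(unique(as.character(x)))
      }
      bad <- setdiff(unique(as.character(x)), levels_v)
      if (length(bad)) {
        stop_data("column ", v, " has level(s) outside the training set: ",
                  paste(bad, collapse = ", "))
      }
      df[[v]] <- factor(as.character(x), levels = levels_v)
      lev[[v]] <- levels_v
    }
  }
  contrast_fun <- switch(spec$coding,
                         sum_to_zero = "contr.sum",
                         treatment = "contr.treatment")
  # one-level factors carry no contrast: their effect is absorbed by the
  # intercept, so they are removed from the term labels (not the frame)
  single <- names(lev)[lengths(lev) == 1L]
  terms_use <- vapply(spec$terms, function(tm) {
    comp <- setdiff(strsplit(tm, ":", fixed = TRUE)[[1L]], single)
    paste(comp, collapse = ":")
  }, character(1), USE.NAMES = FALSE)
  terms_use <- unique(terms_use[nzchar(terms_use)])
  contrasts_arg <- stats::setNames(
    rep(list(contrast_fun), sum(lengths(lev) > 1L)),
    names(lev)[lengths(lev) > 1L])
  formula <- if (length(terms_use)) {
    stats::reformulate(terms_use)
  } else {
    stats::as.formula("~ 1")
  }
  X <- stats::model.matrix(formula, df, contrasts.arg = contrasts_arg)
  if (check_rank) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      aliased <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
      stop_data("design matrix is rank deficient; inestimable column(s): ",
                paste(aliased, collapse = ", "),
                " (not all level combinations observed?)")
    }
  }
  list(X = X, xlevels = lev, contrasts = contrasts_arg, formula = formula)
}

new_rte_fit <- function(family, coefficients, vcov, loglik, deviance,
                        df_residual, converged, iterations,
                        sigma2 = NA_real_, flags = character()) {
  vcov <- (vcov + t(vcov)) / 2  # enforce symmetry against round-off
  structure(
    list(family = family, coefficients = coefficients, vcov = vcov,
         loglik = loglik, deviance = deviance, df_residual = df_residual,
         converged = converged, iterations = iterations, sigma2 = sigma2,
         flags = flags, spec = NULL, model_frame = NULL),
    class = "rte_fit"
  )
}

#' @export
print.rte_fit <- function(x, ...) {
  cat("<rte_fit>", x$family,
      if (!x$converged) "(NOT converged)" else "", "\n")
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se)
  print(round(tab, 4))
  cat("log-likelihood:", format(x$loglik), " deviance:",
      format(x$deviance), "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

binomial_loglik <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

geometric_loglik <- function(beta, k, censored, X) {
  eta <- drop(X %*% beta)
  q <- stats::plogis(eta)
  sum(k * log(q) + ifelse(censored, 0, log1p(-q)))
}

#' Fit a binomial-logit regression by IRLS
#'
#' Iteratively reweighted least squares to convergence (relative deviance
#' change below `tol` or `max_iter` iterations); the coefficient
#' covariance is the inverse Fisher information. Complete or
#' quasi-complete separation is detected from diverging linear predictors
#' and handled by refitting with a small L2 penalty (`ridge`) on the
#' non-intercept coefficients; such fits carry the flag `"separation"` and
#' a warning.
#'
#' @param y Binary 0/1 response vector.
#' @param X Full-rank numeric design matrix (with intercept column).
#' @param tol Convergence tolerance on the relative deviance change.
#' @param max_iter Maximum IRLS iterations.
#' @param ridge L2 penalty used only under separation.
#' @return An `rte_fit` object.
#' @export
fit_binomial_logit <- function(y, X, tol = 1e-10, max_iter = 100L,
                               ridge = 1e-4) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_data("response must be binary 0/1")
  irls <- function(lambda) {
    p <- ncol(X)
    pen <- diag(lambda, nrow = p, ncol = p)
    if ("(Intercept)" %in% colnames(X)) {
      pen[match("(Intercept)", colnames(X)),
          match("(Intercept)", colnames(X))] <- 0
    }
    beta <- rep(0, p)
    dev_old <- Inf
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-12)
      z <- eta + (y - mu) / w
      XtW <- t(X * w)
      beta <- drop(solve(XtW %*% X + pen, XtW %*% z))
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      dev <- -2 * binomial_loglik(beta, y, X)
      if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
        return(list(beta = beta, dev = dev, it = it, eta = eta,
                    converged = TRUE, pen = pen))
      }
      dev_old <- dev
    }
    list(beta = beta, dev = dev_old, it = max_iter, eta = eta,
         converged = FALSE, pen = pen)
  }
  res <- irls(0)
  flags <- character()
  separated <- max(abs(res$eta)) > 15
  if (separated || !res$converged) {
    if (separated) {
      warning("separation detected; refitting with L2 penalty ", ridge,
              " on non-intercept coefficients", call. = FALSE)
      flags <- "separation"
      res <- irls(ridge)
    }
    if (!res$converged) {
      stop_data("IRLS failed to converge after ", max_iter,
                " iterations (deviance ", format(res$dev), ")")
    }
  }
  mu <- stats::plogis(res$eta)
  w <- mu * (1 - mu)
  info <- t(X * w) %*% X + res$pen
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  ll <- binomial_loglik(res$beta, y, X)
  fit <- new_rte_fit("binomial_logit",
                     stats::setNames(res$beta, colnames(X)), vcov,
                     loglik = ll, deviance = -2 * ll,
                     df_residual = length(y) - ncol(X),
                     converged = res$converged, iterations = res$it,
                     flags = flags)
  fit
}

#' Fit a censored geometric time-to-event regression
#'
#' Models observed whole years survived `k` as geometric: an individual
#' continues a further year with probability `q`; an uncensored
#' observation contributes `q^k (1-q)` and a right-censored one `q^k` to
#' the likelihood. The linear predictor is `logit(q) = X beta`, which is
#' identical to a log link on the mean number of completed years
#' `q/(1-q)`, so `link` only selects the reporting convention. Newton
#' iterations with analytic gradient and Hessian; covariance from the
#' observed information at the optimum.
#'
#' @param k Non-negative integer vector of completed years.
#' @param censored Logical vector, `TRUE` when still alive at last census.
#' @param X Full-rank design matrix.
#' @param link `"logit_on_survival"` or `"log_on_mean"` (same fit; see
#'   above).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return An `rte_fit` object with attribute-level link information.
#' @export
fit_geometric <- function(k, censored, X,
                          link = c("logit_on_survival", "log_on_mean"),
                          tol = 1e-10, max_iter = 100L) {
  link <- match.arg(link)
  k <- as.numeric(k)
  censored <- as.logical(censored)
  if (any(k < 0 | k != floor(k))) {
    stop_data("k must contain non-negative integers")
  }
  if (all(censored)) {
    stop_data("all observations censored: continuation probability ",
              "not identifiable")
  }
  u <- as.numeric(!censored)
  p <- ncol(X)
  beta <- rep(0, p)
  if ("(Intercept)" %in% colnames(X)) {
    q0 <- sum(k) / (sum(k) + sum(u))
    beta[match("(Intercept)", colnames(X))] <-
      stats::qlogis(min(max(q0, 1e-6), 1 - 1e-6))
  }
  ll_old <- geometric_loglik(beta, k, censored, X)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    q <- stats::plogis(eta)
    score <- drop(t(X) %*% (k * (1 - q) - u * q))
    w <- (k + u) * q * (1 - q)
    info <- t(X * w) %*% X
    step <- drop(solve(info, score))
    # step-halving line search on the log-likelihood
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      ll_new <- geometric_loglik(beta_new, k, censored, X)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta_new
    if (abs(ll_new - ll_old) / (abs(ll_new) + 0.1) < tol) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  if (!converged) {
    stop_data("geometric fit failed to converge after ", max_iter,
              " iterations (log-likelihood ", format(ll_old), ")")
  }
  eta <- drop(X %*% beta)
  q <- stats::plogis(eta)
  info <- t(X * ((k + u) * q * (1 - q))) %*% X
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  # saturated log-likelihood for the deviance
  ll_sat <- sum(ifelse(u == 1 & k > 0,
                       k * log(k / (k + 1)) - log(k + 1),
                       0))
  fit <- new_rte_fit("geometric", stats::setNames(beta, colnames(X)), vcov,
                     loglik = ll_old, deviance = 2 * (ll_sat - ll_old),
                     df_residual = length(k) - p,
                     converged = TRUE, iterations = it)
  fit$link <- link
  fit
}

#' Fit a Gaussian linear model by QR decomposition
#'
#' Ordinary least squares through a QR decomposition (no normal
#' equations), with `sigma2 = RSS / (n - p)` and coefficient covariance
#' `sigma2 (X'X)^-1`. Growth traits are modelled on the natural-log
#' scale; the caller supplies the transformed response.
#'
#' @param y Numeric response (already log-transformed where applicable).
#' @param X Full-rank design matrix.
#' @return An `rte_fit` object with `sigma2` set.
#' @export
fit_gaussian_lm <- function(y, X) {
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) {
    stop_data("underdetermined: n = ", n, " observations for p = ", p,
              " coefficients")
  }
  qx <- qr(X)
  if (qx$rank < p) {
    stop_data("design matrix is rank deficient (rank ", qx$rank,
              " < ", p, ")")
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  Rinv <- backsolve(qr.R(qx), diag(p))
  xtx_inv <- Rinv %*% t(Rinv)
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  sig2_ml <- rss / n
  ll <- if (sig2_ml > 0) -n / 2 * (log(2 * pi * sig2_ml) + 1) else Inf
  new_rte_fit("gaussian", stats::setNames(drop(beta), colnames(X)), vcov,
              loglik = ll, deviance = rss, df_residual = n - p,
              converged = TRUE, iterations = 1L, sigma2 = sigma2)
}

#' Fit an RTE model from a model frame
#'
#' High-level entry point that builds the design matrix from `terms`,
#' dispatches to the family fitter and attaches the design metadata needed
#' by the least-squares-means layer ([lsmean()], [home_away_contrast()]).
#'
#' @param data Model frame with the term variables, the response column
#'   and, for the geometric family, a logical censoring column.
#' @param response Name of the response column (0/1 for binomial, numeric
#'   for gaussian, non-negative integer years for geometric).
#' @param terms Character vector of term labels (see
#'   [build_design_matrix()]).
#' @param family `"binomial_logit"`, `"geometric"` or `"gaussian"`.
#' @param coding Factor coding, as in [design_spec()].
#' @param censored For the geometric family, name of the logical
#'   censoring column (default `"censored"`).
#' @param link Geometric link convention, see [fit_geometric()].
#' @param ... Passed to the family fitter.
#' @return An `rte_fit` with `$spec` (terms, coding, xlevels) populated.
#' @export
rte_glm <- function(data, response, terms,
                    family = c("binomial_logit", "geometric", "gaussian"),
                    coding = c("sum_to_zero", "treatment"),
                    censored = "censored",
                    link = "logit_on_survival", ...) {
  family <- match.arg(family)
  coding <- match.arg(coding)
  if (!response %in% names(data)) {
    stop_config("response column '", response, "' not found")
  }
  spec <- design_spec(terms, coding)
  built <- build_design_matrix(data, spec)
  fit <- switch(
    family,
    binomial_logit = fit_binomial_logit(data[[response]], built$X, ...),
    geometric = {
      if (!censored %in% names(data)) {
        stop_config("censoring column '", censored, "' not found")
      }
      fit_geometric(data[[response]], data[[censored]], built$X,
                    link = link, ...)
    },
    gaussian = fit_gaussian_lm(data[[response]], built$X, ...)
  )
  fit$spec <- list(terms = terms, coding = coding, xlevels = built$xlevels,
                   contrasts = built$contrasts, response = response)
  fit$model_frame <- data
  fit
}

#' Linear predictor for new design cells
#'
#' Rebuilds the design rows for `newdata` with the training factor levels
#' and coding and returns `X` and the predicted linear predictor.
#'
#' @param fit An `rte_fit` from [rte_glm()].
#' @param newdata Data frame of term variables.
#' @return List with `X` and `eta`.
#' @export
predict_linear <- function(fit, newdata) {
  if (is.null(fit$spec)) {
    stop_config("fit carries no design spec; use rte_glm() to fit")
  }
  spec <- design_spec(fit$spec$terms, fit$spec$coding)
  built <- build_design_matrix(newdata, spec, xlevels = fit$spec$xlevels,
                               check_rank = FALSE)
  X <- built$X[, names(fit$coefficients), drop = FALSE]
  list(X = X, eta = drop(X %*% fit$coefficients))
}

pseudo_inverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(list(inv = A * 0, rank = 0L))
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(inv = inv, rank = sum(keep))
}

#' Wald test of a linear hypothesis L beta = 0
#'
#' Computes `(L b)' (L V L')^-1 (L b)` with a chi-square reference for the
#' GLM families and an F reference (on the residual degrees of freedom)
#' for Gaussian fits. Degenerate rows (all zero) contribute nothing; a
#' fully zero `L` returns statistic 0 with p-value 1.
#'
#' @param fit An `rte_fit`.
#' @param L Contrast matrix (or single contrast vector), columns matching
#'   the coefficients.
#' @return List with `statistic`, `df`, `p_value` (and `df2` for F tests).
#' @export
wald_test <- function(fit, L) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  if (ncol(L) != length(fit$coefficients)) {
    stop_config("contrast has ", ncol(L), " columns for ",
                length(fit$coefficients), " coefficients")
  }
  Lb <- drop(L %*% fit$coefficients)
  M <- L %*% fit$vcov %*% t(L)
  pinv <- pseudo_inverse(M)
  df <- pinv$rank
  if (df == 0L) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  stat <- drop(t(Lb) %*% pinv$inv %*% Lb)
  if (identical(fit$family, "gaussian")) {
    fstat <- stat / df
    p <- stats::pf(fstat, df, fit$df_residual, lower.tail = FALSE)
    list(statistic = fstat, df = df, df2 = fit$df_residual, p_value = p)
  } else {
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }
}
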