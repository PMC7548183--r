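# Least-squares (adjusted) means and the combined home-vs-away /
# local-vs-foreign contrast.
#
# An LS mean for a focal cell is the unweighted average of model-predicted
# linear predictors over every nuisance-factor cell (at fixed covariate
# values). Computing it by prediction averaging keeps it invariant to the
# factor coding; under sum-to-zero coding it reduces to the familiar
# closed-form weight vectors (1/2 over provenance for shadehouse
# germination, 1/8 over provenance x plantation x status for survival and
# growth).

# ---- model frames ---------------------------------------------------------

#' Model frames for the standard RTE analyses
#'
#' Build the model frame for one of the standard analyses. Short variable
#' names follow the field convention: `e` ecotype, `h` habitat, `o`
#' provenance region, `r` plantation region, `s` transplant status, `a`
#' age, `t` shadehouse days.
#'
#' * `shadehouse_germination`: all individuals; `y` = germinated before
#'   transplant, with `e`, `o`, `t`.
#' * `overall_germination`: all individuals; `y` = germinated at any point,
#'   with `e`, `o`, `h`, `r`.
#' * `survival`: germinated individuals; completed years `k` and
#'   `censored`, with `e`, `h`, `o`, `r`, `s`.
#' * `germination_timing`: germinated individuals; delay `k` in years
#'   (0 = germinated before transplant), with `e`, `o`.
#' * `growth`: one row per (alive individual, age) measurement of `trait`;
#'   `y` = log value, with `e`, `h`, `o`, `r`, `s`, `a`.
#'
#' @param records An [rte_records] object.
#' @param analysis One of the analyses above.
#' @param trait Trait name, for `analysis = "growth"`.
#' @return A model frame data frame.
#' @export
model_frame <- function(records,
                        analysis = c("shadehouse_germination",
                                     "overall_germination", "survival",
                                     "germination_timing", "growth"),
                        trait = NULL) {
  stopifnot(inherits(records, "rte_records"))
  analysis <- match.arg(analysis)
  ind <- records$individuals
  base <- data.frame(
    individual_id = ind$individual_id,
    e = ind$ecotype, h = ind$habitat, o = ind$provenance,
    r = ind$plantation, s = ind$status,
    stringsAsFactors = FALSE
  )
  switch(analysis,
    shadehouse_germination = {
      base$t <- ind$shadehouse_days
      base$y <- as.integer(ind$status == "seedling")
      base
    },
    overall_germination = {
      base$y <- as.integer(ind$germ_timing != "never")
      base
    },
    survival = {
      surv <- encode_survival(records)
      out <- merge(base, surv, by = "individual_id", sort = FALSE)
      names(out)[names(out) == "final_age"] <- "k"
      out
    },
    germination_timing = {
      keep <- ind$germ_timing != "never"
      out <- base[keep, , drop = FALSE]
      delay <- match(ind$germ_timing[keep],
                     paste0("year", seq_len(records$n_years)))
      out$k <- ifelse(is.na(delay), 0L, delay)
      out$censored <- FALSE
      out
    },
    growth = {
      if (is.null(records$measurements)) {
        stop_config("records carry no measurements")
      }
      if (is.null(trait) || !trait %in% rte_traits) {
        stop_config("growth frame needs a valid trait name")
      }
      mea <- records$measurements
      mt <- mea[mea$trait == trait & mea$value > 0, , drop = FALSE]
      out <- merge(mt[c("individual_id", "age", "value")], base,
                   by = "individual_id", sort = FALSE)
      out$a <- out$age
      out$y <- log(out$value)
      out
    })
}

#' Default term sets of the standard RTE models
#'
#' The shadehouse germination model crosses ecotype and provenance with
#' shadehouse time; survival and growth use the (ecotype x habitat) cell,
#' the (provenance x plantation x status) cell and (for growth) their age
#' interactions — without an (e,h) x (o,r,s) interaction, which the design
#' cannot estimate.
#'
#' @param analysis Analysis name as in [model_frame()].
#' @return Character vector of term labels.
#' @export
default_terms <- function(analysis) {
  eh <- c("e", "h", "e:h")
  ors <- c("o", "r", "s", "o:r", "o:s", "r:s", "o:r:s")
  switch(analysis,
    shadehouse_germination = c("e", "o", "e:o", "t", "e:t", "o:t"),
    overall_germination = c("e", "o", "e:o", "h", "r", "h:r"),
    survival = c(eh, ors),
    germination_timing = c("e", "o", "e:o"),
    growth = c(eh, ors, "a",
               paste0("a:", eh), paste0("a:", ors)),
    stop_config("unknown analysis: ", analysis))
}

# ---- adjusted means -------------------------------------------------------

model_variables <- function(fit) {
  unique(unlist(strsplit(fit$spec$terms, ":", fixed = TRUE)))
}

#' Least-squares (adjusted) mean of a focal cell
#'
#' Averages the model's predicted linear predictor uniformly over every
#' combination of nuisance-factor levels, at the supplied covariate
#' values, and returns the corresponding linear functional of the
#' coefficients with its delta-method standard error. The returned weight
#' vector reproduces the estimate exactly as `weights %*% coef(fit)`.
#'
#' @param fit An `rte_fit` from [rte_glm()].
#' @param focal Named list of the focal factor levels, e.g.
#'   `list(e = "glo", h = "SF")`.
#' @param nuisance Character vector of factor names to average over.
#' @param at Named list of covariate values (e.g. `list(a = 3)` or
#'   `list(t = 89)`).
#' @return Object of class `adjusted_mean`: focal cell, `estimate` (link
#'   scale), `se`, `weights`.
#' @export
lsmean <- function(fit, focal, nuisance = character(), at = list()) {
  vars <- model_variables(fit)
  supplied <- c(names(focal), nuisance, names(at))
  missing_vars <- setdiff(vars, supplied)
  if (length(missing_vars)) {
    stop_config("model variable(s) not covered by focal/nuisance/at: ",
                paste(missing_vars, collapse = ", "))
  }
  bad <- setdiff(nuisance, names(fit$spec$xlevels))
  if (length(bad)) {
    stop_config("nuisance variable(s) without stored factor levels: ",
                paste(bad, collapse = ", "))
  }
  grid <- if (length(nuisance)) {
    expand.grid(fit$spec$xlevels[nuisance], stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(row.names = 1L)
  }
  n_cells <- max(1L, nrow(grid))
  newdata <- grid
  for (nm in names(focal)) newdata[[nm]] <- focal[[nm]]
  for (nm in names(at)) newdata[[nm]] <- at[[nm]]
  pred <- predict_linear(fit, newdata)
  w <- colMeans(pred$X)
  est <- drop(w %*% fit$coefficients)
  se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
  structure(
    list(focal = focal, at = at, nuisance = nuisance, n_cells = n_cells,
         weights = w, estimate = est, se = se),
    class = "adjusted_mean"
  )
}

#' @export
print.adjusted_mean <- function(x, ...) {
  cat("<adjusted_mean>",
      paste(names(x$focal), unlist(x$focal), sep = "=", collapse = " "),
      if (length(x$at)) paste("at",
        paste(names(x$at), unlist(x$at), sep = "=", collapse = " ")) else "",
      "\n  estimate", format(x$estimate), " se", format(x$se),
      " (averaged over", x$n_cells, "nuisance cell(s))\n")
  invisible(x)
}

p_stars <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "NS")))
}

contrast_p_value <- function(fit, statistic) {
  if (identical(fit$family, "gaussian")) {
    2 * stats::pt(-abs(statistic), df = fit$df_residual)
  } else {
    2 * stats::pnorm(-abs(statistic))
  }
}

#' Combined home-vs-away / local-vs-foreign contrast
#'
#' For a pair of crossed two-level factors (origin x environment), forms
#' `C = (mu_11 + mu_22) - (mu_12 + mu_21)` from the four adjusted means of
#' one fit, where cells 11 and 22 are the sympatric ("home") combinations
#' and 12, 21 the allopatric ("away") ones. `C > 0` means average home
#' performance exceeds average away performance; the single Wald test of
#' `C = 0` subsumes the classical home-vs-away and local-vs-foreign
#' comparisons. Computed independently at each requested covariate setting
#' (e.g. each age).
#'
#' @param fit An `rte_fit` from [rte_glm()].
#' @param factors Length-2 character vector: origin factor then
#'   environment factor, e.g. `c("e", "h")` or `c("o", "r")`.
#' @param nuisance Factors averaged over (uniform weights).
#' @param at_values Named list of covariate settings; each element is a
#'   vector and the contrast is computed for every combination (typically
#'   `list(a = 0:5)`).
#' @param home Optional list of two length-2 character vectors naming the
#'   home cells; by default level i of the origin factor is at home in
#'   level i of the environment factor.
#' @return Data frame of class `contrast_result` with one row per
#'   covariate setting: estimate `C`, `se`, `statistic`, `p_value`,
#'   `stars`.
#' @export
home_away_contrast <- function(fit, factors, nuisance = character(),
                               at_values = list(), home = NULL) {
  stopifnot(length(factors) == 2L)
  lev1 <- fit$spec$xlevels[[factors[1]]]
  lev2 <- fit$spec$xlevels[[factors[2]]]
  if (length(lev1) != 2L || length(lev2) != 2L) {
    stop_config("home/away contrast needs two 2-level factors")
  }
  if (is.null(home)) home <- list(c(lev1[1], lev2[1]), c(lev1[2], lev2[2]))
  is_home <- function(v1, v2) {
    any(vapply(home, function(hc) hc[1] == v1 && hc[2] == v2, logical(1)))
  }
  settings <- if (length(at_values)) {
    expand.grid(at_values, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(row.names = 1L)
  }
  rows <- vector("list", max(1L, nrow(settings)))
  for (si in seq_len(max(1L, nrow(settings)))) {
    at <- as.list(settings[si, , drop = FALSE])
    w <- 0
    for (v1 in lev1) for (v2 in lev2) {
      m <- lsmean(fit, focal = stats::setNames(list(v1, v2), factors),
                  nuisance = nuisance, at = at)
      w <- w + if (is_home(v1, v2)) m$weights else -m$weights
    }
    est <- drop(w %*% fit$coefficients)
    se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
    statistic <- if (se > 0) est / se else 0
    p <- if (se > 0) contrast_p_value(fit, statistic) else 1
    rows[[si]] <- cbind(
      if (nrow(settings)) settings[si, , drop = FALSE] else NULL,
      data.frame(estimate = est, se = se, statistic = statistic,
                 p_value = p, stars = p_stars(p),
                 stringsAsFactors = FALSE)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_result", class(out))
  out
}

#' Adjusted means and pairwise comparisons for overall germination
#'
#' Computes one LS mean per combination of the focal factors (averaging
#' over the remaining model factors) and all pairwise Wald comparisons on
#' the link scale, with a configurable multiplicity adjustment.
#'
#' @param fit Overall-germination logit fit (no shadehouse-time term).
#' @param focal_factors Factors whose level combinations are compared.
#' @param adjust Multiplicity adjustment for the pairwise p-values.
#' @return List with `lsmeans` and `comparisons` data frames.
#' @export
germination_overall_lsmeans <- function(fit, focal_factors = c("e", "o"),
                                        adjust = c("bonferroni", "holm",
                                                   "none")) {
  adjust <- match.arg(adjust)
  vars <- model_variables(fit)
  nuisance <- setdiff(intersect(vars, names(fit$spec$xlevels)),
                      focal_factors)
  cells <- if (length(focal_factors)) {
    expand.grid(fit$spec$xlevels[focal_factors],
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(row.names = 1L)
  }
  ms <- lapply(seq_len(nrow(cells)), function(i) {
    lsmean(fit, focal = as.list(cells[i, , drop = FALSE]),
           nuisance = nuisance)
  })
  lsm <- cbind(cells, data.frame(
    estimate = vapply(ms, `[[`, numeric(1), "estimate"),
    se = vapply(ms, `[[`, numeric(1), "se"),
    prob = stats::plogis(vapply(ms, `[[`, numeric(1), "estimate"))
  ))
  comparisons <- NULL
  if (nrow(cells) > 1L) {
    pairs <- utils::combn(nrow(cells), 2L)
    cell_label <- apply(cells, 1L, paste, collapse = ":")
    cmp <- lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      w <- ms[[i1]]$weights - ms[[i2]]$weights
      est <- drop(w %*% fit$coefficients)
      se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
      z <- if (se > 0) est / se else 0
      data.frame(cell_1 = cell_label[i1], cell_2 = cell_label[i2],
                 estimate = est, se = se, statistic = z,
                 p_value = contrast_p_value(fit, z),
                 stringsAsFactors = FALSE)
    })
    comparisons <- do.call(rbind, cmp)
    comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value,
                                              method = adjust)
    comparisons$stars <- p_stars(comparisons$p_adjusted)
  }
  list(lsmeans = lsm, comparisons = comparisons)
}

#' Expected-time comparison from a germination-timing fit
#'
#' Back-transforms the adjusted means of a geometric timing fit to
#' expected waiting times (the model's mean number of completed waiting
#' periods, `exp(eta)`), with delta-method standard errors, and performs
#' pairwise contrasts on the link scale.
#'
#' @param fit Geometric timing fit from [rte_glm()].
#' @param by Factors whose level combinations are compared.
#' @param adjust Multiplicity adjustment for pairwise p-values.
#' @return List with `lsmeans` (expected times) and `comparisons`.
#' @export
germination_time_comparison <- function(fit, by = c("o"),
                                        adjust = c("bonferroni", "holm",
                                                   "none")) {
  adjust <- match.arg(adjust)
  if (!identical(fit$family, "geometric")) {
    stop_config("expected-time comparison needs a geometric fit")
  }
  vars <- model_variables(fit)
  nuisance <- setdiff(intersect(vars, names(fit$spec$xlevels)), by)
  cells <- expand.grid(fit$spec$xlevels[by], stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  ms <- lapply(seq_len(nrow(cells)), function(i) {
    lsmean(fit, focal = as.list(cells[i, , drop = FALSE]),
           nuisance = nuisance)
  })
  eta <- vapply(ms, `[[`, numeric(1), "estimate")
  se_eta <- vapply(ms, `[[`, numeric(1), "se")
  lsm <- cbind(cells, data.frame(
    link_estimate = eta, link_se = se_eta,
    expected_time = exp(eta), expected_time_se = exp(eta) * se_eta
  ))
  comparisons <- NULL
  if (nrow(cells) > 1L) {
    pairs <- utils::combn(nrow(cells), 2L)
    cell_label <- apply(cells, 1L, paste, collapse = ":")
    cmp <- lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      w <- ms[[i1]]$weights - ms[[i2]]$weights
      est <- drop(w %*% fit$coefficients)
      se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
      z <- if (se > 0) est / se else 0
      data.frame(cell_1 = cell_label[i1], cell_2 = cell_label[i2],
                 link_difference = est, se = se, statistic = z,
                 p_value = contrast_p_value(fit, z),
                 stringsAsFactors = FALSE)
    })
    comparisons <- do.call(rbind, cmp)
    comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value,
                                              method = adjust)
    comparisons$stars <- p_stars(comparisons$p_adjusted)
  }
  list(lsmeans = lsm, comparisons = comparisons)
}
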