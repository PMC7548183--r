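# Random forest of conditional inference trees with out-of-bag (OOB)
# permutation variable importance: a covariate is important when permuting
# its OOB values makes the predictions noticeably worse.

#' Random-forest permutation variable importance
#'
#' Grows `n_trees` conditional inference trees, each on a bootstrap sample
#' of the rows with `mtry` candidate covariates per node, and measures
#' each covariate's importance as the mean decrease in OOB prediction
#' performance when that covariate's OOB values are permuted. Performance
#' is classification accuracy for a nominal response and negative mean
#' squared error for a numeric one (so importance is the mean MSE
#' increase, reported on the accuracy-drop scale as-is). Fully
#' reproducible from `seed`.
#'
#' @param data Data frame of categorical covariates.
#' @param y Response (factor or numeric).
#' @param n_trees Number of trees.
#' @param mtry Covariates sampled per node (1..number of covariates).
#' @param covariates Covariate names (default all columns).
#' @param alpha,min_obs,n_perm Passed to [grow_tree()]; forest trees
#'   default to cheaper permutation tests.
#' @param seed Master seed.
#' @return Object of class `rte_forest`: `importance` (named vector,
#'   mean performance drop per covariate), `oob_performance` (per tree),
#'   `n_trees`, `response_type`.
#' @export
forest_importance <- function(data, y, n_trees = 100L, mtry = 2L,
                              covariates = names(data), alpha = 0.05,
                              min_obs = 2L, n_perm = 199L, seed = 1L) {
  if (n_trees < 1L) stop_config("n_trees must be >= 1")
  if (mtry < 1L || mtry > length(covariates)) {
    stop_config("mtry must lie in [1, ", length(covariates), "]")
  }
  nominal <- is.factor(y) || is.character(y)
  if (nominal) y <- factor(y)
  n <- length(y)
  perf <- function(pred, truth) {
    if (nominal) mean(pred == as.character(truth)) else
      -mean((pred - truth)^2)
  }
  imp <- matrix(NA_real_, n_trees, length(covariates),
                dimnames = list(NULL, covariates))
  oob_perf <- rep(NA_real_, n_trees)
  for (b in seq_len(n_trees)) {
    set.seed(stage_seed(seed, "forest") + b)
    boot <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(boot))
    tree <- grow_tree(data[boot, , drop = FALSE], y[boot],
                      covariates = covariates, alpha = alpha,
                      min_obs = min_obs, n_perm = n_perm,
                      seed = stage_seed(seed, "forest") + 7919L * b,
                      mtry = mtry)
    if (!length(oob)) next
    oob_data <- data[oob, , drop = FALSE]
    base <- perf(predict_node(tree, oob_data)$prediction, y[oob])
    oob_perf[b] <- base
    set.seed(stage_seed(seed, "forest") + 15485863L + b)
    for (v in covariates) {
      shuffled <- oob_data
      shuffled[[v]] <- shuffled[[v]][sample.int(length(oob))]
      imp[b, v] <- base -
        perf(predict_node(tree, shuffled)$prediction, y[oob])
    }
  }
  structure(
    list(importance = colMeans(imp, na.rm = TRUE),
         importance_per_tree = imp,
         oob_performance = oob_perf,
         n_trees = n_trees, mtry = mtry,
         response_type = if (nominal) "nominal" else "numeric"),
    class = "rte_forest"
  )
}

#' @export
print.rte_forest <- function(x, ...) {
  cat("<rte_forest>", x$n_trees, "trees, mtry =", x$mtry, "\n")
  cat("mean OOB", if (x$response_type == "nominal") "accuracy:"
      else "(-MSE):", format(mean(x$oob_performance, na.rm = TRUE)), "\n")
  print(round(sort(x$importance, decreasing = TRUE), 4))
  invisible(x)
}
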