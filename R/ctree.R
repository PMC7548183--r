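# Conditional inference trees by permutation tests.
#
# A node is split only when a permutation test rejects independence of the
# response and some covariate at level alpha after Bonferroni adjustment
# across covariates; within the selected covariate the binary level
# partition maximizing the association statistic is retained. Covariates
# are categorical (the design factors are binary); the response is either
# a nominal class (the 7-level fate code) or numeric (a derived trait).

# association statistic: Pearson X^2 for nominal response (contingency
# table against covariate levels), between-level sum of squares for a
# numeric response
association_stat <- function(y_int, n_y_levels, x_int, n_x_levels,
                             y_num = NULL) {
  if (is.null(y_num)) {
    tab <- matrix(tabulate(y_int + n_y_levels * (x_int - 1L),
                           nbins = n_y_levels * n_x_levels),
                  n_y_levels, n_x_levels)
    rs <- rowSums(tab)
    cs <- colSums(tab)
    keep_r <- rs > 0
    keep_c <- cs > 0
    if (sum(keep_r) < 2L || sum(keep_c) < 2L) return(0)
    expected <- outer(rs[keep_r], cs[keep_c]) / sum(tab)
    sum((tab[keep_r, keep_c, drop = FALSE] - expected)^2 / expected)
  } else {
    gsum <- vapply(seq_len(n_x_levels),
                   function(l) sum(y_num[x_int == l]), numeric(1))
    gn <- tabulate(x_int, nbins = n_x_levels)
    keep <- gn > 0
    if (sum(keep) < 2L) return(0)
    gmean <- sum(y_num) / length(y_num)
    sum(gn[keep] * (gsum[keep] / gn[keep] - gmean)^2)
  }
}

# number of distinct rearrangements of a multiset (capped to avoid overflow)
n_distinct_perms <- function(counts, cap = 1e7) {
  n <- sum(counts)
  logp <- lgamma(n + 1) - sum(lgamma(counts + 1))
  if (logp > log(cap)) Inf else round(exp(logp))
}

multiset_permutations <- function(levels_left) {
  # levels_left: integer counts per level; returns matrix, one row per
  # distinct arrangement of the level indices
  n <- sum(levels_left)
  out <- list()
  recurse <- function(prefix, left) {
    if (sum(left) == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (l in which(left > 0L)) {
      left2 <- left
      left2[l] <- left2[l] - 1L
      recurse(c(prefix, l), left2)
    }
  }
  recurse(integer(), levels_left)
  do.call(rbind, out)
}

#' Permutation test of response-covariate independence
#'
#' Tests independence of a response (nominal or numeric) and a categorical
#' covariate with a permutation distribution of a chi-square-type
#' statistic: Pearson X^2 on the contingency table for a nominal response,
#' the between-level sum of squares for a numeric one. When the number of
#' distinct covariate rearrangements is at most `exact_max` the null set
#' is enumerated exactly; otherwise `n_perm` Monte Carlo permutations are
#' drawn from the stream given by `seed`. The observed statistic is always
#' part of the null set, so the p-value is never 0. A constant response or
#' covariate yields p = 1 with the flag `"degenerate"`.
#'
#' @param y Response vector (factor/character for nominal, numeric
#'   otherwise).
#' @param x Categorical covariate vector.
#' @param n_perm Number of Monte Carlo permutations.
#' @param seed Seed for the Monte Carlo stream.
#' @param exact_max Enumeration threshold on the number of distinct
#'   rearrangements.
#' @return List with `p_value`, `statistic`, `method` (`"exact"` or
#'   `"monte_carlo"`) and `flags`.
#' @export
independence_test <- function(y, x, n_perm = 9999L, seed = 1L,
                              exact_max = 10000) {
  if (length(y) != length(x)) stop_config("y and x must have equal length")
  if (length(y) < 2L) stop_config("need at least 2 observations")
  x <- factor(x)
  x_obs <- droplevels(x)
  nominal <- is.factor(y) || is.character(y)
  if (nominal) y <- droplevels(factor(y))
  degenerate <- nlevels(x_obs) < 2L ||
    (nominal && nlevels(y) < 2L) ||
    (!nominal && stats::var(as.numeric(y)) == 0)
  if (degenerate) {
    return(list(p_value = 1, statistic = 0, method = "degenerate",
                flags = "degenerate"))
  }
  x_int <- as.integer(x_obs)
  nx <- nlevels(x_obs)
  if (nominal) {
    y_int <- as.integer(y)
    ny <- nlevels(y)
    y_num <- NULL
  } else {
    y_int <- NULL
    ny <- 0L
    y_num <- as.numeric(y)
  }
  obs <- association_stat(y_int, ny, x_int, nx, y_num)
  counts <- tabulate(x_int, nbins = nx)
  tol <- 1e-9 * max(1, abs(obs))
  if (n_distinct_perms(counts) <= exact_max) {
    perms <- multiset_permutations(counts)
    stats_null <- apply(perms, 1L, function(xp)
      association_stat(y_int, ny, xp, nx, y_num))
    p <- mean(stats_null >= obs - tol)
    return(list(p_value = p, statistic = obs, method = "exact",
                flags = character()))
  }
  # canonicalize the row order so Monte Carlo p-values are invariant to
  # permutations of the input rows (the statistic already is)
  ord <- if (nominal) order(y_int, x_int) else order(y_num, x_int)
  x_int <- x_int[ord]
  if (nominal) y_int <- y_int[ord] else y_num <- y_num[ord]
  set.seed(seed)
  n <- length(x_int)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    xp <- x_int[sample.int(n)]
    if (association_stat(y_int, ny, xp, nx, y_num) >= obs - tol) {
      hits <- hits + 1L
    }
  }
  p <- (hits + 1L) / (n_perm + 1L)
  list(p_value = p, statistic = obs, method = "monte_carlo",
       flags = character())
}

binary_partitions <- function(levels) {
  # all binary partitions of a level set (left set contains the first
  # level, so each partition is generated once)
  L <- length(levels)
  out <- list()
  for (mask in seq_len(2^(L - 1L)) - 1L) {
    left <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(L - 1L) - 1L)) > 0))
    if (all(left) || !any(left)) next
    out[[length(out) + 1L]] <- list(left = levels[left],
                                    right = levels[!left])
  }
  out
}

node_summary <- function(y) {
  if (is.factor(y)) {
    counts <- table(y)
    list(type = "nominal", n = length(y),
         counts = stats::setNames(as.integer(counts), names(counts)),
         prediction = names(counts)[which.max(counts)])
  } else {
    list(type = "numeric", n = length(y), mean = mean(y),
         sd = if (length(y) > 1L) stats::sd(y) else 0,
         prediction = mean(y))
  }
}

#' Grow a conditional inference tree
#'
#' Recursive binary partitioning: at each node, every candidate covariate
#' is tested against the response with [independence_test()]; the
#' p-values are Bonferroni-adjusted across the covariates tested at that
#' node. If the smallest adjusted p-value exceeds `alpha` the node becomes
#' a leaf; otherwise the covariate with the smallest adjusted p-value
#' (ties broken by covariate order) is split at the binary level partition
#' maximizing the association statistic, subject to both children holding
#' at least `min_obs` observations. Monte Carlo streams are derived
#' deterministically from `seed` and the node id, so the tree is
#' reproducible and invariant to row order.
#'
#' @param data Data frame of categorical covariates.
#' @param y Response: factor (nominal) or numeric vector.
#' @param covariates Covariate names (default: all columns of `data`);
#'   their order is the tie-breaking order.
#' @param alpha Significance level for the adjusted independence tests.
#' @param min_obs Minimum observations per branch.
#' @param n_perm Monte Carlo permutations per test.
#' @param seed Master seed.
#' @param mtry If non-`NULL`, number of covariates sampled (without
#'   replacement) as candidates at each node — used by the forest.
#' @return Object of class `rte_tree`: the root node, with nested
#'   children.
#' @export
grow_tree <- function(data, y, covariates = names(data), alpha = 0.05,
                      min_obs = 2L, n_perm = 9999L, seed = 1L,
                      mtry = NULL) {
  if (!nrow(data)) stop_config("empty data")
  if (length(y) != nrow(data)) {
    stop_config("response length does not match data")
  }
  bad <- setdiff(covariates, names(data))
  if (length(bad)) {
    stop_config("unknown covariate(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(mtry) &&
      (mtry < 1L || mtry > length(covariates))) {
    stop_config("mtry must lie in [1, ", length(covariates), "]")
  }
  nominal <- is.factor(y) || is.character(y)
  if (nominal) y <- factor(y)
  for (v in covariates) data[[v]] <- factor(data[[v]])

  next_id <- 0L
  build <- function(idx) {
    next_id <<- next_id + 1L
    id <- next_id
    node <- list(id = id, n = length(idx), indices = idx,
                 summary = node_summary(y[idx]),
                 covariate = NULL, split = NULL, p_value = NA_real_,
                 children = NULL)
    cand <- covariates
    if (!is.null(mtry)) {
      set.seed(stage_seed(seed, "tree_mtry") + id)
      cand <- sort(sample(covariates, mtry))
    }
    # per-covariate permutation tests, Bonferroni across candidates
    pvals <- rep(NA_real_, length(cand))
    for (ci in seq_along(cand)) {
      tst <- independence_test(y[idx], data[[cand[ci]]][idx],
                               n_perm = n_perm,
                               seed = stage_seed(seed, "tree_perm") +
                                 id * 131L + ci)
      pvals[ci] <- tst$p_value
    }
    p_adj <- pmin(1, pvals * length(cand))
    if (!length(p_adj) || min(p_adj) > alpha) return(node)
    best_cov <- cand[which.min(p_adj)]  # ties: first in covariate order
    xv <- droplevels(data[[best_cov]][idx])
    obs_levels <- levels(xv)
    if (length(obs_levels) < 2L) return(node)
    # best binary level partition by association statistic, honouring
    # the minimum branch size
    parts <- binary_partitions(obs_levels)
    best <- NULL
    best_stat <- -Inf
    for (pt in parts) {
      grp <- ifelse(xv %in% pt$left, 1L, 2L)
      nl <- sum(grp == 1L)
      if (nl < min_obs || length(idx) - nl < min_obs) next
      st <- if (is.factor(y)) {
        association_stat(as.integer(droplevels(y[idx])),
                         nlevels(droplevels(y[idx])), grp, 2L)
      } else {
        association_stat(NULL, 0L, grp, 2L, as.numeric(y[idx]))
      }
      if (st > best_stat + 1e-12) {
        best_stat <- st
        best <- pt
      }
    }
    if (is.null(best)) return(node)  # no feasible split at min_obs
    node$covariate <- best_cov
    node$split <- best
    node$p_value <- min(p_adj)
    left_idx <- idx[data[[best_cov]][idx] %in% best$left]
    right_idx <- setdiff(idx, left_idx)
    node$children <- list(build(left_idx), build(right_idx))
    node
  }
  root <- build(seq_along(y))
  structure(list(root = root, covariates = covariates,
                 response_type = if (nominal) "nominal" else "numeric",
                 alpha = alpha, min_obs = min_obs, n_perm = n_perm,
                 seed = seed),
            class = "rte_tree")
}

tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1L]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

is_leaf <- function(node) is.null(node$children)

#' Route records through a fitted tree
#'
#' Deterministic routing by the stored split definitions. A record whose
#' covariate level was not seen in training is routed to the child with
#' more training samples, with a warning.
#'
#' @param tree An `rte_tree`.
#' @param newdata Data frame with the tree's covariates.
#' @return Data frame with `leaf_id` and the leaf `prediction` per row.
#' @export
predict_node <- function(tree, newdata) {
  missing_cols <- setdiff(tree$covariates, names(newdata))
  if (length(missing_cols)) {
    stop_config("newdata is missing covariate(s): ",
                paste(missing_cols, collapse = ", "))
  }
  route <- function(node, row) {
    if (is_leaf(node)) return(node)
    val <- as.character(newdata[[node$covariate]][row])
    if (val %in% node$split$left) {
      route(node$children[[1L]], row)
    } else if (val %in% node$split$right) {
      route(node$children[[2L]], row)
    } else {
      warning("level '", val, "' of ", node$covariate,
              " unseen at node ", node$id,
              "; routing to the larger child", call. = FALSE)
      larger <- which.max(vapply(node$children, `[[`, integer(1), "n"))
      route(node$children[[larger]], row)
    }
  }
  leaves <- lapply(seq_len(nrow(newdata)), function(i) route(tree$root, i))
  data.frame(
    leaf_id = vapply(leaves, `[[`, integer(1), "id"),
    prediction = if (tree$response_type == "nominal") {
      vapply(leaves, function(nd) nd$summary$prediction, character(1))
    } else {
      vapply(leaves, function(nd) nd$summary$prediction, numeric(1))
    },
    stringsAsFactors = FALSE
  )
}

#' @export
print.rte_tree <- function(x, ...) {
  cat(format_tree(x), sep = "\n")
  invisible(x)
}

#' Indented text rendering of a tree
#'
#' @param tree An `rte_tree`.
#' @return Character vector, one line per node.
#' @export
format_tree <- function(tree) {
  lines <- character()
  walk <- function(node, depth) {
    pad <- strrep("  ", depth)
    desc <- if (is_leaf(node)) {
      s <- node$summary
      if (s$type == "nominal") {
        paste0("leaf [", paste(names(s$counts), s$counts, sep = "=",
                               collapse = " "), "]")
      } else {
        sprintf("leaf [mean=%.3f sd=%.3f]", s$mean, s$sd)
      }
    } else {
      sprintf("%s in {%s} | {%s} (adj p=%.4g)", node$covariate,
              paste(node$split$left, collapse = ","),
              paste(node$split$right, collapse = ","), node$p_value)
    }
    lines <<- c(lines, sprintf("%s[%d] n=%d %s", pad, node$id, node$n, desc))
    for (ch in node$children) walk(ch, depth + 1L)
  }
  walk(tree$root, 0L)
  lines
}

#' DOT (Graphviz) export of a tree
#'
#' Nodes are annotated with the split covariate and adjusted p-value;
#' leaves with their class counts (or mean and SD).
#'
#' @param tree An `rte_tree`.
#' @return A single character string of DOT source.
#' @export
tree_to_dot <- function(tree) {
  lines <- c("digraph rte_tree {", "  node [shape=box];")
  walk <- function(node) {
    label <- if (is_leaf(node)) {
      s <- node$summary
      if (s$type == "nominal") {
        paste0("n=", s$n, "\\n",
               paste(names(s$counts), s$counts, sep = "=",
                     collapse = "\\n"))
      } else {
        sprintf("n=%d\\nmean=%.3f\\nsd=%.3f", s$n, s$mean, s$sd)
      }
    } else {
      sprintf("%s\\np=%.4g\\nn=%d", node$covariate, node$p_value, node$n)
    }
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", node$id, label))
    if (!is_leaf(node)) {
      for (k in 1:2) {
        side <- if (k == 1) node$split$left else node$split$right
        lines <<- c(lines, sprintf(
          "  n%d -> n%d [label=\"%s\"];", node$id,
          node$children[[k]]$id, paste(side, collapse = ",")))
        walk(node$children[[k]])
      }
    }
  }
  walk(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}

#' JSON serialization of a tree (round-trip safe)
#'
#' @param tree An `rte_tree`.
#' @return JSON string.
#' @export
tree_to_json <- function(tree) {
  strip <- function(node) {
    s <- node$summary
    if (!is.null(s$counts)) s$counts <- as.list(s$counts)
    list(id = node$id, n = node$n, summary = s,
         covariate = node$covariate, split = node$split,
         p_value = node$p_value,
         children = if (is_leaf(node)) NULL else
           lapply(node$children, strip))
  }
  jsonlite::toJSON(
    list(root = strip(tree$root), covariates = tree$covariates,
         response_type = tree$response_type, alpha = tree$alpha,
         min_obs = tree$min_obs, n_perm = tree$n_perm, seed = tree$seed),
    auto_unbox = TRUE, null = "null", na = "null", digits = NA)
}

#' Rebuild a tree from its JSON serialization
#'
#' The rebuilt tree routes and predicts identically to the original
#' (training-row indices are not serialized).
#'
#' @param json JSON string from [tree_to_json()].
#' @return An `rte_tree`.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  rebuild <- function(node) {
    node$indices <- NULL
    if (!is.null(node$summary$counts)) {
      node$summary$counts <- unlist(node$summary$counts)
    }
    if (!is.null(node$children)) {
      node$children <- lapply(node$children, rebuild)
    }
    node
  }
  structure(list(root = rebuild(obj$root),
                 covariates = unlist(obj$covariates),
                 response_type = obj$response_type, alpha = obj$alpha,
                 min_obs = obj$min_obs, n_perm = obj$n_perm,
                 seed = obj$seed),
            class = "rte_tree")
}
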