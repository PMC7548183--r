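# End-to-end orchestration: validate -> counts -> model fits -> adjusted
# means and home/away contrasts -> trees and forest -> report bundle.
# Every stage writes plain CSV/JSON/DOT files into the output directory
# and appends one line to the run manifest; re-running with the same
# configuration and seed reproduces every output byte for byte.

#' Analysis configuration
#'
#' @param input Either `NULL` (simulate a synthetic dataset) or a list
#'   with `individuals` and optionally `measurements` CSV paths.
#' @param sim Named list of [sim_config()] overrides (used when `input`
#'   is `NULL`).
#' @param traits Growth traits to analyse.
#' @param ages Ages at which growth contrasts are evaluated.
#' @param alpha Significance level for tree splits.
#' @param adjust Multiplicity adjustment for pairwise germination
#'   comparisons (`"bonferroni"`, `"holm"`, `"none"`).
#' @param n_perm Monte Carlo permutations per tree test.
#' @param n_trees,mtry Forest size and candidate covariates per node.
#' @param run_forest Whether to run the (comparatively slow) forest
#'   importance stage.
#' @param seed Master seed for every stochastic stage.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, sim = list(),
                            traits = c("height_cm", "diameter_mm", "tnl",
                                       "herbivory_pct"),
                            ages = rte_observed_ages, alpha = 0.05,
                            adjust = "bonferroni", n_perm = 999L,
                            n_trees = 50L, mtry = 2L, run_forest = TRUE,
                            seed = 1L) {
  bad <- setdiff(traits, rte_traits)
  if (length(bad)) {
    stop_config("unknown trait(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(input = input, sim = sim, traits = traits, ages = ages,
         alpha = alpha, adjust = adjust, n_perm = as.integer(n_perm),
         n_trees = as.integer(n_trees), mtry = as.integer(mtry),
         run_forest = isTRUE(run_forest), seed = as.integer(seed)),
    class = "analysis_config"
  )
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full RTE analysis pipeline
#'
#' Stages: acquire data (load or simulate), validation report, count
#' tables (grand, per mother, per garden), shadehouse-germination
#' adjusted means at the mean shadehouse time, overall-germination
#' adjusted means with pairwise comparisons, germination-timing
#' expected-time comparison, survival home/away contrasts, per-trait
#' per-age growth home/away contrasts (the plot-ready tables behind the
#' yearly LS-means figures), a fate-code classification tree, per-trait
#' regression trees on the derived year-6 responses, and forest variable
#' importances. A `manifest.json` records the configuration, seed,
#' package version and per-stage row counts. Any stage failure aborts
#' with the stage name after writing a partial manifest.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(
    package = "rtadapt",
    version = as.character(utils::packageVersion("rtadapt")),
    seed = config$seed,
    config = config[setdiff(names(config), "input")],
    input = config$input,
    stages = list()
  )
  log_stage <- function(name, info) {
    manifest$stages[[name]] <<- info
    if (!quiet) {
      message(sprintf("[%s] %s", name,
                      paste(names(info), unlist(info), sep = "=",
                            collapse = " ")))
    }
  }
  abort_stage <- function(name, err) {
    manifest$stages[[name]] <- list(status = "failed",
                                    error = conditionMessage(err))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         force = TRUE)
    stop_data("pipeline stage '", name, "' failed: ",
              conditionMessage(err))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) abort_stage(name, e))
  }

  # ---- data ----
  records <- run_stage("data", {
    if (is.null(config$input)) {
      rec <- simulate_rte(do.call(sim_config,
                                  c(list(seed = config$seed), config$sim)))
      write_records(rec, out_dir)
      rec
    } else {
      load_records(config$input$individuals, config$input$measurements)
    }
  })
  has_measurements <- !is.null(records$measurements)
  log_stage("data", list(individuals = nrow(records$individuals),
                         measurements = if (has_measurements)
                           nrow(records$measurements) else 0L))

  run_stage("validate", {
    problems <- validate_records(records$individuals, records$measurements,
                                 ages = records$ages)
    jsonlite::write_json(
      list(n_individuals = nrow(records$individuals),
           n_problems = length(problems), problems = problems),
      file.path(out_dir, "validation.json"),
      auto_unbox = TRUE, pretty = TRUE)
  })
  log_stage("validate", list(status = "ok"))

  run_stage("counts", {
    write_stage_csv(tabulate_counts(records), out_dir, "counts_total.csv")
    write_stage_csv(tabulate_counts(records, "mother_id"), out_dir,
                    "counts_by_mother.csv")
    write_stage_csv(tabulate_counts(records, "garden_id"), out_dir,
                    "counts_by_garden.csv")
  })
  log_stage("counts", list(files = 3L))

  # ---- germination models ----
  mf_shade <- model_frame(records, "shadehouse_germination")
  if (stats::var(mf_shade$t) > 0 && stats::var(mf_shade$y) > 0) {
    run_stage("shadehouse_germination", {
      fit <- rte_glm(mf_shade, "y", default_terms("shadehouse_germination"),
                     "binomial_logit")
      t_bar <- mean(mf_shade$t)
      cells <- expand.grid(e = rte_levels$ecotype,
                           o = rte_levels$provenance,
                           stringsAsFactors = FALSE)
      out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
        m <- lsmean(fit, focal = list(e = cells$e[i], o = cells$o[i]),
                    at = list(t = t_bar))
        data.frame(ecotype = cells$e[i], provenance = cells$o[i],
                   t_bar = t_bar, logit = m$estimate, se = m$se,
                   prob = stats::plogis(m$estimate))
      }))
      write_stage_csv(out, out_dir, "germination_shadehouse_lsmeans.csv")
    })
    log_stage("shadehouse_germination", list(cells = 4L))
  } else {
    log_stage("shadehouse_germination",
              list(status = "skipped: no shadehouse-time variation"))
  }

  run_stage("overall_germination", {
    mf <- model_frame(records, "overall_germination")
    fit <- rte_glm(mf, "y", default_terms("overall_germination"),
                   "binomial_logit")
    res <- germination_overall_lsmeans(fit, c("e", "o"),
                                       adjust = config$adjust)
    write_stage_csv(res$lsmeans, out_dir,
                    "germination_overall_lsmeans.csv")
    if (!is.null(res$comparisons)) {
      write_stage_csv(res$comparisons, out_dir,
                      "germination_overall_comparisons.csv")
    }
  })
  log_stage("overall_germination", list(status = "ok"))

  run_stage("germination_timing", {
    mf <- model_frame(records, "germination_timing")
    fit <- rte_glm(mf, "k", default_terms("germination_timing"),
                   "geometric", link = "log_on_mean")
    res <- germination_time_comparison(fit, by = "o",
                                       adjust = config$adjust)
    write_stage_csv(res$lsmeans, out_dir, "germination_timing_lsmeans.csv")
    if (!is.null(res$comparisons)) {
      write_stage_csv(res$comparisons, out_dir,
                      "germination_timing_comparisons.csv")
    }
  })
  log_stage("germination_timing", list(status = "ok"))

  run_stage("survival", {
    mf <- model_frame(records, "survival")
    fit <- rte_glm(mf, "k", default_terms("survival"), "geometric")
    rows <- rbind(
      cbind(comparison = "ecotype_habitat",
            home_away_contrast(fit, c("e", "h"),
                               nuisance = c("o", "r", "s"))),
      cbind(comparison = "provenance_plantation",
            home_away_contrast(fit, c("o", "r"),
                               nuisance = c("e", "h", "s")))
    )
    write_stage_csv(rows, out_dir, "survival_contrasts.csv")
  })
  log_stage("survival", list(contrasts = 2L))

  # ---- growth (needs measurements) ----
  if (has_measurements) {
    run_stage("growth", {
      lsm_rows <- list()
      con_rows <- list()
      for (tr in config$traits) {
        mf <- model_frame(records, "growth", trait = tr)
        if (!nrow(mf)) next
        fit <- rte_glm(mf, "y", default_terms("growth"), "gaussian")
        for (cmp in list(c("e", "h"), c("o", "r"))) {
          nuis <- setdiff(c("e", "h", "o", "r", "s"), cmp)
          cells <- expand.grid(fit$spec$xlevels[cmp],
                               stringsAsFactors = FALSE)
          for (a in config$ages) {
            for (i in seq_len(nrow(cells))) {
              m <- lsmean(fit, focal = as.list(cells[i, , drop = FALSE]),
                          nuisance = nuis, at = list(a = a))
              lsm_rows[[length(lsm_rows) + 1L]] <- data.frame(
                trait = tr, comparison = paste(cmp, collapse = "x"),
                cell = paste(cells[i, ], collapse = ":"), age = a,
                estimate = m$estimate, se = m$se)
            }
          }
          cc <- home_away_contrast(fit, cmp, nuisance = nuis,
                                   at_values = list(a = config$ages))
          con_rows[[length(con_rows) + 1L]] <-
            cbind(trait = tr, comparison = paste(cmp, collapse = "x"), cc)
        }
      }
      write_stage_csv(do.call(rbind, lsm_rows), out_dir, "lsmeans.csv")
      write_stage_csv(do.call(rbind, con_rows), out_dir, "contrasts.csv")
    })
    log_stage("growth", list(traits = length(config$traits)))
  } else {
    log_stage("growth", list(status = "skipped: no measurements"))
  }

  # ---- trees ----
  covs <- with(records$individuals, data.frame(
    Prov_Region = provenance, Plant_Region = plantation,
    Habitat = habitat, Ecotype = ecotype, Status = status,
    stringsAsFactors = FALSE))
  run_stage("fate_tree", {
    tree <- grow_tree(covs, fate_code(records), alpha = config$alpha,
                      min_obs = 2L, n_perm = config$n_perm,
                      seed = config$seed)
    writeLines(format_tree(tree), file.path(out_dir, "fate_tree.txt"))
    writeLines(tree_to_dot(tree), file.path(out_dir, "fate_tree.dot"))
    writeLines(tree_to_json(tree), file.path(out_dir, "fate_tree.json"))
  })
  log_stage("fate_tree", list(status = "ok"))

  if (has_measurements) {
    run_stage("trait_trees", {
      traits6 <- derive_year6_traits(records)
      resp_cols <- setdiff(names(traits6),
                           c("individual_id", "mother_id", "garden_id",
                             "ecotype", "habitat", "provenance",
                             "plantation", "status"))
      cov6 <- with(traits6, data.frame(
        Prov_Region = provenance, Plant_Region = plantation,
        Habitat = habitat, Ecotype = ecotype, Status = status,
        stringsAsFactors = FALSE))
      for (rc in resp_cols) {
        yv <- traits6[[rc]]
        keep <- !is.na(yv)
        if (sum(keep) < 4L) next
        tree <- grow_tree(cov6[keep, , drop = FALSE], yv[keep],
                          alpha = config$alpha, min_obs = 2L,
                          n_perm = config$n_perm, seed = config$seed)
        writeLines(format_tree(tree),
                   file.path(out_dir, paste0("tree_", rc, ".txt")))
        writeLines(tree_to_dot(tree),
                   file.path(out_dir, paste0("tree_", rc, ".dot")))
      }
    })
    log_stage("trait_trees", list(status = "ok"))
  } else {
    log_stage("trait_trees", list(status = "skipped: no measurements"))
  }

  if (config$run_forest) {
    run_stage("forest", {
      fi <- forest_importance(covs, fate_code(records),
                              n_trees = config$n_trees, mtry = config$mtry,
                              n_perm = 99L, seed = config$seed)
      write_stage_csv(
        data.frame(covariate = names(fi$importance),
                   importance = unname(fi$importance)),
        out_dir, "forest_importance.csv")
    })
    log_stage("forest", list(n_trees = config$n_trees))
  } else {
    log_stage("forest", list(status = "skipped"))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(manifest)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic dataset), `validate`,
#' `counts`, `analyze` (models + contrasts), `trees`, `run` (full
#' pipeline). Options: `--config <json>` (an [analysis_config()] as
#' JSON), `--seed <int>`, `--out <dir>`, `--individuals <csv>`,
#' `--measurements <csv>`, `--quiet`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly.
#' @export
rte_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rte <simulate|validate|counts|analyze|trees|run>",
    "[--config cfg.json] [--seed N] [--out dir]",
    "[--individuals f.csv] [--measurements f.csv] [--quiet]")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list(seed = 1L, out = "rte_output", config = NULL,
               individuals = NULL, measurements = NULL, quiet = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--quiet") {
      opts$quiet <- TRUE
      i <- i + 1L
    } else if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i + 1L > length(args)) stop_config("missing value for ", a)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      stop_config("unexpected argument: ", a)
    }
  }
  opts$seed <- as.integer(opts$seed)
  cfg_args <- list(seed = opts$seed)
  if (!is.null(opts$config)) {
    file_cfg <- jsonlite::fromJSON(opts$config, simplifyVector = TRUE)
    cfg_args <- utils::modifyList(cfg_args, as.list(file_cfg))
  }
  if (!is.null(opts$individuals)) {
    cfg_args$input <- list(individuals = opts$individuals,
                           measurements = opts$measurements)
  }
  config <- do.call(analysis_config, cfg_args)

  get_records <- function() {
    if (is.null(config$input)) {
      simulate_rte(do.call(sim_config,
                           c(list(seed = config$seed), config$sim)))
    } else {
      load_records(config$input$individuals, config$input$measurements)
    }
  }
  switch(cmd,
    simulate = {
      rec <- simulate_rte(do.call(sim_config,
                                  c(list(seed = config$seed), config$sim)))
      if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
      write_records(rec, opts$out)
      jsonlite::write_json(
        list(seed = config$seed, sim = config$sim,
             n_individuals = nrow(rec$individuals)),
        file.path(opts$out, "simulation.json"),
        auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      if (!opts$quiet) message("wrote synthetic dataset to ", opts$out)
    },
    validate = {
      rec <- get_records()
      if (!opts$quiet) message("records valid: ",
                               nrow(rec$individuals), " individuals")
    },
    counts = {
      rec <- get_records()
      if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
      write_stage_csv(tabulate_counts(rec), opts$out, "counts_total.csv")
      write_stage_csv(tabulate_counts(rec, "mother_id"), opts$out,
                      "counts_by_mother.csv")
      write_stage_csv(tabulate_counts(rec, "garden_id"), opts$out,
                      "counts_by_garden.csv")
    },
    analyze = ,
    trees = ,
    run = {
      run_pipeline(config, opts$out, quiet = opts$quiet)
    },
    {
      message(usage)
      return(invisible(1L))
    })
  invisible(0L)
}
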