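# Record model and I/O for reciprocal transplant experiment (RTE) data.
#
# Two long-format tables describe an experiment:
#   individuals:  one row per seed/seedling with its design-factor levels,
#                 shadehouse time, germination timing and yearly fate codes
#   measurements: one row per (individual, age, trait) value
# All validation is row-addressed so a rejected file can be fixed by hand.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("rte_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("rte_data_error", "error")))
}

individual_columns <- function(n_years = rte_n_years) {
  c("individual_id", "mother_id", "garden_id", "ecotype", "habitat",
    "provenance", "plantation", "status", "shadehouse_days", "germ_timing",
    paste0("fate_y", seq_len(n_years)))
}

measurement_columns <- function() c("individual_id", "age", "trait", "value")

germ_timing_levels <- function(n_years = rte_n_years) {
  c("at_transplant", paste0("year", seq_len(n_years)), "never")
}

#' Assemble and validate an RTE record set
#'
#' Bundles an individuals table and an optional measurements table into a
#' validated `rte_records` object, the container every analysis function in
#' the package accepts.
#'
#' @param individuals Data frame with columns `individual_id`, `mother_id`,
#'   `garden_id`, `ecotype`, `habitat`, `provenance`, `plantation`,
#'   `status`, `shadehouse_days`, `germ_timing`, `fate_y1` .. `fate_y5`.
#' @param measurements Optional data frame with columns `individual_id`,
#'   `age`, `trait`, `value`.
#' @param ages Integer vector of valid measurement ages (years since
#'   transplant); defaults to the observed-age set [rte_observed_ages].
#' @param validate If `FALSE`, skip validation (internal use).
#' @return An object of class `rte_records`: a list with elements
#'   `individuals`, `measurements` (possibly `NULL`), `ages` and `n_years`.
#' @export
rte_records <- function(individuals, measurements = NULL,
                        ages = rte_observed_ages, validate = TRUE) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (!is.null(measurements)) {
    measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
    if (nrow(measurements)) {
      measurements$age <- as.integer(measurements$age)
      measurements$value <- as.numeric(measurements$value)
    }
  }
  if (validate) {
    problems <- validate_records(individuals, measurements, ages = ages)
    if (length(problems)) {
      stop_data("invalid RTE records:\n", paste("-", problems, collapse = "\n"))
    }
  }
  structure(
    list(individuals = individuals, measurements = measurements,
         ages = as.integer(ages), n_years = rte_n_years),
    class = "rte_records"
  )
}

#' @export
print.rte_records <- function(x, ...) {
  cat("<rte_records>\n")
  cat("  individuals :", nrow(x$individuals), "rows,",
      length(unique(x$individuals$mother_id)), "mothers,",
      length(unique(x$individuals$garden_id)), "gardens\n")
  if (is.null(x$measurements)) {
    cat("  measurements: none\n")
  } else {
    cat("  measurements:", nrow(x$measurements), "rows,",
        length(unique(x$measurements$trait)), "traits\n")
  }
  invisible(x)
}

#' Validate RTE record tables
#'
#' Checks every structural invariant of the record model and returns a
#' character vector of row-addressed problems (empty when valid):
#' factor levels, non-negative shadehouse days, the equivalence
#' status == "seedling" <=> germ_timing == "at_transplant", monotone fate
#' sequences (dead stays dead; alive never reverts to pre-germination;
#' pre-germination exactly until the germination year), one
#' (plantation, habitat) pair per garden, and measurement-value ranges.
#'
#' @inheritParams rte_records
#' @return Character vector of problem descriptions.
#' @export
validate_records <- function(individuals, measurements = NULL,
                             ages = rte_observed_ages) {
  problems <- character()
  need <- individual_columns()
  missing_cols <- setdiff(need, names(individuals))
  if (length(missing_cols)) {
    stop_config("individuals table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  n <- nrow(individuals)
  if (n == 0L) return(problems)

  add <- function(rows, msg, values = NULL) {
    if (!length(rows)) return()
    lab <- if (is.null(values)) "" else paste0(" (value ", values, ")")
    problems <<- c(problems, paste0("row ", rows, ": ", msg, lab))
  }

  if (anyDuplicated(individuals$individual_id)) {
    dup <- which(duplicated(individuals$individual_id))
    add(dup, "duplicate individual_id", individuals$individual_id[dup])
  }
  for (col in names(rte_levels)) {
    bad <- which(!(individuals[[col]] %in% rte_levels[[col]]))
    add(bad, paste0("unknown ", col, " level"), individuals[[col]][bad])
  }
  gt <- individuals$germ_timing
  bad <- which(!(gt %in% germ_timing_levels()))
  add(bad, "unknown germ_timing", gt[bad])
  sd_ <- individuals$shadehouse_days
  bad <- which(!is.finite(sd_) | sd_ < 0 | sd_ != floor(sd_))
  add(bad, "shadehouse_days must be a non-negative integer", sd_[bad])

  # status <=> germination timing equivalence
  bad <- which((individuals$status == "seedling") != (gt == "at_transplant"))
  add(bad, "status 'seedling' must coincide with germ_timing 'at_transplant'")

  # fate sequence invariants
  fate_cols <- paste0("fate_y", seq_len(rte_n_years))
  fates <- as.matrix(individuals[fate_cols])
  bad <- which(apply(fates, 1L, function(f) any(!(f %in% rte_fates))))
  add(bad, "unknown fate code")
  germ_year <- match(gt, paste0("year", seq_len(rte_n_years)))  # NA unless field germ
  for (i in seq_len(n)) {
    f <- fates[i, ]
    if (any(!(f %in% rte_fates))) next
    if (identical(gt[i], "never")) {
      if (any(f != "pre_germination"))
        add(i, "never-germinated individual must stay pre_germination")
      next
    }
    g <- if (identical(gt[i], "at_transplant")) 0L else germ_year[i]
    if (is.na(g)) next  # unknown timing already reported
    if (g > 1L && any(f[seq_len(g - 1L)] != "pre_germination"))
      add(i, "fate must be pre_germination before the germination year")
    post <- f[seq.int(max(1L, g), rte_n_years)]
    if (g >= 1L && f[g] != "alive")
      add(i, "individual must be alive at its germination-year census")
    if (any(post == "pre_germination"))
      add(i, "fate cannot revert to pre_germination after germination")
    dead_at <- which(post == "dead")
    if (length(dead_at) && any(post[seq.int(min(dead_at), length(post))] != "dead"))
      add(i, "once dead an individual must remain dead")
  }

  # garden determines (plantation, habitat)
  gh <- unique(individuals[c("garden_id", "plantation", "habitat")])
  dup_g <- gh$garden_id[duplicated(gh$garden_id)]
  if (length(dup_g)) {
    problems <- c(problems, paste0(
      "garden ", unique(dup_g),
      ": inconsistent (plantation, habitat) across rows"))
  }
  # mother determines (ecotype, provenance)
  mo <- unique(individuals[c("mother_id", "ecotype", "provenance")])
  dup_m <- mo$mother_id[duplicated(mo$mother_id)]
  if (length(dup_m)) {
    problems <- c(problems, paste0(
      "mother ", unique(dup_m),
      ": inconsistent (ecotype, provenance) across rows"))
  }

  if (!is.null(measurements) && nrow(measurements)) {
    needm <- measurement_columns()
    missing_cols <- setdiff(needm, names(measurements))
    if (length(missing_cols)) {
      stop_config("measurements table is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
    }
    addm <- function(rows, msg, values = NULL) {
      if (!length(rows)) return()
      lab <- if (is.null(values)) "" else paste0(" (value ", values, ")")
      problems <<- c(problems,
                     paste0("measurements row ", rows, ": ", msg, lab))
    }
    m <- measurements
    bad <- which(!(m$trait %in% rte_traits))
    addm(bad, "unknown trait", m$trait[bad])
    bad <- which(!(m$individual_id %in% individuals$individual_id))
    addm(bad, "individual_id not present in individuals table",
         m$individual_id[bad])
    bad <- which(!(m$age %in% ages))
    addm(bad, "age outside the observed-age set", m$age[bad])
    key <- paste(m$individual_id, m$age, m$trait, sep = "\r")
    bad <- which(duplicated(key))
    addm(bad, "duplicate (individual_id, age, trait)")
    bad <- which(!is.finite(m$value) | m$value < 0)
    addm(bad, "value must be a non-negative number", m$value[bad])
    pos <- m$trait %in% c("height_cm", "diameter_mm")
    addm(which(pos & m$value <= 0), "size traits must be strictly positive")
    addm(which(m$trait == "tnl" & m$value < 1), "tnl must be >= 1 when alive")
    herb <- m$trait == "herbivory_pct"
    addm(which(herb & (m$value < 10 | m$value > 90)),
         "herbivory_pct must lie in [10, 90] (class-midpoint convention)")
  }
  problems
}

#' Read RTE record tables from CSV files
#'
#' Reads the individuals table (and optionally a long-format measurements
#' table), remaps columns through `layout`, validates all invariants and
#' returns an [rte_records] object. Files are comma-separated UTF-8 with a
#' header row and "." as the decimal mark.
#'
#' @param individuals_path Path to the individuals CSV.
#' @param measurements_path Optional path to the measurements CSV.
#' @param layout Optional named list with elements `individuals` and/or
#'   `measurements`, each a named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `list(individuals = c(ecotype = "Ecotype"))`.
#' @inheritParams rte_records
#' @return An [rte_records] object.
#' @export
load_records <- function(individuals_path, measurements_path = NULL,
                         layout = NULL, ages = rte_observed_ages) {
  read_one <- function(path, canonical, map) {
    if (!file.exists(path)) stop_config("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    if (!is.null(map)) {
      for (canon in names(map)) {
        if (!(map[[canon]] %in% names(df))) {
          stop_config("mapped column '", map[[canon]], "' (for '", canon,
                      "') not found in ", path)
        }
        names(df)[names(df) == map[[canon]]] <- canon
      }
    }
    missing_cols <- setdiff(canonical, names(df))
    if (length(missing_cols)) {
      stop_config(path, " is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
    }
    df[canonical]
  }
  ind <- read_one(individuals_path, individual_columns(),
                  layout$individuals)
  mea <- NULL
  if (!is.null(measurements_path)) {
    mea <- read_one(measurements_path, measurement_columns(),
                    layout$measurements)
  }
  rte_records(ind, mea, ages = ages)
}

#' Write RTE records back to CSV
#'
#' Inverse of [load_records()]: writes `individuals.csv` (and
#' `measurements.csv` when present) into `dir`, preserving every field
#' value exactly, so that a load/write/load round trip is the identity.
#'
#' @param records An [rte_records] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_records <- function(records, dir) {
  stopifnot(inherits(records, "rte_records"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "individuals.csv")
  utils::write.csv(records$individuals, paths[1], row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(records$measurements)) {
    mp <- file.path(dir, "measurements.csv")
    utils::write.csv(records$measurements, mp, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, mp)
  }
  invisible(paths)
}
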