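# Derived per-individual traits: herbivory score, relative growth rate,
# survival coding for the geometric model and the 7-level fate code.

#' Seedling herbivory score from per-leaf damage classes
#'
#' Each leaf carries one of five damage classes; the seedling score is the
#' arithmetic mean of the class midpoints (10, 30, 50, 70, 90 percent), so
#' it always lies in \[10, 90\] and is invariant to leaf ordering.
#'
#' @param leaf_classes Character vector of damage classes, levels
#'   `names(rte_herbivory_midpoints)`.
#' @return Herbivory score in percent.
#' @export
herbivory_score <- function(leaf_classes) {
  if (!length(leaf_classes)) {
    stop_data("herbivory score undefined: individual has no leaves")
  }
  mid <- rte_herbivory_midpoints[leaf_classes]
  if (anyNA(mid)) {
    bad <- unique(leaf_classes[is.na(mid)])
    stop_data("unknown herbivory class: ", paste(bad, collapse = ", "))
  }
  mean(mid)
}

#' Average yearly relative growth rate
#'
#' Mean over consecutive measurement pairs of `(log(Y2) - log(Y1)) /
#' (a2 - a1)`. Years without a census contribute through the elapsed-time
#' denominator, so a gap in the age sequence needs no special handling,
#' and inserting an intermediate point lying exactly on the log-linear
#' path leaves the rate unchanged.
#'
#' @param ages Numeric vector of measurement ages (years).
#' @param values Strictly positive trait values at those ages.
#' @return Average relative growth rate per year.
#' @export
relative_growth_rate <- function(ages, values) {
  if (length(ages) != length(values)) {
    stop_config("ages and values must have equal length")
  }
  keep <- is.finite(ages) & is.finite(values)
  ages <- ages[keep]; values <- values[keep]
  if (any(values <= 0)) {
    stop_data("relative growth rate requires strictly positive values")
  }
  if (length(unique(ages)) < 2L) {
    stop_data("relative growth rate undefined: fewer than 2 usable points")
  }
  ord <- order(ages)
  ages <- ages[ord]; values <- values[ord]
  mean(diff(log(values)) / diff(ages))
}

#' Survival coding for the geometric lifetime model
#'
#' Converts one individual's germination timing and yearly fate sequence
#' into the observed number of whole years survived after germination and
#' a right-censoring flag. A year is counted as survived when the
#' individual was recorded alive at that post-transplant census, so a
#' seedling transplanted already germinated and found dead at the first
#' census has age 0, and any individual alive at the final census is
#' censored at its observed age. Never-germinated seeds do not enter
#' survival fits.
#'
#' @param germ_timing One of `"at_transplant"`, `"year1"` .. `"year5"`,
#'   `"never"`.
#' @param fates Character vector of yearly fate codes (`fate_y1` ..),
#'   levels [rte_fates].
#' @return A list with `final_age` (integer) and `censored` (logical), or
#'   `NULL` for a never-germinated seed.
#' @export
encode_survival_series <- function(germ_timing, fates) {
  if (identical(germ_timing, "never")) return(NULL)
  if (!germ_timing %in% germ_timing_levels()) {
    stop_data("unknown germ_timing: ", germ_timing)
  }
  list(
    final_age = sum(fates == "alive"),
    censored = identical(fates[length(fates)], "alive")
  )
}

#' Survival codings for every germinated individual in a record set
#'
#' @param records An [rte_records] object.
#' @return Data frame with `individual_id`, `final_age`, `censored` for
#'   germinated individuals only.
#' @export
encode_survival <- function(records) {
  stopifnot(inherits(records, "rte_records"))
  ind <- records$individuals
  fate_cols <- paste0("fate_y", seq_len(records$n_years))
  keep <- ind$germ_timing != "never"
  fates <- as.matrix(ind[keep, fate_cols, drop = FALSE])
  data.frame(
    individual_id = ind$individual_id[keep],
    final_age = as.integer(rowSums(fates == "alive")),
    censored = fates[, records$n_years] == "alive",
    stringsAsFactors = FALSE
  )
}

#' Seven-level fate code for classification trees
#'
#' Collapses each individual's history into `U` (never germinated),
#' `D1` .. `D5` (first recorded dead at census year 1..5) or `A` (alive at
#' the final census).
#'
#' @param records An [rte_records] object.
#' @return Factor with levels `U`, `D1` .. `D5`, `A`, one per individual,
#'   in the row order of `records$individuals`.
#' @export
fate_code <- function(records) {
  stopifnot(inherits(records, "rte_records"))
  ind <- records$individuals
  fate_cols <- paste0("fate_y", seq_len(records$n_years))
  fates <- as.matrix(ind[fate_cols])
  code <- character(nrow(ind))
  for (i in seq_len(nrow(ind))) {
    if (ind$germ_timing[i] == "never") {
      code[i] <- "U"
    } else if (fates[i, records$n_years] == "alive") {
      code[i] <- "A"
    } else {
      code[i] <- paste0("D", which(fates[i, ] == "dead")[1L])
    }
  }
  factor(code, levels = c("U", paste0("D", seq_len(records$n_years)), "A"))
}

#' Derived-trait table for year-6 tree/forest analyses
#'
#' For individuals germinated in the first year (in the shadehouse or the
#' field), assembles final-age trait values and average yearly relative
#' growth rates: `H5`, `D5`, `TNL5` (values at the final age, alive
#' individuals only), `RGR_H`, `RGR_D`, `RGR_TNL` (individuals with at
#' least two measurements) and `HERB_AVE` (mean herbivory over the
#' experiment).
#'
#' @param records An [rte_records] object with measurements.
#' @return Data frame keyed by `individual_id` with the design factors and
#'   the derived responses (NA where undefined).
#' @export
derive_year6_traits <- function(records) {
  stopifnot(inherits(records, "rte_records"))
  if (is.null(records$measurements)) {
    stop_config("records carry no measurements")
  }
  ind <- records$individuals
  mea <- records$measurements
  final_age <- max(records$ages)
  early <- ind$germ_timing %in% c("at_transplant", "year1")
  out <- ind[early, c("individual_id", "mother_id", "garden_id", "ecotype",
                      "habitat", "provenance", "plantation", "status")]
  trait_map <- c(height_cm = "H", diameter_mm = "D", tnl = "TNL")
  for (tr in names(trait_map)) {
    lab <- trait_map[[tr]]
    mt <- mea[mea$trait == tr, ]
    at5 <- mt[mt$age == final_age, ]
    out[[paste0(lab, final_age)]] <-
      at5$value[match(out$individual_id, at5$individual_id)]
    rgr <- vapply(out$individual_id, function(id) {
      mi <- mt[mt$individual_id == id & mt$value > 0, ]
      if (length(unique(mi$age)) < 2L) return(NA_real_)
      relative_growth_rate(mi$age, mi$value)
    }, numeric(1))
    out[[paste0("RGR_", lab)]] <- unname(rgr)
  }
  mh <- mea[mea$trait == "herbivory_pct", ]
  herb <- tapply(mh$value, mh$individual_id, mean)
  out$HERB_AVE <- unname(herb[out$individual_id])
  rownames(out) <- NULL
  out
}
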