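# Count tabulations (Ni / Gt / Go / AliveY6) and reconstruction of minimal
# individual records from published count summaries.

count_group_keys <- c("mother_id", "garden_id", "ecotype", "habitat",
                      "provenance", "plantation")

#' Tabulate seed counts per group
#'
#' For each group defined by `group_by`, counts the seeds planted (`Ni`),
#' those germinated at the time of transplant (`Gt`), those germinated at
#' any point by the end of the experiment (`Go`) and the seedlings alive at
#' the final census (`AliveY6`). An empty `group_by` yields the grand
#' totals. By construction `0 <= Gt <= Go <= Ni` and `AliveY6 <= Go`, and
#' group counts sum to the grand totals over any partition.
#'
#' @param records An [rte_records] object.
#' @param group_by Character vector of grouping keys, a subset of
#'   `mother_id`, `garden_id`, `ecotype`, `habitat`, `provenance`,
#'   `plantation`.
#' @return A data frame with the grouping keys and columns `Ni`, `Gt`,
#'   `Go`, `AliveY6`.
#' @export
tabulate_counts <- function(records, group_by = character()) {
  stopifnot(inherits(records, "rte_records"))
  bad <- setdiff(group_by, count_group_keys)
  if (length(bad)) {
    stop_config("unknown grouping key(s): ", paste(bad, collapse = ", "),
                "; valid keys: ", paste(count_group_keys, collapse = ", "))
  }
  ind <- records$individuals
  final_fate <- ind[[paste0("fate_y", records$n_years)]]
  flags <- data.frame(
    Ni = 1L,
    Gt = as.integer(ind$status == "seedling"),
    Go = as.integer(ind$germ_timing != "never"),
    AliveY6 = as.integer(final_fate == "alive")
  )
  if (!length(group_by)) {
    out <- as.data.frame(t(colSums(flags)))
    out[] <- lapply(out, as.integer)
    return(out)
  }
  agg <- stats::aggregate(flags, by = ind[group_by], FUN = sum)
  ord <- do.call(order, agg[group_by])
  out <- agg[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconstruct minimal individual records from a count summary
#'
#' Builds a set of individual records consistent with a published per-mother
#' or per-garden count table (columns `Ni`, `Gt`, `Go`, `AliveY6`). The
#' reconstruction is minimal: `Gt` individuals are transplanted as
#' seedlings, `Go - Gt` germinate in the field in year 1, the remainder
#' never germinate; `AliveY6` of the germinated survive every census and
#' the rest die the year after germination. Fields the summary does not
#' determine (e.g. garden for a per-mother table) are filled with a fixed
#' synthetic allocation. Every count tabulated by [tabulate_counts()] on
#' the result reproduces the input exactly; individual-level fields beyond
#' the counts are placeholders, not data.
#'
#' @param counts Data frame with columns `Ni`, `Gt`, `Go`, `AliveY6` plus
#'   either (`mother_id`, `ecotype`, `provenance`) for `type = "mother"` or
#'   (`garden_id`, `plantation`, `habitat`) for `type = "garden"`.
#' @param type `"mother"` or `"garden"` summary.
#' @return An [rte_records] object (individuals only).
#' @export
records_from_count_table <- function(counts, type = c("mother", "garden")) {
  type <- match.arg(type)
  need <- c(switch(type,
                   mother = c("mother_id", "ecotype", "provenance"),
                   garden = c("garden_id", "plantation", "habitat")),
            c("Ni", "Gt", "Go", "AliveY6"))
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    stop_config("count table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  bad <- with(counts, Gt > Go | Go > Ni | AliveY6 > Go |
                Ni < 0 | Gt < 0 | AliveY6 < 0)
  if (any(bad)) {
    stop_data("count table violates 0 <= Gt <= Go <= Ni, AliveY6 <= Go ",
              "in row(s) ", paste(which(bad), collapse = ", "))
  }
  rows <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    ci <- counts[i, ]
    n <- ci$Ni
    if (n == 0L) next
    idx <- seq_len(n)
    germinated <- idx <= ci$Go
    at_transplant <- idx <= ci$Gt
    # survivors are taken among the germinated, transplanted seedlings first
    alive_final <- idx <= ci$AliveY6
    status <- ifelse(at_transplant, "seedling", "seed")
    germ_timing <- ifelse(at_transplant, "at_transplant",
                          ifelse(germinated, "year1", "never"))
    fates <- matrix("pre_germination", n, rte_n_years)
    for (j in idx) {
      if (!germinated[j]) next
      if (alive_final[j]) {
        fates[j, ] <- "alive"
      } else if (at_transplant[j]) {
        fates[j, ] <- "dead"
      } else {
        fates[j, ] <- c("alive", rep("dead", rte_n_years - 1L))
      }
    }
    if (type == "mother") {
      mother_id <- ci$mother_id
      ecotype <- ci$ecotype
      provenance <- ci$provenance
      # fixed synthetic allocation over the 12 standard gardens
      g <- standard_gardens()
      gi <- g[rep_len(seq_len(nrow(g)), n), ]
      garden_id <- gi$garden_id
      plantation <- gi$plantation
      habitat <- gi$habitat
    } else {
      garden_id <- ci$garden_id
      plantation <- ci$plantation
      habitat <- ci$habitat
      mother_id <- paste0("M_", ci$garden_id)  # synthetic placeholder
      ecotype <- "glo"
      provenance <- "E"
    }
    df <- data.frame(
      individual_id = sprintf("%s_%s_%03d", type,
                              if (type == "mother") mother_id else garden_id,
                              idx),
      mother_id = mother_id, garden_id = garden_id,
      ecotype = ecotype, habitat = habitat,
      provenance = provenance, plantation = plantation,
      status = status, shadehouse_days = 89L, germ_timing = germ_timing,
      stringsAsFactors = FALSE
    )
    fdf <- as.data.frame(fates, stringsAsFactors = FALSE)
    names(fdf) <- paste0("fate_y", seq_len(rte_n_years))
    rows[[i]] <- cbind(df, fdf)
  }
  ind <- do.call(rbind, rows)
  rte_records(ind)
}

#' The 12 standard experimental gardens
#'
#' Three replicate gardens per (plantation region, habitat) cell: gardens
#' 1-3 western hilltop, 4-6 western seasonally flooded, 7-9 eastern
#' seasonally flooded, 10-12 eastern hilltop.
#'
#' @return Data frame with columns `garden_id`, `plantation`, `habitat`.
#' @export
standard_gardens <- function() {
  data.frame(
    garden_id  = sprintf("G%02d", 1:12),
    plantation = rep(c("W", "E"), each = 6),
    habitat    = rep(c("HT", "SF", "SF", "HT"), each = 3),
    stringsAsFactors = FALSE
  )
}

#' Bundled example count summaries
#'
#' Returns one of the two count summaries from the motivating field
#' experiment, shipped as plain-text CSV: per-mother counts
#' (`"mothers"`: 14 mother trees, 510 seeds) or per-garden counts
#' (`"gardens"`: 12 experimental gardens, same 510 seeds).
#'
#' @param which `"mothers"` or `"gardens"`.
#' @return Data frame of counts.
#' @export
rte_example_counts <- function(which = c("mothers", "gardens")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0(sub("s$", "", which), "_counts.csv"),
                      package = "rtadapt", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
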