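# Record model: loading, validation, round trip, counts, derived traits.

test_that("load/write round trip preserves every field value", {
  rec <- rte_records(tiny_individuals(), tiny_measurements())
  dir <- withr::local_tempdir()
  write_records(rec, dir)
  rec2 <- load_records(file.path(dir, "individuals.csv"),
                       file.path(dir, "measurements.csv"))
  expect_identical(rec2$individuals, rec$individuals)
  expect_identical(rec2$measurements$value, rec$measurements$value)
  expect_identical(rec2$measurements$age, rec$measurements$age)
})

test_that("layout remapping and empty files work", {
  ind <- tiny_individuals()
  names(ind)[names(ind) == "ecotype"] <- "Ecotype"
  dir <- withr::local_tempdir()
  utils::write.csv(ind, file.path(dir, "ind.csv"), row.names = FALSE)
  rec <- load_records(file.path(dir, "ind.csv"),
                      layout = list(individuals = c(ecotype = "Ecotype")))
  expect_equal(nrow(rec$individuals), 4L)
  # empty file with a valid header -> empty record set
  utils::write.csv(tiny_individuals()[0, ], file.path(dir, "empty.csv"),
                   row.names = FALSE)
  expect_equal(nrow(load_records(file.path(dir, "empty.csv"))$individuals),
               0L)
})

test_that("validation is row-addressed and classed", {
  ind <- tiny_individuals()
  ind$habitat[2] <- "BOG"
  err <- expect_error(rte_records(ind), class = "rte_data_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "BOG")
  # missing column is a configuration error
  expect_error(validate_records(tiny_individuals()[-3]),
               class = "rte_config_error")
  # fate invariants: dead cannot resurrect
  ind <- tiny_individuals()
  ind$fate_y5[4] <- "alive"
  expect_error(rte_records(ind), class = "rte_data_error")
  # seedling status must match at_transplant timing
  ind <- tiny_individuals()
  ind$status[2] <- "seedling"
  expect_error(rte_records(ind), class = "rte_data_error")
  # garden must determine (plantation, habitat)
  ind <- tiny_individuals()
  ind$habitat[2] <- "HT"
  expect_error(rte_records(ind), "garden g1")
  # duplicate measurement key
  mea <- tiny_measurements()
  mea <- rbind(mea, mea[1, ])
  expect_error(rte_records(tiny_individuals(), mea),
               class = "rte_data_error")
})

test_that("tabulate_counts reproduces totals and respects partitions", {
  rec <- rte_records(tiny_individuals())
  tot <- tabulate_counts(rec)
  expect_equal(unlist(tot), c(Ni = 4L, Gt = 1L, Go = 3L, AliveY6 = 1L))
  for (key in c("mother_id", "garden_id", "ecotype", "provenance")) {
    by <- tabulate_counts(rec, key)
    expect_equal(colSums(by[c("Ni", "Gt", "Go", "AliveY6")]),
                 unlist(tot)[c("Ni", "Gt", "Go", "AliveY6")])
    expect_true(all(by$Gt <= by$Go & by$Go <= by$Ni & by$AliveY6 <= by$Go))
  }
  expect_error(tabulate_counts(rec, "shadehouse_days"),
               class = "rte_config_error")
})

test_that("count reconstruction reproduces an arbitrary count table", {
  counts <- data.frame(
    mother_id = c("mA", "mB"), ecotype = c("glo", "sp1"),
    provenance = c("E", "W"),
    Ni = c(10L, 7L), Gt = c(4L, 0L), Go = c(8L, 3L), AliveY6 = c(5L, 3L))
  rec <- records_from_count_table(counts, "mother")
  by <- tabulate_counts(rec, "mother_id")
  expect_equal(by$Ni, counts$Ni)
  expect_equal(by$Gt, counts$Gt)
  expect_equal(by$Go, counts$Go)
  expect_equal(by$AliveY6, counts$AliveY6)
  # inconsistent counts rejected
  bad <- counts
  bad$Go[1] <- 12L
  expect_error(records_from_count_table(bad, "mother"),
               class = "rte_data_error")
})

test_that("herbivory score follows the midpoint convention", {
  expect_equal(herbivory_score(rep("c0_20", 5)), 10)
  expect_equal(herbivory_score(c("c0_20", "c20_40")), 20)
  expect_equal(herbivory_score(c("c0_20", "c0_20", "c80_100")),
               (10 + 10 + 90) / 3)
  expect_error(herbivory_score(character()), class = "rte_data_error")
  expect_error(herbivory_score("c95_100"), class = "rte_data_error")
  # order invariance and bounds over random leaf sets
  set.seed(1)
  cls <- names(rte_herbivory_midpoints)
  for (i in 1:25) {
    leaves <- sample(cls, sample(1:12, 1), replace = TRUE)
    s <- herbivory_score(leaves)
    expect_equal(s, herbivory_score(rev(leaves)))
    expect_gte(s, 10)
    expect_lte(s, 90)
  }
})

test_that("relative growth rate handles gaps and stays path-invariant", {
  expect_equal(relative_growth_rate(c(0, 1), c(10, 20)), log(2))
  expect_equal(relative_growth_rate(c(2, 4), c(10, 40)), log(4) / 2)
  expect_equal(relative_growth_rate(c(0, 1, 2), c(10, 20, 10)), 0)
  # inserting a point on the exact log-linear path changes nothing
  set.seed(2)
  for (i in 1:20) {
    a <- sort(sample(0:6, 3))
    y0 <- runif(1, 1, 50)
    rate <- runif(1, -0.5, 0.8)
    y <- y0 * exp(rate * (a - a[1]))
    expect_equal(relative_growth_rate(a[c(1, 3)], y[c(1, 3)]),
                 relative_growth_rate(a, y), tolerance = 1e-12)
  }
  expect_error(relative_growth_rate(0, 10), class = "rte_data_error")
  expect_error(relative_growth_rate(c(0, 1), c(10, -2)),
               class = "rte_data_error")
})

test_that("survival coding counts whole years survived after germination", {
  # germinated year 1, recorded dead at year 3
  s <- encode_survival_series("year1",
                              c("alive", "alive", "dead", "dead", "dead"))
  expect_equal(s$final_age, 2L)
  expect_false(s$censored)
  # transplanted germinated, alive at the final census: censored at 5
  s <- encode_survival_series("at_transplant", rep("alive", 5))
  expect_equal(s$final_age, 5L)
  expect_true(s$censored)
  # never germinated: excluded
  expect_null(encode_survival_series("never", rep("pre_germination", 5)))
  # dead at first census after transplanting as seedling: age 0
  s <- encode_survival_series("at_transplant", rep("dead", 5))
  expect_equal(s$final_age, 0L)
  # whole-record-set coding matches the per-record rule
  rec <- rte_records(tiny_individuals())
  surv <- encode_survival(rec)
  expect_equal(surv$individual_id, c("i1", "i2", "i4"))
  expect_equal(surv$final_age, c(5L, 2L, 2L))
  expect_equal(surv$censored, c(TRUE, FALSE, FALSE))
})

test_that("fate code collapses histories to U / D1-D5 / A", {
  rec <- rte_records(tiny_individuals())
  expect_equal(as.character(fate_code(rec)), c("A", "D4", "U", "D3"))
})

test_that("derived year-6 traits compute RGR over measured individuals", {
  rec <- rte_records(tiny_individuals(), tiny_measurements())
  tr <- derive_year6_traits(rec)
  # i1 (at_transplant) and i4 (year1) qualify as first-year germinators
  expect_setequal(tr$individual_id, c("i1", "i4"))
  expect_equal(tr$RGR_H[tr$individual_id == "i1"], log(2))
})
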