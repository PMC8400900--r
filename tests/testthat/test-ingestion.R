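write_csv_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

test_that("read_products maps rows to records; absent cells stay absent", {
  rec <- make_records(3, total_sugar = c(1, NA, 3), sodium = c(100, 200, NA))
  path <- write_csv_fixture(rec)
  got <- read_products(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$total_sugar, c(1, NA, 3))
  expect_equal(got$sodium, c(100, 200, NA))
  expect_false(any(got$nutrient_error))

  # empty file with header
  path2 <- write_csv_fixture(rec[0, ])
  expect_equal(nrow(read_products(path2)), 0)
})

test_that("malformed numeric cells flag the record, not abort the read", {
  rec <- make_records(2)
  df <- rec
  df$sodium <- c("abc", "100")
  path <- write_csv_fixture(df)
  got <- read_products(path)
  expect_equal(got$nutrient_error, c(TRUE, FALSE))
  expect_true(is.na(got$sodium[1]))
})

test_that("panel invariant violations are nutrient errors", {
  rec <- make_records(3, total_fat = c(5, 5, 5), saturated_fat = c(6, 2, NA),
                      total_sugar = c(10, 10, 10), added_sugar = c(0, 12, 0))
  path <- write_csv_fixture(rec)
  got <- read_products(path)
  expect_equal(got$nutrient_error, c(TRUE, TRUE, FALSE))
})

test_that("header mismatch names the missing column", {
  df <- make_records(1)
  names(df)[names(df) == "barcode"] <- "ean"
  path <- write_csv_fixture(df)
  expect_error(read_products(path), "barcode")
  got <- read_products(path, default_schema(columns = c(barcode = "ean")))
  expect_equal(got$barcode, "B00001")
})

test_that("salt and kJ columns are converted to sodium mg and kcal at read", {
  df <- make_records(1, sodium = 2.5, energy = 418.4) # 2.5 g salt, 418.4 kJ
  path <- write_csv_fixture(df)
  got <- read_products(path, default_schema(sodium_unit = "salt_g",
                                            energy_unit = "kJ"))
  expect_equal(got$sodium, 1000)
  expect_equal(got$energy, 100)
})

test_that("deduplicate keeps first occurrence per barcode in input order", {
  rec <- make_records(5, barcode = c("a", "b", "a", "c", "b"),
                      total_sugar = 1:5)
  dd <- deduplicate(rec)
  expect_equal(dd$duplicates_removed, 2)
  expect_equal(dd$records$barcode, c("a", "b", "c"))
  expect_equal(dd$records$total_sugar, c(1, 2, 4))
  # all-unique input is untouched
  uniq <- make_records(4)
  expect_equal(deduplicate(uniq)$records, uniq)
})

test_that("exclusion cascade is first-match-wins and partitions the input", {
  rec <- rbind(
    make_records(1, barcode = "ok"),
    make_records(1, barcode = "err+nocat", category_code = "99",
                 nutrient_error = TRUE),
    make_records(1, barcode = "nocat", category_code = "ZZ"),
    make_records(1, barcode = "variety", is_variety_pack = TRUE),
    make_records(1, barcode = "baby+variety", is_variety_pack = TRUE,
                 is_baby_food = TRUE),
    make_records(1, barcode = "baby", is_baby_food = TRUE)
  )
  ex <- apply_exclusions(rec)
  # the err+nocat record lands in missing_or_error only
  expect_equal(unname(ex$counts), c(1L, 1L, 2L, 1L))
  expect_equal(ex$records$barcode, "ok")
  expect_equal(sum(ex$counts) + nrow(ex$records), nrow(rec))
  # no exclusions planted -> all buckets zero
  clean <- apply_exclusions(make_records(3))
  expect_true(all(clean$counts == 0))
})

test_that("reconstitute divides amounts by the dilution factor", {
  panel <- make_records(1, basis = "as_sold", total_sugar = 80, sodium = 500,
                        requires_preparation = TRUE)
  out <- reconstitute(panel, 10, is_beverage = TRUE)
  expect_equal(out$total_sugar, 8)
  expect_equal(out$sodium, 50)
  expect_equal(out$basis, "as_consumed")
  expect_equal(out$per, "100 ml")

  # dilution factor 1: amounts unchanged, basis flipped
  ident <- reconstitute(make_records(1, basis = "as_sold", total_sugar = 7), 1)
  expect_equal(ident$total_sugar, 7)
  expect_equal(ident$basis, "as_consumed")

  # already as consumed: untouched
  rtd <- make_records(1, total_sugar = 5)
  expect_equal(reconstitute(rtd, 10), rtd)

  # missing factor raises the typed no-preparation signal
  expect_error(reconstitute(make_records(1, basis = "as_sold"), NA),
               class = "fopwarn_no_preparation")
})

test_that("reconstitution is homogeneous in the panel amounts", {
  set.seed(42)
  for (k in c(0.5, 2, 7)) {
    panel <- make_records(1, basis = "as_sold", energy = 100, total_fat = 10,
                          saturated_fat = 4, total_sugar = 30, added_sugar = 12,
                          sodium = 800)
    scaled <- panel
    for (nut in c("energy", "total_fat", "saturated_fat", "total_sugar",
                  "added_sugar", "sodium")) {
      scaled[[nut]] <- panel[[nut]] * k
    }
    a <- reconstitute(scaled, 5)
    b <- reconstitute(panel, 5)
    for (nut in c("energy", "total_sugar", "sodium")) {
      expect_equal(a[[nut]], k * b[[nut]])
    }
  }
})

test_that("sufficiency requires every rule-referenced nutrient, both models", {
  tabs <- list(searo_thresholds(), cwo_thresholds())
  # confectionary missing total_sugar where sugar rules apply
  rec <- make_records(2, category_code = "1",
                      total_sugar = c(NA, 5), energy = 100, total_fat = 1,
                      saturated_fat = 0.5, sodium = 10)
  expect_equal(sufficiency_check(rec, tabs), c(FALSE, TRUE))
  # category 6A needs no total fat for SEARO, but CWO needs saturated fat
  juice <- make_records(1, category_code = "6A", total_sugar = 5,
                        saturated_fat = NA, energy = 40, sodium = 5)
  expect_false(sufficiency_check(juice, tabs))
  expect_true(sufficiency_check(juice, list(searo_thresholds())))
})

test_that("filter_products ledger conserves every input record", {
  cfg <- generator_config(seed = 5, n_products = 3000)
  rec <- generate_products(cfg)
  flt <- filter_products(rec, cfg$tables)
  expect_silent(ledger_check(flt$ledger))
  l <- as.list(flt$ledger)
  expect_equal(l$n_input, nrow(rec))
  expect_equal(l$duplicates_removed + l$missing_or_error + l$no_category +
                 l$variety_pack + l$baby_food + l$missing_nutrients +
                 l$no_preparation_instructions + l$analyzable, l$n_input)
  expect_true(all(flt$products$basis == "as_consumed"))
  # deterministic: same input gives identical ledger and retained set
  flt2 <- filter_products(rec, cfg$tables)
  expect_identical(unclass(flt$ledger), unclass(flt2$ledger))
  expect_identical(flt$products, flt2$products)
})

test_that("ledger_check rejects a broken cascade", {
  bad <- structure(c(n_input = 10L, duplicates_removed = 1L,
                     unique_products = 9L, missing_or_error = 1L,
                     no_category = 0L, variety_pack = 0L, baby_food = 0L,
                     category_assigned = 7L, missing_nutrients = 1L,
                     no_preparation_instructions = 0L, analyzable = 6L),
                   class = "exclusion_ledger")
  expect_error(ledger_check(bad), "category_assigned")
})
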