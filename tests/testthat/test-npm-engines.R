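searo <- searo_thresholds()
cwo <- cwo_thresholds()
tax <- searo_taxonomy()

test_that("zero panel with all flags no earns no label under either model", {
  rec <- make_records(3, category_code = c("1", "6C", "18"))
  for (res in list(evaluate_searo(rec, searo, tax),
                   evaluate_cwo(rec, cwo, tax))) {
    expect_equal(res$label_count, c(0L, 0L, 0L))
    expect_false(any(res$meets_any))
  }
})

test_that("an NNS flag alone makes a product meet the SEARO criteria", {
  rec <- make_records(1, category_code = "6C", flag_nns = "yes")
  res <- evaluate_searo(rec, searo, tax)
  expect_true(res$meets_any)
  expect_true(res$nns_triggered)
  expect_equal(res$label_count, 1L) # default: the trigger counts as a label
  res2 <- evaluate_model(rec, searo, tax, nns_counts = "meets_any")
  expect_true(res2$meets_any)
  expect_equal(res2$label_count, 0L)
  # CWO has no NNS rule
  expect_false(evaluate_cwo(rec, cwo, tax)$meets_any)
})

test_that("SEARO fires exactly the exceeded category rule", {
  # category 1 product one unit over the shipped sugar limit, all else 0
  lim <- searo$limit[searo$scope_key == "1" & searo$nutrient == "total_sugar"]
  rec <- make_records(1, category_code = "1", total_sugar = lim + 1)
  res <- evaluate_searo(rec, searo, tax)
  expect_equal(res$criteria_met, "sugar")
  expect_equal(res$label_count, 1L)
  # exactly at the limit: greater_than comparator does not fire
  at <- make_records(1, category_code = "1", total_sugar = lim)
  expect_equal(evaluate_searo(at, searo, tax)$label_count, 0L)
})

test_that("CWO gating: the same over-limit beverage labels only with added sugar", {
  lim <- cwo$limit[cwo$scope_key == "beverage" & cwo$nutrient == "total_sugar"]
  base <- make_records(1, category_code = "6B", total_sugar = lim + 3)
  for (fl in c("no", "unknown")) {
    base$flag_added_sugar <- fl
    expect_false(evaluate_cwo(base, cwo, tax)$meets_any, info = fl)
  }
  base$flag_added_sugar <- "yes"
  res <- evaluate_cwo(base, cwo, tax)
  expect_equal(res$criteria_met, "sugar")
  # strict mode evaluates unknown gates
  base$flag_added_sugar <- "unknown"
  expect_true(evaluate_cwo(base, cwo, tax, gate_unknown = "evaluate")$meets_any)
})

test_that("multiple rules sharing a label yield at most one label", {
  # CWO: energy has two gated rules with the same label identity
  lim <- cwo$limit[cwo$scope_key == "food" & cwo$nutrient == "energy"][1]
  rec <- make_records(1, category_code = "1", energy = lim + 50,
                      flag_added_sugar = "yes", flag_added_sat_fat = "yes")
  res <- evaluate_cwo(rec, cwo, tax)
  expect_equal(res$criteria_met, "energy")
  expect_equal(res$label_count, 1L)
})

test_that("evaluate_batch is order-preserving, pure, and stacks models", {
  rec <- random_records(40, seed = 9)
  both <- evaluate_batch(rec, list(searo, cwo), tax)
  expect_equal(nrow(both), 80)
  expect_setequal(unique(both$model), c("SEARO", "CWO_phase3"))
  # batch equals concatenation of singleton evaluations
  single <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    evaluate_batch(rec[i, ], list(searo, cwo), tax)
  }))
  ord <- function(d) d[order(d$model, d$barcode), ]
  expect_equal(ord(single), ord(both), ignore_attr = TRUE)
  # empty input -> empty result
  expect_equal(nrow(evaluate_batch(rec[0, ], list(searo, cwo), tax)), 0)
})

test_that("both engines match the brute-force oracle on random panels", {
  rec <- random_records(2500, seed = 31)
  for (tab in list(searo, cwo)) {
    for (gu in c("skip", "evaluate")) {
      got <- evaluate_model(rec, tab, tax, gate_unknown = gu)
      want <- oracle_evaluate(rec, tab, gate_unknown = gu)
      expect_equal(got$label_count, want$label_count)
      expect_equal(got$meets_any, want$meets_any)
      expect_equal(got$criteria_met, want$criteria_met)
    }
  }
})

test_that("label_count is monotone in any single nutrient amount", {
  rec <- random_records(300, seed = 77, na_rate = 0)
  for (tab in list(searo, cwo)) {
    base <- evaluate_model(rec, tab, tax)$label_count
    for (nut in c("total_sugar", "sodium", "saturated_fat", "energy")) {
      up <- rec
      up[[nut]] <- up[[nut]] * 2 + 1
      if (nut == "saturated_fat") up$total_fat <- pmax(up$total_fat, up[[nut]])
      bumped <- evaluate_model(up, tab, tax)$label_count
      expect_true(all(bumped >= base), info = paste(attr(tab, "model_name"), nut))
    }
  }
})

test_that("CWO gating dominance: all-no flags floor, all-yes superset", {
  rec <- random_records(400, seed = 13, na_rate = 0)
  closed <- rec
  closed$flag_added_sugar <- "no"
  closed$flag_added_sodium <- "no"
  closed$flag_added_sat_fat <- "no"
  res_closed <- evaluate_cwo(closed, cwo, tax)
  expect_true(all(res_closed$label_count == 0))
  open <- rec
  open$flag_added_sugar <- "yes"
  open$flag_added_sodium <- "yes"
  open$flag_added_sat_fat <- "yes"
  res_open <- evaluate_cwo(open, cwo, tax)
  res_asis <- evaluate_cwo(rec, cwo, tax)
  expect_true(all(res_open$label_count >= res_asis$label_count))
  met_open <- strsplit(res_open$criteria_met, ",")
  met_asis <- strsplit(res_asis$criteria_met, ",")
  expect_true(all(mapply(function(a, b) all(b %in% a), met_open, met_asis)))
})

test_that("dairy-beverage divergence: SEARO labels sugar that CWO skips, and the gap closes when added-sugar flags open", {
  lim <- searo$limit[searo$scope_key == "6B" & searo$nutrient == "total_sugar"]
  rec <- make_records(50, category_code = "6B", total_sugar = lim + 1:50 / 10,
                      flag_added_sugar = "no")
  s <- evaluate_searo(rec, searo, tax)
  c0 <- evaluate_cwo(rec, cwo, tax)
  expect_true(all(s$meets_any))
  expect_false(any(grepl("sugar", c0$criteria_met)))
  rec$flag_added_sugar <- "yes"
  c1 <- evaluate_cwo(rec, cwo, tax)
  expect_true(all(grepl("sugar", c1$criteria_met)))
})

test_that("a category missing from the table signals a taxonomy mismatch", {
  partial <- searo[searo$scope_key != "12", ]
  attributes(partial)[c("model_name", "scope_type", "nns_rule", "class")] <-
    attributes(searo)[c("model_name", "scope_type", "nns_rule", "class")]
  rec <- make_records(1, category_code = "12")
  expect_error(evaluate_model(rec, partial, tax), "mismatch")
})
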