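# Fixture builders: records are constructed in code, never stored.

make_records <- function(n = 1, barcode = sprintf("B%05d", seq_len(n)),
                         name = sprintf("product %d", seq_len(n)),
                         category_code = "1",
                         energy = 0, total_fat = 0, saturated_fat = 0,
                         total_sugar = 0, added_sugar = 0, sodium = 0,
                         basis = "as_consumed", per = "100 g",
                         requires_preparation = FALSE, dilution_factor = NA_real_,
                         flag_added_sugar = "no", flag_added_sodium = "no",
                         flag_added_sat_fat = "no", flag_nns = "no",
                         is_variety_pack = FALSE, is_baby_food = FALSE,
                         nutrient_error = FALSE) {
  data.frame(barcode = barcode, name = name, category_code = category_code,
             energy = energy, total_fat = total_fat,
             saturated_fat = saturated_fat, total_sugar = total_sugar,
             added_sugar = added_sugar, sodium = sodium,
             basis = basis, per = per,
             requires_preparation = requires_preparation,
             dilution_factor = dilution_factor,
             flag_added_sugar = flag_added_sugar,
             flag_added_sodium = flag_added_sodium,
             flag_added_sat_fat = flag_added_sat_fat, flag_nns = flag_nns,
             is_variety_pack = is_variety_pack, is_baby_food = is_baby_food,
             nutrient_error = nutrient_error, stringsAsFactors = FALSE)
}

# Random analyzable records spanning all categories, amounts on the scale of
# each category's limits (so rules fire for a substantial fraction), flags in
# all three states, occasional absent nutrients.
random_records <- function(n, seed, na_rate = 0.05,
                           taxonomy = searo_taxonomy()) {
  set.seed(seed)
  codes <- sample(taxonomy$code, n, replace = TRUE)
  amounts <- function(scale) scale * rexp(n)
  rec <- make_records(
    n, category_code = codes,
    energy = amounts(200), total_fat = amounts(12),
    total_sugar = amounts(12), sodium = amounts(450),
    flag_added_sugar = sample(c("yes", "no", "unknown"), n, TRUE),
    flag_added_sodium = sample(c("yes", "no", "unknown"), n, TRUE),
    flag_added_sat_fat = sample(c("yes", "no", "unknown"), n, TRUE),
    flag_nns = sample(c("yes", "no", "unknown"), n, TRUE,
                      prob = c(0.1, 0.8, 0.1))
  )
  rec$saturated_fat <- rec$total_fat * runif(n)
  rec$added_sugar <- rec$total_sugar * runif(n)
  for (nut in c("energy", "total_fat", "saturated_fat", "total_sugar",
                "added_sugar", "sodium")) {
    rec[[nut]][runif(n) < na_rate] <- NA_real_
  }
  rec
}
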