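# Ingestion and the exclusion cascade.
#
# A product record is one row of a plain data frame:
#   barcode, name, category_code,
#   energy (kcal), total_fat, saturated_fat, total_sugar, added_sugar (g),
#   sodium (mg)            -- per 100 g (foods) / 100 ml (beverages); NA = absent,
#                             never zero: nutrient reporting is not mandatory in
#                             the source market and absence is informative,
#   basis ("as_sold"/"as_consumed"), per ("100 g"/"100 ml"),
#   requires_preparation (logical), dilution_factor (ratio, NA if none given),
#   flag_added_sugar / flag_added_sodium / flag_added_sat_fat / flag_nns
#                          ("yes"/"no"/"unknown"),
#   is_variety_pack, is_baby_food (logical),
#   nutrient_error (logical; set by the reader on malformed cells or panel
#                   invariant violations).

#' Default column-mapping schema for product CSV files
#'
#' Maps internal field names to source-file column names and declares source
#' units. `sodium_unit = "salt_g"` converts a salt column to sodium at read
#' time (sodium mg = salt g × 1000 / 2.5); `energy_unit = "kJ"` divides by
#' 4.184. A single internal unit (mg sodium, kcal) prevents double
#' conversion downstream.
#'
#' @param columns Named character vector, internal name -> file column.
#' @param sodium_unit `"mg"` or `"salt_g"`.
#' @param energy_unit `"kcal"` or `"kJ"`.
#' @export
default_schema <- function(columns = NULL, sodium_unit = "mg", energy_unit = "kcal") {
  base <- stats::setNames(RECORD_COLUMNS, RECORD_COLUMNS)
  if (!is.null(columns)) base[names(columns)] <- columns
  stopifnot(sodium_unit %in% c("mg", "salt_g"), energy_unit %in% c("kcal", "kJ"))
  list(columns = base, sodium_unit = sodium_unit, energy_unit = energy_unit)
}

parse_num <- function(x) {
  suppressWarnings(as.numeric(ifelse(trimws(x) == "", NA, x)))
}

#' Read product records from a delimited file
#'
#' Absent cells become absent (`NA`) fields, never zeros. A malformed numeric
#' cell (e.g. sodium `"abc"`) does not abort the read: the record is flagged
#' `nutrient_error` and is later counted under the missing-or-error exclusion.
#'
#' @param path CSV file with a header row.
#' @param schema Column mapping from [default_schema()].
#' @return Data frame of raw product records.
#' @export
read_products <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop(sprintf("cannot read product file: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cols <- schema$columns
  core <- c("barcode", "category_code")
  miss <- setdiff(cols[core], names(raw))
  if (length(miss)) {
    stop(sprintf("header mismatch: expected column(s) %s not found in %s",
                 paste(miss, collapse = ", "), path), call. = FALSE)
  }
  n <- nrow(raw)
  get <- function(internal, default = NA_character_) {
    col <- cols[[internal]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, n)
  }
  rec <- data.frame(
    barcode = get("barcode"), name = get("name"),
    category_code = toupper(trimws(get("category_code"))),
    stringsAsFactors = FALSE
  )
  err <- rep(FALSE, n)
  for (nut in NUTRIENT_FIELDS) {
    cell <- get(nut)
    val <- parse_num(cell)
    # malformed: non-empty text that fails to parse
    err <- err | (!is.na(cell) & trimws(cell) != "" & is.na(val))
    rec[[nut]] <- val
  }
  if (schema$sodium_unit == "salt_g") rec$sodium <- rec$sodium * 1000 / 2.5
  if (schema$energy_unit == "kJ") rec$energy <- rec$energy / 4.184
  basis <- get("basis")
  basis[is.na(basis) | basis == ""] <- "as_sold"
  rec$basis <- basis
  per <- get("per")
  per[is.na(per) | per == ""] <- "100 g"
  rec$per <- per
  rp <- tolower(get("requires_preparation", "FALSE"))
  rec$requires_preparation <- rp %in% c("true", "1", "yes")
  dil <- parse_num(get("dilution_factor"))
  err <- err | (!is.na(dil) & dil <= 0)
  rec$dilution_factor <- dil
  for (fl in FLAG_FIELDS) {
    v <- tolower(trimws(get(paste0("flag_", fl), "unknown")))
    v[!v %in% c("yes", "no")] <- "unknown"
    rec[[paste0("flag_", fl)]] <- v
  }
  rec$is_variety_pack <- tolower(get("is_variety_pack", "FALSE")) %in% c("true", "1", "yes")
  rec$is_baby_food <- tolower(get("is_baby_food", "FALSE")) %in% c("true", "1", "yes")
  rec$nutrient_error <- err | panel_invalid(rec)
  rec
}

# Panel invariant violations: negative amounts, saturated fat exceeding total
# fat, added sugar exceeding total sugar. NA comparisons are not violations.
panel_invalid <- function(rec) {
  bad <- rep(FALSE, nrow(rec))
  for (nut in NUTRIENT_FIELDS) {
    v <- rec[[nut]]
    bad <- bad | (!is.na(v) & (v < 0 | !is.finite(v)))
  }
  both <- !is.na(rec$saturated_fat) & !is.na(rec$total_fat)
  bad[both] <- bad[both] | (rec$saturated_fat[both] > rec$total_fat[both])
  both <- !is.na(rec$added_sugar) & !is.na(rec$total_sugar)
  bad[both] <- bad[both] | (rec$added_sugar[both] > rec$total_sugar[both])
  bad
}

#' Collapse duplicate barcodes
#'
#' Keeps the first occurrence of each barcode in file order (the source
#' carries no timestamps, so first-in-order is the deterministic choice).
#'
#' @param records Raw record data frame.
#' @return `list(records, duplicates_removed)`.
#' @export
deduplicate <- function(records) {
  keep <- !duplicated(records$barcode)
  list(records = records[keep, , drop = FALSE],
       duplicates_removed = sum(!keep))
}

#' Apply the pre-category exclusion cascade
#'
#' Fixed order, first matching rule wins, so each excluded product is counted
#' in exactly one bucket and the ledger partitions the input:
#' (1) missing information / nutrient errors on the label,
#' (2) no SEARO category assignment, (3) variety packs, (4) baby food.
#'
#' @param records Deduplicated records.
#' @param taxonomy Registry from [searo_taxonomy()].
#' @return `list(records, counts)` where `counts` is a named integer vector.
#' @export
apply_exclusions <- function(records, taxonomy = searo_taxonomy()) {
  n <- nrow(records)
  excluded <- rep(FALSE, n)
  counts <- c(missing_or_error = 0L, no_category = 0L,
              variety_pack = 0L, baby_food = 0L)
  hit <- function(mask) {
    mask <- mask & !excluded
    excluded <<- excluded | mask
    sum(mask)
  }
  counts["missing_or_error"] <- hit(records$nutrient_error |
                                      is.na(records$barcode) | records$barcode == "")
  counts["no_category"] <- hit(is.na(records$category_code) |
                                 !(records$category_code %in% taxonomy$code))
  counts["variety_pack"] <- hit(records$is_variety_pack)
  counts["baby_food"] <- hit(records$is_baby_food)
  list(records = records[!excluded, , drop = FALSE], counts = counts)
}

#' Reconstitute an as-sold panel to the as-consumed basis
#'
#' Concentrates and powders are diluted with water per package instructions;
#' water contributes zero nutrients, so every amount is divided by the
#' dilution factor (ratio of as-consumed volume to as-sold quantity). The
#' basis flips to `as_consumed`; for beverages the reference quantity becomes
#' 100 ml.
#'
#' @param panel One-row data frame (or list) with the nutrient fields,
#'   `basis` and `per`.
#' @param dilution_factor Positive ratio; missing raises a condition of class
#'   `fopwarn_no_preparation`, which the cascade maps to the
#'   no-preparation-instructions bucket.
#' @param is_beverage Whether the product is a beverage (sets `per`).
#' @return The panel on an as-consumed basis.
#' @export
reconstitute <- function(panel, dilution_factor, is_beverage = FALSE) {
  if (identical(panel$basis, "as_consumed")) return(panel)
  if (missing(dilution_factor) || is.null(dilution_factor) || is.na(dilution_factor)) {
    stop(structure(class = c("fopwarn_no_preparation", "error", "condition"),
                   list(message = "reconstitution impossible: no dilution factor",
                        call = sys.call(-1))))
  }
  stopifnot(dilution_factor > 0)
  for (nut in NUTRIENT_FIELDS) panel[[nut]] <- panel[[nut]] / dilution_factor
  panel$basis <- "as_consumed"
  if (is_beverage) panel$per <- "100 ml"
  panel
}

#' Nutrient sufficiency for model evaluation
#'
#' A product can be evaluated only if every nutrient referenced by any rule
#' applicable to its category (category-scoped models) or food/beverage form
#' (form-scoped models), across *all* requested models, is present on the
#' panel. Vectorised over records.
#'
#' @param records Record data frame (category-assigned).
#' @param tables List of `threshold_table` objects.
#' @param taxonomy Registry.
#' @return Logical vector.
#' @export
sufficiency_check <- function(records, tables, taxonomy = searo_taxonomy()) {
  if (inherits(tables, "threshold_table")) tables <- list(tables)
  forms <- product_form(records$category_code, taxonomy)
  ok <- rep(TRUE, nrow(records))
  for (code in unique(records$category_code)) {
    idx <- which(records$category_code == code)
    need <- rule_nutrients_for(code, forms[idx[1]], tables)
    for (nut in need) ok[idx] <- ok[idx] & !is.na(records[[nut]][idx])
  }
  ok
}

# Vectorised reconstitution for the pipeline: returns records with panels on
# the as-consumed basis; assumes unreconstitutable records were removed.
reconstitute_records <- function(records, taxonomy = searo_taxonomy()) {
  needs <- records$basis == "as_sold" & records$requires_preparation
  d <- ifelse(needs, records$dilution_factor, 1)
  for (nut in NUTRIENT_FIELDS) records[[nut]] <- records[[nut]] / d
  records$basis <- "as_consumed"
  bev <- records$category_code %in% searo_codes_beverage(taxonomy)
  records$per <- ifelse(bev, "100 ml", "100 g")
  records
}

searo_codes_beverage <- function(taxonomy) taxonomy$code[taxonomy$is_beverage]

#' Run the full exclusion cascade
#'
#' Deduplicate, apply the label/category/variety/baby-food exclusions, check
#' nutrient sufficiency, then reconstitutability (sufficiency first:
#' a product missing required nutrients is counted there even if it also
#' lacks preparation instructions), and reconstitute survivors to the
#' as-consumed basis.
#'
#' @param records Raw records from [read_products()] (or the generator).
#' @param tables Threshold tables whose rules define sufficiency.
#' @param taxonomy Registry.
#' @return `list(products, ledger)`: the analyzable as-consumed records and an
#'   `exclusion_ledger`.
#' @export
filter_products <- function(records, tables, taxonomy = searo_taxonomy()) {
  n_input <- nrow(records)
  dd <- deduplicate(records)
  ex <- apply_exclusions(dd$records, taxonomy)
  assigned <- ex$records
  suff <- sufficiency_check(assigned, tables, taxonomy)
  kept <- assigned[suff, , drop = FALSE]
  unrecon <- kept$basis == "as_sold" & kept$requires_preparation &
    is.na(kept$dilution_factor)
  analyzable <- reconstitute_records(kept[!unrecon, , drop = FALSE], taxonomy)
  ledger <- new_ledger(
    n_input = n_input,
    duplicates_removed = dd$duplicates_removed,
    unique_products = nrow(dd$records),
    missing_or_error = ex$counts[["missing_or_error"]],
    no_category = ex$counts[["no_category"]],
    variety_pack = ex$counts[["variety_pack"]],
    baby_food = ex$counts[["baby_food"]],
    category_assigned = nrow(assigned),
    missing_nutrients = sum(!suff),
    no_preparation_instructions = sum(unrecon),
    analyzable = nrow(analyzable)
  )
  list(products = analyzable, ledger = ledger)
}

new_ledger <- function(...) {
  led <- c(...)
  storage.mode(led) <- "integer"
  structure(led, class = "exclusion_ledger")
}

#' Check exclusion-ledger conservation invariants
#'
#' Every input product must be counted exactly once: as retained-analyzable or
#' in a single exclusion bucket.
#'
#' @param ledger An `exclusion_ledger`.
#' @return `TRUE` invisibly, or an error naming the violated identity.
#' @export
ledger_check <- function(ledger) {
  l <- as.list(ledger)
  with(l, {
    if (n_input - duplicates_removed != unique_products)
      stop("ledger: n_input - duplicates_removed != unique_products", call. = FALSE)
    if (unique_products - (missing_or_error + no_category + variety_pack + baby_food)
        != category_assigned)
      stop("ledger: unique_products - exclusions != category_assigned", call. = FALSE)
    if (category_assigned - (missing_nutrients + no_preparation_instructions)
        != analyzable)
      stop("ledger: category_assigned - (missing_nutrients + no_preparation_instructions) != analyzable",
           call. = FALSE)
  })
  invisible(TRUE)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion cascade (in order applied):\n")
  for (nm in names(x)) cat(sprintf("  %-28s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Write the ledger as a key,count CSV
#' @param ledger An `exclusion_ledger`.
#' @param path Output file.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(data.frame(stage = names(ledger), count = as.integer(ledger)),
                   path, row.names = FALSE)
}
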