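# Seeded synthetic product-database generator.
#
# The generator emulates the *structure* of a commercial new-product database
# extract: a category mix proportional to the published per-category totals,
# right-skewed (log-normal) nutrient panels per 100 g / 100 ml, ingredient
# flags correlated with amounts through a logistic link, duplicate barcodes,
# planted label errors / unassignable categories / variety packs / baby food
# at the published exclusion rates, as-sold concentrates with (or without)
# dilution instructions, and per-nutrient missingness tuned so the expected
# analyzable fraction matches the published cascade. It does not attempt to
# match any real joint nutrient distribution.

run_seeded <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Read the published per-category counts shipped with the package
#'
#' Total products per SEARO category, evaluable counts, and per-model
#' coverage, used as the default category mix and calibration targets.
#' @return Data frame keyed by `category_code`.
#' @export
table1_counts <- function() {
  utils::read.csv(system.file("extdata", "table1_counts.csv", package = "fopwarn"),
                  comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(category_code = "character"))
}

#' Build a generator configuration
#'
#' Defaults restate the published study's world: 41,255 raw rows with a
#' 6,113/41,255 duplicate rate; label-error, no-category, variety-pack and
#' baby-food rates equal to the published exclusion counts over 35,142 unique
#' products; a category mix proportional to the published per-category
#' totals; and a single per-nutrient missingness probability solved (at
#' config-build time, by `uniroot`) so the expected analyzable fraction of
#' category-assigned products equals 10,501/31,519.
#'
#' @param seed Integer seed; fully determines the generated output.
#' @param n_products Number of raw rows (including duplicates).
#' @param category_weights Named probability vector over the 25 codes.
#' @param sdlog Log-scale spread of nutrient amounts.
#' @param shifts Named per-category log-location shift applied to all nutrient
#'   amounts (0 = amounts centred on the category's own limits); set by
#'   [calibrate_to_table1()].
#' @param modes Named per-category mode: `"lognormal"`, `"zero"` (all panels
#'   below every limit) or `"high"` (all panels above some limit) — the
#'   degenerate point-mass handling for 0%/100% coverage targets.
#' @param missingness Per-nutrient absence probability; `NULL` solves it from
#'   the cascade target above.
#' @param duplicate_rate,error_rate,no_category_rate,variety_rate,baby_rate
#'   Planting rates for the exclusion cascade.
#' @param p_as_sold Fraction of products whose label reports the panel as
#'   sold (concentrates/powders/mixes requiring preparation).
#' @param p_no_instructions Fraction of those lacking usable dilution
#'   instructions.
#' @param dilution_range Range of dilution factors (as-consumed volume per
#'   as-sold quantity).
#' @param flag_unknown Probability an ingredient flag is "unknown".
#' @param nns_base,nns_beverage Baseline probability of a non-nutritive
#'   sweetener flag for foods and beverages.
#' @param tables Threshold tables defining sufficiency (defaults: shipped
#'   SEARO + CWO Phase 3).
#' @param taxonomy Registry.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_products = 41255L,
                             category_weights = NULL, sdlog = 0.8,
                             shifts = NULL, modes = NULL,
                             missingness = NULL,
                             duplicate_rate = 6113 / 41255,
                             error_rate = 1339 / 35142,
                             no_category_rate = 1921 / 35142,
                             variety_rate = 204 / 35142,
                             baby_rate = 159 / 35142,
                             p_as_sold = 0.20, p_no_instructions = 0.55,
                             dilution_range = c(4, 12),
                             flag_unknown = 0.15,
                             nns_base = 0.02, nns_beverage = 0.04,
                             tables = list(searo_thresholds(), cwo_thresholds()),
                             taxonomy = searo_taxonomy()) {
  codes <- taxonomy$code
  if (is.null(category_weights)) {
    t1 <- table1_counts()
    category_weights <- stats::setNames(t1$total_n[match(codes, t1$category_code)], codes)
    category_weights <- category_weights / sum(category_weights)
  }
  if (abs(sum(category_weights) - 1) > 1e-8 || any(category_weights < 0)) {
    stop("infeasible config: category_weights must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (is.null(names(category_weights)) || !setequal(names(category_weights), codes)) {
    stop("infeasible config: category_weights must be named by the 25 category codes",
         call. = FALSE)
  }
  rates <- c(duplicate_rate, error_rate, no_category_rate, variety_rate, baby_rate,
             p_as_sold, p_no_instructions, flag_unknown, nns_base, nns_beverage)
  if (any(rates < 0 | rates > 1)) {
    stop("infeasible config: all rates/probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(shifts)) shifts <- stats::setNames(rep(0, length(codes)), codes)
  if (is.null(modes)) modes <- stats::setNames(rep("lognormal", length(codes)), codes)
  forms <- product_form(codes, taxonomy)
  k <- vapply(seq_along(codes), function(i) {
    length(rule_nutrients_for(codes[i], forms[i], tables))
  }, integer(1))
  if (is.null(missingness)) {
    # expected analyzable fraction of category-assigned products:
    # sum_c w_c (1-p)^{k_c} * (1 - p_as_sold * p_no_instructions) = 10501/31519
    target_pass <- (10501 / 31519) / (1 - p_as_sold * p_no_instructions)
    w <- category_weights[codes]
    f <- function(p) sum(w * (1 - p)^k) - target_pass
    missingness <- stats::uniroot(f, c(1e-6, 1 - 1e-6))$root
  }
  structure(list(
    seed = as.integer(seed), n_products = as.integer(n_products),
    category_weights = category_weights[codes], sdlog = sdlog,
    shifts = shifts, modes = modes, missingness = missingness,
    duplicate_rate = duplicate_rate, error_rate = error_rate,
    no_category_rate = no_category_rate, variety_rate = variety_rate,
    baby_rate = baby_rate, p_as_sold = p_as_sold,
    p_no_instructions = p_no_instructions, dilution_range = dilution_range,
    flag_unknown = flag_unknown, nns_base = nns_base,
    nns_beverage = nns_beverage, tables = tables, taxonomy = taxonomy
  ), class = "generator_config")
}

# Reference limit per nutrient for a category: the category's own SEARO limit
# where one exists, else the CWO limit for the product form, else a plausible
# scale constant (total fat has no CWO rule).
ref_limits <- function(code, config) {
  form <- product_form(code, config$taxonomy)
  L <- stats::setNames(rep(NA_real_, length(NUTRIENT_FIELDS)), NUTRIENT_FIELDS)
  for (tab in config$tables) {
    key <- if (attr(tab, "scope_type") == "category") code else form
    rows <- tab[tab$scope_key == key, ]
    for (i in seq_len(nrow(rows))) {
      if (is.na(L[rows$nutrient[i]])) L[rows$nutrient[i]] <- rows$limit[i]
    }
  }
  if (is.na(L["total_fat"])) L["total_fat"] <- if (form == "beverage") 2.5 else 10
  if (is.na(L["saturated_fat"])) L["saturated_fat"] <- L["total_fat"] / 2
  if (is.na(L["total_sugar"])) L["total_sugar"] <- 10
  if (is.na(L["added_sugar"])) L["added_sugar"] <- L["total_sugar"]
  if (is.na(L["sodium"])) L["sodium"] <- 400
  if (is.na(L["energy"])) L["energy"] <- if (form == "beverage") 70 else 275
  L
}

# As-consumed panels for n products of one category. `draws`, when supplied,
# freezes the underlying uniforms/normals so calibration can scan the location
# shift over common random numbers.
gen_panels <- function(code, n, config, shift = config$shifts[[code]],
                       mode = config$modes[[code]], draws = NULL) {
  L <- ref_limits(code, config)
  is_bev <- product_form(code, config$taxonomy) == "beverage"
  if (is.null(draws)) {
    draws <- list(z = matrix(stats::rnorm(n * 4), n, 4),
                  u = matrix(stats::runif(n * 8), n, 8))
  }
  caps <- c(energy = 900, total_fat = 100, saturated_fat = 100,
            total_sugar = 100, added_sugar = 100, sodium = 5000)
  panel <- data.frame(total_fat = numeric(n))
  if (mode == "zero") {
    panel$total_fat <- L["total_fat"] * 0.5 * draws$u[, 1]
    panel$saturated_fat <- panel$total_fat * (0.2 + 0.6 * draws$u[, 2])
    panel$total_sugar <- L["total_sugar"] * 0.5 * draws$u[, 3]
    panel$added_sugar <- rep(0, n)
    panel$sodium <- L["sodium"] * 0.5 * draws$u[, 4]
    panel$energy <- L["energy"] * 0.5 * draws$u[, 5]
  } else if (mode == "high") {
    over <- 1.2 + draws$u[, 1]
    panel$total_fat <- pmax(L["total_fat"], 1) * over
    panel$saturated_fat <- panel$total_fat * (0.3 + 0.5 * draws$u[, 2])
    panel$total_sugar <- pmax(L["total_sugar"], 1) * over
    panel$added_sugar <- panel$total_sugar * 0.8
    panel$sodium <- pmax(L["sodium"], 10) * over
    panel$energy <- pmax(L["energy"], 10) * over
  } else {
    panel$total_fat <- L["total_fat"] * exp(shift + config$sdlog * draws$z[, 1])
    panel$saturated_fat <- panel$total_fat * (0.2 + 0.7 * draws$u[, 2])
    panel$total_sugar <- L["total_sugar"] * exp(shift + config$sdlog * draws$z[, 2])
    has_added <- draws$u[, 3] < 0.7
    panel$added_sugar <- panel$total_sugar * draws$u[, 4] * has_added
    panel$sodium <- L["sodium"] * exp(shift + config$sdlog * draws$z[, 3])
    panel$energy <- L["energy"] * exp(shift + config$sdlog * draws$z[, 4])
  }
  for (nut in names(caps)) panel[[nut]] <- pmin(panel[[nut]], caps[[nut]])
  panel$saturated_fat <- pmin(panel$saturated_fat, panel$total_fat)
  panel$added_sugar <- pmin(panel$added_sugar, panel$total_sugar)
  # ingredient flags: logistic in the amount relative to the category limit,
  # so gating and amounts are correlated as in real formulations
  rel <- function(x, ref) x / pmax(ref, 1e-6)
  p_yes <- function(r) stats::plogis(-1.5 + 2 * r)
  flag_from <- function(r, u1, u2) {
    ifelse(u1 < config$flag_unknown, "unknown",
           ifelse(u2 < p_yes(r), "yes", "no"))
  }
  if (mode == "zero") {
    panel$flag_added_sugar <- rep("no", n)
    panel$flag_added_sodium <- rep("no", n)
    panel$flag_added_sat_fat <- rep("no", n)
    panel$flag_nns <- rep("no", n)
  } else {
    panel$flag_added_sugar <- flag_from(rel(panel$added_sugar, L["total_sugar"]),
                                        draws$u[, 5], draws$u[, 6])
    panel$flag_added_sodium <- flag_from(rel(panel$sodium, L["sodium"]),
                                         draws$u[, 5], draws$u[, 7])
    panel$flag_added_sat_fat <- flag_from(rel(panel$saturated_fat, L["saturated_fat"]),
                                          draws$u[, 5], draws$u[, 8])
    p_nns <- if (is_bev) config$nns_beverage else config$nns_base
    panel$flag_nns <- ifelse(draws$u[, 6] * draws$u[, 7] < p_nns^1.5, "yes", "no")
  }
  panel
}

#' Generate a synthetic product database
#'
#' Deterministic given `config$seed`. Records satisfy the product-record
#' invariants except for deliberately planted violations (duplicates, label
#' errors, unassignable categories, variety packs, baby food, missing
#' nutrients, missing preparation instructions) at the configured rates.
#'
#' @param config A [generator_config()].
#' @return Raw product-record data frame in the schema [read_products()]
#'   emits, ready for [filter_products()].
#' @export
generate_products <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_products
  empty <- utils::read.csv(text = paste(RECORD_COLUMNS, collapse = ","),
                           colClasses = "character")
  if (n == 0L) return(empty)
  run_seeded(config$seed, {
    n_dup <- round(config$duplicate_rate * n)
    n_base <- n - n_dup
    codes <- names(config$category_weights)
    cat_draw <- sample(codes, n_base, replace = TRUE, prob = config$category_weights)
    parts <- lapply(unique(cat_draw), function(code) {
      m <- sum(cat_draw == code)
      panel <- gen_panels(code, m, config)
      panel$category_code <- code
      panel
    })
    rec <- do.call(rbind, parts)
    rec <- rec[sample.int(nrow(rec)), , drop = FALSE]
    rec$barcode <- sprintf("B%08d", seq_len(n_base))
    rec$name <- sprintf("Synthetic product %d", seq_len(n_base))
    # as-sold concentrates: scale the as-consumed panel up by the dilution
    # factor so reconstitution recovers it; some lack usable instructions
    as_sold <- stats::runif(n_base) < config$p_as_sold
    dil <- round(stats::runif(n_base, config$dilution_range[1], config$dilution_range[2]), 1)
    no_instr <- as_sold & stats::runif(n_base) < config$p_no_instructions
    for (nut in NUTRIENT_FIELDS) {
      rec[[nut]] <- ifelse(as_sold, rec[[nut]] * dil, rec[[nut]])
    }
    rec$basis <- ifelse(as_sold, "as_sold", "as_consumed")
    rec$per <- ifelse(rec$basis == "as_sold" |
                        !(rec$category_code %in% searo_codes_beverage(config$taxonomy)),
                      "100 g", "100 ml")
    rec$requires_preparation <- as_sold
    rec$dilution_factor <- ifelse(as_sold & !no_instr, dil, NA_real_)
    # per-nutrient missingness (absent, never zero)
    for (nut in NUTRIENT_FIELDS) {
      gone <- stats::runif(n_base) < config$missingness
      rec[[nut]][gone] <- NA_real_
    }
    # planted exclusions
    rec$nutrient_error <- stats::runif(n_base) < config$error_rate
    rec$category_code[stats::runif(n_base) < config$no_category_rate] <- "99"
    rec$is_variety_pack <- stats::runif(n_base) < config$variety_rate
    rec$is_baby_food <- stats::runif(n_base) < config$baby_rate
    if (n_dup > 0) {
      rec <- rbind(rec, rec[sample.int(n_base, n_dup, replace = FALSE), , drop = FALSE])
    }
    rownames(rec) <- NULL
    rec[, RECORD_COLUMNS]
  })
}

#' Write generated records as a CSV the ingestion module can read back
#'
#' Records flagged `nutrient_error` get a malformed sodium cell so the
#' round-trip through [read_products()] reproduces the planted label errors.
#'
#' @param records Generated records.
#' @param path Output CSV path.
#' @export
write_products <- function(records, path) {
  out <- records
  out$sodium <- as.character(out$sodium)
  out$sodium[out$nutrient_error] <- "ERR"
  out$nutrient_error <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
}

#' Industry-style biased subsample
#'
#' Weighted sampling without replacement with weights
#' `(1 + label_count)^weight_exponent`, so products carrying many warning
#' labels are over-represented — the mechanism by which a small
#' industry-selected sample inflates apparent warning-label coverage.
#' `weight_exponent = 0` recovers simple random sampling.
#'
#' @param records Analyzable records.
#' @param results Evaluation results for one model, aligned by barcode.
#' @param sample_size Subsample size (published industry sample: 1,306).
#' @param weight_exponent Bias strength, >= 0.
#' @param seed Integer seed.
#' @return Subsampled records.
#' @export
biased_subsample <- function(records, results, sample_size = 1306L,
                             weight_exponent = 0, seed = 1L) {
  stopifnot(weight_exponent >= 0)
  lc <- stats::setNames(results$label_count, results$barcode)[records$barcode]
  if (anyNA(lc)) stop("results missing for some records", call. = FALSE)
  if (sample_size >= nrow(records)) return(records)
  w <- (1 + lc)^weight_exponent
  run_seeded(seed, {
    idx <- sample.int(nrow(records), sample_size, replace = FALSE, prob = w)
    records[idx, , drop = FALSE]
  })
}

#' Calibrate the generator to per-category coverage targets
#'
#' Adjusts each category's log-location shift by monotone bisection so the
#' expected fraction of its products meeting at least one SEARO criterion
#' matches the target within one percentage point. Coverage is estimated on
#' `m` panels per category with common random numbers across the bisection
#' scan, so the objective is monotone and deterministic. Targets of 0 or 100
#' are unreachable with a positive log-normal scale and are handled by the
#' degenerate `"zero"`/`"high"` point-mass modes.
#'
#' @param targets Named per-category coverage percentages in \[0, 100\];
#'   default: the published per-category SEARO coverage (categories with no
#'   published value fall back to 50).
#' @param config Base [generator_config()].
#' @param m Panels per category for coverage estimation.
#' @return The config with `shifts` and `modes` set.
#' @export
calibrate_to_table1 <- function(targets = NULL, config = generator_config(), m = 4000L) {
  codes <- names(config$category_weights)
  if (is.null(targets)) {
    t1 <- table1_counts()
    targets <- stats::setNames(t1$searo_pct[match(codes, t1$category_code)], codes)
    targets[is.na(targets)] <- 50
  }
  if (any(targets < 0 | targets > 100)) {
    stop("coverage targets must lie in [0, 100]", call. = FALSE)
  }
  searo <- config$tables[[which(vapply(config$tables, attr, "", "model_name") == "SEARO")]]
  for (code in codes) {
    t <- targets[[code]]
    if (t <= 0) { config$modes[[code]] <- "zero"; config$shifts[[code]] <- 0; next }
    if (t >= 100) { config$modes[[code]] <- "high"; config$shifts[[code]] <- 0; next }
    config$modes[[code]] <- "lognormal"
    draws <- run_seeded(config$seed + match(code, codes), {
      list(z = matrix(stats::rnorm(m * 4), m, 4),
           u = matrix(stats::runif(m * 8), m, 8))
    })
    coverage <- function(delta) {
      panel <- gen_panels(code, m, config, shift = delta, mode = "lognormal",
                          draws = draws)
      panel$category_code <- code
      panel$barcode <- as.character(seq_len(m))
      100 * mean(evaluate_model(panel, searo, config$taxonomy)$meets_any)
    }
    lo <- -8; hi <- 8
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (coverage(mid) < t) lo <- mid else hi <- mid
      if (hi - lo < 1e-3) break
    }
    config$shifts[[code]] <- (lo + hi) / 2
  }
  config
}
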