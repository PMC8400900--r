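# Nutrient profile models as data: a threshold table is a plain data frame of
# rules (scope_key, nutrient, limit, comparator, gate, label) plus a couple of
# attributes. The engine never hard-codes a limit.

#' Load a nutrient-profile threshold table
#'
#' @param path CSV with columns `scope_key`, `nutrient`, `limit`, `unit`,
#'   `comparator`, `gate`, `label`. `scope_key` is a SEARO category code
#'   (category-scoped models) or `food`/`beverage` (form-scoped models such as
#'   the CWO). `gate`, when non-empty, names the ingredient flag that must be
#'   "yes" for the rule to be evaluated at all.
#' @param model_name Identifier stored on the table (e.g. `"SEARO"`).
#' @param scope_type `"category"` or `"form"`.
#' @param nns_rule Whether presence of a non-nutritive sweetener alone makes a
#'   product meet the model's criteria (the SEARO convention).
#' @return A data frame of class `threshold_table`.
#' @export
load_threshold_table <- function(path, model_name, scope_type = c("category", "form"),
                                 nns_rule = FALSE) {
  scope_type <- match.arg(scope_type)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(scope_key = "character"))
  need <- c("scope_key", "nutrient", "limit", "comparator", "gate", "label")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("threshold table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab$scope_key <- if (scope_type == "category") {
    toupper(trimws(tab$scope_key))
  } else {
    trimws(tab$scope_key)
  }
  tab$gate[is.na(tab$gate)] <- ""
  bad <- setdiff(unique(tab$nutrient), NUTRIENT_FIELDS)
  if (length(bad)) {
    stop(sprintf("unknown nutrient(s) in threshold table: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(tab, model_name = model_name, scope_type = scope_type,
            nns_rule = nns_rule, class = c("threshold_table", "data.frame"))
}

#' @rdname load_threshold_table
#' @details `searo_thresholds()` and `cwo_thresholds()` load the defaults
#'   shipped with the package. The SEARO file is a reconstruction of the
#'   published per-category limits (see the file header and the methods
#'   vignette); the CWO file carries the Phase 3 (2019) statutory limits.
#' @export
searo_thresholds <- function(path = system.file("extdata", "searo_thresholds.csv",
                                                package = "fopwarn")) {
  load_threshold_table(path, model_name = "SEARO", scope_type = "category",
                       nns_rule = TRUE)
}

#' @rdname load_threshold_table
#' @export
cwo_thresholds <- function(path = system.file("extdata", "cwo_phase3_thresholds.csv",
                                              package = "fopwarn")) {
  load_threshold_table(path, model_name = "CWO_phase3", scope_type = "form",
                       nns_rule = FALSE)
}

#' Validate threshold tables against the taxonomy
#'
#' Checks scope completeness (a category-scoped table must cover all 25 SEARO
#' codes; a form-scoped table exactly `food` and `beverage`), limit sanity
#' (non-negative, finite), comparator and gate vocabulary, and — for the SEARO
#' table — agreement between each category's rule nutrients and the taxonomy's
#' `required_nutrients`.
#'
#' @param tables List of `threshold_table` objects.
#' @param taxonomy Registry from [searo_taxonomy()].
#' @return Character vector of violations, `character(0)` when clean, with
#'   attribute `valid`.
#' @export
validate_thresholds <- function(tables, taxonomy = searo_taxonomy()) {
  if (inherits(tables, "threshold_table")) tables <- list(tables)
  problems <- character(0)
  for (tab in tables) {
    nm <- attr(tab, "model_name")
    if (attr(tab, "scope_type") == "category") {
      absent <- setdiff(taxonomy$code, unique(tab$scope_key))
      if (length(absent)) {
        problems <- c(problems, sprintf(
          "%s: no rules for category code(s): %s", nm, paste(absent, collapse = ", ")))
      }
      extra <- setdiff(unique(tab$scope_key), taxonomy$code)
      if (length(extra)) {
        problems <- c(problems, sprintf(
          "%s: rules for unknown category code(s): %s", nm, paste(extra, collapse = ", ")))
      }
      for (i in seq_len(nrow(taxonomy))) {
        code <- taxonomy$code[i]
        rule_nut <- sort(unique(tab$nutrient[tab$scope_key == code]))
        if (length(rule_nut) &&
            !identical(rule_nut, taxonomy$required_nutrients[[i]])) {
          problems <- c(problems, sprintf(
            "%s: category %s rule nutrients (%s) disagree with taxonomy required_nutrients (%s)",
            nm, code, paste(rule_nut, collapse = ";"),
            paste(taxonomy$required_nutrients[[i]], collapse = ";")))
        }
      }
    } else {
      if (!setequal(unique(tab$scope_key), c("food", "beverage"))) {
        problems <- c(problems, sprintf(
          "%s: form-scoped table must cover exactly {food, beverage}, found {%s}",
          nm, paste(unique(tab$scope_key), collapse = ", ")))
      }
    }
    bad_lim <- !is.finite(tab$limit) | tab$limit < 0
    if (any(bad_lim)) {
      problems <- c(problems, sprintf(
        "%s: negative or non-finite limit for %s", nm,
        paste(sprintf("%s/%s", tab$scope_key[bad_lim], tab$nutrient[bad_lim]),
              collapse = ", ")))
    }
    bad_cmp <- !tab$comparator %in% COMPARATORS
    if (any(bad_cmp)) {
      problems <- c(problems, sprintf("%s: unknown comparator(s): %s", nm,
                                      paste(unique(tab$comparator[bad_cmp]), collapse = ", ")))
    }
    bad_gate <- nzchar(tab$gate) & !tab$gate %in% FLAG_FIELDS
    if (any(bad_gate)) {
      problems <- c(problems, sprintf("%s: unknown gate flag(s): %s", nm,
                                      paste(unique(tab$gate[bad_gate]), collapse = ", ")))
    }
  }
  structure(problems, valid = length(problems) == 0L)
}

# Nutrients any applicable rule references for a given product, across models.
# scope resolution: category tables key on category code, form tables on the
# food/beverage dichotomy.
rule_nutrients_for <- function(category_code, form, tables) {
  out <- character(0)
  for (tab in tables) {
    key <- if (attr(tab, "scope_type") == "category") category_code else form
    out <- c(out, tab$nutrient[tab$scope_key == key])
  }
  sort(unique(out))
}
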