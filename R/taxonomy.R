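#' SEARO food-category taxonomy
#'
#' The WHO SEARO nutrient profile model partitions the packaged-food supply
#' into 25 categories; codes beginning with "6" (6A--6E) are beverages and are
#' evaluated per 100 ml as consumed, all others per 100 g. The registry is
#' shipped as a version-controlled CSV so a revised category list can be
#' dropped in without touching code.
#'
#' @param path Optional path to a registry CSV with columns `code`, `name`,
#'   `is_beverage`, `required_nutrients` (semicolon-separated). Defaults to
#'   the registry shipped with the package.
#' @return A data frame of class `searo_taxonomy` with one row per category;
#'   `required_nutrients` is a list column of character vectors.
#' @export
#' @examples
#' tax <- searo_taxonomy()
#' nrow(tax)            # 25
#' sum(tax$is_beverage) # 5
searo_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "searo_categories.csv", package = "fopwarn")
  }
  tax <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(code = "character"))
  stopifnot(all(c("code", "name", "is_beverage", "required_nutrients") %in% names(tax)))
  tax$code <- toupper(trimws(tax$code))
  if (anyDuplicated(tax$code)) {
    stop("taxonomy registry contains duplicated category codes", call. = FALSE)
  }
  tax$is_beverage <- as.logical(tax$is_beverage)
  bev_by_code <- startsWith(tax$code, "6")
  if (!all(tax$is_beverage == bev_by_code)) {
    stop("taxonomy registry: is_beverage must be true exactly for codes starting with '6'",
         call. = FALSE)
  }
  tax$required_nutrients <- lapply(strsplit(tax$required_nutrients, ";", fixed = TRUE),
                                   function(x) sort(trimws(x)))
  class(tax) <- c("searo_taxonomy", "data.frame")
  tax
}

#' Look up a SEARO category by code
#'
#' Case-insensitive on the letter suffix ("6b" and "6B" are the same
#' category). An unknown code raises a condition of class
#' `fopwarn_unknown_category`; the ingestion cascade maps that condition to
#' the "no category" exclusion bucket.
#'
#' @param code Category code string, e.g. `"5A"`.
#' @param taxonomy A registry from [searo_taxonomy()].
#' @return One-row data frame (the registry entry).
#' @export
lookup_category <- function(code, taxonomy = searo_taxonomy()) {
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code)) {
    stop("category code must be a single non-empty string", call. = FALSE)
  }
  i <- match(toupper(trimws(code)), taxonomy$code)
  if (is.na(i)) {
    stop(structure(
      class = c("fopwarn_unknown_category", "error", "condition"),
      list(message = sprintf("unknown SEARO category code: '%s'", code),
           call = sys.call(-1))))
  }
  taxonomy[i, , drop = FALSE]
}

#' Food/beverage form of a category (the CWO dichotomy)
#'
#' The Chilean Warning Octagon applies one threshold set to all foods and a
#' separate set to all beverages; the form is derived deterministically from
#' the SEARO beverage flag.
#'
#' @param category A registry entry from [lookup_category()], or a character
#'   vector of category codes.
#' @param taxonomy Registry used to resolve codes when `category` is character.
#' @return `"food"` or `"beverage"` (vectorised over codes).
#' @export
product_form <- function(category, taxonomy = searo_taxonomy()) {
  if (is.character(category)) {
    i <- match(toupper(trimws(category)), taxonomy$code)
    if (anyNA(i)) {
      stop(sprintf("unknown SEARO category code(s): %s",
                   paste(unique(category[is.na(i)]), collapse = ", ")), call. = FALSE)
    }
    bev <- taxonomy$is_beverage[i]
  } else {
    bev <- category$is_beverage
  }
  ifelse(bev, "beverage", "food")
}
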