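# Survey-style coverage reporting: per-category counts, percent meeting at
# least one criterion per model, and the 0/1/2/3+ warning-label distribution.
#
# Rounding: percentages are computed as 100 * numerator / denominator and
# formatted under an explicit policy. The default is round-half-up; several
# published tables in this literature are consistent with truncation instead,
# so "truncate" is available and tests should pin only cells where the two
# agree. An empty denominator renders "-", never 0 or NaN.

#' Round-half-up / truncation percentage formatting
#'
#' `round()` in R rounds half to even; survey tables conventionally round
#' half up, so that policy is implemented explicitly.
#'
#' @param x Numeric vector of percentages.
#' @param digits Decimal places.
#' @param policy `"round"` (half-up) or `"truncate"`.
#' @return Numeric vector.
#' @export
round_pct <- function(x, digits = 1, policy = c("round", "truncate")) {
  policy <- match.arg(policy)
  f <- 10^digits
  if (policy == "round") floor(x * f + 0.5) / f else trunc(x * f) / f
}

pct_of <- function(num, den, digits, policy) {
  ifelse(den > 0, round_pct(100 * num / den, digits, policy), NA_real_)
}

#' Build the per-category coverage report
#'
#' One row per SEARO category in registry order plus a `Total` row. For each
#' model present in `results`: the number and percent of evaluable products
#' meeting at least one criterion. Categories with zero evaluable products
#' report `NA` percentages (rendered "-" in the formatted table).
#'
#' @param results Stacked evaluation results from [evaluate_batch()].
#' @param records Category-assigned records (analyzable and not), used for
#'   `n_total`; the evaluable set is whatever appears in `results`.
#' @param taxonomy Registry.
#' @param digits,policy Percentage formatting (see [round_pct()]).
#' @return A data frame of class `study_report`; model columns are
#'   `<model>_n` and `<model>_pct`.
#' @export
build_report <- function(results, records, taxonomy = searo_taxonomy(),
                         digits = 1, policy = "round") {
  stray <- setdiff(results$barcode, records$barcode)
  if (length(stray)) {
    stop(sprintf("results reference barcode(s) absent from records: %s",
                 paste(utils::head(stray, 5), collapse = ", ")), call. = FALSE)
  }
  cat_of <- stats::setNames(records$category_code, records$barcode)
  results$category_code <- unname(cat_of[results$barcode])
  models <- unique(results$model)
  codes <- taxonomy$code
  rep_df <- data.frame(category_code = c(codes, "Total"),
                       name = c(taxonomy$name, "Total"),
                       stringsAsFactors = FALSE)
  tot_n <- table(factor(records$category_code, levels = codes))
  rep_df$n_total <- c(as.integer(tot_n), nrow(records))
  first <- results[results$model == models[1], ]
  ev_n <- table(factor(first$category_code, levels = codes))
  rep_df$n_evaluable <- c(as.integer(ev_n), nrow(first))
  for (m in models) {
    r <- results[results$model == m, ]
    meet <- tapply(r$meets_any, factor(r$category_code, levels = codes), sum)
    meet[is.na(meet)] <- 0L
    n_meet <- c(as.integer(meet), sum(r$meets_any))
    rep_df[[paste0(m, "_n")]] <- n_meet
    rep_df[[paste0(m, "_pct")]] <- pct_of(n_meet, rep_df$n_evaluable, digits, policy)
  }
  structure(rep_df, models = models, digits = digits, policy = policy,
            class = c("study_report", "data.frame"))
}

#' Warning-label count distribution (0, 1, 2, ..., bucket_top+)
#'
#' Counts are top-coded at `bucket_top` (the published convention is 3, giving
#' buckets 0/1/2/3+). Buckets partition the evaluable products, so each row's
#' percentages sum to 100 within rounding.
#'
#' @param results Evaluation results for ONE model (filter before calling).
#' @param records Records carrying `category_code` per barcode.
#' @param bucket_top Top-coding point, >= 1.
#' @param taxonomy,digits,policy As in [build_report()].
#' @return Data frame: category rows plus Total, with `n` and one `pct_<k>`
#'   column per bucket (`pct_<bucket_top>plus` for the last).
#' @export
label_distribution <- function(results, records, bucket_top = 3,
                               taxonomy = searo_taxonomy(),
                               digits = 1, policy = "round") {
  stopifnot(bucket_top >= 1, length(unique(results$model)) <= 1)
  cat_of <- stats::setNames(records$category_code, records$barcode)
  cats <- unname(cat_of[results$barcode])
  k <- pmin(results$label_count, bucket_top)
  codes <- taxonomy$code
  lev <- 0:bucket_top
  tab <- table(factor(cats, levels = codes), factor(k, levels = lev))
  tab <- rbind(tab, Total = colSums(tab))
  n <- rowSums(tab)
  out <- data.frame(category_code = rownames(tab), n = as.integer(n),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_along(lev)) {
    nm <- if (lev[j] == bucket_top) sprintf("pct_%dplus", bucket_top)
          else sprintf("pct_%d", lev[j])
    out[[nm]] <- pct_of(as.integer(tab[, j]), n, digits, policy)
  }
  out
}

#' Between-model coverage differences
#'
#' Signed per-category difference in percent meeting at least one criterion
#' (first model minus second), with the largest-gap category flagged.
#'
#' @param report A `study_report` containing both models.
#' @param models Character vector of two model names; defaults to the first
#'   two in the report.
#' @return Data frame with `diff_pct` and logical `largest_gap` (Total row
#'   excluded from the largest-gap search).
#' @export
compare_models <- function(report, models = attr(report, "models")[1:2]) {
  stopifnot(length(models) == 2)
  cols <- paste0(models, "_pct")
  if (!all(cols %in% names(report))) {
    stop("report does not contain both requested models", call. = FALSE)
  }
  out <- report[, c("category_code", "name", "n_evaluable", cols)]
  out$diff_pct <- out[[cols[1]]] - out[[cols[2]]]
  body <- out$category_code != "Total" & !is.na(out$diff_pct)
  out$largest_gap <- FALSE
  if (any(body)) {
    out$largest_gap[body][which.max(abs(out$diff_pct[body]))] <- TRUE
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in grep("_pct$", names(y), value = TRUE)) {
    y[[col]] <- ifelse(is.na(y[[col]]), "-",
                       formatC(y[[col]], format = "f",
                               digits = attr(x, "digits")))
  }
  print(y, right = TRUE, row.names = FALSE)
  invisible(x)
}

#' Write a study report to CSV (machine) with "-" for empty denominators
#' @param report A `study_report`.
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  y <- as.data.frame(report)
  for (col in grep("_pct$", names(y), value = TRUE)) {
    y[[col]] <- ifelse(is.na(y[[col]]), "-", format(y[[col]], trim = TRUE))
  }
  utils::write.csv(y, path, row.names = FALSE)
}
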