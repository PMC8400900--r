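# The rule engine. Both models share one evaluator: a rule fires when the
# panel amount exceeds its limit (comparator from the table) AND its gate, if
# any, is open. Distinct rules can share a label identity (e.g. total and
# added sugar both feed the "sugar" label); a product earns each label at most
# once, because the published 0/1/2/3+ distributions count warning labels, not
# rules.

#' Evaluate products against a nutrient profile model
#'
#' `evaluate_model()` is the shared engine; [evaluate_searo()] and
#' [evaluate_cwo()] are thin wrappers that pick the scope semantics from the
#' table. Panels must already be on the as-consumed basis.
#'
#' SEARO semantics: rules are category-specific and ungated; additionally, any
#' product with an added non-nutritive sweetener meets the model's criteria
#' outright (`nns_triggered`). Whether that trigger counts as a warning label
#' of its own (default) or only forces `meets_any` is controlled by
#' `nns_counts`, since published label-count tables do not resolve it.
#'
#' CWO semantics: one rule set for all foods and one for all beverages; a rule
#' is evaluated only when the ingredient flag named by its gate is `"yes"`.
#' With `gate_unknown = "skip"` (default) an unknown flag closes the gate,
#' matching the observation that gating lowers CWO coverage relative to
#' SEARO; `"evaluate"` treats unknown as open (strict mode).
#'
#' @param records Analyzable product records (as-consumed basis).
#' @param table A `threshold_table`.
#' @param taxonomy Registry from [searo_taxonomy()].
#' @param nns_counts `"label"` or `"meets_any"`.
#' @param gate_unknown `"skip"` or `"evaluate"`.
#' @return Data frame with one row per product: `barcode`, `model`,
#'   `criteria_met` (comma-joined label identities), `label_count`,
#'   `meets_any`, `nns_triggered`.
#' @export
evaluate_model <- function(records, table, taxonomy = searo_taxonomy(),
                           nns_counts = c("label", "meets_any"),
                           gate_unknown = c("skip", "evaluate")) {
  nns_counts <- match.arg(nns_counts)
  gate_unknown <- match.arg(gate_unknown)
  n <- nrow(records)
  if (n == 0L) {
    return(data.frame(barcode = character(0), model = character(0),
                      criteria_met = character(0), label_count = integer(0),
                      meets_any = logical(0), nns_triggered = logical(0),
                      stringsAsFactors = FALSE))
  }
  scope_type <- attr(table, "scope_type")
  keys <- if (scope_type == "category") {
    records$category_code
  } else {
    product_form(records$category_code, taxonomy)
  }
  unknown <- setdiff(unique(keys), unique(table$scope_key))
  if (scope_type == "category" && length(unknown)) {
    stop(sprintf("threshold table '%s' has no rules for category code(s): %s (table/taxonomy mismatch)",
                 attr(table, "model_name"), paste(unknown, collapse = ", ")), call. = FALSE)
  }
  labels <- sort(unique(table$label))
  met <- matrix(FALSE, n, length(labels), dimnames = list(NULL, labels))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    rules <- table[table$scope_key == key, , drop = FALSE]
    for (r in seq_len(nrow(rules))) {
      open <- rep(TRUE, length(idx))
      if (nzchar(rules$gate[r])) {
        fl <- records[[paste0("flag_", rules$gate[r])]][idx]
        open <- if (gate_unknown == "skip") fl == "yes" else fl != "no"
      }
      amt <- records[[rules$nutrient[r]]][idx]
      fired <- !is.na(amt) & open &
        if (rules$comparator[r] == "greater_than") amt > rules$limit[r] else amt >= rules$limit[r]
      met[idx, rules$label[r]] <- met[idx, rules$label[r]] | fired
    }
  }
  nns_trig <- attr(table, "nns_rule") & records$flag_nns == "yes"
  count <- rowSums(met)
  if (nns_counts == "label") count <- count + nns_trig
  res <- data.frame(
    barcode = records$barcode,
    model = attr(table, "model_name"),
    criteria_met = apply(met, 1, function(row) paste(labels[row], collapse = ",")),
    label_count = as.integer(count),
    meets_any = count > 0 | nns_trig,
    nns_triggered = as.logical(nns_trig),
    stringsAsFactors = FALSE
  )
  res
}

#' @rdname evaluate_model
#' @export
evaluate_searo <- function(records, table = searo_thresholds(),
                           taxonomy = searo_taxonomy(), nns_counts = "label") {
  evaluate_model(records, table, taxonomy, nns_counts = nns_counts)
}

#' @rdname evaluate_model
#' @export
evaluate_cwo <- function(records, table = cwo_thresholds(),
                         taxonomy = searo_taxonomy(), gate_unknown = "skip") {
  evaluate_model(records, table, taxonomy, gate_unknown = gate_unknown)
}

#' Evaluate a batch of products against several models
#'
#' Order-preserving and pure: the result for a record does not depend on the
#' rest of the batch.
#'
#' @param records Analyzable product records.
#' @param tables List of `threshold_table` objects.
#' @inheritParams evaluate_model
#' @return One data frame with a row per product per model (stacked).
#' @export
evaluate_batch <- function(records, tables, taxonomy = searo_taxonomy(),
                           nns_counts = "label", gate_unknown = "skip") {
  if (inherits(tables, "threshold_table")) tables <- list(tables)
  out <- lapply(tables, function(tab) {
    tryCatch(
      evaluate_model(records, tab, taxonomy,
                     nns_counts = nns_counts, gate_unknown = gate_unknown),
      error = function(e) {
        stop(sprintf("model %s failed: %s", attr(tab, "model_name"),
                     conditionMessage(e)), call. = FALSE)
      })
  })
  do.call(rbind, out)
}
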