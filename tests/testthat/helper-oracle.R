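# Independent brute-force rule evaluator: loops product by product and rule
# by rule with explicit comparisons. Deliberately shares no code with the
# vectorised engine it checks.

oracle_evaluate <- function(records, table, nns_counts = "label",
                            gate_unknown = "skip") {
  scope_type <- attr(table, "scope_type")
  nns_rule <- isTRUE(attr(table, "nns_rule"))
  res <- data.frame(barcode = records$barcode,
                    label_count = NA_integer_, meets_any = NA,
                    criteria_met = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    key <- if (scope_type == "category") {
      rec$category_code
    } else if (substr(rec$category_code, 1, 1) == "6") "beverage" else "food"
    labels <- character(0)
    for (j in seq_len(nrow(table))) {
      rule <- table[j, ]
      if (rule$scope_key != key) next
      if (nzchar(rule$gate)) {
        fl <- rec[[paste0("flag_", rule$gate)]]
        if (gate_unknown == "skip" && fl != "yes") next
        if (gate_unknown == "evaluate" && fl == "no") next
      }
      amt <- rec[[rule$nutrient]]
      if (is.na(amt)) next
      hit <- if (rule$comparator == "greater_than") amt > rule$limit else amt >= rule$limit
      if (hit) labels <- union(labels, rule$label)
    }
    nns <- nns_rule && rec$flag_nns == "yes"
    count <- length(labels) + as.integer(nns && nns_counts == "label")
    res$label_count[i] <- count
    res$meets_any[i] <- count > 0 || nns
    res$criteria_met[i] <- paste(sort(labels), collapse = ",")
  }
  res
}
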