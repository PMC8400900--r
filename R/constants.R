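# Shared vocabulary (load order matters: this file precedes the modules that
# use these at top level).

NUTRIENT_FIELDS <- c("energy", "total_fat", "saturated_fat",
                     "total_sugar", "added_sugar", "sodium")
FLAG_FIELDS <- c("added_sugar", "added_sodium", "added_sat_fat", "nns")
COMPARATORS <- c("greater_than", "at_least")

RECORD_COLUMNS <- c("barcode", "name", "category_code", NUTRIENT_FIELDS,
                    "basis", "per", "requires_preparation", "dilution_factor",
                    paste0("flag_", FLAG_FIELDS),
                    "is_variety_pack", "is_baby_food", "nutrient_error")
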