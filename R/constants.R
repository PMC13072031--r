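# Closed categorical level sets and canonical column orders of the sampling
# design, shared by every module.

condition_levels <- c("healthy", "chlorotic")
position_levels <- c("apical", "basal")
soil_layer_levels <- c("0-20", "20-40", "40-60", "60-80", "80-100")
ratio_levels <- c("c_n", "c_p", "n_p")

needle_columns <- c("sample_id", "tree_id", "condition", "position",
                    "c_mg_g", "n_mg_g", "p_mg_g")
soil_columns <- c("sample_id", "tree_id", "condition", "soil_layer",
                  "c_mg_g", "n_mg_g", "p_mg_g")

conc_columns <- c("c_mg_g", "n_mg_g", "p_mg_g")

schema_columns <- function(schema) {
  switch(schema, needle = needle_columns, soil = soil_columns,
         abort(sprintf("unknown schema '%s'; use \"needle\" or \"soil\"", schema)))
}

design_column <- function(schema) if (schema == "needle") "position" else "soil_layer"

design_levels <- function(schema) {
  if (schema == "needle") position_levels else soil_layer_levels
}
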