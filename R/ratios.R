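# Mass-based stoichiometric ratios. Dimensionless because numerator and
# denominator share the unit (mg per g dry mass).

#' Compute C:N, C:P and N:P mass ratios
#'
#' @param c_mg_g,n_mg_g,p_mg_g Concentrations in mg per g dry mass; strictly
#'   positive, recycled to a common length.
#' @return A tibble with columns `c_n`, `c_p`, `n_p`. The three satisfy
#'   `n_p * c_n == c_p` to floating-point accuracy.
#' @examples
#' compute_ratios(472.4, 7.2, 1.6)
#' @export
compute_ratios <- function(c_mg_g, n_mg_g, p_mg_g) {
  if (any(c(c_mg_g, n_mg_g, p_mg_g) <= 0)) {
    abort("concentrations must be strictly positive to form ratios")
  }
  tibble(c_n = c_mg_g / n_mg_g, c_p = c_mg_g / p_mg_g, n_p = n_mg_g / p_mg_g)
}

#' Append stoichiometric ratio columns to a sample table
#'
#' Adds `c_n`, `c_p` and `n_p` columns computed row-wise from the `c_mg_g`,
#' `n_mg_g` and `p_mg_g` concentrations.
#'
#' @param samples A validated sample table (needle or soil).
#' @return The input tibble with three ratio columns appended.
#' @export
add_stoich_ratios <- function(samples) {
  for (cc in conc_columns) {
    if (!cc %in% names(samples)) abort(sprintf("column %s is required", cc))
  }
  dplyr::bind_cols(as_tibble(samples),
                   compute_ratios(samples$c_mg_g, samples$n_mg_g, samples$p_mg_g))
}
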