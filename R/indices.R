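# The five stoichiometric indices: HI, NSI, NRE, RPI, SDI.
#
# Conventions fixed across the package:
#   * sample SD (n - 1 denominator) everywhere a spread enters (HI, CV, NSI);
#   * NRE and RPI are computed per tree, then summarized per condition, so the
#     between-tree variance that the t-test needs is preserved;
#   * the SDI denominator is always the soil ratio (the index is deliberately
#     asymmetric: it measures the needle's relative distance from the soil).

#' Homeostatic index (mean/SD) group summary
#'
#' Summarizes a variable per group as mean, sample SD, coefficient of
#' variation CV = SD/mean and homeostatic index HI = mean/SD = 1/CV. A higher
#' HI means the group holds the quantity more stable (stronger stoichiometric
#' homeostasis); a low HI signals a breakdown of regulation. With zero spread
#' the HI is reported as `Inf` and flagged `degenerate`, not an error.
#'
#' @param data A data frame.
#' @param value Column to summarize (tidy-eval).
#' @param ... Grouping columns (tidy-eval); omit to treat `data` as one group.
#' @return A tibble with the grouping columns plus `variable`, `n`, `mean`,
#'   `sd`, `cv`, `hi`, `degenerate`. Requires `n >= 2` and a nonzero mean in
#'   every group.
#' @examples
#' homeostatic_index(data.frame(x = c(2, 4, 6)), x)
#' @export
homeostatic_index <- function(data, value, ...) {
  value <- enquo(value)
  vname <- as_name(value)
  out <- data |>
    group_by(...) |>
    summarise(variable = !!vname,
              n = dplyr::n(),
              mean = base::mean({{ value }}),
              sd = stats::sd({{ value }}),
              .groups = "drop")
  if (any(out$n < 2)) {
    abort("homeostatic index needs at least 2 observations per group")
  }
  if (any(out$mean == 0)) {
    abort("homeostatic index undefined for a zero group mean")
  }
  out |>
    mutate(cv = .data$sd / .data$mean,
           hi = ifelse(.data$sd > 0, .data$mean / .data$sd, Inf),
           degenerate = .data$sd == 0)
}

#' Nutrient stress index from needle ratios
#'
#' NSI = z(C:N) + z(C:P), where the z-scores are standardized across the whole
#' reference set of needle samples (all samples in `data`, never per group).
#' More positive values indicate stronger combined N and P limitation of the
#' tissue. By construction the NSI sums to zero over the reference set.
#'
#' @param data A data frame with `c_n` and `c_p` columns (and usually
#'   `sample_id`); see [add_stoich_ratios()].
#' @return A tibble with the identifying columns of `data` plus `z_cn`,
#'   `z_cp`, `nsi`.
#' @export
nutrient_stress_index <- function(data) {
  for (cc in c("c_n", "c_p")) {
    if (!cc %in% names(data)) abort(sprintf("column %s is required", cc))
  }
  if (nrow(data) < 2) abort("NSI standardization needs at least 2 samples")
  sds <- c(c_n = stats::sd(data$c_n), c_p = stats::sd(data$c_p))
  if (any(sds == 0)) {
    abort(sprintf("zero variance in reference set for %s; z-scores undefined",
                  paste(names(sds)[sds == 0], collapse = ", ")))
  }
  as_tibble(data) |>
    mutate(z_cn = (.data$c_n - base::mean(.data$c_n)) / sds[["c_n"]],
           z_cp = (.data$c_p - base::mean(.data$c_p)) / sds[["c_p"]],
           nsi = .data$z_cn + .data$z_cp)
}

#' Nutrient resorption efficiency
#'
#' NRE = (apical - basal) / apical x 100, the percentage of a nutrient
#' withdrawn from the basal (older, senescing) needles relative to the apical
#' (mature, green) needles of the same branch. Values are always below 100%
#' for positive concentrations and may be negative when the element
#' accumulates basally (typical for carbon).
#'
#' @param c_apical,c_basal Concentrations (mg/g), recycled; `c_apical` must be
#'   strictly positive.
#' @return NRE in percent.
#' @examples
#' resorption_efficiency(24.7, 7.2)  # 70.85
#' @export
resorption_efficiency <- function(c_apical, c_basal) {
  if (any(c_apical <= 0)) abort("apical concentration must be strictly positive")
  (c_apical - c_basal) / c_apical * 100
}

#' Resorption priority index
#'
#' RPI = NRE_N / NRE_P. Values above 1 indicate preferential resorption of
#' nitrogen, below 1 of phosphorus, and values near 1 coupled withdrawal of
#' both. Undefined (NA, with a warning) when `nre_p` is zero.
#'
#' @param nre_n,nre_p Resorption efficiencies in percent, recycled.
#' @return The dimensionless RPI.
#' @seealso [rpi_label()] for the interpretation band.
#' @export
resorption_priority <- function(nre_n, nre_p) {
  out <- nre_n / nre_p
  if (any(nre_p == 0)) {
    warn("RPI undefined where NRE_P = 0; returning NA")
    out[nre_p == 0] <- NA_real_
  }
  out
}

#' Label an RPI value
#'
#' Attaches the interpretation band: `"N-priority"` when RPI > 1 + tolerance,
#' `"P-priority"` when RPI < 1 - tolerance, otherwise `"coupled"` with a
#' leaning hint (`"coupled (N-leaning)"` / `"coupled (P-leaning)"`) when the
#' value is inside the band but off 1.
#'
#' @param rpi RPI values.
#' @param tolerance Half-width of the "approximately 1" band (default 0.1).
#' @return A character vector of labels.
#' @export
rpi_label <- function(rpi, tolerance = 0.1) {
  dplyr::case_when(
    is.na(rpi) ~ NA_character_,
    rpi > 1 + tolerance ~ "N-priority",
    rpi < 1 - tolerance ~ "P-priority",
    rpi > 1 ~ "coupled (N-leaning)",
    rpi < 1 ~ "coupled (P-leaning)",
    TRUE ~ "coupled"
  )
}

#' Stoichiometric deviation index
#'
#' SDI = |needle ratio - soil ratio| / soil ratio: the relative distance of a
#' tissue ratio from the corresponding soil ratio. A large SDI means the
#' needle's stoichiometry is decoupled from the soil's nutrient balance. The
#' index is asymmetric by design — the denominator is always the soil ratio —
#' and is invariant to a common rescaling of both ratios.
#'
#' @param needle_ratio,soil_ratio Dimensionless ratios, recycled; the soil
#'   ratio must be strictly positive.
#' @return The dimensionless SDI (>= 0; 0 iff the two ratios are equal).
#' @export
stoichiometric_deviation <- function(needle_ratio, soil_ratio) {
  if (any(soil_ratio <= 0)) abort("soil ratio must be strictly positive")
  abs(needle_ratio - soil_ratio) / soil_ratio
}

#' Per-tree nutrient resorption table
#'
#' Pairs each tree's apical and basal needle composites and computes NRE for
#' N, P (and C, as a sanity column — carbon typically shows negative
#' "resorption") plus the per-tree RPI. Trees carrying only an apical sample
#' are excluded with a warning; a basal sample without an apical partner on
#' the same tree is an error.
#'
#' @param dataset A [study_dataset()] or a needle sample table.
#' @param rpi_tolerance Band half-width passed to [rpi_label()].
#' @return A tibble with one row per tree: `tree_id`, `condition`, apical and
#'   basal N/P concentrations, `nre_n`, `nre_p`, `nre_c`, `rpi`, `rpi_band`.
#' @export
pair_resorption <- function(dataset, rpi_tolerance = 0.1) {
  needles <- if (is_study_dataset(dataset)) dataset$needles else
    validate_samples(dataset, "needle")
  wide <- needles |>
    select(all_of(c("tree_id", "condition", "position", conc_columns))) |>
    tidyr::pivot_wider(names_from = "position",
                       values_from = all_of(conc_columns))
  for (col in c("c_mg_g_apical", "c_mg_g_basal", "n_mg_g_apical",
                "n_mg_g_basal", "p_mg_g_apical", "p_mg_g_basal")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  orphan_basal <- wide$tree_id[!is.na(wide$n_mg_g_basal) & is.na(wide$n_mg_g_apical)]
  if (length(orphan_basal)) {
    abort(sprintf("basal needle sample without apical partner for tree(s): %s",
                  paste(orphan_basal, collapse = ", ")))
  }
  unpaired <- wide$tree_id[is.na(wide$n_mg_g_basal)]
  if (length(unpaired)) {
    warn(sprintf("tree(s) without a basal needle sample excluded from resorption: %s",
                 paste(unpaired, collapse = ", ")))
    wide <- filter(wide, !is.na(.data$n_mg_g_basal))
  }
  wide |>
    mutate(nre_n = resorption_efficiency(.data$n_mg_g_apical, .data$n_mg_g_basal),
           nre_p = resorption_efficiency(.data$p_mg_g_apical, .data$p_mg_g_basal),
           nre_c = resorption_efficiency(.data$c_mg_g_apical, .data$c_mg_g_basal),
           rpi = resorption_priority(.data$nre_n, .data$nre_p),
           rpi_band = rpi_label(.data$rpi, rpi_tolerance)) |>
    rename(n_apical = "n_mg_g_apical", n_basal = "n_mg_g_basal",
           p_apical = "p_mg_g_apical", p_basal = "p_mg_g_basal",
           c_apical = "c_mg_g_apical", c_basal = "c_mg_g_basal") |>
    arrange(.data$condition, .data$tree_id)
}

#' Needle-vs-soil stoichiometric deviation grid
#'
#' Computes the SDI for every condition x needle position x soil layer x
#' ratio cell, under one of two conventions:
#' * `"group_mean"`: SDI of the group-mean needle ratio against the group-mean
#'   soil ratio (one number per cell);
#' * `"per_tree"`: SDI computed tree by tree (needle ratio of tree i against
#'   the soil ratio of the same tree i at that layer), then averaged.
#'
#' With zero within-group variation the two conventions coincide.
#'
#' @param dataset A [study_dataset()].
#' @param convention `"group_mean"` (default) or `"per_tree"`.
#' @return A tibble with `condition`, `position`, `soil_layer`, `ratio`
#'   (`c_n`/`c_p`/`n_p`), `needle_ratio`, `soil_ratio`, `sdi`, `n_trees`,
#'   `convention`. Under `"per_tree"` the ratio columns hold per-tree means.
#' @export
sdi_grid <- function(dataset, convention = c("group_mean", "per_tree")) {
  convention <- match.arg(convention)
  stopifnot(is_study_dataset(dataset))
  needle_long <- add_stoich_ratios(dataset$needles) |>
    select(all_of(c("tree_id", "condition", "position", ratio_levels))) |>
    tidyr::pivot_longer(all_of(ratio_levels), names_to = "ratio",
                        values_to = "needle_ratio")
  soil_long <- add_stoich_ratios(dataset$soils) |>
    select(all_of(c("tree_id", "condition", "soil_layer", ratio_levels))) |>
    tidyr::pivot_longer(all_of(ratio_levels), names_to = "ratio",
                        values_to = "soil_ratio")
  paired <- inner_join(needle_long, soil_long,
                       by = c("tree_id", "condition", "ratio"),
                       relationship = "many-to-many")
  if (convention == "group_mean") {
    out <- paired |>
      group_by(.data$condition, .data$position, .data$soil_layer, .data$ratio) |>
      summarise(n_trees = dplyr::n(),
                needle_ratio = base::mean(.data$needle_ratio),
                soil_ratio = base::mean(.data$soil_ratio),
                .groups = "drop") |>
      mutate(sdi = stoichiometric_deviation(.data$needle_ratio, .data$soil_ratio))
  } else {
    out <- paired |>
      mutate(sdi = stoichiometric_deviation(.data$needle_ratio, .data$soil_ratio)) |>
      group_by(.data$condition, .data$position, .data$soil_layer, .data$ratio) |>
      summarise(n_trees = dplyr::n(),
                needle_ratio = base::mean(.data$needle_ratio),
                soil_ratio = base::mean(.data$soil_ratio),
                sdi = base::mean(.data$sdi),
                .groups = "drop")
  }
  out |>
    mutate(convention = convention) |>
    select(all_of(c("condition", "position", "soil_layer", "ratio",
                    "needle_ratio", "soil_ratio", "sdi", "n_trees", "convention"))) |>
    arrange(.data$condition, .data$position, .data$soil_layer, .data$ratio)
}
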