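# Synthetic generator of the study design: n trees per condition, one
# apical + one basal needle composite per tree, five soil layers per tree.
#
# Two generative modes:
#   * descriptive — every sample's C/N/P drawn around its group's configured
#     mean (the four needle groups and the per-layer soil means);
#   * mechanistic — chlorotic trees start from the healthy branch pools and
#     move a fixed fraction of the basal N and P pool to the apical
#     compartment before noise, so the expected resorption efficiency is
#     known in closed form.
#
# Noise is a truncated-at-zero normal with SD = cv * mean, so variance scales
# with the mean. One root seed; each tree gets a documented child seed, so
# enlarging the design does not reshuffle the trees already generated.

#' Reference needle group means
#'
#' Published group means (mg/g dry mass) for the four needle groups of the
#' Otindag Sandy Land Scots pine chlorosis study (raw data deposit:
#' Zenodo doi:10.5281/zenodo.18136353): apical/basal x healthy/chlorotic.
#' These seed the generator defaults and the benchmark comparison.
#'
#' @return A tibble with `condition`, `position`, `c_mg_g`, `n_mg_g`,
#'   `p_mg_g`.
#' @export
needle_reference_means <- function() {
  tibble(condition = rep(condition_levels, each = 2),
         position = rep(position_levels, 2),
         c_mg_g = c(447.8, 481.8, 461.4, 472.4),
         n_mg_g = c(21.9, 12.8, 24.7, 7.2),
         p_mg_g = c(8.3, 4.3, 7.9, 1.6))
}

#' Reference soil means
#'
#' Regional mean soil organic C, total N and total P for aeolian sandy soils
#' of the Otindag Sandy Land (2.30, 0.23, 0.13 mg/g), used depth-constant as
#' the generator's default profile for both conditions. Per-layer or
#' per-condition offsets can be expressed by editing the returned table.
#'
#' @return A tibble with `condition`, `soil_layer`, `c_mg_g`, `n_mg_g`,
#'   `p_mg_g` (2 x 5 rows).
#' @export
soil_reference_means <- function() {
  tidyr::expand_grid(condition = condition_levels,
                     soil_layer = soil_layer_levels) |>
    mutate(c_mg_g = 2.30, n_mg_g = 0.23, p_mg_g = 0.13)
}

#' Generator configuration
#'
#' Bundles and validates every knob of the synthetic study generator.
#'
#' @param n_trees_per_condition Trees per condition (>= 2; the study design
#'   used 3).
#' @param needle_means Needle group means, a tibble as
#'   [needle_reference_means()].
#' @param needle_cv Within-group coefficient of variation of needle
#'   concentrations (default 0.10).
#' @param soil_means Soil means per condition x layer, as
#'   [soil_reference_means()].
#' @param soil_cv Within-group CV of soil concentrations (default 0.15).
#' @param reallocation_fraction_n,reallocation_fraction_p Fraction of the
#'   basal N (resp. P) pool moved apically in chlorotic trees under the
#'   mechanistic mode; in [0, 1). Defaults (0.39, 0.51) reproduce the
#'   reference study's chlorotic resorption efficiencies from its healthy
#'   pools.
#' @param mode `"descriptive"` or `"mechanistic"`.
#' @param seed Root random seed (integer).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_trees_per_condition = 3,
                             needle_means = needle_reference_means(),
                             needle_cv = 0.10,
                             soil_means = soil_reference_means(),
                             soil_cv = 0.15,
                             reallocation_fraction_n = 0.39,
                             reallocation_fraction_p = 0.51,
                             mode = c("descriptive", "mechanistic"),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (n_trees_per_condition < 2) abort("n_trees_per_condition must be >= 2")
  if (n_trees_per_condition > 400000) abort("n_trees_per_condition too large for the seed scheme")
  needle_means <- as_tibble(needle_means)
  soil_means <- as_tibble(soil_means)
  for (tab in list(needle_means, soil_means)) {
    if (any(as.matrix(tab[conc_columns]) <= 0)) abort("all configured means must be > 0")
  }
  if (nrow(needle_means) != 4 ||
      nrow(dplyr::distinct(needle_means[c("condition", "position")])) != 4) {
    abort("needle_means must cover the 4 condition x position groups")
  }
  if (nrow(soil_means) != 10 ||
      nrow(dplyr::distinct(soil_means[c("condition", "soil_layer")])) != 10) {
    abort("soil_means must cover the 2 x 5 condition x layer cells")
  }
  if (needle_cv < 0 || soil_cv < 0) abort("cv values must be >= 0")
  for (f in c(reallocation_fraction_n, reallocation_fraction_p)) {
    if (f < 0 || f >= 1) abort("reallocation fractions must lie in [0, 1)")
  }
  structure(list(n_trees_per_condition = as.integer(n_trees_per_condition),
                 needle_means = needle_means, needle_cv = needle_cv,
                 soil_means = soil_means, soil_cv = soil_cv,
                 reallocation_fraction_n = reallocation_fraction_n,
                 reallocation_fraction_p = reallocation_fraction_p,
                 mode = mode, seed = as.integer(seed)),
            class = "generator_config")
}

# Child seed per tree: healthy trees occupy one block of the derived stream
# space, chlorotic trees another, so growing one condition never reshuffles
# the other. Root seeds are folded below 1e6 to keep every child < 2^31.
tree_seed <- function(root_seed, condition, index) {
  offset <- if (condition == "healthy") 0L else 500000L
  (abs(root_seed) %% 1000000L) * 1000L + offset + index
}

# normal truncated to the data model's concentration range (0, 1000) mg/g,
# via rejection; exact at cv = 0
rtruncnorm_pos <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- mean
  todo <- sd > 0
  if (any(todo)) out[todo] <- rnorm(sum(todo), mean[todo], sd[todo])
  for (it in 1:1000) {
    bad <- out <= 0 | out >= 1000
    if (!any(bad)) return(out)
    out[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
  }
  abort("truncated sampling failed to produce in-range values")
}

#' Expected group means implied by a configuration (noise-free)
#'
#' Under the descriptive mode these are the configured needle means. Under
#' the mechanistic mode the chlorotic groups are derived from the healthy
#' pools: apical = healthy apical + f x healthy basal, basal = (1 - f) x
#' healthy basal for N and P (C pools are not reallocated).
#'
#' @param config A [generator_config()].
#' @return A tibble like [needle_reference_means()].
#' @export
expected_needle_means <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  means <- config$needle_means
  if (config$mode == "descriptive") return(means)
  h_api <- filter(means, .data$condition == "healthy", .data$position == "apical")
  h_bas <- filter(means, .data$condition == "healthy", .data$position == "basal")
  fn <- config$reallocation_fraction_n
  fp <- config$reallocation_fraction_p
  means |>
    mutate(n_mg_g = dplyr::case_when(
             .data$condition == "chlorotic" & .data$position == "apical" ~
               h_api$n_mg_g + fn * h_bas$n_mg_g,
             .data$condition == "chlorotic" & .data$position == "basal" ~
               (1 - fn) * h_bas$n_mg_g,
             TRUE ~ .data$n_mg_g),
           p_mg_g = dplyr::case_when(
             .data$condition == "chlorotic" & .data$position == "apical" ~
               h_api$p_mg_g + fp * h_bas$p_mg_g,
             .data$condition == "chlorotic" & .data$position == "basal" ~
               (1 - fp) * h_bas$p_mg_g,
             TRUE ~ .data$p_mg_g),
           c_mg_g = dplyr::case_when(
             .data$condition == "chlorotic" & .data$position == "apical" ~ h_api$c_mg_g,
             .data$condition == "chlorotic" & .data$position == "basal" ~ h_bas$c_mg_g,
             TRUE ~ .data$c_mg_g))
}

#' Generate a synthetic study dataset
#'
#' Draws a full study design — `n_trees_per_condition` trees per condition,
#' one apical and one basal needle composite per tree, five soil layers per
#' tree — around the configured means with CV-scaled truncated-normal noise.
#' Deterministic given the root seed: the same configuration yields the same
#' dataset field for field, and adding trees leaves existing trees unchanged.
#'
#' @param config A [generator_config()].
#' @return A [study_dataset()] with provenance recording mode and seed.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  means <- expected_needle_means(config)
  n_tree <- config$n_trees_per_condition
  # per-tree draw order is fixed and documented: apical (C, N, P), basal
  # (C, N, P), then the five soil layers shallow to deep (C, N, P each)
  needle_mu <- lapply(condition_levels, function(cond) {
    cm <- filter(means, .data$condition == cond)
    unlist(lapply(position_levels, function(pos)
      as.numeric(cm[cm$position == pos, conc_columns][1, ])))
  })
  names(needle_mu) <- condition_levels
  soil_mu <- lapply(condition_levels, function(cond) {
    cm <- filter(config$soil_means, .data$condition == cond)
    unlist(lapply(soil_layer_levels, function(layer)
      as.numeric(cm[cm$soil_layer == layer, conc_columns][1, ])))
  })
  names(soil_mu) <- condition_levels
  needle_draws <- matrix(0, nrow = 2 * n_tree, ncol = 6)
  soil_draws <- matrix(0, nrow = 2 * n_tree, ncol = 15)
  trees <- character(2 * n_tree)
  conds <- character(2 * n_tree)
  row <- 0L
  for (cond in condition_levels) {
    prefix <- if (cond == "healthy") "H" else "C"
    for (i in seq_len(n_tree)) {
      set.seed(tree_seed(config$seed, cond, i))
      row <- row + 1L
      trees[row] <- paste0(prefix, i)
      conds[row] <- cond
      needle_draws[row, ] <- rtruncnorm_pos(6, needle_mu[[cond]],
                                            config$needle_cv * needle_mu[[cond]])
      soil_draws[row, ] <- rtruncnorm_pos(15, soil_mu[[cond]],
                                          config$soil_cv * soil_mu[[cond]])
    }
  }
  needles <- tibble(
    sample_id = paste0(rep(trees, each = 2), "-",
                       substr(rep(position_levels, 2 * n_tree), 1, 3)),
    tree_id = rep(trees, each = 2),
    condition = rep(conds, each = 2),
    position = rep(position_levels, 2 * n_tree),
    c_mg_g = as.vector(t(needle_draws[, c(1, 4)])),
    n_mg_g = as.vector(t(needle_draws[, c(2, 5)])),
    p_mg_g = as.vector(t(needle_draws[, c(3, 6)])))
  soils <- tibble(
    sample_id = paste0(rep(trees, each = 5), "-s",
                       rep(soil_layer_levels, 2 * n_tree)),
    tree_id = rep(trees, each = 5),
    condition = rep(conds, each = 5),
    soil_layer = rep(soil_layer_levels, 2 * n_tree),
    c_mg_g = as.vector(t(soil_draws[, c(1, 4, 7, 10, 13)])),
    n_mg_g = as.vector(t(soil_draws[, c(2, 5, 8, 11, 14)])),
    p_mg_g = as.vector(t(soil_draws[, c(3, 6, 9, 12, 15)])))
  study_dataset(needles, soils,
                provenance = sprintf("generate_study(mode=%s, seed=%d, n=%d)",
                                     config$mode, config$seed,
                                     config$n_trees_per_condition))
}

#' Closed-form ground truth for a generator configuration
#'
#' The noise-free expected values of every index implied by the configured
#' means: per-condition NRE for N and P, RPI, group-mean stoichiometric
#' ratios for needles and soils, and the SDI of every condition x position x
#' layer x ratio cell. Used to validate the pipeline by parameter recovery.
#'
#' @param config A [generator_config()].
#' @return A list with `needle_means`, `needle_ratios`, `soil_ratios`,
#'   `resorption` (per condition: `nre_n`, `nre_p`, `rpi`), and `sdi`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  means <- expected_needle_means(config)
  needle_ratios <- dplyr::bind_cols(
    means[c("condition", "position")],
    compute_ratios(means$c_mg_g, means$n_mg_g, means$p_mg_g))
  soil_ratios <- dplyr::bind_cols(
    config$soil_means[c("condition", "soil_layer")],
    compute_ratios(config$soil_means$c_mg_g, config$soil_means$n_mg_g,
                   config$soil_means$p_mg_g))
  wide <- means |>
    tidyr::pivot_longer(all_of(conc_columns), names_to = "element") |>
    tidyr::pivot_wider(names_from = c("element", "position"),
                       values_from = "value")
  resorption <- wide |>
    mutate(nre_n = resorption_efficiency(.data$n_mg_g_apical, .data$n_mg_g_basal),
           nre_p = resorption_efficiency(.data$p_mg_g_apical, .data$p_mg_g_basal),
           rpi = resorption_priority(.data$nre_n, .data$nre_p)) |>
    select(all_of(c("condition", "nre_n", "nre_p", "rpi")))
  sdi <- inner_join(
    tidyr::pivot_longer(needle_ratios, all_of(ratio_levels),
                        names_to = "ratio", values_to = "needle_ratio"),
    tidyr::pivot_longer(soil_ratios, all_of(ratio_levels),
                        names_to = "ratio", values_to = "soil_ratio"),
    by = c("condition", "ratio"), relationship = "many-to-many") |>
    mutate(sdi = stoichiometric_deviation(.data$needle_ratio, .data$soil_ratio)) |>
    select(all_of(c("condition", "position", "soil_layer", "ratio", "sdi")))
  list(needle_means = means, needle_ratios = needle_ratios,
       soil_ratios = soil_ratios, resorption = resorption, sdi = sdi)
}
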