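# Inferential chain: Levene's gate, classical/Welch ANOVA, Tukey HSD,
# Games-Howell pairwise comparisons, compact letter displays, Welch t-test,
# needle-soil Pearson correlation grid, PCA of needle ratios.
#
# All tests two-sided; significance level alpha = 0.05 unless overridden.
# Standard tests are delegated to base R / car; the Games-Howell pairwise
# procedure and the insert-and-absorb letter display are implemented here.

split_groups <- function(data, value, group) {
  v <- rlang::eval_tidy(enquo(value), data)
  g <- rlang::eval_tidy(enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  split(v[keep], droplevels(factor(g[keep])))
}

check_group_sizes <- function(groups, min_n = 2, min_k = 2) {
  if (length(groups) < min_k) {
    abort(sprintf("need at least %d groups, got %d", min_k, length(groups)))
  }
  small <- names(groups)[lengths(groups) < min_n]
  if (length(small)) {
    abort(sprintf("group(s) with fewer than %d observations: %s",
                  min_n, paste(small, collapse = ", ")))
  }
  invisible(groups)
}

#' Levene's test for homogeneity of variances
#'
#' Mean-centred Levene test (an ANOVA on absolute deviations from the group
#' means), the gate of [gated_group_comparison()]. The degenerate case where
#' the absolute deviations show no between-group spread is reported as
#' statistic 0 with p = 1.
#'
#' @param data A data frame.
#' @param value Numeric response column (tidy-eval).
#' @param group Grouping column (tidy-eval); each group needs `n >= 2`.
#' @return A one-row tibble: `method`, `statistic`, `df1`, `df2`, `p_value`.
#' @export
levene_test <- function(data, value, group) {
  groups <- check_group_sizes(split_groups(data, {{ value }}, {{ group }}))
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  lt <- car::leveneTest(v, g, center = base::mean)
  statistic <- lt$`F value`[1]
  p <- lt$`Pr(>F)`[1]
  # between-group spread of |x - group mean| can vanish (e.g. mirror-image
  # groups): report "no evidence of heterogeneity" rather than NaN
  if (!is.finite(statistic)) {
    absdev <- unlist(lapply(groups, function(x) abs(x - base::mean(x))))
    if (stats::var(tapply(absdev, g, base::mean)) < .Machine$double.eps) {
      statistic <- 0
      p <- 1
    }
  }
  tibble(method = "Levene (mean-centred)", statistic = statistic,
         df1 = lt$Df[1], df2 = lt$Df[2], p_value = p)
}

#' One-way ANOVA (classical and Welch)
#'
#' `oneway_anova()` is the classical equal-variance F test with
#' `(k - 1, N - k)` degrees of freedom; `welch_anova()` is Welch's
#' heteroscedasticity-robust variant with Satterthwaite-type denominator df.
#' For two groups with equal sample variances and sizes the two statistics
#' coincide exactly; with more groups Welch's small-sample correction shrinks
#' the statistic slightly even under perfect balance.
#'
#' @inheritParams levene_test
#' @return A one-row tibble: `method`, `statistic`, `df1`, `df2`, `p_value`.
#' @export
oneway_anova <- function(data, value, group) {
  groups <- check_group_sizes(split_groups(data, {{ value }}, {{ group }}))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    abort("zero within-group variance in every group: F undefined")
  }
  ow <- stats::oneway.test(v ~ g, data = stack_groups(groups), var.equal = TRUE)
  tibble(method = "one-way ANOVA", statistic = unname(ow$statistic),
         df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
         p_value = unname(ow$p.value))
}

#' @rdname oneway_anova
#' @export
welch_anova <- function(data, value, group) {
  groups <- check_group_sizes(split_groups(data, {{ value }}, {{ group }}))
  if (any(vapply(groups, stats::var, numeric(1)) == 0)) {
    abort("zero within-group variance: Welch F undefined")
  }
  ow <- stats::oneway.test(v ~ g, data = stack_groups(groups), var.equal = FALSE)
  tibble(method = "Welch ANOVA", statistic = unname(ow$statistic),
         df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
         p_value = unname(ow$p.value))
}

stack_groups <- function(groups) {
  data.frame(v = unlist(groups, use.names = FALSE),
             g = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons after a classical ANOVA, with p-values from the
#' studentized-range distribution.
#'
#' @inheritParams levene_test
#' @param conf_level Confidence level for the interval columns.
#' @return A tibble with one row per pair: `group1`, `group2`, `estimate`
#'   (mean of `group2` minus mean of `group1`), `conf_low`, `conf_high`,
#'   `p_value`.
#' @export
tukey_hsd <- function(data, value, group, conf_level = 0.95) {
  groups <- check_group_sizes(split_groups(data, {{ value }}, {{ group }}))
  fit <- stats::aov(v ~ g, data = stack_groups(groups))
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble(group1 = vapply(pairs, `[`, "", 2),
         group2 = vapply(pairs, `[`, "", 1),
         estimate = unname(tk[, "diff"]),
         conf_low = unname(tk[, "lwr"]),
         conf_high = unname(tk[, "upr"]),
         p_value = unname(tk[, "p adj"]))
}

#' Games-Howell pairwise comparisons
#'
#' Pairwise Welch-type comparisons for heteroscedastic groups: each pair gets
#' a Welch t statistic with Satterthwaite df, referred to the studentized
#' range distribution over all k groups (q = |t| * sqrt(2)). This is the
#' post-hoc companion of [welch_anova()] so that compact letter displays can
#' be produced on either route of [gated_group_comparison()].
#'
#' @inheritParams levene_test
#' @return A tibble with one row per pair: `group1`, `group2`, `estimate`,
#'   `statistic` (the pair's Welch t), `df`, `p_value`.
#' @export
games_howell <- function(data, value, group) {
  groups <- check_group_sizes(split_groups(data, {{ value }}, {{ group }}))
  k <- length(groups)
  nm <- names(groups)
  m <- vapply(groups, base::mean, numeric(1))
  s2 <- vapply(groups, stats::var, numeric(1))
  n <- lengths(groups)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se2 <- s2[i] / n[i] + s2[j] / n[j]
      if (se2 == 0) {
        abort(sprintf("zero variance in pair %s-%s: comparison undefined", nm[i], nm[j]))
      }
      tstat <- (m[j] - m[i]) / sqrt(se2)
      df <- se2^2 / ((s2[i] / n[i])^2 / (n[i] - 1) + (s2[j] / n[j])^2 / (n[j] - 1))
      p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
      out[[length(out) + 1]] <- tibble(group1 = nm[i], group2 = nm[j],
                                       estimate = unname(m[j] - m[i]),
                                       statistic = unname(tstat),
                                       df = unname(df), p_value = unname(p))
    }
  }
  bind_rows(out)
}

#' Welch two-sample t-test
#'
#' Two-sided Welch t with Satterthwaite df, used for healthy-vs-chlorotic
#' contrasts of per-tree indices (RPI, NRE). If both groups are constant with
#' equal means the statistic is undefined and returned as NA with a note.
#'
#' @param x,y Numeric vectors, each of length >= 2. Alternatively pass a data
#'   frame as `x` together with `value` and `group` columns.
#' @param value,group Tidy-eval columns when `x` is a data frame; `group` must
#'   have exactly two levels.
#' @return A one-row tibble: `method`, `group1`, `group2`, `estimate`
#'   (mean difference `group1 - group2`), `statistic`, `df`, `p_value`,
#'   `note`.
#' @export
welch_t_test <- function(x, y = NULL, value = NULL, group = NULL) {
  if (is.data.frame(x)) {
    groups <- check_group_sizes(split_groups(x, {{ value }}, {{ group }}))
    if (length(groups) != 2) abort("welch_t_test needs exactly two groups")
    nm <- names(groups)
    y <- groups[[2]]
    x <- groups[[1]]
  } else {
    nm <- c("x", "y")
    if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (base::mean(x) == base::mean(y)) {
      return(tibble(method = "Welch t-test", group1 = nm[1], group2 = nm[2],
                    estimate = 0, statistic = NA_real_, df = NA_real_,
                    p_value = NA_real_, note = "degenerate: both groups constant and equal"))
    }
    return(tibble(method = "Welch t-test", group1 = nm[1], group2 = nm[2],
                  estimate = base::mean(x) - base::mean(y), statistic = Inf * sign(base::mean(x) - base::mean(y)),
                  df = NA_real_, p_value = 0, note = "degenerate: both groups constant"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble(method = "Welch t-test", group1 = nm[1], group2 = nm[2],
         estimate = base::mean(x) - base::mean(y),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = unname(tt$p.value), note = NA_character_)
}

# ---- compact letter display --------------------------------------------

pairwise_to_matrix <- function(pairwise) {
  if (is.matrix(pairwise)) {
    if (nrow(pairwise) != ncol(pairwise)) abort("pairwise p matrix must be square")
    if (is.null(rownames(pairwise))) {
      rownames(pairwise) <- colnames(pairwise) <- paste0("g", seq_len(nrow(pairwise)))
    }
    if (!isTRUE(all.equal(pairwise, t(pairwise), tolerance = 1e-12, check.attributes = FALSE))) {
      abort("pairwise p matrix must be symmetric")
    }
    return(pairwise)
  }
  needed <- c("group1", "group2", "p_value")
  if (!all(needed %in% names(pairwise))) {
    abort("pairwise table must have columns group1, group2, p_value")
  }
  nm <- unique(c(pairwise$group1, pairwise$group2))
  m <- matrix(1, length(nm), length(nm), dimnames = list(nm, nm))
  for (r in seq_len(nrow(pairwise))) {
    m[pairwise$group1[r], pairwise$group2[r]] <- pairwise$p_value[r]
    m[pairwise$group2[r], pairwise$group1[r]] <- pairwise$p_value[r]
  }
  m
}

#' Compact letter display from a pairwise significance matrix
#'
#' Implements the insert-and-absorb construction: start with all groups under
#' one letter; for every significant pair split each letter column containing
#' both members into two (one without each member); absorb columns that
#' became subsets of others. The result satisfies the display contract —
#' two groups share at least one letter if and only if their pairwise
#' comparison is not significant at `alpha` — and uses a minimal number of
#' letters on the group counts that occur in this design (an exact reduction
#' over the cliques of the non-significance graph is applied for up to 10
#' groups).
#'
#' @param pairwise Either a symmetric matrix of pairwise p-values (unit
#'   diagonal, treated as non-significant) or a tibble with `group1`,
#'   `group2`, `p_value` (as returned by [tukey_hsd()] / [games_howell()]).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `group` and `letters`, groups in input order.
#' @export
compact_letter_display <- function(pairwise, alpha = 0.05) {
  m <- pairwise_to_matrix(pairwise)
  nm <- rownames(m)
  k <- length(nm)
  sig <- which(m < alpha & upper.tri(m), arr.ind = TRUE)

  # insert-and-absorb over letter columns (sets of group indices)
  cols <- list(seq_len(k))
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      i <- sig[r, 1]; j <- sig[r, 2]
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      cols <- absorb_columns(new_cols)
    }
  }
  if (k <= 10) cols <- minimise_columns(cols, m < alpha)
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  letters_by_group <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
           collapse = "")
  }, "")
  tibble(group = nm, letters = letters_by_group)
}

absorb_columns <- function(cols) {
  cols <- unique(lapply(cols, sort))
  keep <- rep(TRUE, length(cols))
  for (a in seq_along(cols)) {
    for (b in seq_along(cols)) {
      if (a != b && keep[b] && keep[a] && all(cols[[a]] %in% cols[[b]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  cols[keep]
}

# Exact minimisation: enumerate maximal cliques of the non-significance graph
# (Bron-Kerbosch) and find the smallest subset covering every non-significant
# pair and every group. Feasible for the small group counts of this design.
minimise_columns <- function(cols, sig_mat) {
  k <- nrow(sig_mat)
  adj <- !sig_mat
  diag(adj) <- TRUE
  cliques <- bron_kerbosch(adj)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  covers <- function(subset) {
    if (nrow(edges)) {
      for (r in seq_len(nrow(edges))) {
        if (!any(vapply(subset, function(cl)
          edges[r, 1] %in% cl && edges[r, 2] %in% cl, logical(1)))) return(FALSE)
      }
    }
    all(seq_len(k) %in% unlist(subset))
  }
  nmax <- length(cols)
  for (size in seq_len(min(nmax - 1, length(cliques)))) {
    if (choose(length(cliques), size) > 50000) break
    combos <- utils::combn(length(cliques), size, simplify = FALSE)
    for (cb in combos) {
      if (covers(cliques[cb])) return(cliques[cb])
    }
  }
  cols
}

bron_kerbosch <- function(adj) {
  k <- nrow(adj)
  cliques <- list()
  recurse <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      cliques[[length(cliques) + 1]] <<- sort(r)
      return()
    }
    pivot_pool <- c(p, x)
    pivot <- pivot_pool[which.max(vapply(pivot_pool, function(u) sum(adj[u, p]), numeric(1)))]
    for (v in setdiff(p, which(adj[pivot, ]))) {
      nb <- which(adj[v, ] & seq_len(k) != v)
      recurse(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  recurse(integer(), seq_len(k), integer())
  cliques
}

#' Variance-gated group comparison
#'
#' The field's standard decision rule for comparing group means: Levene's
#' test (mean-centred) decides the route at level `alpha`. Homogeneous
#' variances (`p >= alpha`) lead to classical one-way ANOVA with Tukey HSD
#' pairwise comparisons; heterogeneous variances to Welch's ANOVA with
#' Games-Howell pairwise comparisons. Either way a compact letter display is
#' built from the pairwise significance matrix.
#'
#' @inheritParams levene_test
#' @param alpha Significance level for the gate, the pairwise tests and the
#'   letters (default 0.05).
#' @return An object of class `gated_comparison`: a list with `levene`,
#'   `route` (`"anova_tukey"` or `"welch_games_howell"`), `omnibus`,
#'   `pairwise`, `letters`, `alpha`, `group_sizes`. [tidy()] returns the
#'   pairwise table, [glance()] a one-row summary, [autoplot()] an annotated
#'   jitter plot.
#' @export
gated_group_comparison <- function(data, value, group, alpha = 0.05) {
  lev <- levene_test(data, {{ value }}, {{ group }})
  groups <- split_groups(data, {{ value }}, {{ group }})
  if (lev$p_value >= alpha) {
    route <- "anova_tukey"
    omnibus <- oneway_anova(data, {{ value }}, {{ group }})
    pairwise <- tukey_hsd(data, {{ value }}, {{ group }})
  } else {
    route <- "welch_games_howell"
    omnibus <- welch_anova(data, {{ value }}, {{ group }})
    pairwise <- games_howell(data, {{ value }}, {{ group }})
  }
  structure(list(levene = lev, route = route, omnibus = omnibus,
                 pairwise = pairwise,
                 letters = compact_letter_display(pairwise, alpha),
                 alpha = alpha,
                 group_sizes = tibble(group = names(groups), n = lengths(groups)),
                 group_means = tibble(group = names(groups),
                                      mean = vapply(groups, base::mean, numeric(1)))),
            class = "gated_comparison")
}

#' @export
print.gated_comparison <- function(x, ...) {
  cat("<gated_comparison>\n")
  cat(sprintf("  Levene p = %.4g -> route: %s\n", x$levene$p_value, x$route))
  cat(sprintf("  omnibus %s: F = %.4g, df = (%.3g, %.3g), p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$df1,
              x$omnibus$df2, x$omnibus$p_value))
  cat("  letters:", paste(sprintf("%s=%s", x$letters$group, x$letters$letters),
                          collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gated_comparison <- function(x, ...) {
  left_join(x$pairwise,
            tibble(group1 = x$letters$group, letters1 = x$letters$letters),
            by = "group1") |>
    left_join(tibble(group2 = x$letters$group, letters2 = x$letters$letters),
              by = "group2")
}

#' @exportS3Method generics::glance
glance.gated_comparison <- function(x, ...) {
  tibble(route = x$route, levene_p = x$levene$p_value,
         statistic = x$omnibus$statistic, df1 = x$omnibus$df1,
         df2 = x$omnibus$df2, p_value = x$omnibus$p_value,
         n_groups = nrow(x$letters), alpha = x$alpha)
}

#' Needle-soil Pearson correlation grid
#'
#' For every needle group (condition x position), soil depth layer and
#' stoichiometric ratio, correlates the needle ratio with the soil ratio of
#' the same trees (Pearson r, two-sided p). Cells with fewer than 3 trees are
#' flagged `"insufficient"`; zero-variance cells `"degenerate"`; cells at the
#' minimal design size (n = 3) are stamped `"low-power"`. A
#' Benjamini-Hochberg adjusted column over the whole grid is appended as a
#' labelled extension; the primary `p_value` column is unadjusted.
#'
#' @param dataset A [study_dataset()].
#' @return A tibble with `condition`, `position`, `soil_layer`, `ratio`, `n`,
#'   `r`, `p_value`, `p_adj_bh`, `flag`.
#' @export
needle_soil_correlation <- function(dataset) {
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
  grid <- paired |>
    group_by(.data$condition, .data$position, .data$soil_layer, .data$ratio) |>
    summarise(n = dplyr::n(),
              r = {
                if (dplyr::n() < 3 || stats::sd(.data$needle_ratio) == 0 ||
                    stats::sd(.data$soil_ratio) == 0) NA_real_
                else stats::cor(.data$needle_ratio, .data$soil_ratio)
              },
              p_value = {
                if (dplyr::n() < 3 || stats::sd(.data$needle_ratio) == 0 ||
                    stats::sd(.data$soil_ratio) == 0 ||
                    abs(stats::cor(.data$needle_ratio, .data$soil_ratio)) >= 1)
                  NA_real_
                else stats::cor.test(.data$needle_ratio, .data$soil_ratio)$p.value
              },
              degenerate = stats::sd(.data$needle_ratio) == 0 ||
                stats::sd(.data$soil_ratio) == 0,
              .groups = "drop")
  grid |>
    mutate(p_adj_bh = p.adjust(.data$p_value, method = "BH"),
           flag = dplyr::case_when(
             n < 3 ~ "insufficient",
             degenerate ~ "degenerate",
             n == 3 ~ "low-power",
             TRUE ~ "ok")) |>
    select(-"degenerate") |>
    arrange(.data$condition, .data$position, .data$soil_layer, .data$ratio)
}

#' PCA of standardized needle stoichiometric ratios
#'
#' Principal component analysis of the three needle ratios (C:N, C:P, N:P),
#' each column centred and scaled to unit sample variance (n - 1), i.e. a
#' decomposition of the correlation structure. Loading signs are fixed so
#' that each component's largest-magnitude loading is positive. Explained
#' variance fractions over all three components sum to 1.
#'
#' @param data A data frame with columns `c_n`, `c_p`, `n_p` (>= 3 rows) and
#'   optionally `sample_id` and grouping columns, which are carried into the
#'   scores table.
#' @return An object of class `ratio_pca` with elements `scores` (tibble),
#'   `loadings` (tibble), `explained` (fraction per component), `center`,
#'   `scale`, and the underlying `prcomp` fit. [tidy()] returns the loadings,
#'   [glance()] the explained fractions, [autoplot()] a biplot.
#' @export
pca_ratios <- function(data) {
  for (cc in ratio_levels) {
    if (!cc %in% names(data)) abort(sprintf("column %s is required", cc))
  }
  if (nrow(data) < 3) abort("PCA needs at least 3 samples")
  x <- as.matrix(as_tibble(data)[ratio_levels])
  degenerate <- ratio_levels[apply(x, 2, stats::sd) == 0]
  if (length(degenerate)) {
    abort(sprintf("zero variance in ratio column(s): %s",
                  paste(degenerate, collapse = ", ")))
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # deterministic sign convention: dominant loading of each PC positive
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  fit$rotation <- sweep(fit$rotation, 2, flip, `*`)
  fit$x <- sweep(fit$x, 2, flip, `*`)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  meta_cols <- intersect(c("sample_id", "tree_id", "condition", "position"),
                         names(data))
  scores <- dplyr::bind_cols(as_tibble(data)[meta_cols], as_tibble(fit$x))
  loadings <- as_tibble(fit$rotation) |>
    mutate(ratio = rownames(fit$rotation), .before = 1)
  structure(list(scores = scores, loadings = loadings, explained = explained,
                 center = fit$center, scale = fit$scale, fit = fit),
            class = "ratio_pca")
}

#' @export
print.ratio_pca <- function(x, ...) {
  cat("<ratio_pca>\n")
  cat(sprintf("  %d samples, explained variance: %s\n", nrow(x$scores),
              paste(sprintf("PC%d %.1f%%", seq_along(x$explained),
                            100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ratio_pca <- function(x, ...) x$loadings

#' @exportS3Method generics::glance
glance.ratio_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$explained)),
         explained_fraction = x$explained)
}
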