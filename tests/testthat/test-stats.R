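# Inferential chain: hand-checked statistics, algebraic identities,
# Monte-Carlo oracles and the compact-letter-display contract.

stack2 <- function(...) {
  gs <- list(...)
  data.frame(v = unlist(gs),
             g = rep(paste0("g", seq_along(gs)), lengths(gs)))
}

test_that("Levene statistic is zero for mirror-image deviation groups", {
  lev <- levene_test(stack2(c(1, 3, 5), c(2, 4, 6)), v, g)
  expect_equal(lev$statistic, 0, tolerance = 1e-12)
  expect_equal(lev$p_value, 1)
  expect_equal(lev$df1, 1)
  expect_equal(lev$df2, 4)
})

test_that("Levene handles constant groups and rejects tiny groups", {
  lev <- levene_test(stack2(c(2, 2, 2), c(5, 5, 5)), v, g)
  expect_equal(lev$statistic, 0)
  expect_equal(lev$p_value, 1)
  expect_error(levene_test(stack2(c(1, 2), 3), v, g), "fewer than 2")
})

test_that("Levene type-I error is near alpha under a homoscedastic null", {
  set.seed(2026)
  reject <- replicate(1000, {
    d <- data.frame(v = rnorm(40), g = rep(letters[1:4], each = 10))
    levene_test(d, v, g)$p_value < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("classical ANOVA reproduces hand sums of squares", {
  an <- oneway_anova(stack2(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)), v, g)
  expect_equal(an$statistic, 3)        # SSB = 6 on 2 df, SSW = 6 on 6 df
  expect_equal(c(an$df1, an$df2), c(2, 6))
  expect_error(oneway_anova(stack2(c(1, 1), c(2, 2)), v, g), "zero within-group")
})

test_that("ANOVA F on two groups equals the squared pooled t", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(6, 1)
    f <- oneway_anova(stack2(x, y), v, g)$statistic
    t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic)^2
    expect_equal(f, t2, tolerance = 1e-10)
  }
})

test_that("Welch F equals classical F for two balanced equal-variance groups", {
  # exact identity at k = 2 (Welch's correction term vanishes); for k > 2 the
  # correction shrinks the Welch statistic even under perfect balance
  base <- c(-1, 0, 1, 2)
  d <- stack2(base + 1, base + 3)
  expect_equal(welch_anova(d, v, g)$statistic,
               oneway_anova(d, v, g)$statistic, tolerance = 1e-12)
  d3 <- stack2(base + 1, base + 3, base + 4)
  expect_lt(welch_anova(d3, v, g)$statistic,
            oneway_anova(d3, v, g)$statistic)
})

test_that("parametric ANOVA p agrees with a permutation oracle at small n", {
  set.seed(31)
  d <- data.frame(v = rnorm(12), g = rep(letters[1:3], each = 4))
  f_obs <- oneway_anova(d, v, g)$statistic
  p_par <- oneway_anova(d, v, g)$p_value
  perm <- replicate(10000, {
    d$g <- sample(d$g)
    oneway_anova(d, v, g)$statistic
  })
  p_perm <- mean(perm >= f_obs)
  expect_lt(abs(p_perm - p_par), 0.02)
})

test_that("Welch t-test matches hand computation and is antisymmetric", {
  tt <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)

  a <- welch_t_test(c(1, 2, 5), c(2, 4, 9))
  b <- welch_t_test(c(2, 4, 9), c(1, 2, 5))
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)

  flat <- welch_t_test(c(2, 2), c(2, 2))
  expect_true(is.na(flat$statistic))
  expect_match(flat$note, "degenerate")
})

test_that("Games-Howell agrees with Tukey under homoscedastic balance", {
  set.seed(8)
  d <- data.frame(v = rnorm(30, rep(c(0, 0.5, 3), each = 10)),
                  g = rep(letters[1:3], each = 10))
  gh <- games_howell(d, v, g)
  tk <- tukey_hsd(d, v, g)
  expect_equal(gh$estimate, tk$estimate, tolerance = 1e-10)
  # same ordering and close p-values when variances are equal
  expect_equal(order(gh$p_value), order(tk$p_value))
  expect_lt(max(abs(gh$p_value - tk$p_value)), 0.05)
})

test_that("compact letters reproduce the canonical small cases", {
  no_sig <- matrix(1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_equal(compact_letter_display(no_sig)$letters, c("a", "a", "a"))

  all_sig <- matrix(0.001, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(all_sig) <- 1
  expect_equal(compact_letter_display(all_sig)$letters, c("a", "b", "c"))

  # only A vs C significant -> A "a", B "ab", C "b"
  chain <- matrix(1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  chain["A", "C"] <- chain["C", "A"] <- 0.01
  expect_equal(compact_letter_display(chain)$letters, c("a", "ab", "b"))

  lopsided <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  lopsided[4, 1:3] <- lopsided[1:3, 4] <- 0.001
  expect_equal(compact_letter_display(lopsided)$letters, c("a", "a", "a", "b"))

  asym <- chain
  asym["A", "C"] <- 0.2
  expect_error(compact_letter_display(asym), "symmetric")
})

test_that("letter display satisfies its contract and minimality vs oracle", {
  set.seed(314)
  for (k in c(3, 4, 5, 6)) {
    for (rep in 1:25) {
      m <- random_p_matrix(k)
      alpha <- sample(c(0.05, 0.3, 0.6), 1)
      cld <- compact_letter_display(m, alpha = alpha)
      expect_true(cld_contract_holds(cld, m, alpha),
                  info = sprintf("contract k=%d rep=%d", k, rep))
      n_letters <- length(unique(unlist(strsplit(cld$letters, ""))))
      expect_equal(n_letters, cld_oracle_min_letters(m, alpha),
                   info = sprintf("minimality k=%d rep=%d", k, rep))
    }
  }
})

test_that("the variance gate routes by Levene and letters separate the odd group", {
  set.seed(404)
  homo <- data.frame(v = rnorm(40, rep(c(0, 0, 0, 2), each = 10)),
                     g = rep(LETTERS[1:4], each = 10))
  res <- gated_group_comparison(homo, v, g)
  expect_equal(res$route, "anova_tukey")
  expect_equal(res$letters$letters[res$letters$group != "D"], rep("a", 3))
  expect_equal(res$letters$letters[res$letters$group == "D"], "b")

  hetero <- data.frame(v = c(rnorm(30, sd = 1), rnorm(30, sd = 10)),
                       g = rep(c("A", "B"), each = 30))
  expect_equal(gated_group_comparison(hetero, v, g)$route, "welch_games_howell")
})

test_that("Levene rejects a 100x variance ratio with overwhelming probability", {
  set.seed(17)
  routes <- replicate(40, {
    d <- data.frame(v = c(rnorm(30, sd = 1), rnorm(30, sd = 10)),
                    g = rep(c("A", "B"), each = 30))
    gated_group_comparison(d, v, g)$route
  })
  expect_true(mean(routes == "welch_games_howell") >= 0.95)
})

test_that("needle-soil correlation grid flags degenerate and low-power cells", {
  ds <- study_dataset(random_valid_needles(n_trees = 3, seed = 2),
                      random_valid_soils(n_trees = 3, seed = 3))
  grid <- needle_soil_correlation(ds)
  expect_equal(nrow(grid), 2 * 2 * 5 * 3)
  expect_true(all(grid$flag == "low-power"))
  expect_true(all(abs(grid$r) <= 1, na.rm = TRUE))

  # constant needle ratios -> undefined r, flagged degenerate
  ds0 <- study_dataset(constant_needle_fixture(), random_valid_soils(seed = 4, n_trees = 3))
  grid0 <- needle_soil_correlation(ds0)
  expect_true(all(is.na(grid0$r)))
  expect_true(all(grid0$flag == "degenerate"))
})

test_that("perfectly proportional needle and soil ratios give r = 1", {
  soils <- random_valid_soils(n_trees = 4, seed = 9)
  # needle concentrations proportional to the same tree's 0-20 cm soil
  top <- soils[soils$soil_layer == "0-20", ]
  needles <- dplyr::bind_rows(
    dplyr::mutate(top, position = "apical",
                  sample_id = paste0(tree_id, "-api"),
                  c_mg_g = c_mg_g * 100, n_mg_g = n_mg_g * 50, p_mg_g = p_mg_g * 20),
    dplyr::mutate(top, position = "basal",
                  sample_id = paste0(tree_id, "-bas"),
                  c_mg_g = c_mg_g * 120, n_mg_g = n_mg_g * 30, p_mg_g = p_mg_g * 10)) |>
    dplyr::select(sample_id, tree_id, condition, position, c_mg_g, n_mg_g, p_mg_g)
  grid <- needle_soil_correlation(study_dataset(needles, soils))
  top_rows <- grid[grid$soil_layer == "0-20", ]
  expect_equal(top_rows$r, rep(1, nrow(top_rows)), tolerance = 1e-9)
})

test_that("Pearson r recovers a true correlation of 0.8 on average", {
  set.seed(55)
  rho <- 0.8; n <- 50
  est <- replicate(1000, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cor(x, y)
  })
  expect_equal(mean(est), rho, tolerance = 0.1)
})

test_that("ratio PCA is an exact rotation of the standardized data", {
  set.seed(20)
  d <- tibble::tibble(sample_id = paste0("s", 1:12),
                      c_n = runif(12, 10, 70),
                      c_p = runif(12, 50, 300),
                      n_p = runif(12, 1, 6))
  pca <- pca_ratios(d)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$explained) <= 1e-12))
  rot <- pca$fit$rotation
  expect_equal(t(rot) %*% rot, diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # reconstruction: scores %*% t(rotation), unscaled, uncentred
  scores <- as.matrix(pca$scores[c("PC1", "PC2", "PC3")])
  recon <- sweep(sweep(scores %*% t(rot), 2, pca$scale, `*`), 2, pca$center, `+`)
  expect_equal(recon, as.matrix(d[c("c_n", "c_p", "n_p")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # sign convention: dominant loading of each component is positive
  expect_true(all(apply(rot, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("PCA splits variance evenly for uncorrelated standardized columns", {
  set.seed(77)
  n <- 20000
  d <- tibble::tibble(c_n = rnorm(n), c_p = rnorm(n), n_p = rnorm(n))
  pca <- pca_ratios(d)
  expect_equal(pca$explained, rep(1 / 3, 3), tolerance = 0.02)

  collinear <- tibble::tibble(c_n = rnorm(20), c_p = 2 * c_n, n_p = rnorm(20))
  pca2 <- pca_ratios(collinear)
  expect_gte(pca2$explained[1], 2 / 3 - 1e-9)
  expect_equal(sum(pca2$explained), 1, tolerance = 1e-12)

  flat <- tibble::tibble(c_n = rep(1, 5), c_p = rnorm(5), n_p = rnorm(5))
  expect_error(pca_ratios(flat), "c_n")
})
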