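# Stoichiometric ratios and the five indices, against hand-computed values
# and their structural invariants.

test_that("ratios match hand arithmetic on published group means", {
  bc <- compute_ratios(472.4, 7.2, 1.6)
  expect_equal(bc$c_n, 65.61111, tolerance = 1e-6)
  expect_equal(bc$c_p, 295.25)
  expect_equal(bc$n_p, 4.5)

  ac <- compute_ratios(461.4, 24.7, 7.9)
  expect_equal(ac$c_n, 18.68016, tolerance = 1e-6)
  expect_equal(ac$c_p, 58.40506, tolerance = 1e-6)
  expect_equal(ac$n_p, 3.126582, tolerance = 1e-6)

  expect_equal(unlist(compute_ratios(100, 100, 100)), c(c_n = 1, c_p = 1, n_p = 1))
  expect_error(compute_ratios(100, 0, 1), "positive")
})

test_that("ratio consistency n_p * c_n = c_p holds over random samples", {
  set.seed(42)
  r <- compute_ratios(runif(200, 100, 600), runif(200, 1, 40), runif(200, 0.3, 10))
  expect_equal(r$n_p * r$c_n, r$c_p, tolerance = 1e-9)
})

test_that("homeostatic index matches hand computation and flags zero spread", {
  hi <- homeostatic_index(data.frame(x = c(2, 4, 6)), x)
  expect_equal(hi$mean, 4)
  expect_equal(hi$sd, 2)
  expect_equal(hi$cv, 0.5)
  expect_equal(hi$hi, 2)
  expect_false(hi$degenerate)

  flat <- homeostatic_index(data.frame(x = c(5, 5, 5)), x)
  expect_equal(flat$sd, 0)
  expect_true(is.infinite(flat$hi))
  expect_true(flat$degenerate)

  expect_error(homeostatic_index(data.frame(x = 1), x), "at least 2")
})

test_that("CV and HI are scale-invariant and hi * cv = 1 on random groups", {
  set.seed(99)
  for (rep in 1:20) {
    x <- rlnorm(sample(3:12, 1), meanlog = 2)
    k <- runif(1, 0.1, 50)
    a <- homeostatic_index(data.frame(x = x), x)
    b <- homeostatic_index(data.frame(x = k * x), x)
    expect_equal(a$cv, b$cv, tolerance = 1e-12)
    expect_equal(a$hi, b$hi, tolerance = 1e-12)
    expect_equal(a$hi * a$cv, 1, tolerance = 1e-12)
  }
})

test_that("NSI reproduces hand z-scores and sums to zero", {
  d <- data.frame(sample_id = c("a", "b"), c_n = c(10, 20), c_p = c(100, 200))
  nsi <- nutrient_stress_index(d)
  expect_equal(nsi$nsi, c(-2 * 0.70711, 2 * 0.70711), tolerance = 1e-4)

  set.seed(7)
  rand <- data.frame(c_n = runif(30, 5, 70), c_p = runif(30, 30, 300))
  expect_equal(sum(nutrient_stress_index(rand)$nsi), 0, tolerance = 1e-9)

  # a sample sitting at both reference means scores zero
  at_mean <- data.frame(c_n = c(10, 20, 15), c_p = c(100, 200, 150))
  expect_equal(nutrient_stress_index(at_mean)$nsi[3], 0, tolerance = 1e-12)

  degenerate <- data.frame(c_n = c(5, 5), c_p = c(1, 2))
  expect_error(nutrient_stress_index(degenerate), "c_n")
})

test_that("resorption efficiency matches hand arithmetic on published means", {
  expect_equal(resorption_efficiency(24.7, 7.2), 70.8502, tolerance = 1e-5)
  expect_equal(resorption_efficiency(447.8, 481.8), -7.592675, tolerance = 1e-6)
  expect_equal(resorption_efficiency(13.7, 13.7), 0)
  expect_error(resorption_efficiency(0, 5), "positive")
})

test_that("NRE stays below 100 and decreases in the basal concentration", {
  set.seed(3)
  apical <- runif(100, 1, 50)
  basal <- runif(100, 0.01, 60)
  expect_true(all(resorption_efficiency(apical, basal) < 100))
  a <- 24.7
  b <- sort(runif(50, 0.1, 40))
  expect_true(all(diff(resorption_efficiency(a, b)) < 0))
})

test_that("RPI is the plain quotient, scale-invariant, with banded labels", {
  rpi <- resorption_priority(70.8502, 79.74684)
  expect_equal(rpi, 0.888439, tolerance = 1e-5)
  expect_equal(rpi_label(rpi), "P-priority")
  expect_equal(rpi_label(rpi, tolerance = 0.15), "coupled (P-leaning)")
  expect_equal(resorption_priority(50, 50), 1)
  expect_equal(rpi_label(1), "coupled")
  expect_equal(resorption_priority(3 * 7, 3 * 9), resorption_priority(7, 9))
  expect_warning(out <- resorption_priority(10, 0), "NRE_P")
  expect_true(is.na(out))
})

test_that("SDI follows the asymmetric soil-denominator formula", {
  expect_equal(stoichiometric_deviation(65.611, 5.2), 11.61750, tolerance = 1e-6)
  expect_equal(stoichiometric_deviation(4.2, 4.2), 0)
  expect_error(stoichiometric_deviation(1, 0), "positive")

  set.seed(12)
  n <- runif(50, 1, 100); s <- runif(50, 1, 100); k <- runif(50, 0.1, 10)
  expect_equal(stoichiometric_deviation(k * n, k * s),
               stoichiometric_deviation(n, s), tolerance = 1e-12)
  asym <- abs(stoichiometric_deviation(n, s) - stoichiometric_deviation(s, n))
  expect_true(all(asym[n != s] > 0))
})

test_that("pair_resorption computes tree-wise NRE with pairing rules", {
  needles <- constant_needle_fixture()
  res <- pair_resorption(study_dataset(needles, constant_soil_fixture()))
  expect_equal(nrow(res), 6)
  chl <- res[res$condition == "chlorotic", ]
  expect_equal(chl$nre_n, rep(70.8502, 3), tolerance = 1e-5)
  expect_equal(chl$nre_p, rep(79.74684, 3), tolerance = 1e-5)

  # tree with only an apical sample is excluded with a warning
  drop_basal <- needles[needles$sample_id != "H1-bas", ]
  expect_warning(res2 <- pair_resorption(drop_basal), "H1")
  expect_equal(nrow(res2), 5)

  # basal without apical partner is an error naming the tree
  drop_apical <- needles[needles$sample_id != "C2-api", ]
  expect_error(pair_resorption(drop_apical), "C2")

  # basal = apical everywhere -> all NRE zero
  flat <- needles
  flat[flat$position == "basal", c("c_mg_g", "n_mg_g", "p_mg_g")] <-
    flat[flat$position == "apical", c("c_mg_g", "n_mg_g", "p_mg_g")]
  expect_warning(res_flat <- pair_resorption(flat), "RPI undefined")
  expect_true(all(abs(res_flat$nre_n) < 1e-12))
})

test_that("sdi_grid conventions coincide for constant groups", {
  ds <- study_dataset(constant_needle_fixture(), constant_soil_fixture())
  gm <- sdi_grid(ds, "group_mean")
  pt <- sdi_grid(ds, "per_tree")
  expect_equal(gm$sdi, pt$sdi, tolerance = 1e-12)
  expect_equal(nrow(gm), 2 * 2 * 5 * 3)
  # BC vs topsoil C:N at the regional soil means: 65.611 vs 10.0
  bc_cn <- gm$sdi[gm$condition == "chlorotic" & gm$position == "basal" &
                    gm$soil_layer == "0-20" & gm$ratio == "c_n"]
  expect_equal(bc_cn, abs(472.4 / 7.2 - 10) / 10, tolerance = 1e-9)
})
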