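pops_tb <- function(lat, lon, ...) {
  tibble::tibble(population_id = paste0("P", seq_along(lat)),
                 latitude = lat, longitude = lon, ...)
}

test_that("great-circle distances match closed forms on a 6371-km sphere", {
  tb <- pops_tb(lat = c(0, 0, 0), lon = c(0, 1, 180))
  M <- geographic_distances(tb)
  expect_equal(M["P1", "P1"], 0)
  expect_equal(M["P1", "P2"], 6371 * pi / 180, tolerance = 1e-4)
  expect_equal(M["P1", "P3"], 6371 * pi, tolerance = 1e-4)
  expect_true(isSymmetric(M))
  expect_error(geographic_distances(pops_tb(lat = 95, lon = 0)),
               class = "oakdemog_input_error")
})

test_that("scaled-Euclidean ecological distances follow the z-score oracle", {
  tb <- pops_tb(lat = c(30, 31), lon = c(100, 101), v1 = c(0, 1))
  M <- ecological_distances(tb, "v1")
  # z-scores with sample SD 0.7071: +-0.7071 -> distance 1.4142
  expect_equal(M["P1", "P2"], sqrt(2), tolerance = 1e-4)

  tb2 <- pops_tb(lat = c(30, 31, 32), lon = c(100, 101, 102),
                 a = c(1, 4, 2), b = c(9, 2, 5), c = c(3, 3, 8))
  M1 <- ecological_distances(tb2, c("a", "b", "c"))
  M2 <- ecological_distances(tb2, c("c", "a", "b"))
  expect_equal(M1, M2, tolerance = 1e-12)

  expect_equal(unname(ecological_distances(
    pops_tb(lat = c(1, 2), lon = c(1, 2), x = c(5, 5), y = c(0, 1)),
    c("x", "y")) |> suppressWarnings() |> (\(m) m[1, 2])()),
    sqrt(2), tolerance = 1e-4)
})

test_that("Mantel statistics hit the identity and anti-identity limits", {
  set.seed(3)
  A <- random_dist(6)
  expect_equal(mantel_test(A, A, 99)$r, 1)
  expect_equal(mantel_test(A, max(A) + 1 - A, 99)$r, -1, tolerance = 1e-12)
  B <- random_dist(5)
  expect_error(mantel_test(A, B), class = "oakdemog_alignment_error")
})

test_that("permutation p matches exact enumeration on four populations", {
  set.seed(5)
  for (rep in 1:3) {
    A <- random_dist(4); B <- random_dist(4)
    p_exact <- exact_mantel_p(A, B)
    p_hat <- mantel_test(A, B, 999)$p_value
    tol <- 3 * sqrt(p_exact * (1 - p_exact) / 999) + 2 / 1000
    expect_lt(abs(p_hat - p_exact), tol + 1e-12)
  }
})

test_that("Mantel r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  A <- random_dist(8); B <- random_dist(8); C <- random_dist(8)
  expect_equal(mantel_test(A, B, 9)$r,
               vegan::mantel(as.dist(A), as.dist(B), permutations = 9)$statistic,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(partial_mantel_test(A, B, C, 9)$r,
               vegan::mantel.partial(as.dist(A), as.dist(B), as.dist(C),
                                     permutations = 9)$statistic,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("partial Mantel reduces, degenerates and cancels as constructed", {
  set.seed(9)
  A <- random_dist(7); B <- random_dist(7)
  Cc <- matrix(1, 7, 7, dimnames = dimnames(A)); diag(Cc) <- 0
  # constant control (zero correlation after tie handling) -> simple Mantel r
  expect_equal(partial_mantel_test(A, B, Cc, 99)$r,
               mantel_test(A, B, 9)$r, tolerance = 1e-12)
  expect_error(partial_mantel_test(A, A, A, 9),
               class = "oakdemog_degenerate_control_error")
  # perfectly collinear control is rejected as degenerate ...
  expect_error(partial_mantel_test(A, B, B, 9),
               class = "oakdemog_degenerate_control_error")
  # ... and when two matrices share their structure through the control,
  # partialling it out cancels the (strong) simple correlation
  Cbig <- random_dist(25)
  A2 <- Cbig + random_dist(25) * 0.3
  B2 <- Cbig + random_dist(25) * 0.3
  r_simple <- mantel_test(A2, B2, 9)$r
  r_part <- partial_mantel_test(A2, B2, Cbig, 99)$r
  expect_gt(r_simple, 0.6)
  expect_lt(abs(r_part), 0.25)
  expect_lt(abs(r_part), r_simple / 2)
})

test_that("stepwise regression selects the null and planted models correctly", {
  # under the null each noise predictor survives AIC elimination with
  # probability ~ P(chisq_1 > 2) ~ 0.16, so false retention stays low but
  # is not rare; planted signal must essentially always be kept
  set.seed(11)
  n_retained <- integer(100); power_hits <- 0
  for (i in 1:100) {
    n <- 21
    X <- as.data.frame(matrix(rnorm(n * 5), n,
                              dimnames = list(NULL, paste0("x", 1:5))))
    X$y_null <- rnorm(n)
    f0 <- stepwise_regression(X, "y_null", paste0("x", 1:5), family = "glm")
    n_retained[i] <- length(f0$selected)

    X$y_sig <- 2 * X$x1 + rnorm(n, 0, 0.5)
    f1 <- stepwise_regression(X, "y_sig", paste0("x", 1:5), family = "glm")
    if ("x1" %in% f1$selected) power_hits <- power_hits + 1
  }
  expect_lte(mean(n_retained), 1.3)
  expect_gte(sum(n_retained == 0), 25)
  expect_gte(power_hits, 95)
})

test_that("GLM and RLM agree on clean planted data and GLM matches stepAIC", {
  set.seed(13)
  agree <- 0
  for (i in 1:20) {
    n <- 21
    dat <- as.data.frame(matrix(rnorm(n * 4), n,
                                dimnames = list(NULL, paste0("x", 1:4))))
    dat$y <- 1.5 * dat$x1 - 2 * dat$x2 + rnorm(n, 0, 0.3)
    fg <- stepwise_regression(dat, "y", paste0("x", 1:4), family = "glm")
    fr <- stepwise_regression(dat, "y", paste0("x", 1:4), family = "rlm")
    if (setequal(fg$selected, fr$selected)) agree <- agree + 1

    full <- glm(y ~ x1 + x2 + x3 + x4, data = dat, family = gaussian())
    ms <- MASS::stepAIC(full, direction = "both", trace = 0)
    expect_setequal(fg$selected,
                    setdiff(all.vars(formula(ms)), "y"))
  }
  expect_gte(agree, 14)
})

test_that("stepwise regression validates dimensions and reports univariate fits", {
  dat <- data.frame(y = rnorm(5), x1 = rnorm(5), x2 = rnorm(5),
                    x3 = rnorm(5), x4 = rnorm(5))
  expect_error(stepwise_regression(dat, "y", paste0("x", 1:4)),
               class = "oakdemog_input_error")
  set.seed(15)
  dat2 <- data.frame(y = rnorm(21), a = rnorm(21), b = rnorm(21))
  f <- stepwise_regression(dat2, "y", c("a", "b"), family = "glm")
  expect_equal(nrow(f$univariate), 2)
  expect_true(all(is.finite(f$univariate$aic)))
  expect_s3_class(tidy(f), "tbl_df")
  expect_equal(glance(f)$n, 21)
})

test_that("ecology-linked structure is detected while shuffled geography stays null", {
  params <- tibble::tibble(scenario = "S4", Ne = 1200, Na = 1500, Ndb = 3000,
                           Ta = 30000, Tdb = 1000, mu_cp = 6e-8, mu_nr = 2e-7)
  eco_hits <- 0; geo_hits <- 0
  n_seeds <- 12
  for (seed in seq_len(n_seeds)) {
    cfg <- synth_config(seed = seed, scenario = "S4", params = params,
                        n_populations = 12, inds_per_pop = 4,
                        nuclear_lengths = c(400), plastid_length = 200,
                        indel_columns = 0, n_pops_cluster2 = 6,
                        cluster_split_time = 20000, ibe_strength = 1)
    st <- generate_study(cfg)
    Fst <- pairwise_fst(st$dataset$loci$nucA)
    E <- ecological_distances(st$dataset$populations,
                              cfg$env_variables)
    if (mantel_test(Fst, E, 199)$p_value < 0.05) eco_hits <- eco_hits + 1
    # geography shuffled relative to genetics: no spatial signal expected
    G <- geographic_distances(st$dataset$populations)
    idx <- sample(nrow(G))
    Gs <- G[idx, idx]; dimnames(Gs) <- dimnames(G)
    if (mantel_test(Fst, Gs, 199)$p_value < 0.05) geo_hits <- geo_hits + 1
  }
  expect_gte(eco_hits, ceiling(0.7 * n_seeds))
  expect_lte(geo_hits, floor(0.35 * n_seeds))
})
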