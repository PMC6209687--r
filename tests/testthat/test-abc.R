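test_that("summary statistics match exhaustive enumeration on the toy alignment", {
  expect_equal(
    oakdemog:::locus_five_stats(toy4()),
    c(VPD = 17 / 30, TajD = 0.5918, PSS = 1, MNS = 1.5, VNS = 0.5),
    tolerance = 1e-3)

  # monomorphic dataset -> zero vector (the ABC S = 0 convention)
  mono <- hap_alignment(rep("ACGTACGT", 6), paste0("s", 1:6), rep("p", 6),
                        ploidy = "plastid")
  expect_equal(unname(oakdemog:::locus_five_stats(mono)), rep(0, 5))

  # duplicating every sequence doubles the rarest counts and kills PSS
  dup <- hap_alignment(rep(toy4()$sequences, each = 2), paste0("s", 1:8),
                       rep("p", 8), ploidy = "plastid")
  st <- oakdemog:::locus_five_stats(dup)
  expect_equal(unname(st["MNS"]), 3)      # {4,2} vs {2,1}: scaled x2
  expect_equal(unname(st["PSS"]), 0)
})

test_that("summary_stats averages per locus group in fixed order", {
  cp <- hap_alignment(rep("ACGTACGT", 4), paste0("c", 1:4), rep("p", 4),
                      ploidy = "plastid")
  cp$locus_name <- "cp"
  nu <- toy4(); nu$locus_name <- "nucA"
  ds <- study_dataset(list(cp, nu), list(plastid = "cp", nuclear = "nucA"))
  st <- summary_stats(ds)
  expect_named(st, STAT_NAMES)
  expect_equal(unname(st[1:5]), rep(0, 5))
  expect_equal(unname(st["nuc_VPD"]), 17 / 30)

  ds2 <- study_dataset(list(nu), list(nuclear = "nucA"))
  expect_error(summary_stats(ds2), class = "oakdemog_configuration_error")
})

test_that("reference and compiled statistic implementations agree exactly", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:30, 1); S <- sample(1:20, 1)
    seg <- matrix(sample(0:3, n * S, replace = TRUE), n, S)
    seg <- seg[, apply(seg, 2, function(c) length(unique(c)) > 1), drop = FALSE]
    if (ncol(seg) == 0) next
    bases <- c("A", "C", "G", "T")
    aln <- hap_alignment(apply(seg, 1, function(r)
      paste(bases[r + 1], collapse = "")), paste0("s", 1:n), rep("p", n),
      ploidy = "plastid")
    expect_equal(oakdemog:::locus_five_stats(aln),
                 oakdemog:::.locus_stats_cpp(seg), tolerance = 1e-10)
  }
})

test_that("reference-table allocation, determinism and separability hold", {
  des <- small_design(2, 3, L_nuc = 150, L_cp = 250)
  rt1 <- build_reference_table(700, design = des, seed = 5)
  expect_equal(as.numeric(table(rt1$scenario)), rep(100, 7))
  rt2 <- build_reference_table(700, design = des, seed = 5)
  expect_identical(as.data.frame(rt1), as.data.frame(rt2))

  # S1 and S4 rows differ in distribution for at least one statistic
  rt <- build_reference_table(2 * 500, scenarios = c("S1", "S4"),
                              design = des, seed = 6)
  ps <- vapply(STAT_NAMES, function(s)
    suppressWarnings(stats::ks.test(rt[[s]][rt$scenario == "S1"],
                                    rt[[s]][rt$scenario == "S4"]))$p.value,
    numeric(1))
  expect_true(any(ps < 0.05))
})

test_that("scenario choice returns coherent probabilities and accepted sets", {
  set.seed(17)
  # well-separated synthetic table: scenario k centred at 3k on every stat
  gens <- setNames(lapply(1:7, function(k)
    function(n) matrix(rnorm(n * 10, mean = 3 * k, sd = 0.5), n, 10)), SCENARIOS)
  rt <- fake_reftable(gens, n_per = 300)
  obs <- setNames(rep(6, 10), STAT_NAMES)  # squarely in S2 territory
  ch <- choose_scenario(obs, rt, tolerance = 0.05, method = "both")
  expect_equal(attr(ch, "n_accepted"), ceiling(0.05 * 2100))
  for (m in c("direct", "logistic")) {
    pp <- ch$pp[ch$method == m]
    expect_equal(sum(pp), 1, tolerance = 1e-6)
    expect_equal(ch$scenario[ch$method == m][which.max(pp)], "S2")
    expect_true(all(ch$ci_lo[ch$method == m] >= 0 &
                    ch$ci_hi[ch$method == m] <= 1))
  }
  # an accepted set drawn wholly from one scenario gives that scenario PP 1
  obs_far <- setNames(rep(21, 10), STAT_NAMES)
  ch7 <- choose_scenario(obs_far, rt, tolerance = 0.01, method = "both")
  expect_equal(ch7$pp[ch7$scenario == "S7"], c(1, 1))
  expect_error(choose_scenario(obs, rt, tolerance = 1e-5),
               class = "oakdemog_tolerance_error")
})

test_that("exchangeable scenarios give uniform posterior probabilities", {
  set.seed(19)
  gens <- setNames(lapply(1:7, function(k) iid_stats), SCENARIOS)
  rt <- fake_reftable(gens, n_per = 1000)
  obs <- setNames(rep(0, 10), STAT_NAMES)
  ch <- choose_scenario(obs, rt, tolerance = 0.1, method = "direct")
  k <- attr(ch, "n_accepted")
  se <- sqrt((1 / 7) * (6 / 7) / k)
  expect_true(all(abs(ch$pp - 1 / 7) < 3 * se + 1e-9))
})

test_that("scenario choice is invariant to affine rescaling of raw statistics", {
  set.seed(23)
  gens <- setNames(lapply(1:7, function(k)
    function(n) matrix(rnorm(n * 10, mean = k), n, 10)), SCENARIOS)
  rt <- fake_reftable(gens, n_per = 200)
  obs <- setNames(rnorm(10, 4), STAT_NAMES)
  ch1 <- choose_scenario(obs, rt, tolerance = 0.05, method = "direct")

  rt2 <- rt
  scl <- runif(10, 0.1, 50); off <- rnorm(10, 0, 10)
  for (j in seq_along(STAT_NAMES))
    rt2[[STAT_NAMES[j]]] <- rt2[[STAT_NAMES[j]]] * scl[j] + off[j]
  X <- as.matrix(rt2[, STAT_NAMES])
  attr(rt2, "stat_mean") <- colMeans(X)
  attr(rt2, "stat_sd") <- apply(X, 2, sd)
  obs2 <- setNames(obs * scl + off, STAT_NAMES)
  ch2 <- choose_scenario(obs2, rt2, tolerance = 0.05, method = "direct")
  expect_equal(ch1$pp, ch2$pp, tolerance = 1e-9)
})

test_that("local-linear adjustment is exact in degenerate and linear regimes", {
  set.seed(29)
  # all accepted stats identical to the observation -> adjusted == raw draws
  gens <- list(S1 = function(n) matrix(5, n, 10))
  rt <- fake_reftable(gens, n_per = 300)
  obs <- setNames(rep(5, 10), STAT_NAMES)
  expect_warning(est <- estimate_params(obs, rt, "S1", tolerance = 0.5))
  expect_equal(attr(est, "adjustment"), "rejection-only")
  draws <- attr(est, "draws")
  expect_true(all(vapply(sort(draws$Ne), function(v)
    any(abs(rt$Ne - v) < 1e-8), logical(1))))

  # linear toy: one stat = Ne + small noise; median tracks the observation
  rtl <- fake_reftable(list(S1 = iid_stats), n_per = 4000)
  rtl$cp_VPD <- rtl$Ne + rnorm(4000, 0, 200)
  X <- as.matrix(rtl[, STAT_NAMES])
  attr(rtl, "stat_mean") <- colMeans(X)
  attr(rtl, "stat_sd") <- apply(X, 2, sd)
  obs2 <- setNames(c(5e4, rep(0, 9)), STAT_NAMES)
  est2 <- estimate_params(obs2, rtl, "S1", tolerance = 0.02)
  expect_lt(abs(est2$median[est2$param == "Ne"] - 5e4), 0.02 * (1e5 - 1e3))
})

test_that("a perfectly informative table drives RMAE toward zero", {
  set.seed(31)
  rt <- fake_reftable(list(S1 = iid_stats), n_per = 2000)
  rt$cp_VPD <- rt$Ne        # noiseless estimator of the parameter
  X <- as.matrix(rt[, STAT_NAMES])
  attr(rt, "stat_mean") <- colMeans(X)
  attr(rt, "stat_sd") <- apply(X, 2, sd)
  errs <- vapply(seq_len(20), function(i) {
    truth <- runif(1, 5e3, 9e4)
    obs <- setNames(c(truth, rep(0, 9)), STAT_NAMES)
    est <- estimate_params(obs, rt, "S1", tolerance = 0.02)
    abs(est$median[est$param == "Ne"] - truth) / truth
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("confidence_in_choice reports coherent error rates", {
  set.seed(37)
  des <- small_design(2, 3, L_nuc = 100, L_cp = 150)
  rt <- build_reference_table(7 * 60, design = des, seed = 37)
  cf <- confidence_in_choice("S4", rt, n_pods = 3, tolerance = 0.05,
                             design = des)
  expect_setequal(cf$method, c("direct", "logistic"))
  expect_true(all(cf$type_I >= 0 & cf$type_I <= 1))
  expect_true(all(cf$type_II >= 0 & cf$type_II <= 1))
  expect_equal(cf$selection_rate, 1 - cf$type_I)
  sel <- attr(cf, "selections")
  expect_equal(nrow(sel), 7 * 3 * 2)
})

test_that("goodness of fit flags displaced observations and accepts central ones", {
  set.seed(41)
  des <- small_design(2, 3, L_nuc = 150, L_cp = 250)
  rt <- build_reference_table(7 * 100, design = des, seed = 41)
  p <- sample_prior("S4", 1)
  obs <- drop(oakdemog:::simulate_stats(p, des))
  est <- estimate_params(obs, rt, "S4", tolerance = 0.3)
  g <- goodness_of_fit(obs, est, rt, n_pods = 150, design = des)
  expect_equal(nrow(g$tail), 10)
  expect_true(all(g$tail$tail_p > 0 & g$tail$tail_p <= 1))
  # a central observation should not be flagged on most statistics
  expect_gte(median(g$tail$tail_p), 0.1)

  # displace one statistic 10 SD into the tail
  obs_bad <- obs
  obs_bad["nuc_VPD"] <- obs["nuc_VPD"] + 10 * attr(rt, "stat_sd")["nuc_VPD"]
  g2 <- goodness_of_fit(obs_bad, est, rt, n_pods = 150, design = des)
  expect_lte(g2$tail$tail_p[g2$tail$stat == "nuc_VPD"], 2 / 150)
})
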