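test_that("prior draws respect ranges, constraints and determinism", {
  set.seed(1)
  p1 <- sample_prior("S1", 2000)
  expect_true(all(p1$Ne >= 1e3 & p1$Ne <= 1e5))
  expect_true(all(p1$Ta >= 1.25e4 & p1$Ta <= 3.75e4))
  expect_true(all(p1$mu_cp >= 5e-8 & p1$mu_cp <= 7e-8))
  expect_true(all(p1$mu_nr >= 1e-7 & p1$mu_nr <= 3e-7))

  p4 <- sample_prior("S4", 2000)
  expect_true(all(p4$Ndb > pmax(p4$Ne, p4$Na)))
  expect_true(all(p4$Tdb < p4$Ta))
  expect_true(all(p4$Tdb >= 250 & p4$Tdb <= 1500))

  p2 <- sample_prior("S2", 500)
  expect_true(all(p2$Na > p2$Ne))
  p3 <- sample_prior("S3", 500)
  expect_true(all(p3$Na < p3$Ne))
  p7 <- sample_prior("S7", 500)
  expect_true(all(p7$Ndb < pmin(p7$Ne, p7$Na)))
  expect_true(all(p7$Tdb >= 75 & p7$Tdb <= 275))

  set.seed(99); a <- sample_prior("S5", 50)
  set.seed(99); b <- sample_prior("S5", 50)
  expect_identical(a, b)
})

test_that("pairwise TMRCA matches 2N-chromosome coalescent expectations", {
  # nuclear diploid: E[T2] = 2N generations; plastid (m = 0.5): E[T2] = N
  p <- list(Ne = 5000)
  nuc <- locus_spec("nuc", "nuclear", 10, 2)
  cp <- locus_spec("cp", "plastid", 10, 2)
  set.seed(21)
  t_nuc <- replicate(2000, {
    tr <- simulate_genealogy(p, "S1", nuc)
    max(ape::node.depth.edgelength(tr))
  })
  se <- sd(t_nuc) / sqrt(length(t_nuc))
  expect_lt(abs(mean(t_nuc) - 10000), 3 * se)

  t_cp <- replicate(2000, {
    tr <- simulate_genealogy(p, "S1", cp)
    max(ape::node.depth.edgelength(tr))
  })
  se <- sd(t_cp) / sqrt(length(t_cp))
  expect_lt(abs(mean(t_cp) - 5000), 3 * se)

  # compiled engine agrees with the same expectation
  t_cpp <- replicate(2000,
    oakdemog:::.sim_locus_cpp(2L, 10L, 0, 5000, 1, 1e-9, 2, rep(.25, 4),
                              FALSE)$tmrca)
  se <- sd(t_cpp) / sqrt(length(t_cpp))
  expect_lt(abs(mean(t_cpp) - 10000), 3 * se)
})

test_that("a steep exponential epoch approaches the two-phase constant model", {
  # decline anchors (0 -> 100, 400 -> 10000) squeezed into a very steep
  # change at ~400 generations behaves like constant 100 then constant 10000
  set.seed(31)
  steep <- replicate(2000, {
    r <- oakdemog:::.sim_locus_cpp(2L, 5L, c(0, 399.99, 400), c(100, 100, 10000),
                                   1, 1e-9, 2, rep(.25, 4), FALSE)
    r$tmrca
  })
  twophase <- replicate(2000, {
    t2 <- stats::rexp(1, 1 / 200)
    if (t2 <= 400) t2 else 400 + stats::rexp(1, 1 / 20000)
  })
  expect_gt(suppressWarnings(stats::ks.test(steep, twophase))$p.value, 0.01)
})

test_that("HKY mutation reproduces closed-form divergence and stationarity", {
  # two tips at divergence t, kappa = 1, equal frequencies: JC69 closed form
  two_tip <- structure(list(
    edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
    edge.length = c(500, 500), tip.label = c("t1", "t2"), Nnode = 1L),
    class = "phylo")
  mu <- 2e-4
  sp <- locus_spec("x", "nuclear", 1e5, 2, kappa = 1)
  set.seed(41)
  aln <- mutate_hky(two_tip, mu, sp)
  m <- aln_matrix(aln)
  p_hat <- mean(m[1, ] != m[2, ])
  t_tot <- 1000
  p_exp <- 0.75 * (1 - exp(-4 * mu * t_tot / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 1e5)
  expect_lt(abs(p_hat - p_exp), 3 * se)

  # mu = 0: tips identical to the root
  aln0 <- mutate_hky(two_tip, 0, sp)
  expect_identical(aln0$sequences[1], aln0$sequences[2])
  expect_identical(aln0$sequences[1], attr(aln0, "ancestral"))

  # unequal frequencies: tip composition ~ stationary (chi-square)
  fr <- c(0.4, 0.3, 0.2, 0.1)
  sp2 <- locus_spec("y", "nuclear", 1e5, 2, kappa = 3, freqs = fr)
  aln2 <- mutate_hky(two_tip, 5e-4, sp2)
  cnt <- table(factor(strsplit(aln2$sequences[1], "")[[1]],
                      levels = c("A", "C", "G", "T")))
  expect_gt(stats::chisq.test(cnt, p = fr)$p.value, 0.01)
})

test_that("segregating sites match the Watterson expectation under S1", {
  # theta_locus = 4 N mu L; E[S] = theta * a_{n-1}
  N <- 5000; mu <- 2e-7; L <- 336L; n <- 210L
  theta <- 4 * N * mu * L
  a_n <- sum(1 / seq_len(n - 1))
  set.seed(51)
  S <- replicate(500, ncol(
    oakdemog:::.sim_locus_cpp(n, L, 0, N, 1, mu, 2, rep(.25, 4), FALSE)$seg))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - theta * a_n), 3 * se)
})

test_that("plastid/nuclear diversity scales with the inheritance multiplier", {
  # at equal N, per-site mean pairwise diversity ratio cp:nuc =
  # (2 N mu_cp * 0.5) / (4 N mu_nr)... i.e. theta ratio = (mu_cp/2)/(2 mu_nr)
  N <- 20000; mu_cp <- 6e-8; mu_nr <- 2e-7
  pi_from_seg <- function(seg, n, L) {
    if (ncol(seg) == 0) return(0)
    h <- apply(seg, 2, function(col) {
      tab <- table(col)
      1 - sum(tab * (tab - 1)) / (n * (n - 1))
    })
    sum(h) / L
  }
  set.seed(61)
  pi_cp <- replicate(300, pi_from_seg(
    oakdemog:::.sim_locus_cpp(20L, 2000L, 0, N, 0.5, mu_cp, 2,
                              rep(.25, 4), FALSE)$seg, 20, 2000))
  pi_nuc <- replicate(300, pi_from_seg(
    oakdemog:::.sim_locus_cpp(20L, 2000L, 0, N, 1, mu_nr, 2,
                              rep(.25, 4), FALSE)$seg, 20, 2000))
  ratio_hat <- mean(pi_cp) / mean(pi_nuc)
  ratio_exp <- (2 * N * 0.5 * mu_cp) / (4 * N * mu_nr)
  expect_equal(ratio_hat, ratio_exp, tolerance = 0.15)
})

test_that("Tajima's D sign tracks recent decline and growth", {
  set.seed(71)
  decline <- tibble::tibble(scenario = "S2", Ne = 1000, Na = 80000, Ndb = NA,
                            Ta = 2000, Tdb = NA, mu_cp = 6e-8, mu_nr = 2e-7)
  growth <- tibble::tibble(scenario = "S3", Ne = 80000, Na = 1000, Ndb = NA,
                           Ta = 2000, Tdb = NA, mu_cp = 6e-8, mu_nr = 2e-7)
  des <- small_design(2, 5, L_nuc = 500, L_cp = 800)
  st_d <- oakdemog:::simulate_stats(decline[rep(1, 500), ], des)
  st_g <- oakdemog:::simulate_stats(growth[rep(1, 500), ], des)
  expect_gt(mean(st_d[, "nuc_TajD"]), 0.1)
  expect_lt(mean(st_g[, "nuc_TajD"]), -0.1)
})

test_that("compiled and reference engines agree in distribution", {
  p <- tibble::tibble(scenario = "S4", Ne = 8000, Na = 4000, Ndb = 30000,
                      Ta = 20000, Tdb = 1000, mu_cp = 6e-8, mu_nr = 2e-7)
  des <- small_design(2, 3, L_nuc = 300, L_cp = 500)
  set.seed(81)
  S_cpp <- replicate(120, {
    ds <- simulate_dataset("S4", p, des, n_populations = 2, inds_per_pop = 3,
                           engine = "compiled")
    compute_diversity(ds$loci$nucA)$S
  })
  S_r <- replicate(120, {
    ds <- simulate_dataset("S4", p, des, n_populations = 2, inds_per_pop = 3,
                           engine = "r")
    compute_diversity(ds$loci$nucA)$S
  })
  expect_gt(suppressWarnings(stats::ks.test(S_cpp, S_r))$p.value, 0.01)
})

test_that("degenerate sample sizes behave", {
  p <- list(Ne = 5000)
  one <- locus_spec("x", "nuclear", 50, 1)
  tr <- simulate_genealogy(p, "S1", one)
  expect_equal(length(tr$tip.label), 1)
  r <- oakdemog:::.sim_locus_cpp(1L, 50L, 0, 5000, 1, 2e-7, 2, rep(.25, 4),
                                 FALSE)
  expect_equal(ncol(r$seg), 0)
})
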