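# DIY-ABC-style inference: summary statistics, reference table, scenario
# choice (direct and logistic), local-linear parameter estimation, POD-based
# confidence and RMAE, and PCA goodness-of-fit.

#' Fixed order of the ten ABC summary statistics
#'
#' Per locus group (plastid first, then nuclear): variance of pairwise
#' differences (VPD), Tajima's D, private (singleton) segregating sites
#' (PSS), mean (MNS) and variance (VNS) of the rarest-nucleotide count over
#' segregating sites.  Statistics are averaged over the loci of a group.
#' @export
STAT_NAMES <- c(paste0("cp_", c("VPD", "TajD", "PSS", "MNS", "VNS")),
                paste0("nuc_", c("VPD", "TajD", "PSS", "MNS", "VNS")))

PARAM_NAMES <- c("Ne", "Na", "Ndb", "Ta", "Tdb", "mu_cp", "mu_nr")
LOG_PARAMS <- c("Ne", "Na", "Ndb", "Ta", "Tdb")

used_params <- function(scenario) {
  switch(scenario,
         S1 = c("Ne", "mu_cp", "mu_nr"),
         S2 = , S3 = c("Ne", "Na", "Ta", "mu_cp", "mu_nr"),
         PARAM_NAMES)
}

# the five per-locus statistics, ABC conventions (S = 0 -> all zero,
# degenerate Tajima variance -> 0); reference implementation mirrored by the
# compiled batch path
locus_five_stats <- function(aln) {
  aln <- drop_gap_columns(aln)
  m <- state_matrix(aln, indels_informative = FALSE)
  n <- nrow(m)
  poly <- poly_columns(m)
  S <- length(poly)
  if (S == 0 || n < 2)
    return(c(VPD = 0, TajD = 0, PSS = 0, MNS = 0, VNS = 0))
  D <- pair_diff_matrix(m)
  d <- D[upper.tri(D)]
  vpd <- if (length(d) > 1) var(d) else 0
  tajd <- tajima_d_from(n, S, mean(d))
  if (is.na(tajd)) tajd <- 0
  rare <- vapply(poly, function(s) {
    cnt <- table(m[!is.na(m[, s]), s])
    as.integer(min(cnt))
  }, integer(1))
  c(VPD = vpd, TajD = tajd, PSS = sum(rare == 1L),
    MNS = mean(rare), VNS = if (S > 1) var(as.numeric(rare)) else 0)
}

#' ABC summary-statistic vector for a multilocus dataset
#'
#' Computes the five statistics per locus (gap columns dropped first, the
#' ABC convention) and averages them within each locus group, returning the
#' fixed-order 10-vector of [STAT_NAMES].
#'
#' @param dataset a [study_dataset()] with both a `plastid` and a `nuclear`
#'   locus group.
#' @return named numeric vector of length 10.
#' @export
summary_stats <- function(dataset) {
  for (g in c("plastid", "nuclear"))
    if (is.null(dataset$locus_groups[[g]]) || !length(dataset$locus_groups[[g]]))
      abort(sprintf("locus group '%s' missing", g),
            class = "oakdemog_configuration_error")
  per_group <- lapply(c("plastid", "nuclear"), function(g) {
    st <- vapply(dataset$locus_groups[[g]],
                 function(nm) locus_five_stats(dataset$loci[[nm]]),
                 numeric(5))
    rowMeans(st)
  })
  setNames(c(per_group[[1]], per_group[[2]]), STAT_NAMES)
}

# anchors matrices for the compiled batch simulator
params_to_anchor_mats <- function(params) {
  n <- nrow(params)
  at <- matrix(0, n, 3)
  aN <- matrix(1, n, 3)
  na <- integer(n)
  for (i in seq_len(n)) {
    a <- scenario_anchors(params$scenario[i], params[i, ])
    k <- length(a$t)
    at[i, seq_len(k)] <- a$t
    aN[i, seq_len(k)] <- a$N
    na[i] <- k
  }
  list(t = at, N = aN, k = na)
}

# batch-simulate the 10 summary statistics for a parameter table
simulate_stats <- function(params, design = default_locus_design(),
                           kappa = 2, freqs = rep(0.25, 4)) {
  am <- params_to_anchor_mats(params)
  grp <- vapply(design, function(s) s$group, character(1))
  st <- .abc_sim_stats_cpp(
    am$t, am$N, am$k, params$mu_cp, params$mu_nr,
    vapply(design, function(s) s$sample_size, integer(1)),
    vapply(design, function(s) s$length, integer(1)),
    vapply(design, function(s) s$size_multiplier, numeric(1)),
    as.integer(grp == "nuclear"), kappa, freqs)
  colnames(st) <- STAT_NAMES
  st
}

#' Build an ABC reference table
#'
#' Mass simulation with equal allocation across scenarios: parameters are
#' drawn from each scenario's prior, datasets simulated under the given
#' locus design, and the ten summary statistics recorded.  Per-column means
#' and standard deviations (the standardization constants used by all
#' downstream distances) are stored as attributes.
#'
#' @param n_sims total number of simulations (split evenly; remainders go to
#'   the first scenarios).
#' @param scenarios character vector of scenario ids.
#' @param design locus design, see [default_locus_design()].
#' @param seed optional integer seed (applied via [set.seed()]).
#' @return tibble of class `oak_reftable`: `scenario` + 7 parameter columns
#'   + 10 statistic columns.
#' @export
build_reference_table <- function(n_sims, scenarios = SCENARIOS,
                                  design = default_locus_design(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nsc <- length(scenarios)
  if (n_sims < nsc)
    abort("n_sims smaller than the number of scenarios",
          class = "oakdemog_input_error")
  alloc <- rep(n_sims %/% nsc, nsc)
  extra <- n_sims %% nsc
  if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
  pieces <- purrr::map2(scenarios, alloc, function(sc, k) {
    p <- sample_prior(sc, k)
    st <- simulate_stats(p, design)
    dplyr::bind_cols(p, as_tibble(st))
  })
  tb <- dplyr::bind_rows(pieces)
  tb$scenario <- factor(tb$scenario, levels = scenarios)
  X <- as.matrix(tb[, STAT_NAMES])
  attr(tb, "stat_mean") <- colMeans(X)
  attr(tb, "stat_sd") <- apply(X, 2L, sd)
  attr(tb, "seed") <- seed
  attr(tb, "design") <- design
  class(tb) <- c("oak_reftable", class(tb))
  tb
}

ref_standardization <- function(table) {
  mu <- attr(table, "stat_mean")
  sdv <- attr(table, "stat_sd")
  if (is.null(mu) || is.null(sdv)) {
    X <- as.matrix(table[, STAT_NAMES])
    mu <- colMeans(X)
    sdv <- apply(X, 2L, sd)
  }
  keep <- sdv > 0
  list(mean = mu, sd = sdv, keep = keep)
}

std_stats <- function(x, std) {
  if (is.data.frame(x)) x <- as.matrix(x[, STAT_NAMES])
  if (is.null(dim(x))) x <- matrix(x[STAT_NAMES], 1,
                                   dimnames = list(NULL, STAT_NAMES))
  sweep(sweep(x[, std$keep, drop = FALSE], 2L, std$mean[std$keep]),
        2L, std$sd[std$keep], "/")
}

accepted_set <- function(obs, table, tolerance, std = NULL) {
  std <- std %||% ref_standardization(table)
  Z <- std_stats(table, std)
  z0 <- std_stats(obs, std)
  d <- sqrt(rowSums(sweep(Z, 2L, z0)^2))
  k <- ceiling(tolerance * nrow(table))
  idx <- order(d)[seq_len(k)]
  list(idx = idx, dist = d[idx], k = k, z = Z[idx, , drop = FALSE],
       z0 = drop(z0))
}

#' ABC scenario choice
#'
#' Selects the accepted set as the `ceiling(tolerance * N)` reference rows
#' closest to the observed statistics in standardized Euclidean distance,
#' then estimates scenario posterior probabilities by the direct method
#' (scenario frequency among accepted rows, normal-approximation binomial
#' CI) and/or multinomial logistic regression of scenario on the centred
#' statistics, evaluated at the observed point (CI from the asymptotic
#' covariance of the intercepts).
#'
#' @param obs observed summary-statistic vector (names of [STAT_NAMES]).
#' @param table an `oak_reftable`.
#' @param tolerance accepted fraction of the table, in (0, 1].
#' @param method `"direct"`, `"logistic"` or `"both"`.
#' @return tibble of class `oak_scenario_choice`: `method`, `scenario`,
#'   `pp`, `ci_lo`, `ci_hi`; attributes `tolerance`, `n_accepted`.
#' @export
choose_scenario <- function(obs, table, tolerance = 0.01,
                            method = c("both", "direct", "logistic")) {
  method <- match.arg(method)
  if (tolerance <= 0 || tolerance > 1)
    abort("tolerance must be in (0, 1]", class = "oakdemog_tolerance_error")
  levs <- levels(table$scenario)
  acc <- accepted_set(obs, table, tolerance)
  if (acc$k < length(levs))
    abort("accepted set smaller than the number of scenarios",
          class = "oakdemog_tolerance_error")
  sc <- table$scenario[acc$idx]
  out <- list()
  if (method %in% c("both", "direct")) {
    p <- as.numeric(table(sc)[levs] / acc$k)
    se <- sqrt(pmax(p * (1 - p), 0) / acc$k)
    out$direct <- tibble(method = "direct", scenario = levs, pp = p,
                         ci_lo = pmax(0, p - 1.96 * se),
                         ci_hi = pmin(1, p + 1.96 * se))
  }
  if (method %in% c("both", "logistic")) {
    out$logistic <- logistic_choice(sc, acc, levs)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "tolerance") <- tolerance
  attr(res, "n_accepted") <- acc$k
  class(res) <- c("oak_scenario_choice", class(res))
  res
}

logistic_choice <- function(sc, acc, levs) {
  X <- sweep(acc$z, 2L, acc$z0)  # centred at the observed point
  present <- levs[levs %in% unique(as.character(sc))]
  if (length(present) == 1L) {
    pp <- as.numeric(levs == present)
    return(tibble(method = "logistic", scenario = levs, pp = pp,
                  ci_lo = pp, ci_hi = pp))
  }
  df <- data.frame(y = factor(as.character(sc), levels = present), X)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 300,
                        MaxNWts = 5000)
  co <- coef(fit)
  if (is.null(dim(co))) co <- matrix(co, 1, dimnames = list(present[2], names(co)))
  eta <- c(0, co[, "(Intercept)"])
  p_present <- exp(eta - max(eta))
  p_present <- p_present / sum(p_present)
  # delta-method variance from the intercept block of the covariance
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  se_present <- rep(NA_real_, length(present))
  if (!is.null(vc)) {
    ii <- grep("\\(Intercept\\)$", rownames(vc))
    V <- vc[ii, ii, drop = FALSE]
    K <- length(present)
    for (i in seq_len(K)) {
      g <- vapply(2:K, function(j) p_present[i] * ((i == j) - p_present[j]),
                  numeric(1))
      se_present[i] <- sqrt(max(0, drop(t(g) %*% V %*% g)))
    }
  }
  pp <- setNames(rep(0, length(levs)), levs)
  se <- setNames(rep(0, length(levs)), levs)
  pp[present] <- p_present
  se[present] <- ifelse(is.na(se_present), 0, se_present)
  tibble(method = "logistic", scenario = levs, pp = unname(pp),
         ci_lo = pmax(0, unname(pp - 1.96 * se)),
         ci_hi = pmin(1, unname(pp + 1.96 * se)))
}

#' @export
print.oak_scenario_choice <- function(x, ...) {
  cat(sprintf("<oak_scenario_choice> tolerance %g, %d accepted\n",
              attr(x, "tolerance"), attr(x, "n_accepted")))
  print(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method autoplot oak_scenario_choice
#' @export
autoplot.oak_scenario_choice <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$scenario, y = .data$pp,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.3) +
    ggplot2::labs(x = "Scenario", y = "Posterior probability") +
    ggplot2::theme_minimal()
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Local-linear ABC parameter estimation
#'
#' Rejection within the focal scenario's reference rows, followed by
#' local-linear regression adjustment (Beaumont-style): each parameter is
#' regressed on the standardized statistics with Epanechnikov weights in
#' distance, and the accepted draws are corrected to the observed point.
#' Sizes and times are adjusted on the log scale and back-transformed; the
#' posterior mode is a Gaussian-kernel density peak (Silverman bandwidth).
#'
#' @inheritParams choose_scenario
#' @param scenario the focal scenario id.
#' @return tibble of class `oak_posterior`: per parameter `mean`, `median`,
#'   `mode`, `q2.5`, `q97.5`; attributes `draws` (adjusted draws + weights),
#'   `n_accepted`, `adjustment`.
#' @export
estimate_params <- function(obs, table, scenario, tolerance = 0.01) {
  rows <- table[table$scenario == scenario, , drop = FALSE]
  if (nrow(rows) < 100)
    abort("fewer than 100 reference rows for the scenario",
          class = "oakdemog_input_error")
  std <- ref_standardization(table)
  acc <- accepted_set(obs, rows, tolerance, std)
  dmax <- max(acc$dist)
  w <- if (dmax > 0) 1 - (acc$dist / dmax)^2 else rep(1, acc$k)
  w[w <= 0] <- min(w[w > 0], 1e-8)
  X <- sweep(acc$z, 2L, acc$z0)
  pars <- used_params(scenario)
  adjustment <- "local-linear"
  draws <- list()
  for (pn in pars) {
    y <- rows[[pn]][acc$idx]
    ylog <- pn %in% LOG_PARAMS
    yt <- if (ylog) log(y) else y
    adj <- tryCatch({
      if (ncol(X) == 0) stop("no informative statistics")
      fit <- stats::lm.wfit(cbind(1, X), yt, w)
      if (any(is.na(fit$coefficients))) stop("singular design")
      yt - drop(X %*% fit$coefficients[-1])
    }, error = function(e) {
      adjustment <<- "rejection-only"
      yt
    })
    draws[[pn]] <- if (ylog) exp(adj) else adj
  }
  if (adjustment == "rejection-only")
    warn("singular local-linear design; falling back to rejection only")
  dr <- as_tibble(draws)
  dr$.weight <- w
  summ <- purrr::map_dfr(pars, function(pn) {
    x <- dr[[pn]]
    dens <- stats::density(x, weights = w / sum(w), bw = stats::bw.nrd0(x))
    q <- weighted_quantile(x, w, c(0.025, 0.5, 0.975))
    tibble(param = pn,
           mean = sum(w * x) / sum(w),
           median = q[2],
           mode = dens$x[which.max(dens$y)],
           q2.5 = q[1], q97.5 = q[3])
  })
  attr(summ, "draws") <- dr
  attr(summ, "n_accepted") <- acc$k
  attr(summ, "adjustment") <- adjustment
  attr(summ, "scenario") <- scenario
  class(summ) <- c("oak_posterior", class(summ))
  summ
}

#' @export
print.oak_posterior <- function(x, ...) {
  cat(sprintf("<oak_posterior> scenario %s, %d accepted (%s)\n",
              attr(x, "scenario"), attr(x, "n_accepted"),
              attr(x, "adjustment")))
  print(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy a posterior summary
#' @param x an `oak_posterior`.
#' @param ... unused.
#' @method tidy oak_posterior
#' @export
tidy.oak_posterior <- function(x, ...) as_tibble(as.data.frame(x))

#' @method glance oak_posterior
#' @export
glance.oak_posterior <- function(x, ...) {
  tibble(scenario = attr(x, "scenario"), n_accepted = attr(x, "n_accepted"),
         adjustment = attr(x, "adjustment"))
}

select_from_choice <- function(choice, method) {
  ch <- choice[choice$method == method, ]
  ch$scenario[which.max(ch$pp)]
}

#' Confidence in scenario choice: type I and II error from PODs
#'
#' Draws pseudo-observed datasets (PODs) from the prior of every scenario,
#' pushes each through [choose_scenario()], and reports, for the focal
#' scenario: type I error (fraction of focal-scenario PODs where the focal
#' scenario is not selected) and type II error (mean over the competing
#' scenarios of the fraction of their PODs in which the focal scenario is
#' selected).
#'
#' @param focal focal scenario id.
#' @param table an `oak_reftable` built over all scenarios.
#' @param n_pods PODs per scenario.
#' @param tolerance accepted fraction for each choice.
#' @param method `"direct"`, `"logistic"` or `"both"`.
#' @param design locus design used to simulate the PODs (defaults to the
#'   table's design).
#' @return tibble of class `oak_confidence`: `method`, `type_I` (fraction of
#'   focal PODs where the focal scenario is not selected), `selection_rate`
#'   (its complement, the probability of selecting the focal scenario when
#'   true), `type_II`; attribute `selections` holds the full per-POD
#'   true/selected record per method.
#' @export
confidence_in_choice <- function(focal, table, n_pods = 100,
                                 tolerance = 0.01,
                                 method = c("both", "direct", "logistic"),
                                 design = NULL) {
  method <- match.arg(method)
  design <- design %||% attr(table, "design") %||% default_locus_design()
  levs <- levels(table$scenario)
  stopifnot(focal %in% levs)
  methods <- if (method == "both") c("direct", "logistic") else method
  sel <- list()
  for (sc in levs) {
    p <- sample_prior(sc, n_pods)
    st <- simulate_stats(p, design)
    sel[[sc]] <- purrr::map_dfr(seq_len(n_pods), function(i) {
      ch <- choose_scenario(st[i, ], table, tolerance, method)
      tibble(true = sc,
             method = methods,
             selected = vapply(methods, function(m)
               as.character(select_from_choice(ch, m)), character(1)))
    })
  }
  sel <- dplyr::bind_rows(sel)
  out <- purrr::map_dfr(methods, function(m) {
    sm <- sel[sel$method == m, ]
    t1 <- mean(sm$selected[sm$true == focal] != focal)
    t2 <- mean(vapply(setdiff(levs, focal), function(sc)
      mean(sm$selected[sm$true == sc] == focal), numeric(1)))
    tibble(method = m, type_I = t1, selection_rate = 1 - t1, type_II = t2)
  })
  attr(out, "selections") <- sel
  attr(out, "focal") <- focal
  class(out) <- c("oak_confidence", class(out))
  out
}

#' Relative median absolute error of ABC parameter estimates
#'
#' PODs are drawn from the focal scenario's prior; each is estimated with
#' [estimate_params()] (posterior median as point estimate) and
#' RMAE = median over PODs of |estimate - truth| / truth is reported per
#' parameter.
#'
#' @inheritParams confidence_in_choice
#' @param scenario focal scenario id.
#' @param n_pods number of PODs.
#' @return tibble: `param`, `rmae`, `n_pods`.
#' @export
rmae_params <- function(scenario, table, n_pods = 100, tolerance = 0.01,
                        design = NULL) {
  design <- design %||% attr(table, "design") %||% default_locus_design()
  p <- sample_prior(scenario, n_pods)
  st <- simulate_stats(p, design)
  pars <- used_params(scenario)
  err <- matrix(NA_real_, n_pods, length(pars),
                dimnames = list(NULL, pars))
  for (i in seq_len(n_pods)) {
    est <- estimate_params(st[i, ], table, scenario, tolerance)
    for (pn in pars)
      err[i, pn] <- abs(est$median[est$param == pn] - p[[pn]][i]) / p[[pn]][i]
  }
  tibble(param = pars, rmae = apply(err, 2L, median), n_pods = n_pods)
}

#' Posterior-predictive goodness of fit with PCA model checking
#'
#' Simulates PODs from the posterior parameter draws of the chosen scenario,
#' reports a two-sided tail probability of the observed value within the POD
#' distribution for each summary statistic, and projects reference rows,
#' PODs and the observation onto the principal components of the
#' standardized reference statistics.
#'
#' @inheritParams choose_scenario
#' @param posterior an `oak_posterior` from [estimate_params()].
#' @param n_pods number of posterior-predictive PODs.
#' @param design locus design (defaults to the table's design).
#' @return object of class `oak_gof`: `$tail` (tibble of per-statistic tail
#'   probabilities), `$pod_scores`, `$obs_scores`, `$ref_scores` (PCA
#'   projections), `$var_explained`.
#' @export
goodness_of_fit <- function(obs, posterior, table, n_pods = 1000,
                            design = NULL) {
  design <- design %||% attr(table, "design") %||% default_locus_design()
  scenario <- attr(posterior, "scenario")
  dr <- attr(posterior, "draws")
  w <- dr$.weight
  idx <- sample.int(nrow(dr), n_pods, replace = TRUE, prob = w / sum(w))
  p <- dr[idx, setdiff(names(dr), ".weight"), drop = FALSE]
  # keep adjusted draws inside the prior box; preserve Tdb < Ta
  for (pn in names(p)) {
    rng <- PRIOR[[pn]] %||% tdb_window(scenario)
    if (pn == "Tdb") rng <- tdb_window(scenario)
    p[[pn]] <- pmin(pmax(p[[pn]], rng[1]), rng[2])
  }
  if (all(c("Ta", "Tdb") %in% names(p)))
    p$Tdb <- pmin(p$Tdb, 0.99 * p$Ta)
  full <- dplyr::bind_cols(
    tibble(scenario = rep(scenario, n_pods)),
    as_tibble(lapply(setNames(PARAM_NAMES, PARAM_NAMES), function(pn)
      if (pn %in% names(p)) p[[pn]] else rep(NA_real_, n_pods))))
  st <- simulate_stats(full, design)
  obs_v <- if (is.data.frame(obs)) unlist(obs[1, STAT_NAMES]) else obs[STAT_NAMES]
  tail <- purrr::map_dfr(STAT_NAMES, function(s) {
    pod <- st[, s]
    r <- (sum(pod < obs_v[s]) + 0.5 * sum(pod == obs_v[s])) / n_pods
    tibble(stat = s, tail_p = max(min(1, 2 * min(r, 1 - r)), 1 / n_pods))
  })
  std <- ref_standardization(table)
  Zr <- std_stats(table, std)
  pca <- prcomp(Zr, center = FALSE, scale. = FALSE)
  pod_sc <- std_stats(st, std) %*% pca$rotation
  obs_sc <- std_stats(obs_v, std) %*% pca$rotation
  structure(list(
    tail = tail,
    pod_scores = as_tibble(pod_sc[, 1:2, drop = FALSE]),
    obs_scores = as_tibble(obs_sc[, 1:2, drop = FALSE]),
    ref_scores = as_tibble((Zr %*% pca$rotation)[, 1:2, drop = FALSE]),
    var_explained = pca$sdev^2 / sum(pca$sdev^2),
    scenario = scenario, n_pods = n_pods), class = "oak_gof")
}

#' @export
print.oak_gof <- function(x, ...) {
  cat(sprintf("<oak_gof> scenario %s, %d posterior-predictive PODs\n",
              x$scenario, x$n_pods))
  print(as.data.frame(x$tail), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @method autoplot oak_gof
#' @export
autoplot.oak_gof <- function(object, ...) {
  pods <- object$pod_scores
  names(pods) <- c("PC1", "PC2")
  obs <- object$obs_scores
  names(obs) <- c("PC1", "PC2")
  ggplot2::ggplot(pods, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.25, colour = "grey40") +
    ggplot2::geom_point(data = obs, colour = "red", size = 3, shape = 17) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$var_explained[2]),
      title = "Posterior-predictive PODs (grey) and observation (red)") +
    ggplot2::theme_minimal()
}
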