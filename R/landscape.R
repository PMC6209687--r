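# Genetic-geographic/ecological association stage: distance matrices,
# Mantel and partial Mantel tests, stepwise-AIC diversity~environment
# regressions.

#' Great-circle geographic distance matrix (km)
#'
#' Haversine distances on a spherical Earth of radius 6371.0 km between
#' population coordinates.
#'
#' @param pops population table (see [read_population_table()]).
#' @return symmetric matrix in km, zero diagonal, attribute
#'   `kind = "geographic-km"`.
#' @export
geographic_distances <- function(pops) {
  pops <- read_population_table(pops)
  n <- nrow(pops)
  xy <- cbind(pops$longitude, pops$latitude)
  M <- matrix(0, n, n, dimnames = list(pops$population_id, pops$population_id))
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(xy[i, , drop = FALSE],
                                  xy[(i + 1):n, , drop = FALSE],
                                  r = 6371000) / 1000
    M[i, (i + 1):n] <- d
    M[(i + 1):n, i] <- d
  }
  attr(M, "kind") <- "geographic-km"
  M
}

#' Scaled-Euclidean ecological distance matrix
#'
#' Each variable is standardized across populations (z-score by default,
#' optionally range scaling) and the Euclidean distance over the variable
#' vector is taken.  Zero-variance variables are dropped with a warning.
#'
#' @param pops population table.
#' @param variables character vector of environmental column names.
#' @param scaling `"zscore"` (sample SD) or `"range"`.
#' @return symmetric matrix, attribute `kind = "ecological-scaled"`.
#' @export
ecological_distances <- function(pops, variables,
                                 scaling = c("zscore", "range")) {
  scaling <- match.arg(scaling)
  pops <- read_population_table(pops)
  miss <- setdiff(variables, names(pops))
  if (length(miss))
    abort(sprintf("variables absent from table: %s", paste(miss, collapse = ", ")),
          class = "oakdemog_input_error")
  X <- as.matrix(pops[, variables, drop = FALSE])
  if (anyNA(X))
    abort("missing environmental values", class = "oakdemog_input_error")
  spread <- if (scaling == "zscore") apply(X, 2L, sd)
            else apply(X, 2L, function(v) diff(range(v)))
  keep <- spread > 0
  if (!all(keep)) {
    warn(sprintf("dropping zero-variance variables: %s",
                 paste(variables[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
    spread <- spread[keep]
  }
  Z <- sweep(sweep(X, 2L, colMeans(X)), 2L, spread, "/")
  M <- as.matrix(dist(Z))
  dimnames(M) <- list(pops$population_id, pops$population_id)
  attr(M, "kind") <- "ecological-scaled"
  M
}

check_conformable <- function(...) {
  ms <- list(...)
  labs <- lapply(ms, rownames)
  if (any(vapply(ms, function(m) is.null(rownames(m)), logical(1))))
    return(invisible(TRUE))
  for (i in seq_along(ms)[-1])
    if (!identical(labs[[1]], labs[[i]]))
      abort("distance matrices have mismatched labels",
            class = "oakdemog_alignment_error")
  invisible(TRUE)
}

upper_vec <- function(M) M[upper.tri(M)]

cor0 <- function(x, y) {
  # Pearson correlation, pairwise-complete, with a zero-variance guard
  # (constant matrices give r = 0 rather than NA)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(0)
  cor(x[ok], y[ok])
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the strictly upper triangles; significance by
#' simultaneously permuting rows and columns of the second matrix, two
#' tailed: \eqn{p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(B + 1)}.
#'
#' @param A,B conformable symmetric distance matrices with matching labels.
#' @param permutations number of permutations (default 999).
#' @return tibble of class `oak_mantel`: `r`, `p_value`, `n_permutations`,
#'   `partialed_on`; attribute `perm_r` holds the permuted statistics.
#' @export
mantel_test <- function(A, B, permutations = 999) {
  check_conformable(A, B)
  a <- upper_vec(A)
  r_obs <- cor0(a, upper_vec(B))
  n <- nrow(A)
  perm_r <- vapply(seq_len(permutations), function(b) {
    idx <- sample.int(n)
    cor0(a, upper_vec(B[idx, idx]))
  }, numeric(1))
  p <- (1 + sum(abs(perm_r) >= abs(r_obs))) / (permutations + 1)
  out <- tibble(r = r_obs, p_value = p, n_permutations = permutations,
                partialed_on = NA_character_)
  attr(out, "perm_r") <- perm_r
  class(out) <- c("oak_mantel", class(out))
  out
}

partial_r <- function(ab, ac, bc) {
  (ab - ac * bc) / sqrt((1 - ac^2) * (1 - bc^2))
}

#' Partial Mantel test
#'
#' First-order partial correlation
#' \eqn{r_{AB.C} = (r_{AB} - r_{AC} r_{BC}) / \sqrt{(1-r_{AC}^2)(1-r_{BC}^2)}}
#' over upper-triangle entries; significance by permuting A and recomputing
#' the partial statistic (two-tailed, as in [mantel_test()]).
#'
#' @param A,B,C conformable distance matrices; C is the controlled matrix.
#' @inheritParams mantel_test
#' @export
partial_mantel_test <- function(A, B, C, permutations = 999) {
  check_conformable(A, B, C)
  a <- upper_vec(A); b <- upper_vec(B); cc <- upper_vec(C)
  r_ac <- cor0(a, cc); r_bc <- cor0(b, cc)
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12)
    abort("control matrix is collinear with an input matrix",
          class = "oakdemog_degenerate_control_error")
  r_obs <- partial_r(cor0(a, b), r_ac, r_bc)
  n <- nrow(A)
  perm_r <- vapply(seq_len(permutations), function(i) {
    idx <- sample.int(n)
    ap <- upper_vec(A[idx, idx])
    partial_r(cor0(ap, b), cor0(ap, cc), r_bc)
  }, numeric(1))
  p <- (1 + sum(abs(perm_r) >= abs(r_obs))) / (permutations + 1)
  kindC <- attr(C, "kind") %||% "control"
  out <- tibble(r = r_obs, p_value = p, n_permutations = permutations,
                partialed_on = kindC)
  attr(out, "perm_r") <- perm_r
  class(out) <- c("oak_mantel", class(out))
  out
}

#' @method autoplot oak_mantel
#' @export
autoplot.oak_mantel <- function(object, ...) {
  df <- data.frame(r = attr(object, "perm_r"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$r, colour = "red") +
    ggplot2::labs(x = "Permutation r", y = "Count",
                  title = sprintf("Mantel r = %.4f, p = %.4f",
                                  object$r, object$p_value)) +
    ggplot2::theme_minimal()
}

# --- stepwise-AIC regression ------------------------------------------------

fit_family <- function(formula, data, family) {
  if (family == "glm") {
    fit <- glm(formula, data = data, family = gaussian())
    list(fit = fit, aic = AIC(fit))
  } else {
    fit <- suppressWarnings(MASS::rlm(formula, data = data, maxit = 100))
    # AIC analogue from the converged Huber-weighted residual sum of squares
    n <- length(fit$residuals)
    rss <- sum(fit$w * fit$residuals^2)
    k <- length(coef(fit)) + 1
    list(fit = fit, aic = n * log(rss / n) + 2 * k)
  }
}

drop_aliased <- function(data, response, predictors) {
  if (length(predictors) < 2) return(predictors)
  X <- as.matrix(data[, predictors, drop = FALSE])
  X <- scale(X)
  kap <- kappa(crossprod(X), exact = TRUE)
  while (is.finite(kap) && kap > 1e8 && length(predictors) > 1) {
    warn("collinear design; dropping an aliased predictor")
    predictors <- predictors[-length(predictors)]
    X <- scale(as.matrix(data[, predictors, drop = FALSE]))
    kap <- kappa(crossprod(X), exact = TRUE)
  }
  predictors
}

#' Stepwise-AIC regression of diversity on environment
#'
#' Greedy forward/backward model search by AIC, starting from the full
#' candidate model, for a Gaussian GLM or a Huber robust linear model
#' (IRLS, MAD scale; its AIC analogue uses the converged weighted residual
#' sum of squares).  Per-predictor univariate fits are also returned.
#'
#' @param data per-population data frame.
#' @param response name of the diversity response column (e.g. `Hd`, `pi`,
#'   `theta_w`).
#' @param predictors character vector of candidate predictor columns.
#' @param family `"glm"` (Gaussian) or `"rlm"` (Huber robust).
#' @param direction currently both directions are always searched.
#' @return object of class `oak_regfit`.
#' @export
stepwise_regression <- function(data, response, predictors,
                                family = c("glm", "rlm"),
                                direction = "both") {
  family <- match.arg(family)
  data <- as.data.frame(data)
  if (nrow(data) <= length(predictors) + 2)
    abort("too few observations for the candidate model",
          class = "oakdemog_input_error")
  predictors <- drop_aliased(data, response, predictors)
  current <- predictors
  make_f <- function(ps) as.formula(
    paste(response, "~", if (length(ps)) paste(ps, collapse = " + ") else "1"))
  best <- fit_family(make_f(current), data, family)
  repeat {
    moves <- list()
    for (p in current)
      moves[[paste0("-", p)]] <- setdiff(current, p)
    for (p in setdiff(predictors, current))
      moves[[paste0("+", p)]] <- c(current, p)
    if (!length(moves)) break
    aics <- vapply(moves, function(ps) fit_family(make_f(ps), data, family)$aic,
                   numeric(1))
    if (min(aics) < best$aic - 1e-8) {
      current <- moves[[which.min(aics)]]
      best <- fit_family(make_f(current), data, family)
    } else break
  }
  fit <- best$fit
  y <- data[[response]]
  r2 <- 1 - sum((y - fitted(fit))^2) / sum((y - mean(y))^2)
  cf <- summary_coefs(fit, family, nrow(data))
  uni <- purrr::map_dfr(predictors, function(p) {
    f1 <- fit_family(make_f(p), data, family)
    cf1 <- summary_coefs(f1$fit, family, nrow(data))
    r21 <- 1 - sum((y - fitted(f1$fit))^2) / sum((y - mean(y))^2)
    tibble(predictor = p, slope = cf1$estimate[2], r_squared = r21,
           p_value = cf1$p_value[2], aic = f1$aic)
  })
  structure(list(
    response = response, family = family,
    selected = current, formula = make_f(current),
    aic = best$aic, r_squared = r2,
    coefficients = cf, univariate = uni, fit = fit,
    n = nrow(data)), class = "oak_regfit")
}

summary_coefs <- function(fit, family, n) {
  cf <- coef(summary(fit))
  df <- n - nrow(cf)
  tb <- tibble(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
               statistic = cf[, 3])
  tb$p_value <- 2 * pt(abs(tb$statistic), df = df, lower.tail = FALSE)
  tb
}

#' @export
print.oak_regfit <- function(x, ...) {
  cat(sprintf("<oak_regfit> %s: %s (AIC %.2f, R^2 %.4f)\n",
              x$family, deparse(x$formula), x$aic, x$r_squared))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy a stepwise regression fit
#' @param x an `oak_regfit`.
#' @param ... unused.
#' @method tidy oak_regfit
#' @export
tidy.oak_regfit <- function(x, ...) x$coefficients

#' @method glance oak_regfit
#' @export
glance.oak_regfit <- function(x, ...) {
  tibble(family = x$family, aic = x$aic, r_squared = x$r_squared,
         n_predictors = length(x$selected), n = x$n)
}
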