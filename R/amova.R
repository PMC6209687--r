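# Analysis of molecular variance (Phi-style, Excoffier-type) on squared
# pairwise sequence distances, with permutation significance, and pairwise
# F_ST matrices.  Distances are counts of differing sites (gaps as a fifth
# state in informative mode, missing excluded pairwise-complete).

# sum of squared distances within each level of a factor, divided by level n
ss_within_levels <- function(D2, f) {
  lv <- unique(f)
  s <- 0
  for (g in lv) {
    idx <- which(f == g)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

amova_components_one <- function(D2, pop) {
  N <- nrow(D2)
  pops <- unique(pop)
  P <- length(pops)
  np <- as.numeric(table(pop)[pops])
  ss_t <- sum(D2) / (2 * N)
  ss_w <- ss_within_levels(D2, pop)
  ss_a <- ss_t - ss_w
  df_a <- P - 1
  df_w <- N - P
  ms_a <- ss_a / df_a
  ms_w <- ss_w / df_w
  n_c <- (N - sum(np^2) / N) / df_a
  sig_w <- ms_w
  sig_a <- (ms_a - ms_w) / n_c
  list(ss = c(among = ss_a, within = ss_w), df = c(df_a, df_w),
       sigma = c(among = sig_a, within = sig_w))
}

phi_from_one <- function(comp) {
  tot <- sum(comp$sigma)
  if (tot <= 0) return(NA_real_)
  unname(comp$sigma["among"] / tot)
}

new_amova <- function(table, phi, perms) {
  structure(list(table = table, phi = phi, n_permutations = perms),
            class = "oak_amova")
}

#' One-level AMOVA with permutation test
#'
#' Decomposes molecular variance among and within populations from squared
#' pairwise sequence distances (Excoffier-style) and reports the fixation
#' index \eqn{\Phi_{ST}} with a permutation p-value obtained by permuting
#' sequences among populations:
#' \eqn{p = (1 + \#\{\Phi_{perm} \ge \Phi_{obs}\})/(B + 1)}.
#'
#' Negative variance components are reported as computed; percentages of
#' variation are computed after flooring negative components at zero (the raw
#' percentages are kept in column `percent_raw`).
#'
#' @param aln a [hap_alignment] sampling at least two populations.
#' @param permutations number of label permutations (default 1000).
#' @param indels_informative see [compute_diversity()].
#' @return an `oak_amova` object; see [tidy.oak_amova()].
#' @export
amova_one_level <- function(aln, permutations = 1000,
                            indels_informative = TRUE) {
  pop <- unname(aln$population_of[aln$sample_ids])
  if (length(unique(pop)) < 2)
    abort("need at least 2 populations", class = "oakdemog_input_error")
  D2 <- pair_diff_matrix(state_matrix(aln, indels_informative))^2
  comp <- amova_components_one(D2, pop)
  phi <- phi_from_one(comp)
  p <- NA_real_
  if (!is.na(phi) && permutations > 0) {
    ge <- 0L
    for (b in seq_len(permutations)) {
      fb <- phi_from_one(amova_components_one(D2, sample(pop)))
      if (!is.na(fb) && fb >= phi) ge <- ge + 1L
    }
    p <- (1 + ge) / (permutations + 1)
  }
  sig <- comp$sigma
  sigf <- pmax(sig, 0)
  tb <- tibble(
    source = c("Among populations", "Within populations"),
    df = comp$df, sum_sq = unname(comp$ss), sigma2 = unname(sig),
    percent_raw = 100 * unname(sig) / sum(sig),
    percent = if (sum(sigf) > 0) 100 * unname(sigf) / sum(sigf) else c(NA, NA),
    statistic = c("Phi_ST", NA), phi = c(phi, NA), p_value = c(p, NA))
  new_amova(tb, c(Phi_ST = phi), permutations)
}

amova_components_two <- function(D2, pop, grp) {
  N <- nrow(D2)
  pops <- unique(pop)
  P <- length(pops)
  G <- length(unique(grp))
  np <- as.numeric(table(pop)[pops])
  grp_of_pop <- grp[match(pops, pop)]
  glev <- unique(grp)
  Ng <- vapply(glev, function(g) sum(np[grp_of_pop == g]), numeric(1))

  ss_t <- sum(D2) / (2 * N)
  ss_w <- ss_within_levels(D2, pop)
  ss_g <- ss_within_levels(D2, grp)   # within-group total SS
  ss_ag <- ss_t - ss_g                # among groups
  ss_ap <- ss_g - ss_w                # among populations within groups
  df_ag <- G - 1
  df_ap <- P - G
  df_w <- N - P
  ms_ag <- ss_ag / df_ag
  ms_ap <- ss_ap / df_ap
  ms_w <- ss_w / df_w
  sum_np2_by_g <- vapply(glev, function(g) sum(np[grp_of_pop == g]^2), numeric(1))
  n1 <- (N - sum(sum_np2_by_g / Ng)) / df_ap
  n2 <- (sum(sum_np2_by_g / Ng) - sum(np^2) / N) / df_ag
  n3 <- (N - sum(Ng^2) / N) / df_ag
  sig_c <- ms_w
  sig_b <- (ms_ap - sig_c) / n1
  sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
  list(ss = c(among_groups = ss_ag, among_pops = ss_ap, within = ss_w),
       df = c(df_ag, df_ap, df_w),
       sigma = c(among_groups = sig_a, among_pops = sig_b, within = sig_c))
}

phis_from_two <- function(comp) {
  s <- comp$sigma
  tot <- sum(s)
  c(Phi_CT = if (tot > 0) unname(s[1] / tot) else NA_real_,
    Phi_SC = if (sum(s[2:3]) > 0) unname(s[2] / sum(s[2:3])) else NA_real_,
    Phi_ST = if (tot > 0) unname(sum(s[1:2]) / tot) else NA_real_)
}

#' Two-level (hierarchical) AMOVA
#'
#' Three-stratum decomposition (among groups / among populations within
#' groups / within populations) with the three Phi-statistics.
#' \eqn{\Phi_{CT}} is tested by permuting whole populations among groups,
#' \eqn{\Phi_{SC}} by permuting sequences among populations within groups,
#' and \eqn{\Phi_{ST}} by permuting sequences among populations.
#'
#' @inheritParams amova_one_level
#' @param groups named vector mapping population id to group (cluster) id,
#'   with at least two groups.
#' @export
amova_two_level <- function(aln, groups, permutations = 1000,
                            indels_informative = TRUE) {
  pop <- unname(aln$population_of[aln$sample_ids])
  grp <- unname(groups[pop])
  if (anyNA(grp))
    abort("groups must cover every population", class = "oakdemog_input_error")
  if (length(unique(grp)) < 2) {
    warn("single group supplied; falling back to one-level AMOVA")
    return(amova_one_level(aln, permutations, indels_informative))
  }
  D2 <- pair_diff_matrix(state_matrix(aln, indels_informative))^2
  comp <- amova_components_two(D2, pop, grp)
  phis <- phis_from_two(comp)

  pops <- unique(pop)
  grp_of_pop <- setNames(grp[match(pops, pop)], pops)
  p <- c(Phi_CT = NA_real_, Phi_SC = NA_real_, Phi_ST = NA_real_)
  if (permutations > 0 && !all(is.na(phis))) {
    ge <- c(0L, 0L, 0L)
    for (b in seq_len(permutations)) {
      # Phi_CT: permute population labels among groups
      g1 <- setNames(sample(unname(grp_of_pop)), pops)[pop]
      f1 <- phis_from_two(amova_components_two(D2, pop, unname(g1)))["Phi_CT"]
      if (!is.na(f1) && !is.na(phis[1]) && f1 >= phis[1]) ge[1] <- ge[1] + 1L
      # Phi_SC: permute sequences among populations within groups
      pop2 <- pop
      for (g in unique(grp)) {
        idx <- which(grp == g)
        pop2[idx] <- pop[sample(idx)]
      }
      f2 <- phis_from_two(amova_components_two(D2, pop2, grp))["Phi_SC"]
      if (!is.na(f2) && !is.na(phis[2]) && f2 >= phis[2]) ge[2] <- ge[2] + 1L
      # Phi_ST: permute sequences among populations
      idx <- sample(length(pop))
      f3 <- phis_from_two(amova_components_two(D2, pop[idx], grp[idx]))["Phi_ST"]
      if (!is.na(f3) && !is.na(phis[3]) && f3 >= phis[3]) ge[3] <- ge[3] + 1L
    }
    p <- (1 + ge) / (permutations + 1)
    p[is.na(phis)] <- NA_real_
  }
  sig <- comp$sigma
  sigf <- pmax(sig, 0)
  tb <- tibble(
    source = c("Among groups", "Among populations within groups",
               "Within populations"),
    df = comp$df, sum_sq = unname(comp$ss), sigma2 = unname(sig),
    percent_raw = 100 * unname(sig) / sum(sig),
    percent = if (sum(sigf) > 0) 100 * unname(sigf) / sum(sigf) else rep(NA_real_, 3),
    statistic = c("Phi_CT", "Phi_SC", "Phi_ST"),
    phi = unname(phis), p_value = unname(p))
  new_amova(tb, phis, permutations)
}

#' Pairwise F_ST distance matrix between populations
#'
#' Two-population Phi-style AMOVA F_ST for every population pair; negative
#' estimates are retained as computed, pairs with zero total variance give
#' `NA`.
#'
#' @inheritParams amova_one_level
#' @return symmetric matrix with zero diagonal, class attribute
#'   `kind = "genetic-FST"`.
#' @export
pairwise_fst <- function(aln, indels_informative = TRUE) {
  pop <- unname(aln$population_of[aln$sample_ids])
  pops <- unique(pop)
  if (length(pops) < 2)
    abort("need at least 2 populations", class = "oakdemog_input_error")
  D2 <- pair_diff_matrix(state_matrix(aln, indels_informative))^2
  k <- length(pops)
  M <- matrix(0, k, k, dimnames = list(pops, pops))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      idx <- which(pop %in% pops[c(a, b)])
      comp <- amova_components_one(D2[idx, idx], pop[idx])
      M[a, b] <- M[b, a] <- phi_from_one(comp)
    }
  }
  attr(M, "kind") <- "genetic-FST"
  M
}

#' @export
print.oak_amova <- function(x, ...) {
  cat(sprintf("<oak_amova> %d permutations\n", x$n_permutations))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy an AMOVA result
#' @param x an `oak_amova` object.
#' @param ... unused.
#' @return tibble with one row per variance stratum.
#' @method tidy oak_amova
#' @export
tidy.oak_amova <- function(x, ...) x$table

#' One-line AMOVA summary
#' @param x an `oak_amova` object.
#' @param ... unused.
#' @method glance oak_amova
#' @export
glance.oak_amova <- function(x, ...) {
  tb <- x$table
  tibble(phi_st = unname(x$phi[length(x$phi)]),
         p_value = tb$p_value[!is.na(tb$p_value)][1] %||% NA_real_,
         n_permutations = x$n_permutations)
}

#' @method autoplot oak_amova
#' @export
autoplot.oak_amova <- function(object, ...) {
  tb <- object$table
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$source, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Percentage of variation") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
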