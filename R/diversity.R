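# Per-locus diversity and neutrality statistics, haplotype accounting and
# the Hudson-Kaplan minimum-recombination bound.
#
# Character-state conventions: 'N' is always missing data.  When
# `indels_informative` is TRUE (the default for these human-facing
# statistics) the gap '-' is a fifth character state entering haplotype
# identity, segregating-site and difference counts; when FALSE it is treated
# like 'N'.  Missing states are excluded pairwise-complete.

state_matrix <- function(aln, indels_informative = TRUE) {
  m <- aln_matrix(aln)
  m[m == "N"] <- NA
  if (!indels_informative) m[m == "-"] <- NA
  m
}

poly_columns <- function(m) {
  nlev <- apply(m, 2L, function(col) length(unique(col[!is.na(col)])))
  which(nlev >= 2L)
}

# pairwise difference counts over polymorphic columns, missing states skipped
pair_diff_matrix <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (s in poly_columns(m)) {
    col <- m[, s]
    ok <- !is.na(col)
    diff <- outer(col, col, "!=")
    diff[!ok, ] <- FALSE
    diff[, !ok] <- FALSE
    D <- D + diff
  }
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

# greedy haplotype assignment; sequences differing only at missing positions
# collapse onto the first compatible haplotype, whose representative is
# completed as new information arrives
haplotype_assign <- function(m) {
  n <- nrow(m)
  reps <- list()
  id <- integer(n)
  for (i in seq_len(n)) {
    x <- m[i, ]
    hit <- 0L
    for (h in seq_along(reps)) {
      r <- reps[[h]]
      ok <- is.na(x) | is.na(r) | x == r
      if (all(ok)) { hit <- h; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- x
      hit <- length(reps)
    } else {
      r <- reps[[hit]]
      r[is.na(r)] <- x[is.na(r)]
      reps[[hit]] <- r
    }
    id[i] <- hit
  }
  list(id = id, reps = reps)
}

tajima_d_from <- function(n, S, pi_total) {
  if (S == 0 || n < 4) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_total - S / a1) / sqrt(v)
}

#' Diversity and neutrality statistics for one locus
#'
#' Computes the standard per-locus summary: sample size, segregating sites,
#' number of distinct haplotypes, haplotype diversity
#' \eqn{Hd = n(1 - \sum p_i^2)/(n-1)}, per-site nucleotide diversity
#' \eqn{\pi}, Watterson's estimator per site
#' \eqn{\theta_W = S/(a_{n-1} L)}, and Tajima's D.  When an ancestral
#' sequence is supplied the MFDM neutrality p-value is included (see
#' [mfdm_test()]).
#'
#' @param aln a [hap_alignment] with at least 2 sequences.
#' @param ancestral optional ancestral sequence (single string, length
#'   matching the alignment) for the MFDM test.
#' @param indels_informative treat `-` as a fifth character state (default
#'   TRUE; the ABC stage instead drops gapped columns).
#' @return one-row tibble with columns `locus`, `n` (gene copies), `n_ind`,
#'   `L`, `L_complete` (columns without missing data), `S`, `Nh`, `Hd`,
#'   `pi`, `theta_w`, `tajima_d`, `mfdm_p`.
#' @export
compute_diversity <- function(aln, ancestral = NULL, indels_informative = TRUE) {
  n <- n_seq(aln)
  if (n < 2) abort("need at least 2 sequences", class = "oakdemog_sample_size_error")
  m <- state_matrix(aln, indels_informative)
  L <- ncol(m)
  Lc <- sum(!apply(is.na(m), 2L, any))
  poly <- poly_columns(m)
  S <- length(poly)
  hap <- haplotype_assign(m)
  Nh <- length(hap$reps)
  p <- tabulate(hap$id) / n
  Hd <- if (S == 0 && Nh == 1) 0 else n * (1 - sum(p^2)) / (n - 1)
  D <- pair_diff_matrix(m)
  pi_total <- mean(D[upper.tri(D)])
  tibble(
    locus = aln$locus_name, n = n,
    n_ind = if (aln$ploidy == "nuclear-phased") n %/% 2L else n,
    L = L, L_complete = Lc, S = S, Nh = Nh, Hd = Hd,
    pi = pi_total / L,
    theta_w = if (n > 1) S / (sum(1 / seq_len(n - 1)) * L) else NA_real_,
    tajima_d = tajima_d_from(n, S, pi_total),
    mfdm_p = if (is.null(ancestral)) NA_real_ else mfdm_test(aln, ancestral))
}

#' Maximum-frequency-of-derived-mutations neutrality test
#'
#' Polarizes each usable segregating site with the supplied ancestral state,
#' finds the maximum derived-allele count \eqn{e} over sites, and reports
#' \eqn{p = \min(1,\, 2(n - e)/(n - 1))}: the tail probability that the most
#' frequent derived mutation reaches frequency \eqn{e/n} on a neutral
#' genealogy.  Sites whose ancestral state is not a plain nucleotide are
#' skipped; `NA` is returned when no usable segregating site exists (the
#' convention for monomorphic partitions).
#'
#' @inheritParams compute_diversity
#' @param ancestral ancestral sequence as a single string (or character
#'   vector of per-site states) of the alignment length.
#' @return p-value in (0, 1], or `NA`.
#' @export
mfdm_test <- function(aln, ancestral, indels_informative = FALSE) {
  if (is.null(ancestral) || !length(ancestral))
    abort("no ancestral information supplied", class = "oakdemog_polarization_error")
  anc <- if (length(ancestral) == 1L)
    strsplit(toupper(ancestral), "", fixed = TRUE)[[1]]
  else toupper(as.character(ancestral))
  m <- state_matrix(aln, indels_informative)
  if (length(anc) != ncol(m))
    abort("ancestral sequence length does not match alignment",
          class = "oakdemog_polarization_error")
  n <- n_seq(aln)
  e <- NA_integer_
  for (s in poly_columns(m)) {
    if (!anc[s] %in% c("A", "C", "G", "T")) next
    col <- m[, s]
    cnt <- table(col[!is.na(col)])
    derived <- cnt[names(cnt) != anc[s]]
    if (!length(derived)) next
    e <- max(e, max(derived), na.rm = TRUE)
  }
  if (is.na(e)) return(NA_real_)
  min(1, 2 * (n - e) / (n - 1))
}

#' Hudson-Kaplan minimum number of recombination events
#'
#' Four-gamete scan over biallelic sites: every pair of sites at which all
#' four haplotypic combinations occur delimits an interval that must contain
#' at least one recombination event; Rm is the size of the largest set of
#' non-overlapping such intervals (greedy reduction by right endpoint).
#'
#' @inheritParams compute_diversity
#' @return non-negative integer Rm (0 whenever S <= 1).
#' @export
min_recomb_events <- function(aln, indels_informative = FALSE) {
  m <- state_matrix(aln, indels_informative)
  biall <- which(apply(m, 2L, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) == 2L
  }))
  if (length(biall) < 2L) return(0L)
  ints <- list()
  for (a in seq_along(biall)[-length(biall)]) {
    for (b in (a + 1L):length(biall)) {
      ca <- m[, biall[a]]; cb <- m[, biall[b]]
      ok <- !is.na(ca) & !is.na(cb)
      if (length(unique(paste(ca[ok], cb[ok]))) == 4L)
        ints[[length(ints) + 1L]] <- c(biall[a], biall[b])
    }
  }
  if (!length(ints)) return(0L)
  ab <- do.call(rbind, ints)
  ord <- order(ab[, 2], ab[, 1])
  rm_ <- 0L
  last_end <- -Inf
  for (k in ord) {
    if (ab[k, 1] >= last_end) {
      rm_ <- rm_ + 1L
      last_end <- ab[k, 2]
    }
  }
  rm_
}

#' Haplotype table with private-haplotype flags
#'
#' Collapses the alignment to distinct haplotypes (missing-tolerant: two
#' sequences differing only where one has missing data share a haplotype),
#' numbers them `H1, H2, ...` by descending count then first occurrence, and
#' flags haplotypes confined to a single population as private.
#'
#' @inheritParams compute_diversity
#' @return tibble with `haplotype_id`, `sequence`, `count`, `populations`
#'   (list column), `private_to` (population id or `NA`).
#' @export
haplotype_table <- function(aln, indels_informative = TRUE) {
  m <- state_matrix(aln, indels_informative)
  hap <- haplotype_assign(m)
  cnt <- tabulate(hap$id)
  first <- match(seq_along(cnt), hap$id)
  ord <- order(-cnt, first)
  pops <- lapply(seq_along(cnt), function(h)
    sort(unique(unname(aln$population_of[aln$sample_ids[hap$id == h]]))))
  seqs <- vapply(hap$reps, function(r) {
    r[is.na(r)] <- "N"
    paste(r, collapse = "")
  }, character(1))
  tibble(
    haplotype_id = paste0("H", seq_along(ord)),
    sequence = seqs[ord],
    count = cnt[ord],
    populations = pops[ord],
    private_to = vapply(pops[ord], function(p)
      if (length(p) == 1L) p else NA_character_, character(1)))
}

#' Diversity statistics across loci and partitions
#'
#' Convenience wrapper producing the per-locus, per-partition summary table:
#' each locus is reported for the full sample and, when a grouping is given,
#' for each cluster separately.
#'
#' @param dataset a [study_dataset()].
#' @param groups optional named vector mapping population id to cluster id.
#' @param ancestral optional named list of ancestral sequences per locus.
#' @inheritParams compute_diversity
#' @return tibble, one row per locus x partition.
#' @export
diversity_table <- function(dataset, groups = NULL, ancestral = NULL,
                            indels_informative = TRUE) {
  purrr::map_dfr(dataset$loci, function(aln) {
    anc <- if (!is.null(ancestral)) ancestral[[aln$locus_name]] else NULL
    full <- dplyr::mutate(
      compute_diversity(aln, anc, indels_informative), partition = "species")
    parts <- list(full)
    if (!is.null(groups)) {
      for (g in sort(unique(groups))) {
        keep <- unname(groups[aln$population_of[aln$sample_ids]]) == g
        sub <- hap_alignment(aln$sequences[keep], aln$sample_ids[keep],
                             aln$population_of[aln$sample_ids[keep]],
                             aln$locus_name, aln$ploidy)
        parts[[length(parts) + 1L]] <- dplyr::mutate(
          compute_diversity(sub, anc, indels_informative), partition = g)
      }
    }
    dplyr::bind_rows(parts)
  }) |>
    dplyr::relocate("partition", .after = "locus")
}
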