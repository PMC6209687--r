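# Shared fixtures and independent oracles.  All fixtures are built in code.

# the four-sequence toy alignment used across diversity/ABC oracle tests:
# two segregating sites, three haplotypes
toy4 <- function(pops = c("p1", "p1", "p2", "p2")) {
  hap_alignment(c("ACGTACGTAC", "ACGTACGTAT", "ACGAACGTAT", "ACGAACGTAT"),
                paste0("s", 1:4), pops)
}

random_aln <- function(n, L, n_states = 4, pops = NULL,
                       ploidy = "nuclear-phased") {
  bases <- c("A", "C", "G", "T")[seq_len(n_states)]
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  hap_alignment(seqs, paste0("s", seq_len(n)),
                pops %||% rep("p1", n), ploidy = ploidy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2 L) brute-force nucleotide diversity: mean pairwise mismatch per site,
# independent of the package's site-wise accumulation
brute_pi <- function(aln) {
  m <- strsplit(aln$sequences, "")
  n <- length(m)
  L <- length(m[[1]])
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[[i]] != "N" & m[[j]] != "N"
    tot <- tot + sum(m[[i]][ok] != m[[j]][ok])
    np <- np + 1
  }
  tot / np / L
}

# brute-force Hudson-Kaplan Rm: enumerate four-gamete-incompatible site
# pairs, then maximum set of non-overlapping intervals by dynamic
# programming (independent of the greedy reduction in the package)
brute_rm <- function(aln) {
  m <- strsplit(aln$sequences, "")
  M <- do.call(rbind, m)
  biall <- which(apply(M, 2, function(col) length(unique(col)) == 2))
  if (length(biall) < 2) return(0L)
  ints <- NULL
  for (a in seq_along(biall)[-length(biall)]) for (b in (a + 1):length(biall)) {
    gam <- unique(paste(M[, biall[a]], M[, biall[b]]))
    if (length(gam) == 4) ints <- rbind(ints, c(biall[a], biall[b]))
  }
  if (is.null(ints)) return(0L)
  ord <- order(ints[, 2])
  ints <- ints[ord, , drop = FALSE]
  k <- nrow(ints)
  dp <- rep(1L, k)
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      if (ints[j, 2] <= ints[i, 1]) dp[i] <- max(dp[i], dp[j] + 1L)
    }
  }
  max(dp)
}

# exact two-tailed Mantel p by full enumeration of relabelings
exact_mantel_p <- function(A, B) {
  n <- nrow(A)
  perms <- gtools_permutations(n)
  a <- A[upper.tri(A)]
  r_obs <- cor(a, B[upper.tri(B)])
  rs <- apply(perms, 1, function(idx) {
    Bp <- B[idx, idx]
    cor(a, Bp[upper.tri(Bp)])
  })
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

random_dist <- function(n) {
  M <- matrix(0, n, n, dimnames = list(paste0("P", 1:n), paste0("P", 1:n)))
  M[upper.tri(M)] <- runif(n * (n - 1) / 2)
  M + t(M)
}

# small locus design for fast simulation-based tests; consistent with a
# (n_pops x inds) sampling design so simulate_dataset() can use it
small_design <- function(n_pops = 2, inds = 5, L_nuc = 200, L_cp = 400)
  list(locus_spec("cp", "plastid", L_cp, n_pops * inds),
       locus_spec("nucA", "nuclear", L_nuc, 2L * n_pops * inds))

# stratified head-subset of a reference table (rows are iid within
# scenario); standardization recomputed on the subset
subset_reftable <- function(rt, n_rows) {
  per <- n_rows %/% length(levels(rt$scenario))
  idx <- unlist(lapply(levels(rt$scenario), function(sc)
    head(which(rt$scenario == sc), per)))
  out <- rt[sort(idx), , drop = FALSE]
  X <- as.matrix(out[, STAT_NAMES])
  attr(out, "stat_mean") <- colMeans(X)
  attr(out, "stat_sd") <- apply(X, 2, sd)
  attr(out, "design") <- attr(rt, "design")
  class(out) <- class(rt)
  out
}

# hand-built reference-table tibble for classifier unit tests
fake_reftable <- function(stats_by_scenario, n_per = 200) {
  levs <- names(stats_by_scenario)
  tb <- purrr::map_dfr(levs, function(sc) {
    gen <- stats_by_scenario[[sc]]
    st <- gen(n_per)
    colnames(st) <- STAT_NAMES
    dplyr::bind_cols(
      tibble::tibble(scenario = rep(sc, n_per),
                     Ne = runif(n_per, 1e3, 1e5), Na = runif(n_per, 1e3, 1e5),
                     Ndb = runif(n_per, 1e3, 1e5), Ta = runif(n_per, 1.25e4, 3.75e4),
                     Tdb = runif(n_per, 75, 1500),
                     mu_cp = runif(n_per, 5e-8, 7e-8),
                     mu_nr = runif(n_per, 1e-7, 3e-7)),
      tibble::as_tibble(st))
  })
  tb$scenario <- factor(tb$scenario, levels = levs)
  X <- as.matrix(tb[, STAT_NAMES])
  attr(tb, "stat_mean") <- colMeans(X)
  attr(tb, "stat_sd") <- apply(X, 2, sd)
  class(tb) <- c("oak_reftable", class(tb))
  tb
}

iid_stats <- function(n) matrix(rnorm(n * 10), n, 10)
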