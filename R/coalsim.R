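# Coalescent simulation under seven piecewise-exponential demographic
# scenarios with HKY mutation.
#
# Scenario catalogue (backward time, generations):
#   S1  constant size Ne for all time
#   S2  exponential decline:  anchors (0 -> Ne, Ta -> Na), Na > Ne
#   S3  exponential growth:   anchors (0 -> Ne, Ta -> Na), Na < Ne
#   S4  expansion then decline, pre-glacial response:
#       anchors (0 -> Ne, Tdb -> Ndb, Ta -> Na), Ndb > max(Ne, Na),
#       Tdb in the last-interglacial-to-LGM window
#   S5  as S4 with Tdb in the LGM-to-Holocene window
#   S6  decline then expansion, pre-glacial: Ndb < min(Ne, Na), LIG-LGM Tdb
#   S7  as S6 with LGM-to-Holocene Tdb
# Between anchors N(t) interpolates exponentially; beyond the last anchor it
# is constant at the ancestral size.  Ne is never constrained against Na.

SCENARIOS <- paste0("S", 1:7)

# prior windows (generations; sizes are diploid Ne)
PRIOR <- list(
  Ne = c(1e3, 1e5), Na = c(1e3, 1e5), Ndb = c(1e3, 1e5),
  Ta = c(1.25e4, 3.75e4),
  Tdb_preglacial = c(2.5e2, 1.5e3),   # LIG -> LGM response, 20-120 ka at 80 y
  Tdb_postglacial = c(75, 275),       # LGM -> Holocene response, 6-22 ka
  mu_cp = c(5e-8, 7e-8), mu_nr = c(1e-7, 3e-7))

scenario_ok <- function(id) {
  if (!id %in% SCENARIOS)
    abort(sprintf("unknown scenario '%s'", id), class = "oakdemog_input_error")
  id
}

tdb_window <- function(id) {
  switch(id,
         S4 = , S6 = PRIOR$Tdb_preglacial,
         S5 = , S7 = PRIOR$Tdb_postglacial,
         c(NA_real_, NA_real_))
}

scenario_constraints <- function(id, p) {
  switch(id,
         S1 = rep(TRUE, nrow(p)),
         S2 = p$Na > p$Ne,
         S3 = p$Na < p$Ne,
         S4 = , S5 = p$Ndb > p$Na & p$Ndb > p$Ne & p$Tdb < p$Ta,
         S6 = , S7 = p$Ndb < p$Na & p$Ndb < p$Ne & p$Tdb < p$Ta)
}

#' Draw demographic parameters from a scenario's prior
#'
#' Uniform priors: `Ne`, `Na`, `Ndb` in `[1e3, 1e5]` (diploid sizes), `Ta` in
#' `[1.25e4, 3.75e4]` generations (1-3 Ma at 80 y/generation), `Tdb` in a
#' scenario-specific window (`S4`/`S6`: `[250, 1500]`; `S5`/`S7`:
#' `[75, 275]` generations), `mu_cp` in `[5e-8, 7e-8]` and `mu_nr` in
#' `[1e-7, 3e-7]` per site per generation.  Scenario ordering constraints
#' (e.g. `Ndb > max(Ne, Na)` for S4/S5) are enforced by rejection; `Ne` is
#' never constrained against `Na`.
#'
#' @param scenario scenario id, `"S1"` to `"S7"`.
#' @param n number of draws.
#' @return tibble with columns `scenario`, `Ne`, `Na`, `Ndb`, `Ta`, `Tdb`,
#'   `mu_cp`, `mu_nr`.  Parameters a scenario does not use are still drawn
#'   from their marginal prior (and ignored by the simulator).
#' @export
sample_prior <- function(scenario, n = 1) {
  scenario_ok(scenario)
  tw <- tdb_window(scenario)
  out <- NULL
  tries <- 0L
  while (is.null(out) || nrow(out) < n) {
    m <- max(n, 2L * (n - if (is.null(out)) 0L else nrow(out)))
    p <- tibble(
      scenario = scenario,
      Ne = runif(m, PRIOR$Ne[1], PRIOR$Ne[2]),
      Na = runif(m, PRIOR$Na[1], PRIOR$Na[2]),
      Ndb = runif(m, PRIOR$Ndb[1], PRIOR$Ndb[2]),
      Ta = runif(m, PRIOR$Ta[1], PRIOR$Ta[2]),
      Tdb = if (is.na(tw[1])) rep(NA_real_, m) else runif(m, tw[1], tw[2]),
      mu_cp = runif(m, PRIOR$mu_cp[1], PRIOR$mu_cp[2]),
      mu_nr = runif(m, PRIOR$mu_nr[1], PRIOR$mu_nr[2]))
    keep <- scenario_constraints(scenario, p)
    out <- dplyr::bind_rows(out, p[keep, , drop = FALSE])
    tries <- tries + m
    if (tries > 1e6 && nrow(out) < n)
      abort("prior rejection loop failed", class = "oakdemog_prior_error")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Demographic anchors implied by a scenario and parameter draw
#'
#' @param scenario scenario id.
#' @param params one-row data frame or named list with the fields of
#'   [sample_prior()].
#' @return list with numeric vectors `t` (generations, starting at 0) and
#'   `N` (diploid effective sizes).
#' @export
scenario_anchors <- function(scenario, params) {
  scenario_ok(scenario)
  p <- as.list(params)
  switch(scenario,
         S1 = list(t = 0, N = p$Ne),
         S2 = , S3 = list(t = c(0, p$Ta), N = c(p$Ne, p$Na)),
         list(t = c(0, p$Tdb, p$Ta), N = c(p$Ne, p$Ndb, p$Na)))
}

#' Locus specification for simulation
#'
#' @param name locus label.
#' @param group `"plastid"` or `"nuclear"`.
#' @param length alignment length in bp.
#' @param sample_size number of gene copies.
#' @param size_multiplier effective-size multiplier on the diploid 2N
#'   scaling: 1 for nuclear autosomal loci, 0.5 for the maternally inherited
#'   haploid plastid.
#' @param kappa HKY transition/transversion rate ratio.
#' @param freqs stationary base frequencies (A, C, G, T), summing to 1.
#' @export
locus_spec <- function(name, group = c("nuclear", "plastid"), length,
                       sample_size, size_multiplier = NULL, kappa = 2,
                       freqs = rep(0.25, 4)) {
  group <- match.arg(group)
  if (length <= 0 || sample_size < 1)
    abort("invalid locus dimensions", class = "oakdemog_input_error")
  if (abs(sum(freqs) - 1) > 1e-8)
    abort("base frequencies must sum to 1", class = "oakdemog_input_error")
  structure(list(
    name = name, group = group, length = as.integer(length),
    sample_size = as.integer(sample_size),
    size_multiplier = size_multiplier %||% if (group == "plastid") 0.5 else 1,
    kappa = kappa, freqs = freqs), class = "locus_spec")
}

#' The study's three-locus sampling design
#'
#' Two phased nuclear loci of 336 and 434 bp with 210 gene copies each
#' (21 populations x 5 diploid individuals x 2), and one concatenated
#' plastid locus of 1814 bp with 105 copies.
#'
#' @param nuclear_n,plastid_n sample sizes (gene copies).
#' @param nuclear_lengths,plastid_length locus lengths in bp.
#' @export
default_locus_design <- function(nuclear_n = 210, plastid_n = 105,
                                 nuclear_lengths = c(336, 434),
                                 plastid_length = 1814) {
  c(list(locus_spec("cpDNA", "plastid", plastid_length, plastid_n)),
    purrr::imap(nuclear_lengths, function(L, i)
      locus_spec(paste0("nuc", c("A", "B", letters)[i]), "nuclear", L, nuclear_n)))
}

# --- pure-R coalescent engine (independent of the compiled path) -----------

# integrated pair-coalescence rate machinery on piecewise-exponential N(t)
traj_growth <- function(anchors) {
  k <- length(anchors$t)
  g <- rep(0, k)
  if (k > 1)
    for (i in seq_len(k - 1))
      g[i] <- log(anchors$N[i + 1] / anchors$N[i]) / (anchors$t[i + 1] - anchors$t[i])
  g
}

# waiting time from `from` until integrated pair rate reaches `target`
traj_wait <- function(anchors, mult, from, target) {
  g <- traj_growth(anchors)
  k <- length(anchors$t)
  a <- from
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      if (anchors$t[i + 1] <= a) next
      lo <- max(a, anchors$t[i])
      gi <- g[i]; Ni <- anchors$N[i]; ti <- anchors$t[i]
      cc <- 2 * mult * Ni
      avail <- if (abs(gi) < 1e-12) (anchors$t[i + 1] - lo) / cc
               else (exp(-gi * (lo - ti)) - exp(-gi * (anchors$t[i + 1] - ti))) / (cc * gi)
      if (target <= avail) {
        b <- if (abs(gi) < 1e-12) lo + target * cc
             else ti - log(exp(-gi * (lo - ti)) - cc * gi * target) / gi
        return(b - from)
      }
      target <- target - avail
    }
  }
  lo <- max(a, anchors$t[k])
  lo + target * 2 * mult * anchors$N[k] - from
}

# merge active lineages until one remains or t_max is reached; `nodes` is a
# list of subtrees (tip labels, ape-style edge fragments)
coalesce_lineages <- function(lineages, anchors, mult, t_start = 0,
                              t_max = Inf) {
  t <- t_start
  while (length(lineages$id) >= 2) {
    k <- length(lineages$id)
    target <- stats::rexp(1) / (k * (k - 1) / 2)
    dt <- traj_wait(anchors, mult, t, target)
    if (t + dt > t_max) { lineages$time <- t_max; return(lineages) }
    t <- t + dt
    pick <- sample.int(k, 2)
    new_id <- lineages$next_id
    lineages$next_id <- new_id + 1L
    lineages$merges <- rbind(lineages$merges,
                             c(new_id, lineages$id[pick[1]],
                               lineages$id[pick[2]], t))
    lineages$node_time[as.character(new_id)] <- t
    lineages$id <- c(lineages$id[-pick], new_id)
  }
  lineages$time <- t
  lineages
}

#' Simulate a coalescent genealogy (reference R implementation)
#'
#' Single-population n-coalescent with time-varying size: the
#' pair-coalescence rate at backward time `t` is
#' \eqn{1/(2\,N(t)\,m)} per generation, where `m` is the locus
#' size multiplier (1 diploid nuclear, 0.5 plastid) and N(t) interpolates
#' exponentially between the scenario anchors.  Waiting times are drawn by
#' closed-form inversion of the integrated rate within each exponential
#' epoch.  This engine is independent of the compiled simulator used by the
#' ABC batch path and serves as its cross-check.
#'
#' @param params parameter draw (see [sample_prior()]).
#' @param scenario scenario id.
#' @param locus a [locus_spec()].
#' @return an `ape::phylo` tree with branch lengths in generations (tip
#'   labels `t1..tn`), or `NULL` for `sample_size` 0; a single-leaf tree is
#'   returned as a degenerate phylo with one tip.
#' @export
simulate_genealogy <- function(params, scenario, locus) {
  anchors <- scenario_anchors(scenario, params)
  n <- locus$sample_size
  if (n == 0) return(NULL)
  if (n == 1) {
    tr <- structure(list(edge = matrix(integer(0), 0, 2),
                         tip.label = "t1", Nnode = 0L,
                         edge.length = numeric(0)), class = "phylo")
    return(tr)
  }
  lin <- list(id = seq_len(n), next_id = n + 1L,
              merges = matrix(numeric(0), 0, 4),
              node_time = setNames(rep(0, n), as.character(seq_len(n))))
  lin <- coalesce_lineages(lin, anchors, locus$size_multiplier)
  merges_to_phylo(lin$merges, n)
}

# build an ape phylo from (new_id, child1, child2, time) merge records
merges_to_phylo <- function(merges, n) {
  n_int <- nrow(merges)
  # ape numbering: tips 1..n, root n+1, internals follow
  root_old <- merges[n_int, 1]
  old_ids <- c(seq_len(n), rev(merges[, 1]))        # root first among internals
  new_of <- setNames(c(seq_len(n), n + seq_len(n_int)),
                     as.character(c(seq_len(n), rev(merges[, 1]))))
  node_time <- c(setNames(rep(0, n), as.character(seq_len(n))),
                 setNames(merges[, 4], as.character(merges[, 1])))
  edge <- matrix(0L, 2 * n_int, 2)
  elen <- numeric(2 * n_int)
  r <- 1L
  for (i in seq_len(n_int)) {
    par <- merges[i, 1]
    for (ch in merges[i, 2:3]) {
      edge[r, ] <- c(new_of[as.character(par)], new_of[as.character(ch)])
      elen[r] <- merges[i, 4] - node_time[as.character(ch)]
      r <- r + 1L
    }
  }
  storage.mode(edge) <- "integer"
  structure(list(edge = edge, edge.length = elen,
                 tip.label = paste0("t", seq_len(n)), Nnode = n_int),
            class = "phylo")
}

#' Evolve sequences along a genealogy under HKY (reference R implementation)
#'
#' The root sequence is drawn from the stationary base frequencies; each
#' branch then evolves by a uniformized HKY jump chain whose rate matrix is
#' scaled so the stationary mean substitution rate equals `mu` per site per
#' generation.  No gaps are generated.
#'
#' @param tree `ape::phylo` with branch lengths in generations.
#' @param mu per-site per-generation substitution rate.
#' @param locus a [locus_spec()] (length, kappa, base frequencies).
#' @param sample_ids,populations optional labels/population assignment for
#'   the output alignment (defaults: tree tip labels, one population).
#' @return a [hap_alignment] with attribute `ancestral` (root sequence).
#' @export
mutate_hky <- function(tree, mu, locus, sample_ids = NULL,
                       populations = NULL) {
  L <- locus$length
  bases <- c("A", "C", "G", "T")
  freqs <- locus$freqs
  kappa <- locus$kappa
  # rate matrix and uniformization
  ti_partner <- c(3, 4, 1, 2)
  q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j)
    q[i, j] <- (if (j == ti_partner[i]) kappa else 1) * freqs[j]
  leave <- rowSums(q)
  scale <- mu / sum(freqs * leave)
  q <- q * scale; leave <- leave * scale
  R <- max(leave)
  P <- q / R; diag(P) <- 1 - leave / R

  ntip <- length(tree$tip.label)
  root_seq <- sample.int(4, L, replace = TRUE, prob = freqs)
  seqs <- matrix(0L, ntip, L)
  if (ntip == 1 || nrow(tree$edge) == 0) {
    seqs[1, ] <- root_seq
  } else {
    nnode <- ntip + tree$Nnode
    # sparse events: per branch Poisson(len * R * L), assigned to sites
    n_ed <- nrow(tree$edge)
    ev_counts <- stats::rpois(n_ed, tree$edge.length * R * L)
    ev_site <- vector("list", n_ed)
    for (e in seq_len(n_ed))
      if (ev_counts[e] > 0)
        ev_site[[e]] <- sample.int(L, ev_counts[e], replace = TRUE)
    hit_sites <- sort(unique(unlist(ev_site)))
    # per-site evolution in preorder
    ord <- preorder_edges(tree)
    full <- matrix(rep(root_seq, each = ntip), ntip, L)
    if (length(hit_sites)) {
      node_state <- integer(nnode)
      for (s in hit_sites) {
        node_state[ntip + 1L] <- root_seq[s]
        for (e in ord) {
          par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
          st <- node_state[par]
          k <- sum(ev_site[[e]] == s)
          if (k > 0) for (j in seq_len(k))
            st <- sample.int(4, 1, prob = P[st, ])
          node_state[ch] <- st
        }
        full[, s] <- node_state[seq_len(ntip)]
      }
    }
    seqs <- full
  }
  seq_str <- apply(matrix(bases[seqs], nrow(seqs), L), 1, paste, collapse = "")
  ids <- sample_ids %||% tree$tip.label
  pops <- populations %||% rep("pop1", length(ids))
  out <- hap_alignment(seq_str, ids, pops, locus_name = locus$name,
                       ploidy = if (locus$group == "plastid") "plastid"
                                else "nuclear-phased")
  attr(out, "ancestral") <- paste(bases[root_seq], collapse = "")
  out
}

preorder_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- integer(0)
  stack <- as.character(root)
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    es <- children[[nd]]
    for (e in es) {
      out <- c(out, e)
      ch <- tree$edge[e, 2]
      if (ch > ntip) stack <- c(stack, as.character(ch))
    }
  }
  out
}

# assemble the default 21x5 population labels for a design sample size
design_labels <- function(n, ploidy, n_populations = 21, inds_per_pop = 5) {
  pops <- sprintf("P%02d", seq_len(n_populations))
  if (ploidy == "nuclear-phased") {
    per_pop <- 2L * inds_per_pop
    stopifnot(n == n_populations * per_pop)
    inds <- paste0(rep(pops, each = inds_per_pop), "_I",
                   rep(seq_len(inds_per_pop), n_populations))
    list(ids = paste0(rep(inds, each = 2), c("_a", "_b")),
         pops = rep(pops, each = per_pop),
         inds = rep(inds, each = 2))
  } else {
    stopifnot(n == n_populations * inds_per_pop)
    inds <- paste0(rep(pops, each = inds_per_pop), "_I",
                   rep(seq_len(inds_per_pop), n_populations))
    list(ids = inds, pops = rep(pops, each = inds_per_pop), inds = inds)
  }
}

#' Simulate a complete multilocus dataset under one scenario
#'
#' Draws an independent genealogy per locus and evolves sequences under HKY;
#' the plastid group uses `mu_cp`, the nuclear group `mu_nr`.  Sequences are
#' assigned to populations in input order (the study design: 21 populations
#' of 5 diploid individuals).
#'
#' @inheritParams simulate_genealogy
#' @param design list of [locus_spec()]s (default [default_locus_design()]).
#' @param n_populations,inds_per_pop sampling design.
#' @param engine `"compiled"` (fast C++ path) or `"r"` (reference
#'   implementation).
#' @return a [study_dataset()]; each alignment carries its ancestral
#'   sequence as attribute `ancestral`.
#' @export
simulate_dataset <- function(scenario, params, design = default_locus_design(),
                             n_populations = 21, inds_per_pop = 5,
                             engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  anchors <- scenario_anchors(scenario, params)
  bases <- c("A", "C", "G", "T")
  loci <- lapply(design, function(sp) {
    mu <- if (sp$group == "plastid") params$mu_cp else params$mu_nr
    lab <- design_labels(sp$sample_size,
                         if (sp$group == "plastid") "plastid" else "nuclear-phased",
                         n_populations, inds_per_pop)
    if (engine == "compiled") {
      sim <- .sim_locus_cpp(sp$sample_size, sp$length, anchors$t, anchors$N,
                            sp$size_multiplier, mu, sp$kappa, sp$freqs, TRUE)
      seqs <- apply(matrix(bases[sim$full + 1L], nrow(sim$full), ncol(sim$full)),
                    1, paste, collapse = "")
      aln <- hap_alignment(seqs, lab$ids, lab$pops, locus_name = sp$name,
                           ploidy = if (sp$group == "plastid") "plastid"
                                    else "nuclear-phased",
                           individuals = lab$inds)
      attr(aln, "ancestral") <- paste(bases[sim$anc_full + 1L], collapse = "")
      aln
    } else {
      tr <- simulate_genealogy(params, scenario, sp)
      mutate_hky(tr, mu, sp, sample_ids = lab$ids, populations = lab$pops)
    }
  })
  groups <- list(
    plastid = vapply(Filter(function(s) s$group == "plastid", design),
                     function(s) s$name, character(1)),
    nuclear = vapply(Filter(function(s) s$group == "nuclear", design),
                     function(s) s$name, character(1)))
  groups <- Filter(length, groups)
  study_dataset(loci, groups)
}
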