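# Synthetic-study generator: complete multilocus datasets with the
# statistical structure the analysis pipeline assumes (21 populations x 5
# diploid individuals, two nuclear loci + one plastid concatenation,
# optional two-cluster structure, tunable isolation by distance/ecology),
# so every stage is testable without any external data.

#' Configuration for a synthetic study
#'
#' Defaults emulate the study design the pipeline targets: 21 populations
#' of 5 diploid individuals, nuclear loci of 336 and 434 bp (210 phased
#' copies), one plastid concatenation of 1814 bp (105 copies) carrying 5
#' indel columns, and an expansion-then-decline demographic history
#' (scenario S4 at its reported posterior point: Ne 3.29e4, Ndb 7.35e4,
#' Na 1.66e4, Ta 24000 and Tdb 878 generations, mu_cp 5.9e-8, mu_nr
#' 1.78e-7).
#'
#' @param seed integer seed driving the whole bundle.
#' @param scenario demographic scenario id.
#' @param params optional parameter draw (default: the posterior point
#'   above for S4, otherwise a prior draw).
#' @param n_populations,inds_per_pop sampling design.
#' @param nuclear_lengths,plastid_length,indel_columns locus design.
#' @param n_pops_cluster2 populations labelled as the second phylogenetic
#'   cluster (the remainder form cluster 1).
#' @param cluster_split_time optional split time in generations; when set,
#'   the two clusters evolve as demes exchanging no migrants since that
#'   time, layered on the global scenario.
#' @param ibe_strength,ibd_strength in `[0, 1]`: magnitude of the
#'   cluster-linked environmental shift and of spatial autocorrelation in
#'   the environmental variables.
#' @param fix_plastid sample a single maternal plastid lineage per
#'   population (each population fixed for one haplotype).
#' @param env_variables names of the environmental variables generated.
#' @export
synth_config <- function(seed = 1, scenario = "S4", params = NULL,
                         n_populations = 21, inds_per_pop = 5,
                         nuclear_lengths = c(336, 434),
                         plastid_length = 1814, indel_columns = 5,
                         n_pops_cluster2 = 6, cluster_split_time = NULL,
                         ibe_strength = 0, ibd_strength = 0,
                         fix_plastid = FALSE,
                         env_variables = c("BIO1", "BIO4", "BIO12", "BIO15",
                                           "BIO17", "carbon_density",
                                           "soil_moisture", "soil_pH")) {
  if (n_populations < 2 || ibe_strength < 0 || ibe_strength > 1 ||
      ibd_strength < 0 || ibd_strength > 1)
    abort("invalid synthetic-study configuration", class = "oakdemog_config_error")
  if (n_pops_cluster2 >= n_populations)
    abort("cluster 2 must leave at least one population in cluster 1",
          class = "oakdemog_config_error")
  if (is.null(params)) {
    params <- if (scenario == "S4")
      tibble(scenario = "S4", Ne = 3.29e4, Na = 1.66e4, Ndb = 7.35e4,
             Ta = 24000, Tdb = 877.5, mu_cp = 5.93e-8, mu_nr = 1.78e-7)
    else NULL
  }
  if (!is.null(cluster_split_time) && !is.null(params) &&
      cluster_split_time >= params$Ta)
    abort("cluster split time must predate the ancestral time Ta... set it below Ta",
          class = "oakdemog_config_error")
  structure(list(
    seed = seed, scenario = scenario, params = params,
    n_populations = n_populations, inds_per_pop = inds_per_pop,
    nuclear_lengths = nuclear_lengths, plastid_length = plastid_length,
    indel_columns = indel_columns, n_pops_cluster2 = n_pops_cluster2,
    cluster_split_time = cluster_split_time,
    ibe_strength = ibe_strength, ibd_strength = ibd_strength,
    fix_plastid = fix_plastid, env_variables = env_variables),
    class = "synth_config")
}

cluster_labels <- function(cfg) {
  pops <- sprintf("P%02d", seq_len(cfg$n_populations))
  grp <- rep("cluster1", cfg$n_populations)
  if (cfg$n_pops_cluster2 > 0)
    grp[seq(cfg$n_populations - cfg$n_pops_cluster2 + 1, cfg$n_populations)] <-
      "cluster2"
  setNames(grp, pops)
}

#' Generate coordinates and environmental covariates only
#'
#' Populations are placed on a jittered grid spanning roughly 10 x 8
#' degrees; environmental variables are drawn around realistic temperate
#' baselines with a spatial (latitudinal/longitudinal) trend proportional
#' to `ibd_strength` and a cluster-2 contrast proportional to
#' `ibe_strength`: temperature seasonality (BIO4) shifted up and
#' precipitation seasonality (BIO15) given a broader spread.
#'
#' @param cfg a [synth_config()].
#' @return population table (tibble) with `population_id`, `group_id`,
#'   coordinates and the configured environmental columns.
#' @export
generate_env_only <- function(cfg) {
  set.seed(cfg$seed + 1L)
  np <- cfg$n_populations
  grp <- cluster_labels(cfg)
  ncol_grid <- ceiling(sqrt(np))
  row <- (seq_len(np) - 1) %/% ncol_grid
  col <- (seq_len(np) - 1) %% ncol_grid
  nrow_grid <- max(row) + 1
  lon <- 104 + 10 * col / max(1, ncol_grid - 1) + runif(np, -0.4, 0.4)
  lat <- 32 + 8 * row / max(1, nrow_grid - 1) + runif(np, -0.4, 0.4)
  lat_z <- as.numeric(scale(lat))
  lon_z <- as.numeric(scale(lon))
  ibd <- cfg$ibd_strength
  ibe <- cfg$ibe_strength
  c2 <- as.numeric(grp == "cluster2")
  base <- list(
    BIO1 = list(mean = 110, sd = 15, trend = -20),     # 0.1 degC units
    BIO4 = list(mean = 900, sd = 40, trend = 60),
    BIO12 = list(mean = 550, sd = 60, trend = -80),
    BIO15 = list(mean = 75, sd = 6, trend = 8),
    BIO17 = list(mean = 15, sd = 5, trend = -4),
    carbon_density = list(mean = 90, sd = 20, trend = 15),
    soil_moisture = list(mean = 20, sd = 4, trend = 3),
    soil_pH = list(mean = 7, sd = 0.4, trend = 0.2))
  env <- lapply(cfg$env_variables, function(v) {
    b <- base[[v]] %||% list(mean = 0, sd = 1, trend = 0.5)
    tr <- if (v %in% c("BIO12", "carbon_density")) lon_z else lat_z
    x <- b$mean + ibd * b$trend * tr + rnorm(np, 0, b$sd)
    if (v == "BIO4") x <- x + ibe * 6 * b$sd * c2
    if (v == "BIO15") x <- x + ibe * rnorm(np, 0, 3 * b$sd) * c2 +
                            ibe * 3 * b$sd * c2
    x
  })
  names(env) <- cfg$env_variables
  dplyr::bind_cols(
    tibble(population_id = names(grp), group_id = unname(grp),
           latitude = lat, longitude = lon),
    as_tibble(env))
}

# structured genealogy: two demes (no migration) merging at split_time,
# each following the global trajectory; pure-R engine
simulate_genealogy_split <- function(deme_of_tip, split_time, anchors, mult) {
  n <- length(deme_of_tip)
  lin <- list(id = integer(0), next_id = n + 1L,
              merges = matrix(numeric(0), 0, 4),
              node_time = setNames(rep(0, n), as.character(seq_len(n))))
  remaining <- list()
  for (d in unique(deme_of_tip)) {
    sub <- lin
    sub$id <- which(deme_of_tip == d)
    sub$merges <- matrix(numeric(0), 0, 4)
    sub <- coalesce_lineages(sub, anchors, mult, 0, split_time)
    remaining[[as.character(d)]] <- sub$id
    lin$merges <- rbind(lin$merges, sub$merges)
    lin$next_id <- max(lin$next_id, sub$next_id)
    lin$node_time <- c(lin$node_time, sub$node_time[
      setdiff(names(sub$node_time), names(lin$node_time))])
  }
  lin$id <- unlist(remaining, use.names = FALSE)
  lin <- coalesce_lineages(lin, anchors, mult, split_time, Inf)
  # renumber internal ids so merge records are sequential for merges_to_phylo
  ord <- order(lin$merges[, 4])
  merges <- lin$merges[ord, , drop = FALSE]
  remap <- setNames(c(seq_len(n), n + seq_len(nrow(merges))),
                    as.character(c(seq_len(n), merges[, 1])))
  merges[, 1] <- remap[as.character(merges[, 1])]
  merges[, 2] <- remap[as.character(merges[, 2])]
  merges[, 3] <- remap[as.character(merges[, 3])]
  merges_to_phylo(merges, n)
}

insert_indel_columns <- function(aln, k) {
  if (k <= 0) return(aln)
  m <- aln_matrix(aln)
  n <- nrow(m)
  poly <- poly_columns(state_matrix(aln, FALSE))
  for (j in seq_len(k)) {
    if (length(poly)) {
      s <- if (length(poly) == 1) poly else sample(poly, 1)
      col <- m[, s]
      allele <- names(sort(table(col), decreasing = FALSE))[1]
      carriers <- which(col == allele)
    } else {
      carriers <- which(runif(n) < 0.25)
      if (!length(carriers)) carriers <- 1L
    }
    newcol <- rep("A", n)
    newcol[carriers] <- "-"
    at <- sample.int(ncol(m) + 1, 1)
    m <- cbind(m[, seq_len(at - 1), drop = FALSE], newcol,
               m[, seq(at, length.out = ncol(m) - at + 1), drop = FALSE])
  }
  out <- mat_to_aln(m, aln)
  out
}

#' Generate a complete synthetic study
#'
#' Simulates genealogies under the configured scenario (optionally with a
#' two-cluster split: the labelled clusters evolve as demes without
#' migration since `cluster_split_time`), evolves sequences under HKY,
#' inserts the configured plastid indel columns, and attaches coordinates
#' and environmental covariates from [generate_env_only()].  The same seed
#' reproduces the bundle exactly.
#'
#' @param cfg a [synth_config()].
#' @return list of class `oak_synth_study` with `$dataset` (a
#'   [study_dataset()] whose population table carries cluster labels) and
#'   `$truth` (seed, scenario, parameters, cluster labels, ancestral
#'   sequences).
#' @export
generate_study <- function(cfg) {
  set.seed(cfg$seed)
  params <- cfg$params %||% sample_prior(cfg$scenario, 1)
  grp <- cluster_labels(cfg)
  np <- cfg$n_populations
  # the configured plastid length includes the indel columns inserted below
  specs <- c(
    list(locus_spec("cpDNA", "plastid", cfg$plastid_length - cfg$indel_columns,
                    if (cfg$fix_plastid) np else np * cfg$inds_per_pop)),
    purrr::imap(cfg$nuclear_lengths, function(L, i)
      locus_spec(paste0("nuc", LETTERS[i]), "nuclear", L,
                 np * cfg$inds_per_pop * 2L)))
  anchors <- scenario_anchors(cfg$scenario, params)
  split <- cfg$cluster_split_time
  loci <- lapply(specs, function(sp) {
    mu <- if (sp$group == "plastid") params$mu_cp else params$mu_nr
    copies_per_pop <- sp$sample_size / np
    lab <- if (sp$group == "plastid" && cfg$fix_plastid)
      list(ids = sprintf("P%02d_cp", seq_len(np)),
           pops = sprintf("P%02d", seq_len(np)),
           inds = sprintf("P%02d_cp", seq_len(np)))
    else design_labels(sp$sample_size,
                       if (sp$group == "plastid") "plastid" else "nuclear-phased",
                       np, cfg$inds_per_pop)
    aln <- if (is.null(split)) {
      ds <- simulate_dataset(cfg$scenario, params, list(sp),
                             n_populations = np,
                             inds_per_pop = as.integer(copies_per_pop /
                               if (sp$group == "plastid") 1 else 2))
      a <- ds$loci[[1]]
      a$sample_ids <- lab$ids
      names(a$population_of) <- lab$ids
      a$individuals <- lab$inds
      a
    } else {
      deme <- as.integer(grp[lab$pops] == "cluster2") + 1L
      tr <- simulate_genealogy_split(deme, split, anchors, sp$size_multiplier)
      mutate_hky(tr, mu, sp, sample_ids = lab$ids, populations = lab$pops)
    }
    if (sp$group == "plastid") {
      if (cfg$fix_plastid) {
        # expand the single maternal lineage to the sampled individuals
        reps <- cfg$inds_per_pop
        full_lab <- design_labels(np * reps, "plastid", np, reps)
        anc <- attr(aln, "ancestral")
        aln <- hap_alignment(rep(aln$sequences, each = reps),
                             full_lab$ids, full_lab$pops,
                             locus_name = sp$name, ploidy = "plastid",
                             individuals = full_lab$inds)
        attr(aln, "ancestral") <- anc
      }
      anc <- attr(aln, "ancestral")
      aln <- insert_indel_columns(aln, cfg$indel_columns)
      attr(aln, "ancestral") <- anc   # ancestral refers to gap-free columns
    }
    aln
  })
  pops_tb <- generate_env_only(cfg)
  ds <- study_dataset(
    loci,
    list(plastid = "cpDNA",
         nuclear = vapply(specs[-1], function(s) s$name, character(1))),
    populations = pops_tb)
  truth <- list(seed = cfg$seed, scenario = cfg$scenario, params = params,
                cluster_of = grp, cluster_split_time = split,
                ancestral = setNames(lapply(ds$loci, attr, "ancestral"),
                                     names(ds$loci)))
  structure(list(dataset = ds, truth = truth, config = cfg),
            class = "oak_synth_study")
}

#' Write a synthetic study bundle to disk
#'
#' Emits one FASTA per locus, the popmap TSV, the population/environment
#' TSV, an ancestral-state FASTA and a plain-text truth manifest.
#'
#' @param study an `oak_synth_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- study$dataset
  for (aln in ds$loci) {
    write_fasta(aln, file.path(dir, paste0(aln$locus_name, ".fasta")))
    write_popmap(aln, file.path(dir, paste0(aln$locus_name, ".popmap.tsv")))
  }
  utils::write.table(ds$populations, file.path(dir, "populations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  anc <- study$truth$ancestral
  writeLines(unlist(purrr::imap(anc, function(s, nm) c(paste0(">", nm), s))),
             file.path(dir, "ancestral.fasta"))
  pr <- study$truth$params
  manifest <- c(
    sprintf("seed\t%d", study$truth$seed),
    sprintf("scenario\t%s", study$truth$scenario),
    sprintf("%s\t%g", names(pr)[-1], unlist(pr[-1])),
    sprintf("cluster_split_time\t%s",
            study$truth$cluster_split_time %||% "none"))
  writeLines(manifest, file.path(dir, "truth.tsv"))
  invisible(dir)
}
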