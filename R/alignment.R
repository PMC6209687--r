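#' Aligned haplotype sequences for one locus
#'
#' The universal genetic container of the pipeline: an alignment of phased
#' haplotype sequences with a sample-to-population mapping.  Sequences are
#' stored as uppercase strings over `A,C,G,T,-,N`; `-` marks an alignment gap
#' (indel) and `N` missing data.
#'
#' @param sequences character vector of equal-length aligned sequences.
#' @param sample_ids character vector of sequence labels (unique).
#' @param populations character vector (parallel to `sequences`) or named
#'   vector mapping label to population id.
#' @param locus_name single string.
#' @param ploidy `"nuclear-phased"` (two gene copies per diploid individual)
#'   or `"plastid"` (one maternally inherited copy per individual).
#' @param individuals optional character vector of individual ids parallel to
#'   `sequences`; phased copies of one individual share an id.
#'
#' @return an object of class `hap_alignment`.
#' @export
hap_alignment <- function(sequences, sample_ids, populations,
                          locus_name = "locus",
                          ploidy = c("nuclear-phased", "plastid"),
                          individuals = NULL) {
  ploidy <- match.arg(ploidy)
  sequences <- toupper(as.character(sequences))
  sample_ids <- as.character(sample_ids)
  if (length(sequences) != length(sample_ids))
    abort("sequences and sample_ids differ in length", class = "oakdemog_alignment_error")
  if (anyDuplicated(sample_ids))
    abort("duplicated sample ids", class = "oakdemog_mapping_error")
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L)
    abort(sprintf("sequences are not aligned: lengths %s",
                  paste(unique(lens), collapse = ", ")),
          class = "oakdemog_alignment_error")
  if (length(sequences) == 0L || lens[1] < 1L)
    abort("empty alignment", class = "oakdemog_alignment_error")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    abort(sprintf("invalid characters in sequences: %s",
                  paste(head(sample_ids[bad]), collapse = ", ")),
          class = "oakdemog_content_error")
  if (is.null(names(populations))) {
    if (length(populations) != length(sequences))
      abort("populations must be parallel to sequences or named by label",
            class = "oakdemog_mapping_error")
    pop_of <- setNames(as.character(populations), sample_ids)
  } else {
    missing_lab <- setdiff(sample_ids, names(populations))
    if (length(missing_lab))
      abort(sprintf("labels missing from population map: %s",
                    paste(head(missing_lab), collapse = ", ")),
            class = "oakdemog_mapping_error")
    pop_of <- setNames(as.character(populations[sample_ids]), sample_ids)
  }
  if (ploidy == "nuclear-phased") {
    cnt <- table(pop_of)
    if (any(cnt %% 2L != 0L))
      abort("nuclear-phased locus: odd number of gene copies in some population",
            class = "oakdemog_alignment_error")
  }
  structure(
    list(locus_name = locus_name, sequences = sequences,
         sample_ids = sample_ids, population_of = pop_of,
         ploidy = ploidy, individuals = individuals),
    class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %s (%s): %d sequences x %d bp, %d populations\n",
              x$locus_name, x$ploidy, n_seq(x), aln_length(x),
              length(unique(x$population_of))))
  invisible(x)
}

#' Number of sequences (gene copies) in an alignment
#' @param aln a [hap_alignment].
#' @export
n_seq <- function(aln) length(aln$sequences)

#' Alignment length in base pairs
#' @param aln a [hap_alignment].
#' @export
aln_length <- function(aln) nchar(aln$sequences[1])

#' Alignment as a character matrix (sequences x sites)
#' @param aln a [hap_alignment].
#' @export
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$sequences, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$sequences), byrow = TRUE)
  rownames(m) <- aln$sample_ids
  m
}

mat_to_aln <- function(m, template, locus_name = template$locus_name) {
  hap_alignment(apply(m, 1L, paste, collapse = ""),
                template$sample_ids, template$population_of,
                locus_name = locus_name, ploidy = template$ploidy,
                individuals = template$individuals)
}

#' Read an aligned FASTA with a population map
#'
#' @param path path to an aligned FASTA file.
#' @param popmap path to a 3-column TSV (`sequence_label`, `individual_id`,
#'   `population_id`) listing every FASTA record, or a data frame of the same
#'   shape.
#' @param locus_name locus label; defaults to the file name.
#' @param ploidy see [hap_alignment()].
#' @return a [hap_alignment], in FASTA record order.
#' @export
read_fasta <- function(path, popmap, locus_name = NULL,
                       ploidy = c("nuclear-phased", "plastid")) {
  ploidy <- match.arg(ploidy)
  ss <- Biostrings::readBStringSet(path)
  labs <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  pm <- if (is.data.frame(popmap)) popmap else read_popmap(popmap)
  missing_lab <- setdiff(labs, pm$sequence_label)
  if (length(missing_lab))
    abort(sprintf("FASTA labels missing from popmap: %s",
                  paste(head(missing_lab), collapse = ", ")),
          class = "oakdemog_mapping_error")
  pop <- setNames(pm$population_id, pm$sequence_label)
  ind <- setNames(pm$individual_id, pm$sequence_label)
  hap_alignment(seqs, labs, pop[labs],
                locus_name = locus_name %||% sub("\\.[^.]*$", "", basename(path)),
                ploidy = ploidy, individuals = unname(ind[labs]))
}

#' Write an alignment to FASTA
#' @param aln a [hap_alignment].
#' @param path output path.
#' @export
write_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(setNames(aln$sequences, aln$sample_ids))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read or write the 3-column population map
#'
#' Tab-separated with header `sequence_label individual_id population_id`;
#' phased copies of one individual are conventionally named `<ind>_a`,
#' `<ind>_b`.
#' @param path TSV path.
#' @return tibble with the three columns.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("sequence_label", "individual_id", "population_id")
  if (!all(need %in% names(pm)))
    abort(sprintf("popmap must have columns %s", paste(need, collapse = ", ")),
          class = "oakdemog_mapping_error")
  as_tibble(pm[need])
}

#' @rdname read_popmap
#' @param aln a [hap_alignment] to derive the map from.
#' @export
write_popmap <- function(aln, path) {
  ind <- aln$individuals %||% sub("_[ab]$", "", aln$sample_ids)
  utils::write.table(
    data.frame(sequence_label = aln$sample_ids, individual_id = ind,
               population_id = unname(aln$population_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove alignment columns containing gaps
#'
#' Drops every column in which at least one sequence carries `-`.  Used ahead
#' of the ABC stage, where indel columns are discarded; the removed column
#' indices are recorded in attribute `removed_columns`.
#'
#' @param aln a [hap_alignment].
#' @return a gap-free [hap_alignment]; idempotent.
#' @export
drop_gap_columns <- function(aln) {
  m <- aln_matrix(aln)
  gap <- apply(m == "-", 2L, any)
  if (all(gap))
    abort("every column contains a gap", class = "oakdemog_empty_alignment_error")
  out <- if (any(gap)) mat_to_aln(m[, !gap, drop = FALSE], aln) else aln
  attr(out, "removed_columns") <- which(gap)
  out
}

#' Read a population table with coordinates and ecological covariates
#'
#' Tab-separated; requires `population_id`, `latitude`, `longitude`, accepts
#' an optional `group_id` (phylogenetic cluster) and any number of numeric
#' environmental columns (e.g. BIO1, BIO4, ..., soil variables).
#'
#' @param path TSV path or data frame.
#' @return tibble, one row per population.
#' @export
read_population_table <- function(path) {
  tb <- if (is.data.frame(path)) path
        else utils::read.delim(path, header = TRUE, sep = "\t")
  tb <- as_tibble(tb)
  need <- c("population_id", "latitude", "longitude")
  if (!all(need %in% names(tb)))
    abort(sprintf("population table must have columns %s",
                  paste(need, collapse = ", ")),
          class = "oakdemog_input_error")
  if (any(tb$latitude < -90 | tb$latitude > 90) ||
      any(tb$longitude < -180 | tb$longitude > 180))
    abort("coordinates out of range", class = "oakdemog_input_error")
  tb
}

#' Bundle loci, locus groups and population metadata into one study
#'
#' @param loci list of [hap_alignment] objects.
#' @param locus_groups named list mapping group name (`"plastid"`,
#'   `"nuclear"`) to locus names.
#' @param populations optional population table (see
#'   [read_population_table()]).
#' @param generation_time_years generation time used to convert coalescent
#'   times to years (default 80, a long-lived temperate oak).
#' @return an object of class `study_dataset`.
#' @export
study_dataset <- function(loci, locus_groups, populations = NULL,
                          generation_time_years = 80) {
  if (generation_time_years <= 0)
    abort("generation_time_years must be > 0", class = "oakdemog_input_error")
  names(loci) <- vapply(loci, function(a) a$locus_name, character(1))
  all_named <- unlist(locus_groups, use.names = FALSE)
  if (!setequal(all_named, names(loci)) || anyDuplicated(all_named))
    abort("every locus must belong to exactly one group",
          class = "oakdemog_input_error")
  structure(list(loci = loci, locus_groups = locus_groups,
                 populations = populations,
                 generation_time_years = generation_time_years),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d loci (%s), generation time %g y\n",
              length(x$loci),
              paste(sprintf("%s: %s", names(x$locus_groups),
                            vapply(x$locus_groups, paste, character(1),
                                   collapse = "+")),
                    collapse = "; "),
              x$generation_time_years))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
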