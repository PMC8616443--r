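#' Synthetic allele-frequency catalog
#'
#' A built-in, fully synthetic stand-in for a global class I
#' allele-frequency catalog (CIWD-style): per locus, a dozen common
#' alleles carrying most of the mass plus a tail of rarer ones, with the
#' frequencies of the three loci each summing to 1/3 so the whole catalog
#' sums to 1. Allele names are real common HLA alleles; the frequencies
#' are plausible but synthetic.
#'
#' @return data frame with columns \code{allele}, \code{frequency}.
#' @export
default_allele_catalog <- function() {
  common <- list(
    A = c("A*02:01" = 23, "A*24:02" = 12, "A*01:01" = 12, "A*03:01" = 10,
          "A*11:01" = 9, "A*26:01" = 5, "A*68:01" = 4, "A*31:01" = 4,
          "A*32:01" = 3, "A*23:01" = 3, "A*30:01" = 3, "A*33:01" = 3),
    B = c("B*07:02" = 11, "B*35:01" = 9, "B*08:01" = 8, "B*44:02" = 8,
          "B*40:01" = 8, "B*51:01" = 8, "B*15:01" = 7, "B*44:03" = 6,
          "B*18:01" = 6, "B*57:01" = 4, "B*58:01" = 4, "B*13:02" = 3),
    C = c("C*07:01" = 15, "C*07:02" = 15, "C*04:01" = 12, "C*06:02" = 9,
          "C*03:04" = 9, "C*05:01" = 7, "C*12:03" = 6, "C*01:02" = 6,
          "C*03:03" = 5, "C*08:02" = 5, "C*02:02" = 5, "C*16:01" = 4)
  )
  rare <- list(
    A = c("A*25:01", "A*29:02", "A*66:01", "A*69:01", "A*34:02",
          "A*36:01", "A*74:01", "A*80:01"),
    B = c("B*14:02", "B*27:05", "B*38:01", "B*39:01", "B*41:01",
          "B*48:01", "B*53:01", "B*81:01"),
    C = c("C*14:02", "C*15:02", "C*17:01", "C*08:01", "C*04:03",
          "C*07:04", "C*18:01", "C*03:02")
  )
  rows <- lapply(c("A", "B", "C"), function(l) {
    w <- c(common[[l]], stats::setNames(rep(0.4, length(rare[[l]])), rare[[l]]))
    data.frame(allele = names(w),
               frequency = unname(w) / sum(w) / 3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample an HLA-genotyped model population
#'
#' Draws, for every subject, two alleles per locus independently from the
#' (per-locus renormalized) allele-frequency catalog; homozygosity arises
#' naturally. Loci are sampled independently (no linkage disequilibrium).
#'
#' @param size number of subjects.
#' @param catalog allele-frequency catalog (columns \code{allele},
#'   \code{frequency}); default \code{\link{default_allele_catalog}}.
#' @param seed optional integer seed; a fixed seed reproduces the
#'   population exactly.
#' @return an \code{hla_population}.
#' @export
sample_population <- function(size, catalog = default_allele_catalog(),
                              seed = NULL) {
  size <- as.integer(size)
  if (size < 1L) stop("population size must be >= 1")
  catalog <- validate_catalog(catalog)
  catalog$locus <- substr(catalog$allele, 1L, 1L)
  draws <- with_seed(seed, {
    lapply(c("A", "B", "C"), function(l) {
      sub <- catalog[catalog$locus == l, , drop = FALSE]
      if (nrow(sub) == 0L) stop("catalog has no alleles at locus ", l)
      if (sum(sub$frequency) <= 0) stop("locus ", l, " has zero total frequency")
      matrix(sample(sub$allele, 2L * size, replace = TRUE,
                    prob = sub$frequency / sum(sub$frequency)),
             ncol = 2L)
    })
  })
  hla_population(data.frame(
    subject_id = sprintf("S%04d", seq_len(size)),
    A1 = draws[[1]][, 1], A2 = draws[[1]][, 2],
    B1 = draws[[2]][, 1], B2 = draws[[2]][, 2],
    C1 = draws[[3]][, 1], C2 = draws[[3]][, 2],
    stringsAsFactors = FALSE))
}

#' Sample random protein antigens
#'
#' Uniform residues over the 20-letter amino-acid alphabet; lengths drawn
#' uniformly from \code{length_range} unless given explicitly.
#'
#' @param count number of antigens.
#' @param length_range integer range of lengths (min >= 9); ignored when
#'   \code{lengths} is supplied.
#' @param lengths optional explicit length per antigen.
#' @param prefix antigen id prefix (ids are \code{prefix1, prefix2, ...}).
#' @param seed optional integer seed.
#' @return named character vector of sequences.
#' @export
sample_antigens <- function(count, length_range = c(100L, 600L),
                            lengths = NULL, prefix = "AG", seed = NULL) {
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  with_seed(seed, {
    if (is.null(lengths)) {
      lengths <- sample(length_range[1]:length_range[2], count,
                        replace = TRUE)
    }
    lengths <- as.integer(rep_len(lengths, count))
    if (any(lengths < 9L)) stop("antigen lengths must be >= 9")
    seqs <- vapply(lengths, function(L) {
      paste(sample(.AA20, L, replace = TRUE), collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0(prefix, seq_len(count)))
  })
}

#' Sample a binding table with planted promiscuity
#'
#' Generates sparse (peptide, allele) binder records under a two-stage
#' model: each pair is a "seed" binder with probability
#' \code{base_binder_rate}; for peptides with at least one seed binder,
#' every remaining allele additionally binds with probability
#' \code{base_binder_rate * promiscuity_boost} (capped at 1). A boost
#' above 1 therefore plants multi-allele ("promiscuous") epitopes at a
#' tunable excess over independence. Binder percentile ranks are drawn
#' uniformly below the binder threshold; non-binding pairs are simply
#' absent from the table.
#'
#' The defaults emulate the conventional strong-binder operating point: a
#' rank <= 2 binder is by definition the top 2\% of random peptides for an
#' allele (\code{base_binder_rate = 0.02}), and a boost of 3 makes roughly
#' a quarter of the epitopes binding a 6-allele genotype bind two or more
#' of its alleles.
#'
#' @param peptides character vector of k-mers.
#' @param alleles character vector of allele names.
#' @param base_binder_rate per-pair seed binder probability.
#' @param promiscuity_boost multiplier for additional alleles of an
#'   already-binding peptide.
#' @param binder_threshold percentile-rank binder cutoff stored in the
#'   table (default 2).
#' @param seed optional integer seed.
#' @return a \code{binding_table} containing the binder records.
#' @export
sample_binding_table <- function(peptides, alleles, base_binder_rate = 0.02,
                                 promiscuity_boost = 3,
                                 binder_threshold = 2, seed = NULL) {
  peptides <- unique(toupper(peptides))
  alleles <- unique(as.character(parse_allele(alleles)))
  if (length(peptides) == 0L || length(alleles) == 0L) {
    stop("peptides and alleles must be non-empty")
  }
  if (base_binder_rate < 0 || base_binder_rate > 1) {
    stop("base_binder_rate must lie in [0, 1]")
  }
  np <- length(peptides); na <- length(alleles)
  with_seed(seed, {
    seed_hit <- matrix(stats::runif(np * na) < base_binder_rate,
                       nrow = np)
    boosted_rate <- min(1, base_binder_rate * promiscuity_boost)
    extra <- matrix(stats::runif(np * na) < boosted_rate, nrow = np)
    extra <- extra & !seed_hit & (rowSums(seed_hit) > 0L)
    bind <- seed_hit | extra
    idx <- which(bind, arr.ind = TRUE)
    recs <- data.frame(
      peptide = peptides[idx[, 1]],
      allele = alleles[idx[, 2]],
      percentile_rank = stats::runif(nrow(idx), 0, binder_threshold),
      stringsAsFactors = FALSE)
    binding_table(recs, binder_threshold = binder_threshold)
  })
}

#' Simulate noisy trial outcomes from a known in silico truth
#'
#' For each vaccine, the "true" response probability is its in silico
#' rate over the model population under \code{truth_spec}; the measured
#' responder count is a binomial draw at that probability over the trial
#' cohort. This yields trial records whose ground truth is known, for
#' parameter-recovery experiments.
#'
#' @param population an \code{hla_population}.
#' @param vaccines list of \code{vaccine} objects.
#' @param table a \code{binding_table} covering the vaccines' peptides.
#' @param truth_spec the \code{irr_spec} whose rate drives outcomes.
#' @param cohort_sizes trial cohort sizes (recycled across vaccines).
#' @param seed optional integer seed for the binomial noise.
#' @param k window length (default 9).
#' @return data frame with columns \code{trial_id}, \code{vaccine_id},
#'   \code{irr_responders}, \code{irr_total}, \code{true_rate}.
#' @export
simulate_trials <- function(population, vaccines, table, truth_spec,
                            cohort_sizes, seed = NULL, k = 9L) {
  if (length(vaccines) == 0L) stop("no vaccines supplied")
  cohort_sizes <- as.integer(rep_len(cohort_sizes, length(vaccines)))
  if (any(cohort_sizes < 1L)) stop("cohort sizes must be >= 1")
  truth <- vapply(vaccines, function(v) {
    in_silico_irr(population, v, table, truth_spec, k = k)$rate
  }, numeric(1))
  responders <- with_seed(seed, stats::rbinom(length(vaccines),
                                              cohort_sizes, truth))
  data.frame(
    trial_id = sprintf("T%03d", seq_along(vaccines)),
    vaccine_id = vapply(vaccines, `[[`, "", "vaccine_id"),
    irr_responders = responders,
    irr_total = cohort_sizes,
    true_rate = truth,
    stringsAsFactors = FALSE)
}

#' Write a complete synthetic toy workspace
#'
#' Generates a small, fully self-consistent input set -- genotype CSV,
#' antigen FASTA, binding TSV, allele-frequency CSV and trial-records CSV
#' -- in the pipeline's own file formats, so every reader and the
#' command-line interface can be exercised without external data.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; component seeds are derived via
#'   \code{\link{child_seed}}.
#' @param n_subjects,n_vaccines,antigen_length workspace dimensions.
#' @return invisibly, a named list of the written file paths.
#' @export
make_fixture_workspace <- function(dir, seed = 1L, n_subjects = 20L,
                                   n_vaccines = 3L, antigen_length = 60L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- default_allele_catalog()
  pop <- sample_population(n_subjects, catalog,
                           seed = child_seed(seed, "population"))
  ags <- sample_antigens(2L * n_vaccines, lengths = antigen_length,
                         seed = child_seed(seed, "antigens"))
  vaccines <- lapply(seq_len(n_vaccines), function(i) {
    vaccine(paste0("VX", i), ags[(2L * i - 1L):(2L * i)])
  })
  windows <- scan_peptides(ags)
  tbl <- sample_binding_table(windows$peptide, population_alleles(pop),
                              seed = child_seed(seed, "binding"))
  trials <- simulate_trials(pop, vaccines, tbl, irr_spec(3),
                            cohort_sizes = 50L,
                            seed = child_seed(seed, "trials"))
  trials$crr_responders <- NA_integer_
  trials$crr_total <- NA_integer_
  trials$restriction <- ""
  trials$per_peptide <- FALSE
  trials$true_rate <- NULL
  paths <- list(
    genotypes = file.path(dir, "genotypes.csv"),
    antigens = file.path(dir, "antigens.fasta"),
    binding = file.path(dir, "binding.tsv"),
    frequencies = file.path(dir, "allele_frequencies.csv"),
    trials = file.path(dir, "trials.csv"))
  write_genotypes(pop, paths$genotypes)
  write_antigens(ags, paths$antigens)
  write_binding_table(tbl, paths$binding)
  utils::write.csv(catalog, paths$frequencies, row.names = FALSE)
  utils::write.csv(trials, paths$trials, row.names = FALSE)
  invisible(paths)
}
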