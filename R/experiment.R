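#' Planted-signal recovery of the HLA threshold
#'
#' End-to-end simulation experiment: trial outcomes are generated from
#' the in silico rate at one "true" HLA threshold, and the full estimator
#' grid is then correlated against the noisy measured rates. When the
#' model is self-consistent, the measured-vs-predicted Pearson r is
#' maximized, on average over replicates, at the planted threshold --
#' the synthetic analogue of recovering which threshold best explains
#' real trial outcomes.
#'
#' Each replicate samples a fresh genotyped cohort, a panel of
#' single-antigen vaccines of varying length, a promiscuous binding
#' table and binomially noisy trial outcomes; all streams are derived
#' from the replicate's master seed via \code{\link{child_seed}}.
#'
#' @param seed master seed; replicate r uses \code{seed + r - 1}.
#' @param n_seeds number of replicates (default 10).
#' @param n_vaccines vaccines per replicate (default 40).
#' @param pop_size model-population size (default 100).
#' @param cohort_size trial cohort size (default 200).
#' @param length_range antigen length range in aa (default 15..80, so
#'   that predicted rates vary across vaccines at every threshold).
#' @param truth_threshold the planted HLA threshold (default 3).
#' @param thresholds thresholds evaluated (default 1:4).
#' @param ... passed to \code{\link{sample_binding_table}}.
#' @return data frame with columns \code{threshold}, \code{mean_r}
#'   (average Pearson r over replicates; a replicate where a threshold's
#'   predicted rates are constant contributes r = 0 there), and
#'   \code{n_seeds}; attribute \code{per_seed} holds the full r matrix.
#' @export
recover_hla_threshold <- function(seed = 1L, n_seeds = 10L,
                                  n_vaccines = 40L, pop_size = 100L,
                                  cohort_size = 200L,
                                  length_range = c(15L, 80L),
                                  truth_threshold = 3L,
                                  thresholds = 1:4, ...) {
  rmat <- matrix(NA_real_, nrow = n_seeds, ncol = length(thresholds),
                 dimnames = list(NULL, paste0("n", thresholds)))
  for (r in seq_len(n_seeds)) {
    s <- seed + r - 1L
    pop <- sample_population(pop_size, seed = child_seed(s, "population"))
    ags <- sample_antigens(n_vaccines, length_range = length_range,
                           prefix = "AG", seed = child_seed(s, "antigens"))
    vaccines <- lapply(seq_len(n_vaccines), function(i) {
      vaccine(paste0("VX", i), ags[i])
    })
    tbl <- sample_binding_table(scan_peptides(ags)$peptide,
                                population_alleles(pop),
                                seed = child_seed(s, "binding"), ...)
    trials <- simulate_trials(pop, vaccines, tbl,
                              irr_spec(truth_threshold),
                              cohort_sizes = cohort_size,
                              seed = child_seed(s, "trials"))
    measured <- trials$irr_responders / trials$irr_total
    for (j in seq_along(thresholds)) {
      predicted <- vapply(vaccines, function(v) {
        in_silico_irr(pop, v, tbl, irr_spec(thresholds[j]))$rate
      }, numeric(1))
      rmat[r, j] <- tryCatch(pearson_with_p(measured, predicted)$r,
                             error = function(e) 0)
    }
  }
  out <- data.frame(threshold = thresholds, mean_r = colMeans(rmat),
                    n_seeds = n_seeds)
  attr(out, "per_seed") <- rmat
  out
}
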