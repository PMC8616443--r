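#' Specification of an in silico response-rate estimator
#'
#' The estimator grid has three axes: the minimum number of qualifying
#' vaccine-specific epitopes per subject (1 or 2), the minimum number of
#' distinct source antigens among them (1, or 2 for the multi-antigen
#' variant), and the HLA threshold n -- an epitope qualifies for a subject
#' when it is predicted to bind at least n of the subject's distinct
#' autologous HLA class I alleles.
#'
#' @param hla_threshold integer n in 1..6; the default reporting grid is
#'   1..4 (thresholds 5 and 6 are computable but flagged out-of-grid,
#'   since epitopes binding that many alleles are vanishingly rare).
#' @param min_epitopes 1 or 2.
#' @param min_antigens 1 or 2; \code{min_antigens = 2} requires
#'   \code{min_epitopes >= 2}.
#' @return list with class \code{"irr_spec"}.
#' @examples
#' irr_spec(3)                                  # In silico IRR (3 x HLA)
#' irr_spec(4, min_epitopes = 2)                # multi-epitope IRR (4 x HLA)
#' irr_spec(1, min_epitopes = 2, min_antigens = 2)  # multi-Ag IRR (1 x HLA)
#' @export
irr_spec <- function(hla_threshold, min_epitopes = 1L, min_antigens = 1L) {
  hla_threshold <- as.integer(hla_threshold)
  min_epitopes <- as.integer(min_epitopes)
  min_antigens <- as.integer(min_antigens)
  if (!hla_threshold %in% 1:6) stop("hla_threshold must be in 1..6")
  if (!min_epitopes %in% 1:2) stop("min_epitopes must be 1 or 2")
  if (!min_antigens %in% 1:2) stop("min_antigens must be 1 or 2")
  if (min_antigens == 2L && min_epitopes < 2L) {
    stop("min_antigens = 2 requires min_epitopes >= 2")
  }
  structure(list(min_epitopes = min_epitopes, min_antigens = min_antigens,
                 hla_threshold = hla_threshold,
                 out_of_grid = hla_threshold > 4L),
            class = "irr_spec")
}

spec_label <- function(spec) {
  base <- if (spec$min_antigens >= 2L) "multi-Ag IRR"
  else if (spec$min_epitopes >= 2L) "multi-epitope IRR"
  else "IRR"
  sprintf("in silico %s (%d x HLA)", base, spec$hla_threshold)
}

#' @export
print.irr_spec <- function(x, ...) {
  cat(spec_label(x),
      if (x$out_of_grid) " [outside the default 1..4 grid]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Exact rate as a responder / total pair
#'
#' @param numerator responder count (integer, \code{0 <= numerator <=
#'   denominator}).
#' @param denominator total count (integer, \code{>= 1}).
#' @return list with fields \code{numerator}, \code{denominator},
#'   \code{rate}, class \code{"rate_point"}.
#' @export
rate_point <- function(numerator, denominator) {
  numerator <- as.integer(round(numerator))
  denominator <- as.integer(round(denominator))
  if (denominator < 1L) stop("denominator must be >= 1")
  if (numerator < 0L || numerator > denominator) {
    stop("numerator must lie in 0..denominator")
  }
  structure(list(numerator = numerator, denominator = denominator,
                 rate = numerator / denominator),
            class = "rate_point")
}

#' @export
print.rate_point <- function(x, ...) {
  cat(sprintf("%d/%d = %.4f\n", x$numerator, x$denominator, x$rate))
  invisible(x)
}

#' Does a subject's epitope profile meet an estimator's criteria?
#'
#' @param profile an \code{epitope_profile} from
#'   \code{\link{build_subject_profile}}.
#' @param spec an \code{irr_spec}.
#' @return \code{TRUE} iff the entries with \code{n_bound >=
#'   hla_threshold} number at least \code{min_epitopes} and originate from
#'   at least \code{min_antigens} distinct antigens.
#' @export
subject_qualifies <- function(profile, spec) {
  q <- profile[profile$n_bound >= spec$hla_threshold, , drop = FALSE]
  nrow(q) >= spec$min_epitopes &&
    length(unique(q$antigen_id)) >= spec$min_antigens
}

# per-subject qualification vector from a precomputed count matrix
qualify_from_counts <- function(bc, spec) {
  pass <- bc$counts >= spec$hla_threshold
  n_epi <- colSums(pass)
  ok <- n_epi >= spec$min_epitopes
  if (spec$min_antigens >= 2L) {
    ag <- rowsum((pass) * 1L, group = bc$windows$antigen_id) > 0L
    ok <- ok & (colSums(ag) >= spec$min_antigens)
  }
  ok
}

#' In silico immune response rate of a vaccine over a model population
#'
#' The fraction of cohort subjects predicted to respond to the vaccine
#' under a given estimator: subjects having at least \code{min_epitopes}
#' vaccine-specific epitopes (from at least \code{min_antigens} distinct
#' antigens) each binding at least \code{hla_threshold} distinct
#' autologous HLA class I alleles.
#'
#' @param population an \code{hla_population}, already stratified by the
#'   vaccine's HLA restriction unless \code{stratify = TRUE}.
#' @param vacc a \code{vaccine}.
#' @param table a \code{binding_table}.
#' @param spec an \code{irr_spec}.
#' @param stratify if \code{TRUE}, apply the vaccine's restriction first.
#' @param k window length (default 9).
#' @return a \code{rate_point}.
#' @export
in_silico_irr <- function(population, vacc, table, spec,
                          stratify = FALSE, k = 9L) {
  if (stratify) population <- stratify_population(population, vacc$restriction)
  if (nrow(population) == 0L) {
    stop("no subjects left after HLA stratification for vaccine ",
         sQuote(vacc$vaccine_id))
  }
  bc <- binder_count_matrix(population, vacc, table, k = k)
  ok <- qualify_from_counts(bc, spec)
  rate_point(sum(ok), length(ok))
}

# the twelve-estimator default grid (Table-style battery)
battery_grid <- function(thresholds = 1:4) {
  grid <- rbind(
    data.frame(estimator = "irr", min_epitopes = 1L, min_antigens = 1L,
               hla_threshold = thresholds),
    data.frame(estimator = "multi_epitope", min_epitopes = 2L,
               min_antigens = 1L, hla_threshold = thresholds),
    data.frame(estimator = "multi_ag", min_epitopes = 2L, min_antigens = 2L,
               hla_threshold = thresholds)
  )
  grid
}

#' Full battery of in silico response-rate estimators
#'
#' Computes the default twelve-estimator grid -- single-epitope,
#' multi-epitope and multi-antigen variants at HLA thresholds 1..4 -- in
#' one pass over the population. For a single-antigen vaccine the
#' multi-antigen rows are impossible by construction and are reported as
#' 0/N with flag \code{"not_applicable"}.
#'
#' @inheritParams in_silico_irr
#' @param thresholds HLA thresholds to evaluate (default \code{1:4}).
#' @return data frame with one row per estimator: \code{vaccine_id},
#'   \code{estimator}, \code{min_epitopes}, \code{min_antigens},
#'   \code{hla_threshold}, \code{numerator}, \code{denominator},
#'   \code{rate}, \code{flag}; class \code{c("irr_battery", "data.frame")}.
#' @export
run_trial_battery <- function(population, vacc, table, thresholds = 1:4,
                              stratify = FALSE, k = 9L) {
  if (stratify) population <- stratify_population(population, vacc$restriction)
  if (nrow(population) == 0L) {
    stop("no subjects left after HLA stratification for vaccine ",
         sQuote(vacc$vaccine_id))
  }
  bc <- binder_count_matrix(population, vacc, table, k = k)
  grid <- battery_grid(thresholds)
  n_ag <- length(vacc$antigens)
  res <- grid
  res$vaccine_id <- vacc$vaccine_id
  res$numerator <- NA_integer_
  res$denominator <- nrow(population)
  res$flag <- ""
  for (i in seq_len(nrow(grid))) {
    spec <- irr_spec(grid$hla_threshold[i], grid$min_epitopes[i],
                     grid$min_antigens[i])
    if (spec$min_antigens > n_ag) {
      res$numerator[i] <- 0L
      res$flag[i] <- "not_applicable"
    } else {
      res$numerator[i] <- sum(qualify_from_counts(bc, spec))
      if (spec$out_of_grid) res$flag[i] <- "out_of_grid"
    }
  }
  res$rate <- res$numerator / res$denominator
  res <- res[, c("vaccine_id", "estimator", "min_epitopes", "min_antigens",
                 "hla_threshold", "numerator", "denominator", "rate",
                 "flag")]
  class(res) <- c("irr_battery", "data.frame")
  res
}

#' Per-peptide in silico response rates
#'
#' For multi-peptide vaccines whose trial immunogenicity was reported per
#' peptide: the fraction of subjects for whom one particular peptide
#' passes the HLA threshold. Two modes are provided, reflecting two
#' readings of "per peptide": mode \code{"antigen"} treats each vaccine
#' antigen as one administered peptide (a subject responds to it when any
#' of its scan windows qualifies); mode \code{"window"} reports every
#' distinct (antigen, 9-mer) window separately.
#'
#' @inheritParams in_silico_irr
#' @param hla_threshold HLA threshold n (per-peptide mode is
#'   single-epitope by construction, so only n is needed).
#' @param mode \code{"antigen"} (default) or \code{"window"}.
#' @return data frame with columns \code{peptide} (antigen id or window
#'   peptide), \code{antigen_id}, \code{numerator}, \code{denominator},
#'   \code{rate}.
#' @export
per_peptide_irrs <- function(population, vacc, table, hla_threshold,
                             mode = c("antigen", "window"),
                             stratify = FALSE, k = 9L) {
  mode <- match.arg(mode)
  spec <- irr_spec(hla_threshold)  # enforces the single-epitope contract
  if (stratify) population <- stratify_population(population, vacc$restriction)
  if (nrow(population) == 0L) {
    stop("no subjects left after HLA stratification for vaccine ",
         sQuote(vacc$vaccine_id))
  }
  bc <- binder_count_matrix(population, vacc, table, k = k)
  pass <- bc$counts >= spec$hla_threshold
  N <- nrow(population)
  if (mode == "antigen") {
    ag <- rowsum(pass * 1L, group = bc$windows$antigen_id) > 0L
    out <- data.frame(peptide = rownames(ag), antigen_id = rownames(ag),
                      numerator = as.integer(rowSums(ag)),
                      denominator = N, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(peptide = bc$windows$peptide,
                      antigen_id = bc$windows$antigen_id,
                      numerator = as.integer(rowSums(pass)),
                      denominator = N, stringsAsFactors = FALSE)
  }
  out$rate <- out$numerator / out$denominator
  rownames(out) <- NULL
  out
}

#' Pool response counts across trials of the same vaccine
#'
#' When several trials report the same vaccine under the same HLA
#' restriction, their cohorts are combined: summed responders over summed
#' totals.
#'
#' @param responders integer vector of responder counts.
#' @param totals integer vector of cohort sizes (same length).
#' @return a \code{rate_point}.
#' @examples
#' combine_cohorts(c(0, 7, 8), c(10, 8, 8))   # 15/26
#' @export
combine_cohorts <- function(responders, totals) {
  if (length(responders) == 0L) stop("no cohorts to combine")
  if (length(responders) != length(totals)) {
    stop("responders and totals must have the same length")
  }
  if (any(responders > totals)) stop("responders exceed totals")
  rate_point(sum(responders), sum(totals))
}
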