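#' Peptide-allele binding prediction table
#'
#' Wraps precomputed epitope-HLA binding predictions (from any external
#' predictor) together with the binder-threshold policy. A record maps a
#' (peptide, four-digit allele) pair to a percentile rank in [0, 100]
#' (lower = stronger binder) and optionally an IC50 in nM. Lookup of an
#' absent pair is "no prediction" and is treated as non-binding.
#'
#' The default policy calls a pair a binder when percentile rank <= 2.0,
#' the conventional strong-binder cutoff; the alternative \code{"ic50"}
#' policy uses IC50 < 150 nM, the conventional strong-affinity range.
#'
#' @param records data frame with columns \code{peptide}, \code{allele},
#'   \code{percentile_rank} and optionally \code{ic50_nm}.
#' @param binder_threshold percentile-rank cutoff (default 2.0).
#' @param policy \code{"rank"} (default) or \code{"ic50"}.
#' @param ic50_threshold IC50 cutoff in nM for the \code{"ic50"} policy
#'   (default 150).
#' @return the validated data frame with class
#'   \code{c("binding_table", "data.frame")} and the policy stored in
#'   attributes.
#' @export
binding_table <- function(records, binder_threshold = 2.0,
                          policy = c("rank", "ic50"), ic50_threshold = 150) {
  policy <- match.arg(policy)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "percentile_rank")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing binding-table columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(records)) {
    records$peptide <- toupper(as.character(records$peptide))
    records$allele <- as.character(parse_allele(records$allele))
    records$percentile_rank <- as.numeric(records$percentile_rank)
    if (anyNA(records$percentile_rank) ||
        any(records$percentile_rank < 0 | records$percentile_rank > 100)) {
      stop("percentile ranks must lie in [0, 100]")
    }
    if ("ic50_nm" %in% names(records)) {
      records$ic50_nm <- as.numeric(records$ic50_nm)
      if (any(!is.na(records$ic50_nm) & records$ic50_nm <= 0)) {
        stop("IC50 values must be positive")
      }
    }
    dup <- duplicated(records[, c("peptide", "allele")])
    if (any(dup)) stop("duplicate (peptide, allele) records; ",
                       "use read_binding_table() for best-rank deduplication")
  }
  if (policy == "ic50" && !"ic50_nm" %in% names(records) && nrow(records)) {
    stop("policy 'ic50' requires an ic50_nm column")
  }
  structure(records,
            class = c("binding_table", "data.frame"),
            binder_threshold = binder_threshold,
            policy = policy,
            ic50_threshold = ic50_threshold)
}

#' @export
print.binding_table <- function(x, ...) {
  pol <- attr(x, "policy")
  cat("Binding table:", nrow(x), "records;",
      if (pol == "rank")
        paste0("binder = percentile rank <= ", attr(x, "binder_threshold"))
      else paste0("binder = IC50 < ", attr(x, "ic50_threshold"), " nM"),
      "\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}

# (peptide, allele) pairs passing the table's binder policy
binder_pairs <- function(table) {
  if (nrow(table) == 0L) {
    return(data.frame(peptide = character(0), allele = character(0)))
  }
  pass <- if (attr(table, "policy") == "ic50") {
    !is.na(table$ic50_nm) & table$ic50_nm < attr(table, "ic50_threshold")
  } else {
    table$percentile_rank <= attr(table, "binder_threshold")
  }
  as.data.frame(table)[pass, c("peptide", "allele"), drop = FALSE]
}

#' Count distinct autologous alleles binding a peptide
#'
#' Counts the alleles of a subject's DISTINCT allele set (a homozygous
#' allele counts once) whose binding record for the peptide passes the
#' table's binder policy. Absent records count as non-binders.
#'
#' @param peptide k-mer amino-acid string.
#' @param g an \code{hla_genotype} (or character vector of four-digit
#'   alleles).
#' @param table a \code{binding_table}.
#' @return integer count in 0..6.
#' @export
count_binding_alleles <- function(peptide, g, table) {
  bp <- binder_pairs(table)
  al <- distinct_alleles(g)
  sum(bp$peptide == toupper(peptide) & bp$allele %in% al)
}

# Core engine: windows x subjects matrix of distinct-autologous-allele
# binder counts. Rows follow vaccine_windows(vacc, k, dedup) order.
binder_count_matrix <- function(population, vacc, table, k = 9L,
                                dedup = TRUE) {
  w <- vaccine_windows(vacc, k = k, dedup = dedup)
  gm <- subject_genotypes(population)
  n_sub <- nrow(gm)
  bp <- binder_pairs(table)
  C <- matrix(0L, nrow = nrow(w), ncol = n_sub,
              dimnames = list(NULL, rownames(gm)))
  if (nrow(bp) == 0L || nrow(w) == 0L) {
    return(list(windows = w, counts = C))
  }
  alleles <- sort(unique(bp$allele))
  # windows x alleles binder incidence
  M <- matrix(0L, nrow = nrow(w), ncol = length(alleles),
              dimnames = list(NULL, alleles))
  hit <- merge(
    data.frame(row = seq_len(nrow(w)), peptide = w$peptide,
               stringsAsFactors = FALSE),
    cbind(bp, col = match(bp$allele, alleles)),
    by = "peptide"
  )
  if (nrow(hit)) M[cbind(hit$row, hit$col)] <- 1L
  # alleles x subjects distinct-set membership
  A <- matrix(0L, nrow = length(alleles), ncol = n_sub,
              dimnames = list(alleles, rownames(gm)))
  for (s in seq_len(n_sub)) {
    idx <- match(distinct_alleles(gm[s, ]), alleles)
    A[idx[!is.na(idx)], s] <- 1L
  }
  C <- M %*% A
  storage.mode(C) <- "integer"
  list(windows = w, counts = C)
}

#' Per-subject epitope profile of a vaccine
#'
#' Scans every antigen of the vaccine with overlapping k-mers and records,
#' for one subject, each (peptide, antigen) whose predicted binders cover
#' at least one of the subject's distinct autologous alleles, together
#' with the number of such alleles. Identical (peptide, antigen) pairs are
#' deduplicated; the same peptide occurring in different antigens is kept
#' once per antigen.
#'
#' @param subject a single-row \code{hla_population}, an
#'   \code{hla_genotype}, or a six-allele character vector.
#' @param vacc a \code{vaccine}.
#' @param table a \code{binding_table}.
#' @param k window length (default 9).
#' @return data frame with columns \code{peptide}, \code{antigen_id},
#'   \code{n_bound} (entries with \code{n_bound >= 1} only), with class
#'   \code{c("epitope_profile", "data.frame")}.
#' @export
build_subject_profile <- function(subject, vacc, table, k = 9L) {
  al <- if (inherits(subject, "hla_population")) {
    if (nrow(subject) != 1L) stop("supply a single subject")
    subject_genotypes(subject)[1L, ]
  } else as.character(subject)
  pop <- hla_population(data.frame(
    subject_id = "s", A1 = al[1], A2 = al[2], B1 = al[3], B2 = al[4],
    C1 = al[5], C2 = al[6], stringsAsFactors = FALSE))
  bc <- binder_count_matrix(pop, vacc, table, k = k, dedup = TRUE)
  keep <- bc$counts[, 1L] >= 1L
  prof <- data.frame(peptide = bc$windows$peptide[keep],
                     antigen_id = bc$windows$antigen_id[keep],
                     n_bound = bc$counts[keep, 1L],
                     stringsAsFactors = FALSE)
  rownames(prof) <- NULL
  class(prof) <- c("epitope_profile", "data.frame")
  prof
}

#' Position-specific scoring matrix with empirical percentile ranks
#'
#' A deliberately simple, self-contained default scorer standing behind
#' the binding-prediction contract: a k x 20 position-specific weight
#' matrix per allele, whose raw score (sum of per-position residue
#' weights) is converted to a percentile rank against a background score
#' sample, so that rank has the usual orientation (lower = stronger, rank
#' r means the peptide scores above 100 - r percent of background
#' peptides).
#'
#' @param allele allele name (any accepted dialect).
#' @param weights numeric k x 20 matrix; columns named by the 20
#'   amino-acid one-letter codes (any order).
#' @param background_peptides character vector of k-mers used to build the
#'   background score distribution.
#' @return list with class \code{"scoring_matrix"}.
#' @export
scoring_matrix <- function(allele, weights, background_peptides) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 20L) stop("weights must have 20 residue columns")
  if (is.null(colnames(weights))) colnames(weights) <- .AA20
  if (!setequal(colnames(weights), .AA20)) {
    stop("weight columns must be named by the 20 amino acids")
  }
  weights <- weights[, .AA20, drop = FALSE]
  if (length(background_peptides) == 0L) {
    stop("background peptide sample must be non-empty")
  }
  obj <- list(allele = as.character(parse_allele(allele)),
              k = nrow(weights), weights = weights,
              background_scores = NULL)
  bg <- vapply(background_peptides, function(p) raw_matrix_score(p, obj),
               numeric(1))
  if (anyNA(bg)) stop("background peptides must be scorable k-mers")
  obj$background_scores <- sort(unname(bg))
  class(obj) <- "scoring_matrix"
  obj
}

raw_matrix_score <- function(peptide, matrix) {
  res <- strsplit(toupper(peptide), "")[[1]]
  if (length(res) != matrix$k) {
    stop("peptide length ", length(res), " does not match matrix window ",
         matrix$k)
  }
  col <- match(res, .AA20)
  if (anyNA(col)) return(NA_real_)
  sum(matrix$weights[cbind(seq_along(col), col)])
}

#' Percentile rank of a peptide under a scoring matrix
#'
#' Rank = 100 x (fraction of background scores strictly greater than the
#' peptide's raw score); 0 is the best possible score, 100 the worst.
#' Peptides containing a residue outside the 20-letter alphabet return
#' \code{NA} (unscorable), not an error.
#'
#' @param peptide k-mer amino-acid string.
#' @param matrix a \code{scoring_matrix}.
#' @return percentile rank in [0, 100], or \code{NA} for unscorable
#'   peptides.
#' @export
matrix_percentile_rank <- function(peptide, matrix) {
  s <- raw_matrix_score(peptide, matrix)
  if (is.na(s)) return(NA_real_)
  bg <- matrix$background_scores
  100 * sum(bg > s) / length(bg)
}

#' Tabulate scoring-matrix predictions into a binding table
#'
#' Runs the default matrix scorer for every (peptide, allele) combination
#' and assembles a \code{binding_table}, the same container a precomputed
#' external prediction table is read into.
#'
#' @param peptides character vector of k-mers.
#' @param matrices list of \code{scoring_matrix} objects (one per allele).
#' @param ... passed to \code{\link{binding_table}} (threshold policy).
#' @return a \code{binding_table}; unscorable peptides are omitted.
#' @export
score_peptides <- function(peptides, matrices, ...) {
  peptides <- unique(toupper(peptides))
  recs <- lapply(matrices, function(m) {
    rk <- vapply(peptides, function(p) matrix_percentile_rank(p, m),
                 numeric(1))
    data.frame(peptide = peptides, allele = m$allele,
               percentile_rank = unname(rk), stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  recs <- recs[!is.na(recs$percentile_rank), , drop = FALSE]
  binding_table(recs, ...)
}
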