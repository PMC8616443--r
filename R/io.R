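#' Read antigen sequences from FASTA
#'
#' Record ids (first whitespace-delimited token of the header) become the
#' antigen ids. Sequences are upper-cased; trailing stop characters
#' (\code{*}) are stripped with a warning.
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
read_antigens <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate antigen ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  if (any(grepl("\\*", seqs))) {
    warning("stop characters ('*') stripped from antigen sequences")
    seqs <- gsub("\\*", "", seqs)
  }
  stats::setNames(seqs, ids)
}

#' Write antigen sequences to FASTA
#'
#' @param antigens named character vector of sequences.
#' @param path output file.
#' @export
write_antigens <- function(antigens, path) {
  aa <- Biostrings::AAStringSet(antigens)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a genotype CSV into a model population
#'
#' Expects columns \code{subject_id, A1, A2, B1, B2, C1, C2} and
#' optionally \code{group_label}; allele names may mix any of the
#' accepted nomenclature dialects. Incomplete genotypes (a missing HLA-C
#' slot, say) are an error: thresholds up to >= 4 alleles are meaningless
#' on partial genotypes.
#'
#' @param path CSV file.
#' @return an \code{hla_population}.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  hla_population(df)
}

#' Write a model population to a genotype CSV
#'
#' @param population an \code{hla_population}.
#' @param path output file.
#' @export
write_genotypes <- function(population, path) {
  utils::write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}

#' Read a binding-prediction TSV into a binding table
#'
#' Expects tab-separated columns \code{peptide}, \code{allele},
#' \code{percentile_rank} and optionally \code{ic50_nm}. Duplicate
#' (peptide, allele) rows keep the best (lowest) rank with a warning;
#' ranks outside [0, 100] are an error.
#'
#' @param path TSV file.
#' @param ... threshold policy passed to \code{\link{binding_table}}.
#' @return a \code{binding_table}.
#' @export
read_binding_table <- function(path, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "percentile_rank")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("binding table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  }
  df$percentile_rank <- as.numeric(df$percentile_rank)
  if (anyNA(df$percentile_rank) ||
      any(df$percentile_rank < 0 | df$percentile_rank > 100)) {
    stop("percentile ranks outside [0, 100] in ", path)
  }
  df$allele <- as.character(parse_allele(df$allele))
  df$peptide <- toupper(df$peptide)
  key <- paste(df$peptide, df$allele)
  if (anyDuplicated(key)) {
    warning("duplicate (peptide, allele) rows in ", path,
            ": keeping the best (lowest) rank")
    df <- df[order(df$percentile_rank), , drop = FALSE]
    df <- df[!duplicated(paste(df$peptide, df$allele)), , drop = FALSE]
  }
  rownames(df) <- NULL
  binding_table(df, ...)
}

#' Write a binding table to TSV
#'
#' @param table a \code{binding_table}.
#' @param path output file.
#' @export
write_binding_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an allele-frequency CSV
#'
#' Columns \code{allele}, \code{frequency}; allele names in any accepted
#' dialect, frequencies non-negative fractions.
#'
#' @param path CSV file.
#' @return validated data frame with canonical allele names.
#' @export
read_allele_frequencies <- function(path) {
  validate_catalog(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a trial-records CSV
#'
#' One row per trial: \code{trial_id}, \code{vaccine_id}, the measured
#' immune-response pair \code{irr_responders}/\code{irr_total} and/or the
#' clinical-response pair \code{crr_responders}/\code{crr_total} (empty
#' cells mean "not reported"), an HLA \code{restriction} pattern string
#' (empty = all-comers; disjunctions separated by \code{|}), and a
#' logical \code{per_peptide} flag.
#'
#' @param path CSV file.
#' @return data frame; at least one response pair must be present per
#'   row, and responders never exceed totals.
#' @export
read_trial_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "vaccine_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial records lack columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("irr_responders", "irr_total", "crr_responders",
                "crr_total")) {
    if (!col %in% names(df)) df[[col]] <- NA_integer_
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  if (!"restriction" %in% names(df)) df$restriction <- ""
  df$restriction[is.na(df$restriction)] <- ""
  if (!"per_peptide" %in% names(df)) df$per_peptide <- FALSE
  df$per_peptide <- as.logical(df$per_peptide)
  df$per_peptide[is.na(df$per_peptide)] <- FALSE
  for (i in seq_len(nrow(df))) {
    has_irr <- !is.na(df$irr_responders[i]) && !is.na(df$irr_total[i])
    has_crr <- !is.na(df$crr_responders[i]) && !is.na(df$crr_total[i])
    if (!has_irr && !has_crr) {
      stop("trial record row ", i, " reports neither an immune nor a ",
           "clinical response pair")
    }
    if ((has_irr && df$irr_responders[i] > df$irr_total[i]) ||
        (has_crr && df$crr_responders[i] > df$crr_total[i])) {
      stop("responders exceed total in trial record row ", i)
    }
  }
  df
}

# parse a restriction cell ("" = none; "A02|A*24:02" = disjunction)
parse_restriction_cell <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(hla_restriction(NULL))
  hla_restriction(trimws(strsplit(cell, "|", fixed = TRUE)[[1]]))
}
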