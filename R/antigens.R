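.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Define a vaccine from its antigen sequences
#'
#' A vaccine is one or more protein antigens (amino-acid sequences) plus an
#' optional HLA restriction describing the trial's enrolment preselection.
#' Antigens may be full proteins or the administered peptides themselves.
#'
#' @param vaccine_id character scalar.
#' @param antigens named character vector of amino-acid sequences (names are
#'   the antigen ids; upper-cased on input). \code{X} is tolerated but
#'   windows containing it are never scored.
#' @param restriction an \code{hla_restriction} or character patterns
#'   (default: none).
#' @return a list with class \code{"vaccine"}.
#' @export
vaccine <- function(vaccine_id, antigens, restriction = NULL) {
  if (is.null(names(antigens)) || any(!nzchar(names(antigens)))) {
    stop("antigens must be a named character vector (names = antigen ids)")
  }
  if (anyDuplicated(names(antigens))) {
    stop("duplicate antigen ids within vaccine ", sQuote(vaccine_id))
  }
  antigens <- stats::setNames(toupper(as.character(antigens)), names(antigens))
  bad <- grepl(sprintf("[^%sX]", paste(.AA20, collapse = "")), antigens)
  if (any(bad)) {
    stop("antigen ", sQuote(names(antigens)[bad][1]),
         " contains characters outside the amino-acid alphabet")
  }
  structure(list(vaccine_id = as.character(vaccine_id),
                 antigens = antigens,
                 restriction = if (inherits(restriction, "hla_restriction"))
                   restriction else hla_restriction(restriction)),
            class = "vaccine")
}

#' @export
print.vaccine <- function(x, ...) {
  cat("Vaccine", sQuote(x$vaccine_id), "-", length(x$antigens),
      "antigen(s),", sum(nchar(x$antigens)), "aa total\n")
  print(x$restriction)
  invisible(x)
}

#' Scan an antigen with overlapping k-mer windows
#'
#' Decomposes an antigen of length L into its L - k + 1 overlapping k-mer
#' peptides (default k = 9, the canonical HLA class I epitope length).
#' Windows containing a non-standard residue (e.g. \code{X}) are emitted
#' but flagged unscorable.
#'
#' @param sequence amino-acid string, or a named character vector of
#'   sequences (names = antigen ids) scanned jointly.
#' @param k window length (default 9).
#' @param antigen_id id used when \code{sequence} is a single unnamed
#'   string.
#' @return data frame with columns \code{antigen_id}, \code{start}
#'   (0-based), \code{peptide}, \code{scorable}.
#' @examples
#' scan_peptides(c(p1 = "MTEYKLVVVGAGGVGKSALT"))   # 12 windows
#' @export
scan_peptides <- function(sequence, k = 9L, antigen_id = "antigen") {
  k <- as.integer(k)
  if (k < 1L) stop("window length k must be >= 1")
  seqs <- if (is.null(names(sequence)) && length(sequence) == 1L) {
    stats::setNames(sequence, antigen_id)
  } else sequence
  out <- vector("list", length(seqs))
  for (j in seq_along(seqs)) {
    s <- toupper(seqs[[j]])
    L <- nchar(s)
    id <- names(seqs)[j]
    if (L < k) {
      stop("antigen ", sQuote(id), " is shorter (", L,
           " aa) than the window length k = ", k)
    }
    starts <- 0:(L - k)
    peps <- substring(s, starts + 1L, starts + k)
    out[[j]] <- data.frame(antigen_id = id, start = starts, peptide = peps,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$scorable <- !grepl(sprintf("[^%s]", paste(.AA20, collapse = "")),
                         res$peptide)
  res
}

# unique (antigen_id, peptide) windows of a vaccine; a k-mer repeated
# inside one antigen counts once, the same k-mer in two antigens counts
# once per antigen
vaccine_windows <- function(vacc, k = 9L, dedup = TRUE) {
  w <- scan_peptides(vacc$antigens, k = k)
  if (dedup) {
    w <- w[!duplicated(w[, c("antigen_id", "peptide")]), , drop = FALSE]
    rownames(w) <- NULL
  }
  w
}
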