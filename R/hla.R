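#' Parse HLA class I allele names
#'
#' Normalizes the nomenclature dialects found in HLA genotype databases to
#' the canonical WHO style, e.g. \code{"A*02:01"}. Four spellings are
#' accepted: \code{"A*02:01"}, \code{"A02:01"}, \code{"A*0201"} /
#' \code{"A0201"}, and group-level names \code{"A02"} or \code{"A2"} (the
#' latter zero-padded to \code{"A*02"}). Anything else is an error, not a
#' guess.
#'
#' @param text character vector of allele names.
#' @return character vector of canonical allele names (class
#'   \code{"hla_allele"}): \code{"A*02:01"} for four-digit alleles,
#'   \code{"A*02"} for group-level alleles.
#' @examples
#' parse_allele(c("A*02:01", "B0702", "A24", "A2"))
#' @export
parse_allele <- function(text) {
  if (length(text) == 0L) stop("no allele names supplied")
  text <- as.character(text)
  out <- character(length(text))
  for (i in seq_along(text)) {
    tok <- gsub("^HLA-", "", trimws(text[i]))
    if (is.na(tok) || !nzchar(tok)) {
      stop("empty allele name at position ", i)
    }
    m <- regmatches(tok, regexec("^([A-Za-z]+)\\*?([0-9:]+)$", tok))[[1]]
    if (length(m) == 0L) {
      stop("cannot parse allele name ", sQuote(tok))
    }
    locus <- toupper(m[2])
    if (!locus %in% c("A", "B", "C")) {
      stop("unknown HLA class I locus ", sQuote(locus), " in ", sQuote(tok))
    }
    digits <- m[3]
    if (grepl(":", digits)) {
      parts <- strsplit(digits, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !all(nzchar(parts)) ||
          any(!grepl("^[0-9]+$", parts))) {
        stop("malformed allele fields in ", sQuote(tok))
      }
      f1 <- parts[1]
      f2 <- parts[2]
    } else if (nchar(digits) >= 4L) {
      # colon-less four-digit dialect, e.g. "0201" -> 02:01
      f1 <- substr(digits, 1L, 2L)
      f2 <- substr(digits, 3L, nchar(digits))
    } else {
      f1 <- digits
      f2 <- NA_character_
    }
    f1 <- formatC(as.integer(f1), width = 2, flag = "0")
    if (!is.na(f2)) f2 <- formatC(as.integer(f2), width = 2, flag = "0")
    out[i] <- if (is.na(f2)) paste0(locus, "*", f1) else {
      paste0(locus, "*", f1, ":", f2)
    }
  }
  structure(out, class = "hla_allele")
}

#' @export
print.hla_allele <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

# locus / allele-group / protein fields of canonical allele names
allele_fields <- function(alleles) {
  alleles <- as.character(alleles)
  locus <- substr(alleles, 1L, 1L)
  rest <- substr(alleles, 3L, nchar(alleles))
  parts <- strsplit(rest, ":", fixed = TRUE)
  data.frame(
    allele = alleles,
    locus = locus,
    group = vapply(parts, `[`, "", 1L),
    protein = vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

is_group_level <- function(alleles) !grepl(":", as.character(alleles))

.GENO_SLOTS <- c("A1", "A2", "B1", "B2", "C1", "C2")
.SLOT_LOCI <- c("A", "A", "B", "B", "C", "C")

#' Construct a six-slot HLA class I genotype
#'
#' A personal genotype is the ordered six-allele vector (A1, A2, B1, B2,
#' C1, C2), all at four-digit resolution. Homozygous loci carry duplicate
#' slots; downstream allele counting always uses the distinct allele set.
#'
#' @param alleles character vector of six allele names (any accepted
#'   dialect), ordered A1, A2, B1, B2, C1, C2.
#' @return named character vector of canonical four-digit alleles with
#'   class \code{"hla_genotype"}.
#' @examples
#' genotype(c("A*02:01", "A*24:02", "B0702", "B*08:01", "C*07:01", "C*07:02"))
#' @export
genotype <- function(alleles) {
  if (length(alleles) != 6L) stop("a genotype needs exactly six alleles")
  al <- parse_allele(alleles)
  if (any(is_group_level(al))) {
    stop("genotype alleles must be four-digit, got group-level: ",
         paste(al[is_group_level(al)], collapse = ", "))
  }
  loci <- substr(as.character(al), 1L, 1L)
  if (!identical(loci, .SLOT_LOCI)) {
    stop("genotype slots must carry loci A,A,B,B,C,C; got ",
         paste(loci, collapse = ","))
  }
  structure(stats::setNames(as.character(al), .GENO_SLOTS),
            class = "hla_genotype")
}

#' Distinct allele set of a genotype
#'
#' @param g an \code{hla_genotype} (or six-allele character vector).
#' @return character vector of 3-6 distinct canonical alleles.
#' @export
distinct_alleles <- function(g) unique(as.character(g))

#' Assemble a model population of HLA-genotyped subjects
#'
#' @param subjects data frame with columns \code{subject_id},
#'   \code{A1,A2,B1,B2,C1,C2} (allele names in any accepted dialect) and
#'   optionally \code{group_label}.
#' @return the validated data frame, alleles canonicalized, with class
#'   \code{c("hla_population", "data.frame")}.
#' @export
hla_population <- function(subjects) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  need <- c("subject_id", .GENO_SLOTS)
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(subjects) == 0L) stop("a model population must be non-empty")
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  }
  for (i in seq_len(nrow(subjects))) {
    al <- unlist(subjects[i, .GENO_SLOTS], use.names = FALSE)
    if (anyNA(al) || any(!nzchar(trimws(as.character(al))))) {
      stop("incomplete genotype in row ", i,
           " (subject ", subjects$subject_id[i], ")")
    }
    g <- tryCatch(genotype(al), error = function(e) {
      stop("row ", i, " (subject ", subjects$subject_id[i], "): ",
           conditionMessage(e), call. = FALSE)
    })
    subjects[i, .GENO_SLOTS] <- as.character(g)
  }
  if (!"group_label" %in% names(subjects)) subjects$group_label <- NA_character_
  subjects$subject_id <- as.character(subjects$subject_id)
  class(subjects) <- c("hla_population", "data.frame")
  subjects
}

#' @export
print.hla_population <- function(x, ...) {
  cat("HLA class I model population:", nrow(x), "subjects,",
      length(population_alleles(x)), "distinct alleles\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more subjects)\n", sep = "")
  invisible(x)
}

#' Distinct alleles occurring anywhere in a population
#'
#' @param population an \code{hla_population}.
#' @return character vector of the distinct four-digit alleles carried by
#'   any subject.
#' @export
population_alleles <- function(population) {
  unique(unlist(population[, .GENO_SLOTS], use.names = FALSE))
}

subject_genotypes <- function(population) {
  m <- as.matrix(population[, .GENO_SLOTS])
  rownames(m) <- population$subject_id
  m
}

#' HLA preselection restriction
#'
#' Trial enrolment criteria restrict subjects to carriers of particular
#' alleles, either at group level (\code{"A02"}: any A*02 protein) or at
#' four-digit level (\code{"A*02:01"}). A restriction may be a disjunction
#' of several patterns; an empty restriction matches every genotype
#' (no preselection).
#'
#' @param patterns character vector of allele patterns (possibly empty or
#'   \code{NULL}).
#' @return character vector of canonical patterns with class
#'   \code{"hla_restriction"}.
#' @examples
#' hla_restriction("A02")
#' hla_restriction(c("A*02:01", "A24"))
#' hla_restriction(NULL)   # no preselection
#' @export
hla_restriction <- function(patterns = NULL) {
  if (is.null(patterns) || length(patterns) == 0L ||
      all(is.na(patterns) | !nzchar(trimws(patterns)))) {
    return(structure(character(0), class = "hla_restriction"))
  }
  structure(as.character(parse_allele(patterns)), class = "hla_restriction")
}

#' @export
print.hla_restriction <- function(x, ...) {
  if (length(x) == 0L) cat("HLA restriction: none (all-comers)\n")
  else cat("HLA restriction:", paste(unclass(x), collapse = " or "), "\n")
  invisible(x)
}

#' Does a genotype satisfy an HLA restriction?
#'
#' A group-level pattern matches on locus and allele group only; a
#' four-digit pattern must match both fields. The empty restriction
#' matches everything.
#'
#' @param g an \code{hla_genotype} or character vector of canonical
#'   four-digit alleles.
#' @param restriction an \code{hla_restriction}.
#' @return \code{TRUE} iff any genotype allele matches any pattern.
#' @export
matches_restriction <- function(g, restriction) {
  restriction <- if (inherits(restriction, "hla_restriction")) restriction
  else hla_restriction(restriction)
  if (length(restriction) == 0L) return(TRUE)
  al <- as.character(g)
  groups <- sub("^([A-C]\\*[0-9]+).*$", "\\1", al)
  for (pat in as.character(restriction)) {
    hit <- if (is_group_level(pat)) pat %in% groups else pat %in% al
    if (hit) return(TRUE)
  }
  FALSE
}

#' Stratify a model population by an HLA restriction
#'
#' Emulates trial enrolment preselection: retains the subjects whose
#' genotype carries a matching allele, preserving order. Note that the
#' restriction filters the population only -- all six alleles of retained
#' subjects still count toward epitope-binding thresholds.
#'
#' @param population an \code{hla_population}.
#' @param restriction an \code{hla_restriction} (or character patterns).
#' @return the stratified \code{hla_population}; may have zero rows.
#' @export
stratify_population <- function(population, restriction) {
  restriction <- if (inherits(restriction, "hla_restriction")) restriction
  else hla_restriction(restriction)
  if (length(restriction) == 0L) return(population)
  gm <- subject_genotypes(population)
  keep <- vapply(seq_len(nrow(gm)), function(i) {
    matches_restriction(gm[i, ], restriction)
  }, logical(1))
  out <- population[keep, , drop = FALSE]
  class(out) <- c("hla_population", "data.frame")
  out
}

#' Summed catalog frequency of a population's allele set
#'
#' Measures how representative a genotyped cohort is of the global allele
#' pool: the sum, over the distinct four-digit alleles occurring anywhere
#' in the population, of their frequencies in an allele-frequency catalog
#' (a CIWD-style table). Alleles absent from the catalog contribute zero
#' and are reported in the \code{"uncatalogued"} attribute.
#'
#' @param population an \code{hla_population}.
#' @param catalog data frame with columns \code{allele} and
#'   \code{frequency}.
#' @return the summed frequency (a single number), with attribute
#'   \code{uncatalogued} listing population alleles missing from the
#'   catalog.
#' @export
allele_coverage <- function(population, catalog) {
  catalog <- validate_catalog(catalog)
  pop_alleles <- population_alleles(population)
  idx <- match(pop_alleles, catalog$allele)
  uncat <- pop_alleles[is.na(idx)]
  cov <- sum(catalog$frequency[idx[!is.na(idx)]])
  structure(cov, uncatalogued = uncat)
}

validate_catalog <- function(catalog) {
  catalog <- as.data.frame(catalog, stringsAsFactors = FALSE)
  if (!all(c("allele", "frequency") %in% names(catalog))) {
    stop("catalog needs columns 'allele' and 'frequency'")
  }
  if (nrow(catalog) == 0L) stop("allele-frequency catalog is empty")
  catalog$allele <- as.character(parse_allele(catalog$allele))
  catalog$frequency <- as.numeric(catalog$frequency)
  if (anyNA(catalog$frequency) || any(catalog$frequency < 0)) {
    stop("catalog frequencies must be non-negative numbers")
  }
  if (anyDuplicated(catalog$allele)) stop("duplicate catalog alleles")
  catalog
}
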