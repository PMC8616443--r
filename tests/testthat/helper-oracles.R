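# Independent brute-force oracles and tiny fixture builders. The oracles
# deliberately share no code with the package's vectorized engine: they
# re-derive every quantity by naive looping over subjects, windows and
# alleles, or by closed-form identities.

toy_population <- function(rows) {
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("A1", "A2", "B1", "B2", "C1", "C2")
  df$subject_id <- sprintf("P%02d", seq_len(nrow(df)))
  hla_population(df)
}

# naive per-subject profile: triple loop over windows x alleles
oracle_profile <- function(alleles6, vacc, tbl, k = 9) {
  thr <- attr(tbl, "binder_threshold")
  recs <- as.data.frame(tbl)
  dist <- unique(alleles6)
  out <- list()
  for (ag in names(vacc$antigens)) {
    s <- vacc$antigens[[ag]]
    seen <- character(0)
    for (start in 0:(nchar(s) - k)) {
      pep <- substr(s, start + 1, start + k)
      if (pep %in% seen) next
      seen <- c(seen, pep)
      n <- 0
      for (al in dist) {
        hit <- recs$peptide == pep & recs$allele == al &
          recs$percentile_rank <= thr
        if (any(hit)) n <- n + 1
      }
      if (n >= 1) {
        out[[length(out) + 1]] <- data.frame(
          peptide = pep, antigen_id = ag, n_bound = n,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(peptide = character(0), antigen_id = character(0),
                      n_bound = integer(0)))
  }
  do.call(rbind, out)
}

oracle_qualifies <- function(prof, min_epitopes, min_antigens, n) {
  q <- prof[prof$n_bound >= n, , drop = FALSE]
  nrow(q) >= min_epitopes && length(unique(q$antigen_id)) >= min_antigens
}

oracle_irr <- function(pop, vacc, tbl, min_epitopes, min_antigens, n,
                       k = 9) {
  gm <- as.matrix(as.data.frame(pop)[, c("A1", "A2", "B1", "B2",
                                         "C1", "C2")])
  hits <- 0
  for (i in seq_len(nrow(gm))) {
    prof <- oracle_profile(gm[i, ], vacc, tbl, k = k)
    if (oracle_qualifies(prof, min_epitopes, min_antigens, n)) {
      hits <- hits + 1
    }
  }
  c(numerator = hits, denominator = nrow(gm))
}

# tie-corrected rank-sum AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Mann-Whitney U p-value, normal approximation with tie correction
oracle_rank_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(rk)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

# a random small trial instance (population + vaccine + binder table)
rand_instance <- function(seed, max_subjects = 20, max_antigens = 3) {
  set.seed(seed)
  catalog <- default_allele_catalog()
  pop <- sample_population(sample(4:max_subjects, 1), catalog,
                           seed = seed + 1)
  n_ag <- sample(seq_len(max_antigens), 1)
  ags <- sample_antigens(n_ag, length_range = c(15L, 60L),
                         seed = seed + 2)
  vacc <- vaccine("VX", ags)
  # high binder rate so that multi-allele epitopes are common in tiny data
  tbl <- sample_binding_table(scan_peptides(ags)$peptide,
                              population_alleles(pop),
                              base_binder_rate = 0.15,
                              promiscuity_boost = 3, seed = seed + 3)
  list(pop = pop, vacc = vacc, tbl = tbl)
}

rand_pairs <- function(seed, n = 20) {
  set.seed(seed)
  mt <- sample(5:80, n, replace = TRUE)
  pt <- sample(20:400, n, replace = TRUE)
  data.frame(
    label = paste0("V", seq_len(n)),
    measured_responders = rbinom(n, mt, runif(n)),
    measured_total = mt,
    predicted_numerator = rbinom(n, pt, runif(n)),
    predicted_denominator = pt)
}
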