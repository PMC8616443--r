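prof3 <- structure(
  data.frame(peptide = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
             antigen_id = c("ag1", "ag1", "ag2"),
             n_bound = c(4L, 4L, 2L)),
  class = c("epitope_profile", "data.frame"))

test_that("estimator qualification counts epitopes and antigen diversity", {
  one <- prof3[1, ]
  expect_true(subject_qualifies(one, irr_spec(3)))
  expect_false(subject_qualifies(one, irr_spec(5)))
  # two epitopes from the SAME antigen fail the multi-antigen criterion
  same_ag <- prof3[1:2, ]
  expect_false(subject_qualifies(same_ag,
                                 irr_spec(1, min_epitopes = 2,
                                          min_antigens = 2)))
  expect_true(subject_qualifies(same_ag, irr_spec(1, min_epitopes = 2)))
  # (2 epitopes, 1 antigen, n = 4): the two n_bound = 4 entries pass
  expect_true(subject_qualifies(prof3, irr_spec(4, min_epitopes = 2)))
})

test_that("irr_spec validates its grid", {
  expect_error(irr_spec(0), "1..6")
  expect_error(irr_spec(3, min_epitopes = 1, min_antigens = 2),
               "min_epitopes")
  expect_true(irr_spec(5)$out_of_grid)
  expect_false(irr_spec(4)$out_of_grid)
})

test_that("in silico IRR on a hand-built two-subject cohort", {
  pop <- toy_population(list(
    c("A*01:01", "A*02:01", "B*07:02", "B*08:01", "C*07:01", "C*07:02"),
    c("A*03:01", "A*24:02", "B*44:02", "B*35:01", "C*04:01", "C*06:02")))
  vacc <- vaccine("VX", c(ag = "AAAAAAAAA"))
  tbl <- binding_table(data.frame(
    peptide = rep("AAAAAAAAA", 4),
    allele = c("A*01:01", "A*02:01", "B*07:02", "A*03:01"),
    percentile_rank = c(0.1, 0.5, 1.0, 1.5)))
  # subject 1 binds via 3 alleles, subject 2 via 1
  expect_equal(in_silico_irr(pop, vacc, tbl, irr_spec(3))$rate, 1 / 2)
  expect_equal(in_silico_irr(pop, vacc, tbl, irr_spec(1))$rate, 2 / 2)
  expect_equal(in_silico_irr(pop, vacc, tbl, irr_spec(4))$numerator, 0)
  # zero predicted binders -> 0/N under every estimator
  none <- binding_table(data.frame(peptide = character(0),
                                   allele = character(0),
                                   percentile_rank = numeric(0)))
  expect_equal(in_silico_irr(pop, vacc, none, irr_spec(1))$numerator, 0)
})

test_that("stratification keeps all six alleles of retained subjects", {
  pop <- toy_population(list(
    c("A*02:01", "A*24:02", "B*07:02", "B*08:01", "C*07:01", "C*07:02"),
    c("A*03:01", "A*11:01", "B*44:02", "B*35:01", "C*04:01", "C*06:02")))
  vacc <- vaccine("VX", c(ag = "AAAAAAAAA"),
                  restriction = hla_restriction("A02"))
  # the qualifying epitope binds only NON-restriction alleles
  tbl <- binding_table(data.frame(
    peptide = rep("AAAAAAAAA", 3),
    allele = c("B*07:02", "C*07:01", "C*07:02"),
    percentile_rank = c(0.1, 0.2, 0.3)))
  rp <- in_silico_irr(pop, vacc, tbl, irr_spec(3), stratify = TRUE)
  expect_equal(rp$denominator, 1)   # only the A*02 carrier is enrolled
  expect_equal(rp$numerator, 1)     # ...but all its alleles count
  # empty post-stratification cohort is an error
  vacc2 <- vaccine("VX2", c(ag = "AAAAAAAAA"),
                   restriction = hla_restriction("A*68:01"))
  expect_error(in_silico_irr(pop, vacc2, tbl, irr_spec(1),
                             stratify = TRUE), "stratification")
})

test_that("the battery equals twelve independent estimator calls", {
  inst <- rand_instance(77, max_subjects = 12, max_antigens = 3)
  bat <- run_trial_battery(inst$pop, inst$vacc, inst$tbl)
  expect_equal(nrow(bat), 12)
  for (i in seq_len(nrow(bat))) {
    spec <- irr_spec(bat$hla_threshold[i], bat$min_epitopes[i],
                     bat$min_antigens[i])
    if (bat$flag[i] == "not_applicable") next
    rp <- in_silico_irr(inst$pop, inst$vacc, inst$tbl, spec)
    expect_equal(bat$numerator[i], rp$numerator)
    expect_equal(bat$denominator[i], rp$denominator)
  }
})

test_that("single-antigen vaccines flag the multi-antigen rows", {
  pop <- sample_population(5, seed = 3)
  ag <- sample_antigens(1, lengths = 30, seed = 4)
  vacc <- vaccine("VX", ag)
  tbl <- sample_binding_table(scan_peptides(ag)$peptide,
                              population_alleles(pop),
                              base_binder_rate = 0.3, seed = 5)
  bat <- run_trial_battery(pop, vacc, tbl)
  ma <- bat[bat$estimator == "multi_ag", ]
  expect_true(all(ma$numerator == 0))
  expect_true(all(ma$flag == "not_applicable"))
})

test_that("per-peptide rates respect the union bound and the restriction oracle", {
  inst <- rand_instance(91, max_subjects = 10, max_antigens = 2)
  for (n in 1:3) {
    ppw <- per_peptide_irrs(inst$pop, inst$vacc, inst$tbl, n,
                            mode = "window")
    vacc_rate <- in_silico_irr(inst$pop, inst$vacc, inst$tbl,
                               irr_spec(n))$rate
    if (nrow(ppw)) expect_lte(max(ppw$rate), vacc_rate)
    # restriction oracle: recompute one window's rate by filtering the
    # per-subject profiles to that peptide alone
    gm <- as.matrix(as.data.frame(inst$pop)[, c("A1", "A2", "B1", "B2",
                                                "C1", "C2")])
    j <- which.max(ppw$rate)
    hits <- 0
    for (i in seq_len(nrow(gm))) {
      prof <- oracle_profile(gm[i, ], inst$vacc, inst$tbl)
      prof <- prof[prof$peptide == ppw$peptide[j] &
                     prof$antigen_id == ppw$antigen_id[j], , drop = FALSE]
      if (nrow(prof) && any(prof$n_bound >= n)) hits <- hits + 1
    }
    expect_equal(ppw$numerator[j], hits)
  }
  # per-peptide mode is single-epitope by construction
  expect_error(per_peptide_irrs(inst$pop, inst$vacc, inst$tbl,
                                irr_spec(1, min_epitopes = 2)))
})

test_that("antigen-level per-peptide mode reports one row per antigen", {
  inst <- rand_instance(95, max_subjects = 8, max_antigens = 3)
  pp <- per_peptide_irrs(inst$pop, inst$vacc, inst$tbl, 1,
                         mode = "antigen")
  expect_setequal(pp$antigen_id, names(inst$vacc$antigens))
  expect_true(all(pp$rate >= 0 & pp$rate <= 1))
})

test_that("cohort pooling sums responders over totals", {
  expect_equal(combine_cohorts(3, 10)$rate, 0.3)
  rp <- combine_cohorts(c(0, 7, 8), c(10, 8, 8))
  expect_equal(rp$numerator, 15)
  expect_equal(rp$denominator, 26)
  expect_equal(combine_cohorts(c(5, 0), c(5, 5))$rate, 0.5)
  expect_error(combine_cohorts(integer(0), integer(0)), "no cohorts")
  expect_error(combine_cohorts(6, 5), "exceed")
})

test_that("adding an antigen never decreases any battery rate", {
  set.seed(123)
  ags <- sample_antigens(2, lengths = c(30, 30), seed = 8)
  pop <- sample_population(10, seed = 9)
  tbl <- sample_binding_table(scan_peptides(ags)$peptide,
                              population_alleles(pop),
                              base_binder_rate = 0.2, seed = 10)
  v1 <- vaccine("V1", ags[1])
  v12 <- vaccine("V12", ags)
  b1 <- run_trial_battery(pop, v1, tbl)
  b12 <- run_trial_battery(pop, v12, tbl)
  expect_true(all(b12$numerator >= b1$numerator))
})
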