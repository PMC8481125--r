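# Synthetic mutation panels, screens and cohorts.

test_that("the default effects template encodes the group selectivity ordering", {
  eff <- egfrsf:::.default_effects()
  argmin <- setNames(colnames(eff)[apply(eff, 1, which.min)], rownames(eff))
  expect_equal(argmin[["classical-like"]], "3rd-gen")
  expect_equal(argmin[["PACC"]], "2nd-gen")
  expect_equal(argmin[["Ex20ins-L"]], "Ex20ins-active")
  expect_equal(argmin[["T790M-like-3S"]], "3rd-gen")
  # 3R is selective only for ALK/PKC inhibitors
  expect_true(all(eff["T790M-like-3R", c("ALKi", "PKCi")] < 0))
  expect_true(all(eff["T790M-like-3R",
                      c("1st-gen", "2nd-gen", "3rd-gen", "Ex20ins-active")] >= 0))
  # Ex20ins-L is non-sensitive outside Ex20ins-active / select 2nd-gen
  expect_true(all(eff["Ex20ins-L", c("1st-gen", "3rd-gen", "ALKi", "PKCi")] >= 0))
})

test_that("panel strings parse and the classifier recovers the intended groups", {
  pools <- egfrsf:::.mutation_pools()
  for (grp in names(pools)) {
    for (mu in pools[[grp]]) {
      a <- classify_allele(mu)
      lab <- if (a$subgroup %in% c("3S", "3R")) {
        paste0(a$group, "-", a$subgroup)
      } else {
        a$group
      }
      expect_equal(lab, grp, info = mu)
    }
  }
})

test_that("panel generation honours counts, groups and regions", {
  expect_equal(nrow(generate_mutation_panel(c(PACC = 0))), 0)
  p <- generate_mutation_panel(c(PACC = 2), seed = 1)
  expect_true(all(p$mutation %in% egfrsf:::.mutation_pools()$PACC))
  p <- generate_mutation_panel(c("Ex20ins-L" = 3), seed = 2)
  for (mu in p$mutation) {
    v <- parse_mutation(mu)
    expect_equal(v$kind, "insertion")
    expect_true(v$start >= 767 && v$start <= 774, info = mu)
  }
  p <- generate_mutation_panel(c("T790M-like" = 6), seed = 3)
  expect_equal(sum(p$group == "T790M-like-3S"), 3)
  expect_equal(unique(p$structure_group), "T790M-like")
  expect_error(generate_mutation_panel(c(PACC = 99)), "pool has only")
  expect_error(generate_mutation_panel(c(bogus = 1)), "unknown group")
})

test_that("screen generation is deterministic given a seed", {
  panel <- generate_mutation_panel(c(PACC = 2, "classical-like" = 2),
                                   seed = 5)
  g1 <- generate_screen(panel, screen_template(), seed = 9)
  g2 <- generate_screen(panel, screen_template(), seed = 9)
  expect_identical(g1$screen, g2$screen)
  expect_identical(g1$truth, g2$truth)
  c1 <- generate_cohort(cohort_template(default_cohort_medians()), seed = 9)
  c2 <- generate_cohort(cohort_template(default_cohort_medians()), seed = 9)
  expect_identical(c1, c2)
  expect_error(screen_template(sigma = -1), "non-negative")
})

test_that("a noiseless screen closes through the pipeline to the template", {
  panel <- generate_mutation_panel(
    c("classical-like" = 2, "PACC" = 2, "Ex20ins-L" = 2, "T790M-like" = 2),
    seed = 11)
  tmpl <- screen_template(sigma = 0, sigma_m = 0, n_bio = 1)
  gen <- generate_screen(panel, tmpl, seed = 12)
  res <- analyze_screen(gen$screen)
  got <- res$matrix$values[rownames(gen$truth), colnames(gen$truth)]
  expect_equal(max(abs(got - gen$truth)), 0, tolerance = 1e-6)
})

test_that("noisy screens recover the truth within the replicate-noise budget", {
  # sigma = 0.2, 3 biological replicates: the cell statistic is the median
  # of 3 lognormal replicates (s.d. ~ 0.67 * sigma = 0.134) and the ratio
  # denominator is the WT replicate mean (adds sigma/sqrt(3) = 0.115,
  # shared per drug), so the predicted per-cell RMSE is
  # sqrt(0.134^2 + 0.115^2) ~ 0.177; allow fit error on top
  panel <- generate_mutation_panel(c("PACC" = 3, "classical-like" = 3),
                                   seed = 21)
  tmpl <- screen_template(
    effects = egfrsf:::.default_effects(),
    drug_panel = egfrsf:::.default_drug_panel()[c(1, 5, 9, 12), ],
    sigma = 0.2, sigma_m = 0.1, n_bio = 3)
  errs <- numeric(0)
  for (s in 1:5) {
    gen <- generate_screen(panel, tmpl, seed = 500 + s)
    res <- analyze_screen(gen$screen)
    got <- res$matrix$values[rownames(gen$truth), colnames(gen$truth)]
    errs <- c(errs, sqrt(mean((got - gen$truth)^2)))
  }
  expect_lt(mean(errs), sqrt((0.67 * 0.2)^2 + (0.2 / sqrt(3))^2) + 0.04)
})

test_that("matrix-level simulation matches its declared truth structure", {
  panel <- generate_mutation_panel(
    c("classical-like" = 3, "PACC" = 3, "Ex20ins-L" = 3, "T790M-like" = 4),
    seed = 31)
  m0 <- simulate_selectivity_matrix(panel, screen_template(sigma = 0,
                                                           sigma_m = 0),
                                    seed = 32)
  eff <- egfrsf:::.default_effects()
  drugs <- egfrsf:::.default_drug_panel()
  expect_equal(unname(m0$values),
               unname(eff[panel$group, drugs$class]), tolerance = 1e-12)
  m1 <- simulate_selectivity_matrix(panel, screen_template(sigma = 0.3),
                                    seed = 33)
  expect_false(any(m1$censored))
  expect_equal(dim(m1$values), c(13L, 18L))
})

test_that("cohort generation hits target medians and censoring fractions", {
  tmpl <- cohort_template(
    data.frame(group = "PACC", tki_generation = "2nd", median_months = 10),
    n_per_arm = 10000, censoring = 0)
  cohort <- generate_cohort(tmpl, seed = 41)
  expect_true(all(cohort$event == 1))
  km <- km_estimate(cohort$time_months, cohort$event)
  expect_gt(km$median, 9.5)
  expect_lt(km$median, 10.5)

  tmpl <- cohort_template(
    data.frame(group = "PACC", tki_generation = "2nd", median_months = 10),
    n_per_arm = 10000, censoring = 0.3)
  cohort <- generate_cohort(tmpl, seed = 42)
  expect_equal(mean(cohort$event == 0), 0.3, tolerance = 0.02)
  expect_true(all(cohort$time_months > 0))
  expect_error(cohort_template(data.frame(group = "a", tki_generation = "1st",
                                          median_months = 5),
                               censoring = 1), "censoring")
})

test_that("the default template drives structure > exon recovery end to end", {
  # closure: generator -> matrix -> grouping comparison favours the
  # generating scheme at moderate noise
  study <- simulation_grouping_study(n_seeds = 5, seed = 77, sigma = 0.3)
  expect_true(all(study$mean_rho_structure > study$mean_rho_exon))
  expect_true(all(study$mean_imp_structure > study$mean_imp_exon))
  expect_true(all(study$rho_paired_p < 0.05))
})

test_that("a flat template produces no false structure-over-exon signal", {
  eff <- egfrsf:::.default_effects()
  eff[] <- -0.5
  tmpl <- screen_template(effects = eff, sigma = 0.3)
  hits <- 0
  for (s in 1:8) {
    set.seed(900 + s)
    panel <- generate_mutation_panel(
      c("classical-like" = 4, "PACC" = 4, "Ex20ins-L" = 4, "T790M-like" = 4))
    m <- simulate_selectivity_matrix(panel, tmpl)
    assignments <- classify_mutations(panel$mutation)
    schemes <- schemes_from_assignments(assignments, ids = panel$id)
    cmp <- compare_groupings(m, schemes$structure, schemes$exon)
    if (cmp$summary$p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 6)
})
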