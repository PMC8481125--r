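# Dose-response fitting, selectivity ratios, matrix assembly, clustering
# and group comparisons.

test_that("viability normalization divides by the DMSO control mean", {
  expect_equal(normalize_viability(5000, c(10000, 10000)), 0.5)
  expect_equal(normalize_viability(10000, c(10000, 10000)), 1.0)
  expect_error(normalize_viability(5000, c(0, 0)), "positive")
})

test_that("a noiseless logistic curve is recovered to numerical tolerance", {
  d <- 100 * 10^seq(-2, 1, by = 0.5)       # 7 half-log doses
  frac <- 1 / (1 + d / 100)                # top 1, bottom 0, hill 1, IC50 100
  fit <- fit_dose_response(d, frac)
  expect_false(fit$ic50_censored)
  expect_equal(fit$ic50, 100, tolerance = 1e-6)
  expect_equal(fit$fit$hill, 1, tolerance = 1e-4)
})

test_that("curves that never reach 50% inhibition are censored", {
  d <- 10^seq(0, 3, length.out = 7)
  fit <- fit_dose_response(d, rep(c(0.95, 0.92, 0.90), length.out = 7))
  expect_true(fit$ic50_censored)
  expect_equal(fit$ic50, max(d))
  expect_equal(fit$censor_side, "high")
  expect_error(fit_dose_response(d[1:3], rep(0.5, 3)), "4 distinct")
})

test_that("noisy-fit IC50 agrees with a dense grid search over the fitted curve", {
  set.seed(7)
  d <- rep(100 * 10^seq(-2, 1, by = 0.5), each = 3)
  for (i in 1:10) {
    true_ic50 <- 10^runif(1, 0.5, 2.5)
    frac <- 1 / (1 + (d / true_ic50)^runif(1, 0.8, 1.5)) +
      rnorm(length(d), 0, 0.03)
    fit <- fit_dose_response(d, frac)
    if (!fit$ic50_censored) {
      expect_equal(fit$ic50, oracle_ic50_grid(fit, d), tolerance = 1e-3)
    }
  }
})

test_that("scaling all doses by k scales the IC50 by k", {
  set.seed(11)
  d <- rep(100 * 10^seq(-2, 1, by = 0.5), each = 3)
  frac <- 1 / (1 + d / 80) + rnorm(length(d), 0, 0.02)
  f1 <- fit_dose_response(d, frac)
  for (k in c(0.1, 3, 10)) {
    f2 <- fit_dose_response(d * k, frac)
    expect_equal(f2$ic50, f1$ic50 * k, tolerance = 1e-5)
  }
})

test_that("mutant/WT ratios follow the mean-denominator definition", {
  r <- mutant_wt_ratio(10, c(100, 100, 100))
  expect_equal(r$ratio, 0.1)
  expect_equal(r$log_ratio, -1)
  expect_equal(mutant_wt_ratio(100, c(100, 100))$log_ratio, 0)
  r <- mutant_wt_ratio(250, c(100, 300))
  expect_equal(r$ratio, 1.25)
  expect_equal(r$log_ratio, log10(1.25), tolerance = 1e-10)
  expect_equal(r$log_ratio, 0.0969, tolerance = 1e-3)
  expect_error(mutant_wt_ratio(-1, c(100)), "positive")
})

test_that("matrix cells are medians over replicates with censor propagation", {
  ratios <- data.frame(
    mutation = c(rep("m1", 3), "m2", rep("m3", 2)),
    drug = "d1",
    log_ratio = c(-1.0, -0.5, -0.2, 0.7, -1.0, 0.0),
    censored = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  m <- build_selectivity_matrix(ratios)
  expect_equal(m$values["m1", "d1"], -0.5)
  expect_equal(m$values["m2", "d1"], 0.7)    # single replicate is itself
  expect_equal(m$values["m3", "d1"], -0.5)   # even count: mean of middle pair
  expect_true(m$censored["m2", "d1"])
  expect_false(m$censored["m1", "d1"])
})

test_that("missing cells are reported, not imputed", {
  ratios <- data.frame(
    mutation = c("m1", "m1", "m2"), drug = c("d1", "d2", "d1"),
    log_ratio = c(0, 1, 2))
  m <- build_selectivity_matrix(ratios)
  expect_equal(nrow(m$missing), 1)
  expect_equal(m$missing$mutation, "m2")
  expect_equal(m$missing$drug, "d2")
  expect_true(is.na(m$values["m2", "d2"]))
})

test_that("clustering merges identical rows first and matches brute force", {
  x <- rbind(a = c(0, 0), b = c(1, 1), c = c(0, 0))
  cl <- hierarchical_cluster(x)
  first <- sort(cl$merge[1, ])
  expect_equal(cl$height[1], 0)
  expect_setequal(cl$labels[-first], c("a", "c"))

  # 3x2 toy: nearest pair (Euclidean) merges first
  y <- rbind(p = c(0, 0), q = c(3, 4), r = c(0.5, 0))
  dists <- c(pq = 5, pr = 0.5, qr = sqrt(2.5^2 + 16))
  cl <- hierarchical_cluster(y)
  expect_setequal(cl$labels[-sort(cl$merge[1, ])], c("p", "r"))
  expect_equal(cl$height[1], min(dists))
  expect_match(cl$newick, "^\\(")
  expect_error(hierarchical_cluster(y[1, , drop = FALSE]), "at least 2")
})

test_that("the merge tree is invariant to input row order", {
  set.seed(3)
  x <- matrix(rnorm(24), 6, 4, dimnames = list(letters[1:6], NULL))
  cl1 <- hierarchical_cluster(x)
  perm <- sample(6)
  cl2 <- hierarchical_cluster(x[perm, ])
  expect_equal(sort(cl1$height), sort(cl2$height))
  # cophenetic distances are label-addressed, hence permutation invariant
  c1 <- as.matrix(stats::cophenetic(cl1$hclust))
  c2 <- as.matrix(stats::cophenetic(cl2$hclust))[rownames(c1), colnames(c1)]
  expect_equal(c1, c2)
})

test_that("Welch ANOVA + Holm-Sidak behaves on degenerate and separated groups", {
  res <- compare_group_selectivity(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_equal(res$anova$p, 1)
  expect_true(all(res$pairwise$p_adj == 1))

  set.seed(5)
  x <- c(rnorm(5, 0, 1e-3), rnorm(5, 1, 1e-3))
  res <- compare_group_selectivity(x, rep(c("a", "b"), each = 5))
  expect_lt(res$pairwise$p_adj[1], 0.001)
  expect_error(compare_group_selectivity(c(1, 2), c("a", "b")),
               "at least 2 observations")
})

test_that("the Welch F statistic equals the hand-computed formula", {
  g <- list(a = c(1, 2, 3), b = c(2, 4, 6, 8), c = c(10, 11, 12))
  x <- unlist(g)
  lab <- rep(names(g), lengths(g))
  res <- compare_group_selectivity(x, lab)
  # Welch (1951): w_i = n_i/s_i^2, F* and df from the weighted means
  w <- vapply(g, function(v) length(v) / var(v), numeric(1))
  xb <- vapply(g, mean, numeric(1))
  xw <- sum(w * xb) / sum(w)
  k <- length(g)
  num <- sum(w * (xb - xw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (lengths(g) - 1)) / (k^2 - 1)
  f_hand <- num / (1 + 2 * (k - 2) * lam)
  expect_equal(res$anova$f, f_hand, tolerance = 1e-10)
})

test_that("Holm-Sidak adjustment is the step-down Sidak with monotonicity", {
  p <- c(0.01, 0.04, 0.03)
  adj <- egfrsf:::holm_sidak(p)
  expect_equal(adj[1], 1 - (1 - 0.01)^3)
  expect_equal(adj[3], max(1 - (1 - 0.03)^2, adj[1]))
  expect_equal(adj[2], max(1 - (1 - 0.04)^1, adj[3]))
})

test_that("the full screen pipeline conserves a WT-equal line at log-ratio 0", {
  panel <- data.frame(id = "neutral", mutation = "L858R",
                      group = "classical", stringsAsFactors = FALSE)
  tmpl <- screen_template(
    effects = matrix(0, 1, 6,
                     dimnames = list("classical",
                                     c("1st-gen", "2nd-gen", "3rd-gen",
                                       "Ex20ins-active", "ALKi", "PKCi"))),
    sigma = 0, sigma_m = 0, n_bio = 2)
  gen <- generate_screen(panel, tmpl, seed = 1)
  res <- analyze_screen(gen$screen)
  expect_equal(max(abs(res$matrix$values)), 0, tolerance = 1e-6)
})
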