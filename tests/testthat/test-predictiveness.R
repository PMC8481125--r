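# Leave-one-out group-profile correlation and CART variable importance.

toy_matrix <- function() {
  m <- rbind(A = c(0, 1, 5), B = c(2, 3, 1), C = c(4, 11, 2), D = c(6, 7, 9))
  colnames(m) <- c("d1", "d2", "d3")
  m
}

test_that("leave-one-out profiles are means over the remaining members", {
  m <- toy_matrix()
  scheme <- grouping_scheme("g", c(A = "x", B = "x", C = "x", D = "y"))
  expect_equal(loo_group_profile(m, scheme, "A"),
               c(d1 = mean(c(2, 4)), d2 = mean(c(3, 11)), d3 = mean(c(1, 2))))
  # identical rows: the LOO profile equals either row
  m2 <- rbind(A = c(1, 2), B = c(1, 2))
  colnames(m2) <- c("d1", "d2")
  s2 <- grouping_scheme("g", c(A = "x", B = "x"))
  expect_equal(loo_group_profile(m2, s2, "A"), c(d1 = 1, d2 = 2))
  # singleton category is not evaluable
  expect_null(loo_group_profile(m, scheme, "D"))
})

test_that("Spearman rho matches known values and handles degeneracy", {
  expect_equal(mutation_rho(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(mutation_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(mutation_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(mutation_rho(c(1, 1, 1), c(1, 2, 3))))
})

test_that("Spearman rho equals brute-force rank correlation, ties included", {
  set.seed(9)
  x_fixed <- c(2, 1, 3, 1, 2)
  perms <- matrix(unlist(
    combinat_perms <- local({
      # all permutations of 1:5 by recursive construction
      perm <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v)) {
          for (rest in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
        }
        out
      }
      perm(1:5)
    })), ncol = 5, byrow = TRUE)
  for (i in seq_len(nrow(perms))) {
    y <- perms[i, ]
    expect_equal(mutation_rho(x_fixed, y), oracle_spearman(x_fixed, y),
                 tolerance = 1e-12)
  }
  # tied vectors over a small value set
  for (i in 1:200) {
    x <- sample(1:3, 5, replace = TRUE)
    y <- sample(1:3, 5, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(mutation_rho(x, y), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("identical schemes give t = 0, p = 1; hand-computed paired t holds", {
  m <- toy_matrix()
  s <- grouping_scheme("s", c(A = "x", B = "x", C = "y", D = "y"))
  cmp <- compare_groupings(m, s, grouping_scheme("s2", s$map))
  expect_equal(cmp$summary$t, 0)
  expect_equal(cmp$summary$p, 1)

  # hand-computed paired t on a 4-mutation toy
  set.seed(21)
  m4 <- matrix(rnorm(20), 4, 5,
               dimnames = list(c("A", "B", "C", "D"), paste0("d", 1:5)))
  sA <- grouping_scheme("A", c(A = "g1", B = "g1", C = "g2", D = "g2"))
  sB <- grouping_scheme("B", c(A = "h1", B = "h2", C = "h1", D = "h2"))
  cmp <- compare_groupings(m4, sA, sB)
  rho_a <- vapply(rownames(m4), function(mu)
    mutation_rho(m4[mu, ], loo_group_profile(m4, sA, mu)), numeric(1))
  rho_b <- vapply(rownames(m4), function(mu)
    mutation_rho(m4[mu, ], loo_group_profile(m4, sB, mu)), numeric(1))
  d <- rho_a - rho_b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$summary$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$summary$mean_a, mean(rho_a))
})

test_that("singleton-category mutations are dropped pairwise and listed", {
  m <- toy_matrix()
  sA <- grouping_scheme("A", c(A = "x", B = "x", C = "x", D = "solo"))
  sB <- grouping_scheme("B", c(A = "u", B = "u", C = "u", D = "u"))
  cmp <- compare_groupings(m, sA, sB)
  expect_equal(cmp$dropped$mutation, "D")
  expect_equal(cmp$dropped$reason_a, "singleton category")
  expect_equal(cmp$summary$n_pairs, 3)
  expect_error(compare_groupings(m[1:3, ],
                                 grouping_scheme("A", c(A = "x", B = "y", C = "z")),
                                 sB),
               "fewer than 3")
})

test_that("a perfectly separating binary predictor yields one split of goodness 1.5", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- data.frame(flag = c(0, 0, 0, 1, 1, 1))
  tree <- cart_fit(y, x, cart_control(minsplit = 2))
  s <- cart_splits(tree)
  expect_equal(nrow(s), 1)
  expect_equal(s$goodness, 1.5)
  expect_equal(variable_importance(tree), c(flag = 100))
})

test_that("a constant response yields a root-only tree with empty importance", {
  tree <- cart_fit(rep(2, 10), data.frame(a = 1:10),
                   cart_control(minsplit = 2))
  expect_null(tree$root$split)
  expect_length(variable_importance(tree), 0)
})

test_that("every chosen split equals the exhaustive-search optimum", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(6:15, 1)
    x <- data.frame(
      num = round(rnorm(n), 1),
      cat = sample(letters[1:sample(2:4, 1)], n, replace = TRUE),
      bin = sample(0:1, n, replace = TRUE))
    y <- rnorm(n) + 2 * (x$bin == 1) + as.numeric(factor(x$cat))
    tree <- cart_fit(y, x, cart_control(minsplit = n, cp = 0))
    s <- cart_splits(tree)
    if (!nrow(s)) next
    expect_equal(s$goodness[1], oracle_best_split_goodness(y, x),
                 tolerance = 1e-9, info = i)
  }
})

test_that("tree splits and importance agree with rpart on toys", {
  skip_if_not_installed("rpart")
  set.seed(17)
  for (i in 1:10) {
    n <- 30
    x <- data.frame(g = factor(sample(letters[1:4], n, replace = TRUE)),
                    z = round(rnorm(n), 2))
    y <- rnorm(n, sd = 0.3) + c(a = 0, b = 1, c = 2.5, d = 4)[as.character(x$g)]
    ctrl <- cart_control(minsplit = 10, cp = 0.01)
    tree <- cart_fit(y, x, ctrl)
    rp <- rpart::rpart(y ~ g + z, data = cbind(x, y), method = "anova",
                       control = rpart::rpart.control(
                         minsplit = 10, minbucket = 1, cp = 0.01,
                         maxsurrogate = 0, maxcompete = 0, xval = 0))
    imp_mine <- variable_importance(tree)
    imp_rp <- rp$variable.importance
    if (is.null(imp_rp)) {
      expect_length(imp_mine, 0)
      next
    }
    imp_rp <- 100 * imp_rp / sum(imp_rp)
    for (v in names(imp_rp)) {
      expect_equal(unname(imp_mine[v]), unname(imp_rp[v]), tolerance = 1e-6,
                   info = paste(i, v))
    }
    expect_equal(cart_splits(tree)$var[1],
                 as.character(rp$frame$var[1]))
  }
})

test_that("importance shares rescale summed goodness to 100", {
  # two splits with goodness 8 and 2 -> shares 80/20
  y <- c(0, 0, 4, 4, 10, 10, 12, 12) / 2
  x <- data.frame(a = c(0, 0, 0, 0, 1, 1, 1, 1),
                  b = c(0, 0, 1, 1, 0, 0, 1, 1))
  tree <- cart_fit(y, x, cart_control(minsplit = 2, cp = 0))
  s <- cart_splits(tree)
  imp <- variable_importance(tree)
  expect_equal(sum(imp), 100)
  by_var <- tapply(s$goodness, s$var, sum)
  expect_equal(unname(imp[names(by_var)]),
               as.numeric(100 * by_var / sum(by_var)))
})

test_that("rho, splits and importance are invariant to adding a constant", {
  set.seed(23)
  panel <- generate_mutation_panel(
    c("classical-like" = 3, "PACC" = 3, "Ex20ins-L" = 3, "T790M-like" = 4))
  m <- simulate_selectivity_matrix(panel, screen_template(sigma = 0.2),
                                   seed = 31)
  assignments <- classify_mutations(panel$mutation)
  schemes <- schemes_from_assignments(assignments, ids = panel$id)
  exons <- setNames(assignments$exon_group, panel$id)
  ctrl <- cart_control(minsplit = 6)

  cmp1 <- compare_groupings(m, schemes$structure, schemes$exon)
  imp1 <- importance_comparison(m, schemes$structure$map, exons, ctrl)
  m2 <- m
  m2$values <- m$values + 5
  cmp2 <- compare_groupings(m2, schemes$structure, schemes$exon)
  imp2 <- importance_comparison(m2, schemes$structure$map, exons, ctrl)
  expect_equal(cmp1$rho, cmp2$rho)
  expect_equal(imp1$per_drug, imp2$per_drug)
})

test_that("permuting the response washes out the structure signal", {
  # Under the permutation null the LOO-rho comparison gives no false signal
  # and the importance advantage collapses relative to the real signal.
  # (CART importance itself keeps the classic selection bias toward the
  # multi-level structure factor, so it is compared against the signal
  # case rather than against uniformity.)
  tmpl <- screen_template(sigma = 0.1)
  rho_p <- perm_diff <- real_diff <- numeric(0)
  for (s in 1:5) {
    set.seed(100 + s)
    panel <- generate_mutation_panel(
      c("classical-like" = 4, "PACC" = 4, "Ex20ins-L" = 4, "T790M-like" = 4))
    m <- simulate_selectivity_matrix(panel, tmpl)
    assignments <- classify_mutations(panel$mutation)
    schemes <- schemes_from_assignments(assignments, ids = panel$id)
    exons <- setNames(assignments$exon_group, panel$id)
    real <- importance_comparison(m, schemes$structure$map, exons,
                                  cart_control(minsplit = 8))
    perm <- sample(nrow(m$values))
    m$values <- m$values[perm, ]
    rownames(m$values) <- rownames(m$censored)
    permed <- importance_comparison(m, schemes$structure$map, exons,
                                    cart_control(minsplit = 8))
    cmp <- compare_groupings(m, schemes$structure, schemes$exon)
    rho_p <- c(rho_p, cmp$summary$p)
    real_diff <- c(real_diff,
                   real$test$mean_structure - real$test$mean_exon)
    perm_diff <- c(perm_diff,
                   permed$test$mean_structure - permed$test$mean_exon)
  }
  expect_gte(sum(rho_p > 0.05), 4)
  expect_true(all(real_diff > perm_diff))
})
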