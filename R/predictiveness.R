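# Does the structure-function grouping predict drug selectivity better than
# the exon grouping? Two complementary procedures: (1) per-mutation Spearman
# correlation of each mutation's selectivity profile against the
# leave-one-out mean profile of its group, compared between grouping schemes
# by a paired t-test; (2) per-drug CART regression trees with the structure
# group and exon indicators as predictors, comparing goodness-of-split
# variable importance.

#' Define a grouping scheme over matrix rows
#'
#' @param name Scheme name (e.g. `"structure"`, `"exon"`).
#' @param map Named character vector: mutation id to category label.
#' @return An object of class `"grouping_scheme"`.
#' @export
grouping_scheme <- function(name, map) {
  stopifnot(is.character(map), !is.null(names(map)), all(nzchar(names(map))))
  structure(list(name = name, map = map), class = "grouping_scheme")
}

#' Grouping schemes from classifier assignments
#'
#' Builds the structure-function scheme (top-level group labels) and the
#' exon scheme (exon of the defining variant) from a list of
#' `"egfr_assignment"` objects or a data frame with columns `id`, `group`,
#' `exon_group`.
#'
#' @param assignments List of [classify_allele()] results, or a data frame.
#' @param ids Row ids to use as names (defaults to the allele strings /
#'   `id` column).
#' @return List with elements `structure` and `exon`, each a
#'   [grouping_scheme()].
#' @export
schemes_from_assignments <- function(assignments, ids = NULL) {
  if (is.data.frame(assignments)) {
    stopifnot(all(c("group", "exon_group") %in% names(assignments)))
    if (is.null(ids)) ids <- assignments$id
    groups <- assignments$group
    exons <- assignments$exon_group
  } else {
    if (is.null(ids)) {
      ids <- vapply(assignments, `[[`, character(1), "allele")
    }
    groups <- vapply(assignments, `[[`, character(1), "group")
    exons <- vapply(assignments, `[[`, integer(1), "exon_group")
  }
  list(
    structure = grouping_scheme("structure", stats::setNames(groups, ids)),
    exon = grouping_scheme("exon",
                           stats::setNames(paste0("exon", exons), ids))
  )
}

#' Leave-one-out group mean profile for a mutation
#'
#' Per-drug mean of the selectivity values over the other members of the
#' mutation's category. A mutation whose category has no other member is
#' not evaluable and returns `NULL`.
#'
#' @param m A `"selectivity_matrix"` (or numeric matrix with rownames).
#' @param scheme A [grouping_scheme()] covering the matrix rows.
#' @param mutation Row id to leave out.
#' @return Named numeric vector over drugs, or `NULL` when not evaluable.
#' @export
loo_group_profile <- function(m, scheme, mutation) {
  v <- if (inherits(m, "selectivity_matrix")) m$values else as.matrix(m)
  stopifnot(inherits(scheme, "grouping_scheme"), mutation %in% rownames(v))
  if (!mutation %in% names(scheme$map)) {
    stop(sprintf("mutation '%s' is not mapped by scheme '%s'", mutation,
                 scheme$name), call. = FALSE)
  }
  category <- scheme$map[[mutation]]
  members <- setdiff(intersect(names(scheme$map)[scheme$map == category],
                               rownames(v)), mutation)
  if (!length(members)) return(NULL)
  colMeans(v[members, , drop = FALSE])
}

#' Spearman correlation between a mutation profile and a group profile
#'
#' Spearman's rank correlation with average-rank tie handling. A
#' zero-variance vector leaves rho undefined (`NA`).
#'
#' @param profile_self,profile_group Numeric vectors over the same set of
#'   at least 3 drugs.
#' @return Spearman's rho, or `NA` when undefined.
#' @export
mutation_rho <- function(profile_self, profile_group) {
  stopifnot(length(profile_self) == length(profile_group),
            length(profile_self) >= 3L)
  if (stats::sd(profile_self) == 0 || stats::sd(profile_group) == 0) {
    return(NA_real_)
  }
  stats::cor(profile_self, profile_group, method = "spearman")
}

#' Compare two grouping schemes by leave-one-out profile correlation
#'
#' For every mutation evaluable under both schemes (its category has
#' another member and neither profile is constant), computes Spearman's rho
#' between the mutation's own selectivity profile and the leave-one-out
#' mean profile of its category, under each scheme. The paired rho vectors
#' are summarized (mean and median per scheme) and compared by a paired
#' two-sided t-test. Mutations evaluable under only one scheme are dropped
#' from the pairing and listed.
#'
#' @param m A `"selectivity_matrix"` (or numeric matrix with rownames).
#' @param scheme_a,scheme_b Two [grouping_scheme()]s over the rows.
#' @return An object of class `"rho_comparison"`: list with `rho` (data
#'   frame: mutation, rho under each scheme), `summary` (means, medians, t,
#'   df, p), and `dropped` (data frame of excluded mutations with reasons).
#' @export
compare_groupings <- function(m, scheme_a, scheme_b) {
  v <- if (inherits(m, "selectivity_matrix")) m$values else as.matrix(m)
  one <- function(scheme, mutation) {
    prof <- loo_group_profile(v, scheme, mutation)
    if (is.null(prof)) return(list(rho = NA_real_, reason = "singleton category"))
    rho <- mutation_rho(v[mutation, ], prof)
    if (is.na(rho)) return(list(rho = NA_real_, reason = "zero-variance profile"))
    list(rho = rho, reason = NA_character_)
  }
  muts <- rownames(v)
  ra <- lapply(muts, function(mu) one(scheme_a, mu))
  rb <- lapply(muts, function(mu) one(scheme_b, mu))
  rho_a <- vapply(ra, `[[`, numeric(1), "rho")
  rho_b <- vapply(rb, `[[`, numeric(1), "rho")
  ok <- !is.na(rho_a) & !is.na(rho_b)
  dropped <- data.frame(
    mutation = muts[!ok],
    reason_a = vapply(ra[!ok], `[[`, character(1), "reason"),
    reason_b = vapply(rb[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  if (sum(ok) < 3L) {
    stop("fewer than 3 mutations are evaluable under both schemes",
         call. = FALSE)
  }
  rho <- data.frame(mutation = muts[ok], rho_a = rho_a[ok], rho_b = rho_b[ok],
                    stringsAsFactors = FALSE)
  names(rho)[2:3] <- paste0("rho_", c(scheme_a$name, scheme_b$name))
  d <- rho_a[ok] - rho_b[ok]
  if (all(d == 0)) {
    t_stat <- 0; p <- 1; df <- length(d) - 1
  } else if (stats::sd(d) / sqrt(length(d)) <
               10 * .Machine$double.eps * abs(mean(d))) {
    # differences constant to machine precision
    t_stat <- sign(mean(d)) * Inf; p <- 0; df <- length(d) - 1
  } else {
    tt <- stats::t.test(rho_a[ok], rho_b[ok], paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
  }
  structure(list(
    rho = rho,
    summary = list(
      scheme_a = scheme_a$name, scheme_b = scheme_b$name,
      mean_a = mean(rho_a[ok]), mean_b = mean(rho_b[ok]),
      median_a = stats::median(rho_a[ok]),
      median_b = stats::median(rho_b[ok]),
      t = t_stat, df = df, p = p, n_pairs = sum(ok)),
    dropped = dropped
  ), class = "rho_comparison")
}

#' @export
print.rho_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<rho_comparison> %s vs %s over %d paired mutations\n",
              s$scheme_a, s$scheme_b, s$n_pairs))
  cat(sprintf("  mean rho: %.3f vs %.3f; median: %.3f vs %.3f\n",
              s$mean_a, s$mean_b, s$median_a, s$median_b))
  cat(sprintf("  paired t = %.3f, df = %g, p = %.3g\n", s$t, s$df, s$p))
  if (nrow(x$dropped)) {
    cat(sprintf("  dropped %d non-evaluable mutation(s)\n", nrow(x$dropped)))
  }
  invisible(x)
}

#' Exon indicator design from an exon map
#'
#' @param exons Named integer vector (mutation id to exon number). A
#'   mutation spanning two exons may instead be supplied as a data frame of
#'   0/1 indicator columns `exon18`, `exon19`, `exon20`, `exon21`.
#' @return Data frame of four 0/1 indicator columns, rownames = ids.
#' @export
exon_indicators <- function(exons) {
  if (is.data.frame(exons)) {
    stopifnot(all(c("exon18", "exon19", "exon20", "exon21") %in% names(exons)))
    return(exons[, c("exon18", "exon19", "exon20", "exon21")])
  }
  stopifnot(!is.null(names(exons)))
  out <- data.frame(
    exon18 = as.integer(exons == 18L), exon19 = as.integer(exons == 19L),
    exon20 = as.integer(exons == 20L), exon21 = as.integer(exons == 21L),
    row.names = names(exons))
  out
}

#' Per-drug CART variable importance: structure group vs exon indicators
#'
#' Fits one regression tree per drug with a single unordered categorical
#' structure-group predictor plus four 0/1 exon indicators, computes
#' goodness-of-split variable importance, and compares the structure
#' importance against the summed exon-indicator importance by a paired
#' two-sided t-test across drugs. Also reports, per tree, whether the
#' structure predictor appears in the first or second split layer.
#'
#' @param m A `"selectivity_matrix"` (or numeric matrix with rownames).
#' @param structure_map Named character vector (mutation id to structure
#'   group), e.g. a [grouping_scheme()]'s `map`.
#' @param exons Named integer vector of exons, or indicator data frame (see
#'   [exon_indicators()]).
#' @param control A [cart_control()]; analyses of small panels need smaller
#'   `minsplit` than the default.
#' @return An object of class `"importance_comparison"`: list with
#'   `per_drug` (data frame: drug, structure and exon importance, whether
#'   the structure variable is in the first two split layers, root-only
#'   flag) and `test` (paired t, df, p, means).
#' @export
importance_comparison <- function(m, structure_map, exons,
                                  control = cart_control()) {
  v <- if (inherits(m, "selectivity_matrix")) m$values else as.matrix(m)
  if (ncol(v) < 2L) stop("need at least 2 drugs", call. = FALSE)
  ids <- rownames(v)
  stopifnot(all(ids %in% names(structure_map)))
  ind <- exon_indicators(exons)
  stopifnot(all(ids %in% rownames(ind)))
  x <- cbind(
    data.frame(structure_group = factor(structure_map[ids]),
               row.names = ids),
    ind[ids, ])

  per <- lapply(colnames(v), function(drug) {
    tree <- cart_fit(v[, drug], x, control = control)
    imp <- variable_importance(tree)
    root_only <- !length(imp)
    s_imp <- if (root_only) NA_real_ else unname(imp["structure_group"])
    e_imp <- if (root_only) NA_real_ else {
      sum(imp[c("exon18", "exon19", "exon20", "exon21")])
    }
    first_two <- c(
      if (!is.null(tree$root$split)) tree$root$split$var,
      if (!is.null(tree$root$left) && !is.null(tree$root$left$split)) {
        tree$root$left$split$var
      },
      if (!is.null(tree$root$right) && !is.null(tree$root$right$split)) {
        tree$root$right$split$var
      })
    data.frame(drug = drug, structure_importance = s_imp,
               exon_importance = e_imp,
               structure_in_first_two = "structure_group" %in% first_two,
               root_only = root_only, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  fitted <- per[!per$root_only, ]
  if (!nrow(fitted)) {
    stop("all per-drug trees are root-only; nothing to compare",
         call. = FALSE)
  }
  d <- fitted$structure_importance - fitted$exon_importance
  if (all(d == 0)) {
    t_stat <- 0; p <- 1; df <- length(d) - 1
  } else if (stats::sd(d) / sqrt(length(d)) <
               10 * .Machine$double.eps * abs(mean(d))) {
    # differences constant to machine precision (e.g. importance 100 vs 0
    # in every tree)
    t_stat <- sign(mean(d)) * Inf; p <- 0; df <- length(d) - 1
  } else {
    tt <- stats::t.test(fitted$structure_importance,
                        fitted$exon_importance, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
  }
  structure(list(
    per_drug = per,
    test = list(t = t_stat, df = df, p = p,
                mean_structure = mean(fitted$structure_importance),
                mean_exon = mean(fitted$exon_importance),
                n_trees = nrow(fitted))
  ), class = "importance_comparison")
}

#' @export
print.importance_comparison <- function(x, ...) {
  cat(sprintf("<importance_comparison> %d tree(s): structure %.1f vs exon %.1f (paired p = %.3g)\n",
              x$test$n_trees, x$test$mean_structure, x$test$mean_exon,
              x$test$p))
  invisible(x)
}
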