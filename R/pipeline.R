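# Configuration, CSV I/O, and the end-to-end pipeline driver.

# Numeric columns are serialized with 17 significant digits so that
# write -> read round-trips doubles losslessly.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

.write_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
}

#' Write / read a long-format screen table
#'
#' Lossless CSV round-trip of the screen schema used by [analyze_screen()]
#' (doubles are written with full precision; missing values as empty
#' fields).
#'
#' @param screen Screen data frame (see [generate_screen()]).
#' @param path File path.
#' @return `read_screen_csv` returns the screen data frame.
#' @export
write_screen_csv <- function(screen, path) {
  .write_csv(screen, path)
  invisible(path)
}

#' @rdname write_screen_csv
#' @export
read_screen_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("screen file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$concentration_nM <- as.numeric(df$concentration_nM)
  df$replicate <- as.integer(df$replicate)
  df$signal <- as.numeric(df$signal)
  df$is_dmso <- as.logical(df$is_dmso)
  df$drug_class[df$drug_class == ""] <- NA_character_
  df
}

#' Write / read a survival cohort table
#'
#' @param cohort Cohort data frame (see [generate_cohort()]).
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  .write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$time_months <- as.numeric(df$time_months)
  df$event <- as.integer(df$event)
  df
}

#' Classify a table of mutation strings
#'
#' Convenience wrapper mapping [classify_allele()] over a character vector,
#' returning a flat assignment table with collapsed rule traces.
#'
#' @param mutations Character vector of (compound) mutation strings.
#' @param rt A [rule_table()].
#' @param rm A [region_map()].
#' @return Data frame: `id`, `allele`, `group`, `subgroup`, `exon_group`,
#'   `bucket`, `contains_pacc`, `rule_trace` (rule ids joined by `";"`).
#' @export
classify_mutations <- function(mutations, rt = rule_table(),
                               rm = region_map()) {
  stopifnot(is.character(mutations), length(mutations) >= 1L)
  rows <- lapply(mutations, function(mu) {
    a <- classify_allele(mu, rt = rt, rm = rm)
    data.frame(id = mu, allele = a$allele, group = a$group,
               subgroup = a$subgroup, exon_group = a$exon_group,
               bucket = a$bucket, contains_pacc = a$contains_pacc,
               rule_trace = paste(a$rule_trace, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' All knobs of the end-to-end synthetic pipeline. Unknown arguments are
#' rejected (the function signature is the schema). The configuration is
#' serialized as JSON alongside every output bundle for provenance.
#'
#' @param seed RNG seed used for every stochastic step.
#' @param panel_counts Named vector for [generate_mutation_panel()].
#' @param screen Optional path to a screen CSV; when `NULL` a synthetic
#'   screen is generated.
#' @param cohort Optional path to a cohort CSV; when `NULL` a synthetic
#'   cohort is generated from [default_cohort_medians()].
#' @param sigma,sigma_m Screen noise parameters (see [screen_template()]).
#' @param n_per_arm,censoring Cohort parameters (see [cohort_template()]).
#' @param minsplit,cp CART controls (see [cart_control()]).
#' @param linkage Clustering linkage (see [hierarchical_cluster()]).
#' @param log_base Selectivity log base.
#' @param out_dir Optional output directory for the report bundle.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            panel_counts = c("classical-like" = 4,
                                             "PACC" = 4, "Ex20ins-L" = 4,
                                             "T790M-like" = 4),
                            screen = NULL, cohort = NULL,
                            sigma = 0.2, sigma_m = 0.1,
                            n_per_arm = 50L, censoring = 0.2,
                            minsplit = 8L, cp = 0.01,
                            linkage = "complete", log_base = 10,
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), panel_counts = panel_counts,
                 screen = screen, cohort = cohort, sigma = sigma,
                 sigma_m = sigma_m, n_per_arm = as.integer(n_per_arm),
                 censoring = censoring, minsplit = as.integer(minsplit),
                 cp = cp, linkage = linkage, log_base = log_base,
                 out_dir = out_dir), class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Composes the full analysis: mutation panel -> classification -> screen
#' (read or simulated) -> selectivity matrix and clustering -> grouping
#' comparison (leave-one-out rho and CART importance) -> survival cohort
#' (read or simulated) -> stratified Kaplan-Meier/log-rank report. All
#' numeric outputs are reproducible bit-for-bit given an identical
#' configuration and seed. When `out_dir` is set, the bundle (assignments,
#' matrix, reports, Newick merge tree) and the configuration JSON are
#' written there; on failure partial outputs are removed.
#'
#' @param config A [pipeline_config()].
#' @return The report bundle: list with `panel`, `assignments`, `matrix`,
#'   `clustering`, `rho_comparison`, `importance`, `cohort`, `survival`,
#'   and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  panel <- generate_mutation_panel(config$panel_counts)
  assignments <- classify_mutations(panel$mutation)
  assignments$id <- panel$id

  tmpl <- screen_template(sigma = config$sigma, sigma_m = config$sigma_m)
  if (!is.null(config$screen)) {
    screen <- read_screen_csv(config$screen)
    truth <- NULL
  } else {
    gen <- generate_screen(panel, tmpl)
    screen <- gen$screen
    truth <- gen$truth
  }
  analysis <- analyze_screen(screen, log_base = config$log_base)
  m <- analysis$matrix
  clustering <- hierarchical_cluster(m, "mutations", linkage = config$linkage)

  schemes <- schemes_from_assignments(assignments, ids = assignments$id)
  rho_cmp <- compare_groupings(m, schemes$structure, schemes$exon)
  exons <- stats::setNames(assignments$exon_group, assignments$id)
  imp <- importance_comparison(
    m, schemes$structure$map, exons,
    control = cart_control(minsplit = config$minsplit, cp = config$cp))

  if (!is.null(config$cohort)) {
    cohort <- read_cohort_csv(config$cohort)
  } else {
    cohort <- generate_cohort(cohort_template(
      default_cohort_medians(), n_per_arm = config$n_per_arm,
      censoring = config$censoring))
  }
  surv_by_group <- lapply(
    stats::setNames(nm = unique(cohort$tki_generation)),
    function(gen) stratified_outcomes(cohort, "group",
                                      tki_generation = gen))

  bundle <- list(panel = panel, assignments = assignments, matrix = m,
                 clustering = clustering, rho_comparison = rho_cmp,
                 importance = imp, cohort = cohort,
                 survival = surv_by_group, truth = truth, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    tryCatch({
      p <- function(f) file.path(config$out_dir, f)
      .write_csv(assignments, p("assignments.csv"))
      written <- c(written, p("assignments.csv"))
      mat_df <- data.frame(mutation = rownames(m$values), m$values,
                           check.names = FALSE, stringsAsFactors = FALSE)
      .write_csv(mat_df, p("selectivity_matrix.csv"))
      written <- c(written, p("selectivity_matrix.csv"))
      .write_csv(rho_cmp$rho, p("rho_comparison.csv"))
      written <- c(written, p("rho_comparison.csv"))
      .write_csv(imp$per_drug, p("importance.csv"))
      written <- c(written, p("importance.csv"))
      surv_tab <- do.call(rbind, lapply(names(surv_by_group), function(gen) {
        cbind(tki_generation = gen, surv_by_group[[gen]]$strata)
      }))
      .write_csv(surv_tab, p("survival_strata.csv"))
      written <- c(written, p("survival_strata.csv"))
      writeLines(clustering$newick, p("merge_tree.nwk"))
      written <- c(written, p("merge_tree.nwk"))
      jsonlite::write_json(config[setdiff(names(config), "out_dir")],
                           p("config.json"), auto_unbox = TRUE, digits = NA,
                           null = "null")
      written <- c(written, p("config.json"))
    }, error = function(e) {
      unlink(written)
      stop(e)
    })
  }
  invisible(bundle)
}

#' Repeated-seed study: structure vs exon grouping recovery
#'
#' For each seed, draws a mutation panel (default 6 mutations from each of
#' the four structure-function groups), simulates a selectivity matrix at
#' replicate noise `sigma`, classifies the panel, and runs both grouping
#' comparisons: leave-one-out Spearman rho (structure vs exon schemes,
#' paired t-test) and per-drug CART variable importance.
#'
#' @param n_seeds Number of independent simulated screens.
#' @param seed Base seed; run `s` uses `seed + s`.
#' @param sigma Replicate noise s.d. in log10 units (default 0.3).
#' @param n_per_group Mutations drawn per structure-function group.
#' @param minsplit,cp CART controls.
#' @return Data frame with one row per seed: mean/median rho per scheme,
#'   paired p, and mean structure/exon importance.
#' @export
simulation_grouping_study <- function(n_seeds = 100L, seed = 1L,
                                      sigma = 0.3, n_per_group = 6L,
                                      minsplit = 8L, cp = 0.01) {
  counts <- c("classical-like" = n_per_group, "PACC" = n_per_group,
              "Ex20ins-L" = n_per_group, "T790M-like" = n_per_group)
  tmpl <- screen_template(sigma = sigma)
  rows <- lapply(seq_len(n_seeds), function(s) {
    set.seed(seed + s)
    panel <- generate_mutation_panel(counts)
    m <- simulate_selectivity_matrix(panel, tmpl)
    assignments <- classify_mutations(panel$mutation)
    assignments$id <- panel$id
    schemes <- schemes_from_assignments(assignments, ids = assignments$id)
    cmp <- compare_groupings(m, schemes$structure, schemes$exon)
    imp <- importance_comparison(
      m, schemes$structure$map,
      stats::setNames(assignments$exon_group, assignments$id),
      control = cart_control(minsplit = minsplit, cp = cp))
    data.frame(seed = seed + s,
               mean_rho_structure = cmp$summary$mean_a,
               mean_rho_exon = cmp$summary$mean_b,
               median_rho_structure = cmp$summary$median_a,
               median_rho_exon = cmp$summary$median_b,
               rho_paired_p = cmp$summary$p,
               mean_imp_structure = imp$test$mean_structure,
               mean_imp_exon = imp$test$mean_exon,
               imp_paired_p = imp$test$p)
  })
  do.call(rbind, rows)
}

#' Repeated-seed study: PACC TKI-generation survival recovery
#'
#' For each seed, simulates a PACC cohort with target medians per TKI
#' generation (defaults 10.0, 21.7 and 4.1 months on first-, second- and
#' third-generation TKIs), and records the recovered Kaplan-Meier medians
#' and the second- vs third-generation log-rank comparison.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param seed Base seed; run `s` uses `seed + s`.
#' @param medians_months Named numeric: target median per generation.
#' @param n_per_arm Patients per generation arm.
#' @param censoring Censoring fraction.
#' @return Data frame per seed: recovered medians, ordering flag
#'   (2nd > 1st > 3rd), and the 2nd-vs-3rd log-rank HR and p.
#' @export
simulation_cohort_study <- function(n_seeds = 100L, seed = 1L,
                                    medians_months = c("1st" = 10.0,
                                                       "2nd" = 21.7,
                                                       "3rd" = 4.1),
                                    n_per_arm = 50L, censoring = 0.2) {
  tmpl <- cohort_template(
    data.frame(group = "PACC", tki_generation = names(medians_months),
               median_months = as.numeric(medians_months),
               stringsAsFactors = FALSE),
    n_per_arm = n_per_arm, censoring = censoring)
  rows <- lapply(seq_len(n_seeds), function(s) {
    cohort <- generate_cohort(tmpl, seed = seed + s)
    strat <- stratified_outcomes(cohort, "tki_generation", group = "PACC")
    med <- stats::setNames(strat$strata$median_months, strat$strata$stratum)
    pw <- strat$pairwise
    row_23 <- pw[(pw$numerator == "2nd" & pw$denominator == "3rd") |
                   (pw$numerator == "3rd" & pw$denominator == "2nd"), ]
    hr_23 <- if (row_23$numerator[1] == "2nd") row_23$hr[1] else 1 / row_23$hr[1]
    data.frame(seed = seed + s,
               median_1st = med[["1st"]], median_2nd = med[["2nd"]],
               median_3rd = med[["3rd"]],
               ordering_ok = !anyNA(med) &&
                 med[["2nd"]] > med[["1st"]] && med[["1st"]] > med[["3rd"]],
               hr_2nd_vs_3rd = hr_23, p_2nd_vs_3rd = row_23$p[1])
  })
  do.call(rbind, rows)
}
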