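# Synthetic screens, cohorts and mutation panels with the statistical
# structure the analysis assumes, so every pipeline stage is testable
# without clinical or screening data.

.sf_groups <- c("classical", "classical-like", "PACC", "Ex20ins-L",
                "T790M-like-3S", "T790M-like-3R")
.drug_classes <- c("1st-gen", "2nd-gen", "3rd-gen", "Ex20ins-active",
                   "ALKi", "PKCi")

# Default 18-drug panel: 3 first-, 4 second-, 3 third-generation TKIs,
# 4 Ex20ins-active inhibitors, 2 ALK inhibitors and 2 PKC inhibitors.
.default_drug_panel <- function() {
  data.frame(
    drug = c("erlotinib", "gefitinib", "icotinib",
             "afatinib", "dacomitinib", "neratinib", "poziotinib",
             "osimertinib", "rociletinib", "nazartinib",
             "mobocertinib", "CLN-081", "DZD9008", "tarloxotinib",
             "brigatinib", "crizotinib",
             "midostaurin", "sotrastaurin"),
    class = rep(.drug_classes, times = c(3, 4, 3, 4, 2, 2)),
    stringsAsFactors = FALSE)
}

# Expected log10(mutant IC50 / WT IC50) per (structure group, drug class).
# Encodes the qualitative selectivity ordering of the groups: classical and
# classical-like lines are most selective for third-generation TKIs; PACC
# for second-generation (covalent) TKIs; Ex20ins-L only for Ex20ins-active
# inhibitors and, mildly, select second-generation TKIs; T790M-like-3S for
# third-generation TKIs; T790M-like-3R only for ALK/PKC inhibitors.
.default_effects <- function() {
  eff <- rbind(
    "classical"      = c(-1.0, -1.2, -1.7, -0.8, -0.2,  0.0),
    "classical-like" = c(-1.0, -1.2, -1.8, -0.8, -0.3,  0.0),
    "PACC"           = c(-0.5, -1.5, -0.3, -0.6, -0.2,  0.0),
    "Ex20ins-L"      = c( 0.3, -0.4,  0.2, -1.2,  0.0,  0.1),
    "T790M-like-3S"  = c( 0.8,  0.5, -1.5, -0.5, -0.4, -0.3),
    "T790M-like-3R"  = c( 0.9,  0.7,  0.6,  0.4, -0.8, -0.7))
  colnames(eff) <- .drug_classes
  eff
}

#' Screen generation template
#'
#' Parameters of the synthetic drug screen: the expected
#' log10(mutant/WT IC50) per (structure group, drug class), the drug panel,
#' noise magnitudes and assay geometry (7 half-log doses spanning
#' 0.01x to 10x the wild-type IC50, technical triplicates).
#'
#' @param effects Groups x drug-classes matrix of expected log10 ratios.
#' @param drug_panel Data frame with columns `drug`, `class`.
#' @param sigma Biological-replicate noise s.d. on log10 IC50 (default 0.2).
#' @param sigma_m Per-mutation offset s.d. on log10 IC50 (default 0.1).
#' @param well_sd Additive per-well viability noise s.d. (default 0).
#' @param n_bio Biological replicates per (cell line, drug) (default 3).
#' @param wt_ic50_nM Wild-type IC50 in nM, common to all drugs (default 100).
#' @param dose_exponents log10 dose offsets relative to `wt_ic50_nM`
#'   (default 7 half-log steps, -2 to +1).
#' @return An object of class `"screen_template"`.
#' @export
screen_template <- function(effects = .default_effects(),
                            drug_panel = .default_drug_panel(),
                            sigma = 0.2, sigma_m = 0.1, well_sd = 0,
                            n_bio = 3L, wt_ic50_nM = 100,
                            dose_exponents = seq(-2, 1, by = 0.5)) {
  if (sigma < 0 || sigma_m < 0 || well_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  stopifnot(is.matrix(effects), !is.null(rownames(effects)),
            all(colnames(effects) %in% unique(drug_panel$class)) ||
              all(unique(drug_panel$class) %in% colnames(effects)),
            n_bio >= 1L, wt_ic50_nM > 0, length(dose_exponents) >= 4L)
  structure(list(effects = effects, drug_panel = drug_panel, sigma = sigma,
                 sigma_m = sigma_m, well_sd = well_sd,
                 n_bio = as.integer(n_bio), wt_ic50_nM = wt_ic50_nM,
                 dose_exponents = dose_exponents),
            class = "screen_template")
}

# Curated mutation pools per structure-function group. Every string parses
# and the classifier recovers the intended group (asserted by the test
# suite, which makes panel generation itself a classifier test).
.mutation_pools <- function() {
  list(
    "classical" = c("L858R", "E746_A750del", "L747_T751del",
                    "L747_P753delinsS", "E746_S752delinsV",
                    "L747_A750delinsP"),
    "classical-like" = c("L861Q", "A763insFQEA", "V834L", "K860I",
                         "A864T", "E866K"),
    "PACC" = c("G719A", "G719S", "L718Q", "S768I", "T854I", "L747P",
               "E709K", "V765L", "G796S", "C797S"),
    "Ex20ins-L" = c("A767insASV", "S768insSVD", "D770insNPG", "D770insSVD",
                    "N771insG", "H773insNPH", "V774insHV"),
    "T790M-like-3S" = c("L747_K754delinsATSPE", "G719A+T790M",
                        "L861Q+T790M", "S768I+T790M"),
    "T790M-like-3R" = c("L858R+T790M+C797S", "E746_A750del+T790M+C797S",
                        "L858R+T790M+L792H", "L861Q+T790M+L718Q")
  )
}

#' Generate a mutation panel with known structure-function groups
#'
#' Draws mutation strings from curated per-group pools: P-loop and other
#' pocket substitutions for PACC, loop insertions anchored at A767-V774 for
#' Ex20ins-L, T790M-containing compound alleles for T790M-like (a
#' `"T790M-like"` count is split between the 3S and 3R pools), L858R-like
#' point mutations and the alpha-C-helix insertion for classical-like, and
#' classical alleles.
#'
#' @param counts Named integer vector of mutations per group; names among
#'   `"classical"`, `"classical-like"`, `"PACC"`, `"Ex20ins-L"`,
#'   `"T790M-like"`, `"T790M-like-3S"`, `"T790M-like-3R"`.
#' @param seed Optional RNG seed for the draw.
#' @return Data frame with columns `id` (= mutation string), `mutation`,
#'   `group` (template-level label, 3S/3R resolved) and `structure_group`
#'   (top-level label).
#' @export
generate_mutation_panel <- function(counts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pools <- .mutation_pools()
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  bad <- setdiff(names(counts), c(names(pools), "T790M-like"))
  if (length(bad)) {
    stop(sprintf("unknown group(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  counts <- counts[counts > 0]
  draws <- list()
  for (grp in names(counts)) {
    n <- as.integer(counts[[grp]])
    if (grp == "T790M-like") {
      n3s <- ceiling(n / 2)
      draws[[length(draws) + 1L]] <-
        cbind(.draw_pool(pools[["T790M-like-3S"]], n3s), "T790M-like-3S")
      if (n - n3s > 0) {
        draws[[length(draws) + 1L]] <-
          cbind(.draw_pool(pools[["T790M-like-3R"]], n - n3s),
                "T790M-like-3R")
      }
    } else {
      draws[[length(draws) + 1L]] <- cbind(.draw_pool(pools[[grp]], n), grp)
    }
  }
  if (!length(draws)) {
    return(data.frame(id = character(0), mutation = character(0),
                      group = character(0), structure_group = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, draws)
  data.frame(id = m[, 1], mutation = m[, 1], group = m[, 2],
             structure_group = sub("-3[SR]$", "", m[, 2]),
             stringsAsFactors = FALSE)
}

.draw_pool <- function(pool, n) {
  if (n > length(pool)) {
    stop(sprintf("requested %d mutations but pool has only %d", n,
                 length(pool)), call. = FALSE)
  }
  matrix(sample(pool, n), ncol = 1)
}

#' Generate a long-format raw viability screen
#'
#' For each (mutation, drug), the true IC50 is
#' `wt_ic50 * 10^(effect + mutation offset)`, each biological replicate adds
#' log-normal replicate noise, and per-well viabilities follow an exact
#' unit-slope logistic at 7 half-log doses (technical triplicate), with
#' optional additive well noise. DMSO control wells (6 per cell line and
#' replicate) carry the plate-level baseline signal. Deterministic given a
#' seed.
#'
#' @param panel A panel from [generate_mutation_panel()] (columns `id`,
#'   `group`).
#' @param template A [screen_template()].
#' @param seed Optional RNG seed.
#' @return List with `screen` (long data frame: `cell_line`, `drug`,
#'   `drug_class`, `concentration_nM`, `replicate`, `signal`, `is_dmso`)
#'   and `truth` (mutations x drugs matrix of true expected log10 ratios,
#'   i.e. group effect + mutation offset, for recovery tests).
#' @export
generate_screen <- function(panel, template = screen_template(),
                            seed = NULL) {
  stopifnot(inherits(template, "screen_template"),
            is.data.frame(panel), all(c("id", "group") %in% names(panel)))
  if (!is.null(seed)) set.seed(seed)
  if (!all(panel$group %in% rownames(template$effects))) {
    stop("panel contains groups absent from the template effects matrix",
         call. = FALSE)
  }
  drugs <- template$drug_panel
  doses <- template$wt_ic50_nM * 10^template$dose_exponents
  baseline <- 10000
  n_tech <- 3L
  offsets <- stats::rnorm(nrow(panel), 0, template$sigma_m)
  truth <- outer(offsets, rep(0, nrow(drugs)), `+`) +
    template$effects[panel$group, drugs$class, drop = FALSE]
  dimnames(truth) <- list(panel$id, drugs$drug)

  rows <- list()
  emit_line <- function(cell_line, log_ratios) {
    for (j in seq_len(nrow(drugs))) {
      for (r in seq_len(template$n_bio)) {
        ic50 <- template$wt_ic50_nM *
          10^(log_ratios[j] + stats::rnorm(1, 0, template$sigma))
        frac <- rep(1 / (1 + doses / ic50), each = n_tech)
        conc <- rep(doses, each = n_tech)
        if (template$well_sd > 0) {
          frac <- pmax(frac + stats::rnorm(length(frac), 0,
                                           template$well_sd), 0)
        }
        rows[[length(rows) + 1L]] <<- data.frame(
          cell_line = cell_line, drug = drugs$drug[j],
          drug_class = drugs$class[j], concentration_nM = conc,
          replicate = r, signal = frac * baseline, is_dmso = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    # DMSO control wells, shared across the line's plates
    for (r in seq_len(template$n_bio)) {
      dm <- rep(baseline, 6)
      if (template$well_sd > 0) {
        dm <- pmax(dm + stats::rnorm(6, 0, template$well_sd) * baseline, 0)
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        cell_line = cell_line, drug = "DMSO", drug_class = NA_character_,
        concentration_nM = 0, replicate = r, signal = dm, is_dmso = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  emit_line("WT", rep(0, nrow(drugs)))
  for (i in seq_len(nrow(panel))) emit_line(panel$id[i], truth[i, ])
  list(screen = do.call(rbind, rows), truth = truth)
}

#' Simulate a selectivity matrix directly (no curve fitting)
#'
#' Matrix-level counterpart of [generate_screen()] + [analyze_screen()]:
#' each cell is the true expected log10 ratio (group effect + mutation
#' offset) plus the median of `n_bio` replicate noise draws, which is the
#' distribution the full pipeline produces for noiseless wells.
#'
#' @inheritParams generate_screen
#' @return A `"selectivity_matrix"` with attribute `"truth"` (the noiseless
#'   matrix) and `groups` filled from the panel.
#' @export
simulate_selectivity_matrix <- function(panel, template = screen_template(),
                                        seed = NULL) {
  stopifnot(inherits(template, "screen_template"),
            is.data.frame(panel), all(c("id", "group") %in% names(panel)))
  if (!is.null(seed)) set.seed(seed)
  drugs <- template$drug_panel
  offsets <- stats::rnorm(nrow(panel), 0, template$sigma_m)
  truth <- offsets + template$effects[panel$group, drugs$class, drop = FALSE]
  dimnames(truth) <- list(panel$id, drugs$drug)
  noise <- matrix(
    apply(matrix(stats::rnorm(length(truth) * template$n_bio, 0,
                              template$sigma),
                 nrow = template$n_bio), 2, stats::median),
    nrow = nrow(truth))
  values <- truth + noise
  dimnames(values) <- dimnames(truth)
  m <- structure(list(
    values = values,
    censored = matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values)),
    drug_class = stats::setNames(drugs$class, drugs$drug),
    missing = data.frame(mutation = character(0), drug = character(0),
                         stringsAsFactors = FALSE),
    groups = stats::setNames(panel$group, panel$id)
  ), class = "selectivity_matrix")
  attr(m, "truth") <- truth
  m
}

#' Cohort generation template
#'
#' @param medians Data frame with columns `group`, `tki_generation`,
#'   `median_months` (> 0): the target Kaplan-Meier median per arm.
#' @param n_per_arm Patients per (group, generation) arm.
#' @param censoring Fraction of patients censored, in \[0, 1).
#' @return An object of class `"cohort_template"`.
#' @export
cohort_template <- function(medians, n_per_arm = 50L, censoring = 0.2) {
  stopifnot(is.data.frame(medians),
            all(c("group", "tki_generation", "median_months") %in%
                  names(medians)))
  if (any(medians$median_months <= 0)) {
    stop("median event times must be positive", call. = FALSE)
  }
  if (censoring < 0 || censoring >= 1) {
    stop("censoring fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(medians = medians, n_per_arm = as.integer(n_per_arm),
                 censoring = censoring), class = "cohort_template")
}

# Upper bound b of the uniform censoring distribution U(0, b) such that the
# expected censored fraction of exponential(rate) event times is `target`:
# P(C < T) = (1 - exp(-rate * b)) / (rate * b), decreasing in b.
.censor_bound <- function(rate, target) {
  f <- function(b) (1 - exp(-rate * b)) / (rate * b) - target
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Generate a synthetic survival cohort
#'
#' Event times are exponential with rate `log(2) / median` per
#' (group, TKI generation) arm (memoryless single-parameter match to a
#' target median); censoring times are independent uniform draws calibrated
#' so the expected censored fraction equals the template's `censoring`.
#' Deterministic given a seed.
#'
#' @param template A [cohort_template()].
#' @param seed Optional RNG seed.
#' @param endpoint Endpoint label stored on each record (default `"TTF"`).
#' @return Data frame of survival records: `patient_id`, `group`,
#'   `tki_generation`, `endpoint`, `time_months`, `event`.
#' @export
generate_cohort <- function(template, seed = NULL, endpoint = "TTF") {
  stopifnot(inherits(template, "cohort_template"))
  if (!is.null(seed)) set.seed(seed)
  arms <- template$medians
  out <- list()
  pid <- 0L
  for (i in seq_len(nrow(arms))) {
    rate <- log(2) / arms$median_months[i]
    n <- template$n_per_arm
    t_event <- stats::rexp(n, rate)
    if (template$censoring > 0) {
      b <- .censor_bound(rate, template$censoring)
      t_cens <- stats::runif(n, 0, b)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    out[[i]] <- data.frame(
      patient_id = sprintf("P%05d", pid + seq_len(n)),
      group = arms$group[i], tki_generation = arms$tki_generation[i],
      endpoint = endpoint, time_months = time, event = event,
      stringsAsFactors = FALSE)
    pid <- pid + n
  }
  do.call(rbind, out)
}

#' Default survival scenario for the synthetic pipeline
#'
#' Per-(group, generation) median event times in months encoding the
#' retrospective directionality: PACC does best on second-generation TKIs
#' (21.7 vs 10.0 and 4.1 months on first/third generation), T790M-like on
#' third-generation, Ex20ins-L poorly on all three TKI generations, and
#' classical-like best on third-generation TKIs.
#'
#' @return Data frame with columns `group`, `tki_generation`,
#'   `median_months`.
#' @export
default_cohort_medians <- function() {
  data.frame(
    group = rep(c("classical-like", "PACC", "Ex20ins-L", "T790M-like"),
                each = 3),
    tki_generation = rep(c("1st", "2nd", "3rd"), times = 4),
    median_months = c(12, 10, 18,
                      10.0, 21.7, 4.1,
                      2.5, 5, 3,
                      3, 3, 10),
    stringsAsFactors = FALSE)
}
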