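# Dose-response fitting, mutant/WT selectivity ratios, the median-log
# selectivity matrix, hierarchical clustering and group comparisons.

#' Normalize raw viability signal to the DMSO vehicle control
#'
#' @param raw Numeric vector of raw per-well signals (e.g. bioluminescence).
#' @param dmso Numeric vector of DMSO control-well signals; their mean must
#'   be positive.
#' @return `raw / mean(dmso)`, so DMSO wells map to mean 1.
#' @examples
#' normalize_viability(5000, c(10000, 10000))   # 0.5
#' @export
normalize_viability <- function(raw, dmso) {
  if (!length(dmso) || !is.finite(mean(dmso)) || mean(dmso) <= 0) {
    stop("DMSO control mean must be positive", call. = FALSE)
  }
  raw / mean(dmso)
}

#' Fit a variable-slope logistic dose-response curve and interpolate the IC50
#'
#' Least-squares fit of the four-parameter logistic
#' `f(d) = bottom + (top - bottom) / (1 + (d / inflection)^hill)` on a log10
#' dose scale, with bounds `bottom` in \[0, 0.5\], `top` in \[0.5, 1.2\] and
#' positive `hill` (monotone non-increasing in dose). The IC50 is the
#' absolute 50%-inhibition point: the dose where the fitted fraction equals
#' 0.5 of the DMSO control (not the curve midpoint). When the fitted curve
#' never crosses 0.5 on the tested range the IC50 is censored at the nearest
#' tested dose (the maximum dose for resistant curves, the minimum for
#' hypersensitive ones) and flagged.
#'
#' @param doses Numeric vector of doses (one entry per observation; repeat
#'   doses for replicate wells). At least 4 distinct positive doses.
#' @param fractions DMSO-normalized viability fractions, same length.
#' @return An object of class `"dose_response"`: list with `fit` (`top`,
#'   `bottom`, `hill`, `inflection`), `ic50`, `ic50_censored`, `censor_side`
#'   (`"high"`, `"low"` or `NA`), and the input data.
#' @examples
#' d <- 10^seq(0, 3, length.out = 7)
#' fit_dose_response(d, 1 / (1 + d / 100))$ic50   # 100 to tolerance
#' @export
fit_dose_response <- function(doses, fractions) {
  if (length(doses) != length(fractions)) {
    stop("doses and fractions must have equal length", call. = FALSE)
  }
  if (length(unique(doses)) < 4L) {
    stop("at least 4 distinct dose levels are required", call. = FALSE)
  }
  if (any(doses <= 0) || !all(is.finite(doses)) || !all(is.finite(fractions))) {
    stop("doses must be positive and all values finite", call. = FALSE)
  }
  ld <- log10(doses)
  out <- function(top, bottom, hill, loginfl, ic50, censored, side) {
    structure(list(
      fit = list(top = top, bottom = bottom, hill = hill,
                 inflection = 10^loginfl),
      ic50 = ic50, ic50_censored = censored, censor_side = side,
      doses = doses, fractions = fractions
    ), class = "dose_response")
  }

  # mean fraction per dose, for starting values
  ord <- order(ld)
  mfrac <- tapply(fractions[ord], ld[ord], mean)
  mld <- as.numeric(names(mfrac))
  start_loginfl <- {
    below <- which(mfrac <= 0.5)
    if (length(below) && below[1] > 1L) {
      i <- below[1]
      # linear interpolation of the 0.5 crossing on the log-dose scale
      mld[i - 1] + (0.5 - mfrac[i - 1]) / (mfrac[i] - mfrac[i - 1]) *
        (mld[i] - mld[i - 1])
    } else if (length(below)) mld[1] else stats::median(mld)
  }
  start <- c(top = min(max(max(mfrac), 0.6), 1.15),
             bottom = max(min(min(mfrac), 0.4), 0.01),
             hill = 1, loginfl = unname(start_loginfl))

  # Levenberg-Marquardt on the residuals directly (robust to exact-fit,
  # zero-residual data, unlike an nls-model construction)
  resid_fn <- function(p) {
    fractions - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
                   (1 + 10^(p[["hill"]] * (ld - p[["loginfl"]]))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = c(top = 0.5, bottom = 0, hill = 1e-3, loginfl = min(ld) - 3),
      upper = c(top = 1.2, bottom = 0.5, hill = 25, loginfl = max(ld) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$info %in% 1:4) {
    if (mean(fractions) > 0.5) {
      # flat resistant curve: no 50% crossing on the tested range
      return(out(mean(fractions), 0, NA_real_, NA_real_,
                 max(doses), TRUE, "high"))
    }
    diag_msg <- if (inherits(fit, "error")) conditionMessage(fit) else
      fit$message
    stop(sprintf("dose-response fit failed to converge: %s", diag_msg),
         call. = FALSE)
  }
  p <- as.list(fit$par)
  f_at <- function(x) {
    p$bottom + (p$top - p$bottom) / (1 + 10^(p$hill * (x - p$loginfl)))
  }
  if (f_at(max(ld)) > 0.5) {
    return(out(p$top, p$bottom, p$hill, p$loginfl, max(doses), TRUE, "high"))
  }
  if (f_at(min(ld)) < 0.5) {
    return(out(p$top, p$bottom, p$hill, p$loginfl, min(doses), TRUE, "low"))
  }
  lic50 <- p$loginfl + log10((p$top - 0.5) / (0.5 - p$bottom)) / p$hill
  lic50 <- min(max(lic50, min(ld)), max(ld))
  out(p$top, p$bottom, p$hill, p$loginfl, 10^lic50, FALSE, NA_character_)
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> IC50 = %.4g%s (top %.3g, bottom %.3g, hill %.3g)\n",
              x$ic50, if (x$ic50_censored) paste0(" [censored ", x$censor_side, "]") else "",
              x$fit$top, x$fit$bottom, x$fit$hill))
  invisible(x)
}

#' Mutant/wild-type selectivity ratio
#'
#' @param ic50_mut Mutant-line IC50.
#' @param wt_ic50s Replicate IC50 values for the wild-type-EGFR line; the
#'   denominator is their mean.
#' @param log_base Base for the log-ratio (default 10).
#' @return List with `ratio` and `log_ratio`.
#' @examples
#' mutant_wt_ratio(10, c(100, 100, 100))   # ratio 0.1, log_ratio -1
#' @export
mutant_wt_ratio <- function(ic50_mut, wt_ic50s, log_base = 10) {
  if (!length(wt_ic50s) || any(wt_ic50s <= 0) || any(ic50_mut <= 0)) {
    stop("IC50 values must be positive and WT replicates non-empty",
         call. = FALSE)
  }
  ratio <- ic50_mut / mean(wt_ic50s)
  list(ratio = ratio, log_ratio = log(ratio, base = log_base))
}

#' Build a selectivity matrix from per-replicate log-ratios
#'
#' Each (mutation, drug) cell is the median over biological replicates of
#' the log(mutant/WT) IC50 ratio (for an even replicate count, the mean of
#' the two middle values). A cell is flagged censored when a censored
#' replicate sits at the median position. Missing (mutation, drug)
#' combinations are reported, not imputed.
#'
#' @param ratios Data frame with columns `mutation`, `drug`, `log_ratio`,
#'   and optionally `censored` (logical) and `drug_class`.
#' @return An object of class `"selectivity_matrix"`: list with `values`
#'   (mutations x drugs matrix), `censored` (logical matrix), `drug_class`
#'   (named character vector over drugs, `NA` when not supplied), `missing`
#'   (data frame of absent cells) and `groups` (placeholder for row
#'   annotations, filled by callers).
#' @export
build_selectivity_matrix <- function(ratios) {
  stopifnot(is.data.frame(ratios),
            all(c("mutation", "drug", "log_ratio") %in% names(ratios)))
  if (!nrow(ratios)) stop("no replicate ratios supplied", call. = FALSE)
  if (is.null(ratios$censored)) ratios$censored <- FALSE
  muts <- unique(ratios$mutation)
  drugs <- unique(ratios$drug)
  values <- matrix(NA_real_, length(muts), length(drugs),
                   dimnames = list(muts, drugs))
  cens <- matrix(FALSE, length(muts), length(drugs),
                 dimnames = list(muts, drugs))
  key <- interaction(ratios$mutation, ratios$drug, drop = TRUE, sep = "\r")
  for (cell in split(seq_len(nrow(ratios)), key)) {
    v <- ratios$log_ratio[cell]
    cflag <- ratios$censored[cell]
    i <- ratios$mutation[cell[1]]
    j <- ratios$drug[cell[1]]
    values[i, j] <- stats::median(v)
    ord <- order(v)
    n <- length(v)
    mid <- if (n %% 2 == 1) (n + 1) / 2 else c(n / 2, n / 2 + 1)
    cens[i, j] <- any(cflag[ord][mid])
  }
  missing_idx <- which(is.na(values), arr.ind = TRUE)
  missing <- data.frame(mutation = muts[missing_idx[, 1]],
                        drug = drugs[missing_idx[, 2]],
                        stringsAsFactors = FALSE)
  drug_class <- rep(NA_character_, length(drugs))
  names(drug_class) <- drugs
  if (!is.null(ratios$drug_class)) {
    dc <- ratios[!duplicated(ratios$drug), c("drug", "drug_class")]
    drug_class[dc$drug] <- dc$drug_class
  }
  structure(list(values = values, censored = cens, drug_class = drug_class,
                 missing = missing, groups = NULL),
            class = "selectivity_matrix")
}

#' @export
print.selectivity_matrix <- function(x, ...) {
  cat(sprintf("<selectivity_matrix> %d mutations x %d drugs (%d censored cells, %d missing)\n",
              nrow(x$values), ncol(x$values), sum(x$censored),
              nrow(x$missing)))
  invisible(x)
}

#' Hierarchically cluster a selectivity matrix
#'
#' Agglomerative clustering of mutations (rows) or drugs (columns) under
#' Euclidean distance between selectivity profiles. Censored cells are
#' already represented at their censoring bound, so the matrix is complete;
#' missing cells raise an error.
#'
#' @param m A `"selectivity_matrix"` (or plain numeric matrix).
#' @param axis `"mutations"` (rows) or `"drugs"` (columns).
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"complete"`.
#' @return List with `order` (leaf order), `labels`, `merge`, `height`, the
#'   `"hclust"` object, and `newick` (the merge tree as Newick text).
#' @export
hierarchical_cluster <- function(m, axis = c("mutations", "drugs"),
                                 linkage = "complete") {
  axis <- match.arg(axis)
  x <- if (inherits(m, "selectivity_matrix")) m$values else as.matrix(m)
  if (axis == "drugs") x <- t(x)
  if (nrow(x) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (anyNA(x)) stop("clustered axis contains missing values", call. = FALSE)
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(order = hc$order, labels = hc$labels, merge = hc$merge,
       height = hc$height, hclust = hc, newick = newick)
}

# Sidak step-down (Holm-Sidak) adjustment of a vector of p-values.
holm_sidak <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  res <- numeric(m)
  res[o] <- adj
  res
}

# Welch two-sample t-test p-value with explicit handling of zero-variance
# degenerate groups (identical constants compare equal, p = 1).
.welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y)$p.value
}

#' Compare selectivity between groups (Welch ANOVA + Holm-Sidak)
#'
#' One-way analysis of variance without the equal-variance assumption
#' (Welch) across groups of selectivity values, followed by pairwise Welch
#' t-tests adjusted by the Holm-Sidak step-down procedure.
#'
#' When `x` is a `"selectivity_matrix"`, observations are its cell values
#' and the default grouping is the drug class of each column (optionally
#' restricted to a subset of mutations), which reproduces per-class
#' selectivity comparisons for a mutation group. Alternatively pass a plain
#' numeric vector `x` with a `groups` vector of equal length.
#'
#' @param x A `"selectivity_matrix"` or numeric vector of observations.
#' @param groups Group label per column (matrix input) or per observation
#'   (vector input); defaults to the matrix drug classes.
#' @param mutations Optional row subset (matrix input).
#' @return List with `anova` (`f`, `df1`, `df2`, `p`) and `pairwise` (data
#'   frame with group pair, mean difference, raw and adjusted p).
#' @export
compare_group_selectivity <- function(x, groups = NULL, mutations = NULL) {
  if (inherits(x, "selectivity_matrix")) {
    v <- x$values
    if (!is.null(mutations)) v <- v[mutations, , drop = FALSE]
    if (is.null(groups)) groups <- x$drug_class
    obs <- as.vector(v)
    g <- rep(as.character(groups), each = nrow(v))
  } else {
    obs <- as.numeric(x)
    g <- as.character(groups)
  }
  keep <- !is.na(obs) & !is.na(g)
  obs <- obs[keep]; g <- g[keep]
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  by_g <- split(obs, g)
  anova <- if (all(vapply(by_g, stats::sd, numeric(1)) == 0)) {
    # all groups constant: no dispersion to test against
    eq <- length(unique(vapply(by_g, mean, numeric(1)))) == 1L
    list(f = 0, df1 = length(by_g) - 1, df2 = NA_real_,
         p = if (eq) 1 else 0)
  } else {
    ow <- stats::oneway.test(obs ~ factor(g), var.equal = FALSE)
    list(f = unname(ow$statistic), df1 = unname(ow$parameter[1]),
         df2 = unname(ow$parameter[2]), p = ow$p.value)
  }
  pairs <- utils::combn(names(by_g), 2)
  raw_p <- numeric(ncol(pairs))
  diffs <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- by_g[[pairs[1, k]]]; b <- by_g[[pairs[2, k]]]
    raw_p[k] <- .welch_p(a, b)
    diffs[k] <- mean(a) - mean(b)
  }
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         mean_diff = diffs, p = raw_p,
                         p_adj = holm_sidak(raw_p),
                         stringsAsFactors = FALSE)
  list(anova = anova, pairwise = pairwise)
}

#' Run the full screen pipeline on a long-format raw screen
#'
#' Normalizes each well to its cell line and replicate's DMSO control mean,
#' fits a dose-response curve per (cell line, drug, biological replicate),
#' interpolates IC50s, divides by the mean wild-type IC50 per drug and
#' builds the median log(Mut/WT) selectivity matrix.
#'
#' @param screen Long-format data frame with columns `cell_line`, `drug`,
#'   `drug_class`, `concentration_nM`, `replicate`, `signal`, `is_dmso`
#'   (see [generate_screen()] for the writer side).
#' @param wt_cell_line Identifier of the wild-type-EGFR control line.
#' @param log_base Base of the selectivity log-ratio (default 10).
#' @return List with `ic50s` (per replicate fits: data frame) and `matrix`
#'   (a `"selectivity_matrix"` over mutant lines).
#' @export
analyze_screen <- function(screen, wt_cell_line = "WT", log_base = 10) {
  needed <- c("cell_line", "drug", "drug_class", "concentration_nM",
              "replicate", "signal", "is_dmso")
  if (!all(needed %in% names(screen))) {
    stop(sprintf("screen table must have columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (!wt_cell_line %in% screen$cell_line) {
    stop(sprintf("wild-type cell line '%s' absent from screen", wt_cell_line),
         call. = FALSE)
  }
  dmso <- screen[screen$is_dmso, ]
  wells <- screen[!screen$is_dmso, ]
  dmso_mean <- tapply(dmso$signal,
                      interaction(dmso$cell_line, dmso$replicate, sep = "\r"),
                      mean)

  key <- interaction(wells$cell_line, wells$drug, wells$replicate,
                     drop = TRUE, sep = "\r")
  rows <- split(seq_len(nrow(wells)), key)
  ic50s <- do.call(rbind, lapply(rows, function(idx) {
    cl <- wells$cell_line[idx[1]]
    rep_id <- wells$replicate[idx[1]]
    dm <- dmso_mean[paste(cl, rep_id, sep = "\r")]
    if (is.na(dm)) {
      stop(sprintf("no DMSO control for cell line '%s' replicate '%s'",
                   cl, rep_id), call. = FALSE)
    }
    frac <- normalize_viability(wells$signal[idx], dm)
    fit <- fit_dose_response(wells$concentration_nM[idx], frac)
    data.frame(cell_line = cl, drug = wells$drug[idx[1]],
               drug_class = wells$drug_class[idx[1]], replicate = rep_id,
               ic50_nM = fit$ic50, censored = fit$ic50_censored,
               stringsAsFactors = FALSE)
  }))
  rownames(ic50s) <- NULL

  wt <- ic50s[ic50s$cell_line == wt_cell_line, ]
  wt_mean <- tapply(wt$ic50_nM, wt$drug, mean)
  mut <- ic50s[ic50s$cell_line != wt_cell_line, ]
  wm <- wt_mean[mut$drug]
  if (anyNA(wm)) {
    stop("some drugs lack wild-type IC50 measurements", call. = FALSE)
  }
  ratios <- data.frame(
    mutation = mut$cell_line, drug = mut$drug, drug_class = mut$drug_class,
    replicate = mut$replicate,
    log_ratio = log(mut$ic50_nM / as.numeric(wm), base = log_base),
    censored = mut$censored, stringsAsFactors = FALSE)
  list(ic50s = ic50s, matrix = build_selectivity_matrix(ratios))
}
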