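# Assignment of EGFR variants and alleles to structure-function groups.
#
# The classifier is an ordered rule table: curated exceptions (mutation names
# with an established group) are checked before positional rules, and the
# first matching rule wins. Every assignment carries a rule trace recording,
# in order, the identifiers of the rules that fired.

#' Default classification rule table
#'
#' Curated entries cover mutations whose group is established by named
#' evidence rather than position: the exon 19 delins `L747_K754delinsATSPE`
#' behaves like a hydrophobic-core (T790M-like) mutation despite its
#' location; PACC membership is pinned for substitutions at E709, L718,
#' G719, L747 and L792 (any replacement residue) and for S768I, T854I,
#' V765L, G796S and C797S. Substitutions at C797, L718 or L792 co-occurring
#' with T790M mark an allele as third-generation-TKI resistant (subgroup
#' 3R). All positional logic (alpha-C-helix insertions, exon 20 loop
#' insertions, P-loop/hinge/post-alpha-C point mutations, the
#' distant-from-pocket fallback) lives in [classify_variant()] and fires
#' after the curated entries.
#'
#' @param curated_alleles Named character vector: canonical mutation string
#'   to group label.
#' @param pacc_positions Residues whose substitutions are curated PACC.
#' @param pacc_names Canonical substitution names that are curated PACC.
#' @param resistance_3r_positions Residues whose substitutions confer
#'   third-generation-TKI resistance when combined with T790M.
#' @return An object of class `"egfr_rule_table"`.
#' @export
rule_table <- function(curated_alleles = c("L747_K754delinsATSPE" = "T790M-like"),
                       pacc_positions = c(709L, 718L, 719L, 747L, 792L),
                       pacc_names = c("S768I", "T854I", "V765L", "G796S", "C797S"),
                       resistance_3r_positions = c(797L, 718L, 792L)) {
  structure(list(
    curated_alleles = curated_alleles,
    pacc_positions = as.integer(pacc_positions),
    pacc_names = pacc_names,
    resistance_3r_positions = as.integer(resistance_3r_positions)
  ), class = "egfr_rule_table")
}

# Classical single variants: L858R, T790M, or an exon 19 deletion (deletions
# with insertions allowed) beginning at E746 or L747 and ending at <= A755.
.is_classical_variant <- function(v) {
  if (v$kind == "substitution") {
    return((v$start == 858L && v$alt_seq == "R") ||
           (v$start == 790L && v$alt_seq == "M"))
  }
  if (v$kind %in% c("deletion", "delins")) {
    return(v$start %in% c(746L, 747L) && v$end <= 755L)
  }
  FALSE
}

# Classical status with curated exceptions honoured: a variant whose
# canonical name carries a curated non-classical group (e.g. the exon 19
# delins L747_K754delinsATSPE, which is T790M-like) is never classical even
# when it matches the mechanical exon 19 deletion definition.
.is_classical_variant_rt <- function(v, rt) {
  canon <- format(v)
  if (canon %in% names(rt$curated_alleles)) {
    return(identical(unname(rt$curated_alleles[canon]), "classical"))
  }
  .is_classical_variant(v)
}

.is_t790m <- function(v) {
  v$kind == "substitution" && v$start == 790L && v$alt_seq == "M"
}

#' Is an allele classical?
#'
#' An allele is classical when every one of its variants is classical:
#' L858R, T790M, or an exon 19 deletion (plain or with inserted residues)
#' beginning at amino acid E746 or L747 and ending at or before A755.
#'
#' @param a An `"egfr_allele"` (or compound string, parsed on the fly).
#' @param rt A [rule_table()]; curated exceptions (names with an
#'   established non-classical group) are never classical even when they
#'   match the mechanical definition.
#' @return `TRUE`/`FALSE`.
#' @examples
#' is_classical("E746_A750del")
#' is_classical("L858R+T790M")
#' is_classical("L861Q")
#' @export
is_classical <- function(a, rt = rule_table()) {
  if (is.character(a)) a <- parse_allele(a)
  stopifnot(inherits(a, "egfr_allele"))
  all(vapply(a$variants, .is_classical_variant_rt, logical(1), rt = rt))
}

#' Classify a single variant into a structure-function group
#'
#' Applies the ordered rule table: curated exceptions first, then the
#' classical definition, hydrophobic-core substitutions (T790M-like),
#' curated PACC names/positions, insertions anchored in the alpha-C helix
#' (classical-like), insertions anchored in the exon 20 loop span
#' (Ex20ins-L, subdivided into near/far loop by anchor), substitutions in
#' the P-loop, hinge, or the loop C-terminal to the alpha-C helix (PACC),
#' and finally the positional distant-from-pocket rule labelling remaining
#' kinase-domain substitutions classical-like. Anything unmatched is
#' reported as `"unclassified"`, never silently absorbed.
#'
#' @param v An `"egfr_variant"` (or string, parsed on the fly).
#' @param rt A [rule_table()].
#' @param rm A [region_map()].
#' @return List with `group` (one of `"classical"`, `"classical-like"`,
#'   `"T790M-like"`, `"Ex20ins-L"`, `"PACC"`, `"unclassified"`), `subgroup`
#'   (`"none"`, `"NL"` or `"FL"`; 3S/3R are allele-level), `rule_trace`
#'   (character vector of fired rule ids) and `variant` (canonical string).
#' @examples
#' classify_variant("L718Q")$group
#' classify_variant("A763insFQEA")$group
#' @export
classify_variant <- function(v, rt = rule_table(), rm = region_map()) {
  if (is.character(v)) v <- parse_mutation(v)
  stopifnot(inherits(v, "egfr_variant"), inherits(rt, "egfr_rule_table"),
            inherits(rm, "egfr_region_map"))
  canon <- format(v)
  res <- function(group, subgroup, trace) {
    list(group = group, subgroup = subgroup, rule_trace = trace,
         variant = canon)
  }

  if (canon %in% names(rt$curated_alleles)) {
    return(res(unname(rt$curated_alleles[canon]), "none",
               paste0("curated_exception:", canon)))
  }
  if (v$kind == "substitution" && v$start %in% rm$hydrophobic_core) {
    # hydrophobic-core substitutions (T790M itself included) define the
    # T790M-like group at variant level; alleles that are fully classical
    # (e.g. L858R+T790M) are still labelled classical at allele level
    return(res("T790M-like", "none", "hydrophobic_core_substitution"))
  }
  if (.is_classical_variant(v)) {
    return(res("classical", "none", "classical_definition"))
  }
  if (v$kind == "substitution" && canon %in% rt$pacc_names) {
    return(res("PACC", "none", paste0("curated_pacc_name:", canon)))
  }
  if (v$kind == "substitution" && v$start %in% rt$pacc_positions) {
    return(res("PACC", "none", paste0("curated_pacc_position:", v$start)))
  }
  if (v$kind %in% c("insertion", "duplication")) {
    anchor <- .variant_interval(v)
    if (.intersects(anchor, rm$alpha_c_helix)) {
      return(res("classical-like", "none", "alpha_c_helix_insertion"))
    }
    if (.intersects(anchor, rm$near_loop)) {
      return(res("Ex20ins-L", "NL", "ex20_loop_insertion_near"))
    }
    if (.intersects(anchor, rm$far_loop)) {
      return(res("Ex20ins-L", "FL", "ex20_loop_insertion_far"))
    }
  }
  if (v$kind == "substitution") {
    for (region in c("p_loop", "hinge", "alpha_c_loop")) {
      if (.intersects(.variant_interval(v), rm[[region]])) {
        return(res("PACC", "none", paste0("positional_pacc:", region)))
      }
    }
    if (v$in_kinase_domain) {
      # positional fallback: kinase-domain point mutation distant from the
      # drug-binding pocket
      return(res("classical-like", "none", "positional_distant_from_pocket"))
    }
  }
  res("unclassified", "none", "no_rule_matched")
}

#' Classify a (possibly compound) allele
#'
#' Variant-level labels are combined with the precedence classical >
#' T790M-like > Ex20ins-L > PACC > classical-like: a fully classical allele
#' is classical; any T790M-containing (or curated T790M-like) allele is
#' T790M-like, with subgroup 3R when a known third-generation-resistance
#' substitution (C797X, L718X or L792X) co-occurs and 3S otherwise; any
#' exon 20 loop insertion dominates remaining combinations; then any PACC
#' variant; alleles whose variants are all classical/classical-like are
#' classical-like. The component variant labels are retained so composites
#' such as classical + acquired PACC can still be grouped as
#' PACC-containing.
#'
#' @param a An `"egfr_allele"` (or compound string, parsed on the fly).
#' @param rt A [rule_table()].
#' @param rm A [region_map()].
#' @return An object of class `"egfr_assignment"`: list with `allele`
#'   (canonical string), `group`, `subgroup` (`"none"`, `"3S"`, `"3R"`,
#'   `"NL"`, `"FL"`), `variant_groups` (named character vector of per-variant
#'   labels), `exon_group` (exon of the defining variant), `bucket` (cohort
#'   bucket, see [bucket_patient()]), `contains_pacc`, and `rule_trace`.
#' @examples
#' classify_allele("L858R+T790M+C797S")$subgroup   # "3R"
#' classify_allele("L747_K754delinsATSPE")$group   # "T790M-like"
#' @export
classify_allele <- function(a, rt = rule_table(), rm = region_map()) {
  if (is.character(a)) a <- parse_allele(a)
  stopifnot(inherits(a, "egfr_allele"))
  per <- lapply(a$variants, classify_variant, rt = rt, rm = rm)
  vgroups <- vapply(per, `[[`, character(1), "group")
  vsubs <- vapply(per, `[[`, character(1), "subgroup")
  canon_v <- vapply(per, `[[`, character(1), "variant")
  names(vgroups) <- canon_v
  trace <- unlist(lapply(per, `[[`, "rule_trace"), use.names = FALSE)

  has_t790m <- any(vapply(a$variants, .is_t790m, logical(1)))
  is_3r_comut <- function(v) {
    v$kind == "substitution" && v$start %in% rt$resistance_3r_positions &&
      !.is_t790m(v)
  }
  comuts <- vapply(a$variants, is_3r_comut, logical(1))

  group <- NULL; subgroup <- "none"; defining <- 1L
  if (is_classical(a, rt = rt)) {
    group <- "classical"
    trace <- c(trace, "allele_all_classical")
  } else if (has_t790m || any(vgroups == "T790M-like")) {
    group <- "T790M-like"
    defining <- which(has_t790m & vapply(a$variants, .is_t790m, logical(1)))[1]
    if (is.na(defining)) defining <- which(vgroups == "T790M-like")[1]
    if (any(comuts)) {
      subgroup <- "3R"
      trace <- c(trace, paste0("resistance_comutation:",
                               canon_v[which(comuts)[1]]))
    } else {
      subgroup <- "3S"
    }
    trace <- c(trace, "allele_t790m_precedence")
  } else if (any(vgroups == "Ex20ins-L")) {
    group <- "Ex20ins-L"
    defining <- which(vgroups == "Ex20ins-L")[1]
    subgroup <- vsubs[defining]
    trace <- c(trace, "allele_ex20ins_precedence")
  } else if (any(vgroups == "PACC")) {
    group <- "PACC"
    defining <- which(vgroups == "PACC")[1]
    trace <- c(trace, "allele_pacc_precedence")
  } else if (all(vgroups %in% c("classical", "classical-like"))) {
    group <- "classical-like"
    defining <- which(vgroups == "classical-like")[1]
    if (is.na(defining)) defining <- 1L
    trace <- c(trace, "allele_all_classical_like")
  } else {
    group <- "unclassified"
    trace <- c(trace, "allele_unclassified")
  }

  def_var <- a$variants[[defining]]
  exon_group <- exon_of(.variant_interval(def_var)[1], rm)

  structure(list(
    allele = paste(canon_v, collapse = "+"),
    raw = a$raw,
    group = group,
    subgroup = subgroup,
    variant_groups = vgroups,
    exon_group = exon_group,
    bucket = bucket_patient(a, rt = rt, rm = rm),
    contains_pacc = any(vgroups == "PACC"),
    rule_trace = trace
  ), class = "egfr_assignment")
}

#' @export
print.egfr_assignment <- function(x, ...) {
  cat(sprintf("<egfr_assignment> %s -> %s%s (exon %s, bucket '%s')\n",
              x$allele, x$group,
              if (x$subgroup != "none") paste0("-", x$subgroup) else "",
              ifelse(is.na(x$exon_group), "NA", x$exon_group), x$bucket))
  cat("  rules:", paste(x$rule_trace, collapse = " > "), "\n")
  invisible(x)
}

#' Cohort bucket for a patient allele
#'
#' The five mutually exclusive cohort categories: `"classical"` (classical
#' variants only, with or without T790M), `"classical+T790M+atypical"`
#' (a classical core plus T790M plus at least one atypical variant),
#' `"Ex20ins"` (a single exon 20 loop insertion with no partner),
#' `"atypical"` (a single atypical, non-loop-insertion variant) and
#' `"complex-with-atypical"` (two or more variants including an atypical
#' one, without the classical+T790M pattern).
#'
#' @param a An `"egfr_allele"` (or compound string).
#' @param rt A [rule_table()].
#' @param rm A [region_map()].
#' @return One of the five bucket labels.
#' @examples
#' bucket_patient("L858R+T790M")          # "classical"
#' bucket_patient("L858R+T790M+L718Q")    # "classical+T790M+atypical"
#' @export
bucket_patient <- function(a, rt = rule_table(), rm = region_map()) {
  if (is.character(a)) a <- parse_allele(a)
  stopifnot(inherits(a, "egfr_allele"))
  classical_v <- vapply(a$variants, .is_classical_variant_rt, logical(1),
                        rt = rt)
  t790m_v <- vapply(a$variants, .is_t790m, logical(1))
  if (all(classical_v)) return("classical")
  has_core <- any(classical_v & !t790m_v)
  if (has_core && any(t790m_v) && any(!classical_v)) {
    return("classical+T790M+atypical")
  }
  if (length(a$variants) == 1L) {
    vg <- classify_variant(a$variants[[1]], rt = rt, rm = rm)$group
    return(if (vg == "Ex20ins-L") "Ex20ins" else "atypical")
  }
  "complex-with-atypical"
}

#' Tabulate a cohort of alleles
#'
#' Counts and percentages of alleles per cohort bucket and per
#' structure-function group, the exon distribution among atypical
#' (non-classical) variants, and the fraction of atypical variants falling
#' in the P-loop and in the C-terminal loop of the alpha-C helix.
#' Percentages sum to 100 within each partition.
#'
#' @param alleles List of `"egfr_allele"` objects or a character vector of
#'   compound mutation strings.
#' @param rt A [rule_table()].
#' @param rm A [region_map()].
#' @return List of data frames: `buckets`, `groups`, `atypical_exons`,
#'   `atypical_regions`, plus `n_alleles` and `n_atypical_variants`.
#' @export
tabulate_cohort <- function(alleles, rt = rule_table(), rm = region_map()) {
  if (is.character(alleles)) alleles <- lapply(alleles, parse_allele)
  if (!length(alleles)) stop("cohort is empty", call. = FALSE)
  stopifnot(all(vapply(alleles, inherits, logical(1), "egfr_allele")))
  assignments <- lapply(alleles, classify_allele, rt = rt, rm = rm)

  pct_table <- function(x, levels) {
    counts <- table(factor(x, levels = levels))
    data.frame(category = names(counts), n = as.integer(counts),
               pct = 100 * as.integer(counts) / length(x),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  bucket_levels <- c("classical", "Ex20ins", "atypical",
                     "complex-with-atypical", "classical+T790M+atypical")
  group_levels <- c("classical", "classical-like", "T790M-like", "Ex20ins-L",
                    "PACC", "unclassified")
  buckets <- pct_table(vapply(assignments, `[[`, character(1), "bucket"),
                       bucket_levels)
  groups <- pct_table(vapply(assignments, `[[`, character(1), "group"),
                      group_levels)

  atypical <- list()
  for (a in alleles) {
    for (v in a$variants) if (!.is_classical_variant_rt(v, rt)) {
      atypical <- c(atypical, list(v))
    }
  }
  if (length(atypical)) {
    exons <- vapply(atypical, function(v) exon_of(.variant_interval(v)[1], rm),
                    integer(1))
    exon_tab <- pct_table(ifelse(is.na(exons), "outside", paste0("exon", exons)),
                          c("exon18", "exon19", "exon20", "exon21", "outside"))
    in_region <- function(region) {
      mean(vapply(atypical, function(v) {
        .intersects(.variant_interval(v), rm[[region]])
      }, logical(1)))
    }
    regions <- data.frame(
      region = c("p_loop", "alpha_c_loop"),
      fraction = c(in_region("p_loop"), in_region("alpha_c_loop")),
      stringsAsFactors = FALSE)
    regions$pct <- 100 * regions$fraction
  } else {
    exon_tab <- data.frame(category = character(0), n = integer(0),
                           pct = numeric(0), stringsAsFactors = FALSE)
    regions <- data.frame(region = character(0), fraction = numeric(0),
                          pct = numeric(0), stringsAsFactors = FALSE)
  }
  list(buckets = buckets, groups = groups, atypical_exons = exon_tab,
       atypical_regions = regions, n_alleles = length(alleles),
       n_atypical_variants = length(atypical))
}

#' Curated mutation-to-group reference examples
#'
#' Mutation assignments with established group labels, used as a concordance
#' panel for the classifier: PACC exemplars across exons 18-21, classical
#' alleles, the pan-sensitive alpha-C-helix insertion A763insFQEA, exon 20
#' loop insertions with their near/far subgroups, and T790M-containing
#' complex alleles with their 3S/3R subgroup.
#'
#' @return Data frame with columns `mutation`, `group`, `subgroup`.
#' @export
curated_assignment_examples <- function() {
  df <- rbind(
    c("L718Q", "PACC", "none"),
    c("S768I", "PACC", "none"),
    c("T854I", "PACC", "none"),
    c("L747P", "PACC", "none"),
    c("G719A", "PACC", "none"),
    c("G719S", "PACC", "none"),
    c("L792H", "PACC", "none"),
    c("C797S", "PACC", "none"),
    c("V765L", "PACC", "none"),
    c("G796S", "PACC", "none"),
    c("E709K", "PACC", "none"),
    c("E746_A750del", "classical", "none"),
    c("L858R", "classical", "none"),
    c("L858R+T790M", "classical", "none"),
    c("A763insFQEA", "classical-like", "none"),
    c("L861Q", "classical-like", "none"),
    c("A767insASV", "Ex20ins-L", "NL"),
    c("D770insNPG", "Ex20ins-L", "NL"),
    c("N771insG", "Ex20ins-L", "FL"),
    c("H773insNPH", "Ex20ins-L", "FL"),
    c("V774insHV", "Ex20ins-L", "FL"),
    c("L747_K754delinsATSPE", "T790M-like", "3S"),
    c("G719A+T790M", "T790M-like", "3S"),
    c("L861Q+T790M", "T790M-like", "3S"),
    c("L858R+T790M+C797S", "T790M-like", "3R"),
    c("L858R+T790M+L792H", "T790M-like", "3R"),
    c("E746_A750del+T790M+L718Q", "T790M-like", "3R")
  )
  data.frame(mutation = df[, 1], group = df[, 2], subgroup = df[, 3],
             stringsAsFactors = FALSE)
}
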