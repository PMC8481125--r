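# Mutation parsing and kinase-domain region annotation.
#
# Coordinates are 1-based UniProt P00533 residue numbers throughout; all
# intervals are inclusive. The tyrosine-kinase domain spans residues 688-875.

KINASE_DOMAIN <- c(688L, 875L)

# Partial curated reference table of canonical P00533 residues. Only residues
# that the classifier or the bundled mutation pools refer to are listed;
# positions absent from the table are never checked. Used only when
# `validate_ref = TRUE` (off by default so synthetic mutation names need not
# match the canonical sequence).
.egfr_ref_aa <- c(
  "709" = "E", "718" = "L", "719" = "G", "726" = "V", "746" = "E",
  "747" = "L", "750" = "A", "751" = "T", "752" = "S", "753" = "P",
  "754" = "K", "755" = "A", "763" = "A", "765" = "V", "767" = "A",
  "768" = "S", "770" = "D", "771" = "N", "773" = "H", "774" = "V",
  "779" = "G", "790" = "T", "792" = "L", "793" = "M", "796" = "G",
  "797" = "C", "854" = "T", "858" = "L", "861" = "L"
)

.parse_error <- function(text, why) {
  stop(sprintf("cannot parse mutation token '%s': %s", text, why), call. = FALSE)
}

.check_ref <- function(pos, aa, text) {
  known <- .egfr_ref_aa[as.character(pos)]
  if (!is.na(known) && !identical(unname(known), aa)) {
    stop(sprintf(
      "reference amino acid '%s' at position %d in '%s' conflicts with canonical P00533 residue '%s'",
      aa, pos, text, known), call. = FALSE)
  }
  invisible(TRUE)
}

new_variant <- function(kind, start, end, ref_aa, ref_aa_end, alt_seq, raw) {
  structure(list(
    kind = kind,
    start = as.integer(start),
    end = as.integer(end),
    ref_aa = ref_aa,
    ref_aa_end = ref_aa_end,
    alt_seq = alt_seq,
    raw = raw,
    in_kinase_domain = start >= KINASE_DOMAIN[1] && end <= KINASE_DOMAIN[2]
  ), class = "egfr_variant")
}

#' Parse a protein-level EGFR mutation string
#'
#' Accepts the shorthand protein notation used for EGFR kinase-domain
#' mutations: substitutions (`"L858R"`), deletions (`"E746_A750del"`),
#' insertions anchored to the residue they follow (`"A763insFQEA"`,
#' `"D770_N771insSVD"`), duplications (`"A767_V769dupASV"`) and combined
#' deletion-insertions (`"L747_K754delinsATSPE"`, also written
#' `"L747_K754del-insATSPE"`). An optional `"p."` prefix is stripped, `"-"`
#' and `"_"` are both accepted as range separators, and the `del`/`ins`/
#' `dup`/`delins` keywords are case-insensitive.
#'
#' @param text A single mutation token.
#' @param validate_ref Check stated reference residues against the curated
#'   partial table of canonical P00533 residues (default `FALSE`).
#' @return An object of class `"egfr_variant"`: a list with fields `kind`
#'   (one of `"substitution"`, `"deletion"`, `"insertion"`, `"duplication"`,
#'   `"delins"`), `start`, `end` (1-based residue positions; for insertions
#'   both equal the anchor residue the insertion follows), `ref_aa` /
#'   `ref_aa_end` (stated reference residues), `alt_seq` (inserted or
#'   substituted residues, `""` for a pure deletion), `raw` (input string)
#'   and `in_kinase_domain` (positions within 688-875).
#' @examples
#' parse_mutation("L858R")
#' parse_mutation("E746_A750del")
#' parse_mutation("A763insFQEA")
#' @seealso [parse_allele()], [annotate_regions()], [format.egfr_variant()]
#' @export
parse_mutation <- function(text, validate_ref = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("mutation token must be a single non-empty string", call. = FALSE)
  }
  raw <- text
  s <- trimws(text)
  s <- sub("^p\\.", "", s, ignore.case = TRUE)
  s <- gsub("del[-_]ins", "delins", s, ignore.case = TRUE)
  # "-" between a digit and a letter acts as a range separator
  s <- gsub("(?<=[0-9])-(?=[A-Za-z])", "_", s, perl = TRUE)

  grab <- function(pattern) {
    m <- regmatches(s, regexec(pattern, s, perl = TRUE))[[1]]
    if (length(m)) m else NULL
  }
  rng <- function(m) {
    start <- as.integer(m[3])
    ref <- toupper(m[2])
    if (nzchar(m[4])) {
      end <- as.integer(m[5])
      ref_end <- toupper(m[4])
    } else {
      end <- start
      ref_end <- NA_character_
    }
    if (start > end) .parse_error(raw, "start position exceeds end position")
    if (validate_ref) {
      .check_ref(start, ref, raw)
      if (!is.na(ref_end)) .check_ref(end, ref_end, raw)
    }
    list(start = start, end = end, ref = ref, ref_end = ref_end)
  }

  aa <- "([A-Za-z])"
  pos <- "([0-9]+)"
  range <- paste0("^", aa, pos, "(?:_", aa, pos, ")?")

  if (!is.null(m <- grab(paste0(range, "(?i:delins)([A-Za-z]+)$")))) {
    r <- rng(m)
    return(new_variant("delins", r$start, r$end, r$ref, r$ref_end,
                       toupper(m[6]), raw))
  }
  if (!is.null(m <- grab(paste0(range, "(?i:del)$")))) {
    r <- rng(m)
    return(new_variant("deletion", r$start, r$end, r$ref, r$ref_end, "", raw))
  }
  if (!is.null(m <- grab(paste0(range, "(?i:dup)([A-Za-z]*)$")))) {
    r <- rng(m)
    alt <- toupper(m[6])
    if (!nzchar(alt)) {
      # duplicated segment not spelled out: reconstruct what is known from the
      # stated end residues, filling interior positions with "X"
      len <- r$end - r$start + 1L
      alt <- if (len == 1L) r$ref else {
        paste0(r$ref, strrep("X", len - 2L), r$ref_end)
      }
    }
    return(new_variant("duplication", r$start, r$end, r$ref, r$ref_end, alt, raw))
  }
  if (!is.null(m <- grab(paste0(range, "(?i:ins)([A-Za-z]+)$")))) {
    r <- rng(m)
    # insertions are anchored to the residue they follow
    return(new_variant("insertion", r$start, r$start, r$ref, NA_character_,
                       toupper(m[6]), raw))
  }
  if (!is.null(m <- grab(paste0("^", aa, pos, aa, "$")))) {
    ref <- toupper(m[2]); alt <- toupper(m[4])
    if (identical(ref, alt)) .parse_error(raw, "synonymous substitution")
    p <- as.integer(m[3])
    if (validate_ref) .check_ref(p, ref, raw)
    return(new_variant("substitution", p, p, ref, NA_character_, alt, raw))
  }
  .parse_error(raw, "unrecognised protein-mutation syntax")
}

#' Format a parsed variant back to canonical notation
#'
#' The canonical form round-trips through [parse_mutation()].
#'
#' @param x An `"egfr_variant"`.
#' @param ... Ignored.
#' @return A single mutation string.
#' @export
format.egfr_variant <- function(x, ...) {
  span <- if (x$end > x$start) {
    paste0(x$ref_aa, x$start, "_", x$ref_aa_end, x$end)
  } else {
    paste0(x$ref_aa, x$start)
  }
  switch(x$kind,
    substitution = paste0(x$ref_aa, x$start, x$alt_seq),
    deletion     = paste0(span, "del"),
    delins       = paste0(span, "delins", x$alt_seq),
    duplication  = paste0(span, "dup", x$alt_seq),
    insertion    = paste0(x$ref_aa, x$start, "ins", x$alt_seq)
  )
}

#' @export
print.egfr_variant <- function(x, ...) {
  cat(sprintf("<egfr_variant> %s (%s, %d-%d%s)\n", format(x), x$kind,
              x$start, x$end,
              if (x$in_kinase_domain) ", kinase domain" else ""))
  invisible(x)
}

#' View a duplication as its insertion equivalent
#'
#' A duplication of residues `start..end` inserts a copy of that segment
#' after `end`; this returns the equivalent insertion variant (other kinds
#' are returned unchanged). Region annotation of duplications uses this
#' equivalence.
#'
#' @param v An `"egfr_variant"`.
#' @return An `"egfr_variant"`.
#' @export
as_insertion <- function(v) {
  stopifnot(inherits(v, "egfr_variant"))
  if (v$kind != "duplication") return(v)
  anchor_ref <- if (!is.na(v$ref_aa_end)) v$ref_aa_end else v$ref_aa
  new_variant("insertion", v$end, v$end, anchor_ref, NA_character_,
              v$alt_seq, v$raw)
}

#' Parse a compound EGFR allele
#'
#' Splits a compound mutation string on `"+"`, `"/"` or `";"` and parses
#' each token with [parse_mutation()]. Duplicate tokens (identical canonical
#' form) are removed; the remaining order is preserved as given, since the
#' order of co-occurring mutations carries no meaning.
#'
#' @param text Compound mutation string, e.g. `"L858R+T790M+C797S"` or
#'   `"E709K/G719S"`.
#' @param validate_ref Passed to [parse_mutation()].
#' @return An object of class `"egfr_allele"`: list with `variants` (list of
#'   `"egfr_variant"`) and `raw`.
#' @examples
#' parse_allele("E709K/G719S")
#' @export
parse_allele <- function(text, validate_ref = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("allele string must be a single non-empty string", call. = FALSE)
  }
  tokens <- trimws(strsplit(text, "[+/;]")[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) {
    stop(sprintf("allele string '%s' contains no mutation tokens", text),
         call. = FALSE)
  }
  variants <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    variants[[i]] <- tryCatch(
      parse_mutation(tokens[i], validate_ref = validate_ref),
      error = function(e) {
        stop(sprintf("allele '%s', token %d ('%s'): %s", text, i, tokens[i],
                     conditionMessage(e)), call. = FALSE)
      })
  }
  canon <- vapply(variants, format, character(1))
  variants <- variants[!duplicated(canon)]
  structure(list(variants = variants, raw = text), class = "egfr_allele")
}

#' @export
format.egfr_allele <- function(x, ...) {
  paste(vapply(x$variants, format, character(1)), collapse = "+")
}

#' @export
print.egfr_allele <- function(x, ...) {
  cat(sprintf("<egfr_allele> %s (%d variant%s)\n", format(x),
              length(x$variants), if (length(x$variants) > 1) "s" else ""))
  invisible(x)
}

#' Kinase-domain region map
#'
#' Named inclusive residue intervals used for exon assignment and structural
#' annotation. Defaults: exon 18 = 688-728, exon 19 = 729-761, exon 20 =
#' 762-823, exon 21 = 824-875 (canonical EGFR transcript convention); the
#' P-loop L718-V726 and the C-terminal loop of the alpha-C helix A767-G779;
#' the exon 20 insertion loop span A767-V774, split into a near loop
#' (insertion anchors 767-770) and a far loop (771-774) at the D770/N771
#' boundary; alpha-C helix 756-766 (immediately N-terminal of its C-terminal
#' loop); hinge 792-797; hydrophobic core residue set \{790\}. All intervals
#' are configurable.
#'
#' @param exon18,exon19,exon20,exon21 Exon residue intervals, `c(start, end)`.
#' @param p_loop,alpha_c_helix,alpha_c_loop,ex20_loop_span,near_loop,far_loop,hinge
#'   Structural intervals, `c(start, end)`.
#' @param hydrophobic_core Integer vector of hydrophobic-core residues.
#' @return An object of class `"egfr_region_map"`.
#' @export
region_map <- function(exon18 = c(688L, 728L),
                       exon19 = c(729L, 761L),
                       exon20 = c(762L, 823L),
                       exon21 = c(824L, 875L),
                       p_loop = c(718L, 726L),
                       alpha_c_helix = c(756L, 766L),
                       alpha_c_loop = c(767L, 779L),
                       ex20_loop_span = c(767L, 774L),
                       near_loop = c(767L, 770L),
                       far_loop = c(771L, 774L),
                       hinge = c(792L, 797L),
                       hydrophobic_core = 790L) {
  rm <- list(
    exon18 = as.integer(exon18), exon19 = as.integer(exon19),
    exon20 = as.integer(exon20), exon21 = as.integer(exon21),
    p_loop = as.integer(p_loop), alpha_c_helix = as.integer(alpha_c_helix),
    alpha_c_loop = as.integer(alpha_c_loop),
    ex20_loop_span = as.integer(ex20_loop_span),
    near_loop = as.integer(near_loop), far_loop = as.integer(far_loop),
    hinge = as.integer(hinge),
    hydrophobic_core = as.integer(hydrophobic_core)
  )
  for (nm in setdiff(names(rm), "hydrophobic_core")) {
    iv <- rm[[nm]]
    if (length(iv) != 2L || anyNA(iv) || iv[1] > iv[2]) {
      stop(sprintf("region '%s' must be an interval c(start, end) with start <= end", nm),
           call. = FALSE)
    }
  }
  if (rm$near_loop[1] != rm$ex20_loop_span[1] ||
      rm$far_loop[2] != rm$ex20_loop_span[2] ||
      rm$near_loop[2] + 1L != rm$far_loop[1]) {
    stop("near_loop and far_loop must partition ex20_loop_span", call. = FALSE)
  }
  structure(rm, class = "egfr_region_map")
}

#' Map a residue position to its kinase-domain exon
#'
#' @param position Integer vector of residue positions.
#' @param rm A [region_map()].
#' @return Integer vector: 18, 19, 20 or 21, or `NA` outside the kinase
#'   domain.
#' @examples
#' exon_of(c(719, 768, 854, 500))
#' @export
exon_of <- function(position, rm = region_map()) {
  stopifnot(inherits(rm, "egfr_region_map"))
  vapply(as.integer(position), function(p) {
    if (is.na(p) || p <= 0L) {
      stop("position must be a positive integer", call. = FALSE)
    }
    for (ex in c(18L, 19L, 20L, 21L)) {
      iv <- rm[[paste0("exon", ex)]]
      if (p >= iv[1] && p <= iv[2]) return(ex)
    }
    NA_integer_
  }, integer(1))
}

# Residue interval a variant occupies for region intersection: insertions use
# the anchor residue they follow; duplications their insertion equivalent.
.variant_interval <- function(v) {
  if (v$kind == "insertion") c(v$start, v$start)
  else if (v$kind == "duplication") c(v$end, v$end)
  else c(v$start, v$end)
}

.intersects <- function(iv, region) iv[1] <= region[2] && iv[2] >= region[1]

#' Annotate a variant with the structural regions it touches
#'
#' Returns every region of the [region_map()] whose interval intersects the
#' variant's residue interval. Insertions (and duplications, via their
#' insertion equivalent) are located at the single residue they follow, so a
#' duplication and its equivalent insertion receive identical tags. The
#' near/far-loop subdivision applies only to insertion anchors, so at most
#' one of `near_loop`/`far_loop` is ever reported.
#'
#' @param v An `"egfr_variant"` (or string, parsed on the fly).
#' @param rm A [region_map()].
#' @return Character vector of region tags.
#' @examples
#' annotate_regions("L718Q")
#' annotate_regions("A767insASV")
#' @export
annotate_regions <- function(v, rm = region_map()) {
  if (is.character(v)) v <- parse_mutation(v)
  stopifnot(inherits(v, "egfr_variant"), inherits(rm, "egfr_region_map"))
  iv <- .variant_interval(v)
  tags <- character(0)
  for (nm in c("exon18", "exon19", "exon20", "exon21", "p_loop",
               "alpha_c_helix", "alpha_c_loop", "ex20_loop_span", "hinge")) {
    if (.intersects(iv, rm[[nm]])) tags <- c(tags, nm)
  }
  if (v$kind %in% c("insertion", "duplication")) {
    if (.intersects(iv, rm$near_loop)) tags <- c(tags, "near_loop")
    else if (.intersects(iv, rm$far_loop)) tags <- c(tags, "far_loop")
  }
  if (any(seq.int(iv[1], iv[2]) %in% rm$hydrophobic_core)) {
    tags <- c(tags, "hydrophobic_core")
  }
  tags
}
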