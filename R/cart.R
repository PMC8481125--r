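# CART regression trees with goodness-of-split variable importance.
#
# Greedy recursive binary partitioning minimizing within-node sum of squares.
# Categorical predictors use the order-categories-by-mean-response reduction,
# which is optimal for a single-split least-squares criterion; the goodness
# of a split is SS(parent) - SS(left) - SS(right). Splitting stops when a
# node is smaller than `minsplit` or when the best split improves the root
# sum of squares by less than the fraction `cp`. Ties are broken toward the
# earlier-listed predictor and the lower split value, so fits are
# deterministic.

#' Control parameters for [cart_fit()]
#'
#' @param minsplit Minimum number of observations in a node for a split to
#'   be attempted (default 20).
#' @param cp Complexity threshold: minimum goodness of a split as a fraction
#'   of the root sum of squares (default 0.01).
#' @return A list with components `minsplit` and `cp`.
#' @export
cart_control <- function(minsplit = 20L, cp = 0.01) {
  stopifnot(minsplit >= 2L, cp >= 0)
  list(minsplit = as.integer(minsplit), cp = cp)
}

.node_ss <- function(y) sum((y - mean(y))^2)

# Best single split of (y, x) over all predictors. Returns NULL when no
# predictor admits a split. Strict improvement comparison keeps the
# earliest predictor / lowest split value on ties.
.cart_best_split <- function(y, x) {
  parent_ss <- .node_ss(y)
  best <- NULL
  for (j in seq_along(x)) {
    xj <- x[[j]]
    if (is.factor(xj) || is.character(xj)) {
      xj <- as.character(xj)
      level_means <- vapply(split(y, xj), mean, numeric(1))
      # deterministic order: by mean response, alphabetical on ties
      ord <- names(level_means)[order(level_means, names(level_means))]
      if (length(ord) < 2L) next
      for (k in seq_len(length(ord) - 1L)) {
        left_levels <- ord[seq_len(k)]
        mask <- xj %in% left_levels
        goodness <- parent_ss - .node_ss(y[mask]) - .node_ss(y[!mask])
        if (is.null(best) || goodness > best$goodness + 1e-12) {
          best <- list(var = names(x)[j], type = "categorical",
                       left_levels = left_levels, cut = NA_real_,
                       goodness = goodness, mask = mask)
        }
      }
    } else {
      u <- sort(unique(xj))
      if (length(u) < 2L) next
      cuts <- (u[-1] + u[-length(u)]) / 2
      for (cut in cuts) {
        mask <- xj <= cut
        goodness <- parent_ss - .node_ss(y[mask]) - .node_ss(y[!mask])
        if (is.null(best) || goodness > best$goodness + 1e-12) {
          best <- list(var = names(x)[j], type = "numeric",
                       left_levels = NULL, cut = cut,
                       goodness = goodness, mask = mask)
        }
      }
    }
  }
  best
}

.cart_grow <- function(y, x, control, root_ss, depth) {
  node <- list(n = length(y), mean = mean(y), ss = .node_ss(y),
               depth = depth, split = NULL, left = NULL, right = NULL)
  if (node$n < control$minsplit || node$ss <= 0) return(node)
  best <- .cart_best_split(y, x)
  if (is.null(best) || best$goodness < control$cp * root_ss) return(node)
  node$split <- best[c("var", "type", "left_levels", "cut", "goodness")]
  mask <- best$mask
  node$left <- .cart_grow(y[mask], x[mask, , drop = FALSE], control,
                          root_ss, depth + 1L)
  node$right <- .cart_grow(y[!mask], x[!mask, , drop = FALSE], control,
                           root_ss, depth + 1L)
  node
}

#' Fit a CART regression tree
#'
#' @param y Numeric response (e.g. one drug's selectivity values across
#'   mutations).
#' @param x Data frame of predictors: factors/characters are treated as
#'   unordered categoricals, anything else as numeric.
#' @param control A [cart_control()].
#' @return An object of class `"egfr_cart"`: list with `root` (nested node
#'   list; internal nodes carry `split` = variable, rule and goodness),
#'   `predictors`, `control` and `root_ss`. A constant response yields a
#'   root-only tree.
#' @export
cart_fit <- function(y, x, control = cart_control()) {
  stopifnot(is.data.frame(x), nrow(x) == length(y), ncol(x) >= 1L)
  if (!all(is.finite(y))) stop("response must be finite", call. = FALSE)
  root_ss <- .node_ss(y)
  root <- .cart_grow(y, x, control, root_ss, 1L)
  structure(list(root = root, predictors = names(x), control = control,
                 root_ss = root_ss), class = "egfr_cart")
}

.cart_walk <- function(node, fn) {
  if (is.null(node)) return(invisible(NULL))
  fn(node)
  .cart_walk(node$left, fn)
  .cart_walk(node$right, fn)
}

#' Splits of a fitted tree as a data frame
#'
#' @param tree An `"egfr_cart"`.
#' @return Data frame with one row per internal node: `var`, `type`, `rule`
#'   (printable split rule), `goodness`, `n`, `depth`.
#' @export
cart_splits <- function(tree) {
  stopifnot(inherits(tree, "egfr_cart"))
  rows <- list()
  .cart_walk(tree$root, function(node) {
    if (is.null(node$split)) return(invisible(NULL))
    s <- node$split
    rule <- if (s$type == "numeric") sprintf("%s <= %g", s$var, s$cut) else {
      sprintf("%s in {%s}", s$var, paste(s$left_levels, collapse = ","))
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      var = s$var, type = s$type, rule = rule, goodness = s$goodness,
      n = node$n, depth = node$depth, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(var = character(0), type = character(0),
                      rule = character(0), goodness = numeric(0),
                      n = integer(0), depth = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.egfr_cart <- function(x, ...) {
  s <- cart_splits(x)
  cat(sprintf("<egfr_cart> %d observation(s), %d split(s), root SS %.4g\n",
              x$root$n, nrow(s), x$root_ss))
  if (nrow(s)) {
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %s%s (goodness %.4g, n %d)\n",
                  strrep("  ", s$depth[i] - 1), s$rule[i], s$goodness[i],
                  s$n[i]))
    }
  }
  invisible(x)
}

#' Goodness-of-split variable importance
#'
#' Per predictor, the sum of the goodness-of-split measures (the reduction
#' in sum of squares) over that predictor's splits, rescaled so the
#' importances of a tree sum to 100. Predictors never used score 0; a
#' root-only tree has empty importance.
#'
#' @param tree An `"egfr_cart"`.
#' @return Named numeric vector over the tree's predictors, or a length-0
#'   vector for a root-only tree.
#' @export
variable_importance <- function(tree) {
  stopifnot(inherits(tree, "egfr_cart"))
  sums <- stats::setNames(numeric(length(tree$predictors)), tree$predictors)
  .cart_walk(tree$root, function(node) {
    if (!is.null(node$split)) {
      sums[node$split$var] <<- sums[node$split$var] + node$split$goodness
    }
  })
  total <- sum(sums)
  if (total <= 0) return(stats::setNames(numeric(0), character(0)))
  100 * sums / total
}
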