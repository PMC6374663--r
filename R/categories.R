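#' Ordinal fruit-count category scheme
#'
#' Field observations place the number of fruit on a tree into ordered
#' abundance classes rather than exact counts. The default scheme has four
#' classes: 0 fruit; 1-100; 101-1,000; more than 1,000. Categories are coded
#' 1..K in all tables and models.
#'
#' @param lower integer vector of interval lower bounds; the first must be 0
#'   and the first interval is exactly zero (`upper[1] == 0`).
#' @param upper integer vector of upper bounds, last may be `Inf`.
#' @return object of class `category_scheme` with elements `lower`, `upper`,
#'   `K`, and `labels`.
#' @examples
#' sc <- category_scheme()
#' sc$K
#' @export
category_scheme <- function(lower = c(0L, 1L, 101L, 1001L),
                            upper = c(0L, 100L, 1000L, Inf)) {
  if (length(lower) != length(upper) || length(lower) < 2)
    stopf("need >= 2 matching intervals")
  if (lower[1] != 0 || upper[1] != 0)
    stopf("first interval must be exactly zero fruit")
  if (any(upper < lower)) stopf("interval upper bound below lower bound")
  if (any(lower[-1] != head(upper, -1) + 1))
    stopf("intervals must be contiguous and non-overlapping")
  structure(
    list(lower = lower, upper = upper, K = length(lower),
         labels = ifelse(is.finite(upper),
                         ifelse(lower == upper, as.character(lower),
                                paste0(lower, "-", upper)),
                         paste0(">", lower - 1))),
    class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("Fruit category scheme (", x$K, " classes): ",
      paste(seq_len(x$K), x$labels, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assign a fruit count to its ordinal category
#'
#' @param count nonnegative integer count(s).
#' @param scheme a [category_scheme()].
#' @return integer category code(s) in `1..scheme$K`.
#' @examples
#' assign_category(c(0, 100, 101, 1500))
#' @export
assign_category <- function(count, scheme = category_scheme()) {
  if (any(!is.finite(count)) || any(count < 0))
    stopf("counts must be finite and nonnegative")
  findInterval(count, scheme$lower)
}

#' Reduce per-period observations to binary reproductive status
#'
#' A tree's reproductive status is 1 if fruit was observed (category above
#' the zero class) in any observation period, else 0. Trees appearing in
#' `trees` but never observed are excluded and reported via the
#' `"excluded"` attribute.
#'
#' @param fruit data frame with columns `tree_id`, `period`, `category`.
#' @return data frame (`tree_id`, `status`) with one row per observed tree.
#' @examples
#' fr <- data.frame(tree_id = c(1, 1, 1, 2, 2, 2),
#'                  period = rep(1:3, 2), category = c(1, 2, 1, 1, 1, 1))
#' reduce_status(fr)
#' @export
reduce_status <- function(fruit) {
  red <- reduce_max_category(fruit)
  out <- data.frame(tree_id = red$tree_id,
                    status = as.integer(red$max_category > 1L),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- attr(red, "excluded")
  out
}

#' Reduce per-period observations to the maximum fruiting category
#'
#' Species differ in fruiting phenology and many fruit in mast cycles, so
#' per-individual fruit output is summarized as the maximum ordinal
#' category observed across all sampling periods.
#'
#' @inheritParams reduce_status
#' @return data frame (`tree_id`, `max_category`), one row per observed tree.
#' @export
reduce_max_category <- function(fruit) {
  stopifnot(all(c("tree_id", "period", "category") %in% names(fruit)))
  if (nrow(fruit) == 0)
    return(structure(data.frame(tree_id = character(), max_category = integer()),
                     excluded = character()))
  agg <- tapply(fruit$category, fruit$tree_id, max)
  out <- data.frame(tree_id = names(agg),
                    max_category = as.integer(agg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- character()
  out
}

#' Estimate whole-tree fruit count from branch counts
#'
#' Whole-tree fruit is estimated as the average of three counted
#' reproductive branches multiplied by the total number of reproductive
#' branches on the tree.
#'
#' @param branch_counts numeric vector of exactly three counts, or an
#'   n-by-3 matrix for many trees.
#' @param n_reproductive_branches nonnegative count(s) of reproductive
#'   branches per tree.
#' @return estimated whole-tree fruit count(s).
#' @examples
#' branch_count_estimate(c(10, 20, 30), 4)
#' @export
branch_count_estimate <- function(branch_counts, n_reproductive_branches) {
  if (is.null(dim(branch_counts))) branch_counts <- matrix(branch_counts, nrow = 1)
  if (ncol(branch_counts) != 3) stopf("exactly three branch counts per tree required")
  if (any(branch_counts < 0) || any(n_reproductive_branches < 0))
    stopf("negative counts not allowed")
  unname(rowMeans(branch_counts) * n_reproductive_branches)
}

#' Agreement between count-derived and observed fruit categories
#'
#' Validates the ordinal method: whole-tree count estimates are converted to
#' categories and compared with the categorical field estimates. Reports the
#' agreement fraction and the Pearson correlation between the count estimate
#' and the category code, both over all pairs and restricted to pairs where
#' both estimates are nonzero.
#'
#' @param count_estimates numeric vector of estimated whole-tree counts.
#' @param categories observed ordinal categories (codes `1..K`).
#' @param scheme a [category_scheme()].
#' @return list with `agreement`, `correlation`, `correlation_nonzero`,
#'   `n`, `n_nonzero`. Correlations are `NA` when undefined (fewer than two
#'   pairs or zero variance).
#' @export
category_agreement <- function(count_estimates, categories,
                               scheme = category_scheme()) {
  if (length(count_estimates) != length(categories))
    stopf("count estimates and categories must be paired")
  derived <- assign_category(count_estimates, scheme)
  agreement <- mean(derived == categories)
  safe_cor <- function(x, y) {
    if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  nz <- count_estimates > 0 & categories > 1
  list(agreement = agreement,
       correlation = safe_cor(count_estimates, as.numeric(categories)),
       correlation_nonzero = safe_cor(count_estimates[nz],
                                      as.numeric(categories[nz])),
       n = length(categories), n_nonzero = sum(nz))
}
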