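# Tabular input/output for the three plot-census schemas.
#
# trees.csv: tree_id, plot_id, species, x_m, y_m, dbh_cm
# soil.csv:  plot_id, x_m, y_m, no3_i, nh4_i, no3_f, nh4_f, p, k, ca, mg
# fruit.csv: tree_id, period, category
# counts.csv (optional): tree_id, branch1, branch2, branch3, n_branches
# All files are UTF-8 CSV with "." as the decimal separator; categories are
# stored as integer codes 1..K.

SCHEMAS <- list(
  trees = c("tree_id", "plot_id", "species", "x_m", "y_m", "dbh_cm"),
  soil = c("plot_id", "x_m", "y_m", "no3_i", "nh4_i", "no3_f", "nh4_f",
           "p", "k", "ca", "mg"),
  fruit = c("tree_id", "period", "category"),
  counts = c("tree_id", "branch1", "branch2", "branch3", "n_branches")
)

check_columns <- function(df, what, path) {
  missing <- setdiff(SCHEMAS[[what]], names(df))
  if (length(missing))
    stopf("%s (%s): missing required column(s): %s", what, path,
          paste(missing, collapse = ", "))
  df[SCHEMAS[[what]]]
}

read_one <- function(path, what) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, what, path)
}

#' Read the stem-map, soil, and fruit-observation tables
#'
#' Reads the delimited-text schemas, validates column presence and record
#' invariants (DBH at least the 5-cm census threshold, categories within the
#' scheme), and reports malformed rows with their line numbers.
#'
#' @param trees,soil,fruit,counts file paths; `counts` is optional.
#' @param scheme the active [category_scheme()].
#' @param min_dbh census threshold in cm (trees below it are invalid input).
#' @return a `fruit_data` object: list with data frames `trees`, `soil`,
#'   `fruit`, optionally `counts`, and the `scheme`.
#' @export
read_tables <- function(trees, soil, fruit, counts = NULL,
                        scheme = category_scheme(), min_dbh = 5) {
  tr <- read_one(trees, "trees")
  so <- read_one(soil, "soil")
  fr <- read_one(fruit, "fruit")
  bad <- which(!is.finite(tr$dbh_cm) | tr$dbh_cm < min_dbh)
  if (length(bad))
    stopf("trees (%s): dbh_cm below census threshold %g at data row(s) %s",
          trees, min_dbh, paste(head(bad, 10), collapse = ", "))
  if (anyDuplicated(tr$tree_id))
    stopf("trees (%s): duplicate tree_id", trees)
  if (nrow(fr)) {
    badc <- which(!(fr$category %in% seq_len(scheme$K)))
    if (length(badc))
      stopf("fruit (%s): category outside 1..%d at data row(s) %s",
            fruit, scheme$K, paste(head(badc, 10), collapse = ", "))
    orphan <- !(fr$tree_id %in% tr$tree_id)
    if (any(orphan))
      stopf("fruit (%s): tree_id not present in trees at data row(s) %s",
            fruit, paste(head(which(orphan), 10), collapse = ", "))
  }
  out <- list(trees = tr, soil = so, fruit = fr, scheme = scheme)
  if (!is.null(counts)) out$counts <- read_one(counts, "counts")
  class(out) <- "fruit_data"
  out
}

#' Bundle in-memory tables into a dataset object
#'
#' @param trees,soil,fruit,counts data frames following the documented
#'   schemas (`counts` optional).
#' @param scheme the active [category_scheme()].
#' @return a `fruit_data` object.
#' @export
fruit_data <- function(trees, soil, fruit, counts = NULL,
                       scheme = category_scheme()) {
  out <- list(trees = check_columns(trees, "trees", "<memory>"),
              soil = check_columns(soil, "soil", "<memory>"),
              fruit = check_columns(fruit, "fruit", "<memory>"),
              scheme = scheme)
  if (!is.null(counts)) out$counts <- check_columns(counts, "counts", "<memory>")
  class(out) <- "fruit_data"
  out
}

#' @export
print.fruit_data <- function(x, ...) {
  cat("fruit_data:", nrow(x$trees), "trees,", nrow(x$soil), "soil samples,",
      nrow(x$fruit), "fruit observations",
      if (!is.null(x$counts)) sprintf("(+%d branch-count records)", nrow(x$counts)) else "",
      "\n")
  invisible(x)
}

#' Per-species tallies of mapped, observed, and fruiting trees
#'
#' Reports, for each species, the number of mapped stems, the number with
#' at least one fruit observation, and the number observed fruiting at
#' least once — both raw and after any modeling exclusions is the
#' caller's concern; this is the raw bookkeeping, with a total row.
#'
#' @param data a `fruit_data` object.
#' @return data frame: `species`, `n_trees`, `n_observed`, `n_fruiting`.
#' @export
species_tally <- function(data) {
  stopifnot(inherits(data, "fruit_data"))
  st <- reduce_status(data$fruit)
  idx <- match(st$tree_id, data$trees$tree_id)
  sp <- sort(unique(data$trees$species))
  n_trees <- as.vector(table(factor(data$trees$species, sp)))
  obs_sp <- factor(data$trees$species[idx], sp)
  n_obs <- as.vector(table(obs_sp))
  n_fru <- vapply(sp, function(s) sum(st$status[obs_sp == s]), 0L)
  out <- data.frame(species = c(sp, "Total"),
                    n_trees = c(n_trees, sum(n_trees)),
                    n_observed = c(n_obs, sum(n_obs)),
                    n_fruiting = as.integer(c(n_fru, sum(n_fru))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a dataset to the three CSV schemas
#'
#' @param data a `fruit_data` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_tables <- function(data, dir) {
  stopifnot(inherits(data, "fruit_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trees = file.path(dir, "trees.csv"),
             soil = file.path(dir, "soil.csv"),
             fruit = file.path(dir, "fruit.csv"))
  write.csv(data$trees, paths["trees"], row.names = FALSE, quote = FALSE)
  write.csv(data$soil, paths["soil"], row.names = FALSE, quote = FALSE)
  write.csv(data$fruit, paths["fruit"], row.names = FALSE, quote = FALSE)
  if (!is.null(data$counts)) {
    paths["counts"] <- file.path(dir, "counts.csv")
    write.csv(data$counts, paths["counts"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
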