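#' Leakage-controlled cross-validation splits
#'
#' Three strategies mirror increasingly strict generalization scenarios:
#' \describe{
#'   \item{random}{stratified k-fold on the binary label (fold active
#'     fractions track the global fraction); identical kinases may appear in
#'     both train and test.}
#'   \item{kinase}{grouped k-fold on `kinase_id`: no kinase appears in more
#'     than one fold, eliminating target leakage.}
#'   \item{family}{grouped k-fold on `family`: no family is shared between
#'     folds; with k equal to the family count each fold's test set is one
#'     family.}
#' }
#' Grouped strategies balance record counts greedily: groups are assigned in
#' descending size order to the currently smallest fold (general
#' stratification inside grouped splits is impossible).
#'
#' @param records activity data.frame with `kinase_id`, `family` and (for
#'   the random strategy) `label`.
#' @param strategy `"random"`, `"kinase"` or `"family"`.
#' @param k fold count (>= 2; at most the number of groups for grouped
#'   strategies). The study convention is 5 folds for random and kinase
#'   splits and 3 for the family split.
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `strategy`, `k`,
#'   `assignments` (fold id per record), `group_key`, `seed`.
#' @export
make_split <- function(records, strategy = c("random", "kinase", "family"),
                       k = if (match.arg(strategy) == "family") 3L else 5L,
                       seed = 1) {
  strategy <- match.arg(strategy)
  n <- nrow(records)
  stopifnot(n >= k)
  if (!is_count(k) || k < 2)
    pcm_stop("'k' must be an integer >= 2", "pcm_config_error")
  assignments <- integer(n)
  if (strategy == "random") {
    if (is.null(records$label))
      pcm_stop("random stratified split needs a 'label' column",
               "pcm_config_error")
    group_key <- as.character(seq_len(n))
    withr::with_seed(seed, {
      for (lv in unique(records$label)) {
        idx <- sample(which(records$label == lv))
        assignments[idx] <- rep_len(sample.int(k), length(idx))
      }
    })
  } else {
    group_key <- if (strategy == "kinase") records$kinase_id else
      records$family
    groups <- table(group_key)
    if (k > length(groups))
      pcm_stop(sprintf("k = %d exceeds the %d available %s groups",
                       k, length(groups), strategy), "pcm_infeasible_error")
    withr::with_seed(seed, {
      ord <- names(groups)[order(-as.integer(groups),
                                 sample.int(length(groups)))]
      fold_load <- numeric(k)
      fold_of <- integer(length(ord))
      for (i in seq_along(ord)) {
        f <- which.min(fold_load)
        fold_of[i] <- f
        fold_load[f] <- fold_load[f] + groups[[ord[i]]]
      }
    })
    assignments <- fold_of[match(group_key, ord)]
  }
  structure(list(strategy = strategy, k = as.integer(k),
                 assignments = assignments, group_key = group_key,
                 seed = seed), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %s, k = %d, %d records (fold sizes: %s)\n",
              x$strategy, x$k, length(x$assignments),
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' Verify the leakage guarantee of a split plan
#'
#' For grouped strategies, asserts that no kinase (resp. family) occurs in
#' more than one fold, i.e. zero overlap between any train and test portion.
#'
#' @param plan a [make_split()] plan.
#' @param records the records the plan was built from.
#' @return `TRUE` invisibly; raises an error on any leakage.
#' @export
check_leakage <- function(plan, records) {
  if (plan$strategy == "random") return(invisible(TRUE))
  key <- if (plan$strategy == "kinase") records$kinase_id else
    records$family
  n_folds <- vapply(split(plan$assignments, key),
                    function(a) length(unique(a)), integer(1))
  if (any(n_folds > 1L))
    pcm_stop(sprintf("leakage: %s group(s) span multiple folds: %s",
                     plan$strategy,
                     paste(names(n_folds)[n_folds > 1L], collapse = ", ")),
             "pcm_leakage_error")
  invisible(TRUE)
}

#' Serialize / load a split plan as CSV
#' @param plan a `split_plan`.
#' @param path file path.
#' @return `read_split_csv` returns a data.frame (record_index, fold, group).
#' @export
write_split_csv <- function(plan, path) {
  utils::write.csv(data.frame(record_index = seq_along(plan$assignments),
                              fold = plan$assignments,
                              group = plan$group_key), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_csv
#' @export
read_split_csv <- function(path) utils::read.csv(path)
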