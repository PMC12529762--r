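#' Run the factorial evaluation grid
#'
#' Enumerates every combination of data split, protein embedding variant,
#' SNA rebalancing and permutation condition; for each combination and
#' cross-validation fold it assembles the joint representation, optionally
#' rebalances the training and held-out folds with decoys, optionally
#' permutes a feature block or the labels in the chosen phase, trains a
#' gradient-boosted classifier, and records all metrics plus the protein
#' feature importance. Every cell is seeded deterministically from the
#' master seed and the factor levels, so a rerun with the same inputs
#' reproduces the metric table exactly. Cell failures are recorded in the
#' `error` column and do not abort the grid.
#'
#' @param records binarized activity records.
#' @param protein_sets named list of protein feature matrices (rownames =
#'   kinase ids); the names are the embedding-variant factor levels.
#' @param ligand_features ligand bit matrix (rownames = ligand ids).
#' @param decoy_features decoy bit matrix; required when any `sna` level is
#'   `TRUE`.
#' @param splits named integer vector/list of fold counts per strategy,
#'   default `c(random = 5, kinase = 5, family = 3)`.
#' @param sna logical vector of rebalancing levels (default `FALSE`).
#' @param sna_folds which folds to rebalance: both the training and held-out
#'   fold (default, each independently) or only the training fold.
#' @param permutations list of [permutation_spec()] objects; the default is
#'   the unpermuted condition.
#' @param model_params hyperparameter overrides for [train_classifier()].
#' @param target_ratio SNA inactive:active target ratio.
#' @param seed master seed.
#' @return data.frame of class `pcm_results`, one row per (factors, fold):
#'   columns `data_split`, `embedding`, `sna`, `permutation`,
#'   `permutation_phase`, `fold`, `seed`, `f1`, `auroc`, `recall`, `mcc`,
#'   `pfi`, `error`.
#' @export
run_experiment_grid <- function(records, protein_sets, ligand_features,
                                decoy_features = NULL,
                                splits = c(random = 5, kinase = 5,
                                           family = 3),
                                sna = FALSE,
                                sna_folds = c("both", "train"),
                                permutations = list(permutation_spec("none")),
                                model_params = list(),
                                target_ratio = 1, seed = 1) {
  sna_folds <- match.arg(sna_folds)
  if (any(sna) && is.null(decoy_features))
    pcm_stop("SNA levels require 'decoy_features'", "pcm_config_error")
  lig_all <- if (is.null(decoy_features)) ligand_features else
    rbind(ligand_features, decoy_features)
  rows <- list()
  for (strategy in names(splits)) {
    k <- as.integer(splits[[strategy]])
    plan <- make_split(records, strategy, k,
                       seed = derive_seed(seed, "split", strategy))
    check_leakage(plan, records)
    for (variant in names(protein_sets)) {
      for (balance in sna) {
        for (pm in permutations) {
          for (fold in seq_len(k)) {
            cell_seed <- derive_seed(seed, strategy, variant, balance,
                                     pm$target, pm$phase, fold)
            res <- tryCatch({
              tr <- records[plan$assignments != fold, , drop = FALSE]
              te <- records[plan$assignments == fold, , drop = FALSE]
              if (balance) {
                tr <- apply_sna(tr, decoy_features, target_ratio,
                                seed = derive_seed(cell_seed, "sna_train"))
                if (sna_folds == "both")
                  te <- apply_sna(te, decoy_features, target_ratio,
                                  seed = derive_seed(cell_seed, "sna_test"))
              }
              dtr <- build_design(tr, protein_sets[[variant]], lig_all)
              dte <- build_design(te, protein_sets[[variant]], lig_all)
              pm_cell <- pm
              pm_cell$seed <- derive_seed(cell_seed, "perm")
              if (pm$phase == "train") dtr <- permute_block(dtr, pm_cell)
              else dte <- permute_block(dte, pm_cell)
              model <- train_classifier(dtr$X, dtr$y, model_params,
                                        seed = cell_seed)
              m <- evaluate_model(model, dte)
              data.frame(data_split = strategy, embedding = variant,
                         sna = balance, permutation = pm$target,
                         permutation_phase = pm$phase, fold = fold,
                         seed = cell_seed, f1 = m$f1, auroc = m$auroc,
                         recall = m$recall, mcc = m$mcc, pfi = m$pfi,
                         error = NA_character_, stringsAsFactors = FALSE)
            }, error = function(e) {
              data.frame(data_split = strategy, embedding = variant,
                         sna = balance, permutation = pm$target,
                         permutation_phase = pm$phase, fold = fold,
                         seed = cell_seed, f1 = NA_real_, auroc = NA_real_,
                         recall = NA_real_, mcc = NA_real_, pfi = NA_real_,
                         error = conditionMessage(e),
                         stringsAsFactors = FALSE)
            })
            rows[[length(rows) + 1L]] <- res
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pcm_results", "data.frame")
  out
}
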