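#' Stochastic negative addition (per-kinase decoy rebalancing)
#'
#' For each kinase in a fold, computes the current ratio of inactive to
#' active ligands; if it falls short of `target_ratio` (default 1:1), draws
#' the missing number of decoy ligands from the pool (uniformly, without
#' replacement within the kinase) and appends them as inactive records with
#' provenance `sna_decoy` and no pX. Kinases already at or above the target
#' ratio are untouched, and measured records are never modified: dropping
#' the `sna_decoy` rows recovers the input exactly. Each fold should be
#' rebalanced independently.
#'
#' @param records one fold's activity records (`kinase_id`, `family`,
#'   `ligand_id`, `label`, `provenance`).
#' @param decoy_pool decoy bit matrix (only its rownames are consumed here);
#'   must be disjoint from the data set's ligand ids.
#' @param target_ratio inactives per active to reach (default 1).
#' @param seed integer seed.
#' @param on_exhausted `"error"` (default) raises if the pool cannot supply
#'   a kinase's deficit; `"warn"` adds all remaining candidates and warns.
#' @return the augmented records.
#' @export
apply_sna <- function(records, decoy_pool, target_ratio = 1, seed = 1,
                      on_exhausted = c("error", "warn")) {
  on_exhausted <- match.arg(on_exhausted)
  pool_ids <- rownames(decoy_pool)
  if (any(pool_ids %in% records$ligand_id))
    pcm_stop("decoy pool overlaps the data set's ligand ids",
             "pcm_config_error")
  add <- list()
  withr::with_seed(seed, {
    for (kin in unique(records$kinase_id)) {
      rows <- records[records$kinase_id == kin, , drop = FALSE]
      a <- sum(rows$label == 1L)
      i <- sum(rows$label == 0L)
      if (a == 0L) next
      need <- ceiling(a * target_ratio) - i
      if (need <= 0L) next
      if (need > length(pool_ids)) {
        if (on_exhausted == "error")
          pcm_stop(sprintf(
            "decoy pool exhausted for %s: need %d, pool has %d",
            kin, need, length(pool_ids)), "pcm_pool_exhausted_error")
        warning(sprintf("decoy pool exhausted for %s: adding %d of %d",
                        kin, length(pool_ids), need))
        need <- length(pool_ids)
      }
      chosen <- sample(pool_ids, need)
      add[[kin]] <- data.frame(
        kinase_id = kin, family = rows$family[1L], ligand_id = chosen,
        measurement_type = NA_character_, value = NA_real_,
        unit = NA_character_, pX = NA_real_, label = 0L,
        provenance = "sna_decoy", stringsAsFactors = FALSE)
    }
  })
  if (length(add) == 0L) return(records)
  decoys <- do.call(rbind, add)
  extra <- setdiff(names(records), names(decoys))
  for (col in extra) decoys[[col]] <- records[[col]][NA_integer_]
  out <- rbind(records, decoys[names(records)])
  rownames(out) <- NULL
  out
}
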