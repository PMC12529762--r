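#' Joint protein-ligand representations with block bookkeeping
#'
#' A joint representation is the protein feature vector concatenated with
#' the ligand feature vector, protein first. The column ranges of the two
#' blocks are recorded exactly because block permutation and protein feature
#' importance depend on them.
#'
#' @param protein_vec numeric protein feature vector (may have length 0 for
#'   ligand-only ablations).
#' @param ligand_vec numeric ligand feature vector.
#' @param kinase_id,ligand_id identifiers carried along.
#' @return object of class `joint_representation`: list with `features`,
#'   `protein_block`, `ligand_block` (integer column index vectors),
#'   `kinase_id`, `ligand_id`.
#' @export
join_representation <- function(protein_vec, ligand_vec, kinase_id = NA,
                                ligand_id = NA) {
  protein_vec <- as.numeric(protein_vec)
  ligand_vec <- as.numeric(ligand_vec)
  if (any(!is.finite(protein_vec)) || any(!is.finite(ligand_vec)))
    pcm_stop("joint representations require finite features",
             "pcm_validation_error")
  p <- length(protein_vec)
  q <- length(ligand_vec)
  structure(list(features = c(protein_vec, ligand_vec),
                 protein_block = seq_len(p),
                 ligand_block = p + seq_len(q),
                 kinase_id = kinase_id, ligand_id = ligand_id),
            class = "joint_representation")
}

#' Block layout of a joint feature matrix
#' @param p,q protein and ligand block widths.
#' @return list with `p`, `q`, `protein` and `ligand` column index vectors.
#' @export
block_layout <- function(p, q) {
  list(p = as.integer(p), q = as.integer(q),
       protein = seq_len(p), ligand = p + seq_len(q))
}

#' Assemble the joint design matrix for a set of activity records
#'
#' Looks up each record's protein feature vector and ligand bit vector and
#' concatenates them protein-first. All rows share one block layout. Decoy
#' records (provenance `sna_decoy`) use the same lookup, so their ligand ids
#' must be present in `ligand_features`.
#'
#' @param records activity data.frame with `kinase_id`, `ligand_id`,
#'   `label`.
#' @param protein_features numeric matrix, rownames = kinase ids.
#' @param ligand_features numeric matrix, rownames = ligand ids.
#' @return list of class `pcm_design`: `X` (n x (p+q) matrix), `y` (integer
#'   labels), `blocks` ([block_layout()]), `meta` (record data.frame).
#' @export
build_design <- function(records, protein_features, ligand_features) {
  pk <- match(records$kinase_id, rownames(protein_features))
  pl <- match(records$ligand_id, rownames(ligand_features))
  if (anyNA(pk))
    pcm_stop(paste("kinase ids missing from protein features:",
                   paste(unique(records$kinase_id[is.na(pk)]),
                         collapse = ", ")), "pcm_lookup_error")
  if (anyNA(pl))
    pcm_stop(paste("ligand ids missing from ligand features:",
                   paste(utils::head(unique(records$ligand_id[is.na(pl)]), 5),
                         collapse = ", ")), "pcm_lookup_error")
  X <- cbind(protein_features[pk, , drop = FALSE],
             ligand_features[pl, , drop = FALSE])
  if (any(!is.finite(X)))
    pcm_stop("non-finite entries in the joint design matrix",
             "pcm_validation_error")
  rownames(X) <- NULL
  colnames(X) <- sprintf("x%05d", seq_len(ncol(X)))
  structure(list(X = X, y = as.integer(records$label),
                 blocks = block_layout(ncol(protein_features),
                                       ncol(ligand_features)),
                 meta = records), class = "pcm_design")
}
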