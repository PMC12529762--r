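#' Per-residue embedding matrices and their MSA-guided derivatives
#'
#' An embedding matrix is a plain numeric matrix with two attributes:
#' `kinase_id` and `form`, one of `raw` (L_seq x c, one row per ungapped
#' residue), `padded` (L_msa x c, zero rows at gap positions), `trimmed`
#' (L_keep x c, plus a `retained_columns` attribute of MSA column indices),
#' `pooled` (1 x c) or `flattened` (1 x rows*c).
#'
#' @param values numeric matrix.
#' @param kinase_id identifier.
#' @param form provenance flag.
#' @param retained_columns for trimmed matrices, the MSA columns kept.
#' @return the matrix with class `embedding_matrix`.
#' @export
embedding_matrix <- function(values, kinase_id,
                             form = c("raw", "padded", "trimmed", "pooled",
                                      "flattened"),
                             retained_columns = NULL) {
  form <- match.arg(form)
  stopifnot(is.matrix(values), is.numeric(values))
  structure(values, kinase_id = kinase_id, form = form,
            retained_columns = retained_columns,
            class = c("embedding_matrix", class(values)))
}

emb_form <- function(m) attr(m, "form") %||% "raw"

#' Pad a raw embedding against its MSA row
#'
#' Inserts zero-vectors (1 x c) at positions indicated as gaps in the
#' aligned sequence, equalizing the size of all kinase embeddings to
#' L_msa x c and giving every kinase the same MSA column coordinates.
#'
#' @param raw raw embedding matrix (L_seq x c).
#' @param aligned_seq the kinase's aligned sequence (string with `-` gaps),
#'   or an [aligned_msa] together with `id`.
#' @param id kinase id, required when `aligned_seq` is an MSA.
#' @return padded [embedding_matrix] of shape L_msa x c.
#' @export
pad_embedding <- function(raw, aligned_seq, id = attr(raw, "kinase_id")) {
  if (inherits(aligned_seq, "aligned_msa")) {
    gaps <- msa_gap_mask(aligned_seq, id)
  } else {
    gaps <- strsplit(aligned_seq, "", fixed = TRUE)[[1L]] == "-"
  }
  if (nrow(raw) != sum(!gaps))
    pcm_stop(sprintf(
      "embedding has %d rows but the aligned sequence has %d residues",
      nrow(raw), sum(!gaps)), "pcm_alignment_error")
  out <- matrix(0, nrow = length(gaps), ncol = ncol(raw))
  out[!gaps, ] <- raw
  embedding_matrix(out, id %||% attr(raw, "kinase_id"), form = "padded")
}

#' Trim sparse MSA columns from padded embeddings
#'
#' Removes alignment positions whose gap fraction strictly exceeds
#' `threshold` ("over 95\%" read literally: a column at exactly the
#' threshold is retained). The same retained column set applies to every
#' kinase, preserving the shared coordinate system.
#'
#' @param padded named list of padded embedding matrices (all L_msa x c).
#' @param msa the [aligned_msa] the embeddings were padded against.
#' @param threshold gap-fraction cutoff in `[0, 1]`, default 0.95.
#' @return list with `embeddings` (trimmed matrices, L_keep x c) and
#'   `retained_columns` (ordered MSA column indices).
#' @export
trim_columns <- function(padded, msa, threshold = 0.95) {
  gf <- column_gap_fraction(msa)
  nr <- vapply(padded, nrow, integer(1))
  if (any(nr != msa$n_columns))
    pcm_stop("all inputs must be padded to the MSA width",
             "pcm_consistency_error")
  keep <- which(gf <= threshold)
  emb <- lapply(names(padded) %||% seq_along(padded), function(k) {
    m <- padded[[k]]
    embedding_matrix(m[keep, , drop = FALSE],
                     attr(m, "kinase_id") %||% k, form = "trimmed",
                     retained_columns = keep)
  })
  names(emb) <- names(padded)
  list(embeddings = emb, retained_columns = keep)
}

#' Mean-aggregate an embedding matrix over residues
#'
#' Collapses a rows x c matrix to a single 1 x c vector by the column mean.
#' Applied to padded or trimmed forms, the zero pad rows are included in the
#' mean (the default convention; pooling the raw form uses only real
#' residues by construction).
#'
#' @param m embedding matrix with at least one row.
#' @return pooled [embedding_matrix] (1 x c).
#' @export
mean_aggregate <- function(m) {
  if (nrow(m) == 0L)
    pcm_stop("cannot pool an embedding with zero rows",
             "pcm_degenerate_error")
  embedding_matrix(matrix(colMeans(m), nrow = 1L), attr(m, "kinase_id"),
                   form = "pooled")
}

#' Flatten a fixed-shape embedding matrix to a single feature vector
#'
#' Residue-major order: row 1's c values come first. Only padded or trimmed
#' (fixed row count across kinases) matrices may be flattened; raw matrices
#' have variable lengths and must be padded first.
#'
#' @param m padded or trimmed embedding matrix.
#' @return flattened [embedding_matrix] (1 x rows*c) carrying `dims`.
#' @export
flatten_embedding <- function(m) {
  if (emb_form(m) %in% c("raw"))
    pcm_stop("raw embeddings have variable length; pad before flattening",
             "pcm_form_error")
  out <- embedding_matrix(matrix(as.vector(t(m)), nrow = 1L),
                          attr(m, "kinase_id"), form = "flattened")
  attr(out, "dims") <- dim(m)
  out
}

#' @rdname flatten_embedding
#' @param v flattened vector (or 1 x rows*c matrix).
#' @param rows,cols original shape.
#' @export
unflatten_embedding <- function(v, rows, cols) {
  matrix(as.numeric(v), nrow = rows, ncol = cols, byrow = TRUE)
}

#' Write / read an embedding container
#'
#' Plain-text array container: one TSV per kinase under `dir`, plus a JSON
#' manifest recording the form, embedding width and retained columns.
#'
#' @param embeddings named list of embedding matrices.
#' @param dir container directory (created if needed).
#' @return `read_embeddings` returns the named list.
#' @export
write_embeddings <- function(embeddings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in names(embeddings))
    utils::write.table(unclass(embeddings[[k]]), file.path(dir,
                       paste0(k, ".tsv")), sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  manifest <- list(
    kinase_ids = names(embeddings),
    form = emb_form(embeddings[[1L]]),
    embed_dim = ncol(embeddings[[1L]]),
    retained_columns = attr(embeddings[[1L]], "retained_columns"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- lapply(manifest$kinase_ids, function(k) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0(k, ".tsv")),
                                     sep = "\t"))
    dimnames(m) <- NULL
    embedding_matrix(m, k, form = manifest$form,
                     retained_columns = manifest$retained_columns)
  })
  names(out) <- manifest$kinase_ids
  out
}
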