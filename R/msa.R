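#' Gap-containing multiple sequence alignment with family labels
#'
#' Lightweight container for an aligned set of kinase-domain sequences over
#' the 20-letter amino-acid alphabet plus the gap character `-`. The MSA
#' defines the shared column coordinate system used for embedding padding
#' and trimming.
#'
#' @param ids character vector of unique kinase identifiers.
#' @param family character vector of family labels, one per row.
#' @param seqs character vector of aligned sequences, all the same width.
#' @return object of class `aligned_msa`: a list with elements `ids`,
#'   `family`, `seqs` and `n_columns`.
#' @export
aligned_msa <- function(ids, family, seqs) {
  if (length(ids) == 0L)
    pcm_stop("an alignment needs at least one row", "pcm_config_error")
  stopifnot(length(ids) == length(family), length(ids) == length(seqs))
  if (anyDuplicated(ids))
    pcm_stop("kinase identifiers must be unique", "pcm_config_error")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    pcm_stop("all aligned sequences must have identical length",
             "pcm_config_error")
  bad <- grepl(paste0("[^-", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad))
    pcm_stop("sequences contain symbols outside the amino-acid alphabet",
             "pcm_config_error")
  structure(list(ids = as.character(ids), family = as.character(family),
                 seqs = as.character(seqs), n_columns = widths[1L]),
            class = "aligned_msa")
}

#' @export
print.aligned_msa <- function(x, ...) {
  cat(sprintf("aligned_msa: %d sequences x %d columns, %d families\n",
              length(x$ids), x$n_columns, length(unique(x$family))))
  invisible(x)
}

# character matrix view (rows x columns) of the alignment
msa_char_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
}

#' Per-row gap mask
#' @param msa an [aligned_msa].
#' @param id kinase identifier.
#' @return logical vector over columns, TRUE at gap positions.
#' @export
msa_gap_mask <- function(msa, id) {
  i <- match(id, msa$ids)
  if (is.na(i)) pcm_stop(paste("unknown kinase id:", id), "pcm_config_error")
  strsplit(msa$seqs[i], "", fixed = TRUE)[[1L]] == "-"
}

#' Ungapped sequence lengths
#' @param msa an [aligned_msa].
#' @return named integer vector of ungapped lengths per kinase.
#' @export
msa_ungapped_lengths <- function(msa) {
  stats::setNames(msa$n_columns - vapply(
    strsplit(msa$seqs, "", fixed = TRUE),
    function(s) sum(s == "-"), integer(1)), msa$ids)
}

#' Fraction of gapped rows per alignment column
#'
#' Entry j is the number of rows carrying `-` at column j divided by the
#' number of rows; this is the statistic that drives column trimming.
#'
#' @param msa an [aligned_msa].
#' @return numeric vector in `[0, 1]` of length `n_columns`.
#' @export
column_gap_fraction <- function(msa) {
  if (length(msa$ids) == 0L)
    pcm_stop("empty alignment", "pcm_config_error")
  colMeans(msa_char_matrix(msa) == "-")
}

#' Read / write an aligned FASTA with family annotations
#'
#' Sequences are stored as standard aligned FASTA via Biostrings; the family
#' label rides in the header as `<id> family=<label>`.
#'
#' @param msa an [aligned_msa].
#' @param path output file.
#' @return `write_msa_fasta` returns `path` invisibly; `read_msa_fasta`
#'   returns an [aligned_msa].
#' @export
write_msa_fasta <- function(msa, path) {
  x <- Biostrings::AAStringSet(msa$seqs)
  names(x) <- paste0(msa$ids, " family=", msa$family)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_msa_fasta
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  fam <- ifelse(grepl("family=", hdr), sub(".*family=(\\S+).*", "\\1", hdr),
                NA_character_)
  aligned_msa(ids, fam, as.character(x))
}
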