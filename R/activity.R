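#' @name activity
#' @title Activity standardization to the pX scale
#' @description Heterogeneous potency measurements (Kd, Ki, IC50) spanning
#'   orders of magnitude are put on the common negative-log-molar scale
#'   `pX = -log10(X)`, with X in molar units. pChEMBL values are already on
#'   that scale and pass through; percent-inhibition / percent-activity
#'   records are carried through curation but never converted.
NULL

UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

PX_TYPES <- c("Kd", "Ki", "IC50")
PCT_TYPES <- c("pct_inhibition", "pct_activity")

#' Convert a measured value to molar concentration
#' @param value numeric vector of measured values.
#' @param unit character vector of units among `M, mM, uM, nM, pM`.
#' @return numeric vector in molar.
#' @export
to_molar <- function(value, unit) {
  f <- UNIT_FACTORS[unit]
  if (anyNA(f))
    pcm_stop(paste("unknown unit(s):",
                   paste(unique(unit[is.na(f)]), collapse = ", ")),
             "pcm_domain_error")
  unname(value * f)
}

#' Standardize a potency measurement to pX
#'
#' `pX = -log10(X)` with X the Kd / Ki / IC50 value in molar concentration.
#' pChEMBL values are already pX and are returned unchanged. Percent-type
#' measurements have no defined conversion and raise an error.
#'
#' @param value positive numeric vector (molar for Kd/Ki/IC50 unless `unit`
#'   says otherwise; dimensionless for pChEMBL).
#' @param measurement_type one of `Kd`, `Ki`, `IC50`, `pChEMBL`.
#' @param unit unit of `value` for the molar types (default `"M"`).
#' @return numeric pX vector.
#' @export
#' @examples
#' to_pX(1e-6, "IC50")        # 6
#' to_pX(50, "Kd", unit = "nM")  # 7.30103
to_pX <- function(value, measurement_type, unit = "M") {
  measurement_type <- rep_len(measurement_type, length(value))
  unit <- rep_len(unit, length(value))
  if (any(measurement_type %in% PCT_TYPES))
    pcm_stop("percent-type measurements cannot be converted to pX",
             "pcm_unsupported_error")
  ok <- measurement_type %in% c(PX_TYPES, "pChEMBL")
  if (!all(ok))
    pcm_stop(paste("unknown measurement type(s):",
                   paste(unique(measurement_type[!ok]), collapse = ", ")),
             "pcm_domain_error")
  out <- numeric(length(value))
  is_p <- measurement_type == "pChEMBL"
  out[is_p] <- value[is_p]
  if (any(!is_p)) {
    molar <- to_molar(value[!is_p], unit[!is_p])
    if (any(!is.finite(molar)) || any(molar <= 0))
      pcm_stop("Kd/Ki/IC50 values must be positive and finite",
               "pcm_domain_error")
    out[!is_p] <- -log10(molar)
  }
  out
}

#' Standardize an activity table in place
#'
#' Adds/overwrites the `pX` column for all rows whose measurement type is
#' derivable (Kd, Ki, IC50, pChEMBL); percent-type rows keep `pX = NA` and
#' are retained for bookkeeping only.
#'
#' @param records activity data.frame with columns `measurement_type`,
#'   `value`, `unit`.
#' @return the records with a `pX` column.
#' @export
standardize_activities <- function(records) {
  records$pX <- NA_real_
  conv <- records$measurement_type %in% c(PX_TYPES, "pChEMBL")
  if (any(conv))
    records$pX[conv] <- to_pX(records$value[conv],
                              records$measurement_type[conv],
                              records$unit[conv])
  records
}

#' Merge replicate measurements
#'
#' One record per (kinase_id, ligand_id, measurement_type); replicate pX
#' values are merged by their median (midpoint of the central pair for even
#' counts), which is robust to heavy-tailed assay error. Measurement types
#' are never merged across each other. The replicate count is recorded in
#' `n_replicates`; the merge is idempotent.
#'
#' @param records standardized activity data.frame with a `pX` column.
#' @return aggregated data.frame with one row per triple.
#' @export
aggregate_replicates <- function(records) {
  if (nrow(records) == 0L) {
    records$n_replicates <- integer(0)
    return(records)
  }
  key <- interaction(records$kinase_id, records$ligand_id,
                     records$measurement_type, drop = TRUE)
  idx <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    r <- records[i[1L], , drop = FALSE]
    r$pX <- stats::median(records$pX[i])
    r$value <- if (r$measurement_type %in% PX_TYPES && !is.na(r$pX)) {
      r$unit <- "M"
      10^(-r$pX)
    } else r$value
    r$n_replicates <- length(i)
    r
  }))
  rownames(out) <- NULL
  out[order(out$kinase_id, out$ligand_id, out$measurement_type), ,
      drop = FALSE]
}

#' Binarize pX into an active/inactive label
#'
#' Active (1) iff `pX >= threshold`; the boundary value is classed active.
#'
#' @param pX numeric pX vector (or a records data.frame with a `pX` column).
#' @param threshold classification threshold on the pX scale (default 6,
#'   i.e. 1 micromolar).
#' @return integer 0/1 vector, or the data.frame with a `label` column.
#' @export
binarize <- function(pX, threshold = 6) {
  if (is.data.frame(pX)) {
    pX$label <- binarize(pX$pX, threshold)
    return(pX)
  }
  if (anyNA(pX))
    pcm_stop("cannot binarize records with missing pX", "pcm_missing_error")
  as.integer(pX >= threshold)
}

#' Restrict an activity table to kinases present in the MSA
#'
#' Kinases whose sequences are absent from the alignment cannot be
#' featurized and their records are dropped; the drop count is reported via
#' `message()`.
#'
#' @param records activity data.frame.
#' @param msa an [aligned_msa].
#' @return the retained records.
#' @export
filter_records <- function(records, msa) {
  keep <- records$kinase_id %in% msa$ids
  if (any(!keep))
    message(sprintf("filter_records: dropped %d of %d records (%d kinases absent from MSA)",
                    sum(!keep), nrow(records),
                    length(unique(records$kinase_id[!keep]))))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write the activity CSV schema
#'
#' Plain CSV with columns kinase_id, family, ligand_id, measurement_type,
#' value, unit and optionally pX, label, provenance.
#'
#' @param records activity data.frame.
#' @param path file path.
#' @return `read_activity_csv` returns the data.frame.
#' @export
write_activity_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
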