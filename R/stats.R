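#' Aggregate per-fold metrics across cross-validation cycles
#'
#' Per condition (combination of the given factor columns): mean, standard
#' deviation, standard error and fold count of each metric. A condition with
#' a single fold reports `NA` for sd and se. The aggregation is invariant to
#' fold order.
#'
#' @param results a `pcm_results` data.frame (or any per-fold table).
#' @param metrics metric column names to summarize.
#' @param factors factor column names defining a condition.
#' @return long-format data.frame: factors, `metric`, `mean`, `sd`, `se`,
#'   `n`.
#' @export
aggregate_cv <- function(results,
                         metrics = c("f1", "auroc", "recall", "mcc", "pfi"),
                         factors = c("data_split", "embedding", "sna",
                                     "permutation", "permutation_phase")) {
  factors <- intersect(factors, names(results))
  metrics <- intersect(metrics, names(results))
  key <- interaction(results[factors], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(results)), key),
    function(idx) {
      head_row <- results[idx[1L], factors, drop = FALSE]
      do.call(rbind, lapply(metrics, function(m) {
        v <- results[[m]][idx]
        v <- v[!is.na(v)]
        cbind(head_row,
              data.frame(metric = m, mean = mean(v),
                         sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                         se = if (length(v) > 1)
                           stats::sd(v) / sqrt(length(v)) else NA_real_,
                         n = length(v), stringsAsFactors = FALSE))
      }))
    }))
  rownames(out) <- NULL
  out
}

#' Multi-factor fixed-effects ANOVA on per-fold metrics
#'
#' Additive linear model of one metric on the experiment factors, tested
#' with Type II sums of squares (robust to unbalanced grids; interactions
#' are not modelled). Observations are per-fold metric values, not condition
#' means.
#'
#' @param results per-fold results table.
#' @param factors factor column names to include (each needs >= 2 observed
#'   levels).
#' @param response metric column name.
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame: `variable`, `df`, `F`, `p`, `stars`, `significant`.
#'   A constant response returns `NA` statistics with a warning and the
#'   `flag` attribute set to `"constant response"`.
#' @export
anova_table <- function(results, factors, response, alpha = 0.05) {
  df <- results[stats::complete.cases(results[c(factors, response)]), ,
                drop = FALSE]
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2L)
      pcm_stop(sprintf("factor '%s' has fewer than 2 observed levels", f),
               "pcm_config_error")
  }
  if (stats::var(df[[response]]) == 0) {
    warning("constant response: F statistics undefined")
    out <- data.frame(variable = factors, df = NA_real_, F = NA_real_,
                      p = NA_real_, stars = NA_character_,
                      significant = NA)
    attr(out, "flag") <- "constant response"
    return(out)
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  a <- car::Anova(fit, type = 2)
  keep <- rownames(a) != "Residuals"
  out <- data.frame(variable = rownames(a)[keep], df = a$Df[keep],
                    F = a$`F value`[keep], p = a$`Pr(>F)`[keep],
                    stringsAsFactors = FALSE)
  out$stars <- significance_stars(out$p)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' All unordered level pairs of one factor, with studentized-range adjusted
#' p-values (for two levels the adjusted p equals the unadjusted pooled
#' two-sample t-test p). Levels with fewer than 2 observations are excluded
#' with a warning.
#'
#' @param results per-fold results table.
#' @param factor_name the factor column.
#' @param response metric column name.
#' @param alpha rejection threshold.
#' @return data.frame: `level_i`, `level_j`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `reject`.
#' @export
tukey_hsd <- function(results, factor_name, response, alpha = 0.05) {
  df <- results[stats::complete.cases(results[c(factor_name, response)]), ,
                drop = FALSE]
  counts <- table(df[[factor_name]])
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning(sprintf("excluding level(s) with < 2 observations: %s",
                    paste(small, collapse = ", ")))
    df <- df[!df[[factor_name]] %in% small, , drop = FALSE]
  }
  df[[factor_name]] <- factor(df[[factor_name]])
  if (nlevels(df[[factor_name]]) < 2L)
    pcm_stop("Tukey HSD needs at least 2 usable levels", "pcm_config_error")
  fml <- stats::as.formula(paste(response, "~", factor_name))
  tk <- stats::TukeyHSD(stats::aov(fml, data = df))[[factor_name]]
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(level_i = vapply(pair, `[`, "", 2L),
                    level_j = vapply(pair, `[`, "", 1L),
                    diff = tk[, "diff"], lwr = tk[, "lwr"],
                    upr = tk[, "upr"], p_adj = tk[, "p adj"],
                    stringsAsFactors = FALSE)
  out$reject <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Significance stars
#'
#' Conventional mapping: `p < 0.001` to `***`, `p < 0.01` to `**`,
#' `p < 0.05` to `*`, otherwise `n.s.`.
#'
#' @param p numeric p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "n.s."))))
}

#' Write the factorial analysis report
#'
#' Emits `summary.csv` (condition means), `anova.csv`, `tukey.csv` and a
#' human-readable `report.md` with significance stars.
#'
#' @param dir output directory (created if needed).
#' @param summary output of [aggregate_cv()].
#' @param anova output of [anova_table()] (optionally with a `metric`
#'   column when several metrics were analysed).
#' @param tukey output of [tukey_hsd()] (optionally stacked likewise).
#' @return the directory, invisibly.
#' @export
write_report <- function(dir, summary, anova, tukey) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(anova, file.path(dir, "anova.csv"), row.names = FALSE)
  utils::write.csv(tukey, file.path(dir, "tukey.csv"), row.names = FALSE)
  lines <- c("# Factorial evaluation report", "",
             "## ANOVA (Type II, additive model)", "",
             paste0("| ", paste(names(anova), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(anova)), collapse = "|"),
                    "|"),
             apply(anova, 1, function(r)
               paste0("| ", paste(format(r, digits = 4), collapse = " | "),
                      " |")),
             "", "## Tukey HSD pairwise comparisons", "",
             paste0("| ", paste(names(tukey), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(tukey)), collapse = "|"),
                    "|"),
             apply(tukey, 1, function(r)
               paste0("| ", paste(format(r, digits = 4), collapse = " | "),
                      " |")))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
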