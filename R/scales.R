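#' @name descriptor-scales
#' @title Amino-acid descriptor scales
#' @description Per-residue descriptor tables used to featurize gap-free
#'   alignment columns: the 3-component Z-scale of Hellberg et al. (principal
#'   properties of physicochemical descriptors), a 2-component physical scale
#'   (Kyte-Doolittle hydrophobicity and residue volume), 5- and 8-component
#'   principal-property scales derived from the AAindex collection (surrogate
#'   T-scale / ST-scale analogues of the published topological scales, built
#'   deterministically by PCA of all complete AAindex indices), and 21-symbol
#'   one-hot encoding (20 amino acids + gap).
NULL

# Hellberg z-scales (z1: hydrophilicity, z2: bulk, z3: electronic)
ZSCALE_TABLE <- matrix(c(
   0.07, -1.73,  0.09,   # A
   0.71, -0.97,  4.13,   # C
   3.64,  1.13,  2.36,   # D
   3.08,  0.39, -0.07,   # E
  -4.92,  1.30,  0.45,   # F
   2.23, -5.36,  0.30,   # G
   2.41,  1.74,  1.11,   # H
  -4.44, -1.68, -1.03,   # I
   2.84,  1.41, -3.14,   # K
  -4.19, -1.03, -0.98,   # L
  -2.49, -0.27, -0.41,   # M
   3.22,  1.45,  0.84,   # N
  -1.22,  0.88,  2.23,   # P
   2.18,  0.53, -1.14,   # Q
   2.88,  2.52, -3.44,   # R
   1.96, -1.63,  0.57,   # S
   0.92, -2.09, -1.40,   # T
  -2.69, -2.53, -1.29,   # V
  -4.75,  3.65,  0.85,   # W
  -1.39,  2.32,  0.01),  # Y
  ncol = 3, byrow = TRUE,
  dimnames = list(AA_ALPHABET, c("z1", "z2", "z3")))

# Kyte-Doolittle hydropathy and residue volume (A^3)
PHYSICAL_TABLE <- matrix(c(
   1.8,  88.6,  2.5, 108.5, -3.5, 111.1, -3.5, 138.4,  2.8, 189.9,
  -0.4,  60.1, -3.2, 153.2,  4.5, 166.7, -3.9, 168.6,  3.8, 166.7,
   1.9, 162.9, -3.5, 114.1, -1.6, 112.7, -3.5, 143.8, -4.5, 173.4,
  -0.8,  89.0, -0.7, 116.1,  4.2, 140.0, -0.9, 227.8, -1.3, 193.6),
  ncol = 2, byrow = TRUE,
  dimnames = list(AA_ALPHABET, c("hydropathy", "volume")))

.pcm_cache <- new.env(parent = emptyenv())

# principal-property scale of dimension k from the AAindex collection;
# deterministic (no RNG): complete indices, standardized, PCA, signed so
# the first loading of each component is positive, scores standardized.
aaindex_pp_scale <- function(k) {
  key <- paste0("pp", k)
  if (!is.null(.pcm_cache[[key]])) return(.pcm_cache[[key]])
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  m <- sapply(e$aaindex, function(a) a$I)          # 20 x n_indices
  rownames(m) <- vapply(rownames(m),
                        function(r) toupper(seqinr::a(r)), character(1))
  m <- m[AA_ALPHABET, colSums(is.na(m)) == 0, drop = FALSE]
  keep <- apply(m, 2, stats::sd) > 0
  pc <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  s <- pc$x[, seq_len(k), drop = FALSE]
  s <- sweep(s, 2, apply(s, 2, function(x) sign(x[1]) %||% 1), `*`)
  s <- scale(s)
  attr(s, "scaled:center") <- NULL
  attr(s, "scaled:scale") <- NULL
  colnames(s) <- paste0("pp", seq_len(k))
  .pcm_cache[[key]] <- s
  s
}

#' Look up a descriptor scale table
#'
#' @param name one of `zscale` (k = 3), `tscale` (k = 5), `stscale`
#'   (k = 8), `physical` (k = 2), `onehot` (k = 21: 20 amino acids + gap).
#' @return list with `name`, `k` and `table` (a residue x k numeric matrix;
#'   for one-hot the table covers the gap symbol too).
#' @export
descriptor_scale <- function(name = c("zscale", "tscale", "stscale",
                                      "physical", "onehot")) {
  name <- match.arg(name)
  table <- switch(name,
    zscale = ZSCALE_TABLE,
    physical = PHYSICAL_TABLE,
    tscale = aaindex_pp_scale(5L),
    stscale = aaindex_pp_scale(8L),
    onehot = {
      syms <- c(AA_ALPHABET, "-")
      m <- diag(length(syms))
      dimnames(m) <- list(syms, syms)
      m
    })
  list(name = name, k = ncol(table), table = table)
}

#' Encode aligned sequences with an amino-acid descriptor scale
#'
#' For the numeric scales, only gap-free alignment columns (no `-` in any
#' row) are encoded, matching a fully trimmed, gap-free final alignment;
#' vector length is `k * n_gapfree`. One-hot encoding uses all columns with
#' the gap as its own 21st symbol. Positions are concatenated residue-major
#' (column 1's k values first).
#'
#' @param msa an [aligned_msa].
#' @param scale a scale name or the result of [descriptor_scale()].
#' @param gap_policy `"gapfree"` (default) restricts numeric scales to
#'   gap-free columns; `"all"` encodes every column and requires the table
#'   to cover the gap symbol.
#' @return named list of numeric feature vectors keyed by kinase id.
#' @export
encode_with_scale <- function(msa, scale = "zscale",
                              gap_policy = c("gapfree", "all")) {
  gap_policy <- match.arg(gap_policy)
  if (is.character(scale)) scale <- descriptor_scale(scale)
  cm <- msa_char_matrix(msa)
  cols <- if (scale$name == "onehot" || gap_policy == "all")
    seq_len(ncol(cm)) else which(colSums(cm == "-") == 0L)
  tab <- scale$table
  lookup <- function(sym) {
    i <- match(sym, rownames(tab))
    if (anyNA(i)) {
      unknown <- unique(sym[is.na(i)])
      if (all(unknown == "X")) {
        warning("unknown residue 'X' mapped to the zero vector")
        out <- matrix(0, length(sym), ncol(tab))
        out[!is.na(i), ] <- tab[i[!is.na(i)], , drop = FALSE]
        return(out)
      }
      pcm_stop(paste("residue symbol(s) absent from scale table:",
                     paste(unknown, collapse = ", ")),
               "pcm_unknown_residue_error")
    }
    tab[i, , drop = FALSE]
  }
  out <- lapply(seq_along(msa$ids), function(r)
    as.numeric(t(lookup(cm[r, cols]))))
  names(out) <- msa$ids
  out
}
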