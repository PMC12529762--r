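#' Specification of an X/Y permutation test
#'
#' X-permutation shuffles one feature block (protein or ligand sub-vectors)
#' across rows; Y-permutation shuffles labels. The phase selects whether the
#' shuffle corrupts the training portion (the model learns from scrambled
#' information) or the held-out portion (an intact model is evaluated on
#' scrambled inputs).
#'
#' @param target `"none"`, `"protein"`, `"ligand"` or `"labels"`.
#' @param phase `"train"` or `"test"`; irrelevant when target is none.
#' @param seed integer seed for the permutation draw.
#' @return object of class `permutation_spec`.
#' @export
permutation_spec <- function(target = c("none", "protein", "ligand",
                                        "labels"),
                             phase = c("train", "test"), seed = 1) {
  structure(list(target = match.arg(target), phase = match.arg(phase),
                 seed = seed), class = "permutation_spec")
}

#' Apply a block permutation to part of a design
#'
#' Draws one uniform random permutation of `rows` and reassigns the targeted
#' block (protein sub-vectors, ligand sub-vectors, or labels) along it; all
#' other columns and all rows outside `rows` are untouched, so the multiset
#' of permuted items is preserved exactly.
#'
#' @param design a [build_design()] object.
#' @param spec a [permutation_spec()].
#' @param rows integer indices of the rows in the targeted phase subset
#'   (default: all rows).
#' @return the design with the permutation applied.
#' @export
permute_block <- function(design, spec, rows = seq_along(design$y)) {
  stopifnot(inherits(design, "pcm_design"),
            inherits(spec, "permutation_spec"))
  if (spec$target == "none" || length(rows) < 2L) return(design)
  perm <- withr::with_seed(spec$seed, sample(seq_along(rows)))
  if (spec$target == "labels") {
    design$y[rows] <- design$y[rows][perm]
  } else {
    cols <- design$blocks[[spec$target]]
    design$X[rows, cols] <- design$X[rows[perm], cols, drop = FALSE]
  }
  design
}
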