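#' @name fingerprints
#' @title Molecular fingerprints from SMILES
#' @description Folded binary fingerprints of the two classical families:
#'   circular (Morgan-style atom environments up to a radius) and linear
#'   path fingerprints (simple bond paths up to a maximum length). SMILES
#'   parsing and canonicalization are delegated to OpenBabel via ChemmineOB /
#'   ChemmineR; environment/path enumeration and hashing onto `n_bits` are
#'   implemented here. Because input SMILES are canonicalized before the
#'   graph is built, two equivalent SMILES of the same molecule yield
#'   identical fingerprints. Multi-fragment inputs (e.g. salts) keep the
#'   largest fragment, with a message. The synthetic-data path of the
#'   package bypasses chemistry entirely: [generate_ligands()] produces
#'   structured bit-vectors directly.
NULL

require_chemistry <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE) ||
      !requireNamespace("ChemmineR", quietly = TRUE))
    pcm_stop("ChemmineOB + ChemmineR are required for SMILES fingerprints",
             "pcm_toolkit_error")
}

# parse a SMILES into an atom/bond graph; canonicalize first so that the
# graph (and hence the fingerprint) is representation-invariant
parse_smiles_graph <- function(smiles) {
  require_chemistry()
  can <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  can <- sub("\\s.*$", "", trimws(can))
  if (!nzchar(can))
    pcm_stop(paste("unparsable SMILES:", smiles), "pcm_parse_error")
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", can)
  # single-atom molecules trip ChemmineR's bond-block validity heuristic
  sdf <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(sdf_txt, "\n", fixed = TRUE)[[1L]])))[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L)
    matrix(integer(0), ncol = 3) else
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  # atom indices are 1-based; an all-zero row means "no bonds" (lone atoms)
  bonds <- bonds[bonds[, 1] >= 1L & bonds[, 2] >= 1L, , drop = FALSE]
  # largest connected fragment
  comp <- seq_along(atoms)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(bonds))) {
      a <- comp[bonds[i, 1]]; b <- comp[bonds[i, 2]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1L) {
    main <- as.integer(names(which.max(table(comp))))
    keep <- which(comp == main)
    message(sprintf("multi-fragment SMILES: keeping largest fragment (%d of %d atoms)",
                    length(keep), length(atoms)))
    remap <- match(seq_along(atoms), keep)
    bonds <- bonds[bonds[, 1] %in% keep & bonds[, 2] %in% keep, ,
                   drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
    atoms <- atoms[keep]
  }
  list(atoms = atoms, bonds = bonds)
}

# order-independent integer hash of an integer/character vector
hash_ints <- function(x) {
  if (is.character(x)) x <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 7
  for (v in x) h <- ((h %% 65521) * 131 + (v %% 65521)) %% 2147483647
  as.integer(h)
}

fold_bits <- function(hashes, n_bits) {
  v <- integer(n_bits)
  v[(unique(hashes) %% n_bits) + 1L] <- 1L
  v
}

#' Circular (Morgan-style) fingerprint
#'
#' Iteratively refines per-atom environment identifiers out to `radius`
#' bonds (initial invariant: element, degree, summed bond order), collects
#' the identifiers of all radii, and folds them onto `n_bits` bits.
#'
#' @param smiles a single SMILES string.
#' @param radius environment radius in bonds (the study default is 5).
#' @param n_bits folded vector length (512 / 1024 / 2048 typical).
#' @return integer 0/1 vector of length `n_bits`.
#' @export
circular_fingerprint <- function(smiles, radius = 5, n_bits = 1024) {
  stopifnot(is_count(radius) || radius == 0, is_count(n_bits))
  g <- parse_smiles_graph(smiles)
  n <- length(g$atoms)
  nbr <- lapply(seq_len(n), function(i) integer(0))
  bord <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds[i, 1]; b <- g$bonds[i, 2]; o <- g$bonds[i, 3]
    nbr[[a]] <- c(nbr[[a]], b); bord[[a]] <- c(bord[[a]], o)
    nbr[[b]] <- c(nbr[[b]], a); bord[[b]] <- c(bord[[b]], o)
  }
  inv <- vapply(seq_len(n), function(i)
    hash_ints(c(utf8ToInt(g$atoms[i]), length(nbr[[i]]), sum(bord[[i]]))),
    integer(1))
  all_ids <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      env <- sort(inv[nbr[[i]]] * 8L %% 2147483647 + bord[[i]])
      hash_ints(c(r, inv[i], env))
    }, integer(1))
    all_ids <- c(all_ids, inv)
  }
  fold_bits(all_ids, n_bits)
}

#' Linear path fingerprint
#'
#' Enumerates simple atom paths of 0..`max_path` bonds, canonicalizes each
#' path string (minimum of the forward and reverse reading of alternating
#' element symbols and bond orders) and folds the set onto `n_bits` bits.
#'
#' @param smiles a single SMILES string.
#' @param max_path maximum path length in bonds.
#' @param n_bits folded vector length.
#' @return integer 0/1 vector of length `n_bits`.
#' @export
path_fingerprint <- function(smiles, max_path = 5, n_bits = 1024) {
  stopifnot(is_count(max_path), is_count(n_bits))
  g <- parse_smiles_graph(smiles)
  n <- length(g$atoms)
  adj <- lapply(seq_len(n), function(i) list(to = integer(0),
                                             order = integer(0)))
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds[i, 1]; b <- g$bonds[i, 2]; o <- g$bonds[i, 3]
    adj[[a]]$to <- c(adj[[a]]$to, b); adj[[a]]$order <- c(adj[[a]]$order, o)
    adj[[b]]$to <- c(adj[[b]]$to, a); adj[[b]]$order <- c(adj[[b]]$order, o)
  }
  paths <- new.env(parent = emptyenv())
  walk <- function(path, orders) {
    last <- path[length(path)]
    fw <- paste(g$atoms[path], c(orders, ""), sep = "", collapse = "")
    rv <- paste(g$atoms[rev(path)], c(rev(orders), ""), sep = "",
                collapse = "")
    assign(min(fw, rv), TRUE, envir = paths)
    if (length(orders) >= max_path) return(invisible())
    for (j in seq_along(adj[[last]]$to)) {
      nxt <- adj[[last]]$to[j]
      if (!nxt %in% path)
        walk(c(path, nxt), c(orders, adj[[last]]$order[j]))
    }
  }
  for (a in seq_len(n)) walk(a, integer(0))
  fold_bits(vapply(ls(paths), hash_ints, integer(1)), n_bits)
}
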