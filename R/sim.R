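#' Configuration for the synthetic kinase-ligand study generator
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study conditions the rest of the package is audited under: a
#' family-structured kinase panel, a bimodal MSA gap profile (a conserved
#' core plus a few near-universal insertion columns), per-residue embeddings
#' whose family information content is controlled by a single standardized
#' effect size, cluster-structured 1024-bit ligand vectors, and a
#' class-imbalanced activity table (20\% actives at the pX >= 6 threshold)
#' with Gaussian pX noise of 0.5 units, mirroring the reproducibility floor
#' of public bioactivity panels.
#'
#' @param n_families number of kinase families.
#' @param seqs_per_family kinase domains per family.
#' @param n_columns MSA width (alignment columns).
#' @param gap_profile per-column gap probability: a scalar, a vector of
#'   length `n_columns`, or a named preset. Preset `"bimodal"` gives 10\%
#'   gap-free core columns, 10\% all-gap insertion columns and 5\% gap
#'   probability elsewhere, so any trimming threshold in (0.05, 1) is
#'   exercised nontrivially; `"none"` gives a gap-free alignment.
#' @param sub_rate per-position probability that a family member differs
#'   from the family consensus residue.
#' @param embed_dim per-residue embedding width `c`.
#' @param family_signal standardized effect size (>= 0) of family identity
#'   on embedding rows; 0 means embeddings carry no family information.
#' @param regime dependency regime of pX on the representations: one of
#'   `"null"`, `"ligand_only"`, `"protein_only"`, `"interaction"`.
#' @param active_fraction target fraction of records with pX >= 6.
#' @param noise_sd standard deviation of the Gaussian pX noise, in pX units.
#' @param n_ligands,n_bits ligand library size and bit-vector width.
#' @param n_clusters number of latent pharmacophore clusters.
#' @param p_on,p_bg probability that a bit inside the ligand's own cluster
#'   subset (resp. any background bit) is set.
#' @param records_per_kinase measured ligands sampled per kinase.
#' @param beta_ligand,beta_protein,beta_interaction effect-size scales used
#'   by the matching regime (standard deviations on the pX scale).
#' @param decoy_pool_size default size of the disjoint decoy pool.
#' @param seed integer master seed; identical config + seed gives
#'   bit-identical outputs from every generator.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_families = 6, seqs_per_family = 4, n_columns = 120,
                       gap_profile = "bimodal", sub_rate = 0.1,
                       embed_dim = 16, family_signal = 1,
                       regime = c("interaction", "null", "ligand_only",
                                  "protein_only"),
                       active_fraction = 0.2, noise_sd = 0.5,
                       n_ligands = 300, n_bits = 1024, n_clusters = 8,
                       p_on = 0.9, p_bg = 0.02, records_per_kinase = 50,
                       beta_ligand = 1, beta_protein = 1,
                       beta_interaction = 1.5, decoy_pool_size = 500,
                       seed = 1) {
  regime <- match.arg(regime)
  cfg <- list(n_families = n_families, seqs_per_family = seqs_per_family,
              n_columns = n_columns, gap_profile = gap_profile,
              sub_rate = sub_rate, embed_dim = embed_dim,
              family_signal = family_signal, regime = regime,
              active_fraction = active_fraction, noise_sd = noise_sd,
              n_ligands = n_ligands, n_bits = n_bits,
              n_clusters = n_clusters, p_on = p_on, p_bg = p_bg,
              records_per_kinase = records_per_kinase,
              beta_ligand = beta_ligand, beta_protein = beta_protein,
              beta_interaction = beta_interaction,
              decoy_pool_size = decoy_pool_size, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_families", "seqs_per_family", "n_columns", "embed_dim",
              "n_ligands", "n_bits", "n_clusters", "records_per_kinase",
              "decoy_pool_size")
  for (f in counts)
    if (!is_count(cfg[[f]]))
      pcm_stop(sprintf("'%s' must be a positive integer", f),
               "pcm_config_error")
  if (!is.character(cfg$gap_profile)) {
    if (!is_prob(cfg$gap_profile))
      pcm_stop("numeric 'gap_profile' must lie in [0, 1]",
               "pcm_config_error")
    if (!length(cfg$gap_profile) %in% c(1L, cfg$n_columns))
      pcm_stop("'gap_profile' must be scalar or one value per column",
               "pcm_config_error")
  } else if (!cfg$gap_profile %in% c("bimodal", "none")) {
    pcm_stop("unknown gap profile preset", "pcm_config_error")
  }
  if (!is_prob(cfg$sub_rate) || !is_prob(cfg$p_on) || !is_prob(cfg$p_bg))
    pcm_stop("'sub_rate', 'p_on' and 'p_bg' must lie in [0, 1]",
             "pcm_config_error")
  if (!is.numeric(cfg$active_fraction) || cfg$active_fraction <= 0 ||
      cfg$active_fraction >= 1)
    pcm_stop("'active_fraction' must lie in (0, 1)", "pcm_config_error")
  if (cfg$noise_sd < 0 || cfg$family_signal < 0)
    pcm_stop("'noise_sd' and 'family_signal' must be >= 0",
             "pcm_config_error")
  if (cfg$n_bits < 8)
    pcm_stop("'n_bits' must be at least 8", "pcm_config_error")
  invisible(cfg)
}

# resolve a gap_profile spec to a per-column probability vector
resolve_gap_profile <- function(cfg) {
  n <- cfg$n_columns
  gp <- cfg$gap_profile
  if (is.numeric(gp)) return(rep_len(gp, n))
  if (identical(gp, "none")) return(rep(0, n))
  # bimodal: conserved core (p = 0), rare insertion columns (p = 1),
  # low-level gapping elsewhere
  n_core <- max(1L, round(0.1 * n))
  n_high <- max(1L, round(0.1 * n))
  p <- rep(0.05, n)
  idx <- withr::with_seed(derive_seed(cfg$seed, "gap_profile"),
                          sample.int(n, n_core + n_high))
  p[idx[seq_len(n_core)]] <- 0
  p[idx[n_core + seq_len(n_high)]] <- 1
  p
}

#' Generate a family-structured multiple sequence alignment
#'
#' Each family has a random consensus sequence; members substitute residues
#' independently at rate `sub_rate`. Gaps are placed per column by
#' independent Bernoulli draws with the column's gap probability.
#'
#' @param config a [sim_config()].
#' @return an [aligned_msa] with `n_families * seqs_per_family` rows,
#'   unique kinase identifiers and per-row family labels.
#' @export
generate_msa <- function(config) {
  validate_sim_config(config)
  p_gap <- resolve_gap_profile(config)
  n_seq <- config$n_families * config$seqs_per_family
  withr::with_seed(derive_seed(config$seed, "msa"), {
    fams <- rep(paste0("FAM", seq_len(config$n_families)),
                each = config$seqs_per_family)
    ids <- sprintf("KIN%04d", seq_len(n_seq))
    seqs <- character(n_seq)
    row <- 0L
    for (f in seq_len(config$n_families)) {
      consensus <- sample(AA_ALPHABET, config$n_columns, replace = TRUE)
      for (s in seq_len(config$seqs_per_family)) {
        row <- row + 1L
        res <- consensus
        mut <- stats::runif(config$n_columns) < config$sub_rate
        res[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
        res[stats::runif(config$n_columns) < p_gap] <- "-"
        seqs[row] <- paste(res, collapse = "")
      }
    }
    aligned_msa(ids, fams, seqs)
  })
}

#' Generate per-residue protein embeddings for every kinase in an MSA
#'
#' Stand-in for per-residue protein language-model or structural embeddings:
#' each kinase gets a matrix with one row per ungapped residue and
#' `embed_dim` columns. Rows are drawn from a family-specific mean vector
#' (each coordinate N(0, family_signal^2)) plus unit Gaussian noise, so
#' `family_signal = 0` makes embeddings exchangeable across families.
#'
#' @param msa an [aligned_msa].
#' @param config a [sim_config()].
#' @return named list of `L_seq x c` matrices keyed by kinase id, each with
#'   attribute `form = "raw"`.
#' @export
generate_embeddings <- function(msa, config) {
  stopifnot(inherits(msa, "aligned_msa"))
  validate_sim_config(config)
  lens <- msa_ungapped_lengths(msa)
  if (any(lens == 0L))
    pcm_stop(sprintf("kinase(s) with zero ungapped residues: %s",
                     paste(msa$ids[lens == 0L], collapse = ", ")),
             "pcm_degenerate_error")
  fam_idx <- match(msa$family, unique(msa$family))
  withr::with_seed(derive_seed(config$seed, "embeddings"), {
    mu <- matrix(stats::rnorm(length(unique(msa$family)) * config$embed_dim,
                              sd = config$family_signal),
                 nrow = length(unique(msa$family)))
    out <- vector("list", length(msa$ids))
    names(out) <- msa$ids
    for (i in seq_along(msa$ids)) {
      m <- matrix(stats::rnorm(lens[i] * config$embed_dim), nrow = lens[i]) +
        matrix(mu[fam_idx[i], ], nrow = lens[i], ncol = config$embed_dim,
               byrow = TRUE)
      out[[i]] <- embedding_matrix(m, msa$ids[i], form = "raw")
    }
    out
  })
}

# shared machinery for ligand libraries: cluster-structured bit vectors
make_bit_library <- function(n, n_bits, n_clusters, p_on, p_bg, prefix,
                             seed) {
  subset_size <- max(1L, floor(n_bits / (2L * n_clusters)))
  withr::with_seed(seed, {
    cl <- sample.int(n_clusters, n, replace = TRUE)
    m <- matrix(as.integer(stats::runif(n * n_bits) < p_bg), nrow = n)
    for (j in seq_len(n_clusters)) {
      rows <- which(cl == j)
      cols <- (j - 1L) * subset_size + seq_len(subset_size)
      if (length(rows))
        m[rows, cols] <- as.integer(
          stats::runif(length(rows) * subset_size) < p_on)
    }
    rownames(m) <- sprintf("%s%05d", prefix, seq_len(n))
    names(cl) <- rownames(m)
    attr(m, "cluster") <- cl
    attr(m, "cluster_bits") <- lapply(seq_len(n_clusters), function(j)
      (j - 1L) * subset_size + seq_len(subset_size))
    m
  })
}

#' Generate a ligand library of cluster-structured bit vectors
#'
#' Binary vectors with latent cluster structure: each ligand belongs to one
#' of `n_clusters` latent pharmacophore factors, each factor switching a
#' disjoint bit subset on with probability `p_on`; all other bits are sparse
#' background noise at rate `p_bg`. The cluster assignment is retained as
#' ground truth in the `"cluster"` attribute.
#'
#' @param config a [sim_config()].
#' @return `n_ligands x n_bits` 0/1 integer matrix, rownames = ligand ids,
#'   with attributes `cluster` (named integer vector) and `cluster_bits`.
#' @export
generate_ligands <- function(config) {
  validate_sim_config(config)
  make_bit_library(config$n_ligands, config$n_bits, config$n_clusters,
                   config$p_on, config$p_bg, "LIG",
                   derive_seed(config$seed, "ligands"))
}

#' Generate a decoy pool disjoint from the main ligand set
#'
#' Decoys are drawn from the same background library distribution as the
#' main set (cluster-structured bit vectors) but carry fresh identifiers;
#' they model presumed-inactive compounds sampled from a large archive,
#' excluding anything already present in the data set.
#'
#' @param config a [sim_config()].
#' @param exclude character vector of ligand ids that must not appear.
#' @param size pool size; defaults to `config$decoy_pool_size`.
#' @return bit matrix like [generate_ligands()], rownames = decoy ids.
#' @export
generate_decoy_pool <- function(config, exclude = character(),
                                size = config$decoy_pool_size) {
  validate_sim_config(config)
  if (!is_count(size))
    pcm_stop("decoy pool size must be a positive integer",
             "pcm_config_error")
  pool <- make_bit_library(size, config$n_bits, config$n_clusters,
                           config$p_on, config$p_bg, "DEC",
                           derive_seed(config$seed, "decoys"))
  if (any(rownames(pool) %in% exclude))
    pcm_stop("decoy pool overlaps excluded ligand ids", "pcm_config_error")
  pool
}

#' Generate a synthetic bioactivity table with known signal structure
#'
#' Samples `records_per_kinase` ligands per kinase and assigns
#' `pX = baseline + eta + noise`, where the structure of `eta` is dictated
#' by the configured regime:
#' \describe{
#'   \item{null}{`eta = 0`: labels are independent of all features.}
#'   \item{ligand_only}{per-cluster ligand effects, sd `beta_ligand`.}
#'   \item{protein_only}{per-family effects, sd `beta_protein`.}
#'   \item{interaction}{family x cluster plus kinase x cluster effects,
#'     each with variance `beta_interaction^2 / 2`. The kinase-level
#'     component is what distinguishes a random from a kinase-grouped
#'     split; the family-level component distinguishes a kinase-grouped
#'     from a family-grouped split.}
#' }
#' The baseline is calibrated (empirical quantile of `eta + noise`) so the
#' fraction of records with pX >= 6 approximates `active_fraction`.
#'
#' @param kinases an [aligned_msa] or a data.frame with columns
#'   `kinase_id`, `family`.
#' @param ligands ligand bit matrix from [generate_ligands()] (its
#'   `cluster` attribute supplies the latent ground truth).
#' @param config a [sim_config()].
#' @return data.frame of activity records (kinase_id, family, ligand_id,
#'   measurement_type, value, unit, pX, label, provenance) with a
#'   `ground_truth` attribute recording the regime, betas, baseline and
#'   sampled effects.
#' @export
generate_activities <- function(kinases, ligands, config) {
  validate_sim_config(config)
  if (inherits(kinases, "aligned_msa"))
    kinases <- data.frame(kinase_id = kinases$ids, family = kinases$family,
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(kinases), nrow(kinases) > 0, nrow(ligands) > 0)
  cl <- attr(ligands, "cluster")
  if (is.null(cl))
    pcm_stop("'ligands' must carry a cluster attribute", "pcm_config_error")
  n_cl <- max(cl)
  fams <- unique(kinases$family)
  withr::with_seed(derive_seed(config$seed, "activities"), {
    per_k <- min(config$records_per_kinase, nrow(ligands))
    rec <- do.call(rbind, lapply(seq_len(nrow(kinases)), function(i) {
      data.frame(kinase_id = kinases$kinase_id[i], family = kinases$family[i],
                 ligand_id = rownames(ligands)[sample.int(nrow(ligands),
                                                          per_k)],
                 stringsAsFactors = FALSE)
    }))
    fi <- match(rec$family, fams)
    ki <- match(rec$kinase_id, kinases$kinase_id)
    ci <- cl[rec$ligand_id]
    eff <- list()
    eta <- numeric(nrow(rec))
    if (config$regime == "ligand_only") {
      eff$cluster <- stats::rnorm(n_cl, sd = config$beta_ligand)
      eta <- eff$cluster[ci]
    } else if (config$regime == "protein_only") {
      eff$family <- stats::rnorm(length(fams), sd = config$beta_protein)
      eta <- eff$family[fi]
    } else if (config$regime == "interaction") {
      s <- config$beta_interaction / sqrt(2)
      eff$family_cluster <- matrix(stats::rnorm(length(fams) * n_cl, sd = s),
                                   nrow = length(fams))
      eff$kinase_cluster <- matrix(
        stats::rnorm(nrow(kinases) * n_cl, sd = s), nrow = nrow(kinases))
      eta <- eff$family_cluster[cbind(fi, ci)] +
        eff$kinase_cluster[cbind(ki, ci)]
    }
    eps <- stats::rnorm(nrow(rec), sd = config$noise_sd)
    baseline <- 6 - stats::quantile(eta + eps, 1 - config$active_fraction,
                                    names = FALSE)
    pX <- baseline + eta + eps
    units <- sample(c("M", "uM", "nM"), nrow(rec), replace = TRUE)
    rec$measurement_type <- sample(c("Kd", "Ki", "IC50"), nrow(rec),
                                   replace = TRUE)
    rec$value <- 10^(-pX) / unname(UNIT_FACTORS[units])
    rec$unit <- units
    rec$pX <- pX
    rec$label <- as.integer(pX >= 6)
    rec$provenance <- "measured"
    rownames(rec) <- NULL
    attr(rec, "ground_truth") <- list(
      regime = config$regime, baseline = baseline,
      betas = c(ligand = config$beta_ligand, protein = config$beta_protein,
                interaction = config$beta_interaction),
      effects = eff, ligand_cluster = cl, threshold = 6)
    rec
  })
}
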