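# shared fixtures and independent brute-force oracles

# small, fast study configuration used throughout the suite
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_families = 6, seqs_per_family = 3, n_columns = 60, embed_dim = 8,
         n_ligands = 200, n_bits = 64, n_clusters = 4,
         records_per_kinase = 40, seed = 1),
    list(...))
  do.call(sim_config, args)
}

# generate a complete small study: msa, embeddings, ligands, decoys, records
# and a pooled protein feature matrix
tiny_study <- function(cfg = tiny_cfg()) {
  msa <- generate_msa(cfg)
  emb <- generate_embeddings(msa, cfg)
  lig <- generate_ligands(cfg)
  dec <- generate_decoy_pool(cfg, exclude = rownames(lig))
  rec <- generate_activities(msa, lig, cfg)
  pooled <- do.call(rbind, lapply(msa$ids, function(k)
    as.numeric(mean_aggregate(emb[[k]]))))
  rownames(pooled) <- msa$ids
  list(cfg = cfg, msa = msa, emb = emb, lig = lig, dec = dec, rec = rec,
       pooled = pooled)
}

# minimal activity record table
make_records <- function(kinase_id, family, ligand_id, pX,
                         label = as.integer(pX >= 6)) {
  data.frame(kinase_id = kinase_id, family = family, ligand_id = ligand_id,
             measurement_type = "IC50", value = 10^(-pX), unit = "M",
             pX = pX, label = label, provenance = "measured",
             stringsAsFactors = FALSE)
}

# O(n^2) pairwise-comparison AUROC (ties count 1/2)
oracle_auroc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# contingency-table metric oracle
oracle_confusion <- function(y, s, thr = 0.5) {
  pred <- as.integer(s >= thr)
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  list(f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
       recall = if (tp + fn == 0) 0 else tp / (tp + fn),
       mcc = {
         d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
         if (d == 0) 0 else (tp * tn - fp * fn) / sqrt(d)
       })
}

# column-by-column rebuild oracle for trimming
oracle_trim <- function(padded, msa, threshold) {
  gf <- column_gap_fraction(msa)
  keep <- which(gf <= threshold)
  lapply(padded, function(m) {
    out <- matrix(NA_real_, nrow = length(keep), ncol = ncol(m))
    for (i in seq_along(keep)) out[i, ] <- m[keep[i], ]
    out
  })
}

# group-means sums-of-squares oracle for a balanced additive two-factor design
oracle_balanced_anova_F <- function(y, A, B) {
  n <- length(y); a <- nlevels(A); b <- nlevels(B)
  grand <- mean(y)
  ss_a <- sum(tapply(y, A, length) * (tapply(y, A, mean) - grand)^2)
  ss_b <- sum(tapply(y, B, length) * (tapply(y, B, mean) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_a - ss_b
  df_res <- n - 1 - (a - 1) - (b - 1)
  c(F_A = (ss_a / (a - 1)) / (ss_res / df_res),
    F_B = (ss_b / (b - 1)) / (ss_res / df_res))
}
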