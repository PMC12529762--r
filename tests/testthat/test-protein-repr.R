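test_that("padding inserts zero rows exactly at gap positions", {
  raw <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE)
  padded <- pad_embedding(raw, "A-C", id = "k1")
  expect_equal(unclass(padded),
               matrix(c(1, 2, 0, 0, 3, 4), nrow = 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(attr(padded, "form"), "padded")
  # a gap-free row is the identity
  expect_equal(unclass(pad_embedding(raw, "AC")), raw, ignore_attr = TRUE)
  # round trip: dropping the gap rows recovers the raw matrix exactly
  msa <- generate_msa(tiny_cfg(seed = 9))
  emb <- generate_embeddings(msa, tiny_cfg(seed = 9))
  k <- msa$ids[5]
  p <- pad_embedding(emb[[k]], msa, k)
  expect_equal(unclass(p)[!msa_gap_mask(msa, k), ], unclass(emb[[k]]),
               ignore_attr = TRUE)
})

test_that("padding rejects a row-count / sequence-length mismatch", {
  expect_error(pad_embedding(matrix(0, 3, 2), "A-C"),
               class = "pcm_alignment_error")
})

test_that("column gap fractions are simple counting", {
  msa <- aligned_msa(paste0("k", 1:4), rep("f", 4),
                     c("A-A-", "A-A-", "AAA-", "A---"))
  expect_equal(column_gap_fraction(msa), c(0, 0.75, 0.25, 1))
})

test_that("trimming removes columns strictly above the threshold", {
  # 20 rows; column 2 has gap fraction exactly 0.95, column 3 exactly 1
  seqs <- c(rep("A--", 19), "AA-")
  msa <- aligned_msa(paste0("k", 1:20), rep("f", 20), seqs)
  expect_equal(column_gap_fraction(msa), c(0, 0.95, 1))
  raw <- lapply(msa$ids, function(k)
    matrix(stats::rnorm(2 * sum(!msa_gap_mask(msa, k))), ncol = 2))
  names(raw) <- msa$ids
  padded <- lapply(msa$ids, function(k) pad_embedding(raw[[k]], msa, k))
  names(padded) <- msa$ids
  tr <- trim_columns(padded, msa, threshold = 0.95)
  expect_equal(tr$retained_columns, c(1L, 2L))  # 0.95 retained, 1.0 removed
  expect_equal(nrow(tr$embeddings[[1]]), 2L)
})

test_that("trimming equals the column-by-column rebuild oracle exactly", {
  cfg <- tiny_cfg(seed = 13)
  msa <- generate_msa(cfg)
  emb <- generate_embeddings(msa, cfg)
  padded <- lapply(msa$ids, function(k) pad_embedding(emb[[k]], msa, k))
  names(padded) <- msa$ids
  for (thr in c(0.5, 0.95)) {
    got <- trim_columns(padded, msa, thr)
    want <- oracle_trim(padded, msa, thr)
    for (k in msa$ids)
      expect_identical(unclass(got$embeddings[[k]])[, ], want[[k]][, ])
  }
})

test_that("for a gap-free MSA raw, padded and trimmed coincide", {
  cfg <- tiny_cfg(gap_profile = "none", seed = 2)
  msa <- generate_msa(cfg)
  emb <- generate_embeddings(msa, cfg)
  padded <- lapply(msa$ids, function(k) pad_embedding(emb[[k]], msa, k))
  names(padded) <- msa$ids
  tr <- trim_columns(padded, msa)
  expect_equal(tr$retained_columns, seq_len(msa$n_columns))
  k <- msa$ids[1]
  expect_equal(unclass(padded[[k]])[, ], unclass(emb[[k]])[, ])
  expect_equal(unclass(tr$embeddings[[k]])[, ], unclass(emb[[k]])[, ])
})

test_that("trimming rejects matrices padded against a different width", {
  msa <- aligned_msa(c("k1", "k2"), c("f", "f"), c("AC-", "A-C"))
  bad <- list(k1 = embedding_matrix(matrix(0, 4, 2), "k1", "padded"),
              k2 = embedding_matrix(matrix(0, 3, 2), "k2", "padded"))
  expect_error(trim_columns(bad, msa), class = "pcm_consistency_error")
})

test_that("mean aggregation is the column mean, pad rows included", {
  m <- embedding_matrix(matrix(c(1, 2, 3, 4), 2, byrow = TRUE), "k", "padded")
  expect_equal(as.numeric(mean_aggregate(m)), c(2, 3))
  const <- embedding_matrix(matrix(5, 7, 384), "k", "padded")
  expect_length(as.numeric(mean_aggregate(const)), 384)
  expect_equal(as.numeric(mean_aggregate(const)), rep(5, 384))
  expect_error(mean_aggregate(embedding_matrix(matrix(0, 0, 3), "k")),
               class = "pcm_degenerate_error")
})

test_that("flattening is residue-major and invertible", {
  m <- embedding_matrix(matrix(1:6, nrow = 3, byrow = TRUE), "k", "padded")
  f <- flatten_embedding(m)
  expect_equal(as.numeric(f), 1:6)  # row 1's values first
  expect_equal(unflatten_embedding(f, 3, 2), unclass(m), ignore_attr = TRUE)
  one_row <- embedding_matrix(matrix(c(4, 5), 1), "k", "pooled")
  expect_equal(as.numeric(flatten_embedding(one_row)), c(4, 5))
  expect_error(flatten_embedding(embedding_matrix(matrix(0, 2, 2), "k",
                                                  "raw")),
               class = "pcm_form_error")
})

test_that("descriptor scale tables cover all 20 amino acids at the stated width", {
  widths <- c(zscale = 3L, tscale = 5L, stscale = 8L, physical = 2L,
              onehot = 21L)
  for (nm in names(widths)) {
    sc <- descriptor_scale(nm)
    expect_equal(sc$k, widths[[nm]])
    expect_true(all(c("A", "C", "W", "Y") %in% rownames(sc$table)))
    expect_equal(nrow(sc$table), if (nm == "onehot") 21L else 20L)
    expect_false(anyNA(sc$table))
  }
})

test_that("scale encodings have length k x gap-free columns", {
  # an alignment with exactly 151 gap-free columns out of 160
  row1 <- rep("A", 160); row1[1:9] <- "-"
  msa <- aligned_msa(c("k1", "k2"), c("f1", "f2"),
                     c(paste(row1, collapse = ""),
                       paste(rep("C", 160), collapse = "")))
  expect_length(encode_with_scale(msa, "zscale")[["k1"]], 453)
  expect_length(encode_with_scale(msa, "tscale")[["k1"]], 755)
  expect_length(encode_with_scale(msa, "stscale")[["k1"]], 1208)
  expect_length(encode_with_scale(msa, "physical")[["k1"]], 302)
  # one-hot runs over all columns with the gap as 21st symbol
  expect_length(encode_with_scale(msa, "onehot")[["k1"]], 21 * 160)
  one_col <- aligned_msa(c("a", "b"), c("f", "f"), c("A", "C"))
  expect_length(encode_with_scale(one_col, "tscale")[["a"]], 5)
})

test_that("scale encoding lengths hold over random alignments", {
  for (seed in 1:3) {
    msa <- generate_msa(tiny_cfg(n_columns = 40, seed = seed))
    n_gapfree <- sum(column_gap_fraction(msa) == 0)
    for (nm in c("zscale", "tscale", "stscale", "physical")) {
      v <- encode_with_scale(msa, nm)
      expect_true(all(lengths(v) == descriptor_scale(nm)$k * n_gapfree))
    }
    expect_true(all(lengths(encode_with_scale(msa, "onehot")) ==
                      21 * msa$n_columns))
  }
})

test_that("one-hot encodes the residue identity at each column", {
  msa <- aligned_msa(c("a", "b"), c("f", "f"), c("A-", "CC"))
  v <- encode_with_scale(msa, "onehot")
  tab <- descriptor_scale("onehot")$table
  expect_equal(v[["a"]], as.numeric(c(tab["A", ], tab["-", ])))
  expect_equal(v[["b"]], as.numeric(c(tab["C", ], tab["C", ])))
})

test_that("the composite-loss reduction compresses and trains", {
  cfg <- tiny_cfg(n_families = 2, seqs_per_family = 10, n_columns = 20,
                  gap_profile = "none", embed_dim = 4, family_signal = 10,
                  seed = 5)
  msa <- generate_msa(cfg)
  emb <- generate_embeddings(msa, cfg)
  red <- fit_reduction(emb, msa$family, latent_dim = 8, epochs = 150,
                       seed = 3)
  expect_equal(dim(red$latents), c(20L, 8L))
  expect_equal(ncol(red$log), 4L)
  # training reduces the composite loss
  expect_lte(red$log$total[nrow(red$log)], red$log$total[1])
  # the encoder reproduces the training latents
  expect_equal(red$encode(emb[[1]]), unname(red$latents[1, ]))
  # a linear probe on latents is at least as good as the mean-pooled
  # baseline, and strong in absolute terms
  pooled <- do.call(rbind, lapply(emb, colMeans))
  tr <- c(1:7, 11:17); te <- setdiff(1:20, tr)
  acc_lat <- centroid_probe_accuracy(red$latents[tr, ], msa$family[tr],
                                     red$latents[te, ], msa$family[te])
  acc_pool <- centroid_probe_accuracy(pooled[tr, ], msa$family[tr],
                                      pooled[te, ], msa$family[te])
  expect_gte(acc_lat, acc_pool)
  expect_gt(acc_lat, 0.9)
})

test_that("the reduction rejects degenerate setups", {
  m <- replicate(4, matrix(stats::rnorm(12), 3), simplify = FALSE)
  expect_error(fit_reduction(m, rep("f1", 4), latent_dim = 2),
               class = "pcm_degenerate_error")
  expect_error(fit_reduction(m, c("a", "a", "b", "b"), latent_dim = 12),
               class = "pcm_no_compression_error")
  bad <- m; bad[[2]] <- matrix(0, 2, 4)
  expect_error(fit_reduction(bad, c("a", "a", "b", "b"), latent_dim = 2),
               class = "pcm_consistency_error")
})

test_that("embedding containers round-trip through the text format", {
  cfg <- tiny_cfg(n_families = 2, seqs_per_family = 2, n_columns = 12,
                  embed_dim = 3, seed = 7)
  msa <- generate_msa(cfg)
  emb <- generate_embeddings(msa, cfg)
  dir <- withr::local_tempdir()
  write_embeddings(emb, dir)
  back <- read_embeddings(dir)
  expect_equal(names(back), names(emb))
  expect_equal(unclass(back[[1]])[, ], unclass(emb[[1]])[, ],
               tolerance = 1e-12)
})

test_that("MSA FASTA round-trips with family labels", {
  msa <- generate_msa(tiny_cfg(seed = 21))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_msa_fasta(msa, path)
  back <- read_msa_fasta(path)
  expect_identical(back$ids, msa$ids)
  expect_identical(back$family, msa$family)
  expect_identical(back$seqs, msa$seqs)
})
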