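test_that("a family split with k = family count tests one family per fold", {
  rec <- make_records(paste0("k", 1:30), rep(c("fA", "fB", "fC"), each = 10),
                      paste0("l", 1:30), stats::runif(30, 4, 8))
  plan <- make_split(rec, "family", k = 3, seed = 1)
  expect_equal(plan$k, 3L)
  for (f in 1:3)
    expect_length(unique(rec$family[plan$assignments == f]), 1)
  expect_setequal(unique(plan$assignments), 1:3)
})

test_that("kinase splits keep each kinase in exactly one fold", {
  st <- tiny_study(tiny_cfg(seed = 5))
  plan <- make_split(st$rec, "kinase", k = 5, seed = 2)
  folds_per_kinase <- vapply(split(plan$assignments, st$rec$kinase_id),
                             function(a) length(unique(a)), integer(1))
  expect_true(all(folds_per_kinase == 1L))
  # test-fold kinase sets are pairwise disjoint
  sets <- lapply(1:5, function(f)
    unique(st$rec$kinase_id[plan$assignments == f]))
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(sets[[i]], sets[[j]]), 0)
  expect_true(check_leakage(plan, st$rec))
})

test_that("random splits stratify the label within 2 percentage points", {
  rec <- make_records(paste0("k", 1:1000), "f", paste0("l", 1:1000),
                      c(stats::runif(200, 6.1, 9), stats::runif(800, 3, 5.9)))
  plan <- make_split(rec, "random", k = 5, seed = 3)
  for (f in 1:5) {
    frac <- mean(rec$label[plan$assignments == f])
    expect_gte(frac, 0.18); expect_lte(frac, 0.22)
  }
})

test_that("splits are deterministic and reject infeasible fold counts", {
  st <- tiny_study(tiny_cfg(seed = 6))
  p1 <- make_split(st$rec, "kinase", 5, seed = 9)
  p2 <- make_split(st$rec, "kinase", 5, seed = 9)
  expect_identical(p1$assignments, p2$assignments)
  expect_error(make_split(st$rec, "family", k = 10, seed = 1),
               class = "pcm_infeasible_error")
  expect_error(make_split(st$rec, "random", k = 1, seed = 1),
               class = "pcm_config_error")
})

test_that("the leakage checker catches a corrupted plan", {
  st <- tiny_study(tiny_cfg(seed = 7))
  plan <- make_split(st$rec, "family", 3, seed = 1)
  plan$assignments[1] <- (plan$assignments[1] %% 3L) + 1L
  expect_error(check_leakage(plan, st$rec), class = "pcm_leakage_error")
})

test_that("split plans serialize to CSV", {
  st <- tiny_study(tiny_cfg(seed = 8))
  plan <- make_split(st$rec, "kinase", 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_csv(plan, path)
  back <- read_split_csv(path)
  expect_equal(back$fold, plan$assignments)
  expect_equal(back$group, plan$group_key)
})

test_that("SNA tops kinases up to the 1:1 inactive:active ratio", {
  rec <- rbind(make_records(rep("kA", 14), "f", sprintf("l%02d", 1:14),
                            c(rep(7, 10), rep(4, 4))),
               make_records(rep("kB", 8), "f", sprintf("m%02d", 1:8),
                            c(rep(7, 3), rep(4, 5))))
  pool <- matrix(0L, 50, 8, dimnames = list(sprintf("DEC%03d", 1:50), NULL))
  out <- apply_sna(rec, pool, target_ratio = 1, seed = 1)
  added <- out[out$provenance == "sna_decoy", ]
  # kA: 10 actives, 4 inactives -> 6 decoys; kB: 3a/5i already balanced
  expect_equal(nrow(added), 6L)
  expect_true(all(added$kinase_id == "kA"))
  expect_true(all(added$label == 0L))
  expect_true(all(is.na(added$pX)))
  ratio <- with(out[out$kinase_id == "kA", ],
                sum(label == 0) / sum(label == 1))
  expect_equal(ratio, 1)
  # measured records are untouched; dropping decoys recovers the input
  expect_identical(out[out$provenance != "sna_decoy", ], rec)
  expect_equal(anyDuplicated(added$ligand_id), 0L)
})

test_that("SNA pool exhaustion errors by default and warns when asked", {
  rec <- make_records(rep("kA", 6), "f", sprintf("l%d", 1:6), rep(7, 6))
  pool <- matrix(0L, 2, 8, dimnames = list(c("DECa", "DECb"), NULL))
  expect_error(apply_sna(rec, pool, seed = 1),
               class = "pcm_pool_exhausted_error")
  expect_warning(out <- apply_sna(rec, pool, seed = 1,
                                  on_exhausted = "warn"), "exhausted")
  expect_equal(sum(out$provenance == "sna_decoy"), 2L)
})

test_that("SNA rejects pools that overlap the data set", {
  rec <- make_records("kA", "f", "l1", 7)
  pool <- matrix(0L, 2, 8, dimnames = list(c("l1", "DECb"), NULL))
  expect_error(apply_sna(rec, pool), class = "pcm_config_error")
})

test_that("block permutation preserves the multiset and the other block", {
  st <- tiny_study(tiny_cfg(seed = 11))
  d <- build_design(st$rec[1:60, ], st$pooled, st$lig)
  pcols <- d$blocks$protein; lcols <- d$blocks$ligand
  out <- permute_block(d, permutation_spec("protein", "train", seed = 4))
  expect_false(identical(out$X[, pcols], d$X[, pcols]))
  # same protein rows, just reassigned
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(out$X[, pcols]), key(d$X[, pcols]))
  expect_identical(out$X[, lcols], d$X[, lcols])
  expect_identical(out$y, d$y)
  # target = none is the identity
  expect_identical(permute_block(d, permutation_spec("none")), d)
  # label permutation preserves the label mean
  lab <- permute_block(d, permutation_spec("labels", "train", seed = 2))
  expect_equal(mean(lab$y), mean(d$y))
  expect_identical(lab$X, d$X)
})

test_that("phase-restricted permutation never touches the other rows", {
  st <- tiny_study(tiny_cfg(seed = 12))
  # take a record subset spanning many kinases so protein rows differ
  d <- build_design(st$rec[seq(1, 560, by = 7), ], st$pooled, st$lig)
  rows <- 1:40
  out <- permute_block(d, permutation_spec("protein", "train", seed = 5),
                       rows = rows)
  expect_identical(out$X[-rows, ], d$X[-rows, ])
  expect_false(identical(out$X[rows, d$blocks$protein],
                         d$X[rows, d$blocks$protein]))
})

test_that("the experiment grid enumerates cells and reruns identically", {
  st <- tiny_study(tiny_cfg(seed = 13))
  run <- function() run_experiment_grid(
    st$rec, list(pooled = st$pooled), st$lig,
    splits = c(random = 5, kinase = 5),
    permutations = list(permutation_spec("none"),
                        permutation_spec("protein", "train")),
    model_params = list(nrounds = 20, max_depth = 3, eta = 0.3), seed = 2)
  res <- run()
  expect_equal(nrow(res), 2 * 2 * 5)  # 2 splits x 2 permutations x 5 folds
  expect_true(all(is.na(res$error)))
  expect_true(all(res$f1 >= 0 & res$f1 <= 1))
  expect_true(all(res$mcc >= -1 & res$mcc <= 1))
  expect_true(all(res$pfi >= 0 & res$pfi <= 1))
  expect_identical(run(), res)
})

test_that("grid cell failures are recorded fail-soft, not thrown", {
  st <- tiny_study(tiny_cfg(seed = 14))
  broken <- st$pooled[-1, , drop = FALSE]  # one kinase missing
  res <- run_experiment_grid(
    st$rec, list(ok = st$pooled, broken = broken), st$lig,
    splits = c(random = 2),
    model_params = list(nrounds = 10, max_depth = 3, eta = 0.3), seed = 3)
  expect_equal(nrow(res), 4L)
  expect_true(all(is.na(res$error[res$embedding == "ok"])))
  expect_true(all(!is.na(res$error[res$embedding == "broken"])))
  expect_true(all(is.na(res$f1[res$embedding == "broken"])))
})

test_that("under the null regime the pipeline AUROC centres on 0.5", {
  aurocs <- vapply(1:20, function(seed) {
    st <- tiny_study(tiny_cfg(regime = "null", seed = seed))
    res <- run_experiment_grid(
      st$rec, list(pooled = st$pooled), st$lig, splits = c(random = 2),
      model_params = list(nrounds = 30, max_depth = 3, eta = 0.3),
      seed = seed)
    mean(res$auroc)
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
})
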