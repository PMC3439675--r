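test_that("bootstrap replicates have the right multiset structure", {
  set.seed(1)
  r <- draw_replicate(10L)
  expect_length(r$in_bag, 10L)
  expect_identical(r$oob, setdiff(1:10, r$in_bag))

  set.seed(123); r1 <- draw_replicate(50L)
  set.seed(123); r2 <- draw_replicate(50L)
  expect_identical(r1, r2)

  set.seed(1)
  r <- draw_replicate(1L)
  expect_identical(r$in_bag, 1L)
  expect_length(r$oob, 0L)
})

test_that("ranking puts a perfectly predictive SNP first and is stable on ties", {
  # SNP 2 separates the classes perfectly; SNPs 1 and 3 are constant
  G <- cbind(rep(1L, 8), c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L), rep(1L, 8))
  ds <- tiny_ds(G, rep(c("case", "control"), each = 4))
  rep_all <- list(in_bag = 1:8, oob = integer(0))
  rk <- rank_snps(ds, rep_all)
  expect_identical(rk$snp_index[1], 2L)
  expect_equal(rk$score[1], 1)

  # all-identical SNPs: every score ties, order falls back to genomic order
  ds2 <- tiny_ds(matrix(1L, 6, 4), rep(c("case", "control"), 3))
  rk2 <- rank_snps(ds2, list(in_bag = 1:6))
  expect_identical(rk2$snp_index, 1:4)
  expect_true(all(rk2$score == rk2$score[1]))

  # composition: ranking agrees with scoring each SNP independently
  set.seed(17)
  ds3 <- random_ds(60L, 50L, missing_rate = 0.02)
  set.seed(2); rep3 <- draw_replicate(60L)
  rk3 <- rank_snps(ds3, rep3)
  manual <- vapply(seq_len(50L), function(j) {
    nb_attribute_score(build_contingency_table(ds3, j, rep3$in_bag))$score
  }, 0)
  expect_equal(rk3$score, sort(manual, decreasing = TRUE), tolerance = 1e-12)
  expect_equal(manual[rk3$snp_index], rk3$score, tolerance = 1e-12)
})

test_that("squared correlation handles identity, mirror and degenerate pairs", {
  g1 <- c(0L, 1L, 2L, 0L, 1L, 2L)
  ds <- tiny_ds(cbind(g1, g1, 2L - g1, rep(1L, 6), c(0L, 1L, 2L, NA, NA, NA)),
                rep(c("case", "control"), 3))
  expect_equal(squared_correlation(ds, 1, 2), 1)
  expect_equal(squared_correlation(ds, 1, 3), 1)       # anticorrelated
  expect_equal(squared_correlation(ds, 1, 4), 0)       # constant SNP
  # hand-computed on a printed 6-subject pair
  x <- c(0, 1, 2, 0, 1, 1); y <- c(0, 1, 1, 0, 2, 1)
  ds2 <- tiny_ds(cbind(as.integer(x), as.integer(y)),
                 rep(c("case", "control"), 3))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(squared_correlation(ds2, 1, 2), r_hand^2, tolerance = 1e-12)
  # multiset weighting: repeating a subject changes the correlation
  expect_equal(squared_correlation(ds2, 1, 2, c(1:6, 3L)),
               cor(x[c(1:6, 3)], y[c(1:6, 3)])^2, tolerance = 1e-12)
})

test_that("a duplicated causal SNP 1 bp away never joins the same classifier", {
  set.seed(31)
  n <- 120L
  causal <- 2L - rbinom(n, 2L, 0.4)
  labels <- ifelse(runif(n) < c(0.9, 0.5, 0.1)[causal + 1L],
                   "case", "control")
  noise <- vapply(1:6, function(i) 2L - rbinom(n, 2L, 0.3), integer(n))
  G <- cbind(causal, causal, noise)
  ds <- tiny_ds(G, labels,
                pos = c(1000L, 1001L,
                        as.integer(seq(10e6, by = 10e6, length.out = 6))))
  set.seed(7); rep1 <- draw_replicate(n)
  model <- select_attributes(ds, rep1, bonb_params(B = 1L))
  expect_false(all(c(1L, 2L) %in% model$attributes))
  expect_true(any(c(1L, 2L) %in% model$attributes))
})

test_that("OOB acceptance keeps the causal SNP and rejects pure noise", {
  set.seed(97)
  n <- 200L
  causal <- 2L - rbinom(n, 2L, 0.4)
  labels <- ifelse(runif(n) < c(0.95, 0.5, 0.05)[causal + 1L],
                   "case", "control")
  noise <- vapply(1:20, function(i) 2L - rbinom(n, 2L, 0.3), integer(n))
  ds <- tiny_ds(cbind(causal, noise), labels,
                pos = as.integer(seq(1e6, by = 5e6, length.out = 21)))
  set.seed(11); rep1 <- draw_replicate(n)
  model <- select_attributes(ds, rep1, bonb_params(B = 1L))
  expect_true(1L %in% model$attributes)
  expect_gt(model$oob_mcc, 0.5)
  # the OOB MCC trace of accepted sets is strictly increasing
  expect_true(all(diff(model$oob_mcc_trace) > 0))
  # batch sizes follow the doubling schedule
  expect_identical(model$batch_sizes,
                   as.integer(2^(seq_along(model$batch_sizes) - 1)))
})

test_that("select_attributes demands a non-empty OOB set", {
  ds <- tiny_ds(cbind(c(0L, 2L)), c("case", "control"))
  expect_error(select_attributes(ds, list(in_bag = c(1L, 2L), oob = integer(0)),
                                 bonb_params(B = 1L)),
               "out-of-bag")
})

test_that("training composes replicate -> rank -> select and is deterministic", {
  set.seed(3)
  ds <- random_ds(80L, 12L)
  params <- bonb_params(B = 3L)

  ens1 <- bonb_train(ds, params, seed = 9L)
  ens2 <- bonb_train(ds, params, seed = 9L)
  expect_identical(ens1$replicates, ens2$replicates)
  expect_equal(ens1$classifiers, ens2$classifiers)

  # B = 1 equals a single select_attributes run on the same stream
  p1 <- bonb_params(B = 1L)
  ens3 <- bonb_train(ds, p1, seed = 4L)
  set.seed(4L)
  sub_seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(sub_seed)
  rep1 <- draw_replicate(80L)
  model <- select_attributes(ds, rep1, p1)
  expect_identical(ens3$replicates[[1]], rep1)
  expect_equal(ens3$classifiers[[1]], model)

  expect_error(bonb_train(tiny_ds(cbind(c(0L, 1L)), c("case", "case")),
                          params, 1L),
               "case and one control")
})

test_that("ensemble prediction averages posteriors and matches by snp_id", {
  set.seed(23)
  n <- 60L
  causal <- 2L - rbinom(n, 2L, 0.4)
  labels <- ifelse(runif(n) < c(0.95, 0.5, 0.05)[causal + 1L],
                   "case", "control")
  noise <- vapply(1:7, function(i) 2L - rbinom(n, 2L, 0.3), integer(n))
  ds <- tiny_ds(cbind(causal, noise), labels,
                pos = as.integer(seq(1e6, by = 5e6, length.out = 8L)))
  ens <- bonb_train(ds, bonb_params(B = 2L), seed = 2L)
  expect_gt(length(ens$classifiers[[1]]$attributes), 0L)
  pred <- predict_proba(ens, ds)
  expect_equal(pred$p_case + pred$p_control, rep(1, n), tolerance = 1e-12)

  manual <- (bonb:::nb_pcase_matrix(ens$classifiers[[1]], ds$genotypes) +
               bonb:::nb_pcase_matrix(ens$classifiers[[2]], ds$genotypes)) / 2
  expect_equal(pred$p_case, manual, tolerance = 1e-12)

  # column order must not matter: permute the SNP columns of the dataset
  perm <- sample(8L)
  ds_perm <- genotype_dataset(ds$genotypes[, perm],
                              ds$snps[perm, ], ds$labels, ds$subject_ids)
  pred_perm <- predict_proba(ens, ds_perm)
  expect_equal(pred_perm$p_case, pred$p_case, tolerance = 1e-12)

  # missing snp_id is a hard error naming the id
  keep <- setdiff(seq_len(8L), ens$classifiers[[1]]$attributes[1])
  ds_missing <- genotype_dataset(ds$genotypes[, keep], ds$snps[keep, ],
                                 ds$labels, ds$subject_ids)
  expect_error(predict_proba(ens, ds_missing),
               ens$classifiers[[1]]$snp_ids[1], fixed = TRUE)
})

test_that("ensemble JSON round trip preserves the trained artifact", {
  set.seed(29)
  ds <- random_ds(50L, 10L)
  ens <- bonb_train(ds, bonb_params(B = 2L), seed = 5L)
  path <- tempfile(fileext = ".json")
  write_bonb_json(ens, path)
  back <- bind_ensemble(read_bonb_json(path), ds)
  expect_identical(back$params, ens$params)
  expect_identical(back$replicates, ens$replicates)
  expect_equal(predict_proba(back, ds)$p_case,
               predict_proba(ens, ds)$p_case, tolerance = 1e-12)
})
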