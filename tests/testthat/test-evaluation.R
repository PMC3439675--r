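# Factories used across the harness tests.
majority_factory <- function(ds_train) {
  maj <- if (mean(ds_train$labels == "case") > 0.5) 1 else 0
  function(ds_test) rep(maj, n_subjects(ds_test))
}
oracle_factory <- function(ds_train) {
  function(ds_test) ifelse(ds_test$labels == "case", 1, 0)
}

test_that("sub-sampling CV brackets the majority and oracle factories", {
  set.seed(61)
  ds <- random_ds(120L, 4L)
  rep_maj <- subsample_cv(ds, majority_factory, repetitions = 5L, seed = 3L)
  expect_equal(rep_maj$metrics$mcc, rep(0, 5L))
  expect_equal(rep_maj$mean_mcc, 0)
  # accuracy of the majority classifier = larger-class fraction of the split
  expect_equal(rep_maj$mean_accuracy, rep_maj$majority_accuracy,
               tolerance = 1e-12)

  rep_orc <- subsample_cv(ds, oracle_factory, repetitions = 5L, seed = 3L)
  expect_equal(rep_orc$metrics$mcc, rep(1, 5L))
  expect_equal(rep_orc$mean_accuracy, 1)

  # reproducibility of a deterministic factory under a fixed seed
  rep_maj2 <- subsample_cv(ds, majority_factory, repetitions = 5L, seed = 3L)
  expect_equal(rep_maj$metrics, rep_maj2$metrics)

  expect_error(subsample_cv(tiny_ds(cbind(c(0L, 2L)), c("case", "control")),
                            majority_factory, seed = 1L),
               "test set")
})

test_that("splits are stratified and sized by the test fraction", {
  set.seed(71)
  ds <- random_ds(100L, 3L)
  n_ca <- sum(ds$labels == "case"); n_co <- sum(ds$labels == "control")
  seen <- new.env()
  probe_factory <- function(ds_train) {
    tr_ca <- sum(ds_train$labels == "case")
    assign("train_cases", c(mget("train_cases", envir = seen,
                                 ifnotfound = list(integer(0)))[[1]], tr_ca),
           envir = seen)
    function(ds_test) rep(0, n_subjects(ds_test))
  }
  subsample_cv(ds, probe_factory, repetitions = 4L, seed = 9L)
  expect_true(all(get("train_cases", envir = seen) ==
                    n_ca - round(0.1 * n_ca)))
})

test_that("PR/ROC sweeps behave at the perfect, random and flipped extremes", {
  y <- rep(c("case", "control"), each = 100L)
  perfect <- c(runif(100, 0.6, 1), runif(100, 0, 0.4))
  cv <- pr_roc_curves(y, perfect)
  expect_true(any(cv$roc$tpr == 1 & cv$roc$tnr == 1))
  expect_true(all(diff(cv$roc$tpr) <= 0))      # monotone over the sweep

  set.seed(5)
  y2 <- rep(c("case", "control"), 1000L)
  rand <- runif(2000)
  expect_lt(abs(roc_auc(pr_roc_curves(y2, rand)) - 0.5), 0.1)

  # flip symmetry: reversing scores and labels together yields the PR curve
  # of the control class, i.e. the point set derivable from the original
  # sweep's confusion counts with the classes swapped (distinct scores)
  set.seed(6)
  scores <- runif(200)
  flip_y <- ifelse(y == "case", "control", "case")
  pr_flip <- pr_roc_curves(flip_y, 1 - scores)$pr
  derived <- lapply(c(sort(unique(scores)), Inf), function(t) {
    pred <- ifelse(scores >= t, "case", "control")
    cc <- confusion_counts(y, pred)
    c(recall = cc[["tn"]] / (cc[["tn"]] + cc[["fp"]]),
      precision = if (cc[["tn"]] + cc[["fn"]] > 0) {
        cc[["tn"]] / (cc[["tn"]] + cc[["fn"]])
      } else 1)
  })
  key_a <- sort(paste(round(pr_flip$recall, 9), round(pr_flip$precision, 9)))
  key_b <- sort(unique(paste(round(vapply(derived, `[[`, 0, "recall"), 9),
                             round(vapply(derived, `[[`, 0, "precision"), 9))))
  expect_setequal(key_a, key_b)

  expect_error(pr_roc_curves(rep("case", 5), runif(5)), "control")
})

test_that("PR/ROC points match a direct confusion-count recomputation", {
  set.seed(15)
  y <- sample(c("case", "control"), 60, replace = TRUE)
  y[1:2] <- c("case", "control")
  s <- round(runif(60), 2)                    # force ties in the scores
  cv <- pr_roc_curves(y, s)
  for (i in seq_along(cv$roc$threshold)) {
    t <- cv$roc$threshold[i]
    pred <- ifelse(s >= t, "case", "control")
    cc <- confusion_counts(y, pred)
    expect_equal(cv$roc$tpr[i], cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]),
                 tolerance = 1e-10)
    expect_equal(cv$roc$tnr[i], cc[["tn"]] / (cc[["tn"]] + cc[["fp"]]),
                 tolerance = 1e-10)
  }
})

test_that("the chi-squared-filtered baseline composes as specified", {
  # penetrance moderate enough that every contingency cell reaches 5, so
  # the applicability gate does not exclude the causal SNP
  set.seed(81)
  n <- 400L
  causal <- 2L - rbinom(n, 2L, 0.4)
  labels <- ifelse(runif(n) < c(0.85, 0.5, 0.15)[causal + 1L],
                   "case", "control")
  noise <- vapply(1:10, function(i) 2L - rbinom(n, 2L, 0.3), integer(n))
  ds <- tiny_ds(cbind(causal, noise), labels,
                pos = as.integer(seq(1e6, by = 5e6, length.out = 11L)))
  out <- standard_nb_baseline(ds, ds)
  expect_identical(out$snp_ids, "snp1")
  expect_identical(out$model$snp_ids, "snp1")
  cc <- confusion_counts(ds$labels, ifelse(out$p_case > 0.5,
                                           "case", "control"))
  expect_gt(mcc(cc), 0.3)

  # null dataset: no significant SNP, majority fallback with MCC 0
  set.seed(82)
  ds_null <- random_ds(100L, 10L)
  expect_message(out_null <- standard_nb_baseline(ds_null, ds_null),
                 "majority")
  expect_length(out_null$snp_ids, 0L)
  pred <- ifelse(out_null$p_case > 0.5, "case", "control")
  expect_equal(mcc(confusion_counts(ds_null$labels, pred)), 0)

  # chi2 p-value matches an independent survival-function computation
  set.seed(83)
  for (i in 1:20) {
    tab <- random_table(40L)
    if (tab$n_ca == 0 || tab$n_co == 0) next
    res <- chi2_general_2df(tab)
    expect_equal(res$p_value, pchisq(res$statistic, 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("parameter sweep tidies the grid and tests across groups", {
  set.seed(91)
  ds <- random_ds(60L, 8L)
  sw <- parameter_sweep(ds, B_grid = c(2L, 3L), theta_grid = c(0.1, 0.5),
                        repetitions = 2L, seed = 1L)
  expect_identical(nrow(sw$results), 2L * 2L * 2L)
  expect_true(!is.na(sw$kruskal_p))

  # single-cell grid reduces to subsample_cv with the bonb factory
  sw1 <- parameter_sweep(ds, B_grid = 2L, theta_grid = 0.1,
                         repetitions = 2L, seed = 1L)
  direct <- subsample_cv(ds, bonb_factory(bonb_params(B = 2L), 1L),
                         repetitions = 2L, seed = 1L)
  expect_equal(sw1$results$mcc, direct$metrics$mcc)
  expect_true(is.na(sw1$kruskal_p))
})
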