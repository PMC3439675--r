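# Experimental harness: repeated random sub-sampling cross-validation,
# MCC/accuracy summaries, precision-recall and ROC curves, the
# chi-squared-filtered standard Naive Bayes baseline, and parameter sweeps.

#' Repeated random sub-sampling cross-validation
#'
#' Repeatedly holds out a random test fraction (stratified by class so every
#' split keeps both cases and controls), trains a model on the remainder
#' with `model_factory`, and scores the held-out predictions with MCC and
#' accuracy. PR/ROC curves are recorded for the first repetition.
#'
#' @param ds a [genotype_dataset]
#' @param model_factory `function(train_ds)` returning a predictor
#'   `function(test_ds)` that yields a numeric vector of `Pr(case)` per
#'   subject. See [bonb_factory()] and [standard_nb_baseline()].
#' @param repetitions number of random splits (default 10)
#' @param test_fraction held-out fraction (default 0.10)
#' @param seed integer seed; splits and training are reproducible given it
#' @return an `eval_report`: list with `metrics` (data.frame repetition /
#'   mcc / accuracy), `mean_mcc`, `sd_mcc`, `mean_accuracy`, `sd_accuracy`,
#'   `majority_mcc` (exactly 0), `majority_accuracy` (mean larger-class test
#'   fraction), `curves` (PR/ROC points of repetition 1)
#' @export
subsample_cv <- function(ds, model_factory, repetitions = 10L,
                         test_fraction = 0.10, seed = 1L) {
  n <- n_subjects(ds)
  ca_idx <- which(ds$labels == "case")
  co_idx <- which(ds$labels == "control")
  n_test_ca <- round(test_fraction * length(ca_idx))
  n_test_co <- round(test_fraction * length(co_idx))
  if (n_test_ca + n_test_co < 1L) {
    stop("n too small for a non-empty test set at test_fraction = ",
         test_fraction)
  }
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, repetitions)

  res <- vector("list", repetitions)
  curves1 <- NULL
  maj_acc <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    test_idx <- sort(c(sample(ca_idx, n_test_ca),
                       sample(co_idx, n_test_co)))
    train_idx <- setdiff(seq_len(n), test_idx)
    ds_train <- subset_subjects(ds, train_idx)
    ds_test <- subset_subjects(ds, test_idx)
    predictor <- model_factory(ds_train)
    p_case <- predictor(ds_test)
    pred <- ifelse(p_case > 0.5, "case", "control")
    cc <- confusion_counts(ds_test$labels, pred)
    res[[r]] <- data.frame(
      repetition = r,
      mcc = mcc(cc),
      accuracy = (cc["tp"] + cc["tn"]) / sum(cc)
    )
    maj_acc[r] <- max(mean(ds_test$labels == "case"),
                      mean(ds_test$labels == "control"))
    if (r == 1L) curves1 <- pr_roc_curves(ds_test$labels, p_case)
  }
  metrics <- do.call(rbind, res)
  rownames(metrics) <- NULL
  structure(
    list(metrics = metrics,
         mean_mcc = mean(metrics$mcc), sd_mcc = sd(metrics$mcc),
         mean_accuracy = mean(metrics$accuracy),
         sd_accuracy = sd(metrics$accuracy),
         majority_mcc = 0, majority_accuracy = mean(maj_acc),
         curves = curves1),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("MCC %.3f +/- %.3f | accuracy %.3f +/- %.3f (%d repetitions)\n",
              x$mean_mcc, x$sd_mcc, x$mean_accuracy, x$sd_accuracy,
              nrow(x$metrics)))
  cat(sprintf("majority baseline: MCC %.1f, accuracy %.3f\n",
              x$majority_mcc, x$majority_accuracy))
  invisible(x)
}

#' Model factory for the bagged ensemble
#'
#' Adapter making [bonb_train()] usable with [subsample_cv()] /
#' [parameter_sweep()].
#'
#' @param params a [bonb_params()]
#' @param seed training seed
#' @return a `model_factory` function
#' @export
bonb_factory <- function(params = bonb_params(), seed = 1L) {
  force(params); force(seed)
  function(ds_train) {
    ens <- bonb_train(ds_train, params, seed)
    function(ds_test) predict_proba(ens, ds_test)$p_case
  }
}

#' Precision-recall and ROC curve points
#'
#' Sweeps the decision threshold over the distinct score values (predict
#' case iff `p_case >= threshold`). Case is the positive class. ROC points
#' carry both TNR (the specificity axis used alongside TPR) and FPR.
#'
#' @param y_true factor/character over `{case, control}`, both present
#' @param p_case numeric scores
#' @return list with data.frames `pr` (threshold, recall, precision) and
#'   `roc` (threshold, tpr, tnr, fpr)
#' @export
pr_roc_curves <- function(y_true, p_case) {
  y <- as.character(y_true)
  n_ca <- sum(y == "case"); n_co <- sum(y == "control")
  if (n_ca == 0L || n_co == 0L) {
    stop("curves need at least one case and one control")
  }
  thr <- c(sort(unique(p_case)), Inf)
  pts <- lapply(thr, function(t) {
    pred_case <- p_case >= t
    tp <- sum(pred_case & y == "case")
    fp <- sum(pred_case & y == "control")
    c(tp = tp, fp = fp)
  })
  tp <- vapply(pts, `[[`, 0, "tp")
  fp <- vapply(pts, `[[`, 0, "fp")
  recall <- tp / n_ca
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  tnr <- (n_co - fp) / n_co
  list(
    pr = data.frame(threshold = thr, recall = recall, precision = precision),
    roc = data.frame(threshold = thr, tpr = recall, tnr = tnr, fpr = 1 - tnr)
  )
}

#' Area under the ROC curve (trapezoidal, FPR axis)
#'
#' @param curves output of [pr_roc_curves()]
#' @return numeric in `[0, 1]`
#' @export
roc_auc <- function(curves) {
  ord <- order(curves$roc$fpr, curves$roc$tpr)
  x <- curves$roc$fpr[ord]; y <- curves$roc$tpr[ord]
  x <- c(0, x, 1); y <- c(0, y, 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Standard Naive Bayes baseline on genome-wide-significant SNPs
#'
#' The univariate-test comparator: selects the SNPs whose 2-df chi-squared
#' test is applicable (all cells >= 5) and reaches `alpha_gw` on the
#' training split, trains a single Naive Bayes classifier on them, and
#' predicts the test split. If no SNP passes, falls back to majority
#' classification (prior only) with a message.
#'
#' @param ds_train,ds_test [genotype_dataset]s sharing snp_ids (or pass
#'   `ds_test = NULL` to get the predictor function)
#' @param alpha_gw genome-wide significance threshold (default 5e-7)
#' @param l Dirichlet weight (default 1)
#' @return list with `p_case` (numeric per test subject), `snp_ids` used,
#'   `model`; or, with `ds_test = NULL`, a predictor function
#' @export
standard_nb_baseline <- function(ds_train, ds_test = NULL, alpha_gw = 5e-7,
                                 l = 1) {
  st <- score_table(ds_train)
  sig <- which(st$applicable & st$chi2_p < alpha_gw)
  if (length(sig) == 0L) {
    message("no SNP reaches genome-wide significance; ",
            "baseline falls back to majority classification")
  }
  model <- train_nb(ds_train, sig, l = l)
  predictor <- function(dst) {
    cols <- match(model$snp_ids, dst$snps$snp_id)
    if (anyNA(cols)) {
      stop("test dataset lacks SNPs required by the baseline: ",
           paste(model$snp_ids[is.na(cols)], collapse = ", "))
    }
    nb_pcase_matrix(model, dst$genotypes, columns = cols)
  }
  if (is.null(ds_test)) return(predictor)
  list(p_case = predictor(ds_test), snp_ids = st$snp_id[sig], model = model)
}

#' Model factory for the baseline
#'
#' @inheritParams standard_nb_baseline
#' @return a `model_factory` function for [subsample_cv()]
#' @export
standard_nb_factory <- function(alpha_gw = 5e-7, l = 1) {
  force(alpha_gw); force(l)
  function(ds_train) standard_nb_baseline(ds_train, NULL, alpha_gw, l)
}

#' Sensitivity sweep over ensemble size and correlation threshold
#'
#' Runs [subsample_cv()] with the bagged ensemble for every combination of
#' `B_grid` x `theta_grid` and reports the per-repetition MCCs in tidy form
#' together with a Kruskal-Wallis test of MCC across the parameter groups
#' (a flat profile gives a large p, i.e. low sensitivity).
#'
#' @param ds a [genotype_dataset]
#' @param B_grid,theta_grid parameter grids
#' @param repetitions sub-sampling repetitions per cell (default 10)
#' @param seed integer seed (shared across cells, so splits are paired)
#' @param base_params parameter template for fields other than B/theta
#' @return list with `results` (data.frame B, theta, repetition, mcc,
#'   accuracy) and `kruskal_p`
#' @export
parameter_sweep <- function(ds, B_grid = c(50L, 200L),
                            theta_grid = 0.1, repetitions = 10L,
                            seed = 1L, base_params = bonb_params()) {
  stopifnot(length(B_grid) >= 1L, length(theta_grid) >= 1L)
  grid <- expand.grid(B = B_grid, theta = theta_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    params <- base_params
    params$B <- as.integer(grid$B[i])
    params$theta <- grid$theta[i]
    rep_out <- subsample_cv(ds, bonb_factory(params, seed),
                            repetitions = repetitions, seed = seed)
    data.frame(B = grid$B[i], theta = grid$theta[i],
               repetition = rep_out$metrics$repetition,
               mcc = rep_out$metrics$mcc,
               accuracy = rep_out$metrics$accuracy)
  })
  results <- do.call(rbind, rows)
  group <- interaction(results$B, results$theta, drop = TRUE)
  kruskal_p <- if (nlevels(group) > 1L) {
    kruskal.test(results$mcc, group)$p.value
  } else NA_real_
  list(results = results, kruskal_p = kruskal_p)
}
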