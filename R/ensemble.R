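# The bagged training engine: bootstrap replicates, per-replicate attribute
# ranking by the closed-form score, linkage-aware selection with an
# exponentially doubling batch schedule stopped by the out-of-bag MCC, and
# ensemble prediction by posterior averaging.

#' Ensemble training parameters
#'
#' @param B number of bootstrap replicates / classifiers (default 200)
#' @param theta squared-correlation threshold above which two nearby SNPs are
#'   considered linked and the lower-ranked one pruned (default 0.1)
#' @param l Dirichlet weight for all Naive Bayes estimates (default 1,
#'   Laplace smoothing)
#' @param ld_window_bp physical window for the pruning rule: only
#'   same-chromosome pairs closer than this are ever pruned (default 1 Mb)
#' @param inclusion_fraction minimum fraction of classifiers that must
#'   include a SNP for it to become a biomarker candidate (default 0.05)
#' @param alpha significance level of the marginal-utility Wilcoxon test
#'   (default 0.05)
#' @param r2_on how to compute the pruning r-squared: on the in-bag multiset
#'   (`"inbag"`, default -- the data the classifier sees) or on the full
#'   training set (`"full"`)
#' @return a `bonb_params` list
#' @export
bonb_params <- function(B = 200L, theta = 0.1, l = 1,
                        ld_window_bp = 1000000L,
                        inclusion_fraction = 0.05, alpha = 0.05,
                        r2_on = c("inbag", "full")) {
  stopifnot(B >= 1L, theta > 0, theta <= 1, l > 0, ld_window_bp >= 1L,
            inclusion_fraction >= 0, inclusion_fraction <= 1,
            alpha > 0, alpha < 1)
  structure(
    list(B = as.integer(B), theta = as.numeric(theta), l = as.numeric(l),
         ld_window_bp = as.integer(ld_window_bp),
         inclusion_fraction = as.numeric(inclusion_fraction),
         alpha = as.numeric(alpha),
         r2_on = match.arg(r2_on)),
    class = "bonb_params"
  )
}

#' Draw a bootstrap replicate
#'
#' `n` uniform draws with replacement; the out-of-bag (OOB) set is the
#' complement of the drawn support. The expected OOB fraction is
#' `(1 - 1/n)^n`, tending to `1/e` (about 0.368) for large `n`.
#'
#' @param n number of subjects
#' @return list with `in_bag` (integer multiset of length `n`, sorted) and
#'   `oob` (sorted integer vector, possibly empty for tiny `n`)
#' @export
draw_replicate <- function(n) {
  in_bag <- sort(sample.int(n, n, replace = TRUE))
  list(in_bag = in_bag, oob = setdiff(seq_len(n), in_bag))
}

#' Rank all SNPs of a replicate by attribute score
#'
#' Contingency tables are built on the in-bag multiset (repeats count) and
#' scored with the closed form ([nb_attribute_score()]); SNPs are sorted in
#' decreasing score order, ties broken by ascending (chromosome, position,
#' snp_id) so the ranking is deterministic.
#'
#' @param ds a [genotype_dataset]
#' @param rep a replicate from [draw_replicate()] (any list with `in_bag`)
#' @return data.frame with columns `snp_index`, `score`, in rank order
#' @export
rank_snps <- function(ds, rep) {
  A <- count_tables(ds, rep$in_bag)
  scores <- .score_mat(A)
  ord <- order(-scores, ds$snps$chromosome, ds$snps$position_bp,
               ds$snps$snp_id)
  data.frame(snp_index = ord, score = scores[ord])
}

#' Squared Pearson correlation between two SNPs
#'
#' Computed over the subjects of the multiset (with multiplicity) at which
#' BOTH genotypes are observed. If fewer than 2 usable subjects remain or
#' either SNP is constant on them, returns 0 (treated as uncorrelated).
#'
#' @param ds a [genotype_dataset]
#' @param snp_i,snp_j SNP column indices
#' @param subject_indices multiset of row indices (default: all)
#' @return numeric in `[0, 1]`
#' @export
squared_correlation <- function(ds, snp_i, snp_j,
                                subject_indices = seq_len(n_subjects(ds))) {
  x <- ds$genotypes[subject_indices, snp_i]
  y <- ds$genotypes[subject_indices, snp_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(0)
  x <- x[ok]; y <- y[ok]
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) return(0)
  r <- cor(x, y)
  r * r
}

# r^2 of one SNP against several, vectorized (hot path of LD pruning).
.r2_against <- function(G, i, js) {
  x <- G[, i]
  vapply(js, function(j) {
    y <- G[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) return(0)
    xs <- x[ok]; ys <- y[ok]
    if (sd(xs) == 0 || sd(ys) == 0) return(0)
    cor(xs, ys)^2
  }, 0)
}

#' Grow one classifier's attribute set from a ranked list
#'
#' Implements the doubling selection schedule: batches of size 1, 2, 4, 8,
#' ... are taken from the top of the still-eligible ranked list; after each
#' inclusion every remaining SNP on the same chromosome within
#' `ld_window_bp` and with in-bag `r^2 > theta` against the included SNP is
#' removed from eligibility. A candidate attribute set is accepted while its
#' OOB MCC strictly exceeds the incumbent's (the empty classifier counts as a
#' majority classifier with OOB MCC 0); the first non-improvement stops the
#' growth and the incumbent is returned. An exhausted eligible list evaluates
#' its partial final batch.
#'
#' (The prose pruning rule -- remove SNPs that are BOTH closer than the
#' window AND correlated above theta -- is the one implemented; the commonly
#' reprinted pseudocode inverts both comparisons, which would discard exactly
#' the independent SNPs the step is meant to keep.)
#'
#' @param ds a [genotype_dataset]
#' @param rep replicate from [draw_replicate()]
#' @param params a [bonb_params()]
#' @param ranked optional precomputed [rank_snps()] result
#' @return an `nb_classifier` (trained on the in-bag multiset) with extra
#'   fields `oob_mcc` (its OOB MCC), `oob_mcc_trace` (accepted-set trace,
#'   strictly increasing) and `batch_sizes` (the attempted batch sizes,
#'   1, 2, 4, ...)
#' @export
select_attributes <- function(ds, rep, params = bonb_params(),
                              ranked = rank_snps(ds, rep)) {
  if (length(rep$oob) == 0L) {
    stop("empty out-of-bag set: training needs more subjects (larger n)")
  }
  r2_rows <- if (params$r2_on == "inbag") rep$in_bag else seq_len(n_subjects(ds))
  Gr2 <- ds$genotypes[r2_rows, , drop = FALSE]
  chrom <- ds$snps$chromosome
  pos <- ds$snps$position_bp
  oob_y <- ds$labels[rep$oob]

  eligible <- ranked$snp_index        # in rank order; shrinks as we prune
  incumbent <- integer(0)
  incumbent_mcc <- 0                  # empty classifier = majority, MCC 0
  trace <- numeric(0)
  batch_sizes <- integer(0)
  M <- 1L

  oob_mcc_of <- function(attrs) {
    model <- train_nb(ds, attrs, rep$in_bag, params$l)
    p_case <- nb_pcase_matrix(model, ds$genotypes, rows = rep$oob)
    pred <- ifelse(p_case > 0.5, "case", "control")
    mcc(confusion_counts(oob_y, pred))
  }

  repeat {
    if (length(eligible) == 0L) break
    batch_sizes <- c(batch_sizes, M)
    batch <- integer(0)
    for (k in seq_len(M)) {
      if (length(eligible) == 0L) break
      s <- eligible[1L]
      eligible <- eligible[-1L]
      batch <- c(batch, s)
      # prune linked neighbours: same chromosome, < window, r^2 > theta
      near <- which(chrom[eligible] == chrom[s] &
                      abs(pos[eligible] - pos[s]) < params$ld_window_bp)
      if (length(near)) {
        r2 <- .r2_against(Gr2, s, eligible[near])
        drop <- near[r2 > params$theta]
        if (length(drop)) eligible <- eligible[-drop]
      }
    }
    exhausted <- length(eligible) == 0L
    candidate <- c(incumbent, batch)
    cand_mcc <- oob_mcc_of(candidate)
    if (cand_mcc > incumbent_mcc) {
      incumbent <- candidate
      incumbent_mcc <- cand_mcc
      trace <- c(trace, cand_mcc)
      if (exhausted) break
      M <- 2L * M
    } else {
      break
    }
  }

  model <- train_nb(ds, incumbent, rep$in_bag, params$l)
  model$oob_mcc <- incumbent_mcc
  model$oob_mcc_trace <- trace
  model$batch_sizes <- batch_sizes
  model
}

#' Train a Bag of Naive Bayes ensemble
#'
#' Runs `B` independent replicate -> rank -> select cycles. Each replicate
#' `b` uses its own RNG substream, derived deterministically from the master
#' seed before any training starts, so results are bit-reproducible and
#' independent of the order in which replicates are processed.
#'
#' @param ds a [genotype_dataset] with at least one case and one control
#' @param params a [bonb_params()]
#' @param seed master integer seed
#' @return a `bonb_ensemble`: list with `classifiers` (length-`B` list of
#'   `nb_classifier`), `replicates` (in-bag/OOB index sets), `params`,
#'   `seed`, `snp_ids` (training SNP universe)
#' @export
bonb_train <- function(ds, params = bonb_params(), seed = 1L) {
  if (nlevels(droplevels(ds$labels)) < 2L) {
    stop("training requires at least one case and one control")
  }
  n <- n_subjects(ds)
  if (n < 2L) stop("training requires n >= 2")
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, params$B)

  classifiers <- vector("list", params$B)
  replicates <- vector("list", params$B)
  for (b in seq_len(params$B)) {
    set.seed(sub_seeds[b])
    rep <- draw_replicate(n)
    replicates[[b]] <- rep
    classifiers[[b]] <- select_attributes(ds, rep, params)
  }
  structure(
    list(classifiers = classifiers, replicates = replicates,
         params = params, seed = as.integer(seed),
         sub_seeds = sub_seeds, snp_ids = ds$snps$snp_id),
    class = "bonb_ensemble"
  )
}

#' @export
print.bonb_ensemble <- function(x, ...) {
  sizes <- vapply(x$classifiers, function(m) length(m$snp_ids), 0L)
  cat("bonb_ensemble: B =", length(x$classifiers),
      "classifiers, theta =", x$params$theta, "\n")
  cat(sprintf("  attributes per classifier: mean %.2f (range %d-%d)\n",
              mean(sizes), min(sizes), max(sizes)))
  cat("  distinct SNPs used:",
      length(unique(unlist(lapply(x$classifiers, `[[`, "snp_ids")))), "\n")
  invisible(x)
}

#' Ensemble class probabilities
#'
#' The arithmetic mean of the `B` classifiers' posteriors. Attributes are
#' matched to the prediction dataset by `snp_id`, not column position.
#'
#' @param ens a `bonb_ensemble`
#' @param ds a [genotype_dataset] containing every SNP any classifier uses
#' @return data.frame with columns `subject_id`, `p_case`, `p_control`,
#'   `label` (argmax, ties to control)
#' @export
predict_proba <- function(ens, ds) {
  needed <- unique(unlist(lapply(ens$classifiers, `[[`, "snp_ids")))
  missing <- setdiff(needed, ds$snps$snp_id)
  if (length(missing)) {
    stop("dataset lacks SNPs required by the ensemble: ",
         paste(missing, collapse = ", "))
  }
  n <- n_subjects(ds)
  acc <- numeric(n)
  for (model in ens$classifiers) {
    cols <- match(model$snp_ids, ds$snps$snp_id)
    acc <- acc + nb_pcase_matrix(model, ds$genotypes, columns = cols)
  }
  p_case <- acc / length(ens$classifiers)
  data.frame(
    subject_id = ds$subject_ids,
    p_case = p_case,
    p_control = 1 - p_case,
    label = ifelse(p_case > 0.5, "case", "control"),
    stringsAsFactors = FALSE
  )
}

#' @export
predict.bonb_ensemble <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' Serialize / restore a trained ensemble as JSON
#'
#' Stores the classifiers (by snp_id, as in [write_nb_json()]), the
#' replicate index sets, the parameters and the master seed.
#'
#' @param ens a `bonb_ensemble`
#' @param path file path
#' @return `read_bonb_json` returns a `bonb_ensemble`
#' @export
write_bonb_json <- function(ens, path) {
  obj <- list(
    params = unclass(ens$params),
    seed = ens$seed,
    sub_seeds = ens$sub_seeds,
    snp_ids = ens$snp_ids,
    replicates = lapply(ens$replicates, function(r) {
      list(in_bag = r$in_bag, oob = r$oob)
    }),
    classifiers = lapply(ens$classifiers, function(m) {
      o <- nb_to_list(m)
      o$oob_mcc <- m$oob_mcc
      o$oob_mcc_trace <- m$oob_mcc_trace
      o$batch_sizes <- m$batch_sizes
      o
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(ens)
}

#' @rdname write_bonb_json
#' @export
read_bonb_json <- function(path) {
  obj <- jsonlite::read_json(path)
  params <- do.call(bonb_params, obj$params)
  classifiers <- lapply(obj$classifiers, function(o) {
    m <- nb_from_list(o)
    m$oob_mcc <- o$oob_mcc
    m$oob_mcc_trace <- as.numeric(unlist(o$oob_mcc_trace))
    m$batch_sizes <- as.integer(unlist(o$batch_sizes))
    m
  })
  replicates <- lapply(obj$replicates, function(r) {
    list(in_bag = as.integer(unlist(r$in_bag)),
         oob = as.integer(unlist(r$oob)))
  })
  structure(
    list(classifiers = classifiers, replicates = replicates,
         params = params, seed = obj$seed,
         sub_seeds = as.integer(unlist(obj$sub_seeds)),
         snp_ids = unlist(obj$snp_ids, use.names = FALSE)),
    class = "bonb_ensemble"
  )
}

#' Rebind a deserialized ensemble's attribute indices to a dataset
#'
#' After [read_bonb_json()] classifier attributes are known only by
#' `snp_id`; this restores column indices against `ds` (required before
#' [marginal_utility()] / [select_biomarkers()]).
#'
#' @param ens a `bonb_ensemble`
#' @param ds a [genotype_dataset]
#' @return the ensemble with `attributes` indices bound to `ds`'s columns
#' @export
bind_ensemble <- function(ens, ds) {
  ens$classifiers <- lapply(ens$classifiers, function(m) {
    m$attributes <- match(m$snp_ids, ds$snps$snp_id)
    if (anyNA(m$attributes)) {
      stop("dataset lacks SNPs required by the ensemble: ",
           paste(m$snp_ids[is.na(m$attributes)], collapse = ", "))
    }
    m
  })
  ens
}
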