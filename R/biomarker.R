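# Biomarker selection: permute a SNP's genotype column in each out-of-bag
# sample, record the relative decrease in OOB MCC (the SNP's marginal
# utility given all other selected attributes), and test the marginal
# utilities for being significantly greater than zero with a one-tailed
# Wilcoxon signed-rank test.

#' Marginal utility of a SNP for one classifier
#'
#' Evaluates classifier `b` on its out-of-bag set before and after randomly
#' permuting the genotype column of the SNP among the OOB subjects (missing
#' values are permuted along with the rest), and returns the relative
#' decrease in MCC: `(MCC_orig - MCC_perm) / |MCC_orig|`. When
#' `MCC_orig = 0` the relative measure is undefined and the absolute
#' decrease is returned instead.
#'
#' @param ens a `bonb_ensemble` (attribute indices bound to `ds`)
#' @param ds the training [genotype_dataset]
#' @param snp_index SNP column index in `ds`
#' @param b classifier index; must include the SNP
#' @param n_permutations average over this many fresh permutations
#'   (default 1, one permutation per classifier)
#' @return numeric marginal utility (positive = the SNP helps)
#' @export
marginal_utility <- function(ens, ds, snp_index, b, n_permutations = 1L) {
  model <- ens$classifiers[[b]]
  pos_in_model <- match(snp_index, model$attributes)
  if (is.na(pos_in_model)) {
    stop("classifier ", b, " does not include SNP column ", snp_index)
  }
  oob <- ens$replicates[[b]]$oob
  if (length(oob) == 0L) stop("classifier ", b, " has an empty OOB set")
  oob_y <- ds$labels[oob]

  mcc_of <- function(G) {
    p_case <- nb_pcase_matrix(model, G, rows = seq_len(nrow(G)),
                              columns = model$attributes)
    pred <- ifelse(p_case > 0.5, "case", "control")
    mcc(confusion_counts(oob_y, pred))
  }

  G <- ds$genotypes[oob, , drop = FALSE]
  mcc_orig <- mcc_of(G)
  mus <- vapply(seq_len(n_permutations), function(k) {
    Gp <- G
    Gp[, snp_index] <- G[sample.int(nrow(G)), snp_index]
    mcc_perm <- mcc_of(Gp)
    if (mcc_orig == 0) mcc_orig - mcc_perm
    else (mcc_orig - mcc_perm) / abs(mcc_orig)
  }, 0)
  mean(mus)
}

#' One-tailed Wilcoxon signed-rank test (location > 0)
#'
#' Zeros are dropped (Wilcoxon's convention); `W` is the sum of the ranks of
#' `|x|` over the positive samples, with average ranks for ties. The p-value
#' is exact when possible -- from the signed-rank null distribution when
#' there are no ties and at most 25 nonzero samples, by full enumeration of
#' the `2^n` sign patterns when there are ties and at most 16 samples -- and
#' otherwise uses the normal approximation with tie correction (no
#' continuity correction). All-zero input gives p = 1.
#'
#' @param x numeric samples
#' @return list with `p_value`, `statistic` (W), `n_nonzero`
#' @export
wilcoxon_signed_rank <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) {
    return(list(p_value = 1, statistic = 0, n_nonzero = 0L))
  }
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  has_ties <- anyDuplicated(r) > 0L
  if (!has_ties && n <= 25L) {
    # exact: P(W+ >= W) under the symmetric null
    p <- psignrank(W - 1, n, lower.tail = FALSE)
  } else if (n <= 16L) {
    # exact with ties: enumerate all sign assignments of the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- mean(w_all >= W - 1e-9)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p <- pnorm((W - mu) / sqrt(sigma2), lower.tail = FALSE)
  }
  list(p_value = p, statistic = W, n_nonzero = n)
}

#' Select genetic biomarkers from a trained ensemble
#'
#' Candidates are the SNPs included as attributes by at least
#' `params$inclusion_fraction` (default 5%) of the classifiers. For each
#' candidate, one marginal utility is recorded per including classifier
#' (one fresh permutation each), and the marginal utilities are tested for
#' being significantly greater than zero with the one-tailed Wilcoxon
#' signed-rank test; a candidate is selected iff `p < params$alpha`. All
#' candidates are reported, sorted by genomic position, with the selected
#' ones flagged.
#'
#' @param ens a `bonb_ensemble`
#' @param ds the training [genotype_dataset]
#' @param params a [bonb_params()]; defaults to the ensemble's own
#' @param seed integer seed for the permutations
#' @param n_permutations permutations per (SNP, classifier), default 1
#' @return data.frame of biomarker records, sorted by (chromosome,
#'   position): `snp_id`, `chromosome`, `position_bp`, `inclusion_fraction`,
#'   `pct_nbcs`, `mu_median`, `p_value`, `selected`, plus a `mu_samples`
#'   list-column with one marginal utility per including classifier.
#' @export
select_biomarkers <- function(ens, ds, params = ens$params, seed = 1L,
                              n_permutations = 1L) {
  B <- length(ens$classifiers)
  incl <- lapply(ens$classifiers, `[[`, "snp_ids")
  counts <- table(unlist(incl))
  candidates <- names(counts)[counts / B >= params$inclusion_fraction]
  set.seed(as.integer(seed))

  rows <- lapply(candidates, function(sid) {
    snp_index <- match(sid, ds$snps$snp_id)
    bs <- which(vapply(incl, function(ids) sid %in% ids, TRUE))
    mus <- vapply(bs, function(b) {
      marginal_utility(ens, ds, snp_index, b, n_permutations)
    }, 0)
    if (sum(mus != 0) < 2L) {
      warning("biomarker candidate ", sid, " has fewer than 2 non-zero ",
              "marginal-utility samples; signed-rank test undefined, p = 1")
      p <- 1
    } else {
      p <- wilcoxon_signed_rank(mus)$p_value
    }
    data.frame(
      snp_id = sid,
      chromosome = ds$snps$chromosome[snp_index],
      position_bp = ds$snps$position_bp[snp_index],
      inclusion_fraction = length(bs) / B,
      pct_nbcs = 100 * length(bs) / B,
      mu_median = median(mus),
      p_value = p,
      selected = p < params$alpha,
      mu_samples = I(list(mus)),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(snp_id = character(0), chromosome = character(0),
               position_bp = integer(0), inclusion_fraction = numeric(0),
               pct_nbcs = numeric(0), mu_median = numeric(0),
               p_value = numeric(0), selected = logical(0),
               mu_samples = I(list()))
  }
  ord <- order(suppressWarnings(as.integer(out$chromosome)),
               out$chromosome, out$position_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
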