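# Matthews Correlation Coefficient and the closed-form Naive Bayes attribute
# score: the MCC of a single-attribute classifier trained and tested on the
# same sample, obtained directly from the SNP's 2x3 contingency table without
# actually training anything -- the key to ranking hundreds of thousands of
# SNPs per bootstrap replicate.

#' Matthews Correlation Coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' convention that a zero factor in the denominator (a degenerate /
#' majority-classification margin) yields 0. Insensitive to class unbalance:
#' ranges from -1 (total inversion) through 0 (majority classification) to 1
#' (perfect prediction). Case is the positive class.
#'
#' @param tp,tn,fp,fn non-negative confusion counts; alternatively `tp` may
#'   be a named vector/list with elements `tp`, `tn`, `fp`, `fn`.
#' @return numeric in `[-1, 1]`
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || !is.null(names(tp)))) {
    cc <- tp
    tp <- cc[["tp"]]; tn <- cc[["tn"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
  }
  tp <- as.numeric(tp); tn <- as.numeric(tn)   # the radicand overflows
  fp <- as.numeric(fp); fn <- as.numeric(fn)   # 32-bit integer counts
  if (tp + tn + fp + fn == 0) stop("MCC undefined for zero subjects")
  rad <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (rad == 0) return(0)
  (tp * tn - fp * fn) / sqrt(rad)
}

#' Confusion counts from labels
#'
#' @param truth,predicted factors/characters over `{case, control}`
#' @return named vector `c(tp=, tn=, fp=, fn=)`; case = positive
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  c(tp = sum(truth == "case" & predicted == "case"),
    tn = sum(truth == "control" & predicted == "control"),
    fp = sum(truth == "control" & predicted == "case"),
    fn = sum(truth == "case" & predicted == "control"))
}

#' Per-genotype classification indicators of a single-attribute classifier
#'
#' With Dirichlet weight 1, a Naive Bayes classifier using one SNP as its
#' sole attribute predicts `case` for genotype `g` iff
#' `(count_case_g + 1)/(n_ca + 3) * (n_ca + 1)/(n + 2) >
#'  (count_ctrl_g + 1)/(n_co + 3) * (n_co + 1)/(n + 2)`.
#' The inequality is strict; ties predict control, matching [nb_classify()].
#'
#' @param table a `contingency_table`
#' @return integer vector `c(I0=, I1=, I2=)` of 0/1 indicators
#' @export
nb_indicators <- function(table) {
  ind <- .indicators_mat(matrix(
    c(table$a, table$b, table$c, table$d, table$e, table$f), nrow = 1L))
  c(I0 = ind[1L, 1L], I1 = ind[1L, 2L], I2 = ind[1L, 3L])
}

# Vectorized indicators: A is a k x 6 matrix of (a,b,c,d,e,f); returns k x 3
# 0/1 matrix. The common factor 1/(n+2) cancels and is omitted.
.indicators_mat <- function(A) {
  n_ca <- A[, 1L] + A[, 2L] + A[, 3L]
  n_co <- A[, 4L] + A[, 5L] + A[, 6L]
  lhs_scale <- (n_ca + 1) / (n_ca + 3)
  rhs_scale <- (n_co + 1) / (n_co + 3)
  ind <- matrix(0L, nrow = nrow(A), ncol = 3L)
  for (g in 1:3) {
    ind[, g] <- as.integer((A[, g] + 1) * lhs_scale >
                             (A[, g + 3L] + 1) * rhs_scale)
  }
  ind
}

#' Closed-form Naive Bayes attribute score of a SNP
#'
#' The MCC of a single-attribute Naive Bayes classifier trained and tested on
#' the same sample, computed in closed form from the SNP's contingency table:
#' the classifier predicts per genotype according to the indicators
#' ([nb_indicators()]), so the confusion counts -- and hence the MCC -- are
#' linear combinations of the table's cells. When the classifier is a
#' majority classifier (all indicators equal) or a margin is degenerate, the
#' score is 0.
#'
#' @param table a `contingency_table`
#' @return list with `score` (numeric in `[-1,1]`) and `indicators`
#'   (`c(I0=,I1=,I2=)`)
#' @export
nb_attribute_score <- function(table) {
  A <- matrix(c(table$a, table$b, table$c, table$d, table$e, table$f),
              nrow = 1L)
  ind <- .indicators_mat(A)
  list(score = .score_mat(A, ind)[1L],
       indicators = c(I0 = ind[1L, 1L], I1 = ind[1L, 2L], I2 = ind[1L, 3L]))
}

# Vectorized score over a k x 6 count matrix (a,b,c,d,e,f per row).
# Double arithmetic throughout: the radicand multiplies four margins and
# overflows 32-bit integers already at a few hundred subjects.
.score_mat <- function(A, ind = .indicators_mat(A)) {
  storage.mode(A) <- "double"
  a <- A[, 1L]; b <- A[, 2L]; c <- A[, 3L]
  d <- A[, 4L]; e <- A[, 5L]; f <- A[, 6L]
  I0 <- ind[, 1L]; I1 <- ind[, 2L]; I2 <- ind[, 3L]
  n_ca <- a + b + c; n_co <- d + e + f
  n0 <- a + d; n1 <- b + e; n2 <- c + f
  num <- (a * e - b * d) * (I0 - I1) +
         (a * f - c * d) * (I0 - I2) +
         (b * f - c * e) * (I1 - I2)
  rad <- n_ca * n_co *
    (n0 * n1 * xor(I0, I1) + n0 * n2 * xor(I0, I2) + n1 * n2 * xor(I1, I2))
  s <- numeric(nrow(A))
  pos <- rad > 0
  s[pos] <- num[pos] / sqrt(rad[pos])
  s
}

#' Pearson chi-squared statistic (2 df, general genetic model)
#'
#' The association test on the full 2x3 genotype table (no genetic model
#' assumed). `applicable` is `FALSE` when any of the six observed cells has
#' fewer than 5 elements -- the classic validity convention -- or when a
#' margin is zero; the statistic is still returned (0 for zero-margin tables)
#' so score-vs-chi2 scatters can include every SNP.
#'
#' @param table a `contingency_table`
#' @return list with `statistic`, `p_value` (upper tail, 2 df), `applicable`
#' @export
chi2_general_2df <- function(table) {
  obs <- rbind(c(table$a, table$b, table$c), c(table$d, table$e, table$f))
  rs <- rowSums(obs); cs <- colSums(obs); n <- sum(obs)
  if (n == 0 || any(rs == 0)) {
    return(list(statistic = 0, p_value = 1, applicable = FALSE))
  }
  keep <- cs > 0
  expd <- outer(rs, cs[keep]) / n
  stat <- sum((obs[, keep, drop = FALSE] - expd)^2 / expd)
  df <- 2L
  list(statistic = stat,
       p_value = pchisq(stat, df = df, lower.tail = FALSE),
       applicable = all(obs >= 5))
}

#' Score every SNP of a dataset
#'
#' Emits the per-SNP attribute score and chi-squared statistic, the substrate
#' of a score-vs-chi2 scatter.
#'
#' @param ds a [genotype_dataset]
#' @param subject_indices training multiset of row indices (default: all)
#' @return data.frame with columns `snp_id`, `chromosome`, `position_bp`,
#'   `score`, `chi2`, `chi2_p`, `applicable`
#' @export
score_table <- function(ds, subject_indices = seq_len(n_subjects(ds))) {
  A <- count_tables(ds, subject_indices)
  scores <- .score_mat(A)
  chi <- lapply(seq_len(nrow(A)), function(i) {
    chi2_general_2df(contingency_table(A[i, 1L], A[i, 2L], A[i, 3L],
                                       A[i, 4L], A[i, 5L], A[i, 6L]))
  })
  data.frame(
    snp_id = ds$snps$snp_id,
    chromosome = ds$snps$chromosome,
    position_bp = ds$snps$position_bp,
    score = scores,
    chi2 = vapply(chi, `[[`, 0, "statistic"),
    chi2_p = vapply(chi, `[[`, 0, "p_value"),
    applicable = vapply(chi, `[[`, TRUE, "applicable"),
    stringsAsFactors = FALSE
  )
}

# All-SNP count matrix (p x 6, columns a,b,c,d,e,f) over a subject multiset.
# Vectorized across SNPs; missing genotypes drop out via na.rm.
count_tables <- function(ds, subject_indices) {
  G <- ds$genotypes[subject_indices, , drop = FALSE]
  ca <- ds$labels[subject_indices] == "case"
  Gca <- G[ca, , drop = FALSE]
  Gco <- G[!ca, , drop = FALSE]
  cbind(
    colSums(Gca == 0L, na.rm = TRUE), colSums(Gca == 1L, na.rm = TRUE),
    colSums(Gca == 2L, na.rm = TRUE),
    colSums(Gco == 0L, na.rm = TRUE), colSums(Gco == 1L, na.rm = TRUE),
    colSums(Gco == 2L, na.rm = TRUE)
  )
}
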