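# Shared fixtures and independent oracles used across the suite.

# Small hand-specified dataset.
tiny_ds <- function(genotypes, labels, chrom = NULL, pos = NULL) {
  p <- ncol(genotypes)
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(pos)) pos <- as.integer(seq_len(p) * 10000000L)
  genotype_dataset(
    genotypes,
    data.frame(snp_id = paste0("snp", seq_len(p)), chromosome = chrom,
               position_bp = pos, stringsAsFactors = FALSE),
    labels
  )
}

# Random dataset respecting the coding orientation (code 2 = homozygous
# major): genotype codes drawn with minor-allele frequency <= 0.5, then
# flipped wherever sampling noise made the realized "minor" dosage exceed
# 50% (the coding invariant is about realized, not nominal, frequencies).
random_ds <- function(n, p, missing_rate = 0.05) {
  maf <- runif(p, 0.05, 0.5)
  G <- vapply(maf, function(f) {
    2L - rbinom(n, 2L, f)               # 2 - minor-allele count
  }, integer(n))
  if (missing_rate > 0) {
    G[matrix(runif(n * p) < missing_rate, n, p)] <- NA_integer_
  }
  for (j in seq_len(p)) {               # orient on the observed entries
    dos <- 2L - G[, j]
    if (sum(dos, na.rm = TRUE) > sum(!is.na(dos))) G[, j] <- 2L - G[, j]
  }
  labels <- sample(c("case", "control"), n, replace = TRUE)
  # ensure both classes present
  labels[1] <- "case"; labels[2] <- "control"
  tiny_ds(G, labels)
}

random_table <- function(max_count = 50L) {
  cells <- sample.int(max_count + 1L, 6L, replace = TRUE) - 1L
  contingency_table(cells[1], cells[2], cells[3],
                    cells[4], cells[5], cells[6])
}

# --- Independent oracle for the closed-form attribute score ---------------
# Trains a single-attribute Naive Bayes classifier on the table's subjects
# (via the estimation + posterior code path, not the closed form), classifies
# every subject in the table, and computes the MCC of the prediction.
oracle_attribute_score <- function(tab) {
  if (tab$n == 0) return(0)
  theta <- estimate_theta(tab, 1)
  prior <- estimate_prior(tab$n_ca, tab$n_co, 1)
  pred_case <- vapply(0:2, function(g) {
    post <- prior * theta[g + 1L, ]
    post <- post / sum(post)
    post[["case"]] > post[["control"]]
  }, TRUE)
  case_counts <- as.numeric(c(tab$a, tab$b, tab$c))   # doubles: the radicand
  ctrl_counts <- as.numeric(c(tab$d, tab$e, tab$f))   # overflows 32-bit ints
  tp <- sum(case_counts[pred_case])
  fn <- sum(case_counts[!pred_case])
  fp <- sum(ctrl_counts[pred_case])
  tn <- sum(ctrl_counts[!pred_case])
  rad <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (rad == 0) return(0)
  (tp * tn - fp * fn) / sqrt(rad)
}

# Enumerate all 2x3 tables with total count <= max_n as a k x 6 matrix.
enumerate_tables <- function(max_n) {
  grids <- expand.grid(a = 0:max_n, b = 0:max_n, c = 0:max_n,
                       d = 0:max_n, e = 0:max_n, f = 0:max_n)
  as.matrix(grids[rowSums(grids) <= max_n, , drop = FALSE])
}

# --- Explicit-fraction Bayes-rule oracle for posteriors -------------------
# Recomputes the posterior of a trained nb_classifier on a genotype row with
# plain products of the stored probabilities (no log space), skipping
# missing attributes.
oracle_posterior <- function(model, row) {
  num <- model$prior
  for (i in seq_along(model$attributes)) {
    g <- row[model$attributes[i]]
    if (!is.na(g)) num <- num * model$theta[[i]][g + 1L, ]
  }
  num / sum(num)
}

# --- Exhaustive signed-rank oracle ----------------------------------------
# One-tailed p by enumerating every sign assignment of the ranked |x|.
oracle_signed_rank <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) return(1)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(w_all >= W - 1e-9)
}
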