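# Categorical Naive Bayes over SNP attributes: 2x3 contingency tables,
# Dirichlet-smoothed parameter estimation, and log-space posteriors with
# missing-genotype marginalization.

#' Build the 2x3 contingency table of a SNP
#'
#' Counts genotypes by class over a multiset of subject rows (repeats count
#' with multiplicity, as in a bootstrap replicate). Missing genotypes
#' contribute to no cell, so the table's `n` is the per-SNP observed count.
#'
#' @param ds a [genotype_dataset]
#' @param snp_index column index of the SNP (1-based)
#' @param subject_indices integer vector of row indices, possibly with
#'   repeats; defaults to all subjects once.
#' @return a `contingency_table`: list with case counts `a`, `b`, `c` and
#'   control counts `d`, `e`, `f` at genotypes 0, 1, 2, plus marginals
#'   `n_ca`, `n_co`, `n0`, `n1`, `n2`, `n`.
#' @export
build_contingency_table <- function(ds, snp_index,
                                    subject_indices = seq_len(n_subjects(ds))) {
  if (snp_index < 1L || snp_index > n_snps(ds)) {
    stop("snp_index out of range: ", snp_index)
  }
  g <- ds$genotypes[subject_indices, snp_index]
  y <- ds$labels[subject_indices]
  keep <- !is.na(g)
  g <- g[keep]; y <- y[keep]
  ca <- y == "case"
  contingency_table(
    a = sum(g == 0L & ca), b = sum(g == 1L & ca), c = sum(g == 2L & ca),
    d = sum(g == 0L & !ca), e = sum(g == 1L & !ca), f = sum(g == 2L & !ca)
  )
}

#' Construct a contingency table from its six cells
#'
#' @param a,b,c case counts at genotype 0, 1, 2
#' @param d,e,f control counts at genotype 0, 1, 2
#' @return a `contingency_table` (see [build_contingency_table()])
#' @export
contingency_table <- function(a, b, c, d, e, f) {
  cells <- c(a = a, b = b, c = c, d = d, e = e, f = f)
  if (any(cells < 0)) stop("contingency counts must be non-negative")
  out <- as.list(cells)
  out$n_ca <- a + b + c
  out$n_co <- d + e + f
  out$n0 <- a + d; out$n1 <- b + e; out$n2 <- c + f
  out$n <- out$n_ca + out$n_co
  structure(out, class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- rbind(case = c(x$a, x$b, x$c), control = c(x$d, x$e, x$f))
  colnames(m) <- c("g=0", "g=1", "g=2")
  print(m)
  invisible(x)
}

#' Dirichlet-smoothed conditional probability table
#'
#' Estimates `theta[j, k] = Pr(X = j | Y = k)` for genotype values
#' `j` in `{0,1,2}` and class `k` from the table's counts with pseudo-count
#' `l` per cell: `(count + l) / (n_k + 3 l)`. With `l = 1` this is Laplace
#' smoothing; every probability is strictly positive even for empty classes.
#'
#' @param table a `contingency_table`
#' @param l positive Dirichlet weight (equivalent sample size), default 1
#' @return a 3 x 2 matrix, rows genotypes `0:2`, columns `case`, `control`;
#'   each column sums to 1.
#' @export
estimate_theta <- function(table, l = 1) {
  stopifnot(l > 0)
  m <- cbind(case = c(table$a, table$b, table$c) + l,
             control = c(table$d, table$e, table$f) + l)
  m[, "case"] <- m[, "case"] / (table$n_ca + 3 * l)
  m[, "control"] <- m[, "control"] / (table$n_co + 3 * l)
  rownames(m) <- c("0", "1", "2")
  m
}

#' Smoothed class prior
#'
#' `pi_k = (n_k + l) / (n + 2 l)`.
#'
#' @param n_ca,n_co case and control counts in the training multiset
#' @param l positive Dirichlet weight, default 1
#' @return named numeric vector `c(case = , control = )`, summing to 1
#' @export
estimate_prior <- function(n_ca, n_co, l = 1) {
  stopifnot(l > 0)
  n <- n_ca + n_co
  c(case = (n_ca + l) / (n + 2 * l), control = (n_co + l) / (n + 2 * l))
}

#' Train a Naive Bayes classifier on selected SNP attributes
#'
#' Estimates the prior from the class counts of `subject_indices` (a
#' bootstrap multiset: repeats count) and one smoothed conditional
#' probability table per attribute from that multiset's contingency tables.
#'
#' @param ds a [genotype_dataset]
#' @param attributes integer vector of SNP column indices (may be empty)
#' @param subject_indices training multiset of row indices
#' @param l positive Dirichlet weight, default 1
#' @return an `nb_classifier`: list with `attributes` (column indices),
#'   `snp_ids`, `theta` (list of 3 x 2 matrices), `log_theta`, `prior`,
#'   `log_prior`, `l`.
#' @export
train_nb <- function(ds, attributes,
                     subject_indices = seq_len(n_subjects(ds)), l = 1) {
  attributes <- as.integer(attributes)
  y <- ds$labels[subject_indices]
  prior <- estimate_prior(sum(y == "case"), sum(y == "control"), l)
  theta <- lapply(attributes, function(j) {
    estimate_theta(build_contingency_table(ds, j, subject_indices), l)
  })
  structure(
    list(attributes = attributes,
         snp_ids = ds$snps$snp_id[attributes],
         theta = theta,
         log_theta = lapply(theta, log),
         prior = prior,
         log_prior = log(prior),
         l = l),
    class = "nb_classifier"
  )
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat("nb_classifier with", length(x$attributes), "attribute(s):",
      paste(utils::head(x$snp_ids, 8L), collapse = ", "),
      if (length(x$snp_ids) > 8L) "..." else "", "\n")
  cat(sprintf("  prior: case %.4f / control %.4f (l = %g)\n",
              x$prior["case"], x$prior["control"], x$l))
  invisible(x)
}

#' Posterior class probabilities for one subject
#'
#' Applies the Naive Bayes rule in log space: the unnormalized class score is
#' the prior times the product of `theta[g_i, k]` over the model's attributes.
#' Attributes with missing genotype are skipped (they contribute a factor of
#' 1, i.e. are marginalized out under the factorization), so a fully missing
#' row returns the prior.
#'
#' @param model an `nb_classifier`
#' @param genotype_row vector over `{0,1,2,NA}` indexable at every attribute
#'   column of the model (usually a full row of the genotype matrix)
#' @return named numeric vector `c(case = , control = )` summing to 1
#' @export
nb_posterior <- function(model, genotype_row) {
  lp <- model$log_prior
  for (i in seq_along(model$attributes)) {
    g <- genotype_row[model$attributes[i]]
    if (!is.na(g)) lp <- lp + model$log_theta[[i]][g + 1L, ]
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Classify one subject
#'
#' Predicts `case` iff `Pr(case) > Pr(control)`; an exact tie resolves to
#' `control` (the a-priori "healthy" default).
#'
#' @inheritParams nb_posterior
#' @return `"case"` or `"control"`
#' @export
nb_classify <- function(model, genotype_row) {
  p <- nb_posterior(model, genotype_row)
  if (p["case"] > p["control"]) "case" else "control"
}

# Vectorized posterior over a genotype matrix restricted to the given rows.
# Returns the per-subject Pr(case). Internal hot path for OOB evaluation and
# ensemble prediction; `columns` lets a prediction dataset remap attribute
# columns by snp_id.
nb_pcase_matrix <- function(model, genotypes,
                            rows = seq_len(nrow(genotypes)),
                            columns = model$attributes) {
  lp_ca <- rep(model$log_prior[["case"]], length(rows))
  lp_co <- rep(model$log_prior[["control"]], length(rows))
  for (i in seq_along(columns)) {
    g <- genotypes[rows, columns[i]]
    ok <- !is.na(g)
    if (any(ok)) {
      lt <- model$log_theta[[i]]
      gi <- g[ok] + 1L
      lp_ca[ok] <- lp_ca[ok] + lt[gi, "case"]
      lp_co[ok] <- lp_co[ok] + lt[gi, "control"]
    }
  }
  m <- pmax(lp_ca, lp_co)
  eca <- exp(lp_ca - m); eco <- exp(lp_co - m)
  eca / (eca + eco)
}

#' Serialize / restore a Naive Bayes classifier as JSON
#'
#' The document stores attributes by `snp_id` (not column position), the
#' conditional probability tables, the prior and the Dirichlet weight, making
#' models portable across datasets with matching SNP identifiers.
#'
#' @param model an `nb_classifier`
#' @param path file path
#' @return `read_nb_json` returns an `nb_classifier` whose `attributes`
#'   indices are `NA` until re-bound to a dataset via snp_ids.
#' @export
write_nb_json <- function(model, path) {
  jsonlite::write_json(nb_to_list(model), path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

nb_to_list <- function(model) {
  list(
    snp_ids = as.list(model$snp_ids),
    theta = lapply(model$theta, function(m) {
      list(case = m[, "case"], control = m[, "control"])
    }),
    prior = as.list(model$prior),
    l = model$l
  )
}

nb_from_list <- function(obj) {
  theta <- lapply(obj$theta, function(t) {
    m <- cbind(case = unlist(t$case), control = unlist(t$control))
    rownames(m) <- c("0", "1", "2")
    m
  })
  prior <- c(case = obj$prior$case, control = obj$prior$control)
  structure(
    list(attributes = rep(NA_integer_, length(obj$snp_ids)),
         snp_ids = unlist(obj$snp_ids, use.names = FALSE) %||% character(0),
         theta = theta,
         log_theta = lapply(theta, log),
         prior = prior,
         log_prior = log(prior),
         l = obj$l),
    class = "nb_classifier"
  )
}

#' @rdname write_nb_json
#' @export
read_nb_json <- function(path) {
  nb_from_list(jsonlite::read_json(path))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
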