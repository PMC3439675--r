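# Data model for case/control SNP genotype matrices plus PLINK transposed-text
# and TSV readers/writers.
#
# Genotype coding follows the contingency-table convention used throughout the
# package: 0 = homozygous minor, 1 = heterozygous, 2 = homozygous major.
# Note this is the OPPOSITE orientation of PLINK's additive minor-allele
# dosage; the .tped reader performs the flip (code = 2 - minor allele count).
# Missing genotypes are NA and are never imputed.

#' Construct a genotype dataset
#'
#' Bundles an `n x p` genotype matrix (codes `0` homozygous minor, `1`
#' heterozygous, `2` homozygous major, `NA` missing), a SNP map, and binary
#' phenotypes into a validated `genotype_dataset` object, the container all
#' other functions in the package operate on.
#'
#' @param genotypes integer/numeric matrix, subjects in rows, SNPs in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param snps data.frame with columns `snp_id` (unique character),
#'   `chromosome` (character token, e.g. `"1"`..`"22"`, `"X"`), `position_bp`
#'   (integer >= 1, base pairs); one row per genotype column, in column order.
#' @param labels factor or character vector of length `n` with values
#'   `"case"` / `"control"`.
#' @param subject_ids character vector of unique subject identifiers; defaults
#'   to rownames of `genotypes` or `subj1..subjn`.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `snps`, `labels` (factor with levels `control`, `case`),
#'   `subject_ids`.
#' @export
genotype_dataset <- function(genotypes, snps, labels, subject_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    stop("genotype codes must be in {0, 1, 2, NA}; found: ",
         paste(unique(genotypes[bad]), collapse = ", "))
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chromosome", "position_bp")
  if (!all(req %in% names(snps))) {
    stop("snp map must have columns snp_id, chromosome, position_bp")
  }
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position_bp <- as.integer(snps$position_bp)
  if (nrow(snps) != ncol(genotypes)) {
    stop("snp map has ", nrow(snps), " rows but genotype matrix has ",
         ncol(genotypes), " columns")
  }
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  if (any(!is.na(snps$position_bp) & snps$position_bp < 1L)) {
    stop("position_bp must be >= 1")
  }
  labels <- factor(as.character(labels), levels = c("control", "case"))
  if (anyNA(labels)) stop("labels must be 'case' or 'control'")
  if (length(labels) != nrow(genotypes)) {
    stop("labels length must equal number of subjects")
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(genotypes)
    if (is.null(subject_ids)) {
      subject_ids <- paste0("subj", seq_len(nrow(genotypes)))
    }
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  if (length(subject_ids) != nrow(genotypes)) {
    stop("subject_ids length must equal number of subjects")
  }
  dimnames(genotypes) <- list(subject_ids, snps$snp_id)
  rownames(snps) <- NULL
  structure(
    list(genotypes = genotypes, snps = snps, labels = labels,
         subject_ids = subject_ids),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset: ", length(x$subject_ids), " subjects x ",
      nrow(x$snps), " SNPs\n", sep = "")
  cat("  cases: ", sum(x$labels == "case"),
      ", controls: ", sum(x$labels == "control"), "\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' Number of subjects / SNPs
#' @param ds a `genotype_dataset`
#' @return integer
#' @export
n_subjects <- function(ds) nrow(ds$genotypes)

#' @rdname n_subjects
#' @export
n_snps <- function(ds) ncol(ds$genotypes)

# ---------------------------------------------------------------------------
# PLINK transposed text (.tped / .tfam)

#' Read PLINK transposed text files
#'
#' Reads a `.tped` / `.tfam` pair into a [genotype_dataset]. Allele pairs are
#' converted to minor-allele counts (minor allele determined per SNP by
#' overall frequency, ties broken by lexicographic allele order) and then
#' recoded to the package convention `2 - count`, so homozygous-minor maps to
#' 0 and homozygous-major to 2. `"0 0"` allele pairs become `NA`. Subjects
#' with unknown phenotype (0 or -9 in column 6 of the `.tfam`) are dropped
#' with a warning.
#'
#' @param tped_path path to the `.tped` file (space-separated: chromosome,
#'   snp_id, genetic distance, position, then two allele columns per subject).
#' @param tfam_path path to the `.tfam` file (six columns; column 2 is the
#'   individual id, column 6 the phenotype: 1 = control, 2 = case,
#'   0 / -9 = unknown).
#' @return a [genotype_dataset]
#' @seealso [write_tped_tfam()]
#' @export
read_tped_tfam <- function(tped_path, tfam_path) {
  if (!file.exists(tped_path)) stop("file not found: ", tped_path)
  if (!file.exists(tfam_path)) stop("file not found: ", tfam_path)

  fam <- read.table(tfam_path, header = FALSE, colClasses = "character")
  if (ncol(fam) < 6L) stop("malformed .tfam (", tfam_path, "): need 6 columns")
  subject_ids <- fam[[2L]]
  pheno <- fam[[6L]]
  known <- pheno %in% c("1", "2")
  if (any(!known)) {
    warning("dropping ", sum(!known), " subject(s) with unknown phenotype")
  }
  subject_ids <- subject_ids[known]
  labels <- ifelse(pheno[known] == "2", "case", "control")
  n <- length(subject_ids)

  lines <- readLines(tped_path)
  lines <- lines[nzchar(trimws(lines))]
  p <- length(lines)
  geno <- matrix(NA_integer_, nrow = n, ncol = p)
  snp_id <- character(p)
  chrom <- character(p)
  pos <- integer(p)
  n_total <- length(known)

  for (i in seq_len(p)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(toks) != 4L + 2L * n_total) {
      stop("malformed line ", i, " in ", tped_path, ": expected ",
           4L + 2L * n_total, " fields, found ", length(toks))
    }
    chrom[i] <- toks[1L]
    snp_id[i] <- toks[2L]
    pos[i] <- suppressWarnings(as.integer(toks[4L]))
    if (is.na(pos[i])) {
      stop("malformed line ", i, " in ", tped_path, ": bad position '",
           toks[4L], "'")
    }
    al <- matrix(toks[-(1:4)], nrow = 2L)   # 2 x n_total, alleles per subject
    al <- al[, known, drop = FALSE]
    al[al == "0"] <- NA_character_
    alleles <- sort(unique(al[!is.na(al)]))
    if (length(alleles) > 2L) {
      stop("malformed line ", i, " in ", tped_path,
           ": more than two alleles (", paste(alleles, collapse = ","), ")")
    }
    if (length(alleles) == 0L) next               # all-missing SNP
    if (length(alleles) == 1L) {
      # monomorphic: the only observed allele has frequency 1, so it is the
      # major allele and every observed genotype is homozygous major
      geno[, i] <- ifelse(is.na(al[1L, ]) | is.na(al[2L, ]), NA_integer_, 2L)
      next
    }
    counts <- vapply(alleles, function(a) sum(al == a, na.rm = TRUE), 0L)
    # minor allele = lower overall frequency; tie -> lexicographically first
    minor <- alleles[order(counts, alleles)][1L]
    dosage <- colSums(al == minor)                # NA where any allele missing
    geno[, i] <- as.integer(2L - dosage)
  }
  if (anyDuplicated(snp_id)) {
    stop("duplicate snp_id in ", tped_path, ": ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  }
  genotype_dataset(
    geno,
    data.frame(snp_id = snp_id, chromosome = chrom, position_bp = pos,
               stringsAsFactors = FALSE),
    labels, subject_ids
  )
}

#' Write PLINK transposed text files
#'
#' Inverse of [read_tped_tfam()]. Genotype code 0 (homozygous minor) is
#' written as `A A`, 1 as `A B`, 2 as `B B`, and `NA` as `0 0`, so the minor
#' allele is always `A` (lexicographically first) and the round trip through
#' [read_tped_tfam()] restores the dataset exactly when the written minor
#' allele really is minor (guaranteed unless a column's minor-allele dosage
#' exceeds 50%, which cannot happen for codes produced by the reader or the
#' simulator at maf <= 0.5; ties resolve to `A` by the reader's rule).
#'
#' @param ds a [genotype_dataset]
#' @inheritParams read_tped_tfam
#' @return invisibly, `ds`
#' @export
write_tped_tfam <- function(ds, tped_path, tfam_path) {
  fam <- data.frame(
    fid = ds$subject_ids, iid = ds$subject_ids,
    pat = "0", mat = "0", sex = "0",
    pheno = ifelse(ds$labels == "case", "2", "1"),
    stringsAsFactors = FALSE
  )
  write.table(fam, tfam_path, quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)

  con <- file(tped_path, "w")
  on.exit(close(con))
  pair <- c("A A", "A B", "B B")   # code 0 = two minor (A) alleles
  for (i in seq_len(n_snps(ds))) {
    g <- ds$genotypes[, i]
    alleles <- ifelse(is.na(g), "0 0", pair[g + 1L])
    writeLines(paste(ds$snps$chromosome[i], ds$snps$snp_id[i], "0",
                     ds$snps$position_bp[i], paste(alleles, collapse = " ")),
               con)
  }
  invisible(ds)
}

# ---------------------------------------------------------------------------
# TSV dialect: genotype matrix + map + phenotype files

#' Read the TSV genotype dialect
#'
#' Three tab-separated files: a genotype matrix (header row of snp_ids, first
#' column `subject_id`, cells in `{0,1,2,NA}`), a map file with columns
#' `snp_id`, `chromosome`, `position_bp`, and a phenotype file with columns
#' `subject_id`, `phenotype` (`case` / `control`).
#'
#' @param matrix_path,map_path,pheno_path file paths
#' @return a [genotype_dataset]
#' @seealso [write_genotype_tsv()]
#' @export
read_genotype_tsv <- function(matrix_path, map_path, pheno_path) {
  mat <- read.table(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character",
                    na.strings = NULL)
  if (names(mat)[1L] != "subject_id") {
    stop("matrix file must have 'subject_id' as its first column")
  }
  subject_ids <- mat[[1L]]
  snp_ids <- names(mat)[-1L]
  cells <- as.matrix(mat[, -1L, drop = FALSE])
  ok <- cells %in% c("0", "1", "2", "NA")
  if (!all(ok)) {
    stop("genotype cell outside {0,1,2,NA} in ", matrix_path, ": '",
         cells[!ok][1L], "'")
  }
  geno <- matrix(suppressWarnings(as.integer(cells)),
                 nrow = nrow(cells), ncol = ncol(cells))

  map <- read.table(map_path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer"))
  if (!all(c("snp_id", "chromosome", "position_bp") %in% names(map))) {
    stop("map file must have columns snp_id, chromosome, position_bp")
  }
  missing_map <- setdiff(snp_ids, map$snp_id)
  if (length(missing_map)) {
    stop("snp_id present in matrix but absent from map: ",
         paste(missing_map, collapse = ", "))
  }
  map <- map[match(snp_ids, map$snp_id), , drop = FALSE]

  ph <- read.table(pheno_path, header = TRUE, sep = "\t",
                   colClasses = "character")
  if (!all(c("subject_id", "phenotype") %in% names(ph))) {
    stop("phenotype file must have columns subject_id, phenotype")
  }
  idx <- match(subject_ids, ph$subject_id)
  if (anyNA(idx)) {
    stop("subjects missing from phenotype file: ",
         paste(subject_ids[is.na(idx)], collapse = ", "))
  }
  genotype_dataset(geno, map, ph$phenotype[idx], subject_ids)
}

#' Write the TSV genotype dialect
#'
#' Inverse of [read_genotype_tsv()]; missing genotypes are written as `NA`.
#'
#' @param ds a [genotype_dataset]
#' @inheritParams read_genotype_tsv
#' @return invisibly, `ds`
#' @export
write_genotype_tsv <- function(ds, matrix_path, map_path, pheno_path) {
  cells <- matrix(as.character(ds$genotypes), nrow = n_subjects(ds))
  cells[is.na(cells)] <- "NA"
  out <- data.frame(subject_id = ds$subject_ids, cells,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("subject_id", ds$snps$snp_id)
  write.table(out, matrix_path, quote = FALSE, sep = "\t", row.names = FALSE)
  write.table(ds$snps, map_path, quote = FALSE, sep = "\t", row.names = FALSE)
  write.table(
    data.frame(subject_id = ds$subject_ids,
               phenotype = as.character(ds$labels)),
    pheno_path, quote = FALSE, sep = "\t", row.names = FALSE
  )
  invisible(ds)
}

#' Subset a genotype dataset by subjects
#'
#' @param ds a [genotype_dataset]
#' @param subjects integer indices (may repeat) or logical mask
#' @return a [genotype_dataset] restricted (or expanded, for repeated indices)
#'   to the requested subjects; repeated indices get suffixed subject ids.
#' @export
subset_subjects <- function(ds, subjects) {
  ids <- ds$subject_ids[subjects]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "#")
  genotype_dataset(ds$genotypes[subjects, , drop = FALSE], ds$snps,
                   ds$labels[subjects], ids)
}
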