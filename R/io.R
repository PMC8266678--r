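# All on-disk formats are plain TSV, UTF-8, "NA" (or empty string) as the
# missing-value sentinel.  Matrices: first column = gene IDs, header = sample
# IDs.

#' Read an expression matrix from TSV
#'
#' @param path path to a tab-separated file; first column gene IDs, header
#'   row sample IDs.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`
#'   (transposed on read).
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path,
                                orientation = c("genes_in_rows",
                                                "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("expression TSV needs an ID column plus >= 1 sample")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate IDs in '", basename(path), "': ",
         paste(dup, collapse = ", "))
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing cell at row '", ids[bad[1]], "', column '",
         colnames(df)[-1][bad[2]], "' in '", basename(path), "'")
  }
  dimnames(num) <- list(ids, colnames(df)[-1])
  if (orientation == "samples_in_rows") num <- t(num)
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param x an [expression_matrix()] (or any named numeric matrix).
#' @param path output path.
#' @param id_column header name for the gene-ID column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_column = "gene_id") {
  write_named_matrix(unclass(x), path, id_column)
}

write_named_matrix <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_named_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""))
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read / write a stable pair set as 3-column TSV
#'
#' Columns: `high_gene`, `low_gene`, `support`.
#'
#' @param path TSV path.
#' @param threshold_f,n_normals metadata recorded in the object (the TSV
#'   carries only the pairs).
#' @return A [stable_pair_set()].
#' @export
read_stable_pairs_tsv <- function(path, threshold_f, n_normals) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric"))
  stable_pair_set(df, threshold_f = threshold_f, n_normals = n_normals)
}

#' @rdname read_stable_pairs_tsv
#' @param x a [stable_pair_set()].
#' @export
write_stable_pairs_tsv <- function(x, path) {
  stopifnot(inherits(x, "stable_pair_set"))
  write.table(x$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an IDE profile directory
#'
#' A profile is serialized as three sibling TSVs in one directory:
#' `calls.tsv` (ternary), `pvals.tsv` and `qvals.tsv`.
#'
#' @param dir directory path.
#' @param alpha FDR level to record on read.
#' @return An [ide_profile()].
#' @export
read_profile_dir <- function(dir, alpha = 0.05) {
  ide_profile(read_named_matrix(file.path(dir, "calls.tsv")),
              read_named_matrix(file.path(dir, "pvals.tsv")),
              read_named_matrix(file.path(dir, "qvals.tsv")),
              alpha = alpha)
}

#' @rdname read_profile_dir
#' @param x an [ide_profile()].
#' @export
write_profile_dir <- function(x, dir) {
  stopifnot(inherits(x, "ide_profile"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_named_matrix(x$calls, file.path(dir, "calls.tsv"))
  write_named_matrix(x$p_values, file.path(dir, "pvals.tsv"))
  write_named_matrix(x$q_values, file.path(dir, "qvals.tsv"))
  invisible(dir)
}

#' Read a binary alteration matrix from TSV
#'
#' @param path TSV path (genes x samples of 0/1).
#' @param alteration_type the matrix's alteration type tag.
#' @return An [alteration_matrix()].
#' @export
read_alteration_tsv <- function(path, alteration_type) {
  alteration_matrix(read_named_matrix(path), alteration_type)
}

#' @rdname read_alteration_tsv
#' @param x an [alteration_matrix()].
#' @export
write_alteration_tsv <- function(x, path) {
  stopifnot(inherits(x, "alteration_matrix"))
  write_named_matrix(x$flags, path)
}

#' Read a sample annotation TSV
#'
#' Expected columns: `sample_id`, optional `subtype`, `surv_time`,
#' `surv_event`; any further numeric columns become covariates.
#'
#' @param path TSV path.
#' @param drug_response_path optional TSV with columns `sample_id`, `drug`
#'   and `response` and/or `act_area`.
#' @return A [sample_annotation()].
#' @export
read_annotation_tsv <- function(path, drug_response_path = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""), stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(df))
  known <- c("sample_id", "subtype", "surv_time", "surv_event")
  cov <- df[setdiff(names(df), known)]
  if (!ncol(cov)) cov <- NULL
  dr <- NULL
  if (!is.null(drug_response_path))
    dr <- read.delim(drug_response_path, header = TRUE, sep = "\t",
                     na.strings = c("NA", ""), stringsAsFactors = FALSE)
  sample_annotation(df$sample_id, subtype = df$subtype,
                    surv_time = df$surv_time, surv_event = df$surv_event,
                    covariates = cov, drug_response = dr)
}

#' @rdname read_annotation_tsv
#' @param x a [sample_annotation()].
#' @export
write_annotation_tsv <- function(x, path) {
  stopifnot(inherits(x, "sample_annotation"))
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
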