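# Readers and writers for the plain-text formats the pipeline exchanges:
# plate CSVs, feature x sample TSV matrices, FASTA, GMT gene sets.

#' Read FASTA sequences as a named character vector
#'
#' @param path FASTA file (RNA or DNA alphabet).
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Read a GMT gene-set file
#'
#' Each line is tab-separated: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT: lines with fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature x sample expression matrix from TSV
#'
#' First column = feature id, header row = sample ids.
#'
#' @param path TSV file path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1L]]
  mat
}

#' Write a feature x sample matrix as TSV
#'
#' @param mat Numeric matrix with rownames (feature ids) and colnames.
#' @param path Output path.
#' @param id_column Name for the feature-id column (default `"feature_id"`).
#' @export
write_expression_matrix <- function(mat, path, id_column = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a screen plate table from CSV
#'
#' Expected columns: `screen_id`, `replicate`, `mirna_id`, `firefly`,
#' `renilla`.
#'
#' @param path CSV file path.
#' @return Data frame in `ScreenPlateTable` layout.
#' @export
read_screen_plates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("screen_id", "replicate", "mirna_id", "firefly", "renilla")
  if (!all(req %in% names(df))) {
    stop("screen plate CSV must have columns ", paste(req, collapse = ", "))
  }
  df
}

#' Write a screen plate table to CSV
#'
#' @param plates Data frame in `ScreenPlateTable` layout.
#' @param path Output path.
#' @export
write_screen_plates <- function(plates, path) {
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample-annotation sidecar TSV
#'
#' Columns: `sample_id`, `genotype` (TG/WT), `time_weeks`, optional `group`.
#'
#' @param path TSV file path.
#' @return Data frame of sample annotations.
#' @export
read_sample_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "genotype", "time_weeks")
  if (!all(req %in% names(df))) {
    stop("annotation TSV must have columns ", paste(req, collapse = ", "))
  }
  df
}
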