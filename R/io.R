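#' Read and write the package's tab-separated file dialects
#'
#' All matrices travel as TSV with a header row and gene identifiers in the
#' first column (named `gene`).  Homology hits use an outfmt-6-like subset
#' with columns `qseqid`, `qspecies`, `sseqid`, `sspecies`, `evalue`.
#' Numeric matrices are written with 17 significant digits so a write/read
#' round trip reproduces the in-memory doubles exactly.
#'
#' @param x matrix with row names (gene IDs) and column names (sample IDs).
#' @param path file path.
#' @return `read_matrix_tsv()` returns a numeric matrix with gene row names;
#'   `write_matrix_tsv()` returns `path` invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), stringsAsFactors = FALSE)
  if (ncol(x) > 0) {
    vals <- apply(x, 2, function(col) {
      if (is.numeric(col) && !is.integer(col)) sprintf("%.17g", col)
      else as.character(col)
    })
    if (nrow(x) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, colnames(x)))
    if (nrow(x) == 0L) vals <- matrix(character(0), nrow = 0L, ncol = ncol(x),
                                      dimnames = list(NULL, colnames(x)))
    df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = NA,
                   stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read or write a gene-length table
#'
#' Two-column TSV (`gene`, `length`), lengths in base pairs.
#'
#' @param lengths named integer/numeric vector of gene lengths (bp).
#' @param path file path.
#' @return named numeric vector (read) or `path` invisibly (write).
#' @export
write_lengths_tsv <- function(lengths, path) {
  df <- data.frame(gene = names(lengths), length = as.integer(lengths))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lengths_tsv
#' @export
read_lengths_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.numeric(df$length), df$gene)
}

#' Read or write the sample metadata table
#'
#' Columns: `sample`, `species`, `limb` (fore/hind), `stage`
#' (ridge/bud/paddle), `replicate`.
#'
#' @param info data frame of sample metadata.
#' @param path file path.
#' @return data frame (read) or `path` invisibly (write).
#' @export
write_sample_info_tsv <- function(info, path) {
  write.table(info, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_info_tsv
#' @export
read_sample_info_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample", "species", "limb", "stage", "replicate")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stopf("sample table %s lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df
}

#' Read or write a homology hit table
#'
#' Tab-separated, outfmt-6-like subset: `qseqid`, `qspecies`, `sseqid`,
#' `sspecies`, `evalue`.
#'
#' @param hits data frame of homology hits.
#' @param path file path.
#' @return data frame (read) or `path` invisibly (write).
#' @export
write_homology_tsv <- function(hits, path) {
  hits$evalue <- sprintf("%.17g", hits$evalue)
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_homology_tsv
#' @export
read_homology_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("qseqid", "qspecies", "sseqid", "sspecies", "evalue")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stopf("homology table %s lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df$evalue <- as.numeric(df$evalue)
  df
}
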