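#' @importFrom stats pnorm pt qnorm rbinom rexp rnorm runif sd setNames
#'   median t.test p.adjust hclust cutree as.dist cor dist prcomp rlnorm
#'   pchisq complete.cases
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

`%|NA|%` <- function(x, y) {
  if (length(x) == 0L || is.na(x)) y else unname(x)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

#' Read a tab-separated expression matrix
#'
#' First column holds transcript keys, remaining columns one sample each.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with transcript rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param matrix Numeric matrix (transcripts x samples).
#' @param path Output path.
#' @param key_column Name for the leading key column.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(matrix, path, key_column = "transcript_key") {
  df <- data.frame(key = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- key_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared checks for the transcripts x samples container
validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression must be a numeric matrix", call. = FALSE)
  if (anyNA(m)) stop("expression matrix has missing cells", call. = FALSE)
  if (any(m < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("transcript keys must be unique", call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("sample ids must be unique", call. = FALSE)
  invisible(m)
}

# log2 with the pipeline's pseudocount
log2p <- function(x, pseudocount = 0.1) log2(x + pseudocount)
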