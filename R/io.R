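#' Read and write expression / annotation tables
#'
#' Expression files are genes x samples, tab- or comma-delimited, with a
#' header row of sample IDs and the gene symbol in the first column.
#' Annotation files map `sample_id` to `group` (`"reference"`/`"case"`) and
#' `stage`.
#'
#' @param path file path.
#' @return `read_expression()`: numeric matrix with gene rownames and sample
#'   colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene symbols in expression file: ",
         paste(utils::head(genes[duplicated(genes)], 3), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  m
}

#' @rdname read_expression
#' @param expr numeric matrix (genes x samples).
#' @return `write_expression()`: `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @return `read_annotations()`: data.frame with columns `sample_id`,
#'   `group`, `stage`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "stage")
  if (!all(req %in% names(ann)))
    stop("annotation table must have columns: ", paste(req, collapse = ", "))
  ann[, req]
}
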