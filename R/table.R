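#' Construct and validate a sample-by-taxon abundance table
#'
#' An abundance table is an ordinary numeric matrix with samples as rows and
#' taxa as columns, carrying unique row and column names and non-negative
#' integral read counts. This constructor validates those invariants and is
#' used by all readers; downstream functions accept any matrix that passes it.
#'
#' @param counts numeric matrix, samples x taxa, with dimnames.
#' @return the validated counts matrix (invisibly unchanged).
#' @examples
#' m <- matrix(c(5, 0, 0, 3), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("A", "B")))
#' abundance_table(m)
#' @export
abundance_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("abundance table must be a numeric matrix", call. = FALSE)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("abundance table is empty: need at least 1 sample and 1 taxon",
         call. = FALSE)
  sn <- rownames(counts); tn <- colnames(counts)
  if (is.null(sn) || is.null(tn))
    stop("abundance table must have sample (row) and taxon (column) names",
         call. = FALSE)
  dup <- unique(sn[duplicated(sn)])
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  dup <- unique(tn[duplicated(tn)])
  if (length(dup))
    stop("duplicate taxon identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("abundance table contains missing or non-numeric cells",
         call. = FALSE)
  if (any(counts < 0))
    stop("abundance table contains negative counts", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("abundance table contains non-integral counts", call. = FALSE)
  counts
}

#' Read a sample-by-taxon count table from TSV or BIOM-JSON
#'
#' Tab-separated tables carry identifiers in the header row and first column.
#' Files ending in `.biom` are parsed as BIOM format 1.0 (JSON, dense or
#' sparse) through the \pkg{biomformat} package; BIOM files declare their own
#' orientation (observations are taxa) so `orientation` is ignored for them.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"taxa_as_rows"`;
#'   the latter is transposed on read so the returned matrix is always
#'   samples x taxa.
#' @return validated samples x taxa count matrix.
#' @seealso [write_abundance_table()], [abundance_table()]
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_as_rows",
                                                 "taxa_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading .biom files requires the 'biomformat' package",
           call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
    return(abundance_table(t(m)))
  }
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) < 1L || ncol(df) < 2L)
    stop("empty or malformed table: ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric cell(s) in table: ", path, call. = FALSE)
  rownames(m) <- ids
  if (orientation == "taxa_as_rows") m <- t(m)
  abundance_table(m)
}

#' Write a sample-by-taxon count table as TSV
#'
#' @param table validated samples x taxa count matrix.
#' @param path output file path; the header's first column is `sample_id`.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  table <- abundance_table(table)
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
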