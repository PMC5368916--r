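#' Read a probes-by-samples matrix from TSV
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Errors on empty files, duplicate probe ids (naming the offender) and
#' non-numeric cells (naming the row and column).
#'
#' @param path TSV file path.
#' @return Numeric matrix with probe ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0 || ncol(dt) < 2) stop("no data rows in ", path)
  ids <- as.character(dt[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate probe id in ", path, ": ", dup[1])
  vals <- dt[, -1, drop = FALSE]
  for (cn in names(vals)) {
    col <- vals[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop("non-numeric value in ", path, " at row ", bad,
           " (probe ", ids[bad], "), column ", cn)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a probes-by-samples matrix as TSV
#'
#' First column `probe_id`, then one column per sample; full double
#' precision so that a write/read round trip reproduces values to 1e-12.
#'
#' @param x Matrix with rownames (probe ids) and colnames (sample ids).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
  dt <- data.table::data.table(probe_id = rownames(x))
  for (cn in colnames(x)) dt[[cn]] <- x[, cn]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read or write a plain table (TSV or CSV by extension)
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated. Missing values are encoded as empty fields.
#' @return `read_table_file`: a data.frame.
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                    na.strings = "")
}

#' @rdname read_table_file
#' @param x Data.frame to write.
#' @export
write_table_file <- function(x, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(x, path, sep = sep, na = "", quote = FALSE)
  invisible(path)
}
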