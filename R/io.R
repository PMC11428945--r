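#' Read a count table from TSV or dense-JSON BIOM
#'
#' TSV layout follows the common amplicon convention: first column holds
#' taxon IDs, remaining columns are samples (`orientation = "taxa_as_rows"`,
#' the default). Set `orientation = "samples_as_rows"` for the transposed
#' layout. The matrix is normalized internally to samples x taxa.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"` (dense JSON variant, read via the
#'   biomformat package).
#' @param orientation `"taxa_as_rows"` (default) or `"samples_as_rows"`.
#' @param taxonomy optional taxonomy data.frame to attach (see
#'   [read_taxonomy]).
#' @return A [count_table].
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             orientation = c("taxa_as_rows", "samples_as_rows"),
                             taxonomy = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_user("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop_user("BIOM input requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples in BIOM
    counts <- t(m)
  } else {
    raw <- tryCatch(
      utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                        stringsAsFactors = FALSE),
      error = function(e) stop_user("malformed TSV '", path, "': ", conditionMessage(e)))
    if (ncol(raw) < 2) stop_user("malformed TSV '", path, "': need an ID column plus data")
    ids <- as.character(raw[[1]])
    mat <- raw[, -1, drop = FALSE]
    for (j in seq_along(mat)) {
      v <- mat[[j]]
      if (is.character(v)) {
        suppressWarnings(num <- as.numeric(v))
        if (anyNA(num) & !anyNA(v)) {
          bad_line <- which(is.na(num))[1] + 1L  # +1 for header
          stop_user("malformed TSV '", path, "': non-numeric value in column '",
                    names(mat)[j], "' at line ", bad_line)
        }
        mat[[j]] <- num
      }
    }
    counts <- as.matrix(mat)
    rownames(counts) <- ids
    if (anyNA(counts)) {
      stop_user("missing count cells in '", path, "' (missing values are an error, not zero)")
    }
    if (orientation == "taxa_as_rows") counts <- t(counts)
  }
  count_table(counts, taxonomy = taxonomy)
}

#' Write a count table as TSV (taxa as rows)
#'
#' @param table a [count_table].
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  m <- t(table$counts)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with header; required columns `sample_id`, `group`,
#'   `timepoint`.
#' @return A validated metadata data.frame (see [validate_metadata]).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(md)
}

#' Read a taxonomy table from TSV
#'
#' @param path TSV with a `taxon_id` column plus rank columns
#'   (Phylum..Genus).
#' @return data.frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  tx <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"taxon_id" %in% names(tx)) stop_user("taxonomy TSV needs a 'taxon_id' column")
  tx
}

#' Write a result table deterministically
#'
#' Columns are written in the table's declared order; numeric columns are
#' rendered at a fixed number of significant digits so identical tables
#' produce byte-identical files. Any `p`/`q` columns are checked to lie in
#' \[0, 1\].
#'
#' @param table data.frame.
#' @param path output path.
#' @param digits significant digits for numeric columns (default 6).
#' @export
write_result <- function(table, path, digits = 6L) {
  stopifnot(is.data.frame(table))
  for (nm in intersect(c("p_value", "q_value", "p", "q"), names(table))) {
    v <- table[[nm]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop_user("column '", nm, "' outside [0, 1]")
  }
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !all(out[[j]] == round(out[[j]]), na.rm = TRUE)) {
      out[[j]] <- fmt_num(out[[j]], digits)
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_user("cannot write '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
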