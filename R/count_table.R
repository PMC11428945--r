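#' Construct a validated count table
#'
#' The canonical container for a sample x taxon matrix of sequencing counts.
#' Internally the orientation is always samples in rows, taxa in columns;
#' readers accept the taxa-as-rows convention common in amplicon workflows
#' and transpose on ingestion.
#'
#' @param counts numeric matrix of non-negative integers with unique
#'   rownames (sample IDs) and colnames (taxon IDs).
#' @param taxonomy optional data.frame mapping `taxon_id` to ranked lineage
#'   columns (any of Phylum, Class, Order, Family, Genus). All taxonomy
#'   keys must be taxa of the table.
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `taxonomy`.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_user("count table requires sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_user("duplicate sample IDs: ",
              paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop_user("duplicate taxon IDs: ",
              paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop_user("counts must be numeric with no missing values (missing cells are an error, not zero)")
  }
  if (any(counts < 0)) stop_user("negative counts are not allowed")
  if (any(counts != round(counts))) stop_user("counts must be integers")
  storage.mode(counts) <- "double"  # keeps grand totals > .Machine$integer.max safe
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    if (!"taxon_id" %in% names(taxonomy)) stop_user("taxonomy needs a 'taxon_id' column")
    extra <- setdiff(taxonomy$taxon_id, colnames(counts))
    if (length(extra)) stop_user("taxonomy keys absent from count table: ",
                                 paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$taxonomy)) {
    cat(sprintf("  taxonomy: %d classified taxa\n", nrow(x$taxonomy)))
  }
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

sample_ids <- function(x) rownames(x$counts)
taxon_ids <- function(x) colnames(x$counts)

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `group` (one of `control`, `stress`) and
#' `timepoint`; `sex` (one of `female`, `castrated_male`) and `pen` are
#' optional. Timepoint labels are ordered by their sorted unique values
#' unless already an ordered factor.
#'
#' @param metadata data.frame.
#' @return The validated data.frame with `group` a factor and `timepoint`
#'   an ordered factor.
#' @export
validate_metadata <- function(metadata) {
  required <- c("sample_id", "group", "timepoint")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop_user("metadata is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) stop_user("duplicate sample_id in metadata")
  bad <- setdiff(unique(as.character(metadata$group)), c("control", "stress"))
  if (length(bad)) stop_user("unknown group label(s): ", paste(bad, collapse = ", "),
                             " (allowed: control, stress)")
  if ("sex" %in% names(metadata)) {
    bad_sex <- setdiff(unique(as.character(metadata$sex)), c("female", "castrated_male"))
    if (length(bad_sex)) stop_user("unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  }
  metadata$group <- factor(as.character(metadata$group), levels = c("control", "stress"))
  if (!is.ordered(metadata$timepoint)) {
    metadata$timepoint <- factor(metadata$timepoint,
                                 levels = sort(unique(as.character(metadata$timepoint))),
                                 ordered = TRUE)
  }
  metadata
}

#' Align a count table with its metadata
#'
#' Every sample in the table must have exactly one metadata row; orphans on
#' either side are an error (counts side) or dropped with a message
#' (metadata side).
#'
#' @param table a [count_table].
#' @param metadata a validated metadata data.frame.
#' @return list(table, metadata) with metadata reordered to the sample order
#'   of the table.
#' @export
align_samples <- function(table, metadata) {
  metadata <- validate_metadata(metadata)
  orphans <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(orphans)) {
    stop_user("samples present in counts but missing from metadata: ",
              paste(orphans, collapse = ", "))
  }
  metadata <- metadata[match(sample_ids(table), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  list(table = table, metadata = metadata)
}
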