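#' Construct an OTU table
#'
#' An `otu_table` is a samples-by-taxa matrix of nonnegative counts with
#' unique sample and feature identifiers. Feature identifiers are opaque
#' taxonomy lineage strings (e.g. `"Family;Genus"`); no parsing is applied.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns. All
#'   entries must be nonnegative and finite. Row/column names are used as
#'   identifiers when `sample_ids`/`feature_ids` are not given.
#' @param sample_ids character vector of unique sample identifiers.
#' @param feature_ids character vector of unique feature identifiers.
#' @return an object of class `otu_table` with elements `counts`
#'   (dimnamed matrix), `sample_ids` and `feature_ids`.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      feature_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%d", seq_len(nrow(counts)))
  if (is.null(feature_ids))
    feature_ids <- sprintf("F%d", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  rownames(counts) <- sample_ids
  colnames(counts) <- feature_ids
  x <- structure(list(counts = counts, sample_ids = sample_ids,
                      feature_ids = feature_ids),
                 class = "otu_table")
  validate_otu_table(x)
  x
}

#' Validate an OTU table
#'
#' Checks the `otu_table` invariants: id vectors match the matrix
#' dimensions, ids are unique within each axis, and all entries are
#' finite and nonnegative. The first offending cell is named in the error.
#'
#' @param x an `otu_table`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_otu_table <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  if (length(x$sample_ids) != nrow(counts))
    stop("sample_ids length (", length(x$sample_ids),
         ") does not match row count (", nrow(counts), ")")
  if (length(x$feature_ids) != ncol(counts))
    stop("feature_ids length (", length(x$feature_ids),
         ") does not match column count (", ncol(counts), ")")
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  if (anyDuplicated(x$feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(x$feature_ids[duplicated(x$feature_ids)]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(counts))
    stop("invalid count at sample '", x$sample_ids[ij[1]], "', feature '",
         x$feature_ids[ij[2]], "': ", counts[bad[1]])
  }
  invisible(x)
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "features\n")
  cat("  zero fraction:", round(mean(x$counts == 0), 3), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Subset an OTU table by samples and/or features
#'
#' @param x an `otu_table`.
#' @param samples sample ids or indices (default all).
#' @param features feature ids or indices (default all).
#' @return the subset `otu_table`.
#' @export
subset_otu <- function(x, samples = NULL, features = NULL) {
  validate_otu_table(x)
  cc <- x$counts
  if (!is.null(samples)) cc <- cc[samples, , drop = FALSE]
  if (!is.null(features)) cc <- cc[, features, drop = FALSE]
  otu_table(cc)
}

.META_COLS <- c("sample_id", "patient_id", "condition", "specimen", "provenance")
.CONDITIONS <- c("AP", "CRC")
.SPECIMENS <- c("stool", "biopsy", "saliva")
.PROVENANCES <- c("real", "synthetic")

#' Construct and validate sample metadata
#'
#' One record per sample: patient of origin, condition (`AP` or `CRC`),
#' specimen (`stool`, `biopsy`, `saliva`) and provenance (`real` or
#' `synthetic`).
#'
#' @param sample_id,patient_id,condition,specimen,provenance vectors of
#'   equal length (recycled where length one).
#' @return a `data.frame` with the five metadata columns.
#' @export
sample_meta <- function(sample_id, patient_id, condition, specimen,
                        provenance = "real") {
  meta <- data.frame(sample_id = as.character(sample_id),
                     patient_id = as.character(patient_id),
                     condition = as.character(condition),
                     specimen = as.character(specimen),
                     provenance = as.character(provenance),
                     stringsAsFactors = FALSE)
  validate_sample_meta(meta)
  meta
}

#' Validate sample metadata, optionally against a table
#'
#' @param meta metadata `data.frame`.
#' @param table optional `otu_table`; when given, every sample id in the
#'   table must have exactly one metadata record.
#' @return `meta`, invisibly.
#' @export
validate_sample_meta <- function(meta, table = NULL) {
  missing_cols <- setdiff(.META_COLS, names(meta))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate metadata sample ids: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  bad_cond <- setdiff(unique(meta$condition), .CONDITIONS)
  if (length(bad_cond))
    stop("unknown condition value(s): ", paste(bad_cond, collapse = ", "))
  bad_spec <- setdiff(unique(meta$specimen), .SPECIMENS)
  if (length(bad_spec))
    stop("unknown specimen value(s): ", paste(bad_spec, collapse = ", "))
  bad_prov <- setdiff(unique(meta$provenance), .PROVENANCES)
  if (length(bad_prov))
    stop("unknown provenance value(s): ", paste(bad_prov, collapse = ", "))
  if (!is.null(table)) {
    orphan <- setdiff(table$sample_ids, meta$sample_id)
    if (length(orphan))
      stop("samples without metadata: ", paste(utils::head(orphan, 5), collapse = ", "))
  }
  invisible(meta)
}

#' Read an OTU table (and optional metadata) from TSV
#'
#' The native dialect is tab-separated with samples as rows and the first
#' column holding sample ids; `orientation = "features_as_rows"` accepts
#' the transposed dialect (first column feature ids, remaining columns one
#' per sample).
#'
#' @param path path to the counts TSV.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`.
#' @param meta_path optional path to a metadata TSV keyed by `sample_id`.
#' @return a list with `table` (an `otu_table`) and `meta` (a `data.frame`
#'   or `NULL`).
#' @export
read_otu_table <- function(path, orientation = c("samples_as_rows", "features_as_rows"),
                           meta_path = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("counts file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          check.names = FALSE, colClasses = list(character = 1))
  if (ncol(dt) < 1) stop("empty counts file: ", path)
  row_ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (ncol(mat) > 0 && !is.numeric(mat))
    stop("non-numeric count entries in ", path)
  storage.mode(mat) <- "double"
  rownames(mat) <- row_ids
  if (orientation == "features_as_rows") mat <- t(mat)
  tab <- otu_table(mat)
  meta <- NULL
  if (!is.null(meta_path)) {
    if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
    meta <- data.table::fread(meta_path, sep = "\t", header = TRUE,
                              data.table = FALSE, check.names = FALSE,
                              colClasses = "character")
    validate_sample_meta(meta, tab)
    meta <- meta[match(tab$sample_ids, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  list(table = tab, meta = meta)
}

#' Write an OTU table (and optional metadata) to TSV
#'
#' Column order is deterministic (the table's feature order); the file is
#' re-readable with [read_otu_table()] and round-trips integer counts
#' bit-exactly. Ids containing tabs or quotes are quoted.
#'
#' @param table an `otu_table`.
#' @param path output path for the counts TSV.
#' @param meta optional metadata `data.frame`.
#' @param meta_path output path for the metadata TSV (required when `meta`
#'   is given).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, meta = NULL, meta_path = NULL) {
  validate_otu_table(table)
  df <- data.frame(sample_id = table$sample_ids, stringsAsFactors = FALSE)
  cnt <- as.data.frame(table$counts, check.names = FALSE, optional = TRUE)
  rownames(cnt) <- NULL
  df <- cbind(df, cnt)
  data.table::fwrite(df, path, sep = "\t", quote = "auto", col.names = TRUE)
  if (!is.null(meta)) {
    if (is.null(meta_path)) stop("meta_path required when writing metadata")
    validate_sample_meta(meta, table)
    data.table::fwrite(meta, meta_path, sep = "\t", quote = "auto")
  }
  invisible(path)
}

#' Partition a dataset by metadata keys
#'
#' Splits an OTU table into disjoint groups whose union is the input;
#' the feature axis is unchanged. The empty key set yields a single group
#' named `"all"`.
#'
#' @param table an `otu_table`.
#' @param meta metadata covering every sample in `table`.
#' @param by character subset of `c("condition", "specimen", "provenance")`.
#' @return named list of groups, each a list with `table` and `meta`;
#'   names join the key values with `"."`.
#' @export
partition_otu <- function(table, meta, by = c("condition", "specimen")) {
  validate_otu_table(table)
  validate_sample_meta(meta, table)
  allowed <- c("condition", "specimen", "provenance")
  bad <- setdiff(by, allowed)
  if (length(bad)) stop("unknown grouping key(s): ", paste(bad, collapse = ", "))
  meta <- meta[match(table$sample_ids, meta$sample_id), , drop = FALSE]
  if (length(by) == 0) {
    return(list(all = list(table = table, meta = meta)))
  }
  key <- do.call(paste, c(meta[by], sep = "."))
  out <- lapply(split(seq_along(key), key), function(idx) {
    list(table = subset_otu(table, samples = idx),
         meta = {m <- meta[idx, , drop = FALSE]; rownames(m) <- NULL; m})
  })
  out
}
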