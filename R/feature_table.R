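#' Feature abundance tables
#'
#' A feature table is a tibble with a `sample_id` character column followed by
#' one numeric column per feature (genus, family, KEGG Ortholog, or KEGG
#' module). Values are RPKM (reads per kilobase per million), relative
#' abundances, or centered/scaled z-scores. The constructor validates the
#' shape and records what the columns and values are, so downstream
#' operations can check they are being fed the right kind of table.
#'
#' @param x A data frame whose first column is `sample_id` and whose remaining
#'   columns are numeric feature abundances.
#' @param feature_kind What the feature columns are: `"genus"`, `"family"`,
#'   `"ko"`, or `"module"`.
#' @param value_kind What the values are: `"rpkm"`, `"relative"`, or
#'   `"scaled"`. Negative values are only permitted for `"scaled"`.
#' @return A tibble of class `feature_table` with attributes `feature_kind`
#'   and `value_kind`.
#' @examples
#' ft <- feature_table(
#'   tibble::tibble(sample_id = c("a", "b"), gX = c(1, 2), gY = c(3, 0)),
#'   feature_kind = "genus", value_kind = "rpkm"
#' )
#' feature_ids(ft)
#' @export
feature_table <- function(x,
                          feature_kind = c("genus", "family", "ko", "module"),
                          value_kind = c("rpkm", "relative", "scaled")) {
  feature_kind <- match.arg(feature_kind)
  value_kind <- match.arg(value_kind)
  x <- as_tibble(x)
  if (ncol(x) < 1 || names(x)[1] != "sample_id") {
    msg_stop("bad-table", "first column must be 'sample_id'")
  }
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    msg_stop("bad-table", "duplicate sample ids: " %+%
               comma(unique(x$sample_id[duplicated(x$sample_id)])))
  }
  feats <- names(x)[-1]
  if (anyDuplicated(feats)) {
    msg_stop("bad-table", "duplicate feature ids: " %+%
               comma(unique(feats[duplicated(feats)])))
  }
  vals <- x[, -1, drop = FALSE]
  not_num <- feats[!vapply(vals, is.numeric, logical(1))]
  if (length(not_num)) {
    msg_stop("bad-table", "non-numeric feature columns: " %+% comma(not_num))
  }
  m <- as.matrix(vals)
  if (length(m) && any(!is.finite(m))) {
    msg_stop("bad-table", "non-finite values in feature table")
  }
  if (value_kind != "scaled" && length(m) && any(m < 0)) {
    msg_stop("bad-table", "negative abundances in a '" %+% value_kind %+% "' table")
  }
  structure(x,
    class = c("feature_table", class(as_tibble(x))),
    feature_kind = feature_kind, value_kind = value_kind
  )
}

`%+%` <- function(a, b) paste0(a, b)
comma <- function(x, max = 8) {
  x <- as.character(x)
  if (length(x) > max) x <- c(head(x, max), "...")
  paste(x, collapse = ", ")
}

#' @rdname feature_table
#' @export
feature_ids <- function(x) setdiff(names(x), "sample_id")

#' @rdname feature_table
#' @export
feature_kind <- function(x) attr(x, "feature_kind") %||% NA_character_

#' @rdname feature_table
#' @export
value_kind <- function(x) attr(x, "value_kind") %||% NA_character_

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the numeric abundance matrix from a feature table
#'
#' @param x A `feature_table` (or any tibble with a leading `sample_id`
#'   column and numeric feature columns).
#' @return A numeric matrix, samples in rows (named by `sample_id`),
#'   features in columns.
#' @export
ft_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

# Rebuild a feature_table from a samples x features matrix.
ft_from_matrix <- function(m, feature_kind, value_kind) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble(sample_id = rownames(m)) %>% dplyr::bind_cols(out)
  feature_table(out, feature_kind = feature_kind, value_kind = value_kind)
}

#' Sample metadata for a time series
#'
#' Validates and completes per-sample metadata: collection date, temporal
#' stage, and period (baseline vs post-disturbance). `year` and `month` are
#' derived from `date` when absent, and checked for consistency when present.
#'
#' @param x A data frame with columns `sample_id`, `date` (Date or ISO-8601
#'   string), `stage`, `period` (values `"baseline"` or `"post"`), and
#'   optionally `year` and `month`.
#' @return A validated tibble with columns `sample_id`, `date`, `year`,
#'   `month`, `stage`, `period`.
#' @export
sample_metadata <- function(x) {
  x <- as_tibble(x)
  need <- c("sample_id", "date", "stage", "period")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    msg_stop("bad-metadata", "missing columns: " %+% comma(missing_cols))
  }
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    msg_stop("bad-metadata", "duplicate sample ids: " %+%
               comma(x$sample_id[duplicated(x$sample_id)]))
  }
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) msg_stop("bad-metadata", "unparseable dates")
  yr <- as.integer(format(x$date, "%Y"))
  mo <- as.integer(format(x$date, "%m"))
  if (!"year" %in% names(x)) x$year <- yr
  if (!"month" %in% names(x)) x$month <- mo
  if (any(x$year != yr) || any(x$month != mo)) {
    msg_stop("bad-metadata", "year/month inconsistent with collection_date")
  }
  if (any(x$month < 1 | x$month > 12)) msg_stop("bad-metadata", "month outside 1..12")
  bad <- setdiff(unique(x$period), c("baseline", "post"))
  if (length(bad)) {
    msg_stop("bad-metadata", "period must be 'baseline' or 'post', got: " %+% comma(bad))
  }
  x[, c("sample_id", "date", "year", "month", "stage", "period")]
}

# Align metadata rows to a table's samples; error on missing samples.
align_metadata <- function(table, metadata) {
  metadata <- sample_metadata(metadata)
  miss <- setdiff(table$sample_id, metadata$sample_id)
  if (length(miss)) {
    msg_stop("bad-metadata", "samples without metadata: " %+% comma(miss))
  }
  metadata[match(table$sample_id, metadata$sample_id), ]
}

#' Read and write feature tables, maps, metadata, and panels
#'
#' Plain TSV interfaces. Feature tables have a `sample_id` first column and
#' one column per feature. Feature maps are two columns `child_id`,
#' `parent_id` (a child may repeat for one-to-many maps such as KO to KEGG
#' module). Metadata has `sample_id`, `date` (ISO-8601), `stage`, `period`.
#'
#' @param path File path.
#' @param feature_kind,value_kind Passed to [feature_table()].
#' @return `read_feature_table()` a `feature_table`; `read_feature_map()` a
#'   tibble `child_id`/`parent_id`; `read_sample_metadata()` a validated
#'   metadata tibble. Writers return `path` invisibly.
#' @export
read_feature_table <- function(path, feature_kind, value_kind = "rpkm") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "sample_id"
  feature_table(x, feature_kind = feature_kind, value_kind = value_kind)
}

#' @rdname read_feature_table
#' @param x Object to write.
#' @export
write_feature_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_feature_table
#' @export
read_feature_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  feature_map(x)
}

#' @rdname read_feature_table
#' @export
feature_map <- function(x) {
  x <- as_tibble(x)
  if (!all(c("child_id", "parent_id") %in% names(x))) {
    msg_stop("bad-map", "map needs columns child_id, parent_id")
  }
  x <- x[, c("child_id", "parent_id")]
  if (anyNA(x$parent_id) || any(x$parent_id == "")) {
    msg_stop("bad-map", "empty parent ids in map")
  }
  if (anyDuplicated(x)) x <- dplyr::distinct(x)
  x
}

#' @rdname read_feature_table
#' @export
read_sample_metadata <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sample_metadata(x)
}
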