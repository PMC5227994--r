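#' Write an abundance table or distance matrix to TSV
#'
#' One header row of feature (or sample) IDs, then one row per sample.
#' Numbers are written with 12 significant digits so that a write/read
#' round-trip is lossless for practical purposes.
#'
#' @param table an [abundance_table()] or [sample_dist()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(table, path) {
  if (inherits(table, "abundance_table")) {
    m <- table$values
    first_col <- "sample_id"
  } else if (inherits(table, "sample_dist")) {
    m <- table$D
    first_col <- "sample_id"
  } else stop("write_table expects an abundance_table or sample_dist")
  df <- data.frame(format(m, digits = 12, scientific = FALSE, trim = TRUE),
                   check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m)), first_col), df)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a TSV written by [write_table()] back into an abundance table
#'
#' @param path TSV path
#' @param kind `"count"`, `"relative"`, or `"auto"` (relative when every row
#'   sums to 100 within tolerance)
#' @return an [abundance_table()]
#' @export
read_table <- function(path, kind = c("auto", "count", "relative")) {
  kind <- match.arg(kind)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (kind == "auto") {
    rs <- rowSums(m)
    kind <- if (all(abs(rs - 100) < 1e-6 | rs == 0)) "relative" else "count"
  }
  abundance_table(m, kind = kind)
}

#' Read a distance-matrix TSV back into a `sample_dist`
#' @param path TSV path
#' @return a [sample_dist()]
#' @export
read_dist <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  sample_dist(m)
}

#' Read sample metadata (TSV, first column = sample_id)
#'
#' Factors may be character or numeric; numeric-looking columns are converted.
#'
#' @param path metadata TSV
#' @param sample_ids optional vector of sample IDs that must all be present
#' @return data.frame with rownames = sample IDs, one column per factor
#' @export
read_metadata <- function(path, sample_ids = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("metadata needs a sample_id column plus >= 1 factor")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in metadata")
  meta <- df[, -1, drop = FALSE]
  rownames(meta) <- ids
  for (j in seq_along(meta)) {
    v <- meta[[j]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) meta[[j]] <- num
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing))
      stop("metadata is missing samples: ", paste(missing, collapse = ", "))
  }
  meta
}

#' Read a sample manifest
#'
#' Two-column TSV (`sample_id`, `path`) with an optional third column `mode`
#' (`amplicon` or `shotgun`). Relative read paths are resolved against the
#' manifest's own directory.
#'
#' @param path manifest TSV
#' @param default_mode mode used when the third column is absent
#' @return data.frame with columns sample_id, path, mode
#' @export
read_manifest <- function(path, default_mode = "amplicon") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   header = TRUE)
  if (ncol(df) < 2L) stop("manifest needs columns: sample_id, path[, mode]")
  out <- data.frame(sample_id = as.character(df[[1]]),
                    path = as.character(df[[2]]),
                    mode = if (ncol(df) >= 3L) as.character(df[[3]])
                           else default_mode,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids in manifest")
  if (!all(out$mode %in% c("amplicon", "shotgun")))
    stop("manifest mode must be 'amplicon' or 'shotgun'")
  rel <- !grepl("^(/|[A-Za-z]:)", out$path)
  out$path[rel] <- file.path(dirname(path), out$path[rel])
  out
}
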