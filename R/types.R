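#' Construct a read set
#'
#' A read set holds all sequence records of one sample. Sequences are
#' normalized to the {A,C,G,T,N} alphabet on construction; record IDs must be
#' unique within the sample.
#'
#' @param sample_id non-empty sample identifier
#' @param ids character vector of record IDs (unique, non-empty)
#' @param seqs character vector of sequences (same length as `ids`)
#' @param quals optional character vector of per-base quality strings
#' @return an object of class `read_set` with elements `sample_id`, `ids`,
#'   `seqs`, `quals`
#' @export
read_set <- function(sample_id, ids, seqs, quals = NULL) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("sample_id must be a non-empty string")
  ids <- as.character(ids)
  seqs <- normalize_seq(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate read IDs in sample '", sample_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) && (any(!nzchar(ids)) || any(!nzchar(seqs))))
    stop("read IDs and sequences must be non-empty")
  if (!is.null(quals)) {
    quals <- as.character(quals)
    if (length(quals) != length(seqs) || any(nchar(quals) != nchar(seqs)))
      stop("quality strings must match sequence lengths")
  }
  structure(list(sample_id = sample_id, ids = ids, seqs = seqs, quals = quals),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$ids)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> sample '%s': %d records%s\n", x$sample_id,
              length(x$ids), if (is.null(x$quals)) "" else " (with qualities)"))
  invisible(x)
}

#' Construct a taxonomy path
#'
#' Five ranks (phylum, class, order, family, genus). The sentinel
#' `"Unclassified"` marks missing annotation; once a rank is unclassified all
#' deeper ranks must be too.
#'
#' @param ranks character vector of length 5
#' @return character vector of class `taxonomy_path`
#' @export
taxonomy_path <- function(ranks) {
  ranks <- as.character(ranks)
  if (length(ranks) != 5L) stop("a taxonomy path has exactly 5 ranks")
  uncl <- ranks == "Unclassified"
  if (any(uncl) && !all(uncl[which(uncl)[1]:5]))
    stop("ranks below an 'Unclassified' rank must also be 'Unclassified'")
  names(ranks) <- TAXONOMY_RANKS
  structure(ranks, class = "taxonomy_path")
}

#' Taxonomic ranks handled by the profiler, shallow to deep
#' @export
TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "genus")

#' Construct a samples-by-features abundance table
#'
#' @param values numeric matrix, samples in rows, features in columns
#' @param kind `"count"` or `"relative"`; relative rows are on the 0-100 scale
#'   and must each sum to 100 (or 0 for an empty sample)
#' @return object of class `abundance_table`
#' @export
abundance_table <- function(values, kind = c("count", "relative")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample (row) and feature (column) names")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids")
  if (any(values < 0)) stop("abundance values must be non-negative")
  if (kind == "relative") {
    rs <- rowSums(values)
    bad <- abs(rs - 100) > 1e-6 & rs != 0
    if (any(bad))
      stop("relative abundance rows must sum to 100: ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  structure(list(sample_ids = rownames(values),
                 feature_ids = colnames(values),
                 values = values, kind = kind),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d features (%s)\n",
              length(x$sample_ids), length(x$feature_ids), x$kind))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Construct a pairwise sample distance matrix
#'
#' Entries must be symmetric, zero on the diagonal, and within \[0, 1\]
#' (distances are 1 minus a bounded similarity).
#'
#' @param D symmetric numeric matrix with sample IDs as dimnames
#' @return object of class `sample_dist`
#' @export
sample_dist <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop("D must carry sample ids as dimnames")
  if (!isSymmetric(unname(D), tol = 1e-9)) stop("D must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  if (any(D < -1e-12 | D > 1 + 1e-9)) stop("distances must lie in [0, 1]")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D[D < 0] <- 0
  structure(list(sample_ids = rownames(D), D = D), class = "sample_dist")
}

#' @export
print.sample_dist <- function(x, ...) {
  cat(sprintf("<sample_dist> %d samples\n", length(x$sample_ids)))
  invisible(x)
}

#' Validate a reference database object
#'
#' Cross-checks that the phylogeny leaves, reference sequences, taxonomy and
#' copy numbers describe the same OTU universe, that every trait-bearing
#' (individually sequenced) taxon is a tree leaf, and that copy numbers are
#' positive integers.
#'
#' @param db a `reference_db` list
#' @return `db`, invisibly, if valid; otherwise an error
#' @export
validate_reference_db <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  otus <- sort(names(db$sequences))
  leaves <- sort(db$tree$tip.label)
  for (part in c("taxonomy", "copy_number")) {
    ids <- sort(names(db[[part]]))
    if (!identical(otus, ids))
      stop("reference database inconsistency: ", part,
           " ids differ from sequence ids (",
           paste(union(setdiff(otus, ids), setdiff(ids, otus)), collapse = ", "), ")")
  }
  if (!identical(otus, leaves))
    stop("reference database inconsistency: tree leaves differ from sequence ids (",
         paste(union(setdiff(otus, leaves), setdiff(leaves, otus)), collapse = ", "), ")")
  if (!all(names(db$traits) %in% leaves))
    stop("trait table contains non-leaf ids: ",
         paste(setdiff(names(db$traits), leaves), collapse = ", "))
  if (length(db$traits) == 0L)
    stop("reference database must contain at least one sequenced (trait-bearing) taxon")
  cn <- unlist(db$copy_number)
  if (any(cn < 1) || any(cn != round(cn)))
    stop("16S copy numbers must be integers >= 1")
  if (any(db$tree$edge.length < 0) || any(!is.finite(db$tree$edge.length)))
    stop("tree branch lengths must be finite and non-negative")
  invisible(db)
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf(
    "<reference_db> %d OTUs (%d sequenced), %d KOs, %d pathways\n",
    length(x$sequences), length(x$traits),
    length(x$ko_ids), length(unique(unlist(x$pathway_map)))))
  invisible(x)
}
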