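#' Copy-number-calibrated relative abundances for one sample
#'
#' 16S copy number varies widely across bacteria, so raw 16S read counts
#' over-represent high-copy organisms. With calibration enabled the relative
#' abundance of OTU i is `100 * (n_i / k_i) / sum_j (n_j / k_j)` where `k_i`
#' is its 16S copies per genome; disabled, it is the plain normalized count.
#' An empty sample yields all zeros.
#'
#' @param counts named OTU count vector aligned to the database OTU IDs
#' @param db a `reference_db` supplying the copy numbers
#' @param enabled apply copy-number calibration? (default TRUE)
#' @return object of class `calibrated_abundance`: list with `abundance`
#'   (0-100 scale, named), `counts`, `copy_number`, `calibrated`
#' @export
calibrate_copy_number <- function(counts, db, enabled = TRUE) {
  stopifnot(inherits(db, "reference_db"))
  if (any(counts < 0)) stop("counts must be non-negative")
  otus <- names(db$sequences)
  if (is.null(names(counts)) || !all(names(counts) %in% otus))
    stop("counts must be named by database OTU ids")
  full <- stats::setNames(numeric(length(otus)), otus)
  full[names(counts)] <- counts
  k <- db$copy_number[otus]
  w <- if (enabled) full / k else full
  total <- sum(w)
  abundance <- if (total > 0) 100 * w / total else w * 0
  structure(list(abundance = abundance, counts = full,
                 copy_number = k, calibrated = enabled),
            class = "calibrated_abundance")
}

#' Roll a sample's OTU abundances up to a taxonomic level
#'
#' A taxon's abundance is the sum of its member OTUs' abundances;
#' `"Unclassified"` at the level forms its own bucket. Row sums are
#' preserved exactly.
#'
#' @param abund a [calibrate_copy_number()] result or a named abundance vector
#' @param db a `reference_db` supplying the taxonomy
#' @param level one of `r toString(TAXONOMY_RANKS)`
#' @return named numeric vector of taxon abundances
#' @export
rollup_taxonomy <- function(abund, db, level = "genus") {
  stopifnot(inherits(db, "reference_db"))
  level <- match.arg(level, TAXONOMY_RANKS)
  a <- if (inherits(abund, "calibrated_abundance")) abund$abundance else abund
  missing <- setdiff(names(a), names(db$taxonomy))
  if (length(missing)) stop("no taxonomy for OTUs: ",
                            paste(missing, collapse = ", "))
  labels <- vapply(db$taxonomy[names(a)], function(tp) unclass(tp)[[level]],
                   character(1))
  rolled <- tapply(a, labels, sum)
  stats::setNames(as.numeric(rolled), names(rolled))
}

#' Rarefy an OTU count vector to a fixed depth
#'
#' Draws `depth` reads without replacement (multivariate hypergeometric).
#' Deterministic given the seed.
#'
#' @param counts non-negative integer count vector
#' @param depth target depth (1 <= depth <= sum(counts))
#' @param seed RNG seed
#' @return rarefied count vector summing to `depth`, same names
#' @export
rarefy <- function(counts, depth, seed = 1) {
  if (depth <= 0) stop("rarefaction depth must be positive")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("rarefaction needs non-negative integer counts")
  total <- sum(counts)
  if (depth > total)
    stop("rarefaction depth ", depth, " exceeds sample total ", total)
  if (depth == total) return(counts)
  idx <- rep.int(seq_along(counts), counts)
  drawn <- with_seed(seed, sample(idx, depth, replace = FALSE))
  out <- tabulate(drawn, nbins = length(counts))
  stats::setNames(as.numeric(out), names(counts))
}

#' Build the per-level relative abundance tables for a set of samples
#'
#' Produces one samples-by-features table for the OTU level and for each of
#' the five taxonomy levels, every row on the 0-100 scale (all-zero rows for
#' samples with no assigned reads).
#'
#' @param abundances named list of [calibrate_copy_number()] results (names =
#'   sample IDs)
#' @param db a `reference_db`
#' @return named list of [abundance_table()]s: `otu`, then one per rank
#' @export
build_profile_tables <- function(abundances, db) {
  stopifnot(inherits(db, "reference_db"))
  ids <- names(abundances)
  if (is.null(ids) || anyDuplicated(ids)) stop("duplicate or missing sample ids")
  otus <- names(db$sequences)
  otu_m <- do.call(rbind, lapply(abundances, function(a) a$abundance[otus]))
  rownames(otu_m) <- ids
  colnames(otu_m) <- otus
  out <- list(otu = abundance_table(otu_m, kind = "relative"))
  for (level in TAXONOMY_RANKS) {
    rows <- lapply(abundances, rollup_taxonomy, db = db, level = level)
    feats <- sort(unique(unlist(lapply(rows, names))))
    m <- matrix(0, nrow = length(ids), ncol = length(feats),
                dimnames = list(ids, feats))
    for (s in ids) m[s, names(rows[[s]])] <- rows[[s]]
    out[[level]] <- abundance_table(m, kind = "relative")
  }
  out
}
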