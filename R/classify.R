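kmer_strings <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  ks <- substring(seq, 1:(L - k + 1), k:L)
  ks[!grepl("N", ks, fixed = TRUE)]
}

#' Build a k-mer prefilter index over the reference sequences
#'
#' Indexes every k-mer of every reference (forward strand only). k-mers
#' containing N are skipped. References shorter than k yield no postings and
#' produce a warning.
#'
#' @param db a `reference_db`
#' @param k k-mer size (>= 4); the default is a standard seed-length scale
#' @return object of class `kmer_index` with the shared-k-mer postings and
#'   per-reference k-mer position maps used for banded alignment seeding
#' @export
build_kmer_index <- function(db, k = 12) {
  stopifnot(inherits(db, "reference_db"))
  if (k < 4) stop("k must be >= 4")
  if (length(db$sequences) == 0L) stop("reference database has no sequences")
  postings <- new.env(hash = TRUE, parent = emptyenv())
  positions <- list()
  for (otu in names(db$sequences)) {
    seq <- db$sequences[[otu]]
    if (nchar(seq) < k) {
      warning("reference '", otu, "' is shorter than k = ", k,
              " and enters no postings")
      next
    }
    ks <- kmer_strings(seq, k)
    pos_env <- new.env(hash = TRUE, parent = emptyenv())
    starts <- which(!grepl("N", substring(seq, 1:(nchar(seq) - k + 1),
                                          k:nchar(seq)), fixed = TRUE))
    for (idx in seq_along(ks)) {
      km <- ks[idx]
      postings[[km]] <- unique(c(postings[[km]], otu))
      pos_env[[km]] <- c(pos_env[[km]], starts[idx] - 1L) # 0-based
    }
    positions[[otu]] <- pos_env
  }
  structure(list(k = as.integer(k), postings = postings, positions = positions),
            class = "kmer_index")
}

#' Look up the postings of one k-mer
#' @param index a `kmer_index`
#' @param kmer k-mer string
#' @return character vector of OTU IDs containing the k-mer
#' @export
kmer_postings <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  index$postings[[kmer]] %||% character()
}

#' Semi-global identity between a read and a reference
#'
#' The read is aligned end-to-end, the reference locally (overhangs free),
#' with unit match/mismatch/indel costs. The dynamic program is restricted to
#' a band of `band` reference positions around the best shared-k-mer diagonal
#' (the full matrix when the band covers it). Identity is matches divided by
#' the alignment columns spanning the read, so indels count against identity;
#' N never matches.
#'
#' @param read,ref sequence strings
#' @param band band half-width in reference positions (>= 1)
#' @param diag_center optional 0-based reference offset to centre the band on;
#'   when `NULL` it is estimated from shared 8-mers
#' @return list with `identity` (in \[0,1\]) and `columns` (aligned length)
#' @export
align_semi_global <- function(read, ref, band = 15, diag_center = NULL) {
  if (!nzchar(read) || !nzchar(ref)) stop("sequences must be non-empty")
  if (band < 1) stop("band must be >= 1")
  read <- normalize_seq(read)
  ref <- normalize_seq(ref)
  m <- nchar(read); n <- nchar(ref)
  if (is.null(diag_center)) {
    k <- max(4L, min(8L, m, n))
    rk <- kmer_strings(read, k)
    diags <- integer()
    if (length(rk)) {
      ref_k <- kmer_strings(ref, k)
      ref_start <- which(!grepl("N", substring(ref, 1:(n - k + 1), k:n),
                                fixed = TRUE)) - 1L
      hit <- match(rk, ref_k)
      ok <- !is.na(hit)
      diags <- ref_start[hit[ok]] - (which(ok) - 1L)
    }
    diag_center <- if (length(diags)) round(median(diags))
                   else max(0L, floor((n - m) / 2))
  }
  diag_center <- max(0L, min(as.integer(diag_center), n))
  res <- .semiglobal_identity(encode_seq(read), encode_seq(ref),
                              diag_center - as.integer(band),
                              diag_center + m + as.integer(band))
  list(identity = res$identity, columns = res$columns, matches = res$matches)
}

#' Assign reads to reference OTUs at an identity threshold
#'
#' For each read, candidate references are ranked by shared k-mer count,
#' checking both the forward read and its reverse complement and keeping the
#' better orientation. The top candidates are aligned with
#' [align_semi_global()]; the best identity wins, with ties broken by the
#' lexicographically smallest OTU ID. A read is assigned only when the best
#' identity reaches `identity_min` (OTU picking at the 97% level by default).
#'
#' @param reads a [read_set()]
#' @param db the `reference_db` the index was built from
#' @param index a [build_kmer_index()] result
#' @param identity_min minimum identity for assignment (default 0.97)
#' @param top_candidates number of k-mer candidates to align (default 20)
#' @param band band half-width for the alignment (default 15)
#' @return data.frame with columns read_id, otu_id (`"UNASSIGNED"` when below
#'   threshold), identity, strand
#' @export
assign_reads <- function(reads, db, index, identity_min = 0.97,
                         top_candidates = 20, band = 15) {
  stopifnot(inherits(reads, "read_set"), inherits(db, "reference_db"),
            inherits(index, "kmer_index"))
  k <- index$k
  n_reads <- length(reads$ids)
  otu_id <- rep("UNASSIGNED", n_reads)
  identity <- rep(NA_real_, n_reads)
  strand <- rep(NA_character_, n_reads)
  ref_codes <- lapply(db$sequences, encode_seq)

  for (i in seq_len(n_reads)) {
    fw <- reads$seqs[i]
    rc <- revcomp(fw)
    cand <- best_orientation_candidates(fw, rc, index, top_candidates)
    if (length(cand$otus) == 0L) next
    strand[i] <- cand$strand
    read_seq <- if (cand$strand == "+") fw else rc
    read_code <- encode_seq(read_seq)
    m <- nchar(read_seq)
    best_id <- -1
    best_otu <- NA_character_
    for (otu in cand$otus) {
      centre <- seed_diagonal(read_seq, index$positions[[otu]], k)
      centre <- if (is.na(centre)) max(0L, floor((nchar(db$sequences[[otu]]) - m) / 2))
                else centre
      res <- .semiglobal_identity(read_code, ref_codes[[otu]],
                                  centre - as.integer(band),
                                  centre + m + as.integer(band))
      if (res$identity > best_id ||
          (res$identity == best_id && otu < best_otu)) {
        best_id <- res$identity
        best_otu <- otu
      }
    }
    identity[i] <- best_id
    if (best_id >= identity_min) otu_id[i] <- best_otu
  }
  data.frame(read_id = reads$ids, otu_id = otu_id, identity = identity,
             strand = strand, stringsAsFactors = FALSE)
}

# Shared-k-mer vote: returns the better orientation and its top candidates,
# ties broken by lexicographic OTU order.
best_orientation_candidates <- function(fw, rc, index, top_candidates) {
  tally <- function(seq) {
    ks <- kmer_strings(seq, index$k)
    if (!length(ks)) return(integer())
    hits <- unlist(lapply(ks, function(km) index$postings[[km]]),
                   use.names = FALSE)
    if (is.null(hits) || !length(hits)) return(integer())
    sort(table(hits), decreasing = TRUE)
  }
  tf <- tally(fw); tr <- tally(rc)
  if (sum(tf) >= sum(tr)) { t <- tf; s <- "+" } else { t <- tr; s <- "-" }
  if (!length(t)) return(list(strand = s, otus = character()))
  ord <- order(-as.integer(t), names(t))
  list(strand = s, otus = names(t)[ord][seq_len(min(top_candidates, length(t)))])
}

# Median shared-k-mer diagonal (0-based ref offset) of read vs one reference.
seed_diagonal <- function(read, pos_env, k) {
  if (is.null(pos_env)) return(NA_integer_)
  L <- nchar(read)
  if (L < k) return(NA_integer_)
  ks <- substring(read, 1:(L - k + 1), k:L)
  diags <- integer()
  for (idx in seq_along(ks)) {
    p <- pos_env[[ks[idx]]]
    if (!is.null(p)) diags <- c(diags, p - (idx - 1L))
  }
  if (!length(diags)) return(NA_integer_)
  as.integer(round(median(diags)))
}

#' Tally OTU counts from one sample's assignments
#'
#' @param assignments data.frame from [assign_reads()]
#' @param db the `reference_db` (fixes the OTU universe; zeros included)
#' @return list with `counts` (named vector over all db OTUs) and
#'   `unassigned` (number of unassigned reads)
#' @export
counts_from_assignments <- function(assignments, db) {
  stopifnot(inherits(db, "reference_db"))
  otus <- names(db$sequences)
  assigned <- assignments$otu_id[assignments$otu_id != "UNASSIGNED"]
  bad <- setdiff(assigned, otus)
  if (length(bad)) stop("assignments reference unknown OTUs: ",
                        paste(unique(bad), collapse = ", "))
  counts <- stats::setNames(as.numeric(table(factor(assigned, levels = otus))),
                            otus)
  list(counts = counts, unassigned = sum(assignments$otu_id == "UNASSIGNED"))
}
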