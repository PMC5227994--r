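#' Read sequences from a FASTA or FASTQ file
#'
#' Reads one sample's worth of reads. Lowercase bases are uppercased, U is
#' mapped to T, and any other non-ACGT symbol becomes N. Malformed records
#' raise a parse error naming the offending line.
#'
#' @param path path to the sequence file
#' @param format `"fasta"` or `"fastq"`; `"auto"` guesses from the first
#'   character (`>` vs `@`) and the file extension
#' @param sample_id sample identifier; defaults to the file base name
#' @return a [read_set()]
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  if (format == "auto") {
    first <- substr(lines[nzchar(lines)][1] %||% "", 1, 1)
    format <- if (identical(first, ">")) "fasta"
              else if (identical(first, "@")) "fastq"
              else stop("cannot guess sequence format of ", path)
  }
  if (format == "fasta") parse_fasta(lines, sample_id, path)
  else parse_fastq(lines, sample_id, path)
}

parse_fasta <- function(lines, sample_id, path = "<fasta>") {
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) return(read_set(sample_id, character(), character()))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop(path, " line ", lineno[1], ": expected a '>' header")
  grp <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste, character(1), collapse = "")
  seqs <- seqs[match(seq_along(ids), as.integer(names(seqs)))]
  empty <- is.na(seqs) | !nzchar(seqs)
  if (any(empty))
    stop(path, " line ", lineno[is_hdr][which(empty)[1]],
         ": record '", ids[which(empty)[1]], "' has no sequence")
  names(seqs) <- NULL
  read_set(sample_id, ids, seqs)
}

parse_fastq <- function(lines, sample_id, path = "<fastq>") {
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(path, " line ", n, ": truncated FASTQ record (line count not a multiple of 4)")
  if (n == 0L) return(read_set(sample_id, character(), character()))
  rec <- matrix(lines, nrow = 4L)
  hdr_at <- seq(1L, n, by = 4L)
  bad_hdr <- !startsWith(rec[1, ], "@")
  if (any(bad_hdr))
    stop(path, " line ", hdr_at[which(bad_hdr)[1]], ": expected '@' header")
  bad_plus <- !startsWith(rec[3, ], "+")
  if (any(bad_plus))
    stop(path, " line ", hdr_at[which(bad_plus)[1]] + 2L,
         ": expected '+' separator")
  bad_len <- nchar(rec[2, ]) != nchar(rec[4, ])
  if (any(bad_len))
    stop(path, " line ", hdr_at[which(bad_len)[1]] + 3L,
         ": quality length differs from sequence length")
  ids <- sub("\\s.*$", "", sub("^@", "", rec[1, ]))
  read_set(sample_id, ids, rec[2, ], quals = rec[4, ])
}

#' Write a read set to FASTA (or FASTQ when qualities are present)
#'
#' @param reads a [read_set()]
#' @param path output file path
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities
#' @return `path`, invisibly
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(reads, "read_set"))
  if (format == "fastq") {
    if (is.null(reads$quals)) stop("cannot write FASTQ without qualities")
    out <- as.vector(rbind(paste0("@", reads$ids), reads$seqs, "+", reads$quals))
  } else {
    out <- as.vector(rbind(paste0(">", reads$ids), reads$seqs))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an aligned FASTA file as a character matrix (one row per sequence)
#'
#' Gaps (`-` or `.`) are preserved; bases are normalized. All sequences must
#' have equal aligned length.
#' @param path aligned FASTA path
#' @return character matrix of single characters, rownames = sequence IDs
#' @export
read_alignment <- function(path) {
  rs <- read_sequences_msa(path)
  lens <- nchar(rs$seqs)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(rs$seqs, "", fixed = TRUE))
  rownames(m) <- rs$ids
  m
}

# FASTA parse that keeps gap characters (read_set would normalize them to N).
read_sequences_msa <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  is_hdr <- startsWith(lines, ">")
  if (!length(lines) || !is_hdr[1]) stop("malformed aligned FASTA: ", path)
  grp <- cumsum(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste, character(1), collapse = "")
  seqs <- toupper(seqs[match(seq_along(ids), as.integer(names(seqs)))])
  seqs <- chartr("U.", "T-", seqs)
  seqs <- gsub("[^ACGT-]", "N", seqs)
  list(ids = ids, seqs = unname(seqs))
}
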