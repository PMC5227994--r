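REFDB_FILES <- c(sequences = "refs.fasta", taxonomy = "taxonomy.tsv",
                 tree = "tree.nwk", copy_number = "copy_number.tsv",
                 traits = "traits.tsv", pathway_map = "pathway_map.tsv")

#' Load a reference database directory
#'
#' The directory must contain `refs.fasta` (reference 16S sequences),
#' `taxonomy.tsv` (otu_id + five rank columns), `tree.nwk` (rooted phylogeny
#' with branch lengths over the same OTU IDs), `copy_number.tsv` (otu_id,
#' copies), `traits.tsv` (KO gene-copy counts for the individually sequenced
#' taxa; one row per taxon, one column per KO), and `pathway_map.tsv`
#' (ko_id, comma-separated pathway IDs). All cross-file invariants are
#' checked at load.
#'
#' @param dir reference database directory
#' @return object of class `reference_db`
#' @export
read_reference_db <- function(dir) {
  paths <- file.path(dir, REFDB_FILES)
  missing <- REFDB_FILES[!file.exists(paths)]
  if (length(missing))
    stop("reference database directory ", dir, " is missing: ",
         paste(missing, collapse = ", "))
  names(paths) <- names(REFDB_FILES)

  rs <- read_sequences(paths["sequences"], format = "fasta", sample_id = "refdb")
  sequences <- stats::setNames(rs$seqs, rs$ids)

  tx <- read.delim(paths["taxonomy"], stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!identical(tolower(names(tx))[-1], TAXONOMY_RANKS))
    stop("taxonomy.tsv must have columns: otu_id, ",
         paste(TAXONOMY_RANKS, collapse = ", "))
  taxonomy <- lapply(seq_len(nrow(tx)), function(i)
    taxonomy_path(as.character(tx[i, -1])))
  names(taxonomy) <- as.character(tx[[1]])

  tree <- ape::read.tree(paths["tree"])
  if (is.null(tree$edge.length)) stop("tree.nwk must carry branch lengths")
  if (!ape::is.rooted(tree)) stop("tree.nwk must be rooted")

  cn <- read.delim(paths["copy_number"], stringsAsFactors = FALSE)
  copy_number <- stats::setNames(as.numeric(cn[[2]]), as.character(cn[[1]]))
  if (any(copy_number < 1 | copy_number != round(copy_number)))
    stop("copy_number.tsv: 16S copy numbers must be integers >= 1 (offending: ",
         paste(cn[[1]][copy_number < 1 | copy_number != round(copy_number)],
               collapse = ", "), ")")

  tr <- read.delim(paths["traits"], check.names = FALSE,
                   stringsAsFactors = FALSE)
  ko_ids <- colnames(tr)[-1]
  trait_m <- as.matrix(tr[, -1, drop = FALSE])
  rownames(trait_m) <- as.character(tr[[1]])
  storage.mode(trait_m) <- "double"
  if (any(trait_m < 0)) stop("traits.tsv: gene copy counts must be >= 0")
  traits <- lapply(seq_len(nrow(trait_m)), function(i) trait_m[i, ])
  names(traits) <- rownames(trait_m)

  pm <- read.delim(paths["pathway_map"], stringsAsFactors = FALSE)
  pathway_map <- lapply(strsplit(as.character(pm[[2]]), ",", fixed = TRUE),
                        function(p) p[nzchar(p)])
  names(pathway_map) <- as.character(pm[[1]])
  pathway_map <- pathway_map[ko_ids[ko_ids %in% names(pathway_map)]]
  # KOs absent from the map map to no pathway
  for (k in setdiff(ko_ids, names(pathway_map))) pathway_map[[k]] <- character()

  db <- structure(list(sequences = sequences, taxonomy = taxonomy, tree = tree,
                       copy_number = copy_number, traits = traits,
                       ko_ids = ko_ids, pathway_map = pathway_map,
                       dir = normalizePath(dir)),
                  class = "reference_db")
  validate_reference_db(db)
  db
}

#' Write a reference database object to a directory
#'
#' Produces the exact file layout consumed by [read_reference_db()].
#'
#' @param db a `reference_db`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_reference_db <- function(db, dir) {
  validate_reference_db(db)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(as.vector(rbind(paste0(">", names(db$sequences)),
                             unname(db$sequences))),
             file.path(dir, "refs.fasta"))
  tx <- do.call(rbind, lapply(db$taxonomy, unclass))
  tx <- data.frame(otu_id = names(db$taxonomy), tx,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write.table(tx, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(db$tree, file.path(dir, "tree.nwk"))
  write.table(data.frame(otu_id = names(db$copy_number),
                         copies = as.integer(db$copy_number)),
              file.path(dir, "copy_number.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  trait_m <- do.call(rbind, db$traits)
  tr <- data.frame(otu_id = names(db$traits), trait_m,
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(tr) <- c("otu_id", db$ko_ids)
  write.table(tr, file.path(dir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pm <- data.frame(ko_id = names(db$pathway_map),
                   pathways = vapply(db$pathway_map, paste, character(1),
                                     collapse = ","))
  write.table(pm, file.path(dir, "pathway_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
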