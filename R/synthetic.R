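#' Generate a synthetic reference database
#'
#' Builds the complete prior-knowledge bundle the profiler consumes: a random
#' rooted bifurcating phylogeny (exponential branch lengths, mean 0.05), a
#' uniform-random root 16S sequence evolved leaf-ward with per-branch
#' substitution probability `1 - exp(-length)`, taxonomy assigned by nested
#' clade cuts at five depth thresholds, 16S copy numbers uniform on
#' `{1..10}`, KO trait vectors (gene copies 0-5 over `n_ko` KOs) for about
#' `frac_sequenced` of the leaves (these are the "individually sequenced"
#' taxa), and a KO-to-pathway map assigning each KO to 1-2 of `n_pathways`
#' pathways. Because the error model has no indels the true multiple
#' alignment is the sequences themselves. Fully deterministic given the seed.
#'
#' @param n_taxa number of reference OTUs (>= 4)
#' @param seq_len 16S sequence length (>= 100)
#' @param seed RNG seed
#' @param mean_branch mean branch length (default 0.05 substitutions/site)
#' @param frac_sequenced fraction of leaves with trait vectors (default 0.7)
#' @param n_ko,n_pathways trait-table dimensions (defaults 20 and 5)
#' @param frac_unclassified fraction of leaves left Unclassified at the genus
#'   level (default 0.1)
#' @return list with `db` (a `reference_db`) and `msa` (character matrix,
#'   the true reference alignment)
#' @export
make_reference_db <- function(n_taxa, seq_len, seed = 1, mean_branch = 0.05,
                              frac_sequenced = 0.7, n_ko = 20, n_pathways = 5,
                              frac_unclassified = 0.1) {
  if (n_taxa < 4) stop("n_taxa must be >= 4")
  if (seq_len < 100) stop("seq_len must be >= 100")
  with_seed(seed, {
    otus <- sprintf("OTU_%02d", seq_len(n_taxa))
    tree <- ape::rtree(n_taxa, rooted = TRUE,
                       br = function(n) rexp(n, rate = 1 / mean_branch))
    tree$tip.label <- otus[as.integer(sub("t", "", tree$tip.label))]

    # evolve sequences root -> leaves (substitution-only, so MSA = sequences)
    n_node <- n_taxa + tree$Nnode
    root <- n_taxa + 1L
    seqs_code <- vector("list", n_node)
    seqs_code[[root]] <- sample(0:3, seq_len, replace = TRUE)
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      p_sub <- 1 - exp(-lens[e])
      s <- seqs_code[[parent]]
      hit <- which(runif(seq_len) < p_sub)
      if (length(hit))
        s[hit] <- (s[hit] + sample(1:3, length(hit), replace = TRUE)) %% 4L
      seqs_code[[child]] <- s
    }
    sequences <- stats::setNames(
      vapply(seq_len(n_taxa), function(i) decode_seq(seqs_code[[i]]),
             character(1)),
      tree$tip.label)[otus]

    taxonomy <- clade_cut_taxonomy(tree, frac_unclassified)

    copy_number <- stats::setNames(sample(1:10, n_taxa, replace = TRUE), otus)

    n_seq <- max(1L, round(frac_sequenced * n_taxa))
    sequenced <- sort(sample(otus, n_seq))
    ko_ids <- sprintf("K%05d", seq_len(n_ko))
    traits <- lapply(sequenced, function(o)
      stats::setNames(sample(0:5, n_ko, replace = TRUE), ko_ids))
    names(traits) <- sequenced

    pathway_ids <- sprintf("path%03d", seq_len(n_pathways))
    pathway_map <- lapply(ko_ids, function(k)
      sort(sample(pathway_ids, sample(1:2, 1))))
    names(pathway_map) <- ko_ids

    db <- structure(list(sequences = sequences, taxonomy = taxonomy,
                         tree = tree, copy_number = copy_number,
                         traits = traits, ko_ids = ko_ids,
                         pathway_map = pathway_map, dir = NA_character_),
                    class = "reference_db")
    validate_reference_db(db)
    msa <- do.call(rbind, strsplit(unname(sequences), "", fixed = TRUE))
    rownames(msa) <- names(sequences)
    list(db = db, msa = msa)
  })
}

# Nested taxonomy labels from clade cuts at increasing depth fractions.
clade_cut_taxonomy <- function(tree, frac_unclassified) {
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  maxd <- max(depths[seq_len(n_tip)])
  cuts <- c(0.15, 0.30, 0.45, 0.60, 0.75) * maxd
  # ancestor chain (root..leaf) per leaf
  parent_of <- integer(n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  labels <- matrix("", nrow = n_tip, ncol = 5)
  for (i in seq_len(n_tip)) {
    chain <- i
    while (chain[1] != root) chain <- c(parent_of[chain[1]], chain)
    for (r in 1:5) {
      crossing <- chain[which(depths[chain] >= cuts[r])[1]]
      if (is.na(crossing)) crossing <- i
      labels[i, r] <- paste0(c("p", "c", "o", "f", "g")[r], "__T", crossing)
    }
  }
  uncl <- runif(n_tip) < frac_unclassified
  labels[uncl, 5] <- "Unclassified"
  out <- lapply(seq_len(n_tip), function(i) taxonomy_path(labels[i, ]))
  names(out) <- tree$tip.label
  out
}

#' Two-group community designs over nine organisms
#'
#' Emulates a ten-sample simulated-shotgun study: two base proportion
#' profiles over the same nine organisms with disjoint dominant members, and
#' five samples per group drawn as Dirichlet jitter (concentration 50)
#' around the group's base profile.
#'
#' @param db a `reference_db` with >= 9 taxa
#' @param seed RNG seed
#' @param n_per_group samples per group (default 5)
#' @return data.frame of designs: sample_id, group, then one proportion
#'   column per organism (rows sum to 1)
#' @export
make_fig_design <- function(db, seed = 1, n_per_group = 5) {
  stopifnot(inherits(db, "reference_db"))
  otus <- names(db$sequences)
  if (length(otus) < 9L) stop("reference database needs >= 9 taxa")
  organisms <- otus[seq_len(9)]
  base1 <- c(0.30, 0.22, 0.18, 0.06, 0.06, 0.06, 0.04, 0.04, 0.04)
  base2 <- rev(base1)  # dominant members disjoint from group 1's
  with_seed(seed, {
    rows <- list()
    for (g in 1:2) {
      base <- if (g == 1) base1 else base2
      for (s in seq_len(n_per_group)) {
        gam <- rgamma(9, shape = 50 * base, rate = 1)
        props <- gam / sum(gam)
        rows[[length(rows) + 1]] <- c(props)
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- organisms
    data.frame(sample_id = sprintf("S%02d", seq_len(2 * n_per_group)),
               group = rep(c("G1", "G2"), each = n_per_group),
               m, stringsAsFactors = FALSE, check.names = FALSE)
  })
}

#' Simulate 16S amplicon reads from a community design
#'
#' Organisms are drawn with probability proportional to
#' `proportion * copy_number` (amplicon reads are 16S-copy-weighted), a
#' random window of the source 16S is taken, the strand is flipped with
#' probability 0.5, and i.i.d. substitutions are applied at rate `err`.
#' The per-read provenance is recorded as the simulation truth.
#'
#' @param design named proportion vector over organism OTU IDs (sums to 1)
#' @param db a `reference_db`
#' @param n_reads number of reads
#' @param read_len read length (<= reference length)
#' @param err substitution rate in \[0, 0.1\]
#' @param seed RNG seed
#' @param sample_id sample identifier (default `"sim"`)
#' @return list with `reads` (a `read_set`) and `truth` (data.frame read_id,
#'   otu, strand, position, is_16s)
#' @export
simulate_amplicon_reads <- function(design, db, n_reads, read_len, err = 0.01,
                                    seed = 1, sample_id = "sim") {
  stopifnot(inherits(db, "reference_db"))
  if (err < 0 || err > 0.1) stop("err must lie in [0, 0.1]")
  organisms <- names(design)
  if (abs(sum(design) - 1) > 1e-9) stop("design proportions must sum to 1")
  if (read_len > min(nchar(db$sequences[organisms])))
    stop("read_len exceeds the reference sequence length")
  w <- design * db$copy_number[organisms]
  w <- w / sum(w)
  with_seed(seed, {
    src <- sample(organisms, n_reads, replace = TRUE, prob = w)
    sim_reads_from(src, db$sequences, n_reads, read_len, err,
                   is_16s = rep(TRUE, n_reads), sample_id = sample_id)
  })
}

#' Simulate metagenomic shotgun reads from a community design
#'
#' The organism of each read is drawn with probability proportional to its
#' genome (cell) proportion - NOT copy-weighted. Given organism i, the read
#' originates inside the 16S gene with probability
#' `frac_16s * copy_number_i / max(copy_number)` (high-copy genomes
#' contribute proportionally more 16S fragments, which is exactly the bias
#' copy-number calibration corrects); otherwise it is drawn from a random
#' per-organism decoy (non-16S genomic background) sequence. Strand and
#' substitution error as in [simulate_amplicon_reads()].
#'
#' @inheritParams simulate_amplicon_reads
#' @param frac_16s 16S sampling weight for the highest-copy organism, in
#'   (0, 1]
#' @param decoy_len length of each organism's decoy background (default 1000)
#' @return list with `reads` and `truth` as in [simulate_amplicon_reads()]
#' @export
simulate_shotgun_reads <- function(design, db, n_reads, read_len, err = 0.01,
                                   frac_16s = 0.5, seed = 1,
                                   sample_id = "sim", decoy_len = 1000) {
  stopifnot(inherits(db, "reference_db"))
  if (frac_16s <= 0 || frac_16s > 1) stop("frac_16s must lie in (0, 1]")
  if (err < 0 || err > 0.1) stop("err must lie in [0, 0.1]")
  organisms <- names(design)
  if (abs(sum(design) - 1) > 1e-9) stop("design proportions must sum to 1")
  with_seed(seed, {
    decoys <- stats::setNames(lapply(organisms, function(o)
      paste(sample(DNA_BASES, decoy_len, replace = TRUE), collapse = "")),
      organisms)
    src <- sample(organisms, n_reads, replace = TRUE, prob = design)
    p16 <- frac_16s * db$copy_number[src] / max(db$copy_number[organisms])
    from_16s <- runif(n_reads) < p16
    pool <- ifelse(from_16s, db$sequences[src], unlist(decoys[src]))
    sim_reads_from(src, NULL, n_reads, read_len, err, is_16s = from_16s,
                   sample_id = sample_id, source_seqs = pool)
  })
}

# Shared window/strand/error machinery (caller manages the seed).
sim_reads_from <- function(src, seq_map, n_reads, read_len, err, is_16s,
                           sample_id, source_seqs = NULL) {
  seqs <- if (is.null(source_seqs)) unname(unlist(seq_map[src])) else
    unname(source_seqs)
  lens <- nchar(seqs)
  if (any(read_len > lens)) stop("read_len exceeds a source sequence length")
  pos <- floor(runif(n_reads) * (lens - read_len + 1)) + 1
  frag <- substr(seqs, pos, pos + read_len - 1)
  minus <- runif(n_reads) < 0.5
  frag[minus] <- revcomp(frag[minus])
  if (err > 0) {
    frag <- vapply(frag, function(s) {
      code <- encode_seq(s)
      hit <- which(runif(read_len) < err & code < 4L)
      if (length(hit))
        code[hit] <- (code[hit] + sample(1:3, length(hit), replace = TRUE)) %% 4L
      decode_seq(code)
    }, character(1), USE.NAMES = FALSE)
  }
  ids <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
  list(reads = read_set(sample_id, ids, frag),
       truth = data.frame(read_id = ids, otu = src,
                          strand = ifelse(minus, "-", "+"),
                          position = as.integer(pos), is_16s = is_16s,
                          stringsAsFactors = FALSE))
}
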