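# Shared fixtures, built in code. Heavier synthetic objects are cached per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 9-taxon synthetic reference database used across modules.
ref9 <- function() cached("ref9", make_reference_db(9, 250, seed = 1))

# Larger database for classification stress tests.
ref16 <- function() cached("ref16", make_reference_db(16, 400, seed = 1))

# A tiny hand-built reference database with fully controlled content:
# two distant clades, known copy numbers, traits on a subset of leaves.
tiny_db <- function() {
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.25,(C:0.2,D:0.3):0.15);")
  seqs <- c(A = paste(rep("ACGT", 30), collapse = ""),        # 120 bp each
            B = paste(rep("ACGA", 30), collapse = ""),
            C = paste(rep("TTGG", 30), collapse = ""),
            D = paste(rep("TTCC", 30), collapse = ""))
  taxonomy <- list(
    A = taxonomy_path(c("p1", "c1", "o1", "f1", "gAB")),
    B = taxonomy_path(c("p1", "c1", "o1", "f1", "gAB")),
    C = taxonomy_path(c("p2", "c2", "o2", "f2", "gC")),
    D = taxonomy_path(c("p2", "c2", "o2", "f2", "Unclassified")))
  traits <- list(
    B = stats::setNames(c(2, 0, 1), c("K00001", "K00002", "K00003")),
    C = stats::setNames(c(0, 4, 0), c("K00001", "K00002", "K00003")))
  structure(list(
    sequences = seqs,
    taxonomy = taxonomy,
    tree = tree,
    copy_number = c(A = 1, B = 4, C = 2, D = 1),
    traits = traits,
    ko_ids = c("K00001", "K00002", "K00003"),
    pathway_map = list(K00001 = "P1", K00002 = c("P1", "P2"),
                       K00003 = character()),
    dir = NA_character_), class = "reference_db")
}

# Deterministic uniform-random read set.
random_reads <- function(n, len, seed, sample_id = "rand") {
  with_seed_test(seed, {
    read_set(sample_id, sprintf("%s_%04d", sample_id, seq_len(n)),
             vapply(seq_len(n), function(i)
               paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""), character(1)))
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Abundance-table fixture helper.
make_table <- function(m, kind = "count", samples = NULL, features = NULL) {
  if (is.null(rownames(m)))
    rownames(m) <- samples %||% sprintf("S%d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- features %||% sprintf("F%d", seq_len(ncol(m)))
  abundance_table(m, kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
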