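#' Nearest individually sequenced taxon for each OTU
#'
#' Uses patristic (branch-length path) distances on the reference phylogeny.
#' Ties go to the lexicographically smallest sequenced taxon; an OTU that is
#' itself sequenced is its own nearest taxon at distance 0.
#'
#' @param tree rooted `ape::phylo` with branch lengths
#' @param otu a leaf label (or vector of leaf labels)
#' @param sequenced non-empty character vector of sequenced leaf labels
#' @return data.frame with columns otu, nearest, distance
#' @export
nearest_sequenced_taxon <- function(tree, otu, sequenced) {
  stopifnot(inherits(tree, "phylo"), length(sequenced) >= 1)
  if (!all(otu %in% tree$tip.label))
    stop("not a tree leaf: ", paste(setdiff(otu, tree$tip.label), collapse = ", "))
  if (!all(sequenced %in% tree$tip.label))
    stop("sequenced taxa must be tree leaves")
  D <- ape::cophenetic.phylo(tree)
  sequenced <- sort(sequenced)
  res <- lapply(otu, function(o) {
    if (o %in% sequenced) return(data.frame(otu = o, nearest = o, distance = 0))
    d <- D[o, sequenced]
    best <- min(d)
    data.frame(otu = o, nearest = sequenced[which(d == best)[1]],
               distance = best, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Predict a sample's KO gene profile from its OTU abundances
#'
#' Each OTU inherits the KO trait vector (gene copies) of its nearest
#' individually sequenced taxon; the community profile is the
#' abundance-weighted mix `ko[k] = sum_i (a_i / 100) * t_{nearest(i), k}`.
#' Zero-abundance OTUs contribute nothing.
#'
#' @param abund a [calibrate_copy_number()] result or named 0-100 vector
#' @param db a `reference_db`
#' @return list with `ko` (named KO abundance vector), `nearest` (the
#'   per-OTU nearest-taxon table for OTUs with positive abundance)
#' @export
predict_gene_profile <- function(abund, db) {
  stopifnot(inherits(db, "reference_db"))
  a <- if (inherits(abund, "calibrated_abundance")) abund$abundance else abund
  present <- names(a)[a > 0]
  ko <- stats::setNames(numeric(length(db$ko_ids)), db$ko_ids)
  if (length(present) == 0L)
    return(list(ko = ko, nearest = NULL))
  nn <- nearest_sequenced_taxon(db$tree, present, names(db$traits))
  for (i in seq_len(nrow(nn))) {
    ko <- ko + (a[[nn$otu[i]]] / 100) * db$traits[[nn$nearest[i]]]
  }
  list(ko = ko, nearest = nn)
}

#' Nearest Sequenced Taxon Index (NSTI) of one sample
#'
#' The abundance-weighted mean patristic distance from each present OTU to
#' its nearest individually sequenced relative:
#' `NSTI = sum_i a_i d_i / sum_i a_i`. Low values mean reliable functional
#' prediction. The unnormalized sum `sum_i a_i d_i` (with abundances as
#' fractions) is reported alongside.
#'
#' @param abund named abundance vector (or `calibrated_abundance`)
#' @param distances named per-OTU nearest-sequenced-taxon distances covering
#'   every OTU with positive abundance
#' @return list with `nsti` (weighted mean) and `nsti_sum` (raw sum over
#'   fractional abundances); both `NA` for an empty sample
#' @export
compute_nsti <- function(abund, distances) {
  a <- if (inherits(abund, "calibrated_abundance")) abund$abundance else abund
  a <- a[a > 0]
  if (length(a) == 0L) return(list(nsti = NA_real_, nsti_sum = NA_real_))
  if (!all(names(a) %in% names(distances)))
    stop("distances missing for OTUs: ",
         paste(setdiff(names(a), names(distances)), collapse = ", "))
  d <- distances[names(a)]
  list(nsti = sum(a * d) / sum(a),
       nsti_sum = sum((a / sum(a)) * d))
}

#' Roll a KO profile up to pathway abundances
#'
#' `pathway[p] = sum over KOs mapped to p of ko[k]`; a KO in several pathways
#' counts once per pathway, a KO mapped to none contributes nowhere.
#'
#' @param ko named KO abundance vector
#' @param pathway_map named list KO -> character vector of pathway IDs
#' @return named pathway abundance vector (empty if no KO maps anywhere)
#' @export
rollup_pathways <- function(ko, pathway_map) {
  pairs <- lapply(names(ko), function(k) {
    p <- pathway_map[[k]]
    if (is.null(p) || length(p) == 0L) return(NULL)
    data.frame(pathway = p, value = ko[[k]], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(stats::setNames(numeric(0), character(0)))
  rolled <- tapply(pairs$value, pairs$pathway, sum)
  stats::setNames(as.numeric(rolled), names(rolled))
}

#' Functional profiles (KO, pathway, NSTI) for a set of samples
#'
#' @param abundances named list of `calibrated_abundance` (names = sample IDs)
#' @param db a `reference_db`
#' @return list with `ko` and `pathway` [abundance_table()]s (counts scale:
#'   expected gene copies per unit community) and `nsti` (data.frame with
#'   sample_id, nsti, nsti_sum)
#' @export
build_functional_tables <- function(abundances, db) {
  stopifnot(inherits(db, "reference_db"))
  ids <- names(abundances)
  nn_all <- nearest_sequenced_taxon(db$tree, names(db$sequences),
                                    names(db$traits))
  dists <- stats::setNames(nn_all$distance, nn_all$otu)
  ko_rows <- lapply(abundances, function(a) predict_gene_profile(a, db)$ko)
  ko_m <- do.call(rbind, ko_rows)
  rownames(ko_m) <- ids
  pw_rows <- lapply(ko_rows, rollup_pathways, pathway_map = db$pathway_map)
  pw_ids <- sort(unique(unlist(lapply(pw_rows, names))))
  pw_m <- matrix(0, length(ids), length(pw_ids), dimnames = list(ids, pw_ids))
  for (s in ids) pw_m[s, names(pw_rows[[s]])] <- pw_rows[[s]]
  nsti <- do.call(rbind, lapply(ids, function(s) {
    r <- compute_nsti(abundances[[s]], dists)
    data.frame(sample_id = s, nsti = r$nsti, nsti_sum = r$nsti_sum,
               stringsAsFactors = FALSE)
  }))
  list(ko = abundance_table(ko_m, kind = "count"),
       pathway = abundance_table(pw_m, kind = "count"),
       nsti = nsti)
}
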