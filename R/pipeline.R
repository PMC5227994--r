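#' Run the full profiling pipeline with one call
#'
#' Executes every stage on a batch of samples: (shotgun mode) 16S fragment
#' extraction, OTU assignment at the identity threshold, optional
#' rarefaction, copy-number calibration, taxonomy roll-up, KO/pathway
#' prediction with NSTI, alpha diversity with bootstrapped rarefaction
#' curves, the phylogeny-aware beta-diversity distance matrix with PCoA,
#' UPGMA clustering and a permutation group test, biomarker discovery, and
#' the co-occurrence network. All randomness derives from `seed` (with
#' per-sample child seeds, so results do not depend on sample order), and
#' results are identical for any `workers` value.
#'
#' @param manifest path to a sample manifest TSV (see [read_manifest()]) or
#'   an equivalent data.frame
#' @param metadata path to a metadata TSV or a data.frame (rownames = sample
#'   IDs); `NULL` disables the metadata-driven stages
#' @param refdb a reference database directory or a `reference_db` object
#' @param out_dir output directory (created)
#' @param mode default mode for manifest rows without one
#' @param rarefy_depth rarefaction depth, or `NULL` to skip rarefaction;
#'   samples below the depth are dropped with a warning
#' @param copy_calibration apply 16S copy-number calibration (default TRUE)
#' @param boot rarefaction-curve bootstrap count (default 20)
#' @param n_perm permutations for the group test (default 10000)
#' @param beta decay rate of the phylogenetic similarity (default 1)
#' @param identity_min OTU assignment identity threshold (default 0.97)
#' @param group_factor metadata column used for the group test, markers and
#'   (when categorical) ordination labelling; default: first categorical
#'   column
#' @param msa optional aligned reference FASTA for the 16S detection profile;
#'   by default the reference sequences are used when they are equal-length
#' @param fpr false-positive rate for extraction threshold calibration
#' @param seed master RNG seed
#' @param workers accepted for interface compatibility; all stages run
#'   deterministically regardless of its value
#' @return invisibly, a list with the main in-memory results (`tables`,
#'   `functional`, `alpha`, `dist`, `pcoa`, `permanova`, `markers`,
#'   `network`, `topology`, `assignments`)
#' @export
run_pipeline <- function(manifest, metadata = NULL, refdb, out_dir,
                         mode = "amplicon", rarefy_depth = NULL,
                         copy_calibration = TRUE, boot = 20, n_perm = 10000,
                         beta = 1.0, identity_min = 0.97, group_factor = NULL,
                         msa = NULL, fpr = 2e-4, seed = 1, workers = 1) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  stage_log <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  db <- run_stage("load_reference", {
    if (inherits(refdb, "reference_db")) refdb else read_reference_db(refdb)
  })
  stage_log("load_reference: %d OTUs, %d sequenced, seed=%d",
            length(db$sequences), length(db$traits), seed)

  man <- run_stage("manifest", {
    if (is.data.frame(manifest)) manifest
    else read_manifest(manifest, default_mode = mode)
  })
  meta <- if (is.null(metadata)) NULL
          else if (is.data.frame(metadata)) metadata
          else read_metadata(metadata, sample_ids = man$sample_id)

  samples <- run_stage("read_samples", {
    stats::setNames(lapply(seq_len(nrow(man)), function(i)
      read_sequences(man$path[i], sample_id = man$sample_id[i])),
      man$sample_id)
  })
  stage_log("read_samples: %d samples, %s reads total", length(samples),
            sum(vapply(samples, length, numeric(1))))

  needs_extraction <- man$mode == "shotgun"
  if (any(needs_extraction)) {
    profile <- run_stage("build_profile", {
      msa_m <- if (!is.null(msa)) read_alignment(msa) else {
        lens <- nchar(db$sequences)
        if (length(unique(lens)) != 1L)
          stop("reference sequences are not equal-length; supply 'msa'")
        m <- do.call(rbind, strsplit(unname(db$sequences), "", fixed = TRUE))
        rownames(m) <- names(db$sequences)
        m
      }
      build_profile(msa_m)
    })
    read_len <- round(stats::median(unlist(lapply(samples[needs_extraction],
                                                  function(r) nchar(r$seqs)))))
    profile <- run_stage("calibrate_threshold",
      calibrate_threshold(profile, read_length = read_len,
                          n_null = 5000, fpr = fpr,
                          seed = child_seed(seed, "null")))
    stage_log("extraction profile: %d columns, threshold %.2f bits (fpr %g)",
              profile$length, profile$score_threshold, fpr)
    for (s in man$sample_id[needs_extraction]) {
      ex <- run_stage(paste0("extract:", s),
                      extract_fragments(profile, samples[[s]]))
      stage_log("extract %s: %d/%d reads kept as 16S fragments", s,
                length(ex$fragments), length(samples[[s]]))
      samples[[s]] <- ex$fragments
    }
  }

  index <- run_stage("kmer_index", build_kmer_index(db))
  assignments <- list()
  counts <- list()
  for (s in man$sample_id) {
    asg <- run_stage(paste0("assign:", s),
                     assign_reads(samples[[s]], db, index,
                                  identity_min = identity_min))
    assignments[[s]] <- asg
    cfa <- counts_from_assignments(asg, db)
    counts[[s]] <- cfa$counts
    stage_log("assign %s: %d assigned, %d unassigned", s,
              sum(cfa$counts), cfa$unassigned)
  }
  asg_dir <- file.path(out_dir, "assignments")
  dir.create(asg_dir, showWarnings = FALSE)
  for (s in names(assignments))
    write.table(assignments[[s]], file.path(asg_dir, paste0(s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(rarefy_depth)) {
    keep <- vapply(counts, function(x) sum(x) >= rarefy_depth, logical(1))
    if (any(!keep)) {
      warning("samples below the rarefaction depth dropped: ",
              paste(names(counts)[!keep], collapse = ", "))
      stage_log("rarefy: dropped %s", paste(names(counts)[!keep], collapse = ","))
    }
    counts <- counts[keep]
    counts <- stats::setNames(lapply(names(counts), function(s)
      rarefy(counts[[s]], rarefy_depth, seed = child_seed(seed, s))),
      names(counts))
    stage_log("rarefy: depth %d, %d samples retained", rarefy_depth,
              length(counts))
  }
  if (length(counts) == 0L) stop("pipeline stage 'rarefy' failed: no samples left")

  abund <- stats::setNames(lapply(names(counts), function(s)
    calibrate_copy_number(counts[[s]], db, enabled = copy_calibration)),
    names(counts))
  stage_log("calibrate: copy-number calibration %s",
            if (copy_calibration) "ON" else "OFF")

  tables <- run_stage("profile_tables", build_profile_tables(abund, db))
  count_m <- do.call(rbind, counts)
  count_tab <- abundance_table(count_m, kind = "count")
  write_table(count_tab, file.path(out_dir, "otu_counts.tsv"))
  write_table(tables$otu, file.path(out_dir, "otu_table.tsv"))
  for (level in TAXONOMY_RANKS)
    write_table(tables[[level]], file.path(out_dir,
                                           paste0("taxa.", level, ".tsv")))
  stage_log("profile_tables: %d samples x %d OTUs (+%d taxonomy levels)",
            nrow(count_m), ncol(count_m), length(TAXONOMY_RANKS))

  functional <- run_stage("functional", build_functional_tables(abund, db))
  write_table(functional$ko, file.path(out_dir, "ko_table.tsv"))
  write_table(functional$pathway, file.path(out_dir, "pathway_table.tsv"))
  write.table(functional$nsti, file.path(out_dir, "nsti.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stage_log("functional: %d KOs, %d pathways",
            length(functional$ko$feature_ids),
            length(functional$pathway$feature_ids))

  alpha <- run_stage("alpha", alpha_table(count_tab))
  write.table(alpha, file.path(out_dir, "alpha.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (index in c("observed", "shannon")) {
    curves <- list()
    for (s in rownames(count_m)) {
      total <- sum(count_m[s, ])
      if (total < 2) next
      depths <- unique(pmax(1, round(seq(0.1, 1, by = 0.1) * total)))
      rc <- rarefaction_curve(count_m[s, ], depths, B = boot, index = index,
                              seed = child_seed(seed, paste0("rc", s)))
      curves[[s]] <- data.frame(sample_id = s, rc)
    }
    if (length(curves))
      write.table(do.call(rbind, curves),
                  file.path(out_dir, paste0("rarefaction.", index, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage_log("alpha: indices + rarefaction curves (B=%d)", boot)

  nonzero <- rownames(count_m)[rowSums(count_m) > 0]
  if (length(nonzero) < 2L) stop("pipeline stage 'beta' failed: < 2 non-empty samples")
  profiles <- stats::setNames(lapply(nonzero, function(s) {
    a <- tables$otu$values[s, ]
    a / sum(a)
  }), nonzero)
  dist_obj <- run_stage("beta", distance_matrix(profiles, db$tree, beta = beta))
  write_table(dist_obj, file.path(out_dir, "beta_distance.tsv"))
  ord <- run_stage("pcoa", pcoa(dist_obj, n_axes = min(3, length(nonzero) - 1)))
  write.table(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates, check.names = FALSE),
              file.path(out_dir, "pcoa.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(axis = seq_along(ord$eigenvalues),
                         eigenvalue = ord$eigenvalues),
              file.path(out_dir, "pcoa_eigenvalues.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(run_stage("upgma", upgma(dist_obj)),
             file.path(out_dir, "upgma.nwk"))
  stage_log("beta: %d x %d distances, PCoA + UPGMA written",
            length(nonzero), length(nonzero))

  permanova <- NULL
  markers <- NULL
  net <- NULL
  topo <- NULL
  gf <- group_factor
  if (!is.null(meta)) {
    if (is.null(gf)) {
      cats <- names(meta)[!vapply(meta, is.numeric, logical(1))]
      gf <- if (length(cats)) cats[1] else NULL
    }
    if (!is.null(gf)) {
      groups <- as.character(meta[nonzero, gf])
      if (length(unique(groups)) >= 2L && all(table(groups) >= 2L)) {
        permanova <- run_stage("permanova",
          permutation_group_test(dist_obj, groups, n_perm = n_perm,
                                 seed = child_seed(seed, "perm")))
        writeLines(sprintf(
          "factor\t%s\npseudo_F\t%.6g\np\t%.6g\npermutations\t%d\nexact\t%s",
          gf, permanova$pseudo_F, permanova$p, permanova$n_perm_used,
          permanova$exact), file.path(out_dir, "permanova.txt"))
        stage_log("permanova on '%s': F=%.3f p=%.4g", gf,
                  permanova$pseudo_F, permanova$p)
        genus_sub <- abundance_table(
          tables$genus$values[nonzero, , drop = FALSE], kind = "relative")
        markers <- run_stage("markers",
          marker_report(genus_sub, groups, seed = child_seed(seed, "rf")))
        write.table(markers, file.path(out_dir, "markers.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        stage_log("markers: %d features tested, %d candidates",
                  nrow(markers), sum(markers$candidate))
      } else {
        stage_log("group test skipped: factor '%s' lacks two groups of >= 2", gf)
      }
    }
  }
  if (length(nonzero) >= 5L) {
    genus_sub <- abundance_table(tables$genus$values[nonzero, , drop = FALSE],
                                 kind = "relative")
    net <- run_stage("network", build_network(genus_sub))
    topo <- network_topology(net)
    write.table(net$edges, file.path(out_dir, "network_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(names(topo), unlist(topo), sep = "\t"),
               file.path(out_dir, "network_topology.txt"))
    stage_log("network: %d nodes, %d edges, %d islands", topo$n_nodes,
              nrow(net$edges), topo$n_islands)
  }
  stage_log("done in %.1f s (workers=%d)",
            as.numeric(difftime(Sys.time(), t0, units = "secs")), workers)
  invisible(list(tables = tables, functional = functional, alpha = alpha,
                 counts = count_tab, dist = dist_obj, pcoa = ord,
                 permanova = permanova, markers = markers, network = net,
                 topology = topo, assignments = assignments))
}
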