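#' Pipeline configuration
#'
#' Bundles the thresholds and options of the end-to-end analysis. Defaults
#' follow the study conventions: E-value cutoff 1e-10, 500-bp neighbor rule,
#' pseudogene rule <60% length at >50% identity, fusion query coverage 0.50,
#' orthoblock validity at >= 2 clustered genes, cohort inclusion at >= 3
#' clustered genes, 10-kb GC flanks with 500-bp windows.
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param out_dir output directory (created if needed); `NULL` for no files.
#' @param evalue_max,neighbor_bp,pseudo_len_frac,pseudo_ident,fusion_cov
#'   stage thresholds (see the stage functions).
#' @param min_block_genes minimum genes for a reportable orthoblock.
#' @param cohort_min_genes minimum clustered genes for a genome to enter the
#'   cohort analysis.
#' @param flank_bp,gc_window GC-screen geometry.
#' @param pseudo_families family labels screened by the pseudogene rule.
#'   The published screen targets cyp115 only; the pipeline defaults to all
#'   families so that any truncated fragment is kept out of the ortholog set
#'   and the concatenated alignment.
#' @param outgroup leaf to root trees on (default: alphabetically first
#'   genome in the cohort).
#' @param bootstrap_n bootstrap replicates for tree support (0 = skip).
#' @param reduce_k if non-`NULL`, also reduce the cohort to `k` taxa by
#'   phylogenetic diversity and repeat the reconstructions.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = NULL,
                            evalue_max = 1e-10, neighbor_bp = 500,
                            pseudo_len_frac = 0.60, pseudo_ident = 0.50,
                            fusion_cov = 0.50, min_block_genes = 2,
                            cohort_min_genes = 3, flank_bp = 10000,
                            gc_window = 500,
                            pseudo_families = c(letters[1:10], "k"),
                            outgroup = NULL,
                            bootstrap_n = 0, reduce_k = NULL) {
  stopifnot(evalue_max > 0, neighbor_bp > 0, pseudo_len_frac > 0,
            pseudo_ident > 0, fusion_cov > 0, min_block_genes > 0,
            cohort_min_genes > 0, flank_bp > 0, gc_window > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

pipe_log <- function(lines, con) {
  message(paste(lines, collapse = "\n"))
  if (!is.null(con)) writeLines(lines, con)
}

#' Run the gene-block evolution pipeline on a synthetic cohort
#'
#' Simulates genomes, then runs the full analysis the way it would run on
#' real annotated genomes: homology search (internal aligner adapter) ->
#' ortholog/pseudogene/fusion calls -> orthoblock assembly and cohort filter
#' -> pairwise event distances -> marker and concatenated-operon
#' neighbor-joining trees -> outgroup rooting -> ancestral reconstruction
#' under both trees -> tree comparison -> optional phylogenetic-diversity
#' reduction and re-analysis -> GC contrast per genome. All steps are
#' deterministic under the simulation seed.
#'
#' @param config a [pipeline_config()].
#' @return list with the per-stage results (`genomes`, `calls`, `blocks`,
#'   `events`, `trees`, `reconstructions`, `comparison`, `reduced`, `gc`,
#'   `excluded`); written as TSV/Newick under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  logcon <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    logcon <- file.path(out, "run.log")
    cat(NULL, file = logcon)
    logcon <- file(logcon, open = "wt")
    on.exit(close(logcon), add = TRUE)
  }
  pipe_log(c(paste("blockevol pipeline, seed", config$sim$seed),
             paste("thresholds: evalue", config$evalue_max, "neighbor",
                   config$neighbor_bp, "pseudo", config$pseudo_len_frac,
                   config$pseudo_ident, "fusion_cov", config$fusion_cov)),
           logcon)

  # simulate
  tree <- sample_tree(config$sim$n_leaves, config$sim$birth_rate,
                      config$sim$seed)
  sim <- evolve_blocks(tree, config$sim)
  em <- emit_genomes(sim, config$sim, flank = config$flank_bp)

  fam_tbl <- reference_families(vapply(sim$templates[names(sim$templates) !=
                                                       "marker"], length, 0))
  queries <- lapply(sim$templates[names(sim$templates) != "marker"],
                    paste, collapse = "")

  # orthology per genome
  calls <- list(); blocks <- list(); excluded <- character(0)
  gene_seqs <- list()
  for (gid in names(em$genomes)) {
    g <- em$genomes[[gid]]
    hits <- align_hits(g, queries)
    cl <- call_orthologs(hits, fam_tbl, config$evalue_max)
    slen <- stats::setNames(g$features$end - g$features$start,
                            g$features$feature_id)
    cl <- classify_pseudo(cl, slen, fam_tbl,
                          pseudo_families = config$pseudo_families,
                          len_frac = config$pseudo_len_frac,
                          min_ident = config$pseudo_ident)
    cl <- detect_fusions(cl, hits, fam_tbl, config$evalue_max,
                         cov_min = config$fusion_cov)
    bl <- build_blocks(cl, g, config$neighbor_bp, config$min_block_genes)
    ngenes <- sum(vapply(bl, function(b) length(unlist(b$segments)), 0L))
    if (ngenes < config$cohort_min_genes) {
      excluded <- c(excluded, gid)
      pipe_log(paste("excluded", gid, "-", ngenes,
                     "clustered operon genes"), logcon)
      next
    }
    calls[[gid]] <- cl
    blocks[[gid]] <- bl[[1]]
    full <- cl[cl$status == "full", ]
    gs <- lapply(stats::setNames(full$subject_feature_id, full$labels),
                 function(fid) feature_seq(g, fid))
    # fusion features feed both constituent family slots
    for (i in which(cl$status == "fusion")) {
      labs <- strsplit(cl$labels[i], ",")[[1]]
      fs <- feature_seq(g, cl$subject_feature_id[i])
      half <- nchar(fs) %/% 2
      gs[[labs[1]]] <- substr(fs, 1, half)
      gs[[labs[2]]] <- substr(fs, half + 1, nchar(fs))
    }
    gene_seqs[[gid]] <- gs
  }
  cohort <- names(blocks)
  if (length(cohort) < 3) stop("run_pipeline: fewer than 3 cohort genomes")

  ev <- event_matrix(blocks)

  # trees: marker (species) and concatenated operon
  marker_aln <- as_alignment_matrix(em$marker[cohort])
  species <- nj_tree(p_distance(marker_aln))
  co <- concat_operon(gene_seqs)
  for (i in seq_len(nrow(co$excluded)))
    pipe_log(paste("operon tree excludes", co$excluded$genome[i],
                   "- missing", co$excluded$missing[i]), logcon)
  trees <- list(species = species)
  operon_taxa <- names(co$sequences)
  if (length(operon_taxa) >= 3) {
    trees$operon <- nj_tree(p_distance(as_alignment_matrix(co$sequences)))
  }

  shared_taxa <- Reduce(intersect, lapply(trees, function(t) t$tip.label))
  if (length(shared_taxa) < 3)
    stop("run_pipeline: fewer than 3 genomes shared by the trees")
  outgroup <- if (!is.null(config$outgroup)) config$outgroup else
    sort(shared_taxa)[1]
  if (!(outgroup %in% shared_taxa))
    stop("run_pipeline: outgroup ", outgroup, " not present in both trees")
  rooted <- lapply(trees, function(t)
    root_with_outgroup(ape::keep.tip(t, shared_taxa), outgroup))

  recs <- lapply(rooted, function(t) reconstruct_blocks(t, blocks))
  comparison <- compare_trees(blocks[shared_taxa], rooted)
  pipe_log(paste("total events:",
                 paste(comparison$tree, comparison$total_events,
                       collapse = "; ")), logcon)

  reduced <- NULL
  if (!is.null(config$reduce_k) &&
      config$reduce_k < length(shared_taxa)) {
    keep_taxa <- pd_reduce(rooted$species, config$reduce_k, keep = outgroup)
    red_trees <- lapply(rooted, function(t)
      root_with_outgroup(ape::keep.tip(t, keep_taxa), outgroup))
    reduced <- list(taxa = keep_taxa,
                    comparison = compare_trees(blocks[keep_taxa], red_trees))
  }

  # GC screen, on spans derived from the called blocks
  gc <- list()
  for (gid in cohort) {
    g <- em$genomes[[gid]]
    called <- g$features[g$features$feature_id %in%
                           calls[[gid]]$subject_feature_id, ]
    span <- c(min(called$start), max(called$end))
    gc[[gid]] <- region_contrast(g, span, flank = config$flank_bp)
  }

  res <- list(genomes = em$genomes, marker = em$marker, calls = calls,
              blocks = blocks, events = ev, trees = rooted,
              reconstructions = recs, comparison = comparison,
              reduced = reduced, gc = gc, excluded = excluded, sim = sim)

  if (!is.null(out)) {
    blk <- data.frame(genome_id = cohort,
                      block = vapply(blocks, render_block, ""),
                      flags = vapply(blocks, block_flags, ""))
    utils::write.table(blk, file.path(out, "blocks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ev, file.path(out, "events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, lapply(cohort, function(gid)
      cbind(genome_id = gid, calls[[gid]]))),
      file.path(out, "calls.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (nm in names(rooted))
      write_tree(rooted[[nm]], file.path(out, paste0("tree_", nm, ".nwk")))
    utils::write.table(comparison, file.path(out, "compare_trees.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gct <- data.frame(genome_id = names(gc),
                      gc_operon = vapply(gc, `[[`, 0, "gc_operon"),
                      gc_upstream = vapply(gc, `[[`, 0, "gc_upstream"),
                      gc_downstream = vapply(gc, `[[`, 0, "gc_downstream"),
                      delta_points = vapply(gc, `[[`, 0, "delta"))
    utils::write.table(gct, file.path(out, "gc_contrast.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(reduced))
      utils::write.table(reduced$comparison,
                         file.path(out, "compare_trees_reduced.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}
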