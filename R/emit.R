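#' Genome container
#'
#' @param genome_id identifier.
#' @param contigs named character vector of contig sequences.
#' @param features data frame with columns `feature_id`, `contig_id`,
#'   `start`, `end` (0-based half-open), `strand`, and optional annotation
#'   columns. Coordinates must fall inside their contig.
#' @return an object of class `genome`.
#' @export
genome <- function(genome_id, contigs, features) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  req <- c("feature_id", "contig_id", "start", "end", "strand")
  if (!all(req %in% names(features)))
    stop("genome: features need columns ", paste(req, collapse = ", "))
  if (anyDuplicated(features$feature_id))
    stop("genome: duplicated feature_id")
  if (!all(features$contig_id %in% names(contigs)))
    stop("genome: feature on unknown contig")
  if (!all(features$strand %in% c("+", "-")))
    stop("genome: strand must be '+' or '-'")
  if (any(features$start < 0) || any(features$start >= features$end))
    stop("genome: need 0 <= start < end")
  too_far <- features$end > nchar(contigs)[features$contig_id]
  if (any(too_far))
    stop("genome: feature beyond contig end: ",
         paste(features$feature_id[too_far], collapse = ", "))
  features <- features[order(features$contig_id, features$start,
                             features$feature_id), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(genome_id = genome_id, contigs = contigs,
                 features = features), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome ", x$genome_id, "> ", length(x$contigs), " contig(s), ",
      nrow(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

#' Extract a feature's nucleotide sequence
#'
#' @param g a [genome()].
#' @param feature_id feature identifier.
#' @return character scalar (reverse-complemented for `-` strand).
#' @export
feature_seq <- function(g, feature_id) {
  f <- g$features[g$features$feature_id == feature_id, ]
  if (nrow(f) != 1L) stop("feature_seq: unknown feature ", feature_id)
  s <- substr(g$contigs[[f$contig_id]], f$start + 1L, f$end)
  if (f$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Emit annotated genome sequences from a simulation
#'
#' Each leaf genome is one contig: an upstream background flank, the evolved
#' gene block (genes separated by intra-block gaps at or below the neighbor
#' threshold; sub-blocks separated by split gaps above it; all genes on the
#' plus strand), and a downstream flank. Background and gap DNA is drawn at
#' `gc_background`; gene sequences are the evolved operon sequences (expected
#' GC `gc_operon`). Pseudogenes are truncated from the 3' end to a uniform
#' 20--59% of the template length, guaranteeing the <60% pseudogene length
#' rule fires on them.
#'
#' @param sim result of [evolve_blocks()] (run with `sequences = TRUE`).
#' @param config the [sim_config()] used.
#' @param flank background flank length in bp (default 10000).
#' @param seed seed for gap lengths, background DNA and truncation points
#'   (default `config$seed + 1`).
#' @return list with `genomes` (named list of [genome()]s), `marker`
#'   (named character vector of marker gene sequences, equal lengths, no
#'   indels -- directly usable as an alignment), and `operon_span` (per
#'   genome, 0-based half-open span from first to last block gene).
#' @export
emit_genomes <- function(sim, config = sim$config, flank = 10000,
                         seed = config$seed + 1L) {
  if (is.null(sim$leaf_seqs))
    stop("emit_genomes: simulation was run without sequences")
  set.seed(as.integer(seed))
  genomes <- list()
  spans <- list()
  for (leaf in names(sim$leaf_blocks)) {
    block <- sim$leaf_blocks[[leaf]]
    seqs <- sim$leaf_seqs[[leaf]]
    for (f in setdiff(unlist(block$segments), names(seqs)))
      stop("emit_genomes: no template/sequence for family ", f)
    parts <- list(random_seq(flank, config$gc_background))
    feat <- list()
    pos <- flank
    first_gene <- NA
    ctg <- paste0(leaf, "_ctg1")
    gi <- 0L
    for (si in seq_along(block$segments)) {
      if (si > 1) {
        gap <- sample(config$split_gap[1]:config$split_gap[2], 1)
        parts[[length(parts) + 1L]] <- random_seq(gap, config$gc_background)
        pos <- pos + gap
      }
      seg <- block$segments[[si]]
      sta <- block$statuses[[si]]
      for (j in seq_along(seg)) {
        if (j > 1) {
          # intergenic spacers inside a sub-block are part of the mobile
          # unit and carry its GC signature
          gap <- sample(config$intra_block_gap[1]:config$intra_block_gap[2], 1)
          parts[[length(parts) + 1L]] <- random_seq(gap, config$gc_operon)
          pos <- pos + gap
        }
        gseq <- seqs[[seg[j]]]
        if (sta[j] == "pseudo") {
          keep <- floor(runif(1, 0.20, 0.59) *
                          length(sim$templates[[seg[j]]]))
          gseq <- gseq[seq_len(max(keep, 30L))]
        }
        gi <- gi + 1L
        parts[[length(parts) + 1L]] <- gseq
        if (is.na(first_gene)) first_gene <- pos
        feat[[length(feat) + 1L]] <- data.frame(
          feature_id = sprintf("%s_gene%02d", leaf, gi), contig_id = ctg,
          start = pos, end = pos + length(gseq), strand = "+",
          family_truth = seg[j], status_truth = sta[j],
          stringsAsFactors = FALSE)
        pos <- pos + length(gseq)
      }
    }
    last_gene <- pos
    parts[[length(parts) + 1L]] <- random_seq(flank, config$gc_background)
    contig <- paste(unlist(parts), collapse = "")
    feats <- if (length(feat)) do.call(rbind, feat) else
      data.frame(feature_id = character(0), contig_id = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 family_truth = character(0), status_truth = character(0),
                 stringsAsFactors = FALSE)
    contigs <- stats::setNames(contig, ctg)
    genomes[[leaf]] <- genome(leaf, contigs, feats)
    spans[[leaf]] <- if (length(feat)) c(first_gene, last_gene) else NULL
  }
  marker <- vapply(sim$marker, paste, "", collapse = "")
  list(genomes = genomes, marker = marker, operon_span = spans)
}
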