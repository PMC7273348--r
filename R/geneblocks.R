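#' Gene-block container
#'
#' A gene block is an ordered list of sub-blocks, each an ordered run of
#' gene-family labels found next to each other on one strand of one contig.
#' Sub-blocks are separated in the string notation by `"|"`, marking a gap
#' larger than the neighbor threshold (or a strand/contig change). Each gene
#' carries a status, `"full"` or `"pseudo"`; pseudogenes are rendered but
#' excluded from event counting by default.
#'
#' @param segments list of character vectors of single-letter family labels
#'   (reference families use `a`..`k`).
#' @param statuses list of character vectors parallel to `segments`, values
#'   `"full"` or `"pseudo"`. Defaults to all `"full"`.
#' @param genome_id optional genome identifier.
#' @return an object of class `gene_block`.
#' @examples
#' gene_block(list(c("b", "c"), "j"))
#' @export
gene_block <- function(segments, statuses = NULL, genome_id = NA_character_) {
  if (!is.list(segments)) segments <- list(segments)
  segments <- lapply(segments, as.character)
  if (any(vapply(segments, length, 1L) == 0L) && length(segments) > 0L)
    stop("gene_block: empty sub-block")
  if (is.null(statuses))
    statuses <- lapply(segments, function(s) rep("full", length(s)))
  if (!is.list(statuses)) statuses <- list(statuses)
  stopifnot(length(statuses) == length(segments))
  for (i in seq_along(segments)) {
    if (length(statuses[[i]]) != length(segments[[i]]))
      stop("gene_block: statuses must parallel segments")
    if (!all(statuses[[i]] %in% c("full", "pseudo")))
      stop("gene_block: status must be 'full' or 'pseudo'")
  }
  structure(list(genome_id = genome_id, segments = segments,
                 statuses = statuses),
            class = "gene_block")
}

#' @export
print.gene_block <- function(x, ...) {
  cat("<gene_block", if (!is.na(x$genome_id)) x$genome_id else "",
      "> ", render_block(x), " ", block_flags(x), "\n", sep = "")
  invisible(x)
}

as_gene_block <- function(x) {
  if (inherits(x, "gene_block")) x else parse_block(x)
}

#' Parse gene-block string notation
#'
#' The string form writes neighboring genes as consecutive letters and marks
#' a split (a gap above the neighbor threshold) with `"|"`, e.g. `"bcdefghi|j"`.
#' A trailing `"~"` after a letter marks a pseudogene (e.g. `"a~bcdefghi"` is
#' a block whose cyp115 is a truncated fragment).
#'
#' @param text block string matching `^[a-k]~?(\\|?[a-k]~?)*$`.
#' @param genome_id optional genome identifier.
#' @return a [gene_block()].
#' @examples
#' parse_block("bcdefghi|j")
#' @export
parse_block <- function(text, genome_id = NA_character_) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("parse_block: empty block string")
  if (!grepl("^[a-k]~?(\\|?[a-k]~?)*$", text))
    stop("parse_block: illegal block string: ", text)
  segs <- strsplit(text, "|", fixed = TRUE)[[1]]
  labels <- lapply(segs, function(s) {
    g <- regmatches(s, gregexpr("[a-k]~?", s))[[1]]
    g
  })
  segments <- lapply(labels, function(g) sub("~", "", g, fixed = TRUE))
  statuses <- lapply(labels, function(g) ifelse(grepl("~", g, fixed = TRUE),
                                                "pseudo", "full"))
  gene_block(segments, statuses, genome_id)
}

#' Render a gene block as its string notation
#'
#' @param block a [gene_block()] or block string.
#' @return a single string; pseudogenes carry a `"~"` suffix.
#' @examples
#' render_block(gene_block(list(c("b", "c", "d"), "j")))
#' @export
render_block <- function(block) {
  block <- as_gene_block(block)
  if (length(block$segments) == 0L) return("")
  paste(vapply(seq_along(block$segments), function(i) {
    paste0(block$segments[[i]],
           ifelse(block$statuses[[i]] == "pseudo", "~", ""),
           collapse = "")
  }, ""), collapse = "|")
}

#' Annotation flags of a gene block
#'
#' Mirrors the reconstruction figure legend: `*` if the block contains a
#' full-length cyp115 (family `a`), `!` if it contains a cyp115
#' truncation/fragment, `?` if it contains ggps2 (family `k`).
#'
#' @param block a [gene_block()] or block string.
#' @return a string of zero or more of `*`, `!`, `?`.
#' @export
block_flags <- function(block) {
  block <- as_gene_block(block)
  lab <- unlist(block$segments)
  st <- unlist(block$statuses)
  paste0(if (any(lab == "a" & st == "full")) "*" else "",
         if (any(lab == "a" & st == "pseudo")) "!" else "",
         if (any(lab == "k")) "?" else "")
}

#' Are two gene features neighbors?
#'
#' Two genes are neighbors when they lie on the same contig and strand and
#' their intergenic distance is at most `threshold` base pairs (500 by
#' default, the boundary being inclusive). Overlapping features have gap 0.
#'
#' @param f1,f2 single-row feature data frames (or lists) with fields
#'   `contig_id`, `start`, `end` (0-based half-open), `strand`.
#' @param threshold maximum intergenic gap in bp.
#' @return `TRUE` or `FALSE`.
#' @export
are_neighbors <- function(f1, f2, threshold = 500) {
  if (!identical(as.character(f1$contig_id), as.character(f2$contig_id)))
    return(FALSE)
  if (!identical(as.character(f1$strand), as.character(f2$strand)))
    return(FALSE)
  gap <- max(f1$start, f2$start) - min(f1$end, f2$end)
  if (gap < 0) gap <- 0
  gap <= threshold
}

#' Assemble orthologous gene blocks from ortholog calls
#'
#' Features with a family call are sorted by position and chained with the
#' neighbor rule into sub-blocks; sub-blocks on the same contig are joined in
#' the rendered string by `"|"` (configurable). A block needs at least
#' `min_genes` genes in total to be reported. Fusion calls contribute both of
#' their family labels as adjacent genes. Blocks never span contigs.
#'
#' @param calls ortholog-call data frame from [call_orthologs()] (columns
#'   `subject_feature_id`, `labels`, `status`).
#' @param genome a genome object from [read_genome()] or [emit_genomes()].
#' @param threshold neighbor gap threshold in bp (default 500).
#' @param min_genes minimum total genes for a reportable block (default 2).
#' @param join_distant if `TRUE` (default) sub-blocks on one contig are
#'   reported as one split-aware block; if `FALSE`, one block per sub-block.
#' @return list of [gene_block()]s (possibly empty).
#' @export
build_blocks <- function(calls, genome, threshold = 500, min_genes = 2,
                         join_distant = TRUE) {
  feats <- genome$features
  feats <- feats[feats$feature_id %in% calls$subject_feature_id, , drop = FALSE]
  if (nrow(feats) == 0L) return(list())
  feats <- feats[order(feats$contig_id, feats$start, feats$feature_id), ,
                 drop = FALSE]
  idx <- match(feats$feature_id, calls$subject_feature_id)
  feats$labels <- calls$labels[idx]
  feats$status <- calls$status[idx]

  blocks <- list()
  for (ctg in unique(feats$contig_id)) {
    fc <- feats[feats$contig_id == ctg, , drop = FALSE]
    # chain into sub-blocks with the neighbor rule
    seg_id <- integer(nrow(fc))
    seg_id[1] <- 1L
    if (nrow(fc) > 1) for (i in 2:nrow(fc)) {
      seg_id[i] <- if (are_neighbors(fc[i - 1, ], fc[i, ], threshold))
        seg_id[i - 1] else seg_id[i - 1] + 1L
    }
    seg_lab <- split(fc$labels, seg_id)
    seg_sta <- split(fc$status, seg_id)
    expand <- function(labs, stas) {
      # fusion calls ("c,d") contribute both families; a fused gene is a
      # functional copy of each constituent, so it enters as "full"
      l <- strsplit(labs, ",", fixed = TRUE)
      status <- rep(ifelse(stas == "pseudo", "pseudo", "full"),
                    vapply(l, length, 1L))
      list(labels = unlist(l), status = status)
    }
    segs <- mapply(expand, seg_lab, seg_sta, SIMPLIFY = FALSE)
    if (join_distant) {
      bl <- gene_block(lapply(segs, `[[`, "labels"),
                       lapply(segs, `[[`, "status"),
                       genome_id = genome$genome_id)
      if (sum(lengths(bl$segments)) >= min_genes)
        blocks[[length(blocks) + 1L]] <- bl
    } else {
      for (s in segs) {
        bl <- gene_block(list(s$labels), list(s$status),
                         genome_id = genome$genome_id)
        if (sum(lengths(bl$segments)) >= min_genes)
          blocks[[length(blocks) + 1L]] <- bl
      }
    }
  }
  blocks
}
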