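#' Read a genome from FASTA + GFF3
#'
#' GFF3 coordinates (1-based, inclusive) are converted once, at parse time,
#' to the package's internal convention of 0-based half-open spans; all
#' downstream coordinate arithmetic (neighbor gaps, GC windows) assumes that
#' convention. Features are sorted by (contig, start).
#'
#' @param fasta_path nucleotide FASTA of the contigs.
#' @param gff3_path GFF3 annotation; features of type in `types` are kept.
#' @param genome_id identifier (default: FASTA file name without extension).
#' @param types feature types to keep (default `gene` and `CDS`; `CDS` rows
#'   duplicating a kept `gene` ID are skipped).
#' @return a [genome()].
#' @export
read_genome <- function(fasta_path, gff3_path,
                        genome_id = sub("\\.[^.]*$", "", basename(fasta_path)),
                        types = c("gene", "CDS")) {
  contigs_set <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- as.character(contigs_set)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- ape::read.gff(gff3_path, GFF3 = TRUE)
  gff <- gff[gff$type %in% types, , drop = FALSE]
  if (nrow(gff) == 0L) stop("read_genome: no features of requested types")
  if (!all(as.character(gff$strand) %in% c("+", "-")))
    stop("read_genome: unknown strand symbol")
  ids <- gff_attribute(gff$attributes, "ID")
  ids[is.na(ids)] <- sprintf("feat%04d", which(is.na(ids)))
  keep <- !duplicated(ids)
  gff <- gff[keep, , drop = FALSE]
  ids <- ids[keep]
  if (!all(gff$seqid %in% names(contigs)))
    stop("read_genome: feature on contig absent from FASTA")
  feats <- data.frame(
    feature_id = ids, contig_id = as.character(gff$seqid),
    start = gff$start - 1L,  # 1-based inclusive -> 0-based half-open
    end = gff$end, strand = as.character(gff$strand),
    type = as.character(gff$type), stringsAsFactors = FALSE)
  fam <- gff_attribute(gff$attributes, "family")
  if (any(!is.na(fam))) feats$family_truth <- fam
  genome(genome_id, contigs, feats)
}

gff_attribute <- function(attributes, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regexec(pat, attributes)
  vapply(regmatches(attributes, m), function(x)
    if (length(x) >= 3) x[3] else NA_character_, "")
}

#' Write a genome as FASTA + GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive GFF3 convention on output.
#'
#' @param g a [genome()].
#' @param fasta_path,gff3_path output paths.
#' @param type GFF3 feature type to write (default `gene`).
#' @return invisibly, the two paths.
#' @export
write_genome <- function(g, fasta_path, gff3_path, type = "gene") {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$contigs), fasta_path)
  f <- g$features
  attrs <- paste0("ID=", f$feature_id)
  if ("family_truth" %in% names(f)) {
    has <- !is.na(f$family_truth)
    attrs[has] <- paste0(attrs[has], ";family=", f$family_truth[has],
                         ";status=", f$status_truth[has])
  }
  lines <- c("##gff-version 3",
             paste(f$contig_id, "blockevol", type, f$start + 1L, f$end, ".",
                   f$strand, ".", attrs, sep = "\t"))
  writeLines(lines, gff3_path)
  invisible(c(fasta_path, gff3_path))
}

#' Minimal GenBank flat-file reader
#'
#' Parses LOCUS name, `gene`/`CDS` feature locations (plain and
#' `complement(...)` ranges) and the ORIGIN sequence of a single- or
#' multi-record GenBank flat file. Joins and fuzzy locations are not
#' supported; this reader covers simple annotated contigs only.
#'
#' @param path GenBank flat file.
#' @param genome_id identifier (default: file name).
#' @return a [genome()].
#' @export
read_genbank <- function(path, genome_id = sub("\\.[^.]*$", "",
                                               basename(path))) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^LOCUS", lines)))
  recs <- recs[names(recs) != "0"]
  if (length(recs) == 0L) stop("read_genbank: no LOCUS record")
  contigs <- character(0)
  feats <- list()
  n <- 0L
  for (rec in recs) {
    locus <- strsplit(trimws(rec[1]), "\\s+")[[1]][2]
    ori <- grep("^ORIGIN", rec)
    if (length(ori) != 1L) stop("read_genbank: missing ORIGIN in ", locus)
    seq_lines <- rec[(ori + 1):length(rec)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    contigs[locus] <- seq
    fstart <- grep("^FEATURES", rec)
    if (length(fstart) == 1L) {
      body <- rec[(fstart + 1):(ori - 1)]
      hits <- grep("^\\s{5}(gene|CDS)\\s", body)
      for (h in hits) {
        type <- trimws(substr(body[h], 1, 21))
        loc <- trimws(substr(body[h], 22, nchar(body[h])))
        comp <- grepl("^complement", loc)
        m <- regmatches(loc, regexec("(\\d+)\\.\\.(\\d+)", loc))[[1]]
        if (length(m) != 3) next
        n <- n + 1L
        feats[[n]] <- data.frame(
          feature_id = sprintf("%s_f%03d", locus, n), contig_id = locus,
          start = as.integer(m[2]) - 1L, end = as.integer(m[3]),
          strand = if (comp) "-" else "+", type = type,
          stringsAsFactors = FALSE)
      }
    }
  }
  feats <- feats[!duplicated(vapply(feats, function(f)
    paste(f$contig_id, f$start, f$end, f$strand), ""))]
  if (length(feats) == 0L) stop("read_genbank: no gene/CDS features")
  genome(genome_id, contigs, do.call(rbind, feats))
}

#' Read / write Newick trees
#'
#' Thin wrappers over `ape` that turn silent parse failures into errors.
#'
#' @param path Newick file (for [read_tree()]) or output path.
#' @param tree a `phylo` object.
#' @return [read_tree()]: a `phylo`; [write_tree()]: the path, invisibly.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("read_tree: cannot parse Newick in ", path)
  tree
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read an aligned FASTA into a residue matrix
#'
#' @param path aligned FASTA (protein or nucleotide); all records must have
#'   equal length.
#' @return character matrix, one row per sequence (rownames = ids), one
#'   column per alignment column.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("read_alignment: ragged alignment (unequal record lengths)")
  as_alignment_matrix(as.character(aln))
}

#' @rdname read_alignment
#' @param seqs named character vector of equal-length sequences.
#' @export
as_alignment_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("as_alignment_matrix: unequal sequence lengths")
  mat <- matrix(unlist(strsplit(unname(seqs), ""), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  rownames(mat) <- names(seqs)
  mat
}

#' Write a residue matrix (or named sequences) as aligned FASTA
#'
#' @param aln character matrix from [read_alignment()] or a named character
#'   vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- if (is.matrix(aln)) apply(aln, 1, paste, collapse = "") else aln
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
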