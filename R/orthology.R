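#' Read tabular homology-search hits (outfmt-6 style)
#'
#' Parses the standard 12-column tab-separated hit table (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) as produced by common search tools. Percent identity is
#' converted to a fraction.
#'
#' @param path TSV file without header.
#' @return hit data frame with columns `query_label`, `subject_feature_id`,
#'   `identity` (fraction), `aligned_length`, `query_start`, `query_end`,
#'   `subject_start`, `subject_end`, `evalue`, `bitscore`.
#' @export
read_hits <- function(path) {
  h <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(h) < 12) stop("read_hits: expected 12 tab-separated columns")
  data.frame(query_label = as.character(h[[1]]),
             subject_feature_id = as.character(h[[2]]),
             identity = h[[3]] / 100, aligned_length = h[[4]],
             query_start = h[[7]], query_end = h[[8]],
             subject_start = h[[9]], subject_end = h[[10]],
             evalue = h[[11]], bitscore = h[[12]],
             stringsAsFactors = FALSE)
}

#' @rdname read_hits
#' @param hits hit data frame as returned by [read_hits()] or [align_hits()].
#' @param path output TSV path.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(hits$query_label, hits$subject_feature_id,
                    round(hits$identity * 100, 2), hits$aligned_length,
                    0L, 0L, hits$query_start, hits$query_end,
                    hits$subject_start, hits$subject_end,
                    format(hits$evalue, digits = 3), hits$bitscore)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Internal pluggable search adapter: local alignment of family queries
#'
#' Aligns each reference-family query sequence against each genome feature
#' with a local (Smith-Waterman) alignment and reports hits in the same shape
#' as [read_hits()]. E-values follow the Karlin-Altschul form
#' `K * m * n * exp(-lambda * S)` with ungapped nucleotide constants, which
#' is adequate for thresholding synthetic data; production pipelines should
#' supply real search-tool output instead.
#'
#' @param g a [genome()].
#' @param queries named character vector/list of family query sequences
#'   (names are family labels).
#' @param evalue_keep drop hits with larger E-value (default 10).
#' @return hit data frame (see [read_hits()]).
#' @export
align_hits <- function(g, queries, evalue_keep = 10) {
  lambda <- 1.33; K <- 0.621
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  rows <- list()
  for (fid in g$features$feature_id) {
    sseq <- feature_seq(g, fid)
    for (f in names(queries)) {
      q <- paste(queries[[f]], collapse = "")
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(sseq),
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      s <- Biostrings::score(aln)
      if (s <= 0) next
      ev <- K * nchar(q) * nchar(sseq) * exp(-lambda * s)
      if (ev > evalue_keep) next
      pat <- Biostrings::pattern(aln)
      sub <- Biostrings::subject(aln)
      rows[[length(rows) + 1L]] <- data.frame(
        query_label = f, subject_feature_id = fid,
        identity = Biostrings::pid(aln) / 100,
        aligned_length = Biostrings::nchar(aln),
        query_start = Biostrings::start(pat), query_end = Biostrings::end(pat),
        subject_start = Biostrings::start(sub), subject_end = Biostrings::end(sub),
        evalue = ev, bitscore = s, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(query_label = character(0),
                      subject_feature_id = character(0), identity = numeric(0),
                      aligned_length = integer(0), query_start = integer(0),
                      query_end = integer(0), subject_start = integer(0),
                      subject_end = integer(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Assign features to reference families from homology hits
#'
#' Hits above the E-value cutoff are discarded (the boundary is inclusive:
#' a hit at exactly `evalue_max` survives). Each surviving subject feature
#' receives the best family by lowest E-value, then highest identity, then
#' label order; output order and content are independent of input row order.
#'
#' @param hits hit data frame ([read_hits()] / [align_hits()]).
#' @param families reference family table ([reference_families()]).
#' @param evalue_max inclusive E-value cutoff (default `1e-10`).
#' @return call data frame: `subject_feature_id`, `labels`, `status`
#'   (`"full"`; see [classify_pseudo()] and [detect_fusions()]), `evalue`,
#'   `identity`.
#' @export
call_orthologs <- function(hits, families = reference_families(),
                           evalue_max = 1e-10) {
  hits <- hits[hits$query_label %in% families$label, , drop = FALSE]
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(subject_feature_id = character(0), labels = character(0),
                      status = character(0), evalue = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  hits <- hits[order(hits$subject_feature_id, hits$evalue, -hits$identity,
                     hits$query_label), , drop = FALSE]
  best <- hits[!duplicated(hits$subject_feature_id), , drop = FALSE]
  out <- data.frame(subject_feature_id = best$subject_feature_id,
                    labels = best$query_label, status = "full",
                    evalue = best$evalue, identity = best$identity,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify pseudogene calls by the length/identity rule
#'
#' A call becomes `pseudo` when the subject is shorter than `len_frac` of the
#' family's query length (strict) and identity exceeds `min_ident` (strict);
#' query and subject lengths must be in the same unit. By default the rule is
#' applied to cyp115 (family `a`) only, the one family the study screens for
#' fragments, but any set of families may be screened.
#'
#' @param calls call data frame from [call_orthologs()].
#' @param subject_lengths named numeric vector: length of each subject
#'   feature (same unit as `query_length` in `families`).
#' @param families reference family table.
#' @param pseudo_families labels the rule applies to (default `"a"`).
#' @param len_frac length threshold as a fraction of the query (default 0.60).
#' @param min_ident identity threshold (default 0.50).
#' @return the calls with `status` updated to `"pseudo"` where the rule fires.
#' @export
classify_pseudo <- function(calls, subject_lengths,
                            families = reference_families(),
                            pseudo_families = "a",
                            len_frac = 0.60, min_ident = 0.50) {
  if (any(families$query_length <= 0))
    stop("classify_pseudo: invalid reference query_length")
  qlen <- stats::setNames(families$query_length, families$label)
  for (i in seq_len(nrow(calls))) {
    lab <- calls$labels[i]
    if (!(lab %in% pseudo_families)) next
    slen <- subject_lengths[[calls$subject_feature_id[i]]]
    if (is.null(slen) || is.na(slen)) next
    if (slen < len_frac * qlen[[lab]] && calls$identity[i] > min_ident)
      calls$status[i] <- "pseudo"
  }
  calls
}

#' Detect ferredoxin fusion genes from hit span placement
#'
#' When the block has no standalone ferredoxin (family `d`) call but the
#' `d` query hits a feature already called cyp114 (`c`) or sdr (`e`) with at
#' least `cov_min` of the `d` query aligned inside that feature, the call is
#' upgraded to a fusion carrying both labels (cyp114-fd or fd-sdr).
#'
#' @param calls call data frame from [call_orthologs()] (one genome).
#' @param hits the full hit table for the same genome (pre-filtering).
#' @param families reference family table.
#' @param evalue_max E-value cutoff for the fusion evidence hit.
#' @param fusion_family the query whose ORF may be merged (default `"d"`).
#' @param partners families it may fuse with (default `c("c", "e")`).
#' @param cov_min minimum fraction of the fusion-family query aligned within
#'   the partner feature (default 0.50).
#' @return the calls, with fused features carrying `labels` like `"c,d"` or
#'   `"d,e"` and `status = "fusion"`.
#' @export
detect_fusions <- function(calls, hits, families = reference_families(),
                           evalue_max = 1e-10, fusion_family = "d",
                           partners = c("c", "e"), cov_min = 0.50) {
  if (fusion_family %in% calls$labels) return(calls)  # standalone fd exists
  qlen <- families$query_length[families$label == fusion_family]
  if (length(qlen) != 1L) stop("detect_fusions: unknown fusion family")
  ev <- hits[hits$query_label == fusion_family &
               hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(ev) == 0L) return(calls)
  for (i in seq_len(nrow(ev))) {
    j <- which(calls$subject_feature_id == ev$subject_feature_id[i] &
                 calls$labels %in% partners & calls$status != "fusion")
    if (length(j) != 1L) next
    coverage <- (ev$query_end[i] - ev$query_start[i] + 1L) / qlen
    if (coverage < cov_min) next
    both <- sort(c(calls$labels[j], fusion_family))
    calls$labels[j] <- paste(both, collapse = ",")
    calls$status[j] <- "fusion"
  }
  calls
}
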