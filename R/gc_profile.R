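#' Sliding-window GC content
#'
#' GC fraction per window of `window_size` bp advanced by `step`, computed
#' as (#G + #C) / (#A + #C + #G + #T), case-insensitive; ambiguity codes are
#' excluded from numerator and denominator (set `ambiguous = "denominator"`
#' to count them toward the denominator instead).
#'
#' @param sequence nucleotide string (or character vector of single bases).
#' @param window_size window width in bp (default 500, as in the operon
#'   GC screen).
#' @param step step between window starts (default 1).
#' @param ambiguous how to treat non-ACGT bases: `"exclude"` (default) or
#'   `"denominator"`.
#' @return data frame with columns `start` (0-based window start) and `gc`.
#' @export
window_gc <- function(sequence, window_size = 500, step = 1,
                      ambiguous = c("exclude", "denominator")) {
  ambiguous <- match.arg(ambiguous)
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (window_size > n)
    stop("window_gc: window_size exceeds sequence length")
  is_gc <- chars %in% c("G", "C", "g", "c")
  is_acgt <- chars %in% c("A", "C", "G", "T", "a", "c", "g", "t")
  cg <- c(0, cumsum(is_gc))
  ct <- c(0, cumsum(if (ambiguous == "exclude") is_acgt else
    rep(TRUE, n)))
  starts <- seq(0L, n - window_size, by = step)
  num <- cg[starts + window_size + 1L] - cg[starts + 1L]
  den <- ct[starts + window_size + 1L] - ct[starts + 1L]
  data.frame(start = starts, gc = ifelse(den > 0, num / den, NA_real_))
}

seq_chars <- function(sequence) {
  if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else
    as.character(sequence)
}

region_gc <- function(chars, from, to, ambiguous = "exclude") {
  # 0-based half-open span
  s <- chars[(from + 1L):to]
  gc <- sum(s %in% c("G", "C", "g", "c"))
  den <- if (ambiguous == "exclude")
    sum(s %in% c("A", "C", "G", "T", "a", "c", "g", "t")) else length(s)
  if (den == 0) NA_real_ else gc / den
}

#' GC contrast of an operon span against its flanking DNA
#'
#' Computes the mean GC of the operon span and of the 10-kb (default)
#' regions on either side, and their difference in percentage points --
#' the horizontally transferred operon is expected to sit several points
#' above its host background. Flanks are truncated at contig ends and
#' flagged.
#'
#' @param g a [genome()] or a plain nucleotide string.
#' @param operon_span length-2 vector, 0-based half-open span of the operon.
#' @param flank flank width in bp (default 10000).
#' @param contig contig name when `g` is a genome (default: first contig).
#' @param ambiguous see [window_gc()].
#' @return list with `gc_operon`, `gc_upstream`, `gc_downstream` (fractions;
#'   `NA` when a flank has zero length), `delta` (operon GC minus mean flank
#'   GC, in percentage points) and `truncated` (logical, flank shorter than
#'   requested).
#' @export
region_contrast <- function(g, operon_span, flank = 10000, contig = NULL,
                            ambiguous = c("exclude", "denominator")) {
  ambiguous <- match.arg(ambiguous)
  seq <- if (inherits(g, "genome")) {
    if (is.null(contig)) contig <- names(g$contigs)[1]
    g$contigs[[contig]]
  } else g
  chars <- seq_chars(seq)
  n <- length(chars)
  s <- operon_span[1]; e <- operon_span[2]
  if (s < 0 || e > n || s >= e)
    stop("region_contrast: invalid operon span")
  up_from <- max(0L, s - flank)
  down_to <- min(n, e + flank)
  gc_up <- if (s > up_from) region_gc(chars, up_from, s, ambiguous) else NA_real_
  gc_down <- if (down_to > e) region_gc(chars, e, down_to, ambiguous) else NA_real_
  gc_op <- region_gc(chars, s, e, ambiguous)
  flank_mean <- mean(c(gc_up, gc_down), na.rm = TRUE)
  list(gc_operon = gc_op, gc_upstream = gc_up, gc_downstream = gc_down,
       delta = 100 * (gc_op - flank_mean),
       truncated = (s - up_from) < flank || (down_to - e) < flank)
}

#' GC content of named subregions and their pairwise contrasts
#'
#' Used to compare parts of a gene cluster against each other, e.g. the core
#' operon against an accessory gene with a different transfer history.
#'
#' @param g a [genome()] or nucleotide string.
#' @param spans named list of 0-based half-open spans.
#' @param contig,ambiguous see [region_contrast()].
#' @return list with `gc` (named fractions) and `delta` (matrix of pairwise
#'   differences, row minus column, in percentage points).
#' @export
subregion_contrast <- function(g, spans, contig = NULL,
                               ambiguous = c("exclude", "denominator")) {
  ambiguous <- match.arg(ambiguous)
  seq <- if (inherits(g, "genome")) {
    if (is.null(contig)) contig <- names(g$contigs)[1]
    g$contigs[[contig]]
  } else g
  chars <- seq_chars(seq)
  n <- length(chars)
  gc <- vapply(spans, function(sp) {
    if (sp[1] < 0 || sp[2] > n || sp[1] >= sp[2])
      stop("subregion_contrast: invalid span")
    region_gc(chars, sp[1], sp[2], ambiguous)
  }, 0)
  delta <- 100 * outer(gc, gc, `-`)
  list(gc = gc, delta = delta)
}
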