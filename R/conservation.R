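#' Construct a per-base DNA conservation track
#'
#' Holds PhyloP-style per-base scores for one or more chromosomes, plus the
#' threshold above which a base counts as conserved. Positions without a
#' score are reported as missing (`NA`), never as 0: downstream code treats
#' missing as "not conserved" but keeps an explicit count.
#'
#' @param chrom chromosome of the scored block
#' @param start 0-based genomic start of the block
#' @param scores numeric vector of per-base scores
#' @param threshold score at or above which a base is conserved (default 1.5,
#'   a package choice documented in the methods vignette, not a published value)
#' @return an object of class `dna_track`
#' @export
dna_track <- function(chrom, start, scores, threshold = 1.5) {
  x <- list(blocks = list(), threshold = threshold)
  class(x) <- "dna_track"
  add_track_block(x, chrom, start, scores)
}

add_track_block <- function(track, chrom, start, scores) {
  track$blocks[[length(track$blocks) + 1L]] <-
    list(chrom = chrom, start = as.integer(start), scores = as.numeric(scores))
  track
}

#' Query per-base conservation scores
#'
#' @param track a [dna_track()]
#' @param chrom chromosome
#' @param positions 0-based genomic positions
#' @return numeric vector of scores, `NA` where no score is available
#' @export
track_scores <- function(track, chrom, positions) {
  out <- rep(NA_real_, length(positions))
  for (b in track$blocks) {
    if (b$chrom != chrom) next
    idx <- positions - b$start + 1L
    ok <- idx >= 1L & idx <= length(b$scores)
    out[ok] <- b$scores[idx[ok]]
  }
  out
}

# Conserved flags for positions; missing scores are FALSE but counted.
conserved_dna <- function(track, chrom, positions) {
  s <- track_scores(track, chrom, positions)
  flags <- !is.na(s) & s >= track$threshold
  attr(flags, "n_missing") <- sum(is.na(s))
  flags
}

#' Read a DNA conservation track from fixed-step wig or bedGraph
#'
#' @param path input file
#' @param threshold conservation threshold stored on the track
#' @param format `"auto"` (by extension), `"wig"` or `"bedGraph"`
#' @return a [dna_track()]
#' @export
read_dna_track <- function(path, threshold = 1.5,
                           format = c("auto", "wig", "bedGraph")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedGraph" else "wig"
  gr <- rtracklayer::import(path, format = format)
  track <- list(blocks = list(), threshold = threshold)
  class(track) <- "dna_track"
  # expand ranges to per-base blocks, merging runs per chromosome
  for (chrom in unique(as.character(GenomicRanges::seqnames(gr)))) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    g <- g[order(GenomicRanges::start(g))]
    pos <- unlist(lapply(seq_along(g), function(i)
      seq.int(GenomicRanges::start(g)[i], GenomicRanges::end(g)[i])), use.names = FALSE)
    val <- rep(S4Vectors::mcols(g)$score, GenomicRanges::width(g))
    # split into contiguous blocks so gaps stay missing
    brk <- cumsum(c(1L, as.integer(diff(pos) != 1L)))
    for (k in unique(brk)) {
      sel <- brk == k
      track <- add_track_block(track, chrom, pos[sel][1] - 1L, val[sel])
    }
  }
  track
}

#' Write a DNA conservation track as fixed-step wig
#'
#' @param track a [dna_track()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in track$blocks) {
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1", b$chrom,
                       b$start + 1L), con)
    writeLines(format(b$scores, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' Construct a per-residue protein conservation track
#'
#' Scores are keyed by transcript id, one value per residue of the encoded
#' protein. When `threshold` is `NULL` (the default) a residue is conserved
#' when its score reaches the upper quartile of that protein's own scores —
#' a per-protein adaptive threshold; pass a number to use a fixed cutoff.
#'
#' @param scores named list: transcript id -> numeric vector of residue scores
#' @param threshold fixed conservation threshold, or `NULL` for per-protein
#'   upper quartile
#' @return an object of class `protein_track`
#' @export
protein_track <- function(scores, threshold = NULL) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  x <- list(scores = lapply(scores, as.numeric), threshold = threshold)
  class(x) <- "protein_track"
  x
}

#' @export
print.protein_track <- function(x, ...) {
  cat(sprintf("<protein_track> %d protein(s), threshold: %s\n",
              length(x$scores),
              if (is.null(x$threshold)) "per-protein upper quartile"
              else format(x$threshold)))
  invisible(x)
}

# Logical conserved flags for one transcript's residues; NULL if no scores.
conserved_residues <- function(track, transcript_id) {
  s <- track$scores[[transcript_id]]
  if (is.null(s)) return(NULL)
  thr <- track$threshold %||% as.numeric(stats::quantile(s, 0.75, names = FALSE))
  s >= thr
}

#' Read protein conservation scores from TSV
#'
#' Expects columns `transcript_id`, `position` (1-based residue index) and
#' `score`.
#'
#' @param path input file
#' @param threshold see [protein_track()]
#' @return a [protein_track()]
#' @export
read_protein_scores <- function(path, threshold = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "score")
  if (!all(need %in% names(d)))
    stop("TSV must have columns: ", paste(need, collapse = ", "))
  scores <- lapply(split(d, d$transcript_id), function(g) {
    v <- rep(NA_real_, max(g$position))
    v[g$position] <- g$score
    v
  })
  protein_track(scores, threshold)
}

#' Write protein conservation scores as TSV
#'
#' @param track a [protein_track()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_protein_scores <- function(track, path) {
  rows <- do.call(rbind, lapply(names(track$scores), function(tx) {
    s <- track$scores[[tx]]
    data.frame(transcript_id = tx, position = seq_along(s), score = s)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
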