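#' Construct a transcript model
#'
#' The transcript model is the coordinate frame for every feature: exon
#' structure plus the genomic bounds of the coding region. All coordinates
#' are 0-based, half-open; exons are stored genomic-ascending, and the
#' `strand` determines transcript (5'->3') orientation.
#'
#' A transcript is *valid/complete* when it has a CDS whose length is a
#' positive multiple of 3. Invalid transcripts are kept but flagged, so
#' callers can mirror the removal of genes with invalid/incomplete
#' transcripts during dataset curation.
#'
#' @param transcript_id,gene_id identifiers
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param exons 2-column matrix (start, end), 0-based half-open
#' @param cds_start,cds_end genomic bounds of the coding region
#'   (0-based half-open); `NA` when the transcript has no CDS
#' @return an object of class `transcript_model`
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds_start = NA, cds_end = NA) {
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons")

  has_cds <- !is.na(cds_start) && !is.na(cds_end) && cds_end > cds_start
  segs <- NULL
  coding_length <- 0L
  if (has_cds) {
    s <- pmax(exons[, 1], as.integer(cds_start))
    e <- pmin(exons[, 2], as.integer(cds_end))
    keep <- e > s
    segs <- cbind(start = s[keep], end = e[keep])
    if (strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
    len <- segs[, 2] - segs[, 1]
    coding_length <- as.integer(sum(len))
    segs <- cbind(segs, toffset = as.integer(cumsum(c(0L, len))[seq_along(len)]))
  }
  t <- list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exons = exons,
    cds_start = if (has_cds) as.integer(cds_start) else NA_integer_,
    cds_end = if (has_cds) as.integer(cds_end) else NA_integer_,
    coding_segs = segs, coding_length = coding_length,
    valid = has_cds && coding_length > 0L && coding_length %% 3L == 0L
  )
  class(t) <- "transcript_model"
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s%s, %d exon(s), CDS %d bp%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$coding_length, if (x$valid) "" else " [INVALID]"))
  invisible(x)
}

transcript_span <- function(t) c(min(t$exons[, 1]), max(t$exons[, 2]))

#' Map a genomic position into CDS coordinates
#'
#' @param t a [transcript_model()]
#' @param pos genomic position (0-based)
#' @return a list with `status` (`"coding"`, `"non-coding"`), `offset`
#'   (0-based bp into the coding sequence, `NA` when non-coding) and
#'   `distance` (bp to the nearest exon edge, for non-coding positions).
#'   Positions outside the transcript span are an error.
#' @export
genomic_to_cds <- function(t, pos) {
  span <- transcript_span(t)
  if (pos < span[1] || pos >= span[2])
    stop(sprintf("position %d outside transcript span [%d, %d)",
                 pos, span[1], span[2]))
  if (!is.null(t$coding_segs)) {
    for (i in seq_len(nrow(t$coding_segs))) {
      s <- t$coding_segs[i, ]
      if (pos >= s["start"] && pos < s["end"]) {
        off <- if (t$strand == "+") s[["toffset"]] + (pos - s[["start"]])
               else s[["toffset"]] + (s[["end"]] - 1L - pos)
        return(list(status = "coding", offset = as.integer(off), distance = 0L))
      }
    }
  }
  # non-coding: distance to the nearest exon edge (0 when inside an exon)
  inside <- pos >= t$exons[, 1] & pos < t$exons[, 2]
  d <- if (any(inside)) 0L else
    min(abs(c(t$exons[, 1] - pos, pos - (t$exons[, 2] - 1L))))
  list(status = "non-coding", offset = NA_integer_, distance = as.integer(d))
}

#' Map a CDS offset back to the genome
#'
#' Inverse of [genomic_to_cds()] for coding positions.
#'
#' @param t a [transcript_model()]
#' @param offset 0-based bp into the coding sequence
#' @return genomic position (0-based)
#' @export
cds_to_genomic <- function(t, offset) {
  if (is.null(t$coding_segs) || offset < 0 || offset >= t$coding_length)
    stop("offset outside coding sequence")
  for (i in seq_len(nrow(t$coding_segs))) {
    s <- t$coding_segs[i, ]
    len <- s[["end"]] - s[["start"]]
    if (offset >= s[["toffset"]] && offset < s[["toffset"]] + len) {
      rel <- offset - s[["toffset"]]
      return(as.integer(if (t$strand == "+") s[["start"]] + rel
                        else s[["end"]] - 1L - rel))
    }
  }
  stop("unreachable")
}

# Genomic positions of all coding bases, in transcript (5'->3') order.
coding_positions <- function(t) {
  if (is.null(t$coding_segs)) return(integer())
  unlist(lapply(seq_len(nrow(t$coding_segs)), function(i) {
    s <- t$coding_segs[i, ]
    p <- seq.int(s[["start"]], s[["end"]] - 1L)
    if (t$strand == "-") rev(p) else p
  }), use.names = FALSE)
}

# Union of coding bases over a gene's transcripts (sorted genomic order).
gene_coding_positions <- function(transcripts) {
  sort(unique(unlist(lapply(transcripts, coding_positions), use.names = FALSE)))
}

#' Read transcript models from GTF/GFF3
#'
#' Exon and CDS records are grouped by transcript; each transcript is
#' validated (CDS present, coding length a positive multiple of 3) and
#' flagged — never silently dropped.
#'
#' @param path GTF or GFF3 file
#' @return a named list mapping `gene_id` to a list of [transcript_model()]s
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]; type <- type[keep]
  tid <- as.character(md$transcript_id)
  gid <- as.character(md$gene_id)
  if (anyNA(tid)) stop("records without transcript_id attribute")

  out <- list()
  for (tx in unique(tid)) {
    sel <- tid == tx
    g <- gr[sel]
    strand <- unique(as.character(GenomicRanges::strand(g)))
    if (length(strand) != 1 || !strand %in% c("+", "-"))
      stop("unknown or inconsistent strand for transcript ", tx)
    is_exon <- type[sel] == "exon"
    ex <- g[is_exon]; cds <- g[!is_exon]
    if (length(ex) == 0) ex <- cds  # CDS-only annotation
    exons <- cbind(GenomicRanges::start(ex) - 1L, GenomicRanges::end(ex))
    cs <- if (length(cds)) min(GenomicRanges::start(cds)) - 1L else NA
    ce <- if (length(cds)) max(GenomicRanges::end(cds)) else NA
    gene <- unique(gid[sel]); gene <- gene[!is.na(gene)][1]
    t <- transcript_model(tx, gene, unique(as.character(GenomicRanges::seqnames(g))),
                          strand, exons, cs, ce)
    out[[gene]] <- c(out[[gene]], setNames(list(t), tx))
  }
  n_invalid <- sum(!vapply(unlist(out, recursive = FALSE), `[[`, TRUE, "valid"))
  if (n_invalid > 0)
    fs_log(sprintf("read_transcripts: %d invalid/incomplete transcript(s) flagged",
                   n_invalid))
  out
}

#' Write transcript models as GTF
#'
#' @param transcripts a list of [transcript_model()]s, or the gene-keyed list
#'   returned by [read_transcripts()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gtf <- function(transcripts, path) {
  if (length(transcripts) && inherits(transcripts[[1]], "transcript_model"))
    txs <- transcripts
  else txs <- unlist(transcripts, recursive = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in txs) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', t$gene_id, t$transcript_id)
    for (i in seq_len(nrow(t$exons)))
      writeLines(sprintf("%s\tfsindel\texon\t%d\t%d\t.\t%s\t.\t%s",
                         t$chrom, t$exons[i, 1] + 1L, t$exons[i, 2],
                         t$strand, attrs), con)
    if (!is.na(t$cds_start) && !is.null(t$coding_segs)) {
      segs <- t$coding_segs[order(t$coding_segs[, 1]), , drop = FALSE]
      for (i in seq_len(nrow(segs)))
        writeLines(sprintf("%s\tfsindel\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                           t$chrom, segs[i, 1] + 1L, segs[i, 2],
                           t$strand, attrs), con)
    }
  }
  invisible(path)
}
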