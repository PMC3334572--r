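#' Construct an indel call set
#'
#' An indel set is a data frame with one row per insertion/deletion call.
#' Positions are stored 0-based at the VCF-style anchor base (the shared
#' base immediately 5' of the inserted/deleted sequence); alleles are kept
#' in VCF style (anchor included) so that I/O round-trips exactly.
#'
#' Only pure insertions or pure deletions are accepted: after trimming the
#' shared anchor base, exactly one of the two alleles must be empty.
#' Substitutions and complex variants are rejected.
#'
#' @param chrom character vector of chromosome names
#' @param pos integer vector of 0-based anchor positions
#' @param ref,alt reference and alternate allele strings (VCF style)
#' @param id optional identifiers; autogenerated when missing
#' @param af optional allele frequencies in `[0, 1]`
#' @return a data frame of class `indel_set` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `id`, `af`, `net_length`
#' @export
indel_set <- function(chrom, pos, ref, alt, id = NULL, af = NULL) {
  n <- length(pos)
  chrom <- as.character(chrom)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  if (is.null(id)) id <- sprintf("indel_%d", seq_len(n))
  if (is.null(af)) af <- rep(NA_real_, n)
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("allele frequencies must lie in [0, 1]")
  for (i in seq_len(n)) {
    tr <- trim_alleles(ref[i], alt[i])
    if (!tr$pure)
      stop(sprintf("record %d (%s:%d %s>%s): not a pure insertion/deletion",
                   i, chrom[i], pos[i] + 1L, ref[i], alt[i]))
  }
  x <- data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    id = as.character(id), af = as.numeric(af),
    net_length = nchar(alt) - nchar(ref),
    stringsAsFactors = FALSE
  )
  class(x) <- c("indel_set", "data.frame")
  x
}

# Trim the shared leading anchor base(s); a call is a pure indel iff one
# trimmed allele is empty and the other is not.
trim_alleles <- function(ref, alt) {
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
  }
  list(ref = ref, alt = alt,
       pure = xor(nchar(ref) == 0, nchar(alt) == 0))
}

#' Is an indel frameshifting?
#'
#' @param x an `indel_set`
#' @return logical vector: `TRUE` where `|net_length| mod 3 != 0`
#' @export
is_frameshifting <- function(x) {
  abs(x$net_length) %% 3L != 0L
}

# Genomic interval of the changed bases, 0-based half-open.
# Deletions: the deleted bases; insertions: zero-width at the junction.
indel_interval <- function(x) {
  start <- x$pos + 1L
  end <- start + pmax(0L, -x$net_length)
  data.frame(start = start, end = end)
}

# First genomic base whose reading is disrupted (leftmost affected base).
indel_affected_start <- function(x) x$pos + 1L

#' Read indel calls from VCF or TSV
#'
#' VCF positions (1-based) are converted to the internal 0-based anchor
#' convention. Records that are not pure insertions/deletions are skipped
#' and their count logged. The TSV format is the one written by
#' [write_indels()]: header `chrom pos ref alt id af` with 1-based
#' positions.
#'
#' @param path input file
#' @param format `"auto"` (default, by extension/content), `"vcf"` or `"tsv"`
#' @return an [indel_set()]; attribute `n_skipped` counts skipped records
#' @export
read_indels <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("\\.vcf$", path) || startsWith(first, "##fileformat=VCF"))
      "vcf" else "tsv"
  }
  if (format == "vcf") read_indels_vcf(path) else read_indels_tsv(path)
}

read_indels_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) return(empty_indel_set(0L))
  keep <- list()
  n_skipped <- 0L
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5)
      stop(sprintf("malformed VCF record at data line %d: fewer than 5 fields", i))
    pos1 <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos1))
      stop(sprintf("malformed VCF record at data line %d: non-integer POS", i))
    ref <- toupper(f[4])
    alts <- strsplit(toupper(f[5]), ",", fixed = TRUE)[[1]]
    af <- NA_real_
    if (length(f) >= 8) {
      m <- regmatches(f[8], regexpr("(?:^|;)AF=([0-9.eE+-]+)", f[8]))
      if (length(m)) af <- as.numeric(sub(".*AF=", "", m))
    }
    for (alt in alts) {
      tr <- trim_alleles(ref, alt)
      if (!tr$pure) { n_skipped <- n_skipped + 1L; next }
      keep[[length(keep) + 1L]] <- list(
        chrom = f[1], pos = pos1 - 1L, ref = ref, alt = alt,
        id = if (f[3] == "." || f[3] == "") NA_character_ else f[3], af = af)
    }
  }
  if (n_skipped > 0)
    fs_log(sprintf("read_indels: skipped %d non-indel record(s)", n_skipped))
  if (length(keep) == 0) {
    out <- empty_indel_set(n_skipped)
    return(out)
  }
  ids <- vapply(keep, `[[`, "", "id")
  if (anyNA(ids)) ids[is.na(ids)] <- sprintf("indel_%d", which(is.na(ids)))
  out <- indel_set(
    chrom = vapply(keep, `[[`, "", "chrom"),
    pos = vapply(keep, `[[`, 0L, "pos"),
    ref = vapply(keep, `[[`, "", "ref"),
    alt = vapply(keep, `[[`, "", "alt"),
    id = ids,
    af = vapply(keep, `[[`, 0, "af"))
  attr(out, "n_skipped") <- n_skipped
  out
}

read_indels_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = NA)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(d)))
    stop("TSV must have columns: ", paste(need, collapse = ", "))
  out <- indel_set(d$chrom, as.integer(d$pos) - 1L, d$ref, d$alt,
                   id = d$id %||% NULL,
                   af = if ("af" %in% names(d)) d$af else NULL)
  attr(out, "n_skipped") <- 0L
  out
}

empty_indel_set <- function(n_skipped = 0L) {
  out <- indel_set(character(), integer(), character(), character())
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write indel calls to VCF or TSV
#'
#' @param x an [indel_set()]
#' @param path output file
#' @param format `"tsv"` (default) or `"vcf"`; positions are written 1-based
#' @return `path`, invisibly
#' @export
write_indels <- function(x, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- data.frame(chrom = x$chrom, pos = x$pos + 1L, ref = x$ref,
                    alt = x$alt, id = x$id, af = x$af,
                    net_length = x$net_length)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    info <- ifelse(is.na(x$af), ".", sprintf("AF=%g", x$af))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                       x$chrom, x$pos + 1L, x$id, x$ref, x$alt, info), con)
  }
  invisible(path)
}

#' Left-normalize indels against a genome
#'
#' Shifts every indel to its leftmost equivalent position (the community
#' standard), so that positions are deterministic before feature extraction
#' and before exact-match comparisons between call sets.
#'
#' @param x an [indel_set()]
#' @param genome a [Biostrings::DNAStringSet] named by chromosome
#' @return the normalized `indel_set`
#' @export
normalize_indels <- function(x, genome) {
  for (i in seq_len(nrow(x))) {
    if (!x$chrom[i] %in% names(genome))
      stop("chromosome not in genome: ", x$chrom[i])
    chromseq <- genome[[x$chrom[i]]]
    tr <- trim_alleles(x$ref[i], x$alt[i])
    s <- strsplit(if (nchar(tr$ref)) tr$ref else tr$alt, "")[[1]]  # event seq
    pos <- x$pos[i]  # 0-based anchor
    # shift left while the base at the anchor equals the event's last base
    while (pos >= 1) {
      anchor_base <- as.character(Biostrings::subseq(chromseq, pos + 1L, pos + 1L))
      if (anchor_base != s[length(s)]) break
      s <- c(anchor_base, s[-length(s)])
      pos <- pos - 1L
    }
    if (pos != x$pos[i]) {
      new_anchor <- as.character(Biostrings::subseq(chromseq, pos + 1L, pos + 1L))
      ev <- paste(s, collapse = "")
      if (x$net_length[i] < 0) {        # deletion
        x$ref[i] <- paste0(new_anchor, ev); x$alt[i] <- new_anchor
      } else {                           # insertion
        x$ref[i] <- new_anchor; x$alt[i] <- paste0(new_anchor, ev)
      }
      x$pos[i] <- pos
    }
  }
  x
}
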