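#' @name features
#' @title The four selected indel features
#'
#' @description
#' For a frameshifting indel, every codon downstream of the indel site is
#' scrambled, so the *affected* part of a transcript is taken to run from
#' the first disrupted coding base to the end of the coding sequence
#' (deleted bases included). The four features quantify how much conserved
#' sequence that region removes and where the indel sits:
#'
#' * `f14` — percentage of the gene's conserved coding DNA bases that fall
#'   in the affected region (union over transcripts; gene-level denominator);
#' * `f5`  — indel location as a percentage of coding length, maximum over
#'   transcripts;
#' * `f18` — percentage of conserved amino acids lost (residues from the
#'   first frameshifted codon onward, counted against the original protein),
#'   maximum over transcripts;
#' * `f15` — minimum distance (bp) of the indel to an exon boundary over
#'   the transcripts whose exon contains it.
NULL

# First affected CDS offset of an indel in one transcript, or NA when the
# indel has no coding consequence for this transcript. Strand-aware: the
# affected set is the deleted coding bases plus everything downstream of
# the event in transcript orientation.
first_affected_offset <- function(indel, t) {
  if (is.null(t$coding_segs) || indel$chrom != t$chrom) return(NA_integer_)
  iv <- indel_interval(indel)
  gpos <- coding_positions(t)
  affected <- if (t$strand == "+") gpos >= iv$start else gpos <= iv$end - 1L
  if (!any(affected)) return(NA_integer_)
  as.integer(which(affected)[1] - 1L)  # coding_positions is in 5'->3' order
}

#' CDS interval affected by a frameshifting indel
#'
#' @param indel one-row [indel_set()]
#' @param t a [transcript_model()]
#' @return integer vector `c(first, coding_length)` describing the half-open
#'   affected interval `[first, coding_length)` in CDS coordinates, or `NULL`
#'   when the indel has no coding effect on this transcript
#' @export
affected_cds_region <- function(indel, t) {
  first <- first_affected_offset(indel, t)
  if (is.na(first)) return(NULL)
  c(first = first, end = t$coding_length)
}

uncomputable <- function(reason) {
  structure(NA_real_, flag = reason)
}

#' Fraction of the gene's conserved DNA bases affected (feature f14)
#'
#' @param indel one-row [indel_set()]
#' @param transcripts list of the gene's [transcript_model()]s
#' @param dna_track a [dna_track()], or `NULL` (feature uncomputable)
#' @return percentage in `[0, 100]`; `NA` with a `flag` attribute when
#'   uncomputable
#' @export
frac_conserved_dna_affected <- function(indel, transcripts, dna_track) {
  if (is.null(dna_track)) return(uncomputable("no-dna-conservation"))
  gene_pos <- gene_coding_positions(transcripts)
  if (length(gene_pos) == 0) return(uncomputable("no-coding-sequence"))
  affected_pos <- unique(unlist(lapply(transcripts, function(t) {
    reg <- affected_cds_region(indel, t)
    if (is.null(reg)) return(integer())
    gpos <- coding_positions(t)
    gpos[seq.int(reg[["first"]] + 1L, length(gpos))]
  }), use.names = FALSE))
  if (length(affected_pos) == 0) return(uncomputable("no-coding-overlap"))
  cons_all <- conserved_dna(dna_track, indel$chrom, gene_pos)
  den <- sum(cons_all)
  if (den == 0) {
    out <- 0
    attr(out, "flag") <- "no-conserved-bases"
    return(out)
  }
  num <- sum(conserved_dna(dna_track, indel$chrom, affected_pos))
  100 * num / den
}

#' Maximum relative indel location (feature f5)
#'
#' @inheritParams frac_conserved_dna_affected
#' @return percentage in `[0, 100]`: `100 * offset / coding_length`,
#'   maximised over transcripts with a coding overlap
#' @export
max_relative_location <- function(indel, transcripts) {
  vals <- vapply(transcripts, function(t) {
    first <- first_affected_offset(indel, t)
    if (is.na(first)) NA_real_ else 100 * first / t$coding_length
  }, numeric(1))
  if (all(is.na(vals))) return(uncomputable("no-coding-overlap"))
  max(vals, na.rm = TRUE)
}

#' Maximum fraction of conserved amino acids lost (feature f18)
#'
#' Residues at or after the first frameshifted codon of the original
#' protein count as lost; the denominator is the number of conserved
#' residues of that protein.
#'
#' @inheritParams frac_conserved_dna_affected
#' @param protein_track a [protein_track()], or `NULL` (uncomputable)
#' @return percentage in `[0, 100]`
#' @export
max_frac_conserved_aa_lost <- function(indel, transcripts, protein_track) {
  if (is.null(protein_track)) return(uncomputable("no-protein-conservation"))
  flagged_zero <- FALSE
  vals <- vapply(transcripts, function(t) {
    first <- first_affected_offset(indel, t)
    cons <- conserved_residues(protein_track, t$transcript_id)
    if (is.na(first) || is.null(cons)) return(NA_real_)
    total <- sum(cons)
    if (total == 0) { flagged_zero <<- TRUE; return(0) }
    k <- first %/% 3L  # 0-based index of the first frameshifted codon
    lost <- if (k + 1L > length(cons)) 0L else sum(cons[seq.int(k + 1L, length(cons))])
    100 * lost / total
  }, numeric(1))
  if (all(is.na(vals))) return(uncomputable("no-protein-scores"))
  out <- max(vals, na.rm = TRUE)
  if (flagged_zero && out == 0) attr(out, "flag") <- "no-conserved-residues"
  out
}

#' Minimum distance of the indel to an exon boundary (feature f15)
#'
#' Distance is measured in bp from the indel's leftmost affected genomic
#' base to each edge of the containing exon; a base at an edge is distance
#' 0. Minimised over all transcripts whose exon contains the indel.
#'
#' @inheritParams frac_conserved_dna_affected
#' @return non-negative integer bp
#' @export
min_dist_exon_boundary <- function(indel, transcripts) {
  a <- indel_affected_start(indel)
  vals <- vapply(transcripts, function(t) {
    if (indel$chrom != t$chrom) return(NA_real_)
    hit <- a >= t$exons[, 1] & a < t$exons[, 2]
    if (!any(hit)) return(NA_real_)
    ex <- t$exons[which(hit)[1], ]
    min(a - ex[1], ex[2] - 1L - a)
  }, numeric(1))
  if (all(is.na(vals))) return(uncomputable("not-exonic"))
  as.integer(min(vals, na.rm = TRUE))
}

# ---- feature registry (extension point for additional features) ----

.feature_registry <- new.env(parent = emptyenv())

#' Register an extra feature function
#'
#' Registered features are computed by [extract_features()] alongside the
#' four built-in ones. The function receives `(indel, transcripts, tracks)`
#' where `tracks` is `list(dna = ..., protein = ...)`, and must return a
#' single numeric value.
#'
#' @param name feature name (column name in feature tables)
#' @param fn feature function
#' @export
register_feature <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .feature_registry)
  invisible(name)
}

#' List registered extra features
#' @return character vector of names
#' @export
registered_features <- function() ls(.feature_registry)

#' Remove a registered extra feature
#' @param name feature name
#' @export
unregister_feature <- function(name) {
  if (exists(name, envir = .feature_registry))
    rm(list = name, envir = .feature_registry)
  invisible(name)
}

#' Extract the feature vector for one frameshifting indel
#'
#' @param indel one-row [indel_set()]
#' @param transcripts list of the gene's [transcript_model()]s
#' @param dna_track a [dna_track()] or `NULL`
#' @param protein_track a [protein_track()] or `NULL`
#' @return one-row data frame with columns `f14`, `f5`, `f18`, `f15` (plus
#'   one column per registered extra feature); uncomputable features are
#'   `NA` and named in the `flags` attribute
#' @export
extract_features <- function(indel, transcripts, dna_track = NULL,
                             protein_track = NULL) {
  if (nrow(indel) != 1) stop("extract_features expects a single indel")
  if (!is_frameshifting(indel))
    stop(sprintf("indel %s is not frameshifting (net length %d); out of scope",
                 indel$id, indel$net_length))
  f5 <- max_relative_location(indel, transcripts)
  if (is.na(f5))
    stop(sprintf("indel %s has no coding overlap with any transcript", indel$id))
  f14 <- frac_conserved_dna_affected(indel, transcripts, dna_track)
  f18 <- max_frac_conserved_aa_lost(indel, transcripts, protein_track)
  f15 <- min_dist_exon_boundary(indel, transcripts)
  fv <- data.frame(f14 = as.numeric(f14), f5 = as.numeric(f5),
                   f18 = as.numeric(f18), f15 = as.numeric(f15))
  flags <- character()
  for (nm in c("f14", "f5", "f18", "f15")) {
    fl <- attr(get(nm), "flag")
    if (!is.null(fl)) flags[nm] <- fl
  }
  tracks <- list(dna = dna_track, protein = protein_track)
  for (nm in registered_features())
    fv[[nm]] <- as.numeric(get(nm, envir = .feature_registry)(indel, transcripts, tracks))
  attr(fv, "flags") <- flags
  fv
}

# canonical long column names for feature tables
feature_long_names <- c(
  f14 = "f14_frac_cons_dna", f5 = "f5_max_rel_loc",
  f18 = "f18_max_frac_cons_aa_lost", f15 = "f15_min_dist_exon")

#' Write a feature table as TSV
#'
#' @param tab data frame with `indel_id`, `gene_id`, the four features
#'   (short names `f14`, `f5`, `f18`, `f15`) and any extra feature columns
#' @param path output file
#' @return `path`, invisibly
#' @export
write_feature_table <- function(tab, path) {
  out <- tab
  for (nm in names(feature_long_names))
    names(out)[names(out) == nm] <- feature_long_names[[nm]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path input file
#' @return data frame with short feature names
#' @export
read_feature_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (nm in names(feature_long_names))
    names(d)[names(d) == feature_long_names[[nm]]] <- nm
  d
}
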