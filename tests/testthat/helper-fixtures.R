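# Fixture builders and independent brute-force oracles.
# Oracles deliberately use plain loops / enumeration, never the package's
# arithmetic code paths.

quiet_fixtures <- function() Sys.setenv(FSINDEL_QUIET = "1")
quiet_fixtures()

# one-row indel helper (net != 0); anchor pos is 0-based
toy_indel <- function(chrom, pos, net, id = "i1") {
  if (net > 0) indel_set(chrom, pos, "A", paste(rep("A", net + 1), collapse = ""), id = id)
  else indel_set(chrom, pos, paste(rep("A", -net + 1), collapse = ""), "A", id = id)
}

# enumeration oracle: genomic positions of coding bases in 5'->3' order
oracle_coding_positions <- function(exons, cds_start, cds_end, strand) {
  pos <- integer()
  for (i in seq_len(nrow(exons)))
    for (p in seq.int(exons[i, 1], exons[i, 2] - 1L))
      if (p >= cds_start && p < cds_end) pos <- c(pos, p)
  if (strand == "-") rev(pos) else pos
}

# random toy transcript on a fresh chromosome; cds covers all exons
random_transcript <- function(seed, chrom = "chrR") {
  withr::with_seed(seed, {
    n_exons <- sample(1:4, 1)
    lens <- sample(3:40, n_exons, replace = TRUE)
    total <- sum(lens)
    total <- total - (total %% 3L)  # trim to multiple of 3
    lens[n_exons] <- lens[n_exons] - (sum(lens) - total)
    if (lens[n_exons] < 1) { lens <- lens[-n_exons]; n_exons <- n_exons - 1L }
    strand <- sample(c("+", "-"), 1)
    cur <- sample(10:60, 1)
    exons <- matrix(0L, length(lens), 2)
    for (i in seq_along(lens)) {
      exons[i, ] <- c(cur, cur + lens[i])
      cur <- cur + lens[i] + sample(5:30, 1)
    }
    transcript_model(paste0("TX", seed), paste0("G", seed), chrom, strand,
                     exons, cds_start = exons[1, 1],
                     cds_end = exons[nrow(exons), 2])
  })
}

# brute-force recount oracle for the four features on a single transcript
# gene with explicit conserved genomic positions / conserved residue flags
oracle_features <- function(indel, t, conserved_genomic, conserved_res) {
  cpos <- oracle_coding_positions(t$exons, t$cds_start, t$cds_end, t$strand)
  a <- indel$pos + 1L                      # leftmost affected genomic base
  iv_end <- a + max(0L, -indel$net_length) # half-open end of deleted bases
  affected <- logical(length(cpos))
  for (k in seq_along(cpos)) {
    g <- cpos[k]
    affected[k] <- if (t$strand == "+") g >= a else g <= iv_end - 1L
  }
  if (!any(affected)) return(NULL)
  first <- which(affected)[1] - 1L         # 0-based CDS offset
  aff_genomic <- cpos[(first + 1):length(cpos)]
  den <- sum(cpos %in% conserved_genomic)
  f14 <- if (den == 0) 0 else 100 * sum(aff_genomic %in% conserved_genomic) / den
  f5 <- 100 * first / length(cpos)
  k0 <- first %/% 3L
  tot_res <- sum(conserved_res)
  f18 <- if (tot_res == 0) 0 else
    100 * sum(conserved_res[seq_along(conserved_res) - 1L >= k0]) / tot_res
  f15 <- NA_real_
  for (i in seq_len(nrow(t$exons)))
    if (a >= t$exons[i, 1] && a < t$exons[i, 2])
      f15 <- min(a - t$exons[i, 1], t$exons[i, 2] - 1L - a)
  list(f14 = f14, f5 = f5, f18 = f18, f15 = f15)
}

# all-pairs single-linkage chaining oracle for clustering
oracle_clusters <- function(pos, window) {
  n <- length(pos)
  if (n == 0) return(list())
  # adjacency by distance, transitive closure by repeated merging
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= window && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- list()
  for (c in unique(comp)) {
    members <- which(comp == c)
    if (length(members) >= 2) out[[length(out) + 1L]] <- sort(members)
  }
  out
}

# make a 2-member cluster object with a given restored status (for
# enrichment arithmetic tests)
stub_pair <- function(restored) {
  net <- if (restored) -3L else -2L
  structure(list(region_id = "r", members = 1:2, net_size = net,
                 frame_restored = restored, max_pairwise_gap = 10),
            class = "indel_cluster")
}
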