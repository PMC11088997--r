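# shared fixture builders; everything is generated in code, no data files

unif_law <- function(sizes) setNames(rep(1 / length(sizes), length(sizes)),
                                     sizes)

# clone table straight from vectors (one row per cell)
make_clone_table <- function(clone, class, arm = "gLacZ", batch = "b1") {
  n <- length(clone)
  data.frame(cell_id = sprintf("c%03d", seq_len(n)),
             clone_id = clone, class = class,
             arm = rep_len(arm, n), batch = rep_len(batch, n),
             stringsAsFactors = FALSE)
}

random_seqs <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# brute-force Hamming distance via character comparison (independent of the
# package's one-hot implementation)
hamming_slow <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force single-linkage components at Hamming <= d via igraph over the
# explicit all-pairs graph
cluster_oracle <- function(bc, d) {
  bc <- sort(unique(bc))
  n <- length(bc)
  edges <- c()
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (hamming_slow(bc[i], bc[j]) <= d) edges <- c(edges, i, j)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  setNames(vapply(split(bc, comp), min, character(1))[as.character(comp)], bc)
}

# a read record wrapping a barcode with anchors and uniform quality
make_read <- function(barcode, anchor5 = "TCGATCCGGA", anchor3 = "AGCTTGGCGT",
                      q = 40, cell = "cellA", umi = "ACGTACGTAC",
                      id = "r1", prefix = "", suffix = "") {
  seqs <- paste0(prefix, anchor5, barcode, anchor3, suffix)
  data.frame(read_id = id, sequence = seqs,
             quality = strrep(intToUtf8(q + 33L), nchar(seqs)),
             cell_id = cell, umi = umi, stringsAsFactors = FALSE)
}

# interval frame helpers for the regulatory tests
iv <- function(chrom, start, end, strand = ".", name = NULL, summit = NULL) {
  genomic_intervals(chrom, start, end,
                    strand = rep_len(strand, length(start)),
                    name = name, summit = summit)
}

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             span = 10000, width_max = 200, prefix = "iv") {
  set.seed(seed)
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(width_max, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + width,
                    name = sprintf("%s_%03d", prefix, seq_len(n)))
}

# brute-force oracles over explicit loops, independent of the IRanges path
overlap_oracle <- function(a, b) {
  hits <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
        b$start[j] < a$end[i])
      hits <- rbind(hits, c(i, j))
  hits
}

nearest_oracle <- function(peaks, tss) {
  pp <- if (!is.null(peaks$summit)) peaks$start + peaks$summit else
    (peaks$start + peaks$end) %/% 2L
  tp <- ifelse(tss$strand == "-", tss$end - 1L, tss$start)
  out <- data.frame(tss_id = rep(NA_character_, nrow(peaks)),
                    distance = rep(NA_real_, nrow(peaks)))
  for (i in seq_len(nrow(peaks))) {
    cand <- which(tss$chrom == peaks$chrom[i])
    if (!length(cand)) next
    d <- abs(pp[i] - tp[cand])
    best <- cand[d == min(d)]
    best <- best[order(tss$name[best])][1]
    signed <- pp[i] - tp[best]
    if (tss$strand[best] == "-") signed <- -signed
    out[i, ] <- list(tss$name[best], signed)
  }
  out
}
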