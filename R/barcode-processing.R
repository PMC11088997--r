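#' Read layout for anchored barcode extraction
#'
#' Describes where the fixed-length lineage barcode sits in a read: a 5'
#' anchor sequence, the barcode span, and a 3' anchor sequence.
#'
#' @param anchor5,anchor3 literal anchor sequences.
#' @param barcode_length barcode length in bases (default 37).
#' @return an object of class \code{read_layout}.
#' @export
read_layout <- function(anchor5 = "TCGATCCGGA", anchor3 = "AGCTTGGCGT",
                        barcode_length = 37) {
  if (!grepl("^[ACGT]+$", anchor5) || !grepl("^[ACGT]+$", anchor3))
    stop("anchors must be A/C/G/T")
  structure(list(anchor5 = anchor5, anchor3 = anchor3,
                 barcode_length = as.integer(barcode_length)),
            class = "read_layout")
}

#' Write and read barcode FASTQ files
#'
#' Reads are written Phred+33 with the cell barcode and UMI encoded in the
#' header comment as \code{cell=<cell_id>;umi=<umi>}; \code{read_barcode_fastq}
#' parses them back (or takes them from a separate read-to-cell table).
#'
#' @param reads data.frame with read_id, sequence, quality, cell_id, umi.
#' @param path FASTQ file path.
#' @return \code{read_barcode_fastq} returns a data.frame with columns
#'   read_id, sequence, quality, cell_id, umi.
#' @export
write_barcode_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  header <- reads$read_id
  if (all(c("cell_id", "umi") %in% names(reads)))
    header <- sprintf("%s cell=%s;umi=%s", reads$read_id, reads$cell_id,
                      reads$umi)
  out <- rbind(paste0("@", header), reads$sequence, "+", reads$quality)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' @rdname write_barcode_fastq
#' @param read_meta optional data.frame (read_id, cell_id, umi) used when the
#'   headers do not carry \code{cell=...;umi=...} comments.
#' @export
read_barcode_fastq <- function(path, read_meta = NULL) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  header <- names(x)
  read_id <- sub("[ \t].*$", "", header)
  comment <- sub("^[^ \t]+[ \t]*", "", header)
  df <- data.frame(read_id = read_id,
                   sequence = as.character(x),
                   quality = as.character(Biostrings::quality(x)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(read_meta)) {
    m <- match(df$read_id, read_meta$read_id)
    if (anyNA(m)) stop("read ids missing from read_meta")
    df$cell_id <- read_meta$cell_id[m]
    df$umi <- read_meta$umi[m]
  } else if (all(grepl("cell=.*;umi=", comment))) {
    df$cell_id <- sub("^cell=([^;]+);umi=.*$", "\\1", comment)
    df$umi <- sub("^.*;umi=([ACGTN]+).*$", "\\1", comment)
  }
  df
}

#' Extract anchored lineage barcodes from reads
#'
#' Scans each read for the 5' anchor / barcode / 3' anchor arrangement:
#' both anchors must match at the same offset within
#' \code{anchor_mismatch_tol} mismatches; the scan slides over offsets
#' \code{0..max_shift} and takes the smallest matching offset. Reads shorter
#' than the layout, or with no matching offset, are rejected with a reason
#' code in the attached report.
#'
#' @param reads data.frame from \code{\link{read_barcode_fastq}} (read_id,
#'   sequence, quality, cell_id, umi).
#' @param layout a \code{\link{read_layout}}.
#' @param anchor_mismatch_tol allowed mismatches per anchor.
#' @param max_shift largest allowed 5'-anchor offset (default: scan the whole
#'   read).
#' @return data.frame (read_id, cell_id, umi, barcode, barcode_quality) of
#'   extracted records, in input order, with attribute \code{report}: counts
#'   of reads in, extracted, too short, and anchor-failed.
#' @export
extract_lineage_barcodes <- function(reads, layout = read_layout(),
                                     anchor_mismatch_tol = 0,
                                     max_shift = NULL) {
  la5 <- nchar(layout$anchor5)
  la3 <- nchar(layout$anchor3)
  bl <- layout$barcode_length
  need <- la5 + bl + la3
  n <- nrow(reads)
  len <- nchar(reads$sequence)
  too_short <- len < need
  offset <- rep(NA_integer_, n)
  a5int <- utf8ToInt(layout$anchor5)
  a3int <- utf8ToInt(layout$anchor3)
  idx <- which(!too_short)
  if (length(idx)) {
    if (is.null(max_shift)) max_shift <- max(len[idx]) - need
    for (sh in 0:max_shift) {
      open <- idx[is.na(offset[idx]) & len[idx] >= need + sh]
      if (!length(open)) next
      s5 <- substr(reads$sequence[open], sh + 1L, sh + la5)
      m5 <- colSums(matrix(utf8ToInt(paste(s5, collapse = "")),
                           nrow = la5) != a5int)
      s3 <- substr(reads$sequence[open], sh + la5 + bl + 1L,
                   sh + la5 + bl + la3)
      m3 <- colSums(matrix(utf8ToInt(paste(s3, collapse = "")),
                           nrow = la3) != a3int)
      hit <- m5 <= anchor_mismatch_tol & m3 <= anchor_mismatch_tol
      offset[open[hit]] <- sh
    }
  }
  keep <- which(!is.na(offset))
  out <- data.frame(
    read_id = reads$read_id[keep],
    cell_id = if ("cell_id" %in% names(reads)) reads$cell_id[keep] else NA,
    umi = if ("umi" %in% names(reads)) reads$umi[keep] else NA,
    barcode = substr(reads$sequence[keep], offset[keep] + la5 + 1L,
                     offset[keep] + la5 + bl),
    barcode_quality = substr(reads$quality[keep], offset[keep] + la5 + 1L,
                             offset[keep] + la5 + bl),
    stringsAsFactors = FALSE)
  attr(out, "report") <- list(
    n_reads = n,
    n_extracted = length(keep),
    n_too_short = sum(too_short),
    n_anchor_failed = n - length(keep) - sum(too_short))
  out
}

#' @rdname extract_lineage_barcodes
#' @param read a single-row read record (list or one-row data.frame).
#' @return \code{extract_lineage_barcode} returns a one-row data.frame, or
#'   \code{NULL} when the read is rejected.
#' @export
extract_lineage_barcode <- function(read, layout = read_layout(),
                                    anchor_mismatch_tol = 0,
                                    max_shift = NULL) {
  df <- as.data.frame(read, stringsAsFactors = FALSE)
  out <- extract_lineage_barcodes(df, layout, anchor_mismatch_tol, max_shift)
  if (nrow(out) == 0L) NULL else out
}

#' Quality-filter extracted barcodes
#'
#' Keeps records whose barcode quality statistic is at least \code{min_q}.
#' The statistic is the mean Phred over the barcode bases by default;
#' \code{mode = "min"} requires every base to pass. The conventional
#' threshold for this protocol is 30.
#'
#' @param records data.frame from \code{\link{extract_lineage_barcodes}}.
#' @param min_q minimum quality (default 30).
#' @param mode "mean" or "min".
#' @return the kept rows, input order preserved.
#' @export
filter_by_quality <- function(records, min_q = 30, mode = c("mean", "min")) {
  mode <- match.arg(mode)
  stopifnot(min_q >= 0)
  if (nrow(records) == 0L) return(records)
  qs <- vapply(records$barcode_quality, function(q) {
    v <- phred_to_int(q)
    if (mode == "mean") mean(v) else min(v)
  }, numeric(1), USE.NAMES = FALSE)
  records[qs >= min_q, , drop = FALSE]
}

#' Collapse reads to UMI counts per cell and barcode
#'
#' Duplicate (cell, UMI, barcode) reads — PCR jackpotting — collapse to one
#' molecule; the result counts distinct UMIs per (cell, barcode).
#'
#' @param records quality-filtered data.frame with cell_id, umi, barcode.
#' @return data.frame (cell_id, barcode, umi_count), sorted by cell then
#'   barcode.
#' @export
collapse_umis <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(cell_id = character(0), barcode = character(0),
                      umi_count = integer(0)))
  u <- unique(records[, c("cell_id", "umi", "barcode")])
  agg <- aggregate(list(umi_count = u$umi),
                   by = list(cell_id = u$cell_id, barcode = u$barcode),
                   FUN = length)
  agg <- agg[order(agg$cell_id, agg$barcode), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Cluster barcodes by Hamming distance
#'
#' Single-linkage clusters: connected components of the graph joining every
#' pair of barcodes at Hamming distance at most \code{d} (default 3, the
#' conventional cluster distance for this protocol). The cluster id is the lexicographically
#' smallest member barcode, so the mapping is deterministic and invariant
#' to input order.
#'
#' @param barcodes character vector of equal-length barcodes.
#' @param d maximum within-edge Hamming distance (default 3).
#' @return named character vector mapping each input barcode to its cluster
#'   id (one entry per distinct barcode).
#' @export
cluster_barcodes <- function(barcodes, d = 3) {
  stopifnot(d >= 0)
  bc <- sort(unique(barcodes))
  if (!length(bc)) return(setNames(character(0), character(0)))
  if (length(unique(nchar(bc))) != 1L)
    stop("barcodes must all have the same length")
  D <- hamming_distance_matrix(bc)
  e <- which(D <= d & upper.tri(D), arr.ind = TRUE)
  comp <- connected_components(length(bc), e[, 1L], e[, 2L])
  # component label -> lexicographically smallest member (bc is sorted, so
  # the root index is already the smallest member)
  setNames(bc[comp], bc)
}

#' Build a clone table from barcode clusters and cell metadata
#'
#' UMI counts are summed per (cell, barcode cluster); pairs below
#' \code{min_umi} are dropped. Within each batch, cells are grouped into
#' clones as connected components of the bipartite cell-to-cluster graph:
#' cells sharing any cluster belong to one clone, and a cell carrying
#' several barcodes merges its clusters. Identical barcodes in different
#' batches are distinct clones (collision guard). Cells whose barcodes are
#' all filtered away are excluded and counted in the attached report.
#'
#' @param cell_barcode_counts data.frame (cell_id, barcode, umi_count) from
#'   \code{\link{collapse_umis}}.
#' @param clusters named mapping barcode -> cluster id from
#'   \code{\link{cluster_barcodes}}.
#' @param cell_metadata data.frame with cell_id, class (or annotation), arm,
#'   batch for every cell in the counts.
#' @param min_umi minimum UMI support per (cell, cluster) pair (default 1).
#' @return clone table data.frame (cell_id, clone_id, class, arm, batch)
#'   with attribute \code{report} (cells in/assigned/dropped).
#' @export
build_clone_table <- function(cell_barcode_counts, clusters, cell_metadata,
                              min_umi = 1) {
  counts <- cell_barcode_counts
  missing_cells <- setdiff(counts$cell_id, cell_metadata$cell_id)
  if (length(missing_cells))
    stop("cells present in counts but missing from metadata: ",
         paste(head(missing_cells, 10), collapse = ", "))
  cl <- clusters[counts$barcode]
  if (anyNA(cl)) stop("counts contain barcodes absent from the cluster map")
  agg <- aggregate(list(umi_count = counts$umi_count),
                   by = list(cell_id = counts$cell_id, cluster = unname(cl)),
                   FUN = sum)
  cells_in <- sort(unique(counts$cell_id))
  agg <- agg[agg$umi_count >= min_umi, , drop = FALSE]

  meta_idx <- match(agg$cell_id, cell_metadata$cell_id)
  agg$batch <- cell_metadata$batch[meta_idx]

  out <- vector("list", 0L)
  for (b in sort(unique(agg$batch))) {
    sub <- agg[agg$batch == b, , drop = FALSE]
    cells <- sort(unique(sub$cell_id))
    clus <- sort(unique(sub$cluster))
    nn <- length(cells) + length(clus)
    from <- match(sub$cell_id, cells)
    to <- length(cells) + match(sub$cluster, clus)
    comp <- connected_components(nn, from, to)
    # clone id: batch-scoped, named after the smallest cluster barcode in
    # the component (deterministic, order-invariant)
    comp_cluster <- comp[(length(cells) + 1L):nn]
    smallest <- vapply(split(clus, comp_cluster), min, character(1))
    cell_comp <- as.character(comp[seq_along(cells)])
    out[[length(out) + 1L]] <- data.frame(
      cell_id = cells,
      clone_id = paste0(b, ":", smallest[cell_comp]),
      batch = b, stringsAsFactors = FALSE)
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = character(0), clone_id = character(0),
               batch = character(0), stringsAsFactors = FALSE)
  m <- match(tab$cell_id, cell_metadata$cell_id)
  class_col <- if ("class" %in% names(cell_metadata)) "class" else "annotation"
  tab$class <- cell_metadata[[class_col]][m]
  tab$arm <- cell_metadata$arm[m]
  tab$batch <- cell_metadata$batch[m]
  tab <- tab[order(tab$cell_id), c("cell_id", "clone_id", "class", "arm",
                                   "batch")]
  rownames(tab) <- NULL
  dropped <- setdiff(cells_in, tab$cell_id)
  attr(tab, "report") <- list(n_cells_in = length(cells_in),
                              n_cells_assigned = nrow(tab),
                              cells_dropped = dropped)
  tab
}

#' Run the full barcode-to-clone pipeline
#'
#' Convenience wrapper: extraction, quality filtering, UMI collapsing,
#' Hamming clustering and clone-table construction with the conventional
#' defaults (mean Phred >= 30, cluster distance 3).
#'
#' @inheritParams extract_lineage_barcodes
#' @inheritParams filter_by_quality
#' @inheritParams cluster_barcodes
#' @inheritParams build_clone_table
#' @return clone table as from \code{\link{build_clone_table}}.
#' @export
call_clones <- function(reads, cell_metadata, layout = read_layout(),
                        anchor_mismatch_tol = 0, min_q = 30,
                        mode = c("mean", "min"), d = 3, min_umi = 1) {
  mode <- match.arg(mode)
  ext <- extract_lineage_barcodes(reads, layout, anchor_mismatch_tol)
  ext <- filter_by_quality(ext, min_q, mode)
  counts <- collapse_umis(ext)
  clusters <- cluster_barcodes(counts$barcode, d)
  build_clone_table(counts, clusters, cell_metadata, min_umi)
}
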