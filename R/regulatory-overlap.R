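#' Genomic intervals in BED coordinates
#'
#' Validates a set of intervals in 0-based half-open (BED) coordinates with
#' optional strand, name and summit offset. All interval operations in the
#' package use this convention throughout.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, \code{start < end}.
#' @param strand "+", "-" or "." (default ".").
#' @param name interval names (default \code{iv_<i>}).
#' @param summit optional summit offsets relative to \code{start} (as in
#'   narrowPeak column 10); must lie in \code{[0, end - start)}.
#' @return data.frame (chrom, start, end, strand, name[, summit]).
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, name = NULL,
                              summit = NULL) {
  n <- length(chrom)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  if (is.null(strand)) strand <- rep(".", n)
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be '+', '-' or '.'")
  if (is.null(name)) name <- sprintf("iv_%d", seq_len(n))
  if (anyDuplicated(name)) stop("interval names must be unique")
  out <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                    name = name, stringsAsFactors = FALSE)
  if (!is.null(summit)) {
    summit <- as.integer(summit)
    bad <- !is.na(summit) & (summit < 0 | summit >= end - start)
    if (any(bad)) stop("summit offsets must lie inside the interval")
    out$summit <- summit
  }
  out
}

#' Read BED / narrowPeak intervals
#'
#' Thin wrapper over \code{rtracklayer::import} converting back to the
#' package's 0-based half-open data.frame; narrowPeak files keep the summit
#' offset (column 10).
#'
#' @param path BED3/BED6 or narrowPeak file.
#' @param format "bed" or "narrowPeak" (default: by file extension).
#' @return data.frame as from \code{\link{genomic_intervals}}.
#' @export
read_bed <- function(path, format = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_bed requires the rtracklayer package")
  if (is.null(format))
    format <- if (grepl("narrowPeak$", path)) "narrowPeak" else "bed"
  gr <- rtracklayer::import(path, format = format)
  nm <- if (!is.null(gr$name) && !anyDuplicated(gr$name) &&
            !any(is.na(gr$name))) gr$name else
    sprintf("iv_%d", seq_along(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                    strand = st, name = nm,
                    summit = if (!is.null(gr$peak)) gr$peak)
}

# GRanges view of a 0-based half-open interval frame
as_granges0 <- function(iv) {
  st <- iv$strand
  st[st == "."] <- "*"
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(iv$start + 1L, iv$end),
                         strand = st)
}

# Reference point of a peak: summit when present, else interval midpoint.
peak_point <- function(peaks) {
  if (!is.null(peaks$summit) && !all(is.na(peaks$summit)))
    ifelse(is.na(peaks$summit),
           (peaks$start + peaks$end) %/% 2L,
           peaks$start + peaks$summit)
  else (peaks$start + peaks$end) %/% 2L
}

# Position of a TSS: start for + / unstranded, end - 1 for - strand.
tss_point <- function(tss) {
  ifelse(tss$strand == "-", tss$end - 1L, tss$start)
}

#' Nearest TSS per peak
#'
#' Distance from each peak's reference point (summit when present, else
#' midpoint) to the nearest TSS. The sign respects the TSS strand: positive
#' downstream of the TSS, negative upstream. Ties go to the smaller
#' absolute distance, then to the lexicographically smallest TSS id. Peaks
#' on a chromosome with no TSS get an \code{NA} distance and a flag.
#'
#' @param peaks,tss interval data.frames (\code{\link{genomic_intervals}});
#'   TSS intervals are typically 1 bp wide with a strand.
#' @return data.frame (peak, tss_id, distance, flag).
#' @export
nearest_tss <- function(peaks, tss) {
  if (nrow(peaks) == 0L || nrow(tss) == 0L)
    stop("peaks and tss must both be nonempty")
  pp <- peak_point(peaks)
  tp <- tss_point(tss)
  out <- data.frame(peak = peaks$name, tss_id = NA_character_,
                    distance = NA_real_, flag = "no_tss_on_chrom",
                    stringsAsFactors = FALSE)
  for (ch in unique(peaks$chrom)) {
    ti <- which(tss$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(ti)) next
    ord <- ti[order(tp[ti], tss$name[ti])]
    pos <- tp[ord]
    # smallest id at each distinct position (for deterministic ties)
    first <- !duplicated(pos)
    upos <- pos[first]
    uid <- vapply(split(tss$name[ord], match(pos, upos)), min, character(1))
    ustrand <- tss$strand[ord][first]
    for (k in pi) {
      p <- pp[k]
      j <- findInterval(p, upos)
      cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(upos)))
      dmin <- min(abs(p - upos[cand]))
      hit <- cand[abs(p - upos[cand]) == dmin]
      pick <- hit[order(uid[hit])][1]
      signed <- p - upos[pick]
      if (ustrand[pick] == "-") signed <- -signed
      out$tss_id[k] <- uid[pick]
      out$distance[k] <- signed
      out$flag[k] <- ""
    }
  }
  out
}

#' Promoter assignment of peaks
#'
#' A peak is assigned to every gene whose promoter window — the 0-based
#' half-open region \code{[TSS - half_width, TSS + half_width)} — it
#' overlaps by at least one base (interval overlap, not summit-only). The
#' default half-width of 5,000 bp encodes peaks lying within 5 kb of a TSS.
#'
#' @inheritParams nearest_tss
#' @param half_width promoter half-width in bp (default 5000).
#' @return data.frame (peak, gene), one row per assignment.
#' @export
promoter_assignment <- function(peaks, tss, half_width = 5000) {
  stopifnot(half_width > 0)
  tp <- tss_point(tss)
  win <- data.frame(chrom = tss$chrom, start = tp - half_width,
                    end = tp + half_width, strand = ".", name = tss$name,
                    stringsAsFactors = FALSE)
  hits <- overlap_pairs(peaks, win)
  data.frame(peak = peaks$name[hits$a], gene = win$name[hits$b],
             stringsAsFactors = FALSE)
}

# Any-overlap pairs between two 0-based half-open interval frames.
# Windows may have negative starts; coordinates are shifted to keep IRanges
# happy, which leaves overlap relations unchanged.
overlap_pairs <- function(a, b) {
  shift <- min(0L, a$start, b$start)
  ga <- IRanges::IRanges(a$start - shift + 1L, a$end - shift)
  gb <- IRanges::IRanges(b$start - shift + 1L, b$end - shift)
  hits <- IRanges::findOverlaps(ga, gb)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  same <- a$chrom[i] == b$chrom[j]
  data.frame(a = i[same], b = j[same])
}

#' Shared vs exclusive binding sites of two factors
#'
#' Labels each site of set A as shared when it overlaps (>= 1 bp) any site
#' of set B, and conversely; a shared pair is counted once per A site, so
#' the shared count is A-site-centric and fractions like "695 of 3,780" are
#' well defined under one-to-many overlaps.
#'
#' @param sites_a,sites_b interval data.frames.
#' @return list with \code{a} and \code{b} (the inputs plus a
#'   \code{shared} logical) and \code{counts} (shared, a_exclusive,
#'   b_exclusive).
#' @export
classify_overlap <- function(sites_a, sites_b) {
  ha <- rep(FALSE, nrow(sites_a))
  hb <- rep(FALSE, nrow(sites_b))
  if (nrow(sites_a) && nrow(sites_b)) {
    hits <- overlap_pairs(sites_a, sites_b)
    ha[unique(hits$a)] <- TRUE
    hb[unique(hits$b)] <- TRUE
  }
  sites_a$shared <- ha
  sites_b$shared <- hb
  list(a = sites_a, b = sites_b,
       counts = c(shared = sum(ha), a_exclusive = sum(!ha),
                  b_exclusive = sum(!hb)))
}

#' Enhancer enrichment across site classes
#'
#' Pearson's Chi-squared test (no continuity correction) on the 3 x 2 table
#' of site class (shared / A-exclusive / B-exclusive) versus
#' enhancer-overlap status; 2 degrees of freedom.
#'
#' @param class_counts 3 x 2 matrix of nonnegative counts (rows: shared,
#'   a_exclusive, b_exclusive; columns: enhancer yes/no).
#' @return list (statistic, dof, p).
#' @export
enhancer_enrichment <- function(class_counts) {
  m <- as.matrix(class_counts)
  if (!all(dim(m) == c(3L, 2L))) stop("class_counts must be 3 x 2")
  if (any(m < 0)) stop("counts must be nonnegative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("row and column totals must be positive")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop("zero expected cell; merge categories before testing")
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value)
}

#' Target genes of peaks via promoters and enhancers
#'
#' A peak's target-gene set is the union of the genes whose promoter window
#' it overlaps and the genes linked to any enhancer it overlaps; the global
#' target list is the deduplicated, sorted union over all peaks.
#'
#' @inheritParams promoter_assignment
#' @param enhancer_links data.frame (chrom, start, end, gene), one row per
#'   enhancer-gene link (0-based half-open).
#' @return list with \code{per_peak} (peak, gene, route in
#'   promoter/enhancer/both) and \code{targets} (sorted unique gene ids).
#' @export
assign_target_genes <- function(peaks, tss, half_width = 5000,
                                enhancer_links = NULL) {
  prom <- promoter_assignment(peaks, tss, half_width)
  prom$route <- "promoter"
  enh <- data.frame(peak = character(0), gene = character(0),
                    route = character(0), stringsAsFactors = FALSE)
  if (!is.null(enhancer_links) && nrow(enhancer_links)) {
    stopifnot(all(c("chrom", "start", "end", "gene") %in%
                    names(enhancer_links)))
    hits <- overlap_pairs(peaks, enhancer_links)
    if (nrow(hits))
      enh <- unique(data.frame(peak = peaks$name[hits$a],
                               gene = enhancer_links$gene[hits$b],
                               route = "enhancer", stringsAsFactors = FALSE))
  }
  both <- merge(prom[, c("peak", "gene")], enh[, c("peak", "gene")])
  per_peak <- unique(rbind(prom, enh)[, c("peak", "gene", "route")])
  if (nrow(both)) {
    key <- paste(per_peak$peak, per_peak$gene)
    bkey <- paste(both$peak, both$gene)
    per_peak <- per_peak[!duplicated(key), , drop = FALSE]
    per_peak$route[key[!duplicated(key)] %in% bkey] <- "both"
  }
  per_peak <- per_peak[order(per_peak$peak, per_peak$gene), , drop = FALSE]
  rownames(per_peak) <- NULL
  list(per_peak = per_peak, targets = sort(unique(per_peak$gene)))
}
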