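int_to_phred_test <- function(q) intToUtf8(q + 33L)

# independent sliding-window matcher used as the extraction oracle
extract_oracle <- function(seq, anchor5, anchor3, bl, tol) {
  la5 <- nchar(anchor5); la3 <- nchar(anchor3)
  for (sh in 0:(nchar(seq) - la5 - bl - la3)) {
    m5 <- hamming_slow(substr(seq, sh + 1, sh + la5), anchor5)
    m3 <- hamming_slow(substr(seq, sh + la5 + bl + 1, sh + la5 + bl + la3),
                       anchor3)
    if (m5 <= tol && m3 <= tol)
      return(substr(seq, sh + la5 + 1, sh + la5 + bl))
  }
  NULL
}

test_that("anchored extraction recovers exact and tolerated templates", {
  bc <- random_seqs(1, 37, 1)
  r <- make_read(bc)
  out <- extract_lineage_barcode(r)
  expect_identical(out$barcode, bc)
  expect_identical(nchar(out$barcode_quality), 37L)

  # read without the 5' anchor is rejected
  r2 <- r
  r2$sequence <- paste0(strrep("T", 10), bc, "AGCTTGGCGT")
  expect_null(extract_lineage_barcode(r2))

  # reads shorter than the layout are rejected with a reason count
  r3 <- make_read(substr(bc, 1, 10))
  r3$sequence <- substr(r3$sequence, 1, 30)
  r3$quality <- substr(r3$quality, 1, 30)
  ext <- extract_lineage_barcodes(r3)
  expect_equal(nrow(ext), 0)
  expect_equal(attr(ext, "report")$n_too_short, 1)

  # one anchor mismatch: rejected at tol 0, accepted at tol 1
  mut <- r
  substr(mut$sequence, 1, 1) <- "A"  # anchor starts with T
  expect_null(extract_lineage_barcode(mut, anchor_mismatch_tol = 0))
  expect_identical(extract_lineage_barcode(mut, anchor_mismatch_tol = 1)$barcode,
                   bc)
})

test_that("extraction agrees with a brute-force sliding-window matcher", {
  set.seed(21)
  layout <- read_layout()
  for (i in 1:40) {
    bc <- random_seqs(1, 37, 100 + i)
    prefix <- paste(sample(c("A", "C", "G", "T"), sample(0:6, 1),
                           replace = TRUE), collapse = "")
    r <- make_read(bc, prefix = prefix, suffix = "AC")
    # sprinkle up to 2 mutations anywhere
    s <- strsplit(r$sequence, "")[[1]]
    nmut <- sample(0:2, 1)
    pos <- sample(length(s), nmut)
    s[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    r$sequence <- paste(s, collapse = "")
    for (tol in 0:1) {
      got <- extract_lineage_barcode(r, layout, anchor_mismatch_tol = tol)
      want <- extract_oracle(r$sequence, layout$anchor5, layout$anchor3,
                             37, tol)
      if (is.null(want)) expect_null(got) else
        expect_identical(got$barcode, want)
    }
  }
})

test_that("quality filtering applies mean and min statistics", {
  recs <- data.frame(
    read_id = c("a", "b", "c"),
    cell_id = "x", umi = "ACGTACGTAC",
    barcode = strrep("A", 4),
    barcode_quality = c(int_to_phred_test(c(40, 40, 40, 40)),
                        int_to_phred_test(c(30, 30, 29, 29)),  # mean 29.5
                        int_to_phred_test(c(40, 40, 40, 29))), # mean 37.25
    stringsAsFactors = FALSE)
  expect_identical(filter_by_quality(recs, 30, "mean")$read_id, c("a", "c"))
  expect_identical(filter_by_quality(recs, 30, "min")$read_id, "a")
  expect_identical(filter_by_quality(recs, 0)$read_id, recs$read_id)
})

test_that("UMI collapsing counts distinct molecules per cell and barcode", {
  jack <- data.frame(cell_id = "c1", umi = "AAAA", barcode = "ACGT",
                     stringsAsFactors = FALSE)[rep(1, 5), ]
  expect_equal(collapse_umis(jack)$umi_count, 1)

  two <- data.frame(cell_id = "c1", umi = c("AAAA", "CCCC"), barcode = "ACGT",
                    stringsAsFactors = FALSE)
  expect_equal(collapse_umis(two)$umi_count, 2)

  mixed <- data.frame(
    cell_id = c("c1", "c1", "c1", "c2", "c2", "c1"),
    umi = c("AAAA", "AAAA", "CCCC", "AAAA", "GGGG", "AAAA"),
    barcode = c("ACGT", "ACGT", "ACGT", "TTTT", "TTTT", "GGGG"),
    stringsAsFactors = FALSE)
  got <- collapse_umis(mixed)
  # oracle: enumerate distinct (cell, umi, barcode) triples by hand
  want <- aggregate(umi ~ cell_id + barcode,
                    unique(mixed[, c("cell_id", "umi", "barcode")]), length)
  want <- want[order(want$cell_id, want$barcode), ]
  expect_equal(got$umi_count,
               want$umi[match(paste(got$cell_id, got$barcode),
                              paste(want$cell_id, want$barcode))])
})

test_that("Hamming clustering matches single-linkage semantics", {
  base <- random_seqs(1, 37, 31)
  mutate_at <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- vapply(v[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                     character(1))
    paste(v, collapse = "")
  }
  # identical barcodes: one cluster
  expect_equal(length(unique(cluster_barcodes(c(base, base), 3))), 1)
  # distance 4 at d = 3: two clusters
  far <- mutate_at(base, 1:4)
  expect_equal(length(unique(cluster_barcodes(c(base, far), 3))), 2)
  # chain b1-b2 (2), b2-b3 (2), b1-b3 (4): one cluster by single linkage
  b2 <- mutate_at(base, 1:2)
  b3 <- mutate_at(base, 1:4)
  expect_equal(hamming_slow(base, b3), 4)
  expect_equal(length(unique(cluster_barcodes(c(base, b2, b3), 3))), 1)
  expect_error(cluster_barcodes(c("ACGT", "ACGTA")), "length")
})

test_that("clustering equals the brute-force union-find oracle", {
  for (i in 1:20) {
    n <- sample(10:30, 1)
    core <- random_seqs(max(3, n %/% 5), 37, 500 + i)
    set.seed(600 + i)
    bc <- vapply(seq_len(n), function(k) {
      s <- strsplit(sample(core, 1), "")[[1]]
      pos <- sample(37, sample(0:5, 1))
      s[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
    got <- cluster_barcodes(bc, 3)
    want <- cluster_oracle(bc, 3)
    expect_identical(got[sort(names(got))], want[sort(names(want))])
  }
})

test_that("clustering cluster ids is the identity (idempotence)", {
  bc <- random_seqs(25, 37, 77)
  cl <- cluster_barcodes(bc, 3)
  again <- cluster_barcodes(unique(unname(cl)), 3)
  expect_identical(again, setNames(sort(unique(unname(cl))),
                                   sort(unique(unname(cl)))))
})

test_that("clone table joins cells through shared barcode clusters", {
  meta <- data.frame(cell_id = c("A", "B", "C", "D"),
                     class = "PN", arm = "gLacZ", batch = "b1",
                     stringsAsFactors = FALSE)
  counts <- data.frame(cell_id = c("A", "B", "B", "C", "D"),
                       barcode = c("bc1", "bc1", "bc2", "bc2", "bc3"),
                       umi_count = c(2L, 1L, 1L, 3L, 1L),
                       stringsAsFactors = FALSE)
  clusters <- setNames(c("bc1", "bc2", "bc3"), c("bc1", "bc2", "bc3"))
  tab <- build_clone_table(counts, clusters, meta)
  # A-bc1-B-bc2-C form one clone (bipartite components); D stands alone
  expect_equal(length(unique(tab$clone_id[tab$cell_id %in% c("A", "B", "C")])),
               1)
  expect_false(tab$clone_id[tab$cell_id == "D"] %in%
                 tab$clone_id[tab$cell_id != "D"])
  # min_umi = 2 severs B and C from the chain
  tab2 <- build_clone_table(counts, clusters, meta, min_umi = 2)
  expect_equal(sort(tab2$cell_id), c("A", "C"))
  expect_equal(length(unique(tab2$clone_id)), 2)
  expect_equal(sort(attr(tab2, "report")$cells_dropped), c("B", "D"))

  expect_error(build_clone_table(
    data.frame(cell_id = "Z", barcode = "bc1", umi_count = 1L),
    clusters, meta), "Z")
})

test_that("identical barcodes in different batches stay separate clones", {
  meta <- data.frame(cell_id = c("A", "B"), class = "PN", arm = "gLacZ",
                     batch = c("b1", "b2"), stringsAsFactors = FALSE)
  counts <- data.frame(cell_id = c("A", "B"), barcode = "bc1",
                       umi_count = 1L, stringsAsFactors = FALSE)
  clusters <- setNames("bc1", "bc1")
  tab <- build_clone_table(counts, clusters, meta)
  expect_equal(length(unique(tab$clone_id)), 2)
})

test_that("the pipeline is invariant to read order and exact without noise", {
  cfg <- sim_config(n_progenitors = 25, per_base_error = 0, seed = 17)
  ct <- simulate_clones(cfg)$clone_table
  lib <- generate_barcode_library(length(unique(ct$clone_id)), seed = 17)
  fq <- synthesize_fastq(ct, lib, cfg)
  meta <- ct[, c("cell_id", "class", "arm", "batch")]
  tab <- call_clones(fq$reads, meta)
  # permutation invariance
  set.seed(1)
  shuf <- fq$reads[sample(nrow(fq$reads)), ]
  expect_identical(call_clones(shuf, meta), tab)
  # exact clone recovery (ARI = 1)
  m <- match(tab$cell_id, ct$cell_id)
  expect_equal(mclust::adjustedRandIndex(tab$clone_id, ct$clone_id[m]), 1)
})
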