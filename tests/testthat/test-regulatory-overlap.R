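test_that("nearest TSS distances are signed by strand and tie-broken", {
  tss <- iv("chr1", c(1000, 5000), c(1001, 5001), strand = c("+", "-"),
            name = c("gPlus", "gMinus"))
  # summit exactly at a TSS: distance 0
  pk0 <- genomic_intervals("chr1", 900, 1100, name = "p0", summit = 100)
  expect_equal(nearest_tss(pk0, tss)$distance, 0)

  # peak downstream of a + gene: positive
  pkd <- genomic_intervals("chr1", 1190, 1210, name = "pd")
  expect_equal(nearest_tss(pkd, tss)$distance, 200)
  # the same coordinates upstream of the - strand gene: negative means
  # upstream relative to transcription, i.e. larger coordinate
  pku <- genomic_intervals("chr1", 5190, 5210, name = "pu")
  expect_equal(nearest_tss(pku, tss)$distance, -200)

  # peak on a chromosome without TSS: flagged
  pkx <- genomic_intervals("chr9", 10, 20, name = "px")
  rx <- nearest_tss(pkx, tss)
  expect_true(is.na(rx$distance))
  expect_equal(rx$flag, "no_tss_on_chrom")
})

test_that("nearest TSS agrees with the all-pairs oracle on random sets", {
  for (i in 1:25) {
    peaks <- random_intervals(20, 800 + i, prefix = "pk")
    set.seed(900 + i)
    tpos <- sample.int(10000, 10)
    tss <- genomic_intervals(sample(c("chr1", "chr2"), 10, replace = TRUE),
                             tpos, tpos + 1L,
                             strand = sample(c("+", "-"), 10, replace = TRUE),
                             name = sprintf("g%02d", 1:10))
    got <- nearest_tss(peaks, tss)
    want <- nearest_oracle(peaks, tss)
    expect_equal(got$distance, want$distance)
    expect_equal(got$tss_id, want$tss_id)
  }
})

test_that("promoter windows are half-open around the TSS", {
  tss <- genomic_intervals("chr1", 10000, 10001, strand = "+", name = "G")
  # peak ending exactly at TSS - half_width does not overlap
  left <- genomic_intervals("chr1", 4000, 5000, name = "pL")
  expect_equal(nrow(promoter_assignment(left, tss, 5000)), 0)
  # one base further does
  left2 <- genomic_intervals("chr1", 4000, 5001, name = "pL2")
  expect_equal(promoter_assignment(left2, tss, 5000)$gene, "G")
  # the window's right edge is exclusive: [5000, 15000)
  right <- genomic_intervals("chr1", 15000, 16000, name = "pR")
  expect_equal(nrow(promoter_assignment(right, tss, 5000)), 0)
  right2 <- genomic_intervals("chr1", 14999, 16000, name = "pR2")
  expect_equal(promoter_assignment(right2, tss, 5000)$gene, "G")
})

test_that("promoter assignment matches brute-force window overlap", {
  for (i in 1:25) {
    peaks <- random_intervals(8, 700 + i, prefix = "pk", span = 30000,
                              width_max = 3000)
    set.seed(750 + i)
    tpos <- sample.int(30000, 3)
    tss <- genomic_intervals(sample(c("chr1", "chr2"), 3, replace = TRUE),
                             tpos, tpos + 1L, strand = "+",
                             name = sprintf("g%d", 1:3))
    hw <- sample(c(2500, 5000), 1)
    got <- promoter_assignment(peaks, tss, hw)
    tp <- tss$start
    win <- data.frame(chrom = tss$chrom, start = tp - hw, end = tp + hw)
    hits <- overlap_oracle(peaks, win)
    want <- if (is.null(hits)) character(0) else
      sort(paste(peaks$name[hits[, 1]], tss$name[hits[, 2]]))
    expect_equal(sort(paste(got$peak, got$gene)), want)
  }
})

test_that("shared/exclusive site classification is A-site-centric", {
  a <- iv("chr1", c(0, 100, 200), c(50, 150, 250),
          name = c("a1", "a2", "a3"))
  b <- iv("chr1", c(40, 300), c(120, 400), name = c("b1", "b2"))
  cl <- classify_overlap(a, b)
  # b1 overlaps both a1 and a2: counted once per A site
  expect_equal(unname(cl$counts), c(2, 1, 1))
  expect_equal(cl$a$shared, c(TRUE, TRUE, FALSE))
  expect_equal(cl$b$shared, c(TRUE, FALSE))

  # disjoint and identical sets
  expect_equal(unname(classify_overlap(a, iv("chr2", 0, 10))$counts[1]), 0)
  self <- classify_overlap(a, a)
  expect_true(all(self$a$shared))
  expect_equal(unname(self$counts["b_exclusive"]), 0)
})

test_that("overlap classification matches the pairwise oracle", {
  for (i in 1:20) {
    a <- random_intervals(25, 300 + i, prefix = "a")
    b <- random_intervals(25, 350 + i, prefix = "b")
    cl <- classify_overlap(a, b)
    hits <- overlap_oracle(a, b)
    a_shared <- if (is.null(hits)) integer(0) else unique(hits[, 1])
    b_shared <- if (is.null(hits)) integer(0) else unique(hits[, 2])
    expect_equal(which(cl$a$shared), sort(a_shared))
    expect_equal(unname(cl$counts),
                 c(length(a_shared), 25 - length(a_shared),
                   25 - length(b_shared)))
  }
})

test_that("enhancer enrichment reproduces the Pearson Chi-square formula", {
  tab <- rbind(c(30, 70), c(10, 90), c(12, 88))
  res <- enhancer_enrichment(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected))
  expect_equal(res$dof, 2)

  # homogeneous table: statistic ~ 0, p ~ 1
  hom <- rbind(c(20, 80), c(10, 40), c(40, 160))
  rh <- enhancer_enrichment(hom)
  expect_lt(rh$statistic, 1e-10)
  expect_gt(rh$p, 0.999)

  expect_error(enhancer_enrichment(rbind(c(0, 0), c(1, 2), c(3, 4))),
               "positive")
})

test_that("target genes union promoter and enhancer routes", {
  tss <- genomic_intervals("chr1", c(1000, 50000), c(1001, 50001),
                           strand = "+", name = c("G1", "G2"))
  links <- data.frame(chrom = "chr1", start = 20000, end = 21000,
                      gene = "G2", stringsAsFactors = FALSE)
  peaks <- genomic_intervals("chr1", c(900, 20500, 48000),
                             c(1100, 20600, 52000),
                             name = c("pProm", "pEnh", "pBoth"))
  links2 <- rbind(links, data.frame(chrom = "chr1", start = 49000,
                                    end = 51000, gene = "G1"))
  res <- assign_target_genes(peaks, tss, 5000, links2)
  pp <- res$per_peak
  expect_equal(pp$gene[pp$peak == "pProm"], "G1")
  expect_equal(pp$route[pp$peak == "pProm"], "promoter")
  expect_equal(pp$gene[pp$peak == "pEnh"], "G2")
  expect_equal(pp$route[pp$peak == "pEnh"], "enhancer")
  # pBoth hits G2's promoter window and G1's linked enhancer
  expect_setequal(pp$gene[pp$peak == "pBoth"], c("G1", "G2"))
  expect_equal(res$targets, c("G1", "G2"))

  # monotone: adding a link never removes a gene
  res0 <- assign_target_genes(peaks, tss, 5000, links)
  expect_true(all(paste(res0$per_peak$peak, res0$per_peak$gene) %in%
                    paste(pp$peak, pp$gene)))
})

test_that("interval operations are invariant to a coordinate shift", {
  peaks <- random_intervals(15, 123, prefix = "pk")
  set.seed(124)
  tpos <- sample.int(10000, 6)
  tss <- genomic_intervals(sample(c("chr1", "chr2"), 6, replace = TRUE),
                           tpos, tpos + 1L, strand = "+",
                           name = sprintf("g%d", 1:6))
  links <- data.frame(chrom = "chr1", start = c(2000, 7000),
                      end = c(2500, 7800), gene = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  shift <- function(df, k) { df$start <- df$start + k; df$end <- df$end + k; df }
  k <- 5000
  a <- assign_target_genes(peaks, tss, 3000, links)
  b <- assign_target_genes(shift(peaks, k), shift(tss, k), 3000,
                           shift(links, k))
  expect_equal(a, b)
  expect_equal(nearest_tss(peaks, tss)$distance,
               nearest_tss(shift(peaks, k), shift(tss, k))$distance)
})
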