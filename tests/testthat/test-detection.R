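test_that("read identity follows (aligned - NM)/aligned", {
  aln <- data.frame(aligned_bases = c(150, 150), edit_distance = c(0, 15))
  expect_equal(read_identity(aln), c(1, 0.9))
  expect_error(read_identity(data.frame(aligned_bases = 0,
                                        edit_distance = 0)), "> 0")
  expect_error(read_identity(data.frame(aligned_bases = 100,
                                        edit_distance = 101)), "exceed")
})

test_that("coverage breadth is an interval union, not a depth sum", {
  g <- c(G = strrep("A", 1000))
  one <- data.frame(read_id = "r1", genome_id = "G", start = 0, end = 1000,
                    aligned_bases = 1000, edit_distance = 0, strand = "+")
  p <- coverage_profile(one, g, 90)
  expect_equal(p$covered_fraction, 1)
  half <- data.frame(read_id = c("r1", "r2"), genome_id = "G",
                     start = c(0, 0), end = c(500, 500),
                     aligned_bases = 500, edit_distance = 0, strand = "+")
  p2 <- coverage_profile(half, g, 90)
  expect_equal(p2$covered_fraction, 0.5)
  expect_equal(p2$qualifying_bases, 1000)  # depth still counts in bases
  # foreign alignments ignored with a warning
  half$genome_id[2] <- "other"
  expect_warning(p3 <- coverage_profile(half, g, 90), "ignored")
  expect_equal(p3$covered_fraction, 0.5)
  expect_equal(p3$n_foreign, 1)
})

test_that("low-identity reads contribute nothing above their threshold", {
  g <- c(A = unname(generate_ancestor(20000, 0.4, 3)))
  rs <- simulate_reads(g, c(A = 1), 150, per_base_divergence = 0.15,
                       total_bases = 20000 * 20, seed = 2)
  aln <- alignments_from_readset(rs)
  p90 <- coverage_profile(aln, g, 90)
  expect_equal(p90$covered_fraction, 0)
  p70 <- coverage_profile(aln, g, 70)
  expect_gt(p70$covered_fraction, 0.99)
})

test_that("coverage is monotone non-increasing in the identity threshold", {
  g <- c(A = unname(generate_ancestor(15000, 0.4, 5)))
  for (div in c(0, 0.08)) {
    rs <- simulate_reads(g, c(A = 1), 150, div, 15000 * 5, seed = 7)
    aln <- alignments_from_readset(rs)
    fr <- vapply(c(70, 90, 95, 99),
                 function(t) coverage_profile(aln, g, t)$covered_fraction, 0)
    expect_true(all(diff(fr) <= 1e-12))
  }
})

test_that("presence rules use strict inequalities at the printed thresholds", {
  prof <- function(thr, frac) data.frame(
    genome_id = "g", identity_threshold = thr, covered_fraction = frac,
    qualifying_bases = 1, n_foreign = 0)
  expect_true(call_presence(prof(90, 0.80), "phage")$present)
  expect_false(call_presence(prof(90, 0.75), "phage")$present)   # exactly 75%
  expect_false(call_presence(prof(95, 0.60), "bacterium")$present)
  expect_true(call_presence(prof(95, 0.600001), "bacterium")$present)
  expect_false(call_presence(prof(70, 0.60), "relative")$present)
  expect_error(call_presence(prof(90, 0.8), "bacterium"), "95")
  expect_error(call_presence(prof(90, 0.8), "plasmid"), "kind")
})

test_that("a phage can be absent at species level while relatives are present", {
  profs <- rbind(
    data.frame(genome_id = "g", identity_threshold = 90,
               covered_fraction = 0.70, qualifying_bases = 1, n_foreign = 0),
    data.frame(genome_id = "g", identity_threshold = 70,
               covered_fraction = 0.65, qualifying_bases = 1, n_foreign = 0))
  expect_false(call_presence(profs, "phage")$present)
  expect_true(call_presence(profs, "relative")$present)
})

test_that("normalized abundance follows bases/genome/Gb with its invariants", {
  expect_equal(normalized_abundance(1e6, 5e4, 2), 10)
  expect_equal(normalized_abundance(0, 5e4, 2), 0)
  expect_equal(normalized_abundance(1e6, 5e4, 4),
               normalized_abundance(1e6, 5e4, 2) / 2)
  expect_equal(normalized_abundance(3e6, 5e4, 2),
               3 * normalized_abundance(1e6, 5e4, 2))
  expect_error(normalized_abundance(1, 0, 1), "> 0")
  expect_error(normalized_abundance(-1, 1, 1), ">= 0")
})

test_that("phage/host ratios divide abundances and flag undefined hosts", {
  expect_equal(phage_host_ratio(10, 10), 1)
  r <- phage_host_ratio(5, 0)
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  expect_equal(format_ratio(phage_host_ratio(53.8, 0.14)), "384")
  expect_equal(format_ratio(phage_host_ratio(0.04, 0.46)), "0.09")
  expect_equal(format_ratio(r), "-")
})

test_that("duplicating alignments preserves breadth and doubles bases", {
  g <- c(A = unname(generate_ancestor(10000, 0.4, 9)))
  rs <- simulate_reads(g, c(A = 1), 100, 0, 10000 * 2, seed = 3)
  aln <- alignments_from_readset(rs)
  doubled <- rbind(aln, aln)
  p1 <- coverage_profile(aln, g, 90)
  p2 <- coverage_profile(doubled, g, 90)
  expect_equal(p2$covered_fraction, p1$covered_fraction)
  expect_equal(p2$qualifying_bases, 2 * p1$qualifying_bases)
})

test_that("deep perfect coverage saturates breadth", {
  g <- c(A = unname(generate_ancestor(5000, 0.4, 13)))
  rs <- simulate_reads(g, c(A = 1), 100, 0, 5000 * 100, seed = 11)
  p <- coverage_profile(alignments_from_readset(rs), g, 100)
  expect_gte(p$covered_fraction, 0.99)
})

test_that("SAM ingestion recovers coordinates, NM and flag filtering", {
  sam <- withr::local_tempfile(fileext = ".sam")
  seq50 <- strrep("ACGTA", 10)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:gA\tLN:200",
    paste("r1", 0, "gA", 11, 60, "50M", "*", 0, 0, seq50, "*", "NM:i:2",
          sep = "\t"),
    paste("r2", 16, "gA", 61, 60, "20M5D30M", "*", 0, 0, seq50, "*", "NM:i:7",
          sep = "\t"),
    paste("r3", 256, "gA", 1, 60, "50M", "*", 0, 0, seq50, "*", "NM:i:0",
          sep = "\t"),
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0, seq50, "*", sep = "\t")),
    sam)
  aln <- read_alignments_sam(sam)
  expect_equal(nrow(aln), 2)  # secondary and unmapped dropped
  expect_equal(aln$start, c(10, 60))
  expect_equal(aln$end, c(60, 115))  # 20M5D30M spans 55 reference bases
  expect_equal(aln$aligned_bases, c(50, 50))
  expect_equal(aln$edit_distance, c(2, 7))
  expect_equal(read_identity(aln), c(48 / 50, 43 / 50))
})

test_that("PAF ingestion reconstructs identity from matches/block length", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(
    paste("r1", 100, 0, 100, "+", "gA", 5000, 200, 300, 95, 100, 60,
          sep = "\t"),
    paste("r2", 100, 0, 100, "-", "gA", 5000, 400, 500, 80, 100, 60,
          sep = "\t")), paf)
  aln <- read_alignments_paf(paf)
  expect_equal(aln$start, c(200, 400))
  expect_equal(read_identity(aln), c(0.95, 0.80))
  empty <- withr::local_tempfile(fileext = ".paf"); writeLines(character(0), empty)
  expect_equal(nrow(read_alignments_paf(empty)), 0)
})

test_that("the bundled bloom coverage table reproduces the printed ratios", {
  cov <- read.delim(system.file("extdata", "bloom2018_coverage.tsv",
                                package = "flavoscope"))
  tab <- bloom_ratio_table(cov)
  d102 <- tab[tab$julian_day == 102, ]
  expect_equal(tab$ratio_printed[tab$name == "Freya"], "384")
  expect_equal(tab$ratio_printed[tab$name == "Danklef"], "74")
  d142 <- tab[tab$julian_day == 142, ]
  expect_equal(nrow(d142), 3)
  expect_true(all(d142$ratio < 0.1))
})
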