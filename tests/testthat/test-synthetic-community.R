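test_that("ancestor generation hits length and GC targets deterministically", {
  g <- generate_ancestor(10000, 0.30, seed = 7)
  expect_equal(unname(nchar(g)), 10000)
  gc <- mean(split_chars(unname(g)) %in% c("G", "C"))
  expect_gte(gc, 0.28); expect_lte(gc, 0.32)
  expect_identical(unname(g), unname(generate_ancestor(10000, 0.30, seed = 7)))
  expect_error(generate_ancestor(0, 0.5, 1), "length")
})

test_that("evolved genomes realize their target identity per the edit-list oracle", {
  parent <- generate_ancestor(50000, 0.35, seed = 3)
  expect_identical(as.character(unname(evolve_genome(parent, 1.0, seed = 1))),
                   as.character(unname(parent)))
  for (t in c(0.95, 0.72)) {
    child <- evolve_genome(parent, t, indel_rate = 0.05, seed = 11)
    ident <- planted_identity(attr(child, "edits"))
    expect_gte(ident, t - 0.005)
    expect_lte(ident, t + 0.005)
  }
  expect_error(evolve_genome(parent, 1.2, seed = 1), "target_identity")
  expect_error(evolve_genome(parent, 0, seed = 1), "target_identity")
})

test_that("edit-list oracle agrees with direct string comparison (no indels)", {
  parent <- generate_ancestor(20000, 0.35, seed = 5)
  child <- evolve_genome(parent, 0.9, indel_rate = 0, seed = 2)
  direct <- mean(split_chars(unname(parent)) == split_chars(unname(child)))
  expect_equal(planted_identity(attr(child, "edits")), direct,
               tolerance = 1e-12)
})

test_that("planted taxonomy has the declared counts, labels and ANI tiers", {
  spec <- community_spec(seed = 3, n_families = 2, genera_per_family = 1,
                         species_per_genus = 2, strains_per_species = 1,
                         genome_length_range = c(12000, 13000))
  comm <- plant_taxonomy(spec)
  expect_length(comm$genomes, 4)
  expect_equal(length(unique(comm$truth$family)), 2)
  # strain-mates are identical sequences
  comm2 <- tiny_community()
  spx <- split(comm2$truth$genome_id, comm2$truth$strain)
  for (ids in spx[lengths(spx) > 1])
    expect_identical(unname(comm2$genomes[ids[1]]),
                     unname(comm2$genomes[ids[2]]))
  # planted ANI: within-genus cross-species pairs inside the genus range
  pa <- comm$planted_ani
  tr <- comm$truth
  for (i in 1:3) for (j in (i + 1):4) {
    if (tr$genus[i] == tr$genus[j] && tr$species[i] != tr$species[j]) {
      expect_gte(pa[i, j], spec$genus_ani_range[1] - 1e-9)
      expect_lte(pa[i, j], spec$genus_ani_range[2] + 1e-9)
    }
  }
  expect_error(plant_taxonomy(community_spec(genera_per_family = 8)),
               "infeasible")
})

test_that("families share no planted gene sequences", {
  comm <- tiny_community()
  by_fam <- split(comm$genes$seq, comm$genes$family)
  expect_length(by_fam, 2)
  expect_length(intersect(by_fam[[1]], by_fam[[2]]), 0)
})

test_that("community generation is deterministic and round-trips via FASTA", {
  spec <- community_spec(seed = 9, n_families = 1, genera_per_family = 1,
                         species_per_genus = 2, strains_per_species = 1,
                         genome_length_range = c(12000, 12500))
  c1 <- plant_taxonomy(spec)
  c2 <- plant_taxonomy(spec)
  expect_identical(c1$genomes, c2$genomes)
  d <- withr::local_tempdir()
  write_community(c1, d)
  back <- read_genomes_fasta(file.path(d, "genomes.fasta"))
  expect_identical(unname(back), unname(c1$genomes))
  expect_true(file.exists(file.path(d, "manifest.json")))
})

test_that("simulated reads respect weights, bases, strands and determinism", {
  g <- c(A = unname(generate_ancestor(5000, 0.4, 1)),
         B = unname(generate_ancestor(5000, 0.4, 2)))
  rs <- simulate_reads(g, c(A = 1, B = 0), read_length = 100,
                       per_base_divergence = 0, total_bases = 50000, seed = 4)
  expect_true(all(rs$reads$origin == "A"))
  expect_equal(sum(nchar(rs$reads$seq)), 50000)
  expect_equal(rs$library_size_gb, 50000 / 1e9)
  expect_true(all(rs$reads$end <= nchar(g["A"])))
  rs2 <- simulate_reads(g, c(A = 1, B = 0), 100, 0, 50000, seed = 4)
  expect_identical(rs$reads, rs2$reads)
  # plus strand reads match their origin interval; minus strand reads match
  # its reverse complement
  r <- rs$reads[1:20, ]
  for (k in seq_len(nrow(r))) {
    ref <- substr(g[r$origin[k]], r$start[k] + 1, r$end[k])
    obs <- if (r$strand[k] == "-") revcomp(r$seq[k]) else r$seq[k]
    expect_identical(obs, unname(ref))
  }
  expect_error(simulate_reads(character(0), c(A = 1), 100, 0, 1000, 1),
               "non-empty")
})

test_that("divergent reads carry the planted substitution load exactly", {
  g <- c(A = unname(generate_ancestor(5000, 0.4, 6)))
  rs <- simulate_reads(g, c(A = 1), 150, 0.08, 30000, seed = 5)
  expect_true(all(rs$reads$n_sub == round(150 * 0.08)))
  r <- rs$reads[3, ]
  obs <- if (r$strand == "-") revcomp(r$seq) else r$seq
  ref <- substr(g["A"], r$start + 1, r$end)
  expect_equal(sum(split_chars(obs) != split_chars(unname(ref))), r$n_sub)
})

test_that("read sets round-trip through FASTA and FASTQ", {
  g <- c(A = unname(generate_ancestor(2000, 0.4, 2)))
  rs <- simulate_reads(g, c(A = 1), 80, 0, 2000, seed = 1)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_reads(rs, fa, "fasta")
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back), setNames(rs$reads$seq, rs$reads$read_id))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads(rs, fq, "fastq")
  qs <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(unname(as.character(qs)), rs$reads$seq)
})

test_that("planted spacers trace back to their phage intervals", {
  g <- generate_ancestor(6000, 0.35, 8, id = "P1")
  tr <- plant_spacers(g, 6, seed = 2)
  expect_equal(nrow(tr), 6)
  for (i in seq_len(nrow(tr))) {
    ref <- substr(g, tr$start[i] + 1, tr$end[i])
    obs <- if (tr$strand[i] == "-") revcomp(tr$seq[i]) else tr$seq[i]
    expect_identical(obs, unname(ref))
  }
  # planted substitutions are recorded and realized
  tr2 <- plant_spacers(g, 2, edits = data.frame(n_sub = 2, gap_len = 0),
                       seed = 3)
  for (i in 1:2) {
    ref <- substr(g, tr2$start[i] + 1, tr2$end[i])
    obs <- if (tr2$strand[i] == "-") revcomp(tr2$seq[i]) else tr2$seq[i]
    expect_equal(sum(split_chars(obs) != split_chars(unname(ref))), 2)
  }
  expect_error(plant_spacers(g, 0, seed = 1), "n must be")
})
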