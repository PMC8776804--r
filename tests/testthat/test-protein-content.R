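test_that("ORF calling finds planted genes on both strands", {
  bb <- strrep("C", 120)
  gene <- paste0("ATG", strrep("GCT", 98), "TAA")  # 99 aa protein
  g <- setNames(paste0(bb, gene, bb), "toy")
  o <- call_orfs(g, min_aa = 30)
  expect_equal(nrow(o), 1)
  expect_equal(o$length_aa, 99)
  expect_equal(o$start, 120)
  expect_equal(o$end, 120 + nchar(gene))
  expect_equal(o$strand, "+")
  expect_equal(o$seq, paste0("M", strrep("A", 98)))
  # all-A sequence has no ORFs
  expect_equal(nrow(call_orfs(setNames(strrep("A", 500), "x"))), 0)
  # reverse-strand planted ORF
  grc <- setNames(revcomp(unname(g)), "toyrc")
  o2 <- call_orfs(grc, min_aa = 30)
  expect_equal(nrow(o2), 1)
  expect_equal(o2$strand, "-")
  expect_equal(o2$seq, o$seq)
  expect_equal(o2$start, unname(nchar(grc)) - o$end)
})

test_that("ORF calling matches a six-frame brute-force oracle", {
  g <- generate_ancestor(3000, 0.4, 31, id = "r")
  o <- call_orfs(g, min_aa = 30)
  # oracle: scan each strand/frame codon-wise with the same maximal-ORF rule
  oracle <- list()
  code <- Biostrings::GENETIC_CODE
  for (strand in c("+", "-")) {
    s <- if (strand == "+") unname(g) else revcomp(unname(g))
    for (fr in 0:2) {
      n_cod <- (nchar(s) - fr) %/% 3
      pos <- fr + seq(1, by = 3, length.out = n_cod)
      cod <- substring(s, pos, pos + 2)
      start_ok <- cod %in% c("ATG", "GTG", "TTG")
      is_stop <- cod %in% c("TAA", "TAG", "TGA")
      open <- NA
      for (i in seq_len(n_cod)) {
        if (is.na(open) && start_ok[i] && !is_stop[i]) open <- i
        if (is_stop[i]) {
          if (!is.na(open) && i - open >= 30)
            oracle[[length(oracle) + 1L]] <-
              c(strand = strand, aa = paste(code[cod[open:(i - 1)]],
                                            collapse = ""))
          open <- NA
        }
      }
    }
  }
  oracle_aa <- sort(vapply(oracle, `[[`, "", "aa"))
  expect_equal(sort(o$seq), oracle_aa)
})

test_that("reciprocal hit filtering applies both e-value and bitscore rules", {
  p1 <- strrep("MKTLLVAGGALLAVSACSSNT", 10)  # 210 aa
  prot <- data.frame(protein_id = c("a|1", "b|1"), genome_id = c("a", "b"),
                     seq = c(p1, p1), stringsAsFactors = FALSE)
  hg <- all_vs_all_hits(prot)
  expect_equal(nrow(hg$edges), 1)
  expect_gte(hg$edges$bitscore, 50)
  expect_lte(hg$edges$evalue, 1e-4)
  # unrelated short proteins: no edge
  prot2 <- data.frame(protein_id = c("a|1", "b|1"), genome_id = c("a", "b"),
                      seq = c(strrep("MKTAYIAKQR", 4), strrep("WFDPLQGEHN", 4)),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(all_vs_all_hits(prot2)$edges), 0)
  expect_error(all_vs_all_hits(prot[0, ]), "at least one")
  # tabular interop: a directional hit failing either filter kills the edge
  tab <- data.frame(
    qseqid = c("a|1", "b|1", "a|1", "c|1", "a|1", "d|1"),
    sseqid = c("b|1", "a|1", "c|1", "a|1", "d|1", "a|1"),
    evalue = c(1e-10, 1e-10, 1e-10, 0.01, 1e-10, 1e-10),
    bitscore = c(200, 200, 200, 200, 200, 40))
  prots <- data.frame(protein_id = c("a|1", "b|1", "c|1", "d|1"),
                      genome_id = c("a", "b", "c", "d"),
                      seq = strrep("A", 100), stringsAsFactors = FALSE)
  hg2 <- hit_graph_from_table(tab, prots)
  expect_equal(nrow(hg2$edges), 1)  # only a-b is reciprocal and passing
  expect_setequal(c(hg2$edges$p1, hg2$edges$p2), c("a|1", "b|1"))
})

test_that("protein clusters equal the connected-components oracle", {
  prots <- data.frame(protein_id = letters[1:5], genome_id = "g",
                      seq = strrep("A", 50), stringsAsFactors = FALSE)
  # edgeless: all singletons
  hg <- structure(list(edges = data.frame(p1 = character(0),
                                          p2 = character(0)),
                       proteins = prots), class = "hit_graph")
  cat0 <- protein_clusters(hg)
  expect_equal(length(unique(cat0$assignment$pc_id)), 5)
  # path a-b-c plus isolated d, e
  hg$edges <- data.frame(p1 = c("a", "b"), p2 = c("b", "c"))
  cat1 <- protein_clusters(hg)
  memb <- setNames(cat1$assignment$pc_id, cat1$assignment$protein_id)
  oracle <- components_oracle(letters[1:5], as.matrix(hg$edges))
  expect_true(same_partition(memb, oracle))
  expect_equal(memb[["a"]], "a")  # deterministic smallest-member id
  # two identical proteomes: every PC has exactly two members
  comm <- tiny_community()
  g <- comm$genomes[1]
  two <- setNames(c(unname(g), unname(g)), c("x", "y"))
  cat2 <- protein_clusters(all_vs_all_hits(primary_proteome(
    call_orfs_all(two, min_aa = 60))))
  expect_true(all(colSums(cat2$matrix) == 2))
})

test_that("genome distance is Dice on PC presence with the documented extremes", {
  m <- matrix(0L, 2, 14, dimnames = list(c("a", "b"), sprintf("pc%02d", 1:14)))
  m["a", 1:10] <- 1L
  m["b", 7:12] <- 1L  # |a|=10, |b|=6, shared 4
  cat_ <- fake_catalog(m)
  expect_equal(genome_distance(cat_, "a", "b"), 0.5)
  expect_equal(genome_distance(cat_, "a", "a"), 0)
  m2 <- m; m2["b", ] <- m2["a", ]
  expect_equal(genome_distance(fake_catalog(m2), "a", "b"), 0)
  m3 <- m; m3["b", ] <- 0L; m3["b", 11:14] <- 1L
  expect_equal(genome_distance(fake_catalog(m3), "a", "b"), 1)
  expect_error(genome_distance(cat_, "a", "zz"), "unknown")
  d <- genome_distance_matrix(cat_)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(diag(d), c(a = 0, b = 0))
})

test_that("complete-linkage trees match the exhaustive oracle on small inputs", {
  d3 <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0.8, 0.8, 0.8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- hierarchical_tree(d3)
  expect_equal(tr$height, c(0.2, 0.8))
  # two leaves
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(hierarchical_tree(d2)$height, 0.4)
  # random 5-leaf matrices against the naive agglomeration oracle
  for (s in 1:6) {
    d <- with_seed(s, {
      x <- matrix(runif(25, 0.05, 1), 5, 5); x <- (x + t(x)) / 2; diag(x) <- 0
      dimnames(x) <- list(LETTERS[1:5], LETTERS[1:5]); x
    })
    tr <- hierarchical_tree(d)
    orc <- complete_linkage_oracle(d)
    expect_equal(tr$height, orc$heights, tolerance = 1e-12)
    expect_setequal(vapply(clade_leafsets(tr), paste, "", collapse = "|"),
                    vapply(orc$clades, paste, "", collapse = "|"))
  }
  bad <- d3; bad[1, 2] <- 0.3
  expect_error(hierarchical_tree(bad), "symmetric")
})

test_that("merge heights are monotone for complete linkage", {
  for (s in 1:5) {
    d <- with_seed(40 + s, {
      x <- matrix(runif(64), 8, 8); x <- (x + t(x)) / 2; diag(x) <- 0
      dimnames(x) <- list(letters[1:8], letters[1:8]); x
    })
    h <- hierarchical_tree(d)$height
    expect_true(all(diff(h) >= -1e-12))
  }
})

test_that("bootstrap supports behave at the edges and separate planted families", {
  cat_ <- tiny_catalog()
  tree <- hierarchical_tree(genome_distance_matrix(cat_))
  t1 <- bootstrap_supports(cat_, tree, n_replicates = 1, seed = 5)
  expect_true(all(attr(t1, "supports") %in% c(0, 1)))
  t2 <- bootstrap_supports(cat_, tree, n_replicates = 50, seed = 5)
  t3 <- bootstrap_supports(cat_, tree, n_replicates = 50, seed = 5)
  expect_identical(attr(t2, "supports"), attr(t3, "supports"))
  # the two planted families have disjoint PC content: the family clades
  # must be near-certain under resampling
  comm <- tiny_community()
  sets <- clade_leafsets(t2)
  sup <- attr(t2, "supports")
  fam_sets <- split(comm$truth$genome_id, comm$truth$family)
  for (fs in fam_sets) {
    idx <- match(paste(sort(fs), collapse = "\r"),
                 vapply(sets, paste, "", collapse = "\r"))
    expect_false(is.na(idx))
    expect_gte(sup[idx], 0.95)
  }
  expect_error(bootstrap_supports(cat_, tree, n_replicates = 0), "replicates")
  # supports are invariant to PC column order
  cat_perm <- cat_
  perm <- with_seed(1, sample.int(ncol(cat_$matrix)))
  cat_perm$matrix <- cat_$matrix[, perm]
  t4 <- bootstrap_supports(cat_perm, tree, n_replicates = 50, seed = 5)
  expect_identical(attr(t2, "supports"), attr(t4, "supports"))
})

test_that("tree cutting is strict, silhouettes computed, refinement holds", {
  d <- matrix(0.95, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[1, 2] <- d[2, 1] <- 0.2; d[3, 4] <- d[4, 3] <- 0.3
  diag(d) <- 0
  tr <- hierarchical_tree(d)
  p <- cut_tree(tr, 0.9, d)
  expect_equal(length(unique(p$membership)), 2)
  expect_true(all(p$silhouette > 0.5))
  # all merges below the cut: one cluster
  expect_equal(length(unique(cut_tree(tr, 0.99, d)$membership)), 1)
  # strict rule: a merge exactly at the cut height separates
  p_exact <- cut_tree(tr, 0.2, d)
  expect_equal(length(unique(p_exact$membership)), 4)
  # agreement with stats::cutree away from boundary ties
  for (s in 1:4) {
    dr <- with_seed(70 + s, {
      x <- matrix(runif(49, 0.01, 1), 7, 7); x <- (x + t(x)) / 2; diag(x) <- 0
      dimnames(x) <- list(letters[1:7], letters[1:7]); x
    })
    trr <- hierarchical_tree(dr)
    for (h in c(0.35, 0.75)) {
      mine <- cut_tree(trr, h)$membership
      ref <- stats::cutree(trr, h = h - 1e-9)
      expect_true(same_partition(mine, setNames(as.character(ref),
                                                names(ref))))
    }
    # lowering the cut refines the partition
    expect_true(partition_refines(
      list(membership = cut_tree(trr, 0.35)$membership),
      list(membership = cut_tree(trr, 0.75)$membership)))
  }
  expect_error(cut_tree(tr, 0), "height")
})

test_that("silhouette widths follow the (b - a)/max(a, b) definition", {
  d <- matrix(0.9, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d["x", "y"] <- d["y", "x"] <- 0.1
  diag(d) <- 0
  memb <- c(x = "c1", y = "c1", z = "c2")
  expect_equal(silhouette_width(d, memb, "x"), (0.9 - 0.1) / 0.9)
  expect_equal(silhouette_width(d, memb, "z"), 0)  # singleton convention
  # a == b gives 0
  d2 <- d; d2["x", "y"] <- d2["y", "x"] <- 0.9
  expect_equal(silhouette_width(d2, memb, "x"), 0)
  expect_error(silhouette_width(d, memb, "zz"), "unknown")
  # cross-check against cluster::silhouette on a random instance
  dd <- with_seed(3, {
    x <- matrix(runif(100, 0.05, 1), 10, 10); x <- (x + t(x)) / 2
    diag(x) <- 0
    dimnames(x) <- list(letters[1:10], letters[1:10]); x
  })
  cl <- rep(1:3, length.out = 10)
  memb2 <- setNames(as.character(cl), letters[1:10])
  ref <- cluster::silhouette(cl, dmatrix = dd)
  mine <- silhouette_widths(dd, memb2)
  expect_equal(unname(mine), unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("core PCs require universal presence and deduplicate paralogs", {
  m <- matrix(1L, 2, 8, dimnames = list(c("a", "b"), sprintf("pc%d", 1:8)))
  cat_ <- fake_catalog(m)
  cs <- core_pcs(cat_, c("a", "b"))
  expect_length(cs$core_pcs, 8)
  # one genome missing one PC drops it from the core
  m2 <- m; m2["b", 8] <- 0L
  expect_length(core_pcs(fake_catalog(m2), c("a", "b"))$core_pcs, 7)
  # paralogs: keep the longest member only and count the dropped ones
  m3 <- matrix(c(2L, 1L), 2, 1, dimnames = list(c("a", "b"), "pcX"))
  cat3 <- fake_catalog(m3)
  cat3$proteins$seq[cat3$proteins$protein_id == "a|pcX.2"] <- strrep("A", 150)
  cs3 <- core_pcs(cat3, c("a", "b"))
  expect_equal(cs3$duplicates_dropped, 1)
  rep_a <- cs3$representatives$protein_id[cs3$representatives$genome_id == "a"]
  expect_equal(rep_a, "a|pcX.2")
  expect_error(core_pcs(cat_, "a"), "at least 2")
  expect_error(core_pcs(cat_, c("a", "zz")), "not present")
  # planted family: universal genes stay core, noise genes do not
  comm <- tiny_community()
  cat4 <- tiny_catalog()
  fam1 <- comm$truth$genome_id[comm$truth$family == "F01"]
  core <- core_pcs(cat4, fam1)
  n_genes_f1 <- sum(comm$genes$family == "F01")
  expect_gte(length(core$core_pcs), round(0.8 * n_genes_f1))
})

test_that("newick export carries leaves and supports", {
  cat_ <- tiny_catalog()
  d <- genome_distance_matrix(cat_)
  tree <- bootstrap_supports(cat_, hierarchical_tree(d),
                             n_replicates = 20, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tree, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, rownames(d))
  expect_true(any(nzchar(phy$node.label)))
})
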