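# shared fixtures, built once per test run

.fixtures <- new.env()

# small planted community: 2 families x 2 genera x 2 species x 1 strain,
# ~12 kb genomes; fast enough for unit tests
tiny_community <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- plant_taxonomy(community_spec(
      seed = 7L, n_families = 2L, genera_per_family = 2L,
      species_per_genus = 2L, strains_per_species = 1L,
      genome_length_range = c(12000L, 14000L)))
  }
  .fixtures$tiny
}

tiny_catalog <- function() {
  if (is.null(.fixtures$tiny_catalog)) {
    comm <- tiny_community()
    prot <- primary_proteome(call_orfs_all(comm$genomes, min_aa = 60L))
    .fixtures$tiny_catalog <- protein_clusters(all_vs_all_hits(prot))
  }
  .fixtures$tiny_catalog
}

# hand-built PC catalog from a presence/count matrix
fake_catalog <- function(m, lengths = NULL) {
  rows <- list()
  for (g in rownames(m)) for (pc in colnames(m)) {
    k <- m[g, pc]
    if (k > 0) for (t in seq_len(k))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = sprintf("%s|%s.%d", g, pc, t), genome_id = g,
        pc_id = pc, stringsAsFactors = FALSE)
  }
  asn <- do.call(rbind, rows)
  prot <- data.frame(protein_id = asn$protein_id, genome_id = asn$genome_id,
                     seq = strrep("A", if (is.null(lengths)) 100L else lengths),
                     stringsAsFactors = FALSE)
  structure(list(assignment = asn, matrix = m, proteins = prot),
            class = "pc_catalog")
}

# independent connected-components oracle (union-find)
components_oracle <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(edges)) for (r in seq_len(nrow(edges)))
    parent[[find(edges[r, 1])]] <- find(edges[r, 2])
  comp <- vapply(ids, find, "")
  reps <- vapply(split(ids, comp[ids]), min, "")
  setNames(unname(reps[comp[ids]]), ids)
}

# independent naive complete-linkage oracle (small n)
complete_linkage_oracle <- function(d) {
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, clades = merges)
}

# random symmetric similarity matrix (percent scale)
random_similarity <- function(n, seed) {
  with_seed(seed, {
    m <- matrix(runif(n * n, 0, 100), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 100
    dimnames(m) <- list(sprintf("g%02d", seq_len(n)),
                        sprintf("g%02d", seq_len(n)))
    m
  })
}

partition_sizes <- function(p) sort(table(p$membership), decreasing = TRUE)

# do two labelings induce the same partition?
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  all(outer(a, a, "==") == outer(b, b, "=="))
}
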