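PROTEIN_ALPHABET <- "ARNDCQEGHILKMFPSTWYVBJZX*"

# BLOSUM62 in the package's fixed alphabet order
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  ab <- strsplit(PROTEIN_ALPHABET, "")[[1]]
  m <- e$BLOSUM62[ab, ab]
  storage.mode(m) <- "integer"
  m
}

# ungapped Karlin-Altschul constants for BLOSUM62
KA_LAMBDA <- 0.3176
KA_K <- 0.134

sw_bitscore <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)
sw_evalue <- function(bits, m, n) m * n * 2^(-bits)

#' Call open reading frames on both strands
#'
#' Maximal ORFs under the standard genetic code with ATG/GTG/TTG starts:
#' within each stop-to-stop stretch of a frame, the ORF runs from the first
#' start codon to the stop. Coordinates are 0-based half-open on the forward
#' strand.
#'
#' @param genome single named character string.
#' @param min_aa minimum protein length in amino acids (stop excluded).
#' @return data.frame of class `protein_records`: `protein_id`, `genome_id`,
#'   `seq` (amino acids), `start`, `end`, `strand`, `length_aa`.
#' @export
call_orfs <- function(genome, min_aa = 30L) {
  assert_that(nchar(genome) > 0, "genome must be non-empty")
  gid <- if (is.null(names(genome))) "genome" else names(genome)
  L <- nchar(genome)
  code <- Biostrings::GENETIC_CODE
  starts <- c("ATG", "GTG", "TTG")
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") unname(genome) else revcomp(unname(genome))
    for (frame in 0:2) {
      n_cod <- (nchar(s) - frame) %/% 3L
      if (n_cod < min_aa + 1L) next
      pos <- frame + seq(1L, by = 3L, length.out = n_cod)
      codons <- substring(s, pos, pos + 2L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      # segment index between stops
      seg <- cumsum(c(TRUE, is_stop[-n_cod]))
      for (sg in split(seq_len(n_cod), seg)) {
        last <- sg[length(sg)]
        if (!is_stop[last]) next  # require a terminating stop codon
        body <- sg[-length(sg)]
        st <- body[codons[body] %in% starts]
        if (!length(st)) next
        first <- st[1]
        aa_len <- last - first
        if (aa_len < min_aa) next
        aa <- paste(code[codons[first:(last - 1L)]], collapse = "")
        # nucleotide span on the scanned strand, 0-based half-open
        nt0 <- pos[first] - 1L
        nt1 <- pos[last] + 2L
        if (strand == "-") { tmp <- nt0; nt0 <- L - nt1; nt1 <- L - tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = gid, seq = aa, start = nt0, end = nt1,
          strand = strand, length_aa = aa_len, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(0), seq = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               length_aa = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  out <- cbind(protein_id = sprintf("%s|orf%04d", gid, seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Call ORFs for every genome of a collection
#'
#' @param genomes named character vector.
#' @param min_aa minimum protein length.
#' @return combined `protein_records` data.frame.
#' @export
call_orfs_all <- function(genomes, min_aa = 30L) {
  out <- do.call(rbind, lapply(names(genomes), function(id)
    call_orfs(genomes[id], min_aa = min_aa)))
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Reduce called ORFs to a primary, mostly non-overlapping proteome
#'
#' A naive six-frame ORF scan over-calls heavily: gene-dense phage genomes
#' are full of spurious nested ORFs on the antisense strand of real genes.
#' Gene callers resolve this by selecting non-overlapping genes; this helper
#' does the same greedily (longest first, ties by coordinates), tolerating
#' small overlaps as real neighbouring genes do.
#'
#' @param records `protein_records` from [call_orfs()]/[call_orfs_all()].
#' @param max_overlap tolerated overlap in nt between kept ORFs (default 30).
#' @return filtered `protein_records`.
#' @export
primary_proteome <- function(records, max_overlap = 30L) {
  keep_rows <- logical(nrow(records))
  for (g in unique(records$genome_id)) {
    idx <- which(records$genome_id == g)
    r <- records[idx, , drop = FALSE]
    ord <- order(-r$length_aa, r$start, r$strand)
    kept <- integer(0)
    for (i in ord) {
      ov <- FALSE
      for (j in kept) {
        inter <- min(r$end[i], r$end[j]) - max(r$start[i], r$start[j])
        # conflict when the overlap is both sizeable and a large share of
        # the shorter ORF; start-codon extensions of a neighbour then do
        # not evict a genuine gene
        shorter <- min(r$end[i] - r$start[i], r$end[j] - r$start[j])
        if (inter > max(max_overlap, 0.5 * shorter)) { ov <- TRUE; break }
      }
      if (!ov) kept <- c(kept, i)
    }
    keep_rows[idx[kept]] <- TRUE
  }
  out <- records[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_records", "data.frame")
  out
}

#' All-vs-all protein similarity graph
#'
#' Smith-Waterman (BLOSUM62, gap open 11 / extend 1) over pairs passing a
#' shared k-mer prefilter; bitscores use ungapped Karlin-Altschul constants
#' and e-value = m x n x 2^-bits. An edge is retained only when it passes
#' e-value <= `max_evalue` and bitscore >= `min_bitscore` (the reciprocal
#' filter; internal scores are symmetric, so one test covers both
#' directions). Self-hits are excluded.
#'
#' @param proteins `protein_records` data.frame (needs `protein_id`,
#'   `genome_id`, `seq`).
#' @param max_evalue,min_bitscore retention filters.
#' @return object of class `hit_graph`: list with `edges` (data.frame p1/p2/
#'   score/bitscore/evalue) and `proteins`.
#' @export
all_vs_all_hits <- function(proteins, max_evalue = 1e-4, min_bitscore = 50) {
  assert_that(nrow(proteins) >= 1, "need at least one protein")
  min_raw <- floor((min_bitscore * log(2) + log(KA_K)) / KA_LAMBDA)
  hits <- cpp_protein_hits(proteins$seq, blosum62_matrix(), PROTEIN_ALPHABET,
                           gap_open = 11L, gap_ext = 1L, kmer = 4L,
                           min_shared = 2L, min_score = min_raw)
  if (nrow(hits)) {
    bits <- sw_bitscore(hits$score)
    ev <- sw_evalue(bits, nchar(proteins$seq[hits$i]),
                    nchar(proteins$seq[hits$j]))
    keep <- bits >= min_bitscore & ev <= max_evalue
    edges <- data.frame(p1 = proteins$protein_id[hits$i[keep]],
                        p2 = proteins$protein_id[hits$j[keep]],
                        score = hits$score[keep], bitscore = bits[keep],
                        evalue = ev[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(p1 = character(0), p2 = character(0),
                        score = numeric(0), bitscore = numeric(0),
                        evalue = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(edges = edges, proteins = proteins), class = "hit_graph")
}

#' Build a hit graph from precomputed directional hits
#'
#' Interop path for tabular protein searches: an undirected edge is kept iff
#' hits exist in both directions and each passes e-value <= `max_evalue` and
#' bitscore >= `min_bitscore`.
#'
#' @param hits data.frame with columns `qseqid`, `sseqid`, `evalue`,
#'   `bitscore` (best hit per directed pair is used).
#' @param proteins `protein_records`.
#' @param max_evalue,min_bitscore retention filters.
#' @return `hit_graph`.
#' @export
hit_graph_from_table <- function(hits, proteins, max_evalue = 1e-4,
                                 min_bitscore = 50) {
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  pass <- hits$evalue <= max_evalue & hits$bitscore >= min_bitscore
  hits <- hits[pass, , drop = FALSE]
  key <- paste(pmin(hits$qseqid, hits$sseqid),
               pmax(hits$qseqid, hits$sseqid), sep = "\r")
  dir1 <- hits$qseqid < hits$sseqid
  both <- intersect(unique(key[dir1]), unique(key[!dir1]))
  parts <- strsplit(both, "\r", fixed = TRUE)
  edges <- data.frame(
    p1 = vapply(parts, `[`, "", 1L), p2 = vapply(parts, `[`, "", 2L),
    score = NA_real_,
    bitscore = vapply(both, function(k) max(hits$bitscore[key == k]), 0),
    evalue = vapply(both, function(k) min(hits$evalue[key == k]), 0),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(edges = edges, proteins = proteins), class = "hit_graph")
}

#' Protein clusters (PCs) from a hit graph
#'
#' PCs are the connected components of the reciprocal-hit graph; isolated
#' proteins form singleton PCs. PC ids are deterministic: the
#' lexicographically smallest member protein id.
#'
#' @param graph a `hit_graph`.
#' @return object of class `pc_catalog`: list with `assignment` (data.frame
#'   protein_id/genome_id/pc_id), `matrix` (genome x PC member counts) and
#'   `proteins`.
#' @export
protein_clusters <- function(graph) {
  prot <- graph$proteins
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("p1", "p2"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = prot$protein_id))
  comp <- igraph::components(g)$membership
  reps <- vapply(split(names(comp), comp), min, "")
  pc_id <- unname(reps[as.character(comp[prot$protein_id])])
  assignment <- data.frame(protein_id = prot$protein_id,
                           genome_id = prot$genome_id,
                           pc_id = pc_id, stringsAsFactors = FALSE)
  counts <- table(assignment$genome_id, assignment$pc_id)
  m <- matrix(as.integer(counts), nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  structure(list(assignment = assignment, matrix = m, proteins = prot),
            class = "pc_catalog")
}

#' @export
print.pc_catalog <- function(x, ...) {
  cat(sprintf("pc_catalog: %d proteins in %d PCs across %d genomes\n",
              nrow(x$assignment), ncol(x$matrix), nrow(x$matrix)))
  invisible(x)
}

#' Protein-cluster content distance between two genomes
#'
#' Soerensen-Dice on PC presence/absence:
#' d = 1 - 2|PCs(a) n PCs(b)| / (|PCs(a)| + |PCs(b)|).
#'
#' @param catalog a `pc_catalog`.
#' @param a,b genome ids present in the catalog.
#' @return distance in [0, 1].
#' @export
genome_distance <- function(catalog, a, b) {
  m <- catalog$matrix > 0
  assert_that(all(c(a, b) %in% rownames(m)), "unknown genome id")
  na <- sum(m[a, ]); nb <- sum(m[b, ])
  if (na + nb == 0) return(if (a == b) 0 else 1)
  shared <- sum(m[a, ] & m[b, ])
  1 - 2 * shared / (na + nb)
}

#' Full pairwise PC-content distance matrix
#'
#' @param catalog a `pc_catalog`.
#' @return symmetric matrix of Dice distances with zero diagonal.
#' @export
genome_distance_matrix <- function(catalog) {
  p <- (catalog$matrix > 0) * 1
  sizes <- rowSums(p)
  inter <- tcrossprod(p)
  denom <- outer(sizes, sizes, "+")
  d <- 1 - 2 * inter / pmax(denom, 1)
  d[denom == 0] <- 1
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical tree of genomes
#'
#' @param distances square symmetric distance matrix with zero diagonal.
#' @param linkage agglomeration method (default "complete").
#' @return an [stats::hclust] tree (leaf labels = genome ids).
#' @export
hierarchical_tree <- function(distances, linkage = "complete") {
  assert_that(is.matrix(distances) && nrow(distances) == ncol(distances),
              "distances must be a square matrix")
  assert_that(max(abs(distances - t(distances))) <= 1e-9,
              "distance matrix must be symmetric (tolerance 1e-9)")
  hclust(as.dist(distances), method = linkage)
}

# leaf set of every internal node of an hclust tree
clade_leafsets <- function(tree) {
  n <- nrow(tree$merge)
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    kids <- tree$merge[i, ]
    leaves <- c()
    for (k in kids) {
      leaves <- c(leaves, if (k < 0) tree$labels[-k] else sets[[k]])
    }
    sets[[i]] <- sort(leaves)
  }
  sets
}

#' Bootstrap supports for a PC-content tree
#'
#' Resamples PC columns with replacement, rebuilds the Dice + complete
#' linkage tree per replicate, and scores each internal node of the
#' reference tree by the fraction of replicates containing its leaf set as a
#' clade.
#'
#' @param catalog a `pc_catalog`.
#' @param tree reference tree from [hierarchical_tree()]; rebuilt from the
#'   catalog when `NULL`.
#' @param n_replicates bootstrap replicates (>= 1; the conventional choice
#'   is 1000).
#' @param seed integer seed.
#' @return the tree with attribute `supports`: numeric vector in [0, 1], one
#'   per merge (internal node), in merge order.
#' @export
bootstrap_supports <- function(catalog, tree = NULL, n_replicates = 1000L,
                               seed = 1L) {
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  p <- (catalog$matrix > 0) * 1
  # canonical column order, so supports do not depend on how PC columns
  # happen to be arranged
  p <- p[, order(colnames(p)), drop = FALSE]
  assert_that(nrow(p) >= 3, "need at least 3 genomes")
  if (is.null(tree)) tree <- hierarchical_tree(dice_from_presence(p))
  ref_sets <- vapply(clade_leafsets(tree), paste, "", collapse = "\r")
  hits <- setNames(numeric(length(ref_sets)), ref_sets)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(ncol(p), replace = TRUE)
      pb <- (p[, cols, drop = FALSE] > 0) * 1
      tb <- hierarchical_tree(dice_from_presence(pb))
      sets <- unique(vapply(clade_leafsets(tb), paste, "", collapse = "\r"))
      found <- ref_sets %in% sets
      hits[found] <- hits[found] + 1
    }
  })
  attr(tree, "supports") <- unname(hits) / n_replicates
  tree
}

# Dice distances straight from a presence matrix
dice_from_presence <- function(p) {
  sizes <- rowSums(p)
  inter <- tcrossprod(p)
  denom <- outer(sizes, sizes, "+")
  d <- 1 - 2 * inter / pmax(denom, 1)
  d[denom == 0] <- 1
  diag(d) <- 0
  d
}

#' Cut a tree into viral genome clusters (VGCs)
#'
#' Strict cut: clusters are the leaves of maximal subtrees whose merge
#' height is < `height` (a merge at exactly the cut height separates).
#' Silhouette widths are computed from the distance matrix against the
#' resulting partition (singletons score 0 by convention).
#'
#' @param tree an [stats::hclust] tree.
#' @param height cut distance in (0, 1]; 0.9 is the family-level convention.
#' @param distances the distance matrix the tree was built from (needed for
#'   silhouettes; optional).
#' @return object of class `vgc_partition`: list with `membership` (named,
#'   VGC id = smallest member genome id), `cut_height`, `silhouette`.
#' @export
cut_tree <- function(tree, height = 0.9, distances = NULL) {
  assert_that(height > 0 && height <= 1, "height must be in (0, 1]")
  labels <- tree$labels
  n <- length(labels)
  # union-find over merges strictly below the cut
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  node_rep <- integer(nrow(tree$merge))  # representative leaf per merge node
  for (i in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[i, ]
    rep_of <- function(k) if (k < 0) -k else node_rep[k]
    r1 <- rep_of(kids[1]); r2 <- rep_of(kids[2])
    node_rep[i] <- r1
    if (tree$height[i] < height) parent[find(r2)] <- find(r1)
  }
  roots <- vapply(seq_len(n), find, 0L)
  reps <- vapply(split(labels, roots), min, "")
  membership <- setNames(unname(reps[as.character(roots)]), labels)
  sil <- if (!is.null(distances))
    silhouette_widths(distances, membership) else
      setNames(rep(NA_real_, n), labels)
  structure(list(membership = membership, cut_height = height,
                 silhouette = sil),
            class = "vgc_partition")
}

#' Silhouette width of one genome under a partition
#'
#' s = (b - a) / max(a, b) with a the mean within-cluster distance and b the
#' smallest mean distance to another cluster; members of singleton clusters
#' score 0 by convention.
#'
#' @param distances symmetric distance matrix.
#' @param membership named vector genome id -> cluster id (or a
#'   `vgc_partition`).
#' @param id genome id.
#' @return value in [-1, 1].
#' @export
silhouette_width <- function(distances, membership, id) {
  if (inherits(membership, "vgc_partition")) membership <- membership$membership
  assert_that(id %in% names(membership), "unknown genome id")
  own <- membership[[id]]
  mates <- setdiff(names(membership)[membership == own], id)
  if (!length(mates)) return(0)
  a <- mean(distances[id, mates])
  others <- setdiff(unique(membership), own)
  if (!length(others)) return(0)  # single-cluster partition
  b <- min(vapply(others, function(cl)
    mean(distances[id, names(membership)[membership == cl]]), 0))
  if (max(a, b) == 0) return(0)
  (b - a) / max(a, b)
}

#' Silhouette widths for every genome
#'
#' @inheritParams silhouette_width
#' @return named numeric vector.
#' @export
silhouette_widths <- function(distances, membership) {
  if (inherits(membership, "vgc_partition")) membership <- membership$membership
  setNames(vapply(names(membership), function(id)
    silhouette_width(distances, membership, id), 0), names(membership))
}

#' Core protein clusters of a genome set
#'
#' PCs present in every member genome. Within each core PC, a genome
#' contributing several proteins (paralogs) is represented by its longest
#' one only; the number of duplicates dropped is recorded.
#'
#' @param catalog a `pc_catalog`.
#' @param members genome ids (>= 2) forming the candidate family.
#' @return object of class `core_set`: list with `core_pcs` (character),
#'   `representatives` (data.frame pc_id/genome_id/protein_id/length_aa),
#'   `duplicates_dropped` (count).
#' @export
core_pcs <- function(catalog, members) {
  assert_that(length(members) >= 2, "need at least 2 member genomes")
  assert_that(all(members %in% rownames(catalog$matrix)),
              "member not present in catalog")
  m <- catalog$matrix[members, , drop = FALSE] > 0
  core <- colnames(m)[colSums(m) == length(members)]
  asn <- catalog$assignment
  prot <- catalog$proteins
  lens <- setNames(nchar(prot$seq), prot$protein_id)
  reps <- list(); dropped <- 0L
  for (pc in core) {
    sel <- asn[asn$pc_id == pc & asn$genome_id %in% members, , drop = FALSE]
    for (g in members) {
      cand <- sel[sel$genome_id == g, , drop = FALSE]
      dropped <- dropped + nrow(cand) - 1L
      best <- cand$protein_id[order(-lens[cand$protein_id],
                                    cand$protein_id)][1]
      reps[[length(reps) + 1L]] <- data.frame(
        pc_id = pc, genome_id = g, protein_id = best,
        length_aa = unname(lens[best]), stringsAsFactors = FALSE)
    }
  }
  structure(list(core_pcs = core,
                 representatives = if (length(reps)) do.call(rbind, reps) else
                   data.frame(pc_id = character(0), genome_id = character(0),
                              protein_id = character(0),
                              length_aa = integer(0)),
                 duplicates_dropped = dropped),
            class = "core_set")
}

#' Export a tree (with optional supports) as Newick
#'
#' @param tree an [stats::hclust] tree, optionally carrying a `supports`
#'   attribute from [bootstrap_supports()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  sup <- attr(tree, "supports")
  if (!is.null(sup)) {
    # ape internal node order: root = n+1 ... ; map via clade leaf sets
    sets <- vapply(clade_leafsets(tree), paste, "", collapse = "\r")
    phy$node.label <- rep("", phy$Nnode)
    for (k in seq_len(phy$Nnode)) {
      node <- length(phy$tip.label) + k
      tips <- sort(ape::extract.clade(phy, node)$tip.label)
      idx <- match(paste(tips, collapse = "\r"), sets)
      if (!is.na(idx)) phy$node.label[k] <- format(sup[idx], digits = 3)
    }
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}
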