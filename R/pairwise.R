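#' Align a genome pair into local similarity blocks
#'
#' Seeded local alignment: exact k-mer seeds on both strands are extended
#' ungapped with X-drop (match +1, mismatch -2) and trimmed to their
#' maximum-scoring extent. Indel-containing homology appears as adjacent
#' blocks on shifted diagonals; [intergenomic_similarity()] merges them by
#' interval union. For bit-compatible interop with precomputed searches,
#' blocks can instead be ingested with [read_blast_tab()].
#'
#' @param a,b single named character strings (names are the genome ids).
#' @param params list; `k` (seed length, default 13), `xdrop` (default 50),
#'   `min_len` (minimum block length, default 20).
#' @return data.frame of class `alignment_blocks` with columns `query_id`,
#'   `subject_id`, `qstart`, `qend`, `sstart`, `send` (0-based half-open),
#'   `strand`, `identical_positions`, `aligned_length`.
#' @export
align_pair <- function(a, b, params = list()) {
  assert_that(nchar(a) > 0 && nchar(b) > 0, "genomes must be non-empty")
  p <- modifyList(list(k = 13L, xdrop = 50L, min_len = 20L), params)
  df <- cpp_hsp_blocks(unname(a), unname(b), p$k, p$xdrop, p$min_len)
  df <- cbind(query_id = rep(if (is.null(names(a))) "a" else names(a),
                             nrow(df)),
              subject_id = rep(if (is.null(names(b))) "b" else names(b),
                               nrow(df)),
              df, stringsAsFactors = FALSE)
  class(df) <- c("alignment_blocks", "data.frame")
  df
}

# per-position match vector of an ungapped block (query orientation)
block_matches <- function(block, a, b) {
  qs <- substr(a, block$qstart + 1L, block$qend)
  ss <- substr(b, block$sstart + 1L, block$send)
  if (block$strand == "-") ss <- revcomp(ss)
  split_chars(qs) == split_chars(ss)
}

#' Intergenomic similarity of a genome pair from alignment blocks
#'
#' sim = 100 x (id_a + id_b) / (len_a + len_b), where id_x counts identical
#' positions on genome x over the union of aligned intervals. Overlaps are
#' resolved best-block-first (decreasing identical positions, ties by query
#' then subject start); for ungapped blocks with sequences available the
#' identical positions of truncated overlaps are recounted exactly,
#' otherwise they are prorated by the surviving interval fraction.
#'
#' @param blocks an `alignment_blocks` data.frame referencing `a` and `b`.
#' @param a,b single named character strings.
#' @param exact logical; recount truncated overlaps from the sequences when
#'   blocks are ungapped (set `FALSE` when sequences are placeholders).
#' @return numeric similarity percentage in [0, 100], with attribute
#'   `aligned_fraction` (named pair: covered fraction of each genome).
#' @export
intergenomic_similarity <- function(blocks, a, b, exact = TRUE) {
  ia <- if (is.null(names(a))) "a" else names(a)
  ib <- if (is.null(names(b))) "b" else names(b)
  la <- nchar(a); lb <- nchar(b)
  if (nrow(blocks) == 0) {
    return(structure(0, aligned_fraction = c(setNames(0, ia), setNames(0, ib))))
  }
  assert_that(all(blocks$query_id == ia & blocks$subject_id == ib),
              "blocks must reference the two supplied genomes")
  ord <- order(-blocks$identical_positions, blocks$qstart, blocks$sstart)
  blocks <- blocks[ord, , drop = FALSE]
  ungapped <- exact &&
    all(blocks$qend - blocks$qstart == blocks$send - blocks$sstart)
  cov_a <- logical(la); cov_b <- logical(lb)
  id_a <- 0; id_b <- 0
  for (r in seq_len(nrow(blocks))) {
    bl <- blocks[r, ]
    qpos <- (bl$qstart + 1L):bl$qend
    spos <- (bl$sstart + 1L):bl$send
    if (ungapped) {
      m <- block_matches(bl, unname(a), unname(b))
      new_q <- !cov_a[qpos]
      id_a <- id_a + sum(m[new_q])
      # subject positions corresponding to query offsets
      soff <- if (bl$strand == "-") rev(spos) else spos
      new_s <- !cov_b[soff]
      id_b <- id_b + sum(m[new_s])
    } else {
      new_q <- !cov_a[qpos]; new_s <- !cov_b[spos]
      id_a <- id_a + bl$identical_positions * sum(new_q) / length(qpos)
      id_b <- id_b + bl$identical_positions * sum(new_s) / length(spos)
    }
    cov_a[qpos] <- TRUE; cov_b[spos] <- TRUE
  }
  sim <- 100 * (id_a + id_b) / (la + lb)
  structure(min(100, sim),
            aligned_fraction = c(setNames(mean(cov_a), ia),
                                 setNames(mean(cov_b), ib)))
}

#' Pairwise intergenomic similarity matrix
#'
#' @param genomes named character vector (>= 2 genomes, unique ids).
#' @param params alignment settings passed to [align_pair()].
#' @return object of class `similarity_matrix`: symmetric percentage matrix
#'   with unit diagonal 100, attribute `aligned_fraction` (matrix: fraction
#'   of the row genome aligned in each pair).
#' @export
similarity_matrix <- function(genomes, params = list()) {
  assert_that(length(genomes) >= 2, "need at least 2 genomes")
  assert_that(!anyDuplicated(names(genomes)), "genome ids must be unique")
  ids <- names(genomes)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  af <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(m) <- 100; diag(af) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    blocks <- align_pair(genomes[i], genomes[j], params)
    s <- intergenomic_similarity(blocks, genomes[i], genomes[j])
    m[i, j] <- m[j, i] <- s
    fr <- attr(s, "aligned_fraction")
    af[i, j] <- fr[[1]]; af[j, i] <- fr[[2]]
  }
  structure(m, aligned_fraction = af, class = c("similarity_matrix", "matrix"))
}

#' Cluster genomes at a similarity threshold
#'
#' Single-linkage semantics: clusters are the connected components of the
#' graph with an edge wherever similarity >= threshold. At the 100% strain
#' threshold, equality is tested within a small tolerance `eps` to absorb
#' floating point.
#'
#' @param matrix a `similarity_matrix` (or plain symmetric percentage matrix).
#' @param threshold percentage in (0, 100].
#' @param level label for the partition (strain/species/genus/custom).
#' @param eps tolerance in percentage points applied when
#'   `threshold == 100` (default 0.01).
#' @return object of class `taxon_partition`: list with `level`, `threshold`
#'   and `membership` (named vector genome id -> cluster id; cluster ids are
#'   the lexicographically smallest member id).
#' @export
cluster_at_threshold <- function(matrix, threshold, level = "custom",
                                 eps = 0.01) {
  assert_that(threshold > 0 && threshold <= 100,
              "threshold must be in (0, 100]")
  m <- unclass(matrix)
  thr <- if (threshold >= 100) 100 - eps else threshold
  adj <- (m >= thr) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  ids <- rownames(m)
  reps <- vapply(split(ids, comp[ids]), function(x) min(x), "")
  membership <- setNames(reps[as.character(comp[ids])], ids)
  structure(list(level = level, threshold = threshold,
                 membership = membership),
            class = "taxon_partition")
}

#' @export
print.taxon_partition <- function(x, ...) {
  cat(sprintf("taxon_partition [%s @ %g%%]: %d genomes in %d clusters\n",
              x$level, x$threshold, length(x$membership),
              length(unique(x$membership))))
  invisible(x)
}

#' Does one partition refine another?
#'
#' @param fine,coarse `taxon_partition` objects over the same genomes.
#' @return logical; `TRUE` when every cluster of `fine` lies inside a single
#'   cluster of `coarse`.
#' @export
partition_refines <- function(fine, coarse) {
  f <- fine$membership; c0 <- coarse$membership[names(f)]
  all(vapply(split(c0, f), function(x) length(unique(x)) == 1L, TRUE))
}

#' Demarcate strains, species and genera from a similarity matrix
#'
#' Applies the conventional whole-genome demarcation tiers: strains at 100%
#' intergenomic similarity, species at 95%, genera at 70%.
#'
#' @param matrix a `similarity_matrix`.
#' @param thresholds named numeric vector with entries strain/species/genus.
#' @return named list of three `taxon_partition`s (strain, species, genus).
#' @export
demarcate_taxa <- function(matrix,
                           thresholds = c(strain = 100, species = 95,
                                          genus = 70)) {
  parts <- lapply(names(thresholds), function(lv)
    cluster_at_threshold(matrix, thresholds[[lv]], level = lv))
  names(parts) <- names(thresholds)
  stopifnot(partition_refines(parts$strain, parts$species),
            partition_refines(parts$species, parts$genus))
  parts
}

#' Read alignment blocks from 12-column BLAST tabular output
#'
#' Standard outfmt 6 columns (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore), 1-based inclusive coordinates,
#' minus strand encoded by sstart > send. Identical positions are
#' reconstructed as `round(pident/100 * length)`.
#'
#' @param path tabular file.
#' @return `alignment_blocks` data.frame (0-based half-open coordinates).
#' @export
read_blast_tab <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 12, "expected 12-column BLAST tabular input")
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  minus <- df$sstart > df$send
  s1 <- ifelse(minus, df$send, df$sstart)
  s2 <- ifelse(minus, df$sstart, df$send)
  out <- data.frame(
    query_id = df$qseqid, subject_id = df$sseqid,
    qstart = df$qstart - 1L, qend = df$qend,
    sstart = s1 - 1L, send = s2,
    strand = ifelse(minus, "-", "+"),
    identical_positions = as.integer(round(df$pident / 100 * df$length)),
    aligned_length = df$length, stringsAsFactors = FALSE)
  class(out) <- c("alignment_blocks", "data.frame")
  out
}

#' Write alignment blocks as 12-column BLAST tabular
#'
#' @param blocks `alignment_blocks` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(blocks, path) {
  minus <- blocks$strand == "-"
  df <- data.frame(
    qseqid = blocks$query_id, sseqid = blocks$subject_id,
    pident = round(100 * blocks$identical_positions / blocks$aligned_length, 3),
    length = blocks$aligned_length,
    mismatch = blocks$aligned_length - blocks$identical_positions,
    gapopen = 0L,
    qstart = blocks$qstart + 1L, qend = blocks$qend,
    sstart = ifelse(minus, blocks$send, blocks$sstart + 1L),
    send = ifelse(minus, blocks$sstart + 1L, blocks$send),
    evalue = 0, bitscore = 2 * blocks$identical_positions)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Build a similarity matrix from precomputed alignment blocks
#'
#' Interop path: all-vs-all blocks (e.g. ingested with [read_blast_tab()])
#' plus genome lengths yield the same similarity matrix as the internal
#' aligner would.
#'
#' @param blocks `alignment_blocks` covering genome pairs.
#' @param genomes named character vector of sequences, or named integer
#'   vector of genome lengths (proration is then used for overlaps).
#' @return `similarity_matrix`.
#' @export
similarity_from_blocks <- function(blocks, genomes) {
  ids <- names(genomes)
  seqs <- is.character(genomes)
  n <- length(ids)
  assert_that(n >= 2, "need at least 2 genomes")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sel <- (blocks$query_id == ids[i] & blocks$subject_id == ids[j])
    bl <- blocks[sel, , drop = FALSE]
    # also accept blocks recorded in the opposite orientation
    sel2 <- (blocks$query_id == ids[j] & blocks$subject_id == ids[i])
    if (any(sel2)) {
      sw <- blocks[sel2, , drop = FALSE]
      sw <- data.frame(query_id = sw$subject_id, subject_id = sw$query_id,
                       qstart = sw$sstart, qend = sw$send,
                       sstart = sw$qstart, send = sw$qend,
                       strand = sw$strand,
                       identical_positions = sw$identical_positions,
                       aligned_length = sw$aligned_length,
                       stringsAsFactors = FALSE)
      bl <- rbind(bl, sw)
    }
    class(bl) <- c("alignment_blocks", "data.frame")
    a <- if (seqs) genomes[i] else setNames(strrep("N", genomes[i]), ids[i])
    b <- if (seqs) genomes[j] else setNames(strrep("N", genomes[j]), ids[j])
    s <- intergenomic_similarity(bl, a, b, exact = seqs)
    m[i, j] <- m[j, i] <- s
  }
  structure(m, class = c("similarity_matrix", "matrix"))
}
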