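#' Specification of a synthetic phage community
#'
#' Describes a community with planted taxonomic structure at four tiers:
#' strains (identical genomes, the 100% similarity tier), species (pairwise
#' nucleotide identity within `species_ani_range`, demarcated at 95%), genera
#' (cross-species pairs within `genus_ani_range`, demarcated at 70%) and
#' families (disjoint gene content, recovered from protein-cluster profiles).
#'
#' @param seed integer seed; all downstream randomness derives from it.
#' @param n_families,genera_per_family,species_per_genus,strains_per_species
#'   counts (>= 1) at each tier.
#' @param genome_length_range bp pair; each family draws one ancestor length.
#' @param gc_content target GC fraction of intergenic backbone (flavophage
#'   genomes sit around 0.29-0.38).
#' @param species_ani_range fraction pair, >= 0.95. If the upper bound is 1
#'   (the default), strain-mates within a species are exact copies.
#' @param genus_ani_range fraction pair in (0.70, 0.95); planted pairwise
#'   identity of cross-species pairs within a genus.
#' @param indel_rate indel events per substitution, applied at the
#'   genus-divergence step (Poisson-thinned, geometric lengths capped at 10).
#' @param gene_length_range bp pair for planted genes (multiples of 3 are
#'   enforced internally).
#' @param coding_density fraction of the genome occupied by planted genes.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(seed = 1L,
                           n_families = 3L,
                           genera_per_family = 2L,
                           species_per_genus = 2L,
                           strains_per_species = 2L,
                           genome_length_range = c(35000L, 45000L),
                           gc_content = 0.35,
                           species_ani_range = c(0.96, 1.0),
                           genus_ani_range = c(0.78, 0.88),
                           indel_rate = 0.01,
                           gene_length_range = c(300L, 1200L),
                           coding_density = 0.9) {
  counts <- c(n_families, genera_per_family, species_per_genus,
              strains_per_species)
  assert_that(all(counts >= 1), "all tier counts must be >= 1")
  assert_that(all(species_ani_range >= 0 & species_ani_range <= 1) &&
                all(genus_ani_range >= 0 & genus_ani_range <= 1),
              "ANI ranges must lie in [0, 1]")
  assert_that(diff(species_ani_range) >= 0 && diff(genus_ani_range) >= 0,
              "ANI ranges must be ordered (low, high)")
  assert_that(species_ani_range[1] > genus_ani_range[2],
              "species ANI range must lie strictly above the genus range")
  assert_that(species_ani_range[1] >= 0.95,
              "species ANI range must be >= 0.95 (the species threshold)")
  assert_that(genus_ani_range[1] >= 0.70,
              "genus ANI range must be >= 0.70 (the genus threshold)")
  assert_that(indel_rate >= 0, "indel_rate must be >= 0")
  assert_that(gc_content > 0 && gc_content < 1, "gc_content must be in (0,1)")
  structure(list(
    seed = as.integer(seed), n_families = as.integer(n_families),
    genera_per_family = as.integer(genera_per_family),
    species_per_genus = as.integer(species_per_genus),
    strains_per_species = as.integer(strains_per_species),
    genome_length_range = as.integer(genome_length_range),
    gc_content = gc_content,
    species_ani_range = species_ani_range,
    genus_ani_range = genus_ani_range,
    indel_rate = indel_rate,
    gene_length_range = as.integer(gene_length_range),
    coding_density = coding_density
  ), class = "community_spec")
}

#' Generate a random ancestor genome
#'
#' Intergenic backbone only; genes are planted by [plant_taxonomy()].
#'
#' @param length genome length in bp (>= 1000).
#' @param gc target GC fraction in (0, 1).
#' @param seed integer seed.
#' @param id genome id.
#' @return single named character string (name = id).
#' @export
generate_ancestor <- function(length, gc, seed, id = "ancestor") {
  assert_that(is.numeric(length) && length >= 1000,
              "length must be a positive number >= 1000")
  assert_that(gc > 0 && gc < 1, "gc must be in (0, 1)")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- with_seed(seed, paste(
    sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = ""))
  setNames(seq, id)
}

# sample one non-stop codon with gc-weighted base composition
sample_codons <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- paste0(sample(DNA_BASES, need + 8, TRUE, probs),
                   sample(DNA_BASES, need + 8, TRUE, probs),
                   sample(DNA_BASES, need + 8, TRUE, probs))
    cand <- cand[!cand %in% c("TAA", "TAG", "TGA")]
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

# plant non-overlapping sense-strand ORFs (ATG ... stop) into a backbone.
# Returns list(seq, genes = data.frame(gene_id, start, end, length, seq))
# with 0-based half-open coordinates.
plant_genes <- function(seq, gene_length_range, coding_density, prefix) {
  L <- nchar(seq)
  chars <- split_chars(seq)
  mean_len <- mean(gene_length_range)
  # intergenic gaps sized so genes occupy ~coding_density of the genome
  gap_mean <- max(10, mean_len * (1 - coding_density) / coding_density)
  rows <- list()
  pos <- 0L  # 1-based end of the last placed gene
  i <- 0L
  repeat {
    gap <- ceiling(runif(1, 0.2, 1.8) * gap_mean)
    len_nt <- 3L * round(runif(1, gene_length_range[1],
                               gene_length_range[2]) / 3)
    start <- pos + gap + 1L  # 1-based start of this gene
    if (start + len_nt - 1L > L - 10L) break
    i <- i + 1L
    gene <- c("A", "T", "G",
              split_chars(paste(sample_codons(len_nt / 3L - 2L, 0.5),
                                collapse = "")),
              split_chars(sample(STOP_CODONS, 1L)))
    chars[start:(start + len_nt - 1L)] <- gene
    rows[[i]] <- data.frame(
      gene_id = sprintf("%s_g%03d", prefix, i),
      start = start - 1L, end = start - 1L + len_nt, length = len_nt,
      seq = paste(gene, collapse = ""), stringsAsFactors = FALSE)
    pos <- start + len_nt - 1L
  }
  list(seq = paste(chars, collapse = ""), genes = do.call(rbind, rows))
}

#' Derive a mutated descendant of a genome
#'
#' Substitutions are placed uniformly at random without replacement (outside
#' deleted intervals); indel events are Poisson-thinned at
#' `indel_rate x substitution count` with geometric lengths capped at 10 bp.
#' The full edit list is recorded so realized identity can be audited
#' position-wise with [planted_identity()].
#'
#' @param parent single (optionally named) character string.
#' @param target_identity fraction in (0, 1]; the planted ANI to the parent,
#'   counting every gap column as non-identical.
#' @param indel_rate indel events per substitution.
#' @param seed integer seed.
#' @param id child id.
#' @return named character string with attribute `edits`
#'   (list `subs`/`dels`/`ins`, 1-based parent coordinates).
#' @export
evolve_genome <- function(parent, target_identity, indel_rate = 0, seed = 1L,
                          id = "child") {
  assert_that(is.numeric(target_identity) && target_identity > 0 &&
                target_identity <= 1,
              "target_identity must be in (0, 1]")
  seq <- unname(parent)
  L <- nchar(seq)
  assert_that(L > 0, "parent sequence must be non-empty")
  res <- with_seed(seed, {
    n_sub0 <- round(L * (1 - target_identity))
    n_ev <- if (indel_rate > 0 && n_sub0 > 0) rpois(1, indel_rate * n_sub0) else 0L
    lens <- if (n_ev > 0) pmin(rgeom(n_ev, 0.5) + 1L, 10L) else integer(0)
    is_del <- if (n_ev > 0) rbinom(n_ev, 1, 0.5) == 1 else logical(0)
    chars <- split_chars(seq)
    deleted <- rep(FALSE, L)
    dels <- list()
    for (g in which(is_del)) {
      for (try in 1:50) {
        s <- sample.int(L - lens[g], 1L)
        if (!any(deleted[s:(s + lens[g] - 1L)])) {
          deleted[s:(s + lens[g] - 1L)] <- TRUE
          dels[[length(dels) + 1L]] <- data.frame(start = s, len = lens[g])
          break
        }
      }
    }
    dels <- if (length(dels)) do.call(rbind, dels) else
      data.frame(start = integer(0), len = integer(0))
    ins_lens <- lens[!is_del]
    ins <- data.frame(after = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
    if (length(ins_lens)) {
      ins <- data.frame(
        after = sample.int(L, length(ins_lens)),
        seq = vapply(ins_lens, function(l)
          paste(sample(DNA_BASES, l, TRUE), collapse = ""), ""),
        stringsAsFactors = FALSE)
    }
    D <- sum(dels$len); I <- sum(nchar(ins$seq))
    n_sub <- max(0L, round((1 - target_identity) * (L + I)) - D - I)
    avail <- which(!deleted)
    n_sub <- min(n_sub, length(avail))
    sub_pos <- if (n_sub > 0) sort(sample(avail, n_sub)) else integer(0)
    subs <- data.frame(pos = sub_pos,
                       from = chars[sub_pos],
                       to = vapply(chars[sub_pos], function(b)
                         sample(setdiff(DNA_BASES, b), 1L), ""),
                       stringsAsFactors = FALSE)
    chars[sub_pos] <- subs$to
    # assemble child: substitute, delete, insert (parent coordinates)
    pieces <- character(L)
    pieces[!deleted] <- chars[!deleted]
    pieces[deleted] <- ""
    if (nrow(ins)) {
      for (r in seq_len(nrow(ins)))
        pieces[ins$after[r]] <- paste0(pieces[ins$after[r]], ins$seq[r])
    }
    list(child = paste(pieces, collapse = ""),
         edits = list(subs = subs, dels = dels, ins = ins, parent_len = L))
  })
  structure(setNames(res$child, id), edits = res$edits)
}

#' Position-wise identity implied by a recorded edit list
#'
#' The oracle for the generator: identity = identical alignment columns /
#' total columns, where gap columns (every inserted or deleted position)
#' count as non-identical.
#'
#' @param edits the `edits` attribute of [evolve_genome()] output.
#' @return fraction in [0, 1].
#' @export
planted_identity <- function(edits) {
  L <- edits$parent_len
  S <- nrow(edits$subs)
  D <- sum(edits$dels$len)
  I <- sum(nchar(edits$ins$seq))
  (L - S - D) / (L + I)
}

# substitute a fraction of positions drawn from `allowed`, returning the
# mutated char vector and the positions used (disjoint planting helper)
mutate_at <- function(chars, positions) {
  chars[positions] <- vapply(chars[positions], function(b)
    sample(setdiff(DNA_BASES, b), 1L), "")
  chars
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# per-position gene bookkeeping for frame-aware mutation: which gene covers
# each position (0 = intergenic), the codon start of in-gene positions, and
# whether the position belongs to a protected start/stop codon.
gene_index <- function(L, genes) {
  in_gene <- integer(L); codon_start <- integer(L); protected <- logical(L)
  if (!is.null(genes) && nrow(genes)) {
    for (r in seq_len(nrow(genes))) {
      s <- genes$start[r] + 1L; e <- genes$end[r]  # 1-based inclusive span
      pos <- s:e
      in_gene[pos] <- r
      codon_start[pos] <- s + 3L * ((pos - s) %/% 3L)
      protected[c(s:(s + 2L), (e - 2L):e)] <- TRUE
    }
  }
  list(in_gene = in_gene, codon_start = codon_start, protected = protected)
}

# substitute positions while emulating purifying selection on reading
# frames: inside genes the replacement base may not create an in-frame stop
# codon. Every substitution still changes the base, so planted divergence
# counts stay exact.
mutate_safe <- function(chars, positions, gi) {
  coding <- positions[gi$in_gene[positions] > 0L]
  inter <- setdiff(positions, coding)
  if (length(inter)) chars <- mutate_at(chars, inter)
  for (p in coding) {
    alts <- setdiff(DNA_BASES, chars[p])
    cs <- gi$codon_start[p]
    cod <- chars[cs:(cs + 2L)]
    off <- p - cs + 1L
    ok <- vapply(alts, function(b) {
      cod[off] <- b
      !(paste(cod, collapse = "") %in% STOP_CODONS)
    }, TRUE)
    alts <- alts[ok]
    chars[p] <- if (length(alts) == 1L) alts else sample(alts, 1L)
  }
  chars
}

# substitution-site pool emulating purifying selection: synonymous-leaning
# third codon positions and intergenic sites are consumed before first/second
# codon positions, so nucleotide divergence accrues faster than amino-acid
# divergence (dN/dS < 1), as in real coding sequences.
weighted_site_pool <- function(gi) {
  avail <- which(!gi$protected)
  in_g <- gi$in_gene[avail] > 0L
  third <- avail[in_g & (avail - gi$codon_start[avail]) == 2L]
  inter <- avail[!in_g]
  rest <- setdiff(avail, c(third, inter))
  c(sample(c(third, inter)), sample(rest))
}

# indels confined to intergenic space (frameshifts are lethal in this
# emulation); gene coordinates are shifted accordingly. `genes` carries
# 0-based half-open start/end columns.
apply_intergenic_indels <- function(seq, genes, n_ev) {
  ch <- split_chars(seq)
  for (e in seq_len(n_ev)) {
    gi <- gene_index(length(ch), genes)
    l <- min(rgeom(1, 0.5) + 1L, 10L)
    is_del <- runif(1) < 0.5
    placed <- FALSE
    for (try in 1:100) {
      p <- sample.int(length(ch) - l, 1L)
      span <- if (is_del) p:(p + l - 1L) else p
      if (all(gi$in_gene[span] == 0L)) { placed <- TRUE; break }
    }
    if (!placed) next
    if (is_del) {
      ch <- ch[-(p:(p + l - 1L))]
      shift <- genes$start >= p  # 0-based start >= 1-based p means after
      genes$start[shift] <- genes$start[shift] - l
      genes$end[shift] <- genes$end[shift] - l
    } else {
      ch <- append(ch, sample(DNA_BASES, l, TRUE), after = p)
      shift <- genes$start >= p
      genes$start[shift] <- genes$start[shift] + l
      genes$end[shift] <- genes$end[shift] + l
    }
  }
  list(seq = paste(ch, collapse = ""), genes = genes)
}

#' Generate a phage community with planted taxonomy
#'
#' Families descend from independent random ancestors carrying disjoint
#' planted gene sets; genera diverge from the family ancestor by disjoint
#' substitution sets (plus indels at `indel_rate`) so cross-genus identity
#' falls below the 70% genus threshold; species within a genus receive
#' disjoint substitution sets sized so every cross-species pair realizes the
#' genus-range identity exactly; strain-mates are exact copies when
#' `species_ani_range` reaches 1.
#'
#' @param spec a [community_spec()].
#' @return object of class `phage_community`: list with `genomes` (named
#'   character vector), `truth` (data.frame genome_id/strain/species/genus/
#'   family), `genes` (per-family planted gene table, 0-based half-open),
#'   `planted_ani` (pairwise matrix, NA where unconstrained) and `spec`.
#' @export
plant_taxonomy <- function(spec) {
  assert_that(inherits(spec, "community_spec"), "spec must be a community_spec")
  # disjoint substitution sets must fit inside the genome
  assert_that(spec$genera_per_family * 0.18 <= 0.95,
              "infeasible: too many genera per family for disjoint divergence")
  assert_that(spec$species_per_genus * (1 - spec$genus_ani_range[1]) / 2 <= 0.95,
              "infeasible: species count incompatible with genus ANI range")
  genomes <- character(0)
  truth <- list()
  genes <- list()
  # per-genome divergence from its genus ancestor (species tier planting)
  sp_div <- list()
  with_seed(spec$seed, {
    for (f in seq_len(spec$n_families)) {
      fam <- sprintf("F%02d", f)
      L <- round(runif(1, spec$genome_length_range[1],
                       spec$genome_length_range[2]))
      backbone <- generate_ancestor(L, spec$gc_content,
                                    seed = derive_seed(spec$seed, f), id = fam)
      pg <- plant_genes(unname(backbone), spec$gene_length_range,
                        spec$coding_density, prefix = fam)
      genes[[fam]] <- cbind(family = fam, pg$genes)
      fam_anc <- pg$seq
      gi_f <- gene_index(nchar(fam_anc), pg$genes)
      # genus divergence: disjoint substitution sets, each ~18% of genome,
      # so cross-genus pairs sit near 64% identity, below the 70% threshold
      d_genus <- 0.18
      pos_pool <- weighted_site_pool(gi_f)
      used <- 0L
      for (g in seq_len(spec$genera_per_family)) {
        gen <- sprintf("%s_G%02d", fam, g)
        n_mut <- round(d_genus * nchar(fam_anc))
        gen_genes <- pg$genes
        if (spec$genera_per_family > 1) {
          take <- pos_pool[(used + 1L):(used + n_mut)]
          used <- used + n_mut
          chars <- mutate_safe(split_chars(fam_anc), take, gi_f)
          gen_anc <- paste(chars, collapse = "")
        } else gen_anc <- fam_anc
        if (spec$indel_rate > 0) {
          # indel events proportional to the genus-level substitution load
          n_ev <- rpois(1, spec$indel_rate * d_genus * nchar(gen_anc))
          if (n_ev > 0) {
            res <- apply_intergenic_indels(gen_anc, gen_genes, n_ev)
            gen_anc <- res$seq
            gen_genes <- res$genes
          }
        }
        gi_g <- gene_index(nchar(gen_anc), gen_genes)
        # species tier: disjoint substitution sets realizing the genus-range
        # pairwise identity exactly between every cross-species pair
        t_pair <- runif(1, spec$genus_ani_range[1], spec$genus_ani_range[2])
        d_sp <- (1 - t_pair) / 2
        Lg <- nchar(gen_anc)
        sp_pool <- weighted_site_pool(gi_g)
        sp_used <- 0L
        for (s in seq_len(spec$species_per_genus)) {
          sp <- sprintf("%s_S%02d", gen, s)
          if (spec$species_per_genus > 1) {
            n_mut <- round(d_sp * Lg)
            take <- sp_pool[(sp_used + 1L):(sp_used + n_mut)]
            sp_used <- sp_used + n_mut
            sp_seq <- paste(mutate_safe(split_chars(gen_anc), take, gi_g),
                            collapse = "")
            this_div <- d_sp
          } else { sp_seq <- gen_anc; this_div <- 0 }
          identical_strains <- spec$species_ani_range[2] >= 1 - 1e-12
          if (!identical_strains) {
            t_str <- mean(spec$species_ani_range)
            d_str <- (1 - t_str) / 2
          }
          str_pool <- setdiff(weighted_site_pool(gi_g), sp_pool[seq_len(sp_used)])
          str_used <- 0L
          for (k in seq_len(spec$strains_per_species)) {
            gid <- sprintf("%s_T%02d", sp, k)
            if (identical_strains || spec$strains_per_species == 1) {
              gseq <- sp_seq
              strain_lab <- sp
              str_div <- 0
            } else {
              n_mut <- round(d_str * nchar(sp_seq))
              take <- str_pool[(str_used + 1L):(str_used + n_mut)]
              str_used <- str_used + n_mut
              gseq <- paste(mutate_safe(split_chars(sp_seq), take, gi_g),
                            collapse = "")
              strain_lab <- gid
              str_div <- d_str
            }
            genomes[gid] <- gseq
            truth[[gid]] <- data.frame(
              genome_id = gid, strain = strain_lab, species = sp,
              genus = gen, family = fam, stringsAsFactors = FALSE)
            sp_div[[gid]] <- c(species_div = this_div, strain_div = str_div)
          }
        }
      }
    }
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  ids <- truth$genome_id
  n <- length(ids)
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(ani) <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ti <- truth[i, ]; tj <- truth[j, ]
    if (ti$strain == tj$strain) ani[i, j] <- 1 - 2 * sp_div[[ids[i]]]["strain_div"]
    else if (ti$species == tj$species)
      ani[i, j] <- 1 - sp_div[[ids[i]]]["strain_div"] - sp_div[[ids[j]]]["strain_div"]
    else if (ti$genus == tj$genus)
      ani[i, j] <- 1 - sp_div[[ids[i]]]["species_div"] - sp_div[[ids[j]]]["species_div"] -
        sp_div[[ids[i]]]["strain_div"] - sp_div[[ids[j]]]["strain_div"]
  }
  structure(list(genomes = genomes, truth = truth,
                 genes = do.call(rbind, unname(genes)),
                 planted_ani = ani, spec = spec),
            class = "phage_community")
}

#' @export
print.phage_community <- function(x, ...) {
  cat(sprintf(
    "phage_community: %d genomes (%d families / %d genera / %d species)\n",
    length(x$genomes), length(unique(x$truth$family)),
    length(unique(x$truth$genus)), length(unique(x$truth$species))))
  invisible(x)
}

#' Simulate shotgun reads from a set of genomes
#'
#' Read origins are drawn with probability proportional to
#' `weight x genome length`; every read carries exactly
#' `round(read_length x per_base_divergence)` substitutions at random
#' positions, so realized identity is uniformly `1 - per_base_divergence`;
#' reads take the reverse-complement strand with probability 0.5. Origin
#' intervals and true edit distances are recorded.
#'
#' @param genomes named character vector of genome sequences.
#' @param abundances named non-negative weights (missing names get weight 0).
#' @param read_length bp, must not exceed the shortest genome.
#' @param per_base_divergence substitution probability per base.
#' @param total_bases target total sequenced bases.
#' @param seed integer seed.
#' @return object of class `read_set`: list with `reads` (data.frame
#'   read_id/origin/start/end/strand/n_sub/seq, 0-based half-open intervals)
#'   and `library_size_gb`.
#' @export
simulate_reads <- function(genomes, abundances, read_length,
                           per_base_divergence = 0, total_bases, seed = 1L) {
  assert_that(length(genomes) > 0, "genome collection must be non-empty")
  assert_that(read_length <= min(nchar(genomes)),
              "read_length must not exceed the shortest genome")
  w <- setNames(rep(0, length(genomes)), names(genomes))
  w[names(abundances)] <- abundances
  assert_that(all(w >= 0) && sum(w) > 0,
              "abundance weights must be >= 0 with positive sum")
  prob <- w * nchar(genomes)
  n_reads <- max(1L, round(total_bases / read_length))
  reads <- with_seed(seed, {
    origin <- sample(names(genomes), n_reads, TRUE, prob = prob)
    glen <- nchar(genomes)[origin]
    start <- floor(runif(n_reads) * (glen - read_length))  # 0-based
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
    seqs <- substr(genomes[origin], start + 1L, start + read_length)
    n_sub <- integer(n_reads)
    if (per_base_divergence > 0) {
      # uniform divergence: every read carries the same substitution load,
      # so read identity is exactly 1 - divergence (no per-read dispersion)
      n_sub <- rep(as.integer(round(read_length * per_base_divergence)),
                   n_reads)
      mut_one <- function(s, k) {
        if (k == 0) return(s)
        ch <- split_chars(s)
        pos <- sample.int(length(ch), k)
        ch <- mutate_at(ch, pos)
        paste(ch, collapse = "")
      }
      seqs <- mapply(mut_one, seqs, n_sub, USE.NAMES = FALSE)
    }
    flip <- strand == "-"
    if (any(flip)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[flip])))
      seqs[flip] <- rc
    }
    data.frame(read_id = sprintf("r%06d", seq_len(n_reads)),
               origin = origin, start = as.integer(start),
               end = as.integer(start + read_length), strand = strand,
               n_sub = n_sub, seq = unname(seqs), stringsAsFactors = FALSE)
  })
  structure(list(reads = reads,
                 library_size_gb = sum(nchar(reads$seq)) / 1e9),
            class = "read_set")
}

#' Plant CRISPR spacers sampled from a phage genome
#'
#' Each spacer is an interval of the phage genome, optionally carrying a
#' planned number of substitutions and one internal gap (a deletion of
#' `gap_len` bases relative to the genome), and takes the reverse-complement
#' orientation with probability 0.5.
#'
#' @param phage single (optionally named) character string.
#' @param n number of spacers (> 0).
#' @param lengths bp pair within [20, 60].
#' @param edits data.frame with columns `n_sub` and `gap_len`, recycled to
#'   `n` rows; defaults to exact spacers.
#' @param seed integer seed.
#' @return object of class `crispr_truth`: data.frame spacer_id/source/start/
#'   end/strand/n_sub/gap_len/seq (0-based half-open genome coordinates).
#' @export
plant_spacers <- function(phage, n, lengths = c(25L, 45L),
                          edits = data.frame(n_sub = 0L, gap_len = 0L),
                          seed = 1L) {
  assert_that(n > 0, "n must be > 0")
  assert_that(lengths[1] >= 20 && lengths[2] <= 60,
              "spacer lengths must lie within [20, 60]")
  seq <- unname(phage)
  src <- if (!is.null(names(phage))) names(phage) else "phage"
  L <- nchar(seq)
  idx <- rep(seq_len(nrow(edits)), length.out = n)
  plan <- edits[idx, , drop = FALSE]
  out <- with_seed(seed, {
    len <- round(runif(n, lengths[1], lengths[2]))
    start <- vapply(len, function(l) sample.int(L - l, 1L) - 1L, 0L)  # 0-based
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    sp <- character(n)
    for (i in seq_len(n)) {
      s <- split_chars(substr(seq, start[i] + 1L, start[i] + len[i]))
      if (plan$gap_len[i] > 0) {
        g <- plan$gap_len[i]
        # keep >= 10 bp (word-length) flanks so the planted gap, not an
        # end-trimmed substitution alignment, is the optimal interpretation
        if (len[i] < g + 21L) len[i] <- g + 21L
        start[i] <- sample.int(L - len[i], 1L) - 1L
        s <- split_chars(substr(seq, start[i] + 1L, start[i] + len[i]))
        p <- sample(seq(11L, length(s) - g - 10L), 1L)
        s <- s[-(p:(p + g - 1L))]
      }
      if (plan$n_sub[i] > 0) {
        pos <- sample(seq(3L, length(s) - 2L), plan$n_sub[i])
        s <- mutate_at(s, pos)
      }
      x <- paste(s, collapse = "")
      if (strand[i] == "-") x <- revcomp(x)
      sp[i] <- x
    }
    data.frame(spacer_id = sprintf("%s_sp%03d", src, seq_len(n)),
               source = src, start = start, end = start + len,
               strand = strand, n_sub = plan$n_sub, gap_len = plan$gap_len,
               seq = sp, stringsAsFactors = FALSE)
  })
  structure(out, class = c("crispr_truth", "data.frame"))
}

#' Write simulated reads as FASTA or FASTQ
#'
#' FASTQ output carries a uniform quality character (the generator plants
#' substitutions, not quality-correlated errors).
#'
#' @param readset a [simulate_reads()] result.
#' @param path output file.
#' @param format "fasta" or "fastq".
#' @param quality single quality character for FASTQ (default "I", Q40).
#' @return `path`, invisibly.
#' @export
write_reads <- function(readset, path, format = c("fasta", "fastq"),
                        quality = "I") {
  format <- match.arg(format)
  r <- readset$reads
  if (format == "fasta") {
    write_fasta(setNames(r$seq, r$read_id), path)
  } else {
    lines <- as.vector(rbind(paste0("@", r$read_id), r$seq, "+",
                             strrep(quality, nchar(r$seq))))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a synthetic community to disk
#'
#' Emits `genomes.fasta`, `truth.tsv`, `genes.tsv`, `spec.json` and a
#' `manifest.json` with md5 checksums.
#'
#' @param community a [plant_taxonomy()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_community <- function(community, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genomes = file.path(dir, "genomes.fasta"),
    truth = file.path(dir, "truth.tsv"),
    genes = file.path(dir, "genes.tsv"),
    spec = file.path(dir, "spec.json"))
  write_fasta(community$genomes, paths[["genomes"]])
  write_tsv(community$truth, paths[["truth"]])
  write_tsv(community$genes, paths[["genes"]])
  jsonlite::write_json(unclass(community$spec), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(files = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}
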