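#' Run configuration for the analysis pipeline
#'
#' Bundles inputs, thresholds and a seed. Thresholds default to the
#' demarcation and detection conventions used throughout the package
#' (strain 100 / species 95 / genus 70, VGC cut 0.9, the three presence
#' rules, spacer constraints with the <=1-mismatch assignment cap); every
#' non-default value is echoed to the log.
#'
#' @param out output directory.
#' @param seed integer seed.
#' @param strain,species,genus similarity thresholds (percent).
#' @param vgc_cut tree-cut distance.
#' @param bootstrap_replicates replicates for tree supports.
#' @param spacer_max_mismatch assignment cap.
#' @param min_orf_aa minimum ORF length for internal proteomes.
#' @param ... further fields (input paths etc.) stored verbatim.
#' @return object of class `run_config`.
#' @export
run_config <- function(out = "results", seed = 1L,
                       strain = 100, species = 95, genus = 70,
                       vgc_cut = 0.9, bootstrap_replicates = 200L,
                       spacer_max_mismatch = 1L, min_orf_aa = 60L, ...) {
  cfg <- list(out = out, seed = as.integer(seed), strain = strain,
              species = species, genus = genus, vgc_cut = vgc_cut,
              bootstrap_replicates = as.integer(bootstrap_replicates),
              spacer_max_mismatch = as.integer(spacer_max_mismatch),
              min_orf_aa = as.integer(min_orf_aa), ...)
  defaults <- list(strain = 100, species = 95, genus = 70, vgc_cut = 0.9,
                   spacer_max_mismatch = 1L)
  cfg$non_default <- names(defaults)[vapply(names(defaults), function(k)
    !isTRUE(all.equal(cfg[[k]], defaults[[k]])), TRUE)]
  class(cfg) <- "run_config"
  cfg
}

log_msg <- function(...) message("[flavoscope] ", sprintf(...))

echo_config <- function(cfg) {
  for (k in c("strain", "species", "genus", "vgc_cut",
              "spacer_max_mismatch"))
    log_msg("threshold %s = %s%s", k, format(cfg[[k]]),
            if (k %in% cfg$non_default) "  [non-default]" else "")
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) { dir.create(d, recursive = TRUE); log_msg("created %s", d) }
  d
}

#' Simulate a community and write its files
#'
#' @param cfg a [run_config()]; honors `cfg$community_spec` (a
#'   [community_spec()]) if present, else builds one from `cfg$seed`.
#' @return written paths (see [write_community()]), invisibly.
#' @export
run_simulate <- function(cfg = run_config()) {
  ensure_dir(cfg$out)
  spec <- if (!is.null(cfg$community_spec)) cfg$community_spec else
    community_spec(seed = cfg$seed)
  comm <- plant_taxonomy(spec)
  paths <- write_community(comm, file.path(cfg$out, "community"))
  log_msg("simulated %d genomes", length(comm$genomes))
  invisible(paths)
}

#' Taxonomy stage: similarity matrix, demarcation, PC tree, VGCs
#'
#' @param genomes named character vector (or `cfg$genomes_fasta` path).
#' @param cfg a [run_config()].
#' @return list with `similarity`, `partitions`, `catalog`, `tree`,
#'   `vgc`, and written file paths.
#' @export
run_taxa <- function(genomes = NULL, cfg = run_config()) {
  echo_config(cfg)
  ensure_dir(cfg$out)
  if (is.null(genomes)) genomes <- read_genomes_fasta(cfg$genomes_fasta)
  assert_that(length(genomes) >= 2, "need at least 2 genomes")
  sim <- similarity_matrix(genomes)
  parts <- demarcate_taxa(sim, thresholds = c(strain = cfg$strain,
                                              species = cfg$species,
                                              genus = cfg$genus))
  log_msg("partition refinement verified (strain < species < genus)")
  prot <- primary_proteome(call_orfs_all(genomes, min_aa = cfg$min_orf_aa))
  catalog <- protein_clusters(all_vs_all_hits(prot))
  d <- genome_distance_matrix(catalog)
  tree <- hierarchical_tree(d)
  if (nrow(d) >= 3)  # supports need at least 3 leaves
    tree <- bootstrap_supports(catalog, tree,
                               n_replicates = cfg$bootstrap_replicates,
                               seed = cfg$seed)
  vgc <- cut_tree(tree, height = cfg$vgc_cut, distances = d)
  sim_df <- as.data.frame(unclass(sim))
  paths <- c(similarity = file.path(cfg$out, "similarity_matrix.tsv"),
             taxa = file.path(cfg$out, "taxon_partitions.tsv"),
             tree = file.path(cfg$out, "pc_tree.nwk"),
             vgc = file.path(cfg$out, "vgc_table.tsv"))
  write_tsv(cbind(genome_id = rownames(sim_df), sim_df), paths[["similarity"]])
  taxa_df <- data.frame(genome_id = names(genomes),
                        strain = parts$strain$membership[names(genomes)],
                        species = parts$species$membership[names(genomes)],
                        genus = parts$genus$membership[names(genomes)],
                        vgc = vgc$membership[names(genomes)],
                        silhouette = vgc$silhouette[names(genomes)],
                        stringsAsFactors = FALSE)
  write_tsv(taxa_df, paths[["taxa"]])
  write_tree_newick(tree, paths[["tree"]])
  write_tsv(data.frame(genome_id = names(vgc$membership),
                       vgc = vgc$membership,
                       silhouette = vgc$silhouette), paths[["vgc"]])
  list(similarity = sim, partitions = parts, catalog = catalog,
       tree = tree, vgc = vgc, taxa_table = taxa_df, paths = paths)
}

#' Detection stage: presence, abundance and phage/host ratio tables
#'
#' @param alignments `read_alignments` (or set `cfg$sam` / `cfg$paf`).
#' @param genomes named character vector of sequences or named lengths.
#' @param library_gb library size in gigabases.
#' @param pairs optional data.frame `phage_id`/`host_id` for ratio rows.
#' @param cfg a [run_config()].
#' @return list with `detection` (per-genome x rule table) and `ratios`.
#' @export
run_detect <- function(alignments = NULL, genomes, library_gb, pairs = NULL,
                       cfg = run_config()) {
  ensure_dir(cfg$out)
  if (is.null(alignments)) {
    if (!is.null(cfg$sam)) alignments <- read_alignments_sam(cfg$sam)
    else if (!is.null(cfg$paf)) alignments <- read_alignments_paf(cfg$paf)
    else stop("no alignments supplied (need alignments, cfg$sam or cfg$paf)",
              call. = FALSE)
  }
  det <- detect_genomes(alignments, genomes, library_gb)
  ratios <- NULL
  if (!is.null(pairs)) {
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      ph <- det[det$genome_id == pairs$phage_id[i] & det$kind == "phage", ]
      ho <- det[det$genome_id == pairs$host_id[i] & det$kind == "bacterium", ]
      r <- phage_host_ratio(ph$abundance, ho$abundance)
      data.frame(phage_id = pairs$phage_id[i], host_id = pairs$host_id[i],
                 phage_abundance = ph$abundance, host_abundance = ho$abundance,
                 ratio = as.numeric(r),
                 ratio_printed = format_ratio(r),
                 undefined = isTRUE(attr(r, "undefined")),
                 stringsAsFactors = FALSE)
    })
    ratios <- do.call(rbind, rows)
    write_tsv(ratios, file.path(cfg$out, "phage_host_ratios.tsv"))
  }
  write_tsv(det, file.path(cfg$out, "detection.tsv"))
  list(detection = det, ratios = ratios)
}

#' Spacer stage: match and assignment tables
#'
#' @param spacers data.frame `spacer_id`/`host_id`/`seq` (or
#'   `cfg$spacers_fasta`).
#' @param phages named character vector.
#' @param cfg a [run_config()].
#' @return the [assign_phage_to_host()] result (matches + assignments).
#' @export
run_spacers <- function(spacers = NULL, phages, cfg = run_config()) {
  ensure_dir(cfg$out)
  if (is.null(spacers)) spacers <- read_spacers_fasta(cfg$spacers_fasta)
  if (!nrow(spacers)) {
    warning("empty spacer input; writing empty tables")
    res <- list(matches = data.frame(), assignments = data.frame())
  } else {
    res <- assign_phage_to_host(spacers, phages,
                                max_mismatch = cfg$spacer_max_mismatch)
  }
  write_tsv(export_spacer_matches(res$matches),
            file.path(cfg$out, "spacer_matches.tsv"))
  write_tsv(res$assignments, file.path(cfg$out, "spacer_assignments.tsv"))
  res
}

# 1-based inclusive coordinates for genome-browser interop
export_spacer_matches <- function(matches) {
  if (!nrow(matches)) return(matches)
  out <- matches
  out$start <- out$start + 1L
  out
}

#' Joined per-genome report
#'
#' One row per input genome with taxonomy (strain/species/genus/VGC +
#' silhouette), joined with any detection verdicts and spacer-based host
#' assignments.
#'
#' @param taxa result of [run_taxa()].
#' @param detect optional result of [run_detect()].
#' @param spacers optional result of [run_spacers()].
#' @param cfg a [run_config()].
#' @return data.frame, one row per genome.
#' @export
run_report <- function(taxa, detect = NULL, spacers = NULL,
                       cfg = run_config()) {
  rep <- taxa$taxa_table
  if (!is.null(detect)) {
    ph <- detect$detection[detect$detection$kind == "phage", ]
    rep$phage_present <- ph$present[match(rep$genome_id, ph$genome_id)]
    rel <- detect$detection[detect$detection$kind == "relative", ]
    rep$relative_present <- rel$present[match(rep$genome_id, rel$genome_id)]
  }
  if (!is.null(spacers) && nrow(spacers$assignments)) {
    a <- spacers$assignments
    hosts <- vapply(rep$genome_id, function(g)
      paste(sort(unique(a$host_id[a$phage_id == g])), collapse = ","), "")
    rep$spacer_hosts <- hosts
  }
  stopifnot(!anyDuplicated(rep$genome_id))
  write_tsv(rep, file.path(ensure_dir(cfg$out), "report.tsv"))
  rep
}
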