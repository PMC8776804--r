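# The presence rules used throughout: breadth is the fraction of the genome
# covered >= 1x by reads at or above the identity threshold; the breadth
# inequality is strict.
PRESENCE_RULES <- data.frame(
  kind = c("bacterium", "phage", "relative"),
  min_identity = c(95, 90, 70),
  min_breadth = c(0.60, 0.75, 0.60),
  stringsAsFactors = FALSE)

new_read_alignments <- function(df) {
  need <- c("read_id", "genome_id", "start", "end", "aligned_bases",
            "edit_distance", "strand")
  assert_that(all(need %in% names(df)), "missing read-alignment columns")
  assert_that(all(df$edit_distance <= df$aligned_bases),
              "edit distance cannot exceed aligned bases")
  class(df) <- c("read_alignments", "data.frame")
  df
}

#' Per-read alignment identity
#'
#' identity = (aligned bases - edit distance) / aligned bases, with the edit
#' distance counting substitutions and indel positions (SAM NM semantics).
#'
#' @param alignments `read_alignments` data.frame (or anything with
#'   `aligned_bases` and `edit_distance` columns).
#' @return numeric vector of fractions in [0, 1].
#' @export
read_identity <- function(alignments) {
  assert_that(all(alignments$aligned_bases > 0),
              "aligned bases must be > 0")
  assert_that(all(alignments$edit_distance <= alignments$aligned_bases),
              "edit distance cannot exceed aligned bases")
  (alignments$aligned_bases - alignments$edit_distance) /
    alignments$aligned_bases
}

#' Identity-filtered coverage of a genome
#'
#' Breadth uses the union of qualifying alignment intervals (depth does not
#' inflate breadth); qualifying aligned bases sum over the same alignments.
#'
#' @param alignments `read_alignments` data.frame.
#' @param genome single named character string, or named genome length.
#' @param min_identity percentage threshold; alignments below it are dropped.
#' @return one-row data.frame of class `coverage_profile`: `genome_id`,
#'   `identity_threshold`, `covered_fraction`, `qualifying_bases`,
#'   `n_foreign` (alignments referencing other genomes, ignored).
#' @export
coverage_profile <- function(alignments, genome, min_identity) {
  gid <- names(genome)
  assert_that(!is.null(gid), "genome must be named")
  L <- if (is.character(genome)) nchar(genome) else as.numeric(genome)
  assert_that(L > 0, "genome length must be > 0")
  foreign <- sum(alignments$genome_id != gid)
  if (foreign > 0)
    warning(sprintf("%d alignments reference other genomes; ignored", foreign))
  aln <- alignments[alignments$genome_id == gid, , drop = FALSE]
  if (nrow(aln)) {
    keep <- read_identity(aln) >= min_identity / 100
    aln <- aln[keep, , drop = FALSE]
  }
  covered <- 0
  qbases <- 0
  if (nrow(aln)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = aln$start + 1L,
                                           end = pmin(aln$end, L)))
    covered <- sum(IRanges::width(ir)) / L
    qbases <- sum(aln$aligned_bases)
  }
  out <- data.frame(genome_id = gid, identity_threshold = min_identity,
                    covered_fraction = covered, qualifying_bases = qbases,
                    n_foreign = foreign, stringsAsFactors = FALSE)
  class(out) <- c("coverage_profile", "data.frame")
  out
}

#' Presence call for a bacterium, phage, or phage relative
#'
#' The three rules: a bacterium is present when >60% of its genome is
#' covered by reads of >= 95% identity; a phage when >75% at >= 90%; a phage
#' relative when >60% at >= 70%. Inequalities are strict, so exactly 60%
#' breadth is absent.
#'
#' @param profiles `coverage_profile` rows for one genome (several identity
#'   thresholds stacked).
#' @param kind one of "bacterium", "phage", "relative".
#' @return one-row data.frame of class `presence_call`: `genome_id`, `kind`,
#'   `identity_threshold`, `min_breadth`, `covered_fraction`, `present`.
#' @export
call_presence <- function(profiles, kind) {
  rule <- PRESENCE_RULES[PRESENCE_RULES$kind == kind, ]
  assert_that(nrow(rule) == 1, "kind must be bacterium, phage or relative")
  row <- profiles[profiles$identity_threshold == rule$min_identity, ,
                  drop = FALSE]
  assert_that(nrow(row) >= 1,
              sprintf("no coverage profile at the %g%% identity threshold",
                      rule$min_identity))
  row <- row[1, ]
  out <- data.frame(genome_id = row$genome_id, kind = kind,
                    identity_threshold = rule$min_identity,
                    min_breadth = rule$min_breadth,
                    covered_fraction = row$covered_fraction,
                    present = row$covered_fraction > rule$min_breadth,
                    stringsAsFactors = FALSE)
  class(out) <- c("presence_call", "data.frame")
  out
}

#' Normalized genome abundance
#'
#' abundance = qualifying aligned bases / genome size in bases / library
#' size in gigabases.
#'
#' @param qualifying_bases bases aligning at or above the identity threshold.
#' @param genome_length bp (> 0).
#' @param library_gb library size in gigabases (> 0): total sequenced bases
#'   of the read set before alignment / 1e9.
#' @return abundance (bases per genome-base per Gb).
#' @export
normalized_abundance <- function(qualifying_bases, genome_length, library_gb) {
  assert_that(all(genome_length > 0) && all(library_gb > 0),
              "genome length and library size must be > 0")
  assert_that(all(qualifying_bases >= 0), "qualifying bases must be >= 0")
  qualifying_bases / genome_length / library_gb
}

#' Phage/host abundance ratio
#'
#' @param phage,host normalized abundances (numbers, or one-row data frames
#'   with an `abundance` column).
#' @return the ratio; `NA` with attribute `undefined = TRUE` when the host
#'   abundance is zero (reported as undefined, not infinity).
#' @export
phage_host_ratio <- function(phage, host) {
  p <- if (is.data.frame(phage)) phage$abundance else phage
  h <- if (is.data.frame(host)) host$abundance else host
  if (h == 0) return(structure(NA_real_, undefined = TRUE))
  p / h
}

#' Format a phage/host ratio the way abundance tables print it
#'
#' Rounded to integer at >= 10, two decimals below; undefined ratios print
#' as "-".
#'
#' @param ratio output of [phage_host_ratio()].
#' @return character scalar.
#' @export
format_ratio <- function(ratio) {
  if (is.na(ratio)) return("-")
  if (ratio >= 10) sprintf("%d", round(ratio)) else sprintf("%.2f", ratio)
}

#' Phage/host ratio table from a precomputed abundance table
#'
#' Joins each phage or phage-relative row to the bacterium row of its host
#' in the same sample (julian_day x fraction) and computes the abundance
#' ratio. The package ships an example table
#' (`system.file("extdata", "bloom2018_coverage.tsv", package =
#' "flavoscope")`) of normalized genome coverages of flavophages and their
#' Flavobacteriia hosts across a North Sea spring phytoplankton bloom.
#'
#' @param coverage data.frame with columns `julian_day`, `fraction`, `name`,
#'   `kind` (phage/relative/bacterium), `norm_coverage`, `host` (host name
#'   or NA).
#' @return data.frame with one row per phage/relative row that has a host
#'   present in the same sample: abundances, `ratio` and `ratio_printed`.
#' @export
bloom_ratio_table <- function(coverage) {
  sel <- coverage$kind %in% c("phage", "relative") & !is.na(coverage$host) &
    coverage$host != "NA"
  rows <- list()
  for (i in which(sel)) {
    h <- coverage[coverage$kind == "bacterium" &
                    coverage$name == coverage$host[i] &
                    coverage$julian_day == coverage$julian_day[i] &
                    coverage$fraction == coverage$fraction[i], , drop = FALSE]
    if (!nrow(h)) next
    r <- phage_host_ratio(coverage$norm_coverage[i], h$norm_coverage[1])
    rows[[length(rows) + 1L]] <- data.frame(
      julian_day = coverage$julian_day[i], fraction = coverage$fraction[i],
      name = coverage$name[i], kind = coverage$kind[i],
      phage_abundance = coverage$norm_coverage[i],
      host = coverage$host[i], host_abundance = h$norm_coverage[1],
      ratio = as.numeric(r), ratio_printed = format_ratio(r),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Ground-truth alignments of a simulated read set
#'
#' Converts a [simulate_reads()] result into perfect-knowledge alignments:
#' every read aligns to its origin interval with its planted substitution
#' count as edit distance.
#'
#' @param readset a `read_set`.
#' @return `read_alignments` data.frame.
#' @export
alignments_from_readset <- function(readset) {
  r <- readset$reads
  new_read_alignments(data.frame(
    read_id = r$read_id, genome_id = r$origin, start = r$start, end = r$end,
    aligned_bases = nchar(r$seq), edit_distance = r$n_sub,
    strand = r$strand, stringsAsFactors = FALSE))
}

#' Read alignments from a SAM/BAM file
#'
#' Requires the NM tag for identity; secondary and supplementary alignments
#' are excluded by default so depth cannot leak into breadth through split
#' hits.
#'
#' @param path SAM or BAM file.
#' @param keep_secondary logical.
#' @return `read_alignments` data.frame (0-based half-open reference
#'   coordinates).
#' @export
read_alignments_sam <- function(path, keep_secondary = FALSE) {
  for (pkg in c("Rsamtools", "GenomicAlignments"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop(pkg, " is required to read SAM/BAM", call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "cigar", "flag", "strand"),
      tag = "NM"))[[1]]
  flag <- res$flag
  keep <- bitwAnd(flag, 4L) == 0L
  if (!keep_secondary)
    keep <- keep & bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  nm <- res$tag$NM
  if (is.null(nm)) stop("SAM/BAM input lacks NM tags; identity undefined",
                        call. = FALSE)
  cig <- res$cigar[keep]
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = TRUE)
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  new_read_alignments(data.frame(
    read_id = res$qname[keep], genome_id = as.character(res$rname[keep]),
    start = res$pos[keep] - 1L, end = res$pos[keep] - 1L + rw,
    aligned_bases = qw, edit_distance = nm[keep],
    strand = as.character(res$strand[keep]), stringsAsFactors = FALSE))
}

#' Read alignments from a PAF file
#'
#' Identity uses residue matches / alignment block length (columns 10/11);
#' the edit distance is reconstructed as block length - matches.
#'
#' @param path PAF file (minimap2-style, may carry extra tag columns).
#' @return `read_alignments` data.frame.
#' @export
read_alignments_paf <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(new_read_alignments(data.frame(
      read_id = character(0), genome_id = character(0), start = integer(0),
      end = integer(0), aligned_bases = integer(0),
      edit_distance = integer(0), strand = character(0))))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i, as = identity) as(vapply(f, `[`, "", i))
  new_read_alignments(data.frame(
    read_id = get(1), genome_id = get(6),
    start = get(8, as.integer), end = get(9, as.integer),
    aligned_bases = get(11, as.integer),
    edit_distance = get(11, as.integer) - get(10, as.integer),
    strand = get(5), stringsAsFactors = FALSE))
}

#' Presence, abundance and coverage table for a set of genomes
#'
#' Evaluates, for every genome, the three presence rules and the normalized
#' abundance at each rule's identity threshold.
#'
#' @param alignments `read_alignments` data.frame.
#' @param genomes named character vector of sequences or named lengths.
#' @param library_gb library size in gigabases.
#' @return data.frame with one row per genome x rule: `genome_id`, `kind`,
#'   `identity_threshold`, `covered_fraction`, `qualifying_bases`,
#'   `abundance`, `present`.
#' @export
detect_genomes <- function(alignments, genomes, library_gb) {
  lens <- if (is.character(genomes)) nchar(genomes) else genomes
  rows <- list()
  for (gid in names(genomes)) {
    aln <- alignments[alignments$genome_id == gid, , drop = FALSE]
    for (k in seq_len(nrow(PRESENCE_RULES))) {
      rule <- PRESENCE_RULES[k, ]
      prof <- coverage_profile(aln, genomes[gid], rule$min_identity)
      call <- call_presence(prof, rule$kind)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, kind = rule$kind,
        identity_threshold = rule$min_identity,
        covered_fraction = prof$covered_fraction,
        qualifying_bases = prof$qualifying_bases,
        abundance = normalized_abundance(prof$qualifying_bases,
                                         lens[[gid]], library_gb),
        present = call$present, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
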