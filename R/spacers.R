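# Constraint set for spacer-to-genome matching, mirroring a
# highest-sensitivity assembler search: exact word-length anchor, gaps up to
# 20% of the spacer (per-event cap 5), gaps count as mismatches, and at most
# 50% effective mismatches per spacer.
spacer_caps <- function(spacer_len, word = 10L, max_gap_frac = 0.2,
                        max_gap_event = 5L, max_mismatch_frac = 0.5) {
  list(word = word,
       max_gap = floor(max_gap_frac * spacer_len),
       max_gap_event = max_gap_event,
       max_eff = floor(max_mismatch_frac * spacer_len))
}

# best-first non-overlapping selection, then the constraint filter: the
# optimal alignment of a locus that violates a gap cap suppresses the locus
# (weaker overlapping alignments do not resurrect it)
select_spacer_hits <- function(cands, caps) {
  if (!nrow(cands)) return(cands)
  cands <- cands[!duplicated(cands[, c("start", "end", "strand")]), ,
                 drop = FALSE]
  cands <- cands[order(cands$effective_mismatches, cands$start, cands$end), ,
                 drop = FALSE]
  kept <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    for (j in which(kept)) {
      if (cands$strand[i] == cands$strand[j] &&
          cands$start[i] < cands$end[j] && cands$end[i] > cands$start[j]) {
        ok <- FALSE
        break
      }
    }
    kept[i] <- ok
  }
  cands <- cands[kept, , drop = FALSE]
  keep <- cands$gap_positions <= caps$max_gap &
    cands$max_gap_event <= caps$max_gap_event &
    cands$effective_mismatches <= caps$max_eff &
    cands$longest_run >= caps$word
  cands[keep, , drop = FALSE]
}

#' Match a CRISPR spacer against a phage genome
#'
#' Candidate loci are seeded by exact 10-mer ("word length") matches on both
#' strands and extended to full-spacer semi-global alignments with unit
#' costs, where every gapped position counts as one effective mismatch.
#' Reported matches satisfy all constraints: total gapped positions <= 20%
#' of the spacer, each gap event <= 5 bp, effective mismatches (substitutions
#' + gapped positions) <= 50% of the spacer, and an exact run of at least
#' the word length. Matches come best-first (effective mismatches, then
#' genome position).
#'
#' @param spacer single named character string (>= word length).
#' @param genome single named character string.
#' @param word exact seed length (default 10).
#' @param max_gap_frac,max_gap_event,max_mismatch_frac constraint knobs.
#' @return data.frame of class `spacer_matches`: `spacer_id`, `genome_id`,
#'   `start`, `end` (0-based half-open), `strand`, `substitutions`,
#'   `gap_positions`, `max_gap_event`, `effective_mismatches`.
#' @export
find_spacer_hits <- function(spacer, genome, word = 10L, max_gap_frac = 0.2,
                             max_gap_event = 5L, max_mismatch_frac = 0.5) {
  m <- nchar(spacer)
  assert_that(m >= word, "spacer shorter than the word length")
  caps <- spacer_caps(m, word, max_gap_frac, max_gap_event, max_mismatch_frac)
  cands <- cpp_spacer_candidates(unname(spacer), unname(genome),
                                 word = word, cap = caps$max_eff)
  hits <- select_spacer_hits(cands, caps)
  finish_spacer_hits(hits, spacer, genome)
}

# exhaustive full-genome DP route; the brute-force oracle for the seeded
# matcher (identical constraint semantics, no seeding)
find_spacer_hits_bruteforce <- function(spacer, genome, word = 10L,
                                        max_gap_frac = 0.2,
                                        max_gap_event = 5L,
                                        max_mismatch_frac = 0.5) {
  m <- nchar(spacer)
  assert_that(m >= word, "spacer shorter than the word length")
  caps <- spacer_caps(m, word, max_gap_frac, max_gap_event, max_mismatch_frac)
  cands <- cpp_spacer_scan(unname(spacer), unname(genome), cap = caps$max_eff)
  hits <- select_spacer_hits(cands, caps)
  finish_spacer_hits(hits, spacer, genome)
}

finish_spacer_hits <- function(hits, spacer, genome) {
  out <- data.frame(
    spacer_id = rep(if (is.null(names(spacer))) "spacer" else names(spacer),
                    nrow(hits)),
    genome_id = rep(if (is.null(names(genome))) "genome" else names(genome),
                    nrow(hits)),
    hits[, c("start", "end", "strand", "substitutions", "gap_positions",
             "max_gap_event", "effective_mismatches"), drop = FALSE],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("spacer_matches", "data.frame")
  out
}

#' Effective mismatches of spacer matches
#'
#' Gaps count as mismatches: the effective count is substitutions plus
#' gapped positions (each inserted or deleted position counts one).
#'
#' @param matches `spacer_matches` data.frame (or anything with
#'   `substitutions` and `gap_positions` columns).
#' @return integer vector.
#' @export
effective_mismatches <- function(matches) {
  as.integer(matches$substitutions + matches$gap_positions)
}

#' Assign phages to hosts from spacer matches
#'
#' A (host, phage) pair is assigned iff some spacer of the host matches the
#' phage with at most `max_mismatch` effective mismatches (the conventional
#' assignment rule keeps only results up to 1 mismatch; a "<2 mismatches"
#' database rule collapses to the same cap).
#'
#' @param spacers data.frame with `spacer_id`, `host_id`, `seq`.
#' @param phages named character vector of phage genomes.
#' @param max_mismatch effective-mismatch cap for assignment (default 1).
#' @param ... passed to [find_spacer_hits()].
#' @return list with `matches` (all constraint-passing matches) and
#'   `assignments` (data.frame host_id/phage_id/best_mismatches/
#'   n_spacers/spacer_ids, best-first).
#' @export
assign_phage_to_host <- function(spacers, phages, max_mismatch = 1L, ...) {
  assert_that(nrow(spacers) >= 1 && length(phages) >= 1,
              "spacers and phages must be non-empty")
  all_matches <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- setNames(spacers$seq[i], spacers$spacer_id[i])
    if (nchar(sp) < 10L) {
      warning("spacer ", spacers$spacer_id[i], " shorter than word length; skipped")
      next
    }
    for (g in names(phages)) {
      h <- find_spacer_hits(sp, phages[g], ...)
      if (nrow(h)) {
        h$host_id <- spacers$host_id[i]
        all_matches[[length(all_matches) + 1L]] <- h
      }
    }
  }
  matches <- if (length(all_matches)) do.call(rbind, all_matches) else
    data.frame(spacer_id = character(0), genome_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               substitutions = integer(0), gap_positions = integer(0),
               max_gap_event = integer(0), effective_mismatches = integer(0),
               host_id = character(0), stringsAsFactors = FALSE)
  ok <- matches[matches$effective_mismatches <= max_mismatch, , drop = FALSE]
  if (nrow(ok)) {
    key <- paste(ok$host_id, ok$genome_id, sep = "\r")
    agg <- lapply(split(ok, key), function(d) data.frame(
      host_id = d$host_id[1], phage_id = d$genome_id[1],
      best_mismatches = min(d$effective_mismatches),
      n_spacers = length(unique(d$spacer_id)),
      spacer_ids = paste(sort(unique(d$spacer_id)), collapse = ","),
      stringsAsFactors = FALSE))
    assignments <- do.call(rbind, agg)
    assignments <- assignments[order(assignments$best_mismatches,
                                     assignments$host_id,
                                     assignments$phage_id), , drop = FALSE]
    rownames(assignments) <- NULL
  } else {
    assignments <- data.frame(host_id = character(0), phage_id = character(0),
                              best_mismatches = integer(0),
                              n_spacers = integer(0),
                              spacer_ids = character(0),
                              stringsAsFactors = FALSE)
  }
  list(matches = matches, assignments = assignments)
}

#' Read spacers from FASTA with hostID|spacerID headers
#'
#' @param path FASTA file.
#' @return data.frame `spacer_id`, `host_id`, `seq`.
#' @export
read_spacers_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- sub("\\s.*$", "", names(ss))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  data.frame(
    spacer_id = vapply(parts, function(p) p[length(p)], ""),
    host_id = vapply(parts, function(p)
      if (length(p) > 1) paste(p[-length(p)], collapse = "|") else "host", ""),
    seq = toupper(as.character(ss)), stringsAsFactors = FALSE)
}
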