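# Cas12a guide candidate enumeration and cross-reactivity screening.
#
# Guides are protospacer windows downstream of a TTTV PAM (LbCas12a
# canonical; configurable). Specificity is defined within the supplied
# species panel: a candidate from one species is mapped through the alignment
# onto every other species and judged on PAM integrity, total protospacer
# mismatches, mismatches in the PAM-proximal seed, and indels in the window.
# No genome-wide off-target search is attempted.

#' Cas12a PAM specification
#'
#' @param pattern IUPAC PAM pattern, 5' of the protospacer (default "TTTV",
#'   the canonical LbCas12a PAM).
#' @param protospacer_len protospacer length in nt, 18-25 (default 20).
#' @return a `pam_spec` list.
#' @export
pam_spec <- function(pattern = "TTTV", protospacer_len = 20L) {
  stopifnot(nchar(pattern) >= 1L,
            protospacer_len >= 18L, protospacer_len <= 25L)
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!all(chars %in% IUPAC_CHARS)) {
    stop("PAM pattern contains non-IUPAC characters", call. = FALSE)
  }
  structure(list(pattern = toupper(pattern),
                 protospacer_len = as.integer(protospacer_len)),
            class = "pam_spec")
}

#' Seed-region specification
#'
#' The seed is the PAM-proximal portion of the protospacer where mismatches
#' most strongly abolish Cas12a recognition; the default of 10 nt follows the
#' convention of counting up to 10 bases proximal to the PAM.
#'
#' @param seed_len seed length in nt (default 10).
#' @return a `seed_spec` list.
#' @export
seed_spec <- function(seed_len = 10L) {
  stopifnot(seed_len >= 1L)
  structure(list(seed_len = as.integer(seed_len)), class = "seed_spec")
}

#' Scan a sequence for PAM sites on both strands
#'
#' Finds every position where the PAM pattern matches (IUPAC-aware; ambiguity
#' codes in the sequence never match) and the full PAM + protospacer window
#' fits within the sequence and intersects no excluded interval. Reverse-
#' strand hits are reported in forward coordinates with `strand == "-"`.
#'
#' @param sequence a gap-free nucleotide string.
#' @param pam a [pam_spec()].
#' @param excluded optional data.frame with `start`,`end` (1-based closed)
#'   intervals that no window may intersect (e.g. template junctions).
#' @return data.frame with columns `win_start`, `win_end` (full PAM +
#'   protospacer window, forward coordinates), `pam_start` (forward
#'   coordinate of the PAM's leftmost base) and `strand`.
#' @export
scan_pam_sites <- function(sequence, pam = pam_spec(), excluded = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (grepl("-", sequence, fixed = TRUE)) {
    stop("sequence contains gap characters", call. = FALSE)
  }
  n <- nchar(sequence)
  plen <- nchar(pam$pattern)
  wlen <- plen + pam$protospacer_len

  fwd <- iupac_match_positions(sequence, pam$pattern)
  fwd <- fwd[fwd + wlen - 1L <= n]
  hits <- data.frame(win_start = fwd, win_end = fwd + wlen - 1L,
                     pam_start = fwd, strand = rep("+", length(fwd)),
                     stringsAsFactors = FALSE)

  rc <- revcomp(sequence)
  rev <- iupac_match_positions(rc, pam$pattern)
  rev <- rev[rev + wlen - 1L <= n]
  if (length(rev)) {
    ws <- n - (rev + wlen - 1L) + 1L
    we <- n - rev + 1L
    hits <- rbind(hits, data.frame(win_start = ws, win_end = we,
                                   pam_start = we - plen + 1L,
                                   strand = rep("-", length(rev)),
                                   stringsAsFactors = FALSE))
  }
  if (!is.null(excluded) && nrow(excluded) > 0L && nrow(hits) > 0L) {
    keep <- vapply(seq_len(nrow(hits)), function(i) {
      !any(intervals_intersect(hits$win_start[i], hits$win_end[i],
                               excluded$start, excluded$end))
    }, logical(1))
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$win_start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Map an ungapped window of one species onto another through the alignment
#'
#' Returns the target species' residues over the alignment columns spanned by
#' the origin species' window (including any inserted columns between the
#' origin positions), and whether any of those columns is gapped in either
#' species.
#'
#' @param x an [msa()] object.
#' @param origin_species,target_species species ids.
#' @param start,end origin window in the origin species' ungapped coordinates
#'   (1-based closed).
#' @return list with `window` (target residues over the spanned columns,
#'   gaps as `-`), `columns` (the spanned column range) and `indel`
#'   (TRUE if any spanned column is gapped in either species).
#' @export
map_window_across_species <- function(x, origin_species, start, end,
                                      target_species) {
  stopifnot(inherits(x, "msa"))
  p2c <- x$pos2col[[origin_species]]
  if (is.null(p2c)) stop("species '", origin_species, "' not in alignment",
                         call. = FALSE)
  if (start < 1L || end > length(p2c) || start > end) {
    stop("window [", start, ",", end, "] out of range for '", origin_species,
         "' (ungapped length ", length(p2c), ")", call. = FALSE)
  }
  cols <- p2c[start]:p2c[end]
  tchars <- x$mat[target_species, cols]
  ochars <- x$mat[origin_species, cols]
  list(window = paste(tchars, collapse = ""),
       columns = c(p2c[start], p2c[end]),
       indel = any(tchars == "-") || any(ochars == "-"))
}

# Three-valued per-species cross-reactivity status under the classification
# rule: a guide is safe against a species when the PAM is broken, an indel
# falls in the window, or there are >= mm_threshold mismatches of which
# >= seed_threshold fall in the seed; it is reactive when the window matches
# perfectly with an intact PAM; anything in between is unresolved and needs
# wet-lab validation.
species_status <- function(pam_intact, total_mm, seed_mm, indel,
                           mm_threshold = 2L, seed_threshold = 1L) {
  ifelse(!pam_intact | indel | (total_mm >= mm_threshold & seed_mm >= seed_threshold),
         "safe",
         ifelse(pam_intact & !indel & total_mm == 0L, "reactive", "unresolved"))
}

#' Score a guide window's cross-reactivity against every other species
#'
#' For each non-origin species the origin PAM + protospacer window is mapped
#' through the alignment; the report records whether the mapped PAM still
#' matches the PAM pattern, the Hamming mismatch count over the protospacer
#' (a gap or ambiguity code in the target counts as a mismatch), the mismatch
#' count restricted to the PAM-proximal seed, whether any indel falls in the
#' window, and the resulting three-valued status (`reactive` / `unresolved` /
#' `safe`; `cross_reactive == (status == "reactive")`).
#'
#' @param x an [msa()] object.
#' @param origin_species origin species id.
#' @param win_start,win_end full PAM + protospacer window in the origin
#'   species' ungapped coordinates.
#' @param strand `"+"` or `"-"` (orientation of the PAM on the origin
#'   sequence).
#' @param pam a [pam_spec()].
#' @param seed a [seed_spec()].
#' @param mm_threshold,seed_threshold classification thresholds (defaults 2
#'   and 1: safe requires at least 2 mismatches with at least 1 in the seed,
#'   unless the PAM is broken or an indel intervenes).
#' @return data.frame with one row per non-origin species: `species`,
#'   `pam_intact`, `total_mismatches`, `seed_mismatches`, `indel_in_window`,
#'   `status`, `cross_reactive`.
#' @export
score_specificity <- function(x, origin_species, win_start, win_end, strand,
                              pam = pam_spec(), seed = seed_spec(),
                              mm_threshold = 2L, seed_threshold = 1L) {
  stopifnot(inherits(x, "msa"), strand %in% c("+", "-"))
  plen <- nchar(pam$pattern)
  slen <- pam$protospacer_len
  stopifnot(win_end - win_start + 1L == plen + slen)
  if (strand == "+") {
    pam_pos <- win_start:(win_start + plen - 1L)
    proto_pos <- (win_start + plen):win_end          # PAM-proximal first
  } else {
    pam_pos <- (win_end - plen + 1L):win_end
    proto_pos <- (win_end - plen):win_start          # PAM-proximal first
  }
  seed_idx <- seq_len(min(seed$seed_len, slen))

  p2c <- x$pos2col[[origin_species]]
  all_cols <- p2c[win_start]:p2c[win_end]
  proto_cols <- p2c[proto_pos]
  pam_cols <- p2c[pam_pos]
  origin_proto <- x$mat[origin_species, proto_cols]

  others <- setdiff(x$ids, origin_species)
  reports <- lapply(others, function(sp) {
    trow <- x$mat[sp, ]
    tchars <- trow[proto_cols]
    mism <- tchars != origin_proto | !(tchars %in% c("A", "C", "G", "T"))
    total_mm <- sum(mism)
    seed_mm <- sum(mism[seed_idx])
    pam_window <- paste(trow[pam_cols], collapse = "")
    if (strand == "-") pam_window <- tryCatch(revcomp(pam_window),
                                              error = function(e) "")
    pam_intact <- !grepl("-", pam_window, fixed = TRUE) &&
      iupac_window_match(pam_window, pam$pattern)
    indel <- any(trow[all_cols] == "-") ||
      any(x$mat[origin_species, all_cols] == "-")
    data.frame(species = sp, pam_intact = pam_intact,
               total_mismatches = as.integer(total_mm),
               seed_mismatches = as.integer(seed_mm),
               indel_in_window = indel, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, reports)
  out$status <- species_status(out$pam_intact, out$total_mismatches,
                               out$seed_mismatches, out$indel_in_window,
                               mm_threshold, seed_threshold)
  out$cross_reactive <- out$status == "reactive"
  out
}

#' Classify a guide from its per-species specificity reports
#'
#' Verdict is `"specific"` only when every non-origin species is safe (broken
#' PAM, indel in the window, or at least `mm_threshold` mismatches with at
#' least `seed_threshold` in the seed); `"cross_reactive"` when any species
#' matches the window perfectly with an intact PAM; otherwise
#' `"unresolved"` — a near-match (e.g. a single non-seed mismatch under an
#' intact PAM) that requires wet-lab validation before the guide can be
#' trusted.
#'
#' @param reports data.frame as from [score_specificity()] (columns
#'   `pam_intact`, `total_mismatches`, `seed_mismatches`, `indel_in_window`).
#' @param mm_threshold,seed_threshold classification thresholds.
#' @return one of `"specific"`, `"unresolved"`, `"cross_reactive"`.
#' @export
classify_guide <- function(reports, mm_threshold = 2L, seed_threshold = 1L) {
  if (is.null(reports) || nrow(reports) == 0L) {
    stop("no specificity reports: nothing to discriminate against",
         call. = FALSE)
  }
  status <- species_status(reports$pam_intact, reports$total_mismatches,
                           reports$seed_mismatches, reports$indel_in_window,
                           mm_threshold, seed_threshold)
  if (any(status == "reactive")) "cross_reactive"
  else if (all(status == "safe")) "specific"
  else "unresolved"
}

#' Enumerate and screen guide candidates on a concatenated template
#'
#' Scans the template for PAM sites on both strands (windows intersecting a
#' linker junction or containing ambiguity codes are discarded), maps each
#' hit back to its origin species and region via the template provenance,
#' scores cross-reactivity against every other species and classifies each
#' candidate. Every emitted candidate's PAM is re-verified against the origin
#' species' ungapped sequence.
#'
#' @param template a [build_concatenated_template()] result.
#' @param x the [msa()] the template was built from.
#' @param pam a [pam_spec()].
#' @param seed a [seed_spec()].
#' @param mm_threshold,seed_threshold classification thresholds.
#' @return data.frame of class `guide_candidates`, ranked by
#'   [rank_candidates()]: `guide_id`, `species`, `region`, `strand`,
#'   `win_start`, `win_end` (origin ungapped coordinates), `pam_seq`,
#'   `protospacer`, `gc_fraction`, `max_homopolymer`, `verdict`, plus a
#'   list-column `specificity` of per-species reports.
#' @export
enumerate_guides <- function(template, x, pam = pam_spec(),
                             seed = seed_spec(), mm_threshold = 2L,
                             seed_threshold = 1L) {
  stopifnot(inherits(template, "concat_template"), inherits(x, "msa"))
  hits <- scan_pam_sites(template$sequence, pam, excluded = template$junctions)
  plen <- nchar(pam$pattern)
  prov <- template$provenance
  rows <- list()
  reports <- list()
  for (i in seq_len(nrow(hits))) {
    ws <- hits$win_start[i]; we <- hits$win_end[i]; st <- hits$strand[i]
    frag <- which(prov$t_start <= ws & prov$t_end >= we)
    if (length(frag) != 1L) next  # window not contained in one fragment
    fr <- prov[frag, ]
    o_ws <- fr$s_start + (ws - fr$t_start)
    o_we <- fr$s_start + (we - fr$t_start)
    wseq <- substr(template$sequence, ws, we)
    if (grepl("[^ACGT]", wseq)) next  # ambiguity in window: discard
    if (st == "+") {
      pam_seq <- substr(wseq, 1L, plen)
      protospacer <- substr(wseq, plen + 1L, nchar(wseq))
    } else {
      pam_seq <- revcomp(substr(wseq, nchar(wseq) - plen + 1L, nchar(wseq)))
      protospacer <- revcomp(substr(wseq, 1L, nchar(wseq) - plen))
    }
    # post-hoc: PAM must hold in the origin sequence itself, not just the
    # template copy
    oseq <- ungapped_seq(x, fr$species)
    owin <- substr(oseq, o_ws, o_we)
    stopifnot(identical(owin, wseq))
    rep_i <- score_specificity(x, fr$species, o_ws, o_we, st, pam, seed,
                               mm_threshold, seed_threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      guide_id = sprintf("%s_%s_%s%d", fr$species, fr$label,
                         if (st == "+") "p" else "m", o_ws),
      species = fr$species, region = fr$label, strand = st,
      win_start = o_ws, win_end = o_we,
      pam_seq = pam_seq, protospacer = protospacer,
      gc_fraction = gc_fraction(protospacer),
      max_homopolymer = max_homopolymer_run(protospacer),
      verdict = classify_guide(rep_i, mm_threshold, seed_threshold),
      stringsAsFactors = FALSE)
    reports[[length(reports) + 1L]] <- rep_i
  }
  if (length(rows) == 0L) {
    out <- data.frame(guide_id = character(0), species = character(0),
                      region = character(0), strand = character(0),
                      win_start = integer(0), win_end = integer(0),
                      pam_seq = character(0), protospacer = character(0),
                      gc_fraction = numeric(0), max_homopolymer = integer(0),
                      verdict = character(0), stringsAsFactors = FALSE)
    out$specificity <- list()
    class(out) <- c("guide_candidates", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$specificity <- reports
  class(out) <- c("guide_candidates", "data.frame")
  rank_candidates(out)
}

#' Rank guide candidates
#'
#' Stable total order: verdict (specific < unresolved < cross_reactive), then
#' descending worst-case discrimination margin (the minimum over non-origin
#' species of `seed_mismatches + 2 * !pam_intact`), then GC fraction within
#' [0.30, 0.70] preferred, then no homopolymer run of 5+ preferred, then
#' origin position, then strand (`+` before `-`), then species and region.
#'
#' @param guides a `guide_candidates` data.frame.
#' @return the same data.frame, reordered.
#' @export
rank_candidates <- function(guides) {
  if (nrow(guides) == 0L) return(guides)
  verdict_rank <- match(guides$verdict,
                        c("specific", "unresolved", "cross_reactive"))
  min_margin <- vapply(guides$specificity, function(r) {
    min(r$seed_mismatches + 2L * (!r$pam_intact))
  }, numeric(1))
  gc_pref <- as.integer(!(guides$gc_fraction >= 0.30 &
                          guides$gc_fraction <= 0.70))
  hp_pref <- as.integer(guides$max_homopolymer >= 5L)
  strand_rank <- match(guides$strand, c("+", "-"))
  ord <- order(verdict_rank, -min_margin, gc_pref, hp_pref,
               guides$win_start, strand_rank, guides$species, guides$region,
               method = "radix")
  out <- guides[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-call guide design from an alignment
#'
#' Calls variable regions (unless supplied), builds the linker-concatenated
#' template and returns ranked, specificity-screened guide candidates for
#' every species.
#'
#' @param x an [msa()] object.
#' @param regions optional precomputed [find_variable_regions()] result.
#' @param pam,seed PAM and seed specifications.
#' @param linker template linker (PAM-free on both strands).
#' @param mm_threshold,seed_threshold classification thresholds.
#' @param ... passed to [find_variable_regions()] when `regions` is NULL.
#' @return a `guide_candidates` data.frame (see [enumerate_guides()]); the
#'   template is attached as attribute `"template"`.
#' @export
design_guides <- function(x, regions = NULL, pam = pam_spec(),
                          seed = seed_spec(), linker = DEFAULT_LINKER,
                          mm_threshold = 2L, seed_threshold = 1L, ...) {
  stopifnot(inherits(x, "msa"))
  if (is.null(regions)) regions <- find_variable_regions(x, ...)
  if (nrow(regions) == 0L) {
    stop("no variable regions found; nothing to design guides in",
         call. = FALSE)
  }
  template <- build_concatenated_template(regions, x, linker,
                                          pam_pattern = pam$pattern)
  guides <- enumerate_guides(template, x, pam, seed, mm_threshold,
                             seed_threshold)
  attr(guides, "template") <- template
  guides
}
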