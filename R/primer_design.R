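# RPA primer design.
#
# RPA runs isothermally at 37-42 degC with recombinase-mediated strand
# invasion, so no melting-temperature model is applied: primers are long
# (default 30-35 nt) and filtered on GC content and homopolymer runs only.
# Universal pairs sit in the conserved flanks (column-identical across all
# species, so one pair amplifies every species' variable region); specific
# pairs sit inside one species' variable region and must mismatch every
# other species.

#' RPA primer design constraints
#'
#' @param min_len,max_len primer length bounds in nt (defaults 30, 35 -- RPA
#'   favours long primers).
#' @param gc_min,gc_max GC-fraction bounds (defaults 0.20, 0.70).
#' @param max_homopolymer longest allowed homopolymer run (default 5).
#' @param min_amplicon,max_amplicon amplicon length bounds in nt (defaults
#'   100, 600; 600 accommodates a 500-column region plus two primers).
#' @return a `primer_constraints` list.
#' @export
primer_constraints <- function(min_len = 30L, max_len = 35L,
                               gc_min = 0.20, gc_max = 0.70,
                               max_homopolymer = 5L,
                               min_amplicon = 100L, max_amplicon = 600L) {
  stopifnot(min_len <= max_len, gc_min < gc_max, min_amplicon < max_amplicon)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 min_amplicon = as.integer(min_amplicon),
                 max_amplicon = as.integer(max_amplicon)),
            class = "primer_constraints")
}

#' GC fraction of a sequence
#'
#' Counts G and C over the sequence length. IUPAC ambiguity codes contribute
#' their expected GC content at the extremes handled exactly: S counts as GC,
#' W as AT, and every other ambiguity code as 0.5.
#'
#' @param seq non-empty, gap-free nucleotide string.
#' @return GC fraction in [0, 1].
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  if (grepl("-", seq, fixed = TRUE)) stop("sequence contains gaps",
                                          call. = FALSE)
  chars <- strsplit(toupper(seq), "")[[1]]
  w <- ifelse(chars %in% c("G", "C", "S"), 1,
              ifelse(chars %in% c("A", "T", "U", "W"), 0, 0.5))
  sum(w) / length(chars)
}

# Enumerate candidate primer windows (all start/length combinations) over a
# closed interval of a sequence, filtered on GC and homopolymer constraints.
# Vectorised: per-position GC weights are cumsum'd for O(1) window GC, and
# homopolymer violations are derived from the run-length encoding (a window
# fails when its overlap with any single-base run exceeds max_homopolymer).
# `drops` (environment) accumulates per-constraint elimination counts.
enumerate_windows <- function(seq, lo, hi, constraints, drops = NULL) {
  chars <- strsplit(substr(seq, lo, hi), "")[[1]]
  n <- length(chars)
  gcw <- ifelse(chars %in% c("G", "C", "S"), 1,
                ifelse(chars %in% c("A", "T", "U", "W"), 0, 0.5))
  cs <- c(0, cumsum(gcw))
  r <- rle(chars)
  rend <- cumsum(r$lengths)
  rstart <- rend - r$lengths + 1L
  long <- which(r$lengths > constraints$max_homopolymer)
  out <- list()
  for (len in constraints$min_len:constraints$max_len) {
    if (n < len) next
    s <- seq_len(n - len + 1L)                 # window starts, local coords
    gc <- (cs[s + len] - cs[s]) / len
    gc_ok <- gc >= constraints$gc_min & gc <= constraints$gc_max
    hp_ok <- rep(TRUE, length(s))
    for (k in long) {
      ov <- pmin(s + len - 1L, rend[k]) - pmax(s, rstart[k]) + 1L
      hp_ok <- hp_ok & ov <= constraints$max_homopolymer
    }
    if (!is.null(drops)) {
      drops$gc <- drops$gc + sum(!gc_ok)
      drops$homopolymer <- drops$homopolymer + sum(gc_ok & !hp_ok)
    }
    keep <- which(gc_ok & hp_ok)
    if (length(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        start = lo + keep - 1L, end = lo + keep + len - 2L,
        seq = substring(substr(seq, lo, hi), keep, keep + len - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) {
    out <- do.call(rbind, out)
    out[order(out$start, out$end), , drop = FALSE]
  } else data.frame(start = integer(0), end = integer(0),
                    seq = character(0))
}

new_drops <- function() {
  e <- new.env()
  e$flank_too_short <- 0L; e$gc <- 0L; e$homopolymer <- 0L
  e$amplicon <- 0L; e$not_discriminating <- 0L; e$no_guide_flanked <- 0L
  e
}

drops_diagnostic <- function(drops) {
  counts <- c(flank_too_short = drops$flank_too_short, gc = drops$gc,
              homopolymer = drops$homopolymer, amplicon = drops$amplicon,
              not_discriminating = drops$not_discriminating,
              no_guide_flanked = drops$no_guide_flanked)
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) return("no candidate windows existed")
  paste0("all candidates eliminated by: ",
         paste(names(counts), "(", counts, ")", sep = "", collapse = ", "))
}

empty_pairs <- function(diagnostic) {
  out <- data.frame(kind = character(0), fwd_seq = character(0),
                    rev_seq = character(0), fwd_start = integer(0),
                    fwd_end = integer(0), rev_start = integer(0),
                    rev_end = integer(0), max_amplicon = integer(0),
                    stringsAsFactors = FALSE)
  out$amplicons <- list()
  out$covered_guides <- list()
  attr(out, "diagnostic") <- diagnostic
  class(out) <- c("primer_pairs", "data.frame")
  out
}

# Guides (origin ungapped coords) covered by an amplicon of one species.
guides_in_amplicon <- function(guides, species, amp_start, amp_end) {
  if (is.null(guides) || nrow(guides) == 0L) return(character(0))
  g <- guides[guides$species == species &
              guides$win_start >= amp_start & guides$win_end <= amp_end, ]
  g$guide_id
}

#' Design universal primer pairs in a region's conserved flanks
#'
#' Enumerates all primer windows of allowed length fully inside the left and
#' right flanking conserved blocks. Because flank columns are strictly
#' identical and gap-free across species, any such window binds every species
#' perfectly; pairs are kept when GC, homopolymer and per-species amplicon
#' constraints hold, ranked by amplicon length (shortest first) then by
#' forward-primer position (closest to the region first).
#'
#' @param region one row of a `variable_regions` data.frame (keep the
#'   attribute-carrying subset, e.g. `regions[1, ]` is fine: pass `regions`
#'   and `which` instead).
#' @param regions a `variable_regions` data.frame.
#' @param which region row index or label.
#' @param x the [msa()] object.
#' @param constraints a [primer_constraints()].
#' @param guides optional `guide_candidates`; covered guide ids are recorded
#'   per pair.
#' @param max_pairs maximum number of pairs returned (default 10).
#' @param max_windows_per_side cap on candidate windows considered per flank,
#'   taken nearest the region (default 200); bounds the pairing search
#'   without affecting the top-ranked pairs in practice.
#' @return a `primer_pairs` data.frame: `kind`, `fwd_seq`, `rev_seq`,
#'   `fwd_start`/`fwd_end`/`rev_start`/`rev_end` (alignment columns),
#'   `max_amplicon`, plus list-columns `amplicons` (per species: binding
#'   coordinates and amplicon length in ungapped coordinates) and
#'   `covered_guides`. When empty, attribute `"diagnostic"` states which
#'   constraint eliminated all candidates.
#' @export
design_universal_primers <- function(regions, which = 1L, x,
                                     constraints = primer_constraints(),
                                     guides = NULL, max_pairs = 10L,
                                     max_windows_per_side = 200L) {
  stopifnot(inherits(x, "msa"))
  region <- regions[if (is.character(which)) match(which, regions$label)
                    else which, ]
  if (nrow(region) != 1L || is.na(region$start)) {
    stop("no such region", call. = FALSE)
  }
  if (is.na(region$left_flank_start) || is.na(region$right_flank_start)) {
    stop("region '", region$label, "' lacks a conserved flank; universal ",
         "primers need both", call. = FALSE)
  }
  drops <- new_drops()
  consensus <- x$seqs[[1]]  # flank columns are identical across species
  lf <- c(region$left_flank_start, region$left_flank_end)
  rf <- c(region$right_flank_start, region$right_flank_end)
  if (lf[2] - lf[1] + 1L < constraints$min_len ||
      rf[2] - rf[1] + 1L < constraints$min_len) {
    drops$flank_too_short <- 1L
    return(empty_pairs(paste0("flank too short: left ", lf[2] - lf[1] + 1L,
                              ", right ", rf[2] - rf[1] + 1L,
                              " columns < min primer length ",
                              constraints$min_len)))
  }
  # only windows within max_amplicon columns of the region can form a valid
  # pair (flank columns are gap-free in every species, so the ungapped
  # distance to the region is at least the column distance)
  lf[1] <- max(lf[1], lf[2] - constraints$max_amplicon + 1L)
  rf[2] <- min(rf[2], rf[1] + constraints$max_amplicon - 1L)
  fwd <- enumerate_windows(consensus, lf[1], lf[2], constraints, drops)
  rev_ <- enumerate_windows(consensus, rf[1], rf[2], constraints, drops)
  if (nrow(fwd) == 0L || nrow(rev_) == 0L) {
    return(empty_pairs(drops_diagnostic(drops)))
  }
  # the ranking prefers short amplicons and region-proximal primers, so the
  # top pairs come from the windows nearest the region; cap each side there
  if (nrow(fwd) > max_windows_per_side) {
    fwd <- fwd[order(-fwd$start, fwd$end), ][seq_len(max_windows_per_side), ]
  }
  if (nrow(rev_) > max_windows_per_side) {
    rev_ <- rev_[order(rev_$end, rev_$start), ][seq_len(max_windows_per_side), ]
  }
  # per-species amplicon lengths for every (fwd, rev) combination: conserved
  # flank columns map to consecutive ungapped positions in every species
  fs_by_sp <- lapply(x$ids, function(sp) x$col2pos[[sp]][fwd$start])
  re_by_sp <- lapply(x$ids, function(sp) x$col2pos[[sp]][rev_$end])
  valid <- matrix(TRUE, nrow(fwd), nrow(rev_))
  max_amp <- matrix(-Inf, nrow(fwd), nrow(rev_))
  for (k in seq_along(x$ids)) {
    amp <- outer(-fs_by_sp[[k]], re_by_sp[[k]], `+`) + 1L
    valid <- valid & amp >= constraints$min_amplicon &
      amp <= constraints$max_amplicon
    max_amp <- pmax(max_amp, amp)
  }
  drops$amplicon <- sum(!valid)
  if (!any(valid)) return(empty_pairs(drops_diagnostic(drops)))
  idx <- which(valid, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  ord <- order(max_amp[valid], -fwd$start[i], rev_$end[j], method = "radix")
  take <- ord[seq_len(min(length(ord), max_pairs))]
  i <- i[take]; j <- j[take]
  out <- data.frame(kind = "universal", fwd_seq = fwd$seq[i],
                    rev_seq = revcomp(rev_$seq[j]),
                    fwd_start = fwd$start[i], fwd_end = fwd$end[i],
                    rev_start = rev_$start[j], rev_end = rev_$end[j],
                    max_amplicon = as.integer(max_amp[valid][take]),
                    stringsAsFactors = FALSE)
  out$amplicons <- lapply(seq_along(i), function(q) {
    do.call(rbind, lapply(seq_along(x$ids), function(k) {
      fs <- fs_by_sp[[k]][i[q]]; re <- re_by_sp[[k]][j[q]]
      data.frame(species = x$ids[k], fwd_start = fs, rev_end = re,
                 amplicon_len = re - fs + 1L, stringsAsFactors = FALSE)
    }))
  })
  out$covered_guides <- lapply(seq_along(i), function(q) {
    amps <- out$amplicons[[q]]
    unique(unlist(lapply(seq_len(nrow(amps)), function(k) {
      guides_in_amplicon(guides, amps$species[k], amps$fwd_start[k],
                         amps$rev_end[k])
    })))
  })
  rownames(out) <- NULL
  class(out) <- c("primer_pairs", "data.frame")
  out
}

#' Design species-specific primer pairs inside a variable region
#'
#' Enumerates primer windows within the named species' ungapped
#' variable-region sequence and keeps only windows that mismatch every other
#' species (at least one substitution or indel over the mapped alignment
#' window). Pairs must satisfy GC, homopolymer and amplicon constraints and,
#' when guide candidates are supplied, must flank at least one guide window
#' for this species. Ranked as in [design_universal_primers()].
#'
#' @inheritParams design_universal_primers
#' @param species the target species id.
#' @return a `primer_pairs` data.frame as in [design_universal_primers()],
#'   with `kind == "specific"`, coordinates in the target species' ungapped
#'   sequence, and a `discrimination` list-column (per pair: for each primer
#'   and non-target species the mismatch count and whether an indel is
#'   involved).
#' @export
design_specific_primers <- function(regions, which = 1L, species, x,
                                    constraints = primer_constraints(),
                                    guides = NULL, max_pairs = 10L) {
  stopifnot(inherits(x, "msa"))
  idx <- if (is.character(which)) match(which, regions$label) else which
  region <- regions[idx, ]
  if (nrow(region) != 1L || is.na(region$start)) {
    stop("no such region", call. = FALSE)
  }
  if (!species %in% x$ids) stop("species '", species, "' not in alignment",
                                call. = FALSE)
  proj <- attr(regions, "projections")[[idx]]
  prow <- proj[proj$species == species, ]
  if (prow$end < prow$start) {
    return(empty_pairs(paste0("region ", region$label, " is empty in species ",
                              species)))
  }
  drops <- new_drops()
  oseq <- ungapped_seq(x, species)
  wins <- enumerate_windows(oseq, prow$start, prow$end, constraints, drops)
  if (nrow(wins) == 0L) return(empty_pairs(drops_diagnostic(drops)))

  # per-column discrimination indicators over the region span, cumsum'd for
  # O(1) queries per window: a window discriminates against a species when
  # its mapped alignment span holds >= 1 substitution or any gap
  others <- setdiff(x$ids, species)
  p2c <- x$pos2col[[species]]
  span <- p2c[prow$start]:p2c[prow$end]
  ochars <- x$mat[species, span]
  cum_mm <- list(); cum_gap <- list()
  for (sp in others) {
    tchars <- x$mat[sp, span]
    mm <- tchars != ochars & tchars != "-" & ochars != "-"
    gap <- tchars == "-" | ochars == "-"
    cum_mm[[sp]] <- c(0L, cumsum(mm))
    cum_gap[[sp]] <- c(0L, cumsum(gap))
  }
  span0 <- span[1] - 1L
  c1 <- p2c[wins$start] - span0                     # local column indices
  c2 <- p2c[wins$end] - span0
  disc <- vector("list", nrow(wins))
  keep <- rep(TRUE, nrow(wins))
  nm_mat <- matrix(0L, nrow(wins), length(others),
                   dimnames = list(NULL, others))
  gap_mat <- matrix(FALSE, nrow(wins), length(others),
                    dimnames = list(NULL, others))
  for (sp in others) {
    nm_mat[, sp] <- cum_mm[[sp]][c2 + 1L] - cum_mm[[sp]][c1]
    gap_mat[, sp] <- (cum_gap[[sp]][c2 + 1L] - cum_gap[[sp]][c1]) > 0L
    keep <- keep & (nm_mat[, sp] >= 1L | gap_mat[, sp])
  }
  drops$not_discriminating <- sum(!keep)
  for (i in which(keep)) {
    disc[[i]] <- data.frame(species = others, n_mismatch = nm_mat[i, ],
                            has_indel = gap_mat[i, ], row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  wins <- wins[keep, , drop = FALSE]
  disc <- disc[keep]
  if (nrow(wins) == 0L) return(empty_pairs(drops_diagnostic(drops)))

  region_guides <- if (!is.null(guides) && nrow(guides) > 0L) {
    guides[guides$species == species & guides$region == region$label, ,
           drop = FALSE]
  } else NULL

  # vectorised pairing: rev must lie strictly right of fwd, amplicon within
  # bounds, and (when guides are given) at least one guide strictly between
  # the primers
  amp <- outer(-wins$start, wins$end, `+`) + 1L          # fwd i x rev j
  valid <- outer(wins$end, wins$start, `<`) &
    amp >= constraints$min_amplicon & amp <= constraints$max_amplicon
  if (!is.null(region_guides)) {
    flanked <- matrix(FALSE, nrow(wins), nrow(wins))
    for (i in seq_len(nrow(wins))) {
      g <- region_guides[region_guides$win_start > wins$end[i], ]
      if (nrow(g) == 0L) next
      flanked[i, ] <- wins$start > min(g$win_end)
    }
    drops$no_guide_flanked <- sum(valid & !flanked)
    valid <- valid & flanked
  }
  drops$amplicon <- sum(amp < constraints$min_amplicon |
                        amp > constraints$max_amplicon)
  if (!any(valid)) return(empty_pairs(drops_diagnostic(drops)))
  idx <- which(valid, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  ord <- order(amp[valid], -wins$start[i], wins$end[j], method = "radix")
  take <- ord[seq_len(min(length(ord), max_pairs))]
  i <- i[take]; j <- j[take]
  out <- data.frame(kind = "specific", fwd_seq = wins$seq[i],
                    rev_seq = revcomp(wins$seq[j]),
                    fwd_start = wins$start[i], fwd_end = wins$end[i],
                    rev_start = wins$start[j], rev_end = wins$end[j],
                    max_amplicon = as.integer(amp[valid][take]),
                    stringsAsFactors = FALSE)
  out$amplicons <- lapply(seq_along(i), function(q) {
    data.frame(species = species, fwd_start = out$fwd_start[q],
               rev_end = out$rev_end[q], amplicon_len = out$max_amplicon[q],
               stringsAsFactors = FALSE)
  })
  out$covered_guides <- lapply(seq_along(i), function(q) {
    if (is.null(region_guides)) character(0)
    else region_guides$guide_id[region_guides$win_start > out$fwd_end[q] &
                                region_guides$win_end < out$rev_start[q]]
  })
  out$discrimination <- lapply(seq_along(i), function(q) {
    list(fwd = disc[[i[q]]], rev = disc[[j[q]]])
  })
  rownames(out) <- NULL
  class(out) <- c("primer_pairs", "data.frame")
  out
}
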