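# Conservation profiling, variable-region calling and construction of the
# linker-concatenated guide-design template.
#
# A column is conserved only when every species carries the same concrete
# residue and none is gapped: universal primers must match all species
# perfectly, so the flank definition is strict identity. Gap columns count as
# divergence (indels are diagnostic signal).

#' Default linker for template concatenation
#'
#' A 20-nt purine repeat containing no TTTV PAM on either strand, used to
#' separate per-species variable-region sequences so no guide can be selected
#' across a stitch point.
#' @export
DEFAULT_LINKER <- "GAGAGAGAGAGAGAGAGAGA"

#' Per-column conservation profile of an alignment
#'
#' For every alignment column, `identity_fraction` is the count of the most
#' common non-gap residue divided by the number of species (gaps count as a
#' mismatching symbol class, so a column that is half gaps can score at most
#' 0.5), and `is_conserved` is TRUE only when all species share one identical
#' non-gap residue.
#'
#' @param x an [msa()] object.
#' @return a data.frame of class `conservation_profile` with columns `column`,
#'   `identity_fraction`, `is_conserved`.
#' @export
conservation_profile <- function(x) {
  stopifnot(inherits(x, "msa"))
  mat <- x$mat
  n <- nrow(mat)
  symbols <- setdiff(unique(as.vector(mat)), "-")
  if (length(symbols) == 0L) {
    top <- rep(0L, ncol(mat))
  } else {
    counts <- vapply(symbols, function(s) .colSums(mat == s, n, ncol(mat)),
                     numeric(ncol(mat)))
    counts <- matrix(counts, ncol = length(symbols))
    top <- apply(counts, 1, max)
  }
  identity_fraction <- top / n
  is_conserved <- identity_fraction == 1
  out <- data.frame(column = seq_len(ncol(mat)),
                    identity_fraction = identity_fraction,
                    is_conserved = is_conserved)
  class(out) <- c("conservation_profile", "data.frame")
  attr(out, "n_species") <- n
  out
}

#' Maximal conserved blocks of minimum length
#'
#' Finds all maximal runs of conserved columns (strict identity, no gaps) at
#' least `min_len` columns long, in positional order. The default of 30
#' columns is the minimum footprint for a universal RPA primer.
#'
#' @param profile a [conservation_profile()].
#' @param min_len minimum block length in columns (default 30).
#' @return data.frame with columns `start`, `end` (1-based closed), `length`.
#' @export
find_conserved_blocks <- function(profile, min_len = 30L) {
  stopifnot(inherits(profile, "conservation_profile"), min_len >= 1L)
  r <- rle(profile$is_conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep])
  rownames(out) <- NULL
  out
}

#' Call variable regions between conserved blocks
#'
#' A variable region is the stretch of columns between two consecutive
#' qualifying conserved blocks, kept when it is no longer than `max_vr_len`
#' columns and its divergence (1 minus mean identity fraction) reaches
#' `min_divergence`. Regions are labelled "VR1", "VR2", ... left to right and
#' carry their projections onto every species' ungapped coordinates.
#' Stretches at the alignment ends lack one flank and are only emitted with
#' `allow_terminal_regions = TRUE`, since universal amplification requires
#' primers on both sides.
#'
#' @param x an [msa()] object.
#' @param profile optional precomputed [conservation_profile()].
#' @param blocks optional precomputed [find_conserved_blocks()] result.
#' @param min_flank minimum conserved flank length in columns (default 30).
#' @param max_vr_len maximum region length in columns (default 500).
#' @param min_divergence minimum divergence over the region (default 0.05).
#' @param allow_terminal_regions emit regions missing one flank at the
#'   alignment ends (default FALSE).
#' @return a data.frame of class `variable_regions` with columns `label`,
#'   `start`, `end`, `length`, `divergence`, `left_flank_start`,
#'   `left_flank_end`, `right_flank_start`, `right_flank_end` (NA for a
#'   missing terminal flank), plus a `projections` attribute: one data.frame
#'   (`species`, `start`, `end`) per region in ungapped coordinates.
#' @export
find_variable_regions <- function(x, profile = NULL, blocks = NULL,
                                  min_flank = 30L, max_vr_len = 500L,
                                  min_divergence = 0.05,
                                  allow_terminal_regions = FALSE) {
  stopifnot(inherits(x, "msa"))
  if (is.null(profile)) profile <- conservation_profile(x)
  if (is.null(blocks)) blocks <- find_conserved_blocks(profile, min_flank)

  empty <- function() {
    out <- data.frame(label = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      divergence = numeric(0),
                      left_flank_start = integer(0), left_flank_end = integer(0),
                      right_flank_start = integer(0), right_flank_end = integer(0))
    class(out) <- c("variable_regions", "data.frame")
    attr(out, "projections") <- list()
    out
  }
  if (nrow(blocks) == 0L) return(empty())

  # candidate gaps: between consecutive blocks, plus terminal stretches
  cand <- list()
  for (i in seq_len(nrow(blocks) - 1L)) {
    cand[[length(cand) + 1L]] <- list(start = blocks$end[i] + 1L,
                                      end = blocks$start[i + 1L] - 1L,
                                      left = i, right = i + 1L)
  }
  if (allow_terminal_regions) {
    if (blocks$start[1] > 1L) {
      cand[[length(cand) + 1L]] <- list(start = 1L, end = blocks$start[1] - 1L,
                                        left = NA_integer_, right = 1L)
    }
    if (blocks$end[nrow(blocks)] < x$ncols) {
      cand[[length(cand) + 1L]] <- list(start = blocks$end[nrow(blocks)] + 1L,
                                        end = x$ncols, left = nrow(blocks),
                                        right = NA_integer_)
    }
  }
  if (length(cand) == 0L) return(empty())
  cand <- cand[order(vapply(cand, `[[`, integer(1), "start"))]

  rows <- list()
  projections <- list()
  for (cd in cand) {
    len <- cd$end - cd$start + 1L
    if (len < 1L || len > max_vr_len) next
    divergence <- 1 - mean(profile$identity_fraction[cd$start:cd$end])
    if (divergence < min_divergence) next
    rows[[length(rows) + 1L]] <- data.frame(
      label = NA_character_, start = cd$start, end = cd$end, length = len,
      divergence = divergence,
      left_flank_start = if (is.na(cd$left)) NA_integer_ else blocks$start[cd$left],
      left_flank_end = if (is.na(cd$left)) NA_integer_ else blocks$end[cd$left],
      right_flank_start = if (is.na(cd$right)) NA_integer_ else blocks$start[cd$right],
      right_flank_end = if (is.na(cd$right)) NA_integer_ else blocks$end[cd$right])
    proj <- do.call(rbind, lapply(x$ids, function(sp) {
      pe <- project_interval(x, sp, cd$start, cd$end)
      data.frame(species = sp, start = pe[1], end = pe[2],
                 stringsAsFactors = FALSE)
    }))
    projections[[length(projections) + 1L]] <- proj
  }
  if (length(rows) == 0L) return(empty())
  out <- do.call(rbind, rows)
  out$label <- paste0("VR", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("variable_regions", "data.frame")
  attr(out, "projections") <- projections
  out
}

#' Build the linker-concatenated guide-design template
#'
#' Joins every species' ungapped variable-region sequence (species-major: all
#' regions of species 1, then species 2, ...) with a fixed PAM-free linker, so
#' guides can be enumerated once over a single sequence while never spanning a
#' stitch between two source fragments. Junction intervals cover each linker
#' occurrence; provenance maps every template interval back to its
#' (species, region, species-local interval) origin.
#'
#' @param regions a `variable_regions` data.frame from
#'   [find_variable_regions()].
#' @param x the [msa()] the regions were called on.
#' @param linker linker sequence; must contain no PAM match (pattern
#'   `pam_pattern`) on either strand.
#' @param pam_pattern IUPAC PAM pattern used to vet the linker (default
#'   "TTTV").
#' @return an object of class `concat_template`: list with `sequence`,
#'   `junctions` (data.frame `start`,`end`, 1-based closed), `provenance`
#'   (data.frame `t_start`,`t_end`,`species`,`label`,`s_start`,`s_end`) and
#'   `linker`.
#' @export
build_concatenated_template <- function(regions, x, linker = DEFAULT_LINKER,
                                        pam_pattern = "TTTV") {
  stopifnot(inherits(x, "msa"))
  if (nrow(regions) == 0L) stop("no regions to concatenate", call. = FALSE)
  if (length(iupac_match_positions(linker, pam_pattern)) > 0L ||
      length(iupac_match_positions(revcomp(linker), pam_pattern)) > 0L) {
    stop("linker contains a '", pam_pattern, "' PAM on one strand; ",
         "choose a PAM-free linker", call. = FALSE)
  }
  projections <- attr(regions, "projections")
  pieces <- list()
  for (sp in x$ids) {
    for (i in seq_len(nrow(regions))) {
      cols <- regions$start[i]:regions$end[i]
      seq <- paste(x$mat[sp, cols][x$mat[sp, cols] != "-"], collapse = "")
      if (nchar(seq) == 0L) next  # species fully gapped over this region
      proj <- projections[[i]]
      row <- proj[proj$species == sp, ]
      pieces[[length(pieces) + 1L]] <- list(species = sp,
                                            label = regions$label[i],
                                            seq = seq,
                                            s_start = row$start,
                                            s_end = row$end)
    }
  }
  if (length(pieces) == 0L) stop("all regions are empty in every species",
                                 call. = FALSE)
  template <- character(0)
  junctions <- list()
  provenance <- list()
  pos <- 0L
  lk <- nchar(linker)
  for (j in seq_along(pieces)) {
    if (j > 1L) {
      junctions[[length(junctions) + 1L]] <- data.frame(start = pos + 1L,
                                                        end = pos + lk)
      template <- c(template, linker)
      pos <- pos + lk
    }
    p <- pieces[[j]]
    provenance[[length(provenance) + 1L]] <- data.frame(
      t_start = pos + 1L, t_end = pos + nchar(p$seq),
      species = p$species, label = p$label,
      s_start = p$s_start, s_end = p$s_end, stringsAsFactors = FALSE)
    template <- c(template, p$seq)
    pos <- pos + nchar(p$seq)
  }
  structure(list(
    sequence = paste(template, collapse = ""),
    junctions = if (length(junctions)) do.call(rbind, junctions)
                else data.frame(start = integer(0), end = integer(0)),
    provenance = do.call(rbind, provenance),
    linker = linker
  ), class = "concat_template")
}

#' @export
print.concat_template <- function(x, ...) {
  cat("Concatenated guide-design template: ", nchar(x$sequence), " nt, ",
      nrow(x$provenance), " fragment(s), ", nrow(x$junctions),
      " linker junction(s)\n", sep = "")
  invisible(x)
}
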