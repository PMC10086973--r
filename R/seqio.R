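# Sequence and alignment I/O.
#
# FASTA parsing and writing go through Biostrings; this module adds the
# validation contracts (IUPAC-only residues, unique ids, equal-length
# alignments) and the bidirectional coordinate maps between alignment columns
# and each species' ungapped sequence.

VALID_RESIDUES <- c(IUPAC_CHARS)
VALID_ALN_RESIDUES <- c(IUPAC_CHARS, "-")

#' Read a FASTA file of nucleotide sequences
#'
#' Residues are uppercased and validated against the IUPAC nucleotide
#' alphabet. Record ids (the first whitespace-delimited token of each header)
#' must be unique and non-empty.
#'
#' @param path path to a FASTA file.
#' @param allow_gaps allow `-`/`.` gap characters (used by
#'   [read_alignment()]); `.` is normalised to `-`.
#' @return a data.frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("record ", which(!nzchar(ids))[1], " in '", path,
         "' has an empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate record id '", dup, "' in '", path, "'", call. = FALSE)
  }
  residues <- toupper(as.character(set))
  residues <- gsub("[ \t\r]", "", residues)
  if (allow_gaps) residues <- gsub("\\.", "-", residues)
  allowed <- if (allow_gaps) VALID_ALN_RESIDUES else VALID_RESIDUES
  for (i in seq_along(residues)) {
    chars <- unique(strsplit(residues[i], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L) {
      stop("record '", ids[i], "' (record ", i, ") in '", path,
           "' contains non-IUPAC character(s): ",
           paste(bad, collapse = " "), call. = FALSE)
    }
  }
  data.frame(id = unname(ids), description = unname(descriptions),
             residues = unname(residues), stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records a data.frame as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          residues = unname(records), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "residues") %in% names(records)))
  headers <- records$id
  desc <- records$description %||% rep("", nrow(records))
  headers <- ifelse(nzchar(desc), paste(headers, desc), headers)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' Validates that all rows have equal length, builds the per-species character
#' matrix and the bidirectional coordinate maps between alignment columns and
#' ungapped positions.
#'
#' @param records a data.frame (`id`, `description`, `residues`) or a named
#'   character vector of equal-length gapped sequences.
#' @return an object of class `msa` with elements `ids`, `descriptions`,
#'   `seqs` (gapped, named), `ncols`, `mat` (species x column character
#'   matrix), `col2pos` (per species: alignment column -> ungapped position,
#'   `NA` at gaps) and `pos2col` (per species: ungapped position -> column).
#' @export
msa <- function(records) {
  if (is.character(records)) {
    records <- data.frame(id = names(records) %||% paste0("seq", seq_along(records)),
                          description = "",
                          residues = toupper(unname(records)),
                          stringsAsFactors = FALSE)
  }
  if (nrow(records) < 2L) {
    stop("an alignment needs at least 2 sequences, got ", nrow(records),
         call. = FALSE)
  }
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows have unequal lengths (",
         paste(paste0(records$id, "=", lens), collapse = ", "),
         "); not a valid alignment", call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    stop("duplicate species id '", records$id[duplicated(records$id)][1], "'",
         call. = FALSE)
  }
  ncols <- lens[1]
  mat <- do.call(rbind, strsplit(records$residues, ""))
  rownames(mat) <- records$id
  col2pos <- lapply(seq_len(nrow(mat)), function(i) {
    nongap <- mat[i, ] != "-"
    p <- rep(NA_integer_, ncols)
    p[nongap] <- seq_len(sum(nongap))
    p
  })
  pos2col <- lapply(col2pos, function(p) which(!is.na(p)))
  names(col2pos) <- names(pos2col) <- records$id
  structure(list(
    ids = records$id,
    descriptions = records$description %||% rep("", nrow(records)),
    seqs = stats::setNames(records$residues, records$id),
    ncols = ncols,
    mat = mat,
    col2pos = col2pos,
    pos2col = pos2col
  ), class = "msa")
}

#' Read an aligned FASTA file as an `msa`
#'
#' Accepts both `-` and `.` gap characters (`.` is normalised to `-`); all
#' records must have identical length.
#'
#' @param path path to an aligned FASTA file.
#' @return an [msa()] object.
#' @export
read_alignment <- function(path) {
  msa(read_fasta(path, allow_gaps = TRUE))
}

#' Write an `msa` to aligned FASTA
#' @param x an [msa()] object.
#' @param path output path.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  write_fasta(data.frame(id = x$ids, description = x$descriptions,
                         residues = unname(x$seqs), stringsAsFactors = FALSE),
              path)
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", length(x$ids), " species x ",
      x$ncols, " columns\n", sep = "")
  for (id in x$ids) {
    cat("  ", id, " (", sum(x$mat[id, ] != "-"), " nt ungapped)\n", sep = "")
  }
  invisible(x)
}

#' Ungapped sequence of one species in an alignment
#' @param x an [msa()] object.
#' @param species species id.
#' @return the species' ungapped sequence as a single string.
#' @export
ungapped_seq <- function(x, species) {
  stopifnot(inherits(x, "msa"))
  if (!species %in% x$ids) stop("species '", species, "' not in alignment",
                                call. = FALSE)
  gsub("-", "", x$seqs[[species]])
}

# Project a closed column interval [start, end] onto one species' ungapped
# coordinates. Returns c(start, end); when the species is all-gap over the
# interval the projection is empty and end == start - 1 (the insertion point).
project_interval <- function(x, species, start, end) {
  p <- x$col2pos[[species]][start:end]
  p <- p[!is.na(p)]
  if (length(p) == 0L) {
    before <- x$col2pos[[species]][seq_len(start - 1L)]
    before <- before[!is.na(before)]
    at <- if (length(before)) max(before) + 1L else 1L
    return(c(at, at - 1L))
  }
  c(min(p), max(p))
}

#' Export variable regions as a BED6 file for one species
#'
#' Intervals are the regions' projections onto the named species' ungapped
#' coordinates, written 0-based half-open per the BED convention, with the
#' region label in the name column and strand `+`. Regions with an empty
#' projection in this species are skipped.
#'
#' @param regions a `variable_regions` data.frame from
#'   [find_variable_regions()].
#' @param species species id to project onto.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, species, path) {
  projections <- attr(regions, "projections")
  if (is.null(projections)) {
    stop("regions carry no per-species projections; run find_variable_regions()",
         call. = FALSE)
  }
  lines <- character(0)
  for (i in seq_len(nrow(regions))) {
    proj <- projections[[i]]
    row <- proj[proj$species == species, , drop = FALSE]
    if (nrow(row) == 0L) {
      stop("species '", species, "' absent from region projections",
           call. = FALSE)
    }
    if (row$end < row$start) next  # empty projection in this species
    lines <- c(lines, paste(species, row$start - 1L, row$end,
                            regions$label[i], 0L, "+", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
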