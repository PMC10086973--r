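# Ground-truth synthetic species panels.
#
# Emulates the toolkit's intended input: a set of long, near-identical marker
# sequences (e.g. mitochondrial genomes of sibling species) that are fully
# conserved except for planted variable regions of elevated substitution and
# indel density. The alignment is emitted from the known edit history -- it
# is never re-aligned -- so region coordinates in the truth are exact and
# tests are independent of any aligner.
#
# Ground-truth contract: each planted region's first and last columns are
# guaranteed divergent, and no internal run of conserved columns reaches
# `max_conserved_run` (default 25). Planted intervals are therefore exactly
# the variable regions recoverable at any flank threshold above
# `max_conserved_run`; without the guarantee, chance conservation inside a
# region could split it and no caller could recover the planted coordinates.

#' Specification of a synthetic species panel
#'
#' @param n_species number of species (>= 2). Species 1 is the unmutated
#'   backbone.
#' @param backbone_len length of the shared backbone in nt.
#' @param n_regions number of planted variable regions.
#' @param flank_len minimum run of conserved columns between / around regions.
#' @param vr_len_range length range (min, max) of each planted region.
#' @param vr_substitution_rate per-column, per-species substitution
#'   probability inside regions.
#' @param vr_indel_rate per-column, per-species indel initiation probability
#'   inside regions (split evenly between insertions and deletions;
#'   geometric lengths, mean 2).
#' @param background_substitution_rate substitution rate outside regions
#'   (default 0, keeping the backbone conserved).
#' @param max_conserved_run planted regions are post-processed so no internal
#'   conserved run reaches this many columns and both boundary columns are
#'   divergent (default 25; must stay below the flank threshold used for
#'   region calling).
#' @param min_region_divergence guaranteed realised divergence (1 minus mean
#'   column identity) of every planted region (default 0.08, comfortably
#'   above the region caller's 0.05 floor, as congeneric mitochondrial
#'   markers are in practice); extra substitutions are forced when the
#'   random draw falls short.
#' @param rng_seed integer seed; the panel is a pure function of the spec.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(n_species = 2L, backbone_len = 4000L, n_regions = 2L,
                       flank_len = 40L, vr_len_range = c(150L, 300L),
                       vr_substitution_rate = 0.15, vr_indel_rate = 0.02,
                       background_substitution_rate = 0,
                       max_conserved_run = 25L, min_region_divergence = 0.08,
                       rng_seed = 1L) {
  stopifnot(n_species >= 2L, n_regions >= 0L, flank_len >= 1L,
            length(vr_len_range) == 2L, vr_len_range[1] <= vr_len_range[2],
            vr_substitution_rate >= 0,
            vr_substitution_rate <= 1, vr_indel_rate >= 0, vr_indel_rate < 1,
            background_substitution_rate >= 0,
            background_substitution_rate < 1, max_conserved_run >= 2L,
            min_region_divergence >= 0, min_region_divergence < 1)
  need <- n_regions * vr_len_range[2] + (n_regions + 1L) * flank_len
  if (need > backbone_len) {
    stop("infeasible panel: ", n_regions, " regions of up to ",
         vr_len_range[2], " nt plus ", n_regions + 1L, " flanks of ",
         flank_len, " nt need ", need, " nt > backbone_len ", backbone_len,
         call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species),
                 backbone_len = as.integer(backbone_len),
                 n_regions = as.integer(n_regions),
                 flank_len = as.integer(flank_len),
                 vr_len_range = as.integer(vr_len_range),
                 vr_substitution_rate = vr_substitution_rate,
                 vr_indel_rate = vr_indel_rate,
                 background_substitution_rate = background_substitution_rate,
                 max_conserved_run = as.integer(max_conserved_run),
                 min_region_divergence = min_region_divergence,
                 rng_seed = as.integer(rng_seed)),
            class = "panel_spec")
}

BASES <- c("A", "C", "G", "T")

# substitute to a uniformly chosen different base
other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

#' Generate a synthetic species panel with exact ground truth
#'
#' Draws a uniform-ACGT backbone, plants `n_regions` variable regions
#' (species 2..n mutate independently inside them; species 1 keeps the
#' backbone), builds the alignment from the edit history, and returns the
#' sequences, the alignment and the truth (planted region intervals in
#' alignment coordinates). Deterministic given `rng_seed`.
#'
#' @param spec a [panel_spec()].
#' @return an object of class `panel`: list with `spec`, `sequences` (named
#'   ungapped strings), `msa` (an [msa()]), and `truth` (list with `regions`:
#'   data.frame `label`,`start`,`end` in alignment columns, and
#'   `planted_sites`, filled by [plant_discriminating_site()]).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  withr::with_seed(spec$rng_seed, generate_panel_impl(spec))
}

generate_panel_impl <- function(spec) {
  n_sp <- spec$n_species
  L <- spec$backbone_len
  ids <- paste0("sp", seq_len(n_sp))

  # layout: flank, region, flank, ..., region, flank; spacers >= flank_len
  lens <- if (spec$n_regions > 0L) {
    sample(spec$vr_len_range[1]:spec$vr_len_range[2], spec$n_regions,
           replace = TRUE)
  } else integer(0)
  # distribute the slack over the n_regions leading spacers (the tail after
  # the last region absorbs the remainder and stays >= flank_len)
  extra <- L - sum(lens) - (spec$n_regions + 1L) * spec$flank_len
  cuts <- sort(sample.int(extra + 1L, spec$n_regions, replace = TRUE) - 1L)
  spacers <- spec$flank_len + diff(c(0L, cuts))
  region_start <- integer(spec$n_regions)
  pos <- 0L
  for (r in seq_len(spec$n_regions)) {
    pos <- pos + spacers[r]
    region_start[r] <- pos + 1L
    pos <- pos + lens[r]
  }
  regions_bb <- data.frame(start = region_start,
                           end = region_start + lens - 1L)

  backbone <- sample(BASES, L, replace = TRUE)
  in_region <- rep(FALSE, L)
  for (r in seq_len(spec$n_regions)) {
    in_region[regions_bb$start[r]:regions_bb$end[r]] <- TRUE
  }

  # per-species edits relative to the backbone; species 1 = backbone
  # base_char[s, i]: residue at backbone position i ('-' if deleted);
  # ins[[s]][[i]]: bases inserted after position i
  base_char <- matrix(rep(backbone, each = n_sp), nrow = n_sp)
  ins <- lapply(seq_len(n_sp), function(s) vector("list", L))
  for (s in seq(2L, n_sp)) {
    mut_pos <- which(in_region & stats::runif(L) < spec$vr_substitution_rate)
    if (spec$background_substitution_rate > 0) {
      mut_pos <- union(mut_pos, which(!in_region &
        stats::runif(L) < spec$background_substitution_rate))
    }
    if (length(mut_pos)) {
      base_char[s, mut_pos] <- other_base(backbone[mut_pos])
    }
    if (spec$vr_indel_rate > 0) {
      del_pos <- which(in_region & stats::runif(L) < spec$vr_indel_rate / 2)
      for (p in del_pos) {
        dlen <- stats::rgeom(1L, 0.5) + 1L
        dend <- min(p + dlen - 1L, L)
        # deletions stay inside the region they started in
        r <- which(regions_bb$start <= p & regions_bb$end >= p)
        if (length(r)) dend <- min(dend, regions_bb$end[r])
        base_char[s, p:dend] <- "-"
      }
      ins_pos <- which(in_region & stats::runif(L) < spec$vr_indel_rate / 2)
      for (p in ins_pos) {
        ilen <- stats::rgeom(1L, 0.5) + 1L
        ins[[s]][[p]] <- sample(BASES, ilen, replace = TRUE)
      }
    }
  }

  # ground-truth guarantee: the region's first and last alignment columns are
  # divergent and no internal conserved run reaches max_conserved_run. Only a
  # substitution or deletion makes a base column itself divergent; an
  # insertion breaks a run between base columns (and, at the region end,
  # extends the truth interval with already-divergent insertion columns).
  # Skipped for the fully-degenerate control (both rates zero), whose
  # contract is that the species stay identical.
  n_ins_after <- integer(L)
  for (s in seq_len(n_sp)) {
    n_ins_after <- n_ins_after + lengths(ins[[s]])
  }
  varied_base <- colSums(base_char != matrix(rep(backbone, each = n_sp),
                                             nrow = n_sp)) > 0L
  varied <- varied_base | n_ins_after > 0L
  if (spec$vr_substitution_rate > 0 || spec$vr_indel_rate > 0) {
    force_sub <- function(p) {
      sp <- if (n_sp == 2L) 2L else sample(2:n_sp, 1L)
      base_char[sp, p] <<- other_base(backbone[p])
      varied_base[p] <<- TRUE
      varied[p] <<- TRUE
    }
    for (r in seq_len(spec$n_regions)) {
      a <- regions_bb$start[r]; b <- regions_bb$end[r]
      if (!varied_base[a]) force_sub(a)
      if (!varied_base[b] && n_ins_after[b] == 0L) force_sub(b)
      repeat {
        runs <- rle(varied[a:b])
        bad <- which(!runs$values & runs$lengths >= spec$max_conserved_run)
        if (length(bad) == 0L) break
        ends <- cumsum(runs$lengths)
        for (k in bad) {
          mid <- a - 1L + ends[k] - runs$lengths[k] %/% 2L
          force_sub(mid)
        }
      }
      # realised-divergence floor: a marginal random draw must not leave the
      # planted region below the divergence callers screen at
      repeat {
        ident <- vapply(a:b, function(p) {
          col <- base_char[, p]
          nongap <- col[col != "-"]
          if (length(nongap)) max(table(nongap)) / n_sp else 0
        }, numeric(1))
        deficit <- spec$min_region_divergence - (1 - mean(ident))
        if (deficit <= 0) break
        open <- which(!varied_base[a:b]) + a - 1L
        if (length(open) == 0L) break      # saturated; cannot diverge more
        need <- min(length(open),
                    ceiling(deficit * (b - a + 1L) * n_sp) + 1L)
        picked <- if (length(open) == 1L) open else sample(open, need)
        for (p in picked) force_sub(p)
      }
    }
  }

  # assemble alignment: base column for position i, then each species'
  # insertion block (inserted bases are not homologous across species)
  ncols <- L + sum(n_ins_after)
  mat <- matrix("-", nrow = n_sp, ncol = ncols)
  ins_before <- cumsum(c(0L, n_ins_after[-L]))
  base_col <- seq_len(L) + ins_before
  mat[, base_col] <- base_char
  for (s in seq_len(n_sp)) {
    has_ins <- which(lengths(ins[[s]]) > 0L)
    for (p in has_ins) {
      # this species' insertion block starts after earlier species' blocks
      offset <- if (s > 1L) {
        sum(vapply(seq_len(s - 1L), function(t) length(ins[[t]][[p]]),
                   integer(1)))
      } else 0L
      cols <- base_col[p] + offset + seq_along(ins[[s]][[p]])
      mat[s, cols] <- ins[[s]][[p]]
    }
  }

  truth_regions <- data.frame(
    label = if (spec$n_regions > 0L) paste0("VR", seq_len(spec$n_regions))
            else character(0),
    start = base_col[regions_bb$start],
    end = base_col[regions_bb$end] + n_ins_after[regions_bb$end])

  rows <- apply(mat, 1, paste, collapse = "")
  names(rows) <- ids
  aln <- msa(rows)
  sequences <- vapply(ids, function(id) gsub("-", "", rows[[id]]),
                      character(1))
  structure(list(spec = spec, sequences = sequences, msa = aln,
                 truth = list(regions = truth_regions,
                              planted_sites = NULL)),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat("Synthetic panel: ", length(x$sequences), " species, backbone ",
      x$spec$backbone_len, " nt, ", nrow(x$truth$regions),
      " planted region(s)\n", sep = "")
  invisible(x)
}

#' Write a panel's sequences, alignment and truth to files
#'
#' @param panel a [generate_panel()] result.
#' @param out_prefix path prefix; writes `<prefix>.species.fasta`,
#'   `<prefix>.msa.fasta`, `<prefix>.truth.json`.
#' @return named character vector of the paths written, invisibly.
#' @export
write_panel <- function(panel, out_prefix) {
  stopifnot(inherits(panel, "panel"))
  paths <- c(species = paste0(out_prefix, ".species.fasta"),
             msa = paste0(out_prefix, ".msa.fasta"),
             truth = paste0(out_prefix, ".truth.json"))
  write_fasta(panel$sequences, paths[["species"]])
  write_alignment(panel$msa, paths[["msa"]])
  truth <- list(spec = unclass(panel$spec),
                regions = panel$truth$regions,
                planted_sites = panel$truth$planted_sites)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Plant a guide window with a known cross-species divergence pattern
#'
#' Overwrites a 24-column window (TTTA PAM + 20-nt protospacer) inside a
#' planted region so that the origin species carries a perfect Cas12a site
#' and every other species carries the requested divergence pattern:
#'
#' * `pam_loss_one_base`: PAM broken by a single T->C substitution;
#'   identical protospacer. Expected verdict: `specific`.
#' * `two_mm_one_seed`: intact PAM; two protospacer substitutions, one
#'   inside the 10-nt PAM-proximal seed. Expected verdict: `specific`.
#' * `one_mm_nonseed`: intact PAM; a single substitution outside the seed.
#'   Expected verdict: `unresolved`.
#' * `identical`: no divergence at all. Expected verdict: `cross_reactive`.
#'
#' The columns immediately before and after the window are forced divergent
#' so the planted window cannot extend a chance-conserved run into a flank
#' that would split the region.
#'
#' @param panel a [generate_panel()] result.
#' @param kind divergence pattern (see above).
#' @param region_index which planted region to use (default 1).
#' @param origin_species index of the species carrying the intact site
#'   (default 1).
#' @return the modified `panel`; `truth$planted_sites` gains a row with the
#'   origin window (ungapped coordinates), strand, kind and expected verdict.
#' @export
plant_discriminating_site <- function(panel, kind = c("pam_loss_one_base",
                                                      "two_mm_one_seed",
                                                      "one_mm_nonseed",
                                                      "identical"),
                                      region_index = 1L,
                                      origin_species = 1L) {
  stopifnot(inherits(panel, "panel"))
  kind <- match.arg(kind)
  tr <- panel$truth$regions
  if (region_index > nrow(tr)) stop("no planted region ", region_index,
                                    call. = FALSE)
  a <- tr$start[region_index]; b <- tr$end[region_index]
  wlen <- 24L  # TTTV PAM (4) + 20-nt protospacer
  if (b - a + 1L < wlen + 2L) {
    stop("region too short to plant a PAM + protospacer window",
         call. = FALSE)
  }
  withr::with_seed(panel$spec$rng_seed + 104729L * region_index, {
    mat <- panel$msa$mat
    n_sp <- nrow(mat)
    o <- origin_species
    # centre the window; leave >= 1 region column on each side for the
    # forced-divergence boundary
    c0 <- a + 1L + ((b - a - wlen) %/% 2L)
    cols <- c0:(c0 + wlen - 1L)
    site <- c("T", "T", "T", "A",
              sample(BASES, 20L, replace = TRUE))
    for (s in seq_len(n_sp)) mat[s, cols] <- site
    others <- setdiff(seq_len(n_sp), o)
    seed_cols <- cols[5:14]     # PAM-proximal 10 nt of the protospacer
    nonseed_cols <- cols[15:24]
    for (s in others) {
      if (kind == "pam_loss_one_base") {
        mat[s, cols[2]] <- "C"           # TTTA -> TCTA: PAM lost
      } else if (kind == "two_mm_one_seed") {
        sc <- sample(seed_cols, 1L); nc <- sample(nonseed_cols, 1L)
        mat[s, sc] <- other_base(mat[o, sc])
        mat[s, nc] <- other_base(mat[o, nc])
      } else if (kind == "one_mm_nonseed") {
        nc <- sample(nonseed_cols, 1L)
        mat[s, nc] <- other_base(mat[o, nc])
      }                                   # "identical": leave as planted
    }
    # boundary columns: keep the region from gaining a >= flank-length
    # conserved run through the planted window
    for (bc in c(c0 - 1L, c0 + wlen)) {
      mat[o, bc] <- "A"
      for (s in others) mat[s, bc] <- "G"
    }
    rows <- apply(mat, 1, paste, collapse = "")
    names(rows) <- panel$msa$ids
    panel$msa <- msa(rows)
    panel$sequences <- vapply(panel$msa$ids,
                              function(id) gsub("-", "", rows[[id]]),
                              character(1))
    origin_id <- panel$msa$ids[o]
    ws <- panel$msa$col2pos[[origin_id]][c0]
    site_row <- data.frame(
      kind = kind, origin_species = origin_id,
      region = tr$label[region_index], strand = "+",
      win_start = ws, win_end = ws + wlen - 1L,
      expected_verdict = switch(kind,
                                pam_loss_one_base = "specific",
                                two_mm_one_seed = "specific",
                                one_mm_nonseed = "unresolved",
                                identical = "cross_reactive"),
      stringsAsFactors = FALSE)
    panel$truth$planted_sites <- rbind(panel$truth$planted_sites, site_row)
  })
  panel
}
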