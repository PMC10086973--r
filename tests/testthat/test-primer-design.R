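test_that("gc_fraction follows its definition including ambiguity codes", {
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATAT"), 0.0)
  expect_equal(gc_fraction("SSWW"), 0.5)   # S counts as GC, W as AT
  expect_equal(gc_fraction("NN"), 0.5)     # other ambiguity codes: 0.5
  expect_error(gc_fraction(""), "empty")
  expect_error(gc_fraction("AC-G"), "gaps")

  withr::local_seed(41)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T", "S", "W", "N", "R"),
                      sample(1:50, 1L), replace = TRUE), collapse = "")
    chars <- strsplit(s, "")[[1]]
    want <- sum(chars %in% c("G", "C", "S")) +
      0.5 * sum(!chars %in% c("G", "C", "S", "A", "T", "W"))
    expect_equal(gc_fraction(s), want / nchar(s))
  }
})

# independent validator: re-extract each species' binding site from the
# alignment matrix and compare to the primer sequence
validate_universal_pair <- function(pair, x) {
  for (sp in x$ids) {
    fwd_site <- paste(x$mat[sp, pair$fwd_start:pair$fwd_end], collapse = "")
    rev_site <- paste(x$mat[sp, pair$rev_start:pair$rev_end], collapse = "")
    if (fwd_site != pair$fwd_seq) return(FALSE)
    if (revcomp(rev_site) != pair$rev_seq) return(FALSE)
  }
  TRUE
}

test_that("universal pairs bind every species identically and span the region", {
  withr::local_seed(42)
  for (i in 1:15) {
    p <- generate_panel(panel_spec(n_species = sample(2:4, 1L),
                                   backbone_len = 1500L, n_regions = 1L,
                                   vr_len_range = c(120L, 250L),
                                   rng_seed = 900L + i))
    x <- p$msa
    regions <- find_variable_regions(x)
    expect_equal(nrow(regions), 1L)
    pairs <- design_universal_primers(regions, 1L, x)
    expect_gt(nrow(pairs), 0L)
    projections <- attr(regions, "projections")[[1]]
    for (k in seq_len(nrow(pairs))) {
      expect_true(validate_universal_pair(pairs[k, ], x))
      amps <- pairs$amplicons[[k]]
      for (q in seq_len(nrow(amps))) {
        sp <- amps$species[q]
        expect_gte(amps$amplicon_len[q], 100L)
        expect_lte(amps$amplicon_len[q], 600L)
        # amplicon contains the region's projection in this species
        prow <- projections[projections$species == sp, ]
        expect_lte(amps$fwd_start[q], prow$start)
        expect_gte(amps$rev_end[q], prow$end)
      }
    }
    # ranking: shortest amplicon first
    expect_true(all(diff(pairs$max_amplicon) >= 0))
  }
})

test_that("a flank shorter than the primer floor yields a diagnostic, not pairs", {
  # flanks of exactly 30 conserved columns: only the full-width window fits
  withr::local_seed(43)
  left <- rand_dna(30)
  right <- rand_dna(30)
  core1 <- strrep("A", 120)
  core2 <- paste(sample(c("C", "G", "T"), 120, replace = TRUE), collapse = "")
  x <- msa(c(sp1 = paste0(left, core1, right),
             sp2 = paste0(left, core2, right)))
  regions <- find_variable_regions(x)
  expect_equal(nrow(regions), 1L)
  ok <- design_universal_primers(regions, 1L, x,
                                 primer_constraints(min_amplicon = 50L,
                                                    max_amplicon = 600L))
  expect_gt(nrow(ok), 0L)
  # at most one window exists per 30-column flank at min_len 30
  expect_lte(nrow(ok), 1L)

  bad <- design_universal_primers(
    regions, 1L, x, primer_constraints(min_len = 31L, max_len = 35L,
                                       min_amplicon = 50L))
  expect_equal(nrow(bad), 0L)
  expect_match(attr(bad, "diagnostic"), "flank too short")
})

test_that("a region identical across species admits no specific primer", {
  withr::local_seed(44)
  # an interval with zero inter-species differences cannot be called by the
  # strict-identity region finder, so the impossibility case is exercised on
  # a user-supplied interval over an identical stretch
  seq <- rand_dna(240)
  x <- msa(c(sp1 = seq, sp2 = seq))
  regions <- data.frame(label = "VR1", start = 41L, end = 200L, length = 160L,
                        divergence = 0,
                        left_flank_start = 1L, left_flank_end = 40L,
                        right_flank_start = 201L, right_flank_end = 240L)
  attr(regions, "projections") <- list(
    data.frame(species = c("sp1", "sp2"), start = 41L, end = 200L,
               stringsAsFactors = FALSE))
  class(regions) <- c("variable_regions", "data.frame")
  pairs <- design_specific_primers(regions, 1L, "sp1", x,
                                   primer_constraints(min_amplicon = 60L))
  expect_equal(nrow(pairs), 0L)
  expect_match(attr(pairs, "diagnostic"), "not_discriminating")
})

test_that("a species-private insert is used with indel-based discrimination", {
  withr::local_seed(45)
  left <- rand_dna(40)
  right <- rand_dna(40)
  core <- rand_dna(100)
  insert <- rand_dna(90)
  # sp1 carries a 90-nt private insert; the called region is exactly the
  # insert columns, so any primer in it discriminates sp2 by the indel
  x <- msa(c(sp1 = paste0(left, substr(core, 1, 50), insert,
                          substr(core, 51, 100), right),
             sp2 = paste0(left, substr(core, 1, 50), strrep("-", 90),
                          substr(core, 51, 100), right)))
  regions <- find_variable_regions(x)
  expect_equal(nrow(regions), 1L)
  pairs <- design_specific_primers(regions, 1L, "sp1", x,
                                   primer_constraints(min_amplicon = 60L))
  expect_gt(nrow(pairs), 0L)
  # every kept primer discriminates sp2 via the indel
  for (k in seq_len(nrow(pairs))) {
    d <- pairs$discrimination[[k]]
    expect_true(d$fwd$n_mismatch >= 1L | d$fwd$has_indel)
    expect_true(d$rev$n_mismatch >= 1L | d$rev$has_indel)
  }
  expect_true(any(vapply(pairs$discrimination,
                         function(d) d$fwd$has_indel || d$rev$has_indel,
                         logical(1))))
})

test_that("specific pairs flank a supplied guide window", {
  withr::local_seed(46)
  p <- generate_panel(panel_spec(n_species = 2L, backbone_len = 1500L,
                                 n_regions = 1L, vr_len_range = c(200L, 250L),
                                 rng_seed = 77L))
  p <- plant_discriminating_site(p, "pam_loss_one_base")
  x <- p$msa
  regions <- find_variable_regions(x)
  guides <- design_guides(x, regions = regions)
  g_specific <- guides[guides$species == "sp1" & guides$verdict == "specific", ]
  expect_gt(nrow(g_specific), 0L)
  pairs <- design_specific_primers(regions, 1L, "sp1", x,
                                   constraints = primer_constraints(
                                     min_amplicon = 80L),
                                   guides = g_specific)
  expect_gt(nrow(pairs), 0L)
  for (k in seq_len(nrow(pairs))) {
    covered <- pairs$covered_guides[[k]]
    expect_gt(length(covered), 0L)
    for (gid in covered) {
      gr <- g_specific[g_specific$guide_id == gid, ]
      expect_gt(gr$win_start, pairs$fwd_end[k])
      expect_lt(gr$win_end, pairs$rev_start[k])
    }
  }
})

test_that("specific primers mismatch every non-target species by re-mapping", {
  withr::local_seed(47)
  for (i in 1:10) {
    p <- generate_panel(panel_spec(n_species = sample(2:3, 1L),
                                   backbone_len = 1200L, n_regions = 1L,
                                   vr_len_range = c(150L, 220L),
                                   rng_seed = 300L + i))
    x <- p$msa
    regions <- find_variable_regions(x)
    target <- sample(x$ids, 1L)
    pairs <- design_specific_primers(regions, 1L, target, x,
                                     primer_constraints(min_amplicon = 80L))
    for (k in seq_len(nrow(pairs))) {
      for (side in c("fwd", "rev")) {
        a <- pairs[[paste0(side, "_start")]][k]
        b <- pairs[[paste0(side, "_end")]][k]
        for (sp in setdiff(x$ids, target)) {
          m <- map_window_across_species(x, target, a, b, sp)
          own <- substr(ungapped_seq(x, target), a, b)
          expect_true(m$indel || m$window != own)
        }
      }
    }
  }
})
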