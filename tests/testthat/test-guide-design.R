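test_that("scan_pam_sites finds direct matches and honours exclusions", {
  s <- paste0("TTTA", strrep("C", 21))
  hits <- scan_pam_sites(s)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$win_start, 1L)
  expect_equal(plus$win_end, 24L)
  expect_equal(plus$pam_start, 1L)

  # PAM only inside an excluded interval: nothing is reported
  excl <- data.frame(start = 1L, end = 4L)
  hits2 <- scan_pam_sites(s, excluded = excl)
  expect_equal(nrow(hits2[hits2$strand == "+", ]), 0L)

  # TTTT does not match TTTV (V = A/C/G); the shifted TTTC at position 2 does
  h <- scan_pam_sites(paste0("TTTT", strrep("C", 21)))
  expect_false(1L %in% h$win_start[h$strand == "+"])
  expect_true(2L %in% h$win_start[h$strand == "+"])
})

test_that("scan_pam_sites equals brute-force window testing on random sequences", {
  withr::local_seed(21)
  pam <- pam_spec()
  for (i in 1:40) {
    # T-rich alphabet so PAMs are common
    s <- paste(sample(c("A", "C", "G", "T", "T"), 300, replace = TRUE),
               collapse = "")
    excl <- if (i %% 3L == 0L) {
      st <- sample(250, 2)
      data.frame(start = st, end = st + sample(5:20, 2, replace = TRUE))
    } else NULL
    got <- scan_pam_sites(s, pam, excluded = excl)
    want <- brute_pam_scan(s, excluded = excl)
    got <- got[order(got$win_start, got$strand), ]
    want <- want[order(want$win_start, want$strand), ]
    expect_equal(got$win_start, want$win_start)
    expect_equal(got$win_end, want$win_end)
    expect_equal(got$strand, want$strand)
  }
})

test_that("reverse-complementing the input mirrors the PAM hit set", {
  withr::local_seed(22)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "T"), 200, replace = TRUE),
               collapse = "")
    n <- nchar(s)
    fwd <- scan_pam_sites(s)
    mirrored <- scan_pam_sites(revcomp(s))
    # a + hit at [ws, we] must appear as a - hit at [n-we+1, n-ws+1]
    key <- function(h) paste(h$win_start, h$win_end, h$strand)
    flipped <- data.frame(win_start = n - mirrored$win_end + 1L,
                          win_end = n - mirrored$win_start + 1L,
                          strand = ifelse(mirrored$strand == "+", "-", "+"))
    expect_setequal(key(fwd), key(flipped))
  }
})

test_that("cross-species window mapping agrees with a per-column walk", {
  # trivial identical alignment
  x <- msa(c(a = "ACGTACGT", b = "ACGTACGT"))
  m <- map_window_across_species(x, "a", 2L, 5L, "b")
  expect_equal(m$window, "CGTA")
  expect_false(m$indel)

  # window spanning a column gapped in the target
  x <- msa(c(a = "ACGTACGT", b = "AC--ACGT"))
  m <- map_window_across_species(x, "a", 2L, 5L, "b")
  expect_equal(m$window, "C--A")
  expect_true(m$indel)
  # and an insertion in the target (gap in origin) also flags indel
  x <- msa(c(a = "AC--GT", b = "ACAAGT"))
  m <- map_window_across_species(x, "a", 2L, 3L, "b")
  expect_true(m$indel)

  expect_error(map_window_across_species(x, "a", 3L, 9L, "b"), "out of range")

  withr::local_seed(23)
  for (i in 1:100) {
    rows <- rand_gapped_alignment(sample(2:4, 1L), sample(20:60, 1L),
                                  gap_prob = 0.1)
    x <- msa(rows)
    origin <- sample(x$ids, 1L)
    target <- sample(setdiff(x$ids, origin), 1L)
    olen <- nchar(ungapped_seq(x, origin))
    if (olen < 4L) next
    a <- sample(olen - 3L, 1L)
    b <- min(olen, a + sample(3:10, 1L))
    m <- map_window_across_species(x, origin, a, b, target)
    # naive walk
    ochars <- strsplit(x$seqs[[origin]], "")[[1]]
    tchars <- strsplit(x$seqs[[target]], "")[[1]]
    opos <- cumsum(ochars != "-")
    cols <- which(opos == a & ochars != "-"):which(opos == b & ochars != "-")
    expect_equal(m$window, paste(tchars[cols], collapse = ""))
    expect_equal(m$indel, any(tchars[cols] == "-") || any(ochars[cols] == "-"))
  }
})

# helper: build a 2+-species alignment where species 1 carries a perfect
# TTTA + 20 nt site and the others carry a controlled divergence pattern
site_alignment <- function(off_windows) {
  flank <- strrep("G", 35)
  site <- paste0("TTTA", strrep("C", 10), strrep("A", 10))
  rows <- c(sp1 = paste0(flank, site, flank))
  for (i in seq_along(off_windows)) {
    rows[paste0("off", i)] <- paste0(flank, off_windows[[i]], flank)
  }
  msa(rows)
}

test_that("specificity scoring reproduces the reference divergence patterns", {
  site <- paste0("TTTA", strrep("C", 10), strrep("A", 10))

  # off-species identical in the window: perfect match, reactive
  x <- site_alignment(site)
  r <- score_specificity(x, "sp1", 36L, 59L, "+")
  expect_true(r$pam_intact)
  expect_equal(r$total_mismatches, 0L)
  expect_true(r$cross_reactive)
  expect_equal(classify_guide(r), "cross_reactive")

  # PAM loses one T: recognition impossible regardless of the protospacer
  x <- site_alignment(sub("TTTA", "TCTA", site))
  r <- score_specificity(x, "sp1", 36L, 59L, "+")
  expect_false(r$pam_intact)
  expect_false(r$cross_reactive)
  expect_equal(classify_guide(r), "specific")

  # two substitutions, one inside the 10-nt PAM-proximal seed
  off <- paste0("TTTA", "CCCTCCCCCC", "AAAAGAAAAA")
  x <- site_alignment(off)
  r <- score_specificity(x, "sp1", 36L, 59L, "+")
  expect_true(r$pam_intact)
  expect_equal(r$total_mismatches, 2L)
  expect_equal(r$seed_mismatches, 1L)
  expect_equal(classify_guide(r), "specific")

  # one mismatch outside the seed under an intact PAM: unresolved
  off <- paste0("TTTA", strrep("C", 10), "AAAAGAAAAA")
  x <- site_alignment(off)
  r <- score_specificity(x, "sp1", 36L, 59L, "+")
  expect_equal(r$total_mismatches, 1L)
  expect_equal(r$seed_mismatches, 0L)
  expect_equal(classify_guide(r), "unresolved")

  # an indel inside the window blocks recognition
  x <- msa(c(sp1 = paste0(strrep("G", 35), site, strrep("G", 35)),
             off1 = paste0(strrep("G", 35), sub("CCC$", "CC-",
                                                substr(site, 1, 14)),
                           substr(site, 15, 24), strrep("G", 35))))
  r <- score_specificity(x, "sp1", 36L, 59L, "+")
  expect_true(r$indel_in_window)
  expect_equal(classify_guide(r), "specific")
})

test_that("mismatch counts equal brute-force Hamming on random windows", {
  withr::local_seed(24)
  done <- 0L
  while (done < 150L) {
    rows <- rand_gapped_alignment(sample(2:4, 1L), 60L, gap_prob = 0.05)
    x <- msa(rows)
    origin <- sample(x$ids, 1L)
    olen <- nchar(ungapped_seq(x, origin))
    if (olen < 24L) next
    ws <- sample(olen - 23L, 1L)
    strand <- sample(c("+", "-"), 1L)
    r <- score_specificity(x, origin, ws, ws + 23L, strand)
    for (k in seq_len(nrow(r))) {
      want <- brute_specificity(x$seqs, origin, r$species[k], ws, ws + 23L,
                                strand)
      expect_equal(r$total_mismatches[k], want$total)
      expect_equal(r$seed_mismatches[k], want$seed)
      expect_equal(r$pam_intact[k], want$pam_intact)
      expect_equal(r$indel_in_window[k], want$indel)
      done <- done + 1L
    }
  }
})

test_that("the verdict rule matches its decision table over all count combinations", {
  grid <- expand.grid(pam_intact = c(TRUE, FALSE),
                      total_mismatches = 0:3,
                      indel_in_window = c(TRUE, FALSE))
  cases <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    data.frame(pam_intact = row$pam_intact,
               total_mismatches = row$total_mismatches,
               indel_in_window = row$indel_in_window,
               seed_mismatches = 0:row$total_mismatches)
  }))
  for (i in seq_len(nrow(cases))) {
    r <- cases[i, c("pam_intact", "total_mismatches", "seed_mismatches",
                    "indel_in_window")]
    expect_equal(classify_guide(r), brute_verdict(r), info = paste(r, collapse = "/"))
  }
  # and over random multi-species report sets
  withr::local_seed(25)
  for (i in 1:100) {
    n <- sample(1:4, 1L)
    tot <- sample(0:3, n, replace = TRUE)
    r <- data.frame(pam_intact = sample(c(TRUE, FALSE), n, replace = TRUE),
                    total_mismatches = tot,
                    seed_mismatches = vapply(tot, function(t) sample(0:t, 1L),
                                             integer(1)),
                    indel_in_window = sample(c(TRUE, FALSE), n, replace = TRUE))
    expect_equal(classify_guide(r), brute_verdict(r))
  }
  expect_error(classify_guide(data.frame()), "nothing to discriminate")
})

test_that("adding divergence never demotes a specific verdict", {
  # monotonicity: start from any report set and make one species more
  # divergent; the verdict can only move toward specific
  rank_of <- c(cross_reactive = 1L, unresolved = 2L, specific = 3L)
  withr::local_seed(26)
  for (i in 1:200) {
    n <- sample(1:3, 1L)
    tot <- sample(0:3, n, replace = TRUE)
    r <- data.frame(pam_intact = sample(c(TRUE, FALSE), n, replace = TRUE),
                    total_mismatches = tot,
                    seed_mismatches = vapply(tot, function(t) sample(0:t, 1L),
                                             integer(1)),
                    indel_in_window = FALSE)
    before <- classify_guide(r)
    k <- sample(n, 1L)
    r2 <- r
    move <- sample(3L, 1L)
    if (move == 1L) {
      r2$total_mismatches[k] <- r2$total_mismatches[k] + 1L
      r2$seed_mismatches[k] <- r2$seed_mismatches[k] + 1L
    } else if (move == 2L) {
      r2$pam_intact[k] <- FALSE
    } else {
      r2$indel_in_window[k] <- TRUE
    }
    expect_gte(rank_of[[classify_guide(r2)]], rank_of[[before]])
  }
})

test_that("candidate ranking is a stable deterministic total order", {
  p <- generate_panel(panel_spec(n_species = 3L, backbone_len = 2000L,
                                 rng_seed = 33L))
  g <- design_guides(p$msa)
  expect_gt(nrow(g), 0L)
  # specific before unresolved before cross_reactive
  vr <- match(g$verdict, c("specific", "unresolved", "cross_reactive"))
  expect_true(all(diff(vr) >= 0))
  # re-ranking a shuffled copy restores the same order
  withr::local_seed(27)
  shuffled <- g[sample(nrow(g)), ]
  again <- rank_candidates(shuffled)
  expect_equal(again$guide_id, g$guide_id)
  # and ranking is idempotent
  expect_equal(rank_candidates(g)$guide_id, g$guide_id)
})

test_that("no emitted guide overlaps a template junction", {
  withr::local_seed(28)
  for (i in 1:20) {
    p <- generate_panel(panel_spec(n_species = sample(2:3, 1L),
                                   backbone_len = 1200L, n_regions = 2L,
                                   vr_len_range = c(80L, 150L),
                                   rng_seed = 500L + i))
    regions <- find_variable_regions(p$msa)
    if (nrow(regions) == 0L) next
    tpl <- build_concatenated_template(regions, p$msa)
    hits <- scan_pam_sites(tpl$sequence, excluded = tpl$junctions)
    for (k in seq_len(nrow(tpl$junctions))) {
      expect_true(all(hits$win_end < tpl$junctions$start[k] |
                      hits$win_start > tpl$junctions$end[k]))
    }
    # every emitted guide's PAM re-verifies in its origin sequence
    g <- enumerate_guides(tpl, p$msa)
    for (k in seq_len(nrow(g))) {
      oseq <- ungapped_seq(p$msa, g$species[k])
      win <- substr(oseq, g$win_start[k], g$win_end[k])
      pam_obs <- if (g$strand[k] == "+") substr(win, 1L, 4L) else
        revcomp(substr(win, nchar(win) - 3L, nchar(win)))
      expect_equal(pam_obs, g$pam_seq[k])
      expect_match(pam_obs, "^TTT[ACG]$")
    }
  }
})
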