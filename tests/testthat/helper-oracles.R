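# Independent brute-force oracles and random-input generators. These are
# deliberately naive (per-position loops, O(n^2) scans) and share no code
# with the package implementation they check.

BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

rand_records <- function(n_records, len_range = c(10L, 60L)) {
  data.frame(
    id = paste0("rec", seq_len(n_records)),
    description = ifelse(stats::runif(n_records) < 0.5, "",
                         paste("desc", seq_len(n_records))),
    residues = vapply(seq_len(n_records), function(i) {
      rand_dna(sample(len_range[1]:len_range[2], 1L))
    }, character(1)),
    stringsAsFactors = FALSE)
}

# random gapped alignment as a named character vector of equal-length rows
rand_gapped_alignment <- function(n_species = 3L, ncols = 40L,
                                  gap_prob = 0.15) {
  rows <- vapply(seq_len(n_species), function(s) {
    chars <- sample(BASES4, ncols, replace = TRUE)
    gaps <- stats::runif(ncols) < gap_prob
    # keep at least one residue per row
    if (all(gaps)) gaps[sample(ncols, 1L)] <- FALSE
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  names(rows) <- paste0("sp", seq_len(n_species))
  rows
}

# ---- conservation / region oracles -----------------------------------------

# per-column tally, naive
brute_profile <- function(mat) {
  n <- nrow(mat)
  t(vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    nongap <- col[col != "-"]
    top <- if (length(nongap)) max(table(nongap)) else 0L
    c(identity_fraction = top / n,
      is_conserved = as.numeric(length(unique(col)) == 1L && col[1] != "-"))
  }, numeric(2)))
}

# maximal conserved runs >= min_len by checking every interval: O(n^2)
brute_blocks <- function(is_conserved, min_len) {
  n <- length(is_conserved)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(is_conserved[i:j]) &&
          (i == 1L || !is_conserved[i - 1L]) &&
          (j == n || !is_conserved[j + 1L]) &&
          j - i + 1L >= min_len) {
        out[[length(out) + 1L]] <- c(start = i, end = j)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

# exhaustive region scan: every inter-block gap, filtered on length and mean
# divergence, computed straight from the definition
brute_regions <- function(identity_fraction, is_conserved, min_flank,
                          max_vr_len, min_divergence) {
  blocks <- brute_blocks(is_conserved, min_flank)
  if (nrow(blocks) < 2L) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  out <- list()
  for (k in seq_len(nrow(blocks) - 1L)) {
    s <- unname(blocks[k, "end"]) + 1L
    e <- unname(blocks[k + 1L, "start"]) - 1L
    len <- e - s + 1L
    if (len < 1L || len > max_vr_len) next
    if (1 - mean(identity_fraction[s:e]) < min_divergence) next
    out[[length(out) + 1L]] <- c(start = s, end = e)
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

# direct-definition region scan: an interval [s, e] is a variable region iff
# the min_flank columns on each side are all conserved, no min_flank-long
# conserved run lies inside it, and it meets the length and divergence
# bounds. Implemented as a per-candidate linear walk straight from that
# predicate, independent of the package's run-length machinery.
scan_regions_direct <- function(identity_fraction, is_conserved, min_flank,
                                max_vr_len, min_divergence) {
  n <- length(is_conserved)
  out <- list()
  for (s in seq_len(n)) {
    if (s - min_flank < 1L) next
    if (!all(is_conserved[(s - min_flank):(s - 1L)])) next
    if (is_conserved[s]) next
    # walk right until a conserved run of min_flank closes the gap
    run <- 0L
    e <- NA_integer_
    for (j in s:n) {
      if (is_conserved[j]) {
        run <- run + 1L
        if (run == min_flank) { e <- j - min_flank; break }
      } else {
        run <- 0L
      }
    }
    if (is.na(e)) next                       # right flank never closes
    if (e - s + 1L > max_vr_len) next
    if (1 - mean(identity_fraction[s:e]) < min_divergence) next
    out[[length(out) + 1L]] <- c(start = s, end = e)
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

# ---- guide oracles ---------------------------------------------------------

IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

brute_iupac_match <- function(window, pattern) {
  w <- strsplit(window, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  length(w) == length(p) &&
    all(mapply(function(wc, pc) wc %in% BASES4 && wc %in% IUPAC_TABLE[[pc]],
               w, p))
}

brute_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B", D = "H",
            H = "D", "-" = "-")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# per-position window test at every position and strand
brute_pam_scan <- function(sequence, pattern = "TTTV", plen = 4L,
                           slen = 20L, excluded = NULL) {
  n <- nchar(sequence)
  wlen <- plen + slen
  hits <- list()
  for (p in seq_len(n)) {
    if (p + wlen - 1L > n) next
    win <- substr(sequence, p, p + wlen - 1L)
    blocked <- FALSE
    if (!is.null(excluded) && nrow(excluded) > 0L) {
      for (k in seq_len(nrow(excluded))) {
        if (p <= excluded$end[k] && excluded$start[k] <= p + wlen - 1L) {
          blocked <- TRUE
        }
      }
    }
    if (blocked) next
    if (brute_iupac_match(substr(win, 1L, plen), pattern)) {
      hits[[length(hits) + 1L]] <- data.frame(
        win_start = p, win_end = p + wlen - 1L, strand = "+")
    }
    if (brute_iupac_match(substr(brute_revcomp(win), 1L, plen), pattern)) {
      hits[[length(hits) + 1L]] <- data.frame(
        win_start = p, win_end = p + wlen - 1L, strand = "-")
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(win_start = integer(0), win_end = integer(0),
               strand = character(0))
}

# naive per-column walk for cross-species mismatch counting
brute_specificity <- function(aln_rows, origin, target, win_start, win_end,
                              strand, plen = 4L, seed_len = 10L) {
  omat <- strsplit(aln_rows[[origin]], "")[[1]]
  tmat <- strsplit(aln_rows[[target]], "")[[1]]
  opos <- cumsum(omat != "-")
  cols_of <- function(p) which(opos == p & omat != "-")
  wcols <- cols_of(win_start):cols_of(win_end)
  if (strand == "+") {
    pam_pos <- win_start:(win_start + plen - 1L)
    proto_pos <- (win_start + plen):win_end
  } else {
    pam_pos <- (win_end - plen + 1L):win_end
    proto_pos <- (win_end - plen):win_start
  }
  total <- 0L; seedmm <- 0L
  for (i in seq_along(proto_pos)) {
    cc <- cols_of(proto_pos[i])
    mm <- tmat[cc] != omat[cc] || !(tmat[cc] %in% BASES4)
    total <- total + mm
    if (i <= seed_len) seedmm <- seedmm + mm
  }
  pam_window <- paste(tmat[vapply(pam_pos, cols_of, integer(1))],
                      collapse = "")
  if (strand == "-") pam_window <- brute_revcomp(pam_window)
  list(total = total, seed = seedmm,
       pam_intact = !grepl("-", pam_window) &&
         brute_iupac_match(pam_window, "TTTV"),
       indel = any(tmat[wcols] == "-") || any(omat[wcols] == "-"))
}

# the classification rule, written out as a plain decision table
brute_verdict <- function(reports, mm_t = 2L, seed_t = 1L) {
  per <- apply(reports, 1, function(r) {
    pam <- as.logical(r[["pam_intact"]])
    tot <- as.integer(r[["total_mismatches"]])
    sd <- as.integer(r[["seed_mismatches"]])
    ind <- as.logical(r[["indel_in_window"]])
    if (!pam || ind || (tot >= mm_t && sd >= seed_t)) "safe"
    else if (pam && !ind && tot == 0L) "reactive"
    else "unresolved"
  })
  if (any(per == "reactive")) "cross_reactive"
  else if (all(per == "safe")) "specific"
  else "unresolved"
}

# a small alignment containing one divergent stretch between conserved flanks
flanked_alignment <- function(flank = 35L, core_len = 60L, n_species = 2L,
                              core_rate = 0.5) {
  left <- rand_dna(flank)
  right <- rand_dna(flank)
  core0 <- strsplit(rand_dna(core_len), "")[[1]]
  rows <- c(paste0(left, paste(core0, collapse = ""), right))
  for (s in seq_len(n_species - 1L)) {
    core <- core0
    mut <- which(stats::runif(core_len) < core_rate)
    for (m in mut) core[m] <- sample(setdiff(BASES4, core[m]), 1L)
    rows <- c(rows, paste0(left, paste(core, collapse = ""), right))
  }
  names(rows) <- paste0("sp", seq_len(n_species))
  rows
}
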