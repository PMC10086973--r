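# End-to-end assay design and reporting.
#
# run_design composes the pipeline: conservation profile -> variable regions
# -> concatenated template -> specificity-screened guides -> universal
# primers (for regions holding a specific guide) -> species-specific primers
# for the target. The result is deterministic for fixed inputs and config;
# reports embed the effective configuration so a design can be reproduced
# byte-identically.

REPORT_SCHEMA_VERSION <- "1.0"

#' Default assay-design configuration
#'
#' One document holding every tunable threshold of the pipeline, with the
#' package defaults: TTTV PAM, 20-nt protospacer, 10-nt seed, 30-column
#' flanks, 500-column region cap, 0.05 divergence floor, RPA primer
#' constraints and the PAM-free template linker.
#'
#' @return a named list of class `pestid_config`.
#' @export
default_config <- function() {
  structure(list(
    pam = "TTTV",
    spacer_len = 20L,
    seed_len = 10L,
    min_flank = 30L,
    max_vr_len = 500L,
    min_divergence = 0.05,
    allow_terminal_regions = FALSE,
    mm_threshold = 2L,
    seed_threshold = 1L,
    linker = DEFAULT_LINKER,
    primer_min_len = 30L,
    primer_max_len = 35L,
    primer_gc_min = 0.20,
    primer_gc_max = 0.70,
    primer_max_homopolymer = 5L,
    min_amplicon = 100L,
    max_amplicon = 600L,
    max_pairs = 10L
  ), class = "pestid_config")
}

#' Read a YAML configuration file
#'
#' Unknown keys are rejected; values are validated against the pipeline's
#' invariants. Keys absent from the file keep their defaults. Precedence is
#' handled by the caller (CLI flag > config file > built-in default).
#'
#' @param path path to a YAML file, or NULL for the defaults.
#' @param overrides named list applied on top of the file (e.g. CLI flags).
#' @return a validated `pestid_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (length(vals)) {
      unknown <- setdiff(names(vals), names(cfg))
      if (length(unknown)) {
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      cfg[names(vals)] <- vals
    }
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (k in c("spacer_len", "seed_len", "min_flank", "max_vr_len",
              "mm_threshold", "seed_threshold", "primer_min_len",
              "primer_max_len", "primer_max_homopolymer", "min_amplicon",
              "max_amplicon", "max_pairs")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  pam_spec(cfg$pam, cfg$spacer_len)                       # validates both
  seed_spec(cfg$seed_len)
  stopifnot(cfg$seed_len <= cfg$spacer_len,
            cfg$min_flank >= 1L, cfg$max_vr_len >= 1L,
            cfg$min_divergence >= 0, cfg$min_divergence <= 1)
  primer_constraints(cfg$primer_min_len, cfg$primer_max_len,
                     cfg$primer_gc_min, cfg$primer_gc_max,
                     cfg$primer_max_homopolymer,
                     cfg$min_amplicon, cfg$max_amplicon)  # validates
  class(cfg) <- "pestid_config"
  cfg
}

design_log <- function(...) message("[pestid] ", ...)

#' Run the full assay-design pipeline
#'
#' @param msa_input an [msa()] object or a path to an aligned FASTA file.
#' @param target the target species id (the species the assay must detect).
#' @param config a `pestid_config` (default [default_config()]).
#' @param quiet suppress progress messages (default FALSE; messages go to
#'   stderr).
#' @return an object of class `assay_design`: list with `schema_version`,
#'   `status` ("ok" or "no-design"), `input` (path and content hash when read
#'   from file), `parameters` (the effective config), `target`, `species`,
#'   `regions`, `guides`, `universal_primers`, `specific_primers` and
#'   `warnings`.
#' @export
run_design <- function(msa_input, target, config = default_config(),
                       quiet = FALSE) {
  config <- validate_config(config)
  log_ <- if (quiet) function(...) invisible() else design_log
  input <- list(path = NA_character_, md5 = NA_character_)
  if (is.character(msa_input)) {
    input$path <- msa_input
    input$md5 <- unname(tools::md5sum(msa_input))
    x <- read_alignment(msa_input)
  } else {
    x <- msa_input
  }
  stopifnot(inherits(x, "msa"))
  if (!target %in% x$ids) {
    stop("target species '", target, "' not in alignment (have: ",
         paste(x$ids, collapse = ", "), ")", call. = FALSE)
  }
  warnings <- character(0)
  pam <- pam_spec(config$pam, config$spacer_len)
  seed <- seed_spec(config$seed_len)
  constraints <- primer_constraints(config$primer_min_len,
                                    config$primer_max_len,
                                    config$primer_gc_min, config$primer_gc_max,
                                    config$primer_max_homopolymer,
                                    config$min_amplicon, config$max_amplicon)

  log_("profiling conservation over ", x$ncols, " columns, ",
       length(x$ids), " species")
  profile <- conservation_profile(x)
  regions <- find_variable_regions(
    x, profile = profile, min_flank = config$min_flank,
    max_vr_len = config$max_vr_len, min_divergence = config$min_divergence,
    allow_terminal_regions = config$allow_terminal_regions)
  log_("called ", nrow(regions), " variable region(s)")

  base <- list(schema_version = REPORT_SCHEMA_VERSION, input = input,
               parameters = unclass(config), target = target,
               species = x$ids)
  if (nrow(regions) == 0L) {
    return(structure(c(base, list(
      status = "no-design", regions = regions,
      guides = NULL, universal_primers = NULL, specific_primers = NULL,
      warnings = "no variable regions found at the configured thresholds")),
      class = "assay_design"))
  }

  guides <- design_guides(x, regions = regions, pam = pam, seed = seed,
                          linker = config$linker,
                          mm_threshold = config$mm_threshold,
                          seed_threshold = config$seed_threshold)
  log_(nrow(guides), " guide candidate(s): ",
       sum(guides$verdict == "specific"), " specific, ",
       sum(guides$verdict == "unresolved"), " unresolved, ",
       sum(guides$verdict == "cross_reactive"), " cross-reactive")
  n_target_specific <- sum(guides$verdict == "specific" &
                           guides$species == target)
  if (n_target_specific == 0L) {
    warnings <- c(warnings, paste0(
      "no specific guide found for target '", target,
      "'; unresolved/cross-reactive candidates are reported and need ",
      "wet-lab validation"))
  }
  if (any(guides$verdict == "unresolved")) {
    warnings <- c(warnings, paste0(
      sum(guides$verdict == "unresolved"),
      " guide(s) are unresolved (near-match in some species with intact ",
      "PAM); wet-lab validation required before use"))
  }

  # universal primers for every region holding a specific-verdict guide
  specific_regions <- unique(guides$region[guides$verdict == "specific"])
  universal <- list()
  for (lab in specific_regions) {
    idx <- match(lab, regions$label)
    if (is.na(regions$left_flank_start[idx]) ||
        is.na(regions$right_flank_start[idx])) next
    up <- design_universal_primers(regions, idx, x, constraints,
                                   guides = guides,
                                   max_pairs = config$max_pairs)
    if (nrow(up) == 0L) {
      warnings <- c(warnings, paste0("no universal primer pair for ", lab,
                                     ": ", attr(up, "diagnostic")))
    } else {
      up$region <- lab
      universal[[lab]] <- up
    }
  }
  universal <- if (length(universal)) do.call(rbind, universal) else
    empty_pairs("no region with a specific guide yielded a universal pair")
  rownames(universal) <- NULL
  log_(nrow(universal), " universal primer pair(s)")

  # specific primers for the target, in regions holding a specific guide of
  # the target (fall back to all regions when none)
  target_regions <- unique(guides$region[guides$verdict == "specific" &
                                         guides$species == target])
  if (length(target_regions) == 0L) target_regions <- regions$label
  specific <- list()
  for (lab in target_regions) {
    idx <- match(lab, regions$label)
    sp_guides <- guides[guides$species == target &
                        guides$verdict == "specific", , drop = FALSE]
    sp <- design_specific_primers(regions, idx, target, x, constraints,
                                  guides = if (nrow(sp_guides)) sp_guides
                                           else NULL,
                                  max_pairs = config$max_pairs)
    if (nrow(sp) == 0L) {
      warnings <- c(warnings, paste0("no specific primer pair for target in ",
                                     lab, ": ", attr(sp, "diagnostic")))
    } else {
      sp$region <- lab
      specific[[lab]] <- sp
    }
  }
  specific <- if (length(specific)) do.call(rbind, specific) else
    empty_pairs("no specific primer pair found for the target")
  rownames(specific) <- NULL
  log_(nrow(specific), " specific primer pair(s) for target '", target, "'")

  structure(c(base, list(status = "ok", regions = regions, guides = guides,
                         universal_primers = universal,
                         specific_primers = specific,
                         warnings = warnings)),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Cas12a assay design (status: ", x$status, ")\n", sep = "")
  cat("  target: ", x$target, " | panel: ", paste(x$species, collapse = ", "),
      "\n", sep = "")
  cat("  regions: ", nrow(x$regions), "\n", sep = "")
  if (!is.null(x$guides)) {
    cat("  guides: ", nrow(x$guides), " (",
        sum(x$guides$verdict == "specific"), " specific)\n", sep = "")
    cat("  universal primer pairs: ", nrow(x$universal_primers),
        " | specific primer pairs: ", nrow(x$specific_primers), "\n",
        sep = "")
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

# ---- report writing ---------------------------------------------------------

# 1-based inclusive coordinates in all human-readable tables; BED stays
# 0-based half-open (conversion happens in write_regions_bed).

guides_table <- function(guides, species) {
  base_cols <- c("guide_id", "species", "region", "strand", "win_start",
                 "win_end", "pam_seq", "protospacer", "gc_fraction",
                 "verdict")
  if (is.null(guides) || nrow(guides) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(base_cols)), base_cols))
    return(df)
  }
  df <- as.data.frame(guides)[, base_cols]
  # one mm/seed/pam column triple per non-origin species
  for (i in seq_len(nrow(df))) {
    rep_i <- guides$specificity[[i]]
    for (k in seq_len(nrow(rep_i))) {
      sp <- rep_i$species[k]
      df[i, paste0(sp, "_mm")] <- rep_i$total_mismatches[k]
      df[i, paste0(sp, "_seed_mm")] <- rep_i$seed_mismatches[k]
      df[i, paste0(sp, "_pam_intact")] <- rep_i$pam_intact[k]
    }
  }
  df
}

primers_table <- function(pairs) {
  cols <- c("kind", "region", "fwd_seq", "rev_seq", "fwd_start", "fwd_end",
            "rev_start", "rev_end", "max_amplicon")
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(as.data.frame(stats::setNames(rep(list(character(0)),
                                             length(cols)), cols)))
  }
  df <- as.data.frame(pairs)
  if (!"region" %in% names(df)) df$region <- NA_character_
  df[, cols]
}

#' Write an assay design to report files
#'
#' Emits `<prefix>.design.json` (machine-readable, schema-versioned, embeds
#' the effective configuration), `<prefix>.regions.tsv`, `<prefix>.guides.tsv`
#' and `<prefix>.primers.tsv` (1-based inclusive coordinates),
#' `<prefix>.guides.fasta` and `<prefix>.primers.fasta`, and one BED6 file of
#' region projections per species. Empty designs produce valid empty tables
#' with headers.
#'
#' @param design an [run_design()] result.
#' @param out_prefix output path prefix.
#' @return named character vector of paths written, invisibly.
#' @export
write_report <- function(design, out_prefix) {
  stopifnot(inherits(design, "assay_design"))
  paths <- c(json = paste0(out_prefix, ".design.json"),
             regions = paste0(out_prefix, ".regions.tsv"),
             guides = paste0(out_prefix, ".guides.tsv"),
             primers = paste0(out_prefix, ".primers.tsv"),
             guides_fasta = paste0(out_prefix, ".guides.fasta"),
             primers_fasta = paste0(out_prefix, ".primers.fasta"))

  regions_df <- as.data.frame(design$regions)
  projections <- attr(design$regions, "projections")
  json_obj <- list(
    schema_version = design$schema_version,
    status = design$status,
    input = design$input,
    parameters = design$parameters,
    target = design$target,
    species = design$species,
    regions = regions_df,
    region_projections = projections %||% list(),
    guides = guides_table(design$guides, design$species),
    guide_specificity = if (is.null(design$guides)) list() else
      stats::setNames(design$guides$specificity, design$guides$guide_id),
    universal_primers = primers_table(design$universal_primers),
    specific_primers = primers_table(design$specific_primers),
    warnings = as.list(design$warnings))
  jsonlite::write_json(json_obj, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  utils::write.table(regions_df, paths[["regions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(guides_table(design$guides, design$species),
                     paths[["guides"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(rbind(primers_table(design$universal_primers),
                           primers_table(design$specific_primers)),
                     paths[["primers"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (!is.null(design$guides) && nrow(design$guides) > 0L) {
    write_fasta(stats::setNames(design$guides$protospacer,
                                design$guides$guide_id),
                paths[["guides_fasta"]])
  } else {
    writeLines(character(0), paths[["guides_fasta"]])
  }
  primer_seqs <- character(0)
  for (tbl in list(design$universal_primers, design$specific_primers)) {
    if (!is.null(tbl) && nrow(tbl) > 0L) {
      for (i in seq_len(nrow(tbl))) {
        rg <- if ("region" %in% names(tbl)) tbl$region[i] else "NA"
        primer_seqs[paste0(tbl$kind[i], "_", rg, "_", i, "_F")] <-
          tbl$fwd_seq[i]
        primer_seqs[paste0(tbl$kind[i], "_", rg, "_", i, "_R")] <-
          tbl$rev_seq[i]
      }
    }
  }
  if (length(primer_seqs)) write_fasta(primer_seqs, paths[["primers_fasta"]])
  else writeLines(character(0), paths[["primers_fasta"]])

  if (nrow(design$regions) > 0L) {
    for (sp in design$species) {
      p <- paste0(out_prefix, ".regions.", sp, ".bed")
      write_regions_bed(design$regions, sp, p)
      paths[paste0("bed_", sp)] <- p
    }
  }
  invisible(paths)
}

#' Read a design report back from its JSON file
#'
#' Reconstructs the machine-readable portion of an [run_design()] result
#' (status, parameters, regions, guide and primer tables, warnings) from the
#' file written by [write_report()].
#'
#' @param path path to a `.design.json` file.
#' @return a list mirroring the report structure, with tables as data.frames.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$warnings <- unlist(obj$warnings) %||% character(0)
  obj
}
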