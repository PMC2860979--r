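#' Run the full discrimination pipeline
#'
#' Reads per-locus aligned FASTA files and specimen metadata, then emits,
#' under `outdir`: per-locus distance matrices (PHYLIP-style and long
#' TSV), the group-pair mean (SD) distance summary table, per-locus
#' mismatch distributions and barcoding-gap results, per-locus diagnostic
#' site tables, assignment results for any query specimens, and a JSON
#' manifest with the package version, parameters and input/output
#' checksums. All outputs are plain text and byte-deterministic for fixed
#' inputs and options.
#'
#' @param fasta Named character vector of aligned FASTA paths (names are
#'   locus names; unnamed paths use the file stem).
#' @param metadata Path to the specimen metadata TSV (`specimen_id`,
#'   `species`, `form`).
#' @param outdir Output directory (created if needed).
#' @param grouping `"form"` (species plus form, the default) or
#'   `"species"` (forms pooled).
#' @param bin_width Mismatch-distribution bin width.
#' @param min_variant_carriers Variation filter threshold for diagnostics.
#' @param sd_estimator `"sample"` or `"population"` SD for summaries.
#' @param queries Character vector of specimen ids to treat as queries:
#'   they are removed from the reference groups and assigned per locus
#'   from pure diagnostic sites.
#' @param plots If `TRUE`, also write one mismatch-distribution PNG per
#'   locus.
#' @return Invisibly, a list with the computed objects (`summaries`,
#'   `gaps`, `diagnostics`, `assignments`, `manifest`).
#' @export
run_pipeline <- function(fasta, metadata, outdir,
                         grouping = c("form", "species"),
                         bin_width = 0.005, min_variant_carriers = 2L,
                         sd_estimator = c("sample", "population"),
                         queries = character(0), plots = FALSE) {
  grouping <- match.arg(grouping)
  sd_estimator <- match.arg(sd_estimator)
  missing_in <- c(fasta, metadata)[!file.exists(c(fasta, metadata))]
  if (length(missing_in)) {
    stop(sprintf("input file(s) not found: %s",
                 paste(missing_in, collapse = ", ")), call. = FALSE)
  }
  if (is.null(names(fasta)) || any(names(fasta) == "")) {
    names(fasta) <- tools::file_path_sans_ext(basename(fasta))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  specimens <- read_metadata(metadata)
  if (grouping == "species") specimens <- species_level(specimens)
  bad_q <- setdiff(queries, specimens$specimen_id)
  if (length(bad_q)) {
    stop(sprintf("query id(s) not in metadata: %s",
                 paste(bad_q, collapse = ", ")), call. = FALSE)
  }
  refs <- specimens[!specimens$specimen_id %in% queries, ]
  class(refs) <- class(specimens)

  loci <- lapply(names(fasta), function(nm) read_fasta_alignment(fasta[[nm]], nm))
  # queries are excluded from the reference dataset used for all statistics
  ref_loci <- lapply(loci, function(loc) {
    keep <- setdiff(rownames(loc$seqs), queries)
    aligned_locus(loc$seqs[keep, , drop = FALSE], loc$locus_name)
  })
  dataset <- build_dataset(ref_loci, refs)

  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  summaries <- all_group_summaries(dataset, sd_estimator = sd_estimator)
  utils::write.table(summaries, emit(file.path(outdir, "group_summaries.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary_table(summaries),
                     emit(file.path(outdir, "summary_table.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gaps <- list(); diags <- list(); assigns <- list()
  for (loc in dataset$loci) {
    nm <- loc$locus_name
    dm <- distance_matrix(loc)
    for (p in write_distance_matrix(dm, file.path(outdir, paste0("dist_", nm)))) emit(p)
    mh <- mismatch_distribution(dm, refs, bin_width)
    write_mismatch_distribution(mh, emit(file.path(outdir, paste0("mismatch_", nm, ".tsv"))))
    if (plots) {
      png_path <- emit(file.path(outdir, paste0("mismatch_", nm, ".png")))
      grDevices::png(png_path, width = 900, height = 600)
      plot(mh)
      grDevices::dev.off()
    }
    gaps[[nm]] <- tryCatch(all_barcoding_gaps(dm, refs), error = function(e) {
      warning(sprintf("gap analysis skipped for locus '%s': %s", nm,
                      conditionMessage(e)))
      NULL
    })
    diags[[nm]] <- tryCatch(
      classify_sites(loc, refs, min_variant_carriers),
      error = function(e) {
        warning(sprintf("diagnostics skipped for locus '%s': %s", nm,
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(diags[[nm]])) {
      write_diag_table(diags[[nm]], emit(file.path(outdir, paste0("diag_", nm, ".tsv"))))
    }
  }
  gap_df <- do.call(rbind, gaps)
  if (!is.null(gap_df)) {
    utils::write.table(gap_df, emit(file.path(outdir, "barcoding_gaps.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (length(queries)) {
    rows <- list()
    for (k in seq_along(loci)) {
      nm <- loci[[k]]$locus_name
      if (is.null(diags[[nm]])) next
      present <- intersect(queries, rownames(loci[[k]]$seqs))
      for (q in present) {
        res <- assign_specimen(loci[[k]]$seqs[q, ], diags[[nm]],
                               locus_length = loci[[k]]$length)
        rows[[length(rows) + 1L]] <- data.frame(
          locus = nm, specimen_id = q, assigned_group = res$group,
          votes = paste(sprintf("%s:%d", names(res$tally), res$tally),
                        collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    assigns <- do.call(rbind, rows)
    if (!is.null(assigns)) {
      utils::write.table(assigns, emit(file.path(outdir, "assignments.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    package = "barcodiag",
    version = as.character(utils::packageVersion("barcodiag")),
    parameters = list(grouping = grouping, bin_width = bin_width,
                      min_variant_carriers = min_variant_carriers,
                      sd_estimator = sd_estimator, queries = queries),
    inputs = as.list(tools::md5sum(c(fasta, metadata))),
    outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, summaries = summaries, gaps = gap_df,
                 diagnostics = diags,
                 assignments = if (length(assigns)) assigns else NULL,
                 manifest = manifest))
}

#' Write a simulated dataset to standard input files
#'
#' Emits one aligned FASTA per locus, the specimen metadata TSV and a
#' `truth.json` describing the generating configuration, so simulated data
#' are format-identical to empirical input for [run_pipeline()].
#'
#' @param config A `sim_config` (e.g. [neocalanus_config()]).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the `simulated_dataset` and the named
#'   vector of FASTA paths.
#' @export
simulate_to_files <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config)
  paths <- character(0)
  for (nm in names(sim$dataset$loci)) {
    p <- file.path(outdir, paste0(nm, ".fasta"))
    write_fasta_alignment(sim$dataset$loci[[nm]], p)
    paths[nm] <- p
  }
  write_metadata(sim$dataset$specimens, file.path(outdir, "metadata.tsv"))
  truth <- list(
    seed = config$seed,
    group_sizes = as.list(config$group_sizes),
    loci = lapply(sim$truth, function(tr) list(
      edges_p = as.list(tr$edges_p),
      edge_counts = as.list(tr$edge_counts))))
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, fasta = paths,
                 metadata = file.path(outdir, "metadata.tsv")))
}
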