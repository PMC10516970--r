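# Orchestration and file I/O: TSV contracts, configuration, and the
# end-to-end run from raw tables (or a synthetic design) to result bundle.

#' Read the four vapor-qSIP input tables from TSV files
#'
#' The feature table is taxa-by-fraction-samples with a `taxon_id` column and
#' one column per fraction named `tubeID:fractionIndex`; fraction metadata,
#' sample metadata and taxonomy are plain TSVs (tab-delimited, UTF-8, `.`
#' decimal). Cross-validates that every feature column has fraction
#' metadata, every tube has sample metadata and every taxon a taxonomy row.
#'
#' @param features,fractions,samples,taxonomy file paths.
#' @return A validated [qsip_data()] bundle.
#' @seealso [write_qsip_data()] for the inverse.
#' @export
load_qsip_data <- function(features, fractions, samples, taxonomy) {
  for (f in c(features, fractions, samples, taxonomy)) {
    if (!file.exists(f)) abort(sprintf("input file not found: %s", f))
  }
  feat <- readr::read_tsv(features, show_col_types = FALSE)
  if (nrow(feat) == 0 || !"taxon_id" %in% names(feat)) {
    abort("feature table must be non-empty with a `taxon_id` column")
  }
  frac_cols <- setdiff(names(feat), "taxon_id")
  if (!all(grepl("^.+:[0-9]+$", frac_cols))) {
    abort("feature-table columns must be named `tubeID:fractionIndex`")
  }
  counts <- feat |>
    tidyr::pivot_longer(-"taxon_id", names_to = "fraction_sample",
                        values_to = "reads") |>
    tidyr::separate_wider_regex("fraction_sample",
                                c(tube_id = ".+", ":", fraction_index = "[0-9]+")) |>
    dplyr::mutate(fraction_index = as.integer(.data$fraction_index)) |>
    dplyr::filter(.data$reads > 0)
  fr <- readr::read_tsv(fractions, show_col_types = FALSE)
  sm <- readr::read_tsv(samples, show_col_types = FALSE)
  tx <- readr::read_tsv(taxonomy, show_col_types = FALSE)
  qsip_data(counts = counts, fractions = fr, samples = sm, taxonomy = tx)
}

#' Write a `qsip_data` bundle as the canonical four TSV files
#'
#' @param data a [qsip_data()] bundle.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (`features.tsv`, `fractions.tsv`,
#'   `samples.tsv`, `taxonomy.tsv`).
#' @export
write_qsip_data <- function(data, dir) {
  assert_qsip_data(data)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- data$counts |>
    dplyr::mutate(fraction_sample = paste0(.data$tube_id, ":", .data$fraction_index)) |>
    dplyr::select("taxon_id", "fraction_sample", "reads") |>
    tidyr::pivot_wider(names_from = "fraction_sample", values_from = "reads",
                       values_fill = 0)
  paths <- file.path(dir, c("features.tsv", "fractions.tsv", "samples.tsv",
                            "taxonomy.tsv"))
  readr::write_tsv(wide, paths[1])
  readr::write_tsv(data$fractions, paths[2])
  readr::write_tsv(data$samples, paths[3])
  readr::write_tsv(data$taxonomy, paths[4])
  invisible(paths)
}

#' Configuration of a full vapor-qSIP pipeline run
#'
#' Collects every threshold and seed of the pipeline; all values are echoed
#' verbatim into the run manifest.
#'
#' @param density_min,density_max retained buoyant-density window (g/mL).
#' @param min_read_pairs fractions must exceed this many read pairs.
#' @param min_fractions,min_replicates prevalence-filter thresholds.
#' @param ape_growing_threshold,ape_active_threshold APE (%) thresholds.
#' @param flagged_tubes tube ids needing WAD offset correction.
#' @param min_growing_replicates replicates in which a taxon must grow to
#'   enter a treatment's growing set (overlap, top assimilators).
#' @param top_n taxa per sample in the top-assimilator ranking.
#' @param pseudocount CLR pseudocount (gene copies).
#' @param n_perm PERMANOVA permutations.
#' @param seed seed for all stochastic stages (permutations).
#' @param constants [qsip_constants()].
#' @return List of class `qsip_config`.
#' @export
qsip_config <- function(density_min = 1.614, density_max = 1.753,
                        min_read_pairs = 2000, min_fractions = 4,
                        min_replicates = 2, ape_growing_threshold = 5,
                        ape_active_threshold = 0, flagged_tubes = character(),
                        min_growing_replicates = 2, top_n = 5,
                        pseudocount = 1, n_perm = 999, seed = 1L,
                        constants = qsip_constants()) {
  structure(
    list(density_min = density_min, density_max = density_max,
         min_read_pairs = min_read_pairs, min_fractions = min_fractions,
         min_replicates = min_replicates,
         ape_growing_threshold = ape_growing_threshold,
         ape_active_threshold = ape_active_threshold,
         flagged_tubes = flagged_tubes,
         min_growing_replicates = min_growing_replicates, top_n = top_n,
         pseudocount = pseudocount, n_perm = n_perm, seed = as.integer(seed),
         constants = constants),
    class = "qsip_config"
  )
}

#' Run the vapor-qSIP pipeline end to end
#'
#' Filter fractions, correct flagged WAD offsets, estimate per-replicate
#' taxon enrichment, summarise growing communities, compute proportional
#' \eqn{^{18}}O assimilation, top assimilators and treatment overlap, and
#' run the statistics layer (CLR + PCA + two-way PERMANOVA on total and
#' growing communities; two-way ANOVAs on richness, growing share and mean
#' growth rates where the design is a 2x2 factorial).
#'
#' @param data a [qsip_data()] bundle (e.g. from [load_qsip_data()] or
#'   `simulate_experiment()$data`).
#' @param config a [qsip_config()].
#' @param out_dir optional directory; when given, writes
#'   `taxon_enrichment.tsv`, `sample_summary.tsv`, `assimilation.tsv`,
#'   `top_assimilators.tsv`, `venn_regions.json`, `phylum_change.tsv`,
#'   `predators.tsv`, `ordination.tsv`, `permanova.json`, `anova.tsv` and
#'   `manifest.json`.
#' @return List of class `qsip_result` with elements `enrichment`,
#'   `sample_summary`, `assimilation`, `top_assimilators`, `overlap`,
#'   `phylum_change`, `predators`, `pca_total`, `pca_growing`,
#'   `permanova_total`, `permanova_growing`, `anova`, and `manifest`.
#' @examples
#' sim <- simulate_experiment(qsip_design(
#'   scenarios = c("ambient", "drought"), n_taxa = 60, replicates = 2,
#'   reads_per_tube = 20000, seed = 11
#' ))
#' res <- run_qsip_pipeline(sim$data, qsip_config(seed = 11))
#' res$sample_summary
#' @export
run_qsip_pipeline <- function(data, config = qsip_config(), out_dir = NULL) {
  assert_qsip_data(data)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline halted in stage '%s': %s", name,
                    conditionMessage(e)))
    })
  }

  filtered <- stage("filter_fractions", filter_fractions(
    data, config$density_min, config$density_max, config$min_read_pairs
  ))
  filtered <- stage("correct_wad_offset",
                    correct_wad_offset(filtered, config$flagged_tubes))
  enrichment <- stage("enrich_all", enrich_all(
    filtered, config$constants, config$ape_growing_threshold,
    config$ape_active_threshold, config$min_fractions, config$min_replicates
  ))
  abund <- stage("absolute_abundances", absolute_abundances(filtered))
  summary <- stage("summarize_samples", summarize_samples(filtered, enrichment))
  assim <- stage("proportional_assimilation",
                 proportional_assimilation(abund, enrichment))
  top <- stage("top_assimilators", top_assimilators(
    assim, data$taxonomy, n = config$top_n,
    min_samples = config$min_growing_replicates
  ))
  gsets <- growing_sets(enrichment, config$min_growing_replicates)
  overlap <- if (length(gsets) >= 2) {
    stage("treatment_overlap", treatment_overlap(gsets))
  } else NULL

  pg_counts <- stage("phylum_growing_counts",
                     phylum_growing_counts(enrichment, data$taxonomy))
  ref_trt <- summary$treatment[1]
  ph_change <- if (length(unique(summary$treatment)) > 1) {
    stage("phylum_change", phylum_change(pg_counts, reference = ref_trt))
  } else NULL

  predators <- data$taxonomy |>
    dplyr::mutate(putative_predator = flag_putative_predators(.data$order)) |>
    dplyr::filter(.data$putative_predator) |>
    dplyr::select("taxon_id", "phylum", "order", "family", "genus")

  # statistics layer ---------------------------------------------------------
  abund_wide <- abund |>
    dplyr::select("tube_id", "taxon_id", "copies") |>
    tidyr::pivot_wider(names_from = "taxon_id", values_from = "copies",
                       values_fill = 0)
  mat_total <- as.matrix(abund_wide[, -1, drop = FALSE])
  rownames(mat_total) <- abund_wide$tube_id
  clr_total <- clr_transform(mat_total, config$pseudocount)
  pca_total <- pca_ordination(clr_total)

  growing_taxa <- unique(enrichment$taxon_id[enrichment$growing])
  pca_growing <- permanova_growing <- NULL
  meta <- data$samples[match(rownames(mat_total), data$samples$tube_id), ]
  two_by_two <- all(c("drought", "climate") %in% names(meta)) &&
    length(unique(meta$drought)) == 2 && length(unique(meta$climate)) == 2

  permanova_total <- if (two_by_two) {
    drought <- meta$drought
    climate <- meta$climate
    permanova_two_way(dist(clr_total), drought, climate,
                      n_perm = config$n_perm, seed = config$seed)
  } else NULL
  if (length(growing_taxa) >= 2) {
    keep <- intersect(colnames(mat_total), growing_taxa)
    mat_g <- mat_total[, keep, drop = FALSE]
    ok <- rowSums(mat_g) > 0
    if (sum(ok) >= 3) {
      clr_g <- clr_transform(mat_g[ok, , drop = FALSE], config$pseudocount)
      pca_growing <- pca_ordination(clr_g)
      if (two_by_two && length(unique(meta$drought[ok])) == 2 &&
          length(unique(meta$climate[ok])) == 2) {
        drought <- meta$drought[ok]
        climate <- meta$climate[ok]
        permanova_growing <- permanova_two_way(
          dist(clr_g), drought, climate,
          n_perm = config$n_perm, seed = config$seed
        )
      }
    }
  }

  anova_tab <- NULL
  if (two_by_two) {
    smeta <- data$samples[match(summary$tube_id, data$samples$tube_id), ]
    cells <- table(smeta$drought, smeta$climate)
    if (all(cells >= 2)) {
      drought <- smeta$drought
      climate <- smeta$climate
      anova_tab <- purrr::map_dfr(
        c("growing_richness", "growing_pct", "mean_rgr_all"),
        function(resp) {
          v <- summary[[resp]]
          if (any(is.na(v))) return(NULL)
          dplyr::mutate(anova_two_way(v, drought, climate),
                        response = resp, .before = 1)
        }
      )
      if (!is.null(anova_tab) && nrow(anova_tab) > 0) {
        anova_tab <- anova_tab |>
          dplyr::group_by(.data$response) |>
          dplyr::mutate(p_adj = ifelse(is.na(.data$p_value), NA,
                                       bh_adjust(.data$p_value))) |>
          dplyr::ungroup()
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vaporqsip")),
    config = config[setdiff(names(config), "constants")],
    constants = unclass(config$constants),
    counts = list(
      taxa_in = length(unique(data$taxonomy$taxon_id)),
      tubes = nrow(data$samples),
      fractions_in = nrow(data$fractions),
      fractions_retained = nrow(filtered$fractions),
      enrichment_rows = nrow(enrichment),
      taxa_retained = length(unique(enrichment$taxon_id)),
      growing_rows = sum(enrichment$growing)
    ),
    offsets = attr(filtered, "offsets")
  )

  result <- structure(
    list(enrichment = enrichment, sample_summary = summary,
         assimilation = assim, top_assimilators = top, overlap = overlap,
         phylum_change = ph_change, predators = predators,
         pca_total = pca_total, pca_growing = pca_growing,
         permanova_total = permanova_total,
         permanova_growing = permanova_growing, anova = anova_tab,
         manifest = manifest),
    class = "qsip_result"
  )
  if (!is.null(out_dir)) write_qsip_result(result, out_dir)
  result
}

#' @export
print.qsip_result <- function(x, ...) {
  cat("vapor-qSIP pipeline result\n")
  cat(sprintf("  taxa retained: %d; enrichment rows: %d; growing rows: %d\n",
              x$manifest$counts$taxa_retained, x$manifest$counts$enrichment_rows,
              x$manifest$counts$growing_rows))
  print(x$sample_summary)
  invisible(x)
}

write_qsip_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) readr::write_tsv(df, file.path(out_dir, name))
  }
  w(result$enrichment, "taxon_enrichment.tsv")
  w(result$sample_summary, "sample_summary.tsv")
  w(result$assimilation, "assimilation.tsv")
  w(result$top_assimilators, "top_assimilators.tsv")
  w(result$phylum_change, "phylum_change.tsv")
  w(result$predators, "predators.tsv")
  w(result$anova, "anova.tsv")
  if (!is.null(result$overlap)) {
    jsonlite::write_json(result$overlap$regions,
                         file.path(out_dir, "venn_regions.json"))
  }
  if (!is.null(result$pca_total)) {
    ord <- tidy(result$pca_total)
    readr::write_tsv(ord, file.path(out_dir, "ordination.tsv"))
  }
  perm <- purrr::compact(list(total = result$permanova_total,
                              growing = result$permanova_growing))
  if (length(perm) > 0) {
    jsonlite::write_json(perm, file.path(out_dir, "permanova.json"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  invisible(out_dir)
}
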