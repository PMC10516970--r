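# The qSIP estimator: density/read filtering, weighted average densities,
# WAD offset correction, GC and molecular-weight inference, and per-replicate
# 18O excess atom fraction with activity/growing thresholds.

#' Bundle the four input tables of a vapor-qSIP analysis
#'
#' @param counts long tibble of per-fraction reads: `tube_id`,
#'   `fraction_index`, `taxon_id`, `reads` (non-negative).
#' @param fractions fraction metadata: `tube_id`, `fraction_index`, `density`
#'   (g/mL), `total_copies` (ddPCR 16S copies), `total_read_pairs`.
#' @param samples tube metadata: `tube_id`, `treatment`, `replicate`,
#'   `isotope` (`"18O"` labeled / `"16O"` natural abundance), `drought`,
#'   `climate`, `incubation_days`, `soil_water_ape` (atom % excess, labeled
#'   tubes).
#' @param taxonomy `taxon_id` plus ranks `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species` (NA where unassigned).
#' @return A validated list of class `qsip_data`.
#' @seealso [load_qsip_data()] to read the TSV representation,
#'   [simulate_experiment()] to generate synthetic bundles.
#' @export
qsip_data <- function(counts, fractions, samples, taxonomy) {
  assert_cols(counts, c("tube_id", "fraction_index", "taxon_id", "reads"), "`counts`")
  assert_cols(fractions,
              c("tube_id", "fraction_index", "density", "total_copies",
                "total_read_pairs"), "`fractions`")
  assert_cols(samples,
              c("tube_id", "treatment", "replicate", "isotope"), "`samples`")
  assert_cols(taxonomy, c("taxon_id", "domain", "phylum", "class", "order",
                          "family", "genus", "species"), "`taxonomy`")
  if (any(counts$reads < 0)) abort("`counts$reads` must be non-negative")
  if (any(fractions$density <= 1)) abort("fraction densities must exceed 1 g/mL")
  if (anyDuplicated(fractions[c("tube_id", "fraction_index")])) {
    abort("duplicate (tube_id, fraction_index) rows in `fractions`")
  }
  if (anyDuplicated(samples$tube_id)) abort("duplicate tube ids in `samples`")
  key_c <- paste(counts$tube_id, counts$fraction_index)
  key_f <- paste(fractions$tube_id, fractions$fraction_index)
  orphan <- setdiff(unique(key_c), key_f)
  if (length(orphan) > 0) {
    abort(sprintf("counts reference fraction(s) with no metadata: %s",
                  paste(head(orphan, 5), collapse = ", ")))
  }
  orphan_t <- setdiff(unique(fractions$tube_id), samples$tube_id)
  if (length(orphan_t) > 0) {
    abort(sprintf("fractions reference tube(s) with no sample metadata: %s",
                  paste(head(orphan_t, 5), collapse = ", ")))
  }
  orphan_x <- setdiff(unique(counts$taxon_id), taxonomy$taxon_id)
  if (length(orphan_x) > 0) {
    abort(sprintf("counts reference taxa missing from taxonomy: %s",
                  paste(head(orphan_x, 5), collapse = ", ")))
  }
  structure(
    list(counts = tibble::as_tibble(counts),
         fractions = tibble::as_tibble(fractions),
         samples = tibble::as_tibble(samples),
         taxonomy = tibble::as_tibble(taxonomy)),
    class = "qsip_data"
  )
}

#' @export
print.qsip_data <- function(x, ...) {
  cat(sprintf(
    "vapor-qSIP dataset: %d taxa, %d tubes, %d fractions, %d count records\n",
    length(unique(x$taxonomy$taxon_id)), nrow(x$samples), nrow(x$fractions),
    nrow(x$counts)
  ))
  invisible(x)
}

#' Retain gradient fractions inside the density window with adequate reads
#'
#' Fractions below the window are typically contaminated with displacement
#' water, those above with concentrated CsCl; fractions with few read pairs
#' have unreliable composition. Keeps fractions whose density lies in
#' `[density_min, density_max]` (inclusive) and whose `total_read_pairs`
#' strictly exceeds `min_read_pairs`. Count records for removed fractions are
#' dropped too.
#'
#' @param data a [qsip_data()] bundle.
#' @param density_min,density_max retained buoyant-density window (g/mL).
#' @param min_read_pairs fractions must have strictly more read pairs.
#' @return The filtered `qsip_data`, with a `retained_fractions` attribute
#'   (tibble of per-tube retained counts; tubes left with fewer than 4
#'   fractions are flagged).
#' @examples
#' sim <- simulate_experiment(qsip_design(
#'   scenarios = "ambient", n_taxa = 30, replicates = 2,
#'   reads_per_tube = 20000, seed = 3
#' ))
#' filt <- filter_fractions(sim$data)
#' attr(filt, "retained_fractions")
#' @export
filter_fractions <- function(data, density_min = 1.614, density_max = 1.753,
                             min_read_pairs = 2000) {
  assert_qsip_data(data)
  fr <- data$fractions
  if (any(!is.finite(fr$density))) abort("fraction densities must be finite")
  keep <- fr$density >= density_min & fr$density <= density_max &
    fr$total_read_pairs > min_read_pairs
  kept <- fr[keep, , drop = FALSE]
  retained <- dplyr::count(kept, .data$tube_id, name = "n_retained") |>
    dplyr::right_join(tibble::tibble(tube_id = unique(fr$tube_id)), by = "tube_id") |>
    dplyr::mutate(n_retained = tidyr::replace_na(.data$n_retained, 0L),
                  flagged_few = .data$n_retained < 4)
  key <- paste(data$counts$tube_id, data$counts$fraction_index)
  keep_key <- paste(kept$tube_id, kept$fraction_index)
  out <- data
  out$fractions <- kept
  out$counts <- data$counts[key %in% keep_key, , drop = FALSE]
  attr(out, "retained_fractions") <- retained
  out
}

# Per-fraction taxon copies: reads proportion within the fraction times the
# fraction's ddPCR total. The per-fraction abundance currency of all WADs.
taxon_fraction_copies <- function(data) {
  totals <- data$counts |>
    dplyr::group_by(.data$tube_id, .data$fraction_index) |>
    dplyr::summarise(fraction_reads = sum(.data$reads), .groups = "drop")
  data$counts |>
    dplyr::left_join(totals, by = c("tube_id", "fraction_index")) |>
    dplyr::left_join(
      dplyr::select(data$fractions, "tube_id", "fraction_index", "density",
                    "total_copies"),
      by = c("tube_id", "fraction_index")
    ) |>
    dplyr::mutate(copies = ifelse(.data$fraction_reads > 0,
                                  .data$reads / .data$fraction_reads * .data$total_copies,
                                  0))
}

#' Weighted average density of every taxon in every tube
#'
#' For each taxon and tube, per-fraction taxon copies are the taxon's read
#' proportion in the fraction times the fraction's ddPCR total; the weighted
#' average density (WAD) is the copy-weighted mean of fraction densities.
#'
#' @param data a (filtered) [qsip_data()] bundle.
#' @return Tibble `tube_id`, `taxon_id`, `wad` (g/mL),
#'   `n_fractions_present` (fractions with nonzero copies). Taxa absent from
#'   a tube simply have no row (absence, not a zero).
#' @examples
#' sim <- simulate_experiment(qsip_design(
#'   scenarios = "ambient", n_taxa = 30, replicates = 2,
#'   reads_per_tube = 20000, seed = 3
#' ))
#' head(taxon_wads(filter_fractions(sim$data)))
#' @export
taxon_wads <- function(data) {
  assert_qsip_data(data)
  taxon_fraction_copies(data) |>
    dplyr::filter(.data$copies > 0) |>
    dplyr::group_by(.data$tube_id, .data$taxon_id) |>
    dplyr::summarise(
      wad = sum(.data$density * .data$copies) / sum(.data$copies),
      n_fractions_present = dplyr::n(),
      .groups = "drop"
    )
}

#' Community-level weighted average density per tube
#'
#' Copy-weighted mean fraction density over each tube's retained fractions,
#' weighting by the ddPCR totals.
#'
#' @param data a (filtered) [qsip_data()] bundle.
#' @return Tibble `tube_id`, `community_wad`.
#' @export
community_wads <- function(data) {
  assert_qsip_data(data)
  data$fractions |>
    dplyr::group_by(.data$tube_id) |>
    dplyr::summarise(
      community_wad = sum(.data$density * .data$total_copies) /
        sum(.data$total_copies),
      .groups = "drop"
    )
}

#' Correct the density offset of tubes with lost fractions
#'
#' When low-density fractions are lost during gradient collection, a tube's
#' community WAD is biased heavy relative to its companions. For each flagged
#' tube the offset is its community WAD minus the mean community WAD of the
#' unflagged tubes in the same treatment-by-isotope group, and that offset is
#' subtracted from every fraction density of the flagged tube. Only
#' explicitly flagged tubes are corrected.
#'
#' @param data a (filtered) [qsip_data()] bundle.
#' @param flagged_tube_ids character vector of tube ids to correct.
#' @return The corrected `qsip_data`, with an `offsets` attribute (tibble
#'   of applied offsets).
#' @examples
#' des <- qsip_design(scenarios = "ambient", n_taxa = 30, replicates = 3,
#'                    reads_per_tube = 20000, seed = 5,
#'                    drop_lightest = c(ambient_r1_18O = 3))
#' sim <- simulate_experiment(des)
#' corr <- correct_wad_offset(filter_fractions(sim$data), "ambient_r1_18O")
#' attr(corr, "offsets")
#' @export
correct_wad_offset <- function(data, flagged_tube_ids) {
  assert_qsip_data(data)
  if (length(flagged_tube_ids) == 0) {
    attr(data, "offsets") <- tibble::tibble(tube_id = character(), offset = numeric())
    return(data)
  }
  unknown <- setdiff(flagged_tube_ids, data$samples$tube_id)
  if (length(unknown) > 0) {
    abort(sprintf("flagged tube(s) not in the dataset: %s",
                  paste(unknown, collapse = ", ")))
  }
  cw <- community_wads(data) |>
    dplyr::left_join(dplyr::select(data$samples, "tube_id", "treatment", "isotope"),
                     by = "tube_id")
  offsets <- purrr::map_dfr(flagged_tube_ids, function(tid) {
    row <- cw[cw$tube_id == tid, ]
    refs <- cw[cw$treatment == row$treatment & cw$isotope == row$isotope &
                 !(cw$tube_id %in% flagged_tube_ids), ]
    if (nrow(refs) == 0) {
      abort(sprintf(
        "uncorrectable tube '%s': no unflagged reference tube in treatment '%s' (%s)",
        tid, row$treatment, row$isotope
      ))
    }
    tibble::tibble(tube_id = tid,
                   offset = row$community_wad - mean(refs$community_wad))
  })
  out <- data
  idx <- match(out$fractions$tube_id, offsets$tube_id)
  shift <- ifelse(is.na(idx), 0, offsets$offset[idx])
  out$fractions$density <- out$fractions$density - shift
  attr(out, "offsets") <- offsets
  out
}

#' Prevalence filter: keep taxa observed consistently within a treatment
#'
#' A taxon is retained for a treatment if it is present (reads > 0) in at
#' least `min_fractions` fractions in each of at least `min_replicates`
#' labeled replicate tubes of that treatment. Infrequent taxa yield unstable
#' WADs and are excluded before enrichment estimation.
#'
#' @param data a (filtered) [qsip_data()] bundle.
#' @param min_fractions minimum fractions per qualifying tube.
#' @param min_replicates minimum qualifying labeled replicate tubes.
#' @return Tibble `treatment`, `taxon_id` of retained pairs, with a
#'   `coverage` attribute giving the fraction of labeled read pairs carried
#'   by retained taxa per treatment.
#' @examples
#' sim <- simulate_experiment(qsip_design(
#'   scenarios = "ambient", n_taxa = 30, replicates = 2,
#'   reads_per_tube = 20000, seed = 3
#' ))
#' nrow(prevalence_filter(filter_fractions(sim$data)))
#' @export
prevalence_filter <- function(data, min_fractions = 4, min_replicates = 2) {
  assert_qsip_data(data)
  labeled <- data$samples$tube_id[data$samples$isotope == "18O"]
  counts <- data$counts |>
    dplyr::filter(.data$tube_id %in% labeled, .data$reads > 0) |>
    dplyr::left_join(dplyr::select(data$samples, "tube_id", "treatment"),
                     by = "tube_id")
  per_tube <- counts |>
    dplyr::group_by(.data$treatment, .data$tube_id, .data$taxon_id) |>
    dplyr::summarise(n_fr = dplyr::n(), .groups = "drop")
  retained <- per_tube |>
    dplyr::filter(.data$n_fr >= min_fractions) |>
    dplyr::group_by(.data$treatment, .data$taxon_id) |>
    dplyr::summarise(n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_rep >= min_replicates) |>
    dplyr::select("treatment", "taxon_id")
  coverage <- counts |>
    dplyr::semi_join(retained, by = c("treatment", "taxon_id")) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(retained_reads = sum(.data$reads), .groups = "drop") |>
    dplyr::left_join(
      counts |>
        dplyr::group_by(.data$treatment) |>
        dplyr::summarise(total_reads = sum(.data$reads), .groups = "drop"),
      by = "treatment"
    ) |>
    dplyr::mutate(coverage = .data$retained_reads / .data$total_reads)
  attr(retained, "coverage") <- coverage
  retained
}

#' Infer GC content from the unlabeled weighted average density
#'
#' Inverts the linear density-GC relation; results outside `[0, 1]` (possible
#' under density noise) are clamped, and the number of clamped values is
#' reported via a warning.
#'
#' @param w_light unlabeled WAD (g/mL), > 0.
#' @param constants [qsip_constants()].
#' @return GC content fraction in `[0, 1]`. Vectorized.
#' @examples
#' gc_from_wad(1.687810)
#' @export
gc_from_wad <- function(w_light, constants = qsip_constants()) {
  if (any(w_light <= 0)) abort("`w_light` must be positive")
  gc <- (w_light - constants$density_gc_intercept) / constants$density_gc_slope
  # 1-ulp overshoot of the exact boundary is numerical, not a data problem
  n_clamped <- sum(gc < -1e-9 | gc > 1 + 1e-9)
  if (n_clamped > 0) {
    warn(sprintf("%d GC value(s) outside [0, 1] were clamped", n_clamped))
  }
  pmin(pmax(gc, 0), 1)
}

#' Molecular weights of unlabeled and fully 18O-substituted DNA
#'
#' @param gc GC content fraction in `[0, 1]`.
#' @param constants [qsip_constants()].
#' @return Tibble with `m_light` and `m_heavymax` (g/mol).
#' @examples
#' molecular_weights(c(0, 0.5, 1))
#' @export
molecular_weights <- function(gc, constants = qsip_constants()) {
  if (any(gc < 0 | gc > 1)) abort("`gc` must lie in [0, 1]")
  m_light <- constants$mw_gc_slope * gc + constants$mw_gc_intercept
  tibble::tibble(m_light = m_light,
                 m_heavymax = m_light + constants$mw_18O_max_shift)
}

#' Excess atom fraction 18O from the labeled/unlabeled density shift
#'
#' The estimator at the heart of qSIP. GC content is inferred from the
#' unlabeled WAD, giving the molecular weight of unlabeled DNA and its
#' maximum at full \eqn{^{18}}O substitution; the labeled molecular weight
#' follows from the proportional density shift,
#' \eqn{M_{lab} = M_{light} \, w_{lab} / w_{light}}; and
#' \deqn{EAF = \frac{M_{lab} - M_{light}}{M_{heavymax} - M_{light}}
#'   (1 - 0.002000429).}
#' Negative values (labeled WAD below the unlabeled reference, possible under
#' noise) are retained.
#'
#' @param w_light unlabeled reference WAD (g/mL), > 0.
#' @param w_lab labeled WAD (g/mL), > 0.
#' @param constants [qsip_constants()].
#' @return Excess atom fraction (decimal; APE is 100 times this). Vectorized.
#' @examples
#' excess_atom_fraction(1.687810, 1.720977)
#' @export
excess_atom_fraction <- function(w_light, w_lab, constants = qsip_constants()) {
  if (any(w_light <= 0) || any(w_lab <= 0)) abort("WADs must be positive")
  gc <- gc_from_wad(w_light, constants)
  mw <- molecular_weights(gc, constants)
  m_lab <- mw$m_light * (w_lab / w_light)
  (m_lab - mw$m_light) / (mw$m_heavymax - mw$m_light) *
    (1 - constants$nat_abund_18O)
}

#' Per-replicate taxon 18O enrichment across an experiment
#'
#' Runs the full estimator over a filtered dataset: prevalence-filters taxa,
#' computes per-tube WADs, forms each taxon's unlabeled reference WAD as the
#' mean of its WADs across the treatment's natural-abundance tubes (falling
#' back to the global unlabeled mean when a taxon is missing from a
#' treatment's unlabeled tubes, and excluding taxa with no unlabeled
#' reference anywhere), then computes the excess atom fraction for every
#' taxon in every labeled tube.
#'
#' @param data a (filtered, offset-corrected) [qsip_data()] bundle.
#' @param constants [qsip_constants()].
#' @param ape_growing_threshold APE (%) above which a taxon is called
#'   growing (default 5, guarding against between-tube density variation).
#' @param ape_active_threshold APE (%) above which a taxon is called active.
#' @param min_fractions,min_replicates prevalence-filter settings, see
#'   [prevalence_filter()].
#' @return A tibble of class `qsip_enrichment`: one row per retained taxon x
#'   labeled tube with `taxon_id`, `treatment`, `tube_id`, `replicate`,
#'   `w_light`, `w_lab`, `gc`, `m_light`, `m_lab`, `m_heavymax`, `eaf`,
#'   `ape`, `active`, `growing`, `n_fractions_present`, `soil_water_ape`,
#'   `incubation_days`. Attribute `excluded_taxa` lists taxa dropped for
#'   lack of any unlabeled reference.
#' @examples
#' sim <- simulate_experiment(qsip_design(
#'   scenarios = "ambient", n_taxa = 30, replicates = 2,
#'   reads_per_tube = 20000, seed = 3
#' ))
#' enr <- enrich_all(filter_fractions(sim$data))
#' dplyr::count(enr, growing)
#' @export
enrich_all <- function(data, constants = qsip_constants(),
                       ape_growing_threshold = 5, ape_active_threshold = 0,
                       min_fractions = 4, min_replicates = 2) {
  assert_qsip_data(data)
  samples <- data$samples
  n_lab <- table(samples$treatment[samples$isotope == "18O"])
  n_unl <- table(samples$treatment[samples$isotope == "16O"])
  trts <- unique(samples$treatment)
  if (!all(trts %in% names(n_lab)) || !all(trts %in% names(n_unl))) {
    abort("every treatment needs at least one labeled and one natural-abundance tube")
  }

  retained <- prevalence_filter(data, min_fractions, min_replicates)
  wads <- taxon_wads(data) |>
    dplyr::left_join(dplyr::select(samples, "tube_id", "treatment", "replicate",
                                   "isotope"),
                     by = "tube_id")

  ref_trt <- wads |>
    dplyr::filter(.data$isotope == "16O") |>
    dplyr::group_by(.data$treatment, .data$taxon_id) |>
    dplyr::summarise(w_light_trt = mean(.data$wad), .groups = "drop")
  ref_global <- wads |>
    dplyr::filter(.data$isotope == "16O") |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(w_light_global = mean(.data$wad), .groups = "drop")

  lab <- wads |>
    dplyr::filter(.data$isotope == "18O") |>
    dplyr::semi_join(retained, by = c("treatment", "taxon_id")) |>
    dplyr::left_join(ref_trt, by = c("treatment", "taxon_id")) |>
    dplyr::left_join(ref_global, by = "taxon_id") |>
    dplyr::mutate(w_light = dplyr::coalesce(.data$w_light_trt, .data$w_light_global))

  excluded <- unique(lab$taxon_id[is.na(lab$w_light)])
  lab <- lab[!is.na(lab$w_light), , drop = FALSE]

  gc <- gc_from_wad(lab$w_light, constants)
  mw <- molecular_weights(gc, constants)
  m_lab <- mw$m_light * lab$wad / lab$w_light
  eaf <- (m_lab - mw$m_light) / (mw$m_heavymax - mw$m_light) *
    (1 - constants$nat_abund_18O)

  out <- tibble::tibble(
    taxon_id = lab$taxon_id,
    treatment = lab$treatment,
    tube_id = lab$tube_id,
    replicate = lab$replicate,
    w_light = lab$w_light,
    w_lab = lab$wad,
    gc = gc,
    m_light = mw$m_light,
    m_lab = m_lab,
    m_heavymax = mw$m_heavymax,
    eaf = eaf,
    ape = 100 * eaf,
    active = 100 * eaf > ape_active_threshold,
    growing = 100 * eaf > ape_growing_threshold,
    n_fractions_present = lab$n_fractions_present
  )
  extra <- intersect(c("soil_water_ape", "incubation_days"), names(samples))
  if (length(extra) > 0) {
    out <- dplyr::left_join(
      out, dplyr::select(samples, "tube_id", dplyr::all_of(extra)),
      by = "tube_id"
    )
  }
  attr(out, "excluded_taxa") <- excluded
  class(out) <- c("qsip_enrichment", class(out))
  out
}
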