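# From 18O enrichment to growth: relative growth rates, absolute abundances,
# growing-community size/richness, proportional 18O assimilation, top
# assimilators, treatment overlap, per-phylum change, putative predators.

#' Relative growth rate from taxon and soil-water enrichment
#'
#' Assuming linear growth, a taxon's per-day relative growth rate is its
#' \eqn{^{18}}O enrichment relative to the (time-averaged) soil-water
#' enrichment, per incubation day:
#' \deqn{RGR = APE_{taxon} / (APE_{soil\,water} \times days)}
#' with both APE values used as decimal atom fraction excess.
#'
#' @param ape_taxon taxon APE \eqn{^{18}}O (percent).
#' @param ape_soil_water time-averaged soil-water APE (percent), > 0.
#' @param days incubation length (days), > 0.
#' @return Relative growth rate (per day). Vectorized.
#' @examples
#' relative_growth_rate(29.65, 59.3, 5)
#' @export
relative_growth_rate <- function(ape_taxon, ape_soil_water, days) {
  if (any(is.na(ape_soil_water)) || any(ape_soil_water <= 0)) {
    abort("invalid label: `ape_soil_water` must be > 0 (labeled tubes only)")
  }
  if (any(days <= 0)) abort("`days` must be > 0")
  (ape_taxon / 100) / ((ape_soil_water / 100) * days)
}

#' Per-sample absolute taxon abundances
#'
#' A taxon's 16S copies in each retained fraction are its sequencing-inferred
#' relative abundance within the fraction times the fraction's ddPCR total;
#' per-sample absolute abundances agglomerate (sum) these per-fraction
#' copies over the gradient. Amplicon libraries are prepared per fraction,
#' so read counts only ever measure within-fraction composition; copy
#' numbers come from the ddPCR totals. The sample's total copies are the
#' ddPCR totals accumulated over all retained fractions.
#'
#' @param data a (filtered) [qsip_data()] bundle.
#' @param isotope which tubes to use; growth summaries use labeled tubes.
#' @return Tibble `tube_id`, `taxon_id`, `rel_abundance` (share of the
#'   sample's summed copies), `copies`, plus the per-tube `total_copies`.
#' @examples
#' sim <- simulate_experiment(qsip_design(
#'   scenarios = "ambient", n_taxa = 30, replicates = 2,
#'   reads_per_tube = 20000, seed = 3
#' ))
#' head(absolute_abundances(filter_fractions(sim$data)))
#' @export
absolute_abundances <- function(data, isotope = "18O") {
  assert_qsip_data(data)
  tubes <- data$samples$tube_id[data$samples$isotope %in% isotope]
  fr <- data$fractions[data$fractions$tube_id %in% tubes, ]
  totals <- fr |>
    dplyr::group_by(.data$tube_id) |>
    dplyr::summarise(total_copies = sum(.data$total_copies), .groups = "drop")
  if (any(totals$total_copies <= 0)) {
    abort(sprintf("empty sample(s): zero total 16S copies in %s",
                  paste(totals$tube_id[totals$total_copies <= 0], collapse = ", ")))
  }
  sub <- data
  sub$counts <- data$counts[data$counts$tube_id %in% tubes, , drop = FALSE]
  sub$fractions <- fr
  taxon_fraction_copies(sub) |>
    dplyr::group_by(.data$tube_id, .data$taxon_id) |>
    dplyr::summarise(copies = sum(.data$copies), .groups = "drop") |>
    dplyr::left_join(totals, by = "tube_id") |>
    dplyr::mutate(rel_abundance = .data$copies / .data$total_copies) |>
    dplyr::select("tube_id", "taxon_id", "rel_abundance", "copies",
                  "total_copies")
}

#' Percent of community 16S copies in growing taxa
#'
#' Per labeled sample: summed copies of growing taxa divided by summed copies
#' of the whole community, times 100.
#'
#' @param abundances output of [absolute_abundances()].
#' @param enrichment a [enrich_all()] table supplying per-sample growing
#'   flags.
#' @return Tibble `tube_id`, `growing_pct`.
#' @export
growing_fraction <- function(abundances, enrichment) {
  flags <- dplyr::select(enrichment, "tube_id", "taxon_id", "growing")
  abundances |>
    dplyr::left_join(flags, by = c("tube_id", "taxon_id")) |>
    dplyr::mutate(growing = dplyr::coalesce(.data$growing, FALSE)) |>
    dplyr::group_by(.data$tube_id) |>
    dplyr::summarise(
      growing_pct = 100 * sum(.data$copies[.data$growing]) / sum(.data$copies),
      .groups = "drop"
    )
}

#' Mean taxon-level relative growth rate per sample
#'
#' Unweighted mean of taxon-specific relative growth rates per labeled
#' sample, avoiding pseudoreplication in treatment comparisons. Either over
#' growing taxa only (APE > 5%), or over all retained taxa with negative
#' enrichment clamped to zero.
#'
#' @param enrichment a [enrich_all()] table.
#' @param include_nongrowing if `TRUE`, average over all retained taxa with
#'   `eaf` clamped at 0; if `FALSE` (default) over growing taxa only.
#' @return Tibble `tube_id`, `treatment`, `mean_rgr`, `n_taxa`. Samples with
#'   no qualifying taxon get `NA`.
#' @export
sample_mean_rgr <- function(enrichment, include_nongrowing = FALSE) {
  df <- enrichment |>
    dplyr::mutate(rgr = relative_growth_rate(
      pmax(.data$ape, 0), .data$soil_water_ape, .data$incubation_days
    ))
  if (!include_nongrowing) df <- dplyr::filter(df, .data$growing)
  all_tubes <- dplyr::distinct(enrichment, .data$tube_id, .data$treatment)
  df |>
    dplyr::group_by(.data$tube_id, .data$treatment) |>
    dplyr::summarise(mean_rgr = mean(.data$rgr), n_taxa = dplyr::n(),
                     .groups = "drop") |>
    dplyr::right_join(all_tubes, by = c("tube_id", "treatment"))
}

#' Per-sample summary of the growing community
#'
#' Combines growing richness, growing-community size (percent of 16S
#' copies), and mean relative growth rates (growing-only and all-taxa
#' variants) into the per-sample table used for treatment statistics.
#'
#' @param data a (filtered) [qsip_data()] bundle.
#' @param enrichment the matching [enrich_all()] table.
#' @return Tibble, one row per labeled sample: `tube_id`, `treatment`,
#'   `replicate`, `growing_richness`, `growing_pct`, `mean_rgr_growing`,
#'   `mean_rgr_all`, `total_copies`.
#' @examples
#' sim <- simulate_experiment(qsip_design(
#'   scenarios = c("ambient", "drought"), n_taxa = 50, replicates = 2,
#'   reads_per_tube = 20000, seed = 3
#' ))
#' filt <- filter_fractions(sim$data)
#' summarize_samples(filt, enrich_all(filt))
#' @export
summarize_samples <- function(data, enrichment) {
  assert_qsip_data(data)
  abund <- absolute_abundances(data)
  gf <- growing_fraction(abund, enrichment)
  rich <- enrichment |>
    dplyr::group_by(.data$tube_id) |>
    dplyr::summarise(growing_richness = sum(.data$growing), .groups = "drop")
  rgr_g <- sample_mean_rgr(enrichment, include_nongrowing = FALSE) |>
    dplyr::select("tube_id", mean_rgr_growing = "mean_rgr")
  rgr_a <- sample_mean_rgr(enrichment, include_nongrowing = TRUE) |>
    dplyr::select("tube_id", mean_rgr_all = "mean_rgr")
  totals <- dplyr::distinct(abund, .data$tube_id, .data$total_copies)
  data$samples |>
    dplyr::filter(.data$isotope == "18O") |>
    dplyr::select("tube_id", "treatment", "replicate") |>
    dplyr::left_join(rich, by = "tube_id") |>
    dplyr::left_join(gf, by = "tube_id") |>
    dplyr::left_join(rgr_g, by = "tube_id") |>
    dplyr::left_join(rgr_a, by = "tube_id") |>
    dplyr::left_join(totals, by = "tube_id") |>
    dplyr::mutate(growing_richness = tidyr::replace_na(.data$growing_richness, 0L))
}

#' Proportional 18O assimilation of growing taxa
#'
#' How much each growing taxon contributes to the community's total growth:
#' relative abundances are re-normalized within the growing subset of each
#' sample (summing to 1), multiplied by the taxon's relative growth rate, and
#' the products divided by their per-sample sum — yielding values in 0-1
#' that sum to 1 per sample.
#'
#' @param abundances output of [absolute_abundances()].
#' @param enrichment a [enrich_all()] table.
#' @return Tibble `tube_id`, `treatment`, `taxon_id`, `rel_abund_growing`,
#'   `rgr`, `proportional_assimilation`, `rank` (1 = top assimilator).
#' @export
proportional_assimilation <- function(abundances, enrichment) {
  growing <- enrichment |>
    dplyr::filter(.data$growing) |>
    dplyr::mutate(rgr = relative_growth_rate(
      .data$ape, .data$soil_water_ape, .data$incubation_days
    )) |>
    dplyr::select("tube_id", "treatment", "taxon_id", "rgr")
  if (nrow(growing) == 0) {
    abort("no growing taxa in any sample; cannot compute assimilation")
  }
  out <- growing |>
    dplyr::inner_join(dplyr::select(abundances, "tube_id", "taxon_id", "copies"),
                      by = c("tube_id", "taxon_id")) |>
    dplyr::group_by(.data$tube_id) |>
    dplyr::mutate(rel_abund_growing = .data$copies / sum(.data$copies),
                  weight = .data$rel_abund_growing * .data$rgr)
  bad <- dplyr::summarise(out, s = sum(.data$weight))
  if (any(bad$s <= 0)) {
    abort(sprintf("undefined assimilation: all growth rates are zero in %s",
                  paste(bad$tube_id[bad$s <= 0], collapse = ", ")))
  }
  out |>
    dplyr::mutate(
      proportional_assimilation = .data$weight / sum(.data$weight),
      rank = rank(-.data$proportional_assimilation, ties.method = "first")
    ) |>
    dplyr::ungroup() |>
    dplyr::select("tube_id", "treatment", "taxon_id", "rel_abund_growing",
                  "rgr", "proportional_assimilation", "rank")
}

# Genus label with fallback to family then phylum when unassigned.
agglomerate_label <- function(taxonomy) {
  dplyr::mutate(
    taxonomy,
    label = dplyr::coalesce(.data$genus, .data$family, .data$phylum),
    label_rank = dplyr::case_when(
      !is.na(.data$genus) ~ "genus",
      !is.na(.data$family) ~ "family",
      TRUE ~ "phylum"
    )
  ) |>
    dplyr::select("taxon_id", "label", "label_rank")
}

#' Top 18O assimilating taxa across samples
#'
#' Ranks taxa within each sample by proportional \eqn{^{18}}O assimilation,
#' keeps the top `n` per sample, and returns the union across samples. Taxa
#' must be growing in at least `min_samples` labeled replicates of their
#' treatment to be eligible. Ranking happens at the taxon (ASV) level;
#' display labels are then agglomerated at genus, falling back to family or
#' phylum where the genus is unassigned.
#'
#' @param assimilation output of [proportional_assimilation()].
#' @param taxonomy the taxonomy table of the dataset.
#' @param n taxa kept per sample.
#' @param min_samples minimum labeled replicates of the treatment in which
#'   the taxon must be growing.
#' @return Tibble of the union of top-`n` records: `tube_id`, `treatment`,
#'   `taxon_id`, `label`, `label_rank`, `proportional_assimilation`, `rank`.
#' @export
top_assimilators <- function(assimilation, taxonomy, n = 5, min_samples = 2) {
  eligible <- assimilation |>
    dplyr::group_by(.data$treatment, .data$taxon_id) |>
    dplyr::summarise(n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_samples >= min_samples) |>
    dplyr::select("treatment", "taxon_id")
  top <- assimilation |>
    dplyr::semi_join(eligible, by = c("treatment", "taxon_id")) |>
    dplyr::group_by(.data$tube_id) |>
    dplyr::mutate(rank = rank(-.data$proportional_assimilation,
                              ties.method = "first")) |>
    dplyr::filter(.data$rank <= n) |>
    dplyr::ungroup()
  top |>
    dplyr::left_join(agglomerate_label(taxonomy), by = "taxon_id") |>
    dplyr::select("tube_id", "treatment", "taxon_id", "label", "label_rank",
                  "proportional_assimilation", "rank") |>
    dplyr::arrange(.data$tube_id, .data$rank)
}

#' Growing-taxon overlap between treatments
#'
#' Computes the cardinality of every Venn region of the given growing-taxon
#' sets (all non-empty membership combinations), the pairwise shared counts
#' \eqn{|X \cap Y|}, and each treatment's unique count (taxa growing only
#' there).
#'
#' @param growing_sets named list of character vectors, one per treatment
#'   (e.g. taxa growing in >= 2 replicates of the treatment, see
#'   [growing_sets()]).
#' @return An object of class `qsip_overlap`: list with `regions` (tibble
#'   `membership`, `sets`, `n`), `shared` (matrix of pairwise intersection
#'   sizes), `unique_counts`, and `sets`.
#' @examples
#' ov <- treatment_overlap(list(a = c("x", "y", "z"), b = c("y", "z", "w")))
#' ov$regions
#' ov$shared
#' @export
treatment_overlap <- function(growing_sets) {
  if (is.null(names(growing_sets)) || any(names(growing_sets) == "")) {
    abort("`growing_sets` must be a fully named list")
  }
  sets <- purrr::map(growing_sets, unique)
  nm <- names(sets)
  k <- length(sets)
  if (k < 2) abort("need at least two sets")
  taxa <- unique(unlist(sets))
  membership <- vapply(taxa, function(t) {
    paste(nm[vapply(sets, function(s) t %in% s, logical(1))], collapse = "&")
  }, character(1))
  combos <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(nm, m, FUN = function(x) paste(x, collapse = "&"))
  }))
  region_n <- vapply(combos, function(cb) sum(membership == cb), integer(1))
  regions <- tibble::tibble(
    membership = combos,
    sets = lengths(strsplit(combos, "&", fixed = TRUE)),
    n = unname(region_n)
  )
  shared <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
    length(intersect(sets[[i]], sets[[j]]))
  }))
  dimnames(shared) <- list(nm, nm)
  unique_counts <- setNames(regions$n[match(nm, regions$membership)], nm)
  structure(
    list(regions = regions, shared = shared, unique_counts = unique_counts,
         sets = sets),
    class = "qsip_overlap"
  )
}

#' @export
print.qsip_overlap <- function(x, ...) {
  cat(sprintf("Growing-taxon overlap of %d treatments (%d taxa in the union)\n",
              length(x$sets), sum(x$regions$n)))
  print(x$shared)
  invisible(x)
}

#' @describeIn treatment_overlap Number of taxa of `target` also present in
#'   at least one of the `reference` sets — e.g. drought-enduring taxa: those
#'   growing under drought that also grow in a drought-unaffected treatment.
#' @param overlap a `qsip_overlap` object.
#' @param target name of the focal set.
#' @param reference names of the sets to overlap with.
#' @export
overlap_with_any <- function(overlap, target, reference) {
  stopifnot(inherits(overlap, "qsip_overlap"))
  missing <- setdiff(c(target, reference), names(overlap$sets))
  if (length(missing) > 0) {
    abort(sprintf("unknown set(s): %s", paste(missing, collapse = ", ")))
  }
  length(intersect(overlap$sets[[target]],
                   unique(unlist(overlap$sets[reference]))))
}

#' Sets of taxa growing consistently within each treatment
#'
#' A taxon belongs to a treatment's growing set if it carries the growing
#' flag in at least `min_replicates` labeled replicates of that treatment.
#'
#' @param enrichment a [enrich_all()] table.
#' @param min_replicates consistency threshold (default 2).
#' @return Named list of character vectors, one per treatment.
#' @export
growing_sets <- function(enrichment, min_replicates = 2) {
  df <- enrichment |>
    dplyr::filter(.data$growing) |>
    dplyr::group_by(.data$treatment, .data$taxon_id) |>
    dplyr::summarise(n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_rep >= min_replicates)
  split(df$taxon_id, df$treatment)
}

#' Relative change in growing-taxon counts per phylum
#'
#' For each phylum, the mean number of growing taxa per sample in a
#' treatment relative to a reference treatment: 0 = no change, 1 = increase
#' by 100%, -0.5 = halving. Phyla whose reference mean is zero are flagged
#' `undefined` rather than dropped.
#'
#' @param growing_counts tibble `tube_id`, `treatment`, `phylum`,
#'   `n_growing` (growing taxa of that phylum in that sample; see
#'   [phylum_growing_counts()]).
#' @param reference name of the reference treatment.
#' @return Tibble `phylum`, `treatment`, `mean_reference`, `mean_treatment`,
#'   `rel_change`, `undefined`.
#' @export
phylum_change <- function(growing_counts, reference) {
  assert_cols(growing_counts, c("tube_id", "treatment", "phylum", "n_growing"),
              "`growing_counts`")
  if (!reference %in% growing_counts$treatment) {
    abort(sprintf("reference treatment '%s' has no samples", reference))
  }
  means <- growing_counts |>
    dplyr::group_by(.data$phylum, .data$treatment) |>
    dplyr::summarise(mean_n = mean(.data$n_growing), .groups = "drop")
  ref <- means |>
    dplyr::filter(.data$treatment == reference) |>
    dplyr::select("phylum", mean_reference = "mean_n")
  means |>
    dplyr::filter(.data$treatment != reference) |>
    dplyr::inner_join(ref, by = "phylum") |>
    dplyr::mutate(
      undefined = .data$mean_reference == 0,
      rel_change = ifelse(.data$undefined, NA_real_,
                          (.data$mean_n - .data$mean_reference) / .data$mean_reference)
    ) |>
    dplyr::select("phylum", "treatment", "mean_reference",
                  mean_treatment = "mean_n", "rel_change", "undefined")
}

#' Count growing taxa per phylum per sample
#'
#' Helper building the input of [phylum_change()] and per-phylum ANOVAs from
#' an enrichment table. Samples with no growing member of a phylum get an
#' explicit zero.
#'
#' @param enrichment a [enrich_all()] table.
#' @param taxonomy the taxonomy table of the dataset.
#' @return Tibble `tube_id`, `treatment`, `phylum`, `n_growing`.
#' @export
phylum_growing_counts <- function(enrichment, taxonomy) {
  counts <- enrichment |>
    dplyr::filter(.data$growing) |>
    dplyr::left_join(dplyr::select(taxonomy, "taxon_id", "phylum"),
                     by = "taxon_id") |>
    dplyr::group_by(.data$tube_id, .data$treatment, .data$phylum) |>
    dplyr::summarise(n_growing = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(
    dplyr::distinct(enrichment, .data$tube_id, .data$treatment),
    phylum = unique(counts$phylum)
  )
  grid |>
    dplyr::left_join(counts, by = c("tube_id", "treatment", "phylum")) |>
    dplyr::mutate(n_growing = tidyr::replace_na(.data$n_growing, 0L))
}

#' Flag putative predatory bacteria from taxonomy
#'
#' Predatory lifestyles in soil bacteria concentrate in a handful of orders;
#' taxa are flagged as putative predators when their order is Myxococcales,
#' Bdellovibrionales, Vampirovibrionales, Haliangiales or Polyangiales
#' (case-insensitive). Unassigned orders are not flagged.
#'
#' @param order character vector of order-rank assignments (NA allowed).
#' @return Logical vector.
#' @examples
#' flag_putative_predators(c("Myxococcales", "Rhizobiales", NA))
#' @export
flag_putative_predators <- function(order) {
  predator_orders <- c("myxococcales", "bdellovibrionales",
                       "vampirovibrionales", "haliangiales", "polyangiales")
  !is.na(order) & tolower(order) %in% predator_orders
}
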