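#' Binding concordance per clonotype and specificity
#'
#' For every (clonotype, assigned pMHC) pair, the fraction of the clonotype's
#' GEMs assigned to that pMHC. A clonotype consistently binding one target
#' has a single entry at concordance 1; dispersed annotations split the mass.
#' The dataset average is the GEM-weighted mean of each GEM's own pair
#' concordance (so large unanimous clonotypes dominate, as they should in a
#' clean dataset); an unweighted per-pair mean is also returned.
#'
#' @param gems GEM tibble with `ct_id` and `assigned_pmhc` set.
#' @return A list of class `itrap_concordance`: `by_pair` (tibble `ct_id,
#'   pmhc, n_gems, size, concordance`), `average_pct` (GEM-weighted, 0-100)
#'   and `average_unweighted_pct`.
#' @export
binding_concordance <- function(gems) {
  sub <- gems |> filter(!is.na(.data$ct_id), !is.na(.data$assigned_pmhc))
  if (nrow(sub) == 0) {
    return(structure(list(by_pair = tibble(ct_id = character(0),
                                           pmhc = character(0),
                                           n_gems = integer(0),
                                           size = integer(0),
                                           concordance = double(0)),
                          average_pct = NA_real_,
                          average_unweighted_pct = NA_real_),
                     class = "itrap_concordance"))
  }
  by_pair <- sub |>
    count(.data$ct_id, pmhc = .data$assigned_pmhc, name = "n_gems") |>
    group_by(.data$ct_id) |>
    mutate(size = sum(.data$n_gems),
           concordance = .data$n_gems / .data$size) |>
    ungroup()
  structure(list(
    by_pair = by_pair,
    average_pct = 100 * sum(by_pair$n_gems * by_pair$concordance) /
      sum(by_pair$n_gems),
    average_unweighted_pct = 100 * mean(by_pair$concordance)
  ), class = "itrap_concordance")
}

#' @export
print.itrap_concordance <- function(x, ...) {
  cat(sprintf(
    "Binding concordance: %.2f%% (GEM-weighted) over %d clonotype-pMHC pairs\n",
    x$average_pct, nrow(x$by_pair)))
  invisible(x)
}

#' Dominant specificity per clonotype
#'
#' The pMHC assigned to the plurality of a clonotype's GEMs (ties broken by
#' feature id), used to place clonotypes on specificity "plateaus" for the
#' similarity analysis.
#'
#' @param gems GEM tibble with `ct_id` and `assigned_pmhc`.
#' @return Tibble `ct_id, specificity, cdr3_a, cdr3_b`.
#' @export
clonotype_specificities <- function(gems) {
  gems |>
    filter(!is.na(.data$ct_id), !is.na(.data$assigned_pmhc)) |>
    group_by(.data$ct_id) |>
    summarise(
      specificity = {
        tab <- sort(table(.data$assigned_pmhc), decreasing = TRUE)
        names(tab)[1]
      },
      cdr3_a = first(stats::na.omit(.data$cdr3_a)),
      cdr3_b = first(stats::na.omit(.data$cdr3_b)),
      .groups = "drop"
    )
}

#' Classify low-concordance outlier GEMs
#'
#' GEMs whose (clonotype, assigned pMHC) concordance falls below `cutoff`
#' are flagged as outliers and classified: `no_expected_binder` when the
#' clonotype has no expected binder (typically too small to annotate);
#' `cross_reactivity_consistent` when the clonotype's dominant pMHC equals
#' its expected binder and the expected binder was detected in the GEM at a
#' lower UMI than the assigned one (the signature of a secondary, weaker
#' binding event); `dispersed_multiplet` when the clonotype scatters across
#' several low-concordance targets and the GEM itself carries pMHC
#' multiplets (an ambient-capture artifact signature); `other` otherwise.
#' GEMs whose assigned and expected pMHC are restricted by different HLA
#' alleles additionally get `hla_divergent = TRUE`.
#'
#' @param gems GEM tibble with `ct_id` and `assigned_pmhc`.
#' @param binders `itrap_binders` from [annotate_expected_binders()].
#' @param cutoff Concordance below which a GEM is an outlier (default 0.5).
#' @return Tibble `barcode_full, ct_id, assigned_pmhc, concordance, category,
#'   hla_divergent`.
#' @export
classify_outliers <- function(gems, binders, cutoff = 0.5) {
  conc <- binding_concordance(gems)$by_pair
  feature_allele <- gems |>
    select("captures") |>
    tidyr::unnest("captures") |>
    distinct(.data$feature_id, .data$hla_allele)

  sub <- gems |>
    filter(!is.na(.data$ct_id), !is.na(.data$assigned_pmhc)) |>
    left_join(conc |> select("ct_id", "pmhc", "concordance"),
              by = c("ct_id", "assigned_pmhc" = "pmhc")) |>
    filter(.data$concordance < cutoff)
  if (nrow(sub) == 0) {
    return(tibble(barcode_full = character(0), ct_id = character(0),
                  assigned_pmhc = character(0), concordance = double(0),
                  category = character(0), hla_divergent = logical(0)))
  }
  dominant <- conc |>
    group_by(.data$ct_id) |>
    arrange(desc(.data$concordance), .data$pmhc, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("ct_id", dominant_pmhc = "pmhc")
  n_low <- conc |>
    filter(.data$concordance < cutoff) |>
    count(.data$ct_id, name = "n_low_targets")

  expected <- binders |> select("ct_id", "expected_pmhc")
  sub <- sub |>
    left_join(expected, by = "ct_id") |>
    left_join(dominant, by = "ct_id") |>
    left_join(n_low, by = "ct_id")

  cat_of <- function(i) {
    row <- sub[i, ]
    exp_p <- row$expected_pmhc
    if (is.na(exp_p)) return("no_expected_binder")
    cp <- row$captures[[1]]
    exp_umi <- cp$umi[match(exp_p, cp$feature_id)]
    assigned_umi <- cp$umi[match(row$assigned_pmhc, cp$feature_id)]
    if (!is.na(row$dominant_pmhc) && row$dominant_pmhc == exp_p &&
        !is.na(exp_umi) && exp_umi < assigned_umi) {
      return("cross_reactivity_consistent")
    }
    if (!is.na(row$n_low_targets) && row$n_low_targets >= 2 && NROW(cp) >= 2) {
      return("dispersed_multiplet")
    }
    "other"
  }
  category <- vapply(seq_len(nrow(sub)), cat_of, character(1))

  allele_of <- function(f) feature_allele$hla_allele[match(f, feature_allele$feature_id)]
  hla_div <- !is.na(sub$expected_pmhc) &
    !is.na(allele_of(sub$expected_pmhc)) &
    allele_of(sub$assigned_pmhc) != allele_of(sub$expected_pmhc)

  tibble(barcode_full = sub$barcode_full, ct_id = sub$ct_id,
         assigned_pmhc = sub$assigned_pmhc, concordance = sub$concordance,
         category = category, hla_divergent = hla_div)
}

#' Summarise a filter state with the four benchmark metrics
#'
#' Computes GEM retention relative to the raw table, assignment accuracy
#' against rank-sum expected binders, GEM-weighted average binding
#' concordance, and the intra/inter kernel-similarity AUC. GEMs lacking an
#' `assigned_pmhc` (e.g. an unfiltered table) are assigned their most
#' abundant capture first, so the raw state is measurable on the same
#' footing as filtered states.
#'
#' @param gems GEM table of the filter state under evaluation.
#' @param raw_gems The unfiltered parent table (retention denominator).
#' @param seed Seed for the inter-specificity sampling.
#' @param min_gems,alpha Passed to [annotate_expected_binders()].
#' @param params [kernel_params()] for the similarity kernel.
#' @return A list of class `itrap_metrics` with `retention_pct`,
#'   `accuracy_pct`, `avg_concordance_pct`, `similarity_auc_pct`, `seed`,
#'   `n_gems`, `n_clonotypes`.
#' @export
metrics_report <- function(gems, raw_gems, seed = 1L, min_gems = 10,
                           alpha = 0.05, params = kernel_params()) {
  if (!"assigned_pmhc" %in% names(gems) || anyNA(gems$assigned_pmhc)) {
    assigned <- purrr::map_chr(gems$captures, top_feature)
    if ("assigned_pmhc" %in% names(gems)) {
      gems$assigned_pmhc <- dplyr::coalesce(gems$assigned_pmhc, assigned)
    } else {
      gems$assigned_pmhc <- assigned
    }
  }
  binders <- annotate_expected_binders(gems, min_gems = min_gems, alpha = alpha)
  acc <- compute_accuracy(gems, binders)
  conc <- binding_concordance(gems)
  specs <- clonotype_specificities(gems)
  scores <- suppressMessages(intra_inter_scores(specs, seed = seed, params = params))
  auc <- if (length(scores$intra) > 0 && length(scores$inter) > 0) {
    similarity_auc(scores)
  } else NA_real_
  structure(list(
    retention_pct = 100 * nrow(gems) / nrow(raw_gems),
    accuracy_pct = 100 * acc$accuracy,
    avg_concordance_pct = conc$average_pct,
    similarity_auc_pct = auc,
    seed = as.integer(seed),
    n_gems = nrow(gems),
    n_clonotypes = dplyr::n_distinct(gems$ct_id[!is.na(gems$ct_id)])
  ), class = "itrap_metrics")
}

#' @export
print.itrap_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("GEMs retained: %.1f%% (%d GEMs, %d clonotypes)\n",
           "accuracy: %s%%  avg. concordance: %s%%  similarity AUC: %s\n"),
    x$retention_pct, x$n_gems, x$n_clonotypes,
    fmt_or_na(x$accuracy_pct), fmt_or_na(x$avg_concordance_pct),
    fmt_or_na(x$similarity_auc_pct)))
  invisible(x)
}

fmt_or_na <- function(x) if (is.na(x)) "NA" else sprintf("%.1f", x)
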