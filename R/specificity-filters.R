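#' ITRAP specificity filters
#'
#' The four filters applied after UMI thresholding, each independently
#' applicable and composable. Every filter records a `filter_state`
#' attribute on its output: name, GEMs in/out, clonotypes out and removal
#' counts by reason.
#'
#' @name specificity_filters
NULL

filter_state <- function(name, gems_in, out, removed_by_reason = NULL) {
  st <- list(
    name = name,
    gems_in = as.integer(gems_in),
    gems_out = nrow(out),
    clonotypes_out = dplyr::n_distinct(out$ct_id[!is.na(out$ct_id)]),
    removed_by_reason = removed_by_reason %||%
      c(removed = as.integer(gems_in - nrow(out)))
  )
  attr(out, "filter_state") <- st
  out
}

#' @describeIn specificity_filters Keep GEMs whose assigned pMHC is
#'   restricted by an HLA allele the GEM's donor carries. A T cell is
#'   restricted to the allele it was positively selected on, so a capture
#'   whose allele the donor lacks cannot be a true binding event.
#' @param gems GEM tibble with `assigned_pmhc` set on every row.
#' @param haplotypes Long tibble `donor_id, allele` ([read_hla_haplotypes()]).
#' @return Filtered GEM tibble (with a `filter_state` attribute).
#' @export
filter_hla_match <- function(gems, haplotypes) {
  n_in <- nrow(gems)
  if (n_in == 0) return(filter_state("hla", 0, gems))
  if (any(is.na(gems$assigned_pmhc))) {
    abort("filter_hla_match requires assigned_pmhc on every GEM",
          class = "itrap_usage_error")
  }
  missing_donors <- setdiff(unique(gems$donor), haplotypes$donor_id)
  if (length(missing_donors) > 0) {
    abort(sprintf("No HLA haplotype for donor(s): %s",
                  paste(missing_donors, collapse = ", ")),
          class = "itrap_integrity_error")
  }
  assigned_allele <- purrr::map2_chr(gems$captures, gems$assigned_pmhc,
                                     function(cp, f) {
                                       cp$hla_allele[match(f, cp$feature_id)]
                                     })
  hap_key <- paste(haplotypes$donor_id, normalize_hla_allele(haplotypes$allele))
  keep <- paste(gems$donor, normalize_hla_allele(assigned_allele)) %in% hap_key
  filter_state("hla", n_in, gems[keep, , drop = FALSE],
               c(hla_mismatch = sum(!keep)))
}

#' @describeIn specificity_filters Keep GEMs with a complete alpha/beta pair
#'   (after multiplet resolution and imputation).
#' @export
filter_paired_chains <- function(gems) {
  n_in <- nrow(gems)
  keep <- !is.na(gems$cdr3_a) & !is.na(gems$cdr3_b)
  filter_state("paired", n_in, gems[keep, , drop = FALSE],
               c(single_chain = sum(!keep)))
}

#' @describeIn specificity_filters Remove specificity singlets: a
#'   (clonotype, assigned pMHC) pair supported by exactly one GEM is too
#'   fragile to trust and is discarded.
#' @export
filter_specificity_singlets <- function(gems) {
  n_in <- nrow(gems)
  if (n_in == 0) return(filter_state("singlet", 0, gems))
  support <- gems |>
    count(.data$ct_id, .data$assigned_pmhc, name = "n_support")
  gems2 <- gems |>
    left_join(support, by = c("ct_id", "assigned_pmhc"))
  keep <- gems2$n_support >= 2
  out <- gems[keep, , drop = FALSE]
  filter_state("singlet", n_in, out, c(specificity_singlet = sum(!keep)))
}

#' @describeIn specificity_filters Keep GEMs the platform called as cells.
#' @export
filter_is_cell <- function(gems) {
  n_in <- nrow(gems)
  keep <- gems$is_cell
  filter_state("is_cell", n_in, gems[keep, , drop = FALSE],
               c(not_cell = sum(!keep)))
}

#' Apply a sequence of ITRAP filters
#'
#' Composes the threshold filter and the specificity filters in a configured
#' order. The default order is the canonical cascade
#' `threshold, hla, paired, singlet, is_cell`; the preset `"recommended"` is
#' the minimum recommended set, thresholding plus HLA matching.
#'
#' @param gems Clonotyped GEM tibble.
#' @param haplotypes Donor haplotype tibble (required when `"hla"` is among
#'   the steps).
#' @param thresholds A [threshold_set()] (required when `"threshold"` is
#'   among the steps).
#' @param steps Character vector, subset of
#'   `c("threshold", "hla", "paired", "singlet", "is_cell")`, applied in the
#'   given order; or use `preset`.
#' @param preset `"full"` (all five steps) or `"recommended"`
#'   (threshold + HLA).
#' @param exempt_imputed Passed to [apply_thresholds()].
#' @return A list with `gems` (final table), `stages` (named list of the
#'   table after each step) and `log` (tibble of per-step filter states).
#' @export
apply_itrap_filters <- function(gems, haplotypes = NULL, thresholds = NULL,
                                steps = NULL, preset = c("full", "recommended"),
                                exempt_imputed = FALSE) {
  if (is.null(steps)) {
    preset <- match.arg(preset)
    steps <- switch(preset,
                    full = c("threshold", "hla", "paired", "singlet", "is_cell"),
                    recommended = c("threshold", "hla"))
  }
  bad <- setdiff(steps, c("threshold", "hla", "paired", "singlet", "is_cell"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown filter step(s): %s", paste(bad, collapse = ", ")),
          class = "itrap_usage_error")
  }
  cur <- gems
  stages <- list()
  log <- list()
  for (s in steps) {
    n_in <- nrow(cur)
    cur <- switch(
      s,
      threshold = {
        if (is.null(thresholds)) {
          abort("`thresholds` required for the threshold step",
                class = "itrap_usage_error")
        }
        filter_state("threshold", n_in,
                     apply_thresholds(cur, thresholds, exempt_imputed))
      },
      hla = {
        if (is.null(haplotypes)) {
          abort("`haplotypes` required for the hla step",
                class = "itrap_usage_error")
        }
        filter_hla_match(cur, haplotypes)
      },
      paired = filter_paired_chains(cur),
      singlet = filter_specificity_singlets(cur),
      is_cell = filter_is_cell(cur)
    )
    st <- attr(cur, "filter_state")
    stages[[s]] <- cur
    log[[s]] <- tibble(step = s, gems_in = st$gems_in, gems_out = st$gems_out,
                       clonotypes_out = st$clonotypes_out)
  }
  list(gems = cur, stages = stages, log = purrr::list_rbind(log))
}
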