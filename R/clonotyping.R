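#' Resolve chain multiplets within GEMs
#'
#' A GEM should carry one TCR alpha and one beta chain, but droplets with
#' doublet cells or ambient contigs can carry several of either type. Per GEM
#' and chain type, the chain with the highest UMI count is selected; ties are
#' broken deterministically by lexicographic `(v_gene, j_gene, cdr3_aa)`.
#' Unselected chains are preserved in the `extra_chains` list-column for
#' downstream multiplet diagnostics.
#'
#' @param gems Curated GEM tibble (with a `chains` list-column).
#' @return GEM tibble with the `chains` list-column replaced by flat columns
#'   `v_a, j_a, cdr3_a, umi_a, v_b, j_b, cdr3_b, umi_b` (NA where the chain
#'   type is absent), `imputed_a`/`imputed_b` flags (all `FALSE` here) and an
#'   `extra_chains` list-column.
#' @export
resolve_multiplet_chains <- function(gems) {
  empty_extra <- tibble(chain_type = character(0), v_gene = character(0),
                        j_gene = character(0), cdr3_aa = character(0),
                        umi = integer(0), productive = logical(0),
                        full_length = logical(0))
  if (nrow(gems) == 0) {
    out <- gems |> select(-dplyr::any_of("chains"))
    out$v_a <- character(0); out$j_a <- character(0)
    out$cdr3_a <- character(0); out$umi_a <- integer(0)
    out$v_b <- character(0); out$j_b <- character(0)
    out$cdr3_b <- character(0); out$umi_b <- integer(0)
    out$imputed_a <- logical(0); out$imputed_b <- logical(0)
    out$extra_chains <- list()
    return(out)
  }
  flat <- gems |>
    select("barcode_full", "chains") |>
    tidyr::unnest("chains") |>
    arrange(.data$barcode_full, .data$chain_type, desc(.data$umi),
            .data$v_gene, .data$j_gene, .data$cdr3_aa) |>
    group_by(.data$barcode_full, .data$chain_type) |>
    mutate(.rank = row_number()) |>
    ungroup()

  selected <- flat |> filter(.data$.rank == 1L) |> select(-".rank")
  extras <- flat |> filter(.data$.rank > 1L) |> select(-".rank")

  wide <- selected |>
    tidyr::pivot_wider(
      id_cols = "barcode_full",
      names_from = "chain_type",
      values_from = c("v_gene", "j_gene", "cdr3_aa", "umi"),
      names_glue = "{.value}_{substr(chain_type, 1, 1)}"
    )
  # guarantee both chain-type column sets even if one type is absent entirely
  for (col in c("v_gene_a", "j_gene_a", "cdr3_aa_a", "umi_a",
                "v_gene_b", "j_gene_b", "cdr3_aa_b", "umi_b")) {
    if (!col %in% names(wide)) {
      wide[[col]] <- if (col %in% c("umi_a", "umi_b")) NA_integer_ else NA_character_
    }
  }
  wide <- wide |>
    rename(v_a = "v_gene_a", j_a = "j_gene_a", cdr3_a = "cdr3_aa_a",
           v_b = "v_gene_b", j_b = "j_gene_b", cdr3_b = "cdr3_aa_b")

  extra_nested <- extras |>
    tidyr::nest(extra_chains = -"barcode_full")

  out <- gems |>
    select(-"chains") |>
    left_join(wide, by = "barcode_full") |>
    left_join(extra_nested, by = "barcode_full") |>
    mutate(
      imputed_a = FALSE, imputed_b = FALSE,
      extra_chains = purrr::map(.data$extra_chains,
                                ~ if (is.null(.x)) empty_extra else .x)
    )
  out
}

#' Redefine clonotypes at the amino-acid level
#'
#' Groups GEMs carrying a complete alpha/beta pair by the six-tuple
#' `(v_a, j_a, cdr3_a, v_b, j_b, cdr3_b)`. Working at the amino-acid rather
#' than nucleotide level merges convergent rearrangements into larger
#' clonotypes, which is what gives the downstream UMI rank-sum test its
#' statistical power. Single-chain GEMs are left unassigned here; see
#' [impute_missing_chain()].
#'
#' @param gems Multiplet-resolved GEM tibble.
#' @return A list with `gems` (input plus a `ct_id` column, NA for unpaired
#'   GEMs) and `clonotypes` (tibble `ct_id, size, v_a, j_a, cdr3_a, v_b, j_b,
#'   cdr3_b`), sorted by decreasing size.
#' @export
redefine_clonotypes <- function(gems) {
  key_cols <- c("v_a", "j_a", "cdr3_a", "v_b", "j_b", "cdr3_b")
  paired <- !is.na(gems$cdr3_a) & !is.na(gems$cdr3_b)

  if (!any(paired)) {
    gems$ct_id <- NA_character_
    return(list(gems = gems,
                clonotypes = tibble(ct_id = character(0), size = integer(0),
                                    v_a = character(0), j_a = character(0),
                                    cdr3_a = character(0), v_b = character(0),
                                    j_b = character(0), cdr3_b = character(0))))
  }

  cts <- gems[paired, ] |>
    count(across(dplyr::all_of(key_cols)), name = "size") |>
    arrange(desc(.data$size), .data$cdr3_b, .data$cdr3_a, .data$v_b,
            .data$v_a, .data$j_b, .data$j_a) |>
    mutate(ct_id = sprintf("ct%05d", row_number())) |>
    select("ct_id", "size", dplyr::all_of(key_cols))

  gems$ct_id <- NULL
  gems <- gems |>
    left_join(cts |> select("ct_id", dplyr::all_of(key_cols)), by = key_cols)
  gems$ct_id[!paired] <- NA_character_
  list(gems = gems, clonotypes = cts)
}

#' Impute the missing chain of single-chain GEMs
#'
#' A GEM annotated with only one chain can still be placed if its half-key
#' `(v, j, cdr3)` occurs in exactly one established clonotype: the missing
#' chain is then copied from that clonotype (flagged imputed, UMI recorded as
#' 0, since no molecule of it was observed). Half-keys matching zero or
#' several clonotypes stay untouched — the same beta chain can pair with many
#' different alpha chains, and guessing among them fabricates pairings.
#'
#' @param gems GEM tibble with `ct_id` from [redefine_clonotypes()].
#' @param clonotypes Clonotype tibble from the same call.
#' @return GEM tibble with imputed chains filled in, `imputed_a`/`imputed_b`
#'   set, and `ct_id` assigned for newly completed GEMs.
#' @export
impute_missing_chain <- function(gems, clonotypes) {
  if (nrow(clonotypes) == 0 || nrow(gems) == 0) return(gems)

  a_key <- clonotypes |>
    group_by(.data$v_a, .data$j_a, .data$cdr3_a) |>
    summarise(n_ct = dplyr::n_distinct(.data$ct_id),
              ct_id = first(.data$ct_id),
              v_b = first(.data$v_b), j_b = first(.data$j_b),
              cdr3_b = first(.data$cdr3_b), .groups = "drop") |>
    filter(.data$n_ct == 1L)
  b_key <- clonotypes |>
    group_by(.data$v_b, .data$j_b, .data$cdr3_b) |>
    summarise(n_ct = dplyr::n_distinct(.data$ct_id),
              ct_id = first(.data$ct_id),
              v_a = first(.data$v_a), j_a = first(.data$j_a),
              cdr3_a = first(.data$cdr3_a), .groups = "drop") |>
    filter(.data$n_ct == 1L)

  alpha_only <- which(!is.na(gems$cdr3_a) & is.na(gems$cdr3_b))
  beta_only <- which(is.na(gems$cdr3_a) & !is.na(gems$cdr3_b))

  if (length(alpha_only) > 0 && nrow(a_key) > 0) {
    m <- match(paste(gems$v_a[alpha_only], gems$j_a[alpha_only],
                     gems$cdr3_a[alpha_only]),
               paste(a_key$v_a, a_key$j_a, a_key$cdr3_a))
    hit <- which(!is.na(m))
    idx <- alpha_only[hit]; src <- m[hit]
    gems$v_b[idx] <- a_key$v_b[src]
    gems$j_b[idx] <- a_key$j_b[src]
    gems$cdr3_b[idx] <- a_key$cdr3_b[src]
    gems$umi_b[idx] <- 0L
    gems$imputed_b[idx] <- TRUE
    gems$ct_id[idx] <- a_key$ct_id[src]
  }
  if (length(beta_only) > 0 && nrow(b_key) > 0) {
    m <- match(paste(gems$v_b[beta_only], gems$j_b[beta_only],
                     gems$cdr3_b[beta_only]),
               paste(b_key$v_b, b_key$j_b, b_key$cdr3_b))
    hit <- which(!is.na(m))
    idx <- beta_only[hit]; src <- m[hit]
    gems$v_a[idx] <- b_key$v_a[src]
    gems$j_a[idx] <- b_key$j_a[src]
    gems$cdr3_a[idx] <- b_key$cdr3_a[src]
    gems$umi_a[idx] <- 0L
    gems$imputed_a[idx] <- TRUE
    gems$ct_id[idx] <- b_key$ct_id[src]
  }
  gems
}

#' Clonotype a GEM table in one step
#'
#' Convenience wrapper running [resolve_multiplet_chains()],
#' [redefine_clonotypes()] and [impute_missing_chain()], then recomputing
#' clonotype sizes so imputed members are counted.
#'
#' @param gems Curated GEM tibble.
#' @return List with `gems` (clonotyped table) and `clonotypes` (summary with
#'   sizes including imputed members).
#' @export
clonotype_gems <- function(gems) {
  res <- resolve_multiplet_chains(gems)
  cl <- redefine_clonotypes(res)
  gems2 <- impute_missing_chain(cl$gems, cl$clonotypes)
  sizes <- gems2 |>
    filter(!is.na(.data$ct_id)) |>
    count(.data$ct_id, name = "size")
  clonotypes <- cl$clonotypes |>
    select(-"size") |>
    left_join(sizes, by = "ct_id") |>
    mutate(size = dplyr::coalesce(.data$size, 0L)) |>
    select("ct_id", "size", dplyr::everything())
  list(gems = gems2, clonotypes = clonotypes)
}
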