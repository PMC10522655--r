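#' Read a Cellranger-style VDJ contig annotation table
#'
#' Parses the `all_contig_annotations.csv` dialect: one row per assembled
#' contig with its chain call, V/J gene annotation, CDR3 amino-acid sequence,
#' UMI support and QC flags. Only TRA and TRB contigs are kept; other chain
#' calls (`Multi`, `IGH`, ...) are dropped and counted.
#'
#' @param path Path to the contig annotation CSV.
#' @return A tibble with one row per retained contig: `barcode`, `chain_type`
#'   (`"alpha"`/`"beta"`), `v_gene`, `j_gene`, `cdr3_aa`, `umi`, `productive`,
#'   `full_length`, `is_cell`. The number of non-TRA/TRB contigs dropped is
#'   attached as attribute `"dropped_other_chains"`.
#' @export
read_contig_annotations <- function(path) {
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "umis",
                "productive", "full_length", "is_cell")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("Contig file is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "itrap_format_error")
  }
  if (nrow(tab) == 0) {
    warn("Contig file contains no data rows")
    out <- tibble(barcode = character(0), chain_type = character(0),
                  v_gene = character(0), j_gene = character(0),
                  cdr3_aa = character(0), umi = integer(0),
                  productive = logical(0), full_length = logical(0),
                  is_cell = logical(0))
    attr(out, "dropped_other_chains") <- 0L
    return(out)
  }

  umi <- suppressWarnings(as.integer(tab$umis))
  bad_umi <- which(is.na(umi) & !is.na(tab$umis))
  if (length(bad_umi) > 0) {
    abort(sprintf("Unparseable UMI count '%s' at data row %d",
                  tab$umis[bad_umi[1]], bad_umi[1]),
          class = "itrap_format_error")
  }

  keep <- tab$chain %in% c("TRA", "TRB")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d contig(s) with non-TRA/TRB chain calls", n_dropped))
  }

  out <- tibble(
    barcode = tab$barcode[keep],
    chain_type = if_else(tab$chain[keep] == "TRA", "alpha", "beta"),
    v_gene = tab$v_gene[keep],
    j_gene = tab$j_gene[keep],
    cdr3_aa = tab$cdr3[keep],
    umi = umi[keep],
    productive = parse_flexible_logical(tab$productive[keep]),
    full_length = parse_flexible_logical(tab$full_length[keep]),
    is_cell = parse_flexible_logical(tab$is_cell[keep])
  )
  attr(out, "dropped_other_chains") <- n_dropped
  out
}

# Cellranger emits "True"/"False"; other exports use "true"/"TRUE". NA and
# unrecognised values map to FALSE (a contig without a QC call is not trusted).
parse_flexible_logical <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "1")
}

#' Read a pMHC multimer panel table
#'
#' The panel maps each DNA-barcoded multimer feature to its peptide, its
#' restricting HLA allele and whether it is a negative control. Alleles are
#' canonicalized to two-field resolution.
#'
#' @param path Path to a CSV with columns
#'   `feature_id,peptide,hla_allele,is_negative_control`.
#' @return A tibble with those four columns, alleles canonical.
#' @export
read_pmhc_panel <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("feature_id", "peptide", "hla_allele", "is_negative_control")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("Panel file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "itrap_format_error")
  }
  tab |>
    mutate(feature_id = as.character(.data$feature_id),
           peptide = as.character(.data$peptide),
           hla_allele = normalize_hla_allele(.data$hla_allele),
           is_negative_control = parse_flexible_logical(.data$is_negative_control)) |>
    select(dplyr::all_of(need))
}

#' Read pMHC UMI counts per GEM barcode
#'
#' Accepts either a wide CSV (first column `barcode`, one column per multimer
#' feature) or a MatrixMarket triplet file with an accompanying feature list
#' (features as rows, barcodes as columns, the Cellranger convention). Zero
#' counts are suppressed: absent captures are never materialized.
#'
#' @param path Path to the wide CSV or the `.mtx` file.
#' @param panel Panel tibble from [read_pmhc_panel()]; every feature id in the
#'   counts must resolve in the panel.
#' @param features,barcodes For MTX input only: paths to plain-text files with
#'   one feature id / one barcode per line (first comma- or tab-separated
#'   field is used).
#' @return A tibble of captures: `barcode`, `feature_id`, `peptide`,
#'   `hla_allele`, `umi`, `is_negative_control`, with `umi >= 1` everywhere.
#' @export
read_pmhc_counts <- function(path, panel, features = NULL, barcodes = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(features) || is.null(barcodes)) {
      abort("MTX input requires `features` and `barcodes` files",
            class = "itrap_format_error")
    }
    m <- Matrix::readMM(path)
    feat_ids <- read_id_list(features)
    bc_ids <- read_id_list(barcodes)
    if (nrow(m) != length(feat_ids) || ncol(m) != length(bc_ids)) {
      abort(sprintf(
        "MTX dimensions %dx%d do not match %d features x %d barcodes",
        nrow(m), ncol(m), length(feat_ids), length(bc_ids)),
        class = "itrap_format_error")
    }
    trip <- Matrix::summary(m)
    long <- tibble(barcode = bc_ids[trip$j],
                   feature_id = feat_ids[trip$i],
                   umi = as.numeric(trip$x))
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"barcode" %in% names(tab)) {
      abort("Wide pMHC count CSV must have a `barcode` column",
            class = "itrap_format_error")
    }
    long <- tab |>
      tidyr::pivot_longer(-"barcode", names_to = "feature_id", values_to = "umi") |>
      mutate(barcode = as.character(.data$barcode))
  }
  long <- long |> filter(!is.na(.data$umi), .data$umi != 0)
  if (any(long$umi < 0)) {
    abort("Negative pMHC counts encountered", class = "itrap_format_error")
  }
  long$umi <- as.integer(long$umi)

  unknown <- setdiff(unique(long$feature_id), panel$feature_id)
  if (length(unknown) > 0) {
    abort(sprintf("Feature id(s) absent from panel: %s",
                  paste(unknown, collapse = ", ")),
          class = "itrap_format_error")
  }
  long |>
    left_join(panel, by = "feature_id") |>
    select("barcode", "feature_id", "peptide", "hla_allele", "umi",
           "is_negative_control")
}

read_id_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[,\t]"), `[[`, character(1), 1L)
}

#' Assemble the canonical GEM table for one donor run
#'
#' Joins contig-level chain annotations with pMHC captures on the droplet
#' barcode and applies the canonical barcode convention
#' `<16nt core>-<well>-<donor>`. Readers strip any pre-existing trailing
#' numeric well suffix and re-append it canonically, so runs exported with
#' inconsistent suffix dialects still align. Only barcodes carrying at least
#' one TCR chain *and* at least one pMHC capture become GEM records.
#'
#' @param chains Contig tibble from [read_contig_annotations()].
#' @param captures Capture tibble from [read_pmhc_counts()].
#' @param donor_id Donor (sample) identifier appended to every barcode.
#' @return The canonical GEM tibble: one row per GEM with `barcode_full`,
#'   `barcode_core`, `well`, `donor`, `is_cell` and list-columns `chains`
#'   (chain annotations) and `captures` (pMHC captures).
#' @export
assemble_gem_table <- function(chains, captures, donor_id) {
  stopifnot(is.character(donor_id), length(donor_id) == 1)

  chain_bc <- split_barcode(chains$barcode)
  capt_bc <- split_barcode(captures$barcode)

  chains2 <- chains |>
    mutate(barcode_core = chain_bc$core, well = chain_bc$well)
  captures2 <- captures |>
    mutate(barcode_core = capt_bc$core, well = capt_bc$well)

  chain_nest <- chains2 |>
    select("barcode_core", "well", "chain_type", "v_gene", "j_gene",
           "cdr3_aa", "umi", "productive", "full_length", "is_cell") |>
    tidyr::nest(chains = c("chain_type", "v_gene", "j_gene", "cdr3_aa",
                           "umi", "productive", "full_length", "is_cell"))
  capt_nest <- captures2 |>
    select("barcode_core", "well", "feature_id", "peptide", "hla_allele",
           "umi", "is_negative_control") |>
    tidyr::nest(captures = c("feature_id", "peptide", "hla_allele", "umi",
                             "is_negative_control"))

  gems <- inner_join(chain_nest, capt_nest, by = c("barcode_core", "well")) |>
    mutate(
      donor = donor_id,
      barcode_full = paste(.data$barcode_core, .data$well, donor_id, sep = "-"),
      is_cell = purrr::map_lgl(.data$chains, ~ any(.x$is_cell)),
      chains = purrr::map(.data$chains, ~ select(.x, -"is_cell"))
    ) |>
    select("barcode_full", "barcode_core", "well", "donor", "is_cell",
           "chains", "captures")

  if (anyDuplicated(gems$barcode_full) > 0) {
    dup <- gems$barcode_full[duplicated(gems$barcode_full)][1]
    abort(sprintf("Duplicate barcode after suffixing within one run: %s", dup),
          class = "itrap_integrity_error")
  }
  gems
}

# Canonical barcode handling: a 16-nt core over {A,C,G,T}, an optional
# trailing "-<digits>" well suffix (default well "1"), anything else is an
# error.
split_barcode <- function(barcode) {
  barcode <- as.character(barcode)
  core <- sub("^([ACGT]{16}).*$", "\\1", barcode)
  ok <- grepl("^[ACGT]{16}(-.*)?$", barcode)
  if (!all(ok)) {
    abort(sprintf("Barcode '%s' does not start with a 16-nt ACGT core",
                  barcode[which(!ok)[1]]),
          class = "itrap_format_error")
  }
  suffix <- sub("^[ACGT]{16}", "", barcode)
  well <- ifelse(grepl("^-[0-9]+", suffix),
                 sub("^-([0-9]+).*$", "\\1", suffix), "1")
  list(core = core, well = well)
}

#' Curate chain annotations within GEMs
#'
#' Drops chains that are not productive, not full length, or whose CDR3
#' contains characters outside the 20 one-letter amino-acid codes. Chains fail
#' individually; a GEM is removed only when none of its chains survive.
#' Curation is total (never errors) and idempotent.
#'
#' @param gems Canonical GEM tibble from [assemble_gem_table()].
#' @return The curated GEM tibble. A tally of dropped chains by reason and of
#'   removed GEMs is attached as attribute `"curation"` and reported via a
#'   message.
#' @export
curate_gems <- function(gems) {
  if (nrow(gems) == 0) {
    attr(gems, "curation") <- list(chains_dropped = c(
      not_productive = 0L, not_full_length = 0L, non_iupac = 0L),
      gems_removed = 0L)
    return(gems)
  }
  flat <- gems |>
    select("barcode_full", "chains") |>
    tidyr::unnest("chains")
  reason <- dplyr::case_when(
    !flat$productive ~ "not_productive",
    !flat$full_length ~ "not_full_length",
    !grepl(IUPAC_AA_REGEX, flat$cdr3_aa) ~ "non_iupac",
    TRUE ~ NA_character_
  )
  tally <- c(not_productive = sum(reason == "not_productive", na.rm = TRUE),
             not_full_length = sum(reason == "not_full_length", na.rm = TRUE),
             non_iupac = sum(reason == "non_iupac", na.rm = TRUE))
  kept <- flat[is.na(reason), ]
  renest <- kept |>
    tidyr::nest(chains = c("chain_type", "v_gene", "j_gene", "cdr3_aa",
                           "umi", "productive", "full_length"))
  out <- gems |>
    select(-"chains") |>
    inner_join(renest, by = "barcode_full") |>
    select(dplyr::all_of(names(gems)))
  gems_removed <- nrow(gems) - nrow(out)
  if (sum(tally) > 0 || gems_removed > 0) {
    inform(sprintf(
      "Curation dropped %d chain(s) (%s) and removed %d GEM(s)",
      sum(tally),
      paste(names(tally), tally, sep = "=", collapse = ", "),
      gems_removed))
  }
  attr(out, "curation") <- list(chains_dropped = tally,
                                gems_removed = as.integer(gems_removed))
  out
}

#' Align GEM barcodes between two annotation sets
#'
#' Matches records of two GEM tables that may use different barcode suffix
#' dialects. Pass 1 matches on the full barcode; records left unmatched are
#' matched in pass 2 on the 16-nt barcode core within the same donor. A core
#' that matches more than one candidate in the counterpart table for the same
#' donor is reported as ambiguous rather than matched.
#'
#' @param table_a,table_b GEM tibbles with at least `barcode_full`,
#'   `barcode_core` and `donor` columns.
#' @return A list with `matches` (tibble `barcode_a`, `barcode_b`, `pass`),
#'   `pass_counts` (named integer vector) and `ambiguous` (tibble of cores
#'   that could not be matched uniquely).
#' @export
align_external_annotations <- function(table_a, table_b) {
  a <- table_a |> select("barcode_full", "barcode_core", "donor")
  b <- table_b |> select("barcode_full", "barcode_core", "donor")

  pass1 <- inner_join(a, b, by = "barcode_full", suffix = c("_a", "_b")) |>
    mutate(barcode_a = .data$barcode_full, barcode_b = .data$barcode_full,
           pass = 1L) |>
    select("barcode_a", "barcode_b", "pass")

  rest_a <- a |> filter(!.data$barcode_full %in% pass1$barcode_a)
  rest_b <- b |> filter(!.data$barcode_full %in% pass1$barcode_b)

  cand <- inner_join(rest_a, rest_b, by = c("barcode_core", "donor"),
                     suffix = c("_a", "_b"),
                     relationship = "many-to-many")
  amb_keys <- cand |>
    group_by(.data$barcode_core, .data$donor) |>
    summarise(n_a = dplyr::n_distinct(.data$barcode_full_a),
              n_b = dplyr::n_distinct(.data$barcode_full_b),
              .groups = "drop") |>
    filter(.data$n_a > 1 | .data$n_b > 1)

  pass2 <- cand |>
    anti_join(amb_keys, by = c("barcode_core", "donor")) |>
    mutate(barcode_a = .data$barcode_full_a, barcode_b = .data$barcode_full_b,
           pass = 2L) |>
    select("barcode_a", "barcode_b", "pass")

  matches <- bind_rows(pass1, pass2)
  list(
    matches = matches,
    pass_counts = c(pass1 = nrow(pass1), pass2 = nrow(pass2)),
    ambiguous = amb_keys
  )
}
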