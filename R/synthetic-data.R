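#' Configuration for the synthetic GEM simulator
#'
#' The simulator emulates the phenomenology of a droplet-based TCR-pMHC
#' screen: clonally expanded T cells each with one true cognate pMHC,
#' ambient multimer barcodes captured at low UMI, chain dropout and spurious
#' chain multiplets, donor-restricted HLA alleles, and per-specificity CDR3
#' motifs so that TCRs of the same specificity are more similar to each
#' other than to TCRs of other specificities.
#'
#' Defaults describe a screen with strong clonal expansion (heavy-tailed
#' clonotype sizes), a cognate capture signal well separated from ambient
#' noise (negative-binomial means 15 vs 2), about three ambient features per
#' GEM, and 10% chain dropout — a realistic signal-to-noise regime for
#' dextramer screens.
#'
#' @param n_donors Number of donors (parallel runs).
#' @param alleles_per_donor Class I alleles per donor haplotype (2 per locus
#'   when 6).
#' @param n_pmhc Panel size, including `n_negative_controls` controls.
#' @param n_negative_controls Negative-control multimers in the panel.
#' @param n_clonotypes Simulated true clonotypes.
#' @param size_exponent,size_max Zeta-like clonotype size law: `P(k)` is
#'   proportional to `k^-size_exponent` on `1..size_max`.
#' @param signal_mean,signal_size Negative-binomial law of the cognate
#'   capture UMI.
#' @param noise_mean,noise_size Negative-binomial law of ambient capture
#'   UMI; the mean must stay below `signal_mean`.
#' @param ambient_rate Poisson mean number of ambient features per GEM.
#' @param chain_dropout_prob Probability a GEM loses one chain annotation.
#' @param chain_multiplet_prob Probability of one extra spurious chain.
#' @param tcr_mean,tcr_size Negative-binomial law (shifted to be `>= 1`) of
#'   chain UMI counts.
#' @param motif_length Length of the per-specificity CDR3 core motif.
#' @param non_cell_rate Probability a GEM is flagged `is_cell = FALSE`.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 4, alleles_per_donor = 6, n_pmhc = 10,
                       n_negative_controls = 1, n_clonotypes = 500,
                       size_exponent = 2.0, size_max = 100,
                       signal_mean = 15, signal_size = 10,
                       noise_mean = 2, noise_size = 2,
                       ambient_rate = 3, chain_dropout_prob = 0.1,
                       chain_multiplet_prob = 0.1,
                       tcr_mean = 4, tcr_size = 5,
                       motif_length = 5, non_cell_rate = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  if (noise_mean >= signal_mean) {
    abort("noise_mean must be below signal_mean", class = "itrap_config_error")
  }
  probs <- c(chain_dropout_prob, chain_multiplet_prob, non_cell_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1]", class = "itrap_config_error")
  }
  if (n_negative_controls >= n_pmhc) {
    abort("Panel must contain at least one non-control pMHC",
          class = "itrap_config_error")
  }
  if (n_pmhc < 2) abort("Need at least 2 pMHC features", class = "itrap_config_error")
  structure(cfg, class = "sim_config")
}

# Fast split of a flat per-GEM tibble (keyed by .g) into a list of tibbles.
vctrs_split <- function(flat) {
  s <- vctrs::vec_split(flat[setdiff(names(flat), ".g")], flat$.g)
  list(g = s$key, pieces = s$val)
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# CDR3 with the specificity motif embedded at a random offset between the
# canonical C...F anchors.
motif_cdr3 <- function(motif) {
  len <- sample(max(10, nchar(motif) + 4):18, 1)
  interior <- len - 2
  off <- sample(0:(interior - nchar(motif)), 1)
  paste0("C", random_aa(off), motif,
         random_aa(interior - nchar(motif) - off), "F")
}

#' Simulate a GEM dataset with known ground truth
#'
#' @param config A [sim_config()].
#' @return A list of class `itrap_simulation`:
#'   * `gems` — canonical GEM tibble (as after [assemble_gem_table()]),
#'   * `truth` — list with `gems` (per-GEM truth: true clonotype, cognate
#'     pMHC, corruption flags) and `clonotypes` (per-clonotype truth:
#'     donor, cognate, TCR sequences),
#'   * `panel` — pMHC panel tibble,
#'   * `haplotypes` — long donor/allele tibble,
#'   * `config` — the configuration used.
#' @export
simulate_gem_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, simulate_gem_dataset_impl(cfg))
}

simulate_gem_dataset_impl <- function(cfg) {
  # --- HLA universe and donor haplotypes -------------------------------
  loci <- c("A", "B", "C")
  allele_pool <- unlist(lapply(loci, function(l) {
    sprintf("%s*%02d:01", l, 1:12)
  }))
  per_locus <- max(1, cfg$alleles_per_donor %/% length(loci))
  haplotypes <- purrr::map(seq_len(cfg$n_donors), function(d) {
    alleles <- unlist(lapply(loci, function(l) {
      sample(grep(paste0("^", l, "\\*"), allele_pool, value = TRUE), per_locus)
    }))
    extra <- cfg$alleles_per_donor - length(alleles)
    if (extra > 0) {
      alleles <- c(alleles, sample(setdiff(allele_pool, alleles), extra))
    }
    tibble(donor_id = sprintf("d%d", d), allele = alleles)
  }) |> purrr::list_rbind()

  # --- pMHC panel: alleles restricted to what donors carry -------------
  donor_alleles <- unique(haplotypes$allele)
  panel <- tibble(
    feature_id = sprintf("pMHC%02d", seq_len(cfg$n_pmhc)),
    peptide = vapply(seq_len(cfg$n_pmhc), function(i) random_aa(9), character(1)),
    hla_allele = sample(donor_alleles, cfg$n_pmhc, replace = TRUE),
    is_negative_control = c(rep(FALSE, cfg$n_pmhc - cfg$n_negative_controls),
                            rep(TRUE, cfg$n_negative_controls))
  )
  cognate_pool <- panel |> filter(!.data$is_negative_control)

  # --- per-specificity CDR3 motifs -------------------------------------
  motifs <- tibble(
    feature_id = panel$feature_id,
    motif_a = vapply(seq_len(nrow(panel)), function(i) random_aa(cfg$motif_length),
                     character(1)),
    motif_b = vapply(seq_len(nrow(panel)), function(i) random_aa(cfg$motif_length),
                     character(1))
  )

  va <- sprintf("TRAV%02d", 1:20); ja <- sprintf("TRAJ%02d", 1:10)
  vb <- sprintf("TRBV%02d", 1:20); jb <- sprintf("TRBJ%02d", 1:10)

  # --- true clonotypes --------------------------------------------------
  sizes_law <- (1:cfg$size_max)^(-cfg$size_exponent)
  ct_sizes <- sample(seq_len(cfg$size_max), cfg$n_clonotypes, replace = TRUE,
                     prob = sizes_law / sum(sizes_law))
  cognate <- sample(cognate_pool$feature_id, cfg$n_clonotypes, replace = TRUE)
  cognate_allele <- cognate_pool$hla_allele[match(cognate, cognate_pool$feature_id)]

  donor_of <- vapply(cognate_allele, function(al) {
    carriers <- unique(haplotypes$donor_id[haplotypes$allele == al])
    if (length(carriers) == 0) {
      abort("No donor carries a panel allele; infeasible configuration",
            class = "itrap_config_error")
    }
    if (length(carriers) == 1) carriers else sample(carriers, 1)
  }, character(1), USE.NAMES = FALSE)

  true_ct <- tibble(
    sim_ct = sprintf("sim%04d", seq_len(cfg$n_clonotypes)),
    size = ct_sizes,
    true_pmhc = cognate,
    donor = donor_of,
    v_a = sample(va, cfg$n_clonotypes, replace = TRUE),
    j_a = sample(ja, cfg$n_clonotypes, replace = TRUE),
    v_b = sample(vb, cfg$n_clonotypes, replace = TRUE),
    j_b = sample(jb, cfg$n_clonotypes, replace = TRUE),
    cdr3_a = vapply(cognate, function(p) {
      motif_cdr3(motifs$motif_a[match(p, motifs$feature_id)])
    }, character(1)),
    cdr3_b = vapply(cognate, function(p) {
      motif_cdr3(motifs$motif_b[match(p, motifs$feature_id)])
    }, character(1))
  )

  n_gems <- sum(true_ct$size)
  # unique 16-nt barcodes, drawn globally so cores never collide
  cores <- character(0)
  while (length(cores) < n_gems) {
    more <- vapply(seq_len(n_gems - length(cores) + 16), function(i) {
      paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = "")
    }, character(1))
    cores <- unique(c(cores, more))
  }
  cores <- cores[seq_len(n_gems)]

  gem_ct <- rep(seq_len(cfg$n_clonotypes), true_ct$size)
  gem_donor <- true_ct$donor[gem_ct]
  barcode_full <- paste(cores, "1", gem_donor, sep = "-")

  # --- captures (flat construction, nested at the end) ------------------
  signal_umi <- rnbinom(n_gems, mu = cfg$signal_mean, size = cfg$signal_size)
  n_noise <- rpois(n_gems, cfg$ambient_rate)
  noise_pool <- lapply(seq_len(cfg$n_clonotypes), function(i) {
    setdiff(panel$feature_id, true_ct$true_pmhc[i])
  })
  noisy <- which(n_noise > 0)
  noise_feat <- lapply(noisy, function(g) {
    pool <- noise_pool[[gem_ct[g]]]
    sample(pool, min(n_noise[g], length(pool)))
  })
  noise_len <- lengths(noise_feat)
  noise_umi <- rnbinom(sum(noise_len), mu = cfg$noise_mean, size = cfg$noise_size)

  flat_g <- c(seq_len(n_gems)[signal_umi >= 1], rep(noisy, noise_len))
  flat_feat <- c(true_ct$true_pmhc[gem_ct[signal_umi >= 1]],
                 unlist(noise_feat, use.names = FALSE))
  flat_umi <- c(signal_umi[signal_umi >= 1], noise_umi)
  keep <- flat_umi >= 1
  flat_g <- flat_g[keep]; flat_feat <- flat_feat[keep]; flat_umi <- flat_umi[keep]

  # a GEM without any capture would not enter the dataset at all;
  # force-retain the cognate at the minimum observable count
  orphan <- setdiff(seq_len(n_gems), unique(flat_g))
  if (length(orphan) > 0) {
    flat_g <- c(flat_g, orphan)
    flat_feat <- c(flat_feat, true_ct$true_pmhc[gem_ct[orphan]])
    flat_umi <- c(flat_umi, rep(1L, length(orphan)))
    signal_umi[orphan] <- 1L
  }
  m <- match(flat_feat, panel$feature_id)
  flat_caps <- tibble(.g = flat_g, feature_id = flat_feat,
                      peptide = panel$peptide[m],
                      hla_allele = panel$hla_allele[m],
                      umi = as.integer(flat_umi),
                      is_negative_control = panel$is_negative_control[m]) |>
    arrange(.data$.g)
  captures <- unname(vector("list", n_gems))
  cap_split <- vctrs_split(flat_caps)
  captures[cap_split$g] <- cap_split$pieces

  # --- chains -----------------------------------------------------------
  tcr_umi_a <- 1L + rnbinom(n_gems, mu = cfg$tcr_mean, size = cfg$tcr_size)
  tcr_umi_b <- 1L + rnbinom(n_gems, mu = cfg$tcr_mean, size = cfg$tcr_size)
  drop_chain <- ifelse(runif(n_gems) < cfg$chain_dropout_prob,
                       sample(c("alpha", "beta"), n_gems, replace = TRUE),
                       NA_character_)
  add_multiplet <- runif(n_gems) < cfg$chain_multiplet_prob
  is_cell <- runif(n_gems) >= cfg$non_cell_rate

  ct_of <- true_ct[gem_ct, ]
  flat_chain <- tibble(
    .g = rep(seq_len(n_gems), each = 2),
    chain_type = rep(c("alpha", "beta"), n_gems),
    v_gene = as.vector(rbind(ct_of$v_a, ct_of$v_b)),
    j_gene = as.vector(rbind(ct_of$j_a, ct_of$j_b)),
    cdr3_aa = as.vector(rbind(ct_of$cdr3_a, ct_of$cdr3_b)),
    umi = as.integer(as.vector(rbind(tcr_umi_a, tcr_umi_b))),
    productive = TRUE, full_length = TRUE
  )
  dropped <- !is.na(drop_chain[flat_chain$.g]) &
    flat_chain$chain_type == drop_chain[flat_chain$.g]
  flat_chain <- flat_chain[!dropped, ]

  mult_g <- which(add_multiplet)
  if (length(mult_g) > 0) {
    sp_type <- sample(c("alpha", "beta"), length(mult_g), replace = TRUE)
    spurious <- tibble(
      .g = mult_g,
      chain_type = sp_type,
      v_gene = ifelse(sp_type == "alpha",
                      sample(va, length(mult_g), replace = TRUE),
                      sample(vb, length(mult_g), replace = TRUE)),
      j_gene = ifelse(sp_type == "alpha",
                      sample(ja, length(mult_g), replace = TRUE),
                      sample(jb, length(mult_g), replace = TRUE)),
      cdr3_aa = vapply(mult_g, function(i) {
        paste0("C", random_aa(sample(8:14, 1)), "F")
      }, character(1)),
      umi = 1L, productive = TRUE, full_length = TRUE
    )
    flat_chain <- bind_rows(flat_chain, spurious)
  }
  flat_chain <- flat_chain |> arrange(.data$.g)
  chains <- unname(vector("list", n_gems))
  ch_split <- vctrs_split(flat_chain)
  chains[ch_split$g] <- ch_split$pieces

  gems <- tibble(
    barcode_full = barcode_full,
    barcode_core = cores,
    well = "1",
    donor = gem_donor,
    is_cell = is_cell,
    chains = chains,
    captures = captures
  )

  truth_gems <- tibble(
    barcode_full = barcode_full,
    sim_ct = true_ct$sim_ct[gem_ct],
    true_pmhc = true_ct$true_pmhc[gem_ct],
    signal_umi = as.integer(signal_umi),
    n_noise = vapply(captures, NROW, integer(1)) - as.integer(signal_umi >= 1),
    dropped_chain = drop_chain,
    has_chain_multiplet = add_multiplet,
    is_cell = is_cell
  )

  structure(list(gems = gems,
                 truth = list(gems = truth_gems, clonotypes = true_ct),
                 panel = panel, haplotypes = haplotypes, config = cfg),
            class = "itrap_simulation")
}

#' Evaluate assignment recovery against simulation ground truth
#'
#' @param filtered GEM tibble derived from a simulated dataset, with
#'   `assigned_pmhc` set on retained GEMs.
#' @param truth The `truth` element of an [simulate_gem_dataset()] result.
#' @return A list: `precision` (retained assignments that match the true
#'   cognate), `recall` (true (GEM, cognate) pairs retained and correctly
#'   assigned), `n_retained`, and `confusion` (per-corruption-type retained
#'   and correct counts).
#' @export
evaluate_recovery <- function(filtered, truth) {
  tg <- truth$gems
  unknown <- setdiff(filtered$barcode_full, tg$barcode_full)
  if (length(unknown) > 0) {
    abort(sprintf("Barcode(s) absent from truth table: %s",
                  paste(head(unknown, 3), collapse = ", ")),
          class = "itrap_integrity_error")
  }
  joined <- filtered |>
    select("barcode_full", "assigned_pmhc") |>
    left_join(tg, by = "barcode_full") |>
    mutate(correct = .data$assigned_pmhc == .data$true_pmhc)
  precision <- if (nrow(joined) == 0) NA_real_ else mean(joined$correct)
  recall <- sum(joined$correct) / nrow(tg)
  confusion <- tg |>
    mutate(corruption = dplyr::case_when(
      !is.na(.data$dropped_chain) & .data$has_chain_multiplet ~ "dropout+multiplet",
      !is.na(.data$dropped_chain) ~ "dropout",
      .data$has_chain_multiplet ~ "multiplet",
      .data$n_noise > 0 ~ "ambient_only",
      TRUE ~ "clean"
    )) |>
    left_join(joined |> select("barcode_full", "correct"), by = "barcode_full") |>
    group_by(.data$corruption) |>
    summarise(n_total = n(),
              n_retained = sum(!is.na(.data$correct)),
              n_correct = sum(.data$correct, na.rm = TRUE),
              .groups = "drop")
  list(precision = precision, recall = recall, n_retained = nrow(joined),
       confusion = confusion)
}

#' Evaluate expected-binder recovery for expanded clonotypes
#'
#' Joins the redefined clonotypes to the simulation truth on the amino-acid
#' six-tuple and reports, among true clonotypes represented by at least
#' `min_size` GEMs in the clonotyped table, the fraction whose annotated
#' expected binder equals the true cognate pMHC.
#'
#' @param binders `itrap_binders` from [annotate_expected_binders()].
#' @param clonotypes Clonotype tibble from [clonotype_gems()].
#' @param truth Simulation truth list.
#' @param min_size Clonotype size floor (default 10).
#' @return A list: `recovery` (fraction), `n_eligible`, `n_correct`.
#' @export
evaluate_binder_recovery <- function(binders, clonotypes, truth, min_size = 10) {
  key <- c("v_a", "j_a", "cdr3_a", "v_b", "j_b", "cdr3_b")
  joined <- clonotypes |>
    filter(.data$size >= min_size) |>
    inner_join(truth$clonotypes |> select(dplyr::all_of(key), "true_pmhc"),
               by = key) |>
    left_join(binders |> select("ct_id", "expected_pmhc"), by = "ct_id")
  n_correct <- sum(!is.na(joined$expected_pmhc) &
                     joined$expected_pmhc == joined$true_pmhc)
  list(recovery = if (nrow(joined) == 0) NA_real_ else n_correct / nrow(joined),
       n_eligible = nrow(joined), n_correct = n_correct)
}

#' Write simulator outputs as raw input files
#'
#' Emits the files a real run would start from — a Cellranger-dialect contig
#' annotation CSV, a wide pMHC count CSV, the HLA haplotype CSV, the panel
#' CSV and a `truth.csv` — so the full ingest path can be exercised against
#' simulated data.
#'
#' @param sim An `itrap_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(contigs = file.path(dir, "contig_annotations.csv"),
             pmhc = file.path(dir, "pmhc_counts.csv"),
             hla = file.path(dir, "hla_haplotypes.csv"),
             panel = file.path(dir, "pmhc_panel.csv"),
             truth = file.path(dir, "truth.csv"))

  contigs <- sim$gems |>
    select("barcode_core", "well", "is_cell", "chains") |>
    tidyr::unnest("chains") |>
    mutate(barcode = paste0(.data$barcode_core, "-", .data$well),
           chain = if_else(.data$chain_type == "alpha", "TRA", "TRB"),
           productive = if_else(.data$productive, "True", "False"),
           full_length = if_else(.data$full_length, "True", "False"),
           is_cell = if_else(.data$is_cell, "True", "False")) |>
    select("barcode", "is_cell", "chain", v_gene = "v_gene",
           j_gene = "j_gene", cdr3 = "cdr3_aa", umis = "umi",
           "productive", "full_length")
  readr::write_csv(contigs, paths[["contigs"]], progress = FALSE)

  wide <- sim$gems |>
    select("barcode_core", "well", "captures") |>
    tidyr::unnest("captures") |>
    mutate(barcode = paste0(.data$barcode_core, "-", .data$well)) |>
    select("barcode", "feature_id", "umi") |>
    tidyr::pivot_wider(names_from = "feature_id", values_from = "umi",
                       values_fill = 0L)
  readr::write_csv(wide, paths[["pmhc"]], progress = FALSE)

  readr::write_csv(sim$haplotypes, paths[["hla"]], progress = FALSE)
  readr::write_csv(sim$panel, paths[["panel"]], progress = FALSE)
  readr::write_csv(sim$truth$gems, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
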