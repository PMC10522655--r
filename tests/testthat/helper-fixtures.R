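# Hand-built fixtures used across the suite. All data is constructed in code.

chain_row <- function(type = "beta", v = "TRBV19", j = "TRBJ2-7",
                      cdr3 = "CASSIRSSYEQYF", umi = 4L,
                      productive = TRUE, full_length = TRUE) {
  tibble::tibble(chain_type = type, v_gene = v, j_gene = j, cdr3_aa = cdr3,
                 umi = as.integer(umi), productive = productive,
                 full_length = full_length)
}

capture_row <- function(feature = "pMHC01", umi = 6L, allele = "A*02:01",
                        peptide = "GILGFVFTL", control = FALSE) {
  tibble::tibble(feature_id = feature, peptide = peptide, hla_allele = allele,
                 umi = as.integer(umi), is_negative_control = control)
}

# random but valid 16-nt cores, deterministic in i
core16 <- function(i) {
  set.seed(10000 + i)
  paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = "")
}

make_gem <- function(i, donor = "d1", chains = chain_row(),
                     captures = capture_row(), is_cell = TRUE,
                     ct_id = NA_character_) {
  core <- core16(i)
  tibble::tibble(
    barcode_full = paste(core, "1", donor, sep = "-"),
    barcode_core = core, well = "1", donor = donor, is_cell = is_cell,
    chains = list(chains), captures = list(captures)
  )
}

# A small clonotyped table built directly at the post-clonotyping stage:
# flat chain columns plus captures.
make_flat_gem <- function(i, donor = "d1", ct_id = "ct00001",
                          cdr3_a = "CAVRDNYQLIF", cdr3_b = "CASSIRSSYEQYF",
                          v_a = "TRAV01", j_a = "TRAJ01",
                          v_b = "TRBV01", j_b = "TRBJ01",
                          umi_a = 3L, umi_b = 4L,
                          captures = capture_row(), is_cell = TRUE) {
  core <- core16(i)
  tibble::tibble(
    barcode_full = paste(core, "1", donor, sep = "-"),
    barcode_core = core, well = "1", donor = donor, is_cell = is_cell,
    v_a = v_a, j_a = j_a, cdr3_a = cdr3_a,
    umi_a = if (is.na(cdr3_a)) NA_integer_ else as.integer(umi_a),
    v_b = v_b, j_b = j_b, cdr3_b = cdr3_b,
    umi_b = if (is.na(cdr3_b)) NA_integer_ else as.integer(umi_b),
    imputed_a = FALSE, imputed_b = FALSE,
    extra_chains = list(chain_row()[0, ]),
    ct_id = ct_id,
    captures = list(captures)
  )
}

small_haplotypes <- function() {
  tibble::tibble(
    donor_id = rep(c("d1", "d2"), each = 3),
    allele = c("A*02:01", "B*07:02", "C*07:01",
               "A*03:01", "B*08:01", "C*04:01")
  )
}

# Independent exact rank-sum oracle: enumerate every assignment of the
# pooled observations to the two groups and count, via direct pairwise
# comparison (U statistic with 1/2 for ties), how often group one is at
# least as extreme as observed.
oracle_rank_sum_p <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- u_stat(x, y)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  mean(us >= u_obs - 1e-9)
}
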