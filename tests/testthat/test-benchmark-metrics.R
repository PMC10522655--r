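# Independent brute-force oracle for the k-mer substitution kernel:
# enumerate every k-mer pair explicitly and multiply position-wise kappa.
oracle_raw_kernel <- function(s, t, beta = 0.11387, ks = 1:3) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  kappa <- exp(beta * e$BLOSUM62[aas, aas])
  sc <- strsplit(s, "")[[1]]; tc <- strsplit(t, "")[[1]]
  total <- 0
  for (k in ks) {
    if (length(sc) < k || length(tc) < k) next
    for (i in seq_len(length(sc) - k + 1)) {
      for (j in seq_len(length(tc) - k + 1)) {
        total <- total + prod(kappa[cbind(sc[i:(i + k - 1)], tc[j:(j + k - 1)])])
      }
    }
  }
  total
}

oracle_chain_sim <- function(s, t) {
  oracle_raw_kernel(s, t) /
    sqrt(oracle_raw_kernel(s, s) * oracle_raw_kernel(t, t))
}

test_that("chain similarity matches brute-force kernel enumeration", {
  pairs <- list(c("CASSF", "CAWWF"), c("CAVRDNYQLIF", "CASSIRSSYEQYF"),
                c("CAF", "CAF"), c("CASSLG", "CASSLG"),
                c("WWWWW", "AAAAA"))
  for (p in pairs) {
    expect_equal(chain_similarity(p[1], p[2]), oracle_chain_sim(p[1], p[2]),
                 tolerance = 1e-10, label = toString(p))
  }
})

test_that("chain similarity is a normalized symmetric kernel", {
  seqs <- c("CASSF", "CAWWF", "CAVRDNYQLIF", "CASSIRSSYEQYF")
  for (s in seqs) expect_equal(chain_similarity(s, s), 1, tolerance = 1e-12)
  for (s in seqs) for (t in seqs) {
    v <- chain_similarity(s, t)
    expect_equal(v, chain_similarity(t, s), tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
  }
  # normalized Gram matrix is positive semidefinite
  K <- outer(seq_along(seqs), seq_along(seqs),
             Vectorize(function(i, j) chain_similarity(seqs[i], seqs[j])))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  expect_error(chain_similarity("", "CASSF"), "non-empty")
  expect_error(chain_similarity("CASS1F", "CASSF"), "non-amino-acid")
})

test_that("paired similarity sums the two chains and validates inputs", {
  t1 <- list(cdr3_a = "CAVRF", cdr3_b = "CASSF")
  t2 <- list(cdr3_a = "CAVWF", cdr3_b = "CASRF")
  expect_equal(paired_similarity(t1, t2),
               chain_similarity("CAVRF", "CAVWF") +
                 chain_similarity("CASSF", "CASRF"),
               tolerance = 1e-12)
  expect_equal(paired_similarity(t1, t1), 2, tolerance = 1e-12)
  expect_error(paired_similarity(list(cdr3_a = "CAVRF", cdr3_b = NA), t2),
               "cdr3_b")
})

test_that("intra/inter scores are deterministic and identical TCRs score 2", {
  cl <- tibble::tibble(
    ct_id = sprintf("ct%02d", 1:6),
    cdr3_a = c("CAVRF", "CAVRF", "CAVQF", "CILPF", "CILPF", "CIWPF"),
    cdr3_b = c("CASSF", "CASSF", "CASRF", "CGGGF", "CGGGF", "CGWGF"),
    specificity = c("p1", "p1", "p1", "p2", "p2", "p2"))
  s1 <- intra_inter_scores(cl, seed = 7)
  s2 <- intra_inter_scores(cl, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1$intra, 6)
  expect_length(s1$inter, 6)
  # clonotypes 1 and 2 are identical TCRs in the same plateau
  expect_equal(s1$intra[1], 2, tolerance = 1e-12)
  expect_equal(s1$intra[2], 2, tolerance = 1e-12)
  expect_true(all(s1$intra >= 0 & s1$intra <= 2 + 1e-12))
  expect_true(all(s1$inter >= 0 & s1$inter <= 2 + 1e-12))

  # singleton plateau contributes nothing (message, not an error)
  cl3 <- dplyr::bind_rows(cl, tibble::tibble(
    ct_id = "ct99", cdr3_a = "CWWWF", cdr3_b = "CYYYF", specificity = "p3"))
  expect_message(s3 <- intra_inter_scores(cl3, seed = 7), "skipped")
  expect_length(s3$intra, 6)
  expect_false("ct99" %in% s3$ct_id)
})

test_that("similarity AUC has the Mann-Whitney values on known score lists", {
  expect_equal(similarity_auc(list(intra = c(3, 4), inter = c(1, 2))), 100)
  expect_equal(similarity_auc(list(intra = c(1, 2), inter = c(1, 2))), 50)
  expect_equal(similarity_auc(list(intra = c(2, 1), inter = c(1.5, 0.5))), 75)
  # invariant under strictly increasing transforms
  intra <- c(0.3, 1.1, 0.8); inter <- c(0.2, 0.9, 0.4)
  expect_equal(similarity_auc(list(intra = intra, inter = inter)),
               similarity_auc(list(intra = exp(intra), inter = exp(inter))))
  expect_error(similarity_auc(list(intra = numeric(0), inter = 1)), "non-empty")
})

test_that("binding concordance splits clonotype mass and weights by GEMs", {
  mk <- function(i, ct, f) {
    g <- make_flat_gem(i, ct_id = ct, captures = capture_row(f, 5))
    g$assigned_pmhc <- f
    g
  }
  gems <- dplyr::bind_rows(
    purrr::map(1:7, mk, ct = "ctA", f = "X"),
    purrr::map(8:10, mk, ct = "ctA", f = "Y"),
    purrr::map(11:15, mk, ct = "ctB", f = "Z"))
  cc <- binding_concordance(gems)
  bp <- cc$by_pair
  expect_equal(nrow(bp), 3)
  expect_equal(bp$concordance[bp$ct_id == "ctA" & bp$pmhc == "X"], 0.7)
  expect_equal(bp$concordance[bp$ct_id == "ctA" & bp$pmhc == "Y"], 0.3)
  expect_equal(bp$concordance[bp$ct_id == "ctB"], 1)
  # per-clonotype concordances sum to exactly one
  sums <- tapply(bp$concordance, bp$ct_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # GEM-weighted average: (7*0.7 + 3*0.3 + 5*1) / 15
  expect_equal(cc$average_pct, 100 * (7 * 0.7 + 3 * 0.3 + 5 * 1) / 15,
               tolerance = 1e-12)
  expect_equal(cc$average_unweighted_pct, 100 * mean(c(0.7, 0.3, 1)),
               tolerance = 1e-12)
  expect_true(is.na(binding_concordance(gems[0, ])$average_pct))
})

test_that("outlier classification assigns the documented categories", {
  mk <- function(i, ct, assigned, caps) {
    g <- make_flat_gem(i, ct_id = ct, captures = caps)
    g$assigned_pmhc <- assigned
    g
  }
  capX <- function(u) capture_row("X", u, allele = "A*02:01")
  capY <- function(u) capture_row("Y", u, allele = "B*07:02")
  capZ <- function(u) capture_row("Z", u, allele = "A*02:01")

  gems <- dplyr::bind_rows(
    # ctA: dominant = expected X (3 GEMs); one outlier GEM assigned Y where
    # X was detected at lower UMI -> cross_reactivity_consistent + hla_divergent
    purrr::map(1:3, mk, ct = "ctA", assigned = "X", caps = capX(9)),
    mk(4, "ctA", "Y", dplyr::bind_rows(capY(9), capX(2))),
    # ctB: small clonotype, no expected binder
    purrr::map(5:6, mk, ct = "ctB", assigned = "X", caps = capX(5)),
    mk(7, "ctB", "Z", capZ(5)),
    # ctC: scattered across 3 low-concordance targets with multiplet captures
    mk(8, "ctC", "X", dplyr::bind_rows(capX(4), capY(2))),
    mk(9, "ctC", "Y", dplyr::bind_rows(capY(4), capZ(2))),
    mk(10, "ctC", "Z", dplyr::bind_rows(capZ(4), capX(2))))
  binders <- tibble::tibble(ct_id = c("ctA", "ctC"),
                            expected_pmhc = c("X", NA_character_))
  out <- classify_outliers(gems, binders, cutoff = 0.5)
  expect_setequal(out$barcode_full,
                  gems$barcode_full[c(4, 7, 8, 9, 10)])
  row4 <- out[out$barcode_full == gems$barcode_full[4], ]
  expect_equal(row4$category, "cross_reactivity_consistent")
  expect_true(row4$hla_divergent)
  expect_equal(out$category[out$ct_id == "ctB"], "no_expected_binder")
  # ctC has no expected binder (annotated NA) -> no_expected_binder
  expect_true(all(out$category[out$ct_id == "ctC"] == "no_expected_binder"))
  expect_true(all(out$concordance < 0.5))

  # with an expected binder, the scattered multiplet clonotype is dispersed
  binders2 <- tibble::tibble(ct_id = "ctC", expected_pmhc = "Q")
  out2 <- classify_outliers(gems[8:10, ], binders2, cutoff = 0.5)
  expect_true(all(out2$category == "dispersed_multiplet"))

  # no outliers above cutoff 0
  expect_equal(nrow(classify_outliers(gems, binders, cutoff = 0)), 0)
})

test_that("metrics report is self-consistent on simulated data", {
  sim <- simulate_gem_dataset(sim_config(n_clonotypes = 80, n_pmhc = 6, seed = 91))
  cl <- clonotype_gems(suppressMessages(curate_gems(sim$gems)))
  m <- metrics_report(cl$gems, cl$gems, seed = 3)
  expect_s3_class(m, "itrap_metrics")
  expect_equal(m$retention_pct, 100)
  expect_gte(m$accuracy_pct, 0); expect_lte(m$accuracy_pct, 100)
  expect_gte(m$avg_concordance_pct, 0); expect_lte(m$avg_concordance_pct, 100)
  expect_true(is.na(m$similarity_auc_pct) ||
                (m$similarity_auc_pct >= 0 && m$similarity_auc_pct <= 100))
  expect_equal(m$n_gems, nrow(cl$gems))
  # deterministic for a fixed seed
  m2 <- metrics_report(cl$gems, cl$gems, seed = 3)
  expect_equal(unclass(m), unclass(m2))
  expect_output(print(m), "GEMs retained")
})
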