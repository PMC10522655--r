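test_that("HLA alleles normalize across dialects and reject junk", {
  expect_equal(
    normalize_hla_allele(c("HLA-A*02:01", "A0201", "A*02:01", "a*2:1",
                           "B*08:01:01", "b0702")),
    c("A*02:01", "A*02:01", "A*02:01", "A*02:01", "B*08:01", "B*07:02"))
  expect_error(normalize_hla_allele("notanallele"), "Cannot parse")
  expect_error(normalize_hla_allele("A*xx"), "Cannot parse")
})

test_that("contig reader maps the Cellranger dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "barcode,is_cell,chain,v_gene,j_gene,cdr3,umis,productive,full_length",
    "AAACCTGTCTAACTTC,True,TRB,TRBV19,TRBJ2-7,CASSIRSSYEQYF,4,True,True",
    "AAACCTGTCTAACTTC,True,TRA,TRAV12,TRAJ23,CAVRDNYQLIF,2,true,false",
    "AAACCTGTCTAACTTC,True,Multi,None,None,None,1,False,False"
  ), path)
  out <- suppressMessages(read_contig_annotations(path))
  expect_equal(nrow(out), 2)
  expect_equal(out$chain_type, c("beta", "alpha"))
  expect_equal(out$umi, c(4L, 2L))
  expect_equal(out$full_length, c(TRUE, FALSE))
  expect_equal(attr(out, "dropped_other_chains"), 1L)
})

test_that("contig reader flags format problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,is_cell,chain,v_gene,j_gene,cdr3,umis,productive,full_length"),
             path)
  expect_warning(out <- read_contig_annotations(path), "no data rows")
  expect_equal(nrow(out), 0)

  writeLines(c("barcode,chain,v_gene,j_gene,cdr3,umis,productive,full_length",
               "AAACCTGTCTAACTTC,TRB,V,J,CASSF,4,True,True"), path)
  expect_error(read_contig_annotations(path), "is_cell")

  writeLines(c("barcode,is_cell,chain,v_gene,j_gene,cdr3,umis,productive,full_length",
               "AAACCTGTCTAACTTC,True,TRB,V,J,CASSF,oops,True,True"), path)
  expect_error(read_contig_annotations(path), "row 1")
})

test_that("pMHC counts read from wide CSV with zero suppression", {
  panel <- tibble::tibble(feature_id = c("featA", "featB"),
                          peptide = c("GILGFVFTL", "NLVPMVATV"),
                          hla_allele = c("A*02:01", "A*02:01"),
                          is_negative_control = c(FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,featA,featB",
               "AAACCTGTCTAACTTC-1,6,0",
               "TTTCCTGTCTAACTTC-1,0,0"), path)
  out <- read_pmhc_counts(path, panel)
  expect_equal(nrow(out), 1)
  expect_equal(out$feature_id, "featA")
  expect_equal(out$umi, 6L)
  expect_equal(out$hla_allele, "A*02:01")

  writeLines(c("barcode,featZ", "AAACCTGTCTAACTTC-1,2"), path)
  expect_error(read_pmhc_counts(path, panel), "featZ")
  writeLines(c("barcode,featA", "AAACCTGTCTAACTTC-1,-2"), path)
  expect_error(read_pmhc_counts(path, panel), "Negative")
})

test_that("pMHC counts read from MTX triplets", {
  panel <- tibble::tibble(feature_id = paste0("f", 1:3),
                          peptide = c("AAA", "BBB", "CCC"),
                          hla_allele = "A*02:01",
                          is_negative_control = FALSE)
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "counts.mtx")
  m <- Matrix::sparseMatrix(i = c(3, 1), j = c(2, 1), x = c(2, 5),
                            dims = c(3, 2))
  Matrix::writeMM(m, mtx)
  writeLines(paste0("f", 1:3), file.path(dir, "features.txt"))
  writeLines(c("AAACCTGTCTAACTTC-1", "CCCCCTGTCTAACTTC-1"),
             file.path(dir, "barcodes.txt"))
  out <- read_pmhc_counts(mtx, panel,
                          features = file.path(dir, "features.txt"),
                          barcodes = file.path(dir, "barcodes.txt"))
  expect_equal(nrow(out), 2)
  row <- out[out$feature_id == "f3", ]
  expect_equal(row$barcode, "CCCCCTGTCTAACTTC-1")
  expect_equal(row$umi, 2L)

  empty <- file.path(dir, "empty.mtx")
  Matrix::writeMM(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                       x = double(0), dims = c(3, 2)), empty)
  expect_equal(nrow(read_pmhc_counts(empty, panel,
                                     features = file.path(dir, "features.txt"),
                                     barcodes = file.path(dir, "barcodes.txt"))), 0)
})

test_that("assembly keeps only barcodes with chains and captures, suffixed by donor", {
  chains <- tibble::tibble(
    barcode = c("AAACCTGTCTAACTTC-1", "AAACCTGTCTAACTTC-1", "CCCCCTGTCTAACTTC-1",
                "GGGGCTGTCTAACTTC"),
    chain_type = c("alpha", "beta", "beta", "beta"),
    v_gene = "V", j_gene = "J", cdr3_aa = "CASSF", umi = 2L,
    productive = TRUE, full_length = TRUE, is_cell = TRUE)
  captures <- tibble::tibble(
    barcode = c("AAACCTGTCTAACTTC-1", "AAACCTGTCTAACTTC-1", "AAACCTGTCTAACTTC-1",
                "GGGGCTGTCTAACTTC", "TTTTCTGTCTAACTTC-1"),
    feature_id = c("f1", "f2", "f3", "f1", "f1"), peptide = "AAA",
    hla_allele = "A*02:01", umi = 3L, is_negative_control = FALSE)

  gems <- assemble_gem_table(chains, captures, donor_id = "s2")
  # CCCC... has chains but no captures; TTTT... captures but no chains
  expect_equal(nrow(gems), 2)
  g1 <- gems[gems$barcode_core == "AAACCTGTCTAACTTC", ]
  expect_equal(g1$barcode_full, "AAACCTGTCTAACTTC-1-s2")
  expect_equal(nrow(g1$chains[[1]]), 2)
  expect_equal(nrow(g1$captures[[1]]), 3)
  # missing well suffix canonicalized to 1
  expect_equal(gems$barcode_full[gems$barcode_core == "GGGGCTGTCTAACTTC"],
               "GGGGCTGTCTAACTTC-1-s2")

  # same core in two donor runs stays distinct
  gems2 <- assemble_gem_table(chains, captures, donor_id = "s3")
  expect_false(any(gems$barcode_full %in% gems2$barcode_full))
  expect_error(assemble_gem_table(
    tibble::tibble(barcode = "NOTACORE", chain_type = "beta", v_gene = "V",
                   j_gene = "J", cdr3_aa = "C", umi = 1L, productive = TRUE,
                   full_length = TRUE, is_cell = TRUE),
    captures, "s2"), "16-nt")
})

test_that("curation drops chains individually and removes empty GEMs, idempotently", {
  g1 <- make_gem(1, chains = chain_row(cdr3 = "CASS*EQYF"))        # non-IUPAC only chain
  g2 <- make_gem(2, chains = dplyr::bind_rows(
    chain_row(type = "alpha", cdr3 = "CAVRF", productive = FALSE),
    chain_row(type = "beta", cdr3 = "CASSF")))                     # alpha dropped, beta kept
  g3 <- make_gem(3)                                                # fully valid
  g4 <- make_gem(4, chains = chain_row(full_length = FALSE))       # removed
  gems <- dplyr::bind_rows(g1, g2, g3, g4)

  out <- suppressMessages(curate_gems(gems))
  expect_equal(nrow(out), 2)
  tally <- attr(out, "curation")
  expect_equal(unname(tally$chains_dropped["non_iupac"]), 1L)
  expect_equal(unname(tally$chains_dropped["not_productive"]), 1L)
  expect_equal(unname(tally$chains_dropped["not_full_length"]), 1L)
  expect_equal(tally$gems_removed, 2L)
  kept2 <- out[out$barcode_full == g2$barcode_full, ]
  expect_equal(kept2$chains[[1]]$chain_type, "beta")
  # unchanged valid GEM
  expect_identical(out$chains[out$barcode_full == g3$barcode_full][[1]],
                   g3$chains[[1]])
  # idempotence (up to the run-specific tally attribute)
  again <- suppressMessages(curate_gems(out))
  strip <- function(x) { attr(x, "curation") <- NULL; tibble::as_tibble(x) }
  expect_identical(strip(again), strip(out))
  expect_equal(sum(attr(again, "curation")$chains_dropped), 0L)
  expect_equal(attr(again, "curation")$gems_removed, 0L)
})

test_that("barcode alignment matches full barcodes first, cores second, ambiguity excluded", {
  base <- c("barcode_full", "barcode_core", "donor")
  a <- tibble::tibble(
    barcode_full = c("AAACCTGTCTAACTTC-6-s2", "CCCCCTGTCTAACTTC-1-s2",
                     "GGGGCTGTCTAACTTC-6-s2"),
    barcode_core = c("AAACCTGTCTAACTTC", "CCCCCTGTCTAACTTC", "GGGGCTGTCTAACTTC"),
    donor = "s2")
  b <- tibble::tibble(
    barcode_full = c("AAACCTGTCTAACTTC-1-s2", "CCCCCTGTCTAACTTC-1-s2",
                     "GGGGCTGTCTAACTTC-1-s2", "GGGGCTGTCTAACTTC-2-s2"),
    barcode_core = c("AAACCTGTCTAACTTC", "CCCCCTGTCTAACTTC", "GGGGCTGTCTAACTTC",
                     "GGGGCTGTCTAACTTC"),
    donor = "s2")
  res <- align_external_annotations(a, b)
  expect_equal(unname(res$pass_counts["pass1"]), 1)  # CCCC exact
  expect_equal(unname(res$pass_counts["pass2"]), 1)  # AAAC core match
  expect_equal(nrow(res$ambiguous), 1)               # GGGG twice in b
  expect_equal(res$matches$pass[res$matches$barcode_a == "AAACCTGTCTAACTTC-6-s2"], 2L)

  # symmetric match count
  res_ba <- align_external_annotations(b, a)
  expect_setequal(paste(res$matches$barcode_a, res$matches$barcode_b),
                  paste(res_ba$matches$barcode_b, res_ba$matches$barcode_a))
})

test_that("canonical GEM table round-trips through CSV exactly", {
  sim <- simulate_gem_dataset(sim_config(n_clonotypes = 15, n_pmhc = 4, seed = 11))
  cl <- clonotype_gems(suppressMessages(curate_gems(sim$gems)))
  tab <- apply_thresholds(cl$gems, threshold_set(1, 1.0, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gem_table(tab, path)
  back <- read_gem_table(path)
  # provenance attributes (curation tally) are not part of the on-disk codec
  attr(tab, "curation") <- NULL
  expect_identical(tibble::as_tibble(back)[names(tab)], tibble::as_tibble(tab))
})

test_that("simulated raw inputs ingest back to the simulated GEM table", {
  sim <- simulate_gem_dataset(sim_config(n_donors = 1, n_clonotypes = 12,
                                         n_pmhc = 4, seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_simulated_inputs(sim, dir)
  chains <- suppressMessages(read_contig_annotations(paths[["contigs"]]))
  panel <- read_pmhc_panel(paths[["panel"]])
  caps <- read_pmhc_counts(paths[["pmhc"]], panel)
  hla <- read_hla_haplotypes(paths[["hla"]])
  gems <- assemble_gem_table(chains, caps, donor_id = "d1")
  expect_equal(nrow(gems), nrow(sim$gems))
  ord <- match(sim$gems$barcode_full, gems$barcode_full)
  expect_false(anyNA(ord))
  cmp <- gems[ord, ]
  expect_equal(cmp$is_cell, sim$gems$is_cell)
  # captures agree up to row order
  for (i in seq_len(nrow(cmp))) {
    a <- dplyr::arrange(cmp$captures[[i]], feature_id)
    b <- dplyr::arrange(sim$gems$captures[[i]], feature_id)
    expect_equal(a, b)
  }
  expect_setequal(hla$allele, sim$haplotypes$allele)
})
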