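#' @keywords internal
#' BLOSUM62 substitution kernel, cached per (beta) value.
kernel_env <- new.env(parent = emptyenv())

get_substitution_kernel <- function(beta) {
  key <- sprintf("kappa_%.8f", beta)
  if (is.null(kernel_env[[key]])) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    kernel_env[[key]] <- exp(beta * b62)
  }
  kernel_env[[key]]
}

#' String-kernel parameters
#'
#' The CDR3 similarity is a k-mer substitution string kernel: every k-mer of
#' one sequence is compared with every k-mer of the other through a
#' position-wise positive substitution kernel
#' `kappa(a, b) = exp(beta * BLOSUM62[a, b])`, and the contributions are
#' summed over the configured k-mer lengths.
#'
#' @param beta Exponential scaling of the BLOSUM62 scores (default 0.11387,
#'   the customary value for this kernel family).
#' @param k Integer vector of k-mer lengths (default `1:3`).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(beta = 0.11387, k = 1:3) {
  stopifnot(beta > 0, all(k >= 1))
  structure(list(beta = beta, k = as.integer(sort(unique(k)))),
            class = "kernel_params")
}

# Raw (unnormalized) k-mer substitution kernel between two sequences given
# as integer index vectors into AA_ALPHABET.
raw_kernel_idx <- function(si, ti, kappa, ks) {
  n <- length(si); m <- length(ti)
  M <- kappa[si, ti, drop = FALSE]
  total <- 0
  P <- M
  if (1L %in% ks) total <- total + sum(P)
  kmax <- max(ks)
  k <- 1L
  while (k < kmax && nrow(P) > 1 && ncol(P) > 1) {
    P <- P[-nrow(P), -ncol(P), drop = FALSE] *
      M[(k + 1):n, (k + 1):m, drop = FALSE]
    k <- k + 1L
    if (k %in% ks) total <- total + sum(P)
  }
  total
}

seq_to_idx <- function(s) {
  idx <- match(strsplit(s, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) {
    abort(sprintf("Sequence '%s' contains non-amino-acid characters", s),
          class = "itrap_usage_error")
  }
  idx
}

#' Normalized CDR3 chain similarity
#'
#' `K(s, t) / sqrt(K(s, s) * K(t, t))` for the k-mer substitution kernel `K`
#' of [kernel_params()]. The result lies in `[0, 1]`, equals 1 for identical
#' sequences, and is symmetric.
#'
#' @param s,t Non-empty amino-acid sequences.
#' @param params A [kernel_params()] object.
#' @return Similarity in `[0, 1]`.
#' @export
chain_similarity <- function(s, t, params = kernel_params()) {
  if (!nzchar(s) || !nzchar(t)) {
    abort("chain_similarity requires non-empty sequences",
          class = "itrap_usage_error")
  }
  kappa <- get_substitution_kernel(params$beta)
  si <- seq_to_idx(s); ti <- seq_to_idx(t)
  kst <- raw_kernel_idx(si, ti, kappa, params$k)
  kss <- raw_kernel_idx(si, si, kappa, params$k)
  ktt <- raw_kernel_idx(ti, ti, kappa, params$k)
  kst / sqrt(kss * ktt)
}

#' Paired alpha+beta TCR similarity
#'
#' Sum of the normalized CDR3 alpha and CDR3 beta chain similarities of two
#' TCRs, bounded by `[0, 2]`.
#'
#' @param tcr1,tcr2 Lists or one-row data frames with `cdr3_a` and `cdr3_b`.
#' @param params A [kernel_params()] object.
#' @return Similarity in `[0, 2]`.
#' @export
paired_similarity <- function(tcr1, tcr2, params = kernel_params()) {
  need <- function(x, f) {
    v <- x[[f]]
    if (is.null(v) || is.na(v) || !nzchar(v)) {
      abort(sprintf("paired_similarity requires a %s sequence", f),
            class = "itrap_usage_error")
    }
    as.character(v)
  }
  chain_similarity(need(tcr1, "cdr3_a"), need(tcr2, "cdr3_a"), params) +
    chain_similarity(need(tcr1, "cdr3_b"), need(tcr2, "cdr3_b"), params)
}

#' Maximal intra- and inter-specificity similarity scores
#'
#' Clonotypes annotated to the same pMHC form a "plateau". Each clonotype in
#' a plateau of size `>= 2` contributes one *intra* score — its maximal
#' paired similarity to another clonotype of the same plateau — and one
#' *inter* score — its maximal paired similarity over an equally sized random
#' sample (without replacement) of clonotypes from other plateaus. The
#' sampling seed is recorded so score lists are reproducible bit-for-bit.
#'
#' @param clonotypes Tibble with `ct_id`, `cdr3_a`, `cdr3_b` and
#'   `specificity` (feature id), one row per clonotype.
#' @param seed Integer seed for the inter-plateau sampling.
#' @param params A [kernel_params()] object.
#' @return A list of class `itrap_similarity_scores`: `intra`, `inter`
#'   (equal-length numeric vectors), `ct_id` (contributing clonotypes) and
#'   `seed`.
#' @export
intra_inter_scores <- function(clonotypes, seed = 1L, params = kernel_params()) {
  cl <- clonotypes |>
    filter(!is.na(.data$specificity), !is.na(.data$cdr3_a), !is.na(.data$cdr3_b))
  counts <- table(cl$specificity)
  eligible_spec <- names(counts)[counts >= 2]
  skipped <- nrow(cl) - sum(cl$specificity %in% eligible_spec)
  if (skipped > 0) {
    inform(sprintf(
      "%d clonotype(s) in single-clonotype plateaus skipped (no intra comparator)",
      skipped))
  }
  cl_el <- cl |> filter(.data$specificity %in% eligible_spec)
  out <- structure(list(intra = double(0), inter = double(0),
                        ct_id = character(0), seed = as.integer(seed)),
                   class = "itrap_similarity_scores")
  if (nrow(cl_el) == 0 || length(eligible_spec) < 2) return(out)

  kappa <- get_substitution_kernel(params$beta)
  idx_a <- lapply(cl_el$cdr3_a, seq_to_idx)
  idx_b <- lapply(cl_el$cdr3_b, seq_to_idx)
  self_a <- vapply(idx_a, function(s) raw_kernel_idx(s, s, kappa, params$k), double(1))
  self_b <- vapply(idx_b, function(s) raw_kernel_idx(s, s, kappa, params$k), double(1))

  pair_sim <- function(i, j) {
    raw_kernel_idx(idx_a[[i]], idx_a[[j]], kappa, params$k) /
      sqrt(self_a[i] * self_a[j]) +
      raw_kernel_idx(idx_b[[i]], idx_b[[j]], kappa, params$k) /
      sqrt(self_b[i] * self_b[j])
  }

  intra <- double(nrow(cl_el)); inter <- double(nrow(cl_el))
  with_seed(seed, {
    for (i in seq_len(nrow(cl_el))) {
      same <- which(cl_el$specificity == cl_el$specificity[i])
      mates <- setdiff(same, i)
      others <- which(cl_el$specificity != cl_el$specificity[i])
      n_sample <- min(length(mates), length(others))
      samp <- if (length(others) == 1) others else
        sample(others, n_sample, replace = FALSE)
      intra[i] <- max(vapply(mates, pair_sim, double(1), i = i))
      inter[i] <- max(vapply(samp, pair_sim, double(1), i = i))
    }
  })
  out$intra <- intra
  out$inter <- inter
  out$ct_id <- cl_el$ct_id
  out
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Rank-based AUC separating intra- from inter-specificity scores
#'
#' The probability (tie-corrected, Mann-Whitney form) that a randomly chosen
#' intra-specificity score exceeds a randomly chosen inter-specificity score,
#' reported on a 0-100 scale. 50 means no separation, 100 perfect
#' separation.
#'
#' @param scores An `itrap_similarity_scores` object, or a list with numeric
#'   `intra` and `inter` elements.
#' @return AUC in `[0, 100]`.
#' @export
similarity_auc <- function(scores) {
  intra <- scores$intra; inter <- scores$inter
  if (length(intra) == 0 || length(inter) == 0) {
    abort("similarity_auc requires non-empty intra and inter score lists",
          class = "itrap_usage_error")
  }
  r <- rank(c(intra, inter))
  n1 <- length(intra); n2 <- length(inter)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  100 * u / (n1 * n2)
}
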