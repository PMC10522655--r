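#' Write / read the canonical GEM table
#'
#' The canonical on-disk form is a flat CSV; list-columns (pMHC captures,
#' unresolved or surplus chains) are serialized into JSON columns
#' (`pmhc_json`, `chains_json`, `extra_chains_json`) so a write followed by a
#' read reproduces every field exactly.
#'
#' @param gems A GEM tibble at any pipeline stage.
#' @param path Output CSV path.
#' @return `write_gem_table()` returns `path` invisibly; `read_gem_table()`
#'   returns the reconstructed tibble.
#' @export
write_gem_table <- function(gems, path) {
  out <- gems
  json_map <- c(captures = "pmhc_json", chains = "chains_json",
                extra_chains = "extra_chains_json")
  for (col in names(json_map)) {
    if (col %in% names(out)) {
      out[[json_map[[col]]]] <- vapply(
        out[[col]],
        function(x) as.character(jsonlite::toJSON(x, dataframe = "rows", digits = NA)),
        character(1))
      out[[col]] <- NULL
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_gem_table
#' @export
read_gem_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  json_map <- c(pmhc_json = "captures", chains_json = "chains",
                extra_chains_json = "extra_chains")
  proto <- list(
    captures = tibble(feature_id = character(0), peptide = character(0),
                      hla_allele = character(0), umi = integer(0),
                      is_negative_control = logical(0)),
    chains = tibble(chain_type = character(0), v_gene = character(0),
                    j_gene = character(0), cdr3_aa = character(0),
                    umi = integer(0), productive = logical(0),
                    full_length = logical(0)),
    extra_chains = tibble(chain_type = character(0), v_gene = character(0),
                          j_gene = character(0), cdr3_aa = character(0),
                          umi = integer(0), productive = logical(0),
                          full_length = logical(0))
  )
  for (jcol in names(json_map)) {
    if (jcol %in% names(tab)) {
      target <- json_map[[jcol]]
      p <- proto[[target]]
      tab[[target]] <- lapply(tab[[jcol]], function(s) {
        parsed <- jsonlite::fromJSON(s)
        if (length(parsed) == 0 || NROW(parsed) == 0) return(p)
        parsed <- as_tibble(parsed)
        for (cn in names(p)) {
          if (!cn %in% names(parsed)) parsed[[cn]] <- p[[cn]][NA_integer_]
          mode_fun <- switch(class(p[[cn]])[1],
                             integer = as.integer,
                             logical = as.logical,
                             character = as.character,
                             identity)
          parsed[[cn]] <- mode_fun(parsed[[cn]])
        }
        parsed[names(p)]
      })
      tab[[jcol]] <- NULL
    }
  }
  # barcode-like and gene columns must stay character even when all-numeric
  for (cn in intersect(c("well", "donor", "ct_id", "assigned_pmhc"), names(tab))) {
    tab[[cn]] <- as.character(tab[[cn]])
  }
  # UMI counts are integral; read_csv guesses double when NAs are present
  for (cn in intersect(c("umi_a", "umi_b"), names(tab))) {
    tab[[cn]] <- as.integer(tab[[cn]])
  }
  tab
}
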