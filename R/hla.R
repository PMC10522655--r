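#' Normalize HLA allele names to two-field resolution
#'
#' Class I HLA alleles appear in many dialects across contig panels, donor
#' haplotype reports and multimer panel sheets: `"HLA-A*02:01"`, `"A*02:01"`,
#' `"A0201"`, `"A*0201"`, or with extra fields such as `"A*02:01:01"`. All
#' comparisons in the pipeline (donor haplotype matching, outlier HLA
#' divergence) are made at two-field resolution, so every allele string is
#' canonicalized to `LOCUS*NN:NN` on entry.
#'
#' @param x Character vector of allele names in any common dialect.
#' @return Character vector of canonical `LOCUS*NN:NN` strings. Unparseable
#'   entries raise an error naming the offending value.
#' @examples
#' normalize_hla_allele(c("HLA-A*02:01", "A0201", "B*08:01:01", "b0702"))
#' @export
normalize_hla_allele <- function(x) {
  if (length(x) == 0) return(character(0))
  orig <- x
  x <- toupper(trimws(as.character(x)))
  x <- sub("^HLA-", "", x)
  # With a separator the locus may carry digits (e.g. DRB1*); in the
  # digit-only dialect ("A0201") the locus is the letter prefix alone.
  locus <- ifelse(grepl("[*:]", x),
                  sub("^([A-Z]+[0-9]*?)[*:].*$", "\\1", x),
                  sub("^([A-Z]+).*$", "\\1", x))
  rest <- substr(x, nchar(locus) + 1, nchar(x))
  rest <- gsub("[*]", "", rest)

  two_field <- function(rest_i, orig_i) {
    if (grepl(":", rest_i)) {
      fields <- strsplit(rest_i, ":", fixed = TRUE)[[1]]
      fields <- fields[fields != ""]
      if (length(fields) < 2) {
        # single field before a stray colon, e.g. "A*02:"
        if (length(fields) == 1 && nchar(fields[1]) >= 3) {
          # "A02:01" style already split above; fall through to digits
          return(two_field(gsub(":", "", rest_i), orig_i))
        }
        abort(sprintf("Cannot parse HLA allele '%s' to two-field resolution", orig_i))
      }
      return(sprintf("%02d:%02d", as.integer(fields[1]), as.integer(fields[2])))
    }
    if (!grepl("^[0-9]+$", rest_i) || nchar(rest_i) < 3) {
      abort(sprintf("Cannot parse HLA allele '%s' to two-field resolution", orig_i))
    }
    # digit-only dialects: 4 digits -> NN+NN; 5 digits -> NNN+NN is ambiguous,
    # resolve as 2+2 using the leading four (extra fields are dropped anyway)
    if (nchar(rest_i) == 3) rest_i <- paste0("0", rest_i)
    sprintf("%02d:%02d",
            as.integer(substr(rest_i, 1, 2)),
            as.integer(substr(rest_i, 3, 4)))
  }

  bad <- !grepl("^[A-Z]", x) | rest == "" | locus == ""
  if (any(bad)) {
    abort(sprintf("Cannot parse HLA allele '%s'", orig[which(bad)[1]]))
  }
  fields <- vapply(seq_along(x), function(i) two_field(rest[i], orig[i]), character(1))
  paste0(locus, "*", fields)
}

#' Read a donor HLA haplotype table
#'
#' Expects a long CSV with columns `donor_id,allele`, one row per class I
#' allele carried by a donor. Alleles are canonicalized with
#' [normalize_hla_allele()].
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `donor_id` and `allele` (canonical form).
#' @export
read_hla_haplotypes <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("donor_id", "allele")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("HLA table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tab |>
    mutate(donor_id = as.character(.data$donor_id),
           allele = normalize_hla_allele(.data$allele)) |>
    distinct(.data$donor_id, .data$allele)
  if (nrow(out) == 0) abort("HLA table contains no alleles")
  out
}
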