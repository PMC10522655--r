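#' Run the full denoising pipeline
#'
#' Orchestrates curation, clonotyping, expected-binder annotation, threshold
#' search (or a fixed threshold set) and the configured filter cascade, and
#' computes a metrics report after each stage. When `out_dir` is given, the
#' staged tables, the threshold set, the objective trace, the binder table
#' and per-stage metrics are written there.
#'
#' @param gems Assembled canonical GEM tibble ([assemble_gem_table()] or
#'   [simulate_gem_dataset()]`$gems`).
#' @param haplotypes Donor haplotype tibble; required when `"hla"` is among
#'   the steps.
#' @param thresholds A fixed [threshold_set()]; when `NULL` (default) the
#'   thresholds are searched on the binder-annotated clonotypes.
#' @param steps Filter steps in order (see [apply_itrap_filters()]).
#' @param min_gems,alpha Binder-annotation parameters.
#' @param grid Threshold search grid ([threshold_grid()]).
#' @param params [kernel_params()] for the similarity metrics.
#' @param seed Seed for the similarity sampling.
#' @param out_dir Optional output directory.
#' @return A list of class `itrap_run`: `gems` (final table), `stages`
#'   (tables after each stage, starting at `"curated"`), `clonotypes`,
#'   `binders`, `thresholds`, `search` (NULL for fixed thresholds),
#'   `metrics` (named list of `itrap_metrics` per stage) and `log`.
#' @export
run_itrap_pipeline <- function(gems, haplotypes = NULL, thresholds = NULL,
                               steps = c("threshold", "hla", "paired",
                                         "singlet", "is_cell"),
                               min_gems = 10, alpha = 0.05,
                               grid = threshold_grid(),
                               params = kernel_params(), seed = 1L,
                               out_dir = NULL) {
  curated <- curate_gems(gems)
  cl <- clonotype_gems(curated)
  binders <- annotate_expected_binders(cl$gems, min_gems = min_gems,
                                       alpha = alpha)
  search <- NULL
  if (is.null(thresholds)) {
    search <- grid_search_thresholds(cl$gems, binders, grid = grid)
    thresholds <- search$thresholds
  }
  filt <- apply_itrap_filters(cl$gems, haplotypes = haplotypes,
                              thresholds = thresholds, steps = steps)

  stages <- c(list(curated = cl$gems), filt$stages)
  raw <- cl$gems
  metrics <- lapply(stages, function(tab) {
    metrics_report(tab, raw, seed = seed, min_gems = min_gems, alpha = alpha,
                   params = params)
  })

  run <- structure(list(gems = filt$gems, stages = stages,
                        clonotypes = cl$clonotypes, binders = binders,
                        thresholds = thresholds, search = search,
                        metrics = metrics, log = filt$log,
                        seed = as.integer(seed)),
                   class = "itrap_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage_names <- names(stages)
    for (i in seq_along(stages)) {
      write_gem_table(stages[[i]],
                      file.path(out_dir, sprintf("%02d_%s.csv", i, stage_names[i])))
      jsonlite::write_json(unclass(metrics[[i]]),
                           file.path(out_dir, sprintf("metrics_%s.json", stage_names[i])),
                           auto_unbox = TRUE, digits = NA)
    }
    readr::write_csv(run$clonotypes, file.path(out_dir, "clonotypes.csv"),
                     progress = FALSE)
    readr::write_csv(binders |> select(-"p_values"),
                     file.path(out_dir, "binders.csv"), progress = FALSE)
    jsonlite::write_json(unclass(thresholds),
                         file.path(out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(search)) {
      readr::write_csv(search$trace, file.path(out_dir, "objective_trace.csv"),
                       progress = FALSE)
    }
  }
  run
}

#' @export
print.itrap_run <- function(x, ...) {
  cat("ITRAP pipeline run\n")
  print(x$thresholds)
  cat(sprintf("stages: %s\n", paste(names(x$stages), collapse = " -> ")))
  g <- glance(x)
  print(as.data.frame(g), row.names = FALSE)
  invisible(x)
}
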