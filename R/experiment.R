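#' Run the full categorization experiment grid
#'
#' For every fold of a k-fold contiguous split: projects each seed on the
#' training part, builds completion tables per context scheme, categorizes
#' the test part, scores hits/misses/false alarms, and (optionally) runs
#' the context-blind chance baseline at the fold's projection rates. One
#' result row per (fold, seed, scheme-or-chance, category).
#'
#' The chance baseline targets every token passing the frequency threshold
#' (the known-context condition is dropped, since the baseline uses no
#' context) and is drawn once per fold with a seed derived from `rng_seed`,
#' so reruns with the same configuration are identical.
#'
#' @param corpus A [tagged_corpus()].
#' @param seeds A [seed_lexicon()] or list of them.
#' @param schemes Context schemes to run.
#' @param k Number of folds.
#' @param train_fraction Training fraction within each mini-corpus.
#' @param threshold,rule,max_count Target-selection filter (see
#'   [select_targets()]).
#' @param rng_seed Integer seed (baseline draws and optional shuffling).
#' @param include_chance Run the chance baseline.
#' @param shuffle_folds Shuffle utterances before cutting mini-corpora.
#' @param output_dir If non-`NULL`, write `results.csv`, `summary.csv`,
#'   `contexts_topk.csv`, `miss_breakdown.csv` and `run_metadata.json`
#'   there. Context/miss reports are for the left scheme under the last
#'   seed, aggregated across folds.
#' @param top_k_contexts Rows in the frequent-context report.
#' @return A tibble of result rows with columns `fold`, `seed_id`,
#'   `scheme`, `category`, `precision`, `recall`, `hits`, `misses`, `fas`,
#'   `n_targets`, `n_abstentions`.
#' @export
run_experiment <- function(corpus, seeds,
                           schemes = c("left", "framing", "right"),
                           k = 10, train_fraction = 2 / 3,
                           threshold = 5e-4, rule = "ratio",
                           max_count = 17L, rng_seed = 1L,
                           include_chance = TRUE, shuffle_folds = FALSE,
                           output_dir = NULL, top_k_contexts = 20) {
  if (inherits(seeds, "seed_lexicon")) seeds <- list(seeds)
  schemes <- match.arg(schemes, c("left", "framing", "right"),
                       several.ok = TRUE)
  folds <- split_folds(corpus, k, train_fraction, shuffle = shuffle_folds,
                       seed = if (shuffle_folds) rng_seed else NULL)
  wf_tags <- majority_tags(corpus)
  rows <- list()
  report_records <- list()  # left-scheme records of the last seed
  last_seed_id <- seeds[[length(seeds)]]$id

  for (fold in folds) {
    if (n_tokens(fold$test) == 0) {
      warning(sprintf("fold %d skipped: empty test set", fold$fold_id),
              call. = FALSE)
      next
    }
    for (si in seq_along(seeds)) {
      seed <- seeds[[si]]
      res <- tryCatch({
        proj <- project_seed(fold$train, seed)
        counts_by_scheme <- lapply(
          setNames(schemes, schemes),
          function(sc) train_tables(proj, sc))
        fold_rows <- list()
        for (sc in schemes) {
          rec <- categorize_corpus(fold$test, counts_by_scheme[[sc]],
                                   threshold = threshold, rule = rule,
                                   max_count = max_count, quiet = TRUE)
          scored <- score_records(rec, wf_tags)
          fold_rows[[sc]] <- result_rows(fold$fold_id, seed$id, sc, scored,
                                         rec)
          if (sc == "left" && seed$id == last_seed_id) {
            report_records[[length(report_records) + 1L]] <- rec
          }
        }
        if (include_chance) {
          any_counts <- counts_by_scheme[[1]]
          sites <- select_targets(fold$test, any_counts,
                                  threshold = threshold, rule = rule,
                                  max_count = max_count,
                                  require_known_context = FALSE)
          crec <- chance_predict(
            sites, chance_rates(proj),
            rng_seed + 7919L * fold$fold_id + 104729L * si)
          fold_rows[["chance"]] <- result_rows(
            fold$fold_id, seed$id, "chance",
            score_records(crec, wf_tags), crec)
        }
        bind_rows(fold_rows)
      }, error = function(e) {
        warning(sprintf("fold %d, seed %s failed: %s", fold$fold_id,
                        seed$id, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  results <- bind_rows(rows)
  if (!is.null(output_dir)) {
    write_experiment_outputs(results, report_records, output_dir,
                             wf_tags, last_seed_id, top_k_contexts,
                             config = list(
                               schemes = schemes, k = k,
                               train_fraction = train_fraction,
                               threshold = threshold, rule = rule,
                               max_count = max_count, rng_seed = rng_seed,
                               include_chance = include_chance,
                               shuffle_folds = shuffle_folds,
                               seed_ids = vapply(seeds, `[[`, "", "id")))
  }
  results
}

result_rows <- function(fold_id, seed_id, scheme, scored, records) {
  n_abst <- sum(records$response_type == "abstain")
  bind_rows(lapply(c("N", "V"), function(cat_) {
    tibble(fold = fold_id, seed_id = seed_id, scheme = scheme,
           category = cat_,
           precision = precision(scored, cat_),
           recall = recall(scored, cat_),
           hits = scored$hits[[cat_]], misses = scored$misses[[cat_]],
           fas = scored$fas[[cat_]],
           n_targets = scored$n_scored, n_abstentions = n_abst)
  }))
}

write_experiment_outputs <- function(results, report_records, output_dir,
                                     wf_tags, last_seed_id, top_k,
                                     config) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(results, file.path(output_dir, "results.csv"))
  readr::write_csv(summarize_experiment(results),
                   file.path(output_dir, "summary.csv"))
  if (length(report_records)) {
    rec <- bind_rows(report_records)
    ctx <- bind_rows(
      mutate(frequent_context_report(rec, "N", top_k),
             target_category = "N"),
      mutate(frequent_context_report(rec, "V", top_k),
             target_category = "V"))
    readr::write_csv(ctx, file.path(output_dir, "contexts_topk.csv"))
    readr::write_csv(
      miss_breakdown(score_records(rec, wf_tags)),
      file.path(output_dir, "miss_breakdown.csv"))
  }
  meta <- c(config,
            list(package_version = as.character(
              utils::packageVersion("semseed")),
              report_condition = list(scheme = "left",
                                      seed_id = last_seed_id)))
  jsonlite::write_json(meta, file.path(output_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

#' Aggregate experiment rows across folds
#'
#' Per (seed, scheme, category) condition: mean and standard error of the
#' mean of precision and recall over folds. The SEM is `NA` with a single
#' fold.
#'
#' @param results Rows from [run_experiment()].
#' @return A tibble with `seed_id`, `scheme`, `category`, `n_folds`,
#'   `mean_precision`, `sem_precision`, `mean_recall`, `sem_recall`.
#' @export
summarize_experiment <- function(results) {
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) <= 1) NA_real_ else sd(x) / sqrt(length(x))
  }
  results |>
    group_by(.data$seed_id, .data$scheme, .data$category) |>
    summarise(n_folds = n(),
              mean_precision = mean(.data$precision, na.rm = TRUE),
              sem_precision = sem(.data$precision),
              mean_recall = mean(.data$recall, na.rm = TRUE),
              sem_recall = sem(.data$recall),
              .groups = "drop")
}
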