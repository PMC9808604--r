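#' Configuration for a full pipeline run
#'
#' A single configuration object drives the whole analysis:
#' simulate (optional) -> preprocess -> fit (per model, per K) -> series ->
#' evaluate -> report. Defaults mirror the closed-cohort quarterly design:
#' patient-quarter analysis rows, T = 20 quarters, K = 50 topics, top-5
#' topic words, both NMF and LDA.
#'
#' @param workspace Directory all artifacts are written under.
#' @param corpus_file Optional path to an existing JSON-lines corpus; when
#'   `NULL` the simulate stage generates one.
#' @param seed Root integer seed; every stage derives its randomness from
#'   it.
#' @param simulate List of simulator settings: `n_patients`, `n_quarters`,
#'   `k_true`, `vocab_size`, `concentration`, `seasonal` (list with `topic`,
#'   `amplitude`, `period`, `phase`; `NULL` for all-constant topics),
#'   `notes_mean` (mean of the Poisson excess over the guaranteed 1 note
#'   per patient-quarter), `doc_length_mean`, `doc_length_min`, `noise`,
#'   `doc_jitter` (per-document Dirichlet concentration multiplier; `NULL`
#'   uses the quarter prevalence directly for every document).
#' @param preprocess List: `min_count`, `stoplist`, `max_vocab`, `level`
#'   (`"patient_quarter"` or `"note"`).
#' @param models Character subset of `c("nmf", "lda")`.
#' @param k_grid Integer vector of topic counts to fit.
#' @param nmf List: `max_iter`, `tol`.
#' @param lda List: `alpha` (`NULL` for `1/K`), `beta`, `n_iter`, `burn_in`.
#' @param evaluate List: `top_l`, `window`, `measures`.
#' @return A `run_config` object.
#' @export
run_config <- function(workspace,
                       corpus_file = NULL,
                       seed = 1L,
                       simulate = list(),
                       preprocess = list(),
                       models = c("nmf", "lda"),
                       k_grid = 50L,
                       nmf = list(),
                       lda = list(),
                       evaluate = list()) {
  sim_defaults <- list(n_patients = 100L, n_quarters = 20L, k_true = 5L,
                       vocab_size = 200L, concentration = 0.05,
                       seasonal = list(topic = 1L, amplitude = 0.5,
                                       period = 4, phase = 0),
                       notes_mean = 1, doc_length_mean = 40,
                       doc_length_min = 5, noise = 0, doc_jitter = NULL)
  pre_defaults <- list(min_count = 1L, stoplist = character(),
                      max_vocab = NULL, level = "patient_quarter")
  nmf_defaults <- list(max_iter = 500L, tol = 1e-5)
  lda_defaults <- list(alpha = NULL, beta = 0.01, n_iter = 400L,
                       burn_in = 200L)
  eval_defaults <- list(top_l = 5L, window = 10L,
                        measures = c("umass", "uci", "npmi"))
  models <- match.arg(models, c("nmf", "lda"), several.ok = TRUE)
  k_grid <- vapply(k_grid, assert_count, integer(1), name = "k_grid")
  if (length(k_grid) == 0L) stop("`k_grid` must be nonempty", call. = FALSE)
  structure(
    list(workspace = workspace,
         corpus_file = corpus_file,
         seed = as.integer(seed),
         simulate = utils::modifyList(sim_defaults, simulate,
                                      keep.null = TRUE),
         preprocess = utils::modifyList(pre_defaults, preprocess,
                                        keep.null = TRUE),
         models = models,
         k_grid = as.integer(k_grid),
         nmf = utils::modifyList(nmf_defaults, nmf),
         lda = utils::modifyList(lda_defaults, lda, keep.null = TRUE),
         evaluate = utils::modifyList(eval_defaults, evaluate)),
    class = "run_config")
}

#' Read/write a run configuration as JSON
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  do.call(run_config, raw)
}

md5_of_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA, null = "null",
                                           force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

md5_of_files <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

pipeline_log <- function(ws, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(...))
  message(msg)
  cat(msg, "\n", file = file.path(ws, "run.log"), append = TRUE)
}

read_manifest <- function(ws) {
  path <- file.path(ws, "manifest.json")
  if (!file.exists(path)) return(list(stages = list()))
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

write_manifest <- function(manifest, ws) {
  jsonlite::write_json(manifest, file.path(ws, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

stage_current <- function(manifest, stage, fingerprint) {
  st <- manifest$stages[[stage]]
  if (is.null(st) || !identical(st$fingerprint, fingerprint)) return(FALSE)
  paths <- unlist(st$output_paths)
  if (is.null(paths) || length(paths) == 0L) return(FALSE)
  if (!all(file.exists(paths))) return(FALSE)
  identical(unname(tools::md5sum(paths)), unname(unlist(st$digests)))
}

record_stage <- function(manifest, stage, fingerprint, paths, status,
                         seconds) {
  manifest$stages[[stage]] <- list(
    fingerprint = fingerprint,
    output_paths = as.list(unname(paths)),
    digests = as.list(unname(tools::md5sum(unlist(paths)))),
    status = status,
    seconds = round(seconds, 3))
  manifest
}

#' Run the full temporal topic-modelling pipeline
#'
#' Executes the requested stages in order, writing every artifact under the
#' workspace together with a manifest recording per-stage fingerprints and
#' output digests. A stage whose fingerprint (stage-relevant configuration
#' plus input digests) matches the manifest, and whose outputs are intact,
#' is skipped; changing a setting re-executes only the stages downstream of
#' it. A stage failure aborts the run with the failing stage named, leaving
#' partial outputs in place for inspection.
#'
#' @param config A [run_config()].
#' @param stages Stages to run, in canonical order.
#' @return A `run_manifest` (invisibly the manifest list).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "fit",
                                    "series", "evaluate", "report")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  ws <- config$workspace
  dir.create(ws, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(ws)
  manifest$config <- unclass(config)
  manifest$package_version <- as.character(utils::packageVersion(
    "cohorttopics"))

  paths <- pipeline_paths(ws, config)
  run_one <- function(stage, fingerprint, outputs, fn) {
    if (stage_current(manifest, stage, fingerprint)) {
      pipeline_log(ws, "stage %-10s skipped (up to date)", stage)
      manifest$stages[[stage]]$status <<- "skipped"
      return(invisible(NULL))
    }
    pipeline_log(ws, "stage %-10s running", stage)
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({fn(); TRUE}, error = function(e) {
      pipeline_log(ws, "stage %-10s FAILED: %s", stage, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    secs <- proc.time()[["elapsed"]] - t0
    missing <- outputs[!file.exists(outputs)]
    if (length(missing)) {
      stop(sprintf("pipeline stage '%s' failed to produce: %s", stage,
                   paste(basename(missing), collapse = ", ")),
           call. = FALSE)
    }
    manifest <<- record_stage(manifest, stage, fingerprint, outputs,
                              "done", secs)
    write_manifest(manifest, ws)
    pipeline_log(ws, "stage %-10s done in %.1fs", stage, secs)
  }

  # ---- simulate ------------------------------------------------------
  if ("simulate" %in% stages && is.null(config$corpus_file)) {
    fp <- md5_of_object(list(sim = config$simulate, seed = config$seed))
    run_one("simulate", fp, unlist(paths$simulate), function() {
      sim <- config$simulate
      trends <- rep(list(trend_constant()), sim$k_true)
      if (!is.null(sim$seasonal)) {
        s <- sim$seasonal
        trends[[s$topic]] <- trend_seasonal(s$amplitude, s$period, s$phase)
      }
      phi <- make_topics(sim$k_true, sim$vocab_size, sim$concentration,
                         seed = config$seed)
      curves <- make_prevalence_curves(sim$n_quarters, trends)
      truth <- synthetic_ground_truth(phi, curves, trend_specs = trends,
                                      seed = config$seed)
      spec <- cohort_spec(
        n_patients = sim$n_patients, n_quarters = sim$n_quarters,
        notes_per_patient_quarter = list(type = "one_plus_poisson",
                                         mean = sim$notes_mean),
        doc_length = list(type = "truncated_poisson",
                          mean = sim$doc_length_mean,
                          min = sim$doc_length_min),
        seed = config$seed)
      corpus <- generate_corpus(spec, truth, doc_jitter = sim$doc_jitter,
                                noise = sim$noise)
      write_corpus_jsonl(corpus, paths$simulate$corpus)
      write_ground_truth(truth, file.path(ws, "truth"))
    })
  }

  corpus_path <- config$corpus_file %||% paths$simulate$corpus

  # ---- preprocess ----------------------------------------------------
  if ("preprocess" %in% stages) {
    fp <- md5_of_object(list(pre = config$preprocess,
                             corpus = unname(tools::md5sum(corpus_path))))
    run_one("preprocess", fp, unlist(paths$preprocess), function() {
      raw <- read_corpus_jsonl(corpus_path)
      tok <- tokenize_corpus(raw)
      n_q <- max(tok$quarter)
      tok <- filter_closed_cohort(tok, n_q)
      vocab <- build_vocabulary(tok,
                                min_count = config$preprocess$min_count,
                                stoplist = config$preprocess$stoplist,
                                max_size = config$preprocess$max_vocab)
      dtm <- build_dtm(tok, vocab, level = config$preprocess$level,
                       n_quarters = if (config$preprocess$level ==
                                          "patient_quarter") n_q else NULL)
      write_dtm(dtm, file.path(ws, "dtm"))
      summ <- summarize_corpus(dtm)
      jsonlite::write_json(
        list(n_units = summ$n_units, n_patients = summ$n_patients,
             n_tokens_total = summ$n_tokens_total,
             vocab_size = summ$vocab_size, sparsity = summ$sparsity,
             level = summ$level, top_terms = summ$top_terms),
        paths$preprocess$summary, auto_unbox = TRUE, digits = NA)
    })
  }

  dtm_digest <- function() {
    unname(tools::md5sum(unlist(paths$preprocess)))
  }

  # ---- fit -----------------------------------------------------------
  if ("fit" %in% stages) {
    fp <- md5_of_object(list(models = config$models, k = config$k_grid,
                             nmf = config$nmf, lda = config$lda,
                             seed = config$seed, dtm = dtm_digest()))
    run_one("fit", fp, unlist(paths$fit), function() {
      dtm <- read_dtm(file.path(ws, "dtm"))
      for (model in config$models) {
        for (K in config$k_grid) {
          fit_dir <- file.path(ws, "fits", sprintf("%s_k%d", model, K))
          dir.create(fit_dir, recursive = TRUE, showWarnings = FALSE)
          if (model == "nmf") {
            raw_fit <- fit_nmf(dtm, K, max_iter = config$nmf$max_iter,
                               tol = config$nmf$tol, seed = config$seed)
            fit <- normalize_nmf(raw_fit)
            trace <- data.frame(iteration = seq_along(raw_fit$loss_trace),
                                loss = raw_fit$loss_trace)
          } else {
            cfg <- lda_config(K,
                              alpha = config$lda$alpha %||% (1 / K),
                              beta = config$lda$beta,
                              n_iter = config$lda$n_iter,
                              burn_in = config$lda$burn_in,
                              seed = config$seed)
            fit <- fit_lda(dtm, cfg)
            trace <- data.frame(
              iteration = seq_along(fit$diagnostics$log_lik_trace),
              log_lik = fit$diagnostics$log_lik_trace)
          }
          write_matrix_tsv(fit$theta, file.path(fit_dir, "theta.tsv"))
          write_matrix_tsv(fit$phi, file.path(fit_dir, "phi.tsv"))
          utils::write.table(trace, file.path(fit_dir, "trace.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          diag_num <- Filter(function(z) is.numeric(z) && length(z) == 1L,
                             fit$diagnostics)
          jsonlite::write_json(
            list(model = model, K = K, seed = config$seed,
                 diagnostics = diag_num),
            file.path(fit_dir, "meta.json"),
            auto_unbox = TRUE, digits = NA)
        }
      }
    })
  }

  # ---- series --------------------------------------------------------
  if ("series" %in% stages) {
    fp <- md5_of_object(list(fits = unname(tools::md5sum(unlist(paths$fit))),
                             top_l = config$evaluate$top_l))
    run_one("series", fp, unlist(paths$series), function() {
      dtm <- read_dtm(file.path(ws, "dtm"))
      dir.create(file.path(ws, "series"), recursive = TRUE,
                 showWarnings = FALSE)
      for (model in config$models) {
        for (K in config$k_grid) {
          fit <- read_fit(ws, model, K)
          labels <- topic_labels(fit, dtm$vocabulary,
                                 L = config$evaluate$top_l, sep = "+")
          series <- topical_time_series(
            fit, dtm$row_meta$quarter,
            n_quarters = max(dtm$row_meta$quarter),
            topic_labels = labels)
          base <- file.path(ws, "series", sprintf("%s_k%d", model, K))
          write_series_tsv(series, paste0(base, "_series.tsv"))
          if (K >= 2) {
            write_linkage_tsv(cluster_topic_series(series),
                              paste0(base, "_linkage.tsv"))
          }
        }
      }
    })
  }

  # ---- evaluate ------------------------------------------------------
  if ("evaluate" %in% stages) {
    fp <- md5_of_object(list(fits = unname(tools::md5sum(unlist(paths$fit))),
                             eval = config$evaluate,
                             corpus = unname(tools::md5sum(corpus_path))))
    run_one("evaluate", fp, unlist(paths$evaluate), function() {
      dtm <- read_dtm(file.path(ws, "dtm"))
      raw <- read_corpus_jsonl(corpus_path)
      tok <- tokenize_corpus(raw)
      top_l <- config$evaluate$top_l
      results <- list()
      bags <- list()
      for (model in config$models) {
        for (K in config$k_grid) {
          fit <- read_fit(ws, model, K)
          tw <- top_words(fit, dtm$vocabulary, L = top_l)
          bag <- topic_bag(tw)
          tag <- sprintf("%s_k%d", model, K)
          bags[[tag]] <- bag
          counts <- count_cooccurrence(tok, unique(unlist(tw)),
                                       window = config$evaluate$window)
          coh <- lapply(config$evaluate$measures, function(m) {
            coherence(tw, counts, measure = m)$mean
          })
          names(coh) <- config$evaluate$measures
          div <- topic_diversity(bag)
          results[[tag]] <- list(
            model = model, K = K,
            diversity = div$diversity,
            diversity_percent = div$percent,
            n_unique = div$n_unique, n_total = div$n_total,
            coherence = coh,
            recurring_words = recurring_words(bag, 5))
        }
      }
      jac <- if (length(bags) >= 2) jaccard_concordance(bags) else NULL
      jsonlite::write_json(
        list(models = results,
             jaccard = if (!is.null(jac)) {
               list(labels = rownames(jac),
                    matrix = unname(as.data.frame(jac)))
             }),
        paths$evaluate$report, auto_unbox = TRUE, digits = NA,
        null = "null")
      if (!is.null(jac)) {
        write_matrix_tsv(jac, paths$evaluate$jaccard)
      } else {
        writeLines("single model: no pairwise concordance",
                   paths$evaluate$jaccard)
      }
    })
  }

  # ---- report --------------------------------------------------------
  if ("report" %in% stages) {
    fp <- md5_of_object(list(
      eval = unname(tools::md5sum(unlist(paths$evaluate))),
      series = unname(tools::md5sum(unlist(paths$series)))))
    run_one("report", fp, unlist(paths$report), function() {
      dir.create(file.path(ws, "report"), recursive = TRUE,
                 showWarnings = FALSE)
      grid <- k_grid_report(paths$evaluate$report)
      utils::write.table(grid, paths$report$k_grid, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      figures <- character()
      for (model in config$models) {
        for (K in config$k_grid) {
          tag <- sprintf("%s_k%d", model, K)
          series <- read_series(ws, model, K)
          fig_heat <- file.path(ws, "report",
                                paste0("heatmap_", tag, ".png"))
          plot_topic_heatmap(series, file = fig_heat)
          fig_series <- file.path(ws, "report",
                                  paste0("series_", tag, ".png"))
          plot_topic_series(series, file = fig_series)
          figures <- c(figures, fig_heat, fig_series)
          if (ncol(series$values) >= 2) {
            fig_dend <- file.path(ws, "report",
                                  paste0("dendrogram_", tag, ".png"))
            plot_topic_dendrogram(cluster_topic_series(series),
                                  file = fig_dend)
            figures <- c(figures, fig_dend)
          }
        }
      }
      jsonlite::write_json(
        list(k_grid_table = paths$report$k_grid,
             figures = figures,
             evaluation = paths$evaluate$report),
        paths$report$index, auto_unbox = TRUE)
    })
  }

  write_manifest(manifest, ws)
  invisible(structure(manifest, class = "run_manifest"))
}

pipeline_paths <- function(ws, config) {
  tags <- as.vector(outer(config$models, config$k_grid,
                          function(m, k) sprintf("%s_k%d", m, k)))
  fit_files <- unlist(lapply(tags, function(tag) {
    file.path(ws, "fits", tag,
              c("theta.tsv", "phi.tsv", "trace.tsv", "meta.json"))
  }))
  series_files <- unlist(lapply(tags, function(tag) {
    file.path(ws, "series", paste0(tag, "_series.tsv"))
  }))
  list(
    simulate = list(
      corpus = file.path(ws, "corpus.jsonl"),
      truth_phi = file.path(ws, "truth", "phi_true.tsv"),
      truth_curves = file.path(ws, "truth", "prevalence_curves.tsv"),
      truth_spec = file.path(ws, "truth", "truth_spec.json")),
    preprocess = list(
      mtx = file.path(ws, "dtm", "dtm.mtx"),
      vocab = file.path(ws, "dtm", "vocabulary.tsv"),
      row_meta = file.path(ws, "dtm", "row_meta.tsv"),
      level = file.path(ws, "dtm", "level.txt"),
      summary = file.path(ws, "summary.json")),
    fit = fit_files,
    series = series_files,
    evaluate = list(
      report = file.path(ws, "evaluation.json"),
      jaccard = file.path(ws, "jaccard.tsv")),
    report = list(
      k_grid = file.path(ws, "report", "k_grid_report.tsv"),
      index = file.path(ws, "report", "report.json")))
}

read_fit <- function(ws, model, K) {
  fit_dir <- file.path(ws, "fits", sprintf("%s_k%d", model, K))
  theta <- read_matrix_tsv(file.path(fit_dir, "theta.tsv"))
  phi <- read_matrix_tsv(file.path(fit_dir, "phi.tsv"))
  meta <- jsonlite::fromJSON(file.path(fit_dir, "meta.json"))
  # round-tripping through text can perturb row sums in the last ulp
  topic_model_fit(theta / rowSums(theta), phi / rowSums(phi),
                  model_tag = model, K = K, seed = meta$seed)
}

read_series <- function(ws, model, K) {
  values <- read_matrix_tsv(
    file.path(ws, "series", sprintf("%s_k%d_series.tsv", model, K)))
  structure(
    list(values = values, quarter_labels = rownames(values),
         topic_labels = colnames(values), model_tag = model),
    class = "temporal_topic_series")
}

#' Per-K model summary table
#'
#' Tabulates topic diversity and the three coherence means for every fitted
#' (model, K) combination, to support an analyst's choice of K. No
#' automatic selection is performed: with too few topics distinct semantic
#' themes merge, with too many they fragment, and the final call is a human
#' judgment.
#'
#' @param evaluation Either the path to an `evaluation.json` written by the
#'   evaluate stage, or the equivalent list.
#' @return Data frame with columns `model`, `K`, `diversity`, and one
#'   column per coherence measure.
#' @export
k_grid_report <- function(evaluation) {
  ev <- if (is.character(evaluation)) {
    jsonlite::fromJSON(evaluation, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else evaluation
  models <- ev$models
  if (length(models) == 0L) stop("no model results", call. = FALSE)
  rows <- lapply(models, function(m) {
    out <- data.frame(model = m$model, K = m$K,
                      diversity = m$diversity,
                      stringsAsFactors = FALSE)
    for (meas in names(m$coherence)) out[[meas]] <- m$coherence[[meas]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
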