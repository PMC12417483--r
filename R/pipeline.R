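pipeline_defaults <- function() {
  list(
    input = list(complaints = NULL, lexicon = NULL, stoplist = NULL),
    columns = list(
      id = "id", text = "text", date = "date",
      channel = "channel", group = "group"
    ),
    preprocess = list(segmenter = "whitespace", max_unit = 5L),
    vectorize = list(weighting = "tfidf", pca_vocab_threshold = 100L),
    clustering = list(
      metric = "euclidean", k_range = NULL, stability_window = 3L,
      fixed_k = NULL, fixed_eps = NULL
    ),
    report = list(period = "all", aggregate = "mean", top_n = 5L),
    output = list(dir = NULL),
    seed = 1L
  )
}

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML/JSON file path or an R list. Missing options are filled
#' with documented defaults; unknown keys trigger a warning (with a
#' closest-match suggestion) rather than being silently dropped; out-of-range
#' values raise a configuration error naming the offending key.
#'
#' @param config Path to a YAML or JSON config file, or a nested list.
#' @return The fully defaulted config list, class `"run_config"`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort_config(paste0("config file not found: ", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort_config("config must be a list or a YAML/JSON file path")
  defaults <- pipeline_defaults()
  warn_unknown_keys(config, defaults, path = "")
  cfg <- modify_defaults(defaults, config)
  if (is.null(cfg$input$complaints)) abort_config("missing required key: input.complaints")
  if (is.null(cfg$input$lexicon)) abort_config("missing required key: input.lexicon")
  for (key in c("complaints", "lexicon", "stoplist")) {
    p <- cfg$input[[key]]
    if (!is.null(p) && !file.exists(p)) {
      abort_config(paste0("input.", key, " does not exist: ", p))
    }
  }
  kr <- cfg$clustering$k_range
  if (!is.null(kr)) {
    if (length(kr) != 2 || kr[2] < kr[1] || kr[1] < 1) {
      abort_config("clustering.k_range must be c(min, max) with 1 <= min <= max")
    }
  }
  if (cfg$clustering$stability_window < 2) {
    abort_config("clustering.stability_window must be >= 2")
  }
  if (!cfg$report$aggregate %in% c("mean", "sum", "min")) {
    abort_config("report.aggregate must be one of mean, sum, min")
  }
  if (cfg$preprocess$max_unit < 0) abort_config("preprocess.max_unit must be >= 0")
  structure(cfg, class = c("run_config", "list"))
}

modify_defaults <- function(defaults, user) {
  for (k in names(user)) {
    if (k %in% names(defaults) && is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- modify_defaults(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

warn_unknown_keys <- function(user, known, path) {
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(known)) {
      near <- agrep(k, names(known), max.distance = 0.3, value = TRUE)
      hint <- if (length(near) > 0) paste0(" (did you mean '", near[1], "'?)") else ""
      warning("unknown config key '", full, "'", hint, call. = FALSE)
    } else if (is.list(known[[k]]) && is.list(user[[k]]) && length(names(known[[k]])) > 0) {
      warn_unknown_keys(user[[k]], known[[k]], full)
    }
  }
  invisible(NULL)
}

new_run_dir <- function(base) {
  dir.create(base, recursive = TRUE, showWarnings = FALSE)
  i <- 1L
  repeat {
    cand <- file.path(base, sprintf("run-%03d", i))
    if (!dir.exists(cand)) {
      dir.create(cand)
      return(cand)
    }
    i <- i + 1L
  }
}

#' Run the complete complaint-analysis pipeline
#'
#' Executes preprocess → sentiment → vectorize → cluster → report →
#' indicators from a validated config, writing each stage's artifacts into a
#' fresh run directory (existing runs are never overwritten) together with a
#' machine-readable manifest (parameters, per-stage record counts, an MD5
#' hash for every artifact, package and R versions). Re-running the same
#' config on the same inputs reproduces identical artifact hashes; only
#' timestamps and the run directory differ. The indicators stage runs only
#' when the complaint table carries outcome columns (`satisfaction` /
#' `compensated` / `petitioned` plus a two-level group column) and is marked
#' `"skipped"` otherwise.
#'
#' @param config A config accepted by [validate_config()].
#' @return The manifest (list), invisibly; element `run_dir` gives the
#'   output location.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (is.null(cfg$output$dir)) abort_config("missing required key: output.dir")
  run_dir <- new_run_dir(cfg$output$dir)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("complaintlens")),
    r_version = as.character(getRversion()),
    run_dir = run_dir,
    config = unclass(cfg),
    inputs = file_hashes(stats::na.omit(unlist(cfg$input))),
    stages = list()
  )
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest(manifest, run_dir)
      rlang::abort(
        paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        parent = e, class = "complaintlens_stage_error"
      )
    })
    manifest$stages[[name]] <<- res$meta
    res$value
  }

  records <- stage("preprocess", function() {
    recs <- read_complaints(
      cfg$input$complaints,
      id_col = cfg$columns$id, text_col = cfg$columns$text,
      date_col = cfg$columns$date, channel_col = cfg$columns$channel,
      group_col = cfg$columns$group
    )
    stoplist <- if (is.null(cfg$input$stoplist)) character(0) else read_stoplist(cfg$input$stoplist)
    recs <- preprocess_corpus(recs, stoplist,
      segmenter = cfg$preprocess$segmenter, max_unit = cfg$preprocess$max_unit
    )
    tok_path <- file.path(run_dir, "tokens.jsonl")
    writeLines(vapply(seq_len(nrow(recs)), function(i) {
      jsonlite::toJSON(list(
        record_id = recs$record_id[i], date = recs$date[i],
        channel = recs$channel[i], tokens = recs$tokens[[i]]
      ), auto_unbox = TRUE)
    }, character(1)), tok_path)
    rec_path <- file.path(run_dir, "records.csv")
    readr::write_csv(dplyr::select(recs, -"tokens"), rec_path)
    cl <- cleaning_summary(recs)
    list(value = recs, meta = list(
      status = "ok",
      counts = list(
        rows_read = cl$rows_read, rows_dropped = cl$rows_dropped,
        dates_sentineled = cl$dates_sentineled, records_out = nrow(recs)
      ),
      outputs = file_hashes(c(rec_path, tok_path))
    ))
  })

  scores <- stage("sentiment", function() {
    lex <- load_lexicon(cfg$input$lexicon)
    sc <- score_corpus(records, lex)
    path <- file.path(run_dir, "scores.csv")
    readr::write_csv(sc, path)
    dist_path <- file.path(run_dir, "polarity.csv")
    readr::write_csv(polarity_distribution(sc), dist_path)
    list(value = sc, meta = list(
      status = "ok",
      counts = list(records_in = nrow(records), records_out = nrow(sc)),
      outputs = file_hashes(c(path, dist_path))
    ))
  })

  mat <- stage("vectorize", function() {
    m <- vectorize_corpus(records,
      weighting = cfg$vectorize$weighting,
      pca_vocab_threshold = cfg$vectorize$pca_vocab_threshold
    )
    path <- file.path(run_dir, "matrix.csv")
    df <- as.data.frame(m)
    readr::write_csv(dplyr::bind_cols(tibble(record_id = records$record_id), df), path)
    list(value = m, meta = list(
      status = "ok",
      counts = list(docs = nrow(m), dims = ncol(m)),
      outputs = file_hashes(path)
    ))
  })

  fit <- stage("cluster", function() {
    kr <- cfg$clustering$k_range
    fit <- kann_dbscan(mat,
      metric = cfg$clustering$metric,
      k_range = if (is.null(kr)) NULL else seq(kr[1], kr[2]),
      stability_window = cfg$clustering$stability_window,
      fixed_k = cfg$clustering$fixed_k, fixed_eps = cfg$clustering$fixed_eps
    )
    lab_path <- file.path(run_dir, "labels.csv")
    readr::write_csv(tibble(record_id = records$record_id, cluster = fit$labels), lab_path)
    trace_path <- file.path(run_dir, "trace.csv")
    readr::write_csv(fit$trace, trace_path)
    par_path <- file.path(run_dir, "params.json")
    jsonlite::write_json(
      list(k = fit$k, eps = fit$eps, pmin = fit$pmin, n_clusters = fit$n_clusters),
      par_path,
      auto_unbox = TRUE, digits = NA
    )
    list(value = fit, meta = list(
      status = "ok",
      counts = list(n_clusters = fit$n_clusters, n_noise = sum(fit$labels == -1L)),
      outputs = file_hashes(c(lab_path, trace_path, par_path))
    ))
  })

  stage("report", function() {
    kw <- cluster_keywords(records, fit$labels, top_n = cfg$report$top_n)
    rep <- negative_report(scores, fit$labels, kw,
      period = cfg$report$period, aggregate = cfg$report$aggregate
    )
    kw_path <- file.path(run_dir, "keywords.csv")
    readr::write_csv(kw, kw_path)
    rep_path <- file.path(run_dir, "report.json")
    jsonlite::write_json(
      list(
        period = rep$period, negative_score = rep$negative_score,
        aggregate = rep$aggregate,
        polarity_counts = as.data.frame(rep$polarity_counts),
        clusters = as.data.frame(kw)
      ),
      rep_path,
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    list(value = rep, meta = list(
      status = "ok",
      counts = list(clusters_reported = length(unique(kw$cluster))),
      outputs = file_hashes(c(kw_path, rep_path))
    ))
  })

  stage("indicators", function() {
    raw <- suppressWarnings(readr::read_csv(cfg$input$complaints, show_col_types = FALSE))
    has_outcomes <- any(c("satisfaction", "compensated", "petitioned") %in% names(raw)) &&
      cfg$columns$group %in% names(raw) &&
      length(unique(stats::na.omit(raw[[cfg$columns$group]]))) == 2
    if (!has_outcomes) {
      return(list(value = NULL, meta = list(
        status = "skipped",
        reason = "no outcome columns / two-level group column in input"
      )))
    }
    ind <- service_indicators(raw, group_col = cfg$columns$group)
    by_path <- file.path(run_dir, "indicators.csv")
    cmp_path <- file.path(run_dir, "comparisons.csv")
    readr::write_csv(ind$by_group, by_path)
    readr::write_csv(ind$comparisons, cmp_path)
    list(value = ind, meta = list(
      status = "ok",
      outputs = file_hashes(c(by_path, cmp_path))
    ))
  })

  write_manifest(manifest, run_dir)
  invisible(manifest)
}

file_hashes <- function(paths) {
  paths <- as.character(paths)
  h <- tools::md5sum(paths)
  stats::setNames(as.list(unname(h)), basename(paths))
}

write_manifest <- function(manifest, run_dir) {
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(manifest)
}
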