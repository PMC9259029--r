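#' Pipeline run configuration
#'
#' Describes a full synthetic cohort and its analysis: one row of
#' `conditions` per experimental cell (treatment x light x frequency) with
#' the generative gain and phase for that cell, `n_per_condition` animals per
#' cell (animal identities are shared across light conditions within a
#' treatment x frequency, so light comparisons are paired within animal), the
#' stimulus parameters, noise levels, analysis settings, and the statistical
#' comparisons to run. All randomness derives from `base_seed`; a config is
#' fully deterministic and round-trips through JSON
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param conditions Data frame with columns `treatment`, `light`,
#'   `frequency`, `gain`, `phase`.
#' @param n_per_condition Animals (= trials) per condition cell.
#' @param amplitude,n_cycles,sample_rate Stimulus parameters shared by all
#'   cells (frequency varies by cell).
#' @param wingbeat_amp,wobble_amp,noise_sd Noise levels shared by all cells.
#' @param base_seed Integer master seed.
#' @param comparisons List of comparison specs; each a list with `type`
#'   (`"paired_signed_rank"`, `"rank_sum"`, or `"kruskal_nemenyi"`), `metric`
#'   (a metrics-table column, default `"epsilon"`), `within` (named list
#'   fixing condition labels), and `between` (the label that varies across
#'   compared groups).
#' @param config An [analysis_config()].
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(conditions, n_per_condition = 8,
                       amplitude = 30, n_cycles = 8, sample_rate = 1200,
                       wingbeat_amp = 2, wobble_amp = 0.5, noise_sd = 0.5,
                       base_seed = 1L, comparisons = list(),
                       config = analysis_config()) {
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  need <- c("treatment", "light", "frequency", "gain", "phase")
  if (!all(need %in% names(conditions)))
    stop("`conditions` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(conditions) == 0L || n_per_condition < 1L)
    stop("configuration describes zero trials", call. = FALSE)
  structure(
    list(conditions = conditions,
         n_per_condition = as.integer(n_per_condition),
         amplitude = amplitude, n_cycles = n_cycles,
         sample_rate = sample_rate,
         wingbeat_amp = wingbeat_amp, wobble_amp = wobble_amp,
         noise_sd = noise_sd, base_seed = as.integer(base_seed),
         comparisons = comparisons, config = config),
    class = "run_config"
  )
}

#' Write / read a run configuration as JSON
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `path` (write) or a [run_config()] (read).
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$config <- unclass(x$config)
  x$config$psd <- unclass(x$config$psd)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ac <- do.call(analysis_config, c(
    x$config[setdiff(names(x$config), "psd")],
    list(psd = do.call(psd_config, as.list(x$config$psd)))))
  comparisons <- x$comparisons
  if (is.data.frame(comparisons))
    comparisons <- lapply(seq_len(nrow(comparisons)),
                          function(i) as.list(comparisons[i, ]))
  run_config(conditions = x$conditions,
             n_per_condition = x$n_per_condition,
             amplitude = x$amplitude, n_cycles = x$n_cycles,
             sample_rate = x$sample_rate,
             wingbeat_amp = x$wingbeat_amp, wobble_amp = x$wobble_amp,
             noise_sd = x$noise_sd, base_seed = x$base_seed,
             comparisons = comparisons, config = ac)
}

trial_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) * 10007 + i) %% .Machine$integer.max)
}

#' Run the full simulate - analyze - compare pipeline
#'
#' Generates every trial described by the configuration, analyzes each one,
#' summarizes every condition cell, and runs the configured statistical
#' comparisons. With `out_dir` set, writes `trials/trial_<id>.csv`,
#' `metrics.csv`, `summaries.csv`, `stats.csv`, the resolved
#' `run_config.json`, and a machine-readable `run_log.json` (config hash,
#' versions, timings). Deterministic: the same configuration yields
#' byte-identical tables.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory.
#' @return List with `trials`, `metrics` (data frame), `summaries` (data
#'   frame), `stats` (data frame), and `metrics_objects`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  conds <- cfg$conditions
  trials <- list()
  metrics_obj <- list()
  rows <- list()
  idx <- 0L
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, ]
    spec <- stimulus_spec(frequency = cond$frequency,
                          amplitude = cfg$amplitude,
                          n_cycles = cfg$n_cycles,
                          sample_rate = cfg$sample_rate)
    stim <- generate_stimulus(spec)
    for (ai in seq_len(cfg$n_per_condition)) {
      idx <- idx + 1L
      animal <- sprintf("%s_f%g_a%02d", cond$treatment, cond$frequency, ai)
      trial_id <- sprintf("t%03d", idx)
      model <- response_model(gain = cond$gain, phase = cond$phase,
                              wingbeat_amp = cfg$wingbeat_amp,
                              wobble_amp = cfg$wobble_amp,
                              noise_sd = cfg$noise_sd,
                              seed = trial_seed(cfg$base_seed, idx))
      tr <- generate_response(stim, model, spec,
                              meta = list(trial_id = trial_id,
                                          animal_id = animal,
                                          treatment = cond$treatment,
                                          light = cond$light))
      m <- analyze_trial(tr, spec, cfg$config)
      trials[[trial_id]] <- tr
      metrics_obj[[trial_id]] <- m
      rows[[idx]] <- as.data.frame(m)
    }
  }
  metrics <- do.call(rbind, rows)
  summaries <- summarize_by_condition(metrics_obj)
  stats_tab <- run_comparisons(metrics, cfg$comparisons)
  out <- list(trials = trials, metrics = metrics, summaries = summaries,
              stats = stats_tab, metrics_objects = metrics_obj)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "trials"), recursive = TRUE,
               showWarnings = FALSE)
    for (id in names(trials))
      write_trial(trials[[id]], file.path(out_dir, "trials",
                                          paste0("trial_", id, ".csv")))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    cfg_path <- file.path(out_dir, "run_config.json")
    write_run_config(cfg, cfg_path)
    log <- list(
      config_hash = unname(tools::md5sum(cfg_path)),
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("gazestab")),
      n_trials = length(trials),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE)
  }
  out
}

summarize_by_condition <- function(metrics_obj) {
  key <- vapply(metrics_obj, function(m)
    paste(m$meta$treatment, m$meta$light, m$meta$frequency, sep = "|"),
    character(1))
  parts <- split(metrics_obj, key)
  rows <- lapply(parts, function(ms) {
    m1 <- ms[[1]]$meta
    as.data.frame(summarize_condition(
      unname(ms),
      labels = list(treatment = m1$treatment, light = m1$light,
                    frequency = m1$frequency)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$treatment, out$frequency, out$light), , drop = FALSE]
}

subset_metrics <- function(metrics, within) {
  if (!length(within)) return(metrics)
  for (nm in names(within))
    metrics <- metrics[metrics[[nm]] == within[[nm]], , drop = FALSE]
  metrics
}

run_comparisons <- function(metrics, comparisons) {
  rows <- lapply(comparisons, function(cmp) {
    metric <- cmp$metric %||% "epsilon"
    sub <- subset_metrics(metrics, cmp$within)
    lvls <- cmp$levels %||% unique(sub[[cmp$between]])
    groups <- lapply(lvls, function(l)
      sub[sub[[cmp$between]] == l, , drop = FALSE])
    label <- paste0(metric, ": ", paste(lvls, collapse = " vs "),
                    if (length(cmp$within))
                      paste0(" [", paste(names(cmp$within),
                                         unlist(cmp$within),
                                         sep = "=", collapse = ","), "]")
                    else "")
    if (cmp$type == "paired_signed_rank") {
      a <- groups[[1]][order(groups[[1]]$animal_id), ]
      b <- groups[[2]][order(groups[[2]]$animal_id), ]
      common <- intersect(a$animal_id, b$animal_id)
      res <- paired_signed_rank(a[[metric]][match(common, a$animal_id)],
                                b[[metric]][match(common, b$animal_id)])
      data.frame(comparison = label, test = "paired_signed_rank",
                 statistic = res$statistic, p = res$p.value,
                 n = res$n, stringsAsFactors = FALSE)
    } else if (cmp$type == "rank_sum") {
      res <- rank_sum(groups[[1]][[metric]], groups[[2]][[metric]])
      data.frame(comparison = label, test = "rank_sum",
                 statistic = res$statistic, p = res$p.value,
                 n = sum(res$n), stringsAsFactors = FALSE)
    } else if (cmp$type == "kruskal_nemenyi") {
      gl <- stats::setNames(lapply(groups, `[[`, metric), lvls)
      res <- kruskal_nemenyi(gl)
      omni <- data.frame(comparison = label, test = "kruskal_wallis",
                         statistic = res$H, p = res$p.value,
                         n = sum(lengths(gl)), stringsAsFactors = FALSE)
      prs <- utils::combn(length(lvls), 2, simplify = FALSE)
      post <- do.call(rbind, lapply(prs, function(ij) {
        data.frame(
          comparison = paste0(metric, ": ", lvls[ij[1]], " vs ", lvls[ij[2]],
                              " (Nemenyi)"),
          test = "nemenyi",
          statistic = NA_real_,
          p = res$pairwise[ij[1], ij[2]],
          n = length(gl[[ij[1]]]) + length(gl[[ij[2]]]),
          stringsAsFactors = FALSE)
      }))
      rbind(omni, post)
    } else stop("unknown comparison type: ", cmp$type, call. = FALSE)
  })
  if (!length(rows))
    return(data.frame(comparison = character(), test = character(),
                      statistic = numeric(), p = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Demonstration cohort configuration
#'
#' A compact 2 (light) x 2 (frequency) x 2 (treatment) design whose
#' generative parameters echo the qualitative regimes of the tethered-moth
#' assay: flagella-intact animals compensate well in twilight
#' (high gain, anti-phase), respond in the wrong direction in the dark at
#' 2 Hz (phase near 300 deg), and flagella-clipped animals barely respond in
#' the dark (gain ~0.1). Used by [make_fixtures()] and the CLI demo.
#'
#' @param n_per_condition Animals per condition cell.
#' @param base_seed Master seed.
#' @return A [run_config()].
#' @export
demo_config <- function(n_per_condition = 4, base_seed = 1L) {
  conditions <- expand.grid(
    treatment = c("intact", "clipped"),
    light = c("twilight", "dark"),
    frequency = c(2, 6),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pars <- list(
    "intact|twilight|2" = c(0.60, 177.6), "intact|dark|2" = c(0.40, 302.4),
    "intact|twilight|6" = c(0.30, 173.7), "intact|dark|6" = c(0.30, 214.2),
    "clipped|twilight|2" = c(0.55, 174.0), "clipped|dark|2" = c(0.10, 300.0),
    "clipped|twilight|6" = c(0.30, 127.8), "clipped|dark|6" = c(0.10, 200.0))
  key <- paste(conditions$treatment, conditions$light, conditions$frequency,
               sep = "|")
  conditions$gain <- vapply(key, function(k) pars[[k]][1], numeric(1))
  conditions$phase <- vapply(key, function(k) pars[[k]][2], numeric(1))
  comparisons <- list(
    list(type = "paired_signed_rank", metric = "epsilon",
         within = list(treatment = "intact", frequency = 2),
         between = "light", levels = c("twilight", "dark")),
    list(type = "rank_sum", metric = "epsilon",
         within = list(light = "dark", frequency = 2),
         between = "treatment", levels = c("intact", "clipped")),
    list(type = "kruskal_nemenyi", metric = "epsilon",
         within = list(light = "twilight", frequency = 6),
         between = "treatment", levels = c("intact", "clipped")))
  run_config(conditions, n_per_condition = n_per_condition,
             base_seed = base_seed, comparisons = comparisons)
}

#' Generate the packaged example dataset
#'
#' Runs [demo_config()] (<= 32 trials) and optionally writes the bundle to
#' `dir`. By construction the fixture reproduces the assay's qualitative
#' effect directions: clipped-dark median gain below intact-twilight, and
#' intact-twilight compensation error below intact-dark.
#'
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @param n_per_condition Animals per cell (default 4, i.e. 32 trials).
#' @return The [run_pipeline()] result bundle.
#' @export
make_fixtures <- function(seed = 1L, dir = NULL, n_per_condition = 4) {
  run_pipeline(demo_config(n_per_condition = n_per_condition,
                           base_seed = seed), out_dir = dir)
}

#' Validate an emitted table against the packaged schema
#'
#' Checks column names (and order) of a pipeline table against
#' `inst/extdata/table_schemas.json`.
#'
#' @param df The table.
#' @param table One of `"metrics"`, `"summaries"`, `"stats"`, `"trial"`.
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
validate_table_schema <- function(df, table) {
  path <- system.file("extdata", "table_schemas.json", package = "gazestab")
  schemas <- jsonlite::fromJSON(path)
  if (!table %in% names(schemas))
    stop("unknown table: ", table, call. = FALSE)
  want <- schemas[[table]]
  if (!identical(names(df), want))
    stop(sprintf("schema mismatch for '%s': got [%s], want [%s]", table,
                 paste(names(df), collapse = ", "),
                 paste(want, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
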