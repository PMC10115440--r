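# Orchestration: config loading/validation, the simulate/quantify/analyze
# stages, deterministic reporting, and the command-line entry point.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    generator = list(
      n_neurons = 2L, n_terminals_per_neuron = 50L,
      ca_e_conditions = c(2.0, 1.2, 0.8),
      modality = "physin-gcamp",
      perturbation = 0, traces_only = TRUE,
      resting_ca = 0.05, f_max_mean = 2000, f_max_cv = 0.2,
      baseline_frac = 0.06, resp_frac_ref = 0.30,
      influx = list(intercept_ca_e = 0.47, slope = 39.2, residual = 5.9),
      silencing = list(kd_sil = 25, coeff = 1.79, mode = "probabilistic"),
      noise = list(read_sd = 2, shot_scale = 0.01),
      geometry = list(width = 160, height = 160, psf_sigma = 1.5,
                      min_separation = 4, background = 20, offset = 100),
      protocol = NULL),
    quantification = list(
      detection = list(sigma_small = 1, sigma_large = 3, threshold = NULL,
                       min_separation = 4, radius = 3),
      max_bg_offset = 30,
      saturation_guard = 0.995),
    analysis = list(hill_fit = TRUE, linear_fit = TRUE))
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("load_config: unknown key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    else defaults[k] <- list(user[[k]])   # [<- keeps explicit NULLs
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON config, rejects unknown keys (naming each), fills defaults,
#' and validates the generator section by constructing its models.
#'
#' @param path JSON file; `NULL` yields the full default config.
#' @return a `pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else
    jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(default_pipeline_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$generator$protocol)) {
    unknown <- setdiff(names(cfg$generator$protocol), .protocol_user_fields)
    if (length(unknown))
      stop("load_config: unknown key(s): ",
           paste(paste0("generator.protocol.", unknown), collapse = ", "))
    # canonical field order so save/load round-trips are identical
    cfg$generator$protocol <- cfg$generator$protocol[
      intersect(.protocol_user_fields, names(cfg$generator$protocol))]
  }
  # fail early on invalid generator parameters
  invisible(build_generator_config(cfg))
  structure(cfg, class = "pipeline_config")
}

build_generator_config <- function(cfg, seed = NULL) {
  g <- cfg$generator
  protocol <- if (is.null(g$protocol)) stimulus_protocol(g$modality) else
    do.call(stimulus_protocol, g$protocol)
  generator_config(
    n_neurons = g$n_neurons,
    n_terminals_per_neuron = g$n_terminals_per_neuron,
    ca_e_conditions = g$ca_e_conditions,
    protocol = protocol,
    sensor = default_sensor(protocol$modality),
    influx = do.call(influx_model, g$influx),
    silencing = do.call(silencing_model, g$silencing),
    resting_ca = g$resting_ca, f_max_mean = g$f_max_mean,
    f_max_cv = g$f_max_cv, baseline_frac = g$baseline_frac,
    resp_frac_ref = g$resp_frac_ref,
    noise = g$noise, perturbation = g$perturbation,
    traces_only = g$traces_only, geometry = g$geometry,
    seed = if (is.null(seed)) cfg$seed else as.integer(seed))
}

# canonical JSON: recursively sorted keys, numbers at 9 significant digits
to_canonical_json <- function(x) {
  fmt_num <- function(v) {
    if (length(v) == 0) return("[]")
    s <- vapply(v, function(z) {
      if (is.na(z)) "null"
      else if (is.logical(z)) if (z) "true" else "false"
      else if (is.numeric(z)) {
        if (is.integer(z) || (is.finite(z) && z == round(z) &&
                              abs(z) < 1e15)) sprintf("%d", as.integer(z))
        else sprintf("%.9g", z)
      } else paste0("\"", gsub("\"", "\\\\\"", as.character(z)), "\"")
    }, "")
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ","), "]")
  }
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (is.null(names(x))) {
      return(paste0("[", paste(vapply(x, to_canonical_json, ""),
                               collapse = ","), "]"))
    }
    nm <- sort(names(x))
    parts <- vapply(nm, function(k)
      paste0("\"", k, "\":", to_canonical_json(x[[k]])), "")
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (length(x) > 1) return(fmt_num(x))
  fmt_num(x)
}

write_canonical_json <- function(x, path) {
  writeLines(to_canonical_json(x), path)
  invisible(path)
}

log_msg <- function(cfg, level, ...) {
  lvl <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (lvl[[level]] >= lvl[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, paste0(...)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

file_digest <- function(paths) {
  d <- tools::md5sum(paths)
  stats::setNames(unname(d), basename(paths))
}

# Run manifest: deterministic by design — no wall-clock timestamps, so a
# repeated stage is bit-identical end to end (see methods vignette).
write_run_manifest <- function(out_dir, stage, cfg_path, seed, inputs,
                               outputs) {
  manifest <- list(
    tool = "boutonsilence",
    version = as.character(utils::packageVersion("boutonsilence")),
    stage = stage,
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    inputs = as.list(file_digest(inputs)),
    outputs = as.list(file_digest(outputs)))
  write_canonical_json(manifest, file.path(out_dir,
                                           paste0("manifest_", stage, ".json")))
}

trace_file <- function(nid, key) sprintf("traces_%s_ca%s.csv", nid, key)
movie_file <- function(nid, key) sprintf("movie_%s_ca%s.tif", nid, key)

#' Run one pipeline stage
#'
#' `simulate` renders a synthetic dataset to `out_dir` (ground truth,
#' manifest, protocol, per-recording trace CSVs or 16-bit TIFF movies).
#' `quantify` turns recordings in `in_dir` into a per-terminal measurement
#' table (detecting ROIs and background-correcting when movies are the
#' input). `analyze` reduces a measurement table to summaries, fits and a
#' deterministic JSON report. Outputs are removed again if the stage fails
#' partway.
#'
#' @param stage `"simulate"`, `"quantify"` or `"analyze"`.
#' @param config a `pipeline_config` from [load_config()].
#' @param in_dir upstream artifact directory (quantify/analyze).
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return invisibly, a character vector of written files.
#' @export
run_stage <- function(stage = c("simulate", "quantify", "analyze"),
                      config, in_dir = NULL, out_dir,
                      seed = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }
  res <- tryCatch({
    cfg_path <- note(file.path(out_dir,
                               sprintf("resolved_config_%s.json", stage)))
    resolved <- config
    if (!is.null(seed)) resolved$seed <- as.integer(seed)
    write_canonical_json(unclass(resolved), cfg_path)
    switch(stage,
      simulate = stage_simulate(resolved, out_dir, cfg_path, note),
      quantify = stage_quantify(resolved, in_dir, out_dir, cfg_path, note),
      analyze = stage_analyze(resolved, in_dir, out_dir, cfg_path, note))
    written
  }, error = function(e) {
    unlink(written)
    stop("run_stage(", stage, ") failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

stage_simulate <- function(cfg, out_dir, cfg_path, note) {
  gen <- build_generator_config(cfg, seed = cfg$seed)
  ds <- generate_dataset(gen)
  data.table::fwrite(ds$ground_truth,
                     note(file.path(out_dir, "ground_truth.csv")))
  write_protocol(gen$protocol, note(file.path(out_dir, "protocol.json")))
  write_canonical_json(ds$manifest,
                       note(file.path(out_dir, "dataset_manifest.json")))
  for (nid in names(ds$recordings)) {
    for (key in names(ds$recordings[[nid]])) {
      rec <- ds$recordings[[nid]][[key]]
      if (gen$traces_only) {
        dt <- data.table::as.data.table(rec$noisy)
        data.table::fwrite(dt, note(file.path(out_dir,
                                              trace_file(nid, key))))
      } else {
        write_tiff(rec$movie, note(file.path(out_dir,
                                             movie_file(nid, key))))
      }
    }
  }
  write_run_manifest(out_dir, "simulate", cfg_path, cfg$seed,
                     character(0), written_files(out_dir))
  invisible(NULL)
}

written_files <- function(dir) {
  f <- list.files(dir, full.names = TRUE)
  f[!grepl("^manifest_", basename(f))]
}

read_dataset_layout <- function(in_dir) {
  man_path <- file.path(in_dir, "dataset_manifest.json")
  if (!file.exists(man_path))
    stop("expected upstream artifact not found: ", man_path)
  jsonlite::read_json(man_path, simplifyVector = TRUE)
}

stage_quantify <- function(cfg, in_dir, out_dir, cfg_path, note) {
  if (is.null(in_dir)) stop("quantify requires --in")
  layout <- read_dataset_layout(in_dir)
  proto_path <- file.path(in_dir, "protocol.json")
  if (!file.exists(proto_path))
    stop("expected upstream artifact not found: ", proto_path)
  protocol <- read_protocol(proto_path)
  sensor <- default_sensor(protocol$modality)
  q <- cfg$quantification
  neuron_ids <- sprintf("neuron%02d", seq_len(layout$n_neurons))
  keys <- vapply(layout$ca_e_conditions, condition_key, "")
  rows <- list(); logs <- list()
  for (nid in neuron_ids) {
    for (i in seq_along(keys)) {
      key <- keys[i]
      if (isTRUE(layout$traces_only)) {
        path <- file.path(in_dir, trace_file(nid, key))
        if (!file.exists(path))
          stop("expected upstream artifact not found: ", path)
        traces <- as.matrix(data.table::fread(path))
      } else {
        path <- file.path(in_dir, movie_file(nid, key))
        if (!file.exists(path))
          stop("expected upstream artifact not found: ", path)
        stack <- read_tiff(path)
        qr <- quantify_stack(stack, protocol,
                             detection = q$detection,
                             max_bg_offset = q$max_bg_offset)
        traces <- qr$traces
        write_roi_table(qr$rois,
                        note(file.path(out_dir,
                                       sprintf("rois_%s_ca%s.csv", nid, key))))
        if (length(qr$excluded))
          logs[[length(logs) + 1]] <- list(
            neuron_id = nid, condition = key,
            reason = "no_background_position", ids = qr$excluded)
      }
      rows[[paste(nid, key)]] <- measure_recording(
        traces, protocol, sensor, neuron_id = nid,
        condition = layout$ca_e_conditions[i],
        saturation_guard = q$saturation_guard)
    }
  }
  meas <- data.table::rbindlist(rows)
  for (flag in c("saturated", "subfloor")) {
    n_flag <- sum(meas[[flag]])
    if (n_flag) logs[[length(logs) + 1]] <-
      list(reason = flag, n_terminals = n_flag)
  }
  data.table::fwrite(meas, note(file.path(out_dir, "measurements.csv")))
  write_canonical_json(list(exclusions = logs),
                       note(file.path(out_dir, "quantify_log.json")))
  write_run_manifest(out_dir, "quantify", cfg_path, cfg$seed,
                     c(file.path(in_dir, "dataset_manifest.json"),
                       proto_path),
                     file.path(out_dir, "measurements.csv"))
  invisible(NULL)
}

#' Quantify a movie: detect ROIs, pair backgrounds, extract corrected traces
#'
#' @param stack a `frame_stack`.
#' @param protocol a [stimulus_protocol()].
#' @param detection list of [detect_puncta()] parameters.
#' @param max_bg_offset see [place_background_rois()].
#' @return list with `traces` (frames x terminals, corrected), `rois`,
#'   `excluded`.
#' @export
quantify_stack <- function(stack, protocol,
                           detection = list(sigma_small = 1, sigma_large = 3,
                                            threshold = NULL,
                                            min_separation = 4, radius = 3),
                           max_bg_offset = 30) {
  ref <- apply(stack[, , seq_len(protocol$baseline_frames), drop = FALSE],
               c(1, 2), mean)
  rois <- do.call(detect_puncta, c(list(image = ref), detection))
  placed <- place_background_rois(rois, dim(ref), max_bg_offset)
  term <- Filter(function(r) r$kind == "terminal", placed$rois)
  bg <- Filter(function(r) r$kind == "background", placed$rois)
  bg_ids <- vapply(bg, `[[`, "", "roi_id")
  n <- length(term)
  traces <- matrix(0, dim(stack)[3], n)
  for (i in seq_len(n)) {
    tt <- extract_trace(stack, term[[i]], protocol$frame_rate)
    bt <- extract_trace(stack, bg[[match(term[[i]]$partner, bg_ids)]],
                        protocol$frame_rate)
    traces[, i] <- background_correct(tt, bt)$values
  }
  colnames(traces) <- vapply(term, `[[`, "", "roi_id")
  list(traces = traces, rois = placed$rois, excluded = placed$excluded)
}

stage_analyze <- function(cfg, in_dir, out_dir, cfg_path, note) {
  if (is.null(in_dir)) stop("analyze requires --in")
  meas_path <- file.path(in_dir, "measurements.csv")
  if (!file.exists(meas_path))
    stop("expected upstream artifact not found: ", meas_path)
  meas <- data.table::fread(meas_path)
  if (nrow(meas) == 0) stop("analyze: empty measurement table")
  summ <- summarize_condition(meas)
  data.table::fwrite(summ$per_neuron,
                     note(file.path(out_dir, "summary_per_neuron.csv")))
  data.table::fwrite(summ$per_condition,
                     note(file.path(out_dir, "summary_per_condition.csv")))
  ecdf_dt <- ecdf_by_class(meas)
  data.table::fwrite(ecdf_dt, note(file.path(out_dir, "ecdf_by_class.csv")))
  gt_path <- file.path(in_dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) data.table::fread(gt_path) else NULL
  report <- build_report(summ, meas, cfg, ground_truth = gt)
  write_canonical_json(report, note(file.path(out_dir, "report.json")))
  write_run_manifest(out_dir, "analyze", cfg_path, cfg$seed, meas_path,
                     file.path(out_dir,
                               c("summary_per_neuron.csv",
                                 "summary_per_condition.csv",
                                 "report.json")))
  invisible(NULL)
}

#' Assemble the analysis report
#'
#' Per-condition silent fractions and responder means, pairwise silencing
#' slopes, the linear influx fit with x-intercept, the constrained Hill fit
#' (conventional negative exponent in `coeff_report`), and — when ground
#' truth is available — silent-fraction recovery errors per condition.
#' Sections that are not requested are explicitly `null`.
#'
#' @param summ result of [summarize_condition()].
#' @param measurements the measurement table.
#' @param cfg a `pipeline_config`.
#' @param ground_truth optional ground-truth table from the generator.
#' @return nested list (serialized with [write_canonical_json] by the
#'   analyze stage).
#' @export
build_report <- function(summ, measurements, cfg, ground_truth = NULL) {
  pc <- summ$per_condition
  conditions <- sort(pc$condition_mM, decreasing = TRUE)
  slopes <- NULL
  if (length(conditions) >= 2) {
    slopes <- lapply(seq_len(length(conditions) - 1), function(i) {
      hi <- conditions[i]; lo <- conditions[i + 1]
      list(ca_high = hi, ca_low = lo,
           slope_pct_per_mM = silencing_slope(
             100 * pc[condition_mM == lo]$silent_fraction_mean,
             100 * pc[condition_mM == hi]$silent_fraction_mean,
             lo, hi))
    })
  }
  linear <- NULL
  if (isTRUE(cfg$analysis$linear_fit) && length(conditions) >= 2) {
    pn <- summ$per_neuron[is.finite(responder_mean_delta_ca)]
    if (nrow(pn) >= 2 && length(unique(pn$condition_mM)) >= 2) {
      lf <- fit_linear_intercept(pn$condition_mM, pn$responder_mean_delta_ca)
      linear <- unclass(lf)
    }
  }
  hill <- NULL
  if (isTRUE(cfg$analysis$hill_fit)) {
    pn <- summ$per_neuron[is.finite(responder_mean_delta_ca)]
    if (nrow(pn) >= 3) {
      hf <- tryCatch(
        fit_hill_silencing(pn$responder_mean_delta_ca,
                           100 * pn$silent_fraction),
        error = function(e) NULL)
      if (!is.null(hf)) hill <- unclass(hf)
    }
  }
  recovery <- NULL
  if (!is.null(ground_truth)) {
    gt <- data.table::as.data.table(ground_truth)
    gt_frac <- gt[, list(silent_fraction_true = mean(silent_true)),
                  by = "condition_mM"]
    merged <- merge(pc[, c("condition_mM", "silent_fraction_mean")],
                    gt_frac, by = "condition_mM")
    recovery <- lapply(seq_len(nrow(merged)), function(i) list(
      condition_mM = merged$condition_mM[i],
      silent_fraction_measured = merged$silent_fraction_mean[i],
      silent_fraction_true = merged$silent_fraction_true[i],
      error = merged$silent_fraction_mean[i] -
        merged$silent_fraction_true[i]))
  }
  list(
    per_condition = lapply(seq_len(nrow(pc)), function(i) as.list(pc[i])),
    silencing_slopes = slopes,
    linear_fit = linear,
    hill_fit = hill,
    ground_truth_recovery = recovery,
    n_terminals = nrow(measurements),
    seed = cfg$seed)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config C --out DIR`,
#' `quantify --in DIR --config C --out DIR`,
#' `analyze --in DIR --config C --out DIR`, `all --config C --out DIR`.
#' `--seed` overrides the config seed; `--traces-only` forces the
#' trace-only fast path. Returns 0 on success, 1 on failure.
#'
#' @param args character vector of CLI arguments.
#' @return integer exit status.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: boutonsilence <simulate|quantify|analyze|all>",
                 "[--config C] [--in DIR] --out DIR [--seed S]",
                 "[--traces-only]")
  if (length(args) < 1) { message(usage); return(1L) }
  cmd <- args[1]
  opts <- list(config = NULL, `in` = NULL, out = NULL, seed = NULL,
               traces_only = FALSE)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--traces-only") { opts$traces_only <- TRUE; i <- i + 1; next }
    if (!a %in% c("--config", "--in", "--out", "--seed")) {
      message("unknown option: ", a, "\n", usage); return(1L)
    }
    if (i == length(args)) { message("missing value for ", a); return(1L) }
    opts[[sub("^--", "", a)]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    cfg <- load_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (opts$traces_only) cfg$generator$traces_only <- TRUE
    if (is.null(opts$out)) stop("--out is required")
    if (cmd == "all") {
      sim_dir <- file.path(opts$out, "simulate")
      q_dir <- file.path(opts$out, "quantify")
      a_dir <- file.path(opts$out, "analyze")
      run_stage("simulate", cfg, out_dir = sim_dir)
      run_stage("quantify", cfg, in_dir = sim_dir, out_dir = q_dir)
      file.copy(file.path(sim_dir, "ground_truth.csv"), q_dir,
                overwrite = TRUE)
      run_stage("analyze", cfg, in_dir = q_dir, out_dir = a_dir)
    } else if (cmd %in% c("simulate", "quantify", "analyze")) {
      run_stage(cmd, cfg, in_dir = opts$`in`, out_dir = opts$out)
    } else {
      stop("unknown subcommand: ", cmd)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
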