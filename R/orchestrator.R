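#' Declare a pipeline stage
#'
#' A stage binds a computation to the external files it reads, the stages it
#' consumes outputs from, the configuration keys it depends on and a manually
#' bumped code version tag. Its fingerprint is a hash of exactly those four
#' things (content hashes of the input files, the upstream stages'
#' fingerprints, the parameter values and the version tag) — so staleness is
#' decided by content, not modification times, and changing an undeclared
#' file never triggers execution.
#'
#' @param name Stage identifier.
#' @param run A function of no arguments that executes the stage (reads its
#'   inputs, writes its outputs).
#' @param upstream Character vector of stage names this stage consumes.
#' @param input_files External files (paths) whose content the stage reads.
#' @param params Named list of parameter values the stage depends on.
#' @param outputs Files the stage writes; a stage with a missing output is
#'   re-executed even when its fingerprint is unchanged.
#' @param code_version Manually bumped version tag of the stage's code.
#' @return A `pipeline_stage` object.
#' @export
pipeline_stage <- function(name, run, upstream = character(),
                           input_files = character(), params = list(),
                           outputs = character(), code_version = "1") {
  stopifnot(is.function(run))
  structure(list(name = name, run = run, upstream = upstream,
                 input_files = input_files, params = params,
                 outputs = outputs, code_version = code_version),
            class = "pipeline_stage")
}

#' Topological execution order of a stage set
#'
#' Deterministic Kahn ordering: among stages whose upstreams are all placed,
#' the lexicographically smallest name goes first. A dependency cycle is an
#' error naming the stages involved.
#'
#' @param stages List of [pipeline_stage()] objects.
#' @return Character vector of stage names in execution order.
#' @export
plan_stages <- function(stages) {
  names(stages) <- vapply(stages, function(s) s$name, character(1))
  for (s in stages) {
    bad <- setdiff(s$upstream, names(stages))
    if (length(bad)) {
      wb_abort("reference", sprintf("stage '%s' names unknown upstream stage(s): %s",
                                    s$name, paste(bad, collapse = ", ")))
    }
  }
  remaining <- names(stages)
  placed <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      all(stages[[nm]]$upstream %in% placed)
    }, logical(1))]
    if (!length(ready)) {
      wb_abort("cycle", sprintf("dependency cycle among stage(s): %s",
                                paste(sort(remaining), collapse = ", ")))
    }
    nxt <- sort(ready)[1]
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  placed
}

stage_fingerprint <- function(stage, upstream_digests) {
  file_digests <- vapply(stage$input_files, hash_file, character(1))
  hash_object(list(files = unname(file_digests),
                   upstream = unname(upstream_digests[stage$upstream]),
                   params = stage$params,
                   code = stage$code_version))
}

read_manifest <- function(path) {
  if (!file.exists(path)) return(list())
  jsonlite::read_json(path, simplifyVector = TRUE)
}

write_manifest <- function(manifest, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE)
  file.rename(tmp, path)
}

stage_descendants <- function(stages, from) {
  names(stages) <- vapply(stages, function(s) s$name, character(1))
  desc <- character()
  frontier <- from
  while (length(frontier)) {
    nxt <- names(stages)[vapply(stages, function(s) {
      any(s$upstream %in% frontier)
    }, logical(1))]
    nxt <- setdiff(nxt, c(desc, from))
    desc <- c(desc, nxt)
    frontier <- nxt
  }
  desc
}

#' Run stages incrementally
#'
#' Executes stages in topological order. A stage runs iff it is forced, its
#' fingerprint differs from the cached one (which covers any upstream whose
#' own fingerprint changed, since fingerprints chain), or one of its outputs
#' is missing; otherwise it is skipped and its cached outputs stand. The
#' cache manifest is rewritten atomically after each success. On a stage
#' failure the run halts: the failing stage's cache entry is left untouched
#' and its downstream stages are reported `blocked`.
#'
#' @param stages List of [pipeline_stage()] objects.
#' @param cache_path Path of the JSON fingerprint manifest.
#' @param force Run every stage regardless of fingerprints.
#' @param dry_run Compute statuses only (`would_execute` / `would_skip`);
#'   nothing is executed and the cache is untouched.
#' @return A tibble `stage`, `status`, `seconds` in execution order. Statuses:
#'   `executed`, `skipped`, `failed`, `blocked`, `not_run`, and the dry-run
#'   pair. An attribute `"digests"` carries the computed fingerprints.
#' @export
run_stages <- function(stages, cache_path, force = FALSE, dry_run = FALSE) {
  names(stages) <- vapply(stages, function(s) s$name, character(1))
  order <- plan_stages(stages)
  manifest <- read_manifest(cache_path)
  digests <- character(0)
  status <- setNames(rep("not_run", length(order)), order)
  secs <- setNames(rep(NA_real_, length(order)), order)

  lock <- paste0(cache_path, ".lock")
  if (!dry_run) {
    if (file.exists(lock)) {
      wb_warn("lock", sprintf("advisory lock file '%s' already exists; continuing", lock))
    }
    file.create(lock)
    on.exit(unlink(lock), add = TRUE)
  }

  for (nm in order) {
    st <- stages[[nm]]
    digest <- stage_fingerprint(st, digests)
    digests[nm] <- digest
    cached <- manifest[[nm]]
    stale <- force || is.null(cached) || !identical(unname(cached), unname(digest)) ||
      (length(st$outputs) && !all(file.exists(st$outputs)))
    if (dry_run) {
      status[nm] <- if (stale) "would_execute" else "would_skip"
      next
    }
    if (!stale) {
      status[nm] <- "skipped"
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      st$run()
      TRUE
    }, error = function(e) e)
    secs[nm] <- proc.time()[["elapsed"]] - t0
    if (isTRUE(res)) {
      status[nm] <- "executed"
      manifest[[nm]] <- digest
      write_manifest(manifest, cache_path)
    } else {
      status[nm] <- "failed"
      blocked <- stage_descendants(stages, nm)
      status[names(status) %in% blocked] <- "blocked"
      wb_warn("stage_failure", sprintf("stage '%s' failed: %s", nm,
                                       conditionMessage(res)))
      break
    }
  }
  out <- tibble(stage = order, status = unname(status[order]),
                seconds = unname(secs[order]))
  attr(out, "digests") <- digests
  out
}

# strict readers for intermediate stage CSVs
read_stage_csv <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

balance_cols <- function() {
  readr::cols(plot_id = readr::col_character(), date = readr::col_date(),
              reset = readr::col_logical(),
              supersaturated = readr::col_logical(),
              .default = readr::col_double())
}

#' Default stage set for the trial pipeline
#'
#' Binds the module functions into six file-based stages — canopy, storage,
#' field capacity, balance, events, export — reading the five input CSVs and
#' writing intermediate and final CSVs under `out_dir`. Each stage declares
#' only the files and configuration keys it actually consumes, so e.g. an
#' edit to the irrigation table re-runs balance, events and export but leaves
#' canopy, storage and field capacity untouched.
#'
#' @param paths Named list of the five input CSV paths (as for
#'   [read_input_tables()]).
#' @param config A [trial_config()].
#' @param out_dir Output directory (created if needed).
#' @param calibration Optional instrument calibration table, or a CSV path
#'   with columns `instrument`, `gain`, `offset`.
#' @return A named list of [pipeline_stage()] objects.
#' @export
default_stages <- function(paths, config, out_dir, calibration = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  calib_files <- character()
  if (is.character(calibration)) {
    calib_files <- calibration
    calibration_tbl <- function() {
      read_stage_csv(calibration, readr::cols(instrument = readr::col_character(),
                                              gain = readr::col_double(),
                                              offset = readr::col_double()))
    }
  } else {
    calib <- calibration
    calibration_tbl <- function() calib
  }

  canopy_run <- function() {
    obs <- standardise_ndvi(read_canopy_obs(paths$canopy), calibration_tbl())
    cal <- read_crop_calendar(paths$calendar)
    daily <- interpolate_daily_cover(obs, cal, config)
    readr::write_csv(daily, out("canopy_daily.csv"), progress = FALSE)
  }
  storage_run <- function() {
    st <- profile_storage(read_probe_readings(paths$probe), config)
    readr::write_csv(st, out("storage.csv"), progress = FALSE)
  }
  fc_run <- function() {
    st <- read_stage_csv(out("storage.csv"),
                         readr::cols(plot_id = readr::col_character(),
                                     date = readr::col_date(),
                                     storage_mm = readr::col_double()))
    cal <- read_crop_calendar(paths$calendar)
    fal <- fallow_intervals(cal, st$date, config)
    fc <- estimate_field_capacity(st, config, fallow = fal)
    readr::write_csv(fc, out("field_capacity.csv"), progress = FALSE)
  }
  balance_run <- function() {
    weather <- read_weather(paths$weather)
    irrigation <- read_irrigation(paths$irrigation)
    daily <- read_stage_csv(out("canopy_daily.csv"),
                            readr::cols(plot_id = readr::col_character(),
                                        date = readr::col_date(),
                                        cover = readr::col_double()))
    st <- read_stage_csv(out("storage.csv"),
                         readr::cols(plot_id = readr::col_character(),
                                     date = readr::col_date(),
                                     storage_mm = readr::col_double()))
    fc <- read_stage_csv(out("field_capacity.csv"),
                         readr::cols(plot_id = readr::col_character(),
                                     fc_mm = readr::col_double(),
                                     n_obs = readr::col_double()))
    traj <- bind_rows(lapply(fc$plot_id, function(p) {
      f <- assemble_forcings(p, weather, irrigation, daily, st)
      run_balance(trim_to_first_observation(f), fc$fc_mm[fc$plot_id == p], config)
    }))
    readr::write_csv(traj, out("balance.csv"), progress = FALSE)
  }
  events_run <- function() {
    traj <- read_stage_csv(out("balance.csv"), balance_cols())
    ev <- detect_events(traj, config)
    readr::write_csv(ev, out("events.csv"), progress = FALSE)
  }
  export_run <- function() {
    traj <- read_stage_csv(out("balance.csv"), balance_cols())
    daily <- read_stage_csv(out("canopy_daily.csv"),
                            readr::cols(plot_id = readr::col_character(),
                                        date = readr::col_date(),
                                        cover = readr::col_double()))
    export_long_table(traj, daily, out("results_long.csv"))
  }

  cfg_keys <- function(...) config[c(...)]
  list(
    canopy = pipeline_stage("canopy", canopy_run,
      input_files = c(paths$canopy, paths$calendar, calib_files),
      params = cfg_keys("ndvi_bare", "ndvi_closure", "fallow_months"),
      outputs = out("canopy_daily.csv")),
    storage = pipeline_stage("storage", storage_run,
      input_files = paths$probe,
      params = cfg_keys("profile_depth_cm"),
      outputs = out("storage.csv")),
    fc = pipeline_stage("fc", fc_run, upstream = "storage",
      input_files = paths$calendar,
      params = cfg_keys("fc_rule", "fc_quantile", "fallow_months"),
      outputs = out("field_capacity.csv")),
    balance = pipeline_stage("balance", balance_run,
      upstream = c("canopy", "fc", "storage"),
      input_files = c(paths$weather, paths$irrigation),
      params = cfg_keys("stress_model", "taw_mm", "raw_mm"),
      outputs = out("balance.csv")),
    events = pipeline_stage("events", events_run, upstream = "balance",
      params = cfg_keys("event_min_mm", "event_merge_gap_days"),
      outputs = out("events.csv")),
    export = pipeline_stage("export", export_run,
      upstream = c("balance", "canopy", "events"),
      outputs = out("results_long.csv")))
}

#' Trim forcings to start at the first storage observation
#'
#' @param forcings A forcings tibble with `observed_storage_mm`.
#' @return The forcings from the first observed day onward.
#' @export
trim_to_first_observation <- function(forcings) {
  has_obs <- !is.na(forcings$observed_storage_mm)
  if (!any(has_obs)) {
    wb_abort("initialization",
             "no storage observation available to anchor the initial deficit")
  }
  forcings[forcings$date >= forcings$date[which(has_obs)[1]], , drop = FALSE]
}
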