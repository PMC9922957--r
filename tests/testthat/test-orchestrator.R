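# small artificial stage sets, with an execution counter per stage
counting_stages <- function(dir, extra_param = list()) {
  counts <- new.env()
  touch <- function(nm, inputs = character()) {
    force(nm); force(inputs)
    function() {
      counts[[nm]] <- (counts[[nm]] %||% 0L) + 1L
      content <- if (length(inputs)) {
        paste(vapply(inputs, function(f) paste(readLines(f), collapse = ";"),
                     character(1)), collapse = "|")
      } else "root"
      writeLines(paste(nm, content), file.path(dir, paste0(nm, ".out")))
    }
  }
  a_in <- file.path(dir, "a_input.txt")
  if (!file.exists(a_in)) writeLines("v1", a_in)
  stages <- list(
    A = pipeline_stage("A", touch("A", a_in), input_files = a_in,
                       outputs = file.path(dir, "A.out")),
    B = pipeline_stage("B", touch("B", file.path(dir, "A.out")),
                       upstream = "A", outputs = file.path(dir, "B.out")),
    C = pipeline_stage("C", touch("C", file.path(dir, "A.out")),
                       upstream = "A", params = extra_param,
                       outputs = file.path(dir, "C.out")),
    D = pipeline_stage("D", touch("D", file.path(dir, c("B.out", "C.out"))),
                       upstream = c("B", "C"), outputs = file.path(dir, "D.out")))
  list(stages = stages, counts = counts, a_in = a_in)
}

executed <- function(report) report$stage[report$status == "executed"]

test_that("planning orders stages topologically with name tie-breaks", {
  mk <- function(nm, up) pipeline_stage(nm, function() NULL, upstream = up)
  chain <- list(mk("A", character()), mk("B", "A"), mk("C", "B"))
  expect_equal(plan_stages(chain), c("A", "B", "C"))

  diamond <- list(mk("D", c("B", "C")), mk("C", "A"), mk("B", "A"),
                  mk("A", character()))
  expect_equal(plan_stages(diamond), c("A", "B", "C", "D"))

  cyc <- list(mk("A", "B"), mk("B", "A"))
  err <- expect_error(plan_stages(cyc), class = "soilwb_error_cycle")
  expect_match(conditionMessage(err), "A, B")

  expect_error(plan_stages(list(mk("A", "ghost"))),
               class = "soilwb_error_reference")
})

test_that("an unchanged rerun is a fixpoint executing zero stages", {
  dir <- withr::local_tempdir()
  cs <- counting_stages(dir)
  cache <- file.path(dir, "cache.json")
  r1 <- run_stages(cs$stages, cache)
  expect_equal(executed(r1), c("A", "B", "C", "D"))
  r2 <- run_stages(cs$stages, cache)
  expect_equal(sum(r2$status == "executed"), 0)
  expect_equal(cs$counts$A, 1L)
  # dry run reports without executing
  r3 <- run_stages(cs$stages, cache, dry_run = TRUE)
  expect_true(all(r3$status == "would_skip"))
  expect_equal(cs$counts$A, 1L)
  # force re-runs everything
  r4 <- run_stages(cs$stages, cache, force = TRUE)
  expect_equal(length(executed(r4)), 4)
})

test_that("execution propagates from a changed input through the DAG only", {
  dir <- withr::local_tempdir()
  cs <- counting_stages(dir)
  cache <- file.path(dir, "cache.json")
  run_stages(cs$stages, cache)

  writeLines("v2", cs$a_in)
  r <- run_stages(cs$stages, cache)
  expect_equal(executed(r), c("A", "B", "C", "D"))

  # changing an undeclared file never triggers execution
  writeLines("noise", file.path(dir, "undeclared.txt"))
  r <- run_stages(cs$stages, cache)
  expect_equal(sum(r$status == "executed"), 0)

  # a changed parameter re-runs only the stage scoped to it and its children
  cs2 <- counting_stages(dir, extra_param = list(threshold = 2))
  r <- run_stages(cs2$stages, cache)
  expect_equal(executed(r), c("C", "D"))

  # a deleted output forces that stage (and, through fingerprints, nothing
  # upstream)
  unlink(file.path(dir, "B.out"))
  r <- run_stages(cs2$stages, cache)
  expect_true("B" %in% executed(r))
  expect_false("A" %in% executed(r))
})

test_that("a failing stage halts the run and blocks its descendants", {
  dir <- withr::local_tempdir()
  boom <- pipeline_stage("B", function() stop("exploded"), upstream = "A")
  ok <- pipeline_stage("A", function() NULL)
  down <- pipeline_stage("C", function() NULL, upstream = "B")
  side <- pipeline_stage("Z", function() NULL)  # independent of B
  cache <- file.path(dir, "cache.json")
  expect_warning(r <- run_stages(list(ok, boom, down, side), cache),
                 class = "soilwb_warning_stage_failure")
  expect_equal(r$status[r$stage == "A"], "executed")
  expect_equal(r$status[r$stage == "B"], "failed")
  expect_equal(r$status[r$stage == "C"], "blocked")
  # the failed stage's fingerprint is not cached: a rerun retries it
  expect_warning(r2 <- run_stages(list(ok, boom, down, side), cache),
                 class = "soilwb_warning_stage_failure")
  expect_equal(r2$status[r2$stage == "B"], "failed")
})

test_that("the default pipeline stages wire the trial CSVs end to end", {
  dir <- withr::local_tempdir()
  tr <- generate_trial(n_plots = 1, seed = 21, end = "2021-06-30")
  paths <- as.list(write_trial_csvs(tr$bundle, file.path(dir, "in")))
  stages <- default_stages(paths, tr$bundle$config, file.path(dir, "out"),
                           calibration = tr$bundle$calibration)
  cache <- file.path(dir, "cache.json")
  r1 <- run_stages(stages, cache)
  expect_true(all(r1$status == "executed"))
  long <- read_long_table(file.path(dir, "out", "results_long.csv"))
  expect_setequal(unique(long$variable),
                  c("smd_mm", "aet_mm", "drainage_mm", "cover"))

  # file-based results agree with the in-memory pipeline
  mem <- run_trial_pipeline(tr$bundle)
  bal <- readr::read_csv(file.path(dir, "out", "balance.csv"),
                         col_types = soilwb:::balance_cols())
  expect_equal(bal$smd_mm, mem$trajectories$smd_mm, tolerance = 1e-9)

  # editing only the irrigation table leaves canopy/storage/fc untouched
  ir <- readr::read_csv(paths$irrigation, show_col_types = FALSE)
  ir$amount_mm[1] <- ir$amount_mm[1] + 2
  readr::write_csv(ir, paths$irrigation)
  r2 <- run_stages(stages, cache)
  expect_equal(executed(r2), c("balance", "events", "export"))
})
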