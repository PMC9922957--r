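#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows distinct filter group_by left_join
#'   mutate n select summarise ungroup across all_of
#' @importFrom rlang .data
#' @importFrom stats quantile rbinom rgamma rnorm runif setNames
NULL

# clamp to [lo, hi], vectorised
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# typed condition helper: all package errors carry class soilwb_error_<type>
wb_abort <- function(type, message, ...) {
  abort(message, class = c(paste0("soilwb_error_", type), "soilwb_error"), ...)
}

wb_warn <- function(type, message) {
  warn(message, class = c(paste0("soilwb_warning_", type), "soilwb_warning"))
}

# md5 of a file's content
hash_file <- function(path) {
  if (!file.exists(path)) wb_abort("io", sprintf("file not found: '%s'", path))
  unname(tools::md5sum(path))
}

# md5 of an arbitrary R object via its (version-2) serialisation
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeBin(serialize(x, connection = NULL, version = 2), f)
  unname(tools::md5sum(f))
}

as_wb_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  if (is.character(x)) {
    out <- as.Date(x, format = "%Y-%m-%d")
    if (anyNA(out)) {
      wb_abort("schema", sprintf(
        "%s contains dates not in ISO-8601 (YYYY-MM-DD) format: %s",
        what, paste(unique(x[is.na(out)]), collapse = ", ")))
    }
    return(out)
  }
  wb_abort("schema", sprintf("%s must be Date or ISO-8601 character", what))
}

# check daily contiguity; returns missing dates (Date vector, possibly empty)
missing_days <- function(dates) {
  full <- seq(min(dates), max(dates), by = "day")
  full[!full %in% dates]
}

month_of <- function(dates) as.integer(format(dates, "%m"))

# southern-hemisphere meteorological seasons
season_of <- function(dates) {
  m <- month_of(dates)
  out <- character(length(m))
  out[m %in% c(12L, 1L, 2L)] <- "summer"
  out[m %in% 3:5] <- "autumn"
  out[m %in% 6:8] <- "winter"
  out[m %in% 9:11] <- "spring"
  out
}
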