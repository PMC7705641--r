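# Delimited-text waveform I/O.
#
# The on-disk format is a CSV/TSV with a header row naming a `time` column
# (seconds) plus `pressure` and optionally `flow` or `velocity`. Units and,
# optionally, the sampling interval come from a JSON sidecar of the form
#   {"pressure_units": "mmHg", "flow_units": "mL/s", "dt": 0.001}
# Timestamps that are not uniform are linearly resampled onto a uniform
# grid before analysis, since all quadrature in the package assumes one.

#' Read a pressure (and optional flow) waveform from delimited text
#'
#' @param path Path to a CSV or TSV file with columns `time`, `pressure`,
#'   and optionally `flow` (mL/s) or `velocity` (m/s).
#' @param sidecar Optional path to a JSON sidecar declaring units and `dt`;
#'   defaults to `<path>.json` when that file exists.
#' @param sep Field separator; guessed from the file extension when `NULL`.
#' @return A list with elements `pressure` (a [uniform_series()]) and `flow`
#'   (a [uniform_series()] or `NULL`).
#' @export
read_waveform <- function(path, sidecar = NULL, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"pressure" %in% names(df)) stop("no `pressure` column in ", path)

  meta <- list()
  if (is.null(sidecar)) {
    cand <- paste0(path, ".json")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  if ("time" %in% names(df)) {
    tt <- as.numeric(df$time)
    if (length(tt) < 2L) stop("need at least 2 samples")
    d <- diff(tt)
    if (any(d <= 0)) stop("time column must be strictly increasing")
    dt <- stats::median(d)
    uniform <- max(abs(d - dt)) < 1e-9 + 1e-6 * dt
  } else {
    if (is.null(meta$dt)) stop("no time column and no `dt` in sidecar")
    dt <- as.numeric(meta$dt)
    tt <- (seq_len(nrow(df)) - 1) * dt
    uniform <- TRUE
  }

  grab <- function(col, quantity) {
    v <- as.numeric(df[[col]])
    if (uniform) {
      uniform_series(v, dt = dt, t0 = tt[1], quantity = quantity)
    } else {
      tg <- seq(tt[1], tt[length(tt)], by = dt)
      uniform_series(stats::approx(tt, v, xout = tg)$y, dt = dt, t0 = tt[1],
                     quantity = quantity)
    }
  }
  pressure <- grab("pressure", "pressure")
  flow <- NULL
  if ("flow" %in% names(df)) {
    flow <- grab("flow", "flow_volumetric")
  } else if ("velocity" %in% names(df)) {
    flow <- grab("velocity", "flow_velocity")
  }
  fu <- if (!is.null(meta$flow_units)) meta$flow_units else NULL
  if (!is.null(flow) && !is.null(fu)) {
    flow$quantity <- if (identical(fu, "m/s")) "flow_velocity"
                     else "flow_volumetric"
  }
  list(pressure = pressure, flow = flow)
}

#' Write a waveform (and derived series) to CSV
#'
#' @param path Output CSV path.
#' @param pressure A pressure [uniform_series()].
#' @param ... Further named [uniform_series()] on the same grid (e.g.
#'   `flow`, `P_res`, `P_xs`), written as additional columns.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(path, pressure, ...) {
  stopifnot(inherits(pressure, "uniform_series"))
  extra <- list(...)
  df <- data.frame(time = series_time(pressure), pressure = pressure$values)
  for (nm in names(extra)) {
    s <- extra[[nm]]
    if (is.null(s)) next
    stopifnot(inherits(s, "uniform_series"),
              length(s$values) == nrow(df))
    df[[nm]] <- s$values
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
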