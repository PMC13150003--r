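# Plain-text formats: spectrometer-style intensity tables (TSV, '#'
# comments), dispersion CSVs, fit-report JSON. Every written artifact
# carries provenance comments (package version, seed, config hash).

.num_fmt <- function(x) sprintf("%.15g", x)

# tiny rolling hash for provenance stamping (no external digest dependency)
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.provenance <- function(seed = NULL, config = NULL) {
  c(sprintf("# generator: r1rhoRD %s",
            as.character(utils::packageVersion("r1rhoRD"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    if (!is.null(config)) sprintf("# config_hash: %s", .config_hash(config)))
}

#' Write an intensity table
#'
#' Tab-separated with a header line and '#' comment lines; columns
#' `power_hz`, `offset_hz`, `duration_s`, `intensity`, `sino`. Numbers are
#' written with 15 significant digits so a write/read round trip is lossless
#' to double precision.
#'
#' @param table `data.frame` with the five columns above.
#' @param path Output file.
#' @param seed,config Optional provenance (seed and the configuration list
#'   hashed into the header).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(table, path, seed = NULL, config = NULL) {
  cols <- c("power_hz", "offset_hz", "duration_s", "intensity", "sino")
  stopifnot(is.data.frame(table), all(cols %in% names(table)))
  lines <- c(.provenance(seed, config),
             paste(cols, collapse = "\t"),
             apply(table[cols], 1L, function(r)
               paste(.num_fmt(as.numeric(r)), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read an intensity table
#'
#' Parses the TSV dialect written by [write_intensity_table()] (and
#' compatible spectrometer exports): '#' lines are comments, the first
#' non-comment line is the header. Malformed rows and non-positive
#' signal-to-noise values are reported with their line number.
#'
#' @param path Input file.
#' @param column_map Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(power_hz = "w1", intensity = "I")`, to ingest alternative layouts.
#' @return `data.frame` of class `intensity_table`.
#' @export
read_intensity_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  body <- raw[keep]
  if (length(body) < 2L) stop("no data rows in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  cols <- c("power_hz", "offset_hz", "duration_s", "intensity", "sino")
  wanted <- cols
  if (!is.null(column_map)) {
    stopifnot(all(names(column_map) %in% cols))
    wanted[match(names(column_map), cols)] <- unname(column_map)
  }
  idx <- match(wanted, header)
  if (any(is.na(idx)))
    stop("missing column(s): ", paste(wanted[is.na(idx)], collapse = ", "))
  rows <- lapply(seq_along(body[-1]) + 1L, function(i) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(fields[idx]))
    if (length(fields) < max(idx) || any(is.na(vals)))
      stop(sprintf("malformed row at line %d of %s", lineno[i], path))
    if (vals[5] <= 0)
      stop(sprintf("non-positive sino at line %d of %s", lineno[i], path))
    vals
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- cols
  if (anyDuplicated(out[c("power_hz", "offset_hz", "duration_s")]))
    stop("duplicate (power, offset, duration) triples in ", path)
  class(out) <- c("intensity_table", "data.frame")
  out
}

#' Group an intensity table into decay curves
#'
#' @param table An intensity table (see [read_intensity_table()]).
#' @return Named list of [decay_curve()] objects, one per
#'   `(power_hz, offset_hz)` condition, names `"<power>|<offset>"`.
#' @export
as_decay_curves <- function(table) {
  stopifnot(is.data.frame(table))
  key <- paste(table$power_hz, table$offset_hz, sep = "|")
  lapply(split(table, factor(key, levels = unique(key))), function(g)
    decay_curve(g$duration_s, g$intensity, g$sino))
}

#' Write / read a dispersion dataset as CSV
#'
#' Columns `spin_label`, `power_hz`, `offset_hz`, `value`, `sd`,
#' `observable`, with '#' provenance comments.
#'
#' @param dataset A [dispersion_dataset()] (or plain `data.frame` with those
#'   columns for `write_dispersion_csv`).
#' @param path File path.
#' @param seed,config Optional provenance.
#' @return The path (write) or a list of [dispersion_dataset()] objects by
#'   spin label (read).
#' @export
write_dispersion_csv <- function(dataset, path, seed = NULL, config = NULL) {
  if (inherits(dataset, "dispersion_dataset")) {
    df <- data.frame(spin_label = attr(dataset, "spin_label"),
                     power_hz = dataset$power_hz,
                     offset_hz = dataset$offset_hz,
                     value = dataset$value, sd = dataset$sd,
                     observable = attr(dataset, "observable"))
  } else df <- dataset
  lines <- c(.provenance(seed, config),
             "spin_label,power_hz,offset_hz,value,sd,observable",
             paste(df$spin_label, .num_fmt(df$power_hz),
                   .num_fmt(df$offset_hz), .num_fmt(df$value),
                   .num_fmt(df$sd), df$observable, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dispersion_csv
#' @export
read_dispersion_csv <- function(path) {
  raw <- readLines(path)
  body <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  lapply(split(df, df$spin_label), function(g)
    dispersion_dataset(g$spin_label[1], g$power_hz, g$offset_hz, g$value,
                       g$sd, observable = g$observable[1]))
}

#' Serialise a fit result to JSON
#'
#' Writes parameter estimates, Monte-Carlo uncertainties, fit statistics and
#' provenance; [read_fit_summary()] recovers the summary used by
#' [compare_models()]-style ranking in the command-line pipeline.
#'
#' @param fit A [fit_model()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  payload <- list(
    topology = fit$model$topology,
    fixed = fit$model$fixed,
    estimates = as.list(fit$estimates),
    mc_sd = if (!is.null(fit$mc_sd)) as.list(fit$mc_sd),
    n_replicas = fit$n_replicas,
    chi2 = fit$chi2, red_chi2 = fit$red_chi2,
    n = fit$n, k = fit$k, aicc = fit$aicc, bic = fit$bic,
    residuals = fit$residuals,
    n_starts = fit$n_starts, seed = fit$seed,
    package_version = as.character(utils::packageVersion("r1rhoRD"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_summary <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
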