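# Trace, report and configuration I/O. Traces are CSV (columns time,
# mtu_force, tendon_strain[, activity]; strain stored in percent) or
# OpenSim-style storage text (whitespace-delimited, `endheader` sentinel,
# first column time). Reports are schema-versioned JSON plus an events CSV.

trace_columns <- c(time = "time", mtu_force = "mtu_force",
                   tendon_strain = "tendon_strain", activity = "activity")

match_trace_columns <- function(nms, column_map = NULL, path = "") {
  map <- trace_columns
  if (!is.null(column_map)) map[names(column_map)] <- unlist(column_map)
  idx <- match(tolower(map), tolower(nms))
  names(idx) <- names(map)
  if (is.na(idx[["time"]])) {
    stop(sprintf("%s: no `%s` column found (columns: %s)",
                 path, map[["time"]], paste(nms, collapse = ", ")),
         call. = FALSE)
  }
  if (is.na(idx[["mtu_force"]]) && is.na(idx[["tendon_strain"]])) {
    stop(sprintf("%s: need at least one of `%s`, `%s` columns",
                 path, map[["mtu_force"]], map[["tendon_strain"]]),
         call. = FALSE)
  }
  idx
}

#' Read an MTU trace from disk
#'
#' Supports plain CSV with a header and OpenSim-style storage text: an
#' arbitrary header block terminated by a line reading `endheader`
#' (optionally including `nRows=`/`nColumns=` lines, which are validated if
#' present), followed by a whitespace- or tab-delimited column-name line
#' and the data. Column names are matched case-insensitively;
#' `column_map` renames, e.g. `list(tendon_strain = "gastroc_strain")`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.sto`/`.mot` is storage,
#'   anything else CSV), `"csv"` or `"opensim_storage"`.
#' @param column_map optional named list mapping canonical names (`time`,
#'   `mtu_force`, `tendon_strain`, `activity`) to file column names.
#' @param muscle optional [muscle_param_set()] or label to attach.
#' @return an [mtu_trace()].
#' @export
read_trace <- function(path, format = c("auto", "csv", "opensim_storage"),
                       column_map = NULL, muscle = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("sto", "mot")) {
      "opensim_storage"
    } else "csv"
  }
  df <- if (format == "csv") {
    utils::read.csv(path, check.names = FALSE)
  } else {
    read_storage_table(path)
  }
  idx <- match_trace_columns(names(df), column_map, path)
  get_col <- function(nm) if (is.na(idx[[nm]])) NULL else as.numeric(df[[idx[[nm]]]])
  time <- get_col("time")
  if (any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop(sprintf("%s: time not strictly increasing at data row %d", path, bad),
         call. = FALSE)
  }
  mtu_trace(time = time, mtu_force = get_col("mtu_force"),
            tendon_strain = get_col("tendon_strain"),
            activity = get_col("activity"), muscle = muscle)
}

read_storage_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0L) {
    stop(sprintf("%s: no `endheader` line found; not a storage file", path),
         call. = FALSE)
  }
  end <- end[1L]
  header <- lines[seq_len(end - 1L)]
  meta <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\s*="), header, value = TRUE)
    if (length(hit) == 0L) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", hit[1L]))
  }
  n_rows <- meta("nRows")
  n_cols <- meta("nColumns")
  if (end + 1L > length(lines)) {
    stop(sprintf("%s: no column-name line after `endheader` (line %d)",
                 path, end), call. = FALSE)
  }
  col_names <- strsplit(trimws(lines[end + 1L]), "\\s+")[[1L]]
  body <- lines[seq(end + 2L, length(lines))]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    stop(sprintf("%s: no data rows after line %d", path, end + 1L),
         call. = FALSE)
  }
  rows <- lapply(seq_along(body), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1L]]))
    if (length(vals) != length(col_names) || anyNA(vals)) {
      stop(sprintf("%s: malformed data at line %d (expected %d numeric fields)",
                   path, end + 1L + i, length(col_names)), call. = FALSE)
    }
    vals
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- col_names
  if (!is.na(n_rows) && n_rows != nrow(df)) {
    stop(sprintf("%s: header declares nRows=%d but %d data rows found",
                 path, n_rows, nrow(df)), call. = FALSE)
  }
  if (!is.na(n_cols) && n_cols != ncol(df)) {
    stop(sprintf("%s: header declares nColumns=%d but %d columns found",
                 path, n_cols, ncol(df)), call. = FALSE)
  }
  df
}

#' Write an MTU trace to disk
#'
#' @param trace an [mtu_trace()].
#' @param path output file path.
#' @param format `"auto"`, `"csv"` or `"opensim_storage"` (see
#'   [read_trace()]).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path,
                        format = c("auto", "csv", "opensim_storage")) {
  stopifnot(inherits(trace, "mtu_trace"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("sto", "mot")) {
      "opensim_storage"
    } else "csv"
  }
  df <- data.frame(time = trace$time)
  if (!is.null(trace$mtu_force)) df$mtu_force <- trace$mtu_force
  if (!is.null(trace$tendon_strain)) df$tendon_strain <- trace$tendon_strain
  if (!is.null(trace$activity)) df$activity <- trace$activity
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste0(trace$label, " (tendon_strain in percent)"),
      "version=1",
      paste0("nRows=", nrow(df)),
      paste0("nColumns=", ncol(df)),
      "endheader",
      paste(names(df), collapse = "\t")
    ), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Write / read an injury report
#'
#' The JSON report is machine-readable and schema-versioned
#' (`schema_version`, `passes`, `n_traces`, `events`); it is byte-stable
#' for identical inputs. An optional events CSV holds one row per event,
#' ordered by muscle then crossing time.
#'
#' @param report an [injury_report][audit_model].
#' @param path JSON output path.
#' @param csv_path optional events CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv_path = NULL) {
  stopifnot(inherits(report, "injury_report"))
  payload <- list(
    schema_version = report$schema_version,
    passes = report$passes,
    n_traces = report$n_traces,
    events = as.data.frame(report$events)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report$events), csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- obj$events
  if (is.null(ev) || length(ev) == 0L || nrow(as.data.frame(ev)) == 0L) {
    ev <- new_events()
  } else {
    ev <- as.data.frame(ev)
    class(ev) <- c("injury_events", "data.frame")
  }
  structure(
    list(events = ev, passes = isTRUE(obj$passes),
         n_traces = obj$n_traces, schema_version = obj$schema_version),
    class = "injury_report"
  )
}

config_keys <- list(
  top = c("muscles", "boundary", "msic"),
  muscle = c("name", "f_max", "l_ce_opt", "l_see_0", "tendon", "pcsa",
             "sigma_max", "l_mtu_model", "slack_reduction"),
  tendon = c("family", "eps0", "f_toe", "k_toe", "u_nll", "du_l", "f_0",
             "slope_pct", "domain"),
  boundary = c("pos_x", "pos_y", "ens_x", "ens_y"),
  msic = c("minor_c0", "minor_c1", "major_c0", "major_c1")
)

reject_unknown <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown key(s) in %s: %s (allowed: %s)", where,
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
}

tendon_from_config <- function(cfg, muscle_name) {
  if (is.null(cfg)) return(tmm_tendon())
  reject_unknown(cfg, config_keys$tendon, paste0("tendon of ", muscle_name))
  fam <- toupper(cfg$family %||% "TMM")
  if (!fam %in% c("TMM", "EHTM")) {
    stop("unknown tendon family: ", fam, " (use TMM or EHTM)", call. = FALSE)
  }
  if (!is.null(cfg$slope_pct)) return(calibrate_tendon(fam, cfg$slope_pct))
  args <- cfg[setdiff(names(cfg), c("family", "slope_pct"))]
  do.call(if (fam == "TMM") tmm_tendon else ehtm_tendon, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON configuration with three top-level
#' sections, all validated with unknown keys rejected:
#' \describe{
#'   \item{`muscles`}{list of muscle entries (see [muscle_param_set()];
#'     tendon as `family` plus shape parameters, or `slope_pct` to
#'     calibrate the family to a target linearised stiffness);}
#'   \item{`boundary`}{optional boundary yield-point override
#'     (`pos_x`, `pos_y`, `ens_x`, `ens_y`);}
#'   \item{`msic`}{optional MSIC coefficients (`minor_c0`, `minor_c1`,
#'     `major_c0`, `major_c1`) for the linear-in-activity template.}
#' }
#'
#' @param path configuration file path.
#' @return list with `muscles` (named list of [muscle_param_set()]),
#'   `pos`/`ens` ([yield_point()]s) and `msic` ([msic_thresholds()]).
#' @export
read_muscle_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  reject_unknown(cfg, config_keys$top, "config")
  if (is.null(cfg$muscles) || length(cfg$muscles) == 0L) {
    stop("config has no `muscles` section", call. = FALSE)
  }
  muscles <- lapply(cfg$muscles, function(m) {
    reject_unknown(m, config_keys$muscle, paste0("muscle '", m$name %||% "?", "'"))
    if (is.null(m$name)) stop("every muscle entry needs a `name`", call. = FALSE)
    muscle_param_set(
      name = m$name, f_max = m$f_max, l_ce_opt = m$l_ce_opt,
      l_see_0 = m$l_see_0, tendon = tendon_from_config(m$tendon, m$name),
      pcsa = m$pcsa, sigma_max = m$sigma_max %||% 23,
      l_mtu_model = m$l_mtu_model, slack_reduction = m$slack_reduction %||% 0
    )
  })
  names(muscles) <- vapply(muscles, function(m) m$name, character(1))
  pos <- positional_yield_point()
  ens <- energy_storage_yield_point()
  if (!is.null(cfg$boundary)) {
    reject_unknown(cfg$boundary, config_keys$boundary, "boundary")
    b <- cfg$boundary
    pos <- yield_point(b$pos_x %||% pos$x, b$pos_y %||% pos$y)
    ens <- yield_point(b$ens_x %||% ens$x, b$ens_y %||% ens$y)
  }
  msic <- msic_thresholds()
  if (!is.null(cfg$msic)) {
    reject_unknown(cfg$msic, config_keys$msic, "msic")
    m <- cfg$msic
    msic <- msic_thresholds(
      minor = c(m$minor_c0 %||% 1, m$minor_c1 %||% 0),
      major = c(m$major_c0 %||% 2.5, m$major_c1 %||% 0)
    )
  }
  list(muscles = muscles, pos = pos, ens = ens, msic = msic)
}

#' Write a threshold table
#'
#' @param table a [build_threshold_table()] result.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the table.
#' @export
write_threshold_table <- function(table, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(table, "threshold_table"))
  df <- as.data.frame(table)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(table)
}
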