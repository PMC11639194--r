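#' Write a sweep family (or single trace) as CSV
#'
#' Columns: `time_ms`, `current`, `voltage_mV`, `sweep_id`.
#'
#' @param x a `kv_sweep_family` or single `kv_trace`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_trace_csv <- function(x, path) {
  df <- .flatten_traces(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.flatten_traces <- function(x) {
  traces <- if (inherits(x, "kv_sweep_family")) x$traces else list(x)
  do.call(rbind, lapply(seq_along(traces), function(k) {
    tr <- traces[[k]]
    data.frame(time_ms = tr$time_ms, current = tr$current,
               voltage_mV = tr$voltage_mV, sweep_id = k)
  }))
}

#' Read traces from CSV
#'
#' Reads files written by [write_trace_csv()].  Segment boundaries are
#' reconstructed from the voltage column.
#'
#' @param path CSV file.
#' @return list of `kv_trace` data.frames, one per sweep id.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "current", "voltage_mV")
  if (!all(need %in% names(df))) stop("not a trace CSV: ", path)
  if (is.null(df$sweep_id)) df$sweep_id <- 1L
  lapply(split(df, df$sweep_id), .as_kv_trace)
}

.as_kv_trace <- function(df) {
  tr <- df[, c("time_ms", "current", "voltage_mV")]
  # segment table from voltage change points
  chg <- c(TRUE, diff(tr$voltage_mV) != 0)
  starts <- which(chg)
  segs <- data.frame(
    start = c(0, tr$time_ms[starts[-1] - 1]),
    end = c(tr$time_ms[starts[-1] - 1], tr$time_ms[nrow(tr)]),
    V = tr$voltage_mV[starts],
    label = paste0("seg", seq_along(starts)))
  # label a lone depolarized segment as the pulse
  dep <- which(segs$V > min(segs$V))
  if (length(dep) == 1) segs$label[dep] <- "step"
  if (length(dep) == 2) segs$label[dep] <- c("1P", "2P")
  attr(tr, "segments") <- segs
  class(tr) <- c("kv_trace", "data.frame")
  tr
}

#' Write a sweep family in Axon Text File (ATF 1.0) dialect
#'
#' Minimal ATF: the two-line magic/header-count preamble, header records,
#' then tab-separated columns (time and one current column per sweep,
#' resampled onto the first sweep's grid).
#'
#' @param x a `kv_sweep_family` or single `kv_trace`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_trace_atf <- function(x, path) {
  traces <- if (inherits(x, "kv_sweep_family")) x$traces else list(x)
  t0 <- traces[[1]]$time_ms
  cols <- lapply(traces, function(tr)
    stats::approx(tr$time_ms, tr$current, xout = t0, rule = 2)$y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ATF\t1.0",
               sprintf("2\t%d", length(traces) + 1L),
               "\"AcquisitionMode=Simulated\"",
               "\"SignalsExported=current\""), con)
  writeLines(paste(c("\"Time (ms)\"",
                     sprintf("\"Trace #%d (norm)\"", seq_along(traces))),
                   collapse = "\t"), con)
  mat <- cbind(t0, do.call(cbind, cols))
  utils::write.table(format(mat, digits = 9, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ATF 1.0 file written by [write_trace_atf()]
#'
#' @param path ATF file.
#' @return data.frame with `time_ms` and one column per trace.
#' @export
read_trace_atf <- function(path) {
  lines <- readLines(path)
  if (!grepl("^ATF", lines[1])) stop("not an ATF file: ", path)
  hdr <- as.integer(strsplit(lines[2], "\t")[[1]])
  n_header <- hdr[1]
  dat <- utils::read.table(path, sep = "\t", skip = 2 + n_header + 1)
  names(dat) <- c("time_ms", paste0("trace", seq_len(ncol(dat) - 1)))
  dat
}

#' Serialize a scheme + parameter preset as JSON
#'
#' Schema: `states`, `conducting`, `transitions` (from/to/rate/z, one entry
#' per direction), `rates`, `modulators`.
#'
#' @param params a [kv_rate_params()] (scheme attached or passed).
#' @param path output file.
#' @param scheme optional [kv_scheme()].
#' @return invisibly, `path`.
#' @export
write_preset_json <- function(params, path, scheme = NULL) {
  scheme <- scheme %||% attr(params, "scheme") %||% kv_scheme_full()
  de <- .directed_edges(scheme)
  p <- unclass(params)
  mod_names <- c("K_K", "theta_push", "K_Zn", "eta_Zn", "u_type")
  rate_names <- setdiff(names(p), c(mod_names, "extra"))
  obj <- list(
    name = attr(params, "channel") %||% scheme$name,
    states = scheme$states,
    conducting = scheme$conducting,
    transitions = lapply(seq_len(nrow(de)), function(i)
      list(from = de$from[i], to = de$to[i], rate = de$rate[i], z = de$z[i])),
    rates = p[rate_names],
    modulators = p[mod_names])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a preset JSON written by [write_preset_json()]
#'
#' @param path JSON file.
#' @return a [kv_rate_params()] with the reconstructed scheme attached.
#' @export
read_preset_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- as.data.frame(obj$transitions)
  fwd <- tr[tr$z >= 0 & !duplicated(paste(pmin(tr$from, tr$to),
                                          pmax(tr$from, tr$to))), ]
  # rebuild reversible edge list: match each forward edge with its reverse
  edges <- do.call(rbind, lapply(seq_len(nrow(fwd)), function(i) {
    rev <- tr[tr$from == fwd$to[i] & tr$to == fwd$from[i], ]
    data.frame(from = fwd$from[i], to = fwd$to[i], fwd = fwd$rate[i],
               bwd = rev$rate[1], z = fwd$z[i])
  }))
  scheme <- kv_scheme(obj$states, obj$conducting, edges, name = obj$name)
  params <- do.call(kv_rate_params, c(obj$rates, obj$modulators))
  attr(params, "scheme") <- scheme
  attr(params, "channel") <- obj$name
  params
}
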