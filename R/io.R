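#' Read a recording from CSV (+ optional sidecar JSON)
#'
#' The CSV dialect is one header row, a `time` column (seconds) and one
#' column per channel per quantity: `CH01_hbo`, `CH01_hhb`, ... for
#' concentration data, or `CH01_od740`, ... for optical-density data.
#' Condition segments and metadata may be supplied in a sidecar JSON file
#' `<path>.json` (written by [write_recording()]); without one, the
#' recording carries a single segment spanning all samples.
#'
#' @param path CSV file path.
#' @param format `"csv"`. (`"snirf"` is recognised but not supported by this
#'   build; requesting it raises an informative error.)
#' @return A [hemo_recording()] or [optical_recording()], depending on the
#'   column set found.
#' @export
read_recording <- function(path, format = c("csv", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf") {
    stop("SNIRF (HDF5) input is not supported by this build; ",
         "convert to the CSV dialect described in ?read_recording")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("malformed header: no 'time' column")
  if (nrow(df) < 2) stop("need at least two samples")
  if (anyNA(df)) {
    bad <- names(df)[vapply(df, anyNA, logical(1))]
    stop("column(s) with missing values (short column?): ",
         paste(bad, collapse = ", "))
  }
  fs <- 1 / stats::median(diff(df$time))
  side <- paste0(path, ".json")
  segments <- NULL; meta <- list()
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(sc$segments)) segments <- tibble::as_tibble(sc$segments)
    if (!is.null(sc$meta)) meta <- as.list(sc$meta)
    if (!is.null(sc$sampling_rate)) fs <- sc$sampling_rate
  }
  cols <- setdiff(names(df), "time")
  m <- regmatches(cols, regexec("^(.+)_(hbo|hhb|od([0-9.]+))$", cols))
  ok <- lengths(m) > 0
  if (!all(ok)) stop("unknown column id(s): ", paste(cols[!ok], collapse = ", "))
  chan <- vapply(m, `[`, "", 2)
  kind <- vapply(m, `[`, "", 3)
  if (all(kind %in% c("hbo", "hhb"))) {
    channels <- unique(chan)
    pick <- function(k) {
      want <- paste0(channels, "_", k)
      miss <- setdiff(want, cols)
      if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
      mm <- as.matrix(df[, want, drop = FALSE]); colnames(mm) <- channels
      mm
    }
    hemo_recording(pick("hbo"), pick("hhb"), fs, segments = segments,
                   meta = meta)
  } else if (all(startsWith(kind, "od"))) {
    wls <- unique(sub("^od", "", kind))
    channels <- unique(chan)
    od <- lapply(wls, function(w) {
      want <- paste0(channels, "_od", w)
      miss <- setdiff(want, cols)
      if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
      mm <- as.matrix(df[, want, drop = FALSE]); colnames(mm) <- channels
      mm
    })
    names(od) <- wls
    optical_recording(od, fs, segments = segments, meta = meta)
  } else {
    stop("mixed concentration and optical-density columns in one file")
  }
}

#' Write a recording to CSV (+ sidecar JSON)
#'
#' @param rec A [hemo_recording()] or [optical_recording()].
#' @param path Output CSV path; a sidecar `<path>.json` holding sampling
#'   rate, segments and metadata is written alongside.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- if (inherits(rec, "hemo_recording")) nrow(rec$hbo) else nrow(rec$od[[1]])
  tt <- (seq_len(n) - 1) / rec$sampling_rate
  if (inherits(rec, "hemo_recording")) {
    out <- data.frame(time = tt, check.names = FALSE)
    for (ch in rec$channels) out[[paste0(ch, "_hbo")]] <- rec$hbo[, ch]
    for (ch in rec$channels) out[[paste0(ch, "_hhb")]] <- rec$hhb[, ch]
  } else if (inherits(rec, "optical_recording")) {
    out <- data.frame(time = tt, check.names = FALSE)
    for (w in names(rec$od)) {
      for (ch in rec$channels) {
        out[[paste0(ch, "_od", w)]] <- rec$od[[w]][, ch]
      }
    }
  } else {
    stop("rec must be a hemo_recording or optical_recording")
  }
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate = rec$sampling_rate,
         segments = rec$segments, meta = rec$meta),
    paste0(path, ".json"), digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Write / read region-network results
#'
#' Region networks are long tibbles (one row per directed region pair per
#' band/condition/chromophore, columns `source`, `target`, `band`,
#' `condition`, `chromophore`, `value`, `n_significant`). Both a JSON and a
#' CSV file are emitted; reading back either reproduces the values exactly.
#'
#' @param networks Tibble as produced by [aggregate_regions()] (possibly
#'   row-bound over bands/conditions/chromophores).
#' @param path Output path without extension; `<path>.csv` and
#'   `<path>.json` are written.
#' @return `read_results` returns the tibble; `write_results` returns
#'   `path` invisibly.
#' @export
write_results <- function(networks, path) {
  networks <- tibble::as_tibble(networks)
  need <- c("source", "target", "band", "condition", "chromophore",
            "value", "n_significant")
  miss <- setdiff(need, names(networks))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(networks, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(networks, paste0(path, ".json"),
                       digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tibble::as_tibble(jsonlite::read_json(paste0(path, ".json"),
                                        simplifyVector = TRUE))
}
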