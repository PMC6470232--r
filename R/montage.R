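#' Optode montage for a multichannel fNIRS recording
#'
#' A montage holds the planar positions of light sources and detectors, the
#' source-detector pairs that define measurement channels, and the mapping of
#' each channel onto one of six cortical regions: left/right prefrontal
#' cortex (`LPFC`, `RPFC`), left/right motor cortex (`LMC`, `RMC`) and
#' left/right occipital lobe (`LOL`, `ROL`).
#'
#' @param optodes Tibble with columns `optode` (id), `type` (`"source"` or
#'   `"detector"`), `x`, `y` (planar scalp coordinates, mm).
#' @param channels Tibble with columns `channel` (id), `source`, `detector`
#'   (optode ids), `region` (one of the six region labels) and `hemisphere`
#'   (`"L"` or `"R"`).
#'
#' @return An object of class `fnirs_montage`: a list with elements
#'   `optodes` and `channels` (the latter gains midpoint coordinates `x`,
#'   `y` and the source-detector separation `sd_mm`).
#' @export
montage <- function(optodes, channels) {
  optodes <- tibble::as_tibble(optodes)
  channels <- tibble::as_tibble(channels)
  stopifnot(all(c("optode", "type", "x", "y") %in% names(optodes)),
            all(c("channel", "source", "detector", "region") %in% names(channels)))
  src <- optodes[optodes$type == "source", ]
  det <- optodes[optodes$type == "detector", ]
  if (!all(channels$source %in% src$optode)) {
    stop("channel references a source that is not in the optode table")
  }
  if (!all(channels$detector %in% det$optode)) {
    stop("channel references a detector that is not in the optode table")
  }
  bad <- setdiff(unique(channels$region), region_labels())
  if (length(bad) > 0) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(channels$channel)) stop("duplicated channel ids")
  sx <- src$x[match(channels$source, src$optode)]
  sy <- src$y[match(channels$source, src$optode)]
  dx <- det$x[match(channels$detector, det$optode)]
  dy <- det$y[match(channels$detector, det$optode)]
  channels$x <- (sx + dx) / 2
  channels$y <- (sy + dy) / 2
  channels$sd_mm <- sqrt((sx - dx)^2 + (sy - dy)^2)
  structure(list(optodes = optodes, channels = channels),
            class = "fnirs_montage")
}

#' The six cortical region labels
#'
#' @return Character vector of the six region labels in canonical order.
#' @export
region_labels <- function() {
  c("LPFC", "RPFC", "LMC", "RMC", "LOL", "ROL")
}

# One region motif: a source-only cross (1 source, 4 detectors) used for the
# prefrontal patches; the source sits at the centre, detectors 30 mm away.
.cross_motif <- function(cx, cy, src_id, det_ids, sep = 30) {
  optodes <- tibble::tibble(
    optode = c(src_id, det_ids),
    type = c("source", rep("detector", 4)),
    x = cx + c(0, sep, -sep, 0, 0),
    y = cy + c(0, 0, 0, sep, -sep)
  )
  channels <- tibble::tibble(source = src_id, detector = det_ids)
  list(optodes = optodes, channels = channels)
}

# Alternating square motif (2 sources, 2 detectors on the corners of a
# 30-mm square): all four source-detector edges are 30 mm.
.square_motif <- function(cx, cy, src_ids, det_ids, sep = 30) {
  h <- sep / 2
  optodes <- tibble::tibble(
    optode = c(src_ids, det_ids),
    type = c("source", "source", "detector", "detector"),
    x = cx + c(-h, h, h, -h),
    y = cy + c(-h, h, -h, h)
  )
  channels <- tibble::tibble(
    source = src_ids[c(1, 1, 2, 2)],
    detector = det_ids[c(1, 2, 1, 2)]
  )
  list(optodes = optodes, channels = channels)
}

#' Default 24-channel, six-region montage
#'
#' Builds the packaged fixture montage: 24 channels from 10 sources and 16
#' detectors, 12 channels per hemisphere, 4 per region, every
#' source-detector separation 30 mm. Coordinates are a schematic planar
#' layout (mm, midline at `x = 0`, anterior towards positive `y`), symmetric
#' about the midline; only the relative geometry is meaningful, the layout
#' is not anatomically registered.
#'
#' @return An `fnirs_montage` object.
#' @export
#' @examples
#' m <- default_montage()
#' table(m$channels$region)
default_montage <- function() {
  centres <- list(
    LPFC = c(-40, 70), RPFC = c(40, 70),
    LMC  = c(-45, 0),  RMC  = c(45, 0),
    LOL  = c(-35, -65), ROL = c(35, -65)
  )
  opt <- list(); chan <- list()
  s_i <- 0L; d_i <- 0L
  for (reg in names(centres)) {
    cc <- centres[[reg]]
    if (grepl("PFC", reg)) {
      m <- .cross_motif(cc[1], cc[2],
                        sprintf("S%02d", s_i + 1L),
                        sprintf("D%02d", d_i + 1:4))
      s_i <- s_i + 1L; d_i <- d_i + 4L
    } else {
      m <- .square_motif(cc[1], cc[2],
                         sprintf("S%02d", s_i + 1:2),
                         sprintf("D%02d", d_i + 1:2))
      s_i <- s_i + 2L; d_i <- d_i + 2L
    }
    m$channels$region <- reg
    m$channels$hemisphere <- substr(reg, 1, 1)
    opt[[reg]] <- m$optodes
    chan[[reg]] <- m$channels
  }
  optodes <- dplyr::bind_rows(opt)
  channels <- dplyr::bind_rows(chan)
  channels$channel <- sprintf("CH%02d", seq_len(nrow(channels)))
  channels <- channels[, c("channel", "source", "detector", "region", "hemisphere")]
  montage(optodes, channels)
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat("<fnirs_montage> ", nrow(x$channels), " channels, ",
      sum(x$optodes$type == "source"), " sources, ",
      sum(x$optodes$type == "detector"), " detectors\n", sep = "")
  print(dplyr::count(x$channels, .data$region))
  invisible(x)
}

#' @method as_tibble fnirs_montage
#' @export
as_tibble.fnirs_montage <- function(x, ...) x$channels

#' Write / read a montage as JSON
#'
#' @param m An `fnirs_montage`.
#' @param path File path.
#' @return `read_montage` returns an `fnirs_montage`; `write_montage`
#'   returns `path` invisibly.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "fnirs_montage"))
  jsonlite::write_json(
    list(optodes = m$optodes,
         channels = m$channels[, c("channel", "source", "detector",
                                   "region", "hemisphere")]),
    path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  montage(tibble::as_tibble(raw$optodes), tibble::as_tibble(raw$channels))
}
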