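#' Channel-level directed effective connectivity
#'
#' For every ordered pair of distinct channels and every requested band,
#' extracts band-limited phases, infers the pairwise phase dynamics, and
#' screens the directed coupling strengths against AAFT surrogates (see
#' [significance_test()]); each condition segment is processed
#' independently. Surrogate series are generated once per channel and
#' reused across all pairs involving that channel, and each unordered pair
#' is inferred once (both directions come from the same joint fit).
#'
#' A band is skipped (with a warning) for segments shorter than 10 cycles
#' of its lower frequency edge.
#'
#' @param rec A preprocessed [hemo_recording()] (see
#'   [preprocess_recording()]).
#' @param montage The montage; channel ids must match the recording.
#' @param bands Band table (default [band_set()]), possibly subset.
#' @param chromophore `"hbo"` or `"hhb"`.
#' @param pairs Tibble with columns `source`, `target` restricting the
#'   ordered channel pairs evaluated, or `NULL` for all ordered pairs.
#' @param conditions Condition names to process (default: all segments).
#' @param n_surrogates Surrogate pairs per channel pair (production
#'   default 100; 19 for quick screening).
#' @param seed Integer seed for surrogate generation.
#' @param K Fourier expansion order.
#' @param voices,omega0 Wavelet settings.
#' @return Tibble with columns `condition`, `chromophore`, `band`,
#'   `source`, `target`, `sigma`, `surrogate_mean`, `surrogate_sd`,
#'   `threshold`, `significant`.
#' @export
compute_channel_ec <- function(rec, montage = default_montage(),
                               bands = band_set(), chromophore = "hbo",
                               pairs = NULL, conditions = NULL,
                               n_surrogates = 100, seed = 1, K = 2,
                               voices = 16, omega0 = 6) {
  stopifnot(inherits(rec, "hemo_recording"),
            chromophore %in% c("hbo", "hhb"))
  if (!all(rec$channels %in% montage$channels$channel)) {
    stop("recording channels absent from montage")
  }
  if (is.null(conditions)) conditions <- rec$segments$condition
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(source = rec$channels,
                                target = rec$channels) |>
      dplyr::filter(.data$source != .data$target)
  }
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c(pairs$source, pairs$target) %in% rec$channels),
            all(pairs$source != pairs$target))
  used_chans <- unique(c(pairs$source, pairs$target))
  # one joint fit per unordered pair
  upairs <- unique(tibble::tibble(
    a = pmin(pairs$source, pairs$target),
    b = pmax(pairs$source, pairs$target)))
  base <- build_base_functions(K)
  fs <- rec$sampling_rate
  out <- list(); oi <- 0L

  for (cond in conditions) {
    seg <- segment_recording(rec, cond)
    x <- seg[[chromophore]]
    seg_s <- nrow(x) / fs
    # surrogates are band-independent: generate once per channel
    set.seed(.study_seed(seed, match(cond, conditions)))
    ch_seeds <- stats::setNames(sample.int(2147483600, length(used_chans)),
                                used_chans)
    surr <- lapply(used_chans, function(ch) {
      aaft_surrogate(x[, ch], n_surrogates, seed = ch_seeds[[ch]])
    })
    names(surr) <- used_chans

    for (bi in seq_len(nrow(bands))) {
      lab <- bands$band[bi]; lo <- bands$low[bi]; hi <- bands$high[bi]
      if (seg_s < 10 / lo) {
        warning("segment '", cond, "' shorter than 10 cycles of band ",
                lab, " lower edge; band skipped")
        next
      }
      stride <- .band_stride(fs, hi)
      bp <- function(v) .band_phase_fast(v, fs, lo, hi, voices, omega0,
                                         stride)
      ph <- lapply(used_chans, function(ch) bp(x[, ch]))
      names(ph) <- used_chans
      ph_s <- lapply(used_chans, function(ch) {
        lapply(seq_len(n_surrogates), function(k) bp(surr[[ch]][, k]))
      })
      names(ph_s) <- used_chans

      fit_sigma <- function(pa, pb) {
        keep <- pa$valid & pb$valid
        fit <- infer_phase_dynamics(pa$phase[keep], pb$phase[keep],
                                    pa$sampling_rate, base = base)
        c(coupling_strength(fit, "phi2", "phi1"),  # b -> a
          coupling_strength(fit, "phi1", "phi2"))  # a -> b
      }
      for (pi in seq_len(nrow(upairs))) {
        a <- upairs$a[pi]; b <- upairs$b[pi]
        orig <- fit_sigma(ph[[a]], ph[[b]])
        sur <- matrix(NA_real_, n_surrogates, 2)
        fail <- 0L
        for (k in seq_len(n_surrogates)) {
          sk <- tryCatch(fit_sigma(ph_s[[a]][[k]], ph_s[[b]][[k]]),
                         error = function(e) NULL)
          if (is.null(sk)) fail <- fail + 1L else sur[k, ] <- sk
        }
        if (fail > 0.2 * n_surrogates) {
          stop("surrogate inference failed for ", fail, " of ",
               n_surrogates, " surrogates (pair ", a, "-", b, ")")
        }
        mu <- colMeans(sur, na.rm = TRUE)
        sdv <- apply(sur, 2, stats::sd, na.rm = TRUE)
        oi <- oi + 1L
        out[[oi]] <- tibble::tibble(
          condition = cond, chromophore = chromophore, band = lab,
          source = c(b, a), target = c(a, b),
          sigma = orig, surrogate_mean = mu, surrogate_sd = sdv,
          threshold = mu + 2 * sdv, significant = orig > mu + 2 * sdv)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(condition = character(), chromophore = character(),
                          band = character(), source = character(),
                          target = character(), sigma = numeric(),
                          surrogate_mean = numeric(),
                          surrogate_sd = numeric(), threshold = numeric(),
                          significant = logical()))
  }
  dplyr::inner_join(pairs, res, by = c("source", "target"))
}

#' Aggregate channel-level connectivity into a six-region directed network
#'
#' Each of the 30 ordered region pairs receives the mean coupling strength
#' over the *significant* channel pairs whose source channel lies in the
#' source region and target channel in the target region; cells with no
#' significant contributor are 0 with count 0. Within-region channel pairs
#' are excluded.
#'
#' @param channel_results Output of [compute_channel_ec()].
#' @param montage The montage mapping channels to regions.
#' @return Tibble with columns `condition`, `chromophore`, `band`,
#'   `source`, `target` (region labels), `value` (mean significant sigma)
#'   and `n_significant`, one row per ordered region pair per
#'   condition/chromophore/band present in the input.
#' @export
aggregate_regions <- function(channel_results, montage = default_montage()) {
  res <- tibble::as_tibble(channel_results)
  reg <- stats::setNames(montage$channels$region, montage$channels$channel)
  if (!all(c(res$source, res$target) %in% names(reg))) {
    stop("channel id(s) in results absent from montage")
  }
  res$source_region <- unname(reg[res$source])
  res$target_region <- unname(reg[res$target])
  res <- dplyr::filter(res, .data$source_region != .data$target_region)
  cells <- tidyr::expand_grid(source = region_labels(),
                              target = region_labels()) |>
    dplyr::filter(.data$source != .data$target)
  keys <- dplyr::distinct(res, .data$condition, .data$chromophore,
                          .data$band)
  grid <- tidyr::crossing(keys, cells)
  agg <- res |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$condition, .data$chromophore, .data$band,
                    source = .data$source_region,
                    target = .data$target_region) |>
    dplyr::summarise(value = mean(.data$sigma),
                     n_significant = dplyr::n(), .groups = "drop")
  grid |>
    dplyr::left_join(agg, by = c("condition", "chromophore", "band",
                                 "source", "target")) |>
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0),
                  n_significant = dplyr::coalesce(.data$n_significant, 0L))
}

#' Region network as a 6 x 6 matrix
#'
#' @param network One condition/chromophore/band slice of
#'   [aggregate_regions()] output.
#' @return 6 x 6 numeric matrix (rows = source region, columns = target),
#'   zero diagonal.
#' @export
network_matrix <- function(network) {
  network <- tibble::as_tibble(network)
  key <- unique(paste(network$condition, network$chromophore, network$band))
  if (length(key) > 1) {
    stop("network holds more than one condition/chromophore/band slice")
  }
  labs <- region_labels()
  m <- matrix(0, 6, 6, dimnames = list(labs, labs))
  m[cbind(match(network$source, labs), match(network$target, labs))] <-
    network$value
  m
}

#' Topographic activation map by inverse-distance interpolation
#'
#' Averages each channel's concentration change over a condition segment
#' and interpolates the channel-midpoint values onto a planar grid with
#' inverse-distance weighting (power `idw_power`, all channels in the
#' neighbourhood); grid nodes that coincide with a channel midpoint take
#' exactly that channel's mean.
#'
#' @param rec A [hemo_recording()].
#' @param condition Condition segment to average.
#' @param montage The montage (channel midpoint coordinates).
#' @param chromophore `"hbo"` or `"hhb"`.
#' @param grid_n Grid resolution per axis (default 64).
#' @param idw_power Inverse-distance exponent (default 2).
#' @param margin Margin around the optode bounding box, mm.
#' @return An object of class `activation_map`: list with `grid` (tibble
#'   `x`, `y`, `value`), `channel_means` (tibble `channel`, `x`, `y`,
#'   `mean`), `condition`, `chromophore`.
#' @export
activation_map <- function(rec, condition, montage = default_montage(),
                           chromophore = "hbo", grid_n = 64,
                           idw_power = 2, margin = 15) {
  stopifnot(grid_n >= 2)
  seg <- segment_recording(rec, condition)
  vals <- colMeans(seg[[chromophore]])
  chpos <- montage$channels[match(names(vals), montage$channels$channel), ]
  if (anyNA(chpos$x)) stop("recording channels absent from montage")
  gx <- seq(min(montage$optodes$x) - margin, max(montage$optodes$x) + margin,
            length.out = grid_n)
  gy <- seq(min(montage$optodes$y) - margin, max(montage$optodes$y) + margin,
            length.out = grid_n)
  grid <- tidyr::expand_grid(x = gx, y = gy)
  d2 <- outer(grid$x, chpos$x, "-")^2 + outer(grid$y, chpos$y, "-")^2
  w <- 1 / pmax(d2, 1e-24)^(idw_power / 2)
  est <- as.vector((w %*% vals) / rowSums(w))
  hit <- d2 < 1e-12
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    est[idx[, 1]] <- vals[idx[, 2]]
  }
  grid$value <- est
  structure(list(grid = grid,
                 channel_means = tibble::tibble(channel = names(vals),
                                                x = chpos$x, y = chpos$y,
                                                mean = unname(vals)),
                 condition = condition, chromophore = chromophore),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat("<activation_map> ", x$chromophore, " / ", x$condition, ", ",
      nrow(x$grid), " grid nodes\n", sep = "")
  invisible(x)
}
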