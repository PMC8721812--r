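# Accurate-mass extracted ion chromatograms over MS1 scans.

#' Extract an accurate-mass ion chromatogram
#'
#' For every MS1 scan of the run, sums the intensity of peaks within
#' `+/- tol_ppm` of any of the target m/z values (all adduct / charge /
#' anomer variants of one species are tracked together as one trace). The
#' targets' ppm windows must not overlap: an overlap would double-count
#' intensity and is an error at trace-definition time.
#'
#' @param run a [glycan_run()] containing MS1 scans.
#' @param target_mz numeric vector of target m/z values.
#' @param tol_ppm window half-width in ppm (default 5).
#' @param label trace label (composition or species name).
#' @param polarity optional polarity filter for the MS1 scans.
#' @return An object of class `xic_trace`: data frame with columns `rt`
#'   and `intensity`, plus attributes `label` and `targets`.
#' @export
extract_xic <- function(run, target_mz, tol_ppm = 5, label = "trace",
                        polarity = NULL) {
  scans <- run_spectra(run, ms_level = 1L, polarity = polarity)
  if (!length(scans)) stop("run contains no MS1 scans")
  target_mz <- sort(as.numeric(target_mz))
  if (length(target_mz) > 1) {
    lo <- target_mz * (1 - tol_ppm * 1e-6)
    hi <- target_mz * (1 + tol_ppm * 1e-6)
    if (any(lo[-1] <= hi[-length(hi)])) {
      stop("target m/z windows overlap at ", tol_ppm,
           " ppm; merge the targets or tighten the tolerance")
    }
  }
  rt <- vapply(scans, `[[`, numeric(1), "retention_time")
  intensity <- vapply(scans, function(s) {
    tot <- 0
    for (t in target_mz) {
      j1 <- findInterval(t * (1 - tol_ppm * 1e-6), s$mz) + 1L
      j2 <- findInterval(t * (1 + tol_ppm * 1e-6), s$mz)
      if (j2 >= j1) tot <- tot + sum(s$intensity[j1:j2])
    }
    tot
  }, numeric(1))
  o <- order(rt)
  out <- data.frame(rt = rt[o], intensity = intensity[o])
  attr(out, "label") <- label
  attr(out, "targets") <- target_mz
  class(out) <- c("xic_trace", "data.frame")
  out
}

#' Detect chromatographic apexes in a trace
#'
#' Local maxima of the 3-point moving-average-smoothed trace, filtered by
#' relative height (default: at least 5% of the trace maximum). Plateau
#' maxima report their first point; the procedure is deterministic.
#'
#' @param trace an [extract_xic()] trace.
#' @param min_prominence minimum apex height as a fraction of the smoothed
#'   trace maximum.
#' @return Data frame with columns `rt` and `height` (smoothed height),
#'   ordered by retention time; zero rows for a flat trace.
#' @export
detect_apexes <- function(trace, min_prominence = 0.05) {
  y <- trace$intensity
  n <- length(y)
  if (n == 0) stop("empty trace")
  if (n >= 3) {
    sm <- y
    sm[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
  } else {
    sm <- y
  }
  mx <- max(sm)
  if (mx <= 0) {
    return(data.frame(rt = numeric(0), height = numeric(0)))
  }
  is_apex <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < n) sm[i + 1] else -Inf
    # strict rise on the left, non-rise on the right: first point of plateaus
    is_apex[i] <- sm[i] > left && sm[i] >= right && sm[i] > 0
  }
  keep <- is_apex & sm >= min_prominence * mx
  data.frame(rt = trace$rt[keep], height = sm[keep])
}

#' Normalize a set of traces to a reference trace
#'
#' Divides every trace's intensities by the apex (maximum) intensity of the
#' reference trace, so the reference apex becomes exactly 1. This is the
#' convention used for overlaid within-run XIC maps normalized to a common
#' abundant structure (or to the most abundant structure per sample).
#'
#' @param traces named list of [extract_xic()] traces (names are labels), or
#'   a list whose elements carry `label` attributes.
#' @param reference_label label of the reference trace.
#' @return The list of traces with scaled intensities.
#' @export
normalize_traces <- function(traces, reference_label) {
  labels <- names(traces)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(traces, function(t) attr(t, "label"), character(1))
    names(traces) <- labels
  }
  if (!reference_label %in% labels) {
    stop("reference trace '", reference_label, "' not found; traces: ",
         paste(labels, collapse = ", "))
  }
  apex <- max(traces[[reference_label]]$intensity)
  if (apex <= 0) stop("reference trace has a zero apex")
  lapply(traces, function(t) {
    t$intensity <- t$intensity / apex
    t
  })
}

#' Export XIC traces as a long-format TSV
#' @param traces named list of traces.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_traces <- function(traces, path) {
  rows <- lapply(names(traces), function(lb) {
    data.frame(label = lb, rt = traces[[lb]]$rt,
               intensity = traces[[lb]]$intensity, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
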