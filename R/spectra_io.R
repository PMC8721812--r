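# Spectrum and run containers plus mzML / peak-list IO.
#
# A run is an ordered list of centroided spectrum records carrying the full
# MS1 / HCD-MS2 / product-dependent CID-MS3 lineage. mzML reading and
# writing is delegated to mzR (proteowizard backend); lineage is carried in
# the standard precursor spectrumRef / scan number fields.

.polarity_levels <- c("negative", "positive")

#' Construct a spectrum record
#'
#' @param scan_id integer scan number, unique within a run.
#' @param ms_level 1, 2 or 3.
#' @param retention_time retention time in seconds.
#' @param polarity `"positive"` or `"negative"`.
#' @param mz,intensity numeric peak vectors (centroids). Peaks are stored
#'   sorted ascending by m/z; intensities must be non-negative.
#' @param precursor_mz precursor m/z (required for levels 2-3).
#' @param precursor_charge precursor charge, or `NA` if undetermined.
#' @param parent_scan_id scan id of the MS2 parent for MS3 records, or `NA`.
#' @return An object of class `spectrum_record`.
#' @export
spectrum_record <- function(scan_id, ms_level, retention_time, polarity,
                            mz = numeric(0), intensity = numeric(0),
                            precursor_mz = NA_real_,
                            precursor_charge = NA_integer_,
                            parent_scan_id = NA_integer_) {
  ms_level <- as.integer(ms_level)
  stopifnot(ms_level %in% 1:3, polarity %in% .polarity_levels,
            length(mz) == length(intensity))
  if (any(intensity < 0)) stop("peak intensities must be non-negative")
  if (ms_level >= 2L && (is.na(precursor_mz) || precursor_mz <= 0)) {
    stop("MS", ms_level, " record requires precursor_mz > 0")
  }
  o <- order(mz)
  structure(
    list(scan_id = as.integer(scan_id), ms_level = ms_level,
         retention_time = as.numeric(retention_time), polarity = polarity,
         mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
         precursor_mz = as.numeric(precursor_mz),
         precursor_charge = as.integer(precursor_charge),
         parent_scan_id = as.integer(parent_scan_id)),
    class = "spectrum_record"
  )
}

#' Construct a run from spectrum records
#'
#' @param spectra list of [spectrum_record()]s, in acquisition order.
#' @param source free-text source label (e.g. a filename).
#' @return An object of class `glycan_run`.
#' @export
glycan_run <- function(spectra, source = "in-memory") {
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum_record")))
  for (lev in 1:3) {
    rts <- vapply(Filter(function(s) s$ms_level == lev, spectra),
                  `[[`, numeric(1), "retention_time")
    if (is.unsorted(rts)) {
      stop("retention times must be non-decreasing within MS level ", lev)
    }
  }
  structure(list(spectra = spectra, source = source,
                 polarity = unique(vapply(spectra, `[[`, character(1),
                                          "polarity"))),
            class = "glycan_run")
}

#' @export
print.glycan_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat("<glycan_run> ", x$source, ": ", length(x$spectra), " spectra (MS1 ",
      sum(lv == 1), ", MS2 ", sum(lv == 2), ", MS3 ", sum(lv == 3),
      "); polarity: ", paste(x$polarity, collapse = "+"), "\n", sep = "")
  invisible(x)
}

#' Subset a run by MS level and/or polarity
#' @param run a [glycan_run()].
#' @param ms_level,polarity optional filters.
#' @return List of `spectrum_record`s.
#' @export
run_spectra <- function(run, ms_level = NULL, polarity = NULL) {
  out <- run$spectra
  if (!is.null(ms_level)) {
    out <- Filter(function(s) s$ms_level %in% ms_level, out)
  }
  if (!is.null(polarity)) {
    out <- Filter(function(s) s$polarity %in% polarity, out)
  }
  out
}

#' Read an mzML file into a run
#'
#' Loads all scans with MS level, polarity, retention time, precursor m/z,
#' charge and MS3 -> MS2 lineage. MS3 scans whose parent scan cannot be
#' resolved are kept with `parent_scan_id = NA` and a warning.
#'
#' @param path path to an mzML file.
#' @return A [glycan_run()].
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) {
                       stop("malformed mzML file '", path, "': ",
                            conditionMessage(e))
                     })
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0) return(glycan_run(list(), source = basename(path)))
  pks <- mzR::peaks(handle)
  if (is.matrix(pks)) pks <- list(pks)
  spectra <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    lev <- hdr$msLevel[i]
    parent <- NA_integer_
    if (lev == 3L) {
      parent <- hdr$precursorScanNum[i]
      if (is.na(parent) || parent == 0L ||
          !parent %in% hdr$acquisitionNum[hdr$msLevel == 2L]) {
        warning("MS3 scan ", hdr$acquisitionNum[i],
                ": parent MS2 scan unresolved; kept with NA parent")
        parent <- NA_integer_
      }
    }
    spectra[[i]] <- spectrum_record(
      scan_id = hdr$acquisitionNum[i], ms_level = lev,
      retention_time = hdr$retentionTime[i],
      polarity = if (isTRUE(hdr$polarity[i] == 0L)) "negative" else "positive",
      mz = pks[[i]][, 1], intensity = pks[[i]][, 2],
      precursor_mz = if (lev >= 2L) hdr$precursorMZ[i] else NA_real_,
      precursor_charge = if (lev >= 2L && !is.na(hdr$precursorCharge[i]) &&
                             hdr$precursorCharge[i] > 0L)
        hdr$precursorCharge[i] else NA_integer_,
      parent_scan_id = parent
    )
  }
  glycan_run(spectra, source = basename(path))
}

#' Write a run to mzML
#'
#' Inverse of [read_mzml()] for the modeled fields (scan id, MS level,
#' retention time, polarity, peaks, precursor m/z/charge, MS3 lineage).
#'
#' @param run a [glycan_run()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "glycan_run"))
  n <- length(run$spectra)
  if (n == 0) stop("cannot write an empty run")
  pk <- lapply(run$spectra, function(s) cbind(s$mz, s$intensity))
  g1 <- function(f, default) {
    vapply(run$spectra, function(s) {
      v <- s[[f]]
      if (length(v) == 0 || is.na(v)) default else v
    }, FUN.VALUE = default)
  }
  lev <- vapply(run$spectra, `[[`, integer(1), "ms_level")
  tic <- vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
  bpi <- vapply(run$spectra, function(s) {
    if (length(s$intensity)) max(s$intensity) else 0
  }, numeric(1))
  bpm <- vapply(run$spectra, function(s) {
    if (length(s$mz)) s$mz[which.max(s$intensity)] else 0
  }, numeric(1))
  hdr <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = vapply(run$spectra, `[[`, integer(1), "scan_id"),
    msLevel = lev,
    polarity = as.integer(vapply(run$spectra, `[[`, character(1),
                                 "polarity") == "positive"),
    peaksCount = lengths(lapply(run$spectra, `[[`, "mz")),
    totIonCurrent = tic,
    retentionTime = vapply(run$spectra, `[[`, numeric(1), "retention_time"),
    basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(s) {
      if (length(s$mz)) min(s$mz) else 0
    }, numeric(1)),
    highMZ = vapply(run$spectra, function(s) {
      if (length(s$mz)) max(s$mz) else 0
    }, numeric(1)),
    precursorScanNum = ifelse(lev == 1L, 0L, g1("parent_scan_id", 0L)),
    precursorMZ = ifelse(lev == 1L, 0, g1("precursor_mz", 0)),
    precursorCharge = ifelse(lev == 1L, 0L, g1("precursor_charge", 0L)),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", vapply(run$spectra, `[[`, integer(1),
                                        "scan_id")),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(lev == 1L, NA_real_,
                                     g1("precursor_mz", 0)),
    isolationWindowLowerOffset = ifelse(lev == 1L, NA_real_, 0.7),
    isolationWindowUpperOffset = ifelse(lev == 1L, NA_real_, 0.7),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  # mzR resolves lineage via precursorScanNum; MS2 scans point at the last
  # preceding MS1 scan.
  last_ms1 <- 0L
  for (i in seq_len(n)) {
    if (lev[i] == 1L) last_ms1 <- hdr$acquisitionNum[i]
    if (lev[i] == 2L) hdr$precursorScanNum[i] <- last_ms1
  }
  mzR::writeMSData(object = pk, file = path, header = hdr)
  invisible(path)
}

#' Read a two-column peak-list text file
#'
#' Whitespace- or tab-delimited `m/z intensity` rows, optionally preceded by
#' a single header line; produces a single MS1 spectrum record (the MALDI
#' screening format).
#'
#' @param path path to the text file.
#' @param polarity polarity to stamp on the record.
#' @return A [spectrum_record()] with `ms_level = 1`.
#' @export
read_peaklist <- function(path, polarity = "positive") {
  if (!file.exists(path)) stop("peak list not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  start <- 1L
  if (length(lines)) {
    first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
    if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L
  }
  mz <- numeric(0); int <- numeric(0)
  for (i in seq(from = start, length.out = max(0L, length(lines) - start + 1L))) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
    if (length(f) < 2 || anyNA(f[1:2])) {
      stop("non-numeric peak-list row at line ", i, " of ", path)
    }
    mz <- c(mz, f[1]); int <- c(int, f[2])
  }
  spectrum_record(scan_id = 1L, ms_level = 1L, retention_time = 0,
                  polarity = polarity, mz = mz, intensity = int)
}

#' Write a spectrum record as a two-column peak list
#' @param spectrum a [spectrum_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spectrum, path) {
  write.table(data.frame(mz = spectrum$mz, intensity = spectrum$intensity),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
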