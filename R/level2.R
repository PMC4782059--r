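# Level-2 preprocessing: noisy-channel detection, neighbor interpolation and
# robust average referencing (a documented, pluggable stand-in exposing the
# same interface as a full published preprocessing pipeline), plus Level-2
# container assembly with per-recording quality reports.

#' Construct an in-memory signal recording
#'
#' @param data Channels-by-samples numeric matrix (microvolts).
#' @param samplingRate Sampling rate in Hz.
#' @param channelLabels One label per row of `data`.
#' @param nonScalpChannels Labels of non-scalp channels (excluded from scalp
#'   processing, never flagged noisy, never re-referenced).
#' @param events List of [event_instance()] objects.
#' @return `signal_recording` object.
#' @export
signal_recording <- function(data, samplingRate, channelLabels,
                             nonScalpChannels = character(0),
                             events = list()) {
  data <- as.matrix(data)
  if (nrow(data) != length(channelLabels)) {
    stop("data has ", nrow(data), " rows but ", length(channelLabels),
         " channel labels")
  }
  if (samplingRate <= 0) stop("samplingRate must be positive")
  if (anyDuplicated(channelLabels)) stop("channel labels must be unique")
  if (length(setdiff(nonScalpChannels, channelLabels)) > 0) {
    stop("nonScalpChannels must be a subset of channelLabels")
  }
  structure(list(data = data, samplingRate = samplingRate,
                 channelLabels = as.character(channelLabels),
                 nonScalpChannels = as.character(nonScalpChannels),
                 events = events),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  cat("<signal_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$samplingRate, " Hz (",
      length(x$nonScalpChannels), " non-scalp, ", length(x$events),
      " events)\n", sep = "")
  invisible(x)
}

.scalp_labels <- function(r) setdiff(r$channelLabels, r$nonScalpChannels)

#' Detect noisy scalp channels
#'
#' A scalp channel is flagged when either its amplitude deviates robustly from
#' the other channels, or it fails to correlate with any of them:
#' \itemize{
#'   \item \emph{Deviation criterion}: per-channel robust standard deviation
#'     (1.4826 x median absolute deviation); a channel is flagged when the
#'     robust z-score of its robust SD — centered at the median and scaled by
#'     1.4826 x MAD across channels — exceeds `deviationZ` in magnitude.
#'   \item \emph{Correlation criterion}: in non-overlapping 1-second windows,
#'     the channel's maximum absolute correlation with any other scalp
#'     channel; a channel is flagged when the median of this across windows
#'     falls below `minCorrelation`. Correlation with a zero-variance signal
#'     is defined as 0, so flat-lined channels are flagged.
#' }
#' Non-scalp channels are never flagged.
#'
#' @param r A [signal_recording()] with at least 2 scalp channels and at
#'   least 1 second of data.
#' @param deviationZ Robust z-score threshold, default 5.0.
#' @param minCorrelation Median max-correlation threshold, default 0.4.
#' @return Character vector of flagged channel labels (in channel order).
#' @export
detect_noisy_channels <- function(r, deviationZ = 5.0, minCorrelation = 0.4) {
  scalp <- .scalp_labels(r)
  if (length(scalp) < 2) stop("need at least 2 scalp channels")
  if (ncol(r$data) < r$samplingRate) stop("need at least 1 second of data")
  x <- r$data[match(scalp, r$channelLabels), , drop = FALSE]

  # deviation criterion
  rsd <- apply(x, 1, stats::mad)                    # 1.4826 * MAD per channel
  center <- stats::median(rsd)
  spread <- stats::mad(rsd)                         # 1.4826 * MAD across channels
  z <- if (spread > 0) {
    (rsd - center) / spread
  } else {
    ifelse(rsd == center, 0, Inf)
  }
  dev_bad <- abs(z) > deviationZ

  # correlation criterion, 1 s non-overlapping windows
  win <- as.integer(r$samplingRate)
  nwin <- floor(ncol(x) / win)
  maxcor <- matrix(NA_real_, nrow = length(scalp), ncol = nwin)
  for (w in seq_len(nwin)) {
    seg <- x[, ((w - 1L) * win + 1L):(w * win), drop = FALSE]
    sds <- apply(seg, 1, stats::sd)
    cm <- suppressWarnings(stats::cor(t(seg)))
    cm[!is.finite(cm)] <- 0                         # zero-variance -> 0
    cm[sds == 0, ] <- 0
    cm[, sds == 0] <- 0
    diag(cm) <- 0
    maxcor[, w] <- apply(abs(cm), 1, max)
  }
  medcor <- apply(maxcor, 1, stats::median)
  cor_bad <- medcor < minCorrelation

  scalp[dev_bad | cor_bad]
}

#' Robust average reference
#'
#' Re-references every scalp channel to the per-sample mean of the scalp
#' channels \emph{not} excluded (typically those flagged noisy are excluded
#' from the reference but still re-referenced). Non-scalp channels are left
#' untouched. After referencing, the mean over retained channels is zero at
#' every sample.
#'
#' @param r A [signal_recording()].
#' @param excluded Labels of scalp channels excluded from the reference
#'   estimate (must leave at least one scalp channel).
#' @return The re-referenced `signal_recording`.
#' @export
robust_average_reference <- function(r, excluded = character(0)) {
  scalp <- .scalp_labels(r)
  if (length(setdiff(excluded, scalp)) > 0) {
    stop("excluded channels must be scalp channels")
  }
  retained <- setdiff(scalp, excluded)
  if (length(retained) == 0) stop("all scalp channels excluded from reference")
  ref <- colMeans(r$data[match(retained, r$channelLabels), , drop = FALSE])
  rows <- match(scalp, r$channelLabels)
  r$data[rows, ] <- sweep(r$data[rows, , drop = FALSE], 2, ref)
  r
}

#' Evenly spaced unit-circle channel positions
#'
#' Fallback electrode geometry when no measured positions are available:
#' channels are placed in label order around the unit circle, so "nearest
#' neighbors" are adjacent channels in recording order.
#'
#' @param labels Channel labels.
#' @return A `length(labels)` x 2 matrix with rownames `labels`.
#' @export
circle_positions <- function(labels) {
  n <- length(labels)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(cos(theta), sin(theta))
  rownames(pos) <- labels
  pos
}

#' Interpolate bad channels from their neighbors
#'
#' Replaces each bad scalp channel by the unweighted mean of its
#' `neighborCount` nearest good scalp channels (Euclidean distance on the
#' supplied positions). All other channels are bit-identical. This is a
#' simple, documented stand-in for spherical-spline interpolation.
#'
#' @param r A [signal_recording()].
#' @param bad Labels of channels to interpolate (subset of scalp channels).
#' @param neighborCount Number of nearest good channels to average, default 4.
#' @param positions Numeric matrix of channel positions with rownames
#'   covering the scalp labels; `NULL` falls back to [circle_positions()].
#' @return The recording with bad channels replaced.
#' @export
interpolate_channels <- function(r, bad, neighborCount = 4, positions = NULL) {
  if (length(bad) == 0) return(r)
  scalp <- .scalp_labels(r)
  if (length(setdiff(bad, scalp)) > 0) {
    stop("bad channels must be scalp channels")
  }
  good <- setdiff(scalp, bad)
  if (length(good) == 0) stop("no good scalp channel left to interpolate from")
  if (is.null(positions)) positions <- circle_positions(scalp)
  if (!all(scalp %in% rownames(positions))) {
    stop("positions must cover every scalp channel (or pass positions = NULL)")
  }
  for (b in bad) {
    d <- sqrt(colSums((t(positions[good, , drop = FALSE]) -
                         positions[b, ])^2))
    nb <- good[order(d)][seq_len(min(neighborCount, length(good)))]
    r$data[match(b, r$channelLabels), ] <-
      colMeans(r$data[match(nb, r$channelLabels), , drop = FALSE])
  }
  r
}

#' Default Level-2 preprocessing pipeline
#'
#' Detect noisy channels, interpolate them from neighbors, then apply a
#' robust average reference excluding the noisy channels from the reference
#' estimate. Returned alongside the processed recording are the flagged and
#' interpolated channel lists and a quality score
#' `1 - flagged / scalp channels`.
#'
#' @param r A [signal_recording()].
#' @param deviationZ,minCorrelation Thresholds for [detect_noisy_channels()].
#' @param neighborCount Neighbors for [interpolate_channels()].
#' @param positions Optional channel positions.
#' @return List: `recording`, `noisyChannels`, `interpolatedChannels`,
#'   `qualityScore`, `parameters`.
#' @export
default_level2_pipeline <- function(r, deviationZ = 5.0, minCorrelation = 0.4,
                                    neighborCount = 4, positions = NULL) {
  noisy <- detect_noisy_channels(r, deviationZ, minCorrelation)
  r2 <- interpolate_channels(r, noisy, neighborCount, positions)
  r2 <- robust_average_reference(r2, excluded = noisy)
  nScalp <- length(.scalp_labels(r))
  list(recording = r2,
       noisyChannels = noisy,
       interpolatedChannels = noisy,
       qualityScore = 1 - length(noisy) / nScalp,
       parameters = list(deviationZ = deviationZ,
                         minCorrelation = minCorrelation,
                         neighborCount = neighborCount))
}

# ---- Level-2 manifest ------------------------------------------------------

.processing_record_to_xml <- function(parent, pr) {
  nd <- xml2::xml_add_child(parent, "processingRecord")
  .add_text_child(nd, "inputRecordingUuid", pr$inputRecordingUuid)
  .add_text_child(nd, "outputFilename", pr$outputFilename)
  .add_text_child(nd, "methodName", pr$methodName)
  .add_text_child(nd, "status", pr$status)
  pn <- xml2::xml_add_child(nd, "parameters")
  for (name in names(pr$parameters)) {
    p <- xml2::xml_add_child(pn, "parameter")
    xml2::xml_set_attr(p, "name", name)
    xml2::xml_set_text(p, .fmt_num(as.numeric(pr$parameters[[name]])))
  }
  nc <- xml2::xml_add_child(nd, "noisyChannels")
  for (l in pr$noisyChannels) .add_text_child(nc, "channelLabel", l)
  ic <- xml2::xml_add_child(nd, "interpolatedChannels")
  for (l in pr$interpolatedChannels) .add_text_child(ic, "channelLabel", l)
  .add_text_child(nd, "qualityScore", .fmt_num(pr$qualityScore))
}

#' Write a Level-2 manifest
#'
#' The Level-2 `study_description.xml` embeds the parent Level-1 manifest
#' verbatim (self-containment survives file moves) and records one processing
#' record per parent data recording.
#'
#' @param l2 List with `pipelineDescription`, `processingRecords` and
#'   `parentLevel1Xml` (the parent document as text).
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_level2_manifest <- function(l2, path) {
  doc <- xml2::xml_new_root("studyLevel2")
  .add_text_child(doc, "essVersion", l2$essVersion %||% "2.0")
  .add_text_child(doc, "pipelineDescription", l2$pipelineDescription)
  prs <- xml2::xml_add_child(doc, "processingRecords")
  for (pr in l2$processingRecords) .processing_record_to_xml(prs, pr)
  parent <- xml2::xml_add_child(doc, "parentLevel1")
  xml2::xml_add_child(parent, xml2::xml_root(xml2::read_xml(l2$parentLevel1Xml)))
  xml2::write_xml(doc, path, options = c("format", "no_declaration"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a Level-2 manifest
#'
#' @param path Path to a Level-2 `study_description.xml`.
#' @return List with `essVersion`, `pipelineDescription`,
#'   `processingRecords`, `parentLevel1Xml` (text) and `parentManifest` (the
#'   embedded Level-1 manifest, parsed).
#' @export
read_level2_manifest <- function(path) {
  root <- xml2::xml_root(xml2::read_xml(path))
  if (xml2::xml_name(root) != "studyLevel2") {
    stop("not a Level-2 manifest: root element is <", xml2::xml_name(root), ">")
  }
  prs <- lapply(xml2::xml_find_all(root, "processingRecords/processingRecord"),
                function(nd) {
    params <- xml2::xml_find_all(nd, "parameters/parameter")
    pv <- lapply(params, function(p) as.numeric(xml2::xml_text(p)))
    names(pv) <- vapply(params, function(p) xml2::xml_attr(p, "name"),
                        character(1))
    list(inputRecordingUuid = .child_text(nd, "inputRecordingUuid"),
         outputFilename = .child_text(nd, "outputFilename"),
         methodName = .child_text(nd, "methodName"),
         status = .child_text(nd, "status"),
         parameters = pv,
         noisyChannels = xml2::xml_text(
           xml2::xml_find_all(nd, "noisyChannels/channelLabel")),
         interpolatedChannels = xml2::xml_text(
           xml2::xml_find_all(nd, "interpolatedChannels/channelLabel")),
         qualityScore = .num_or_na(.child_text(nd, "qualityScore")))
  })
  parentNode <- xml2::xml_find_first(root, "parentLevel1/studyLevel1")
  if (inherits(parentNode, "xml_missing")) {
    stop("Level-2 manifest embeds no parent Level-1 content")
  }
  parentXml <- as.character(parentNode)
  tmp <- tempfile(fileext = ".xml")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(parentXml, tmp, useBytes = TRUE)
  list(essVersion = .child_text(root, "essVersion"),
       pipelineDescription = .child_text(root, "pipelineDescription"),
       processingRecords = prs,
       parentLevel1Xml = parentXml,
       parentManifest = read_level1_manifest(tmp))
}

# Load one recording of a Level-1 container as a signal_recording, with
# channel metadata from its parameter set and events from the event file.
read_container_recording <- function(root, m, sessionIdx, recIdx) {
  s <- m$sessions[[sessionIdx]]
  dr <- s$dataRecordings[[recIdx]]
  path <- file.path(root, "session", .fmt_int(s$number), dr$essFilename)
  edf <- read_edf(path)
  rs <- NULL
  for (cand in m$recordingParameterSets) {
    if (cand$id == dr$parameterSetId) rs <- cand
  }
  labels <- edf$channelLabels
  nonScalp <- character(0)
  if (!is.null(rs)) {
    labels <- unlist(lapply(rs$modalities, `[[`, "channelLabels"))
    nonScalp <- unlist(lapply(rs$modalities, `[[`, "nonScalpChannelLabels"))
  }
  events <- list()
  evp <- file.path(root, "session", .fmt_int(s$number),
                   dr$eventInstanceFilename)
  if (nzchar(dr$eventInstanceFilename) && file.exists(evp)) {
    events <- parse_event_instance_file(readChar(evp, file.size(evp),
                                                 useBytes = TRUE))
  }
  signal_recording(edf$data, edf$samplingRate, labels, nonScalp, events)
}

#' Create a Standardized Data Level 2 container
#'
#' Fully automated: validates the Level-1 container, runs the preprocessing
#' pipeline (default: noisy-channel detection, neighbor interpolation, robust
#' average reference) over every recording, writes processed signals as EDF
#' into a mirrored `session/` layout, a per-recording quality report under
#' `reports/`, and a Level-2 manifest embedding the parent manifest verbatim.
#' A recording that fails to process is recorded with status `"failed"` and
#' the run continues.
#'
#' @param level1Root Root of a valid Level-1 container.
#' @param destDir Destination Level-2 container root.
#' @param pipeline Processing function `function(r) -> list(recording,
#'   noisyChannels, interpolatedChannels, qualityScore, parameters)`; `NULL`
#'   uses [default_level2_pipeline()] with the thresholds below.
#' @param deviationZ,minCorrelation,neighborCount Default-pipeline thresholds.
#' @param overwrite Allow building into a non-empty `destDir`.
#' @return List with `manifest` (the Level-2 manifest structure), `root`, and
#'   `nFailed`.
#' @export
create_level2_container <- function(level1Root, destDir, pipeline = NULL,
                                    deviationZ = 5.0, minCorrelation = 0.4,
                                    neighborCount = 4, overwrite = FALSE) {
  m <- read_level1_manifest(file.path(level1Root, "study_description.xml"))
  v <- validate_level1(m, containerRoot = level1Root)
  errs <- v$issues[v$issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("Level-1 container fails validation; first: [", errs$checkId[1], "] ",
         errs$message[1])
  }
  m <- v$fixed
  if (dir.exists(destDir) && length(dir(destDir, all.files = TRUE,
                                        no.. = TRUE)) > 0 && !overwrite) {
    stop("destination directory is not empty: ", destDir)
  }
  dir.create(file.path(destDir, "session"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(destDir, "reports"), showWarnings = FALSE)

  if (is.null(pipeline)) {
    pipeline <- function(r) {
      default_level2_pipeline(r, deviationZ, minCorrelation, neighborCount)
    }
  }

  records <- list()
  nFailed <- 0L
  for (i in seq_along(m$sessions)) {
    s <- m$sessions[[i]]
    sdir <- file.path(destDir, "session", .fmt_int(s$number))
    dir.create(sdir, showWarnings = FALSE)
    for (j in seq_along(s$dataRecordings)) {
      dr <- s$dataRecordings[[j]]
      outRel <- file.path("session", .fmt_int(s$number), dr$essFilename)
      pr <- tryCatch({
        r <- read_container_recording(level1Root, m, i, j)
        res <- pipeline(r)
        write_edf(file.path(destDir, outRel), res$recording$data,
                  res$recording$samplingRate, res$recording$channelLabels)
        # keep the event-instance file alongside the processed signal
        file.copy(file.path(level1Root, "session", .fmt_int(s$number),
                            dr$eventInstanceFilename),
                  file.path(sdir, dr$eventInstanceFilename), overwrite = TRUE)
        list(inputRecordingUuid = dr$uuid, outputFilename = outRel,
             methodName = "default_level2_pipeline",
             status = "ok",
             parameters = res$parameters,
             noisyChannels = res$noisyChannels,
             interpolatedChannels = res$interpolatedChannels,
             qualityScore = res$qualityScore)
      }, error = function(e) {
        list(inputRecordingUuid = dr$uuid, outputFilename = outRel,
             methodName = "default_level2_pipeline",
             status = paste0("failed: ", conditionMessage(e)),
             parameters = list(), noisyChannels = character(0),
             interpolatedChannels = character(0), qualityScore = NA_real_)
      })
      if (pr$status != "ok") nFailed <- nFailed + 1L
      records[[length(records) + 1L]] <- pr
      report <- file.path(destDir, "reports",
                          paste0("quality_", dr$uuid, ".txt"))
      writeLines(c(
        paste0("recording: ", dr$uuid),
        paste0("session: ", .fmt_int(s$number)),
        paste0("status: ", pr$status),
        paste0("noisy channels: ",
               paste(pr$noisyChannels, collapse = ", ")),
        paste0("interpolated channels: ",
               paste(pr$interpolatedChannels, collapse = ", ")),
        paste0("quality score: ", .fmt_num(pr$qualityScore))), report)
    }
  }

  parentXml <- paste(readLines(file.path(level1Root, "study_description.xml"),
                               encoding = "UTF-8", warn = FALSE),
                     collapse = "\n")
  l2 <- list(essVersion = m$essVersion,
             pipelineDescription = paste(
               "Automated Level-2 preprocessing: robust-deviation and",
               "correlation-based noisy channel detection, nearest-neighbor",
               "interpolation, robust average reference."),
             processingRecords = records,
             parentLevel1Xml = parentXml)
  write_level2_manifest(l2, file.path(destDir, "study_description.xml"))
  list(manifest = l2, root = destDir, nFailed = nFailed)
}
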