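# Level-1 container assembly: ESS file naming, event-instance files, and the
# standardized folder layout (study_description.xml + README + session/<N>/).

.sanitize_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Build an ESS container filename
#'
#' Filenames encapsulate session number, task label and the original file
#' name, following the fixed template
#' `<prefix>_session_<N>_<taskLabel>_<originalStem>.<ext>` with prefix
#' `eeg`, `event` or `channel_locations`. Event files always get extension
#' `.tsv`. Unsafe characters in the original name are replaced by underscores,
#' never rejected, so the mapping is deterministic and collision-free within a
#' session for distinct original stems.
#'
#' @param sessionNumber Positive integer session number.
#' @param taskLabel Filesystem-safe task label (empty is an error).
#' @param originalName Original file name (basename used).
#' @param kind One of `"data"`, `"event"`, `"channelLocations"`.
#' @return The container filename.
#' @export
#' @examples
#' ess_filename(1, "oddball", "subj01.bdf", "data")
#' ess_filename(1, "oddball", "subj01.bdf", "event")
ess_filename <- function(sessionNumber, taskLabel, originalName,
                         kind = c("data", "event", "channelLocations")) {
  kind <- match.arg(kind)
  if (!nzchar(taskLabel)) stop("taskLabel must be non-empty")
  if (!nzchar(originalName)) stop("originalName must be non-empty")
  prefix <- switch(kind, data = "eeg", event = "event",
                   channelLocations = "channel_locations")
  base <- basename(originalName)
  stem <- .sanitize_name(tools::file_path_sans_ext(base))
  ext <- if (kind == "event") "tsv" else tools::file_ext(base)
  name <- sprintf("%s_session_%s_%s_%s", prefix, .fmt_int(sessionNumber),
                  .sanitize_name(taskLabel), stem)
  if (nzchar(ext)) paste0(name, ".", ext) else name
}

#' Render an event-instance file
#'
#' Produces the per-recording tab-separated event file: one line per event in
#' ascending latency order (ties keep input order), three columns — code,
#' latency in seconds with 6 decimals, and the full HED annotation (category
#' tag followed by the mapped HED string). No header line is written.
#'
#' @param events List of [event_instance()] objects (hedString may be `NULL`;
#'   the annotation is taken from the mapping).
#' @param mapping List of [event_code_mapping()] objects.
#' @param task Task label selecting the applicable mappings.
#' @return File content as a single UTF-8 string (empty for no events).
#' @export
render_event_instance_file <- function(events, mapping, task) {
  if (length(events) == 0) return("")
  lat <- vapply(events, `[[`, numeric(1), "latency")
  if (any(lat < 0)) stop("negative event latency: ", min(lat))
  map <- list()
  for (em in mapping) {
    if (em$taskLabel == task) map[[em$code]] <- em
  }
  ord <- order(lat)  # stable in R: ties keep input order
  lines <- vapply(events[ord], function(ev) {
    em <- map[[ev$code]]
    if (is.null(em)) {
      stop("event code '", ev$code, "' has no mapping for task '", task, "'")
    }
    parts <- character(0)
    if (inherits(em$categoryTag, "hed_tag")) parts <- format(em$categoryTag)
    if (inherits(em$hedString, "hed_string")) {
      parts <- c(parts, format(em$hedString))
    }
    sprintf("%s\t%.6f\t%s", ev$code, ev$latency, paste(parts, collapse = ", "))
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse an event-instance file
#'
#' Inverse of [render_event_instance_file()]: reads the 3-column tab-separated
#' content back into event instances with parsed HED strings.
#'
#' @param content File content as a single string.
#' @return List of [event_instance()] objects (empty for empty content).
#' @export
parse_event_instance_file <- function(content) {
  if (length(content) != 1L || !nzchar(trimws(content))) return(list())
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      stop("line ", i, ": expected 3 tab-separated columns, got ",
           length(parts))
    }
    lat <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(lat)) stop("line ", i, ": non-numeric latency '", parts[2], "'")
    out[[i]] <- event_instance(parts[1], lat,
                               if (nzchar(parts[3])) parts[3] else NULL)
  }
  out
}

# Read a sidecar event log: two tab-separated columns, code TAB latency.
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(path, " line ", i, ": expected 'code<TAB>latency'")
    }
    event_instance(parts[1], as.numeric(parts[2]))
  })
}

.default_event_log_path <- function(recordingPath) {
  paste0(tools::file_path_sans_ext(recordingPath), ".events.tsv")
}

#' Assemble a Standardized Data Level 1 container
#'
#' Validates the manifest (auto-fixes applied; any error aborts), stages all
#' source recordings and sidecar event logs (all-or-nothing: a missing source
#' aborts before any copy), then realizes the Level-1 layout: raw payloads
#' copied byte-identically into numbered `session/` subdirectories under ESS
#' names, an event-instance file generated per recording from its event log
#' and the manifest's code-to-HED mapping, a README stub, an
#' `additional_documentation/` directory, and the updated manifest written as
#' `study_description.xml`. The finished container passes full validation
#' including file-level checks.
#'
#' @param m A [study_level1_manifest()] (may carry empty UUIDs; auto-fixed).
#' @param sourceDir Directory holding the original recordings.
#' @param destDir Destination container root (must be empty unless
#'   `overwrite`).
#' @param eventLogs Optional named character vector mapping
#'   `originalFileNameAndPath` to event-log paths; by default the sidecar
#'   `<original stem>.events.tsv` next to each recording is used.
#' @param overwrite Allow building into a non-empty `destDir`.
#' @return A list with `manifest` (updated) and `layout` (paths: `root`,
#'   `manifestPath`, `readmePath`, `additionalDocsDir`, `sessionsDir`).
#' @export
create_level1_container <- function(m, sourceDir, destDir, eventLogs = NULL,
                                    overwrite = FALSE) {
  v <- validate_level1(m)
  errs <- v$issues[v$issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("manifest has ", nrow(errs), " validation error(s); first: [",
         errs$checkId[1], "] ", errs$message[1])
  }
  m <- v$fixed

  # stage: resolve every source file before touching destDir
  staged <- list()
  for (i in seq_along(m$sessions)) {
    s <- m$sessions[[i]]
    for (j in seq_along(s$dataRecordings)) {
      dr <- s$dataRecordings[[j]]
      src <- file.path(sourceDir, dr$originalFileNameAndPath)
      if (!file.exists(src)) {
        stop("source recording missing: ", src, " (no files were copied)")
      }
      ev <- if (!is.null(eventLogs) &&
                dr$originalFileNameAndPath %in% names(eventLogs)) {
        eventLogs[[dr$originalFileNameAndPath]]
      } else {
        .default_event_log_path(src)
      }
      if (!file.exists(ev)) {
        stop("event log missing for ", dr$originalFileNameAndPath, ": ", ev,
             " (no files were copied)")
      }
      staged[[length(staged) + 1L]] <- list(si = i, ri = j, src = src,
                                            events = read_event_log(ev))
    }
  }

  if (dir.exists(destDir) && length(dir(destDir, all.files = TRUE,
                                        no.. = TRUE)) > 0 && !overwrite) {
    stop("destination directory is not empty: ", destDir,
         " (use overwrite = TRUE to rebuild)")
  }
  dir.create(destDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(destDir, "additional_documentation"),
             showWarnings = FALSE)
  dir.create(file.path(destDir, "session"), showWarnings = FALSE)

  for (st in staged) {
    s <- m$sessions[[st$si]]
    dr <- s$dataRecordings[[st$ri]]
    sdir <- file.path(destDir, "session", .fmt_int(s$number))
    dir.create(sdir, showWarnings = FALSE)
    orig <- basename(dr$originalFileNameAndPath)
    dataName <- ess_filename(s$number, s$taskLabel, orig, "data")
    eventName <- ess_filename(s$number, s$taskLabel, orig, "event")
    file.copy(st$src, file.path(sdir, dataName), overwrite = TRUE)
    content <- render_event_instance_file(st$events, m$eventCodeMappings,
                                          s$taskLabel)
    writeLines(content, file.path(sdir, eventName), sep = "", useBytes = TRUE)
    # guard: annotated events must lie within the recording when readable
    hdr <- tryCatch(read_edf_header(file.path(sdir, dataName)),
                    error = function(e) NULL)
    if (!is.null(hdr) && length(st$events) > 0) {
      dur <- hdr$nRecords * hdr$recordDuration
      lat <- vapply(st$events, `[[`, numeric(1), "latency")
      if (any(lat > dur)) {
        stop("recording ", orig, ": ", sum(lat > dur),
             " event(s) beyond recording duration ", dur, " s")
      }
    }
    m$sessions[[st$si]]$dataRecordings[[st$ri]]$essFilename <- dataName
    m$sessions[[st$si]]$dataRecordings[[st$ri]]$eventInstanceFilename <- eventName
  }

  readme <- file.path(destDir, "README.txt")
  writeLines(c(
    paste0("Study: ", m$title),
    paste0("ESS version: ", m$essVersion),
    "Standardized Data Level 1 container.",
    "Layout: study_description.xml (manifest), session/<N>/ (recordings and",
    "tab-separated event-instance files), additional_documentation/.",
    paste0("Built by esskit ",
           as.character(utils::packageVersion("esskit")),
           " on ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    readme)

  manifestPath <- file.path(destDir, "study_description.xml")
  write_level1_manifest(m, manifestPath)

  check <- validate_level1(m, containerRoot = destDir)
  errs <- check$issues[check$issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("built container fails validation; first: [", errs$checkId[1], "] ",
         errs$message[1])
  }

  list(manifest = m,
       layout = list(root = destDir,
                     manifestPath = manifestPath,
                     readmePath = readme,
                     additionalDocsDir = file.path(destDir,
                                                   "additional_documentation"),
                     sessionsDir = file.path(destDir, "session")))
}
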