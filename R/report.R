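# Self-contained HTML study report, generated directly from the manifest data
# model (summarize_study and the provenance parser) rather than through a
# stylesheet, so it renders identically from local files in any browser.

.h <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.html_table <- function(headers, rows) {
  body <- if (length(rows) == 0) "" else paste(vapply(rows, function(r) {
    paste0("<tr>", paste0("<td>", .h(as.character(r)), "</td>",
                          collapse = ""), "</tr>")
  }, character(1)), collapse = "\n")
  paste0("<table><tr>",
         paste0("<th>", .h(headers), "</th>", collapse = ""),
         "</tr>\n", body, "</table>")
}

.report_css <- paste(
  "body{font-family:sans-serif;margin:2em;color:#222}",
  "h1{border-bottom:2px solid #369}",
  "table{border-collapse:collapse;margin:1em 0}",
  "th,td{border:1px solid #aaa;padding:4px 10px;text-align:left}",
  "th{background:#e8eef7}")

#' Render an HTML study report from a manifest
#'
#' Produces a self-contained HTML document (inline styles, no external
#' fetches) for a manifest at any container level: study summary, per-session
#' table, event-code table with HED strings, and — for Level-2 and derived
#' containers — the processing/provenance chain and per-recording quality
#' table. Every number shown is derived from [summarize_study()] or the
#' provenance parser, never counted independently in the template. Output is
#' deterministic given the manifest bytes.
#'
#' @param manifestPath Path to a `study_description.xml` at any level.
#' @return The HTML document as a single string.
#' @export
render_html_report <- function(manifestPath) {
  root <- tryCatch(xml2::xml_root(xml2::read_xml(manifestPath)),
                   error = function(e) {
                     stop("cannot parse manifest: ", conditionMessage(e))
                   })
  kind <- xml2::xml_name(root)
  chainHtml <- ""
  qualityHtml <- ""
  if (kind == "studyLevel1") {
    m <- read_level1_manifest(manifestPath)
  } else if (kind %in% c("studyLevel2", "studyLevelDerived")) {
    chain <- provenance_chain(manifestPath)
    if (is.null(chain$level1)) {
      stop("provenance chain does not reach a Level-1 manifest")
    }
    m <- chain$level1
    chainHtml <- paste0(
      "<h2>Processing chain</h2>",
      .html_table(c("step", "function", "parameters"),
                  lapply(seq_along(chain$filters), function(i) {
        fd <- chain$filters[[i]]
        params <- paste(sprintf("%s=%s", names(fd$parameters),
                                vapply(fd$parameters, as.character,
                                       character(1))), collapse = ", ")
        c(i, fd$functionName, params)
      })))
    if (kind == "studyLevel2") {
      l2 <- read_level2_manifest(manifestPath)
      qualityHtml <- paste0(
        "<h2>Recording quality</h2>",
        .html_table(c("recording uuid", "status", "noisy channels",
                      "quality score"),
                    lapply(l2$processingRecords, function(pr) {
          c(pr$inputRecordingUuid, pr$status,
            paste(pr$noisyChannels, collapse = " "),
            ifelse(is.na(pr$qualityScore), "",
                   format(pr$qualityScore, digits = 4)))
        })))
    }
  } else {
    stop("unrecognized manifest root <", kind, ">")
  }

  sm <- summarize_study(m)
  summaryHtml <- .html_table(c("field", "value"), list(
    c("Title", sm$title),
    c("ESS version", sm$essVersion),
    c("Container level", kind),
    c("Sessions", sm$nSessions),
    c("Subjects", sm$nSubjects),
    c("Data recordings", sm$nRecordings),
    c("Scalp EEG channels", sm$scalpEegChannels),
    c("Sampling rate(s) [Hz]", paste(sm$samplingRates, collapse = ", ")),
    c("Tasks", paste(sm$taskLabels, collapse = ", "))))

  sessionHtml <- .html_table(
    c("session", "task", "subjects", "recordings"),
    lapply(m$sessions, function(s) {
      c(.fmt_int(s$number), s$taskLabel,
        paste(vapply(s$subjects, `[[`, character(1), "labId"),
              collapse = " "),
        length(s$dataRecordings))
    }))

  eventHtml <- .html_table(
    c("task", "code", "category", "HED string"),
    lapply(m$eventCodeMappings, function(em) {
      c(em$taskLabel, em$code,
        if (inherits(em$categoryTag, "hed_tag")) format(em$categoryTag) else "",
        if (inherits(em$hedString, "hed_string")) format(em$hedString) else "")
    }))

  modHtml <- .html_table(
    c("parameter set", "modality", "channels", "non-scalp", "rate [Hz]"),
    lapply(seq_len(nrow(sm$modalities)), function(i) {
      r <- sm$modalities[i, ]
      c(r$parameterSetId, r$type, r$nChannels, r$nNonScalp, r$samplingRate)
    }))

  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
         "<title>", .h(sm$title), "</title>",
         "<style>", .report_css, "</style></head><body>",
         "<h1>", .h(sm$title), "</h1>",
         "<h2>Study summary</h2>", summaryHtml,
         chainHtml,
         "<h2>Recording modalities</h2>", modHtml,
         "<h2>Sessions</h2>", sessionHtml,
         "<h2>Event codes</h2>", eventHtml,
         qualityHtml,
         "</body></html>\n")
}
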