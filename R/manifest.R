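# Level-1 study model: domain-type constructors and the pinned XML dialect for
# study_description.xml. The reader and writer are inverse up to canonical form
# (unknown root children are preserved under <additionalMetadata>).

.fmt_int <- function(x) {
  if (length(x) != 1L || is.na(x)) "" else format(as.integer(x), scientific = FALSE)
}

.fmt_num <- function(x) {
  if (length(x) != 1L || is.na(x)) "" else format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

.num_or_na <- function(txt) {
  txt <- trimws(txt)
  if (length(txt) != 1L || !nzchar(txt)) return(NA_real_)
  suppressWarnings(as.numeric(txt))
}

.chr1 <- function(x, what) {
  if (is.null(x)) return("")
  if (length(x) != 1L || is.na(x)) stop(what, " must be a single string")
  as.character(x)
}

#' Task specification
#'
#' @param taskLabel Short filesystem-safe label naming the task.
#' @param description Free-text description.
#' @return `task_spec` object.
#' @export
task_spec <- function(taskLabel, description = "") {
  structure(list(taskLabel = .chr1(taskLabel, "taskLabel"),
                 description = .chr1(description, "description")),
            class = "task_spec")
}

#' Channel modality within a recording parameter set
#'
#' A modality is a contiguous block of consecutively numbered recording
#' channels of one signal kind (EEG, EOG, ...) sharing a sampling rate.
#' Channel numbering is 1-based.
#'
#' @param type One of EEG, EOG, GSR, ECG, Mocap, EyeTracking, Other.
#' @param startChannel,endChannel Inclusive 1-based channel range.
#' @param samplingRate Sampling rate in Hz.
#' @param channelLabels One label per channel in the range.
#' @param nonScalpChannelLabels Labels of channels not on the scalp (excluded
#'   from scalp-level processing such as average referencing).
#' @param channelLocationType `"10-20"`, `"Custom"` or `"n/a"`.
#' @param referenceLabel Label of the recording reference, if any.
#' @return `ess_modality` object.
#' @export
ess_modality <- function(type, startChannel, endChannel, samplingRate,
                         channelLabels, nonScalpChannelLabels = character(0),
                         channelLocationType = "n/a", referenceLabel = "") {
  structure(list(
    type = .chr1(type, "type"),
    startChannel = as.numeric(startChannel),
    endChannel = as.numeric(endChannel),
    samplingRate = as.numeric(samplingRate),
    channelLabels = as.character(channelLabels),
    nonScalpChannelLabels = as.character(nonScalpChannelLabels),
    channelLocationType = .chr1(channelLocationType, "channelLocationType"),
    referenceLabel = .chr1(referenceLabel, "referenceLabel")),
    class = "ess_modality")
}

#' Recording parameter set
#'
#' Describes the channel layout shared by one or more data recordings, as a
#' list of modalities whose channel ranges must tile `1..N` without gaps
#' (enforced by the validator, not the constructor).
#'
#' @param id Identifier referenced by recordings, e.g. `"rset_1"`.
#' @param modalities List of [ess_modality()] objects.
#' @return `recording_parameter_set` object.
#' @export
recording_parameter_set <- function(id, modalities) {
  structure(list(id = .chr1(id, "id"), modalities = modalities),
            class = "recording_parameter_set")
}

#' Anonymized subject record
#'
#' The schema deliberately exposes no identifying fields (no name, address,
#' email, phone or national-id); subjects are referenced only by lab-specific
#' anonymized codes.
#'
#' @param labId Anonymized lab-specific subject code.
#' @param group,gender,hand,medication Free-text attributes.
#' @param age Age in years, `NA` if unknown.
#' @param height,weight Height (cm) and weight (kg), `NA` if unknown.
#' @param channelLocationFile Relative path to a measured channel-location
#'   file, or empty when a standard montage is declared.
#' @return `subject_record` object.
#' @export
subject_record <- function(labId, group = "", gender = "", age = NA_real_,
                           hand = "", height = NA_real_, weight = NA_real_,
                           medication = "", channelLocationFile = "") {
  structure(list(
    labId = .chr1(labId, "labId"),
    group = .chr1(group, "group"),
    gender = .chr1(gender, "gender"),
    age = as.numeric(age),
    hand = .chr1(hand, "hand"),
    height = as.numeric(height),
    weight = as.numeric(weight),
    medication = .chr1(medication, "medication"),
    channelLocationFile = .chr1(channelLocationFile, "channelLocationFile")),
    class = "subject_record")
}

#' Data recording entry
#'
#' Associates one continuous raw recording file with a recording parameter
#' set. `essFilename` and `eventInstanceFilename` are filled by the container
#' builder; a missing `uuid` is filled by the validator's auto-fix.
#'
#' @param uuid Version-4 UUID text, or empty to be generator-filled.
#' @param originalFileNameAndPath Path of the raw file relative to the source
#'   directory (forward slashes).
#' @param essFilename,eventInstanceFilename Container filenames (builder-filled).
#' @param parameterSetId Id of the governing [recording_parameter_set()].
#' @param startDateTime ISO-8601 start time or empty.
#' @return `data_recording` object.
#' @export
data_recording <- function(uuid = "", originalFileNameAndPath,
                           essFilename = "", eventInstanceFilename = "",
                           parameterSetId, startDateTime = "") {
  structure(list(
    uuid = .chr1(uuid, "uuid"),
    originalFileNameAndPath = .chr1(originalFileNameAndPath,
                                    "originalFileNameAndPath"),
    essFilename = .chr1(essFilename, "essFilename"),
    eventInstanceFilename = .chr1(eventInstanceFilename,
                                  "eventInstanceFilename"),
    parameterSetId = .chr1(parameterSetId, "parameterSetId"),
    startDateTime = .chr1(startDateTime, "startDateTime")),
    class = "data_recording")
}

#' Session record
#'
#' A session is all data collected with a single montage application from one
#' subject (or several recorded simultaneously).
#'
#' @param number Positive integer session number (unique within the study).
#' @param taskLabel Label of the task performed.
#' @param subjects List of [subject_record()] objects.
#' @param dataRecordings List of [data_recording()] objects.
#' @param notes Free-text notes.
#' @return `session_record` object.
#' @export
session_record <- function(number, taskLabel, subjects, dataRecordings,
                           notes = "") {
  structure(list(
    number = as.numeric(number),
    taskLabel = .chr1(taskLabel, "taskLabel"),
    subjects = subjects,
    notes = .chr1(notes, "notes"),
    dataRecordings = dataRecordings),
    class = "session_record")
}

#' Event code mapping
#'
#' Maps a task-specific event code (label of at most 20 characters) to its
#' category tag and full HED annotation string.
#'
#' @param taskLabel Task the mapping belongs to.
#' @param code Event code/label, 1-20 characters.
#' @param categoryTag The required event-category tag ([hed_tag()] or string).
#' @param hedString The HED annotation ([parse_hed_string()] result or string).
#' @param description Free text.
#' @return `event_code_mapping` object.
#' @export
event_code_mapping <- function(taskLabel, code, categoryTag, hedString,
                               description = "") {
  if (is.character(categoryTag) && nzchar(categoryTag)) {
    categoryTag <- hed_tag(categoryTag)
  }
  if (is.character(hedString) && nzchar(hedString)) {
    hedString <- parse_hed_string(hedString)
  }
  structure(list(
    taskLabel = .chr1(taskLabel, "taskLabel"),
    code = .chr1(code, "code"),
    categoryTag = categoryTag,
    hedString = hedString,
    description = .chr1(description, "description")),
    class = "event_code_mapping")
}

#' Event instance
#'
#' One row of a per-recording event-instance file: code, latency in seconds
#' from the start of the recording, and the full HED annotation.
#'
#' @param code Event code.
#' @param latency Seconds from recording start (non-negative).
#' @param hedString Parsed `hed_string` (or string), or `NULL`.
#' @return `event_instance` object.
#' @export
event_instance <- function(code, latency, hedString = NULL) {
  if (is.character(hedString)) hedString <- parse_hed_string(hedString)
  structure(list(code = .chr1(code, "code"), latency = as.numeric(latency),
                 hedString = hedString),
            class = "event_instance")
}

#' Level-1 study manifest
#'
#' The in-memory form of `study_description.xml`, the "header" of a Level-1
#' container: study metadata, tasks, recording parameter sets, sessions with
#' subjects and data recordings, and the event-code-to-HED mapping table.
#'
#' @param title,description Study title and description.
#' @param essVersion Schema version text, default `"2.0"`.
#' @param studyUuid Study UUID (auto-fixed by the validator when empty).
#' @param tasks List of [task_spec()].
#' @param recordingParameterSets List of [recording_parameter_set()].
#' @param sessions List of [session_record()].
#' @param eventCodeMappings List of [event_code_mapping()].
#' @param publications,pointOfContact,license Free-text metadata.
#' @return `study_level1_manifest` object.
#' @export
study_level1_manifest <- function(title, description = "", essVersion = "2.0",
                                  studyUuid = "", tasks = list(),
                                  recordingParameterSets = list(),
                                  sessions = list(),
                                  eventCodeMappings = list(),
                                  publications = "", pointOfContact = "",
                                  license = "") {
  structure(list(
    title = .chr1(title, "title"),
    description = .chr1(description, "description"),
    essVersion = .chr1(essVersion, "essVersion"),
    studyUuid = .chr1(studyUuid, "studyUuid"),
    publications = .chr1(publications, "publications"),
    pointOfContact = .chr1(pointOfContact, "pointOfContact"),
    license = .chr1(license, "license"),
    tasks = tasks,
    recordingParameterSets = recordingParameterSets,
    sessions = sessions,
    eventCodeMappings = eventCodeMappings,
    additionalMetadata = character(0)),
    class = "study_level1_manifest")
}

#' @export
print.study_level1_manifest <- function(x, ...) {
  cat("<study_level1_manifest> \"", x$title, "\" (ESS ", x$essVersion, ")\n",
      "  tasks: ", length(x$tasks),
      ", parameter sets: ", length(x$recordingParameterSets),
      ", sessions: ", length(x$sessions),
      ", event mappings: ", length(x$eventCodeMappings), "\n", sep = "")
  invisible(x)
}

#' Generate a random version-4 UUID
#'
#' Lowercase hyphenated text drawn from R's RNG stream (hence reproducible
#' under a seed).
#'
#' @return A single UUID string.
#' @export
ess_uuid <- function() {
  hx <- c(0:9, letters[1:6])
  d <- sample(hx, 32, replace = TRUE)
  d[13] <- "4"
  d[17] <- sample(c("8", "9", "a", "b"), 1)
  paste0(paste(d[1:8], collapse = ""), "-", paste(d[9:12], collapse = ""), "-",
         paste(d[13:16], collapse = ""), "-", paste(d[17:20], collapse = ""),
         "-", paste(d[21:32], collapse = ""))
}

.is_uuid <- function(x) {
  grepl("^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$", x)
}

# ---- XML writing -----------------------------------------------------------

.add_text_child <- function(parent, name, value) {
  nd <- xml2::xml_add_child(parent, name)
  if (nzchar(value)) xml2::xml_set_text(nd, value)
  nd
}

.modality_to_xml <- function(parent, mo) {
  nd <- xml2::xml_add_child(parent, "modality")
  .add_text_child(nd, "type", mo$type)
  .add_text_child(nd, "startChannel", .fmt_int(mo$startChannel))
  .add_text_child(nd, "endChannel", .fmt_int(mo$endChannel))
  .add_text_child(nd, "samplingRate", .fmt_num(mo$samplingRate))
  labs <- xml2::xml_add_child(nd, "channelLabels")
  for (l in mo$channelLabels) .add_text_child(labs, "channelLabel", l)
  nsl <- xml2::xml_add_child(nd, "nonScalpChannelLabels")
  for (l in mo$nonScalpChannelLabels) .add_text_child(nsl, "channelLabel", l)
  .add_text_child(nd, "channelLocationType", mo$channelLocationType)
  .add_text_child(nd, "referenceLabel", mo$referenceLabel)
}

#' Write a Level-1 manifest as study_description.xml
#'
#' Serializes to the package's pinned UTF-8 XML dialect (see the shipped XSD in
#' `inst/extdata/ess_level1.xsd`). Empty optional fields are emitted as empty
#' elements rather than omitted, so output is canonical and diffs are stable.
#' `read_level1_manifest(write_level1_manifest(m))` reproduces `m`
#' field-for-field.
#'
#' @param m A [study_level1_manifest()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_level1_manifest <- function(m, path) {
  doc <- xml2::xml_new_root("studyLevel1")
  .add_text_child(doc, "title", m$title)
  .add_text_child(doc, "description", m$description)
  .add_text_child(doc, "essVersion", m$essVersion)
  .add_text_child(doc, "studyUuid", m$studyUuid)
  .add_text_child(doc, "publications", m$publications)
  .add_text_child(doc, "pointOfContact", m$pointOfContact)
  .add_text_child(doc, "license", m$license)
  tasks <- xml2::xml_add_child(doc, "tasks")
  for (t in m$tasks) {
    nd <- xml2::xml_add_child(tasks, "task")
    .add_text_child(nd, "taskLabel", t$taskLabel)
    .add_text_child(nd, "description", t$description)
  }
  rsets <- xml2::xml_add_child(doc, "recordingParameterSets")
  for (rs in m$recordingParameterSets) {
    nd <- xml2::xml_add_child(rsets, "recordingParameterSet")
    .add_text_child(nd, "id", rs$id)
    mods <- xml2::xml_add_child(nd, "modalities")
    for (mo in rs$modalities) .modality_to_xml(mods, mo)
  }
  sessions <- xml2::xml_add_child(doc, "sessions")
  for (s in m$sessions) {
    nd <- xml2::xml_add_child(sessions, "session")
    .add_text_child(nd, "number", .fmt_int(s$number))
    .add_text_child(nd, "taskLabel", s$taskLabel)
    .add_text_child(nd, "notes", s$notes)
    subs <- xml2::xml_add_child(nd, "subjects")
    for (su in s$subjects) {
      sn <- xml2::xml_add_child(subs, "subject")
      .add_text_child(sn, "labId", su$labId)
      .add_text_child(sn, "group", su$group)
      .add_text_child(sn, "gender", su$gender)
      .add_text_child(sn, "age", .fmt_num(su$age))
      .add_text_child(sn, "hand", su$hand)
      .add_text_child(sn, "height", .fmt_num(su$height))
      .add_text_child(sn, "weight", .fmt_num(su$weight))
      .add_text_child(sn, "medication", su$medication)
      .add_text_child(sn, "channelLocationFile", su$channelLocationFile)
    }
    recs <- xml2::xml_add_child(nd, "dataRecordings")
    for (dr in s$dataRecordings) {
      rn <- xml2::xml_add_child(recs, "dataRecording")
      .add_text_child(rn, "uuid", dr$uuid)
      .add_text_child(rn, "originalFileNameAndPath", dr$originalFileNameAndPath)
      .add_text_child(rn, "essFilename", dr$essFilename)
      .add_text_child(rn, "eventInstanceFilename", dr$eventInstanceFilename)
      .add_text_child(rn, "parameterSetId", dr$parameterSetId)
      .add_text_child(rn, "startDateTime", dr$startDateTime)
    }
  }
  maps <- xml2::xml_add_child(doc, "eventCodeMappings")
  for (em in m$eventCodeMappings) {
    nd <- xml2::xml_add_child(maps, "eventCodeMapping")
    .add_text_child(nd, "taskLabel", em$taskLabel)
    .add_text_child(nd, "code", em$code)
    cat_txt <- if (inherits(em$categoryTag, "hed_tag")) format(em$categoryTag) else ""
    .add_text_child(nd, "categoryTag", cat_txt)
    hed_txt <- if (inherits(em$hedString, "hed_string")) format(em$hedString) else ""
    .add_text_child(nd, "hedString", hed_txt)
    .add_text_child(nd, "description", em$description)
  }
  if (length(m$additionalMetadata) > 0) {
    am <- xml2::xml_add_child(doc, "additionalMetadata")
    for (frag in m$additionalMetadata) {
      sub <- xml2::read_xml(frag)
      xml2::xml_add_child(am, sub)
    }
  }
  xml2::write_xml(doc, path, options = c("format", "no_declaration"))
  invisible(path)
}

# ---- XML reading -----------------------------------------------------------

.child_text <- function(node, name) {
  ch <- xml2::xml_find_first(node, name)
  if (inherits(ch, "xml_missing")) "" else xml2::xml_text(ch)
}

.modality_from_xml <- function(nd) {
  ess_modality(
    type = .child_text(nd, "type"),
    startChannel = .num_or_na(.child_text(nd, "startChannel")),
    endChannel = .num_or_na(.child_text(nd, "endChannel")),
    samplingRate = .num_or_na(.child_text(nd, "samplingRate")),
    channelLabels = xml2::xml_text(
      xml2::xml_find_all(nd, "channelLabels/channelLabel")),
    nonScalpChannelLabels = xml2::xml_text(
      xml2::xml_find_all(nd, "nonScalpChannelLabels/channelLabel")),
    channelLocationType = .child_text(nd, "channelLocationType"),
    referenceLabel = .child_text(nd, "referenceLabel"))
}

#' Read a Level-1 manifest from study_description.xml
#'
#' Parses the pinned XML dialect back into a [study_level1_manifest()].
#' Semantic invariants are not enforced here; run [validate_level1()] to
#' obtain structured issues. Unknown children of the root are preserved (under
#' `additionalMetadata`) so foreign metadata round-trips.
#'
#' @param path Path to the XML document.
#' @return A `study_level1_manifest`.
#' @export
read_level1_manifest <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "studyLevel1") {
    stop("not a Level-1 manifest: root element is <", xml2::xml_name(root), ">")
  }
  for (req in c("title", "essVersion", "sessions")) {
    if (inherits(xml2::xml_find_first(root, req), "xml_missing")) {
      stop("missing required element: studyLevel1/", req)
    }
  }
  m <- study_level1_manifest(
    title = .child_text(root, "title"),
    description = .child_text(root, "description"),
    essVersion = .child_text(root, "essVersion"),
    studyUuid = .child_text(root, "studyUuid"),
    publications = .child_text(root, "publications"),
    pointOfContact = .child_text(root, "pointOfContact"),
    license = .child_text(root, "license"),
    tasks = lapply(xml2::xml_find_all(root, "tasks/task"), function(nd) {
      task_spec(.child_text(nd, "taskLabel"), .child_text(nd, "description"))
    }),
    recordingParameterSets = lapply(
      xml2::xml_find_all(root, "recordingParameterSets/recordingParameterSet"),
      function(nd) {
        recording_parameter_set(
          id = .child_text(nd, "id"),
          modalities = lapply(xml2::xml_find_all(nd, "modalities/modality"),
                              .modality_from_xml))
      }),
    sessions = lapply(xml2::xml_find_all(root, "sessions/session"),
                      function(nd) {
      session_record(
        number = .num_or_na(.child_text(nd, "number")),
        taskLabel = .child_text(nd, "taskLabel"),
        notes = .child_text(nd, "notes"),
        subjects = lapply(xml2::xml_find_all(nd, "subjects/subject"),
                          function(sn) {
          subject_record(
            labId = .child_text(sn, "labId"),
            group = .child_text(sn, "group"),
            gender = .child_text(sn, "gender"),
            age = .num_or_na(.child_text(sn, "age")),
            hand = .child_text(sn, "hand"),
            height = .num_or_na(.child_text(sn, "height")),
            weight = .num_or_na(.child_text(sn, "weight")),
            medication = .child_text(sn, "medication"),
            channelLocationFile = .child_text(sn, "channelLocationFile"))
        }),
        dataRecordings = lapply(
          xml2::xml_find_all(nd, "dataRecordings/dataRecording"),
          function(rn) {
            data_recording(
              uuid = .child_text(rn, "uuid"),
              originalFileNameAndPath = .child_text(rn, "originalFileNameAndPath"),
              essFilename = .child_text(rn, "essFilename"),
              eventInstanceFilename = .child_text(rn, "eventInstanceFilename"),
              parameterSetId = .child_text(rn, "parameterSetId"),
              startDateTime = .child_text(rn, "startDateTime"))
          }))
    }),
    eventCodeMappings = lapply(
      xml2::xml_find_all(root, "eventCodeMappings/eventCodeMapping"),
      function(nd) {
        event_code_mapping(
          taskLabel = .child_text(nd, "taskLabel"),
          code = .child_text(nd, "code"),
          categoryTag = .child_text(nd, "categoryTag"),
          hedString = .child_text(nd, "hedString"),
          description = .child_text(nd, "description"))
      }))
  known <- c("title", "description", "essVersion", "studyUuid", "publications",
             "pointOfContact", "license", "tasks", "recordingParameterSets",
             "sessions", "eventCodeMappings")
  extras <- character(0)
  for (ch in xml2::xml_children(root)) {
    nm <- xml2::xml_name(ch)
    if (nm == "additionalMetadata") {
      extras <- c(extras, vapply(xml2::xml_children(ch), as.character,
                                 character(1)))
    } else if (!(nm %in% known)) {
      extras <- c(extras, as.character(ch))
    }
  }
  m$additionalMetadata <- extras
  m
}

# ---- Summary ---------------------------------------------------------------

#' Summarize a study manifest
#'
#' Counts sessions, subject entries and recordings, lists tasks, and tabulates
#' per-modality channel counts and sampling rates. Feeds the HTML report.
#'
#' @param m A [study_level1_manifest()].
#' @return An `ess_study_summary` list with fields `title`, `essVersion`,
#'   `nSessions`, `nSubjects`, `nRecordings`, `taskLabels`, `modalities`
#'   (a data.frame), `scalpEegChannels` and `samplingRates`.
#' @export
summarize_study <- function(m) {
  nSubjects <- sum(vapply(m$sessions, function(s) length(s$subjects),
                          integer(1)))
  nRecordings <- sum(vapply(m$sessions, function(s) length(s$dataRecordings),
                            integer(1)))
  mods <- do.call(rbind, lapply(m$recordingParameterSets, function(rs) {
    do.call(rbind, lapply(rs$modalities, function(mo) {
      data.frame(parameterSetId = rs$id, type = mo$type,
                 nChannels = length(mo$channelLabels),
                 nNonScalp = length(mo$nonScalpChannelLabels),
                 samplingRate = mo$samplingRate,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(mods)) {
    mods <- data.frame(parameterSetId = character(0), type = character(0),
                       nChannels = integer(0), nNonScalp = integer(0),
                       samplingRate = numeric(0), stringsAsFactors = FALSE)
  }
  eeg <- mods[mods$type == "EEG", , drop = FALSE]
  structure(list(
    title = m$title,
    essVersion = m$essVersion,
    nSessions = length(m$sessions),
    nSubjects = nSubjects,
    nRecordings = nRecordings,
    taskLabels = vapply(m$tasks, `[[`, character(1), "taskLabel"),
    modalities = mods,
    scalpEegChannels = sum(eeg$nChannels - eeg$nNonScalp),
    samplingRates = sort(unique(mods$samplingRate))),
    class = "ess_study_summary")
}

#' @export
print.ess_study_summary <- function(x, ...) {
  cat("Study: ", x$title, " (ESS ", x$essVersion, ")\n",
      "  sessions: ", x$nSessions, "  subjects: ", x$nSubjects,
      "  recordings: ", x$nRecordings, "\n",
      "  tasks: ", paste(x$taskLabels, collapse = ", "), "\n",
      "  scalp EEG channels: ", x$scalpEegChannels,
      "  sampling rate(s): ", paste(x$samplingRates, collapse = ", "),
      " Hz\n", sep = "")
  invisible(x)
}
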