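# Level-1 manifest validator: a catalog of named checks with severities and
# safe auto-fixes. Issues are returned as data, never raised; a manifest is
# container-ready iff validation yields zero error-severity issues.

.iss <- function(checkId, severity, location, message) {
  data.frame(checkId = checkId, severity = severity, location = location,
             message = message, stringsAsFactors = FALSE)
}

.no_issues <- function() {
  data.frame(checkId = character(0), severity = character(0),
             location = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

.fs_safe <- function(x) grepl("^[A-Za-z0-9_-]+$", x)

# Each catalog entry: id, description, default severity, autoFix flag, scope
# ("manifest" or "file"), and fun(m, root, h) -> list(issues, m).
.ess_check <- function(id, description, severity, autoFix, scope, fun) {
  list(id = id, description = description, severity = severity,
       autoFix = autoFix, scope = scope, fun = fun)
}

.for_sessions <- function(m, fun) {
  out <- .no_issues()
  for (i in seq_along(m$sessions)) {
    out <- rbind(out, fun(m$sessions[[i]], sprintf("sessions/session[%d]", i)))
  }
  out
}

.for_recordings <- function(m, fun) {
  out <- .no_issues()
  for (i in seq_along(m$sessions)) {
    s <- m$sessions[[i]]
    for (j in seq_along(s$dataRecordings)) {
      loc <- sprintf("sessions/session[%d]/dataRecordings/dataRecording[%d]",
                     i, j)
      out <- rbind(out, fun(s$dataRecordings[[j]], s, loc))
    }
  }
  out
}

.for_mappings <- function(m, fun) {
  out <- .no_issues()
  for (i in seq_along(m$eventCodeMappings)) {
    loc <- sprintf("eventCodeMappings/eventCodeMapping[%d]", i)
    out <- rbind(out, fun(m$eventCodeMappings[[i]], loc))
  }
  out
}

.for_modalities <- function(m, fun) {
  out <- .no_issues()
  for (i in seq_along(m$recordingParameterSets)) {
    rs <- m$recordingParameterSets[[i]]
    for (j in seq_along(rs$modalities)) {
      loc <- sprintf("recordingParameterSets/recordingParameterSet[%d]/modalities/modality[%d]",
                     i, j)
      out <- rbind(out, fun(rs$modalities[[j]], loc))
    }
  }
  out
}

.ess_checks <- local({
  ck <- list()
  add <- function(id, description, severity = "error", autoFix = FALSE,
                  scope = "manifest", fun) {
    ck[[length(ck) + 1L]] <<- .ess_check(id, description, severity, autoFix,
                                         scope, fun)
  }

  add("title-present", "Study title is present and non-empty.",
      fun = function(m, root, h) {
        if (!nzchar(trimws(m$title))) {
          return(list(issues = .iss("title-present", "error", "title",
                                    "study title is empty"), m = m))
        }
        list(issues = .no_issues(), m = m)
      })

  add("description-present", "Study description is present.",
      severity = "warning",
      fun = function(m, root, h) {
        iss <- if (!nzchar(trimws(m$description)))
          .iss("description-present", "warning", "description",
               "study description is empty") else .no_issues()
        list(issues = iss, m = m)
      })

  add("ess-version-present", "Schema version (essVersion) is present.",
      fun = function(m, root, h) {
        iss <- if (!nzchar(trimws(m$essVersion)))
          .iss("ess-version-present", "error", "essVersion",
               "essVersion is empty") else .no_issues()
        list(issues = iss, m = m)
      })

  add("ess-version-format", "essVersion looks like a dotted version number.",
      severity = "warning",
      fun = function(m, root, h) {
        iss <- if (nzchar(m$essVersion) &&
                   !grepl("^[0-9]+(\\.[0-9]+)*$", m$essVersion))
          .iss("ess-version-format", "warning", "essVersion",
               paste0("unusual essVersion '", m$essVersion, "'"))
          else .no_issues()
        list(issues = iss, m = m)
      })

  add("study-uuid-present", "Study UUID present (auto-fixed when missing).",
      autoFix = TRUE,
      fun = function(m, root, h) {
        if (!nzchar(m$studyUuid)) {
          m$studyUuid <- ess_uuid()
          return(list(issues = .iss("study-uuid-present", "fixed", "studyUuid",
                                    "missing study UUID generated"), m = m))
        }
        list(issues = .no_issues(), m = m)
      })

  add("study-uuid-format", "Study UUID is a lowercase hyphenated v4 UUID.",
      fun = function(m, root, h) {
        iss <- if (nzchar(m$studyUuid) && !.is_uuid(m$studyUuid))
          .iss("study-uuid-format", "error", "studyUuid",
               paste0("malformed study UUID '", m$studyUuid, "'"))
          else .no_issues()
        list(issues = iss, m = m)
      })

  add("task-present", "At least one task is defined.",
      fun = function(m, root, h) {
        iss <- if (length(m$tasks) == 0)
          .iss("task-present", "error", "tasks", "no tasks defined")
          else .no_issues()
        list(issues = iss, m = m)
      })

  add("task-label-unique", "Task labels are unique.",
      fun = function(m, root, h) {
        labs <- vapply(m$tasks, `[[`, character(1), "taskLabel")
        dup <- unique(labs[duplicated(labs)])
        iss <- if (length(dup) > 0)
          .iss("task-label-unique", "error", "tasks",
               paste0("duplicate task label(s): ", paste(dup, collapse = ", ")))
          else .no_issues()
        list(issues = iss, m = m)
      })

  add("task-label-safe",
      "Task labels are filesystem-safe (letters, digits, hyphen, underscore).",
      fun = function(m, root, h) {
        labs <- vapply(m$tasks, `[[`, character(1), "taskLabel")
        bad <- labs[!.fs_safe(labs)]
        iss <- if (length(bad) > 0)
          .iss("task-label-safe", "error", "tasks",
               paste0("unsafe task label(s): ",
                      paste(sprintf("'%s'", bad), collapse = ", ")))
          else .no_issues()
        list(issues = iss, m = m)
      })

  add("session-present", "Study contains at least one session.",
      severity = "warning",
      fun = function(m, root, h) {
        iss <- if (length(m$sessions) == 0)
          .iss("session-present", "warning", "sessions",
               "study has no sessions") else .no_issues()
        list(issues = iss, m = m)
      })

  add("session-number-positive", "Session numbers are positive integers.",
      fun = function(m, root, h) {
        iss <- .for_sessions(m, function(s, loc) {
          if (is.na(s$number) || s$number < 1 || s$number != round(s$number))
            .iss("session-number-positive", "error", loc,
                 paste0("session number '", s$number, "' is not a positive integer"))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("session-number-unique", "Session numbers are unique.",
      fun = function(m, root, h) {
        nums <- vapply(m$sessions, `[[`, numeric(1), "number")
        dup <- unique(nums[duplicated(nums)])
        iss <- if (length(dup) > 0)
          .iss("session-number-unique", "error", "sessions",
               paste0("duplicate session number(s): ",
                      paste(dup, collapse = ", ")))
          else .no_issues()
        list(issues = iss, m = m)
      })

  add("session-task-ref", "Each session references an existing task.",
      fun = function(m, root, h) {
        labs <- vapply(m$tasks, `[[`, character(1), "taskLabel")
        iss <- .for_sessions(m, function(s, loc) {
          if (!(s$taskLabel %in% labs))
            .iss("session-task-ref", "error", loc,
                 paste0("session task label '", s$taskLabel,
                        "' names no defined task"))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("session-has-subject", "Each session has at least one subject.",
      fun = function(m, root, h) {
        iss <- .for_sessions(m, function(s, loc) {
          if (length(s$subjects) == 0)
            .iss("session-has-subject", "error", loc, "session has no subjects")
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("session-has-recording", "Each session has at least one data recording.",
      fun = function(m, root, h) {
        iss <- .for_sessions(m, function(s, loc) {
          if (length(s$dataRecordings) == 0)
            .iss("session-has-recording", "error", loc,
                 "session has no data recordings")
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("subject-labid-present", "Each subject carries an anonymized lab id.",
      severity = "warning",
      fun = function(m, root, h) {
        out <- .no_issues()
        for (i in seq_along(m$sessions)) {
          subs <- m$sessions[[i]]$subjects
          for (j in seq_along(subs)) {
            if (!nzchar(trimws(subs[[j]]$labId))) {
              out <- rbind(out, .iss(
                "subject-labid-present", "warning",
                sprintf("sessions/session[%d]/subjects/subject[%d]", i, j),
                "subject labId is empty"))
            }
          }
        }
        list(issues = out, m = m)
      })

  add("rset-present", "At least one recording parameter set is defined.",
      fun = function(m, root, h) {
        iss <- if (length(m$recordingParameterSets) == 0 &&
                   sum(vapply(m$sessions, function(s) length(s$dataRecordings),
                              integer(1))) > 0)
          .iss("rset-present", "error", "recordingParameterSets",
               "recordings exist but no recording parameter set is defined")
          else .no_issues()
        list(issues = iss, m = m)
      })

  add("rset-id-unique", "Recording parameter set ids are unique.",
      fun = function(m, root, h) {
        ids <- vapply(m$recordingParameterSets, `[[`, character(1), "id")
        dup <- unique(ids[duplicated(ids)])
        iss <- if (length(dup) > 0)
          .iss("rset-id-unique", "error", "recordingParameterSets",
               paste0("duplicate parameter set id(s): ",
                      paste(dup, collapse = ", ")))
          else .no_issues()
        list(issues = iss, m = m)
      })

  add("recording-rset-ref",
      "Each recording references an existing parameter set.",
      fun = function(m, root, h) {
        ids <- vapply(m$recordingParameterSets, `[[`, character(1), "id")
        iss <- .for_recordings(m, function(dr, s, loc) {
          if (!(dr$parameterSetId %in% ids))
            .iss("recording-rset-ref", "error", loc,
                 paste0("parameterSetId '", dr$parameterSetId,
                        "' names no recording parameter set"))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("modality-channel-range",
      "Modality channel ranges satisfy 1 <= start <= end.",
      fun = function(m, root, h) {
        iss <- .for_modalities(m, function(mo, loc) {
          if (is.na(mo$startChannel) || is.na(mo$endChannel) ||
              mo$startChannel < 1 || mo$startChannel > mo$endChannel)
            .iss("modality-channel-range", "error", loc,
                 sprintf("invalid channel range %s..%s",
                         mo$startChannel, mo$endChannel))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("modality-contiguity",
      "Within a parameter set, modality ranges are disjoint and tile 1..N.",
      fun = function(m, root, h) {
        out <- .no_issues()
        for (i in seq_along(m$recordingParameterSets)) {
          rs <- m$recordingParameterSets[[i]]
          loc <- sprintf("recordingParameterSets/recordingParameterSet[%d]", i)
          chans <- unlist(lapply(rs$modalities, function(mo) {
            if (is.na(mo$startChannel) || is.na(mo$endChannel) ||
                mo$startChannel > mo$endChannel) return(integer(0))
            seq.int(mo$startChannel, mo$endChannel)
          }))
          if (length(chans) == 0) next
          if (anyDuplicated(chans)) {
            out <- rbind(out, .iss("modality-contiguity", "error", loc,
                                   "modality channel ranges overlap"))
          } else if (!identical(sort(chans), seq_along(chans))) {
            out <- rbind(out, .iss("modality-contiguity", "error", loc,
                 "modality channel ranges do not form a contiguous 1..N block"))
          }
        }
        list(issues = out, m = m)
      })

  add("modality-label-count",
      "Channel label count equals the modality's channel range width.",
      fun = function(m, root, h) {
        iss <- .for_modalities(m, function(mo, loc) {
          want <- mo$endChannel - mo$startChannel + 1
          if (!is.na(want) && length(mo$channelLabels) != want)
            .iss("modality-label-count", "error", loc,
                 sprintf("%d channel labels for a range of %d channels",
                         length(mo$channelLabels), want))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("modality-sampling-rate", "Modality sampling rates are positive.",
      fun = function(m, root, h) {
        iss <- .for_modalities(m, function(mo, loc) {
          if (is.na(mo$samplingRate) || mo$samplingRate <= 0)
            .iss("modality-sampling-rate", "error", loc,
                 paste0("non-positive sampling rate '", mo$samplingRate, "'"))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("modality-nonscalp-subset",
      "Non-scalp channel labels are a subset of the channel labels.",
      fun = function(m, root, h) {
        iss <- .for_modalities(m, function(mo, loc) {
          stray <- setdiff(mo$nonScalpChannelLabels, mo$channelLabels)
          if (length(stray) > 0)
            .iss("modality-nonscalp-subset", "error", loc,
                 paste0("non-scalp label(s) not among channel labels: ",
                        paste(stray, collapse = ", ")))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("recording-uuid-present",
      "Each recording has a UUID (auto-fixed when missing).", autoFix = TRUE,
      fun = function(m, root, h) {
        out <- .no_issues()
        for (i in seq_along(m$sessions)) {
          for (j in seq_along(m$sessions[[i]]$dataRecordings)) {
            if (!nzchar(m$sessions[[i]]$dataRecordings[[j]]$uuid)) {
              m$sessions[[i]]$dataRecordings[[j]]$uuid <- ess_uuid()
              out <- rbind(out, .iss(
                "recording-uuid-present", "fixed",
                sprintf("sessions/session[%d]/dataRecordings/dataRecording[%d]/uuid",
                        i, j),
                "missing data recording UUID generated"))
            }
          }
        }
        list(issues = out, m = m)
      })

  add("recording-uuid-format", "Recording UUIDs are well-formed v4 UUIDs.",
      fun = function(m, root, h) {
        iss <- .for_recordings(m, function(dr, s, loc) {
          if (nzchar(dr$uuid) && !.is_uuid(dr$uuid))
            .iss("recording-uuid-format", "error", paste0(loc, "/uuid"),
                 paste0("malformed recording UUID '", dr$uuid, "'"))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("recording-uuid-unique", "Recording UUIDs are unique across the study.",
      fun = function(m, root, h) {
        uu <- unlist(lapply(m$sessions, function(s) {
          vapply(s$dataRecordings, `[[`, character(1), "uuid")
        }))
        uu <- uu[nzchar(uu)]
        dup <- unique(uu[duplicated(uu)])
        iss <- if (length(dup) > 0)
          .iss("recording-uuid-unique", "error", "sessions",
               paste0("duplicate recording UUID(s): ",
                      paste(dup, collapse = ", ")))
          else .no_issues()
        list(issues = iss, m = m)
      })

  add("recording-original-path",
      "Each recording names its original file path.",
      fun = function(m, root, h) {
        iss <- .for_recordings(m, function(dr, s, loc) {
          if (!nzchar(trimws(dr$originalFileNameAndPath)))
            .iss("recording-original-path", "error", loc,
                 "originalFileNameAndPath is empty")
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("mapping-task-ref", "Event code mappings reference existing tasks.",
      fun = function(m, root, h) {
        labs <- vapply(m$tasks, `[[`, character(1), "taskLabel")
        iss <- .for_mappings(m, function(em, loc) {
          if (!(em$taskLabel %in% labs))
            .iss("mapping-task-ref", "error", loc,
                 paste0("mapping task label '", em$taskLabel,
                        "' names no defined task"))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("event-code-present", "Event codes are non-empty.",
      fun = function(m, root, h) {
        iss <- .for_mappings(m, function(em, loc) {
          if (!nzchar(em$code))
            .iss("event-code-present", "error", loc, "event code is empty")
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("event-code-length", "Event codes (labels) are 20 characters or less.",
      fun = function(m, root, h) {
        iss <- .for_mappings(m, function(em, loc) {
          if (nchar(em$code) > 20)
            .iss("event-code-length", "error", loc,
                 sprintf("event label '%s' has %d characters (max 20)",
                         em$code, nchar(em$code)))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("event-category-present", "Each event mapping carries a category tag.",
      fun = function(m, root, h) {
        iss <- .for_mappings(m, function(em, loc) {
          if (!inherits(em$categoryTag, "hed_tag"))
            .iss("event-category-present", "error", loc,
                 paste0("event '", em$code, "' has no category tag"))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("event-hed-parses", "Event HED strings parse.",
      fun = function(m, root, h) {
        iss <- .for_mappings(m, function(em, loc) {
          hs <- em$hedString
          if (is.character(hs) && nzchar(hs)) {
            err <- tryCatch({ parse_hed_string(hs); NULL },
                            error = function(e) conditionMessage(e))
            if (!is.null(err))
              return(.iss("event-hed-parses", "error", loc,
                          paste0("HED string for '", em$code,
                                 "' does not parse: ", err)))
          }
          .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("event-hed-vocabulary",
      "Event HED tags exist in (or validly extend) the vocabulary.",
      severity = "warning",
      fun = function(m, root, h) {
        iss <- .for_mappings(m, function(em, loc) {
          out <- .no_issues()
          for (s in list(em$categoryTag, em$hedString)) {
            hs <- NULL
            if (inherits(s, "hed_tag")) {
              hs <- structure(list(items = list(s)), class = "hed_string")
            } else if (inherits(s, "hed_string")) hs <- s
            if (is.null(hs)) next
            for (msg in validate_hed_string(hs, h)) {
              out <- rbind(out, .iss("event-hed-vocabulary", "warning", loc,
                                     paste0("event '", em$code, "': ", msg)))
            }
          }
          out
        })
        list(issues = iss, m = m)
      })

  add("task-event-coverage", "Each task has at least one event code mapping.",
      severity = "warning",
      fun = function(m, root, h) {
        mapped <- vapply(m$eventCodeMappings, `[[`, character(1), "taskLabel")
        out <- .no_issues()
        for (t in m$tasks) {
          if (!(t$taskLabel %in% mapped)) {
            out <- rbind(out, .iss("task-event-coverage", "warning", "tasks",
                                   paste0("task '", t$taskLabel,
                                          "' has no event code mappings")))
          }
        }
        list(issues = out, m = m)
      })

  add("channel-locations-declared",
      "A standard montage is declared or channel location files are given.",
      severity = "warning",
      fun = function(m, root, h) {
        std <- any(vapply(m$recordingParameterSets, function(rs) {
          any(vapply(rs$modalities, function(mo) {
            mo$type == "EEG" && mo$channelLocationType %in% c("10-20")
          }, logical(1)))
        }, logical(1)))
        out <- .no_issues()
        if (!std) {
          iss <- .for_sessions(m, function(s, loc) {
            locfiles <- vapply(s$subjects, `[[`, character(1),
                               "channelLocationFile")
            if (length(locfiles) > 0 && !any(nzchar(locfiles)))
              .iss("channel-locations-declared", "warning", loc,
                   "no standard montage declared and no channel location file")
            else .no_issues()
          })
          out <- rbind(out, iss)
        }
        list(issues = out, m = m)
      })

  add("schema-conformance",
      "The serialized manifest validates against the pinned XSD.",
      fun = function(m, root, h) {
        tmp <- tempfile(fileext = ".xml")
        on.exit(unlink(tmp), add = TRUE)
        out <- tryCatch({
          write_level1_manifest(m, tmp)
          xsd <- xml2::read_xml(system.file("extdata", "ess_level1.xsd",
                                            package = "esskit",
                                            mustWork = TRUE))
          ok <- xml2::xml_validate(xml2::read_xml(tmp), xsd)
          if (isTRUE(ok)) .no_issues()
          else .iss("schema-conformance", "error", "studyLevel1",
                    paste0("XSD violation: ",
                           paste(utils::head(attr(ok, "errors"), 3),
                                 collapse = "; ")))
        }, error = function(e) {
          .iss("schema-conformance", "error", "studyLevel1",
               paste0("manifest cannot be serialized: ", conditionMessage(e)))
        })
        list(issues = out, m = m)
      })

  # ---- file-level checks (run only when a container root is given) ---------

  add("file-data-exists", "Container data files exist on disk.",
      scope = "file",
      fun = function(m, root, h) {
        iss <- .for_recordings(m, function(dr, s, loc) {
          p <- file.path(root, "session", .fmt_int(s$number), dr$essFilename)
          if (!nzchar(dr$essFilename) || !file.exists(p))
            .iss("file-data-exists", "error", loc,
                 paste0("data file missing: ", p))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("file-event-exists", "Container event-instance files exist on disk.",
      scope = "file",
      fun = function(m, root, h) {
        iss <- .for_recordings(m, function(dr, s, loc) {
          p <- file.path(root, "session", .fmt_int(s$number),
                         dr$eventInstanceFilename)
          if (!nzchar(dr$eventInstanceFilename) || !file.exists(p))
            .iss("file-event-exists", "error", loc,
                 paste0("event-instance file missing: ", p))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("ess-filename-conforms",
      "Container filenames follow the ESS naming convention.",
      scope = "file",
      fun = function(m, root, h) {
        iss <- .for_recordings(m, function(dr, s, loc) {
          pre_d <- sprintf("eeg_session_%s_%s_", .fmt_int(s$number),
                           s$taskLabel)
          pre_e <- sprintf("event_session_%s_%s_", .fmt_int(s$number),
                           s$taskLabel)
          bad <- character(0)
          if (nzchar(dr$essFilename) && !startsWith(dr$essFilename, pre_d))
            bad <- c(bad, dr$essFilename)
          if (nzchar(dr$eventInstanceFilename) &&
              (!startsWith(dr$eventInstanceFilename, pre_e) ||
               !endsWith(dr$eventInstanceFilename, ".tsv")))
            bad <- c(bad, dr$eventInstanceFilename)
          if (length(bad) > 0)
            .iss("ess-filename-conforms", "error", loc,
                 paste0("non-conforming filename(s): ",
                        paste(bad, collapse = ", ")))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("event-file-parses",
      "Event-instance files parse as 3-column tab-separated text.",
      scope = "file",
      fun = function(m, root, h) {
        iss <- .for_recordings(m, function(dr, s, loc) {
          p <- file.path(root, "session", .fmt_int(s$number),
                         dr$eventInstanceFilename)
          if (!file.exists(p)) return(.no_issues())
          err <- tryCatch({
            parse_event_instance_file(readChar(p, file.size(p),
                                               useBytes = TRUE))
            NULL
          }, error = function(e) conditionMessage(e))
          if (!is.null(err))
            .iss("event-file-parses", "error", loc,
                 paste0(dr$eventInstanceFilename, ": ", err))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("event-latency-nonnegative", "Event latencies are non-negative.",
      scope = "file",
      fun = function(m, root, h) {
        iss <- .for_recordings(m, function(dr, s, loc) {
          ev <- .try_read_events(root, s, dr)
          if (is.null(ev)) return(.no_issues())
          lat <- vapply(ev, `[[`, numeric(1), "latency")
          if (any(lat < 0))
            .iss("event-latency-nonnegative", "error", loc,
                 paste0(sum(lat < 0), " negative event latenc(ies) in ",
                        dr$eventInstanceFilename))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("event-latency-sorted",
      "Event-instance files are sorted by ascending latency.",
      scope = "file",
      fun = function(m, root, h) {
        iss <- .for_recordings(m, function(dr, s, loc) {
          ev <- .try_read_events(root, s, dr)
          if (is.null(ev)) return(.no_issues())
          lat <- vapply(ev, `[[`, numeric(1), "latency")
          if (is.unsorted(lat))
            .iss("event-latency-sorted", "error", loc,
                 paste0("latencies out of order in ",
                        dr$eventInstanceFilename))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  add("event-latency-within-duration",
      "Event latencies do not exceed the recording duration (EDF header).",
      scope = "file",
      fun = function(m, root, h) {
        iss <- .for_recordings(m, function(dr, s, loc) {
          ev <- .try_read_events(root, s, dr)
          if (is.null(ev) || length(ev) == 0) return(.no_issues())
          p <- file.path(root, "session", .fmt_int(s$number), dr$essFilename)
          # a missing data file is file-data-exists territory, not ours
          if (!nzchar(dr$essFilename) || !file.exists(p)) return(.no_issues())
          hdr <- tryCatch(read_edf_header(p), error = function(e) NULL)
          if (is.null(hdr)) {
            return(.iss("event-latency-within-duration", "warning", loc,
                        paste0("duration check skipped: cannot read EDF header of ",
                               dr$essFilename)))
          }
          dur <- hdr$nRecords * hdr$recordDuration
          lat <- vapply(ev, `[[`, numeric(1), "latency")
          if (any(lat > dur))
            .iss("event-latency-within-duration", "error", loc,
                 sprintf("%d event(s) beyond recording end (%.3f s)",
                         sum(lat > dur), dur))
          else .no_issues()
        })
        list(issues = iss, m = m)
      })

  ck
})

.try_read_events <- function(root, s, dr) {
  p <- file.path(root, "session", .fmt_int(s$number), dr$eventInstanceFilename)
  if (!nzchar(dr$eventInstanceFilename) || !file.exists(p)) return(NULL)
  tryCatch(parse_event_instance_file(readChar(p, file.size(p),
                                              useBytes = TRUE)),
           error = function(e) NULL)
}

#' The validation check catalog
#'
#' Enumerates every named check run by [validate_level1()]: required-field
#' presence, referential integrity, channel-layout consistency, event-mapping
#' and HED constraints, identifier formats (with UUID auto-fixes) and — when a
#' container directory is supplied — on-disk file checks. The catalog contains
#' more than 30 checks.
#'
#' @return A data.frame with columns `checkId`, `description`, `severity`,
#'   `autoFix` and `scope`.
#' @export
check_catalog <- function() {
  do.call(rbind, lapply(.ess_checks, function(ck) {
    data.frame(checkId = ck$id, description = ck$description,
               severity = ck$severity, autoFix = ck$autoFix, scope = ck$scope,
               stringsAsFactors = FALSE)
  }))
}

#' Validate a Level-1 manifest
#'
#' Runs the full check catalog (see [check_catalog()]) over a manifest,
#' applying safe auto-fixes (missing UUIDs) and collecting issues as data.
#' File-level checks run only when `containerRoot` is given. A manifest is
#' container-ready exactly when the returned issue table has no
#' `"error"`-severity rows. Validation is idempotent: re-validating the fixed
#' manifest yields no further `"fixed"` issues.
#'
#' @param m A [study_level1_manifest()].
#' @param containerRoot Optional path to a built Level-1 container, enabling
#'   file-level checks.
#' @param hierarchy HED hierarchy for vocabulary checks (default: shipped
#'   snapshot).
#' @return A list with `issues` (data.frame: checkId, severity, location,
#'   message) and `fixed` (the manifest with auto-fixes applied).
#' @export
validate_level1 <- function(m, containerRoot = NULL, hierarchy = NULL) {
  stopifnot(inherits(m, "study_level1_manifest"))
  if (is.null(hierarchy)) hierarchy <- ess_default_hierarchy()
  issues <- .no_issues()
  for (ck in .ess_checks) {
    if (ck$scope == "file" && is.null(containerRoot)) next
    res <- ck$fun(m, containerRoot, hierarchy)
    issues <- rbind(issues, res$issues)
    m <- res$m
  }
  list(issues = issues, fixed = m)
}

#' Format validation issues as tab-separated text
#'
#' @param issues Issue data.frame from [validate_level1()].
#' @return A single string, one issue per line (severity, checkId, location,
#'   message), with a header line.
#' @export
format_issue_report <- function(issues) {
  lines <- c("severity\tcheckId\tlocation\tmessage",
             sprintf("%s\t%s\t%s\t%s", issues$severity, issues$checkId,
                     issues$location, issues$message))
  paste0(paste(lines, collapse = "\n"), "\n")
}
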