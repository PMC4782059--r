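# Shared fixtures: a small fully-valid manifest, a cached synthetic Level-1
# container, random generators for property tests, and the per-check mutation
# registry used to verify that every validator check is triggered by exactly
# the corruption it targets.

.fix <- new.env(parent = emptyenv())

uuid_n <- function(i) sprintf("00000000-0000-4000-8000-%012d", i)

make_valid_manifest <- function() {
  study_level1_manifest(
    title = "Test oddball study",
    description = "Small fully-valid manifest used as mutation baseline.",
    essVersion = "2.0",
    studyUuid = uuid_n(999),
    tasks = list(task_spec("oddball", "Auditory oddball task.")),
    recordingParameterSets = list(recording_parameter_set("rset_1", list(
      ess_modality("EEG", 1, 7, 64,
                   c("C1", "C2", "C3", "C4", "C5", "C6", "X1"),
                   nonScalpChannelLabels = "X1",
                   channelLocationType = "10-20")))),
    sessions = list(
      session_record(1, "oddball", list(subject_record("S01", age = 30)),
                     list(data_recording(uuid_n(1), "a.edf",
                                         parameterSetId = "rset_1"))),
      session_record(2, "oddball", list(subject_record("S02", age = 25)),
                     list(data_recording(uuid_n(2), "b.edf",
                                         parameterSetId = "rset_1")))),
    eventCodeMappings = list(
      event_code_mapping("oddball", "ding",
                         "Event/Category/Experimental stimulus",
                         paste("Sensory Presentation/Auditory/Ding,",
                               "Participant/Effect/Cognitive/Expected")),
      event_code_mapping("oddball", "buzz",
                         "Event/Category/Experimental stimulus",
                         paste("Sensory Presentation/Auditory/Buzz,",
                               "Participant/Effect/Cognitive/Oddball/Target"))),
    pointOfContact = "tester")
}

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(nSessions = 2L, scalpChannels = 6L, nonScalpChannels = 1L,
                   samplingRate = 64, durationSeconds = 3, seed = 7L)
  defaults[names(args)] <- args
  do.call(synth_config, defaults)
}

# Cached small synthetic study + built Level-1 container (read-only; copy
# before corrupting).
get_l1_fixture <- function() {
  if (is.null(.fix$l1)) {
    cfg <- small_cfg()
    src <- file.path(tempdir(), "esskit-fix-src")
    root <- file.path(tempdir(), "esskit-fix-l1")
    m <- generate_source_study(cfg, src)
    res <- create_level1_container(m, src, root, overwrite = TRUE)
    .fix$l1 <- list(cfg = cfg, src = src, root = root,
                    manifest = res$manifest, layout = res$layout)
  }
  .fix$l1
}

copy_container <- function(root) {
  dst <- tempfile("cc")
  dir.create(dst)
  file.copy(dir(root, full.names = TRUE), dst, recursive = TRUE)
  dst
}

# ---- random generators for property tests ---------------------------------

rand_tag <- function(maxdepth = 4) {
  words <- c("Alpha", "beta gamma", "Delta-1", "Epsilon", "ZETA", "eta")
  hed_tag(sample(words, sample.int(maxdepth, 1), replace = TRUE))
}

rand_hed_string <- function(depth = 0) {
  n <- sample.int(3, 1)
  items <- lapply(seq_len(n), function(i) {
    if (depth < 2 && stats::runif(1) < 0.25) rand_hed_string(depth + 1)
    else rand_tag()
  })
  structure(list(items = items), class = "hed_string")
}

rand_text <- function() {
  pool <- c(letters, LETTERS, " ", "é", "ü", "中", "-", "'")
  paste(sample(pool, sample.int(12, 1), replace = TRUE), collapse = "")
}

rand_manifest <- function() {
  nTasks <- sample.int(2, 1)
  tasks <- lapply(seq_len(nTasks), function(i) {
    task_spec(sprintf("task%d", i), rand_text())
  })
  nCh <- sample(2:5, 1)
  labels <- sprintf("ch%d", seq_len(nCh))
  rsets <- list(recording_parameter_set("rset_1", list(
    ess_modality("EEG", 1, nCh, sample(c(100, 250, 512), 1), labels,
                 nonScalpChannelLabels = labels[nCh],
                 channelLocationType = "10-20"))))
  nSess <- sample(0:3, 1)
  sessions <- lapply(seq_len(nSess), function(i) {
    session_record(i, sprintf("task%d", sample.int(nTasks, 1)),
                   subjects = list(subject_record(sprintf("S%02d", i),
                                                  gender = rand_text(),
                                                  age = sample(18:70, 1),
                                                  hand = "R",
                                                  height = round(stats::runif(1, 150, 200), 1))),
                   dataRecordings = list(data_recording(
                     uuid = uuid_n(i), originalFileNameAndPath = sprintf("f%d.edf", i),
                     parameterSetId = "rset_1",
                     startDateTime = "2020-01-01T00:00:00+0000")),
                   notes = rand_text())
  })
  study_level1_manifest(
    title = rand_text(), description = rand_text(),
    studyUuid = uuid_n(12345),
    tasks = tasks, recordingParameterSets = rsets, sessions = sessions,
    eventCodeMappings = list(event_code_mapping(
      "task1", "ev1", "Event/Category/Experimental stimulus",
      "Sensory Presentation/Auditory/Ding, (Participant/Effect/Auditory, Attribute/Onset)",
      description = rand_text())),
    publications = rand_text(), pointOfContact = rand_text(),
    license = rand_text())
}

rand_events <- function(n, codes = c("a", "b", "c")) {
  lapply(seq_len(n), function(i) {
    event_instance(sample(codes, 1), round(stats::runif(1, 0, 100), 6),
                   rand_hed_string())
  })
}

# Independent exhaustive-scan oracle for HED search: collects tags by its own
# recursion and compares case-insensitive path prefixes element by element.
oracle_search <- function(events, query) {
  qp <- tolower(unclass(query))
  collect <- function(s) {
    out <- list()
    for (it in s$items) {
      if (inherits(it, "hed_tag")) out <- c(out, list(tolower(unclass(it))))
      else out <- c(out, collect(it))
    }
    out
  }
  keep <- vapply(events, function(ev) {
    any(vapply(collect(ev$hedString), function(tp) {
      length(tp) >= length(qp) && identical(tp[seq_along(qp)], qp)
    }, logical(1)))
  }, logical(1))
  events[keep]
}

# ---- mutation registry -----------------------------------------------------
# One mutator per catalog checkId. Manifest-scope mutators take and return a
# manifest; file-scope mutators take (m, root) and return list(m, root) with
# root a corrupted copy of the fixture container. `overlap` lists checks whose
# corruption necessarily violates other invariants too (membership asserted
# instead of exclusivity).

mutation_overlap_ok <- c("task-present", "rset-present",
                         "modality-channel-range", "schema-conformance")

manifest_mutators <- list(
  `title-present` = function(m) { m$title <- ""; m },
  `description-present` = function(m) { m$description <- ""; m },
  `ess-version-present` = function(m) { m$essVersion <- ""; m },
  `ess-version-format` = function(m) { m$essVersion <- "two"; m },
  `study-uuid-present` = function(m) { m$studyUuid <- ""; m },
  `study-uuid-format` = function(m) { m$studyUuid <- "zzz"; m },
  `task-present` = function(m) { m$tasks <- list(); m },
  `task-label-unique` = function(m) {
    m$tasks <- c(m$tasks, list(task_spec("oddball", "duplicate"))); m
  },
  `task-label-safe` = function(m) {
    bad <- "bad label!"
    m$tasks[[1]]$taskLabel <- bad
    for (i in seq_along(m$sessions)) m$sessions[[i]]$taskLabel <- bad
    for (i in seq_along(m$eventCodeMappings)) {
      m$eventCodeMappings[[i]]$taskLabel <- bad
    }
    m
  },
  `session-present` = function(m) { m$sessions <- list(); m },
  `session-number-positive` = function(m) { m$sessions[[1]]$number <- 0; m },
  `session-number-unique` = function(m) {
    m$sessions[[2]]$number <- m$sessions[[1]]$number; m
  },
  `session-task-ref` = function(m) { m$sessions[[1]]$taskLabel <- "nope"; m },
  `session-has-subject` = function(m) { m$sessions[[1]]$subjects <- list(); m },
  `session-has-recording` = function(m) {
    m$sessions[[1]]$dataRecordings <- list(); m
  },
  `subject-labid-present` = function(m) {
    m$sessions[[1]]$subjects[[1]]$labId <- ""; m
  },
  `rset-present` = function(m) { m$recordingParameterSets <- list(); m },
  `rset-id-unique` = function(m) {
    m$recordingParameterSets <- c(m$recordingParameterSets,
                                  m$recordingParameterSets); m
  },
  `recording-rset-ref` = function(m) {
    m$sessions[[1]]$dataRecordings[[1]]$parameterSetId <- "nope"; m
  },
  `modality-channel-range` = function(m) {
    m$recordingParameterSets[[1]]$modalities[[1]]$startChannel <- 0; m
  },
  `modality-contiguity` = function(m) {
    m$recordingParameterSets[[1]]$modalities <- list(
      ess_modality("EEG", 1, 4, 64, c("C1", "C2", "C3", "C4"),
                   channelLocationType = "10-20"),
      ess_modality("EOG", 6, 8, 64, c("E1", "E2", "E3")))
    m
  },
  `modality-label-count` = function(m) {
    mo <- m$recordingParameterSets[[1]]$modalities[[1]]
    mo$channelLabels <- mo$channelLabels[-6]   # drop a scalp label, keep X1
    m$recordingParameterSets[[1]]$modalities[[1]] <- mo
    m
  },
  `modality-sampling-rate` = function(m) {
    m$recordingParameterSets[[1]]$modalities[[1]]$samplingRate <- 0; m
  },
  `modality-nonscalp-subset` = function(m) {
    m$recordingParameterSets[[1]]$modalities[[1]]$nonScalpChannelLabels <-
      c("X1", "QQ"); m
  },
  `recording-uuid-present` = function(m) {
    m$sessions[[1]]$dataRecordings[[1]]$uuid <- ""; m
  },
  `recording-uuid-format` = function(m) {
    m$sessions[[1]]$dataRecordings[[1]]$uuid <- "not-a-uuid"; m
  },
  `recording-uuid-unique` = function(m) {
    m$sessions[[2]]$dataRecordings[[1]]$uuid <-
      m$sessions[[1]]$dataRecordings[[1]]$uuid; m
  },
  `recording-original-path` = function(m) {
    m$sessions[[1]]$dataRecordings[[1]]$originalFileNameAndPath <- ""; m
  },
  `mapping-task-ref` = function(m) {
    m$eventCodeMappings[[1]]$taskLabel <- "nope"; m
  },
  `event-code-present` = function(m) { m$eventCodeMappings[[1]]$code <- ""; m },
  `event-code-length` = function(m) {
    m$eventCodeMappings[[1]]$code <- strrep("x", 21); m
  },
  `event-category-present` = function(m) {
    m$eventCodeMappings[[1]]$categoryTag <- ""; m
  },
  `event-hed-parses` = function(m) {
    m$eventCodeMappings[[1]]$hedString <- "(A, B"; m
  },
  `event-hed-vocabulary` = function(m) {
    m$eventCodeMappings[[1]]$hedString <-
      parse_hed_string("Participant/Nonexistent/X"); m
  },
  `task-event-coverage` = function(m) {
    m$tasks <- c(m$tasks, list(task_spec("resting", "uncovered task"))); m
  },
  `channel-locations-declared` = function(m) {
    m$recordingParameterSets[[1]]$modalities[[1]]$channelLocationType <- "Custom"
    m
  },
  `schema-conformance` = function(m) { m$sessions[[1]]$number <- NA_real_; m }
)

.session_dir <- function(root, n) file.path(root, "session", as.character(n))

.first_rec <- function(m) m$sessions[[1]]$dataRecordings[[1]]

file_mutators <- list(
  `file-data-exists` = function(m, root) {
    unlink(file.path(.session_dir(root, 1), .first_rec(m)$essFilename))
    list(m = m, root = root)
  },
  `file-event-exists` = function(m, root) {
    unlink(file.path(.session_dir(root, 1), .first_rec(m)$eventInstanceFilename))
    list(m = m, root = root)
  },
  `ess-filename-conforms` = function(m, root) {
    old <- .first_rec(m)$essFilename
    file.copy(file.path(.session_dir(root, 1), old),
              file.path(.session_dir(root, 1), "bad.edf"))
    m$sessions[[1]]$dataRecordings[[1]]$essFilename <- "bad.edf"
    list(m = m, root = root)
  },
  `event-file-parses` = function(m, root) {
    writeLines("only\ttwo",
               file.path(.session_dir(root, 1),
                         .first_rec(m)$eventInstanceFilename))
    list(m = m, root = root)
  },
  `event-latency-nonnegative` = function(m, root) {
    writeLines("ding\t-1.000000\tEvent/Category/Experimental stimulus",
               file.path(.session_dir(root, 1),
                         .first_rec(m)$eventInstanceFilename))
    list(m = m, root = root)
  },
  `event-latency-sorted` = function(m, root) {
    writeLines(c("ding\t2.000000\tEvent/Category/Experimental stimulus",
                 "ding\t1.000000\tEvent/Category/Experimental stimulus"),
               file.path(.session_dir(root, 1),
                         .first_rec(m)$eventInstanceFilename))
    list(m = m, root = root)
  },
  `event-latency-within-duration` = function(m, root) {
    writeLines("ding\t9999.000000\tEvent/Category/Experimental stimulus",
               file.path(.session_dir(root, 1),
                         .first_rec(m)$eventInstanceFilename))
    list(m = m, root = root)
  }
)

# Runs every catalog entry's mutation; used by both the validator unit tests
# and the acceptance suite.
run_mutation_checks <- function() {
  cat <- check_catalog()
  fix <- get_l1_fixture()
  for (k in seq_len(nrow(cat))) {
    id <- cat$checkId[k]
    expected_sev <- if (cat$autoFix[k]) "fixed" else cat$severity[k]
    if (id %in% names(manifest_mutators)) {
      m <- manifest_mutators[[id]](make_valid_manifest())
      v <- validate_level1(m)
      got <- v$issues
    } else if (id %in% names(file_mutators)) {
      root <- copy_container(fix$root)
      mu <- file_mutators[[id]](fix$manifest, root)
      v <- validate_level1(mu$m, containerRoot = mu$root)
      got <- v$issues
    } else {
      fail(paste0("no mutation registered for check '", id, "'"))
      next
    }
    hit <- got[got$checkId == id, , drop = FALSE]
    expect_gt(nrow(hit), 0, label = paste0("check '", id, "' triggered"))
    expect_true(all(hit$severity == expected_sev),
                label = paste0("check '", id, "' severity ", expected_sev))
    if (!(id %in% mutation_overlap_ok)) {
      expect_identical(unique(got$checkId), id,
                       label = paste0("check '", id, "' is the only issue"))
    }
  }
  invisible(cat)
}
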