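# Synthetic source-study generator: multichannel 1/f-shaped noise written as
# EDF, Poisson-timed event logs over a small code set, and a draft Level-1
# manifest. The default configuration reproduces the shape of a 24-participant
# auditory oddball study: 64 scalp EEG + 4 non-scalp channels at 1024 Hz, one
# session per participant, with standard ("ding") and oddball target ("buzz")
# stimuli. Session duration defaults to 20 s — a compute-friendly stand-in
# for real-session lengths; structure, not duration, is what downstream
# modules consume.

.default_event_codes <- function() {
  list(
    list(code = "ding",
         category = "Event/Category/Experimental stimulus",
         hedString = paste("Sensory Presentation/Auditory/Ding,",
                           "Participant/Effect/Auditory,",
                           "Participant/Effect/Cognitive/Expected"),
         description = "Standard (expected) auditory stimulus.",
         meanRate = 0.5),
    list(code = "buzz",
         category = "Event/Category/Experimental stimulus",
         hedString = paste("Sensory Presentation/Auditory/Buzz,",
                           "Participant/Effect/Auditory,",
                           "Participant/Effect/Cognitive/Oddball/Target"),
         description = "Oddball auditory stimulus serving as detection target.",
         meanRate = 0.125))
}

#' Configuration for a synthetic study
#'
#' Defaults emulate a 24-participant auditory oddball study recorded with 64
#' scalp EEG and 4 non-scalp (EOG) channels at 1024 Hz, with a frequent
#' standard and a rarer oddball stimulus (4:1).
#'
#' @param nSessions Number of sessions (one participant each).
#' @param scalpChannels,nonScalpChannels Channel counts.
#' @param samplingRate Sampling rate in Hz.
#' @param durationSeconds Recording duration per session (integer seconds).
#' @param eventCodes List of code specs: `code`, `category`, `hedString`,
#'   `description`, `meanRate` (events/second of a homogeneous Poisson
#'   process).
#' @param noisyChannelPerRecording Plant one high-variance channel per
#'   recording (a deterministic, seeded choice) to exercise noisy-channel
#'   detection.
#' @param seed Integer seed; together with the session index it fully
#'   determines signals, events and the draft manifest.
#' @return `synth_config` object.
#' @export
synth_config <- function(nSessions = 24, scalpChannels = 64,
                         nonScalpChannels = 4, samplingRate = 1024,
                         durationSeconds = 20,
                         eventCodes = .default_event_codes(),
                         noisyChannelPerRecording = FALSE, seed = 1) {
  stopifnot(nSessions >= 0, scalpChannels >= 0, nonScalpChannels >= 0,
            samplingRate > 0, durationSeconds > 0)
  structure(list(nSessions = as.integer(nSessions),
                 scalpChannels = as.integer(scalpChannels),
                 nonScalpChannels = as.integer(nonScalpChannels),
                 samplingRate = samplingRate,
                 durationSeconds = durationSeconds,
                 eventCodes = eventCodes,
                 noisyChannelPerRecording = isTRUE(noisyChannelPerRecording),
                 seed = as.integer(seed)),
            class = "synth_config")
}

.synth_channel_labels <- function(cfg) {
  scalp <- if (cfg$scalpChannels <= 32) {
    sprintf("A%d", seq_len(cfg$scalpChannels))
  } else {
    c(sprintf("A%d", 1:32),
      sprintf("B%d", seq_len(cfg$scalpChannels - 32)))
  }
  nonScalp <- if (cfg$nonScalpChannels > 0) {
    sprintf("EXG%d", seq_len(cfg$nonScalpChannels))
  } else character(0)
  list(scalp = scalp, nonScalp = nonScalp, all = c(scalp, nonScalp))
}

.synth_seed <- function(cfg, sessionIndex, salt = 0L) {
  (abs(cfg$seed) %% 1000003L) * 1009L + sessionIndex * 13L + salt
}

#' Generate the multichannel signal of one synthetic session
#'
#' Channels are 1/f-shaped Gaussian noise standardized to unit variance, plus
#' a shared 10 Hz sinusoid (amplitude 2, i.e. pairwise correlation about
#' 0.67, comparable to neighboring scalp electrodes) so clean channels pass
#' the correlation criterion of [detect_noisy_channels()] at its default
#' threshold. With `noisyChannelPerRecording`, one
#' deterministically chosen scalp channel receives 100x noise variance.
#' Output is fully determined by `(cfg$seed, sessionIndex)`.
#'
#' @param cfg A [synth_config()].
#' @param sessionIndex Session number (1-based).
#' @return A [signal_recording()].
#' @export
generate_signals <- function(cfg, sessionIndex) {
  labs <- .synth_channel_labels(cfg)
  nCh <- length(labs$all)
  if (cfg$scalpChannels == 0) stop("scalpChannels must be positive")
  nS <- as.integer(round(cfg$samplingRate * cfg$durationSeconds))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.synth_seed(cfg, sessionIndex, salt = 1L))

  freqs <- seq(0, cfg$samplingRate / 2, length.out = floor(nS / 2) + 1)
  shape <- c(0, 1 / sqrt(freqs[-1]))                 # 1/f amplitude profile
  data <- matrix(0, nrow = nCh, ncol = nS)
  phase <- stats::runif(1, 0, 2 * pi)
  shared <- 2 * sin(2 * pi * 10 * (seq_len(nS) - 1) / cfg$samplingRate +
                      phase)
  for (i in seq_len(nCh)) {
    white <- stats::rnorm(nS)
    spec <- stats::fft(white)
    half <- seq_along(shape)
    spec[half] <- spec[half] * shape
    if (nS %% 2 == 0) {
      spec[(nS / 2 + 2):nS] <- Conj(spec[seq(nS / 2, 2)])
    } else if (nS > 1) {
      spec[(floor(nS / 2) + 2):nS] <- Conj(spec[seq(floor(nS / 2) + 1, 2)])
    }
    pink <- Re(stats::fft(spec, inverse = TRUE)) / nS
    pink <- pink / stats::sd(pink)                   # unit-variance target
    data[i, ] <- pink + shared
  }
  if (cfg$noisyChannelPerRecording) {
    planted <- ((sessionIndex - 1L) %% cfg$scalpChannels) + 1L
    data[planted, ] <- 10 * stats::rnorm(nS)         # 100x variance, unshared
  }
  signal_recording(data, cfg$samplingRate, labs$all,
                   nonScalpChannels = labs$nonScalp)
}

# Generating functions must not disturb the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate the event stream of one synthetic session
#'
#' Per event code, occurrence times are drawn from a homogeneous Poisson
#' process at `meanRate` events/second truncated to `[0, duration)`; the
#' merged stream is sorted by latency. Deterministic per
#' `(cfg$seed, sessionIndex)`.
#'
#' @param cfg A [synth_config()].
#' @param sessionIndex Session number (1-based).
#' @return List of [event_instance()] objects sorted by latency.
#' @export
generate_events <- function(cfg, sessionIndex) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.synth_seed(cfg, sessionIndex, salt = 2L))
  events <- list()
  for (spec in cfg$eventCodes) {
    n <- stats::rpois(1, spec$meanRate * cfg$durationSeconds)
    if (n == 0) next
    times <- sort(stats::runif(n, 0, cfg$durationSeconds))
    for (t in times) {
      events[[length(events) + 1L]] <- event_instance(spec$code, t)
    }
  }
  lat <- vapply(events, `[[`, numeric(1), "latency")
  events[order(lat)]
}

#' Generate a complete synthetic source study
#'
#' Writes one EDF recording and one sidecar event log
#' (`subj_<N>.events.tsv`, `code TAB latency`) per session into `destDir`,
#' and returns a draft Level-1 manifest: one task, one recording parameter
#' set with a single EEG modality (scalp + non-scalp channels), per-session
#' subjects with seeded plausible metadata and anonymized lab ids
#' (`S01`, ...), and the event-code-to-HED mappings. Recording UUIDs are left
#' empty, as in a hand-drafted manifest, for the validator to fill.
#'
#' @param cfg A [synth_config()].
#' @param destDir Writable directory for the raw files.
#' @return The draft [study_level1_manifest()].
#' @export
generate_source_study <- function(cfg, destDir) {
  dir.create(destDir, recursive = TRUE, showWarnings = FALSE)
  labs <- .synth_channel_labels(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.synth_seed(cfg, 0L, salt = 3L))

  sessions <- vector("list", cfg$nSessions)
  for (i in seq_len(cfg$nSessions)) {
    fname <- sprintf("subj_%02d.edf", i)
    r <- generate_signals(cfg, i)
    write_edf(file.path(destDir, fname), r$data, cfg$samplingRate, labs$all)
    events <- generate_events(cfg, i)
    lines <- vapply(events, function(ev) {
      sprintf("%s\t%.6f", ev$code, ev$latency)
    }, character(1))
    writeLines(lines, file.path(destDir, sprintf("subj_%02d.events.tsv", i)))
    subject <- subject_record(
      labId = sprintf("S%02d", i),
      gender = sample(c("F", "M"), 1),
      age = sample(18:65, 1),
      hand = sample(c("R", "R", "R", "L"), 1),
      height = round(stats::runif(1, 150, 195)),
      weight = round(stats::runif(1, 50, 100)))
    sessions[[i]] <- session_record(
      number = i, taskLabel = "oddball",
      subjects = list(subject),
      dataRecordings = list(data_recording(
        originalFileNameAndPath = fname, parameterSetId = "rset_1")))
  }

  mappings <- lapply(cfg$eventCodes, function(spec) {
    event_code_mapping("oddball", spec$code, spec$category, spec$hedString,
                       spec$description)
  })

  study_level1_manifest(
    title = "Synthetic auditory oddball study",
    description = paste0(
      "Synthetic study: ", cfg$nSessions, " participants, auditory oddball ",
      "paradigm, ", cfg$scalpChannels, " scalp EEG and ",
      cfg$nonScalpChannels, " non-scalp channels at ", cfg$samplingRate,
      " Hz. Signals are 1/f noise with a shared 10 Hz component; events are ",
      "Poisson-timed. Generated by esskit (seed ", cfg$seed, ")."),
    tasks = list(task_spec("oddball",
                           "Auditory oddball: frequent ding, rare buzz target.")),
    recordingParameterSets = list(recording_parameter_set("rset_1", list(
      ess_modality("EEG", 1, length(labs$all), cfg$samplingRate, labs$all,
                   nonScalpChannelLabels = labs$nonScalp,
                   channelLocationType = "10-20")))),
    sessions = sessions,
    eventCodeMappings = mappings,
    pointOfContact = "esskit synthetic data generator",
    license = "CC0")
}
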