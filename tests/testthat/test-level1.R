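# Level-1 assembly: filename template, event-instance files, container build.

test_that("ESS filenames follow the pinned template", {
  expect_identical(ess_filename(1, "oddball", "subj01.bdf", "data"),
                   "eeg_session_1_oddball_subj01.bdf")
  expect_identical(ess_filename(1, "oddball", "subj01.bdf", "event"),
                   "event_session_1_oddball_subj01.tsv")
  expect_identical(ess_filename(3, "oddball", "caps.locs", "channelLocations"),
                   "channel_locations_session_3_oddball_caps.locs")
  # distinct originals stay distinct within a session
  expect_false(ess_filename(1, "t", "a.edf", "data") ==
                 ess_filename(1, "t", "b.edf", "data"))
  # unsafe characters are replaced, never rejected
  expect_identical(ess_filename(1, "t", "my file (v2).edf", "data"),
                   "eeg_session_1_t_my_file__v2_.edf")
  expect_error(ess_filename(1, "", "a.edf", "data"), "taskLabel")
})

test_that("event-instance files render sorted, 3-column, 6-decimal rows", {
  mapping <- make_valid_manifest()$eventCodeMappings
  events <- list(event_instance("ding", 1.0), event_instance("buzz", 2.5))
  content <- render_event_instance_file(events, mapping, "oddball")
  lines <- strsplit(content, "\n")[[1]]
  expect_length(lines, 2)
  expect_match(lines[1], "^ding\t1\\.000000\t")
  expect_match(lines[2], "Participant/Effect/Cognitive/Oddball/Target")
  expect_match(lines[2], "^buzz\t2\\.500000\t")

  expect_identical(render_event_instance_file(list(), mapping, "oddball"), "")
})

test_that("shuffled latencies are emitted ascending with stable ties", {
  mapping <- make_valid_manifest()$eventCodeMappings
  set.seed(406)
  lat <- c(5, 1, 3, 3, 0.5, 3)
  codes <- c("ding", "buzz", "ding", "buzz", "ding", "ding")
  events <- Map(event_instance, codes, lat)
  content <- render_event_instance_file(events, mapping, "oddball")
  got <- parse_event_instance_file(content)
  gotlat <- vapply(got, `[[`, numeric(1), "latency")
  # oracle: stable sort of the input
  ord <- order(lat)
  expect_equal(gotlat, lat[ord])
  expect_identical(vapply(got, `[[`, character(1), "code"), codes[ord])
})

test_that("render/parse round-trips events including their annotations", {
  mapping <- make_valid_manifest()$eventCodeMappings
  events <- list(event_instance("ding", 1.25), event_instance("buzz", 2.5))
  content <- render_event_instance_file(events, mapping, "oddball")
  got <- parse_event_instance_file(content)
  expect_length(got, 2)
  expect_identical(render_event_instance_file(got, mapping, "oddball"),
                   content)
  expect_identical(parse_event_instance_file(""), list())
})

test_that("event-file errors are specific", {
  mapping <- make_valid_manifest()$eventCodeMappings
  expect_error(
    render_event_instance_file(list(event_instance("mystery", 1)),
                               mapping, "oddball"),
    "'mystery' has no mapping for task 'oddball'")
  expect_error(
    render_event_instance_file(list(event_instance("ding", -2)),
                               mapping, "oddball"),
    "negative")
  expect_error(parse_event_instance_file("a\t1.0\n"), "line 1")
})

test_that("container build realizes the Level-1 layout and passes validation", {
  fix <- get_l1_fixture()
  root <- fix$root
  expect_true(file.exists(file.path(root, "study_description.xml")))
  expect_true(file.exists(file.path(root, "README.txt")))
  expect_true(dir.exists(file.path(root, "additional_documentation")))
  sess <- dir(file.path(root, "session"))
  expect_setequal(sess, c("1", "2"))
  for (s in fix$manifest$sessions) {
    for (dr in s$dataRecordings) {
      sdir <- file.path(root, "session", as.character(s$number))
      expect_true(file.exists(file.path(sdir, dr$essFilename)))
      expect_true(file.exists(file.path(sdir, dr$eventInstanceFilename)))
    }
  }
  v <- validate_level1(fix$manifest, containerRoot = root)
  expect_identical(sum(v$issues$severity == "error"), 0L)
})

test_that("payload bytes are conserved by the copy", {
  fix <- get_l1_fixture()
  for (s in fix$manifest$sessions) {
    dr <- s$dataRecordings[[1]]
    src <- file.path(fix$src, dr$originalFileNameAndPath)
    dst <- file.path(fix$root, "session", as.character(s$number),
                     dr$essFilename)
    expect_identical(unname(tools::md5sum(src)), unname(tools::md5sum(dst)))
  }
})

test_that("a missing source aborts before any copy", {
  cfg <- small_cfg(nSessions = 2L, seed = 8L)
  src <- tempfile("src")
  m <- generate_source_study(cfg, src)
  unlink(file.path(src, "subj_02.edf"))
  dest <- tempfile("dest")
  expect_error(create_level1_container(m, src, dest),
               "source recording missing.*no files were copied")
  expect_false(dir.exists(dest))
})

test_that("non-empty destinations require an explicit overwrite", {
  fix <- get_l1_fixture()
  cfg <- fix$cfg
  m <- generate_source_study(cfg, fix$src)   # deterministic: same study
  expect_error(create_level1_container(m, fix$src, fix$root),
               "not empty")
  res <- create_level1_container(m, fix$src, fix$root, overwrite = TRUE)
  # rebuild is idempotent up to generated UUIDs (drafts carry none)
  a <- res$manifest; b <- fix$manifest
  for (i in seq_along(a$sessions)) {
    a$sessions[[i]]$dataRecordings[[1]]$uuid <- ""
    b$sessions[[i]]$dataRecordings[[1]]$uuid <- ""
  }
  a$studyUuid <- b$studyUuid <- ""
  expect_equal(a, b)
  .fix$l1 <- NULL   # fixture root was rebuilt; force regeneration downstream
})

test_that("event latencies beyond the recording duration abort the build", {
  cfg <- small_cfg(nSessions = 1L, seed = 9L)
  src <- tempfile("src")
  m <- generate_source_study(cfg, src)
  # corrupt the sidecar log with an impossible latency
  log <- file.path(src, "subj_01.events.tsv")
  writeLines(c(readLines(log), "ding\t500.0"), log)
  expect_error(create_level1_container(m, src, tempfile("dest")),
               "beyond recording duration")
})
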