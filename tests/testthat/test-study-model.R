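# Study model: manifest XML round-trips, required-element errors, summary
# counts, and the anonymization guarantee of the subject schema.

test_that("manifest writes and reads back field-for-field", {
  m <- make_valid_manifest()
  path <- tempfile(fileext = ".xml")
  write_level1_manifest(m, path)
  m2 <- read_level1_manifest(path)
  expect_equal(m2, m)
})

test_that("random manifests round-trip (property)", {
  set.seed(404)
  for (i in 1:12) {
    m <- rand_manifest()
    path <- tempfile(fileext = ".xml")
    write_level1_manifest(m, path)
    expect_equal(read_level1_manifest(path), m)
  }
})

test_that("non-ASCII text survives the round-trip byte-identically", {
  m <- make_valid_manifest()
  m$sessions[[1]]$notes <- "Größe ≥ 10 µV — 测试 ©"
  path <- tempfile(fileext = ".xml")
  write_level1_manifest(m, path)
  m2 <- read_level1_manifest(path)
  expect_identical(m2$sessions[[1]]$notes, m$sessions[[1]]$notes)
})

test_that("empty optional fields are emitted as empty elements, not omitted", {
  m <- make_valid_manifest()
  m$publications <- ""
  m$license <- ""
  path <- tempfile(fileext = ".xml")
  write_level1_manifest(m, path)
  root <- xml2::xml_root(xml2::read_xml(path))
  for (el in c("publications", "license")) {
    nd <- xml2::xml_find_first(root, el)
    expect_false(inherits(nd, "xml_missing"), label = el)
    expect_identical(xml2::xml_text(nd), "")
  }
})

test_that("unknown root elements are preserved across a round-trip", {
  m <- make_valid_manifest()
  path <- tempfile(fileext = ".xml")
  write_level1_manifest(m, path)
  # splice a foreign element into the document
  doc <- xml2::read_xml(path)
  xml2::xml_add_child(xml2::xml_root(doc), xml2::read_xml(
    "<labCustom note='kept'><depth>2</depth></labCustom>"))
  xml2::write_xml(doc, path)
  m2 <- read_level1_manifest(path)
  expect_length(m2$additionalMetadata, 1)
  expect_match(m2$additionalMetadata[1], "labCustom")
  path2 <- tempfile(fileext = ".xml")
  write_level1_manifest(m2, path2)
  m3 <- read_level1_manifest(path2)
  expect_equal(m3$additionalMetadata, m2$additionalMetadata)
})

test_that("reader errors name missing required elements and malformed XML", {
  path <- tempfile(fileext = ".xml")
  writeLines("<studyLevel1><essVersion>2.0</essVersion><sessions/></studyLevel1>",
             path)
  expect_error(read_level1_manifest(path), "studyLevel1/title")

  writeLines("<studyLevel1><title>t</title><essVersion>2.0</essVersion></studyLevel1>",
             path)
  expect_error(read_level1_manifest(path), "studyLevel1/sessions")

  writeLines("<studyLevel1><title>t</titl", path)     # truncated
  expect_error(read_level1_manifest(path))
})

test_that("a zero-session manifest parses; the validator flags it", {
  m <- study_level1_manifest(title = "empty", description = "d",
                             tasks = list(task_spec("t1", "")))
  path <- tempfile(fileext = ".xml")
  write_level1_manifest(m, path)
  m2 <- read_level1_manifest(path)
  expect_length(m2$sessions, 0)
  v <- validate_level1(m2)
  expect_true("session-present" %in% v$issues$checkId)
  expect_false("session-present" %in%
                 v$issues$checkId[v$issues$severity == "error"])
})

test_that("study summary equals direct enumeration", {
  m <- make_valid_manifest()
  # 3 sessions x 2 recordings
  mk_rec <- function(i) data_recording(uuid_n(10 + i), sprintf("r%d.edf", i),
                                       parameterSetId = "rset_1")
  m$sessions <- lapply(1:3, function(i) {
    session_record(i, "oddball", list(subject_record(sprintf("S%02d", i))),
                   list(mk_rec(2 * i), mk_rec(2 * i + 1)))
  })
  s <- summarize_study(m)
  expect_identical(s$nSessions, 3L)
  expect_identical(s$nRecordings, 6L)
  expect_identical(s$nSubjects, 3L)
  expect_identical(s$scalpEegChannels, 6L)   # 7 channels, 1 non-scalp
  expect_equal(s$samplingRates, 64)

  empty <- study_level1_manifest(title = "x")
  s0 <- summarize_study(empty)
  expect_identical(s0$nSessions, 0L)
  expect_identical(s0$nRecordings, 0L)
  expect_identical(s0$nSubjects, 0L)
  expect_identical(nrow(s0$modalities), 0L)
})

test_that("subject schema exposes only anonymized fields", {
  fields <- names(subject_record("S01"))
  expect_setequal(fields, c("labId", "group", "gender", "age", "hand",
                            "height", "weight", "medication",
                            "channelLocationFile"))
  banned <- c("name", "firstName", "lastName", "address", "email", "phone",
              "ssn", "nationalId", "dateOfBirth")
  expect_length(intersect(tolower(fields), tolower(banned)), 0)
})

test_that("generated UUIDs are well-formed v4 and seed-reproducible", {
  set.seed(99); u1 <- ess_uuid()
  set.seed(99); u2 <- ess_uuid()
  expect_identical(u1, u2)
  expect_match(u1, "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$")
})
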