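# Level-derived containers: Butterworth high-pass against the analytic
# magnitude oracle, filter registry, provenance chaining and functoriality.

test_that("high-pass rejects DC to machine-level precision", {
  r <- signal_recording(matrix(5, nrow = 2, ncol = 256), 64, c("a", "b"))
  out <- high_pass(r, 0.5)
  expect_lt(max(abs(out$data)), 1e-6 * 5)
  expect_identical(dim(out$data), dim(r$data))
})

test_that("sine attenuation matches the analytic Butterworth response", {
  # forward-backward 4th-order high-pass: |H|^2 with
  # |H(f)|^2 = (W/Wc)^8 / (1 + (W/Wc)^8), W = tan(pi f / fs) (bilinear warp)
  analytic_gain <- function(f, fc, fs) {
    ratio <- tan(pi * f / fs) / tan(pi * fc / fs)
    (ratio^8 / (1 + ratio^8))
  }
  fs <- 256
  dur <- 60
  t <- seq_len(fs * dur) / fs
  mid <- seq(round(length(t) / 3), round(2 * length(t) / 3))
  for (f in c(10, 1, 0.5, 0.3)) {
    r <- signal_recording(matrix(sin(2 * pi * f * t), 1), fs, "x")
    out <- high_pass(r, 0.5)
    amp <- (max(out$data[1, mid]) - min(out$data[1, mid])) / 2
    expect_equal(amp, analytic_gain(f, 0.5, fs), tolerance = 0.02,
                 label = paste0("steady-state amplitude at ", f, " Hz"))
  }
  # 10 Hz passes essentially unattenuated; 0.05 Hz is crushed
  r10 <- signal_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "x")
  expect_equal((max(high_pass(r10, 0.5)$data[1, mid]) -
                  min(high_pass(r10, 0.5)$data[1, mid])) / 2, 1,
               tolerance = 0.02)
  rslow <- signal_recording(matrix(sin(2 * pi * 0.05 * t), 1), fs, "x")
  amp_slow <- (max(high_pass(rslow, 0.5)$data[1, mid]) -
                 min(high_pass(rslow, 0.5)$data[1, mid])) / 2
  expect_lt(amp_slow, 0.01)
})

test_that("cutoffs at or above Nyquist are rejected; events untouched", {
  r <- signal_recording(matrix(rnorm(128), 1), 64, "x",
                        events = list(event_instance("e", 1)))
  expect_error(high_pass(r, 32), "Nyquist")
  out <- high_pass(r, 1)
  expect_identical(out$events, r$events)
})

test_that("derived container records the highPass parameter value", {
  fix <- get_l1_fixture()
  fd <- filter_description("highPass", list(detrendCutoff = 0.5))
  res <- apply_filter_to_container(fix$root, tempfile("d"), fd)
  expect_identical(res$nFailed, 0L)
  ld <- read_derived_manifest(file.path(res$root, "study_description.xml"))
  expect_identical(ld$filter$functionName, "highPass")
  expect_identical(ld$filter$parameters$detrendCutoff, 0.5)
  expect_length(ld$recordingOutputs, 2)
  expect_identical(ld$parentKind, "studyLevel1")
})

test_that("the parent manifest is embedded verbatim", {
  fix <- get_l1_fixture()
  fd <- filter_description("identity")
  res <- apply_filter_to_container(fix$root, tempfile("d"), fd)
  ld <- read_derived_manifest(file.path(res$root, "study_description.xml"))
  norm <- function(txt) gsub(">\\s+<", "><", paste(txt, collapse = ""))
  orig <- readLines(file.path(fix$root, "study_description.xml"), warn = FALSE)
  expect_identical(norm(ld$parentXml), norm(orig))
})

test_that("an identity filter reproduces parent payload bytes", {
  fix <- get_l1_fixture()
  res <- apply_filter_to_container(fix$root, tempfile("d"),
                                   filter_description("identity"))
  for (s in fix$manifest$sessions) {
    dr <- s$dataRecordings[[1]]
    rel <- file.path("session", as.character(s$number), dr$essFilename)
    expect_identical(unname(tools::md5sum(file.path(fix$root, rel))),
                     unname(tools::md5sum(file.path(res$root, rel))))
  }
})

test_that("3-deep chains recover full ancestry down to Level 1", {
  fix <- get_l1_fixture()
  p <- fix$root
  cut <- c(2, 4, 8)
  for (i in 1:3) {
    res <- apply_filter_to_container(
      p, tempfile(sprintf("d%d", i)),
      filter_description("highPass", list(detrendCutoff = cut[i])))
    expect_identical(res$nFailed, 0L)
    p <- res$root
  }
  chain <- provenance_chain(file.path(p, "study_description.xml"))
  expect_identical(chain$levels, c(rep("studyLevelDerived", 3), "studyLevel1"))
  expect_equal(vapply(chain$filters, function(f) f$parameters$detrendCutoff,
                      numeric(1)), rev(cut))
  expect_equal(chain$level1$title, fix$manifest$title)
  expect_length(chain$level1$sessions, 2)
})

test_that("chained filters equal direct composition through quantization", {
  # functoriality: f then g via two containers == g(f(x)) applied directly,
  # where the direct route replicates the declared EDF 16-bit quantization
  # between steps (the container machinery must add nothing beyond it)
  fix <- get_l1_fixture()
  f <- function(r, p) { r$data <- 2 * r$data + 1; r }
  g <- function(r, p) { r$data <- r$data / 3 - 2; r }
  register_filter("testScaleF", f)
  register_filter("testScaleG", g)
  d1 <- apply_filter_to_container(fix$root, tempfile("df"),
                                  filter_description("testScaleF"))
  d2 <- apply_filter_to_container(d1$root, tempfile("dg"),
                                  filter_description("testScaleG"))
  quantize <- function(r) {
    tmp <- tempfile(fileext = ".edf")
    write_edf(tmp, r$data, r$samplingRate, r$channelLabels)
    e <- read_edf(tmp)
    signal_recording(e$data, e$samplingRate, e$channelLabels)
  }
  for (s in fix$manifest$sessions) {
    dr <- s$dataRecordings[[1]]
    rel <- file.path("session", as.character(s$number), dr$essFilename)
    e0 <- read_edf(file.path(fix$root, rel))
    direct <- quantize(g(quantize(f(signal_recording(
      e0$data, e0$samplingRate, e0$channelLabels), NULL)), NULL))
    chained <- read_edf(file.path(d2$root, rel))
    expect_equal(max(abs(chained$data - direct$data)), 0, tolerance = 1e-9)
  }
})

test_that("a failing filter marks recordings failed without dropping them", {
  fix <- get_l1_fixture()
  res <- apply_filter_to_container(
    fix$root, tempfile("dfail"), filter_description("identity"),
    fn = function(r, p) stop("boom"))
  expect_identical(res$nFailed, 2L)
  expect_length(res$manifest$recordingOutputs, 2)   # conserved, flagged
  statuses <- vapply(res$manifest$recordingOutputs, `[[`, character(1),
                     "status")
  expect_true(all(grepl("^failed: boom", statuses)))
})

test_that("unknown filter names produce a helpful registry error", {
  expect_error(get_filter("noSuchFilter"), "no filter registered")
})
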