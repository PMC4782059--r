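# Level-2 preprocessing: noisy-channel detection, robust average reference,
# neighbor interpolation, and automated container creation.

mk_rec <- function(data, rate = 128, nonScalp = character(0)) {
  signal_recording(data, rate, sprintf("C%d", seq_len(nrow(data))),
                   nonScalpChannels = nonScalp)
}

test_that("a single high-amplitude channel is the only one flagged", {
  set.seed(407)
  t <- seq_len(5 * 128) / 128
  base <- sin(2 * pi * 5 * t)
  data <- do.call(rbind, replicate(6, base, simplify = FALSE))
  data <- data + matrix(rnorm(length(data), sd = 0.05), nrow = 6)
  data[4, ] <- 100 * rnorm(ncol(data))
  r <- mk_rec(data)
  flagged <- detect_noisy_channels(r)
  expect_identical(flagged, "C4")

  # brute-force criterion evaluation (independent of the implementation)
  rsd <- apply(data, 1, mad)
  z <- (rsd - median(rsd)) / mad(rsd)
  expect_true(abs(z[4]) > 5)
  expect_true(all(abs(z[-4]) <= 5))
})

test_that("identical channels yield no flags", {
  base <- sin(seq_len(256) / 5)
  data <- do.call(rbind, replicate(4, base, simplify = FALSE))
  expect_identical(detect_noisy_channels(mk_rec(data, 64)), character(0))
})

test_that("a flat-line channel is flagged through the correlation criterion", {
  set.seed(408)
  shared <- rnorm(4 * 64)
  data <- do.call(rbind, replicate(5, shared, simplify = FALSE))
  data <- data + matrix(rnorm(length(data), sd = 0.1), nrow = 5)
  data[3, ] <- 0
  flagged <- detect_noisy_channels(mk_rec(data, 64))
  expect_true("C3" %in% flagged)
})

test_that("non-scalp channels are never flagged and preconditions hold", {
  set.seed(409)
  data <- rbind(rnorm(256), rnorm(256), 100 * rnorm(256))
  r <- signal_recording(data, 64, c("C1", "C2", "EXG1"),
                        nonScalpChannels = "EXG1")
  expect_false("EXG1" %in% detect_noisy_channels(r))
  r2 <- signal_recording(data[c(1, 3), ], 64, c("C1", "EXG1"),
                         nonScalpChannels = "EXG1")
  expect_error(detect_noisy_channels(r2), "2 scalp channels")
})

test_that("robust average reference subtracts the retained-channel mean", {
  r <- mk_rec(rbind(rep(1, 10), rep(3, 10)), 10)
  out <- robust_average_reference(r)
  expect_equal(out$data, rbind(rep(-1, 10), rep(1, 10)))

  # random matrix vs the one-line oracle
  set.seed(410)
  x <- matrix(rnorm(6 * 100), nrow = 6)
  got <- robust_average_reference(mk_rec(x, 50))$data
  expect_equal(got, sweep(x, 2, colMeans(x)), tolerance = 1e-12)
})

test_that("excluded channels are re-referenced but retained mean is zero", {
  set.seed(411)
  x <- matrix(rnorm(5 * 64), nrow = 5)
  x[2, ] <- x[2, ] * 50
  r <- mk_rec(x, 64)
  out <- robust_average_reference(r, excluded = "C2")
  retained <- out$data[-2, ]
  expect_true(max(abs(colMeans(retained))) < 1e-9 * max(abs(x)))
  # the excluded channel was still shifted by the same reference
  ref <- colMeans(x[-2, ])
  expect_equal(out$data[2, ], x[2, ] - ref, tolerance = 1e-12)
  expect_error(robust_average_reference(r, excluded = paste0("C", 1:5)),
               "all scalp channels excluded")
})

test_that("interpolation reconstructs a channel equal to its neighbor mean", {
  set.seed(412)
  pos <- cbind(c(0, 1, -1, 0, 0, 3), c(0, 0, 0, 1, -1, 3))
  rownames(pos) <- sprintf("C%d", 1:6)
  x <- matrix(rnorm(6 * 50), nrow = 6)
  # C1 constructed as the mean of its 4 nearest neighbors C2..C5
  x[1, ] <- colMeans(x[2:5, ])
  r <- mk_rec(x, 25)
  out <- interpolate_channels(r, "C1", neighborCount = 4, positions = pos)
  expect_equal(out$data[1, ], x[1, ], tolerance = 1e-12)
  expect_identical(out$data[-1, ], x[-1, ])

  expect_identical(interpolate_channels(r, character(0)), r)

  # all-but-one bad: every bad channel equals the single good one
  out2 <- interpolate_channels(r, sprintf("C%d", 2:6), positions = pos)
  for (i in 2:6) expect_equal(out2$data[i, ], x[1, ])
  expect_error(interpolate_channels(r, sprintf("C%d", 1:6), positions = pos),
               "no good scalp channel")
})

test_that("level-2 container interpolates exactly the planted channels", {
  cfg <- small_cfg(nSessions = 4L, scalpChannels = 8L, samplingRate = 128,
                   durationSeconds = 5, noisyChannelPerRecording = TRUE,
                   seed = 11L)
  src <- tempfile("src")
  m <- generate_source_study(cfg, src)
  l1 <- tempfile("l1")
  create_level1_container(m, src, l1)
  res <- create_level2_container(l1, tempfile("l2"))
  expect_identical(res$nFailed, 0L)
  expect_length(res$manifest$processingRecords, 4)
  for (i in seq_along(res$manifest$processingRecords)) {
    pr <- res$manifest$processingRecords[[i]]
    planted <- sprintf("A%d", ((i - 1) %% 8) + 1)
    expect_identical(pr$interpolatedChannels, planted)
    expect_identical(pr$noisyChannels, planted)
    expect_equal(pr$qualityScore, 1 - 1 / 8)
  }
  # manifest on disk round-trips and embeds the parent
  l2m <- read_level2_manifest(file.path(res$root, "study_description.xml"))
  expect_length(l2m$processingRecords, 4)
  expect_equal(l2m$parentManifest$title, m$title)
})

test_that("default pipeline conserves shape and zeroes the retained mean", {
  cfg <- small_cfg(nSessions = 1L, scalpChannels = 6L, samplingRate = 64,
                   durationSeconds = 3, noisyChannelPerRecording = TRUE,
                   seed = 12L)
  r <- generate_signals(cfg, 1)
  res <- default_level2_pipeline(r)
  expect_identical(dim(res$recording$data), dim(r$data))
  retained <- setdiff(setdiff(r$channelLabels, r$nonScalpChannels),
                      res$noisyChannels)
  idx <- match(retained, r$channelLabels)
  expect_true(max(abs(colMeans(res$recording$data[idx, ]))) <
                1e-9 * max(abs(r$data)))
  # non-scalp rows untouched
  ns <- match(r$nonScalpChannels, r$channelLabels)
  expect_identical(res$recording$data[ns, ], r$data[ns, ])
})

test_that("an identity pipeline reproduces the input payload bytes", {
  fix <- get_l1_fixture()
  idp <- function(r) list(recording = r, noisyChannels = character(0),
                          interpolatedChannels = character(0),
                          qualityScore = 1, parameters = list())
  res <- create_level2_container(fix$root, tempfile("l2"), pipeline = idp)
  expect_identical(res$nFailed, 0L)
  for (s in fix$manifest$sessions) {
    dr <- s$dataRecordings[[1]]
    a <- file.path(fix$root, "session", as.character(s$number),
                   dr$essFilename)
    b <- file.path(res$root, "session", as.character(s$number),
                   dr$essFilename)
    expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
  }
})

test_that("a zero-session Level-1 yields a valid empty Level-2", {
  m <- study_level1_manifest(title = "empty", description = "d",
                             studyUuid = uuid_n(77),
                             tasks = list(task_spec("t", "")))
  root <- tempfile("l1empty")
  dir.create(root)
  write_level1_manifest(m, file.path(root, "study_description.xml"))
  res <- create_level2_container(root, tempfile("l2empty"))
  expect_identical(res$nFailed, 0L)
  expect_length(res$manifest$processingRecords, 0)
  expect_true(file.exists(file.path(res$root, "study_description.xml")))
})

test_that("an unreadable recording is marked failed and the run continues", {
  fix <- get_l1_fixture()
  root <- copy_container(fix$root)
  dr <- fix$manifest$sessions[[1]]$dataRecordings[[1]]
  # truncate the first recording's payload
  path <- file.path(root, "session", "1", dr$essFilename)
  writeBin(readBin(path, "raw", 300), path)
  res <- create_level2_container(root, tempfile("l2f"))
  expect_identical(res$nFailed, 1L)
  statuses <- vapply(res$manifest$processingRecords, `[[`, character(1),
                     "status")
  expect_identical(sum(statuses != "ok"), 1L)
  expect_length(statuses, 2)
})
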