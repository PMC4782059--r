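# HED vocabulary: hierarchy loading, string parsing, validation against the
# tree, and prefix matching/search.

test_that("shipped vocabulary snapshot loads with the oddball paths", {
  h <- load_hed_hierarchy()
  expect_s3_class(h, "hed_hierarchy")
  expect_identical(h$version, "2.0")
  for (p in c("Participant/Effect/Cognitive/Oddball/Target",
              "Participant/Effect/Cognitive/Expected",
              "Sensory Presentation/Auditory/Ding",
              "Sensory Presentation/Auditory/Buzz",
              "Participant/Effect/Auditory")) {
    expect_length(validate_hed_string(p, h), 0)
  }
})

test_that("degenerate and malformed vocabulary documents", {
  one <- tempfile(fileext = ".txt")
  writeLines(c("version: 1.0", "Only"), one)
  h <- load_hed_hierarchy(one)
  expect_length(h$roots, 1)
  expect_identical(h$roots[[1]]$name, "Only")
  expect_length(h$roots[[1]]$children, 0)

  dup <- tempfile(fileext = ".txt")
  writeLines(c("Root", "\tA", "\ta"), dup)
  expect_error(load_hed_hierarchy(dup), "duplicate sibling.*Root/a",
               ignore.case = TRUE)
})

test_that("HED string parsing handles tags, groups and whitespace", {
  s <- parse_hed_string(
    "Sensory Presentation/Auditory/Ding, Participant/Effect/Auditory")
  expect_length(s$items, 2)
  expect_s3_class(s$items[[1]], "hed_tag")

  s2 <- parse_hed_string("A/B")
  expect_identical(unclass(s2$items[[1]]), c("A", "B"))

  s3 <- parse_hed_string("(A/B, C), D")
  expect_length(s3$items, 2)
  expect_s3_class(s3$items[[1]], "hed_string")
  expect_length(s3$items[[1]]$items, 2)
  expect_identical(format(s3), "(A/B, C), D")

  expect_identical(format(parse_hed_string("  A ,(B , C/D )")), "A, (B, C/D)")
})

test_that("HED parse errors carry positions and clear causes", {
  expect_error(parse_hed_string("(A, B"), "unbalanced")
  expect_error(parse_hed_string("A, B)"), "position 5")
  expect_error(parse_hed_string("A,,B"), "empty item")
  expect_error(parse_hed_string("A ~ B"), "tilde")
  expect_error(parse_hed_string(""), "non-empty")
})

test_that("parse/serialize round-trips random HED strings", {
  set.seed(401)
  for (i in 1:60) {
    s <- rand_hed_string()
    txt <- format(s)
    expect_identical(format(parse_hed_string(txt)), txt)
    expect_equal(parse_hed_string(txt), s)
  }
})

test_that("string validation permits extensions and values as declared", {
  h <- ess_default_hierarchy()
  expect_length(validate_hed_string("Participant/Effect/Cognitive/Expected", h), 0)
  expect_length(validate_hed_string("Participant/Nonexistent/X", h), 1)
  # extension beneath an extensionAllowed leaf
  expect_length(validate_hed_string("Participant/Effect/Auditory/Whistle", h), 0)
  # two unknown levels beneath a non-extensible node
  expect_length(validate_hed_string("Event/Category/X/Y", h), 1)
  # a single value beneath a takesValue node, but not two
  expect_length(validate_hed_string("Event/Label/mycode", h), 0)
  expect_length(validate_hed_string("Event/Label/a/b", h), 1)
})

test_that("validation agrees with a brute-force walk of the snapshot file", {
  # independent oracle: re-read the vocabulary text with its own tiny parser
  path <- system.file("extdata", "hed_vocabulary.txt", package = "esskit")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#|^version:", lines)]
  lines <- lines[nzchar(trimws(lines))]
  depth <- nchar(lines) - nchar(sub("^\t+", "", lines))
  name <- trimws(gsub("\\[[a-zA-Z]+\\]", "", sub("^\t+", "", lines)))
  ext <- grepl("[extensionAllowed]", lines, fixed = TRUE)
  tv <- grepl("[takesValue]", lines, fixed = TRUE)
  stack <- character(0)
  extstack <- logical(0)
  paths <- character(0); pext <- logical(0); ptv <- logical(0)
  for (i in seq_along(lines)) {
    stack <- c(stack[seq_len(depth[i])], name[i])
    extstack <- c(extstack[seq_len(depth[i])], ext[i])
    paths <- c(paths, paste(stack, collapse = "/"))
    pext <- c(pext, any(extstack))         # extension permission inherits
    ptv <- c(ptv, tv[i])
  }
  h <- ess_default_hierarchy()
  for (i in seq_along(paths)) {
    expect_length(validate_hed_string(paths[i], h), 0)
    below <- paste0(paths[i], "/Zzz9")
    ok <- pext[i] || ptv[i]
    expect_identical(length(validate_hed_string(below, h)) == 0L, ok,
                     label = paste("extension below", paths[i]))
  }
})

test_that("tag matching is case-insensitive path prefixing", {
  t1 <- hed_tag("Participant/Effect/Cognitive/Oddball/Target")
  expect_true(tag_matches(t1, hed_tag("Participant/Effect")))
  expect_false(tag_matches(t1, hed_tag("Sensory Presentation")))
  expect_true(tag_matches(hed_tag("a/b/c"), hed_tag("A/B/C")))
  expect_false(tag_matches(hed_tag("a/b"), hed_tag("a/b/c")))
})

test_that("matching is transitive along the hierarchy", {
  set.seed(402)
  for (i in 1:40) {
    tag <- rand_tag(5)
    k <- sample.int(length(tag), 1)
    q2 <- hed_tag(unclass(tag)[seq_len(k)])          # prefix of tag
    j <- sample.int(k, 1)
    q1 <- hed_tag(unclass(q2)[seq_len(j)])           # prefix of q2
    expect_true(tag_matches(tag, q2))
    expect_true(tag_matches(tag, q1))
  }
})

test_that("event search equals the exhaustive scan oracle", {
  set.seed(403)
  events <- rand_events(50)
  for (i in 1:25) {
    q <- rand_tag(3)
    expect_identical(search_event_instances(events, q),
                     oracle_search(events, q))
  }
  # query by a tag's own full path always returns every carrier
  ev <- events[[7]]
  first_tag <- function(s) {
    it <- s$items[[1]]
    if (inherits(it, "hed_tag")) it else first_tag(it)
  }
  own <- first_tag(ev$hedString)
  expect_true(any(vapply(search_event_instances(events, own),
                         identical, logical(1), y = ev)))
  # a query matching nothing returns an empty, order-preserving subset
  none <- search_event_instances(events, hed_tag("Nowhere/To/Be/Found"))
  expect_length(none, 0)
})

test_that("oddball events are retrieved by the Oddball query", {
  mapping <- make_valid_manifest()$eventCodeMappings
  content <- render_event_instance_file(
    list(event_instance("ding", 1.0), event_instance("buzz", 2.5),
         event_instance("ding", 3.0)),
    mapping, "oddball")
  events <- parse_event_instance_file(content)
  hits <- search_event_instances(events,
                                 hed_tag("Participant/Effect/Cognitive/Oddball"))
  expect_length(hits, 1)
  expect_identical(hits[[1]]$code, "buzz")
})
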