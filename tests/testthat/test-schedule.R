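test_that("the packaged 13-piece programme parses with its known structure", {
  sched <- table1()
  expect_s3_class(sched, "stimulus_schedule")
  expect_equal(nrow(sched), 13)
  expect_equal(attr(sched, "silence_s"), 2)
  expect_equal(max(sched$end_s), 507)
  expect_equal(sort(table(sched$label)),
               sort(c(happy = 3, sad = 3, neutral = 7)), ignore_attr = TRUE)
  # every sad and happy piece is followed by a neutral one
  followers <- sched$label[-1][sched$label[-13] %in% c("sad", "happy")]
  expect_true(all(followers == "neutral"))
})

test_that("schedule validation rejects malformed inputs and names the row", {
  rows <- data.frame(index = 1:2, start_s = c(0, 20), end_s = c(25, 40),
                     label = c("happy", "sad"))
  expect_error(parse_schedule(rows), "overlap.*row 2")
  rows2 <- data.frame(index = 1, start_s = 10, end_s = 5, label = "sad")
  expect_error(parse_schedule(rows2), "ends before")
  rows3 <- data.frame(index = 1, start_s = 0, end_s = 5, label = "angry")
  expect_error(parse_schedule(rows3), "unknown label 'angry'")
  rows4 <- data.frame(index = 1:3, start_s = c(0, 7, 20), end_s = c(5, 15, 30),
                      label = rep("neutral", 3))
  expect_error(parse_schedule(rows4), "not constant.*row 3")
})

test_that("a single-event schedule is flagged but accepted", {
  rows <- data.frame(index = 1, start_s = 0, end_s = 29, label = "neutral")
  expect_warning(s <- parse_schedule(rows), "silence undefined")
  expect_true(is.na(attr(s, "silence_s")))
})

test_that("schedules round-trip through write and re-parse", {
  sched <- table1()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(sched, path)
  again <- parse_schedule(read_schedule(path))
  expect_equal(as.data.frame(sched), as.data.frame(again))
  expect_equal(attr(again, "silence_s"), 2)
})

test_that("volumes map to events by midpoint with half-open windows", {
  sched <- table1()
  labs <- label_timepoints(sched, tr_s = 2, n_volumes = 254)
  # volume 61 covers [120, 122), midpoint 121 -> inside 111-147 (happy)
  expect_equal(labs$label[labs$t_mid_s == 121], "happy")
  expect_equal(labs$event[labs$t_mid_s == 121], 4L)
  # midpoint 29 sits in the gap between end 29 (exclusive) and start 31
  expect_equal(labs$label[labs$t_mid_s == 29], "silence")
  # the neutral piece after the first sad piece carries the derived tag
  expect_true(all(labs$derived[labs$event %in% 3] == "neutral_following_sad"))
  expect_true(all(labs$derived[labs$event %in% 5] == "neutral_following_happy"))
  # opening neutral piece follows nothing
  expect_true(all(labs$derived[labs$event %in% 1] == "none"))
  # derived tags only ever sit on neutral volumes
  expect_true(all(labs$label[labs$derived != "none"] == "neutral"))
})

test_that("every volume receives exactly one label and counts add up", {
  sched <- table1()
  for (tr in c(1, 2, 3.5)) {
    labs <- label_timepoints(sched, tr_s = tr, n_volumes = 100)
    expect_equal(nrow(labs), 100)
    expect_equal(sum(table(labs$label)), 100)
    expect_false(anyNA(labs$label))
  }
  # volumes past the schedule end are silence
  labs <- label_timepoints(sched, tr_s = 2, n_volumes = 300)
  expect_true(all(labs$label[labs$t_mid_s > 507] == "silence"))
})

test_that("rating traces resample to volume midpoints by nearest sample", {
  sched <- table1()
  labs <- label_timepoints(sched, tr_s = 2, n_volumes = 100)
  # constant trace
  trace <- data.frame(time_s = seq(0, 510, by = 0.5), rating = 3)
  expect_equal(resample_ratings(trace, labs)$rating, rep(3, 100))
  # aligned grid: identity up to offset
  trace2 <- data.frame(time_s = labs$t_mid_s, rating = seq_len(100) / 20 - 2)
  expect_equal(resample_ratings(trace2, labs)$rating, trace2$rating)
  # linear ramp vs brute-force index arithmetic
  tg <- seq(0, 510, by = 0.7)
  trace3 <- data.frame(time_s = tg, rating = (tg - 255) / 100)
  got <- resample_ratings(trace3, labs)$rating
  idx <- vapply(labs$t_mid_s, function(t) {
    d <- abs(tg - t)
    which(d == min(d))[1]  # ties toward the earlier sample
  }, 1L)
  expect_equal(got, trace3$rating[idx])
  # trace not covering the span
  short <- data.frame(time_s = seq(0, 100, by = 0.5), rating = 0)
  expect_error(resample_ratings(short, labs), "does not cover")
})
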