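test_that("weekly aggregation sums fixed 7-day windows", {
  mon <- as.Date("2004-04-26")  # a Monday
  ps <- as_pollen_series(data.frame(date = mon + 0:6, count = 1))
  wk <- weekly_pollen_index(ps)
  expect_equal(nrow(wk), 1)
  expect_equal(wk$index, 7)
  expect_true(wk$complete)
  expect_equal(wk$week_start, mon)

  # 14 days alternating 0/10 -> direct summation oracle
  counts <- rep(c(0, 10), 7)
  ps2 <- as_pollen_series(data.frame(date = mon + 0:13, count = counts))
  wk2 <- weekly_pollen_index(ps2)
  expect_equal(wk2$index, c(sum(counts[1:7]), sum(counts[8:14])))

  # a single day is a flagged partial week
  ps3 <- as_pollen_series(data.frame(date = mon + 2, count = 5))
  wk3 <- weekly_pollen_index(ps3)
  expect_equal(nrow(wk3), 1)
  expect_false(wk3$complete)
  expect_equal(wk3$week_start, mon)  # anchored to the Monday before
  expect_error(weekly_pollen_index(
    as_pollen_series(data.frame(date = as.Date(character(0)),
                                count = numeric(0)))), "empty")
})

test_that("weekly indices conserve the daily total and survive chunking", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(14:70, 1)
    start <- as.Date("2004-03-01") + sample(0:20, 1)
    ps <- as_pollen_series(data.frame(date = start + 0:(n - 1),
                                      count = rpois(n, 20)))
    wk <- weekly_pollen_index(ps)
    expect_equal(sum(wk$index), sum(ps$count), tolerance = 1e-9)
    # splitting the series into chunks changes nothing given the anchor
    anchor <- wk$week_start[1]
    half <- floor(n / 2)
    wk_a <- weekly_pollen_index(ps[1:half, ], week_anchor = anchor)
    wk_b <- weekly_pollen_index(ps[(half + 1):n, ], week_anchor = anchor)
    merged <- rep(0, nrow(wk))
    merged[seq_len(nrow(wk_a))] <- wk_a$index
    ib <- match(wk_b$week_start, wk$week_start)
    merged[ib] <- merged[ib] + wk_b$index
    expect_equal(merged, wk$index, tolerance = 1e-9)
  }
})

test_that("the peak week is the argmax with earliest-week ties", {
  mon <- as.Date("2004-04-26")
  wk <- weekly_pollen_index(as_pollen_series(
    data.frame(date = mon + 0:20, count = rep(c(1, 5, 3), each = 7))))
  pk <- peak_week(wk)
  expect_equal(pk$week_start, mon + 7)
  expect_equal(pk$index, 35)
  expect_false(pk$tie)

  wk_tie <- weekly_pollen_index(as_pollen_series(
    data.frame(date = mon + 0:13, count = 2)))
  pk2 <- peak_week(wk_tie)
  expect_equal(pk2$week_start, mon)
  expect_true(pk2$tie)

  # random series -> exhaustive scan oracle
  set.seed(19)
  ps <- as_pollen_series(data.frame(date = mon + 0:48,
                                    count = runif(49, 0, 40)))
  wkr <- weekly_pollen_index(ps)
  pk3 <- peak_week(wkr)
  best <- -Inf; best_w <- NULL
  for (r in seq_len(nrow(wkr))) {
    if (wkr$index[r] > best) { best <- wkr$index[r]
      best_w <- wkr$week_start[r] }
  }
  expect_equal(pk3$index, best)
  expect_equal(pk3$week_start, best_w)
})

test_that("the flowering/pollen join pairs dates with their weeks", {
  mon <- as.Date("2004-04-26")
  wk <- weekly_pollen_index(as_pollen_series(
    data.frame(date = mon + 0:13, count = c(rep(1, 7), rep(3, 7)))))
  tab <- flowering_pollen_table(
    data.frame(date = mon + 8, area_fraction = 0.4), wk)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pollen_index, 21)
  expect_equal(tab$week_start, mon + 7)
  expect_true(tab$in_span)

  # a date outside the span is kept but flagged
  tab2 <- flowering_pollen_table(
    data.frame(date = c(mon + 3, mon + 60),
               area_fraction = c(0.2, 0.5)), wk)
  expect_equal(tab2$in_span, c(TRUE, FALSE))
  expect_true(is.na(tab2$pollen_index[2]))

  # empty mask list -> empty table
  expect_equal(nrow(flowering_pollen_table(list(), wk)), 0)
})
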