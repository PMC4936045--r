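test_that("the DOP filter removes the boundary value and is idempotent", {
  rec <- tibble::tibble(dop = c(2, 4.9, 5.0, 7), x = 1:4, y = 1:4)
  out <- filter_dop(rec)
  expect_equal(out$dop, c(2, 4.9))  # 5.0 removed: the cutoff is dop < 5
  expect_equal(out$x, c(1L, 2L))    # order preserved

  all_good <- tibble::tibble(dop = runif(20, 1, 4.9))
  expect_identical(filter_dop(all_good), all_good)
  expect_identical(filter_dop(filter_dop(rec)), filter_dop(rec))
  expect_equal(nrow(filter_dop(rec[0, ])), 0L)

  set.seed(8)
  big <- tibble::tibble(dop = runif(10000, 0, 10))
  expect_equal(nrow(filter_dop(big)), sum(big$dop < 5))
})

test_that("fix rates are retained fixes over the 30-min schedule", {
  day <- as.Date("2008-05-01")
  mk <- function(n) tibble::tibble(timestamp = as.POSIXct(day) + seq_len(n))
  expect_equal(compute_fix_rate(mk(48), c(day, day)), 1.0)
  expect_equal(compute_fix_rate(mk(24), c(day, day)), 0.5)
  expect_error(compute_fix_rate(mk(5), c(day, day), schedule_minutes = Inf),
               "zero expected")

  set.seed(9)
  n_days <- 30
  keep <- runif(n_days * 48) > 0.4
  rate <- compute_fix_rate(mk(sum(keep)), c(day, day + n_days - 1))
  expect_lt(abs(rate - 0.6), 3 * sqrt(0.6 * 0.4 / (n_days * 48)))
})

test_that("Welch's t-test matches the textbook formula and its symmetries", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 4, 5, 6)
  got <- welch_t_test(a, b)
  # independently coded Welch-Satterthwaite oracle
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_or <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_or <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_or <- 2 * pt(-abs(t_or), df_or)
  expect_equal(got$t, t_or, tolerance = 1e-10)
  expect_equal(got$df, df_or, tolerance = 1e-10)
  expect_equal(got$p, p_or, tolerance = 1e-10)

  same <- welch_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  swapped <- welch_t_test(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  expect_error(welch_t_test(c(1, 1), c(1, 1)), "degenerate")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("end-date randomization follows the loss-date density within season bounds", {
  mk_surv <- function(i) {
    r <- bear_year_record(paste0("S", i), 2008L,
                          tibble::tibble(timestamp = as.POSIXct(character()),
                                         x = numeric(), y = numeric(),
                                         dop = numeric()))
    r$fate <- "survived"; r
  }
  # degenerate density: a single loss event pins every end date
  one <- assign_end_dates(lapply(1:20, mk_surv), as.Date("2008-05-08"),
                          "05-01", "06-16", seed = 1)
  expect_true(all(vapply(one, function(b) as.character(b$end_date), "") ==
                    "2008-05-08"))

  events <- seq(as.Date("2008-05-08"), as.Date("2008-06-16"), by = "5 days")
  many <- assign_end_dates(lapply(1:200, mk_surv), events, "05-01", "06-16",
                           seed = 2)
  ed <- as.Date(vapply(many, function(b) as.character(b$end_date), ""))
  expect_true(all(ed >= as.Date("2008-05-01") & ed <= as.Date("2008-06-16")))

  # KDE mass ratio: events 10 May x3, 1 June x1 -> ~3x more mass near 10 May
  ev <- as.Date(c(rep("2008-05-10", 3), "2008-06-01"))
  draws <- assign_end_dates(lapply(1:10000, mk_surv), ev, "05-01", "06-16",
                            seed = 3)
  dd <- as.Date(vapply(draws, function(b) as.character(b$end_date), ""))
  near1 <- sum(abs(as.numeric(dd - as.Date("2008-05-10"))) <= 8)
  near2 <- sum(abs(as.numeric(dd - as.Date("2008-06-01"))) <= 8)
  expect_gt(near1 / near2, 2.2)
  expect_lt(near1 / near2, 3.8)

  # reproducible under a fixed seed
  again <- assign_end_dates(lapply(1:50, mk_surv), ev, "05-01", "06-16",
                            seed = 3)
  again2 <- assign_end_dates(lapply(1:50, mk_surv), ev, "05-01", "06-16",
                             seed = 3)
  expect_identical(vapply(again, function(b) as.character(b$end_date), ""),
                   vapply(again2, function(b) as.character(b$end_date), ""))
  expect_error(assign_end_dates(lapply(1:2, mk_surv), as.Date(character()),
                                "05-01", "06-16"), "empty")
})

test_that("period truncation keeps the closed season interval and flags exclusions", {
  ts <- seq(as.POSIXct("2008-04-20 00:00", tz = "UTC"),
            as.POSIXct("2008-07-01 00:00", tz = "UTC"), by = "6 hours")
  rel <- tibble::tibble(bear_id = "B1", year = 2008L, timestamp = ts,
                        x = seq_along(ts), y = 0, dop = 2)
  lost <- bear_year_record("B1", 2008L, rel, fate = "lost",
                           loss_date = as.Date("2008-05-08"))
  out <- truncate_period(lost, "05-01", "06-16")
  d <- as.Date(out$relocations$timestamp)
  expect_true(all(d >= as.Date("2008-05-01") & d <= as.Date("2008-05-08")))
  expect_equal(min(d), as.Date("2008-05-01"))
  expect_equal(max(d), as.Date("2008-05-08"))  # the end date itself retained
  expect_lte(nrow(out$relocations), nrow(rel))

  surv <- bear_year_record("B2", 2008L, rel, fate = "survived",
                           end_date = as.Date("2008-06-16"))
  out2 <- truncate_period(surv, "05-01", "06-16")
  expect_equal(max(as.Date(out2$relocations$timestamp)), as.Date("2008-06-16"))
  # the global truncation caps later end dates
  surv_late <- bear_year_record("B3", 2008L, rel, fate = "survived",
                                end_date = as.Date("2008-06-30"))
  out3 <- truncate_period(surv_late, "05-01", "06-16")
  expect_equal(out3$end_date, as.Date("2008-06-16"))

  part <- bear_year_record("B4", 2008L, rel, fate = "partial_loss")
  out4 <- truncate_period(part, "05-01", "06-16")
  expect_true(out4$excluded)
  expect_equal(out4$exclusion_reason, "partial litter loss")

  # fixes entirely before the season: empty period, minimum-data flag
  april <- rel[as.Date(rel$timestamp) < as.Date("2008-05-01"), ]
  early <- bear_year_record("B5", 2008L, april, fate = "lost",
                            loss_date = as.Date("2008-05-08"))
  out5 <- apply_min_data_rule(truncate_period(early, "05-01", "06-16"))
  expect_equal(nrow(out5$relocations), 0L)
  expect_true(out5$excluded)
  expect_match(out5$exclusion_reason, "insufficient data")
})

test_that("cluster detection matches an exhaustive windowed oracle", {
  # three coincident points form one cluster
  co <- tibble::tibble(x = c(0, 0, 0), y = c(0, 0, 0))
  cl <- detect_clusters(co)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n, 3L)

  # consecutive points 20 m apart never cluster at a 15 m radius
  line <- tibble::tibble(x = seq(0, 200, by = 20), y = 0)
  expect_equal(nrow(detect_clusters(line)), 0L)

  # random walk vs an independent from-scratch scan with the same greedy
  # centroid rule
  set.seed(13)
  n <- 200
  steps <- matrix(rnorm(2 * n, 0, 8), ncol = 2)
  walk <- apply(steps, 2, cumsum)
  rec <- tibble::tibble(x = walk[, 1], y = walk[, 2])
  oracle <- local({
    out <- list(); i <- 1
    while (i <= n) {
      best_j <- i
      for (j in (i + 1):n) {
        if (j > n) break
        idx <- i:j
        cen <- c(mean(rec$x[idx]), mean(rec$y[idx]))
        if (max(sqrt((rec$x[idx] - cen[1])^2 + (rec$y[idx] - cen[2])^2)) <= 15)
          best_j <- j
        else break
      }
      if (best_j - i + 1 >= 3) {
        out[[length(out) + 1]] <- c(i, best_j)
        i <- best_j + 1
      } else i <- i + 1
    }
    out
  })
  got <- detect_clusters(rec)
  expect_equal(nrow(got), length(oracle))
  for (k in seq_along(oracle)) {
    expect_equal(got$start[k], oracle[[k]][1])
    expect_equal(got$end[k], oracle[[k]][2])
  }
})

test_that("study preparation excludes partial losses and balances periods", {
  st <- small_study(seed = 31)
  st$bear_years[[1]]$fate <- "partial_loss"
  pr <- prepare_study(st$bear_years, seed = 3)
  expect_true("partial litter loss" %in% pr$exclusions$reason)
  # every retained bear-year lies within [1 May, last loss date]
  for (b in pr$bear_years) {
    d <- as.Date(b$relocations$timestamp)
    expect_true(all(format(d, "%m-%d") >= "05-01"))
    expect_true(all(d <= pr$truncation | b$year != as.integer(format(pr$truncation, "%Y"))))
    expect_true(all(format(d, "%m-%d") <= format(pr$truncation, "%m-%d")))
  }
  # survivors got end dates, lost kept loss dates
  for (b in pr$bear_years)
    expect_false(is.na(if (b$fate == "survived") b$end_date else b$loss_date))
})
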