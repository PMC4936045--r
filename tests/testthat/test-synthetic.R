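test_that("landscape generation is deterministic and hits target proportions", {
  g <- grid_spec(400, 400, cell_size = 25)
  cfg <- landscape_config()
  a <- gen_landscape(g, cfg, seed = 9)
  b <- gen_landscape(g, cfg, seed = 9)
  expect_identical(a$landscape$continuous, b$landscape$continuous)
  expect_identical(a$landscape$landcover, b$landscape$landcover)

  props <- c(bog = 0.1, TRB = 0.1, clearcut = 0.15, young = 0.2,
             mid_aged = 0.2, old = 0.15, other = 0.1)
  realized <- as.numeric(table(factor(
    landcover_classes()[a$landscape$landcover],
    levels = landcover_classes()))) / length(a$landscape$landcover)
  expect_true(all(abs(realized - props[landcover_classes()]) <= 0.03))
  expect_true(all(a$landscape$continuous$ndvi >= -1 &
                    a$landscape$continuous$ndvi <= 1))
  expect_true(all(a$landscape$continuous$dist_road >= 0))
})

test_that("a single habitation yields a distance layer increasing from it", {
  g <- grid_spec(60, 60, cell_size = 25)
  cfg <- landscape_config(habitation_intensity = 1e-12)  # max(1, Pois) -> 1
  ls <- gen_landscape(g, cfg, seed = 4)
  expect_equal(nrow(ls$features$habitations), 1L)
  hab <- ls$features$habitations[1, ]
  cc <- cell_centers(g)
  d <- ls$landscape$continuous$dist_habitation
  # exact Euclidean distance to the single point, everywhere
  for (k in 1:30) {
    i <- sample(60, 1); j <- sample(60, 1)
    expect_equal(d[i, j],
                 sqrt((cc$x[j] - hab[1])^2 + (cc$y[i] - hab[2])^2) / 1000,
                 tolerance = 1e-12)
  }
  expect_lte(min(d) * 1000, sqrt(2) * g$cell_size / 2)
})

test_that("null selection produces uniform use over the home disc", {
  tl <- tiny_landscape(n = 40, cell = 100)
  tr <- truth_config(fix_success_rate = 1, fixes_per_day = 48)
  beta0 <- setNames(rep(0, 4), continuous_covariates())
  rec <- simulate_bear_year(tl$stack, home_center = c(2000, 2000),
                            home_radius = 1200, beta = beta0,
                            start_date = "2008-05-01", n_days = 110,
                            truth = tr, seed = 6)
  pts <- cbind(rec$relocations$x, rec$relocations$y)
  n <- nrow(pts)
  expect_gte(n, 5000)
  r <- sqrt((pts[, 1] - 2000)^2 + (pts[, 2] - 2000)^2)
  expect_true(all(r <= 1200))
  ang <- atan2(pts[, 2] - 2000, pts[, 1] - 2000)
  # 4 equal-area annuli x 4 sectors
  rbin <- cut(r, breaks = 1200 * sqrt(0:4 / 4), include.lowest = TRUE)
  abin <- cut(ang, breaks = seq(-pi, pi, length.out = 5),
              include.lowest = TRUE)
  counts <- table(rbin, abin)
  chi <- sum((counts - n / 16)^2 / (n / 16))
  expect_lt(chi, qchisq(0.999, df = 15))
})

test_that("positive selection concentrates use as the exponential RSF predicts", {
  set.seed(11)
  g <- grid_spec(40, 40, cell_size = 100)
  cc <- cell_centers(g)
  landcover <- matrix(sample(1:7, 1600, replace = TRUE,
                             prob = c(.1, .1, .2, .2, .2, .1, .1)), 40, 40)
  stack <- landscape_stack(g, list(ndvi = matrix(0, 40, 40)), landcover)
  tr <- truth_config(fix_success_rate = 1)
  center <- c(2000, 2000); R <- 1500
  rec <- simulate_bear_year(stack, center, R, beta = c(clearcut = 2),
                            start_date = "2008-05-01", n_days = 60,
                            truth = tr, seed = 12)
  ex <- extract_at_points(stack, cbind(rec$relocations$x, rec$relocations$y))
  frac_used <- mean(ex$landcover == "clearcut")
  # brute-force e^2-weighted availability integral over disc cells
  gx <- rep(cc$x, each = 40); gy <- rep(cc$y, times = 40)
  in_disc <- (gx - center[1])^2 + (gy - center[2])^2 <= R^2
  cells <- extract_at_points(stack, cbind(gx[in_disc], gy[in_disc]))
  a_cl <- mean(cells$landcover == "clearcut")
  expected <- exp(2) * a_cl / (exp(2) * a_cl + (1 - a_cl))
  expect_gt(frac_used, a_cl)                    # exceeds areal availability
  expect_lt(abs(frac_used - expected), 0.05)    # matches the weighted integral

  # determinism of the relocation table
  rec2 <- simulate_bear_year(stack, center, R, beta = c(clearcut = 2),
                             start_date = "2008-05-01", n_days = 60,
                             truth = tr, seed = 12)
  expect_identical(rec$relocations, rec2$relocations)

  # runaway linear predictor is refused with advice
  expect_error(
    simulate_bear_year(stack, center, R, beta = c(clearcut = 60),
                       start_date = "2008-05-01", n_days = 1, truth = tr,
                       seed = 1),
    "rescale beta")
})

test_that("fate simulation respects boundaries and the configured loss rate", {
  empty_rec <- function(i)
    bear_year_record(paste0("B", i), 2008L,
                     tibble::tibble(bear_id = character(), year = integer(),
                                    timestamp = as.POSIXct(character()),
                                    x = numeric(), y = numeric(),
                                    dop = numeric()))
  recs <- lapply(1:2000, empty_rec)

  all_live <- simulate_fates(recs[1:50], truth_config(p_litter_loss = 0), seed = 1)
  expect_true(all(vapply(all_live, function(b) b$fate, "") == "survived"))
  expect_true(all(is.na(vapply(all_live, function(b)
    as.character(b$loss_date), NA_character_))))

  # degenerate loss-date distribution: window collapsed onto 8 May
  tr8 <- truth_config(p_litter_loss = 1, season_start = "05-08",
                      loss_end = "05-08")
  all_lost <- simulate_fates(recs[1:50], tr8, seed = 2)
  expect_true(all(vapply(all_lost, function(b) b$fate, "") == "lost"))
  expect_true(all(vapply(all_lost, function(b)
    as.character(b$loss_date), "") == "2008-05-08"))

  got <- simulate_fates(recs, truth_config(p_litter_loss = 0.35), seed = 3)
  frac <- mean(vapply(got, function(b) b$fate, "") == "lost")
  expect_lt(abs(frac - 0.35), 3 * sqrt(0.35 * 0.65 / 2000))
  # loss dates confined to the loss window
  ld <- as.Date(unlist(lapply(got, function(b)
    if (b$fate == "lost") as.character(b$loss_date))))
  expect_true(all(format(ld, "%m-%d") >= "05-01" &
                    format(ld, "%m-%d") <= "06-16"))

  expect_identical(simulate_fates(list(), truth_config(), seed = 1), list())
})

test_that("a regenerated study is byte-identical under the same seed", {
  a <- small_study(seed = 5)
  b <- small_study(seed = 5)
  expect_identical(telemetry_table(a$bear_years), telemetry_table(b$bear_years))
  expect_identical(fate_table(a$bear_years), fate_table(b$bear_years))
})

test_that("single-covariate selection recovers its coefficient by binned regression", {
  # defining RSF property: log(used density / available density) regressed on
  # the covariate has slope -> beta
  tl <- tiny_landscape(n = 40, cell = 100)
  tr <- truth_config(fix_success_rate = 1)
  beta <- c(ndvi = 0.8)
  rec <- simulate_bear_year(tl$stack, c(2000, 2000), 1500, beta,
                            start_date = "2008-05-01", n_days = 90,
                            truth = tr, seed = 21)
  used <- extract_at_points(tl$stack, cbind(rec$relocations$x,
                                            rec$relocations$y))
  av <- sample_availability(nrow(used) * 2,
                            region = c(500, 3500, 500, 3500), seed = 22)
  r2 <- sqrt((av[, 1] - 2000)^2 + (av[, 2] - 2000)^2)
  av <- av[r2 <= 1500, ]
  avx <- extract_at_points(tl$stack, av)
  # bin on the landscape-standardized scale the generator uses
  std <- (c(used$ndvi, avx$ndvi) - mean(tl$stack$continuous$ndvi)) /
    sd(tl$stack$continuous$ndvi)
  zu <- std[seq_len(nrow(used))]; za <- std[-seq_len(nrow(used))]
  brks <- quantile(za, 0:8 / 8); brks[1] <- -Inf; brks[9] <- Inf
  cu <- table(cut(zu, brks)); ca <- table(cut(za, brks))
  mid <- tapply(za, cut(za, brks), mean)
  keep <- cu > 5 & ca > 5
  slope <- coef(lm(log(as.numeric(cu[keep]) / as.numeric(ca[keep])) ~
                     mid[keep]))[2]
  expect_lt(abs(slope - 0.8), 0.2)
})
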