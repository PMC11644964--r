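# In-process broker contract and online forecasting.

stream_fixture <- function(n = 120, lag = 6, seed = 5) {
  series <- simulate_cgm(cgm_sim_params(n, seed = seed))
  task <- prepare_task(series, lag, 1)
  fit <- fit_forecaster(build_model(tiny_hp("gru", lag)), task$train,
                        epochs = 2, seed = 1)
  list(series = series, fit = fit, scaler = task$scaler, lag = lag)
}

test_that("the in-process broker delivers FIFO to every subscriber", {
  br <- inproc_broker()
  s1 <- subscribe(br, "bgl")
  s2 <- subscribe(br, "bgl")
  for (i in 1:100) publish(br, "bgl", list(i = i))
  m1 <- poll(s1)
  m2 <- poll(s2)
  expect_length(m1, 100)
  expect_length(m2, 100)
  expect_equal(vapply(m1, `[[`, numeric(1), "i"), as.numeric(1:100))
  expect_equal(vapply(m2, `[[`, numeric(1), "i"), as.numeric(1:100))
  # partial polls drain in order
  publish(br, "bgl", list(i = 101))
  publish(br, "bgl", list(i = 102))
  expect_equal(poll(s1, 1)[[1]]$i, 101)
  expect_equal(poll(s1)[[1]]$i, 102)
  # messages published on other topics are not delivered
  s3 <- subscribe(br, "other")
  publish(br, "bgl", list(i = 103))
  expect_length(poll(s3), 0)
  close_broker(br)
  expect_error(publish(br, "bgl", list(i = 1)),
               class = "glucast_lifecycle_error")
  expect_error(subscribe(br, "bgl"), class = "glucast_lifecycle_error")
  br2 <- inproc_broker()
  expect_error(publish(br2, "", list()), class = "glucast_param_error")
})

test_that("replaying a series emits each reading once, in sequence order", {
  ev <- sensor_source(cgm_sample())
  expect_equal(nrow(ev), 12)
  expect_equal(ev$value[1], 8.9)
  expect_equal(ev$value[12], 9.5)
  expect_equal(ev$seq, 0:11)
  expect_true(all(diff(ev$seq) > 0))
  # generator mode is seed-deterministic
  p <- cgm_sim_params(30, seed = 9)
  expect_identical(sensor_source(p)$value, sensor_source(p)$value)
})

test_that("streamed forecasts equal batch predictions through the broker", {
  fx <- stream_fixture()
  br <- inproc_broker()
  sub <- subscribe(br, "bgl")
  publish_events(br, "bgl", sensor_source(fx$series))
  log <- stream_forecast(poll(sub), fx$fit, horizon = 1)
  # independent batch oracle: rolling windows built with embed()
  v <- fx$series$glucose
  W <- stats::embed(v, fx$lag)[, fx$lag:1, drop = FALSE]
  batch <- pmax(0, predict(fx$fit, scale_values(W, fx$scaler)))
  expect_equal(nrow(log), nrow(W))
  expect_lt(max(abs(log$forecast - batch)), 1e-9)
  cnt <- attr(log, "counters")
  expect_equal(cnt$warmup, fx$lag - 1)
  expect_equal(cnt$forecasts + cnt$warmup, nrow(fx$series))
  expect_equal(cnt$duplicates + cnt$out_of_order + cnt$rejected, 0)
  expect_true(all(log$latency_ms >= 0))
})

test_that("duplicates, out-of-order and nonpositive events are screened", {
  fx <- stream_fixture(n = 40)
  ev <- sensor_source(fx$series)
  rows <- seq_len(20)
  mangled <- ev[c(rows[1:10], 10, rows[11:20]), ]   # duplicate seq 9
  mangled$value[5] <- -2                            # quarantined reading
  log <- stream_forecast(mangled, fx$fit, horizon = 1)
  cnt <- attr(log, "counters")
  expect_equal(cnt$duplicates, 1)
  expect_equal(cnt$rejected, 1)
  expect_length(attr(log, "rejects"), 1)
  # accounting: every input event is a forecast, warm-up or screened out
  expect_equal(cnt$forecasts + cnt$warmup + cnt$duplicates +
                 cnt$out_of_order + cnt$rejected, nrow(mangled))
  # an event arriving behind the newest sequence number is dropped
  ooo <- ev[c(1:10, 3), ]
  ooo$seq[11] <- 2L   # stale replayed reading
  log2 <- stream_forecast(ooo[-3, ], fx$fit)
  expect_equal(attr(log2, "counters")$out_of_order, 1)
})

test_that("the JSONL sink round-trips and appends", {
  fx <- stream_fixture(n = 30)
  log <- stream_forecast(sensor_source(fx$series), fx$fit, horizon = 2)
  path <- tempfile(fileext = ".jsonl")
  write_forecast_log(log, path)
  expect_equal(length(readLines(path)), nrow(log))
  back <- read_forecast_log(path)
  expect_equal(back$forecast, log$forecast)
  expect_equal(back$event_seq, log$event_seq)
  expect_equal(back$horizon, log$horizon)
  expect_equal(back$event_time, log$event_time)
  write_forecast_log(log, path, append = TRUE)
  expect_equal(nrow(read_forecast_log(path)), 2 * nrow(log))
  # empty stream produces an empty but readable file
  p2 <- tempfile(fileext = ".jsonl")
  write_forecast_log(log[0, ], p2)
  expect_true(file.exists(p2))
  expect_equal(nrow(read_forecast_log(p2)), 0)
})
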