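# Online forecasting pipeline: sensor source -> publish/subscribe broker ->
# sliding-window forecaster -> JSONL sink. The in-process broker realises
# the delivery contract (per-topic FIFO, loss-free fan-out to every
# subscriber); external adapters can satisfy the same contract.

#' In-process publish/subscribe broker
#'
#' A loss-free, per-topic FIFO broker for composing the streaming pipeline
#' without external infrastructure. Every subscriber to a topic receives
#' every event published after it subscribed, in publication order
#' (at-least-once, in-order delivery).
#'
#' @return An object of class `inproc_broker`.
#' @examples
#' br <- inproc_broker()
#' sub <- subscribe(br, "bgl")
#' publish(br, "bgl", list(value = 7.5))
#' poll(sub)
#' @export
inproc_broker <- function() {
  env <- new.env(parent = emptyenv())
  env$topics <- new.env(parent = emptyenv())
  env$closed <- FALSE
  structure(env, class = "inproc_broker")
}

check_open <- function(broker) {
  stopifnot(inherits(broker, "inproc_broker"))
  if (broker$closed) {
    abort("broker is closed.", class = "glucast_lifecycle_error")
  }
}

check_topic <- function(topic) {
  if (!is_scalar_string(topic) || !nzchar(topic)) {
    abort("topic name must be a nonempty string.",
          class = "glucast_param_error")
  }
}

#' @rdname inproc_broker
#' @param broker an `inproc_broker`.
#' @param topic nonempty topic name.
#' @param message any R object to deliver.
#' @export
publish <- function(broker, topic, message) {
  check_open(broker)
  check_topic(topic)
  t_env <- get_topic(broker, topic)
  for (sub in t_env$subs) sub$queue[[length(sub$queue) + 1L]] <- message
  invisible(broker)
}

get_topic <- function(broker, topic) {
  if (!exists(topic, envir = broker$topics, inherits = FALSE)) {
    t_env <- new.env(parent = emptyenv())
    t_env$subs <- list()
    assign(topic, t_env, envir = broker$topics)
  }
  get(topic, envir = broker$topics, inherits = FALSE)
}

#' @rdname inproc_broker
#' @export
subscribe <- function(broker, topic) {
  check_open(broker)
  check_topic(topic)
  t_env <- get_topic(broker, topic)
  sub <- new.env(parent = emptyenv())
  sub$queue <- list()
  t_env$subs <- c(t_env$subs, sub)
  structure(sub, class = "inproc_subscription")
}

#' @rdname inproc_broker
#' @param subscription an object from `subscribe()`.
#' @param n maximum number of messages to take (default all pending).
#' @return `poll()` returns a list of pending messages (possibly empty),
#'   removing them from the subscription queue.
#' @export
poll <- function(subscription, n = Inf) {
  stopifnot(inherits(subscription, "inproc_subscription"))
  k <- min(n, length(subscription$queue))
  if (k == 0) return(list())
  out <- subscription$queue[seq_len(k)]
  subscription$queue <- subscription$queue[-seq_len(k)]
  out
}

#' @rdname inproc_broker
#' @export
close_broker <- function(broker) {
  stopifnot(inherits(broker, "inproc_broker"))
  broker$closed <- TRUE
  invisible(broker)
}

#' Sensor event source
#'
#' Turns a glucose trace into a stream of sensor events (`time`, `value`,
#' `source_id`, `seq`). In replay mode an existing [cgm_series()] is
#' emitted exactly once, point by point; in simulate mode a fresh trace is
#' generated from [cgm_sim_params()] (seed-deterministic).
#'
#' @param x a `cgm_ts` series (replay) or `cgm_sim_params` (simulate).
#' @param source_id identifier stamped on every event.
#' @return A tibble of events ordered by `seq` (0-based, strictly
#'   increasing), one per reading.
#' @export
sensor_source <- function(x, source_id = "cgm-sensor-1") {
  series <- if (inherits(x, "cgm_sim_params")) simulate_cgm(x)
            else validate_cgm(x)
  tibble(time = series$time, value = series$glucose,
         source_id = source_id, seq = seq_len(nrow(series)) - 1L)
}

#' @rdname sensor_source
#' @param broker,topic destination broker and topic.
#' @param events an event tibble from `sensor_source()`.
#' @param rate events per second; `Inf` (default) publishes without
#'   pacing, a finite rate sleeps between events to emulate a live,
#'   possibly accelerated sensor.
#' @return `publish_events()` returns the number of events published,
#'   invisibly.
#' @export
publish_events <- function(broker, topic, events, rate = Inf) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    abort("`rate` must be a positive number of events per second (or Inf).",
          class = "glucast_param_error")
  }
  pause <- if (is.finite(rate)) 1 / rate else 0
  for (i in seq_len(nrow(events))) {
    publish(broker, topic, as.list(events[i, ]))
    if (pause > 0) Sys.sleep(pause)
  }
  invisible(nrow(events))
}

#' Sliding-window online forecasting
#'
#' Consumes sensor events in order while maintaining a window buffer of
#' the model's `lag` most recent scaled values. From the `lag`-th accepted
#' event onward, every event yields one forecast (`horizon` steps ahead,
#' in mmol/L, clamped at 0 on output). Events are screened first:
#' duplicated sequence numbers are dropped, events arriving more than
#' `tolerance` sequence numbers behind the newest are dropped as
#' out-of-order, and nonpositive glucose values are quarantined to a
#' rejects table rather than forecast.
#'
#' Streamed forecasts are identical (to floating tolerance) to batch
#' [predict.trained_forecaster()] calls on the corresponding windows of
#' the same series.
#'
#' @param events event tibble (or list of event lists) from
#'   [sensor_source()]/[poll()].
#' @param model a `trained_forecaster`.
#' @param horizon forecast steps ahead recorded on each output row.
#' @param tolerance allowed sequence-number lateness before an event is
#'   dropped (default 0: any regression on the newest sequence number is
#'   out-of-order).
#' @return A tibble of class `forecast_log` with columns `event_time`,
#'   `event_seq`, `forecast`, `horizon`, `model_id`, `latency_ms`.
#'   Attributes `counters` (warmup, duplicates, out_of_order, rejected,
#'   forecasts) and `rejects` (quarantined events) carry the audit trail.
#' @export
stream_forecast <- function(events, model, horizon = 1L, tolerance = 0L) {
  stopifnot(inherits(model, "trained_forecaster"))
  check_number(horizon, "horizon", min = 1, integerish = TRUE)
  check_number(tolerance, "tolerance", min = 0, integerish = TRUE)
  if (is.data.frame(events)) {
    events <- lapply(seq_len(nrow(events)), function(i) as.list(events[i, ]))
  }
  lag <- model$hp$lag
  model_id <- sprintf("%s-lag%d", model$hp$model_kind, lag)
  buffer <- numeric(0)
  seen_seq <- integer(0)
  max_seq <- -Inf
  counters <- c(warmup = 0L, duplicates = 0L, out_of_order = 0L,
                rejected = 0L, forecasts = 0L)
  rejects <- list()
  out <- list()
  for (ev in events) {
    t0 <- proc.time()[["elapsed"]]
    sq <- as.integer(ev$seq)
    if (sq %in% seen_seq) {
      counters[["duplicates"]] <- counters[["duplicates"]] + 1L
      next
    }
    if (is.finite(max_seq) && sq < max_seq - tolerance) {
      counters[["out_of_order"]] <- counters[["out_of_order"]] + 1L
      next
    }
    seen_seq <- c(seen_seq, sq)
    max_seq <- max(max_seq, sq)
    val <- as.numeric(ev$value)
    if (!is.finite(val) || val <= 0) {
      counters[["rejected"]] <- counters[["rejected"]] + 1L
      rejects[[length(rejects) + 1L]] <- ev
      next
    }
    buffer <- c(buffer, scale_values(val, model$scaler))
    if (length(buffer) > lag) buffer <- buffer[-1L]
    if (length(buffer) < lag) {
      counters[["warmup"]] <- counters[["warmup"]] + 1L
      next
    }
    fc <- max(0, predict(model, buffer))
    counters[["forecasts"]] <- counters[["forecasts"]] + 1L
    out[[length(out) + 1L]] <- tibble(
      event_time = ev$time, event_seq = sq, forecast = fc,
      horizon = as.integer(horizon), model_id = model_id,
      latency_ms = max(0, (proc.time()[["elapsed"]] - t0) * 1000))
  }
  log <- if (length(out)) dplyr::bind_rows(out) else
    tibble(event_time = as.POSIXct(character(0), tz = "UTC"),
           event_seq = integer(0), forecast = numeric(0),
           horizon = integer(0), model_id = character(0),
           latency_ms = numeric(0))
  class(log) <- c("forecast_log", class(log))
  attr(log, "counters") <- as.list(counters)
  attr(log, "rejects") <- rejects
  log
}

#' JSONL sink for forecast records
#'
#' `write_forecast_log()` appends one JSON object per record to a text
#' file; `read_forecast_log()` parses the file back into an identical
#' table.
#'
#' @param log a `forecast_log` tibble.
#' @param path output path.
#' @param append add to an existing file instead of replacing it.
#' @return `path` / the restored tibble.
#' @export
write_forecast_log <- function(log, path, append = FALSE) {
  stopifnot(is.data.frame(log))
  lines <- vapply(seq_len(nrow(log)), function(i) {
    rec <- as.list(log[i, ])
    rec$event_time <- format(rec$event_time, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' @rdname write_forecast_log
#' @export
read_forecast_log <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no forecast log at %s.", path), class = "glucast_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(event_time = as.POSIXct(character(0), tz = "UTC"),
                  event_seq = integer(0), forecast = numeric(0),
                  horizon = integer(0), model_id = character(0),
                  latency_ms = numeric(0)))
  }
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec$event_time <- as.POSIXct(rec$event_time,
                                 format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
    as_tibble(rec)
  })
  out <- dplyr::bind_rows(rows)
  out$event_seq <- as.integer(out$event_seq)
  out$horizon <- as.integer(out$horizon)
  out
}
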