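test_that("set_nu changes the growth magnitude and preserves orientation", {
  st <- tiny_two_pop(seed = 1)
  st <- apply_command(st, steering_command(8, "set_nu", value = 5e-5))
  expect_true(all(abs(st$pools$nu) == 5e-5))
  # inhibitory elements keep their create-above-target orientation
  expect_true(all(st$pools$nu[st$pools$element_type == "Den_in"] < 0))
  expect_true(all(st$pools$nu[st$pools$element_type == "Axon_ex"] > 0))
  # curve peak equals the new magnitude thereafter
  gc <- growth_curve(0, 5, 5e-5)
  expect_equal(growth_rate(gc, 2.5), 5e-5)
  expect_equal(nrow(st$command_log), 1)
})

test_that("set_nu can target one population and element type", {
  st <- tiny_two_pop(seed = 1)
  st <- apply_command(st, steering_command(1, "set_nu", population = "exc",
                                          element_type = "Axon_ex",
                                          value = 3e-4))
  p <- st$pools
  expect_true(all(p$nu[p$element_type == "Axon_ex"] == 3e-4))
  expect_true(all(p$nu[p$element_type == "Den_ex" &
                       p$neuron %in% population_ids(st, "exc")] == 1e-4))
})

test_that("unknown targets and out-of-bounds values are rejected", {
  st <- tiny_two_pop(seed = 1)
  expect_error(apply_command(st, steering_command(1, "set_nu",
                                                  population = "nope",
                                                  value = 1e-4)),
               "unknown population")
  expect_error(apply_command(st, steering_command(1, "set_nu",
                                                  element_type = "Axon_zz",
                                                  value = 1e-4)),
               "unknown element type")
  st$struct$param_bounds <- list(nu = c(0, 1e-3))
  expect_error(apply_command(st, steering_command(1, "set_nu", value = 2e-3)),
               "bounds")
  expect_error(apply_command(st, steering_command(1, "set_eta", value = 30)),
               "eps")
  expect_error(apply_command(st, steering_command(1, "set_update_interval",
                                                  value = -5)), "> 0")
})

test_that("update-interval command shifts subsequent update times", {
  st <- tiny_two_pop(seed = 2)
  sched <- command_log(steering_command(3, "set_update_interval", value = 500))
  res <- run_with_schedule(st, sched, horizon = 5)
  tr <- res$trajectory[res$trajectory$population == "exc", ]
  expect_equal(tr$time_ms, c(100, 200, 700, 1200, 1700))
  expect_equal(tr$update_interval_ms, c(100, 100, 500, 500, 500))
})

test_that("pause/resume are recorded but do not disturb the trajectory", {
  sched <- command_log(steering_command(2, "pause"),
                       steering_command(4, "resume"))
  a <- run_with_schedule(tiny_two_pop(seed = 5), sched, horizon = 6)
  b <- run_with_schedule(tiny_two_pop(seed = 5), command_log(), horizon = 6)
  expect_equal(a$trajectory$rate_spikes_per_s, b$trajectory$rate_spikes_per_s)
  expect_equal(nrow(a$state$command_log), 2)
})

test_that("empty schedule reproduces a plain run and replays are bit-identical", {
  a <- run_with_schedule(tiny_two_pop(seed = 9), command_log(), horizon = 8)
  b <- run_with_schedule(tiny_two_pop(seed = 9), command_log(), horizon = 8)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$state$conn, b$state$conn)

  # replay from a serialized command log: write, read, rerun
  sched <- command_log(steering_command(2, "set_nu", value = 2e-4),
                       steering_command(5, "set_update_interval", value = 200))
  f <- tempfile(fileext = ".csv")
  write_schedule(sched, f)
  c1 <- run_with_schedule(tiny_two_pop(seed = 9), sched, horizon = 8)
  c2 <- run_with_schedule(tiny_two_pop(seed = 9), read_schedule(f), horizon = 8)
  expect_identical(c1$trajectory, c2$trajectory)
  expect_false(identical(a$trajectory$nu, c1$trajectory$nu))
})

test_that("steered parameters change only at update boundaries", {
  sched <- command_log(steering_command(4, "set_nu", value = 7e-4))
  res <- run_with_schedule(tiny_two_pop(seed = 3), sched, horizon = 8)
  tr <- res$trajectory[res$trajectory$population == "exc", ]
  expect_equal(unique(tr$nu[tr$iteration < 4]), 1e-4)
  expect_equal(unique(tr$nu[tr$iteration >= 4]), 7e-4)
})

test_that("observer sinks receive every event once; failing sinks never halt the run", {
  seen1 <- new.env(); seen1$n <- 0L
  seen2 <- new.env(); seen2$n <- 0L
  bomb_calls <- new.env(); bomb_calls$n <- 0L
  sinks <- list(
    function(ev) seen1$n <- seen1$n + 1L,
    function(ev) seen2$n <- seen2$n + 1L,
    function(ev) { bomb_calls$n <- bomb_calls$n + 1L; stop("observer broke") }
  )
  res <- suppressWarnings(
    run_with_schedule(tiny_two_pop(seed = 6), command_log(), horizon = 5,
                      sinks = sinks))
  expect_equal(seen1$n, 5L)
  expect_equal(seen2$n, 5L)
  expect_equal(bomb_calls$n, 1L)  # disabled after the first failure
  expect_true(res$sink_status$disabled[3])
  expect_equal(nrow(res$trajectory), 10)  # 5 iterations x 2 populations
})

test_that("file sink rows equal the returned trajectory", {
  f <- tempfile(fileext = ".csv")
  res <- run_with_schedule(tiny_two_pop(seed = 13), command_log(),
                           horizon = 4, sinks = list(file_sink(f)))
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(res$trajectory))
  expect_equal(back$rate_spikes_per_s, res$trajectory$rate_spikes_per_s,
               tolerance = 1e-6)
  expect_equal(back$total_out_connections,
               res$trajectory$total_out_connections)
})
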