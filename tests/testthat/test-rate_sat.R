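# The 8-bit rate-saturation (refractory) machinery, checked both on its
# published micro-behaviors and against a full-resolution oracle that stores
# the exact 32-bit t_lim.

test_that("the allow gate compares 8-bit slices and honors the overflow flag", {
  b <- 10L; q <- 2^(b - 7)
  fresh <- list(tlim8b = 0, f_of = FALSE, f_dt = FALSE)
  a <- rate_sat_allow(fresh, 5 * q, b)        # any t with t8b > 0
  expect_true(a$allowed)
  expect_false(a$entry$f_dt)

  under <- list(tlim8b = 100, f_of = FALSE, f_dt = FALSE)
  a <- rate_sat_allow(under, 40 * q, b)       # t8b = 40 < 100
  expect_false(a$allowed)
  expect_true(a$entry$f_dt)                   # delta-t pending

  of <- list(tlim8b = 10, f_of = TRUE, f_dt = FALSE)
  a <- rate_sat_allow(of, 200 * q, b)         # t8b > tlim8b but f_of up
  expect_false(a$allowed)
  expect_true(a$entry$f_dt)
})

test_that("the update stores the slice of t + T_R and flags overflow", {
  for (b in c(7L, 10L, 15L)) {
    e <- rate_sat_update(list(tlim8b = 0, f_of = FALSE, f_dt = FALSE),
                         t = 0, t_r = 2^b, b_tr = b)
    expect_equal(e$tlim8b, 128)               # bit b_tr set
    expect_false(e$f_of)
    expect_false(e$f_dt)
  }
  # t + T_R carrying past bit b_tr -> stored slice below t8b -> overflow flag
  b <- 10L; q <- 8
  e <- rate_sat_update(list(tlim8b = 0, f_of = FALSE, f_dt = FALSE),
                       t = 200 * q, t_r = 100 * q, b_tr = b)
  expect_equal(e$tlim8b, (200 + 100) %% 256)
  expect_true(e$f_of)
})

test_that("a delayed fire is compensated from the previous t_lim", {
  # fire at t0; threshold reached at t1 < t_lim is denied; the event goes out
  # at the next input t2 > t_lim and the new t_lim is t2 + T_R - (t2 - t_lim)
  b <- 10L; q <- 8; t_r <- 150 * q
  t0 <- 10 * q
  e <- rate_sat_update(list(tlim8b = 0, f_of = FALSE, f_dt = FALSE),
                       t0, t_r, b)
  tlim <- t0 + t_r
  expect_equal(e$tlim8b, (tlim / q) %% 256)
  t1 <- tlim - 20 * q
  a <- rate_sat_allow(e, t1, b)
  expect_false(a$allowed)
  t2 <- tlim + 12 * q
  a2 <- rate_sat_allow(a$entry, t2, b)
  expect_true(a2$allowed)
  e2 <- rate_sat_update(a2$entry, t2, t_r, b)
  # next t_lim measured from the previous one, not from t2
  expect_equal(e2$tlim8b, ((tlim + t_r) / q) %% 256)
  expect_false(e2$f_dt)
})

test_that("refresh lowers overflow flags first, then clears the slice", {
  ones <- list(tlim8b = matrix(c(17, 200), 2, 1),
               f_of = matrix(TRUE, 2, 1), f_dt = matrix(FALSE, 2, 1))
  r1 <- rate_sat_refresh(ones)
  expect_false(any(r1$f_of))
  expect_equal(r1$tlim8b, ones$tlim8b)        # slices kept while f_of was up
  r2 <- rate_sat_refresh(r1)
  expect_true(all(r2$tlim8b == 0))            # second pass clears
  r3 <- rate_sat_refresh(r2)
  expect_identical(r3, r2)                    # idempotent after two passes
  # works on a whole unit state too
  cfg <- unit_config(2, 2, kernel_spec(1), th = 10, t_r = 256, b_tr = 8)
  st <- conv_unit_state(cfg)
  st$rs$tlim8b[] <- 9
  st2 <- rate_sat_refresh(st)
  expect_true(all(st2$rs$tlim8b == 0))
})

test_that("the mechanism is never early and agrees with the 32-bit oracle within a quantum", {
  # vectorized batch of independent random fire schedules per configuration;
  # the oracle stores the full-resolution t_lim. Disagreements may only occur
  # (i) within one quantum of the true t_lim, (ii) in the first quantum after
  # a refresh window starts (t8b == 0 denies), or (iii) after a refresh pulse
  # landed inside a denial streak, where the 8-bit store provably loses the
  # delta-t information (the mechanism then fires late, never early).
  for (cse in list(c(b = 10, t_r = 1504, lo = 20, hi = 250),
                   c(b = 15, t_r = 51200, lo = 200, hi = 800),
                   c(b = 7, t_r = 100, lo = 2, hi = 30))) {
    set.seed(cse["b"])
    N <- 4000L; steps <- 12L
    b <- cse["b"]; t_r <- cse["t_r"]
    q <- 2^(b - 7); W <- 2^(b + 1)
    ent <- list(tlim8b = rep(0, N), f_of = rep(FALSE, N),
                f_dt = rep(FALSE, N))
    t <- sample.int(10 * W, N, replace = TRUE)
    otlim <- rep(-1, N); opend <- rep(FALSE, N)
    ofirst <- rep(NA_real_, N)  # first denied attempt of the current streak
    nref <- floor(t / W)
    crossed <- rep(FALSE, N)
    for (s in seq_len(steps)) {
      t <- t + sample(cse["lo"]:cse["hi"], N, replace = TRUE)
      nr <- floor(t / W)
      dr <- nr - nref
      crossed <- crossed | (dr > 0 & opend)
      ent <- evconvnet:::refresh_n(ent, pmin(dr, 2))
      nref <- nr
      a <- rate_sat_allow(ent, t, b)
      o_allow <- t > otlim
      # safety: never fire before t_lim - one quantum, on every schedule
      expect_false(any(a$allowed & otlim >= 0 & t <= otlim - q))
      dis <- a$allowed != o_allow
      unexplained <- dis & !(abs(t - otlim) <= q) & !((t %% W) < q) & !crossed
      expect_equal(sum(unexplained), 0L)
      # an allow the oracle denies can only be the one-quantum-early case
      expect_false(any(dis & a$allowed & otlim >= 0 & abs(t - otlim) > q))
      upd <- rate_sat_update(a$entry, t, t_r, b)
      f <- a$allowed
      ent <- list(tlim8b = ifelse(f, upd$tlim8b, a$entry$tlim8b),
                  f_of = ifelse(f, upd$f_of, a$entry$f_of),
                  f_dt = ifelse(f, upd$f_dt, a$entry$f_dt))
      ofirst <- ifelse(!f & !opend, t, ofirst)
      # ideal fire time of a delayed fire: the previous t_lim, or (first
      # cycle, no t_lim yet) the first denied threshold attempt
      base <- ifelse(otlim >= 0, otlim, ofirst)
      dt <- ifelse(opend & f, pmin(pmax(t - base, 0), t_r), 0)
      otlim <- ifelse(f, t + t_r - dt, otlim)
      ofirst <- ifelse(f, NA_real_, ofirst)
      opend <- !f
    }
  }
})

test_that("saturation and linear laws hold for a single pixel", {
  tick <- 1e-6
  t_r <- 51200                                 # 51.2 ms at 1 us ticks
  cfg <- unit_config(1, 1, kernel_spec(1), th = 10, t_r = t_r, b_tr = 15)
  dur <- 20
  # far above the boundary: f_out = 1/T_R within 2%
  train <- gen_isi_train(2000, dur, seed = 11, tick_seconds = tick)
  r <- process_stream(conv_unit_state(cfg), train, cfg)
  f_out <- nrow(r$events) / dur
  expect_lt(abs(f_out - 1 / 0.0512) / (1 / 0.0512), 0.02)
  # below the boundary Th/T_R = 195.3 Hz: f_out = f_in/Th
  train <- gen_isi_train(100, dur, seed = 12, tick_seconds = tick)
  r <- process_stream(conv_unit_state(cfg), train, cfg)
  expect_lt(abs(nrow(r$events) / dur - 10) / 10, 0.05)
})

test_that("without the delta-t correction the saturated rate falls below 1/T_R", {
  tick <- 1e-6
  cfg <- unit_config(1, 1, kernel_spec(1), th = 10, t_r = 51200, b_tr = 15)
  cfg_no <- cfg; cfg_no$dt_correction <- FALSE
  train <- gen_isi_train(2000, 20, seed = 13, tick_seconds = tick)
  with_dt <- nrow(process_stream(conv_unit_state(cfg), train, cfg)$events)
  without <- nrow(process_stream(conv_unit_state(cfg_no), train, cfg_no)$events)
  expect_lt(without, with_dt)
})
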