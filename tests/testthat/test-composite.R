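test_that("enumerate_combinations counts and orders subsets deterministically", {
  expect_length(enumerate_combinations(PHENO_COVARIATES), 127)
  expect_length(enumerate_combinations(c("a", "b", "c")), 7)
  expect_length(enumerate_combinations("a"), 1)
  expect_error(enumerate_combinations(c("a", "a")), "duplicated")
  subs <- enumerate_combinations(c("b", "a", "c"))
  sizes <- lengths(subs)
  expect_true(!is.unsorted(sizes))
  ids <- vapply(subs, subset_id, "")
  expect_identical(ids[1:3], c("a", "b", "c"))  # lexicographic within size
})

test_that("build_design produces the balanced daily design", {
  w <- toy_weather(60, tas = 25)
  env <- data.frame(station_id = "TST", harvest_year = 2001,
                    sowing = as.Date(NA), emergence = as.Date(NA),
                    jointing = w$date[1], heading = w$date[1] + 10,
                    senescence = as.Date(NA))
  dm <- list(tas = drc_spec("wang_engel", "tas", "jointing-heading",
                            list(psi_base = 0, psi_opt = 25, psi_max = 35, r = 1)))
  des <- build_design(env, w, dm, "jointing-heading")
  expect_equal(nrow(des), 20)
  expect_equal(sum(des$label == 0), 10)
  expect_equal(sum(des$label == 1), 10)
  # constant optimum: dose is the arithmetic sequence 0, r, 2r, ...
  expect_equal(des$Z_tas, (0:19) * 1)
})

test_that("build_design matches an explicit per-day loop on two environments", {
  set.seed(41)
  w <- toy_weather(80, tas = runif(80, 0, 35))
  env <- data.frame(station_id = "TST", harvest_year = c(2001, 2001),
                    sowing = as.Date(NA), emergence = as.Date(NA),
                    jointing = c(w$date[1], w$date[20]),
                    heading = c(w$date[1] + 8, w$date[20] + 12),
                    senescence = as.Date(NA))
  spec <- drc_spec("broken_stick", "tas", "jointing-heading",
                   list(psi_base = 5, slope = 0.2))
  des <- build_design(env, w, list(tas = spec), "jointing-heading")

  # brute force: env 2, day index d (dose over first d days of its window)
  i0 <- 20; D <- 12
  x <- w$tas[i0:(i0 + 2 * D - 2)]
  f <- ifelse(x > 5, (x - 5) * 0.2, 0)
  manual <- c(0, cumsum(f))[1:(2 * D)]
  got <- des[des$env == "TST/2001" & seq_len(nrow(des)) > 2 * 8, ]
  expect_equal(got$Z_tas, manual, tolerance = 1e-12)
  expect_equal(got$label, as.integer(0:(2 * D - 1) >= D))

  env$heading[2] <- w$date[80]  # buffer would run past the weather
  expect_error(build_design(env, w, list(tas = spec), "jointing-heading"),
               "buffer")
})

make_logistic_design <- function(n = 400, crossing = 10, noise = 1.5, seed = 42) {
  set.seed(seed)
  Z <- runif(n, 0, 20)
  p <- plogis((Z - crossing) / noise * 2)
  data.frame(env = "e", day = seq_len(n), label = rbinom(n, 1, p), Z_tas = Z)
}

test_that("fit_composite recovers the probability crossing of a 1-D design", {
  des <- make_logistic_design()
  m <- fit_composite(des, "tas")
  crossing <- -m$coefficients[["(Intercept)"]] / m$coefficients[["Z_tas"]]
  expect_lt(abs(crossing - 10), 1)

  dup <- fit_composite(rbind(des, des), "tas")  # likelihood invariance
  expect_equal(unname(dup$coefficients), unname(m$coefficients),
               tolerance = 1e-6)

  expect_error(fit_composite(des, "GR"), "Z_GR")
  one_class <- des; one_class$label <- 1
  expect_error(fit_composite(one_class, "tas"), "single class")
})

test_that("complete separation falls back to a finite ridge fit", {
  des <- data.frame(env = "e", day = 1:40, label = rep(c(0, 1), each = 20),
                    Z_tas = c(seq(0, 9.5, length.out = 20),
                              seq(10.5, 20, length.out = 20)))
  m <- fit_composite(des, "tas")
  expect_true(m$penalized)
  expect_true(all(is.finite(m$coefficients)))
  crossing <- -m$coefficients[["(Intercept)"]] / m$coefficients[["Z_tas"]]
  expect_lt(abs(crossing - 10), 1)
})

test_that("roc_threshold maximizes Youden's J", {
  tau <- roc_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(tau), 0.5)
  expect_equal(attr(tau, "J"), 1)

  # 20-point toy set vs exhaustive search over every candidate threshold
  set.seed(43)
  p <- runif(20); y <- rbinom(20, 1, p)
  if (length(unique(y)) > 1) {
    u <- sort(unique(p))
    cand <- (u[-1] + u[-length(u)]) / 2
    J <- vapply(cand, function(t)
      mean(p[y == 1] >= t) + mean(p[y == 0] < t) - 1, 0)
    best <- min(cand[J == max(J)])
    expect_equal(as.numeric(suppressWarnings(roc_threshold(p, y))), best)
  }

  expect_error(roc_threshold(c(0.2, 0.8), c(1, 1)), "both classes")
  set.seed(44)
  expect_warning(roc_threshold(runif(10000), rbinom(10000, 1, 0.5)),
                 "independent")
})

test_that("nested models do not lose training log-likelihood", {
  wb <- world_b()
  g <- wb$grid$models
  expect_gte(g[["GR+tas"]]$loglik, g[["tas"]]$loglik - 1e-6)
  expect_gte(g[["GR+SPI+tas"]]$loglik, g[["GR+tas"]]$loglik - 1e-6)
  expect_gte(g[["GR+SPI+tas"]]$loglik, g[["SPI"]]$loglik - 1e-6)
})

test_that("predict_phase_end crosses once, censors, and ignores zero-beta covariates", {
  w <- toy_weather(120, tas = 25)
  dm <- list(tas = drc_spec("wang_engel", "tas", NULL,
                            list(psi_base = 0, psi_opt = 25, psi_max = 35, r = 1)),
             GR = drc_spec("linear", "GR", NULL, list(intercept = 1, slope = 0)))
  base <- structure(list(phase = "jointing-heading", subset = "tas",
                         subset_id = "tas",
                         coefficients = c("(Intercept)" = -10, Z_tas = 1),
                         drc_map = dm["tas"], threshold = 0.5,
                         penalized = FALSE, loglik = NA_real_, complexity = 1L),
                    class = "composite_model")
  pr <- predict_phase_end(base, w, w$date[1], 60)
  expect_false(pr$censored)
  expect_equal(pr$duration, 10)  # dose reaches 10 after 10 days at the optimum

  plus_zero <- base
  plus_zero$subset <- c("GR", "tas")
  plus_zero$coefficients <- c("(Intercept)" = -10, Z_GR = 0, Z_tas = 1)
  plus_zero$drc_map <- dm
  expect_equal(predict_phase_end(plus_zero, w, w$date[1], 60)$duration, 10)

  unreachable <- base
  # bounded doses with a weak slope: eta stays negative, tau never reached
  unreachable$coefficients[] <- c(-10, 0.01)
  pr2 <- predict_phase_end(unreachable, w, w$date[1], 60)
  expect_true(pr2$censored)
  expect_equal(pr2$duration, 60)
})

test_that("chain_phases propagates censoring and is translation-equivariant", {
  cfg <- synthetic_config(n_stations = 1, n_years = 3, seed = 51)
  w <- gen_weather(cfg)
  chain <- truth_model_chain(cfg)
  sowing <- as.Date("2000-10-30")
  res <- chain_phases(chain, w, sowing)
  expect_false(any(res$censored))
  expect_true(all(diff(as.numeric(res$end)) > 0))

  # same weather relabelled k days later: all predictions shift by k
  k <- 7
  w2 <- w; w2$date <- w$date + k
  res2 <- chain_phases(chain, w2, sowing + k)
  expect_equal(as.numeric(res2$end - res$end), rep(k, 4))

  # censored first phase censors everything downstream
  dead <- chain
  dead[["sowing-emergence"]]$coefficients[] <-
    c(-50, rep(1e-9, length(dead[["sowing-emergence"]]$coefficients) - 1))
  res3 <- chain_phases(dead, w, sowing)
  expect_true(all(res3$censored))

  expect_error(chain_phases(chain[1:3], w, sowing), "missing model")
})

test_that("evaluate_model computes standard metrics and excludes censored pairs", {
  expect_equal(evaluate_model(1:5, 1:5),
               list(rmse = 0, mae = 0, cor = 1, n = 5, n_censored = 0))
  m <- evaluate_model(1:5 + 3, 1:5)
  expect_equal(m$rmse, 3); expect_equal(m$mae, 3); expect_equal(m$cor, 1)

  obs <- c(10, 12, 15, 9, 20); pred <- c(11, 10, 18, 9, 16)
  m2 <- evaluate_model(pred, obs)
  expect_equal(m2$rmse, sqrt(mean((obs - pred)^2)))
  expect_equal(m2$mae, mean(abs(obs - pred)))
  expect_equal(m2$cor, cor(obs, pred))

  m3 <- evaluate_model(c(1, NA, 3), c(1, 2, 3))
  expect_equal(m3$n_censored, 1)
  expect_equal(m3$n, 2)

  set.seed(45)
  for (i in 1:5) {
    p <- rnorm(10); o <- rnorm(10)
    mm <- evaluate_model(p, o)
    expect_gte(mm$rmse, mm$mae)  # norm inequality
  }
})

test_that("composite models and grids survive a JSON round-trip", {
  wb <- world_b()
  m <- wb$grid$models[["GR+tas"]]
  path <- withr::local_tempfile(fileext = ".json")
  write_composite(m, path)
  back <- read_composite(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$threshold, m$threshold)
  expect_equal(back$drc_map$tas$params, m$drc_map$tas$params)

  gpath <- withr::local_tempfile(fileext = ".json")
  write_model_grid(wb$grid, gpath)
  gback <- read_model_grid(gpath)
  expect_identical(names(gback$models), names(wb$grid$models))
  expect_equal(gback$models[["tas"]]$coefficients,
               wb$grid$models[["tas"]]$coefficients)
})
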