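test_that("noiseless saturating curves are recovered to high precision", {
  t <- 0:59
  g <- 0.8 + 0.2 * exp(-t / 20)
  fit <- fit_trajectory_family(t, g, "sat_decay")
  expect_false(fit$flagged)
  expect_equal(unname(coef(fit)[c("ginf", "g0", "tau")]), c(0.8, 1.0, 20),
               tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  grow <- 0.1 + 0.3 * (1 - exp(-t / 15))
  fg <- fit_trajectory_family(t, grow, "sat_growth")
  expect_equal(unname(coef(fg)[c("ginf", "g0", "tau")]), c(0.4, 0.1, 15),
               tolerance = 1e-6)

  sig <- 0.2 + 0.5 / (1 + exp(-(t - 22) / 3))
  fs <- fit_trajectory_family(t, sig, "sigmoid")
  expect_equal(unname(coef(fs)[c("g0", "ginf", "t_m", "s")]),
               c(0.2, 0.7, 22, 3), tolerance = 1e-5)

  expect_error(fit_trajectory_family(0:2, c(1, 2, 3), "sat_decay"),
               "at least 4")
})

test_that("a constant series degenerates in both exponential families", {
  t <- 0:30
  g <- rep(0.5, 31)
  for (fam in c("sat_decay", "sat_growth")) {
    fit <- fit_trajectory_family(t, g, fam)
    expect_false(fit$flagged)
    expect_lt(fit$rss, 1e-20)
    expect_equal(unname(coef(fit)["g0"]), unname(coef(fit)["ginf"]),
                 tolerance = 1e-6)
    expect_equal(temporal_change(fit), 0, tolerance = 1e-8)
  }
})

test_that("AIC selection identifies the generating family at low noise", {
  t <- 0:59
  set.seed(8)
  cases <- list(
    sat_decay = 0.8 + 0.2 * exp(-t / 20),
    sat_growth = 0.1 + 0.3 * (1 - exp(-t / 15)),
    sigmoid = 0.2 + 0.5 / (1 + exp(-(t - 22) / 3)))
  for (fam in names(cases)) {
    g <- cases[[fam]] + rnorm(length(t), 0, 0.01)
    fits <- lapply(c("sat_decay", "sat_growth", "sigmoid"),
                   function(f) fit_trajectory_family(t, g, f))
    rss <- vapply(fits, function(f) f$rss, numeric(1))
    names(rss) <- c("sat_decay", "sat_growth", "sigmoid")
    if (fam == "sigmoid") expect_identical(names(which.min(rss)), "sigmoid")
    best <- select_best_trajectory(fits)
    expect_identical(best$family, fam)
  }
})

test_that("AIC improves monotonically as noise decreases (family fixed)", {
  t <- 0:59
  truth <- 0.8 + 0.2 * exp(-t / 20)
  set.seed(12)
  eps <- rnorm(length(t))
  aics <- vapply(c(0.05, 0.01, 0.002), function(s) {
    fit_trajectory_family(t, truth + s * eps, "sat_decay")$aic
  }, numeric(1))
  expect_true(all(diff(aics) < 0))
})

test_that("selection applies the parsimony and tie rules", {
  mk <- function(family, aic) {
    structure(list(family = family, coefficients = c(a = 1), rss = 1,
                   aic = aic, n_points = 60, flagged = FALSE,
                   t = 0:59, g = rep(1, 60)), class = "ct_traj")
  }
  # clear winner
  s1 <- select_best_trajectory(list(mk("sat_decay", -100),
                                    mk("sat_growth", -50),
                                    mk("sigmoid", -40)))
  expect_identical(s1$family, "sat_decay")
  expect_match(attr(s1$selection, "rule"), "lowest AIC")
  # delta <= 2: 3-coefficient decay beats 4-coefficient sigmoid
  s2 <- select_best_trajectory(list(mk("sigmoid", -100),
                                    mk("sat_decay", -99),
                                    mk("sat_growth", -20)))
  expect_identical(s2$family, "sat_decay")
  expect_match(attr(s2$selection, "rule"), "fewest")
  # exact tie: supply order decides (exponentials first by convention)
  s3 <- select_best_trajectory(list(mk("sat_decay", -10),
                                    mk("sat_growth", -10),
                                    mk("sigmoid", -10)))
  expect_identical(s3$family, "sat_decay")
  # order invariance away from ties
  s4 <- select_best_trajectory(list(mk("sigmoid", -40),
                                    mk("sat_growth", -50),
                                    mk("sat_decay", -100)))
  expect_identical(s4$family, s1$family)
  expect_error(select_best_trajectory(list(
    structure(list(family = "sigmoid", aic = Inf, rss = Inf, flagged = TRUE),
              class = "ct_traj"))), "flagged")
})

test_that("temporal change evaluates the fitted curve at the hour ends", {
  t <- 0:59
  fit <- fit_trajectory_family(t, 0.8 + 0.2 * exp(-t / 20), "sat_decay")
  expect_equal(temporal_change(fit), (0.8 + 0.2 * exp(-3)) - 1.0,
               tolerance = 1e-9)
  # steep sigmoid limit approaches a unit step
  sig <- 0 + 1 / (1 + exp(-(t - 30) / 0.2))
  fsig <- fit_trajectory_family(t, sig, "sigmoid")
  expect_equal(temporal_change(fsig), 1, tolerance = 1e-3)
})

test_that("regime values are read off curves at the three time points", {
  t <- 0:59
  fits <- list(
    X = fit_trajectory_family(t, 0.72 + 0.23 * exp(-t / 20), "sat_decay"),
    Y = fit_trajectory_family(t, -0.08 - 0.22 * exp(-t / 20), "sat_growth"))
  rv <- regime_values(fits, rot_minute = 22)
  expect_identical(rv$gain, c("X", "Y"))
  expect_equal(rv$at_minute1[1], 0.95, tolerance = 1e-8)
  expect_equal(rv$at_rot[1], 0.72 + 0.23 * exp(-22 / 20), tolerance = 1e-8)
  expect_equal(rv$at_minute60[2], -0.08 - 0.22 * exp(-3), tolerance = 1e-8)
  # coincident time points
  rv0 <- regime_values(fits, rot_minute = 0)
  expect_identical(rv0$at_rot, rv0$at_minute1)
  # missing ROT
  rvNA <- regime_values(fits, rot_minute = NA)
  expect_true(all(is.na(rvNA$at_rot)))
  expect_false(any(is.na(rvNA$at_minute1)))
  expect_error(regime_values(fits, rot_minute = 70), "span")
})

test_that("regime extraction shrinks scatter when crossings are synchronized", {
  # cohort built so every recording crosses X = 0.81 at its own ROT minute
  set.seed(99)
  t <- 0:59
  rots <- round(rnorm(12, 22.4, 4.8))
  x0 <- rnorm(12, 0.95, 0.03)
  xinf <- rnorm(12, 0.72, 0.02)
  at1 <- numeric(12); atrot <- numeric(12)
  for (j in 1:12) {
    tau <- -rots[j] / log((0.81 - xinf[j]) / (x0[j] - xinf[j]))
    g <- xinf[j] + (x0[j] - xinf[j]) * exp(-t / tau) + rnorm(60, 0, 0.005)
    fit <- fit_trajectory(t, g)
    rv <- regime_values(list(X = fit), rot_minute = rots[j])
    at1[j] <- rv$at_minute1; atrot[j] <- rv$at_rot
  }
  expect_lt(sd(atrot), sd(at1))
  expect_equal(mean(atrot), 0.81, tolerance = 0.02)
})

test_that("cohort table has the expected cardinality and round-trips", {
  t <- 0:59
  mkfits <- function() list(
    X = fit_trajectory_family(t, 0.72 + 0.23 * exp(-t / 20), "sat_decay"),
    Y = fit_trajectory_family(t, -0.08 - 0.22 * exp(-t / 20), "sat_growth"),
    Z = fit_trajectory_family(t, 0.12 - 0.10 * exp(-t / 25), "sat_growth"))
  regimes <- list(); meta <- NULL
  for (subj in 1:2) for (sess in 1:2) {
    rot <- if (subj == 2 && sess == 2) NA else 20 + subj + sess
    regimes[[length(regimes) + 1]] <- regime_values(mkfits(), rot)
    meta <- rbind(meta, data.frame(subject = subj, session = sess,
                                   seizure_duration = 30 + subj,
                                   placement = "BL", charge = 400,
                                   etomidate_dose = 20,
                                   benzodiazepine = FALSE,
                                   session_number = sess, rot_minute = rot))
  }
  tab <- cohort_table(regimes, meta)
  expect_identical(nrow(tab), 2L * 2L * 3L * 3L)
  # missing ROT keeps its rows, flagged
  miss <- tab[tab$subject == 2 & tab$session == 2 & tab$timepoint == "rot", ]
  expect_identical(nrow(miss), 3L)
  expect_true(all(miss$missing))
  tmp <- tempfile(fileext = ".tsv")
  write_cohort_table(tab, tmp)
  back <- read_cohort_table(tmp)
  expect_identical(back$value, tab$value)
  expect_identical(back$gain, tab$gain)
})
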