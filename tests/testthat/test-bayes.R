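# simulate a group-model epoch table: y = b0 + bg*g + u_j + e
simGroupTable <- function(n_part = 20, n_ev = 30, b0 = 0, bg = 0.2,
                          sd_u = 0.3, sd_e = 1, seed = 1) {
  set.seed(seed)
  part <- rep(sprintf("p%02d", seq_len(n_part)), each = n_ev)
  grp <- rep(rep(c("PD", "HC"), length.out = n_part), each = n_ev)
  u <- rnorm(n_part, 0, sd_u)
  g <- ifelse(grp == "PD", 1, -1)
  data.frame(value = b0 + bg * g + u[as.integer(factor(part))] +
               rnorm(length(part), 0, sd_e),
             participant = part, group = grp, stringsAsFactors = FALSE)
}

fastSpec <- function(kind = "group", seed = 1)
  modelSpec(kind, chains = 2, draws = 800, warmup = 500, seed = seed)

test_that("model preconditions are enforced", {
  tab <- simGroupTable(2, 5)
  one <- tab[tab$participant == "p01", ]
  expect_error(fitHierModel(one, fastSpec()), "2 participants")
  bad <- tab; bad$value[1] <- NA
  expect_error(fitHierModel(bad, fastSpec()), "finite")
  expect_error(modelSpec("group", chains = 1), "chains")
})

test_that("the group model recovers a known fixed effect", {
  skip_if_not_installed("lme4")
  tab <- simGroupTable(20, 30, b0 = 0.1, bg = 0.2, seed = 2)
  fit <- fitHierModel(tab, fastSpec(seed = 2))
  s <- fit$summary
  bg <- s[s$effect == "group", ]
  # a single fit is checked against the dataset's realized effect (the
  # REML estimate); truth-coverage calibration is a replicate property
  lm4 <- lme4::lmer(value ~ g + (1 | participant),
                    data = transform(tab, g = ifelse(group == "PD", 1,
                                                     -1)))
  real <- lme4::fixef(lm4)[["g"]]
  expect_lt(abs(bg$mean - real), 0.05)
  expect_true(bg$q2.5 < real && bg$q97.5 > real)
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  # R-hat reported for every monitored parameter
  expect_true(all(is.finite(s$rhat[!startsWith(s$effect, "u[")])))
  # reproducible from the seed
  fit2 <- fitHierModel(tab, fastSpec(seed = 2))
  expect_identical(fit$draws, fit2$draws)
})

test_that("posterior means approach the (RE)ML fit on well-identified
           data", {
  skip_if_not_installed("lme4")
  tab <- simGroupTable(24, 40, b0 = 0.15, bg = 0.25, sd_u = 0.4,
                       sd_e = 0.8, seed = 3)
  fit <- fitHierModel(tab, fastSpec(seed = 3))
  lm4 <- lme4::lmer(value ~ g + (1 | participant),
                    data = transform(tab, g = ifelse(group == "PD", 1,
                                                     -1)))
  fe <- lme4::fixef(lm4)
  s <- fit$summary
  expect_lt(abs(s$mean[s$effect == "intercept"] - fe[["(Intercept)"]]),
            0.02)
  expect_lt(abs(s$mean[s$effect == "group"] - fe[["g"]]), 0.02)
  expect_lt(abs(s$mean[s$effect == "sigma"] -
                  attr(lme4::VarCorr(lm4), "sc")), 0.03)
})

test_that("hierarchical shrinkage pulls sparse participants toward the
           group mean", {
  # two participants with the same raw mean 0.8, one with 2 events and
  # one with 50; the sparse one's random effect shrinks further
  set.seed(4)
  dense <- data.frame(value = 0.8 + rnorm(50, 0, 0.6),
                      participant = "dense", group = "PD")
  sparse <- data.frame(value = 0.8 + rnorm(2, 0, 0.6),
                       participant = "sparse", group = "PD")
  sparse$value <- sparse$value - mean(sparse$value) + mean(dense$value)
  others <- do.call(rbind, lapply(1:10, function(j)
    data.frame(value = rnorm(30, 0, 0.6),
               participant = sprintf("o%02d", j), group = "PD")))
  hc <- do.call(rbind, lapply(1:6, function(j)
    data.frame(value = rnorm(30, 0, 0.6),
               participant = sprintf("h%02d", j), group = "HC")))
  tab <- rbind(dense, sparse, others, hc)
  fit <- fitHierModel(tab, fastSpec(seed = 4))
  parts <- fit$participants
  uDense <- fit$summary$mean[fit$summary$effect ==
                               sprintf("u[%d,1]", match("dense", parts))]
  uSparse <- fit$summary$mean[fit$summary$effect ==
                                sprintf("u[%d,1]", match("sparse",
                                                         parts))]
  expect_lt(abs(uSparse), abs(uDense))
  expect_gt(abs(uDense), 0.2)     # the dense signal is actually seen
})

test_that("condition contrasts are computed on draws", {
  set.seed(5)
  n_part <- 12
  part <- rep(sprintf("p%02d", 1:n_part), each = 30)
  cond <- rep(rep(c("freeze", "stop", "successful"), each = 10), n_part)
  mu <- c(freeze = -0.3, stop = 0.2, successful = 0)
  u <- rnorm(n_part, 0, 0.2)
  tab <- data.frame(value = mu[cond] + u[as.integer(factor(part))] +
                      rnorm(length(part), 0, 0.5),
                    participant = part, condition = cond,
                    stringsAsFactors = FALSE)
  fit <- fitHierModel(tab, fastSpec("condition", seed = 5))
  cc <- conditionContrasts(fit)
  fs <- cc[cc$effect == "freeze - stop", ]
  expect_lt(fs$q97.5, 0)            # freeze below stop by construction
  expect_lt(abs(fs$mean - (-0.5)), 0.15)
  # contrast of a condition with itself is exactly zero
  self <- conditionContrasts(fit, list(c("stop", "stop")))
  expect_equal(self$mean, 0)
  expect_equal(self$q97.5, 0)
  # symmetric conditions -> CrI straddles zero
  tab0 <- tab
  tab0$value <- u[as.integer(factor(part))] + rnorm(nrow(tab0), 0, 0.5)
  cc0 <- conditionContrasts(fitHierModel(tab0,
                                         fastSpec("condition", seed = 6)))
  expect_true(all(cc0$q2.5 < 0 & cc0$q97.5 > 0))
})

test_that("severity model standardizes covariates and recovers coupling", {
  set.seed(7)
  n_part <- 18
  pct <- runif(n_part, 0, 40)
  updrs <- rnorm(n_part, 44, 10)
  u <- rnorm(n_part, 0, 0.2)
  part <- rep(sprintf("p%02d", 1:n_part), each = 20)
  idx <- as.integer(factor(part))
  zpct <- (pct - mean(pct)) / sd(pct)
  tab <- data.frame(value = 0.3 * zpct[idx] + u[idx] +
                      rnorm(length(part), 0, 0.4),
                    participant = part,
                    pct_time_frozen = pct[idx], updrs = updrs[idx],
                    stringsAsFactors = FALSE)
  fit <- severityModel(tab, fastSpec("severity", seed = 7))
  s <- fit$summary[fit$summary$effect == "pct_time_frozen", ]
  expect_true(s$excludes_zero_95)
  expect_true(s$q2.5 < 0.3 && s$q97.5 > 0.3)
  # a constant covariate is refused by name
  tabC <- tab; tabC$updrs <- 44
  expect_error(severityModel(tabC, fastSpec("severity")), "updrs")
})

test_that("channel maps star channels whose effect excludes zero", {
  set.seed(8)
  mk <- function(chan, shift) {
    part <- rep(sprintf("p%02d", 1:10), each = 12)
    grp <- rep(rep(c("PD", "HC"), 5), each = 12)
    data.frame(value = shift + rnorm(120, 0, 0.5),
               participant = part, group = grp, channel = chan,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(mk("S1-D1", 1.0), mk("S2-D2", 0))
  maps <- channelMaps(tab, modelSpec("group", chains = 2, draws = 600,
                                     warmup = 400, seed = 8))
  expect_equal(nrow(maps), 2L)
  expect_equal(maps$star[maps$channel == "S1-D1"], "99")
  # channels absent from the table (e.g. masked) are absent from the map
  expect_false("S3-D3" %in% maps$channel)
})
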