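#' Hierarchical-model specification
#'
#' The three model families used on the ROI-level epoch values (z-units):
#' \describe{
#'   \item{`group`}{fixed intercept (global activity during the event vs
#'     baseline) + fixed group effect, sum-contrast coded (PD = +1,
#'     HC = -1, so the coefficient is the PD deviation from the grand
#'     mean and the PD-HC difference is twice it); random intercept per
#'     participant.}
#'   \item{`condition`}{fixed intercept + two sum-contrast columns over
#'     condition (freeze / stop / successful); random intercept per
#'     participant plus independent random slopes on the two condition
#'     columns.}
#'   \item{`severity`}{fixed intercept + fixed effects for % time frozen
#'     and motor score (both centred and standardized internally);
#'     random intercept per participant.}
#' }
#' Priors: essentially flat normals on fixed effects, half-normal(1) on
#' every standard-deviation component (a flat prior alone is not
#' samplable for variances); Gaussian likelihood. Sampling is MCMC
#' (JAGS), reproducible from `seed`.
#'
#' @param kind Model family.
#' @param chains Number of chains (>= 2).
#' @param draws Post-warmup draws per chain.
#' @param warmup Adaptation + burn-in iterations.
#' @param seed Integer seed.
#' @return List of class `"model_spec"`.
#' @export
modelSpec <- function(kind = c("group", "condition", "severity"),
                      chains = 4, draws = 2000, warmup = 1000, seed = 1) {
  kind <- match.arg(kind)
  if (chains < 2) stop("at least 2 chains required")
  structure(list(kind = kind, chains = chains, draws = draws,
                 warmup = warmup, seed = seed), class = "model_spec")
}

.JAGS_LMM <- "
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i, ], beta) + inprod(Z[i, ], u[part[i], ])
    y[i] ~ dnorm(mu[i], tau)
  }
  for (j in 1:J) {
    for (m in 1:M) { u[j, m] ~ dnorm(0, tau_u[m]) }
  }
  for (p in 1:P) { beta[p] ~ dnorm(0, 1.0E-6) }
  for (m in 1:M) {
    sigma_u[m] ~ dnorm(0, 1) T(0,)
    tau_u[m] <- pow(sigma_u[m], -2)
  }
  sigma ~ dnorm(0, 1) T(0,)
  tau <- pow(sigma, -2)
}"

#' Fit a Bayesian hierarchical linear mixed model
#'
#' Gaussian likelihood `y = X beta + Z u + e`, `u ~ N(0, diag(sigma_u^2))`
#' per participant, `e ~ N(0, sigma^2)`; design per [modelSpec()] kind.
#' Posterior summaries use quantiles of the MCMC draws; convergence is
#' checked with split-chain R-hat (warning above 1.01) and effective
#' sample sizes.
#'
#' @param table Data frame with columns `value`, `participant`, and,
#'   depending on the model kind, `group` (`"PD"`/`"HC"`), `condition`
#'   (`freeze`/`stop`/`successful`), or `pct_time_frozen` and `updrs`.
#' @param spec A [modelSpec()].
#' @return Object of class `"fog_fit"`: `summary` (per-effect posterior
#'   mean, 95% and 99% credibility bounds, exclusion flags, R-hat, ESS),
#'   `draws` (combined-chain matrix), `spec`, `levels`.
#' @export
fitHierModel <- function(table, spec = modelSpec()) {
  stopifnot(is.data.frame(table), "value" %in% names(table),
            "participant" %in% names(table))
  if (any(!is.finite(table$value))) stop("non-finite response values")
  part <- factor(table$participant)
  if (nlevels(part) < 2)
    stop("at least 2 participants required (got ", nlevels(part), ")")
  y <- table$value
  levels_used <- NULL
  if (spec$kind == "group") {
    g <- ifelse(table$group == "PD", 1, -1)
    X <- cbind(intercept = 1, group = g)
    Z <- cbind(r_intercept = rep(1, length(y)))
  } else if (spec$kind == "condition") {
    cond <- factor(table$condition,
                   levels = intersect(c("freeze", "stop", "successful"),
                                      unique(table$condition)))
    if (nlevels(cond) < 2) stop("need >= 2 condition levels")
    levels_used <- levels(cond)
    C <- stats::contr.sum(nlevels(cond))
    Xc <- C[as.integer(cond), , drop = FALSE]
    colnames(Xc) <- paste0("condition", seq_len(ncol(Xc)))
    X <- cbind(intercept = 1, Xc)
    Z <- cbind(r_intercept = 1, Xc)
    colnames(Z) <- c("r_intercept", paste0("r_", colnames(Xc)))
  } else {
    for (cv in c("pct_time_frozen", "updrs")) {
      if (!cv %in% names(table)) stop("missing covariate: ", cv)
      if (stats::sd(table[[cv]]) == 0)
        stop("degenerate covariate (constant): ", cv)
    }
    X <- cbind(intercept = 1,
               pct_time_frozen = .ztrans(table$pct_time_frozen),
               updrs = .ztrans(table$updrs))
    Z <- cbind(r_intercept = rep(1, length(y)))
  }
  dat <- list(y = y, X = X, Z = Z, part = as.integer(part),
              N = length(y), J = nlevels(part), P = ncol(X), M = ncol(Z))
  inits <- lapply(seq_len(spec$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = .childSeed(spec$seed, ch)))
  jm <- rjags::jags.model(textConnection(.JAGS_LMM), data = dat,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = max(100, spec$warmup %/% 2),
                          quiet = TRUE)
  stats::update(jm, max(100, spec$warmup %/% 2), progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta", "sigma", "sigma_u", "u"),
                              n.iter = spec$draws, progress.bar = "none")
  nm <- colnames(samp[[1]])
  lab <- nm
  for (p in seq_len(ncol(X)))
    lab[nm == sprintf("beta[%d]", p)] <- colnames(X)[p]
  for (m in seq_len(ncol(Z)))
    lab[nm == sprintf("sigma_u[%d]", m)] <-
      paste0("sigma_", colnames(Z)[m])
  summ <- .summarizeDraws(samp, lab)
  draws <- do.call(rbind, lapply(samp, as.matrix))
  colnames(draws) <- lab
  bad <- summ$rhat > 1.01 & !startsWith(summ$effect, "u[")
  if (any(bad, na.rm = TRUE))
    warning("R-hat > 1.01 for: ",
            paste(summ$effect[which(bad)], collapse = ", "))
  structure(list(summary = summ, draws = draws, spec = spec,
                 levels = levels_used,
                 participants = levels(part)), class = "fog_fit")
}

# posterior summary table from an mcmc.list
.summarizeDraws <- function(samp, labels) {
  mat <- do.call(rbind, lapply(samp, as.matrix))
  qs <- t(apply(mat, 2, stats::quantile,
                probs = c(0.025, 0.975, 0.005, 0.995)))
  rhat <- tryCatch(
    coda::gelman.diag(samp, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(mat)))
  ess <- coda::effectiveSize(samp)
  data.frame(effect = labels, mean = colMeans(mat),
             q2.5 = qs[, 1], q97.5 = qs[, 2],
             q0.5 = qs[, 3], q99.5 = qs[, 4],
             excludes_zero_95 = qs[, 1] > 0 | qs[, 2] < 0,
             excludes_zero_99 = qs[, 3] > 0 | qs[, 4] < 0,
             rhat = unname(rhat), ess = unname(ess),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.fog_fit <- function(x, ...) {
  cat("Hierarchical model (", x$spec$kind, "), ", x$spec$chains,
      " chains x ", x$spec$draws, " draws\n", sep = "")
  keep <- !startsWith(x$summary$effect, "u[")
  print(x$summary[keep, c("effect", "mean", "q2.5", "q97.5",
                          "excludes_zero_95", "rhat")], digits = 3,
        row.names = FALSE)
  invisible(x)
}

#' Posterior condition contrasts
#'
#' Pairwise condition differences (freeze - stop, freeze - successful,
#' stop - successful) computed on the posterior draws of the condition
#' model -- no refitting -- with credibility intervals from draw
#' quantiles. A condition contrasted with itself is exactly zero.
#'
#' @param fit A `"fog_fit"` from the `condition` model.
#' @param pairs List of length-2 character vectors of condition levels;
#'   default all ordered pairs among the fitted levels.
#' @return Posterior summary data.frame, one row per contrast.
#' @export
conditionContrasts <- function(fit, pairs = NULL) {
  lv <- fit$levels
  if (is.null(lv)) stop("fit is not a condition model")
  C <- stats::contr.sum(length(lv))
  rownames(C) <- lv
  cols <- paste0("condition", seq_len(ncol(C)))
  B <- fit$draws[, cols, drop = FALSE]
  dev <- B %*% t(C)          # draws x levels: per-level deviations
  colnames(dev) <- lv
  if (is.null(pairs)) {
    pairs <- list()
    for (i in seq_along(lv)) for (j in seq_along(lv))
      if (i < j) pairs[[length(pairs) + 1L]] <- c(lv[i], lv[j])
  }
  rows <- lapply(pairs, function(p) {
    d <- dev[, p[1]] - dev[, p[2]]
    qs <- stats::quantile(d, c(0.025, 0.975, 0.005, 0.995))
    data.frame(effect = paste(p[1], "-", p[2]), mean = mean(d),
               q2.5 = qs[1], q97.5 = qs[2], q0.5 = qs[3], q99.5 = qs[4],
               excludes_zero_95 = qs[1] > 0 | qs[2] < 0,
               excludes_zero_99 = qs[3] > 0 | qs[4] < 0,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-channel activity maps with star classification
#'
#' Fits the group model independently for every channel of a
#' channel-level epoch table and classifies each channel by whether the
#' chosen effect's credibility interval excludes zero: `"none"`, `"95"`
#' (95% CrI excludes zero, small star) or `"99"` (99% CrI excludes zero,
#' large star). Masked channels are absent from the input and hence from
#' the map.
#'
#' @param table Channel-level epoch table (columns `channel`, `value`,
#'   `participant`, `group`).
#' @param spec A [modelSpec()] of kind `group`.
#' @param effect Effect to classify (`"intercept"` = global activity vs
#'   baseline, or `"group"`).
#' @return Data frame, one row per channel: posterior mean, CrI bounds,
#'   `star`.
#' @export
channelMaps <- function(table, spec = modelSpec("group"),
                        effect = "intercept") {
  stopifnot(spec$kind == "group")
  chans <- unique(table$channel)
  rows <- lapply(seq_along(chans), function(i) {
    sub <- table[table$channel == chans[i], , drop = FALSE]
    sp <- spec; sp$seed <- .childSeed(spec$seed, i)
    fit <- fitHierModel(sub, sp)
    s <- fit$summary[fit$summary$effect == effect, , drop = FALSE]
    data.frame(channel = chans[i], mean = s$mean, q2.5 = s$q2.5,
               q97.5 = s$q97.5, q0.5 = s$q0.5, q99.5 = s$q99.5,
               star = if (s$excludes_zero_99) "99"
                      else if (s$excludes_zero_95) "95" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Freezing-severity model
#'
#' The exploratory third model family: PD-group epoch values regressed on
#' the participant's % time frozen (for the studied trigger) and motor
#' score, both centred and standardized before fitting, with a random
#' intercept per participant. Coefficients are on the standardized
#' covariate scale.
#'
#' @param table Epoch table with `pct_time_frozen` and `updrs` columns.
#' @param spec A [modelSpec()]; its kind is forced to `severity`.
#' @return A `"fog_fit"`.
#' @export
severityModel <- function(table, spec = modelSpec("severity")) {
  spec$kind <- "severity"
  fitHierModel(table, spec)
}
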