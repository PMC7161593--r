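#' Counterfactual outcome mean under a fixed exposure regime (g-formula)
#'
#' Computes \eqn{E[Y(\bar a)]} for the data-generating process of a
#' [dgp_config] with the exposure sequence held fixed at `regime`,
#' standardizing over the confounder process -- the g-formula. Three routes:
#'
#' * gaussian confounder, unclamped outcome: closed form. Under a fixed
#'   regime the confounder mean evolves linearly,
#'   \eqn{E[L_t] = \lambda E[L_{t-1}] + \delta a_{t-1}}, and the outcome is
#'   linear in \eqn{\bar L}, so the expectation requires no integration.
#' * binary confounder, unclamped outcome: exact enumeration over all
#'   \eqn{2^{t+1}} confounder branches and the baseline covariate.
#' * clamped outcome (0--7 survey scale): Monte-Carlo with `mc_draws`
#'   simulated confounder paths and outcome noise (the clamping makes the
#'   mean non-analytic); a message notes the fallback.
#'
#' @param config A `dgp_config`.
#' @param regime Integer 0/1 vector of length `config$t_max`.
#' @param mc_draws Draws for the Monte-Carlo route.
#' @param mc_seed Seed for the Monte-Carlo route.
#' @return The expected outcome, a scalar.
#' @examples
#' cfg <- dgp_preset("binary_small")
#' counterfactual_mean(cfg, c(1, 1))
#' @export
counterfactual_mean <- function(config, regime, mc_draws = 1e6,
                                mc_seed = 1L) {
  stopifnot(inherits(config, "dgp_config"),
            length(regime) == config$t_max,
            all(regime %in% c(0, 1)))
  if (config$clamp_outcome) {
    message("clamped outcome: falling back to Monte-Carlo with ",
            format(mc_draws, scientific = FALSE), " draws")
    return(cf_mean_mc(config, regime, mc_draws, mc_seed))
  }
  if (config$l_type == "gaussian") cf_mean_gaussian(config, regime)
  else cf_mean_binary(config, regime)
}

cf_mean_gaussian <- function(config, regime) {
  t_max <- config$t_max
  el <- numeric(t_max)
  prev <- config$l_mu0
  a_prev <- 0
  for (t in seq_len(t_max)) {
    el[t] <- config$lambda * prev + config$delta * a_prev
    prev <- el[t]
    a_prev <- regime[t]
  }
  config$theta0 + config$theta_a * sum(regime) +
    config$theta_l * mean(el) + config$theta_v * config$p_v
}

cf_mean_binary <- function(config, regime) {
  t_max <- config$t_max
  # enumerate branches of (L_0, L_1, ..., L_T); V enters Y linearly so its
  # expectation can be taken outside the L-sum
  n_l <- t_max + 1L
  grid <- as.matrix(expand.grid(rep(list(0:1), n_l)))
  total <- 0
  for (i in seq_len(nrow(grid))) {
    l <- grid[i, ]
    p <- if (l[1] == 1) config$l_p0 else 1 - config$l_p0
    a_prev <- 0
    for (t in seq_len(t_max)) {
      q <- expit(config$kappa0 + config$kappa_l * l[t] +
                   config$delta * a_prev)
      p <- p * if (l[t + 1] == 1) q else 1 - q
      a_prev <- regime[t]
    }
    l_bar <- mean(l[-1])
    y <- config$theta0 + config$theta_a * sum(regime) +
      config$theta_l * l_bar
    total <- total + p * y
  }
  total + config$theta_v * config$p_v
}

cf_mean_mc <- function(config, regime, mc_draws, mc_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mc_seed)
  n <- as.integer(mc_draws)
  v <- rbinom(n, 1, config$p_v)
  l_prev <- if (config$l_type == "gaussian") {
    rnorm(n, config$l_mu0, config$l_sd0)
  } else {
    rbinom(n, 1, config$l_p0)
  }
  a_prev <- rep(0, n)
  l_sum <- rep(0, n)
  for (t in seq_len(config$t_max)) {
    lt <- if (config$l_type == "gaussian") {
      config$lambda * l_prev + config$delta * a_prev + rnorm(n, 0, config$l_sd)
    } else {
      rbinom(n, 1, expit(config$kappa0 + config$kappa_l * l_prev +
                           config$delta * a_prev))
    }
    l_sum <- l_sum + lt
    l_prev <- lt
    a_prev <- rep(regime[t], n)
  }
  y <- config$theta0 + config$theta_a * sum(regime) +
    config$theta_l * l_sum / config$t_max + config$theta_v * v +
    rnorm(n, 0, config$sigma_y)
  if (config$clamp_outcome) y <- pmin(pmax(round(y), 0), 7)
  mean(y)
}

#' Marginal dose-response slope of the counterfactual means (oracle slope)
#'
#' The weighted-regression estimand is the least-squares slope of
#' \eqn{E[Y(\bar a)]} on the cumulative exposure \eqn{\sum_t a_t} over all
#' \eqn{2^{t_{max}}} regimes. This is the recovery target for the
#' simulation studies: with exposure-confounder feedback
#' (`delta != 0`) it exceeds the direct outcome coefficient `theta_a`
#' because part of the effect flows through the confounder path.
#'
#' @param config A `dgp_config`.
#' @param ... Passed to [counterfactual_mean] (Monte-Carlo controls).
#' @return A list: `slope`, and `regimes` (a tibble of regime, cumulative
#'   count and counterfactual mean).
#' @export
oracle_slope <- function(config, ...) {
  t_max <- config$t_max
  regimes <- as.matrix(expand.grid(rep(list(0:1), t_max)))
  ey <- apply(regimes, 1, function(r) counterfactual_mean(config, r, ...))
  cum <- rowSums(regimes)
  fit <- lm(ey ~ cum)
  list(slope = unname(coef(fit)[2]),
       regimes = tibble::tibble(regime = apply(regimes, 1, paste, collapse = ""),
                                cumulative = cum, ey = ey))
}
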