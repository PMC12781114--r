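#' Convert an absorbance slope to a normalised initial rate
#'
#' Beer-Lambert conversion of a spectrophotometric progress-curve slope to
#' `v0/e`. The default extinction coefficient is that of NADH at 340 nm
#' (6220 1/(M cm)).
#'
#' @param slope absorbance change, AU/s (sign ignored).
#' @param extinction molar extinction coefficient, 1/(M cm).
#' @param path_length cuvette path, cm.
#' @param enzyme_concentration enzyme concentration, uM.
#' @return `v0/e` in 1/s.
#' @export
absorbance_to_rate <- function(slope, extinction = 6220, path_length = 1,
                               enzyme_concentration) {
  if (extinction <= 0 || path_length <= 0 || enzyme_concentration <= 0)
    stop("extinction, path_length and enzyme_concentration must be > 0")
  v0_uM_per_s <- abs(slope) / (extinction * path_length) * 1e6
  v0_uM_per_s / enzyme_concentration
}

# Deterministic multistart Levenberg-Marquardt on a residual function of a
# named parameter vector. Offsets are applied in the (mostly log-scale)
# internal parameterisation, so starts stay positive and local minima are
# escaped reproducibly. Returns the lowest-RSS converged run.
multistart_nls <- function(resid_fn, base_start, n_starts = 8L,
                           offset_step = log(4)) {
  base <- unlist(base_start)
  p <- length(base)
  offs <- list(rep(0, p))
  for (s in c(offset_step, -offset_step, 2 * offset_step,
              -2 * offset_step))
    for (j in seq_len(p)) {
      o <- rep(0, p); o[j] <- s
      offs[[length(offs) + 1L]] <- o
    }
  offs <- offs[seq_len(min(n_starts, length(offs)))]
  best <- NULL
  for (o in offs) {
    out <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par = base + o, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(out) || !all(is.finite(out$par))) next
    rss <- sum(out$fvec^2)
    if (is.null(best) || rss < best_rss * (1 - 1e-12)) {
      best <- out
      best_rss <- rss
    }
  }
  if (is.null(best))
    stop("nonlinear least squares failed to converge from any start")
  best
}

# covariance of the internal parameters at the optimum; pseudo-inverse of
# J'J so rank-deficient (practically unidentifiable) directions give large
# finite variances instead of an error
lm_covariance <- function(fit, n_obs) {
  p <- length(fit$par)
  sigma2 <- sum(fit$fvec^2) / max(n_obs - p, 1L)
  h <- as.matrix(fit$hessian)
  sv <- svd(h)
  tol <- max(sv$d) * 1e-12
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 1 / tol)
  sigma2 * (sv$v %*% (dinv * t(sv$u)))
}

# delta-method natural-scale values and SEs for log-scale parameters
natural_params <- function(fit, n_obs, log_names) {
  cv <- lm_covariance(fit, n_obs)
  idx <- match(log_names, names(fit$par))
  val <- exp(fit$par[idx])
  se <- val * sqrt(pmax(diag(cv)[idx], 0))
  list(value = stats::setNames(val, sub("^l", "", log_names)),
       se = stats::setNames(se, sub("^l", "", log_names)))
}

r_squared_rss <- function(obs, rss) 1 - rss / sum((obs - mean(obs))^2)

new_ss_fit <- function(fit, data, model) {
  log_names <- if (model == "eq1") c("lkcat", "lKa", "lKb") else
    c("lkcat", "lKa", "lKb", "lKis")
  np <- natural_params(fit, nrow(data), log_names)
  rss <- sum(fit$fvec^2)
  structure(list(kcat = np$value[["kcat"]], Ka = np$value[["Ka"]],
                 Kb = np$value[["Kb"]],
                 Kis = if (model == "eq2") np$value[["Kis"]] else NA_real_,
                 se = np$se, r_squared = r_squared_rss(data$v, rss),
                 model = model, n = nrow(data), rss = rss,
                 n_par = length(log_names), fit = fit, data = data),
            class = "SteadyStateFit")
}

rates_to_df <- function(data) {
  if (inherits(data, "RateDataset") || is.data.frame(data))
    data.frame(A = data$NADH_uM, B = data$CoQ0_uM,
               v = data$v0_over_e_per_s)
  else stop("data must be a RateDataset")
}

check_ss_design <- function(d) {
  if (nrow(unique(d[, c("A", "B")])) < 3L)
    stop("need at least 3 distinct (NADH, CoQ0) combinations")
  if (length(unique(d$A)) < 2L || length(unique(d$B)) < 2L)
    stop("design must span both substrates")
}

#' Fit the ping-pong bi-bi steady-state rate law
#'
#' Unweighted nonlinear least squares of
#' `v0/e = A B kcat / (A Kb + B Ka + A B)` to an initial-rate table over
#' NADH (`A`) and CoQ0 (`B`). Parameters are log-parameterised internally
#' (so strictly positive) and fitted from a deterministic multistart;
#' standard errors come from the covariance at the optimum by the delta
#' method and are reported on the natural scale.
#'
#' @param data a `RateDataset` (columns `NADH_uM`, `CoQ0_uM`,
#'   `v0_over_e_per_s`).
#' @return a `SteadyStateFit` with `kcat` (1/s), `Ka` = K_NADH (uM),
#'   `Kb` = K_CoQ0 (uM), `se`, `r_squared` and `model = "eq1"`.
#' @export
fit_pingpong <- function(data) {
  d <- rates_to_df(data)
  check_ss_design(d)
  base <- c(lkcat = log(max(d$v)), lKa = log(stats::median(d$A)),
            lKb = log(stats::median(d$B)))
  fit <- multistart_nls(function(p)
    d$v - pingpong_rate(d$A, d$B, exp(p[["lkcat"]]), exp(p[["lKa"]]),
                        exp(p[["lKb"]])), base)
  new_ss_fit(fit, d, "eq1")
}

#' Fit ping-pong bi-bi kinetics with NADH substrate inhibition
#'
#' As [fit_pingpong()] but with the dead-end NADH inhibition term:
#' `v0/e = A B kcat / (Ka B + Kb A (1 + A / Kis) + A B)`.
#'
#' @inheritParams fit_pingpong
#' @return a `SteadyStateFit` with additionally `Kis` (uM) and
#'   `model = "eq2"`.
#' @export
fit_pingpong_substrate_inhibition <- function(data) {
  d <- rates_to_df(data)
  check_ss_design(d)
  base <- c(lkcat = log(max(d$v)), lKa = log(stats::median(d$A)),
            lKb = log(stats::median(d$B)), lKis = log(stats::median(d$A)))
  fit <- multistart_nls(function(p)
    d$v - pingpong_rate(d$A, d$B, exp(p[["lkcat"]]), exp(p[["lKa"]]),
                        exp(p[["lKb"]]), exp(p[["lKis"]])), base)
  new_ss_fit(fit, d, "eq2")
}

#' @export
print.SteadyStateFit <- function(x, ...) {
  cat("Ping-pong bi-bi fit (", if (x$model == "eq1") "no inhibition"
      else "NADH substrate inhibition", ")\n", sep = "")
  cat(sprintf("  kcat   = %.4g +/- %.2g 1/s\n", x$kcat, x$se[["kcat"]]))
  cat(sprintf("  K_NADH = %.4g +/- %.2g uM\n", x$Ka, x$se[["Ka"]]))
  cat(sprintf("  K_CoQ0 = %.4g +/- %.2g uM\n", x$Kb, x$se[["Kb"]]))
  if (x$model == "eq2")
    cat(sprintf("  K_is   = %.4g +/- %.2g uM\n", x$Kis, x$se[["Kis"]]))
  cat(sprintf("  R^2 = %.4f on %d points\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.SteadyStateFit <- function(object, ...) {
  out <- c(kcat = object$kcat, Ka = object$Ka, Kb = object$Kb)
  if (object$model == "eq2") out <- c(out, Kis = object$Kis)
  out
}

#' @export
predict.SteadyStateFit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else
    data.frame(A = newdata$NADH_uM, B = newdata$CoQ0_uM)
  pingpong_rate(d$A, d$B, object$kcat, object$Ka, object$Kb,
                if (object$model == "eq2") object$Kis else NULL)
}

#' @export
residuals.SteadyStateFit <- function(object, ...) {
  object$data$v - predict(object)
}

aicc_from_rss <- function(rss, n, n_par) {
  k <- n_par + 1  # + residual variance
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

#' Choose between the plain and substrate-inhibition rate laws
#'
#' The inhibition law nests the plain one, so the choice is made by the
#' extra-sum-of-squares F-test: the inhibition term is kept only when it
#' improves the fit significantly (default alpha 0.05). With identical
#' residuals the simpler model therefore wins. The corrected Akaike
#' information criterion (AICc) of both models is reported alongside; an
#' information criterion alone over-selects the larger nested model at a
#' fixed asymptotic rate, which is why it is not the deciding rule here.
#'
#' @param fit1 `SteadyStateFit` of the plain model (`eq1`).
#' @param fit2 `SteadyStateFit` of the inhibition model (`eq2`).
#' @param alpha significance level of the F-test.
#' @return a `model_selection` list: `choice` (`"eq1"`/`"eq2"`), per-model
#'   `aicc`, `f_statistic`, `p_value`, `alpha`.
#' @export
select_model <- function(fit1, fit2, alpha = 0.05) {
  if (fit1$n != fit2$n) stop("fits are not on the same data")
  a1 <- aicc_from_rss(fit1$rss, fit1$n, fit1$n_par)
  a2 <- aicc_from_rss(fit2$rss, fit2$n, fit2$n_par)
  df1 <- fit2$n_par - fit1$n_par
  df2 <- fit2$n - fit2$n_par
  fstat <- max(fit1$rss - fit2$rss, 0) / df1 / (fit2$rss / df2)
  pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  choice <- if (pval < alpha) fit2$model else fit1$model
  structure(list(choice = choice, aicc = c(eq1 = a1, eq2 = a2),
                 f_statistic = fstat, p_value = pval, alpha = alpha),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection: ", x$choice, " (AICc eq1 ", sprintf("%.2f", x$aicc[1]),
      ", eq2 ", sprintf("%.2f", x$aicc[2]), "; F = ",
      sprintf("%.2f", x$f_statistic), ", p = ",
      sprintf("%.3g", x$p_value), ")\n", sep = "")
  invisible(x)
}

#' Fit a double-exponential stopped-flow transient
#'
#' Least-squares fit of `A(t) = B1 exp(-kobs1 t) + B2 exp(-kobs2 t) + C` to
#' an absorbance trace. Initial guesses come from log-linear analysis of
#' the baseline-subtracted trace (tail for the slow phase, head for the
#' fast phase); rates and amplitudes are log-parameterised. Phases are
#' relabelled so `kobs1 >= kobs2`; a rate ratio under 1.5 is flagged as
#' poorly separable.
#'
#' @param trace a `StoppedFlowTrace` (columns `time_s`, `A461`) with at
#'   least 10 points and an overall decreasing signal.
#' @return a `BiexpFit`: `B1`, `B2` (AU), `kobs1`, `kobs2` (1/s), `C` (AU),
#'   `amplitude_fraction_fast`, `se`, `r_squared`,
#'   `rates_distinguishable`.
#' @export
fit_biexponential <- function(trace) {
  t <- trace$time_s; A <- trace$A461
  if (length(t) < 10L) stop("need at least 10 time points")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  n <- length(t)
  head_mean <- mean(A[seq_len(max(3L, n %/% 20))])
  tail_mean <- mean(A[seq.int(n - max(3L, n %/% 20) + 1L, n)])
  if (head_mean <= tail_mean) stop("trace is not decreasing overall")
  # initialisation from the decay itself (robust to log-spaced sampling):
  # fast rate from the 1/e crossing of the baseline-subtracted signal,
  # slow phase from a log-linear fit beyond ~3 fast lifetimes
  C0 <- tail_mean
  y <- pmax(A - C0, 1e-12)
  y0 <- mean(y[seq_len(max(3L, n %/% 50))])
  i63 <- which(y <= y0 * exp(-1))[1]
  k1_0 <- if (is.na(i63)) 1 / t[n] else 1 / t[i63]
  late <- which(t > 3 / k1_0 & y > 1e-10)
  if (length(late) >= 5L) {
    slow <- stats::lm.fit(cbind(1, t[late]), log(y[late]))$coefficients
    k2_0 <- max(-slow[2], k1_0 * 1e-4)
    B2_0 <- min(max(exp(slow[1]), 1e-10), y0)
  } else {
    k2_0 <- k1_0 / 30
    B2_0 <- 0.05 * y0
  }
  if (k2_0 >= k1_0) k2_0 <- k1_0 / 30
  B1_0 <- max(y0 - B2_0, 1e-10)
  base <- c(lB1 = log(B1_0), lk1 = log(k1_0), lB2 = log(B2_0),
            lk2 = log(k2_0), C = C0)
  # amplitudes/rates log-scale (clamped against overflow); the offset C
  # stays on the natural scale
  cexp <- function(x) exp(pmin(pmax(x, -60), 60))
  fit <- multistart_nls(function(p)
    A - (cexp(p[["lB1"]]) * exp(-cexp(p[["lk1"]]) * t) +
           cexp(p[["lB2"]]) * exp(-cexp(p[["lk2"]]) * t) + p[["C"]]),
    base, n_starts = 9L)
  fit$par[1:4] <- pmin(pmax(fit$par[1:4], -60), 60)
  cv <- lm_covariance(fit, n)
  sd_int <- sqrt(pmax(diag(cv), 0))
  B1 <- exp(fit$par[["lB1"]]); k1 <- exp(fit$par[["lk1"]])
  B2 <- exp(fit$par[["lB2"]]); k2 <- exp(fit$par[["lk2"]])
  se <- c(B1 = B1 * sd_int[1], kobs1 = k1 * sd_int[2],
          B2 = B2 * sd_int[3], kobs2 = k2 * sd_int[4], C = sd_int[5])
  if (k1 < k2) {  # relabel: phase 1 is the fast phase
    tmp <- c(B1, k1); B1 <- B2; k1 <- k2; B2 <- tmp[1]; k2 <- tmp[2]
    se[c("B1", "kobs1", "B2", "kobs2")] <-
      se[c("B2", "kobs2", "B1", "kobs1")]
  }
  structure(list(B1 = B1, B2 = B2, kobs1 = k1, kobs2 = k2,
                 C = fit$par[["C"]],
                 amplitude_fraction_fast = B1 / (B1 + B2), se = se,
                 r_squared = r_squared_rss(A, sum(fit$fvec^2)),
                 rates_distinguishable = (k1 / k2) >= 1.5,
                 fit = fit),
            class = "BiexpFit")
}

#' @export
print.BiexpFit <- function(x, ...) {
  cat("Biexponential fit:\n")
  cat(sprintf("  kobs1 = %.4g 1/s (B1 = %.3g AU, %.1f%% of amplitude)\n",
              x$kobs1, x$B1, 100 * x$amplitude_fraction_fast))
  cat(sprintf("  kobs2 = %.4g 1/s (B2 = %.3g AU)\n", x$kobs2, x$B2))
  cat(sprintf("  C = %.4g AU, R^2 = %.5f\n", x$C, x$r_squared))
  if (!x$rates_distinguishable)
    cat("  note: rate ratio < 1.5, phases poorly separable\n")
  invisible(x)
}

#' @export
coef.BiexpFit <- function(object, ...) {
  c(B1 = object$B1, kobs1 = object$kobs1, B2 = object$B2,
    kobs2 = object$kobs2, C = object$C)
}

#' Fit hyperbolic saturation of the observed reduction rate
#'
#' Least squares of `kobs = kred S / (Kd + S)` (y-intercept fixed at zero)
#' to fast-phase rates against substrate concentration. A fitted `Kd`
#' outside the informative range of the design (above ten times the
#' largest concentration, or below a tenth of the smallest, as when every
#' point is already saturated) is flagged as unconstrained.
#'
#' @param points data.frame with columns `S` (uM) and `kobs` (1/s), at
#'   least 3 concentrations, all `S > 0`.
#' @return a `SaturationFit`: `kred` (1/s), `Kd` (uM), `se`, `r_squared`,
#'   `kd_constrained`.
#' @export
fit_saturation <- function(points) {
  if (!all(c("S", "kobs") %in% names(points)))
    stop("points must have columns S and kobs")
  if (any(points$S <= 0)) stop("substrate concentrations must be > 0")
  if (length(unique(points$S)) < 3L) stop("need at least 3 concentrations")
  d <- data.frame(S = points$S, kobs = points$kobs)
  base <- c(lkred = log(max(d$kobs)), lKd = log(stats::median(d$S)))
  fit <- multistart_nls(function(p)
    d$kobs - exp(p[["lkred"]]) * d$S / (exp(p[["lKd"]]) + d$S), base)
  np <- natural_params(fit, nrow(d), c("lkred", "lKd"))
  structure(list(kred = np$value[["kred"]], Kd = np$value[["Kd"]],
                 se = c(kred = np$se[["kred"]], Kd = np$se[["Kd"]]),
                 r_squared = r_squared_rss(d$kobs, sum(fit$fvec^2)),
                 kd_constrained = np$value[["Kd"]] <= 10 * max(d$S) &&
                   np$value[["Kd"]] >= min(d$S) / 10,
                 fit = fit),
            class = "SaturationFit")
}

#' @export
print.SaturationFit <- function(x, ...) {
  cat(sprintf("Saturation fit: kred = %.4g +/- %.2g 1/s, Kd = %.4g +/- %.2g uM (R^2 = %.4f)\n",
              x$kred, x$se[["kred"]], x$Kd, x$se[["Kd"]], x$r_squared))
  if (!x$kd_constrained)
    cat("  note: Kd outside the informative concentration range -",
        "unconstrained\n")
  invisible(x)
}

#' @export
coef.SaturationFit <- function(object, ...) {
  c(kred = object$kred, Kd = object$Kd)
}

#' Catalytic efficiency with propagated uncertainty
#'
#' `kcat / K` converted to 1/(M s) (K given in uM), with first-order error
#' propagation `se(r)/r = sqrt((se_k/k)^2 + (se_K/K)^2)`.
#'
#' @param kcat turnover number, 1/s.
#' @param K Michaelis constant, uM.
#' @param se_kcat,se_K standard errors (default 0).
#' @return list with `value` and `se`, both 1/(M s).
#' @export
efficiency <- function(kcat, K, se_kcat = 0, se_K = 0) {
  if (kcat <= 0 || K <= 0) stop("kcat and K must be > 0")
  value <- kcat / (K * 1e-6)
  list(value = value,
       se = value * sqrt((se_kcat / kcat)^2 + (se_K / K)^2))
}

#' Fold change between two parameter values
#'
#' The ratio is always reported as `max/min` (>= 1); the direction states
#' how `value_b` compares to `value_a`.
#'
#' @param value_a,value_b positive values (e.g. wild type then mutant).
#' @param labels character(2) semantic labels.
#' @return a `FoldChange`: `ratio`, `direction` (`"increase"`,
#'   `"decrease"` or `"unchanged"`), labels.
#' @export
fold_change <- function(value_a, value_b, labels = c("a", "b")) {
  if (value_a <= 0 || value_b <= 0) stop("values must be > 0")
  structure(list(ratio = max(value_a, value_b) / min(value_a, value_b),
                 direction = if (value_b > value_a) "increase"
                 else if (value_b < value_a) "decrease" else "unchanged",
                 denominator_label = labels[1], numerator_label = labels[2]),
            class = "FoldChange")
}

#' @export
print.FoldChange <- function(x, ...) {
  cat(sprintf("%.2g-fold %s (%s -> %s)\n", x$ratio, x$direction,
              x$denominator_label, x$numerator_label))
  invisible(x)
}
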