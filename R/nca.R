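# Non-compartmental analysis: AUC by trapezoid, terminal log-linear fit with
# adjusted-R2 point selection, per-subject IV/oral parameter derivation and
# bioavailability summaries.

#' Area under a concentration-time curve by trapezoid
#'
#' Linear trapezoid by default; `"linear_up_log_down"` applies logarithmic
#' interpolation over strictly decreasing positive segments and linear
#' elsewhere.
#'
#' @param times sampling times, h, strictly increasing.
#' @param concs concentrations, ng/mL, non-negative.
#' @param method `"linear"` or `"linear_up_log_down"`.
#' @return AUC in h*ng/mL over the observed span.
#' @examples
#' auc_trapezoid(c(0, 1), c(0, 2))  # 1
#' @export
auc_trapezoid <- function(times, concs, method = c("linear", "linear_up_log_down")) {
  method <- match.arg(method)
  n <- length(times)
  if (n < 2L) abort_validation("need at least 2 points for AUC")
  if (length(concs) != n) abort_validation("times and concs differ in length")
  if (is.unsorted(times, strictly = TRUE)) {
    abort_validation("times must be strictly increasing")
  }
  dt <- diff(times)
  c1 <- concs[-n]; c2 <- concs[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linear_up_log_down") {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    seg[logdown] <- (c1[logdown] - c2[logdown]) * dt[logdown] /
      log(c1[logdown] / c2[logdown])
  }
  sum(seg)
}

# AUMC (first-moment area): linear trapezoid on t*C, or with exponential
# interpolation over strictly decreasing positive segments (closed form
# integral of t * C1 exp(-k(t - t1))) to match the log-down AUC method.
aumc_trapezoid <- function(times, concs, method = "linear") {
  if (method == "linear") return(auc_trapezoid(times, times * concs))
  n <- length(times)
  if (n < 2L) abort_validation("need at least 2 points for AUMC")
  dt <- diff(times)
  t1 <- times[-n]; t2 <- times[-1]
  c1 <- concs[-n]; c2 <- concs[-1]
  seg <- (t1 * c1 + t2 * c2) / 2 * dt
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  if (any(logdown)) {
    k <- log(c1[logdown] / c2[logdown]) / dt[logdown]
    seg[logdown] <- (t1[logdown] * c1[logdown] - t2[logdown] * c2[logdown]) / k +
      (c1[logdown] - c2[logdown]) / k^2
  }
  sum(seg)
}

#' Terminal log-linear regression
#'
#' Estimates the terminal elimination rate constant lambda_z by log-linear
#' regression on the terminal phase. The point subset is chosen to maximise
#' adjusted R2 among candidate sets of the last m points (m >= 3, excluding
#' Tmax); ties within 1e-4 prefer more points. The AUC tail is
#' C_last / lambda_z.
#'
#' @param times sampling times, h.
#' @param concs concentrations, ng/mL; non-positive values are ignored.
#' @return list: `lambda_z` (1/h), `t_half` (h), `n_points`, `adj_r2`,
#'   `auc_tail`, `aumc_tail` and `defined` (FALSE when no decreasing terminal
#'   phase exists, with the estimates NA).
#' @export
terminal_fit <- function(times, concs) {
  pos <- concs > 0
  tt <- times[pos]; cc <- concs[pos]
  undefined <- list(lambda_z = NA_real_, t_half = NA_real_,
                    n_points = 0L, adj_r2 = NA_real_,
                    auc_tail = NA_real_, aumc_tail = NA_real_, defined = FALSE)
  if (length(tt) < 3L) return(undefined)
  i_tmax <- which.max(cc)
  # candidates: last m points, all strictly after Tmax, m in 3..(n - i_tmax)
  n <- length(tt)
  best <- NULL
  for (m in seq(3L, n)) {
    idx <- seq(n - m + 1L, n)
    if (idx[1] <= i_tmax) next
    fit <- stats::lm(log(cc[idx]) ~ tt[idx])
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0) next
    y <- log(cc[idx])
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
    adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
    if (is.null(best) || adj > best$adj_r2 + 1e-4 ||
        (abs(adj - best$adj_r2) <= 1e-4 && m > best$n_points)) {
      best <- list(lambda_z = -slope, n_points = m, adj_r2 = adj)
    }
  }
  if (is.null(best)) return(undefined)
  clast <- cc[n]; tlast <- tt[n]
  lz <- best$lambda_z
  list(lambda_z = lz, t_half = log(2) / lz, n_points = best$n_points,
       adj_r2 = best$adj_r2, auc_tail = clast / lz,
       aumc_tail = clast * tlast / lz + clast / lz^2, defined = TRUE)
}

# Single-profile NCA. dose in mg/kg, concentrations ng/mL, times h.
# CL in L/h/kg, Vss in L/kg (IV bolus only).
nca_profile <- function(times, concs, dose, route, method = "linear") {
  if (is.na(dose)) abort_validation("dose missing")
  ord <- order(times)
  times <- times[ord]; concs <- concs[ord]
  # IV bolus: back-extrapolate C0 from the first two positive samples
  # (log-linear) and include the 0 -> t1 segment
  if (route == "iv_bolus" && times[1] > 0 && length(times) >= 2 &&
      concs[1] > 0 && concs[2] > 0 && concs[2] < concs[1]) {
    k0 <- log(concs[1] / concs[2]) / (times[2] - times[1])
    c0 <- concs[1] * exp(k0 * times[1])
    times <- c(0, times)
    concs <- c(c0, concs)
  }
  auc_t <- auc_trapezoid(times, concs, method)
  aumc_t <- aumc_trapezoid(times, concs, method)
  term <- terminal_fit(times, concs)
  auc_inf <- if (term$defined) auc_t + term$auc_tail else NA_real_
  aumc_inf <- if (term$defined) aumc_t + term$aumc_tail else NA_real_
  extrap <- if (term$defined) term$auc_tail / auc_inf else NA_real_
  out <- list(
    cmax = max(concs), tmax = times[which.max(concs)],
    auc_0_t = auc_t, auc_0_inf = auc_inf,
    lambda_z = term$lambda_z, t_half = term$t_half,
    extrap_frac = extrap,
    extrap_flag = isTRUE(extrap > 0.2),
    cl = NA_real_, vss = NA_real_, mrt = NA_real_
  )
  if (route == "iv_bolus" && term$defined) {
    # dose mg/kg = 1e6 ng/kg; AUC h*ng/mL -> CL mL/h/kg; /1000 -> L/h/kg
    out$cl <- dose * 1000 / auc_inf
    out$mrt <- aumc_inf / auc_inf
    out$vss <- out$cl * out$mrt
    if (out$mrt <= 0) {
      out$vss <- NA_real_
      warn_flag("non-positive MRT; Vss undefined")
    }
  }
  out
}

#' Non-compartmental analysis of a study dataset
#'
#' Computes per-subject NCA parameters for one matrix of a [study_dataset()]
#' and summarises them as mean +/- sd per (route, dose, sex) group, the layout
#' of a preclinical PK report table. IV-bolus subjects additionally get CL
#' (Dose/AUC_0-inf), MRT (AUMC/AUC) and Vss (CL x MRT); results with terminal
#' extrapolation above 20% of AUC_0-inf are flagged. Below-quantification
#' records are excluded from the computation but counted.
#'
#' @param dataset a `study_dataset`.
#' @param matrix which matrix to analyse (default `"plasma"`).
#' @param method AUC method, see [auc_trapezoid()].
#' @return object of class `nca_result`: list with `subjects` (per-subject
#'   data.frame) and `summary` (group mean +/- sd data.frame).
#' @export
nca <- function(dataset, matrix = "plasma", method = "linear") {
  df <- as.data.frame(dataset)
  df <- df[df$matrix == matrix & !df$blq, , drop = FALSE]
  if (nrow(df) == 0L) abort_validation(sprintf("no records for matrix '%s'", matrix))
  subjects <- unique(df$subject_id)
  rows <- lapply(subjects, function(s) {
    d <- df[df$subject_id == s, ]
    p <- nca_profile(d$time_h, d$conc_ng_per_ml, d$dose[1], d$route[1], method)
    data.frame(subject_id = s, species = d$species[1], sex = d$sex[1],
               group = d$group[1], route = d$route[1], dose = d$dose[1],
               cmax = p$cmax, tmax = p$tmax, auc_0_t = p$auc_0_t,
               auc_0_inf = p$auc_0_inf, lambda_z = p$lambda_z,
               t_half = p$t_half, mrt = p$mrt, cl = p$cl, vss = p$vss,
               extrap_flag = p$extrap_flag, stringsAsFactors = FALSE)
  })
  subj <- do.call(rbind, rows)
  key <- interaction(subj$route, subj$dose, subj$sex, drop = TRUE)
  params <- c("tmax", "t_half", "cmax", "auc_0_t", "auc_0_inf", "cl", "vss")
  summ <- do.call(rbind, lapply(split(subj, key), function(g) {
    out <- data.frame(route = g$route[1], dose = g$dose[1], sex = g$sex[1],
                      n = nrow(g), stringsAsFactors = FALSE)
    for (p in params) {
      out[[paste0(p, "_mean")]] <- mean(g[[p]], na.rm = TRUE)
      out[[paste0(p, "_sd")]] <- stats::sd(g[[p]], na.rm = TRUE)
    }
    out
  }))
  rownames(summ) <- NULL
  structure(list(subjects = subj, summary = summ, matrix = matrix,
                 label = attr(dataset, "label")),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result '%s' (%s): %d subjects, %d groups>\n",
              x$label, x$matrix, nrow(x$subjects), nrow(x$summary)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Absolute oral bioavailability
#'
#' F = 100 x (AUC_po / Dose_po) / (AUC_iv / Dose_iv).
#'
#' @param auc_po,dose_po oral AUC (h*ng/mL) and dose.
#' @param auc_iv,dose_iv IV reference AUC and dose (same dose basis).
#' @return bioavailability, percent.
#' @examples
#' bioavailability(94.9, 2, 488.3, 1)  # ~9.7%
#' @export
bioavailability <- function(auc_po, dose_po, auc_iv, dose_iv) {
  if (auc_iv <= 0) abort_validation("IV AUC must be > 0")
  stopifnot_scalar_positive(dose_po, "dose_po")
  stopifnot_scalar_positive(dose_iv, "dose_iv")
  100 * (auc_po / dose_po) / (auc_iv / dose_iv)
}

#' Summarise bioavailability values
#'
#' Arithmetic mean and range of a set of per-group bioavailabilities.
#'
#' @param values bioavailability values, percent.
#' @return list with `mean`, `min`, `max`.
#' @export
summarize_f <- function(values) {
  if (length(values) == 0L) abort_validation("no bioavailability values supplied")
  list(mean = mean(values), min = min(values), max = max(values))
}

#' Human bioavailability prediction policy
#'
#' The translation policy for oral bioavailability: the non-rodent (dog)
#' species mean is the typical human value, and the rodent (rat) mean the
#' lower bound of the predicted range.
#'
#' @param f_by_species named list of per-species bioavailability vectors
#'   (percent), with at least elements `dog` and `rat`.
#' @return list with `typical`, `low`, `high` (percent).
#' @export
f_policy <- function(f_by_species) {
  if (!all(c("rat", "dog") %in% names(f_by_species))) {
    abort_validation("f_policy needs rat and dog bioavailability values")
  }
  dog <- summarize_f(f_by_species$dog)$mean
  rat <- summarize_f(f_by_species$rat)$mean
  list(typical = dog, low = min(rat, dog), high = max(rat, dog))
}
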