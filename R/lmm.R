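#' Replace zero loads before log transformation
#'
#' Loads enter the mixed models on the log10 scale; zero loads (possible in
#' small simulated tiles, never observed in real samples) are replaced by
#' half the smallest positive load observed in the vector, and the number of
#' replacements is recorded.
#'
#' @param x Non-negative loads.
#' @return `x` with zeros replaced; attribute `n_zero_replaced`.
#' @export
replace_zero_loads <- function(x) {
  stopifnot(all(x >= 0, na.rm = TRUE))
  zero <- which(x == 0)
  if (length(zero)) {
    pos <- x[x > 0 & !is.na(x)]
    if (!length(pos)) stop("all loads are zero; nothing to log", call. = FALSE)
    x[zero] <- min(pos) / 2
  }
  attr(x, "n_zero_replaced") <- length(zero)
  x
}

#' Mixed-effects biometry model for one organ
#'
#' Fits `response ~ log10(cp_load) + group + sex` with a random intercept
#' per dam — plus a random slope on the log10 load for the placenta, whose
#' load spans litters widely enough to support one — by maximum likelihood
#' (so fixed effects are comparable across organs; switch with `method`).
#' The load slope is expressed per 10-fold increase in load. Singular or
#' non-convergent random-slope fits fall back to the intercept-only random
#' structure and are flagged, never silently approximated.
#'
#' @param data Fetus-level table containing `cp_load`, `dam_id`, `group`,
#'   `sex` and the response column.
#' @param response Name of the response column (an organ weight or weight
#'   ratio).
#' @param random_slope Add a per-dam random slope on log10 load (the
#'   placenta convention).
#' @param method `"ML"` (default) or `"REML"`.
#' @return A `cp_lmm`: the nlme fit plus a tidy fixed-effects table with
#'   Wald 95% confidence intervals.
#' @export
fit_lmm <- function(data, response, random_slope = FALSE, method = "ML") {
  stopifnot(all(c("cp_load", "dam_id", "group", "sex", response) %in%
                  names(data)))
  data <- data[stats::complete.cases(data[, c("cp_load", "dam_id", "group",
                                              "sex", response)]), ]
  if (length(unique(data$dam_id)) < 2) {
    stop("at least two dams are required for a dam-level random effect",
         call. = FALSE)
  }
  load <- replace_zero_loads(data$cp_load)
  d <- data.frame(
    resp = data[[response]],
    log10_load = log10(load),
    group = factor(data$group),
    sex = factor(data$sex),
    dam_id = factor(data$dam_id)
  )
  ctrl <- nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200)
  fallback <- FALSE
  fit <- NULL
  if (random_slope) {
    # a singular or non-convergent random-slope fit surfaces as an error or
    # warning; either one triggers the documented intercept-only fallback
    fit <- tryCatch(
      nlme::lme(resp ~ log10_load + group + sex,
                random = ~ 1 + log10_load | dam_id,
                data = d, method = method, control = ctrl),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      slope_sd <- suppressWarnings(
        as.numeric(nlme::VarCorr(fit)["log10_load", "StdDev"]))
      if (!is.finite(slope_sd) || slope_sd < 1e-6) fit <- NULL
    }
    if (is.null(fit)) fallback <- TRUE
  }
  if (is.null(fit)) {
    fit <- nlme::lme(resp ~ log10_load + group + sex, random = ~ 1 | dam_id,
                     data = d, method = method, control = ctrl)
  }
  tt <- summary(fit)$tTable
  se <- tt[, "Std.Error"]
  est <- tt[, "Value"]
  fixed <- tibble::tibble(
    term = rownames(tt),
    estimate = unname(est),
    std_error = unname(se),
    conf_low = unname(est - stats::qnorm(0.975) * se),
    conf_high = unname(est + stats::qnorm(0.975) * se),
    p_value = unname(tt[, "p-value"])
  )
  vc <- nlme::VarCorr(fit)
  structure(
    list(fit = fit, fixed = fixed, response = response,
         random_slope = random_slope && !fallback,
         fallback_intercept_only = fallback,
         n_zero_replaced = attr(load, "n_zero_replaced"),
         n_obs = nrow(d), n_dams = length(unique(d$dam_id)),
         varcorr = vc, method = method),
    class = "cp_lmm"
  )
}

#' @export
print.cp_lmm <- function(x, ...) {
  cat(sprintf("<cp_lmm> %s ~ log10(load) + group + sex; %d fetuses, %d dams%s\n",
              x$response, x$n_obs, x$n_dams,
              if (x$fallback_intercept_only) " [random slope dropped: singular]"
              else ""))
  print(x$fixed)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cp_lmm <- function(x, ...) x$fixed

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::glance
glance.cp_lmm <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_dams = x$n_dams,
    sigma = x$fit$sigma,
    logLik = as.numeric(stats::logLik(x$fit)),
    AIC = stats::AIC(x$fit),
    random_slope = x$random_slope,
    fallback_intercept_only = x$fallback_intercept_only,
    n_zero_replaced = x$n_zero_replaced,
    method = x$method
  )
}

#' Load slope of a fitted biometry model
#'
#' Convenience accessor for the `log10_load` fixed effect: the change in the
#' response per 10-fold increase in particle load, with its Wald 95% CI.
#'
#' @param x A `cp_lmm`.
#' @return One-row tibble.
#' @export
load_slope <- function(x) {
  stopifnot(inherits(x, "cp_lmm"))
  x$fixed[x$fixed$term == "log10_load", ]
}

#' Fit the full biometry model battery of a study
#'
#' For each organ, regresses the organ weight, the organ/fetus weight ratio
#' and the fetal weight on the organ's log10 particle load (placenta with a
#' random slope, other organs random intercept only), mirroring the biometry
#' table of the study report.
#'
#' @param study Fetus-level study table with `cp_load`, biometry columns and
#'   identifiers.
#' @param fetuses Wide per-fetus biometry from [derive_biometry()].
#' @return Tibble with one row per organ and response: slope estimate, CI, p.
#' @export
biometry_models <- function(study, fetuses) {
  ratio_col <- c(placenta = "placenta_fetus_ratio_x10",
                 heart = "heart_fetus_ratio_x1e3",
                 kidney = "kidney_fetus_ratio_x1e3",
                 liver = "liver_fetus_ratio_x1e2",
                 lung = "lung_fetus_ratio_x1e2",
                 gonad = NA_character_)
  purrr::map_dfr(cp_organs(), function(org) {
    d <- study[study$organ == org, ]
    d <- dplyr::left_join(
      d, fetuses[, setdiff(names(fetuses),
                           c("dam_id", "group", "sex", "fetal_weight_g"))],
      by = "fetus_id")
    responses <- c("fetal_weight_g",
                   if (org != "gonad") paste0(org, "_g"),
                   if (!is.na(ratio_col[[org]])) ratio_col[[org]])
    purrr::map_dfr(responses, function(resp) {
      fit <- fit_lmm(d, resp, random_slope = org == "placenta")
      sl <- load_slope(fit)
      tibble::tibble(
        organ = org, response = resp,
        estimate = sl$estimate, conf_low = sl$conf_low,
        conf_high = sl$conf_high, p_value = sl$p_value,
        n_obs = fit$n_obs,
        random_slope = fit$random_slope,
        fallback = fit$fallback_intercept_only
      )
    })
  })
}
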