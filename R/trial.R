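# Whole-trial execution: interim analysis triggered by the planned S1 event
# count, threshold selection, error-spending early stopping, enrichment, and
# the final analysis at the planned total event count in the selected
# population. Spent errors and boundaries are recomputed from realized
# information levels, which is what makes the error-spending guarantee hold
# for any information path.

.null_result <- function() {
  tibble::tibble(
    w = NA_character_, stage_stopped = NA_integer_, rejected = NA_character_,
    z1_interim = NA_real_, z2_interim = NA_real_, zF_interim = NA_real_,
    z_final = NA_real_,
    d1_interim = NA_integer_, d2_interim = NA_integer_,
    d_final = NA_integer_,
    info1_interim = NA_real_, info2_interim = NA_real_,
    infoF_interim = NA_real_, info_final = NA_real_,
    a1 = NA_real_, b1 = NA_real_, a2 = NA_real_, b2 = NA_real_,
    failed = TRUE, fail_reason = NA_character_
  )
}

# Run the two-stage procedure on an already simulated cohort.
.run_trial_impl <- function(trial, plan, config, method,
                            use_planned_boundaries = FALSE) {
  zeta <- plan$zeta
  theta_alt <- c(-config$delta, 0)
  lam <- config$lambda

  snap1 <- snapshot_at_event_count(trial, "1", plan$d1_interim, 1L)
  fit1 <- suppressWarnings(fit_snapshot(snap1, 1, method))
  fit2 <- suppressWarnings(fit_snapshot(snap1, 2, method))
  fitF <- combine_subgroups(fit1, fit2, lam)
  d1o <- n_events(snap1, 1); d2o <- n_events(snap1, 2)
  dFo <- d1o + d2o

  sel1 <- fit1$z > zeta
  sel2 <- fit2$z > zeta
  w <- if (sel1 && sel2) "F"
  else if (sel1) "1"
  else if (sel2 && config$omega == "full") "2"
  else "none"

  res <- .null_result()
  res$failed <- FALSE
  res$w <- w
  res$z1_interim <- fit1$z; res$z2_interim <- fit2$z; res$zF_interim <- fitF$z
  res$d1_interim <- d1o; res$d2_interim <- d2o
  res$info1_interim <- fit1$info; res$info2_interim <- fit2$info
  res$infoF_interim <- fitF$info

  if (w == "none") {
    res$stage_stopped <- 1L
    res$rejected <- "none"
    return(res)
  }

  infos1 <- c(`1` = fit1$info, `2` = fit2$info, F = fitF$info)
  fracs <- function(IF) min(IF / plan$imax, 1)
  alpha1 <- config$alpha * fracs(fitF$info)^2
  beta1 <- config$beta * fracs(fitF$info)^2

  if (use_planned_boundaries) {
    a1 <- plan$boundaries$a1; b1 <- plan$boundaries$b1
  } else {
    s1 <- solve_stage1_boundaries(alpha1, beta1, zeta, theta_alt,
                                  fit1$info, fit2$info, lam,
                                  omega = config$omega)
    a1 <- s1$a1; b1 <- s1$b1
  }
  res$a1 <- a1; res$b1 <- b1
  zw1 <- switch(w, `1` = fit1$z, `2` = fit2$z, F = fitF$z)

  if (zw1 > b1) {
    res$stage_stopped <- 1L
    res$rejected <- paste0("H0,", w)
    return(res)
  }
  if (zw1 < a1) {
    res$stage_stopped <- 1L
    res$rejected <- "none"
    return(res)
  }

  snap2 <- snapshot_at_event_count(trial, w, plan$d_total, 2L)
  if (w == "F") {
    f1b <- suppressWarnings(fit_snapshot(snap2, 1, method))
    f2b <- suppressWarnings(fit_snapshot(snap2, 2, method))
    fw2 <- combine_subgroups(f1b, f2b, lam)
  } else {
    fw2 <- suppressWarnings(fit_snapshot(snap2, as.integer(w), method))
  }
  res$d_final <- n_events(snap2, w)
  res$z_final <- fw2$z
  res$info_final <- fw2$info

  d1v <- c(`1` = d1o, `2` = d2o, F = dFo)
  infos2 <- vapply(c("1", "2", "F"), function(j) {
    predict_information(infos1[[j]], d1v[[j]], plan$d_total)
  }, numeric(1))
  names(infos2) <- c("1", "2", "F")
  infos2[[w]] <- fw2$info
  # guard: predicted stage-2 information must exceed stage-1
  infos2 <- pmax(infos2, infos1 * 1.01)

  # the trial terminates at the second analysis, so the whole error budget
  # remaining after the interim is spent there (information fraction 1)
  alpha2 <- max(config$alpha - alpha1, 0)
  beta2 <- max(config$beta - beta1, 0)
  s2 <- suppressWarnings(
    solve_stage2_boundaries(alpha2, beta2, a1, b1, zeta, theta_alt,
                            infos1, infos2, lam, omega = config$omega))
  a2 <- min(s2$a2, s2$b2)   # binding final analysis: accept iff not rejected
  res$a2 <- a2; res$b2 <- s2$b2
  res$stage_stopped <- 2L
  res$rejected <- if (fw2$z > s2$b2) paste0("H0,", w) else "none"
  res
}

#' Run one adaptive enrichment trial
#'
#' Simulates a cohort and executes the two-stage procedure: interim analysis
#' once the planned number of S1 events is observed, threshold selection,
#' early stopping against the stage-1 error-spending boundaries, and (if the
#' trial continues) a final analysis once the planned total number of events
#' is observed in the selected population, rejecting the selected hypothesis
#' if its Z-statistic exceeds the final boundary. Only the selected
#' hypothesis is ever tested.
#'
#' @param params a [joint_model_params()].
#' @param plan a [plan_design()] result.
#' @param config the [design_config()] used for the plan.
#' @param method analysis method.
#' @param n_patients cohort size (must be generous enough that the planned
#'   event counts are attainable in any selectable population).
#' @param theta optional scenario override of the treatment effects.
#' @param use_planned_boundaries use the planning-stage boundaries verbatim
#'   instead of re-solving at realized information (default `FALSE`).
#' @return A one-row tibble (class `trial_result`): selection `w`, stage
#'   stopped, rejected hypothesis, interim and final Z-statistics, realized
#'   event counts, informations and boundaries.
#' @export
run_trial <- function(params, plan, config, method = "condscore",
                      n_patients = 1500, theta = NULL,
                      use_planned_boundaries = FALSE) {
  trial <- simulate_trial(params, n_patients, theta = theta)
  out <- .run_trial_impl(trial, plan, config, method,
                         use_planned_boundaries = use_planned_boundaries)
  class(out) <- c("trial_result", class(out))
  out
}

#' Monte-Carlo standard error of a proportion
#'
#' @param p the proportion.
#' @param N number of replicates.
#' @return `sqrt(p (1 - p) / N)`.
#' @examples
#' mc_standard_error(0.025, 1e4)  # 0.00156
#' mc_standard_error(0.9, 1e4)    # 0.003
#' @export
mc_standard_error <- function(p, N) {
  stopifnot(all(p >= 0), all(p <= 1), all(N >= 1))
  sqrt(p * (1 - p) / N)
}

#' Operating characteristics of the enrichment design
#'
#' Replicates whole trials and summarises rejection and selection behaviour.
#' When several methods are compared they are run on the same simulated
#' datasets (common random numbers), so that differences are attributable to
#' the analysis method alone. The familywise error rate is the proportion of
#' replicates rejecting a true null (a hypothesis whose effect is
#' non-negative benefit, i.e. `theta >= 0`); conditional power is the
#' proportion rejecting `H0,1` among replicates that selected S1.
#'
#' @param params a [joint_model_params()].
#' @param plan a `design_plan`.
#' @param config the matching `design_config`.
#' @param methods character vector of analysis methods.
#' @param n_reps number of replicate trials (>= 100).
#' @param theta scenario treatment effects, e.g. `c(0, 0)` for the global
#'   null or `c(-0.5, 0)` for the design alternative.
#' @param n_patients cohort size per replicate.
#' @param max_fail_frac abort if more than this fraction of replicates fails.
#' @return An object of class `enrich_oc` with `$summary` (one row per
#'   method) and `$results` (one row per replicate and method).
#' @export
operating_characteristics <- function(params, plan, config,
                                      methods = "condscore", n_reps = 500,
                                      theta = c(0, 0), n_patients = 1500,
                                      max_fail_frac = 0.05) {
  stopifnot(n_reps >= 100)
  res <- vector("list", n_reps * length(methods))
  k <- 0L
  for (r in seq_len(n_reps)) {
    trial <- simulate_trial(params, n_patients, theta = theta)
    for (m in methods) {
      k <- k + 1L
      row <- tryCatch(
        .run_trial_impl(trial, plan, config, m),
        error = function(e) {
          out <- .null_result()
          out$fail_reason <- conditionMessage(e)
          out
        })
      row$method <- m
      row$rep <- r
      res[[k]] <- row
    }
  }
  results <- dplyr::bind_rows(res)

  theta_all <- c(theta[1], theta[2],
                 config$lambda * theta[1] + (1 - config$lambda) * theta[2])
  names(theta_all) <- c("H0,1", "H0,2", "H0,F")
  true_nulls <- names(theta_all)[theta_all >= -1e-12]

  summary <- results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      n_failed = sum(.data$failed),
      p_select_1 = mean(.data$w == "1", na.rm = TRUE),
      p_select_2 = mean(.data$w == "2", na.rm = TRUE),
      p_select_F = mean(.data$w == "F", na.rm = TRUE),
      p_select_none = mean(.data$w == "none", na.rm = TRUE),
      p_reject_any = mean(.data$rejected != "none", na.rm = TRUE),
      fwer = mean(.data$rejected %in% true_nulls, na.rm = TRUE),
      n_select_1 = sum(.data$w == "1", na.rm = TRUE),
      power_conditional = {
        sel <- .data$w == "1" & !.data$failed
        if (any(sel, na.rm = TRUE)) {
          mean(.data$rejected[which(sel)] == "H0,1")
        } else NA_real_
      },
      mean_d1_interim = mean(.data$d1_interim, na.rm = TRUE),
      mean_d2_interim = mean(.data$d2_interim, na.rm = TRUE),
      mean_d_final = mean(.data$d_final, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      fwer_se = mc_standard_error(.data$fwer, .data$n_reps - .data$n_failed),
      power_se = ifelse(.data$n_select_1 > 0,
                        mc_standard_error(.data$power_conditional,
                                          .data$n_select_1), NA_real_))

  frac_failed <- max(summary$n_failed / summary$n_reps)
  if (frac_failed > max_fail_frac) {
    stop(sprintf(
      "%.1f%% of replicates failed (limit %.0f%%); first reason: %s",
      100 * frac_failed, 100 * max_fail_frac,
      results$fail_reason[which(results$failed)[1]]), call. = FALSE)
  }

  structure(list(summary = summary, results = results, theta = theta,
                 true_nulls = true_nulls, n_reps = n_reps),
            class = "enrich_oc")
}

#' @export
print.enrich_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d replicate trials (theta = %.2f, %.2f)\n",
              x$n_reps, x$theta[1], x$theta[2]))
  print(x$summary)
  invisible(x)
}

#' @rdname operating_characteristics
#' @param x an `enrich_oc`.
#' @param ... unused.
#' @export
tidy.enrich_oc <- function(x, ...) x$summary

#' Plot selection and rejection frequencies
#'
#' @param object an `enrich_oc`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.enrich_oc <- function(object, ...) {
  long <- object$summary |>
    dplyr::select(.data$method, dplyr::starts_with("p_select_")) |>
    tidyr::pivot_longer(-"method", names_to = "population",
                        names_prefix = "p_select_", values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population,
                                     y = .data$probability,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "selected population", y = "probability",
                  title = "Interim selection frequencies") +
    ggplot2::theme_minimal()
}
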