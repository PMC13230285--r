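#' Simulate the stable disease population
#'
#' Generates the stable population: a fixed number of DCIS onsets at every
#' calendar step, each assigned an inverse growth rate from the Gamma prior
#' and sojourn times by closed-form inversion sampling
#' ([sample_sojourns()]).  If a screening schedule is supplied, each
#' individual's offered screens are walked chronologically from onset:
#' while in the preclinical DCIS state the logistic DCIS sensitivity is
#' applied to the current lesion diameter, while in the preclinical
#' invasive state the invasive sensitivity is applied to the current lesion
#' diameter and tumour diameter (the lesion keeps growing after
#' transition); the first positive screen detects the individual.
#' Undetected individuals are detected symptomatically at
#' `onset + T_D` (DCIS) or `onset + T_T + T_I` (invasive).  A screen at the
#' exact instant of transition uses the invasive (state 4) sensitivity, and
#' a screen at the exact instant of onset sees a lesion of size `l0`.
#' Screens before onset can never detect (sensitivity zero).
#'
#' Simulation is chunked: onsets are generated in fixed blocks of calendar
#' steps with per-chunk seeds derived deterministically from `pop$seed` and
#' the absolute chunk index, so results depend only on the root seed and
#' the fixed chunk layout (`chunk_steps`), never on available memory.  When
#' `keep_window` is supplied, only onsets within the preceding sojourn
#' horizon of the window are materialised (older onsets have a negligible
#' probability — bounded below `horizon_miss` expected individuals in
#' total — of still being undetected), and only individuals whose
#' detection time falls at or after `keep_window[1]` are retained.
#'
#' @param params an [nh_params()] object.
#' @param pop a [population_config()].
#' @param schedule a [screening_schedule()] or `NULL` for no screening.
#'   Schedule times outside the simulation window are ignored with a
#'   warning.
#' @param keep_window length-2 numeric: retain individuals detected at or
#'   after `keep_window[1]` with onset at or before `keep_window[2]`.
#'   `NULL` keeps everything (only feasible at small scale).
#' @param chunk_steps number of calendar steps per chunk.
#' @param horizon_miss tolerated expected number of individuals missed by
#'   the onset-window truncation.
#' @return An object of class `nh_population`: a list with `individuals`
#'   (data frame: `onset`, `r`, `t_D`, `t_T`, `t_I`, `type`, `mode`,
#'   `fate`, `detection_time`, `size_mm`), the configuration, schedule and
#'   the horizon used.
#' @export
simulate_population <- function(params, pop, schedule = NULL,
                                keep_window = NULL, chunk_steps = 2000L,
                                horizon_miss = 0.1) {
  validate_params(params)
  screens <- if (is.null(schedule)) numeric() else as.numeric(schedule)
  if (length(screens)) {
    out_of_window <- screens < pop$t_start | screens > pop$t_end
    if (any(out_of_window)) {
      warning(sum(out_of_window),
              " screening time(s) outside the simulation window ignored")
      screens <- screens[!out_of_window]
    }
  }
  grid_n <- floor((pop$t_end - pop$t_start) / pop$step + 1e-9) + 1L
  first_idx <- 1L
  last_idx <- grid_n
  horizon <- NA_real_
  if (!is.null(keep_window)) {
    rate <- pop$onsets_per_step / pop$step
    horizon <- .sojourn_horizon(params, rate, horizon_miss)
    t_min <- keep_window[1] - horizon
    if (t_min < pop$t_start)
      warning("burn-in shorter than the sojourn horizon (", round(horizon, 1),
              " y); stationarity at keep_window[1] is not guaranteed")
    first_idx <- max(1L, ceiling((t_min - pop$t_start) / pop$step) + 1L)
    last_idx <- min(grid_n,
                    floor((keep_window[2] - pop$t_start) / pop$step + 1e-9) + 1L)
  }
  chunk_starts <- seq(first_idx, last_idx, by = chunk_steps)
  keep <- vector("list", length(chunk_starts))
  for (ci in seq_along(chunk_starts)) {
    i0 <- chunk_starts[ci]
    i1 <- min(i0 + chunk_steps - 1L, last_idx)
    # chunk seed tied to the absolute step index so that window choice does
    # not perturb other chunks' draws
    set.seed((pop$seed + 100003 * (((i0 - 1L) %/% chunk_steps) + 1)) %%
               2147483647)
    onset <- pop$t_start + (seq(i0, i1) - 1L) * pop$step
    onset <- rep(onset, each = pop$onsets_per_step)
    ind <- .simulate_individuals(onset, params, screens)
    if (!is.null(keep_window))
      ind <- ind[ind$detection_time >= keep_window[1] &
                   ind$onset <= keep_window[2], , drop = FALSE]
    keep[[ci]] <- ind
  }
  individuals <- do.call(rbind, keep)
  rownames(individuals) <- NULL
  structure(list(individuals = individuals, params = params, pop = pop,
                 schedule = screens, keep_window = keep_window,
                 horizon = horizon),
            class = "nh_population")
}

# core vectorised generator for a vector of onset times
.simulate_individuals <- function(onset, params, screens) {
  n <- length(onset)
  sj <- sample_sojourns(n, r = NULL, params = params)
  trans <- sj$t_T < sj$t_D
  sym_time <- onset + ifelse(trans, sj$t_T + sj$t_I, sj$t_D)
  det_time <- sym_time
  det_mode <- rep("symptomatic", n)
  det_type <- ifelse(trans, "invasive", "dcis")
  size <- sj$l_D
  size[trans] <- diameter_from_volume(sj$v_I[trans])
  detected <- rep(FALSE, n)
  t_e <- pmin(sj$t_D, sj$t_T)
  for (s in screens) {
    open <- !detected & s >= onset & s < sym_time
    if (!any(open)) next
    age <- s - onset[open]
    r <- sj$r[open]
    in4 <- trans[open] & age >= sj$t_T[open]
    l_now <- dcis_size(age, r, params)
    prob <- stats::plogis(params$b0 + params$b1 * l_now)
    d_now <- rep(NA_real_, sum(open))
    if (any(in4)) {
      d_now[in4] <- diameter_from_volume(
        invasive_volume(age[in4] - sj$t_T[open][in4], r[in4], params))
      prob[in4] <- stats::plogis(params$b0 + params$b1 * l_now[in4] +
                                   params$b2 * d_now[in4])
    }
    # individuals past their DCIS exit but not (yet) invasive are only
    # reachable when trans & age >= t_T; others with age >= t_e and !in4
    # cannot occur since sym_time caps DCIS-symptomatic cases
    hit <- stats::runif(sum(open)) < prob
    if (any(hit)) {
      idx <- which(open)[hit]
      detected[idx] <- TRUE
      det_time[idx] <- s
      det_mode[idx] <- "screen"
      det_type[idx] <- ifelse(in4[hit], "invasive", "dcis")
      size[idx] <- ifelse(in4[hit], d_now[hit], l_now[hit])
    }
  }
  fate <- paste(ifelse(det_mode == "screen", "screen_detected",
                       det_mode), det_type, sep = "_")
  fate[det_mode == "symptomatic"] <-
    paste0(det_type[det_mode == "symptomatic"], "_symptomatic")
  data.frame(onset = onset, r = sj$r, t_D = sj$t_D, t_T = sj$t_T,
             t_I = sj$t_I, type = det_type, mode = det_mode, fate = fate,
             detection_time = det_time, size_mm = size)
}

#' Snapshot of the preclinical population
#'
#' Cross-section of the simulated population at a calendar query time:
#' preclinical DCIS members (`onset <= q < onset + min(T_D, T_T)`) and
#' preclinical invasive members (`T_T < T_D` and
#' `onset + T_T <= q < onset + T_T + T_I`), excluding anyone
#' screen-detected strictly before `q`.  Sizes are computed from the growth
#' functions at `q`.
#'
#' @param popobj an `nh_population` from [simulate_population()].
#' @param query_time calendar time of the cross-section (years).
#' @return Object of class `nh_snapshot`: data frame with columns `type`
#'   (`"dcis"`/`"invasive"`), `r`, `onset`, `lesion_mm` (current lesion
#'   diameter), `volume_mm3` and `diameter_mm` (invasive members only,
#'   else `NA`).
#' @export
snapshot_preclinical <- function(popobj, query_time) {
  q <- query_time
  kw <- popobj$keep_window
  if (!is.null(kw) && (q < kw[1] || q > kw[2] + 1e-9))
    warning("query time outside the retained window; counts will be biased")
  if (is.null(kw) && is.finite(popobj$horizon) == FALSE) {
    burn <- q - popobj$pop$t_start
    if (burn < 60)
      warning("short burn-in before the query time; ",
              "stationarity is not guaranteed")
  }
  ind <- popobj$individuals
  not_removed <- ind$detection_time >= q
  t_e <- pmin(ind$t_D, ind$t_T)
  dcis <- not_removed & ind$onset <= q & q < ind$onset + t_e
  inv <- not_removed & ind$t_T < ind$t_D & ind$onset + ind$t_T <= q &
    q < ind$onset + ind$t_T + ind$t_I
  idx <- which(dcis | inv)
  if (!length(idx)) {
    snap <- data.frame(type = character(), r = numeric(), onset = numeric(),
                       lesion_mm = numeric(), volume_mm3 = numeric(),
                       diameter_mm = numeric())
  } else {
    sub <- ind[idx, , drop = FALSE]
    is_inv <- inv[idx]
    lesion <- dcis_size(q - sub$onset, sub$r, popobj$params)
    vol <- rep(NA_real_, length(idx))
    vol[is_inv] <- invasive_volume(q - sub$onset[is_inv] - sub$t_T[is_inv],
                                   sub$r[is_inv], popobj$params)
    diam <- rep(NA_real_, length(idx))
    diam[is_inv] <- diameter_from_volume(vol[is_inv])
    snap <- data.frame(type = ifelse(is_inv, "invasive", "dcis"),
                       r = sub$r, onset = sub$onset, lesion_mm = lesion,
                       volume_mm3 = vol, diameter_mm = diam)
  }
  structure(list(snapshot = snap, query_time = q,
                 counts = c(dcis = sum(snap$type == "dcis"),
                            invasive = sum(snap$type == "invasive"))),
            class = "nh_snapshot")
}

#' @export
print.nh_snapshot <- function(x, ...) {
  cat(sprintf("Preclinical snapshot at t = %g: %d DCIS, %d invasive (DCIS share %.4f)\n",
              x$query_time, x$counts["dcis"], x$counts["invasive"],
              x$counts["dcis"] / sum(x$counts)))
  invisible(x)
}

#' Sample an incident-case dataset
#'
#' Emulates a register-based cases-only design: a Bernoulli sample of the
#' screen-detected cases of one screening round and of the symptomatically
#' detected cases of a calendar window.  Each sampled case carries its
#' disease type, detection mode, size at detection (lesion diameter for
#' DCIS, tumour diameter for invasive cancer, mm), detection time and the
#' calendar times of all attended screens up to and including detection
#' (screens that predate the latent onset are retained: a register cannot
#' observe onset, and they carry no likelihood information).
#'
#' @param popobj an `nh_population` simulated with a screening schedule.
#' @param screen_sample_time calendar time of the sampled screening round.
#' @param symptomatic_window half-open calendar interval `[w1, w2)` over
#'   which symptomatic detections are sampled.
#' @param fraction sampling fraction(s); either a single number or a named
#'   vector `c(screen = , symptomatic = )`.
#' @return An `nh_cases` data frame with columns `case_id`, `disease_type`,
#'   `detection_mode`, `size_mm`, `detection_time` and `screen_times` (a
#'   list column of attended screen times).
#' @export
sample_case_dataset <- function(popobj, screen_sample_time = 340,
                                symptomatic_window = c(340, 342),
                                fraction = 0.14) {
  if (length(popobj$schedule) == 0)
    stop("population was simulated without screening")
  if (length(fraction) == 1) fraction <- c(screen = fraction,
                                           symptomatic = fraction)
  ind <- popobj$individuals
  scr <- ind$mode == "screen" &
    abs(ind$detection_time - screen_sample_time) < 1e-9
  sym <- ind$mode == "symptomatic" &
    ind$detection_time >= symptomatic_window[1] &
    ind$detection_time < symptomatic_window[2]
  if (!any(scr) && !any(sym)) warning("no eligible cases in the windows")
  pick <- logical(nrow(ind))
  pick[scr] <- stats::runif(sum(scr)) < fraction[["screen"]]
  pick[sym] <- stats::runif(sum(sym)) < fraction[["symptomatic"]]
  sub <- ind[pick, , drop = FALSE]
  screens <- popobj$schedule
  st <- lapply(sub$detection_time, function(dt) screens[screens <= dt + 1e-9])
  out <- data.frame(case_id = seq_len(nrow(sub)),
                    disease_type = sub$type,
                    detection_mode = sub$mode,
                    size_mm = sub$size_mm,
                    detection_time = sub$detection_time)
  out$screen_times <- st
  class(out) <- c("nh_cases", "data.frame")
  out
}
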