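#' Kinematic parameters of the synthetic behaviours
#'
#' The generator realises each of the eight stereotyped behaviours as a
#' correlated random walk with a class-specific steering rule: a preferred
#' radial band (thigmotaxis, chaining response), an attraction point
#' (focused search, target scanning), a waypoint rule (scanning
#' surroundings), a fixed-rate turn (self orienting), or free diffusion
#' with wall avoidance (scanning). Defaults are chosen so that the classes
#' are separable in the eight-feature space yet overlap at behaviour
#' transitions, which is what exercises the undefined clusters downstream.
#' All lengths in cm, angles in radians, rates per step.
#'
#' @return Named list of per-class parameter lists.
#' @export
behaviour_kinematics <- function() {
  list(
    thigmotaxis = list(band = 0.93, band_gain = 0.12, noise = 0.12,
                       tangential = TRUE),
    incursion = list(band_lo = 0.62, band_hi = 0.95, period = 9,
                     band_gain = 0.10, noise = 0.22, tangential = TRUE),
    scanning = list(noise = 0.28, wall_r = 0.60, speed_factor = 1),
    focused_search = list(anchor_r = 0.45, pull = 0.75, noise = 0.95,
                          jitter_r = 12, speed_factor = 0.75),
    chaining_response = list(band_gain = 0.15, noise = 0.10,
                             tangential = TRUE),
    self_orienting = list(loop_len = 120, noise = 0.06),
    scanning_surroundings = list(noise = 0.18),
    target_scanning = list(orbit_r = 20, band_gain = 0.35, noise = 0.22,
                           tangential = TRUE)
  )
}

# smallest signed angle from a to b
ang_diff <- function(a, b) {
  d <- (b - a) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Generate one behaviour bout
#'
#' Simulates \code{duration} seconds of one behavioural class at a fixed
#' sampling rate, starting from a given position and heading so that bouts
#' concatenate into a continuous trial. All samples stay strictly inside
#' the arena (soft steering toward the centre near the wall, plus a radial
#' clamp).
#'
#' @param class one of \code{\link{behaviour_classes}()}.
#' @param duration bout duration (s).
#' @param arena an \code{arena_geometry}.
#' @param start numeric length-2 start position (cm).
#' @param heading initial heading (rad).
#' @param speed mean swim speed (cm/s); rats swim at roughly 20-30 cm/s.
#' @param dt sampling interval (s); 1/25 s emulates a 25 Hz tracker.
#' @param kin kinematic parameter list, see
#'   \code{\link{behaviour_kinematics}}.
#' @param seed optional integer seed (bouts inside
#'   \code{\link{generate_trial}} inherit its RNG stream instead).
#' @return List: \code{points} (n x 2 matrix, excluding the start point),
#'   \code{heading} (final), \code{labels} (class per generated sample).
#' @export
generate_behaviour <- function(class, duration, arena, start,
                               heading = 0, speed = 22, dt = 0.04,
                               kin = behaviour_kinematics(), seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, generate_behaviour(class, duration, arena,
                                              start, heading, speed, dt,
                                              kin)))
  if (!class %in% behaviour_classes()) stop("unknown behaviour class: ",
                                            class)
  p <- kin[[class]]
  R <- arena$arena_radius
  ctr <- arena$centre
  n <- max(1L, round(duration / dt))
  pts <- matrix(0, n, 2)
  pos <- as.numeric(start)
  spd <- speed * if (is.null(p$speed_factor)) 1 else p$speed_factor
  omega <- sample(c(-1, 1), 1L)             # orbit sense for this bout
  phase <- stats::runif(1, 0, 2 * pi)
  # class-specific state
  anchor <- if (class == "focused_search") {
    # a small search area away from the platform region: focused search
    # targets other parts of the arena, not the platform
    repeat {
      a_r <- p$anchor_r * R * sqrt(stats::runif(1))
      a_th <- stats::runif(1, 0, 2 * pi)
      cand <- ctr + a_r * c(cos(a_th), sin(a_th))
      if (sqrt(sum((cand - arena$platform_centre)^2)) >
            7 * arena$platform_radius) break
    }
    cand
  }
  turn_per_step <- if (class == "self_orienting")
    omega * 2 * pi * spd * dt / p$loop_len
  loop_left <- 2 * pi
  straight_left <- 0L
  waypoint <- if (class == "scanning_surroundings") arena$platform_centre

  for (i in seq_len(n)) {
    rel <- pos - ctr
    r <- sqrt(sum(rel^2))
    phi <- atan2(rel[2], rel[1])
    r_hat <- if (r > 1e-9) rel / r else c(1, 0)
    t_hat <- omega * c(-r_hat[2], r_hat[1])

    des <- heading
    if (class %in% c("thigmotaxis", "chaining_response",
                     "target_scanning", "incursion")) {
      if (class == "thigmotaxis") {
        r_t <- p$band * R; org <- ctr; rr <- r
      } else if (class == "chaining_response") {
        r_t <- sqrt(sum((arena$platform_centre - ctr)^2)); org <- ctr
        rr <- r
      } else if (class == "incursion") {
        mid <- (p$band_lo + p$band_hi) / 2
        amp <- (p$band_hi - p$band_lo) / 2
        r_t <- R * (mid + amp * sin(2 * pi * i * dt / p$period + phase))
        org <- ctr; rr <- r
      } else {                               # target_scanning
        relp <- pos - arena$platform_centre
        rr <- sqrt(sum(relp^2))
        r_t <- p$orbit_r; org <- arena$platform_centre
        r_hat <- if (rr > 1e-9) relp / rr else c(1, 0)
        t_hat <- omega * c(-r_hat[2], r_hat[1])
      }
      v <- t_hat + p$band_gain * (r_t - rr) / 10 * r_hat
      des <- atan2(v[2], v[1])
    } else if (class == "scanning") {
      if (r > p$wall_r * R) des <- atan2(-rel[2], -rel[1])
    } else if (class == "focused_search") {
      da <- anchor - pos
      if (sqrt(sum(da^2)) > p$jitter_r) des <- atan2(da[2], da[1])
    } else if (class == "self_orienting") {
      if (loop_left > 0) {
        des <- heading + turn_per_step
        loop_left <- loop_left - abs(turn_per_step)
        if (loop_left <= 0) straight_left <- round(5 / dt)
      } else {
        # between turns: swim on; re-orient again if the bout lasts long
        straight_left <- straight_left - 1L
        if (straight_left <= 0L) loop_left <- 2 * pi
      }
    } else if (class == "scanning_surroundings") {
      dw <- waypoint - pos
      if (sqrt(sum(dw^2)) < 8 || r > 0.88 * R) {
        # new pass: aim through the platform region and well beyond it, so
        # the path crosses the critical zone without circling it
        dir <- arena$platform_centre - pos
        dn <- sqrt(sum(dir^2))
        dir <- if (dn > 1e-9) dir / dn else c(1, 0)
        rot <- stats::runif(1, -0.4, 0.4)
        dir <- c(cos(rot) * dir[1] - sin(rot) * dir[2],
                 sin(rot) * dir[1] + cos(rot) * dir[2])
        w <- arena$platform_centre + stats::runif(1, 0.45, 0.75) * R * dir
        wr <- sqrt(sum((w - ctr)^2))
        if (wr > 0.88 * R) w <- ctr + (w - ctr) / wr * 0.88 * R
        waypoint <- w
        dw <- waypoint - pos
      }
      if (sqrt(sum(dw^2)) > 1) des <- atan2(dw[2], dw[1])
    }

    # steer toward desired heading, with class noise
    gain <- if (class == "self_orienting" && loop_left > 0) 1 else 0.55
    heading <- heading + gain * ang_diff(heading, des) +
      p$noise * stats::rnorm(1)
    # hard wall avoidance: steer inward when close to the wall
    step_len <- spd * dt * (1 + 0.1 * stats::rnorm(1))
    nxt <- pos + step_len * c(cos(heading), sin(heading))
    if (sqrt(sum((nxt - ctr)^2)) > 0.985 * R) {
      inward <- atan2(ctr[2] - pos[2], ctr[1] - pos[1])
      heading <- heading + 0.8 * ang_diff(heading, inward)
      nxt <- pos + step_len * c(cos(heading), sin(heading))
      rel2 <- nxt - ctr; r2 <- sqrt(sum(rel2^2))
      if (r2 > 0.995 * R) nxt <- ctr + rel2 / r2 * 0.995 * R
    }
    pos <- nxt
    pts[i, ] <- pos
  }
  list(points = pts, heading = heading,
       labels = rep(class, n))
}

#' Generate a full synthetic trial
#'
#' Concatenates a sequence of behaviour bouts into one continuous
#' trajectory sampled at a fixed rate, carrying a ground-truth class per
#' sample. Reproducible from the seed.
#'
#' @param specs list of \code{list(class =, duration =)} bout
#'   specifications.
#' @param arena an \code{arena_geometry}.
#' @param seed integer seed.
#' @param id,animal_id,group,day,trial trial metadata.
#' @param speed mean swim speed (cm/s).
#' @param dt sampling interval (s).
#' @param start optional start position; default a random point near the
#'   wall (animals are released at the arena edge).
#' @return Object of class \code{synthetic_trial}: list with
#'   \code{trajectory}, \code{truth} (class per sample), \code{specs},
#'   \code{seed}.
#' @export
generate_trial <- function(specs, arena = arena_geometry(), seed = 1L,
                           id = "trial", animal_id = NA, group = NA,
                           day = NA, trial = NA, speed = 22, dt = 0.04,
                           start = NULL) {
  with_seed(seed, {
    R <- arena$arena_radius
    if (is.null(start)) {
      th <- stats::runif(1, 0, 2 * pi)
      start <- arena$centre + 0.9 * R * c(cos(th), sin(th))
    }
    heading <- stats::runif(1, 0, 2 * pi)
    pts <- list(); labs <- list()
    pos <- start
    for (s in specs) {
      bout <- generate_behaviour(s$class, s$duration, arena, pos,
                                 heading = heading, speed = speed, dt = dt)
      pts[[length(pts) + 1L]] <- bout$points
      labs[[length(labs) + 1L]] <- bout$labels
      pos <- bout$points[nrow(bout$points), ]
      heading <- bout$heading
    }
    P <- rbind(matrix(start, 1), do.call(rbind, pts))
    truth <- c(specs[[1]]$class, unlist(labs))
    tt <- (seq_len(nrow(P)) - 1) * dt
    traj <- trajectory(tt, P[, 1], P[, 2], arena, id = id,
                       animal_id = animal_id, group = group,
                       day = day, trial = trial)
    structure(list(trajectory = traj, truth = truth, specs = specs,
                   seed = seed),
              class = "synthetic_trial")
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("Synthetic trial", x$trajectory$id, "- bouts:",
      paste(vapply(x$specs, `[[`, "", "class"), collapse = ", "), "\n")
  print(x$trajectory)
  invisible(x)
}

# learning-stage behaviour weights: early trials favour wall behaviours,
# later trials platform-directed search
stage_weights <- function(frac) {
  early <- c(thigmotaxis = 0.32, incursion = 0.24, scanning = 0.16,
             focused_search = 0.06, chaining_response = 0.05,
             self_orienting = 0.07, scanning_surroundings = 0.05,
             target_scanning = 0.05)
  late <- c(thigmotaxis = 0.05, incursion = 0.07, scanning = 0.14,
            focused_search = 0.09, chaining_response = 0.15,
            self_orienting = 0.10, scanning_surroundings = 0.16,
            target_scanning = 0.24)
  w <- (1 - frac) * early + frac * late
  w / sum(w)
}

#' Generate a synthetic cohort of two animal groups
#'
#' Emulates the design of a spatial-acquisition experiment: two groups of
#' animals, a fixed set of trials per animal (grouped into days), 90 s
#' trials tracked at 25 Hz in a 2 m arena. Behaviour bout sequences follow
#' a learning progression (wall-bound strategies early, platform-directed
#' search late). The group contrast is parameterised by a speed multiplier
#' and a dwell multiplier inflating the weight of the low-efficiency
#' strategies (thigmotaxis, incursion, scanning) in the second ("stress")
#' group; both set to 1 give two statistically identical groups (the null).
#'
#' @param n_control,n_stress animals per group.
#' @param n_trials trials per animal.
#' @param trial_duration trial length (s).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param speed_effect stress-group speed multiplier (default 1.15).
#' @param dwell_effect stress-group multiplier on the weights of
#'   thigmotaxis/incursion/scanning (default 1.8).
#' @param speed baseline swim speed (cm/s).
#' @param dt sampling interval (s).
#' @param arena an \code{arena_geometry}.
#' @return List of class \code{mwm_cohort}: \code{manifest} (data.frame
#'   \code{id, animal_id, group, day, trial, file}) and \code{trials}
#'   (named list of \code{synthetic_trial}s).
#' @export
generate_cohort <- function(n_control = 27, n_stress = 30, n_trials = 12,
                            trial_duration = 90, seed = 1L,
                            speed_effect = 1.15, dwell_effect = 1.8,
                            speed = 22, dt = 0.04,
                            arena = arena_geometry()) {
  animals <- data.frame(
    animal_id = c(sprintf("c%02d", seq_len(n_control)),
                  sprintf("s%02d", seq_len(n_stress))),
    group = rep(c("control", "stress"), c(n_control, n_stress)),
    stringsAsFactors = FALSE)
  trials <- list()
  manifest <- NULL
  days <- sort(rep_len(seq_len(max(1L, min(3L, n_trials))), n_trials))
  with_seed(seed, {
    for (ai in seq_len(nrow(animals))) {
      for (tr in seq_len(n_trials)) {
        frac <- if (n_trials > 1) (tr - 1) / (n_trials - 1) else 0.5
        w <- stage_weights(frac)
        sp <- speed
        if (animals$group[ai] == "stress") {
          w[c("thigmotaxis", "incursion", "scanning")] <-
            w[c("thigmotaxis", "incursion", "scanning")] * dwell_effect
          w <- w / sum(w)
          sp <- speed * speed_effect
        }
        n_bouts <- sample(2:4, 1L)
        cls <- sample(names(w), n_bouts, prob = w)
        dur <- stats::rgamma(n_bouts, shape = 2)
        dur <- trial_duration * dur / sum(dur)
        dur <- pmax(dur, 0.12 * trial_duration)
        dur <- trial_duration * dur / sum(dur)
        # self-orienting is a transient behaviour (one full turn): keep its
        # bouts short and give the spare time to the other bouts
        so <- cls == "self_orienting"
        if (any(so) && !all(so)) {
          spare <- sum(pmax(dur[so] - 9, 0))
          dur[so] <- pmin(dur[so], 9)
          dur[!so] <- dur[!so] + spare * dur[!so] / sum(dur[!so])
        }
        specs <- mapply(function(cl, du) list(class = cl, duration = du),
                        cls, dur, SIMPLIFY = FALSE)
        tid <- sprintf("%s_t%02d", animals$animal_id[ai], tr)
        t_seed <- (seed * 7919L + ai * 1009L + tr * 101L) %% 2147483629L
        trials[[tid]] <- generate_trial(
          specs, arena, seed = t_seed, id = tid,
          animal_id = animals$animal_id[ai], group = animals$group[ai],
          day = days[tr], trial = tr, speed = sp, dt = dt)
      }
    }
  })
  manifest <- data.frame(
    id = names(trials),
    animal_id = vapply(trials, function(x) x$trajectory$animal_id, ""),
    group = vapply(trials, function(x) x$trajectory$group, ""),
    day = vapply(trials, function(x) x$trajectory$day, 0L),
    trial = vapply(trials, function(x) x$trajectory$trial, 0L),
    file = NA_character_, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(manifest = manifest, trials = trials),
            class = "mwm_cohort")
}

#' @export
print.mwm_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$manifest), "trials,",
      length(unique(x$manifest$animal_id)), "animals (",
      paste(names(table(x$manifest$group[!duplicated(
        x$manifest$animal_id)])), table(x$manifest$group[!duplicated(
          x$manifest$animal_id)]), collapse = ", "), ")\n")
  invisible(x)
}

#' Ground-truth class of an arc-length range of a synthetic trial
#'
#' Majority truth label over the samples whose cumulative arc length falls
#' in [from, to]; used to label segments and to score interval
#' classifications against the generative truth.
#'
#' @param trial a \code{synthetic_trial}.
#' @param from,to arc-length range (cm).
#' @return Class name (majority over samples in range).
#' @export
truth_of_range <- function(trial, from, to) {
  names(truth_shares_of_range(trial, from, to))[1]
}

#' @rdname truth_of_range
#' @details \code{truth_shares_of_range} returns the full composition
#'   (sample share per class, decreasing), useful to spot ranges that
#'   straddle a behaviour transition.
#' @export
truth_shares_of_range <- function(trial, from, to) {
  cum <- arc_lengths(trial$trajectory)
  in_rng <- cum >= from - 1e-9 & cum <= to + 1e-9
  if (!any(in_rng)) in_rng[which.min(abs(cum - (from + to) / 2))] <- TRUE
  tab <- table(trial$truth[in_rng])
  sort(tab / sum(tab), decreasing = TRUE)
}

#' Ground-truth labels for a random subset of segments
#'
#' Emulates the manual labelling step: a fraction of segments receives its
#' generative (majority) class. A segment that straddles a behaviour
#' transition — no class reaching the \code{ambiguity} share of its
#' samples — is given the labels of its two dominant classes, the way an
#' annotator marks a segment showing traits of more than one behaviour;
#' such multi-label segments are excluded downstream from constraints and
#' cluster-class mapping.
#'
#' @param cohort an \code{mwm_cohort}.
#' @param index segment index table (see \code{\link{segment_index}}).
#' @param fraction fraction of segments to label.
#' @param seed integer seed.
#' @param ambiguity minimum majority share for a single label
#'   (default 0.8).
#' @return data.frame \code{segment_id, class} (ambiguous segments appear
#'   on two rows).
#' @export
truth_labels <- function(cohort, index, fraction = 0.1, seed = 1L,
                         ambiguity = 0.8) {
  n_lab <- max(1L, round(fraction * nrow(index)))
  pick <- with_seed(seed, sample.int(nrow(index), n_lab))
  rows <- index[pick, , drop = FALSE]
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    tr <- cohort$trials[[rows$trajectory_id[i]]]
    sh <- truth_shares_of_range(tr, rows$start_offset_cm[i],
                                rows$start_offset_cm[i] +
                                  rows$actual_length_cm[i])
    cls <- if (sh[1] >= ambiguity || length(sh) == 1L) names(sh)[1] else
      names(sh)[1:2]
    out[[i]] <- data.frame(segment_id = rows$segment_id[i], class = cls,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
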