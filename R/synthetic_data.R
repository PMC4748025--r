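# Synthetic multilevel society and its observation process.
#
# The generator states a world: a gang of a few parties, each party a handful
# of one-male units (1 primary male, 0-2 secondary males, 1-4 adult females),
# plus bachelor males. Females are scan-sampled during 30-min focal follows
# (4 scans at 10-min spacing) and their dyadic interactions recorded; an ad
# libitum stream covers every study day. Default rates are anchored to field
# estimates for Guinea baboons (scan proximity shares, greeting logits by
# reproductive state, 98.6% copulation fidelity to the primary male, male
# shares of approach initiation, grooming bout lengths).

AFFILIATIVE_TYPES <- c("GROOM", "GREET", "COPULATION")

#' Derive a reproducible substream seed
#'
#' Named substreams (society, states, observation, ...) decouple the stages:
#' changing one stage's parameters does not perturb another stage's draws.
#'
#' @param seed integer master seed.
#' @param name substream name.
#' @return an integer seed in `[1, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) %% 65011 + 1) * 32717 + h %% 32717)
}

#' Simulator configuration
#'
#' Builds a validated configuration for [simulate_society()],
#' [simulate_states()] and [simulate_observation()]. Probabilities are
#' per-scan or per-event; rates are per focal hour unless noted. Defaults are
#' the stated world: field-anchored where an estimate exists, otherwise fixed
#' assumptions documented in the methods vignette.
#'
#' @param n_parties number of parties in the gang.
#' @param units_per_party integer range `c(lo, hi)` of units per party.
#' @param females_per_unit integer range of adult females per unit.
#' @param females_per_unit_weights sampling weights over that range; the
#'   default gives a mean of ~1.9 females per unit, matching a gang of ~16
#'   females spread over ~10 units.
#' @param secondary_males_per_unit integer range of secondary males per unit.
#' @param secondary_males_per_unit_weights sampling weights over that range.
#' @param n_bachelors number of unit-less adult males (transfer targets).
#' @param study_days length of the study horizon in days.
#' @param focals_per_female_per_week integer range of 30-min focal follows.
#' @param p2m_primary,p2m_secondary,p2m_other per-scan probability that a male
#'   of that relation to the focal female is inside her 2-m ring.
#' @param p5m_primary,p5m_secondary,p5m_other same for the (2 m, 5 m] annulus.
#' @param greet_logit_by_state named log-odds that a focal sample contains at
#'   least one greeting with the primary male, by reproductive state.
#' @param greet_excess_mean mean extra greetings per greeting-positive focal.
#' @param groom_rate_primary,groom_rate_secondary grooming minutes per focal
#'   hour with the primary male / per secondary male.
#' @param groom_bout_mean_primary,groom_bout_mean_secondary mean bout minutes.
#' @param aggression_rate_per_h,greet_rate_per_h,copulation_rate_per_h event
#'   rates per hour (copulations only while the female is tumescent, C1-C3).
#' @param copulation_fidelity probability the copulation partner is the
#'   female's current primary male.
#' @param approach_rate_primary_per_h,approach_rate_secondary_per_h
#'   approach (and, equally, retreat) event rates per dyad class.
#' @param p_approach_by_male_primary,p_approach_by_male_secondary probability
#'   the male is the approacher in the dyad class.
#' @param p_retreat_by_female_primary,p_retreat_by_female_secondary probability
#'   the female is the retreater.
#' @param supplant_rate_per_h supplant rate with the primary male (excluded
#'   from Hinde-index counts downstream; generated to exercise that rule).
#' @param p_greet_secondary per-focal probability of a greeting with a random
#'   secondary male (keeps ~90% of greetings with the primary male).
#' @param infant_handling_rate_per_h rate while the female is lactating.
#' @param p_infant_handling_primary share of handling done by the primary male.
#' @param surreptitious_fraction fraction of secondary-male interactions that
#'   occur out of the primary male's line of sight.
#' @param adlib_hours_per_day effective ad libitum observation hours per day.
#' @param mean_state_days named mean block lengths (days) of the reproductive
#'   state machine L -> C0 -> C1 -> C2 -> C3 -> (cycle | P) -> L.
#' @param mean_cycles mean number of C0-C3 cycles before conception.
#' @param transfer_hazard_per_fortnight probability a female switches primary
#'   male at a fortnight boundary.
#' @param seed master random seed.
#' @return a validated list of class `society_config`.
#' @export
society_config <- function(n_parties = 3,
                           units_per_party = c(3, 4),
                           females_per_unit = c(1, 4),
                           females_per_unit_weights = c(0.45, 0.30, 0.15, 0.10),
                           secondary_males_per_unit = c(0, 2),
                           secondary_males_per_unit_weights = c(0.5, 0.3, 0.2),
                           n_bachelors = 2,
                           study_days = 507,
                           focals_per_female_per_week = c(1, 3),
                           p2m_primary = 0.20, p2m_secondary = 0.02, p2m_other = 0.002,
                           p5m_primary = 0.20, p5m_secondary = 0.08, p5m_other = 0.01,
                           greet_logit_by_state = c(L = -1.442, P = -0.801,
                                                    C0 = -0.672, C1 = -0.501,
                                                    C2 = -0.408, C3 = -0.233),
                           greet_excess_mean = 0.3,
                           groom_rate_primary = 1.26, groom_rate_secondary = 0.16,
                           groom_bout_mean_primary = 3.52, groom_bout_mean_secondary = 2.85,
                           aggression_rate_per_h = 0.10,
                           greet_rate_per_h = 0.85,
                           copulation_rate_per_h = 0.69,
                           copulation_fidelity = 0.986,
                           approach_rate_primary_per_h = 4,
                           approach_rate_secondary_per_h = 1.2,
                           p_approach_by_male_primary = 0.60,
                           p_approach_by_male_secondary = 0.76,
                           p_retreat_by_female_primary = 0.57,
                           p_retreat_by_female_secondary = 0.60,
                           supplant_rate_per_h = 0.2,
                           p_greet_secondary = 0.05,
                           infant_handling_rate_per_h = 0.15,
                           p_infant_handling_primary = 0.59,
                           surreptitious_fraction = 0.39,
                           adlib_hours_per_day = 4.3,
                           mean_state_days = c(L = 180, P = 185, C0 = 20,
                                               C1 = 7, C2 = 5, C3 = 7),
                           mean_cycles = 2,
                           transfer_hazard_per_fortnight = 0.03,
                           seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "society_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  rng <- function(x) length(x) == 2 && x[1] <= x[2] && x[1] >= 0
  if (!rng(cfg$units_per_party) || !rng(cfg$females_per_unit) ||
      !rng(cfg$secondary_males_per_unit) || !rng(cfg$focals_per_female_per_week))
    stop("configuration error: ranges must be c(lo, hi) with 0 <= lo <= hi", call. = FALSE)
  probs <- c(cfg$p2m_primary, cfg$p2m_secondary, cfg$p2m_other,
             cfg$p5m_primary, cfg$p5m_secondary, cfg$p5m_other,
             cfg$copulation_fidelity, cfg$p_approach_by_male_primary,
             cfg$p_approach_by_male_secondary, cfg$p_retreat_by_female_primary,
             cfg$p_retreat_by_female_secondary, cfg$surreptitious_fraction,
             cfg$transfer_hazard_per_fortnight, cfg$p_greet_secondary,
             cfg$p_infant_handling_primary)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
  rates <- c(cfg$groom_rate_primary, cfg$groom_rate_secondary,
             cfg$aggression_rate_per_h, cfg$greet_rate_per_h,
             cfg$copulation_rate_per_h, cfg$approach_rate_primary_per_h,
             cfg$approach_rate_secondary_per_h, cfg$supplant_rate_per_h,
             cfg$infant_handling_rate_per_h, cfg$adlib_hours_per_day)
  if (any(rates < 0)) stop("configuration error: rates must be non-negative", call. = FALSE)
  if (!setequal(names(cfg$greet_logit_by_state), REPRO_STATES))
    stop("configuration error: greet_logit_by_state must name all six states", call. = FALSE)
  if (!setequal(names(cfg$mean_state_days), REPRO_STATES) || any(cfg$mean_state_days < 1))
    stop("configuration error: mean_state_days must name all six states, each >= 1 day", call. = FALSE)
  if (cfg$study_days < 1 || cfg$n_parties < 1 || cfg$mean_cycles < 1)
    stop("configuration error: counts must be positive", call. = FALSE)
  span <- function(r) r[2] - r[1] + 1
  if (length(cfg$females_per_unit_weights) != span(cfg$females_per_unit) ||
      length(cfg$secondary_males_per_unit_weights) != span(cfg$secondary_males_per_unit))
    stop("configuration error: unit-size weights must match their range", call. = FALSE)
  cfg
}

sample_range <- function(rng, n = 1, weights = NULL) {
  if (rng[1] == rng[2]) return(rep(rng[1], n))
  sample(rng[1]:rng[2], n, replace = TRUE, prob = weights)
}

#' Simulate the social structure of a multilevel society
#'
#' Draws a gang of `n_parties` parties, each containing units of one primary
#' male, 0-2 secondary males and 1-4 adult females, plus bachelor males, and a
#' fortnight-resolution transfer schedule. Transfers move a female to a
#' bachelor or another established primary male, never to one of her own
#' secondary males.
#'
#' @param config a [society_config()].
#' @return an object of class `society_truth`: list with `roster`, `unit_of`
#'   (named unit per individual; bachelors hold their own singleton unit),
#'   `party_of` (named party per unit), `primary_segments` (data.frame
#'   `female`, `start_day`, `end_day`, `male`), `transfer_schedule`
#'   (data.frame `female`, `day`, `old_male`, `new_male`, `type`) and `config`.
#' @export
simulate_society <- function(config) {
  config <- validate_config(config)
  set.seed(derive_seed(config$seed, "society"))

  n_units <- sample_range(config$units_per_party, config$n_parties)
  if (sum(n_units) == 0) stop("configuration error: no units", call. = FALSE)
  units <- sprintf("U%02d", seq_len(sum(n_units)))
  party_of_unit <- sprintf("P%d", rep(seq_len(config$n_parties), n_units))
  names(party_of_unit) <- units

  n_sec <- sample_range(config$secondary_males_per_unit, length(units),
                        config$secondary_males_per_unit_weights)
  n_fem <- sample_range(config$females_per_unit, length(units),
                        config$females_per_unit_weights)

  ids <- character(0); sexes <- character(0); ages <- character(0); unit_of <- character(0)
  primary_of_unit <- character(0)
  fi <- 0; mi <- 0
  for (u in seq_along(units)) {
    mi <- mi + 1
    pm <- sprintf("M%02d", mi)
    ids <- c(ids, pm); sexes <- c(sexes, "MALE"); ages <- c(ages, "ADULT")
    unit_of <- c(unit_of, stats::setNames(units[u], pm))
    primary_of_unit[units[u]] <- pm
    if (n_sec[u] > 0) {
      for (s in seq_len(n_sec[u])) {
        mi <- mi + 1
        sm <- sprintf("M%02d", mi)
        ids <- c(ids, sm); sexes <- c(sexes, "MALE")
        ages <- c(ages, sample(c("SUBADULT", "ADULT"), 1, prob = c(0.7, 0.3)))
        unit_of <- c(unit_of, stats::setNames(units[u], sm))
      }
    }
    if (n_fem[u] > 0) {
      for (f in seq_len(n_fem[u])) {
        fi <- fi + 1
        fm <- sprintf("F%02d", fi)
        ids <- c(ids, fm); sexes <- c(sexes, "FEMALE"); ages <- c(ages, "ADULT")
        unit_of <- c(unit_of, stats::setNames(units[u], fm))
      }
    }
  }
  # bachelors: each holds an initially female-less unit in a random party
  if (config$n_bachelors > 0) {
    for (b in seq_len(config$n_bachelors)) {
      mi <- mi + 1
      bm <- sprintf("M%02d", mi)
      bu <- sprintf("B%02d", b)
      ids <- c(ids, bm); sexes <- c(sexes, "MALE"); ages <- c(ages, "ADULT")
      unit_of <- c(unit_of, stats::setNames(bu, bm))
      party_of_unit[bu] <- sprintf("P%d", sample(config$n_parties, 1))
      primary_of_unit[bu] <- bm
    }
  }
  ros <- roster(ids, sexes, ages)
  females <- ros$id[ros$sex == "FEMALE"]
  if (length(females) == 0) stop("configuration error: society has no females", call. = FALSE)

  secondaries_of_unit <- split(
    names(unit_of)[ids %in% names(unit_of) & sexes == "MALE" &
                     !(names(unit_of) %in% primary_of_unit)],
    unit_of[sexes == "MALE" & !(ids %in% primary_of_unit)])

  # fortnight-boundary transfer schedule
  n_fort <- max(0L, (config$study_days - 1L) %/% 14L)
  cur_primary <- vapply(females, function(f) primary_of_unit[[unit_of[[f]]]], character(1))
  segs <- list(); sched <- list()
  seg_start <- stats::setNames(rep(1L, length(females)), females)
  for (ft in seq_len(n_fort)) {
    day <- 14L * ft + 1L
    for (f in females) {
      if (stats::runif(1) >= config$transfer_hazard_per_fortnight) next
      cur <- cur_primary[[f]]
      cur_unit <- names(primary_of_unit)[match(cur, primary_of_unit)]
      forbidden <- c(cur, secondaries_of_unit[[cur_unit]])
      targets <- setdiff(unname(primary_of_unit), forbidden)
      if (length(targets) == 0) next
      new <- sample(targets, 1)
      segs[[length(segs) + 1]] <- data.frame(
        female = f, start_day = seg_start[[f]], end_day = day - 1L, male = cur,
        stringsAsFactors = FALSE)
      sched[[length(sched) + 1]] <- data.frame(
        female = f, day = day, old_male = cur, new_male = new,
        type = transfer_type(cur, new, unit_of, party_of_unit),
        stringsAsFactors = FALSE)
      cur_primary[[f]] <- new
      seg_start[[f]] <- day
    }
  }
  for (f in females) {
    segs[[length(segs) + 1]] <- data.frame(
      female = f, start_day = seg_start[[f]], end_day = as.integer(config$study_days),
      male = cur_primary[[f]], stringsAsFactors = FALSE)
  }
  primary_segments <- do.call(rbind, segs)
  primary_segments <- primary_segments[order(primary_segments$female,
                                             primary_segments$start_day), ]
  rownames(primary_segments) <- NULL
  transfer_schedule <- if (length(sched)) do.call(rbind, sched) else
    data.frame(female = character(0), day = integer(0), old_male = character(0),
               new_male = character(0), type = character(0), stringsAsFactors = FALSE)

  structure(list(roster = ros, unit_of = unit_of, party_of = party_of_unit,
                 primary_of_unit = primary_of_unit,
                 secondaries_of_unit = secondaries_of_unit,
                 primary_segments = primary_segments,
                 transfer_schedule = transfer_schedule,
                 config = config),
            class = "society_truth")
}

#' Classify a transfer by the social level it crosses
#'
#' @param old_male,new_male male ids.
#' @param unit_of named unit per individual.
#' @param party_of named party per unit.
#' @param gang_of optional named gang per party; with a single gang the
#'   `INTER_GANG` class cannot arise.
#' @return one of `"INTRA_PARTY"`, `"INTER_PARTY"`, `"INTER_GANG"`.
#' @export
transfer_type <- function(old_male, new_male, unit_of, party_of, gang_of = NULL) {
  p_old <- party_of[[unit_of[[old_male]]]]
  p_new <- party_of[[unit_of[[new_male]]]]
  if (p_old == p_new) return("INTRA_PARTY")
  if (!is.null(gang_of) && gang_of[[p_old]] != gang_of[[p_new]]) return("INTER_GANG")
  "INTER_PARTY"
}

#' Ground-truth primary male of a female on a given day
#'
#' @param truth a `society_truth`.
#' @param female female id.
#' @param day study day.
#' @return male id.
#' @export
primary_at <- function(truth, female, day) {
  s <- truth$primary_segments
  hit <- s$female == female & s$start_day <= day & s$end_day >= day
  if (!any(hit)) stop(sprintf("no primary segment for %s on day %d", female, day), call. = FALSE)
  s$male[which(hit)[1]]
}

next_state <- function(state, mean_cycles) {
  switch(state,
         L = "C0", C0 = "C1", C1 = "C2", C2 = "C3",
         C3 = if (stats::runif(1) < 1 / mean_cycles) "P" else "C0",
         P = "L")
}

#' Simulate daily reproductive-state series
#'
#' Each female traverses semi-Markov blocks along the cycle
#' L -> C0 -> C1 -> C2 -> C3 -> (back to C0, or conception -> P) -> L, with
#' geometric block durations at the configured means. Initial state and phase
#' are randomised per female.
#'
#' @param truth a `society_truth`.
#' @param config a [society_config()]; defaults to the one inside `truth`.
#' @return states data.frame (`female`, `day`, `state`) covering every study
#'   day for every adult female.
#' @export
simulate_states <- function(truth, config = truth$config) {
  config <- validate_config(config)
  set.seed(derive_seed(config$seed, "states"))
  females <- truth$roster$id[truth$roster$sex == "FEMALE"]
  md <- config$mean_state_days
  out <- vector("list", length(females))
  for (i in seq_along(females)) {
    state <- sample(REPRO_STATES, 1, prob = md[REPRO_STATES])
    days <- character(config$study_days)
    d <- 1L
    while (d <= config$study_days) {
      len <- 1L + stats::rgeom(1, 1 / md[[state]])
      upto <- min(config$study_days, d + len - 1L)
      days[d:upto] <- state
      d <- upto + 1L
      state <- next_state(state, config$mean_cycles)
    }
    out[[i]] <- data.frame(female = females[i], day = seq_len(config$study_days),
                           state = days, stringsAsFactors = FALSE)
  }
  validate_states(do.call(rbind, out), truth$roster)
}

clock_time <- function(start_min, offset_min = 0) {
  m <- start_min + offset_min
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

male_relation <- function(male, primary, secondaries) {
  ifelse(male == primary, "primary",
         ifelse(male %in% secondaries, "secondary", "other"))
}

# Row collector: O(1) amortised appends of typed scalar rows, materialised
# into a data.frame once at the end (rbind of many 1-row frames is quadratic).
new_collector <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- vector("list", 1024L)
  e$n <- 0L
  e
}

collect <- function(col, template) {
  rows <- col$rows[seq_len(col$n)]
  if (length(rows) == 0) return(template)
  out <- lapply(seq_along(template), function(k) {
    v <- vapply(rows, function(r) r[[k]], template[[k]][NA_integer_][1])
    v
  })
  names(out) <- names(template)
  as.data.frame(out, stringsAsFactors = FALSE)
}

emit_event <- function(col, focal_id, type, actor, recipient, day, time,
                       duration_s = NA_real_, surreptitious = FALSE,
                       protocol = "FOCAL") {
  col$n <- col$n + 1L
  if (col$n > length(col$rows)) length(col$rows) <- 2L * length(col$rows)
  col$rows[[col$n]] <- list(as.integer(focal_id), type, actor, recipient,
                            as.integer(day), time, as.numeric(duration_s),
                            surreptitious, protocol)
}

#' Simulate the observation process
#'
#' Generates focal follows (scan samples plus focal behaviour events) and an
#' ad libitum event stream over the whole study horizon. Per focal follow:
#' four scans at 10-min spacing, each candidate male entering the focal
#' female's 2-m ring (else the 5-m annulus) independently with the probability
#' matching his relation to her; approach/retreat/supplant/groom/greet/
#' aggression/copulation events drawn from Poisson counts at the configured
#' rates; greeting occurrence per focal follows the state-dependent logits;
#' copulations occur only while the female is tumescent (C1-C3) and go to the
#' primary male with the configured fidelity. Interactions with non-primary
#' males are flagged surreptitious with the configured probability.
#'
#' @param truth a `society_truth`.
#' @param states daily state series from [simulate_states()].
#' @param config a [society_config()]; defaults to the one inside `truth`.
#' @return list with `focals` (data.frame `focal_id`, `focal_female`, `day`,
#'   `time`, `state`), `scans`, `events` (focal and ad libitum rows combined).
#' @export
simulate_observation <- function(truth, states, config = truth$config) {
  config <- validate_config(config)
  set.seed(derive_seed(config$seed, "observation"))
  ros <- truth$roster
  females <- ros$id[ros$sex == "FEMALE"]
  males <- ros$id[ros$sex == "MALE"]
  state_of <- stats::setNames(states$state, paste(states$female, states$day))

  foc <- new_collector(); scn <- new_collector(); evt <- new_collector()
  fid <- 0L
  n_weeks <- ceiling(config$study_days / 7)
  for (f in females) {
    for (w in seq_len(n_weeks)) {
      n_foc <- sample_range(config$focals_per_female_per_week)
      if (n_foc == 0) next
      wk_days <- (7 * (w - 1) + 1):min(7 * w, config$study_days)
      days <- sample(rep(wk_days, 2), min(n_foc, length(wk_days)))
      for (d in sort(unique(days))) {
        fid <- fid + 1L
        start_min <- sample(c(6:12, 15:18), 1) * 60 + sample(c(0L, 30L), 1)
        st <- state_of[[paste(f, d)]]
        pm <- primary_at(truth, f, d)
        pm_unit <- names(truth$primary_of_unit)[match(pm, truth$primary_of_unit)]
        sec <- truth$secondaries_of_unit[[pm_unit]]
        if (is.null(sec)) sec <- character(0)
        foc$n <- foc$n + 1L
        if (foc$n > length(foc$rows)) length(foc$rows) <- 2L * length(foc$rows)
        foc$rows[[foc$n]] <- list(fid, f, as.integer(d), clock_time(start_min), st)
        rel <- male_relation(males, pm, sec)
        p2 <- c(primary = config$p2m_primary, secondary = config$p2m_secondary,
                other = config$p2m_other)[rel]
        p5 <- c(primary = config$p5m_primary, secondary = config$p5m_secondary,
                other = config$p5m_other)[rel]
        for (s in 0:3) {
          u <- stats::runif(length(males))
          in2 <- u < p2
          in5 <- !in2 & u < p2 + p5
          scn$n <- scn$n + 1L
          if (scn$n > length(scn$rows)) length(scn$rows) <- 2L * length(scn$rows)
          scn$rows[[scn$n]] <- list(fid, f, as.integer(d),
                                    clock_time(start_min, 10 * s),
                                    ring_join(males[in2]), ring_join(males[in5]))
        }
        focal_events(evt, fid, f, d, start_min, st, pm, sec, males, config)
      }
    }
  }
  adlib_events(evt, truth, states, config)
  focals <- collect(foc, data.frame(focal_id = integer(0), focal_female = character(0),
                                    day = integer(0), time = character(0),
                                    state = character(0), stringsAsFactors = FALSE))
  scans <- collect(scn, empty_scans())
  ev <- collect(evt, empty_events())
  ev <- ev[order(ev$day, ev$time, ev$actor, ev$type, method = "radix"), ]
  rownames(ev) <- NULL
  list(focals = focals, scans = validate_scans(scans, ros),
       events = validate_events(ev, ros))
}

# events inside one 30-min focal follow
focal_events <- function(col, fid, f, d, start_min, st, pm, sec, males, config) {
  H <- 0.5
  surrep <- function(partner) {
    partner != pm && stats::runif(1) < config$surreptitious_fraction
  }
  tm <- function() clock_time(start_min, sample(0:29, 1))
  add <- function(type, actor, recipient, duration_s = NA_real_,
                  surreptitious = FALSE) {
    emit_event(col, fid, type, actor, recipient, d, tm(), duration_s,
               surreptitious, "FOCAL")
  }
  dyads_male <- c(pm, sec)
  dyads_rel <- c("primary", rep("secondary", length(sec)))
  for (i in seq_along(dyads_male)) {
    m <- dyads_male[i]; rel <- dyads_rel[i]
    a_rate <- if (rel == "primary") config$approach_rate_primary_per_h else config$approach_rate_secondary_per_h
    p_male <- if (rel == "primary") config$p_approach_by_male_primary else config$p_approach_by_male_secondary
    p_fem_r <- if (rel == "primary") config$p_retreat_by_female_primary else config$p_retreat_by_female_secondary
    for (k in seq_len(stats::rpois(1, a_rate * H))) {
      by_male <- stats::runif(1) < p_male
      add("APPROACH", if (by_male) m else f, if (by_male) f else m,
          surreptitious = surrep(m))
    }
    for (k in seq_len(stats::rpois(1, a_rate * H))) {
      by_fem <- stats::runif(1) < p_fem_r
      add("RETREAT", if (by_fem) f else m, if (by_fem) m else f,
          surreptitious = surrep(m))
    }
    g_rate <- if (rel == "primary") config$groom_rate_primary else config$groom_rate_secondary
    g_mean <- if (rel == "primary") config$groom_bout_mean_primary else config$groom_bout_mean_secondary
    for (k in seq_len(stats::rpois(1, g_rate * H / g_mean))) {
      by_fem <- stats::runif(1) < 0.76
      add("GROOM", if (by_fem) f else m, if (by_fem) m else f,
          duration_s = max(1, round(stats::rexp(1, 1 / (g_mean * 60)))),
          surreptitious = surrep(m))
    }
  }
  for (k in seq_len(stats::rpois(1, config$supplant_rate_per_h * H))) {
    by_male <- stats::runif(1) < 0.5
    add("SUPPLANT", if (by_male) pm else f, if (by_male) f else pm)
  }
  # state-dependent greeting occurrence with the primary male
  if (stats::runif(1) < stats::plogis(config$greet_logit_by_state[[st]])) {
    for (k in seq_len(1L + stats::rpois(1, config$greet_excess_mean))) {
      by_male <- stats::runif(1) < 0.5
      add("GREET", if (by_male) pm else f, if (by_male) f else pm)
    }
  }
  if (length(sec) && stats::runif(1) < config$p_greet_secondary) {
    m <- sec[sample.int(length(sec), 1)]
    add("GREET", m, f, surreptitious = surrep(m))
  }
  for (k in seq_len(stats::rpois(1, config$aggression_rate_per_h * H))) {
    m <- if (length(sec) && stats::runif(1) > 0.8) sec[sample.int(length(sec), 1)] else pm
    by_male <- stats::runif(1) < 0.8
    add("AGGRESSION", if (by_male) m else f, if (by_male) f else m,
        surreptitious = surrep(m))
  }
  if (st %in% c("C1", "C2", "C3")) {
    for (k in seq_len(stats::rpois(1, config$copulation_rate_per_h * H))) {
      others <- setdiff(males, pm)
      m <- if (stats::runif(1) < config$copulation_fidelity) pm else
        others[sample.int(length(others), 1)]
      add("COPULATION", m, f, surreptitious = surrep(m))
    }
  }
  if (st == "L") {
    for (k in seq_len(stats::rpois(1, config$infant_handling_rate_per_h * H))) {
      m <- if (stats::runif(1) < config$p_infant_handling_primary || !length(sec)) pm
      else sec[sample.int(length(sec), 1)]
      add("INFANT_HANDLING", m, f, surreptitious = surrep(m))
    }
  }
  invisible(col)
}

# daily ad libitum stream covering every study day
adlib_events <- function(col, truth, states, config) {
  females <- truth$roster$id[truth$roster$sex == "FEMALE"]
  males <- truth$roster$id[truth$roster$sex == "MALE"]
  state_of <- stats::setNames(states$state, paste(states$female, states$day))
  H <- config$adlib_hours_per_day
  tm <- function() clock_time(sample(c(6:12, 15:18), 1) * 60, sample(0:59, 1))
  for (f in females) {
    seg <- truth$primary_segments[truth$primary_segments$female == f, ]
    pm_day <- character(config$study_days)
    for (i in seq_len(nrow(seg))) pm_day[seg$start_day[i]:seg$end_day[i]] <- seg$male[i]
    for (d in seq_len(config$study_days)) {
      pm <- pm_day[d]
      pm_unit <- names(truth$primary_of_unit)[match(pm, truth$primary_of_unit)]
      sec <- truth$secondaries_of_unit[[pm_unit]]
      if (is.null(sec)) sec <- character(0)
      st <- state_of[[paste(f, d)]]
      partner <- function(p_primary) {
        if (stats::runif(1) < p_primary || !length(sec)) pm else
          sec[sample.int(length(sec), 1)]
      }
      surrep <- function(m) m != pm && stats::runif(1) < config$surreptitious_fraction
      for (k in seq_len(stats::rpois(1, config$greet_rate_per_h * H))) {
        m <- partner(0.9)
        by_male <- stats::runif(1) < 0.5
        emit_event(col, NA_integer_, "GREET", if (by_male) m else f,
                   if (by_male) f else m, d, tm(), surreptitious = surrep(m),
                   protocol = "AD_LIBITUM")
      }
      for (k in seq_len(stats::rpois(1, config$groom_rate_primary * H /
                                       config$groom_bout_mean_primary))) {
        m <- partner(0.9)
        emit_event(col, NA_integer_, "GROOM", f, m, d, tm(),
                   duration_s = max(1, round(stats::rexp(1, 1 / (config$groom_bout_mean_primary * 60)))),
                   surreptitious = surrep(m), protocol = "AD_LIBITUM")
      }
      for (k in seq_len(stats::rpois(1, config$aggression_rate_per_h * H))) {
        m <- partner(0.8)
        emit_event(col, NA_integer_, "AGGRESSION", m, f, d, tm(),
                   surreptitious = surrep(m), protocol = "AD_LIBITUM")
      }
      if (st %in% c("C1", "C2", "C3")) {
        for (k in seq_len(stats::rpois(1, config$copulation_rate_per_h * H))) {
          others <- setdiff(males, pm)
          m <- if (stats::runif(1) < config$copulation_fidelity) pm else
            others[sample.int(length(others), 1)]
          emit_event(col, NA_integer_, "COPULATION", m, f, d, tm(),
                     surreptitious = surrep(m), protocol = "AD_LIBITUM")
        }
      }
    }
  }
  invisible(col)
}
#' Run the full simulator: society, states, observation
#'
#' @param config a [society_config()].
#' @return list with `truth`, `states`, `focals`, `scans`, `events`.
#' @export
simulate_study <- function(config = society_config()) {
  truth <- simulate_society(config)
  states <- simulate_states(truth, config)
  obs <- simulate_observation(truth, states, config)
  c(list(truth = truth, states = states), obs)
}
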