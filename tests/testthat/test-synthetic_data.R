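test_that("config validation rejects bad probabilities, ranges and rates", {
  expect_s3_class(society_config(), "society_config")
  expect_error(society_config(p2m_primary = 1.2), "probabilities")
  expect_error(society_config(units_per_party = c(4, 2)), "ranges")
  expect_error(society_config(greet_rate_per_h = -1), "rates")
  expect_error(society_config(mean_state_days = c(L = 10)), "six states")
  expect_error(society_config(females_per_unit_weights = c(1, 1)), "weights")
})

test_that("simulate_society: structure, determinism, no-transfer limit", {
  cfg <- society_config(seed = 3)
  tr <- simulate_society(cfg)
  ros <- tr$roster
  units <- setdiff(unique(tr$unit_of), grep("^B", unique(tr$unit_of), value = TRUE))
  expect_equal(length(unique(tr$party_of[units])), 3)
  # every real unit: exactly 1 primary male, 1-4 females, 0-2 secondaries
  for (u in units) {
    members <- names(tr$unit_of)[tr$unit_of == u]
    sex <- ros$sex[match(members, ros$id)]
    expect_equal(sum(members %in% tr$primary_of_unit), 1)
    expect_gte(sum(sex == "FEMALE"), 1)
    expect_lte(sum(sex == "FEMALE"), 4)
    expect_lte(sum(sex == "MALE") - 1, 2)
  }
  # piecewise-constant primary assignment tiles the horizon
  for (f in ros$id[ros$sex == "FEMALE"]) {
    seg <- tr$primary_segments[tr$primary_segments$female == f, ]
    expect_equal(seg$start_day[1], 1)
    expect_equal(seg$end_day[nrow(seg)], cfg$study_days)
    if (nrow(seg) > 1) expect_equal(seg$start_day[-1], seg$end_day[-nrow(seg)] + 1)
  }
  # transfers never go to one of the female's own secondary males
  sched <- tr$transfer_schedule
  if (nrow(sched)) {
    for (i in seq_len(nrow(sched))) {
      old_unit <- tr$unit_of[[sched$old_male[i]]]
      expect_false(sched$new_male[i] %in% tr$secondaries_of_unit[[old_unit]])
      expect_true(sched$new_male[i] %in% tr$primary_of_unit)
    }
  }
  expect_identical(simulate_society(cfg), tr)   # determinism
  # no-transfer limit
  tr0 <- simulate_society(society_config(seed = 3, transfer_hazard_per_fortnight = 0))
  expect_equal(nrow(tr0$transfer_schedule), 0)
  expect_true(all(table(tr0$primary_segments$female) == 1))
})

test_that("state series follow the cycle structure and cover every day", {
  sim <- shared_sim()
  st <- sim$states
  cfg <- sim$truth$config
  females <- unique(st$female)
  expect_equal(nrow(st), length(females) * cfg$study_days)
  allowed <- list(L = c("L", "C0"), C0 = c("C0", "C1"), C1 = c("C1", "C2"),
                  C2 = c("C2", "C3"), C3 = c("C3", "C0", "P"), P = c("P", "L"))
  for (f in females) {
    s <- st$state[st$female == f]
    trans <- unique(data.frame(from = s[-length(s)], to = s[-1]))
    ok <- mapply(function(a, b) b %in% allowed[[a]], trans$from, trans$to)
    expect_true(all(ok), label = sprintf("state transitions for %s legal", f))
  }
})

test_that("equal mean block lengths give ~uniform long-run state frequencies", {
  cfg <- society_config(seed = 9, study_days = 60000, n_parties = 1,
                        units_per_party = c(1, 1), females_per_unit = c(1, 1),
                        females_per_unit_weights = 1,
                        mean_state_days = stats::setNames(rep(10, 6), omusoc:::REPRO_STATES),
                        mean_cycles = 1, transfer_hazard_per_fortnight = 0)
  tr <- simulate_society(cfg)
  st <- simulate_states(tr, cfg)
  freq <- table(st$state) / nrow(st)
  expect_true(all(abs(freq - 1 / 6) < 0.025),
              label = paste("state frequencies", paste(round(freq, 3), collapse = " ")))
})

test_that("degenerate observation probabilities behave as specified", {
  cfg <- society_config(seed = 5, study_days = 21, n_parties = 1,
                        units_per_party = c(2, 2),
                        p2m_primary = 1, p2m_secondary = 0, p2m_other = 0,
                        p5m_primary = 0, p5m_secondary = 0, p5m_other = 0,
                        copulation_fidelity = 1,
                        transfer_hazard_per_fortnight = 0)
  sim <- simulate_study(cfg)
  prim <- true_primaries_at(sim, 1)
  expect_true(all(sim$scans$males_2m == prim[sim$scans$focal_female]))
  expect_true(all(sim$scans$males_5m == ""))
  cop <- sim$events[sim$events$type == "COPULATION", ]
  if (nrow(cop)) expect_true(all(cop$actor == prim[cop$recipient]))
})

test_that("focal structure: four scans at 10-min spacing, first at start", {
  sim <- shared_sim()
  sc <- split(sim$scans, sim$scans$focal_id)
  expect_true(all(vapply(sc, nrow, integer(1)) == 4))
  foc <- sim$focals
  one <- sc[[as.character(foc$focal_id[1])]]
  mins <- as.integer(substr(one$time, 1, 2)) * 60 + as.integer(substr(one$time, 4, 5))
  expect_equal(diff(sort(mins)), c(10, 10, 10))
  expect_equal(sort(mins)[1],
               as.integer(substr(foc$time[1], 1, 2)) * 60 +
                 as.integer(substr(foc$time[1], 4, 5)))
})

test_that("generative consistency: scan and event frequencies match config", {
  sim <- shared_sim()
  cfg <- sim$truth$config
  # per-scan 2-m frequency of the current primary male
  prim <- mapply(function(f, d) primary_at(sim$truth, f, d),
                 sim$scans$focal_female, sim$scans$day)
  in2 <- mapply(function(p, ring) p %in% ring_split(ring)[[1]],
                prim, sim$scans$males_2m)
  n <- length(in2)
  se <- sqrt(cfg$p2m_primary * (1 - cfg$p2m_primary) / n)
  expect_lt(abs(mean(in2) - cfg$p2m_primary), 3 * se)

  # copulation partner fidelity
  cop <- sim$events[sim$events$type == "COPULATION", ]
  with_prim <- mapply(function(m, f, d) m == primary_at(sim$truth, f, d),
                      cop$actor, cop$recipient, cop$day)
  se_c <- sqrt(cfg$copulation_fidelity * (1 - cfg$copulation_fidelity) / nrow(cop))
  expect_lt(abs(mean(with_prim) - cfg$copulation_fidelity), 3 * se_c)

  # state-dependent greeting occurrence in focals: lactating intercept
  foc <- sim$focals
  ev <- sim$events
  prim_f <- mapply(function(f, d) primary_at(sim$truth, f, d),
                   foc$focal_female, foc$day)
  males <- sim$truth$roster$id[sim$truth$roster$sex == "MALE"]
  gf <- ev[ev$type == "GREET" & !is.na(ev$focal_id), ]
  partner <- ifelse(gf$actor %in% males, gf$actor, gf$recipient)
  prim_by_fid <- stats::setNames(prim_f, foc$focal_id)
  greet_fid <- unique(gf$focal_id[partner == prim_by_fid[as.character(gf$focal_id)]])
  has_greet <- foc$focal_id %in% greet_fid
  lact <- foc$state == "L"
  p_hat <- mean(has_greet[lact])
  p_exp <- stats::plogis(cfg$greet_logit_by_state[["L"]])  # 0.1911
  se_g <- sqrt(p_exp * (1 - p_exp) / sum(lact))
  expect_lt(abs(p_hat - p_exp), 3 * se_g)
})

test_that("simulator is deterministic given config and seed", {
  cfg <- society_config(seed = 8, study_days = 28)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$scans, s2$scans)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$states, s2$states)
})
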