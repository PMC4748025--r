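test_that("status assignment: argmax primary, secondaries, unaffiliated", {
  ros <- tiny_roster()
  scans <- rbind(
    scan_row("F01", 1, males_2m = "M01"), scan_row("F01", 2, males_2m = "M01"),
    scan_row("F01", 3, males_2m = "M01;M02"), scan_row("F01", 4, males_2m = "M01"),
    scan_row("F01", 5, males_2m = "M01"), scan_row("F01", 6, males_2m = "M02"),
    scan_row("F02", 1, males_2m = "M02"))
  asg <- assign_status(scans, ros)
  st <- asg$statuses
  r1 <- st[st$female == "F01", ]
  expect_equal(r1$primary, "M01")   # counts {M01: 5, M02: 2}
  expect_equal(r1$secondaries, "M02")
  # M03 never within 2 m of any female -> unaffiliated, per window and study
  expect_true("M03" %in% ring_split(asg$unaffiliated$males[1])[[1]])
  expect_equal(asg$study_unaffiliated, "M03")
  expect_equal(status_of(asg, "F01", "M01", 3), "primary")
  expect_equal(status_of(asg, "F01", "M02", 3), "secondary")
  expect_equal(status_of(asg, "F01", "M03", 3), "unaffiliated")
  expect_equal(status_of(asg, "F02", "M01", 3), "other")
})

test_that("tie cascade: 5-m count, carry-over, lexicographic — all flagged", {
  ros <- tiny_roster()
  # window 1: tie M01/M02 at 2 m, M02 ahead at 5 m -> M02 by five_m rule
  w1 <- rbind(scan_row("F01", 1, males_2m = "M01"),
              scan_row("F01", 2, males_2m = "M02", males_5m = ""),
              scan_row("F01", 3, males_5m = "M02"))
  # window 2: tie again, equal 5-m -> carry-over of M02
  w2 <- rbind(scan_row("F01", 15, males_2m = "M01"),
              scan_row("F01", 16, males_2m = "M02"))
  # window 3: no 2-m data at all -> carried_over flag
  w3 <- scan_row("F01", 29, males_5m = "M01")
  asg <- suppressWarnings(assign_status(rbind(w1, w2, w3), ros))
  st <- asg$statuses[asg$statuses$female == "F01", ]
  expect_equal(st$primary, c("M02", "M02", "M02"))
  expect_equal(st$tie_break, c("five_m", "carry_over", ""))
  expect_equal(st$carried_over, c(FALSE, FALSE, TRUE))
  # fresh tie with no history: lexicographic
  asg2 <- suppressWarnings(assign_status(rbind(scan_row("F01", 1, males_2m = "M02"),
                                               scan_row("F01", 2, males_2m = "M01")),
                                         ros))
  expect_equal(asg2$statuses$primary, "M01")
  expect_equal(asg2$statuses$tie_break, "lexicographic")
})

test_that("window invariance: duplicated fortnight gives identical primaries", {
  sim <- shared_sim()
  w1 <- sim$scans[sim$scans$day <= 14, ]
  shifted <- w1
  shifted$day <- shifted$day + 14L
  a_one <- suppressWarnings(assign_status(w1, sim$truth$roster))
  a_two <- suppressWarnings(assign_status(rbind(w1, shifted), sim$truth$roster))
  m1 <- a_one$statuses[a_one$statuses$window == 1, c("female", "primary")]
  m2a <- a_two$statuses[a_two$statuses$window == 1, c("female", "primary")]
  m2b <- a_two$statuses[a_two$statuses$window == 2, c("female", "primary")]
  rownames(m1) <- rownames(m2a) <- rownames(m2b) <- NULL
  expect_identical(m2a, m1)
  expect_identical(m2b, m1)
})

test_that("preference test: degenerate and contrasting count matrices", {
  # always with male A, never others -> A preferred
  mat <- cbind(A = c(8, 9, 10, 8, 9, 10, 9, 8), B = 0, C = 0)
  pr <- preference_test(mat)
  expect_equal(pr$preferred, "A")
  # identical counts -> exchangeable, no preference
  mat0 <- matrix(3, nrow = 5, ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_true(is.na(preference_test(mat0)$preferred))
  # all-zero matrix is a valid no-preference result, not an error
  expect_true(is.na(preference_test(matrix(0, 4, 3))$preferred))
})

test_that("status recovery improves with the 2-m contrast and is high at default", {
  sim <- shared_sim()
  asg <- shared_assignment()
  st <- asg$statuses
  truth_pm <- mapply(function(f, w)
    primary_at(sim$truth, f, min((w - 1) * 14 + 7, sim$truth$config$study_days)),
    st$female, st$window)
  expect_gte(mean(st$primary == truth_pm), 0.90)

  # monotone non-decreasing accuracy in the primary/secondary contrast
  acc <- vapply(c(0.03, 0.08, 0.20), function(p2m) {
    cfg <- society_config(seed = 21, study_days = 28, p2m_primary = p2m,
                          focals_per_female_per_week = c(1, 1),
                          transfer_hazard_per_fortnight = 0)
    s <- simulate_study(cfg)
    a <- suppressWarnings(assign_status(s$scans, s$truth$roster))
    tp <- mapply(function(f, w) primary_at(s$truth, f, 1), a$statuses$female,
                 a$statuses$window)
    mean(a$statuses$primary == tp)
  }, numeric(1))
  expect_true(all(diff(acc) >= -1e-9),
              label = paste("accuracies", paste(round(acc, 3), collapse = " ")))
})

test_that("behaviour occurrence table scores focals per male and behaviour", {
  ros <- tiny_roster()
  focals <- data.frame(focal_id = 1:2, focal_female = "F01", day = c(1, 2),
                       time = "08:00", state = c("L", "C3"), stringsAsFactors = FALSE)
  events <- rbind(
    event_rows("GROOM", "F01", "M01", day = 1, duration_s = 60, focal_id = 1L),
    event_rows("GREET", "M02", "F01", day = 1, focal_id = 1L))
  asg <- suppressWarnings(assign_status(rbind(scan_row("F01", 1, males_2m = "M01"),
                                              scan_row("F01", 2, males_2m = "M01;M02")),
                                        ros))
  occ <- behaviour_occurrence_table(focals, events, asg, ros)
  expect_equal(nrow(occ), 2 * 3 * 4)   # focals x males x behaviours
  hit <- occ[occ$occurred == 1, ]
  expect_setequal(paste(hit$focal_id, hit$male, hit$behaviour),
                  c("1 M01 GROOM", "1 M02 GREET"))
  expect_true(all(occ$occurred[occ$focal_id == 2] == 0))  # empty focal
  expect_equal(unique(occ$male_status[occ$male == "M01"]), "primary")
  expect_equal(unique(occ$male_status[occ$male == "M03"]), "unaffiliated")
})

test_that("occurrence direction on simulated data: primary > secondary >= unaffiliated", {
  sim <- shared_sim()
  asg <- shared_assignment()
  occ <- behaviour_occurrence_table(sim$focals, sim$events, asg, sim$truth$roster,
                                    behaviours = "GROOM")
  by_status <- tapply(occ$occurred, occ$male_status, mean)
  expect_gt(by_status[["primary"]], by_status[["secondary"]])
  expect_gte(by_status[["secondary"]], by_status[["unaffiliated"]])
})
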