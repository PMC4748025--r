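# Shared fixtures, built in code. The mid-sized simulated study is generated
# once per session and reused across test files.

tiny_roster <- function() {
  roster(c("F01", "F02", "M01", "M02", "M03"),
         c("FEMALE", "FEMALE", "MALE", "MALE", "MALE"),
         c("ADULT", "ADULT", "ADULT", "ADULT", "SUBADULT"))
}

scan_row <- function(female, day, males_2m = "", males_5m = "", time = "08:00",
                     focal_id = NA_integer_) {
  data.frame(focal_id = focal_id, focal_female = female, day = day, time = time,
             males_2m = males_2m, males_5m = males_5m, stringsAsFactors = FALSE)
}

event_rows <- function(type, actor, recipient, day = 1, time = "08:00",
                       duration_s = NA_real_, surreptitious = FALSE,
                       protocol = "FOCAL", focal_id = NA_integer_) {
  if (length(actor) == 0 || length(recipient) == 0 || length(day) == 0) {
    return(omusoc:::empty_events())
  }
  data.frame(focal_id = focal_id, type = type, actor = actor,
             recipient = recipient, day = day, time = time,
             duration_s = duration_s, surreptitious = surreptitious,
             protocol = protocol, stringsAsFactors = FALSE)
}

# n approach/retreat interactions of a dyad with given female shares
dyad_stream <- function(female, male, n_app, n_app_by_female, n_ret,
                        n_ret_by_female) {
  rbind(
    event_rows("APPROACH",
               c(rep(female, n_app_by_female), rep(male, n_app - n_app_by_female)),
               c(rep(male, n_app_by_female), rep(female, n_app - n_app_by_female))),
    event_rows("RETREAT",
               c(rep(female, n_ret_by_female), rep(male, n_ret - n_ret_by_female)),
               c(rep(male, n_ret_by_female), rep(female, n_ret - n_ret_by_female))))
}

.sim_cache <- new.env(parent = emptyenv())

# 120-day study at default rates: large enough for recovery statistics,
# small enough to keep the suite inside its budget
shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_study(society_config(study_days = 120, seed = 42))
  }
  .sim_cache$sim
}

shared_assignment <- function() {
  if (is.null(.sim_cache$asg)) {
    sim <- shared_sim()
    .sim_cache$asg <- assign_status(sim$scans, sim$truth$roster)
  }
  .sim_cache$asg
}

true_primaries_at <- function(sim, day) {
  females <- sim$truth$roster$id[sim$truth$roster$sex == "FEMALE"]
  vapply(females, function(f) primary_at(sim$truth, f, day), character(1))
}
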