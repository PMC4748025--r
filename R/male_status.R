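# Per-female, per-fortnight classification of males as primary / secondary /
# unaffiliated, the Friedman/Nemenyi preference test, and the model-ready
# behaviour-occurrence table handed off to external mixed-model fitting.

#' Fortnight index of a study day
#'
#' Non-overlapping 14-day windows anchored at study day 1.
#'
#' @param day integer study day(s).
#' @param window_days window length in days.
#' @return integer window index, starting at 1.
#' @export
fortnight_index <- function(day, window_days = 14) {
  (as.integer(day) - 1L) %/% as.integer(window_days) + 1L
}

#' Assign male status per female and fortnight window
#'
#' Within each window, 2-m scan co-occurrence counts are pooled per
#' (female, male) dyad. The male recorded most often within 2 m is the
#' female's *primary* male; other males seen within 2 m of her at least once
#' are her *secondary* males; males never within 2 m of any female in the
#' window are globally *unaffiliated*. Ties for the top count are broken by
#' (1) higher 5-m count, (2) carry-over of the previous window's primary,
#' (3) lexicographic id; every tie-break and carry-over is flagged in the
#' output. A female with no 2-m scans in a window carries over her previous
#' primary (flagged); a female with no scans in any window is excluded with a
#' warning.
#'
#' @param scans scan data.frame.
#' @param roster roster data.frame.
#' @param window_days pooling window length (14 = fortnight).
#' @return object of class `status_assignment`: list with `statuses`
#'   (data.frame `window`, `female`, `primary`, `secondaries` (";"-list),
#'   `carried_over`, `tie_break`), `unaffiliated` (data.frame `window`,
#'   `males`), `study_unaffiliated` (character vector: never within 2 m of
#'   any female over the whole span) and `window_days`.
#' @export
assign_status <- function(scans, roster, window_days = 14) {
  scans <- validate_scans(scans, roster)
  females <- sort(unique(scans$focal_female))
  excluded <- setdiff(roster$id[roster$sex == "FEMALE"], females)
  if (length(excluded)) {
    warning(sprintf("female(s) with no scans excluded: %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
  }
  males <- roster$id[roster$sex == "MALE"]
  scans$window <- fortnight_index(scans$day, window_days)
  windows <- sort(unique(scans$window))

  count_ring <- function(rows, col) {
    ids <- ring_split(rows[[col]])
    n <- lengths(ids)
    if (sum(n) == 0) return(stats::setNames(integer(0), character(0)))
    tab <- table(data.frame(female = rep(rows$focal_female, n), male = unlist(ids)))
    tab
  }

  prev_primary <- stats::setNames(rep(NA_character_, length(females)), females)
  st_rows <- list(); un_rows <- list()
  for (w in windows) {
    rows <- scans[scans$window == w, ]
    t2 <- count_ring(rows, "males_2m")
    t5 <- count_ring(rows, "males_5m")
    seen_2m <- if (length(t2)) colnames(t2)[colSums(t2) > 0] else character(0)
    un_rows[[length(un_rows) + 1]] <- data.frame(
      window = w, males = ring_join(setdiff(males, seen_2m)), stringsAsFactors = FALSE)
    for (f in females) {
      c2 <- if (length(t2) && f %in% rownames(t2)) {
        stats::setNames(as.integer(t2[f, , drop = FALSE]), colnames(t2))
      } else integer(0)
      c2 <- c2[c2 > 0]
      tie <- ""; carried <- FALSE
      if (length(c2) == 0) {
        primary <- prev_primary[[f]]
        carried <- TRUE
        secondaries <- character(0)
      } else {
        top <- names(c2)[c2 == max(c2)]
        if (length(top) > 1) {
          c5 <- vapply(top, function(m) {
            if (length(t5) && f %in% rownames(t5) && m %in% colnames(t5)) t5[f, m] else 0L
          }, numeric(1))
          top2 <- top[c5 == max(c5)]
          if (length(top2) == 1) {
            tie <- "five_m"
          } else if (!is.na(prev_primary[[f]]) && prev_primary[[f]] %in% top2) {
            top2 <- prev_primary[[f]]
            tie <- "carry_over"
          } else {
            top2 <- sort(top2, method = "radix")[1]
            tie <- "lexicographic"
          }
          primary <- top2[1]
        } else {
          primary <- top
        }
        secondaries <- setdiff(names(c2), primary)
      }
      st_rows[[length(st_rows) + 1]] <- data.frame(
        window = w, female = f, primary = primary,
        secondaries = ring_join(secondaries), carried_over = carried,
        tie_break = tie, stringsAsFactors = FALSE)
      if (!is.na(primary)) prev_primary[[f]] <- primary
    }
  }
  statuses <- do.call(rbind, st_rows)
  # drop leading windows where a female had no 2-m data and nothing to carry
  statuses <- statuses[!is.na(statuses$primary), ]
  rownames(statuses) <- NULL
  unaff <- do.call(rbind, un_rows)
  seen_2m_all <- unique(unlist(ring_split(scans$males_2m)))
  structure(list(statuses = statuses, unaffiliated = unaff,
                 study_unaffiliated = setdiff(males, seen_2m_all),
                 window_days = window_days),
            class = "status_assignment")
}

#' Status of a male relative to a female on a given day
#'
#' @param assignment a [assign_status()] result.
#' @param female,male ids.
#' @param day study day (mapped to its window).
#' @return `"primary"`, `"secondary"`, `"unaffiliated"` (never within 2 m of
#'   any female in that window) or `"other"`.
#' @export
status_of <- function(assignment, female, male, day) {
  w <- fortnight_index(day, assignment$window_days)
  row <- assignment$statuses[assignment$statuses$window == w &
                               assignment$statuses$female == female, ]
  if (nrow(row)) {
    if (male == row$primary[1]) return("primary")
    if (male %in% ring_split(row$secondaries[1])[[1]]) return("secondary")
  }
  un <- assignment$unaffiliated
  urow <- un[un$window == w, ]
  if (nrow(urow) && male %in% ring_split(urow$males[1])[[1]]) return("unaffiliated")
  "other"
}

#' Friedman/Nemenyi preference test for a female's male associates
#'
#' Blocks are pooling windows, treatments are males, entries are 2-m scan
#' counts. A *preferred associate* is declared when the top-ranked male's mean
#' rank differs significantly (Nemenyi, level `alpha`) from every other
#' male's.
#'
#' @param counts N-blocks x k-males count matrix (column names = male ids).
#' @param alpha significance level.
#' @return list with `preferred` (male id or `NA`), `friedman`
#'   ([friedman_test()] result), `nemenyi` ([nemenyi()] result) and
#'   `mean_ranks`.
#' @export
preference_test <- function(counts, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (all(counts == counts[1])) {
    # exchangeable table: no information, no preference
    fr <- friedman_test(counts)
    return(list(preferred = NA_character_, friedman = fr,
                nemenyi = nemenyi(fr, alpha), mean_ranks = fr$mean_ranks))
  }
  fr <- friedman_test(counts)
  nm <- nemenyi(fr, alpha)
  top <- which.max(fr$mean_ranks)
  sig_vs_all <- all(nm$significant[top, -top])
  preferred <- if (sig_vs_all) colnames(counts)[top] else NA_character_
  list(preferred = preferred, friedman = fr, nemenyi = nm,
       mean_ranks = fr$mean_ranks)
}

#' Per-female male-by-window scan-count matrix
#'
#' @param scans scan data.frame.
#' @param female female id.
#' @param males male ids (columns).
#' @param radius `"two_m"` or `"five_m"` (cumulative).
#' @param window_days pooling window length.
#' @return N x k integer matrix of co-occurrence counts.
#' @export
scan_count_matrix <- function(scans, female, males, radius = c("two_m", "five_m"),
                              window_days = 14) {
  radius <- match.arg(radius)
  scans <- scans[scans$focal_female == female, ]
  windows <- sort(unique(fortnight_index(scans$day, window_days)))
  mat <- matrix(0L, nrow = length(windows), ncol = length(males),
                dimnames = list(windows, males))
  ids <- ring_split(scans$males_2m)
  if (radius == "five_m") {
    ids <- mapply(function(a, b) unique(c(a, b)), ids, ring_split(scans$males_5m),
                  SIMPLIFY = FALSE)
  }
  w <- fortnight_index(scans$day, window_days)
  for (i in seq_along(ids)) {
    hit <- intersect(ids[[i]], males)
    if (length(hit)) {
      wi <- as.character(w[i])
      mat[wi, hit] <- mat[wi, hit] + 1L
    }
  }
  mat
}

#' Model-ready behaviour-occurrence table
#'
#' One row per (focal sample, male, behaviour class): did the behaviour occur
#' between the focal female and that male during that 30-min follow? The
#' table carries the male's status relative to the focal female in the
#' sample's window and the female's reproductive state, and is the hand-off
#' artifact for external mixed-model fitting (no fitting is done here).
#'
#' @param focals focal-sample data.frame (`focal_id`, `focal_female`, `day`,
#'   `time`, `state`).
#' @param events event data.frame; only `protocol == "FOCAL"` rows with a
#'   matching `focal_id` are scored.
#' @param assignment a [assign_status()] result.
#' @param roster roster data.frame (defines the candidate male set).
#' @param behaviours behaviour classes to score.
#' @return long-format data.frame (`focal_id`, `female`, `male`,
#'   `male_status`, `behaviour`, `occurred`, `state`, `in_window`). Rows from
#'   focal samples outside any status window are flagged `in_window = FALSE`.
#' @export
behaviour_occurrence_table <- function(focals, events, assignment, roster,
                                       behaviours = c("GROOM", "GREET",
                                                      "AGGRESSION",
                                                      "INFANT_HANDLING")) {
  males <- roster$id[roster$sex == "MALE"]
  ev <- events[events$protocol == "FOCAL" & !is.na(events$focal_id) &
                 events$type %in% behaviours, ]
  key <- paste(ev$focal_id, ifelse(ev$actor %in% males, ev$actor, ev$recipient),
               ev$type)
  occurred_key <- unique(key)
  covered <- unique(assignment$statuses$window)
  out <- vector("list", nrow(focals))
  for (i in seq_len(nrow(focals))) {
    fid <- focals$focal_id[i]
    f <- focals$focal_female[i]
    d <- focals$day[i]
    w <- fortnight_index(d, assignment$window_days)
    stats_row <- vapply(males, function(m) status_of(assignment, f, m, d), character(1))
    grid <- expand.grid(male = males, behaviour = behaviours,
                        stringsAsFactors = FALSE)
    out[[i]] <- data.frame(focal_id = fid, female = f, male = grid$male,
                           male_status = stats_row[grid$male],
                           behaviour = grid$behaviour,
                           occurred = as.integer(paste(fid, grid$male, grid$behaviour)
                                                 %in% occurred_key),
                           state = focals$state[i],
                           in_window = w %in% covered,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
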