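# Observational data model and delimited-text I/O.
#
# All tables are plain data.frames; multi-id ring fields are ";"-separated,
# canonically sorted id lists so that write -> read is the identity.

SEXES <- c("FEMALE", "MALE")
AGE_CLASSES <- c("ADULT", "SUBADULT")
REPRO_STATES <- c("L", "P", "C0", "C1", "C2", "C3")
EVENT_TYPES <- c("APPROACH", "RETREAT", "SUPPLANT", "GROOM", "GREET",
                 "AGGRESSION", "COPULATION", "INFANT_HANDLING")
PROTOCOLS <- c("FOCAL", "AD_LIBITUM")

#' Split a ring field into a character vector of ids
#'
#' Ring fields (`males_2m`, `males_5m`) hold ";"-separated id lists; the empty
#' string is the empty set.
#'
#' @param x character vector of ring fields.
#' @return list of character vectors, one per element of `x`.
#' @export
ring_split <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

#' Join ids into a canonical ring field
#'
#' Ids are sorted (C locale) and ";"-joined so equal sets serialise equally.
#'
#' @param ids character vector of ids (or list of such vectors).
#' @return character scalar (or vector, for a list input).
#' @export
ring_join <- function(ids) {
  if (is.list(ids)) return(vapply(ids, ring_join, character(1)))
  if (length(ids) == 0) return("")
  paste(sort(unique(as.character(ids)), method = "radix"), collapse = ";")
}

stop_schema <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct and validate a roster of individuals
#'
#' @param id character ids, unique.
#' @param sex one of `"FEMALE"`, `"MALE"` per individual.
#' @param age_class one of `"ADULT"`, `"SUBADULT"` per individual.
#' @return a `data.frame` with columns `id`, `sex`, `age_class`.
#' @export
roster <- function(id, sex, age_class) {
  validate_roster(data.frame(id = as.character(id), sex = as.character(sex),
                             age_class = as.character(age_class),
                             stringsAsFactors = FALSE))
}

#' @rdname roster
#' @param x a candidate roster data.frame.
#' @export
validate_roster <- function(x) {
  need <- c("id", "sex", "age_class")
  if (!all(need %in% names(x))) stop_schema("roster must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(x$id)) stop_schema("duplicate id in roster: %s",
                                       paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  if (!all(x$sex %in% SEXES)) stop_schema("unknown sex token: %s",
                                          paste(setdiff(x$sex, SEXES), collapse = ", "))
  if (!all(x$age_class %in% AGE_CLASSES)) stop_schema("unknown age_class token: %s",
                                                      paste(setdiff(x$age_class, AGE_CLASSES), collapse = ", "))
  x
}

#' Validate a scan table against a roster
#'
#' Scans are instantaneous proximity samples on a focal female: the set of
#' males within 2 m and within the (2 m, 5 m] annulus. The two rings are
#' disjoint by construction of the field protocol.
#'
#' @param x scan data.frame with columns `focal_id`, `focal_female`, `day`,
#'   `time`, `males_2m`, `males_5m`.
#' @param roster roster data.frame; all referenced ids must resolve.
#' @return `x`, with ring fields canonicalised.
#' @export
validate_scans <- function(x, roster = NULL) {
  need <- c("focal_female", "day", "time", "males_2m", "males_5m")
  if (!all(need %in% names(x))) stop_schema("scans must have columns %s", paste(need, collapse = ", "))
  if (!"focal_id" %in% names(x)) x$focal_id <- NA_integer_
  x$males_2m[is.na(x$males_2m)] <- ""
  x$males_5m[is.na(x$males_5m)] <- ""
  r2 <- ring_split(x$males_2m)
  r5 <- ring_split(x$males_5m)
  both <- vapply(seq_along(r2),
                 function(i) length(intersect(r2[[i]], r5[[i]])) > 0, logical(1))
  if (any(both)) stop_schema("scan row %d: id present in both the 2-m and 5-m rings",
                             which(both)[1])
  if (!is.null(roster)) {
    validate_roster(roster)
    ids <- unique(c(x$focal_female, unlist(r2), unlist(r5)))
    bad <- setdiff(ids, roster$id)
    if (length(bad)) stop_schema("scan references unknown id(s): %s", paste(bad, collapse = ", "))
    fem <- roster$id[roster$sex == "FEMALE"]
    if (!all(x$focal_female %in% fem)) stop_schema("focal_female must be a female from the roster")
    males <- roster$id[roster$sex == "MALE"]
    ring_ids <- unique(c(unlist(r2), unlist(r5)))
    if (length(setdiff(ring_ids, males))) stop_schema("ring ids must be males from the roster")
  }
  x$males_2m <- ring_join(r2)
  x$males_5m <- ring_join(r5)
  x$day <- as.integer(x$day)
  x
}

#' Validate a behaviour-event table
#'
#' @param x event data.frame with columns `focal_id`, `type`, `actor`,
#'   `recipient`, `day`, `time`, `duration_s`, `surreptitious`, `protocol`.
#' @param roster optional roster for referential-integrity checking.
#' @return `x` with normalised column types.
#' @export
validate_events <- function(x, roster = NULL) {
  need <- c("type", "actor", "recipient", "day", "time", "duration_s",
            "surreptitious", "protocol")
  if (!all(need %in% names(x))) stop_schema("events must have columns %s", paste(need, collapse = ", "))
  if (!"focal_id" %in% names(x)) x$focal_id <- NA_integer_
  if (!all(x$type %in% EVENT_TYPES)) stop_schema("unknown event type: %s",
                                                 paste(setdiff(x$type, EVENT_TYPES), collapse = ", "))
  if (!all(x$protocol %in% PROTOCOLS)) stop_schema("unknown protocol token")
  if (any(x$actor == x$recipient)) stop_schema("event row %d: actor equals recipient",
                                               which(x$actor == x$recipient)[1])
  is_groom <- x$type == "GROOM"
  if (any(is_groom & is.na(x$duration_s))) stop_schema("GROOM events must carry duration_s")
  if (any(!is_groom & !is.na(x$duration_s))) stop_schema("duration_s is only valid for GROOM events")
  if (any(!is.na(x$duration_s) & x$duration_s < 0)) stop_schema("duration_s must be non-negative")
  if (!is.null(roster)) {
    bad <- setdiff(unique(c(x$actor, x$recipient)), roster$id)
    if (length(bad)) stop_schema("event references unknown id(s): %s", paste(bad, collapse = ", "))
  }
  x$day <- as.integer(x$day)
  x$surreptitious <- as.logical(x$surreptitious)
  x
}

#' Validate a daily reproductive-state table
#'
#' States follow the field scoring: `L` lactating, `P` pregnant, `C0`-`C3`
#' the graded swelling scale of a cycling female (`C3` = full swelling).
#'
#' @param x data.frame with columns `female`, `day`, `state`.
#' @param roster optional roster.
#' @return `x` normalised.
#' @export
validate_states <- function(x, roster = NULL) {
  need <- c("female", "day", "state")
  if (!all(need %in% names(x))) stop_schema("states must have columns %s", paste(need, collapse = ", "))
  if (!all(x$state %in% REPRO_STATES)) stop_schema("unknown reproductive state: %s",
                                                   paste(setdiff(x$state, REPRO_STATES), collapse = ", "))
  if (!is.null(roster)) {
    bad <- setdiff(unique(x$female), roster$id)
    if (length(bad)) stop_schema("state references unknown id(s): %s", paste(bad, collapse = ", "))
  }
  x$day <- as.integer(x$day)
  x
}

write_table <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(x, con, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

read_table <- function(path, col_classes) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = col_classes,
                  fileEncoding = "UTF-8")
}

#' Read / write the four record tables
#'
#' Writers emit locale-independent, UTF-8, quoted CSV with a `\n` end-of-line;
#' readers validate schema and referential integrity. `write_*` then `read_*`
#' is the identity on valid collections.
#'
#' @param path file path.
#' @param x the collection to write.
#' @param roster roster used for referential-integrity checks.
#' @return the collection (readers) or `path`, invisibly (writers).
#' @export
read_roster <- function(path) {
  validate_roster(read_table(path, c(id = "character", sex = "character",
                                     age_class = "character")))
}

#' @rdname read_roster
#' @export
write_roster <- function(x, path) write_table(validate_roster(x), path)

#' @rdname read_roster
#' @export
read_scans <- function(path, roster = NULL) {
  x <- read_table(path, c(focal_id = "integer", focal_female = "character",
                          day = "integer", time = "character",
                          males_2m = "character", males_5m = "character"))
  validate_scans(x, roster)
}

#' @rdname read_roster
#' @export
write_scans <- function(x, path, roster = NULL) {
  x <- validate_scans(x, roster)
  write_table(x[, c("focal_id", "focal_female", "day", "time", "males_2m", "males_5m")], path)
}

#' @rdname read_roster
#' @export
read_events <- function(path, roster = NULL) {
  x <- read_table(path, c(focal_id = "integer", type = "character",
                          actor = "character", recipient = "character",
                          day = "integer", time = "character",
                          duration_s = "numeric", surreptitious = "logical",
                          protocol = "character"))
  validate_events(x, roster)
}

#' @rdname read_roster
#' @export
write_events <- function(x, path, roster = NULL) {
  x <- validate_events(x, roster)
  write_table(x[, c("focal_id", "type", "actor", "recipient", "day", "time",
                    "duration_s", "surreptitious", "protocol")], path)
}

#' @rdname read_roster
#' @export
read_states <- function(path, roster = NULL) {
  x <- read_table(path, c(female = "character", day = "integer", state = "character"))
  validate_states(x, roster)
}

#' @rdname read_roster
#' @export
write_states <- function(x, path, roster = NULL) write_table(validate_states(x, roster), path)

empty_scans <- function() {
  data.frame(focal_id = integer(0), focal_female = character(0), day = integer(0),
             time = character(0), males_2m = character(0), males_5m = character(0),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(focal_id = integer(0), type = character(0), actor = character(0),
             recipient = character(0), day = integer(0), time = character(0),
             duration_s = numeric(0), surreptitious = logical(0),
             protocol = character(0), stringsAsFactors = FALSE)
}
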