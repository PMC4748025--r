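# Dyad-level statistics: the Hinde index of relationship maintenance, the
# Friedman average-rank test (with tie correction and, on small tables, an
# exact permutation p-value), the Nemenyi post hoc test, and the male share
# of approach initiation by status class.

#' Hinde index of a female-male dyad
#'
#' `HI = A_f - R_f`, where `A_f` is the proportion of the dyad's approaches
#' performed by the female and `R_f` the proportion of its retreats performed
#' by the female. Supplants are excluded from all counts. Positive values
#' indicate a female-driven relationship (she maintains proximity), negative
#' values a male-driven one. Dyads with fewer than `min_interactions`
#' approach-retreat interactions are excluded, as are dyads where either
#' proportion is undefined (zero approaches or zero retreats in total).
#'
#' @param events event data.frame (any protocol); only APPROACH and RETREAT
#'   rows between the two individuals are used.
#' @param female,male the dyad.
#' @param min_interactions inclusion threshold on approaches + retreats.
#' @return list of class `hinde_result`: `female`, `male`, `hi` (in
#'   `[-1, 1]`, or `NA` when excluded), `included`, `reason` (`""`,
#'   `"below_threshold"` or `"undefined_proportion"`), and the four counts.
#' @export
hinde_index <- function(events, female, male, min_interactions = 10) {
  dy <- events[events$type %in% c("APPROACH", "RETREAT") &
                 ((events$actor == female & events$recipient == male) |
                    (events$actor == male & events$recipient == female)), ]
  app <- dy[dy$type == "APPROACH", ]
  ret <- dy[dy$type == "RETREAT", ]
  counts <- list(approaches_by_female = sum(app$actor == female),
                 approaches_total = nrow(app),
                 retreats_by_female = sum(ret$actor == female),
                 retreats_total = nrow(ret))
  total <- counts$approaches_total + counts$retreats_total
  res <- c(list(female = female, male = male), counts)
  if (total < min_interactions) {
    res <- c(res, list(hi = NA_real_, included = FALSE, reason = "below_threshold"))
  } else if (counts$approaches_total == 0 || counts$retreats_total == 0) {
    res <- c(res, list(hi = NA_real_, included = FALSE, reason = "undefined_proportion"))
  } else {
    hi <- counts$approaches_by_female / counts$approaches_total -
      counts$retreats_by_female / counts$retreats_total
    res <- c(res, list(hi = hi, included = TRUE, reason = ""))
  }
  structure(res, class = "hinde_result")
}

#' Hinde indices for all observed female-male dyads
#'
#' @param events event data.frame.
#' @param roster roster (to orient dyads as female-male).
#' @param assignment optional [assign_status()] result; when given, each dyad
#'   is labelled with the male's modal status across the windows in which the
#'   dyad interacted.
#' @param min_interactions inclusion threshold.
#' @return data.frame, one row per dyad with any approach/retreat record.
#' @export
hinde_table <- function(events, roster, assignment = NULL, min_interactions = 10) {
  females <- roster$id[roster$sex == "FEMALE"]
  males <- roster$id[roster$sex == "MALE"]
  ar <- events[events$type %in% c("APPROACH", "RETREAT"), ]
  f <- ifelse(ar$actor %in% females, ar$actor, ar$recipient)
  m <- ifelse(ar$actor %in% males, ar$actor, ar$recipient)
  dyads <- unique(data.frame(female = f, male = m, stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(dyads)), function(i) {
    h <- hinde_index(events, dyads$female[i], dyads$male[i], min_interactions)
    status <- NA_character_
    if (!is.null(assignment)) {
      days <- ar$day[f == dyads$female[i] & m == dyads$male[i]]
      sts <- vapply(days, function(d) status_of(assignment, dyads$female[i],
                                                dyads$male[i], d), character(1))
      status <- names(sort(table(sts), decreasing = TRUE))[1]
    }
    data.frame(female = h$female, male = h$male, male_status = status,
               hi = h$hi, included = h$included, reason = h$reason,
               n_interactions = h$approaches_total + h$retreats_total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

rank_rows <- function(x) t(apply(x, 1, rank))

friedman_stat <- function(r) {
  n <- nrow(r); k <- ncol(r)
  stat <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
  ties <- sum(apply(r, 1, function(b) {
    t <- table(b)
    sum(t^3 - t)
  }))
  C <- 1 - ties / (n * k * (k^2 - 1))
  if (C <= 0) return(list(stat = 0, C = C))   # all blocks completely tied
  list(stat = stat / C, C = C)
}

#' Friedman average-rank test
#'
#' Nonparametric test for k related treatments over N blocks. Within-block
#' midranks are used for ties; the statistic is
#' `chi2_F = [12N / (k(k+1))] * sum_j (Rbar_j - (k+1)/2)^2` divided by the
#' standard tie-correction factor `1 - sum(t^3 - t) / (N k (k^2 - 1))`. The
#' p-value comes from the chi-square distribution with `k - 1` df, or — on
#' small tables — from the exact permutation distribution over all `(k!)^N`
#' within-block orderings.
#'
#' @param x N x k matrix (blocks x treatments).
#' @param p_method `"auto"` (exact when `(k!)^N <= 5e4`, else chi-square),
#'   `"exact"`, or `"chisq"`.
#' @return list of class `friedman_result`: `statistic`, `df`, `p_value`,
#'   `mean_ranks`, `n_blocks`, `k`, `tie_correction`, `p_method`.
#' @export
friedman_test <- function(x, p_method = c("auto", "exact", "chisq")) {
  p_method <- match.arg(p_method)
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("friedman_test needs N >= 2 blocks and k >= 2 treatments", call. = FALSE)
  if (anyNA(x)) stop("friedman_test: missing entries are not allowed", call. = FALSE)
  r <- rank_rows(x)
  fs <- friedman_stat(r)
  mean_ranks <- colMeans(r)
  names(mean_ranks) <- colnames(x)
  n_perm <- factorial(k)^n
  if (p_method == "auto") p_method <- if (n_perm <= 5e4) "exact" else "chisq"
  if (p_method == "exact") {
    if (n_perm > 5e6) stop("exact permutation p-value infeasible for this table size", call. = FALSE)
    perms <- perm_matrix(k)
    idx <- rep(1L, n)
    count <- 0L; total <- 0L
    repeat {
      rp <- t(vapply(seq_len(n), function(b) r[b, perms[idx[b], ]], numeric(k)))
      sp <- friedman_stat(rp)$stat
      total <- total + 1L
      if (sp >= fs$stat - 1e-12) count <- count + 1L
      j <- 1L
      repeat {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nrow(perms)) break
        idx[j] <- 1L
        j <- j + 1L
        if (j > n) break
      }
      if (j > n) break
    }
    p <- count / total
  } else {
    p <- stats::pchisq(fs$stat, df = k - 1, lower.tail = FALSE)
  }
  structure(list(statistic = fs$stat, df = k - 1, p_value = p,
                 mean_ranks = mean_ranks, n_blocks = n, k = k,
                 tie_correction = fs$C, p_method = p_method),
            class = "friedman_result")
}

# all k! permutations of 1..k, one per row
perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], k, after = pos - 1L)
    }
  }
  out
}

#' Nemenyi post hoc test on mean ranks
#'
#' Pair (i, j) differs significantly when `|Rbar_i - Rbar_j| > CD` with
#' critical difference `CD = q_{alpha,k} / sqrt(2) * sqrt(k(k+1) / (6N))`,
#' `q` the studentized-range quantile with infinite df.
#'
#' @param result a [friedman_test()] result.
#' @param alpha significance level in (0, 1).
#' @return list with `cd`, `diff` (|mean-rank| difference matrix),
#'   `p_values` (studentized-range tail probabilities) and `significant`
#'   (logical matrix, symmetric, `NA` diagonal).
#' @export
nemenyi <- function(result, alpha = 0.05) {
  if (!inherits(result, "friedman_result")) stop("nemenyi expects a friedman_result", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("configuration error: alpha must be in (0, 1)", call. = FALSE)
  k <- result$k; n <- result$n_blocks
  se <- sqrt(k * (k + 1) / (6 * n))
  cd <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2) * se
  d <- abs(outer(result$mean_ranks, result$mean_ranks, "-"))
  p <- stats::ptukey(d / se * sqrt(2), k, Inf, lower.tail = FALSE)
  sig <- d > cd
  diag(sig) <- NA
  list(cd = cd, diff = d, p_values = p, significant = sig, alpha = alpha)
}

#' Male share of approach initiation, by status class
#'
#' For each male-status class, the fraction of the class's approach events
#' initiated by the male. A class with no approaches is reported as `NA`.
#'
#' @param events event data.frame containing APPROACH rows.
#' @param assignment a [assign_status()] result.
#' @param roster roster data.frame.
#' @return named numeric vector over `c("primary", "secondary",
#'   "unaffiliated", "other")` plus attribute `n` (approach counts per class).
#' @export
approach_proportions <- function(events, assignment, roster) {
  classes <- c("primary", "secondary", "unaffiliated", "other")
  ap <- events[events$type == "APPROACH", ]
  out <- stats::setNames(rep(NA_real_, length(classes)), classes)
  n <- stats::setNames(rep(0L, length(classes)), classes)
  if (nrow(ap)) {
    males <- roster$id[roster$sex == "MALE"]
    m <- ifelse(ap$actor %in% males, ap$actor, ap$recipient)
    f <- ifelse(ap$actor %in% males, ap$recipient, ap$actor)
    by_male <- ap$actor %in% males
    cls <- vapply(seq_len(nrow(ap)),
                  function(i) status_of(assignment, f[i], m[i], ap$day[i]),
                  character(1))
    for (cl in classes) {
      sel <- cls == cl
      n[cl] <- sum(sel)
      if (n[cl] > 0) out[cl] <- mean(by_male[sel])
    }
  }
  attr(out, "n") <- n
  out
}
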