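#' Synthesize operant, progressive-ratio and locomotor session logs
#'
#' Generates per-mouse daily operant logs (timestamped correct/incorrect
#' nose pokes with pellet deliveries under a fixed-ratio schedule), one
#' progressive-ratio session, and a locomotor beam-break path, together
#' with the planted ground truth.  For a learner with planted acquisition
#' day `d`, daily accuracy follows a ramp that stays strictly below the
#' 70% criterion before day `d` and is at or above it from day `d`
#' onward (poke counts are adjusted after rounding so the planted day is
#' exact); non-learners stay below criterion on all days.
#'
#' @param n_mice Number of mice.
#' @param learner_fraction Fraction of learners.
#' @param acquisition_days Pool the planted learning day is sampled from.
#' @param n_days Training days (default 14).
#' @param pokes_per_day Mean pokes per daily session.
#' @param fr Fixed-ratio requirement used for pellet events.
#' @param pr_pellet_range Range of pellets earned in the PR session.
#' @param n_path Locomotor path samples.
#' @param seed Integer seed.
#' @return A list with `mice`: per-mouse lists (`daily_logs`, `pr_log`,
#'   `path`), and `ground_truth` (`acquisition_day` with `NA` for
#'   non-learners, `pr_pellets`, `breakpoint`).
#' @export
synth_behavior <- function(n_mice = 8, learner_fraction = 0.75,
                           acquisition_days = 3:10, n_days = 14,
                           pokes_per_day = 100, fr = 5,
                           pr_pellet_range = c(5, 15), n_path = 3600,
                           seed = 1L) {
  if (learner_fraction < 0 || learner_fraction > 1)
    stop("synth_behavior: learner_fraction must lie in [0, 1]")
  set.seed(seed)
  n_learn <- round(learner_fraction * n_mice)
  is_learner <- rep(c(TRUE, FALSE), c(n_learn, n_mice - n_learn))
  acq <- ifelse(is_learner, sample(acquisition_days, n_mice, replace = TRUE),
                NA_integer_)
  mice <- vector("list", n_mice)
  for (m in seq_len(n_mice)) {
    daily <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      target <- if (is_learner[m]) {
        if (d < acq[m]) min(68, 40 + 28 * (d - 1) / max(1, acq[m] - 1))
        else min(95, 70 + 3 * (d - acq[m]))
      } else 40 + 20 * (d - 1) / (n_days - 1)   # plateaus below criterion
      n_pokes <- pokes_per_day + sample(-10:10, 1)
      nc <- round(target / 100 * n_pokes)
      # enforce the planted criterion relation exactly after rounding
      if (target >= 70) nc <- max(nc, ceiling(0.7 * n_pokes))
      else nc <- min(nc, ceiling(0.7 * n_pokes) - 1L)
      ni <- n_pokes - nc
      ev <- data.frame(
        time_s = sort(runif(n_pokes, 0, 10800)),
        event = sample(rep(c("poke_correct", "poke_incorrect"), c(nc, ni))),
        stringsAsFactors = FALSE)
      cum_c <- cumsum(ev$event == "poke_correct")
      pellet_t <- ev$time_s[ev$event == "poke_correct" &
                              cum_c %% fr == 0 & cum_c > 0]
      if (length(pellet_t))
        ev <- rbind(ev, data.frame(time_s = pellet_t + 0.5,
                                   event = "pellet",
                                   stringsAsFactors = FALSE))
      ev <- ev[order(ev$time_s), ]
      rownames(ev) <- NULL
      attr(ev, "day") <- d
      attr(ev, "schedule") <- paste0("FR", fr)
      daily[[d]] <- ev
    }
    n_pr <- sample(pr_pellet_range[1]:pr_pellet_range[2], 1)
    sched <- pr_schedule()
    pr_times <- cumsum(runif(n_pr, 30, 300))
    pokes <- data.frame(
      time_s = sort(runif(sum(sched[seq_len(n_pr)]), 0, max(pr_times))),
      event = "poke_correct", stringsAsFactors = FALSE)
    pr_log <- rbind(pokes,
                    data.frame(time_s = pr_times, event = "pellet",
                               stringsAsFactors = FALSE))
    pr_log <- pr_log[order(pr_log$time_s), ]
    rownames(pr_log) <- NULL
    attr(pr_log, "schedule") <- "PR"
    # locomotor random walk on the 16 x 16 beam grid
    xy <- matrix(8L, n_path, 2)
    steps <- matrix(sample(c(-1L, 0L, 1L), 2 * n_path, replace = TRUE),
                    n_path, 2)
    for (i in 2:n_path)
      xy[i, ] <- pmin(16L, pmax(1L, xy[i - 1, ] + steps[i, ]))
    path <- data.frame(x = xy[, 1], y = xy[, 2])
    mice[[m]] <- list(daily_logs = daily, pr_log = pr_log, path = path,
                      mouse = sprintf("mouse_%02d", m))
  }
  gt <- data.frame(
    mouse = vapply(mice, `[[`, "", "mouse"),
    acquisition_day = acq,
    pr_pellets = vapply(mice, function(m) sum(m$pr_log$event == "pellet"), 0),
    stringsAsFactors = FALSE)
  gt$breakpoint <- vapply(gt$pr_pellets, pr_breakpoint, 0L)
  list(mice = mice, ground_truth = gt)
}
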