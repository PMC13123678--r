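#' Build an assignment-model instance
#'
#' Translates a waiting list, roster and calendar into the day-level
#' assignment model: binary variables x\[p, e, d\] over eligible
#' endoscopists and horizon days, profit `omega1 - omega2 * (d - due)^2`
#' for overdue days (no credit for being early), knapsack capacity per
#' room-day on planned appointment minutes, and at most one appointment
#' per patient. The weights must satisfy
#' `omega1 > omega2 * max_lateness^2`, so that scheduling any patient
#' always improves the objective; a violating `omega2` is scaled down with
#' a warning. Patients with an empty eligible set are excluded with a
#' warning.
#'
#' @param cohort waiting-list data frame; planned minutes are taken from
#'   `appointment_minutes`, or computed as `predicted_minutes + buffer`
#'   when absent.
#' @param roster,calendar provider roster and capacity calendar.
#' @param omega1,omega2 objective weights (throughput vs squared overdue).
#' @param buffer_minutes buffer used when planned minutes must be derived.
#' @return A `mip_instance` list.
#' @export
build_instance <- function(cohort, roster, calendar,
                           omega1 = 1, omega2 = 1e-3,
                           buffer_minutes = DEFAULT_BUFFER_MINUTES) {
  dur <- cohort$appointment_minutes
  if (is.null(dur) || anyNA(dur)) {
    dur <- appointment_duration(cohort$predicted_minutes, "predictive",
                                buffer_minutes = buffer_minutes)
  }
  stopifnot(all(dur > 0))
  days <- sort(unique(calendar$day[calendar$block_minutes > 0]))
  cap <- matrix(0, nrow = nrow(roster), ncol = length(days),
                dimnames = list(roster$id, days))
  inside <- calendar$day %in% days
  cap[cbind(match(calendar$endoscopist_id[inside], roster$id),
            match(calendar$day[inside], days))] <-
    calendar$block_minutes[inside]

  n <- nrow(cohort)
  elig <- vector("list", n)
  for (i in seq_len(n)) {
    elig[[i]] <- match(eligible_endoscopists(cohort[i, , drop = FALSE],
                                             roster), roster$id)
  }
  excluded <- which(lengths(elig) == 0L)
  if (length(excluded)) {
    warning(sprintf("%d patient(s) have no eligible endoscopist and are excluded: %s",
                    length(excluded),
                    paste(cohort$id[excluded], collapse = ", ")),
            call. = FALSE)
  }
  keep <- setdiff(seq_len(n), excluded)
  patients <- data.frame(id = cohort$id[keep], dur = dur[keep],
                         due = cohort$due_date[keep],
                         stringsAsFactors = FALSE)
  max_late <- if (nrow(patients) && length(days)) {
    max(0, max(outer(max(days), patients$due, "-")))
  } else 0
  if (max_late > 0 && omega1 <= omega2 * max_late^2) {
    omega2_new <- 0.9 * omega1 / max_late^2
    warning(sprintf(paste0("omega2 = %g violates the weight condition ",
                           "omega1 > omega2 * max_lateness^2 (max lateness %d); ",
                           "scaled down to %g"),
                    omega2, max_late, omega2_new), call. = FALSE)
    omega2 <- omega2_new
  }
  opts <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    es <- elig[[keep[i]]]
    grid <- expand.grid(e = es, d = seq_along(days), KEEP.OUT.ATTRS = FALSE)
    late <- pmax(0, days[grid$d] - patients$due[i])
    profit <- omega1 - omega2 * late^2
    ord <- order(-profit, grid$d, grid$e)
    opts[[i]] <- list(e = grid$e[ord], d = grid$d[ord],
                      profit = profit[ord])
  }
  structure(list(patients = patients, endoscopists = roster$id, days = days,
                 cap = cap, omega1 = omega1, omega2 = omega2, opts = opts,
                 n_vars = sum(vapply(opts, function(o) length(o$e), integer(1))),
                 excluded_ids = cohort$id[excluded]),
            class = "mip_instance")
}

# objective of an assignment vector (per patient: 0 = unscheduled, else the
# index into that patient's option list)
assignment_objective <- function(instance, assign) {
  s <- 0
  for (i in seq_along(assign)) {
    if (assign[i] > 0L) s <- s + instance$opts[[i]]$profit[assign[i]]
  }
  s
}

assignment_residuals <- function(instance, assign) {
  res <- instance$cap
  for (i in seq_along(assign)) {
    a <- assign[i]
    if (a > 0L) {
      o <- instance$opts[[i]]
      res[o$e[a], o$d[a]] <- res[o$e[a], o$d[a]] - instance$patients$dur[i]
    }
  }
  res
}

# Local improvement: insert unscheduled patients where they fit (best
# profit first), then relocate scheduled patients to strictly more
# profitable (less overdue) room-days; repeat until stable.
improve_assignment <- function(instance, assign) {
  res <- assignment_residuals(instance, assign)
  dur <- instance$patients$dur
  repeat {
    changed <- FALSE
    for (i in order(dur)) {
      o <- instance$opts[[i]]
      cur <- assign[i]
      cur_profit <- if (cur > 0L) o$profit[cur] else -Inf
      for (j in seq_along(o$e)) {
        if (o$profit[j] <= cur_profit) break
        if (res[o$e[j], o$d[j]] >= dur[i] - 1e-9) {
          if (cur > 0L) res[o$e[cur], o$d[cur]] <- res[o$e[cur], o$d[cur]] + dur[i]
          res[o$e[j], o$d[j]] <- res[o$e[j], o$d[j]] - dur[i]
          assign[i] <- j
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  assign
}

#' Solve the assignment model by branch and bound
#'
#' Exact depth-first branch and bound. Patients are branched in decreasing
#' profit-density order; at each node the options of the current patient
#' (plus leaving them unscheduled) are explored best-profit first, with a
#' symmetry reduction that collapses same-day room-days holding equal
#' residual capacity. Nodes are pruned against a fractional-knapsack upper
#' bound computed over pooled residual capacity. The search is exact when
#' it terminates; under a node or time limit it returns the best incumbent
#' with a certified optimality gap, which is the standard contract of
#' branch-and-bound solvers. A warm-start assignment (e.g. a greedy
#' schedule) seeds the incumbent and is first tightened by local
#' improvement.
#'
#' @param instance a [build_instance()] result.
#' @param gap_tol relative optimality gap at which the search may stop.
#' @param time_limit wall-clock seconds before returning the incumbent.
#' @param node_limit maximum number of search nodes.
#' @param warm_start optional `endo_schedule` or assignment data frame with
#'   columns `patient_id`, `endoscopist_id`, `day`.
#' @return A `mip_solution`: `assignments` data frame, `objective`,
#'   `bound`, `gap`, `status` (`"optimal"` or `"limit"`), `n_nodes`.
#' @export
solve_mip <- function(instance, gap_tol = 1e-6, time_limit = Inf,
                      node_limit = Inf, warm_start = NULL) {
  n <- nrow(instance$patients)
  if (n == 0L || instance$n_vars == 0L) {
    return(structure(list(assignments = empty_assignments(),
                          objective = 0, bound = 0, gap = 0,
                          status = "optimal", n_nodes = 0L),
                     class = "mip_solution"))
  }
  dur <- instance$patients$dur
  w_max <- vapply(instance$opts, function(o) o$profit[1L], numeric(1))
  dens <- w_max / dur
  ord <- order(-dens, dur, instance$patients$id)
  # prefix sums over the branching order for the fractional-knapsack bound
  pd <- cumsum(dur[ord])
  pw <- cumsum(w_max[ord])
  suffix_bound <- function(i, pool) {
    if (i > n || pool <= 1e-9) return(0)
    base_d <- if (i == 1L) 0 else pd[i - 1L]
    base_w <- if (i == 1L) 0 else pw[i - 1L]
    # largest j with total duration of ord[i..j] <= pool
    j <- findInterval(base_d + pool + 1e-9, pd)
    b <- (if (j >= i) pw[j] - base_w else 0)
    if (j < n) {
      nxt <- ord[j + 1L]
      used <- if (j >= i) pd[j] - base_d else 0
      b <- b + (pool - used) * dens[nxt]
    }
    b
  }

  env <- new.env(parent = emptyenv())
  # x = 0 is always feasible, so the empty schedule seeds the incumbent
  env$best_obj <- 0
  env$best_assign <- integer(n)
  env$nodes <- 0L
  env$stop <- FALSE
  t0 <- Sys.time()

  consider <- function(assign) {
    obj <- assignment_objective(instance, assign)
    if (obj > env$best_obj + 1e-12) {
      env$best_obj <- obj
      env$best_assign <- assign
    }
  }
  if (!is.null(warm_start)) {
    consider(improve_assignment(instance, warm_start_assignment(instance, warm_start)))
  }
  root_bound <- suffix_bound(1L, sum(instance$cap))

  # Depth-first search with an explicit stack (instances can be 1000+
  # patients deep, beyond safe recursion depth). Frame t holds the position
  # in the branching order, the accumulated profit, the next child to try
  # (1..n_opts are options, n_opts+1 is "leave unscheduled", n_opts+2 is
  # exhausted), the symmetry keys already expanded, and the edge taken from
  # the parent (for undo on backtrack).
  res <- instance$cap
  assign <- integer(n)
  depth_cap <- n + 2L
  st_i <- integer(depth_cap); st_cur <- numeric(depth_cap)
  st_state <- integer(depth_cap); st_j <- integer(depth_cap)
  st_seen <- vector("list", depth_cap)
  st_edge_p <- integer(depth_cap); st_edge_e <- integer(depth_cap)
  st_edge_d <- integer(depth_cap)
  t <- 1L
  st_i[1L] <- 1L; st_cur[1L] <- 0; st_state[1L] <- 0L; st_edge_p[1L] <- 0L
  pop <- function() {
    if (st_edge_p[t] > 0L) {
      p <- st_edge_p[t]
      res[st_edge_e[t], st_edge_d[t]] <<-
        res[st_edge_e[t], st_edge_d[t]] + dur[p]
      assign[p] <<- 0L
    }
    t <<- t - 1L
  }
  while (t > 0L && !env$stop) {
    i <- st_i[t]
    if (st_state[t] == 0L) {           # entering the node
      env$nodes <- env$nodes + 1L
      if (env$nodes %% 512L == 0L &&
          (env$nodes >= node_limit ||
           as.numeric(Sys.time() - t0, units = "secs") > time_limit)) {
        env$stop <- TRUE
        break
      }
      if (root_bound - env$best_obj <= gap_tol * max(1, abs(env$best_obj))) {
        break                          # incumbent certified within gap_tol
      }
      if (i > n) {
        if (st_cur[t] > env$best_obj + 1e-12) {
          env$best_obj <- st_cur[t]
          env$best_assign <- assign
        }
        pop(); next
      }
      if (st_cur[t] + suffix_bound(i, sum(res)) <= env$best_obj + 1e-9) {
        pop(); next
      }
      st_state[t] <- 1L; st_j[t] <- 0L; st_seen[[t]] <- character()
    }
    p <- ord[i]
    o <- instance$opts[[p]]
    n_opts <- length(o$e)
    descended <- FALSE
    while (st_j[t] < n_opts) {         # next feasible, non-symmetric option
      st_j[t] <- st_j[t] + 1L
      j <- st_j[t]
      r <- res[o$e[j], o$d[j]]
      if (r < dur[p] - 1e-9) next
      key <- paste(o$d[j], signif(r, 12))
      if (key %in% st_seen[[t]]) next  # symmetric room-day, identical subtree
      st_seen[[t]] <- c(st_seen[[t]], key)
      res[o$e[j], o$d[j]] <- r - dur[p]
      assign[p] <- j
      t <- t + 1L
      st_i[t] <- i + 1L; st_cur[t] <- st_cur[t - 1L] + o$profit[j]
      st_state[t] <- 0L
      st_edge_p[t] <- p; st_edge_e[t] <- o$e[j]; st_edge_d[t] <- o$d[j]
      descended <- TRUE
      break
    }
    if (descended) next
    if (st_j[t] == n_opts) {           # the "leave unscheduled" child
      st_j[t] <- n_opts + 1L
      t <- t + 1L
      st_i[t] <- i + 1L; st_cur[t] <- st_cur[t - 1L]
      st_state[t] <- 0L; st_edge_p[t] <- 0L
      next
    }
    pop()
  }

  completed <- !env$stop ||
    (root_bound - env$best_obj <= gap_tol * max(1, abs(env$best_obj)))
  gap <- max(0, root_bound - env$best_obj) / max(1, abs(env$best_obj))
  structure(list(assignments = assignments_frame(instance, env$best_assign),
                 objective = env$best_obj,
                 bound = if (completed) env$best_obj else root_bound,
                 gap = if (completed) 0 else gap,
                 status = if (completed) "optimal" else "limit",
                 n_nodes = env$nodes),
            class = "mip_solution")
}

empty_assignments <- function() {
  data.frame(patient_id = character(), endoscopist_id = character(),
             day = integer(), stringsAsFactors = FALSE)
}

assignments_frame <- function(instance, assign) {
  idx <- which(assign > 0L)
  if (!length(idx)) return(empty_assignments())
  data.frame(
    patient_id = instance$patients$id[idx],
    endoscopist_id = instance$endoscopists[
      vapply(idx, function(i) instance$opts[[i]]$e[assign[i]], integer(1))],
    day = instance$days[
      vapply(idx, function(i) instance$opts[[i]]$d[assign[i]], integer(1))],
    stringsAsFactors = FALSE)
}

warm_start_assignment <- function(instance, warm_start) {
  ws <- as.data.frame(warm_start)
  assign <- integer(nrow(instance$patients))
  pi <- match(ws$patient_id, instance$patients$id)
  ei <- match(ws$endoscopist_id, instance$endoscopists)
  di <- match(ws$day, instance$days)
  for (k in seq_len(nrow(ws))) {
    if (is.na(pi[k]) || is.na(ei[k]) || is.na(di[k])) next
    o <- instance$opts[[pi[k]]]
    j <- which(o$e == ei[k] & o$d == di[k])
    if (length(j)) assign[pi[k]] <- j[1L]
  }
  if (any(assignment_residuals(instance, assign) < -1e-9)) {
    stop("warm start violates room-day capacities", call. = FALSE)
  }
  assign
}

#' @export
print.mip_solution <- function(x, ...) {
  cat(sprintf("<mip_solution> %s: %d scheduled, objective %.6f (gap %.2g, %d nodes)\n",
              x$status, nrow(x$assignments), x$objective, x$gap, x$n_nodes))
  invisible(x)
}

#' Exhaustive small-instance oracle
#'
#' Enumerates every feasible assignment set of a small instance and returns
#' the true optimum. Independent of [solve_mip()] (no bounding, no symmetry
#' reduction); it refuses instances with more binary variables than
#' `max_vars`.
#'
#' @param instance a [build_instance()] result.
#' @param max_vars enumeration cap on the number of binary variables.
#' @return A `mip_solution` with status `"optimal"`.
#' @export
brute_force_oracle <- function(instance, max_vars = 20L) {
  if (instance$n_vars > max_vars) {
    stop(sprintf("instance has %d binary variables; oracle enumerates at most %d",
                 instance$n_vars, max_vars), call. = FALSE)
  }
  n <- nrow(instance$patients)
  best <- list(obj = 0, assign = integer(n))
  if (n > 0L) {
    dur <- instance$patients$dur
    res <- instance$cap
    assign <- integer(n)
    recurse <- function(i, cur) {
      if (i > n) {
        if (cur > best$obj + 1e-12) best <<- list(obj = cur, assign = assign)
        return()
      }
      o <- instance$opts[[i]]
      for (j in seq_along(o$e)) {
        if (res[o$e[j], o$d[j]] >= dur[i] - 1e-9) {
          res[o$e[j], o$d[j]] <<- res[o$e[j], o$d[j]] - dur[i]
          assign[i] <<- j
          recurse(i + 1L, cur + o$profit[j])
          res[o$e[j], o$d[j]] <<- res[o$e[j], o$d[j]] + dur[i]
          assign[i] <<- 0L
        }
      }
      recurse(i + 1L, cur)
    }
    recurse(1L, 0)
  }
  structure(list(assignments = assignments_frame(instance, best$assign),
                 objective = best$obj, bound = best$obj, gap = 0,
                 status = "optimal", n_nodes = NA_integer_),
            class = "mip_solution")
}

#' Turn a day-level solution into a timed schedule
#'
#' The assignment model decides who is seen by whom on which day; within
#' each room-day, patients are ordered by the greedy waiting-list keys
#' (priority, due date, longer appointments first) and packed back-to-back
#' from minute 0. Capacity feasibility of the solution guarantees the last
#' appointment ends within the block.
#'
#' @param solution a `mip_solution`.
#' @param instance the instance it solves.
#' @param cohort the waiting list (for sort keys).
#' @return An `endo_schedule` with policy label `"mip"`.
#' @export
sequence_within_day <- function(solution, instance, cohort) {
  asg <- solution$assignments
  if (nrow(asg) == 0L) {
    return(new_schedule(empty_schedule_frame(), policy_label = "mip"))
  }
  ci <- match(asg$patient_id, cohort$id)
  pi <- match(asg$patient_id, instance$patients$id)
  asg$planned_minutes <- instance$patients$dur[pi]
  key_ord <- order(asg$endoscopist_id, asg$day,
                   match(cohort$priority[ci], PRIORITY_LEVELS),
                   cohort$due_date[ci], -asg$planned_minutes,
                   cohort$admission_date[ci], asg$patient_id)
  asg <- asg[key_ord, , drop = FALSE]
  grp <- paste(asg$endoscopist_id, asg$day)
  start <- numeric(nrow(asg))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    start[rows] <- cumsum(c(0, asg$planned_minutes[rows]))[seq_along(rows)]
  }
  asg$start_minute <- start
  new_schedule(asg[, c("patient_id", "endoscopist_id", "day", "start_minute",
                       "planned_minutes")],
               policy_label = "mip")
}

empty_schedule_frame <- function() {
  data.frame(patient_id = character(), endoscopist_id = character(),
             day = integer(), start_minute = numeric(),
             planned_minutes = numeric(), stringsAsFactors = FALSE)
}
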