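#' Job scheduling by mixed-integer linear programming
#'
#' At every scheduling round the engine selects the subset E of pending
#' schedulable units maximizing, in lexicographic order: (1) total priority,
#' (2) extent of parallelization, (3) total size of temporary files that can
#' be deleted after the round, and (4) the summed lifetime fraction of the
#' remaining temporary files. The lexicographic order is enforced through a
#' single weighted objective
#'
#'   W1 * sum(p_j x_j) + W2 * sum(max(u_cj, 1) x_j)
#'     + W3 * sum(S_f gamma_f) + sum(S_f delta_f)
#'
#' subject to resource capacities (sum of u_rj x_j <= U_r), with
#' delta_f <= (selected consumers of f) / (open consumers of f) and
#' gamma_f <= delta_f. Each weight is chosen strictly larger than the
#' maximum value the terms to its right can jointly acquire, which is what
#' makes the single objective genuinely lexicographic: with S the total
#' temporary-file size (floored at 1) and Uc the core capacity,
#'
#'   W3 = 2*S          (> S,        the ceiling of the delta term)
#'   W2 = 2*S*(S + 1)  (> 2*S^2 + S, the ceiling of terms 3 + 4)
#'   W1 = 4*max(Uc,1)*S*(S + 1)  (> W2*Uc + 2*S^2 + S)
#'
#' The `max(u,1)` floor in the parallelization term keeps zero-core
#' streaming jobs visible to the objective; the raw u_cj is still what
#' counts against the capacity constraint.
#'
#' Since gamma and delta are determined by the x's in closed form, the
#' program reduces to a multi-dimensional knapsack with file-coverage
#' bonuses, which [solve_milp()] solves exactly by branch and bound using
#' integer arithmetic over a common denominator (no floating-point
#' precision hazard). [brute_force_schedule()] is an independent
#' subset-enumeration oracle with the same tie-break.
#'
#' @name scheduling
NULL

#' Construct a scheduling instance
#'
#' @param jobs data.frame with columns `id`, `priority`, plus one column per
#'   resource (at least `cores`): the pending schedulable units J.
#' @param capacity named integer vector of free capacities U_r.
#' @param files data.frame with columns `file`, `size`, `open_consumers`
#'   (total number of open jobs consuming the file), or `NULL`: the
#'   currently present temporary files F with at least one open consumer.
#' @param z integer matrix `nrow(jobs) x nrow(files)`: how many open
#'   consumers of file f are covered by selecting pending unit j (0/1 for
#'   plain jobs; member counts for group units).
#' @return object of class `fk_sched_instance`.
#' @export
scheduling_instance <- function(jobs, capacity, files = NULL, z = NULL) {
  stopifnot(is.data.frame(jobs), all(c("id", "priority") %in% names(jobs)))
  res_names <- setdiff(names(jobs), c("id", "priority"))
  if (!"cores" %in% res_names)
    stop("jobs must have a 'cores' usage column", call. = FALSE)
  capacity <- .as_resources(capacity)
  missing_cap <- setdiff(res_names, names(capacity))
  if (length(missing_cap))
    stop("capacity missing for resource(s): ",
         paste(missing_cap, collapse = ", "), call. = FALSE)
  if (is.null(files))
    files <- data.frame(file = character(0), size = integer(0),
                        open_consumers = integer(0),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("file", "size", "open_consumers") %in% names(files)))
  if (nrow(files)) {
    if (any(files$size < 1))
      stop("temporary file sizes must be >= 1 unit", call. = FALSE)
    if (any(files$open_consumers < 1))
      stop("every tracked temporary file needs >= 1 open consumer",
           call. = FALSE)
  }
  if (is.null(z)) z <- matrix(0L, nrow(jobs), nrow(files))
  stopifnot(nrow(z) == nrow(jobs), ncol(z) == nrow(files))
  if (nrow(files) && any(colSums(z) > files$open_consumers))
    stop("selected-consumer weights exceed open-consumer counts",
         call. = FALSE)
  ord <- order(jobs$id)
  jobs <- jobs[ord, , drop = FALSE]
  z <- z[ord, , drop = FALSE]
  rownames(jobs) <- NULL
  # a job exceeding the instance's free capacity simply cannot be selected
  # this round; exceeding the *configured* capacity is diagnosed by
  # build_instance
  structure(list(jobs = jobs, capacity = capacity, files = files, z = z,
                 resources = res_names),
            class = "fk_sched_instance")
}

# S floored at 1 so the lexicographic weights stay positive without temp
# files.
.instance_S <- function(instance) max(sum(instance$files$size), 1)

# lexicographic weights (see the scheduling help page for the derivation)
.weights <- function(instance) {
  S <- .instance_S(instance)
  Uc <- max(instance$capacity[["cores"]], 1)
  list(S = S, W1 = 4 * Uc * S * (S + 1), W2 = 2 * S * (S + 1), W3 = 2 * S)
}

.lcm2 <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  a %/% gcd(a, b) * b
}

# Common denominator for exact delta arithmetic.
.instance_denom <- function(instance) {
  d <- 1
  for (n in instance$files$open_consumers) d <- .lcm2(d, n)
  d
}

#' Exact objective value of a selection
#'
#' Computes the weighted objective with gamma and delta derived exactly from
#' the selection. The value is returned as an exact rational (integer
#' numerator over the least common multiple of the open-consumer counts).
#'
#' @param instance an `fk_sched_instance`.
#' @param selected character vector of selected unit ids (must respect the
#'   resource constraints).
#' @return list with `value` (numeric), `num`/`den` (exact rational),
#'   `gamma` and `delta` (named by file), and the four lexicographic
#'   component sums.
#' @export
objective_value <- function(instance, selected) {
  jobs <- instance$jobs
  sel <- jobs$id %in% selected
  if (length(setdiff(selected, jobs$id)))
    stop("unknown unit id(s) in selection", call. = FALSE)
  for (r in instance$resources) {
    if (sum(jobs[[r]][sel]) > instance$capacity[[r]])
      stop("selection violates capacity of resource '", r, "'",
           call. = FALSE)
  }
  w <- .weights(instance)
  D <- .instance_denom(instance)
  pr <- sum(jobs$priority[sel])
  par <- sum(pmax(jobs$cores[sel], 1))
  nf <- nrow(instance$files)
  gamma <- delta_num <- numeric(nf)
  if (nf) {
    covered <- if (any(sel)) colSums(instance$z[sel, , drop = FALSE]) else
      numeric(nf)
    n_open <- instance$files$open_consumers
    gamma <- as.numeric(covered == n_open)
    delta_num <- covered * (D / n_open)        # delta_f * D, integer
    names(gamma) <- names(delta_num) <- instance$files$file
  }
  num <- D * (w$W1 * pr + w$W2 * par +
                w$W3 * sum(instance$files$size * gamma)) +
    sum(instance$files$size * delta_num)
  list(value = num / D, num = num, den = D,
       gamma = gamma, delta = if (nf) delta_num / D else delta_num,
       priority_sum = pr, parallelization = par,
       deletable_size = sum(instance$files$size * gamma),
       lifetime_sum = if (nf) sum(instance$files$size * delta_num) / D else 0)
}

# Deterministic tie-break among co-optimal selections: the selection
# containing the smallest job id on which the two selections differ wins.
# (Because every job has strictly positive objective gain, co-optimal
# selections are never nested, so this order is total on ties.)
.selection_less <- function(a, b) {
  for (id in sort(union(a, b))) {
    ina <- id %in% a
    if (ina != (id %in% b)) return(ina)
  }
  FALSE
}

.decision <- function(instance, selected) {
  ov <- objective_value(instance, selected)
  structure(list(selected = sort(selected), gamma = ov$gamma,
                 delta = ov$delta, objective = ov$value,
                 objective_num = ov$num, objective_den = ov$den),
            class = "fk_sched_decision")
}

#' Solve the scheduling program exactly
#'
#' Branch and bound over the selection indicators in job-id order, include
#' branch first. The bound combines a fractional-knapsack relaxation of the
#' priority/parallelization gain (on the cores resource) with the largest
#' temporary-file bonus still attainable. Exploring include-first in id
#' order makes the first optimal leaf the deterministic tie-break winner
#' (the co-optimal selection containing the smallest non-shared job id), so
#' equal-bound subtrees are pruned.
#'
#' @param instance an `fk_sched_instance`.
#' @return object of class `fk_sched_decision` with fields `selected`,
#'   `gamma`, `delta`, `objective`.
#' @export
solve_milp <- function(instance) {
  jobs <- instance$jobs
  n <- nrow(jobs)
  if (n == 0L) return(.decision(instance, character(0)))
  w <- .weights(instance)
  D <- .instance_denom(instance)
  nf <- nrow(instance$files)
  sizes <- instance$files$size
  n_open <- instance$files$open_consumers
  # per-job scaled gain from the priority + parallelization terms
  gain <- D * (w$W1 * jobs$priority + w$W2 * pmax(jobs$cores, 1))
  usage <- as.matrix(jobs[, instance$resources, drop = FALSE])
  cap <- as.numeric(instance$capacity[instance$resources])
  cores_col <- match("cores", instance$resources)
  z <- instance$z
  # jobs in decreasing gain density (gain per core; zero-core jobs first)
  density_ord <- order(-(gain / pmax(jobs$cores, 1e-9)))
  suffix_z <- if (nf) apply(z, 2, function(col) rev(cumsum(rev(col))))
              else NULL
  if (nf && n == 1L) suffix_z <- matrix(suffix_z, nrow = 1L)

  file_terms <- function(covered) {
    # scaled contribution of the file terms for final coverage counts
    full <- covered == n_open
    D * w$W3 * sum(sizes[full]) + sum(sizes * covered * (D / n_open))
  }
  file_bound <- function(i, covered) {
    # optimistic: all remaining consumers of each file get selected
    reach <- covered + if (i <= n) suffix_z[i, ] else 0
    reach <- pmin(reach, n_open)
    full <- reach == n_open
    D * w$W3 * sum(sizes[full]) + sum(sizes * reach * (D / n_open))
  }
  gain_bound <- function(i, used_cores) {
    # fractional-knapsack relaxation on the cores resource over the
    # undecided suffix; a valid upper bound on the attainable job gain
    c_rem <- cap[cores_col] - used_cores
    b <- 0
    for (j in density_ord) {
      if (j < i) next
      cj <- jobs$cores[j]
      if (cj == 0) {
        b <- b + gain[j]
      } else if (c_rem >= cj) {
        b <- b + gain[j]
        c_rem <- c_rem - cj
      } else {
        b <- b + gain[j] * c_rem / cj
        break
      }
    }
    b
  }

  # DFS in job-id order, include branch first: the first optimal leaf found
  # is exactly the tie-break winner, so subtrees whose bound does not
  # exceed the incumbent can be pruned outright.
  best_val <- -Inf
  best_sel <- logical(n)
  cur_sel <- logical(n)
  recurse <- function(i, used, covered, cur_gain) {
    if (i > n) {
      leaf_val <- cur_gain + if (nf) file_terms(covered) else 0
      if (leaf_val > best_val) {
        best_val <<- leaf_val
        best_sel <<- cur_sel
      }
      return(invisible())
    }
    bound <- cur_gain + gain_bound(i, used[cores_col]) +
      if (nf) file_bound(i, covered) else 0
    # all attainable leaf values are integers on this scale, so a bound
    # within 0.25 of the incumbent cannot hide a strictly better leaf
    if (bound <= best_val + 0.25) return(invisible())
    # include job i if it fits
    if (all(used + usage[i, ] <= cap)) {
      cur_sel[i] <<- TRUE
      recurse(i + 1L, used + usage[i, ],
              covered + if (nf) z[i, ] else 0, cur_gain + gain[i])
      cur_sel[i] <<- FALSE
    }
    recurse(i + 1L, used, covered, cur_gain)
    invisible()
  }
  recurse(1L, numeric(length(cap)), if (nf) numeric(nf) else 0, 0)
  .decision(instance, jobs$id[best_sel])
}

#' Brute-force scheduling oracle
#'
#' Enumerates all 2^|J| subsets, filters by the resource constraints,
#' computes gamma and delta exactly, and returns the argmax with the same
#' deterministic tie-break as [solve_milp()]. Refuses more than 20 jobs.
#'
#' @param instance an `fk_sched_instance`.
#' @return an `fk_sched_decision`.
#' @export
brute_force_schedule <- function(instance) {
  jobs <- instance$jobs
  n <- nrow(jobs)
  if (n > 20L)
    stop("brute_force_schedule refuses |J| > 20 (", n, " given)",
         call. = FALSE)
  if (n == 0L) return(.decision(instance, character(0)))
  usage <- as.matrix(jobs[, instance$resources, drop = FALSE])
  cap <- as.numeric(instance$capacity[instance$resources])
  best <- NULL
  best_num <- -Inf
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    if (any(colSums(usage[sel, , drop = FALSE]) > cap)) next
    ov <- objective_value(instance, jobs$id[sel])
    if (ov$num > best_num ||
        (ov$num == best_num &&
         .selection_less(jobs$id[sel], best))) {
      best_num <- ov$num
      best <- jobs$id[sel]
    }
  }
  .decision(instance, best)
}

#' Greedy fallback scheduler
#'
#' Orders schedulable units by priority, then cores (descending), then by
#' whether selecting them helps complete a temporary file's consumer set,
#' then id, and packs greedily under the capacities. Provided as a
#' documented fallback and for comparison; the engine uses [solve_milp()].
#'
#' @param instance an `fk_sched_instance`.
#' @return an `fk_sched_decision`.
#' @export
greedy_schedule <- function(instance) {
  jobs <- instance$jobs
  n <- nrow(jobs)
  if (n == 0L) return(.decision(instance, character(0)))
  helps <- if (nrow(instance$files))
    as.integer(rowSums(instance$z) > 0) else rep(0L, n)
  ord <- order(-jobs$priority, -pmax(jobs$cores, 1), -helps, jobs$id)
  usage <- as.matrix(jobs[, instance$resources, drop = FALSE])
  cap <- as.numeric(instance$capacity[instance$resources])
  used <- numeric(length(cap))
  sel <- logical(n)
  for (i in ord) {
    if (all(used + usage[i, ] <= cap)) {
      sel[i] <- TRUE
      used <- used + usage[i, ]
    }
  }
  .decision(instance, jobs$id[sel])
}

#' @export
print.fk_sched_decision <- function(x, ...) {
  cat("<flowkern schedule>", length(x$selected), "unit(s) selected\n")
  if (length(x$selected))
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  if (length(x$gamma) && any(x$gamma == 1))
    cat("  deletable:", paste(names(x$gamma)[x$gamma == 1], collapse = ", "),
        "\n")
  cat("  objective:", format(x$objective), "\n")
  invisible(x)
}

#' Serialize an instance and decision to JSON
#'
#' Documented debugging shape used by the CLI's `--dump-schedule`.
#'
#' @param instance an `fk_sched_instance`.
#' @param decision an `fk_sched_decision`.
#' @return JSON text.
#' @export
schedule_to_json <- function(instance, decision) {
  jsonlite::toJSON(list(
    jobs = instance$jobs,
    capacity = as.list(instance$capacity),
    files = instance$files,
    z = instance$z,
    selected = decision$selected,
    gamma = as.list(decision$gamma),
    delta = as.list(decision$delta),
    objective = decision$objective
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
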