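test_that("the worked example schedules the three blue jobs", {
  t0 <- Sys.time()
  inst <- fig4_instance()
  dec <- solve_milp(inst)
  expect_setequal(dec$selected, c("blue1", "blue2", "blue3"))
  expect_equal(unname(dec$gamma[["tempfile"]]), 1)
  expect_equal(unname(dec$delta[["tempfile"]]), 1)
  # the tempting two-green-plus-one-blue choice scores strictly lower
  sub <- objective_value(inst, c("green1", "green2", "blue1"))
  expect_lt(sub$num / sub$den, dec$objective)
  # oracle agrees
  bf <- brute_force_schedule(inst)
  expect_identical(bf$selected, dec$selected)
  expect_equal(bf$objective, dec$objective)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
})

test_that("a single fitting job is selected with the documented objective", {
  jobs <- data.frame(id = "only", priority = 2L, cores = 3L,
                     stringsAsFactors = FALSE)
  inst <- scheduling_instance(jobs, c(cores = 4L))
  dec <- solve_milp(inst)
  expect_equal(dec$selected, "only")
  # no temp files: S floored at 1 gives W1 = 4*Uc*1*2, W2 = 2*1*2
  expect_equal(dec$objective, (4 * 4 * 1 * 2) * 2 + (2 * 1 * 2) * 3)
})

test_that("a hand-built two-job instance scores as manual arithmetic says", {
  jobs <- data.frame(id = c("p", "q"), priority = c(1L, 0L),
                     cores = c(2L, 1L), stringsAsFactors = FALSE)
  files <- data.frame(file = "t", size = 7L, open_consumers = 2L,
                      stringsAsFactors = FALSE)
  z <- matrix(c(1L, 1L), ncol = 1)
  inst <- scheduling_instance(jobs, c(cores = 3L), files, z)
  # spreadsheet-style recomputation: S = 7, Uc = 3 gives
  # W1 = 4*3*7*8 = 672, W2 = 2*7*8 = 112, W3 = 2*7 = 14
  # select both: 672*1 + 112*(2+1) + 14*7*1 + 7*1 = 1113
  ov <- objective_value(inst, c("p", "q"))
  expect_equal(ov$value, 672 + 336 + 98 + 7)
  # select p alone: 672 + 112*2 + 0 + 7*(1/2) = 899.5
  ov_p <- objective_value(inst, "p")
  expect_equal(ov_p$value, 672 + 224 + 0 + 3.5)
  # empty selection with no temp consumers selected
  expect_equal(objective_value(inst, character(0))$value, 0)
  # capacity violations are errors, not silently scored
  expect_error(objective_value(scheduling_instance(jobs, c(cores = 2L)),
                               c("p", "q")), "capacity")
})

test_that("exact solver and enumeration oracle agree on 200 random instances", {
  t0 <- Sys.time()
  for (s in 1:200) {
    inst <- generate_scheduler_instance(s)
    a <- solve_milp(inst)
    b <- brute_force_schedule(inst)
    expect_equal(a$objective_num, b$objective_num, info = paste("seed", s))
    expect_equal(a$objective_den, b$objective_den, info = paste("seed", s))
    expect_identical(a$selected, b$selected, info = paste("seed", s))
  }
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 120)
})

test_that("equal-priority selections are lexicographically dominant", {
  # selection maximizes sum(max(u,1) x); among such maximizers it
  # maximizes the deletable file size -- verified by enumeration
  t0 <- Sys.time()
  for (s in 301:400) {
    inst <- generate_scheduler_instance(s)
    inst$jobs$priority <- 0L
    dec <- solve_milp(inst)
    jobs <- inst$jobs
    usage <- as.matrix(jobs[, inst$resources, drop = FALSE])
    cap <- as.numeric(inst$capacity[inst$resources])
    best_par <- -1
    best_del <- -1
    n <- nrow(jobs)
    for (mask in 0:(2^n - 1)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
      if (any(colSums(usage[sel, , drop = FALSE]) > cap)) next
      par <- sum(pmax(jobs$cores[sel], 1))
      del <- objective_value(inst, jobs$id[sel])$deletable_size
      if (par > best_par) {
        best_par <- par
        best_del <- del
      } else if (par == best_par) best_del <- max(best_del, del)
    }
    got <- objective_value(inst, dec$selected)
    expect_equal(got$parallelization, best_par, info = paste("seed", s))
    expect_equal(got$deletable_size, best_del, info = paste("seed", s))
  }
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})

test_that("raising a job's priority keeps it selected if it fits alone", {
  for (s in 501:540) {
    inst <- generate_scheduler_instance(s, n_jobs = 6)
    pick <- inst$jobs$id[3]
    inst$jobs$priority[3] <- max(inst$jobs$priority) + 50L
    dec <- solve_milp(inst)
    expect_true(pick %in% dec$selected, info = paste("seed", s))
  }
})

test_that("returned selections never violate a capacity", {
  for (s in 601:650) {
    inst <- generate_scheduler_instance(s)
    dec <- solve_milp(inst)
    sel <- inst$jobs$id %in% dec$selected
    for (r in inst$resources)
      expect_lte(sum(inst$jobs[[r]][sel]), inst$capacity[[r]])
  }
})

test_that("greedy-by-priority can be suboptimal where the program is not", {
  # one 2-core job versus two 1-core jobs that finish a temp file, U = 2
  jobs <- data.frame(id = c("big", "t1", "t2"), priority = 0L,
                     cores = c(2L, 1L, 1L), stringsAsFactors = FALSE)
  files <- data.frame(file = "tmp", size = 50L, open_consumers = 2L,
                      stringsAsFactors = FALSE)
  z <- matrix(c(0L, 1L, 1L), ncol = 1)
  inst <- scheduling_instance(jobs, c(cores = 2L), files, z)
  dec <- brute_force_schedule(inst)
  expect_setequal(dec$selected, c("t1", "t2"))
  expect_identical(solve_milp(inst)$selected, dec$selected)
})

test_that("empty instances produce an empty, zero-objective decision", {
  inst <- scheduling_instance(
    data.frame(id = character(0), priority = integer(0),
               cores = integer(0), stringsAsFactors = FALSE),
    c(cores = 4L))
  for (dec in list(solve_milp(inst), brute_force_schedule(inst))) {
    expect_length(dec$selected, 0)
    expect_equal(dec$objective, 0)
  }
  expect_error(brute_force_schedule(scheduling_instance(
    data.frame(id = sprintf("x%02d", 1:21), priority = 0L, cores = 1L,
               stringsAsFactors = FALSE), c(cores = 1L))), "refuses")
})

test_that("schedule decisions serialize to JSON for debugging", {
  inst <- fig4_instance()
  dec <- solve_milp(inst)
  parsed <- jsonlite::fromJSON(schedule_to_json(inst, dec))
  expect_setequal(parsed$selected, c("blue1", "blue2", "blue3"))
  expect_equal(parsed$gamma$tempfile, 1)
})
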